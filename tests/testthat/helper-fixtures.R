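## Shared fixtures, built once per test run and cached.

.fixtures <- new.env(parent = emptyenv())

fixture <- function(key, builder) {
  if (!exists(key, envir = .fixtures)) {
    assign(key, builder(), envir = .fixtures)
  }
  get(key, envir = .fixtures)
}

## default scaled synthetic plastome (1/10 of the reference region lengths)
sim_default <- function(seed = 7L) {
  fixture(paste0("sim_", seed), function() {
    generate_genome(plastome_spec(scale = 1 / 10, seed = seed))
  })
}

## a light structural genome: no transcriptome payload, 1/20 scale
light_plan <- function() {
  data.frame(
    gene = c("geneA", "geneB", "geneC"),
    type = "CDS", len = c(150L, 300L, 150L), region = c("lsc", "lsc", "ssc"),
    n_introns = c(1L, 0L, 0L), unit = NA_character_,
    stringsAsFactors = FALSE
  )
}

sim_light <- function(seed) {
  generate_genome(plastome_spec(
    scale = 1 / 20, seed = seed, gene_plan = light_plan(),
    editing_n = c(cds = 2L, intron = 0L, intergenic = 1L)
  ))
}

## error-free transcript pool over the default sim, mapped
aligned_pool_clean <- function() {
  fixture("aligned_clean", function() {
    sim <- sim_default()
    iso <- simulate_isoseq(sim$genome, sim$truth, depth = 10L,
                           error_rate = 0, seed = 101L)
    list(sim = sim, iso = iso,
         alns = spliced_map_pool(iso, spliced_target(sim$genome)))
  })
}

## deep pool with 1% error for editing-efficiency work
aligned_pool_deep <- function() {
  fixture("aligned_deep", function() {
    sim <- sim_default()
    iso <- simulate_isoseq(sim$genome, sim$truth, depth = 500L,
                           error_rate = 0.01, seed = 202L)
    list(sim = sim, iso = iso,
         alns = spliced_map_pool(iso, spliced_target(sim$genome)))
  })
}

expect_same_table <- function(a, b) {
  rownames(a) <- rownames(b) <- NULL
  expect_equal(a, b, ignore_attr = TRUE)
}
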