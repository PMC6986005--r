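#!/usr/bin/env Rscript
## Call the three transcript-level feature classes — group-II introns,
## C-to-U editing sites with efficiencies, polycistronic operons — from a
## deep full-length cDNA pool and compare every call against the planted
## truth.

library(chloroplastr)

dir.create("results", showWarnings = FALSE)

sim <- generate_genome(plastome_spec(scale = 1 / 10, seed = 7L))
iso <- simulate_isoseq(sim$genome, sim$truth, depth = 200L,
                       error_rate = 0.01, seed = 91L)
cat(sprintf("mapping %d full-length cDNAs...\n", nrow(iso)))
alns <- spliced_map_pool(iso, spliced_target(sim$genome))

introns <- call_introns(alns, sim$annotation, genome = sim$genome)
write_tsv(introns, "results/intron_calls.tsv")
cat(sprintf("introns: %d calls in %d genes, %d boundary-exact vs truth\n",
            nrow(introns), length(unique(introns$gene)),
            nrow(merge(introns, sim$truth$introns,
                       by = c("donor", "acceptor")))))

sites <- call_editing(alns, sim$genome, sim$annotation, introns = introns)
write_tsv(sites, "results/editing_calls.tsv")
es <- editing_summary(sites)
m <- merge(sites, sim$truth$editing, by = "pos")
cat(sprintf("editing: %d sites (%d CDS / %d intron / %d intergenic), efficiencies %.0f-%.0f%% (median %.0f%%)\n",
            es$n, es$by_category[["CDS"]], es$by_category[["intron"]],
            es$by_category[["intergenic"]],
            100 * es$efficiency[["min"]], 100 * es$efficiency[["max"]],
            100 * es$efficiency[["median"]]))
cat(sprintf("  %d/%d truth sites recovered, max efficiency error %.3f\n",
            nrow(m), nrow(sim$truth$editing),
            max(abs(m$efficiency.x - m$efficiency.y))))

operons <- call_operons(alns, sim$annotation)
write_tsv(operons, "results/operon_calls.tsv")
cat(sprintf("operons: %d units, sizes %s\n", nrow(operons),
            paste(sort(operons$n_genes), collapse = ",")))
print(operons[, c("name", "genes", "strand", "support")])
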