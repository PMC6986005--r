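## Chloroplast read fishing by shared-k-mer containment.
##
## A read is accepted when enough of its k-mers (strand-collapsed canonical
## form) occur in the reference plastome. This stands in the pipeline where
## a long-read aligner's reference matching step would sit; the thresholds
## are deliberately permissive because long reads carry ~10-15% indel-heavy
## error, leaving only ~0.88^15 ~ 15% of 15-mers intact.

#' Build a canonical k-mer index of a reference genome
#'
#' Indexes every canonical (strand-collapsed) k-mer of the reference; for a
#' circular reference the origin-spanning k-mers are included.
#'
#' @param reference a [plastome()] or DNA string.
#' @param k odd k-mer size in `[11, 31]`.
#' @return object of class `kmer_index`.
#' @export
build_kmer_index <- function(reference, k = 15L) {
  reference <- as_plastome(reference)
  k <- as.integer(k)
  if (k %% 2L == 0L || k < 11L || k > 31L) {
    stop("k must be odd and within [11, 31]")
  }
  if (nchar(reference$seq) < k) stop("reference shorter than k")
  seq <- if (reference$circular) {
    paste0(reference$seq, substr0(reference$seq, 0L, k - 1L))
  } else reference$seq
  km <- unique(canonical_kmers(kmers_of(seq, k)))
  structure(list(k = k, kmers = km, reference_id = reference$id),
            class = "kmer_index")
}

#' @export
print.kmer_index <- function(x, ...) {
  cat(sprintf("<kmer_index> %s: %s canonical %d-mers\n", x$reference_id,
              format(length(x$kmers), big.mark = ","), x$k))
  invisible(x)
}

classify_impl <- function(seqs, index, min_frac, min_hits) {
  k <- index$k
  n_reads <- length(seqs)
  lens <- nchar(seqs)
  n_kmers <- pmax(0L, lens - k + 1L)
  hits <- integer(n_reads)
  ok <- n_kmers > 0L
  if (any(ok)) {
    all_km <- lapply(seqs[ok], kmers_of, k = k)
    flat <- canonical_kmers(unlist(all_km, use.names = FALSE))
    is_hit <- flat %in% index$kmers
    hits[ok] <- vapply(split(is_hit, rep(seq_along(all_km), lengths(all_km))),
                       sum, integer(1))
  }
  frac <- ifelse(n_kmers > 0L, hits / n_kmers, 0)
  accept <- ok & hits >= min_hits & frac >= min_frac
  data.frame(
    hits = hits, kmer_count = n_kmers, fraction = frac, accept = accept,
    reason = ifelse(!ok, "too-short", ifelse(accept, "accepted", "below-threshold")),
    stringsAsFactors = FALSE
  )
}

#' Classify a single read against a k-mer index
#'
#' Accepts when the read has at least `min_hits` index k-mers and the hit
#' fraction `hits / (len - k + 1)` is at least `min_frac`. Deterministic.
#'
#' @param read DNA string (or one-row `read_set`).
#' @param index a [build_kmer_index()] result.
#' @param min_frac minimum hit fraction.
#' @param min_hits minimum absolute hit count.
#' @return one-row data.frame: `hits`, `kmer_count`, `fraction`, `accept`,
#'   `reason` (reads shorter than k are rejected with reason "too-short").
#' @export
classify_read <- function(read, index, min_frac = 0.02, min_hits = 25L) {
  if (is.data.frame(read)) read <- read$seq
  stopifnot(length(read) == 1L)
  classify_impl(toupper(read), index, min_frac, min_hits)
}

#' Filter a read pool against a reference k-mer index
#'
#' Order-preserving; the per-read report records every decision.
#'
#' @param reads a `read_set` (or character vector of sequences).
#' @param index a [build_kmer_index()] result.
#' @param min_frac,min_hits acceptance thresholds, see [classify_read()].
#' @return list with `accepted` (the accepted subset of `reads`) and
#'   `report` (per-read data.frame with `id` and classification columns).
#' @export
filter_pool <- function(reads, index, min_frac = 0.02, min_hits = 25L) {
  if (is.character(reads)) {
    reads <- data.frame(id = sprintf("read_%05d", seq_along(reads)),
                        seq = reads, stringsAsFactors = FALSE)
  }
  if (nrow(reads) == 0L) {
    return(list(accepted = reads,
                report = data.frame(id = character(0), hits = integer(0),
                                    kmer_count = integer(0),
                                    fraction = numeric(0), accept = logical(0),
                                    reason = character(0))))
  }
  rep <- classify_impl(toupper(reads$seq), index, min_frac, min_hits)
  rep <- cbind(id = reads$id, rep)
  list(accepted = reads[rep$accept, , drop = FALSE], report = rep)
}
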