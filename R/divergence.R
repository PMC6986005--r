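## Divergence scoring of candidate barcode markers from multiple sequence
## alignments: variable sites (gap-free columns only), pairwise p-distance
## (pairwise or complete deletion), overall mean distance, marker ranking.

msa_matrix <- function(msa) {
  if (is.matrix(msa)) return(msa)
  if (is.list(msa) && !is.null(msa$seqs)) msa <- msa$seqs
  seqs <- toupper(as.character(msa))
  if (length(seqs) < 2L) stop("an alignment needs at least 2 sequences")
  if (length(unique(nchar(seqs))) != 1L) {
    stop("aligned sequences must have equal lengths")
  }
  m <- do.call(rbind, strsplit(seqs, ""))
  rownames(m) <- names(seqs)
  bad <- setdiff(unique(as.vector(m)), c("A", "C", "G", "T", "N", "-"))
  if (length(bad) > 0L) stop("unexpected alignment characters: ",
                             paste(bad, collapse = ","))
  m
}

#' Read an aligned FASTA marker file
#'
#' @param path aligned FASTA (gap character `-`).
#' @param name marker name; defaults to the file name.
#' @return a `marker_alignment` (list with `name` and named `seqs`).
#' @export
read_marker_alignment <- function(path, name = NULL) {
  ss <- Biostrings::readBStringSet(path)
  seqs <- toupper(as.character(ss))
  structure(list(name = if (is.null(name))
    sub("\\.[^.]*$", "", basename(path)) else name, seqs = seqs),
    class = "marker_alignment")
}

#' Count variable sites of an alignment
#'
#' A column is variable iff it contains no gap in any sequence and at least
#' two distinct bases among the non-N characters.
#'
#' @param msa a `marker_alignment`, named character vector of equal-length
#'   aligned sequences, or character matrix.
#' @return integer count.
#' @export
variable_sites <- function(msa) {
  m <- msa_matrix(msa)
  sum(apply(m, 2L, function(col) {
    if (any(col == "-")) return(FALSE)
    b <- unique(col[col != "N"])
    length(b) >= 2L
  }))
}

#' Pairwise p-distance between two aligned sequences
#'
#' Mismatches divided by compared sites. Under pairwise deletion, compared
#' sites exclude positions gapped or N in either sequence; under complete
#' deletion (requires the full alignment as `msa`), columns gapped in any
#' alignment member are excluded first.
#'
#' @param a,b aligned sequences (equal length) or names into `msa`.
#' @param deletion `"pairwise"` or `"complete"`.
#' @param msa optional full alignment context for complete deletion.
#' @return p-distance in `[0, 1]`.
#' @export
p_distance <- function(a, b, deletion = c("pairwise", "complete"), msa = NULL) {
  deletion <- match.arg(deletion)
  ca <- strsplit(toupper(a), "")[[1]]
  cb <- strsplit(toupper(b), "")[[1]]
  if (length(ca) != length(cb)) stop("sequences have different aligned lengths")
  usable <- rep(TRUE, length(ca))
  if (deletion == "complete") {
    if (is.null(msa)) stop("complete deletion needs the full alignment (msa=)")
    m <- msa_matrix(msa)
    if (ncol(m) != length(ca)) stop("msa length does not match the sequences")
    usable <- colSums(m == "-") == 0L
  }
  comp <- usable & ca != "-" & cb != "-" & ca != "N" & cb != "N"
  n <- sum(comp)
  if (n == 0L) stop("no comparable sites between the two sequences")
  sum(ca[comp] != cb[comp]) / n
}

#' Overall mean p-distance of an alignment
#'
#' Unweighted mean of all pairwise distances.
#'
#' @param msa alignment (see [variable_sites()]).
#' @param deletion `"pairwise"` or `"complete"`.
#' @return mean distance in `[0, 1]`.
#' @export
overall_mean_distance <- function(msa, deletion = c("pairwise", "complete")) {
  deletion <- match.arg(deletion)
  m <- msa_matrix(msa)
  nseq <- nrow(m)
  seqs <- apply(m, 1L, paste, collapse = "")
  d <- c()
  for (i in seq_len(nseq - 1L)) {
    for (j in (i + 1L):nseq) {
      d <- c(d, p_distance(seqs[i], seqs[j], deletion = deletion, msa = m))
    }
  }
  mean(d)
}

#' Divergence record of one marker alignment
#'
#' @param msa a `marker_alignment` or alignment object.
#' @param name marker name (taken from the object if absent).
#' @param deletion distance mode.
#' @return one-row data.frame: `marker`, `aligned_length`, `variable_sites`,
#'   `mean_distance`.
#' @export
divergence_record <- function(msa, name = NULL, deletion = "pairwise") {
  if (inherits(msa, "marker_alignment")) {
    if (is.null(name)) name <- msa$name
    msa <- msa$seqs
  }
  m <- msa_matrix(msa)
  data.frame(
    marker = if (is.null(name)) "marker" else name,
    aligned_length = ncol(m),
    variable_sites = variable_sites(m),
    mean_distance = overall_mean_distance(m, deletion = deletion),
    stringsAsFactors = FALSE
  )
}

#' Rank markers by overall mean distance
#'
#' Stable sort, descending by `mean_distance`; ties broken by
#' `variable_sites` (descending), then marker name.
#'
#' @param records data.frame with columns `marker`, `variable_sites`,
#'   `mean_distance` (e.g. rows from [divergence_record()]).
#' @return the ranked data.frame with a `rank` column.
#' @export
rank_markers <- function(records) {
  ord <- order(-records$mean_distance, -records$variable_sites,
               records$marker)
  out <- records[ord, , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}
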