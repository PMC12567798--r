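# Discriminative minimotif mining: literal substrings present in toxins and
# absent from non-toxins, encoded as binary flags.

all_substrings <- function(seq, min_len, max_len) {
  L <- nchar(seq)
  out <- character(0)
  for (k in min_len:max_len) {
    if (L < k) break
    out <- c(out, substring(seq, 1:(L - k + 1L), k:L))
  }
  unique(out)
}

#' Mine discriminative minimotifs
#'
#' Exhaustively enumerates substrings of length `min_len`..`max_len`
#' occurring in the positive (toxin) sequences, keeps those with zero
#' occurrences in the negative sequences, ranks them by positive coverage
#' (number of positive sequences containing the motif; ties broken by
#' shorter motif first, then lexicographically) and returns the top `top_k`
#' (fewer if fewer qualify). Mining uses label information, so inside
#' cross-validation it must be run on training folds only; pass a
#' `recorder` from [label_access_recorder()] to audit this.
#'
#' @param pos Positive (toxin) [tox_dataset()], cleaned.
#' @param neg Negative (non-toxin) [tox_dataset()], cleaned.
#' @param min_len,max_len Motif length bounds (defaults 3 and 6).
#' @param top_k Maximum number of motifs returned (default 50).
#' @param recorder Optional label-access recorder for leakage audits.
#' @return A `motif_set`: data frame with columns `motif`, `coverage`.
#' @export
discover_motifs <- function(pos, neg, min_len = 3L, max_len = 6L,
                            top_k = 50L, recorder = NULL) {
  stopifnot(inherits(pos, "tox_dataset"), inherits(neg, "tox_dataset"))
  if (length(pos) == 0L || length(neg) == 0L)
    stop("both positive and negative datasets must be non-empty")
  if (!is.null(recorder)) record_label_access(recorder, c(pos$id, neg$id))
  pos_subs <- lapply(pos$sequence, all_substrings, min_len, max_len)
  coverage <- table(unlist(pos_subs))
  neg_set <- unique(unlist(lapply(neg$sequence, all_substrings,
                                  min_len, max_len)))
  cand <- setdiff(names(coverage), neg_set)
  if (length(cand) == 0L) {
    ms <- data.frame(motif = character(0), coverage = integer(0),
                     stringsAsFactors = FALSE)
    class(ms) <- c("motif_set", "data.frame")
    return(ms)
  }
  cov <- as.integer(coverage[cand])
  ord <- order(-cov, nchar(cand), cand)
  keep <- ord[seq_len(min(top_k, length(ord)))]
  ms <- data.frame(motif = cand[keep], coverage = cov[keep],
                   stringsAsFactors = FALSE)
  rownames(ms) <- NULL
  class(ms) <- c("motif_set", "data.frame")
  ms
}

#' One-hot motif encoding
#'
#' Binary vector over a fixed motif set: 1 iff the motif occurs as a literal
#' substring of the sequence. Monotone under concatenation (appending
#' residues never turns a 1 into a 0).
#'
#' @param seq Amino-acid sequence (single string).
#' @param motif_set A `motif_set` from [discover_motifs()] (or any data
#'   frame with a `motif` column).
#' @return Named integer vector (`motif_<string>`), length `nrow(motif_set)`.
#' @export
encode_motifs <- function(seq, motif_set) {
  motifs <- motif_set$motif
  if (length(motifs) == 0L)
    return(stats::setNames(integer(0), character(0)))
  out <- vapply(motifs, function(m) as.integer(grepl(m, seq, fixed = TRUE)),
                integer(1))
  names(out) <- paste0("motif_", motifs)
  out
}

#' Write / read a motif set as plain text
#'
#' One motif per line, coverage as a second tab-separated column.
#'
#' @param ms A `motif_set`.
#' @param path File path.
#' @return Invisibly `path` (write) or the `motif_set` (read).
#' @export
write_motif_set <- function(ms, path) {
  utils::write.table(ms, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_motif_set
#' @export
read_motif_set <- function(path) {
  ms <- utils::read.table(path, sep = "\t", header = TRUE,
                          colClasses = c("character", "integer"))
  class(ms) <- c("motif_set", "data.frame")
  ms
}
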