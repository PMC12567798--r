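# FASTA IO and dataset cleaning.

#' Construct a protein dataset
#'
#' A dataset is an ordered collection of identified protein sequences sharing
#' one class label ("toxin", "non-toxin" or "unlabelled").
#'
#' @param id Character vector of unique record identifiers.
#' @param sequence Character vector of amino-acid sequences (uppercased).
#' @param description Optional character vector of FASTA descriptions.
#' @param label Class label applying to every record.
#' @return An object of class `tox_dataset`.
#' @export
tox_dataset <- function(id, sequence,
                        description = rep("", length(id)),
                        label = c("unlabelled", "toxin", "non-toxin")) {
  label <- match.arg(label)
  id <- as.character(id)
  sequence <- toupper(as.character(sequence))
  if (length(id) != length(sequence))
    stop("id and sequence must have the same length")
  if (anyDuplicated(id))
    stop("duplicate record ids: ",
         paste(unique(id[duplicated(id)]), collapse = ", "))
  structure(list(id = id, description = as.character(description),
                 sequence = sequence, label = label),
            class = "tox_dataset")
}

#' @export
length.tox_dataset <- function(x) length(x$id)

#' @export
print.tox_dataset <- function(x, ...) {
  cat(sprintf("<tox_dataset> %d sequences, label: %s\n", length(x), x$label))
  if (length(x) > 0L) {
    n <- min(3L, length(x))
    for (i in seq_len(n)) {
      cat(sprintf("  %s (%d aa) %s\n", x$id[i], nchar(x$sequence[i]),
                  substr(x$sequence[i], 1, 40)))
    }
    if (length(x) > n) cat(sprintf("  ... and %d more\n", length(x) - n))
  }
  invisible(x)
}

subset_dataset <- function(ds, idx) {
  tox_dataset(ds$id[idx], ds$sequence[idx], ds$description[idx],
              label = ds$label)
}

#' Read a FASTA file into a dataset
#'
#' Wraps `Biostrings::readAAStringSet()` with the error contract needed for
#' dataset bookkeeping: an empty file, a file whose first record lacks a `>`
#' header, or duplicate ids raise errors (duplicate ids are never silently
#' renamed, so label bookkeeping stays sound). Lowercase residues are
#' uppercased and terminal `*` stop characters stripped.
#'
#' @param path Path to a FASTA file (wrapped or unwrapped).
#' @param label Class label to attach ("toxin", "non-toxin", "unlabelled").
#' @return A [tox_dataset()].
#' @export
read_fasta <- function(path, label = "unlabelled") {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  nonblank <- which(nzchar(trimws(lines)))
  if (length(nonblank) == 0L) stop("empty FASTA: ", path)
  first <- nonblank[1L]
  if (!startsWith(trimws(lines[first]), ">"))
    stop(sprintf("malformed FASTA header at line %d of %s", first, path))
  set <- Biostrings::readAAStringSet(path)
  if (length(set) == 0L) stop("empty FASTA: ", path)
  headers <- names(set)
  ids <- vapply(strsplit(headers, "\\s+"), `[`, character(1), 1L)
  desc <- sub("^\\S+\\s*", "", headers)
  seqs <- toupper(as.character(set))
  seqs <- sub("\\*+$", "", seqs)
  if (any(!nzchar(seqs))) {
    stop("zero-length sequence for record(s): ",
         paste(ids[!nzchar(seqs)], collapse = ", "))
  }
  tox_dataset(ids, seqs, desc, label = label)
}

#' Write a dataset to FASTA
#'
#' Round-trip safe: `read_fasta(write_fasta(ds, f))` reproduces ids and
#' sequences.
#'
#' @param ds A [tox_dataset()].
#' @param path Output path.
#' @param width Line-wrap width for sequence bodies.
#' @return Invisibly, `path`.
#' @export
write_fasta <- function(ds, path, width = 60L) {
  stopifnot(inherits(ds, "tox_dataset"))
  if (length(ds) == 0L) {
    file.create(path)
    return(invisible(path))
  }
  set <- Biostrings::AAStringSet(ds$sequence)
  names(set) <- ifelse(nzchar(ds$description),
                       paste(ds$id, ds$description), ds$id)
  Biostrings::writeXStringSet(set, filepath = path, width = width)
  invisible(path)
}

#' Apply the sequence-validity rules
#'
#' Removes every record shorter than `min_len` residues and every record
#' containing an ambiguous or nonstandard residue (B, J, O, U, X or Z), the
#' cleaning rules used when assembling toxin training sets. The function is
#' idempotent and accounts for every input record:
#' `length(input) == length(kept) + nrow(rejected)`.
#'
#' @param ds A [tox_dataset()].
#' @param min_len Minimum sequence length retained (default 35).
#' @return A list with `dataset` (the cleaned [tox_dataset()]) and
#'   `rejected` (data frame with columns `id`, `reason`).
#' @export
clean_sequences <- function(ds, min_len = 35L) {
  stopifnot(inherits(ds, "tox_dataset"))
  seqs <- sub("\\*+$", "", toupper(ds$sequence))
  nonstd <- paste0("[", paste(NONSTANDARD_AA, collapse = ""), "]")
  bad_res <- grepl(nonstd, seqs)
  # anything outside the 20-letter alphabet that is not in the named
  # ambiguity set (digits, gaps, ...) is rejected for the same reason
  bad_res <- bad_res | grepl(paste0("[^", paste(aa_alphabet(), collapse = ""), "]"), seqs)
  short <- nchar(seqs) < min_len
  keep <- !(short | bad_res)
  reason <- character(0)
  rej_id <- character(0)
  if (any(!keep)) {
    rej_id <- ds$id[!keep]
    reason <- ifelse(short[!keep], sprintf("length<%d", min_len),
                     "nonstandard residue")
  }
  kept <- tox_dataset(ds$id[keep], seqs[keep], ds$description[keep],
                      label = ds$label)
  list(dataset = kept,
       rejected = data.frame(id = rej_id, reason = reason,
                             stringsAsFactors = FALSE))
}

#' Write a rejection log as TSV
#'
#' @param rejected Data frame from [clean_sequences()].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_rejection_log <- function(rejected, path) {
  utils::write.table(rejected, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
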