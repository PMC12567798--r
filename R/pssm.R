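# Evolutionary profile features: PSI-BLAST PSSM parsing, pluggable profile
# providers, and global average pooling into 20 fixed features.

# native residue column order of PSI-BLAST ASCII PSSM output
PSIBLAST_AA_ORDER <- c("A","R","N","D","C","Q","E","G","H","I",
                       "L","K","M","F","P","S","T","W","Y","V")

new_pssm <- function(id, scores, provenance = "unknown") {
  stopifnot(is.matrix(scores), ncol(scores) == 20L, nrow(scores) >= 1L)
  structure(list(id = id, scores = scores, provenance = provenance),
            class = "pssm_matrix")
}

#' @export
print.pssm_matrix <- function(x, ...) {
  cat(sprintf("<pssm_matrix> %s: %d x 20 (%s)\n", x$id, nrow(x$scores),
              x$provenance))
  invisible(x)
}

#' Parse a PSI-BLAST ASCII PSSM
#'
#' Reads the layout emitted by `psiblast -out_ascii_pssm`: header lines are
#' skipped, and for each residue position the first 20 numeric columns (the
#' log-odds score block; the second 20-column block holds percentages and is
#' ignored) are collected. Columns are stored in PSI-BLAST's native residue
#' order with the consensus residue per row as rownames.
#'
#' @param text Character vector of lines, a single string, or a file path.
#' @param id Sequence identifier to attach.
#' @return A `pssm_matrix` (fields `id`, `scores` L x 20, `provenance`).
#' @export
parse_pssm <- function(text, id = "query") {
  if (length(text) == 1L && file.exists(text)) {
    lines <- readLines(text, warn = FALSE)
  } else if (length(text) == 1L) {
    lines <- strsplit(text, "\n", fixed = TRUE)[[1]]
  } else {
    lines <- text
  }
  if (length(lines) == 0L || all(!nzchar(trimws(lines))))
    stop("empty PSSM text")
  rows <- list()
  res <- character(0)
  for (ln in lines) {
    tok <- strsplit(trimws(ln), "\\s+")[[1]]
    if (length(tok) < 22L) next
    if (is.na(suppressWarnings(as.integer(tok[1]))) ||
        !(tok[2] %in% PSIBLAST_AA_ORDER)) next
    vals <- suppressWarnings(as.numeric(tok[3:22]))
    if (any(is.na(vals)))
      stop("malformed PSSM row (wrong column count): ", ln)
    rows[[length(rows) + 1L]] <- vals
    res <- c(res, tok[2])
  }
  if (length(rows) == 0L)
    stop("no PSSM score rows found; is this an -out_ascii_pssm file?")
  scores <- do.call(rbind, rows)
  colnames(scores) <- PSIBLAST_AA_ORDER
  rownames(scores) <- res
  new_pssm(id, scores, provenance = "psiblast-ascii")
}

#' Format a PSSM as ASCII text
#'
#' Writes the score block back in a `-out_ascii_pssm`-compatible layout, so
#' that `parse_pssm(format_pssm(p))` round-trips all scores.
#'
#' @param p A `pssm_matrix`.
#' @return Character vector of lines.
#' @export
format_pssm <- function(p) {
  stopifnot(inherits(p, "pssm_matrix"))
  header <- c("", "Last position-specific scoring matrix computed",
              paste0("            ",
                     paste(sprintf("%3s", PSIBLAST_AA_ORDER), collapse = " ")))
  res <- rownames(p$scores)
  if (is.null(res)) res <- rep("A", nrow(p$scores))
  body <- vapply(seq_len(nrow(p$scores)), function(i) {
    paste0(sprintf("%5d %s ", i, res[i]),
           paste(sprintf("%3d", round(p$scores[i, ])), collapse = " "),
           "  ", paste(rep("0", 20), collapse = " "), "  0.00 0.00")
  }, character(1))
  c(header, body, "")
}

#' Global average pooling of a PSSM
#'
#' Compresses an L x 20 position-specific scoring matrix to a fixed
#' 20-vector by column means: `GAP_j = (1/L) sum_i P_ij`. Feature names are
#' `PSSM_A` .. `PSSM_Y` in alphabetical residue order (remapped from
#' PSI-BLAST's native column order).
#'
#' @param p A `pssm_matrix`.
#' @return Named numeric vector of length 20.
#' @export
gap_pool <- function(p) {
  stopifnot(inherits(p, "pssm_matrix"))
  m <- colMeans(p$scores)
  m <- m[aa_alphabet()]
  names(m) <- paste0("PSSM_", aa_alphabet())
  m
}

#' Run PSI-BLAST and capture the PSSM
#'
#' Invokes the external `psiblast` executable against a formatted protein
#' database and parses the resulting ASCII PSSM. When the search yields no
#' hits (so no PSSM is produced), the deterministic substitution-matrix
#' fallback profile is returned instead, flagged by its provenance field.
#'
#' @param seq Amino-acid sequence (single string).
#' @param database Path to a formatted BLAST protein database.
#' @param id Sequence identifier.
#' @param evalue E-value inclusion threshold (default 0.001).
#' @param iterations Number of PSI-BLAST iterations (default 3).
#' @param exe Name/path of the psiblast executable.
#' @return A `pssm_matrix`.
#' @export
run_psiblast <- function(seq, database, id = "query", evalue = 0.001,
                         iterations = 3L, exe = "psiblast") {
  if (Sys.which(exe) == "")
    stop("psiblast executable not found (", exe, "); either install BLAST+, ",
         "point featurization at a directory of precomputed ASCII PSSMs ",
         "(pssm_provider_dir), or use the substitution-matrix fallback ",
         "(pssm_provider_fallback)")
  qf <- tempfile(fileext = ".fasta")
  pf <- tempfile(fileext = ".pssm")
  on.exit(unlink(c(qf, pf)), add = TRUE)
  writeLines(c(paste0(">", id), seq), qf)
  out <- suppressWarnings(system2(exe,
    c("-query", qf, "-db", database,
      "-evalue", format(evalue, scientific = FALSE),
      "-num_iterations", iterations,
      "-out_ascii_pssm", pf, "-out", "/dev/null",
      "-num_threads", "1"),
    stdout = TRUE, stderr = TRUE))
  status <- attr(out, "status")
  if (!is.null(status) && status != 0L)
    stop("psiblast failed (exit ", status, "): ",
         paste(utils::tail(out, 3), collapse = " | "))
  if (!file.exists(pf) || file.size(pf) == 0L) {
    p <- fallback_profile(seq, id)
    p$provenance <- "fallback-nohits"
    return(p)
  }
  p <- parse_pssm(pf, id = id)
  p$provenance <- "psiblast"
  p
}

# deterministic pseudo-profile: one substitution-matrix row per residue
fallback_profile <- function(seq, id = "query", matrix_name = "BLOSUM62") {
  if (is.null(.toxscreen_cache[[matrix_name]])) {
    env <- new.env()
    utils::data(list = matrix_name, package = "Biostrings", envir = env)
    .toxscreen_cache[[matrix_name]] <-
      env[[matrix_name]][aa_alphabet(), PSIBLAST_AA_ORDER]
  }
  sub <- .toxscreen_cache[[matrix_name]]
  chars <- seq_chars(seq)
  scores <- sub[chars, , drop = FALSE]
  rownames(scores) <- chars
  new_pssm(id, scores, provenance = "fallback-blosum62")
}

#' PSSM providers
#'
#' A provider is a function `(id, seq) -> pssm_matrix` used by
#' [featurize()]. Three are available: a directory of precomputed ASCII
#' PSSMs keyed by sequence id (`<id>.pssm`), a live PSI-BLAST wrapper, and a
#' deterministic fallback that builds a pseudo-profile from BLOSUM62 rows
#' (useful where no sequence database is at hand; features are flagged by
#' provenance).
#'
#' @param dir Directory containing `<id>.pssm` ASCII files.
#' @return A provider function.
#' @export
pssm_provider_dir <- function(dir) {
  force(dir)
  function(id, seq) {
    f <- file.path(dir, paste0(id, ".pssm"))
    if (!file.exists(f))
      stop("no precomputed PSSM for sequence id: ", id)
    parse_pssm(f, id = id)
  }
}

#' @rdname pssm_provider_dir
#' @inheritParams run_psiblast
#' @export
pssm_provider_psiblast <- function(database, evalue = 0.001,
                                   iterations = 3L, exe = "psiblast") {
  force(database)
  function(id, seq) run_psiblast(seq, database, id = id, evalue = evalue,
                                 iterations = iterations, exe = exe)
}

#' @rdname pssm_provider_dir
#' @export
pssm_provider_fallback <- function() {
  function(id, seq) fallback_profile(seq, id = id)
}
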