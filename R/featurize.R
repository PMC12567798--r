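# Feature-matrix assembly: fixed family order, stable unique column names,
# and the packaged manifest of published selected features.

#' Descriptor configuration
#'
#' Collects the tunable parameters of the descriptor families. At the
#' defaults the eight classical families contribute exactly 1920 columns
#' (AAC 20, DPC 400, Moreau-Broto/Moran/Geary autocorrelation 240 each, CTD
#' 147, conjoint triad 343, QSO/SOCN 160, PAAC 50, APAAC 80), the PSSM pool
#' 20, the amino-acid groups + length block 7. The AAindex family is off by
#' default (`aaindex_table = NULL`); supply a table to enable it.
#'
#' @param families Which classical families to compute.
#' @param nlag Autocorrelation and sequence-order maximum lag (default 30).
#' @param lambda PAAC/APAAC correlation tiers (default 30).
#' @param paac_w PAAC/APAAC weight (default 0.05).
#' @param qso_w QSO weight (default 0.1).
#' @param autocorr_indices AAindex accessions for the autocorrelation
#'   property scales (8 by default).
#' @param ctd_props Three-class property encodings for CTD.
#' @param aaindex_table Optional AAindex table (named list of 20-vectors);
#'   NULL disables the family.
#' @param include_groups Include the amino-acid group counts + length block.
#' @return A `descriptor_config` list.
#' @export
descriptor_config <- function(families = c("aac", "dpc", "mb", "moran",
                                           "geary", "ctd", "ctriad", "qso",
                                           "paac", "apaac"),
                              nlag = 30L, lambda = 30L,
                              paac_w = 0.05, qso_w = 0.1,
                              autocorr_indices = autocorr_default_indices(),
                              ctd_props = ctd_properties(),
                              aaindex_table = NULL,
                              include_groups = TRUE) {
  stopifnot(nlag >= 1L, lambda >= 0L)
  structure(list(families = families, nlag = as.integer(nlag),
                 lambda = as.integer(lambda), paac_w = paac_w, qso_w = qso_w,
                 autocorr_indices = autocorr_indices, ctd_props = ctd_props,
                 aaindex_table = aaindex_table,
                 include_groups = include_groups,
                 ctriad_normalization = "(f - min f) / max f"),
            class = "descriptor_config")
}

# all classical-family features for one sequence, in fixed family order;
# autocorrelation families carry a family prefix so the three methods'
# otherwise identical names stay unique in the assembled matrix
protr_block <- function(seq, config) {
  fams <- config$families
  out <- numeric(0)
  add <- function(out, v) c(out, v)
  if ("aac" %in% fams) out <- add(out, aac(seq))
  if ("dpc" %in% fams) out <- add(out, dpc(seq))
  for (m in c("mb", "moran", "geary")) {
    if (m %in% fams) {
      v <- autocorrelation(seq,
                           method = c(mb = "moreau-broto", moran = "moran",
                                      geary = "geary")[[m]],
                           indices = config$autocorr_indices,
                           nlag = config$nlag)
      names(v) <- paste0(m, ".", names(v))
      out <- add(out, v)
    }
  }
  if ("ctd" %in% fams) out <- add(out, ctd(seq, config$ctd_props))
  if ("ctriad" %in% fams) out <- add(out, conjoint_triad(seq))
  if ("qso" %in% fams)
    out <- add(out, qso_socn(seq, nlag = config$nlag, w = config$qso_w))
  if ("paac" %in% fams)
    out <- add(out, paac(seq, lambda = config$lambda, w = config$paac_w))
  if ("apaac" %in% fams)
    out <- add(out, apaac(seq, lambda = config$lambda, w = config$paac_w))
  out
}

#' Featurize a dataset
#'
#' Computes the full feature matrix for a cleaned dataset: the classical
#' descriptor families in fixed documented order, then the pooled PSSM
#' block, the amino-acid group counts + length, the minimotif one-hot block
#' (if a motif set is given) and the AAindex profile (if a table is
#' configured). Deterministic for fixed inputs; any per-family error is
#' re-raised with the offending sequence id attached.
#'
#' @param ds A cleaned [tox_dataset()].
#' @param config A [descriptor_config()].
#' @param pssm_provider Provider function from [pssm_provider_dir()],
#'   [pssm_provider_psiblast()] or [pssm_provider_fallback()] (default);
#'   NULL drops the PSSM block.
#' @param motif_set Optional motif set from [discover_motifs()].
#' @return Numeric matrix, rows = sequence ids, columns = feature names;
#'   the configuration is attached as attribute `"config"`.
#' @export
featurize <- function(ds, config = descriptor_config(),
                      pssm_provider = pssm_provider_fallback(),
                      motif_set = NULL) {
  stopifnot(inherits(ds, "tox_dataset"), inherits(config, "descriptor_config"))
  if (length(ds) == 0L) stop("cannot featurize an empty dataset")
  rows <- vector("list", length(ds))
  for (i in seq_along(ds$id)) {
    id <- ds$id[i]; seq <- ds$sequence[i]
    v <- tryCatch({
      x <- protr_block(seq, config)
      if (!is.null(pssm_provider))
        x <- c(x, gap_pool(pssm_provider(id, seq)))
      if (isTRUE(config$include_groups))
        x <- c(x, aa_groups_length(seq))
      if (!is.null(motif_set))
        x <- c(x, encode_motifs(seq, motif_set))
      if (!is.null(config$aaindex_table))
        x <- c(x, aaindex_profile(seq, config$aaindex_table))
      x
    }, error = function(e) {
      stop(sprintf("featurization failed for sequence '%s': %s",
                   id, conditionMessage(e)), call. = FALSE)
    })
    rows[[i]] <- v
  }
  nm <- names(rows[[1]])
  if (anyDuplicated(nm))
    stop("internal error: duplicated feature names: ",
         paste(unique(nm[duplicated(nm)]), collapse = ", "))
  mat <- do.call(rbind, rows)
  rownames(mat) <- ds$id
  colnames(mat) <- nm
  attr(mat, "config") <- config
  mat
}

#' Write / read a feature matrix as TSV
#'
#' First column `id`, remaining columns the features (header row = names).
#'
#' @param fm Feature matrix from [featurize()].
#' @param path Output path.
#' @return Invisibly `path` (write) or the matrix (read).
#' @export
write_feature_matrix <- function(fm, path) {
  df <- data.frame(id = rownames(fm), fm, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_feature_matrix
#' @export
read_feature_matrix <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df$id
  m
}

#' The published 88-feature manifest
#'
#' The selected-feature list shipped with the package (feature group +
#' feature name per row), so users can bypass selection and reproduce the
#' published feature space.
#'
#' @return Data frame with columns `group` and `name` (88 rows).
#' @export
feature_manifest <- function() {
  path <- system.file("extdata", "selected_feature_manifest.tsv",
                      package = "toxscreen")
  utils::read.table(path, sep = "\t", header = TRUE,
                    stringsAsFactors = FALSE)
}

#' Resolve manifest entries to feature-matrix columns
#'
#' Maps published (group, name) pairs onto this package's column names:
#' most names are identical; autocorrelation names gain their family prefix
#' (`mb.`, `geary.`), and quasi-sequence-order names published against the
#' Schneider-Wrede matrix map onto the package's side-chain physicochemical
#' distance block (`scdist.`).
#'
#' @param manifest Data frame with columns `group`, `name`
#'   (default: the packaged 88-feature manifest).
#' @param columns Character vector of available feature-matrix columns.
#' @return The manifest with added columns `column` (mapped name) and
#'   `resolved` (logical: present among `columns`).
#' @export
resolve_manifest <- function(manifest = feature_manifest(), columns) {
  map_one <- function(group, name) {
    switch(group,
      protr_mb    = paste0("mb.", name),
      protr_moran = paste0("moran.", name),
      protr_geary = paste0("geary.", name),
      protr_qso   = sub("^Schneider\\.", "scdist.", name),
      name)
  }
  manifest$column <- mapply(map_one, manifest$group, manifest$name,
                            USE.NAMES = FALSE)
  manifest$resolved <- manifest$column %in% columns
  manifest
}
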