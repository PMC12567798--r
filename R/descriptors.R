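# Classical sequence descriptor families. All functions take one cleaned
# sequence (a string over the 20 standard residues) and return a named
# numeric vector; feature names follow the conventions of the protr family
# of descriptor libraries so published feature lists remain readable.

#' Amino acid composition (AAC)
#'
#' Relative frequency of each of the 20 residues; 20 values summing to 1.
#'
#' @param seq Cleaned amino-acid sequence (single string).
#' @return Named numeric vector (names are one-letter residue codes).
#' @export
aac <- function(seq) {
  chars <- seq_chars(seq)
  counts <- table(factor(chars, levels = aa_alphabet()))
  out <- as.numeric(counts) / length(chars)
  names(out) <- aa_alphabet()
  out
}

#' Dipeptide composition (DPC)
#'
#' Relative frequencies of the 400 overlapping residue pairs; sums to 1.
#'
#' @inheritParams aac
#' @return Named numeric vector of length 400 (names like "SL").
#' @export
dpc <- function(seq) {
  chars <- seq_chars(seq)
  L <- length(chars)
  if (L < 2L) stop("dpc requires a sequence of length >= 2")
  aa <- aa_alphabet()
  lev <- paste0(rep(aa, each = 20L), aa)
  pairs <- paste0(chars[-L], chars[-1L])
  counts <- table(factor(pairs, levels = lev))
  out <- as.numeric(counts) / (L - 1L)
  names(out) <- lev
  out
}

# map residues to 1/2/3 classes for one CTD property
ctd_class_map <- function(groups) {
  cls <- integer(20)
  names(cls) <- aa_alphabet()
  for (g in seq_along(groups)) cls[groups[[g]]] <- g
  cls
}

#' Composition/transition/distribution (CTD) descriptors
#'
#' For each of seven three-class physicochemical encodings
#' (hydrophobicity, normalized van der Waals volume, polarity,
#' polarizability, charge, secondary structure, solvent accessibility):
#' composition (class fractions, 21 values), transition (fractions of
#' adjacent cross-class pairs, 21 values) and distribution (percent position
#' in the sequence of the 1st, 25%, 50%, 75% and 100% occurrence of each
#' class, 105 values). 147 values in total.
#'
#' @inheritParams aac
#' @param properties List of three-class encodings, as [ctd_properties()].
#' @return Named numeric vector of length 147.
#' @export
ctd <- function(seq, properties = ctd_properties()) {
  chars <- seq_chars(seq)
  L <- length(chars)
  pn <- names(properties)
  comp <- numeric(0); tran <- numeric(0); dist <- numeric(0)
  for (i in seq_along(properties)) {
    cls <- ctd_class_map(properties[[i]])[chars]
    # composition
    cc <- tabulate(cls, nbins = 3L) / L
    names(cc) <- paste0(pn[i], ".Group", 1:3)
    comp <- c(comp, cc)
    # transition: unordered adjacent cross-class pairs, normalized by L-1
    tt <- c(0, 0, 0)
    if (L >= 2L) {
      a <- cls[-L]; b <- cls[-1L]
      lo <- pmin(a, b); hi <- pmax(a, b)
      tt <- c(sum(lo == 1 & hi == 2), sum(lo == 1 & hi == 3),
              sum(lo == 2 & hi == 3)) / (L - 1L)
    }
    names(tt) <- paste0("prop", i, c(".Tr1221", ".Tr1331", ".Tr2332"))
    tran <- c(tran, tt)
    # distribution: percent positions of quantile occurrences per class
    for (g in 1:3) {
      pos <- which(cls == g)
      n <- length(pos)
      if (n == 0L) {
        dd <- rep(0, 5)
      } else {
        idx <- c(1L, pmax(1L, ceiling(c(0.25, 0.5, 0.75) * n)), n)
        dd <- pos[idx] / L * 100
      }
      names(dd) <- paste0("prop", i, ".G", g,
                          ".residue", c(0, 25, 50, 75, 100))
      dist <- c(dist, dd)
    }
  }
  c(comp, tran, dist)
}

#' Conjoint triad descriptors
#'
#' Residues are mapped to seven physicochemical classes; the 343 contiguous
#' class triads are counted and normalized as `(f - min(f)) / max(f)`, the
#' convention of the original conjoint-triad encoding.
#'
#' @inheritParams aac
#' @return Named numeric vector of length 343 (names "VS111".."VS777").
#' @export
conjoint_triad <- function(seq) {
  chars <- seq_chars(seq)
  L <- length(chars)
  if (L < 3L) stop("conjoint_triad requires a sequence of length >= 3")
  classes <- conjoint_triad_classes()
  cls <- integer(20); names(cls) <- aa_alphabet()
  for (g in seq_along(classes)) cls[classes[[g]]] <- g
  digits <- cls[chars]
  tri <- paste0("VS", digits[1:(L - 2L)], digits[2:(L - 1L)], digits[3:L])
  lev <- paste0("VS", rep(1:7, each = 49L), rep(rep(1:7, each = 7L), 7L),
                rep(1:7, 49L))
  f <- as.numeric(table(factor(tri, levels = lev)))
  out <- (f - min(f)) / max(f)
  names(out) <- lev
  out
}

#' Sequence autocorrelation descriptors
#'
#' Normalized Moreau-Broto, Moran or Geary autocorrelation of physicochemical
#' property profiles along the sequence. Property scales are z-scored over
#' the 20 residues (population standard deviation) before mapping onto the
#' sequence. Degenerate profiles with zero positional variance yield 0 for
#' Moran and Geary rather than 0/0.
#'
#' @inheritParams aac
#' @param method One of "moreau-broto", "moran", "geary".
#' @param indices Character vector of AAindex accessions (resolved through
#'   [aaindex_default_table()]) or a named list of 20-value numeric vectors.
#' @param nlag Maximum lag (default 30); requires `nchar(seq) > nlag`.
#' @return Named numeric vector of length `length(indices) * nlag`
#'   (names like "CHAM820102.lag3").
#' @export
autocorrelation <- function(seq,
                            method = c("moreau-broto", "moran", "geary"),
                            indices = autocorr_default_indices(),
                            nlag = 30L) {
  method <- match.arg(method)
  chars <- seq_chars(seq)
  L <- length(chars)
  if (L <= nlag)
    stop(sprintf("sequence length %d must exceed nlag = %d", L, nlag))
  if (is.character(indices)) {
    tab <- aaindex_default_table()
    missing <- setdiff(indices, names(tab))
    if (length(missing) > 0L)
      stop("unknown AAindex accession(s): ", paste(missing, collapse = ", "))
    props <- tab[indices]
  } else {
    props <- indices
  }
  out <- numeric(length(props) * nlag)
  names(out) <- paste0(rep(names(props), each = nlag), ".lag",
                       rep(seq_len(nlag), length(props)))
  k <- 0L
  for (p in props) {
    prof <- sequence_profile(paste(chars, collapse = ""),
                             standardize_property(p[aa_alphabet()]))
    pbar <- mean(prof)
    cvar <- sum((prof - pbar)^2)
    for (d in seq_len(nlag)) {
      i <- seq_len(L - d)
      val <- switch(method,
        "moreau-broto" = sum(prof[i] * prof[i + d]) / (L - d),
        "moran" = if (cvar == 0) 0 else
          (sum((prof[i] - pbar) * (prof[i + d] - pbar)) / (L - d)) /
          (cvar / L),
        "geary" = if (cvar == 0) 0 else
          (sum((prof[i] - prof[i + d])^2) / (2 * (L - d))) /
          (cvar / (L - 1L))
      )
      k <- k + 1L
      out[k] <- val
    }
  }
  out
}

#' Quasi-sequence-order descriptors and sequence-order coupling numbers
#'
#' For each of two inter-residue distance matrices (the package's side-chain
#' physicochemical distance, prefix `scdist`, and the Grantham distance,
#' prefix `Grantham`), computes the sequence-order coupling numbers
#' `tau_d = sum_i d(R_i, R_(i+d))^2` for lags 1..nlag (the SOCN block,
#' `<matrix>.lag<d>`) and the quasi-sequence-order descriptors
#' `Xr_u = f_u / (sum f + w sum tau)` and `Xd_d = w tau_d / (sum f + w sum
#' tau)` (`<matrix>.Xr.<residue>` and `<matrix>.Xd.<d>`). With `w = 0` the
#' first 20 QSO values reduce to the amino acid composition.
#'
#' @inheritParams aac
#' @param nlag Maximum lag (default 30); requires `nchar(seq) > nlag`.
#' @param w Weighting factor for the sequence-order effect (default 0.1).
#' @return Named numeric vector of length `2 * nlag + 2 * (20 + nlag)`
#'   (160 at the default nlag = 30).
#' @export
qso_socn <- function(seq, nlag = 30L, w = 0.1) {
  chars <- seq_chars(seq)
  L <- length(chars)
  if (L <= nlag)
    stop(sprintf("sequence length %d must exceed nlag = %d", L, nlag))
  mats <- list(scdist = scdist_matrix(), Grantham = grantham_matrix())
  f <- aac(seq)
  socn <- numeric(0); qso <- numeric(0)
  for (m in names(mats)) {
    D <- mats[[m]]
    tau <- vapply(seq_len(nlag), function(d) {
      i <- seq_len(L - d)
      sum(D[cbind(chars[i], chars[i + d])]^2)
    }, numeric(1))
    names(tau) <- paste0(m, ".lag", seq_len(nlag))
    socn <- c(socn, tau)
    denom <- sum(f) + w * sum(tau)
    xr <- f / denom
    names(xr) <- paste0(m, ".Xr.", aa_alphabet())
    xd <- w * tau / denom
    names(xd) <- paste0(m, ".Xd.", seq_len(nlag))
    qso <- c(qso, xr, xd)
  }
  c(socn, qso)
}

#' Pseudo amino acid composition (PAAC)
#'
#' Chou's type-1 pseudo amino acid composition over the standard property
#' trio (hydrophobicity, hydrophilicity, side-chain mass), 20 + lambda
#' values.
#'
#' @inheritParams aac
#' @param lambda Number of sequence-order correlation tiers (default 30);
#'   requires `nchar(seq) > lambda`.
#' @param w Weighting factor (default 0.05).
#' @return Named numeric vector ("Xc1.<residue>", "Xc2.lambda.<d>").
#' @export
paac <- function(seq, lambda = 30L, w = 0.05) {
  chars <- seq_chars(seq)
  L <- length(chars)
  if (lambda > 0L && L <= lambda)
    stop(sprintf("sequence length %d must exceed lambda = %d", L, lambda))
  props <- lapply(paac_properties(), standardize_property)
  profs <- lapply(props, function(p) unname(p[chars]))
  theta <- numeric(lambda)
  if (lambda > 0L) {
    for (d in seq_len(lambda)) {
      i <- seq_len(L - d)
      acc <- 0
      for (pr in profs) acc <- acc + (pr[i + d] - pr[i])^2
      theta[d] <- mean(acc / length(profs))
    }
  }
  f <- aac(seq)
  denom <- sum(f) + w * sum(theta)
  out <- c(f / denom, if (lambda > 0L) w * theta / denom else numeric(0))
  names(out) <- c(paste0("Xc1.", aa_alphabet()),
                  if (lambda > 0L) paste0("Xc2.lambda.", seq_len(lambda)))
  out
}

#' Amphiphilic pseudo amino acid composition (APAAC)
#'
#' Chou's type-2 (amphiphilic) pseudo amino acid composition using
#' hydrophobicity and hydrophilicity correlation functions, 20 + 2*lambda
#' values.
#'
#' @inheritParams paac
#' @return Named numeric vector ("Pc1.<residue>",
#'   "Pc2.Hydrophobicity.<d>", "Pc2.Hydrophilicity.<d>").
#' @export
apaac <- function(seq, lambda = 30L, w = 0.05) {
  chars <- seq_chars(seq)
  L <- length(chars)
  if (lambda > 0L && L <= lambda)
    stop(sprintf("sequence length %d must exceed lambda = %d", L, lambda))
  props <- lapply(paac_properties()[c("hydrophobicity", "hydrophilicity")],
                  standardize_property)
  h1 <- unname(props[[1]][chars]); h2 <- unname(props[[2]][chars])
  tau <- numeric(2L * lambda)
  tnames <- character(2L * lambda)
  if (lambda > 0L) {
    for (d in seq_len(lambda)) {
      i <- seq_len(L - d)
      tau[2L * d - 1L] <- sum(h1[i] * h1[i + d]) / (L - d)
      tau[2L * d] <- sum(h2[i] * h2[i + d]) / (L - d)
      tnames[2L * d - 1L] <- paste0("Pc2.Hydrophobicity.", d)
      tnames[2L * d] <- paste0("Pc2.Hydrophilicity.", d)
    }
  }
  f <- aac(seq)
  denom <- sum(f) + w * sum(tau)
  out <- c(f / denom, if (lambda > 0L) w * tau / denom else numeric(0))
  names(out) <- c(paste0("Pc1.", aa_alphabet()), tnames[nzchar(tnames)])
  out
}

#' Combined PAAC + APAAC block
#'
#' @inheritParams paac
#' @return Named numeric vector of length `(20 + lambda) + (20 + 2*lambda)`
#'   (130 at the default lambda = 30).
#' @export
paac_apaac <- function(seq, lambda = 30L, w = 0.05) {
  c(paac(seq, lambda, w), apaac(seq, lambda, w))
}

#' AAindex physicochemical profile
#'
#' One value per index: the mean of the index over all residues of the
#' sequence. Indices with missing residue values are excluded from the
#' default table.
#'
#' @inheritParams aac
#' @param aaindex_table Named list of 20-value numeric vectors (names are
#'   AAindex accessions), e.g. [aaindex_default_table()] or the result of
#'   [read_aaindex()].
#' @return Named numeric vector, one value per usable index.
#' @export
aaindex_profile <- function(seq, aaindex_table = aaindex_default_table()) {
  chars <- seq_chars(seq)
  vapply(aaindex_table, function(v) mean(v[chars]), numeric(1))
}

#' Amino-acid group counts and sequence length
#'
#' Counts of residues in six physicochemical groups -- hydrophobic
#' (V,I,L,F,M,W,Y,C), negatively charged (D,E), positively charged (R,K,H),
#' conformational (G,P), polar (N,Q,S) and other (A,T) -- plus the raw
#' sequence length. The six counts always sum to the length.
#'
#' @inheritParams aac
#' @return Named numeric vector of length 7.
#' @export
aa_groups_length <- function(seq) {
  chars <- seq_chars(seq)
  groups <- aa_six_groups()
  out <- vapply(groups, function(g) sum(chars %in% g), numeric(1))
  c(out, length = length(chars))
}

#' Read an AAindex1 flat file
#'
#' Parses the standard AAindex1 record format ("H" accession line, "I" value
#' block with the 20 residue values in the A/L R/K ... column layout, records
#' terminated by "//"). Indices with non-numeric ("NA") residue values are
#' dropped.
#'
#' @param path Path to an AAindex1-format flat file.
#' @return Named list of numeric vectors (length 20, alphabetical order).
#' @export
read_aaindex <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  if (length(lines) == 0L) stop("empty AAindex file: ", path)
  recs <- split(lines, cumsum(c(TRUE, lines[-length(lines)] == "//")))
  row1 <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I")
  row2 <- c("L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")
  out <- list()
  for (rec in recs) {
    hline <- grep("^H ", rec, value = TRUE)
    iline <- grep("^I ", rec)
    if (length(hline) == 0L || length(iline) == 0L) next
    acc <- trimws(sub("^H ", "", hline[1]))
    if (length(rec) < iline[1] + 2L)
      stop("truncated AAindex record: ", acc)
    vals1 <- suppressWarnings(as.numeric(strsplit(trimws(rec[iline[1] + 1L]),
                                                  "\\s+")[[1]]))
    vals2 <- suppressWarnings(as.numeric(strsplit(trimws(rec[iline[1] + 2L]),
                                                  "\\s+")[[1]]))
    if (length(vals1) != 10L || length(vals2) != 10L)
      stop("malformed AAindex value block in record: ", acc)
    v <- c(vals1, vals2)
    names(v) <- c(row1, row2)
    if (any(!is.finite(v))) next
    out[[acc]] <- v[aa_alphabet()]
  }
  if (length(out) == 0L)
    stop("no parseable AAindex records in: ", path)
  out
}
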