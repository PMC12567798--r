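# Synthetic labelled datasets with controllable toxin-like signal, so every
# pipeline stage is testable without external downloads. The signal is
# multi-channel -- cysteine enrichment (composition), planted minimotifs and
# a dipeptide bias -- mirroring the kinds of sequence evidence that separate
# short cysteine-rich toxins from a diverse proteome background.

# background residue frequencies (approximate proteome-wide composition)
background_frequencies <- function() {
  f <- c(A = 0.0826, C = 0.0137, D = 0.0546, E = 0.0674, F = 0.0386,
         G = 0.0708, H = 0.0227, I = 0.0593, K = 0.0582, L = 0.0965,
         M = 0.0241, N = 0.0406, P = 0.0472, Q = 0.0393, R = 0.0553,
         S = 0.0664, T = 0.0535, V = 0.0686, W = 0.0110, Y = 0.0292)
  f / sum(f)
}

#' Specification of a synthetic benchmark dataset
#'
#' Positives emulate short cysteine-rich toxins: residue frequencies with
#' the cysteine probability multiplied by `cys_enrichment` (renormalized),
#' short minimotifs planted with probability `plant_prob` each, and an
#' optional dipeptide bias (first-order repeat boost for the named pairs).
#' Negatives are drawn from the background frequencies and are guaranteed
#' free of the planted motifs (rejection sampling). Lengths follow a
#' lognormal body truncated to `[min_len, max_len]`.
#'
#' @param n_pos,n_neg Number of positive / negative sequences.
#' @param min_len Minimum length (default 35, the cleaning cutoff).
#' @param max_len Maximum length (default 400).
#' @param meanlog,sdlog Lognormal length parameters (default log(90), 0.45:
#'   a short-protein body typical of secreted toxins).
#' @param cys_enrichment Multiplier (>= 1) on the cysteine frequency in
#'   positives (default 3).
#' @param motifs Planted minimotifs (default five cysteine-rich 5-mers).
#' @param plant_prob Per-motif planting probability per positive sequence.
#' @param dipeptide_boost Multiplier on P(next = b | current = a) for each
#'   named pair (default doubles "CC"); applied to positives only.
#' @param seed Random seed.
#' @return A `synthetic_spec` list.
#' @export
synthetic_spec <- function(n_pos = 400L, n_neg = 400L, min_len = 35L,
                           max_len = 400L, meanlog = log(90), sdlog = 0.45,
                           cys_enrichment = 3,
                           motifs = c("CYCKR", "WCKQC", "CCHGK",
                                      "KCYNC", "GCWCV"),
                           plant_prob = 0.6,
                           dipeptide_boost = c(CC = 2),
                           seed = 1L) {
  stopifnot(min_len >= 35L, cys_enrichment >= 1,
            plant_prob >= 0, plant_prob <= 1)
  if (length(motifs) > 0L && max(nchar(motifs)) > min_len)
    stop("planted motifs must not exceed the minimum sequence length")
  structure(list(n_pos = as.integer(n_pos), n_neg = as.integer(n_neg),
                 min_len = as.integer(min_len), max_len = as.integer(max_len),
                 meanlog = meanlog, sdlog = sdlog,
                 cys_enrichment = cys_enrichment, motifs = motifs,
                 plant_prob = plant_prob, dipeptide_boost = dipeptide_boost,
                 seed = as.integer(seed)),
            class = "synthetic_spec")
}

draw_lengths <- function(n, spec) {
  len <- round(stats::rlnorm(n, spec$meanlog, spec$sdlog))
  pmin(pmax(len, spec$min_len), spec$max_len)
}

# draw one sequence from residue frequencies, with optional first-order
# dipeptide boost
draw_sequence <- function(len, freqs, boost = NULL) {
  aa <- aa_alphabet()
  if (is.null(boost) || length(boost) == 0L) {
    return(paste(sample(aa, len, replace = TRUE, prob = freqs),
                 collapse = ""))
  }
  out <- character(len)
  out[1] <- sample(aa, 1, prob = freqs)
  for (i in 2:len) {
    p <- freqs
    key <- names(boost)
    hit <- substr(key, 1, 1) == out[i - 1]
    if (any(hit)) {
      nxt <- substr(key[hit], 2, 2)
      p[nxt] <- p[nxt] * boost[hit]
      p <- p / sum(p)
    }
    out[i] <- sample(aa, 1, prob = p)
  }
  paste(out, collapse = "")
}

# plant motifs at non-overlapping positions so that one planted motif never
# overwrites another: the sequence is divided into slots of the maximal
# motif length and each motif lands in a distinct random slot
plant_motifs <- function(seq, motifs) {
  if (length(motifs) == 0L) return(seq)
  L <- nchar(seq)
  k <- max(nchar(motifs))
  n_slots <- L %/% k
  if (n_slots < length(motifs))
    stop("sequence too short to plant ", length(motifs), " motifs")
  slots <- sample.int(n_slots, length(motifs))
  for (i in seq_along(motifs)) {
    pos <- (slots[i] - 1L) * k + 1L
    m <- motifs[i]
    seq <- paste0(substr(seq, 1, pos - 1L), m,
                  substr(seq, pos + nchar(m), L))
  }
  seq
}

contains_any <- function(seq, motifs) {
  any(vapply(motifs, function(m) grepl(m, seq, fixed = TRUE), logical(1)))
}

#' Generate a synthetic labelled dataset pair
#'
#' Deterministic for a fixed spec (the seed lives in the spec). The
#' annotation records, per positive sequence, which motifs were planted;
#' negatives are certified free of all planted motifs.
#'
#' @param spec A [synthetic_spec()].
#' @return List with `pos` and `neg` ([tox_dataset()]s) and `annotation`
#'   (list with the spec echo and per-sequence planted motifs).
#' @export
generate_synthetic <- function(spec = synthetic_spec()) {
  stopifnot(inherits(spec, "synthetic_spec"))
  set.seed(spec$seed)
  bg <- background_frequencies()
  pf <- bg
  pf["C"] <- pf["C"] * spec$cys_enrichment
  pf <- pf / sum(pf)
  pos_len <- draw_lengths(spec$n_pos, spec)
  neg_len <- draw_lengths(spec$n_neg, spec)
  planted <- vector("list", spec$n_pos)
  pos_seq <- character(spec$n_pos)
  for (i in seq_len(spec$n_pos)) {
    s <- draw_sequence(pos_len[i], pf, spec$dipeptide_boost)
    which_planted <- spec$motifs[stats::runif(length(spec$motifs)) <
                                   spec$plant_prob]
    s <- plant_motifs(s, which_planted)
    pos_seq[i] <- s
    planted[[i]] <- which_planted
  }
  neg_seq <- character(spec$n_neg)
  for (i in seq_len(spec$n_neg)) {
    repeat {
      s <- draw_sequence(neg_len[i], bg)
      if (length(spec$motifs) == 0L || !contains_any(s, spec$motifs)) break
    }
    neg_seq[i] <- s
  }
  pos <- tox_dataset(sprintf("TOX%05d", seq_len(spec$n_pos)), pos_seq,
                     label = "toxin")
  neg <- tox_dataset(sprintf("NEG%05d", seq_len(spec$n_neg)), neg_seq,
                     label = "non-toxin")
  names(planted) <- pos$id
  list(pos = pos, neg = neg,
       annotation = list(spec = unclass(spec), planted = planted))
}

#' Versioned benchmark presets
#'
#' Fixed, seeded dataset presets: `tiny` (20/20), `default` (400/400
#' training plus a 100/100 held-out test set drawn from the same
#' distribution), and `imbalanced` (200 positives / 6000 negatives, for
#' negative-sampling experiments).
#'
#' @param preset One of "tiny", "default", "imbalanced".
#' @param seed Base seed (each preset derives its train/test seeds from it).
#' @return List with `train` (list `pos`, `neg`), `test` (or NULL) and
#'   `annotation`.
#' @export
make_benchmark <- function(preset = c("tiny", "default", "imbalanced"),
                           seed = 2024L) {
  preset <- match.arg(preset)
  if (preset == "tiny") {
    g <- generate_synthetic(synthetic_spec(n_pos = 20L, n_neg = 20L,
                                           seed = seed))
    return(list(train = list(pos = g$pos, neg = g$neg), test = NULL,
                annotation = g$annotation))
  }
  if (preset == "imbalanced") {
    g <- generate_synthetic(synthetic_spec(n_pos = 200L, n_neg = 6000L,
                                           seed = seed + 2L))
    return(list(train = list(pos = g$pos, neg = g$neg), test = NULL,
                annotation = g$annotation))
  }
  tr <- generate_synthetic(synthetic_spec(n_pos = 400L, n_neg = 400L,
                                          seed = seed))
  te <- generate_synthetic(synthetic_spec(n_pos = 100L, n_neg = 100L,
                                          seed = seed + 1L))
  te$pos$id <- sub("^TOX", "TSTTOX", te$pos$id)
  te$neg$id <- sub("^NEG", "TSTNEG", te$neg$id)
  names(te$annotation$planted) <- te$pos$id
  list(train = list(pos = tr$pos, neg = tr$neg),
       test = list(pos = te$pos, neg = te$neg),
       annotation = list(train = tr$annotation, test = te$annotation))
}
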