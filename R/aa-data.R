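# Amino-acid reference data shared by the descriptor families.

#' Standard amino-acid alphabet
#'
#' The 20 standard one-letter residue codes in alphabetical order. All
#' descriptor families index residues through this vector, so feature naming
#' is alphabetical throughout the package.
#'
#' @return Character vector of length 20.
#' @export
aa_alphabet <- function() {
  c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
    "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")
}

# residues that trigger removal during cleaning (ambiguous / nonstandard)
NONSTANDARD_AA <- c("B", "J", "O", "U", "X", "Z")

#' Three-class physicochemical encodings for the CTD descriptors
#'
#' The seven standard properties (hydrophobicity, normalized van der Waals
#' volume, polarity, polarizability, charge, secondary structure, solvent
#' accessibility), each splitting the 20 residues into three classes.
#'
#' @return Named list of 7 properties, each a list of three residue groups.
#' @export
ctd_properties <- function() {
  list(
    hydrophobicity  = list(G1 = c("R","K","E","D","Q","N"),
                           G2 = c("G","A","S","T","P","H","Y"),
                           G3 = c("C","L","V","I","M","F","W")),
    normwaalsvolume = list(G1 = c("G","A","S","T","P","D","C"),
                           G2 = c("N","V","E","Q","I","L"),
                           G3 = c("M","H","K","F","R","Y","W")),
    polarity        = list(G1 = c("L","I","F","W","C","M","V","Y"),
                           G2 = c("P","A","T","G","S"),
                           G3 = c("H","Q","R","K","N","E","D")),
    polarizability  = list(G1 = c("G","A","S","D","T"),
                           G2 = c("C","P","N","V","E","Q","I","L"),
                           G3 = c("K","M","H","F","R","Y","W")),
    charge          = list(G1 = c("K","R"),
                           G2 = c("A","N","C","Q","G","H","I","L",
                                  "M","F","P","S","T","W","Y","V"),
                           G3 = c("D","E")),
    secondarystruct = list(G1 = c("E","A","L","M","Q","K","R","H"),
                           G2 = c("V","I","Y","C","W","F","T"),
                           G3 = c("G","N","P","S","D")),
    solventaccess   = list(G1 = c("A","L","F","C","G","I","V","W"),
                           G2 = c("R","K","Q","E","N","D"),
                           G3 = c("M","S","P","T","H","Y"))
  )
}

#' Conjoint-triad residue classification
#'
#' The seven residue groups (by dipole and side-chain volume) underlying
#' the conjoint-triad descriptors.
#'
#' @return Named list of 7 residue groups.
#' @export
conjoint_triad_classes <- function() {
  list(`1` = c("A","G","V"),
       `2` = c("I","L","F","P"),
       `3` = c("Y","M","T","S"),
       `4` = c("H","N","Q","W"),
       `5` = c("R","K"),
       `6` = c("D","E"),
       `7` = c("C"))
}

#' Six physicochemical amino-acid groups
#'
#' Residue groups whose counts (plus sequence length) form the compact
#' seven-feature block of [aa_groups_length()].
#'
#' @return Named list of 6 residue groups.
#' @export
aa_six_groups <- function() {
  list(hydrophobic        = c("V","I","L","F","M","W","Y","C"),
       negatively.charged = c("D","E"),
       positively.charged = c("R","K","H"),
       conformational     = c("G","P"),
       polar              = c("N","Q","S"),
       other              = c("A","T"))
}

#' Property trio of the pseudo amino-acid composition
#'
#' Hydrophobicity (the consensus scale conventional for PAAC),
#' hydrophilicity (Hopp-Woods) and side-chain mass; z-scored versions also
#' drive the package's side-chain physicochemical distance matrix.
#'
#' @return Named list of three numeric 20-vectors (alphabetical order).
#' @export
paac_properties <- function() {
  hydrophobicity <- c(A = 0.62, C = 0.29, D = -0.90, E = -0.74, F = 1.19,
                      G = 0.48, H = -0.40, I = 1.38, K = -1.50, L = 1.06,
                      M = 0.64, N = -0.78, P = 0.12, Q = -0.85, R = -2.53,
                      S = -0.18, T = -0.05, V = 1.08, W = 0.81, Y = 0.26)
  hydrophilicity <- c(A = -0.5, C = -1.0, D = 3.0, E = 3.0, F = -2.5,
                      G = 0.0, H = -0.5, I = -1.8, K = 3.0, L = -1.8,
                      M = -1.3, N = 0.2, P = 0.0, Q = 0.2, R = 3.0,
                      S = 0.3, T = -0.4, V = -1.5, W = -3.4, Y = -2.3)
  sidechainmass <- c(A = 15, C = 47, D = 59, E = 73, F = 91,
                     G = 1, H = 82, I = 57, K = 73, L = 57,
                     M = 75, N = 58, P = 42, Q = 72, R = 101,
                     S = 31, T = 45, V = 43, W = 130, Y = 107)
  aa <- aa_alphabet()
  list(hydrophobicity = hydrophobicity[aa],
       hydrophilicity = hydrophilicity[aa],
       sidechainmass  = sidechainmass[aa])
}

# z-score over the 20 residues with population (n = 20) standard deviation
standardize_property <- function(p) {
  (p - mean(p)) / sqrt(mean((p - mean(p))^2))
}

#' Grantham amino-acid distance matrix
#'
#' Computed from Grantham's published composition, polarity and molecular
#' volume values, `D_ij = rho * sqrt(a (c_i - c_j)^2 + b (p_i - p_j)^2 +
#' g (v_i - v_j)^2)` with a = 1.833, b = 0.1018, g = 0.000399 and `rho`
#' scaling the mean of all pairwise distances to 100. Reproduces the printed
#' table (e.g. Leu-Ile 5, Trp-Cys 215, Arg-Leu 102) after rounding.
#'
#' @param rounded Round to integers as in the published table (default TRUE).
#' @return A 20 x 20 symmetric numeric matrix, alphabetical residue order.
#' @export
grantham_matrix <- function(rounded = TRUE) {
  comp <- c(A = 0, R = 0.65, N = 1.33, D = 1.38, C = 2.75, Q = 0.89,
            E = 0.92, G = 0.74, H = 0.58, I = 0, L = 0, K = 0.33,
            M = 0, F = 0, P = 0.39, S = 1.42, T = 0.71, W = 0.13,
            Y = 0.20, V = 0)
  pol <- c(A = 8.1, R = 10.5, N = 11.6, D = 13.0, C = 5.5, Q = 10.5,
           E = 12.3, G = 9.0, H = 10.4, I = 5.2, L = 4.9, K = 11.3,
           M = 5.7, F = 5.2, P = 8.0, S = 9.2, T = 8.6, W = 5.4,
           Y = 6.2, V = 5.9)
  vol <- c(A = 31, R = 124, N = 56, D = 54, C = 55, Q = 85, E = 83,
           G = 3, H = 96, I = 111, L = 111, K = 119, M = 105, F = 132,
           P = 32.5, S = 32, T = 61, W = 170, Y = 136, V = 84)
  aa <- aa_alphabet()
  d <- outer(aa, aa, function(i, j) {
    sqrt(1.833 * (comp[i] - comp[j])^2 +
         0.1018 * (pol[i] - pol[j])^2 +
         0.000399 * (vol[i] - vol[j])^2)
  })
  rho <- 100 / mean(d[upper.tri(d)])
  d <- d * rho
  if (rounded) d <- round(d)
  dimnames(d) <- list(aa, aa)
  d
}

#' Side-chain physicochemical distance matrix
#'
#' Squared-difference distance over the z-scored hydrophobicity,
#' hydrophilicity and side-chain mass scales of [paac_properties()]:
#' `d(i,j) = sqrt(mean_p (P_p(i) - P_p(j))^2)`. This matrix fills the
#' physicochemical slot of the quasi-sequence-order descriptors (feature
#' prefix `scdist`); see the methods vignette for how it relates to other
#' published inter-residue distance scales.
#'
#' @return A 20 x 20 symmetric numeric matrix, alphabetical residue order.
#' @export
scdist_matrix <- function() {
  props <- lapply(paac_properties(), standardize_property)
  aa <- aa_alphabet()
  d <- matrix(0, 20, 20, dimnames = list(aa, aa))
  for (p in props) d <- d + outer(p, p, function(a, b) (a - b)^2)
  sqrt(d / length(props))
}

# Default autocorrelation indices: eight AAindex1 physicochemical scales
# (protr-compatible default set), pulled from seqinr's bundled AAindex data.
autocorr_default_indices <- function() {
  c("CIDH920105", "BHAR880101", "CHAM820101", "CHAM820102",
    "CHOC760101", "BIGC670101", "CHAM810101", "DAYM780201")
}

# cache for the seqinr AAindex table (one-letter recoded)
.toxscreen_cache <- new.env(parent = emptyenv())

three_to_one <- function(x) {
  map <- c(Ala = "A", Arg = "R", Asn = "N", Asp = "D", Cys = "C",
           Gln = "Q", Glu = "E", Gly = "G", His = "H", Ile = "I",
           Leu = "L", Lys = "K", Met = "M", Phe = "F", Pro = "P",
           Ser = "S", Thr = "T", Trp = "W", Tyr = "Y", Val = "V")
  out <- unname(map[x])
  out
}

#' Default AAindex table
#'
#' The AAindex1 collection bundled with the seqinr package, recoded to
#' one-letter residue names and restricted to indices with a complete set of
#' 20 finite values. Used as the default table for [aaindex_profile()] and as
#' the source of the autocorrelation property scales.
#'
#' @return Named list of numeric vectors (length 20, alphabetical order);
#'   names are AAindex accessions.
#' @export
aaindex_default_table <- function() {
  if (!is.null(.toxscreen_cache$aaindex)) return(.toxscreen_cache$aaindex)
  env <- new.env()
  utils::data("aaindex", package = "seqinr", envir = env)
  aa <- aa_alphabet()
  tab <- lapply(env$aaindex, function(entry) {
    v <- entry$I
    names(v) <- three_to_one(names(v))
    v <- v[aa]
    if (any(!is.finite(v))) return(NULL)
    v
  })
  names(tab) <- vapply(env$aaindex, function(e) e$H, character(1))
  tab <- tab[!vapply(tab, is.null, logical(1))]
  .toxscreen_cache$aaindex <- tab
  tab
}

# numeric property profile along a sequence (stops on unknown residues)
sequence_profile <- function(seq, values) {
  chars <- strsplit(seq, "", fixed = TRUE)[[1]]
  v <- values[chars]
  if (any(is.na(v))) {
    stop("sequence contains residues without a property value: ",
         paste(unique(chars[is.na(v)]), collapse = ", "))
  }
  unname(v)
}

# split into single characters, validating against the standard alphabet
seq_chars <- function(seq) {
  if (!is.character(seq) || length(seq) != 1L || is.na(seq) || nchar(seq) == 0L)
    stop("sequence must be a single non-empty string")
  chars <- strsplit(seq, "", fixed = TRUE)[[1]]
  bad <- setdiff(unique(chars), aa_alphabet())
  if (length(bad) > 0L)
    stop("non-standard residues in sequence: ", paste(bad, collapse = ", "))
  chars
}
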