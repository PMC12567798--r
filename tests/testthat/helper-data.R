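# Shared data builders for the tests.

make_dataset <- function(seqs, ids = sprintf("seq%02d", seq_along(seqs)),
                         label = "unlabelled") {
  tox_dataset(ids, seqs, label = label)
}

random_dataset <- function(n, len_range = c(40, 120), seed = 1,
                           label = "unlabelled") {
  set.seed(seed)
  seqs <- vapply(seq_len(n), function(i)
    random_protein(sample(len_range[1]:len_range[2], 1)), character(1))
  make_dataset(seqs, sprintf("rnd%03d", seq_len(n)), label = label)
}

# labelled feature matrix with 5 informative columns among noise
make_planted_matrix <- function(n = 300, p_noise = 95, effect = 1.2,
                                seed = 1) {
  set.seed(seed)
  y <- rep(c(0L, 1L), each = n / 2)
  x <- matrix(stats::rnorm(n * (p_noise + 5)), n)
  colnames(x) <- c(paste0("inf", 1:5), sprintf("noise%03d", seq_len(p_noise)))
  rownames(x) <- paste0("s", seq_len(n))
  x[y == 1, 1:5] <- x[y == 1, 1:5] + effect
  list(x = x, y = stats::setNames(y, rownames(x)))
}

# tiny linearly separable toy: C-rich positives vs C-free negatives,
# featurized by amino acid composition
separable_toy <- function(n_per_class = 10, seed = 42) {
  set.seed(seed)
  pos <- vapply(seq_len(n_per_class), function(i)
    paste(sample(c(rep("C", 15), sample(AA20[AA20 != "C"], 25,
                                        replace = TRUE))), collapse = ""),
    character(1))
  neg <- vapply(seq_len(n_per_class), function(i)
    paste(sample(AA20[AA20 != "C"], 40, replace = TRUE), collapse = ""),
    character(1))
  ds <- make_dataset(c(pos, neg), sprintf("t%02d", seq_len(2 * n_per_class)))
  x <- t(vapply(ds$sequence, aac, numeric(20)))
  rownames(x) <- ds$id
  list(x = x, y = stats::setNames(rep(c(1L, 0L), each = n_per_class),
                                  ds$id), ds = ds)
}

# native residue column order of PSI-BLAST ASCII PSSMs (public format)
PSIBLAST_ORD <- c("A","R","N","D","C","Q","E","G","H","I",
                  "L","K","M","F","P","S","T","W","Y","V")
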