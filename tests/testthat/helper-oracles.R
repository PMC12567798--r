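# Independent brute-force reference implementations used as oracles.
# These deliberately use naive position-by-position loops and share no code
# with the package's descriptor implementations.

AA20 <- c("A","C","D","E","F","G","H","I","K","L",
          "M","N","P","Q","R","S","T","V","W","Y")

oracle_aac <- function(seq) {
  chars <- strsplit(seq, "")[[1]]
  out <- numeric(20); names(out) <- AA20
  for (ch in chars) out[ch] <- out[ch] + 1
  out / length(chars)
}

oracle_dpc <- function(seq) {
  chars <- strsplit(seq, "")[[1]]
  L <- length(chars)
  nm <- character(0)
  for (a in AA20) for (b in AA20) nm <- c(nm, paste0(a, b))
  out <- numeric(400); names(out) <- nm
  for (i in 1:(L - 1)) {
    p <- paste0(chars[i], chars[i + 1])
    out[p] <- out[p] + 1
  }
  out / (L - 1)
}

# class index of one residue under one three-class encoding
oracle_ctd_class <- function(ch, prop) {
  for (g in 1:3) if (ch %in% prop[[g]]) return(g)
  stop("uncovered residue ", ch)
}

oracle_ctd <- function(seq, properties = toxscreen::ctd_properties()) {
  chars <- strsplit(seq, "")[[1]]
  L <- length(chars)
  pn <- names(properties)
  comp <- numeric(0); tran <- numeric(0); dist <- numeric(0)
  for (i in seq_along(properties)) {
    cls <- vapply(chars, oracle_ctd_class, numeric(1), properties[[i]])
    for (g in 1:3) {
      v <- sum(cls == g) / L
      names(v) <- paste0(pn[i], ".Group", g)
      comp <- c(comp, v)
    }
    pairs <- list(c(1, 2), c(1, 3), c(2, 3))
    lab <- c("Tr1221", "Tr1331", "Tr2332")
    for (k in 1:3) {
      cnt <- 0
      if (L >= 2) for (j in 1:(L - 1)) {
        ab <- sort(c(cls[j], cls[j + 1]))
        if (all(ab == pairs[[k]])) cnt <- cnt + 1
      }
      v <- if (L >= 2) cnt / (L - 1) else 0  # single residue: no pairs
      names(v) <- paste0("prop", i, ".", lab[k])
      tran <- c(tran, v)
    }
    for (g in 1:3) {
      pos <- which(cls == g); n <- length(pos)
      if (n == 0) vals <- rep(0, 5)
      else {
        idx <- c(1, max(1, ceiling(0.25 * n)), max(1, ceiling(0.5 * n)),
                 max(1, ceiling(0.75 * n)), n)
        vals <- pos[idx] / L * 100
      }
      names(vals) <- paste0("prop", i, ".G", g,
                            ".residue", c(0, 25, 50, 75, 100))
      dist <- c(dist, vals)
    }
  }
  c(comp, tran, dist)
}

oracle_ctriad <- function(seq) {
  groups <- list(c("A","G","V"), c("I","L","F","P"), c("Y","M","T","S"),
                 c("H","N","Q","W"), c("R","K"), c("D","E"), c("C"))
  cls_of <- function(ch) {
    for (g in 1:7) if (ch %in% groups[[g]]) return(g)
    stop("uncovered residue")
  }
  chars <- strsplit(seq, "")[[1]]
  L <- length(chars)
  nm <- character(0)
  for (i in 1:7) for (j in 1:7) for (k in 1:7)
    nm <- c(nm, paste0("VS", i, j, k))
  f <- numeric(343); names(f) <- nm
  for (p in 1:(L - 2)) {
    key <- paste0("VS", cls_of(chars[p]), cls_of(chars[p + 1]),
                  cls_of(chars[p + 2]))
    f[key] <- f[key] + 1
  }
  (f - min(f)) / max(f)
}

oracle_gap <- function(scores) {
  L <- nrow(scores)
  out <- numeric(ncol(scores))
  for (j in seq_len(ncol(scores))) {
    s <- 0
    for (i in seq_len(L)) s <- s + scores[i, j]
    out[j] <- s / L
  }
  names(out) <- colnames(scores)
  out
}

oracle_auc <- function(scores, labels) {
  pos <- scores[labels == 1]; neg <- scores[labels == 0]
  tot <- 0
  for (p in pos) for (n in neg)
    tot <- tot + if (p > n) 1 else if (p == n) 0.5 else 0
  tot / (length(pos) * length(neg))
}

# exhaustive k-means SSE: minimum over all assignments of n points to k
# clusters (centroid = cluster mean); feasible for n <= 8, k <= 3
oracle_kmeans_sse <- function(x, k) {
  x <- as.matrix(x)
  n <- nrow(x)
  stopifnot(n <= 8, k <= 3)
  best <- Inf
  assign <- rep(1L, n)
  repeat {
    if (length(unique(assign)) == k) {
      sse <- 0
      for (j in unique(assign)) {
        pts <- x[assign == j, , drop = FALSE]
        ctr <- colMeans(pts)
        for (i in seq_len(nrow(pts))) sse <- sse + sum((pts[i, ] - ctr)^2)
      }
      best <- min(best, sse)
    }
    i <- n
    while (i >= 1 && assign[i] == k) { assign[i] <- 1L; i <- i - 1L }
    if (i == 0L) break
    assign[i] <- assign[i] + 1L
  }
  best
}

# direct-sum sequence-order coupling number for one distance matrix
oracle_socn <- function(seq, d, D) {
  chars <- strsplit(seq, "")[[1]]
  L <- length(chars)
  s <- 0
  for (i in 1:(L - d)) s <- s + D[chars[i], chars[i + d]]^2
  s
}

# per-sample metric recomputation from raw label/prediction vectors
oracle_metrics <- function(truth, pred) {
  tp <- sum(truth == 1 & pred == 1); tn <- sum(truth == 0 & pred == 0)
  fp <- sum(truth == 0 & pred == 1); fn <- sum(truth == 1 & pred == 0)
  acc <- mean(truth == pred)
  sens <- if (tp + fn == 0) 0 else tp / (tp + fn)
  spec <- if (tn + fp == 0) 0 else tn / (tn + fp)
  ppv <- if (tp + fp == 0) 0 else tp / (tp + fp)
  npv <- if (tn + fn == 0) 0 else tn / (tn + fn)
  den <- sqrt(tp + fp) * sqrt(tp + fn) * sqrt(tn + fp) * sqrt(tn + fn)
  mcc <- if (den == 0) 0 else (tp * tn - fp * fn) / den
  list(accuracy = acc, sensitivity = sens, specificity = spec,
       PPV = ppv, NPV = npv, MCC = mcc)
}

# all sequences of length 1..max_len over a reduced alphabet
enumerate_sequences <- function(alphabet, max_len) {
  out <- character(0)
  cur <- alphabet
  for (len in 1:max_len) {
    out <- c(out, cur)
    if (len < max_len)
      cur <- as.vector(outer(cur, alphabet, paste0))
  }
  out
}

random_protein <- function(len, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  paste(sample(AA20, len, replace = TRUE), collapse = "")
}
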