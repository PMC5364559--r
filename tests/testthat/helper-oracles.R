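# Naive reference implementations, independent of the package's vectorized
# encoders: plain loops over positions, used to freeze expected values.

random_sequence <- function(L) {
  paste(sample(AA_ALPHABET, L, replace = TRUE), collapse = "")
}

chars_of <- function(s) strsplit(s, "", fixed = TRUE)[[1L]]

# population-sd standardization over the 20 residues (Chou convention)
std20 <- function(v) (v - mean(v)) / sqrt(mean((v - mean(v))^2))

oracle_aac <- function(s) {
  ch <- chars_of(s)
  vapply(AA_ALPHABET, function(a) sum(ch == a) / length(ch), numeric(1))
}

oracle_dpc <- function(s) {
  ch <- chars_of(s)
  L <- length(ch)
  out <- numeric(400)
  names(out) <- as.vector(t(outer(AA_ALPHABET, AA_ALPHABET, paste0)))
  for (i in seq_len(L - 1L)) {
    dp <- paste0(ch[i], ch[i + 1L])
    out[dp] <- out[dp] + 1
  }
  out / (L - 1L)
}

# props: raw 3 x 20 matrix, columns in AA_ALPHABET order
oracle_theta <- function(s, props, j) {
  ch <- chars_of(s)
  L <- length(ch)
  std <- t(apply(props, 1L, std20))
  colnames(std) <- AA_ALPHABET
  total <- 0
  for (i in seq_len(L - j)) {
    d <- 0
    for (k in seq_len(nrow(std))) {
      d <- d + (std[k, ch[i]] - std[k, ch[i + j]])^2
    }
    total <- total + d / nrow(std)
  }
  total / (L - j)
}

oracle_paac <- function(s, props, lambda, w) {
  ch <- chars_of(s)
  f <- oracle_aac(s)
  theta <- vapply(seq_len(lambda), function(j) oracle_theta(s, props, j),
                  numeric(1))
  c(f, w * theta) / (1 + w * sum(theta))
}

oracle_ctd <- function(s, grouping) {
  ch <- chars_of(s)
  L <- length(ch)
  g <- grouping$group_of[ch]
  comp <- vapply(1:3, function(k) sum(g == k) / L, numeric(1))
  trans <- numeric(3)
  pairs <- list(c(1, 2), c(1, 3), c(2, 3))
  for (i in seq_len(L - 1L)) {
    for (p in seq_along(pairs)) {
      if ((g[i] == pairs[[p]][1] && g[i + 1] == pairs[[p]][2]) ||
          (g[i] == pairs[[p]][2] && g[i + 1] == pairs[[p]][1])) {
        trans[p] <- trans[p] + 1
      }
    }
  }
  trans <- trans / (L - 1L)
  distr <- numeric(15)
  for (k in 1:3) {
    pos <- which(g == k)
    if (length(pos) > 0) {
      n_g <- length(pos)
      idx <- c(1L,
               max(1L, ceiling(0.25 * n_g)),
               max(1L, ceiling(0.50 * n_g)),
               max(1L, ceiling(0.75 * n_g)),
               n_g)
      distr[(k - 1L) * 5L + 1:5] <- pos[idx] / L * 100
    }
  }
  c(comp, trans, distr)
}

# values: raw index matrix (M x 20, AA_ALPHABET columns)
oracle_acf <- function(s, values, n) {
  ch <- chars_of(s)
  L <- length(ch)
  out <- numeric(0)
  for (m in seq_len(nrow(values))) {
    p <- std20(values[m, ])
    names(p) <- AA_ALPHABET
    for (d in seq_len(n)) {
      acc <- 0
      for (i in seq_len(L - d)) acc <- acc + p[[ch[i]]] * p[[ch[i + d]]]
      out <- c(out, acc / (L - d))
    }
  }
  out
}

# Mann-Whitney estimate over all positive-negative pairs, ties counted 1/2
oracle_auc <- function(scores, labels) {
  sp <- scores[labels == 1]
  sn <- scores[labels == -1]
  total <- 0
  for (a in sp) for (b in sn) {
    total <- total + if (a > b) 1 else if (a == b) 0.5 else 0
  }
  total / (length(sp) * length(sn))
}

# small toy index table for ACF tests
toy_index_table <- function(m = 5L, seed = 42L) {
  vals <- withr::with_seed(seed, matrix(round(rnorm(m * 20), 3), m, 20))
  aaindex_table(sprintf("TOY%03d", seq_len(m)), vals, source = "toy")
}

# small separable feature fixture for SVM tests
separable_clouds <- function(n = 20L, gap = 4, seed = 1L, d = 2L) {
  X <- withr::with_seed(seed, rbind(
    matrix(rnorm(n * d, mean = -gap / 2), n, d),
    matrix(rnorm(n * d, mean = gap / 2), n, d)))
  colnames(X) <- paste0("f", seq_len(d))
  list(features = feature_matrix(X, "AAC"),
       labels = rep(c(-1, 1), each = n))
}
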