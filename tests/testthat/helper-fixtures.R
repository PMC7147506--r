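# Shared fixture builders (all data generated in code).

# small labelled expression matrix
make_mat <- function(nr = 5, nc = 6, seed = 1, row_prefix = "G",
                     col_prefix = "S") {
  set.seed(seed)
  matrix(rnorm(nr * nc, 8, 1), nr, nc,
         dimnames = list(sprintf("%s%02d", row_prefix, seq_len(nr)),
                         sprintf("%s%02d", col_prefix, seq_len(nc))))
}

# two-class labels for nc samples
two_class <- function(nc, groups = c("sepsis", "SIRS")) {
  rep(groups, length.out = nc)[order(rep(seq_len(nc) <= nc / 2,
                                         length.out = nc), decreasing = TRUE)]
}

balanced_labels <- function(n, groups = c("sepsis", "SIRS")) {
  rep(groups, each = n / 2)
}

# straight-line reference forward pass, independent of the C++ engine
forward_oracle <- function(model, x) {
  W <- model$input_weights
  V <- model$output_weights
  n_in <- nrow(W) - 1
  n_h <- ncol(W)
  out <- numeric(nrow(x))
  for (r in seq_len(nrow(x))) {
    h <- numeric(n_h)
    for (j in seq_len(n_h)) {
      a <- W[n_in + 1, j]
      for (i in seq_len(n_in)) a <- a + W[i, j] * x[r, i]
      h[j] <- 1 / (1 + exp(-a))
    }
    a <- V[n_h + 1]
    for (j in seq_len(n_h)) a <- a + V[j] * h[j]
    out[r] <- 1 / (1 + exp(-a))
  }
  out
}

# brute-force BH step-up, written from the definition
bh_oracle <- function(p) {
  n <- length(p)
  o <- order(p)
  adj <- numeric(n)
  ranked <- p[o] * n / seq_len(n)
  # enforce monotonicity from the largest rank down
  for (i in n:1) {
    adj[i] <- if (i == n) ranked[i] else min(ranked[i], adj[i + 1])
  }
  out <- numeric(n)
  out[o] <- pmin(adj, 1)
  out
}

tmp_path <- function(ext = ".tsv") tempfile(fileext = ext)
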