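# Internal deterministic RNG plumbing.
#
# Every stochastic operation takes an integer seed and derives child seeds
# through the helpers below, so results are independent of R's global RNG
# state and of the order in which genes are screened.  The generator is a
# Lehmer / MINSTD congruential stream computed in doubles (all intermediates
# stay below 2^53, so the arithmetic is exact).

.LEHMER_M <- 2147483647  # 2^31 - 1

# coerce any integerish seed into [1, m-1]
.seed_norm <- function(seed) {
  s <- as.numeric(seed) %% .LEHMER_M
  if (s <= 0) s <- s + .LEHMER_M - 1
  if (s == 0) s <- 1
  s
}

.lehmer_next <- function(state) (state * 48271) %% .LEHMER_M

# stable 31-bit string hash (rolling polynomial), exact in doubles
.hash_string <- function(x) {
  h <- 7
  for (code in utf8ToInt(x)) h <- (h * 31 + code) %% .LEHMER_M
  h
}

# derive a child seed from a master seed plus a label and/or an index;
# two Lehmer steps decorrelate adjacent indices
.child_seed <- function(master, label = "", index = 0) {
  s <- .seed_norm(master)
  s <- (s + .hash_string(as.character(label)) + 65539 * (index %% 32749)) %% .LEHMER_M
  s <- .lehmer_next(.seed_norm(s))
  .lehmer_next(s)
}

# deterministic uniform draws / permutation from a Lehmer stream, leaving
# R's RNG untouched
.lehmer_runif <- function(n, seed) {
  s <- .seed_norm(seed)
  out <- numeric(n)
  for (i in seq_len(n)) {
    s <- .lehmer_next(s)
    out[i] <- s / .LEHMER_M
  }
  out
}

.lehmer_shuffle <- function(x, seed) {
  n <- length(x)
  if (n <= 1) return(x)
  u <- .lehmer_runif(n - 1, seed)
  for (k in n:2) {
    j <- floor(u[n - k + 1] * k) + 1
    tmp <- x[k]; x[k] <- x[j]; x[j] <- tmp
  }
  x
}

# run expr with R's RNG seeded, restoring any prior state afterwards
.with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(expr)
}

.stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
.warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

# fixed-format numeric TSV writer so pipeline outputs are byte-stable
.format_num <- function(x) {
  ifelse(is.na(x), "NA", sprintf("%.10g", x))
}

.write_tsv <- function(df, path) {
  df2 <- df
  for (j in seq_along(df2)) {
    if (is.numeric(df2[[j]]) && !is.integer(df2[[j]]))
      df2[[j]] <- .format_num(df2[[j]])
  }
  write.table(df2, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = TRUE, na = "NA")
  invisible(path)
}
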