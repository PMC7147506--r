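test_that("SRE is the across-genes z-score of class mean differences", {
  m <- matrix(c(2, 2, 1, 1,
                1, 1, 2, 2), 2, 4, byrow = TRUE,
              dimnames = list(c("g1", "g2"), sprintf("S%d", 1:4)))
  labs <- c("sepsis", "sepsis", "SIRS", "SIRS")
  sre <- compute_sre(m, labs)
  expect_equal(unname(sre), c(1 / sqrt(2), -1 / sqrt(2)), tolerance = 1e-12)
  # antisymmetry under label swap
  m2 <- make_mat(10, 8, seed = 4)
  labs2 <- balanced_labels(8)
  s1 <- compute_sre(m2, labs2, positive_class = "sepsis")
  s2 <- compute_sre(m2, labs2, positive_class = "SIRS")
  expect_equal(s1, -s2, tolerance = 1e-12)
  # mean 0, sd 1 by construction
  expect_lt(abs(mean(s1)), 1e-9)
  expect_lt(abs(sd(s1) - 1), 1e-9)
  # degenerate: identical differences everywhere
  m3 <- m2
  m3[] <- rep(colMeans(m2), each = nrow(m2))
  expect_warning(s3 <- compute_sre(m3, labs2), "SRE set to 0")
  expect_true(all(s3 == 0))
  expect_error(compute_sre(m2[1, , drop = FALSE], labs2), "2 genes")
})

test_that("single-gene screening separates planted signal from noise", {
  labs <- balanced_labels(60)
  wins <- 0
  for (s in 1:3) {
    set.seed(400 + s)
    planted <- c(rnorm(30, 1.5, .5), rnorm(30, -1.5, .5))
    noise <- rnorm(60)
    cfg <- ann_config(seed = s)
    rp <- screen_single_gene(planted, labs, n_resamples = 10, config = cfg,
                             gene_id = "planted")
    rn <- screen_single_gene(noise, labs, n_resamples = 10, config = cfg,
                             gene_id = "noise")
    wins <- wins + (rp$mean_validation_mse < rn$mean_validation_mse)
    expect_lt(rp$predictive_p, 0.05)
  }
  expect_equal(wins, 3)
})

test_that("a single resample reports that resample's values unaggregated", {
  set.seed(5)
  vals <- rnorm(24)
  labs <- balanced_labels(24)
  r <- screen_single_gene(vals, labs, n_resamples = 1,
                          config = ann_config(seed = 3), gene_id = "g")
  expect_identical(r$n_resamples, 1L)
  expect_length(r$mean_test_mse, 1)
  expect_true(is.finite(r$mean_validation_mse))
  # identical reruns (aggregation of one value is that value)
  r2 <- screen_single_gene(vals, labs, n_resamples = 1,
                           config = ann_config(seed = 3), gene_id = "g")
  expect_identical(r, r2)
})

test_that("predictive p is roughly uniform under a permutation null", {
  set.seed(42)
  vals <- c(rnorm(30, 1.5, .5), rnorm(30, -1.5, .5))
  ps <- numeric(200)
  for (i in 1:200) {
    perm <- sample(balanced_labels(60))
    ps[i] <- screen_single_gene(vals, perm, n_resamples = 10,
                                config = ann_config(seed = i),
                                gene_id = paste0("perm", i))$predictive_p
  }
  expect_gte(mean(ps < 0.05), 0.01)
  expect_lte(mean(ps < 0.05), 0.12)
})

test_that("screen_all ranks duplicated genes adjacently and is order-equivariant", {
  set.seed(6)
  m <- make_mat(4, 20, seed = 6)
  m["G02", ] <- m["G01", ]  # same gene under two ids
  labs <- balanced_labels(20)
  cfg <- ann_config(seed = 5)
  res <- screen_all(m, labs, n_resamples = 3, config = cfg)
  expect_identical(res$sre[res$gene_id == "G01"], res$sre[res$gene_id == "G02"])
  r1 <- res$rank[res$gene_id == "G01"]
  expect_identical(res$gene_id[res$rank == r1 + 1], "G02")
  # permuting the input rows leaves per-gene results identical
  res2 <- screen_all(m[c(3, 1, 4, 2), ], labs, n_resamples = 3, config = cfg)
  expect_identical(res, res2)
  # reruns are deterministic
  expect_identical(res, screen_all(m, labs, n_resamples = 3, config = cfg))
})

test_that("filter_candidates applies the per-criterion rules", {
  results <- data.frame(
    gene_id = c("p1", "p2", "p3", "p4", "p5"),
    sre = c(0.4, -0.3, 0.4, 1.1, 2.0), stringsAsFactors = FALSE)
  ann <- list(p1 = "GA", p2 = "GA",           # sign conflict -> criterion ii
              p3 = "GB", p4 = "GB",           # consistent -> retained, mean
              p5 = c("GC", "GD"))             # multi-gene -> criterion i
  out <- filter_candidates(results, ann)
  expect_identical(out$genes$gene_id, "GB")
  expect_equal(out$genes$sre, mean(c(0.4, 1.1)))
  expect_identical(sort(out$rejected$criterion[out$rejected$probe %in%
                                                 c("p1", "p2")]), c("ii", "ii"))
  expect_identical(out$rejected$criterion[out$rejected$probe == "p5"], "i")
  # unannotated probes flagged under iii, not rescued
  out2 <- filter_candidates(rbind(results,
                                  data.frame(gene_id = "p6", sre = 3)),
                            c(ann, list(p6 = character(0))))
  expect_identical(out2$rejected$criterion[out2$rejected$probe == "p6"], "iii")
})

test_that("Welch t-test matches the closed-form computation", {
  a <- c(19.8, 23.4, 21.1, 25.0, 22.6, 20.3)
  b <- c(17.7, 18.2, 20.1, 16.5, 19.9)
  t_oracle <- (mean(a) - mean(b)) /
    sqrt(var(a) / length(a) + var(b) / length(b))
  df_oracle <- (var(a) / length(a) + var(b) / length(b))^2 /
    ((var(a) / length(a))^2 / (length(a) - 1) +
       (var(b) / length(b))^2 / (length(b) - 1))
  p_oracle <- 2 * pt(-abs(t_oracle), df_oracle)
  got <- ttest_two_sample(c(a, b), rep(c("x", "y"), c(6, 5)))
  expect_equal(got$t, t_oracle, tolerance = 1e-10)
  expect_equal(got$p, p_oracle, tolerance = 1e-10)
  # swapping which group is listed first negates t, keeps p
  sw <- ttest_two_sample(c(b, a), rep(c("y", "x"), c(5, 6)))
  expect_equal(sw$t, -got$t, tolerance = 1e-12)
  expect_equal(sw$p, got$p, tolerance = 1e-12)
  # same distribution, large n: p near 1 is typical, t near 0
  set.seed(1)
  big <- rnorm(2000)
  eq <- ttest_two_sample(big, balanced_labels(2000))
  expect_lt(abs(eq$t), 3)
  # degenerate: both groups constant and equal
  expect_identical(ttest_two_sample(rep(2, 6), balanced_labels(6)),
                   list(t = 0, p = 1))
})

test_that("one-way ANOVA agrees with t-squared and brute-force sums of squares", {
  set.seed(3)
  v <- rnorm(24)
  labs <- balanced_labels(24)
  aout <- anova_one_way(v, labs)
  tt <- t.test(v[labs == "sepsis"], v[labs == "SIRS"], var.equal = TRUE)
  expect_equal(aout$F, unname(tt$statistic)^2, tolerance = 1e-9)
  # 3-group brute force
  g <- rep(c("a", "b", "c"), each = 6)
  v3 <- rnorm(18, mean = rep(c(0, 1, 0), each = 6))
  grand <- mean(v3)
  ssb <- sum(tapply(v3, g, function(x) length(x) * (mean(x) - grand)^2))
  ssw <- sum(tapply(v3, g, function(x) sum((x - mean(x))^2)))
  f_oracle <- (ssb / 2) / (ssw / 15)
  expect_equal(anova_one_way(v3, g)$F, f_oracle, tolerance = 1e-9)
  expect_equal(anova_one_way(v3, g)$p, pf(f_oracle, 2, 15, lower.tail = FALSE),
               tolerance = 1e-9)
  expect_identical(anova_one_way(rep(1, 8), balanced_labels(8)),
                   list(F = 0, p = 1))
  expect_error(anova_one_way(v3, rep("a", 18)), "2 groups")
})

test_that("BH adjustment equals the brute-force step-up procedure", {
  expect_equal(bh_fdr(c(.01, .02, .03)), rep(.03, 3), tolerance = 1e-12)
  expect_identical(bh_fdr(0.2), 0.2)
  for (seed in 1:50) {
    set.seed(seed)
    p <- runif(sample(1:40, 1))^sample(1:3, 1)
    adj <- bh_fdr(p)
    expect_equal(adj, bh_oracle(p), tolerance = 1e-12)
    expect_true(all(adj >= p))
    expect_true(all(adj <= 1))
  }
  expect_error(bh_fdr(c(.5, 1.2)), "\\[0, 1\\]")
})

test_that("rank products combine and order the two p-value streams", {
  rp <- rank_product_p(c(a = .1, b = 1, c = .5), c(.2, .3, 1))
  expect_equal(rp$product[rp$gene_id == "a"], .02)
  expect_equal(rp$product[rp$gene_id == "b"], .3)
  expect_identical(rp$gene_id, c("a", "b", "c"))  # .02 < .3 < .5
  # ranking matches a brute-force re-sort
  set.seed(8)
  pa <- runif(30); pb <- runif(30)
  rp2 <- rank_product_p(pa, pb)
  expect_identical(rp2$gene_id, rp2$gene_id[order(rp2$product, rp2$gene_id)])
  expect_error(rank_product_p(runif(3), runif(4)), "mismatch")
})

test_that("housekeeping selection prefers invariant genes over planted DE", {
  for (s in 1:3) {
    set.seed(500 + s)
    labs <- balanced_labels(40)
    m <- make_mat(11, 40, seed = 500 + s)
    m["G11", labs == "sepsis"] <- m["G11", labs == "sepsis"] + 3  # planted DE
    res <- screen_all(m, labs, n_resamples = 5, config = ann_config(seed = s))
    ttp <- vapply(rownames(m), function(g) ttest_two_sample(m[g, ], labs)$p,
                  numeric(1))
    ranked <- select_housekeeping(res, ttp, n = 11)
    expect_identical(ranked$gene_id[11], "G11")  # DE gene last
    hk <- select_housekeeping(res, ttp, n = 3)
    expect_identical(nrow(hk), 3L)
    expect_false("G11" %in% hk$gene_id)
  }
  expect_error(select_housekeeping(data.frame(gene_id = "a", predictive_p = 1),
                                   c(a = 1), n = 2), "pool")
})

test_that("panel assembly enforces disjoint candidate and housekeeping sets", {
  p <- candidate_panel(sprintf("c%d", 1:5), sprintf("h%d", 1:2))
  expect_identical(p$size, 7L)
  expect_error(candidate_panel(c("a", "b"), "a"), "both")
  expect_error(candidate_panel(c("a", "a")), "duplicated")
})

test_that("t-test type-I rate is nominal under a global null", {
  set.seed(77)
  labs <- balanced_labels(40)
  rej <- vapply(1:2000, function(i)
    ttest_two_sample(rnorm(40), labs)$p < 0.05, logical(1))
  expect_gte(mean(rej), 0.03)
  expect_lte(mean(rej), 0.07)
})
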