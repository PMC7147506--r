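test_that("sigmoid has the textbook shape", {
  expect_identical(sigmoid(0), 0.5)
  x <- c(-3.2, -0.5, 0.7, 2.1)
  expect_equal(sigmoid(x) + sigmoid(-x), rep(1, 4), tolerance = 1e-15)
  expect_lt(abs(sigmoid(10) - 1), 1e-4)
  expect_true(all(diff(sigmoid(seq(-5, 5, .1))) > 0))
})

test_that("split_samples apportions 60/20/20 and is seed-deterministic", {
  labs <- balanced_labels(10)
  sp <- split_samples(labs, seed = 4)
  expect_identical(vapply(sp, length, 1L),
                   c(train = 6L, test = 2L, validation = 2L))
  sp70 <- split_samples(balanced_labels(70), seed = 4)
  expect_identical(vapply(sp70, length, 1L),
                   c(train = 42L, test = 14L, validation = 14L))
  expect_identical(split_samples(labs, seed = 11), split_samples(labs, seed = 11))
  expect_false(identical(split_samples(labs, seed = 11),
                         split_samples(labs, seed = 12)))
  expect_error(split_samples(c("a", "a", "b", "b", "b"), seed = 1),
               "at least 3")
})

test_that("split_samples partitions are disjoint, covering and stratified", {
  for (case in 1:8) {
    set.seed(case)
    n1 <- sample(3:40, 1)
    n0 <- sample(3:40, 1)
    labs <- c(rep("g1", n1), rep("g0", n0))
    sp <- split_samples(labs, seed = case * 7)
    all_idx <- unname(unlist(sp))
    expect_identical(sort(all_idx), seq_along(labs))
    expect_identical(anyDuplicated(all_idx), 0L)
    for (part in sp) {
      # every class appears in every partition
      expect_setequal(unique(labs[part]), c("g1", "g0"))
      # per-class proportions within rounding of the ratio
      for (cl in c("g1", "g0")) {
        n_cl <- sum(labs == cl)
        got <- sum(labs[part] == cl)
        frac <- if (identical(part, sp$train)) .6 else .2
        expect_lte(abs(got - frac * n_cl), 1.5)
      }
    }
  }
})

test_that("scale_features fits on train only, clips, and handles constants", {
  expect_equal(scale_features(c(2, 4)), c(0, 1))
  expect_equal(scale_features(c(3, 3, 3)), c(.5, .5, .5))
  expect_equal(scale_features(c(2, 4), c(1, 5)), c(0, 1))  # clipping
  expect_equal(scale_features(c(2, 4), 3), 0.5)
})

test_that("mse matches an independent loop computation", {
  expect_identical(mse(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_identical(mse(c(0, 1), c(1, 0)), 1)
  set.seed(2)
  a <- runif(20); b <- runif(20)
  acc <- 0
  for (i in 1:20) acc <- acc + (a[i] - b[i])^2
  expect_equal(mse(a, b), acc / 20, tolerance = 1e-15)
  expect_error(mse(numeric(0), numeric(0)), "empty")
  expect_error(mse(1:3, 1:2), "mismatch")
})

test_that("prediction equals an independent straight-line forward pass", {
  set.seed(5)
  model <- structure(list(input_weights = matrix(rnorm(3 * 2), 3, 2),
                          output_weights = rnorm(3)), class = "mlp")
  x <- matrix(runif(10 * 2), 10, 2)
  expect_equal(mlp_predict(model, x), forward_oracle(model, x),
               tolerance = 1e-12)
  # batch prediction equals the per-sample loop
  one_by_one <- vapply(seq_len(nrow(x)), function(r)
    mlp_predict(model, x[r, , drop = FALSE]), numeric(1))
  expect_identical(mlp_predict(model, x), one_by_one)
  # zero weights force 0.5 everywhere
  z <- structure(list(input_weights = matrix(0, 3, 2),
                      output_weights = rep(0, 3)), class = "mlp")
  expect_equal(mlp_predict(z, x), rep(0.5, 10), tolerance = 1e-15)
  expect_error(mlp_predict(model, matrix(0, 2, 3)), "features")
})

test_that("training is bit-deterministic and the snapshot cannot worsen", {
  set.seed(7)
  x <- matrix(runif(40), ncol = 1)
  y <- rep(0.5, 40)
  sp <- split_samples(NULL, seed = 3, n = 40)
  cfg <- ann_config(seed = 9)
  r1 <- mlp_train(x, y, sp, cfg)
  r2 <- mlp_train(x, y, sp, cfg)
  expect_identical(r1, r2)
  expect_lte(r1$best_test_mse, r1$test_mse_by_epoch[1])
  expect_equal(r1$best_test_mse, min(r1$test_mse_by_epoch), tolerance = 0)
})

test_that("infinite improvement threshold stops right after the patience window", {
  set.seed(8)
  x <- matrix(runif(30), ncol = 1)
  y <- runif(30)
  sp <- split_samples(NULL, seed = 2, n = 30)
  cfg <- ann_config(seed = 1, min_mse_improvement = Inf,
                    test_window_epochs = 17, max_train_epochs = 300)
  expect_identical(mlp_train(x, y, sp, cfg)$stop_epoch, 18L)
})

test_that("no early stop fires while the window still sees improvement", {
  set.seed(21)
  x <- matrix(runif(60), ncol = 1)
  y <- as.numeric(x > .5)
  sp <- split_samples(NULL, seed = 5, n = 60)
  cfg <- ann_config(seed = 2, test_window_epochs = 20)
  rec <- mlp_train(x, y, sp, cfg)
  if (rec$stop_epoch < cfg$max_train_epochs) {
    # over the final window before the stop, the running best improved < 0.01
    best <- cummin(rec$test_mse_by_epoch)
    w <- cfg$test_window_epochs
    expect_lt(best[rec$stop_epoch - w] - best[rec$stop_epoch],
              cfg$min_mse_improvement)
  }
  expect_lte(rec$stop_epoch, cfg$max_train_epochs)
})

test_that("a linearly separated 1-D problem is learned to low validation MSE", {
  vm <- numeric(10)
  for (s in 1:10) {
    set.seed(300 + s)
    vals <- c(rnorm(30, 2, .5), rnorm(30, -2, .5))
    labs <- balanced_labels(60)
    y <- as.numeric(labs == "sepsis")
    sp <- split_samples(labs, seed = s)
    x <- scale_features(vals[sp$train], vals)
    rec <- mlp_train(matrix(x, ncol = 1), y, sp, ann_config(seed = s))
    vm[s] <- mse(mlp_predict(rec$model, matrix(x[sp$validation], ncol = 1)),
                 y[sp$validation])
  }
  expect_lt(mean(vm), 0.1)
})

test_that("ann_config survives a YAML round trip", {
  cfg <- ann_config(n_hidden = 3, learning_rate = .2, seed = 42)
  p <- tmp_path(".yaml")
  write_ann_config(cfg, p)
  expect_equal(read_ann_config(p), cfg)
})

test_that("per-epoch losses export as a parseable TSV", {
  set.seed(30)
  x <- matrix(runif(20), ncol = 1)
  rec <- mlp_train(x, runif(20), split_samples(NULL, seed = 1, n = 20),
                   ann_config(seed = 4, max_train_epochs = 25,
                              test_window_epochs = 5))
  p <- tmp_path()
  write_train_record(rec, p)
  df <- read.delim(p)
  expect_identical(names(df), c("epoch", "train_mse", "test_mse"))
  expect_identical(nrow(df), rec$stop_epoch)
})
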