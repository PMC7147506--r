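# helper: panel with one driven gene among independent noise
planted_panel <- function(seed, sign = 1, n = 60, n_noise = 8, noise_sd = .3) {
  set.seed(seed)
  g1 <- rnorm(n)
  g2 <- sign * g1 + rnorm(n, 0, noise_sd)
  m <- rbind(g1 = g1, g2 = g2,
             matrix(rnorm(n_noise * n), n_noise, n,
                    dimnames = list(sprintf("n%02d", seq_len(n_noise)), NULL)))
  colnames(m) <- sprintf("S%02d", seq_len(n))
  m
}

test_that("ANNI recovers a planted positive dependency as the top stimulatory edge", {
  hits <- 0
  for (s in 1:3) {
    im <- anni_infer(planted_panel(600 + s), ann_config(seed = s),
                     n_resamples = 10)
    w <- im$influence[, "g2"]
    hits <- hits + (w["g1"] > 0 && names(which.max(abs(w))) == "g1")
  }
  expect_equal(hits, 3)
})

test_that("ANNI recovers a planted negative dependency as inhibitory", {
  hits <- 0
  for (s in 1:3) {
    im <- anni_infer(planted_panel(700 + s, sign = -1), ann_config(seed = s),
                     n_resamples = 10)
    hits <- hits + (im$influence["g1", "g2"] < 0)
  }
  expect_equal(hits, 3)
})

test_that("ANNI is equivariant under gene reordering and has a zero diagonal", {
  m <- planted_panel(42, n = 30, n_noise = 3)
  cfg <- ann_config(seed = 9)
  im <- anni_infer(m, cfg, n_resamples = 3)
  perm <- c(3, 1, 5, 2, 4)
  im2 <- anni_infer(m[perm, ], cfg, n_resamples = 3)
  expect_identical(im2$influence, im$influence[perm, perm])
  expect_true(all(diag(im$influence) == 0))
  expect_error(anni_infer(m[1:2, ], cfg), "at least 3")
})

test_that("independent panels carry weaker influence tails than planted ones", {
  set.seed(11)
  n <- 40
  indep <- matrix(rnorm(6 * n), 6, n,
                  dimnames = list(sprintf("i%d", 1:6), sprintf("S%d", 1:n)))
  planted <- planted_panel(11, n = n, n_noise = 4)
  cfg <- ann_config(seed = 4)
  q_indep <- quantile(abs(anni_infer(indep, cfg, n_resamples = 5)$influence), .95)
  q_plant <- quantile(abs(anni_infer(planted, cfg, n_resamples = 5)$influence), .95)
  expect_lt(q_indep, q_plant)
})

test_that("edge signs follow the influence sign and zeros yield no edge", {
  expect_identical(edge_sign(0.3), "stimulatory")
  expect_identical(edge_sign(-0.3), "inhibitory")
  expect_identical(edge_sign(0), NA_character_)
  im <- structure(list(
    gene_ids = c("a", "b", "c"),
    influence = matrix(c(0, 1, 0, -2, 0, 0, 0, 0.5, 0), 3, 3, byrow = TRUE,
                       dimnames = list(c("a", "b", "c"), c("a", "b", "c"))),
    n_models = 3L, n_resamples = 1L), class = "interaction_matrix")
  e <- interaction_edges(im)
  expect_identical(nrow(e), 3L)
  expect_false(any(e$source == e$target))
  expect_identical(e$sign[e$source == "b" & e$target == "a"], "inhibitory")
  # zero-weight entries are omitted
  expect_false(any(e$weight == 0))
  # top-n pruning keeps the strongest per source
  e1 <- interaction_edges(im, top_n_per_source = 1, sources = "b")
  expect_identical(e1$target, "a")
})

test_that("rank_hubs orders by total interaction activity with stable ties", {
  im <- structure(list(
    gene_ids = c("a", "b", "c"),
    influence = matrix(c(0, 2, 0, 1, 0, 0, 0, 0, 0), 3, 3, byrow = TRUE,
                       dimnames = list(c("a", "b", "c"), c("a", "b", "c"))),
    n_models = 3L, n_resamples = 1L), class = "interaction_matrix")
  all3 <- rank_hubs(im, k = 3)
  expect_identical(all3$gene_id, c("a", "b", "c"))
  expect_equal(all3$score, c(3, 3, 0))  # tie a/b broken lexicographically
  expect_error(rank_hubs(im, k = 4), "4 hubs")
  # two mutually dependent genes both land in the top 2
  m <- planted_panel(13, n = 40, n_noise = 2, noise_sd = .2)
  rh <- rank_hubs(anni_infer(m, ann_config(seed = 2), n_resamples = 5), k = 2)
  expect_setequal(rh$gene_id, c("g1", "g2"))
})

test_that("hub expansion recovers planted monotone targets", {
  recovered <- integer(0)
  for (s in 1:2) {
    set.seed(800 + s)
    n <- 60
    hub <- rnorm(n)
    targets <- sprintf("t%02d", 1:10)
    signs <- rep(c(1, -1), 5)
    m <- rbind(hub = hub,
               do.call(rbind, lapply(1:10, function(i)
                 signs[i] * hub + rnorm(n, 0, .3))),
               matrix(rnorm(40 * n), 40, n))
    rownames(m) <- c("hub", targets, sprintf("b%02d", 1:40))
    colnames(m) <- sprintf("S%02d", 1:n)
    ex <- expand_hub("hub", m, top_n = 10, config = ann_config(seed = s),
                     n_resamples = 50, group = "adult.sepsis")
    expect_true(ex$available)
    expect_identical(nrow(ex$selections), 10L)
    expect_true(all(ex$selections$mean_validation_mse >= 0))
    recovered <- c(recovered, sum(ex$selections$gene_id %in% targets))
  }
  expect_true(all(recovered >= 8))
})

test_that("a hub absent from the platform yields a flag and no selections", {
  m <- make_mat(6, 12)
  ex <- expand_hub("MISSING", m, config = ann_config(seed = 1),
                   n_resamples = 2, group = "pediatric.gram_positive")
  expect_false(ex$available)
  expect_identical(nrow(ex$selections), 0L)
  expect_true(is.na(ex$mean_error))
})

test_that("expansion accounting matches a brute-force recount", {
  mk <- function(group, navail, nabs, top_n) {
    c(lapply(seq_len(navail), function(i)
      structure(list(hub = paste0("h", i), group = group, available = TRUE,
                     selections = data.frame(
                       gene_id = sprintf("g%d", seq_len(top_n)),
                       mean_validation_mse = runif(top_n)),
                     mean_error = .1), class = "hub_expansion")),
      lapply(seq_len(nabs), function(i)
        structure(list(hub = paste0("x", i), group = group, available = FALSE,
                       selections = data.frame(gene_id = character(0),
                                               mean_validation_mse = numeric(0)),
                       mean_error = NA_real_), class = "hub_expansion")))
  }
  expect_identical(expansion_accounting(list())$total, 0L)
  one <- mk("g1", 1, 0, 10)
  expect_identical(expansion_accounting(one)$total, 10L)
  set.seed(2)
  res <- c(mk("a", 3, 1, 7), mk("b", 2, 2, 4))
  acct <- expansion_accounting(res)
  brute <- sum(vapply(res, function(r) nrow(r$selections), 1L))
  expect_identical(acct$total, brute)
  expect_identical(sum(acct$per_group$slots), brute)
  expect_identical(acct$per_group$absent_hubs[acct$per_group$group == "b"], 2L)
})

test_that("overlap sets equal brute-force set intersections", {
  mk1 <- function(group, genes) structure(
    list(hub = "h", group = group, available = TRUE,
         selections = data.frame(gene_id = genes,
                                 mean_validation_mse = seq_along(genes) / 10),
         mean_error = .1), class = "hub_expansion")
  same <- list(mk1("a", c("x", "y", "z")), mk1("b", c("x", "y", "z")))
  ov <- overlap_sets(same)
  expect_identical(ov$group_overlap["a", "b"], 3L)
  disj <- list(mk1("a", c("x", "y")), mk1("b", c("u", "v")))
  expect_identical(overlap_sets(disj)$group_overlap["a", "b"], 0L)
  set.seed(4)
  pool <- sprintf("g%02d", 1:30)
  r3 <- list(mk1("a", sample(pool, 12)), mk1("b", sample(pool, 9)),
             mk1("c", sample(pool, 15)))
  ov3 <- overlap_sets(r3)
  for (i in 1:3) for (j in 1:3) {
    expect_identical(ov3$group_overlap[i, j],
                     length(intersect(r3[[i]]$selections$gene_id,
                                      r3[[j]]$selections$gene_id)))
  }
  expect_error(overlap_sets(list(mk1("a", "x"))), "2 groups")
})

test_that("similar entities uses signed correlation with an inclusive cutoff", {
  set.seed(15)
  n <- 50
  anchor <- rnorm(n)
  m <- rbind(anchor = anchor,
             twin = anchor,
             anti = -anchor,
             partial = anchor + rnorm(n, 0, 1.5),
             noise = rnorm(n))
  colnames(m) <- sprintf("S%02d", 1:n)
  out <- similar_entities(m, "anchor")
  expect_true("twin" %in% out$gene_id)
  expect_equal(out$similarity[out$gene_id == "twin"], 1, tolerance = 1e-12)
  expect_false("anti" %in% out$gene_id)     # r = -1 excluded (signed cutoff)
  expect_false("anchor" %in% out$gene_id)   # never its own neighbour
  expect_false("noise" %in% out$gene_id)    # null correlation is a tail event
  mc <- m; mc["anchor", ] <- 5
  expect_error(similar_entities(mc, "anchor"), "constant")
  # Euclidean similarity variant available
  out2 <- similar_entities(m, "anchor", cutoff = .99, method = "euclidean")
  expect_true("twin" %in% out2$gene_id)
})
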