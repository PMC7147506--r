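# Tier-1 exhaustive single-gene ANN screening, SRE ranking, candidate
# filtering, housekeeping-gene selection and supporting statistics.

# class coding used throughout: class 1 = positive_class (first-listed group
# of the comparison), class 0 = the other group
.binary_labels <- function(labels, positive_class = NULL) {
  labels <- as.character(labels)
  lev <- unique(labels)
  if (length(lev) != 2)
    .stopf("exactly two classes are required; found %d", length(lev))
  if (is.null(positive_class)) positive_class <- lev[1]
  if (!positive_class %in% lev)
    .stopf("positive class '%s' not present in labels", positive_class)
  list(y = as.numeric(labels == positive_class),
       positive = positive_class,
       negative = setdiff(lev, positive_class))
}

#' Screen one gene with resampled 1-2-1 ANN models
#'
#' Trains a single-input, `n_hidden`-node, single-output backpropagation
#' network to classify the two groups from this gene alone, over
#' `n_resamples` random train/test/validation reshuffles (stratified
#' 0.6:0.2:0.2 by default).  Test MSE drives early stopping; validation MSE
#' measures classification performance.  The gene's predictive p-value is
#' the two-sided Welch t-test p comparing the model's validation-set outputs
#' between the two classes, pooled across resamples — high p means the gene
#' carries no class signal.
#'
#' @param values numeric vector, expression of one gene per sample.
#' @param labels two-class label per sample.
#' @param n_resamples number of random reshuffles (default 50).
#' @param ratio a [split_ratio()].
#' @param config an [ann_config()]; `config$seed` is the master seed.
#' @param positive_class label coded as class 1 (default: first label
#'   listed in the data); fixes the sign convention of `direction`.
#' @param gene_id identifier recorded in the result.
#' @return one-row data frame: gene_id, mean_test_mse, mean_validation_mse,
#'   predictive_p, sre (NA here; filled by [screen_all()]), direction,
#'   n_resamples.
#' @export
screen_single_gene <- function(values, labels, n_resamples = 50L,
                               ratio = split_ratio(), config = ann_config(),
                               positive_class = NULL, gene_id = "gene") {
  if (anyNA(values) || any(!is.finite(values)))
    .stopf("non-finite expression values for %s", gene_id)
  bl <- .binary_labels(labels, positive_class)
  y <- bl$y
  test_mses <- val_mses <- numeric(n_resamples)
  val_pred <- val_y <- vector("list", n_resamples)
  for (r in seq_len(n_resamples)) {
    rseed <- .child_seed(config$seed, gene_id, r)
    sp <- split_samples(labels, ratio, seed = rseed)
    x <- scale_features(values[sp$train], values)
    cfg <- config
    cfg$seed <- .lehmer_next(.seed_norm(rseed))
    rec <- mlp_train(matrix(x, ncol = 1), y, sp, cfg)
    test_mses[r] <- rec$best_test_mse
    pv <- mlp_predict(rec$model, matrix(x[sp$validation], ncol = 1))
    val_mses[r] <- mse(pv, y[sp$validation])
    val_pred[[r]] <- pv
    val_y[[r]] <- y[sp$validation]
  }
  pred <- unlist(val_pred)
  yy <- unlist(val_y)
  predictive_p <- ttest_two_sample(pred, yy)$p
  d <- mean(values[y == 1]) - mean(values[y == 0])
  data.frame(gene_id = gene_id,
             mean_test_mse = mean(test_mses),
             mean_validation_mse = mean(val_mses),
             predictive_p = predictive_p,
             sre = NA_real_,
             direction = if (d >= 0) "up_in_class1" else "up_in_class0",
             n_resamples = as.integer(n_resamples),
             stringsAsFactors = FALSE)
}

#' Signed standard residual errors (SRE)
#'
#' The per-gene between-class mean difference on the log2 scale,
#' z-standardized across genes: `SRE_g = (d_g - mean(d)) / sd(d)` with
#' `d_g = mean(class 1) - mean(class 0)`.  Positive values indicate
#' up-regulation in class 1; the scores are fold-change-like and symmetric,
#' with mean 0 and sample sd 1 across genes by construction.
#'
#' @param mat genes x samples [expression_matrix()].
#' @param labels two-class label per sample.
#' @param positive_class label treated as class 1 (default first listed).
#' @return named numeric vector of SRE values, one per gene.
#' @export
compute_sre <- function(mat, labels, positive_class = NULL) {
  mat <- expression_matrix(mat)
  bl <- .binary_labels(labels, positive_class)
  if (sum(bl$y == 1) < 2 || sum(bl$y == 0) < 2)
    .stopf("each class needs at least 2 samples")
  if (nrow(mat) < 2)
    .stopf("SRE standardization needs at least 2 genes")
  d <- rowMeans(mat[, bl$y == 1, drop = FALSE]) -
    rowMeans(mat[, bl$y == 0, drop = FALSE])
  s <- sd(d)
  if (s == 0) {
    .warnf("all genes share the same class difference; SRE set to 0")
    return(setNames(rep(0, length(d)), names(d)))
  }
  (d - mean(d)) / s
}

#' Exhaustively screen every gene and rank by |SRE|
#'
#' Runs [screen_single_gene()] on every row of the matrix (each gene gets a
#' child seed derived from the master seed and its identifier, so results do
#' not depend on screening order), attaches the across-genes [compute_sre()]
#' scores, and ranks by decreasing absolute SRE with lexicographic
#' tie-breaking on gene id.
#'
#' @inheritParams screen_single_gene
#' @param mat genes x samples [expression_matrix()].
#' @param progress print one line per 50 genes (default FALSE).
#' @return data frame of per-gene results, ordered by rank, with columns
#'   gene_id, mean_test_mse, mean_validation_mse, predictive_p, sre,
#'   direction, n_resamples, rank.
#' @export
screen_all <- function(mat, labels, n_resamples = 50L, ratio = split_ratio(),
                       config = ann_config(), positive_class = NULL,
                       progress = FALSE) {
  mat <- expression_matrix(mat)
  if (nrow(mat) < 2) .stopf("screening needs at least 2 genes")
  bl <- .binary_labels(labels, positive_class)
  rows <- vector("list", nrow(mat))
  for (g in seq_len(nrow(mat))) {
    gid <- rownames(mat)[g]
    rows[[g]] <- screen_single_gene(mat[g, ], labels, n_resamples, ratio,
                                    config, positive_class = bl$positive,
                                    gene_id = gid)
    if (progress && g %% 50 == 0)
      message(sprintf("screened %d / %d genes", g, nrow(mat)))
  }
  res <- do.call(rbind, rows)
  sre <- compute_sre(mat, labels, positive_class = bl$positive)
  res$sre <- unname(sre[res$gene_id])
  res$direction <- ifelse(res$sre >= 0, "up_in_class1", "up_in_class0")
  ord <- order(-abs(res$sre), res$gene_id)
  res <- res[ord, ]
  res$rank <- seq_len(nrow(res))
  rownames(res) <- NULL
  res
}

#' Counts of genes in the SRE tails
#'
#' @param sre numeric vector of SRE scores.
#' @param threshold tail cut (default 1): up counts `sre > threshold`, down
#'   counts `sre < -threshold`.
#' @return list with `up`, `down` and `total = up + down`.
#' @export
sre_tail_counts <- function(sre, threshold = 1) {
  up <- sum(sre > threshold)
  down <- sum(sre < -threshold)
  list(up = up, down = down, total = up + down)
}

#' Filter probe-level screening results into gene-level candidates
#'
#' Applies the consistency criteria: (i) a probe must map to exactly one
#' gene symbol (multi-gene probes rejected); (ii) all probes of a gene must
#' agree in SRE sign (disagreeing genes rejected — a true marker should show
#' a consistent regulation response in the same disease group); (iii)
#' unannotated probes are flagged for external sequence-based resolution and
#' excluded here.
#'
#' @param results probe-level data frame with columns gene_id (probe id) and
#'   sre, as from [screen_all()].
#' @param ann probe annotation (named list probe -> gene symbols).
#' @return list with `genes` (data frame gene_id, sre = mean probe SRE,
#'   direction, n_probes) and `rejected` (data frame probe, criterion,
#'   detail).
#' @export
filter_candidates <- function(results, ann) {
  probes <- results$gene_id
  n_sym <- vapply(probes, function(p) {
    if (is.null(ann[[p]])) 0L else length(ann[[p]])
  }, integer(1))
  reject_df <- function(probes, criterion, detail) {
    data.frame(probe = probes, criterion = rep(criterion, length(probes)),
               detail = rep(detail, length(probes)), stringsAsFactors = FALSE)
  }
  rej <- list()
  rej$multi <- reject_df(probes[n_sym >= 2], "i", "multi-gene probe")
  rej$unann <- reject_df(probes[n_sym == 0], "iii",
                         "unannotated probe flagged for external resolution")
  keep <- n_sym == 1
  sym <- vapply(probes[keep], function(p) ann[[p]], character(1))
  sres <- results$sre[keep]
  genes <- sort(unique(sym))
  rows <- list()
  incons <- list()
  for (g in genes) {
    s <- sres[sym == g]
    if (length(unique(sign(s[s != 0]))) > 1) {
      incons[[g]] <- data.frame(probe = probes[keep][sym == g], criterion = "ii",
                                detail = sprintf("inconsistent SRE signs for gene %s", g),
                                stringsAsFactors = FALSE)
    } else {
      rows[[g]] <- data.frame(gene_id = g, sre = mean(s),
                              direction = if (mean(s) >= 0) "up_in_class1" else "up_in_class0",
                              n_probes = length(s), stringsAsFactors = FALSE)
    }
  }
  rejected <- do.call(rbind, c(unname(rej), unname(incons)))
  if (is.null(rejected))
    rejected <- data.frame(probe = character(0), criterion = character(0),
                           detail = character(0), stringsAsFactors = FALSE)
  out <- do.call(rbind, unname(rows))
  if (is.null(out)) {
    .warnf("no gene passed the filtering criteria")
    out <- data.frame(gene_id = character(0), sre = numeric(0),
                      direction = character(0), n_probes = integer(0),
                      stringsAsFactors = FALSE)
  }
  rownames(out) <- NULL
  rownames(rejected) <- NULL
  list(genes = out, rejected = rejected)
}

#' Two-sample Welch t-test
#'
#' @param values numeric vector.
#' @param labels two-class label per value (or a 0/1 numeric vector).
#' @return list with `t` (positive when class 1 mean is larger) and `p`
#'   (two-sided).  When both groups are constant: p = 1 if the means are
#'   equal, otherwise p = 0 with an infinite statistic.
#' @export
ttest_two_sample <- function(values, labels) {
  bl <- .binary_labels(labels)
  a <- values[bl$y == 1]
  b <- values[bl$y == 0]
  if (length(a) < 2 || length(b) < 2) .stopf("each class needs >= 2 values")
  if (sd(a) == 0 && sd(b) == 0) {
    if (mean(a) == mean(b)) return(list(t = 0, p = 1))
    return(list(t = sign(mean(a) - mean(b)) * Inf, p = 0))
  }
  tt <- tryCatch(t.test(a, b, var.equal = FALSE),
                 error = function(e) NULL)  # "data are essentially constant"
  if (is.null(tt)) {
    return(list(t = 0, p = if (isTRUE(all.equal(mean(a), mean(b)))) 1 else 0))
  }
  list(t = unname(tt$statistic), p = tt$p.value)
}

#' One-way ANOVA
#'
#' Classical equal-variance one-way F test across two or more groups.
#'
#' @param values numeric vector.
#' @param labels group label per value (>= 2 groups, each >= 2 values).
#' @return list with `F` and `p`.  All groups constant and equal gives
#'   p = 1 (F = 0).
#' @export
anova_one_way <- function(values, labels) {
  labels <- as.character(labels)
  lev <- unique(labels)
  if (length(lev) < 2) .stopf("ANOVA needs at least 2 groups")
  if (any(table(labels) < 2)) .stopf("each group needs >= 2 values")
  if (sd(values) == 0) return(list(F = 0, p = 1))
  ow <- oneway.test(values ~ factor(labels), var.equal = TRUE)
  list(F = unname(ow$statistic), p = ow$p.value)
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up adjustment with monotonicity enforcement, capped at 1; input
#' order is preserved.
#'
#' @param pvalues numeric vector of raw p-values in `[0, 1]`.
#' @return adjusted p-values, same order.
#' @export
bh_fdr <- function(pvalues) {
  if (anyNA(pvalues) || any(pvalues < 0 | pvalues > 1))
    .stopf("p-values must lie in [0, 1]")
  p.adjust(pvalues, method = "BH")
}

#' Rank product of ANN and t-test p-values
#'
#' Combines the two evidence streams per gene as the product
#' `p_ann * p_ttest`; genes are ranked by ascending product (lexicographic
#' gene-id tie-break).
#'
#' @param p_ann,p_ttest aligned numeric vectors of p-values.
#' @param gene_ids optional identifiers (default from names or index).
#' @return data frame gene_id, p_ann, p_ttest, product, rank (1 = smallest
#'   product), ordered by rank.
#' @export
rank_product_p <- function(p_ann, p_ttest, gene_ids = NULL) {
  if (length(p_ann) != length(p_ttest))
    .stopf("length mismatch: %d vs %d", length(p_ann), length(p_ttest))
  if (is.null(gene_ids))
    gene_ids <- if (!is.null(names(p_ann))) names(p_ann)
                else sprintf("g%03d", seq_along(p_ann))
  df <- data.frame(gene_id = gene_ids, p_ann = p_ann, p_ttest = p_ttest,
                   product = p_ann * p_ttest, stringsAsFactors = FALSE)
  df <- df[order(df$product, df$gene_id), ]
  df$rank <- seq_len(nrow(df))
  rownames(df) <- NULL
  df
}

#' Select housekeeping genes from a candidate pool
#'
#' Ranks the pool by invariance across the two disease groups: the
#' invariance score is `min(predictive_p, ttest_p)` and the most invariant
#' genes (largest score — no class signal under either the ANN or the
#' t-test) are selected.
#'
#' @param screen_results data frame with gene_id and predictive_p (the
#'   candidate housekeeping pool, e.g. from [screen_all()]).
#' @param ttest_p named numeric vector of two-sided t-test p-values for the
#'   same genes.
#' @param n how many housekeeping genes to select (default 3).
#' @return data frame gene_id, predictive_p, ttest_p, invariance, ordered
#'   most-invariant first, `n` rows.
#' @export
select_housekeeping <- function(screen_results, ttest_p, n = 3L) {
  pool <- screen_results$gene_id
  if (n > length(pool))
    .stopf("requested %d housekeeping genes from a pool of %d", n, length(pool))
  tp <- unname(ttest_p[pool])
  if (anyNA(tp)) .stopf("missing t-test p-value for some pool genes")
  df <- data.frame(gene_id = pool, predictive_p = screen_results$predictive_p,
                   ttest_p = tp,
                   invariance = pmin(screen_results$predictive_p, tp),
                   stringsAsFactors = FALSE)
  df <- df[order(-df$invariance, df$gene_id), ]
  rownames(df) <- NULL
  df[seq_len(n), ]
}

#' Assemble a candidate + housekeeping gene panel
#'
#' @param candidates character vector of candidate marker genes.
#' @param housekeeping character vector of housekeeping genes; must be
#'   disjoint from the candidates.
#' @return a `candidate_panel` list with `candidates`, `housekeeping` and
#'   `size` (total panel genes).
#' @export
candidate_panel <- function(candidates, housekeeping = character(0)) {
  candidates <- as.character(candidates)
  housekeeping <- as.character(housekeeping)
  if (anyDuplicated(candidates)) .stopf("duplicated candidate gene")
  if (anyDuplicated(housekeeping)) .stopf("duplicated housekeeping gene")
  both <- intersect(candidates, housekeeping)
  if (length(both))
    .stopf("gene %s is listed as both candidate and housekeeping", both[1])
  structure(list(candidates = candidates, housekeeping = housekeeping,
                 size = length(candidates) + length(housekeeping)),
            class = "candidate_panel")
}

#' Write a screening report as TSV
#' @param results data frame from [screen_all()] (optionally augmented with
#'   ttest_p / fdr_p columns).
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_screen_report <- function(results, path) {
  .write_tsv(results, path)
}
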