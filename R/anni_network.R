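# Tier-2 leave-one-gene-out interaction inference (ANNI), hub detection,
# per-group hub expansion, overlap sets and similar-entities screening.

#' Infer a signed gene-gene influence matrix by leave-one-gene-out ANN
#' regression
#'
#' For each target gene in turn, a 3-layer network with the remaining
#' `N - 1` genes as inputs is trained to predict the omitted gene's min-max
#' scaled expression; the trained weights are condensed into a per-source
#' influence (the linearized input-to-output weight path, `sum_h
#' w_in[s, h] * w_out[h]`, which preserves sign) and averaged over
#' `n_resamples` random train/test reshuffles.  Positive influence is
#' stimulatory, negative inhibitory.
#'
#' @param panel genes x samples [expression_matrix()] restricted to the
#'   candidate panel (N >= 3 genes).
#' @param config an [ann_config()]; its `seed` is the master seed (each
#'   target gene gets an order-independent child seed).
#' @param n_resamples random reshuffles per target (default 50).
#' @param ratio a [split_ratio()]; the train and test partitions drive
#'   fitting and early stopping (no validation partition is needed for
#'   inference).
#' @return an `interaction_matrix`: list with `gene_ids`, `influence` (N x N
#'   signed matrix, `[s, t]` = averaged influence of source s on target t,
#'   zero diagonal), `n_models = N`, `n_resamples`.
#' @export
anni_infer <- function(panel, config = ann_config(), n_resamples = 50L,
                       ratio = split_ratio()) {
  panel <- expression_matrix(panel)
  n <- nrow(panel)
  if (n < 3) .stopf("ANNI needs at least 3 genes; got %d", n)
  input_order <- rownames(panel)
  # canonical lexicographic gene order makes the result equivariant under
  # row reordering (weight initialization is consumed input by input)
  panel <- panel[order(input_order), , drop = FALSE]
  genes <- rownames(panel)
  # per-gene min-max scaling so the sigmoid output can reach every target
  scaled <- t(apply(panel, 1, function(v) scale_features(v)))
  influence <- matrix(0, n, n, dimnames = list(genes, genes))
  ns <- ncol(panel)
  for (t_idx in seq_len(n)) {
    tgt <- genes[t_idx]
    acc <- numeric(n - 1)
    x <- t(scaled[-t_idx, , drop = FALSE])
    y <- scaled[t_idx, ]
    for (r in seq_len(n_resamples)) {
      rseed <- .child_seed(config$seed, paste0("anni:", tgt), r)
      sp <- split_samples(NULL, ratio, seed = rseed, n = ns)
      cfg <- config
      cfg$seed <- .lehmer_next(.seed_norm(rseed))
      rec <- tryCatch(mlp_train(x, y, sp, cfg), error = function(e) {
        .stopf("ANNI training failed for target gene %s: %s", tgt,
               conditionMessage(e))
      })
      acc <- acc + .mlp_influence(rec$model)
    }
    influence[-t_idx, t_idx] <- acc / n_resamples
  }
  influence <- influence[input_order, input_order, drop = FALSE]
  structure(list(gene_ids = input_order, influence = influence, n_models = n,
                 n_resamples = as.integer(n_resamples)),
            class = "interaction_matrix")
}

#' Sign of an inferred influence
#' @param weight signed influence value(s).
#' @return "stimulatory" for positive, "inhibitory" for negative, NA for
#'   exactly zero (a zero influence yields no edge).
#' @export
edge_sign <- function(weight) {
  ifelse(weight > 0, "stimulatory", ifelse(weight < 0, "inhibitory", NA_character_))
}

#' Extract an edge list from an interaction matrix
#'
#' @param im an `interaction_matrix` from [anni_infer()].
#' @param top_n_per_source keep only the strongest `|influence|` edges per
#'   source gene (NULL = keep all non-zero edges).
#' @param sources restrict to these source genes (default all).
#' @return data frame source, target, weight, sign; zero influences are
#'   omitted, self-edges never occur.
#' @export
interaction_edges <- function(im, top_n_per_source = NULL, sources = NULL) {
  genes <- im$gene_ids
  if (is.null(sources)) sources <- genes
  rows <- list()
  for (s in sources) {
    w <- im$influence[s, ]
    w <- w[names(w) != s & w != 0]
    if (!length(w)) next
    if (!is.null(top_n_per_source) && length(w) > top_n_per_source) {
      ord <- order(-abs(w), names(w))
      w <- w[ord[seq_len(top_n_per_source)]]
    }
    rows[[s]] <- data.frame(source = s, target = names(w), weight = unname(w),
                            sign = edge_sign(unname(w)), stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, unname(rows))
  if (is.null(out))
    out <- data.frame(source = character(0), target = character(0),
                      weight = numeric(0), sign = character(0),
                      stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Rank hub genes by total interaction activity
#'
#' The hub score of a gene is the sum of absolute influences over all its
#' partners, incoming plus outgoing (the diagonal is zero by construction).
#'
#' @param im an `interaction_matrix`.
#' @param k how many hubs to return (default 8).
#' @return data frame gene_id, score, rank — top `k` by score, ties broken
#'   lexicographically.
#' @export
rank_hubs <- function(im, k = 8L) {
  n <- length(im$gene_ids)
  if (k > n) .stopf("requested %d hubs from %d genes", k, n)
  score <- rowSums(abs(im$influence)) + colSums(abs(im$influence))
  df <- data.frame(gene_id = im$gene_ids, score = unname(score),
                   stringsAsFactors = FALSE)
  df <- df[order(-df$score, df$gene_id), ]
  df$rank <- seq_len(nrow(df))
  rownames(df) <- NULL
  df[seq_len(k), ]
}

#' Expand one hub gene within one disease group
#'
#' Exhaustive single-input screening against the hub: every other gene in
#' the group's matrix is used (one at a time) as the input of a small ANN
#' regressing the hub's min-max scaled expression, over resampled
#' train/test/validation splits; genes are ranked by mean validation MSE
#' (lower = more predictive of the hub) and the best `top_n` are selected.
#' A hub absent from the group's platform yields an availability flag and
#' no selections.
#'
#' @param hub hub gene identifier.
#' @param group_mat genes x samples [expression_matrix()] for one
#'   cohort-group.
#' @param top_n selections to return (default 10).
#' @param config an [ann_config()].
#' @param n_resamples reshuffles per candidate gene (default 50).
#' @param ratio a [split_ratio()].
#' @param group label recorded in the result.
#' @return a `hub_expansion` list: hub, group, available, selections (data
#'   frame gene_id, mean_validation_mse, ordered best first), mean_error
#'   (mean validation MSE over the selections; NA when unavailable).
#' @export
expand_hub <- function(hub, group_mat, top_n = 10L, config = ann_config(),
                       n_resamples = 50L, ratio = split_ratio(),
                       group = "group") {
  group_mat <- expression_matrix(group_mat)
  empty <- data.frame(gene_id = character(0), mean_validation_mse = numeric(0),
                      stringsAsFactors = FALSE)
  if (!hub %in% rownames(group_mat)) {
    return(structure(list(hub = hub, group = group, available = FALSE,
                          selections = empty, mean_error = NA_real_),
                     class = "hub_expansion"))
  }
  others <- setdiff(rownames(group_mat), hub)
  if (!length(others)) .stopf("no genes besides the hub in the group matrix")
  if (length(others) < top_n)
    .warnf("only %d genes available for hub %s in %s; returning all",
           length(others), hub, group)
  yfull <- as.numeric(group_mat[hub, ])
  ns <- ncol(group_mat)
  errs <- numeric(length(others))
  for (i in seq_along(others)) {
    g <- others[i]
    xfull <- as.numeric(group_mat[g, ])
    vm <- numeric(n_resamples)
    for (r in seq_len(n_resamples)) {
      rseed <- .child_seed(config$seed, paste0("expand:", group, ":", hub, ":", g), r)
      sp <- split_samples(NULL, ratio, seed = rseed, n = ns)
      x <- scale_features(xfull[sp$train], xfull)
      y <- scale_features(yfull[sp$train], yfull)
      cfg <- config
      cfg$seed <- .lehmer_next(.seed_norm(rseed))
      rec <- mlp_train(matrix(x, ncol = 1), y, sp, cfg)
      pv <- mlp_predict(rec$model, matrix(x[sp$validation], ncol = 1))
      vm[r] <- mse(pv, y[sp$validation])
    }
    errs[i] <- mean(vm)
  }
  ord <- order(errs, others)
  take <- ord[seq_len(min(top_n, length(others)))]
  sel <- data.frame(gene_id = others[take], mean_validation_mse = errs[take],
                    stringsAsFactors = FALSE)
  structure(list(hub = hub, group = group, available = TRUE, selections = sel,
                 mean_error = mean(sel$mean_validation_mse)),
            class = "hub_expansion")
}

#' Tally selection slots across hub expansions
#'
#' Each available (hub, group) expansion contributes its number of selected
#' genes (with multiplicity — the same gene selected for two hubs counts
#' twice); absent hubs contribute zero.
#'
#' @param results list of `hub_expansion` objects.
#' @return list with `total` slots and `per_group` data frame (group,
#'   available_hubs, absent_hubs, slots).
#' @export
expansion_accounting <- function(results) {
  if (!length(results))
    return(list(total = 0L,
                per_group = data.frame(group = character(0),
                                       available_hubs = integer(0),
                                       absent_hubs = integer(0),
                                       slots = integer(0),
                                       stringsAsFactors = FALSE)))
  groups <- vapply(results, `[[`, character(1), "group")
  avail <- vapply(results, `[[`, logical(1), "available")
  slots <- vapply(results, function(r) nrow(r$selections), integer(1))
  per_group <- do.call(rbind, lapply(unique(groups), function(g) {
    i <- groups == g
    data.frame(group = g, available_hubs = sum(avail[i]),
               absent_hubs = sum(!avail[i]), slots = sum(slots[i]),
               stringsAsFactors = FALSE)
  }))
  rownames(per_group) <- NULL
  list(total = sum(slots), per_group = per_group)
}

#' Overlap of expansion-selected genes between groups
#'
#' @param results list of `hub_expansion` objects spanning >= 2 groups.
#' @return list with `occurrences` (data frame gene, hub, group — one row
#'   per selection) and `group_overlap` (symmetric matrix of counts of
#'   distinct genes shared between each pair of groups' selection sets).
#' @export
overlap_sets <- function(results) {
  occ <- do.call(rbind, lapply(results, function(r) {
    if (!nrow(r$selections)) return(NULL)
    data.frame(gene = r$selections$gene_id, hub = r$hub, group = r$group,
               stringsAsFactors = FALSE)
  }))
  if (is.null(occ))
    occ <- data.frame(gene = character(0), hub = character(0),
                      group = character(0), stringsAsFactors = FALSE)
  groups <- unique(vapply(results, `[[`, character(1), "group"))
  if (length(groups) < 2) .stopf("overlap analysis needs >= 2 groups")
  sets <- lapply(groups, function(g) unique(occ$gene[occ$group == g]))
  names(sets) <- groups
  ov <- matrix(0L, length(groups), length(groups),
               dimnames = list(groups, groups))
  for (i in seq_along(groups)) {
    for (j in seq_along(groups)) {
      ov[i, j] <- length(intersect(sets[[i]], sets[[j]]))
    }
  }
  list(occurrences = occ, group_overlap = ov)
}

#' Genes with expression profiles similar to an anchor gene
#'
#' Similarity is the Pearson correlation of expression profiles across
#' samples (the scale-free member of the Euclidean/covariance family); an
#' alternative normalized-Euclidean similarity `1 / (1 + d / sqrt(n))` is
#' available.  The cut-off is inclusive and signed: anti-correlated genes
#' are excluded under the default metric.
#'
#' @param mat genes x samples [expression_matrix()].
#' @param anchor anchor gene identifier (excluded from its own result).
#' @param cutoff minimum similarity (default 0.7).
#' @param candidates restrict to these genes (default all others).
#' @param method "pearson" (default) or "euclidean".
#' @return data frame gene_id, similarity — genes with similarity >=
#'   cutoff, ordered by decreasing similarity.
#' @export
similar_entities <- function(mat, anchor, cutoff = 0.7, candidates = NULL,
                             method = c("pearson", "euclidean")) {
  mat <- expression_matrix(mat)
  method <- match.arg(method)
  if (!anchor %in% rownames(mat)) .stopf("anchor gene %s not in matrix", anchor)
  a <- mat[anchor, ]
  if (sd(a) == 0)
    .stopf("anchor gene %s has a constant profile; similarity is undefined", anchor)
  if (is.null(candidates)) candidates <- setdiff(rownames(mat), anchor)
  candidates <- setdiff(candidates, anchor)
  simv <- vapply(candidates, function(g) {
    v <- mat[g, ]
    if (method == "pearson") {
      if (sd(v) == 0) return(-Inf)
      cor(a, v)
    } else {
      1 / (1 + sqrt(sum((a - v)^2)) / sqrt(length(a)))
    }
  }, numeric(1))
  keep <- simv >= cutoff
  df <- data.frame(gene_id = candidates[keep], similarity = unname(simv[keep]),
                   stringsAsFactors = FALSE)
  df <- df[order(-df$similarity, df$gene_id), ]
  rownames(df) <- NULL
  df
}

#' Write an interaction matrix (square TSV) and its edge list
#' @param im an `interaction_matrix`.
#' @param path output path for the square matrix TSV.
#' @param edge_path optional output path for the long-form edge TSV
#'   (source, target, weight, sign).
#' @return the matrix path, invisibly.
#' @export
write_interaction_matrix <- function(im, path, edge_path = NULL) {
  df <- data.frame(gene_id = im$gene_ids,
                   as.data.frame(im$influence, optional = TRUE),
                   check.names = FALSE, stringsAsFactors = FALSE)
  .write_tsv(df, path)
  if (!is.null(edge_path)) .write_tsv(interaction_edges(im), edge_path)
  invisible(path)
}
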