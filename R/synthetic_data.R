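# Synthetic expression data with planted ground truth: differentially
# expressed genes, invariant housekeeping genes, hub genes with signed
# targets, probe-level redundancy, and platform-specific gene absence.

#' Specification of a synthetic expression study
#'
#' Describes a two-class study on the log2 scale with additive Gaussian
#' noise.  Defaults give a desk-scale study: two groups of 60 samples, 200
#' genes of which 10 are differentially expressed at 2 noise-sd effect size,
#' 10 are invariant housekeeping genes, and 2 are hubs each driving 5
#' target genes (alternating stimulatory/inhibitory signs) with target
#' noise sd 0.3.
#'
#' @param n_per_group named integer vector: samples per disease group
#'   (names from [DISEASE_GROUPS]).
#' @param cohort cohort label for all samples.
#' @param n_genes total genes (background + planted).
#' @param n_de planted differentially expressed genes.
#' @param de_effect effect size in units of `noise_sd` (mean shift of the
#'   affected groups).
#' @param de_groups groups receiving the shift (default the first group).
#' @param n_housekeeping planted invariant genes.
#' @param n_hubs hub genes.
#' @param targets_per_hub target genes per hub.
#' @param target_sign per-target signs (+1 stimulatory / -1 inhibitory),
#'   recycled; default alternates.
#' @param target_noise_sd sd of the target-specific noise around the signed
#'   hub signal.
#' @param noise_sd background biological + technical noise sd (log2 units).
#' @param baseline_mean,baseline_sd per-gene baseline log2 intensity
#'   distribution.
#' @param probe_dup_fraction fraction of genes measured by two probes
#'   instead of one.
#' @param n_multigene_probes probes annotated to two gene symbols.
#' @param n_unannotated_probes probes with no gene symbol.
#' @param probe_noise_sd probe-level measurement noise sd.
#' @param absent_genes,absent_groups genes absent from the platform used for
#'   the listed groups (their rows are withheld from those groups'
#'   matrices by [pipeline_group_matrices()]).
#' @param hub_transfer "linear" (default) or "sigmoid" hub-to-target
#'   transfer.
#' @param seed integer seed.
#' @return a `simulation_spec` list.
#' @export
simulation_spec <- function(n_per_group = c(sepsis = 60L, SIRS = 60L),
                            cohort = "adult", n_genes = 200L, n_de = 10L,
                            de_effect = 2, de_groups = names(n_per_group)[1],
                            n_housekeeping = 10L, n_hubs = 2L,
                            targets_per_hub = 5L,
                            target_sign = c(1, -1),
                            target_noise_sd = 0.3, noise_sd = 1,
                            baseline_mean = 8, baseline_sd = 1,
                            probe_dup_fraction = 0.3,
                            n_multigene_probes = 5L,
                            n_unannotated_probes = 5L,
                            probe_noise_sd = 0.05,
                            absent_genes = character(0),
                            absent_groups = character(0),
                            hub_transfer = c("linear", "sigmoid"),
                            seed = 1L) {
  hub_transfer <- match.arg(hub_transfer)
  if (is.null(names(n_per_group)) || !all(names(n_per_group) %in% DISEASE_GROUPS))
    .stopf("n_per_group must be named with disease-group labels")
  if (!cohort %in% COHORTS) .stopf("unknown cohort '%s'", cohort)
  if (!all(de_groups %in% names(n_per_group)))
    .stopf("de_groups must be a subset of the sampled groups")
  n_planted <- n_de + n_housekeeping + n_hubs * (1 + targets_per_hub)
  if (n_genes < n_planted)
    .stopf("n_genes (%d) smaller than planted genes (%d)", n_genes, n_planted)
  stopifnot(de_effect >= 0, target_noise_sd >= 0, noise_sd > 0,
            probe_dup_fraction >= 0, probe_dup_fraction <= 1,
            probe_noise_sd >= 0)
  structure(list(n_per_group = n_per_group, cohort = cohort,
                 n_genes = as.integer(n_genes), n_de = as.integer(n_de),
                 de_effect = de_effect, de_groups = de_groups,
                 n_housekeeping = as.integer(n_housekeeping),
                 n_hubs = as.integer(n_hubs),
                 targets_per_hub = as.integer(targets_per_hub),
                 target_sign = target_sign,
                 target_noise_sd = target_noise_sd, noise_sd = noise_sd,
                 baseline_mean = baseline_mean, baseline_sd = baseline_sd,
                 probe_dup_fraction = probe_dup_fraction,
                 n_multigene_probes = as.integer(n_multigene_probes),
                 n_unannotated_probes = as.integer(n_unannotated_probes),
                 probe_noise_sd = probe_noise_sd,
                 absent_genes = absent_genes, absent_groups = absent_groups,
                 hub_transfer = hub_transfer, seed = as.integer(seed)),
            class = "simulation_spec")
}

#' Simulate a probe-level expression study with ground truth
#'
#' Background genes are independent Gaussians on the log2 scale
#' (`baseline + N(0, noise_sd)`); planted DE genes get a
#' `de_effect * noise_sd` mean shift in the affected groups; housekeeping
#' genes are distributed identically in every group; each hub's targets are
#' `baseline + sign * (hub - hub_baseline) + N(0, target_noise_sd)` (or a
#' sigmoidal transfer of the same signal).  The probe layer duplicates a
#' fraction of genes with small probe noise and injects multi-gene and
#' unannotated probes.  Deterministic for a given spec seed.
#'
#' @param spec a [simulation_spec()].
#' @return list with `expression` (probe-level [expression_matrix()]),
#'   `gene_expression` (the underlying gene-level matrix), `annotation`
#'   (probe -> symbols), `metadata` (sample metadata data frame) and
#'   `truth` (list: `roles` data frame gene/role, `edges` data frame
#'   source/target/sign, `effects` data frame gene/effect/direction/groups).
#' @export
simulate_dataset <- function(spec = simulation_spec()) {
  .with_seed(spec$seed, {
    groups <- rep(names(spec$n_per_group), spec$n_per_group)
    ns <- length(groups)
    sample_ids <- sprintf("S%03d", seq_len(ns))
    meta <- data.frame(sample_id = sample_ids, cohort = spec$cohort,
                       group = groups, stringsAsFactors = FALSE)

    genes <- sprintf("G%03d", seq_len(spec$n_genes))
    role <- rep("background", spec$n_genes)
    i <- 1
    de_genes <- genes[seq_len(spec$n_de) + i - 1]; i <- i + spec$n_de
    hk_genes <- genes[seq_len(spec$n_housekeeping) + i - 1]
    i <- i + spec$n_housekeeping
    hub_genes <- character(spec$n_hubs)
    target_map <- list()
    for (h in seq_len(spec$n_hubs)) {
      hub_genes[h] <- genes[i]; i <- i + 1
      target_map[[hub_genes[h]]] <- genes[seq_len(spec$targets_per_hub) + i - 1]
      i <- i + spec$targets_per_hub
    }
    role[genes %in% de_genes] <- "DE"
    role[genes %in% hk_genes] <- "housekeeping"
    role[genes %in% hub_genes] <- "hub"
    role[genes %in% unlist(target_map)] <- "hub_target"

    baseline <- rnorm(spec$n_genes, spec$baseline_mean, spec$baseline_sd)
    names(baseline) <- genes
    gm <- matrix(rnorm(spec$n_genes * ns, 0, spec$noise_sd), spec$n_genes, ns,
                 dimnames = list(genes, sample_ids)) + baseline

    # DE shift in affected groups; direction alternates up/down
    de_dir <- rep(c(1, -1), length.out = spec$n_de)
    affected <- groups %in% spec$de_groups
    for (k in seq_along(de_genes)) {
      gm[de_genes[k], affected] <- gm[de_genes[k], affected] +
        de_dir[k] * spec$de_effect * spec$noise_sd
    }

    # hub targets: signed transfer of the hub's centred signal
    edges <- list()
    signs <- rep(spec$target_sign, length.out = spec$targets_per_hub)
    for (h in hub_genes) {
      centred <- gm[h, ] - baseline[h]
      for (k in seq_along(target_map[[h]])) {
        tg <- target_map[[h]][k]
        signal <- if (spec$hub_transfer == "linear") {
          signs[k] * centred
        } else {
          # sigmoidal transfer matched in scale to the linear one
          signs[k] * 4 * spec$noise_sd *
            (sigmoid(centred / spec$noise_sd) - 0.5)
        }
        gm[tg, ] <- baseline[tg] + signal +
          rnorm(ns, 0, spec$target_noise_sd)
        edges[[paste(h, tg)]] <- data.frame(source = h, target = tg,
                                            sign = signs[k],
                                            stringsAsFactors = FALSE)
      }
    }

    # probe layer: 1 or 2 probes per gene, plus multi-gene and unannotated
    n_probes_per_gene <- 1L + (runif(spec$n_genes) < spec$probe_dup_fraction)
    probe_rows <- list()
    ann <- list()
    pn <- 0
    for (g in seq_along(genes)) {
      for (pp in seq_len(n_probes_per_gene[g])) {
        pn <- pn + 1
        pid <- sprintf("P%04d", pn)
        probe_rows[[pid]] <- gm[g, ] + rnorm(ns, 0, spec$probe_noise_sd)
        ann[[pid]] <- genes[g]
      }
    }
    for (k in seq_len(spec$n_multigene_probes)) {
      pn <- pn + 1
      pid <- sprintf("P%04d", pn)
      pair <- sample(genes, 2)
      probe_rows[[pid]] <- colMeans(gm[pair, ]) + rnorm(ns, 0, spec$probe_noise_sd)
      ann[[pid]] <- pair
    }
    for (k in seq_len(spec$n_unannotated_probes)) {
      pn <- pn + 1
      pid <- sprintf("P%04d", pn)
      probe_rows[[pid]] <- spec$baseline_mean + rnorm(ns, 0, spec$noise_sd)
      ann[[pid]] <- character(0)
    }
    pm <- do.call(rbind, probe_rows)
    dimnames(pm) <- list(names(probe_rows), sample_ids)

    truth <- list(
      roles = data.frame(gene = genes, role = role, stringsAsFactors = FALSE),
      edges = do.call(rbind, c(unname(edges),
                               list(data.frame(source = character(0),
                                               target = character(0),
                                               sign = numeric(0))))),
      effects = data.frame(gene = de_genes,
                           effect = spec$de_effect * de_dir,
                           direction = ifelse(de_dir > 0, "up", "down"),
                           groups = rep(paste(spec$de_groups, collapse = ","),
                                        length(de_genes)),
                           stringsAsFactors = FALSE))
    list(expression = expression_matrix(pm),
         gene_expression = expression_matrix(gm),
         annotation = ann, metadata = meta, truth = truth)
  })
}

#' Score pipeline outputs against planted truth
#'
#' Exact set arithmetic: precision and recall of DE-gene detection,
#' housekeeping selection and hub ranking, plus the sign-agreement rate of
#' recovered edges (computed only over planted edges that were recovered).
#' Precision of an empty selection is reported as NA.
#'
#' @param truth the `truth` component of [simulate_dataset()] output.
#' @param de_selected,housekeeping_selected,hubs character vectors of gene
#'   identifiers selected by the pipeline (any may be NULL to skip).
#' @param edges data frame source/target/weight (or sign) of inferred
#'   edges, or NULL.
#' @return data frame with columns component, precision, recall, n_true,
#'   n_selected; edge rows add sign agreement as `precision` over recovered
#'   planted edges.
#' @export
truth_recovery_report <- function(truth, de_selected = NULL,
                                  housekeeping_selected = NULL, hubs = NULL,
                                  edges = NULL) {
  known <- truth$roles$gene
  score_set <- function(selected, true_set, component) {
    if (is.null(selected)) return(NULL)
    bad <- setdiff(selected, known)
    if (length(bad)) .stopf("unknown gene id in %s selection: %s", component, bad[1])
    tp <- length(intersect(selected, true_set))
    data.frame(component = component,
               precision = if (length(selected)) tp / length(selected) else NA_real_,
               recall = if (length(true_set)) tp / length(true_set) else NA_real_,
               n_true = length(true_set), n_selected = length(selected),
               stringsAsFactors = FALSE)
  }
  out <- list(
    score_set(de_selected, truth$roles$gene[truth$roles$role == "DE"], "de"),
    score_set(housekeeping_selected,
              truth$roles$gene[truth$roles$role == "housekeeping"], "housekeeping"),
    score_set(hubs, truth$roles$gene[truth$roles$role == "hub"], "hubs"))
  if (!is.null(edges) && nrow(truth$edges)) {
    bad <- setdiff(c(edges$source, edges$target), known)
    if (length(bad)) .stopf("unknown gene id in edges: %s", bad[1])
    key <- paste(truth$edges$source, truth$edges$target)
    ekey <- paste(edges$source, edges$target)
    hit <- match(key, ekey)
    recovered <- !is.na(hit)
    agree <- NA_real_
    if (any(recovered)) {
      inferred_sign <- if ("weight" %in% names(edges)) {
        sign(edges$weight[hit[recovered]])
      } else {
        ifelse(edges$sign[hit[recovered]] == "stimulatory", 1, -1)
      }
      agree <- mean(inferred_sign == sign(truth$edges$sign[recovered]))
    }
    out <- c(out, list(data.frame(
      component = "edges",
      precision = agree,  # sign agreement over recovered planted edges
      recall = mean(recovered), n_true = nrow(truth$edges),
      n_selected = nrow(edges), stringsAsFactors = FALSE)))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Write simulation truth tables as TSV
#' @param truth the `truth` component of [simulate_dataset()] output.
#' @param prefix output path prefix (`<prefix>.roles.tsv`,
#'   `<prefix>.edges.tsv`, `<prefix>.effects.tsv`).
#' @return the written paths, invisibly.
#' @export
write_truth <- function(truth, prefix) {
  paths <- c(roles = paste0(prefix, ".roles.tsv"),
             edges = paste0(prefix, ".edges.tsv"),
             effects = paste0(prefix, ".effects.tsv"))
  .write_tsv(truth$roles, paths["roles"])
  .write_tsv(truth$edges, paths["edges"])
  .write_tsv(truth$effects, paths["effects"])
  invisible(paths)
}
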