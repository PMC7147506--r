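# End-to-end pipeline: simulate/load -> collapse -> normalize -> tier-1
# screen -> housekeeping -> ANNI -> hubs -> per-group expansion -> overlaps
# -> exports.  Driven by a YAML-able config; byte-identical outputs for a
# fixed config + seed.

#' Default pipeline configuration
#'
#' @param seed master seed for every stochastic stage.
#' @param out_dir output directory.
#' @param simulation a [simulation_spec()] (set `input` instead to read
#'   files).
#' @param input optional list with paths `expression`, `annotation`,
#'   `metadata` for real data.
#' @param comparison list: `cohort`, `groups` (two labels; the first is
#'   coded class 1 and fixes all sign conventions).
#' @param normalize apply 75th-percentile + median-baseline normalization
#'   before screening (default FALSE; screening operates on collapsed log2
#'   values).
#' @param n_resamples ANN reshuffles for screening and ANNI.
#' @param n_candidates candidate genes taken from the top of the |SRE|
#'   ranking.
#' @param n_housekeeping housekeeping genes to select.
#' @param housekeeping_pool optional gene ids forming the housekeeping
#'   candidate pool (default: the simulation's planted housekeeping genes
#'   plus an equal number of low-|SRE| genes, or the bottom of the |SRE|
#'   ranking for file input).
#' @param n_hubs hubs to rank (k).
#' @param expansion_top_n genes selected per (hub, group).
#' @param expansion_groups `cohort.group` keys to expand over (default: all
#'   groups present).
#' @param expansion_resamples reshuffles per candidate in hub expansion.
#' @param ann named list overriding [ann_config()] fields.
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(seed = 1L, out_dir = "anninet_out",
                            simulation = simulation_spec(seed = seed),
                            input = NULL,
                            comparison = list(cohort = "adult",
                                              groups = c("sepsis", "SIRS")),
                            normalize = FALSE, n_resamples = 50L,
                            n_candidates = 12L, n_housekeeping = 3L,
                            housekeeping_pool = NULL, n_hubs = 2L,
                            expansion_top_n = 10L,
                            expansion_groups = NULL,
                            expansion_resamples = 10L, ann = list()) {
  structure(list(seed = as.integer(seed), out_dir = out_dir,
                 simulation = simulation, input = input,
                 comparison = comparison, normalize = normalize,
                 n_resamples = as.integer(n_resamples),
                 n_candidates = as.integer(n_candidates),
                 n_housekeeping = as.integer(n_housekeeping),
                 housekeeping_pool = housekeeping_pool,
                 n_hubs = as.integer(n_hubs),
                 expansion_top_n = as.integer(expansion_top_n),
                 expansion_groups = expansion_groups,
                 expansion_resamples = as.integer(expansion_resamples),
                 ann = ann),
            class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#' @param path YAML file; keys mirror [pipeline_config()] arguments
#'   (`simulation` is passed to [simulation_spec()]).
#' @return a `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  raw <- yaml::read_yaml(path)
  if (!is.null(raw$simulation)) {
    sim <- raw$simulation
    if (!is.null(sim$n_per_group)) sim$n_per_group <- unlist(sim$n_per_group)
    raw$simulation <- do.call(simulation_spec, sim)
  }
  if (!is.null(raw$comparison$groups))
    raw$comparison$groups <- unlist(raw$comparison$groups)
  do.call(pipeline_config, raw)
}

#' Per-group gene matrices with platform absence applied
#'
#' Splits a gene-level matrix into one matrix per (cohort, group); genes
#' listed as absent from the platform of a group are withheld from that
#' group's matrix, emulating markers not represented on a chip.
#'
#' @param mat gene-level [expression_matrix()].
#' @param meta sample metadata.
#' @param absent_genes,absent_groups platform-absence description: the
#'   genes in `absent_genes` are removed from the matrices of the
#'   `cohort.group` keys (or bare group labels) in `absent_groups`.
#' @return named list of expression matrices, one per non-empty
#'   `cohort.group`.
#' @export
pipeline_group_matrices <- function(mat, meta, absent_genes = character(0),
                                    absent_groups = character(0)) {
  idx <- group_samples(meta, mat)
  idx <- idx[vapply(idx, length, integer(1)) > 0]
  out <- lapply(names(idx), function(k) {
    m <- mat[, idx[[k]], drop = FALSE]
    bare <- sub("^[^.]*\\.", "", k)
    if ((k %in% absent_groups || bare %in% absent_groups) &&
        length(absent_genes)) {
      m <- m[setdiff(rownames(m), absent_genes), , drop = FALSE]
    }
    expression_matrix(m)
  })
  names(out) <- names(idx)
  out
}

.log_stage <- function(con, stage, seed, ...) {
  extra <- c(...)
  kv <- if (length(extra))
    paste(names(extra), unname(extra), sep = "=", collapse = " ") else ""
  writeLines(sprintf("stage=%s seed=%d %s", stage, seed, kv), con)
}

#' Run the full two-tier pipeline
#'
#' Executes simulate/load, probe collapsing, optional normalization, tier-1
#' screening and |SRE| ranking, housekeeping selection, ANNI interaction
#' inference on the candidate panel, hub ranking, per-group hub expansion
#' with platform-absence handling, overlap analysis and Cytoscape export.
#' Every stage appends a structured line (stage, seed, input/output sizes)
#' to `pipeline.log`.  Outputs are byte-identical for a fixed config.
#'
#' @param config a [pipeline_config()] or path to its YAML form.
#' @param out_dir overrides `config$out_dir`.
#' @return invisibly, a list with the in-memory results of every stage
#'   (`data`, `collapsed`, `screen`, `housekeeping`, `panel`, `anni`,
#'   `hubs`, `expansions`, `accounting`, `overlap`, `files`).
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir = NULL) {
  if (is.character(config)) config <- read_pipeline_config(config)
  if (!is.null(out_dir)) config$out_dir <- out_dir
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  logp <- file.path(config$out_dir, "pipeline.log")
  con <- file(logp, "w")
  on.exit(close(con))
  seed <- config$seed
  acfg <- do.call(ann_config, c(list(seed = seed), config$ann))
  stage <- "load"
  res <- tryCatch({
    # ---- load / simulate -------------------------------------------------
    truth <- NULL
    if (!is.null(config$input)) {
      expr <- read_expression_table(config$input$expression)
      ann <- read_probe_annotation(config$input$annotation)
      meta <- read_sample_metadata(config$input$metadata)
    } else {
      sim <- config$simulation
      sim$seed <- seed
      data <- simulate_dataset(sim)
      expr <- data$expression; ann <- data$annotation; meta <- data$metadata
      truth <- data$truth
      write_truth(truth, file.path(config$out_dir, "truth"))
    }
    .log_stage(con, "load", seed, probes = nrow(expr), samples = ncol(expr))

    # ---- collapse --------------------------------------------------------
    stage <- "collapse"
    coll <- collapse_probes(expr, ann)
    gmat <- coll$matrix
    .write_tsv(coll$dropped, file.path(config$out_dir, "dropped_probes.tsv"))
    .log_stage(con, "collapse", seed, genes = nrow(gmat),
               dropped = nrow(coll$dropped))

    # ---- normalize -------------------------------------------------------
    if (isTRUE(config$normalize)) {
      stage <- "normalize"
      gmat <- median_baseline(percentile_normalize(gmat))
      .log_stage(con, "normalize", seed, genes = nrow(gmat))
    }

    # ---- comparison subset ----------------------------------------------
    stage <- "screen"
    cmp <- config$comparison
    keys <- paste(cmp$cohort, cmp$groups, sep = ".")
    gidx <- group_samples(meta, gmat)
    for (k in keys) if (is.null(gidx[[k]]) || !length(gidx[[k]]))
      .stopf("comparison group %s has no samples", k)
    sel <- c(gidx[[keys[1]]], gidx[[keys[2]]])
    labels <- rep(cmp$groups, c(length(gidx[[keys[1]]]), length(gidx[[keys[2]]])))
    smat <- expression_matrix(gmat[, sel, drop = FALSE])

    # ---- tier-1 screening ------------------------------------------------
    screen <- screen_all(smat, labels, n_resamples = config$n_resamples,
                         config = acfg, positive_class = cmp$groups[1])
    ttp <- vapply(rownames(smat), function(g)
      ttest_two_sample(smat[g, ], labels)$p, numeric(1))
    screen$ttest_p <- unname(ttp[screen$gene_id])
    screen$fdr_p <- bh_fdr(screen$ttest_p)
    write_screen_report(screen, file.path(config$out_dir, "screen_report.tsv"))
    .log_stage(con, "screen", seed, genes = nrow(screen),
               resamples = config$n_resamples)

    # ---- housekeeping ----------------------------------------------------
    stage <- "housekeeping"
    pool <- config$housekeeping_pool
    if (is.null(pool)) {
      pool <- if (!is.null(truth)) {
        truth$roles$gene[truth$roles$role == "housekeeping"]
      } else {
        # most invariant tail of the ranking as the default pool
        utils::tail(screen$gene_id, max(10L, 3L * config$n_housekeeping))
      }
    }
    hk <- select_housekeeping(screen[screen$gene_id %in% pool, ], ttp,
                              n = config$n_housekeeping)
    .write_tsv(hk, file.path(config$out_dir, "housekeeping.tsv"))
    .log_stage(con, "housekeeping", seed, pool = length(pool),
               selected = nrow(hk))

    # ---- candidate panel -------------------------------------------------
    stage <- "panel"
    cand <- utils::head(setdiff(screen$gene_id, hk$gene_id), config$n_candidates)
    panel <- candidate_panel(cand, hk$gene_id)
    .write_tsv(data.frame(gene_id = c(panel$candidates, panel$housekeeping),
                          role = rep(c("candidate", "housekeeping"),
                                     c(length(panel$candidates),
                                       length(panel$housekeeping)))),
               file.path(config$out_dir, "panel.tsv"))
    .log_stage(con, "panel", seed, candidates = length(panel$candidates),
               housekeeping = length(panel$housekeeping),
               size = panel$size)

    # ---- ANNI ------------------------------------------------------------
    stage <- "anni"
    pmat <- expression_matrix(smat[panel$candidates, , drop = FALSE])
    im <- anni_infer(pmat, acfg, n_resamples = config$n_resamples)
    write_interaction_matrix(im,
                             file.path(config$out_dir, "interaction_matrix.tsv"),
                             file.path(config$out_dir, "interaction_edges.tsv"))
    .log_stage(con, "anni", seed, genes = im$n_models,
               resamples = im$n_resamples)

    # ---- hubs ------------------------------------------------------------
    stage <- "hubs"
    hubs <- rank_hubs(im, k = config$n_hubs)
    .write_tsv(hubs, file.path(config$out_dir, "hubs.tsv"))
    .log_stage(con, "hubs", seed, k = nrow(hubs))

    # ---- expansion -------------------------------------------------------
    stage <- "expand"
    sim <- config$simulation
    gmats <- pipeline_group_matrices(
      gmat, meta,
      absent_genes = if (!is.null(sim)) sim$absent_genes else character(0),
      absent_groups = if (!is.null(sim)) sim$absent_groups else character(0))
    gkeys <- config$expansion_groups
    if (is.null(gkeys)) gkeys <- names(gmats)
    expansions <- list()
    for (k in gkeys) {
      for (h in hubs$gene_id) {
        expansions[[paste(k, h, sep = ":")]] <-
          expand_hub(h, gmats[[k]], top_n = config$expansion_top_n,
                     config = acfg, n_resamples = config$expansion_resamples,
                     group = k)
      }
    }
    acct <- expansion_accounting(expansions)
    .write_tsv(acct$per_group, file.path(config$out_dir, "expansion_accounting.tsv"))
    exp_rows <- do.call(rbind, lapply(expansions, function(r) {
      if (!nrow(r$selections)) return(NULL)
      data.frame(group = r$group, hub = r$hub, r$selections,
                 stringsAsFactors = FALSE)
    }))
    if (!is.null(exp_rows))
      .write_tsv(exp_rows, file.path(config$out_dir, "expansions.tsv"))
    .log_stage(con, "expand", seed, pairs = length(expansions),
               slots = acct$total)

    # ---- overlap ---------------------------------------------------------
    overlap <- NULL
    if (length(gkeys) >= 2) {
      stage <- "overlap"
      overlap <- overlap_sets(expansions)
      .write_tsv(overlap$occurrences, file.path(config$out_dir, "overlap_occurrences.tsv"))
      .log_stage(con, "overlap", seed, occurrences = nrow(overlap$occurrences))
    }

    # ---- export ----------------------------------------------------------
    stage <- "export"
    edges <- interaction_edges(im, top_n_per_source = config$expansion_top_n,
                               sources = hubs$gene_id)
    node_attr <- data.frame(node = im$gene_ids,
                            sre = screen$sre[match(im$gene_ids, screen$gene_id)],
                            hub = im$gene_ids %in% hubs$gene_id,
                            stringsAsFactors = FALSE)
    files <- export_network(edges, file.path(config$out_dir, "network"),
                            node_attr)
    .log_stage(con, "export", seed, edges = nrow(edges))

    list(data = list(expression = expr, annotation = ann, metadata = meta,
                     truth = truth),
         collapsed = coll, screen = screen, housekeeping = hk, panel = panel,
         anni = im, hubs = hubs, expansions = expansions, accounting = acct,
         overlap = overlap, files = files, out_dir = config$out_dir)
  }, error = function(e) {
    .stopf("pipeline stage '%s' failed: %s", stage, conditionMessage(e))
  })
  invisible(res)
}
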