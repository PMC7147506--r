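# Cytoscape export, fold-change and pathway-percentage summaries, tallies.

.SIF_RELATION <- c(stimulatory = "stimulates", inhibitory = "inhibits")

#' Export a network for Cytoscape
#'
#' Writes a SIF file (`source <relation> target`, tab-separated, relation
#' `stimulates` or `inhibits`), an edge-attribute TSV (source, target,
#' relation, weight) and a node-attribute TSV.
#'
#' @param edges data frame with columns source, target, weight, sign (as
#'   from [interaction_edges()]); self-edges are rejected.
#' @param prefix output path prefix; files `<prefix>.sif`,
#'   `<prefix>.edges.tsv`, `<prefix>.nodes.tsv` are written.
#' @param node_attributes optional data frame with a `node` column (plus any
#'   attribute columns); every edge endpoint must appear when supplied.
#' @return named character vector of the written paths, invisibly.
#' @export
export_network <- function(edges, prefix, node_attributes = NULL) {
  if (nrow(edges) && any(edges$source == edges$target))
    .stopf("self-edge on node %s", edges$source[edges$source == edges$target][1])
  if (nrow(edges) && !all(edges$sign %in% names(.SIF_RELATION)))
    .stopf("unknown edge sign; expected stimulatory/inhibitory")
  nodes <- unique(c(edges$source, edges$target))
  if (!is.null(node_attributes)) {
    if (!"node" %in% names(node_attributes))
      .stopf("node_attributes needs a `node` column")
    unknown <- setdiff(nodes, node_attributes$node)
    if (length(unknown)) .stopf("edge references unknown node %s", unknown[1])
  } else {
    node_attributes <- data.frame(node = nodes, stringsAsFactors = FALSE)
  }
  sif_path <- paste0(prefix, ".sif")
  edge_path <- paste0(prefix, ".edges.tsv")
  node_path <- paste0(prefix, ".nodes.tsv")
  if (!nrow(edges)) {
    .warnf("exporting an empty network to %s", sif_path)
    writeLines(character(0), sif_path)
  } else {
    writeLines(paste(edges$source, .SIF_RELATION[edges$sign], edges$target,
                     sep = "\t"), sif_path)
  }
  .write_tsv(data.frame(source = edges$source, target = edges$target,
                        relation = unname(.SIF_RELATION[edges$sign]),
                        weight = edges$weight, stringsAsFactors = FALSE),
             edge_path)
  .write_tsv(node_attributes, node_path)
  invisible(c(sif = sif_path, edges = edge_path, nodes = node_path))
}

#' Parse a SIF file back into an edge list
#' @param path SIF file path.
#' @return data frame source, target, sign.
#' @export
read_sif <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (!length(lines))
    return(data.frame(source = character(0), target = character(0),
                      sign = character(0), stringsAsFactors = FALSE))
  fields <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(vapply(fields, length, integer(1)) != 3)
  if (length(bad)) .stopf("malformed SIF line %d", bad[1])
  rel <- vapply(fields, `[`, character(1), 2)
  unknown <- setdiff(unique(rel), .SIF_RELATION)
  if (length(unknown)) .stopf("unknown SIF relation '%s'", unknown[1])
  back <- setNames(names(.SIF_RELATION), .SIF_RELATION)
  data.frame(source = vapply(fields, `[`, character(1), 1),
             target = vapply(fields, `[`, character(1), 3),
             sign = unname(back[rel]), stringsAsFactors = FALSE)
}

#' Log2 fold changes of every group versus a baseline group
#'
#' Per cohort, the fold change of a gene in a group is the difference of
#' group-mean log2 expression from the baseline group's mean (so the
#' baseline column is identically zero).
#'
#' @param mat genes x samples [expression_matrix()] of log2 values.
#' @param meta sample metadata covering the matrix samples.
#' @param baseline baseline group label (default "healthy_control"); must be
#'   present in every cohort analysed.
#' @return list with `fold_change` (genes x `cohort.group` matrix) and
#'   `direction` (same shape, "up"/"down"/"baseline" labels).
#' @export
fold_change_table <- function(mat, meta, baseline = "healthy_control") {
  mat <- expression_matrix(mat)
  groups <- group_samples(meta, mat)
  cohorts <- unique(sub("\\..*$", "", names(groups)))
  cols <- names(groups)[vapply(groups, length, integer(1)) > 0]
  fc <- matrix(NA_real_, nrow(mat), length(cols),
               dimnames = list(rownames(mat), cols))
  for (co in cohorts) {
    bkey <- paste(co, baseline, sep = ".")
    if (is.null(groups[[bkey]]) || !length(groups[[bkey]]))
      .stopf("baseline group '%s' has no samples in cohort %s", baseline, co)
    bmean <- rowMeans(mat[, groups[[bkey]], drop = FALSE])
    for (k in cols[startsWith(cols, paste0(co, "."))]) {
      fc[, k] <- rowMeans(mat[, groups[[k]], drop = FALSE]) - bmean
    }
  }
  dir <- ifelse(fc > 0, "up", ifelse(fc < 0, "down", "baseline"))
  for (co in cohorts) dir[, paste(co, baseline, sep = ".")] <- "baseline"
  list(fold_change = fc, direction = dir)
}

#' Per-group pathway hit percentages
#'
#' @param counts named nonnegative integer vector of pathway hits per group.
#' @param total total hits across all groups (default `sum(counts)`).
#' @return data frame group, hits, percent (exact `100 * hits / total`),
#'   percent_display (rounded to one decimal, as printed in reports).
#' @export
pathway_percentages <- function(counts, total = sum(counts)) {
  if (total <= 0) .stopf("total hit count must be positive")
  if (any(counts < 0)) .stopf("hit counts must be nonnegative")
  if (any(counts > total)) .stopf("a group's hits exceed the total")
  groups <- if (!is.null(names(counts))) names(counts)
            else sprintf("group%d", seq_along(counts))
  pct <- 100 * counts / total
  data.frame(group = groups, hits = as.integer(counts), percent = unname(pct),
             percent_display = round(unname(pct), 1), stringsAsFactors = FALSE)
}

#' Combine per-direction tallies into a total
#'
#' Validated integer addition for combining counts reported separately per
#' regulation direction (e.g. up- and down-regulated tail counts).
#'
#' @param counts nonnegative integer vector.
#' @return their sum, as an integer-valued numeric.
#' @export
tally_total <- function(counts) {
  if (!length(counts)) return(0)
  if (any(!is.finite(counts)) || any(counts < 0) || any(counts != floor(counts)))
    .stopf("tallies must be nonnegative integers")
  sum(counts)
}
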