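# Expression-table IO, probe collapsing and the GeneSpring-style
# normalizations.

#' @title Closed vocabulary of disease-group labels
#' @description Cohorts and disease groups supported by the sample-metadata
#'   reader: two patient cohorts and eight groups (sepsis, SIRS,
#'   post-surgical sepsis, septic shock, resolved SIRS, healthy control, and
#'   gram-positive / gram-negative bacteraemia).
#' @rdname group-vocabulary
#' @export
COHORTS <- c("adult", "pediatric")

#' @rdname group-vocabulary
#' @export
DISEASE_GROUPS <- c("sepsis", "SIRS", "post_surgical_sepsis", "septic_shock",
                    "resolved_SIRS", "healthy_control", "gram_positive",
                    "gram_negative")

#' Construct an expression matrix
#'
#' An `expression_matrix` is a plain numeric matrix (rows = probes or genes,
#' columns = samples, values = log2-scale intensities) with unique, non-empty
#' dimnames and no missing values.
#'
#' @param values numeric matrix of log2 intensities.
#' @param row_ids,sample_ids character identifiers; taken from `dimnames`
#'   when omitted.
#' @return a validated `expression_matrix` (a base matrix with dimnames).
#' @export
expression_matrix <- function(values, row_ids = rownames(values),
                              sample_ids = colnames(values)) {
  if (!is.matrix(values) || !is.numeric(values))
    .stopf("`values` must be a numeric matrix")
  if (is.null(row_ids) || is.null(sample_ids))
    .stopf("row and sample identifiers are required")
  row_ids <- as.character(row_ids)
  sample_ids <- as.character(sample_ids)
  if (length(row_ids) != nrow(values) || length(sample_ids) != ncol(values))
    .stopf("identifier lengths do not match matrix dimensions")
  dup <- row_ids[duplicated(row_ids)]
  if (length(dup)) .stopf("duplicated row identifier: %s", dup[1])
  dup <- sample_ids[duplicated(sample_ids)]
  if (length(dup)) .stopf("duplicated sample identifier: %s", dup[1])
  if (anyNA(values)) {
    idx <- which(is.na(values), arr.ind = TRUE)[1, ]
    .stopf("missing value at row '%s', sample '%s' (no imputation is applied)",
           row_ids[idx[1]], sample_ids[idx[2]])
  }
  dimnames(values) <- list(row_ids, sample_ids)
  values
}

#' Read an expression table from TSV
#'
#' Expects a tab-separated file with a header row of sample identifiers and a
#' first column of probe/gene identifiers; the body must be fully numeric
#' (dot decimal separator, locale independent).  Duplicated identifiers,
#' missing values and non-numeric cells are hard errors.
#'
#' @param path file path.
#' @return an [expression_matrix()].
#' @seealso [write_expression_table()]
#' @export
read_expression_table <- function(path) {
  if (!file.exists(path)) .stopf("file not found: %s", path)
  lines <- readLines(path)
  if (length(lines) < 2) .stopf("expression table needs a header and at least one row")
  header <- strsplit(lines[1], "\t", fixed = TRUE)[[1]]
  sample_ids <- header[-1]
  dup <- sample_ids[duplicated(sample_ids)]
  if (length(dup)) .stopf("duplicated sample identifier in header: %s", dup[1])
  body <- strsplit(lines[-1], "\t", fixed = TRUE)
  ncol_expect <- length(header)
  row_ids <- character(length(body))
  values <- matrix(NA_real_, length(body), length(sample_ids))
  for (r in seq_along(body)) {
    f <- body[[r]]
    if (length(f) != ncol_expect)
      .stopf("row %d has %d fields; expected %d", r + 1, length(f), ncol_expect)
    row_ids[r] <- f[1]
    v <- suppressWarnings(as.numeric(f[-1]))
    bad <- which(is.na(v) & f[-1] != "NA")
    if (length(bad))
      .stopf("non-numeric value '%s' at row '%s', column '%s'",
             f[-1][bad[1]], f[1], sample_ids[bad[1]])
    if (anyNA(v)) {
      miss <- which(is.na(v))[1]
      .stopf("missing value at row '%s', column '%s'", f[1], sample_ids[miss])
    }
    values[r, ] <- v
  }
  expression_matrix(values, row_ids, sample_ids)
}

#' Write an expression table to TSV
#'
#' Emits the same dialect [read_expression_table()] consumes, with full
#' numeric precision (round-trips exactly through the reader).
#'
#' @param mat an [expression_matrix()].
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_expression_table <- function(mat, path) {
  mat <- expression_matrix(mat)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(c("id", colnames(mat)), collapse = "\t"), con)
  for (r in seq_len(nrow(mat))) {
    writeLines(paste(c(rownames(mat)[r], sprintf("%.17g", mat[r, ])),
                     collapse = "\t"), con)
  }
  invisible(path)
}

#' Read a probe annotation table
#'
#' Two-column TSV: probe identifier, then a comma-separated list of gene
#' symbols (empty = unannotated probe).  Probes must be unique.
#'
#' @param path file path.
#' @return a named list mapping probe id to a character vector of gene
#'   symbols (possibly empty).
#' @export
read_probe_annotation <- function(path) {
  if (!file.exists(path)) .stopf("file not found: %s", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  probes <- vapply(fields, `[`, character(1), 1)
  dup <- probes[duplicated(probes)]
  if (length(dup)) .stopf("duplicated probe in annotation: %s", dup[1])
  ann <- lapply(fields, function(f) {
    if (length(f) < 2 || !nzchar(f[2])) return(character(0))
    syms <- strsplit(f[2], ",", fixed = TRUE)[[1]]
    syms <- trimws(syms)
    if (any(!nzchar(syms))) .stopf("empty gene symbol for probe %s", f[1])
    syms
  })
  names(ann) <- probes
  ann
}

#' Write a probe annotation table
#' @param ann named list probe -> character vector of symbols.
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_probe_annotation <- function(ann, path) {
  lines <- vapply(seq_along(ann), function(i) {
    paste(names(ann)[i], paste(ann[[i]], collapse = ","), sep = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read sample metadata
#'
#' Three-column TSV with header `sample_id`, `cohort`, `group`.  Cohort must
#' be in [COHORTS], group in [DISEASE_GROUPS]; unknown vocabulary is
#' rejected.
#'
#' @param path file path.
#' @return data frame with columns sample_id, cohort, group.
#' @export
read_sample_metadata <- function(path) {
  if (!file.exists(path)) .stopf("file not found: %s", path)
  df <- read.delim(path, stringsAsFactors = FALSE, colClasses = "character")
  sample_metadata(df)
}

#' Validate sample metadata
#'
#' @param df data frame with columns sample_id, cohort, group.
#' @return the validated data frame.
#' @export
sample_metadata <- function(df) {
  need <- c("sample_id", "cohort", "group")
  if (!all(need %in% names(df)))
    .stopf("metadata must have columns %s", paste(need, collapse = ", "))
  df <- df[, need]
  dup <- df$sample_id[duplicated(df$sample_id)]
  if (length(dup)) .stopf("duplicated sample_id in metadata: %s", dup[1])
  bad <- setdiff(unique(df$cohort), COHORTS)
  if (length(bad)) .stopf("unknown cohort label: %s", bad[1])
  bad <- setdiff(unique(df$group), DISEASE_GROUPS)
  if (length(bad)) .stopf("unknown disease-group label: %s", bad[1])
  df
}

#' Write sample metadata
#' @param meta metadata data frame.
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_sample_metadata <- function(meta, path) {
  meta <- sample_metadata(meta)
  write.table(meta, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Collapse probe-level rows to gene symbols
#'
#' Probes associated with no gene symbol ("unidentifiable") or with more than
#' one symbol ("multi-gene") are dropped; the expression values of probes
#' mapping to a single symbol are averaged (arithmetic mean per sample) to
#' give the gene's final expression value.  Probes present in the matrix but
#' absent from the annotation are classed unidentifiable.
#'
#' @param mat probe-level [expression_matrix()].
#' @param ann probe annotation as from [read_probe_annotation()].
#' @return list with `matrix` (gene-level expression_matrix, rows sorted by
#'   gene symbol) and `dropped` (data frame probe/reason).
#' @export
collapse_probes <- function(mat, ann) {
  mat <- expression_matrix(mat)
  probes <- rownames(mat)
  n_genes <- vapply(probes, function(p) {
    if (is.null(ann[[p]])) 0L else length(ann[[p]])
  }, integer(1))
  reason <- rep(NA_character_, length(probes))
  reason[n_genes == 0] <- "unidentifiable"
  reason[n_genes >= 2] <- "multi-gene"
  dropped <- data.frame(probe = probes[!is.na(reason)],
                        reason = reason[!is.na(reason)],
                        stringsAsFactors = FALSE)
  keep <- which(n_genes == 1)
  if (!length(keep))
    .stopf("all %d probes were dropped during collapsing", length(probes))
  sym <- vapply(probes[keep], function(p) ann[[p]], character(1))
  genes <- sort(unique(sym))
  out <- matrix(0, length(genes), ncol(mat),
                dimnames = list(genes, colnames(mat)))
  for (g in genes) {
    rows <- keep[sym == g]
    out[g, ] <- colMeans(mat[rows, , drop = FALSE])
  }
  list(matrix = expression_matrix(out), dropped = dropped)
}

#' Percentile normalization of samples
#'
#' Shifts each sample (column) so that its chosen percentile becomes zero —
#' the log-scale analogue of scaling each array to its 75th percentile.
#' Percentiles use linear interpolation between closest ranks (type 7).
#'
#' @param mat an [expression_matrix()].
#' @param percentile percentile in (0, 100); default 75.
#' @return the shifted expression_matrix.
#' @export
percentile_normalize <- function(mat, percentile = 75) {
  mat <- expression_matrix(mat)
  if (!is.numeric(percentile) || length(percentile) != 1 ||
      percentile <= 0 || percentile >= 100)
    .stopf("`percentile` must lie strictly between 0 and 100")
  shift <- apply(mat, 2, quantile, probs = percentile / 100, names = FALSE)
  expression_matrix(sweep(mat, 2, shift, "-"))
}

#' Median baseline transformation of genes
#'
#' Subtracts each row's median across samples, so every gene is centred at
#' its own median (zero per-row median afterwards).
#'
#' @param mat an [expression_matrix()].
#' @return the centred expression_matrix.
#' @export
median_baseline <- function(mat) {
  mat <- expression_matrix(mat)
  med <- apply(mat, 1, median)
  expression_matrix(sweep(mat, 1, med, "-"))
}

#' Partition samples into (cohort, group) index lists
#'
#' Every (cohort, group) combination present in the metadata is reported,
#' including combinations with no matrix samples (empty index vector), so
#' empty groups are visible rather than silently dropped.
#'
#' @param meta sample metadata covering every matrix sample.
#' @param mat an [expression_matrix()].
#' @return named list, names `cohort.group`, values integer column indices
#'   into `mat`.  The lists partition the matrix samples.
#' @export
group_samples <- function(meta, mat) {
  meta <- sample_metadata(meta)
  mat <- expression_matrix(mat)
  missing <- setdiff(colnames(mat), meta$sample_id)
  if (length(missing)) .stopf("sample without metadata: %s", missing[1])
  m <- meta[match(colnames(mat), meta$sample_id), ]
  combos <- unique(paste(meta$cohort, meta$group, sep = "."))
  key <- paste(m$cohort, m$group, sep = ".")
  out <- lapply(combos, function(k) which(key == k))
  names(out) <- combos
  out
}
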