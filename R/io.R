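#' Read a gene expression matrix
#'
#' Reads a delimited text table (TSV or CSV, autodetected from the header
#' line unless `sep` is given) into a validated genes x samples numeric
#' matrix. The first column holds gene ids and the header row sample ids;
#' `orientation = "samples_rows"` transposes after reading. Duplicate gene
#' ids are collapsed by keeping the row with the largest variance across
#' samples. Any expression scale is accepted — downstream scoring is
#' rank-based — and the declared unit is recorded as an attribute without
#' validation.
#'
#' @param path Path to the delimited table.
#' @param orientation `"genes_rows"` (default) or `"samples_rows"`.
#' @param sep Field separator; `NULL` autodetects (tab if the header
#'   contains a tab, else comma).
#' @param unit Optional free-text expression unit (e.g. `"TPM"`,
#'   `"log2(FPKM+1)"`), stored as attribute `"unit"`.
#' @return Numeric matrix, genes in rows, samples in columns.
#' @export
read_expression <- function(path, orientation = c("genes_rows", "samples_rows"),
                            sep = NULL, unit = NULL) {
  orientation <- match.arg(orientation)
  lines <- readLines(path, n = 1L)
  if (length(lines) == 0L) abort("empty expression file")
  if (is.null(sep)) sep <- if (grepl("\t", lines[1])) "\t" else ","
  # header parsed by hand: data-frame subsetting would mangle duplicated
  # sample ids before they can be rejected
  header <- strsplit(lines[1], sep, fixed = TRUE)[[1]]
  raw <- utils::read.table(path, sep = sep, header = FALSE, skip = 1L,
                           stringsAsFactors = FALSE, quote = "\"",
                           comment.char = "", colClasses = "character")
  ids <- as.character(raw[[1]])
  mat <- as.matrix(raw[, -1, drop = FALSE])
  suppressWarnings(storage.mode(mat) <- "double")
  colnames(mat) <- header[-1]
  # coercion NAs mean a non-numeric cell; literal NA/empty cells are also fatal
  nas <- which(is.na(mat), arr.ind = TRUE)
  if (nrow(nas) > 0L) {
    cell <- nas[1L, ]
    abort(sprintf(
      "non-numeric or missing expression value at gene '%s', sample '%s' (row %d, column %d)",
      ids[cell[1L]], colnames(mat)[cell[2L]], cell[1L], cell[2L] + 1L))
  }
  rownames(mat) <- ids
  if (orientation == "samples_rows") {
    mat <- t(mat)
  }
  if (anyDuplicated(colnames(mat))) {
    abort(sprintf("duplicate sample ids: %s",
                  paste(unique(colnames(mat)[duplicated(colnames(mat))]), collapse = ", ")))
  }
  mat <- collapse_duplicate_genes(mat)
  validate_expression(mat)
  attr(mat, "unit") <- unit %||% "unspecified"
  mat
}

# keep the max-variance row within each duplicated gene id group;
# first occurrence wins a variance tie
collapse_duplicate_genes <- function(mat) {
  if (!anyDuplicated(rownames(mat))) return(mat)
  v <- apply(mat, 1L, var)
  ord <- order(factor(rownames(mat), levels = unique(rownames(mat))), -v)
  mat <- mat[ord, , drop = FALSE]
  mat[!duplicated(rownames(mat)), , drop = FALSE]
}

validate_expression <- function(mat) {
  if (is.null(rownames(mat)) || is.null(colnames(mat)))
    abort("expression matrix must have gene and sample ids")
  if (nrow(mat) < 2L || ncol(mat) < 2L)
    abort("expression matrix needs at least 2 genes and 2 samples")
  if (anyDuplicated(rownames(mat))) abort("duplicate gene ids after collapsing")
  if (anyDuplicated(colnames(mat))) abort("duplicate sample ids")
  if (anyNA(mat)) abort("missing values in expression matrix")
  invisible(mat)
}

#' Write an expression matrix to TSV
#'
#' Full-precision round-trip companion to [read_expression()].
#'
#' @param mat Genes x samples numeric matrix.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_expression <- function(mat, path) {
  df <- data.frame(gene_id = rownames(mat),
                   format(mat, digits = 17, trim = TRUE, scientific = FALSE),
                   check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read gene sets from a GMT file
#'
#' Standard GMT: one set per line, tab-separated `name`, `description`,
#' then gene ids. Descriptions are discarded; duplicate genes within a set
#' are deduplicated (first occurrence kept); empty lines are skipped with a
#' message.
#'
#' @param path Path to a GMT file.
#' @return Named list of character vectors (gene ids), in file order.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  empty <- !nzchar(trimws(lines))
  if (any(empty)) {
    inform(sprintf("skipping %d empty line(s) in %s", sum(empty), path))
    lines <- lines[!empty]
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  short <- lengths(fields) < 3L
  if (any(short))
    abort(sprintf("GMT line %d has fewer than 3 fields", which(short)[1L]))
  nms <- vapply(fields, `[[`, "", 1L)
  if (anyDuplicated(nms))
    abort(sprintf("duplicate gene set name: %s",
                  paste(unique(nms[duplicated(nms)]), collapse = ", ")))
  sets <- lapply(fields, function(f) unique(f[-(1:2)]))
  setNames(sets, nms)
}

#' Write gene sets to a GMT file
#'
#' @param sets Named list of character vectors.
#' @param path Output path.
#' @param description Description field written for every set.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(sets, path, description = "na") {
  lines <- vapply(seq_along(sets), function(i) {
    paste(c(names(sets)[i], description, sets[[i]]), collapse = "\t")
  }, "")
  writeLines(lines, path)
  invisible(path)
}

#' Read a clinical/survival table
#'
#' Reads a CSV and splits it into a survival tibble (`sample_id`, `time`,
#' `event`) and a clinical covariate tibble according to a column schema.
#' Rows lacking follow-up time or event status are dropped with a message,
#' mirroring the usual cohort exclusion of cases without survival data.
#' Categorical covariates become factors; when a covariate has a declared
#' reference level (e.g. ulceration `"no"`, nodal stage `"N0"`) it is set
#' first.
#'
#' @param path Path to a CSV file.
#' @param schema Named list mapping roles to column names: `id`, `time`,
#'   `event`, and optionally `covariates` (character vector of column
#'   names). Defaults assume columns named `sample_id`, `time`, `event`,
#'   with every other column a covariate.
#' @param units Time unit of the `time` column: `"days"`, `"months"` or
#'   `"years"`; recorded as attribute `"units"` on the survival tibble.
#' @return List with elements `survival` (tibble: sample_id, time, event)
#'   and `clinical` (tibble: sample_id plus covariates).
#' @export
read_clinical <- function(path, schema = list(), units = c("days", "months", "years")) {
  units <- match.arg(units)
  raw <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  id_col <- schema$id %||% "sample_id"
  time_col <- schema$time %||% "time"
  event_col <- schema$event %||% "event"
  for (col in c(id_col, time_col, event_col)) {
    if (!col %in% names(raw)) abort(sprintf("column '%s' not found in %s", col, path))
  }
  cov_cols <- schema$covariates %||% setdiff(names(raw), c(id_col, time_col, event_col))

  time <- suppressWarnings(as.numeric(raw[[time_col]]))
  event <- suppressWarnings(as.numeric(raw[[event_col]]))
  keep <- !is.na(time) & !is.na(event)
  if (any(!keep)) {
    inform(sprintf("dropping %d sample(s) lacking survival time or event status",
                   sum(!keep)))
  }
  raw <- raw[keep, , drop = FALSE]
  time <- time[keep]; event <- event[keep]
  if (any(time <= 0)) abort("survival time must be positive")
  if (!all(event %in% c(0, 1))) abort("event indicator must be 0 (censored) or 1 (event)")

  surv <- tibble(sample_id = as.character(raw[[id_col]]), time = time, event = event)
  attr(surv, "units") <- units

  clin <- tibble(sample_id = as.character(raw[[id_col]]))
  ref_levels <- c(ulceration = "no", n_stage = "N0", gender = "male")
  for (col in cov_cols) {
    x <- raw[[col]]
    if (is.character(x)) {
      x <- factor(x)
      if (col %in% names(ref_levels) && ref_levels[[col]] %in% levels(x))
        x <- stats::relevel(x, ref = ref_levels[[col]])
    }
    clin[[col]] <- x
  }
  list(survival = surv, clinical = clin)
}

#' Impute missing clinical covariates
#'
#' Deterministic single imputation: numeric covariates get their median,
#' categorical covariates their mode (ties broken by factor level order).
#' `method = "drop"` instead removes incomplete rows.
#'
#' @param clinical Tibble with `sample_id` and covariates.
#' @param method `"median_mode"` (default) or `"drop"`.
#' @return Imputed tibble.
#' @export
impute_clinical <- function(clinical, method = c("median_mode", "drop")) {
  method <- match.arg(method)
  if (method == "drop") {
    out <- clinical[stats::complete.cases(clinical), , drop = FALSE]
    if (nrow(out) < nrow(clinical))
      inform(sprintf("dropped %d incomplete row(s)", nrow(clinical) - nrow(out)))
    return(out)
  }
  for (col in setdiff(names(clinical), "sample_id")) {
    x <- clinical[[col]]
    if (!anyNA(x)) next
    if (is.numeric(x)) {
      x[is.na(x)] <- median(x, na.rm = TRUE)
    } else {
      f <- factor(x)
      mode_lvl <- levels(f)[which.max(tabulate(f))]
      x[is.na(x)] <- mode_lvl
    }
    clinical[[col]] <- x
  }
  clinical
}

#' Align expression, survival and clinical data on shared samples
#'
#' Restricts every input to the intersection of sample ids, in the
#' expression matrix's column order. Everything downstream of loading
#' receives this aligned triplet.
#'
#' @param expr Genes x samples matrix.
#' @param survival Survival tibble (`sample_id`, `time`, `event`).
#' @param clinical Optional clinical tibble.
#' @return List `expression`, `survival`, `clinical` (NULL if not given).
#' @export
align_samples <- function(expr, survival, clinical = NULL) {
  ids <- intersect(colnames(expr), survival$sample_id)
  if (!is.null(clinical)) ids <- intersect(ids, clinical$sample_id)
  if (length(ids) < 2L) abort("fewer than 2 samples shared across inputs")
  ids <- colnames(expr)[colnames(expr) %in% ids]
  units <- attr(survival, "units")
  survival <- survival[match(ids, survival$sample_id), , drop = FALSE]
  attr(survival, "units") <- units
  list(
    expression = expr[, ids, drop = FALSE],
    survival = survival,
    clinical = if (is.null(clinical)) NULL else
      clinical[match(ids, clinical$sample_id), , drop = FALSE]
  )
}

# horizons expressed in years -> the survival table's time unit
horizon_to_units <- function(horizon_years, units) {
  switch(units,
         days = horizon_years * 365.25,
         months = horizon_years * 12,
         years = horizon_years,
         abort(sprintf("unknown time unit '%s'", units)))
}
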