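pair_name <- function(a, b) paste(a, b, sep = "|")

split_pair <- function(pair) {
  parts <- strsplit(pair, "|", fixed = TRUE)
  bad <- lengths(parts) != 2L
  if (any(bad)) abort(sprintf("malformed pair name: %s", pair[bad][1L]))
  list(a = vapply(parts, `[[`, "", 1L), b = vapply(parts, `[[`, "", 2L))
}

#' Enumerate candidate cell pairs
#'
#' Pairs every prognosis-associated cell type (the "A cells") with every
#' cell type in the vocabulary (the "B cells") in turn, giving
#' `length(prognostic_cells) * length(all_cells)` ordered pairs. Self-pairs
#' are included — their indicator is constantly 0 and the prevalence filter
#' removes them — so the enumeration count stays interpretable (e.g. 19
#' prognostic cells over a 28-cell vocabulary give 532 pairs).
#'
#' @param prognostic_cells Character vector of A cells (must be a subset of
#'   `all_cells`).
#' @param all_cells Character vector of the full cell-type vocabulary.
#' @return Tibble with columns `pair`, `a_cell`, `b_cell`.
#' @export
enumerate_pairs <- function(prognostic_cells, all_cells) {
  if (length(prognostic_cells) == 0L)
    abort("no prognosis-associated cells survived screening")
  if (!all(prognostic_cells %in% all_cells))
    abort("prognostic cells must be a subset of the cell vocabulary")
  grid <- tidyr::expand_grid(a_cell = prognostic_cells, b_cell = all_cells)
  mutate(grid, pair = pair_name(.data$a_cell, .data$b_cell),
         .before = "a_cell")
}

#' Build the binary cell-pair indicator matrix
#'
#' For each pair A|B and sample j, the indicator is 1 when cell A's
#' enrichment score strictly exceeds cell B's in that sample, 0 otherwise
#' (ties score 0). Only within-sample comparisons enter, so the matrix is
#' invariant to any sample-wise positive rescaling of the abundances.
#'
#' @param abund Cell types x samples abundance matrix (e.g. from
#'   [ssgsea_scores()]).
#' @param pairs Tibble from [enumerate_pairs()], or a character vector of
#'   `"A|B"` pair names.
#' @return Binary matrix, pairs x samples, rownames `"A|B"`.
#' @export
build_pair_matrix <- function(abund, pairs) {
  if (is.character(pairs)) {
    sp <- split_pair(pairs)
    pairs <- tibble(pair = pairs, a_cell = sp$a, b_cell = sp$b)
  }
  missing <- setdiff(unique(c(pairs$a_cell, pairs$b_cell)), rownames(abund))
  if (length(missing) > 0L)
    abort(sprintf("cell type(s) absent from the abundance matrix: %s",
                  paste(missing, collapse = ", ")))
  out <- (abund[pairs$a_cell, , drop = FALSE] >
            abund[pairs$b_cell, , drop = FALSE]) * 1
  rownames(out) <- pairs$pair
  out
}

#' Remove near-constant cell pairs
#'
#' Drops pairs whose indicator is 0 (or 1) in more than `threshold` of the
#' samples; pairs at exactly the threshold are kept. Such pairs reflect
#' systematic abundance differences between cell populations (some immune
#' cells are always more plentiful than others) and carry no
#' between-patient information.
#'
#' @param m Binary pairs x samples matrix.
#' @param threshold Maximum allowed majority-class fraction, in (0, 1);
#'   default 0.80.
#' @return The filtered matrix (possibly with fewer rows).
#' @export
prevalence_filter <- function(m, threshold = 0.8) {
  if (!is.numeric(threshold) || length(threshold) != 1L ||
      threshold <= 0 || threshold >= 1)
    abort("threshold must be a single number in (0, 1)")
  f1 <- rowMeans(m)
  keep <- pmax(f1, 1 - f1) <= threshold
  if (!any(keep))
    abort("prevalence filter removed every pair; review the threshold")
  m[keep, , drop = FALSE]
}
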