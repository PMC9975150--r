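#' Fit an immune-cell-pair risk model end to end
#'
#' Runs the full cascade on a training cohort: per-sample enrichment
#' scoring of the signatures, univariate Cox screening of cell types,
#' pair enumeration (prognostic cells against the full vocabulary),
#' within-sample binarization, prevalence filtering, univariate Cox
#' screening of pairs, cross-validated LASSO Cox selection, and the final
#' multivariate Cox fit with the training-median threshold. Feature
#' counts are recorded at every stage.
#'
#' @param expr Genes x samples expression matrix.
#' @param gene_sets Named list of signature gene sets (cell types).
#' @param surv Survival tibble (`sample_id`, `time`, `event`); samples
#'   are aligned with `expr` via [align_samples()].
#' @param alpha,normalize Enrichment parameters, see [ssgsea_scores()].
#' @param p_cut_cells,p_cut_pairs Wald p thresholds for the two screens
#'   (defaults 0.05).
#' @param filter_threshold Prevalence filter threshold (default 0.80).
#' @param cv_folds,rule LASSO Cox cross-validation settings.
#' @param backward_aic Prune the final model by AIC (default TRUE).
#' @param seed Single seed driving every stochastic step.
#' @return Object of class `irrs_fit`: `model` (an `irrs_model`),
#'   `scores` (tibble with `sample_id`, `irrs`, `group`), `stage_report`
#'   (tibble of per-stage feature counts), `cell_screen`, `pair_screen`,
#'   `abundance`, `pair_matrix`.
#' @export
#' @examples
#' \donttest{
#' cohort <- simulate_cohort(n_samples = 120, n_cell_types = 8,
#'                           n_true_pairs = 2, seed = 7)
#' fit <- irrs_fit(cohort$expression, cohort$gene_sets, cohort$survival,
#'                 seed = 7)
#' fit$stage_report
#' tidy(fit$model)
#' }
irrs_fit <- function(expr, gene_sets, surv, alpha = 0.25,
                     normalize = c("none", "minmax"),
                     p_cut_cells = 0.05, p_cut_pairs = 0.05,
                     filter_threshold = 0.8, cv_folds = 10,
                     rule = c("min", "1se"), backward_aic = TRUE, seed = 1) {
  normalize <- match.arg(normalize)
  rule <- match.arg(rule)
  al <- align_samples(expr, surv)
  expr <- al$expression; surv <- al$survival
  stage <- function(name, count) tibble(stage = name, count = count)

  abund <- ssgsea_scores(expr, gene_sets, alpha = alpha, normalize = normalize)
  report <- list(stage("cell_types_scored", nrow(abund)))

  cell_screen <- screen_prognostic_cells(abund, surv, p_cut = p_cut_cells)
  prognostic <- cell_screen$cell_type[cell_screen$selected]
  report <- c(report, list(stage("prognostic_cells", length(prognostic))))
  inform(sprintf("stage prognostic_cells: %d of %d cell types (p < %g)",
                 length(prognostic), nrow(abund), p_cut_cells))

  pairs <- enumerate_pairs(prognostic, rownames(abund))
  report <- c(report, list(stage("pairs_enumerated", nrow(pairs))))
  inform(sprintf("stage pairs_enumerated: %d", nrow(pairs)))

  pm <- build_pair_matrix(abund, pairs)
  pm_f <- prevalence_filter(pm, threshold = filter_threshold)
  report <- c(report, list(stage("pairs_after_prevalence_filter", nrow(pm_f))))
  inform(sprintf("stage pairs_after_prevalence_filter: %d", nrow(pm_f)))

  pm_s <- screen_prognostic_pairs(pm_f, surv, p_cut = p_cut_pairs)
  pair_screen <- attr(pm_s, "screen")
  report <- c(report, list(stage("pairs_after_cox_screen", nrow(pm_s))))
  inform(sprintf("stage pairs_after_cox_screen: %d", nrow(pm_s)))

  selected <- lasso_cox_select(pm_s, surv, cv_folds = cv_folds, seed = seed,
                               rule = rule)
  report <- c(report, list(stage("pairs_after_lasso", length(selected))))
  inform(sprintf("stage pairs_after_lasso: %d", length(selected)))

  ssgsea_params <- list(alpha = alpha, normalize = normalize)
  model <- finalize_model(pm_s, as.character(selected), surv,
                          backward_aic = backward_aic,
                          ssgsea_params = ssgsea_params,
                          filter_threshold = filter_threshold,
                          p_cut = p_cut_cells, seed = as.integer(seed))
  report <- c(report, list(stage("pairs_in_final_model", nrow(model$pairs))))
  inform(sprintf("stage pairs_in_final_model: %d", nrow(model$pairs)))

  scores <- compute_irrs(model, pm) |>
    stratify_by_median(threshold = model$training_median)

  structure(list(model = model, scores = scores,
                 stage_report = bind_rows(report),
                 cell_screen = cell_screen, pair_screen = pair_screen,
                 abundance = abund, pair_matrix = pm),
            class = "irrs_fit")
}

#' @export
print.irrs_fit <- function(x, ...) {
  cat("IRRS pipeline fit\n")
  print(x$stage_report, n = nrow(x$stage_report))
  print(x$model)
  invisible(x)
}

#' @method tidy irrs_fit
#' @export
tidy.irrs_fit <- function(x, ...) tidy(x$model)

#' @method glance irrs_fit
#' @export
glance.irrs_fit <- function(x, ...) {
  g <- glance(x$model)
  mutate(g, n_samples = nrow(x$scores), .before = 1L)
}

#' Score a cohort with a fitted IRRS model
#'
#' Rebuilds the abundance matrix of a (possibly new) cohort with the
#' model's stored enrichment parameters, reconstructs the model's pair
#' indicators from that cohort's own within-sample comparisons, computes
#' the risk score and stratifies it. Signature genes missing from the
#' cohort beyond `max_missing_fraction` of any model cell type's set are
#' an error.
#'
#' @param model An `irrs_model`.
#' @param expr Genes x samples expression matrix of the cohort.
#' @param gene_sets Named list of signature gene sets covering every cell
#'   type used by the model's pairs.
#' @param median_policy `"cohort"` (default; re-compute the median on
#'   this cohort, as done when validating on external series) or
#'   `"training"` (reuse the stored training median).
#' @param max_missing_fraction Maximum tolerated fraction of a model cell
#'   type's signature genes absent from `expr` (default 0.5).
#' @return Tibble: `sample_id`, `irrs`, `group`.
#' @export
irrs_score <- function(model, expr, gene_sets,
                       median_policy = c("cohort", "training"),
                       max_missing_fraction = 0.5) {
  median_policy <- match.arg(median_policy)
  cells_needed <- unique(c(model$pairs$a_cell, model$pairs$b_cell))
  missing_sets <- setdiff(cells_needed, names(gene_sets))
  if (length(missing_sets) > 0L)
    abort(sprintf("gene sets missing for model cell type(s): %s",
                  paste(missing_sets, collapse = ", ")))
  sets <- gene_sets[cells_needed]
  frac_missing <- vapply(sets, function(g) mean(!g %in% rownames(expr)), 0)
  if (any(frac_missing > max_missing_fraction))
    abort(sprintf("more than %.0f%% of signature genes missing for: %s",
                  100 * max_missing_fraction,
                  paste(names(sets)[frac_missing > max_missing_fraction],
                        collapse = ", ")))
  abund <- ssgsea_scores(expr, sets, alpha = model$ssgsea_params$alpha,
                         normalize = model$ssgsea_params$normalize)
  pm <- build_pair_matrix(abund, model$pairs$pair)
  scores <- compute_irrs(model, pm)
  thr <- if (median_policy == "training") {
    if (is.na(model$training_median))
      abort("model has no stored training median; use median_policy = 'cohort'")
    model$training_median
  } else NULL
  stratify_by_median(scores, threshold = thr)
}

#' Evaluate risk scores on a cohort
#'
#' Convenience battery: concordance, per-horizon time-dependent AUC, and
#' the two-group Kaplan-Meier / log-rank comparison of the median split.
#'
#' @param scores Tibble (`sample_id`, `irrs`, optionally `group`).
#' @param surv Survival tibble; attribute `"units"` (days/months/years)
#'   controls horizon conversion.
#' @param horizons_years Evaluation horizons in years (default 1, 3, 5).
#' @param units Override for the survival time unit; default taken from
#'   `attr(surv, "units")`, falling back to `"years"`.
#' @return List: `c_index`, `auc` (tibble `horizon_years`, `auc`),
#'   `logrank`, `km` (an `irrs_km` tibble), `groups`.
#' @export
irrs_evaluate <- function(scores, surv, horizons_years = c(1, 3, 5),
                          units = NULL) {
  units <- units %||% attr(surv, "units") %||% "years"
  scores <- scores[match(surv$sample_id, scores$sample_id), , drop = FALSE]
  if (!"group" %in% names(scores)) scores <- stratify_by_median(scores)
  auc <- purrr::map_dfr(horizons_years, function(h) {
    t_h <- horizon_to_units(h, units)
    a <- tryCatch(td_auc(scores, surv, t_h), error = function(e) NA_real_)
    tibble(horizon_years = h, auc = a)
  })
  list(c_index = c_index(scores, surv),
       auc = auc,
       logrank = logrank_test(surv, scores$group),
       km = km_estimate(surv, scores$group),
       groups = scores$group)
}
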