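surv_object <- function(surv) {
  if (!all(c("sample_id", "time", "event") %in% names(surv)))
    abort("survival data needs columns sample_id, time, event")
  if (any(surv$time <= 0)) abort("survival time must be positive")
  if (!all(surv$event %in% c(0, 1))) abort("event must be 0 or 1")
  survival::Surv(surv$time, surv$event)
}

check_alignment <- function(m, surv) {
  if (ncol(m) != nrow(surv) || !all(colnames(m) == surv$sample_id))
    abort("feature matrix samples and survival samples are not aligned")
}

# univariate Cox fit of one feature; Efron ties; NULL on failure
uni_cox_one <- function(x, y) {
  fit <- tryCatch(
    suppressWarnings(survival::coxph(y ~ x, ties = "efron")),
    error = function(e) NULL)
  if (is.null(fit)) return(NULL)
  s <- summary(fit)
  beta <- unname(coef(fit)[1L])
  se <- s$coefficients[1L, "se(coef)"]
  if (!is.finite(beta) || !is.finite(se) || se > 50) return(NULL)
  tibble(coef = beta, hr = exp(beta),
         ci_lower = exp(beta - 1.96 * se), ci_upper = exp(beta + 1.96 * se),
         p_value = s$coefficients[1L, "Pr(>|z|)"])
}

#' Screen cell types for prognostic association
#'
#' Fits a univariate Cox proportional-hazards model (Efron tie handling)
#' of survival on each cell type's enrichment score and flags cells whose
#' Wald p-value falls below `p_cut`. Cells whose fit fails to converge are
#' excluded with a warning.
#'
#' @param abund Cell types x samples abundance matrix, columns aligned
#'   with `surv$sample_id`.
#' @param surv Survival tibble (`sample_id`, `time`, `event`).
#' @param p_cut Wald p-value threshold (default 0.05).
#' @return Tibble with one row per cell type: `cell_type`, `coef`, `hr`,
#'   `ci_lower`, `ci_upper`, `p_value`, `selected`. Use
#'   `dplyr::filter(., selected)` for the prognostic list.
#' @export
screen_prognostic_cells <- function(abund, surv, p_cut = 0.05) {
  if (is.null(dim(abund)) || nrow(abund) == 0L || ncol(abund) == 0L)
    abort("empty abundance matrix")
  check_alignment(abund, surv)
  if (sum(surv$event) < 2L) abort("need at least 2 events to screen")
  y <- surv_object(surv)
  rows <- lapply(rownames(abund), function(ct) {
    res <- uni_cox_one(abund[ct, ], y)
    if (is.null(res)) {
      warn(sprintf("Cox fit failed to converge for cell type '%s'; excluded", ct))
      return(tibble(cell_type = ct, coef = NA_real_, hr = NA_real_,
                    ci_lower = NA_real_, ci_upper = NA_real_,
                    p_value = NA_real_, selected = FALSE))
    }
    mutate(res, cell_type = ct, selected = .data$p_value < p_cut,
           .before = 1L)
  })
  bind_rows(rows)
}

#' Screen cell pairs for prognostic association
#'
#' Univariate Cox screen of each binary pair indicator (Wald p < `p_cut`).
#' Constant indicator columns are rejected with an error — they should
#' have been removed by [prevalence_filter()].
#'
#' @param m Binary pairs x samples matrix, columns aligned with
#'   `surv$sample_id`.
#' @inheritParams screen_prognostic_cells
#' @return The matrix restricted to selected pairs, with the full screen
#'   tibble (`pair`, `coef`, `hr`, `ci_lower`, `ci_upper`, `p_value`,
#'   `selected`) as attribute `"screen"`.
#' @export
screen_prognostic_pairs <- function(m, surv, p_cut = 0.05) {
  if (is.null(dim(m)) || nrow(m) == 0L) abort("empty pair matrix")
  check_alignment(m, surv)
  cst <- apply(m, 1L, function(x) all(x == x[1L]))
  if (any(cst))
    abort(sprintf("constant pair indicator(s): %s; apply prevalence_filter first",
                  paste(head(rownames(m)[cst], 5L), collapse = ", ")))
  y <- surv_object(surv)
  rows <- lapply(rownames(m), function(p) {
    res <- uni_cox_one(m[p, ], y)
    if (is.null(res)) {
      warn(sprintf("Cox fit failed to converge for pair '%s'; excluded", p))
      return(tibble(pair = p, coef = NA_real_, hr = NA_real_,
                    ci_lower = NA_real_, ci_upper = NA_real_,
                    p_value = NA_real_, selected = FALSE))
    }
    mutate(res, pair = p, selected = .data$p_value < p_cut, .before = 1L)
  })
  screen <- bind_rows(rows)
  sel <- screen$pair[screen$selected]
  if (length(sel) == 0L)
    abort("no pair passed the univariate Cox screen; consider raising p_cut")
  out <- m[sel, , drop = FALSE]
  attr(out, "screen") <- screen
  out
}

#' L1-penalized Cox selection of cell pairs
#'
#' Fits LASSO Cox regression on the pair indicators and returns the pairs
#' with nonzero coefficients at the cross-validated penalty (partial
#' likelihood deviance criterion, penalty minimizing the mean CV deviance
#' by default). Fold assignment is a seeded shuffle, so selection is
#' deterministic given `seed`.
#'
#' @param m Binary pairs x samples matrix (>= 2 pairs).
#' @param surv Survival tibble.
#' @param cv_folds Number of CV folds (default 10).
#' @param seed Integer seed for fold assignment.
#' @param rule `"min"` (default, lambda at minimum mean CV deviance) or
#'   `"1se"`.
#' @param penalty Optional fixed penalty; skips cross-validation and
#'   selects at this lambda (0 gives the unpenalized fit, large values an
#'   empty selection — which is an error).
#' @return Character vector of selected pair names, with attributes
#'   `"coefficients"` (named numeric at the chosen penalty) and
#'   `"lambda"`.
#' @export
lasso_cox_select <- function(m, surv, cv_folds = 10, seed = 1,
                             rule = c("min", "1se"), penalty = NULL) {
  rule <- match.arg(rule)
  if (nrow(m) < 2L) abort("need at least 2 pairs for penalized selection")
  check_alignment(m, surv)
  x <- t(m)
  y <- surv_object(surv)
  if (is.null(penalty)) {
    if (sum(surv$event) < cv_folds)
      abort("need at least as many events as CV folds")
    foldid <- withr::with_seed(as.integer(seed),
      sample(rep(seq_len(cv_folds), length.out = nrow(x))))
    cvfit <- glmnet::cv.glmnet(x, y, family = "cox", alpha = 1,
                               type.measure = "deviance", foldid = foldid)
    lam <- if (rule == "min") cvfit$lambda.min else cvfit$lambda.1se
    cf <- as.numeric(coef(cvfit, s = lam))
    names(cf) <- rownames(coef(cvfit, s = lam))
  } else {
    fit <- glmnet::glmnet(x, y, family = "cox", alpha = 1, thresh = 1e-12)
    cfm <- coef(fit, s = penalty, exact = TRUE, x = x, y = y,
                family = "cox", alpha = 1, thresh = 1e-12)
    cf <- as.numeric(cfm)
    names(cf) <- rownames(cfm)
    lam <- penalty
  }
  sel <- names(cf)[cf != 0]
  if (length(sel) == 0L)
    abort("no pair selected at the chosen penalty; try rule = 'min' or a smaller penalty")
  structure(sel, coefficients = cf[sel], lambda = lam)
}

# backward elimination by AIC on a coxph fit over named columns of df
backward_eliminate_aic <- function(df, y, vars) {
  log_rows <- list()
  step_i <- 0L
  repeat {
    fit <- survival::coxph(y ~ ., data = df[, vars, drop = FALSE], ties = "efron")
    aic_now <- stats::extractAIC(fit)[2L]
    if (length(vars) == 1L) break
    aics <- vapply(vars, function(v) {
      f <- survival::coxph(y ~ ., data = df[, setdiff(vars, v), drop = FALSE],
                           ties = "efron")
      stats::extractAIC(f)[2L]
    }, 0)
    best <- which.min(aics)
    if (aics[best] < aic_now) {
      step_i <- step_i + 1L
      log_rows[[step_i]] <- tibble(step = step_i, dropped = vars[best],
                                   aic_before = aic_now, aic_after = aics[best])
      inform(sprintf("backward elimination: dropping '%s' (AIC %.2f -> %.2f)",
                     vars[best], aic_now, aics[best]))
      vars <- vars[-best]
    } else break
  }
  list(vars = vars, log = if (length(log_rows)) bind_rows(log_rows) else
    tibble(step = integer(), dropped = character(),
           aic_before = double(), aic_after = double()))
}

#' Fit the final multivariate Cox model over selected pairs
#'
#' Fits a multivariate proportional-hazards model (Efron ties) on the
#' selected pair indicators; the coefficients become the pair weights
#' `Coef_A|B` of the risk score. Exactly collinear pairs (e.g. reciprocal
#' orderings selected together) are dropped with a message before
#' fitting. Optional backward elimination by AIC (on by default, logged
#' step by step) prunes pairs that do not earn their keep. The median
#' training risk score is stored as the stratification threshold.
#'
#' @param m Binary pairs x samples matrix containing at least the
#'   selected pairs.
#' @param selected Character vector of pair names to fit.
#' @param surv Survival tibble aligned with `m`.
#' @param backward_aic Prune the model by AIC (default TRUE).
#' @param ssgsea_params Enrichment parameters to record in the model.
#' @param filter_threshold,p_cut,seed Provenance fields echoed into the
#'   model document.
#' @return An `irrs_model`.
#' @export
finalize_model <- function(m, selected, surv, backward_aic = TRUE,
                           ssgsea_params = list(alpha = 0.25, normalize = "none"),
                           filter_threshold = 0.8, p_cut = 0.05,
                           seed = NA_integer_) {
  if (length(selected) == 0L) abort("no pairs selected for the final model")
  missing <- setdiff(selected, rownames(m))
  if (length(missing) > 0L)
    abort(sprintf("selected pair(s) absent from the matrix: %s",
                  paste(missing, collapse = ", ")))
  check_alignment(m, surv)
  y <- surv_object(surv)
  safe <- paste0("P", seq_along(selected))
  df <- as.data.frame(t(m[selected, , drop = FALSE]))
  names(df) <- safe
  name_map <- setNames(selected, safe)

  fit <- survival::coxph(y ~ ., data = df, ties = "efron")
  dropped <- names(coef(fit))[is.na(coef(fit))]
  if (length(dropped) > 0L) {
    inform(sprintf("dropping collinear pair(s): %s",
                   paste(name_map[dropped], collapse = ", ")))
    safe <- setdiff(safe, dropped)
  }
  if (backward_aic) {
    bk <- backward_eliminate_aic(df, y, safe)
    safe <- bk$vars
    elim_log <- mutate(bk$log, dropped = unname(name_map[.data$dropped]))
  } else {
    elim_log <- NULL
  }
  fit <- survival::coxph(y ~ ., data = df[, safe, drop = FALSE], ties = "efron")
  s <- summary(fit)
  sp <- split_pair(unname(name_map[safe]))
  pairs <- tibble(
    pair = unname(name_map[safe]), a_cell = sp$a, b_cell = sp$b,
    coef = unname(coef(fit)),
    std_error = unname(s$coefficients[, "se(coef)"]),
    p_value = unname(s$coefficients[, "Pr(>|z|)"]))

  model <- new_irrs_model(pairs, NA_real_, ssgsea_params, filter_threshold,
                          p_cut, seed, elim_log)
  scores <- compute_irrs(model, m)
  model$training_median <- median(scores$irrs)
  model
}

#' Compute the immune-related risk score
#'
#' `IRRS(j) = sum over model pairs of Score_A|B(j) * Coef_A|B` — the exact
#' linear combination, with no intercept and no standardization.
#'
#' @param model An `irrs_model`.
#' @param m Binary pairs x samples matrix containing every model pair
#'   (rebuild it for a new cohort with [build_pair_matrix()] on that
#'   cohort's own abundance matrix).
#' @return Tibble with columns `sample_id`, `irrs`.
#' @export
compute_irrs <- function(model, m) {
  missing <- setdiff(model$pairs$pair, rownames(m))
  if (length(missing) > 0L) {
    cells <- unique(unlist(split_pair(missing)))
    abort(sprintf("pair(s) absent from the indicator matrix: %s (cell types involved: %s)",
                  paste(missing, collapse = ", "), paste(cells, collapse = ", ")))
  }
  sub <- m[model$pairs$pair, , drop = FALSE]
  tibble(sample_id = colnames(m),
         irrs = as.numeric(crossprod(sub, model$pairs$coef)))
}

#' Stratify samples into high and low risk groups
#'
#' Samples with a score strictly above the threshold are labelled
#' `"high"`; scores at or below it (including a sample exactly at the
#' median) are `"low"`. The default threshold is the median of the
#' supplied scores; pass a stored training median to reuse it on a new
#' cohort.
#'
#' @param scores Tibble with columns `sample_id`, `irrs` (or a bare
#'   numeric vector).
#' @param threshold Optional numeric threshold; default the median of the
#'   scores.
#' @return The scores tibble with a `group` factor (`low`, `high`)
#'   appended.
#' @export
stratify_by_median <- function(scores, threshold = NULL) {
  if (is.numeric(scores) && is.null(dim(scores))) {
    scores <- tibble(sample_id = names(scores) %||% as.character(seq_along(scores)),
                     irrs = unname(scores))
  }
  if (nrow(scores) < 2L) abort("need at least 2 samples to stratify")
  if (length(unique(scores$irrs)) == 1L)
    abort("all scores identical; no stratification possible")
  thr <- threshold %||% median(scores$irrs)
  mutate(scores, group = factor(ifelse(.data$irrs > thr, "high", "low"),
                                levels = c("low", "high")))
}
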