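#' Combined clinical prediction model (nomogram)
#'
#' Fits a multivariate Cox proportional-hazards model on the risk score
#' plus clinical covariates (typically age, ulceration, Breslow depth and
#' nodal stage), with the Breslow baseline survival evaluated at the
#' covariate reference (categorical covariates at their reference level,
#' numeric covariates at their observed minimum) and the conventional
#' 0-100 points scaling: the covariate with the widest
#' `|coefficient x range|` spans 100 points, every other covariate scales
#' linearly.
#'
#' @param scores Tibble (`sample_id`, `irrs`) from [compute_irrs()].
#' @param clinical Tibble with `sample_id` and covariates, complete after
#'   [impute_clinical()].
#' @param surv Survival tibble.
#' @param covariates Character vector of clinical columns to include;
#'   default every non-id column.
#' @return An object of class `irrs_nomogram`: the Cox fit, the baseline
#'   survival step function, and the points table.
#' @export
fit_nomogram <- function(scores, clinical, surv,
                         covariates = setdiff(names(clinical), "sample_id")) {
  df <- dplyr::inner_join(scores, clinical, by = "sample_id")
  df <- dplyr::inner_join(df, surv, by = "sample_id")
  if (nrow(df) < 2L) abort("too few samples shared between scores, clinical and survival data")
  if (anyNA(df[, covariates, drop = FALSE]))
    abort("clinical covariates contain missing values; run impute_clinical() first")
  vars <- c("irrs", covariates)
  form <- stats::as.formula(paste("survival::Surv(time, event) ~",
                                  paste(sprintf("`%s`", vars), collapse = " + ")))
  fit <- survival::coxph(form, data = df, ties = "efron", model = TRUE, x = TRUE)
  if (anyNA(coef(fit)))
    abort("nomogram Cox fit produced undefined coefficients (collinear covariates?)")

  # reference row: factor reference levels, numeric minima
  ref <- df[1L, vars, drop = FALSE]
  for (v in vars) {
    x <- df[[v]]
    if (is.numeric(x)) {
      ref[[v]] <- min(x)
    } else {
      f <- factor(x)
      ref[[v]] <- factor(levels(f)[1L], levels = levels(f))
      df[[v]] <- f
    }
  }
  sf <- survival::survfit(fit, newdata = ref)
  baseline <- tibble(time = sf$time, s0 = sf$surv)

  # per-covariate contribution range on the linear-predictor scale
  contrib_range <- vapply(vars, function(v) {
    x <- df[[v]]
    if (is.numeric(x)) {
      cf <- coef(fit)[[if (v == "irrs") "irrs" else v]] %||% coef(fit)[[sprintf("`%s`", v)]]
      abs(cf * (max(x) - min(x)))
    } else {
      lv <- levels(x)
      cfs <- c(0, vapply(lv[-1L], function(l) {
        nm <- paste0(v, l)
        nm2 <- paste0(sprintf("`%s`", v), l)
        unname(coef(fit)[nm] %||% coef(fit)[nm2])
      }, 0))
      diff(range(cfs))
    }
  }, 0)
  points <- tibble(term = vars,
                   lp_range = unname(contrib_range),
                   points = 100 * unname(contrib_range) / max(contrib_range))

  structure(list(fit = fit, vars = vars, reference = ref,
                 lp_ref = unname(predict(fit, newdata = ref, type = "lp")),
                 baseline = baseline, points = points),
            class = "irrs_nomogram")
}

#' @export
print.irrs_nomogram <- function(x, ...) {
  cat("Combined clinical prediction model (Cox) with points scaling\n")
  print(x$points)
  invisible(x)
}

#' @method tidy irrs_nomogram
#' @export
tidy.irrs_nomogram <- function(x, ...) {
  s <- summary(x$fit)$coefficients
  tibble(term = rownames(s), estimate = s[, "coef"],
         hazard_ratio = s[, "exp(coef)"], std_error = s[, "se(coef)"],
         p_value = s[, "Pr(>|z|)"])
}

#' @method glance irrs_nomogram
#' @export
glance.irrs_nomogram <- function(x, ...) {
  s <- summary(x$fit)
  tibble(n = s$n, n_events = s$nevent,
         concordance = unname(s$concordance["C"]),
         logtest_p = unname(s$logtest["pvalue"]))
}

#' Predict survival probabilities from a nomogram model
#'
#' `S(t | x) = S0(t)^exp(lp(x) - lp(reference))`, with `S0` the Breslow
#' baseline survival at the covariate reference.
#'
#' @param object An `irrs_nomogram`.
#' @param newdata Tibble with the model's covariate columns (and
#'   optionally `sample_id`).
#' @param horizons Numeric vector of evaluation times, in the survival
#'   table's own units.
#' @param ... Unused.
#' @return Tibble: `sample_id`, `horizon`, `surv_prob`, `risk`.
#' @export
predict.irrs_nomogram <- function(object, newdata, horizons, ...) {
  ids <- newdata$sample_id %||% as.character(seq_len(nrow(newdata)))
  lp <- predict(object$fit, newdata = newdata, type = "lp")
  rel <- exp(lp - object$lp_ref)
  s0_at <- vapply(horizons, function(h) {
    c(1, object$baseline$s0)[findInterval(h, c(0, object$baseline$time))]
  }, 0)
  out <- tidyr::expand_grid(sample_id = ids, horizon = horizons)
  out$surv_prob <- as.vector(outer(s0_at, rel, function(s, r) s^r))
  out$risk <- 1 - out$surv_prob
  out
}
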