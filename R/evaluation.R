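align_scores <- function(scores, surv) {
  if (is.numeric(scores) && is.null(dim(scores))) {
    if (length(scores) != nrow(surv))
      abort("score vector length does not match survival data")
    return(unname(scores))
  }
  if (!all(c("sample_id", "irrs") %in% names(scores)))
    abort("scores must be a numeric vector or a tibble with sample_id and irrs")
  idx <- match(surv$sample_id, scores$sample_id)
  if (anyNA(idx)) abort("scores missing for some survival samples")
  scores$irrs[idx]
}

#' Kaplan-Meier survival estimate
#'
#' Product-limit estimator of the survival function, overall or per
#' group. A thin tidy wrapper around [survival::survfit()].
#'
#' @param surv Survival tibble (`sample_id`, `time`, `event`).
#' @param groups Optional factor/character vector aligned with `surv`
#'   rows (e.g. risk groups from [stratify_by_median()]).
#' @return Tibble of class `irrs_km` with columns `group`, `time`,
#'   `n_risk`, `n_event`, `n_censor`, `estimate`.
#' @export
km_estimate <- function(surv, groups = NULL) {
  y <- surv_object(surv)
  if (is.null(groups)) {
    fit <- survival::survfit(y ~ 1)
    out <- tibble(group = factor("all"), time = fit$time, n_risk = fit$n.risk,
                  n_event = fit$n.event, n_censor = fit$n.censor,
                  estimate = fit$surv)
  } else {
    g <- factor(groups)
    fit <- survival::survfit(y ~ g)
    out <- tibble(
      group = factor(rep(sub("^g=", "", names(fit$strata)), fit$strata),
                     levels = levels(g)),
      time = fit$time, n_risk = fit$n.risk, n_event = fit$n.event,
      n_censor = fit$n.censor, estimate = fit$surv)
  }
  class(out) <- c("irrs_km", class(out))
  out
}

#' Two-group log-rank test
#'
#' @param surv Survival tibble.
#' @param groups Two-level factor/character vector aligned with `surv`.
#' @return One-row tibble: `statistic` (chi-square, 1 df), `df`,
#'   `p_value`.
#' @export
logrank_test <- function(surv, groups) {
  g <- factor(groups)
  if (nlevels(g) != 2L) abort("log-rank test requires exactly 2 groups")
  if (any(table(g) < 1L)) abort("each group needs at least 1 subject")
  y <- surv_object(surv)
  d <- survival::survdiff(y ~ g)
  tibble(statistic = d$chisq, df = 1L,
         p_value = stats::pchisq(d$chisq, df = 1L, lower.tail = FALSE))
}

#' Harrell's concordance index
#'
#' Probability that of two comparable subjects, the one with the higher
#' risk score fails first. A pair is comparable when the shorter observed
#' time belongs to a subject who had the event (pairs tied on time are
#' usable only as event-versus-censored); risk-score ties count 0.5.
#'
#' @param scores Numeric risk vector, or tibble (`sample_id`, `irrs`).
#' @param surv Survival tibble.
#' @return Concordance in `[0, 1]`.
#' @export
c_index <- function(scores, surv) {
  x <- align_scores(scores, surv)
  t <- surv$time; e <- surv$event
  ti <- matrix(t, length(t), length(t))          # ti[i, j] = t_i
  ei <- matrix(e, length(t), length(t))
  comparable <- (ti < t(ti) & ei == 1) | (ti == t(ti) & ei == 1 & t(ei) == 0)
  diag(comparable) <- FALSE
  n_comp <- sum(comparable)
  if (n_comp == 0L) abort("no comparable pairs")
  xi <- matrix(x, length(x), length(x))
  conc <- sum(comparable & (xi > t(xi)))
  ties <- sum(comparable & (xi == t(xi)))
  (conc + 0.5 * ties) / n_comp
}

# censoring-distribution KM; returns a left-continuous lookup function
censoring_km <- function(surv) {
  fit <- survival::survfit(survival::Surv(surv$time, 1 - surv$event) ~ 1)
  times <- fit$time; s <- fit$surv
  function(t, left = FALSE) {
    vapply(t, function(tt) {
      idx <- if (left) which(times < tt) else which(times <= tt)
      if (length(idx) == 0L) 1 else s[max(idx)]
    }, 0)
  }
}

#' Time-dependent ROC AUC
#'
#' Cumulative-case / dynamic-control AUC at horizon `t`: cases are
#' subjects with an event by `t`, controls those still event-free beyond
#' `t`. Censoring before `t` is handled by inverse-probability-of-
#' censoring weights from the Kaplan-Meier estimate of the censoring
#' distribution (cases weighted by `1/G(T_i-)`); with no censoring before
#' `t` this reduces to the plain binary AUC. Score ties count 0.5.
#'
#' @param scores Numeric risk vector or tibble (`sample_id`, `irrs`).
#' @param surv Survival tibble.
#' @param horizon Evaluation time, in the survival table's own units.
#' @return AUC(t) in `[0, 1]`.
#' @export
td_auc <- function(scores, surv, horizon) {
  x <- align_scores(scores, surv)
  case <- surv$time <= horizon & surv$event == 1
  control <- surv$time > horizon
  if (!any(case)) abort("no events by the horizon")
  if (!any(control)) abort("no subjects at risk beyond the horizon")
  G <- censoring_km(surv)
  w_case <- 1 / G(surv$time[case], left = TRUE)
  w_case[!is.finite(w_case)] <- 0
  xc <- x[case]; xk <- x[control]
  gt <- outer(xc, xk, ">")
  eq <- outer(xc, xk, "==")
  num <- sum(w_case * (rowSums(gt) + 0.5 * rowSums(eq)))
  den <- sum(w_case) * length(xk)
  num / den
}

# event status at a horizon, excluding subjects censored before it
status_at_horizon <- function(surv, horizon) {
  status <- ifelse(surv$time <= horizon & surv$event == 1, 1L,
                   ifelse(surv$time > horizon, 0L, NA_integer_))
  if (all(is.na(status) | status == 0L)) abort("no events by the horizon")
  status
}

#' Integrated discrimination improvement
#'
#' Gain in discrimination slope — (mean risk in events) minus (mean risk
#' in non-events) — of a new risk model over a reference model, for event
#' status at horizon `t`. Subjects censored before `t` are excluded.
#' Significance by seeded bootstrap percentile interval.
#'
#' @param new_risk,ref_risk Numeric risk vectors on the same samples (any
#'   common risk scale).
#' @param surv Survival tibble.
#' @param horizon Evaluation time, in the survival table's units.
#' @param n_boot Bootstrap replicates (default 1000).
#' @param seed Seed for the bootstrap.
#' @param conf_level Confidence level of the percentile interval.
#' @return One-row tibble: `idi`, `conf_low`, `conf_high`, `p_value`,
#'   `n_used`, `n_events`.
#' @export
idi <- function(new_risk, ref_risk, surv, horizon, n_boot = 1000, seed = 1,
                conf_level = 0.95) {
  if (length(new_risk) != nrow(surv) || length(ref_risk) != nrow(surv))
    abort("risk vectors must align with the survival data")
  status <- status_at_horizon(surv, horizon)
  keep <- !is.na(status)
  s <- status[keep]; nr <- new_risk[keep]; rr <- ref_risk[keep]
  slope <- function(risk, st) mean(risk[st == 1]) - mean(risk[st == 0])
  est <- slope(nr, s) - slope(rr, s)
  boot <- withr::with_seed(as.integer(seed), {
    vapply(seq_len(n_boot), function(b) {
      idx <- sample.int(length(s), replace = TRUE)
      if (length(unique(s[idx])) < 2L) return(NA_real_)
      slope(nr[idx], s[idx]) - slope(rr[idx], s[idx])
    }, 0)
  })
  boot <- boot[!is.na(boot)]
  a <- (1 - conf_level) / 2
  tibble(idi = est,
         conf_low = unname(quantile(boot, a)),
         conf_high = unname(quantile(boot, 1 - a)),
         p_value = min(1, 2 * min(mean(boot <= 0), mean(boot >= 0))),
         n_used = sum(keep), n_events = sum(s))
}

#' Decision-curve net benefit
#'
#' Net benefit of treating subjects whose predicted risk exceeds each
#' threshold probability: `NB(pt) = TP/n - FP/n * pt/(1 - pt)`, with
#' event status at the horizon as in [idi()]. Treat-all and treat-none
#' reference policies are returned alongside the model.
#'
#' @param risks Predicted event probabilities in `[0, 1]`.
#' @param surv Survival tibble.
#' @param horizon Evaluation time, in the survival table's units.
#' @param thresholds Threshold probabilities in `[0, 1)`; values >= 1 are
#'   excluded with a message.
#' @return Tibble of class `irrs_dca`: `threshold`, `strategy`
#'   (`model` / `treat_all` / `treat_none`), `net_benefit`.
#' @export
dca_net_benefit <- function(risks, surv, horizon,
                            thresholds = seq(0.01, 0.6, by = 0.01)) {
  if (length(risks) != nrow(surv)) abort("risks must align with the survival data")
  drop <- thresholds >= 1 | thresholds < 0
  if (any(drop)) {
    inform(sprintf("excluding %d threshold(s) outside [0, 1)", sum(drop)))
    thresholds <- thresholds[!drop]
  }
  status <- status_at_horizon(surv, horizon)
  keep <- !is.na(status)
  s <- status[keep]; r <- risks[keep]
  n <- length(s)
  event_rate <- mean(s)
  rows <- purrr::map(thresholds, function(pt) {
    treat <- r > pt
    tp <- sum(treat & s == 1) / n
    fp <- sum(treat & s == 0) / n
    odds <- pt / (1 - pt)
    tibble(threshold = pt,
           strategy = c("model", "treat_all", "treat_none"),
           net_benefit = c(tp - fp * odds,
                           event_rate - (1 - event_rate) * odds,
                           0))
  })
  out <- bind_rows(rows)
  class(out) <- c("irrs_dca", class(out))
  out
}

#' Calibration of predicted risks against observed outcome
#'
#' Bins subjects by quantiles of predicted risk at horizon `t` and
#' compares the mean predicted risk per bin with the Kaplan-Meier
#' estimate of the observed event probability (1 - S(t)) within the bin.
#' Bins emptied by tied quantiles are merged with a message.
#'
#' @param risks Predicted event probabilities at the horizon.
#' @param surv Survival tibble.
#' @param horizon Evaluation time, in the survival table's units.
#' @param bins Number of quantile bins (>= 2, default 5).
#' @return Tibble of class `irrs_calibration`: `bin`, `n`,
#'   `mean_predicted`, `observed`.
#' @export
calibration_curve <- function(risks, surv, horizon, bins = 5) {
  if (length(risks) != nrow(surv)) abort("risks must align with the survival data")
  if (bins < 2L) abort("need at least 2 bins")
  br <- unique(quantile(risks, probs = seq(0, 1, length.out = bins + 1L)))
  if (length(br) < 3L) {
    inform("predictions nearly constant; using a single bin")
    bin <- factor(rep(1L, length(risks)))
  } else {
    if (length(br) < bins + 1L) inform("merging empty calibration bin(s)")
    bin <- cut(risks, breaks = br, include.lowest = TRUE, labels = FALSE)
    bin <- factor(bin)
  }
  rows <- purrr::map(levels(bin), function(b) {
    idx <- bin == b
    km <- survival::survfit(survival::Surv(surv$time[idx], surv$event[idx]) ~ 1)
    st <- c(1, km$surv)[findInterval(horizon, c(0, km$time))]
    tibble(bin = as.integer(b), n = sum(idx),
           mean_predicted = mean(risks[idx]), observed = 1 - st)
  })
  out <- bind_rows(rows)
  class(out) <- c("irrs_calibration", class(out))
  out
}
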