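test_that("Kaplan-Meier estimates match hand computation and limits", {
  # all censored: survival stays at 1
  km0 <- km_estimate(toy_surv(c(2, 4, 6), c(0, 0, 0)))
  expect_true(all(km0$estimate == 1))
  # no censoring: KM equals 1 - ECDF at the event times
  tt <- c(3, 1, 4, 2, 5)
  km1 <- km_estimate(toy_surv(tt, rep(1, 5)))
  expect_equal(km1$estimate, 1 - ecdf(tt)(sort(tt)), tolerance = 1e-15)
  # classic 6-subject toy: times 1, 2+, 3, 4, 5+, 6
  km2 <- km_estimate(toy_surv(1:6, c(1, 0, 1, 1, 0, 1)))
  expect_equal(km2$estimate,
               c(5/6, 5/6, 5/6 * 3/4, 5/6 * 3/4 * 2/3, 5/6 * 3/4 * 2/3, 0),
               tolerance = 1e-15)
})

test_that("log-rank test matches the (O-E)^2/V oracle and symmetry", {
  # identical event patterns in both groups: statistic 0, p = 1
  surv <- toy_surv(rep(c(1, 2, 3), 2), rep(c(1, 0, 1), 2))
  lr0 <- logrank_test(surv, rep(c("a", "b"), each = 3))
  expect_equal(lr0$statistic, 0, tolerance = 1e-12)
  expect_equal(lr0$p_value, 1, tolerance = 1e-12)
  # toy with a real difference: compare with the direct computation
  surv2 <- toy_surv(c(1, 3, 5, 7, 2, 4, 6, 8), c(1, 1, 0, 1, 1, 0, 1, 1))
  g2 <- rep(c("a", "b"), each = 4)
  lr2 <- logrank_test(surv2, g2)
  expect_equal(lr2$statistic, oracle_logrank(surv2$time, surv2$event, g2),
               tolerance = 1e-10)
  expect_error(logrank_test(surv2, rep("a", 8)), "2 groups")
  # a strong planted effect is detected decisively
  withr::with_seed(41, {
    n <- 200
    grp <- rep(c("lo", "hi"), each = n / 2)
    tm <- rexp(n, 0.1 * exp(1.5 * (grp == "hi")))
    cn <- runif(n, 0, 25)
    surv3 <- toy_surv(pmin(tm, cn), as.numeric(tm <= cn))
  })
  expect_lt(logrank_test(surv3, grp)$p_value, 0.001)
})

test_that("concordance handles perfect, reversed and tied orderings", {
  surv <- toy_surv(c(1, 2, 3, 4), rep(1, 4))
  expect_identical(c_index(c(4, 3, 2, 1), surv), 1)   # higher risk fails first
  expect_identical(c_index(c(1, 2, 3, 4), surv), 0)
  expect_identical(c_index(c(1, 1, 1, 1), surv), 0.5)
  expect_error(c_index(c(1, 2), toy_surv(c(3, 3), c(0, 0))), "comparable")
})

test_that("concordance equals brute-force pair enumeration on random data", {
  set.seed(42)
  for (rep in 1:25) {
    n <- sample(5:30, 1)
    t <- sample(1:12, n, replace = TRUE)
    e <- rbinom(n, 1, 0.6)
    x <- sample(1:6, n, replace = TRUE)
    surv <- toy_surv(t, e)
    want <- tryCatch(oracle_c_index(x, t, e), error = function(err) NaN)
    if (!is.finite(want)) next
    expect_equal(c_index(x, surv), want, tolerance = 1e-12)
  }
  # on tie-free data the established library implementation agrees too
  for (rep in 1:5) {
    n <- 25
    t <- rexp(n); e <- rbinom(n, 1, 0.6); x <- rnorm(n)
    if (sum(e) == 0) next
    lib <- survival::concordance(survival::Surv(t, e) ~ x, reverse = TRUE)
    expect_equal(c_index(x, toy_surv(t, e)), unname(lib$concordance),
                 tolerance = 1e-12)
  }
})

test_that("time-dependent AUC reduces to binary AUC without censoring", {
  withr::with_seed(43, {
    n <- 300
    t <- rexp(n, 0.2)
    x <- -t + rnorm(n, sd = 0.5)    # higher score, earlier event
  })
  surv <- toy_surv(t, rep(1, n))
  h <- 4
  case <- t <= h
  plain <- mean(outer(x[case], x[!case], ">") + 0.5 * outer(x[case], x[!case], "=="))
  expect_equal(td_auc(x, surv, h), plain, tolerance = 1e-12)
  expect_gt(td_auc(x, surv, h), 0.8)
  expect_error(td_auc(x, surv, 1e-9), "no events")
})

test_that("time-dependent AUC matches a hand-weighted oracle under censoring", {
  # 6 subjects, one censored before the horizon
  surv <- toy_surv(c(1, 2, 3, 4, 5, 6), c(1, 0, 1, 1, 1, 0))
  x <- c(6, 5, 1, 3, 2, 4)
  h <- 4.5
  # censoring KM: censoring event at t=2 with 5 at risk -> G drops to 4/5
  # cases: t=1 (G(1-)=1), t=3 (G(3-)=4/5), t=4 (G(4-)=4/5); controls: t=5, t=6
  w <- c(1, 5/4, 5/4)
  conc <- c(2, 0, 1) # case scores 6, 1, 3 against control scores 2 and 4
  want <- sum(w * conc) / (sum(w) * 2)
  expect_equal(td_auc(x, surv, h), want, tolerance = 1e-12)
})

test_that("discrimination improvement is zero against itself and matches hand math", {
  surv <- toy_surv(c(1, 2, 3, 4, 5, 6, 7, 8, 9, 10),
                   c(1, 1, 1, 0, 1, 0, 0, 0, 0, 0))
  new <- c(0.9, 0.8, 0.7, 0.4, 0.6, 0.3, 0.2, 0.3, 0.1, 0.2)
  ref <- c(0.6, 0.5, 0.5, 0.5, 0.5, 0.4, 0.4, 0.5, 0.3, 0.4)
  h <- 5.5
  self <- idi(new, new, surv, h, n_boot = 50, seed = 1)
  expect_identical(self$idi, 0)
  res <- idi(new, ref, surv, h, n_boot = 50, seed = 1)
  # events by 5.5: subjects 1,2,3,5; non-events: 6..10 (subject 4 censored early)
  ev <- c(1, 2, 3, 5); ne <- 6:10
  want <- (mean(new[ev]) - mean(new[ne])) - (mean(ref[ev]) - mean(ref[ne]))
  expect_equal(res$idi, want, tolerance = 1e-12)
  expect_identical(res$n_used, 9L)
})

test_that("net benefit reproduces its closed forms and hand counts", {
  withr::with_seed(44, {
    n <- 20
    t <- rexp(n, 0.15)
    risk <- runif(n)
  })
  surv <- toy_surv(t, rep(1, n))
  h <- 5
  dca <- dca_net_benefit(risk, surv, h, thresholds = c(0, 0.2, 0.4))
  none <- dplyr::filter(dca, strategy == "treat_none")
  expect_true(all(none$net_benefit == 0))
  s <- as.integer(t <= h)
  rate <- mean(s)
  all02 <- dplyr::filter(dca, strategy == "treat_all", threshold == 0.2)
  expect_equal(all02$net_benefit, rate - (1 - rate) * 0.2 / 0.8,
               tolerance = 1e-12)
  all0 <- dplyr::filter(dca, strategy == "treat_all", threshold == 0)
  expect_equal(all0$net_benefit, rate, tolerance = 1e-12)
  mod02 <- dplyr::filter(dca, strategy == "model", threshold == 0.2)
  tp <- sum(risk > 0.2 & s == 1) / n
  fp <- sum(risk > 0.2 & s == 0) / n
  expect_equal(mod02$net_benefit, tp - fp * 0.25, tolerance = 1e-12)
  expect_message(dca_net_benefit(risk, surv, h, thresholds = c(0.2, 1)),
                 "excluding")
})

test_that("nomogram predictions follow S0^exp(lp) with standard points scaling", {
  withr::with_seed(45, {
    n <- 250
    cl <- tibble::tibble(
      sample_id = paste0("s", 1:n),
      age = runif(n, 30, 85),
      ulceration = factor(sample(c("no", "yes"), n, TRUE), levels = c("no", "yes")),
      breslow_depth = rexp(n, 0.5),
      n_stage = factor(sample(c("N0", "N1-3"), n, TRUE), levels = c("N0", "N1-3")))
    sc <- tibble::tibble(sample_id = cl$sample_id, irrs = rnorm(n, sd = 0.4))
    lp_true <- 0.03 * (cl$age - 55) + 0.6 * (cl$ulceration == "yes") +
      0.15 * cl$breslow_depth + 0.4 * (cl$n_stage == "N1-3") + 1.2 * sc$irrs
    tm <- rexp(n, 0.08 * exp(lp_true))
    cn <- runif(n, 0, 30)
  })
  surv <- toy_surv(pmin(tm, cn), as.numeric(tm <= cn), ids = cl$sample_id)
  nom <- fit_nomogram(sc, cl, surv)

  # at the covariate reference the prediction is the baseline itself
  ref <- nom$reference
  ref$sample_id <- "ref"
  pr_ref <- predict(nom, ref, horizons = c(2, 8))
  s0 <- vapply(c(2, 8), function(h) {
    c(1, nom$baseline$s0)[findInterval(h, c(0, nom$baseline$time))]
  }, 0)
  expect_equal(pr_ref$surv_prob, s0, tolerance = 1e-12)

  # independent oracle: survfit on the coxph fit at arbitrary covariates
  new <- cl[7:9, ]
  new$irrs <- sc$irrs[7:9]
  pr <- predict(nom, new, horizons = 6)
  sf <- survival::survfit(nom$fit, newdata = new)
  want <- vapply(1:3, function(i) {
    s <- if (is.matrix(sf$surv)) sf$surv[, i] else sf$surv
    c(1, s)[findInterval(6, c(0, sf$time))]
  }, 0)
  expect_equal(pr$surv_prob, want, tolerance = 1e-8)

  # higher linear predictor gives lower survival at every horizon
  hi <- new[1, ]; hi$sample_id <- "hi"; hi$irrs <- 3; hi$breslow_depth <- 8
  lo <- new[1, ]; lo$sample_id <- "lo"; lo$irrs <- -3; lo$breslow_depth <- 0
  pr2 <- predict(nom, dplyr::bind_rows(hi, lo), horizons = c(1, 4, 9))
  wide <- tidyr::pivot_wider(pr2, id_cols = "horizon",
                             names_from = "sample_id",
                             values_from = "surv_prob")
  expect_true(all(wide[[2]] < wide[[3]]))

  # points: widest contribution spans 100, all non-negative
  expect_equal(max(nom$points$points), 100)
  expect_true(all(nom$points$points >= 0))
})

test_that("calibration bins recover the diagonal for a well-specified model", {
  withr::with_seed(46, {
    n <- 2000
    lp <- rnorm(n, sd = 0.8)
    tm <- rexp(n, 0.1 * exp(lp))
    cn <- runif(n, 0, 30)
  })
  surv <- toy_surv(pmin(tm, cn), as.numeric(tm <= cn))
  h <- 5
  true_risk <- 1 - exp(-0.1 * exp(lp) * h)
  cal <- calibration_curve(true_risk, surv, h, bins = 5)
  expect_true(all(abs(cal$mean_predicted - cal$observed) < 0.05))
  # anti-calibrated predictions reverse the relationship
  anti <- calibration_curve(1 - true_risk, surv, h, bins = 5)
  expect_true(all(diff(anti$observed) < 0))
  # constant predictions: one effective bin equal to the overall KM risk
  expect_message(cal1 <- calibration_curve(rep(0.3, n), surv, h), "constant")
  km <- km_estimate(surv)
  overall <- 1 - km$estimate[max(which(km$time <= h))]
  expect_equal(cal1$observed, overall, tolerance = 1e-12)
  expect_identical(nrow(cal1), 1L)
})
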