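make_direct_effect_cohort <- function(n = 300, k = 6, coef = 1.0, seed = 31) {
  ab <- generate_abundances(n, k, seed = seed)
  z <- scale(log(ab[1, ]))[, 1]          # cell 1 drives hazard
  withr::with_seed(seed + 1L, {
    tm <- rexp(n, 0.1 * exp(coef * z))
    cn <- runif(n, 0, 25)
  })
  list(abund = ab,
       surv = toy_surv(pmin(tm, cn), as.numeric(tm <= cn), ids = colnames(ab)))
}

test_that("the cell screen finds a cell that drives hazard and controls errors", {
  co <- make_direct_effect_cohort()
  scr <- screen_prognostic_cells(co$abund, co$surv)
  expect_true(scr$selected[scr$cell_type == rownames(co$abund)[1]])
  expect_true(all(scr$hr == exp(scr$coef), na.rm = TRUE))
  expect_true(all(scr$ci_lower <= scr$hr & scr$hr <= scr$ci_upper, na.rm = TRUE))
  expect_error(screen_prognostic_cells(matrix(0, 0, 0), co$surv), "empty")
  few_events <- toy_surv(seq_len(ncol(co$abund)),
                         c(1, rep(0, ncol(co$abund) - 1L)),
                         ids = colnames(co$abund))
  expect_error(screen_prognostic_cells(co$abund, few_events), "2 events")
})

test_that("the pair screen keeps a true risk indicator and rejects constants", {
  set.seed(33)
  n <- 250
  ind <- rbind(true_pair = rbinom(n, 1, 0.5), noise_pair = rbinom(n, 1, 0.5))
  colnames(ind) <- paste0("s", 1:n)
  tm <- rexp(n, 0.1 * exp(0.8 * ind["true_pair", ]))
  cn <- runif(n, 0, 25)
  surv <- toy_surv(pmin(tm, cn), as.numeric(tm <= cn), ids = colnames(ind))
  kept <- screen_prognostic_pairs(ind, surv)
  expect_true("true_pair" %in% rownames(kept))
  expect_s3_class(attr(kept, "screen"), "tbl_df")
  bad <- rbind(ind, flat = rep(0, n))
  expect_error(screen_prognostic_pairs(bad, surv), "constant")
})

test_that("LASSO selection recovers planted pairs and honours penalty limits", {
  set.seed(34)
  n <- 400
  p <- 50
  m <- matrix(rbinom(p * n, 1, 0.5), p, n,
              dimnames = list(paste0("pair", 1:p), paste0("s", 1:n)))
  beta <- c(0.9, -0.9, 0.9, rep(0, p - 3))
  tm <- rexp(n, 0.1 * exp(as.vector(crossprod(m, beta))))
  cn <- runif(n, 0, 25)
  surv <- toy_surv(pmin(tm, cn), as.numeric(tm <= cn), ids = colnames(m))
  sel <- lasso_cox_select(m, surv, seed = 99)
  expect_true(all(c("pair1", "pair2", "pair3") %in% sel))
  # same seed, same folds, same selection
  expect_identical(as.character(lasso_cox_select(m, surv, seed = 99)),
                   as.character(sel))
  # heavy penalty shrinks everything away
  expect_error(lasso_cox_select(m, surv, penalty = 50), "no pair selected")
  # zero penalty reproduces the unpenalized multivariate fit
  small <- m[1:4, 1:120]
  surv_small <- surv[1:120, ]
  sel0 <- lasso_cox_select(small, surv_small, penalty = 0)
  cf0 <- attr(sel0, "coefficients")[rownames(small)]
  fit <- survival::coxph(survival::Surv(surv_small$time, surv_small$event) ~
                           t(small), ties = "breslow")
  expect_equal(unname(cf0), unname(coef(fit)), tolerance = 1e-4)
})

test_that("the final multivariate fit matches an independent maximizer", {
  set.seed(35)
  n <- 150
  m <- matrix(rbinom(3 * n, 1, 0.5), 3, n,
              dimnames = list(c("a|b", "c|d", "e|f"), paste0("s", 1:n)))
  tm <- rexp(n, 0.1 * exp(as.vector(crossprod(m, c(0.6, -0.4, 0.2)))))
  cn <- runif(n, 0, 30)
  surv <- toy_surv(pmin(tm, cn), as.numeric(tm <= cn), ids = colnames(m))
  model <- finalize_model(m, rownames(m), surv, backward_aic = FALSE)
  want <- oracle_cox_fit(t(m)[, model$pairs$pair, drop = FALSE],
                         surv$time, surv$event)
  expect_lt(max(abs(model$pairs$coef - want)), 1e-6)

  # a single selected pair reduces to the univariate fit
  one <- finalize_model(m, "a|b", surv, backward_aic = FALSE)
  uni <- survival::coxph(survival::Surv(surv$time, surv$event) ~ m["a|b", ],
                         ties = "efron")
  expect_equal(one$pairs$coef, unname(coef(uni)), tolerance = 1e-10)

  # exactly collinear reciprocal pairs: one is dropped, fit proceeds
  m2 <- rbind(m, `b|a` = 1 - m["a|b", ])
  expect_message(
    model2 <- finalize_model(m2, rownames(m2), surv, backward_aic = FALSE),
    "collinear")
  expect_lt(nrow(model2$pairs), 4L)
})

test_that("risk scores are the exact linear form over pair indicators", {
  model <- irrs_published_model()
  m <- matrix(0, 6, 3, dimnames = list(model$pairs$pair, c("x", "y", "z")))
  m["MDSC|Monocyte", "y"] <- 1
  m[, "z"] <- 1
  sc <- compute_irrs(model, m)
  expect_identical(sc$irrs[sc$sample_id == "x"], 0)
  expect_identical(sc$irrs[sc$sample_id == "y"], -0.146018787)
  expect_equal(sc$irrs[sc$sample_id == "z"], sum(model$pairs$coef),
               tolerance = 1e-15)
  # missing pair rows name the absent cell types
  expect_error(compute_irrs(model, m[1:4, ]), "MDSC")
})

test_that("scoring concatenated cohorts equals per-cohort scoring", {
  set.seed(36)
  model <- irrs_published_model()
  m1 <- matrix(rbinom(6 * 5, 1, 0.5), 6, 5,
               dimnames = list(model$pairs$pair, paste0("a", 1:5)))
  m2 <- matrix(rbinom(6 * 4, 1, 0.5), 6, 4,
               dimnames = list(model$pairs$pair, paste0("b", 1:4)))
  joint <- compute_irrs(model, cbind(m1, m2))
  expect_identical(joint$irrs[1:5], compute_irrs(model, m1)$irrs)
  expect_identical(joint$irrs[6:9], compute_irrs(model, m2)$irrs)
})

test_that("median stratification uses a strict threshold with ties to low", {
  sc <- tibble::tibble(sample_id = paste0("s", 1:4), irrs = c(1, 2, 3, 4))
  g <- stratify_by_median(sc)
  expect_identical(as.character(g$group), c("low", "low", "high", "high"))
  # odd n: the sample exactly at the median goes low
  g5 <- stratify_by_median(tibble::tibble(sample_id = paste0("s", 1:5),
                                          irrs = c(1, 2, 3, 4, 5)))
  expect_identical(as.character(g5$group[3]), "low")
  # brute-force agreement on random scores
  set.seed(37)
  for (rep in 1:10) {
    x <- rnorm(11)
    g <- stratify_by_median(tibble::tibble(sample_id = as.character(1:11),
                                           irrs = x))
    expect_identical(g$group == "high", x > median(x))
  }
  expect_error(stratify_by_median(tibble::tibble(sample_id = c("a", "b"),
                                                 irrs = c(1, 1))),
               "identical")
})

test_that("model documents round-trip exactly through YAML", {
  model <- irrs_published_model()
  model$training_median <- 0.1234567890123456
  path <- withr::local_tempfile(fileext = ".yaml")
  write_irrs_model(model, path)
  back <- read_irrs_model(path)
  expect_identical(back$pairs$pair, model$pairs$pair)
  expect_identical(back$pairs$coef, model$pairs$coef)
  expect_identical(back$training_median, model$training_median)
  expect_identical(back$ssgsea_params$alpha, model$ssgsea_params$alpha)
})
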