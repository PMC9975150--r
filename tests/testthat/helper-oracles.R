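# Independent brute-force oracles used across the suite. These deliberately
# re-derive each quantity from its definition (loops, enumeration, direct
# optimization) rather than calling the package's vectorized code paths.

# direct running-sum enrichment score for one sample and one set
oracle_es <- function(x, genes, set, alpha = 0.25) {
  n <- length(x)
  ord <- order(-x, genes)
  r <- rank(-x, ties.method = "average")
  w <- (n - r + 1)^alpha
  inset <- genes %in% set
  W <- sum(w[inset])
  m <- sum(inset)
  run <- 0
  es <- 0
  for (k in ord) {
    run <- run + if (inset[k]) w[k] / W else -1 / (n - m)
    es <- es + run
  }
  es
}

# Harrell concordance by explicit double loop
oracle_c_index <- function(x, t, e) {
  num <- den <- 0
  for (i in seq_along(t)) {
    for (j in seq_along(t)) {
      if (i == j) next
      usable <- (t[i] < t[j] && e[i] == 1) ||
        (t[i] == t[j] && e[i] == 1 && e[j] == 0)
      if (!usable) next
      den <- den + 1
      num <- num + if (x[i] > x[j]) 1 else if (x[i] == x[j]) 0.5 else 0
    }
  }
  num / den
}

# negative log partial likelihood with Efron tie correction
oracle_neg_logpl_efron <- function(beta, X, time, event) {
  lp <- as.vector(X %*% beta)
  elp <- exp(lp)
  ll <- 0
  for (tt in sort(unique(time[event == 1]))) {
    D <- which(time == tt & event == 1)
    R <- which(time >= tt)
    d <- length(D)
    sumD <- sum(elp[D])
    sumR <- sum(elp[R])
    ll <- ll + sum(lp[D])
    for (l in seq_len(d) - 1L) {
      ll <- ll - log(sumR - (l / d) * sumD)
    }
  }
  -ll
}

# analytic gradient of the Efron negative log partial likelihood
oracle_grad_efron <- function(beta, X, time, event) {
  lp <- as.vector(X %*% beta)
  elp <- exp(lp)
  g <- rep(0, ncol(X))
  for (tt in sort(unique(time[event == 1]))) {
    D <- which(time == tt & event == 1)
    R <- which(time >= tt)
    d <- length(D)
    sumD <- sum(elp[D])
    sumR <- sum(elp[R])
    xD <- colSums(X[D, , drop = FALSE] * elp[D])
    xR <- colSums(X[R, , drop = FALSE] * elp[R])
    g <- g + colSums(X[D, , drop = FALSE])
    for (l in seq_len(d) - 1L) {
      g <- g - (xR - (l / d) * xD) / (sumR - (l / d) * sumD)
    }
  }
  -g
}

# maximize the Efron partial likelihood directly
oracle_cox_fit <- function(X, time, event, start = NULL) {
  X <- as.matrix(X)
  start <- start %||% rep(0, ncol(X))
  opt <- stats::optim(start, oracle_neg_logpl_efron, gr = oracle_grad_efron,
                      X = X, time = time, event = event, method = "BFGS",
                      control = list(maxit = 2000, reltol = 1e-16))
  opt$par
}

# two-group log-rank chi-square from the (O - E)^2 / V definition
oracle_logrank <- function(time, event, group) {
  g <- as.integer(factor(group)) # 1 or 2
  O1 <- E1 <- V <- 0
  for (tt in sort(unique(time[event == 1]))) {
    at_risk <- time >= tt
    n <- sum(at_risk)
    n1 <- sum(at_risk & g == 1)
    d <- sum(time == tt & event == 1)
    d1 <- sum(time == tt & event == 1 & g == 1)
    O1 <- O1 + d1
    E1 <- E1 + d * n1 / n
    if (n > 1) V <- V + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  (O1 - E1)^2 / V
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# tiny labelled abundance matrix for pair tests
toy_abundance <- function(values, cells = NULL, samples = NULL) {
  k <- nrow(values)
  n <- ncol(values)
  cells <- cells %||% paste0("cell", seq_len(k))
  samples <- samples %||% paste0("s", seq_len(n))
  dimnames(values) <- list(cells, samples)
  values
}

# small right-censored survival tibble
toy_surv <- function(time, event, ids = NULL) {
  tibble::tibble(sample_id = ids %||% paste0("s", seq_along(time)),
                 time = time, event = event)
}
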