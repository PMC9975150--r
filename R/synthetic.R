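#' Generate latent immune-cell abundances
#'
#' Draws per-sample latent cell-type abundances from a log-normal
#' distribution with an exchangeable cross-cell correlation on the log
#' scale. With 28 cell types (the default) the rows carry the standard
#' immune-cell vocabulary.
#'
#' @param n_samples Number of samples (default 458, a typical bulk
#'   melanoma training-cohort size).
#' @param n_cell_types Number of cell types (>= 2, default 28).
#' @param correlation Common pairwise correlation of log-abundances, in
#'   (-1/(k-1), 1).
#' @param meanlog,sdlog Log-normal parameters (defaults 0 and 1).
#' @param seed Integer seed; regeneration is bit-identical.
#' @return Cell types x samples abundance matrix with attribute
#'   `"params"`.
#' @export
generate_abundances <- function(n_samples = 458, n_cell_types = 28,
                                correlation = 0, meanlog = 0, sdlog = 1,
                                seed = 1) {
  if (n_cell_types < 2L) abort("need at least 2 cell types")
  sigma <- matrix(correlation, n_cell_types, n_cell_types)
  diag(sigma) <- 1
  sigma <- sigma * sdlog^2
  ev <- eigen(sigma, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 0) abort("invalid correlation: covariance matrix is not positive definite")
  z <- withr::with_seed(as.integer(seed),
    MASS::mvrnorm(n_samples, mu = rep(meanlog, n_cell_types), Sigma = sigma))
  ab <- t(exp(z))
  rownames(ab) <- if (n_cell_types == 28L) immune_cell_types_28() else
    sprintf("Cell type %02d", seq_len(n_cell_types))
  colnames(ab) <- sprintf("S%04d", seq_len(n_samples))
  attr(ab, "params") <- list(correlation = correlation, meanlog = meanlog,
                             sdlog = sdlog, seed = as.integer(seed))
  ab
}

#' Generate an expression matrix with planted signatures
#'
#' Each cell type gets `genes_per_signature` marker genes whose expression
#' is a positive gain times the cell's latent abundance plus Gaussian
#' noise; background genes are independent log-normal noise. The matching
#' signature gene sets are returned alongside, so rank-based enrichment
#' scoring of the output can be checked against the planted abundances.
#'
#' @param abund Cell types x samples matrix from [generate_abundances()].
#' @param genes_per_signature Marker genes per cell type (default 10).
#' @param n_background_genes Pure-noise genes (default 500).
#' @param noise_sd Gaussian noise SD on marker genes (default 0.5;
#'   abundances have SD ~1 on the log scale, so this is moderate noise).
#' @param seed Integer seed.
#' @return List: `expression` (genes x samples), `gene_sets` (named list,
#'   one set per cell type).
#' @export
generate_expression <- function(abund, genes_per_signature = 10,
                                n_background_genes = 500, noise_sd = 0.5,
                                seed = 1) {
  if (genes_per_signature < 1L) abort("genes_per_signature must be >= 1")
  if (noise_sd < 0) abort("noise_sd must be non-negative")
  k <- nrow(abund); n <- ncol(abund)
  n_sig <- k * genes_per_signature
  withr::with_seed(as.integer(seed), {
    gain <- runif(n_sig, 0.5, 1.5)
    noise <- matrix(rnorm(n_sig * n, sd = noise_sd), n_sig, n)
    bg <- matrix(rlnorm(n_background_genes * n), n_background_genes, n)
  })
  sig_expr <- gain * abund[rep(seq_len(k), each = genes_per_signature), , drop = FALSE] + noise
  gene_ids <- c(sprintf("sig_gene_%04d", seq_len(n_sig)),
                sprintf("bg_gene_%04d", seq_len(n_background_genes)))
  expr <- rbind(sig_expr, bg)
  dimnames(expr) <- list(gene_ids, colnames(abund))
  sets <- split(gene_ids[seq_len(n_sig)], rep(seq_len(k), each = genes_per_signature))
  names(sets) <- rownames(abund)
  list(expression = expr, gene_sets = sets)
}

#' Generate proportional-hazards survival from pair indicators
#'
#' Event times are exponential with rate
#' `baseline_rate * exp(sum(coef * indicator))`; censoring times are
#' uniform on `(0, censor_max)`; the observed time is the minimum and the
#' event flag marks whether the event came first.
#'
#' @param pair_ind Binary true-pairs x samples indicator matrix (may have
#'   0 rows for a null cohort).
#' @param coefs Numeric vector of true log-hazard coefficients, one per
#'   row of `pair_ind`.
#' @param baseline_rate Baseline hazard (> 0), events per time unit
#'   (default 0.1 per year).
#' @param censor_max Upper bound of the uniform censoring distribution
#'   (default 20 years; with the default baseline this yields ~43%
#'   censoring).
#' @param seed Integer seed.
#' @return Survival tibble (`sample_id`, `time`, `event`) with attribute
#'   `"units" = "years"`.
#' @export
generate_survival <- function(pair_ind, coefs, baseline_rate = 0.1,
                              censor_max = 20, seed = 1) {
  if (baseline_rate <= 0) abort("baseline_rate must be positive")
  if (nrow(pair_ind) != length(coefs))
    abort("one coefficient per true pair required")
  if (nrow(pair_ind) == 0L && length(coefs) > 0L)
    abort("nonzero coefficients need a non-empty true pair set")
  n <- ncol(pair_ind)
  lp <- if (nrow(pair_ind) == 0L) rep(0, n) else
    as.numeric(crossprod(pair_ind, coefs))
  withr::with_seed(as.integer(seed), {
    t_event <- rexp(n, rate = baseline_rate * exp(lp))
    t_cens <- runif(n, 0, censor_max)
  })
  out <- tibble(sample_id = colnames(pair_ind),
                time = pmin(t_event, t_cens),
                event = as.numeric(t_event <= t_cens))
  attr(out, "units") <- "years"
  out
}

#' Simulate a full synthetic cohort with planted truth
#'
#' Draws latent cell abundances, plants marker-gene signatures in an
#' expression matrix, picks true prognostic cell pairs on disjoint cell
#' types, and generates proportional-hazards survival from the true pair
#' indicators. The returned truth record allows every pipeline stage to
#' be scored against what was planted.
#'
#' @inheritParams generate_abundances
#' @inheritParams generate_expression
#' @inheritParams generate_survival
#' @param n_true_pairs Number of planted prognostic pairs (default 4;
#'   0 gives a null cohort).
#' @param true_coef Coefficient magnitude of planted pairs, alternating
#'   sign (default 0.5).
#' @param seed Single integer seed; internal stages use derived
#'   substreams so the whole cohort is reproducible bit-for-bit.
#' @return List: `expression`, `gene_sets`, `survival`, and `truth`
#'   (abundance matrix, signature assignment, tibble of true pairs with
#'   coefficients, true pair indicator matrix, seed, parameters).
#' @export
simulate_cohort <- function(n_samples = 458, n_cell_types = 28,
                            correlation = 0, genes_per_signature = 10,
                            n_background_genes = 500, noise_sd = 0.5,
                            n_true_pairs = 4, true_coef = 0.5,
                            baseline_rate = 0.1, censor_max = 20, seed = 1) {
  seed <- as.integer(seed)
  # named substreams derived from the one top-level seed
  sub <- function(k) as.integer((as.double(seed %% 10000019L) * 101 + k) %% 2147483647)
  abund <- generate_abundances(n_samples, n_cell_types, correlation,
                               seed = sub(1L))
  ge <- generate_expression(abund, genes_per_signature, n_background_genes,
                            noise_sd, seed = sub(2L))
  cells <- rownames(abund)
  if (2L * n_true_pairs > length(cells))
    abort("not enough cell types for disjoint true pairs")
  if (n_true_pairs > 0L) {
    picked <- withr::with_seed(sub(3L),
      sample(cells, 2L * n_true_pairs, replace = FALSE))
    a <- picked[seq_len(n_true_pairs)]
    b <- picked[n_true_pairs + seq_len(n_true_pairs)]
    coefs <- true_coef * (-1)^(seq_len(n_true_pairs) - 1L)
    true_pairs <- tibble(pair = pair_name(a, b), a_cell = a, b_cell = b,
                         coef = coefs)
    ind <- build_pair_matrix(abund, true_pairs)
  } else {
    true_pairs <- tibble(pair = character(), a_cell = character(),
                         b_cell = character(), coef = double())
    ind <- matrix(0, 0L, n_samples, dimnames = list(NULL, colnames(abund)))
  }
  survival <- generate_survival(ind, true_pairs$coef, baseline_rate,
                                censor_max, seed = sub(4L))
  list(
    expression = ge$expression,
    gene_sets = ge$gene_sets,
    survival = survival,
    truth = list(abundance = abund, signatures = ge$gene_sets,
                 true_pairs = true_pairs, pair_indicators = ind,
                 baseline_rate = baseline_rate, censor_max = censor_max,
                 noise_sd = noise_sd, seed = seed)
  )
}
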