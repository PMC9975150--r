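new_irrs_model <- function(pairs, training_median, ssgsea_params = list(alpha = 0.25, normalize = "none"),
                           filter_threshold = 0.8, p_cut = 0.05, seed = NA_integer_,
                           elimination_log = NULL) {
  stopifnot(is.data.frame(pairs), all(c("pair", "a_cell", "b_cell", "coef") %in% names(pairs)))
  structure(
    list(
      pairs = as_tibble(pairs),
      training_median = training_median,
      ssgsea_params = ssgsea_params,
      filter_threshold = filter_threshold,
      p_cut = p_cut,
      seed = seed,
      elimination_log = elimination_log,
      version = as.character(utils::packageVersion("irrs"))
    ),
    class = "irrs_model"
  )
}

#' @export
print.irrs_model <- function(x, ...) {
  cat("Immune-related risk score (IRRS) model\n")
  cat(sprintf("  %d cell pair(s); training median %s\n", nrow(x$pairs),
              if (is.na(x$training_median)) "unknown" else format(x$training_median)))
  cat(sprintf("  enrichment: alpha = %g, normalize = %s\n",
              x$ssgsea_params$alpha, x$ssgsea_params$normalize))
  print(x$pairs, n = nrow(x$pairs))
  invisible(x)
}

#' Tidy an IRRS model
#'
#' One row per cell pair in the final model, with the log-hazard
#' coefficient and hazard ratio.
#'
#' @param x An `irrs_model`.
#' @param ... Unused.
#' @return Tibble with columns `pair`, `a_cell`, `b_cell`, `coef` (named
#'   `estimate` alias kept as `coef`), `hazard_ratio`, and, when the model
#'   was fit in-session, `std_error` and `p_value`.
#' @method tidy irrs_model
#' @export
tidy.irrs_model <- function(x, ...) {
  mutate(x$pairs, hazard_ratio = exp(.data$coef))
}

#' @method glance irrs_model
#' @export
glance.irrs_model <- function(x, ...) {
  tibble(n_pairs = nrow(x$pairs),
         training_median = x$training_median,
         alpha = x$ssgsea_params$alpha,
         normalize = x$ssgsea_params$normalize,
         filter_threshold = x$filter_threshold,
         p_cut = x$p_cut,
         seed = x$seed)
}

#' Serialize an IRRS model to a YAML document
#'
#' Human-readable key-value document holding the pairs, coefficients,
#' training median, enrichment parameters and provenance fields. Numeric
#' fields are written with 17 significant digits so the document
#' round-trips doubles exactly and refitting with the same seed yields a
#' bit-identical file.
#'
#' @param model An `irrs_model`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_irrs_model <- function(model, path) {
  doc <- list(
    format = "irrs_model",
    version = model$version,
    pairs = model$pairs$pair,
    coefficients = model$pairs$coef,
    training_median = if (is.na(model$training_median)) "NA" else model$training_median,
    ssgsea = model$ssgsea_params,
    filter_threshold = model$filter_threshold,
    p_cut = model$p_cut,
    seed = if (is.na(model$seed)) "NA" else model$seed
  )
  writeLines(yaml::as.yaml(doc, precision = 17L), path)
  invisible(path)
}

#' Read an IRRS model document
#'
#' @param path Path to a YAML document written by [write_irrs_model()].
#' @return An `irrs_model`.
#' @export
read_irrs_model <- function(path) {
  doc <- yaml::yaml.load_file(path)
  if (!identical(doc$format, "irrs_model"))
    abort(sprintf("%s is not an IRRS model document", path))
  sp <- split_pair(doc$pairs)
  pairs <- tibble(pair = doc$pairs, a_cell = sp$a, b_cell = sp$b,
                  coef = as.numeric(doc$coefficients))
  tm <- doc$training_median
  tm <- if (identical(tm, "NA") || is.null(tm)) NA_real_ else as.numeric(tm)
  sd <- doc$seed
  sd <- if (identical(sd, "NA") || is.null(sd)) NA_integer_ else as.integer(sd)
  m <- new_irrs_model(pairs, tm, doc$ssgsea, doc$filter_threshold, doc$p_cut, sd)
  m$version <- doc$version
  m
}

#' The published six-pair melanoma IRRS model
#'
#' Loads the final six immune-cell-pair model with its multivariate Cox
#' coefficients as published for the TCGA cutaneous-melanoma training
#' cohort. The training median risk score was not published and is stored
#' as `NA`; stratifying a new cohort therefore uses that cohort's own
#' median, matching how the model was validated on external series.
#'
#' @return An `irrs_model` with six pairs.
#' @export
#' @examples
#' tidy(irrs_published_model())
irrs_published_model <- function() {
  read_irrs_model(system.file("extdata", "published_irrs_model.yaml",
                              package = "irrs", mustWork = TRUE))
}
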