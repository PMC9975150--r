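#' Within-sample descending ranks
#'
#' Ranks genes within each sample, rank 1 for the highest expression, ties
#' receiving the average rank. The ranks are what the enrichment statistic
#' consumes, making every downstream score invariant to strictly increasing
#' transforms of each sample's expression vector.
#'
#' @param expr Genes x samples numeric matrix.
#' @return Matrix of the same shape holding descending ranks.
#' @export
rank_transform <- function(expr) {
  validate_expression(expr)
  out <- apply(expr, 2L, function(x) rank(-x, ties.method = "average"))
  dimnames(out) <- dimnames(expr)
  cst <- apply(expr, 2L, function(x) all(x == x[1L]))
  if (any(cst)) {
    warn(sprintf("constant expression in sample(s): %s (all ranks tied)",
                 paste(colnames(expr)[cst], collapse = ", ")))
  }
  out
}

#' Single-sample gene set enrichment scores
#'
#' Computes one enrichment score per gene set and sample — used here as a
#' surrogate for the within-tumor abundance of each immune cell type. For
#' sample `j` with `N` genes and a set `G` (after intersecting with the
#' gene universe), genes are walked in descending expression order; an
#' in-set gene increments a running sum by its rank weight
#' `(N - r + 1)^alpha` normalized by the sum of in-set rank weights, an
#' out-of-set gene decrements it by `1/(N - |G|)`. The score is the sum of
#' the running sum over all steps (an integrated difference between the
#' weighted in-set and uniform out-of-set cumulative distributions). Ties
#' in expression are ordered by gene id so scores do not depend on row or
#' set order.
#'
#' @param expr Genes x samples numeric matrix.
#' @param sets Named list of character vectors (gene ids), e.g. from
#'   [read_gmt()].
#' @param alpha Non-negative rank weighting exponent (default 0.25).
#' @param normalize `"none"` (default) or `"minmax"` — rescale the whole
#'   score matrix to `[0, 1]` by its range. Within-sample comparisons,
#'   which are all the pair algorithm uses, are unaffected.
#' @return Numeric matrix, sets (cell types) x samples.
#' @export
#' @examples
#' expr <- matrix(rnorm(40), 10, 4,
#'                dimnames = list(paste0("g", 1:10), paste0("s", 1:4)))
#' sets <- list(up = c("g1", "g2", "g3"), down = c("g8", "g9"))
#' ssgsea_scores(expr, sets)
ssgsea_scores <- function(expr, sets, alpha = 0.25,
                          normalize = c("none", "minmax")) {
  normalize <- match.arg(normalize)
  validate_expression(expr)
  if (!is.numeric(alpha) || length(alpha) != 1L || alpha < 0)
    abort("alpha must be a single non-negative number")
  if (is.null(names(sets)) || anyDuplicated(names(sets)))
    abort("gene sets must be uniquely named")
  genes <- rownames(expr)
  n <- length(genes)
  members <- lapply(sets, function(g) {
    m <- genes %in% g
    m
  })
  sizes <- vapply(members, sum, 0L)
  if (any(sizes == 0L))
    abort(sprintf("gene set(s) with empty intersection with the expression matrix: %s",
                  paste(names(sets)[sizes == 0L], collapse = ", ")))
  if (any(sizes == n))
    abort(sprintf("gene set(s) covering the whole gene universe: %s",
                  paste(names(sets)[sizes == n], collapse = ", ")))
  memb <- do.call(rbind, members)            # sets x genes logical
  scores <- matrix(NA_real_, nrow = length(sets), ncol = ncol(expr),
                   dimnames = list(names(sets), colnames(expr)))
  for (j in seq_len(ncol(expr))) {
    x <- expr[, j]
    ord <- order(-x, genes)                  # ties broken by gene id
    r <- rank(-x, ties.method = "average")
    w <- (n - r + 1)^alpha                   # rank weight per gene
    w_ord <- w[ord]
    memb_ord <- memb[, ord, drop = FALSE]
    # ES = sum over steps of the running sum; a step at position k
    # contributes to the (n - k + 1) subsequent cumulative sums
    tailcount <- n - seq_len(n) + 1
    in_w <- memb_ord * rep(w_ord, each = nrow(memb_ord))
    in_norm <- in_w / rowSums(in_w)
    dec <- (!memb_ord) / (n - sizes)
    scores[, j] <- as.vector((in_norm - dec) %*% tailcount)
  }
  if (normalize == "minmax") {
    rng <- range(scores)
    if (rng[2] > rng[1]) scores <- (scores - rng[1]) / (rng[2] - rng[1])
  }
  attr(scores, "params") <- list(alpha = alpha, normalize = normalize)
  scores
}
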