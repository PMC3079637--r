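#' Quantile-based rank-one matrix approximation (QMA)
#'
#' Estimates single-mutant fitness vectors `x` (queries, rows) and `y`
#' (arrays, columns) from a double-mutant fitness matrix `W` under the
#' multiplicative model `W ~ x %o% y`. The procedure is a multiplicative
#' analogue of Tukey's median polish with quantiles in place of medians:
#' `x` is initialized as the row `p`-quantiles of `W`, then the column
#' `q`-quantiles of the ratios `w[a,b] / x[a]` give `y`, and further sweeps
#' alternate row `p`-quantiles of `w[a,b] / y[b]` and column `q`-quantiles of
#' `w[a,b] / x[a]` until the estimates stabilize.
#'
#' The decomposition is identifiable only up to a scale exchanged between
#' `x` and `y`. The gauge used here anchors `x` in the fitness units of `W`
#' through its initialization from raw row quantiles; `y`, computed from
#' ratios, then also lands on the fitness scale for screens normalized to a
#' median near 1. No post-hoc rescaling is applied.
#'
#' Quantiles use linear interpolation between order statistics
#' (`stats::quantile()` type 7) over present values only. Entries of `x` or
#' `y` below a small positivity floor are excluded from ratio denominators
#' so lethal strains cannot cause divisions by zero; a strain whose estimate
#' collapses entirely below the floor is pinned at the floor. Rows or
#' columns with fewer than `min_obs` usable observations get an undefined
#' (`NA`) estimate.
#'
#' @param fm A `fitness_matrix`.
#' @param p Row (query) quantile level in `[0, 1]`; default 0.5 (median).
#' @param q Column (array) quantile level in `[0, 1]`; default 0.5.
#' @param max_iter Maximum number of sweeps; the first sweep is the
#'   initialization of `x` from raw row quantiles followed by the ratio
#'   update of `y`, so `max_iter = 1` reproduces the plain two-pass
#'   row-then-column quantile estimate.
#' @param tol Convergence tolerance on the maximum relative change of the
#'   concatenated `(x, y)` between sweeps.
#' @param min_obs Minimum number of usable observations for an estimate to
#'   be defined; default 5.
#'
#' @return An object of class `qma_fit` with elements `x`, `y` (named
#'   numeric vectors), `p`, `q`, `iterations_run`, `converged`, and the call
#'   parameters.
#' @examples
#' W <- outer(c(1, 0.5, 0.9), c(1, 0.8, 0.6))
#' fit <- qma_estimate(fitness_matrix(W), min_obs = 1)
#' max(abs(W - outer(fit$x, fit$y))) # 0: rank-one matrices are fixed points
#' @export
qma_estimate <- function(fm, p = 0.5, q = 0.5, max_iter = 20, tol = 1e-6,
                         min_obs = 5) {
  if (!is.numeric(p) || length(p) != 1 || is.na(p) || p < 0 || p > 1) {
    stop("p must be a quantile level in [0, 1]", call. = FALSE)
  }
  if (!is.numeric(q) || length(q) != 1 || is.na(q) || q < 0 || q > 1) {
    stop("q must be a quantile level in [0, 1]", call. = FALSE)
  }
  if (max_iter < 1) stop("max_iter must be >= 1", call. = FALSE)
  if (min_obs < 1) stop("min_obs must be >= 1", call. = FALSE)
  W <- unclass(fm)
  if (all(is.na(W))) {
    stop("cannot estimate single-mutant effects from an all-missing matrix",
      call. = FALSE
    )
  }
  floor_pos <- 1e-8

  x <- row_quantiles(W, p, min_obs)
  x <- apply_floor(x, floor_pos)
  y <- rep(NA_real_, ncol(W))
  iterations <- 0L
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    x_old <- x
    y_old <- y
    if (it > 1) {
      x <- ratio_quantiles(W, y, p, min_obs, floor_pos, margin = 1L)
      x <- apply_floor(x, floor_pos)
    }
    y <- ratio_quantiles(W, x, q, min_obs, floor_pos, margin = 2L)
    y <- apply_floor(y, floor_pos)
    iterations <- it
    if (it > 1 && rel_change(c(x_old, y_old), c(x, y), floor_pos) < tol) {
      converged <- TRUE
      break
    }
  }
  names(x) <- rownames(W)
  names(y) <- colnames(W)
  structure(
    list(
      x = x, y = y, p = p, q = q, iterations_run = iterations,
      converged = converged, max_iter = max_iter, tol = tol,
      min_obs = min_obs, m = nrow(W), n = ncol(W)
    ),
    class = "qma_fit"
  )
}

row_quantiles <- function(W, p, min_obs) {
  apply(W, 1L, function(r) {
    r <- r[!is.na(r)]
    if (length(r) < min_obs) NA_real_ else unname(stats::quantile(r, p, type = 7, names = FALSE))
  })
}

# quantile of ratios W / other along `margin`, skipping denominators at or
# below the positivity floor
ratio_quantiles <- function(W, other, level, min_obs, floor_pos, margin) {
  usable <- !is.na(other) & other > floor_pos
  if (margin == 1L) {
    R <- sweep(W[, usable, drop = FALSE], 2L, other[usable], `/`)
    apply(R, 1L, function(r) {
      r <- r[!is.na(r)]
      if (length(r) < min_obs) NA_real_ else unname(stats::quantile(r, level, type = 7, names = FALSE))
    })
  } else {
    R <- W[usable, , drop = FALSE] / other[usable]
    apply(R, 2L, function(cl) {
      cl <- cl[!is.na(cl)]
      if (length(cl) < min_obs) NA_real_ else unname(stats::quantile(cl, level, type = 7, names = FALSE))
    })
  }
}

apply_floor <- function(v, floor_pos) {
  v[!is.na(v) & v < floor_pos] <- floor_pos
  v
}

rel_change <- function(old, new, floor_pos) {
  ok <- !is.na(old) & !is.na(new)
  if (!any(ok)) {
    return(0)
  }
  max(abs(new[ok] - old[ok]) / pmax(abs(old[ok]), floor_pos))
}

#' @export
print.qma_fit <- function(x, ...) {
  cat(sprintf(
    "<qma_fit> %d x %d screen; p = %g, q = %g; %d sweep(s)%s\n",
    x$m, x$n, x$p, x$q, x$iterations_run,
    if (x$converged) " (converged)" else ""
  ))
  cat(sprintf(
    "  x: %d defined, median %.4g | y: %d defined, median %.4g\n",
    sum(!is.na(x$x)), stats::median(x$x, na.rm = TRUE),
    sum(!is.na(x$y)), stats::median(x$y, na.rm = TRUE)
  ))
  invisible(x)
}

#' Expected neutral double-mutant fitness under a null model
#'
#' Evaluates the chosen null scoring function `s(x[a], y[b])` for every pair,
#' giving the fitness expected if the two mutations act independently.
#' The product null `x[a] * y[b]` is the classical multiplicative model for
#' fitness; `minimum` and `maximum` are the masking-style alternatives. The
#' `scaled_epistasis_base` expectation equals the product (the scaling only
#' affects the residual normalization in [score_interactions()]).
#'
#' @param est A `qma_fit`.
#' @param null_fn One of `"product"`, `"minimum"`, `"maximum"`,
#'   `"scaled_epistasis_base"`.
#' @return An `m x n` numeric matrix; `NA` where either estimate is
#'   undefined.
#' @export
expected_fitness <- function(est, null_fn = "product") {
  null_fn <- match.arg(null_fn, c("product", "minimum", "maximum", "scaled_epistasis_base"))
  x <- est$x
  y <- est$y
  E <- switch(null_fn,
    product = outer(x, y),
    scaled_epistasis_base = outer(x, y),
    minimum = outer(x, y, pmin),
    maximum = outer(x, y, pmax)
  )
  E[is.na(x), ] <- NA_real_
  E[, is.na(y)] <- NA_real_
  E
}
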