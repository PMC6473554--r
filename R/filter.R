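#' Prior and discount settings for the per-node dynamic linear model
#'
#' Each node's regression on its parents is a conjugate normal-gamma DLM:
#' coefficients are a priori `N(m0, c0_scale * I)` given the observation
#' variance, and the observation precision is `Gamma(n0/2, d0/2)`. State
#' evolution is governed by a discount factor `delta` in (0, 1]: the prior
#' covariance is inflated to `C_{t-1} / delta` each step, so `delta = 1`
#' is the static-coefficient model. When scoring, the local score is the
#' maximum over `delta_grid`, chosen per (subject, node, parent set).
#'
#' Defaults are weakly informative for standardized (unit-scale) series.
#'
#' @param c0_scale Prior coefficient variance scale (`C0 = c0_scale * I`).
#' @param n0,d0 Prior precision degrees of freedom and rate sum; the prior
#'   point estimate of the observation variance is `d0 / n0`.
#' @param delta_grid Candidate discount factors, each in (0, 1].
#' @param burn_in Number of initial one-step forecasts excluded from the
#'   score (must be identical across all models being compared).
#' @return An object of class `mdm_prior`.
#' @export
mdm_prior <- function(c0_scale = 3, n0 = 0.001, d0 = 0.001,
                      delta_grid = c(0.80, 0.85, 0.90, 0.95, 0.99, 1.00),
                      burn_in = 0) {
  stopifnot(
    c0_scale > 0, n0 > 0, d0 > 0,
    all(delta_grid > 0), all(delta_grid <= 1), length(delta_grid) >= 1,
    burn_in >= 0
  )
  structure(
    list(c0_scale = c0_scale, n0 = n0, d0 = d0,
         delta_grid = as.numeric(delta_grid), burn_in = as.integer(burn_in)),
    class = "mdm_prior"
  )
}

#' @export
print.mdm_prior <- function(x, ...) {
  cat("<mdm_prior> C0 = ", x$c0_scale, " I, n0 = ", x$n0, ", d0 = ", x$d0,
      ", delta grid {", paste(x$delta_grid, collapse = ", "), "}",
      if (x$burn_in > 0) paste0(", burn-in ", x$burn_in), "\n", sep = "")
  invisible(x)
}

#' Build the regression matrix for one node given its parents
#'
#' Column 1 is the constant intercept; the remaining columns are the
#' parent series at the same time point (contemporaneous, not lagged), in
#' the order given.
#'
#' @param y Numeric `T x n` matrix of observations.
#' @param r Child node index.
#' @param parents Integer vector of parent node indices (possibly empty).
#' @return A `T x (1 + length(parents))` matrix.
#' @export
build_regressors <- function(y, r, parents = integer(0)) {
  y <- as.matrix(y)
  parents <- as.integer(parents)
  if (r %in% parents) stop("node ", r, " cannot be its own parent")
  cbind(1, y[, parents, drop = FALSE])
}

#' Kalman-filter one node model and return its forecast decomposition
#'
#' Runs the conjugate filtering recurrences for a single node regression
#' and returns the filtered moments, the precision counts, and the
#' one-step-ahead Student-t log forecast densities whose sum is the node's
#' local log predictive likelihood.
#'
#' @param y Numeric response vector (length `T`).
#' @param F Regression matrix `T x p` from [build_regressors()].
#' @param prior An [mdm_prior()].
#' @param delta Discount factor; defaults to the last entry of the prior's
#'   grid (1 unless reconfigured).
#' @return A list of class `mdm_filter` with elements `m`, `C`, `a`, `R`
#'   (filtered/prior moments), `f`, `q` (forecast mean/variance), `n`,
#'   `d`, `S` (precision bookkeeping), `logf` (per-time log densities) and
#'   `total`.
#' @export
filter_node <- function(y, F, prior = mdm_prior(), delta = NULL) {
  y <- as.numeric(y)
  F <- as.matrix(F)
  stopifnot(length(y) == nrow(F))
  if (anyNA(y) || any(!is.finite(y)) || anyNA(F) || any(!is.finite(F))) {
    stop("non-finite values in filter input")
  }
  if (is.null(delta)) delta <- prior$delta_grid[length(prior$delta_grid)]
  stopifnot(delta > 0, delta <= 1)
  p <- ncol(F)
  out <- dlm_filter_cpp(y, F, rep(0, p), diag(prior$c0_scale, p),
                        prior$n0, prior$d0, delta)
  for (nm in c("f", "q", "n", "d", "S", "logf")) {
    out[[nm]] <- as.numeric(out[[nm]])
  }
  out$delta <- delta
  out$T_len <- length(y)
  if (prior$burn_in > 0) {
    keep <- seq_along(y) > prior$burn_in
    out$total <- sum(out$logf[keep])
  }
  structure(out, class = "mdm_filter")
}

#' Backward-smooth a filtered node model
#'
#' Backward recursions on the filter output give the retrospective
#' (smoothed) coefficient distribution at every time point, with the
#' variance rescaled to the final precision estimate. With `delta = 1`
#' every smoothed mean equals the final filtered mean.
#'
#' @param filter An `mdm_filter` from [filter_node()].
#' @return A list of class `mdm_smooth` with `theta` (`p x T` smoothed
#'   means), `V` (`p x p x T` smoothed covariances), and time-averaged
#'   summaries `theta_bar`, `sigma2_bar` (per-coefficient means of the
#'   smoothed locations and variances).
#' @export
smooth_node <- function(filter) {
  if (!inherits(filter, "mdm_filter")) stop("expected an 'mdm_filter'")
  T_len <- filter$T_len
  p <- nrow(filter$m)
  theta <- matrix(0, p, T_len)
  V <- array(0, c(p, p, T_len))
  S_T <- filter$S[T_len]
  theta[, T_len] <- filter$m[, T_len]
  V[, , T_len] <- matrix(filter$C[, , T_len], p, p)
  Rt <- matrix(filter$C[, , T_len], p, p)
  if (T_len >= 2) {
    for (t in (T_len - 1):1) {
      Ct <- matrix(filter$C[, , t], p, p)
      Rnext <- matrix(filter$R[, , t + 1], p, p)
      B <- Ct %*% solve(Rnext)
      theta[, t] <- filter$m[, t] +
        B %*% (theta[, t + 1] - filter$a[, t + 1])
      Rt <- Ct + B %*% (Rt - Rnext) %*% t(B)
      V[, , t] <- (S_T / filter$S[t]) * Rt
    }
  }
  structure(
    list(theta = theta, V = V,
         theta_bar = rowMeans(theta),
         sigma2_bar = rowMeans(matrix(vapply(seq_len(T_len),
                                             function(t) {
                                               diag(matrix(V[, , t], p, p))
                                             }, numeric(p)),
                                      nrow = p))),
    class = "mdm_smooth"
  )
}

#' Local log predictive likelihood of one node under a given parent set
#'
#' The local score `c(r, Pa)` is the sum over time of one-step-ahead log
#' forecast densities of node `r` regressed on the contemporaneous parent
#' series, maximized over the prior's discount grid. The total score of a
#' network is the sum of its nodes' local scores, and a log Bayes factor
#' between two networks is the difference of their totals.
#'
#' @param y Numeric `T x n` matrix of (standardized) observations.
#' @param r Child node index.
#' @param parents Integer vector of parent indices.
#' @param prior An [mdm_prior()].
#' @return The scalar local score.
#' @export
local_score <- function(y, r, parents = integer(0), prior = mdm_prior()) {
  y <- as.matrix(y)
  if (r %in% parents) stop("node ", r, " cannot be its own parent")
  sc <- score_sets_cpp(y, as.integer(r), nodes_to_mask(parents),
                       prior$delta_grid, prior$c0_scale, prior$n0, prior$d0)
  if (prior$burn_in > 0) {
    return(local_score_burnin(y, r, parents, prior))
  }
  max(sc)
}

# Burn-in requires per-time densities, so go through filter_node.
local_score_burnin <- function(y, r, parents, prior) {
  F <- build_regressors(y, r, parents)
  max(vapply(prior$delta_grid, function(d) {
    filter_node(y[, r], F, prior, delta = d)$total
  }, numeric(1)))
}

#' @export
print.mdm_filter <- function(x, ...) {
  cat("<mdm_filter> T = ", x$T_len, ", p = ", nrow(x$m),
      ", delta = ", x$delta, ", LPL = ", format(x$total), "\n", sep = "")
  invisible(x)
}

#' @describeIn filter_node Tidy per-time forecast summary of a filter fit.
#' @param x An `mdm_filter`.
#' @param ... Unused.
#' @export
tidy.mdm_filter <- function(x, ...) {
  tibble::tibble(
    t = seq_len(x$T_len),
    forecast = as.numeric(x$f),
    forecast_var = as.numeric(x$q),
    log_density = as.numeric(x$logf),
    df = as.numeric(x$n) - 1
  )
}

#' @describeIn filter_node One-row fit summary.
#' @export
glance.mdm_filter <- function(x, ...) {
  tibble::tibble(
    T_len = x$T_len, p = nrow(x$m), delta = x$delta,
    lpl = x$total, s2_final = x$S[x$T_len]
  )
}
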