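## Predicted cumulative distributions.
##
## The CDF of the basic model is obtained by solving the backward PDE
## dF/dt = 1/2 F_zz + v F_z on the starting-point corridor with a
## Crank-Nicolson finite-difference scheme; one solve yields the upper-
## threshold CDF for every starting point simultaneously, which makes the
## uniform starting-point integration nearly free. Drift variability is
## averaged with Gauss-Hermite nodes, non-decision-time variability by a
## midpoint rule on the time axis.

#' Finite-difference solution of the CDF PDE
#'
#' Solves the backward PDE for the probability `F(t, z)` that the process
#' started at `z` has been absorbed at the upper threshold by decision time
#' `t`, with boundary conditions `F(t, 0) = 0`, `F(t, a) = 1` and the
#' discontinuous initial condition (`0` below `a`, `1` at `a`). The scheme is
#' Crank-Nicolson in time with centered second-order space differences and
#' two damped (fully implicit) startup steps.
#'
#' @param params A [dm_params()] object; only `v` and `a` are used (basic
#'   model).
#' @param t_max Upper end of the time grid (s).
#' @param precision Precision parameter controlling step sizes.
#' @param strict If `TRUE` (default) an error is thrown when the residual
#'   probability mass not yet absorbed at `t_max` (at `z = zr * a`) exceeds
#'   `10^-precision`.
#' @return A list with `t` (time grid), `z` (space grid), `F` (matrix, times
#'   in rows, starting points in columns) and `residual` (unabsorbed mass at
#'   `t_max` for starting point `zr * a`).
#' @export
solve_pde_cdf <- function(params, t_max, precision = 3, strict = TRUE) {
  ps <- dm_precision(precision, a = params$a, v = params$v)
  nt <- max(2L, as.integer(ceiling(t_max / ps$dt)))
  Fup <- cdf_pde_grid(params$v, params$a, ps$nz, ps$dt, nt)
  Flo <- cdf_pde_grid(-params$v, params$a, ps$nz, ps$dt, nt)
  z <- seq(0, params$a, length.out = ps$nz + 1)
  tg <- seq(0, by = ps$dt, length.out = nt + 1)
  up_end <- grid_interp_col(Fup, z, params$zr * params$a)[nt + 1]
  lo_end <- grid_interp_col(Flo, z, (1 - params$zr) * params$a)[nt + 1]
  residual <- 1 - up_end - lo_end
  if (strict && residual > 10^(-precision)) {
    stop(sprintf(paste0("PDE solution has not absorbed enough mass by t_max = %g: ",
                        "residual %.3g exceeds 10^-%g"), t_max, residual, precision),
         call. = FALSE)
  }
  list(t = tg, z = z, F = Fup, residual = residual)
}

# linear interpolation of a (t x z) grid at one z value -> vector over t
grid_interp_col <- function(F, z, z0) {
  nz <- length(z) - 1L
  h <- z[2] - z[1]
  j <- min(max(floor(z0 / h), 0), nz - 1)
  frac <- z0 / h - j
  F[, j + 1] * (1 - frac) + F[, j + 2] * frac
}

# Gauss-Hermite nodes/weights via the Golub-Welsch eigen decomposition
gauss_hermite <- function(n) {
  if (n == 1) return(list(x = 0, w = sqrt(pi)))
  k <- seq_len(n - 1)
  J <- matrix(0, n, n)
  J[cbind(k, k + 1)] <- sqrt(k / 2)
  J <- J + t(J)
  e <- eigen(J, symmetric = TRUE)
  ord <- order(e$values)
  list(x = e$values[ord], w = (e$vectors[1, ]^2 * sqrt(pi))[ord])
}

# default horizon for the decision-time grid: slowest decay mode plus slack
t_max_guess <- function(params, precision) {
  lambda <- (0 + pi^2 / params$a^2) / 2  # conservative: zero-drift decay
  max(0.5, (precision * log(10) + 1.5) / lambda)
}

# Core engine: decision-time CDF curves at both thresholds, averaged over
# drift (Gauss-Hermite) and starting-point (z-grid window) variability.
# Returns joint cumulative curves: up(t) = P(upper response AND T <= t).
predicted_curves <- function(params, precision = 3, t_max = NULL,
                             strict = FALSE) {
  ps <- dm_precision(precision, a = params$a, v = abs(params$v) + 3 * params$sv)
  a <- params$a
  z0 <- params$zr * a
  sz <- params$szr * a
  if (params$sv > 0) {
    gh <- gauss_hermite(ps$n_hermite)
    vs <- params$v + sqrt(2) * params$sv * gh$x
    ws <- gh$w / sqrt(pi)
  } else {
    vs <- params$v; ws <- 1
  }
  if (is.null(t_max)) t_max <- t_max_guess(params, precision)

  for (attempt in 1:7) {
    nt <- max(2L, as.integer(ceiling(t_max / ps$dt)))
    tg <- seq(0, by = ps$dt, length.out = nt + 1)
    up <- low <- numeric(nt + 1)
    for (i in seq_along(vs)) {
      Fup <- cdf_pde_grid(vs[i], a, ps$nz, ps$dt, nt)
      Flo <- if (abs(vs[i]) < 1e-14) Fup else cdf_pde_grid(-vs[i], a, ps$nz, ps$dt, nt)
      zg <- seq(0, a, length.out = ps$nz + 1)
      if (sz > 0) {
        zn <- z0 + sz * ((seq_len(ps$n_int) - 0.5) / ps$n_int - 0.5)
        cu <- Reduce(`+`, lapply(zn, function(zz) grid_interp_col(Fup, zg, zz))) / length(zn)
        cl <- Reduce(`+`, lapply(zn, function(zz) grid_interp_col(Flo, zg, a - zz))) / length(zn)
      } else {
        cu <- grid_interp_col(Fup, zg, z0)
        cl <- grid_interp_col(Flo, zg, a - z0)
      }
      up <- up + ws[i] * cu
      low <- low + ws[i] * cl
    }
    residual <- 1 - up[nt + 1] - low[nt + 1]
    if (residual <= 10^(-precision) || attempt == 7) break
    t_max <- t_max * 2
  }
  if (strict && residual > 10^(-precision)) {
    stop(sprintf("CDF engine: unabsorbed mass %.3g at t_max = %g exceeds 10^-%g",
                 residual, t_max, precision), call. = FALSE)
  }
  list(t = tg, up = up, low = low,
       p_up = up[nt + 1], p_low = low[nt + 1], residual = residual)
}

# cumulative value of one threshold's joint decision-time curve at times td
curve_at <- function(tg, curve, td) {
  end <- curve[length(curve)]
  y <- stats::approx(tg, curve, xout = td, yleft = 0, yright = end)$y
  y[td <= 0] <- 0
  y
}

#' Full-model cumulative probability at a response time
#'
#' Joint probability `P(response at threshold AND RT <= t_rt)` under the
#' complete model: the PDE solution, averaged over drift and starting-point
#' variability, is shifted by the per-threshold non-decision time and averaged
#' over the uniform non-decision window (midpoint rule, minimum 4 steps).
#' With all variabilities zero this reduces to the basic-model CDF.
#'
#' @param t_rt Response time(s) in seconds.
#' @param params A [dm_params()] object.
#' @param threshold `"upper"` or `"lower"`.
#' @param precision Precision parameter.
#' @return Cumulative probability value(s), vectorized over `t_rt`.
#' @export
cdf_full <- function(t_rt, params, threshold = c("upper", "lower"),
                     precision = 3) {
  threshold <- match.arg(threshold)
  dist <- combined_cdf(params, precision)
  threshold_cdf(dist, t_rt, threshold)
}

# evaluate one threshold's joint RT-CDF from a dm_dist object
threshold_cdf <- function(dist, t_rt, threshold) {
  t0_thr <- unname(split_t0(dist$params$t0, dist$params$d)[threshold])
  curve <- if (threshold == "upper") dist$up else dist$low
  offs <- dist$t0_offsets
  acc <- 0
  for (o in offs) acc <- acc + curve_at(dist$t, curve, t_rt - t0_thr - o)
  acc / length(offs)
}

#' Predicted combined CDF over signed response times
#'
#' Merges the two response distributions into a single cumulative function
#' over signed time: response times of lower-threshold responses carry a
#' negative sign. For `tau < 0` the value is `P(lower response AND RT > -tau)`
#' accumulated downward; for `tau > 0` it is
#' `P(lower) + P(upper response AND RT <= tau)`. The function is nondecreasing
#' on the whole signed axis, tends to 0 and 1 in the tails, and equals the
#' total lower-response probability at 0.
#'
#' @param params A [dm_params()] object.
#' @param precision Precision parameter.
#' @param t_max Optional fixed decision-time horizon (s); found automatically
#'   by doubling when omitted.
#' @return An object of class `dm_dist`; see [as_tibble.dm_dist()],
#'   [predicted_cdf()] and [autoplot.dm_dist()].
#' @export
combined_cdf <- function(params, precision = 3, t_max = NULL) {
  chk <- validate_parameters(params)
  if (!chk$valid) {
    stop("invalid parameter set: ", paste(chk$violations, collapse = ", "),
         call. = FALSE)
  }
  cur <- predicted_curves(params, precision, t_max)
  ps <- dm_precision(precision, a = params$a, v = params$v)
  offs <- if (params$st0 > 0) {
    params$st0 * ((seq_len(ps$n_int) - 0.5) / ps$n_int - 0.5)
  } else 0
  structure(c(cur, list(params = params, precision = precision,
                        t0_offsets = offs)),
            class = "dm_dist")
}

#' Evaluate the predicted combined CDF at signed times
#'
#' @param dist A `dm_dist` object from [combined_cdf()].
#' @param tau Signed response time(s): negative values denote lower-threshold
#'   responses.
#' @return Cumulative probability value(s).
#' @export
predicted_cdf <- function(dist, tau) {
  stopifnot(inherits(dist, "dm_dist"))
  out <- numeric(length(tau))
  neg <- tau < 0
  if (any(neg)) {
    out[neg] <- dist$p_low - threshold_cdf(dist, -tau[neg], "lower")
  }
  if (any(!neg)) {
    out[!neg] <- dist$p_low + threshold_cdf(dist, tau[!neg], "upper")
  }
  pmin(pmax(out, 0), 1)
}

#' Tabulate a predicted combined CDF
#'
#' @param x A `dm_dist` object.
#' @param ... Unused.
#' @param t_step Spacing of the signed time grid (s); default 0.001.
#' @return A tibble with columns `time` (signed RT, seconds) and `cdf`.
#' @export
as_tibble.dm_dist <- function(x, ..., t_step = 1e-3) {
  t0s <- split_t0(x$params$t0, x$params$d)
  half <- x$params$st0 / 2
  tmax_rt_up <- max(x$t) + t0s["upper"] + half
  tmax_rt_lo <- max(x$t) + t0s["lower"] + half
  tau <- c(-rev(seq(0, tmax_rt_lo, by = t_step)), seq(t_step, tmax_rt_up, by = t_step))
  tibble::tibble(time = tau, cdf = predicted_cdf(x, tau))
}

#' @export
print.dm_dist <- function(x, ...) {
  cat("<dm_dist> predicted combined CDF\n")
  cat("  P(upper) =", format(x$p_up), " P(lower) =", format(x$p_low),
      " residual =", format(x$residual), "\n")
  cat("  decision-time grid: [0,", format(max(x$t)), "] s,",
      length(x$t), "points\n")
  invisible(x)
}
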