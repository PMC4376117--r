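#' Diffusion model parameter set
#'
#' Bundles the eight parameters of the full Wiener diffusion model together
#' with the diffusion constant `s`. Times are in seconds; `a` and `v` are in
#' evidence units defined by the scale `s`; `zr` and `szr` are dimensionless
#' fractions of `a`.
#'
#' @param v Drift rate: mean speed of evidence accumulation (evidence/s).
#' @param a Threshold separation (> 0): distance between the two absorbing
#'   boundaries; indexes response caution.
#' @param zr Relative starting point in (0, 1); the absolute start is
#'   `z = zr * a`. `zr = 0.5` means no decision bias.
#' @param t0 Mean non-decision time (s, >= 0): encoding plus motor time added
#'   to the decision time.
#' @param d Difference in non-decision time between the responses at the lower
#'   and upper threshold (s); see [split_t0()].
#' @param sv Inter-trial standard deviation of drift (normal distribution).
#' @param szr Inter-trial range of the relative starting point (uniform);
#'   the absolute range is `sz = szr * a`.
#' @param st0 Inter-trial range of non-decision time (uniform, s).
#' @param s Diffusion constant (> 0); the scaling parameter of the
#'   accumulation noise. Default 1.
#'
#' @return An object of class `dm_params`: a named list of the nine values.
#' @examples
#' p <- dm_params(v = 1, a = 1.2, t0 = 0.3)
#' validate_parameters(p)
#' @export
dm_params <- function(v = 0, a = 1, zr = 0.5, t0 = 0.3, d = 0,
                      sv = 0, szr = 0, st0 = 0, s = 1) {
  p <- list(v = v, a = a, zr = zr, t0 = t0, d = d,
            sv = sv, szr = szr, st0 = st0, s = s)
  for (nm in names(p)) {
    if (!is.numeric(p[[nm]]) || length(p[[nm]]) != 1L || !is.finite(p[[nm]])) {
      stop("parameter '", nm, "' must be a single finite number", call. = FALSE)
    }
  }
  structure(p, class = "dm_params")
}

#' @export
print.dm_params <- function(x, ...) {
  cat("<dm_params>  (s =", format(x$s), ")\n")
  vals <- unlist(x[c("v", "a", "zr", "t0", "d", "sv", "szr", "st0")])
  print(vals, ...)
  invisible(x)
}

#' Canonical parameter order used throughout the package
#' @keywords internal
dm_param_names <- function() c("v", "a", "zr", "t0", "d", "sv", "szr", "st0")

#' Validate a parameter set
#'
#' Checks every theoretical constraint of the model and returns a verdict
#' rather than throwing: the optimizer's penalty branch consumes the list of
#' violated constraints and their total magnitude.
#'
#' Constraints: `a > 0`; `0 < zr < 1`; `t0 >= 0`; `sv, szr, st0 >= 0`;
#' `s > 0`; the starting-point distribution must stay inside the corridor
#' (`zr - szr/2 > 0`, `zr + szr/2 < 1`); and the smallest realizable
#' non-decision time must be non-negative (`t0 - st0/2 - |d|/2 >= 0`), so no
#' trial can be predicted to have a negative response time.
#'
#' @param p A [dm_params()] object.
#' @return A list with `valid` (logical), `violations` (character vector of
#'   violated constraint names) and `magnitude` (non-negative total violation
#'   size; 0 when valid).
#' @export
validate_parameters <- function(p) {
  viol <- character()
  mag <- 0
  bump <- function(excess) mag <<- mag + 1e-3 + excess

  if (!(p$a > 0)) { viol <- c(viol, "a"); bump(max(0, -p$a)) }
  if (!(p$zr > 0 && p$zr < 1)) {
    viol <- c(viol, "zr"); bump(max(0, -p$zr, p$zr - 1))
  }
  if (!(p$t0 >= 0)) { viol <- c(viol, "t0"); bump(-p$t0) }
  if (!(p$sv >= 0)) { viol <- c(viol, "sv"); bump(-p$sv) }
  if (!(p$szr >= 0)) { viol <- c(viol, "szr"); bump(-p$szr) }
  if (!(p$st0 >= 0)) { viol <- c(viol, "st0"); bump(-p$st0) }
  if (!(p$s > 0)) { viol <- c(viol, "s"); bump(max(0, -p$s)) }
  # corridor for the starting-point distribution
  if (p$szr >= 0 && p$zr > 0 && p$zr < 1) {
    lo <- p$zr - p$szr / 2
    hi <- p$zr + p$szr / 2
    if (!(lo > 0 && hi < 1)) {
      viol <- c(viol, "zr_szr")
      bump(max(0, -lo) + max(0, hi - 1))
    }
  }
  # smallest realizable non-decision time
  if (p$t0 >= 0 && p$st0 >= 0) {
    tmin <- p$t0 - p$st0 / 2 - abs(p$d) / 2
    if (tmin < 0) { viol <- c(viol, "t0_st0_d"); bump(-tmin) }
  }
  list(valid = length(viol) == 0L, violations = viol, magnitude = mag)
}

#' Rescale parameters to a different diffusion constant
#'
#' Estimates obtained under one diffusion constant are mapped onto another
#' scale by multiplying `v`, `a` and `sv` by `s_new / s_old`. The relative
#' quantities `zr` and `szr` are ratios of scaled quantities and cancel; the
#' time parameters `t0`, `d` and `st0` are unaffected.
#'
#' @param p A [dm_params()] object.
#' @param s_new New diffusion constant (> 0).
#' @return A [dm_params()] object expressed on the new scale.
#' @examples
#' p <- dm_params(v = 0.3, a = 0.12, sv = 0.08, s = 0.1)
#' rescale_parameters(p, 1)$v  # 3
#' @export
rescale_parameters <- function(p, s_new) {
  if (!is.numeric(s_new) || length(s_new) != 1L || !is.finite(s_new) || s_new <= 0) {
    stop("'s_new' must be a single positive number", call. = FALSE)
  }
  f <- s_new / p$s
  dm_params(v = p$v * f, a = p$a * f, zr = p$zr, t0 = p$t0, d = p$d,
            sv = p$sv * f, szr = p$szr, st0 = p$st0, s = s_new)
}

#' Split the mean non-decision time by the execution-bias parameter
#'
#' The model carries a common mean non-decision time `t0` and a difference
#' `d` between the two responses. The per-threshold values are
#' `t0 - d/2` (upper) and `t0 + d/2` (lower); their mean recovers `t0`.
#'
#' @param t0 Mean non-decision time (s).
#' @param d Non-decision-time difference (s).
#' @return Named numeric vector `c(upper = , lower = )`.
#' @examples
#' split_t0(0.5, 0.1)  # upper 0.45, lower 0.55
#' @export
split_t0 <- function(t0, d) {
  c(upper = t0 - 0.5 * d, lower = t0 + 0.5 * d)
}

#' Probability of absorption at the upper threshold
#'
#' Closed form for the basic model (no inter-trial variability): the
#' probability that the accumulator hits `a` before 0, starting at
#' `z = zr * a` with drift `v` and diffusion constant `s`. For `v = 0` the
#' continuous limit `zr` is returned. Used as an independent oracle for the
#' density and CDF engines.
#'
#' @inheritParams dm_params
#' @return Probability in \[0, 1\].
#' @examples
#' exit_probability_upper(v = 3, a = 2, zr = 0.5)  # ~0.99753
#' @export
exit_probability_upper <- function(v, a, zr, s = 1) {
  stopifnot(a > 0, zr > 0, zr < 1, s > 0)
  v <- v / s^2  # absorb the scale; P depends on v/s^2 only
  if (abs(v) < 1e-10) return(zr + (v * a) * zr * (1 - zr))  # first-order limit
  if (v < 0) return(1 - exit_probability_upper(-v, a, 1 - zr, s = 1))
  expm1(-2 * v * zr * a) / expm1(-2 * v * a)
}

#' Discretization settings derived from the precision parameter
#'
#' A single positive `precision` value governs every numerical knob, with a
#' target error of roughly `10^-precision`: the series truncation bound for
#' the density representations, the step counts of the starting-point and
#' non-decision-time integrations (minimum 4 steps each), the spatial and
#' temporal resolution of the finite-difference CDF solver, and the number of
#' Gauss-Hermite nodes used for drift variability in the CDF engine.
#'
#' @param precision Positive real; default 3. Reasonable values 2-5.
#' @param a Threshold separation the settings will be used with (affects the
#'   spatial grid of the CDF solver).
#' @param v Drift magnitude the settings will be used with (guards the
#'   advection resolution of the CDF solver).
#' @return A list of derived settings (class `dm_precision`).
#' @export
dm_precision <- function(precision = 3, a = 1, v = 0) {
  stopifnot(is.numeric(precision), length(precision) == 1L, precision > 0)
  # series truncation: never looser than 1e-6, tighter when asked
  eps_series <- min(1e-6, 10^(-precision))
  # midpoint step counts for the uniform zr / t0 integrations
  n_int <- max(4L, as.integer(ceiling(0.8 * 10^(precision / 2))))
  # CDF solver grid: spatial steps scale with a and the target error;
  # keep enough resolution for the drift term (cell Peclet number <= ~0.5)
  nz <- max(ceiling(a * 60 * 10^((precision - 3) / 2)), ceiling(2 * abs(v) * a), 20)
  h <- a / nz
  dt <- min(0.5 * h / max(1, abs(v)), 0.005 * 10^(-(precision - 3) / 2))
  n_hermite <- max(4L, as.integer(ceiling(2 * precision)))
  structure(list(precision = precision, eps_series = eps_series,
                 n_int = n_int, nz = as.integer(nz), dt = dt,
                 n_hermite = n_hermite),
            class = "dm_precision")
}
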