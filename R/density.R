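## First-passage-time densities of the Wiener diffusion process.
##
## Two series representations of the upper-threshold density exist: one that
## converges quickly for small decision times and one for large times. Both
## factor the drift dependence out of the series, which makes the normal
## drift-variability mixture available in closed form. All functions work on
## the s = 1 scale; rescale first via rescale_parameters() if needed.

#' Small-time series representation of the first-passage density
#'
#' Partial sum over `n = -n_terms ... n_terms` of the small-time expansion of
#' the density of absorption at the upper threshold `a`, starting at absolute
#' position `z` with drift `v` (diffusion constant 1).
#'
#' @param t Decision time(s) in seconds (> 0 for a non-zero value).
#' @param z Absolute starting point, `z = zr * a`.
#' @param a Threshold separation.
#' @param v Drift rate.
#' @param n_terms Number of series terms on each side of n = 0.
#' @return Density value(s), vectorized over `t`.
#' @export
density_small_time <- function(t, z, a, v, n_terms) {
  stopifnot(n_terms >= 1)
  out <- numeric(length(t))
  ok <- t > 0
  if (!any(ok)) return(out)
  tt <- t[ok]
  n <- seq.int(-n_terms, n_terms)
  w <- (1 + 2 * n) * a - z                      # term offsets
  # exponent combined per term to avoid overflow of the drift prefactor
  ex <- outer(tt, w, function(ti, wi) (a - z) * v - 0.5 * v^2 * ti - wi^2 / (2 * ti))
  terms <- exp(ex) * rep(w, each = length(tt))
  out[ok] <- rowSums(terms) / sqrt(2 * pi * tt^3)
  out
}

#' Large-time series representation of the first-passage density
#'
#' Partial sum over `n = 1 ... n_terms` of the spectral (large-time) expansion
#' of the upper-threshold density.
#'
#' @inheritParams density_small_time
#' @return Density value(s), vectorized over `t`.
#' @export
density_large_time <- function(t, z, a, v, n_terms) {
  stopifnot(n_terms >= 1)
  out <- numeric(length(t))
  ok <- t > 0
  if (!any(ok)) return(out)
  tt <- t[ok]
  n <- seq_len(n_terms)
  sines <- n * sin(pi * (a - z) * n / a)
  ex <- outer(tt, n, function(ti, ni) (a - z) * v - 0.5 * (v^2 + pi^2 * ni^2 / a^2) * ti)
  terms <- exp(ex) * rep(sines, each = length(tt))
  out[ok] <- (pi / a^2) * rowSums(terms)
  out
}

#' Choose the faster-converging series representation
#'
#' Given the dimensionless time `t_scaled = t / a^2` and a truncation error
#' bound `eps`, computes the minimal number of terms each representation needs
#' (published truncation bounds for the two expansions) and returns the
#' representation with the smaller count.
#'
#' @param t_scaled Decision time divided by `a^2` (dimensionless).
#' @param eps Maximum permitted truncation error (> 0).
#' @return A list with `representation` ("small" or "large") and `n_terms`.
#' @export
choose_representation <- function(t_scaled, eps = 1e-6) {
  stopifnot(t_scaled > 0, eps > 0)
  ks <- n_terms_small(t_scaled, eps)
  kl <- n_terms_large(t_scaled, eps)
  if (ks <= kl) list(representation = "small", n_terms = ks)
  else list(representation = "large", n_terms = kl)
}

# truncation bound for the small-time expansion (vectorized over tau)
n_terms_small <- function(tau, eps) {
  k <- rep(2, length(tau))
  need <- 2 * sqrt(2 * pi * tau) * eps < 1
  if (any(need)) {
    tn <- tau[need]
    ks <- 2 + sqrt(-2 * tn * log(2 * eps * sqrt(2 * pi * tn)))
    k[need] <- pmax(ks, sqrt(tn) + 1)
  }
  pmax(1L, as.integer(ceiling(k)))
}

# truncation bound for the large-time expansion (vectorized over tau)
n_terms_large <- function(tau, eps) {
  k <- 1 / (pi * sqrt(tau))
  need <- pi * tau * eps < 1
  if (any(need)) {
    tn <- tau[need]
    kl <- sqrt(-2 * log(pi * tn * eps) / (pi^2 * tn))
    k[need] <- pmax(kl, 1 / (pi * sqrt(tn)))
  }
  pmax(1L, as.integer(ceiling(k)))
}

#' First-passage density of the basic model
#'
#' Density of absorption at one threshold for the model without inter-trial
#' variabilities, automatically using the series representation that converges
#' faster at each `t`. The lower-threshold density is obtained from the upper
#' one by the reflection `v -> -v`, `z -> a - z`. Zero for `t <= 0`.
#'
#' @param t Decision time(s) in seconds.
#' @param params A [dm_params()] object (sv/szr/st0 are ignored here).
#' @param threshold `"upper"` or `"lower"`.
#' @param eps Series truncation error bound.
#' @return Density value(s), vectorized over `t`.
#' @export
density_basic <- function(t, params, threshold = c("upper", "lower"), eps = 1e-6) {
  threshold <- match.arg(threshold)
  v <- params$v
  z <- params$zr * params$a
  a <- params$a
  if (threshold == "lower") { v <- -v; z <- a - z }
  wfpt_upper(t, z, a, v, eps)
}

# workhorse: upper-threshold density, per-element representation choice
wfpt_upper <- function(t, z, a, v, eps = 1e-6) {
  out <- numeric(length(t))
  ok <- t > 0
  if (!any(ok)) return(out)
  tt <- t[ok]
  tau <- tt / a^2
  ks <- n_terms_small(tau, eps)
  kl <- n_terms_large(tau, eps)
  use_small <- ks <= kl
  res <- numeric(length(tt))
  if (any(use_small)) {
    idx <- which(use_small)
    res[idx] <- density_small_time(tt[idx], z, a, v, max(ks[idx]))
  }
  if (any(!use_small)) {
    idx <- which(!use_small)
    res[idx] <- density_large_time(tt[idx], z, a, v, max(kl[idx]))
  }
  out[ok] <- pmax(res, 0)  # truncation can leave ~eps-size negative dust
  out
}

#' Density with normal inter-trial drift variability
#'
#' Mixture of the basic density over a normal drift distribution with mean `v`
#' and standard deviation `sv`, evaluated in closed form: the drift enters the
#' series only through the factor `exp((a - z) v - v^2 t / 2)`, whose normal
#' mixture is a Gaussian integral. Reduces exactly to the basic density when
#' `sv = 0`.
#'
#' @inheritParams density_small_time
#' @param sv Inter-trial standard deviation of drift (>= 0).
#' @param eps Series truncation error bound.
#' @return Density value(s), vectorized over `t` (and over `z` if supplied as
#'   a vector of matching length).
#' @export
density_sv <- function(t, z, a, v, sv, eps = 1e-6) {
  if (sv == 0 && length(z) == 1L) return(wfpt_upper(t, z, a, v, eps))
  n <- max(length(t), length(z))
  t <- rep_len(t, n); z <- rep_len(z, n)
  out <- numeric(n)
  ok <- t > 0
  if (!any(ok)) return(out)
  tt <- t[ok]; zz <- z[ok]
  # drift-free series value M(t, z, a) = g(t; v = 0)
  m <- wfpt_upper_vecz(tt, zz, a, eps)
  b <- a - zz
  denom <- 1 + tt * sv^2
  fac <- exp((b^2 * sv^2 + 2 * b * v - tt * v^2) / (2 * denom)) / sqrt(denom)
  out[ok] <- m * fac
  out
}

# drift-free upper density, vectorized over (t, z) jointly
wfpt_upper_vecz <- function(t, z, a, eps = 1e-6) {
  tau <- t / a^2
  ks <- n_terms_small(tau, eps)
  kl <- n_terms_large(tau, eps)
  use_small <- ks <= kl
  res <- numeric(length(t))
  if (any(use_small)) {
    i <- which(use_small)
    K <- max(ks[i])
    n <- seq.int(-K, K)
    ti <- t[i]; zi <- z[i]
    acc <- 0
    for (nn in n) {
      w <- (1 + 2 * nn) * a - zi
      acc <- acc + exp(-w^2 / (2 * ti)) * w
    }
    res[i] <- acc / sqrt(2 * pi * ti^3)
  }
  if (any(!use_small)) {
    i <- which(!use_small)
    K <- max(kl[i])
    ti <- t[i]; zi <- z[i]
    acc <- 0
    for (nn in seq_len(K)) {
      acc <- acc + nn * sin(pi * (a - zi) * nn / a) * exp(-0.5 * pi^2 * nn^2 * ti / a^2)
    }
    res[i] <- (pi / a^2) * acc
  }
  pmax(res, 0)
}

#' Full-model first-passage density at a response time
#'
#' Density of observing response time `t_rt` at the given threshold under the
#' complete model: the analytic drift mixture is integrated numerically
#' (midpoint rule, at least 4 steps, step count set by `precision`) over the
#' uniform starting-point range `zr +/- szr/2` and the uniform non-decision
#' time range `t0 +/- st0/2`, with the per-threshold non-decision time from
#' [split_t0()]. Returns 0 whenever the whole non-decision window exceeds
#' `t_rt`.
#'
#' @param t_rt Response time(s) in seconds.
#' @param params A [dm_params()] object.
#' @param threshold `"upper"` or `"lower"`.
#' @param precision Precision parameter (see [dm_precision()]).
#' @return Density value(s), vectorized over `t_rt`.
#' @export
density_full <- function(t_rt, params, threshold = c("upper", "lower"),
                         precision = 3) {
  threshold <- match.arg(threshold)
  ps <- dm_precision(precision, a = params$a, v = params$v)
  eps <- ps$eps_series
  a <- params$a
  v <- params$v
  z <- params$zr * a
  if (threshold == "lower") { v <- -v; z <- a - z }
  t0_thr <- unname(split_t0(params$t0, params$d)[threshold])
  sz <- params$szr * a

  # midpoint nodes for the two uniform integrations
  z_nodes <- if (sz > 0) z + sz * ((seq_len(ps$n_int) - 0.5) / ps$n_int - 0.5) else z
  t_off <- if (params$st0 > 0) {
    params$st0 * ((seq_len(ps$n_int) - 0.5) / ps$n_int - 0.5)
  } else 0

  nt <- length(t_rt)
  grid <- expand.grid(zi = z_nodes, oi = t_off)
  acc <- numeric(nt)
  for (k in seq_len(nrow(grid))) {
    tdec <- t_rt - t0_thr - grid$oi[k]
    acc <- acc + density_sv(tdec, grid$zi[k], a, v, params$sv, eps)
  }
  acc / nrow(grid)
}
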