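# Shared helpers and independent oracles.

# signed response times (lower-threshold RTs negated)
signed_tau <- function(data) {
  ifelse(data$response == 1, data$rt, -data$rt)
}

# Gauss-Hermite quadrature of the drift-variability mixture (independent
# oracle for the closed-form density_sv): integrates the basic series over
# a normal drift distribution with K nodes.
gh_mixture_density <- function(t, z, a, v, sv, K = 64) {
  k <- seq_len(K - 1)
  J <- matrix(0, K, K)
  J[cbind(k, k + 1)] <- sqrt(k / 2)
  J <- J + t(J)
  e <- eigen(J, symmetric = TRUE)
  x <- e$values
  w <- e$vectors[1, ]^2
  vapply(t, function(ti) {
    sum(w * vapply(v + sqrt(2) * sv * x,
                   function(vv) density_small_time(ti, z, a, vv, 40),
                   numeric(1)))
  }, numeric(1))
}

# brute-force midpoint integration over the uniform starting-point and
# non-decision windows (refinement oracle for density_full)
brute_density_full <- function(t_rt, params, threshold, n_steps = 1e4) {
  a <- params$a
  v <- params$v
  z <- params$zr * a
  if (threshold == "lower") { v <- -v; z <- a - z }
  t0_thr <- unname(split_t0(params$t0, params$d)[threshold])
  sz <- params$szr * a
  zn <- if (sz > 0) z + sz * ((seq_len(n_steps) - 0.5) / n_steps - 0.5) else z
  on <- if (params$st0 > 0) {
    params$st0 * ((seq_len(n_steps) - 0.5) / n_steps - 0.5)
  } else 0
  acc <- 0
  for (o in on) {
    acc <- acc + mean(density_sv(rep(t_rt - t0_thr - o, length(zn)), zn, a, v,
                                 params$sv, eps = 1e-8))
  }
  acc / length(on)
}

# total response probability at one threshold under the full model,
# by integrating the density engine out to a long horizon
exit_prob_threshold <- function(p, thr) {
  hi <- p$t0 + p$st0 / 2 + abs(p$d) / 2 +
    30 / (p$v^2 / 2 + pi^2 / (2 * p$a^2))
  integrate(function(t) density_full(t, p, thr, 3), 0, hi,
            rel.tol = 1e-7, abs.tol = 1e-10)$value
}

# random valid parameter set with inter-trial variabilities
random_valid_params <- function() {
  repeat {
    p <- dm_params(v = stats::runif(1, -3, 3),
                   a = stats::runif(1, 0.6, 2),
                   zr = stats::runif(1, 0.35, 0.65),
                   t0 = stats::runif(1, 0.2, 0.5),
                   d = stats::runif(1, -0.05, 0.05),
                   sv = stats::runif(1, 0, 0.8),
                   szr = stats::runif(1, 0, 0.3),
                   st0 = stats::runif(1, 0, 0.2))
    if (validate_parameters(p)$valid) return(p)
  }
}

# two-condition data set with condition-specific drifts
two_condition_data <- function(v_by_cond, n_per_cond, a = 1, t0 = 0.3,
                               precision = 4) {
  dplyr::bind_rows(lapply(seq_along(v_by_cond), function(i) {
    d <- sample_dataset(dm_params(v = v_by_cond[i], a = a, t0 = t0),
                        n_per_cond, precision)
    d$stimulus <- names(v_by_cond)[i]
    d
  }))
}

# content of a control file in the style of the worked example:
# ML criterion, reduced precision, four fixed parameters, drift depending
# on two crossed condition columns
example_control_lines <- function() {
  c("# example control file",
    "method ml",
    "precision 2.5",
    "set d 0",
    "set zr 0.5",
    "set szr 0",
    "set sv 0",
    "depends v stimulus difficulty",
    "format RESPONSE TIME stimulus difficulty",
    "load data_*.dat",
    "save parameters_*.dat",
    "log experiment.log")
}

# 2 x 2 condition trial table (levels crossed, m trials per cell)
crossed_data <- function(m = 5) {
  g <- expand.grid(stimulus = c("word", "nonword"),
                   difficulty = c("easy", "hard"),
                   stringsAsFactors = FALSE)
  dplyr::bind_rows(lapply(seq_len(nrow(g)), function(i) {
    tibble::tibble(response = rep(c(0L, 1L), length.out = m),
                   rt = seq(0.4, 0.8, length.out = m),
                   stimulus = g$stimulus[i], difficulty = g$difficulty[i])
  }))
}
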