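## Companion tools: data-set simulation (random and deterministic-quantile
## modes), export of predicted combined CDFs and densities, and Monte-Carlo
## calibration of a critical fit value for model-fit assessment.

#' Simulate a random data set
#'
#' Draws trials from the full model: per trial the drift, relative starting
#' point and non-decision time are drawn from their inter-trial distributions
#' (normal / uniform / uniform), then the response and decision time are drawn
#' by inverse-transform sampling on the basic-model combined CDF at the
#' realized drift and starting point, and the response time is the decision
#' time plus the realized non-decision time (split by `d` between thresholds).
#' Randomness comes from R's RNG; use `set.seed()` for reproducibility.
#'
#' @param params A [dm_params()] object.
#' @param n Number of trials (default 100).
#' @param precision Precision of the distribution calculations (default 4).
#' @return A tibble with columns `response` (0/1) and `rt` (seconds).
#' @export
sample_dataset <- function(params, n = 100, precision = 4) {
  chk <- validate_parameters(params)
  if (!chk$valid) stop("invalid parameter set: ",
                       paste(chk$violations, collapse = ", "), call. = FALSE)
  stopifnot(n >= 1)
  a <- params$a
  t0i <- if (params$st0 > 0) stats::runif(n, params$t0 - params$st0 / 2,
                                          params$t0 + params$st0 / 2)
         else rep(params$t0, n)
  zri <- if (params$szr > 0) stats::runif(n, params$zr - params$szr / 2,
                                          params$zr + params$szr / 2)
         else rep(params$zr, n)
  vi <- if (params$sv > 0) stats::rnorm(n, params$v, params$sv)
        else rep(params$v, n)
  u <- stats::runif(n)
  resp <- integer(n)
  tdec <- numeric(n)

  if (params$sv == 0 && params$szr == 0) {
    cur <- predicted_curves(basic_params(params), precision)
    for (i in seq_len(n)) {
      s <- invert_joint(cur$t, cur$up, cur$low, u[i])
      resp[i] <- s$response; tdec[i] <- s$t
    }
  } else if (params$sv == 0) {
    # one PDE solve pair serves every starting-point draw
    ps <- dm_precision(precision, a = a, v = params$v)
    tmax <- t_max_guess(params, precision)
    nt <- max(2L, as.integer(ceiling(tmax / ps$dt)))
    Fup <- cdf_pde_grid(params$v, a, ps$nz, ps$dt, nt)
    Flo <- if (abs(params$v) < 1e-14) Fup
           else cdf_pde_grid(-params$v, a, ps$nz, ps$dt, nt)
    zg <- seq(0, a, length.out = ps$nz + 1)
    tg <- seq(0, by = ps$dt, length.out = nt + 1)
    for (i in seq_len(n)) {
      cu <- grid_interp_col(Fup, zg, zri[i] * a)
      cl <- grid_interp_col(Flo, zg, (1 - zri[i]) * a)
      s <- invert_joint(tg, cu, cl, u[i])
      resp[i] <- s$response; tdec[i] <- s$t
    }
  } else {
    for (i in seq_len(n)) {
      pi_ <- dm_params(v = vi[i], a = a, zr = zri[i], t0 = 0)
      cur <- predicted_curves(pi_, precision)
      s <- invert_joint(cur$t, cur$up, cur$low, u[i])
      resp[i] <- s$response; tdec[i] <- s$t
    }
  }
  rt <- tdec + t0i + ifelse(resp == 1L, -params$d / 2, params$d / 2)
  tibble::tibble(response = resp, rt = rt)
}

# strip inter-trial variabilities (basic model for per-trial draws)
basic_params <- function(p) {
  dm_params(v = p$v, a = p$a, zr = p$zr, t0 = 0, d = 0)
}

# inverse-transform one uniform draw on joint decision-time curves
invert_joint <- function(tg, up, low, u) {
  p_low <- low[length(low)]
  total <- p_low + up[length(up)]
  u <- u * total  # fold the unabsorbed residual (~10^-precision) back in
  if (u <= p_low) {
    list(response = 0L, t = inverse_curve(tg, low, u))
  } else {
    list(response = 1L, t = inverse_curve(tg, up, u - p_low))
  }
}

inverse_curve <- function(tg, curve, q) {
  # strictly increasing section only (skip the flat start)
  i0 <- max(1L, which(curve > 0)[1] - 1L)
  stats::approx(curve[i0:length(curve)], tg[i0:length(tg)], xout = q,
                ties = "ordered", rule = 2)$y
}

#' Generate a deterministic (quantile) data set
#'
#' Places `n` trials at the quantiles of the predicted full-model combined
#' distribution at probabilities `(i - 0.5) / n`: the sign of the signed-time
#' quantile determines the response. The output is noise free and bit
#' reproducible; fitting it recovers the generating parameters up to
#' discretization error.
#'
#' @inheritParams sample_dataset
#' @return A tibble with columns `response` and `rt`, ordered by signed time.
#' @export
deterministic_dataset <- function(params, n = 100, precision = 4) {
  chk <- validate_parameters(params)
  if (!chk$valid) stop("invalid parameter set: ",
                       paste(chk$violations, collapse = ", "), call. = FALSE)
  stopifnot(n >= 1)
  dist <- combined_cdf(params, precision)
  grid <- as_tibble.dm_dist(dist, t_step = 1e-3)
  probs <- (seq_len(n) - 0.5) / n
  tau <- stats::approx(grid$cdf, grid$time, xout = probs, ties = "ordered",
                       rule = 2)$y
  tibble::tibble(response = as.integer(tau > 0), rt = abs(tau))
}

#' Simulate data sets in the command-line tool's interface
#'
#' Thin wrapper matching the simulation tool's flags: one call generates `N`
#' data sets of `n` trials each, random (`random = TRUE`) or deterministic,
#' and either returns them or writes two-column (response, RT) text files.
#' With `N > 1` the output pattern must contain `%d`, replaced by
#' `0 ... N - 1`.
#'
#' @param a,zr,v,t0,d,szr,sv,st0 Model parameters (defaults: `a = 1`,
#'   `zr = 0.5`, `v = 0`, `t0 = 0.3`, rest 0).
#' @param precision Computational precision (default 4).
#' @param n Trials per data set (default 100).
#' @param N Number of data sets (default 1).
#' @param random Generate random samples (`TRUE`) or the deterministic
#'   quantile sample (`FALSE`, default).
#' @param output Output file name or `%d` pattern; `NULL` returns the data.
#' @return Invisibly, a list of trial tibbles (length `N`).
#' @export
construct_samples <- function(a = 1, zr = 0.5, v = 0, t0 = 0.3, d = 0,
                              szr = 0, sv = 0, st0 = 0, precision = 4,
                              n = 100, N = 1, random = FALSE, output = NULL) {
  stopifnot(N >= 1)
  params <- dm_params(v = v, a = a, zr = zr, t0 = t0, d = d,
                      sv = sv, szr = szr, st0 = st0)
  if (N > 1 && !is.null(output) && !grepl("%d", output, fixed = TRUE)) {
    stop("output pattern must contain %d when N > 1", call. = FALSE)
  }
  out <- vector("list", N)
  for (k in seq_len(N)) {
    d_k <- if (random) sample_dataset(params, n, precision)
           else deterministic_dataset(params, n, precision)
    out[[k]] <- d_k
    if (!is.null(output)) {
      path <- if (grepl("%d", output, fixed = TRUE)) sprintf(output, k - 1)
              else output
      writeLines(paste(d_k$response, formatC(d_k$rt, digits = 6, format = "f")),
                 path)
    }
  }
  invisible(out)
}

#' Export a predicted combined CDF
#'
#' Tabulates the predicted combined CDF on a signed time grid (negative times
#' are lower-threshold responses): column 1 the signed RT, column 2 the
#' cumulative probability, rows ascending in signed time.
#'
#' @param params A [dm_params()] object.
#' @param precision Precision (default 4).
#' @param file Optional output file (two whitespace-separated columns).
#' @param t_step Grid spacing in seconds (default 0.001).
#' @return A tibble with columns `time` and `cdf`.
#' @export
export_cdf <- function(params, precision = 4, file = NULL, t_step = 1e-3) {
  dist <- combined_cdf(params, precision)
  tab <- as_tibble.dm_dist(dist, t_step = t_step)
  if (!is.null(file)) {
    writeLines(paste(formatC(tab$time, digits = 6, format = "f"),
                     formatC(tab$cdf, digits = 6, format = "f")), file)
  }
  tab
}

#' Export predicted density functions
#'
#' Tabulates the full-model first-passage densities at both thresholds over
#' response time: column 1 the RT, column 2 the upper-threshold density,
#' column 3 the lower-threshold density with a negative sign.
#'
#' @inheritParams export_cdf
#' @return A tibble with columns `time`, `upper` and `lower`.
#' @export
export_density <- function(params, precision = 4, file = NULL, t_step = 1e-3) {
  t_hi <- params$t0 + params$st0 / 2 + abs(params$d) / 2 +
    t_max_guess(params, precision)
  tg <- seq(0, t_hi, by = t_step)
  up <- density_full(tg, params, "upper", precision)
  lo <- density_full(tg, params, "lower", precision)
  tab <- tibble::tibble(time = tg, upper = up, lower = -lo)
  if (!is.null(file)) {
    writeLines(paste(formatC(tab$time, digits = 6, format = "f"),
                     formatC(tab$upper, digits = 6, format = "f"),
                     formatC(tab$lower, digits = 6, format = "f")), file)
  }
  tab
}

#' Monte-Carlo calibration of a critical fit value
#'
#' Assesses what fit index value still indicates an acceptable fit for a given
#' design: parameter vectors are drawn from the multivariate normal
#' distribution defined by the mean and covariance of the supplied
#' per-participant estimates (invalid draws are rejected and redrawn), one
#' data set is simulated per draw (each condition cell separately, then
#' combined), every data set is refitted with the same specification, and the
#' 5% bad-fit quantile of the resulting fit indices is returned: the lower 5%
#' quantile for KS (small p bad), the upper 95% quantile for CS and ML (large
#' CS / -LL bad). Empirical data sets fitting worse than the critical value
#' should be flagged.
#'
#' @param estimates A data frame of per-participant free-parameter estimates
#'   (columns named like the fit's free slots; at least 2 rows).
#' @param spec The [dm_spec()] used for the empirical analysis.
#' @param data A representative trials tibble (defines the condition cells and
#'   default per-cell trial counts).
#' @param n_sets Number of simulated parameter sets (default 1000).
#' @param n_trials Trials per condition cell (default: the counts observed in
#'   `data`).
#' @param precision_sim Precision used for simulation (default 4).
#' @return A list with `critical` (the critical fit value), `values` (all
#'   simulated fit indices), `direction` (`"lower"` or `"upper"`: the bad-fit
#'   side) and `n_failed` (simulated sets whose refit failed).
#' @export
montecarlo_fit_threshold <- function(estimates, spec, data, n_sets = 1000,
                                     n_trials = NULL, precision_sim = 4) {
  estimates <- as.data.frame(estimates)
  data <- assign_cells(data, spec)
  ptable <- build_parameter_table(spec, data)
  slots <- ptable$slots$slot
  missing_slots <- setdiff(slots, names(estimates))
  if (length(missing_slots)) {
    stop("estimates lack column(s): ", paste(missing_slots, collapse = ", "),
         call. = FALSE)
  }
  estimates <- estimates[, slots, drop = FALSE]
  if (nrow(estimates) < 2L) {
    stop("at least 2 participants' estimates are required", call. = FALSE)
  }
  mu <- colMeans(estimates)
  Sigma <- stats::cov(estimates)
  ev <- eigen(Sigma, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 1e-12 * max(abs(ev), 1)) {
    warning("singular covariance of estimates; adding a small ridge")
    Sigma <- Sigma + diag(1e-6 * pmax(diag(Sigma), 1e-6), ncol(Sigma))
  }
  cells <- ptable$cells
  counts <- table(data$cell)
  if (is.null(n_trials)) {
    n_cell <- as.integer(counts[cells$cell])
    n_cell[is.na(n_cell)] <- 0L
  } else {
    n_cell <- rep_len(n_trials, nrow(cells))
  }

  draw_valid <- function() {
    for (k in 1:1000) {
      th <- as.numeric(MASS::mvrnorm(1, mu, Sigma))
      names(th) <- slots
      pars <- expand_theta(th, ptable)
      if (all(vapply(pars, function(p) validate_parameters(p)$valid, logical(1))))
        return(pars)
    }
    stop("could not draw a valid parameter set in 1000 attempts", call. = FALSE)
  }

  vals <- rep(NA_real_, n_sets)
  for (s in seq_len(n_sets)) {
    pars <- draw_valid()
    sim <- dplyr::bind_rows(lapply(seq_len(nrow(cells)), function(i) {
      if (n_cell[i] == 0L) return(NULL)
      d <- sample_dataset(pars[[cells$cell[i]]], n_cell[i], precision_sim)
      for (lab in setdiff(names(cells), "cell")) d[[lab]] <- cells[[lab]][i]
      d
    }))
    f <- tryCatch(fit_spec(sim, spec, check_minimums = FALSE),
                  error = function(e) NULL)
    if (!is.null(f) && !f$index$penalized) vals[s] <- f$index$value
  }
  ok <- vals[!is.na(vals)]
  direction <- if (spec$method == "ks") "lower" else "upper"
  critical <- if (direction == "lower") {
    unname(stats::quantile(ok, 0.05, type = 7))
  } else {
    unname(stats::quantile(ok, 0.95, type = 7))
  }
  list(critical = critical, values = vals, direction = direction,
       n_failed = sum(is.na(vals)))
}

#' Euler-Maruyama path simulation of the full model
#'
#' Direct stochastic simulation of the accumulation process (step size `dt`),
#' including the inter-trial parameter distributions. Slower than
#' [sample_dataset()] but completely independent of the density/CDF engines,
#' which makes it the reference oracle in the package's own tests.
#'
#' @param params A [dm_params()] object.
#' @param n Number of trials.
#' @param dt Euler step size in seconds (default 1e-4).
#' @param t_cap Time cap per path (s); unabsorbed paths are assigned the
#'   nearer threshold.
#' @return A tibble with columns `response` and `rt`.
#' @export
simulate_paths <- function(params, n, dt = 1e-4, t_cap = 20) {
  chk <- validate_parameters(params)
  if (!chk$valid) stop("invalid parameter set", call. = FALSE)
  vi <- if (params$sv > 0) stats::rnorm(n, params$v, params$sv) else rep(params$v, n)
  zri <- if (params$szr > 0) stats::runif(n, params$zr - params$szr / 2,
                                          params$zr + params$szr / 2)
         else rep(params$zr, n)
  t0i <- if (params$st0 > 0) stats::runif(n, params$t0 - params$st0 / 2,
                                          params$t0 + params$st0 / 2)
         else rep(params$t0, n)
  m <- em_first_passage(vi, params$a, zri * params$a, dt, t_cap)
  resp <- as.integer(m[, 1])
  rt <- m[, 2] + t0i + ifelse(resp == 1L, -params$d / 2, params$d / 2)
  tibble::tibble(response = resp, rt = rt)
}
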