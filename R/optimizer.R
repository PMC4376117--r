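## Parameter search: Nelder-Mead simplex with a lexicographic penalty rule
## (any theoretically impossible parameter constellation ranks worse than any
## valid one, and among impossible ones the total constraint violation is
## minimized, which lets the simplex walk back into the valid region), started
## from closed-form EZ estimates and repeated three times with consecutively
## stricter stopping criteria.

# simplex perturbation step per parameter ("a small amount")
simplex_steps <- c(v = 0.1, a = 0.1, zr = 0.05, t0 = 0.02, d = 0.02,
                   sv = 0.1, szr = 0.05, st0 = 0.1)

#' EZ closed-form starting values
#'
#' Moment-based estimates of drift, threshold separation and non-decision time
#' from the accuracy (fraction of upper-threshold responses), the response
#' time variance and the response time mean, on the `s = 1` scale. Used to
#' seed the simplex; the relative starting point is set to 0.5 and all
#' inter-trial variabilities to 0. Edge accuracies (0, 0.5, 1) are nudged by
#' half a trial before the logit. Degenerate cells (fewer than two distinct
#' response times) fall back to `a = 1`, `v = 0`, `t0 = min(rt) - 0.1`
#' (floored at 0).
#'
#' @param data A trials tibble (`response`, `rt`) for one condition cell.
#' @return A valid [dm_params()] object.
#' @export
ez_start <- function(data) {
  data <- normalize_trials(data)
  rts <- data$rt
  n <- nrow(data)
  fallback <- dm_params(v = 0, a = 1, zr = 0.5,
                        t0 = max(min(rts) - 0.1, 0))
  if (length(unique(rts)) < 2L) return(fallback)
  pc <- mean(data$response == 1)
  if (pc == 0 || pc == 1) pc <- (n * pc + 0.5) / (n + 1)
  if (pc == 0.5) pc <- 0.5 + 0.5 / (n + 1)
  vrt <- stats::var(rts)
  mrt <- mean(rts)
  L <- stats::qlogis(pc)
  x <- L * (L * pc^2 - L * pc + pc - 0.5) / vrt
  if (!is.finite(x) || x <= 0) return(fallback)
  v <- sign(pc - 0.5) * x^(1 / 4)
  a <- L / v
  if (!is.finite(a) || a <= 0) return(fallback)
  a <- min(max(a, 0.1), 10)
  mdt <- (a / (2 * v)) * (1 - exp(-v * a)) / (1 + exp(-v * a))
  t0 <- mrt - mdt
  # keep the start inside the admissible region: t0 in [0, just below min RT]
  t0 <- min(max(t0, 0), max(min(rts) - 0.05, 0))
  p <- dm_params(v = v, a = a, zr = 0.5, t0 = t0)
  stopifnot(validate_parameters(p)$valid)
  p
}

#' Build the initial simplex around a starting vector
#'
#' Vertex 0 is the start; vertex i adds a parameter-specific step to free
#' parameter i (0.1 for `a`, `v`, `sv`, `st0`; 0.05 for `zr`, `szr`; 0.02 s
#' for `t0`, `d`), giving n + 1 vertices for n free parameters.
#'
#' @param start Named numeric vector of free-parameter starting values; names
#'   identify the underlying parameter before any condition suffix.
#' @param param_of Character vector: which of the eight model parameters each
#'   coordinate belongs to (determines the step size).
#' @return A numeric matrix with n + 1 rows (vertices) and n columns.
#' @export
build_initial_simplex <- function(start, param_of = names(start)) {
  n <- length(start)
  stopifnot(n >= 1, all(param_of %in% names(simplex_steps)))
  S <- matrix(rep(start, each = n + 1), nrow = n + 1,
              dimnames = list(NULL, names(start)))
  for (i in seq_len(n)) S[i + 1, i] <- S[i + 1, i] + simplex_steps[[param_of[i]]]
  S
}

# objective protocol: f(theta) returns list(penalized = lgl, key = numeric)
# where key is the penalty magnitude when penalized, else the minimized value.
obj_better <- function(a, b) {
  if (a$penalized != b$penalized) return(!a$penalized)
  a$key < b$key
}

#' Nelder-Mead search under the lexicographic penalty rule
#'
#' Standard reflection/expansion/contraction/shrink moves; vertices are
#' compared first by penalty status (penalized always worse), then by penalty
#' magnitude or objective value. Terminates when the objective spread across
#' unpenalized vertices and the simplex diameter fall below the tolerances, or
#' at the iteration cap (returned with `converged = FALSE`).
#'
#' @param objective Function of a numeric vector returning a list with
#'   elements `penalized` (logical) and `key` (numeric: penalty magnitude if
#'   penalized, minimized objective value otherwise).
#' @param simplex Initial simplex matrix from [build_initial_simplex()].
#' @param tol_f Objective-spread tolerance.
#' @param tol_x Simplex-diameter tolerance.
#' @param max_iter Iteration cap.
#' @return A list: `par` (best vertex), `value` (its objective list),
#'   `iterations`, `converged`.
#' @export
simplex_search <- function(objective, simplex, tol_f = 1e-4,
                           tol_x = 1e-5, max_iter = 500) {
  S <- simplex
  n <- ncol(S)
  vals <- lapply(seq_len(n + 1), function(i) objective(S[i, ]))
  iter <- 0
  converged <- FALSE
  repeat {
    ord <- order(vapply(vals, function(v) v$penalized, logical(1)),
                 vapply(vals, function(v) v$key, numeric(1)))
    S <- S[ord, , drop = FALSE]
    vals <- vals[ord]
    # convergence: all vertices valid, small value spread, small diameter
    if (!vals[[n + 1]]$penalized) {
      spread <- vals[[n + 1]]$key - vals[[1]]$key
      diam <- max(abs(sweep(S[-1, , drop = FALSE], 2, S[1, ])))
      if (is.finite(spread) && spread < tol_f && diam < tol_x) {
        converged <- TRUE
        break
      }
    }
    if (iter >= max_iter) break
    iter <- iter + 1
    best <- vals[[1]]; worst <- vals[[n + 1]]; second <- vals[[n]]
    centroid <- colMeans(S[seq_len(n), , drop = FALSE])
    xr <- centroid + (centroid - S[n + 1, ])
    fr <- objective(xr)
    if (obj_better(fr, best)) {
      xe <- centroid + 2 * (centroid - S[n + 1, ])
      fe <- objective(xe)
      if (obj_better(fe, fr)) { S[n + 1, ] <- xe; vals[[n + 1]] <- fe }
      else { S[n + 1, ] <- xr; vals[[n + 1]] <- fr }
    } else if (obj_better(fr, second)) {
      S[n + 1, ] <- xr; vals[[n + 1]] <- fr
    } else {
      if (obj_better(fr, worst)) {  # outside contraction
        xc <- centroid + 0.5 * (xr - centroid)
        fc <- objective(xc)
        if (obj_better(fc, fr)) { S[n + 1, ] <- xc; vals[[n + 1]] <- fc; next }
        S[n + 1, ] <- xr; vals[[n + 1]] <- fr
      } else {                      # inside contraction
        xc <- centroid - 0.5 * (centroid - S[n + 1, ])
        fc <- objective(xc)
        if (obj_better(fc, worst)) { S[n + 1, ] <- xc; vals[[n + 1]] <- fc; next }
        # shrink toward the best vertex
        for (i in 2:(n + 1)) {
          S[i, ] <- S[1, ] + 0.5 * (S[i, ] - S[1, ])
          vals[[i]] <- objective(S[i, ])
        }
      }
    }
  }
  list(par = S[1, ], value = vals[[1]], iterations = iter,
       converged = converged)
}

# staged tolerances for the three consecutive runs
restart_schedule <- function() {
  list(tol_f = c(1e-2, 1e-3, 1e-4),
       tol_x = c(1e-3, 1e-4, 1e-5),
       max_iter = c(400, 600, 800))
}

#' Fit a diffusion model to trial data
#'
#' The main estimation entry point. Free parameters are searched by the
#' penalized simplex, starting from EZ estimates; the search is repeated three
#' times, re-inflating the simplex around the incumbent and tightening the
#' stopping criteria, and the three fit values are reported. Condition
#' dependencies (`depends`) give a parameter a separate free value for every
#' combination of the named condition columns; `fixed` removes parameters from
#' the search.
#'
#' @param data A trials data frame: columns `response` (0/1), `rt` (seconds),
#'   plus any condition columns named in `depends`.
#' @param method Optimization criterion: `"ks"` (default), `"cs"` or `"ml"`.
#' @param precision Precision of the distribution calculations (default 3).
#' @param fixed Named list of parameters fixed to given values,
#'   e.g. `list(zr = 0.5, d = 0)`.
#' @param depends Named list mapping parameter names to character vectors of
#'   condition columns, e.g. `list(v = c("stimulus", "difficulty"))`.
#' @param check_minimums If `TRUE` (default), abort when a condition has too
#'   few trials for the chosen method (see [check_trial_minimums()]).
#' @return An object of class `dm_fit`; see [tidy.dm_fit()],
#'   [glance.dm_fit()] and [autoplot.dm_fit()].
#' @examples
#' \donttest{
#' set.seed(1)
#' d <- sample_dataset(dm_params(v = 1.5, a = 1, t0 = 0.3), n = 200)
#' fit <- dm_fit(d, method = "ml", fixed = list(zr = 0.5, d = 0, sv = 0,
#'                                              szr = 0, st0 = 0))
#' generics::tidy(fit)
#' }
#' @export
dm_fit <- function(data, method = c("ks", "cs", "ml"), precision = 3,
                   fixed = list(), depends = list(), check_minimums = TRUE) {
  method <- match.arg(method)
  spec <- dm_spec(method = method, precision = precision, fixed = fixed,
                  depends = depends,
                  format = c("RESPONSE", "TIME",
                             setdiff(names(data), c("response", "rt", "cell"))))
  fit_spec(data, spec, check_minimums = check_minimums)
}

# internal: fit with a parsed dm_spec
fit_spec <- function(data, spec, check_minimums = TRUE) {
  data <- assign_cells(data, spec)
  if (check_minimums) {
    chk <- check_trial_minimums(data, spec$method)
    if (!chk$ok) {
      stop("estimation stopped: ", paste(chk$messages, collapse = "; "),
           call. = FALSE)
    }
  }
  ptable <- build_parameter_table(spec, data)
  start <- ez_start_table(data, ptable)
  objective <- make_objective(data, ptable, spec$method, spec$precision)

  sched <- restart_schedule()
  runs <- vector("list", 3L)
  incumbent <- start
  for (r in 1:3) {
    S <- build_initial_simplex(incumbent, param_of = ptable$slots$param)
    res <- simplex_search(objective, S, tol_f = sched$tol_f[r],
                          tol_x = sched$tol_x[r], max_iter = sched$max_iter[r])
    incumbent <- res$par
    runs[[r]] <- res
  }
  best <- runs[[3]]
  idx <- objective_report(best$par, data, ptable, spec$method, spec$precision)
  run_tbl <- tibble::tibble(
    run = 1:3,
    fit_value = vapply(runs, function(r) {
      objective_report(r$par, data, ptable, spec$method, spec$precision)$value
    }, numeric(1)),
    minimized = vapply(runs, function(r) r$value$key, numeric(1)),
    penalized = vapply(runs, function(r) r$value$penalized, logical(1)),
    iterations = vapply(runs, function(r) r$iterations, numeric(1)),
    converged = vapply(runs, function(r) r$converged, logical(1)))

  structure(list(estimates = best$par, ptable = ptable, spec = spec,
                 method = spec$method, precision = spec$precision,
                 index = idx, runs = run_tbl,
                 n_trials = nrow(data),
                 cell_counts = cell_counts(data)),
            class = "dm_fit")
}

# per-cell EZ starts mapped onto the free-slot vector
ez_start_table <- function(data, ptable) {
  cells <- unique(data$cell)
  ez <- lapply(cells, function(cl) ez_start(data[data$cell == cl, ]))
  names(ez) <- cells
  defaults <- c(v = 0, a = 1, zr = 0.5, t0 = 0.3, d = 0, sv = 0, szr = 0, st0 = 0)
  slots <- ptable$slots
  start <- numeric(nrow(slots))
  names(start) <- slots$slot
  for (i in seq_len(nrow(slots))) {
    par <- slots$param[i]
    use <- if (is.na(slots$cells[i])) cells else {
      intersect(strsplit(slots$cells[i], "\r", fixed = TRUE)[[1]], cells)
    }
    if (!length(use)) use <- cells
    if (par %in% c("v", "a", "t0")) {
      start[i] <- mean(vapply(use, function(cl) ez[[cl]][[par]], numeric(1)))
    } else {
      start[i] <- defaults[[par]]
    }
  }
  start
}

# expand a free vector into per-cell dm_params via the parameter table
expand_theta <- function(theta, ptable) {
  out <- vector("list", nrow(ptable$cells))
  names(out) <- ptable$cells$cell
  for (i in seq_len(nrow(ptable$cells))) {
    vals <- ptable$cell_map[[i]]
    p <- lapply(vals, function(ref) {
      if (ref$type == "fixed") ref$value else theta[[ref$slot]]
    })
    out[[i]] <- dm_params(v = p$v, a = p$a, zr = p$zr, t0 = p$t0, d = p$d,
                          sv = p$sv, szr = p$szr, st0 = p$st0)
  }
  out
}

# build the minimized objective function for the simplex
make_objective <- function(data, ptable, method, precision) {
  cells <- ptable$cells$cell
  cell_data <- lapply(cells, function(cl) data[data$cell == cl, ])
  names(cell_data) <- cells
  force(method); force(precision)
  function(theta) {
    names(theta) <- ptable$slots$slot
    params <- expand_theta(theta, ptable)
    pen <- 0
    for (p in params) {
      chk <- validate_parameters(p)
      if (!chk$valid) pen <- pen + chk$magnitude
    }
    if (pen > 0) return(list(penalized = TRUE, key = pen))
    key <- tryCatch({
      vals <- per_condition_values(cell_data, params, method, precision)
      aggregate_objective(method, vals)$minimized
    }, error = function(e) Inf)
    list(penalized = FALSE, key = key)
  }
}

per_condition_values <- function(cell_data, params, method, precision) {
  vapply(names(cell_data), function(cl) {
    d <- cell_data[[cl]]
    if (nrow(d) == 0L) return(switch(method, ml = 0, cs = 0, ks = 1))
    p <- params[[cl]]
    switch(method,
      ml = log_likelihood(d, p, precision),
      cs = cs_statistic(d, p, precision),
      ks = ks_pvalue(ks_statistic(d, p, precision), nrow(d)))
  }, numeric(1))
}

# full fit index (reporting scale) at a parameter vector
objective_report <- function(theta, data, ptable, method, precision) {
  names(theta) <- ptable$slots$slot
  params <- expand_theta(theta, ptable)
  pen <- 0
  for (p in params) {
    chk <- validate_parameters(p)
    if (!chk$valid) pen <- pen + chk$magnitude
  }
  if (pen > 0) return(aggregate_objective(method, numeric(0), penalty = pen))
  cells <- ptable$cells$cell
  cell_data <- lapply(cells, function(cl) data[data$cell == cl, ])
  names(cell_data) <- cells
  vals <- per_condition_values(cell_data, params, method, precision)
  aggregate_objective(method, vals)
}

cell_counts <- function(data) {
  out <- dplyr::count(dplyr::group_by(data, .data$cell, .data$response),
                      name = "n") |>
    tidyr::pivot_wider(names_from = "response", values_from = "n",
                       names_prefix = "resp_", values_fill = 0L) |>
    dplyr::ungroup()
  for (col in c("resp_0", "resp_1")) if (!col %in% names(out)) out[[col]] <- 0L
  out
}

#' @export
print.dm_fit <- function(x, ...) {
  cat("<dm_fit> method =", x$method, " precision =", x$precision,
      " trials =", x$n_trials, "\n")
  lab <- switch(x$method, ml = "-LL", cs = "CS", ks = "p(KS)")
  cat("fit values (3 runs):",
      paste(formatC(x$runs$fit_value, digits = 6), collapse = "  "), "\n")
  if (x$index$penalized) cat("final solution carries a penalty:",
                             format(x$index$penalty), "\n")
  cat("\nestimates:\n")
  print(generics::tidy(x), n = Inf)
  invisible(x)
}
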