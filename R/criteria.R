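## Fit criteria: maximum likelihood, chi-square on quantile bins, and the
## Kolmogorov-Smirnov distance on the combined (signed-time) distribution.
## All three are reduced to a single minimized objective by the optimizer;
## the reporting scale is -LL, CS, and the product of per-condition KS
## p-values respectively.

DENSITY_FLOOR <- 1e-6

#' Log-likelihood of a data set
#'
#' Sums the log predicted density over trials, with each density floored at
#' `10^-6` for robustness against outliers, and sums over condition cells.
#'
#' @param data A trials tibble with columns `response` (0/1), `rt` (s) and a
#'   `cell` column naming the condition cell (absent means one cell).
#' @param params_by_cell Named list of [dm_params()] objects, one per cell
#'   (or a single `dm_params` for one-cell data).
#' @param precision Precision parameter.
#' @return The summed log-likelihood (a single number).
#' @export
log_likelihood <- function(data, params_by_cell, precision = 3) {
  data <- normalize_trials(data)
  if (nrow(data) == 0L) stop("empty dataset", call. = FALSE)
  if (inherits(params_by_cell, "dm_params")) {
    params_by_cell <- stats::setNames(list(params_by_cell), unique(data$cell)[1])
  }
  ll <- 0
  for (cl in unique(data$cell)) {
    p <- params_by_cell[[cl]]
    if (is.null(p)) stop("no parameters for condition cell '", cl, "'", call. = FALSE)
    d <- data[data$cell == cl, ]
    for (resp in c(0L, 1L)) {
      rts <- d$rt[d$response == resp]
      if (!length(rts)) next
      g <- density_full(rts, p, if (resp == 1L) "upper" else "lower", precision)
      ll <- ll + sum(log(pmax(g, DENSITY_FLOOR)))
    }
  }
  ll
}

# coerce a trials data frame to (response, rt, cell)
normalize_trials <- function(data) {
  stopifnot(is.data.frame(data), all(c("response", "rt") %in% names(data)))
  if (!"cell" %in% names(data)) data$cell <- "all"
  if (!all(data$response %in% c(0, 1))) {
    stop("'response' must contain only 0 and 1", call. = FALSE)
  }
  if (!all(is.finite(data$rt) & data$rt > 0)) {
    stop("'rt' must be finite and positive", call. = FALSE)
  }
  data
}

#' Bayesian information criterion
#'
#' `BIC = -2 LL + P log(M)` with `P` free parameters and `M` trials; lower
#' values indicate the better model.
#'
#' @param LL Maximized log-likelihood.
#' @param P Number of free parameters (>= 0).
#' @param M Number of trials (>= 1).
#' @return The BIC value.
#' @examples
#' bic(-500, 7, 200)  # 1000 + 7 log(200)
#' @export
bic <- function(LL, P, M) {
  stopifnot(M >= 1, P >= 0)
  -2 * LL + P * log(M)
}

#' Quantile bins for the chi-square criterion
#'
#' Splits the response times observed at one threshold into 6 bins bounded by
#' the empirical 0.1, 0.3, 0.5, 0.7 and 0.9 quantiles (linear interpolation
#' between order statistics). The observed counts always sum to the number of
#' response times, also with tied or degenerate edges.
#'
#' @param rts Response times observed at one threshold.
#' @return A list with `edges` (5 interior bin borders) and `counts`
#'   (6 observed counts).
#' @export
cs_bins <- function(rts) {
  probs <- c(0.1, 0.3, 0.5, 0.7, 0.9)
  edges <- stats::quantile(rts, probs, names = FALSE, type = 7)
  below <- vapply(edges, function(e) sum(rts <= e), numeric(1))
  counts <- diff(c(0, below, length(rts)))
  list(edges = edges, counts = counts)
}

#' Chi-square fit statistic
#'
#' Compares observed and predicted trial counts in the quantile bins of both
#' thresholds, summed over condition cells:
#' `CS = sum (o_i - p_i)^2 / p_i`. Predicted counts are joint bin masses
#' (total cell trials times the probability of the response and the bin), so
#' the response frequencies are part of the fit. A threshold observed in fewer
#' than 12 trials within a cell contributes no bins; a cell with no includable
#' threshold anywhere aborts the calculation.
#'
#' @inheritParams log_likelihood
#' @return The summed chi-square statistic.
#' @export
cs_statistic <- function(data, params_by_cell, precision = 3) {
  data <- normalize_trials(data)
  if (inherits(params_by_cell, "dm_params")) {
    params_by_cell <- stats::setNames(list(params_by_cell), unique(data$cell)[1])
  }
  total <- 0
  any_included <- FALSE
  for (cl in unique(data$cell)) {
    p <- params_by_cell[[cl]]
    d <- data[data$cell == cl, ]
    dist <- combined_cdf(p, precision)
    n_cell <- nrow(d)
    for (resp in c(0L, 1L)) {
      rts <- d$rt[d$response == resp]
      if (length(rts) < 12L) next
      any_included <- TRUE
      thr <- if (resp == 1L) "upper" else "lower"
      b <- cs_bins(rts)
      cum <- threshold_cdf(dist, b$edges, thr)
      p_end <- if (resp == 1L) dist$p_up else dist$p_low
      mass <- diff(c(0, cum, p_end))
      pred <- pmax(n_cell * mass, 1e-10)
      total <- total + sum((b$counts - pred)^2 / pred)
    }
  }
  if (!any_included) {
    stop("chi-square criterion: no threshold with at least 12 responses in any condition",
         call. = FALSE)
  }
  total
}

#' Degrees of freedom of the chi-square fit test
#'
#' `df = K (N - 1) - P` for `K` conditions, `N` bins per condition (12 when
#' both thresholds contribute) and `P` free parameters. Non-positive values
#' mark an untestable model.
#'
#' @param K Number of conditions.
#' @param N Bins per condition.
#' @param P Number of free parameters.
#' @return A list with `df` and `testable` (logical, `df > 0`).
#' @export
cs_df <- function(K, N = 12, P) {
  df <- K * (N - 1) - P
  list(df = df, testable = df > 0)
}

#' Kolmogorov-Smirnov distance on the combined distribution
#'
#' Maximum absolute vertical distance between the empirical CDF of the signed
#' response times (lower-threshold RTs negated) and the predicted combined
#' CDF, with the empirical step function evaluated on both sides of each
#' jump.
#'
#' @param data A trials tibble for one condition cell (`response`, `rt`).
#' @param params A [dm_params()] object for that cell.
#' @param precision Precision parameter.
#' @param dist Optional precomputed `dm_dist` for the same parameters.
#' @return The KS distance `D`.
#' @export
ks_statistic <- function(data, params, precision = 3, dist = NULL) {
  data <- normalize_trials(data)
  if (nrow(data) == 0L) stop("empty condition cell", call. = FALSE)
  if (is.null(dist)) dist <- combined_cdf(params, precision)
  tau <- sort(ifelse(data$response == 1, data$rt, -data$rt))
  n <- length(tau)
  pc <- predicted_cdf(dist, tau)
  ec_hi <- seq_len(n) / n
  ec_lo <- (seq_len(n) - 1) / n
  max(abs(ec_hi - pc), abs(ec_lo - pc))
}

#' P-value of a Kolmogorov-Smirnov distance
#'
#' Asymptotic Kolmogorov tail probability with the small-sample adjustment
#' `lambda = (sqrt(n) + 0.12 + 0.11 / sqrt(n)) * D`, evaluated by the
#' alternating exponential series.
#'
#' @param D KS distance in \[0, 1\].
#' @param n Effective number of responses (>= 1).
#' @return A p-value in \[0, 1\], decreasing in `D`.
#' @export
ks_pvalue <- function(D, n) {
  stopifnot(n >= 1, D >= 0, D <= 1)
  if (D == 0) return(1)
  lambda <- (sqrt(n) + 0.12 + 0.11 / sqrt(n)) * D
  j <- seq_len(101)
  terms <- 2 * (-1)^(j - 1) * exp(-2 * j^2 * lambda^2)
  p <- sum(terms)
  min(max(p, 0), 1)
}

#' Aggregate per-condition fit values into a single fit index
#'
#' ML: per-condition log-likelihoods are summed and reported as `-LL`
#' (minimized). CS: chi-square values are summed (minimized). KS: per-condition
#' p-values are multiplied (maximized); the stored `minimized` component is the
#' negative log product so that all three criteria share a minimization
#' orientation.
#'
#' @param method `"ml"`, `"cs"` or `"ks"`.
#' @param values Per-condition values: log-likelihoods for `ml`, chi-square
#'   values for `cs`, p-values for `ks`.
#' @param penalty Optional penalty magnitude (`NULL` or 0 for valid solutions).
#' @return A list of class `dm_fit_index`: `method`, `value` (reporting scale:
#'   -LL, CS, or the p product), `minimized` (the internally minimized
#'   objective), `penalized`, `penalty`, and the per-condition `components`.
#' @examples
#' aggregate_objective("ks", c(0.10, 0.35, 0.12, 0.60))$value  # 0.00252
#' @export
aggregate_objective <- function(method = c("ml", "cs", "ks"), values,
                                penalty = NULL) {
  method <- match.arg(method)
  penalized <- !is.null(penalty) && penalty > 0
  if (penalized) {
    return(structure(list(method = method, value = NA_real_,
                          minimized = Inf, penalized = TRUE,
                          penalty = penalty, components = values),
                     class = "dm_fit_index"))
  }
  out <- switch(method,
    ml = list(value = -sum(values), minimized = -sum(values)),
    cs = list(value = sum(values), minimized = sum(values)),
    ks = {
      prodp <- prod(values)
      list(value = prodp,
           minimized = if (prodp > 0) -sum(log(values)) else Inf)
    })
  structure(c(list(method = method), out,
              list(penalized = FALSE, penalty = 0, components = values)),
            class = "dm_fit_index")
}

#' @export
print.dm_fit_index <- function(x, ...) {
  lab <- switch(x$method, ml = "-LL", cs = "CS", ks = "p(KS)")
  if (x$penalized) {
    cat("<dm_fit_index>", lab, ": penalized (penalty =", format(x$penalty), ")\n")
  } else {
    cat("<dm_fit_index>", lab, "=", format(x$value), "\n")
  }
  invisible(x)
}
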