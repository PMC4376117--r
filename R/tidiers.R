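## broom-style accessors and ggplot2 autoplot methods.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @importFrom tibble as_tibble
#' @export
tibble::as_tibble

#' Tidy the parameter estimates of a fit
#'
#' @param x A `dm_fit` object.
#' @param ... Unused.
#' @return A tibble with one row per parameter slot: `term` (slot name, with
#'   condition suffix for condition-dependent parameters), `parameter` (the
#'   underlying model parameter), `estimate`, and `fixed` (logical; fixed
#'   parameters are included with their set values).
#' @export
tidy.dm_fit <- function(x, ...) {
  free <- tibble::tibble(term = x$ptable$slots$slot,
                         parameter = x$ptable$slots$param,
                         estimate = unname(x$estimates),
                         fixed = FALSE)
  if (length(x$spec$fixed)) {
    fixed <- tibble::tibble(term = names(x$spec$fixed),
                            parameter = names(x$spec$fixed),
                            estimate = unlist(x$spec$fixed),
                            fixed = TRUE)
    free <- dplyr::bind_rows(free, fixed)
  }
  free
}

#' One-row summary of a fit
#'
#' @param x A `dm_fit` object.
#' @param ... Unused.
#' @return A tibble with `method`, `fit` (the reporting-scale index: -LL, CS
#'   or the KS p product), `penalized`, `penalty`, `n_trials`, `n_free`, and
#'   `bic` (for ML fits; `NA` otherwise).
#' @export
glance.dm_fit <- function(x, ...) {
  bic_val <- if (x$method == "ml" && !x$index$penalized) {
    bic(-x$index$value, x$ptable$P, x$n_trials)
  } else NA_real_
  tibble::tibble(method = x$method,
                 fit = if (x$index$penalized) NA_real_ else x$index$value,
                 penalized = x$index$penalized,
                 penalty = x$index$penalty,
                 n_trials = x$n_trials,
                 n_free = x$ptable$P,
                 bic = bic_val)
}

#' Plot a predicted combined CDF
#'
#' @param object A `dm_dist` object from [combined_cdf()].
#' @param ... Unused.
#' @return A ggplot: the combined CDF over signed response time (negative
#'   times are lower-threshold responses).
#' @export
autoplot.dm_dist <- function(object, ...) {
  tab <- as_tibble.dm_dist(object)
  ggplot2::ggplot(tab, ggplot2::aes(x = .data$time, y = .data$cdf)) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = 0, linetype = 3) +
    ggplot2::labs(x = "signed response time (s)", y = "combined CDF")
}

#' Plot predicted against empirical combined CDFs of a fit
#'
#' @param object A `dm_fit` object.
#' @param data The trials data the model was fitted to.
#' @param ... Unused.
#' @return A ggplot: per condition cell, the empirical signed-time CDF (steps)
#'   overlaid with the fitted model's combined CDF (line).
#' @export
autoplot.dm_fit <- function(object, data, ...) {
  data <- assign_cells(data, object$spec)
  params <- expand_theta(object$estimates, object$ptable)
  pieces <- lapply(names(params), function(cl) {
    d <- data[data$cell == cl, ]
    if (nrow(d) == 0L) return(NULL)
    tau <- sort(ifelse(d$response == 1, d$rt, -d$rt))
    dist <- combined_cdf(params[[cl]], object$precision)
    grid <- as_tibble.dm_dist(dist, t_step = 5e-3)
    dplyr::bind_rows(
      tibble::tibble(cell = cl, time = tau,
                     cdf = seq_along(tau) / length(tau), kind = "empirical"),
      tibble::tibble(cell = cl, time = grid$time, cdf = grid$cdf,
                     kind = "predicted"))
  })
  tab <- dplyr::bind_rows(pieces)
  ggplot2::ggplot(tab, ggplot2::aes(x = .data$time, y = .data$cdf)) +
    ggplot2::geom_step(data = function(d) d[d$kind == "empirical", ]) +
    ggplot2::geom_line(data = function(d) d[d$kind == "predicted", ],
                       colour = "red3") +
    ggplot2::facet_wrap(~cell) +
    ggplot2::labs(x = "signed response time (s)", y = "combined CDF")
}
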