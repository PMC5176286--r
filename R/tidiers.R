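# broom-style tidiers and ggplot2 autoplot methods for the result types.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a fitted modular component
#'
#' One row per node x module with the module weight; zero-weight rows can
#' be dropped.
#'
#' @param x an `mcf_component`.
#' @param drop_zero drop rows with zero weight (default `TRUE`).
#' @param ... unused.
#' @return tibble with columns `node_id`, `module`, `weight`.
#' @method tidy mcf_component
#' @export
tidy.mcf_component <- function(x, drop_zero = TRUE, ...) {
  out <- tibble::tibble(
    node_id = rep(x$node_labels, times = x$K),
    module = rep(seq_len(x$K), each = length(x$node_labels)),
    weight = as.numeric(x$W))
  if (drop_zero) out <- out[out$weight != 0, ]
  out
}

#' @rdname tidy.mcf_component
#' @method glance mcf_component
#' @export
glance.mcf_component <- function(x, ...) {
  tibble::tibble(K = x$K, objective = x$objective,
                 init_objective = x$init_objective,
                 iterations = x$iterations, converged = x$converged)
}

#' Tidy a fitted modular factorization model
#'
#' @param x an `mcf_model`.
#' @param ... passed to the component tidier.
#' @return tibble with columns `component`, `node_id`, `module`, `weight`.
#' @method tidy mcf_model
#' @export
tidy.mcf_model <- function(x, ...) {
  dplyr::bind_rows(lapply(seq_along(x$components), function(m) {
    dplyr::mutate(tidy(x$components[[m]], ...), component = m,
                  .before = 1)
  }))
}

#' @rdname tidy.mcf_model
#' @method glance mcf_model
#' @export
glance.mcf_model <- function(x, ...) {
  tibble::tibble(
    K = x$K, M = x$M,
    total_variance = x$total_variance,
    adjusted_variance = max(x$adjusted$cumulative_adjusted),
    prop_explained = max(x$adjusted$cumulative_adjusted) / x$total_variance,
    all_converged = all(vapply(x$components, `[[`, logical(1), "converged")))
}

#' Plot an eigenvalue spectrum
#'
#' Squared-eigenvalue proportions and their cumulative sum, the diagnostic
#' used to choose the number of modules K.
#'
#' @param object tibble from [eigen_spectrum()].
#' @param top number of leading eigenvalues to display.
#' @param ... unused.
#' @return a ggplot.
#' @method autoplot mcf_spectrum
#' @export
autoplot.mcf_spectrum <- function(object, top = 20, ...) {
  autoplot_spectrum(object, top)
}

#' @rdname autoplot.mcf_spectrum
#' @param spectrum tibble from [eigen_spectrum()].
#' @export
autoplot_spectrum <- function(spectrum, top = 20) {
  df <- utils::head(spectrum, top)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$index)) +
    ggplot2::geom_col(ggplot2::aes(y = .data$squared_proportion),
                      fill = "grey40") +
    ggplot2::geom_line(ggplot2::aes(y = .data$squared_cumulative),
                       color = "steelblue") +
    ggplot2::geom_point(ggplot2::aes(y = .data$squared_cumulative),
                        color = "steelblue") +
    ggplot2::labs(x = "eigenvalue index",
                  y = "squared proportion / cumulative") +
    ggplot2::theme_minimal()
}

#' Plot a benchmark table
#'
#' Mean recovery error against sample size (log scale) per method, one
#' panel per condition x component, with one-SD error bars.
#'
#' @param object a tibble from [run_benchmark()].
#' @param ... unused.
#' @return a ggplot.
#' @method autoplot mcf_benchmark
#' @export
autoplot.mcf_benchmark <- function(object, ...) {
  summ <- summarize_benchmark(object)
  ggplot2::ggplot(summ,
                  ggplot2::aes(x = .data$N, y = .data$mean_error,
                               color = .data$method,
                               group = .data$method)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::geom_errorbar(
      ggplot2::aes(ymin = pmax(.data$mean_error - .data$sd_error, 0),
                   ymax = .data$mean_error + .data$sd_error),
      width = 0.05) +
    ggplot2::scale_x_log10() +
    ggplot2::facet_grid(component ~ condition) +
    ggplot2::labs(x = "sample size N", y = "recovery error") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @importFrom rlang .data
NULL
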