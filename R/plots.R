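#' Plot methods
#'
#' `autoplot.history_contrasts()` draws the contrast estimates with their 90%
#' (thick) and 95% (thin) percentile intervals against a zero reference line;
#' `autoplot.structure_slopes()` does the same for the slopes;
#' `autoplot.flux_result()` shows the per-function flux decomposition of one
#' mesocosm.
#'
#' @param object a fitted object.
#' @param ... ignored.
#' @return A ggplot object.
#' @name soilflux-autoplot
NULL

#' @rdname soilflux-autoplot
#' @export
autoplot.history_contrasts <- function(object, ...) {
  tab <- object$contrasts
  tab$contrast <- factor(tab$contrast, rev(tab$contrast))
  ggplot2::ggplot(tab, ggplot2::aes(x = .data$estimate, y = .data$contrast)) +
    ggplot2::geom_vline(xintercept = 0, linetype = 2, colour = "grey50") +
    ggplot2::geom_linerange(ggplot2::aes(xmin = .data$lower_95,
                                         xmax = .data$upper_95),
                            linewidth = 0.4) +
    ggplot2::geom_linerange(ggplot2::aes(xmin = .data$lower_90,
                                         xmax = .data$upper_90),
                            linewidth = 1.1) +
    ggplot2::geom_point(ggplot2::aes(colour = .data$decision), size = 2.5) +
    ggplot2::labs(
      x = paste0("difference in ",
                 if (object$transform == "log") "log " else "",
                 object$response),
      y = NULL, colour = "decision",
      title = paste0("History contrasts: ", object$response),
      subtitle = paste0("hierarchical bootstrap, ", object$n_boot,
                        " draws; thick = 90%, thin = 95% interval")) +
    ggplot2::theme_minimal()
}

#' @rdname soilflux-autoplot
#' @export
autoplot.structure_slopes <- function(object, ...) {
  tab <- object$slopes
  ggplot2::ggplot(tab, ggplot2::aes(x = .data$estimate, y = .data$predictor)) +
    ggplot2::geom_vline(xintercept = 0, linetype = 2, colour = "grey50") +
    ggplot2::geom_linerange(ggplot2::aes(xmin = .data$lower_95,
                                         xmax = .data$upper_95),
                            linewidth = 0.4) +
    ggplot2::geom_linerange(ggplot2::aes(xmin = .data$lower_90,
                                         xmax = .data$upper_90),
                            linewidth = 1.1) +
    ggplot2::geom_point(size = 2.5) +
    ggplot2::labs(x = paste0("slope of log ", object$response,
                             " on standardized log predictor"),
                  y = NULL,
                  title = "Flux-structure slopes") +
    ggplot2::theme_minimal()
}

#' @rdname soilflux-autoplot
#' @export
autoplot.flux_result <- function(object, ...) {
  agg <- object$aggregates
  tab <- tibble::tibble(
    function_name = factor(names(agg)[-1], names(agg)[-1]),
    flux = unname(agg[-1]))
  ggplot2::ggplot(tab, ggplot2::aes(x = .data$function_name, y = .data$flux)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(x = NULL, y = "energy flux (J/h per mesocosm)",
                  title = paste0("Flux decomposition",
                                 if (!is.null(object$mesocosm_id)) {
                                   paste0(": ", object$mesocosm_id)
                                 } else ""),
                  subtitle = paste0("total = ",
                                    signif(agg[["total"]], 4), " J/h")) +
    ggplot2::theme_minimal()
}

#' Treatment-level summary plot of per-mesocosm responses
#'
#' Jittered per-mesocosm values by history treatment with the bootstrap
#' treatment means and 95% intervals from a [pairwise_contrasts()] fit.
#'
#' @param data per-mesocosm tibble with `history` and the response column.
#' @param fit the matching `history_contrasts` object.
#' @return A ggplot object.
#' @export
plot_treatment_response <- function(data, fit) {
  stopifnot(inherits(fit, "history_contrasts"))
  y <- data[[fit$response]]
  if (fit$transform == "log") y <- log(y)
  pts <- tibble::tibble(history = data$history, value = y)
  ggplot2::ggplot(pts, ggplot2::aes(x = .data$history, y = .data$value)) +
    ggplot2::geom_jitter(width = 0.15, alpha = 0.4, colour = "grey40") +
    ggplot2::geom_pointrange(
      data = fit$treatment_means,
      ggplot2::aes(x = .data$history, y = .data$mean,
                   ymin = .data$lower_95, ymax = .data$upper_95),
      colour = "black", linewidth = 0.8, size = 0.5) +
    ggplot2::labs(x = "community history",
                  y = paste0(if (fit$transform == "log") "log " else "",
                             fit$response)) +
    ggplot2::theme_minimal()
}
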