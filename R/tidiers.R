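#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy methods for design results
#'
#' `tidy()` returns the per-step optimization trace; `glance()` a one-row
#' summary; `autoplot()` the loss curve.
#'
#' @param x a `design_result` or `mrna_design_result`.
#' @param ... unused.
#' @return a tibble (or a ggplot for `autoplot`).
#' @name design-tidiers
NULL

#' @rdname design-tidiers
#' @export
tidy.design_result <- function(x, ...) x$trace

#' @rdname design-tidiers
#' @export
glance.design_result <- function(x, ...) {
  tibble(method = x$method, n = x$target$n, steps = x$steps,
         learning_rate = x$learning_rate, seed = x$seed,
         param_count = x$param_count,
         final_loss = x$trace$loss[nrow(x$trace)],
         best_loss = x$best_loss,
         sequence = x$sequence,
         probability = x$probability)
}

#' @rdname design-tidiers
#' @export
tidy.mrna_design_result <- function(x, ...) x$trace

#' @rdname design-tidiers
#' @export
glance.mrna_design_result <- function(x, ...) {
  tibble(protein = x$protein, steps = x$steps, seed = x$seed,
         sequence = x$sequence, efe = x$efe, cai = x$cai,
         coding_probability = x$coding_probability,
         picked_step = x$picked_step,
         warm_start_efe = if (is.null(x$warm_start)) NA_real_
                          else x$warm_start$efe)
}

#' @rdname design-tidiers
#' @export
autoplot.design_result <- function(x, ...) {
  ggplot2::ggplot(x$trace, ggplot2::aes(x = .data$step, y = .data$loss)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "step", y = "design loss",
                  title = paste0(x$method, " optimization, n = ", x$target$n)) +
    ggplot2::theme_minimal()
}

#' @rdname design-tidiers
#' @export
autoplot.mrna_design_result <- function(x, ...) {
  df <- tidyr::pivot_longer(
    x$trace[, c("step", "loss", "decoded_efe", "expected_cai", "coding_prob")],
    -"step", names_to = "quantity", values_to = "value")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$step, y = .data$value)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~quantity, scales = "free_y") +
    ggplot2::labs(x = "step", title = paste("stability-CAI design:", x$protein)) +
    ggplot2::theme_minimal()
}

#' @importFrom rlang .data
NULL
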