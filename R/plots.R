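#' Plot an optimization trace
#'
#' Loss and predicted property value against iteration; points where the
#' search decoded a molecule (Algorithm B projections) are marked.
#'
#' @param object A `jtprop_trace` (from [optimize_A()] / [optimize_B()]).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.jtprop_trace <- function(object, ...) {
  df <- tibble::tibble(
    iteration = rep(object$iteration, 2L),
    value = c(object$loss, object$predicted),
    panel = rep(c("loss", "predicted value"), each = nrow(object)),
    decoded = rep(!is.na(object$smiles), 2L)
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$iteration, y = .data$value)) +
    ggplot2::geom_line(colour = "grey40") +
    ggplot2::geom_point(data = df[df$decoded, , drop = FALSE],
                        colour = "firebrick", size = 2) +
    ggplot2::facet_wrap(~panel, scales = "free_y", ncol = 1L) +
    ggplot2::labs(x = "iteration", y = NULL,
                  title = "latent-space property optimization",
                  subtitle = "red points: decoded molecules (re-encode projections)") +
    ggplot2::theme_minimal()
}

#' Plot a training loss history
#'
#' @param model A trained `jtprop_model`.
#' @param which Which history entry to plot (default "vae").
#' @return A ggplot object.
#' @export
plot_training_history <- function(model, which = "vae") {
  h <- model$history[[which]]
  if (is.null(h)) stop(sprintf("model has no '%s' training history", which),
                       call. = FALSE)
  h$x <- seq_len(nrow(h))
  p <- ggplot2::ggplot(h, ggplot2::aes(x = .data$x, y = .data$loss)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "epoch", y = "loss",
                  title = sprintf("%s training loss", which)) +
    ggplot2::theme_minimal()
  if ("phase" %in% names(h)) {
    p <- p + ggplot2::aes(colour = factor(.data$phase)) +
      ggplot2::labs(colour = "phase")
  }
  p
}
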