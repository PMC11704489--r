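# broom-style tidiers and ggplot2 displays for the result objects.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a metrics report
#'
#' @param x a `metrics_report` from [evaluate_cases()] or [evaluate_model()].
#' @param ... unused.
#' @return tibble with one row per evaluated class.
#' @method tidy metrics_report
#' @export
tidy.metrics_report <- function(x, ...) {
  x$per_class
}

#' @rdname tidy.metrics_report
#' @return `glance()`: one-row tibble with the summary metrics.
#' @method glance metrics_report
#' @export
glance.metrics_report <- function(x, ...) {
  tibble::tibble(mean_dsc = x$mean_dsc, mean_hd = x$mean_hd,
                 AC = x$AC, PR = x$PR, SP = x$SP)
}

#' Tidy a training fit
#'
#' @param x an `mipc_fit` from [train_model()].
#' @param ... unused.
#' @return the per-epoch history tibble (epoch, loss, dice).
#' @method tidy mipc_fit
#' @export
tidy.mipc_fit <- function(x, ...) {
  x$history
}

#' @rdname tidy.mipc_fit
#' @method glance mipc_fit
#' @export
glance.mipc_fit <- function(x, ...) {
  h <- x$history
  d <- h$dice[!is.na(h$dice)]
  tibble::tibble(epochs = nrow(h), final_loss = h$loss[nrow(h)],
                 best_loss = min(h$loss),
                 final_dice = if (length(d)) d[length(d)] else NA_real_,
                 n_params = n_parameters(x$model$layers))
}

#' Plot a training curve
#'
#' @param object an `mipc_fit`.
#' @param ... unused.
#' @return a ggplot object showing loss per epoch (and Dice where logged).
#' @method autoplot mipc_fit
#' @export
autoplot.mipc_fit <- function(object, ...) {
  h <- object$history
  p <- ggplot2::ggplot(h, ggplot2::aes(x = .data$epoch, y = .data$loss)) +
    ggplot2::geom_line(colour = "steelblue") +
    ggplot2::labs(x = "epoch", y = "compound loss",
                  title = "Training loss") +
    ggplot2::theme_minimal()
  if (any(!is.na(h$dice))) {
    hd <- h[!is.na(h$dice), ]
    p <- p + ggplot2::geom_line(
      data = hd, ggplot2::aes(y = .data$dice), colour = "darkorange",
      linetype = "dashed")
  }
  p
}

#' Plot per-class metrics
#'
#' @param object a `metrics_report`.
#' @param ... unused.
#' @return a ggplot bar chart of per-class Dice.
#' @method autoplot metrics_report
#' @export
autoplot.metrics_report <- function(object, ...) {
  ggplot2::ggplot(object$per_class,
                  ggplot2::aes(x = factor(.data$class), y = .data$mean_dsc)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = "class", y = "mean Dice",
                  title = "Per-class Dice") +
    ggplot2::theme_minimal()
}

#' Display phantoms
#'
#' @param object a `phantom_dataset`.
#' @param n how many images to show.
#' @param ... unused.
#' @return a ggplot raster panel of images and their label masks.
#' @method autoplot phantom_dataset
#' @export
autoplot.phantom_dataset <- function(object, n = 4L, ...) {
  n <- min(n, length(object))
  dfs <- lapply(seq_len(n), function(i) {
    img <- object[[i]]$image
    msk <- object[[i]]$mask
    sz <- nrow(img)
    grid <- expand.grid(row = seq_len(sz), col = seq_len(sz))
    rbind(
      tibble::tibble(image = i, panel = "image", row = grid$row,
                     col = grid$col, value = as.vector(img)),
      tibble::tibble(image = i, panel = "mask", row = grid$row,
                     col = grid$col, value = as.vector(msk) / max(1, max(msk)))
    )
  })
  df <- do.call(rbind, dfs)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$col, y = .data$row,
                                   fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_reverse() +
    ggplot2::facet_grid(panel ~ image) +
    ggplot2::scale_fill_viridis_c(guide = "none") +
    ggplot2::coord_fixed() +
    ggplot2::theme_void()
}

#' @importFrom ggplot2 autoplot .data
#' @export
ggplot2::autoplot
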