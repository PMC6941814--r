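# Sequence-logo rendering. Letters are built from simple stroke and
# ring polygons so the package has no dependency beyond ggplot2.

stroke_poly <- function(x0, y0, x1, y1, w = 0.18) {
  dx <- x1 - x0; dy <- y1 - y0
  len <- sqrt(dx^2 + dy^2)
  nx <- -dy / len * w / 2; ny <- dx / len * w / 2
  data.frame(x = c(x0 + nx, x1 + nx, x1 - nx, x0 - nx),
             y = c(y0 + ny, y1 + ny, y1 - ny, y0 - ny))
}

ring_poly <- function(th0, th1, r_out = 0.48, r_in = 0.30, n = 36) {
  th <- seq(th0, th1, length.out = n) * pi / 180
  data.frame(x = 0.5 + c(r_out * cos(th), rev(r_in * cos(th))),
             y = 0.5 + c(r_out * sin(th), rev(r_in * sin(th))))
}

letter_polys <- function() {
  part <- function(df, id) {
    df$x <- pmin(pmax(df$x, 0), 1)
    df$y <- pmin(pmax(df$y, 0), 1)
    df$part <- id
    df
  }
  list(
    A = rbind(part(stroke_poly(0.06, 0, 0.5, 1), 1),
              part(stroke_poly(0.94, 0, 0.5, 1), 2),
              part(stroke_poly(0.25, 0.32, 0.75, 0.32, w = 0.14), 3)),
    C = part(ring_poly(45, 315), 1),
    G = rbind(part(ring_poly(40, 320), 1),
              part(stroke_poly(0.58, 0.40, 0.95, 0.40, w = 0.15), 2),
              part(stroke_poly(0.90, 0.40, 0.90, 0.12, w = 0.15), 3)),
    T = rbind(part(stroke_poly(0.5, 0, 0.5, 0.92), 1),
              part(stroke_poly(0.04, 0.91, 0.96, 0.91, w = 0.17), 2)))
}

logo_colors <- c(A = "#109648", C = "#255C99", G = "#F7B32B",
                 T = "#D62839")

logo_data <- function(mat) {
  ic <- information_content(mat)
  letters <- letter_polys()
  out <- list()
  for (i in seq_len(ncol(mat))) {
    h <- mat[, i] * ic[i]
    ord <- order(h)
    y0 <- 0
    for (b in ord) {
      if (h[b] < 1e-3) next
      lp <- letters[[DNA_BASES[b]]]
      out[[length(out) + 1L]] <- data.frame(
        x = i - 0.45 + 0.9 * lp$x, y = y0 + h[b] * lp$y,
        base = DNA_BASES[b],
        id = paste(i, DNA_BASES[b], lp$part, sep = "_"))
      y0 <- y0 + h[b]
    }
  }
  if (!length(out)) return(data.frame(x = numeric(), y = numeric(),
                                      base = character(),
                                      id = character()))
  do.call(rbind, out)
}

logo_plot <- function(mat, title = NULL) {
  d <- logo_data(mat)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$x, y = .data$y,
                                  group = .data$id,
                                  fill = .data$base)) +
    ggplot2::geom_polygon(show.legend = FALSE) +
    ggplot2::scale_fill_manual(values = logo_colors) +
    ggplot2::scale_x_continuous(breaks = seq_len(ncol(mat)),
                                limits = c(0.4, ncol(mat) + 0.6),
                                expand = c(0, 0)) +
    ggplot2::coord_cartesian(ylim = c(0, 2)) +
    ggplot2::labs(x = "position", y = "bits", title = title) +
    ggplot2::theme_classic()
}

#' Sequence logo of a filter PPM
#'
#' Letter heights are `p * IC` per position (bits); a uniform column has
#' zero height, a deterministic one reaches 2 bits.
#'
#' @param object A `filter_ppm`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.filter_ppm <- function(object, ...) {
  if (isTRUE(object$empty)) stop("cannot plot an empty PPM")
  logo_plot(object$matrix,
            sprintf("layer %d filter %d (%d sites)", object$layer,
                    object$filter_index, object$n_sites))
}

#' Sequence logo of a motif PWM
#'
#' @param object A `motif_pwm`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.motif_pwm <- function(object, ...) {
  logo_plot(object$matrix, object$name)
}

#' Render a sequence logo to an image file
#'
#' @param ppm A `filter_ppm` or `motif_pwm`.
#' @param path Output image path (format from extension, e.g. `.png`).
#' @param width,height Device size in inches.
#' @return `path`, invisibly.
#' @export
render_logo <- function(ppm, path, width = 5, height = 1.8) {
  p <- autoplot(ppm)
  ggplot2::ggsave(path, p, width = width, height = height, dpi = 150)
  invisible(path)
}

#' Training-history curves
#'
#' @param object A trained `cnn_model`.
#' @param ... Unused.
#' @return A ggplot of train and validation loss per epoch.
#' @export
autoplot.cnn_model <- function(object, ...) {
  d <- tidy(object) |>
    tidyr::pivot_longer(c("train_loss", "val_loss"), names_to = "set",
                        values_to = "loss")
  ggplot2::ggplot(d, ggplot2::aes(.data$epoch, .data$loss,
                                  color = .data$set)) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = object$best_epoch,
                        linetype = "dashed", color = "grey50") +
    ggplot2::labs(title = object$spec$name, color = NULL) +
    ggplot2::theme_classic()
}
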