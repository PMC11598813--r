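# Quick-look base-graphics plots.

#' Plot a beat trace
#'
#' @param samples Beat amplitude vector.
#' @param fs Sampling rate in Hz.
#' @param ... Passed to [graphics::plot()].
#' @return Invisibly, `NULL`.
#' @export
plot_beat <- function(samples, fs = 360, ...) {
  graphics::plot((seq_along(samples) - 1) / fs, samples, type = "l",
                 xlab = "time (s)", ylab = "amplitude (a.u.)", ...)
  invisible(NULL)
}

#' Plot a binary beat image
#'
#' @param image 0/1 matrix (row 1 = top).
#' @param ... Passed to [graphics::image()].
#' @return Invisibly, `NULL`.
#' @export
plot_image <- function(image, ...) {
  m <- t(image[rev(seq_len(nrow(image))), , drop = FALSE])
  graphics::image(m, col = c("white", "black"), axes = FALSE, asp = 1, ...)
  invisible(NULL)
}

#' Plot a training log
#'
#' @param w A trained `bdscnn_weights` object with a `log` field.
#' @param ... Passed to [graphics::plot()].
#' @return Invisibly, `NULL`.
#' @export
plot_training <- function(w, ...) {
  stopifnot(inherits(w, "bdscnn_weights"), !is.null(w$log))
  lg <- w$log
  graphics::plot(lg$epoch, lg$train_loss, type = "l", xlab = "epoch",
                 ylab = "loss", ylim = range(c(lg$train_loss, lg$val_loss)),
                 ...)
  graphics::lines(lg$epoch, lg$val_loss, lty = 2)
  graphics::legend("topright", c("train", "validation"), lty = 1:2,
                   bty = "n")
  invisible(NULL)
}
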