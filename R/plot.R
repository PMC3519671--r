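#' Plot a smoothed hook curve
#' @param x a `hook_curve`.
#' @param fit optional `hook_fit` whose theoretical curve is overlaid.
#' @param ... passed to [graphics::plot()].
#' @export
plot.hook_curve <- function(x, fit = NULL, ...) {
  graphics::plot(x$sigma, x$delta, type = "l", lwd = 2,
                 xlab = expression(Sigma), ylab = expression(Delta),
                 main = "Hook curve", ...)
  if (!is.null(fit)) {
    g <- .hook_grid(fit)
    graphics::lines(g$sigma, g$delta, col = "red", lty = 2)
    graphics::legend("topright", c("smoothed", "model"),
                     col = c("black", "red"), lty = c(1, 2), bty = "n")
  }
  invisible(x)
}

#' Plot the tongs branches
#' @param x a `tongs_curve` from [tongs_and_deghook()].
#' @param ... passed to [graphics::matplot()].
#' @export
plot.tongs_curve <- function(x, ...) {
  graphics::matplot(x$sigma, cbind(x$dsig_3, x$dsig_m, x$dsig_5),
                    type = "l", lty = 1, col = c("red", "grey40", "blue"),
                    xlab = expression(Sigma), ylab = expression(Delta * Sigma[s]),
                    main = "Tongs plot", ...)
  graphics::abline(h = 0, lty = 3)
  graphics::legend("topleft", c("3'", "middle", "5'"),
                   col = c("red", "grey40", "blue"), lty = 1, bty = "n")
  invisible(x)
}

#' Plot the degradation hook
#' @param x a `deghook_curve` from [tongs_and_deghook()].
#' @param ... passed to [graphics::plot()].
#' @export
plot.deghook_curve <- function(x, ...) {
  graphics::plot(x$sigma, x$dsig_35, type = "l", lwd = 2, col = "darkgreen",
                 xlab = expression(Sigma),
                 ylab = expression(Delta * Sigma["3'/5'"]),
                 main = "Degradation hook", ...)
  graphics::abline(h = 0, lty = 3)
  invisible(x)
}

#' Plot a positional decay profile
#' @param x a `decay_profile`.
#' @param fit optional `decay_fit` overlay.
#' @param ... passed to [graphics::plot()].
#' @export
plot.decay_profile <- function(x, fit = NULL, ...) {
  xl <- if (attr(x, "scale") == "k") "probe index k" else "distance L (nt)"
  graphics::plot(x$x, x$d, pch = 19,
                 xlab = xl, ylab = "d(x)",
                 main = paste0("Positional decay (", attr(x, "subset"),
                               " ensemble)"), ...)
  if (!is.null(fit)) {
    xx <- seq(min(x$x), max(x$x), length.out = 200)
    graphics::lines(xx, predict(fit, xx), col = "red")
  }
  invisible(x)
}
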