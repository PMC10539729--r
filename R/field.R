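#' Static field and gyromagnetic configuration
#'
#' Collects the applied magnetic field, its direction in the molecular frame,
#' and the gyromagnetic ratios entering all couplings.  The lab frame is
#' completed deterministically: \code{z} along the field, \code{x} the
#' projection of a fixed reference axis onto the plane perpendicular to
#' \code{z}, and \code{y = z x x}.  All frequencies are carried in angular
#' units (rad/s).
#'
#' @param B0 magnetic field in tesla.  Default 3.38 T (W band).
#' @param direction field direction in the molecular frame (length-3 vector,
#'   need not be normalized).
#' @param g_e electron g value; the free-electron value by default.
#' @return An object of class \code{field_config} with elements \code{B0},
#'   \code{g_e}, \code{gamma_e}, \code{gamma_H} (rad/s/T), \code{omega_I}
#'   (proton Zeeman angular frequency, rad/s) and the orthonormal lab frame
#'   \code{x}, \code{y}, \code{z}.
#' @examples
#' fc <- field_config()
#' fc$omega_I / (2 * pi) / 1e6  # proton Larmor frequency in MHz at 3.38 T
#' @export
field_config <- function(B0 = 3.38, direction = c(0, 0, 1),
                         g_e = .ccecho_const$g_e) {
  stopifnot(is.numeric(B0), length(B0) == 1L, B0 > 0,
            is.numeric(direction), length(direction) == 3L,
            all(is.finite(direction)), any(direction != 0))
  z <- direction / sqrt(sum(direction^2))
  ref <- if (abs(z[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  x <- ref - sum(ref * z) * z
  x <- x / sqrt(sum(x^2))
  y <- c(z[2] * x[3] - z[3] * x[2],
         z[3] * x[1] - z[1] * x[3],
         z[1] * x[2] - z[2] * x[1])
  gamma_e <- g_e * .ccecho_const$muB / .ccecho_const$hbar
  structure(list(B0 = B0, g_e = g_e,
                 gamma_e = gamma_e,
                 gamma_H = .ccecho_const$gamma_H,
                 omega_I = .ccecho_const$gamma_H * B0,
                 x = x, y = y, z = z),
            class = "field_config")
}

#' @export
print.field_config <- function(x, ...) {
  cat(sprintf("<field_config> B0 = %.4g T along (%.3f, %.3f, %.3f)\n",
              x$B0, x$z[1], x$z[2], x$z[3]))
  cat(sprintf("  proton Larmor: %.4f MHz; g_e = %.5f\n",
              x$omega_I / (2 * pi) / 1e6, x$g_e))
  invisible(x)
}
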