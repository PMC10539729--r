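#' Second-order linked-cluster exponent of the refocused echo
#'
#' Evaluates the pair-correlation (second order in the nucleus-nucleus
#' couplings) exponent of the refocused echo,
#' \deqn{\langle V_2 \rangle = -\sum_{m \ne n} \frac{2 b_{mn}^2}
#'   {\omega_{mn}^2} (\cos \omega_{mn} \tau_1 - \cos \omega_{mn} \tau_2)^2,
#'   \qquad \omega_{mn} = (A_m - A_n)/2,}
#' summed over ordered pairs, with \code{A} the secular hyperfine
#' couplings (pseudo-secular components are excluded from the analytic
#' model).  Degenerate pairs (\code{omega_mn = 0}) contribute zero, their
#' continuous limit.  The ordered-sum normalization is the one that
#' matches the perturbative pair limit \code{ln V -> <V2>} as \code{b -> 0}.
#' The exponent is nonpositive everywhere and exactly zero on the diagonal
#' \code{tau1 = tau2}.
#'
#' @param couplings a \code{\link{coupling_set}}.
#' @param tau1,tau2 delay grids in seconds.
#' @param details when TRUE, attach a \code{pairs} attribute tabulating
#'   \code{omega_mn} and \code{b_mn} (rad/s) per unordered pair.
#' @return Matrix \code{V2[i, j]} on the grid (a scalar if both grids have
#'   length one).
#' @export
v2_map <- function(couplings, tau1, tau2, details = FALSE) {
  stopifnot(inherits(couplings, "coupling_set"))
  n <- couplings$n
  n1 <- length(tau1); n2 <- length(tau2)
  V2 <- matrix(0, n1, n2)
  pairs <- NULL
  if (n >= 2L) {
    ij <- which(upper.tri(couplings$b), arr.ind = TRUE)
    b <- couplings$b[ij]
    om <- (couplings$A_zz[ij[, 1L]] - couplings$A_zz[ij[, 2L]]) / 2
    if (details)
      pairs <- data.frame(m = ij[, 1L], n = ij[, 2L], omega_mn = om,
                          b_mn = b)
    act <- which(b != 0 & om != 0)
    for (p in act) {
      d <- outer(cos(om[p] * tau1), cos(om[p] * tau2), "-")
      ## x2: ordered pairs
      V2 <- V2 - 2 * (2 * b[p]^2 / om[p]^2) * d * d
    }
  }
  if (n1 == 1L && n2 == 1L) V2 <- V2[1L, 1L]
  if (details) attr(V2, "pairs") <- pairs
  V2
}

#' Factorize an echo map into its second-order exponent and residual
#'
#' Splits a simulated (or measured) refocused echo map as
#' \code{V = exp(<V2>) * f}: the second-order linked-cluster factor
#' captures the dynamical-decoupling structure along the diagonal, while
#' the residual \code{f} collects all higher orders in the
#' nucleus-nucleus couplings and carries the decay along the total
#' evolution time.  Since \code{exp(-<V2>) >= 1} the division is safe.
#'
#' @param map an \code{\link{echo_map}} (or plain matrix on the same grid).
#' @param V2 the exponent map from \code{\link{v2_map}} on the same grid.
#' @return An object of class \code{analytic_factorization}: list with
#'   \code{V2}, \code{exp_V2}, \code{f}, and the delay axes.
#' @export
factorize <- function(map, V2) {
  if (inherits(map, "echo_map")) {
    V <- map$V; tau1 <- map$tau1; tau2 <- map$tau2
  } else {
    V <- as.matrix(map); tau1 <- NULL; tau2 <- NULL
  }
  V2 <- as.matrix(V2)
  if (!all(dim(V) == dim(V2)))
    stop("echo map and V2 map are on different grids")
  structure(list(V2 = V2, exp_V2 = exp(V2), f = V * exp(-V2),
                 tau1 = tau1, tau2 = tau2),
            class = "analytic_factorization")
}

#' @export
print.analytic_factorization <- function(x, ...) {
  cat(sprintf("<analytic_factorization> %d x %d grid, min exp(V2) = %.4g, f range [%.4g, %.4g]\n",
              nrow(x$V2), ncol(x$V2), min(x$exp_V2), min(x$f), max(x$f)))
  invisible(x)
}

#' Ridge of slice-wise echo maxima
#'
#' For every fixed \code{tau2} the echo amplitude along \code{tau1} is
#' scanned for its maximum; the discrete argmax is refined by a
#' three-point parabolic fit when it is interior, ties are broken toward
#' smaller \code{tau1}, and an all-flat slice yields \code{tau1* = 0} with
#' a flag.  The locus of these maxima is the optimal first interpulse
#' delay for each second delay.  The transposed ridge (maxima along
#' \code{tau2} for fixed \code{tau1}) is returned as well.
#'
#' @param map an \code{\link{echo_map}}.
#' @return An object of class \code{ridge_curve}: data frames
#'   \code{along_tau1} (columns \code{tau2}, \code{tau1_star}, \code{flag})
#'   and \code{along_tau2} (columns \code{tau1}, \code{tau2_star},
#'   \code{flag}), with the \code{tau1} grid step as attribute
#'   \code{tau1_step}.
#' @export
ridge <- function(map) {
  stopifnot(inherits(map, "echo_map"))
  r1 <- slice_maxima(map$tau1, map$V, margin = 2L)
  r2 <- slice_maxima(map$tau2, map$V, margin = 1L)
  structure(list(along_tau1 = data.frame(tau2 = map$tau2,
                                         tau1_star = r1$xstar,
                                         flag = r1$flag),
                 along_tau2 = data.frame(tau1 = map$tau1,
                                         tau2_star = r2$xstar,
                                         flag = r2$flag)),
            tau1_step = if (length(map$tau1) > 1L)
              median(diff(map$tau1)) else 0,
            tau2_step = if (length(map$tau2) > 1L)
              median(diff(map$tau2)) else 0,
            class = "ridge_curve")
}

## argmax with parabolic sub-grid refinement along rows/columns of V
slice_maxima <- function(x, V, margin) {
  nslice <- if (margin == 2L) ncol(V) else nrow(V)
  xstar <- numeric(nslice)
  flag <- character(nslice)
  for (j in seq_len(nslice)) {
    v <- if (margin == 2L) V[, j] else V[j, ]
    rng <- max(v) - min(v)
    if (rng <= 1e-12 * max(abs(v), 1e-300)) {
      xstar[j] <- 0
      flag[j] <- "flat"
      next
    }
    i <- which.max(v)  # first maximum: ties toward smaller delay
    flag[j] <- "ok"
    if (i > 1L && i < length(v)) {
      den <- v[i - 1L] - 2 * v[i] + v[i + 1L]
      if (den < 0) {
        ## parabola through the three bracketing points (uniform-step form
        ## generalized to the local spacing)
        hl <- x[i] - x[i - 1L]
        hr <- x[i + 1L] - x[i]
        num <- hl^2 * (v[i] - v[i + 1L]) - hr^2 * (v[i] - v[i - 1L])
        xs <- x[i] - 0.5 * num / (hl * (v[i] - v[i + 1L]) +
                                  hr * (v[i] - v[i - 1L]))
        xstar[j] <- if (is.finite(xs) && xs >= x[i - 1L] && xs <= x[i + 1L])
          xs else x[i]
      } else {
        xstar[j] <- x[i]
        flag[j] <- "degenerate"
      }
    } else {
      xstar[j] <- x[i]
      flag[j] <- if (i == 1L) "boundary_low" else "boundary_high"
    }
  }
  list(xstar = xstar, flag = flag)
}

#' @export
print.ridge_curve <- function(x, ...) {
  r <- x$along_tau1
  cat(sprintf("<ridge_curve> %d tau2 slices; tau1* range %.3g-%.3g us\n",
              nrow(r), min(r$tau1_star) * 1e6, max(r$tau1_star) * 1e6))
  invisible(x)
}

#' Onset of the ridge deviation from the diagonal
#'
#' Finds the smallest \code{tau2} at which the slice-wise maximum
#' persistently leaves the dynamical-decoupling diagonal, i.e. at which
#' \code{tau2 - tau1*} exceeds \code{tolerance} for that and all larger
#' \code{tau2} on the grid.
#'
#' @param rc a \code{\link{ridge_curve}}.
#' @param tolerance deviation tolerance in seconds; defaults to one
#'   \code{tau1} grid step.
#' @return The onset \code{tau2} in seconds, or \code{NA_real_} when the
#'   ridge never deviates persistently ("none").
#' @export
deviation_onset <- function(rc, tolerance = NULL) {
  stopifnot(inherits(rc, "ridge_curve"))
  tolerance <- tolerance %||% attr(rc, "tau1_step")
  r <- rc$along_tau1
  dev <- r$tau2 - r$tau1_star
  ok <- dev > tolerance
  if (!any(ok)) return(NA_real_)
  tail_ok <- rev(cumprod(rev(ok))) > 0  # TRUE for the trailing all-ok run
  if (!tail_ok[length(tail_ok)] || !any(tail_ok)) return(NA_real_)
  r$tau2[which(tail_ok)[1L]]
}
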