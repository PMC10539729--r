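#' Two-dimensional echo map container
#'
#' Echo amplitude \code{V[i, j] = V(tau1[i], tau2[j])} on strictly
#' increasing delay axes, normalized so that \code{V = 1} at zero delay
#' when the normalization flag is set.
#'
#' @param tau1,tau2 delay axes in seconds, strictly increasing.
#' @param V amplitude matrix, \code{length(tau1) x length(tau2)}.
#' @param normalized logical flag; when TRUE and both axes start at zero,
#'   \code{V[1, 1]} must be 1 within 1e-6.
#' @return An object of class \code{echo_map}.
#' @export
echo_map <- function(tau1, tau2, V, normalized = TRUE) {
  check_grid(tau1, "tau1")
  check_grid(tau2, "tau2")
  V <- as.matrix(V)
  if (!all(dim(V) == c(length(tau1), length(tau2))))
    stop("V dimensions inconsistent with the delay axes")
  if (!all(is.finite(V))) stop("V contains non-finite values")
  if (normalized && tau1[1L] == 0 && tau2[1L] == 0 &&
      abs(V[1L, 1L] - 1) > 1e-6)
    stop("normalized map must have V(0, 0) = 1")
  structure(list(tau1 = as.numeric(tau1), tau2 = as.numeric(tau2), V = V,
                 normalized = normalized),
            class = "echo_map")
}

#' @export
print.echo_map <- function(x, ...) {
  cat(sprintf("<echo_map> %d x %d, tau1 %.3g-%.3g us, tau2 %.3g-%.3g us, V range [%.4g, %.4g]\n",
              length(x$tau1), length(x$tau2),
              min(x$tau1) * 1e6, max(x$tau1) * 1e6,
              min(x$tau2) * 1e6, max(x$tau2) * 1e6, min(x$V), max(x$V)))
  invisible(x)
}

#' @param x an \code{echo_map}.
#' @param ridge optional \code{\link{ridge}} result overlaid in red.
#' @param ... passed to \code{\link[graphics]{image}}.
#' @rdname echo_map
#' @export
plot.echo_map <- function(x, ridge = NULL, ...) {
  graphics::image(x$tau1 * 1e6, x$tau2 * 1e6, x$V,
                  xlab = "tau1 (us)", ylab = "tau2 (us)",
                  col = grDevices::hcl.colors(64, "viridis"), ...)
  graphics::abline(0, 1, col = "black", lty = 2)
  if (!is.null(ridge)) {
    graphics::lines(ridge$along_tau1$tau1_star * 1e6,
                    ridge$along_tau1$tau2 * 1e6, col = "red", lwd = 2)
    graphics::lines(ridge$along_tau2$tau1 * 1e6,
                    ridge$along_tau2$tau2_star * 1e6, col = "red", lwd = 2)
  }
  invisible(x)
}

#' Normalize each slice of an echo map to unit maximum
#'
#' Divides every slice along the chosen axis by its own maximum, the
#' display transformation that makes the ridge of slice-wise maxima
#' visible.  All-zero slices are left unchanged and flagged.
#'
#' @param map an \code{\link{echo_map}}.
#' @param axis \code{"tau1"}: each fixed-\code{tau2} slice along
#'   \code{tau1} is normalized; \code{"tau2"}: the transpose.
#' @return An \code{echo_map} with every slice maximum equal to 1 (and
#'   attribute \code{zero_slices} listing flagged slices, if any).
#' @export
normalize_slices <- function(map, axis = c("tau1", "tau2")) {
  stopifnot(inherits(map, "echo_map"))
  axis <- match.arg(axis)
  V <- map$V
  margin <- if (axis == "tau1") 2L else 1L
  mx <- apply(V, margin, max)
  zero <- mx == 0
  mx[zero] <- 1
  V <- if (margin == 2L) sweep(V, 2L, mx, "/") else sweep(V, 1L, mx, "/")
  out <- echo_map(map$tau1, map$tau2, V, normalized = FALSE)
  if (any(zero)) attr(out, "zero_slices") <- which(zero)
  out
}

#' Stretched-exponential phase-memory fit
#'
#' Least-squares fit of \code{V(t) = V0 exp[-(t / TM)^x]} to an echo
#' decay, where \code{t} is the total evolution time (for a two-pulse echo
#' recorded against the interpulse delay tau, \code{t = 2 tau}; the
#' \code{echo_trace} method applies this automatically).  Initialization
#' is a deterministic multi-start over stretch exponents
#' \code{x in {0.8, 1.5, 2.5}} with \code{TM} from the 1/e crossing;
#' the best converged Levenberg-Marquardt solution is returned.
#' Parameter uncertainties come from the local curvature of the
#' least-squares objective.
#'
#' @param time total evolution times, seconds (nonnegative, at least 6
#'   points); alternatively an \code{echo_trace} or a two-column matrix or
#'   data frame.
#' @param V echo amplitudes (omitted when \code{time} carries both columns).
#' @param ... unused.
#' @return An object of class \code{stretched_exp_fit} with components
#'   \code{coefficients} (\code{V0}, \code{TM} in seconds, \code{x}),
#'   \code{se}, \code{resid_norm} and the data; methods: \code{coef},
#'   \code{predict}, \code{residuals}, \code{print}, \code{summary},
#'   \code{plot}.
#' @examples
#' t <- seq(0.05, 8, length.out = 60) * 1e-6
#' V <- exp(-(t / 2.14e-6)^2.01)
#' coef(stretched_exp_fit(t, V))
#' @export
stretched_exp_fit <- function(time, V, ...) UseMethod("stretched_exp_fit")

#' @rdname stretched_exp_fit
#' @export
stretched_exp_fit.echo_trace <- function(time, V, ...)
  stretched_exp_fit.default(2 * time$tau, time$V, ...)

#' @rdname stretched_exp_fit
#' @export
stretched_exp_fit.default <- function(time, V, ...) {
  if (missing(V)) {
    m <- as.matrix(time)
    if (ncol(m) < 2L) stop("need both times and amplitudes")
    V <- m[, 2L]
    time <- m[, 1L]
  }
  t <- as.numeric(time)
  V <- as.numeric(V)
  if (length(t) < 6L) stop("need at least 6 points")
  if (any(t < 0)) stop("times must be nonnegative")
  if (anyNA(t) || anyNA(V)) stop("missing values in trace")
  o <- order(t)
  t <- t[o]; V <- V[o]
  V0_0 <- max(V)
  if (V[length(V)] > 0.95 * V0_0)
    stop("degenerate trace: no decay over the observation window")
  ## 1/e crossing for the TM start
  below <- which(V <= V0_0 / exp(1))
  TM_0 <- if (length(below)) {
    i <- below[1L]
    if (i > 1L) approx(V[(i - 1L):i], t[(i - 1L):i], xout = V0_0 / exp(1))$y
    else t[i]
  } else max(t)
  if (!is.finite(TM_0) || TM_0 <= 0) TM_0 <- max(t) / 2
  dat <- data.frame(t = t, V = V)
  best <- NULL
  for (x0 in c(0.8, 1.5, 2.5)) {
    fit <- tryCatch(
      minpack.lm::nlsLM(V ~ V0 * exp(-(t / TM)^x), data = dat,
                        start = list(V0 = V0_0, TM = TM_0, x = x0),
                        lower = c(V0 = 1e-12, TM = 1e-12, x = 0.05),
                        upper = c(V0 = Inf, TM = Inf, x = 4),
                        control = minpack.lm::nls.lm.control(maxiter = 500)),
      error = function(e) NULL)
    if (!is.null(fit) &&
        (is.null(best) || stats::deviance(fit) < stats::deviance(best)))
      best <- fit
  }
  if (is.null(best))
    stop("stretched-exponential fit failed to converge from all starts")
  cf <- coef(best)
  se <- tryCatch(sqrt(diag(vcov(best))), error = function(e)
    setNames(rep(NA_real_, 3L), names(cf)))
  structure(list(coefficients = cf, se = se,
                 resid_norm = sqrt(stats::deviance(best)),
                 fitted = fitted(best), data = dat, nls = best),
            class = "stretched_exp_fit")
}

#' @export
coef.stretched_exp_fit <- function(object, ...) object$coefficients

#' @export
residuals.stretched_exp_fit <- function(object, ...)
  object$data$V - object$fitted

#' @param object a \code{stretched_exp_fit}.
#' @param time new total evolution times (seconds); the fitted times by
#'   default.
#' @rdname stretched_exp_fit
#' @export
predict.stretched_exp_fit <- function(object, time = object$data$t, ...) {
  cf <- object$coefficients
  cf[["V0"]] * exp(-(time / cf[["TM"]])^cf[["x"]])
}

#' @export
print.stretched_exp_fit <- function(x, ...) {
  cf <- x$coefficients; se <- x$se
  cat("Stretched-exponential decay fit: V(t) = V0 exp[-(t/TM)^x]\n")
  cat(sprintf("  V0 = %.4g +/- %.2g\n", cf[["V0"]], se[["V0"]]))
  cat(sprintf("  TM = %.4g us +/- %.2g us\n", cf[["TM"]] * 1e6,
              se[["TM"]] * 1e6))
  cat(sprintf("  x  = %.4g +/- %.2g\n", cf[["x"]], se[["x"]]))
  cat(sprintf("  residual norm %.3g on %d points\n", x$resid_norm,
              nrow(x$data)))
  invisible(x)
}

#' @export
summary.stretched_exp_fit <- function(object, ...) {
  print(object)
  invisible(object)
}

#' @export
plot.stretched_exp_fit <- function(x, ...) {
  graphics::plot(x$data$t * 1e6, x$data$V, xlab = "t (us)",
                 ylab = "echo amplitude", ...)
  tt <- seq(min(x$data$t), max(x$data$t), length.out = 200L)
  graphics::lines(tt * 1e6, predict(x, tt), col = "red")
  invisible(x)
}

#' Relative DEER signal-to-noise estimate
#'
#' Evaluates the proportionality
#' \code{SNR ~ V0 lambda exp[-(2 tau / TM)^x] / sqrt(T1)}
#' (constant instrumental factors dropped): the echo amplitude surviving
#' dephasing, scaled by the pump modulation depth and by the shot-rate
#' limit set by the spin-lattice relaxation time.
#'
#' @param fit a \code{\link{stretched_exp_fit}}, or a named list/vector
#'   with \code{V0}, \code{TM} (seconds) and \code{x}.
#' @param lambda modulation depth in [0, 1].
#' @param T1 spin-lattice relaxation time, seconds.
#' @param tau dipolar evolution delay tau, seconds (the decay kernel uses
#'   the total evolution time 2 tau); vectorized.
#' @return Relative SNR values (arbitrary units).
#' @export
snr_estimate <- function(fit, lambda, T1, tau) {
  cf <- if (inherits(fit, "stretched_exp_fit")) coef(fit) else unlist(fit)
  stopifnot(all(c("V0", "TM", "x") %in% names(cf)),
            cf[["TM"]] > 0, cf[["V0"]] > 0,
            lambda >= 0, lambda <= 1, T1 > 0, all(tau >= 0))
  cf[["V0"]] * lambda * exp(-(2 * tau / cf[["TM"]])^cf[["x"]]) / sqrt(T1)
}

## ---- plain-text file formats (times in microseconds on disk) ----

#' Read or write an echo decay trace
#'
#' Traces are two-column plain text (time in microseconds, amplitude),
#' with \code{#} comment lines.
#'
#' @param path file path.
#' @param time times in seconds (written as microseconds).
#' @param V amplitudes.
#' @param comment optional extra header comment lines.
#' @return \code{read_trace}: a data frame with \code{time} (seconds) and
#'   \code{V}.  \code{write_trace} returns \code{path} invisibly.
#' @export
read_trace <- function(path) {
  d <- tryCatch(read.table(path, comment.char = "#"),
                error = function(e) stop("unparseable trace file: ",
                                         conditionMessage(e)))
  if (ncol(d) < 2L) stop("trace file needs two columns (time_us, V)")
  data.frame(time = as.numeric(d[, 1L]) * 1e-6, V = as.numeric(d[, 2L]))
}

#' @rdname read_trace
#' @export
write_trace <- function(time, V, path, comment = character()) {
  stopifnot(length(time) == length(V))
  writeLines(c("# ccecho echo trace", paste0("# ", comment),
               "# time_us V",
               paste(fmt_full(time * 1e6), fmt_full(V))), path)
  invisible(path)
}

#' Read or write a 2D echo map as CSV
#'
#' The dialect: optional \code{#} comment lines; a header row whose first
#' cell is \code{tau2_us\\tau1_us} followed by the tau1 axis in
#' microseconds; then one row per tau2 value (first column) with the
#' amplitudes.  Values are written in full double precision, so a
#' write/read round trip is exact.
#'
#' @param map an \code{\link{echo_map}}.
#' @param path file path.
#' @return \code{read_map}: an \code{echo_map}; \code{write_map}: the path,
#'   invisibly.
#' @export
write_map <- function(map, path) {
  stopifnot(inherits(map, "echo_map"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# ccecho echo map",
               sprintf("# normalized = %s", map$normalized)), con)
  writeLines(paste(c("tau2_us\\tau1_us", fmt_full(map$tau1 * 1e6)),
                   collapse = ","), con)
  for (j in seq_along(map$tau2))
    writeLines(paste(c(fmt_full(map$tau2[j] * 1e6), fmt_full(map$V[, j])),
                     collapse = ","), con)
  invisible(path)
}

#' @rdname write_map
#' @export
read_map <- function(path) {
  ln <- readLines(path, warn = FALSE)
  normalized <- any(grepl("^#\\s*normalized\\s*=\\s*TRUE", ln))
  ln <- ln[!startsWith(ln, "#") & nzchar(trimws(ln))]
  if (length(ln) < 2L) stop("malformed map file: too few rows")
  cells <- strsplit(ln, ",")
  if (!grepl("tau1", cells[[1L]][1L]))
    stop("malformed header: expected a tau2/tau1 corner cell")
  tau1 <- as.numeric(cells[[1L]][-1L]) * 1e-6
  if (anyNA(tau1)) stop("malformed header: non-numeric tau1 axis")
  nlen <- lengths(cells[-1L])
  if (any(nlen != length(tau1) + 1L))
    stop("inconsistent row lengths in map file")
  body <- do.call(rbind, lapply(cells[-1L], as.numeric))
  if (anyNA(body)) stop("non-numeric values in map file")
  tau2 <- body[, 1L] * 1e-6
  if (length(tau1) > 1L && any(diff(tau1) <= 0)) stop("non-monotonic axis")
  if (length(tau2) > 1L && any(diff(tau2) <= 0)) stop("non-monotonic axis")
  echo_map(tau1, tau2, t(body[, -1L, drop = FALSE]),
           normalized = normalized)
}

#' Write a ridge curve as CSV
#'
#' @param rc a \code{\link{ridge_curve}}.
#' @param path file path.
#' @param which which ridge: \code{"tau1"} writes tau1*(tau2) (maxima
#'   along tau1), \code{"tau2"} the transpose.
#' @export
write_ridge <- function(rc, path, which = c("tau1", "tau2")) {
  stopifnot(inherits(rc, "ridge_curve"))
  which <- match.arg(which)
  if (which == "tau1") {
    d <- rc$along_tau1
    hdr <- "tau2_us,tau1_star_us,flag"
    rows <- paste(fmt_full(d$tau2 * 1e6), fmt_full(d$tau1_star * 1e6),
                  d$flag, sep = ",")
  } else {
    d <- rc$along_tau2
    hdr <- "tau1_us,tau2_star_us,flag"
    rows <- paste(fmt_full(d$tau1 * 1e6), fmt_full(d$tau2_star * 1e6),
                  d$flag, sep = ",")
  }
  writeLines(c("# ccecho ridge curve", hdr, rows), path)
  invisible(path)
}
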