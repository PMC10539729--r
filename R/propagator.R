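#' Pulse sequences
#'
#' Delay grids for the two-pulse (Hahn, pi/2 - tau - pi - tau - echo) and
#' refocused (pi/2 - tau1 - pi - tau1+tau2 - pi - tau2 - echo) sequences.
#' Pulses are ideal, instantaneous and electron-only; grids are in seconds,
#' nonnegative and strictly increasing.
#'
#' @param tau,tau1,tau2 delay grids in seconds.
#' @return An object of class \code{pulse_sequence}.
#' @export
pulse_hahn <- function(tau) {
  check_grid(tau, "tau")
  structure(list(kind = "hahn", tau1 = as.numeric(tau), tau2 = numeric()),
            class = "pulse_sequence")
}

#' @rdname pulse_hahn
#' @export
pulse_refocused <- function(tau1, tau2) {
  check_grid(tau1, "tau1")
  check_grid(tau2, "tau2")
  structure(list(kind = "refocused", tau1 = as.numeric(tau1),
                 tau2 = as.numeric(tau2)),
            class = "pulse_sequence")
}

check_grid <- function(x, name) {
  if (!is.numeric(x) || length(x) == 0L)
    stop("'", name, "' must be a nonempty numeric grid")
  if (any(x < 0)) stop("'", name, "' must be nonnegative")
  if (length(x) > 1L && any(diff(x) <= 0))
    stop("'", name, "' must be strictly increasing")
  invisible(x)
}

#' @export
print.pulse_sequence <- function(x, ...) {
  if (x$kind == "hahn")
    cat(sprintf("<pulse_sequence> Hahn, %d tau points, %.3g-%.3g us\n",
                length(x$tau1), min(x$tau1) * 1e6, max(x$tau1) * 1e6))
  else
    cat(sprintf("<pulse_sequence> refocused, %d x %d (tau1, tau2) points\n",
                length(x$tau1), length(x$tau2)))
  invisible(x)
}

check_hermitian <- function(H, name) {
  if (!is.matrix(H)) stop("'", name, "' must be a matrix")
  s <- max(abs(H))
  if (max(abs(H - Conj(t(H)))) > 1e-9 * max(1, s))
    stop("'", name, "' is not Hermitian")
  invisible(H)
}

#' Cluster echo amplitude by coherent propagation
#'
#' Echo amplitude of a single cluster from the coherence-overlap trace
#' formula \code{V = 2^-N Re Tr[W_A W_B^H]}, with the branch propagators of
#' the two-pulse sequence (\code{hahn_echo}) or of the refocused sequence
#' (\code{refocused_echo}).  This equals full density-matrix propagation of
#' the sequence with ideal electron-only pulses from the high-temperature
#' initial state (see \code{\link{exact_oracle}}).
#'
#' @param h a \code{\link{cluster_hamiltonians}} object.
#' @param tau,tau1,tau2 delay grids in seconds.
#' @return \code{hahn_echo}: numeric vector along \code{tau};
#'   \code{refocused_echo}: matrix \code{V[i, j] = V(tau1[i], tau2[j])}.
#'   Both equal 1 at zero delay.
#' @export
hahn_echo <- function(h, tau) {
  stopifnot(inherits(h, "cluster_hamiltonians"))
  check_grid(tau, "tau")
  check_hermitian(h$H_alpha, "H_alpha")
  check_hermitian(h$H_beta, "H_beta")
  as.numeric(echo_signal_cpp(h$H_alpha, h$H_beta, as.numeric(tau),
                             numeric(), FALSE))
}

#' @rdname hahn_echo
#' @export
refocused_echo <- function(h, tau1, tau2) {
  stopifnot(inherits(h, "cluster_hamiltonians"))
  check_grid(tau1, "tau1")
  check_grid(tau2, "tau2")
  check_hermitian(h$H_alpha, "H_alpha")
  check_hermitian(h$H_beta, "H_beta")
  matrix(echo_signal_cpp(h$H_alpha, h$H_beta, as.numeric(tau1),
                         as.numeric(tau2), TRUE),
         length(tau1), length(tau2))
}

#' Brute-force full-Hilbert-space echo (verification oracle)
#'
#' Propagates the full electron + bath density matrix through the pulse
#' sequence with explicit ideal pi/2 and pi rotations on the electron and
#' no relaxation, starting from the high-temperature initial state
#' (electron polarization, maximally mixed nuclei).  The echo is read out
#' as the transverse electron coherence amplitude, normalized to its value
#' at zero delay.  Independent of the trace-formula path; exponential in
#' the proton count, so capped at \code{max_protons}.
#'
#' @param couplings a \code{\link{coupling_set}} for the whole (small) bath.
#' @param sequence a \code{\link{pulse_hahn}} or \code{\link{pulse_refocused}}
#'   sequence.
#' @param max_protons refuse baths larger than this (default 12).
#' @return Vector (Hahn) or \code{length(tau1) x length(tau2)} matrix
#'   (refocused) of normalized echo amplitudes.
#' @export
exact_oracle <- function(couplings, sequence, max_protons = 12) {
  stopifnot(inherits(couplings, "coupling_set"),
            inherits(sequence, "pulse_sequence"))
  n <- couplings$n
  if (n > max_protons)
    stop("bath of ", n, " protons exceeds max_protons = ", max_protons)
  dn <- 2L^n

  ## nuclear-space conditional Hamiltonians, built independently of the
  ## compiled path via explicit Kronecker products
  Iz1 <- matrix(c(0.5, 0, 0, -0.5), 2L, 2L)
  Ix1 <- matrix(c(0, 0.5, 0.5, 0), 2L, 2L)
  Iy1 <- matrix(c(0, 1i, -1i, 0) / 2, 2L, 2L)  # basis order (up, down)
  site_op <- function(op, k) {
    m <- matrix(1 + 0i, 1L, 1L)
    for (j in seq_len(n))   # site 1 = fastest (rightmost) factor
      m <- if (j == k) kronecker(op, m) else kronecker(diag(2L), m)
    m
  }
  Izs <- lapply(seq_len(n), function(k) site_op(Iz1, k))
  Ha <- matrix(0i, dn, dn)
  Hb <- matrix(0i, dn, dn)
  for (k in seq_len(n)) {
    hz <- -couplings$omega_I * Izs[[k]]
    hf <- 0.5 * (couplings$A_zz[k] * Izs[[k]] +
                 couplings$A_zx[k] * site_op(Ix1, k) +
                 couplings$A_zy[k] * site_op(Iy1, k))
    Ha <- Ha + hz + hf
    Hb <- Hb + hz - hf
  }
  if (n > 1L) {
    Ip1 <- matrix(c(0, 0, 1, 0), 2L, 2L)  # I+ in basis (up, down)
    Ips <- lapply(seq_len(n), function(k) site_op(Ip1, k))
    for (m in seq_len(n - 1L)) for (k in (m + 1L):n) {
      b <- couplings$b[m, k]
      if (b == 0) next
      ff <- Ips[[m]] %*% Conj(t(Ips[[k]])) + Conj(t(Ips[[m]])) %*% Ips[[k]]
      Ha <- Ha + b * (ff - 4 * Izs[[m]] %*% Izs[[k]])
      Hb <- Hb + b * (ff - 4 * Izs[[m]] %*% Izs[[k]])
    }
  }

  ea <- eigen(Ha, symmetric = TRUE)
  eb <- eigen(Hb, symmetric = TRUE)
  Ublock <- function(e, t)
    e$vectors %*% (exp(-1i * e$values * t) * Conj(t(e$vectors)))

  ## full space: electron (first factor) x nuclei; alpha block first
  d <- 2L * dn
  iA <- seq_len(dn)
  iB <- dn + seq_len(dn)
  Sx <- matrix(0i, d, d); Sx[cbind(iA, iB)] <- 0.5; Sx[cbind(iB, iA)] <- 0.5
  Sy <- matrix(0i, d, d); Sy[cbind(iA, iB)] <- -0.5i; Sy[cbind(iB, iA)] <- 0.5i
  Sz <- diag(c(rep(0.5, dn), rep(-0.5, dn))) + 0i
  rot <- function(theta) {
    cos(theta / 2) * diag(d) - 2i * sin(theta / 2) * Sx
  }
  P90 <- rot(pi / 2)
  P180 <- rot(pi)
  evolve <- function(rho, t) {
    U <- matrix(0i, d, d)
    U[iA, iA] <- Ublock(ea, t)
    U[iB, iB] <- Ublock(eb, t)
    U %*% rho %*% Conj(t(U))
  }
  detect <- function(rho) sum(diag((Sx + 1i * Sy) %*% rho))  # <S+>

  run <- function(t1, t2 = NULL) {
    rho <- P90 %*% Sz %*% Conj(t(P90))
    rho <- evolve(rho, t1)
    rho <- P180 %*% rho %*% Conj(t(P180))
    if (is.null(t2)) {
      rho <- evolve(rho, t1)
    } else {
      rho <- evolve(rho, t1 + t2)
      rho <- P180 %*% rho %*% Conj(t(P180))
      rho <- evolve(rho, t2)
    }
    detect(rho)
  }

  if (sequence$kind == "hahn") {
    s0 <- run(0)
    vapply(sequence$tau1, function(t) Re(run(t) / s0), 0)
  } else {
    s0 <- run(0, 0)
    outer(sequence$tau1, sequence$tau2,
          Vectorize(function(t1, t2) Re(run(t1, t2) / s0)))
  }
}
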