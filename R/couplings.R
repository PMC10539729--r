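## angstrom -> metre
.A2M <- 1e-10

#' Point-dipole hyperfine components of one proton
#'
#' Secular (\code{A_zz}) and pseudo-secular (\code{A_zx}, \code{A_zy})
#' components of the electron-proton dipolar hyperfine coupling, from the
#' point-dipole approximation.  With \code{u} the unit electron-to-proton
#' vector expressed in the lab frame of \code{field} and
#' \code{D = (mu0/4pi) gamma_e gamma_H hbar / r^3},
#' \deqn{A_{zz} = D (3 u_z^2 - 1), \quad A_{zx} = 3 D u_z u_x, \quad
#'       A_{zy} = 3 D u_z u_y,}
#' so the pseudo-secular magnitude is \code{3 D |sin(theta) cos(theta)|}.
#' The isotropic (Fermi contact) part is taken as zero.  All values in
#' rad/s.
#'
#' @param electron_position,proton_position positions in angstrom.
#' @param field a \code{\link{field_config}}.
#' @param exclusion warn when the distance falls below this radius
#'   (angstrom), where the point-dipole form loses validity.
#' @return Named numeric vector \code{c(A_zz, A_zx, A_zy)} in rad/s.
#' @examples
#' fc <- field_config()
#' a <- hyperfine_tensor(c(0, 0, 0), c(0, 0, 3), fc)
#' a[["A_zz"]] / (2 * pi) / 1e6  # about +5.86 MHz at 3 A along the field
#' @export
hyperfine_tensor <- function(electron_position, proton_position, field,
                             exclusion = 2.5) {
  stopifnot(inherits(field, "field_config"))
  v <- as.numeric(proton_position) - as.numeric(electron_position)
  r <- sqrt(sum(v^2))
  if (r == 0) stop("electron and proton positions coincide")
  if (r < exclusion)
    warning("electron-proton distance ", signif(r, 3),
            " A below the point-dipole exclusion radius")
  u <- v / r
  uz <- sum(u * field$z); ux <- sum(u * field$x); uy <- sum(u * field$y)
  D <- .ccecho_const$mu0 / (4 * pi) * field$gamma_e * field$gamma_H *
    .ccecho_const$hbar / (r * .A2M)^3
  c(A_zz = D * (3 * uz^2 - 1), A_zx = 3 * D * uz * ux, A_zy = 3 * D * uz * uy)
}

#' Secular dipolar coupling parameter of a proton pair
#'
#' Returns \code{b_mn = (mu0/4pi) gamma_H^2 hbar (3 cos^2 theta - 1) /
#' (4 r^3)} in rad/s, the prefactor of the secular nuclear dipolar pair
#' term \code{b_mn (I+I- + I-I+ - 4 IzIz)}, which reproduces the truncated
#' homonuclear dipolar Hamiltonian.
#'
#' @param pos_m,pos_n proton positions in angstrom.
#' @param field a \code{\link{field_config}}.
#' @return Scalar coupling in rad/s (symmetric in its arguments).
#' @examples
#' fc <- field_config()
#' pair_coupling(c(0, 0, 0), c(0, 0, 2), fc) / (2 * pi)  # about +7.51 kHz
#' @export
pair_coupling <- function(pos_m, pos_n, field) {
  stopifnot(inherits(field, "field_config"))
  v <- as.numeric(pos_n) - as.numeric(pos_m)
  r <- sqrt(sum(v^2))
  if (r == 0) stop("coincident nuclei")
  cz <- sum(v * field$z) / r
  .ccecho_const$mu0 / (4 * pi) * field$gamma_H^2 * .ccecho_const$hbar *
    (3 * cz^2 - 1) / (4 * (r * .A2M)^3)
}

#' Assemble the coupling set of a proton bath
#'
#' Evaluates \code{\link{hyperfine_tensor}} for every proton and
#' \code{\link{pair_coupling}} for every proton pair, after optionally
#' applying a molecular-frame rotation to all positions about the electron.
#'
#' @param bath a nonempty \code{\link{generate_bath} proton_bath}.
#' @param field a \code{\link{field_config}}.
#' @param rotation optional 3 x 3 rotation matrix applied to all
#'   electron-to-proton vectors before evaluating couplings.
#' @return An object of class \code{coupling_set}; see
#'   \code{\link{coupling_set}}.
#' @export
build_coupling_set <- function(bath, field = field_config(), rotation = NULL) {
  stopifnot(inherits(bath, "proton_bath"), inherits(field, "field_config"))
  n <- nrow(bath$protons)
  if (n == 0L) stop("bath is empty")
  rel <- sweep(bath$protons, 2L, as.numeric(bath$electron))
  if (!is.null(rotation)) {
    stopifnot(is.matrix(rotation), all(dim(rotation) == c(3L, 3L)))
    rel <- rel %*% t(rotation)
  }
  r <- sqrt(rowSums(rel^2))
  if (any(r == 0)) stop("a proton coincides with the electron")
  uz <- (rel %*% field$z)[, 1L] / r
  ux <- (rel %*% field$x)[, 1L] / r
  uy <- (rel %*% field$y)[, 1L] / r
  D <- .ccecho_const$mu0 / (4 * pi) * field$gamma_e * field$gamma_H *
    .ccecho_const$hbar / (r * .A2M)^3
  A_zz <- D * (3 * uz^2 - 1)
  A_zx <- 3 * D * uz * ux
  A_zy <- 3 * D * uz * uy
  ## pairwise separations and orientations, vectorized
  dx <- outer(rel[, 1L], rel[, 1L], "-")
  dy <- outer(rel[, 2L], rel[, 2L], "-")
  dz_ <- outer(rel[, 3L], rel[, 3L], "-")
  pz <- dx * field$z[1L] + dy * field$z[2L] + dz_ * field$z[3L]
  r2 <- dx * dx + dy * dy + dz_ * dz_
  diag(r2) <- 1  # avoid 0/0; diagonal zeroed below
  cz2 <- pz * pz / r2
  b <- .ccecho_const$mu0 / (4 * pi) * field$gamma_H^2 * .ccecho_const$hbar *
    (3 * cz2 - 1) / (4 * (sqrt(r2) * .A2M)^3)
  diag(b) <- 0
  coupling_set(A_zz, A_zx, A_zy, b, omega_I = field$omega_I,
               field = field, r_en = r)
}

#' Construct a coupling set directly
#'
#' Low-level constructor used by \code{\link{build_coupling_set}} and for
#' synthetic spin systems in which couplings are specified rather than
#' derived from geometry.
#'
#' @param A_zz,A_zx,A_zy per-proton secular and pseudo-secular hyperfine
#'   components, rad/s.  \code{A_zx}/\code{A_zy} default to zero.
#' @param b symmetric nucleus-nucleus coupling matrix with zero diagonal,
#'   rad/s.
#' @param omega_I nuclear Zeeman angular frequency, rad/s.
#' @param field optional \code{\link{field_config}} the set was built from.
#' @param r_en optional electron-proton distances (angstrom), metadata only.
#' @return An object of class \code{coupling_set}.
#' @export
coupling_set <- function(A_zz, A_zx = 0, A_zy = 0, b = NULL,
                         omega_I = field_config()$omega_I, field = NULL,
                         r_en = NULL) {
  n <- length(A_zz)
  A_zx <- rep_len(as.numeric(A_zx), n)
  A_zy <- rep_len(as.numeric(A_zy), n)
  if (is.null(b)) b <- matrix(0, n, n)
  stopifnot(is.matrix(b), all(dim(b) == n),
            all(is.finite(A_zz)), all(is.finite(A_zx)), all(is.finite(A_zy)),
            all(is.finite(b)))
  if (max(abs(b - t(b))) > 1e-9 * max(1, max(abs(b))))
    stop("pair coupling matrix must be symmetric")
  if (any(diag(b) != 0)) stop("pair coupling matrix must have zero diagonal")
  structure(list(A_zz = as.numeric(A_zz), A_zx = A_zx, A_zy = A_zy,
                 b = b, n = n, omega_I = omega_I, field = field,
                 r_en = r_en),
            class = "coupling_set")
}

#' @export
print.coupling_set <- function(x, ...) {
  cat(sprintf("<coupling_set> %d protons, omega_I/2pi = %.4f MHz\n",
              x$n, x$omega_I / (2 * pi) / 1e6))
  if (x$n > 1L) {
    bb <- abs(x$b[upper.tri(x$b)]) / (2 * pi)
    cat(sprintf("  |b|/2pi: median %.3g Hz, max %.3g Hz\n",
                median(bb), max(bb)))
  }
  invisible(x)
}

#' Conditional nuclear Hamiltonians of a cluster
#'
#' Builds the two nuclear sub-Hamiltonians of a cluster, conditional on the
#' electron projection mS = +1/2 (\code{H_alpha}) and -1/2 (\code{H_beta}):
#' \deqn{H_\pm = \sum_n [-\omega_I I_z^n \pm \tfrac12 (A_{zz}^n I_z^n +
#'   A_{zx}^n I_x^n + A_{zy}^n I_y^n)] + \sum_{m<n} b_{mn}
#'   (I_+^m I_-^n + I_-^m I_+^n - 4 I_z^m I_z^n).}
#' The electron Zeeman term, constant within each block, is omitted.
#'
#' @param couplings a \code{\link{coupling_set}}.
#' @param cluster integer vector of proton indices.
#' @return An object of class \code{cluster_hamiltonians}: a list with the
#'   sorted \code{cluster}, complex Hermitian \code{H_alpha} and
#'   \code{H_beta} of dimension \code{2^length(cluster)}, and
#'   \code{omega_I}.
#' @export
cluster_hamiltonians <- function(couplings, cluster) {
  stopifnot(inherits(couplings, "coupling_set"))
  cluster <- sort(unique(as.integer(cluster)))
  if (length(cluster) == 0L) stop("empty cluster")
  if (any(cluster < 1L) || any(cluster > couplings$n))
    stop("cluster indices out of range")
  h <- cluster_hams_cpp(cluster, couplings$A_zz, couplings$A_zx,
                        couplings$A_zy, couplings$b, couplings$omega_I)
  structure(list(cluster = cluster, H_alpha = h$H_alpha, H_beta = h$H_beta,
                 omega_I = couplings$omega_I),
            class = "cluster_hamiltonians")
}

#' Export a coupling set as a plain-text table
#'
#' Writes per-proton hyperfine components and per-pair couplings in Hz, a
#' debugging/fixture format.
#'
#' @param couplings a \code{\link{coupling_set}}.
#' @param path output file.
#' @export
write_couplings <- function(couplings, path) {
  stopifnot(inherits(couplings, "coupling_set"))
  n <- couplings$n
  r <- couplings$r_en %||% rep(NA_real_, n)
  ln <- c("# ccecho coupling set",
          sprintf("# omega_I_Hz = %s", fmt_full(couplings$omega_I / (2 * pi))),
          "# proton id r_A Azz_Hz Azx_Hz Azy_Hz",
          paste("proton", seq_len(n), fmt_full(r),
                fmt_full(couplings$A_zz / (2 * pi)),
                fmt_full(couplings$A_zx / (2 * pi)),
                fmt_full(couplings$A_zy / (2 * pi))))
  if (n > 1L) {
    ij <- which(upper.tri(couplings$b), arr.ind = TRUE)
    ln <- c(ln, "# pair m n b_Hz",
            paste("pair", ij[, 1L], ij[, 2L],
                  fmt_full(couplings$b[ij] / (2 * pi))))
  }
  writeLines(ln, path)
  invisible(path)
}
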