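#' Lebedev quadrature grid on the sphere
#'
#' Standard Lebedev-Laikov points and weights for powder (orientational)
#' averaging; exact for spherical harmonics up to the grid's degree.
#' Orders 6, 14 and 26 are provided, which suffices for the smooth
#' orientation dependence of bath-driven decoherence.
#'
#' @param order number of points: 6, 14 or 26.
#' @return An object of class \code{lebedev_grid}: \code{points}
#'   (\code{order} x 3 unit vectors) and \code{weights} (summing to 1).
#' @export
lebedev_grid <- function(order = 14) {
  s <- 1 / sqrt(2)
  c3 <- 1 / sqrt(3)
  oct6 <- rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0), c(0, -1, 0),
                c(0, 0, 1), c(0, 0, -1))
  cube8 <- as.matrix(expand.grid(c(-c3, c3), c(-c3, c3), c(-c3, c3)))
  edge12 <- rbind(c(s, s, 0), c(s, -s, 0), c(-s, s, 0), c(-s, -s, 0),
                  c(s, 0, s), c(s, 0, -s), c(-s, 0, s), c(-s, 0, -s),
                  c(0, s, s), c(0, s, -s), c(0, -s, s), c(0, -s, -s))
  g <- switch(as.character(order),
    "6"  = list(points = oct6, weights = rep(1 / 6, 6)),
    "14" = list(points = rbind(oct6, cube8),
                weights = c(rep(1 / 15, 6), rep(3 / 40, 8))),
    "26" = list(points = rbind(oct6, edge12, cube8),
                weights = c(rep(1 / 21, 6), rep(4 / 105, 12),
                            rep(9 / 280, 8))),
    stop("unsupported Lebedev order ", order, "; available: 6, 14, 26"))
  dimnames(g$points) <- NULL
  structure(list(order = order, points = g$points, weights = g$weights),
            class = "lebedev_grid")
}

#' @export
print.lebedev_grid <- function(x, ...) {
  cat(sprintf("<lebedev_grid> %d orientations, weights sum %.12f\n",
              nrow(x$points), sum(x$weights)))
  invisible(x)
}

#' Orientation-dependent excitation weights for finite pulses
#'
#' Rectangular-pulse transfer factors at a per-orientation resonance
#' offset, multiplied over the pulses of the sequence and combined with the
#' Lebedev weights.  For offset \code{Delta} and nutation frequency
#' \code{omega1} (\code{omega_eff = sqrt(omega1^2 + Delta^2)}), a pi/2
#' pulse contributes \code{(omega1/omega_eff) sin(omega_eff t_p)} and a pi
#' pulse \code{(omega1/omega_eff)^2 sin^2(omega_eff t_p / 2)}.  With ideal
#' pulses (zero offset everywhere) the result reduces to the plain Lebedev
#' weights.
#'
#' @param grid a \code{\link{lebedev_grid}}.
#' @param offset_model function mapping an orientation unit vector to a
#'   resonance offset in rad/s.
#' @param omega1 pulse amplitude (nutation angular frequency), rad/s.
#' @param t_p90,t_p180 pi/2 and pi pulse lengths, seconds.
#' @param kind sequence kind: \code{"refocused"} (one pi/2, two pi pulses)
#'   or \code{"hahn"} (one pi/2, one pi pulse).
#' @return Normalized per-orientation weights (length \code{nrow(grid$points)}).
#' @export
excitation_weights <- function(grid, offset_model, omega1, t_p90, t_p180,
                               kind = c("refocused", "hahn")) {
  stopifnot(inherits(grid, "lebedev_grid"), is.function(offset_model),
            omega1 > 0, t_p90 > 0, t_p180 > 0)
  kind <- match.arg(kind)
  delta <- apply(grid$points, 1L, offset_model)
  weff <- sqrt(omega1^2 + delta^2)
  f90 <- (omega1 / weff) * abs(sin(weff * t_p90))
  f180 <- (omega1 / weff)^2 * sin(weff * t_p180 / 2)^2
  w <- grid$weights * f90 * f180^(if (kind == "refocused") 2 else 1)
  w / sum(w)
}

#' Enumerate nuclear clusters up to a maximum size
#'
#' Builds the coupling graph whose edges are proton pairs with
#' \code{|b_mn|/2pi >= threshold} and returns all singletons plus, under
#' the default \code{"connectivity"} rule, every connected subset of 2 to
#' \code{k} protons.  The stricter \code{"all_pairs"} rule additionally
#' requires every intra-cluster pair to be above threshold.
#'
#' @param couplings a \code{\link{coupling_set}}.
#' @param k maximum cluster size; 2 to 4 in production use, up to the bath
#'   size for untruncated (exact) expansions of small baths.
#' @param threshold coupling threshold in Hz (default 1580, i.e. 1.58 kHz).
#' @param rule cluster retention rule; see Details.
#' @return An object of class \code{cluster_list}: sorted unique index
#'   tuples (singletons first, then increasing size), with the parameters
#'   and a per-size count attached.
#' @export
enumerate_clusters <- function(couplings, k = 2, threshold = 1580,
                               rule = c("connectivity", "all_pairs")) {
  stopifnot(inherits(couplings, "coupling_set"),
            k >= 1, k <= couplings$n, threshold >= 0)
  rule <- match.arg(rule)
  n <- couplings$n
  clusters <- lapply(seq_len(n), identity)
  if (k >= 2 && n >= 2) {
    strong <- abs(couplings$b) / (2 * pi) >= threshold
    strong[lower.tri(strong, diag = TRUE)] <- FALSE
    ij <- which(strong, arr.ind = TRUE)
    if (nrow(ij)) {
      bigger <- connected_subsets_cpp(n, ij[, 1L], ij[, 2L], as.integer(k))
      if (rule == "all_pairs" && length(bigger)) {
        adj <- abs(couplings$b) / (2 * pi) >= threshold
        keep <- vapply(bigger, function(cl) {
          if (length(cl) == 2L) return(TRUE)
          all(adj[t(utils::combn(cl, 2L))])
        }, TRUE)
        bigger <- bigger[keep]
      }
      clusters <- c(clusters, bigger)
    }
  }
  sizes <- lengths(clusters)
  clusters <- clusters[order(sizes)]
  counts <- tabulate(lengths(clusters), nbins = k)
  structure(list(clusters = clusters, k = as.integer(k),
                 threshold = threshold, rule = rule, n = n,
                 counts = counts),
            class = "cluster_list")
}

#' @export
print.cluster_list <- function(x, ...) {
  cat(sprintf("<cluster_list> %d clusters (k = %d, threshold %.3g Hz, %s)\n",
              length(x$clusters), x$k, x$threshold, x$rule))
  cat("  per size:", paste(seq_along(x$counts), x$counts, sep = ":",
                           collapse = "  "), "\n")
  invisible(x)
}

#' Combine cluster signals by cluster-correlation expansion
#'
#' Computes the irreducible correlation factor of every cluster,
#' \deqn{\tilde V_C = V_C / \prod_{C' \subset C} \tilde V_{C'},}
#' recursively over the proper sub-clusters present in the list (absent
#' sub-clusters, e.g. below-threshold pairs inside a connected triple,
#' contribute a factor 1), and returns the pointwise product of all
#' correlation factors.  Where a denominator magnitude falls below
#' \code{guard} the cluster's factor is set to 1 at that point; such points
#' are already deep in the decayed region.
#'
#' @param signals numeric matrix, one column per cluster (rows = delay-grid
#'   points), as returned by the compiled propagation.
#' @param clusters list of integer index vectors matching the columns of
#'   \code{signals}.
#' @param guard denominator guard (default 1e-6).
#' @return Numeric vector: the combined total signal on the grid.
#' @export
cce_combine <- function(signals, clusters, guard = 1e-6) {
  if (is.list(signals) && !is.matrix(signals))
    signals <- do.call(cbind, signals)
  stopifnot(is.matrix(signals), ncol(signals) == length(clusters))
  nc <- length(clusters)
  npts <- nrow(signals)
  key <- vapply(clusters, paste, "", collapse = ",")
  if (anyDuplicated(key)) stop("duplicate clusters in list")
  row_of <- new.env(hash = TRUE, size = max(2L * nc, 16L))
  for (r in seq_len(nc)) assign(key[r], r, envir = row_of)
  ord <- order(lengths(clusters))
  tilde <- signals
  total <- rep(1, npts)
  n_guarded <- 0L
  for (r in ord) {
    cl <- clusters[[r]]
    sz <- length(cl)
    if (sz > 1L) {
      denom <- rep(1, npts)
      for (m in seq_len(sz - 1L)) {
        combs <- utils::combn(cl, m)
        for (j in seq_len(ncol(combs))) {
          rr <- row_of[[paste(combs[, j], collapse = ",")]]
          if (!is.null(rr)) denom <- denom * tilde[, rr]
        }
      }
      bad <- abs(denom) < guard
      tv <- signals[, r] / denom
      if (any(bad)) {
        tv[bad] <- 1
        n_guarded <- n_guarded + sum(bad)
      }
      tilde[, r] <- tv
    }
    total <- total * tilde[, r]
  }
  if (n_guarded > 0L)
    attr(total, "n_guarded") <- n_guarded
  total
}

#' Simulate the powder-averaged echo decay of a proton bath
#'
#' The full pipeline: for each orientation of the Lebedev grid the field
#' direction is rotated in the molecular frame, couplings are built,
#' clusters enumerated, every cluster propagated coherently, the cluster
#' signals combined by CCE, and the resulting total signals averaged with
#' the grid weights (optionally replaced by excitation-efficiency weights).
#'
#' @param bath a \code{\link{generate_bath} proton_bath}; an empty bath
#'   yields a unit signal with a warning.
#' @param sequence a \code{\link{pulse_hahn}} or
#'   \code{\link{pulse_refocused}} sequence.
#' @param field a \code{\link{field_config}} (its direction is replaced by
#'   each grid orientation in turn).
#' @param k CCE truncation level (1-4).
#' @param threshold cluster coupling threshold in Hz (default 1580).
#' @param grid a \code{\link{lebedev_grid}}; a single fixed orientation can
#'   be simulated by passing a one-point grid via \code{orientations}.
#' @param weights optional per-orientation weights overriding
#'   \code{grid$weights} (see \code{\link{excitation_weights}}); renormalized.
#' @param orientations optional matrix of unit vectors replacing the grid
#'   points (with uniform weights unless \code{weights} is given).
#' @param pseudo_secular include the pseudo-secular hyperfine components
#'   (default TRUE).
#' @param pair_couplings include the nucleus-nucleus couplings (default
#'   TRUE); with FALSE the signal is the product of single-nucleus ESEEM
#'   signals and shows no decay envelope.
#' @param rule cluster retention rule, see \code{\link{enumerate_clusters}}.
#' @param guard CCE division guard, see \code{\link{cce_combine}}.
#' @return For a Hahn sequence, an \code{echo_trace} (data frame with
#'   \code{tau} and \code{V}); for a refocused sequence an
#'   \code{\link{echo_map}}.  Both carry a \code{cluster_counts} attribute
#'   (orientations x sizes).
#' @export
simulate_echo <- function(bath, sequence, field = field_config(), k = 2,
                          threshold = 1580, grid = lebedev_grid(14),
                          weights = NULL, orientations = NULL,
                          pseudo_secular = TRUE, pair_couplings = TRUE,
                          rule = "connectivity", guard = 1e-6) {
  stopifnot(inherits(bath, "proton_bath"),
            inherits(sequence, "pulse_sequence"))
  refocused <- sequence$kind == "refocused"
  n1 <- length(sequence$tau1)
  npts <- if (refocused) n1 * length(sequence$tau2) else n1
  pts <- orientations %||% grid$points
  if (is.null(dim(pts))) pts <- matrix(pts, ncol = 3L)
  w <- weights %||% (if (is.null(orientations)) grid$weights
                     else rep(1 / nrow(pts), nrow(pts)))
  stopifnot(length(w) == nrow(pts), all(w >= 0))
  w <- w / sum(w)

  if (nrow(bath$protons) == 0L) {
    warning("empty bath: echo amplitude is identically 1")
    V <- rep(1, npts)
    counts <- matrix(0L, nrow(pts), k)
  } else {
    V <- numeric(npts)
    counts <- matrix(0L, nrow(pts), k)
    for (i in seq_len(nrow(pts))) {
      fld <- field_config(B0 = field$B0, direction = pts[i, ],
                          g_e = field$g_e)
      cs <- build_coupling_set(bath, fld)
      if (!pseudo_secular) {
        cs$A_zx[] <- 0
        cs$A_zy[] <- 0
      }
      if (!pair_couplings) cs$b[] <- 0
      cl <- enumerate_clusters(cs, k = k, threshold = threshold, rule = rule)
      counts[i, ] <- cl$counts
      sig <- cce_signals_cpp(cl$clusters, cs$A_zz, cs$A_zx, cs$A_zy, cs$b,
                             cs$omega_I, sequence$tau1, sequence$tau2,
                             refocused)
      V <- V + w[i] * cce_combine(sig, cl$clusters, guard = guard)
    }
  }
  out <- if (refocused)
    echo_map(sequence$tau1, sequence$tau2, matrix(V, n1), normalized = TRUE)
  else
    echo_trace(sequence$tau1, V)
  attr(out, "cluster_counts") <- counts
  attr(out, "params") <- list(k = k, threshold = threshold, rule = rule,
                              B0 = field$B0, n_protons = nrow(bath$protons),
                              pseudo_secular = pseudo_secular,
                              pair_couplings = pair_couplings)
  out
}

#' One-dimensional echo decay container
#'
#' @param tau delay grid, seconds.
#' @param V echo amplitudes.
#' @return An object of class \code{echo_trace} (a data frame with columns
#'   \code{tau} and \code{V}).
#' @export
echo_trace <- function(tau, V) {
  stopifnot(length(tau) == length(V))
  structure(data.frame(tau = as.numeric(tau), V = as.numeric(V)),
            class = c("echo_trace", "data.frame"))
}

#' @export
plot.echo_trace <- function(x, xunit = 1e6, xlab = "tau (us)",
                            ylab = "echo amplitude", ...) {
  graphics::plot(x$tau * xunit, x$V, type = "l", xlab = xlab, ylab = ylab,
                 ...)
  invisible(x)
}
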