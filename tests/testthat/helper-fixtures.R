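fc0 <- field_config()

## random synthetic coupling set (rad/s), reproducible
random_coupling_set <- function(n, seed, a_scale = 2 * pi * 5e6,
                                b_scale = 2 * pi * 5e3, pseudo = TRUE) {
  set.seed(seed)
  A_zz <- runif(n, -1, 1) * a_scale
  A_zx <- if (pseudo) runif(n, 0, 0.6) * a_scale else rep(0, n)
  A_zy <- if (pseudo) runif(n, -0.6, 0.6) * a_scale else rep(0, n)
  b <- matrix(0, n, n)
  b[upper.tri(b)] <- runif(n * (n - 1) / 2, -1, 1) * b_scale
  coupling_set(A_zz, A_zx, A_zy, b + t(b), omega_I = fc0$omega_I)
}

## geometry-derived coupling set for the k protons closest to the electron
bath_coupling_subset <- function(seed, k, cutoff = 6, pseudo = TRUE) {
  b <- generate_bath(seed = seed, cutoff = cutoff)
  cs <- build_coupling_set(b, fc0)
  idx <- order(cs$r_en)[seq_len(k)]
  coupling_set(cs$A_zz[idx], if (pseudo) cs$A_zx[idx] else 0,
               if (pseudo) cs$A_zy[idx] else 0, cs$b[idx, idx],
               omega_I = cs$omega_I)
}

## textbook two-pulse ESEEM closed form (independent oracle)
mims_eseem <- function(A, B, omega_I, tau) {
  wa <- sqrt((omega_I - A / 2)^2 + (B / 2)^2)
  wb <- sqrt((omega_I + A / 2)^2 + (B / 2)^2)
  k <- (B * omega_I / (wa * wb))^2
  1 - k / 2 * (1 - cos(wa * tau)) * (1 - cos(wb * tau))
}

## CCE total signal assembled from exported per-cluster propagation only
cce_total_exported <- function(cs, clusters, tau1, tau2) {
  sig <- vapply(clusters, function(cl) {
    h <- cluster_hamiltonians(cs, cl)
    as.numeric(refocused_echo(h, tau1, tau2))
  }, numeric(length(tau1) * length(tau2)))
  matrix(cce_combine(sig, clusters), length(tau1), length(tau2))
}

expect_exit_status <- function(object, status) {
  expect_identical(as.integer(object), as.integer(status))
}
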