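cs_pair <- function(b_khz, n = 2) {
  b <- matrix(0, n, n)
  b[1, 2] <- b[2, 1] <- 2 * pi * b_khz * 1e3
  coupling_set(A_zz = 2 * pi * seq(1e6, by = 1e6, length.out = n), b = b,
               omega_I = fc0$omega_I)
}

test_that("cluster enumeration applies the coupling threshold", {
  cl <- enumerate_clusters(cs_pair(2.0), k = 2, threshold = 1580)
  expect_identical(cl$clusters, list(1L, 2L, c(1L, 2L)))
  cl2 <- enumerate_clusters(cs_pair(1.0), k = 2, threshold = 1580)
  expect_identical(cl2$clusters, list(1L, 2L))
})

test_that("connectivity keeps triangles linked by strong edges only", {
  b <- matrix(0, 3, 3)
  b[1, 2] <- b[2, 1] <- 2 * pi * 2e3
  b[2, 3] <- b[3, 2] <- 2 * pi * 2e3
  b[1, 3] <- b[3, 1] <- 2 * pi * 0.5e3
  cs <- coupling_set(A_zz = 2 * pi * c(1e6, 2e6, 3e6), b = b,
                     omega_I = fc0$omega_I)
  cl <- enumerate_clusters(cs, k = 3, threshold = 1580)
  key <- vapply(cl$clusters, paste, "", collapse = ",")
  expect_setequal(key, c("1", "2", "3", "1,2", "2,3", "1,2,3"))
  ## the stricter all-pairs rule drops the triple with one weak edge
  cl2 <- enumerate_clusters(cs, k = 3, threshold = 1580, rule = "all_pairs")
  key2 <- vapply(cl2$clusters, paste, "", collapse = ",")
  expect_setequal(key2, c("1", "2", "3", "1,2", "2,3"))
})

test_that("raising the threshold never increases the cluster count", {
  cs <- build_coupling_set(generate_bath(seed = 8, cutoff = 7), fc0)
  sizes <- vapply(c(200, 800, 1580, 5000),
                  function(th) length(enumerate_clusters(cs, 3, th)$clusters),
                  0L)
  expect_true(all(diff(sizes) <= 0))
})

test_that("connected-subset enumeration matches brute force on random graphs", {
  brute <- function(n, adj, k) {
    out <- character()
    for (sz in 2:k) for (cmb in utils::combn(n, sz, simplify = FALSE)) {
      sub <- adj[cmb, cmb, drop = FALSE]
      reach <- c(TRUE, rep(FALSE, sz - 1))
      repeat {
        new <- reach | (colSums(sub[reach, , drop = FALSE]) > 0)
        if (all(new == reach)) break
        reach <- new
      }
      if (all(reach)) out <- c(out, paste(cmb, collapse = ","))
    }
    out
  }
  set.seed(31)
  for (r in 1:4) {
    n <- 9
    adj <- matrix(0, n, n)
    ij <- which(upper.tri(adj), arr.ind = TRUE)
    sel <- ij[runif(nrow(ij)) < 0.25, , drop = FALSE]
    adj[sel] <- 1
    adj <- adj + t(adj)
    b <- 2 * pi * 2e3 * adj
    cs <- coupling_set(A_zz = 2 * pi * seq_len(n) * 1e5, b = b,
                       omega_I = fc0$omega_I)
    cl <- enumerate_clusters(cs, k = 4, threshold = 1000)
    got <- vapply(cl$clusters[lengths(cl$clusters) > 1], paste, "",
                  collapse = ",")
    expect_setequal(got, brute(n, adj, 4))
  }
})

test_that("a lone cluster's correlation factor is its own signal", {
  sig <- matrix(c(1, 0.8, 0.5), 3, 1)
  expect_equal(cce_combine(sig, list(c(1L, 2L))), sig[, 1])
})

test_that("untruncated CCE reproduces the exact oracle", {
  t1 <- seq(0, 4e-6, length.out = 6)
  t2 <- seq(0, 5e-6, length.out = 7)
  for (seed in 1:2) {
    cs <- bath_coupling_subset(seed, 4)
    cl <- enumerate_clusters(cs, k = 4, threshold = 0)
    tot <- cce_total_exported(cs, cl$clusters, t1, t2)
    Vo <- exact_oracle(cs, pulse_refocused(t1, t2))
    expect_lt(max(abs(tot - Vo)), 1e-8)
  }
})

test_that("CCE is multiplicative over spatially disjoint sub-baths", {
  ## two pairs with no inter-pair coupling: total = product of pair signals
  csA <- bath_coupling_subset(3, 2)
  csB <- bath_coupling_subset(9, 2)
  b <- matrix(0, 4, 4)
  b[1:2, 1:2] <- csA$b
  b[3:4, 3:4] <- csB$b
  cs <- coupling_set(c(csA$A_zz, csB$A_zz), c(csA$A_zx, csB$A_zx),
                     c(csA$A_zy, csB$A_zy), b, omega_I = fc0$omega_I)
  t1 <- seq(0, 4e-6, length.out = 5)
  t2 <- seq(0, 4e-6, length.out = 5)
  cl <- enumerate_clusters(cs, k = 4, threshold = 0)
  tot <- cce_total_exported(cs, cl$clusters, t1, t2)
  Vo <- exact_oracle(cs, pulse_refocused(t1, t2))
  expect_lt(max(abs(tot - Vo)), 1e-8)
  VA <- cce_total_exported(csA, enumerate_clusters(csA, 2, 0)$clusters, t1, t2)
  VB <- cce_total_exported(csB, enumerate_clusters(csB, 2, 0)$clusters, t1, t2)
  expect_lt(max(abs(tot - VA * VB)), 1e-10)
})

test_that("one-nucleus clusters alone produce no decay envelope", {
  b <- generate_bath(seed = 3, cutoff = 6)
  sq <- pulse_refocused(seq(0, 6e-6, length.out = 7),
                        seq(0, 6e-6, length.out = 7))
  m_off <- simulate_echo(b, sq, k = 1, pseudo_secular = FALSE)
  expect_lt(max(abs(m_off$V - 1)), 1e-12)
  m_on <- simulate_echo(b, sq, k = 1)
  ## shallow ESEEM oscillation about 1, but no envelope
  expect_gt(min(m_on$V), 0.9)
  expect_lt(mean(abs(m_on$V - 1)), 0.05)
})

test_that("removing the nucleus-nucleus couplings removes the decay", {
  b <- generate_bath(seed = 3, cutoff = 4.6)
  sq <- pulse_refocused(seq(0, 6e-6, length.out = 7),
                        seq(0, 6e-6, length.out = 7))
  m1 <- simulate_echo(b, sq, k = 1)
  m0 <- simulate_echo(b, sq, k = 3, threshold = 0, pair_couplings = FALSE)
  expect_lt(max(abs(m0$V - m1$V)), 1e-10)
})

test_that("an empty bath yields a unit signal with a warning", {
  b <- generate_bath(seed = 1, cutoff = 6, fraction = 0)
  expect_warning(m <- simulate_echo(b, pulse_hahn(c(0, 1e-6, 2e-6))),
                 "empty bath")
  expect_equal(m$V, rep(1, 3))
})

test_that("Lebedev grids normalize and integrate degree-2 harmonics exactly", {
  for (o in c(6, 14, 26)) {
    g <- lebedev_grid(o)
    expect_identical(nrow(g$points), as.integer(o))
    expect_lt(abs(sum(g$weights) - 1), 1e-12)
    expect_true(all(abs(rowSums(g$points^2) - 1) < 1e-12))
    for (u in list(c(0, 0, 1), c(1, 2, -1) / sqrt(6))) {
      f <- 3 * (g$points %*% u)^2 - 1
      expect_lt(abs(sum(g$weights * f)), 1e-12)
    }
  }
  g6 <- lebedev_grid(6)
  expect_equal(g6$weights, rep(1 / 6, 6))
  expect_error(lebedev_grid(10), "unsupported")
})

test_that("excitation weights reduce to Lebedev weights on resonance", {
  g <- lebedev_grid(14)
  w <- excitation_weights(g, function(u) 0, omega1 = 2 * pi * 10e6,
                          t_p90 = 25e-9, t_p180 = 50e-9)
  expect_equal(w, g$weights, tolerance = 1e-12)
})

test_that("a far-off-resonance orientation loses all weight", {
  g <- lebedev_grid(6)
  w <- excitation_weights(g, function(u) if (u[3] > 0.9) 1e12 else 0,
                          omega1 = 2 * pi * 10e6,
                          t_p90 = 25e-9, t_p180 = 50e-9)
  expect_lt(w[5], 1e-6)   # +z orientation
  expect_gt(w[1], 0.1)
})

test_that("pi-pulse transfer at offset omega1 matches the closed form", {
  w1 <- 2 * pi * 10e6
  tp <- 50e-9
  g <- lebedev_grid(6)
  ## orientation +z off-resonant by omega1, others on resonance
  w <- excitation_weights(g, function(u) if (u[3] > 0.9) w1 else 0,
                          omega1 = w1, t_p90 = 25e-9, t_p180 = tp,
                          kind = "hahn")
  f_on <- sin(w1 * tp / 2)^2
  f_off <- 0.5 * sin(sqrt(2) * w1 * tp / 2)^2
  expect_equal(w[5] / w[1],
               (abs(sin(sqrt(2) * w1 * 25e-9)) / sqrt(2) * f_off) /
               (abs(sin(w1 * 25e-9)) * f_on),
               tolerance = 1e-10)
})

test_that("simulated maps are reproducible and carry cluster logs", {
  b <- generate_bath(seed = 5, cutoff = 5)
  sq <- pulse_hahn(seq(0, 2e-6, length.out = 5))
  m1 <- simulate_echo(b, sq, k = 2)
  m2 <- simulate_echo(b, sq, k = 2)
  expect_identical(m1$V, m2$V)
  counts <- attr(m1, "cluster_counts")
  expect_identical(dim(counts), c(14L, 2L))
  expect_true(all(counts[, 1] == nrow(b$protons)))
})
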