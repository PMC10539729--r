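test_that("point-dipole hyperfine matches the closed form", {
  a <- hyperfine_tensor(c(0, 0, 0), c(0, 0, 3), fc0)
  expect_equal(a[["A_zz"]] / (2 * pi) / 1e6, 5.86, tolerance = 2e-3)
  expect_equal(a[["A_zx"]], 0)
  expect_equal(a[["A_zy"]], 0)
  ## magic angle: secular part vanishes
  um <- c(sqrt(1 - 1 / 3), 0, sqrt(1 / 3))
  am <- hyperfine_tensor(c(0, 0, 0), 3 * um, fc0)
  expect_lt(abs(am[["A_zz"]]) / abs(a[["A_zz"]]), 1e-12)
  ## 90 degrees: half magnitude, opposite sign, no pseudo-secular
  a90 <- hyperfine_tensor(c(0, 0, 0), c(3, 0, 0), fc0)
  expect_equal(a90[["A_zz"]], -a[["A_zz"]] / 2)
  expect_equal(a90[["A_zx"]], 0)
  ## 45 degrees: pseudo-secular magnitude 3 D |sin cos|
  a45 <- hyperfine_tensor(c(0, 0, 0), c(3 / sqrt(2), 0, 3 / sqrt(2)), fc0)
  D <- a[["A_zz"]] / 2
  expect_equal(sqrt(a45[["A_zx"]]^2 + a45[["A_zy"]]^2), 3 * D / 2,
               tolerance = 1e-12)
  expect_warning(hyperfine_tensor(c(0, 0, 0), c(0, 0, 1), fc0),
                 "point-dipole")
})

test_that("nuclear pair coupling matches the closed form and is symmetric", {
  b <- pair_coupling(c(0, 0, 0), c(0, 0, 2), fc0)
  expect_equal(b / (2 * pi) / 1e3, 7.51, tolerance = 2e-3)
  expect_identical(pair_coupling(c(0, 0, 2), c(0, 0, 0), fc0), b)
  um <- c(sqrt(1 - 1 / 3), 0, sqrt(1 / 3))
  expect_lt(abs(pair_coupling(c(0, 0, 0), 2 * um, fc0)) / abs(b), 1e-12)
  expect_error(pair_coupling(c(1, 1, 1), c(1, 1, 1), fc0), "coincident")
})

test_that("proton Larmor frequency at 3.38 T is 143.9 MHz", {
  expect_equal(fc0$omega_I / (2 * pi) / 1e6, 143.9, tolerance = 1e-4)
})

test_that("coupling sets assemble all singles and pairs from geometry", {
  b1 <- proton_bath(c(0, 0, 0), matrix(c(0, 0, 3), 1), cutoff = 12)
  cs1 <- build_coupling_set(b1, fc0)
  expect_identical(cs1$n, 1L)
  expect_true(all(cs1$b == 0))
  b <- generate_bath(seed = 4, cutoff = 6)
  cs <- build_coupling_set(b, fc0)
  n <- cs$n
  expect_identical(sum(upper.tri(cs$b)), n * (n - 1L) %/% 2L)
  expect_equal(cs$b, t(cs$b))
  expect_true(all(diag(cs$b) == 0))
  ## consistency with the scalar operations
  k <- which.min(cs$r_en)
  a <- hyperfine_tensor(b$electron, b$protons[k, ], fc0,
                        exclusion = 0)
  expect_equal(cs$A_zz[k], a[["A_zz"]], tolerance = 1e-12)
  expect_equal(sqrt(cs$A_zx[k]^2 + cs$A_zy[k]^2),
               sqrt(a[["A_zx"]]^2 + a[["A_zy"]]^2), tolerance = 1e-12)
  expect_equal(cs$b[1, 2], pair_coupling(b$protons[1, ], b$protons[2, ], fc0),
               tolerance = 1e-12)
  expect_error(build_coupling_set(generate_bath(seed = 1, cutoff = 6,
                                                fraction = 0), fc0),
               "empty")
})

test_that("a 90-degree rotation about an axis perpendicular to B0 halves and flips A_zz", {
  b <- proton_bath(c(0, 0, 0), matrix(c(0, 0, 3), 1), cutoff = 12)
  R <- matrix(c(1, 0, 0, 0, 0, 1, 0, -1, 0), 3, 3)  # 90 deg about x
  cs0 <- build_coupling_set(b, fc0)
  cs90 <- build_coupling_set(b, fc0, rotation = R)
  expect_equal(cs90$A_zz[1], -cs0$A_zz[1] / 2, tolerance = 1e-12)
})

test_that("rotating the geometry and the field together leaves couplings unchanged", {
  b <- generate_bath(seed = 6, cutoff = 6)
  th <- 0.7
  R <- matrix(c(cos(th), sin(th), 0, -sin(th), cos(th), 0, 0, 0, 1), 3, 3) %*%
       matrix(c(1, 0, 0, 0, cos(th), sin(th), 0, -sin(th), cos(th)), 3, 3)
  cs0 <- build_coupling_set(b, field_config(direction = c(0.3, -0.2, 0.9)))
  csR <- build_coupling_set(b, field_config(direction = R %*% c(0.3, -0.2, 0.9)),
                            rotation = R)
  expect_equal(csR$A_zz, cs0$A_zz, tolerance = 1e-9)
  expect_equal(abs(csR$b), abs(cs0$b), tolerance = 1e-9)
  expect_equal(sqrt(csR$A_zx^2 + csR$A_zy^2), sqrt(cs0$A_zx^2 + cs0$A_zy^2),
               tolerance = 1e-9)
})

test_that("cluster Hamiltonians are Hermitian with the required block difference", {
  for (seed in 1:3) {
    cs <- random_coupling_set(3, seed)
    h <- cluster_hamiltonians(cs, 1:3)
    expect_lt(max(abs(h$H_alpha - Conj(t(h$H_alpha)))), 1e-9)
    expect_lt(max(abs(h$H_beta - Conj(t(h$H_beta)))), 1e-9)
    ## H_alpha - H_beta = sum_n (A_zz Iz + A_zx Ix + A_zy Iy)
    dif <- h$H_alpha - h$H_beta
    Iz <- matrix(c(-0.5, 0, 0, 0.5), 2)  # basis order: down, up
    Ix <- matrix(c(0, 0.5, 0.5, 0), 2)
    Iy <- matrix(c(0, -1i, 1i, 0) / 2, 2)  # <up|Iy|down> = -i/2
    ref <- matrix(0i, 8, 8)
    for (k in 1:3) {
      op <- cs$A_zz[k] * Iz + cs$A_zx[k] * Ix + cs$A_zy[k] * Iy
      m <- matrix(1 + 0i, 1, 1)
      for (j in 1:3) m <- if (j == k) kronecker(op, m) else kronecker(diag(2), m)
      ref <- ref + m
    }
    expect_lt(max(abs(dif - ref)), 1e-6 * max(abs(ref)))
  }
})

test_that("single-nucleus secular Hamiltonians have splittings omega_I -/+ A/2", {
  A <- 2 * pi * 3e6
  cs <- coupling_set(A_zz = A, omega_I = fc0$omega_I)
  h <- cluster_hamiltonians(cs, 1)
  ea <- sort(Re(diag(h$H_alpha)))
  eb <- sort(Re(diag(h$H_beta)))
  expect_equal(diff(ea), abs(fc0$omega_I - A / 2), tolerance = 1e-9)
  expect_equal(diff(eb), abs(fc0$omega_I + A / 2), tolerance = 1e-9)
})

test_that("the pair term has flip-flop coefficient b and IzIz coefficient -4b", {
  bv <- 2 * pi * 4e3
  cs <- coupling_set(A_zz = c(0, 0), b = matrix(c(0, bv, bv, 0), 2),
                     omega_I = 0)
  h <- cluster_hamiltonians(cs, 1:2)
  ## basis: 1 |dd>, 2 |ud (site1 up)>, 3 |du>, 4 |uu>
  H <- h$H_alpha
  expect_equal(Re(H[2, 3]), bv, tolerance = 1e-12)
  expect_equal(Re(H[1, 1]), -4 * bv * 0.25, tolerance = 1e-12)
  expect_equal(Re(H[4, 4]), -4 * bv * 0.25, tolerance = 1e-12)
  expect_equal(Re(H[2, 2]), 4 * bv * 0.25, tolerance = 1e-12)
  expect_equal(H, h$H_beta)
  expect_error(cluster_hamiltonians(cs, c(1, 3)), "out of range")
})

test_that("coupling sets export as plain-text tables", {
  cs <- build_coupling_set(generate_bath(seed = 1, cutoff = 5), fc0)
  f <- withr::local_tempfile(fileext = ".txt")
  write_couplings(cs, f)
  ln <- readLines(f)
  expect_identical(sum(startsWith(ln, "proton")), cs$n)
  expect_identical(sum(startsWith(ln, "pair")), cs$n * (cs$n - 1L) %/% 2L)
})
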