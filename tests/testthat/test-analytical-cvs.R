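test_that("rational switch hits its anchor points and decreases", {
  p <- switch_params(d0 = 0.2, r0 = 1.1, l = 6, m = 12)
  expect_equal(rational_switch(0.2, p)$value, 1)
  # removable singularity at (r - d0)/r0 = 1 -> l/m
  expect_equal(rational_switch(0.2 + 1.1, p)$value, 0.5, tolerance = 1e-9)
  expect_lt(rational_switch(50, p)$value, 1e-8)
  r <- seq(0.2, 6, length.out = 200)
  v <- rational_switch(r, p)$value
  expect_true(all(diff(v) < 1e-12))
  expect_true(all(v >= 0 & v <= 1))
  # derivative matches finite differences, including near the singularity
  for (r0 in c(0.5, 1.0, 1.299999, 1.3, 1.300001, 2.7)) {
    fd <- (rational_switch(r0 + 1e-6, p)$value -
             rational_switch(r0 - 1e-6, p)$value) / 2e-6
    expect_equal(rational_switch(r0, p)$deriv, fd, tolerance = 1e-5)
  }
  expect_error(switch_params(r0 = -1), "positive")
  expect_error(switch_params(l = 5, m = 12), "even")
  expect_error(switch_params(l = 12, m = 6), "m > l")
})

test_that("smooth more-than counter is a monotone step at the threshold", {
  t <- threshold_params(0.5)
  expect_equal(more_than(0.5, t)$value, 0.5, tolerance = 1e-9)
  expect_lt(more_than(0.05, t)$value, 0.01)
  expect_gt(more_than(2, t)$value, 0.97)
  x <- seq(0, 3, length.out = 100)
  expect_true(all(diff(more_than(x, t)$value) > -1e-12))
})

test_that("l = 6 spherical harmonics satisfy closed-form identities", {
  # z-axis: only m = 0 survives, with value sqrt(13/4pi)
  Yz <- spherical_harmonics_l6(c(0, 0, 1))
  expect_equal(Re(Yz[7]), sqrt(13 / (4 * pi)), tolerance = 1e-12)
  expect_lt(max(Mod(Yz[-7])), 1e-12)
  set.seed(10)
  for (i in 1:20) {
    v <- stats::rnorm(3)
    Y <- spherical_harmonics_l6(v)
    # addition theorem and conjugation symmetry
    expect_equal(sum(Mod(Y)^2), 13 / (4 * pi), tolerance = 1e-10)
    for (m in 1:6)
      expect_lt(Mod(Y[7 - m] - (-1)^m * Conj(Y[7 + m])), 1e-12)
    # scale invariance (depends only on direction)
    expect_equal(Y, spherical_harmonics_l6(3.7 * v), tolerance = 1e-12)
  }
  expect_error(spherical_harmonics_l6(c(0, 0, 0)), "zero vector")
  # fast path equals the frozen-table reference implementation
  set.seed(11)
  rv <- matrix(stats::rnorm(60), ncol = 3)
  a <- .y6_eval(rv, deriv = TRUE)
  b <- .y6_eval_slow(rv, deriv = TRUE)
  expect_lt(max(Mod(a$Y - b$Y)), 1e-13)
  for (k in 1:3) expect_lt(max(Mod(a$dY[[k]] - b$dY[[k]])), 1e-12)
})

test_that("coordination numbers count switch-weighted neighbors", {
  cvp <- test_cv_params()
  # isolated particle
  iso <- configuration(rbind(c(5, 5, 5), c(5, 5, 12)), box(15))
  g <- build_graph(iso, cvp$cutoff)
  expect_equal(coordination_numbers(iso, g, cvp$p), c(0, 0))
  # ideal fcc interior particle with a near-step switch: c_i ~ 12
  a <- 1.6
  fcc <- make_fcc(4, a)
  steep <- switch_params(0, 0.85 * a, 24, 48)
  gf <- build_graph(fcc, 0.99 * a)
  ci <- coordination_numbers(fcc, gf, steep)
  expect_equal(ci, rep(12, nrow(fcc$positions)), tolerance = 0.02)
  # brute-force all-pairs oracle; a steep switch (tail ~ u^-12) makes the
  # truncation beyond the graph cutoff negligible
  set.seed(12)
  steep2 <- switch_params(0, 1.3, 12, 24)
  cf <- gen_margin_cluster(50, 4.5, seed = 12, sd = 1.5, margin = 0)
  gb <- brute_force_graph(cf, 4.5)
  csum <- coordination_numbers(cf, gb, steep2)
  oracle <- vapply(seq_len(50), function(i) {
    d <- sqrt(colSums((t(cf$positions[-i, ]) - cf$positions[i, ])^2))
    sum(rational_switch(d, steep2)$value)
  }, 0)
  expect_equal(csum, oracle, tolerance = 1e-6)
  expect_error(coordination_numbers(iso, gf, cvp$p), "do not match")
})

test_that("Steinhardt q6m and local Q6 reproduce lattice reference values", {
  cvp <- test_cv_params()
  # ideal 12-neighbor fcc shell: q6 invariant ~ 0.5745
  ctr <- 10
  X <- rbind(c(ctr, ctr, ctr),
             sweep(1.1 * fcc_shell_dirs(), 2, rep(ctr, 3), `+`))
  cf <- configuration(X, box(20))
  g <- build_graph(cf, 1.3)
  q <- steinhardt_q6m(cf, g, cvp$p)
  q6 <- sqrt(4 * pi / 13 * sum(Mod(q[1, ])^2))
  expect_equal(q6, 0.57452, tolerance = 1e-4)
  # single neighbor along z: only m = 0 is nonzero
  pair <- configuration(rbind(c(5, 5, 5), c(5, 5, 6)), box(12))
  gp <- build_graph(pair, 1.3)
  qp <- steinhardt_q6m(pair, gp, cvp$p)
  expect_equal(Re(qp[1, 7]), sqrt(13 / (4 * pi)), tolerance = 1e-10)
  expect_lt(max(Mod(qp[1, -7])), 1e-12)
  # permutation equivariance of the rows
  set.seed(13)
  cl <- gen_margin_cluster(20, 2.6, seed = 13)
  gcl <- build_graph(cl, 2.6)
  qa <- steinhardt_q6m(cl, gcl, cvp$p)
  perm <- sample(20)
  cl2 <- configuration(cl$positions[perm, ], cl$box)
  qb <- steinhardt_q6m(cl2, build_graph(cl2, 2.6), cvp$p)
  expect_equal(qb, qa[perm, ], tolerance = 1e-12)
  # many well-separated random neighbors: q6 invariant ~ 1/sqrt(N), small
  set.seed(14)
  nn <- 200
  dirs <- matrix(0, 0, 3)
  while (nrow(dirs) < nn) {
    v <- stats::rnorm(3); v <- v / sqrt(sum(v^2))
    if (nrow(dirs) == 0 ||
        min(sqrt(rowSums(sweep(dirs, 2, v)^2))) > 0.06)
      dirs <- rbind(dirs, v)
  }
  Xr <- rbind(c(ctr, ctr, ctr), sweep(1.1 * dirs, 2, rep(ctr, 3), `+`))
  cfr <- configuration(Xr, box(20))
  qr <- steinhardt_q6m(cfr, build_graph(cfr, 1.2), cvp$p)
  expect_lt(sqrt(4 * pi / 13 * sum(Mod(qr[1, ])^2)), 0.25)

  # local Q6: interior fcc particles have matching shells -> ~ 1
  fcc <- make_fcc(4, 1.6)
  gq <- build_graph(fcc, 1.9)
  Q6 <- local_Q6(fcc, gq, switch_params(0, 1.15, 6, 12))
  expect_true(all(Q6 > 0.95))
  # isolated particle -> 0
  iso <- configuration(rbind(c(5, 5, 5), c(5, 5, 12)), box(15))
  expect_equal(local_Q6(iso, build_graph(iso, 2), cvp$p), c(0, 0))
})

test_that("cv_n and cv_nQ6 discriminate gas from crystal and stay in [0, N]", {
  cvp <- test_cv_params()
  gas <- make_random_gas(40, box(30), min_sep = 2 * cvp$cutoff, seed = 5)
  gg <- build_graph(gas, cvp$cutoff)
  expect_lt(cv_n(gas, gg, cvp$p, cvp$tc, gradient = FALSE)$value, 0.01)
  expect_lt(cv_nQ6(gas, gg, cvp$p, cvp$tq, gradient = FALSE)$value, 0.01)
  fcc <- make_fcc(4, 1.45)
  N <- nrow(fcc$positions)
  gf <- build_graph(fcc, 2.05)
  pf <- switch_params(0, 1.2, 6, 12)
  vq <- cv_nQ6(fcc, gf, pf, cvp$tq, gradient = FALSE)
  expect_gt(vq$value, 0.95 * N)
  expect_lte(vq$value, N)
  expect_equal(vq$cube_root, vq$value^(1 / 3))
  vn <- cv_n(fcc, gf, pf, cvp$tc, gradient = FALSE)
  expect_gt(vn$value, 0.95 * N)
  expect_lte(vn$value, N)
})

test_that("analytic CV gradients match central finite differences", {
  cvp <- test_cv_params()
  cutoff <- cvp$cutoff
  cf <- gen_margin_cluster(20, cutoff, seed = 42)
  g <- build_graph(cf, cutoff)
  rn <- cv_n(cf, g, cvp$p, cvp$tc)
  fd_n <- finite_difference_gradient(function(c2)
    cv_n(c2, build_graph(c2, cutoff), cvp$p, cvp$tc, gradient = FALSE), cf)
  expect_lt(max(abs(rn$gradient - fd_n)) / max(abs(fd_n)), 1e-5)
  rq <- cv_nQ6(cf, g, cvp$p, cvp$tq)
  fd_q <- finite_difference_gradient(function(c2)
    cv_nQ6(c2, build_graph(c2, cutoff), cvp$p, cvp$tq, gradient = FALSE), cf)
  expect_lt(max(abs(rq$gradient - fd_q)) / max(abs(fd_q)), 1e-5)
  # isolated particles have exactly zero gradient rows
  Xi <- rbind(cf$positions, c(1, 1, 1))
  cfi <- configuration(Xi, cf$box)
  gi <- build_graph(cfi, cutoff)
  ri <- cv_nQ6(cfi, gi, cvp$p, cvp$tq)
  expect_identical(ri$gradient[21, ], c(0, 0, 0))
})

test_that("finite_difference_gradient itself is exact on linear functionals", {
  cf <- configuration(matrix(runif(30, 2, 8), 10, 3), box(50))
  expect_equal(finite_difference_gradient(function(c2) 7, cf),
               matrix(0, 10, 3))
  a <- c(0.3, -1.2, 2.5)
  lin <- function(c2) sum(sweep(c2$positions, 2, a, `*`))
  expect_equal(finite_difference_gradient(lin, cf),
               matrix(a, 10, 3, byrow = TRUE), tolerance = 1e-7)
})

test_that("CVs are invariant under rigid motions and relabeling", {
  cvp <- test_cv_params()
  cf <- gen_margin_cluster(24, cvp$cutoff, seed = 77)
  g <- build_graph(cf, cvp$cutoff)
  v0 <- cv_nQ6(cf, g, cvp$p, cvp$tq, gradient = FALSE)$value
  n0 <- cv_n(cf, g, cvp$p, cvp$tc, gradient = FALSE)$value
  set.seed(99)
  for (i in 1:5) {
    copies <- augment_rotations(cf, 1, seed = i)
    cfr <- copies[[1]]
    gr <- build_graph(cfr, cvp$cutoff)
    expect_equal(cv_nQ6(cfr, gr, cvp$p, cvp$tq, gradient = FALSE)$value, v0,
                 tolerance = 1e-8)
    expect_equal(cv_n(cfr, gr, cvp$p, cvp$tc, gradient = FALSE)$value, n0,
                 tolerance = 1e-8)
    perm <- sample(24)
    cfp <- configuration(cf$positions[perm, ], cf$box)
    gp <- build_graph(cfp, cvp$cutoff)
    expect_equal(cv_nQ6(cfp, gp, cvp$p, cvp$tq, gradient = FALSE)$value, v0,
                 tolerance = 1e-10)
  }
})

test_that("pooled-local and direct n(Q6) formulations agree", {
  cvp <- test_cv_params()
  for (seed in c(21, 22)) {
    cf <- gen_margin_cluster(18, cvp$cutoff, seed = seed)
    g <- build_graph(cf, cvp$cutoff)
    direct <- cv_nQ6(cf, g, cvp$p, cvp$tq, gradient = FALSE)$value
    pooled <- cv_nQ6_pooled(cf, g, cvp$p, cvp$tq)
    expect_lt(abs(direct - pooled), 1e-10)
  }
})

test_that("adding ordered particles increases both counts", {
  cvp <- test_cv_params()
  p <- switch_params(0, 1.2, 6, 12)
  vals_q <- c(); vals_n <- c()
  for (cells in 2:4) {
    fcc <- make_fcc(cells, 1.45)
    g <- build_graph(fcc, min(2.05, min(fcc$box$lengths) / 2 * 0.99))
    vals_q <- c(vals_q, cv_nQ6(fcc, g, p, cvp$tq, gradient = FALSE)$value)
    vals_n <- c(vals_n, cv_n(fcc, g, p, cvp$tc, gradient = FALSE)$value)
  }
  expect_true(all(diff(vals_q) > 0))
  expect_true(all(diff(vals_n) > 0))
})
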