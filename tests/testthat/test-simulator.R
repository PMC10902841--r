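test_that("fixture generators produce the stated geometries reproducibly", {
  fcc <- make_fcc(3, a = 1.5)
  expect_equal(nrow(fcc$positions), 108L)
  expect_equal(fcc$box$lengths, rep(4.5, 3))
  # nearest-neighbor distance is a / sqrt(2) exactly
  g <- brute_force_graph(fcc, 1.2)
  expect_equal(min(sqrt(rowSums(g$rel_vectors^2))), 1.5 / sqrt(2),
               tolerance = 1e-12)
  gas <- make_random_gas(30, box(20), min_sep = 2.5, seed = 4)
  gg <- brute_force_graph(gas, 2.5 - 1e-9)
  expect_equal(length(gg$edges_i), 0L)
  expect_identical(gas$positions,
                   make_random_gas(30, box(20), min_sep = 2.5, seed = 4)$positions)
  expect_error(make_random_gas(500, box(6), min_sep = 2.5, seed = 1,
                               max_tries = 50), "infeasible")
  dr <- make_droplet(40, 8, box(10), seed = 2)
  expect_equal(nrow(dr$positions), 48L)
  expect_identical(dr$positions, make_droplet(40, 8, box(10), seed = 2)$positions)
  # droplet: dense but disordered (high n; n(Q6) well below the particle
  # count - raw packings carry some spurious shell correlation at the
  # low-coordination surface, so "low" means a small fraction of N)
  cvp <- test_cv_params(1.45)
  gq <- build_graph(dr, cvp$cutoff)
  expect_gt(cv_n(dr, gq, cvp$p, threshold_params(3), gradient = FALSE)$value, 10)
  expect_lt(cv_nQ6(dr, gq, cvp$p, cvp$tq, gradient = FALSE)$value,
            0.25 * nrow(dr$positions))
})

test_that("pair forces match the LJ anchors and the energy gradient", {
  pot <- pair_potential(cutoff = 3, shift = FALSE)
  cf <- configuration(rbind(c(5, 5, 5), c(5 + 2^(1 / 6), 5, 5)), box(12))
  fr <- forces(cf, pot)
  expect_equal(fr$energy, -1, tolerance = 1e-12)
  expect_lt(max(abs(fr$forces)), 1e-12)
  # Newton's third law on a generic pair
  cf2 <- configuration(rbind(c(5, 5, 5), c(6.2, 5.4, 5.1)), box(12))
  fr2 <- forces(cf2, pot)
  expect_equal(fr2$forces[1, ], -fr2$forces[2, ], tolerance = 1e-12)
  # finite-difference oracle on a cluster
  cfr <- gen_margin_cluster(12, 2.5, seed = 3, min_sep = 0.9)
  pot2 <- pair_potential(cutoff = 2.5)
  fr3 <- forces(cfr, pot2)
  fd <- finite_difference_gradient(function(c2) forces(c2, pot2)$energy, cfr,
                                   h = 1e-6)
  expect_lt(max(abs(fr3$forces + fd)) / max(abs(fd)), 1e-6)
  over <- configuration(rbind(c(5, 5, 5), c(5, 5, 5 + 1e-6)), box(12))
  expect_error(forces(over, pot), "overlapping")
})

test_that("the integrator conserves energy at zero friction and thermalizes otherwise", {
  fcc <- make_fcc(3, a = 1.55)
  set.seed(3)
  cfp <- configuration(fcc$positions +
                         matrix(stats::rnorm(324, sd = 0.03), ncol = 3),
                       fcc$box)
  pot <- pair_potential(cutoff = 2.2)
  n <- nrow(cfp$positions)
  # NVE: per-particle energy drift below 1e-4 per step
  run <- langevin_run(cfp, pot, sim_config(0.004, 0.3, friction = 0,
                                           n_steps = 300, seed = 5),
                      record_stride = 30, record_frames = FALSE)
  E <- rowSums(run$energies)
  expect_lt(abs(E[length(E)] - E[1]) / 300 / n, 1e-4)
  # zero-temperature quench: potential energy non-increasing to a minimum
  runq <- langevin_run(cfp, pot, sim_config(0.002, 0, friction = 5,
                                            n_steps = 400, seed = 6),
                       record_stride = 40, record_frames = FALSE)
  pe <- runq$energies[, "potential"]
  expect_lt(pe[length(pe)], pe[1])
  # NVT equipartition: mean kinetic energy per particle ~ 3/2 T
  runt <- langevin_run(cfp, pot, sim_config(0.004, 0.7, friction = 2,
                                            n_steps = 1500, seed = 7),
                       record_stride = 10, record_frames = FALSE)
  ke <- runt$energies[-(1:50), "kinetic"] / n
  expect_equal(mean(ke), 1.5 * 0.7, tolerance = 0.08)
  # bitwise reproducibility
  r1 <- langevin_run(cfp, pot, sim_config(0.004, 0.5, 1, 50, 9),
                     record_stride = 25, record_frames = FALSE)
  r2 <- langevin_run(cfp, pot, sim_config(0.004, 0.5, 1, 50, 9),
                     record_stride = 25, record_frames = FALSE)
  expect_identical(r1$final$positions, r2$final$positions)
})

test_that("harmonic pulling tracks the moving center and degenerates correctly", {
  dw <- double_well_potential(height = 2, center = 25, width = 1)
  pot <- pair_potential("none")
  cf <- configuration(matrix(c(24, 10, 10), 1, 3), box(50))
  cv <- make_coordinate_cv(1, 1, offset = 25)
  sc <- sim_config(0.01, temperature = 0.2, friction = 2, n_steps = 3000,
                   seed = 11)
  # stiff spring: CV follows the schedule from one basin to the other
  run <- pull(cf, pot, sc, cv, kappa = 50, schedule = c(-1, 1), ext = dw,
              record_stride = 50)
  s <- drop(run$cv)
  ctr <- drop(run$centers)
  expect_lt(max(abs(s - ctr)[-(1:5)]), 0.35)
  expect_gt(tail(s, 1), 0.6)
  # zero kappa equals the unbiased run with the same seed
  run0 <- pull(cf, pot, sc, cv, kappa = 0, schedule = c(-1, 1), ext = dw,
               record_stride = 50)
  free <- langevin_run(cf, pot, sc, ext = dw, record_stride = 50,
                       record_frames = FALSE)
  expect_identical(run0$final$positions, free$final$positions)
  # schedule of length 1 is a static restraint
  run1 <- pull(cf, pot, sc, cv, kappa = 50, schedule = -1, ext = dw,
               record_stride = 50)
  expect_equal(mean(drop(run1$cv)[-(1:5)]), -1, tolerance = 0.15)
})

test_that("umbrella windows overlap and WHAM recovers the double-well barrier", {
  h <- 2
  dw <- double_well_potential(height = h, center = 25, width = 1)
  pot <- pair_potential("none")
  cf <- configuration(matrix(c(24, 10, 10), 1, 3), box(50))
  cv <- make_coordinate_cv(1, 1, offset = 25)
  sc <- sim_config(0.01, temperature = 0.4, friction = 2, n_steps = 4000,
                   seed = 13)
  centers <- seq(-1.3, 1.3, length.out = 9)
  run <- umbrella_scan(cf, pot, sc, cv, kappa = 20, centers, ext = dw,
                       record_stride = 4)
  expect_s3_class(run, "umbrella_run")
  # adjacent windows overlap
  for (w in seq_len(8)) {
    a <- range(run$series[[w]]); b <- range(run$series[[w + 1]])
    expect_gt(min(a[2], b[2]) - max(a[1], b[1]), 0)
  }
  prof <- wham_1d(run, n_bins = 48)
  barrier <- profile_barrier(prof$s, prof$F, split = 0)
  expect_lt(abs(barrier - h) / h, 0.10)
  # seeded reruns reproduce every series
  run2 <- umbrella_scan(cf, pot, sc, cv, kappa = 20, centers, ext = dw,
                        record_stride = 4)
  expect_identical(run$series, run2$series)
})

test_that("WHAM degenerates to -T log histogram for one unbiased window", {
  set.seed(5)
  samples <- stats::rnorm(4000, sd = 0.7)
  run <- structure(list(centers = 0, series = list(samples), kappa = 0,
                        temperature = 0.5), class = "umbrella_run")
  prof <- wham_1d(run, n_bins = 24)
  edges <- seq(min(samples) - 1e-9, max(samples) + 1e-9, length.out = 25)
  Hc <- tabulate(findInterval(samples, edges, rightmost.closed = TRUE), 24)
  ref <- -0.5 * log(Hc / sum(Hc))
  ref <- ref - min(ref[is.finite(ref)])
  expect_equal(prof$F[is.finite(prof$F)], ref[is.finite(ref)],
               tolerance = 1e-8)
})

test_that("metadynamics deposits Gaussians correctly and crosses the double well", {
  # a single deposited Gaussian evaluates to exactly w at its center
  bs <- bias_spec("metadynamics", make_coordinate_cv(1, 1), w = 0.3,
                  sigma_g = 0.2, pace = 1, gamma = Inf, grid_min = -2,
                  grid_max = 2, grid_n = 401)
  gr <- .metad_grid_init(bs)
  expect_true(all(gr$V == 0))          # zero bias before any deposition
  gr <- .metad_deposit(gr, 0.37, 0.3, 0.2)
  lk <- .metad_lookup(gr, 0.37)
  expect_equal(lk$V, 0.3, tolerance = 1e-4)
  expect_equal(.metad_lookup(gr, 0.37 + 0.2)$V, 0.3 * exp(-0.5),
               tolerance = 1e-3)

  h <- 2
  dw <- double_well_potential(height = h, center = 25, width = 1)
  pot <- pair_potential("none")
  cf <- configuration(matrix(c(24, 10, 10), 1, 3), box(50))
  cv <- make_coordinate_cv(1, 1, offset = 25)
  sc <- sim_config(0.01, temperature = 0.4, friction = 2, n_steps = 30000,
                   seed = 17)
  run <- metadynamics_run(cf, pot, sc, cv, w = 0.15, sigma_g = 0.15,
                          pace = 100, gamma = 10, grid_min = -2.2,
                          grid_max = 2.2, grid_n = 301,
                          ext = dw, record_stride = 20)
  s <- drop(run$cv)
  expect_gte(count_recrossings(s, -0.5, 0.5), 2)
  fes <- metad_free_energy(run, gamma = 10)
  inner <- fes$s > -1.6 & fes$s < 1.6
  barrier <- profile_barrier(fes$s[inner], fes$F[inner], split = 0)
  expect_lt(abs(barrier - h) / h, 0.15)
})

test_that("well-tempered heights decay while standard metadynamics keeps them fixed", {
  dw <- double_well_potential(height = 1, center = 25, width = 1)
  pot <- pair_potential("none")
  cf <- configuration(matrix(c(24, 10, 10), 1, 3), box(50))
  cv <- make_coordinate_cv(1, 1, offset = 25)
  sc <- sim_config(0.01, 0.4, 2, 4000, 19)
  wt <- metadynamics_run(cf, pot, sc, cv, w = 0.2, sigma_g = 0.15,
                         pace = 50, gamma = 5, grid_min = -2.2,
                         grid_max = 2.2, grid_n = 221, ext = dw)
  expect_lt(min(wt$bias_state$heights), 0.2)
  expect_true(all(diff(range(wt$bias_state$heights)) > 0))
  std <- metadynamics_run(cf, pot, sc, cv, w = 0.2, sigma_g = 0.15,
                          pace = 50, gamma = Inf, grid_min = -2.2,
                          grid_max = 2.2, grid_n = 221, ext = dw)
  expect_true(all(std$bias_state$heights == 0.2))
})

test_that("transition enrichment increases the in-band fraction", {
  fit <- toy_trained()
  ds <- fit$dataset
  cvp <- fit$cvp
  pot <- pair_potential(cutoff = 2.5)
  sc <- sim_config(0.004, 0.42, 1, 100, 23)
  rng <- range(ds$labels)
  band <- rng[1] + c(0.35, 0.55) * diff(rng)
  label_fun <- function(cf) {
    g <- build_graph(cf, cvp$cutoff)
    cube_root_transform(cv_nQ6(cf, g, cvp$p, cvp$tq, gradient = FALSE)$value)
  }
  expect_identical(transition_enrichment(ds, band, 0, 100, pot, sc, label_fun),
                   ds)
  expect_error(transition_enrichment(ds, rng[2] + c(1, 2), 3, 100, pot, sc,
                                     label_fun), "band")
  enriched <- transition_enrichment(ds, band, 4, 60, pot, sc, label_fun,
                                    seed = 3, record_stride = 20)
  expect_gt(length(enriched$frames), length(ds$frames))
  expect_true(any(enriched$provenance == "burst"))
  frac0 <- mean(ds$labels >= band[1] & ds$labels <= band[2])
  frac1 <- mean(enriched$labels >= band[1] & enriched$labels <= band[2])
  expect_gt(frac1, frac0)
})
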