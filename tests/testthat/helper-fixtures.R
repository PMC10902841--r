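# shared fixtures and oracles, built in code at test time

# dense random cluster in a large box, rejecting pair distances too close
# to `cutoff` so finite-difference probes cannot flip graph edges
gen_margin_cluster <- function(n, cutoff, seed, sd = 1.2, min_sep = 0.75,
                               margin = 0.02, box_len = 20) {
  set.seed(seed)
  repeat {
    X <- matrix(stats::rnorm(3 * n, sd = sd), ncol = 3) + box_len / 2
    d <- as.matrix(stats::dist(X)); diag(d) <- Inf
    if (min(d) <= min_sep) next
    # margin only matters when finite differences probe the configuration;
    # it is feasible only for small n (the rejection succeeds rarely
    # otherwise), so it is skipped when margin = 0
    if (margin > 0 && min(abs(d[is.finite(d)] - cutoff)) <= margin) next
    return(configuration(X, box(box_len)))
  }
}

# default analytical-CV parameter set used across tests
test_cv_params <- function(r0 = 1.3) {
  list(p = switch_params(0, r0, 6, 12),
       tq = threshold_params(0.5),
       tc = threshold_params(5),
       cutoff = 2 * r0)
}

# the 12 ideal fcc nearest-neighbor directions
fcc_shell_dirs <- function() {
  rbind(c(1, 1, 0), c(1, -1, 0), c(-1, 1, 0), c(-1, -1, 0),
        c(1, 0, 1), c(1, 0, -1), c(-1, 0, 1), c(-1, 0, -1),
        c(0, 1, 1), c(0, 1, -1), c(0, -1, 1), c(0, -1, -1)) / sqrt(2)
}

# memoised small equilibrated droplet shared by slower tests
.fixture_env <- new.env()

toy_droplet <- function() {
  if (is.null(.fixture_env$droplet)) {
    start <- make_droplet(60, 10, box(10), seed = 11)
    pot <- pair_potential(cutoff = 2.5)
    eq <- langevin_run(start, pot, sim_config(0.004, 0.33, 1, 500, 21),
                       record_stride = 500, record_frames = FALSE)
    .fixture_env$droplet <- eq$final
  }
  .fixture_env$droplet
}

# small labeled pulling dataset + trained model shared by biasing tests
toy_trained <- function() {
  if (is.null(.fixture_env$trained)) {
    pot <- pair_potential(cutoff = 2.5)
    cvp <- test_cv_params(1.45)
    cv <- make_analytical_cv("nQ6", cvp$p, cvp$tq, cvp$cutoff)
    start <- toy_droplet()
    q0 <- eval_cv(cv, start, gradient = FALSE)$values
    run <- pull(start, pot, sim_config(0.004, 0.33, 1, 1500, 31), cv,
                kappa = 1, schedule = c(q0, 45), record_stride = 10)
    frames <- run$frames[-1]
    labels <- cube_root_transform(drop(run$cv)[-1])
    ds <- labeled_dataset(frames, labels)
    model <- init_model(gnn_config(8, 2, cutoff = 1.45, seed = 7))
    tc <- train_config(1e-3, epochs = 40, batch_size = 16, split = 0.8,
                       seed = 7, patience = 40)
    fit <- train_model(model, ds, tc)
    .fixture_env$trained <- list(model = fit$model, dataset = ds,
                                 cv = cv, cvp = cvp, start = start,
                                 report = fit$report)
  }
  .fixture_env$trained
}


# memoised reduced-scale model-quality experiment shared by the acceptance
# criteria (1 trains/evaluates it, 7a biases with its model)
acceptance_t1 <- function() {
  if (is.null(.fixture_env$t1)) {
    # reduced scale: fewer recorded frames at the full trajectory length
    # (matching the pulling rate of the full protocol)
    gen_train <- generate_nucleation_dataset(seed = 1211L, n_frames = 150L,
                                             steps_per_frame = 32L,
                                             start_seed = 11L)
    gen_test <- generate_nucleation_dataset(seed = 1999L, n_frames = 60L,
                                            steps_per_frame = 80L,
                                            start_seed = 11L)
    fit <- train_default_model(gen_train, seed = 77L, epochs = 40L,
                               patience = 15L, n_restarts = 1L)
    .fixture_env$t1 <- list(gen_train = gen_train, gen_test = gen_test,
                            fit = fit)
  }
  .fixture_env$t1
}
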