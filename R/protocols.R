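# End-to-end data-generation protocol for the train-then-bias workflow:
# condense a droplet, adapt the CV scales to its radial distribution
# function, then drive it toward a crystal with a moving restraint on the
# analytical n(Q6), labeling every recorded frame. Produces the labeled
# synthetic trajectories that the model-quality experiments train and
# evaluate on, with no external data.

#' Generate a labeled droplet-to-crystal pulling trajectory
#'
#' Builds a dense Lennard-Jones droplet with a dilute gas background,
#' equilibrates it in the canonical ensemble, derives the coordination
#' length scale from the first minimum of the radial distribution
#' function, and then pulls the system along the analytical n(Q6) with a
#' harmonic restraint whose center moves linearly to `target`. Every
#' recorded frame is labeled with its analytical n(Q6) (the biased CV
#' itself, evaluated at recording time).
#'
#' All stochastic stages derive their streams from `seed`; two calls with
#' the same arguments are bitwise identical, and different seeds give
#' independent realizations of the biased dynamics from the same
#' equilibrated starting state (`start_seed` controls the droplet and its
#' equilibration so train/test trajectories share a starting basin, as
#' independent members of one transition-path ensemble).
#'
#' @param seed seed of the pulling dynamics.
#' @param n_frames number of labeled frames to record.
#' @param steps_per_frame Langevin steps between recorded frames.
#' @param start_seed seed of the droplet construction and equilibration.
#' @param n_core,n_gas droplet core and gas particle counts.
#' @param box_len cubic box edge (reduced units).
#' @param temperature reduced temperature. Default 0.38, chosen by two
#'   desk-scale diagnostics (measurements in the methods vignette): order
#'   persistence after the restraint is released (poor at 0.42, where a
#'   ~130-particle cluster is above its size-depressed melting point) and
#'   reproducibility of the pulled ensemble across realizations (poor at
#'   0.33, where the supercooled paths turn glassy and heterogeneous).
#' @param kappa pulling spring constant.
#' @param target final restraint center (n(Q6) particles).
#' @param equil_steps unbiased equilibration steps before pulling.
#' @param timestep,friction integrator parameters.
#' @return list with `dataset` (a [labeled_dataset()] of `n_frames`
#'   frames, labels = cube root of n(Q6)), `r0` (first RDF minimum),
#'   `switch` ([switch_params()]), `threshold` ([threshold_params()]),
#'   `cv_cutoff`, `cv` (the analytical evaluator), and `start` (the
#'   equilibrated configuration).
#' @export
generate_nucleation_dataset <- function(seed, n_frames = 300L,
                                        steps_per_frame = 16L,
                                        start_seed = 11L, n_core = 130L,
                                        n_gas = 20L, box_len = 12,
                                        temperature = 0.38, kappa = 1,
                                        target = 110, equil_steps = 800L,
                                        timestep = 0.004, friction = 1) {
  pot <- pair_potential(cutoff = 2.5)
  start <- make_droplet(n_core, n_gas, box(box_len), seed = start_seed)
  eq <- langevin_run(start, pot,
                     sim_config(timestep, temperature, friction,
                                as.integer(equil_steps), start_seed + 100L),
                     record_stride = as.integer(equil_steps),
                     record_frames = FALSE)
  rdf <- radial_distribution(eq$final,
                             r_max = box_len / 2 * 0.8, n_bins = 100L)
  r0 <- first_rdf_minimum(rdf)
  p <- switch_params(0, r0, 6L, 12L)
  tq <- threshold_params(0.5)
  cvq <- make_analytical_cv("nQ6", p, tq, 2 * r0)
  q0 <- eval_cv(cvq, eq$final, gradient = FALSE)$values
  run <- pull(eq$final, pot,
              sim_config(timestep, temperature, friction,
                         as.integer(n_frames) * as.integer(steps_per_frame),
                         seed),
              cvq, kappa = kappa, schedule = c(q0, target),
              record_stride = as.integer(steps_per_frame))
  frames <- run$frames[-1]          # drop the unpulled frame 0
  labels_raw <- drop(run$cv)[-1]
  list(dataset = labeled_dataset(frames, cube_root_transform(labels_raw)),
       labels_raw = labels_raw, r0 = r0, switch = p, threshold = tq,
       cv_cutoff = 2 * r0, cv = cvq, start = eq$final, potential = pot)
}

#' Train the default graph CV approximator on a labeled trajectory
#'
#' Convenience wrapper reproducing the reference training recipe: default
#' model (latent dimension 8, two graph-convolutional layers) with the
#' neighbor-list cutoff at the system's first RDF minimum, Adam at
#' learning rate 1e-3 on the cube-root labels with an 80/20 split and
#' early stopping.
#'
#' @param gen result of [generate_nucleation_dataset()].
#' @param seed training seed (initialization, split, shuffling).
#' @param epochs,patience training schedule.
#' @param n_restarts independent training runs (seeds `seed`,
#'   `seed + 1000`, ...); the run with the lowest validation MSE is
#'   returned. Training from small single-trajectory datasets is
#'   seed-sensitive (occasional runs collapse to a mis-scaled fit), and
#'   best-of-restarts on the hold-out is the standard remedy.
#' @param n_aug_rot roto-translated copies added per frame (fixed, seeded;
#'   labels carried over). The learning target is exactly rotation
#'   invariant while the architecture is not, and a single trajectory
#'   shows essentially one crystal orientation, so without this the model
#'   generalizes across independent realizations only by luck (measured:
#'   cross-realization r between -0.6 and +0.98 over seed pairs without
#'   augmentation, >= 0.97 with it). Default 3.
#' @return as [train_model()].
#' @export
train_default_model <- function(gen, seed = 1L, epochs = 50L,
                                patience = 12L, n_restarts = 2L,
                                n_aug_rot = 3L) {
  ds <- gen$dataset
  if (n_aug_rot > 0) {
    frames <- ds$frames; labels <- ds$labels
    af <- list(); al <- c()
    for (i in seq_along(frames)) {
      cps <- augment_rotations(frames[[i]], n_aug_rot, seed = 5000L + i)
      af <- c(af, cps); al <- c(al, rep(labels[i], length(cps)))
    }
    ds <- labeled_dataset(c(frames, af), c(labels, al),
                          c(rep("base", length(frames)),
                            rep("augmented", length(af))))
  }
  best <- NULL
  for (k in seq_len(max(1L, n_restarts))) {
    sk <- as.integer(seed + (k - 1L) * 1000L)
    model <- init_model(gnn_config(latent_dim = 8L, n_layers = 2L,
                                   cutoff = gen$r0, seed = sk))
    tc <- train_config(learning_rate = 1e-3, epochs = epochs,
                       batch_size = 16L, split = 0.8, seed = sk,
                       target_transform = "cube_root", patience = patience)
    fit <- train_model(model, ds, tc)
    if (is.null(best) ||
        min(fit$report$val_mse) < min(best$report$val_mse)) best <- fit
  }
  best
}
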