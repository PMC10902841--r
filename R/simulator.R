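# Desk-scale particle simulator: lattice / gas / droplet fixture
# generators, a Lennard-Jones pair-potential engine, BAOAB Langevin
# dynamics in the canonical ensemble, and the bias protocols (moving
# restraint, umbrella windows, well-tempered metadynamics) driven by any
# cv_evaluator. All runs are bitwise reproducible from their seeds.

#' Pair potential
#'
#' Lennard-Jones stands in for the colloidal pair interaction; the "none"
#' kind turns off pair forces (single-particle diagnostics on external
#' potentials).
#'
#' @param kind "lennard_jones" or "none".
#' @param epsilon energy scale.
#' @param sigma length scale.
#' @param cutoff interaction cutoff (> sigma).
#' @param shift shift the energy so it is continuous at the cutoff.
#' @return object of class `pair_potential`.
#' @export
pair_potential <- function(kind = c("lennard_jones", "none"), epsilon = 1,
                           sigma = 1, cutoff = 2.5, shift = TRUE) {
  kind <- match.arg(kind)
  if (kind == "lennard_jones" && cutoff <= sigma)
    stop("cutoff must exceed sigma")
  structure(list(kind = kind, epsilon = epsilon, sigma = sigma,
                 cutoff = cutoff, shift = isTRUE(shift)),
            class = "pair_potential")
}

#' Simulation parameters
#'
#' @param timestep integration step (reduced time units, > 0).
#' @param temperature reduced temperature (>= 0).
#' @param friction Langevin friction coefficient (0 gives microcanonical
#'   velocity Verlet).
#' @param n_steps number of steps.
#' @param seed RNG seed (thermostat noise and initial velocities).
#' @return object of class `sim_config`.
#' @export
sim_config <- function(timestep = 0.005, temperature = 0.5, friction = 1,
                       n_steps = 1000L, seed = 1L) {
  if (timestep <= 0) stop("timestep must be positive")
  if (temperature < 0) stop("temperature must be >= 0")
  structure(list(timestep = timestep, temperature = temperature,
                 friction = friction, n_steps = as.integer(n_steps),
                 seed = as.integer(seed)), class = "sim_config")
}

#' Pairwise energy and forces
#'
#' Minimum-image pair sum at the potential cutoff; forces are the exact
#' negative gradient of the energy.
#'
#' @param config a [configuration()].
#' @param potential a [pair_potential()].
#' @param graph optional prebuilt graph at the potential cutoff.
#' @return list with `energy` and N x 3 `forces`.
#' @export
forces <- function(config, potential, graph = NULL) {
  n <- nrow(config$positions)
  if (potential$kind == "none")
    return(list(energy = 0, forces = matrix(0, n, 3)))
  if (is.null(graph)) graph <- build_graph(config, potential$cutoff)
  if (length(graph$edges_i) == 0)
    return(list(energy = 0, forces = matrix(0, n, 3)))
  rel <- graph$rel_vectors
  r <- sqrt(rowSums(rel^2))
  if (any(r < 1e-3 * potential$sigma)) stop("overlapping particles (r -> 0)")
  sr6 <- (potential$sigma / r)^6
  eps4 <- 4 * potential$epsilon
  phi <- eps4 * (sr6^2 - sr6)
  if (potential$shift) {
    src6 <- (potential$sigma / potential$cutoff)^6
    phi <- phi - eps4 * (src6^2 - src6)
  }
  dphi <- eps4 * (-12 * sr6^2 + 6 * sr6) / r     # d phi / d r
  # F_i = sum_j phi'(r_ij) rhat_ij  (per directed edge grouped by i)
  F <- .rowsum_full(rel * (dphi / r), graph$edges_i, n)
  list(energy = sum(phi) / 2, forces = F)
}

#' Closed-form double-well external potential
#'
#' V(u) = height * ((u^2 - width^2) / width^2)^2 acting on one coordinate
#' u = x[particle, axis] - center; minima at u = +-width, barrier = height
#' at u = 0. The exact free-energy profile along u is V itself, which
#' makes this the analytic oracle for umbrella/WHAM and metadynamics.
#'
#' @param height barrier height (reduced energy units).
#' @param center coordinate offset (e.g. box center).
#' @param axis,particle which coordinate the well acts on.
#' @param width half-distance between the minima.
#' @return object of class `external_potential` with fields
#'   `energy_force(positions)` and `profile(u)`.
#' @export
double_well_potential <- function(height = 2, center = 0, axis = 1L,
                                  particle = 1L, width = 1) {
  ef <- function(positions) {
    u <- positions[particle, axis] - center
    q <- (u^2 - width^2) / width^2
    Fm <- matrix(0, nrow(positions), 3)
    Fm[particle, axis] <- -height * 2 * q * 2 * u / width^2
    list(energy = height * q^2, forces = Fm)
  }
  structure(list(energy_force = ef,
                 profile = function(u) height * ((u^2 - width^2) / width^2)^2,
                 height = height, center = center, axis = axis,
                 particle = particle, width = width),
            class = "external_potential")
}

#' Bias protocol specification
#'
#' @param kind "pull" (moving harmonic restraint), "umbrella" (static
#'   restraint) or "metadynamics".
#' @param cv a [cv_evaluator()].
#' @param kappa spring constant (pull/umbrella; >= 0).
#' @param center static center (umbrella) or length-2 schedule
#'   `c(start, end)` moved linearly over the run (pull). Vectors of
#'   matching dimension for multivariate CVs.
#' @param w Gaussian height (metadynamics).
#' @param sigma_g Gaussian widths per CV dimension.
#' @param pace deposition interval in steps (>= 1).
#' @param gamma well-tempered bias factor (> 1, or Inf for standard
#'   non-tempered metadynamics).
#' @param grid_min,grid_max,grid_n bias grid per CV dimension (spacing
#'   should be <= sigma_g / 5).
#' @return object of class `bias_spec`.
#' @export
bias_spec <- function(kind = c("pull", "umbrella", "metadynamics"), cv,
                      kappa = 0, center = NULL, w = 1, sigma_g = 0.1,
                      pace = 500L, gamma = Inf, grid_min = NULL,
                      grid_max = NULL, grid_n = NULL) {
  kind <- match.arg(kind)
  if (!inherits(cv, "cv_evaluator")) stop("cv must be a cv_evaluator")
  if (kappa < 0) stop("kappa must be >= 0")
  if (kind == "metadynamics") {
    if (pace < 1) stop("pace must be >= 1")
    if (!(gamma > 1)) stop("gamma must be > 1 (Inf for standard metadynamics)")
    if (any(sigma_g <= 0) || w <= 0) stop("w and sigma_g must be positive")
    if (is.null(grid_min) || is.null(grid_max) || is.null(grid_n))
      stop("metadynamics needs grid_min/grid_max/grid_n")
  }
  structure(list(kind = kind, cv = cv, kappa = kappa, center = center,
                 w = w, sigma_g = sigma_g, pace = as.integer(pace),
                 gamma = gamma, grid_min = grid_min, grid_max = grid_max,
                 grid_n = grid_n), class = "bias_spec")
}

# -- metadynamics bias grid (1-D or 2-D) ------------------------------------

.metad_grid_init <- function(bs) {
  d <- length(bs$grid_min)
  axes <- lapply(seq_len(d), function(k)
    seq(bs$grid_min[k], bs$grid_max[k], length.out = bs$grid_n[k]))
  dims <- vapply(axes, length, 0L)
  list(d = d, axes = axes,
       V = array(0, dims),
       dV = lapply(seq_len(d), function(k) array(0, dims)),
       heights = numeric(0), centers = NULL)
}

# analytic Gaussian accumulated onto the grid (value and gradient grids)
.metad_deposit <- function(gr, s, h, sigma_g) {
  if (gr$d == 1) {
    u <- (gr$axes[[1]] - s[1]) / sigma_g[1]
    g <- h * exp(-0.5 * u^2)
    gr$V <- gr$V + g
    gr$dV[[1]] <- gr$dV[[1]] - g * u / sigma_g[1]
  } else {
    u1 <- (gr$axes[[1]] - s[1]) / sigma_g[1]
    u2 <- (gr$axes[[2]] - s[2]) / sigma_g[2]
    g1 <- exp(-0.5 * u1^2); g2 <- exp(-0.5 * u2^2)
    G <- h * outer(g1, g2)
    gr$V <- gr$V + G
    gr$dV[[1]] <- gr$dV[[1]] - G * (u1 / sigma_g[1])
    gr$dV[[2]] <- gr$dV[[2]] - sweep(G, 2, u2 / sigma_g[2], `*`)
  }
  gr$heights <- c(gr$heights, h)
  gr$centers <- rbind(gr$centers, s)
  gr
}

# linear interpolation of the bias value and gradient at CV point s
.metad_lookup <- function(gr, s) {
  idx <- list(); frac <- list()
  for (k in seq_len(gr$d)) {
    ax <- gr$axes[[k]]
    x <- min(max(s[k], ax[1]), ax[length(ax)])
    i <- max(1L, min(length(ax) - 1L, findInterval(x, ax)))
    idx[[k]] <- i
    frac[[k]] <- (x - ax[i]) / (ax[i + 1] - ax[i])
  }
  lin1 <- function(A, i, f) A[i] * (1 - f) + A[i + 1] * f
  if (gr$d == 1) {
    i <- idx[[1]]; f <- frac[[1]]
    list(V = lin1(gr$V, i, f), dV = lin1(gr$dV[[1]], i, f))
  } else {
    i <- idx[[1]]; j <- idx[[2]]; f <- frac[[1]]; g <- frac[[2]]
    bil <- function(A) {
      (A[i, j] * (1 - f) + A[i + 1, j] * f) * (1 - g) +
        (A[i, j + 1] * (1 - f) + A[i + 1, j + 1] * f) * g
    }
    list(V = bil(gr$V), dV = c(bil(gr$dV[[1]]), bil(gr$dV[[2]])))
  }
}

# -- Langevin dynamics -------------------------------------------------------

#' BAOAB Langevin dynamics with optional CV bias
#'
#' Canonical-ensemble integrator (BAOAB splitting); friction 0 recovers
#' microcanonical velocity Verlet. When a [bias_spec()] is supplied, the
#' CV evaluator's gradient (already masked for model CVs) enters the
#' force: harmonic restraints contribute -kappa (s - center) grad s, and
#' metadynamics contributes -dV_bias/ds grad s with Gaussians deposited
#' every `pace` steps (well-tempered height scaling for finite gamma).
#'
#' @param config starting [configuration()].
#' @param potential a [pair_potential()].
#' @param sc a [sim_config()].
#' @param bias optional [bias_spec()].
#' @param ext optional external potential (e.g.
#'   [double_well_potential()]).
#' @param record_stride store a frame and CV samples every this many steps.
#' @param monitors named list of extra [cv_evaluator()]s evaluated
#'   (without gradients) at each recorded frame.
#' @param record_frames store configurations (disable to save memory).
#' @return list with `frames`, `steps`, `cv` (matrix of biased-CV values
#'   per recorded step), `monitor` (matrix of monitor values), `energies`
#'   (potential/kinetic per record), `final` configuration, `bias_state`
#'   (metadynamics grid), `centers` (restraint center per record).
#' @export
langevin_run <- function(config, potential, sc, bias = NULL, ext = NULL,
                         record_stride = 10L, monitors = list(),
                         record_frames = TRUE) {
  X <- config$positions
  n <- nrow(X)
  L <- config$box$lengths
  dt <- sc$timestep
  gam <- sc$friction
  c1 <- exp(-gam * dt)
  c2 <- sqrt(sc$temperature * (1 - c1^2))
  grid <- if (!is.null(bias) && bias$kind == "metadynamics")
    .metad_grid_init(bias) else NULL

  # one neighbor search per step, shared by the pair potential and the CV
  cut_pot <- if (potential$kind == "none") 0 else potential$cutoff
  cut_cv <- if (!is.null(bias)) bias$cv$cutoff else 0
  cut_max <- max(cut_pot, cut_cv)

  eval_forces <- function(cf, step) {
    G <- if (cut_max > 0) build_graph(cf, cut_max) else NULL
    fr <- if (cut_pot > 0) forces(cf, potential, subgraph(G, cut_pot))
          else list(energy = 0, forces = matrix(0, n, 3))
    Ftot <- fr$forces
    E <- fr$energy
    sval <- NULL
    if (!is.null(ext)) {
      ex <- ext$energy_force(cf$positions)
      Ftot <- Ftot + ex$forces
      E <- E + ex$energy
    }
    if (!is.null(bias)) {
      cvr <- eval_cv(bias$cv, cf, gradient = TRUE, graph = G)
      sval <- cvr$values
      if (bias$kind %in% c("pull", "umbrella")) {
        ctr <- .bias_center(bias, step, sc$n_steps)
        for (q in seq_along(sval)) {
          Ftot <- Ftot - bias$kappa * (sval[q] - ctr[q]) * cvr$gradients[[q]]
          E <- E + 0.5 * bias$kappa * (sval[q] - ctr[q])^2
        }
      } else {
        lk <- .metad_lookup(grid, sval)
        for (q in seq_along(sval)) {
          Ftot <- Ftot - lk$dV[q] * cvr$gradients[[q]]
        }
      }
    }
    list(F = Ftot, E = E, s = sval)
  }

  nrec <- 0L
  frames <- list(); cvs <- list(); mons <- list(); ens <- list()
  ctrs <- list(); steps_rec <- integer(0)

  with_seed(sc$seed, {
    V <- matrix(stats::rnorm(n * 3, sd = sqrt(max(sc$temperature, 0))), n, 3)
    cf <- configuration(X, config$box, config$id)
    fe <- eval_forces(cf, 0L)
    record <- function(step, fe, Vm) {
      nrec <<- nrec + 1L
      if (record_frames) frames[[nrec]] <<- cf
      steps_rec[nrec] <<- step
      cvs[[nrec]] <<- if (is.null(fe$s)) NA_real_ else fe$s
      ens[[nrec]] <<- c(potential = fe$E, kinetic = 0.5 * sum(Vm^2))
      if (!is.null(bias) && bias$kind %in% c("pull", "umbrella"))
        ctrs[[nrec]] <<- .bias_center(bias, step, sc$n_steps)
      if (length(monitors))
        mons[[nrec]] <<- vapply(monitors, function(m)
          eval_cv(m, cf, gradient = FALSE)$values[1], 0)
    }
    record(0L, fe, V)
    for (step in seq_len(sc$n_steps)) {
      V <- V + 0.5 * dt * fe$F
      Xn <- cf$positions + 0.5 * dt * V
      if (gam > 0) V <- c1 * V + c2 * matrix(stats::rnorm(n * 3), n, 3)
      Xn <- Xn + 0.5 * dt * V
      if (any(!is.finite(Xn)))
        stop(sprintf("non-finite coordinates at step %d", step))
      cf <- configuration(Xn, config$box, config$id)
      fe <- eval_forces(cf, step)
      V <- V + 0.5 * dt * fe$F
      if (!is.null(grid) && step %% bias$pace == 0L) {
        h <- bias$w
        if (is.finite(bias$gamma)) {
          vb <- .metad_lookup(grid, fe$s)$V
          h <- bias$w * exp(-vb / (sc$temperature * (bias$gamma - 1)))
        }
        grid <- .metad_deposit(grid, fe$s, h, bias$sigma_g)
        # force field changed; refresh cached bias force at current point
        fe <- eval_forces(cf, step)
      }
      if (step %% record_stride == 0L) record(step, fe, V)
    }
  })
  list(frames = frames, steps = steps_rec,
       cv = do.call(rbind, cvs),
       monitor = if (length(monitors)) do.call(rbind, mons) else NULL,
       energies = do.call(rbind, ens),
       centers = if (length(ctrs)) do.call(rbind, ctrs) else NULL,
       final = cf, bias_state = grid)
}

.bias_center <- function(bias, step, n_steps) {
  if (bias$kind == "umbrella" || length(bias$center) == bias$cv$dim)
    return(bias$center)
  # pull: center is rbind(start, end) or c(start, end) for 1-D
  ctr <- bias$center
  if (is.null(dim(ctr))) ctr <- matrix(ctr, 2)
  frac <- if (n_steps > 0) step / n_steps else 1
  ctr[1, ] + frac * (ctr[2, ] - ctr[1, ])
}

#' Pulling (moving restraint) simulation
#'
#' Drags the system along a CV with a harmonic restraint whose center
#' moves linearly from `schedule[1]` to `schedule[2]`; records the biased
#' CV and an analytical reference CV per frame.
#'
#' @inheritParams langevin_run
#' @param cv the biased [cv_evaluator()].
#' @param kappa spring constant.
#' @param schedule numeric `c(start, end)` (a single value gives a static
#'   restraint).
#' @param ref_cv optional reference [cv_evaluator()] monitored per frame.
#' @return as [langevin_run()], plus `ref` (reference CV series).
#' @export
pull <- function(config, potential, sc, cv, kappa, schedule, ext = NULL,
                 ref_cv = NULL, record_stride = 10L) {
  if (length(schedule) == 1) schedule <- c(schedule, schedule)
  bs <- bias_spec("pull", cv, kappa = kappa, center = schedule)
  monitors <- if (is.null(ref_cv)) list() else list(ref = ref_cv)
  out <- langevin_run(config, potential, sc, bias = bs, ext = ext,
                      record_stride = record_stride, monitors = monitors)
  out$ref <- if (is.null(ref_cv)) NULL else drop(out$monitor)
  out
}

#' Umbrella-sampling window scan
#'
#' Static-restraint windows at a ladder of centers. Windows are run with
#' independent seeds; each starts from the final configuration of the
#' previous window (a standard ladder initialization that promotes
#' histogram overlap) and discards a burn-in fraction.
#'
#' @inheritParams pull
#' @param centers sorted vector of window centers.
#' @param burn_in fraction of each window discarded before sampling.
#' @return object of class `umbrella_run`: `centers`, `series` (list of
#'   CV sample vectors per window), `kappa`, `temperature`.
#' @export
umbrella_scan <- function(config, potential, sc, cv, kappa, centers,
                          ext = NULL, record_stride = 5L, burn_in = 0.2) {
  if (length(centers) < 1) stop("need at least one window center")
  series <- vector("list", length(centers))
  start <- config
  for (wdx in seq_along(centers)) {
    scw <- sc
    scw$seed <- sc$seed + wdx
    bs <- bias_spec("umbrella", cv, kappa = kappa, center = centers[wdx])
    run <- langevin_run(start, potential, scw, bias = bs, ext = ext,
                        record_stride = record_stride, record_frames = FALSE)
    svals <- drop(run$cv)
    keep <- seq_along(svals) > ceiling(burn_in * length(svals))
    if (!any(keep)) stop(sprintf("window %d produced no samples", wdx))
    series[[wdx]] <- svals[keep]
    start <- run$final
  }
  structure(list(centers = centers, series = series, kappa = kappa,
                 temperature = sc$temperature), class = "umbrella_run")
}

#' Well-tempered metadynamics run
#'
#' Deposits Gaussians of height `w exp(-V_bias / (T (gamma - 1)))` (or
#' constant height for gamma = Inf) every `pace` steps along a 1-D or 2-D
#' CV; the bias and its gradient are accumulated analytically on a grid
#' and interpolated linearly for the force.
#'
#' @inheritParams pull
#' @param w,sigma_g,pace,gamma,grid_min,grid_max,grid_n see [bias_spec()].
#' @return as [langevin_run()]; `bias_state` holds the grid (fields
#'   `axes`, `V`, `dV`, `heights`, `centers`).
#' @export
metadynamics_run <- function(config, potential, sc, cv, w, sigma_g, pace,
                             gamma = Inf, grid_min, grid_max, grid_n,
                             ext = NULL, record_stride = 10L, monitors = list()) {
  bs <- bias_spec("metadynamics", cv, w = w, sigma_g = sigma_g, pace = pace,
                  gamma = gamma, grid_min = grid_min, grid_max = grid_max,
                  grid_n = grid_n)
  langevin_run(config, potential, sc, bias = bs, ext = ext,
               record_stride = record_stride, monitors = monitors)
}

#' Free-energy estimate from a well-tempered bias
#'
#' F(s) = -(gamma / (gamma - 1)) V_bias(s) (+ constant), the standard
#' well-tempered relation; for gamma = Inf, F = -V_bias. Minimum set to 0.
#'
#' @param run result of [metadynamics_run()] (1-D CV).
#' @param gamma the bias factor used in the run.
#' @return list with `s` (grid) and `F` (profile).
#' @export
metad_free_energy <- function(run, gamma = Inf) {
  gr <- run$bias_state
  if (gr$d != 1) stop("free-energy readout implemented for 1-D runs")
  fac <- if (is.finite(gamma)) gamma / (gamma - 1) else 1
  Fv <- -fac * gr$V
  list(s = gr$axes[[1]], F = Fv - min(Fv))
}

#' Count basin recrossings of a 1-D CV series
#'
#' Hysteresis counter: a crossing is registered each time the series
#' passes from below `low` to above `high` or vice versa.
#'
#' @param s numeric series.
#' @param low,high basin thresholds (low < high).
#' @return integer number of transitions.
#' @export
count_recrossings <- function(s, low, high) {
  state <- 0L; crossings <- 0L
  for (v in s) {
    if (state == 0L) {
      if (v <= low) state <- -1L else if (v >= high) state <- 1L
    } else if (state == -1L && v >= high) {
      crossings <- crossings + 1L; state <- 1L
    } else if (state == 1L && v <= low) {
      crossings <- crossings + 1L; state <- -1L
    }
  }
  crossings
}

# -- fixture generators ------------------------------------------------------

#' FCC lattice fixture
#'
#' @param n_cells integer vector of 3 unit-cell counts (a single number is
#'   recycled).
#' @param a lattice constant.
#' @return a [configuration()] with `4 * prod(n_cells)` particles in a
#'   matched periodic box.
#' @export
make_fcc <- function(n_cells = 3L, a = 1.5) {
  if (length(n_cells) == 1) n_cells <- rep(n_cells, 3)
  if (any(n_cells < 1)) stop("n_cells must be >= 1")
  basis <- matrix(c(0, 0, 0, 0, .5, .5, .5, 0, .5, .5, .5, 0), 4, 3,
                  byrow = TRUE)
  cells <- as.matrix(expand.grid(x = seq_len(n_cells[1]) - 1,
                                 y = seq_len(n_cells[2]) - 1,
                                 z = seq_len(n_cells[3]) - 1))
  X <- do.call(rbind, lapply(seq_len(nrow(cells)), function(i)
    sweep(basis, 2, cells[i, ], `+`)))
  configuration(X * a, box(n_cells * a))
}

#' Random-gas fixture
#'
#' Uniform positions with rejection below a minimal pair separation.
#'
#' @param n number of particles.
#' @param box a [box()].
#' @param min_sep minimal minimum-image pair distance.
#' @param seed RNG seed.
#' @param max_tries rejection budget per particle.
#' @return a [configuration()].
#' @export
make_random_gas <- function(n, box, min_sep = 2.0, seed = 1L,
                            max_tries = 500L) {
  with_seed(seed, {
    X <- matrix(NA_real_, n, 3)
    for (i in seq_len(n)) {
      placed <- FALSE
      for (try in seq_len(max_tries)) {
        cand <- stats::runif(3) * box$lengths
        if (i == 1) { X[i, ] <- cand; placed <- TRUE; break }
        d <- .min_image_mat(sweep(X[seq_len(i - 1), , drop = FALSE], 2, cand,
                                  function(a, b) b - a), box$lengths)
        if (min(sqrt(rowSums(d^2))) >= min_sep) {
          X[i, ] <- cand; placed <- TRUE; break
        }
      }
      if (!placed) stop("packing infeasible: rejection budget exhausted")
    }
    configuration(X, box)
  })
}

#' Dense-droplet fixture
#'
#' An amorphous dense cluster centered in the box, optionally surrounded
#' by a dilute gas: the dispersed-phase/dense-droplet starting point of a
#' toy nucleation run.
#'
#' @param n_core particles in the dense cluster.
#' @param n_gas particles in the surrounding gas.
#' @param box a [box()].
#' @param seed RNG seed.
#' @param core_density target number density of the cluster.
#' @param min_sep_core minimal pair distance inside the cluster.
#' @param min_sep_gas minimal distance of gas particles to everything.
#' @param max_tries rejection budget per particle.
#' @return a [configuration()].
#' @export
make_droplet <- function(n_core, n_gas = 0L, box, seed = 1L,
                         core_density = 0.55, min_sep_core = 0.92,
                         min_sep_gas = 1.8, max_tries = 4000L) {
  with_seed(seed, {
    R <- (3 * n_core / (4 * pi * core_density))^(1 / 3)
    if (2 * (R + min_sep_gas) > min(box$lengths))
      stop("packing infeasible: droplet does not fit the box")
    ctr <- box$lengths / 2
    X <- matrix(NA_real_, n_core + n_gas, 3)
    for (i in seq_len(n_core)) {
      placed <- FALSE
      for (try in seq_len(max_tries)) {
        u <- stats::rnorm(3)
        cand <- ctr + R * stats::runif(1)^(1 / 3) * u / sqrt(sum(u^2))
        if (i == 1) { X[i, ] <- cand; placed <- TRUE; break }
        d <- sweep(X[seq_len(i - 1), , drop = FALSE], 2, cand)
        if (min(sqrt(rowSums(d^2))) >= min_sep_core) {
          X[i, ] <- cand; placed <- TRUE; break
        }
      }
      if (!placed) stop("packing infeasible: rejection budget exhausted (core)")
    }
    for (i in n_core + seq_len(n_gas)) {
      placed <- FALSE
      for (try in seq_len(max_tries)) {
        cand <- stats::runif(3) * box$lengths
        d <- .min_image_mat(sweep(X[seq_len(i - 1), , drop = FALSE], 2, cand,
                                  function(a, b) b - a), box$lengths)
        if (min(sqrt(rowSums(d^2))) >= min_sep_gas) {
          X[i, ] <- cand; placed <- TRUE; break
        }
      }
      if (!placed) stop("packing infeasible: rejection budget exhausted (gas)")
    }
    configuration(X, box)
  })
}

#' Transition-region dataset enrichment
#'
#' Rare-event datasets underrepresent the transition region; this
#' selects up to `n_bursts` frames whose labels fall inside `band`, runs
#' short unbiased bursts from each until a basin test fires (or the burst
#' length is exhausted), labels the visited frames with `label_fun`, and
#' returns the original data plus the provenance-tagged burst frames.
#'
#' @param dataset a [labeled_dataset()].
#' @param band numeric `c(low, high)` label band defining the transition
#'   region.
#' @param n_bursts number of burst restarts (0 returns the input).
#' @param burst_length steps per burst.
#' @param potential,sc simulation setup for the bursts (`sc$n_steps` is
#'   ignored in favor of `burst_length`).
#' @param label_fun function(configuration) -> label.
#' @param basin_test function(label) -> TRUE when a basin is reached;
#'   default: label outside `band`.
#' @param seed RNG seed (frame selection and burst seeds).
#' @param record_stride burst frame/label stride.
#' @return a [labeled_dataset()] with provenance "base" + "burst".
#' @export
transition_enrichment <- function(dataset, band, n_bursts, burst_length,
                                  potential, sc, label_fun,
                                  basin_test = NULL, seed = 1L,
                                  record_stride = 10L) {
  if (band[1] >= band[2]) stop("band must be c(low, high) with low < high")
  if (n_bursts == 0) return(dataset)
  in_band <- which(dataset$labels >= band[1] & dataset$labels <= band[2])
  if (length(in_band) == 0) stop("no frames with labels inside the band")
  if (is.null(basin_test))
    basin_test <- function(label) label < band[1] || label > band[2]
  sel <- with_seed(seed, {
    if (length(in_band) <= n_bursts) in_band
    else sort(sample(in_band, n_bursts))
  })
  new_frames <- list(); new_labels <- c()
  for (b in seq_along(sel)) {
    scb <- sc
    scb$n_steps <- as.integer(burst_length)
    scb$seed <- sc$seed + 1000L * b + seed
    run <- langevin_run(dataset$frames[[sel[b]]], potential, scb,
                       record_stride = record_stride)
    for (f in run$frames[-1]) {
      lb <- label_fun(f)
      new_frames <- c(new_frames, list(f))
      new_labels <- c(new_labels, lb)
      if (basin_test(lb)) break
    }
  }
  labeled_dataset(c(dataset$frames, new_frames),
                  c(dataset$labels, new_labels),
                  c(dataset$provenance, rep("burst", length(new_frames))))
}
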