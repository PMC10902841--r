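# Permutation-invariant message-passing model of a nucleation CV:
# per-node embedding of box-scaled coordinates, per-edge messages over raw
# minimum-image displacement vectors, k neighborhood updates with constant
# edge weights (= 1), sum pooling, and a graph decoder. Reverse-mode
# gradients with respect to both parameters and coordinates are hand-coded.

#' Graph-model hyperparameters
#'
#' @param latent_dim latent (internal) dimensionality m (>= 1).
#' @param n_layers number of graph-convolutional rounds k (>= 0).
#' @param cutoff neighbor-list cutoff radius used to build input graphs.
#' @param out_dim number of CVs predicted at once (>= 1); multivariate
#'   models widen only the decoder's last layer.
#' @param seed integer seed for parameter initialization.
#' @param hidden hidden-layer width of the four maps (default twice the
#'   latent dimension).
#' @param envelope multiply edge messages by a smooth cosine cutoff
#'   function so the model is continuous when pairs cross the graph
#'   cutoff (default TRUE; standard practice in message-passing
#'   interatomic models, and it keeps bias forces continuous).
#' @param linear_decoder if TRUE the decoder is a single linear layer
#'   (used for additivity diagnostics); default FALSE.
#' @return object of class `gnn_config`.
#' @export
gnn_config <- function(latent_dim = 8L, n_layers = 2L, cutoff = 1.5,
                       out_dim = 1L, seed = 1L, hidden = 2L * latent_dim,
                       envelope = TRUE, linear_decoder = FALSE) {
  latent_dim <- as.integer(latent_dim); n_layers <- as.integer(n_layers)
  out_dim <- as.integer(out_dim); hidden <- as.integer(hidden)
  if (latent_dim < 1 || out_dim < 1 || n_layers < 0 || hidden < 1)
    stop("invalid model dimensions")
  if (cutoff <= 0) stop("cutoff must be positive")
  structure(list(latent_dim = latent_dim, n_layers = n_layers,
                 cutoff = cutoff, out_dim = out_dim, seed = as.integer(seed),
                 hidden = hidden, envelope = isTRUE(envelope),
                 linear_decoder = isTRUE(linear_decoder)),
            class = "gnn_config")
}

#' Initialize a graph model
#'
#' Parameters are drawn with Glorot-uniform initialization from
#' `config$seed`; identical seeds give bitwise-identical models. Each of
#' the maps (embed, per-layer edge and node-update, decoder) is a
#' two-layer perceptron of width `latent_dim` with tanh hidden activation.
#'
#' @param config a [gnn_config()].
#' @return object of class `gnn_model`.
#' @export
init_model <- function(config) {
  if (!inherits(config, "gnn_config")) stop("config must be a gnn_config")
  m <- config$latent_dim
  h <- config$hidden
  with_seed(config$seed, {
    embed <- mlp_init(c(3, h, m))
    psiE <- lapply(seq_len(config$n_layers), function(i) mlp_init(c(3, h, m)))
    psiN <- lapply(seq_len(config$n_layers), function(i) mlp_init(c(2 * m, h, m)))
    decoder <- if (config$linear_decoder) mlp_init(c(m, config$out_dim))
               else mlp_init(c(m, h, config$out_dim))
    structure(list(config = config, embed = embed, psiE = psiE,
                   psiN = psiN, decoder = decoder,
                   scalers = list(node = vector("list", config$n_layers),
                                  dec = NULL)),
              class = "gnn_model")
  })
}

#' Fit the frozen feature scalers of a model
#'
#' Sum pooling over hundreds of nodes (and message pooling over dozens of
#' neighbors) produces pre-activation magnitudes far outside the linear
#' range of tanh, which stalls optimization. This fits per-feature affine
#' standardizers (mean / standard deviation over the supplied inputs) in
#' front of each node-update map and the decoder. The statistics are
#' frozen into the model, so predictions stay exactly permutation
#' invariant and differentiable; [train_model()] calls this automatically
#' before optimizing.
#'
#' @param model a `gnn_model`.
#' @param inputs list of [gnn_input()] objects (typically the training
#'   frames).
#' @return the model with fitted `scalers`.
#' @export
fit_scalers <- function(model, inputs) {
  k <- model$config$n_layers
  m <- model$config$latent_dim
  model$scalers <- list(node = vector("list", k), dec = NULL)
  mk <- function(M) {
    sd <- apply(M, 2, stats::sd)
    sd[!is.finite(sd) | sd < 1e-8] <- 1
    list(mu = colMeans(M), sd = sd)
  }
  # fit layer by layer: each fit changes the inputs downstream maps see
  for (t in seq_len(k)) {
    feats <- lapply(inputs, function(inp) {
      fwc <- .gnn_forward_cache(model, inp)
      if (t == 1) {
        H <- fwc$fw_embed$out
      } else {
        H <- fwc$fwN[[t - 1]]$out
      }
      M <- matrix(0, inp$n, m)
      if (length(inp$ei) > 0)
        M <- .rowsum_full(mlp_forward(model$psiE[[t]], inp$rel), inp$ei, inp$n)
      cbind(H, M)
    })
    model$scalers$node[[t]] <- mk(do.call(rbind, feats))
  }
  pooled <- t(vapply(inputs, function(inp)
    .gnn_forward_cache(model, inp)$pooled, numeric(m)))
  model$scalers$dec <- mk(pooled)
  model
}

#' @export
print.gnn_model <- function(x, ...) {
  cat(sprintf(
    "graph CV model: latent %d, %d conv layers, out_dim %d, cutoff %g, %d parameters\n",
    x$config$latent_dim, x$config$n_layers, x$config$out_dim,
    x$config$cutoff, count_parameters(x)))
  invisible(x)
}

#' Number of learnable parameters
#' @param model a `gnn_model`.
#' @return integer total across all maps.
#' @export
count_parameters <- function(model) {
  sum(vapply(.gnn_nets(model), mlp_n_params, 0))
}

.gnn_nets <- function(model) {
  c(list(model$embed), model$psiE, model$psiN, list(model$decoder))
}

.gnn_set_nets <- function(model, nets) {
  k <- model$config$n_layers
  model$embed <- nets[[1]]
  model$psiE <- nets[seq_len(k) + 1]
  model$psiN <- nets[seq_len(k) + 1 + k]
  model$decoder <- nets[[2 * k + 2]]
  model
}

#' Precompute the model input of a configuration
#'
#' Packs box-scaled coordinates and the directed edge list with raw
#' minimum-image displacement vectors; reusable across forward/backward
#' passes and training epochs.
#'
#' @param config a [configuration()].
#' @param graph optional prebuilt `particle_graph`; built at `cutoff`
#'   otherwise.
#' @param cutoff cutoff used when `graph` is NULL.
#' @return object of class `gnn_input`.
#' @export
gnn_input <- function(config, graph = NULL, cutoff = NULL) {
  if (is.null(graph)) {
    if (is.null(cutoff)) stop("need a graph or a cutoff")
    graph <- build_graph(config, cutoff)
  }
  .check_sizes(config, graph)
  n <- graph$n_nodes
  structure(list(
    X0 = sweep(config$positions, 2, config$box$lengths, `/`),
    ei = graph$edges_i, ej = graph$edges_j, rel = graph$rel_vectors,
    deg = graph_degrees(graph), n = n, cutoff = graph$cutoff,
    box_lengths = config$box$lengths), class = "gnn_input")
}

.as_gnn_input <- function(model, config, graph = NULL) {
  if (inherits(config, "gnn_input")) {
    inp <- config
  } else {
    inp <- gnn_input(config, graph, model$config$cutoff)
  }
  if (abs(inp$cutoff - model$config$cutoff) > 1e-12)
    stop("graph cutoff does not match the model cutoff")
  inp
}

# apply / invert a frozen feature scaler (affine standardization fitted on
# the training set; identity when NULL). Keeping the statistics frozen
# preserves exact permutation invariance and differentiability.
.scale_fwd <- function(X, sc) {
  if (is.null(sc)) X
  else sweep(sweep(X, 2, sc$mu), 2, sc$sd, `/`)
}
.scale_bwd <- function(dX, sc) {
  if (is.null(sc)) dX else sweep(dX, 2, sc$sd, `/`)
}

# smooth cosine cutoff envelope: 1 at r = 0, 0 with zero slope at rc
.envelope <- function(r, rc) {
  list(f = 0.5 * (cos(pi * r / rc) + 1),
       df = -0.5 * pi / rc * sin(pi * r / rc))
}

# forward pass with caches for reverse mode
.gnn_forward_cache <- function(model, inp) {
  n <- inp$n; m <- model$config$latent_dim
  scl <- model$scalers
  fw_embed <- mlp_forward(model$embed, inp$X0, cache = TRUE)
  H <- fw_embed$out
  k <- model$config$n_layers
  fwE <- vector("list", k); fwN <- vector("list", k)
  has_edges <- length(inp$ei) > 0
  env <- NULL
  if (has_edges && model$config$envelope) {
    re <- sqrt(rowSums(inp$rel^2))
    env <- .envelope(re, model$config$cutoff)
    env$r <- re
  }
  for (t in seq_len(k)) {
    M <- matrix(0, n, m)
    if (has_edges) {
      fwE[[t]] <- mlp_forward(model$psiE[[t]], inp$rel, cache = TRUE)
      Eout <- if (is.null(env)) fwE[[t]]$out else fwE[[t]]$out * env$f
      M <- .rowsum_full(Eout, inp$ei, n)
    }
    C <- .scale_fwd(cbind(H, M), scl$node[[t]])
    fwN[[t]] <- mlp_forward(model$psiN[[t]], C, cache = TRUE)
    H <- fwN[[t]]$out
  }
  P <- matrix(colSums(H), 1, m)
  fw_dec <- mlp_forward(model$decoder, .scale_fwd(P, scl$dec), cache = TRUE)
  list(out = drop(fw_dec$out), pooled = drop(P), nodes = H,
       fw_embed = fw_embed, fwE = fwE, fwN = fwN, fw_dec = fw_dec,
       has_edges = has_edges, env = env)
}

# backward pass from an output adjoint vector; returns coordinate adjoints
# (N x 3, in real coordinates, unmasked) and optionally parameter gradients
.gnn_backward <- function(model, inp, fwc, dout, param_grad = FALSE) {
  n <- inp$n; m <- model$config$latent_dim
  k <- model$config$n_layers
  scl <- model$scalers
  bd <- mlp_backward(model$decoder, fwc$fw_dec, matrix(dout, 1))
  gdec <- bd$grads
  dP <- .scale_bwd(bd$dX, scl$dec)
  dH <- matrix(rep(drop(dP), each = n), n, m)      # sum pooling fan-out
  dRel <- matrix(0, length(inp$ei), 3)
  gE <- vector("list", k); gN <- vector("list", k)
  for (t in rev(seq_len(k))) {
    bn <- mlp_backward(model$psiN[[t]], fwc$fwN[[t]], dH)
    gN[[t]] <- bn$grads
    dC <- .scale_bwd(bn$dX, scl$node[[t]])
    dH <- dC[, seq_len(m), drop = FALSE]
    dM <- dC[, m + seq_len(m), drop = FALSE]
    if (fwc$has_edges) {
      dMe <- dM[inp$ei, , drop = FALSE]
      env <- fwc$env
      if (is.null(env)) {
        be <- mlp_backward(model$psiE[[t]], fwc$fwE[[t]], dMe)
        gE[[t]] <- be$grads
        dRel <- dRel + be$dX
      } else {
        be <- mlp_backward(model$psiE[[t]], fwc$fwE[[t]], dMe * env$f)
        gE[[t]] <- be$grads
        denv <- rowSums(fwc$fwE[[t]]$out * dMe) * env$df / env$r
        dRel <- dRel + be$dX + inp$rel * denv
      }
    } else {
      gE[[t]] <- .zero_grads(model$psiE[[t]])
    }
  }
  bemb <- mlp_backward(model$embed, fwc$fw_embed, dH)
  gemb <- bemb$grads
  dX <- sweep(bemb$dX, 2, inp$box_lengths, `/`)   # scaled-coordinate chain
  if (fwc$has_edges) {
    dX <- dX + .rowsum_full(dRel, inp$ej, n) - .rowsum_full(dRel, inp$ei, n)
  }
  res <- list(dX = dX)
  if (param_grad) {
    nets <- vector("list", 2 * k + 2)
    nets[[1]] <- list(layers = gemb)
    for (t in seq_len(k)) { nets[[t + 1]] <- list(layers = gE[[t]]) }
    for (t in seq_len(k)) { nets[[t + 1 + k]] <- list(layers = gN[[t]]) }
    nets[[2 * k + 2]] <- list(layers = gdec)
    res$grad_flat <- .flatten_params(nets)
  }
  res
}

.zero_grads <- function(net) {
  lapply(net$layers, function(l) list(W = l$W * 0, b = l$b * 0))
}

#' Evaluate the graph model
#'
#' @param model a `gnn_model`.
#' @param config a [configuration()] or precomputed [gnn_input()].
#' @param graph optional prebuilt graph (must match the model cutoff).
#' @param nodes if TRUE, also return per-node latent states and the pooled
#'   latent vector.
#' @return numeric vector of length `out_dim` (with attributes `pooled`
#'   and `nodes` when `nodes = TRUE`).
#' @export
gnn_forward <- function(model, config, graph = NULL, nodes = FALSE) {
  inp <- .as_gnn_input(model, config, graph)
  fwc <- .gnn_forward_cache(model, inp)
  out <- fwc$out
  if (nodes) {
    attr(out, "pooled") <- fwc$pooled
    attr(out, "nodes") <- fwc$nodes
  }
  out
}

#' Model prediction with masked coordinate gradient
#'
#' Exact reverse-mode derivative of [gnn_forward()] with respect to all
#' coordinates; the gradient rows of particles with no graph neighbors are
#' then overwritten with zeros before the result is handed to any biasing
#' code (node-level noise must not push on isolated particles).
#'
#' @inheritParams gnn_forward
#' @param mask apply the isolated-particle masking rule (default TRUE).
#' @return list of class `model_prediction` with `values` (length
#'   `out_dim`) and `gradients` (list of N x 3 matrices, one per output);
#'   `gradient` aliases the first one.
#' @export
gnn_gradient <- function(model, config, graph = NULL, mask = TRUE) {
  inp <- .as_gnn_input(model, config, graph)
  fwc <- .gnn_forward_cache(model, inp)
  od <- model$config$out_dim
  grads <- vector("list", od)
  for (q in seq_len(od)) {
    dout <- rep(0, od); dout[q] <- 1
    G <- .gnn_backward(model, inp, fwc, dout)$dX
    if (mask && any(inp$deg == 0)) G[inp$deg == 0, ] <- 0
    grads[[q]] <- G
  }
  structure(list(values = fwc$out, gradients = grads,
                 gradient = grads[[1]]), class = "model_prediction")
}

#' Serialize a model to a portable self-describing file
#'
#' JSON container with a format version, the full configuration, all
#' parameter arrays, and a checksum over configuration and parameters.
#' Round trips reproduce predictions bitwise on the same platform.
#'
#' @param model a `gnn_model`.
#' @param path destination file.
#' @export
serialize_model <- function(model, path) {
  theta <- .flatten_params(.gnn_nets(model))
  cfg <- unclass(model$config)
  sc <- unlist(model$scalers)                 # NULL-safe flattening
  obj <- list(format = "gnncv-model", version = 1L, config = cfg,
              n_params = length(theta),
              params = theta,
              scalers = model$scalers,
              checksum = .model_checksum(cfg, c(sc, theta)))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = I(17))
  invisible(path)
}

#' @rdname serialize_model
#' @return `deserialize_model` returns the reconstructed `gnn_model`.
#' @export
deserialize_model <- function(path) {
  obj <- tryCatch(jsonlite::read_json(path, simplifyVector = TRUE,
                                      simplifyDataFrame = FALSE,
                                      simplifyMatrix = FALSE),
                  error = function(e) stop("truncated or unreadable model file: ",
                                           conditionMessage(e)))
  if (is.null(obj$format) || obj$format != "gnncv-model" ||
      is.null(obj$version) || obj$version != 1L)
    stop("model file version mismatch (expected gnncv-model v1)")
  cfg <- obj$config
  config <- gnn_config(latent_dim = cfg$latent_dim, n_layers = cfg$n_layers,
                       cutoff = cfg$cutoff, out_dim = cfg$out_dim,
                       seed = cfg$seed, hidden = cfg$hidden,
                       envelope = cfg$envelope,
                       linear_decoder = cfg$linear_decoder)
  theta <- as.numeric(obj$params)
  if (length(theta) != obj$n_params) stop("truncated model file")
  scalers <- list(node = vector("list", config$n_layers), dec = NULL)
  valid_sc <- function(x) !is.null(x) && length(x$mu) > 0
  if (!is.null(obj$scalers)) {
    sn <- obj$scalers$node
    for (t in seq_along(sn)) {
      if (valid_sc(sn[[t]]))
        scalers$node[[t]] <- list(mu = as.numeric(sn[[t]]$mu),
                                  sd = as.numeric(sn[[t]]$sd))
    }
    if (valid_sc(obj$scalers$dec))
      scalers$dec <- list(mu = as.numeric(obj$scalers$dec$mu),
                          sd = as.numeric(obj$scalers$dec$sd))
  }
  if (!identical(.model_checksum(unclass(config),
                                 c(unlist(scalers), theta)),
                 obj$checksum))
    stop("model file checksum mismatch: file was modified or corrupted")
  model <- init_model(config)
  model$scalers <- scalers
  set_parameters(model, theta)
}

# rolling polynomial hash over the printed configuration and parameters
# (integrity guard against hand-edited model files, not cryptographic)
.model_checksum <- function(cfg, theta) {
  txt <- paste(c(unlist(cfg), sprintf("%.17g", theta)), collapse = "|")
  bytes <- utf8ToInt(txt)
  h <- 0
  for (b in bytes) h <- (h * 131 + b) %% 2147483647
  sprintf("%08x", h)
}

#' Get or set the flat parameter vector of a model
#' @param model a `gnn_model`.
#' @return `get_parameters`: numeric vector of all parameters.
#' @export
get_parameters <- function(model) .flatten_params(.gnn_nets(model))

#' @rdname get_parameters
#' @param theta replacement flat parameter vector.
#' @export
set_parameters <- function(model, theta) {
  if (length(theta) != count_parameters(model))
    stop("parameter vector has the wrong length")
  .gnn_set_nets(model, .unflatten_params(.gnn_nets(model), theta))
}
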