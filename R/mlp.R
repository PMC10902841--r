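# Minimal dense-network machinery shared by the graph model's four maps
# (embed, edge, node-update, decoder) and the brute-force MLP baseline.
# Hand-coded forward/backward; tanh hidden activations keep bias forces
# continuous when a trained model is used as a CV.

# seed-scoped RNG: runs code under a temporary seed, restoring global state
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  set.seed(seed)
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  code
}

# layer sizes: c(in, h1, ..., out); final layer linear, hidden layers tanh
mlp_init <- function(sizes) {
  n <- length(sizes) - 1
  layers <- vector("list", n)
  for (k in seq_len(n)) {
    fan_in <- sizes[k]; fan_out <- sizes[k + 1]
    lim <- sqrt(6 / (fan_in + fan_out))    # Glorot uniform
    layers[[k]] <- list(
      W = matrix(stats::runif(fan_in * fan_out, -lim, lim), fan_in, fan_out),
      b = rep(0, fan_out))
  }
  structure(list(layers = layers, sizes = sizes), class = "mlp")
}

# forward pass on an n x in matrix; returns output and per-layer caches
mlp_forward <- function(net, X, cache = FALSE) {
  nl <- length(net$layers)
  acts <- if (cache) vector("list", nl) else NULL
  A <- X
  for (k in seq_len(nl)) {
    ly <- net$layers[[k]]
    Z <- sweep(A %*% ly$W, 2, ly$b, `+`)
    out <- if (k < nl) tanh(Z) else Z
    if (cache) acts[[k]] <- list(inp = A, out = out)
    A <- out
  }
  if (cache) list(out = A, acts = acts) else A
}

# backward pass: dOut is n x out adjoint; returns input adjoint and
# parameter gradients (same shape as net$layers)
mlp_backward <- function(net, fw, dOut) {
  nl <- length(net$layers)
  grads <- vector("list", nl)
  dA <- dOut
  for (k in rev(seq_len(nl))) {
    cache <- fw$acts[[k]]
    A_in <- cache$inp
    dZ <- if (k < nl) dA * (1 - cache$out^2) else dA
    grads[[k]] <- list(W = crossprod(A_in, dZ), b = colSums(dZ))
    dA <- tcrossprod(dZ, net$layers[[k]]$W)
  }
  list(dX = dA, grads = grads)
}

mlp_n_params <- function(net) {
  sum(vapply(net$layers, function(l) length(l$W) + length(l$b), 0))
}

# flatten / unflatten parameter lists (list of mlp-like layer lists)
.flatten_params <- function(nets) {
  unlist(lapply(nets, function(net)
    lapply(net$layers, function(l) c(l$W, l$b))), use.names = FALSE)
}

.unflatten_params <- function(nets, theta) {
  pos <- 1
  for (a in seq_along(nets)) {
    for (k in seq_along(nets[[a]]$layers)) {
      l <- nets[[a]]$layers[[k]]
      nw <- length(l$W)
      nets[[a]]$layers[[k]]$W[] <- theta[pos:(pos + nw - 1)]
      pos <- pos + nw
      nb <- length(l$b)
      nets[[a]]$layers[[k]]$b[] <- theta[pos:(pos + nb - 1)]
      pos <- pos + nb
    }
  }
  nets
}

# Adam optimizer state-update on a flat parameter vector
adam_init <- function(n, lr = 1e-3, beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  list(m = rep(0, n), v = rep(0, n), t = 0,
       lr = lr, beta1 = beta1, beta2 = beta2, eps = eps)
}

adam_step <- function(state, theta, grad) {
  state$t <- state$t + 1
  state$m <- state$beta1 * state$m + (1 - state$beta1) * grad
  state$v <- state$beta2 * state$v + (1 - state$beta2) * grad^2
  mh <- state$m / (1 - state$beta1^state$t)
  vh <- state$v / (1 - state$beta2^state$t)
  list(theta = theta - state$lr * mh / (sqrt(vh) + state$eps), state = state)
}
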