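test_that("initialization is deterministic and counts parameters in closed form", {
  cfg <- gnn_config(latent_dim = 8, n_layers = 2, cutoff = 1.5, seed = 3)
  m1 <- init_model(cfg)
  m2 <- init_model(cfg)
  expect_identical(get_parameters(m1), get_parameters(m2))
  # closed-form count for two-layer maps with hidden width h = 2m:
  # embed 3->h->m, per layer psiE 3->h->m and psiN 2m->h->m, decoder m->h->1
  m <- 8; h <- 16
  embed <- (3 * h + h) + (h * m + m)
  psiE <- embed
  psiN <- (2 * m * h + h) + (h * m + m)
  dec <- (m * h + h) + (h + 1)
  expect_equal(count_parameters(m1), embed + 2 * (psiE + psiN) + dec)
  # monotone in latent_dim; the default lands at the expected scale
  c2 <- count_parameters(init_model(gnn_config(16, 2, 1.5)))
  expect_gt(c2, count_parameters(m1))
  expect_gt(count_parameters(m1), 300)
  expect_lt(count_parameters(m1), 2000)
  expect_error(gnn_config(latent_dim = 0), "invalid")
})

test_that("a zero-layer model reduces to embed + decoder over pooled embeddings", {
  cfg <- gnn_config(latent_dim = 4, n_layers = 0, cutoff = 1.5, seed = 5)
  mod <- init_model(cfg)
  cf <- configuration(matrix(runif(12, 1, 9), 4, 3), box(10))
  v <- gnn_forward(mod, cf)
  # manual recomputation through the two MLPs
  H <- mlp_forward(mod$embed, sweep(cf$positions, 2, cf$box$lengths, `/`))
  expect_equal(v, drop(mlp_forward(mod$decoder, matrix(colSums(H), 1))),
               tolerance = 1e-12)
})

test_that("forward is exactly permutation invariant and matches a loop oracle", {
  cfg <- gnn_config(latent_dim = 6, n_layers = 2, cutoff = 2.2, seed = 9)
  mod <- init_model(cfg)
  set.seed(31)
  cf <- gen_margin_cluster(20, 2.2, seed = 31)
  v <- gnn_forward(mod, cf)
  for (i in 1:5) {
    perm <- sample(20)
    vp <- gnn_forward(mod, configuration(cf$positions[perm, ], cf$box))
    expect_lt(abs(v - vp), 1e-10)
  }
  # naive per-node / per-edge reference implementation
  g <- build_graph(cf, 2.2)
  Xs <- sweep(cf$positions, 2, cf$box$lengths, `/`)
  H <- t(vapply(seq_len(20), function(i)
    drop(mlp_forward(mod$embed, matrix(Xs[i, ], 1))), numeric(6)))
  for (t in 1:2) {
    Hn <- matrix(0, 20, 6)
    for (i in seq_len(20)) {
      msg <- rep(0, 6)
      for (e in which(g$edges_i == i)) {
        rv <- g$rel_vectors[e, ]
        env <- 0.5 * (cos(pi * sqrt(sum(rv^2)) / 2.2) + 1)
        msg <- msg + env * drop(mlp_forward(mod$psiE[[t]], matrix(rv, 1)))
      }
      Hn[i, ] <- drop(mlp_forward(mod$psiN[[t]], matrix(c(H[i, ], msg), 1)))
    }
    H <- Hn
  }
  ref <- drop(mlp_forward(mod$decoder, matrix(colSums(H), 1)))
  expect_lt(abs(v - ref), 1e-12)
})

test_that("disconnected halves pool additively and distant nodes cannot interact", {
  cfg <- gnn_config(latent_dim = 5, n_layers = 2, cutoff = 1.5, seed = 2)
  mod <- init_model(cfg)
  set.seed(8)
  A <- matrix(runif(18, 1, 4), 6, 3)
  B <- A + 10   # far beyond (k+1) * cutoff, no cross edges
  b <- box(30)
  pooledA <- attr(gnn_forward(mod, configuration(A, b), nodes = TRUE), "pooled")
  pooledB <- attr(gnn_forward(mod, configuration(B, b), nodes = TRUE), "pooled")
  both <- gnn_forward(mod, configuration(rbind(A, B), b), nodes = TRUE)
  expect_equal(attr(both, "pooled"), pooledA + pooledB, tolerance = 1e-11)
  # locality: perturbing a far particle leaves near-node latents unchanged
  nodes1 <- attr(both, "nodes")
  B2 <- B; B2[1, ] <- B2[1, ] + 0.3
  both2 <- gnn_forward(mod, configuration(rbind(A, B2), b), nodes = TRUE)
  expect_equal(attr(both2, "nodes")[1:6, ], nodes1[1:6, ], tolerance = 1e-12)
})

test_that("coordinate gradients match finite differences and are equivariant", {
  cfg <- gnn_config(latent_dim = 6, n_layers = 2, cutoff = 2.4, seed = 13)
  mod <- init_model(cfg)
  cf <- gen_margin_cluster(15, 2.4, seed = 17)
  gp <- gnn_gradient(mod, cf, mask = FALSE)
  fd <- finite_difference_gradient(function(c2) gnn_forward(mod, c2), cf,
                                   h = 1e-6)
  expect_lt(max(abs(gp$gradient - fd)) / max(abs(fd)), 1e-5)
  perm <- sample(15)
  gp2 <- gnn_gradient(mod, configuration(cf$positions[perm, ], cf$box),
                      mask = FALSE)
  expect_lt(max(abs(gp2$gradient - gp$gradient[perm, ])), 1e-10)
})

test_that("isolated particles get exactly zero gradient rows after masking", {
  cfg <- gnn_config(latent_dim = 6, n_layers = 1, cutoff = 1.5, seed = 4)
  mod <- init_model(cfg)
  X <- rbind(matrix(runif(27, 4, 6), 9, 3), c(1, 1, 1))
  cf <- configuration(X, box(20))
  pr <- gnn_gradient(mod, cf)
  expect_identical(pr$gradient[10, ], c(0, 0, 0))
  # unmasked gradient of the same particle is generically nonzero
  pr2 <- gnn_gradient(mod, cf, mask = FALSE)
  expect_gt(max(abs(pr2$gradient[10, ])), 0)
})

test_that("multivariate models widen only the decoder and return per-output gradients", {
  c1 <- gnn_config(6, 1, 1.5, out_dim = 1, seed = 6)
  c2 <- gnn_config(6, 1, 1.5, out_dim = 2, seed = 6)
  m1 <- init_model(c1); m2 <- init_model(c2)
  expect_equal(count_parameters(m2) - count_parameters(m1),
               c2$hidden + 1)   # one extra decoder output row + bias
  cf <- gen_margin_cluster(10, 1.5, seed = 23, sd = 0.8)
  v <- gnn_forward(m2, cf)
  expect_length(v, 2)
  pr <- gnn_gradient(m2, cf, mask = FALSE)
  expect_length(pr$gradients, 2)
  for (q in 1:2) {
    fd <- finite_difference_gradient(function(c2f) gnn_forward(m2, c2f)[q],
                                     cf, h = 1e-6)
    expect_lt(max(abs(pr$gradients[[q]] - fd)) / max(abs(fd)), 1e-5)
  }
})

test_that("serialization round trips bitwise and guards integrity", {
  mod <- init_model(gnn_config(5, 2, 1.8, seed = 42))
  path <- tempfile(fileext = ".json")
  serialize_model(mod, path)
  m2 <- deserialize_model(path)
  expect_identical(get_parameters(m2), get_parameters(mod))
  set.seed(3)
  for (i in 1:5) {
    cf <- configuration(matrix(runif(24, 1, 9), 8, 3), box(10))
    expect_identical(gnn_forward(m2, cf), gnn_forward(mod, cf))
  }
  # version guard
  txt <- jsonlite::read_json(path, simplifyVector = TRUE)
  txt$version <- 2L
  bad <- tempfile(fileext = ".json")
  jsonlite::write_json(txt, bad, auto_unbox = TRUE, digits = I(17))
  expect_error(deserialize_model(bad), "version mismatch")
  # editing the cutoff trips the checksum guard
  txt2 <- jsonlite::read_json(path, simplifyVector = TRUE)
  txt2$config$cutoff <- 2.5
  bad2 <- tempfile(fileext = ".json")
  jsonlite::write_json(txt2, bad2, auto_unbox = TRUE, digits = I(17))
  expect_error(deserialize_model(bad2), "checksum")
  # truncation
  lines <- readLines(path, warn = FALSE)
  writeLines(substr(lines, 1, nchar(lines) %/% 2), bad2)
  expect_error(deserialize_model(bad2))
})

test_that("graph cutoff mismatches are rejected", {
  mod <- init_model(gnn_config(4, 1, 1.5, seed = 1))
  cf <- configuration(matrix(runif(15, 1, 9), 5, 3), box(10))
  g <- build_graph(cf, 2.0)
  expect_error(gnn_forward(mod, gnn_input(cf, graph = g)), "cutoff")
})
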