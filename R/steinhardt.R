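# Sixth-order Steinhardt machinery and the two analytical nucleation CVs
# (coordination count n and crystalline-particle count n(Q6)), with exact
# chain-rule gradients with respect to every Cartesian coordinate.
#
# Internal convention: only m = 0..6 of the l = 6 harmonics are carried
# (columns 1..7); the m < 0 components follow from conjugation symmetry and
# enter all rotationally invariant contractions through the column weights
# w = (1, 2, 2, 2, 2, 2, 2).

.Y6_W <- c(1, 2, 2, 2, 2, 2, 2)

# Precomputed real coefficient matrices mapping monomial columns to the
# harmonics and their polynomial derivatives. Built once from .Y6_TAB:
# degree-6 monomials for P_m, degree-5 monomials for each dP_m/d{x,y,z}.
.y6_cache <- new.env(parent = emptyenv())

.y6_tables <- function() {
  if (!is.null(.y6_cache$tab)) return(.y6_cache$tab)
  mono_key <- function(M) paste(M[, 1], M[, 2], M[, 3])
  deg6 <- as.matrix(expand.grid(a = 0:6, b = 0:6, c = 0:6))
  deg6 <- deg6[rowSums(deg6) == 6, , drop = FALSE]
  deg5 <- as.matrix(expand.grid(a = 0:5, b = 0:5, c = 0:5))
  deg5 <- deg5[rowSums(deg5) == 5, , drop = FALSE]
  k6 <- mono_key(deg6); k5 <- mono_key(deg5)
  CR6 <- matrix(0, nrow(deg6), 7); CI6 <- matrix(0, nrow(deg6), 7)
  CR5 <- lapply(1:3, function(k) matrix(0, nrow(deg5), 7))
  CI5 <- lapply(1:3, function(k) matrix(0, nrow(deg5), 7))
  for (mm in 0:6) {
    tab <- .Y6_TAB[[mm + 1]]
    for (t in seq_len(nrow(tab))) {
      pw <- tab[t, 1:3]
      i6 <- match(paste(pw[1], pw[2], pw[3]), k6)
      CR6[i6, mm + 1] <- CR6[i6, mm + 1] + tab[t, 4]
      CI6[i6, mm + 1] <- CI6[i6, mm + 1] + tab[t, 5]
      for (k in 1:3) {
        if (pw[k] == 0) next
        dp <- pw; dp[k] <- dp[k] - 1
        i5 <- match(paste(dp[1], dp[2], dp[3]), k5)
        CR5[[k]][i5, mm + 1] <- CR5[[k]][i5, mm + 1] + pw[k] * tab[t, 4]
        CI5[[k]][i5, mm + 1] <- CI5[[k]][i5, mm + 1] + pw[k] * tab[t, 5]
      }
    }
  }
  .y6_cache$tab <- list(deg6 = deg6, deg5 = deg5, CR6 = CR6, CI6 = CI6,
                        CR5 = CR5, CI5 = CI5)
  .y6_cache$tab
}

# monomial design matrix for an exponent table, from cumulative powers
.mono_cols <- function(XP, YP, ZP, expo) {
  M <- matrix(0, nrow(XP), nrow(expo))
  for (t in seq_len(nrow(expo)))
    M[, t] <- XP[, expo[t, 1] + 1] * YP[, expo[t, 2] + 1] * ZP[, expo[t, 3] + 1]
  M
}

# Evaluate Y_6m (m = 0..6) and optionally their Cartesian gradients on a
# D x 3 matrix of displacement vectors. Y = P_m(x,y,z) / r^6 with P_m the
# frozen homogeneous polynomial; grad Y = grad P / r^6 - 6 P r_vec / r^8.
.y6_eval <- function(rvec, deriv = FALSE) {
  tb <- .y6_tables()
  D <- nrow(rvec)
  x <- rvec[, 1]; y <- rvec[, 2]; z <- rvec[, 3]
  r2 <- x * x + y * y + z * z
  if (any(r2 == 0)) stop("zero displacement vector in spherical harmonics")
  r6 <- r2^3
  pw <- function(v) {
    P <- matrix(1, D, 7)
    for (k in 2:7) P[, k] <- P[, k - 1] * v
    P
  }
  XP <- pw(x); YP <- pw(y); ZP <- pw(z)
  M6 <- .mono_cols(XP, YP, ZP, tb$deg6)
  PR <- M6 %*% tb$CR6; PI <- M6 %*% tb$CI6
  Y <- (PR + 1i * PI) / r6
  dY <- NULL
  if (deriv) {
    M5 <- .mono_cols(XP, YP, ZP, tb$deg5)
    r8 <- r6 * r2
    dY <- vector("list", 3)
    comp <- list(x, y, z)
    for (k in 1:3) {
      dPR <- M5 %*% tb$CR5[[k]]; dPI <- M5 %*% tb$CI5[[k]]
      dY[[k]] <- (dPR + 1i * dPI) / r6 - Y * (6 * comp[[k]] / r2)
    }
  }
  list(Y = Y, dY = dY)
}

# reference implementation kept for cross-checks in the test suite
.y6_eval_slow <- function(rvec, deriv = FALSE) {
  D <- nrow(rvec)
  x <- rvec[, 1]; y <- rvec[, 2]; z <- rvec[, 3]
  r2 <- x * x + y * y + z * z
  if (any(r2 == 0)) stop("zero displacement vector in spherical harmonics")
  r6 <- r2^3
  Y <- matrix(0 + 0i, D, 7)
  dY <- if (deriv) list(matrix(0 + 0i, D, 7), matrix(0 + 0i, D, 7),
                        matrix(0 + 0i, D, 7)) else NULL
  for (mm in 0:6) {
    tab <- .Y6_TAB[[mm + 1]]
    P <- complex(real = rep(0, D))
    dPx <- dPy <- dPz <- if (deriv) complex(real = rep(0, D)) else NULL
    for (t in seq_len(nrow(tab))) {
      a <- tab[t, 1]; b <- tab[t, 2]; cc <- tab[t, 3]
      cf <- complex(real = tab[t, 4], imaginary = tab[t, 5])
      xa <- if (a > 0) x^a else 1
      yb <- if (b > 0) y^b else 1
      zc <- if (cc > 0) z^cc else 1
      P <- P + cf * xa * yb * zc
      if (deriv) {
        if (a > 0) dPx <- dPx + cf * a * (if (a > 1) x^(a - 1) else 1) * yb * zc
        if (b > 0) dPy <- dPy + cf * b * xa * (if (b > 1) y^(b - 1) else 1) * zc
        if (cc > 0) dPz <- dPz + cf * cc * xa * yb * (if (cc > 1) z^(cc - 1) else 1)
      }
    }
    Y[, mm + 1] <- P / r6
    if (deriv) {
      r8 <- r6 * r2
      dY[[1]][, mm + 1] <- dPx / r6 - 6 * P * x / r8
      dY[[2]][, mm + 1] <- dPy / r6 - 6 * P * y / r8
      dY[[3]][, mm + 1] <- dPz / r6 - 6 * P * z / r8
    }
  }
  list(Y = Y, dY = dY)
}

#' Sixth-order spherical harmonics of a direction
#'
#' Standard orthonormal complex spherical harmonics at l = 6 evaluated at
#' the direction of `r_vec`, for m = -6..6 (Condon-Shortley phase).
#'
#' @param r_vec numeric 3-vector with positive norm.
#' @return complex vector of length 13, ordered m = -6, ..., 6.
#' @export
spherical_harmonics_l6 <- function(r_vec) {
  if (sum(r_vec^2) == 0) stop("zero vector has no direction")
  Y <- .y6_eval(matrix(r_vec, 1, 3))$Y[1, ]
  neg <- rev((-1)^(1:6) * Conj(Y[2:7]))
  c(neg, Y)
}

# group-sum helper: sums rows of M by index idx into an n-row matrix
.rowsum_full <- function(M, idx, n) {
  if (is.null(dim(M))) M <- matrix(M, ncol = 1)
  out <- matrix(0, n, ncol(M))
  if (nrow(M) > 0) {
    rs <- rowsum(M, idx)
    out[as.integer(rownames(rs)), ] <- rs
  }
  out
}

.check_sizes <- function(config, graph) {
  if (nrow(config$positions) != graph$n_nodes)
    stop("graph and configuration sizes do not match")
}

#' Smooth coordination numbers
#'
#' c_i = sum over graph neighbors j of s(r_ij) with the rational switch s.
#' Isolated particles get c_i = 0.
#'
#' @param config a [configuration()].
#' @param graph a `particle_graph` built from `config` with a cutoff beyond
#'   which s is negligible.
#' @param p a [switch_params()].
#' @return numeric vector of length N.
#' @export
coordination_numbers <- function(config, graph, p) {
  .check_sizes(config, graph)
  r <- sqrt(rowSums(graph$rel_vectors^2))
  s <- rational_switch(r, p)$value
  drop(.rowsum_full(s, graph$edges_i, graph$n_nodes))
}

#' Droplet-size CV: smooth count of highly coordinated particles
#'
#' n = sum_i F(c_i) where F is the smooth more-than counter at threshold
#' `t$sigma` and c_i the smooth coordination number. Counts the particles
#' in the dense (liquid-like) phase; its gradient supplies bias forces.
#'
#' @inheritParams coordination_numbers
#' @param t a [threshold_params()] on the coordination number.
#' @param gradient compute the N x 3 gradient (default TRUE).
#' @return list of class `cv_result` with `value` and `gradient`.
#' @export
cv_n <- function(config, graph, p, t, gradient = TRUE) {
  .check_sizes(config, graph)
  n <- graph$n_nodes
  ei <- graph$edges_i; ej <- graph$edges_j
  rel <- graph$rel_vectors
  r <- sqrt(rowSums(rel^2))
  sw <- rational_switch(r, p)
  ci <- drop(.rowsum_full(sw$value, ei, n))
  F <- more_than(ci, t)
  res <- list(value = sum(F$value), gradient = NULL)
  if (gradient) {
    G <- matrix(0, n, 3)
    if (length(ei) > 0) {
      coef <- F$deriv[ei] * sw$deriv / r     # d value / d s_e * ds/dr / r
      Ge <- rel * coef                       # contribution along +rhat to x_j
      G <- .rowsum_full(Ge, ej, n) - .rowsum_full(Ge, ei, n)
    }
    res$gradient <- G
  }
  class(res) <- "cv_result"
  res
}

# Core of the Q6 pipeline. Returns per-particle quantities and, on request,
# the exact gradient of n(Q6) = sum_i F(Q6_i).
.q6_core <- function(config, graph, p, t = NULL, gradient = FALSE) {
  .check_sizes(config, graph)
  n <- graph$n_nodes
  ei <- graph$edges_i; ej <- graph$edges_j
  rel <- graph$rel_vectors
  D <- length(ei)
  w <- .Y6_W
  if (D == 0) {
    out <- list(c = rep(0, n), Q6 = rep(0, n), u = matrix(0 + 0i, n, 7),
                value = 0, gradient = if (gradient) matrix(0, n, 3) else NULL)
    return(out)
  }
  r <- sqrt(rowSums(rel^2))
  sw <- rational_switch(r, p)
  s <- sw$value; sp <- sw$deriv
  ye <- .y6_eval(rel, deriv = gradient)
  Y <- ye$Y
  BR <- .rowsum_full(Re(Y) * s, ei, n)
  BI <- .rowsum_full(Im(Y) * s, ei, n)
  B <- BR + 1i * BI
  nrm <- sqrt(drop((Re(B)^2 + Im(B)^2) %*% w))
  ok <- nrm > 1e-300
  U <- B
  U[ok, ] <- B[ok, , drop = FALSE] / nrm[ok]
  U[!ok, ] <- 0 + 0i
  wden <- drop(.rowsum_full(s, ei, n))            # sum_j s_ij per particle
  deg <- tabulate(ei, nbins = n)
  # normalized-shell match per directed edge: d_e = <u_i, u_j>_w (real)
  Ui <- U[ei, , drop = FALSE]; Uj <- U[ej, , drop = FALSE]
  de <- drop((Re(Ui) * Re(Uj) + Im(Ui) * Im(Uj)) %*% w)
  A <- drop(.rowsum_full(s * de, ei, n))
  Q6 <- ifelse(deg > 0, A / wden, 0)
  out <- list(c = wden, Q6 = Q6, u = U)
  if (is.null(t)) return(out)
  F <- more_than(Q6, t)
  out$value <- sum(F$value)
  if (!gradient) return(out)

  g <- ifelse(deg > 0, F$deriv, 0)
  # adjoint of u_i: z_i = sum_j beta_e u_j, beta_e = g_i s/w_i + g_j s/w_j
  safe_w <- ifelse(deg > 0, wden, 1)
  beta <- g[ei] * s / safe_w[ei] + g[ej] * s / safe_w[ej]
  ZR <- .rowsum_full(Re(Uj) * beta, ei, n)
  ZI <- .rowsum_full(Im(Uj) * beta, ei, n)
  Z <- ZR + 1i * ZI
  h <- drop((Re(U) * Re(Z) + Im(U) * Im(Z)) %*% w)   # <u_i, z_i>_w
  Vbar <- sweep(Z - U * h, 2, w, `*`)
  Vbar[ok, ] <- Vbar[ok, , drop = FALSE] / nrm[ok]
  Vbar[!ok, ] <- 0 + 0i
  # adjoint of s_e (Q6_i share for the directed edge + through v_i)
  Vbi <- Vbar[ei, , drop = FALSE]
  sbar <- g[ei] * (de - Q6[ei]) / safe_w[ei] +
    drop((Re(Vbi) * Re(Y) + Im(Vbi) * Im(Y)) %*% rep(1, 7))
  # adjoint of the harmonic values: ybar_e = s_e vbar_i
  Ge <- rel * (sbar * sp / r)
  for (k in 1:3) {
    dYk <- ye$dY[[k]]
    Ge[, k] <- Ge[, k] +
      s * drop((Re(Vbi) * Re(dYk) + Im(Vbi) * Im(dYk)) %*% rep(1, 7))
  }
  G <- .rowsum_full(Ge, ej, n) - .rowsum_full(Ge, ei, n)
  out$gradient <- G
  out
}

#' Per-particle sixth-order Steinhardt vectors
#'
#' q_6m(i) = sum_j s(r_ij) Y_6m(r_ij) / sum_j s(r_ij); the zero vector for
#' isolated particles.
#'
#' @inheritParams coordination_numbers
#' @return N x 13 complex matrix, columns ordered m = -6..6.
#' @export
steinhardt_q6m <- function(config, graph, p) {
  .check_sizes(config, graph)
  n <- graph$n_nodes
  ei <- graph$edges_i
  rel <- graph$rel_vectors
  out <- matrix(0 + 0i, n, 13)
  if (length(ei) == 0) return(out)
  r <- sqrt(rowSums(rel^2))
  s <- rational_switch(r, p)$value
  Y <- .y6_eval(rel)$Y
  BR <- .rowsum_full(Re(Y) * s, ei, n)
  BI <- .rowsum_full(Im(Y) * s, ei, n)
  wden <- drop(.rowsum_full(s, ei, n))
  deg <- tabulate(ei, nbins = n)
  B <- BR + 1i * BI
  B[deg > 0, ] <- B[deg > 0, , drop = FALSE] / wden[deg > 0]
  B[deg == 0, ] <- 0 + 0i
  sgn <- (-1)^(1:6)
  cbind(Conj(B[, 7:2, drop = FALSE]) %*% diag(rev(sgn)), B)
}

#' Local Q6 crystalline-order parameter
#'
#' Q6_i is the switch-weighted average over neighbors of the normalized
#' complex dot product between the unit Steinhardt 13-vectors of particle i
#' and its neighbor j (real part), measuring how much the orientation of
#' the two coordination shells matches. Isolated particles get 0.
#'
#' @inheritParams coordination_numbers
#' @return numeric vector of length N, each in [-1, 1].
#' @export
local_Q6 <- function(config, graph, p) {
  .q6_core(config, graph, p)$Q6
}

#' Crystalline-domain-size CV: smooth count of particles with high local Q6
#'
#' n(Q6) = sum_i F(Q6_i) with F the smooth more-than counter at threshold
#' `t$sigma`. The returned object also carries `cube_root`, the learning
#' target used when training graph models (interpretable as the radius of
#' the crystalline domain), and the exact N x 3 gradient.
#'
#' @inheritParams coordination_numbers
#' @param t a [threshold_params()] on local Q6 (typically sigma ~ 0.5).
#' @param gradient compute the gradient (default TRUE).
#' @return list of class `cv_result` with `value`, `cube_root`, `gradient`.
#' @export
cv_nQ6 <- function(config, graph, p, t, gradient = TRUE) {
  core <- .q6_core(config, graph, p, t, gradient = gradient)
  res <- list(value = core$value, cube_root = core$value^(1 / 3),
              gradient = core$gradient)
  class(res) <- "cv_result"
  res
}

#' Pooled-local reference evaluation of n(Q6)
#'
#' A deliberately independent second code path for the same order
#' parameter, written as an explicit per-node pooling of neighbor-level
#' contributions (node loop over a locally evaluated shell match), used to
#' cross-check the vectorised [cv_nQ6()] implementation. Value only.
#'
#' @inheritParams cv_nQ6
#' @return scalar n(Q6) value.
#' @export
cv_nQ6_pooled <- function(config, graph, p, t) {
  .check_sizes(config, graph)
  n <- graph$n_nodes
  nbrs <- split(seq_along(graph$edges_i), graph$edges_i)
  # per-node unit Steinhardt vectors via an explicit loop
  uhat <- vector("list", n)
  for (i in seq_len(n)) {
    ix <- nbrs[[as.character(i)]]
    if (is.null(ix)) { uhat[[i]] <- NULL; next }
    b <- rep(0 + 0i, 13)
    for (e in ix) {
      rv <- graph$rel_vectors[e, ]
      s <- rational_switch(sqrt(sum(rv^2)), p)$value
      b <- b + s * spherical_harmonics_l6(rv)
    }
    nb <- sqrt(sum(Mod(b)^2))
    uhat[[i]] <- if (nb > 0) b / nb else rep(0 + 0i, 13)
  }
  total <- 0
  for (i in seq_len(n)) {
    ix <- nbrs[[as.character(i)]]
    if (is.null(ix)) { total <- total + more_than(0, t)$value; next }
    num <- 0; den <- 0
    for (e in ix) {
      j <- graph$edges_j[e]
      rv <- graph$rel_vectors[e, ]
      s <- rational_switch(sqrt(sum(rv^2)), p)$value
      num <- num + s * Re(sum(Conj(uhat[[i]]) * uhat[[j]]))
      den <- den + s
    }
    total <- total + more_than(num / den, t)$value
  }
  total
}

#' Central finite-difference gradient oracle
#'
#' Test-only reference: central differences of a scalar CV evaluator with
#' respect to every coordinate.
#'
#' @param cv function(configuration) -> scalar (or list with `$value`).
#' @param config a [configuration()].
#' @param h step size (small relative to interparticle spacing).
#' @return N x 3 matrix of derivatives.
#' @export
finite_difference_gradient <- function(cv, config, h = 1e-5) {
  val <- function(cf) {
    v <- cv(cf)
    if (is.list(v)) v$value else v
  }
  X <- config$positions
  G <- matrix(0, nrow(X), 3)
  for (i in seq_len(nrow(X))) for (k in 1:3) {
    Xp <- X; Xp[i, k] <- Xp[i, k] + h
    Xm <- X; Xm[i, k] <- Xm[i, k] - h
    cp <- configuration(Xp, config$box, config$id)
    cm <- configuration(Xm, config$box, config$id)
    G[i, k] <- (val(cp) - val(cm)) / (2 * h)
  }
  G
}
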