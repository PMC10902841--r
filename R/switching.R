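#' Rational switching function parameters
#'
#' The smooth, monotone switch s(r) = [1 - u^l] / [1 - u^m] with
#' u = (r - d0) / r0 that makes coordination counts and thresholded
#' order-parameter counts differentiable. `l` and `m` are even positive
#' integers with m > l; at u = 1 the removable singularity is filled with
#' the limit l/m.
#'
#' @param d0 offset (reduced length units).
#' @param r0 scale (> 0, reduced length units).
#' @param l,m even positive integer exponents, m > l.
#' @return object of class `switch_params`.
#' @export
switch_params <- function(d0 = 0, r0 = 1, l = 6L, m = 12L) {
  if (r0 <= 0) stop("r0 must be positive")
  l <- as.integer(l); m <- as.integer(m)
  if (l <= 0 || m <= l) stop("need positive exponents with m > l")
  if (l %% 2L != 0L || m %% 2L != 0L) stop("exponents must be even")
  structure(list(d0 = d0, r0 = r0, l = l, m = m), class = "switch_params")
}

#' Rational switching function and derivative
#'
#' Vectorised evaluation of s(r) and ds/dr. s(d0) = 1, s is monotonically
#' decreasing for r > d0 and tends to 0 as r grows (m > l). Continuous at
#' u = 1 through the limit l/m.
#'
#' @param r numeric vector of distances (>= 0).
#' @param p a [switch_params()].
#' @return list with `value` and `deriv`, each the length of `r`.
#' @export
rational_switch <- function(r, p) {
  u <- (r - p$d0) / p$r0
  l <- p$l; m <- p$m
  ul <- u^l; um <- u^m
  den <- 1 - um
  val <- ifelse(abs(den) > 1e-9, (1 - ul) / den, l / m)
  # s'(u) = [-l u^(l-1) (1-u^m) + m u^(m-1) (1-u^l)] / (1-u^m)^2
  der <- ifelse(abs(den) > 1e-9,
                (-l * u^(l - 1) * den + m * u^(m - 1) * (1 - ul)) / den^2,
                -l * (m - l) / (2 * m)) # limit of s'(u) at u -> 1
  list(value = val, deriv = der / p$r0)
}

#' Smooth threshold ("more than") parameters
#'
#' Parameters of the smooth counter of values exceeding a threshold
#' `sigma`: F(x) = 1 - s(x) with the rational switch s scaled so that
#' F(sigma) = 1/2. Used to turn per-particle order values (coordination
#' numbers, local Q6) into differentiable global counts.
#'
#' @param sigma threshold on the per-particle order value.
#' @param sharpness a [switch_params()] giving the switch shape; its `r0`
#'   is interpreted relative to `sigma` (the effective scale is
#'   `sigma * sharpness$r0`). Default: l = 6, m = 12, r0 = 1.
#' @return object of class `threshold_params`.
#' @export
threshold_params <- function(sigma, sharpness = switch_params()) {
  if (!is.finite(sigma) || sigma <= 0) stop("sigma must be positive")
  structure(list(sigma = sigma, sharpness = sharpness),
            class = "threshold_params")
}

#' Smooth "more than" counter
#'
#' @param x numeric vector of per-particle order values.
#' @param t a [threshold_params()].
#' @return list with `value` (in [0, 1]) and `deriv` per element.
#' @export
more_than <- function(x, t) {
  p <- t$sharpness
  ps <- switch_params(d0 = p$d0, r0 = p$r0 * t$sigma, l = p$l, m = p$m)
  s <- rational_switch(x, ps)
  list(value = 1 - s$value, deriv = -s$deriv)
}
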