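#' Weighted histogram analysis method (1-D)
#'
#' Self-consistent WHAM estimate of the unbiased free-energy profile from
#' overlapping harmonic umbrella windows. Iterates the window free
#' energies f_w until convergence of the standard coupled equations
#'   P(b) ~ H(b) / sum_w N_w exp((f_w - U_w(b)) / T)
#'   f_w  = -T log sum_b P(b) exp(-U_w(b) / T)
#' and returns F(b) = -T log P(b), shifted so its minimum is 0.
#'
#' The degenerate single-window, zero-kappa case reduces to
#' F = -T log(histogram) + const.
#'
#' @param run an `umbrella_run` from [umbrella_scan()].
#' @param n_bins number of histogram bins over the sampled CV range.
#' @param temperature reduced temperature (defaults to the run's).
#' @param tol convergence tolerance on max |delta f_w|.
#' @param max_iter iteration budget; non-convergence (e.g. windows with no
#'   histogram overlap) is an error.
#' @return list with `s` (bin centers), `F` (free energy, min 0), `f_w`
#'   (window free energies), `iterations`.
#' @export
wham_1d <- function(run, n_bins = 60L, temperature = NULL, tol = 1e-8,
                    max_iter = 20000L) {
  if (!inherits(run, "umbrella_run")) stop("run must be an umbrella_run")
  if (any(vapply(run$series, length, 0L) == 0)) stop("empty umbrella window")
  Tr <- if (is.null(temperature)) run$temperature else temperature
  all_s <- unlist(run$series)
  rng <- range(all_s)
  edges <- seq(rng[1] - 1e-9, rng[2] + 1e-9, length.out = n_bins + 1)
  mids <- (edges[-1] + edges[-(n_bins + 1)]) / 2
  W <- length(run$series)
  H <- numeric(n_bins)
  Nw <- vapply(run$series, length, 0L)
  for (w in seq_len(W)) {
    H <- H + tabulate(findInterval(run$series[[w]], edges,
                                   rightmost.closed = TRUE), nbins = n_bins)
  }
  # bias energy of window w at each bin center
  U <- vapply(seq_len(W), function(w)
    0.5 * run$kappa * (mids - run$centers[w])^2, numeric(n_bins))
  fw <- rep(0, W)
  expU <- exp(-U / Tr)                     # n_bins x W
  for (it in seq_len(max_iter)) {
    denom <- drop(expU %*% (Nw * exp(fw / Tr)))
    P <- ifelse(denom > 0, H / denom, 0)
    Z <- drop(crossprod(expU, P))          # per-window partition sums
    if (any(Z <= 0)) stop("WHAM failed: window without histogram overlap")
    fw_new <- -Tr * log(Z)
    fw_new <- fw_new - fw_new[1]
    delta <- max(abs(fw_new - fw))
    fw <- fw_new
    if (delta < tol) {
      P <- P / sum(P)
      Fv <- ifelse(P > 0, -Tr * log(P), NA_real_)
      return(list(s = mids, F = Fv - min(Fv, na.rm = TRUE), f_w = fw,
                  iterations = it))
    }
  }
  stop("WHAM did not converge: insufficient window overlap")
}

#' Barrier height of a 1-D free-energy profile
#'
#' Highest point between the two outermost local minima of the profile,
#' relative to the lower-lying of the two minima flanking it.
#'
#' @param s,F profile as returned by [wham_1d()] or
#'   [metad_free_energy()].
#' @param split optional CV value separating the basins (defaults to the
#'   profile midpoint).
#' @return barrier height (same units as F).
#' @export
profile_barrier <- function(s, F, split = NULL) {
  ok <- is.finite(F)
  s <- s[ok]; F <- F[ok]
  if (is.null(split)) split <- mean(range(s))
  li <- which(s < split); ri <- which(s >= split)
  if (!length(li) || !length(ri)) stop("profile does not span the split")
  lmin <- li[which.min(F[li])]
  rmin <- ri[which.min(F[ri])]
  inner <- seq(min(lmin, rmin), max(lmin, rmin))
  max(F[inner]) - mean(c(F[lmin], F[rmin]))
}
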