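#' Degree distributions
#'
#' A degree distribution is a tibble with integer column `k` (the support)
#' and numeric column `p` (probability weights summing to one), carrying the
#' class `degree_dist`. All mean-field quantities in the package are moments
#' of such a distribution; node counts \eqn{P(k)} are recovered as `N * p`
#' when a finite population is needed.
#'
#' `dist_powerlaw()` builds a truncated power law \eqn{p(k) \propto k^{-r}}
#' on the integer range `kmin..kmax`; `dist_uniform()` puts equal weight on
#' `kmin..kmax`; `dist_regular()` is the degenerate distribution of a
#' k-regular network. Bounds are inclusive.
#'
#' `dist_preset()` returns the three calibrated distributions used throughout
#' the package's examples, all with mean degree (essentially) 100:
#' `"uniform-100"` (uniform on 51..149, mean exactly 100),
#' `"powerlaw-r4"` (exponent 4 on 67..1000) and
#' `"powerlaw-r3"` (exponent 3 on 53..1000).
#'
#' @param r positive power-law exponent (r = 0 gives a uniform distribution).
#' @param kmin,kmax inclusive integer support bounds.
#' @param k degree of the regular network (non-negative integer).
#' @param name preset name.
#' @return a `degree_dist` tibble with columns `k`, `p`.
#' @examples
#' d <- dist_powerlaw(4, 67, 1000)
#' dist_moment(d, 1)   # close to 100
#' @export
dist_powerlaw <- function(r, kmin, kmax) {
  check_bounds(kmin, kmax)
  if (!is.numeric(r) || length(r) != 1L || !is.finite(r) || r < 0) {
    stop("`r` must be a single finite non-negative number", call. = FALSE)
  }
  k <- seq.int(kmin, kmax)
  w <- as.numeric(k)^(-r)
  if (!all(is.finite(w)) || sum(w) <= 0) {
    stop("power-law weights are not finite for r = ", r, call. = FALSE)
  }
  new_degree_dist(k, w / sum(w),
                  label = sprintf("powerlaw r=%g [%d,%d]", r, kmin, kmax))
}

#' @rdname dist_powerlaw
#' @export
dist_uniform <- function(kmin, kmax) {
  check_bounds(kmin, kmax)
  k <- seq.int(kmin, kmax)
  new_degree_dist(k, rep(1 / length(k), length(k)),
                  label = sprintf("uniform [%d,%d]", kmin, kmax))
}

#' @rdname dist_powerlaw
#' @export
dist_regular <- function(k) {
  if (!is.numeric(k) || length(k) != 1L || k < 0 || k != round(k)) {
    stop("`k` must be a single non-negative integer", call. = FALSE)
  }
  new_degree_dist(as.integer(k), 1, label = sprintf("regular k=%d", as.integer(k)))
}

#' @rdname dist_powerlaw
#' @export
dist_preset <- function(name = c("uniform-100", "powerlaw-r4", "powerlaw-r3")) {
  switch(match.arg(name),
    "uniform-100" = dist_uniform(51L, 149L),
    "powerlaw-r4" = dist_powerlaw(4, 67L, 1000L),
    "powerlaw-r3" = dist_powerlaw(3, 53L, 1000L)
  )
}

check_bounds <- function(kmin, kmax) {
  if (length(kmin) != 1L || length(kmax) != 1L ||
      kmin != round(kmin) || kmax != round(kmax)) {
    stop("`kmin` and `kmax` must be single integers", call. = FALSE)
  }
  if (kmin < 0) stop("degrees must be non-negative", call. = FALSE)
  if (kmin > kmax) {
    stop("`kmin` must not exceed `kmax` (got ", kmin, " > ", kmax, ")",
         call. = FALSE)
  }
  invisible(TRUE)
}

new_degree_dist <- function(k, p, label = "") {
  stopifnot(length(k) == length(p))
  if (any(p < 0)) stop("probabilities must be non-negative", call. = FALSE)
  if (abs(sum(p) - 1) > 1e-12) {
    stop("probabilities must sum to 1 (off by ", format(sum(p) - 1), ")",
         call. = FALSE)
  }
  if (is.unsorted(k, strictly = TRUE)) {
    stop("support must be strictly increasing", call. = FALSE)
  }
  out <- tibble::tibble(k = as.integer(k), p = as.numeric(p))
  class(out) <- c("degree_dist", class(out))
  attr(out, "label") <- label
  out
}

#' @export
print.degree_dist <- function(x, ...) {
  cat(sprintf("<degree_dist> %s: %d support points, <k> = %.4g\n",
              attr(x, "label"), nrow(x), dist_moment(x, 1)))
  NextMethod()
}

#' Moments of a degree distribution
#'
#' Computes \eqn{\langle k^n \rangle = \sum_k p_k k^n} by direct summation.
#' Thresholds and bistability onsets are ratios of these moments: the
#' pairwise epidemic threshold is \eqn{\gamma\langle k\rangle/\langle
#' k^2\rangle} and the closed-form onset expressions use moments up to
#' \eqn{\langle k^5 \rangle}.
#'
#' @param dist a `degree_dist`.
#' @param n non-negative integer moment order (vectorised).
#' @return numeric vector of moments, one per entry of `n`.
#' @export
dist_moment <- function(dist, n) {
  stopifnot(inherits(dist, "degree_dist"), all(n >= 0), all(n == round(n)))
  vapply(n, function(nn) sum(dist$p * as.numeric(dist$k)^nn), numeric(1))
}

#' Sample a degree sequence
#'
#' Draws `n` i.i.d. degrees from the distribution. A fixed `seed` makes the
#' draw reproducible without disturbing the caller's RNG stream.
#'
#' @param dist a `degree_dist`.
#' @param n number of nodes.
#' @param seed optional integer seed.
#' @return integer vector of length `n`.
#' @export
sample_degrees <- function(dist, n, seed = NULL) {
  stopifnot(inherits(dist, "degree_dist"))
  if (length(n) != 1L || n < 1 || n != round(n)) {
    stop("`n` must be a positive integer", call. = FALSE)
  }
  with_seed(seed, {
    if (nrow(dist) == 1L) rep(dist$k, n)
    else dist$k[sample_weighted(nrow(dist), n, dist$p)]
  })
}
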