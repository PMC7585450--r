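# beta2 grid used to detect solution multiplicity: the extra solutions are
# born for beta2 just below beta2c, so the grid clusters geometrically toward
# beta2c from below (relative distance down to 1e-9; the onset detection bias
# scales like the square root of that distance) plus a few points above
multiplicity_beta2_grid <- function(beta2c, n = 26) {
  n_lo <- max(2L, n %/% 3L)
  lo <- seq(0.5 * beta2c, 0.9 * beta2c, length.out = n_lo + 1)[-(n_lo + 1)]
  gap <- exp(seq(log(1e-9), log(0.1), length.out = n - n_lo - 2L))
  hi <- beta2c * (1 - rev(gap))
  sort(c(lo, hi, beta2c * c(1.01, 1.02)))
}

#' Count steady-state solutions
#'
#' Number of equilibria of the reduced self-consistency system at the given
#' rates (the disease-free state always counts). Shares its scan grid with
#' [find_fixed_points()] but skips root polishing; `beta2` and `beta3` may be
#' equal-length vectors for batch evaluation.
#'
#' @param dist a `degree_dist`.
#' @param gamma healing rate.
#' @param beta2,beta3 rate vectors (recycled to a common length).
#' @param rule,wiring,triangle_sign model choices as in [epidemic_params()].
#' @param n_grid uniform scan points on \[0,1\].
#' @return integer vector of solution counts.
#' @export
count_fixed_points <- function(dist, gamma, beta2, beta3,
                               rule = c("collective", "individual"),
                               wiring = c("correlated", "uncorrelated"),
                               triangle_sign = c("contagion", "healing"),
                               n_grid = 2001) {
  rule <- match.arg(rule); wiring <- match.arg(wiring)
  triangle_sign <- match.arg(triangle_sign)
  nn <- max(length(beta2), length(beta3))
  beta2 <- rep_len(beta2, nn); beta3 <- rep_len(beta3, nn)
  cpp_count_roots_grid(beta2, beta3, v_scan_grid(n_grid),
                       as.numeric(dist$k), dist$p, gamma,
                       if (rule == "collective") 0L else 1L,
                       if (wiring == "correlated") 0L else 1L,
                       if (triangle_sign == "contagion") 1L else -1L)
}

#' Critical triangle infectivity for bistability
#'
#' `beta3c_numeric()` locates the onset of bistability by bisection on
#' `beta3` of the predicate "some pairwise rate in the multiplicity grid
#' yields three steady-state solutions", refined to relative width `tol_rel`.
#' The pairwise-rate grid concentrates points just below the epidemic
#' threshold, where the extra solution pair is born.
#'
#' `beta3c_correlated()` is the closed-form onset for the degree-correlated
#' collective model, \eqn{\beta_{3c} = \gamma \langle k^3\rangle \langle
#' k\rangle^2 / \langle k^2\rangle^3}, obtained from the slope of the
#' self-consistency residual at the origin at the epidemic threshold. For a
#' k-regular network it equals the pairwise threshold, i.e.
#' \eqn{\beta_{3c}/\beta_{2c} = 1}.
#'
#' `beta3c_uncorrelated()` is the piecewise closed form for the uncorrelated
#' collective model built from the quartic expansion of the residual at the
#' threshold (see [expansion_coefficients()]): the smallest admissible root
#' of the saddle-node condition \eqn{a_1^2 - 4a_0a_2 = 0} (admissible when
#' \eqn{a_2 < 0} and the quadratic's vertex \eqn{-a_1/(2a_2)} lies in
#' \[0,1\]), else the transcritical value \eqn{\gamma\langle
#' k^3\rangle/\langle k\rangle^4}.
#'
#' @param dist a `degree_dist`.
#' @param gamma healing rate (> 0).
#' @param wiring triangle wiring for the numeric search.
#' @param rule contagion rule (the bistability searches address the
#'   collective rule).
#' @param tol_rel relative bisection tolerance on `beta3`.
#' @param beta2_grid optional explicit pairwise-rate grid for the
#'   multiplicity predicate.
#' @param n_grid V-scan resolution.
#' @return a rate (1/time).
#' @export
beta3c_numeric <- function(dist, gamma,
                           wiring = c("correlated", "uncorrelated"),
                           rule = "collective", tol_rel = 1e-4,
                           beta2_grid = NULL, n_grid = 2001) {
  wiring <- match.arg(wiring)
  stopifnot(identical(rule, "collective"))
  b2c <- beta2_critical(dist, gamma)
  b2_grid <- beta2_grid %||% multiplicity_beta2_grid(b2c)
  bistable <- function(b3) {
    any(count_fixed_points(dist, gamma, b2_grid, b3, rule = rule,
                           wiring = wiring, n_grid = n_grid) == 3L)
  }
  lo <- 0
  hi <- 3 * beta3c_correlated(dist, gamma)
  for (i in 1:8) {
    if (bistable(hi)) break
    lo <- hi; hi <- 2 * hi
    if (i == 8) stop("no bistability found up to beta3 = ", format(hi),
                     call. = FALSE)
  }
  while ((hi - lo) > tol_rel * hi) {
    mid <- (lo + hi) / 2
    if (bistable(mid)) hi <- mid else lo <- mid
  }
  (lo + hi) / 2
}

#' @rdname beta3c_numeric
#' @export
beta3c_correlated <- function(dist, gamma) {
  m <- dist_moment(dist, 1:3)
  gamma * m[3] * m[1]^2 / m[2]^3
}

#' Quartic expansion coefficients at the epidemic threshold
#'
#' At \eqn{\beta_2 = \beta_{2c}}, after eliminating U to second order in V,
#' the uncorrelated collective self-consistency residual expands as
#' \eqn{h(V) = (a_0 + a_1 V + a_2 V^2)V^2}. The coefficients, in moments
#' \eqn{\langle k\rangle \ldots \langle k^5\rangle} and \eqn{b =
#' \beta_3/\gamma}:
#' \deqn{a_0 = \langle k\rangle(\langle k\rangle^4 b - \langle k^3\rangle) /
#'       \langle k^2\rangle^2}
#' \deqn{a_1 = \langle k\rangle^2(2\langle k\rangle^6 b^2 -
#'       4\langle k\rangle^3\langle k^2\rangle b + \langle k^4\rangle) /
#'       \langle k^2\rangle^3}
#' \deqn{a_2 = \langle k\rangle^3(\langle k\rangle^8 b^3 -
#'       \langle k\rangle^7 b^2 - 6\langle k\rangle^5\langle k^2\rangle b^2 +
#'       3\langle k\rangle^3\langle k^3\rangle b +
#'       5\langle k\rangle^2\langle k^2\rangle^2 b -
#'       \langle k^5\rangle) / \langle k^2\rangle^4}
#' The expressions were re-derived symbolically from the coupled U,V
#' equations (see the methods vignette); they satisfy the two anchor
#' identities: \eqn{a_0 = 0} exactly at \eqn{\beta_3 = \gamma\langle
#' k^3\rangle/\langle k\rangle^4}, and at \eqn{\beta_3 = 0},
#' \eqn{a_0 = -\langle k\rangle\langle k^3\rangle/\langle k^2\rangle^2 < 0}
#' (no bistability without triangles).
#'
#' @param dist a `degree_dist`.
#' @param gamma healing rate (> 0).
#' @param beta3 triangle rate (vectorised).
#' @return a tibble with columns `beta3`, `a0`, `a1`, `a2`.
#' @export
expansion_coefficients <- function(dist, gamma, beta3) {
  m <- dist_moment(dist, 1:5)
  M1 <- m[1]; M2 <- m[2]; M3 <- m[3]; M4 <- m[4]; M5 <- m[5]
  b <- beta3 / gamma
  tibble::tibble(
    beta3 = beta3,
    a0 = M1 * (M1^4 * b - M3) / M2^2,
    a1 = M1^2 * (2 * M1^6 * b^2 - 4 * M1^3 * M2 * b + M4) / M2^3,
    a2 = M1^3 * (M1^8 * b^3 - M1^7 * b^2 - 6 * M1^5 * M2 * b^2 +
                   3 * M1^3 * M3 * b + 5 * M1^2 * M2^2 * b - M5) / M2^4
  )
}

#' @rdname beta3c_numeric
#' @export
beta3c_uncorrelated <- function(dist, gamma) {
  m <- dist_moment(dist, 1:3)
  transcritical <- gamma * m[3] / m[1]^4
  disc <- function(b3) {
    cf <- expansion_coefficients(dist, gamma, b3)
    cf$a1^2 - 4 * cf$a0 * cf$a2
  }
  upper <- max(transcritical, 10 * beta3c_correlated(dist, gamma))
  grid <- seq(1e-8, upper, length.out = 4001)
  d <- disc(grid)
  admissible <- numeric(0)
  for (i in seq_len(length(grid) - 1)) {
    if (!is.finite(d[i]) || !is.finite(d[i + 1])) next
    if (sign(d[i]) * sign(d[i + 1]) < 0) {
      root <- stats::uniroot(disc, c(grid[i], grid[i + 1]), tol = 1e-12)$root
      cf <- expansion_coefficients(dist, gamma, root)
      vertex <- -cf$a1 / (2 * cf$a2)
      if (cf$a2 < 0 && vertex >= 0 && vertex <= 1) {
        admissible <- c(admissible, root)
      }
    }
  }
  if (length(admissible)) min(admissible) else transcritical
}

#' Bistability index
#'
#' The bistability index B(beta3) is the maximum separation, over pairwise
#' rates beta2, between the largest and smallest *stable* equilibrium values
#' of the infected-node fraction U (the stable disease-free state counts,
#' with U = 0). B is zero below the bistability onset and grows with the
#' triangle rate past it.
#'
#' @param dist a `degree_dist`.
#' @param gamma healing rate.
#' @param beta3 triangle rate (vectorised; one B per value).
#' @param wiring,rule model choices.
#' @param beta2_grid pairwise-rate grid to maximise over; default 201 points
#'   spanning 0.5 to 1.5 times the epidemic threshold.
#' @param n_grid V-scan resolution.
#' @return a `bistability_curve` tibble with columns `beta3`, `B`.
#' @export
bistability_index <- function(dist, gamma, beta3,
                              wiring = c("correlated", "uncorrelated"),
                              rule = c("collective", "individual"),
                              beta2_grid = NULL, n_grid = 2001) {
  wiring <- match.arg(wiring); rule <- match.arg(rule)
  b2c <- beta2_critical(dist, gamma)
  b2_grid <- beta2_grid %||% seq(0.5 * b2c, 1.5 * b2c, length.out = 201)
  B <- vapply(beta3, function(b3) {
    gaps <- vapply(b2_grid, function(b2) {
      fp <- find_fixed_points(
        dist, epidemic_params(gamma, beta2 = b2, beta3 = b3, rule = rule,
                              wiring = wiring), n_grid = n_grid)
      su <- fp$U[fp$stability == "stable"]
      if (length(su) < 2) 0 else max(su) - min(su)
    }, numeric(1))
    max(gaps)
  }, numeric(1))
  out <- tibble::tibble(beta3 = beta3, B = B)
  class(out) <- c("bistability_curve", class(out))
  attr(out, "source") <- "meanfield"
  out
}

#' Phase diagram by solution counting
#'
#' Counts steady-state solutions over a (beta2, beta3) grid. The collective
#' contagion models show three regimes: one solution (no infection), two
#' (unstable disease-free plus a stable endemic state) and three (bistable),
#' the last confined to triangle rates above the onset. Individual contagion
#' with triangle contagion shows only the one- and two-solution regimes;
#' collective contagion with higher-order healing never reaches three
#' solutions at non-negative rates, while individual contagion with healing
#' exhibits a narrow three-solution band.
#'
#' @param dist a `degree_dist`.
#' @param gamma healing rate.
#' @param beta2_grid,beta3_grid rate grids (101 points each by default).
#'   The defaults span 0 to 2*beta2c and 0 to 3*beta3c, which covers the
#'   three regimes of the contagion models; for individual contagion with
#'   higher-order healing the unstable region is shifted to pairwise rates
#'   near beta2c + 2*beta3, so the defaults widen to 0..10*beta2c and
#'   0..5*beta2c to reach the narrow bistable band.
#' @param rule,wiring,triangle_sign model choices.
#' @param n_grid V-scan resolution.
#' @return a `phase_diagram` tibble in long format: `beta2`, `beta3`,
#'   `n_solutions`.
#' @export
phase_diagram <- function(dist, gamma, beta2_grid = NULL, beta3_grid = NULL,
                          rule = c("collective", "individual"),
                          wiring = c("correlated", "uncorrelated"),
                          triangle_sign = c("contagion", "healing"),
                          n_grid = 1001) {
  rule <- match.arg(rule); wiring <- match.arg(wiring)
  triangle_sign <- match.arg(triangle_sign)
  b2c <- beta2_critical(dist, gamma)
  healing_band <- triangle_sign == "healing" && rule == "individual"
  beta2_grid <- beta2_grid %||%
    seq(0, if (healing_band) 10 * b2c else 2 * b2c, length.out = 101)
  beta3_grid <- beta3_grid %||% {
    if (healing_band) seq(0, 5 * b2c, length.out = 101)
    else seq(0, 3 * beta3c_correlated(dist, gamma), length.out = 101)
  }
  cells <- tidyr::expand_grid(beta3 = beta3_grid, beta2 = beta2_grid)
  cells$n_solutions <- count_fixed_points(
    dist, gamma, cells$beta2, cells$beta3, rule = rule, wiring = wiring,
    triangle_sign = triangle_sign, n_grid = n_grid)
  out <- cells[, c("beta2", "beta3", "n_solutions")]
  class(out) <- c("phase_diagram", class(out))
  attr(out, "model") <- list(rule = rule, wiring = wiring,
                             triangle_sign = triangle_sign, gamma = gamma)
  out
}

#' Mean-field bifurcation diagram
#'
#' Sweeps the pairwise rate and records every equilibrium with its stability;
#' the standard way to visualise continuous versus explosive transitions.
#'
#' @param dist a `degree_dist`.
#' @param params an `epidemic_params` (its `beta2` is ignored).
#' @param beta2_grid pairwise rates to solve at.
#' @return a tibble with columns `beta2`, `V`, `U`, `stability`.
#' @export
bifurcation_diagram <- function(dist, params, beta2_grid) {
  purrr::map_dfr(beta2_grid, function(b2) {
    p2 <- params; p2$beta2 <- b2
    fp <- find_fixed_points(dist, p2)
    tibble::tibble(beta2 = b2, V = fp$V, U = fp$U, stability = fp$stability)
  })
}
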