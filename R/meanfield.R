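#' Epidemic parameters
#'
#' Bundles the rates and model choices of the hypergraph SIS model: healing
#' rate `gamma`, link infectivity `beta2`, triangle rate `beta3`, the
#' contagion rule (`"collective"`: a hyperedge infects its one susceptible
#' member only when all other members are infected; `"individual"`: a
#' susceptible member is infected as soon as at least one other member is),
#' the wiring of triangles relative to link degrees (`"correlated"` or
#' `"uncorrelated"`), and the triangle action (`"contagion"` or `"healing"`,
#' the latter turning triangles into a higher-order recovery channel).
#' `beta_m` optionally maps hyperedge sizes to rates for the all-sizes model
#' (named numeric vector, names = sizes); `mean_km` gives the matching mean
#' hyperdegrees per size.
#'
#' @param gamma healing rate (>= 0; mean-field threshold formulas need > 0).
#' @param beta2,beta3 link and triangle rates (>= 0).
#' @param rule contagion rule.
#' @param wiring triangle wiring mode.
#' @param triangle_sign triangle action.
#' @param beta_m optional named rate vector for the all-sizes model.
#' @param mean_km optional named mean hyperdegrees, aligned with `beta_m`.
#' @return an `epidemic_params` list.
#' @export
epidemic_params <- function(gamma, beta2 = 0, beta3 = 0,
                            rule = c("collective", "individual"),
                            wiring = c("correlated", "uncorrelated"),
                            triangle_sign = c("contagion", "healing"),
                            beta_m = NULL, mean_km = NULL) {
  rule <- match.arg(rule)
  wiring <- match.arg(wiring)
  triangle_sign <- match.arg(triangle_sign)
  stopifnot(length(gamma) == 1L, gamma >= 0,
            length(beta2) == 1L, beta2 >= 0,
            length(beta3) == 1L, beta3 >= 0)
  if (!is.null(beta_m)) {
    stopifnot(!is.null(names(beta_m)), all(beta_m >= 0),
              !is.null(mean_km), identical(names(beta_m), names(mean_km)))
  }
  structure(list(gamma = gamma, beta2 = beta2, beta3 = beta3, rule = rule,
                 wiring = wiring, triangle_sign = triangle_sign,
                 beta_m = beta_m, mean_km = mean_km),
            class = "epidemic_params")
}

#' @export
print.epidemic_params <- function(x, ...) {
  cat(sprintf(
    "<epidemic_params> gamma=%g beta2=%g beta3=%g [%s, %s, triangle %s]\n",
    x$gamma, x$beta2, x$beta3, x$rule, x$wiring, x$triangle_sign))
  if (!is.null(x$beta_m)) {
    cat("  all-sizes rates beta_m:",
        paste(sprintf("m=%s:%g", names(x$beta_m), x$beta_m), collapse = " "),
        "\n")
  }
  invisible(x)
}

rule_code <- function(p) if (p$rule == "collective") 0L else 1L
wiring_code <- function(p) if (p$wiring == "correlated") 0L else 1L
sign_code <- function(p) if (p$triangle_sign == "contagion") 1L else -1L

# net per-class infection pressure n_k given global order parameters;
# the per-class equilibrium is n/(gamma+n) on the physical branch n > 0
class_pressure <- function(k, V, U, dist, params) {
  s <- sign_code(params)
  M1 <- dist_moment(dist, 1)
  if (!is.null(params$beta_m)) {
    # all-sizes degree-correlated model
    ms <- as.integer(names(params$beta_m))
    g <- if (params$rule == "collective") V^(ms - 1) else 1 - (1 - V)^(ms - 1)
    return(k * sum(params$beta_m * params$mean_km / M1 * g))
  }
  if (params$wiring == "correlated") {
    if (params$rule == "collective") {
      k * (params$beta2 * V + s * params$beta3 * V^2)
    } else {
      k * ((params$beta2 + 2 * s * params$beta3) * V - s * params$beta3 * V^2)
    }
  } else {
    if (params$rule == "collective") {
      params$beta2 * k * V + s * params$beta3 * M1 * U^2
    } else {
      params$beta2 * k * V + s * params$beta3 * M1 * (2 * U - U^2)
    }
  }
}

#' Mean-field right-hand side
#'
#' Time derivative of the per-degree-class infected fractions \eqn{x_k} under
#' the hyperdegree mean-field closure. Covers the links-plus-triangles model
#' in all four rule-by-wiring combinations (with either triangle sign) and,
#' when `params$beta_m` is given, the all-sizes degree-correlated model. For
#' a model with only pairwise edges the collective and individual rules
#' coincide.
#'
#' @param x numeric vector of infected fractions, aligned with `dist$k`.
#' @param dist a `degree_dist`.
#' @param params an `epidemic_params`.
#' @return numeric vector `dx/dt` per degree class.
#' @export
mf_rhs <- function(x, dist, params) {
  stopifnot(length(x) == nrow(dist))
  M1 <- dist_moment(dist, 1)
  U <- sum(dist$p * x)
  V <- sum(dist$p * dist$k * x) / M1
  n <- class_pressure(dist$k, V, U, dist, params)
  -params$gamma * x + (1 - x) * n
}

#' Integrate the mean-field dynamics
#'
#' Solves the per-class ODE system forward in time with `deSolve::ode`
#' (adaptive `lsoda`), reporting the infected-node fraction U and the
#' infected-link fraction V along the trajectory. States are clamped to
#' \[0,1\] against roundoff-level violations only.
#'
#' @param dist a `degree_dist`.
#' @param params an `epidemic_params`.
#' @param x0 initial infected fraction per class; a single number is recycled.
#' @param t_end end time.
#' @param dt output time step.
#' @return a tibble with columns `t`, `U`, `V`; the final class state is in
#'   attribute `"x_final"`.
#' @export
mf_integrate <- function(dist, params, x0 = 0.01, t_end = 50, dt = 0.1) {
  x0 <- rep_len(x0, nrow(dist))
  stopifnot(all(x0 >= 0), all(x0 <= 1))
  deriv <- function(t, x, parms) {
    x <- pmin(pmax(x, 0), 1)
    list(mf_rhs(x, dist, params))
  }
  times <- seq(0, t_end, by = dt)
  sol <- deSolve::ode(y = x0, times = times, func = deriv, parms = NULL)
  if (any(!is.finite(sol))) {
    stop("mean-field integration produced non-finite state", call. = FALSE)
  }
  xs <- pmin(pmax(sol[, -1, drop = FALSE], 0), 1)
  M1 <- dist_moment(dist, 1)
  out <- tibble::tibble(
    t = sol[, 1],
    U = as.numeric(xs %*% dist$p),
    V = as.numeric(xs %*% (dist$p * dist$k)) / M1
  )
  attr(out, "x_final") <- xs[nrow(xs), ]
  out
}

#' Self-consistency residuals
#'
#' `mf_residual_correlated()` evaluates the one-dimensional steady-state
#' residual h(V) of the degree-correlated model: its roots in \[0,1\] are the
#' equilibria, V = 0 always among them. `mf_residual_uncorrelated()`
#' evaluates the residual *pair* of the uncorrelated model at a candidate
#' (U, V). `mf_residual_reduced()` gives the reduced one-dimensional
#' residual used by the root scanner, where for uncorrelated wiring U is
#' eliminated at each V by damped fixed-point iteration of the U equation
#' (warm-started along the V grid).
#'
#' @param V,U candidate order parameters in \[0,1\] (`V` may be a vector).
#' @param dist a `degree_dist`.
#' @param params an `epidemic_params`.
#' @return `mf_residual_correlated()` and `mf_residual_reduced()`: numeric
#'   residual vector (the reduced form also carries the eliminated `U` as an
#'   attribute); `mf_residual_uncorrelated()`: named vector with residuals of
#'   the U and V equations.
#' @export
mf_residual_correlated <- function(V, dist, params) {
  stopifnot(all(V >= 0), all(V <= 1))
  res <- cpp_residual_curve(V, as.numeric(dist$k), dist$p, params$gamma,
                            params$beta2, params$beta3, rule_code(params),
                            0L, sign_code(params))
  res$h
}

#' @rdname mf_residual_correlated
#' @export
mf_residual_uncorrelated <- function(U, V, dist, params) {
  stopifnot(length(U) == 1L, length(V) == 1L)
  n <- class_pressure(dist$k, V, U, dist, params)
  x <- ifelse(n > 0, n / (params$gamma + n), 0)
  c(U = sum(dist$p * x) - U,
    V = sum(dist$p * dist$k * x) / dist_moment(dist, 1) - V)
}

#' @rdname mf_residual_correlated
#' @export
mf_residual_reduced <- function(V, dist, params) {
  res <- cpp_residual_curve(V, as.numeric(dist$k), dist$p, params$gamma,
                            params$beta2, params$beta3, rule_code(params),
                            wiring_code(params), sign_code(params))
  structure(res$h, U = res$U)
}

# scan grid: uniform on (0,1] plus geometric refinement near 0, where roots
# are born at the bistability onset
v_scan_grid <- function(n_grid = 2001, refine = 200) {
  u <- seq(0, 1, length.out = n_grid)[-1]
  lo <- exp(seq(log(1e-7), log(1e-3), length.out = refine))
  sort(unique(c(lo, u)))
}

# linear growth rate of the disease-free state (ODE linearisation)
zero_state_growth <- function(dist, params) {
  M1 <- dist_moment(dist, 1)
  M2 <- dist_moment(dist, 2)
  s <- sign_code(params)
  if (!is.null(params$beta_m)) {
    ms <- as.integer(names(params$beta_m))
    if (params$rule == "collective") {
      b2 <- if (any(ms == 2L)) params$beta_m[["2"]] else 0
      return(b2 * M2 / M1 - params$gamma)
    }
    lhs <- sum((ms - 1) * params$beta_m * params$mean_km / M1)
    return(lhs * M2 / M1 - params$gamma)  # growth of degree-weighted mode
  }
  if (params$rule == "collective") {
    return(params$beta2 * M2 / M1 - params$gamma)
  }
  if (params$wiring == "correlated") {
    return((params$beta2 + 2 * s * params$beta3) * M2 / M1 - params$gamma)
  }
  A <- matrix(c(2 * s * params$beta3 * M1 - params$gamma,
                2 * s * params$beta3 * M1,
                params$beta2 * M1,
                params$beta2 * M2 / M1 - params$gamma), 2, 2)
  max(Re(eigen(A, only.values = TRUE)$values))
}

#' Steady states of the mean-field model
#'
#' Locates all equilibria of the reduced self-consistency system on a dense
#' V grid (sign-change bracketing, bisection polish to 1e-12, merge tolerance
#' 1e-6) and labels their stability: interior roots by the slope of the
#' residual, the disease-free root by the linearisation of the dynamics. The
#' links-plus-triangles models have 1, 2 or 3 equilibria in the regimes of
#' interest: the disease-free state alone; disease-free (unstable) plus an
#' endemic state; or the bistable triple stable-0 / unstable / stable-endemic.
#'
#' @param dist a `degree_dist`.
#' @param params an `epidemic_params`.
#' @param n_grid number of uniform scan points on \[0,1\].
#' @return a `fixed_points` tibble with columns `V`, `U`, `stability`.
#' @examples
#' d <- dist_regular(100)
#' p <- epidemic_params(gamma = 2, beta2 = 0.03)
#' find_fixed_points(d, p)   # V = 0 unstable, V = 1/3 stable
#' @export
find_fixed_points <- function(dist, params, n_grid = 2001) {
  grid <- v_scan_grid(n_grid)
  h <- mf_residual_reduced(grid, dist, params)
  Us <- attr(h, "U")
  roots_v <- numeric(0); roots_u <- numeric(0); slopes <- numeric(0)
  hv <- as.numeric(h)
  ok <- is.finite(hv)
  last_i <- 0L            # last grid point with a nonzero finite residual
  for (i in seq_along(grid)) {
    if (!ok[i]) { last_i <- 0L; next }
    if (hv[i] == 0) {
      # root sitting exactly on a grid point
      slope <- if (i > 1L && i < length(grid) && ok[i - 1] && ok[i + 1]) {
        (hv[i + 1] - hv[i - 1]) / (grid[i + 1] - grid[i - 1])
      } else NA_real_
      roots_v <- c(roots_v, grid[i])
      roots_u <- c(roots_u, Us[i])
      slopes <- c(slopes, slope)
      last_i <- 0L
      next
    }
    if (last_i > 0L && sign(hv[i]) != sign(hv[last_i])) {
      pol <- cpp_polish_root(grid[last_i], grid[i], Us[last_i],
                             as.numeric(dist$k), dist$p, params$gamma,
                             params$beta2, params$beta3, rule_code(params),
                             wiring_code(params), sign_code(params), 1e-12)
      roots_v <- c(roots_v, pol$V)
      roots_u <- c(roots_u, pol$U)
      slopes <- c(slopes, pol$slope)
    }
    last_i <- i
  }
  # merge near-duplicates
  if (length(roots_v) > 1) {
    ord <- order(roots_v)
    roots_v <- roots_v[ord]; roots_u <- roots_u[ord]; slopes <- slopes[ord]
    keep <- c(TRUE, diff(roots_v) > 1e-6)
    roots_v <- roots_v[keep]; roots_u <- roots_u[keep]; slopes <- slopes[keep]
  }
  out <- tibble::tibble(
    V = c(0, roots_v),
    U = c(0, roots_u),
    stability = c(
      if (zero_state_growth(dist, params) > 0) "unstable" else "stable",
      ifelse(slopes < 0, "stable", "unstable")
    )
  )
  class(out) <- c("fixed_points", class(out))
  attr(out, "params") <- params
  attr(out, "dist_label") <- attr(dist, "label")
  out
}

#' Per-class state at an equilibrium
#'
#' Recovers the per-degree-class infected fractions \eqn{x_k} from the order
#' parameters (V, U) of a fixed point, via the per-class equilibrium
#' \eqn{x_k = n_k/(\gamma + n_k)} on the physical branch.
#'
#' @param dist a `degree_dist`.
#' @param params an `epidemic_params`.
#' @param V,U order parameters of the equilibrium.
#' @return numeric vector aligned with `dist$k`.
#' @export
equilibrium_state <- function(dist, params, V, U) {
  n <- class_pressure(dist$k, V, U, dist, params)
  ifelse(n > 0, n / (params$gamma + n), 0)
}

#' Epidemic thresholds
#'
#' `beta2_critical()` is the pairwise epidemic threshold
#' \eqn{\beta_{2c} = \gamma\langle k\rangle/\langle k^2\rangle}, above which
#' the disease-free state is linearly unstable; it is the same for the
#' correlated and uncorrelated collective models, and is unaffected by the
#' triangle rate under collective contagion.
#'
#' `beta2_critical_individual()` is the critical pairwise rate under
#' individual contagion at a given triangle rate: in the correlated case
#' \eqn{\beta_2 = \gamma\langle k\rangle/\langle k^2\rangle - 2\beta_3}
#' (triangles shift the threshold linearly), and in the uncorrelated case the
#' rational expression obtained from the two-variable linearisation, which
#' has a pole at \eqn{\beta_3^* = \gamma\langle k^2\rangle /
#' [2(\langle k^2\rangle - \langle k\rangle^2)\langle k\rangle]} (where the
#' formula's numerator is already negative, so the pole is not physically
#' relevant; the pole location is attached as attribute `"pole"`). With
#' `triangle_sign = "healing"` the sign of `beta3` is flipped. A negative
#' returned value means no non-negative pairwise rate makes the disease-free
#' state unstable at that `beta3`; it is reported as-is.
#'
#' `threshold_multisize()` evaluates the propagation condition of the
#' all-sizes degree-correlated individual-contagion model: contagion
#' propagates when \eqn{\sum_m (m-1)\beta_m \langle k^{(m)}\rangle/\langle
#' k\rangle} exceeds \eqn{\gamma\langle k\rangle/\langle k^2\rangle}.
#'
#' @param dist a `degree_dist`.
#' @param gamma healing rate (> 0).
#' @param beta3 triangle rate.
#' @param wiring `"correlated"` or `"uncorrelated"`.
#' @param triangle_sign `"contagion"` or `"healing"`.
#' @param beta_m named rate vector (names = hyperedge sizes).
#' @param mean_km named mean hyperdegrees, aligned with `beta_m`.
#' @return `beta2_critical*()`: a rate; `threshold_multisize()`: a one-row
#'   tibble with `lhs`, `rhs`, `margin` and logical `propagates`.
#' @export
beta2_critical <- function(dist, gamma) {
  M2 <- dist_moment(dist, 2)
  if (M2 == 0) stop("degenerate distribution: <k^2> = 0", call. = FALSE)
  gamma * dist_moment(dist, 1) / M2
}

#' @rdname beta2_critical
#' @export
beta2_critical_individual <- function(dist, gamma, beta3,
                                      wiring = c("correlated", "uncorrelated"),
                                      triangle_sign = c("contagion", "healing")) {
  wiring <- match.arg(wiring)
  s <- if (match.arg(triangle_sign) == "contagion") 1 else -1
  b3 <- s * beta3
  M1 <- dist_moment(dist, 1); M2 <- dist_moment(dist, 2)
  if (wiring == "correlated") {
    return(gamma * M1 / M2 - 2 * b3)
  }
  den <- M2 * gamma - 2 * (M2 - M1^2) * M1 * b3
  pole <- if (M2 > M1^2) gamma * M2 / (2 * (M2 - M1^2) * M1) else Inf
  if (den == 0) {
    warning("requested beta3 sits at the threshold formula's pole beta3* = ",
            format(pole), "; returning Inf (not physically relevant)")
    return(structure(Inf, pole = pole))
  }
  structure((M1 * gamma^2 - 2 * M1^2 * gamma * b3) / den, pole = pole)
}

#' @rdname beta2_critical
#' @export
threshold_multisize <- function(dist, gamma, beta_m, mean_km) {
  stopifnot(!is.null(names(beta_m)), identical(names(beta_m), names(mean_km)))
  ms <- as.integer(names(beta_m))
  M1 <- dist_moment(dist, 1)
  lhs <- sum((ms - 1) * beta_m * mean_km / M1)
  rhs <- gamma * M1 / dist_moment(dist, 2)
  tibble::tibble(lhs = lhs, rhs = rhs, margin = lhs - rhs,
                 propagates = lhs > rhs)
}
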