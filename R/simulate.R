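params_betas <- function(h, params) {
  sizes <- as.integer(names(h$edges))
  betas <- vapply(sizes, function(m) {
    if (!is.null(params$beta_m) && as.character(m) %in% names(params$beta_m)) {
      params$beta_m[[as.character(m)]]
    } else if (m == 2L) params$beta2
    else if (m == 3L) params$beta3
    else 0
  }, numeric(1))
  betas
}

resolve_x0 <- function(x0, n) {
  is_fraction <- is.numeric(x0) && length(x0) == 1L && x0 >= 0 && x0 <= 1 &&
    (x0 %% 1 != 0 || x0 == 0 || x0 == 1)
  if (is_fraction) {
    n_inf <- round(x0 * n)
    if (n_inf >= n) return(seq_len(n))
    if (n_inf == 0L) return(integer(0))
    return(sort(sample.int(n, n_inf)))
  }
  x0 <- as.integer(x0)
  if (any(x0 < 1) || any(x0 > n)) stop("infected ids out of range", call. = FALSE)
  sort(unique(x0))
}

#' Stochastic SIS simulation on a hypergraph
#'
#' Statistically exact continuous-time simulation of the hypergraph SIS
#' chain: infected nodes heal at rate `gamma`; each size-2 edge with exactly
#' one infected endpoint infects the other at rate `beta2`; each size-m
#' hyperedge acts at rate `beta_m` according to the contagion rule
#' (collective: the single remaining susceptible is infected when all other
#' members are infected; individual: every susceptible member with at least
#' one infected co-member is infected). With `triangle_sign = "healing"` the
#' size-3 action recovers qualifying infected members instead. The
#' disease-free state is absorbing.
#'
#' @param h a `hypergraph`.
#' @param params an `epidemic_params`.
#' @param x0 initial infected fraction in \[0,1) (nodes drawn at random), or
#'   an explicit vector of infected node ids, or 1 for all infected.
#' @param t_end simulation end time (> 0).
#' @param seed optional integer seed.
#' @param record_dt sampling interval of the returned trajectory.
#' @param burnin start of the averaging window for the reported mean
#'   prevalence.
#' @param event_log if TRUE, attach per-event times and infected counts
#'   (attribute `"events"`; intended for small systems).
#' @return a `sis_trajectory` tibble with columns `t`, `U`; attributes
#'   `u_mean` (time-averaged prevalence over `[burnin, t_end]`),
#'   `final_infected`, `n_events`.
#' @export
simulate_sis <- function(h, params, x0 = 0.01, t_end = 10, seed = NULL,
                         record_dt = 0.1, burnin = 0, event_log = FALSE) {
  stopifnot(inherits(h, "hypergraph"), inherits(params, "epidemic_params"))
  if (h$n < 1) stop("empty hypergraph", call. = FALSE)
  if (t_end <= 0) stop("`t_end` must be positive", call. = FALSE)
  with_seed(seed, {
    inf0 <- resolve_x0(x0, h$n)
    res <- cpp_gillespie(h$n, unname(h$edges), params_betas(h, params),
                         params$gamma, rule_code(params),
                         params$triangle_sign == "healing",
                         as.integer(inf0), t_end, record_dt, burnin,
                         event_log)
    out <- tibble::tibble(t = res$t, U = res$U)
    class(out) <- c("sis_trajectory", class(out))
    attr(out, "u_mean") <- res$u_mean
    attr(out, "final_infected") <- res$final_infected
    attr(out, "n_events") <- res$n_events
    if (event_log) {
      attr(out, "events") <- tibble::tibble(t = res$event_t,
                                            n_infected = res$event_i)
    }
    out
  })
}

#' Waiting time to the first event
#'
#' Replicated sampling of the first state change from a fixed initial
#' condition — the exactness probe for the event engine. On a single
#' triangle with two infected members and `gamma = 0`, the collective rule
#' makes the returned times exponential with rate `beta3`.
#'
#' @inheritParams simulate_sis
#' @param infected0 initial infected node ids.
#' @param n_rep number of replicates.
#' @param t_max censoring time returned when no event can occur.
#' @return tibble with columns `t` (waiting time) and `node` (the node whose
#'   state changed; 0 when censored).
#' @export
first_event_times <- function(h, params, infected0, n_rep = 1000,
                              t_max = Inf, seed = NULL) {
  stopifnot(inherits(h, "hypergraph"))
  with_seed(seed, {
    res <- cpp_first_event(h$n, unname(h$edges), params_betas(h, params),
                           params$gamma, rule_code(params),
                           params$triangle_sign == "healing",
                           as.integer(infected0), n_rep, t_max)
    tibble::tibble(t = res$t, node = res$node)
  })
}

#' Hysteresis sweep in the pairwise rate
#'
#' The sweep protocol behind explosive-transition detection: the pairwise
#' rate is stepped slowly up to a maximum and back down, carrying the final
#' microscopic state of each step into the next (adiabatic continuation).
#' Each step discards a transient and reports the time-averaged prevalence.
#' If the chain hits the absorbing disease-free state on the *up* branch it
#' is re-seeded with a small infected set (with a message), since escape from
#' the absorbing state would otherwise be impossible.
#'
#' @param h a `hypergraph`.
#' @param params an `epidemic_params` (its `beta2` is ignored).
#' @param beta2_min,beta2_max ends of the sweep; a common choice is 0.5 and
#'   1.5 times the pairwise epidemic threshold of the degree distribution
#'   the hypergraph was generated from.
#' @param n_steps steps per branch (up and down each get `n_steps`).
#' @param t_transient discarded time at the start of each step.
#' @param t_per_step averaging window per step (after the transient).
#' @param x0 initial infected fraction at the first step, and the re-seeding
#'   fraction after extinction on the up branch.
#' @param seed optional integer seed.
#' @return a `sweep_result` tibble with columns `step`, `direction`
#'   (`"up"`/`"down"`), `beta2`, `U_mean`.
#' @export
hysteresis_sweep <- function(h, params, beta2_min, beta2_max, n_steps = 40,
                             t_transient = 5, t_per_step = 15, x0 = 0.005,
                             seed = NULL) {
  stopifnot(n_steps >= 2, beta2_max >= beta2_min)
  up <- seq(beta2_min, beta2_max, length.out = n_steps)
  path <- c(up, rev(up))
  dirs <- rep(c("up", "down"), each = n_steps)
  with_seed(seed, {
    state <- resolve_x0(x0, h$n)
    U_mean <- numeric(length(path))
    for (i in seq_along(path)) {
      if (dirs[i] == "up" && length(state) == 0L) {
        message(sprintf("step %d: extinct state re-seeded (%.2g%% infected)",
                        i, 100 * x0))
        state <- resolve_x0(x0, h$n)
      }
      p2 <- params; p2$beta2 <- path[i]
      res <- cpp_gillespie(h$n, unname(h$edges), params_betas(h, p2),
                           p2$gamma, rule_code(p2),
                           p2$triangle_sign == "healing",
                           as.integer(state),
                           t_transient + t_per_step,
                           t_transient + t_per_step,  # no trajectory needed
                           t_transient, FALSE)
      U_mean[i] <- res$u_mean
      state <- res$final_infected
    }
    out <- tibble::tibble(step = seq_along(path), direction = dirs,
                          beta2 = path, U_mean = U_mean)
    class(out) <- c("sweep_result", class(out))
    out
  })
}

#' Bistability index from microscopic simulation
#'
#' For each triangle rate, runs the hysteresis sweep and reports the maximum
#' over the pairwise rate of the down-branch minus up-branch prevalence gap
#' (clipped at zero), averaged over seeds. Near the onset the curve is noisy:
#' finite-size fluctuations let the chain jump between basins, which is the
#' known practical limit of measuring bistability from simulation.
#'
#' @param h a `hypergraph`.
#' @param params an `epidemic_params` template.
#' @param beta3_grid triangle rates to probe.
#' @param beta2_min,beta2_max,n_steps,t_transient,t_per_step,x0 sweep
#'   controls, as in [hysteresis_sweep()].
#' @param seeds integer vector of seeds to average over.
#' @return a `bistability_curve` tibble with columns `beta3`, `B`.
#' @export
bistability_index_sim <- function(h, params, beta3_grid, beta2_min, beta2_max,
                                  n_steps = 40, t_transient = 5,
                                  t_per_step = 15, x0 = 0.005, seeds = 1L) {
  stopifnot(length(seeds) >= 1)
  B <- vapply(beta3_grid, function(b3) {
    p2 <- params; p2$beta3 <- b3
    gaps <- vapply(seeds, function(s) {
      sw <- hysteresis_sweep(h, p2, beta2_min, beta2_max, n_steps,
                             t_transient, t_per_step, x0, seed = s)
      upb <- sw$U_mean[sw$direction == "up"]
      dnb <- rev(sw$U_mean[sw$direction == "down"])
      max(pmax(dnb - upb, 0))
    }, numeric(1))
    mean(gaps)
  }, numeric(1))
  out <- tibble::tibble(beta3 = beta3_grid, B = B)
  class(out) <- c("bistability_curve", class(out))
  attr(out, "source") <- "simulation"
  out
}
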