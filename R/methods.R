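#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @importFrom tibble as_tibble
#' @export
tibble::as_tibble

#' Tidiers for result objects
#'
#' `tidy()` returns the result as a plain tibble; `glance()` returns a
#' one-row summary (root counts and bistability for `fixed_points`, branch
#' separation for `sweep_result`, regime counts for `phase_diagram`, onset
#' estimate for `bistability_curve`).
#'
#' @param x a result object.
#' @param ... unused.
#' @return a tibble.
#' @name tidiers
NULL

#' @rdname tidiers
#' @export
tidy.fixed_points <- function(x, ...) {
  out <- x
  class(out) <- class(tibble::tibble())
  out
}

#' @rdname tidiers
#' @export
glance.fixed_points <- function(x, ...) {
  stable_u <- x$U[x$stability == "stable"]
  tibble::tibble(
    n_roots = nrow(x),
    n_stable = length(stable_u),
    bistable = length(stable_u) >= 2,
    u_gap = if (length(stable_u) >= 2) max(stable_u) - min(stable_u) else 0
  )
}

#' @rdname tidiers
#' @export
tidy.sweep_result <- function(x, ...) {
  out <- x
  class(out) <- class(tibble::tibble())
  out
}

#' @rdname tidiers
#' @export
glance.sweep_result <- function(x, ...) {
  upb <- x$U_mean[x$direction == "up"]
  dnb <- rev(x$U_mean[x$direction == "down"])
  tibble::tibble(
    n_steps = sum(x$direction == "up"),
    max_branch_gap = max(pmax(dnb - upb, 0)),
    u_top = max(x$U_mean)
  )
}

#' @rdname tidiers
#' @export
glance.phase_diagram <- function(x, ...) {
  tibble::tibble(
    n_cells = nrow(x),
    regimes = length(unique(x$n_solutions)),
    max_solutions = max(x$n_solutions),
    frac_bistable = mean(x$n_solutions == 3)
  )
}

#' @rdname tidiers
#' @export
glance.bistability_curve <- function(x, ...) {
  onset <- x$beta3[which(x$B > 1e-3)[1]]
  tibble::tibble(
    beta3_onset = if (length(onset) && !is.na(onset)) onset else NA_real_,
    B_max = max(x$B)
  )
}

#' Plots for result objects
#'
#' `autoplot()` methods: phase diagrams as solution-count rasters,
#' hysteresis sweeps as up/down prevalence branches, bistability curves as
#' B(beta3) lines, trajectories as U(t), degree distributions as probability
#' sticks.
#'
#' @param object a result object.
#' @param ... unused.
#' @return a ggplot.
#' @name autoplots
NULL

#' @rdname autoplots
#' @export
autoplot.phase_diagram <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$beta2, y = .data$beta3,
                                       fill = factor(.data$n_solutions))) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_manual(
      values = c(`1` = "#fde0dd", `2` = "#fa9fb5", `3` = "#7a0177"),
      name = "solutions") +
    ggplot2::labs(x = expression(beta[2]), y = expression(beta[3]))
}

#' @rdname autoplots
#' @export
autoplot.sweep_result <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$beta2, y = .data$U_mean,
                                       colour = .data$direction)) +
    ggplot2::geom_point() + ggplot2::geom_line() +
    ggplot2::labs(x = expression(beta[2]), y = "mean prevalence U")
}

#' @rdname autoplots
#' @export
autoplot.bistability_curve <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$beta3, y = .data$B)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::labs(x = expression(beta[3]), y = "bistability index B")
}

#' @rdname autoplots
#' @export
autoplot.sis_trajectory <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$t, y = .data$U)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "time", y = "prevalence U")
}

#' @rdname autoplots
#' @export
autoplot.degree_dist <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$k, y = .data$p)) +
    ggplot2::geom_col(width = 1) +
    ggplot2::labs(x = "degree k", y = "P(k)")
}
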