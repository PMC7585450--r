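test_that("the disease-free state is absorbing and the death process is exact", {
  h <- attr(make_fixture("toy-triangle", seed = 1), "hypergraph")
  p <- epidemic_params(2, beta2 = 1, beta3 = 1)
  tr <- simulate_sis(h, p, x0 = 0, t_end = 5, seed = 1)
  expect_true(all(tr$U == 0))
  expect_equal(attr(tr, "n_events"), 0)

  # all rates off except healing: mean infected decays as N exp(-gamma t)
  n <- 400
  hreg <- hypergraph(list(`2` = matrix(c(1L, 2L), 2, 1)), n = n)
  pd <- epidemic_params(gamma = 1, beta2 = 0)
  u1 <- vapply(1:30, function(i) {
    tr <- simulate_sis(hreg, pd, x0 = 1, t_end = 1, record_dt = 1, seed = 500 + i)
    tr$U[tr$t == 1]
  }, numeric(1))
  expected <- exp(-1)
  se <- sd(u1) / sqrt(length(u1))
  expect_lt(abs(mean(u1) - expected), 3 * se + 1e-9)
})

test_that("waiting times on the toy triangle are exponential (collective rule)", {
  h <- toy_triangle()
  b3 <- 1.7
  p <- epidemic_params(gamma = 0, beta3 = b3, rule = "collective")
  fe <- first_event_times(h, p, infected0 = c(1, 2), n_rep = 10000, seed = 2)
  expect_true(all(fe$node == 3))
  ks <- suppressWarnings(ks.test(fe$t, "pexp", b3))
  expect_gt(ks$p.value, 0.01)
})

test_that("waiting times under the individual rule run at beta3 per susceptible", {
  h <- toy_triangle()
  b3 <- 1.3
  p <- epidemic_params(gamma = 0, beta3 = b3, rule = "individual")
  # one infected member: both susceptibles eligible, total rate 2 beta3
  fe <- first_event_times(h, p, infected0 = 1, n_rep = 10000, seed = 3)
  expect_true(all(fe$node %in% c(2, 3)))
  ks <- suppressWarnings(ks.test(fe$t, "pexp", 2 * b3))
  expect_gt(ks$p.value, 0.01)
  # collective rule with one infected member: no infection can occur
  pc <- epidemic_params(gamma = 0, beta3 = b3, rule = "collective")
  fec <- first_event_times(h, pc, infected0 = 1, n_rep = 200, t_max = 50,
                           seed = 4)
  expect_true(all(fec$t == 50))
})

test_that("higher-order healing recovers qualifying infected members", {
  h <- toy_triangle()
  p <- epidemic_params(gamma = 0, beta3 = 2, rule = "collective",
                       triangle_sign = "healing")
  # collective healing requires all three infected; then someone recovers
  fe <- first_event_times(h, p, infected0 = 1:3, n_rep = 2000, seed = 5)
  ks <- suppressWarnings(ks.test(fe$t, "pexp", 3 * 2))
  expect_gt(ks$p.value, 0.01)
  # with only two infected nothing qualifies under the collective condition
  fe2 <- first_event_times(h, p, infected0 = 1:2, n_rep = 100, t_max = 9,
                           seed = 6)
  expect_true(all(fe2$t == 9))
  # individual healing: two infected, each sees one infected partner
  pi <- epidemic_params(gamma = 0, beta3 = 2, rule = "individual",
                        triangle_sign = "healing")
  fe3 <- first_event_times(h, pi, infected0 = 1:2, n_rep = 2000, seed = 7)
  ks3 <- suppressWarnings(ks.test(fe3$t, "pexp", 2 * 2))
  expect_gt(ks3$p.value, 0.01)
})

test_that("rescaling all rates rescales time and nothing else", {
  d <- small_powerlaw()
  degs <- sample_degrees(d, 60, seed = 8)
  h <- merge_hypergraphs(
    sample_links(degs, seed = 8),
    sample_triangles(degs, wiring = "correlated", mean_q = 3, seed = 9)
  )
  run <- function(fac) {
    p <- epidemic_params(gamma = 1 * fac, beta2 = 0.2 * fac,
                         beta3 = 0.1 * fac)
    simulate_sis(h, p, x0 = c(1:10), t_end = 6 / fac, seed = 99,
                 record_dt = 6 / fac, event_log = TRUE)
  }
  a <- attr(run(1), "events")
  b <- attr(run(2), "events")
  expect_identical(a$n_infected, b$n_infected)
  expect_equal(a$t, 2 * b$t, tolerance = 1e-12)
})

test_that("quasi-stationary prevalence on a regular graph matches 1 - gamma/(beta2 k)", {
  h <- attr(make_fixture("regular-links", seed = 10), "hypergraph")
  p <- epidemic_params(2, beta2 = 0.03)
  tr <- simulate_sis(h, p, x0 = 0.5, t_end = 40, seed = 11, burnin = 20)
  expect_lt(abs(attr(tr, "u_mean") - 1 / 3), 0.02)
})

test_that("simulation runs are reproducible for a fixed seed", {
  h <- attr(make_fixture("toy-triangle", seed = 1), "hypergraph")
  p <- epidemic_params(1, beta2 = 0.5, beta3 = 0.8)
  t1 <- simulate_sis(h, p, x0 = c(1, 2), t_end = 4, seed = 123)
  t2 <- simulate_sis(h, p, x0 = c(1, 2), t_end = 4, seed = 123)
  expect_identical(t1$U, t2$U)
  expect_identical(attr(t1, "final_infected"), attr(t2, "final_infected"))
})

test_that("the hysteresis sweep carries state and its branches behave", {
  # small, fast system: the detailed branch-separation checks live in the
  # acceptance suite on the calibrated fixture
  d <- small_powerlaw()
  degs <- sample_degrees(d, 300, seed = 12)
  h <- sample_links(degs, seed = 12)
  g <- 1
  mk <- mean(degs); mk2 <- mean(degs^2)
  b2c <- g * mk / mk2
  p <- epidemic_params(g, beta3 = 0)
  sw <- suppressMessages(
    hysteresis_sweep(h, p, 0.5 * b2c, 3 * b2c, n_steps = 10,
                     t_transient = 2, t_per_step = 6, seed = 13))
  expect_s3_class(sw, "sweep_result")
  expect_equal(nrow(sw), 20)
  # path is up then down
  expect_true(all(diff(sw$beta2[sw$direction == "up"]) >= 0))
  expect_true(all(diff(sw$beta2[sw$direction == "down"]) <= 0))
  # prevalence is high well above threshold on both branches
  expect_gt(sw$U_mean[sw$direction == "up"][10], 0.3)
  expect_gt(sw$U_mean[sw$direction == "down"][1], 0.3)
})

test_that("the simulated bistability index vanishes without triangles", {
  d <- small_powerlaw()
  degs <- sample_degrees(d, 600, seed = 14)
  h <- sample_links(degs, seed = 14)
  g <- 1
  b2c <- g * mean(degs) / mean(degs^2)
  p <- epidemic_params(g)
  bc <- suppressMessages(
    bistability_index_sim(h, p, beta3_grid = 0, beta2_min = 0.5 * b2c,
                          beta2_max = 2 * b2c, n_steps = 10, t_transient = 3,
                          t_per_step = 10, seeds = 1:2))
  expect_s3_class(bc, "bistability_curve")
  expect_lt(bc$B, 0.15)
})
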