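test_that("the mean-field vector field vanishes at 0 and points inward at 1", {
  d <- dist_preset("powerlaw-r4")
  for (rule in c("collective", "individual")) {
    for (wiring in c("correlated", "uncorrelated")) {
      p <- epidemic_params(2, beta2 = 0.02, beta3 = 0.03, rule = rule,
                           wiring = wiring)
      expect_equal(mf_rhs(rep(0, nrow(d)), d, p), rep(0, nrow(d)))
      expect_true(all(mf_rhs(rep(1, nrow(d)), d, p) == -2))
    }
  }
})

test_that("with pairwise edges only the two contagion rules coincide", {
  d <- dist_preset("powerlaw-r4")
  x <- seq(0.05, 0.9, length.out = nrow(d))
  pc <- epidemic_params(2, beta2 = 0.02, beta3 = 0, rule = "collective")
  pi <- epidemic_params(2, beta2 = 0.02, beta3 = 0, rule = "individual")
  expect_equal(mf_rhs(x, d, pc), mf_rhs(x, d, pi))
  # also through the all-sizes interface with a single size-2 entry
  pm_c <- epidemic_params(2, rule = "collective",
                          beta_m = c(`2` = 0.02), mean_km = c(`2` = 100))
  pm_i <- epidemic_params(2, rule = "individual",
                          beta_m = c(`2` = 0.02), mean_km = c(`2` = 100))
  dr <- dist_regular(100)
  xr <- 0.3
  expect_equal(mf_rhs(xr, dr, pm_c), mf_rhs(xr, dr, pm_i))
})

test_that("integration relaxes to the known equilibria", {
  dr <- dist_regular(100)
  # subcritical: beta2 < beta2c, no triangles
  p_sub <- epidemic_params(2, beta2 = 0.01)
  tr <- mf_integrate(dr, p_sub, x0 = 0.2, t_end = 30)
  expect_lt(tail(tr$U, 1), 1e-4)
  expect_true(all(tr$U >= 0 & tr$U <= 1))

  # supercritical regular graph: U -> 1 - gamma/(beta2 k) = 1/3
  p_sup <- epidemic_params(2, beta2 = 0.03)
  tr2 <- mf_integrate(dr, p_sup, x0 = 0.5, t_end = 50)
  expect_equal(tail(tr2$U, 1), 1 / 3, tolerance = 1e-6)

  # bistable: beta3 well above onset, beta2 slightly below threshold
  p_bi <- epidemic_params(2, beta2 = 0.019, beta3 = 0.04)
  lo <- mf_integrate(dr, p_bi, x0 = 0.01, t_end = 60)
  hi <- mf_integrate(dr, p_bi, x0 = 0.5, t_end = 60)
  expect_lt(tail(lo$U, 1), 1e-4)
  # closed-form upper root of beta3 k V^2 + (beta2-beta3) k V + gamma - beta2 k
  vroot <- max(Re(polyroot(c(2 - 1.9, (0.019 - 0.04) * 100, 0.04 * 100))))
  expect_equal(tail(hi$U, 1), vroot, tolerance = 1e-4)
})

test_that("correlated self-consistency residual has the right roots", {
  dr <- dist_regular(100)
  p <- epidemic_params(2, beta2 = 0.03)
  expect_equal(mf_residual_correlated(0, dr, p), 0)
  fp <- find_fixed_points(dr, p)
  expect_equal(nrow(fp), 2)
  expect_equal(fp$V[2], 1 / 3, tolerance = 1e-9)
  expect_equal(fp$stability, c("unstable", "stable"))

  # individual rule: residual sign at small V flips at beta2 + 2 beta3 = beta2c
  b3 <- 0.005
  for (eps in c(-1e-4, 1e-4)) {
    p_i <- epidemic_params(2, beta2 = 0.02 - 2 * b3 + eps, beta3 = b3,
                           rule = "individual")
    h <- mf_residual_correlated(1e-6, dr, p_i)
    expect_equal(sign(h), sign(eps))
  }
})

test_that("uncorrelated system collapses to the correlated one for regular P(k)", {
  dr <- dist_regular(100)
  expect_equal(unname(mf_residual_uncorrelated(0, 0, dr,
    epidemic_params(2, beta2 = 0.03, beta3 = 0.02, wiring = "uncorrelated"))),
    c(0, 0))
  for (b2 in c(0.015, 0.019, 0.025)) {
    for (b3 in c(0, 0.03, 0.05)) {
      pc <- epidemic_params(2, beta2 = b2, beta3 = b3, wiring = "correlated")
      pu <- epidemic_params(2, beta2 = b2, beta3 = b3, wiring = "uncorrelated")
      fc <- find_fixed_points(dr, pc)
      fu <- find_fixed_points(dr, pu)
      expect_equal(fu$V, fc$V, tolerance = 1e-8)
      expect_equal(fu$U, fc$U, tolerance = 1e-8)
      expect_identical(fu$stability, fc$stability)
      # single degree class: U = V at every root
      expect_equal(fu$U, fu$V, tolerance = 1e-8)
    }
  }
})

test_that("solution counts follow the three regimes and residuals vanish at roots", {
  d <- dist_preset("powerlaw-r4")
  g <- 2
  b2c <- beta2_critical(d, g)
  b3c <- beta3c_correlated(d, g)

  fp1 <- find_fixed_points(d, epidemic_params(g, beta2 = 0.5 * b2c, beta3 = 0.5 * b3c))
  expect_equal(nrow(fp1), 1)
  expect_equal(fp1$stability, "stable")

  fp2 <- find_fixed_points(d, epidemic_params(g, beta2 = 1.2 * b2c, beta3 = 0.5 * b3c))
  expect_equal(nrow(fp2), 2)
  expect_equal(fp2$stability, c("unstable", "stable"))

  fp3 <- find_fixed_points(d, epidemic_params(g, beta2 = 0.995 * b2c, beta3 = 2 * b3c))
  expect_equal(nrow(fp3), 3)
  expect_equal(fp3$stability, c("stable", "unstable", "stable"))

  for (fp in list(fp1, fp2, fp3)) {
    p <- attr(fp, "params")
    for (v in fp$V) {
      expect_lt(abs(mf_residual_correlated(v, d, p)), 1e-10)
    }
  }
})

test_that("stability labels agree with the flow of the dynamics", {
  cases <- list(
    list(d = dist_regular(100),
         p = epidemic_params(2, beta2 = 0.019, beta3 = 0.04)),
    list(d = dist_preset("powerlaw-r4"),
         p = epidemic_params(2, beta2 = 0.0159, beta3 = 0.05,
                             wiring = "uncorrelated"))
  )
  for (cs in cases) {
    fp <- find_fixed_points(cs$d, cs$p)
    expect_gte(nrow(fp), 3)   # bistable points chosen
    for (i in seq_len(nrow(fp))) {
      x_eq <- equilibrium_state(cs$d, cs$p, fp$V[i], fp$U[i])
      for (delta in c(-1e-4, 1e-4)) {
        x0 <- pmin(pmax(x_eq + delta, 0), 1)
        tr <- mf_integrate(cs$d, cs$p, x0 = x0, t_end = 40)
        u_end <- tail(tr$U, 1)
        if (fp$stability[i] == "stable") {
          expect_lt(abs(u_end - fp$U[i]), 1e-3)
        }
      }
      if (fp$stability[i] == "unstable") {
        # departing flows must leave the root (slow near-threshold growth
        # rates need a long horizon)
        x0 <- pmin(pmax(x_eq + 1e-4, 0), 1)
        tr <- mf_integrate(cs$d, cs$p, x0 = x0, t_end = 300, dt = 0.5)
        expect_gt(abs(tail(tr$U, 1) - fp$U[i]), 1e-3)
      }
    }
  }
})

test_that("epidemic thresholds match the moment formulas", {
  dr <- dist_regular(100)
  expect_equal(beta2_critical(dr, 2), 0.02)
  expect_equal(beta2_critical(dr, 0), 0)
  d <- dist_preset("powerlaw-r4")
  expect_equal(beta2_critical(d, 2),
               2 * sum(d$p * d$k) / sum(d$p * as.numeric(d$k)^2))
  expect_error(beta2_critical(dist_regular(0), 2), "degenerate")
})

test_that("individual-contagion thresholds: linear shift, regular collapse, pole", {
  d <- dist_preset("powerlaw-r4")
  dr <- dist_regular(100)
  b2c <- beta2_critical(d, 2)
  # beta3 = 0 recovers the pairwise threshold in both wirings
  expect_equal(beta2_critical_individual(d, 2, 0, "correlated"), b2c)
  expect_equal(as.numeric(beta2_critical_individual(d, 2, 0, "uncorrelated")),
               b2c)
  # correlated: beta2c - 2 beta3
  expect_equal(beta2_critical_individual(dr, 2, 0.005, "correlated"), 0.01)
  # regular: uncorrelated formula equals the correlated one for any beta3
  for (b3 in c(0, 0.003, 0.008, 0.02)) {
    expect_equal(
      as.numeric(beta2_critical_individual(dr, 2, b3, "uncorrelated")),
      beta2_critical_individual(dr, 2, b3, "correlated"), tolerance = 1e-12)
  }
  # healing flips the sign of the shift
  expect_equal(beta2_critical_individual(dr, 2, 0.005, "correlated", "healing"),
               0.03)
  # the pole of the uncorrelated formula is reported and lies where beta2 < 0
  b2u <- beta2_critical_individual(d, 2, 0.01, "uncorrelated")
  pole <- attr(b2u, "pole")
  expect_true(is.finite(pole) && pole > 0)
  near_pole <- beta2_critical_individual(d, 2, pole * 0.999, "uncorrelated")
  expect_lt(as.numeric(near_pole), 0)
})

test_that("the all-sizes propagation condition nests the links+triangles one", {
  d <- dist_preset("powerlaw-r4")
  m1 <- dist_moment(d, 1)
  b2c <- beta2_critical(d, 2)
  # M = 2 only: condition reduces to beta2 vs beta2c
  for (b2 in c(0.9, 1.1) * b2c) {
    res <- threshold_multisize(d, 2, c(`2` = b2), c(`2` = m1))
    expect_equal(res$propagates, b2 > b2c)
  }
  # M = 3 with <k^(3)> = <k>: condition identical to beta2 + 2 beta3 = beta2c
  b3 <- 0.004
  res <- threshold_multisize(d, 2, c(`2` = b2c - 2 * b3, `3` = b3),
                             c(`2` = m1, `3` = m1))
  expect_equal(res$lhs, res$rhs, tolerance = 1e-12)
  # truncating the series never increases the left-hand sum
  beta_m <- c(`2` = 0.005, `3` = 0.003, `4` = 0.002, `5` = 0.001)
  mean_km <- c(`2` = m1, `3` = m1, `4` = 50, `5` = 20)
  full <- threshold_multisize(d, 2, beta_m, mean_km)$lhs
  for (M in 2:4) {
    keep <- as.integer(names(beta_m)) <= M
    expect_lte(threshold_multisize(d, 2, beta_m[keep], mean_km[keep])$lhs, full)
  }
})

test_that("collective healing never yields bistability at non-negative rates", {
  d <- dist_preset("powerlaw-r4")
  b2c <- beta2_critical(d, 2)
  grid <- expand.grid(b2 = seq(0, 3 * b2c, length.out = 12),
                      b3 = seq(0, 0.15, length.out = 12))
  counts <- count_fixed_points(d, 2, grid$b2, grid$b3, rule = "collective",
                               wiring = "correlated",
                               triangle_sign = "healing", n_grid = 801)
  expect_true(all(counts <= 2))
})
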