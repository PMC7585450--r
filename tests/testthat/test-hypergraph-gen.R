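test_that("link sampling hits the target counts", {
  h0 <- sample_links(rep(0L, 10))
  expect_equal(ncol(h0$edges[["2"]]), 0)

  h <- sample_links(rep(4L, 1000), seed = 1)
  expect_equal(ncol(h$edges[["2"]]), 2000)           # N<k>/2
  hs <- sample_links(rep(4L, 1000), seed = 1, method = "stub")
  expect_equal(ncol(hs$edges[["2"]]), 2000)
  expect_equal(sort(unique(hyperdegree(hs, 2))), 4L)  # exact degree sequence
  expect_error(sample_links(integer(0)), "empty")
})

test_that("link probability matches the configuration-model form k k'/(N<k>)", {
  d <- small_powerlaw()
  n <- 800
  degs <- sample_degrees(d, n, seed = 3)
  mk <- mean(degs)
  # track the highest-degree pair plus two arbitrary pairs across seeds
  ord <- order(degs, decreasing = TRUE)
  pairs <- rbind(ord[1:2], ord[3:4], c(ord[1], ord[10]))
  n_rep <- 200
  hits <- matrix(0, n_rep, nrow(pairs))
  for (r in seq_len(n_rep)) {
    em <- sample_links(degs, seed = 1000 + r)$edges[["2"]]
    key <- paste(pmin(em[1, ], em[2, ]), pmax(em[1, ], em[2, ]))
    for (q in seq_len(nrow(pairs))) {
      i <- pairs[q, 1]; j <- pairs[q, 2]
      hits[r, q] <- sum(key == paste(min(i, j), max(i, j)))
    }
  }
  for (q in seq_len(nrow(pairs))) {
    i <- pairs[q, 1]; j <- pairs[q, 2]
    expected <- degs[i] * degs[j] / (n * mk)
    se <- sd(hits[, q]) / sqrt(n_rep)
    expect_lt(abs(mean(hits[, q]) - expected), 3 * se + 1e-9)
  }
})

test_that("triangle sampling respects counts and wiring correlations", {
  expect_equal(ncol(sample_triangles(rep(5L, 100), mean_q = 0)$edges[["3"]]), 0)

  # counting: N = 9999, <q> = 100 gives exactly N<q>/3 triangles
  h <- sample_triangles(sample_degrees(small_powerlaw(), 9999, seed = 1),
                        wiring = "uncorrelated", mean_q = 100, seed = 2)
  expect_equal(ncol(h$edges[["3"]]), 333300)

  d <- small_powerlaw()
  degs <- sample_degrees(d, 5000, seed = 5)
  hc <- sample_triangles(degs, wiring = "correlated", mean_q = mean(degs),
                         seed = 6)
  hu <- sample_triangles(degs, wiring = "uncorrelated", mean_q = mean(degs),
                         seed = 6)
  expect_gt(cor(degs, hyperdegree(hc, 3)), 0.5)
  expect_lt(abs(cor(degs, hyperdegree(hu, 3))), 3 / sqrt(5000))
  expect_error(sample_triangles(c(1L, 2L), mean_q = 1), "3 nodes")
})

test_that("correlated triangle membership scales with the degree product", {
  d <- small_powerlaw()
  degs <- sample_degrees(d, 2000, seed = 8)
  h <- sample_triangles(degs, wiring = "correlated", mean_q = 30, seed = 9)
  q <- hyperdegree(h, 3)
  # per-node triangle membership should be proportional to degree:
  # regress q on degree through the origin and check rank correlation
  expect_gt(cor(degs, q, method = "spearman"), 0.8)
  slope <- sum(q * degs) / sum(degs^2)       # least squares through the origin
  expected_slope <- 30 / mean(degs)          # q_i proportional to k_i
  expect_lt(abs(slope - expected_slope) / expected_slope, 0.15)
})

test_that("general hyperedge sampling reduces to links and hits counts", {
  degs <- rep(10L, 1000)
  h5 <- sample_hyperedges(degs, sizes = 5L, mean_km = 1, seed = 1)
  expect_equal(ncol(h5$edges[["5"]]), 200)           # N/5
  expect_equal(mean_hyperdegree(h5, 5), 1)

  h2 <- sample_hyperedges(degs, sizes = 2L, mean_km = 10, seed = 2)
  expect_equal(ncol(h2$edges[["2"]]), 5000)          # same count as links
  # regular degrees: every node's expected hyperdegree is the mean
  km <- hyperdegree(h2, 2)
  expect_lt(abs(mean(km) - 10), 1e-12)
  expect_lt(max(abs(tapply(km, rep(1:10, each = 100), mean) - 10)), 1)
  expect_error(sample_hyperedges(degs, sizes = 2000L, mean_km = 1), "exceeds")
})

test_that("the hyperdegree counting identity holds exactly", {
  d <- small_powerlaw()
  for (seed in 1:3) {
    degs <- sample_degrees(d, 500, seed = seed)
    h <- merge_hypergraphs(
      sample_links(degs, seed = seed),
      sample_triangles(degs, wiring = "correlated", mean_q = 8, seed = seed)
    )
    for (m in c(2, 3)) {
      expect_identical(sum(hyperdegree(h, m)),
                       as.integer(m * ncol(h$edges[[as.character(m)]])))
      expect_equal(mean_hyperdegree(h, m),
                   m * ncol(h$edges[[as.character(m)]]) / h$n)
    }
  }
  # degenerate cases
  expect_equal(mean_hyperdegree(hypergraph(n = 5), 3), 0)
  expect_equal(mean_hyperdegree(toy_triangle(), 3), 1)
})

test_that("hyperedges have distinct members and valid ids", {
  degs <- sample_degrees(small_powerlaw(), 300, seed = 11)
  h <- merge_hypergraphs(
    sample_links(degs, seed = 11),
    sample_triangles(degs, wiring = "correlated", mean_q = 5, seed = 11)
  )
  for (m in names(h$edges)) {
    em <- h$edges[[m]]
    expect_true(all(em >= 1 & em <= h$n))
    expect_false(any(apply(em, 2, anyDuplicated) > 0))
  }
  expect_error(hypergraph(list(c(1L, 1L, 2L))), "distinct")
})
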