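# shared fixtures, built in code

toy_triangle <- function() hypergraph(list(c(1L, 2L, 3L)), n = 3L)

# small heterogeneous distribution for cheap Monte-Carlo wiring checks
small_powerlaw <- function() dist_powerlaw(2.5, 3L, 30L)

# the three calibrated distributions with mean degree ~100
calibrated_dists <- function() {
  list(
    uniform = dist_preset("uniform-100"),
    powerlaw4 = dist_preset("powerlaw-r4"),
    powerlaw3 = dist_preset("powerlaw-r3")
  )
}

expect_tibble <- function(x) expect_s3_class(x, "tbl_df")

# beta2 grid clustered just below the epidemic threshold, where the extra
# solution pair is born; used to keep bistability-index tests fast
multiplicity_grid_for_tests <- function(d, g) {
  b2c <- beta2_critical(d, g)
  sort(c(seq(0.5, 0.9, length.out = 8) * b2c,
         b2c * (1 - exp(seq(log(1e-9), log(0.1), length.out = 16)))))
}
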