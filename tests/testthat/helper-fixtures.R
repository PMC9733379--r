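# Shared fixtures. Module tests use a scaled-down field (10 x 10 m, sparser
# plants) so the default suite stays fast; the acceptance tests run the
# full-size stated configuration once and cache it for the session.

small_field_config <- function(seed = 7, ...) {
  field_config(extent = c(10, 10), points_per_plant = 120,
               ground_density = 120, seed = seed, ...)
}

small_field <- local({
  cache <- new.env(parent = emptyenv())
  function(seed = 7) {
    key <- paste0("s", seed)
    if (is.null(cache[[key]]))
      cache[[key]] <- generate_field(small_field_config(seed = seed))
    cache[[key]]
  }
})

full_field <- local({
  cache <- new.env(parent = emptyenv())
  function(seed = 1) {
    key <- paste0("s", seed)
    if (is.null(cache[[key]]))
      cache[[key]] <- generate_field(field_config(seed = seed))
    cache[[key]]
  }
})

# Feature tables for LAI-model recovery experiments: descriptor ranges span
# what a defoliating cotton canopy produces (occupancy 0.2-0.9, quadrat
# canopy diameters 0.6-1.4 m, plant heights around 0.6 m), with the
# published coefficients as the generating truth.
true_lai_coefs <- c(g = 1.37618, d_t = 0.66738, h_e = -0.02035)
true_lai_intercept <- -0.51087
true_lai_delta <- 0.76

make_feature_table <- function(n = 128, seed = 1, sd_lai = 0.1,
                               with_noise_col = FALSE) {
  set.seed(seed)
  d <- data.frame(g = runif(n, 0.2, 0.9),
                  d_t = runif(n, 0.6, 1.4),
                  h_e = rnorm(n, 0.6, 0.1))
  if (with_noise_col) d$junk <- rnorm(n)
  d$lai <- (true_lai_coefs[["g"]] * d$g +
            true_lai_coefs[["d_t"]] * d$d_t +
            true_lai_coefs[["h_e"]] * d$h_e +
            true_lai_intercept) / true_lai_delta + rnorm(n, 0, sd_lai)
  d
}

expect_error_class <- function(expr, class) {
  testthat::expect_error(expr, class = class)
}
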