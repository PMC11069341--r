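# Impact model: expected-richness power law and impact coefficients.

make_groups <- function(A, d, taxon = "tax", impl = "I", context = "ctx") {
  data.frame(taxon = taxon, implementation = impl, context = context,
             abundance_tpm = A, d_obs = d)
}

test_that("noiseless power-law groups recover (c, gamma) exactly", {
  A <- c(1, 4, 16, 64)
  m <- fit_richness_model(make_groups(A, 2 * A^0.5))
  expect_lt(abs(m$c - 2) / 2, 1e-9)
  expect_lt(abs(m$gamma - 0.5) / 0.5, 1e-9)
  expect_equal(m$r_squared, 1, tolerance = 1e-12)
  expect_equal(m$n_points, 4L)
})

test_that("fit refuses degenerate inputs", {
  expect_error(fit_richness_model(make_groups(c(1, 2), c(1, 2))),
               "insufficient points")
  expect_error(fit_richness_model(make_groups(rep(5, 4), c(2, 2, 3, 3))),
               "degenerate regressor")
  # zero-abundance groups are excluded and counted, not fitted
  m <- fit_richness_model(make_groups(c(0, 1, 4, 16), c(0, 1, 2, 4)))
  expect_equal(m$n_points, 3L)
  expect_equal(m$n_excluded, 1L)
})

test_that("noisy power-law fit matches a closed-form OLS oracle and recovers gamma", {
  set.seed(101)
  A <- exp(rnorm(100, 3, 1))
  d <- 1 * A^0.5 * exp(rnorm(100, 0, 0.1)) # lognormal noise, sigma_log = 0.1
  m <- fit_richness_model(make_groups(A, round(pmax(d, 1))))
  # oracle computed from moments, independent of lm
  usable <- round(pmax(d, 1)) >= 1
  o <- ols_oracle(log(A[usable]), log(round(pmax(d, 1))[usable]))
  expect_equal(m$gamma, o$slope, tolerance = 1e-10)
  expect_equal(log(m$c), o$intercept, tolerance = 1e-10)
  expect_equal(m$r_squared, o$r_squared, tolerance = 1e-10)
  expect_lt(abs(m$gamma - 0.5), 0.05)
  expect_gt(m$r_squared, 0.8)
})

test_that("expected richness evaluates the power law and rejects A <= 0", {
  m <- structure(list(c = 2, gamma = 0.5), class = "richness_model")
  expect_equal(expected_richness(m, 16), 8)
  m0 <- structure(list(c = 1, gamma = 0), class = "richness_model")
  expect_equal(expected_richness(m0, 123.4), 1)
  m1 <- structure(list(c = 1, gamma = 1), class = "richness_model")
  expect_equal(expected_richness(m1, 100), 100)
  expect_error(expected_richness(m, 0), "> 0")
  expect_error(expected_richness(m, -3), "> 0")
})

test_that("impact coefficient identities hold", {
  expect_equal(impact_coefficient(120, 5, 5, 1), 120)
  expect_equal(impact_coefficient(50, 4, 8, 0), 0)
  expect_equal(impact_coefficient(100, 8, 10, 1), 80)
  expect_error(impact_coefficient(10, 2, 0, 1), "d_exp")
  expect_error(impact_coefficient(10, 2, 2, 1.5), "u must")

  # randomized identity / annulment / exactness properties
  set.seed(7)
  for (i in 1:200) {
    A <- runif(1, 0, 1e4)
    d <- sample(1:50, 1)
    de <- runif(1, 0.1, 50)
    expect_identical(impact_coefficient(A, d, d, 1), A)       # d_obs = d_exp
    expect_identical(impact_coefficient(A, d, de, 0), 0)      # u = 0 annuls
    expect_identical(impact_coefficient(A, d, de, 1),
                     A * (d / de) * 1)                        # bit-exact
  }
})

test_that("impact increases with abundance when gamma < 1 (u = 1, d fixed)", {
  m <- fit_richness_model(make_groups(c(1, 4, 16, 64), 2 * c(1, 4, 16, 64)^0.5))
  A <- sort(runif(20, 1, 1000))
  k <- impact_coefficient(A, 5, expected_richness(m, A), 1)
  expect_true(all(diff(k) > 0))
})

test_that("impact table applies the model per group and handles u = 0 / incertae", {
  m <- structure(list(c = 1, gamma = 0.5), class = "richness_model")
  g <- make_groups(100, 8)
  tab <- build_impact_table(g, m, c(I = 1))
  expect_equal(tab$k, 80)
  expect_equal(tab$status, "functional")

  g2 <- rbind(make_groups(100, 8, impl = "I"),
              make_groups(50, 4, impl = "II"),
              make_groups(30, 3, impl = "incertae"))
  tab2 <- build_impact_table(g2, m, c(I = 1, II = 0))
  expect_equal(tab2$k[tab2$implementation == "II"], 0)
  expect_equal(tab2$status[tab2$implementation == "II"], "non_functional")
  # undefined sequence space: k missing, not zero
  expect_true(is.na(tab2$k[tab2$implementation == "incertae"]))
  expect_equal(tab2$status[tab2$implementation == "incertae"], "incertae")

  expect_error(build_impact_table(g2, m, c(I = 1)), "II")

  # one group per (taxon, implementation, context): contexts independent
  g3 <- rbind(make_groups(10, 2, context = "epi"),
              make_groups(40, 5, context = "meso"))
  tab3 <- build_impact_table(g3, m, c(I = 1))
  expect_equal(nrow(tab3), 2L)
})

test_that("aggregation sums k and conserves the grand total", {
  m <- structure(list(c = 1, gamma = 0.5), class = "richness_model")
  g <- rbind(make_groups(9, 3, taxon = "a", context = "epi"),
             make_groups(49, 7, taxon = "b", context = "epi"),
             make_groups(100, 10, taxon = "a", context = "meso"),
             make_groups(67.24, 8.2 * 8.2 / 8.2, taxon = "b", context = "meso"))
  g$d_obs <- c(3, 7, 10, 8)
  tab <- build_impact_table(g, m, c(I = 1))
  byc <- aggregate_k(tab, "context")
  total <- aggregate_k(tab)$k
  expect_equal(sum(byc$k), total)
  for (by in list("taxon", "implementation", c("taxon", "context"),
                  c("taxon", "implementation", "context"))) {
    expect_equal(sum(aggregate_k(tab, by)$k), total)
  }
  expect_error(aggregate_k(tab, "depth"), "unknown grouping key")
})

test_that("aggregation of an all-incertae table is empty, not an error", {
  m <- structure(list(c = 1, gamma = 0.5), class = "richness_model")
  g <- make_groups(c(10, 20, 40), c(3, 4, 6), impl = "incertae")
  tab <- build_impact_table(g, m, c())
  out <- aggregate_k(tab, "context")
  expect_equal(nrow(out), 0L)
})

test_that("fold change is the ratio of aggregated k", {
  m <- structure(list(c = 1, gamma = 0.5), class = "richness_model")
  g <- rbind(make_groups(3, 3, taxon = "a", context = "epi"),
             make_groups(7, 7, taxon = "b", context = "epi"),
             make_groups(10, 10, taxon = "a", context = "meso"),
             make_groups(8.2, 9, taxon = "b", context = "meso"))
  tab <- build_impact_table(g, m, c(I = 1))
  tab$k <- c(3, 7, 10, 8.2) # pin exact k values for the arithmetic check
  fc <- fold_change(tab, list(context = "meso"), list(context = "epi"))
  expect_equal(fc, 18.2 / 10)
  expect_equal(fold_change(tab, list(context = "epi"), list(context = "epi")),
               1.0)
  tab0 <- tab
  tab0$k[tab0$context == "epi"] <- 0
  expect_error(fold_change(tab0, list(context = "meso"),
                           list(context = "epi")), "zero")
  expect_error(fold_change(tab, list(context = "abyss"),
                           list(context = "epi")), "empty")
})

test_that("pooled fold-change mode re-applies the impact formula to pooled sets", {
  m <- structure(list(c = 1, gamma = 0.5), class = "richness_model")
  g <- rbind(make_groups(16, 4, taxon = "a", context = "epi"),
             make_groups(25, 5, taxon = "b", context = "epi"),
             make_groups(64, 8, taxon = "a", context = "meso"))
  tab <- build_impact_table(g, m, c(I = 1))
  fc <- fold_change(tab, list(context = "meso"), list(context = "epi"),
                    mode = "pooled", model = m)
  k_epi <- 41 * (9 / sqrt(41))   # pooled A = 41, d = 9
  k_meso <- 64 * (8 / sqrt(64))
  expect_equal(fc, k_meso / k_epi)
})
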