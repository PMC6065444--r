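test_that("expected tract density is an exponential mixture with thinning", {
  h <- build_history(c(EUR = 1), T_max = 15,
                     pulses = data.frame(t = 10, ancestry = "AFR", m = 0.2))
  f <- expected_tract_density(h, "AFR")
  cmp <- attr(f, "components")
  expect_equal(nrow(cmp), 1)
  # neighbor correction thins the junction rate by the pool fraction
  expect_equal(cmp$rate, 10 * (1 - 0.2))
  expect_equal(attr(f, "tracts_per_morgan"), 0.2 * 8)
  f0 <- expected_tract_density(h, "AFR", correction = "none")
  expect_equal(attr(f0, "components")$rate, 10)
  # density integrates to ~1
  expect_equal(integrate(f, 0, 50)$value, 1, tolerance = 1e-6)
  expect_error(expected_tract_density(h, "NAM"), "absent")
})

test_that("two-pulse densities mix the per-entry exponentials", {
  h <- build_history(c(EUR = 1), T_max = 15,
                     pulses = data.frame(t = c(10, 4), ancestry = "AFR",
                                         m = c(0.17, 0.15)))
  f <- expected_tract_density(h, "AFR")
  cmp <- attr(f, "components")
  expect_equal(nrow(cmp), 2)
  expect_equal(sum(cmp$weight), 1)
  expect_true(all(diff(cmp$rate[order(cmp$t)]) > 0))
})

test_that("expected bin counts scale linearly and vanish beyond the map", {
  h <- fix_history_single_pulse()
  co <- simulate_tracts(h, toy_genetic_map(3, 1), n_hap = 20,
                        pop_size = Inf, seed = 3)
  hs <- tract_histogram(co$tracts)
  lam <- expected_bin_counts(h, hs)
  hs2 <- hs
  hs2$n_hap <- hs$n_hap * 2
  expect_equal(expected_bin_counts(h, hs2), 2 * lam)
  # a bin entirely beyond the chromosome length gets zero expectation
  hs3 <- tract_histogram(co$tracts, bin_edges_cM = c(5, 50, 99.9))
  lam3 <- expected_bin_counts(h, hs3)
  hs4 <- hs3
  hs4$edges_cM <- c(100, 140)
  hs4$counts <- hs3$counts[, 1, drop = FALSE]
  expect_true(all(expected_bin_counts(h, hs4) == 0))
})

test_that("expected interior counts match a large simulation within 5%", {
  h <- fix_history_single_pulse(t = 10, m = 0.2)
  map <- toy_genetic_map(5, 1.4)
  co <- simulate_tracts(h, map, n_hap = 800, pop_size = Inf, seed = 17)
  hs <- tract_histogram(co$tracts)
  lam <- expected_bin_counts(h, hs)
  for (a in c("AFR", "NAM"))
    expect_lt(abs(sum(lam[a, ]) - sum(hs$counts[a, ])) /
                sum(hs$counts[a, ]), 0.05)
})

test_that("poisson_loglik matches hand arithmetic and flags impossibles", {
  obs <- matrix(2)
  expect_equal(poisson_loglik(obs, matrix(1)), 2 * log(1) - 1 - log(2))
  expect_equal(round(poisson_loglik(obs, matrix(1)), 4), -1.6931)
  expect_identical(poisson_loglik(matrix(1), matrix(0)), -Inf)
  expect_error(poisson_loglik(matrix(1, 2, 2), matrix(1)), "shapes")
  # lambda = n maximizes the likelihood over lambda
  n <- matrix(c(3, 7, 0, 2), 2)
  base <- poisson_loglik(n, pmax(n, 1e-9))
  set.seed(2)
  for (i in 1:10)
    expect_lte(poisson_loglik(n, pmax(n + rnorm(4, 0, 0.3), 1e-9)), base)
})

test_that("model specs have the advertised parameter counts", {
  mods <- admixture_models()
  expect_equal(vapply(mods, function(m) m$n_par, 0L),
               c(M1 = 3L, M2 = 5L, M3 = 5L, M4 = 7L, M5 = 9L))
  expect_equal(mods$M2$pulses$after, c(NA, "AFR1"))
})

test_that("fitting is deterministic and recovers a single pulse", {
  h <- fix_history_single_pulse(t = 10, m = 0.2)
  co <- simulate_tracts(h, toy_genetic_map(10, 2), n_hap = 120,
                        pop_size = Inf, seed = 41)
  hs <- tract_histogram(co$tracts)
  f1 <- fit_pulse_model(hs, "M1", n_restarts = 25, seed = 5)
  f2 <- fit_pulse_model(hs, "M1", n_restarts = 25, seed = 5)
  expect_identical(coef(f1), coef(f2))
  expect_lt(abs(coef(f1)[["t_AFR1"]] - 10), 1.5)
  expect_lt(abs(coef(f1)[["m_AFR1"]] - 0.2), 0.03)
  expect_s3_class(f1, "pulse_fit")
  expect_equal(unname(attr(logLik(f1), "df")), 3)
  # methods behave
  expect_equal(dim(residuals(f1)), dim(fitted(f1)))
  expect_equal(predict(f1), fitted(f1))
  sim <- simulate(f1, seed = 1)
  expect_s3_class(sim, "tract_histogram")
  expect_equal(dim(sim$counts), dim(f1$lambda))
})

test_that("nested models never fit worse than their submodels", {
  h <- fix_history_single_pulse(t = 8, m = 0.15)
  co <- simulate_tracts(h, toy_genetic_map(8, 2), n_hap = 80,
                        pop_size = Inf, seed = 51)
  hs <- tract_histogram(co$tracts)
  f1 <- fit_pulse_model(hs, "M1", n_restarts = 40, seed = 6)
  f4 <- fit_pulse_model(hs, "M4", n_restarts = 40, seed = 6)
  expect_gte(f4$logLik, f1$logLik - 0.5)
})

test_that("log-likelihood is stable under bin refinement", {
  h <- fix_history_single_pulse(t = 10, m = 0.2)
  co <- simulate_tracts(h, toy_genetic_map(10, 2), n_hap = 120,
                        pop_size = Inf, seed = 61)
  hs1 <- tract_histogram(co$tracts, n_bins = 16)
  hs2 <- tract_histogram(co$tracts, n_bins = 31)
  f1 <- fit_pulse_model(hs1, "M1", n_restarts = 20, seed = 7)
  f2 <- fit_pulse_model(hs2, "M1", n_restarts = 20, seed = 7)
  # parameter estimates agree across bin resolutions
  expect_lt(abs(coef(f1)[["t_AFR1"]] - coef(f2)[["t_AFR1"]]), 0.5)
  expect_lt(abs(coef(f1)[["m_AFR1"]] - coef(f2)[["m_AFR1"]]), 0.01)
})

test_that("model comparison ranks by log-likelihood with tie-breaks", {
  h <- fix_history_single_pulse(t = 9, m = 0.18)
  co <- simulate_tracts(h, toy_genetic_map(6, 2), n_hap = 60,
                        pop_size = Inf, seed = 71)
  hs <- tract_histogram(co$tracts)
  fa <- fit_pulse_model(hs, "M1", n_restarts = 20, seed = 8)
  fb <- fit_pulse_model(hs, "M1", n_restarts = 20, seed = 8)
  fc <- fit_pulse_model(hs, "M3", n_restarts = 20, seed = 8)
  cmp <- compare_models(fa, fb, fc)
  expect_equal(cmp$delta_logLik[1], 0)
  expect_true(all(diff(cmp$logLik) <= 1e-9))
  # an exact log-likelihood tie is broken by fewer parameters
  fake <- fa
  fake$model$id <- "M9"
  fake$model$n_par <- 99L
  cmp2 <- compare_models(fake, fa)
  expect_equal(cmp2$model, c("M1", "M9"))
  other <- fit_pulse_model(tract_histogram(co$tracts, n_bins = 10), "M1",
                           n_restarts = 5, seed = 1)
  expect_error(compare_models(fa, other), "different histograms")
})

test_that("bootstrap intervals contain the estimate and behave sanely", {
  h <- fix_history_single_pulse(t = 10, m = 0.2)
  co <- simulate_tracts(h, toy_genetic_map(10, 2), n_hap = 150,
                        pop_size = Inf, seed = 81)
  hs <- tract_histogram(co$tracts)
  f <- fit_pulse_model(hs, "M1", n_restarts = 25, seed = 9,
                       ci = "bootstrap", B = 40)
  ci <- f$ci
  expect_true(all(ci[, "lower"] <= coef(f) & coef(f) <= ci[, "upper"]))
  expect_lt(ci["t_AFR1", "upper"] - ci["t_AFR1", "lower"], 6)
})

test_that("parametric-bootstrap refits recover the generating estimate", {
  # draw data from a fitted model, refit, and check CI coverage of the
  # generating parameters at the nominal 68.3% level
  h <- fix_history_single_pulse(t = 10, m = 0.2)
  co <- simulate_tracts(h, toy_genetic_map(10, 2), n_hap = 150,
                        pop_size = Inf, seed = 91)
  hs <- tract_histogram(co$tracts)
  f0 <- fit_pulse_model(hs, "M1", n_restarts = 25, seed = 10)
  set.seed(11)
  cover <- matrix(NA, 40, 3)
  for (i in 1:40) {
    hb <- f0$histogram
    hb$counts[] <- rpois(length(f0$lambda), f0$lambda)
    fb <- fit_pulse_model(hb, "M1", n_restarts = 8, seed = 100 + i,
                          ci = "bootstrap", B = 60)
    cover[i, ] <- fb$ci[, "lower"] <= coef(f0) & coef(f0) <= fb$ci[, "upper"]
  }
  cov_rate <- colMeans(cover)
  # nominal 68.3%, tolerance +-10 points plus binomial noise at n = 40
  expect_true(all(cov_rate >= 0.58 - 0.15 & cov_rate <= 0.78 + 0.15))
})

test_that("generation-to-year conversion is exact and monotone", {
  expect_equal(generations_to_years(15, anchor_year = 1937), 1502)
  expect_equal(generations_to_years(0, anchor_year = 1937), 1937)
  expect_equal(generations_to_years(c(14, 15), anchor_year = 1937),
               c(1531, 1502))
  expect_error(generations_to_years(5), "anchor_year")
  expect_error(generations_to_years(-1, 1900), "non-negative")
})
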