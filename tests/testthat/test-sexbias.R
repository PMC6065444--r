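test_that("compartment ancestry separates autosomes and X", {
  # one individual: all-EUR autosomes, all-AFR X
  auto <- as_tract_set(
    data.frame(haplotype = 1:2, chrom = "chr1", start_cM = 0, end_cM = 100,
               ancestry = "EUR", individual = 1),
    c(chr1 = 100), n_hap = 2)
  x <- as_tract_set(
    data.frame(haplotype = 1:2, chrom = "chrX", start_cM = 0, end_cM = 180,
               ancestry = "AFR", individual = 1),
    c(chrX = 180), n_hap = 2)
  meta <- data.frame(individual = 1, sex = "F")
  ca <- compartment_ancestry(auto, x, meta)
  expect_equal(ca$q_auto[ca$ancestry == "EUR"], 1)
  expect_equal(ca$q_auto[ca$ancestry == "AFR"], 0)
  expect_equal(ca$q_x[ca$ancestry == "AFR"], 1)

  # a male with two X haplotypes is rejected
  meta_m <- data.frame(individual = 1, sex = "M")
  expect_error(compartment_ancestry(auto, x, meta_m), "two X")
})

test_that("a female's X fraction averages her two X haplotypes", {
  auto <- as_tract_set(
    data.frame(haplotype = 1:2, chrom = "chr1", start_cM = 0, end_cM = 100,
               ancestry = "EUR", individual = 1),
    c(chr1 = 100), n_hap = 2)
  x <- as_tract_set(
    data.frame(haplotype = 1:2, chrom = "chrX", start_cM = 0, end_cM = 180,
               ancestry = c("AFR", "EUR"), individual = 1),
    c(chrX = 180), n_hap = 2)
  ca <- compartment_ancestry(auto, x, data.frame(individual = 1, sex = "F"))
  expect_equal(ca$q_x[ca$ancestry == "AFR"], 0.5)
})

test_that("compartment means match the sexed-simulation closed forms", {
  h <- fix_sexed_history(0.3, 0.1)
  map <- toy_genetic_map(3, 1.5, include_x = TRUE)
  co <- simulate_sexed_cohort(h, map, n_ind = 250, pop_size = Inf, seed = 23)
  ca <- compartment_ancestry(co)
  afr <- ca[ca$ancestry == "AFR", ]
  se_a <- sd(afr$q_auto) / sqrt(nrow(afr))
  se_x <- sd(afr$q_x) / sqrt(nrow(afr))
  expect_lt(abs(mean(afr$q_auto) - 0.2), 3 * se_a)
  expect_lt(abs(mean(afr$q_x) - 7 / 30), 3 * se_x)
})

test_that("delta_admix reports differences, ratios and bootstrap CIs", {
  # constructed cohort with q_x = 0.3, q_auto = 0.2 exactly for AFR
  set.seed(4)
  n <- 40
  qa <- 0.2 + rnorm(n, 0, 0.02)
  ca <- fix_compartment(qa, qa + 0.1)
  d <- delta_admix(ca, B = 200, seed = 3)
  afr <- d[d$ancestry == "AFR", ]
  expect_equal(afr$D, 0.1, tolerance = 1e-12)
  expect_equal(afr$delta, 0.1 / mean(qa), tolerance = 1e-12)
  expect_gt(afr$D_lower, 0)
  # zero difference gives zero D and delta
  ca0 <- fix_compartment(qa, qa)
  d0 <- delta_admix(ca0, B = 50, seed = 3)
  expect_equal(d0$D[d0$ancestry == "AFR"], 0)
  expect_equal(d0$delta[d0$ancestry == "AFR"], 0)
  expect_error(delta_admix(fix_compartment(rep(0.2, 4), rep(0.2, 4)),
                           B = 10, seed = 1), "fewer than 5")
})

test_that("delta_admix is deterministic under a seed", {
  set.seed(8)
  ca <- fix_compartment(runif(20, 0.1, 0.3), runif(20, 0.1, 0.3))
  expect_identical(as.data.frame(delta_admix(ca, B = 100, seed = 5)),
                   as.data.frame(delta_admix(ca, B = 100, seed = 5)))
})

test_that("signed-rank test matches the exact extreme-case p-value", {
  # all ten X fractions exceed the autosomal ones (distinct differences):
  # the exact two-sided p is 2 / 2^10 = 2^-9
  qa <- seq(0.1, 0.28, length.out = 10)
  ca <- fix_compartment(qa, qa + seq(0.01, 0.1, length.out = 10))
  out <- wilcoxon_xa_test(ca, "AFR")
  expect_equal(out$p_value, 2 / 2^10, tolerance = 1e-10)
  expect_equal(out$p_value, 0.001953125)

  # all differences zero -> p = 1 with flag
  ca0 <- fix_compartment(rep(0.2, 8), rep(0.2, 8))
  out0 <- wilcoxon_xa_test(ca0, "AFR")
  expect_equal(out0$p_value, 1)
  expect_true(out0$all_zero)
  expect_error(wilcoxon_xa_test(fix_compartment(rep(0.2, 5), rep(0.3, 5)),
                                "AFR"), "at least 6")
})

test_that("sex-contribution inversion solves the equilibrium equations", {
  inv <- invert_sex_contributions(0.5, 0.5)
  expect_equal(inv$s_f, 0.5)
  expect_equal(inv$s_m, 0.5)
  inv2 <- invert_sex_contributions(0.2, 0.26)
  expect_equal(inv2$s_f, 0.38)
  expect_equal(inv2$s_m, 0.02, tolerance = 1e-12)
  expect_false(inv2$clipped)
  # clipping flagged outside the feasible region
  inv3 <- invert_sex_contributions(0.1, 0.5)
  expect_true(inv3$clipped)
  expect_true(inv3$s_f >= 0 && inv3$s_f <= 1)
  expect_error(invert_sex_contributions(1.2, 0.5), "\\[0, 1\\]")
})

test_that("inversion is the exact inverse of the forward map", {
  grid <- expand.grid(s_f = seq(0, 1, 0.1), s_m = seq(0, 1, 0.1))
  q_a <- (grid$s_f + grid$s_m) / 2
  q_x <- (2 * grid$s_f + grid$s_m) / 3
  inv <- invert_sex_contributions(q_a, q_x)
  expect_equal(inv$s_f, grid$s_f, tolerance = 1e-12)
  expect_equal(inv$s_m, grid$s_m, tolerance = 1e-12)
  expect_false(any(inv$clipped))
})

test_that("inversion recovers simulated sex-specific founding within 0.05", {
  h <- fix_sexed_history(0.3, 0.1)
  map <- toy_genetic_map(3, 1.5, include_x = TRUE)
  co <- simulate_sexed_cohort(h, map, n_ind = 200, pop_size = Inf, seed = 33)
  tru <- co$truth
  afr <- tru[tru$ancestry == "AFR", ]
  inv <- invert_sex_contributions(mean(afr$q_auto), mean(afr$q_x))
  expect_lt(abs(inv$s_f - 0.3), 0.05)
  expect_lt(abs(inv$s_m - 0.1), 0.05)
})

test_that("the X recursion converges to (2 s_f + s_m) / 3", {
  # equal contributions stay constant
  tr <- x_recursion(0.25, 0.25, 10)
  expect_true(all(tr$q_x == 0.25))
  # female-biased example converges to 7/30 by generation 15
  tr2 <- x_recursion(0.3, 0.1, 15)
  expect_lt(abs(tr2$q_x[16] - 7 / 30), 1e-3)
  expect_equal(attr(tr2, "limit"), 7 / 30)
  # damped oscillation: deviation magnitude decreases after g = 2
  dev <- abs(tr2$q_x - 7 / 30)
  expect_true(all(diff(dev[-(1:2)]) <= 1e-12))
  # X-copy pool mean (2 q_f + q_m)/3 is invariant from the start
  pool <- (2 * tr2$q_f + tr2$q_m) / 3
  expect_equal(pool, rep(7 / 30, 16), tolerance = 1e-12)
})

test_that("positive delta follows female-biased simulations", {
  h <- fix_sexed_history(0.3, 0.1)
  map <- toy_genetic_map(3, 1.5, include_x = TRUE)
  co <- simulate_sexed_cohort(h, map, n_ind = 200, pop_size = Inf, seed = 43)
  da <- delta_admix(compartment_ancestry(co), B = 300, seed = 44)
  afr <- da[da$ancestry == "AFR", ]
  expect_gt(afr$delta, 0)
  expect_gt(afr$delta_lower, 0)
  eur <- da[da$ancestry == "EUR", ]
  expect_lt(eur$delta, 0)
})
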