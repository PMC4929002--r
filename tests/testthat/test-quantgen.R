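# Quantitative genetics: transforms, mixtures, variance partitioning, k,
# heritability, sequence variance, selection report, FDR.

test_that("normal-quantile transform preserves ranks and location", {
  set.seed(1)
  x <- rnorm(1000, mean = 5, sd = 2)
  y <- normal_quantile_transform(x)
  expect_gt(cor(x, y), 0.99)
  expect_identical(rank(x), rank(y))
  expect_lt(abs(median(y) - median(x)), 0.05)
  # monotone transforms of the input give identical standardized output
  # (the location and scale track the input's median and MAD)
  std <- function(z) (z - median(z)) / (1.4824 * mad(z, constant = 1))
  expect_equal(std(normal_quantile_transform(exp(x / 3))),
               std(normal_quantile_transform(x)), tolerance = 1e-9)
  # ties share averaged ranks -> equal output values
  xt <- c(1, 2, 2, 3, 4, 10)
  yt <- normal_quantile_transform(xt)
  expect_equal(yt[2], yt[3])
  expect_error(normal_quantile_transform(rep(1, 10)), "degenerate")
  expect_error(normal_quantile_transform(c(1, 2)), "at least 3")
})

test_that("expression mixture finds the Bayes boundary when separated", {
  set.seed(2)
  x <- c(rnorm(300, 0, 1), rnorm(300, 10, 1))
  fit <- fit_expression_mixture(x)
  expect_gt(fit$cutoff, 3)
  expect_lt(fit$cutoff, 7)
  truth <- rep(c(FALSE, TRUE), each = 300)
  expect_gte(mean(fit$expressed == truth), 0.99)
  # degenerate: one component
  expect_error(fit_expression_mixture(rnorm(300)), "degenerate")
  expect_error(fit_expression_mixture(rnorm(40)), "at least 50")
})

test_that("REML variance partition equals closed-form balanced ANOVA", {
  set.seed(3)
  for (i in 1:5) {
    n_l <- sample(5:12, 1); r <- sample(3:6, 1)
    p <- simulate_trait_panel(n_l, r, v_line = 2, v_within = 1,
                              seed = 100 + i)
    vc <- partition_variance(p)
    a <- stats::anova(stats::lm(value ~ line, data = p))
    ms_line <- a$`Mean Sq`[1]; ms_within <- a$`Mean Sq`[2]
    v_line_anova <- max(0, (ms_line - ms_within) / r)
    expect_equal(vc$v_line, v_line_anova, tolerance = 1e-6)
    expect_equal(vc$v_within,
                 if (v_line_anova > 0) ms_within else
                   sum(a$`Sum Sq`) / (n_l * r - 1),
                 tolerance = 1e-6)
  }
})

test_that("boundary LRT for among-line variance holds its size", {
  # under v_line = 0 truth, the half-mixture null gives ~nominal rejections
  set.seed(4)
  pvals <- vapply(1:400, function(s) {
    p <- simulate_trait_panel(15, 3, v_line = 0, v_within = 1,
                              seed = 7000 + s)
    partition_variance(p)$p_value
  }, 0)
  rate <- mean(pvals < 0.05)
  # binomial 4-SE band around 0.05
  expect_lt(abs(rate - 0.05), 4 * sqrt(0.05 * 0.95 / 400))
  # and the test has power under a real among-line component
  p1 <- simulate_trait_panel(25, 4, v_line = 5, v_within = 1, seed = 1)
  expect_lt(partition_variance(p1)$p_value, 1e-4)
})

test_that("nested replicate term separates vial from residual variance", {
  set.seed(5)
  n_l <- 25; n_r <- 2; n_i <- 10
  line_eff <- rnorm(n_l, 0, sqrt(4))
  d <- expand.grid(line = sprintf("L%02d", 1:n_l), replicate = 1:n_r,
                   ind = 1:n_i)
  rep_eff <- rnorm(n_l * n_r, 0, sqrt(2))
  names(rep_eff) <- paste(rep(sprintf("L%02d", 1:n_l), n_r),
                          rep(1:n_r, each = n_l))
  d$value <- line_eff[as.integer(factor(d$line))] +
    rep_eff[paste(d$line, d$replicate)] + rnorm(nrow(d), 0, 1)
  d$trait <- "bristles"; d$sex <- "F"
  vc <- partition_variance(d, with_replicate_term = TRUE)
  expect_lt(abs(vc$v_line - 4), 2)
  expect_lt(abs(vc$v_rep - 2), 1)
  expect_lt(abs(vc$v_within - 1), 0.3)
})

test_that("the drift factor k follows the closed form and its limits", {
  expect_equal(round(k_factor(60, 21), 2), 89.84)
  # monotone increasing in t, decreasing in 2Ne
  t_scan <- k_factor(seq(1, 500, by = 7), 21)
  expect_true(all(diff(t_scan) > 0))
  ne_scan <- vapply(seq(2, 100, by = 2), function(ne) k_factor(60, ne), 0)
  expect_true(all(diff(ne_scan) < 0))
  # large-t asymptote: k -> 2 (t - 2Ne + 5)
  expect_equal(k_factor(1e5, 21), 2 * (1e5 - 21 + 5), tolerance = 1e-8)
})

test_that("mutational heritability applies the mode-specific Ve", {
  vc <- list(v_line = k_factor(60, 21), v_within = 100, v_rep = 50,
             trait = "t", sex = "F")
  class(vc) <- "varcomp"
  mexp <- mutational_heritability(vc, t = 60, two_ne = 21, pool_n = 10,
                                  mode = "expression")
  expect_equal(mexp$vm, 1)
  expect_equal(mexp$ve, 1000)
  expect_equal(mexp$h2m, 1e-3)
  msleep <- mutational_heritability(vc, mode = "sleep")
  expect_equal(msleep$ve, 100)           # pool size ignored
  mbr <- mutational_heritability(vc, mode = "bristle")
  expect_equal(mbr$ve, 150)
  # scale equivariance: multiplying the trait by c scales Vm and Ve by c^2
  vc2 <- vc; vc2$v_line <- vc$v_line * 9; vc2$v_within <- 900
  m2 <- mutational_heritability(vc2, mode = "sleep")
  expect_equal(m2$h2m, mutational_heritability(vc, mode = "sleep")$h2m)
})

test_that("h2m recovery from panels simulated with known Vm and Ve", {
  t <- 60; two_ne <- 21; k <- k_factor(t, two_ne)
  vm_true <- 0.02; ve_true <- 10; pool_n <- 10
  h2 <- vapply(1:40, function(s) {
    p <- simulate_trait_panel(25, 2, v_line = k * vm_true,
                              v_within = ve_true / pool_n,
                              pool_n = pool_n, seed = 800 + s)
    vc <- partition_variance(p)
    mutational_heritability(vc, t, two_ne, pool_n, "expression")$h2m
  }, 0)
  expect_lt(abs(median(h2) / (vm_true / ve_true) - 1), 0.25)
})

test_that("neutral population size inverts pi = 4 N mu", {
  expect_equal(floor(neutral_population_size(4.92e-3, 6.60e-9)), 186363)
  expect_equal(neutral_population_size(4e-9 * 250, 1e-9) * 4 * 1e-9,
               4e-9 * 250)
  expect_equal(neutral_population_size(4 * 1e-8, 1e-8), 1)
})

test_that("sequence variance sums per-locus dosage variances", {
  # a mutation fixed in one of 23 lines: sample variance 4/23
  v <- sequence_variance_sum(matrix(c(2, rep(0, 22)), ncol = 1))
  expect_equal(v, var(c(2, rep(0, 22))))
  expect_equal(v, 4 / 23)
  # monomorphic locus contributes nothing
  expect_equal(sequence_variance_sum(cbind(rep(1, 10), rep(0, 10))), 0)
  # 50 lines at dosage frequency 0.5: per-locus ~ (50/49) * 1
  set.seed(6)
  dos <- matrix(2 * rbinom(50 * 500, 1, 0.5), nrow = 50)
  expect_lt(abs(sequence_variance_sum(dos) / 500 - 4 * 0.25 * 50 / 49),
            0.03)
  # k scaling and sub-cutoff augmentation
  sp <- expected_spectrum(23, reps = 5e4, seed = 3)
  sampler <- make_below_cutoff_sampler(sp, n_detected = 100)
  expect_gt(attr(sampler, "n_below_default"), 0)
  base <- sequence_variance_sum(dos, k = 2)
  expect_equal(base, sequence_variance_sum(dos) / 2)
  aug <- sequence_variance_sum(dos, k = 2, below_cutoff_sampler = sampler,
                               seed = 9)
  expect_gt(aug, base)
  expect_error(sequence_variance_sum(matrix(1, 1, 3)), "2 lines")
})

test_that("selection report assembles the model comparisons exactly", {
  # house-of-cards locus number at Vs = 20 Ve, Vg = Ve, mu = 6.6e-9
  rep1 <- selection_report(vm = 1e-3, vg = 1, sum_var_m_over_k = 1,
                           sum_var_g = 1, n_pop = 1e6, mu = 6.60e-9,
                           ve = 1, vs_multiplier = 20)
  expect_equal(signif(rep1$hoc_n_loci, 2), 1.9e6)
  expect_equal(rep1$s_pleiotropic, 1e-3)
  expect_equal(rep1$neutral_expectation, 2.5e-7)
  # equal effect-size distributions: Vm/Vg equals the sequence ratio
  rep2 <- selection_report(vm = 0.004, vg = 2, sum_var_m_over_k = 0.02,
                           sum_var_g = 10, n_pop = 1e5, mu = 1e-8, ve = 1)
  expect_equal(rep2$vm_vg, rep2$sequence_ratio)
  expect_equal(rep2$effect_size_ratio, 1)
  # the effect-size-ratio identity holds for arbitrary inputs
  set.seed(7)
  for (i in 1:20) {
    v <- runif(7, 0.1, 10)
    r <- selection_report(v[1], v[2], v[3], v[4], 10^runif(1, 3, 6),
                          10^-runif(1, 7, 9), v[5])
    expect_equal(r$effect_size_ratio,
                 (r$vm / r$vg) * (v[4] / v[3]), tolerance = 1e-12)
  }
  # pleiotropic s equals the observed Vm/Vg scale
  rep3 <- selection_report(vm = 1.94e-3, vg = 1, sum_var_m_over_k = 1,
                           sum_var_g = 1, n_pop = 1e6, mu = 1e-8, ve = 1)
  expect_equal(rep3$s_pleiotropic, 1.94e-3)
})

test_that("BH adjustment matches hand computation and bounds p", {
  expect_equal(fdr_adjust(rep(0.01, 100)), rep(0.01, 100))
  expect_equal(fdr_adjust(c(0.01, 0.04, 0.03, 0.005)),
               c(0.02, 0.04, 0.04, 0.02))
  expect_equal(fdr_adjust(0.0321), 0.0321)
  p <- runif(50)
  q <- fdr_adjust(p)
  expect_true(all(q >= p))
  expect_true(all(q[order(p)] == cummax(q[order(p)])) ||
                all(diff(q[order(p)]) >= -1e-15))
})

test_that("neutral DGRP-like panels center Vm/Vg on 1/(4N)", {
  # simulate standing variance at its neutral expectation Vg = 4 N Vm and
  # check the estimated ratio centers on 1/(4N)
  n_pop <- 250
  t <- 60; k <- k_factor(t, 21)
  vm_true <- 0.01
  vg_true <- 4 * n_pop * vm_true
  ratio <- vapply(1:120, function(s) {
    ma <- simulate_trait_panel(25, 4, v_line = k * vm_true, v_within = 1,
                               seed = 2000 + s)
    dg <- simulate_trait_panel(40, 4, v_line = vg_true, v_within = 1,
                               seed = 3000 + s)
    vm_hat <- partition_variance(ma)$v_line / k
    vg_hat <- partition_variance(dg)$v_line
    vm_hat / vg_hat
  }, 0)
  med <- median(ratio)
  expect_lt(abs(med / (1 / (4 * n_pop)) - 1), 0.25)
})
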