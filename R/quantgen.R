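# Quantitative genetics of mutational and standing variance: variance
# partitioning, the drift correction k, mutational heritability, and the
# comparison of Vm/Vg with neutral and mutation-selection-balance
# expectations.

#' Rank-based normal-quantile transform
#'
#' Maps values, rank-preservingly, onto quantiles of a normal distribution
#' centred on the sample median with standard deviation `scale_factor`
#' times the raw median absolute deviation (1.4824 rescales the MAD to the
#' standard-deviation scale for normal data). Plotting positions are
#' `rank / (n + 1)`; ties share averaged ranks.
#'
#' @param values Numeric vector (>= 3 finite values).
#' @param scale_factor MAD-to-SD scale factor (default 1.4824; use 1 for a
#'   raw-MAD transform — the choice only rescales the output and does not
#'   affect rank-based inference).
#' @return The transformed values.
#' @export
normal_quantile_transform <- function(values, scale_factor = 1.4824) {
  v <- values[is.finite(values)]
  if (length(v) < 3) stop("need at least 3 finite values")
  if (length(v) != length(values)) stop("values must all be finite")
  m <- stats::median(values)
  s <- scale_factor * stats::mad(values, constant = 1)
  if (s == 0) stop("median absolute deviation is zero: degenerate input")
  r <- rank(values, ties.method = "average")
  stats::qnorm(r / (length(values) + 1), mean = m, sd = s)
}

#' Two-component normal mixture call of expressed genes
#'
#' Fits a two-component Gaussian mixture (EM, via \pkg{mclust}) to
#' per-gene median expression values and derives an expression cutoff: the
#' smallest value whose posterior probability of belonging to the
#' higher-mean component is at least `posterior_cutoff`. Genes at or above
#' the cutoff are labelled expressed.
#'
#' @param medians Numeric vector of per-gene median expression (>= 50
#'   genes).
#' @param posterior_cutoff Posterior threshold (default 2/3).
#' @return A list of class `expression_mixture`: `means`, `sds`,
#'   `proportions` (low component first), `cutoff`, `expressed` (logical
#'   per gene), `posterior_high`.
#' @export
fit_expression_mixture <- function(medians, posterior_cutoff = 2 / 3) {
  if (length(medians) < 50) stop("need at least 50 genes")
  # a second component must earn its keep: if one normal explains the
  # data better (BIC), there is no expressed/unexpressed structure
  bic <- mclust::mclustBIC(medians, G = 1:2, modelNames = "V",
                           verbose = FALSE)
  g_best <- as.integer(rownames(which(bic == max(bic, na.rm = TRUE),
                                      arr.ind = TRUE))[1])
  if (g_best < 2)
    stop("degenerate mixture: a single component fits best")
  fit <- mclust::Mclust(medians, G = 2, modelNames = "V", verbose = FALSE)
  if (is.null(fit)) stop("mixture fit failed")
  mu <- fit$parameters$mean
  pro <- fit$parameters$pro
  sd <- sqrt(fit$parameters$variance$sigmasq)
  if (length(sd) == 1) sd <- rep(sd, 2)
  pooled <- stats::sd(medians)
  if (min(pro) < 1e-3)
    stop("degenerate mixture: a component has vanishing weight")
  if (abs(diff(mu)) < 0.05 * pooled)
    stop("degenerate mixture: component means indistinguishable")
  hi <- which.max(mu); lo <- which.min(mu)
  post_high <- function(x) {
    num <- pro[hi] * stats::dnorm(x, mu[hi], sd[hi])
    den <- num + pro[lo] * stats::dnorm(x, mu[lo], sd[lo])
    num / den
  }
  grid <- sort(unique(c(medians,
                        seq(min(medians), max(medians), length.out = 2048))))
  pg <- post_high(grid)
  ok <- which(pg >= posterior_cutoff)
  if (!length(ok)) stop("no value reaches the posterior cutoff")
  cutoff <- grid[min(ok)]
  ph <- post_high(medians)
  structure(list(means = mu[c(lo, hi)], sds = sd[c(lo, hi)],
                 proportions = pro[c(lo, hi)], cutoff = cutoff,
                 expressed = ph >= posterior_cutoff, posterior_high = ph),
            class = "expression_mixture")
}

#' @export
print.expression_mixture <- function(x, ...) {
  cat(sprintf(
    "Two-normal expression mixture: means %.3f / %.3f, cutoff %.3f\n",
    x$means[1], x$means[2], x$cutoff))
  cat(sprintf("  %d / %d genes called expressed\n",
              sum(x$expressed), length(x$expressed)))
  invisible(x)
}

# REML log-likelihood of the intercept-only model y ~ 1 (no random effect),
# on the same scale as lme4's REML criterion (-2 logLik = REMLcrit).
null_reml_loglik <- function(y) {
  n <- length(y)
  rss <- sum((y - mean(y))^2)
  s2 <- rss / (n - 1)
  -0.5 * ((n - 1) * log(2 * pi * s2) + rss / s2 + log(n))
}

#' Partition trait variance into among- and within-line components
#'
#' Fits the random-effects model `value ~ (1 | line)` by REML (via
#' \pkg{lme4}), optionally with an additional between-replicate term
#' `(1 | line:replicate)` as used for bristle numbers, and tests the
#' among-line variance against zero with a likelihood-ratio test on the
#' boundary null `0.5 * chi2_0 + 0.5 * chi2_1`. Unbalanced designs are
#' allowed; negative component estimates are truncated at zero by REML
#' itself.
#'
#' @param panel A `trait_panel` data.frame (columns `line`, `value`,
#'   optionally `replicate`, `trait`, `sex`).
#' @param with_replicate_term Include the between-replicate (vial) random
#'   effect (default FALSE).
#' @return An object of class `varcomp`: `trait`, `sex`, `v_line`,
#'   `v_rep` (NA unless requested), `v_within`, `n_lines`, `n_obs`, `lrt`,
#'   `p_value`.
#' @export
partition_variance <- function(panel, with_replicate_term = FALSE) {
  d <- as.data.frame(panel)
  if (length(unique(d$line)) < 2) stop("need >= 2 lines")
  if (min(table(d$line)) < 2) stop("need >= 2 observations per line")
  if (stats::var(d$value) == 0) {
    fit <- NULL
    v_line <- 0; v_rep <- if (with_replicate_term) 0 else NA_real_
    v_within <- 0; lrt <- 0; p <- 1
  } else {
    form <- if (with_replicate_term)
      value ~ (1 | line) + (1 | line:replicate) else value ~ (1 | line)
    fit <- lme4::lmer(form, data = d, REML = TRUE,
                      control = lme4::lmerControl(check.conv.singular =
                                                    "ignore"))
    vc <- as.data.frame(lme4::VarCorr(fit))
    v_line <- vc$vcov[vc$grp == "line"]
    v_rep <- if (with_replicate_term)
      vc$vcov[vc$grp == "line:replicate"] else NA_real_
    v_within <- vc$vcov[vc$grp == "Residual"]
    # boundary LRT for v_line > 0
    ll_full <- as.numeric(stats::logLik(fit))
    ll_null <- if (with_replicate_term) {
      fit0 <- lme4::lmer(value ~ (1 | line:replicate), data = d, REML = TRUE,
                         control = lme4::lmerControl(check.conv.singular =
                                                       "ignore"))
      as.numeric(stats::logLik(fit0))
    } else null_reml_loglik(d$value)
    lrt <- max(0, 2 * (ll_full - ll_null))
    p <- if (lrt <= 0) 1 else 0.5 * stats::pchisq(lrt, df = 1,
                                                  lower.tail = FALSE)
  }
  structure(list(trait = d$trait[1] %||% NA, sex = d$sex[1] %||% NA,
                 v_line = v_line, v_rep = v_rep, v_within = v_within,
                 n_lines = length(unique(d$line)), n_obs = nrow(d),
                 lrt = lrt, p_value = p, fit = fit),
            class = "varcomp")
}

#' @export
print.varcomp <- function(x, ...) {
  cat(sprintf("Variance components (%s, %s): %d lines, %d obs\n",
              x$trait, x$sex, x$n_lines, x$n_obs))
  cat(sprintf("  among-line  V_line   = %.6g\n", x$v_line))
  if (!is.na(x$v_rep))
    cat(sprintf("  between-rep V_rep    = %.6g\n", x$v_rep))
  cat(sprintf("  within-line V_within = %.6g\n", x$v_within))
  cat(sprintf("  LRT(V_line > 0) = %.3f, p = %.4g\n", x$lrt, x$p_value))
  invisible(x)
}

#' Drift correction factor k linking V_MA to Vm
#'
#' The among-line variance accumulated by generation `t` under neutral
#' drift is `V_MA = k * Vm` with
#' `k = 2 * (t - (2Ne - 5) * (1 - exp(-t / (2Ne))))`:
#' new variance arises every generation but part of it is still
#' within-line while mutations segregate.
#'
#' @param t Generations since line founding (>= 1).
#' @param two_ne Haploid effective size (>= 2; default 21, the average of
#'   the X and autosomal fits).
#' @return The factor `k` (> 0). Vectorized.
#' @examples
#' k_factor(60, 21)  # ~89.84
#' @export
k_factor <- function(t, two_ne = 21) {
  if (any(t < 1)) stop("t must be >= 1")
  if (any(two_ne < 2)) stop("two_ne must be >= 2")
  2 * (t - (two_ne - 5) * (1 - exp(-t / two_ne)))
}

#' Mutational variance, environmental variance and heritability
#'
#' Converts among-/within-line components into the per-generation
#' mutational variance `Vm = V_line / k` and an environmental variance
#' appropriate to the assay: pooled-sample expression measurements use
#' `Ve = pool_n * V_within` (an upwardly biased Ve, hence conservative
#' heritability), individually measured sleep traits use `Ve = V_within`,
#' and bristle counts use `Ve = V_within + V_rep`.
#'
#' @param components A `varcomp` from [partition_variance()].
#' @param t Generations (default 60).
#' @param two_ne Haploid effective size for `k` (default 21).
#' @param pool_n Individuals pooled per measurement (expression mode).
#' @param mode One of `"expression"`, `"sleep"`, `"bristle"`.
#' @return A list of class `mutational_params`: `vm`, `ve`, `h2m`, `k`,
#'   `t`, `two_ne`, `pool_n`, `mode`.
#' @export
mutational_heritability <- function(components, t = 60, two_ne = 21,
                                    pool_n = 10,
                                    mode = c("expression", "sleep",
                                             "bristle")) {
  mode <- match.arg(mode)
  k <- k_factor(t, two_ne)
  vm <- components$v_line / k
  ve <- switch(mode,
    expression = pool_n * components$v_within,
    sleep = components$v_within,
    bristle = components$v_within +
      (if (is.na(components$v_rep)) 0 else components$v_rep))
  if (ve == 0) stop("environmental variance is zero: h2m undefined")
  structure(list(vm = vm, ve = ve, h2m = vm / ve, k = k, t = t,
                 two_ne = two_ne, pool_n = pool_n, mode = mode),
            class = "mutational_params")
}

#' @export
print.mutational_params <- function(x, ...) {
  cat(sprintf("Mutational parameters (%s mode): k = %.2f\n", x$mode, x$k))
  cat(sprintf("  Vm = %.6g, Ve = %.6g, h2m = %.6g\n", x$vm, x$ve, x$h2m))
  invisible(x)
}

#' Effective population size from neutral nucleotide diversity
#'
#' Inverts `pi = 4 N mu`: `N = pi / (4 mu)`.
#'
#' @param pi Pairwise nucleotide diversity.
#' @param mu Per-base per-generation mutation rate.
#' @return The effective population size `N`.
#' @examples
#' neutral_population_size(4.92e-3, 6.60e-9)  # ~186,364
#' @export
neutral_population_size <- function(pi, mu) {
  if (pi <= 0 || mu <= 0) stop("pi and mu must be positive")
  pi / (4 * mu)
}

#' Sum over loci of the sample variance of allele dosage
#'
#' Connects sequence variation to expected trait variance: for an inbred
#' panel, `Vg = E(a^2) * sum_i Var(g_i)` with `g_i` the mutant-allele
#' dosage (0..2) at locus i and `Var` the n-1 sample variance across
#' lines. In MA mode the sum is divided by the drift factor `k` and
#' augmented with mutations segregating below the detection cutoff, drawn
#' from the expected sampled-frequency distribution of a [expected_spectrum()]
#' fit: each undetected mutation is assigned to a random line with dosage
#' twice its drawn frequency.
#'
#' @param dosage Lines x loci matrix of dosages in `[0, 2]`.
#' @param k Optional drift divisor (MA mode).
#' @param below_cutoff_sampler Optional function `n -> n frequencies`
#'   (e.g. from [make_below_cutoff_sampler()]); used with `n_below`.
#' @param n_below Number of undetected mutations to augment (default: the
#'   expected number implied by the sampler's detection fractions when the
#'   sampler carries them, otherwise 0).
#' @param seed Optional seed for the augmentation draws.
#' @return The (possibly k-scaled) sum of per-locus dosage variances.
#' @export
sequence_variance_sum <- function(dosage, k = NULL,
                                  below_cutoff_sampler = NULL,
                                  n_below = NULL, seed = NULL) {
  if (is.null(dim(dosage))) dosage <- matrix(dosage, ncol = 1)
  if (nrow(dosage) < 2) stop("need at least 2 lines")
  if (any(dosage < 0 | dosage > 2)) stop("dosages must be in [0, 2]")
  s <- sum(apply(dosage, 2, stats::var))
  if (!is.null(below_cutoff_sampler)) {
    if (!is.null(seed)) set.seed(seed)
    if (is.null(n_below))
      n_below <- attr(below_cutoff_sampler, "n_below_default") %||% 0
    n_below <- round(n_below)
    if (n_below > 0) {
      fr <- below_cutoff_sampler(n_below)
      n <- nrow(dosage)
      # each undetected mutation: dosage 2f in one line, 0 elsewhere
      # sample variance of such a vector is (2f)^2 * (1 - 1/n) / (n - 1)
      s <- s + sum((2 * fr)^2 * (1 - 1 / n) / (n - 1))
    }
  }
  if (!is.null(k)) s <- s / k
  s
}

#' Sampler of sub-cutoff mutant frequencies from an expected spectrum
#'
#' Builds a draw function for the sampled frequencies of mutations that
#' segregate below the detection cutoff (but above zero), using the
#' `below` counts of a [expected_spectrum()] result. The attribute
#' `n_below_default`, the expected number of undetected segregating
#' mutations per detected mutation, is scaled by `n_detected`.
#'
#' @param spectrum A `wf_spectrum` from [expected_spectrum()].
#' @param n_detected Number of detected mutations in the data the sampler
#'   will augment.
#' @return A function `n -> n frequencies`, with attribute
#'   `n_below_default`.
#' @export
make_below_cutoff_sampler <- function(spectrum, n_detected) {
  counts <- spectrum$below
  ks <- seq_along(counts)                     # sampled counts 1..thr
  freqs <- ks / spectrum$sample_n
  probs <- counts / sum(counts)
  f <- function(n) sample(freqs, n, replace = TRUE, prob = probs)
  attr(f, "n_below_default") <- n_detected * spectrum$p_below / spectrum$p
  f
}

#' Mutation-selection balance report for a trait
#'
#' Assembles the comparison of mutational to standing variance: the ratio
#' `Vm/Vg`; its neutral expectation `1/(4N)`; the sequence-based neutral
#' ratio `sum Var(m_i)/k / sum Var(g_i)` expected if mutational and
#' standing allelic effects were equal; the effect-size ratio
#' `E(a_m^2)/E(a_g^2)` implied by the two (their quotient, exactly); the
#' selection coefficient `s = Vm/Vg` of the simple pleiotropic model; and
#' the house-of-cards locus number `n = Vg / (4 mu Vs)` with
#' `Vs = Vs_multiplier * Ve`.
#'
#' @param vm,vg Mutational and standing variance of the trait.
#' @param sum_var_m_over_k Sequence variance sum of MA mutations, already
#'   divided by k (see [sequence_variance_sum()]).
#' @param sum_var_g Sequence variance sum of the inbred panel.
#' @param n_pop Effective size of the natural population.
#' @param mu Per-base per-generation mutation rate.
#' @param ve Environmental variance of the trait.
#' @param vs_multiplier Strength of stabilizing selection as a multiple of
#'   `Ve` (default 20).
#' @return A list of class `selection_report`.
#' @export
selection_report <- function(vm, vg, sum_var_m_over_k, sum_var_g, n_pop,
                             mu, ve, vs_multiplier = 20) {
  if (any(c(vm, vg, sum_var_m_over_k, sum_var_g, n_pop, mu, ve) <= 0))
    stop("all inputs must be positive")
  vm_vg <- vm / vg
  seq_ratio <- sum_var_m_over_k / sum_var_g
  vs <- vs_multiplier * ve
  structure(list(
    vm = vm, vg = vg, vm_vg = vm_vg,
    neutral_expectation = 1 / (4 * n_pop),
    sequence_ratio = seq_ratio,
    effect_size_ratio = vm_vg / seq_ratio,
    s_pleiotropic = vm_vg,
    vs = vs,
    hoc_n_loci = vg / (4 * mu * vs)
  ), class = "selection_report")
}

#' @export
print.selection_report <- function(x, ...) {
  cat("Mutation-selection balance report\n")
  cat(sprintf("  Vm/Vg                 = %.4g\n", x$vm_vg))
  cat(sprintf("  neutral 1/(4N)        = %.4g\n", x$neutral_expectation))
  cat(sprintf("  sequence-based ratio  = %.4g\n", x$sequence_ratio))
  cat(sprintf("  E(am^2)/E(ag^2)       = %.4g\n", x$effect_size_ratio))
  cat(sprintf("  pleiotropic s         = %.4g\n", x$s_pleiotropic))
  cat(sprintf("  house-of-cards n      = %.4g\n", x$hoc_n_loci))
  invisible(x)
}

#' Benjamini-Hochberg false-discovery-rate adjustment
#'
#' Step-up adjusted q-values; `q >= p` and the adjustment is monotone.
#'
#' @param p P-values in `[0, 1]`.
#' @return Q-values.
#' @export
fdr_adjust <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p-values must be in [0, 1]")
  stats::p.adjust(p, method = "BH")
}
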