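# Synthetic-data generator: MA-line mutation histories under drift, pileup
# read counts, and trait panels with known ground truth.

#' Simulate mutation accumulation lines under neutral drift
#'
#' Each line is propagated for `t` generations at haploid effective size
#' `two_ne` (or `two_ne_x` for X-linked sites). Every generation,
#' `Poisson(two_ne * mu * B)` new mutations arise, each at a single copy,
#' and every segregating mutation is resampled binomially (Wright-Fisher).
#' Setting `one_per_generation = TRUE` reproduces the calibration design
#' used for the 2Ne likelihood (exactly one new mutation per line per
#' generation, positions still drawn from the genome). Mutations arising at
#' an already-mutated position within a line are re-drawn (infinite-sites).
#'
#' @param genome An `ma_genome` from [generate_genome()].
#' @param n_lines Number of MA lines.
#' @param t Generations of accumulation (default 60).
#' @param mu Per-base per-generation mutation rate.
#' @param two_ne Haploid effective size for autosomal sites (default 23).
#' @param two_ne_x Haploid effective size for X-linked sites (default:
#'   `two_ne`).
#' @param seed Optional integer seed.
#' @param one_per_generation If TRUE, ignore `mu` and introduce exactly one
#'   mutation per line per generation.
#' @return An object of class `ma_truth`: list with `mutations` (data.frame:
#'   `line_id`, `position` (global 1-based), `chrom`, `pos` (within-chrom),
#'   `ancestral`, `mutant`, `origin_gen`, `final_count`, `final_freq`,
#'   `two_ne`), `trajectories` (list of per-generation copy counts, from the
#'   origin generation to `t`), and `params`.
#' @examples
#' g <- generate_genome(1e4, seed = 1)
#' tr <- simulate_ma_lines(g, n_lines = 5, t = 60, mu = 1e-6, seed = 2)
#' @export
simulate_ma_lines <- function(genome, n_lines, t = 60, mu, two_ne = 23,
                              two_ne_x = two_ne, seed = NULL,
                              one_per_generation = FALSE) {
  if (two_ne < 2 || two_ne_x < 2) stop("two_ne must be >= 2")
  if (mu < 0) stop("mu must be nonnegative")
  if (!is.null(seed)) set.seed(seed)
  B <- genome$length
  rows <- list()
  trajs <- list()
  k <- 0
  for (line in seq_len(n_lines)) {
    line_id <- sprintf("MA%02d", line)
    used <- integer(0)
    # active mutations in this line: position, origin, current count, 2Ne
    act_pos <- integer(0); act_gen <- integer(0); act_cnt <- integer(0)
    act_ne <- integer(0); act_traj <- list()
    for (g in seq_len(t)) {
      # drift update for mutations that arose before this generation
      seg <- act_cnt > 0L & act_cnt < act_ne
      if (any(seg))
        act_cnt[seg] <- stats::rbinom(sum(seg), act_ne[seg],
                                      act_cnt[seg] / act_ne[seg])
      if (length(act_traj))
        act_traj <- lapply(seq_along(act_traj), function(i)
          c(act_traj[[i]], act_cnt[i]))
      # new mutations this generation
      n_new <- if (one_per_generation) 1L
               else stats::rpois(1, two_ne * mu * B)
      if (n_new > 0) {
        pos <- sample.int(B, n_new, replace = TRUE)
        while (any(dup <- duplicated(pos) | pos %in% used))
          pos[dup] <- sample.int(B, sum(dup), replace = TRUE)
        used <- c(used, pos)
        ne_new <- ifelse(pos <= genome$x_boundary, two_ne_x, two_ne)
        act_pos <- c(act_pos, pos)
        act_gen <- c(act_gen, rep.int(g, n_new))
        act_cnt <- c(act_cnt, rep.int(1L, n_new))
        act_ne <- c(act_ne, as.integer(ne_new))
        act_traj <- c(act_traj, lapply(seq_len(n_new), function(i) 1L))
      }
    }
    if (length(act_pos)) {
      anc <- bases_at(genome, act_pos)
      mut <- vapply(anc, function(a)
        sample(setdiff(c("A", "C", "G", "T"), a), 1), "")
      rows[[length(rows) + 1]] <- data.frame(
        line_id = line_id, position = act_pos,
        chrom = chrom_of(genome, act_pos),
        pos = pos_in_chrom(genome, act_pos),
        ancestral = anc, mutant = unname(mut), origin_gen = act_gen,
        final_count = act_cnt, final_freq = act_cnt / act_ne,
        two_ne = act_ne, row.names = NULL)
      trajs <- c(trajs, act_traj)
    }
  }
  mutations <- if (length(rows)) do.call(rbind, rows) else
    data.frame(line_id = character(0), position = integer(0),
               chrom = character(0), pos = integer(0),
               ancestral = character(0), mutant = character(0),
               origin_gen = integer(0), final_count = integer(0),
               final_freq = numeric(0), two_ne = integer(0))
  structure(list(mutations = mutations, trajectories = trajs,
                 params = list(n_lines = n_lines, t = t, mu = mu,
                               two_ne = two_ne, two_ne_x = two_ne_x,
                               B = B, seed = seed)),
            class = "ma_truth")
}

#' @export
print.ma_truth <- function(x, ...) {
  cat(sprintf(
    "MA-line truth: %d lines, t = %d, %d mutations (%d segregating, %d fixed)\n",
    x$params$n_lines, x$params$t, nrow(x$mutations),
    sum(x$mutations$final_freq > 0 & x$mutations$final_freq < 1),
    sum(x$mutations$final_freq == 1)))
  invisible(x)
}

# truncated-Poisson depths via rejection (bounds are wide; acceptance ~1)
rtrunc_pois <- function(n, lambda, lo, hi) {
  d <- stats::rpois(n, lambda)
  bad <- d < lo | d > hi
  while (any(bad)) {
    d[bad] <- stats::rpois(sum(bad), lambda)
    bad <- d < lo | d > hi
  }
  d
}

#' Render per-site, per-line pileup read counts
#'
#' Emulates the allele-count tables produced by piling up aligned reads.
#' For every line (including the parental line, which carries no mutations)
#' and every site, total depth is Poisson(`mean_depth`) truncated to
#' `depth_bounds`; reads supporting the line's mutant allele are
#' `Binomial(depth, line frequency)`; each remaining read is independently
#' converted to a uniformly chosen alternate allele with probability
#' `error_rate`; every allele's reads are split across the two strands
#' `Binomial(count, 0.5)`.
#'
#' @param genome An `ma_genome`.
#' @param truth An `ma_truth` from [simulate_ma_lines()].
#' @param mean_depth Mean sequencing depth (> 0; default 30).
#' @param depth_bounds Length-2 inclusive truncation bounds (default
#'   `c(15, 250)`).
#' @param error_rate Per-read error probability in `[0, 0.01)`.
#' @param seed Optional integer seed.
#' @param parental_id Label of the parental line (default `"P0"`).
#' @param sites Optional integer vector of global positions to render
#'   (default: every genome position).
#' @return A `data.table` of class `pileup_table` with columns `chrom`,
#'   `pos` (1-based within chromosome), `line_id`, `allele`, `strand`
#'   (`+`/`-`), `count`; only nonzero counts are stored. The parental line
#'   id is attached as attribute `parental`.
#' @export
render_pileups <- function(genome, truth, mean_depth = 30,
                           depth_bounds = c(15, 250), error_rate = 1e-3,
                           seed = NULL, parental_id = "P0", sites = NULL) {
  if (mean_depth <= 0) stop("mean_depth must be positive")
  if (depth_bounds[1] > depth_bounds[2]) stop("depth bounds inverted")
  if (error_rate < 0 || error_rate >= 0.01)
    stop("error_rate must be in [0, 0.01)")
  if (!is.null(seed)) set.seed(seed)
  if (is.null(sites)) sites <- seq_len(genome$length)
  sites <- sort(unique(as.integer(sites)))
  ns <- length(sites)
  anc <- bases_at(genome, sites)
  site_chrom <- chrom_of(genome, sites)
  site_pos <- pos_in_chrom(genome, sites)
  lines <- c(parental_id,
             sprintf("MA%02d", seq_len(truth$params$n_lines)))
  ALL <- c("A", "C", "G", "T")
  out <- vector("list", length(lines))
  mut <- truth$mutations
  for (li in seq_along(lines)) {
    id <- lines[li]
    depth <- rtrunc_pois(ns, mean_depth, depth_bounds[1], depth_bounds[2])
    # mutant reads at this line's mutated sites
    mut_reads <- integer(ns)
    mut_allele <- character(ns)
    if (id != parental_id) {
      ml <- mut[mut$line_id == id & mut$final_freq > 0, ]
      if (nrow(ml)) {
        idx <- match(ml$position, sites)
        keep <- !is.na(idx)
        if (any(keep)) {
          idx <- idx[keep]
          mut_reads[idx] <- stats::rbinom(length(idx), depth[idx],
                                          ml$final_freq[keep])
          mut_allele[idx] <- ml$mutant[keep]
        }
      }
    }
    anc_reads <- depth - mut_reads
    # sequencing errors among the ancestral-allele reads
    err <- if (error_rate > 0) stats::rbinom(ns, anc_reads, error_rate)
           else integer(ns)
    anc_reads <- anc_reads - err
    # assemble long-format rows for this line
    pieces <- list(data.frame(si = seq_len(ns), allele = anc,
                              count = anc_reads))
    has_mut <- mut_reads > 0
    if (any(has_mut))
      pieces <- c(pieces, list(data.frame(si = which(has_mut),
                                          allele = mut_allele[has_mut],
                                          count = mut_reads[has_mut])))
    has_err <- which(err > 0)
    if (length(has_err)) {
      # each error read gets a uniform alternate allele
      esite <- rep.int(has_err, err[has_err])
      ealt <- vapply(anc[esite], function(a)
        sample(setdiff(ALL, a), 1), "")
      et <- data.table::data.table(si = esite, allele = unname(ealt))
      et <- et[, list(count = .N), by = c("si", "allele")]
      pieces <- c(pieces, list(as.data.frame(et)))
    }
    dd <- data.table::rbindlist(pieces)
    dd <- dd[dd$count > 0, ]
    # strand split
    plus <- stats::rbinom(nrow(dd), dd$count, 0.5)
    dd2 <- data.table::data.table(
      si = rep(dd$si, 2), allele = rep(dd$allele, 2),
      strand = rep(c("+", "-"), each = nrow(dd)),
      count = c(plus, dd$count - plus))
    dd2 <- dd2[dd2$count > 0, ]
    dd2[, `:=`(chrom = site_chrom[si], pos = site_pos[si], line_id = id)]
    out[[li]] <- dd2[, c("chrom", "pos", "line_id", "allele", "strand",
                         "count"), with = FALSE]
  }
  res <- data.table::rbindlist(out)
  data.table::setkeyv(res, c("chrom", "pos", "line_id"))
  data.table::setattr(res, "parental", parental_id)
  data.table::setattr(res, "class",
                      c("pileup_table", class(res)))
  res
}

#' Simulate a balanced MA trait panel
#'
#' Line-structured quantitative-trait measurements: each value is a line
#' effect `N(0, v_line)` plus an independent residual `N(0, v_within)`,
#' optionally shifted by `mean`. Pools of `pool_n` individuals per measured
#' sample are recorded so the environmental variance can be recovered from
#' the within-line variance of pooled measurements.
#'
#' @param n_lines Number of lines (>= 2).
#' @param reps_per_line Replicates per line (>= 2).
#' @param v_line Among-line variance (>= 0).
#' @param v_within Within-line (residual) variance (>= 0).
#' @param pool_n Individuals pooled per measurement (default 10).
#' @param trait,sex Labels for the panel.
#' @param mean Grand mean (default 0).
#' @param seed Optional integer seed.
#' @return A data.frame of class `trait_panel` with columns `trait`, `sex`,
#'   `line`, `replicate`, `value`; `pool_n` is attached as an attribute.
#' @export
simulate_trait_panel <- function(n_lines, reps_per_line, v_line, v_within,
                                 pool_n = 10, trait = "trait", sex = "female",
                                 mean = 0, seed = NULL) {
  if (n_lines < 2 || reps_per_line < 2)
    stop("need >= 2 lines with >= 2 observations each")
  if (v_line < 0 || v_within < 0) stop("variances must be nonnegative")
  if (!is.null(seed)) set.seed(seed)
  line_eff <- stats::rnorm(n_lines, 0, sqrt(v_line))
  d <- data.frame(
    trait = trait, sex = sex,
    line = rep(sprintf("L%03d", seq_len(n_lines)), each = reps_per_line),
    replicate = rep(seq_len(reps_per_line), n_lines),
    value = mean + rep(line_eff, each = reps_per_line) +
      stats::rnorm(n_lines * reps_per_line, 0, sqrt(v_within)))
  attr(d, "pool_n") <- pool_n
  class(d) <- c("trait_panel", "data.frame")
  d
}

#' Simulate an inbred (DGRP-like) panel with genotyped loci
#'
#' Each of `n_loci` biallelic loci has a population mutant-allele frequency
#' from `allele_freqs`; inbred lines carry dosage 0 or 2 (homozygous) with
#' probability equal to that frequency. Locus effects are
#' `a_i ~ N(0, effect_var)`; a line's genetic value is `sum(a_i * g_i)` and
#' measurements add residual `N(0, v_within)`. The realized among-line
#' genetic variance converges to `effect_var * sum(Var(g_i))` as loci grow.
#'
#' @param n_lines Number of inbred lines (>= 2).
#' @param n_loci Number of loci.
#' @param allele_freqs Mutant-allele frequency per locus (recycled), in
#'   (0, 1).
#' @param effect_var Variance of locus allelic effects (>= 0).
#' @param v_within Residual variance.
#' @param reps_per_line Replicates per line (default 2).
#' @param pool_n,trait,sex,seed As [simulate_trait_panel()].
#' @return A list with `panel` (a `trait_panel`) and `dosage` (an
#'   `n_lines x n_loci` matrix of 0/2 dosages) and `effects`.
#' @export
simulate_inbred_panel <- function(n_lines, n_loci, allele_freqs, effect_var,
                                  v_within, reps_per_line = 2, pool_n = 1,
                                  trait = "trait", sex = "female", seed = NULL) {
  if (any(allele_freqs <= 0) || any(allele_freqs >= 1))
    stop("allele_freqs must be in (0, 1)")
  if (!is.null(seed)) set.seed(seed)
  freqs <- rep_len(allele_freqs, n_loci)
  dosage <- matrix(2 * stats::rbinom(n_lines * n_loci, 1,
                                     rep(freqs, each = n_lines)),
                   nrow = n_lines)
  rownames(dosage) <- sprintf("L%03d", seq_len(n_lines))
  effects <- stats::rnorm(n_loci, 0, sqrt(effect_var))
  gvalue <- as.vector(dosage %*% effects)
  d <- data.frame(
    trait = trait, sex = sex,
    line = rep(rownames(dosage), each = reps_per_line),
    replicate = rep(seq_len(reps_per_line), n_lines),
    value = rep(gvalue, each = reps_per_line) +
      stats::rnorm(n_lines * reps_per_line, 0, sqrt(v_within)))
  attr(d, "pool_n") <- pool_n
  class(d) <- c("trait_panel", "data.frame")
  list(panel = d, dosage = dosage, effects = effects)
}
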