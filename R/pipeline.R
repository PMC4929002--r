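# End-to-end orchestration: simulate -> pileup -> call -> infer 2Ne ->
# mutation rate -> trait variance -> selection report, from a single
# validated config with derived per-stage seeds and a run manifest.

config_schema <- function() {
  list(
    version = "integer", seed = "integer",
    genome = list(length = "integer", gc = "numeric",
                  x_fraction = "numeric"),
    ma = list(n_lines = "integer", t = "integer", two_ne = "integer",
              mu = "numeric"),
    pileup = list(mean_depth = "numeric", depth_min = "integer",
                  depth_max = "integer", error_rate = "numeric"),
    calling = list(freq_cutoff = "numeric", leak_freq = "numeric",
                   max_leak_lines = "integer", strand_p = "numeric"),
    inference = list(grid_min = "integer", grid_max = "integer",
                     reps = "numeric", sample_n = "integer"),
    traits = list(n_lines = "integer", reps_per_line = "integer",
                  v_line = "numeric", v_within = "numeric",
                  pool_n = "integer", mode = "character"),
    selection = list(pi = "numeric", vs_multiplier = "numeric",
                     dgrp_n_lines = "integer", dgrp_n_loci = "integer",
                     dgrp_effect_var = "numeric",
                     dgrp_v_within = "numeric")
  )
}

#' Default pipeline configuration
#'
#' A small desk-scale demonstration configuration mirroring the MA design:
#' 23 sequenced lines, 60 generations, 2Ne = 23, depth 30. The genome and
#' mutation rate are scaled so that a full run finishes in seconds; scale
#' `genome$length` up (and `ma$mu` down) for larger experiments.
#'
#' @param seed Master seed (default 1).
#' @return A nested config list (see [run_pipeline()]).
#' @export
default_config <- function(seed = 1) {
  list(
    version = 1L, seed = as.integer(seed),
    genome = list(length = 20000L, gc = 0.4248, x_fraction = 0.2),
    ma = list(n_lines = 23L, t = 60L, two_ne = 23L, mu = 2e-6),
    pileup = list(mean_depth = 30, depth_min = 15L, depth_max = 250L,
                  error_rate = 1e-3),
    calling = list(freq_cutoff = 0.2, leak_freq = 0.05,
                   max_leak_lines = 2L, strand_p = 0.001),
    inference = list(grid_min = 10L, grid_max = 40L, reps = 1e5,
                     sample_n = 200L),
    traits = list(n_lines = 23L, reps_per_line = 2L, v_line = 1,
                  v_within = 1, pool_n = 10L, mode = "expression"),
    selection = list(pi = 4.92e-3, vs_multiplier = 20,
                     dgrp_n_lines = 40L, dgrp_n_loci = 200L,
                     dgrp_effect_var = 0.01, dgrp_v_within = 1)
  )
}

validate_config <- function(config, schema = config_schema(), path = "") {
  if (!is.list(config)) stop(sprintf("config%s must be a mapping", path))
  unknown <- setdiff(names(config), names(schema))
  if (length(unknown))
    stop(sprintf("unknown config key%s: %s",
                 if (length(unknown) > 1) "s" else "",
                 paste0(path, ".", unknown, collapse = ", ")))
  missing <- setdiff(names(schema), names(config))
  if (length(missing))
    stop(sprintf("missing config key(s): %s",
                 paste0(path, ".", missing, collapse = ", ")))
  for (nm in names(schema)) {
    here <- paste0(path, ".", nm)
    if (is.list(schema[[nm]])) {
      validate_config(config[[nm]], schema[[nm]], here)
    } else {
      v <- config[[nm]]
      if (!is.numeric(v) && !is.character(v))
        stop(sprintf("config field %s has invalid type", here))
    }
  }
  if (config$version %||% 0 != 1 && path == "")
    stop("unsupported config version (expected 1)")
  invisible(TRUE)
}

check_config_values <- function(cfg) {
  if (cfg$ma$t < 1) stop("invalid config field .ma.t: must be >= 1")
  if (cfg$ma$two_ne < 2) stop("invalid config field .ma.two_ne: must be >= 2")
  if (cfg$genome$length < 1000)
    stop("invalid config field .genome.length: must be >= 1000")
  if (cfg$pileup$depth_min > cfg$pileup$depth_max)
    stop("invalid config field .pileup: depth bounds inverted")
  invisible(TRUE)
}

#' Read and validate a pipeline config file (YAML)
#'
#' Unknown keys are errors, not warnings, so threshold typos cannot pass
#' silently; every field is required (start from [default_config()] and
#' edit).
#'
#' @param path YAML config path.
#' @return The validated config list.
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  validate_config(cfg)
  check_config_values(cfg)
  cfg
}

#' Write a config list as YAML
#' @param config Config list.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_run_config <- function(config, path) {
  yaml::write_yaml(config, path)
  invisible(path)
}

config_digest <- function(cfg) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(yaml::as.yaml(cfg), tmp)
  unname(tools::md5sum(tmp))
}

stage_log <- function(run_dir, stage, seed, files, t0, quiet) {
  elapsed <- as.numeric(Sys.time()) - t0
  digests <- unname(tools::md5sum(files))
  if (!quiet)
    message(sprintf("[madrift] stage=%s seed=%s elapsed=%.2fs files=%s",
                    stage, seed, elapsed,
                    paste(basename(files), collapse = ",")))
  list(stage = stage, seed = seed, elapsed_s = elapsed,
       files = as.list(stats::setNames(digests, basename(files))))
}

#' Run the full MA analysis pipeline
#'
#' Executes simulate (genome + mutation histories), pileup rendering,
#' mutation calling, 2Ne inference per chromosome class, per-line mutation
#' rates, trait-panel variance partitioning, and the selection report, in
#' order, writing every interchange file (FASTA, VCF, TSV, JSON) plus a
#' manifest to `run_dir`. Per-stage seeds are derived deterministically
#' from the master seed, so the same config reproduces identical outputs;
#' a completed run directory is not recomputed unless `force = TRUE`.
#'
#' @param config A config list ([default_config()]) or a YAML path.
#' @param run_dir Output directory (created if needed).
#' @param force Re-run even if a manifest for the same config exists.
#' @param quiet Suppress per-stage log lines.
#' @return The run manifest (list), invisibly written as
#'   `manifest.json`.
#' @export
run_pipeline <- function(config = default_config(), run_dir, force = FALSE,
                         quiet = FALSE) {
  cfg <- if (is.character(config)) read_run_config(config) else config
  validate_config(cfg)
  check_config_values(cfg)
  dir.create(run_dir, showWarnings = FALSE, recursive = TRUE)
  digest <- config_digest(cfg)
  man_path <- file.path(run_dir, "manifest.json")
  if (!force && file.exists(man_path)) {
    old <- jsonlite::read_json(man_path)
    if (identical(old$config_digest, digest)) {
      if (!quiet) message("[madrift] run up to date; use force = TRUE")
      return(invisible(old))
    }
  }
  seeds <- cfg$seed + 1000L * seq_len(8)   # per-stage derived seeds
  stages <- list()
  atomic <- function(write_fun, path) {
    tmp <- paste0(path, ".tmp")
    write_fun(tmp)
    file.rename(tmp, path)
    path
  }

  # stage 1: simulate genome + truth
  t0 <- as.numeric(Sys.time())
  genome <- generate_genome(cfg$genome$length, cfg$genome$gc,
                            cfg$genome$x_fraction, seed = seeds[1])
  truth <- simulate_ma_lines(genome, cfg$ma$n_lines, cfg$ma$t, cfg$ma$mu,
                             cfg$ma$two_ne, seed = seeds[2])
  fa <- file.path(run_dir, "genome.fasta")
  write_genome_fasta(genome, fa)
  tv <- file.path(run_dir, "truth.vcf")
  write_truth_vcf(truth, tv)
  stages$simulate <- stage_log(run_dir, "simulate", seeds[1], c(fa, tv),
                               t0, quiet)

  # stage 2: pileups
  t0 <- as.numeric(Sys.time())
  pile <- render_pileups(genome, truth, cfg$pileup$mean_depth,
                         c(cfg$pileup$depth_min, cfg$pileup$depth_max),
                         cfg$pileup$error_rate, seed = seeds[3])
  pv <- file.path(run_dir, "pileups.tsv")
  atomic(function(p) write_pileup_tsv(pile, p), pv)
  stages$pileup <- stage_log(run_dir, "pileup", seeds[3], pv, t0, quiet)

  # stage 3: mutation calling
  t0 <- as.numeric(Sys.time())
  elig <- eligible_sites(pile, c(cfg$pileup$depth_min,
                                 cfg$pileup$depth_max))
  calls <- call_mutations(pile, cfg$calling$freq_cutoff,
                          cfg$calling$leak_freq,
                          cfg$calling$max_leak_lines,
                          cfg$calling$strand_p, eligible = elig)
  calls$position <- global_pos(genome, calls$chrom, calls$pos)
  cv <- file.path(run_dir, "calls.vcf")
  atomic(function(p) write_calls_vcf(calls, p), cv)
  spec_sum <- spectrum_summary(calls, genome_gc(genome))
  sv <- file.path(run_dir, "spectrum_summary.tsv")
  atomic(function(p) utils::write.table(data.frame(
    metric = c(names(spec_sum$class_counts), "Ti", "Tv", "TiTv_norm",
               "n_GC", "n_AT", "GC_fold_bias"),
    value = c(as.numeric(spec_sum$class_counts), spec_sum$ti, spec_sum$tv,
              spec_sum$titv_ratio, spec_sum$n_gc, spec_sum$n_at,
              spec_sum$gc_fold_bias)),
    p, sep = "\t", row.names = FALSE, quote = FALSE), sv)
  stages$call <- stage_log(run_dir, "call", seeds[3], c(cv, sv), t0, quiet)

  # stage 4: 2Ne inference (pooled over lines, per chromosome class)
  t0 <- as.numeric(Sys.time())
  grid <- cfg$inference$grid_min:cfg$inference$grid_max
  fits <- list()
  for (cl in c("A", "X")) {
    fr <- calls$freq[calls$chrom == cl & calls$freq > 0.2 &
                       calls$freq <= 1]
    if (length(fr) >= 1) {
      sp <- bin_spectrum(fr)
      fits[[cl]] <- estimate_ne(sp, grid = grid, t = cfg$ma$t,
                                reps = cfg$inference$reps,
                                sample_n = cfg$inference$sample_n,
                                seed = seeds[4])
      atomic(function(p) write_ne_fit(fits[[cl]], p),
             file.path(run_dir, sprintf("nefit_%s.json", cl)))
    }
  }
  if (!length(fits)) stop("stage infer-ne: no mutations above the cutoff")
  nf <- file.path(run_dir, paste0("nefit_", names(fits), ".json"))
  stages$infer_ne <- stage_log(run_dir, "infer-ne", seeds[4], nf, t0, quiet)

  # stage 5: per-line mutation rates (pooled 2Ne across classes)
  t0 <- as.numeric(Sys.time())
  main <- fits[[if ("A" %in% names(fits)) "A" else 1L]]
  per_line <- table(factor(calls$line_id,
                           levels = sprintf("MA%02d",
                                            seq_len(cfg$ma$n_lines))))
  # callable bases per line: eligible sites (identical across lines here)
  B <- nrow(elig)
  rates <- estimate_mutation_rate(as.integer(per_line), cfg$ma$t,
                                  main$two_ne, main$p_ml, B,
                                  line_id = names(per_line))
  rv <- file.path(run_dir, "rates.tsv")
  atomic(function(p) utils::write.table(rates, p, sep = "\t",
                                        row.names = FALSE, quote = FALSE),
         rv)
  stages$mu <- stage_log(run_dir, "mu", seeds[4], rv, t0, quiet)

  # stage 6: trait panel + variance components
  t0 <- as.numeric(Sys.time())
  panel <- simulate_trait_panel(cfg$traits$n_lines, cfg$traits$reps_per_line,
                                cfg$traits$v_line, cfg$traits$v_within,
                                cfg$traits$pool_n, seed = seeds[5])
  pv2 <- file.path(run_dir, "traits.tsv")
  atomic(function(p) write_trait_tsv(panel, p), pv2)
  vc <- partition_variance(panel)
  mp <- mutational_heritability(vc, t = cfg$ma$t, two_ne = main$two_ne,
                                pool_n = cfg$traits$pool_n,
                                mode = cfg$traits$mode)
  vcv <- file.path(run_dir, "varcomp.tsv")
  atomic(function(p) utils::write.table(data.frame(
    trait = vc$trait, sex = vc$sex, v_line = vc$v_line,
    v_within = vc$v_within, p_value = vc$p_value, k = mp$k, vm = mp$vm,
    ve = mp$ve, h2m = mp$h2m), p, sep = "\t", row.names = FALSE,
    quote = FALSE), vcv)
  stages$quantgen <- stage_log(run_dir, "quantgen", seeds[5],
                               c(pv2, vcv), t0, quiet)

  # stage 7: selection report
  t0 <- as.numeric(Sys.time())
  mu_hat <- stats::median(rates$mu[rates$m > 0])
  n_pop <- neutral_population_size(cfg$selection$pi, mu_hat)
  # DGRP-like inbred panel: standing trait variance + genotyped dosages
  dg <- simulate_inbred_panel(cfg$selection$dgrp_n_lines,
                              cfg$selection$dgrp_n_loci,
                              allele_freqs = stats::runif(
                                cfg$selection$dgrp_n_loci, 0.05, 0.95),
                              effect_var = cfg$selection$dgrp_effect_var,
                              v_within = cfg$selection$dgrp_v_within,
                              seed = seeds[6])
  vc_dg <- partition_variance(dg$panel)
  sum_var_g <- sequence_variance_sum(dg$dosage)
  # MA dosages: 2 x line frequency per called mutation, augmented with
  # sub-cutoff mutations drawn from the expected sampled-freq distribution
  ma_sp <- expected_spectrum(main$two_ne, t = cfg$ma$t,
                             reps = min(cfg$inference$reps, 1e5),
                             sample_n = cfg$inference$sample_n,
                             seed = seeds[7])
  line_levels <- sprintf("MA%02d", seq_len(cfg$ma$n_lines))
  ma_dosage <- matrix(0, nrow = length(line_levels), ncol = nrow(calls),
                      dimnames = list(line_levels, NULL))
  if (nrow(calls))
    ma_dosage[cbind(match(calls$line_id, line_levels),
                    seq_len(nrow(calls)))] <- 2 * calls$freq
  sampler <- make_below_cutoff_sampler(ma_sp, n_detected = nrow(calls))
  kf <- k_factor(cfg$ma$t, main$two_ne)
  sum_var_m_over_k <- sequence_variance_sum(ma_dosage, k = kf,
                                            below_cutoff_sampler = sampler,
                                            seed = seeds[8])
  sel <- selection_report(vm = mp$vm, vg = max(vc_dg$v_line, 1e-12),
                          sum_var_m_over_k = sum_var_m_over_k,
                          sum_var_g = sum_var_g,
                          n_pop = n_pop, mu = mu_hat, ve = mp$ve,
                          vs_multiplier = cfg$selection$vs_multiplier)
  sev <- file.path(run_dir, "selection.tsv")
  atomic(function(p) utils::write.table(data.frame(
    vm_vg = sel$vm_vg, neutral = sel$neutral_expectation,
    sequence_ratio = sel$sequence_ratio,
    effect_ratio = sel$effect_size_ratio, s = sel$s_pleiotropic,
    hoc_n = sel$hoc_n_loci, N = n_pop, mu = mu_hat),
    p, sep = "\t", row.names = FALSE, quote = FALSE), sev)
  stages$selection <- stage_log(run_dir, "selection", seeds[6], sev, t0,
                                quiet)

  manifest <- list(config = cfg, config_digest = digest,
                   created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"),
                   stages = stages)
  jsonlite::write_json(manifest, man_path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(manifest)
}

#' Summarize a completed pipeline run
#'
#' Reads the interchange files of a run directory back and tabulates the
#' per-line mutation-rate estimates, the ML 2Ne per chromosome class, the
#' spectrum summary, and the variance-component/heritability and selection
#' tables; optionally overlays the generator's ground truth.
#'
#' @param run_dir A directory produced by [run_pipeline()].
#' @param truth_overlay Include true-vs-estimated comparisons from
#'   `truth.vcf` (default TRUE when present).
#' @return A list of class `run_report` with elements `rates`, `ne`,
#'   `spectrum`, `varcomp`, `selection`, and optionally `truth`;
#'   incomplete runs yield the available tables with a warning.
#' @export
summarize_run <- function(run_dir, truth_overlay = TRUE) {
  grab_tsv <- function(f) {
    p <- file.path(run_dir, f)
    if (file.exists(p))
      as.data.frame(data.table::fread(p, sep = "\t")) else NULL
  }
  rep <- list()
  rep$rates <- grab_tsv("rates.tsv")
  rep$spectrum <- grab_tsv("spectrum_summary.tsv")
  rep$varcomp <- grab_tsv("varcomp.tsv")
  rep$selection <- grab_tsv("selection.tsv")
  ne <- list()
  for (cl in c("A", "X")) {
    p <- file.path(run_dir, sprintf("nefit_%s.json", cl))
    if (file.exists(p)) {
      fit <- read_ne_fit(p)
      ne[[cl]] <- data.frame(chrom_class = cl, two_ne = fit$two_ne,
                             p = fit$p_ml, n_mutations = fit$spectrum$total)
    }
  }
  rep$ne <- if (length(ne)) do.call(rbind, ne) else NULL
  tp <- file.path(run_dir, "truth.vcf")
  if (truth_overlay && file.exists(tp) && !is.null(rep$rates)) {
    truth <- read_calls_vcf(tp)
    seg <- truth[truth$freq > 0, ]
    rep$truth <- data.frame(
      true_mutations = nrow(truth),
      surviving = nrow(seg),
      detected = sum(rep$rates$m),
      true_high_freq = sum(truth$freq > 0.2))
  }
  missing <- names(Filter(is.null,
                          rep[c("rates", "spectrum", "varcomp",
                                "selection", "ne")]))
  if (length(missing))
    warning(sprintf("partial run: missing %s",
                    paste(missing, collapse = ", ")))
  structure(rep, class = "run_report")
}

#' @export
print.run_report <- function(x, ...) {
  cat("== MA pipeline run report ==\n")
  if (!is.null(x$ne)) { cat("\n-- ML effective size --\n")
    print(x$ne, row.names = FALSE) }
  if (!is.null(x$rates)) {
    cat("\n-- per-line mutation rates --\n")
    print(utils::head(x$rates, 25), row.names = FALSE)
    cat(sprintf("median mu = %.3g\n", stats::median(x$rates$mu)))
  }
  if (!is.null(x$spectrum)) { cat("\n-- spectrum summary --\n")
    print(x$spectrum, row.names = FALSE) }
  if (!is.null(x$varcomp)) { cat("\n-- variance components --\n")
    print(x$varcomp, row.names = FALSE) }
  if (!is.null(x$selection)) { cat("\n-- selection report --\n")
    print(x$selection, row.names = FALSE) }
  if (!is.null(x$truth)) { cat("\n-- ground-truth overlay --\n")
    print(x$truth, row.names = FALSE) }
  invisible(x)
}
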