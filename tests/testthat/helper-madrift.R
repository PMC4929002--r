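# Shared fixture builders: hand-crafted pileup tables and small synthetic
# runs. All fixtures are built in code; no data files.

# Build a pileup_table from per-row specifications. Each row: counts for
# one (site, line, allele) are split evenly across strands unless plus /
# minus are given explicitly.
make_pileup <- function(..., parental = "P0") {
  rows <- list(...)
  out <- do.call(rbind, lapply(rows, function(r) {
    plus <- if (!is.null(r$plus)) r$plus else ceiling(r$count / 2)
    minus <- if (!is.null(r$minus)) r$minus else r$count - plus
    data.frame(chrom = r$chrom %||% "A", pos = as.integer(r$pos),
               line_id = r$line, allele = r$allele,
               strand = c("+", "-"), count = c(plus, minus))
  }))
  out <- out[out$count > 0, ]
  dt <- data.table::as.data.table(out)
  data.table::setkeyv(dt, c("chrom", "pos", "line_id"))
  data.table::setattr(dt, "parental", parental)
  data.table::setattr(dt, "class", c("pileup_table", class(dt)))
  dt
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# A clean site: parental depth 30 ancestral A; n_ma lines with depth 30.
# `mutant_lines` maps line id -> mutant reads of allele `mut` (rest
# ancestral).
site_rows <- function(pos, n_ma = 12, anc = "A", mut = "G", depth = 30,
                      mutant_reads = c(), chrom = "A") {
  rows <- list(list(chrom = chrom, pos = pos, line = "P0", allele = anc,
                    count = depth))
  for (i in seq_len(n_ma)) {
    id <- sprintf("MA%02d", i)
    mr <- if (id %in% names(mutant_reads)) mutant_reads[[id]] else 0
    if (mr > 0)
      rows <- c(rows, list(list(chrom = chrom, pos = pos, line = id,
                                allele = mut, count = mr)))
    if (depth - mr > 0)
      rows <- c(rows, list(list(chrom = chrom, pos = pos, line = id,
                                allele = anc, count = depth - mr)))
  }
  rows
}

make_site_pileup <- function(...) do.call(make_pileup, c(...))

# Small error-free synthetic run shared across calling tests.
perfect_run <- function(seed = 42, n_lines = 12, genome_len = 5000,
                        mu = 2e-6, depth = 40) {
  g <- generate_genome(genome_len, seed = seed)
  tr <- simulate_ma_lines(g, n_lines = n_lines, t = 60, mu = mu,
                          seed = seed + 1)
  pile <- render_pileups(g, tr, mean_depth = depth, error_rate = 0,
                         seed = seed + 2)
  list(genome = g, truth = tr, pileup = pile)
}

# Brute-force fixation probabilities of the Wright-Fisher chain with
# haploid selection (fitness 1 vs 1+s), by solving the absorbing system.
wf_chain_fixation <- function(two_ne, s) {
  states <- 0:two_ne
  pprime <- function(p) p * (1 + s) / (1 + p * s)
  T <- outer(states, states, function(i, j)
    stats::dbinom(j, two_ne, pprime(i / two_ne)))
  interior <- 2:two_ne                     # states 1 .. two_ne - 1
  Q <- T[interior, interior, drop = FALSE]
  b <- T[interior, two_ne + 1]
  u <- solve(diag(length(interior)) - Q, b)
  c(0, u, 1)                               # indexed by copy number 0..two_ne
}
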