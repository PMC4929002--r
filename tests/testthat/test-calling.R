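# Six-clause mutation calling, site eligibility, Fisher exact test,
# mutation classification.

test_that("site eligibility applies all three clauses", {
  # six crafted sites, one violating each clause, three survivors
  rows <- c(
    site_rows(1, n_ma = 12),                       # clean -> eligible
    site_rows(2, n_ma = 12, depth = 30)[-1],       # drop parental row
    list(list(pos = 2, line = "P0", allele = "A", count = 14)),  # par 14
    site_rows(3, n_ma = 9),                        # only 9 MA lines
    site_rows(4, n_ma = 12),                       # clean -> eligible
    # site 5: 11 alleles across lines (parental A + 10 extra singletons
    # on top of depth-29 ancestral in MA01..MA10)
    list(list(pos = 5, line = "P0", allele = "A", count = 30)),
    lapply(1:12, function(i) list(pos = 5, line = sprintf("MA%02d", i),
                                  allele = "A", count = 29)),
    lapply(1:10, function(i) list(pos = 5, line = sprintf("MA%02d", i),
                                  allele = paste0("AL", i), count = 1)),
    site_rows(6, n_ma = 12)                        # clean -> eligible
  )
  pile <- make_site_pileup(rows)
  el <- eligible_sites(pile)
  expect_identical(sort(el$pos), c(1L, 4L, 6L))

  # parental depth boundaries are inclusive
  lo <- make_site_pileup(site_rows(1, n_ma = 12, depth = 15))
  expect_identical(eligible_sites(lo)$pos, 1L)
  hi <- make_site_pileup(site_rows(1, n_ma = 12, depth = 250))
  expect_identical(eligible_sites(hi)$pos, 1L)
  over <- make_site_pileup(site_rows(1, n_ma = 12, depth = 251))
  expect_identical(nrow(eligible_sites(over)), 0L)

  expect_error(eligible_sites(make_site_pileup(site_rows(1)),
                              parental = "NOPE"), "parental")
})

test_that("Fisher exact p-values match hypergeometric enumeration", {
  expect_equal(fisher_exact_2x2(10, 10, 10, 10), 1.0)
  expect_equal(fisher_exact_2x2(0, 10, 10, 0), 2 / choose(20, 10))
  expect_equal(fisher_exact_2x2(5, 0, 0, 5), 2 / choose(10, 5))
  expect_equal(fisher_exact_2x2(0, 0, 0, 0), 1.0)

  # agreement with stats::fisher.test for all tables with margins <= 12
  set.seed(1)
  for (i in 1:200) {
    tb <- matrix(sample(0:12, 4, replace = TRUE), 2)
    if (sum(tb) == 0) next
    expect_equal(fisher_exact_2x2(tb[1, 1], tb[1, 2], tb[2, 1], tb[2, 2]),
                 stats::fisher.test(tb)$p.value, tolerance = 1e-10)
  }
  # symmetry under row and column swaps
  expect_equal(fisher_exact_2x2(3, 9, 7, 2), fisher_exact_2x2(7, 2, 3, 9))
  expect_equal(fisher_exact_2x2(3, 9, 7, 2), fisher_exact_2x2(9, 3, 2, 7))
})

test_that("each calling clause independently flips a call", {
  base_reads <- c(MA01 = 25)   # freq 25/30 in MA01
  ok <- make_site_pileup(site_rows(1, mutant_reads = base_reads))
  expect_identical(nrow(call_mutations(ok)), 1L)

  # (1) one parental mutant read kills the call
  p1 <- make_site_pileup(c(site_rows(1, mutant_reads = base_reads),
                           list(list(pos = 1, line = "P0", allele = "G",
                                     count = 1))))
  expect_identical(nrow(call_mutations(p1)), 0L)

  # (2) complete strand bias of the mutant allele kills the call
  p2 <- make_site_pileup(c(
    site_rows(1)[-2],   # rebuild MA01 by hand below
    list(list(pos = 1, line = "MA01", allele = "G", count = 25,
              plus = 25, minus = 0),
         list(pos = 1, line = "MA01", allele = "A", count = 5,
              plus = 0, minus = 5))))
  expect_identical(nrow(call_mutations(p2)), 0L)

  # (3) a third allele in the mutant line kills the call
  p3 <- make_site_pileup(c(
    list(list(pos = 1, line = "P0", allele = "A", count = 30)),
    list(list(pos = 1, line = "MA01", allele = "G", count = 20),
         list(pos = 1, line = "MA01", allele = "T", count = 2),
         list(pos = 1, line = "MA01", allele = "A", count = 8)),
    lapply(2:12, function(i) list(pos = 1, line = sprintf("MA%02d", i),
                                  allele = "A", count = 30))))
  expect_identical(nrow(call_mutations(p3)), 0L)

  # (4) mutant frequency exactly at the cutoff is not called (strict >)
  p4 <- make_site_pileup(site_rows(1, mutant_reads = c(MA01 = 6)))
  expect_identical(nrow(call_mutations(p4)), 0L)   # 6/30 = 0.2
  p4b <- make_site_pileup(site_rows(1, mutant_reads = c(MA01 = 7)))
  expect_identical(nrow(call_mutations(p4b)), 1L)  # 7/30 > 0.2

  # (5) another line with the mutant allele above 5% kills the call
  p5 <- make_site_pileup(site_rows(1, mutant_reads = c(MA01 = 25,
                                                       MA02 = 2)))
  expect_identical(nrow(call_mutations(p5)), 0L)   # 2/30 = 6.7% > 5%

  # (6) three other lines with any mutant read kill the call; two do not
  p6 <- make_site_pileup(site_rows(1, mutant_reads = c(MA01 = 25,
                                                       MA02 = 1, MA03 = 1,
                                                       MA04 = 1)))
  expect_identical(nrow(call_mutations(p6)), 0L)
  p6b <- make_site_pileup(site_rows(1, mutant_reads = c(MA01 = 25,
                                                        MA02 = 1,
                                                        MA03 = 1)))
  expect_identical(nrow(call_mutations(p6b)), 1L)

  # two lines sharing a high-frequency mutant allele kill each other
  p7 <- make_site_pileup(site_rows(1, mutant_reads = c(MA01 = 25,
                                                       MA02 = 25)))
  expect_identical(nrow(call_mutations(p7)), 0L)
})

test_that("relaxing any single threshold never removes a call", {
  run <- perfect_run(seed = 11, n_lines = 12, genome_len = 4000, mu = 4e-6)
  pile <- render_pileups(run$genome, run$truth, mean_depth = 30,
                         error_rate = 0.004, seed = 99)
  key <- function(calls) paste(calls$chrom, calls$pos, calls$line_id)
  base <- call_mutations(pile)
  relaxed <- list(
    call_mutations(pile, freq_cutoff = 0.1),
    call_mutations(pile, leak_freq = 0.2),
    call_mutations(pile, strand_p = 1e-6),
    call_mutations(pile, max_leak_lines = 5))
  for (r in relaxed) expect_true(all(key(base) %in% key(r)))
})

test_that("perfect data yields perfect recall of high-frequency mutations", {
  run <- perfect_run(seed = 21, n_lines = 12, genome_len = 5000, mu = 3e-6)
  calls <- call_mutations(run$pileup)
  truth <- run$truth$mutations
  # every fixed mutation is recovered exactly once
  fixed <- truth[truth$final_freq == 1, ]
  key_t <- paste(fixed$chrom, fixed$pos, fixed$line_id)
  key_c <- paste(calls$chrom, calls$pos, calls$line_id)
  expect_true(all(key_t %in% key_c))
  # every call corresponds to a true mutation (no errors injected)
  key_all <- paste(truth$chrom, truth$pos, truth$line_id)
  expect_true(all(key_c %in% key_all))
  # recall of mutations whose *sampled* read frequency exceeds the cutoff
  d <- as.data.frame(run$pileup)
  seg <- truth[truth$final_freq > 0, ]
  for (i in seq_len(nrow(seg))) {
    r <- seg[i, ]
    site <- d[d$chrom == r$chrom & d$pos == r$pos & d$line_id == r$line_id, ]
    f <- sum(site$count[site$allele == r$mutant]) / sum(site$count)
    if (f > 0.2)
      expect_true(paste(r$chrom, r$pos, r$line_id) %in% key_c)
  }
})

test_that("mutation classes partition all valid allele pairs", {
  expect_identical(classify_mutation("A", "G"), "SBS")
  expect_identical(classify_mutation("AC", "A"), "DEL")
  expect_identical(classify_mutation("A", "AT"), "INS")
  expect_identical(classify_mutation("ACG", "TG"), "COMPLEX")
  expect_identical(classify_mutation("AC", "GT"), "MBS")
  expect_identical(classify_mutation("AC", "AT"), "SBS")
  expect_error(classify_mutation("A", "A"), "identical")
  expect_error(classify_mutation("", "A"), "non-empty")

  # property: every random pair maps to exactly one class
  set.seed(3)
  rand_allele <- function() paste(sample(c("A", "C", "G", "T"),
                                         sample(1:4, 1), replace = TRUE),
                                  collapse = "")
  for (i in 1:200) {
    a <- rand_allele(); m <- rand_allele()
    if (a == m) next
    cls <- classify_mutation(a, m)
    expect_true(cls %in% c("SBS", "MBS", "INS", "DEL", "COMPLEX"))
    if (nchar(a) == nchar(m)) expect_true(cls %in% c("SBS", "MBS"))
    else expect_true(cls %in% c("INS", "DEL", "COMPLEX"))
  }
})

test_that("calls round-trip through VCF and match vcfR's reading", {
  run <- perfect_run(seed = 31, n_lines = 12, genome_len = 3000, mu = 4e-6)
  calls <- call_mutations(run$pileup)
  f <- withr::local_tempfile(fileext = ".vcf")
  write_calls_vcf(calls, f)
  back <- read_calls_vcf(f)
  expect_identical(nrow(back), nrow(calls))
  expect_identical(back$line_id, calls$line_id)
  expect_equal(back$freq, calls$freq, tolerance = 1e-5)
  skip_if_not_installed("vcfR")
  v <- suppressWarnings(vcfR::read.vcfR(f, verbose = FALSE))
  expect_identical(nrow(v@fix), nrow(calls))
  expect_identical(as.integer(v@fix[, "POS"]), calls$pos)
  expect_identical(unname(v@fix[, "ALT"]), calls$mutant)
})
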