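# Six-clause spontaneous-mutation calling from pileup allele counts.
# A mutation is called in a line iff, at an eligible site:
#   (1) no parental read supports the mutant allele;
#   (2) the two-sided Fisher exact p for strand bias exceeds `strand_p`;
#   (3) at most two alleles have reads in the mutant line;
#   (4) the mutant allele frequency in the line is > `freq_cutoff`;
#   (5) no other line carries the mutant allele at frequency > `leak_freq`;
#   (6) at most `max_leak_lines` other lines have any mutant-allele read.

#' Sites eligible for mutation calling
#'
#' A site is eligible when the read depth lies within `depth_bounds`
#' (inclusive) in the parental line and in at least `min_lines` MA lines,
#' and no more than `max_alleles` distinct alleles are observed across all
#' lines combined.
#'
#' @param pileup A `pileup_table` (parental id in attribute `parental`, or
#'   pass `parental`).
#' @param depth_bounds Inclusive depth window (default `c(15, 250)`).
#' @param min_lines Minimum number of MA lines inside the window (default
#'   10).
#' @param max_alleles Maximum distinct alleles across all lines (default
#'   10).
#' @param parental Parental line id (default: the table's attribute).
#' @return A `data.table` with columns `chrom`, `pos` of eligible sites.
#' @export
eligible_sites <- function(pileup, depth_bounds = c(15, 250), min_lines = 10,
                           max_alleles = 10, parental = NULL) {
  parental <- parental %||% attr(pileup, "parental")
  if (is.null(parental) || !parental %in% pileup$line_id)
    stop("parental line missing from pileup")
  dt <- data.table::as.data.table(pileup)
  dep <- dt[, list(site_depth = sum(count)),
            by = c("chrom", "pos", "line_id")]
  ok <- dep$site_depth >= depth_bounds[1] & dep$site_depth <= depth_bounds[2]
  par_ok <- dep[which(ok & dep$line_id == parental),
                c("chrom", "pos"), with = FALSE]
  ma_ok <- dep[which(ok & dep$line_id != parental),
               list(n_lines = .N), by = c("chrom", "pos")]
  ma_ok <- ma_ok[ma_ok$n_lines >= min_lines, c("chrom", "pos"), with = FALSE]
  nall <- dt[, list(n_alleles = length(unique(allele))),
             by = c("chrom", "pos")]
  nall <- nall[nall$n_alleles <= max_alleles, c("chrom", "pos"), with = FALSE]
  out <- merge(merge(par_ok, ma_ok, by = c("chrom", "pos")), nall,
               by = c("chrom", "pos"))
  data.table::setkeyv(out, c("chrom", "pos"))
  out
}

#' Two-sided Fisher exact test for a 2x2 table
#'
#' Exact hypergeometric two-sided p-value for the table
#' `rbind(c(a, b), c(c, d))`: the sum of probabilities of all tables with
#' the same margins whose probability does not exceed that of the observed
#' table (with the customary `1 + 1e-7` relative tolerance). Symmetric
#' under row and column swaps. Vectorized over the four counts. An all-zero
#' table returns p = 1.
#'
#' @param a,b,c,d Nonnegative integer cell counts.
#' @return Two-sided p-value(s).
#' @examples
#' fisher_exact_2x2(0, 10, 10, 0)  # 2 / choose(20, 10)
#' @export
fisher_exact_2x2 <- function(a, b, c, d) {
  if (any(c(a, b, c, d) < 0)) stop("counts must be nonnegative")
  n <- max(length(a), length(b), length(c), length(d))
  a <- rep_len(a, n); b <- rep_len(b, n)
  c <- rep_len(c, n); d <- rep_len(d, n)
  vapply(seq_len(n), function(i) {
    m <- a[i] + b[i]           # row 1 total
    k <- a[i] + c[i]           # column 1 total
    N <- a[i] + b[i] + c[i] + d[i]
    if (N == 0) return(1)
    x <- max(0, k - (N - m)):min(k, m)
    px <- stats::dhyper(x, m, N - m, k)
    p_obs <- stats::dhyper(a[i], m, N - m, k)
    min(1, sum(px[px <= p_obs * (1 + 1e-7)]))
  }, 0)
}

#' Call spontaneous mutations from a pileup table
#'
#' Applies the six filter clauses (see the package overview) to every
#' candidate (site, line, allele) at eligible sites. A candidate allele is
#' any allele with reads in an MA line that differs from the ancestral
#' allele, taken as the parental majority allele at the site. Each line is
#' evaluated independently against all others, so two lines sharing a
#' mutant allele can eliminate one another through clauses (5)-(6).
#'
#' @param pileup A `pileup_table`.
#' @param freq_cutoff Clause (4): mutant frequency must exceed this
#'   (strict; default 0.2).
#' @param leak_freq Clause (5): no other line above this frequency (strict;
#'   default 0.05).
#' @param max_leak_lines Clause (6): at most this many other lines with any
#'   mutant read (default 2).
#' @param strand_p Clause (2): Fisher strand-bias p must exceed this
#'   (default 0.001). The table is (mutant +, mutant -, other +, other -)
#'   within the mutant line.
#' @param eligible Optional precomputed [eligible_sites()] table.
#' @param parental Parental line id (default: the table's attribute).
#' @return A data.frame of class `mutation_calls`: `line_id`, `chrom`,
#'   `pos`, `ancestral`, `mutant`, `freq` (mutant reads / line depth),
#'   `class` (from [classify_mutation()]).
#' @export
call_mutations <- function(pileup, freq_cutoff = 0.2, leak_freq = 0.05,
                           max_leak_lines = 2, strand_p = 0.001,
                           eligible = NULL, parental = NULL) {
  parental <- parental %||% attr(pileup, "parental")
  if (is.null(parental) || !parental %in% pileup$line_id)
    stop("parental line missing from pileup")
  dt <- data.table::as.data.table(pileup)
  if (is.null(eligible)) eligible <- eligible_sites(pileup,
                                                    parental = parental)
  dt <- merge(dt, eligible, by = c("chrom", "pos"))
  # per (site, line, allele): strand-split and total counts
  al <- dt[, list(n_plus = sum(count[strand == "+"]),
                  n_minus = sum(count[strand == "-"])),
           by = c("chrom", "pos", "line_id", "allele")]
  al[, n := n_plus + n_minus]
  al[, depth := sum(n), by = c("chrom", "pos", "line_id")]
  al[, n_alleles_line := .N, by = c("chrom", "pos", "line_id")]
  # ancestral allele: parental majority (ties broken alphabetically)
  anc <- al[al$line_id == parental, ]
  data.table::setorderv(anc, c("chrom", "pos", "n", "allele"),
                        order = c(1, 1, -1, 1))
  anc <- anc[, list(ancestral = allele[1]), by = c("chrom", "pos")]
  al <- merge(al, anc, by = c("chrom", "pos"))
  # candidates: non-parental lines, non-ancestral alleles, freq > cutoff
  cand <- al[al$line_id != parental & al$allele != al$ancestral &
               al$n / al$depth > freq_cutoff, ]
  if (nrow(cand) == 0) return(empty_calls())
  # clause (1): parental support; clauses (5)-(6): leakage in other lines
  key <- function(x) paste(x$chrom, x$pos, x$allele, sep = "\r")
  par_n <- al[al$line_id == parental, ]
  i <- match(key(cand), key(par_n))
  par_reads <- ifelse(is.na(i), 0L, par_n$n[i])
  carriers <- al[al$line_id != parental, list(n_carriers = .N),
                 by = c("chrom", "pos", "allele")]
  hi <- al[al$line_id != parental & al$n / al$depth > leak_freq,
           list(n_hi = .N), by = c("chrom", "pos", "allele")]
  i <- match(key(cand), key(carriers))
  n_carriers <- ifelse(is.na(i), 0L, carriers$n_carriers[i])
  i <- match(key(cand), key(hi))
  n_hi <- ifelse(is.na(i), 0L, hi$n_hi[i])
  # the candidate line itself is a carrier and (by clause 4) above leak_freq
  pass <- par_reads == 0 &                             # (1)
    cand$n_alleles_line <= 2 &                         # (3)
    n_hi - 1 <= 0 &                                    # (5)
    n_carriers - 1 <= max_leak_lines                   # (6)
  cand <- cand[pass, ]
  if (nrow(cand) == 0) return(empty_calls())
  # clause (2): strand bias within the mutant line
  line_strand <- al[, list(tot_plus = sum(n_plus), tot_minus = sum(n_minus)),
                    by = c("chrom", "pos", "line_id")]
  idx <- match(paste(cand$chrom, cand$pos, cand$line_id),
               paste(line_strand$chrom, line_strand$pos,
                     line_strand$line_id))
  o_plus <- line_strand$tot_plus[idx] - cand$n_plus
  o_minus <- line_strand$tot_minus[idx] - cand$n_minus
  pv <- fisher_exact_2x2(cand$n_plus, cand$n_minus, o_plus, o_minus)
  cand <- cand[pv > strand_p, ]
  if (nrow(cand) == 0) return(empty_calls())
  out <- data.frame(line_id = cand$line_id, chrom = cand$chrom,
                    pos = cand$pos, ancestral = cand$ancestral,
                    mutant = cand$allele, freq = cand$n / cand$depth,
                    class = classify_mutation(cand$ancestral, cand$allele))
  out <- out[order(out$chrom, out$pos, out$line_id), ]
  rownames(out) <- NULL
  class(out) <- c("mutation_calls", "data.frame")
  out
}

empty_calls <- function() {
  out <- data.frame(line_id = character(0), chrom = character(0),
                    pos = integer(0), ancestral = character(0),
                    mutant = character(0), freq = numeric(0),
                    class = character(0))
  class(out) <- c("mutation_calls", "data.frame")
  out
}

#' @export
print.mutation_calls <- function(x, ...) {
  cat(sprintf("%d mutation calls in %d lines\n", nrow(x),
              length(unique(x$line_id))))
  if (nrow(x)) print(table(class = x$class))
  invisible(x)
}

#' Classify a mutation from its allele strings
#'
#' Equal length 1: single base substitution (`SBS`); equal length > 1 with
#' at least two differing positions: multiple base substitution (`MBS`);
#' pure length gain/loss (one allele a prefix-extension of the other with
#' no substituted base): `INS` / `DEL`; any length change combined with a
#' substitution: `COMPLEX`. Vectorized.
#'
#' @param ancestral,mutant Non-empty allele strings.
#' @return Character vector of classes.
#' @examples
#' classify_mutation(c("A", "AC", "A", "ACG"), c("G", "A", "AT", "TG"))
#' @export
classify_mutation <- function(ancestral, mutant) {
  if (any(nchar(ancestral) == 0) || any(nchar(mutant) == 0))
    stop("allele strings must be non-empty")
  if (any(ancestral == mutant)) stop("ancestral and mutant alleles identical")
  n <- max(length(ancestral), length(mutant))
  ancestral <- rep_len(ancestral, n); mutant <- rep_len(mutant, n)
  vapply(seq_len(n), function(i) {
    a <- ancestral[i]; m <- mutant[i]
    la <- nchar(a); lm <- nchar(m)
    if (la == lm) {
      if (la == 1) return("SBS")
      diffs <- sum(strsplit(a, "")[[1]] != strsplit(m, "")[[1]])
      return(if (diffs >= 2) "MBS" else "SBS")
    }
    # length change: pure indel iff the shorter is a prefix of the longer
    shorter <- if (la < lm) a else m
    longer <- if (la < lm) m else a
    pure <- substr(longer, 1, nchar(shorter)) == shorter
    if (!pure) return("COMPLEX")
    if (lm > la) "INS" else "DEL"
  }, "")
}

# transitions: A<->G, C<->T
is_transition <- function(anc, mut) {
  (anc == "A" & mut == "G") | (anc == "G" & mut == "A") |
    (anc == "C" & mut == "T") | (anc == "T" & mut == "C")
}
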