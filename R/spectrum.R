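# Mutation-spectrum summaries: transition/transversion ratio, GC bias,
# local sequence context (GC + DUST complexity), and per-gene counts.

#' Transition/transversion summary of SBS calls
#'
#' Transitions are A<->G and C<->T. The normalized ratio is `2 * ti / tv`:
#' each site offers one transition but two transversions, so under a
#' uniform substitution spectrum the normalized ratio is 1.
#'
#' @param calls A `mutation_calls` data.frame; only `class == "SBS"` rows
#'   are used.
#' @return A list with `ti`, `tv`, and `ratio` (`NA` with a warning when
#'   `tv` is 0).
#' @seealso [titv_normalized()] for the bare-counts form.
#' @export
titv_summary <- function(calls) {
  sbs <- calls[calls$class == "SBS", ]
  ti <- sum(is_transition(sbs$ancestral, sbs$mutant))
  tv <- nrow(sbs) - ti
  list(ti = ti, tv = tv, ratio = titv_normalized(ti, tv))
}

#' Opportunity-normalized Ti/Tv ratio from counts
#'
#' @param ti,tv Transition and transversion counts.
#' @return `2 * ti / tv`; `NA` with a warning when `tv` is 0.
#' @examples
#' titv_normalized(595, 608)  # ~1.96
#' @export
titv_normalized <- function(ti, tv) {
  if (tv == 0) {
    warning("no transversions: normalized Ti/Tv undefined")
    return(NA_real_)
  }
  2 * ti / tv
}

#' Fold bias of mutations toward G/C ancestral bases
#'
#' Rate ratio of mutations at G/C versus A/T ancestral bases after
#' normalizing by base composition:
#' `(n_gc / genome_gc) / (n_at / (1 - genome_gc))`.
#'
#' @param n_gc,n_at Counts of mutations with G/C and A/T ancestral bases.
#' @param genome_gc Genomic GC fraction in (0, 1).
#' @return The fold bias.
#' @examples
#' gc_bias(828, 401, 0.4248)  # ~2.80
#' @export
gc_bias <- function(n_gc, n_at, genome_gc) {
  if (genome_gc <= 0 || genome_gc >= 1) stop("genome_gc must be in (0, 1)")
  if (n_at == 0) stop("no mutations at A/T bases: fold bias undefined")
  (n_gc / genome_gc) / (n_at / (1 - genome_gc))
}

#' Spectrum summary of a call set
#'
#' Class counts, transition/transversion counts and normalized ratio, and
#' the GC fold bias of single-base ancestral states.
#'
#' @param calls A `mutation_calls` data.frame.
#' @param genome_gc Genomic GC fraction.
#' @return A list of class `spectrum_summary` with `class_counts`, `ti`,
#'   `tv`, `titv_ratio`, `n_gc`, `n_at`, `gc_fold_bias`.
#' @export
spectrum_summary <- function(calls, genome_gc) {
  cls <- table(factor(calls$class,
                      levels = c("SBS", "MBS", "INS", "DEL", "COMPLEX")))
  tt <- titv_summary(calls)
  single <- calls[nchar(calls$ancestral) == 1 &
                    calls$class %in% c("SBS", "MBS"), ]
  n_gc <- sum(single$ancestral %in% c("G", "C"))
  n_at <- sum(single$ancestral %in% c("A", "T"))
  fold <- if (n_at > 0) gc_bias(n_gc, n_at, genome_gc) else NA_real_
  structure(list(class_counts = cls, ti = tt$ti, tv = tt$tv,
                 titv_ratio = tt$ratio, n_gc = n_gc, n_at = n_at,
                 gc_fold_bias = fold),
            class = "spectrum_summary")
}

#' @export
print.spectrum_summary <- function(x, ...) {
  cat("Mutation spectrum summary\n")
  print(x$class_counts)
  cat(sprintf("  Ti = %d, Tv = %d, normalized Ti/Tv = %.3f\n",
              x$ti, x$tv, x$titv_ratio))
  cat(sprintf("  G/C vs A/T: %d vs %d, fold bias = %.3f\n",
              x$n_gc, x$n_at, x$gc_fold_bias))
  invisible(x)
}

#' DUST low-complexity score of a sequence window
#'
#' The classic triplet score: with `c_i` the count of each distinct
#' overlapping trinucleotide in the window and `w` the number of triplets,
#' `S = sum(c_i * (c_i - 1) / 2) / (w - 1)`. Low-complexity sequence
#' (homopolymers, short tandem repeats) gives large `S`; a window with all
#' triplets distinct gives `S = 0`. The complexity scale is `-ln S`
#' (`+Inf` when `S = 0`). Triplets containing non-ACGT characters are
#' skipped.
#'
#' @param window A character string of length >= 3.
#' @return A list with `S` and `neg_log_S`.
#' @examples
#' dust_complexity(strrep("A", 10))  # S = 4
#' @export
dust_complexity <- function(window) {
  n <- nchar(window)
  if (n < 3) stop("window must be at least 3 bases")
  ch <- strsplit(toupper(window), "", fixed = TRUE)[[1]]
  tri <- paste0(ch[1:(n - 2)], ch[2:(n - 1)], ch[3:n])
  tri <- tri[!grepl("[^ACGT]", tri)]
  w <- length(tri)
  if (w < 2) stop("fewer than 2 valid triplets in window")
  cc <- table(tri)
  S <- sum(cc * (cc - 1) / 2) / (w - 1)
  list(S = S, neg_log_S = if (S == 0) Inf else -log(S))
}

#' Local sequence context of a mutation call
#'
#' GC content and DUST complexity of the window `flank` bases up- and
#' downstream of a position (41 bp by default). The window is truncated at
#' genome ends and the effective range is reported.
#'
#' @param genome An `ma_genome`.
#' @param position Global 1-based position (or a calls row via `chrom` +
#'   `pos` converted beforehand).
#' @param flank Flank size in bases (default 20).
#' @return A list with `gc_content`, `S`, `neg_log_S`, `window`, `start`,
#'   `end`.
#' @export
local_context <- function(genome, position, flank = 20) {
  start <- max(1, position - flank)
  end <- min(genome$length, position + flank)
  win <- substr(genome$sequence, start, end)
  d <- dust_complexity(win)
  list(gc_content = genome_gc(win), S = d$S, neg_log_S = d$neg_log_S,
       window = win, start = start, end = end)
}

#' Mutation counts per gene interval
#'
#' Counts calls falling in each gene interval (0-based, half-open
#' `[start, end)`, on global genome coordinates) together with the covered
#' length, suitable for a count-versus-length regression. A call inside
#' overlapping genes is counted in every one of them.
#'
#' @param calls A `mutation_calls` data.frame with a `position` column of
#'   global 1-based positions (or supply `positions`).
#' @param genes A data.frame with columns `start`, `end` (0-based
#'   half-open) and optionally `gene`.
#' @param positions Optional explicit global positions overriding
#'   `calls$position`.
#' @return A data.frame: `gene`, `covered_bases`, `n_mutations`.
#' @export
mutations_per_gene <- function(calls, genes, positions = NULL) {
  if (is.null(positions)) {
    positions <- calls$position
    if (is.null(positions))
      stop("calls lack a `position` column; pass `positions`")
  }
  gr <- IRanges::IRanges(start = genes$start + 1L, end = genes$end)
  qr <- IRanges::IRanges(start = positions, width = 1L)
  hits <- IRanges::countOverlaps(gr, qr)
  data.frame(
    gene = if (!is.null(genes$gene)) genes$gene
           else sprintf("g%04d", seq_len(nrow(genes))),
    covered_bases = genes$end - genes$start,
    n_mutations = as.integer(hits))
}
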