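#' Generate a random progenitor genome
#'
#' Draws an i.i.d. base sequence with a target GC content, split into an
#' X-linked segment (the first `x_fraction` of bases, chromosome label `"X"`)
#' and an autosomal segment (label `"A"`). The genome is the fixed ancestral
#' background against which mutation accumulation lines are simulated.
#'
#' @param length Genome size in bases (positive integer).
#' @param gc Target GC fraction in (0, 1); each base is G or C with this
#'   probability (split equally between G and C). The boundary values 0 and 1
#'   are allowed and give pure A/T or pure G/C sequences.
#' @param x_fraction Fraction of the genome (from the start) tagged as the X
#'   chromosome; in `[0, 1)`.
#' @param seed Optional integer seed; when supplied the sequence is
#'   reproducible bit-for-bit.
#'
#' @return An object of class `ma_genome`: a list with elements `sequence`
#'   (a single character string), `length`, `x_boundary` (index of the last
#'   X-linked base; 0 when `x_fraction = 0`) and `gc_target`.
#' @examples
#' g <- generate_genome(1000, gc = 0.4248, x_fraction = 0.2, seed = 1)
#' genome_gc(g)
#' @export
generate_genome <- function(length, gc = 0.4248, x_fraction = 0.2, seed = NULL) {
  if (length <= 0) stop("genome length must be positive")
  if (gc < 0 || gc > 1) stop("gc must be in [0, 1]")
  if (x_fraction < 0 || x_fraction >= 1) stop("x_fraction must be in [0, 1)")
  if (!is.null(seed)) set.seed(seed)
  length <- as.integer(length)
  bases <- sample(c("A", "C", "G", "T"), length, replace = TRUE,
                  prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2))
  structure(list(
    sequence   = paste(bases, collapse = ""),
    length     = length,
    x_boundary = as.integer(floor(x_fraction * length)),
    gc_target  = gc
  ), class = "ma_genome")
}

#' @export
print.ma_genome <- function(x, ...) {
  cat(sprintf("MA progenitor genome: %d bp (X: %d bp, A: %d bp), GC = %.4f\n",
              x$length, x$x_boundary, x$length - x$x_boundary, genome_gc(x)))
  invisible(x)
}

#' Realized GC content of a genome or sequence
#'
#' @param x An `ma_genome` or a character string of bases.
#' @return GC fraction over A/C/G/T bases (other characters ignored).
#' @export
genome_gc <- function(x) {
  s <- if (inherits(x, "ma_genome")) x$sequence else x
  b <- charToRaw(s)
  n_gc <- sum(b == charToRaw("G") | b == charToRaw("C"))
  n_at <- sum(b == charToRaw("A") | b == charToRaw("T"))
  n_gc / (n_gc + n_at)
}

#' Chromosome label of genomic positions
#'
#' @param genome An `ma_genome`.
#' @param pos 1-based global positions.
#' @return Character vector of `"X"` or `"A"`.
#' @export
chrom_of <- function(genome, pos) {
  ifelse(pos <= genome$x_boundary, "X", "A")
}

#' Position within the chromosome of a global position
#' @noRd
pos_in_chrom <- function(genome, pos) {
  ifelse(pos <= genome$x_boundary, pos, pos - genome$x_boundary)
}

#' Global position from (chrom, within-chromosome position)
#' @noRd
global_pos <- function(genome, chrom, pos) {
  ifelse(chrom == "X", pos, pos + genome$x_boundary)
}

# fast vectorized base extraction (1-based global positions)
bases_at <- function(genome, pos) {
  strsplit(rawToChar(charToRaw(genome$sequence)[pos]), "", fixed = TRUE)[[1]]
}

#' Write a genome to FASTA
#'
#' The X-linked and autosomal segments are written as two records named
#' `X` and `A`; positions within each record are 1-based.
#'
#' @param genome An `ma_genome`.
#' @param path Output FASTA path.
#' @return `path`, invisibly.
#' @export
write_genome_fasta <- function(genome, path) {
  seqs <- character(0)
  if (genome$x_boundary > 0)
    seqs <- c(X = substr(genome$sequence, 1, genome$x_boundary))
  seqs <- c(seqs, A = substr(genome$sequence, genome$x_boundary + 1,
                             genome$length))
  set <- Biostrings::DNAStringSet(seqs)
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}

#' Read a genome from FASTA
#'
#' Inverse of [write_genome_fasta()]: expects records named `X` (optional)
#' and `A`, concatenated as X then A.
#'
#' @param path FASTA path.
#' @return An `ma_genome`.
#' @export
read_genome_fasta <- function(path) {
  set <- Biostrings::readDNAStringSet(path)
  nm <- names(set)
  xlen <- if ("X" %in% nm) length(set[["X"]]) else 0L
  seq <- paste0(if (xlen > 0) as.character(set[["X"]]) else "",
                as.character(set[["A"]]))
  structure(list(sequence = seq, length = nchar(seq),
                 x_boundary = as.integer(xlen),
                 gc_target = genome_gc(seq)),
            class = "ma_genome")
}
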