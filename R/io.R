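# Interchange formats: pileup and trait TSV, mutation VCF v4.2.

#' Write / read a pileup table as TSV
#'
#' Columns: `chrom`, `pos` (1-based), `line_id`, `allele`, `strand`, `count`.
#' The parental line id is recorded in a `#parental=` header comment and
#' restored on read.
#'
#' @param pileup A `pileup_table`.
#' @param path Output path.
#' @return `path` invisibly; `read_pileup_tsv` returns the `pileup_table`.
#' @export
write_pileup_tsv <- function(pileup, path) {
  con <- file(path, "w")
  writeLines(sprintf("#parental=%s", attr(pileup, "parental")), con)
  close(con)
  data.table::fwrite(as.data.frame(pileup), path, sep = "\t", append = TRUE,
                     col.names = TRUE)
  invisible(path)
}

#' @rdname write_pileup_tsv
#' @param parental Parental line id (overrides the header comment).
#' @export
read_pileup_tsv <- function(path, parental = NULL) {
  first <- readLines(path, n = 1)
  if (is.null(parental) && startsWith(first, "#parental="))
    parental <- sub("^#parental=", "", first)
  d <- data.table::fread(path, sep = "\t", skip = "chrom\tpos")
  if (is.null(parental)) stop("parental line id not found; pass `parental`")
  data.table::setkeyv(d, c("chrom", "pos", "line_id"))
  data.table::setattr(d, "parental", parental)
  data.table::setattr(d, "class", c("pileup_table", class(d)))
  d
}

#' Write / read a trait panel as TSV
#'
#' Columns: `trait`, `sex`, `line`, `replicate`, `value`; the pool size is
#' stored in a `#pool_n=` header comment.
#'
#' @param panel A `trait_panel`.
#' @param path Output path.
#' @return `path` invisibly; `read_trait_tsv` returns the `trait_panel`.
#' @export
write_trait_tsv <- function(panel, path) {
  con <- file(path, "w")
  writeLines(sprintf("#pool_n=%d", as.integer(attr(panel, "pool_n") %||% 1)),
             con)
  close(con)
  data.table::fwrite(as.data.frame(panel), path, sep = "\t", append = TRUE,
                     col.names = TRUE)
  invisible(path)
}

#' @rdname write_trait_tsv
#' @export
read_trait_tsv <- function(path) {
  first <- readLines(path, n = 1)
  pool_n <- if (startsWith(first, "#pool_n="))
    as.integer(sub("^#pool_n=", "", first)) else 1L
  d <- as.data.frame(data.table::fread(path, sep = "\t",
                                       skip = "trait\tsex"))
  attr(d, "pool_n") <- pool_n
  class(d) <- c("trait_panel", "data.frame")
  d
}

`%||%` <- function(a, b) if (is.null(a)) b else a

vcf_header <- function(extra_info = character(0)) {
  c("##fileformat=VCFv4.2",
    "##source=madrift",
    "##INFO=<ID=LINE,Number=1,Type=String,Description=\"MA line carrying the mutation\">",
    "##INFO=<ID=AF,Number=1,Type=Float,Description=\"Mutant allele frequency in the line\">",
    extra_info,
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO")
}

#' Write simulated true mutations as VCF v4.2
#'
#' INFO fields: `LINE` (line id), `GEN` (origin generation), `AF` (final
#' frequency in the line at generation t).
#'
#' @param truth An `ma_truth`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_truth_vcf <- function(truth, path) {
  m <- truth$mutations
  hdr <- vcf_header(
    "##INFO=<ID=GEN,Number=1,Type=Integer,Description=\"Origin generation\">")
  body <- if (nrow(m)) sprintf(
    "%s\t%d\t.\t%s\t%s\t.\t.\tLINE=%s;GEN=%d;AF=%.6g",
    m$chrom, m$pos, m$ancestral, m$mutant, m$line_id, m$origin_gen,
    m$final_freq) else character(0)
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Write called mutations as VCF v4.2
#'
#' INFO fields: `LINE`, `AF` (mutant read frequency), `CLASS` (SBS, MBS,
#' INS, DEL or COMPLEX) and, for single base substitutions, `TITV` (`Ti` or
#' `Tv`).
#'
#' @param calls A `mutation_calls` data.frame from [call_mutations()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_calls_vcf <- function(calls, path) {
  hdr <- vcf_header(c(
    "##INFO=<ID=CLASS,Number=1,Type=String,Description=\"Mutation class\">",
    "##INFO=<ID=TITV,Number=1,Type=String,Description=\"Transition or transversion (SBS only)\">"))
  body <- character(0)
  if (nrow(calls)) {
    titv <- ifelse(calls$class == "SBS",
                   ifelse(is_transition(calls$ancestral, calls$mutant),
                          ";TITV=Ti", ";TITV=Tv"), "")
    body <- sprintf("%s\t%d\t.\t%s\t%s\t.\tPASS\tLINE=%s;AF=%.6g;CLASS=%s%s",
                    calls$chrom, calls$pos, calls$ancestral, calls$mutant,
                    calls$line_id, calls$freq, calls$class, titv)
  }
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Read a madrift mutation VCF
#'
#' Parses VCFs written by [write_calls_vcf()] or [write_truth_vcf()] back
#' into a calls data.frame.
#'
#' @param path VCF path.
#' @return A data.frame with columns `chrom`, `pos`, `ancestral`, `mutant`,
#'   `line_id`, `freq`, and `class` (NA when absent).
#' @export
read_calls_vcf <- function(path) {
  ln <- readLines(path)
  ln <- ln[!startsWith(ln, "#")]
  if (!length(ln))
    return(data.frame(chrom = character(0), pos = integer(0),
                      ancestral = character(0), mutant = character(0),
                      line_id = character(0), freq = numeric(0),
                      class = character(0)))
  f <- strsplit(ln, "\t", fixed = TRUE)
  info <- vapply(f, `[[`, "", 8)
  grab <- function(key) {
    m <- regmatches(info, regexpr(sprintf("%s=[^;]+", key), info))
    out <- rep(NA_character_, length(info))
    hit <- grepl(sprintf("%s=", key), info)
    out[hit] <- sub(sprintf("^%s=", key), "", m)
    out
  }
  data.frame(
    chrom = vapply(f, `[[`, "", 1),
    pos = as.integer(vapply(f, `[[`, "", 2)),
    ancestral = vapply(f, `[[`, "", 4),
    mutant = vapply(f, `[[`, "", 5),
    line_id = grab("LINE"),
    freq = as.numeric(grab("AF")),
    class = grab("CLASS"))
}
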