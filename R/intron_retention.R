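# intron_retention: per-base intronic coverage, the IR ratio, and retention
# calls, with a coverage-only fallback for nonmeasurable introns.
#
# Depth counts only non-gap-aligned read segments: a read that splices across
# the intron contributes nothing to intronic depth. The IR ratio is defined
# here as
#     median intronic depth / (median intronic depth + canonical junction reads)
# i.e. the estimated fraction of transcripts retaining the intron.

new_intron_coverage <- function(contig, start, end, depth, measurable,
                                config = detection_config()) {
  meas <- depth[measurable]
  structure(list(contig = contig, start = start, end = end,
                 depth = depth, measurable = measurable,
                 nonmeasurable = !any(measurable),
                 median_depth = lower_median(meas),
                 fraction_ge3 = if (length(meas)) mean(meas >= config$min_base_depth) else 0),
            class = "intron_coverage")
}

mask_to_logical <- function(mask, contig, start, end) {
  keep <- rep(TRUE, end - start + 1L)
  if (is.null(mask)) return(keep)
  if (is.character(mask)) mask <- rtracklayer::import(mask)
  mask <- mask[as.character(GenomicRanges::seqnames(mask)) == contig]
  for (i in seq_along(mask)) {
    a <- max(start, BiocGenerics::start(mask)[i])
    b <- min(end, BiocGenerics::end(mask)[i])
    if (a <= b) keep[(a - start + 1L):(b - start + 1L)] <- FALSE
  }
  keep
}

#' Per-base coverage of an intron
#'
#' Computes gap-aware per-base depth over an intron from primary alignments.
#' Bases under the exclusion mask are removed from the measurable set; the
#' median depth (lower-median convention, so integer depths give integer
#' medians) and the fraction of measurable bases at or above the minimum
#' depth are computed over measurable bases only.
#'
#' @param alignments Path to a SAM/BAM file.
#' @param intron Genomic interval: `list(contig =, start =, end =)` or a
#'   single `GRanges` (see [intron_region()]).
#' @param mask Optional BED path or `GRanges` of nonmeasurable bases.
#' @param config A [detection_config()].
#' @return An `intron_coverage` object; `nonmeasurable` is `TRUE` when every
#'   base is masked, in which case [fallback_coverage_quant()] applies.
#' @export
compute_intron_coverage <- function(alignments, intron, mask = NULL,
                                    config = detection_config()) {
  intron <- as_region(intron)
  bam <- prepare_alignments(alignments)
  gal <- read_gaps(bam, intron, config)
  depth <- integer(intron$end - intron$start + 1L)
  if (length(gal) > 0L) {
    cov <- GenomicAlignments::coverage(gal)[[intron$contig]]
    if (length(cov) < intron$end)
      cov <- c(cov, S4Vectors::Rle(0L, intron$end - length(cov)))
    depth <- as.integer(cov[intron$start:intron$end])
  }
  measurable <- mask_to_logical(mask, intron$contig, intron$start, intron$end)
  new_intron_coverage(intron$contig, intron$start, intron$end, depth,
                      measurable, config)
}

#' @export
print.intron_coverage <- function(x, ...) {
  cat(sprintf("intron_coverage %s:%d-%d | median depth %s | %.0f%% of %d measurable bases >= min depth%s\n",
              x$contig, x$start, x$end, x$median_depth, 100 * x$fraction_ge3,
              sum(x$measurable), if (x$nonmeasurable) " | NONMEASURABLE" else ""))
  invisible(x)
}

#' Compute the intron-retention ratio and call retention
#'
#' `ir_ratio = median_depth / (median_depth + canonical_junction_reads)`,
#' the estimated fraction of transcripts retaining the intron. Retention is
#' called when the ratio strictly exceeds the threshold (default 0.1) and
#' every measurable base reaches the minimum depth (default 3 reads). A zero
#' denominator yields ratio 0, not called.
#'
#' @param cov An `intron_coverage` from [compute_intron_coverage()].
#' @param canonical_junction_reads Reads on the canonical junction of this
#'   intron.
#' @param config A [detection_config()].
#' @return An `ir_call` list: `ir_ratio`, `called`, `method`
#'   (`"ratio_based"`), `median_depth`, `fraction_ge3`,
#'   `canonical_junction_reads`.
#' @examples
#' # ratio exactly at the threshold is NOT called (strict inequality)
#' cov <- splicetx:::new_intron_coverage("c", 1, 10, rep(10L, 10), rep(TRUE, 10))
#' compute_ir_ratio(cov, canonical_junction_reads = 90)$called
#' @export
compute_ir_ratio <- function(cov, canonical_junction_reads,
                             config = detection_config()) {
  stopifnot(inherits(cov, "intron_coverage"))
  if (canonical_junction_reads < 0) stopf("canonical_junction_reads must be non-negative")
  if (cov$nonmeasurable)
    stopf("intron %s:%d-%d is nonmeasurable; use fallback_coverage_quant()",
          cov$contig, cov$start, cov$end)
  md <- cov$median_depth
  denom <- md + canonical_junction_reads
  ratio <- if (denom > 0) md / denom else 0
  structure(list(ir_ratio = ratio,
                 called = ratio > config$ir_ratio_threshold && cov$fraction_ge3 == 1,
                 method = "ratio_based",
                 median_depth = md, fraction_ge3 = cov$fraction_ge3,
                 canonical_junction_reads = canonical_junction_reads,
                 contig = cov$contig, start = cov$start, end = cov$end),
            class = "ir_call")
}

#' Coverage-only retention quantification for nonmeasurable introns
#'
#' When the ratio-based method cannot evaluate an intron (all bases masked),
#' depth is quantified over every base regardless of the mask, and the same
#' ratio and per-base depth thresholds are applied. The method is recorded so
#' reports distinguish fallback calls.
#'
#' @param alignments Path to a SAM/BAM file.
#' @param intron Genomic interval of the intron.
#' @param canonical_junction_reads Reads on the canonical junction.
#' @param config A [detection_config()].
#' @return An `ir_call` with `method = "coverage_fallback"`.
#' @export
fallback_coverage_quant <- function(alignments, intron, canonical_junction_reads,
                                    config = detection_config()) {
  cov <- compute_intron_coverage(alignments, intron, mask = NULL, config = config)
  out <- compute_ir_ratio(cov, canonical_junction_reads, config)
  out$method <- "coverage_fallback"
  out
}

#' @export
print.ir_call <- function(x, ...) {
  cat(sprintf("ir_call %s:%d-%d | IR ratio %.3f (depth %s vs %d junction reads) | %s | %s\n",
              x$contig, x$start, x$end, x$ir_ratio, x$median_depth,
              x$canonical_junction_reads,
              if (x$called) "CALLED" else "not called", x$method))
  invisible(x)
}
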