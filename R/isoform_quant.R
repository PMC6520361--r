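# isoform_quant: combine junction-based event evidence and intron-retention
# depth into per-sample relative expression of canonical and aberrant
# transcript variants.
#
# Junction read counts and median intron depth are treated as commensurate
# evidence units and normalised jointly. This equivalence is an explicit
# modelling assumption: under per-base sampling of an RNA-seq library, both
# quantities estimate the coverage depth contributed by a variant at an
# informative position.

#' Estimate relative expression of transcript variants
#'
#' Builds the per-sample variant expression table from canonical junction
#' reads, filter-passing aberrant junction events, and called intron
#' retentions. Evidence units are supporting reads for junction-based
#' variants and median intronic depth for retention variants;
#' `relative_expression` is each variant's evidence divided by the total.
#'
#' @param canonical_junction_reads Reads on the canonical junction(s) of the
#'   affected intron(s); when two introns are affected, the mean of their
#'   canonical junction counts.
#' @param events A `splice_event_calls` data frame (only rows with
#'   `passes_filters` enter the table), or `NULL`.
#' @param ir_calls An `ir_call` or list of `ir_call`s (only called ones
#'   enter), or `NULL`.
#' @param sample_id Optional sample label.
#' @return A `variant_expression` data frame with columns `variant`,
#'   `evidence_basis`, `evidence_units`, `relative_expression` (sums to 1)
#'   and `aberrant_to_canonical` (evidence ratio against the canonical
#'   variant), ordered by decreasing relative expression with the canonical
#'   variant first on ties.
#' @examples
#' # canonical 70 junction reads vs 30 skipping reads -> 0.30
#' ev <- data.frame(event_type = "exon_skipping", intron = 3, skipped_exons = "4",
#'                  distance = NA, supporting_reads = 30, passes_filters = TRUE)
#' estimate_relative_expression(70, ev)
#' @export
estimate_relative_expression <- function(canonical_junction_reads, events = NULL,
                                         ir_calls = NULL, sample_id = NA_character_) {
  if (canonical_junction_reads < 0) stopf("canonical evidence must be non-negative")
  rows <- list(data.frame(variant = "canonical", evidence_basis = "junction_count",
                          evidence_units = as.numeric(canonical_junction_reads),
                          stringsAsFactors = FALSE))
  if (!is.null(events) && nrow(events) > 0L) {
    pass <- events[events$passes_filters, , drop = FALSE]
    for (i in seq_len(nrow(pass))) {
      lab <- if (pass$event_type[i] == "exon_skipping") {
        paste0("exon_skipping:", pass$skipped_exons[i])
      } else {
        paste0(pass$event_type[i], ":", pass$intron[i], ":", pass$distance[i])
      }
      rows[[length(rows) + 1L]] <- data.frame(
        variant = lab, evidence_basis = "junction_count",
        evidence_units = as.numeric(pass$supporting_reads[i]),
        stringsAsFactors = FALSE)
    }
  }
  if (!is.null(ir_calls)) {
    if (inherits(ir_calls, "ir_call")) ir_calls <- list(ir_calls)
    for (ir in ir_calls) {
      if (!isTRUE(ir$called)) next
      k <- ir$intron %||% NA_integer_
      rows[[length(rows) + 1L]] <- data.frame(
        variant = if (is.na(k)) sprintf("intron_retention:%d-%d", ir$start, ir$end)
                  else paste0("intron_retention:", k),
        evidence_basis = "median_intron_depth",
        evidence_units = as.numeric(ir$median_depth),
        stringsAsFactors = FALSE)
    }
  }
  tab <- do.call(rbind, rows)
  total <- sum(tab$evidence_units)
  if (total <= 0) stopf("no expression evidence detected for any variant")
  tab$relative_expression <- tab$evidence_units / total
  canon_ev <- tab$evidence_units[tab$variant == "canonical"]
  tab$aberrant_to_canonical <- ifelse(tab$variant == "canonical", NA_real_,
                                      tab$evidence_units / canon_ev)
  ord <- order(-tab$relative_expression, tab$variant != "canonical")
  tab <- tab[ord, , drop = FALSE]
  rownames(tab) <- NULL
  structure(tab, sample_id = sample_id,
            class = c("variant_expression", "data.frame"))
}

#' @export
print.variant_expression <- function(x, ...) {
  sid <- attr(x, "sample_id")
  cat(sprintf("Variant expression%s\n",
              if (!is.na(sid)) paste0(" [", sid, "]") else ""))
  for (i in seq_len(nrow(x))) {
    cat(sprintf("  %-32s %6.1f%%  (%g %s)\n", x$variant[i],
                100 * x$relative_expression[i], x$evidence_units[i],
                sub("_", " ", x$evidence_basis[i])))
  }
  invisible(x)
}
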