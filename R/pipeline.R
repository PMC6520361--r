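# cli_report: per-sample orchestration (mutation -> events -> intron
# retention -> quantification -> consequences), cohort-level summaries, and a
# text rendition of the junction-arc (Sashimi) view.

#' Run the per-sample splice-variant pipeline
#'
#' Classifies the mutation, extracts junction evidence over the affected
#' intron plus search window, calls aberrant events with the evidence
#' filters, quantifies intron retention, estimates relative expression of
#' all passing variants, and predicts each variant's protein consequence.
#' Samples with no passing event report canonical-only / full-length.
#'
#' @param alignments Path to the sample's SAM/BAM.
#' @param hgvs The sample's splice mutation in HGVS c. notation.
#' @param model A `transcript_model`; alternatively give `annotation`,
#'   `fasta` and `transcript_id` to load one.
#' @param annotation,fasta,transcript_id Used when `model` is `NULL`.
#' @param config A [detection_config()].
#' @param control_alignments Optional control SAM/BAM for event subtraction.
#' @param mask Optional BED path or `GRanges` of nonmeasurable intronic bases.
#' @param sample_id Sample label for reports.
#' @return A `sample_report` list: `sample_id`, `mutation`, `affected_intron`,
#'   `junctions` (annotated), `events` (all calls with pass/fail status),
#'   `ir` (`ir_call`), `expression` (`variant_expression` or `NULL`),
#'   `consequences` (data frame, one row per passing variant), `config`,
#'   `version`.
#' @export
run_sample_pipeline <- function(alignments, hgvs, model = NULL,
                                annotation = NULL, fasta = NULL,
                                transcript_id = NULL,
                                config = detection_config(),
                                control_alignments = NULL, mask = NULL,
                                sample_id = "sample") {
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stopf("[%s] stage '%s' failed: %s", sample_id, name, conditionMessage(e)))
  }
  if (is.null(model))
    model <- stage("gene_model", load_gene_model(annotation, fasta, transcript_id))
  mut <- stage("mutation", classify_splice_mutation(parse_hgvs_c(hgvs), model))
  k <- affected_intron_index(mut, model)
  win <- affected_window(model, k, config$search_window_bp)

  bam <- stage("alignments", prepare_alignments(alignments))
  junctions <- stage("junctions", extract_junctions(bam, win, config))
  ctrl <- NULL
  if (!is.null(control_alignments)) {
    ctrl_bam <- stage("control_alignments", prepare_alignments(control_alignments))
    ctrl <- stage("control_junctions", extract_junctions(ctrl_bam, win, config))
  }
  calls <- stage("detect_events", detect_events(junctions, model, mut, config, ctrl))
  ann <- attr(calls, "junctions")
  canon <- ann$annotation == "canonical" & !is.na(ann$intron) & ann$intron == k
  canonical_reads <- sum(ann$read_count[canon])

  ir <- stage("intron_retention", {
    covr <- compute_intron_coverage(bam, intron_region(model, k), mask, config)
    if (covr$nonmeasurable) {
      fallback_coverage_quant(bam, intron_region(model, k), canonical_reads, config)
    } else {
      compute_ir_ratio(covr, canonical_reads, config)
    }
  })
  ir$intron <- k

  expression <- NULL
  total_ev <- canonical_reads + sum(calls$supporting_reads[calls$passes_filters]) +
    if (isTRUE(ir$called)) ir$median_depth else 0
  if (total_ev > 0) {
    expression <- stage("quantification",
                        estimate_relative_expression(canonical_reads, calls,
                                                     ir, sample_id))
  }

  variant_events <- events_from_calls(calls)
  if (isTRUE(ir$called))
    variant_events <- c(variant_events,
                        list(splice_event("intron_retention", intron = k)))
  consequences <- if (length(variant_events)) {
    stage("consequence", consequence_table(model, variant_events))
  } else {
    data.frame(event = "canonical", frame_disturbed = FALSE,
               premature_stop = FALSE, aa_lost = 0L, ptc_codon = NA_integer_,
               protein_class = "full_length", named_isoform = NA_character_,
               stringsAsFactors = FALSE)
  }

  structure(list(sample_id = sample_id, mutation = mut, affected_intron = k,
                 junctions = ann, events = calls, ir = ir,
                 expression = expression, consequences = consequences,
                 config = config,
                 version = as.character(utils::packageVersion("splicetx"))),
            class = "sample_report")
}

#' @export
print.sample_report <- function(x, ...) {
  cat(sprintf("== sample %s | %s (%s, exon %d; intron %d) ==\n", x$sample_id,
              x$mutation$hgvs_c, x$mutation$site_class,
              x$mutation$adjacent_exon, x$affected_intron))
  npass <- sum(x$events$passes_filters) + as.integer(isTRUE(x$ir$called))
  if (npass == 0L) {
    cat("  aberrant transcript variants: not present (canonical only, full length)\n")
  } else {
    cat(sprintf("  aberrant transcript variants: %d passing\n", npass))
    if (!is.null(x$expression)) print(x$expression)
    for (i in seq_len(nrow(x$consequences))) {
      r <- x$consequences[i, ]
      cat(sprintf("  %-32s frame=%s PTC=%s class=%s%s\n", r$event,
                  r$frame_disturbed, r$premature_stop, r$protein_class,
                  if (!is.na(r$named_isoform)) paste0(" [", r$named_isoform, "]") else ""))
    }
  }
  invisible(x)
}

#' Write a sample report as JSON
#'
#' The full report, including the effective configuration snapshot, is
#' serialised so that a run can be audited and reproduced.
#'
#' @param report A `sample_report`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_sample_report <- function(report, path) {
  stopifnot(inherits(report, "sample_report"))
  x <- list(
    sample_id = report$sample_id,
    version = report$version,
    config = unclass(report$config),
    mutation = report$mutation[c("hgvs_c", "edit_type", "side", "offset",
                                 "length", "adjacent_exon", "site_class",
                                 "is_consensus_point")],
    affected_intron = report$affected_intron,
    junctions = report$junctions,
    events = as.data.frame(report$events),
    ir = unclass(report$ir),
    expression = if (!is.null(report$expression)) as.data.frame(report$expression),
    consequences = report$consequences)
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, na = "null")
  invisible(path)
}

#' Summarise a cohort of sample reports or fixture tables
#'
#' Counts samples expressing at least one aberrant transcript variant and
#' samples expressing two, and (when HGVS strings are available) attaches the
#' mutation-classification summary.
#'
#' @param reports A list of `sample_report` objects, or `NULL` when
#'   summarising fixture tables.
#' @param mutations Optional mutation data frame (columns `sample_no`,
#'   `hgvs_c`), e.g. [tp53_cohort_mutations()].
#' @param events Optional declared-variant data frame (column `sample_no`,
#'   one row per variant), e.g. [tp53_cohort_variants()].
#' @param model A `transcript_model`, required to classify `mutations`.
#' @param total_mutations Optional cohort-wide total mutation count for the
#'   splice-share percentage.
#' @return A `cohort_report` list: `n_samples`, `n_with_aberrant`,
#'   `n_with_two`, `pct_with_aberrant`, `per_sample` counts, and
#'   `classification` (a `cohort_summary`) when derivable.
#' @export
summarize_cohort_reports <- function(reports = NULL, mutations = NULL,
                                     events = NULL, model = NULL,
                                     total_mutations = NULL) {
  if (is.null(reports) && is.null(mutations))
    stopf("need sample reports or a mutation table")
  if (!is.null(reports)) {
    stopifnot(all(vapply(reports, inherits, logical(1), "sample_report")))
    if (length(reports) == 0L) stopf("empty report list")
    nv <- vapply(reports, function(r)
      sum(r$events$passes_filters) + as.integer(isTRUE(r$ir$called)), integer(1))
    ids <- vapply(reports, `[[`, character(1), "sample_id")
    muts <- lapply(reports, `[[`, "mutation")
  } else {
    ids <- as.character(mutations$sample_no %||% mutations$sample_id)
    nv <- if (is.null(events)) rep(0L, length(ids)) else {
      vapply(ids, function(s)
        sum(as.character(events$sample_no) == s), integer(1))
    }
    muts <- NULL
    if (!is.null(model))
      muts <- lapply(mutations$hgvs_c, function(h)
        classify_splice_mutation(parse_hgvs_c(h), model))
  }
  out <- list(n_samples = length(ids),
              n_with_aberrant = sum(nv >= 1L),
              n_with_two = sum(nv == 2L),
              pct_with_aberrant = round(100 * sum(nv >= 1L) / length(ids)),
              per_sample = stats::setNames(nv, ids))
  if (!is.null(muts)) out$classification <- summarize_cohort(muts, total_mutations)
  structure(out, class = "cohort_report")
}

#' @export
print.cohort_report <- function(x, ...) {
  cat(sprintf("Cohort report: %d samples | %d (%d%%) with aberrant variants | %d with two\n",
              x$n_samples, x$n_with_aberrant, x$pct_with_aberrant, x$n_with_two))
  if (!is.null(x$classification)) print(x$classification)
  invisible(x)
}

#' Text rendition of a junction (Sashimi) view
#'
#' Lists the junction arcs over a region with their supporting read counts
#' and annotations, plus the median intronic depth when supplied —
#' a deterministic monospace analogue of a genome-browser Sashimi plot.
#'
#' @param junctions Annotated junction table (from a `sample_report` or
#'   [detect_events()]'s `junctions` attribute, or raw
#'   [extract_junctions()] output).
#' @param events Optional `splice_event_calls` to flag passing events.
#' @param ir Optional `ir_call` to append intron depth.
#' @param region Optional region label for the header.
#' @return Invisibly, the character vector of lines (also printed).
#' @export
render_text_sashimi <- function(junctions, events = NULL, ir = NULL,
                                region = NULL) {
  lines <- sprintf("sashimi%s", if (!is.null(region)) {
    r <- as_region(region); sprintf(" %s:%d-%d", r$contig, r$start, r$end)
  } else "")
  if (nrow(junctions) == 0L) {
    lines <- c(lines, "  (no junction-spanning reads)")
  } else {
    j <- junctions[order(junctions$intron_start, junctions$intron_end), , drop = FALSE]
    counts <- j$read_count %||% j$supporting_reads
    for (i in seq_len(nrow(j))) {
      ann <- if (!is.null(j$annotation)) sprintf("  [%s]", j$annotation[i]) else ""
      lines <- c(lines, sprintf("  %8d )----- %4d reads -----( %-8d%s",
                                j$intron_start[i] - 1L, counts[i],
                                j$intron_end[i] + 1L, ann))
    }
  }
  if (!is.null(events) && nrow(events) > 0L) {
    for (i in seq_len(nrow(events)))
      lines <- c(lines, sprintf("  event %s (%s): %d reads, %.1f%% of relevant, %s",
                                events$event_type[i], events$label_c[i] %||% "",
                                events$supporting_reads[i],
                                100 * events$fraction_of_relevant[i],
                                if (events$passes_filters[i]) "PASS" else "fail"))
  }
  if (!is.null(ir))
    lines <- c(lines, sprintf("  intron depth (median): %s | IR ratio %.3f | %s",
                              ir$median_depth, ir$ir_ratio,
                              if (ir$called) "retention CALLED" else "retention not called"))
  cat(lines, sep = "\n")
  cat("\n")
  invisible(lines)
}

#' Reproduce the published per-variant consequence table on the fixture
#'
#' Recomputes frame / PTC / protein class from sequence for every declared
#' variant of the 16-sample cohort fixture on the synthetic TP53-like
#' reference and compares them with the published annotations, flagging any
#' discordance instead of forcing the printed value.
#'
#' @param model Optional `transcript_model`; defaults to the synthetic
#'   fixture.
#' @return A data frame with one row per declared variant: computed
#'   `frame_disturbed`/`premature_stop`/`aa_lost`/`protein_class`/
#'   `named_isoform`, the `*_printed` annotations, and logical
#'   `frame_concordant`, `ptc_concordant`, `class_concordant`, `concordant`.
#' @export
tp53_cohort_concordance <- function(model = NULL) {
  if (is.null(model)) model <- tp53_synthetic_fixture()$model
  ev <- tp53_cohort_variants()
  comp <- consequence_table(model, as.list(ev$event))
  out <- cbind(ev[c("sample_no", "variant_no", "event")],
               comp[c("frame_disturbed", "premature_stop", "aa_lost",
                      "protein_class", "named_isoform")],
               ev[c("frame_printed", "ptc_printed", "protein_printed")])
  out$frame_concordant <- out$frame_disturbed == (out$frame_printed == "Yes")
  out$ptc_concordant <- out$premature_stop == (out$ptc_printed == "Yes")
  printed_class <- ifelse(out$protein_printed == "Truncated", "truncated",
                          ifelse(grepl("^Loss of", out$protein_printed),
                                 "inframe_loss", "full_length"))
  out$class_concordant <- out$protein_class == printed_class
  out$concordant <- out$frame_concordant & out$ptc_concordant & out$class_concordant
  out
}
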