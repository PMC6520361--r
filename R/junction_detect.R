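# junction_detect: exon-exon junction evidence from aligned reads, and calling
# of aberrant splice events (exon skipping, cryptic donor/acceptor) around a
# mutated splice site.

#' Detection configuration
#'
#' Thresholds applied to aberrant transcript evidence. An aberrant junction
#' passes only when supported by at least `min_reads` reads that account for
#' at least `min_fraction` of all relevant junction reads, and when not
#' present in the control sample; intron retention is called at
#' `ir_ratio > ir_ratio_threshold` with every measurable intronic base
#' covered by at least `min_base_depth` reads.
#'
#' @param min_reads Minimum supporting reads for an aberrant junction.
#' @param min_fraction Minimum fraction of all relevant junction reads.
#' @param search_window_bp Search window around the affected intron for
#'   cryptic sites and relevant junctions.
#' @param min_mapping_quality Reads below this MAPQ are ignored.
#' @param count_duplicates Count duplicate-flagged reads?
#' @param ir_ratio_threshold Intron-retention ratio threshold (strict `>`).
#' @param min_base_depth Minimum per-base depth over measurable intronic
#'   bases for a ratio-based retention call.
#' @return A `detection_config` list.
#' @export
detection_config <- function(min_reads = 5L, min_fraction = 0.05,
                             search_window_bp = 500L, min_mapping_quality = 1L,
                             count_duplicates = FALSE,
                             ir_ratio_threshold = 0.1, min_base_depth = 3L) {
  if (min_reads < 1L) stopf("min_reads must be at least 1")
  if (min_fraction <= 0 || min_fraction >= 1) stopf("min_fraction must lie in (0, 1)")
  if (search_window_bp < 0L) stopf("search_window_bp must be non-negative")
  structure(list(min_reads = as.integer(min_reads), min_fraction = min_fraction,
                 search_window_bp = as.integer(search_window_bp),
                 min_mapping_quality = as.integer(min_mapping_quality),
                 count_duplicates = isTRUE(count_duplicates),
                 ir_ratio_threshold = ir_ratio_threshold,
                 min_base_depth = as.integer(min_base_depth)),
            class = "detection_config")
}

#' Ensure alignments are a sorted, indexed BAM
#'
#' SAM input is converted; BAM input is indexed if no index is present.
#'
#' @param alignments Path to a SAM or BAM file.
#' @return Path to an indexed BAM.
#' @export
prepare_alignments <- function(alignments) {
  if (!file.exists(alignments)) stopf("alignment file '%s' not found", alignments)
  if (grepl("\\.sam$", alignments, ignore.case = TRUE))
    return(sam_to_bam(alignments))
  if (!file.exists(paste0(alignments, ".bai")))
    Rsamtools::indexBam(alignments)
  alignments
}

as_region <- function(region) {
  if (inherits(region, "GRanges")) {
    if (length(region) != 1L) stopf("region must be a single interval")
    return(list(contig = as.character(GenomicRanges::seqnames(region)),
                start = BiocGenerics::start(region), end = BiocGenerics::end(region)))
  }
  stopifnot(is.list(region), all(c("contig", "start", "end") %in% names(region)))
  region
}

read_gaps <- function(bam, region, config) {
  region <- as_region(region)
  if (region$end < region$start) stopf("empty region %d-%d", region$start, region$end)
  which <- GenomicRanges::GRanges(region$contig,
                                  IRanges::IRanges(region$start, region$end))
  flag <- Rsamtools::scanBamFlag(
    isSecondaryAlignment = FALSE, isSupplementaryAlignment = FALSE,
    isDuplicate = if (config$count_duplicates) NA else FALSE)
  param <- Rsamtools::ScanBamParam(which = which, flag = flag,
                                   mapqFilter = config$min_mapping_quality)
  GenomicAlignments::readGAlignments(Rsamtools::BamFile(bam), param = param)
}

#' Extract exon-exon junction evidence from aligned reads
#'
#' Tallies the distinct gap (CIGAR N) operations of primary alignments
#' overlapping a region. Each gap operation of each counted read contributes
#' one supporting read to its junction, so a read spanning two junctions
#' counts towards both — the semantics of junction-arc read labels in a
#' Sashimi view.
#'
#' @param alignments Path to a coordinate-sorted SAM/BAM file.
#' @param region The genomic interval to inspect: a single
#'   [GenomicRanges::GRanges] or `list(contig =, start =, end =)`.
#' @param config A [detection_config()].
#' @return A data frame with one row per distinct junction: `contig`,
#'   `intron_start`, `intron_end` (first and last intronic base) and
#'   `read_count`.
#' @export
extract_junctions <- function(alignments, region, config = detection_config()) {
  bam <- prepare_alignments(alignments)
  gal <- read_gaps(bam, region, config)
  j <- unlist(GenomicAlignments::junctions(gal))
  if (length(j) == 0L)
    return(data.frame(contig = character(0), intron_start = integer(0),
                      intron_end = integer(0), read_count = integer(0)))
  key <- paste(BiocGenerics::start(j), BiocGenerics::end(j), sep = "-")
  tab <- table(key)
  parts <- strsplit(names(tab), "-", fixed = TRUE)
  out <- data.frame(
    contig = as_region(region)$contig,
    intron_start = vapply(parts, function(p) as.integer(p[1L]), integer(1)),
    intron_end = vapply(parts, function(p) as.integer(p[2L]), integer(1)),
    read_count = as.integer(tab))
  out <- out[order(out$intron_start, out$intron_end), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# annotate junction records against the canonical intron set of a model
annotate_junctions <- function(junctions, model) {
  introns <- model_introns(model)
  plus <- model$strand == "+"
  n <- nrow(junctions)
  junctions$donor_g <- if (plus) junctions$intron_start else junctions$intron_end
  junctions$acceptor_g <- if (plus) junctions$intron_end else junctions$intron_start
  junctions$annotation <- rep("unrelated", n)
  junctions$intron <- NA_integer_
  junctions$skipped_exons <- NA_character_
  junctions$distance <- NA_integer_
  for (i in seq_len(n)) {
    canon <- which(introns$gstart == junctions$intron_start[i] &
                     introns$gend == junctions$intron_end[i])
    if (length(canon) == 1L) {
      junctions$annotation[i] <- "canonical"
      junctions$intron[i] <- introns$intron[canon]
      next
    }
    d_hit <- which(introns$donor_g == junctions$donor_g[i])
    a_hit <- which(introns$acceptor_g == junctions$acceptor_g[i])
    if (length(d_hit) == 1L && length(a_hit) == 1L &&
        introns$intron[a_hit] > introns$intron[d_hit]) {
      junctions$annotation[i] <- "exon_skipping"
      ki <- introns$intron[d_hit]; kj <- introns$intron[a_hit]
      junctions$intron[i] <- ki
      junctions$skipped_exons[i] <- paste((ki + 1L):kj, collapse = ",")
    } else if (length(a_hit) == 1L && length(d_hit) == 0L) {
      junctions$annotation[i] <- "cryptic_donor"
      k <- introns$intron[a_hit]
      junctions$intron[i] <- k
      junctions$distance[i] <- if (plus) {
        junctions$donor_g[i] - introns$donor_g[introns$intron == k]
      } else {
        introns$donor_g[introns$intron == k] - junctions$donor_g[i]
      }
    } else if (length(d_hit) == 1L && length(a_hit) == 0L) {
      junctions$annotation[i] <- "cryptic_acceptor"
      k <- introns$intron[d_hit]
      junctions$intron[i] <- k
      junctions$distance[i] <- if (plus) {
        junctions$acceptor_g[i] - introns$acceptor_g[introns$intron == k]
      } else {
        introns$acceptor_g[introns$intron == k] - junctions$acceptor_g[i]
      }
    }
  }
  junctions
}

# window (genomic) around the intron affected by a classified mutation
affected_intron_index <- function(mut, model) {
  if (is.null(mut$adjacent_exon)) stopf("mutation must be classified first")
  if (mut$side == "donor") mut$adjacent_exon else mut$adjacent_exon - 1L
}

affected_window <- function(model, intron, window_bp) {
  reg <- intron_region(model, intron)
  contig_len <- if (!is.null(model$genome)) length(model$genome[[model$contig]]) else NA
  list(contig = reg$contig,
       start = max(1L, reg$start - window_bp),
       end = if (is.na(contig_len)) reg$end + window_bp
             else min(contig_len, reg$end + window_bp))
}

#' Call aberrant splice events near a mutated splice site
#'
#' Annotates extracted junctions against the canonical intron chain, keeps
#' the non-canonical ones touching the affected intron, and applies the
#' evidence filters: supporting reads at or above `min_reads`, fraction of
#' all relevant junction reads at or above `min_fraction`, and absence from
#' the control sample. "Relevant" reads are all junction reads, canonical and
#' aberrant, with either splice end inside the affected intron — the arcs a
#' Sashimi view over the mutated intron displays. Control events are
#' "present" when they pass the same read-count and fraction filters in the
#' control.
#'
#' @param junctions Junction records from [extract_junctions()] over the
#'   affected intron plus search window.
#' @param model A `transcript_model`.
#' @param mut A classified `splice_mutation` locating the affected intron.
#' @param config A [detection_config()].
#' @param control Optional junction records from a control sample over the
#'   same region.
#' @return A `splice_event_calls` data frame, one row per aberrant junction:
#'   coordinates (genomic and c.-space), `supporting_reads`,
#'   `fraction_of_relevant`, `present_in_control`, `passes_filters`. The
#'   annotated junction table and the relevant-read denominator are attached
#'   as attributes `junctions` and `relevant_reads`.
#' @export
detect_events <- function(junctions, model, mut, config = detection_config(),
                          control = NULL) {
  k <- affected_intron_index(mut, model)
  reg <- intron_region(model, k)
  ann <- annotate_junctions(junctions, model)
  in_intron <- function(x) x >= reg$start & x <= reg$end
  relevant <- in_intron(ann$donor_g) | in_intron(ann$acceptor_g)
  denom <- sum(ann$read_count[relevant])

  ctrl_ann <- NULL; ctrl_denom <- 0L
  if (!is.null(control) && nrow(control) > 0L) {
    ctrl_ann <- annotate_junctions(control, model)
    ctrl_rel <- in_intron(ctrl_ann$donor_g) | in_intron(ctrl_ann$acceptor_g)
    ctrl_ann <- ctrl_ann[ctrl_rel, , drop = FALSE]
    ctrl_denom <- sum(ctrl_ann$read_count)
  }

  ab <- ann[relevant & ann$annotation %in%
              c("exon_skipping", "cryptic_donor", "cryptic_acceptor"), , drop = FALSE]
  if (nrow(ab) > 0L) {
    ab$fraction_of_relevant <- if (denom > 0L) ab$read_count / denom else 0
    ab$present_in_control <- vapply(seq_len(nrow(ab)), function(i) {
      if (is.null(ctrl_ann)) return(FALSE)
      hit <- ctrl_ann$intron_start == ab$intron_start[i] &
        ctrl_ann$intron_end == ab$intron_end[i]
      any(hit & ctrl_ann$read_count >= config$min_reads &
            (ctrl_denom > 0L & ctrl_ann$read_count / max(1L, ctrl_denom) >= config$min_fraction))
    }, logical(1))
    ab$passes_filters <- ab$read_count >= config$min_reads &
      ab$fraction_of_relevant >= config$min_fraction &
      !ab$present_in_control
    ab$label_c <- vapply(seq_len(nrow(ab)), function(i) {
      g <- if (ab$annotation[i] == "cryptic_donor") ab$donor_g[i] else ab$acceptor_g[i]
      tryCatch(genomic_to_c(model, g)$label, error = function(e) NA_character_)
    }, character(1))
  } else {
    ab$fraction_of_relevant <- numeric(0)
    ab$present_in_control <- logical(0)
    ab$passes_filters <- logical(0)
    ab$label_c <- character(0)
  }
  names(ab)[names(ab) == "read_count"] <- "supporting_reads"
  names(ab)[names(ab) == "annotation"] <- "event_type"
  rownames(ab) <- NULL
  structure(ab, junctions = ann, relevant_reads = denom,
            affected_intron = k, class = c("splice_event_calls", "data.frame"))
}

# turn passing event calls into splice_event descriptors
events_from_calls <- function(calls) {
  pass <- calls[calls$passes_filters, , drop = FALSE]
  lapply(seq_len(nrow(pass)), function(i) {
    if (pass$event_type[i] == "exon_skipping") {
      splice_event("exon_skipping",
                   exons = as.integer(strsplit(pass$skipped_exons[i], ",")[[1L]]))
    } else {
      splice_event(pass$event_type[i], intron = pass$intron[i],
                   distance = pass$distance[i])
    }
  })
}

#' Scan for candidate cryptic splice sites around a mutated site
#'
#' Enumerates AG dinucleotides (acceptor side) or GT dinucleotides (donor
#' side) within a window of the canonical splice site affected by the
#' mutation, in transcript orientation. Distances follow the junction-shift
#' convention of [splice_event()]: for an acceptor, negative distances lie in
#' the intron (bases retained) and positive distances in the exon (bases
#' lost); for a donor the signs are mirrored.
#'
#' @param model A `transcript_model` with sequence loaded.
#' @param mut A classified `splice_mutation`.
#' @param window_bp Scan window on each side of the canonical site.
#' @return A data frame ordered by `abs(distance)`: `side`, `distance`,
#'   `location` (`intronic`/`exonic`), `genomic` (genomic coordinate of the
#'   first base of the dinucleotide).
#' @export
scan_cryptic_sites <- function(model, mut, window_bp = 500L) {
  if (is.null(model$genome)) stopf("no sequence loaded for '%s'", model$transcript_id)
  if (window_bp < 2L)
    return(data.frame(side = character(0), distance = integer(0),
                      location = character(0), genomic = integer(0)))
  k <- affected_intron_index(mut, model)
  side <- mut$side
  introns <- model_introns(model)
  plus <- model$strand == "+"
  contig_len <- length(model$genome[[model$contig]])

  # canonical junction base in genomic space: for a donor the first intronic
  # base, for an acceptor the first base of the downstream exon
  if (side == "donor") {
    canon_g <- introns$donor_g[introns$intron == k]
  } else {
    ex_dn <- model$exons[model$exons$index == k + 1L, ]
    canon_g <- if (plus) ex_dn$gstart else ex_dn$gend
  }

  # transcript-oriented sequence window centred on the canonical junction
  lo <- canon_g - (window_bp + 2L); hi <- canon_g + (window_bp + 2L)
  lo <- max(1L, lo); hi <- min(contig_len, hi)
  s <- as.character(tx_seq(model, lo, hi))
  centre <- if (plus) canon_g - lo + 1L else hi - canon_g + 1L  # tx index of canon_g

  din <- if (side == "acceptor") "AG" else "GT"
  hits <- gregexpr(din, s, fixed = TRUE)[[1L]]
  if (hits[1L] == -1L) hits <- integer(0)
  out <- lapply(as.integer(hits), function(p) {
    if (side == "acceptor") {
      # candidate acceptor: exon would start at p + 2 (tx orientation)
      dist <- (p + 2L) - centre
    } else {
      # candidate donor: intron would start at p
      dist <- p - centre
    }
    if (dist == 0L || abs(dist) > window_bp) return(NULL)
    g <- if (plus) lo + p - 1L else hi - p + 1L
    loc <- if (side == "acceptor") {
      if (dist < 0L) "intronic" else "exonic"
    } else {
      if (dist > 0L) "intronic" else "exonic"
    }
    data.frame(side = side, distance = dist, location = loc, genomic = g)
  })
  out <- do.call(rbind, out)
  if (is.null(out))
    return(data.frame(side = character(0), distance = integer(0),
                      location = character(0), genomic = integer(0)))
  out <- out[order(abs(out$distance)), , drop = FALSE]
  rownames(out) <- NULL
  out
}
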