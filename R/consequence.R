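# consequence: reconstruct the aberrant transcript implied by a splice event,
# translate it, and predict the protein-level outcome (reading-frame
# disturbance, premature termination codon, amino acids lost, protein class,
# named isoform).

#' Describe a splice event
#'
#' A declared or detected transcript alteration. Event descriptors are shared
#' between read-based detection and table-driven consequence prediction, so
#' the consequence engine is testable without alignments.
#'
#' @param type One of `"exon_skipping"`, `"intron_retention"`,
#'   `"cryptic_donor"`, `"cryptic_acceptor"`.
#' @param exons For exon skipping: integer vector of skipped exon indices
#'   (contiguous).
#' @param intron For intron retention and cryptic sites: the intron index
#'   (intron `k` lies between exons `k` and `k+1`).
#' @param distance For cryptic sites: signed transcript-direction offset of
#'   the cryptic junction from the canonical one. For an acceptor, positive
#'   values move the junction into the exon (exonic bases lost), negative
#'   values into the intron (intronic bases retained); for a donor the signs
#'   are reversed (negative = exonic).
#' @return A `splice_event` list.
#' @examples
#' splice_event("cryptic_acceptor", intron = 6, distance = -49)  # p53psi event
#' @export
splice_event <- function(type = c("exon_skipping", "intron_retention",
                                  "cryptic_donor", "cryptic_acceptor"),
                         exons = NULL, intron = NULL, distance = NULL) {
  type <- match.arg(type)
  if (type == "exon_skipping") {
    if (is.null(exons) || length(exons) == 0L)
      stopf("exon_skipping requires the skipped exon indices")
    exons <- sort(as.integer(exons))
    if (length(exons) > 1L && any(diff(exons) != 1L))
      stopf("skipped exons must be contiguous")
  } else {
    if (is.null(intron)) stopf("%s requires an intron index", type)
    intron <- as.integer(intron)
  }
  if (startsWith(type, "cryptic")) {
    if (is.null(distance) || distance == 0L)
      stopf("%s requires a non-zero distance from the canonical site", type)
    distance <- as.integer(distance)
  }
  structure(list(type = type, exons = exons, intron = intron,
                 distance = distance), class = "splice_event")
}

#' @export
print.splice_event <- function(x, ...) {
  cat("splice_event:", event_label(x), "\n")
  invisible(x)
}

#' Compact machine label for a splice event
#' @param event A `splice_event`.
#' @return A string such as `"exon_skipping:3"` or `"cryptic_acceptor:6:-49"`.
#' @export
event_label <- function(event) {
  if (is.null(event)) return("canonical")
  switch(event$type,
         exon_skipping = paste0("exon_skipping:", paste(event$exons, collapse = ",")),
         intron_retention = paste0("intron_retention:", event$intron),
         paste0(event$type, ":", event$intron, ":", event$distance))
}

#' Parse a compact event label back into a `splice_event`
#' @param label A string as produced by [event_label()].
#' @return A `splice_event`, or `NULL` for `"canonical"`.
#' @export
parse_event <- function(label) {
  if (identical(label, "canonical")) return(NULL)
  parts <- strsplit(label, ":", fixed = TRUE)[[1L]]
  type <- parts[1L]
  if (type == "exon_skipping")
    return(splice_event(type, exons = as.integer(strsplit(parts[2L], ",")[[1L]])))
  if (type == "intron_retention")
    return(splice_event(type, intron = as.integer(parts[2L])))
  splice_event(type, intron = as.integer(parts[2L]), distance = as.integer(parts[3L]))
}

# exon chain (transcript order) of the canonical transcript
canonical_chain <- function(model) {
  data.frame(gstart = model$exons$gstart, gend = model$exons$gend)
}

chain_width <- function(chain) sum(chain$gend - chain$gstart + 1L)

# transcript position(s) of genomic coordinate(s) on a chain; NA when absent
map_g_to_chain <- function(chain, g, strand) {
  res <- rep(NA_integer_, length(g))
  cum <- 0L
  for (i in seq_len(nrow(chain))) {
    a <- chain$gstart[i]; b <- chain$gend[i]
    inside <- !is.na(g) & g >= a & g <= b
    res[inside] <- cum + if (strand == "+") g[inside] - a + 1L else b - g[inside] + 1L
    cum <- cum + (b - a + 1L)
  }
  res
}

#' Reconstruct the transcript implied by a splice event
#'
#' Exon skipping removes the skipped exon(s); intron retention keeps the
#' intron as a contiguous insert between its flanking exons; a cryptic donor
#' or acceptor moves one end of the affected junction to the cryptic position.
#'
#' @param model A `transcript_model`.
#' @param event A `splice_event`, or `NULL` for the canonical transcript.
#' @return A `variant_transcript` list: `event`, `chain` (genomic intervals in
#'   transcript order), `mrna` (a [Biostrings::DNAString] when sequence is
#'   loaded, else `NULL`), `cds_offset_change` (net coding-length change in
#'   bases) and `tx_cds_start` (position of `c.1` in the variant mRNA).
#' @examples
#' fx <- tp53_synthetic_fixture()
#' v <- reconstruct_variant_transcript(fx$model, splice_event("exon_skipping", exons = 3))
#' v$cds_offset_change  # -22
#' @export
reconstruct_variant_transcript <- function(model, event) {
  chain <- canonical_chain(model)
  n <- nrow(chain)
  plus <- model$strand == "+"
  introns <- model_introns(model)

  if (!is.null(event)) {
    stopifnot(inherits(event, "splice_event"))
    if (event$type == "exon_skipping") {
      if (any(event$exons <= 1L) || any(event$exons >= n))
        stopf("cannot skip exon(s) %s: the flanking junctions do not exist",
              paste(event$exons, collapse = ","))
      chain <- chain[-event$exons, , drop = FALSE]
    } else {
      k <- event$intron
      if (!k %in% introns$intron) stopf("no intron %d on '%s'", k, model$transcript_id)
      iw <- introns$width[introns$intron == k]
      if (event$type == "intron_retention") {
        merged <- data.frame(gstart = min(chain$gstart[k], chain$gstart[k + 1L]),
                             gend = max(chain$gend[k], chain$gend[k + 1L]))
        chain <- rbind(chain[seq_len(k - 1L), ], merged,
                       chain[setdiff(seq_len(n), seq_len(k + 1L)), ])
      } else if (event$type == "cryptic_acceptor") {
        d <- event$distance
        exw <- chain$gend[k + 1L] - chain$gstart[k + 1L] + 1L
        if (d <= -iw || d >= exw)
          stopf("cryptic acceptor distance %d outside intron %d / exon %d", d, k, k + 1L)
        if (plus) chain$gstart[k + 1L] <- chain$gstart[k + 1L] + d
        else chain$gend[k + 1L] <- chain$gend[k + 1L] - d
      } else {  # cryptic_donor
        d <- event$distance
        exw <- chain$gend[k] - chain$gstart[k] + 1L
        if (d >= iw || d <= -exw)
          stopf("cryptic donor distance %d outside exon %d / intron %d", d, k, k)
        if (plus) chain$gend[k] <- chain$gend[k] + d
        else chain$gstart[k] <- chain$gstart[k] - d
      }
    }
  }
  rownames(chain) <- NULL

  mrna <- NULL
  if (!is.null(model$genome)) {
    parts <- vapply(seq_len(nrow(chain)), function(i)
      as.character(tx_seq(model, chain$gstart[i], chain$gend[i])), character(1))
    mrna <- Biostrings::DNAString(paste(parts, collapse = ""))
  }
  g1 <- c_to_genomic(model, 1L)
  tx_cds_start <- map_g_to_chain(chain, g1, model$strand)
  if (is.na(tx_cds_start))
    stopf("event removes the translation start; not supported")
  structure(list(event = event, chain = chain, mrna = mrna,
                 cds_offset_change = chain_width(chain) - chain_width(canonical_chain(model)),
                 tx_cds_start = tx_cds_start),
            class = "variant_transcript")
}

#' @export
print.variant_transcript <- function(x, ...) {
  cat(sprintf("variant_transcript (%s): %d blocks, coding-length change %+d\n",
              event_label(x$event), nrow(x$chain), x$cds_offset_change))
  invisible(x)
}

# genomic coordinate of every CDS base, c.1 first
cds_genomic_positions <- function(model) {
  ex <- model$exons[!is.na(model$exons$coding_start_c), , drop = FALSE]
  unlist(lapply(seq_len(nrow(ex)), function(i) {
    if (model$strand == "+") ex$cstart_g[i]:ex$cend_g[i] else ex$cend_g[i]:ex$cstart_g[i]
  }), use.names = FALSE)
}

#' Predict the protein-level consequence of a variant transcript
#'
#' Translation proceeds from the canonical start codon through the variant
#' mRNA. A premature termination codon (PTC) is any in-frame stop whose
#' position is not that of the canonical termination codon. `aa_lost` counts
#' canonical codons destroyed by the event: codons with a base removed, or
#' whose bases are no longer contiguous in the variant transcript (hybrid
#' codons straddling a new junction). Degradation of PTC transcripts by
#' nonsense-mediated decay is deliberately not modelled.
#'
#' @param variant A `variant_transcript` (sequence must be present).
#' @param model The `transcript_model` it was derived from.
#' @return A `protein_consequence` list: `frame_disturbed`, `premature_stop`,
#'   `aa_lost`, `ptc_codon` (codon index of the PTC, or `NA`), and
#'   `protein_class` (`full_length`, `truncated`, `inframe_loss`,
#'   `frameshift_no_ptc`).
#' @examples
#' fx <- tp53_synthetic_fixture()
#' v <- reconstruct_variant_transcript(fx$model,
#'   splice_event("cryptic_acceptor", intron = 4, distance = 21))
#' predict_consequence(v, fx$model)$aa_lost  # 7
#' @export
predict_consequence <- function(variant, model) {
  stopifnot(inherits(variant, "variant_transcript"))
  if (is.null(variant$mrna))
    stopf("variant mRNA sequence is required for consequence prediction")
  no_event <- is.null(variant$event)

  s <- variant$tx_cds_start
  seq_chr <- as.character(variant$mrna)
  cds_chr <- substring(seq_chr, s, nchar(seq_chr))
  codons <- split_codons(cds_chr)
  stops <- which(codons %in% STOP_CODONS)
  first_stop <- if (length(stops)) stops[1L] else NA_integer_

  # transcript position of the canonical termination codon in this variant
  g_stop <- c_to_genomic(model, model$cds_end_c - 2L)
  tx_stop <- map_g_to_chain(variant$chain, g_stop, model$strand)
  stop_tx_of_first <- if (is.na(first_stop)) NA_integer_ else s + 3L * (first_stop - 1L)
  premature <- !is.na(first_stop) &&
    (is.na(tx_stop) || stop_tx_of_first != tx_stop)

  frame_disturbed <- (variant$cds_offset_change %% 3L) != 0L

  # canonical codons destroyed by the event
  gpos <- cds_genomic_positions(model)
  txpos <- map_g_to_chain(variant$chain, gpos, model$strand)
  ncod <- model$cds_end_c %/% 3L
  idx <- matrix(seq_len(3L * ncod), nrow = 3L)
  destroyed <- vapply(seq_len(ncod - 1L), function(j) {
    t3 <- txpos[idx[, j]]
    any(is.na(t3)) || t3[2L] != t3[1L] + 1L || t3[3L] != t3[2L] + 1L
  }, logical(1))
  aa_lost <- sum(destroyed)

  protein_class <- if (no_event && !premature) "full_length"
  else if (premature) "truncated"
  else if (frame_disturbed) "frameshift_no_ptc"
  else if (aa_lost > 0L) "inframe_loss"
  else "full_length"

  structure(list(frame_disturbed = frame_disturbed && !no_event,
                 premature_stop = premature,
                 aa_lost = aa_lost,
                 ptc_codon = if (premature) first_stop else NA_integer_,
                 protein_class = protein_class),
            class = "protein_consequence")
}

#' @export
print.protein_consequence <- function(x, ...) {
  cat(sprintf("protein_consequence: %s | frame disturbed: %s | PTC: %s%s | AAs lost: %d\n",
              x$protein_class, x$frame_disturbed, x$premature_stop,
              if (!is.na(x$ptc_codon)) sprintf(" (codon %d)", x$ptc_codon) else "",
              x$aa_lost))
  invisible(x)
}

#' Label a variant transcript with a named isoform, if catalogued
#'
#' Returns the label only on an exact match of gene, event type and event
#' coordinates. The shipped catalogue contains the truncated TP53 isoform
#' p53psi (cryptic acceptor 49 bp upstream of the canonical intron 6
#' acceptor).
#'
#' @param variant A `variant_transcript`.
#' @param model The `transcript_model`.
#' @param catalog Optional catalogue (list of entries with `label`, `gene`,
#'   `event_type`, `intron`, `distance`); defaults to the one shipped with
#'   the package.
#' @return The isoform label, or `NA_character_` when no entry matches.
#' @export
annotate_named_isoform <- function(variant, model, catalog = NULL) {
  if (is.null(catalog)) catalog <- named_isoform_catalog()
  ev <- variant$event
  if (is.null(ev) || !startsWith(ev$type, "cryptic")) return(NA_character_)
  for (entry in catalog) {
    if (identical(entry$gene, model$gene_id) &&
        identical(entry$event_type, ev$type) &&
        identical(as.integer(entry$intron), ev$intron) &&
        identical(as.integer(entry$distance), ev$distance))
      return(entry$label)
  }
  NA_character_
}

#' The packaged named-isoform catalogue
#' @return A list of catalogue entries.
#' @export
named_isoform_catalog <- function() {
  jsonlite::fromJSON(system.file("extdata", "named_isoforms.json",
                                 package = "splicetx"),
                     simplifyVector = FALSE)
}

#' Consequence table for a set of declared events
#'
#' Reconstructs and predicts each event independently and returns one row per
#' event, mirroring a clinical variant table (frame / PTC / protein class).
#'
#' @param model A `transcript_model` with sequence.
#' @param events A list of `splice_event` objects (or compact labels).
#' @return A data frame with columns `event`, `frame_disturbed`,
#'   `premature_stop`, `aa_lost`, `ptc_codon`, `protein_class`,
#'   `named_isoform`.
#' @export
consequence_table <- function(model, events) {
  rows <- lapply(events, function(ev) {
    if (is.character(ev)) ev <- parse_event(ev)
    v <- reconstruct_variant_transcript(model, ev)
    p <- predict_consequence(v, model)
    data.frame(event = event_label(ev),
               frame_disturbed = p$frame_disturbed,
               premature_stop = p$premature_stop,
               aa_lost = p$aa_lost, ptc_codon = p$ptc_codon,
               protein_class = p$protein_class,
               named_isoform = annotate_named_isoform(v, model),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
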