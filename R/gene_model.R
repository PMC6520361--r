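# gene_model: transcript models, genomic sequence access, and conversion
# between genomic and CDS (HGVS c.) coordinates.
#
# All coordinates are 1-based closed intervals, the Bioconductor convention.
# Exons are stored in transcript order (5' to 3' of the mRNA), so for a
# minus-strand gene exon 1 sits at the genomic right end.

#' Load a transcript model from annotation and sequence files
#'
#' Reads exon and CDS features for one transcript from a GTF or GFF3 file and
#' (optionally) the genomic sequence from a FASTA file, and assembles a
#' transcript model against which splice mutations, junction evidence and
#' protein consequences are computed.
#'
#' @param annotation Path to a GTF or GFF3 file containing `exon` and `CDS`
#'   features for the transcript.
#' @param fasta Optional path to the genomic FASTA. Required for operations
#'   that inspect sequence (cryptic-site scanning, consequence prediction).
#' @param transcript_id Identifier of the transcript to load.
#' @return An object of class `transcript_model`: a list with elements
#'   `transcript_id`, `gene_id`, `contig`, `strand`, `exons` (a data frame in
#'   transcript order with genomic bounds `gstart`/`gend`, coding genomic
#'   bounds `cstart_g`/`cend_g` and coding CDS span `coding_start_c`/
#'   `coding_end_c`), `cds_end_c` (CDS length) and `genome` (a
#'   [Biostrings::DNAStringSet] or `NULL`).
#' @examples
#' fx <- simulate_gene(seed = 1, n_exons = 3)
#' model <- load_gene_model(fx$gtf, fx$fasta, fx$transcript_id)
#' model$cds_end_c %% 3  # CDS length is a multiple of three
#' @export
load_gene_model <- function(annotation, fasta = NULL, transcript_id) {
  gr <- rtracklayer::import(annotation)
  mc <- S4Vectors::mcols(gr)
  tx <- if ("transcript_id" %in% names(mc)) {
    as.character(mc$transcript_id)
  } else if ("Parent" %in% names(mc)) {
    vapply(mc$Parent, function(p) if (length(p)) as.character(p[[1L]]) else NA_character_,
           character(1))
  } else {
    stopf("annotation '%s' carries neither transcript_id nor Parent attributes", annotation)
  }
  type <- as.character(mc$type)
  keep <- !is.na(tx) & tx == transcript_id
  ex_gr <- gr[keep & type == "exon"]
  cds_gr <- gr[keep & type == "CDS"]
  if (length(ex_gr) == 0L)
    stopf("transcript '%s' not found in '%s'", transcript_id, annotation)
  if (length(cds_gr) == 0L)
    stopf("transcript '%s' has no CDS features", transcript_id)

  strand <- unique(as.character(BiocGenerics::strand(ex_gr)))
  contig <- unique(as.character(GenomicRanges::seqnames(ex_gr)))
  if (length(strand) != 1L || length(contig) != 1L || !strand %in% c("+", "-"))
    stopf("transcript '%s' must lie on one contig and one strand", transcript_id)

  ex <- data.frame(gstart = BiocGenerics::start(ex_gr), gend = BiocGenerics::end(ex_gr))
  ex <- ex[order(ex$gstart, decreasing = (strand == "-")), , drop = FALSE]
  ex$index <- seq_len(nrow(ex))

  cds <- data.frame(gstart = BiocGenerics::start(cds_gr), gend = BiocGenerics::end(cds_gr))
  cds <- cds[order(cds$gstart, decreasing = (strand == "-")), , drop = FALSE]

  # every CDS piece must be contained in exactly one exon
  ex$cstart_g <- NA_integer_; ex$cend_g <- NA_integer_
  for (i in seq_len(nrow(cds))) {
    host <- which(ex$gstart <= cds$gstart[i] & ex$gend >= cds$gend[i])
    if (length(host) != 1L)
      stopf("CDS piece %d-%d of '%s' is not contained in an exon",
            cds$gstart[i], cds$gend[i], transcript_id)
    if (!is.na(ex$cstart_g[host]))
      stopf("exon %d of '%s' holds more than one CDS piece", host, transcript_id)
    ex$cstart_g[host] <- cds$gstart[i]
    ex$cend_g[host] <- cds$gend[i]
  }

  # assign cumulative CDS (c.) spans in transcript order
  ex$coding_start_c <- NA_integer_; ex$coding_end_c <- NA_integer_
  at <- 0L
  for (i in seq_len(nrow(ex))) {
    if (is.na(ex$cstart_g[i])) next
    w <- ex$cend_g[i] - ex$cstart_g[i] + 1L
    ex$coding_start_c[i] <- at + 1L
    ex$coding_end_c[i] <- at + w
    at <- at + w
  }
  if (at %% 3L != 0L)
    stopf("CDS of '%s' has length %d, not a multiple of 3", transcript_id, at)
  coding <- which(!is.na(ex$coding_start_c))
  if (any(diff(coding) != 1L))
    stopf("coding exons of '%s' are not contiguous in transcript order", transcript_id)

  gene_id <- if ("gene_id" %in% names(mc)) {
    gid <- as.character(mc$gene_id)[keep & type == "exon"]
    unique(gid)[1L]
  } else NA_character_

  genome <- NULL
  if (!is.null(fasta)) {
    genome <- Biostrings::readDNAStringSet(fasta)
    names(genome) <- sub("\\s.*$", "", names(genome))
    if (!contig %in% names(genome))
      stopf("contig '%s' not present in FASTA '%s'", contig, fasta)
  }

  model <- structure(
    list(transcript_id = transcript_id, gene_id = gene_id, contig = contig,
         strand = strand,
         exons = ex[, c("index", "gstart", "gend", "cstart_g", "cend_g",
                        "coding_start_c", "coding_end_c")],
         cds_end_c = at, genome = genome),
    class = "transcript_model")
  if (!is.null(genome)) validate_model_sequence(model)
  model
}

validate_model_sequence <- function(model) {
  cds <- as.character(spliced_cds(model))
  if (substr(cds, 1L, 3L) != "ATG")
    stopf("spliced CDS of '%s' does not begin with a start codon", model$transcript_id)
  last <- substr(cds, nchar(cds) - 2L, nchar(cds))
  if (!last %in% STOP_CODONS)
    stopf("spliced CDS of '%s' does not end with a stop codon", model$transcript_id)
  invisible(model)
}

#' @export
print.transcript_model <- function(x, ...) {
  ncod <- sum(!is.na(x$exons$coding_start_c))
  cat(sprintf("transcript_model %s (%s) on %s [%s]\n", x$transcript_id,
              x$gene_id %||% NA, x$contig, x$strand))
  cat(sprintf("  %d exons (%d coding), CDS length %d (%d codons incl. stop)\n",
              nrow(x$exons), ncod, x$cds_end_c, x$cds_end_c %/% 3L))
  cat(sprintf("  sequence: %s\n", if (is.null(x$genome)) "absent" else "loaded"))
  invisible(x)
}

# genomic sequence of [gstart, gend], oriented in transcript direction
tx_seq <- function(model, gstart, gend) {
  if (is.null(model$genome)) stopf("no sequence loaded for '%s'", model$transcript_id)
  contig <- model$genome[[model$contig]]
  if (gstart < 1L || gend > length(contig) || gstart > gend)
    stopf("sequence lookup [%d, %d] outside contig bounds (1-%d)",
          gstart, gend, length(contig))
  s <- Biostrings::subseq(contig, gstart, gend)
  if (model$strand == "-") s <- Biostrings::reverseComplement(s)
  s
}

#' Spliced CDS sequence of a transcript model
#'
#' @param model A `transcript_model` with sequence loaded.
#' @return A [Biostrings::DNAString] of the coding sequence, `c.1` first.
#' @export
spliced_cds <- function(model) {
  ex <- model$exons[!is.na(model$exons$coding_start_c), , drop = FALSE]
  parts <- lapply(seq_len(nrow(ex)), function(i)
    tx_seq(model, ex$cstart_g[i], ex$cend_g[i]))
  Biostrings::DNAString(paste(vapply(parts, as.character, character(1)), collapse = ""))
}

# intron table in transcript order; intron k separates exon k from exon k+1
model_introns <- function(model) {
  ex <- model$exons
  n <- nrow(ex)
  if (n < 2L) return(data.frame(intron = integer(0)))
  up <- ex[-n, ]; dn <- ex[-1L, ]
  if (model$strand == "+") {
    gstart <- up$gend + 1L; gend <- dn$gstart - 1L
    donor_g <- gstart; acceptor_g <- gend
  } else {
    gstart <- dn$gend + 1L; gend <- up$gstart - 1L
    donor_g <- gend; acceptor_g <- gstart
  }
  data.frame(intron = up$index, gstart = gstart, gend = gend,
             donor_g = donor_g, acceptor_g = acceptor_g,
             width = gend - gstart + 1L)
}

#' Genomic interval of an intron
#'
#' @param model A `transcript_model`.
#' @param intron Intron index; intron `k` lies between exons `k` and `k+1`.
#' @return A list with `contig`, `start`, `end` (1-based, closed).
#' @export
intron_region <- function(model, intron) {
  ir <- model_introns(model)
  row <- ir[ir$intron == intron, , drop = FALSE]
  if (nrow(row) != 1L) stopf("transcript '%s' has no intron %s", model$transcript_id, intron)
  list(contig = model$contig, start = row$gstart, end = row$gend)
}

# parse "376-1", "c.96+1", "1182" into list(pos, offset)
parse_c_position <- function(x) {
  x <- gsub("–|−|—", "-", trimws(x))
  m <- regmatches(x, regexec("^(?:c\\.)?(\\d+)([+-]\\d+)?$", x))[[1L]]
  if (length(m) == 0L) stopf("cannot parse coding position '%s'", x)
  list(pos = as.integer(m[2L]),
       offset = if (nzchar(m[3L])) as.integer(m[3L]) else 0L)
}

format_c_position <- function(pos, offset = 0L) {
  paste0("c.", pos, if (offset > 0L) paste0("+", offset) else if (offset < 0L) offset else "")
}

#' Convert a CDS (HGVS c.) position to a genomic coordinate
#'
#' Intronic offsets are resolved relative to the flanking exon boundary:
#' `c.X+n` is the n-th intronic base after the exon whose last coding position
#' is `X` (donor side), `c.X-n` the n-th intronic base before the exon whose
#' first coding position is `X` (acceptor side).
#'
#' @param model A `transcript_model`.
#' @param position CDS position (integer), or a string such as `"c.376-1"`
#'   (in which case `offset` is ignored).
#' @param offset Signed intronic offset; 0 for exonic positions.
#' @return The 1-based genomic coordinate.
#' @examples
#' fx <- tp53_synthetic_fixture()
#' c_to_genomic(fx$model, "c.376-1")  # last base of intron 4
#' @export
c_to_genomic <- function(model, position, offset = 0L) {
  if (is.character(position)) {
    p <- parse_c_position(position)
    position <- p$pos; offset <- p$offset
  }
  position <- as.integer(position); offset <- as.integer(offset)
  if (is.na(position) || position < 1L || position > model$cds_end_c)
    stopf("coding position %s is outside c.1-c.%d", position, model$cds_end_c)
  ex <- model$exons
  host <- which(!is.na(ex$coding_start_c) &
                  ex$coding_start_c <= position & ex$coding_end_c >= position)
  if (length(host) != 1L)
    stopf("coding position %d not covered by any exon", position)
  plus <- model$strand == "+"
  if (offset == 0L) {
    d <- position - ex$coding_start_c[host]
    return(if (plus) ex$cstart_g[host] + d else ex$cend_g[host] - d)
  }
  introns <- model_introns(model)
  if (offset > 0L) {
    if (position != ex$coding_end_c[host])
      stopf("donor offset +%d attached to c.%d, which is not an exon boundary",
            offset, position)
    k <- ex$index[host]
    iw <- introns$width[introns$intron == k]
    if (length(iw) == 0L) stopf("exon %d has no downstream intron", k)
    if (offset > iw) stopf("offset +%d exceeds intron %d length (%d)", offset, k, iw)
    return(if (plus) ex$gend[host] + offset else ex$gstart[host] - offset)
  }
  if (position != ex$coding_start_c[host])
    stopf("acceptor offset %d attached to c.%d, which is not an exon boundary",
          offset, position)
  k <- ex$index[host] - 1L
  iw <- introns$width[introns$intron == k]
  if (length(iw) == 0L) stopf("exon %d has no upstream intron", ex$index[host])
  if (-offset > iw) stopf("offset %d exceeds intron %d length (%d)", offset, k, iw)
  if (plus) ex$gstart[host] + offset else ex$gend[host] - offset
}

#' Convert a genomic coordinate to a CDS position with intronic offset
#'
#' Inverse of [c_to_genomic()]. Exonic coding bases map to a pure `c.`
#' position; intronic bases map to the nearer exon boundary (donor `+n` for
#' the 5' half of the intron, acceptor `-n` for the 3' half).
#'
#' @param model A `transcript_model`.
#' @param genomic 1-based genomic coordinate.
#' @return A list with `pos`, `offset` and formatted `label`.
#' @export
genomic_to_c <- function(model, genomic) {
  genomic <- as.integer(genomic)
  ex <- model$exons
  plus <- model$strand == "+"
  host <- which(!is.na(ex$cstart_g) & ex$cstart_g <= genomic & ex$cend_g >= genomic)
  if (length(host) == 1L) {
    pos <- ex$coding_start_c[host] +
      (if (plus) genomic - ex$cstart_g[host] else ex$cend_g[host] - genomic)
    return(list(pos = pos, offset = 0L, label = format_c_position(pos)))
  }
  introns <- model_introns(model)
  hit <- which(introns$gstart <= genomic & introns$gend >= genomic)
  if (length(hit) != 1L)
    stopf("genomic position %d is not in a coding exon or an intron of '%s'",
          genomic, model$transcript_id)
  k <- introns$intron[hit]
  up <- ex[ex$index == k, ]; dn <- ex[ex$index == k + 1L, ]
  d_donor <- if (plus) genomic - up$gend else up$gstart - genomic
  d_acc <- if (plus) dn$gstart - genomic else genomic - dn$gend
  # a boundary is usable only when the exon edge facing this intron is coding
  donor_ok <- !is.na(up$coding_end_c) &&
    (if (plus) up$cend_g == up$gend else up$cstart_g == up$gstart)
  acc_ok <- !is.na(dn$coding_start_c) &&
    (if (plus) dn$cstart_g == dn$gstart else dn$cend_g == dn$gend)
  if (!donor_ok && !acc_ok)
    stopf("genomic position %d lies in intron %d, which has no coding boundary", genomic, k)
  use_donor <- donor_ok && (!acc_ok || d_donor <= d_acc)
  if (use_donor) {
    list(pos = up$coding_end_c, offset = d_donor,
         label = format_c_position(up$coding_end_c, d_donor))
  } else {
    list(pos = dn$coding_start_c, offset = -d_acc,
         label = format_c_position(dn$coding_start_c, -d_acc))
  }
}
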