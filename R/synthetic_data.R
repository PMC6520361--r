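# synthetic_data: deterministic toy gene models and aligned-read simulations
# with known mixtures of canonical and aberrant transcripts, plus the packaged
# cohort fixtures. Everything is generated in code; no binary assets.

SENSE_CODONS <- setdiff(
  as.vector(outer(as.vector(outer(c("A", "C", "G", "T"), c("A", "C", "G", "T"), paste0)),
                  c("A", "C", "G", "T"), paste0)),
  STOP_CODONS)

filler_seq <- function(n, unit = "TTTCC") {
  paste(rep_len(strsplit(unit, "")[[1L]], n), collapse = "")
}

revcomp_chr <- function(s) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
}

# write a one-contig FASTA and a GTF with exon + CDS features
write_gene_files <- function(dir, contig, genome_seq, strand, gene_id,
                             transcript_id, exons) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  fasta <- file.path(dir, paste0(contig, ".fa"))
  seqs <- Biostrings::DNAStringSet(genome_seq)
  names(seqs) <- contig
  Biostrings::writeXStringSet(seqs, fasta, width = 70L)

  gtf <- file.path(dir, paste0(transcript_id, ".gtf"))
  attrs <- sprintf('gene_id "%s"; transcript_id "%s";', gene_id, transcript_id)
  rows <- character(0)
  for (i in seq_len(nrow(exons))) {
    rows <- c(rows, paste(contig, "splicetx", "exon", exons$gstart[i], exons$gend[i],
                          ".", strand, ".", attrs, sep = "\t"))
    if (!is.na(exons$cstart_g[i])) {
      frame <- (3L - ((exons$coding_start_c[i] - 1L) %% 3L)) %% 3L
      rows <- c(rows, paste(contig, "splicetx", "CDS", exons$cstart_g[i], exons$cend_g[i],
                            ".", strand, frame, attrs, sep = "\t"))
    }
  }
  writeLines(rows, gtf)
  list(fasta = fasta, gtf = gtf)
}

# exon genomic coordinates from pre-mRNA segment positions
exon_coords_from_premrna <- function(starts, ends, strand, flank, premrna_len) {
  if (strand == "+") {
    data.frame(gstart = flank + starts, gend = flank + ends)
  } else {
    data.frame(gstart = flank + premrna_len - ends + 1L,
               gend = flank + premrna_len - starts + 1L)
  }
}

#' Simulate a toy gene model
#'
#' Builds a fully coding multi-exon gene with valid GT/AG splice sites at
#' every junction, a CDS that is a multiple of three beginning with a start
#' codon and ending with a stop codon, writes it as GTF + FASTA, and loads it
#' back through [load_gene_model()] so the public readers are exercised.
#'
#' @param seed Integer seed; the gene is deterministic given the seed.
#' @param n_exons Number of exons (at least 2).
#' @param exon_lengths,intron_lengths Optional explicit lengths; defaults are
#'   drawn from the seed. The exon-length sum is padded to a multiple of 3.
#' @param strand `"+"` or `"-"`.
#' @param dir Output directory for the FASTA/GTF pair.
#' @param contig,gene_id,transcript_id Identifiers used in the files.
#' @param flank Plain-sequence flank on each side of the gene.
#' @return A list with `model`, `gtf`, `fasta`, `transcript_id`, and the
#'   realised `exon_lengths`/`intron_lengths`.
#' @export
simulate_gene <- function(seed = 1L, n_exons = 4L, exon_lengths = NULL,
                          intron_lengths = NULL, strand = "+",
                          dir = tempfile("toygene"), contig = "toy1",
                          gene_id = "TOY1", transcript_id = "toy1.t1",
                          flank = 200L) {
  if (n_exons < 2L) stopf("a spliced gene needs at least 2 exons")
  local_seed(seed, {
    if (is.null(exon_lengths))
      exon_lengths <- sample(60:150, n_exons, replace = TRUE)
    if (length(exon_lengths) != n_exons) stopf("need %d exon lengths", n_exons)
    pad <- (3L - sum(exon_lengths) %% 3L) %% 3L
    exon_lengths[n_exons] <- exon_lengths[n_exons] + pad
    if (any(exon_lengths < 3L)) stopf("exon lengths below 3 are infeasible")
    if (is.null(intron_lengths))
      intron_lengths <- sample(60:200, n_exons - 1L, replace = TRUE)
    if (length(intron_lengths) != n_exons - 1L) stopf("need %d intron lengths", n_exons - 1L)
    if (any(intron_lengths < 10L)) stopf("intron lengths below 10 are infeasible")

    ncod <- sum(exon_lengths) %/% 3L
    cds <- paste0("ATG",
                  paste(sample(SENSE_CODONS, ncod - 2L, replace = TRUE), collapse = ""),
                  sample(STOP_CODONS, 1L))
    rand_seq <- function(n) paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                                  collapse = "")
    introns <- vapply(intron_lengths, function(L)
      paste0("GT", rand_seq(L - 4L), "AG"), character(1))

    at <- 0L; segs <- character(0)
    starts <- integer(n_exons); ends <- integer(n_exons)
    pos <- 0L
    for (i in seq_len(n_exons)) {
      exon <- substring(cds, at + 1L, at + exon_lengths[i])
      at <- at + exon_lengths[i]
      starts[i] <- pos + 1L; ends[i] <- pos + exon_lengths[i]
      pos <- ends[i]
      segs <- c(segs, exon)
      if (i < n_exons) {
        segs <- c(segs, introns[i])
        pos <- pos + intron_lengths[i]
      }
    }
    premrna <- paste(segs, collapse = "")
    genome_seq <- paste0(rand_seq(flank),
                         if (strand == "+") premrna else revcomp_chr(premrna),
                         rand_seq(flank))
    ex <- exon_coords_from_premrna(starts, ends, strand, flank, nchar(premrna))
    ex$cstart_g <- ex$gstart; ex$cend_g <- ex$gend
    ex$coding_start_c <- c(0L, cumsum(exon_lengths))[seq_len(n_exons)] + 1L
    ex$coding_end_c <- cumsum(exon_lengths)
    files <- write_gene_files(dir, contig, genome_seq, strand, gene_id,
                              transcript_id, ex)
    model <- load_gene_model(files$gtf, files$fasta, transcript_id)
    list(model = model, gtf = files$gtf, fasta = files$fasta,
         transcript_id = transcript_id, exon_lengths = exon_lengths,
         intron_lengths = intron_lengths)
  })
}

.fx_cache <- new.env(parent = emptyenv())

#' The synthetic TP53-like reference fixture
#'
#' A minus-strand gene whose coding exon architecture follows the TP53
#' reference transcript NM_000546.4 (noncoding exon 1; coding exons 2-11 with
#' CDS spans c.1-74, 75-96, 97-375, 376-559, 560-672, 673-782, 783-919,
#' 920-993, 994-1100, 1101-1182). The nucleotide sequence is fully synthetic:
#' it is engineered so that the splice-site dinucleotides are canonical, a
#' cryptic acceptor ends 21 bases into exon 5 (AG at c.395-396), a cryptic
#' acceptor ends 24 bases into exon 8 (AG at c.805-806), a cryptic acceptor
#' sits 49 bases upstream of the canonical intron 6 acceptor (the p53psi
#' junction), a cryptic donor GT sits at c.550-551, and each of introns 4-8
#' carries an early in-frame stop codon when retained. Intron lengths are
#' chosen so that retention of introns 4, 6 and 8 preserves the reading frame
#' while retention of introns 5 and 7 disturbs it.
#'
#' @param dir Output directory; `NULL` (default) builds once per session in a
#'   temporary directory and caches the result.
#' @return A list with `model` (a `transcript_model`, gene id `TP53`),
#'   `gtf` and `fasta` paths, and `transcript_id`.
#' @export
tp53_synthetic_fixture <- function(dir = NULL) {
  cached <- is.null(dir)
  if (cached && !is.null(.fx_cache$tp53) && file.exists(.fx_cache$tp53$fasta))
    return(.fx_cache$tp53)
  dir <- dir %||% tempfile("tp53fx")

  coding_len <- c(74L, 22L, 279L, 184L, 113L, 110L, 137L, 74L, 107L, 82L)
  intron_len <- c(200L, 113L, 119L, 300L, 250L, 150L, 200L, 180L, 140L, 130L)
  exon1_len <- 100L

  # CDS: pyrimidine-only codon filler, then deterministic patches that place
  # the start/stop codons, the cryptic splice sites and the variant-frame
  # stop codons that give each aberrant transcript its documented outcome
  cds <- strsplit(paste(rep_len(c("CTT", "CCT", "TCT", "CTC"), 394L), collapse = ""),
                  "")[[1L]]
  patch <- function(x, at, s) { x[at:(at + nchar(s) - 1L)] <- strsplit(s, "")[[1L]]; x }
  cds <- patch(cds, 1L, "ATG")
  cds <- patch(cds, 98L, "TGA")                       # stop seen after exon 3 skipping
  cds <- patch(cds, 376L, "CTTCTTCTTCTTCTTCTTCAG")    # exon 5 head; AG ends at c.396
  cds <- patch(cds, 550L, "GT")                       # cryptic donor in exon 5
  cds <- patch(cds, 560L, "TAA")                      # stop seen after that donor
  cds <- patch(cds, 675L, "TAA")                      # stop seen after exon 6 skipping
  cds <- patch(cds, 781L, "CC")
  cds <- patch(cds, 783L, "TTCTTTCTTCTTTCTTCTTTCTAG")  # exon 8 head; AG ends at c.806
  cds <- patch(cds, 807L, "A")
  cds <- patch(cds, 921L, "TGA")                      # stop seen after exon 8 skipping
  cds <- patch(cds, 996L, "TAA")                      # stop seen after exon 9 skipping
  cds <- patch(cds, 1180L, "TAA")                     # canonical stop
  cds <- paste(cds, collapse = "")

  make_intron <- function(L, patches = list()) {
    x <- strsplit(filler_seq(L), "")[[1L]]
    x[1:2] <- c("G", "T"); x[(L - 1L):L] <- c("A", "G")
    for (p in patches) x <- patch(x, p$at, p$s)
    paste(x, collapse = "")
  }
  introns <- list(
    make_intron(intron_len[1L]),
    make_intron(intron_len[2L]),
    make_intron(intron_len[3L]),
    make_intron(intron_len[4L], list(list(at = 4L, s = "TAA"))),
    make_intron(intron_len[5L], list(list(at = 3L, s = "TAA"))),
    make_intron(intron_len[6L], list(list(at = 4L, s = "TAA"),
                                     list(at = 100L, s = "AG"),   # p53psi acceptor
                                     list(at = 105L, s = "TAA"))),
    make_intron(intron_len[7L], list(list(at = 3L, s = "AA"))),
    make_intron(intron_len[8L], list(list(at = 3L, s = "TAG"))),
    make_intron(intron_len[9L]),
    make_intron(intron_len[10L])
  )

  cuts <- cumsum(coding_len)
  exon_seqs <- c(filler_seq(exon1_len),
                 substring(cds, c(1L, cuts[-10L] + 1L), cuts))
  segs <- character(0)
  n_ex <- 11L
  starts <- integer(n_ex); ends <- integer(n_ex); pos <- 0L
  for (i in seq_len(n_ex)) {
    starts[i] <- pos + 1L
    ends[i] <- pos + nchar(exon_seqs[i])
    pos <- ends[i]
    segs <- c(segs, exon_seqs[i])
    if (i < n_ex) { segs <- c(segs, introns[[i]]); pos <- pos + intron_len[i] }
  }
  premrna <- paste(segs, collapse = "")
  flank <- 300L
  genome_seq <- paste0(filler_seq(flank), revcomp_chr(premrna), filler_seq(flank))

  ex <- exon_coords_from_premrna(starts, ends, "-", flank, nchar(premrna))
  ex$cstart_g <- ex$gstart; ex$cend_g <- ex$gend
  ex$cstart_g[1L] <- NA_integer_; ex$cend_g[1L] <- NA_integer_
  ex$coding_start_c <- c(NA_integer_, c(0L, cuts[-10L]) + 1L)
  ex$coding_end_c <- c(NA_integer_, cuts)

  files <- write_gene_files(dir, "chr17fx", genome_seq, "-", "TP53", "TP53fx.1", ex)
  model <- load_gene_model(files$gtf, files$fasta, "TP53fx.1")
  out <- list(model = model, gtf = files$gtf, fasta = files$fasta,
              transcript_id = "TP53fx.1")
  if (cached) .fx_cache$tp53 <- out
  out
}

#' Packaged cohort fixture: 16 TP53 splice mutations
#'
#' The mutation list of the 16-sample splice-mutation cohort, with the HGVS
#' strings preserved in their printed dialects (en-dashes, spaces, length
#' suffixes).
#'
#' @return A data frame with `sample_no`, `splice_site_label`, `hgvs_c`.
#' @export
tp53_cohort_mutations <- function() {
  load_mutation_table(system.file("extdata", "tp53_cohort_mutations.tsv",
                                  package = "splicetx"))
}

#' Packaged fixture: declared aberrant transcript variants per sample
#'
#' One row per reported aberrant variant (samples 13-16, in which no aberrant
#' variant was detected, have no rows). `event` is a compact [event_label()]
#' string; the `*_printed` columns carry the published frame / PTC / protein
#' annotations for concordance checks.
#'
#' @return A data frame.
#' @export
tp53_cohort_variants <- function() {
  utils::read.delim(system.file("extdata", "tp53_cohort_variants.tsv",
                                package = "splicetx"),
                    stringsAsFactors = FALSE, fileEncoding = "UTF-8")
}

#' Write the cohort mutation fixture to a file
#'
#' @param path Optional output TSV path; when `NULL` the data frame is simply
#'   returned.
#' @return The fixture data frame, invisibly when written.
#' @export
make_cohort_fixture <- function(path = NULL) {
  df <- tp53_cohort_mutations()
  if (!is.null(path)) {
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                       fileEncoding = "UTF-8")
    return(invisible(df))
  }
  df
}

#' Convert SAM to a sorted, indexed BAM
#'
#' @param sam Path to a SAM file.
#' @return Path to the coordinate-sorted, indexed BAM.
#' @export
sam_to_bam <- function(sam) {
  stem <- sub("\\.sam$", "", sam)
  raw <- Rsamtools::asBam(sam, paste0(stem, "_raw"), indexDestination = FALSE,
                          overwrite = TRUE)
  sorted <- Rsamtools::sortBam(raw, stem)
  unlink(raw)
  Rsamtools::indexBam(sorted)
  sorted
}

# map a transcript-space interval [s, e] on a chain to ascending genomic
# blocks; chain given as precomputed piece bounds (t0/t1 transcript, a/b
# genomic); returns a 2-column matrix (gstart, gend)
tx_interval_to_blocks <- function(pieces, s, e, plus) {
  hit <- which(pieces$t0 <= e & pieces$t1 >= s)
  u0 <- pmax(s, pieces$t0[hit]); u1 <- pmin(e, pieces$t1[hit])
  if (plus) {
    m <- cbind(pieces$a[hit] + (u0 - pieces$t0[hit]),
               pieces$a[hit] + (u1 - pieces$t0[hit]))
  } else {
    m <- cbind(pieces$b[hit] - (u1 - pieces$t0[hit]),
               pieces$b[hit] - (u0 - pieces$t0[hit]))
  }
  m[order(m[, 1L]), , drop = FALSE]
}

blocks_to_cigar <- function(m) {
  w <- m[, 2L] - m[, 1L] + 1L
  n <- nrow(m)
  if (n == 1L) return(paste0(w, "M"))
  gaps <- m[-1L, 1L] - m[-n, 2L] - 1L
  if (any(gaps < 0L)) stopf("overlapping alignment blocks")
  paste0(paste0(w[-n], "M", ifelse(gaps > 0L, paste0(gaps, "N"), ""), collapse = ""),
         w[n], "M")
}

#' Simulate aligned RNA-seq reads for a transcript mixture
#'
#' Emits pre-aligned single-end reads (SAM, converted to a sorted indexed
#' BAM) for a mixture of the canonical transcript and aberrant variants at
#' given proportions, together with a truth table. Each variant is tiled at a
#' coverage depth proportional to its mixture fraction, so junction-spanning
#' read counts and intronic per-base depth are on a common scale: a variant
#' at fraction f contributes about `f * total_informative_reads` reads across
#' any point of its transcript. Junction reads carry N gap operations;
#' intron-retaining reads align contiguously across the intron.
#'
#' @param model A `transcript_model` with sequence loaded.
#' @param variants A list of `list(event =, fraction =)` entries; `event` is a
#'   `splice_event`, a compact label, or `NULL`/`"canonical"` for the
#'   canonical transcript. Fractions must sum to 1.
#' @param total_informative_reads Target depth at any informative position
#'   (junction or intronic base), summed over variants.
#' @param read_length Read length in bases.
#' @param seed Integer seed; output is deterministic given the seed.
#' @param dir Output directory.
#' @param coverage_model `"systematic"` (evenly spaced read starts with a
#'   random phase; the default uniform-coverage model) or `"random"`
#'   (independent uniform starts).
#' @param sample_id Sample name used in file names and the truth table.
#' @return A list with `sam`, `bam`, `truth` (data frame: `variant`,
#'   `fraction`, `n_reads`, `target_coverage`) and `truth_file`.
#' @export
simulate_reads <- function(model, variants, total_informative_reads = 200L,
                           read_length = 100L, seed = 1L,
                           dir = tempfile("sim"),
                           coverage_model = c("systematic", "random"),
                           sample_id = "sim") {
  coverage_model <- match.arg(coverage_model)
  if (total_informative_reads <= 0L) stopf("at least one read must be requested")
  if (read_length < 20L) stopf("read_length below 20 is not supported")
  fr <- vapply(variants, `[[`, numeric(1), "fraction")
  if (abs(sum(fr) - 1) > 1e-6) stopf("variant fractions must sum to 1")

  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  contig_chr <- as.character(model$genome[[model$contig]])
  contig_len <- nchar(contig_chr)
  plus <- model$strand == "+"
  qname <- character(0); rpos <- integer(0); cig <- character(0); rseq <- character(0)
  truth <- list()

  local_seed(seed, {
    for (vi in seq_along(variants)) {
      ev <- variants[[vi]]$event
      if (is.character(ev)) ev <- parse_event(ev)
      label <- event_label(ev)
      chain <- reconstruct_variant_transcript(model, ev)$chain
      w <- chain$gend - chain$gstart + 1L
      pieces <- list(a = chain$gstart, b = chain$gend,
                     t0 = cumsum(c(0L, w[-length(w)])) + 1L, t1 = cumsum(w))
      L <- sum(w)
      cov <- fr[vi] * total_informative_reads
      A <- L + read_length - 1L
      n <- round(cov * A / read_length)
      if (fr[vi] > 0 && n < 1L) n <- 1L
      starts <- if (n == 0L) integer(0) else if (coverage_model == "systematic") {
        step <- A / n
        as.integer(floor((2L - read_length) + stats::runif(1L, 0, step) +
                           step * (seq_len(n) - 1L)))
      } else {
        sample.int(A, n, replace = TRUE) + (1L - read_length)
      }
      kept <- 0L
      tag <- paste0(sample_id, "_", gsub("[^A-Za-z0-9]+", ".", label), "_")
      v_pos <- integer(length(starts))
      v_cig <- character(length(starts)); v_seq <- character(length(starts))
      for (j in seq_along(starts)) {
        s <- max(1L, starts[j]); e <- min(L, starts[j] + read_length - 1L)
        if (e - s + 1L < 20L) next
        blocks <- tx_interval_to_blocks(pieces, s, e, plus)
        kept <- kept + 1L
        v_pos[kept] <- blocks[1L, 1L]
        v_cig[kept] <- blocks_to_cigar(blocks)
        v_seq[kept] <- paste(substring(contig_chr, blocks[, 1L], blocks[, 2L]),
                             collapse = "")
      }
      v_qn <- paste0(tag, seq_len(kept))
      qname <- c(qname, v_qn); rpos <- c(rpos, v_pos[seq_len(kept)])
      cig <- c(cig, v_cig[seq_len(kept)]); rseq <- c(rseq, v_seq[seq_len(kept)])
      truth[[vi]] <- data.frame(variant = label, fraction = fr[vi], n_reads = kept,
                                target_coverage = cov, stringsAsFactors = FALSE)
    }
  })

  ord <- order(rpos)
  lines <- c(
    "@HD\tVN:1.6\tSO:coordinate",
    sprintf("@SQ\tSN:%s\tLN:%d", model$contig, contig_len),
    paste(qname[ord], 0L, model$contig, rpos[ord], 60L, cig[ord], "*", 0L, 0L,
          rseq[ord], "*", sep = "\t")
  )
  sam <- file.path(dir, paste0(sample_id, ".sam"))
  writeLines(lines, sam)
  bam <- sam_to_bam(sam)
  truth <- do.call(rbind, truth)
  truth_file <- file.path(dir, paste0(sample_id, "_truth.tsv"))
  utils::write.table(truth, truth_file, sep = "\t", quote = FALSE, row.names = FALSE)
  list(sam = sam, bam = bam, truth = truth, truth_file = truth_file)
}
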