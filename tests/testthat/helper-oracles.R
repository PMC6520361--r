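# Shared fixtures and independent oracles. The oracles work on SAM/FASTA text
# with base-R string operations only, so they share no code path with the
# package internals they check.

get_fx <- function() tp53_synthetic_fixture()

.toy_env <- new.env()
get_toy <- function(strand = "+") {
  key <- paste0("toy", strand)
  if (is.null(.toy_env[[key]]))
    .toy_env[[key]] <- simulate_gene(
      seed = 101, n_exons = 5,
      exon_lengths = c(60L, 45L, 90L, 33L, 60L),
      intron_lengths = c(80L, 70L, 90L, 60L),
      strand = strand,
      contig = if (strand == "+") "toyp" else "toym",
      transcript_id = if (strand == "+") "toyp.t1" else "toym.t1")
  .toy_env[[key]]
}

oracle_revcomp <- function(s) {
  paste(rev(strsplit(chartr("ACGTacgt", "TGCAtgca", s), "")[[1L]]), collapse = "")
}

read_fasta_seq <- function(path) {
  lines <- readLines(path)
  paste(lines[!startsWith(lines, ">")], collapse = "")
}

oracle_chain_seq <- function(genome_chr, chain, strand) {
  parts <- vapply(seq_len(nrow(chain)), function(i) {
    p <- substr(genome_chr, chain$gstart[i], chain$gend[i])
    if (strand == "-") oracle_revcomp(p) else p
  }, character(1))
  paste(parts, collapse = "")
}

oracle_first_stop <- function(cds) {
  n <- nchar(cds) %/% 3L
  for (i in seq_len(n)) {
    if (substr(cds, 3L * i - 2L, 3L * i) %in% c("TAA", "TAG", "TGA")) return(i)
  }
  NA_integer_
}

cigar_ops <- function(cigar) regmatches(cigar, gregexpr("\\d+[MIDNSHP=X]", cigar))[[1L]]

# every gap (N) operation in a SAM file, tallied by intronic interval
oracle_sam_gaps <- function(sam) {
  lines <- readLines(sam)
  lines <- lines[!startsWith(lines, "@")]
  out <- list()
  for (ln in lines) {
    f <- strsplit(ln, "\t", fixed = TRUE)[[1L]]
    at <- as.integer(f[4L])
    for (op in cigar_ops(f[6L])) {
      n <- as.integer(sub("[A-Z=]$", "", op))
      type <- sub("^\\d+", "", op)
      if (type %in% c("M", "D", "=", "X")) at <- at + n
      else if (type == "N") {
        out[[length(out) + 1L]] <- c(at, at + n - 1L)
        at <- at + n
      }
    }
  }
  if (!length(out))
    return(data.frame(start = integer(0), end = integer(0), n = integer(0)))
  m <- do.call(rbind, out)
  tab <- table(paste(m[, 1L], m[, 2L]))
  parts <- strsplit(names(tab), " ", fixed = TRUE)
  out <- data.frame(start = vapply(parts, function(p) as.integer(p[1L]), integer(1)),
                    end = vapply(parts, function(p) as.integer(p[2L]), integer(1)),
                    n = as.integer(tab))
  out[order(out$start, out$end), ]
}

# per-base depth over [start, end] from SAM text; N and D consume reference
# without adding depth
oracle_sam_pileup <- function(sam, start, end) {
  depth <- integer(end - start + 1L)
  lines <- readLines(sam)
  lines <- lines[!startsWith(lines, "@")]
  for (ln in lines) {
    f <- strsplit(ln, "\t", fixed = TRUE)[[1L]]
    at <- as.integer(f[4L])
    for (op in cigar_ops(f[6L])) {
      n <- as.integer(sub("[A-Z=]$", "", op))
      type <- sub("^\\d+", "", op)
      if (type %in% c("M", "=", "X")) {
        a <- max(at, start); b <- min(at + n - 1L, end)
        if (a <= b) {
          ix <- (a - start + 1L):(b - start + 1L)
          depth[ix] <- depth[ix] + 1L
        }
        at <- at + n
      } else if (type %in% c("D", "N")) at <- at + n
    }
  }
  depth
}

# brute-force consequence flags for a skip/retention event on a fully coding
# toy gene: reassemble the variant mRNA from the FASTA text and translate
oracle_consequence <- function(gene, event) {
  model <- gene$model
  genome_chr <- read_fasta_seq(gene$fasta)
  ex <- model$exons
  chain <- data.frame(gstart = ex$gstart, gend = ex$gend)
  if (event$type == "exon_skipping") {
    chain <- chain[-event$exons, ]
  } else if (event$type == "intron_retention") {
    k <- event$intron
    merged <- data.frame(gstart = min(chain$gstart[k:(k + 1L)]),
                         gend = max(chain$gend[k:(k + 1L)]))
    chain <- rbind(chain[seq_len(k - 1L), ], merged,
                   chain[-seq_len(k + 1L), ])
  } else {
    stop("oracle handles exon skips and intron retentions only")
  }
  v <- oracle_chain_seq(genome_chr, chain, model$strand)
  canon <- oracle_chain_seq(genome_chr,
                            data.frame(gstart = ex$gstart, gend = ex$gend),
                            model$strand)
  delta <- nchar(v) - nchar(canon)
  f <- oracle_first_stop(v)
  canonical_stop_start <- nchar(canon) - 2L
  list(frame_disturbed = (delta %% 3L) != 0L,
       premature_stop = !is.na(f) &&
         (3L * (f - 1L) + 1L) != canonical_stop_start + delta)
}
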