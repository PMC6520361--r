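# mutation_catalog: HGVS c. splice-mutation parsing, classification against a
# transcript model, and cohort summary statistics.
#
# The splice region is taken as the first ten and last ten nucleotides of each
# intron; the consensus sites are the invariant GT (donor, +1/+2) and AG
# (acceptor, -1/-2) dinucleotides.

C_POS_RE <- "(\\d+)([+-]\\d+)?"

#' Parse an HGVS coding-DNA splice-mutation description
#'
#' Accepts the common dialects seen in clinical tables: en-dash or hyphen for
#' the acceptor offset, optional spaces, and deletion/insertion length
#' suffixes (`del1`, `del14`, `ins6`) as well as explicit bases (`delA`,
#' `insCAT`).
#'
#' @param hgvs A string beginning with `"c."`, e.g. `"c.376-1G>A"`,
#'   `"c.560-9_564del14"`, `"c.782+3_782+4ins6"`.
#' @return A `splice_mutation` list with elements `hgvs_c` (as given),
#'   `edit_type` (`substitution`, `deletion`, `insertion_or_duplication`,
#'   `delins`), `start`/`end` (each `list(pos, offset)`), `length` (affected
#'   bases; `NA` when not derivable without a model), `ref`/`alt` (for
#'   substitutions), `offset` (signed offset of the first affected intronic
#'   base, 0 for purely exonic events) and `side` (`donor`, `acceptor`, or
#'   `NA` for purely exonic events). Exon assignment and site class are added
#'   by [classify_splice_mutation()].
#' @examples
#' parse_hgvs_c("c.376-1G>A")
#' parse_hgvs_c("c.782+3_782+4ins6")$edit_type
#' @export
parse_hgvs_c <- function(hgvs) {
  stopifnot(is.character(hgvs), length(hgvs) == 1L)
  norm <- gsub("–|−|—", "-", hgvs)
  norm <- gsub("[[:space:]]+", "", norm)
  if (!startsWith(norm, "c."))
    stopf("HGVS description '%s' does not begin with 'c.'", hgvs)
  body <- substring(norm, 3L)

  take <- function(re) {
    m <- regmatches(body, regexec(paste0("^", re, "$"), body))[[1L]]
    if (length(m)) m else NULL
  }
  pos_of <- function(p, o) list(pos = as.integer(p),
                                offset = if (nzchar(o)) as.integer(o) else 0L)

  edit_type <- NULL; start <- NULL; end <- NULL; len <- NA_integer_
  ref <- NA_character_; alt <- NA_character_

  if (!is.null(m <- take(paste0(C_POS_RE, "([ACGTacgt])>([ACGTacgt])")))) {
    edit_type <- "substitution"
    start <- end <- pos_of(m[2L], m[3L])
    ref <- toupper(m[4L]); alt <- toupper(m[5L]); len <- 1L
  } else if (!is.null(m <- take(paste0(C_POS_RE, "(?:_", C_POS_RE, ")?delins([ACGTacgt]+|\\d+)")))) {
    edit_type <- "delins"
    start <- pos_of(m[2L], m[3L])
    end <- if (nzchar(m[4L])) pos_of(m[4L], m[5L]) else start
    len <- span_length(start, end, NULL)
    alt <- if (grepl("^\\d+$", m[6L])) NA_character_ else toupper(m[6L])
  } else if (!is.null(m <- take(paste0(C_POS_RE, "(?:_", C_POS_RE, ")?del([ACGTacgt]+|\\d+)?")))) {
    edit_type <- "deletion"
    start <- pos_of(m[2L], m[3L])
    end <- if (nzchar(m[4L])) pos_of(m[4L], m[5L]) else start
    len <- span_length(start, end, m[6L])
  } else if (!is.null(m <- take(paste0(C_POS_RE, "(?:_", C_POS_RE, ")?(ins|dup)([ACGTacgt]+|\\d+)?")))) {
    edit_type <- "insertion_or_duplication"
    start <- pos_of(m[2L], m[3L])
    end <- if (nzchar(m[4L])) pos_of(m[4L], m[5L]) else start
    suffix <- m[7L]
    len <- if (nzchar(suffix)) {
      if (grepl("^\\d+$", suffix)) as.integer(suffix) else nchar(suffix)
    } else {
      span_length(start, end, NULL)  # bare dup: duplicated span
    }
    if (nzchar(suffix) && !grepl("^\\d+$", suffix)) alt <- toupper(suffix)
  } else {
    stopf("cannot parse HGVS description '%s': unrecognised token '%s'", hgvs, body)
  }

  anchor <- if (start$offset != 0L) start$offset else end$offset
  structure(
    list(hgvs_c = hgvs, edit_type = edit_type, start = start, end = end,
         length = len, ref = ref, alt = alt, offset = anchor,
         side = if (anchor > 0L) "donor" else if (anchor < 0L) "acceptor" else NA_character_),
    class = "splice_mutation")
}

# span length in bases when derivable without a transcript model
span_length <- function(start, end, suffix) {
  if (!is.null(suffix) && nzchar(suffix))
    return(if (grepl("^\\d+$", suffix)) as.integer(suffix) else nchar(suffix))
  if (identical(start, end)) return(1L)
  if (start$pos == end$pos)                      # both intronic, same anchor
    return(abs(end$offset - start$offset) + 1L)
  if (start$offset == 0L && end$offset == 0L)    # both exonic
    return(end$pos - start$pos + 1L)
  NA_integer_                                    # crosses a boundary; needs model
}

#' Classify a splice mutation against a transcript model
#'
#' Donor-side mutations are assigned the exon they terminate, acceptor-side
#' mutations the exon they precede. Single-base substitutions and single-base
#' deletions at intronic offsets +/-1 or +/-2 are consensus splice-site point
#' mutations; other single-base intronic events within the ten-base splice
#' region are splice-region mutations; multi-base events (deletions spanning a
#' boundary, insertions/duplications) are classified `boundary_spanning` and
#' never count as consensus point mutations.
#'
#' @param mut A `splice_mutation` from [parse_hgvs_c()].
#' @param model A `transcript_model`.
#' @return The mutation with `adjacent_exon`, `site_class` (one of
#'   `consensus_donor`, `consensus_acceptor`, `splice_region_donor`,
#'   `splice_region_acceptor`, `boundary_spanning`) and `is_consensus_point`
#'   added.
#' @examples
#' fx <- tp53_synthetic_fixture()
#' m <- classify_splice_mutation(parse_hgvs_c("c.919+1G>A"), fx$model)
#' m$site_class     # consensus_donor
#' m$adjacent_exon  # 8
#' @export
classify_splice_mutation <- function(mut, model) {
  stopifnot(inherits(mut, "splice_mutation"))
  if (is.na(mut$side))
    stopf("'%s' affects exonic bases only; purely exonic events are out of scope",
          mut$hgvs_c)
  if (abs(mut$offset) > 10L)
    stopf("'%s' anchors %d bases into the intron, outside the ten-base splice region",
          mut$hgvs_c, abs(mut$offset))
  anchor_pos <- if (mut$start$offset != 0L) mut$start$pos else mut$end$pos
  ex <- model$exons
  host <- if (mut$side == "donor") {
    which(!is.na(ex$coding_end_c) & ex$coding_end_c == anchor_pos)
  } else {
    which(!is.na(ex$coding_start_c) & ex$coding_start_c == anchor_pos)
  }
  if (length(host) != 1L)
    stopf("c.%d is not a %s-side exon boundary of '%s'", anchor_pos, mut$side,
          model$transcript_id)
  single <- !is.na(mut$length) && mut$length == 1L &&
    mut$edit_type %in% c("substitution", "deletion")
  mut$adjacent_exon <- ex$index[host]
  mut$site_class <- if (single && abs(mut$offset) <= 2L) {
    paste0("consensus_", mut$side)
  } else if (single) {
    paste0("splice_region_", mut$side)
  } else {
    "boundary_spanning"
  }
  mut$is_consensus_point <- startsWith(mut$site_class, "consensus")
  mut
}

#' @export
print.splice_mutation <- function(x, ...) {
  cat(sprintf("splice_mutation %s: %s", x$hgvs_c, x$edit_type))
  if (!is.null(x$site_class))
    cat(sprintf(" | %s, exon %d", x$site_class, x$adjacent_exon))
  cat(sprintf(" | side=%s offset=%s length=%s\n", x$side, x$offset, x$length))
  invisible(x)
}

#' Summarise a cohort of classified splice mutations
#'
#' @param mutations A list of classified `splice_mutation` objects
#'   (see [classify_splice_mutation()]).
#' @param total_mutations Optional total mutation count of the cohort
#'   (splice and exonic together); when given, the splice share is reported
#'   as a whole-number percentage.
#' @return A `cohort_summary` list of tallies: total mutations, consensus
#'   point mutations split by donor/acceptor and by substitution/single-base
#'   deletion, mutations adjacent to exons 5-8, a per-exon tally, and rounded
#'   percentages.
#' @examples
#' fx <- tp53_synthetic_fixture()
#' muts <- lapply(tp53_cohort_mutations()$hgvs_c, function(h)
#'   classify_splice_mutation(parse_hgvs_c(h), fx$model))
#' summarize_cohort(muts, total_mutations = 252)
#' @export
summarize_cohort <- function(mutations, total_mutations = NULL) {
  if (length(mutations) == 0L) stopf("cannot summarise an empty mutation list")
  ok <- vapply(mutations, function(m)
    inherits(m, "splice_mutation") && !is.null(m$site_class), logical(1))
  if (!all(ok)) stopf("all mutations must be classified (see classify_splice_mutation)")

  site <- vapply(mutations, `[[`, character(1), "site_class")
  side <- vapply(mutations, `[[`, character(1), "side")
  edit <- vapply(mutations, `[[`, character(1), "edit_type")
  exon <- vapply(mutations, `[[`, integer(1), "adjacent_exon")
  cons <- startsWith(site, "consensus")

  per_exon <- table(factor(exon, levels = sort(unique(exon))))
  out <- list(
    n_mutations = length(mutations),
    n_consensus_point = sum(cons),
    n_donor_consensus = sum(cons & side == "donor"),
    n_acceptor_consensus = sum(cons & side == "acceptor"),
    n_substitutions_at_consensus = sum(cons & edit == "substitution"),
    n_single_base_deletions_at_consensus = sum(cons & edit == "deletion"),
    n_adjacent_exons_5_to_8 = sum(exon >= 5L & exon <= 8L),
    per_exon = per_exon,
    pct_consensus = round(100 * sum(cons) / length(mutations)),
    pct_adjacent_exons_5_to_8 = round(100 * sum(exon >= 5L & exon <= 8L) / length(mutations))
  )
  if (!is.null(total_mutations)) {
    out$total_mutations <- as.integer(total_mutations)
    out$splice_share_pct <- round(100 * out$n_mutations / total_mutations)
  }
  structure(out, class = "cohort_summary")
}

#' @export
print.cohort_summary <- function(x, ...) {
  cat("Splice-mutation cohort summary\n")
  cat(sprintf("  mutations: %d", x$n_mutations))
  if (!is.null(x$splice_share_pct))
    cat(sprintf("  (%d%% of %d total mutations)", x$splice_share_pct, x$total_mutations))
  cat("\n")
  cat(sprintf("  consensus-site point mutations: %d (%d%%): %d donor, %d acceptor\n",
              x$n_consensus_point, x$pct_consensus,
              x$n_donor_consensus, x$n_acceptor_consensus))
  cat(sprintf("    of which %d substitutions, %d single-base deletions\n",
              x$n_substitutions_at_consensus, x$n_single_base_deletions_at_consensus))
  cat(sprintf("  adjacent to exons 5-8: %d (%d%%)\n",
              x$n_adjacent_exons_5_to_8, x$pct_adjacent_exons_5_to_8))
  cat("  per-exon tally: ",
      paste(sprintf("exon %s: %d", names(x$per_exon), as.integer(x$per_exon)),
            collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Write a cohort summary to JSON or TSV
#'
#' @param x A `cohort_summary`.
#' @param path Output file path.
#' @param format `"json"` or `"tsv"` (default guessed from the extension).
#' @return `path`, invisibly.
#' @export
write_cohort_summary <- function(x, path, format = NULL) {
  stopifnot(inherits(x, "cohort_summary"))
  format <- format %||% if (grepl("\\.json$", path)) "json" else "tsv"
  flat <- x[!vapply(x, is.table, logical(1))]
  flat$per_exon <- stats::setNames(as.integer(x$per_exon), names(x$per_exon))
  if (format == "json") {
    jsonlite::write_json(flat, path, auto_unbox = TRUE, digits = NA)
  } else {
    scal <- flat[!names(flat) %in% "per_exon"]
    utils::write.table(data.frame(field = names(scal), value = unlist(scal)),
                       path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}

#' Read a sample/mutation table
#'
#' Reads a tab-separated file with at least the columns `sample_no` (or
#' `sample_id`) and `hgvs_c`.
#'
#' @param path TSV file path.
#' @return A data frame.
#' @export
load_mutation_table <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE,
                          fileEncoding = "UTF-8")
  if (!"hgvs_c" %in% names(df))
    stopf("mutation table '%s' lacks an 'hgvs_c' column", path)
  df
}
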