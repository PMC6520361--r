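test_that("HGVS parsing handles the table dialects", {
  m <- parse_hgvs_c("c.376-1G>A")
  expect_equal(m$edit_type, "substitution")
  expect_equal(m$length, 1L)
  expect_equal(m$offset, -1L)
  expect_equal(m$side, "acceptor")

  # en-dash and spaces are equivalent to the plain form
  m2 <- parse_hgvs_c("c.376–1 G>A")
  expect_equal(m2[c("edit_type", "start", "end", "offset", "ref", "alt")],
               m[c("edit_type", "start", "end", "offset", "ref", "alt")])

  ins <- parse_hgvs_c("c.782+3_782+4ins6")
  expect_equal(ins$edit_type, "insertion_or_duplication")
  expect_equal(ins$length, 6L)
  expect_equal(ins$offset, 3L)
  expect_equal(ins$side, "donor")

  del <- parse_hgvs_c("c.560-9_564del14")
  expect_equal(del$edit_type, "deletion")
  expect_equal(del$length, 14L)
  expect_equal(del$offset, -9L)

  del1 <- parse_hgvs_c("c.559+1del1")
  expect_equal(del1$edit_type, "deletion")
  expect_equal(del1$length, 1L)
  expect_equal(del1$offset, 1L)

  expect_error(parse_hgvs_c("c.banana"), "unrecognised token")
  expect_error(parse_hgvs_c("g.123A>T"), "does not begin with 'c.'")
})

test_that("classification assigns exons, sides and site classes", {
  m <- get_fx()$model
  cl <- function(h) classify_splice_mutation(parse_hgvs_c(h), m)

  d <- cl("c.919+1G>A")
  expect_equal(d$site_class, "consensus_donor")
  expect_equal(d$adjacent_exon, 8L)
  expect_true(d$is_consensus_point)

  r <- cl("c.375+5G>A")
  expect_equal(r$site_class, "splice_region_donor")
  expect_equal(r$adjacent_exon, 4L)
  expect_false(r$is_consensus_point)

  # a single-base deletion at +1 is a consensus point mutation
  sd <- cl("c.559+1del1")
  expect_equal(sd$site_class, "consensus_donor")
  expect_equal(sd$adjacent_exon, 5L)
  expect_true(sd$is_consensus_point)

  # multi-base events never count as consensus point mutations
  b1 <- cl("c.560-9_564del14")
  expect_equal(b1$site_class, "boundary_spanning")
  expect_equal(b1$adjacent_exon, 6L)
  b2 <- cl("c.782+3_782+4ins6")
  expect_equal(b2$site_class, "boundary_spanning")
  expect_equal(b2$adjacent_exon, 7L)

  expect_error(cl("c.376-11G>A"), "outside the ten-base splice region")
  expect_error(cl("c.100A>G"), "exonic")
  expect_error(cl("c.100+1G>A"), "not a donor-side exon boundary")
})

test_that("classification agrees with the human splice-site labels for all 16 fixtures", {
  m <- get_fx()$model
  tab <- tp53_cohort_mutations()
  expect_equal(nrow(tab), 16L)
  for (i in seq_len(nrow(tab))) {
    mut <- classify_splice_mutation(parse_hgvs_c(tab$hgvs_c[i]), m)
    lab <- tab$splice_site_label[i]
    expect_equal(mut$adjacent_exon,
                 as.integer(sub("^Exon (\\d+).*$", "\\1", lab)),
                 info = lab)
    if (grepl("(SD)", lab, fixed = TRUE)) expect_equal(mut$side, "donor", info = lab)
    if (grepl("(SA)", lab, fixed = TRUE)) expect_equal(mut$side, "acceptor", info = lab)
  }
})

test_that("cohort summary tallies a single mutation and rejects empty input", {
  m <- get_fx()$model
  s <- summarize_cohort(list(classify_splice_mutation(parse_hgvs_c("c.376-1G>A"), m)))
  expect_equal(s$n_mutations, 1L)
  expect_equal(s$n_consensus_point, 1L)
  expect_equal(s$n_acceptor_consensus, 1L)
  expect_equal(s$n_donor_consensus, 0L)
  expect_equal(s$n_adjacent_exons_5_to_8, 1L)
  expect_error(summarize_cohort(list()), "empty")
})

test_that("cohort summary equals a brute-force recount on random synthetic cohorts", {
  m <- get_toy("+")$model
  ex <- m$exons
  donors <- ex$coding_end_c[-nrow(ex)]
  acceptors <- ex$coding_start_c[-1]
  withr::with_seed(424242, {
    for (rep in 1:100) {
      n <- sample(3:20, 1)
      muts <- lapply(seq_len(n), function(i) {
        donor <- runif(1) < 0.5
        off <- sample(1:10, 1)
        h <- if (donor) {
          sprintf("c.%d+%d%s", sample(donors, 1), off,
                  if (runif(1) < 0.8) "G>A" else "del1")
        } else {
          sprintf("c.%d-%d%s", sample(acceptors, 1), off,
                  if (runif(1) < 0.8) "A>G" else "del1")
        }
        classify_splice_mutation(parse_hgvs_c(h), m)
      })
      s <- summarize_cohort(muts)
      # independent recount over the classified list
      side <- vapply(muts, `[[`, character(1), "side")
      off <- vapply(muts, `[[`, integer(1), "offset")
      edit <- vapply(muts, `[[`, character(1), "edit_type")
      exo <- vapply(muts, `[[`, integer(1), "adjacent_exon")
      cons <- abs(off) <= 2
      expect_equal(s$n_consensus_point, sum(cons))
      expect_equal(s$n_donor_consensus, sum(cons & side == "donor"))
      expect_equal(s$n_acceptor_consensus, sum(cons & side == "acceptor"))
      expect_equal(s$n_substitutions_at_consensus, sum(cons & edit == "substitution"))
      expect_equal(s$n_single_base_deletions_at_consensus, sum(cons & edit == "deletion"))
      expect_equal(s$n_adjacent_exons_5_to_8, sum(exo %in% 5:8))
      expect_equal(s$n_donor_consensus + s$n_acceptor_consensus, s$n_consensus_point)
      expect_true(all(unlist(s[startsWith(names(s), "n_")]) <= s$n_mutations))
    }
  })
})
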