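test_that("reconstruction applies each event type to the exon chain", {
  fx <- get_fx()
  m <- fx$model
  skip3 <- reconstruct_variant_transcript(m, splice_event("exon_skipping", exons = 3))
  expect_equal(skip3$cds_offset_change, -22L)
  expect_equal(nrow(skip3$chain), 10L)

  ret7 <- reconstruct_variant_transcript(m, splice_event("intron_retention", intron = 7))
  iw <- splicetx:::model_introns(m)
  expect_equal(ret7$cds_offset_change, iw$width[iw$intron == 7])
  expect_equal(nrow(ret7$chain), 10L)  # exons 7 and 8 merged with the intron
  # the retained intron is contiguous between its flanking exons
  expect_equal(ret7$chain$gstart[7], m$exons$gstart[8])
  expect_equal(ret7$chain$gend[7], m$exons$gend[7])

  cry <- reconstruct_variant_transcript(m, splice_event("cryptic_acceptor",
                                                        intron = 6, distance = -49))
  expect_equal(cry$cds_offset_change, 49L)

  expect_error(reconstruct_variant_transcript(m, splice_event("exon_skipping", exons = 1)),
               "do not exist")
  expect_error(reconstruct_variant_transcript(m, splice_event("exon_skipping", exons = 11)),
               "do not exist")
})

test_that("consequences match the published annotations for the fixture events", {
  fx <- get_fx()
  m <- fx$model

  skip3 <- predict_consequence(
    reconstruct_variant_transcript(m, splice_event("exon_skipping", exons = 3)), m)
  expect_true(skip3$frame_disturbed)
  expect_true(skip3$premature_stop)
  expect_equal(skip3$protein_class, "truncated")

  cry5 <- predict_consequence(
    reconstruct_variant_transcript(m, splice_event("cryptic_acceptor",
                                                   intron = 4, distance = 21)), m)
  expect_false(cry5$frame_disturbed)
  expect_false(cry5$premature_stop)
  expect_equal(cry5$aa_lost, 7L)
  expect_equal(cry5$protein_class, "inframe_loss")

  ret6 <- predict_consequence(
    reconstruct_variant_transcript(m, splice_event("intron_retention", intron = 6)), m)
  expect_true(ret6$premature_stop)
  expect_false(ret6$frame_disturbed)  # intron 6 length is a multiple of 3
  # the PTC lies inside the retained intron: within its codon span
  expect_gt(ret6$ptc_codon, 672 / 3)
  expect_lt(ret6$ptc_codon, (672 + 150) / 3 + 1)
  expect_equal(ret6$protein_class, "truncated")
})

test_that("skipping a stop-free exon with length a multiple of three is an in-frame loss", {
  gene <- simulate_gene(seed = 77, n_exons = 3, exon_lengths = c(60, 9, 60),
                        intron_lengths = c(70, 70), contig = "t9",
                        transcript_id = "t9.t1")
  v <- reconstruct_variant_transcript(gene$model, splice_event("exon_skipping", exons = 2))
  p <- predict_consequence(v, gene$model)
  expect_false(p$frame_disturbed)
  expect_false(p$premature_stop)
  expect_equal(p$aa_lost, 3L)
  expect_equal(p$protein_class, "inframe_loss")
})

test_that("consequence flags equal brute-force translation over all skips and retentions", {
  for (strand in c("+", "-")) {
    gene <- get_toy(strand)
    m <- gene$model
    n <- nrow(m$exons)
    events <- c(lapply(2:(n - 1), function(k) splice_event("exon_skipping", exons = k)),
                lapply(seq_len(n - 1), function(k) splice_event("intron_retention",
                                                                intron = k)))
    for (ev in events) {
      p <- predict_consequence(reconstruct_variant_transcript(m, ev), m)
      o <- oracle_consequence(gene, ev)
      expect_equal(p$frame_disturbed, o$frame_disturbed, info = event_label(ev))
      expect_equal(p$premature_stop, o$premature_stop, info = event_label(ev))
      if (o$premature_stop) expect_equal(p$protein_class, "truncated")
    }
  }
})

test_that("the named-isoform catalogue labels the p53psi event and nothing else", {
  fx <- get_fx()
  m <- fx$model
  psi <- reconstruct_variant_transcript(m, splice_event("cryptic_acceptor",
                                                        intron = 6, distance = -49))
  expect_equal(annotate_named_isoform(psi, m), "p53ψ")
  p <- predict_consequence(psi, m)
  expect_true(p$premature_stop)
  expect_equal(p$protein_class, "truncated")

  other <- reconstruct_variant_transcript(m, splice_event("cryptic_acceptor",
                                                          intron = 7, distance = 24))
  expect_true(is.na(annotate_named_isoform(other, m)))
  canon <- reconstruct_variant_transcript(m, NULL)
  expect_true(is.na(annotate_named_isoform(canon, m)))
})

test_that("a sample without any event is predicted full length", {
  fx <- get_fx()
  canon <- reconstruct_variant_transcript(fx$model, NULL)
  p <- predict_consequence(canon, fx$model)
  expect_false(p$frame_disturbed)
  expect_false(p$premature_stop)
  expect_equal(p$aa_lost, 0L)
  expect_equal(p$protein_class, "full_length")
})
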