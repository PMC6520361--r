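fx_gene_span <- function(model) {
  list(contig = model$contig, start = min(model$exons$gstart),
       end = max(model$exons$gend))
}

test_that("a file with no gapped reads yields no junction records", {
  toy <- simulate_gene(seed = 5, n_exons = 2, exon_lengths = c(90, 90),
                       intron_lengths = 120, contig = "t2", transcript_id = "t2.t1")
  sim <- simulate_reads(toy$model, list(list(event = "intron_retention:1", fraction = 1)),
                        total_informative_reads = 60, seed = 2)
  jx <- extract_junctions(sim$bam, fx_gene_span(toy$model))
  expect_equal(nrow(jx), 0L)
})

test_that("junction counts equal a direct gap-operation recount of the alignment file", {
  toy <- get_toy("+")
  sim <- simulate_reads(toy$model,
                        list(list(event = NULL, fraction = 0.6),
                             list(event = "exon_skipping:3", fraction = 0.4)),
                        total_informative_reads = 120, seed = 31)
  jx <- extract_junctions(sim$bam, fx_gene_span(toy$model))
  gaps <- oracle_sam_gaps(sim$sam)
  expect_equal(nrow(jx), nrow(gaps))
  expect_equal(jx$intron_start, gaps$start)
  expect_equal(jx$intron_end, gaps$end)
  expect_equal(jx$read_count, gaps$n)
  expect_equal(sum(jx$read_count), sum(gaps$n))
})

test_that("a canonical-only sample produces no aberrant records in the mutated intron", {
  fx <- get_fx()
  sim <- simulate_reads(fx$model, list(list(event = NULL, fraction = 1)),
                        total_informative_reads = 100, seed = 8)
  mut <- classify_splice_mutation(parse_hgvs_c("c.783-1G>T"), fx$model)
  win <- splicetx:::affected_window(fx$model, 7L, 500L)
  calls <- detect_events(extract_junctions(sim$bam, win), fx$model, mut)
  expect_equal(nrow(calls), 0L)
  ann <- attr(calls, "junctions")
  expect_true(all(ann$annotation == "canonical"))
})

manual_junctions <- function(model, counts) {
  # canonical intron 5 plus an exon-6-skipping junction (donor of intron 5
  # joined to the acceptor of intron 6; minus-strand gene, so the skip gap
  # runs from intron 6's genomic start to intron 5's genomic end)
  ir <- splicetx:::model_introns(model)
  i5 <- ir[ir$intron == 5, ]; i6 <- ir[ir$intron == 6, ]
  data.frame(contig = model$contig,
             intron_start = c(i5$gstart, i6$gstart),
             intron_end = c(i5$gend, i5$gend),
             read_count = counts)
}

test_that("evidence filters apply the read-count and fraction thresholds exactly", {
  fx <- get_fx()
  mut <- classify_splice_mutation(parse_hgvs_c("c.560-1G>A"), fx$model)
  # 4 supporting reads: below the read threshold even at a high fraction
  calls <- detect_events(manual_junctions(fx$model, c(20L, 4L)), fx$model, mut)
  expect_equal(calls$event_type, "exon_skipping")
  expect_equal(calls$skipped_exons, "6")
  expect_false(calls$passes_filters)
  # 6 reads but 3% of 200 relevant reads: below the fraction threshold
  calls <- detect_events(manual_junctions(fx$model, c(194L, 6L)), fx$model, mut)
  expect_equal(calls$fraction_of_relevant, 0.03)
  expect_false(calls$passes_filters)
  # 5 reads and exactly 5%: passes (thresholds are inclusive)
  calls <- detect_events(manual_junctions(fx$model, c(95L, 5L)), fx$model, mut)
  expect_equal(calls$fraction_of_relevant, 0.05)
  expect_true(calls$passes_filters)
  expect_equal(attr(calls, "relevant_reads"), 100L)
})

test_that("an event present in the control at similar fraction never passes", {
  fx <- get_fx()
  mut <- classify_splice_mutation(parse_hgvs_c("c.560-1G>A"), fx$model)
  j <- manual_junctions(fx$model, c(80L, 20L))
  expect_true(detect_events(j, fx$model, mut)$passes_filters)
  calls <- detect_events(j, fx$model, mut, control = j)
  expect_true(calls$present_in_control)
  expect_false(calls$passes_filters)
  # an event absent from the control still passes
  ctrl <- j[1, , drop = FALSE]
  expect_true(detect_events(j, fx$model, mut, control = ctrl)$passes_filters)
})

test_that("raising thresholds never increases the number of passing calls", {
  fx <- get_fx()
  mut <- classify_splice_mutation(parse_hgvs_c("c.560-1G>A"), fx$model)
  withr::with_seed(7, {
    for (rep in 1:20) {
      j <- manual_junctions(fx$model, as.integer(sample(1:300, 2)))
      npass <- function(mr, mf) {
        cfg <- detection_config(min_reads = mr, min_fraction = mf)
        sum(detect_events(j, fx$model, mut, cfg)$passes_filters)
      }
      for (mr in c(1, 5, 20)) {
        expect_true(npass(mr, 0.05) >= npass(mr, 0.2))
      }
      for (mf in c(0.01, 0.05, 0.3)) {
        expect_true(npass(1, mf) >= npass(10, mf))
      }
    }
  })
})

test_that("noise-free mixtures are recovered exactly at 10% and depth 100", {
  fx <- get_fx()
  sim <- simulate_reads(fx$model,
                        list(list(event = NULL, fraction = 0.9),
                             list(event = "exon_skipping:6", fraction = 0.1)),
                        total_informative_reads = 100, seed = 12)
  mut <- classify_splice_mutation(parse_hgvs_c("c.560-1G>A"), fx$model)
  win <- splicetx:::affected_window(fx$model, 5L, 500L)
  calls <- detect_events(extract_junctions(sim$bam, win), fx$model, mut)
  pass <- calls[calls$passes_filters, ]
  expect_equal(nrow(pass), 1L)
  expect_equal(pass$event_type, "exon_skipping")
  expect_equal(pass$skipped_exons, "6")
})

test_that("cryptic-site scans find the engineered sites and honour the window", {
  fx <- get_fx()
  mut5 <- classify_splice_mutation(parse_hgvs_c("c.376-1G>A"), fx$model)
  s <- scan_cryptic_sites(fx$model, mut5, 60)
  exonic <- s[s$location == "exonic", ]
  expect_equal(exonic$distance[1], 21L)  # AG ends at c.396, 21 bases into exon 5
  mut10 <- classify_splice_mutation(parse_hgvs_c("c.673-2A>T"), fx$model)
  s6 <- scan_cryptic_sites(fx$model, mut10, 100)
  expect_true(any(s6$distance == -49L & s6$location == "intronic"))
  mut11 <- classify_splice_mutation(parse_hgvs_c("c.559+1G>A"), fx$model)
  sd <- scan_cryptic_sites(fx$model, mut11, 60)
  expect_true(any(sd$distance == -10L & sd$location == "exonic"))
  expect_equal(nrow(scan_cryptic_sites(fx$model, mut5, 0)), 0L)
  # ordering by absolute distance
  expect_true(!is.unsorted(abs(s6$distance)))
  nogenome <- load_gene_model(get_fx()$gtf, NULL, "TP53fx.1")
  expect_error(scan_cryptic_sites(nogenome, mut5, 60), "no sequence")
})
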