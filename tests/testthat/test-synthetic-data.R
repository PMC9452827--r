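test_that("generated transcripts have cumulative contiguous spans and planted motifs", {
  tm <- make_transcript(c(140, 111, 112), seed = 5)
  expect_equal(tm$exons$c_start, c(1L, 141L, 252L))
  expect_equal(tm$exons$c_end, c(140L, 251L, 363L))
  expect_equal(nchar(tm$exons$sequence), c(140L, 111L, 112L))

  planted <- data.frame(exon = 2, offset = 10, motif = "GAAGAA")
  tm2 <- make_transcript(c(60, 60), planted_motifs = planted, seed = 5)
  hits <- scan_hits(motif_set("p", "enhancer", "GAAGAA"),
                    tm2$exons$sequence[2])
  expect_true(10L %in% hits$offset)
})

test_that("motif collisions are detected and named", {
  clash <- data.frame(exon = 1, offset = c(5, 8),
                      motif = c("AAAAAA", "TTTTTT"))
  expect_error(make_transcript(30, planted_motifs = clash, seed = 1),
               "motif collision")
  # compatible overlap (shared bases agree) is allowed
  ok <- data.frame(exon = 1, offset = c(5, 8), motif = c("AAAAAA", "AAATTT"))
  tm <- make_transcript(30, planted_motifs = ok, seed = 1)
  expect_equal(substr(tm$exons$sequence, 5, 13), "AAAAAATTT")
})

test_that("generation is deterministic by seed, down to the FASTA bytes", {
  f1 <- withr::local_tempfile(fileext = ".fa")
  f2 <- withr::local_tempfile(fileext = ".fa")
  f3 <- withr::local_tempfile(fileext = ".fa")
  write_exon_fasta(make_transcript(c(50, 70), seed = 123), f1)
  write_exon_fasta(make_transcript(c(50, 70), seed = 123), f2)
  write_exon_fasta(make_transcript(c(50, 70), seed = 124), f3)
  expect_identical(readLines(f1), readLines(f2))
  expect_false(identical(readLines(f1), readLines(f3)))

  sets1 <- synthetic_motif_sets(seed = 9)
  sets2 <- synthetic_motif_sets(seed = 9)
  expect_identical(sets1$ese$entries, sets2$ese$entries)
  expect_length(intersect(sets1$ese$entries, sets1$ess$entries), 0)
})

test_that("junction windows carry the requested consensus strength", {
  tm <- make_transcript(c(30, 30), junction_strength = "strong", seed = 2)
  j <- attr(tm, "junctions")
  expect_true(all(substr(j$donor_window, 4, 5) == "GT"))
  expect_true(all(substr(j$acceptor_window, 19, 20) == "AG"))
  broken <- attr(make_transcript(30, junction_strength = "broken", seed = 2),
                 "junctions")
  expect_false(substr(broken$donor_window, 4, 5) == "GT")
})

test_that("assay replicates respect their noise model", {
  noiseless <- make_assay_replicates(42, noise_sd = 0, n = 3, seed = 1)
  expect_equal(noiseless$exclusion_percent, rep(42, 3))
  expect_equal(exclusion_percent(noiseless$lower, noiseless$upper),
               noiseless$exclusion_percent)

  # large-n mean lands within 3 SEM of the truth
  big <- make_assay_replicates(50, noise_sd = 5, n = 1e4, seed = 6)
  sem <- 5 / sqrt(1e4)
  expect_lt(abs(mean(big$exclusion_percent) - 50), 3 * sem)

  expect_true(all(make_assay_replicates(99, 10, 100, seed = 3)$exclusion_percent <= 100))
  expect_false(identical(make_assay_replicates(50, 3, 3, seed = 1)$exclusion_percent,
                         make_assay_replicates(50, 3, 3, seed = 2)$exclusion_percent))
})

test_that("anchors extracted from generated variants rebuild identical spans", {
  tm <- make_transcript(c(90, 120, 60), seed = 14)
  sets <- synthetic_motif_sets(seed = 14)
  cases <- make_variant_cases(tm, sets$ese, sets$ess, n = 30, seed = 14)
  located <- locate_in_exon(cases[c("hgvs_c", "c_pos")], tm)
  anchors <- dplyr::distinct(located, exon_number, .keep_all = TRUE)
  rebuilt <- build_model_from_anchors(
    anchors[c("hgvs_c", "exon_number", "exon_length", "location_in_exon")],
    gene_id = tm$gene_id
  )
  got <- rebuilt$exons[c("exon_number", "c_start", "c_end")]
  want <- tm$exons[tm$exons$exon_number %in% got$exon_number,
                   c("exon_number", "c_start", "c_end")]
  expect_equal(got, want)
})

test_that("the pipeline recovers constructive ground truth on every generated case", {
  # a motif-dense landscape so motif-change events are common
  sets <- synthetic_motif_sets(n_ese = 60, n_ess = 60, seed = 101)
  tm <- make_transcript(c(140, 111, 129, 87, 152), seed = 101)
  cases <- make_variant_cases(tm, sets$ese, sets$ess, n = 300, seed = 101)

  located <- locate_in_exon(cases[c("hgvs_c", "c_pos")], tm)
  expect_equal(located$offset5, cases$expected_offset5)
  expect_equal(pmin(located$offset5, located$offset3), cases$expected_distance)

  deltas <- purrr::pmap(
    list(cases$wt_window, cases$mut_window, cases$window_offset),
    function(w, m, v) motif_delta(w, m, v, sets$ese, sets$ess)
  ) |> purrr::list_rbind()
  expect_equal(deltas$ese_broken, cases$expected_ese_broken)
  expect_equal(deltas$ess_gained, cases$expected_ess_gained)

  decided <- triage_decide(cases$expected_distance, deltas$ese_broken,
                           deltas$ess_gained)
  expect_equal(decided$by_proximity, cases$expected_by_proximity)
  expect_equal(decided$by_regulatory, cases$expected_by_regulatory)
  expect_equal(decided$selected, cases$expected_selected)
  # both label classes are represented, so the check is not vacuous
  expect_gt(sum(decided$selected), 0)
  expect_gt(sum(!decided$selected), 0)

  skips <- purrr::map(unique(cases$exon_number), ~ skip_exon(tm, .x)) |>
    purrr::list_rbind()
  joined <- dplyr::left_join(cases, skips, by = "exon_number")
  expect_equal(joined$frame_preserved, joined$expected_frame_preserved)
  expect_equal(joined$aa_lost, joined$expected_aa_lost)
  expect_equal(joined$first_codon, joined$expected_first_codon)
  expect_equal(joined$last_codon, joined$expected_last_codon)
})
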