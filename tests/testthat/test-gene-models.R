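test_that("HGVS cDNA substitutions parse and unsupported classes are rejected", {
  v <- parse_cdna_variant(c("c.728G>A", "c.1A>T"))
  expect_equal(v$c_pos, c(728L, 1L))
  expect_equal(v$ref, c("G", "A"))
  expect_equal(v$alt, c("A", "T"))
  expect_equal(v$label, c("c.728G>A", "c.1A>T"))

  expect_error(parse_cdna_variant("c.100+2T>C"), "intronic")
  expect_error(parse_cdna_variant("c.100-15T>C"), "intronic")
  expect_error(parse_cdna_variant("c.100delA"), "indel")
  expect_error(parse_cdna_variant("c.100_101insT"), "indel")
  expect_error(parse_cdna_variant("c.100N>A"), "non-ACGT")
  expect_error(parse_cdna_variant("c.100A>A"), "identical")
  expect_error(parse_cdna_variant("garbage"), "not a parsable")
})

test_that("transcript models validate spans, contiguity and sequences", {
  expect_error(
    transcript_model(data.frame(exon_number = 1, c_start = 10, c_end = 5)),
    "c_start <= c_end"
  )
  expect_error(
    transcript_model(data.frame(exon_number = 1:2, c_start = c(1, 120),
                                c_end = c(100, 200))),
    "not contiguous"
  )
  # gap allowed when exon numbers are not consecutive (partial model)
  tm <- transcript_model(data.frame(exon_number = c(2, 18),
                                    c_start = c(101, 1930),
                                    c_end = c(229, 2016)), "CLCNKB")
  expect_s3_class(tm, "transcript_model")
  expect_error(
    transcript_model(data.frame(exon_number = 1, c_start = 1, c_end = 6,
                                sequence = "ACGT")),
    "length does not match"
  )
})

test_that("locate_in_exon reproduces the signed location convention", {
  slc <- transcript_model(
    data.frame(exon_number = 5, c_start = 725, c_end = 864), "SLC12A1"
  )
  loc <- locate_in_exon(data.frame(hgvs_c = "c.728G>A"), slc)
  expect_equal(loc$exon_number, 5L)
  expect_equal(loc$location_in_exon, 4L)

  clc <- transcript_model(
    data.frame(exon_number = 2, c_start = 101, c_end = 229), "CLCNKB"
  )
  loc2 <- locate_in_exon(data.frame(hgvs_c = "c.229G>A"), clc)
  expect_equal(loc2$location_in_exon, -1L)

  # exact middle of an odd-length exon ties and reports the 5' (+) distance
  odd <- transcript_model(data.frame(exon_number = 1, c_start = 1, c_end = 9))
  mid <- locate_in_exon(data.frame(c_pos = 5), odd)
  expect_equal(mid$offset5, mid$offset3)
  expect_equal(mid$location_in_exon, 5L)

  expect_error(locate_in_exon(data.frame(hgvs_c = "c.999G>A"), clc),
               "not exonic")
})

test_that("anchors rebuild the published exon spans", {
  slc_anchors <- data.frame(
    hgvs_c = c("c.728G>A", "c.904C>T", "c.1010C>T"),
    exon_number = c(5, 6, 7),
    exon_length = c(140, 111, 112),
    location_in_exon = c(4, 40, 35)
  )
  tm <- build_model_from_anchors(slc_anchors, gene_id = "SLC12A1")
  expect_equal(tm$exons$c_start, c(725L, 865L, 976L))
  expect_equal(tm$exons$c_end, c(864L, 975L, 1087L))

  clc <- build_model_from_anchors(
    data.frame(hgvs_c = "c.229G>A", exon_number = 2, exon_length = 129,
               location_in_exon = -1),
    gene_id = "CLCNKB"
  )
  expect_equal(clc$exons$c_start, 101L)
  expect_equal(clc$exons$c_end, 229L)

  # single anchor at the exon 5' end spans c_pos .. c_pos + L - 1
  one <- build_model_from_anchors(
    data.frame(hgvs_c = "c.50A>G", exon_number = 3, exon_length = 30,
               location_in_exon = 1)
  )
  expect_equal(c(one$exons$c_start, one$exons$c_end), c(50L, 79L))

  expect_error(
    build_model_from_anchors(data.frame(
      hgvs_c = c("c.728G>A", "c.730G>A"),
      exon_number = 5, exon_length = 140,
      location_in_exon = c(4, 4)
    )),
    "inconsistent anchors"
  )
})

test_that("adjacent anchored exons come out contiguous where the table implies it", {
  tm <- build_model_from_anchors(data.frame(
    hgvs_c = c("c.1304C>T", "c.1493C>T"),
    exon_number = c(10, 11),
    exon_length = c(152, 108),
    location_in_exon = c(4, 41)
  ), gene_id = "SLC12A1")
  expect_equal(tm$exons$c_start, c(1301L, 1453L))
  expect_equal(tm$exons$c_end, c(1452L, 1560L))
  expect_equal(tm$exons$c_end[1] + 1L, tm$exons$c_start[2])
})

test_that("round trip: models built from all fixture anchors reproduce every printed location", {
  fix <- bartter_variants()
  models <- bartter_models()
  for (g in names(models)) {
    rows <- dplyr::filter(fix, gene_id == g)
    relocated <- locate_in_exon(rows["hgvs_c"], models[[g]])
    expect_equal(relocated$location_in_exon, rows$location_in_exon,
                 info = g)
    expect_equal(relocated$exon_number, rows$exon_number, info = g)
    expect_equal(relocated$exon_length, rows$exon_length, info = g)
  }
})

test_that("offset5 + offset3 = exon_length + 1 on random models", {
  set.seed(42)
  for (i in 1:50) {
    n_ex <- sample(1:5, 1)
    lens <- sample(3:200, n_ex, replace = TRUE)
    ends <- cumsum(lens)
    starts <- c(1L, head(ends, -1) + 1L)
    tm <- transcript_model(data.frame(exon_number = seq_len(n_ex),
                                      c_start = starts, c_end = ends))
    pos <- sample(max(ends), 5, replace = TRUE)
    loc <- locate_in_exon(data.frame(c_pos = pos), tm)
    expect_equal(loc$offset5 + loc$offset3, loc$exon_length + 1L)
    expect_equal(abs(loc$location_in_exon), pmin(loc$offset5, loc$offset3))
  }
})

test_that("gene-model JSON and exon FASTA round-trip", {
  tm <- make_transcript(c(30, 33), seed = 11)
  json <- withr::local_tempfile(fileext = ".json")
  write_gene_model(tm, json)
  back <- read_gene_model(json)
  expect_equal(back$exons, tm$exons)
  expect_equal(back$gene_id, tm$gene_id)

  fa <- withr::local_tempfile(fileext = ".fa")
  write_exon_fasta(tm, fa)
  stripped <- transcript_model(
    dplyr::select(tm$exons, -exon_length, -sequence), tm$gene_id
  )
  reattached <- attach_exon_fasta(stripped, fa)
  expect_equal(reattached$exons$sequence, tm$exons$sequence)
})
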