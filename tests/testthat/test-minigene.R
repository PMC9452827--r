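test_that("product sizes are backbone plus insert", {
  p <- expected_products(111)
  expect_equal(p$inclusion_size, 374L)
  expect_equal(p$exclusion_size, 263L)
  expect_equal(expected_products(129)$inclusion_size, 392L)
  expect_equal(expected_products(0)$inclusion_size, 263L)
  expect_error(expected_products(-1), "non-negative")
})

test_that("the product-size model reproduces 7 of the 9 printed wild-type band sizes", {
  printed <- tibble::tribble(
    ~construct, ~exon_length, ~printed_inclusion,
    "SLC12A1_Ex3", 76, 339,
    "SLC12A1_Ex5", 140, 405, # printed size disagrees with 263 + 140 = 403
    "SLC12A1_Ex6", 111, 374,
    "SLC12A1_Ex7", 112, 375,
    "SLC12A1_Ex10", 152, 415,
    "SLC12A1_Ex11", 108, 415, # printed size disagrees with 263 + 108 = 371
    "SLC12A1_Ex17", 141, 404,
    "CLCNKB_Ex2", 129, 392,
    "CLCNKB_Ex18", 87, 350
  )
  printed$modelled <- expected_products(printed$exon_length)$inclusion_size
  agree <- printed$modelled == printed$printed_inclusion
  expect_equal(sum(agree), 7)
  # the two known discrepancies are exactly the Ex5/Ex11 captions
  expect_setequal(printed$construct[!agree], c("SLC12A1_Ex5", "SLC12A1_Ex11"))
})

test_that("exclusion percentage follows the densitometric definition and is scale-invariant", {
  expect_equal(exclusion_percent(5, 5), 50)
  expect_equal(exclusion_percent(0, 7), 0)
  expect_equal(exclusion_percent(679, 321), 67.9)
  expect_error(exclusion_percent(0, 0), "undefined")
  expect_error(exclusion_percent(-1, 2), "non-negative")

  set.seed(12)
  for (i in 1:20) {
    lo <- runif(1, 1, 100); up <- runif(1, 1, 100); k <- runif(1, 0.01, 50)
    expect_equal(exclusion_percent(lo * k, up * k), exclusion_percent(lo, up),
                 tolerance = 1e-12)
  }
})

test_that("the pooled t-test matches the textbook formula to 1e-9", {
  set.seed(77)
  for (i in 1:50) {
    n1 <- sample(2:8, 1); n2 <- sample(2:8, 1)
    x <- runif(n1, 20, 80); y <- runif(n2, 20, 80)
    got <- splicing_comparison(x, y)
    want <- oracle_pooled_t(x, y)
    # comparison reports t for wt vs mut in the same orientation
    expect_equal(got$t_statistic, want$t, tolerance = 1e-9)
    expect_equal(got$df, want$df)
    expect_equal(got$p_value, want$p, tolerance = 1e-9)
  }
})

test_that("the worked comparison classifies partial skipping", {
  wt <- c(67.0, 68.5, 68.2)
  mut <- c(87.0, 88.3, 88.0)
  res <- splicing_comparison(wt, mut)
  want <- oracle_pooled_t(wt, mut)
  expect_equal(res$t_statistic, want$t, tolerance = 1e-9)
  expect_lt(res$p_value, 0.05)
  expect_equal(res$classification, "partial")
})

test_that("classification honours band detection and degenerate inputs", {
  # backbone-only mutant: complete, regardless of the test outcome
  res <- splicing_comparison(c(50, 51, 52), c(99, 99.5, 100),
                             mut_inclusion_detected = FALSE)
  expect_equal(res$classification, "complete")

  # identical replicate sets: zero pooled variance, p = 1 by convention
  res2 <- splicing_comparison(c(60, 60, 60), c(60, 60, 60))
  expect_equal(res2$p_value, 1)
  expect_equal(res2$t_statistic, 0)
  expect_equal(res2$classification, "none")

  # constant but different groups: p = 0 convention
  res3 <- splicing_comparison(c(60, 60, 60), c(80, 80, 80))
  expect_equal(res3$p_value, 0)
  expect_equal(res3$classification, "partial")

  # significantly LOWER mutant exclusion is not "partial skipping"
  res4 <- splicing_comparison(c(80, 81, 82), c(40, 41, 42))
  expect_lt(res4$p_value, 0.05)
  expect_equal(res4$classification, "none")
})

test_that("compare_splicing processes a long band table per construct", {
  bands <- dplyr::bind_rows(
    make_assay_replicates(55, 1.5, 3, seed = 1) |>
      dplyr::mutate(construct_id = "Ex2", group = "WT"),
    make_assay_replicates(88, 1.5, 3, seed = 2) |>
      dplyr::mutate(construct_id = "Ex2", group = "MUT"),
    make_assay_replicates(70, 1.5, 3, seed = 3) |>
      dplyr::mutate(construct_id = "Ex18", group = "WT"),
    # backbone-only mutant: upper band intensity ~ 0
    tibble::tibble(construct_id = "Ex18", group = "MUT", replicate = 1:3,
                   exclusion_percent = 100, lower = 1000, upper = 0)
  )
  res <- compare_splicing(bands)
  expect_equal(nrow(res), 2)
  ex2 <- res[res$construct_id == "Ex2", ]
  expect_equal(ex2$classification, "partial")
  expect_lt(ex2$p_value, 0.05)
  ex18 <- res[res$construct_id == "Ex18", ]
  expect_equal(ex18$classification, "complete")

  g <- glance(res)
  expect_equal(g$n_altered, 2L)
  expect_equal(g$n_complete, 1L)

  p <- autoplot(res)
  expect_s3_class(p, "ggplot")
})

test_that("a group with a single replicate skips the test with a warning", {
  bands <- tibble::tibble(
    construct_id = "X", group = c("WT", "WT", "MUT"), replicate = c(1, 2, 1),
    upper = c(500, 480, 300), lower = c(500, 520, 700)
  )
  expect_warning(res <- compare_splicing(bands), "n < 2")
  expect_true(is.na(res$p_value))
  expect_equal(res$classification, "none")
})

test_that("band TSVs round-trip through read_band_intensities", {
  bands <- tibble::tibble(construct_id = "A", group = c("WT", "MUT"),
                          replicate = 1L, upper = c(400, 100),
                          lower = c(600, 900))
  path <- withr::local_tempfile(fileext = ".tsv")
  readr::write_tsv(bands, path)
  expect_equal(read_band_intensities(path), bands)
  expect_error(read_band_intensities(
    withr::local_tempfile(lines = "a\tb\n1\t2", fileext = ".tsv")
  ), "needs columns")
})
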