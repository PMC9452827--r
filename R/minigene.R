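#' Expected exon-trap RT-PCR product sizes
#'
#' An exon-trap (pSPL3-type) minigene yields two possible spliced products:
#' the backbone-only product (test exon excluded) and the backbone plus the
#' test exon (included). The backbone product defaults to 263 bp.
#'
#' @param insert_exon_length Length (nt) of the cloned test exon(s);
#'   vectorised.
#' @param backbone_product Backbone-only product size (bp).
#' @return Tibble with `insert_exon_length`, `inclusion_size`,
#'   `exclusion_size`.
#' @export
#' @examples
#' expected_products(c(111, 129)) # 374/263 and 392/263 bp
expected_products <- function(insert_exon_length, backbone_product = 263L) {
  if (any(insert_exon_length < 0) || backbone_product < 0) {
    abort("lengths must be non-negative")
  }
  tibble(
    insert_exon_length = as.integer(insert_exon_length),
    inclusion_size = as.integer(backbone_product + insert_exon_length),
    exclusion_size = as.integer(backbone_product)
  )
}

#' Densitometric exon-exclusion percentage
#'
#' The proportion of the exon-excluded (lower, smaller) product among both
#' products: `100 * lower / (lower + upper)`. Scale-invariant in the two
#' intensities.
#'
#' @param lower Intensity of the exon-excluded band.
#' @param upper Intensity of the exon-included band.
#' @return Numeric vector of percentages in `[0, 100]`.
#' @export
#' @examples
#' exclusion_percent(679, 321)
exclusion_percent <- function(lower, upper) {
  if (any(lower < 0) || any(upper < 0)) abort("band intensities must be non-negative")
  if (any(lower + upper == 0)) {
    abort("exclusion percentage is undefined when both band intensities are 0")
  }
  100 * lower / (lower + upper)
}

#' Add exclusion percentages to a band-intensity table
#'
#' @param bands Data frame with `upper` and `lower` intensity columns
#'   (one row per replicate lane).
#' @return The tibble with an `exclusion_percent` column added.
#' @export
quantify_bands <- function(bands) {
  bands <- as_tibble(bands)
  if (!all(c("upper", "lower") %in% names(bands))) {
    abort("band table needs 'upper' and 'lower' columns")
  }
  mutate(bands, exclusion_percent = exclusion_percent(.data$lower, .data$upper))
}

# pooled-variance two-sample t-test with degenerate-case conventions:
# zero pooled variance => p = 1 when means are equal, p = 0 otherwise
pooled_t_test <- function(x, y) {
  if (length(x) < 2 || length(y) < 2) {
    return(tibble(t_statistic = NA_real_, df = NA_real_, p_value = NA_real_))
  }
  if (stats::var(x) == 0 && stats::var(y) == 0) {
    if (isTRUE(all.equal(mean(x), mean(y)))) {
      return(tibble(t_statistic = 0, df = length(x) + length(y) - 2, p_value = 1))
    }
    return(tibble(t_statistic = sign(mean(y) - mean(x)) * Inf,
                  df = length(x) + length(y) - 2, p_value = 0))
  }
  fit <- stats::t.test(x, y, var.equal = TRUE)
  tibble(t_statistic = unname(fit$statistic), df = unname(fit$parameter),
         p_value = fit$p.value)
}

#' Compare wild-type and mutant splicing from assay replicates
#'
#' Applies an unpaired pooled-variance (Student's) two-sample t-test to the
#' replicate exclusion percentages and classifies the mutant splicing
#' outcome:
#'
#' * `"complete"` -- only the backbone (exon-excluded) product is detected
#'   in the mutant, regardless of the test;
#' * `"partial"` -- both products are detected and mutant exclusion is
#'   significantly higher than wild type (`p < alpha`);
#' * `"none"` -- otherwise (mutant indistinguishable from wild type).
#'
#' @param wt,mut Numeric vectors of replicate exclusion percentages
#'   (typically n = 3 each; n >= 2 needed for the test).
#' @param mut_inclusion_detected Is the exon-included product detectable in
#'   the mutant? Supply `FALSE` when the mutant shows the backbone product
#'   only. Defaults to `TRUE`.
#' @param alpha Significance level (default 0.05).
#' @return One-row tibble: group means, SEMs, `t_statistic`, `df`,
#'   `p_value`, `classification`.
#' @export
#' @examples
#' splicing_comparison(c(67.0, 68.5, 68.2), c(87.0, 88.3, 88.0))
splicing_comparison <- function(wt, mut, mut_inclusion_detected = TRUE,
                                alpha = 0.05) {
  if (any(c(wt, mut) < 0 | c(wt, mut) > 100)) {
    abort("exclusion percentages must lie in [0, 100]")
  }
  test <- pooled_t_test(wt, mut)
  classification <- if (!mut_inclusion_detected) {
    "complete"
  } else if (!is.na(test$p_value) && test$p_value < alpha && mean(mut) > mean(wt)) {
    "partial"
  } else {
    "none"
  }
  tibble(
    n_wt = length(wt), n_mut = length(mut),
    mean_wt = mean(wt), mean_mut = mean(mut),
    sem_wt = stats::sd(wt) / sqrt(length(wt)),
    sem_mut = stats::sd(mut) / sqrt(length(mut)),
    t_statistic = test$t_statistic, df = test$df, p_value = test$p_value,
    classification = classification
  )
}

#' Quantify and compare splicing per construct from a band table
#'
#' Takes the long band-intensity table a densitometry export produces
#' (columns `construct_id`, `group` = `"WT"`/`"MUT"`, `replicate`, `upper`,
#' `lower`) and returns one row per construct with exclusion percentages,
#' the pooled t-test and the outcome classification. The exon-included
#' product counts as undetected (complete skipping) when its mean share of
#' total intensity in the mutant falls below `detection_fraction`.
#' Constructs with fewer than 2 replicates in a group get their
#' classification from band detection alone, with the test skipped and a
#' warning raised.
#'
#' @param bands Band-intensity data frame (see above).
#' @param alpha Significance level.
#' @param detection_fraction Fraction of total lane intensity below which
#'   the inclusion band is treated as absent (default 0.01).
#' @return Tibble of class `splice_comparison_tbl`, one row per construct.
#' @export
compare_splicing <- function(bands, alpha = 0.05, detection_fraction = 0.01) {
  bands <- as_tibble(bands)
  needed <- c("construct_id", "group", "upper", "lower")
  if (!all(needed %in% names(bands))) {
    abort(paste0("band table needs columns: ", paste(needed, collapse = ", ")))
  }
  if (!all(bands$group %in% c("WT", "MUT"))) {
    abort("group must be 'WT' or 'MUT'")
  }
  bands <- quantify_bands(bands)
  out <- bands |>
    group_by(.data$construct_id) |>
    group_modify(function(d, key) {
      wt <- filter(d, .data$group == "WT")
      mut <- filter(d, .data$group == "MUT")
      if (nrow(wt) == 0 || nrow(mut) == 0) {
        abort(sprintf("construct %s lacks a WT or MUT group", key$construct_id))
      }
      detected <- mean(mut$upper / (mut$upper + mut$lower)) >= detection_fraction
      if (nrow(wt) < 2 || nrow(mut) < 2) {
        warn(sprintf("construct %s has a group with n < 2; t-test skipped",
                     key$construct_id))
      }
      splicing_comparison(wt$exclusion_percent, mut$exclusion_percent,
                          mut_inclusion_detected = detected, alpha = alpha)
    }) |>
    ungroup()
  structure(out, class = c("splice_comparison_tbl", class(out)), alpha = alpha)
}

#' @exportS3Method generics::glance
glance.splice_comparison_tbl <- function(x, ...) {
  tibble(
    n_constructs = nrow(x),
    n_altered = sum(x$classification != "none"),
    n_complete = sum(x$classification == "complete"),
    n_partial = sum(x$classification == "partial"),
    alpha = attr(x, "alpha")
  )
}

#' Read a band-intensity TSV
#'
#' Columns: `construct_id`, `group` (WT|MUT), `replicate`, `upper`, `lower`.
#'
#' @param path TSV file path.
#' @return Tibble.
#' @export
read_band_intensities <- function(path) {
  df <- readr::read_tsv(path, show_col_types = FALSE, comment = "#")
  needed <- c("construct_id", "group", "replicate", "upper", "lower")
  if (!all(needed %in% names(df))) {
    abort(paste0("'", path, "' needs columns: ", paste(needed, collapse = ", ")))
  }
  df
}

#' @describeIn compare_splicing Bar chart of mean exclusion percentage with
#'   SEM error bars, WT vs MUT per construct.
#' @param x A `splice_comparison_tbl`.
#' @param ... Unused.
#' @exportS3Method ggplot2::autoplot
autoplot.splice_comparison_tbl <- function(x, ...) {
  d <- as_tibble(x) |>
    tidyr::pivot_longer(
      cols = c("mean_wt", "mean_mut"),
      names_to = "group", values_to = "mean_exclusion"
    ) |>
    mutate(
      group = ifelse(.data$group == "mean_wt", "WT", "MUT"),
      sem = ifelse(.data$group == "WT", .data$sem_wt, .data$sem_mut)
    )
  ggplot2::ggplot(d, ggplot2::aes(x = .data$construct_id,
                                  y = .data$mean_exclusion,
                                  fill = .data$group)) +
    ggplot2::geom_col(position = ggplot2::position_dodge(width = 0.8), width = 0.7) +
    ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data$mean_exclusion - .data$sem,
                   ymax = .data$mean_exclusion + .data$sem),
      position = ggplot2::position_dodge(width = 0.8), width = 0.25
    ) +
    ggplot2::labs(x = NULL, y = "exon exclusion (%)", fill = NULL) +
    ggplot2::ylim(0, 100) +
    ggplot2::theme_minimal()
}
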