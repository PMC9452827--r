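#' Packaged candidate-variant annotations for the two Bartter-syndrome genes
#'
#' The 14 exonic SNVs in *SLC12A1* and *CLCNKB* studied by minigene assay,
#' with the published in-silico annotations: exon number and length, signed
#' location within the exon (positive = distance from the 5' end, negative =
#' from the 3' end), the counts of ESEs broken and ESSs gained reported by
#' the external regulatory-element scanner, the external splice-site score
#' notes, and the percent change of the maximum-entropy splice-site score
#' where the underlying scores were printed. These counts come from external
#' services and are consumed as trusted annotations by [triage()].
#'
#' @return A tibble with one row per variant.
#' @export
#' @examples
#' bartter_variants()
bartter_variants <- function() {
  readr::read_tsv(
    system.file("extdata", "bartter_variants.tsv", package = "spliceshift"),
    show_col_types = FALSE, na = "NA"
  )
}

#' Packaged exon-skipping consequence annotations
#'
#' The published per-variant splicing outcomes and predicted protein
#' consequences for the assayed variants: which exon skips, whether the
#' skip is in-frame, and the protein-level summary. Used as the reference
#' for consequence-prediction tests and report formatting.
#'
#' @return A tibble with one row per variant.
#' @export
bartter_skipping <- function() {
  readr::read_tsv(
    system.file("extdata", "bartter_skipping.tsv", package = "spliceshift"),
    show_col_types = FALSE, na = "NA"
  )
}

#' Packaged wet-lab exclusion percentages
#'
#' The densitometric exon-exclusion percentages measured for the *CLCNKB*
#' constructs in two cell lines. These are experimental outcomes -- they
#' cannot be recomputed in silico -- and are packaged only for report
#' formatting and plotting examples.
#'
#' @return A tibble with `construct_id`, `variant`, `cell_line`,
#'   `exclusion_percent` and the band `pattern` observed.
#' @export
bartter_exclusion <- function() {
  readr::read_tsv(
    system.file("extdata", "bartter_exclusion.tsv", package = "spliceshift"),
    show_col_types = FALSE, na = "NA"
  )
}

#' Transcript models reconstructed from the packaged variant anchors
#'
#' Runs [build_model_from_anchors()] on the [bartter_variants()] table,
#' one model per gene. The resulting (partial) models reproduce every
#' published within-exon location and are the coordinate frame for
#' [skip_exon()] on the assayed exons.
#'
#' @return Named list of [transcript_model()] objects
#'   (`SLC12A1`, `CLCNKB`).
#' @export
#' @examples
#' bartter_models()$CLCNKB
bartter_models <- function() {
  anchors <- bartter_variants()
  genes <- unique(anchors$gene_id)
  setNames(
    lapply(genes, function(g) {
      build_model_from_anchors(filter(anchors, .data$gene_id == g), gene_id = g)
    }),
    genes
  )
}
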