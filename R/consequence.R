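#' Predict the consequence of skipping an exon
#'
#' Skipping an exon whose length is a multiple of 3 deletes whole codons
#' (an in-frame deletion); any other length shifts the downstream reading
#' frame, typically creating a premature termination codon. The affected
#' codon range is reported as the first and last codon *touched* by the
#' exon (`ceiling(c_pos / 3)`), so an exon starting mid-codon still counts
#' the shared codon; for in-frame skips the amino acids lost are
#' `exon_length / 3`, the deleted-codon-equivalent count.
#'
#' For a frameshift the termination codon can only be located when the
#' model carries the full CDS sequence from c.1 through the downstream
#' exons; otherwise a frame-only summary is returned with
#' `termination_codon = NA`.
#'
#' @param transcript A [transcript_model()].
#' @param exon_number Exon to skip (must be modelled).
#' @return One-row tibble: `gene_id`, `exon_number`, `exon_length`,
#'   `frame_preserved`, `aa_lost`, `first_codon`, `last_codon`,
#'   `annotation`, `termination_codon`, `runs_through`.
#' @export
#' @examples
#' tm <- transcript_model(
#'   data.frame(exon_number = 2, c_start = 101, c_end = 229), "CLCNKB"
#' )
#' skip_exon(tm, 2) # in-frame, 43 aa lost, codons 34-77
skip_exon <- function(transcript, exon_number) {
  stopifnot(inherits(transcript, "transcript_model"))
  row <- exon_row(transcript, exon_number)
  len <- row$exon_length
  first_codon <- as.integer(ceiling(row$c_start / 3))
  last_codon <- as.integer(ceiling(row$c_end / 3))
  frame_preserved <- len %% 3L == 0L
  out <- tibble(
    gene_id = transcript$gene_id,
    exon_number = as.integer(exon_number),
    exon_length = len,
    frame_preserved = frame_preserved,
    aa_lost = if (frame_preserved) len %/% 3L else NA_integer_,
    first_codon = first_codon,
    last_codon = last_codon,
    annotation = NA_character_,
    termination_codon = NA_integer_,
    runs_through = NA
  )
  if (frame_preserved) {
    out$annotation <- sprintf("in-frame deletion (codon %d-%d)", first_codon, last_codon)
    return(out)
  }
  ex <- transcript$exons
  full_cds <- min(ex$c_start) == 1L &&
    all(!is.na(ex$sequence)) &&
    (nrow(ex) == 1 || all(utils::tail(ex$c_start, -1) == utils::head(ex$c_end, -1) + 1L))
  if (!full_cds) {
    out$annotation <- sprintf("frameshift (from codon %d); termination unavailable without full CDS sequence",
                              first_codon)
    return(out)
  }
  wt_cds <- paste(ex$sequence, collapse = "")
  keep <- ex$exon_number != exon_number
  mut_cds <- paste(ex$sequence[keep], collapse = "")
  anchor_base <- 3L * (first_codon - 1L) + 1L
  term <- find_termination(substring(mut_cds, anchor_base), first_codon)
  out$termination_codon <- term$termination_codon
  out$runs_through <- term$runs_through
  wt_codon <- substring(wt_cds, anchor_base, anchor_base + 2L)
  mut_codon <- substring(mut_cds, anchor_base, anchor_base + 2L)
  wt_aa <- if (nchar(wt_codon) == 3) aa_three(translate_codon(wt_codon)) else "Xaa"
  mut_aa <- if (nchar(mut_codon) == 3) aa_three(translate_codon(mut_codon)) else "Xaa"
  out$annotation <- if (term$runs_through) {
    sprintf("p.%s%d%sfs (no stop codon in modelled sequence)", wt_aa, first_codon, mut_aa)
  } else {
    sprintf("p.%s%d%sfs*%d", wt_aa, first_codon, mut_aa, term$fs_offset)
  }
  out
}

#' Locate the premature termination codon after a frameshift
#'
#' Scans in-frame triplets (TAA/TAG/TGA are stops) from the first codon
#' affected by the frameshift. The `fs*K` offset follows the convention in
#' which the anchor codon (the first codon touched, which retains its amino
#' acid when the shift starts inside it) is position 0, i.e.
#' `termination_codon = anchor + K`.
#'
#' @param seq Nucleotide sequence of the shifted transcript starting at the
#'   first base of the anchor codon; a trailing partial codon is ignored.
#' @param start_codon CDS codon index of the anchor codon (default 1).
#' @return One-row tibble: `termination_codon`, `fs_offset` (the `K` of
#'   `fs*K`), `runs_through` (`TRUE` when no stop occurs before the
#'   sequence ends, with the other fields `NA`).
#' @export
#' @examples
#' find_termination("GGATAGAAA", 242) # stop in the codon after the anchor
find_termination <- function(seq, start_codon = 1L) {
  seq <- toupper(seq)
  assert_dna(seq, "CDS sequence")
  codons <- codon_split(seq)
  stop_at <- which(codons %in% STOP_CODONS)
  if (length(stop_at) == 0) {
    return(tibble(termination_codon = NA_integer_, fs_offset = NA_integer_,
                  runs_through = TRUE))
  }
  i <- stop_at[1]
  tibble(
    termination_codon = as.integer(start_codon + i - 1L),
    fs_offset = as.integer(i - 1L),
    runs_through = FALSE
  )
}

#' Tabulate exon-skipping consequences across variants
#'
#' Builds a report with one row per (variant, skipped exon): the frame
#' status, amino acids lost and affected codon range from [skip_exon()],
#' joined to the variant labels. Rows whose exon cannot be resolved in the
#' model are flagged in a `note` column and the run continues.
#'
#' @param models A named list of [transcript_model()] objects (names =
#'   gene_id), or a single model.
#' @param skips Data frame with columns `gene_id` and `exon_number`;
#'   optional extra columns (e.g. `hgvs_c`, `splicing_change`) are carried
#'   through. Defaults to every modelled exon of every model.
#' @return Tibble combining the input rows with the [skip_exon()] columns
#'   plus `note` (NA when the row resolved cleanly).
#' @export
#' @examples
#' consequence_table(bartter_models(), bartter_variants())
consequence_table <- function(models, skips = NULL) {
  if (inherits(models, "transcript_model")) {
    models <- setNames(list(models), models$gene_id)
  }
  if (is.null(names(models))) {
    names(models) <- vapply(models, function(m) m$gene_id, character(1))
  }
  if (is.null(skips)) {
    skips <- purrr::imap(models, function(m, g) {
      tibble(gene_id = g, exon_number = m$exons$exon_number)
    }) |> list_rbind()
  }
  skips <- as_tibble(skips)
  if (!all(c("gene_id", "exon_number") %in% names(skips))) {
    abort("skips need gene_id and exon_number columns")
  }
  rows <- purrr::pmap(list(seq_len(nrow(skips))), function(i) {
    g <- skips$gene_id[i]; e <- skips$exon_number[i]
    res <- tryCatch({
      if (!g %in% names(models)) {
        abort(sprintf("no model for gene %s", g))
      }
      skip_exon(models[[g]], e) |> mutate(note = NA_character_)
    }, error = function(err) {
      tibble(gene_id = g, exon_number = as.integer(e),
             exon_length = NA_integer_, frame_preserved = NA,
             aa_lost = NA_integer_, first_codon = NA_integer_,
             last_codon = NA_integer_, annotation = NA_character_,
             termination_codon = NA_integer_, runs_through = NA,
             note = conditionMessage(err))
    })
    bind_cols(skips[i, setdiff(names(skips), names(res)), drop = FALSE], res)
  })
  list_rbind(rows)
}
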