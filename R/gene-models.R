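#' Construct a transcript model from an exon table
#'
#' A transcript model is the frame of reference for all variant mapping: an
#' ordered set of exon spans in CDS ("c.") coordinates, where c.1 is the A of
#' the translation start codon. Models may be partial -- only the exons under
#' study need to be present -- but whenever two exons with consecutive
#' biological numbers are both modelled their spans must be contiguous.
#'
#' @param exons Data frame with columns `exon_number` (biological exon index,
#'   as published; need not start at 1), `c_start`, `c_end` (1-based, closed
#'   cDNA interval) and optionally `sequence` (A/C/G/T string of length
#'   `c_end - c_start + 1`, or `NA`).
#' @param gene_id Gene identifier attached to the model.
#'
#' @return An object of class `transcript_model`: a list with `gene_id` and
#'   an `exons` tibble (with derived `exon_length` column).
#' @export
#' @examples
#' tm <- transcript_model(
#'   data.frame(exon_number = 5:6, c_start = c(725, 865), c_end = c(864, 975)),
#'   gene_id = "SLC12A1"
#' )
#' tm
transcript_model <- function(exons, gene_id = "unknown") {
  exons <- as_tibble(exons)
  needed <- c("exon_number", "c_start", "c_end")
  missing_cols <- setdiff(needed, names(exons))
  if (length(missing_cols) > 0) {
    abort(paste0("exon table lacks column(s): ", paste(missing_cols, collapse = ", ")))
  }
  if (!"sequence" %in% names(exons)) exons$sequence <- NA_character_
  exons <- exons |>
    mutate(
      exon_number = as.integer(.data$exon_number),
      c_start = as.integer(.data$c_start),
      c_end = as.integer(.data$c_end)
    ) |>
    arrange(.data$exon_number) |>
    mutate(exon_length = .data$c_end - .data$c_start + 1L) |>
    select("exon_number", "c_start", "c_end", "exon_length", "sequence")

  if (anyDuplicated(exons$exon_number)) {
    abort("duplicated exon_number in exon table")
  }
  if (any(exons$c_start < 1L)) abort("c_start must be >= 1")
  if (any(exons$exon_length < 1L)) abort("every exon needs c_start <= c_end")
  if (nrow(exons) > 1) {
    if (any(diff(exons$c_start) <= 0) || any(utils::head(exons$c_end, -1) >=
                                             utils::tail(exons$c_start, -1))) {
      abort("exon spans must be strictly increasing and non-overlapping")
    }
    adjacent <- diff(exons$exon_number) == 1L
    gap_ok <- utils::tail(exons$c_start, -1) == utils::head(exons$c_end, -1) + 1L
    if (any(adjacent & !gap_ok)) {
      bad <- which(adjacent & !gap_ok)[1]
      abort(sprintf(
        "exons %d and %d are consecutive but their spans are not contiguous (c.%d..%d then c.%d..%d)",
        exons$exon_number[bad], exons$exon_number[bad + 1],
        exons$c_start[bad], exons$c_end[bad],
        exons$c_start[bad + 1], exons$c_end[bad + 1]
      ))
    }
  }
  has_seq <- !is.na(exons$sequence)
  if (any(has_seq)) {
    assert_dna(exons$sequence[has_seq], "exon sequence")
    len_ok <- nchar(exons$sequence[has_seq]) == exons$exon_length[has_seq]
    if (!all(len_ok)) {
      abort(sprintf(
        "sequence length does not match span for exon %d",
        exons$exon_number[has_seq][!len_ok][1]
      ))
    }
  }
  structure(list(gene_id = gene_id, exons = exons), class = "transcript_model")
}

#' @export
print.transcript_model <- function(x, ...) {
  cat(sprintf(
    "<transcript_model> %s: %d exon(s), c.%d..c.%d%s\n",
    x$gene_id, nrow(x$exons), min(x$exons$c_start), max(x$exons$c_end),
    if (all(!is.na(x$exons$sequence))) ", with sequence" else ""
  ))
  print(x$exons, ...)
  invisible(x)
}

#' Parse HGVS cDNA single-nucleotide substitutions
#'
#' Accepts strings of the form `c.<pos><ref>><alt>` (e.g. `"c.728G>A"`).
#' Intronic offset notation (`c.100+2T>C`), indels/duplications and
#' non-A/C/G/T bases are rejected with a message naming the unsupported
#' class, since the downstream pipeline is defined for exonic SNVs only.
#'
#' @param hgvs Character vector of HGVS cDNA variant strings.
#' @return A tibble with columns `label` (the input, verbatim), `c_pos`,
#'   `ref`, `alt`.
#' @export
#' @examples
#' parse_cdna_variant(c("c.728G>A", "c.229G>C"))
parse_cdna_variant <- function(hgvs) {
  hgvs <- as.character(hgvs)
  if (any(is.na(hgvs))) abort("NA is not a valid HGVS string")
  if (any(grepl("^c\\.\\d+[+-]\\d+", hgvs))) {
    bad <- hgvs[grepl("^c\\.\\d+[+-]\\d+", hgvs)][1]
    abort(sprintf("'%s': intronic offset notation is not supported (exonic SNVs only)", bad))
  }
  if (any(grepl("del|ins|dup|inv", hgvs))) {
    bad <- hgvs[grepl("del|ins|dup|inv", hgvs)][1]
    abort(sprintf("'%s': indel/duplication notation is not supported (SNVs only)", bad))
  }
  m <- str_match(hgvs, "^c\\.(\\d+)([A-Za-z])>([A-Za-z])$")
  if (any(is.na(m[, 1]))) {
    abort(sprintf("'%s': not a parsable HGVS cDNA substitution (expected c.<pos><ref>><alt>)",
                  hgvs[is.na(m[, 1])][1]))
  }
  ref <- toupper(m[, 3]); alt <- toupper(m[, 4])
  non_acgt <- !(ref %in% DNA_BASES) | !(alt %in% DNA_BASES)
  if (any(non_acgt)) {
    abort(sprintf("'%s': non-ACGT base is not supported", hgvs[non_acgt][1]))
  }
  if (any(ref == alt)) {
    abort(sprintf("'%s': reference and alternate base are identical", hgvs[ref == alt][1]))
  }
  tibble(
    label = hgvs,
    c_pos = as.integer(m[, 2]),
    ref = ref,
    alt = alt
  )
}

#' Locate variants within the exons of a transcript model
#'
#' Computes, for each variant, its exon, the 1-based distance from the exon
#' 5' end (`offset5`), from the 3' end (`offset3`), and a signed
#' `location_in_exon` following the reporting convention used for candidate
#' tables: the smaller of the two distances is reported, positive when
#' measured from the 5' end and negative when measured from the 3' end;
#' ties report the 5' (positive) distance.
#'
#' @param variants Data frame with a `c_pos` column (or an `hgvs_c` column,
#'   which is parsed first). Extra columns are carried through.
#' @param transcript A [transcript_model()].
#' @return The input tibble with `exon_number`, `exon_length`, `offset5`,
#'   `offset3` and `location_in_exon` columns added.
#' @export
#' @examples
#' tm <- transcript_model(
#'   data.frame(exon_number = 2, c_start = 101, c_end = 229), "CLCNKB"
#' )
#' locate_in_exon(data.frame(hgvs_c = "c.229G>A"), tm)
locate_in_exon <- function(variants, transcript) {
  stopifnot(inherits(transcript, "transcript_model"))
  variants <- as_tibble(variants)
  if (!"c_pos" %in% names(variants)) {
    if (!"hgvs_c" %in% names(variants)) {
      abort("variants need a c_pos or hgvs_c column")
    }
    parsed <- parse_cdna_variant(variants$hgvs_c)
    variants <- bind_cols(variants, parsed[setdiff(names(parsed), "label")])
  }
  ex <- transcript$exons
  idx <- vapply(variants$c_pos, function(p) {
    hit <- which(ex$c_start <= p & p <= ex$c_end)
    if (length(hit) == 0) NA_integer_ else hit[1]
  }, integer(1))
  if (anyNA(idx)) {
    labels <- if ("hgvs_c" %in% names(variants)) variants$hgvs_c else variants$c_pos
    abort(sprintf(
      "position(s) not exonic in model for %s: %s",
      transcript$gene_id,
      paste(labels[is.na(idx)], collapse = ", ")
    ))
  }
  variants |>
    mutate(
      exon_number = ex$exon_number[idx],
      exon_length = ex$exon_length[idx],
      offset5 = .data$c_pos - ex$c_start[idx] + 1L,
      offset3 = ex$c_end[idx] - .data$c_pos + 1L,
      location_in_exon = ifelse(.data$offset5 <= .data$offset3,
                                .data$offset5, -.data$offset3)
    )
}

#' Reconstruct a transcript model from variant anchor annotations
#'
#' Candidate tables typically report, for each variant, its exon number, the
#' exon length and a signed location within the exon. Each such row "anchors"
#' its exon: the span in c. coordinates is solved from the variant position
#' and the reported offset. This builds a (possibly partial) transcript model
#' from those anchors, erroring if two anchors imply different spans for the
#' same exon.
#'
#' @param anchors Data frame with columns `hgvs_c` (or `label`),
#'   `exon_number`, `exon_length`, `location_in_exon` and optionally
#'   `gene_id` (must be a single gene).
#' @param gene_id Gene identifier; defaults to the `gene_id` column if present.
#' @return A [transcript_model()].
#' @export
#' @examples
#' build_model_from_anchors(data.frame(
#'   hgvs_c = "c.229G>A", exon_number = 2, exon_length = 129,
#'   location_in_exon = -1
#' ), gene_id = "CLCNKB")
build_model_from_anchors <- function(anchors, gene_id = NULL) {
  anchors <- as_tibble(anchors)
  if (!"hgvs_c" %in% names(anchors) && "label" %in% names(anchors)) {
    anchors <- rename(anchors, hgvs_c = "label")
  }
  needed <- c("hgvs_c", "exon_number", "exon_length", "location_in_exon")
  if (!all(needed %in% names(anchors))) {
    abort(paste0("anchors need columns: ", paste(needed, collapse = ", ")))
  }
  if (is.null(gene_id)) {
    gene_id <- if ("gene_id" %in% names(anchors)) unique(anchors$gene_id) else "unknown"
  }
  if (length(gene_id) != 1) {
    abort("anchors span multiple genes; build one model per gene")
  }
  if (any(anchors$location_in_exon == 0)) {
    abort("location_in_exon of 0 is not a valid signed offset")
  }
  parsed <- parse_cdna_variant(anchors$hgvs_c)
  implied <- anchors |>
    mutate(
      c_pos = parsed$c_pos,
      c_start = ifelse(.data$location_in_exon > 0,
                       .data$c_pos - .data$location_in_exon + 1L,
                       (.data$c_pos + abs(.data$location_in_exon) - 1L) -
                         .data$exon_length + 1L),
      c_end = .data$c_start + .data$exon_length - 1L
    )
  conflicts <- implied |>
    group_by(.data$exon_number) |>
    filter(n_distinct(.data$c_start) > 1 | n_distinct(.data$c_end) > 1) |>
    ungroup()
  if (nrow(conflicts) > 0) {
    msg <- conflicts |>
      mutate(txt = sprintf("%s => exon %d spans c.%d..%d",
                           .data$hgvs_c, .data$exon_number,
                           .data$c_start, .data$c_end)) |>
      pull(.data$txt)
    abort(paste0("inconsistent anchors:\n  ", paste(msg, collapse = "\n  ")))
  }
  spans <- implied |>
    distinct(.data$exon_number, .data$c_start, .data$c_end)
  transcript_model(spans, gene_id = gene_id)
}

#' Read / write a gene-model JSON file
#'
#' The on-disk format is a small JSON object:
#' `{"gene_id": ..., "exons": [{"exon_number", "c_start", "c_end",
#' "sequence"?}, ...]}`. Coordinates are transcript-relative (CDS-based), so
#' a transcript-level JSON is used rather than a genomic annotation format.
#'
#' @param path File path.
#' @return `read_gene_model()` returns a [transcript_model()];
#'   `write_gene_model()` returns `path` invisibly.
#' @export
read_gene_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(obj$gene_id) || is.null(obj$exons)) {
    abort(sprintf("'%s' is not a gene-model JSON (need gene_id and exons)", path))
  }
  transcript_model(as_tibble(obj$exons), gene_id = obj$gene_id)
}

#' @rdname read_gene_model
#' @param transcript A [transcript_model()] to serialise.
#' @export
write_gene_model <- function(transcript, path) {
  stopifnot(inherits(transcript, "transcript_model"))
  ex <- transcript$exons |> select(-"exon_length")
  if (all(is.na(ex$sequence))) ex$sequence <- NULL
  jsonlite::write_json(
    list(gene_id = transcript$gene_id, exons = ex),
    path, auto_unbox = TRUE, pretty = TRUE
  )
  invisible(path)
}

#' Write / attach exon sequences as FASTA
#'
#' Records are named `<gene_id>|exon<k>` so that sequences can be re-attached
#' to a model read from JSON.
#'
#' @param transcript A [transcript_model()] with sequences.
#' @param path FASTA file path.
#' @export
write_exon_fasta <- function(transcript, path) {
  stopifnot(inherits(transcript, "transcript_model"))
  ex <- transcript$exons
  if (any(is.na(ex$sequence))) abort("transcript has exons without sequence")
  set <- Biostrings::DNAStringSet(ex$sequence)
  names(set) <- sprintf("%s|exon%d", transcript$gene_id, ex$exon_number)
  Biostrings::writeXStringSet(set, path, width = 70L)
  invisible(path)
}

#' @rdname write_exon_fasta
#' @export
attach_exon_fasta <- function(transcript, path) {
  stopifnot(inherits(transcript, "transcript_model"))
  set <- Biostrings::readDNAStringSet(path)
  nums <- as.integer(str_match(names(set), "\\|exon(\\d+)$")[, 2])
  if (anyNA(nums)) abort("FASTA record names must end in '|exon<k>'")
  ex <- transcript$exons
  hit <- match(ex$exon_number, nums)
  if (anyNA(hit)) {
    abort(sprintf("FASTA lacks sequence for exon %d",
                  ex$exon_number[is.na(hit)][1]))
  }
  ex$sequence <- unname(as.character(set))[hit]
  transcript_model(select(ex, -"exon_length"), gene_id = transcript$gene_id)
}

#' Read a variant TSV (columns gene_id, hgvs_c)
#'
#' @param path TSV file path.
#' @return Tibble with `gene_id`, `hgvs_c`, `c_pos`, `ref`, `alt`.
#' @export
read_variants <- function(path) {
  df <- readr::read_tsv(path, show_col_types = FALSE, comment = "#")
  if (!all(c("gene_id", "hgvs_c") %in% names(df))) {
    abort(sprintf("'%s' needs columns gene_id and hgvs_c", path))
  }
  parsed <- parse_cdna_variant(df$hgvs_c)
  bind_cols(df, parsed[c("c_pos", "ref", "alt")])
}

# look up a single exon row, erroring if absent
exon_row <- function(transcript, exon_number) {
  row <- filter(transcript$exons, .data$exon_number == !!exon_number)
  if (nrow(row) == 0) {
    abort(sprintf("exon %d is not modelled in %s", exon_number, transcript$gene_id))
  }
  row
}
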