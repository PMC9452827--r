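#' Parameters for the candidate-selection filter
#'
#' A variant is carried forward as a candidate splicing variant if it lies
#' within `max_boundary_distance` nucleotides of either exon end (boundary
#' proximity), or if the number of broken enhancers plus gained silencers is
#' strictly greater than `disruption_threshold` (regulatory disruption).
#'
#' @param max_boundary_distance Maximum distance (nt) from the nearer exon
#'   end for the proximity criterion; default 4, with the boundary base
#'   itself at distance 1.
#' @param disruption_threshold Count that `ese_broken + ess_gained` must
#'   strictly exceed for the regulatory criterion; default 5.
#' @return A list of class `triage_params`.
#' @export
triage_params <- function(max_boundary_distance = 4L, disruption_threshold = 5L) {
  if (max_boundary_distance < 0 || disruption_threshold < 0) {
    abort("triage parameters must be non-negative")
  }
  structure(
    list(max_boundary_distance = as.integer(max_boundary_distance),
         disruption_threshold = as.integer(disruption_threshold)),
    class = "triage_params"
  )
}

#' @export
print.triage_params <- function(x, ...) {
  cat(sprintf("<triage_params> boundary distance <= %d nt OR ese_broken + ess_gained > %d\n",
              x$max_boundary_distance, x$disruption_threshold))
  invisible(x)
}

#' Decide the two selection criteria for given inputs
#'
#' Vectorised core of the filter; [triage()] applies it to an annotated
#' variant table.
#'
#' @param boundary_distance Distance (nt) from the nearer exon end
#'   (boundary base = 1).
#' @param ese_broken,ess_gained Counts of enhancers broken and silencers
#'   gained by the variant.
#' @param params A [triage_params()].
#' @return Tibble with `by_proximity`, `by_regulatory`, `selected`
#'   (`selected` is the disjunction).
#' @export
#' @examples
#' triage_decide(4, 0, 0)  # selected via proximity
#' triage_decide(40, 6, 1) # selected via regulatory disruption
triage_decide <- function(boundary_distance, ese_broken, ess_gained,
                          params = triage_params()) {
  stopifnot(inherits(params, "triage_params"))
  if (any(stats::na.omit(c(ese_broken, ess_gained)) < 0)) {
    abort("motif counts must be non-negative")
  }
  by_proximity <- boundary_distance <= params$max_boundary_distance
  by_regulatory <- (ese_broken + ess_gained) > params$disruption_threshold
  tibble(
    by_proximity = by_proximity,
    by_regulatory = by_regulatory,
    selected = by_proximity | by_regulatory
  )
}

#' Apply the candidate-selection filter to an annotated variant table
#'
#' Each row needs a within-exon location (either `offset5`/`offset3` or a
#' signed `location_in_exon`, whose absolute value is the distance to the
#' nearer exon end) and the counts `ese_broken` and `ess_gained` -- either
#' produced live by [motif_delta()] or supplied from an external annotation
#' table. Rows with missing counts are decided as `NA`, excluded from
#' summaries, and reported with a warning.
#'
#' @param variants Annotated variant data frame.
#' @param params A [triage_params()].
#' @param exclude_terminal If `TRUE` and a logical `terminal_exon` column is
#'   present, first/last-exon variants are dropped before filtering (such
#'   variants cannot be assayed in an exon-trap minigene).
#' @return The input tibble with `boundary_distance`, `disruption_sum`,
#'   `by_proximity`, `by_regulatory` and `selected` columns added; class
#'   `triage_tbl` with the parameters attached. Use [glance()] for the
#'   overall summary and [triage_summary()] for per-gene counts.
#' @export
#' @examples
#' triage(bartter_variants()) |> glance()
triage <- function(variants, params = triage_params(), exclude_terminal = FALSE) {
  stopifnot(inherits(params, "triage_params"))
  variants <- as_tibble(variants)
  if (exclude_terminal && "terminal_exon" %in% names(variants)) {
    n_drop <- sum(variants$terminal_exon, na.rm = TRUE)
    if (n_drop > 0) {
      inform(sprintf("dropping %d first/last-exon variant(s) before triage", n_drop))
      variants <- filter(variants, !.data$terminal_exon %in% TRUE)
    }
  }
  if (all(c("offset5", "offset3") %in% names(variants))) {
    dist <- pmin(variants$offset5, variants$offset3)
  } else if ("location_in_exon" %in% names(variants)) {
    dist <- abs(variants$location_in_exon)
  } else {
    abort("variants need offset5/offset3 or location_in_exon columns")
  }
  for (col in c("ese_broken", "ess_gained")) {
    if (!col %in% names(variants)) {
      abort(sprintf("variants need an '%s' column", col))
    }
  }
  incomplete <- is.na(variants$ese_broken) | is.na(variants$ess_gained) | is.na(dist)
  if (any(incomplete)) {
    lab <- if ("hgvs_c" %in% names(variants)) variants$hgvs_c[incomplete] else which(incomplete)
    warn(sprintf("%d row(s) missing counts or location, excluded from summary: %s",
                 sum(incomplete), paste(lab, collapse = ", ")))
  }
  decision <- triage_decide(dist, variants$ese_broken, variants$ess_gained, params)
  decision[incomplete, ] <- NA
  out <- variants |>
    mutate(
      boundary_distance = dist,
      disruption_sum = .data$ese_broken + .data$ess_gained
    ) |>
    bind_cols(decision)
  structure(out, class = c("triage_tbl", class(out)),
            params = params, n_incomplete = sum(incomplete))
}

#' @exportS3Method generics::tidy
tidy.triage_tbl <- function(x, ...) {
  as_tibble(unclass_triage(x))
}

unclass_triage <- function(x) {
  attr(x, "params") <- NULL
  attr(x, "n_incomplete") <- NULL
  class(x) <- setdiff(class(x), "triage_tbl")
  x
}

#' @exportS3Method generics::glance
glance.triage_tbl <- function(x, ...) {
  p <- attr(x, "params")
  d <- filter(as_tibble(unclass_triage(x)), !is.na(.data$selected))
  tibble(
    n = nrow(x),
    n_selected = sum(d$selected),
    n_proximity_only = sum(d$by_proximity & !d$by_regulatory),
    n_regulatory_only = sum(d$by_regulatory & !d$by_proximity),
    n_both = sum(d$by_proximity & d$by_regulatory),
    n_incomplete = attr(x, "n_incomplete"),
    max_boundary_distance = p$max_boundary_distance,
    disruption_threshold = p$disruption_threshold
  )
}

#' Per-gene summary of a triage result
#'
#' @param x A `triage_tbl` from [triage()].
#' @return Tibble with one row per gene: totals and counts selected by each
#'   criterion.
#' @export
triage_summary <- function(x) {
  stopifnot(inherits(x, "triage_tbl"))
  d <- as_tibble(unclass_triage(x))
  if (!"gene_id" %in% names(d)) d$gene_id <- "all"
  d |>
    filter(!is.na(.data$selected)) |>
    group_by(.data$gene_id) |>
    summarise(
      n = n(),
      n_selected = sum(.data$selected),
      n_by_proximity = sum(.data$by_proximity),
      n_by_regulatory = sum(.data$by_regulatory),
      .groups = "drop"
    )
}

#' @describeIn triage Scatter of boundary distance against disruption sum
#'   with the two selection thresholds drawn; points coloured by the
#'   criterion that selected them.
#' @param x A `triage_tbl`.
#' @param ... Unused.
#' @exportS3Method ggplot2::autoplot
autoplot.triage_tbl <- function(x, ...) {
  p <- attr(x, "params")
  d <- as_tibble(unclass_triage(x)) |>
    filter(!is.na(.data$selected)) |>
    mutate(criterion = case_when(
      .data$by_proximity & .data$by_regulatory ~ "both",
      .data$by_proximity ~ "proximity",
      .data$by_regulatory ~ "regulatory",
      TRUE ~ "not selected"
    ))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$boundary_distance,
                                  y = .data$disruption_sum,
                                  colour = .data$criterion)) +
    ggplot2::geom_vline(xintercept = p$max_boundary_distance + 0.5, linetype = 2) +
    ggplot2::geom_hline(yintercept = p$disruption_threshold + 0.5, linetype = 2) +
    ggplot2::geom_jitter(width = 0.15, height = 0.15, size = 2) +
    ggplot2::labs(
      x = "distance to nearer exon end (nt)",
      y = "ESEs broken + ESSs gained",
      colour = "selected by"
    ) +
    ggplot2::theme_minimal()
}
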