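#' Generate disjoint synthetic ESE/ESS hexamer sets
#'
#' Draws two disjoint sets of random k-mers to act as enhancer and silencer
#' motif alphabets for simulation and testing. No published motif database
#' is bundled; these sets exist so that planted ground truth can be scored
#' without downloads.
#'
#' @param n_ese,n_ess Number of motifs per set (defaults 20 each).
#' @param k Motif length (default 6).
#' @param seed RNG seed; the same seed always yields the same sets.
#' @return List with elements `ese` and `ess`, each a [motif_set()].
#' @export
synthetic_motif_sets <- function(n_ese = 20, n_ess = 20, k = 6, seed = 1L) {
  withr::with_seed(seed, {
    pool <- character(0)
    while (length(pool) < n_ese + n_ess) {
      cand <- vapply(seq_len(2 * (n_ese + n_ess)), function(i) {
        paste(sample(DNA_BASES, k, replace = TRUE), collapse = "")
      }, character(1))
      pool <- unique(c(pool, cand))
    }
    list(
      ese = motif_set("synthetic_ese", "enhancer", pool[seq_len(n_ese)]),
      ess = motif_set("synthetic_ess", "silencer", pool[n_ese + seq_len(n_ess)])
    )
  })
}

junction_flanks <- function(strength) {
  donor <- switch(strength,
    strong = "GTAAGT",
    weak = "GTATTT",
    broken = "TTAAGT",
    abort(sprintf("unknown junction strength '%s'", strength))
  )
  acceptor_tail <- switch(strength,
    strong = "TTTTTCCTTTCTTTCCAG",
    weak = "TATATACTATACTATAAG",
    broken = "TTTTTCCTTTCTTTCCAA",
    NULL
  )
  list(donor = donor, acceptor = acceptor_tail)
}

#' Simulate a transcript with sequences and planted motifs
#'
#' Generates a contiguous CDS-coordinate transcript (exon 1 starting at
#' c.1) with random sequence, optionally planting motif occurrences at
#' requested positions, and records per-junction donor/acceptor windows
#' (using synthetic intron flanks of the requested consensus strength) as a
#' `junctions` attribute. Fully reproducible by seed.
#'
#' @param exon_lengths Integer vector of exon lengths (nt).
#' @param planted_motifs Optional data frame with columns `exon`, `offset`
#'   (1-based within the exon), `motif`, and optionally `role`; each motif
#'   is written verbatim at its position. Overlapping plants that disagree
#'   on a base raise a collision error naming both motifs.
#' @param junction_strength `"strong"`, `"weak"` or `"broken"` splice-site
#'   consensus for the synthetic intron flanks (recycled across junctions).
#' @param gene_id Gene identifier.
#' @param seed RNG seed.
#' @return A [transcript_model()] with sequences; attributes `planted`
#'   (the plant table) and `junctions` (tibble of `exon_number`,
#'   `donor_window` 3 exonic + 6 intronic nt, `acceptor_window` 20 intronic
#'   + 3 exonic nt).
#' @export
#' @examples
#' tm <- make_transcript(c(140, 111, 112), seed = 7)
#' tm$exons$c_start # 1, 141, 252
make_transcript <- function(exon_lengths, planted_motifs = NULL,
                            junction_strength = "strong",
                            gene_id = "SYNTH1", seed = 1L) {
  exon_lengths <- as.integer(exon_lengths)
  if (any(exon_lengths < 1)) abort("exon lengths must be >= 1")
  n_ex <- length(exon_lengths)
  strengths <- rep(junction_strength, length.out = n_ex)
  withr::with_seed(seed, {
    seqs <- vapply(exon_lengths, function(len) {
      paste(sample(DNA_BASES, len, replace = TRUE), collapse = "")
    }, character(1))
    if (!is.null(planted_motifs)) {
      planted_motifs <- as_tibble(planted_motifs)
      if (!all(c("exon", "offset", "motif") %in% names(planted_motifs))) {
        abort("planted_motifs needs columns exon, offset, motif")
      }
      assert_dna(planted_motifs$motif, "planted motif")
      # owner of each written base, for collision reporting
      owners <- lapply(exon_lengths, function(len) rep(NA_integer_, len))
      for (i in seq_len(nrow(planted_motifs))) {
        e <- planted_motifs$exon[i]
        o <- planted_motifs$offset[i]
        m <- planted_motifs$motif[i]
        if (e < 1 || e > n_ex) abort(sprintf("planted motif %d: no exon %d", i, e))
        if (o < 1 || o + nchar(m) - 1 > exon_lengths[e]) {
          abort(sprintf("planted motif '%s' does not fit in exon %d at offset %d", m, e, o))
        }
        span <- o:(o + nchar(m) - 1)
        clash <- which(!is.na(owners[[e]][span]) &
                         strsplit(substr(seqs[e], o, o + nchar(m) - 1), "")[[1]] !=
                         strsplit(m, "")[[1]])
        if (length(clash) > 0) {
          other <- owners[[e]][span][clash[1]]
          abort(sprintf(
            "motif collision in exon %d: '%s' at offset %d conflicts with '%s' at offset %d",
            e, m, o, planted_motifs$motif[other], planted_motifs$offset[other]
          ))
        }
        substr(seqs[e], o, o + nchar(m) - 1) <- m
        owners[[e]][span] <- i
      }
    }
    junctions <- tibble(
      exon_number = seq_len(n_ex),
      donor_window = vapply(seq_len(n_ex), function(i) {
        paste0(substr(seqs[i], exon_lengths[i] - 2, exon_lengths[i]),
               junction_flanks(strengths[i])$donor)
      }, character(1)),
      acceptor_window = vapply(seq_len(n_ex), function(i) {
        intron <- paste0(
          paste(sample(c("C", "T", "T"), 2, replace = TRUE), collapse = ""),
          junction_flanks(strengths[i])$acceptor
        )
        paste0(intron, substr(seqs[i], 1, 3))
      }, character(1))
    )
  })
  ends <- cumsum(exon_lengths)
  starts <- c(1L, utils::head(ends, -1) + 1L)
  tm <- transcript_model(
    tibble(exon_number = seq_len(n_ex), c_start = starts, c_end = ends,
           sequence = seqs),
    gene_id = gene_id
  )
  attr(tm, "planted") <- planted_motifs
  attr(tm, "junctions") <- junctions
  tm
}

# brute-force motif change counter used ONLY to record ground truth at
# construction time; deliberately independent of scan_hits()/motif_delta()
brute_count_changes <- function(sets, wt, mut, v) {
  broken <- 0L; gained <- 0L
  for (set in sets) {
    k <- set$k
    n_w <- nchar(wt) - k + 1L
    if (n_w < 1) next
    for (o in seq_len(n_w)) {
      if (o > v || v > o + k - 1L) next
      wk <- substr(wt, o, o + k - 1L)
      mk <- substr(mut, o, o + k - 1L)
      if (wk == mk) next # identical window: the hit (if any) is unchanged
      if (wk %in% set$entries) broken <- broken + 1L
      if (mk %in% set$entries) gained <- gained + 1L
    }
  }
  c(broken = broken, gained = gained)
}

#' Generate labelled variant cases with constructive ground truth
#'
#' Draws random exonic SNVs on a sequence-bearing transcript and records,
#' for each case, the expected triage and exon-skipping consequence labels.
#' All ground truth is computed during construction -- the boundary distance
#' from the chosen position, motif breaks/gains by direct window
#' enumeration against the motif lists, frame status from exon-length
#' arithmetic -- never by the scanning/triage pipeline under test, so
#' recovery tests are not circular.
#'
#' @param transcript A sequence-bearing [transcript_model()] (e.g. from
#'   [make_transcript()]).
#' @param ese,ess [motif_set()]s (or lists of them) defining the regulatory
#'   alphabet.
#' @param n Number of cases.
#' @param seed RNG seed.
#' @param params [triage_params()] used for the expected labels.
#' @return Tibble with the variant (`hgvs_c`, `c_pos`, `ref`, `alt`,
#'   `exon_number`), the scan windows (`wt_window`, `mut_window`,
#'   `window_offset` = variant position within the window) and
#'   `expected_*` ground-truth columns for distance, motif counts, triage
#'   decision and skipping consequence.
#' @export
make_variant_cases <- function(transcript, ese, ess, n = 100, seed = 1L,
                               params = triage_params()) {
  stopifnot(inherits(transcript, "transcript_model"))
  ex <- transcript$exons
  if (any(is.na(ex$sequence))) abort("transcript needs sequences on every exon")
  ese <- as_motif_set_list(ese, "enhancer")
  ess <- as_motif_set_list(ess, "silencer")
  k_max <- max(vapply(c(ese, ess), function(s) s$k, integer(1)))
  withr::with_seed(seed, {
    rows <- purrr::map(seq_len(n), function(i) {
      ei <- sample.int(nrow(ex), 1)
      len <- ex$exon_length[ei]
      off5 <- sample.int(len, 1)
      pos <- ex$c_start[ei] + off5 - 1L
      ref <- substr(ex$sequence[ei], off5, off5)
      alt <- sample(setdiff(DNA_BASES, ref), 1)
      w_lo <- max(1L, off5 - (k_max - 1L))
      w_hi <- min(len, off5 + (k_max - 1L))
      wt_win <- substr(ex$sequence[ei], w_lo, w_hi)
      v <- off5 - w_lo + 1L
      mut_win <- wt_win
      substr(mut_win, v, v) <- alt
      chg <- brute_count_changes(c(ese, ess), wt_win, mut_win, v)
      # split per role with the same direct enumeration
      e_chg <- brute_count_changes(ese, wt_win, mut_win, v)
      s_chg <- brute_count_changes(ess, wt_win, mut_win, v)
      off3 <- len - off5 + 1L
      dist <- min(off5, off3)
      by_prox <- dist <= params$max_boundary_distance
      by_reg <- (e_chg[["broken"]] + s_chg[["gained"]]) > params$disruption_threshold
      tibble(
        gene_id = transcript$gene_id,
        hgvs_c = sprintf("c.%d%s>%s", pos, ref, alt),
        c_pos = pos, ref = ref, alt = alt,
        exon_number = ex$exon_number[ei],
        wt_window = wt_win, mut_window = mut_win, window_offset = v,
        expected_offset5 = off5, expected_offset3 = off3,
        expected_distance = dist,
        expected_ese_broken = e_chg[["broken"]],
        expected_ese_gained = e_chg[["gained"]],
        expected_ess_broken = s_chg[["broken"]],
        expected_ess_gained = s_chg[["gained"]],
        expected_by_proximity = by_prox,
        expected_by_regulatory = by_reg,
        expected_selected = by_prox || by_reg,
        expected_frame_preserved = len %% 3L == 0L,
        expected_aa_lost = if (len %% 3L == 0L) len %/% 3L else NA_integer_,
        expected_first_codon = as.integer(ceiling(ex$c_start[ei] / 3)),
        expected_last_codon = as.integer(ceiling(ex$c_end[ei] / 3))
      )
    })
  })
  list_rbind(rows)
}

#' Simulate densitometry replicates around a true exclusion percentage
#'
#' Adds Gaussian noise to a true exon-exclusion percentage and clips to
#' `[0, 100]`, returning replicate band intensities consistent with each
#' replicate's percentage (fixed total lane intensity).
#'
#' @param true_exclusion True exclusion percentage in `[0, 100]`.
#' @param noise_sd Standard deviation of the additive noise (percentage
#'   points); 0 gives identical replicates.
#' @param n Number of replicates (default 3, the usual assay design).
#' @param seed RNG seed.
#' @param total Total lane intensity (arbitrary units).
#' @return Tibble with `replicate`, `exclusion_percent`, `upper`, `lower`.
#' @export
make_assay_replicates <- function(true_exclusion, noise_sd = 3, n = 3,
                                  seed = 1L, total = 1000) {
  if (true_exclusion < 0 || true_exclusion > 100) {
    abort("true_exclusion must lie in [0, 100]")
  }
  if (n < 1) abort("n must be >= 1")
  withr::with_seed(seed, {
    excl <- pmin(100, pmax(0, rnorm(n, true_exclusion, noise_sd)))
  })
  tibble(
    replicate = seq_len(n),
    exclusion_percent = excl,
    lower = total * excl / 100,
    upper = total * (1 - excl / 100)
  )
}
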