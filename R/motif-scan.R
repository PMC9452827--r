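#' Define a splicing-regulatory motif set
#'
#' A motif set is a named collection of exonic splicing enhancer (ESE) or
#' silencer (ESS) motifs, either as an explicit fixed-length k-mer list or as
#' a weight matrix with a score threshold (a window is a hit when its summed
#' log2-odds score reaches the threshold).
#'
#' @param name Set identifier.
#' @param role `"enhancer"` or `"silencer"`.
#' @param entries Character vector of equal-length k-mers (kind `"kmer"`),
#'   or a 4-row matrix with rownames A/C/G/T (kind `"pwm"`).
#' @param kind `"kmer"` or `"pwm"`.
#' @param threshold Score threshold; required iff `kind = "pwm"`.
#' @return An object of class `motif_set`.
#' @export
#' @examples
#' motif_set("toy", "enhancer", c("GAAGAA", "TGAAGA"))
motif_set <- function(name, role = c("enhancer", "silencer"),
                      entries, kind = c("kmer", "pwm"), threshold = NULL) {
  role <- match.arg(role)
  kind <- match.arg(kind)
  if (kind == "kmer") {
    if (!is.null(threshold)) abort("threshold is only meaningful for pwm motif sets")
    entries <- toupper(as.character(entries))
    assert_dna(entries, "motif")
    ks <- unique(nchar(entries))
    if (length(ks) != 1) abort("all motifs in a set must have the same length")
    entries <- unique(entries)
    k <- ks
  } else {
    if (is.null(threshold)) abort("pwm motif sets need a threshold")
    if (!is.matrix(entries) || !identical(rownames(entries), DNA_BASES)) {
      abort("pwm entries must be a 4-row matrix with rownames A,C,G,T")
    }
    k <- ncol(entries)
  }
  structure(
    list(name = name, role = role, kind = kind, k = as.integer(k),
         entries = entries, threshold = threshold),
    class = "motif_set"
  )
}

#' @export
print.motif_set <- function(x, ...) {
  n <- if (x$kind == "kmer") length(x$entries) else 1L
  cat(sprintf("<motif_set> %s (%s, %s, k = %d, %d entr%s)\n",
              x$name, x$role, x$kind, x$k, n, if (n == 1) "y" else "ies"))
  invisible(x)
}

# score every k-window of seq under a pwm motif matrix (uniform background)
pwm_window_scores <- function(mat, seq) {
  k <- ncol(mat)
  n <- nchar(seq) - k + 1
  vapply(seq_len(n), function(i) {
    bases <- strsplit(substr(seq, i, i + k - 1), "")[[1]]
    sum(log2(mat[cbind(match(bases, c("A", "C", "G", "T")), seq_len(k))] / 0.25))
  }, numeric(1))
}

#' Scan a sequence for motif-set hits
#'
#' Every k-length window of `seq` is tested for membership in (kmer kind) or
#' a threshold-passing score under (pwm kind) the set. Overlapping
#' occurrences are reported separately.
#'
#' @param set A [motif_set()].
#' @param seq A single A/C/G/T string.
#' @return Tibble of hits ordered by `offset` (1-based window start), with
#'   columns `offset` and `motif` (the window sequence); empty when the
#'   sequence is shorter than k or has no hits.
#' @export
#' @examples
#' scan_hits(motif_set("toy", "enhancer", "GAAGAA"), "TTGAAGAATT")
scan_hits <- function(set, seq) {
  stopifnot(inherits(set, "motif_set"))
  seq <- toupper(seq)
  assert_dna(seq, "scan sequence")
  k <- set$k
  n <- nchar(seq) - k + 1
  empty <- tibble(offset = integer(0), motif = character(0))
  if (n < 1) return(empty)
  windows <- substring(seq, seq_len(n), seq_len(n) + k - 1)
  hit <- if (set$kind == "kmer") {
    windows %in% set$entries
  } else {
    pwm_window_scores(set$entries, seq) >= set$threshold
  }
  tibble(offset = seq_len(n)[hit], motif = windows[hit])
}

as_motif_set_list <- function(x, role) {
  if (inherits(x, "motif_set")) x <- list(x)
  if (!is.list(x) || !all(vapply(x, inherits, logical(1), "motif_set"))) {
    abort("expected a motif_set or a list of motif_sets")
  }
  bad <- vapply(x, function(s) s$role != role, logical(1))
  if (any(bad)) {
    abort(sprintf("motif set '%s' has role '%s', expected '%s'",
                  x[[which(bad)[1]]]$name, x[[which(bad)[1]]]$role, role))
  }
  x
}

# hits of one set overlapping a position
overlapping_hits <- function(set, seq, pos) {
  scan_hits(set, seq) |>
    filter(.data$offset <= pos, pos <= .data$offset + set$k - 1)
}

#' Count motifs broken and gained by a single-nucleotide variant
#'
#' Compares motif-set hits between the wild-type and mutant sequence window,
#' restricted to hits overlapping the variant position (an SNV cannot change
#' hits elsewhere). A hit present in wild type and absent in mutant is
#' *broken*; the converse is *gained*. `disruption_sum` is the number of
#' broken enhancers plus gained silencers -- the quantity used by the
#' candidate-selection filter.
#'
#' @param wt_seq,mut_seq Equal-length sequences identical except (at most)
#'   at `variant_offset`. For complete counts the window should extend
#'   `k - 1` bases either side of the variant.
#' @param variant_offset 1-based position of the variant within the window.
#' @param ese,ess A [motif_set()] or list of motif sets with the matching
#'   role. Identical motifs appearing in two sets count once per set.
#' @return One-row tibble: `ese_broken`, `ese_gained`, `ess_broken`,
#'   `ess_gained`, `disruption_sum`.
#' @export
#' @examples
#' ese <- motif_set("toy", "enhancer", "GAAGAA")
#' ess <- motif_set("toy2", "silencer", "TTTTTT")
#' motif_delta("TTGAAGAATT", "TTGACGAATT", 5, ese, ess)
motif_delta <- function(wt_seq, mut_seq, variant_offset, ese, ess) {
  wt_seq <- toupper(wt_seq); mut_seq <- toupper(mut_seq)
  assert_dna(c(wt_seq, mut_seq), "sequence window")
  if (nchar(wt_seq) != nchar(mut_seq)) {
    abort("wild-type and mutant windows must have equal length")
  }
  wt_b <- strsplit(wt_seq, "")[[1]]; mut_b <- strsplit(mut_seq, "")[[1]]
  diff_at <- which(wt_b != mut_b)
  if (length(diff_at) > 1) {
    abort("windows differ at more than one position; expected a single SNV")
  }
  if (length(diff_at) == 1 && diff_at != variant_offset) {
    abort(sprintf("windows differ at position %d, not at variant_offset %d",
                  diff_at, variant_offset))
  }
  ese <- as_motif_set_list(ese, "enhancer")
  ess <- as_motif_set_list(ess, "silencer")

  count_changes <- function(sets) {
    broken <- 0L; gained <- 0L
    for (set in sets) {
      wt_hits <- overlapping_hits(set, wt_seq, variant_offset)
      mut_hits <- overlapping_hits(set, mut_seq, variant_offset)
      broken <- broken + nrow(anti_join(wt_hits, mut_hits, by = c("offset", "motif")))
      gained <- gained + nrow(anti_join(mut_hits, wt_hits, by = c("offset", "motif")))
    }
    c(broken = broken, gained = gained)
  }
  e <- count_changes(ese)
  s <- count_changes(ess)
  tibble(
    ese_broken = e[["broken"]], ese_gained = e[["gained"]],
    ess_broken = s[["broken"]], ess_gained = s[["gained"]],
    disruption_sum = e[["broken"]] + s[["gained"]]
  )
}

#' Read / write motif sets as plain text
#'
#' Format: a header line `#<name> <role> <k> <kind> [<threshold>]` followed
#' by one k-mer per line (kmer kind) or four whitespace-separated weight
#' rows in A,C,G,T order (pwm kind).
#'
#' @param path File path.
#' @return A [motif_set()].
#' @export
read_motif_set <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0 || !startsWith(lines[1], "#")) {
    abort(sprintf("'%s': first line must be a '#name role k kind [threshold]' header", path))
  }
  hdr <- strsplit(sub("^#\\s*", "", lines[1]), "\\s+")[[1]]
  if (length(hdr) < 4) abort("motif-set header needs: name role k kind [threshold]")
  name <- hdr[1]; role <- hdr[2]; k <- as.integer(hdr[3]); kind <- hdr[4]
  threshold <- if (length(hdr) >= 5) as.numeric(hdr[5]) else NULL
  body <- lines[-1]
  if (kind == "kmer") {
    motif_set(name, role, trimws(body), kind = "kmer")
  } else {
    rows <- lapply(body[1:4], function(l) as.numeric(strsplit(trimws(l), "\\s+")[[1]]))
    mat <- do.call(rbind, rows)
    rownames(mat) <- DNA_BASES
    motif_set(name, role, mat, kind = "pwm", threshold = threshold)
  }
}

#' @rdname read_motif_set
#' @param set A [motif_set()] to serialise.
#' @export
write_motif_set <- function(set, path) {
  stopifnot(inherits(set, "motif_set"))
  hdr <- sprintf("#%s %s %d %s%s", set$name, set$role, set$k, set$kind,
                 if (is.null(set$threshold)) "" else paste0(" ", set$threshold))
  body <- if (set$kind == "kmer") {
    set$entries
  } else {
    apply(set$entries, 1, paste, collapse = "\t")
  }
  writeLines(c(hdr, body), path)
  invisible(path)
}
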