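#' Define a splice-site scoring model
#'
#' Two pluggable model kinds are supported, mirroring how published
#' splice-site strength tools expose their scores:
#'
#' * `"pwm"` -- a position weight matrix in frequency form (rows A/C/G/T,
#'   one column per window position, columns summing to 1) with a background
#'   base composition. A window is scored as the sum over positions of
#'   `log2(weight / background)`.
#' * `"kmer"` -- an explicit score table mapping every window sequence to a
#'   score (the form in which maximum-entropy score tables are distributed).
#'
#' The window convention is `n_exonic` exonic plus `n_intronic` intronic
#' bases: donors default to 3+6 (9-mer) and acceptors to 20 intronic + 3
#' exonic (23-mer), the conventional definitions of the widely used scoring
#' services.
#'
#' @param site_type `"donor"` or `"acceptor"`.
#' @param kind `"pwm"` or `"kmer"`.
#' @param payload For `"pwm"`: a 4-row numeric matrix with rownames
#'   A/C/G/T; for `"kmer"`: a named numeric vector keyed by window sequence.
#' @param background Length-4 base frequencies (A,C,G,T) for the pwm kind;
#'   defaults to uniform.
#' @param n_exonic,n_intronic Window composition; defaults depend on
#'   `site_type`.
#' @return An object of class `splice_site_model`.
#' @export
#' @examples
#' pwm <- matrix(0.25, 4, 9, dimnames = list(c("A", "C", "G", "T"), NULL))
#' m <- splice_site_model("donor", "pwm", pwm)
#' score_site(m, "CAGGTAAGT") # uniform matrix scores 0 everywhere
splice_site_model <- function(site_type = c("donor", "acceptor"),
                              kind = c("pwm", "kmer"),
                              payload,
                              background = rep(0.25, 4),
                              n_exonic = NULL, n_intronic = NULL) {
  site_type <- match.arg(site_type)
  kind <- match.arg(kind)
  if (is.null(n_exonic)) n_exonic <- if (site_type == "donor") 3L else 3L
  if (is.null(n_intronic)) n_intronic <- if (site_type == "donor") 6L else 20L
  if (kind == "pwm") {
    if (!is.matrix(payload) || nrow(payload) != 4 ||
        !identical(rownames(payload), DNA_BASES)) {
      abort("pwm payload must be a 4-row matrix with rownames A,C,G,T")
    }
    width <- ncol(payload)
    if (width != n_exonic + n_intronic) {
      abort(sprintf("pwm width %d does not match window %d exonic + %d intronic",
                    width, n_exonic, n_intronic))
    }
    csums <- colSums(payload)
    if (any(abs(csums - 1) > 1e-6)) {
      abort("pwm columns must each sum to 1 (frequency form)")
    }
    if (length(background) != 4 || abs(sum(background) - 1) > 1e-6) {
      abort("background must be 4 frequencies summing to 1")
    }
    background <- setNames(as.numeric(background), DNA_BASES)
  } else {
    if (is.null(names(payload)) || !is.numeric(payload)) {
      abort("kmer payload must be a named numeric vector")
    }
    names(payload) <- toupper(names(payload))
    assert_dna(names(payload), "k-mer table key")
    klens <- unique(nchar(names(payload)))
    if (length(klens) != 1) abort("all k-mer table keys must have equal length")
    if (klens != n_exonic + n_intronic) {
      abort(sprintf("k-mer length %d does not match window %d exonic + %d intronic",
                    klens, n_exonic, n_intronic))
    }
    background <- NULL
  }
  structure(
    list(site_type = site_type, kind = kind, payload = payload,
         background = background,
         n_exonic = as.integer(n_exonic), n_intronic = as.integer(n_intronic)),
    class = "splice_site_model"
  )
}

#' @export
print.splice_site_model <- function(x, ...) {
  cat(sprintf("<splice_site_model> %s %s, window %d exonic + %d intronic\n",
              x$site_type, x$kind, x$n_exonic, x$n_intronic))
  invisible(x)
}

model_width <- function(model) model$n_exonic + model$n_intronic

#' Score splice-site windows under a model
#'
#' @param model A [splice_site_model()].
#' @param seq Character vector of window sequences, each exactly the model
#'   window width, over A/C/G/T.
#' @return Numeric vector of scores (log2 odds for the pwm kind; table
#'   values for the kmer kind). A pwm weight of 0 at an observed base yields
#'   `-Inf`. An unknown window under the kmer kind is an error.
#' @export
score_site <- function(model, seq) {
  stopifnot(inherits(model, "splice_site_model"))
  seq <- toupper(seq)
  assert_dna(seq, "splice-site window")
  w <- model_width(model)
  if (any(nchar(seq) != w)) {
    abort(sprintf("window length must be %d for this model", w))
  }
  if (model$kind == "kmer") {
    out <- unname(model$payload[seq])
    if (anyNA(out)) {
      abort(sprintf("no score table entry for window '%s'", seq[is.na(out)][1]))
    }
    return(out)
  }
  vapply(seq, function(s) {
    bases <- strsplit(s, "")[[1]]
    weights <- model$payload[cbind(match(bases, DNA_BASES), seq_len(w))]
    sum(log2(weights / model$background[bases]))
  }, numeric(1), USE.NAMES = FALSE)
}

#' Percent change of a splice-site score
#'
#' `100 * (mut - wt) / wt`, rounded half-away-from-zero to `digits` decimal
#' places -- the reporting convention for wild-type to mutant score changes.
#' Negative values indicate potential loss of the site.
#'
#' @param wt,mut Wild-type and mutant scores (any common model units);
#'   `wt` must be non-zero.
#' @param digits Decimal places for reporting (default 2).
#' @return Numeric vector of percent changes.
#' @export
#' @examples
#' percent_change(8.55, c(5.41, 2.25, 3.78))
percent_change <- function(wt, mut, digits = 2) {
  if (any(wt == 0)) {
    abort("percent change is undefined for a wild-type score of 0")
  }
  round_half_out(100 * (mut - wt) / wt, digits)
}

#' Wild-type vs mutant splice-site score delta
#'
#' `score_delta()` takes scores directly (e.g. values printed by an external
#' scoring service); `site_delta()` scores the two windows under a model
#' first. The delta is `mut - wt`; a negative delta flags a potential loss
#' of the site.
#'
#' @param wt_score,mut_score Numeric scores.
#' @return One-row tibble with `wt_score`, `mut_score`, `delta`,
#'   `percent_change` (2 d.p.) and `flagged_loss` (`delta < 0`).
#' @export
#' @examples
#' score_delta(8.55, 2.25)
score_delta <- function(wt_score, mut_score) {
  tibble(
    wt_score = wt_score,
    mut_score = mut_score,
    delta = mut_score - wt_score,
    percent_change = percent_change(wt_score, mut_score),
    flagged_loss = mut_score - wt_score < 0
  )
}

#' @rdname score_delta
#' @param model A [splice_site_model()].
#' @param wt_window,mut_window Window sequences differing in at most one
#'   position (an SNV); identical windows are allowed (delta 0, not flagged).
#' @export
site_delta <- function(model, wt_window, mut_window) {
  stopifnot(inherits(model, "splice_site_model"))
  if (nchar(wt_window) != nchar(mut_window)) {
    abort("wild-type and mutant windows must have equal length")
  }
  diffs <- sum(strsplit(wt_window, "")[[1]] != strsplit(mut_window, "")[[1]])
  if (diffs > 1) {
    abort("windows differ at more than one position; expected a single SNV")
  }
  score_delta(score_site(model, wt_window), score_site(model, mut_window))
}

#' Read / write splice-site models as TSV
#'
#' Weight matrices are stored as a TSV with a `base` column holding
#' `A,C,G,T,background` and one column per window position; k-mer score
#' tables as a two-column TSV (`kmer`, `score`).
#'
#' @param path File path.
#' @inheritParams splice_site_model
#' @return A [splice_site_model()].
#' @export
read_pwm_model <- function(path, site_type = c("donor", "acceptor"),
                           n_exonic = NULL, n_intronic = NULL) {
  df <- readr::read_tsv(path, show_col_types = FALSE, comment = "#")
  if (names(df)[1] != "base") abort("first column of a pwm TSV must be 'base'")
  rows <- df$base
  mat <- as.matrix(df[-1])
  bg_row <- which(rows == "background")
  if (length(bg_row) != 1 || !all(DNA_BASES %in% rows)) {
    abort("pwm TSV needs rows A,C,G,T and background")
  }
  pwm <- mat[match(DNA_BASES, rows), , drop = FALSE]
  rownames(pwm) <- DNA_BASES
  splice_site_model(site_type, "pwm", pwm,
                    background = mat[bg_row, 1:4],
                    n_exonic = n_exonic, n_intronic = n_intronic)
}

#' @rdname read_pwm_model
#' @export
read_kmer_model <- function(path, site_type = c("donor", "acceptor"),
                            n_exonic = NULL, n_intronic = NULL) {
  df <- readr::read_tsv(path, show_col_types = FALSE, comment = "#")
  if (!all(c("kmer", "score") %in% names(df))) {
    abort("k-mer TSV needs columns kmer and score")
  }
  kl <- unique(nchar(df$kmer))
  if (length(kl) != 1) abort("all k-mers must have the same length")
  if (is.null(n_exonic)) {
    site_type_m <- match.arg(site_type)
    n_exonic <- 3L
    n_intronic <- kl - 3L
  }
  splice_site_model(site_type, "kmer", setNames(df$score, df$kmer),
                    n_exonic = n_exonic, n_intronic = n_intronic)
}

#' @rdname read_pwm_model
#' @param model A pwm-kind [splice_site_model()] to serialise.
#' @export
write_pwm_model <- function(model, path) {
  stopifnot(inherits(model, "splice_site_model"), model$kind == "pwm")
  w <- model_width(model)
  df <- as_tibble(model$payload, .name_repair = ~ paste0("p", seq_len(w)))
  df <- bind_cols(tibble(base = DNA_BASES), df)
  bg <- c(list(base = "background"),
          as.list(c(unname(model$background), rep(NA_real_, w - 4))[seq_len(w)]))
  names(bg) <- names(df)
  readr::write_tsv(bind_rows(df, as_tibble(bg)), path)
  invisible(path)
}
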