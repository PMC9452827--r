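# Independent oracle implementations used to cross-check the package.
# These are deliberately naive re-derivations, not calls into package internals.

# per-position log-odds sum, written directly from the definition
oracle_pwm_score <- function(pwm, background, window) {
  bases <- strsplit(window, "")[[1]]
  total <- 0
  for (i in seq_along(bases)) {
    total <- total + log2(pwm[bases[i], i] / background[bases[i]])
  }
  unname(total)
}

# exhaustive window diff of motif hits overlapping the variant position
oracle_motif_delta <- function(ese_entries, ess_entries, wt, mut, v) {
  count_one <- function(entries, k) {
    broken <- 0L; gained <- 0L
    if (nchar(wt) >= k) {
      for (o in 1:(nchar(wt) - k + 1)) {
        if (o > v || v > o + k - 1) next
        wk <- substr(wt, o, o + k - 1)
        mk <- substr(mut, o, o + k - 1)
        if (wk == mk) next # unchanged window keeps its hit
        broken <- broken + (wk %in% entries)
        gained <- gained + (mk %in% entries)
      }
    }
    c(broken, gained)
  }
  e <- count_one(ese_entries, nchar(ese_entries[1]))
  s <- count_one(ess_entries, nchar(ess_entries[1]))
  list(ese_broken = e[1], ese_gained = e[2],
       ess_broken = s[1], ess_gained = s[2],
       disruption_sum = e[1] + s[2])
}

# textbook pooled-variance two-sample t statistic and two-sided p
oracle_pooled_t <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  sp2 <- ((n1 - 1) * var(x) + (n2 - 1) * var(y)) / (n1 + n2 - 2)
  t_stat <- (mean(x) - mean(y)) / sqrt(sp2 * (1 / n1 + 1 / n2))
  df <- n1 + n2 - 2
  list(t = t_stat, df = df, p = 2 * pt(-abs(t_stat), df))
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}
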