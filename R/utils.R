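# internal helpers shared across modules

STOP_CODONS <- c("TAA", "TAG", "TGA")

DNA_BASES <- c("A", "C", "G", "T")

# three-letter amino-acid codes keyed by one-letter code, plus "*" for stop
AA_THREE <- c(
  A = "Ala", R = "Arg", N = "Asn", D = "Asp", C = "Cys",
  Q = "Gln", E = "Glu", G = "Gly", H = "His", I = "Ile",
  L = "Leu", K = "Lys", M = "Met", F = "Phe", P = "Pro",
  S = "Ser", T = "Thr", W = "Trp", Y = "Tyr", V = "Val",
  `*` = "Ter"
)

is_dna <- function(x) {
  !is.na(x) & grepl("^[ACGT]+$", x)
}

assert_dna <- function(x, what = "sequence") {
  bad <- !is_dna(x)
  if (any(bad)) {
    abort(sprintf(
      "%s must contain only A/C/G/T (offending value: '%s')",
      what, x[which(bad)[1]]
    ))
  }
  invisible(x)
}

# round half away from zero; base round() rounds half to even
round_half_out <- function(x, digits = 2) {
  scale <- 10^digits
  sign(x) * floor(abs(x) * scale + 0.5 + 1e-9) / scale
}

# split a string into codons (triplets), dropping a trailing partial codon
codon_split <- function(seq) {
  n <- floor(nchar(seq) / 3)
  if (n == 0) return(character(0))
  substring(seq, 3 * seq_len(n) - 2, 3 * seq_len(n))
}

translate_codon <- function(codon) {
  unname(Biostrings::GENETIC_CODE[codon])
}

aa_three <- function(one_letter) {
  unname(AA_THREE[one_letter])
}
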