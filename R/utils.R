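# Shared low-level helpers: codon translation, rounding, RNG scoping.

AA_ALPHABET <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                 "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

# one representative codon per amino acid, used when synthesising junctions
AA_TO_CODON <- c(
  A = "GCT", R = "CGT", N = "AAT", D = "GAT", C = "TGT", Q = "CAA",
  E = "GAA", G = "GGT", H = "CAT", I = "ATT", L = "CTG", K = "AAA",
  M = "ATG", F = "TTT", P = "CCT", S = "AGC", T = "ACT", W = "TGG",
  V = "GTG", Y = "TAT")

#' Translate in-frame nucleotide strings
#'
#' Codon-wise translation using the standard genetic code. Stop codons
#' translate to `"*"`. Strings whose length is not a multiple of 3, or that
#' contain a codon with ambiguity characters, yield `NA`.
#'
#' @param nt Character vector of nucleotide strings.
#' @return Character vector of amino-acid strings (`NA` where untranslatable).
#' @export
translate_nt <- function(nt) {
  vapply(nt, function(s) {
    if (is.na(s)) return(NA_character_)
    n <- nchar(s)
    if (n == 0L || n %% 3L != 0L) return(NA_character_)
    codons <- substring(toupper(s), seq(1L, n, 3L), seq(3L, n, 3L))
    aa <- unname(Biostrings::GENETIC_CODE[codons])
    if (anyNA(aa)) return(NA_character_)
    paste(aa, collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

# CDR3 = IMGT junction minus the flanking 2nd-CYS and J-TRP/J-PHE residues
junction_aa_to_cdr3 <- function(junction_aa) {
  ifelse(is.na(junction_aa) | nchar(junction_aa) < 3L, NA_character_,
         substr(junction_aa, 2L, nchar(junction_aa) - 1L))
}

#' Round half away from zero
#'
#' Deterministic rounding used for all reported percentages (base `round`
#' uses banker's rounding, which is unsuitable for reproducing printed
#' report tables).
#'
#' @param x Numeric vector.
#' @param digits Number of decimal places.
#' @return Rounded numeric vector.
#' @export
round_half_away <- function(x, digits = 0) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5 + 1e-9) / m
}

# Evaluate `expr` under a locally seeded RNG, restoring global state after.
with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

`%||%` <- function(a, b) if (is.null(a)) b else a
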