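# Shared helpers: seeded RNG scoping, codon tables, small sequence utilities.

#' Run code with a local, fully-determining RNG seed
#'
#' All stochastic generators in the package route their randomness through
#' this helper so that a given seed reproduces output byte-for-byte and the
#' caller's RNG state is left untouched.
#'
#' @param seed Integer seed.
#' @param code Code to evaluate.
#' @return The value of `code`.
#' @noRd
with_seed <- function(seed, code) {
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed)) {
    abort("`seed` must be a single finite number.")
  }
  withr::with_seed(as.integer(seed), code, .rng_kind = "Mersenne-Twister",
                   .rng_normal_kind = "Inversion", .rng_sample_kind = "Rejection")
}

DNA_BASES <- c("A", "C", "G", "T")

#' Standard genetic code as a named vector codon -> amino acid
#' @noRd
genetic_code <- function() {
  gc <- Biostrings::GENETIC_CODE
  setNames(as.character(gc), names(gc))
}

STOP_CODONS <- c("TAA", "TAG", "TGA")

#' Synonymous codon families (excluding stops), split by third-base class
#'
#' @return A list keyed by amino acid with elements `gc` (codons ending G/C)
#'   and `at` (codons ending A/T).
#' @noRd
codon_families <- function() {
  code <- genetic_code()
  code <- code[!names(code) %in% STOP_CODONS]
  aas <- unique(code)
  out <- lapply(aas, function(a) {
    cods <- names(code)[code == a]
    third <- substr(cods, 3, 3)
    list(gc = cods[third %in% c("G", "C")], at = cods[third %in% c("A", "T")])
  })
  setNames(out, aas)
}

#' Reverse complement of character DNA string(s)
#' @noRd
revcomp <- function(x) {
  vapply(x, function(s) {
    intToUtf8(rev(utf8ToInt(chartr("ACGTacgtNn", "TGCAtgcaNn", s))))
  }, character(1), USE.NAMES = FALSE)
}

#' Split a DNA string into codons (truncating a trailing partial codon)
#' @noRd
split_codons <- function(x) {
  n <- nchar(x) %/% 3L
  if (n == 0L) return(character(0))
  substring(x, 3L * seq_len(n) - 2L, 3L * seq_len(n))
}

#' Translate a DNA string in frame +1 with the standard code ('*' for stops)
#' @noRd
translate_seq <- function(x) {
  cods <- split_codons(x)
  if (length(cods) == 0L) return("")
  code <- genetic_code()
  aa <- ifelse(cods %in% STOP_CODONS, "*", unname(code[cods]))
  aa[is.na(aa)] <- "X"   # codons containing N
  paste0(aa, collapse = "")
}

#' GC fraction of a nucleotide string, ignoring N
#' @noRd
gc_fraction <- function(x) {
  b <- strsplit(toupper(x), "", fixed = TRUE)[[1]]
  b <- b[b %in% DNA_BASES]
  if (length(b) == 0L) return(NA_real_)
  mean(b %in% c("G", "C"))
}

#' Rolling window means of a numeric vector (window fully inside)
#' @noRd
roll_mean <- function(x, w) {
  n <- length(x)
  if (n < w) return(numeric(0))
  cs <- cumsum(c(0, x))
  (cs[(w + 1L):(n + 1L)] - cs[1:(n - w + 1L)]) / w
}

#' Sample nucleotides with a target GC fraction
#' @noRd
random_dna <- function(n, gc = 0.5) {
  if (n <= 0L) return("")
  p <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
  paste0(sample(DNA_BASES, n, replace = TRUE, prob = p), collapse = "")
}

#' Clamp numeric values
#' @noRd
clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)
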