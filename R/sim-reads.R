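# Sanger-style read simulator: length/quality structure, vector contamination,
# poly(A) tails, substitution errors, with an exact planted truth table.

#' Default logistic quality profile
#'
#' Expected phred value as a function of distance to the nearest read end:
#' high (~45) in the read centre, decaying logistically to ~8 over the last
#' ~30 bases of each end, emulating Sanger trace quality.
#'
#' @param position 0-based position(s) within the read.
#' @param read_len Read length.
#' @param centre,edge Phred values in the centre and at the extreme ends.
#' @return Numeric vector of expected phred values.
#' @export
quality_logistic <- function(position, read_len, centre = 45, edge = 8) {
  d <- pmin(position, read_len - 1 - position)
  edge + (centre - edge) / (1 + exp(-(d - 15) / 4))
}

#' A fixed example cloning-vector sequence
#'
#' A deterministic 300 nt pseudo-vector used as the default contaminant in
#' simulations and tests (it stands in for a real vector database entry;
#' synthetic, not a UniVec record).
#'
#' @return A single character string.
#' @export
example_vector <- function() {
  with_seed(424242L, random_dna(300L, 0.5))
}

#' Simulate quality-annotated reads from a transcriptome
#'
#' Reads are substrings of the reference mRNAs with, optionally: a 3'
#' poly(A) tail appended (read anchored at the transcript 3' end), 5' and/or
#' 3' vector contamination (a vector *suffix* at the 5' end and a vector
#' *prefix* at the 3' end, as at real cloning junctions), reverse
#' complementation, and uniform substitution errors. Per-base phred values
#' are drawn around a positional quality profile. The returned truth table
#' records every planted feature exactly, in 0-based half-open read
#' coordinates.
#'
#' @param transcripts Tibble from [sim_transcriptome()].
#' @param n_reads Total number of reads; allocated to transcripts
#'   proportionally to `copy_number` (largest-remainder rounding). If `NULL`,
#'   `reads_per_copy` reads are emitted per copy.
#' @param reads_per_copy Reads per transcript copy when `n_reads` is `NULL`.
#' @param mean_read_len,len_sd Gaussian read-length model (nt), truncated to
#'   the transcript length.
#' @param error_rate Per-base substitution probability.
#' @param vector_seq Contaminating vector sequence (>= 12 nt when
#'   `vector_rate > 0`).
#' @param vector_rate Fraction of reads carrying vector sequence.
#' @param polya_rate Fraction of reads carrying a 3' poly(A) tail (these
#'   reads are anchored at the transcript 3' end).
#' @param polya_len_range Integer range of tail lengths.
#' @param cap_rate Fraction of the remaining reads anchored at the
#'   transcript 5' end, emulating full-length-enriched (oligo-capped)
#'   library construction.
#' @param revcomp_rate Fraction of reads emitted reverse-complemented.
#' @param quality_profile `function(position, read_len)` giving expected
#'   phred per base; defaults to [quality_logistic()].
#' @param qual_noise_sd Gaussian noise around the profile (rounded, clamped
#'   to \[2, 60\]).
#' @param seed Integer seed; fully determines the output.
#' @return A list with elements `reads` (tibble `id`, `seq`, `qual`
#'   list-column) and `truth` (tibble of per-read planted coordinates:
#'   source transcript and interval, strand, insert/poly(A)/vector intervals
#'   on the read, error count).
#' @export
sim_reads <- function(transcripts,
                      n_reads = NULL, reads_per_copy = 1,
                      mean_read_len = 674, len_sd = 80,
                      error_rate = 0.001,
                      vector_seq = NULL, vector_rate = 0,
                      polya_rate = 0.15, polya_len_range = c(15L, 60L),
                      cap_rate = 0.1, revcomp_rate = 0,
                      quality_profile = NULL, qual_noise_sd = 2,
                      seed = 1L) {
  if (nrow(transcripts) == 0L) abort("`transcripts` must be non-empty.")
  rates <- c(error_rate, vector_rate, polya_rate, revcomp_rate)
  if (any(rates < 0 | rates > 1)) abort("All rates must lie in [0, 1].")
  if (vector_rate > 0 && (is.null(vector_seq) || nchar(vector_seq) < 12L)) {
    abort("`vector_seq` must be at least 12 nt when `vector_rate` > 0.")
  }
  if (is.null(quality_profile)) quality_profile <- quality_logistic

  cn <- transcripts$copy_number
  if (is.null(n_reads)) {
    alloc <- as.integer(round(cn * reads_per_copy))
  } else {
    raw <- n_reads * cn / sum(cn)
    alloc <- floor(raw)
    rem <- n_reads - sum(alloc)
    if (rem > 0) {
      extra <- order(raw - alloc, decreasing = TRUE)[seq_len(rem)]
      alloc[extra] <- alloc[extra] + 1L
    }
    alloc <- as.integer(alloc)
  }

  with_seed(seed, {
    out <- vector("list", sum(alloc))
    k <- 0L
    for (t in seq_len(nrow(transcripts))) {
      if (alloc[t] == 0L) next
      mrna <- transcripts$mrna[[t]]
      L <- nchar(mrna)
      for (r in seq_len(alloc[t])) {
        k <- k + 1L
        out[[k]] <- simulate_one_read(
          mrna, L, transcripts$gene_id[[t]],
          mean_read_len, len_sd, error_rate,
          vector_seq, vector_rate, polya_rate, polya_len_range,
          cap_rate, revcomp_rate, quality_profile, qual_noise_sd)
      }
    }
    col <- function(nm, proto) vapply(out, `[[`, proto, nm)
    ids <- sprintf("R%06d", seq_len(k))
    reads <- tibble(id = ids, seq = col("seq", character(1)),
                    qual = lapply(out, `[[`, "qual"))
    truth <- tibble(
      read_id = ids,
      gene_id = col("gene_id", character(1)),
      strand = col("strand", character(1)),
      mrna_start = col("mrna_start", integer(1)),
      mrna_end = col("mrna_end", integer(1)),
      read_len = col("read_len", integer(1)),
      insert_start = col("insert_start", integer(1)),
      insert_end = col("insert_end", integer(1)),
      polya_start = col("polya_start", integer(1)),
      polya_end = col("polya_end", integer(1)),
      vec5_start = col("vec5_start", integer(1)),
      vec5_end = col("vec5_end", integer(1)),
      vec3_start = col("vec3_start", integer(1)),
      vec3_end = col("vec3_end", integer(1)),
      has_polya = col("has_polya", logical(1)),
      n_errors = col("n_errors", integer(1)))
    list(reads = reads, truth = truth)
  })
}

# Build one read; returns a plain list including seq and qual.
# All coordinates 0-based half-open.
#' @noRd
simulate_one_read <- function(mrna, L, gene_id,
                              mean_read_len, len_sd, error_rate,
                              vector_seq, vector_rate, polya_rate,
                              polya_len_range, cap_rate, revcomp_rate,
                              quality_profile, qual_noise_sd) {
  ilen <- as.integer(clamp(round(rnorm(1, mean_read_len, len_sd)), 40, L))
  has_polya <- runif(1) < polya_rate
  if (has_polya) {
    src_start <- L - ilen
    tail_len <- sample(seq(polya_len_range[1], polya_len_range[2]), 1L)
  } else {
    src_start <- if (runif(1) < cap_rate) 0L else sample.int(L - ilen + 1L, 1L) - 1L
    tail_len <- 0L
  }
  insert <- substr(mrna, src_start + 1L, src_start + ilen)

  v5 <- ""
  v3 <- ""
  if (!is.null(vector_seq) && vector_rate > 0 && runif(1) < vector_rate) {
    vlen <- nchar(vector_seq)
    side <- sample(c("5p", "3p", "both"), 1L, prob = c(0.4, 0.4, 0.2))
    pick <- function() sample(20:min(60L, vlen), 1L)
    if (side %in% c("5p", "both")) v5 <- substr(vector_seq, vlen - pick() + 1L, vlen)
    if (side %in% c("3p", "both")) v3 <- substr(vector_seq, 1L, pick())
  }

  seq <- paste0(v5, insert, strrep("A", tail_len), v3)
  n <- nchar(seq)
  a <- nchar(v5)                       # insert start on read
  ins <- c(a, a + ilen)
  pa <- if (tail_len > 0) c(a + ilen, a + ilen + tail_len) else c(NA_integer_, NA_integer_)
  vi5 <- if (nzchar(v5)) c(0L, nchar(v5)) else c(NA_integer_, NA_integer_)
  vi3 <- if (nzchar(v3)) c(n - nchar(v3), n) else c(NA_integer_, NA_integer_)
  strand <- "+"

  if (runif(1) < revcomp_rate) {
    seq <- revcomp(seq)
    strand <- "-"
    flip <- function(iv) if (is.na(iv[1])) iv else c(n - iv[2], n - iv[1])
    ins <- flip(ins); pa <- flip(pa); tmp <- flip(vi5); vi5 <- flip(vi3); vi3 <- tmp
  }

  n_err <- 0L
  if (error_rate > 0) {
    b <- strsplit(seq, "", fixed = TRUE)[[1]]
    hit <- which(runif(n) < error_rate)
    for (i in hit) b[i] <- sample(setdiff(DNA_BASES, b[i]), 1L)
    n_err <- length(hit)
    seq <- paste0(b, collapse = "")
  }

  expect_q <- quality_profile(seq_len(n) - 1L, n)
  qual <- as.integer(clamp(round(expect_q + rnorm(n, 0, qual_noise_sd)), 2L, 60L))

  list(gene_id = gene_id, strand = strand,
       mrna_start = as.integer(src_start), mrna_end = as.integer(src_start + ilen),
       read_len = as.integer(n),
       insert_start = as.integer(ins[1]), insert_end = as.integer(ins[2]),
       polya_start = as.integer(pa[1]), polya_end = as.integer(pa[2]),
       vec5_start = as.integer(vi5[1]), vec5_end = as.integer(vi5[2]),
       vec3_start = as.integer(vi3[1]), vec3_end = as.integer(vi3[2]),
       has_polya = has_polya, n_errors = n_err,
       seq = seq, qual = qual)
}
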