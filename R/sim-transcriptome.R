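# Synthetic transcriptome generator: mRNAs with distinct CDS/UTR GC structure
# and an expression-dependent GC3 planted by construction.

#' Saturating expression-to-GC3 model
#'
#' GC3 rises with gene copy number (a cDNA-library expression proxy) and
#' plateaus: `gc3(c) = plateau - (plateau - base) * c^(-rate)`. At one copy
#' the value is `base`; for large copy numbers it approaches `plateau`.
#'
#' @param copy_number Positive numeric vector of copy numbers.
#' @param base GC3 at copy number 1.
#' @param plateau Asymptotic GC3 at high expression.
#' @param rate Positive decay exponent controlling how fast the plateau is
#'   reached (the default reaches ~96% of the rise by 25 copies).
#' @return Numeric vector of model GC3 values.
#' @export
gc3_saturating <- function(copy_number, base = 0.40, plateau = 0.55, rate = 1) {
  stopifnot(all(copy_number > 0), is.finite(base), is.finite(plateau), rate > 0)
  plateau - (plateau - base) * copy_number^(-rate)
}

#' Simulate a transcriptome with expression-dependent GC3
#'
#' Generates mRNA models (5'UTR + CDS + 3'UTR) whose third-codon-position GC
#' follows a saturating function of copy number plus Gaussian noise. The CDS
#' starts with ATG, ends with a stop codon, and its realized GC3 tracks the
#' per-gene target closely (GC-ending synonymous codons are allocated by
#' exact count, so the only bias comes from the single-codon amino acids
#' Met and Trp). UTR base composition uses fixed GC targets typical of
#' invertebrate mRNAs.
#'
#' @param n_genes Number of transcripts (>= 1).
#' @param gc3_base,gc3_plateau,gc3_rate Parameters of [gc3_saturating()].
#' @param gc3_noise_sd Gaussian noise added to the per-gene GC3 target
#'   (biological scatter around the expression trend; the default keeps the
#'   planted parameters identifiable at ribosomal-set sample sizes).
#' @param copy_range Integer range of copy numbers; values are drawn
#'   log-uniformly and (for `n_genes >= 2`) both endpoints are forced to be
#'   present so the planted expression gradient spans the full range.
#' @param cds_len_mean Mean CDS length in nt (lognormal; rounded to codons).
#' @param utr5_len_mean,utr3_len_mean Mean UTR lengths in nt.
#' @param gc_utr5,gc_utr3 GC targets of the UTRs.
#' @param fixed_copy_number Optional single value overriding copy-number
#'   sampling (useful for noise-free model checks).
#' @param seed Integer seed; fully determines the output.
#' @return A tibble with one row per transcript: `gene_id`, `utr5`, `cds`,
#'   `utr3`, `mrna`, `copy_number`, `gc3_target`, `gc3_model` (noise-free
#'   model value) and `taxon_profile_id`.
#' @export
sim_transcriptome <- function(n_genes,
                              gc3_base = 0.40, gc3_plateau = 0.55, gc3_rate = 1,
                              gc3_noise_sd = 0.008,
                              copy_range = c(1L, 223L),
                              cds_len_mean = 540, utr5_len_mean = 100,
                              utr3_len_mean = 300,
                              gc_utr5 = 0.457, gc_utr3 = 0.397,
                              fixed_copy_number = NULL,
                              seed = 1L) {
  if (!is.numeric(n_genes) || n_genes < 1) {
    abort("`n_genes` must be a positive count.")
  }
  n_genes <- as.integer(n_genes)
  stopifnot(is.finite(gc3_base), is.finite(gc3_plateau), is.finite(gc3_rate),
            gc3_noise_sd >= 0)
  fams <- codon_families()
  with_seed(seed, {
    if (is.null(fixed_copy_number)) {
      cn <- round(exp(runif(n_genes, log(copy_range[1]), log(copy_range[2]))))
      cn <- as.integer(clamp(cn, copy_range[1], copy_range[2]))
      if (n_genes >= 2L) {
        cn[1L] <- as.integer(copy_range[1])
        cn[n_genes] <- as.integer(copy_range[2])
      }
    } else {
      cn <- rep(as.integer(fixed_copy_number), n_genes)
    }
    model_gc3 <- gc3_saturating(cn, gc3_base, gc3_plateau, gc3_rate)
    target <- clamp(model_gc3 + rnorm(n_genes, 0, gc3_noise_sd), 0.05, 0.95)

    rows <- lapply(seq_len(n_genes), function(i) {
      n_codons <- max(30L, round(stats::rlnorm(1, log(cds_len_mean / 3), 0.45)))
      cds <- make_cds(n_codons, target[i], fams)
      u5 <- random_dna(max(20L, stats::rpois(1, utr5_len_mean)), gc_utr5)
      # in-frame stop immediately upstream of the start codon, so the true
      # initiation site is identifiable by homology-guided frame extension
      substr(u5, nchar(u5) - 2L, nchar(u5)) <- sample(STOP_CODONS, 1L)
      u3 <- random_dna(max(30L, stats::rpois(1, utr3_len_mean)), gc_utr3)
      tibble(gene_id = sprintf("G%04d", i), utr5 = u5, cds = cds, utr3 = u3)
    })
    out <- bind_rows(rows)
    out$mrna <- paste0(out$utr5, out$cds, out$utr3)
    out$copy_number <- cn
    out$gc3_target <- target
    out$gc3_model <- model_gc3
    out$taxon_profile_id <- out$gene_id
    out
  })
}

#' Build one CDS with a planted GC3 (internal)
#'
#' Interior amino acids are drawn uniformly; for each position with a
#' synonymous choice the third-base class (G/C vs A/T) is assigned by exact
#' count. Codons without a synonymous choice (interior ATG/TGG and the
#' start ATG) always end in G; their fixed contribution is subtracted from
#' the GC-ending quota so realized GC3 matches the target up to rounding.
#' @noRd
make_cds <- function(n_codons, gc3_target, fams) {
  n_int <- n_codons - 2L   # minus start ATG and stop
  aas <- sample(names(fams), n_int, replace = TRUE)
  has_choice <- vapply(fams[aas], function(f) length(f$gc) > 0 && length(f$at) > 0, logical(1))
  idx_choice <- which(has_choice)
  n_fixed_gc <- sum(!has_choice) + 1L       # interior ATG/TGG + start ATG
  n_countable <- n_int + 1L                 # all non-stop codons
  n_gc <- max(0L, round(gc3_target * n_countable) - n_fixed_gc)
  gc_pos <- if (length(idx_choice)) sample(idx_choice, min(n_gc, length(idx_choice))) else integer(0)
  use_gc <- logical(n_int)
  use_gc[gc_pos] <- TRUE
  cods <- vapply(seq_len(n_int), function(j) {
    f <- fams[[aas[j]]]
    pool <- if (has_choice[j]) {
      if (use_gc[j]) f$gc else f$at
    } else {
      c(f$gc, f$at)
    }
    pool[sample.int(length(pool), 1L)]
  }, character(1))
  paste0("ATG", paste0(cods, collapse = ""), sample(STOP_CODONS, 1L))
}

#' Realized GC3 of a CDS string (stop codon excluded)
#'
#' @param cds In-frame coding sequence starting at its first codon.
#' @return GC fraction at third codon positions of non-stop codons, or `NA`
#'   if no positions are countable.
#' @export
gc3_of <- function(cds) {
  cods <- split_codons(toupper(cds))
  cods <- cods[!cods %in% STOP_CODONS]
  third <- substr(cods, 3, 3)
  third <- third[third %in% DNA_BASES]
  if (length(third) == 0L) return(NA_real_)
  mean(third %in% c("G", "C"))
}
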