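# Sequence-composition statistics: GC by mRNA region, GC3, codon usage and
# RSCU, correspondence analysis of codon counts, optimal-codon detection,
# expression-vs-GC model fitting, amino-acid composition/charge/
# hydrophobicity profiles, and mean pairwise identity over gapless
# alignment columns.

#' GC content by mRNA region
#'
#' Computes GC fractions of the CDS, its third codon positions (stop codon
#' excluded), and both UTRs for every annotated unigene. N bases are
#' excluded from numerator and denominator; the 3'UTR GC is computed after
#' removal of a terminal poly(A) run when `trim_polya` is set.
#'
#' @param unigenes Tibble with `unigene_id` and `consensus` (or `seq`).
#' @param annotations Tibble from [annotate_cds()] (forward-strand CDS
#'   coordinates `cds_start`, `cds_end`, 0-based half-open; minus-strand
#'   annotations are handled by complementing the region roles).
#' @param expression Optional tibble `unigene_id`, `n_reads` (e.g. from
#'   [expression_proxy()]) joined into the result as `copy_number`.
#' @param trim_polya Remove a trailing A-run (>= 5 nt) from the 3'UTR
#'   before computing its GC.
#' @return A tibble `unigene_id`, `gc_cds`, `gc3`, `gc_utr5`, `gc_utr3`
#'   (and `copy_number` when expression is given). Regions with no
#'   countable base are `NA`.
#' @export
region_gc <- function(unigenes, annotations, expression = NULL,
                      trim_polya = TRUE) {
  seq_col <- if ("consensus" %in% names(unigenes)) "consensus" else "seq"
  ann <- annotations[!is.na(annotations$cds_start), ]
  rows <- lapply(seq_len(nrow(ann)), function(i) {
    a <- ann[i, ]
    s <- toupper(unigenes[[seq_col]][match(a$unigene_id, unigenes$unigene_id)])
    if (identical(a$strand, "-")) s <- revcomp(s)
    n <- nchar(s)
    cs <- if (identical(a$strand, "-")) n - a$cds_end else a$cds_start
    ce <- if (identical(a$strand, "-")) n - a$cds_start else a$cds_end
    cds <- substring(s, cs + 1L, ce)
    u5 <- if (cs > 0) substring(s, 1L, cs) else ""
    u3 <- if (ce < n) substring(s, ce + 1L, n) else ""
    if (trim_polya && nchar(u3) > 0L) {
      u3 <- sub("A{5,}$", "", u3)
    }
    tibble(unigene_id = a$unigene_id,
           gc_cds = gc_fraction(cds),
           gc3 = gc3_of(cds),
           gc_utr5 = if (nzchar(u5)) gc_fraction(u5) else NA_real_,
           gc_utr3 = if (nzchar(u3)) gc_fraction(u3) else NA_real_)
  })
  out <- bind_rows(rows)
  if (!is.null(expression)) {
    out <- left_join(out,
                     rename(expression[, c("unigene_id", "n_reads")],
                            copy_number = "n_reads"),
                     by = "unigene_id")
  }
  out
}

#' Codon usage counts and RSCU
#'
#' Counts all 61 sense codons per gene (codons containing N and
#' frameshift-masked positions are skipped; stop codons are tallied
#' separately) and computes the relative synonymous codon usage, the
#' observed count divided by the expected count under uniform synonymous
#' usage. Codons of amino acids absent from a gene get RSCU `NA`.
#'
#' @param cds_tbl Tibble with a gene id column and an in-frame CDS column.
#' @param gene_col,cds_col Column names.
#' @return A list with `counts` (wide tibble: gene id + one column per
#'   sense codon), `rscu` (long tibble `gene_id`, `codon`, `aa`, `count`,
#'   `rscu`), `stop_counts` (long), and `pooled` (long over all genes).
#' @export
codon_usage <- function(cds_tbl, gene_col = "gene_id", cds_col = "cds") {
  code <- genetic_code()
  sense <- names(code)[!names(code) %in% STOP_CODONS]
  count_one <- function(s) {
    cods <- split_codons(toupper(s))
    cods <- cods[!grepl("[^ACGT]", cods)]
    tab <- table(factor(cods, levels = names(code)))
    as.integer(tab)
  }
  cmat <- t(vapply(cds_tbl[[cds_col]], count_one, integer(length(code))))
  colnames(cmat) <- names(code)
  genes <- cds_tbl[[gene_col]]
  counts <- as_tibble(cmat[, sense, drop = FALSE])
  counts <- dplyr::bind_cols(tibble(gene_id = genes), counts)
  long <- tidyr::pivot_longer(counts, -"gene_id", names_to = "codon",
                              values_to = "count") %>%
    mutate(aa = unname(code[.data$codon]))
  rscu_of <- function(count) {
    s <- sum(count)
    if (s > 0) count / (s / length(count)) else rep(NA_real_, length(count))
  }
  rscu_tbl <- long %>%
    group_by(.data$gene_id, .data$aa) %>%
    mutate(rscu = rscu_of(.data$count)) %>%
    ungroup() %>%
    select("gene_id", "codon", "aa", "count", "rscu")
  stop_long <- tibble(gene_id = rep(genes, each = length(STOP_CODONS)),
                      codon = rep(STOP_CODONS, length(genes)),
                      count = as.integer(t(cmat[, STOP_CODONS, drop = FALSE])))
  pooled <- rscu_tbl %>%
    group_by(.data$codon, .data$aa) %>%
    summarise(count = sum(.data$count), .groups = "drop") %>%
    group_by(.data$aa) %>%
    mutate(rscu = rscu_of(.data$count)) %>%
    ungroup()
  list(counts = counts, rscu = rscu_tbl, stop_counts = stop_long, pooled = pooled)
}

#' Correspondence analysis of a gene-by-codon count matrix
#'
#' Standard CA: singular value decomposition of the standardized Pearson
#' residuals of the relative-frequency matrix. Axes are ordered by inertia;
#' signs are fixed by making the largest-magnitude codon loading on each
#' axis positive, so results are deterministic. Total inertia equals the
#' table's chi-square statistic divided by the grand total.
#'
#' @param counts A numeric matrix (genes x codons), or the `counts` tibble
#'   of [codon_usage()]. All-zero rows/columns are dropped.
#' @param n_axes Number of axes to retain.
#' @return An object of class `est_coa`: list with `row_coords` (tibble:
#'   `gene_id` + `axis1..`), `col_coords` (`codon` + axes), `inertia`
#'   (fraction per retained axis), `eig` (all principal inertias), and
#'   `total_inertia`.
#' @export
correspondence_analysis <- function(counts, n_axes = 4L) {
  if (is.data.frame(counts)) {
    ids <- counts$gene_id
    m <- as.matrix(counts[, setdiff(names(counts), "gene_id")])
    rownames(m) <- ids
  } else {
    m <- as.matrix(counts)
    if (is.null(rownames(m))) rownames(m) <- paste0("row", seq_len(nrow(m)))
  }
  if (is.null(colnames(m))) colnames(m) <- paste0("col", seq_len(ncol(m)))
  if (any(m < 0)) abort("Count matrix must be non-negative.")
  m <- m[rowSums(m) > 0, colSums(m) > 0, drop = FALSE]
  if (nrow(m) < 2L || ncol(m) < 2L) abort("Count matrix has rank < 1 after filtering.")
  n <- sum(m)
  P <- m / n
  r <- rowSums(P)
  c_ <- colSums(P)
  E <- outer(r, c_)
  S <- (P - E) / sqrt(E)
  sv <- svd(S)
  pos <- sv$d > 1e-12
  if (!any(pos)) abort("Count matrix carries no association (rank 0 residuals).")
  d <- sv$d[pos]
  U <- sv$u[, pos, drop = FALSE]
  V <- sv$v[, pos, drop = FALSE]
  k <- min(n_axes, length(d))
  eig <- d^2
  # principal coordinates
  F_ <- sweep(U, 1, sqrt(r), "/") %*% diag(d, nrow = length(d))
  G_ <- sweep(V, 1, sqrt(c_), "/") %*% diag(d, nrow = length(d))
  for (j in seq_len(length(d))) {
    s <- sign(G_[which.max(abs(G_[, j])), j])
    if (s < 0) { G_[, j] <- -G_[, j]; F_[, j] <- -F_[, j] }
  }
  axis_names <- paste0("axis", seq_len(k))
  row_coords <- dplyr::bind_cols(tibble(gene_id = rownames(m)),
                                 as_tibble(setNames(as.data.frame(F_[, seq_len(k), drop = FALSE]),
                                                    axis_names)))
  col_coords <- dplyr::bind_cols(tibble(codon = colnames(m)),
                                 as_tibble(setNames(as.data.frame(G_[, seq_len(k), drop = FALSE]),
                                                    axis_names)))
  structure(list(row_coords = row_coords, col_coords = col_coords,
                 inertia = eig[seq_len(k)] / sum(eig),
                 eig = eig, total_inertia = sum(eig)),
            class = "est_coa")
}

#' @export
print.est_coa <- function(x, ...) {
  cat("Correspondence analysis: ", nrow(x$row_coords), " genes x ",
      nrow(x$col_coords), " codons\n", sep = "")
  cat("Axis inertia fractions:",
      paste(sprintf("%.3f", x$inertia), collapse = ", "), "\n")
  invisible(x)
}

#' Optimal-codon detection from CA axis extremes
#'
#' Reports the codons whose first-axis coordinate lies in the extreme
#' `tail_fraction` at each pole, oriented by the rank correlation between
#' gene axis-1 coordinates and expression: the pole associated with low
#' expression comes first (these are the paper-style candidate non-optimal
#' codons; the opposite pole holds the candidate optimal codons of highly
#' expressed genes).
#'
#' @param coa An `est_coa` object.
#' @param expression Tibble `gene_id`, `copy_number` (or `n_reads`).
#' @param tail_fraction Fraction of codons taken at each pole (0 gives
#'   empty sets).
#' @return A list: `low_expression_codons`, `high_expression_codons`,
#'   `axis1_expression_cor` (Spearman), `p_value`, `tail_fraction`.
#' @export
optimal_codons <- function(coa, expression, tail_fraction = 0.1) {
  expr_col <- if ("copy_number" %in% names(expression)) "copy_number" else "n_reads"
  df <- left_join(coa$row_coords, expression, by = "gene_id")
  ok <- !is.na(df[[expr_col]])
  rho <- NA_real_; pval <- NA_real_
  if (sum(ok) >= 3L && stats::sd(df$axis1[ok]) > 0 && stats::sd(df[[expr_col]][ok]) > 0) {
    ct <- suppressWarnings(stats::cor.test(df$axis1[ok], df[[expr_col]][ok],
                                           method = "spearman"))
    rho <- unname(ct$estimate); pval <- ct$p.value
  }
  cc <- coa$col_coords
  if (tail_fraction <= 0) {
    lo <- character(0); hi <- character(0)
  } else {
    qs <- quantile(cc$axis1, c(tail_fraction, 1 - tail_fraction), names = FALSE)
    neg <- cc$codon[cc$axis1 <= qs[1]]
    pos <- cc$codon[cc$axis1 >= qs[2]]
    # orient: genes with low expression sit where rho says
    if (!is.na(rho) && rho < 0) { lo <- pos; hi <- neg } else { lo <- neg; hi <- pos }
  }
  list(low_expression_codons = sort(lo),
       high_expression_codons = sort(hi),
       axis1_expression_cor = rho, p_value = pval,
       tail_fraction = tail_fraction)
}

#' Fit an expression-to-GC regression model
#'
#' Least-squares fit of GC (or GC3) against an expression proxy under one
#' of the model forms used for EST GC analyses: `linear` (a + b x),
#' `power` (a x^b), `exponential` (a e^(b x)), `logarithmic` (a + b log x)
#' or `saturating` (plateau - (plateau - base) x^(-rate), the planted form
#' of [sim_transcriptome()]). The F statistic compares the fit against the
#' intercept-only model.
#'
#' @param x Positive expression values (copy numbers).
#' @param y GC fractions.
#' @param model Model form.
#' @return An object of class `est_gc_fit`: list with `model`, `params`
#'   (named vector), `rss`, `f_statistic`, `p_value`, `n`, `fitted`,
#'   `residuals`, `data`.
#' @export
fit_expression_gc <- function(x, y,
                              model = c("saturating", "power", "linear",
                                        "exponential", "logarithmic")) {
  model <- match.arg(model)
  x <- unname(x); y <- unname(y)
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3L) abort("Need at least 3 observations.")
  if (model %in% c("power", "logarithmic", "saturating") && any(x <= 0)) {
    abort("`x` must be positive under power/logarithmic/saturating models.")
  }
  fit <- switch(model,
    linear = {
      f <- lm(y ~ x)
      list(params = c(a = unname(coef(f)[1]), b = unname(coef(f)[2])),
           fitted = unname(stats::fitted(f)), npar = 2L)
    },
    logarithmic = {
      f <- lm(y ~ log(x))
      list(params = c(a = unname(coef(f)[1]), b = unname(coef(f)[2])),
           fitted = unname(stats::fitted(f)), npar = 2L)
    },
    power = {
      st <- power_start(x, y)
      f <- minpack.lm::nlsLM(y ~ a * x^b, start = st,
                             control = minpack.lm::nls.lm.control(maxiter = 200))
      list(params = coef(f), fitted = unname(stats::fitted(f)), npar = 2L)
    },
    exponential = {
      pos <- y > 0
      st <- if (sum(pos) >= 2) {
        cf <- coef(lm(log(y[pos]) ~ x[pos]))
        list(a = exp(unname(cf[1])), b = unname(cf[2]))
      } else list(a = mean(y), b = 0)
      f <- minpack.lm::nlsLM(y ~ a * exp(b * x), start = st,
                             control = minpack.lm::nls.lm.control(maxiter = 200))
      list(params = coef(f), fitted = unname(stats::fitted(f)), npar = 2L)
    },
    saturating = {
      st <- list(plateau = max(y), base = y[which.min(x)], rate = 1)
      f <- minpack.lm::nlsLM(y ~ plateau - (plateau - base) * x^(-rate),
                             start = st,
                             control = minpack.lm::nls.lm.control(maxiter = 500))
      list(params = coef(f), fitted = unname(stats::fitted(f)), npar = 3L)
    })
  rss <- sum((y - fit$fitted)^2)
  rss0 <- sum((y - mean(y))^2)
  p <- fit$npar
  fstat <- if (rss > 0 && n > p) ((rss0 - rss) / (p - 1)) / (rss / (n - p)) else Inf
  pv <- if (is.finite(fstat)) stats::pf(fstat, p - 1, n - p, lower.tail = FALSE) else 0
  structure(list(model = model, params = fit$params, rss = rss,
                 f_statistic = fstat, p_value = pv, n = n,
                 fitted = fit$fitted, residuals = y - fit$fitted,
                 data = tibble(x = x, y = y)),
            class = "est_gc_fit")
}

#' @noRd
power_start <- function(x, y) {
  pos <- y > 0
  if (sum(pos) >= 2) {
    cf <- coef(lm(log(y[pos]) ~ log(x[pos])))
    list(a = exp(unname(cf[1])), b = unname(cf[2]))
  } else list(a = mean(y), b = 0)
}

#' @export
print.est_gc_fit <- function(x, ...) {
  cat("Expression-GC fit (", x$model, "), n = ", x$n, "\n", sep = "")
  print(round(x$params, 5))
  cat(sprintf("RSS = %.5g, F = %.3f, p = %.3g\n", x$rss, x$f_statistic, x$p_value))
  invisible(x)
}

#' Compare all expression-to-GC model forms by residual sum of squares
#'
#' @param x,y As in [fit_expression_gc()].
#' @return A tibble `model`, `rss`, `f_statistic`, `p_value`, sorted by RSS.
#' @export
compare_expression_gc <- function(x, y) {
  forms <- c("linear", "power", "exponential", "logarithmic", "saturating")
  rows <- lapply(forms, function(m) {
    f <- tryCatch(fit_expression_gc(x, y, m), error = function(e) NULL)
    if (is.null(f)) return(NULL)
    tibble(model = m, rss = f$rss, f_statistic = f$f_statistic,
           p_value = f$p_value)
  })
  bind_rows(rows) %>% arrange(.data$rss)
}

AA_ORDER <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
              "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

#' The optimal matching hydrophobicity (OMH) scale
#'
#' Per-residue hydrophobicity values of the Sweet & Eisenberg optimal
#' matching scale, which weights hydrophobicity by evolutionary
#' replaceability.
#'
#' @return A named numeric vector over the 20 amino acids.
#' @export
omh_scale <- function() {
  c(A = -0.40, R = -0.59, N = -0.92, D = -1.31, C = 0.17,
    Q = -0.91, E = -1.22, G = -0.67, H = -0.64, I = 1.25,
    L = 1.22, K = -0.67, M = 1.02, F = 1.92, P = -0.49,
    S = -0.55, T = -0.28, W = 0.50, Y = 1.67, V = 0.91)
}

#' Amino-acid composition profiles by taxon, with homogeneity tests
#'
#' Computes per-taxon amino-acid frequencies, the charged fraction
#' (D+E+K+R, optionally including H), the positively-charged fraction
#' (K+R), and the OMH-scale mean hydrophobicity; tests compositional
#' homogeneity across taxa with the chi-square and G (log-likelihood
#' ratio) statistics on the taxon-by-amino-acid count table.
#'
#' @param proteomes Tibble with columns `taxon` and `protein` (amino-acid
#'   strings; non-standard letters ignored).
#' @param include_histidine Count H among charged residues.
#' @return A list with `profiles` (tibble: `taxon`, `n_residues`, one
#'   column per amino acid, `charged_fraction`, `positive_fraction`,
#'   `omh_mean`) and `homogeneity` (one-row tibble: `chi2`, `g`, `df`,
#'   `p_chi2`, `p_g`).
#' @export
aa_composition <- function(proteomes, include_histidine = FALSE) {
  taxa <- unique(proteomes$taxon)
  counts <- t(vapply(taxa, function(tx) {
    s <- paste0(proteomes$protein[proteomes$taxon == tx], collapse = "")
    b <- strsplit(toupper(s), "", fixed = TRUE)[[1]]
    as.integer(table(factor(b, levels = AA_ORDER)))
  }, integer(length(AA_ORDER))))
  colnames(counts) <- AA_ORDER
  rownames(counts) <- taxa
  if (any(rowSums(counts) == 0)) abort("Empty proteome for some taxon.")
  freq <- counts / rowSums(counts)
  charged_set <- c("D", "E", "K", "R", if (include_histidine) "H")
  omh <- omh_scale()
  profiles <- dplyr::bind_cols(
    tibble(taxon = taxa, n_residues = unname(rowSums(counts))),
    as_tibble(freq)) %>%
    mutate(charged_fraction = unname(rowSums(freq[, charged_set, drop = FALSE])),
           positive_fraction = unname(rowSums(freq[, c("K", "R"), drop = FALSE])),
           omh_mean = as.numeric(freq %*% omh[AA_ORDER]))
  homo <- if (length(taxa) >= 2L) {
    keep <- colSums(counts) > 0
    ct <- counts[, keep, drop = FALSE]
    chi <- suppressWarnings(chisq.test(ct))
    E <- chi$expected
    O <- ct
    g <- 2 * sum(ifelse(O > 0, O * log(O / E), 0))
    df <- unname(chi$parameter)
    tibble(chi2 = unname(chi$statistic), g = g, df = df,
           p_chi2 = chi$p.value,
           p_g = pchisq(g, df, lower.tail = FALSE))
  } else {
    tibble(chi2 = NA_real_, g = NA_real_, df = NA_integer_,
           p_chi2 = NA_real_, p_g = NA_real_)
  }
  list(profiles = profiles, homogeneity = homo)
}

#' Mean percent identity between taxa over gapless alignment columns
#'
#' For each ortholog family (one aligned sequence per taxon), columns
#' containing a gap in any sequence are discarded; identities are computed
#' over the concatenation of all retained columns, so every taxon pair
#' uses the identical position set.
#'
#' @param alignments Tibble with columns `family`, `taxon`, `aligned_seq`
#'   (equal lengths within a family; `-` for gaps).
#' @param taxa Taxa to include (default: all taxa present in every family
#'   retained). Families missing any requested taxon are skipped with a
#'   warning.
#' @return A list with `identity` (symmetric percent matrix, diagonal 100),
#'   `n_positions` (gapless columns used) and `n_families`.
#' @export
mean_identity <- function(alignments, taxa = NULL) {
  if (is.null(taxa)) taxa <- sort(unique(alignments$taxon))
  fams <- unique(alignments$family)
  mats <- list()
  used <- 0L
  for (f in fams) {
    a <- alignments[alignments$family == f, ]
    if (!all(taxa %in% a$taxon)) {
      warn(paste0("Family ", f, " is missing some taxa; skipped."))
      next
    }
    a <- a[match(taxa, a$taxon), ]
    chs <- do.call(rbind, strsplit(toupper(a$aligned_seq), "", fixed = TRUE))
    keep <- colSums(chs == "-") == 0
    if (!any(keep)) next
    mats[[length(mats) + 1L]] <- chs[, keep, drop = FALSE]
    used <- used + 1L
  }
  if (length(mats) == 0L) abort("No usable families.")
  big <- do.call(cbind, mats)
  k <- length(taxa)
  idm <- matrix(100, k, k, dimnames = list(taxa, taxa))
  for (i in seq_len(k - 1L)) {
    for (j in (i + 1L):k) {
      v <- 100 * mean(big[i, ] == big[j, ])
      idm[i, j] <- v; idm[j, i] <- v
    }
  }
  list(identity = idm, n_positions = ncol(big), n_families = used)
}
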