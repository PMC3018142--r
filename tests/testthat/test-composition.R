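# Composition statistics: GC hand counts, RSCU, CA vs eigen oracle,
# model fits, amino-acid profiles, identity matrices.

test_that("region GC and GC3 match hand counts on toy sequences", {
  # CDS "ATG GCG TAA": non-stop third positions G, G -> GC3 = 1
  uni <- tibble::tibble(unigene_id = "u1",
                        consensus = paste0("AT", "ATGGCGTAA", "AATT"))
  ann <- tibble::tibble(unigene_id = "u1", cds_start = 2L, cds_end = 11L,
                        strand = "+", seq_length = 15L, source = "homology")
  gc <- region_gc(uni, ann, trim_polya = FALSE)
  expect_equal(gc$gc3, 1.0)
  expect_equal(gc$gc_cds, gc_fraction("ATGGCGTAA"))
  expect_equal(gc$gc_utr5, 0.0)           # "AT"
  expect_equal(gc$gc_utr3, 0.0)           # "AATT"

  # all-N third positions -> GC3 NA
  expect_true(is.na(gc3_of("ATNGCNTAN")))
  # 3'UTR poly(A) removal
  uni2 <- tibble::tibble(unigene_id = "u2",
                         consensus = paste0("ATGGCGTAA", "GGCC", strrep("A", 30)))
  ann2 <- tibble::tibble(unigene_id = "u2", cds_start = 0L, cds_end = 9L,
                         strand = "+", seq_length = nchar(uni2$consensus),
                         source = "homology")
  expect_equal(region_gc(uni2, ann2, trim_polya = TRUE)$gc_utr3, 1.0)
  expect_lt(region_gc(uni2, ann2, trim_polya = FALSE)$gc_utr3, 0.2)
})

test_that("GC3 from the codon table equals GC3 from raw third positions", {
  tx <- sim_transcriptome(30, seed = 131)
  cu <- codon_usage(tx[, c("gene_id", "cds")])
  for (i in seq_len(10)) {
    cnt <- cu$rscu[cu$rscu$gene_id == tx$gene_id[i], ]
    third <- substr(cnt$codon, 3, 3)
    gc3_from_table <- sum(cnt$count[third %in% c("G", "C")]) / sum(cnt$count)
    expect_equal(gc3_from_table, gc3_of(tx$cds[i]), tolerance = 1e-12)
  }
})

test_that("RSCU follows the standard definition", {
  # Met has a single codon: RSCU 1
  cu <- codon_usage(tibble::tibble(gene_id = "g", cds = "ATGATGATG"))
  r <- cu$rscu[cu$rscu$gene_id == "g" & cu$rscu$codon == "ATG", ]
  expect_equal(r$count, 3L)
  expect_equal(r$rscu, 1)
  # uniform synonymous usage of all six Leu codons: RSCU 1 each
  leu <- c("TTA", "TTG", "CTT", "CTC", "CTA", "CTG")
  cu2 <- codon_usage(tibble::tibble(gene_id = "g",
                                    cds = paste0(leu, collapse = "")))
  r2 <- cu2$rscu[cu2$rscu$codon %in% leu, ]
  expect_true(all(r2$rscu == 1))
  # unexpressed amino acids get NA
  expect_true(all(is.na(cu$rscu$rscu[cu$rscu$aa == "L"])))
  # per-amino-acid RSCU averages to 1 when the amino acid occurs
  tx <- sim_transcriptome(5, seed = 132)
  cu3 <- codon_usage(tx[, c("gene_id", "cds")])
  avg <- cu3$rscu |>
    dplyr::filter(!is.na(.data$rscu)) |>
    dplyr::group_by(.data$gene_id, .data$aa) |>
    dplyr::summarise(m = mean(.data$rscu), .groups = "drop")
  expect_true(all(abs(avg$m - 1) < 1e-9))
  # pooled equals the sum of per-gene counts
  pooled_count <- sum(cu3$pooled$count)
  expect_equal(pooled_count, sum(vapply(tx$cds, function(s) {
    cods <- substring(s, seq(1, nchar(s) - 2, 3), seq(3, nchar(s), 3))
    sum(!cods %in% c("TAA", "TAG", "TGA"))
  }, numeric(1))))
})

test_that("correspondence analysis matches the eigendecomposition oracle", {
  skip_if_not_installed("vegan")
  set.seed(141)
  for (i in 1:20) {
    m <- matrix(rpois(10 * 59, sample(5:30, 1)), 10, 59)
    m <- m + 1L   # avoid empty rows/cols
    rownames(m) <- paste0("g", 1:10)
    colnames(m) <- paste0("c", 1:59)
    ca <- correspondence_analysis(m, n_axes = 6)
    ve <- vegan::cca(m)
    k <- min(length(ca$eig), length(ve$CA$eig))
    expect_equal(unname(ca$eig[1:k]), unname(ve$CA$eig[1:k]), tolerance = 1e-8)
    # total inertia identity: chi-square / n
    expect_equal(ca$total_inertia, oracle_total_inertia(m), tolerance = 1e-8)
  }
})

test_that("CA degenerate cases behave as the theory prescribes", {
  # rank-1 association: independence holds exactly, total inertia ~ 0
  r <- c(2, 5, 9, 1)
  cvec <- c(3, 7, 2, 8, 4)
  m <- outer(r, cvec)
  expect_error(correspondence_analysis(m), "no association")
  # identical rows -> same thing
  m2 <- matrix(rep(c(4, 1, 6, 2), each = 5), nrow = 5, byrow = FALSE)
  expect_error(correspondence_analysis(m2), "no association")
  # near-rank-1 perturbation concentrates inertia on axis 1
  set.seed(5)
  m3 <- outer(r * 20, cvec * 10)
  m3[1, 1] <- m3[1, 1] + 40
  ca3 <- correspondence_analysis(m3)
  expect_gt(ca3$inertia[1], 0.99)
  expect_error(correspondence_analysis(matrix(-1, 2, 2)), "non-negative")
})

test_that("optimal codons are recovered from a planted two-regime design", {
  # two gene classes: low-expression genes enriched in a fixed AT-ended
  # codon set, high-expression genes enriched in the GC-ended partners
  at_set <- c("TTA", "CTA", "ATA", "TTT", "AGT", "GAA", "TCA")
  gc_set <- c("TTG", "CTG", "ATC", "TTC", "AGC", "GAG", "TCG")
  other <- c("GGA", "CCA", "GTT", "GCA", "AAA", "CGT")
  set.seed(151)
  mk_gene <- function(low) {
    n <- 300
    pr_main <- if (low) at_set else gc_set
    cods <- c(sample(pr_main, round(n * 0.6), TRUE),
              sample(other, round(n * 0.4), TRUE))
    paste0(sample(cods), collapse = "")
  }
  genes <- tibble::tibble(
    gene_id = sprintf("g%02d", 1:30),
    cds = c(replicate(15, mk_gene(TRUE)), replicate(15, mk_gene(FALSE))))
  expr <- tibble::tibble(gene_id = genes$gene_id,
                         copy_number = c(sample(1:5, 15, TRUE),
                                         sample(80:200, 15, TRUE)))
  cu <- codon_usage(genes)
  ca <- correspondence_analysis(cu$counts, n_axes = 2)
  oc <- optimal_codons(ca, expr, tail_fraction = 7 / nrow(ca$col_coords))
  expect_gte(length(intersect(oc$low_expression_codons, at_set)), 6)
  expect_lte(length(intersect(oc$low_expression_codons, gc_set)), 1)

  # no expression gradient: rank correlation ~ 0
  expr0 <- dplyr::mutate(expr, copy_number = sample(copy_number))
  null_cors <- replicate(50, {
    e <- dplyr::mutate(expr, copy_number = sample(copy_number))
    abs(optimal_codons(ca, e, 0.1)$axis1_expression_cor)
  })
  # observed correlation with planted gradient is extreme vs the null
  expect_gt(abs(oc$axis1_expression_cor), quantile(null_cors, 0.98))

  # degenerate tail fraction
  oc0 <- optimal_codons(ca, expr, tail_fraction = 0)
  expect_length(oc0$low_expression_codons, 0)
  expect_length(oc0$high_expression_codons, 0)
})

test_that("model fits recover noise-free parameters exactly", {
  x <- seq(1, 100, length.out = 40)
  # power: y = 2 x^0.5
  f <- fit_expression_gc(x, 2 * x^0.5, "power")
  expect_equal(unname(f$params["a"]), 2, tolerance = 1e-6)
  expect_equal(unname(f$params["b"]), 0.5, tolerance = 1e-6)
  # constant y: F ~ 0 under the linear model
  fc <- fit_expression_gc(x, rep(0.4, 40), "linear")
  expect_equal(unname(fc$params["b"]), 0, tolerance = 1e-12)
  expect_lt(fc$f_statistic, 1e-6)
  # linear model equals the closed-form least-squares solution
  set.seed(161)
  y <- 0.3 + 0.002 * x + rnorm(40, 0, 0.01)
  fl <- fit_expression_gc(x, y, "linear")
  beta <- cov(x, y) / var(x)
  expect_equal(unname(fl$params["b"]), beta, tolerance = 1e-10)
  expect_equal(unname(fl$params["a"]), mean(y) - beta * mean(x), tolerance = 1e-10)
  # errors
  expect_error(fit_expression_gc(c(-1, 2, 3), c(1, 2, 3), "power"), "positive")
  expect_error(fit_expression_gc(1:2, 1:2, "linear"), "at least 3")
  # tidy/glance accessors
  expect_identical(tidy(fl)$term, c("a", "b"))
  expect_identical(glance(fl)$model, "linear")
})

test_that("saturating parameters are recovered across simulation seeds", {
  ok <- 0L
  n_seeds <- 60L
  for (s in seq_len(n_seeds)) {
    tx <- sim_transcriptome(84, seed = 5000 + s)
    y <- vapply(tx$cds, gc3_of, numeric(1))
    f <- tryCatch(fit_expression_gc(tx$copy_number, y, "saturating"),
                  error = function(e) NULL)
    if (is.null(f)) next
    rel <- abs(c(f$params[["plateau"]] - 0.55, f$params[["base"]] - 0.40,
                 f$params[["rate"]] - 1) / c(0.55, 0.40, 1))
    if (all(rel <= 0.10)) ok <- ok + 1L
  }
  expect_gte(ok / n_seeds, 0.95)
})

test_that("model comparison reports all forms ordered by RSS", {
  x <- seq(1, 120, length.out = 50)
  set.seed(171)
  y <- gc3_saturating(x) + rnorm(50, 0, 0.01)
  cmp <- compare_expression_gc(x, y)
  expect_setequal(cmp$model, c("linear", "power", "exponential",
                               "logarithmic", "saturating"))
  expect_true(!is.unsorted(cmp$rss))
  expect_equal(cmp$model[1], "saturating")
})

test_that("amino-acid profiles, charge fractions and homogeneity behave", {
  p <- tibble::tibble(taxon = c("A", "A", "B"),
                      protein = c("KRKR", "DEDE", "ACDEFGHIKLMNPQRSTVWY"))
  out <- aa_composition(p)
  prof <- out$profiles
  a <- prof[prof$taxon == "A", ]
  expect_equal(a$positive_fraction, 0.5)       # KRKR + DEDE
  expect_equal(a$charged_fraction, 1.0)
  # frequencies sum to 1
  aa_cols <- intersect(names(prof), strsplit("ARNDCQEGHILKMFPSTWYV", "")[[1]])
  expect_equal(rowSums(as.matrix(prof[, aa_cols])), c(1, 1),
               tolerance = 1e-9, ignore_attr = TRUE)
  # single-protein checks
  one <- aa_composition(tibble::tibble(taxon = "t", protein = "KRKR"))$profiles
  expect_equal(one$positive_fraction, 1.0)
  expect_equal(one$charged_fraction, 1.0)
  one2 <- aa_composition(tibble::tibble(taxon = "t", protein = "DEDE"))$profiles
  expect_equal(one2$positive_fraction, 0.0)
  expect_equal(one2$charged_fraction, 1.0)
  # histidine flag
  h1 <- aa_composition(tibble::tibble(taxon = "t", protein = "HHKK"))$profiles
  h2 <- aa_composition(tibble::tibble(taxon = "t", protein = "HHKK"),
                       include_histidine = TRUE)$profiles
  expect_equal(h1$charged_fraction, 0.5)
  expect_equal(h2$charged_fraction, 1.0)
  # identical compositions: chi2 = G = 0
  same <- tibble::tibble(taxon = c("x", "y"),
                         protein = c("ACDKACDK", "ACDKACDK"))
  hom <- aa_composition(same)$homogeneity
  expect_equal(hom$chi2, 0)
  expect_equal(hom$g, 0)
  # homogeneity invariant under row permutation
  p2 <- tibble::tibble(taxon = c("B", "A", "A"),
                       protein = c("ACDEFGHIKLMNPQRSTVWY", "DEDE", "KRKR"))
  expect_equal(aa_composition(p2)$homogeneity$chi2, out$homogeneity$chi2)
  expect_error(aa_composition(tibble::tibble(taxon = "e", protein = "")),
               "Empty")
  # OMH mean: hand check on a single residue
  expect_equal(aa_composition(tibble::tibble(taxon = "t", protein = "FFFF")
                              )$profiles$omh_mean, 1.92)
})

test_that("mean identity uses only shared gapless columns", {
  al <- tibble::tibble(
    family = "f1",
    taxon = c("t1", "t2", "t3"),
    aligned_seq = c("ACDEFG-I",
                    "ACDEFG-I",
                    "ACDEYGHI"))
  # column 7 has a gap in t1/t2 -> dropped for ALL pairs; 7 columns used
  out <- mean_identity(al)
  expect_equal(out$n_positions, 7L)
  expect_equal(out$identity["t1", "t2"], 100)
  expect_equal(out$identity["t1", "t3"], 100 * 6 / 7)
  expect_true(isSymmetric(out$identity))
  expect_equal(unname(diag(out$identity)), rep(100, 3))

  # two sequences differing at exactly half the gapless columns -> 50
  al2 <- tibble::tibble(family = "f", taxon = c("a", "b"),
                        aligned_seq = c("AAAACCCC", "AAAADDDD"))
  expect_equal(mean_identity(al2)$identity["a", "b"], 50)

  # family missing a taxon is skipped with a warning
  al3 <- dplyr::bind_rows(al2, tibble::tibble(family = "g", taxon = "a",
                                              aligned_seq = "AA"))
  expect_warning(out3 <- mean_identity(al3, taxa = c("a", "b")), "skipped")
  expect_equal(out3$n_families, 1L)
})
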