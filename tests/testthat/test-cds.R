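# CDS annotation: homology extension vs brute-force oracle, completeness
# rules, frameshift masking, coding scores, cutoff optimization.

test_that("homology extension equals the brute-force six-frame oracle", {
  for (i in 1:250) {
    fx <- make_mrna_with_hit(i)
    n_sub <- (fx$h1 - fx$h0) / 3
    hit <- list(qstart = fx$h0, qend = fx$h1, frame = fx$frame,
                sstart = 1, send = n_sub, subject_length = n_sub,
                evalue = 1e-20)
    ann <- cds_from_homology(fx$m, hit)
    expect_equal(c(ann$cds_start, ann$cds_end), c(fx$cds_start, fx$cds_end))
    expect_identical(ann$completeness, "complete")
    orc <- oracle_cds_interval(fx$m, fx$h0, fx$h1, fx$frame)
    expect_equal(c(ann$cds_start, ann$cds_end), c(orc[1], orc[2]))
    # frame consistency: protein length x 3 == CDS length (minus stop)
    expect_equal(nchar(ann$protein) * 3 + 3, ann$cds_end - ann$cds_start)
  }
})

test_that("homology extension handles minus-strand hits symmetrically", {
  for (i in 1:50) {
    fx <- make_mrna_with_hit(1000 + i)
    m_rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(fx$m)))
    n <- nchar(fx$m)
    # hit coordinates on the forward strand of the reverse-complemented seq;
    # the minus frame offset is the hit start on the original (work) strand
    h0r <- n - fx$h1; h1r <- n - fx$h0
    fr <- -((fx$h0 %% 3) + 1)
    n_sub <- (fx$h1 - fx$h0) / 3
    hit <- list(qstart = h0r, qend = h1r, frame = fr,
                sstart = 1, send = n_sub, subject_length = n_sub,
                evalue = 1e-20)
    ann <- cds_from_homology(m_rc, hit)
    expect_identical(ann$strand, "-")
    expect_equal(c(n - ann$cds_end, n - ann$cds_start),
                 c(fx$cds_start, fx$cds_end))
  }
})

test_that("completeness follows the start/stop and 80% coverage rules", {
  fx <- make_mrna_with_hit(7)
  n_sub <- (fx$h1 - fx$h0) / 3
  # structurally complete but hit covers only 70% of the subject
  hit70 <- list(qstart = fx$h0, qend = fx$h1, frame = fx$frame,
                sstart = 1, send = round(0.7 * n_sub),
                subject_length = n_sub, evalue = 1e-20)
  ann <- cds_from_homology(fx$m, hit70)
  expect_false(ann$completeness == "complete")
  expect_lt(ann$coverage_of_best_hit, 0.8)
  # coverage >= 80% restores completeness
  hit90 <- modifyList(hit70, list(send = ceiling(0.9 * n_sub)))
  expect_identical(cds_from_homology(fx$m, hit90)$completeness, "complete")

  # no in-frame 5' stop before the sequence start -> partial_5p
  set.seed(99)
  pool <- setdiff(names(Biostrings::GENETIC_CODE), c("TAA", "TAG", "TGA"))
  body <- paste0(paste0(sample(pool, 40, TRUE), collapse = ""), "TGA")
  hit <- list(qstart = 30, qend = 60, frame = 1, sstart = 1, send = 10,
              subject_length = 10, evalue = 1e-10)
  ann2 <- cds_from_homology(body, hit)
  expect_identical(ann2$completeness, "partial_5p")
  expect_identical(ann2$cds_start, 0L)

  # E-value above the cutoff is rejected
  expect_error(cds_from_homology(fx$m, modifyList(hit70, list(evalue = 1e-3))),
               "cutoff")
  expect_error(cds_from_homology(fx$m, modifyList(hit70, list(qstart = fx$h0 + 1))),
               "frame")
})

test_that("frameshift masking inserts X at junctions, rejects mixed strands", {
  set.seed(11)
  pool <- setdiff(names(Biostrings::GENETIC_CODE), c("TAA", "TAG", "TGA"))
  segA <- paste0(sample(pool, 10, TRUE), collapse = "")   # 30 nt, frame +1
  gap <- "ACGTACGTA"                                       # 9 nt
  segB <- paste0(sample(pool, 10, TRUE), collapse = "")
  s <- paste0(segA, gap, "C", segB)                        # +1 shift after gap
  segs <- tibble::tibble(qstart = c(0, 40), qend = c(30, 70),
                         frame = c(1, 2))
  out <- mask_frameshift(s, segs)
  expect_equal(out$n_masked, 3L)
  expect_match(out$protein, "XXX")
  expect_equal(nchar(out$protein), 10 + 3 + 10)

  # single frame: no masking
  one <- mask_frameshift(s, tibble::tibble(qstart = 0, qend = 30, frame = 1))
  expect_equal(one$n_masked, 0L)
  expect_false(grepl("X", one$protein))
  # merged when both segments share a frame
  two_same <- mask_frameshift(s, tibble::tibble(qstart = c(0, 33),
                                                qend = c(30, 60),
                                                frame = c(1, 1)))
  expect_equal(two_same$n_masked, 0L)
  # inconsistent orientation is an error
  expect_error(mask_frameshift(s, tibble::tibble(qstart = c(0, 40),
                                                 qend = c(30, 70),
                                                 frame = c(1, -2))),
               "orientation")
})

test_that("coding score separates model from background and is frame-symmetric", {
  tx <- sim_transcriptome(80, seed = 111)
  set.seed(112)
  bg_train <- replicate(80, paste0(sample(c("A", "C", "G", "T"), 900, TRUE),
                                   collapse = ""))
  model <- train_coding_model(tx$cds, bg_train)
  expect_true(all(is.finite(unclass(model))))
  expect_length(unclass(model), 4096L)

  # Monte-Carlo separation: coding sample scores above same-length background
  wins <- 0L
  for (i in 1:60) {
    sc <- coding_score(sim_model_sequence(model, 3000, "coding", seed = i), model)$score
    sb <- coding_score(sim_model_sequence(model, 3000, "background", seed = 10000 + i), model)$score
    if (sc > sb) wins <- wins + 1L
  }
  expect_gte(wins / 60, 0.99)

  # reverse complement has the identical best-of-six-frames score set
  s <- sim_model_sequence(model, 600, "coding", seed = 5)
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
  expect_equal(unname(sort(coding_score(s, model)$all_frames[[1]])),
               unname(sort(coding_score(rc, model)$all_frames[[1]])),
               tolerance = 1e-9)

  # log-odds additivity: concatenating two in-frame coding parts scores at
  # least as high as either part alone
  a <- sim_model_sequence(model, 900, "coding", seed = 21)
  b <- sim_model_sequence(model, 900, "coding", seed = 22)
  f1 <- function(x) coding_score(x, model)$all_frames[[1]][["1"]]
  expect_gte(f1(paste0(a, b)), max(f1(a), f1(b)))

  expect_error(coding_score("ACGTA", model), "6 nt")
})

test_that("cutoff optimization matches direct counting and ROC is monotone", {
  set.seed(113)
  scores <- c(rnorm(300, 250, 60), rnorm(300, 80, 60))
  labels <- rep(c(TRUE, FALSE), each = 300)
  opt <- optimize_cutoff(scores, labels)
  # independent tally at the returned cutoff
  expect_equal(opt$sensitivity, sum(scores >= opt$cutoff & labels) / 300)
  expect_equal(opt$specificity, sum(scores < opt$cutoff & !labels) / 300)
  # monotonicity across the whole table
  expect_true(all(diff(opt$roc$sensitivity) <= 1e-12))
  expect_true(all(diff(opt$roc$specificity) >= -1e-12))

  # perfectly separated scores: J = 1, sens = spec = 1 inside the gap
  sep <- optimize_cutoff(c(1:10, 101:110), rep(c(FALSE, TRUE), each = 10))
  expect_equal(sep$youden_j, 1)
  expect_equal(sep$sensitivity, 1)
  expect_equal(sep$specificity, 1)

  # permuted labels give J within the permutation null band
  perm_j <- replicate(200, {
    optimize_cutoff(scores, sample(labels))$youden_j
  })
  obs <- optimize_cutoff(scores, sample(labels))$youden_j
  expect_lte(obs, quantile(perm_j, 0.995) + 1e-9)

  expect_error(optimize_cutoff(scores, rep(TRUE, 600)), "Both label classes")
})

test_that("reconciliation applies homology precedence and the score cutoff", {
  hom <- tibble::tibble(cds_start = 0L, cds_end = 30L, strand = "+", frame = 1,
                        protein = "MAAAAAAAA", completeness = "complete",
                        source = "homology", coverage_of_best_hit = 0.9)
  ab <- tibble::tibble(cds_start = 3L, cds_end = 33L, strand = "+", frame = 1,
                       protein = "MV", completeness = "partial_3p",
                       source = "ab_initio", coverage_of_best_hit = NA,
                       score = 300)
  both <- reconcile_cds(hom, ab, cutoff = 200)
  expect_identical(both$source, "homology")
  expect_identical(both$secondary_source, "ab_initio")
  # only ab initio below cutoff: no CDS
  expect_null(reconcile_cds(NULL, dplyr::mutate(ab, score = 150), cutoff = 200))
  # only homology: kept regardless of score
  expect_identical(reconcile_cds(hom, NULL, cutoff = 200)$source, "homology")
})

test_that("annotate_cds recovers planted CDS intervals through the pipeline", {
  tx <- sim_transcriptome(60, seed = 121)
  # planted hits: a protein hit covering codons 3..(k) of each true CDS
  unigenes <- tibble::tibble(unigene_id = tx$gene_id, consensus = tx$mrna)
  hits <- lapply(seq_len(nrow(tx)), function(i) {
    cds0 <- nchar(tx$utr5[i])
    n_cod <- nchar(tx$cds[i]) / 3 - 1   # sans stop
    k0 <- 3L; k1 <- max(k0 + 5L, n_cod - 3L)
    tibble::tibble(query = tx$gene_id[i], subject = paste0("sbj", i),
                   pident = 98, length = (k1 - k0), mismatch = 1, gapopen = 0,
                   qstart = cds0 + 3 * k0 + 1, qend = cds0 + 3 * k1,
                   sstart = k0, send = k1 - 1,
                   evalue = 1e-30, bitscore = 500,
                   frame = ((cds0 + 3 * k0) %% 3) + 1,
                   subject_length = k1 - k0 + 3)
  })
  hits <- dplyr::bind_rows(hits)
  ann <- annotate_cds(unigenes, hits)
  expect_equal(nrow(ann), nrow(tx))
  ok <- 0L
  for (i in seq_len(nrow(tx))) {
    a <- ann[ann$unigene_id == tx$gene_id[i], ]
    if (a$cds_start == nchar(tx$utr5[i]) &&
        a$cds_end == nchar(tx$utr5[i]) + nchar(tx$cds[i])) ok <- ok + 1L
  }
  expect_equal(ok, nrow(tx))
  # UTR/CDS tiling: coordinates partition the unigene
  expect_true(all(ann$cds_start >= 0 & ann$cds_end <= ann$seq_length))
})
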