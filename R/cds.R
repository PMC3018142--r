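# Coding-region determination on unigenes: homology-guided frame extension,
# frameshift masking, ab initio hexamer coding-potential scoring with
# cutoff optimization, and reconciliation with completeness rules.
# Nucleotide coordinates are 0-based half-open on the unigene's forward
# strand; frames follow the BLAST convention (+1..+3, -1..-3).

#' Derive a CDS from a best homology hit by in-frame extension
#'
#' Starting from the frame and interval of the best protein hit
#' (E-value <= `max_evalue`), the match is extended 3' to the first in-frame
#' stop codon (included) or the sequence end, and 5' to the first in-frame
#' stop; when a 5' stop is found, the first ATG after it becomes the
#' initiation codon; when none is found the CDS runs to the sequence start
#' in frame (5'-partial). Completeness requires an ATG start, a stop end,
#' and coverage of at least `min_coverage` of the best hit's subject;
#' structurally complete CDS under that coverage are downgraded to the
#' partial class of the uncovered subject end(s).
#'
#' @param seq Unigene nucleotide sequence.
#' @param hit One-row tibble/list with fields `qstart`, `qend` (0-based
#'   half-open on the forward strand), `frame` (+1..+3 or -1..-3), `sstart`,
#'   `send` (1-based aligned subject residues), `subject_length` (residues),
#'   `evalue`, and optionally `subject`.
#' @param max_evalue Maximum accepted hit E-value.
#' @param min_coverage Best-hit coverage required for completeness.
#' @return One-row tibble: `cds_start`, `cds_end`, `strand`, `frame`,
#'   `protein`, `completeness`, `source`, `coverage_of_best_hit`.
#' @export
cds_from_homology <- function(seq, hit, max_evalue = 1e-5, min_coverage = 0.8) {
  if (hit$evalue > max_evalue) abort("Best hit exceeds the E-value cutoff.")
  frame <- as.integer(hit$frame)
  if (frame == 0L || abs(frame) > 3L) abort("`frame` must be in -3..-1, +1..+3.")
  n <- nchar(seq)
  work <- if (frame > 0) toupper(seq) else revcomp(toupper(seq))
  # hit interval on the working (frame) strand, 0-based half-open
  if (frame > 0) {
    h0 <- hit$qstart; h1 <- hit$qend
  } else {
    h0 <- n - hit$qend; h1 <- n - hit$qstart
  }
  off <- abs(frame) - 1L
  if ((h0 - off) %% 3L != 0L) {
    abort("Hit interval is inconsistent with the stated frame.")
  }

  cods <- split_codons(substring(work, off + 1L, n))
  n_cod <- length(cods)
  hit_c0 <- (h0 - off) %/% 3L + 1L            # first hit codon (1-based)
  hit_c1 <- (h1 - off - 1L) %/% 3L + 1L       # last hit codon
  is_stop <- cods %in% STOP_CODONS

  # 3' extension: first in-frame stop at/after the hit end (included)
  stops_after <- which(is_stop & seq_len(n_cod) >= hit_c1)
  end_c <- if (length(stops_after)) stops_after[1L] else n_cod
  ends_with_stop <- length(stops_after) > 0L

  # 5' extension: first in-frame stop before the hit start, then first ATG
  stops_before <- which(is_stop & seq_len(n_cod) < hit_c0)
  if (length(stops_before)) {
    s5 <- stops_before[length(stops_before)]
    atgs <- which(cods == "ATG" & seq_len(n_cod) > s5 & seq_len(n_cod) <= hit_c1)
    if (length(atgs)) {
      start_c <- atgs[1L]
      starts_with_atg <- TRUE
    } else {
      start_c <- s5 + 1L        # nothing translatable before the hit start
      starts_with_atg <- FALSE
    }
  } else {
    start_c <- 1L
    starts_with_atg <- identical(cods[1L], "ATG")
  }

  cds_w0 <- off + (start_c - 1L) * 3L         # working-strand coords
  cds_w1 <- off + end_c * 3L
  protein <- translate_seq(substring(work, cds_w0 + 1L, cds_w1))
  protein <- sub("\\*$", "", protein)

  coverage <- (hit$send - hit$sstart + 1L) / hit$subject_length
  comp <- completeness_call(starts_with_atg, ends_with_stop, coverage,
                            min_coverage, hit)
  if (frame > 0) {
    cds0 <- cds_w0; cds1 <- cds_w1
  } else {
    cds0 <- n - cds_w1; cds1 <- n - cds_w0
  }
  tibble(cds_start = cds0, cds_end = cds1,
         strand = if (frame > 0) "+" else "-",
         frame = frame, protein = protein,
         completeness = comp, source = "homology",
         coverage_of_best_hit = coverage)
}

# Completeness rules: ATG + stop structurally complete; homology CDS must in
# addition cover >= min_coverage of the best hit, else downgraded to the
# partial class of the uncovered subject end(s).
#' @noRd
completeness_call <- function(starts_with_atg, ends_with_stop, coverage,
                              min_coverage, hit = NULL) {
  structural <- if (starts_with_atg && ends_with_stop) "complete"
    else if (!starts_with_atg && !ends_with_stop) "partial_both"
    else if (!starts_with_atg) "partial_5p"
    else "partial_3p"
  if (structural != "complete" || is.na(coverage) || coverage >= min_coverage) {
    return(structural)
  }
  miss5 <- hit$sstart > 1L
  miss3 <- hit$send < hit$subject_length
  if (miss5 && miss3) "partial_both" else if (miss5) "partial_5p"
  else if (miss3) "partial_3p" else "partial_both"
}

#' Select the best hit per query from a hit table
#'
#' Best = lowest E-value, ties broken by highest alignment length x identity
#' (a bit-score proxy), then by subject id, for determinism.
#'
#' @param hits Tibble with at least `query`, `subject`, `evalue`, `length`,
#'   `pident`.
#' @param max_evalue Maximum E-value retained.
#' @return One row per query.
#' @export
best_hits <- function(hits, max_evalue = 1e-5) {
  hits %>%
    filter(.data$evalue <= max_evalue) %>%
    mutate(bitproxy = .data$length * .data$pident) %>%
    arrange(.data$query, .data$evalue, -.data$bitproxy, .data$subject) %>%
    group_by(.data$query) %>%
    slice(1L) %>%
    ungroup() %>%
    select(-"bitproxy")
}

#' Mask a frameshift junction between hit segments in different frames
#'
#' Given two or more local alignments of the same unigene to the same
#' subject in different frames (same orientation), the translation between
#' adjacent segments is replaced with one 'X' per residue; the flanks are
#' translated in their own frames.
#'
#' @param seq Unigene nucleotide sequence.
#' @param segments Tibble with columns `qstart`, `qend` (0-based half-open,
#'   forward strand) and `frame`; ordered or not.
#' @return A list with `protein` (the masked translation) and `n_masked`
#'   (number of X residues inserted between segments).
#' @export
mask_frameshift <- function(seq, segments) {
  segments <- arrange(as_tibble(segments), .data$qstart)
  fr <- segments$frame
  if (length(unique(sign(fr))) > 1L) {
    abort("Hit segments with inconsistent orientation (mixed +/- frames).")
  }
  if (nrow(segments) >= 2L) {
    same <- all(fr == fr[1L])
    if (same) {
      # overlapping/adjacent segments in one frame: no frameshift, merge
      segments <- tibble(qstart = min(segments$qstart),
                         qend = max(segments$qend), frame = fr[1L])
    }
  }
  n <- nchar(seq)
  work <- if (fr[1L] > 0) toupper(seq) else revcomp(toupper(seq))
  conv <- function(q0, q1) if (fr[1L] > 0) c(q0, q1) else c(n - q1, n - q0)
  if (fr[1L] < 0) segments <- segments[rev(seq_len(nrow(segments))), ]
  parts <- character(0)
  n_masked <- 0L
  for (i in seq_len(nrow(segments))) {
    iv <- conv(segments$qstart[i], segments$qend[i])
    len3 <- ((iv[2] - iv[1]) %/% 3L) * 3L
    parts <- c(parts, translate_seq(substring(work, iv[1] + 1L, iv[1] + len3)))
    if (i < nrow(segments)) {
      nxt <- conv(segments$qstart[i + 1L], segments$qend[i + 1L])
      gap <- max(0L, nxt[1] - iv[2])
      nx <- max(1L, round(gap / 3))
      n_masked <- n_masked + nx
      parts <- c(parts, strrep("X", nx))
    }
  }
  list(protein = paste0(parts, collapse = ""), n_masked = n_masked)
}

#' Train a hexamer coding-potential model
#'
#' An order-5 Markov stand-in for an ESTScan-style coding model: in-frame
#' hexamer (dicodon) frequencies from coding training sequences versus
#' position-free hexamer frequencies from noncoding sequences, as
#' pseudocount-smoothed log-odds. Scores are sums of log2 odds over
#' hexamers stepped by one codon in a fixed frame.
#'
#' @param coding Character vector of in-frame CDS training sequences.
#' @param noncoding Character vector of noncoding training sequences.
#' @param pseudocount Added to every hexamer count.
#' @return An object of class `coding_model` (named numeric log-odds vector
#'   over all 4096 hexamers, all finite).
#' @export
train_coding_model <- function(coding, noncoding, pseudocount = 1) {
  hex_counts <- function(seqs, step) {
    tab <- integer(0)
    for (s in seqs) {
      s <- toupper(s)
      n <- nchar(s)
      if (n < 6L) next
      starts <- seq(1L, n - 5L, by = step)
      h <- substring(s, starts, starts + 5L)
      h <- h[!grepl("[^ACGT]", h)]
      t2 <- table(h)
      tab <- c(tab, t2)
    }
    tapply(as.integer(tab), names(tab), sum)
  }
  all_hex <- all_hexamers()
  cc <- hex_counts(coding, 3L)
  nc <- hex_counts(noncoding, 1L)
  ccv <- setNames(rep(0, length(all_hex)), all_hex)
  ncv <- ccv
  ccv[names(cc)] <- cc
  ncv[names(nc)] <- nc
  ccp <- (ccv + pseudocount) / sum(ccv + pseudocount)
  ncp <- (ncv + pseudocount) / sum(ncv + pseudocount)
  lo <- log2(ccp / ncp)
  structure(lo, class = "coding_model")
}

#' @noRd
all_hexamers <- function() {
  g <- expand.grid(rep(list(DNA_BASES), 6L), stringsAsFactors = FALSE)
  apply(g[, 6:1], 1L, paste0, collapse = "")
}

#' Score the coding potential of a sequence (best of six frames)
#'
#' Sums hexamer log-odds stepped by one codon in each of the six reading
#' frames (three per strand) and reports the best.
#'
#' @param seq Nucleotide sequence (>= 6 nt).
#' @param model A `coding_model` from [train_coding_model()].
#' @return One-row tibble: `score` (best frame), `frame`, plus a list-column
#'   `all_frames` with the six per-frame scores.
#' @export
coding_score <- function(seq, model) {
  if (nchar(seq) < 6L) abort("Coding score is undefined for sequences < 6 nt.")
  fwd <- toupper(seq)
  rev <- revcomp(fwd)
  frames <- c(1L, 2L, 3L, -1L, -2L, -3L)
  scores <- vapply(frames, function(f) {
    s <- if (f > 0) fwd else rev
    off <- abs(f) - 1L
    n <- nchar(s)
    if (n - off < 6L) return(-Inf)
    starts <- seq(off + 1L, n - 5L, by = 3L)
    h <- substring(s, starts, starts + 5L)
    h <- h[!grepl("[^ACGT]", h)]
    if (length(h) == 0L) return(-Inf)
    sum(unclass(model)[h])
  }, numeric(1))
  best <- which.max(scores)
  tibble(score = scores[best], frame = frames[best],
         all_frames = list(setNames(scores, frames)))
}

#' Sample a sequence from a coding or background hexamer process
#'
#' Used to exercise the coding-potential score: emits codons drawn from the
#' model's implied codon distribution (`which = "coding"`) or uniform random
#' bases (`which = "background"`).
#'
#' @param model A `coding_model`.
#' @param length Output length in nt (rounded down to codons for coding).
#' @param which `"coding"` or `"background"`.
#' @param seed Integer seed.
#' @return A character string.
#' @export
sim_model_sequence <- function(model, length, which = c("coding", "background"),
                               seed = 1L) {
  which <- match.arg(which)
  with_seed(seed, {
    if (which == "background") return(random_dna(length, 0.5))
    # derive a codon distribution from the model's high-odds hexamers
    lo <- unclass(model)
    cod <- substr(names(lo), 1L, 3L)
    w <- tapply(2^lo, cod, sum)
    w <- w / sum(w)
    n_cod <- length %/% 3L
    paste0(sample(names(w), n_cod, replace = TRUE, prob = w), collapse = "")
  })
}

#' Optimize an ab initio score cutoff against homology labels
#'
#' For every candidate cutoff c: sensitivity(c) is the fraction of
#' homology-supported sequences with score >= c and specificity(c) the
#' fraction of unsupported sequences with score < c. Returns the full ROC
#' table and the cutoff maximizing Youden's J = sens + spec - 1.
#'
#' @param scores Numeric vector of per-sequence coding scores.
#' @param labels Logical vector: `TRUE` when the sequence has homology
#'   support (treated as the coding class).
#' @return A list with `cutoff`, `sensitivity`, `specificity`, `youden_j`
#'   and `roc` (tibble `cutoff`, `sensitivity`, `specificity`, `youden_j`).
#' @export
optimize_cutoff <- function(scores, labels) {
  labels <- as.logical(labels)
  if (length(unique(labels)) < 2L) {
    abort("Both label classes must be present to optimize a cutoff.")
  }
  cand <- sort(unique(scores))
  n_pos <- sum(labels)
  n_neg <- sum(!labels)
  roc <- tibble(
    cutoff = cand,
    sensitivity = vapply(cand, function(c) sum(scores >= c & labels) / n_pos, numeric(1)),
    specificity = vapply(cand, function(c) sum(scores < c & !labels) / n_neg, numeric(1))
  ) %>% mutate(youden_j = .data$sensitivity + .data$specificity - 1)
  best <- which.max(roc$youden_j)
  list(cutoff = roc$cutoff[best],
       sensitivity = roc$sensitivity[best],
       specificity = roc$specificity[best],
       youden_j = roc$youden_j[best],
       roc = roc)
}

#' Ab initio CDS call in the best-scoring frame
#'
#' Finds the longest open reading frame (ATG..stop when available) in the
#' best-scoring frame of [coding_score()].
#'
#' @param seq Unigene sequence.
#' @param model A `coding_model`.
#' @return One-row tibble matching the [cds_from_homology()] layout with
#'   `source = "ab_initio"` and the coding score in `score`.
#' @export
cds_ab_initio <- function(seq, model) {
  cs <- coding_score(seq, model)
  f <- cs$frame
  n <- nchar(seq)
  work <- if (f > 0) toupper(seq) else revcomp(toupper(seq))
  off <- abs(f) - 1L
  cods <- split_codons(substring(work, off + 1L, nchar(work)))
  orf <- longest_orf(cods)
  if (is.null(orf)) {
    return(tibble(cds_start = NA_integer_, cds_end = NA_integer_,
                  strand = if (f > 0) "+" else "-", frame = f,
                  protein = NA_character_, completeness = NA_character_,
                  source = "ab_initio", coverage_of_best_hit = NA_real_,
                  score = cs$score))
  }
  w0 <- off + (orf$start - 1L) * 3L
  w1 <- off + orf$end * 3L
  protein <- sub("\\*$", "", translate_seq(substring(work, w0 + 1L, w1)))
  comp <- completeness_call(orf$has_atg, orf$has_stop, NA_real_, 0)
  if (f > 0) { c0 <- w0; c1 <- w1 } else { c0 <- n - w1; c1 <- n - w0 }
  tibble(cds_start = c0, cds_end = c1,
         strand = if (f > 0) "+" else "-", frame = f,
         protein = protein, completeness = comp,
         source = "ab_initio", coverage_of_best_hit = NA_real_,
         score = cs$score)
}

# Longest stop-free stretch in a codon vector, preferring ATG starts.
#' @noRd
longest_orf <- function(cods) {
  n <- length(cods)
  if (n == 0L) return(NULL)
  is_stop <- cods %in% STOP_CODONS
  bounds <- c(0L, which(is_stop), n + 1L)
  best <- NULL
  for (i in seq_len(length(bounds) - 1L)) {
    a <- bounds[i] + 1L            # first codon after previous stop
    b <- bounds[i + 1L]            # stop codon (or n+1)
    has_stop <- b <= n && is_stop[b]
    if (a > min(b, n)) next
    atg <- which(cods[a:min(b - 1L, n)] == "ATG")
    if (length(atg) && i > 1L) {   # after a stop, start at the first ATG
      s <- a + atg[1L] - 1L
      has_atg <- TRUE
    } else if (i == 1L) {          # 5'-open segment: run to sequence start
      s <- a
      has_atg <- length(atg) > 0 && atg[1L] == 1L
    } else {
      next
    }
    e <- if (has_stop) b else min(b - 1L, n)
    len <- e - s + 1L
    if (is.null(best) || len > best$len) {
      best <- list(start = s, end = e, len = len,
                   has_atg = has_atg, has_stop = has_stop)
    }
  }
  best
}

#' Reconcile homology and ab initio CDS calls
#'
#' Homology wins when present (frames are deduced from best protein hits);
#' an ab initio call is accepted only when its coding score reaches
#' `cutoff`, and is otherwise dropped.
#'
#' @param homology One-row tibble from [cds_from_homology()] or `NULL`.
#' @param ab_initio One-row tibble from [cds_ab_initio()] or `NULL`.
#' @param cutoff Ab initio acceptance cutoff (e.g. from [optimize_cutoff()]).
#' @return A one-row tibble (the accepted call, with `secondary_source`
#'   recording corroborating evidence) or `NULL` when no call survives.
#' @export
reconcile_cds <- function(homology, ab_initio, cutoff) {
  has_ab <- !is.null(ab_initio) && !is.na(ab_initio$cds_start) &&
    ab_initio$score >= cutoff
  if (!is.null(homology)) {
    homology$secondary_source <- if (has_ab) "ab_initio" else NA_character_
    return(homology)
  }
  if (has_ab) {
    ab_initio$secondary_source <- NA_character_
    return(ab_initio)
  }
  NULL
}

#' Annotate coding regions on a unigene collection
#'
#' Runs the homology track (best hit per unigene, in-frame extension,
#' completeness rules) and the ab initio track (hexamer score in six
#' frames, ORF in the best frame), then reconciles them with homology
#' precedence and the score cutoff.
#'
#' @param unigenes Tibble with `unigene_id` and `consensus` (or `seq`).
#' @param hits Hit table (see [read_hit_table()]) with `frame` and
#'   `subject_length` columns; query coordinates `qstart`/`qend` 1-based
#'   inclusive as in BLAST output (converted internally).
#' @param model A `coding_model`, or `NULL` to skip the ab initio track.
#' @param cutoff Ab initio score cutoff, or `"auto"` to optimize it against
#'   the homology labels via [optimize_cutoff()].
#' @param max_evalue Hit E-value cutoff.
#' @return A tibble with one row per annotated unigene: coordinates, frame,
#'   protein, completeness class, source, coverage, score, plus
#'   `seq_length`; attribute `"cutoff"` stores the cutoff used.
#' @export
annotate_cds <- function(unigenes, hits, model = NULL, cutoff = "auto",
                         max_evalue = 1e-5) {
  seq_col <- if ("consensus" %in% names(unigenes)) "consensus" else "seq"
  bh <- if (!is.null(hits) && nrow(hits)) best_hits(hits, max_evalue) else NULL

  scores <- NULL
  ab_calls <- setNames(vector("list", nrow(unigenes)), unigenes$unigene_id)
  if (!is.null(model)) {
    for (i in seq_len(nrow(unigenes))) {
      s <- unigenes[[seq_col]][[i]]
      if (nchar(s) >= 6L) ab_calls[[i]] <- cds_ab_initio(s, model)
    }
    scores <- vapply(ab_calls, function(x) if (is.null(x)) NA_real_ else x$score,
                     numeric(1))
  }
  if (identical(cutoff, "auto")) {
    if (is.null(model) || is.null(bh)) {
      cutoff <- Inf
    } else {
      lab <- unigenes$unigene_id %in% bh$query
      ok <- !is.na(scores)
      cutoff <- if (length(unique(lab[ok])) == 2L) {
        optimize_cutoff(scores[ok], lab[ok])$cutoff
      } else Inf
    }
  }

  out <- vector("list", nrow(unigenes))
  for (i in seq_len(nrow(unigenes))) {
    uid <- unigenes$unigene_id[[i]]
    s <- unigenes[[seq_col]][[i]]
    hom <- NULL
    if (!is.null(bh) && uid %in% bh$query) {
      h <- bh[bh$query == uid, ]
      hit <- list(qstart = h$qstart - 1L, qend = h$qend,   # to 0-based half-open
                  frame = h$frame, sstart = h$sstart, send = h$send,
                  subject_length = h$subject_length, evalue = h$evalue)
      hom <- tryCatch(cds_from_homology(s, hit, max_evalue),
                      error = function(e) NULL)
    }
    call <- reconcile_cds(hom, ab_calls[[i]], cutoff)
    if (!is.null(call)) {
      call$unigene_id <- uid
      call$seq_length <- nchar(s)
      if (!"score" %in% names(call)) {
        call$score <- if (!is.null(ab_calls[[i]])) ab_calls[[i]]$score else NA_real_
      }
      out[[i]] <- call
    }
  }
  res <- bind_rows(out)
  if (nrow(res)) res <- dplyr::relocate(res, "unigene_id")
  attr(res, "cutoff") <- cutoff
  res
}
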