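# Read cleaning: sliding-window quality clipping, vector masking,
# poly(A)/poly(T) boundary masking, and the keep/too-short/empty-vector
# disposition. Coordinates are 0-based half-open throughout.

#' Quality-clip a read by sliding-window phred means
#'
#' A window of `window` bases is slid through the quality vector from both
#' sides; the clip interval runs from the start of the first window
#' (scanning left to right) whose mean phred exceeds `threshold` to the end
#' of the first such window scanning right to left. Reads shorter than the
#' window are evaluated as a single window. Returns the empty interval
#' `c(0, 0)` when no window qualifies.
#'
#' @param qual Integer/numeric vector of per-base phred values.
#' @param window Window size in bases (>= 1).
#' @param threshold Phred threshold; a window qualifies when its mean is
#'   strictly greater.
#' @return Integer vector `c(start, end)`, a 0-based half-open interval.
#' @export
quality_clip <- function(qual, window = 20L, threshold = 13) {
  if (window <= 0) abort("`window` must be a positive count.")
  n <- length(qual)
  if (n == 0L) return(c(0L, 0L))
  if (n < window) {
    return(if (mean(qual) > threshold) c(0L, n) else c(0L, 0L))
  }
  m <- roll_mean(qual, window)
  ok <- which(m > threshold)
  if (length(ok) == 0L) return(c(0L, 0L))
  c(ok[1L] - 1L, ok[length(ok)] - 1L + window)
}

#' Mask vector-derived segments of reads
#'
#' A seeded-alignment stand-in for cross_match: reads sharing at least one
#' exact `seed_k`-mer with a vector (either strand) are locally aligned to
#' it; every maximal aligned segment of length >= `min_match` with a
#' mismatch+indel rate <= `max_mismatch_rate` is recorded as a `vector`
#' mask. Masking is iterated on the unmasked remainder so that independent
#' 5' and 3' contaminations of the same read are both found.
#'
#' @param reads Tibble with columns `id`, `seq` (and optionally `qual`).
#' @param vectors Character vector of vector sequences (e.g. a UniVec
#'   subset); `NULL` or empty is a no-op.
#' @param min_match Minimum masked segment length (nt).
#' @param max_mismatch_rate Maximum tolerated mismatch+indel fraction.
#' @param seed_k Exact k-mer length required to consider a read at all.
#' @return A tibble `read_id`, `mask_start`, `mask_end`, `label` ("vector"),
#'   0-based half-open on the read.
#' @export
mask_vector <- function(reads, vectors, min_match = 20L,
                        max_mismatch_rate = 0.1, seed_k = 12L) {
  empty <- tibble(read_id = character(0), mask_start = integer(0),
                  mask_end = integer(0), label = character(0))
  if (is.null(vectors) || length(vectors) == 0L || nrow(reads) == 0L) return(empty)
  vec_all <- unique(c(vectors, vapply(vectors, revcomp, character(1))))

  # seed prefilter: any exact k-mer shared with any vector (either strand)
  kmer_starts <- function(s) substring(s, seq_len(max(0L, nchar(s) - seed_k + 1L)),
                                       seq_len(max(0L, nchar(s) - seed_k + 1L)) + seed_k - 1L)
  vec_kmers <- unique(unlist(lapply(vec_all, kmer_starts)))
  pd <- Biostrings::PDict(Biostrings::DNAStringSet(vec_kmers))
  counts <- Biostrings::vcountPDict(pd, Biostrings::DNAStringSet(reads$seq), collapse = 2L)
  cand <- which(counts > 0L)
  if (length(cand) == 0L) return(empty)

  # iterative rounds, vectorized across read fragments: in each round every
  # active fragment is locally aligned to every vector strand in one
  # vectorized call per strand; accepted segments become masks and split
  # their fragment for the next round (so 5' and 3' contamination by the
  # same or different vectors are both found)
  frags <- tibble(read = cand, frag_start = 0L,
                  frag_seq = reads$seq[cand])
  masks <- list()
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -2,
                                                  baseOnly = FALSE)
  repeat {
    frags <- frags[nchar(frags$frag_seq) >= min_match, ]
    if (nrow(frags) == 0L) break
    best_w <- rep(0L, nrow(frags))
    best_s <- rep(NA_integer_, nrow(frags))
    best_e <- rep(NA_integer_, nrow(frags))
    pats <- Biostrings::DNAStringSet(frags$frag_seq)
    for (v in vec_all) {
      al <- Biostrings::pairwiseAlignment(pats, v, type = "local",
                                          substitutionMatrix = mat,
                                          gapOpening = 4, gapExtension = 1)
      w <- Biostrings::nchar(al)
      ind <- Biostrings::nindel(al)
      bad <- Biostrings::nmismatch(al) +
        Biostrings::insertion(ind)[, "WidthSum"] +
        Biostrings::deletion(ind)[, "WidthSum"]
      ok <- w >= min_match & bad / w <= max_mismatch_rate & w > best_w
      if (any(ok)) {
        ps <- Biostrings::start(Biostrings::pattern(al))
        pe <- Biostrings::end(Biostrings::pattern(al))
        best_w[ok] <- w[ok]
        best_s[ok] <- frags$frag_start[ok] + ps[ok] - 1L
        best_e[ok] <- frags$frag_start[ok] + pe[ok]
      }
    }
    hit <- which(best_w > 0L)
    if (length(hit) == 0L) break
    masks[[length(masks) + 1L]] <- tibble(read = frags$read[hit],
                                          mask_start = best_s[hit],
                                          mask_end = best_e[hit])
    # split hit fragments around their mask; unhit fragments are done
    nxt <- list()
    for (h in hit) {
      ridx <- frags$read[h]
      full <- reads$seq[[ridx]]
      fs <- frags$frag_start[h]
      fe <- fs + nchar(frags$frag_seq[h])
      if (best_s[h] - fs >= min_match) {
        nxt[[length(nxt) + 1L]] <- tibble(read = ridx, frag_start = fs,
                                          frag_seq = substr(full, fs + 1L, best_s[h]))
      }
      if (fe - best_e[h] >= min_match) {
        nxt[[length(nxt) + 1L]] <- tibble(read = ridx, frag_start = best_e[h],
                                          frag_seq = substr(full, best_e[h] + 1L, fe))
      }
    }
    frags <- if (length(nxt)) bind_rows(nxt) else frags[0, ]
  }
  if (length(masks) == 0L) return(empty)
  out <- bind_rows(masks)
  tibble(read_id = reads$id[out$read],
         mask_start = as.integer(out$mask_start),
         mask_end = as.integer(out$mask_end),
         label = "vector") %>%
    arrange(.data$read_id, .data$mask_start)
}

#' Mask terminal poly(A)/poly(T) runs
#'
#' Tail presence is detected with the 20-of-25 rule: scanning inward from a
#' read end (or from the inner edge of a terminal vector mask), windows of
#' `window` nt containing at least `hits_required` A (or T) extend a
#' candidate tail region. The reported mask is then trimmed to the maximal
#' contiguous terminal A (or T) run inside that region, so that on
#' error-free reads the mask equals the planted tail exactly. Both base
#' types are searched at both ends.
#'
#' @param seq Read sequence (character scalar).
#' @param hits_required Minimum matching bases per window (<= `window`).
#' @param window Window length (nt).
#' @param bounds Optional 0-based half-open interval to scan within (e.g.
#'   the read minus terminal vector masks); default the whole read.
#' @return Tibble `mask_start`, `mask_end`, `label` ("polyA"/"polyT").
#' @export
mask_poly_tails <- function(seq, hits_required = 20L, window = 25L,
                            bounds = NULL) {
  if (hits_required > window) abort("`hits_required` must be <= `window`.")
  n <- nchar(seq)
  if (is.null(bounds)) bounds <- c(0L, n)
  m <- poly_masks_matrix(toupper(seq), bounds, hits_required, window)
  if (is.null(m)) {
    return(tibble(mask_start = integer(0), mask_end = integer(0), label = character(0)))
  }
  out <- tibble(mask_start = as.integer(m[, 1]), mask_end = as.integer(m[, 2]),
                label = c("polyA", "polyT")[m[, 3]])
  out %>% distinct() %>% arrange(.data$mask_start)
}

# Matrix version (start, end, 1=polyA/2=polyT) used on the hot path.
#' @noRd
poly_masks_matrix <- function(seq_upper, bounds, hits_required, window) {
  b <- strsplit(seq_upper, "", fixed = TRUE)[[1]]
  rows <- NULL
  for (bi in 1:2) {
    base <- c("A", "T")[bi]
    isb <- as.integer(b == base)
    for (end in c("left", "right")) {
      iv <- poly_tail_at_end(isb, bounds, end, hits_required, window)
      if (!is.null(iv)) rows <- rbind(rows, c(iv[1], iv[2], bi))
    }
  }
  rows
}

# Window-detect then run-trim one terminal tail. isb: 0/1 indicator vector.
#' @noRd
poly_tail_at_end <- function(isb, bounds, end, hits_required, window) {
  lo <- bounds[1]; hi <- bounds[2]
  len <- hi - lo
  if (len <= 0L) return(NULL)
  region <- isb[(lo + 1L):hi]
  if (end == "right") region <- rev(region)
  w <- min(window, len)
  need <- if (w < window) ceiling(hits_required * w / window) else hits_required
  # windows anchored at the end, moving inward while qualifying
  cs <- cumsum(c(0L, region))
  count_in <- function(i) cs[i + w] - cs[i]      # window [i-1, i-1+w) 1-based i
  if (count_in(1L) < need) return(NULL)
  imax <- 1L
  while (imax + w < len + 1L && count_in(imax + 1L) >= need) imax <- imax + 1L
  # region qualified: trim to the maximal contiguous terminal run of the base
  run <- 0L
  while (run < len && region[run + 1L] == 1L) run <- run + 1L
  if (run == 0L) return(NULL)
  if (end == "left") c(lo, lo + run) else c(hi - run, hi)
}

#' Clean a collection of reads
#'
#' Applies, in order: sliding-window quality clipping, vector masking,
#' poly(A)/poly(T) boundary masking (anchored at the quality-clip/vector
#' boundaries), and the final length filter. The kept, trimmed sequence is
#' the longest contiguous unmasked stretch inside the quality clip.
#'
#' @param reads Tibble `id`, `seq`, `qual` (list-column), e.g.
#'   `sim_reads()$reads` or [read_fasta_qual()].
#' @param vectors Character vector of vector sequences, or `NULL`.
#' @param window,qual_threshold Quality-clip parameters ([quality_clip()]).
#' @param min_len Minimum kept length in nt (reads shorter are `too_short`).
#' @param min_match,max_mismatch_rate Vector-masking parameters.
#' @param poly_hits,poly_window Poly-tail masking parameters.
#' @return A list with `reads` (kept reads: `id`, `seq`, `qual`,
#'   `clip_start`, `clip_end`, `has_polya`), `masks` (all mask intervals),
#'   `report` (per-read disposition tibble) and `summary` (one-row tibble:
#'   `n_input`, `n_clean`, `n_too_short`, `n_empty_vector`,
#'   `polya_fraction`, `mean_clean_length`).
#' @export
clean_reads <- function(reads, vectors = NULL,
                        window = 20L, qual_threshold = 13,
                        min_len = 100L,
                        min_match = 20L, max_mismatch_rate = 0.1,
                        poly_hits = 20L, poly_window = 25L) {
  n_in <- nrow(reads)
  clips <- lapply(reads$qual, quality_clip, window = window, threshold = qual_threshold)
  clip_mat <- do.call(rbind, clips)
  vmasks <- mask_vector(reads, vectors, min_match = min_match,
                        max_mismatch_rate = max_mismatch_rate)

  vmask_by_read <- split(seq_len(nrow(vmasks)), vmasks$read_id)
  disposition <- character(n_in)
  out_rows <- vector("list", n_in)
  poly_list <- vector("list", n_in)
  for (i in seq_len(n_in)) {
    vrows <- vmask_by_read[[reads$id[[i]]]]
    vm <- if (is.null(vrows)) NULL else
      cbind(vmasks$mask_start[vrows], vmasks$mask_end[vrows])
    res <- finalize_read(reads$id[[i]], reads$seq[[i]], reads$qual[[i]],
                         clip_mat[i, ], vm, min_len, poly_hits, poly_window)
    disposition[i] <- res$disposition
    out_rows[[i]] <- res$row
    poly_list[[i]] <- res$poly_masks
  }
  keep_idx <- which(!vapply(out_rows, is.null, logical(1)))
  kept <- tibble(
    id = vapply(out_rows[keep_idx], `[[`, character(1), "id"),
    seq = vapply(out_rows[keep_idx], `[[`, character(1), "seq"),
    qual = lapply(out_rows[keep_idx], `[[`, "qual"),
    clip_start = vapply(out_rows[keep_idx], function(r) as.integer(r$clip_start), integer(1)),
    clip_end = vapply(out_rows[keep_idx], function(r) as.integer(r$clip_end), integer(1)),
    has_polya = vapply(out_rows[keep_idx], `[[`, logical(1), "has_polya"))
  poly_idx <- which(!vapply(poly_list, is.null, logical(1)))
  poly_tbl <- if (length(poly_idx)) {
    pm <- do.call(rbind, poly_list[poly_idx])
    tibble(read_id = rep(reads$id[poly_idx],
                         vapply(poly_list[poly_idx], nrow, integer(1))),
           mask_start = as.integer(pm[, 1]), mask_end = as.integer(pm[, 2]),
           label = c("polyA", "polyT")[pm[, 3]])
  } else {
    tibble(read_id = character(0), mask_start = integer(0),
           mask_end = integer(0), label = character(0))
  }
  all_masks <- list(vmasks, poly_tbl)
  report <- tibble(read_id = reads$id, disposition = disposition)
  polya_fraction <- if (nrow(kept)) mean(kept$has_polya) else NA_real_
  summary <- tibble(
    n_input = n_in,
    n_clean = sum(disposition == "kept"),
    n_too_short = sum(disposition == "too_short"),
    n_empty_vector = sum(disposition == "empty_vector"),
    polya_fraction = polya_fraction,
    mean_clean_length = if (nrow(kept)) mean(nchar(kept$seq)) else NA_real_)
  list(reads = kept, masks = bind_rows(all_masks), report = report, summary = summary)
}

# Apply poly masking + disposition rules to one read. Returns a plain list:
# disposition, kept fields (or NULL) and poly-mask matrix (or NULL).
#' @noRd
finalize_read <- function(id, seq, qual, clip, vm, min_len, poly_hits, poly_window) {
  cs <- clip[1]; ce <- clip[2]
  if (ce <= cs) {
    return(list(disposition = "too_short", row = NULL, poly_masks = NULL))
  }
  # clip region minus vector masks -> unmasked sub-intervals
  ivs <- subtract_intervals(c(cs, ce), vm)
  if (is.null(ivs)) {
    return(list(disposition = "empty_vector", row = NULL, poly_masks = NULL))
  }
  # poly-tail masking inside each unmasked sub-interval (boundaries =
  # read/clip ends and vector-mask edges)
  su <- toupper(seq)
  poly <- NULL
  for (r in seq_len(nrow(ivs))) {
    pm <- poly_masks_matrix(su, c(ivs[r, 1], ivs[r, 2]), poly_hits, poly_window)
    if (!is.null(pm)) poly <- rbind(poly, pm)
  }
  has_polya <- !is.null(poly)
  # subtract poly masks too, keep the longest contiguous unmasked stretch
  remain <- ivs
  if (has_polya) {
    pieces <- lapply(seq_len(nrow(remain)), function(r) {
      subtract_intervals(c(remain[r, 1], remain[r, 2]), poly[, 1:2, drop = FALSE])
    })
    pieces <- pieces[!vapply(pieces, is.null, logical(1))]
    remain <- if (length(pieces)) do.call(rbind, pieces) else NULL
  }
  if (is.null(remain) || max(remain[, 2] - remain[, 1]) < min_len) {
    disp <- "too_short"
    row <- NULL
  } else {
    disp <- "kept"
    bi <- which.max(remain[, 2] - remain[, 1])
    s0 <- remain[bi, 1]; e0 <- remain[bi, 2]
    row <- list(id = id,
                seq = substr(seq, s0 + 1L, e0),
                qual = qual[(s0 + 1L):e0],
                clip_start = s0, clip_end = e0,
                has_polya = has_polya)
  }
  list(disposition = disp, row = row, poly_masks = poly)
}

# Subtract mask intervals (matrix start/end cols) from one interval.
# Returns a matrix of start/end rows, or NULL if nothing remains.
#' @noRd
subtract_intervals <- function(iv, masks) {
  cur <- list(iv)
  if (!is.null(masks) && nrow(masks)) {
    for (m in seq_len(nrow(masks))) {
      ms <- masks[m, 1]; me <- masks[m, 2]
      nxt <- list()
      for (x in cur) {
        if (me <= x[1] || ms >= x[2]) { nxt[[length(nxt) + 1L]] <- x; next }
        if (ms > x[1]) nxt[[length(nxt) + 1L]] <- c(x[1], ms)
        if (me < x[2]) nxt[[length(nxt) + 1L]] <- c(me, x[2])
      }
      cur <- nxt
      if (length(cur) == 0L) break
    }
  }
  if (length(cur) == 0L) return(NULL)
  do.call(rbind, cur)
}
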