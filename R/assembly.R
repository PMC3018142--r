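# Stringent greedy overlap-layout-consensus assembly of cleaned reads into
# unigenes (contigs + singletons), honouring the CAP3-style contract:
# merge only on overlaps of >= min_overlap nt at >= overlap_identity, with
# at most clip_range nt of read end clipped to reconcile an overlap;
# reverse-complement overlaps allowed; consensus by per-column
# quality-weighted majority. Deterministic: no RNG, fixed processing order.

#' Assemble cleaned reads into unigenes
#'
#' Reads are processed in descending length (ties by id). Each read is
#' compared, via shared k-mers, against the consensus of every unigene
#' built so far; candidate overlaps are scored by ends-free pairwise
#' alignment and the read joins the best unigene whose overlap passes the
#' length/identity/clipping thresholds (on either strand), extending the
#' consensus where the read overhangs. Reads with no qualifying overlap
#' start new unigenes. A final consolidation pass greedily merges unigene
#' pairs whose consensi themselves overlap above the same thresholds
#' (highest overlap score first), so that reads bridging two growing
#' contigs end up in a single unigene.
#'
#' @param reads Tibble `id`, `seq`, `qual` (list-column), e.g.
#'   `clean_reads()$reads`.
#' @param overlap_identity Minimum overlap percent identity (fraction).
#' @param clip_range Maximum read-end clipping (nt) tolerated when
#'   reconciling a read with an overlap.
#' @param min_overlap Minimum overlap length (nt).
#' @param k K-mer length for candidate detection.
#' @param min_kmer_hits Minimum shared k-mers to attempt an alignment.
#' @return A list with `unigenes` (tibble `unigene_id`, `consensus`, `kind`,
#'   `n_members`, `length`) and `members` (tibble `read_id`, `unigene_id`,
#'   `offset`, `strand`), where `offset` is the 0-based start of the read on
#'   the unigene consensus.
#' @export
assemble_reads <- function(reads, overlap_identity = 0.90, clip_range = 30L,
                           min_overlap = 40L, k = 16L, min_kmer_hits = 2L) {
  if (overlap_identity <= 0 || overlap_identity > 1) {
    abort("`overlap_identity` must lie in (0, 1].")
  }
  if (nrow(reads) == 0L) {
    return(list(unigenes = tibble(unigene_id = character(0), consensus = character(0),
                                  kind = character(0), n_members = integer(0),
                                  length = integer(0)),
                members = tibble(read_id = character(0), unigene_id = character(0),
                                 offset = integer(0), strand = character(0))))
  }
  ord <- order(-nchar(reads$seq), reads$id)
  reads <- reads[ord, ]

  st <- new_assembly_state(k)
  for (i in seq_len(nrow(reads))) {
    place_read(st, reads$id[[i]], reads$seq[[i]], as.numeric(reads$qual[[i]]),
               overlap_identity, clip_range, min_overlap, min_kmer_hits)
  }
  consolidate_unigenes(st, overlap_identity, clip_range, min_overlap, min_kmer_hits)
  finish_assembly(st)
}

# Mutable assembly state in an environment.
#' @noRd
new_assembly_state <- function(k) {
  st <- new.env(parent = emptyenv())
  st$k <- as.integer(k)
  st$unigenes <- list()      # each: list(profile, members=tibble, alive=TRUE)
  st$index <- new.env(hash = TRUE, parent = emptyenv())  # kmer -> int ids
  st
}

#' @noRd
kmers_of <- function(seq, k) {
  n <- nchar(seq)
  if (n < k) return(character(0))
  unique(substring(seq, 1:(n - k + 1L), k:n))
}

#' @noRd
index_add <- function(st, seq, uid) {
  for (km in kmers_of(seq, st$k)) {
    st$index[[km]] <- c(st$index[[km]], uid)
  }
}

# Candidate unigene ids for a sequence, by shared-kmer count (descending).
#' @noRd
index_candidates <- function(st, seq, min_hits, exclude = integer(0)) {
  kms <- kmers_of(seq, st$k)
  acc <- vector("list", length(kms))
  for (i in seq_along(kms)) {
    v <- st$index[[kms[i]]]
    if (!is.null(v)) acc[[i]] <- v
  }
  hits <- unlist(acc, use.names = FALSE)
  if (length(hits) == 0L) return(integer(0))
  cnt_all <- tabulate(hits)
  ids <- which(cnt_all >= min_hits)
  ids <- setdiff(ids, exclude)
  if (length(ids) == 0L) return(integer(0))
  alive <- vapply(ids, function(u) isTRUE(st$unigenes[[u]]$alive), logical(1))
  ids <- ids[alive]
  ids[order(-cnt_all[ids], ids)]
}

#' @noRd
profile_consensus <- function(profile) {
  if (ncol(profile) == 0L) return("")
  paste0(DNA_BASES[max.col(t(profile), ties.method = "first")], collapse = "")
}

# Score an ends-free overlap between seq (pattern) and consensus (subject):
# a seed-diagonal ungapped check first (exact for substitution-only
# divergence), falling back to banded ends-free alignment only when the
# ungapped check comes close but misses (suggesting indels).
#' @noRd
score_overlap <- function(seq, cons, overlap_identity, clip_range, min_overlap,
                          k = 16L) {
  fast <- fast_overlap(seq, cons, overlap_identity, min_overlap, k)
  if (!is.null(fast$hit)) return(fast$hit)
  if (!isTRUE(fast$near_miss)) return(NULL)
  score_overlap_align(seq, cons, overlap_identity, clip_range, min_overlap)
}

# Ungapped overlap via shared-kmer diagonals.
#' @noRd
fast_overlap <- function(seq, cons, overlap_identity, min_overlap, k = 16L) {
  n <- nchar(seq); L <- nchar(cons)
  if (n < k || L < k) return(list(hit = NULL, near_miss = TRUE))
  offs <- unique(c(seq(1L, n - k + 1L, by = 12L), n - k + 1L))
  diags <- integer(0)
  for (o in offs) {
    km <- substr(seq, o, o + k - 1L)
    if (grepl("[^ACGT]", km)) next
    hits <- gregexpr(km, cons, fixed = TRUE)[[1]]
    if (hits[1] == -1L) next
    diags <- c(diags, as.integer(hits) - o)
  }
  if (length(diags) == 0L) return(list(hit = NULL, near_miss = FALSE))
  tab <- sort(table(diags), decreasing = TRUE)
  best <- NULL
  best_ident <- 0
  for (d in as.integer(names(tab))[seq_len(min(3L, length(tab)))]) {
    rs <- max(1L, 1L - d)
    re <- min(n, L - d)
    ov <- re - rs + 1L
    if (ov < min_overlap) next
    a <- charToRaw(substr(seq, rs, re))
    b <- charToRaw(substr(cons, rs + d, re + d))
    ident <- 1 - sum(a != b) / ov
    if (ident > best_ident) best_ident <- ident
    if (ident >= overlap_identity) {
      cand <- list(score = ov * ident, ov = ov, identity = ident,
                   ps = rs, pe = re, ss = rs + d, se = re + d,
                   pat = substr(seq, rs, re), sub = substr(cons, rs + d, re + d))
      if (is.null(best) || cand$score > best$score) best <- cand
    }
  }
  list(hit = best, near_miss = best_ident >= overlap_identity - 0.05)
}

#' @noRd
score_overlap_align <- function(seq, cons, overlap_identity, clip_range, min_overlap) {
  al <- Biostrings::pairwiseAlignment(seq, cons, type = "overlap",
                                      substitutionMatrix = overlap_submat(),
                                      gapOpening = 6, gapExtension = 1)
  ov <- Biostrings::nchar(al)
  if (ov < min_overlap) return(NULL)
  ident <- Biostrings::nmatch(al) / ov
  if (ident < overlap_identity) return(NULL)
  ps <- Biostrings::start(Biostrings::pattern(al)); pe <- Biostrings::end(Biostrings::pattern(al))
  ss <- Biostrings::start(Biostrings::subject(al)); se <- Biostrings::end(Biostrings::subject(al))
  # read-end clipping: read bases left unaligned on an end where the
  # consensus also continues (i.e. not a legitimate overhang)
  left_clip <- if (ss > 1L) ps - 1L else 0L
  right_clip <- if (se < nchar(cons)) nchar(seq) - pe else 0L
  if (left_clip > clip_range || right_clip > clip_range) return(NULL)
  list(score = ov * ident, ov = ov, identity = ident,
       ps = ps, pe = pe, ss = ss, se = se,
       pat = as.character(Biostrings::pattern(al)),
       sub = as.character(Biostrings::subject(al)))
}

#' @noRd
overlap_submat <- function() {
  if (is.null(.estkit_cache$submat)) {
    .estkit_cache$submat <- Biostrings::nucleotideSubstitutionMatrix(
      match = 2, mismatch = -5, baseOnly = FALSE)
  }
  .estkit_cache$submat
}

.estkit_cache <- new.env(parent = emptyenv())

# Project an accepted overlap onto consensus coordinates. Returns
# cons_pos (may extend beyond [1, cons_len]), base index (1..4) and weight
# for every contributed read base, plus the read's placement offset.
#' @noRd
project_read <- function(seq, qual, ov, cons_len) {
  gapless <- !grepl("-", ov$pat, fixed = TRUE) && !grepl("-", ov$sub, fixed = TRUE)
  if (gapless) {
    rps <- ov$ps:ov$pe
    pos <- ov$ss:ov$se
    base <- match(strsplit(ov$pat, "", fixed = TRUE)[[1]], DNA_BASES)
    wt <- qual[rps]
    keep <- !is.na(base)
    pos <- pos[keep]; base <- base[keep]; wt <- wt[keep]
    cp <- ov$se
  } else {
    pchars <- strsplit(ov$pat, "", fixed = TRUE)[[1]]
    schars <- strsplit(ov$sub, "", fixed = TRUE)[[1]]
    m <- length(pchars)
    pos <- integer(m); base <- integer(m); wt <- numeric(m)
    nkeep <- 0L
    rp <- ov$ps - 1L      # read bases consumed
    cp <- ov$ss - 1L      # consensus bases consumed
    for (j in seq_len(m)) {
      pc <- pchars[j]; sc <- schars[j]
      if (pc != "-" && sc != "-") {
        rp <- rp + 1L; cp <- cp + 1L
        b <- match(pc, DNA_BASES)
        if (!is.na(b)) {
          nkeep <- nkeep + 1L
          pos[nkeep] <- cp; base[nkeep] <- b; wt[nkeep] <- qual[rp]
        }
      } else if (pc != "-") {        # read insertion relative to consensus: dropped
        rp <- rp + 1L
      } else {                       # consensus base absent from read
        cp <- cp + 1L
      }
    }
    pos <- pos[seq_len(nkeep)]; base <- base[seq_len(nkeep)]; wt <- wt[seq_len(nkeep)]
  }
  # overhangs extend the consensus (only where the consensus truly ends)
  if (ov$ss == 1L && ov$ps > 1L) {
    idx <- seq_len(ov$ps - 1L)
    b <- match(substring(seq, idx, idx), DNA_BASES)
    keep <- !is.na(b)
    pos <- c((idx - length(idx))[keep], pos)    # coords <= 0
    base <- c(b[keep], base)
    wt <- c(qual[idx][keep], wt)
  }
  n <- nchar(seq)
  if (ov$se == cons_len && ov$pe < n) {   # read continues past consensus end
    idx <- (ov$pe + 1L):n
    b <- match(substring(seq, idx, idx), DNA_BASES)
    keep <- !is.na(b)
    ext_pos <- cp + seq_along(idx)
    pos <- c(pos, ext_pos[keep])
    base <- c(base, b[keep])
    wt <- c(wt, qual[idx][keep])
  }
  list(pos = pos, base = base, wt = wt,
       offset = (ov$ss - 1L) - (ov$ps - 1L))
}

# Place one read: join the best qualifying unigene, else start a new one.
#' @noRd
place_read <- function(st, id, seq, qual, overlap_identity, clip_range,
                       min_overlap, min_kmer_hits) {
  rc <- revcomp(seq)
  best <- NULL
  for (strand in c("+", "-")) {
    s <- if (strand == "+") seq else rc
    cands <- index_candidates(st, s, min_kmer_hits)
    for (u in head(cands, 8L)) {
      cons <- st$unigenes[[u]]$consensus
      ov <- score_overlap(s, cons, overlap_identity, clip_range, min_overlap)
      if (!is.null(ov) && (is.null(best) || ov$score > best$ov$score ||
                           (ov$score == best$ov$score && u < best$u))) {
        best <- list(u = u, strand = strand, s = s, ov = ov)
      }
    }
    if (!is.null(best) && strand == "+" && best$ov$identity == 1) break
  }
  if (is.null(best)) {
    new_unigene(st, id, seq, qual)
  } else {
    q <- if (best$strand == "+") qual else rev(qual)
    add_read_to_unigene(st, best$u, id, best$s, q, best$ov, best$strand)
  }
  invisible(NULL)
}

#' @noRd
new_unigene <- function(st, id, seq, qual) {
  profile <- matrix(0, nrow = 4L, ncol = nchar(seq),
                    dimnames = list(DNA_BASES, NULL))
  b <- match(strsplit(seq, "", fixed = TRUE)[[1]], DNA_BASES)
  keep <- !is.na(b)
  profile[cbind(b[keep], which(keep))] <- qual[keep]
  uid <- length(st$unigenes) + 1L
  st$unigenes[[uid]] <- list(
    profile = profile,
    consensus = seq,
    members = list(read_id = id, offset = 0L, strand = "+",
                   read_len = nchar(seq)),
    alive = TRUE)
  index_add(st, seq, uid)
  uid
}

#' @noRd
add_read_to_unigene <- function(st, u, id, s, qual, ov, strand) {
  ug <- st$unigenes[[u]]
  pr <- project_read(s, qual, ov, nchar(ug$consensus))
  L <- ncol(ug$profile)
  lo <- min(c(1L, pr$pos)); hi <- max(c(L, pr$pos))
  if (lo < 1L || hi > L) {
    newp <- matrix(0, nrow = 4L, ncol = hi - lo + 1L, dimnames = list(DNA_BASES, NULL))
    newp[, (1L - lo + 1L):(L - lo + 1L)] <- ug$profile
    ug$profile <- newp
    shift <- 1L - lo
    ug$members$offset <- ug$members$offset + shift
    pr$pos <- pr$pos + shift
    pr$offset <- pr$offset + shift
  }
  idx <- cbind(pr$base, pr$pos)
  ug$profile[idx] <- ug$profile[idx] + pr$wt
  old_cons <- ug$consensus
  ug$consensus <- profile_consensus(ug$profile)
  ug$members$read_id <- c(ug$members$read_id, id)
  ug$members$offset <- c(ug$members$offset, as.integer(pr$offset))
  ug$members$strand <- c(ug$members$strand, strand)
  ug$members$read_len <- c(ug$members$read_len, nchar(s))
  st$unigenes[[u]] <- ug
  if (!identical(old_cons, ug$consensus)) index_add(st, ug$consensus, u)
  invisible(NULL)
}

# Greedy consolidation: merge unigene pairs whose consensi overlap above the
# thresholds, best score first, until no pair qualifies.
#' @noRd
consolidate_unigenes <- function(st, overlap_identity, clip_range,
                                 min_overlap, min_kmer_hits) {
  repeat {
    best <- NULL
    alive <- which(vapply(st$unigenes, function(u) isTRUE(u$alive), logical(1)))
    if (length(alive) < 2L) break
    for (a in alive) {
      cons_a <- st$unigenes[[a]]$consensus
      rc_a <- revcomp(cons_a)
      for (strand in c("+", "-")) {
        s <- if (strand == "+") cons_a else rc_a
        cands <- index_candidates(st, s, min_kmer_hits, exclude = a)
        for (bu in head(cands, 6L)) {
          if (bu == a) next
          ov <- score_overlap(s, st$unigenes[[bu]]$consensus,
                              overlap_identity, clip_range, min_overlap)
          if (!is.null(ov)) {
            if (is.null(best) || ov$score > best$ov$score ||
                (ov$score == best$ov$score && min(a, bu) < min(best$a, best$b))) {
              best <- list(a = a, b = bu, strand = strand, s = s, ov = ov)
            }
          }
        }
      }
    }
    if (is.null(best)) break
    merge_unigenes(st, best$a, best$b, best$strand, best$ov)
  }
  invisible(NULL)
}

# Merge unigene a (possibly reverse-complemented, as aligned) into unigene b.
#' @noRd
merge_unigenes <- function(st, a, b, strand, ov) {
  ua <- st$unigenes[[a]]
  ub <- st$unigenes[[b]]
  La <- ncol(ua$profile)
  # orient a's profile/members as aligned
  if (strand == "-") {
    ua$profile <- ua$profile[c("T", "G", "C", "A"), rev(seq_len(La)), drop = FALSE]
    rownames(ua$profile) <- DNA_BASES
    ua$members$offset <- La - (ua$members$offset + ua$members$read_len)
    ua$members$strand <- ifelse(ua$members$strand == "+", "-", "+")
  }
  # placement of a's consensus on b's coords (ends-free; offset as in reads)
  offset <- (ov$ss - 1L) - (ov$ps - 1L)
  Lb <- ncol(ub$profile)
  lo <- min(1L, offset + 1L); hi <- max(Lb, offset + La)
  newp <- matrix(0, nrow = 4L, ncol = hi - lo + 1L, dimnames = list(DNA_BASES, NULL))
  shift_b <- 1L - lo
  newp[, (1L + shift_b):(Lb + shift_b)] <- ub$profile
  acols <- (offset + 1L + shift_b):(offset + La + shift_b)
  newp[, acols] <- newp[, acols] + ua$profile
  ub$profile <- newp
  ub$members$offset <- ub$members$offset + shift_b
  ua$members$offset <- ua$members$offset + offset + shift_b
  ub$members <- list(read_id = c(ub$members$read_id, ua$members$read_id),
                     offset = c(ub$members$offset, ua$members$offset),
                     strand = c(ub$members$strand, ua$members$strand),
                     read_len = c(ub$members$read_len, ua$members$read_len))
  ub$consensus <- profile_consensus(ub$profile)
  st$unigenes[[b]] <- ub
  st$unigenes[[a]] <- list(alive = FALSE)
  index_add(st, ub$consensus, b)
  invisible(NULL)
}

#' @noRd
finish_assembly <- function(st) {
  alive <- which(vapply(st$unigenes, function(u) isTRUE(u$alive), logical(1)))
  info <- lapply(alive, function(u) {
    ug <- st$unigenes[[u]]
    tibble(uid = u, consensus = ug$consensus,
           n_members = length(ug$members$read_id),
           first_read = min(ug$members$read_id))
  })
  info <- bind_rows(info) %>%
    mutate(kind = ifelse(.data$n_members >= 2L, "contig", "singleton")) %>%
    arrange(dplyr::desc(.data$kind == "contig"), -.data$n_members, .data$first_read)
  ids <- character(nrow(info))
  ids[info$kind == "contig"] <- sprintf("CT%04d", seq_len(sum(info$kind == "contig")))
  ids[info$kind == "singleton"] <- sprintf("SG%05d", seq_len(sum(info$kind == "singleton")))
  info$unigene_id <- ids
  members <- bind_rows(lapply(seq_len(nrow(info)), function(i) {
    m <- st$unigenes[[info$uid[i]]]$members
    tibble(read_id = m$read_id, unigene_id = info$unigene_id[i],
           offset = as.integer(m$offset), strand = m$strand)
  }))
  list(unigenes = tibble(unigene_id = info$unigene_id,
                         consensus = info$consensus,
                         kind = info$kind,
                         n_members = info$n_members,
                         length = nchar(info$consensus)),
       members = members)
}

#' Expression proxy: member read count per unigene
#'
#' The number of reads assembled into a unigene is the classical cDNA-library
#' expression proxy; ranking by it defines "highly expressed" gene lists.
#'
#' @param assembly Result of [assemble_reads()].
#' @return A tibble `unigene_id`, `n_reads`, sorted by decreasing count.
#' @export
expression_proxy <- function(assembly) {
  assembly$unigenes %>%
    select("unigene_id", n_reads = "n_members") %>%
    arrange(-.data$n_reads, .data$unigene_id)
}

#' Summary statistics of an assembly
#'
#' @param assembly Result of [assemble_reads()].
#' @return One-row tibble: `n_unigenes`, `n_contigs`, `n_singletons`,
#'   `contig_mean_length`, `mean_members`, `median_members`, `max_members`
#'   (`NA` where undefined on empty input).
#' @export
assembly_stats <- function(assembly) {
  u <- assembly$unigenes
  contigs <- u[u$kind == "contig", ]
  tibble(
    n_unigenes = nrow(u),
    n_contigs = nrow(contigs),
    n_singletons = sum(u$kind == "singleton"),
    contig_mean_length = if (nrow(contigs)) mean(contigs$length) else NA_real_,
    mean_members = if (nrow(contigs)) mean(contigs$n_members) else NA_real_,
    median_members = if (nrow(contigs)) median(contigs$n_members) else NA_real_,
    max_members = if (nrow(u)) max(u$n_members) else NA_integer_)
}
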