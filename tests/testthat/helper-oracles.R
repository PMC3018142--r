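# Independent oracles and small fixture builders shared across tests.
# Oracles deliberately use naive enumeration, never the package's own
# implementation path.

# Brute-force sliding-window clip: enumerate every window position, take
# the first qualifying window from each side.
oracle_quality_clip <- function(qual, window = 20L, threshold = 13) {
  n <- length(qual)
  if (n == 0L) return(c(0L, 0L))
  if (n < window) {
    return(if (mean(qual) > threshold) c(0L, n) else c(0L, 0L))
  }
  ok <- logical(n - window + 1L)
  for (i in seq_len(n - window + 1L)) {
    ok[i] <- mean(qual[i:(i + window - 1L)]) > threshold
  }
  if (!any(ok)) return(c(0L, 0L))
  c(which(ok)[1L] - 1L, max(which(ok)) - 1L + window)
}

# Brute-force six-frame scan for the homology-extension rule: given the
# hit interval and frame on the forward strand, find the CDS by walking
# codons directly on the (possibly reverse-complemented) sequence.
oracle_cds_interval <- function(seq, h0, h1, frame) {
  n <- nchar(seq)
  rc <- function(x) {
    paste(rev(strsplit(chartr("ACGT", "TGCA", x), "")[[1]]), collapse = "")
  }
  work <- if (frame > 0) seq else rc(seq)
  if (frame < 0) { t0 <- n - h1; h1 <- n - h0; h0 <- t0 }
  off <- abs(frame) - 1L
  codon_at <- function(ci) substr(work, off + (ci - 1L) * 3L + 1L, off + ci * 3L)
  n_cod <- (nchar(work) - off) %/% 3L
  stops <- c("TAA", "TAG", "TGA")
  hit_c0 <- (h0 - off) %/% 3L + 1L
  hit_c1 <- (h1 - off - 1L) %/% 3L + 1L
  # walk 3'
  e <- hit_c1
  while (e <= n_cod && !(codon_at(e) %in% stops)) e <- e + 1L
  e <- min(e, n_cod)
  # walk 5'
  s <- hit_c0
  s5stop <- NA
  while (s > 1L) {
    if (codon_at(s - 1L) %in% stops) { s5stop <- s - 1L; break }
    s <- s - 1L
  }
  if (!is.na(s5stop)) {
    a <- s5stop + 1L
    while (a <= hit_c1 && codon_at(a) != "ATG") a <- a + 1L
    s <- if (a <= hit_c1) a else s5stop + 1L
  }
  w0 <- off + (s - 1L) * 3L
  w1 <- off + e * 3L
  if (frame > 0) c(w0, w1) else c(n - w1, n - w0)
}

# Chi-square / n total inertia of a count matrix (CA oracle support).
oracle_total_inertia <- function(m) {
  m <- m[rowSums(m) > 0, colSums(m) > 0, drop = FALSE]
  n <- sum(m)
  E <- outer(rowSums(m), colSums(m)) / n
  sum((m - E)^2 / E) / n
}

# Exhaustive-search fusion oracle for small sub-network pools: enumerates
# the same greedy rule by full recomputation at every step, sharing only
# the published Rc/Nc formulas.
oracle_fuse <- function(node_sets, graph, score_threshold = 0.7,
                        nc_threshold = 0.5) {
  rc_of <- function(ns) {
    n <- length(ns)
    if (n <= 1L) return(1)
    igraph::ecount(igraph::induced_subgraph(graph, ns)) / (n * (n - 1) / 2)
  }
  pool <- lapply(node_sets, function(ns) sort(unique(ns)))
  names(pool) <- NULL
  repeat {
    keys <- vapply(pool, paste, character(1), collapse = "\r")
    if (anyDuplicated(keys)) pool <- pool[!duplicated(keys)]
    if (length(pool) < 2L) break
    best <- NULL
    for (i in seq_len(length(pool) - 1L)) {
      for (j in (i + 1L):length(pool)) {
        nc <- length(intersect(pool[[i]], pool[[j]])) /
          min(length(pool[[i]]), length(pool[[j]]))
        sc <- 1 - (1 - nc) * (1 - rc_of(pool[[i]])) * (1 - rc_of(pool[[j]]))
        if (sc >= score_threshold && nc >= nc_threshold) {
          if (is.null(best) || sc > best$sc || (sc == best$sc && nc > best$nc)) {
            best <- list(i = i, j = j, sc = sc, nc = nc)
          }
        }
      }
    }
    if (is.null(best)) break
    merged <- sort(union(pool[[best$i]], pool[[best$j]]))
    pool[[best$i]] <- merged
    pool[[best$j]] <- NULL
  }
  # canonical form: sorted list of sorted node sets
  pool[order(vapply(pool, paste, character(1), collapse = "\r"))]
}

# Brute-force specificity rule on one profile.
oracle_classify <- function(taxa, evalues, cutoff = 1e-5) {
  keep <- evalues <= cutoff & !(taxa %in% c("Annelida", "Mollusca"))
  eff <- sort(unique(taxa[keep]))
  if (length(eff) == 0L) "no_homolog" else if (length(eff) == 1L) "specific" else "shared"
}

# Constructed mRNA with a planted in-frame homology hit: 5' stop codon,
# then ATG, a stop-free coding stretch, a stop, flanking random sequence.
# The hit covers interior codons only.
make_mrna_with_hit <- function(seed) {
  set.seed(seed)
  rand <- function(n) paste0(sample(c("A", "C", "G", "T"), n, TRUE), collapse = "")
  no_stop_codons <- function(k) {
    pool <- setdiff(names(Biostrings::GENETIC_CODE), c("TAA", "TAG", "TGA"))
    paste0(sample(pool, k, TRUE), collapse = "")
  }
  lead <- rand(sample(3:20, 1))
  n_cod <- sample(20:60, 1)
  body <- no_stop_codons(n_cod)
  stop5 <- sample(c("TAA", "TAG", "TGA"), 1)
  # codons between the 5' stop and the true ATG: no stops and no ATG, so
  # the first-ATG-after-stop rule lands on the planted start
  gap_pool <- setdiff(names(Biostrings::GENETIC_CODE),
                      c("TAA", "TAG", "TGA", "ATG"))
  gap <- paste0(sample(gap_pool, sample(1:4, 1), TRUE), collapse = "")
  mid <- paste0(stop5, gap, "ATG", body, sample(c("TAA", "TAG", "TGA"), 1))
  trail <- rand(sample(3:30, 1))
  m <- paste0(lead, mid, trail)
  cds_start <- nchar(lead) + nchar(stop5) + nchar(gap)   # 0-based at ATG
  cds_end <- cds_start + 3 + n_cod * 3 + 3
  # hit covering some interior codons (same frame as ATG)
  k0 <- sample(1:5, 1); k1 <- sample((k0 + 5):(n_cod - 2), 1)
  h0 <- cds_start + 3 * k0
  h1 <- cds_start + 3 * (k1 + 1)
  list(m = m, cds_start = cds_start, cds_end = cds_end, h0 = h0, h1 = h1,
       frame = (h0 %% 3) + 1)
}

# Random quality vector with structure resembling real traces.
random_qual <- function(n) {
  base <- sample(5:45, 1L) + cumsum(sample(-3:3, n, replace = TRUE))
  pmax(2L, pmin(60L, as.integer(base)))
}
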