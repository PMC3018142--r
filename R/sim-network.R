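# Planted-partition interactome and taxon-labelled homology-hit simulators.

#' Simulate a modular protein-interaction network (planted partition)
#'
#' Nodes are split into `n_modules` modules of `module_size`; each
#' intra-module pair is joined with probability `p_in` and each inter-module
#' pair with probability `p_out` (`p_in > p_out`, otherwise the modules are
#' not recoverable). Every edge carries a combined confidence score drawn
#' uniformly from `score_range` (intra-module) or `score_range_out`
#' (inter-module); the defaults emulate an integrated-confidence score in
#' which within-module interactions carry high support, so that a
#' combined-score cutoff of 0.9 retains the planted modules and discards
#' most cross-module contacts.
#'
#' @param n_modules,module_size Module count and size (>= 1).
#' @param p_in,p_out Intra-/inter-module edge probabilities.
#' @param score_range Uniform score range for intra-module edges.
#' @param score_range_out Uniform score range for inter-module edges.
#' @param seed Integer seed.
#' @return A list with `edges` (tibble `node_a`, `node_b`, `score`), `nodes`
#'   (tibble `node`, `module`) — an undirected simple graph with no
#'   self-loops.
#' @export
sim_ppi <- function(n_modules, module_size, p_in, p_out,
                    score_range = c(0.9, 1.0),
                    score_range_out = c(0.5, 0.9), seed = 1L) {
  stopifnot(n_modules >= 1, module_size >= 1)
  if (!(p_in > p_out)) abort("`p_in` must exceed `p_out` (planted modules must be denser inside).")
  if (any(c(p_in, p_out) < 0 | c(p_in, p_out) > 1)) abort("Probabilities must lie in [0, 1].")
  n <- n_modules * module_size
  module <- rep(seq_len(n_modules), each = module_size)
  node <- sprintf("M%02d_N%03d", module, seq_len(n))
  with_seed(seed, {
    pairs <- utils::combn(n, 2L)
    same <- module[pairs[1, ]] == module[pairs[2, ]]
    p <- ifelse(same, p_in, p_out)
    keep <- runif(ncol(pairs)) < p
    ia <- pairs[1, keep]; ib <- pairs[2, keep]
    lo <- ifelse(same[keep], score_range[1], score_range_out[1])
    hi <- ifelse(same[keep], score_range[2], score_range_out[2])
    edges <- tibble(node_a = node[ia], node_b = node[ib],
                    score = lo + runif(sum(keep)) * (hi - lo))
    list(edges = edges, nodes = tibble(node = node, module = module))
  })
}

#' Simulate taxon-labelled homology hit profiles
#'
#' Given a scenario mapping each query protein to the set of taxa in which
#' it has homologs, emits 1 or more hits per (protein, taxon) pair, all with
#' E-values at or below `max_evalue`, and none outside the scenario.
#'
#' @param scenario A tibble with columns `query` and `taxon` (one row per
#'   protein-taxon pair), or a named list of character vectors of taxa.
#'   Proteins mapped to an empty set yield no hits.
#' @param vocab Controlled taxon vocabulary, see [taxon_vocabulary()].
#' @param hits_per_pair Integer range of hits per (protein, taxon) pair.
#' @param max_evalue Upper bound for simulated E-values.
#' @param seed Integer seed.
#' @return A tibble of hits: `query`, `subject`, `taxon`, `evalue`.
#' @export
sim_hit_profiles <- function(scenario, vocab = taxon_vocabulary(),
                             hits_per_pair = c(1L, 3L),
                             max_evalue = 1e-5, seed = 1L) {
  if (is.list(scenario) && !is.data.frame(scenario)) {
    taxa <- unlist(scenario, use.names = FALSE)
    scenario <- tibble(
      query = rep(names(scenario), lengths(scenario)),
      taxon = if (is.null(taxa)) character(0) else taxa
    )
  }
  unknown <- setdiff(unique(scenario$taxon), vocab$label)
  if (length(unknown)) {
    abort(paste0("Unknown taxon label(s): ", paste(unknown, collapse = ", ")))
  }
  with_seed(seed, {
    if (nrow(scenario) == 0L) {
      return(tibble(query = character(0), subject = character(0),
                    taxon = character(0), evalue = numeric(0)))
    }
    rows <- lapply(seq_len(nrow(scenario)), function(i) {
      k <- sample(seq(hits_per_pair[1], hits_per_pair[2]), 1L)
      tibble(query = scenario$query[i],
             subject = sprintf("%s_%s_h%d", scenario$query[i],
                               gsub("\\s+", "", scenario$taxon[i]), seq_len(k)),
             taxon = scenario$taxon[i],
             evalue = 10^runif(k, -50, log10(max_evalue)))
    })
    bind_rows(rows)
  })
}
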