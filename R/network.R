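# Interaction-network mapping: scored-network construction, level-1
# sub-network extraction, Ratio-of-consistency (Rc) scoring, node-overlap
# (Nc) and the fusion criterion, greedy fusion to fixpoint, and
# pathway/sub-network coverage summaries.

#' Build a scored interaction network from an edge list
#'
#' Retains edges with combined score >= `cutoff`; duplicate undirected
#' edges are deduplicated keeping the maximum score; self-loops are
#' dropped. Nodes listed in `nodes` but absent from retained edges are kept
#' as isolated nodes.
#'
#' @param edges Tibble `node_a`, `node_b`, `score` (scores in \[0, 1\]).
#' @param cutoff Combined-score cutoff (inclusive).
#' @param nodes Optional character vector of the full node universe.
#' @return An [igraph::graph] with edge attribute `score`.
#' @export
build_network <- function(edges, cutoff = 0.9, nodes = NULL) {
  if (nrow(edges)) {
    if (any(is.na(edges$score)) || any(edges$score < 0 | edges$score > 1)) {
      bad <- which(is.na(edges$score) | edges$score < 0 | edges$score > 1)
      abort(paste0("Malformed edge rows (score outside [0,1]) at row(s): ",
                   paste(head(bad, 5), collapse = ", ")))
    }
  }
  e <- edges %>%
    filter(.data$node_a != .data$node_b) %>%
    mutate(a = pmin(.data$node_a, .data$node_b),
           b = pmax(.data$node_a, .data$node_b)) %>%
    group_by(.data$a, .data$b) %>%
    summarise(score = max(.data$score), .groups = "drop") %>%
    filter(.data$score >= cutoff)
  verts <- sort(unique(c(e$a, e$b, nodes, edges$node_a, edges$node_b)))
  g <- igraph::graph_from_data_frame(e, directed = FALSE,
                                     vertices = data.frame(name = verts))
  g
}

#' Ratio of consistency of a node set
#'
#' Rc = observed induced edges / maximum theoretical edges n(n-1)/2. For
#' n <= 1 the sub-network is vacuously consistent and Rc = 1.
#'
#' @param graph An igraph graph.
#' @param nodes Character vector of node names.
#' @return A single number in \[0, 1\].
#' @export
rc_score <- function(graph, nodes) {
  n <- length(unique(nodes))
  if (n <= 1L) return(1)
  m <- igraph::ecount(igraph::induced_subgraph(graph, nodes))
  m / (n * (n - 1) / 2)
}

#' Extract level-1 sub-networks around seed nodes
#'
#' One sub-network per seed: the seed plus its direct neighbours, with all
#' induced edges, scored by Rc.
#'
#' @param graph An igraph graph from [build_network()].
#' @param seeds Character vector of seed node names (must exist in `graph`).
#' @return A tibble `seed`, `nodes` (list-column), `n_nodes`, `n_edges`,
#'   `rc`.
#' @export
extract_subnetworks <- function(graph, seeds) {
  missing <- setdiff(seeds, igraph::V(graph)$name)
  if (length(missing)) {
    abort(paste0("Seeds not in the network: ", paste(head(missing, 5), collapse = ", ")))
  }
  rows <- lapply(seeds, function(s) {
    nb <- igraph::neighbors(graph, s)$name
    ns <- sort(unique(c(s, nb)))
    m <- igraph::ecount(igraph::induced_subgraph(graph, ns))
    tibble(seed = s, nodes = list(ns), n_nodes = length(ns),
           n_edges = m, rc = rc_score(graph, ns))
  })
  bind_rows(rows)
}

#' Node overlap between two sub-networks
#'
#' Nc = shared nodes / size of the smaller sub-network.
#'
#' @param nodes_a,nodes_b Character vectors of node names (non-empty).
#' @return A single number in \[0, 1\].
#' @export
nc_score <- function(nodes_a, nodes_b) {
  if (length(nodes_a) == 0L || length(nodes_b) == 0L) {
    abort("Nc is undefined for an empty sub-network.")
  }
  length(intersect(nodes_a, nodes_b)) / min(length(unique(nodes_a)),
                                            length(unique(nodes_b)))
}

#' The sub-network fusion criterion
#'
#' Two sub-networks A and B fuse when both
#' `1 - (1 - Nc) * (1 - RcA) * (1 - RcB) >= score_threshold` and
#' `Nc >= nc_threshold` hold.
#'
#' @param rc_a,rc_b Rc scores of the two sub-networks.
#' @param nc Their node overlap ([nc_score()]).
#' @param score_threshold,nc_threshold Fusion thresholds.
#' @return A list `fuse` (logical) and `score` (the fusion score).
#' @export
should_fuse <- function(rc_a, rc_b, nc, score_threshold = 0.7,
                        nc_threshold = 0.5) {
  score <- 1 - (1 - nc) * (1 - rc_a) * (1 - rc_b)
  list(fuse = score >= score_threshold && nc >= nc_threshold, score = score)
}

#' Fuse sub-networks to fixpoint
#'
#' Repeatedly evaluates all sub-network pairs, fuses the pair with the
#' highest fusion score among those meeting both criteria (ties broken by
#' larger Nc, then by lexicographically smallest pair of current ids),
#' recomputes the union's nodes, induced edges and Rc, and repeats until
#' no pair qualifies. Deterministic and invariant to input order.
#'
#' @param subnets Tibble from [extract_subnetworks()] (needs `nodes`
#'   list-column; `seed` used for reporting).
#' @param graph The parent igraph graph (for induced edge/Rc recomputation).
#' @param score_threshold,nc_threshold Fusion thresholds.
#' @return A tibble like [extract_subnetworks()]'s with `seed` replaced by
#'   `members` (the seeds merged into each final sub-network, sorted,
#'   collapsed with `+`).
#' @export
fuse_all <- function(subnets, graph, score_threshold = 0.7, nc_threshold = 0.5) {
  if (nrow(subnets) == 0L) return(subnets)
  pool <- lapply(seq_len(nrow(subnets)), function(i) {
    list(seeds = sort(subnets$seed[[i]]), nodes = sort(unique(subnets$nodes[[i]])),
         rc = rc_score(graph, subnets$nodes[[i]]))
  })
  # deduplicate identical node sets up front (a fusion no-op)
  repeat {
    nsets <- vapply(pool, function(p) paste(p$nodes, collapse = "\r"), character(1))
    dup <- duplicated(nsets)
    if (any(dup)) {
      for (i in which(dup)) {
        j <- match(nsets[i], nsets)
        pool[[j]]$seeds <- sort(union(pool[[j]]$seeds, pool[[i]]$seeds))
      }
      pool <- pool[!dup]
    }
    if (length(pool) < 2L) break
    best <- NULL
    for (i in seq_len(length(pool) - 1L)) {
      for (j in (i + 1L):length(pool)) {
        nc <- nc_score(pool[[i]]$nodes, pool[[j]]$nodes)
        sf <- should_fuse(pool[[i]]$rc, pool[[j]]$rc, nc,
                          score_threshold, nc_threshold)
        if (!sf$fuse) next
        key_ids <- sort(c(paste(pool[[i]]$seeds, collapse = "+"),
                          paste(pool[[j]]$seeds, collapse = "+")))
        cand <- list(i = i, j = j, score = sf$score, nc = nc, key = key_ids)
        if (is.null(best) ||
            cand$score > best$score ||
            (cand$score == best$score && cand$nc > best$nc) ||
            (cand$score == best$score && cand$nc == best$nc &&
             paste(cand$key, collapse = " ") < paste(best$key, collapse = " "))) {
          best <- cand
        }
      }
    }
    if (is.null(best)) break
    a <- pool[[best$i]]; b <- pool[[best$j]]
    merged <- list(seeds = sort(union(a$seeds, b$seeds)),
                   nodes = sort(union(a$nodes, b$nodes)))
    merged$rc <- rc_score(graph, merged$nodes)
    pool[[best$i]] <- merged
    pool[[best$j]] <- NULL
  }
  rows <- lapply(pool, function(p) {
    m <- if (length(p$nodes) > 1L) {
      igraph::ecount(igraph::induced_subgraph(graph, p$nodes))
    } else 0L
    tibble(members = paste(p$seeds, collapse = "+"), nodes = list(p$nodes),
           n_nodes = length(p$nodes), n_edges = m, rc = p$rc)
  })
  bind_rows(rows) %>% arrange(.data$members)
}

#' Map query proteins to network nodes
#'
#' For each query, the first identifier type (in the supplied order) with a
#' unique match wins; an ambiguous match at a level falls through to the
#' next with a warning; queries without any textual match fall back to the
#' best similarity hit with E-value <= `max_evalue`; otherwise unmapped.
#'
#' @param queries Character vector of query ids.
#' @param id_tables Tibble `query`, `id_type`, `node` of textual matches.
#' @param similarity_hits Optional tibble `query`, `node`, `evalue`.
#' @param id_order Identifier types in decreasing priority.
#' @param max_evalue Similarity-mapping E-value cutoff.
#' @return A tibble `query`, `node` (`NA` when unmapped), `method`
#'   (`textual:<type>`, `similarity`, or `unmapped`).
#' @export
map_to_network <- function(queries, id_tables = NULL, similarity_hits = NULL,
                           id_order = c("uniprot_id", "uniprot_ensembl",
                                        "refseq", "genome_reviews", "gene_name"),
                           max_evalue = 1e-5) {
  rows <- lapply(queries, function(q) {
    if (!is.null(id_tables)) {
      for (ty in id_order) {
        m <- id_tables[id_tables$query == q & id_tables$id_type == ty, ]
        hits <- unique(m$node)
        if (length(hits) == 1L) {
          return(tibble(query = q, node = hits, method = paste0("textual:", ty)))
        }
        if (length(hits) > 1L) {
          warn(paste0("Ambiguous ", ty, " match for ", q, "; falling through."))
        }
      }
    }
    if (!is.null(similarity_hits)) {
      sh <- similarity_hits[similarity_hits$query == q &
                              similarity_hits$evalue <= max_evalue, ]
      if (nrow(sh)) {
        sh <- sh[order(sh$evalue, sh$node), ]
        return(tibble(query = q, node = sh$node[1L], method = "similarity"))
      }
    }
    tibble(query = q, node = NA_character_, method = "unmapped")
  })
  bind_rows(rows)
}

#' Pathway and sub-network coverage summaries
#'
#' Per pathway: the fraction of distinct member enzymes populated by at
#' least one mapped query (repeated enzymes counted once), flagged when
#' above `flag_threshold`. Per sub-network: whether at least one node is
#' populated.
#'
#' @param mapping Tibble from [map_to_network()] (or any tibble with a
#'   `node` column of populated network nodes / enzyme ids).
#' @param pathways Tibble `pathway`, `enzyme`; empty pathways are excluded
#'   with a warning.
#' @param subnets Optional tibble with a `nodes` list-column (before or
#'   after fusion).
#' @param flag_threshold Coverage level that flags a pathway as well
#'   covered.
#' @return A list with `pathway_coverage` (tibble `pathway`, `n_enzymes`,
#'   `n_populated`, `coverage`, `flagged`), `pathway_summary` (one-row
#'   tibble: totals and flagged fraction), and when `subnets` is given
#'   `subnet_populated` + `subnet_summary`.
#' @export
coverage_summary <- function(mapping, pathways, subnets = NULL,
                             flag_threshold = 0.5) {
  mapped <- unique(mapping$node[!is.na(mapping$node)])
  pw <- distinct(pathways, .data$pathway, .data$enzyme)
  empty <- setdiff(unique(pathways$pathway), unique(pw$pathway[!is.na(pw$enzyme)]))
  if (length(empty)) warn(paste0("Empty pathway(s) excluded: ",
                                 paste(empty, collapse = ", ")))
  cov <- pw %>%
    filter(!is.na(.data$enzyme)) %>%
    group_by(.data$pathway) %>%
    summarise(n_enzymes = dplyr::n_distinct(.data$enzyme),
              n_populated = dplyr::n_distinct(.data$enzyme[.data$enzyme %in% mapped]),
              .groups = "drop") %>%
    mutate(coverage = .data$n_populated / .data$n_enzymes,
           flagged = .data$coverage > flag_threshold)
  out <- list(
    pathway_coverage = cov,
    pathway_summary = tibble(
      n_pathways = nrow(cov),
      n_flagged = sum(cov$flagged),
      flagged_fraction = if (nrow(cov)) mean(cov$flagged) else NA_real_))
  if (!is.null(subnets)) {
    pop <- vapply(subnets$nodes, function(ns) any(ns %in% mapped), logical(1))
    out$subnet_populated <- mutate(subnets, populated = pop)
    out$subnet_summary <- tibble(
      n_subnets = nrow(subnets),
      n_populated = sum(pop),
      populated_fraction = if (nrow(subnets)) mean(pop) else NA_real_)
  }
  out
}
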