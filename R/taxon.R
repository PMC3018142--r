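# Taxonomic-specificity classification of homology hit profiles, and the
# differential-gene-loss set definitions built on top of the calls.

#' The controlled taxon vocabulary
#'
#' The taxonomic groups used to classify homology hits of an annelid query
#' proteome. Hits in the query's own lineage and its sister group
#' (Annelida, Mollusca) are flagged `ignored`: they carry no information
#' about presence outside the query lineage.
#'
#' @return A tibble `label`, `ignored`.
#' @export
taxon_vocabulary <- function() {
  labels <- c("Deuterostomia", "Nematoda", "Arthropoda", "Platyhelminthes",
              "Cnidaria", "other Metazoa", "Choanoflagellida", "protists",
              "Viridiplantae", "Fungi", "other Eukaryota", "Prokaryotes",
              "Viruses", "Annelida", "Mollusca")
  tibble(label = labels, ignored = labels %in% c("Annelida", "Mollusca"))
}

PROTOSTOME_TAXA <- c("Nematoda", "Arthropoda", "Platyhelminthes")

#' Classify a query by the taxonomic distribution of its hits
#'
#' Hits above the E-value cutoff are discarded; hits in ignored taxa
#' (Annelida, Mollusca) are removed; if the remaining taxa reduce to a
#' single label the query is specific to that taxon, if none remain it has
#' no (informative) homolog, otherwise it is shared among the remaining
#' set.
#'
#' @param hits Tibble `query`, `taxon`, `evalue` (one row per hit), for one
#'   or many queries.
#' @param vocab Taxon vocabulary, see [taxon_vocabulary()].
#' @param evalue_cutoff Maximum retained E-value.
#' @param queries Optional query universe; queries without any hit row are
#'   then included as `no_homolog`.
#' @return A tibble `query`, `call` (`"specific"`, `"shared"`,
#'   `"no_homolog"`), `taxa` (list-column: the effective taxon set, sorted),
#'   `taxon` (the single taxon for specific calls, else `NA`).
#' @export
classify_taxon <- function(hits, vocab = taxon_vocabulary(),
                           evalue_cutoff = 1e-5, queries = NULL) {
  unknown <- setdiff(unique(hits$taxon), vocab$label)
  if (length(unknown)) {
    abort(paste0("Unknown taxon label(s): ", paste(unknown, collapse = ", ")))
  }
  ignored <- vocab$label[vocab$ignored]
  if (is.null(queries)) queries <- unique(hits$query)
  kept <- hits[hits$evalue <= evalue_cutoff & !(hits$taxon %in% ignored), ]
  eff_by_q <- lapply(split(kept$taxon, kept$query), function(t) sort(unique(t)))
  taxa <- lapply(queries, function(q) {
    t <- eff_by_q[[q]]
    if (is.null(t)) character(0) else t
  })
  nl <- lengths(taxa)
  tibble(query = queries,
         call = ifelse(nl == 0L, "no_homolog",
                       ifelse(nl == 1L, "specific", "shared")),
         taxa = taxa,
         taxon = ifelse(nl == 1L,
                        vapply(taxa, function(t) t[1] %||% NA_character_,
                               character(1)),
                        NA_character_))
}

#' @noRd
`%||%` <- function(a, b) if (is.null(a) || length(a) == 0L) b else a

#' Assemble differential-gene-loss sets from specificity calls
#'
#' Named sets over the effective taxon sets of [classify_taxon()] calls:
#' \describe{
#'   \item{deuterostomia_specific}{effective set exactly \{Deuterostomia\}.}
#'   \item{deuterostomia_cnidaria}{exactly \{Deuterostomia, Cnidaria\}.}
#'   \item{cnidaria_protostome}{Cnidaria plus at least one protostome taxon
#'     (Nematoda/Arthropoda/Platyhelminthes) and nothing else — in
#'     particular no Deuterostomia.}
#'   \item{protostome_specific}{a non-empty subset of the protostome taxa
#'     only.}
#'   \item{lineage_specific}{no informative homolog at all (the query
#'     lineage's "specific" gene pool).}
#' }
#' The sets are pairwise disjoint by construction.
#'
#' @param calls Tibble from [classify_taxon()].
#' @return A list with `sets` (named list of query-id vectors) and `counts`
#'   (tibble `set`, `n`).
#' @export
build_taxon_sets <- function(calls) {
  set_of <- function(taxa) sort(taxa)
  is_exact <- function(taxa, ref) identical(set_of(taxa), sort(ref))
  sets <- list(
    deuterostomia_specific = calls$query[vapply(calls$taxa, is_exact, logical(1),
                                                ref = "Deuterostomia")],
    deuterostomia_cnidaria = calls$query[vapply(calls$taxa, is_exact, logical(1),
                                                ref = c("Deuterostomia", "Cnidaria"))],
    cnidaria_protostome = calls$query[vapply(calls$taxa, function(t) {
      "Cnidaria" %in% t &&
        any(PROTOSTOME_TAXA %in% t) &&
        all(t %in% c("Cnidaria", PROTOSTOME_TAXA))
    }, logical(1))],
    protostome_specific = calls$query[vapply(calls$taxa, function(t) {
      length(t) > 0 && all(t %in% PROTOSTOME_TAXA)
    }, logical(1))],
    lineage_specific = calls$query[calls$call == "no_homolog"]
  )
  list(sets = sets,
       counts = tibble(set = names(sets), n = lengths(sets)))
}

#' Aggregate per-query calls by a family mapping (majority vote)
#'
#' Optionally groups queries into user-supplied families and assigns each
#' family the majority effective taxon set (ties broken by the
#' lexicographically smallest collapsed set).
#'
#' @param calls Tibble from [classify_taxon()].
#' @param families Tibble `query`, `family`.
#' @return A tibble like `calls` keyed by `family`.
#' @export
aggregate_calls <- function(calls, families) {
  df <- left_join(calls, families, by = "query")
  df$key <- vapply(df$taxa, paste, character(1), collapse = "|")
  fam_rows <- df %>%
    group_by(.data$family, .data$key) %>%
    summarise(n = n(), call = dplyr::first(.data$call),
              taxa = list(.data$taxa[[1]]), .groups = "drop_last") %>%
    arrange(-.data$n, .data$key) %>%
    slice(1L) %>%
    ungroup()
  fam_rows %>%
    mutate(taxon = vapply(.data$taxa, function(t)
      if (length(t) == 1L) t else NA_character_, character(1))) %>%
    select(query = "family", "call", "taxa", "taxon")
}
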