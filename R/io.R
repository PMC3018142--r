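# File formats: FASTA (via Biostrings), phred QUAL, TSV tables, GFF3.

#' Write sequences and per-base qualities as paired FASTA + QUAL files
#'
#' The QUAL format mirrors classic phred output: the same record order and
#' headers as the FASTA, with space-separated integer qualities wrapped at
#' `wrap` values per line.
#'
#' @param reads A tibble with columns `id`, `seq` and a list-column `qual`
#'   of integer vectors (one phred value per base), e.g. from [sim_reads()].
#' @param fasta_path,qual_path Output file paths.
#' @param wrap Values per QUAL line and bases per FASTA line.
#' @return Invisibly, `reads`.
#' @export
write_fasta_qual <- function(reads, fasta_path, qual_path, wrap = 60L) {
  stopifnot(all(c("id", "seq", "qual") %in% names(reads)))
  seqs <- Biostrings::DNAStringSet(setNames(reads$seq, reads$id))
  Biostrings::writeXStringSet(seqs, fasta_path, width = wrap)
  con <- file(qual_path, open = "wt")
  on.exit(close(con))
  for (i in seq_len(nrow(reads))) {
    writeLines(paste0(">", reads$id[[i]]), con)
    q <- reads$qual[[i]]
    idx <- split(q, ceiling(seq_along(q) / wrap))
    writeLines(vapply(idx, paste, character(1), collapse = " "), con)
  }
  invisible(reads)
}

#' Read paired FASTA + QUAL files into a read tibble
#'
#' @param fasta_path,qual_path Input files; records are paired by id and must
#'   be in the same order with equal sequence/quality lengths.
#' @return A tibble with columns `id`, `seq`, `qual` (list-column of integers).
#' @export
read_fasta_qual <- function(fasta_path, qual_path) {
  seqs <- Biostrings::readDNAStringSet(fasta_path)
  ids <- sub("\\s.*$", "", names(seqs))
  lines <- readLines(qual_path)
  hdr <- grepl("^>", lines)
  rec <- cumsum(hdr)
  qids <- sub("^>", "", sub("\\s.*$", "", lines[hdr]))
  vals <- split(lines[!hdr], rec[!hdr])
  quals <- lapply(vals, function(v) as.integer(strsplit(paste(v, collapse = " "), "\\s+")[[1]] |> (\(x) x[x != ""])()))
  if (!identical(ids, qids)) abort("FASTA and QUAL record ids differ or are out of order.")
  lens_ok <- vapply(seq_along(seqs), function(i) length(quals[[i]]) == Biostrings::width(seqs)[i], logical(1))
  if (!all(lens_ok)) abort("QUAL length differs from sequence length for some records.")
  tibble(id = ids, seq = unname(as.character(seqs)), qual = unname(quals))
}

#' Write a simple FASTA file from an id/seq tibble
#'
#' @param x Tibble with an id column and a sequence column.
#' @param path Output path.
#' @param seq_col Name of the sequence column.
#' @param id_col Name of the id column; by default the first of `id`,
#'   `unigene_id`, `gene_id` present in `x`.
#' @return Invisibly, `x`.
#' @export
write_fasta <- function(x, path, seq_col = "seq", id_col = NULL) {
  if (is.null(id_col)) {
    id_col <- intersect(c("id", "unigene_id", "gene_id"), names(x))[1]
    if (is.na(id_col)) abort("No id column found; pass `id_col`.")
  }
  s <- Biostrings::BStringSet(setNames(x[[seq_col]], x[[id_col]]))
  Biostrings::writeXStringSet(s, path, width = 60L)
  invisible(x)
}

#' Write CDS/UTR annotations as GFF3
#'
#' Emits `five_prime_UTR`, `CDS` and `three_prime_UTR` features per annotated
#' unigene in 1-based inclusive GFF3 coordinates.
#'
#' @param annotations A tibble from [annotate_cds()] (needs columns
#'   `unigene_id`, `cds_start`, `cds_end`, `strand`, `seq_length`, `source`).
#' @param path Output path.
#' @return Invisibly, `annotations`.
#' @export
write_gff3 <- function(annotations, path) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines("##gff-version 3", con)
  for (i in seq_len(nrow(annotations))) {
    a <- annotations[i, ]
    if (is.na(a$cds_start)) next
    src <- paste0("estkit_", a$source)
    feats <- list()
    # coordinates are 0-based half-open internally; GFF3 is 1-based inclusive
    if (a$cds_start > 0) {
      feats[[length(feats) + 1L]] <- c("five_prime_UTR", 1L, a$cds_start)
    }
    feats[[length(feats) + 1L]] <- c("CDS", a$cds_start + 1L, a$cds_end)
    if (a$cds_end < a$seq_length) {
      feats[[length(feats) + 1L]] <- c("three_prime_UTR", a$cds_end + 1L, a$seq_length)
    }
    for (f in feats) {
      writeLines(paste(a$unigene_id, src, f[1], f[2], f[3], ".",
                       a$strand, if (f[1] == "CDS") "0" else ".",
                       paste0("ID=", a$unigene_id, ".", f[1]),
                       sep = "\t"), con)
    }
  }
  invisible(annotations)
}

#' Read a BLAST outfmt-6 style hit table
#'
#' Columns: query, subject, pident, length, mismatch, gapopen, qstart, qend,
#' sstart, send, evalue, bitscore (the standard 12 columns). Extra columns
#' `frame` and `subject_length`, when present, are kept.
#'
#' @param path TSV file path.
#' @return A tibble of hits.
#' @export
read_hit_table <- function(path) {
  x <- readr::read_tsv(path, col_names = FALSE, show_col_types = FALSE)
  base <- c("query", "subject", "pident", "length", "mismatch", "gapopen",
            "qstart", "qend", "sstart", "send", "evalue", "bitscore")
  extra <- c("frame", "subject_length")
  nm <- c(base, extra)[seq_len(ncol(x))]
  setNames(x, nm)
}

#' Write a scored edge list as a 3-column TSV
#'
#' @param edges Tibble with columns `node_a`, `node_b`, `score`.
#' @param path Output path.
#' @return Invisibly, `edges`.
#' @export
write_edge_list <- function(edges, path) {
  readr::write_tsv(edges[, c("node_a", "node_b", "score")], path, col_names = FALSE)
  invisible(edges)
}

#' Read a scored edge list TSV (node_a, node_b, score)
#'
#' @param path Input path.
#' @return Tibble with columns `node_a`, `node_b`, `score`.
#' @export
read_edge_list <- function(path) {
  x <- readr::read_tsv(path, col_names = c("node_a", "node_b", "score"),
                       col_types = "ccd")
  bad <- which(is.na(x$score) | x$score < 0 | x$score > 1)
  if (length(bad)) {
    abort(paste0("Malformed edge rows (score outside [0,1] or missing) at line(s): ",
                 paste(head(bad, 5), collapse = ", ")))
  }
  x
}
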