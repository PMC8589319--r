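#' Read and write pipeline tables
#'
#' All tables are UTF-8 tab-separated files with a single header row;
#' missing values are empty fields. These helpers wrap readr with the
#' column contracts used throughout the package.
#'
#' @param path File path.
#' @return A tibble.
#' @name diglyq_io
NULL

#' @rdname diglyq_io
#' @export
read_psm_table <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE, na = "")
}

#' @rdname diglyq_io
#' @param x Table to write.
#' @export
write_table <- function(x, path) {
  readr::write_tsv(x, path, na = "")
  invisible(path)
}

#' Write a simulated experiment to disk
#'
#' Serializes a [simulate_experiment()] result as TSV tables, the ground
#' truth as a JSON sidecar, and the configuration as JSON, so a run can be
#' reproduced from flat files alone.
#'
#' @param sim A `digly_sim` object.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the written paths.
#' @export
write_experiment <- function(sim, dir) {
  stopifnot(inherits(sim, "digly_sim"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  readr::write_tsv(sim$psms, file.path(dir, "psms.tsv"), na = "")
  readr::write_tsv(sim$proteins, file.path(dir, "proteins.tsv"), na = "")
  readr::write_tsv(sim$annotation, file.path(dir, "annotation.tsv"), na = "")
  readr::write_tsv(sim$channels, file.path(dir, "channels.tsv"), na = "")
  jsonlite::write_json(
    list(sites = sim$truth$sites, proteins = sim$truth$proteins),
    file.path(dir, "ground_truth.json"), digits = NA)
  jsonlite::write_json(unclass(sim$truth$config),
                       file.path(dir, "config.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(file.path(dir, c("psms.tsv", "proteins.tsv", "annotation.tsv",
                             "channels.tsv", "ground_truth.json",
                             "config.json")))
}

#' Write ortholog pairs as FASTA with a pairing table
#'
#' @param orthologs Tibble with `gene_a`, `gene_b`, `seq_a`, `seq_b`.
#' @param fasta_path,pairs_path Output paths for the FASTA file and the
#'   two-column pairing TSV.
#' @return Invisibly, the two paths.
#' @export
write_ortholog_fasta <- function(orthologs, fasta_path, pairs_path) {
  seqs <- Biostrings::AAStringSet(c(
    stats::setNames(orthologs$seq_a, orthologs$gene_a),
    stats::setNames(orthologs$seq_b, orthologs$gene_b)))
  Biostrings::writeXStringSet(seqs, fasta_path)
  readr::write_tsv(orthologs[c("gene_a", "gene_b")], pairs_path)
  invisible(c(fasta_path, pairs_path))
}

#' Read ortholog pairs from FASTA plus pairing table
#'
#' @param fasta_path FASTA of all sequences, names matching the pairing
#'   table's gene symbols.
#' @param pairs_path Two-column TSV (`gene_a`, `gene_b`).
#' @return Ortholog tibble (`gene_a`, `gene_b`, `seq_a`, `seq_b`).
#' @export
read_ortholog_fasta <- function(fasta_path, pairs_path) {
  seqs <- Biostrings::readAAStringSet(fasta_path)
  pairs <- readr::read_tsv(pairs_path, show_col_types = FALSE)
  tibble::tibble(
    gene_a = pairs$gene_a, gene_b = pairs$gene_b,
    seq_a = as.character(seqs[pairs$gene_a]),
    seq_b = as.character(seqs[pairs$gene_b])
  )
}
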