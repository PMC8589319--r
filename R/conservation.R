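#' Global protein alignment with affine gap penalties
#'
#' Optimal Needleman-Wunsch/Gotoh global alignment of two amino-acid
#' sequences under BLOSUM62 (default) with affine gap costs: a gap of length
#' L is penalized `gap_open + L * gap_extend`. `X` is tolerated and scored 0
#' against everything. Alignment is delegated to
#' [Biostrings::pairwiseAlignment()].
#'
#' @param seq_a,seq_b Amino-acid sequences (character scalars).
#' @param matrix Substitution matrix name (default `"BLOSUM62"`).
#' @param gap_open,gap_extend Affine gap parameters (defaults 11 and 1, the
#'   standard protein settings).
#' @return Object of class `ub_alignment`: gapped sequences `a` and `b` of
#'   equal length, `score`, and the parameters used.
#' @export
global_align <- function(seq_a, seq_b, matrix = "BLOSUM62",
                         gap_open = 11, gap_extend = 1) {
  if (!nzchar(seq_a) || !nzchar(seq_b)) {
    stop("sequences must be nonempty", call. = FALSE)
  }
  submat <- .substitution_matrix(matrix)
  alphabet <- rownames(submat)
  for (s in c(seq_a, seq_b)) {
    bad <- setdiff(strsplit(toupper(s), "")[[1]], alphabet)
    if (length(bad) > 0) {
      stop("illegal residue character(s): ", paste(unique(bad), collapse = ", "),
           call. = FALSE)
    }
  }
  pa <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(toupper(seq_a)), Biostrings::AAString(toupper(seq_b)),
    substitutionMatrix = submat, gapOpening = gap_open,
    gapExtension = gap_extend, type = "global"
  )
  structure(
    list(a = as.character(Biostrings::alignedPattern(pa)),
         b = as.character(Biostrings::alignedSubject(pa)),
         score = Biostrings::score(pa),
         matrix = matrix, gap_open = gap_open, gap_extend = gap_extend),
    class = "ub_alignment"
  )
}

# BLOSUM-style matrix with X scored 0 against everything
.substitution_matrix <- function(name) {
  env <- new.env()
  utils::data(list = name, package = "Biostrings", envir = env)
  m <- get(name, envir = env)
  if ("X" %in% rownames(m)) {
    m["X", ] <- 0L
    m[, "X"] <- 0L
  }
  m
}

#' @export
print.ub_alignment <- function(x, ...) {
  cat("Global alignment (", x$matrix, ", open ", x$gap_open, " / extend ",
      x$gap_extend, "), score ", x$score, "\n", sep = "")
  cat(x$a, "\n", x$b, "\n", sep = "")
  invisible(x)
}

#' @export
glance.ub_alignment <- function(x, ...) {
  ca <- strsplit(x$a, "")[[1]]; cb <- strsplit(x$b, "")[[1]]
  tibble::tibble(
    score = x$score,
    length = length(ca),
    identity = mean(ca == cb & ca != "-"),
    gaps = sum(ca == "-" | cb == "-")
  )
}

#' Map a modified site through an alignment
#'
#' Walks the alignment columns to find the residue of sequence `b` aligned
#' to position `position_a` (1-based, ungapped coordinates) of sequence `a`.
#' If the source residue is aligned to a gap the target is `NA`. The
#' `conserved_k` flag records whether both aligned residues are lysine —
#' the requirement for a ubiquitylation site to be conserved.
#'
#' @param alignment An `ub_alignment` from [global_align()].
#' @param position_a 1-based position in ungapped sequence `a`.
#' @return One-row tibble: `position_a`, `position_b` (or `NA`),
#'   `residue_a`, `residue_b`, `conserved_k`.
#' @export
map_site <- function(alignment, position_a) {
  stopifnot(inherits(alignment, "ub_alignment"))
  ca <- strsplit(alignment$a, "")[[1]]
  cb <- strsplit(alignment$b, "")[[1]]
  pos_a <- cumsum(ca != "-")
  if (position_a < 1 || position_a > max(pos_a)) {
    stop("position ", position_a, " outside sequence a (length ",
         max(pos_a), ")", call. = FALSE)
  }
  col <- which(pos_a == position_a & ca != "-")[1]
  pos_b_all <- cumsum(cb != "-")
  res_b <- cb[col]
  tibble::tibble(
    position_a = as.integer(position_a),
    position_b = if (res_b == "-") NA_integer_ else as.integer(pos_b_all[col]),
    residue_a = ca[col],
    residue_b = if (res_b == "-") NA_character_ else res_b,
    conserved_k = ca[col] == "K" && res_b == "K"
  )
}

#' Cross-species conserved regulated-site overlap
#'
#' Filters two regulated-site sets by the conservation thresholds (strictly
#' `log2 ratio > log2_min` and `p < p_max`), maps each species-a site into
#' species-b coordinates through a global alignment of the ortholog pair,
#' and classifies each site as shared (mapped position present in the other
#' set with lysine conserved on both sides), a-only, or b-only. Proteins
#' present in both sets but with no shared site are reported as
#' shared-protein/nonshared-site in the protein rollup. Genes lacking an
#' ortholog sequence are listed as unmappable, never silently dropped.
#'
#' @param set_a,set_b Tibbles with columns `gene`, `position`, `log2`, `p`.
#'   Gene symbols in `set_b` are matched through the ortholog pairing.
#' @param orthologs Tibble with columns `gene_a`, `gene_b`, `seq_a`, `seq_b`.
#' @param log2_min,p_max Conservation thresholds (defaults 1.0 and 0.05;
#'   both strict inequalities).
#' @param ... Passed to [global_align()].
#' @return List with `sites` (per-site classification), `venn_sites`,
#'   `venn_proteins` (counts: a_only/shared/b_only), `shared_protein_distinct_sites`
#'   (genes shared at protein level only) and `unmappable` (genes without
#'   ortholog sequences).
#' @export
conserved_overlap <- function(set_a, set_b, orthologs,
                              log2_min = 1.0, p_max = 0.05, ...) {
  for (s in list(set_a, set_b)) {
    stopifnot(all(c("gene", "position", "log2", "p") %in% names(s)))
  }
  fa <- set_a[set_a$log2 > log2_min & set_a$p < p_max, , drop = FALSE]
  fb <- set_b[set_b$log2 > log2_min & set_b$p < p_max, , drop = FALSE]

  genes_a <- unique(fa$gene)
  genes_b <- unique(fb$gene)
  unmappable <- union(setdiff(genes_a, orthologs$gene_a),
                      setdiff(genes_b, orthologs$gene_b))

  # map a-sites to b coordinates, one alignment per ortholog pair
  pair_genes <- unique(fa$gene[fa$gene %in% orthologs$gene_a])
  mapped <- purrr::map_dfr(pair_genes, function(g) {
    o <- orthologs[orthologs$gene_a == g, ][1, ]
    aln <- global_align(o$seq_a, o$seq_b, ...)
    sites_g <- fa[fa$gene == g, , drop = FALSE]
    purrr::map_dfr(sites_g$position, function(pos) {
      m <- map_site(aln, pos)
      tibble::tibble(gene_a = g, gene_b = o$gene_b,
                     position_a = m$position_a, position_b = m$position_b,
                     conserved_k = m$conserved_k)
    })
  })

  b_keys <- paste(fb$gene, fb$position)
  if (nrow(mapped) > 0) {
    mapped$shared <- !is.na(mapped$position_b) & mapped$conserved_k &
      paste(mapped$gene_b, mapped$position_b) %in% b_keys
  } else {
    mapped <- tibble::tibble(gene_a = character(), gene_b = character(),
                             position_a = integer(), position_b = integer(),
                             conserved_k = logical(), shared = logical())
  }

  shared_b_keys <- paste(mapped$gene_b[mapped$shared],
                         mapped$position_b[mapped$shared])
  a_tbl <- fa |>
    dplyr::mutate(status = dplyr::case_when(
      paste(.data$gene, .data$position) %in%
        paste(mapped$gene_a[mapped$shared], mapped$position_a[mapped$shared]) ~ "shared",
      TRUE ~ "a_only"
    ), species = "a")
  b_tbl <- fb |>
    dplyr::mutate(status = dplyr::if_else(
      paste(.data$gene, .data$position) %in% shared_b_keys, "shared", "b_only"),
      species = "b")
  sites <- dplyr::bind_rows(a_tbl, b_tbl)

  n_shared_sites <- sum(a_tbl$status == "shared")
  venn_sites <- tibble::tibble(
    a_only = sum(a_tbl$status == "a_only"),
    shared = n_shared_sites,
    b_only = sum(b_tbl$status == "b_only")
  )

  # protein level: translate b genes into a-gene space where an ortholog exists
  b2a <- stats::setNames(orthologs$gene_a, orthologs$gene_b)
  genes_b_in_a <- ifelse(genes_b %in% names(b2a), b2a[genes_b], genes_b)
  shared_site_proteins <- unique(a_tbl$gene[a_tbl$status == "shared"])
  both <- intersect(genes_a, genes_b_in_a)
  shared_protein_distinct <- setdiff(both, shared_site_proteins)
  venn_proteins <- tibble::tibble(
    a_only = length(setdiff(genes_a, both)),
    shared = length(both),
    shared_with_shared_sites = length(shared_site_proteins),
    b_only = length(setdiff(genes_b_in_a, both))
  )

  list(sites = sites, venn_sites = venn_sites, venn_proteins = venn_proteins,
       shared_protein_distinct_sites = sort(shared_protein_distinct),
       unmappable = sort(unmappable))
}
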