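#' Run the full diGLY quantification pipeline
#'
#' Orchestrates the stages in their canonical order: PSM quality filtering,
#' target-decoy FDR control, site localization and aggregation,
#' equal-loading normalization of the protein and site reporter matrices,
#' site-to-protein normalization, log2 transform and median-centering,
#' differential testing by both routes (S0-modified Welch statistic with
#' permutation FDR, and moderated t with Benjamini-Hochberg), annotation,
#' MS1 abundance ranking, optional cross-species conservation, histone-ruler
#' copy numbers, and optional AQUA quantification. Every stage's input and
#' output row counts are recorded in the stage log; no stage drops records
#' silently.
#'
#' @param psms PSM tibble (see [simulate_experiment()] for the column
#'   contract).
#' @param proteins Protein table with `protein`, `gene`, `sequence`, `mw`,
#'   `intensity` and reporter `sn_*` columns.
#' @param channels Channel metadata tibble (`channel`, `treatment`,
#'   optionally `genotype`).
#' @param annotation Optional MitoCarta-style annotation table; when absent
#'   the annotation columns are marked unavailable.
#' @param aqua Optional AQUA measurement table for [quantify_aqua()].
#' @param conservation Optional list with `set_b` and `orthologs` for
#'   [conserved_overlap()]; the species-a set is taken from this run's
#'   significant up-regulated sites.
#' @param contrast Two treatment labels, tested as `contrast[1]` vs
#'   `contrast[2]` (default AO vs UT).
#' @param genotype_filter Optional genotype label; restricts the tested
#'   channels to that genotype.
#' @param s0,fdr_level,n_permutations,seed Differential-testing settings
#'   (see [permutation_fdr()]).
#' @param psm_fdr_level Target-decoy FDR level (default 0.01).
#' @param min_ascore Localization threshold (default 13).
#' @param min_isolation_specificity,min_summed_sn,charge_range PSM filter
#'   thresholds (see [filter_psms()]).
#' @param histones Histone accessions for the proteomic ruler; default:
#'   accessions starting with `"HIST"`.
#' @param ploidy,genome_size_bp Ruler genome parameters.
#' @return Object of class `result_bundle`: a list with the filter report,
#'   site matrices (raw, normalized, centered), `diff_perm` (a `perm_fdr`),
#'   `diff_moderated`, `annotated` site results, `ranking`, `copy_numbers`,
#'   optional `conservation` and `aqua`, the per-stage `log`, and a
#'   `manifest` (settings, seed, input hash, package version) sufficient to
#'   reproduce the run.
#' @export
run_pipeline <- function(psms, proteins, channels,
                         annotation = NULL, aqua = NULL, conservation = NULL,
                         contrast = c("AO", "UT"), genotype_filter = NULL,
                         s0 = 2, fdr_level = 0.01, n_permutations = 250,
                         seed = 1L, psm_fdr_level = 0.01, min_ascore = 13,
                         min_isolation_specificity = 0.7, min_summed_sn = 150,
                         charge_range = c(3, 6),
                         histones = NULL,
                         ploidy = 2, genome_size_bp = 2.7e9) {
  log <- list()
  note <- function(stage, n_in, n_out) {
    log[[length(log) + 1]] <<- tibble::tibble(stage = stage, n_in = n_in,
                                              n_out = n_out)
  }
  sn_cols <- channels$channel

  ## 1-2: quality filter, then target-decoy FDR
  filt <- filter_psms(psms, min_isolation_specificity, min_summed_sn,
                      charge_range, digly = TRUE)
  note("filter_psms", nrow(psms), nrow(filt$kept))
  kept <- target_decoy_fdr(filt$kept, level = psm_fdr_level, by = "psm")
  note("target_decoy_fdr", nrow(filt$kept), nrow(kept))

  ## 3: localization + aggregation to sites
  sites <- aggregate_to_sites(kept, proteins[c("protein", "sequence")],
                              min_ascore = min_ascore)
  note("aggregate_to_sites", nrow(kept), nrow(sites))
  gene_of <- stats::setNames(proteins$gene, proteins$protein)
  sites$gene <- unname(gene_of[sites$protein])
  sites$site_id <- paste0(sites$protein, "_K", sites$position)

  ## 4: equal-loading normalization of the total-proteome matrix (channel
  ## sums over all quantified proteins; the diGLY matrix is instead
  ## corrected per protein and median-centered below, since its column sums
  ## carry real regulation)
  prot_norm <- equal_loading_normalize(proteins, sn_cols)
  note("equal_loading_normalize", nrow(proteins), nrow(prot_norm))

  ## 5: site-to-protein normalization (channel-wise division)
  site_rel <- normalize_site_to_protein(sites, prot_norm, sn_cols)
  note("normalize_site_to_protein", nrow(sites), nrow(site_rel))

  ## 6: log2; median-center feeds the moderated route only (one-sided
  ## regulation shifts column medians, so the permutation volcano tests the
  ## protein-normalized log ratios directly)
  logged <- site_rel
  logged[sn_cols] <- log2(as.matrix(site_rel[sn_cols]))
  centered <- median_center(logged, sn_cols)
  note("median_center", nrow(logged), nrow(centered))

  ## 7: differential testing on the contrast channels
  ch <- channels
  if (!is.null(genotype_filter)) {
    ch <- ch[ch$genotype == genotype_filter, , drop = FALSE]
  }
  ch <- ch[ch$treatment %in% contrast, , drop = FALSE]
  test_cols <- ch$channel
  groups <- factor(ch$treatment, levels = contrast)
  diff_perm <- permutation_fdr(logged[c("site_id", test_cols)], groups,
                               s0 = s0, fdr_level = fdr_level,
                               n_permutations = n_permutations, seed = seed,
                               id = "site_id")
  diff_mod <- moderated_t(centered[c("site_id", test_cols)], groups,
                          id = "site_id")
  note("differential", nrow(logged), nrow(tidy(diff_perm)))

  ## 8: annotation
  res <- tidy(diff_perm) |>
    dplyr::left_join(sites[c("site_id", "protein", "gene", "position")],
                     by = c(feature = "site_id"))
  res$normalized <- site_rel$normalized[match(res$feature, site_rel$site_id)]
  if (!is.null(annotation)) {
    res <- annotate_sites(res, annotation)
  } else {
    res$mito <- NA
    res$subcompartment <- NA_character_
  }
  note("annotate", nrow(res), nrow(res))

  ## 9: MS1 apportionment ranking
  ranking <- rank_site_abundance(sites, rank_channels = sn_cols)
  note("rank_site_abundance", nrow(sites), nrow(ranking))

  ## 10: conservation
  cons <- NULL
  if (!is.null(conservation)) {
    set_a <- res |>
      dplyr::transmute(gene = .data$gene, position = .data$position,
                       log2 = .data$log2fc, p = .data$q)
    cons <- conserved_overlap(set_a, conservation$set_b,
                              conservation$orthologs)
    note("conserved_overlap", nrow(set_a), nrow(cons$sites))
  }

  ## 11: proteomic ruler
  if (is.null(histones)) {
    histones <- proteins$protein[startsWith(proteins$protein, "HIST")]
  }
  copy_numbers <- proteomic_ruler_copies(
    proteins[c("protein", "gene", "intensity", "mw")], histones,
    ploidy = ploidy, genome_size_bp = genome_size_bp)
  note("proteomic_ruler", nrow(proteins), nrow(copy_numbers))

  ## 12: AQUA
  aqua_profile <- NULL
  if (!is.null(aqua)) {
    aqua_profile <- quantify_aqua(aqua)
    note("quantify_aqua", nrow(aqua), nrow(aqua_profile$by_locus))
  }

  settings <- list(
    contrast = contrast, genotype_filter = genotype_filter, s0 = s0,
    fdr_level = fdr_level, n_permutations = n_permutations, seed = seed,
    psm_fdr_level = psm_fdr_level, min_ascore = min_ascore,
    min_isolation_specificity = min_isolation_specificity,
    min_summed_sn = min_summed_sn, charge_range = charge_range,
    ploidy = ploidy, genome_size_bp = genome_size_bp
  )
  manifest <- list(
    package = "diglyq",
    version = as.character(utils::packageVersion("diglyq")),
    settings = settings,
    input_hash = rlang::hash(list(psms, proteins, channels, annotation,
                                  aqua, conservation)),
    result_hash = rlang::hash(list(tidy(diff_perm), copy_numbers))
  )

  structure(
    list(filter_report = filt$report, sites_raw = sites,
         sites_normalized = site_rel, sites_centered = centered,
         protein_norm = prot_norm,
         diff_perm = diff_perm, diff_moderated = diff_mod,
         annotated = res, ranking = ranking, conservation = cons,
         copy_numbers = copy_numbers, aqua = aqua_profile,
         channels = channels, log = dplyr::bind_rows(log),
         manifest = manifest),
    class = "result_bundle"
  )
}

#' @export
print.result_bundle <- function(x, ...) {
  cat("diGLY pipeline result bundle\n")
  print(x$log)
  print(glance(x$diff_perm))
  invisible(x)
}

#' @export
glance.result_bundle <- function(x, ...) {
  g <- glance(x$diff_perm)
  g$n_proteins <- nrow(x$copy_numbers)
  g
}

#' Classify sites as genotype-dependent from paired contrasts
#'
#' Compares the same depolarization contrast estimated in wild-type and
#' knockout channels and flags a site as genotype-dependent when its KO
#' effect collapses below half of its WT effect — the signature of a
#' response licensed by the knocked-out kinase.
#'
#' @param wt,ko Differential result tibbles (e.g. `tidy()` of the
#'   `diff_perm` component) from WT-only and KO-only runs, sharing the
#'   `feature` column.
#' @return Tibble with `feature`, `log2fc_wt`, `log2fc_ko`,
#'   `genotype_dependent`.
#' @export
genotype_dependence <- function(wt, ko) {
  dplyr::inner_join(
    dplyr::select(wt, "feature", log2fc_wt = "log2fc"),
    dplyr::select(ko, "feature", log2fc_ko = "log2fc"),
    by = "feature"
  ) |>
    dplyr::mutate(genotype_dependent = .data$log2fc_ko < .data$log2fc_wt / 2)
}

#' Export the searchable result tables
#'
#' Writes the bundle as flat UTF-8 TSV files plus JSON summaries: a
#' peptide-level master table filterable by significance, fold change,
#' mitochondrial annotation and total-proteome presence; the normalized and
#' centered site matrices; both differential results; the copy-number table;
#' conservation Venn summaries (JSON) when present; AQUA profiles (with
#' `n.d.` for not-determined values); and the run manifest (JSON). Missing
#' values are written as empty fields.
#'
#' @param bundle A `result_bundle` from [run_pipeline()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, the named vector of written paths.
#' @export
export_resource_tables <- function(bundle, dir) {
  stopifnot(inherits(bundle, "result_bundle"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- c()
  put <- function(x, name) {
    p <- file.path(dir, name)
    readr::write_tsv(x, p, na = "")
    paths[name] <<- p
  }

  rank_of <- stats::setNames(bundle$ranking$rank,
                             paste0(bundle$ranking$protein, "_K",
                                    bundle$ranking$position))
  in_proteome <- bundle$annotated$protein %in% bundle$copy_numbers$protein
  master <- bundle$annotated |>
    dplyr::mutate(
      site = paste0("K", .data$position),
      in_total_proteome = in_proteome,
      rank_abundance = unname(rank_of[.data$feature])
    ) |>
    dplyr::select("gene", "protein", "site", "position", "log2fc", "d",
                  "q", "significant", "direction", "normalized", "mito",
                  "subcompartment", "in_total_proteome", "rank_abundance")
  put(master, "master_table.tsv")
  put(bundle$sites_normalized, "site_matrix_normalized.tsv")
  put(bundle$sites_centered, "site_matrix_centered.tsv")
  put(tidy(bundle$diff_perm), "differential_permutation.tsv")
  put(bundle$diff_moderated, "differential_moderated.tsv")
  put(bundle$copy_numbers, "copy_numbers.tsv")
  put(bundle$log, "stage_log.tsv")

  if (!is.null(bundle$conservation)) {
    put(bundle$conservation$sites, "conservation_sites.tsv")
    venn <- list(sites = as.list(bundle$conservation$venn_sites),
                 proteins = as.list(bundle$conservation$venn_proteins),
                 shared_protein_distinct_sites =
                   bundle$conservation$shared_protein_distinct_sites,
                 unmappable = bundle$conservation$unmappable)
    p <- file.path(dir, "conservation_venn.json")
    jsonlite::write_json(venn, p, auto_unbox = TRUE, digits = NA)
    paths["conservation_venn.json"] <- p
  }
  if (!is.null(bundle$aqua)) {
    by_locus <- bundle$aqua$by_locus
    stoich <- bundle$aqua$stoichiometry |>
      dplyr::mutate(stoichiometry = ifelse(is.na(.data$stoichiometry), "n.d.",
                                           format(.data$stoichiometry)))
    put(by_locus, "aqua_linkage_profile.tsv")
    put(stoich, "aqua_stoichiometry.tsv")
  }
  p <- file.path(dir, "manifest.json")
  jsonlite::write_json(bundle$manifest, p, auto_unbox = TRUE, digits = NA)
  paths["manifest.json"] <- p
  invisible(paths)
}
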