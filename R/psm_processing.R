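#' Quality-filter peptide-spectrum matches
#'
#' Applies the MS3 quantification quality filters: records are kept if and
#' only if isolation specificity >= `min_isolation_specificity`, summed
#' reporter signal-to-noise >= `min_summed_sn`, an MS3 spectrum was acquired,
#' and (in diGLY mode) the precursor charge lies within `charge_range`.
#' Exclusions in the source protocol are stated as strict "less than", so the
#' boundary values 0.7 and 150 are kept.
#'
#' @param psms Tibble of PSM records with columns `isolation_specificity`,
#'   `summed_sn`, `has_ms3`, `charge` (see [simulate_experiment()] for the
#'   full column contract).
#' @param min_isolation_specificity Minimum fraction of isolation-window
#'   signal attributable to the precursor (default 0.7).
#' @param min_summed_sn Minimum summed reporter signal-to-noise (default 150).
#' @param charge_range Inclusive charge window applied in diGLY mode
#'   (default `c(3, 6)`).
#' @param digly Logical; apply the charge window (diGLY searches select
#'   precursors of charge 3-6).
#' @return An object of class `psm_filter`: a list with `kept` (the passing
#'   records, same columns as the input), `report` (tibble of kept/excluded
#'   counts per criterion) and `reasons` (per excluded record, its row index
#'   and the criteria it violated).
#' @export
filter_psms <- function(psms,
                        min_isolation_specificity = 0.7,
                        min_summed_sn = 150,
                        charge_range = c(3, 6),
                        digly = TRUE) {
  stopifnot(is.data.frame(psms))
  needed <- c("isolation_specificity", "summed_sn", "has_ms3", "charge")
  missing_cols <- setdiff(needed, names(psms))
  if (length(missing_cols) > 0) {
    stop("psms is missing column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }

  fails <- list(
    isolation_specificity = psms$isolation_specificity < min_isolation_specificity,
    summed_sn             = psms$summed_sn < min_summed_sn,
    no_ms3                = !psms$has_ms3
  )
  if (digly) {
    fails$charge <- psms$charge < charge_range[1] | psms$charge > charge_range[2]
  }
  fail_mat <- do.call(cbind, fails)
  excluded <- if (nrow(psms) == 0) logical(0) else rowSums(fail_mat) > 0

  reasons <- tibble::tibble(
    row = rep(seq_len(nrow(psms)), times = ncol(fail_mat)),
    reason = rep(colnames(fail_mat), each = nrow(psms)),
    violated = as.vector(fail_mat)
  ) |>
    dplyr::filter(.data$violated) |>
    dplyr::select("row", "reason") |>
    dplyr::arrange(.data$row)

  report <- tibble::tibble(
    criterion = c(colnames(fail_mat), "total"),
    excluded = unname(c(colSums(fail_mat), sum(excluded))),
    kept = nrow(psms) - excluded
  )

  structure(
    list(kept = psms[!excluded, , drop = FALSE], report = report,
         reasons = reasons, n_input = nrow(psms)),
    class = "psm_filter"
  )
}

#' @export
print.psm_filter <- function(x, ...) {
  cat("PSM quality filter: ", nrow(x$kept), "/", x$n_input, " records kept\n",
      sep = "")
  print(x$report)
  invisible(x)
}

#' Target-decoy false discovery rate thresholding
#'
#' Sorts records by decreasing search score and keeps the largest
#' score-prefix whose estimated FDR, the number of decoys above the cutoff
#' divided by the number of targets above it, does not exceed `level`.
#' Decoys are removed from the output. At `by = "peptide"` or `"protein"`,
#' groups are scored by their best PSM and thresholded as units.
#'
#' @param psms Tibble with columns `score`, `is_decoy`, and (for grouped
#'   levels) `peptide` / `protein`.
#' @param level FDR level in (0, 1); the study uses 0.01 at PSM, peptide and
#'   protein level. `level = 0` keeps the top prefix containing no decoys.
#' @param by Grouping level: `"psm"`, `"peptide"` or `"protein"`.
#' @return Tibble of kept target records, with an attribute
#'   `"fdr_estimate"` (the estimate at the chosen cutoff).
#' @export
target_decoy_fdr <- function(psms, level = 0.01, by = c("psm", "peptide", "protein")) {
  by <- match.arg(by)
  stopifnot(is.data.frame(psms), level >= 0, level < 1)
  if (!all(c("score", "is_decoy") %in% names(psms))) {
    stop("psms needs `score` and `is_decoy` columns", call. = FALSE)
  }

  if (by == "psm") {
    units <- psms |> dplyr::mutate(.unit_score = .data$score)
  } else {
    key <- if (by == "peptide") "peptide" else "protein"
    units <- psms |>
      dplyr::group_by(.data[[key]], .data$is_decoy) |>
      dplyr::mutate(.unit_score = max(.data$score)) |>
      dplyr::ungroup()
    # threshold distinct (group, decoy) units, not individual PSMs
    unit_tbl <- units |> dplyr::distinct(.data[[key]], .data$is_decoy, .data$.unit_score)
    keep_units <- .fdr_prefix(unit_tbl$.unit_score, unit_tbl$is_decoy, level)
    kept_keys <- unit_tbl[keep_units & !unit_tbl$is_decoy, ][[key]]
    out <- units |>
      dplyr::filter(!.data$is_decoy, .data[[key]] %in% kept_keys) |>
      dplyr::select(-".unit_score")
    attr(out, "fdr_estimate") <- attr(keep_units, "fdr_estimate")
    return(out)
  }

  keep <- .fdr_prefix(units$.unit_score, units$is_decoy, level)
  out <- units |> dplyr::filter(keep & !.data$is_decoy) |> dplyr::select(-".unit_score")
  attr(out, "fdr_estimate") <- attr(keep, "fdr_estimate")
  out
}

# Largest score-prefix with estimated FDR <= level. Ties in score are kept
# or dropped together (a cutoff is a score value, not a row index).
.fdr_prefix <- function(score, is_decoy, level) {
  n <- length(score)
  if (n == 0) return(structure(logical(0), fdr_estimate = NA_real_))
  ord <- order(score, decreasing = TRUE)
  dec <- cumsum(is_decoy[ord])
  tar <- cumsum(!is_decoy[ord])
  fdr <- dec / pmax(1, tar)
  # candidate cutoffs: last row of each tied score block
  block_end <- c(score[ord][-1] != score[ord][-n], TRUE)
  ok <- which(block_end & fdr <= level)
  keep <- logical(n)
  est <- NA_real_
  if (length(ok) > 0) {
    k <- max(ok)
    keep[ord[seq_len(k)]] <- TRUE
    est <- fdr[k]
  }
  structure(keep, fdr_estimate = est)
}

#' Binomial site-localization score (AScore)
#'
#' Probability-based localization score for a post-translational modification
#' site: `-10 * log10 P(X >= k)` for `X ~ Binomial(n, p)`, where `n` is the
#' number of site-determining fragment ions, `k` the number matched, and `p`
#' the per-ion chance probability at the chosen peak depth. For two candidate
#' site isomers, the reported site score is the best candidate's score minus
#' the runner-up's ([ascore_site()]); a score of at least 13 corresponds to
#' 95% confidence in the localization.
#'
#' @param n Number of site-determining ions (vectorized).
#' @param k Number of matched site-determining ions, `0 <= k <= n`.
#' @param p Peak-depth (chance match) probability in (0, 1).
#' @return Score in decibans; 0 when `k = 0`.
#' @examples
#' ascore(10, 5, 0.1)
#' ascore(1, 1, 0.05) # tail probability 0.05 -> 13.0, the 95% threshold
#' @export
ascore <- function(n, k, p) {
  if (any(p <= 0 | p >= 1)) stop("`p` must lie in (0, 1)", call. = FALSE)
  if (any(k < 0 | k > n)) stop("`k` must satisfy 0 <= k <= n", call. = FALSE)
  tail <- stats::pbinom(k - 1, n, p, lower.tail = FALSE)
  -10 * log10(tail)
}

#' @rdname ascore
#' @param n_best,k_best,n_runner,k_runner Ion counts for the best and
#'   runner-up candidate site isomers.
#' @export
ascore_site <- function(n_best, k_best, n_runner, k_runner, p) {
  ascore(n_best, k_best, p) - ascore(n_runner, k_runner, p)
}

#' Parsimonious protein grouping
#'
#' Greedy set cover producing the smallest set of proteins needed to account
#' for all observed peptides: repeatedly select the protein explaining the
#' most still-unexplained peptides (ties broken by lexicographic accession
#' order); each selected protein claims its unexplained peptides, so shared
#' (razor) peptides are assigned to the first group that covers them.
#'
#' @param peptide_map Tibble with columns `peptide` and `protein`, one row
#'   per candidate assignment (a peptide may map to several proteins).
#' @return Tibble with columns `protein` (group representative), `peptide`,
#'   and `shared` (whether the peptide had more than one candidate protein).
#' @export
parsimony_protein_groups <- function(peptide_map) {
  stopifnot(is.data.frame(peptide_map))
  if (nrow(peptide_map) == 0) {
    return(tibble::tibble(protein = character(), peptide = character(),
                          shared = logical()))
  }
  if (!all(c("peptide", "protein") %in% names(peptide_map))) {
    stop("peptide_map needs `peptide` and `protein` columns", call. = FALSE)
  }
  pm <- dplyr::distinct(peptide_map, .data$peptide, .data$protein)
  n_cand <- table(pm$peptide)
  cover <- split(pm$peptide, pm$protein)
  unexplained <- unique(pm$peptide)
  out <- list()
  while (length(unexplained) > 0) {
    gain <- vapply(cover, function(p) sum(p %in% unexplained), integer(1))
    best <- sort(names(cover)[gain == max(gain)])[1]
    claimed <- intersect(cover[[best]], unexplained)
    out[[best]] <- claimed
    unexplained <- setdiff(unexplained, claimed)
    cover[[best]] <- NULL
  }
  tibble::tibble(
    protein = rep(names(out), lengths(out)),
    peptide = unlist(out, use.names = FALSE)
  ) |>
    dplyr::mutate(shared = as.integer(n_cand[.data$peptide]) > 1L) |>
    dplyr::arrange(.data$protein, .data$peptide)
}

#' Aggregate diGLY PSMs to protein sites
#'
#' Maps each PSM's modified residue to protein coordinates (exact substring
#' search of the peptide in the protein sequence; on multiple occurrences the
#' first is used with a warning) and sums per-channel reporter
#' signal-to-noise and MS1 precursor intensity across all PSMs supporting
#' the same (protein, site). PSMs whose localization score is below
#' `min_ascore` are flagged ambiguous and excluded from the primary output.
#'
#' @param psms Tibble of kept diGLY PSMs with columns `peptide`, `protein`,
#'   `mod_position` (1-based within the peptide), `ascore`, `ms1_intensity`
#'   and reporter columns `sn_*`.
#' @param proteins Tibble with columns `protein`, `sequence`, or a named
#'   character vector of sequences.
#' @param min_ascore Localization threshold (default 13, the 95%-confidence
#'   anchor).
#' @return Tibble of site quantifications: `protein`, `position` (1-based in
#'   the protein), `residue`, `n_psms`, `ms1_total`, and the summed `sn_*`
#'   channels; the ambiguous records are attached as attribute `"ambiguous"`.
#' @export
aggregate_to_sites <- function(psms, proteins, min_ascore = 13) {
  stopifnot(is.data.frame(psms))
  if (is.data.frame(proteins)) {
    seqs <- stats::setNames(proteins$sequence, proteins$protein)
  } else {
    seqs <- proteins
  }
  sn_cols <- grep("^sn_", names(psms), value = TRUE)
  if (length(sn_cols) == 0) stop("no reporter `sn_*` columns found", call. = FALSE)

  localized <- !is.na(psms$ascore) & psms$ascore >= min_ascore
  ambiguous <- psms[!localized, , drop = FALSE]
  psms <- psms[localized, , drop = FALSE]
  if (nrow(psms) == 0) {
    out <- tibble::tibble(protein = character(), position = integer(),
                          residue = character(), n_psms = integer(),
                          ms1_total = double())
    attr(out, "ambiguous") <- ambiguous
    return(out)
  }

  unknown <- setdiff(unique(psms$protein), names(seqs))
  if (length(unknown) > 0) {
    stop("no sequence for protein(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  starts <- purrr::map2_int(psms$peptide, psms$protein, function(pep, prot) {
    hits <- gregexpr(pep, seqs[[prot]], fixed = TRUE)[[1]]
    if (hits[1] == -1) {
      stop("peptide ", pep, " not found in protein ", prot, call. = FALSE)
    }
    if (length(hits) > 1) {
      warning("peptide ", pep, " occurs ", length(hits), " times in ", prot,
              "; using first occurrence", call. = FALSE)
    }
    as.integer(hits[1])
  })
  psms$position <- starts + psms$mod_position - 1L
  psms$residue <- substr(seqs[psms$protein], psms$position, psms$position)

  out <- psms |>
    dplyr::group_by(.data$protein, .data$position, .data$residue) |>
    dplyr::summarise(
      n_psms = dplyr::n(),
      ms1_total = sum(.data$ms1_intensity),
      dplyr::across(dplyr::all_of(sn_cols), sum),
      .groups = "drop"
    ) |>
    dplyr::arrange(.data$protein, .data$position)
  attr(out, "ambiguous") <- ambiguous
  out
}
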