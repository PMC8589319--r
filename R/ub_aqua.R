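#' Absolute peptide abundance from a heavy-reference measurement
#'
#' AQUA quantification: the light (endogenous) peptide amount is the
#' light/heavy chromatographic area ratio times the known heavy spike,
#' `fmol = light_area / heavy_area * spike_fmol`. Linear in both the light
#' area and the spike.
#'
#' @param light_area,heavy_area Chromatographic peak areas (vectorized);
#'   heavy areas must be positive.
#' @param spike_fmol Heavy peptide amount spiked into the sample (fmol, > 0).
#' @return Light peptide amount in fmol.
#' @export
aqua_abundance <- function(light_area, heavy_area, spike_fmol) {
  if (any(light_area < 0)) stop("light areas must be >= 0", call. = FALSE)
  if (any(heavy_area <= 0)) {
    stop("heavy area must be > 0 (unquantifiable measurement)", call. = FALSE)
  }
  if (any(spike_fmol <= 0)) stop("spike amount must be > 0", call. = FALSE)
  light_area / heavy_area * spike_fmol
}

#' Total ubiquitin from locus-level measurements
#'
#' Total ubiquitin is the arithmetic mean of the total-ubiquitin amounts
#' calculated from each individual locus peptide.
#'
#' @param locus_fmol Numeric vector of per-locus total-ubiquitin amounts.
#' @return Mean fmol.
#' @export
total_ub <- function(locus_fmol) {
  locus_fmol <- locus_fmol[is.finite(locus_fmol)]
  if (length(locus_fmol) == 0) stop("no locus measurements", call. = FALSE)
  mean(locus_fmol)
}

#' Phosphorylation stoichiometry at a locus
#'
#' Fraction of the locus that is phosphorylated,
#' `phospho / (phospho + unmodified)`, from the locus's phospho/unmodified
#' peptide pair. Scale-invariant. When both amounts are zero the
#' stoichiometry is not determined and `NA` is returned (reported as "n.d.").
#'
#' @param phospho_fmol,unmodified_fmol Amounts (fmol, >= 0; vectorized).
#' @return Fraction in `[0, 1]`, or `NA` where undetermined.
#' @export
phospho_stoichiometry <- function(phospho_fmol, unmodified_fmol) {
  if (any(phospho_fmol < 0) || any(unmodified_fmol < 0)) {
    stop("amounts must be >= 0", call. = FALSE)
  }
  tot <- phospho_fmol + unmodified_fmol
  ifelse(tot == 0, NA_real_, phospho_fmol / tot)
}

#' Per-locus fold change between two linkage profiles
#'
#' Treated over untreated abundance per locus. Loci with zero baseline are
#' not determined (`NA`, exported as "n.d.") rather than infinite.
#'
#' @param treated,untreated Tibbles with columns `locus`, `fmol` (e.g. from
#'   [quantify_aqua()]), or named numeric vectors.
#' @return Tibble with `locus`, `treated_fmol`, `untreated_fmol`, `fold`.
#' @export
linkage_fold_change <- function(treated, untreated) {
  to_tbl <- function(x, col) {
    if (is.data.frame(x)) {
      tibble::tibble(locus = x$locus, !!col := x$fmol)
    } else {
      tibble::tibble(locus = names(x), !!col := unname(x))
    }
  }
  t <- to_tbl(treated, "treated_fmol")
  u <- to_tbl(untreated, "untreated_fmol")
  if (any(t$treated_fmol < 0, na.rm = TRUE) ||
      any(u$untreated_fmol < 0, na.rm = TRUE)) {
    stop("abundances must be >= 0", call. = FALSE)
  }
  dplyr::full_join(t, u, by = "locus") |>
    dplyr::mutate(fold = dplyr::if_else(
      is.na(.data$untreated_fmol) | .data$untreated_fmol == 0,
      NA_real_, .data$treated_fmol / .data$untreated_fmol))
}

#' Quantify an AQUA measurement table into linkage profiles
#'
#' Converts light/heavy area pairs to absolute amounts per measurement, then
#' summarizes replicates per condition and locus as mean and standard error
#' of the mean. Total ubiquitin is the mean over loci labeled
#' `"total_*"`; phospho-Ser65 stoichiometry is computed from the
#' `Ser65_phospho` / `Ser65_unmodified` pair.
#'
#' @param aqua Tibble with columns `peptide`, `locus`, `light_area`,
#'   `heavy_area`, `spike_fmol`, `replicate`, `condition` (see
#'   [simulate_aqua()]).
#' @return List of class `aqua_profile` with `by_locus` (per condition and
#'   locus: `fmol`, `sem`, `n`), `total_ub` (per condition) and
#'   `stoichiometry` (per condition, phospho-Ser65 fraction; `NA` = n.d.).
#' @export
quantify_aqua <- function(aqua) {
  needed <- c("peptide", "locus", "light_area", "heavy_area", "spike_fmol",
              "replicate", "condition")
  missing_cols <- setdiff(needed, names(aqua))
  if (length(missing_cols) > 0) {
    stop("aqua table missing column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  aqua$fmol <- aqua_abundance(aqua$light_area, aqua$heavy_area, aqua$spike_fmol)

  by_locus <- aqua |>
    dplyr::group_by(.data$condition, .data$locus) |>
    dplyr::summarise(
      n = dplyr::n(),
      sem = stats::sd(.data$fmol) / sqrt(dplyr::n()),
      fmol = mean(.data$fmol),
      .groups = "drop"
    ) |>
    dplyr::select("condition", "locus", "fmol", "sem", "n")

  totals <- by_locus |>
    dplyr::filter(startsWith(.data$locus, "total_")) |>
    dplyr::group_by(.data$condition) |>
    dplyr::summarise(total_ub_fmol = total_ub(.data$fmol), .groups = "drop")

  stoich <- by_locus |>
    dplyr::filter(.data$locus %in% c("Ser65_phospho", "Ser65_unmodified")) |>
    dplyr::select("condition", "locus", "fmol") |>
    tidyr::pivot_wider(names_from = "locus", values_from = "fmol") |>
    dplyr::mutate(stoichiometry = phospho_stoichiometry(
      .data$Ser65_phospho, .data$Ser65_unmodified))

  structure(list(by_locus = by_locus, total_ub = totals,
                 stoichiometry = stoich),
            class = "aqua_profile")
}

#' @export
print.aqua_profile <- function(x, ...) {
  cat("AQUA linkage profile:", nrow(x$by_locus), "condition x locus means\n")
  print(x$by_locus, n = 20)
  if (nrow(x$stoichiometry) > 0) {
    cat("phospho-Ser65 stoichiometry:\n")
    print(x$stoichiometry[, c("condition", "stoichiometry")])
  }
  invisible(x)
}

#' @export
tidy.aqua_profile <- function(x, ...) x$by_locus
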