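#' Annotate sites with mitochondrial localization
#'
#' Joins site-level records to a MitoCarta-style annotation table keyed by
#' gene symbol (case-insensitive). Records whose gene is absent from the
#' table are labeled non-mitochondrial. Re-annotating already annotated
#' output is a no-op.
#'
#' @param sites Tibble with a `gene` column.
#' @param annotation Tibble with columns `gene`, `mito` (logical) and
#'   `subcompartment` (one of MOM, MIM, Matrix, IMS, Membrane, unknown;
#'   `NA` for non-mitochondrial genes).
#' @param synonyms Optional named character vector mapping alternative gene
#'   symbols to annotation symbols (empty by default).
#' @return `sites` with `mito` and `subcompartment` columns added or
#'   replaced.
#' @export
annotate_sites <- function(sites, annotation, synonyms = character()) {
  stopifnot(is.data.frame(sites), is.data.frame(annotation))
  if (!"gene" %in% names(sites)) stop("sites needs a `gene` column", call. = FALSE)
  if (!all(c("gene", "mito", "subcompartment") %in% names(annotation))) {
    stop("annotation needs `gene`, `mito`, `subcompartment` columns",
         call. = FALSE)
  }
  ann <- annotation |>
    dplyr::mutate(.key = tolower(.data$gene)) |>
    dplyr::select(".key", "mito", "subcompartment")
  dup <- ann |>
    dplyr::distinct() |>
    dplyr::count(.data$.key) |>
    dplyr::filter(.data$n > 1)
  if (nrow(dup) > 0) {
    stop("conflicting annotation rows for gene(s): ",
         paste(dup$.key, collapse = ", "), call. = FALSE)
  }
  ann <- dplyr::distinct(ann)

  key <- tolower(sites$gene)
  if (length(synonyms) > 0) {
    names(synonyms) <- tolower(names(synonyms))
    hit <- key %in% names(synonyms)
    key[hit] <- tolower(synonyms[key[hit]])
  }
  idx <- match(key, ann$.key)
  sites$mito <- !is.na(idx) & ann$mito[idx]
  sites$subcompartment <- ifelse(sites$mito, ann$subcompartment[idx], NA_character_)
  sites
}

#' Subcompartment distribution of regulated sites
#'
#' Counts and fractions of annotated sites per mitochondrial subcompartment,
#' optionally restricted to one regulation direction. Fractions are reported
#' on two denominators: over all input sites (`fraction`; mitochondrial plus
#' non-mitochondrial fractions sum to 1) and over mitochondrial sites only
#' (`fraction_mito`).
#'
#' @param sites Annotated tibble (from [annotate_sites()]), typically the
#'   significant sites of a differential result.
#' @param direction Optional `"up"` or `"down"` filter applied to a
#'   `direction` column.
#' @return Tibble with `subcompartment` (including `"non-mito"`), `n`,
#'   `fraction`, `fraction_mito`.
#' @export
compartment_distribution <- function(sites, direction = NULL) {
  stopifnot(is.data.frame(sites))
  if (!is.null(direction)) {
    sites <- sites[sites$direction == direction, , drop = FALSE]
  }
  if (nrow(sites) == 0) {
    stop("no sites remain after filtering", call. = FALSE)
  }
  lab <- ifelse(sites$mito,
                dplyr::coalesce(sites$subcompartment, "unknown"),
                "non-mito")
  tot_mito <- sum(sites$mito)
  tibble::tibble(subcompartment = lab) |>
    dplyr::count(.data$subcompartment, name = "n") |>
    dplyr::mutate(
      fraction = .data$n / nrow(sites),
      fraction_mito = dplyr::if_else(
        .data$subcompartment == "non-mito", NA_real_,
        .data$n / max(1, tot_mito))
    ) |>
    dplyr::arrange(dplyr::desc(.data$n))
}
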