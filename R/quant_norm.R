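#' Equal-loading normalization of a reporter matrix
#'
#' Scales each reporter channel so that every column sums to the mean of the
#' original column sums, the standard correction assuming equal protein
#' loading of all TMT channels. Row and column order are preserved.
#'
#' @param m Tibble with one identifier column (anything non-numeric) and
#'   numeric channel columns, or a numeric matrix.
#' @param channels Optional character vector naming the channel columns;
#'   defaults to all numeric columns.
#' @return The input with channel columns rescaled.
#' @export
equal_loading_normalize <- function(m, channels = NULL) {
  channels <- .channel_cols(m, channels)
  mat <- as.matrix(m[channels])
  sums <- colSums(mat)
  if (any(sums <= 0)) {
    stop("channel(s) with nonpositive sum: ",
         paste(channels[sums <= 0], collapse = ", "), call. = FALSE)
  }
  m[channels] <- sweep(mat, 2, mean(sums) / sums, `*`)
  m
}

#' Normalize site ratios to their protein's ratios
#'
#' Divides each site's per-channel ratio by the matching protein's ratio in
#' the same channel, correcting diGLY signal for changes in the parent
#' protein's abundance. Sites whose protein was not quantified in the total
#' proteome (or whose protein ratio is 0 in any channel) pass through
#' unchanged and are flagged `normalized = FALSE` — these correspond to
#' "not determined" protein normalization in volcano displays.
#'
#' @param sites Tibble with a `protein` column and channel ratio columns.
#' @param protein_ratios Tibble with a `protein` column and the same channel
#'   columns.
#' @param channels Channel column names; default all shared numeric columns.
#' @return `sites` with channel columns divided where possible and a logical
#'   `normalized` column appended.
#' @export
normalize_site_to_protein <- function(sites, protein_ratios, channels = NULL) {
  if (is.null(channels)) {
    channels <- intersect(.channel_cols(sites, NULL),
                          .channel_cols(protein_ratios, NULL))
  }
  if (length(channels) == 0) stop("no shared channel columns", call. = FALSE)
  idx <- match(sites$protein, protein_ratios$protein)
  pmat <- as.matrix(protein_ratios[channels])[idx, , drop = FALSE]
  ok <- !is.na(idx) & apply(pmat, 1, function(r) all(is.finite(r) & r != 0))
  smat <- as.matrix(sites[channels])
  smat[ok, ] <- smat[ok, , drop = FALSE] / pmat[ok, , drop = FALSE]
  sites[channels] <- smat
  sites$normalized <- ok
  sites
}

#' Median-center a log-ratio matrix
#'
#' Subtracts each channel's median so every output column has median 0,
#' absorbing sample-to-sample variation before differential testing. Values
#' must already be on the log scale.
#'
#' @inheritParams equal_loading_normalize
#' @export
median_center <- function(m, channels = NULL) {
  channels <- .channel_cols(m, channels)
  mat <- as.matrix(m[channels])
  meds <- apply(mat, 2, stats::median, na.rm = TRUE)
  if (any(is.na(meds))) {
    stop("channel(s) with no observed values: ",
         paste(channels[is.na(meds)], collapse = ", "), call. = FALSE)
  }
  m[channels] <- sweep(mat, 2, meds, `-`)
  m
}

#' Absolute-scale site ranking by MS1 apportionment
#'
#' Produces a per-channel absolute-scale abundance estimate for each diGLY
#' site by apportioning its total MS1 precursor intensity across TMT channels
#' in proportion to each channel's share of the summed reporter
#' signal-to-noise: `A(s, c) = MS1(s) * SN(s, c) / sum_c SN(s, c)`. The
#' apportionment conserves each site's total MS1 mass. Sites are ranked in
#' decreasing order of their mean estimate over `rank_channels`, ties broken
#' by protein accession then position.
#'
#' @param sites Site quantification tibble from [aggregate_to_sites()]
#'   (columns `protein`, `position`, `ms1_total`, `sn_*`).
#' @param rank_channels Channels defining the ranking (default: all).
#' @return Tibble with per-channel `abund_*` estimates and a `rank` column;
#'   sites with zero summed signal-to-noise are dropped with a warning.
#' @export
rank_site_abundance <- function(sites, rank_channels = NULL) {
  sn_cols <- grep("^sn_", names(sites), value = TRUE)
  if (length(sn_cols) == 0) stop("no `sn_*` columns found", call. = FALSE)
  tot <- rowSums(as.matrix(sites[sn_cols]))
  if (any(tot <= 0)) {
    warning(sum(tot <= 0), " site(s) with zero summed signal-to-noise excluded",
            call. = FALSE)
    sites <- sites[tot > 0, , drop = FALSE]
    tot <- tot[tot > 0]
  }
  amat <- as.matrix(sites[sn_cols]) / tot * sites$ms1_total
  acols <- sub("^sn_", "abund_", sn_cols)
  sites[acols] <- amat
  if (is.null(rank_channels)) rank_channels <- acols
  rank_channels <- ifelse(startsWith(rank_channels, "abund_"),
                          rank_channels, sub("^sn_", "abund_", rank_channels))
  key <- rowMeans(as.matrix(sites[rank_channels]))
  ord <- order(-key, sites$protein, sites$position)
  sites$rank <- integer(nrow(sites))
  sites$rank[ord] <- seq_len(nrow(sites))
  dplyr::arrange(sites, .data$rank)
}

#' Histone proteomic-ruler copy numbers
#'
#' Estimates protein copies per cell by anchoring summed MS intensity to the
#' histone signal, which scales with cellular DNA mass: with
#' `m_DNA = ploidy * genome_size_bp * bp_mass / N_A` grams per cell and the
#' assumption that total histone mass equals DNA mass,
#' `copies_i = I_i * N_A * m_DNA / (MW_i * sum(I_histone))`. Invariant to
#' global intensity rescaling and linear in ploidy.
#'
#' @param proteins Tibble with columns `protein`, `intensity` and
#'   `mw` (g/mol) — or supply `mw` separately via [protein_molecular_weight()].
#' @param histones Character vector of histone accessions present in
#'   `proteins`.
#' @param ploidy Genome copies per cell (default 2, diploid mouse).
#' @param genome_size_bp Haploid genome size in base pairs (default 2.7e9,
#'   mouse).
#' @param bp_mass Average mass of a DNA base pair in g/mol (default
#'   615.8771).
#' @return Tibble with `copies` (per cell) and `rank` (1 = most abundant)
#'   appended.
#' @export
proteomic_ruler_copies <- function(proteins, histones,
                                   ploidy = 2, genome_size_bp = 2.7e9,
                                   bp_mass = 615.8771) {
  stopifnot(is.data.frame(proteins),
            all(c("protein", "intensity", "mw") %in% names(proteins)))
  if (length(histones) == 0 || !any(histones %in% proteins$protein)) {
    stop("histone accessions missing from the protein table", call. = FALSE)
  }
  if (any(proteins$mw <= 0)) stop("molecular weights must be > 0", call. = FALSE)
  hist_sum <- sum(proteins$intensity[proteins$protein %in% histones])
  if (hist_sum <= 0) stop("histone intensities sum to 0", call. = FALSE)
  # N_A cancels between m_DNA and the copies formula
  dna_mass_mol <- ploidy * genome_size_bp * bp_mass   # grams per cell * N_A
  proteins$copies <- proteins$intensity * dna_mass_mol / (proteins$mw * hist_sum)
  ord <- order(-proteins$copies, proteins$protein)
  proteins$rank <- integer(nrow(proteins))
  proteins$rank[ord] <- seq_len(nrow(proteins))
  dplyr::arrange(proteins, .data$rank)
}

# channel columns: explicit, else all numeric columns
.channel_cols <- function(m, channels) {
  if (!is.null(channels)) {
    missing_cols <- setdiff(channels, names(m))
    if (length(missing_cols) > 0) {
      stop("unknown channel column(s): ", paste(missing_cols, collapse = ", "),
           call. = FALSE)
    }
    return(channels)
  }
  names(m)[vapply(m, is.numeric, logical(1))]
}
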