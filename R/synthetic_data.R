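#' Configuration for a synthetic diGLY TMT experiment
#'
#' Validates and assembles the parameters of the simulated 11-plex TMT-MS3
#' diGLY design: per-channel treatment (untreated / depolarized / spare) and
#' genotype labels, protein and site counts, the fraction of sites carrying
#' a planted depolarization response and the log2 effect range, the fraction
#' of responsive sites silenced in knockout channels, multiplicative
#' log-normal reporter noise, decoy and histone content for target-decoy FDR
#' and the proteomic ruler, and the genome parameters the ruler needs.
#'
#' @param n_channels Number of TMT channels (default 11).
#' @param treatment Per-channel condition labels; default 5 untreated
#'   (`"UT"`), 5 depolarized (`"AO"`), 1 spare.
#' @param genotype Per-channel genotype labels (`"WT"`/`"KO"`); default all
#'   wild type.
#' @param n_proteins,n_sites Number of simulated proteins and diGLY sites.
#' @param fraction_responsive Fraction of sites with a planted up-regulation
#'   on depolarized channels.
#' @param effect_log2_range Interval the planted log2 effects are drawn
#'   from (default `c(1, 3)`, i.e. 2- to 8-fold).
#' @param fraction_genotype_dependent Fraction of responsive sites whose
#'   effect is abolished (multiplier 1) in KO channels, mirroring loss of
#'   the kinase that licenses the response.
#' @param reporter_cv Coefficient of variation of the multiplicative
#'   log-normal reporter noise.
#' @param decoy_fraction Decoy PSMs as a fraction of target PSMs.
#' @param histone_count Number of histone proteins included for the ruler.
#' @param ploidy,genome_size_bp Genome copies per cell and haploid genome
#'   size (mouse defaults 2 and 2.7e9).
#' @param seed Integer seed; identical config and seed give byte-identical
#'   outputs.
#' @return Validated list of class `sim_config`.
#' @export
sim_config <- function(n_channels = 11,
                       treatment = c(rep("UT", 5), rep("AO", 5), "spare"),
                       genotype = rep("WT", n_channels),
                       n_proteins = 200,
                       n_sites = 400,
                       fraction_responsive = 0.1,
                       effect_log2_range = c(1, 3),
                       fraction_genotype_dependent = 0.9,
                       reporter_cv = 0.1,
                       decoy_fraction = 0.1,
                       histone_count = 5,
                       ploidy = 2,
                       genome_size_bp = 2.7e9,
                       seed = 1L) {
  chk <- function(ok, field, why) {
    if (!ok) stop("invalid `", field, "`: ", why, call. = FALSE)
  }
  chk(is.numeric(n_channels) && n_channels >= 2, "n_channels", "must be >= 2")
  chk(length(treatment) == n_channels, "treatment",
      "must have one label per channel")
  chk(length(genotype) == n_channels, "genotype",
      "must have one label per channel")
  for (f in c("fraction_responsive", "fraction_genotype_dependent",
              "decoy_fraction")) {
    v <- get(f)
    chk(is.numeric(v) && v >= 0 && v <= 1, f, "must lie in [0, 1]")
  }
  chk(length(effect_log2_range) == 2 && effect_log2_range[1] >= 0 &&
        diff(effect_log2_range) >= 0, "effect_log2_range",
      "must be an interval with lower bound >= 0")
  chk(reporter_cv >= 0, "reporter_cv", "must be >= 0")
  chk(n_proteins >= 1, "n_proteins", "must be >= 1")
  chk(n_sites >= 1, "n_sites", "must be >= 1")
  chk(histone_count >= 1, "histone_count", "must be >= 1")
  chk(ploidy >= 1, "ploidy", "must be >= 1")
  chk(genome_size_bp > 0, "genome_size_bp", "must be > 0")
  chk(is.numeric(seed) && length(seed) == 1, "seed", "must be a single integer")
  structure(
    list(n_channels = as.integer(n_channels), treatment = treatment,
         genotype = genotype, n_proteins = as.integer(n_proteins),
         n_sites = as.integer(n_sites),
         fraction_responsive = fraction_responsive,
         effect_log2_range = effect_log2_range,
         fraction_genotype_dependent = fraction_genotype_dependent,
         reporter_cv = reporter_cv, decoy_fraction = decoy_fraction,
         histone_count = as.integer(histone_count), ploidy = ploidy,
         genome_size_bp = genome_size_bp, seed = as.integer(seed)),
    class = "sim_config"
  )
}

.AA20 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

.random_protein <- function(len, min_k = 3) {
  aa <- sample(.AA20, len, replace = TRUE, prob = ifelse(.AA20 == "K", 3, 1))
  if (sum(aa == "K") < min_k) {
    aa[sample(which(aa != "K"), min_k - sum(aa == "K"))] <- "K"
  }
  paste(aa, collapse = "")
}

#' Simulate a full diGLY TMT-MS3 experiment with planted ground truth
#'
#' Generates every table the pipeline consumes: a PSM table (targets and
#' decoys, reporter signal-to-noise per channel, isolation specificity drawn
#' from a mixture so roughly 5-10% fall below 0.7, MS1 intensity
#' proportional to summed channel abundance, charge states, localization
#' scores), a total-proteome protein table whose summed intensities are
#' consistent with the planted copy numbers (histones included so the
#' proteomic ruler is exact in the noise-free direction), a MitoCarta-style
#' annotation table, and the ground truth. Responsive sites carry
#' multiplicative `2^effect` up-regulation on depolarized channels, silenced
#' in KO channels when genotype-dependent, and their proteins are placed on
#' the outer membrane (MOM) in the annotation.
#'
#' @param config A [sim_config()].
#' @return List of class `digly_sim` with elements `psms`, `proteins`,
#'   `annotation`, `channels` (channel metadata tibble) and `truth` (list of
#'   `sites`, `proteins`, the `config`).
#' @export
simulate_experiment <- function(config) {
  if (!inherits(config, "sim_config")) {
    stop("`config` must be created by sim_config()", call. = FALSE)
  }
  withr::with_seed(config$seed, .simulate_experiment_impl(config))
}

.simulate_experiment_impl <- function(cfg) {
  nch <- cfg$n_channels
  sn_cols <- paste0("sn_", seq_len(nch))
  sdlog <- sqrt(log(1 + cfg$reporter_cv^2))

  ## proteins: ordinary + histones
  n_ord <- cfg$n_proteins
  ordinary <- tibble::tibble(
    protein = sprintf("P%04d", seq_len(n_ord)),
    gene = sprintf("Gene%d", seq_len(n_ord)),
    sequence = vapply(pmax(80, stats::rpois(n_ord, 220)), .random_protein,
                      character(1)),
    copies = stats::rlnorm(n_ord, meanlog = log(2e5), sdlog = 1.6)
  )
  ordinary$mw <- protein_molecular_weight(ordinary$sequence)

  # histone copies chosen so total histone mass equals DNA mass (the ruler's
  # anchoring assumption), making noise-free copy recovery exact
  nh <- cfg$histone_count
  hist_mw <- stats::runif(nh, 11000, 22000)
  share <- stats::runif(nh, 0.5, 1.5); share <- share / sum(share)
  dna_mass_mol <- cfg$ploidy * cfg$genome_size_bp * 615.8771
  histones <- tibble::tibble(
    protein = sprintf("HIST%d", seq_len(nh)),
    gene = sprintf("H2bc%d", seq_len(nh)),
    sequence = vapply(rep(130, nh), .random_protein, character(1)),
    copies = share * dna_mass_mol / hist_mw,
    mw = hist_mw
  )
  proteins <- dplyr::bind_rows(ordinary, histones)
  intensity_scale <- 1e-6
  proteins$intensity <- proteins$copies * proteins$mw * intensity_scale

  # total-proteome reporter channels: abundance-proportional, proteome flat
  # across treatment (depolarization leaves the proteome largely unchanged)
  pbase <- proteins$copies / stats::median(proteins$copies) * 100
  pnoise <- matrix(stats::rlnorm(nrow(proteins) * nch, -sdlog^2 / 2, sdlog),
                   nrow(proteins), nch)
  pmat <- pbase * pnoise
  proteins[sn_cols] <- pmat

  ## sites
  prot_idx <- sample(n_ord, cfg$n_sites, replace = TRUE)
  pos <- vapply(prot_idx, function(i) {
    ks <- which(strsplit(ordinary$sequence[i], "")[[1]] == "K")
    as.integer(sample(rep(ks, 2), 1))   # rep() guards length-1 sampling
  }, integer(1))
  sites <- tibble::tibble(protein = ordinary$protein[prot_idx],
                          gene = ordinary$gene[prot_idx],
                          position = pos) |>
    dplyr::distinct(.data$protein, .data$position, .keep_all = TRUE)
  ns <- nrow(sites)
  sites$site_id <- paste0(sites$protein, "_K", sites$position)
  sites$base <- stats::rlnorm(ns, meanlog = log(80), sdlog = 0.9)

  n_resp <- round(cfg$fraction_responsive * ns)
  responsive <- rep(FALSE, ns); responsive[seq_len(n_resp)] <- TRUE
  responsive <- sample(responsive)
  effect <- ifelse(responsive,
                   stats::runif(ns, cfg$effect_log2_range[1],
                                cfg$effect_log2_range[2]), 0)
  n_dep <- round(cfg$fraction_genotype_dependent * n_resp)
  dep <- rep(FALSE, ns)
  resp_idx <- which(responsive)
  if (n_dep > 0) dep[resp_idx[seq_len(n_dep)]] <- TRUE
  sites$responsive <- responsive
  sites$log2_effect <- effect
  sites$genotype_dependent <- dep

  # channel multipliers: effect on AO channels, silenced in KO when dependent
  mult <- matrix(1, ns, nch)
  ao <- cfg$treatment == "AO"
  for (c in which(ao)) {
    silenced <- dep & cfg$genotype[c] == "KO"
    mult[, c] <- ifelse(silenced, 1, 2^effect)
  }

  ## annotation: responsive sites' proteins are MOM; others mixed
  mom_genes <- unique(sites$gene[responsive])
  other <- setdiff(ordinary$gene, mom_genes)
  n_mito_extra <- round(0.25 * length(other))
  mito_extra <- sample(other, n_mito_extra)
  sub_lab <- sample(c("MOM", "MIM", "Matrix", "IMS", "Membrane", "unknown"),
                    n_mito_extra, replace = TRUE,
                    prob = c(25, 30, 20, 5, 10, 10))
  annotation <- tibble::tibble(
    gene = c(ordinary$gene, histones$gene),
    mito = c(ordinary$gene %in% c(mom_genes, mito_extra), rep(FALSE, nh)),
    subcompartment = NA_character_
  )
  annotation$subcompartment[match(mom_genes, annotation$gene)] <- "MOM"
  annotation$subcompartment[match(mito_extra, annotation$gene)] <- sub_lab

  ## target PSMs
  n_psms <- 1L + stats::rpois(ns, 0.6)
  psm_site <- rep(seq_len(ns), n_psms)
  npsm <- length(psm_site)
  seqs <- stats::setNames(ordinary$sequence, ordinary$protein)
  lens <- nchar(seqs[sites$protein[psm_site]])
  start <- pmax(1L, sites$position[psm_site] - sample(5:10, npsm, replace = TRUE))
  end <- pmin(lens, sites$position[psm_site] + sample(5:10, npsm, replace = TRUE))
  peptide <- substr(seqs[sites$protein[psm_site]], start, end)

  base_pp <- sites$base[psm_site] / n_psms[psm_site]
  noise <- matrix(stats::rlnorm(npsm * nch, -sdlog^2 / 2, sdlog), npsm, nch)
  snmat <- base_pp * mult[psm_site, , drop = FALSE] * noise

  targets <- tibble::tibble(
    peptide = peptide,
    protein = sites$protein[psm_site],
    gene = sites$gene[psm_site],
    mod_position = as.integer(sites$position[psm_site] - start + 1L),
    charge = sample(2:6, npsm, replace = TRUE,
                    prob = c(0.05, 0.40, 0.33, 0.15, 0.07)),
    score = stats::rnorm(npsm, 4, 1.1),
    is_decoy = FALSE,
    isolation_specificity = ifelse(stats::runif(npsm) < 0.075,
                                   stats::runif(npsm, 0.3, 0.699),
                                   stats::runif(npsm, 0.72, 1.0)),
    has_ms3 = stats::runif(npsm) < 0.97,
    ascore = ifelse(stats::runif(npsm) < 0.9,
                    stats::runif(npsm, 14, 60), stats::runif(npsm, 0, 12.9))
  )
  targets[sn_cols] <- snmat
  targets$summed_sn <- rowSums(snmat)
  targets$ms1_intensity <- targets$summed_sn * 5e4 *
    stats::rlnorm(npsm, -sdlog^2 / 2, sdlog)

  ## decoys: reversed-sequence style records with a shifted score null
  nd <- round(cfg$decoy_fraction * npsm)
  if (nd > 0) {
    dsn <- matrix(stats::rlnorm(nd * nch, log(20), sdlog), nd, nch)
    decoys <- tibble::tibble(
      peptide = vapply(rep(12, nd), .random_protein, character(1), min_k = 1),
      protein = sprintf("DECOY_P%04d", seq_len(nd)),
      gene = NA_character_,
      mod_position = 1L,
      charge = sample(3:5, nd, replace = TRUE),
      score = stats::rnorm(nd, 1, 1),
      is_decoy = TRUE,
      isolation_specificity = stats::runif(nd, 0.72, 1.0),
      has_ms3 = TRUE,
      ascore = stats::runif(nd, 0, 40)
    )
    decoys[sn_cols] <- dsn
    decoys$summed_sn <- rowSums(dsn)
    decoys$ms1_intensity <- decoys$summed_sn * 5e4
    psms <- dplyr::bind_rows(targets, decoys)
  } else {
    psms <- targets
  }
  psms <- psms[sample(nrow(psms)), , drop = FALSE]

  channels <- tibble::tibble(
    channel = sn_cols,
    treatment = cfg$treatment,
    genotype = cfg$genotype
  )

  truth <- list(
    sites = sites[c("site_id", "protein", "gene", "position", "responsive",
                    "log2_effect", "genotype_dependent", "base")],
    proteins = proteins[c("protein", "gene", "copies", "mw")],
    config = cfg
  )
  structure(list(psms = psms, proteins = proteins, annotation = annotation,
                 channels = channels, truth = truth),
            class = "digly_sim")
}

#' @export
print.digly_sim <- function(x, ...) {
  cat("Synthetic diGLY TMT experiment: ", nrow(x$psms), " PSMs (",
      sum(x$psms$is_decoy), " decoys), ", nrow(x$truth$sites), " sites, ",
      nrow(x$proteins), " proteins, ", nrow(x$channels), " channels\n",
      sep = "")
  invisible(x)
}

#' Simulate an ortholog sequence pair with known site correspondence
#'
#' Builds a random protein of the requested length with lysines fixed at
#' `conserved_k_positions`, then derives an ortholog by substituting
#' non-conserved residues at rate `1 - identity` and applying short indels.
#' The residue correspondence actually used in generation is returned so
#' alignment-based site mapping can be scored against truth.
#'
#' @param length Sequence length of the source protein (residues).
#' @param identity Target sequence identity in (0, 1]; 1 gives identical
#'   sequences and the identity mapping.
#' @param conserved_k_positions Integer positions forced to lysine in both
#'   sequences and exempt from mutation.
#' @param seed Integer seed.
#' @param insertions Optional tibble (`after`, `length`): insertions into
#'   the ortholog after the given source positions. Default: random short
#'   insertions scaled with divergence.
#' @param deletions Optional integer vector of source positions deleted in
#'   the ortholog. Default: random, scaled with divergence.
#' @return List with `seq_a`, `seq_b`, `mapping` (tibble `pos_a`, `pos_b`
#'   for positions present in both) and `conserved_k_positions`.
#' @export
simulate_ortholog_pair <- function(length, identity, conserved_k_positions = integer(),
                                   seed = 1L, insertions = NULL, deletions = NULL) {
  if (!(identity > 0 && identity <= 1)) {
    stop("`identity` must lie in (0, 1]", call. = FALSE)
  }
  if (any(conserved_k_positions < 1 | conserved_k_positions > length)) {
    stop("conserved position outside sequence; not representable", call. = FALSE)
  }
  withr::with_seed(seed, {
    aa <- sample(.AA20, length, replace = TRUE)
    aa[conserved_k_positions] <- "K"
    mutable <- setdiff(seq_len(length), conserved_k_positions)

    bb <- aa
    if (identity < 1) {
      sub_at <- mutable[stats::runif(base::length(mutable)) < (1 - identity)]
      bb[sub_at] <- vapply(bb[sub_at], function(r) {
        sample(setdiff(.AA20, c(r, "K")), 1)
      }, character(1))
    }

    if (is.null(deletions)) {
      n_del <- if (identity < 1) max(0L, round(length * (1 - identity) * 0.03)) else 0L
      deletions <- if (n_del > 0) sample(mutable, n_del) else integer()
    }
    if (any(deletions %in% conserved_k_positions)) {
      stop("cannot delete a conserved position; not representable", call. = FALSE)
    }
    if (is.null(insertions)) {
      n_ins <- if (identity < 1) max(0L, round(length * (1 - identity) * 0.03)) else 0L
      insertions <- tibble::tibble(
        after = if (n_ins > 0) sort(sample(seq_len(length - 1), n_ins)) else integer(),
        length = if (n_ins > 0) sample(1:3, n_ins, replace = TRUE) else integer()
      )
    }

    # assemble b and the position mapping
    seq_b_parts <- character(0)
    pos_b <- rep(NA_integer_, length)
    cursor <- 0L
    for (i in seq_len(length)) {
      if (!(i %in% deletions)) {
        cursor <- cursor + 1L
        pos_b[i] <- cursor
        seq_b_parts <- c(seq_b_parts, bb[i])
      }
      ins_here <- insertions$length[insertions$after == i]
      if (base::length(ins_here) > 0) {
        nins <- sum(ins_here)
        seq_b_parts <- c(seq_b_parts,
                         sample(setdiff(.AA20, "K"), nins, replace = TRUE))
        cursor <- cursor + nins
      }
    }
    list(
      seq_a = paste(aa, collapse = ""),
      seq_b = paste(seq_b_parts, collapse = ""),
      mapping = tibble::tibble(pos_a = which(!is.na(pos_b)),
                               pos_b = pos_b[!is.na(pos_b)]),
      conserved_k_positions = as.integer(conserved_k_positions)
    )
  })
}

#' Simulate an AQUA/PRM measurement table
#'
#' Generates light/heavy area pairs for ubiquitin chain-linkage peptides,
#' total-ubiquitin locus peptides and the phospho-Ser65 / unmodified Ser65
#' pair, with planted absolute amounts and phospho stoichiometry. Light
#' area equals heavy area times `true_fmol / spike` times multiplicative
#' log-normal noise; `noise_cv = 0` makes quantification exact.
#'
#' @param true_fmol_by_linkage Named numeric vector of planted chain-linkage
#'   amounts (fmol), e.g. `c(K6 = 1, K11 = 2, K48 = 40, K63 = 60)`.
#' @param true_phospho_fraction Planted phospho-Ser65 stoichiometry in
#'   `[0, 1]`.
#' @param heavy_spike_fmol Heavy reference spike per peptide (fmol, > 0).
#' @param noise_cv Coefficient of variation of the area noise.
#' @param seed Integer seed.
#' @param total_ub_fmol Planted total ubiquitin (default: sum of the linkage
#'   amounts).
#' @param n_replicates Replicates per condition (default 3).
#' @param condition Condition label attached to all rows.
#' @param n_total_loci Number of total-ubiquitin locus peptides (default 4).
#' @return Tibble with columns `peptide`, `locus`, `light_area`,
#'   `heavy_area`, `spike_fmol`, `replicate`, `condition`.
#' @export
simulate_aqua <- function(true_fmol_by_linkage, true_phospho_fraction,
                          heavy_spike_fmol = 100, noise_cv = 0.05, seed = 1L,
                          total_ub_fmol = NULL, n_replicates = 3,
                          condition = "treated", n_total_loci = 4) {
  if (any(true_fmol_by_linkage < 0)) stop("fmol amounts must be >= 0", call. = FALSE)
  if (true_phospho_fraction < 0 || true_phospho_fraction > 1) {
    stop("`true_phospho_fraction` must lie in [0, 1]", call. = FALSE)
  }
  if (heavy_spike_fmol <= 0) stop("spike must be > 0", call. = FALSE)
  if (is.null(total_ub_fmol)) total_ub_fmol <- sum(true_fmol_by_linkage)

  loci <- c(names(true_fmol_by_linkage),
            paste0("total_", seq_len(n_total_loci)),
            "Ser65_phospho", "Ser65_unmodified")
  truth <- c(unname(true_fmol_by_linkage),
             rep(total_ub_fmol, n_total_loci),
             true_phospho_fraction * total_ub_fmol,
             (1 - true_phospho_fraction) * total_ub_fmol)

  withr::with_seed(seed, {
    heavy <- stats::rlnorm(length(loci), log(1e7), 0.3)
    sdlog <- if (noise_cv > 0) sqrt(log(1 + noise_cv^2)) else 0
    out <- purrr::map_dfr(seq_len(n_replicates), function(r) {
      noise <- if (sdlog > 0) {
        stats::rlnorm(length(loci), -sdlog^2 / 2, sdlog)
      } else rep(1, length(loci))
      tibble::tibble(
        peptide = paste0("pep_", loci),
        locus = loci,
        light_area = heavy * (truth / heavy_spike_fmol) * noise,
        heavy_area = heavy,
        spike_fmol = heavy_spike_fmol,
        replicate = r,
        condition = condition
      )
    })
    out
  })
}
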