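#' Welch's two-sample t statistic
#'
#' Unequal-variance t test on log-scale values:
#' `t = (mean(x) - mean(y)) / sqrt(var(x)/n1 + var(y)/n2)` with
#' Welch-Satterthwaite degrees of freedom and a two-sided p value.
#'
#' @param x,y Numeric vectors of log-scale values, each with at least two
#'   finite entries.
#' @return Tibble with columns `estimate` (mean difference), `t`, `df`, `p`.
#' @export
welch_statistic <- function(x, y) {
  x <- x[is.finite(x)]; y <- y[is.finite(y)]
  if (length(x) < 2 || length(y) < 2) {
    stop("each group needs at least 2 finite values", call. = FALSE)
  }
  v1 <- stats::var(x) / length(x)
  v2 <- stats::var(y) / length(y)
  se <- sqrt(v1 + v2)
  t <- (mean(x) - mean(y)) / se
  df <- (v1 + v2)^2 / (v1^2 / (length(x) - 1) + v2^2 / (length(y) - 1))
  tibble::tibble(estimate = mean(x) - mean(y), t = t, df = df,
                 p = 2 * stats::pt(-abs(t), df))
}

#' S0-modified Welch statistic
#'
#' The significance-analysis variant of the Welch statistic with a fudge
#' constant added to the standard error,
#' `d = (mean(x) - mean(y)) / (se_Welch + s0)`, which damps the significance
#' of features whose fold change is small even when their variance is tiny.
#' `s0 = 0` recovers the ordinary Welch t.
#'
#' @inheritParams welch_statistic
#' @param s0 Nonnegative fudge constant (the study uses 2 for diGLY site
#'   volcanoes, 1 for the genotype comparison and 0.585 for the proteome).
#' @return The modified statistic `d` (double scalar).
#' @export
s0_statistic <- function(x, y, s0) {
  stopifnot(s0 >= 0)
  x <- x[is.finite(x)]; y <- y[is.finite(y)]
  if (length(x) < 2 || length(y) < 2) {
    stop("each group needs at least 2 finite values", call. = FALSE)
  }
  se <- sqrt(stats::var(x) / length(x) + stats::var(y) / length(y))
  (mean(x) - mean(y)) / (se + s0)
}

# rowwise d statistics for a features x samples matrix
.row_d <- function(mat, idx1, idx2, s0) {
  n1 <- length(idx1); n2 <- length(idx2)
  m1 <- rowMeans(mat[, idx1, drop = FALSE])
  m2 <- rowMeans(mat[, idx2, drop = FALSE])
  v1 <- rowSums((mat[, idx1, drop = FALSE] - m1)^2) / (n1 - 1)
  v2 <- rowSums((mat[, idx2, drop = FALSE] - m2)^2) / (n2 - 1)
  se <- sqrt(v1 / n1 + v2 / n2)
  list(diff = m1 - m2, se = se, d = (m1 - m2) / (se + s0))
}

#' Permutation-based FDR for the S0-modified Welch statistic
#'
#' Computes the observed modified statistic per feature, rebuilds its null
#' distribution by permuting the sample labels (the same permutation applied
#' to all features, preserving feature correlation), and for each candidate
#' threshold `tau` estimates
#' `FDR(tau) = mean_perm #\{|d_null| >= tau\} / max(1, #\{|d_obs| >= tau\})`.
#' A feature's q value is the minimum FDR estimate over thresholds at or
#' below its own `|d|`; the significant set (q <= level) is therefore the
#' largest downward-closed set in `|d|` meeting the level. All distinct
#' group-label assignments are enumerated when there are at most
#' `n_permutations` of them, otherwise `n_permutations` are sampled using
#' `seed`.
#'
#' @param data Tibble with a feature identifier column plus numeric sample
#'   columns, or a numeric matrix with rownames.
#' @param groups Character/factor vector assigning each sample column to one
#'   of two groups, in column order.
#' @param s0 Fudge constant (see [s0_statistic()]).
#' @param fdr_level FDR level, e.g. 0.01.
#' @param n_permutations Maximum number of label permutations (default 250).
#' @param seed Integer seed for permutation sampling.
#' @param id Name of the identifier column when `data` is a data frame
#'   (default: first non-numeric column, or rownames of a matrix).
#' @return Object of class `perm_fdr`. Its [generics::tidy()] method returns
#'   one row per feature: `feature`, `log2fc` (group1 minus group2 mean),
#'   `d`, `q`, `significant`, `direction`; [generics::glance()] summarizes
#'   the run.
#' @export
permutation_fdr <- function(data, groups, s0 = 2, fdr_level = 0.01,
                            n_permutations = 250, seed = 1L, id = NULL) {
  prep <- .as_feature_matrix(data, id)
  mat <- prep$mat
  lv <- if (is.factor(groups)) levels(groups) else unique(as.character(groups))
  groups <- as.character(groups)
  if (length(groups) != ncol(mat)) {
    stop("`groups` must have one label per sample column", call. = FALSE)
  }
  if (length(lv) != 2) stop("exactly two groups are required", call. = FALSE)
  idx1 <- which(groups == lv[1]); idx2 <- which(groups == lv[2])
  if (length(idx1) < 2 || length(idx2) < 2) {
    stop("each group needs at least 2 samples", call. = FALSE)
  }
  stopifnot(s0 >= 0, fdr_level > 0, fdr_level < 1, n_permutations >= 1)

  obs <- .row_d(mat, idx1, idx2, s0)

  n <- ncol(mat); n1 <- length(idx1)
  n_distinct <- choose(n1 + length(idx2), n1)
  if (n_distinct < 2) stop("fewer than 2 distinct permutations", call. = FALSE)
  cols <- c(idx1, idx2)
  if (n_distinct <= n_permutations) {
    assignments <- utils::combn(seq_along(cols), n1, simplify = FALSE)
  } else if (n_distinct <= 1e5) {
    # sample distinct relabelings, excluding the observed labeling and (for
    # equal group sizes) its mirror, which are not null relabelings
    all_asn <- utils::combn(seq_along(cols), n1, simplify = FALSE)
    obs_key <- paste(seq_len(n1), collapse = ",")
    mirror_key <- paste((n1 + 1):length(cols), collapse = ",")
    keys <- vapply(all_asn, paste, character(1), collapse = ",")
    all_asn <- all_asn[!keys %in% c(obs_key, mirror_key)]
    assignments <- withr::with_seed(
      seed, all_asn[sample(length(all_asn), min(n_permutations, length(all_asn)))])
  } else {
    assignments <- withr::with_seed(seed, replicate(
      n_permutations, sample(seq_along(cols), n1), simplify = FALSE))
  }

  null_abs <- unlist(lapply(assignments, function(a) {
    g1 <- cols[a]; g2 <- cols[-a]
    abs(.row_d(mat, g1, g2, s0)$d)
  }))
  n_perm <- length(assignments)

  # FDR at each observed |d| as candidate threshold, descending
  ord <- order(-abs(obs$d))
  taus <- abs(obs$d)[ord]
  null_sorted <- sort(null_abs)
  n_null_ge <- length(null_sorted) -
    findInterval(taus - 1e-12, null_sorted)  # count null values >= tau
  enumerated <- n_distinct <= n_permutations
  # sampled permutations: add-one correction so the null exceedance rate is
  # never estimated as exactly zero (enumeration already contains the
  # observed labeling)
  mean_null <- if (enumerated) n_null_ge / n_perm else
    (1 + n_null_ge) / (n_perm + 1)
  fdr_at <- pmin(1, mean_null / pmax(1, seq_along(taus)))
  # q for the k-th ranked feature: min FDR over thresholds <= its |d|
  q_sorted <- rev(cummin(rev(fdr_at)))
  q <- numeric(length(taus)); q[ord] <- q_sorted

  res <- tibble::tibble(
    feature = prep$ids,
    log2fc = obs$diff,
    welch_t = obs$diff / obs$se,
    d = obs$d,
    q = q,
    significant = q <= fdr_level,
    direction = dplyr::if_else(obs$diff >= 0, "up", "down")
  )
  structure(
    list(result = res, s0 = s0, fdr_level = fdr_level,
         n_permutations = n_perm, enumerated = enumerated,
         groups = stats::setNames(c(lv[1], lv[2]), c("group1", "group2")),
         seed = seed),
    class = "perm_fdr"
  )
}

#' @export
print.perm_fdr <- function(x, ...) {
  g <- glance(x)
  cat("Permutation FDR (S0 = ", x$s0, ", level = ", x$fdr_level, ", ",
      x$n_permutations, if (x$enumerated) " enumerated" else " sampled",
      " permutations)\n", sep = "")
  cat(g$n_features, " features: ", g$n_up, " up, ", g$n_down,
      " down at q <= ", x$fdr_level, "\n", sep = "")
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @export
tidy.perm_fdr <- function(x, ...) x$result

#' @export
glance.perm_fdr <- function(x, ...) {
  tibble::tibble(
    n_features = nrow(x$result),
    n_significant = sum(x$result$significant),
    n_up = sum(x$result$significant & x$result$direction == "up"),
    n_down = sum(x$result$significant & x$result$direction == "down"),
    s0 = x$s0, fdr_level = x$fdr_level, n_permutations = x$n_permutations
  )
}

#' Moderated t statistics with empirical-Bayes variance shrinkage
#'
#' The limma route used for the searchable result tables: per-feature linear
#' model on log ratios, residual variances shrunk toward a common prior by
#' empirical Bayes (`s2_post = (d0 * s0^2 + d_g * s_g^2) / (d0 + d_g)`),
#' moderated t on `d0 + d_g` degrees of freedom, two-sided p values, and
#' Benjamini-Hochberg adjustment.
#'
#' @inheritParams permutation_fdr
#' @return Tibble with `feature`, `log2fc`, `t`, `df`, `p`, `p_adj`, plus
#'   attributes `"d0"` and `"s0_sq"` (the estimated prior).
#' @export
moderated_t <- function(data, groups, id = NULL) {
  prep <- .as_feature_matrix(data, id)
  mat <- prep$mat
  lv <- if (is.factor(groups)) levels(groups) else unique(as.character(groups))
  groups <- as.character(groups)
  if (length(lv) != 2) stop("exactly two groups are required", call. = FALSE)
  design <- cbind(intercept = 1, diff = as.integer(groups == lv[1]))
  fit <- limma::eBayes(limma::lmFit(mat, design))
  out <- tibble::tibble(
    feature = prep$ids,
    log2fc = unname(fit$coefficients[, "diff"]),
    t = unname(fit$t[, "diff"]),
    df = unname(fit$df.total),
    p = unname(fit$p.value[, "diff"]),
    p_adj = unname(benjamini_hochberg(fit$p.value[, "diff"]))
  )
  attr(out, "d0") <- fit$df.prior
  attr(out, "s0_sq") <- fit$s2.prior
  out
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up adjusted p values with monotonicity enforcement; inputs outside
#' `[0, 1]` are an error rather than silently clamped.
#'
#' @param p Numeric vector of raw p values.
#' @return Adjusted p values, same length and order.
#' @export
benjamini_hochberg <- function(p) {
  if (any(!is.na(p) & (p < 0 | p > 1))) {
    stop("p values must lie in [0, 1]", call. = FALSE)
  }
  stats::p.adjust(p, method = "BH")
}

# data frame (id column + numeric sample columns) or matrix -> matrix + ids
.as_feature_matrix <- function(data, id = NULL) {
  if (is.matrix(data)) {
    ids <- rownames(data)
    if (is.null(ids)) ids <- as.character(seq_len(nrow(data)))
    return(list(mat = data, ids = ids))
  }
  stopifnot(is.data.frame(data))
  if (is.null(id)) {
    non_num <- names(data)[!vapply(data, is.numeric, logical(1))]
    id <- if (length(non_num) > 0) non_num[1] else NULL
  }
  num_cols <- setdiff(names(data)[vapply(data, is.numeric, logical(1))], id)
  mat <- as.matrix(data[num_cols])
  ids <- if (!is.null(id)) as.character(data[[id]]) else as.character(seq_len(nrow(data)))
  list(mat = mat, ids = ids)
}
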