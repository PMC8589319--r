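# Independent brute-force oracles used to validate the implementation paths.

# Exhaustive recursion over every global alignment path (no DP memoization):
# affine gap cost open + extend per gap residue, substitution via `submat`.
bf_align_score <- function(a, b, submat, open = 11, ext = 1) {
  ca <- strsplit(a, "")[[1]]
  cb <- strsplit(b, "")[[1]]
  rec <- function(i, j, prev) {
    if (i > length(ca) && j > length(cb)) return(0)
    best <- -Inf
    if (i <= length(ca) && j <= length(cb)) {
      best <- max(best, submat[ca[i], cb[j]] + rec(i + 1, j + 1, "M"))
    }
    if (i <= length(ca)) {  # gap in b
      cost <- ext + if (prev != "D") open else 0
      best <- max(best, -cost + rec(i + 1, j, "D"))
    }
    if (j <= length(cb)) {  # gap in a
      cost <- ext + if (prev != "I") open else 0
      best <- max(best, -cost + rec(i, j + 1, "I"))
    }
    best
  }
  rec(1, 1, "M")
}

# Explicit binomial upper-tail sum P(X >= k), X ~ Binomial(n, p)
bf_binom_tail <- function(n, k, p) {
  if (k <= 0) return(1)
  sum(vapply(k:n, function(i) choose(n, i) * p^i * (1 - p)^(n - i),
             numeric(1)))
}

# Exhaustive target-decoy cutoff search: evaluate the FDR at every prefix of
# the score-sorted list and return the kept target scores of the largest
# prefix meeting the level (whole tied-score blocks kept together).
bf_td_kept_targets <- function(score, is_decoy, level) {
  ord <- order(score, decreasing = TRUE)
  s <- score[ord]; d <- is_decoy[ord]
  n <- length(s)
  best_k <- 0
  for (k in seq_len(n)) {
    if (k < n && s[k + 1] == s[k]) next  # cutoffs are score values
    fdr <- sum(d[1:k]) / max(1, sum(!d[1:k]))
    if (fdr <= level) best_k <- k
  }
  if (best_k == 0) return(numeric(0))
  sort(s[1:best_k][!d[1:best_k]])
}

# Minimal protein set covering all peptides, by exhaustive subset search
bf_min_cover_size <- function(peptide_map) {
  prots <- unique(peptide_map$protein)
  peps <- unique(peptide_map$peptide)
  for (k in seq_along(prots)) {
    combs <- utils::combn(prots, k, simplify = FALSE)
    for (cc in combs) {
      covered <- unique(peptide_map$peptide[peptide_map$protein %in% cc])
      if (length(covered) == length(peps)) return(k)
    }
  }
  length(prots)
}

blosum62 <- local({
  env <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = env)
  m <- get("BLOSUM62", envir = env)
  m["X", ] <- 0L; m[, "X"] <- 0L
  m
})

random_aa <- function(n, alphabet = strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]) {
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}
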