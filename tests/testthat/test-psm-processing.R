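make_psm <- function(n = 1, ...) {
  base <- tibble::tibble(
    peptide = "AKGGR", protein = "P1", mod_position = 2L, charge = 3L,
    score = 5, is_decoy = FALSE, isolation_specificity = 0.9,
    summed_sn = 200, has_ms3 = TRUE, ascore = 30,
    ms1_intensity = 1e6, sn_1 = 100, sn_2 = 100
  )
  out <- base[rep(1, n), ]
  args <- list(...)
  for (nm in names(args)) out[[nm]] <- args[[nm]]
  out
}

test_that("each quality criterion excludes on strict less-than and keeps boundaries", {
  # boundary record passes: 0.70, 150, charge 3, MS3 present
  boundary <- make_psm(isolation_specificity = 0.70, summed_sn = 150, charge = 3L)
  expect_equal(nrow(filter_psms(boundary)$kept), 1)

  low_spec <- make_psm(isolation_specificity = 0.69)
  f <- filter_psms(low_spec)
  expect_equal(nrow(f$kept), 0)
  expect_equal(f$reasons$reason, "isolation_specificity")

  # six records: one per violated criterion (charge low/high separately),
  # plus one clean record
  fixture <- dplyr::bind_rows(
    make_psm(isolation_specificity = 0.5),
    make_psm(summed_sn = 149),
    make_psm(has_ms3 = FALSE),
    make_psm(charge = 2L),
    make_psm(charge = 7L),
    make_psm()
  )
  f <- filter_psms(fixture)
  expect_equal(nrow(f$kept), 1)
  expect_equal(sum(f$report$excluded[f$report$criterion == "total"]), 5)
  expect_setequal(f$reasons$reason[f$reasons$row %in% 1:3],
                  c("isolation_specificity", "summed_sn", "no_ms3"))
  expect_true(all(f$reasons$reason[f$reasons$row %in% 4:5] == "charge"))

  # outside diGLY mode the charge window does not apply
  expect_equal(nrow(filter_psms(make_psm(charge = 2L), digly = FALSE)$kept), 1)
})

test_that("filtering is idempotent and empty input yields a zero report", {
  set.seed(4)
  psms <- make_psm(50,
                   isolation_specificity = runif(50, 0.4, 1),
                   summed_sn = runif(50, 50, 400),
                   charge = sample(2:7, 50, replace = TRUE))
  once <- filter_psms(psms)$kept
  twice <- filter_psms(once)
  expect_identical(twice$kept, once)
  expect_equal(sum(twice$report$excluded), 0)

  f0 <- filter_psms(psms[0, ])
  expect_equal(nrow(f0$kept), 0)
  expect_true(all(f0$report$excluded == 0))
})

test_that("target-decoy thresholding matches exhaustive cutoff search", {
  # worked fixture: targets scored 10..1, decoys at 5.5 and 2.5
  psms <- tibble::tibble(
    score = c(10:1, 5.5, 2.5),
    is_decoy = c(rep(FALSE, 10), TRUE, TRUE),
    peptide = paste0("pep", 1:12), protein = paste0("prot", 1:12)
  )
  kept <- target_decoy_fdr(psms, level = 0.1)
  expect_equal(sort(kept$score), bf_td_kept_targets(psms$score, psms$is_decoy, 0.1))

  set.seed(11)
  for (i in 1:50) {
    n <- sample(5:40, 1)
    sc <- round(rnorm(n, 5, 2), 2)
    dec <- runif(n) < 0.3
    lvl <- sample(c(0.01, 0.05, 0.1, 0.3), 1)
    tbl <- tibble::tibble(score = sc, is_decoy = dec,
                          peptide = paste0("p", 1:n), protein = paste0("q", 1:n))
    kept <- target_decoy_fdr(tbl, level = lvl)
    expect_equal(sort(kept$score), bf_td_kept_targets(sc, dec, lvl),
                 info = paste("random list", i))
  }
})

test_that("target-decoy edge cases: all targets kept, level 0, maximality", {
  all_t <- tibble::tibble(score = 5:1, is_decoy = FALSE)
  expect_equal(nrow(target_decoy_fdr(all_t, 0.01)), 5)

  mixed <- tibble::tibble(score = c(9, 8, 7, 6, 5),
                          is_decoy = c(FALSE, FALSE, TRUE, FALSE, FALSE))
  k0 <- target_decoy_fdr(mixed, level = 0)
  expect_equal(sort(k0$score, decreasing = TRUE), c(9, 8))

  # estimated FDR at the chosen cutoff is within the level, and the kept set
  # agrees with the exhaustive search (which by construction is maximal)
  set.seed(3)
  dec <- runif(60) < 0.3
  sc <- rnorm(60, ifelse(dec, 0, 2))
  kept <- target_decoy_fdr(tibble::tibble(score = sc, is_decoy = dec), 0.2)
  expect_lte(attr(kept, "fdr_estimate"), 0.2)
  expect_equal(sort(kept$score), bf_td_kept_targets(sc, dec, 0.2))

  expect_equal(nrow(target_decoy_fdr(tibble::tibble(score = 1, is_decoy = TRUE), 0.5)), 0)
})

test_that("ascore equals the explicit binomial tail on a grid and at the anchor", {
  for (n in c(1, 3, 7, 12, 20)) {
    for (k in unique(c(0, 1, floor(n / 2), n))) {
      for (p in c(0.01, 0.05, 0.1, 0.25, 0.5)) {
        expect_equal(ascore(n, k, p), -10 * log10(bf_binom_tail(n, k, p)),
                     tolerance = 1e-10, info = paste(n, k, p))
      }
    }
  }
  # tail probability exactly 0.05 gives the 95%-confidence threshold of 13
  expect_equal(round(ascore(1, 1, 0.05), 1), 13.0)
  expect_equal(ascore(10, 0, 0.1), 0)
  expect_equal(ascore(10, 5, 0.1), -10 * log10(bf_binom_tail(10, 5, 0.1)))
})

test_that("ascore is monotone in k and p, and validates inputs", {
  ks <- 0:10
  sc_k <- ascore(10, ks, 0.1)
  expect_true(all(diff(sc_k) >= 0))
  ps <- c(0.05, 0.1, 0.2, 0.3, 0.5)
  sc_p <- vapply(ps, function(p) ascore(10, 6, p), numeric(1))
  expect_true(all(diff(sc_p) <= 0))
  expect_error(ascore(5, 6, 0.1), "k")
  expect_error(ascore(5, 2, 0), "p")
  expect_equal(ascore_site(10, 8, 10, 3, 0.1),
               ascore(10, 8, 0.1) - ascore(10, 3, 0.1))
})

test_that("parsimony grouping finds a minimal cover with razor assignment", {
  # unique peptides: one group per protein
  uniq <- tibble::tibble(peptide = c("p1", "p2"), protein = c("A", "B"))
  g <- parsimony_protein_groups(uniq)
  expect_setequal(unique(g$protein), c("A", "B"))
  expect_false(any(g$shared))

  # shared p2 goes to the first-selected group; cover is minimal
  pm <- tibble::tibble(peptide = c("p1", "p2", "p2", "p3"),
                       protein = c("A", "A", "B", "B"))
  g <- parsimony_protein_groups(pm)
  expect_equal(length(unique(g$protein)), bf_min_cover_size(pm))
  expect_true(g$shared[g$peptide == "p2"])

  expect_equal(nrow(parsimony_protein_groups(uniq[0, ])), 0)

  set.seed(21)
  for (i in 1:10) {
    np <- sample(4:8, 1)
    pm <- tibble::tibble(
      peptide = paste0("pep", sample(6, 14, replace = TRUE)),
      protein = paste0("pr", sample(np, 14, replace = TRUE))
    ) |> dplyr::distinct()
    g <- parsimony_protein_groups(pm)
    expect_setequal(g$peptide, unique(pm$peptide))
    expect_equal(anyDuplicated(g$peptide), 0)
    expect_equal(length(unique(g$protein)), bf_min_cover_size(pm),
                 info = paste("random cover", i))
  }
})

test_that("site aggregation sums supporting PSMs and maps to protein coordinates", {
  prot <- tibble::tibble(protein = "P1", sequence = "MAKVLKDEWKR")
  psms <- dplyr::bind_rows(
    make_psm(peptide = "AKVLK", mod_position = 2L, sn_1 = 10, sn_2 = 20),  # K3
    make_psm(peptide = "AKVLK", mod_position = 2L, sn_1 = 1,  sn_2 = 2),   # K3
    make_psm(peptide = "KDEWK", mod_position = 1L, sn_1 = 5,  sn_2 = 7)    # K6
  )
  s <- aggregate_to_sites(psms, prot)
  expect_equal(nrow(s), 2)
  k3 <- s[s$position == 3, ]
  expect_equal(c(k3$sn_1, k3$sn_2), c(11, 22))
  expect_equal(k3$n_psms, 2)
  expect_equal(k3$ms1_total, 2e6)
  k6 <- s[s$position == 6, ]
  expect_equal(c(k6$sn_1, k6$sn_2), c(5, 7))
  expect_true(all(s$residue == "K"))

  # ambiguous localization (ascore < 13) is excluded and flagged
  amb <- aggregate_to_sites(make_psm(peptide = "AKVLK", ascore = 5), prot)
  expect_equal(nrow(amb), 0)
  expect_equal(nrow(attr(amb, "ambiguous")), 1)

  expect_error(aggregate_to_sites(make_psm(peptide = "WWWW"), prot), "WWWW")
})
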