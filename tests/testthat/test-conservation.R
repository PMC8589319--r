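test_that("global alignment equals brute-force enumeration on short pairs", {
  # identical sequences align gapless with the diagonal score
  s <- "ACDKWM"
  a <- global_align(s, s)
  expect_equal(a$a, s)
  expect_equal(a$b, s)
  cs <- strsplit(s, "")[[1]]
  expect_equal(a$score, sum(diag(blosum62[cs, cs])))

  # worked case: KAA vs KA, open 11 / extend 1
  a2 <- global_align("KAA", "KA")
  expect_equal(a2$score, bf_align_score("KAA", "KA", blosum62))

  set.seed(17)
  for (i in 1:40) {
    la <- sample(2:6, 1); lb <- sample(2:6, 1)
    sa <- random_aa(la); sb <- random_aa(lb)
    expect_equal(global_align(sa, sb)$score,
                 bf_align_score(sa, sb, blosum62),
                 info = paste(sa, sb))
  }
  expect_error(global_align("AC1", "AC"), "illegal")
  expect_error(global_align("", "AC"), "nonempty")
})

test_that("alignment invariants: gap removal recovers inputs, equal gapped lengths", {
  set.seed(23)
  for (i in 1:10) {
    sa <- random_aa(sample(10:30, 1)); sb <- random_aa(sample(10:30, 1))
    al <- global_align(sa, sb)
    expect_equal(nchar(al$a), nchar(al$b))
    expect_equal(gsub("-", "", al$a), sa)
    expect_equal(gsub("-", "", al$b), sb)
  }
})

test_that("site mapping walks alignment columns and round-trips", {
  s <- "MKAVKWDE"
  al <- global_align(s, s)
  m <- map_site(al, 5)
  expect_equal(m$position_b, 5L)
  expect_true(m$conserved_k)
  expect_false(map_site(al, 3)$conserved_k)  # A is not K

  # hand-constructed alignment: b has a 2-residue insertion before the site
  al2 <- structure(list(a = "MK--AVK", b = "MKGGAVK", score = 0,
                        matrix = "BLOSUM62", gap_open = 11, gap_extend = 1),
                   class = "ub_alignment")
  m2 <- map_site(al2, 5)          # K at ungapped position 5 of a
  expect_equal(m2$position_b, 7L) # offset by the insertion
  expect_true(m2$conserved_k)

  # source residue aligned to a gap maps to none
  al3 <- structure(list(a = "MKA", b = "MK-", score = 0,
                        matrix = "BLOSUM62", gap_open = 11, gap_extend = 1),
                   class = "ub_alignment")
  expect_true(is.na(map_site(al3, 3)$position_b))
  expect_error(map_site(al3, 9), "outside")

  # a -> b -> a on the reversed alignment is the identity
  set.seed(5)
  pair <- simulate_ortholog_pair(60, 0.8, conserved_k_positions = c(10, 30), seed = 5)
  ab <- global_align(pair$seq_a, pair$seq_b)
  ba <- structure(list(a = ab$b, b = ab$a, score = ab$score,
                       matrix = ab$matrix, gap_open = ab$gap_open,
                       gap_extend = ab$gap_extend), class = "ub_alignment")
  for (pos in c(10, 30)) {
    fwd <- map_site(ab, pos)
    expect_false(is.na(fwd$position_b))
    expect_equal(map_site(ba, fwd$position_b)$position_b, as.integer(pos))
  }
})

test_that("ortholog simulation honors identity, indels and conserved lysines", {
  # identity 1: sequences equal, mapping is the identity
  p1 <- simulate_ortholog_pair(40, 1.0, conserved_k_positions = c(7, 21), seed = 2)
  expect_identical(p1$seq_a, p1$seq_b)
  expect_equal(p1$mapping$pos_a, p1$mapping$pos_b)

  # explicit 2-residue insertion after position 10 offsets later positions
  p2 <- simulate_ortholog_pair(30, 0.8, conserved_k_positions = c(5, 20), seed = 3,
                               insertions = tibble::tibble(after = 10L, length = 2L),
                               deletions = integer())
  expect_equal(p2$mapping$pos_b[p2$mapping$pos_a <= 10],
               p2$mapping$pos_a[p2$mapping$pos_a <= 10])
  expect_equal(p2$mapping$pos_b[p2$mapping$pos_a > 10],
               p2$mapping$pos_a[p2$mapping$pos_a > 10] + 2L)

  # conserved positions are K in both sequences
  for (p in list(p1, p2)) {
    for (k in p$conserved_k_positions) {
      expect_equal(substr(p$seq_a, k, k), "K")
      kb <- p$mapping$pos_b[p$mapping$pos_a == k]
      expect_equal(substr(p$seq_b, kb, kb), "K")
    }
  }

  expect_error(simulate_ortholog_pair(10, 0), "identity")
  expect_error(simulate_ortholog_pair(10, 0.5, conserved_k_positions = 99),
               "not representable")
})

test_that("alignment recovers >= 95% of the generator's true site mapping", {
  recov <- vapply(1:20, function(s) {
    pair <- simulate_ortholog_pair(200, 0.7,
                                   conserved_k_positions = c(20, 90, 150),
                                   seed = s)
    al <- global_align(pair$seq_a, pair$seq_b)
    hits <- vapply(seq_len(nrow(pair$mapping)), function(i) {
      m <- map_site(al, pair$mapping$pos_a[i])
      isTRUE(m$position_b == pair$mapping$pos_b[i])
    }, logical(1))
    mean(hits)
  }, numeric(1))
  expect_gte(mean(recov), 0.95)
})

test_that("conserved overlap applies strict thresholds and exact Venn bookkeeping", {
  # three ortholog pairs; plant known correspondences
  pairs <- lapply(1:3, function(i) {
    simulate_ortholog_pair(80, 0.9, conserved_k_positions = c(12, 40), seed = i,
                           deletions = integer(),
                           insertions = tibble::tibble(after = integer(),
                                                       length = integer()))
  })
  orth <- tibble::tibble(
    gene_a = c("GA1", "GA2", "GA3"), gene_b = c("GB1", "GB2", "GB3"),
    seq_a = vapply(pairs, `[[`, character(1), "seq_a"),
    seq_b = vapply(pairs, `[[`, character(1), "seq_b")
  )
  # a: GA1 K12 (shared), GA1 K40 (a-only), GA2 K12 at boundary log2 == 1.0
  # (excluded), GA3 K12 shared; b adds its own b-only site on GB2 K40
  set_a <- tibble::tibble(
    gene = c("GA1", "GA1", "GA2", "GA3"),
    position = c(12L, 40L, 12L, 12L),
    log2 = c(2.5, 1.8, 1.0, 3.1),
    p = c(0.001, 0.01, 0.001, 0.02)
  )
  set_b <- tibble::tibble(
    gene = c("GB1", "GB3", "GB2"),
    position = c(12L, 12L, 40L),
    log2 = c(2.0, 2.2, 1.6),
    p = c(0.01, 0.03, 0.04)
  )
  ov <- conserved_overlap(set_a, set_b, orth)
  expect_equal(ov$venn_sites$shared, 2)     # GA1 K12, GA3 K12
  expect_equal(ov$venn_sites$a_only, 1)     # GA1 K40 (GA2 excluded at boundary)
  expect_equal(ov$venn_sites$b_only, 1)     # GB2 K40
  expect_equal(ov$venn_proteins$shared, 2)  # GA1, GA3 in both species
  expect_equal(ov$venn_proteins$shared_with_shared_sites, 2)
  expect_equal(ov$venn_proteins$a_only, 0)  # both passing a-proteins are shared
  expect_equal(ov$venn_proteins$b_only, 1)  # GB2 passes only in species b
  expect_equal(length(ov$unmappable), 0)

  # shared protein with distinct sites: move b site of GB1 to K40
  set_b2 <- set_b
  set_b2$position[1] <- 40L
  set_a2 <- set_a[c(1, 4), ]               # GA1 K12, GA3 K12
  ov2 <- conserved_overlap(set_a2, set_b2, orth)
  expect_equal(ov2$venn_sites$shared, 1)    # GA3 K12 only
  expect_true("GA1" %in% ov2$shared_protein_distinct_sites)

  # swapping the sets swaps a-only/b-only and preserves the shared count
  orth_rev <- tibble::tibble(gene_a = orth$gene_b, gene_b = orth$gene_a,
                             seq_a = orth$seq_b, seq_b = orth$seq_a)
  ov_rev <- conserved_overlap(set_b, set_a, orth_rev)
  expect_equal(ov_rev$venn_sites$shared, ov$venn_sites$shared)
  expect_equal(ov_rev$venn_sites$a_only, ov$venn_sites$b_only)
  expect_equal(ov_rev$venn_sites$b_only, ov$venn_sites$a_only)

  # missing ortholog sequence is reported, not dropped
  ov3 <- conserved_overlap(
    dplyr::bind_rows(set_a, tibble::tibble(gene = "GA9", position = 3L,
                                           log2 = 2, p = 0.01)),
    set_b, orth)
  expect_true("GA9" %in% ov3$unmappable)
})
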