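test_that("allele frequencies count every copy of diploid calls only", {
  gt <- gt_from_calls(list(
    I1 = list(L1 = c(10L, 10L)),
    I2 = list(L1 = c(10L, 12L)),
    I3 = list(L1 = integer(0)),          # missing: excluded from N
    I4 = list(L1 = c(10L, 12L, 14L))     # triallelic: excluded
  ))
  f <- allele_frequencies(gt)
  expect_equal(f$freq[f$allele == 10], 0.75)
  expect_equal(f$freq[f$allele == 12], 0.25)
  expect_equal(unique(f$n_copies), 4L)
  # frequencies sum to 1 per locus within any grouping; the all-missing
  # group/locus cell is flagged with a warning
  expect_warning(g <- allele_frequencies(gt, group_by = c("a", "a", "b", "b")),
                 "no scored")
  sums <- dplyr::summarise(dplyr::group_by(g, group, locus), s = sum(freq))
  expect_true(all(abs(sums$s - 1) < 1e-9))
})

test_that("probability of identity matches the analytic forms", {
  f5050 <- tibble::tibble(group = "all", locus = "L1",
                          allele = c(1L, 2L), count = c(2L, 2L),
                          freq = c(0.5, 0.5), n_copies = 4L)
  expect_equal(probability_of_identity(f5050)$pid, 0.375)

  fmono <- tibble::tibble(group = "all", locus = "L1", allele = 1L,
                          count = 4L, freq = 1, n_copies = 4L)
  expect_equal(probability_of_identity(fmono)$pid, 1.0)

  k <- 4
  funif <- tibble::tibble(group = "all", locus = "L1", allele = seq_len(k),
                          count = 2L, freq = 1 / k, n_copies = 2L * k)
  expect_equal(probability_of_identity(funif)$pid, (2 * k - 1) / k^3)

  bad <- f5050; bad$freq <- c(0.5, 0.6)
  expect_error(probability_of_identity(bad), "normalized")
})

test_that("P_ID equals exhaustive genotype-pair summation for random frequencies", {
  set.seed(42)
  for (rep in 1:10) {
    k <- sample(2:6, 1)
    p <- as.numeric(rmultinom(1, 50, rep(1, k))) + 1
    p <- p / sum(p)
    f <- tibble::tibble(group = "all", locus = "L1", allele = seq_len(k),
                        count = 1L, freq = p, n_copies = 100L)
    expect_equal(probability_of_identity(f)$pid, brute_force_pid(p),
                 tolerance = 1e-12)
  }
})

test_that("diversity statistics obey their identities and bounds", {
  # k uniform alleles: N_E = k exactly
  gt <- gt_from_calls(list(
    I1 = list(L1 = c(1L, 2L)), I2 = list(L1 = c(3L, 4L)),
    I3 = list(L1 = c(1L, 3L)), I4 = list(L1 = c(2L, 4L))
  ))
  st <- diversity_stats(gt)
  expect_equal(st$n_e, 4)
  expect_equal(st$ho, 1)

  # all homozygotes: Ho = 0
  gt0 <- gt_from_calls(list(I1 = list(L1 = c(1L, 1L)),
                            I2 = list(L1 = c(2L, 2L))))
  expect_equal(diversity_stats(gt0)$ho, 0)

  # invariants on simulated data: corrected He >= plain, both in [0,1], N_E <= N_A
  sim <- simulate_structured_population(
    sim_config(n_groups = 2, n_per_group = 25, seed = 7, missing_rate = 0.05))
  st2 <- diversity_stats(sim$table, group_by = sim$truth$q$true_group)
  expect_true(all(st2$he >= st2$he_uncorrected))
  expect_true(all(st2$he >= 0 & st2$he <= 1))
  expect_true(all(st2$ho >= 0 & st2$ho <= 1))
  expect_true(all(st2$n_e <= st2$n_a + 1e-9))
  expect_true(all(st2$n_b <= st2$n_a))
  expect_true(all(st2$a_r <= st2$n_a + 1e-9, na.rm = TRUE))
})

test_that("statistics are invariant to accession order and allele relabeling", {
  sim <- simulate_structured_population(
    sim_config(n_groups = 1, n_per_group = 20, seed = 13, missing_rate = 0))
  gt <- sim$table
  st <- diversity_stats(gt)
  perm <- sample(nrow(gt))
  st_perm <- diversity_stats(ssrclust:::keep_rows(gt, perm))
  expect_equal(st, st_perm, ignore_attr = TRUE)
  # add a constant to every allele size at one locus: all stats unchanged
  gt2 <- gt
  gt2$L01 <- lapply(gt2$L01, function(a) a + 50L)
  expect_equal(diversity_stats(gt2)[, -2], st[, -2], ignore_attr = TRUE)
})

test_that("rarefied richness matches enumeration and Monte-Carlo subsampling", {
  # counts (2,2), g = 2: of the C(4,2)=6 draws, 4 show two distinct alleles
  expect_equal(allelic_richness(c(2, 2), 2), 5 / 3)
  expect_equal(allelic_richness(c(3, 5, 2), 10), 3)   # g = N -> N_A
  expect_equal(allelic_richness(c(4, 6), 1), 1)       # one copy, one allele
  expect_error(allelic_richness(c(2, 2), 5), "exceeds")

  counts <- c(12L, 5L, 2L, 1L)
  gs <- c(2, 5, 10, 15, 20)
  ar <- vapply(gs, function(g) allelic_richness(counts, g), numeric(1))
  expect_true(all(diff(ar) > 0))  # non-decreasing in g

  set.seed(99)
  pool <- rep(seq_along(counts), counts)
  mc <- replicate(4000, length(unique(sample(pool, 10))))
  se <- sd(mc) / sqrt(length(mc))
  expect_lt(abs(allelic_richness(counts, 10) - mean(mc)), 3 * se)
})

test_that("private and unique alleles follow their definitions", {
  gt <- gt_from_calls(list(
    A1 = list(L1 = c(1L, 2L)), A2 = list(L1 = c(1L, 2L)),
    B1 = list(L1 = c(1L, 3L)), B2 = list(L1 = c(3L, 4L))
  ))
  pu <- private_and_unique_alleles(gt, group_by = c("G1", "G1", "G2", "G2"))
  g1 <- pu[pu$group == "G1", ]; g2 <- pu[pu$group == "G2", ]
  expect_equal(g1$n_private, 1L)  # allele 2 only in G1
  expect_equal(g2$n_private, 2L)  # alleles 3, 4 only in G2
  expect_equal(g2$n_unique, 1L)   # allele 4 carried by B2 only
  # allele 1 occurs in both groups: neither private nor unique
  expect_equal(g1$n_alleles, 2L)
  expect_error(private_and_unique_alleles(gt, group_by = rep("G", 4)), "2 groups")
})

test_that("frequent-allele chi-square matches hand computations", {
  # two groups fixed for different alleles: 2x2 table [[10,0],[0,10]] -> X2 = 20
  gt <- gt_from_calls(c(
    setNames(lapply(1:5, function(i) list(L1 = c(1L, 1L))), paste0("A", 1:5)),
    setNames(lapply(1:5, function(i) list(L1 = c(2L, 2L))), paste0("B", 1:5))
  ))
  res <- frequent_allele_chi2(gt, group_by = rep(c("G1", "G2"), each = 5))
  expect_equal(res$statistic, 20)
  expect_equal(res$df, 1L)

  # identical compositions: statistic 0, p = 1
  gt2 <- gt_from_calls(c(
    setNames(lapply(1:4, function(i) list(L1 = c(1L, 2L))), paste0("A", 1:4)),
    setNames(lapply(1:4, function(i) list(L1 = c(1L, 2L))), paste0("B", 1:4))
  ))
  res2 <- frequent_allele_chi2(gt2, group_by = rep(c("G1", "G2"), each = 4))
  expect_equal(res2$statistic, 0)
  expect_equal(res2$p_value, 1)

  # three equal groups: statistic ~ 0, p > 0.99
  gt3 <- gt_from_calls(c(
    setNames(lapply(1:4, function(i) list(L1 = c(1L, 2L))), paste0("A", 1:4)),
    setNames(lapply(1:4, function(i) list(L1 = c(1L, 2L))), paste0("B", 1:4)),
    setNames(lapply(1:4, function(i) list(L1 = c(1L, 2L))), paste0("C", 1:4))
  ))
  res3 <- frequent_allele_chi2(gt3, group_by = rep(c("G1", "G2", "G3"), each = 4))
  expect_gt(res3$p_value, 0.99)
})
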