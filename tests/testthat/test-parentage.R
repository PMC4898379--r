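biallelic_freqs <- function(p = 0.5, loci = "L1") {
  dplyr::bind_rows(lapply(loci, function(l) {
    tibble::tibble(group = "all", locus = l, allele = c(1L, 2L),
                   count = c(10L, 10L), freq = c(p, 1 - p), n_copies = 20L)
  }))
}

test_that("trio LOD matches the hand-computed Mendelian ratio", {
  # offspring {1,2} from parents {1,1} x {2,2}, p = 0.5: per-locus ratio
  # T / P_HWE = 1 / (2 * 0.5 * 0.5) = 2, LOD = ln 2
  lod <- trio_lod(list(L1 = c(1L, 2L)), list(L1 = c(1L, 1L)),
                  list(L1 = c(2L, 2L)), biallelic_freqs(), error_rate = 0)
  expect_equal(lod$lod, log(2))
  expect_equal(lod$n_mismatch, 0L)

  # Mendelian-impossible at e = 0: -Inf and one mismatch
  bad <- trio_lod(list(L1 = c(2L, 2L)), list(L1 = c(1L, 1L)),
                  list(L1 = c(1L, 1L)), biallelic_freqs(), error_rate = 0)
  expect_equal(bad$lod, -Inf)
  expect_equal(bad$n_mismatch, 1L)

  # with e > 0 the same mismatch is finite but penalized
  soft <- trio_lod(list(L1 = c(2L, 2L)), list(L1 = c(1L, 1L)),
                   list(L1 = c(1L, 1L)), biallelic_freqs(), error_rate = 0.01)
  expect_true(is.finite(soft$lod) && soft$lod < 0)
  expect_equal(soft$n_mismatch, 1L)
})

test_that("rare parental alleles increase the LOD", {
  rare <- tibble::tibble(group = "all", locus = "L1", allele = c(1L, 2L, 3L),
                         count = c(1L, 1L, 98L), freq = c(0.01, 0.01, 0.98),
                         n_copies = 100L)
  common <- tibble::tibble(group = "all", locus = "L1", allele = c(1L, 2L, 3L),
                           count = c(49L, 49L, 2L), freq = c(0.49, 0.49, 0.02),
                           n_copies = 100L)
  args <- list(list(L1 = c(1L, 2L)), list(L1 = c(1L, 1L)), list(L1 = c(2L, 2L)))
  expect_gt(do.call(trio_lod, c(args, list(rare, 0.01)))$lod,
            do.call(trio_lod, c(args, list(common, 0.01)))$lod)
})

test_that("LOD is additive over loci and invariant to locus order", {
  f2 <- biallelic_freqs(loci = c("L1", "L2"))
  off <- list(L1 = c(1L, 2L), L2 = c(1L, 1L))
  pa <- list(L1 = c(1L, 1L), L2 = c(1L, 2L))
  pb <- list(L1 = c(2L, 2L), L2 = c(1L, 2L))
  both <- trio_lod(off, pa, pb, f2, 0.01)
  one <- trio_lod(off["L1"], pa["L1"], pb["L1"], f2[f2$locus == "L1", ], 0.01)
  two <- trio_lod(off["L2"], pa["L2"], pb["L2"], f2[f2$locus == "L2", ], 0.01)
  expect_equal(both$lod, one$lod + two$lod)
  rev_order <- trio_lod(rev(off), rev(pa), rev(pb), f2, 0.01)
  expect_equal(rev_order$lod, both$lod)
  # loci missing in any member are skipped
  off_m <- off; off_m$L2 <- integer(0)
  expect_equal(trio_lod(off_m, pa, pb, f2, 0.01)$lod, one$lod)
  expect_error(trio_lod(off, pa, pb, f2, 0.6), "error_rate")
})

test_that("planted trios rank first and the mismatch cap excludes bad trios", {
  cfg <- sim_config(n_groups = 1, n_per_group = 60, seed = 41, n_trios = 5,
                    genotyping_error_rate = 0, missing_rate = 0)
  sim <- plant_trios(simulate_structured_population(cfg), cfg)
  trios <- enumerate_trios(sim$table, offspring_ids = sim$truth$pedigree$offspring_id,
                           error_rate = 0.01)
  best <- trios[trios$rank == 1, ]
  found <- dplyr::inner_join(best, sim$truth$pedigree,
                             by = c("offspring_id", "parent_a", "parent_b"))
  expect_equal(nrow(found), 5)
  expect_true(all(best$n_mismatch == 0))
  # no self-pairs anywhere
  expect_false(any(trios$parent_a == trios$offspring_id |
                     trios$parent_b == trios$offspring_id))

  # corrupt an offspring at 2 loci so the true trio is Mendelian-impossible
  # at both: it must disappear from the candidate list
  gt <- sim$table
  loci <- gt_loci(gt)
  off1 <- sim$truth$pedigree$offspring_id[1]
  i <- match(off1, gt$accession_id)
  for (l in loci[1:2]) gt[[l]][[i]] <- c(999L, 999L)
  trios2 <- enumerate_trios(gt, offspring_ids = off1, error_rate = 0.01,
                            max_mismatch = 1)
  expect_equal(nrow(dplyr::inner_join(trios2, sim$truth$pedigree,
                                      by = c("offspring_id", "parent_a", "parent_b"))),
               0)
})

test_that("confidence calibration is deterministic and meets its target", {
  cfg <- sim_config(n_groups = 1, n_per_group = 50, seed = 43, missing_rate = 0)
  sim <- simulate_structured_population(cfg)
  cal1 <- calibrate_confidence(sim$table, n_sims = 60, seed = 9)
  cal2 <- calibrate_confidence(sim$table, n_sims = 60, seed = 9)
  expect_equal(cal1$delta_threshold, cal2$delta_threshold)
  expect_gte(cal1$achieved_rate, 0.95)
  expect_true(is.finite(cal1$delta_threshold))
  gl <- glance(cal1)
  expect_equal(gl$n_sims, 60)
  expect_error(calibrate_confidence(sim$table, n_sims = 5, seed = 1), "few")
})

test_that("accepted trios are invariant to candidate row order", {
  cfg <- sim_config(n_groups = 1, n_per_group = 40, seed = 47, n_trios = 3,
                    genotyping_error_rate = 0, missing_rate = 0)
  sim <- plant_trios(simulate_structured_population(cfg), cfg)
  cal <- calibrate_confidence(sim$table, n_sims = 50, seed = 2)
  acc1 <- infer_trios(sim$table, cal)
  perm_gt <- ssrclust:::keep_rows(sim$table, rev(seq_len(nrow(sim$table))))
  acc2 <- infer_trios(perm_gt, cal)
  expect_equal(acc1, acc2)
  # every accepted trio satisfies the caps
  expect_true(all(acc1$n_mismatch <= 1))
  expect_true(all(acc1$delta >= cal$delta_threshold))
})
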