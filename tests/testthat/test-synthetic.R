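test_that("the generator is a pure function of config and seed", {
  cfg <- sim_config(n_groups = 2, n_per_group = 15, clone_groups = 2,
                    triploid_fraction = 0.1, n_trios = 2, seed = 55)
  a <- simulate_germplasm(cfg)
  b <- simulate_germplasm(cfg)
  expect_equal(a$table, b$table)
  expect_equal(a$truth$pedigree, b$truth$pedigree)
  # emitted tables pass validation
  expect_silent(validate_genotype_tbl(a$table, region_map = NULL))
})

test_that("panmixia (F = 0) yields near-zero differentiation", {
  sim <- simulate_structured_population(
    sim_config(n_groups = 2, n_per_group = 100, n_loci = 20, drift = 0,
               seed = 61, missing_rate = 0))
  th <- wc_theta(sim$table, sim$truth$q$true_group)
  expect_lt(abs(th), 0.01)
})

test_that("simulated heterozygosity lands in the intended band", {
  sim <- simulate_structured_population(
    sim_config(n_groups = 3, n_per_group = 40, seed = 63, missing_rate = 0))
  st <- diversity_summary(diversity_stats(sim$table))
  expect_gt(st$he, 0.70)
  expect_lt(st$he, 0.90)
})

test_that("planted clone groups are exactly recoverable and truths consistent", {
  cfg <- sim_config(n_groups = 2, n_per_group = 40, clone_groups = 8,
                    triploid_fraction = 0, seed = 65, missing_rate = 0)
  sim <- plant_clones_and_triploids(simulate_structured_population(cfg), cfg)
  dg <- find_duplicate_groups(sim$table)
  truth_groups <- split(sim$truth$clones$member, sim$truth$clones$source)
  got <- split(dg$groups$member, dg$groups$representative)
  expect_equal(length(got), length(truth_groups))
  for (src in names(truth_groups)) {
    expect_setequal(unname(got[[src]]), unname(c(src, truth_groups[[src]])))
  }
  # zero clone spec: no groups at all
  cfg0 <- sim_config(n_groups = 2, n_per_group = 30, seed = 66, missing_rate = 0)
  sim0 <- simulate_germplasm(cfg0)
  expect_equal(nrow(find_duplicate_groups(sim0$table)$groups), 0)
})

test_that("triploid planting matches the flagging rule and binomial scale", {
  cfg <- sim_config(n_groups = 2, n_per_group = 100, triploid_fraction = 0.08,
                    seed = 67, missing_rate = 0)
  sim <- plant_clones_and_triploids(simulate_structured_population(cfg), cfg)
  fl <- flag_triploids(sim$table)
  flagged <- fl$accession_id[fl$is_putative_triploid]
  expect_setequal(flagged, sim$truth$ploidy$accession_id)
  expect_equal(length(flagged), round(0.08 * 200))
})

test_that("error-free planted offspring are Mendelian-consistent everywhere", {
  cfg <- sim_config(n_groups = 1, n_per_group = 30, n_trios = 6,
                    genotyping_error_rate = 0, seed = 69, missing_rate = 0)
  sim <- plant_trios(simulate_structured_population(cfg), cfg)
  expect_equal(nrow(sim$truth$pedigree), 6)
  freqs <- allele_frequencies(ssrclust:::keep_rows(
    sim$table, !grepl("^OFF", sim$table$accession_id)))
  for (r in seq_len(nrow(sim$truth$pedigree))) {
    ped <- sim$truth$pedigree[r, ]
    gt <- sim$table
    loci <- gt_loci(gt)
    pick <- function(id) setNames(
      lapply(loci, function(l) gt[[l]][[match(id, gt$accession_id)]]), loci)
    s <- trio_lod(pick(ped$offspring_id), pick(ped$parent_a), pick(ped$parent_b),
                  freqs, error_rate = 0)
    expect_equal(s$n_mismatch, 0L)
  }
})

test_that("offspring mismatch counts under genotyping error follow a binomial scale", {
  cfg <- sim_config(n_groups = 1, n_per_group = 40, n_trios = 40,
                    genotyping_error_rate = 0.05, seed = 71, missing_rate = 0)
  sim <- plant_trios(simulate_structured_population(cfg), cfg)
  freqs <- allele_frequencies(ssrclust:::keep_rows(
    sim$table, !grepl("^OFF", sim$table$accession_id)))
  gt <- sim$table
  loci <- gt_loci(gt)
  pick <- function(id) setNames(
    lapply(loci, function(l) gt[[l]][[match(id, gt$accession_id)]]), loci)
  mism <- vapply(seq_len(nrow(sim$truth$pedigree)), function(r) {
    ped <- sim$truth$pedigree[r, ]
    trio_lod(pick(ped$offspring_id), pick(ped$parent_a), pick(ped$parent_b),
             freqs, error_rate = 0)$n_mismatch
  }, integer(1))
  # each of 16 loci carries 2 copies, each erred with p = 0.05; an erroneous
  # copy breaks Mendelian consistency only when the replacement allele is
  # not transmissible, so the per-locus mismatch rate is below 2 * 0.05
  p_max <- 2 * 0.05
  n <- length(mism) * length(loci)
  upper <- n * p_max + 3 * sqrt(n * p_max * (1 - p_max))
  expect_lt(sum(mism), upper)
  expect_gt(sum(mism), 0)  # with 40 trios some errors must surface
})

test_that("infeasible specs are rejected", {
  expect_error(sim_config(n_groups = 2, drift = 1.2))
  cfg <- sim_config(n_groups = 2, n_per_group = 3,
                    nested = list("1" = list(n_sub = 5, drift = 0.05)))
  expect_error(simulate_structured_population(cfg), "subgroup")
})

test_that("nested splits produce real substructure inside the split group", {
  cfg <- sim_config(n_groups = 2, n_per_group = 60, drift = 0.08, seed = 73,
                    nested = list("1" = list(n_sub = 2, drift = 0.15)),
                    missing_rate = 0)
  sim <- simulate_structured_population(cfg)
  q <- sim$truth$q
  inside <- q[q$true_group == 1, ]
  expect_setequal(unique(inside$true_subgroup), 1:2)
  sub_gt <- ssrclust:::keep_rows(sim$table,
                                 sim$table$accession_id %in% inside$accession_id)
  th <- wc_theta(sub_gt, inside$true_subgroup)
  expect_gt(th, 0.05)  # the sub-split is genuinely differentiated
})
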