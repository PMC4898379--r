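#' Configuration for the germplasm simulator
#'
#' Bundles the parameters of [simulate_germplasm()]. Defaults emulate the
#' statistical structure of a multi-collection apple germplasm panel:
#' 16 SSR loci with many (mostly rare) alleles and expected heterozygosity
#' around 0.8, three weakly differentiated genepools (drift F per group
#' around 0.02-0.05) with optional nested subgroups, admixed individuals,
#' clonal duplicate groups of size 2-9 mutated at no more than two loci,
#' about 8 % putative triploids, and planted parent-pair/offspring trios.
#'
#' @param n_loci Number of SSR loci.
#' @param alleles_per_locus Integer range (min, max) of alleles per locus.
#' @param anc_dirichlet Symmetric Dirichlet concentration for ancestral
#'   allele frequencies; smaller values give more rare alleles.
#' @param n_groups Number of top-level genepools (K).
#' @param drift Per-group drift F of the Balding-Nichols model (recycled).
#' @param n_per_group Individuals per group (recycled).
#' @param own_weight,admixture_alpha Dirichlet parameters for individual
#'   ancestry: individual i of group g draws
#'   `q_i ~ Dirichlet(admixture_alpha + own_weight * e_g)`; larger
#'   `admixture_alpha` means more admixture.
#' @param nested Optional named list: top-level group index (as character)
#'   to `list(n_sub =, drift =)` describing subgroup splits.
#' @param clone_groups Number of clonal duplicate groups to plant.
#' @param clone_size_range Size range of a clone group (source included).
#' @param clone_max_mutations Maximum mutated loci per clone copy (0-2).
#' @param triploid_fraction Fraction of base accessions converted to
#'   putative triploid profiles.
#' @param n_trios Number of planted parent-pair/offspring trios.
#' @param genotyping_error_rate Per-allele error rate applied to planted
#'   offspring.
#' @param missing_rate Per-call probability that a base accession's locus
#'   is missing.
#' @param ladder_start,ladder_step Synthetic allele sizes form a regular
#'   fragment-size ladder so a one-step mutation is well defined.
#' @param seed Master seed; the whole simulation is a pure function of the
#'   config including the seed.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_loci = 16, alleles_per_locus = c(8, 30),
                       anc_dirichlet = 0.3,
                       n_groups = 3, drift = 0.04, n_per_group = 50,
                       own_weight = 5, admixture_alpha = 0.3,
                       nested = NULL,
                       clone_groups = 0, clone_size_range = c(2, 9),
                       clone_max_mutations = 2,
                       triploid_fraction = 0, n_trios = 0,
                       genotyping_error_rate = 0.01, missing_rate = 0.01,
                       ladder_start = 100L, ladder_step = 2L, seed = 1L) {
  cfg <- as.list(environment())
  stopifnot(n_loci >= 1, n_groups >= 1, all(drift >= 0 & drift < 1),
            triploid_fraction >= 0, triploid_fraction <= 1,
            missing_rate >= 0, missing_rate < 1,
            genotyping_error_rate >= 0, genotyping_error_rate < 0.5,
            clone_max_mutations <= 2)
  structure(cfg, class = "sim_config")
}

# sample() without the scalar-x surprise
sample_from <- function(x, size, ...) x[sample.int(length(x), size, ...)]

rdirichlet1 <- function(a) {
  g <- stats::rgamma(length(a), shape = pmax(a, 1e-8), rate = 1)
  if (sum(g) == 0) g <- rep(1, length(a))
  g / sum(g)
}

#' Simulate a structured population of diploid SSR genotypes
#'
#' Balding-Nichols construction: ancestral allele frequencies per locus
#' are Dirichlet-distributed on a synthetic fragment-size ladder; each
#' group's frequencies are `Dirichlet(p_anc * (1 - F)/F)`; optional nested
#' subgroups repeat the construction inside a group around the group's
#' frequencies. Each individual draws ancestry `q` (see [sim_config()])
#' and each allele copy first a cluster of origin from `q`, then an allele
#' from that cluster's frequencies (its own subgroup's frequencies when
#' the copy originates from the individual's own group and a split is
#' configured).
#'
#' @param config A [sim_config()].
#' @return List with `table` (a `genotype_tbl`) and `truth` (list:
#'   `q` tibble with `accession_id`, `true_group`, `true_subgroup`, `q1..qK`,
#'   `freqs` with ancestral and per-group frequencies, `config`).
#' @export
simulate_structured_population <- function(config) {
  set.seed(as.integer(config$seed))
  K <- config$n_groups
  n_per <- rep_len(config$n_per_group, K)
  drift <- rep_len(config$drift, K)
  if (any(n_per < 1)) abort("n_per_group must be positive")
  L <- config$n_loci
  loci <- sprintf("L%02d", seq_len(L))

  j_range <- config$alleles_per_locus[1]:config$alleles_per_locus[2]
  J <- j_range[sample.int(length(j_range), L, replace = TRUE)]
  sizes <- lapply(J, function(j) config$ladder_start + config$ladder_step * (0:(j - 1)))
  p_anc <- lapply(J, function(j) rdirichlet1(rep(config$anc_dirichlet, j)))
  p_grp <- lapply(seq_len(L), function(l) {
    t(vapply(seq_len(K), function(k) {
      if (drift[k] == 0) p_anc[[l]]  # F = 0: panmixia, no drift
      else rdirichlet1(p_anc[[l]] * (1 - drift[k]) / drift[k])
    }, numeric(J[l])))
  })

  # nested splits: subgroup frequencies drawn around the group frequencies
  sub_of <- vector("list", K)
  p_sub <- vector("list", K)
  if (!is.null(config$nested)) {
    for (g_chr in names(config$nested)) {
      g <- as.integer(g_chr)
      spec <- config$nested[[g_chr]]
      if (spec$n_sub > n_per[g]) abort("subgroup count exceeds group size")
      p_sub[[g]] <- lapply(seq_len(L), function(l) {
        t(vapply(seq_len(spec$n_sub), function(s) {
          rdirichlet1(p_grp[[l]][g, ] * (1 - spec$drift) / spec$drift)
        }, numeric(J[l])))
      })
      sub_of[[g]] <- spec$n_sub
    }
  }

  n_tot <- sum(n_per)
  grp <- rep(seq_len(K), n_per)
  subgrp <- integer(n_tot)
  for (g in seq_len(K)) {
    idx <- which(grp == g)
    if (!is.null(sub_of[[g]])) {
      subgrp[idx] <- rep_len(seq_len(sub_of[[g]]), length(idx))
    }
  }
  qmat <- matrix(0, n_tot, K)
  for (i in seq_len(n_tot)) {
    a <- rep(config$admixture_alpha, K)
    a[grp[i]] <- a[grp[i]] + config$own_weight
    qmat[i, ] <- rdirichlet1(a)
  }

  tab <- tibble(accession_id = sprintf("A%04d", seq_len(n_tot)))
  for (l in seq_len(L)) {
    calls <- vector("list", n_tot)
    for (i in seq_len(n_tot)) {
      ks <- sample.int(K, 2, replace = TRUE, prob = qmat[i, ])
      al <- vapply(ks, function(k) {
        pvec <- if (k == grp[i] && subgrp[i] > 0) p_sub[[k]][[l]][subgrp[i], ]
                else p_grp[[l]][k, ]
        sizes[[l]][sample.int(J[l], 1, prob = pvec)]
      }, numeric(1))
      calls[[i]] <- sort(as.integer(al))
    }
    if (config$missing_rate > 0) {
      drop <- stats::runif(n_tot) < config$missing_rate
      calls[drop] <- list(integer(0))
    }
    tab[[loci[l]]] <- calls
  }
  gt <- as_genotype_tbl(tab, loci = loci)

  truth_q <- bind_cols(
    tibble(accession_id = gt$accession_id,
           true_group = grp,
           true_subgroup = ifelse(subgrp > 0, subgrp, NA_integer_)),
    as_tibble(setNames(as.data.frame(qmat), paste0("q", seq_len(K))))
  )
  list(table = gt,
       truth = list(q = truth_q,
                    freqs = list(loci = loci, sizes = sizes, ancestral = p_anc,
                                 group = p_grp, subgroup = p_sub),
                    clones = NULL, ploidy = NULL, pedigree = NULL,
                    config = config))
}

#' Plant clonal duplicate groups and triploid profiles
#'
#' Clone copies duplicate a source profile and then mutate at most
#' `clone_max_mutations` loci by moving a single allele copy one ladder
#' step, which keeps every planted group inside the duplicate-detection
#' tolerance. Triploids get a third distinct allele at 3-6 loci. Clone ids
#' extend the source id (`<source>.c1`, ...) so the source remains the
#' lexicographically smallest group member.
#'
#' @param sim Output of [simulate_structured_population()].
#' @param config The same [sim_config()] (uses `clone_groups`,
#'   `clone_size_range`, `clone_max_mutations`, `triploid_fraction`).
#' @return `sim` with augmented `table` and `truth$clones`, `truth$ploidy`.
#' @export
plant_clones_and_triploids <- function(sim, config = sim$truth$config) {
  set.seed(as.integer(config$seed) + 1L)
  gt <- sim$table
  loci <- gt_loci(gt)
  step <- config$ladder_step
  n_base <- nrow(gt)

  # triploids first, on base accessions (they are excluded from cloning)
  n_tri <- round(config$triploid_fraction * n_base)
  tri_idx <- if (n_tri > 0) sort(sample.int(n_base, n_tri)) else integer(0)
  for (i in tri_idx) {
    n_loci_tri <- sample_from(3:min(6, length(loci)), 1)
    at <- sample(seq_along(loci), n_loci_tri)
    for (j in at) {
      a <- gt[[loci[j]]][[i]]
      if (length(a) == 0) a <- c(config$ladder_start, config$ladder_start)
      if (length(a) == 1) a <- c(a, a)
      # a putative-triploid locus shows three *distinct* alleles
      if (a[1] == a[2]) a[2] <- a[2] + step
      extra <- a[2] + step
      while (extra %in% a) extra <- extra + step
      gt[[loci[j]]][[i]] <- sort(as.integer(c(a[1:2], extra)))
    }
  }

  clone_rows <- list(); clone_map <- list()
  if (config$clone_groups > 0) {
    eligible <- setdiff(seq_len(n_base), tri_idx)
    src_idx <- sample_from(eligible, config$clone_groups)
    sizes <- sample_from(config$clone_size_range[1]:config$clone_size_range[2],
                         config$clone_groups, replace = TRUE,
                         prob = rev(seq_len(diff(config$clone_size_range) + 1)))
    for (ci in seq_along(src_idx)) {
      src <- src_idx[ci]
      src_id <- gt$accession_id[src]
      for (copy in seq_len(sizes[ci] - 1)) {
        row <- tibble(accession_id = sprintf("%s.c%d", src_id, copy))
        n_mut <- sample_from(0:config$clone_max_mutations, 1)
        mut_at <- if (n_mut > 0) sample(seq_along(loci), n_mut) else integer(0)
        for (j in seq_along(loci)) {
          a <- gt[[loci[j]]][[src]]
          if (j %in% mut_at && length(a) == 2) {
            w <- sample(1:2, 1)
            a[w] <- a[w] + step * sample(c(-1L, 1L), 1)
            a <- sort(pmax(a, step))
          }
          row[[loci[j]]] <- list(as.integer(a))
        }
        clone_rows[[length(clone_rows) + 1]] <- row
        clone_map[[length(clone_map) + 1]] <-
          tibble(source = src_id, member = row$accession_id)
      }
    }
  }
  if (length(clone_rows) > 0) {
    gt <- bind_rows(tibble::as_tibble(gt), bind_rows(clone_rows))
    gt <- structure(gt, loci = loci,
                    class = c("genotype_tbl", class(tibble::tibble())))
  }
  sim$table <- validate_genotype_tbl(gt, region_map = NULL)
  sim$truth$clones <- if (length(clone_map)) bind_rows(clone_map) else
    tibble(source = character(), member = character())
  sim$truth$ploidy <- tibble(accession_id = gt$accession_id[seq_len(n_base)][tri_idx],
                             ploidy = 3L)
  sim
}

#' Plant parent-pair/offspring trios
#'
#' Each offspring receives one Mendelian allele per parent per locus,
#' after which per-allele genotyping error is applied at the configured
#' rate (an erroneous copy is replaced by a draw from the population
#' frequencies). Parents are diploid non-clone base accessions.
#'
#' @inheritParams plant_clones_and_triploids
#' @return `sim` with offspring rows appended and `truth$pedigree` filled.
#' @export
plant_trios <- function(sim, config = sim$truth$config) {
  set.seed(as.integer(config$seed) + 2L)
  if (config$n_trios == 0) {
    sim$truth$pedigree <- tibble(offspring_id = character(),
                                 parent_a = character(), parent_b = character())
    return(sim)
  }
  gt <- sim$table
  loci <- gt_loci(gt)
  tri_ids <- sim$truth$ploidy$accession_id %||% character(0)
  clone_ids <- sim$truth$clones$member %||% character(0)
  pool <- which(!gt$accession_id %in% c(tri_ids, clone_ids) &
                  !grepl("^OFF", gt$accession_id))
  if (length(pool) < 2) abort("need at least 2 candidate parents")
  freqs <- allele_frequencies(filter_diploid(keep_rows(gt, pool)))

  rows <- list(); ped <- list()
  for (t in seq_len(config$n_trios)) {
    pr <- sample_from(pool, 2)
    off <- simulate_offspring_call(gt, pr[1], pr[2], freqs,
                                   config$genotyping_error_rate)
    row <- tibble(accession_id = sprintf("OFF%03d", t))
    for (l in loci) row[[l]] <- list(off[[l]])
    rows[[t]] <- row
    ids <- sort(gt$accession_id[pr])
    ped[[t]] <- tibble(offspring_id = row$accession_id,
                       parent_a = ids[1], parent_b = ids[2])
  }
  gt <- bind_rows(tibble::as_tibble(gt), bind_rows(rows))
  sim$table <- structure(gt, loci = loci,
                         class = c("genotype_tbl", class(tibble::tibble())))
  sim$truth$pedigree <- bind_rows(ped)
  sim
}

#' Simulate a complete synthetic germplasm collection
#'
#' Chains [simulate_structured_population()],
#' [plant_clones_and_triploids()] and [plant_trios()].
#'
#' @param config A [sim_config()].
#' @return List with `table` and `truth` as documented in the stage
#'   functions.
#' @export
simulate_germplasm <- function(config = sim_config()) {
  sim <- simulate_structured_population(config)
  sim <- plant_clones_and_triploids(sim, config)
  plant_trios(sim, config)
}
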