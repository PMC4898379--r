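#' Trio LOD score for a candidate parent pair
#'
#' Log-likelihood ratio comparing the hypothesis that two candidate
#' parents produced the offspring against the hypothesis that the
#' offspring is an unrelated random draw from the population:
#' \deqn{LOD = \sum_l \ln \frac{(1-E)\,T(g_o \mid g_A, g_B) + E\,P_{HWE}(g_o)}
#'   {P_{HWE}(g_o)},}
#' where \eqn{T} is the Mendelian transmission probability,
#' \eqn{P_{HWE}} the Hardy-Weinberg genotype probability from the
#' population allele frequencies, and \eqn{E = 1-(1-e)^2} the probability
#' that a genotype is mistyped given a per-allele error rate `e` (an
#' erroneous genotype is modeled as a random population draw). Loci
#' missing in any member are skipped. The mismatch count is the number of
#' loci that are Mendelian-impossible at `e = 0`; at `e = 0` any mismatch
#' makes the LOD `-Inf`.
#'
#' @param offspring,parent_a,parent_b Named lists of diploid calls per
#'   locus (e.g. rows of a `genotype_tbl`: `as.list(gt[i, gt_loci(gt)])`).
#' @param freqs Allele frequencies ([allele_frequencies()], single group).
#' @param error_rate Per-allele genotyping error rate in `[0, 0.5)`.
#' @return List with `lod`, `n_mismatch`, `n_loci_compared`.
#' @export
trio_lod <- function(offspring, parent_a, parent_b, freqs, error_rate = 0.01) {
  if (error_rate < 0 || error_rate >= 0.5) abort("error_rate must be in [0, 0.5)")
  ftab <- freq_lookup(freqs)
  loci <- intersect(names(ftab), names(offspring))
  lod <- 0; mism <- 0L; used <- 0L
  E <- 1 - (1 - error_rate)^2
  for (l in loci) {
    go <- offspring[[l]]; ga <- parent_a[[l]]; gb <- parent_b[[l]]
    if (length(go) != 2 || length(ga) != 2 || length(gb) != 2) next
    used <- used + 1L
    tr <- mendel_prob(go, ga, gb)
    hwe <- hwe_prob(go, ftab[[l]])
    if (tr == 0) mism <- mism + 1L
    lod <- lod + log(((1 - E) * tr + E * hwe) / hwe)
  }
  list(lod = lod, n_mismatch = mism, n_loci_compared = used)
}

# P(offspring genotype | parental genotypes) under Mendelian segregation
mendel_prob <- function(go, ga, gb) {
  p <- 0
  for (a in 1:2) for (b in 1:2) {
    gam <- sort(c(ga[a], gb[b]))
    if (gam[1] == go[1] && gam[2] == go[2]) p <- p + 0.25
  }
  p
}

hwe_prob <- function(go, f) {
  p1 <- f[as.character(go[1])]; p2 <- f[as.character(go[2])]
  p1 <- ifelse(is.na(p1), 1e-6, p1); p2 <- ifelse(is.na(p2), 1e-6, p2)
  unname(if (go[1] == go[2]) p1^2 else 2 * p1 * p2)
}

# freqs tibble -> list per locus of named frequency vectors
freq_lookup <- function(freqs) {
  if (dplyr::n_distinct(freqs$group) > 1) {
    abort("parentage needs frequencies from a single (pooled) group")
  }
  split(setNames(freqs$freq, freqs$allele), freqs$locus)
}

#' Enumerate and rank candidate parent pairs for each offspring
#'
#' Scores all parent pairs surviving the mismatch cap for each offspring
#' and keeps the ranked list. Candidates are all accessions except the
#' offspring itself and any candidate with a profile identical to it
#' (self-assignment guard). A pre-filter keeps only single parents that
#' share at least one allele copy with the offspring at all but
#' `max_mismatch` co-scored loci, which prunes the cubic pair enumeration
#' to near-relatives before any likelihood is computed.
#'
#' @param gt Unique diploid `genotype_tbl` of candidates (and offspring).
#' @param freqs Population allele frequencies; defaults to frequencies
#'   computed from `gt`.
#' @param offspring_ids Accessions to treat as offspring (default: all).
#' @param error_rate Per-allele genotyping error rate.
#' @param max_mismatch Maximum Mendelian-impossible loci tolerated in an
#'   accepted trio (default 1).
#' @param min_loci Minimum co-scored loci for a trio to be scored.
#' @return Tibble of class `trio_candidates`: per offspring the ranked
#'   trios with `offspring_id`, `parent_a`, `parent_b` (sorted ids),
#'   `lod`, `delta` (LOD gap to the offspring's second-best trio; equals
#'   `lod` when unique), `n_mismatch`, `rank`.
#' @export
enumerate_trios <- function(gt, freqs = NULL, offspring_ids = NULL,
                            error_rate = 0.01, max_mismatch = 1,
                            min_loci = 10) {
  gt <- filter_diploid(gt)
  freqs <- freqs %||% allele_frequencies(gt)
  offspring_ids <- offspring_ids %||% gt$accession_id
  loci <- gt_loci(gt)
  enc <- gt_index_encode(gt)
  n <- nrow(gt)

  a1 <- enc$geno[, 2 * seq_along(loci) - 1, drop = FALSE]
  a2 <- enc$geno[, 2 * seq_along(loci), drop = FALSE]
  ok <- !is.na(a1)

  calls <- lapply(seq_len(n), function(i) {
    setNames(lapply(loci, function(l) gt[[l]][[i]]), loci)
  })
  names(calls) <- gt$accession_id
  ftab_ok <- freqs

  out <- list()
  for (o_id in offspring_ids) {
    oi <- match(o_id, gt$accession_id)
    if (is.na(oi)) next
    # single-parent compatibility: share >= 1 allele copy at all but
    # max_mismatch co-scored loci (O(n * L), no pairwise matrices)
    share_o <- integer(n); scored_o <- integer(n)
    for (j in seq_along(loci)) {
      if (!ok[oi, j]) next
      okj <- ok[, j]
      sh <- (a1[oi, j] == a1[, j] | a1[oi, j] == a2[, j] |
               a2[oi, j] == a1[, j] | a2[oi, j] == a2[, j]) & okj
      share_o <- share_o + ifelse(is.na(sh), FALSE, sh)
      scored_o <- scored_o + okj
    }
    compat <- which(share_o >= scored_o - max_mismatch & scored_o >= min_loci)
    compat <- setdiff(compat, oi)
    # self-assignment guard: identical profile to the offspring
    compat <- compat[vapply(compat, function(ci) {
      !identical(calls[[ci]], calls[[oi]])
    }, logical(1))]
    if (length(compat) < 2) next
    pairs <- utils::combn(compat, 2)
    scored <- lapply(seq_len(ncol(pairs)), function(p) {
      ia <- pairs[1, p]; ib <- pairs[2, p]
      s <- trio_lod(calls[[oi]], calls[[ia]], calls[[ib]], ftab_ok, error_rate)
      if (s$n_loci_compared < min_loci || s$n_mismatch > max_mismatch ||
          !is.finite(s$lod)) return(NULL)
      ids <- sort(gt$accession_id[c(ia, ib)])
      tibble(offspring_id = o_id, parent_a = ids[1], parent_b = ids[2],
             lod = s$lod, n_mismatch = s$n_mismatch)
    })
    scored <- bind_rows(scored)
    if (nrow(scored) == 0) next
    scored <- scored %>% arrange(dplyr::desc(.data$lod)) %>%
      mutate(rank = dplyr::row_number(),
             delta = if (dplyr::n() >= 2) .data$lod - .data$lod[2] else .data$lod)
    out[[o_id]] <- scored
  }
  res <- if (length(out)) bind_rows(out) else
    tibble(offspring_id = character(), parent_a = character(),
           parent_b = character(), lod = numeric(), n_mismatch = integer(),
           rank = integer(), delta = numeric())
  structure(res, class = c("trio_candidates", class(tibble::tibble())),
            error_rate = error_rate, max_mismatch = max_mismatch)
}

#' Calibrate the Delta confidence threshold by simulation
#'
#' Emulates the simulation-based confidence assessment of likelihood
#' parentage software: offspring are simulated from random parent pairs
#' drawn from the candidate pool, each true parent is independently
#' included in the candidate set with probability `sampled_fraction`, the
#' trio search is run, and the Delta threshold is set to the smallest
#' value at which at least `confidence` of the accepted best trios are
#' correct. When every assignment is correct the threshold degenerates to
#' the smallest observed Delta.
#'
#' @param gt Unique diploid `genotype_tbl` serving as the candidate pool.
#' @param n_sims Number of simulated offspring.
#' @param sampled_fraction Probability that a true parent is present in
#'   the candidate pool.
#' @param confidence Target fraction of correct assignments (default 0.95).
#' @param error_rate Per-allele genotyping error applied to simulated
#'   offspring and assumed in scoring.
#' @param seed Integer seed.
#' @inheritParams enumerate_trios
#' @return Object of class `parentage_calibration`: `delta_threshold`,
#'   `achieved_rate` (correct fraction at the threshold), `n_assignments`,
#'   `n_sims`, `sims` (per-simulation tibble).
#' @export
calibrate_confidence <- function(gt, n_sims = 1000, sampled_fraction = 0.9,
                                 confidence = 0.95, error_rate = 0.01,
                                 max_mismatch = 1, seed = 1L) {
  gt <- filter_diploid(gt)
  freqs <- allele_frequencies(gt)
  loci <- gt_loci(gt)
  set.seed(as.integer(seed))
  n <- nrow(gt)
  if (n < 3) abort("candidate pool too small")

  sims <- vector("list", n_sims)
  for (s in seq_len(n_sims)) {
    par_idx <- sample.int(n, 2)
    off <- simulate_offspring_call(gt, par_idx[1], par_idx[2], freqs, error_rate)
    pool <- rep(TRUE, n)
    pool[par_idx] <- stats::runif(2) < sampled_fraction
    sim_gt <- keep_rows(gt, pool)
    new_row <- tibble(accession_id = "__SIMOFF__")
    for (l in loci) new_row[[l]] <- list(off[[l]])
    aug <- bind_rows(tibble::as_tibble(sim_gt), new_row)
    aug <- structure(aug, loci = loci,
                     class = c("genotype_tbl", class(tibble::tibble())))
    tr <- enumerate_trios(aug, freqs = freqs, offspring_ids = "__SIMOFF__",
                          error_rate = error_rate, max_mismatch = max_mismatch)
    best <- tr[tr$rank == 1, ]
    if (nrow(best) == 0) {
      sims[[s]] <- tibble(sim = s, assigned = FALSE, correct = NA, delta = NA_real_)
    } else {
      truth <- sort(gt$accession_id[par_idx])
      sims[[s]] <- tibble(sim = s, assigned = TRUE,
                          correct = all(pool[par_idx]) &&
                            best$parent_a == truth[1] && best$parent_b == truth[2],
                          delta = best$delta)
    }
  }
  sims <- bind_rows(sims)
  asg <- sims %>% filter(.data$assigned)
  if (nrow(asg) < 20) abort("too few simulated assignments to place the confidence threshold; increase n_sims")

  asg <- asg %>% arrange(.data$delta)
  # smallest threshold whose exceedance set is >= confidence correct
  thr <- NA_real_; rate <- NA_real_
  cand <- c(0, unique(asg$delta))
  for (t in cand) {
    sel <- asg$delta >= t
    if (!any(sel)) break
    r <- mean(asg$correct[sel])
    if (r >= confidence) { thr <- t; rate <- r; break }
  }
  if (is.na(thr)) {
    thr <- max(asg$delta) + 1e-9
    rate <- 1.0
    warn("target confidence not reachable at any observed Delta; threshold set above all observations")
  }
  structure(list(delta_threshold = thr, achieved_rate = rate,
                 n_assignments = nrow(asg), n_sims = n_sims,
                 sampled_fraction = sampled_fraction, confidence = confidence,
                 error_rate = error_rate, sims = sims),
            class = "parentage_calibration")
}

# Mendelian offspring of two rows of gt, with per-allele error: with
# probability e an allele copy is replaced by a population draw
simulate_offspring_call <- function(gt, ia, ib, freqs, error_rate) {
  loci <- gt_loci(gt)
  ftab <- freq_lookup(freqs)
  out <- lapply(loci, function(l) {
    ga <- gt[[l]][[ia]]; gb <- gt[[l]][[ib]]
    if (length(ga) != 2 || length(gb) != 2) return(integer(0))
    al <- c(ga[sample.int(2, 1)], gb[sample.int(2, 1)])
    err <- stats::runif(2) < error_rate
    if (any(err)) {
      f <- ftab[[l]]
      al[err] <- as.integer(names(f))[sample.int(length(f), sum(err),
                                                 replace = TRUE, prob = f)]
    }
    sort(al)
  })
  setNames(out, loci)
}

#' @export
print.parentage_calibration <- function(x, ...) {
  cat(sprintf("<parentage_calibration: Delta threshold %.3f (%.1f%% correct among %d assignments, %d sims)>\n",
              x$delta_threshold, 100 * x$achieved_rate, x$n_assignments, x$n_sims))
  invisible(x)
}

#' Infer high-confidence parent-offspring trios
#'
#' Runs the trio search over the unique diploid genotype set and accepts
#' the best trio of each offspring when its Delta reaches the calibrated
#' threshold and its mismatch count is within the cap. Parent pairs are
#' unordered (ids sorted): the markers cannot tell which parent was seed
#' vs pollen donor.
#'
#' @param gt Unique diploid `genotype_tbl`.
#' @param calibration A `parentage_calibration`; required for the
#'   confidence flag.
#' @inheritParams enumerate_trios
#' @return Tibble of accepted trios: `offspring_id`, `parent_a`,
#'   `parent_b`, `lod`, `delta`, `n_mismatch`, `confidence` (`"high_95"`).
#' @export
infer_trios <- function(gt, calibration, error_rate = NULL, max_mismatch = 1) {
  error_rate <- error_rate %||% calibration$error_rate
  trios <- enumerate_trios(gt, error_rate = error_rate,
                           max_mismatch = max_mismatch)
  accepted <- trios %>%
    filter(.data$rank == 1,
           .data$delta >= calibration$delta_threshold,
           .data$n_mismatch <= max_mismatch) %>%
    mutate(confidence = "high_95") %>%
    select("offspring_id", "parent_a", "parent_b", "lod", "delta",
           "n_mismatch", "confidence") %>%
    arrange(.data$offspring_id)
  accepted
}
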