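#' Per-locus allele frequencies
#'
#' Counts every allele copy of the strictly diploid calls (missing and
#' triallelic calls excluded) and normalizes per locus within each group.
#'
#' @param gt A `genotype_tbl`.
#' @param group_by `NULL` for a single pooled group, the name of a metadata
#'   column of `gt`, or a vector of group labels of length `nrow(gt)`
#'   (`NA` labels are excluded).
#' @return Tibble with columns `group`, `locus`, `allele`, `count`, `freq`,
#'   `n_copies` (gene copies scored at that locus in that group). Frequencies
#'   sum to one within each `group`/`locus`. Groups with no scored copies at
#'   a locus have no rows and trigger a warning.
#' @export
allele_frequencies <- function(gt, group_by = NULL) {
  grp <- resolve_grouping(gt, group_by)
  keep <- !is.na(grp)
  if (!any(keep)) abort("no accessions with a group label")
  gt2 <- keep_rows(gt, keep)
  grp <- grp[keep]
  loci <- gt_loci(gt2)

  parts <- lapply(loci, function(l) {
    m <- locus_diploid_matrix(gt2, l)
    ok <- !is.na(m[, 1])
    if (!any(ok)) return(NULL)
    tibble(group = rep(grp[ok], 2), locus = l,
           allele = c(m[ok, 1], m[ok, 2]))
  })
  counts <- bind_rows(parts) %>%
    count(.data$group, .data$locus, .data$allele, name = "count") %>%
    group_by(.data$group, .data$locus) %>%
    mutate(n_copies = sum(.data$count), freq = .data$count / .data$n_copies) %>%
    ungroup() %>%
    select("group", "locus", "allele", "count", "freq", "n_copies") %>%
    arrange(.data$group, match(.data$locus, loci), .data$allele)

  missing_cells <- setdiff(
    paste(rep(unique(grp), each = length(loci)), loci),
    paste(counts$group, counts$locus)
  )
  if (length(missing_cells) > 0) {
    warn(sprintf("no scored gene copies for %d group/locus combination(s): %s",
                 length(missing_cells),
                 paste(utils::head(missing_cells, 3), collapse = "; ")))
  }
  counts
}

# group_by -> character vector of labels (NA = unassigned)
resolve_grouping <- function(gt, group_by) {
  if (is.null(group_by)) return(rep("all", nrow(gt)))
  if (is.character(group_by) && length(group_by) == 1 && group_by %in% names(gt)) {
    return(as.character(gt[[group_by]]))
  }
  if (length(group_by) != nrow(gt)) {
    abort("`group_by` must be NULL, a metadata column name, or one label per accession")
  }
  as.character(group_by)
}

check_normalized <- function(freqs) {
  s <- freqs %>% group_by(.data$group, .data$locus) %>%
    summarise(s = sum(.data$freq), .groups = "drop")
  if (any(abs(s$s - 1) > 1e-9)) abort("allele frequencies are not normalized per locus")
  invisible(freqs)
}

#' Probability of identity
#'
#' For each locus, the probability that two random unrelated genotypes drawn
#' from the same allele frequencies share their genotype:
#' \deqn{P_{ID} = \sum_i p_i^4 + \sum_{i<j} (2 p_i p_j)^2.}
#' The multilocus probability is the product over loci (independence
#' assumed); retrieve it with [cumulative_pid_report()] or by grouping.
#'
#' @param freqs Tibble from [allele_frequencies()].
#' @return Tibble with `group`, `locus`, `pid`.
#' @export
probability_of_identity <- function(freqs) {
  check_normalized(freqs)
  freqs %>%
    group_by(.data$group, .data$locus) %>%
    summarise(pid = sum(.data$freq^4) +
                2 * ((sum(.data$freq^2))^2 - sum(.data$freq^4)),
              .groups = "drop")
}

#' Rarefied allelic richness at a locus
#'
#' Expected number of distinct alleles in a random draw of `g` gene copies
#' without replacement from the observed copies (hypergeometric
#' rarefaction): \eqn{A_R(g) = \sum_i [1 - C(N - N_i, g)/C(N, g)]} for
#' allele copy counts \eqn{N_i} summing to \eqn{N}.
#'
#' @param counts Positive integer allele copy counts.
#' @param g Number of gene copies to rarefy to; `g <= sum(counts)`.
#' @return Expected allele count (numeric).
#' @export
allelic_richness <- function(counts, g) {
  counts <- as.integer(counts)
  if (any(counts <= 0)) abort("allele counts must be positive")
  n_tot <- sum(counts)
  if (g > n_tot) abort(sprintf("g = %d exceeds available gene copies (%d)", g, n_tot))
  if (g < 1) abort("g must be >= 1")
  sum(1 - exp(lchoose(n_tot - counts, g) - lchoose(n_tot, g)))
}

#' Per-locus diversity statistics
#'
#' For each group and locus: gene copies scored (`n_copies`), allele count
#' (`n_a`), rare alleles below the 5 % and 1 % frequency thresholds (`n_b`,
#' `n_b_01`), effective allele number (`n_e = 1/\sum p_i^2`), observed
#' heterozygosity (`ho`, fraction of scored diploids with two distinct
#' alleles), Nei's gene diversity with (`he`) and without
#' (`he_uncorrected`) the small-sample correction \eqn{N/(N-1)}, and
#' rarefied allelic richness `a_r` at `rarefy_to` gene copies.
#'
#' @inheritParams allele_frequencies
#' @param rare_threshold Frequency below which an allele is rare (default
#'   0.05, strictly below; a 1 % column is always reported too).
#' @param rarefy_to `"auto"` (smallest `n_copies` over all group/locus
#'   cells) or an integer number of gene copies; cells with fewer copies get
#'   `NA` richness.
#' @return Tibble, one row per `group`/`locus`.
#' @seealso [diversity_summary()] for across-locus means.
#' @export
diversity_stats <- function(gt, group_by = NULL, rare_threshold = 0.05,
                            rarefy_to = "auto") {
  grp <- resolve_grouping(gt, group_by)
  freqs <- allele_frequencies(gt, group_by)
  g_target <- if (identical(rarefy_to, "auto")) min(freqs$n_copies) else as.integer(rarefy_to)

  stats <- freqs %>%
    group_by(.data$group, .data$locus) %>%
    summarise(
      n_copies = .data$n_copies[1],
      n_a = dplyr::n(),
      n_b = sum(.data$freq < rare_threshold),
      n_b_01 = sum(.data$freq < 0.01),
      n_e = 1 / sum(.data$freq^2),
      he_uncorrected = 1 - sum(.data$freq^2),
      he = .data$n_copies[1] / (.data$n_copies[1] - 1) * (1 - sum(.data$freq^2)),
      a_r = if (g_target <= .data$n_copies[1])
        allelic_richness(.data$count, g_target) else NA_real_,
      .groups = "drop"
    )

  ho <- lapply(gt_loci(gt), function(l) {
    m <- locus_diploid_matrix(gt, l)
    ok <- !is.na(m[, 1]) & !is.na(grp)
    if (!any(ok)) return(NULL)
    tibble(group = grp[ok], locus = l, het = m[ok, 1] != m[ok, 2]) %>%
      group_by(.data$group, .data$locus) %>%
      summarise(ho = mean(.data$het), .groups = "drop")
  })
  out <- left_join(stats, bind_rows(ho), by = c("group", "locus")) %>%
    select("group", "locus", "n_copies", "n_a", "n_b", "n_b_01",
           "n_e", "ho", "he", "he_uncorrected", "a_r")
  attr(out, "rarefy_to") <- g_target
  out
}

#' Across-locus means of diversity statistics
#'
#' @param stats Output of [diversity_stats()].
#' @return One row per group with locus-averaged statistics.
#' @export
diversity_summary <- function(stats) {
  stats %>%
    group_by(.data$group) %>%
    summarise(n_loci = dplyr::n(),
              across(c("n_a", "n_b", "n_b_01", "n_e", "ho", "he", "a_r"),
                     ~ mean(.x, na.rm = TRUE)),
              .groups = "drop")
}

#' Private and unique alleles per group
#'
#' A *private* allele occurs in exactly one group of the partition; a
#' *unique* allele is carried by exactly one accession in the whole table
#' (counted on diploid calls, irrespective of grouping).
#'
#' @inheritParams allele_frequencies
#' @return Tibble with `group`, `n_alleles` (total distinct alleles observed
#'   in the group), `n_private`, `n_unique` (unique alleles carried by the
#'   group's accessions).
#' @export
private_and_unique_alleles <- function(gt, group_by) {
  grp <- resolve_grouping(gt, group_by)
  if (dplyr::n_distinct(grp[!is.na(grp)]) < 2) abort("need at least 2 groups")
  long <- gt_alleles_long(gt) %>%
    mutate(group = grp[match(.data$accession_id, gt$accession_id)])

  carriers <- long %>%
    distinct(.data$locus, .data$allele, .data$accession_id) %>%
    count(.data$locus, .data$allele, name = "n_carriers")
  in_groups <- long %>%
    filter(!is.na(.data$group)) %>%
    distinct(.data$locus, .data$allele, .data$group)
  n_groups_of <- in_groups %>% count(.data$locus, .data$allele, name = "n_groups")

  in_groups %>%
    left_join(n_groups_of, by = c("locus", "allele")) %>%
    left_join(carriers, by = c("locus", "allele")) %>%
    group_by(.data$group) %>%
    summarise(n_alleles = dplyr::n(),
              n_private = sum(.data$n_groups == 1),
              n_unique = sum(.data$n_carriers == 1),
              .groups = "drop")
}

#' Chi-square tests of frequent-allele distributions across groups
#'
#' For each locus, alleles with pooled frequency above `frequent_threshold`
#' form the columns of a group-by-allele copy-count table (all remaining
#' alleles pooled into one `other` column to stabilize expected counts) and
#' a Pearson chi-square test of homogeneity is performed. When any expected
#' cell falls below 1 the asymptotic p-value is unreliable and a Monte Carlo
#' p-value (`b` table simulations) is substituted.
#'
#' @inheritParams allele_frequencies
#' @param frequent_threshold Pooled frequency above which an allele counts
#'   as frequent (default 0.05, strictly above).
#' @param b Monte Carlo replicates for the fallback p-value.
#' @return Tibble: `locus`, `statistic`, `df`, `p_value`, `simulated`.
#' @export
frequent_allele_chi2 <- function(gt, group_by, frequent_threshold = 0.05,
                                 b = 10000) {
  freqs <- allele_frequencies(gt, group_by)
  if (dplyr::n_distinct(freqs$group) < 2) abort("need at least 2 groups")
  pooled <- freqs %>%
    group_by(.data$locus, .data$allele) %>%
    summarise(count = sum(.data$count), .groups = "drop") %>%
    group_by(.data$locus) %>%
    mutate(freq = .data$count / sum(.data$count)) %>%
    ungroup()

  out <- lapply(unique(freqs$locus), function(l) {
    freq_alleles <- pooled$allele[pooled$locus == l & pooled$freq > frequent_threshold]
    sub <- freqs %>% filter(.data$locus == l) %>%
      mutate(col = ifelse(.data$allele %in% freq_alleles,
                          as.character(.data$allele), "other"))
    tab <- sub %>% group_by(.data$group, .data$col) %>%
      summarise(count = sum(.data$count), .groups = "drop") %>%
      tidyr::pivot_wider(names_from = "col", values_from = "count", values_fill = 0L)
    m <- as.matrix(tab[-1])
    if (ncol(m) < 2) {
      return(tibble(locus = l, statistic = 0, df = 0L, p_value = 1, simulated = FALSE))
    }
    suppressWarnings({
      asym <- stats::chisq.test(m, correct = FALSE)
      need_sim <- any(asym$expected < 1)
      if (need_sim) {
        sim <- stats::chisq.test(m, simulate.p.value = TRUE, B = b)
        tibble(locus = l, statistic = unname(sim$statistic),
               df = as.integer((nrow(m) - 1) * (ncol(m) - 1)),
               p_value = sim$p.value, simulated = TRUE)
      } else {
        tibble(locus = l, statistic = unname(asym$statistic),
               df = as.integer(asym$parameter), p_value = asym$p.value,
               simulated = FALSE)
      }
    })
  })
  bind_rows(out)
}
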