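#' Allelic difference between two diploid calls
#'
#' Compares two diploid single-locus genotypes as multisets of two allele
#' copies and returns `2 - |intersection|`: 0 when identical, 1 when the
#' genotypes share exactly one allele copy, 2 when fully disjoint. Missing
#' or non-diploid calls yield `NA` so callers can skip the locus.
#'
#' @param a,b Integer vectors of sorted allele sizes (length 2 for a valid
#'   comparison).
#' @return Integer 0, 1, 2, or `NA`.
#' @export
locus_difference <- function(a, b) {
  if (length(a) != 2 || length(b) != 2) return(NA_integer_)
  if (a[1] == b[1] && a[2] == b[2]) return(0L)
  if (a[1] == b[1] || a[1] == b[2] || a[2] == b[1] || a[2] == b[2]) return(1L)
  2L
}

# pairwise locus-difference profile between all rows, vectorized per locus.
# Returns list(d1 = matrix of counts of single-allele differences,
#              d2 = matrix of counts of disjoint loci,
#              shared = matrix of co-scored diploid locus counts)
pairwise_difference_counts <- function(gt) {
  n <- nrow(gt)
  d1 <- matrix(0L, n, n)
  d2 <- matrix(0L, n, n)
  shared <- matrix(0L, n, n)
  for (loc in gt_loci(gt)) {
    m <- locus_diploid_matrix(gt, loc)
    ok <- !is.na(m[, 1])
    if (sum(ok) < 2) next
    x1 <- m[, 1]; x2 <- m[, 2]
    okm <- outer(ok, ok, `&`)
    eq <- outer(x1, x1, `==`) & outer(x2, x2, `==`)
    share <- outer(x1, x1, `==`) | outer(x1, x2, `==`) |
      outer(x2, x1, `==`) | outer(x2, x2, `==`)
    shared <- shared + okm
    d1 <- d1 + (okm & !eq & share)
    d2 <- d2 + (okm & !share)
  }
  list(d1 = d1, d2 = d2, shared = shared)
}

#' Are two accessions duplicates?
#'
#' Two diploid SSR profiles are treated as the same genotype when, over the
#' loci scored in both, they are identical or differ by a single allele copy
#' at no more than `max_mismatch_loci` loci, with no locus fully disjoint.
#' This tolerance absorbs occasional genotyping errors and spontaneous SSR
#' mutations. Pairs sharing fewer than `min_shared_loci` co-scored loci are
#' incomparable and reported as non-duplicates.
#'
#' @param a,b Named lists (or `genotype_tbl` rows) of allele calls per
#'   locus: integer vectors as in [locus_difference()].
#' @param max_mismatch_loci Maximum number of loci allowed to differ by one
#'   allele copy (default 2).
#' @param min_shared_loci Minimum co-scored diploid loci for a comparison to
#'   count (default 12 of a 16-locus panel).
#' @return Logical.
#' @export
are_duplicates <- function(a, b, max_mismatch_loci = 2, min_shared_loci = 12) {
  loci <- intersect(names(a), names(b))
  diffs <- vapply(loci, function(l) locus_difference(a[[l]], b[[l]]), integer(1))
  diffs <- diffs[!is.na(diffs)]
  if (length(diffs) < min_shared_loci) return(FALSE)
  sum(diffs == 1L) <= max_mismatch_loci && !any(diffs == 2L)
}

#' Find duplicate (clonal) groups and reduce to unique genotypes
#'
#' Builds the graph of pairwise duplicates under the [are_duplicates()]
#' tolerance and takes its connected components as duplicate groups, so
#' group membership is transitive even when two distant members exceed the
#' pairwise tolerance. One representative per group (the lexicographically
#' smallest `accession_id`) is retained in the reduced table together with
#' all singletons.
#'
#' Accessions flagged as putative triploids by [flag_triploids()] are
#' excluded from the comparison by default (`exclude_triploids = TRUE`) and
#' do not appear in either the groups or the reduced table; set it to
#' `FALSE` to compare them on their diploid loci.
#'
#' @param gt A `genotype_tbl`.
#' @inheritParams are_duplicates
#' @param exclude_triploids Drop putative triploids before grouping.
#' @return A list of class `duplicate_groups`: `groups` (tibble `group_id`,
#'   `member`, `representative`; only true groups of size >= 2), `unique`
#'   (the reduced `genotype_tbl`), and `excluded_triploids` (character).
#' @export
find_duplicate_groups <- function(gt, max_mismatch_loci = 2, min_shared_loci = 12,
                                  exclude_triploids = TRUE) {
  excluded <- character(0)
  if (exclude_triploids) {
    fl <- flag_triploids(gt)
    excluded <- fl$accession_id[fl$is_putative_triploid]
    gt <- keep_rows(gt, !gt$accession_id %in% excluded)
  }
  n <- nrow(gt)
  if (n == 0) {
    return(structure(list(groups = tibble(group_id = character(), member = character(),
                                          representative = character()),
                          unique = gt, excluded_triploids = excluded),
                     class = "duplicate_groups"))
  }
  pc <- pairwise_difference_counts(gt)
  adj <- pc$shared >= min_shared_loci & pc$d2 == 0L & pc$d1 <= max_mismatch_loci
  diag(adj) <- FALSE

  comp <- connected_components(adj)
  ids <- gt$accession_id
  groups <- tibble(accession_id = ids, comp = comp) %>%
    group_by(.data$comp) %>%
    filter(n() >= 2) %>%
    ungroup()
  if (nrow(groups) > 0) {
    groups <- groups %>%
      group_by(.data$comp) %>%
      mutate(representative = min(.data$accession_id)) %>%
      ungroup() %>%
      arrange(.data$representative, .data$accession_id)
    groups <- groups %>%
      mutate(group_id = paste0("DUP", formatC(match(.data$representative,
                                                    unique(.data$representative)),
                                              width = 3, flag = "0"))) %>%
      select(group_id, member = "accession_id", "representative")
  } else {
    groups <- tibble(group_id = character(), member = character(),
                     representative = character())
  }
  drop <- setdiff(groups$member, groups$representative)
  reduced <- keep_rows(gt, !gt$accession_id %in% drop)
  structure(list(groups = groups, unique = reduced, excluded_triploids = excluded),
            class = "duplicate_groups")
}

# iterative union-find on a logical adjacency matrix
connected_components <- function(adj) {
  n <- nrow(adj)
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  edges <- which(adj & upper.tri(adj), arr.ind = TRUE)
  for (k in seq_len(nrow(edges))) {
    ri <- find(edges[k, 1]); rj <- find(edges[k, 2])
    if (ri != rj) parent[ri] <- rj
  }
  roots <- vapply(seq_len(n), find, integer(1))
  match(roots, unique(roots))
}

#' @export
print.duplicate_groups <- function(x, ...) {
  cat(sprintf("<duplicate_groups: %d groups covering %d accessions; %d unique genotypes; %d triploids excluded>\n",
              dplyr::n_distinct(x$groups$group_id), nrow(x$groups),
              nrow(x$unique), length(x$excluded_triploids)))
  print(x$groups, ...)
  invisible(x)
}

#' Flag putative triploids
#'
#' An accession is declared a putative triploid when at least
#' `min_triallelic_loci` loci show three distinct alleles.
#'
#' @param gt A `genotype_tbl`.
#' @param min_triallelic_loci Threshold on triallelic loci (default 3).
#' @return Tibble: `accession_id`, `n_triallelic_loci`, `is_putative_triploid`.
#' @export
flag_triploids <- function(gt, min_triallelic_loci = 3) {
  loci <- gt_loci(gt)
  tri <- rowSums(vapply(loci, function(l) {
    vapply(gt[[l]], function(a) length(a) == 3 && length(unique(a)) == 3, logical(1))
  }, logical(nrow(gt))))
  tibble(accession_id = gt$accession_id,
         n_triallelic_loci = as.integer(unname(tri)),
         is_putative_triploid = unname(tri >= min_triallelic_loci))
}

#' Cumulative probability of identity for a duplicate report
#'
#' Convenience wrapper around [probability_of_identity()] returning the
#' multilocus product only, used to qualify the confidence of duplicate
#' matches: the probability that two unrelated genotypes share a full
#' multilocus profile by chance.
#'
#' @param freqs Allele frequencies from [allele_frequencies()].
#' @return Named numeric, one cumulative probability per group.
#' @export
cumulative_pid_report <- function(freqs) {
  pid <- probability_of_identity(freqs)
  out <- pid %>% group_by(.data$group) %>%
    summarise(cum = prod(.data$pid), .groups = "drop")
  setNames(out$cum, out$group)
}
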