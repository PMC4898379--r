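#' Simple-matching dissimilarity between diploid SSR profiles
#'
#' Per-locus similarity between two diploid calls is the number of shared
#' allele copies (multiset overlap) divided by the ploidy (2); the
#' dissimilarity between two accessions is one minus the mean similarity
#' over the loci scored in both:
#' \deqn{d(a,b) = 1 - \frac{1}{L_{ab}} \sum_l \frac{shared_l}{2}.}
#' Pairs with no comparable locus get `NA` (with a warning).
#'
#' @param gt A `genotype_tbl`; triallelic profiles are dropped.
#' @return A [stats::dist] object labeled by `accession_id`.
#' @export
simple_matching_dissimilarity <- function(gt) {
  gt <- filter_diploid(gt)
  n <- nrow(gt)
  shared_sum <- matrix(0, n, n)
  n_loci <- matrix(0, n, n)
  for (loc in gt_loci(gt)) {
    m <- locus_diploid_matrix(gt, loc)
    ok <- !is.na(m[, 1])
    if (sum(ok) < 2) next
    x1 <- m[, 1]; x2 <- m[, 2]
    x1[!ok] <- -1L; x2[!ok] <- -2L  # sentinels: never match anything
    okm <- outer(ok, ok, `&`)
    eq <- outer(x1, x1, `==`) & outer(x2, x2, `==`)
    share1 <- outer(x1, x1, `==`) | outer(x1, x2, `==`) |
      outer(x2, x1, `==`) | outer(x2, x2, `==`)
    shared <- (eq * 2 + (!eq & share1) * 1) * okm
    shared_sum <- shared_sum + shared
    n_loci <- n_loci + okm
  }
  d <- 1 - (shared_sum / 2) / n_loci
  if (any(!is.finite(d[upper.tri(d)]))) {
    warn("some accession pairs share no comparable locus (NA dissimilarity)")
  }
  diag(d) <- 0
  rownames(d) <- colnames(d) <- gt$accession_id
  stats::as.dist(d)
}

#' Principal coordinate analysis
#'
#' Classical metric scaling of a dissimilarity matrix: double-centering of
#' \eqn{-d^2/2} followed by eigendecomposition. Axes with positive
#' eigenvalues are returned; negative eigenvalues (a consequence of
#' non-Euclidean dissimilarities) are reported, not corrected, unless
#' `correction = "cailliez"`.
#'
#' @param dm A [stats::dist] or symmetric matrix, no `NA`s.
#' @param correction `"none"` or `"cailliez"` (additive constant making the
#'   configuration Euclidean).
#' @return Object of class `pcoa_result`: `points` (tibble with
#'   `accession_id` and `axis1`, `axis2`, ...), `eigenvalues` (all,
#'   including negatives), `prop_var` (share of the positive eigenvalue
#'   sum per returned axis), `n_negative`.
#' @export
pcoa <- function(dm, correction = c("none", "cailliez")) {
  correction <- match.arg(correction)
  dm <- stats::as.dist(dm)
  if (anyNA(dm)) {
    abort("dissimilarity matrix contains NA; impute or drop the accessions involved")
  }
  n <- attr(dm, "Size")
  # cmdscale warns when fewer than k axes have positive eigenvalues; the
  # eigenvalue spectrum is reported explicitly, so the warning is redundant
  fit <- suppressWarnings(stats::cmdscale(dm, k = n - 1, eig = TRUE,
                                          add = correction == "cailliez"))
  eig <- fit$eig
  pos <- which(eig > 1e-9)
  pts <- fit$points[, pos, drop = FALSE]
  colnames(pts) <- paste0("axis", seq_along(pos))
  labels <- attr(dm, "Labels") %||% as.character(seq_len(n))
  structure(list(
    points = bind_cols(tibble(accession_id = labels), as_tibble(pts)),
    eigenvalues = eig,
    prop_var = eig[pos] / sum(eig[pos]),
    n_negative = sum(eig < -1e-9),
    correction = correction
  ), class = "pcoa_result")
}

#' @export
print.pcoa_result <- function(x, ...) {
  cat(sprintf("<pcoa: %d points, %d positive axes (%d negative eigenvalues%s)>\n",
              nrow(x$points), length(x$prop_var), x$n_negative,
              if (x$correction == "cailliez") ", Cailliez-corrected" else ""))
  cat(sprintf("  axis variance: %s\n",
              paste(sprintf("%.1f%%", 100 * utils::head(x$prop_var, 4)),
                    collapse = ", ")))
  invisible(x)
}

#' Unweighted neighbor-joining tree
#'
#' Saitou-Nei neighbor joining (via [ape::nj()]) on a dissimilarity
#' matrix. Negative branch lengths are clamped to zero for serialization;
#' the raw lengths are kept in the `raw_edge_length` attribute.
#'
#' @param dm A [stats::dist] or symmetric matrix without `NA`; 2 labels
#'   give the degenerate single-edge tree.
#' @param newick_path Optional path; when given, the (clamped) tree is
#'   written in Newick format.
#' @return An [ape::phylo] tree.
#' @export
neighbor_joining <- function(dm, newick_path = NULL) {
  m <- as.matrix(dm)
  if (anyNA(m[upper.tri(m)])) abort("dissimilarity matrix contains NA")
  if (nrow(m) < 2) abort("need at least 2 labels")
  if (nrow(m) == 2) {
    tr <- ape::read.tree(text = sprintf("(%s:%.10g,%s:0);",
                                        rownames(m)[1], m[1, 2], rownames(m)[2]))
  } else {
    tr <- ape::nj(stats::as.dist(m))
  }
  raw <- tr$edge.length
  tr$edge.length <- pmax(raw, 0)
  attr(tr, "raw_edge_length") <- raw
  if (!is.null(newick_path)) ape::write.tree(tr, file = newick_path)
  tr
}
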