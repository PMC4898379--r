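#' Weir-Cockerham F_ST (theta)
#'
#' Multi-allelic Weir-Cockerham (1984) variance-component estimator of
#' F_ST for co-dominant diploid data: the among-population (`a`),
#' between-individual (`b`) and within-individual (`c`) components are
#' summed over alleles and loci and theta is the ratio of sums
#' `sum(a) / sum(a + b + c)` (not a mean of per-locus ratios).
#'
#' @param gt A `genotype_tbl` (triallelic profiles dropped).
#' @param group_by Grouping as in [allele_frequencies()]; accessions with
#'   `NA` labels are excluded.
#' @return A single numeric theta estimate.
#' @export
wc_theta <- function(gt, group_by) {
  grp <- resolve_grouping(gt, group_by)
  dip <- diploid_rows(gt)
  keep <- !is.na(grp) & dip
  pre <- wc_precompute(keep_rows(gt, keep))
  wc_theta_from_pre(pre, as.integer(factor(grp[keep])))
}

# per-individual allele copy counts and heterozygote indicators, stacked
# over loci, for fast recomputation under permutation
wc_precompute <- function(gt) {
  loci <- gt_loci(gt)
  n <- nrow(gt)
  cnt_cols <- list(); het_cols <- list(); locus_of <- integer(0)
  scored <- matrix(FALSE, n, length(loci))
  for (j in seq_along(loci)) {
    m <- locus_diploid_matrix(gt, loci[j])
    ok <- !is.na(m[, 1])
    scored[, j] <- ok
    lev <- sort(unique(as.integer(na.omit(as.vector(m)))))
    cnt <- matrix(0L, n, length(lev))
    cnt[ok, ] <- (outer(m[ok, 1], lev, `==`) + outer(m[ok, 2], lev, `==`))
    cnt_cols[[j]] <- cnt
    het_cols[[j]] <- (cnt == 1L) * 1L
    locus_of <- c(locus_of, rep(j, length(lev)))
  }
  list(cnt = do.call(cbind, cnt_cols), het = do.call(cbind, het_cols),
       scored = scored * 1L, locus_of = locus_of, n = n, n_loci = length(loci))
}

# theta from precomputed incidence matrices and integer group labels
wc_theta_from_pre <- function(pre, grp, return_components = FALSE) {
  r <- max(grp)
  G <- matrix(0, r, pre$n)
  G[cbind(grp, seq_len(pre$n))] <- 1
  n_il <- G %*% pre$scored               # r x L individuals scored per locus
  csum <- G %*% pre$cnt                  # r x sumJ allele copy counts
  hsum <- G %*% pre$het                  # r x sumJ heterozygote carriers

  lo <- pre$locus_of
  n_i <- n_il[, lo, drop = FALSE]        # r x sumJ sample sizes per column
  ok_col <- colSums(n_i > 0) == r & colSums(n_i) > r  # all pops scored
  a_tot <- b_tot <- c_tot <- 0
  p_i <- csum / pmax(2 * n_i, 1)
  h_i <- hsum / pmax(n_i, 1)
  for (col in which(ok_col)) {
    ni <- n_i[, col]
    nbar <- mean(ni)
    if (nbar <= 1) next
    nc <- (r * nbar - sum(ni^2) / (r * nbar)) / (r - 1)
    if (nc <= 0) next
    pbar <- sum(ni * p_i[, col]) / (r * nbar)
    s2 <- sum(ni * (p_i[, col] - pbar)^2) / ((r - 1) * nbar)
    hbar <- sum(ni * h_i[, col]) / (r * nbar)
    a <- (nbar / nc) * (s2 - (pbar * (1 - pbar) - (r - 1) / r * s2 - hbar / 4) / (nbar - 1))
    b <- (nbar / (nbar - 1)) * (pbar * (1 - pbar) - (r - 1) / r * s2 -
                                  (2 * nbar - 1) / (4 * nbar) * hbar)
    cc <- hbar / 2
    a_tot <- a_tot + a; b_tot <- b_tot + b; c_tot <- c_tot + cc
  }
  denom <- a_tot + b_tot + c_tot
  th <- if (denom > 0) a_tot / denom else NA_real_
  if (return_components) list(theta = th, a = a_tot, b = b_tot, c = c_tot) else th
}

#' Pairwise F_ST with permutation significance
#'
#' Weir-Cockerham theta for every pair of groups, with a p-value from
#' permuting individuals (both allele copies together) between the two
#' groups: `p = (#{theta_perm >= theta_obs} + 1) / (n_permutations + 1)`.
#' Raw (possibly negative) estimates are kept in `fst`; `fst_clamped`
#' floors them at 0 for reporting.
#'
#' @inheritParams wc_theta
#' @param n_permutations Number of label permutations (default 999).
#' @param seed Integer seed for the permutations.
#' @param min_group_size Pairs with a group below this many scored diploids
#'   are reported `NA`.
#' @return Tibble of class `fst_pairwise`: `group1`, `group2`, `fst`,
#'   `fst_clamped`, `p_value`, `n1`, `n2`. Use [as.matrix()] for the square
#'   form.
#' @export
pairwise_fst <- function(gt, group_by, n_permutations = 999, seed = 1L,
                         min_group_size = 2) {
  grp <- resolve_grouping(gt, group_by)
  keep <- !is.na(grp) & diploid_rows(gt)
  gt <- keep_rows(gt, keep)
  grp <- grp[keep]
  groups <- sort(unique(grp))
  if (length(groups) < 2) abort("need at least 2 groups")
  set.seed(as.integer(seed))
  out <- list()
  for (i in seq_along(groups)) {
    for (j in seq_len(i - 1)) {
      g1 <- groups[j]; g2 <- groups[i]
      sel <- grp %in% c(g1, g2)
      sub <- keep_rows(gt, sel)
      lab <- as.integer(factor(grp[sel], levels = c(g1, g2)))
      n1 <- sum(lab == 1); n2 <- sum(lab == 2)
      if (min(n1, n2) < min_group_size) {
        out[[length(out) + 1]] <- tibble(group1 = g1, group2 = g2,
                                         fst = NA_real_, fst_clamped = NA_real_,
                                         p_value = NA_real_, n1 = n1, n2 = n2)
        next
      }
      pre <- wc_precompute(sub)
      obs <- wc_theta_from_pre(pre, lab)
      perm_ge <- 0L
      for (b in seq_len(n_permutations)) {
        perm_ge <- perm_ge +
          (wc_theta_from_pre(pre, sample(lab)) >= obs)
      }
      out[[length(out) + 1]] <- tibble(
        group1 = g1, group2 = g2, fst = obs, fst_clamped = max(obs, 0),
        p_value = (perm_ge + 1) / (n_permutations + 1), n1 = n1, n2 = n2)
    }
  }
  structure(bind_rows(out), class = c("fst_pairwise", class(tibble::tibble())),
            groups = groups)
}

#' @export
as.matrix.fst_pairwise <- function(x, value = "fst", ...) {
  groups <- attr(x, "groups")
  m <- matrix(0, length(groups), length(groups), dimnames = list(groups, groups))
  for (r in seq_len(nrow(x))) {
    m[x$group1[r], x$group2[r]] <- m[x$group2[r], x$group1[r]] <- x[[value]][r]
  }
  m
}

#' Analysis of molecular variance (AMOVA)
#'
#' Two-level AMOVA (among vs within groups) on allele copies under the
#' infinite-allele 0/1 mismatch distance: two copies are at squared
#' distance 1 when they carry different alleles. Sums of squares follow the
#' standard distance formulation, variance components are estimated per
#' locus and summed, and the among-group component is tested by permuting
#' individuals (both copies together) across groups.
#'
#' @inheritParams pairwise_fst
#' @return Object of class `amova_result` with fields `table` (tibble:
#'   source, df, SS, variance component sigma2, percentage), `phi_st`,
#'   `p_value`, `n_permutations`. `tidy()` returns the table, `glance()`
#'   a one-row summary.
#' @export
amova <- function(gt, group_by, n_permutations = 999, seed = 1L) {
  grp <- resolve_grouping(gt, group_by)
  keep <- !is.na(grp) & diploid_rows(gt)
  gt <- keep_rows(gt, keep)
  grp <- as.integer(factor(grp[keep]))
  G <- max(grp)
  pre <- wc_precompute(gt)
  obs <- amova_components(pre, grp)
  p_val <- NA_real_
  if (G >= 2) {
    set.seed(as.integer(seed))
    ge <- 0L
    for (b in seq_len(n_permutations)) {
      ge <- ge + (amova_components(pre, sample(grp))$sigma_a >= obs$sigma_a)
    }
    p_val <- (ge + 1) / (n_permutations + 1)
  }
  total <- obs$sigma_a + obs$sigma_w
  pct_a <- if (total > 0) max(obs$sigma_a, 0) / (max(obs$sigma_a, 0) + obs$sigma_w) * 100 else NA_real_
  tab <- tibble(
    source = c("among_groups", "within_groups"),
    df = c(G - 1L, 2L * nrow(gt) - G),
    ss = c(obs$ss_a, obs$ss_w),
    sigma2 = c(obs$sigma_a, obs$sigma_w),
    percent = c(pct_a, 100 - pct_a)
  )
  structure(list(table = tab, phi_st = obs$sigma_a / total,
                 p_value = p_val, n_permutations = n_permutations,
                 n_groups = G, n_individuals = nrow(gt)),
            class = "amova_result")
}

# haploid-copy sums of squares from per-group allele counts; distances 0/1
amova_components <- function(pre, grp) {
  G <- max(grp)
  Gm <- matrix(0, G, pre$n)
  Gm[cbind(grp, seq_len(pre$n))] <- 1
  csum_g <- Gm %*% pre$cnt                 # G x sumJ
  copies_gl <- 2 * (Gm %*% pre$scored)     # G x L gene copies per group/locus
  lo <- pre$locus_of
  ss_w <- ss_t <- 0
  sigma_a <- sigma_w <- 0
  for (l in seq_len(pre$n_loci)) {
    cols <- which(lo == l)
    ng <- copies_gl[, l]
    use <- ng > 0
    if (sum(use) < 1) next
    Ntot <- sum(ng)
    ctot <- colSums(csum_g[, cols, drop = FALSE])
    sst <- (Ntot - sum(ctot^2) / Ntot) / 2
    ssw <- sum(vapply(which(use), function(g) {
      (ng[g] - sum(csum_g[g, cols]^2) / ng[g]) / 2
    }, numeric(1)))
    ssa <- sst - ssw
    g_eff <- sum(use)
    if (g_eff < 2) next
    df_a <- g_eff - 1
    df_w <- Ntot - g_eff
    n0 <- (Ntot - sum(ng[use]^2) / Ntot) / df_a
    sw <- if (df_w > 0) ssw / df_w else 0
    sa <- (ssa / df_a - sw) / n0
    ss_w <- ss_w + ssw; ss_t <- ss_t + sst
    sigma_a <- sigma_a + sa; sigma_w <- sigma_w + sw
  }
  list(ss_a = ss_t - ss_w, ss_w = ss_w, sigma_a = sigma_a, sigma_w = sigma_w)
}

#' @export
print.amova_result <- function(x, ...) {
  cat(sprintf("<amova: %d groups, %d individuals, Phi_ST = %.4f, p = %s (%d permutations)>\n",
              x$n_groups, x$n_individuals, x$phi_st,
              format(x$p_value), x$n_permutations))
  print(x$table, ...)
  invisible(x)
}

#' @rdname amova
#' @param x An `amova_result`.
#' @param ... Unused.
#' @export
tidy.amova_result <- function(x, ...) x$table

#' @rdname amova
#' @export
glance.amova_result <- function(x, ...) {
  tibble(phi_st = x$phi_st, p_value = x$p_value,
         percent_among = x$table$percent[1],
         n_groups = x$n_groups, n_individuals = x$n_individuals,
         n_permutations = x$n_permutations)
}
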