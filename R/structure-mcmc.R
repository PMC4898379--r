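#' MCMC profiles for the admixture model
#'
#' Named chain-length presets. `"desk"` (2,000 burn-in, 10,000 iterations,
#' 3 replicate runs) is sized for interactive use and testing on data sets
#' of a few hundred accessions; `"paper"` (200,000 burn-in, 500,000
#' iterations, 10 runs) matches the chain lengths customary for full-scale
#' germplasm surveys.
#'
#' @param name `"desk"` or `"paper"`.
#' @return List with `burnin`, `iterations`, `n_runs`, `thin`.
#' @export
structure_profile <- function(name = c("desk", "paper")) {
  switch(match.arg(name),
         desk  = list(burnin = 2000L, iterations = 10000L, n_runs = 3L, thin = 10L),
         paper = list(burnin = 200000L, iterations = 500000L, n_runs = 10L, thin = 50L))
}

# encode diploid calls as allele indices: n x 2L matrix + per-locus levels
gt_index_encode <- function(gt) {
  loci <- gt_loci(gt)
  n <- nrow(gt)
  levels <- vector("list", length(loci))
  geno <- matrix(NA_integer_, n, 2 * length(loci))
  for (j in seq_along(loci)) {
    m <- locus_diploid_matrix(gt, loci[j])
    lev <- sort(unique(as.integer(na.omit(as.vector(m)))))
    levels[[j]] <- lev
    geno[, 2 * j - 1] <- match(m[, 1], lev)
    geno[, 2 * j] <- match(m[, 2], lev)
  }
  list(geno = geno, levels = levels, loci = loci,
       n_alleles = vapply(levels, length, integer(1)),
       accession_id = gt$accession_id)
}

#' Fit the Bayesian admixture model by MCMC
#'
#' Clusters diploid multilocus genotypes into `K` genepools under the
#' admixture model with correlated allele frequencies: each individual has
#' ancestry proportions \eqn{q_i} (Dirichlet(\eqn{\alpha}) prior,
#' \eqn{\alpha} updated by Metropolis), each allele copy carries a latent
#' cluster of origin (Gibbs), and cluster allele frequencies follow an
#' F-model — Dirichlet around inferred ancestral frequencies with
#' cluster-specific drift \eqn{F_k} (Metropolis updates for the ancestral
#' frequencies and \eqn{F_k}). Missing alleles are skipped in the
#' likelihood. Reported `Q` and `P` are posterior means over post-burn-in
#' samples; the model evidence proxy is
#' `lnpd = mean(lnL) - var(lnL)/2` over the same samples.
#'
#' @param gt A `genotype_tbl`; accessions with triallelic calls are dropped.
#' @param K Number of clusters (>= 1).
#' @param burnin,iterations,thin Chain control; defaults from `profile`.
#' @param profile Preset from [structure_profile()].
#' @param seed Integer seed; the run is bit-reproducible given the seed.
#' @param alpha_init Initial Dirichlet admixture parameter (default 1).
#' @param lambda Dirichlet prior parameter for ancestral frequencies.
#' @return Object of class `structure_run`: `Q` (individuals x K, rows sum
#'   to 1), `P` (per-locus cluster x allele frequency matrices), `lnl`
#'   (post-burn-in log-likelihood samples), `lnl_trace`, `lnpd`, `alpha`,
#'   `F`, `accept` (Metropolis acceptance rates), `K`, `accession_id`.
#' @export
run_admixture_mcmc <- function(gt, K, burnin = NULL, iterations = NULL,
                               thin = NULL, profile = "desk", seed = 1L,
                               alpha_init = 1.0, lambda = 1.0) {
  if (K < 1) abort("K must be >= 1")
  prof <- structure_profile(profile)
  burnin <- burnin %||% prof$burnin
  iterations <- iterations %||% prof$iterations
  thin <- thin %||% prof$thin
  gt <- filter_diploid(gt)
  enc <- gt_index_encode(gt)
  if (any(enc$n_alleles < 1)) abort("locus with no scored alleles")
  if (K > 1 && all(enc$n_alleles == 1)) {
    warn("all loci monomorphic: q will converge to the symmetric 1/K solution")
  }

  set.seed(as.integer(seed))
  res <- admixture_mcmc_cpp(enc$geno, enc$n_alleles, as.integer(K),
                            as.integer(burnin), as.integer(iterations),
                            as.integer(thin),
                            alpha_init, lambda,
                            0.025, 10.0,      # alpha Metropolis step, upper bound
                            0.01, 0.01, 0.05, # F init, prior mean, prior sd
                            0.01, 0.05)       # F step, ancestral-freq step
  lnl <- res$lnl
  dimnames(res$Q) <- list(enc$accession_id, paste0("K", seq_len(K)))
  for (j in seq_along(res$P)) {
    dimnames(res$P[[j]]) <- list(paste0("K", seq_len(K)), enc$levels[[j]])
  }
  names(res$P) <- enc$loci
  structure(list(Q = res$Q, P = res$P, lnl = lnl, lnl_trace = res$lnl_trace,
                 lnpd = mean(lnl) - stats::var(lnl) / 2,
                 alpha = res$alpha, F = res$F, accept = res$accept,
                 K = as.integer(K), seed = seed, accession_id = enc$accession_id),
            class = "structure_run")
}

#' @export
print.structure_run <- function(x, ...) {
  cat(sprintf("<structure_run: K = %d, %d individuals, lnPD = %.1f>\n",
              x$K, nrow(x$Q), x$lnpd))
  cat(sprintf("  mean alpha = %.3f; acceptance alpha/F/pA = %.2f/%.2f/%.2f\n",
              mean(x$alpha), x$accept[["alpha"]], x$accept[["F"]],
              x$accept[["pA"]]))
  invisible(x)
}

#' Replicate admixture runs over a range of K
#'
#' Runs [run_admixture_mcmc()] `n_runs` times per value of `K`, with
#' per-run seeds derived deterministically from `seed`.
#'
#' @inheritParams run_admixture_mcmc
#' @param k_range Integer vector of K values (e.g. `1:6`).
#' @param n_runs Replicate runs per K; defaults from `profile`.
#' @return Object of class `structure_sweep`: a list of lists of
#'   `structure_run`, indexed `[[as.character(K)]][[run]]`.
#' @export
structure_sweep <- function(gt, k_range = 1:6, n_runs = NULL, profile = "desk",
                            burnin = NULL, iterations = NULL, thin = NULL,
                            seed = 1L) {
  prof <- structure_profile(profile)
  n_runs <- n_runs %||% prof$n_runs
  set.seed(as.integer(seed))
  seeds <- matrix(sample.int(.Machine$integer.max, length(k_range) * n_runs),
                  nrow = length(k_range))
  runs <- lapply(seq_along(k_range), function(i) {
    lapply(seq_len(n_runs), function(r) {
      run_admixture_mcmc(gt, K = k_range[i], burnin = burnin,
                         iterations = iterations, thin = thin,
                         profile = profile, seed = seeds[i, r])
    })
  })
  names(runs) <- as.character(k_range)
  structure(runs, class = "structure_sweep", k_range = k_range, seed = seed)
}

#' @export
print.structure_sweep <- function(x, ...) {
  ks <- attr(x, "k_range")
  cat(sprintf("<structure_sweep: K in {%s}, %d runs each>\n",
              paste(ks, collapse = ","), length(x[[1]])))
  invisible(x)
}
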