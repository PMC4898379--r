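#' Align replicate runs and average their Q matrices
#'
#' Cluster labels are arbitrary within each MCMC run (label switching
#' across runs). Each run's columns are permuted to best match the first
#' run — exhaustively over all `K!` permutations for `K <= 8`, greedily
#' otherwise — minimizing the summed squared difference between Q matrices,
#' and the aligned matrices are averaged.
#'
#' @param runs A list of `structure_run`s sharing `K` and individuals, or a
#'   single-K slice of a `structure_sweep`.
#' @return Object of class `qmatrix`: `Q` (aligned mean), `permutations`
#'   (list, one per run), `similarity` (mean pairwise 1 - normalized
#'   distance to the reference run), `K`, `accession_id`.
#' @export
align_runs <- function(runs) {
  if (inherits(runs, "structure_run")) runs <- list(runs)
  Ks <- vapply(runs, function(r) as.integer(r$K), integer(1))
  if (length(unique(Ks)) != 1) abort("all runs must share K")
  K <- Ks[1]
  ref <- runs[[1]]$Q
  perms <- lapply(runs, function(r) best_permutation(ref, r$Q))
  aligned <- map2(runs, perms, function(r, p) r$Q[, p, drop = FALSE])
  Qbar <- Reduce(`+`, aligned) / length(aligned)
  colnames(Qbar) <- paste0("K", seq_len(K))
  sim <- mean(vapply(aligned, function(a) {
    1 - sum((a - ref)^2) / (2 * nrow(ref))
  }, numeric(1)))
  structure(list(Q = Qbar, permutations = perms, similarity = sim, K = K,
                 accession_id = runs[[1]]$accession_id),
            class = "qmatrix")
}

# permutation p minimizing ||ref - Q[, p]||^2
best_permutation <- function(ref, Q) {
  K <- ncol(ref)
  if (K == 1) return(1L)
  cost <- crossprod(ref, Q)  # maximize trace of cost[p, ] selection
  if (K <= 8) {
    perms <- all_permutations(K)
    scores <- vapply(perms, function(p) {
      sum(cost[cbind(seq_len(K), p)])
    }, numeric(1))
    perms[[which.max(scores)]]
  } else {
    # greedy assignment
    p <- integer(K)
    free <- seq_len(K)
    for (k in seq_len(K)) {
      j <- free[which.max(cost[k, free])]
      p[k] <- j
      free <- setdiff(free, j)
    }
    p
  }
}

# all permutations of 1..K, built by inserting K at every position
all_permutations <- function(K) {
  if (K == 1) return(list(1L))
  sub <- all_permutations(K - 1)
  out <- vector("list", K * length(sub))
  i <- 0
  for (s in sub) {
    for (pos in 0:(K - 1)) {
      i <- i + 1
      out[[i]] <- append(s, K, after = pos)
    }
  }
  out
}

#' @export
print.qmatrix <- function(x, ...) {
  cat(sprintf("<qmatrix: %d individuals x K = %d, run similarity %.3f>\n",
              nrow(x$Q), x$K, x$similarity))
  invisible(x)
}

#' Evanno delta-K table and model choice
#'
#' For each K with replicate runs, tabulates the mean and standard
#' deviation of the model evidence proxy L(K) (`lnpd` of each run), the
#' first and absolute second differences, and
#' \deqn{\Delta K = |L(K+1) - 2L(K) + L(K-1)| / \mathrm{sd}(L(K)),}
#' defined for interior K only. The selected K maximizes delta-K.
#'
#' @param sweep A `structure_sweep`, or a named list (names = K) of lists of
#'   `structure_run`s, or a data frame with columns `k` and `lnpd`.
#' @return A tibble of class `delta_k_tbl` with columns `k`, `n_runs`,
#'   `mean_lnpd`, `sd_lnpd`, `lprime`, `lsecond`, `delta_k`, and attribute
#'   `selected_k`.
#' @export
delta_k <- function(sweep) {
  if (is.data.frame(sweep)) {
    tab <- sweep %>% group_by(.data$k) %>%
      summarise(n_runs = dplyr::n(), mean_lnpd = mean(.data$lnpd),
                sd_lnpd = stats::sd(.data$lnpd), .groups = "drop")
  } else {
    tab <- bind_rows(imap(sweep, function(runs, k) {
      l <- vapply(runs, `[[`, numeric(1), "lnpd")
      tibble(k = as.integer(k), n_runs = length(l),
             mean_lnpd = mean(l), sd_lnpd = stats::sd(l))
    }))
  }
  tab <- arrange(tab, .data$k)
  if (nrow(tab) < 3) abort("delta-K needs at least 3 consecutive K values")
  if (any(diff(tab$k) != 1)) abort("K values must be consecutive")
  if (any(tab$sd_lnpd == 0 | is.na(tab$sd_lnpd))) {
    abort("sd of L(K) is zero or undefined at some K; use more runs or jitter seeds")
  }
  m <- tab$mean_lnpd
  nk <- nrow(tab)
  tab$lprime <- c(NA, diff(m))
  tab$lsecond <- c(NA, abs(m[3:nk] - 2 * m[2:(nk - 1)] + m[1:(nk - 2)]), NA)
  tab$delta_k <- tab$lsecond / tab$sd_lnpd
  sel <- tab$k[which.max(tab$delta_k)]
  structure(tab, selected_k = sel,
            class = c("delta_k_tbl", class(tibble::tibble())))
}

#' @export
print.delta_k_tbl <- function(x, ...) {
  NextMethod()
  cat(sprintf("selected K (max delta-K): %d\n", attr(x, "selected_k")))
  invisible(x)
}

#' Selected K of a delta-K table
#' @param dk A `delta_k_tbl`.
#' @export
selected_k <- function(dk) attr(dk, "selected_k")

#' Assign individuals to clusters by membership coefficient
#'
#' Each individual goes to the cluster with its highest ancestry proportion
#' (ties broken toward the lowest cluster index). Status is `strong` when
#' the maximum qI is at least `strong` (default 0.80), `unambiguous_admixed`
#' when it is below `admixed_max` (default 0.55), and `admixed` in between.
#'
#' @param qmat A `qmatrix` from [align_runs()], a `structure_run`, or a
#'   numeric matrix of ancestry proportions.
#' @param strong Threshold for strong assignment.
#' @param admixed_max Maximum-qI threshold below which an individual is
#'   unambiguously admixed.
#' @param prefix Cluster label prefix (default `"K"`).
#' @return Tibble: `accession_id`, `group`, `max_q`, `status`.
#' @export
assign_groups <- function(qmat, strong = 0.80, admixed_max = 0.55,
                          prefix = "K") {
  Q <- if (is.matrix(qmat)) qmat else qmat$Q
  ids <- if (is.matrix(qmat)) rownames(qmat) %||% as.character(seq_len(nrow(qmat)))
         else qmat$accession_id
  g <- apply(Q, 1, which.max)  # which.max breaks ties toward the lowest index
  mx <- Q[cbind(seq_len(nrow(Q)), g)]
  tibble(accession_id = ids,
         group = paste0(prefix, g),
         max_q = as.numeric(mx),
         status = dplyr::case_when(mx >= strong ~ "strong",
                                   mx < admixed_max ~ "unambiguous_admixed",
                                   TRUE ~ "admixed"))
}

#' Nested substructure analysis
#'
#' Re-runs the admixture clustering separately inside each top-level group:
#' every individual (admixed ones included) is placed with its argmax
#' parent group, and each group with at least `min_group` members gets its
#' own K sweep, delta-K selection and assignment. Subgroup labels combine
#' parent and child (e.g. `K1.2`).
#'
#' @param gt The `genotype_tbl` used for the parent analysis.
#' @param parent_assignments Tibble from [assign_groups()].
#' @param k_range K values swept within each group.
#' @param min_group Minimum group size for a sub-analysis (default 25).
#' @inheritParams structure_sweep
#' @return Object of class `nested_structure`: per-group list with
#'   `delta_k` table, aligned `qmatrix`, `assignments` (subgroup labels),
#'   plus combined `assignments` tibble covering every analyzed individual.
#' @export
nested_structure <- function(gt, parent_assignments, k_range = 1:4,
                             min_group = 25, profile = "desk",
                             n_runs = NULL, burnin = NULL, iterations = NULL,
                             seed = 1L) {
  groups <- sort(unique(parent_assignments$group))
  set.seed(as.integer(seed))
  g_seeds <- sample.int(.Machine$integer.max, length(groups))
  per_group <- list()
  combined <- list()
  for (gi in seq_along(groups)) {
    g <- groups[gi]
    members <- parent_assignments$accession_id[parent_assignments$group == g]
    sub_gt <- keep_rows(gt, gt$accession_id %in% members)
    if (nrow(sub_gt) < min_group) {
      warn(sprintf("group %s has %d members (< %d): sub-analysis skipped",
                   g, nrow(sub_gt), min_group))
      combined[[g]] <- tibble(accession_id = sub_gt$accession_id,
                              subgroup = paste0(g, ".1"),
                              max_q = NA_real_, status = NA_character_)
      next
    }
    sw <- structure_sweep(sub_gt, k_range = k_range, n_runs = n_runs,
                          profile = profile, burnin = burnin,
                          iterations = iterations, seed = g_seeds[gi])
    dk <- delta_k(sw)
    k_sel <- selected_k(dk)
    qm <- align_runs(sw[[as.character(k_sel)]])
    asg <- assign_groups(qm, prefix = paste0(g, "."))
    per_group[[g]] <- list(delta_k = dk, qmatrix = qm, selected_k = k_sel,
                           assignments = asg)
    combined[[g]] <- asg %>% rename(subgroup = "group")
  }
  structure(list(per_group = per_group, assignments = bind_rows(combined),
                 parent = parent_assignments),
            class = "nested_structure")
}

#' @export
print.nested_structure <- function(x, ...) {
  cat("<nested_structure>\n")
  for (g in names(x$per_group)) {
    cat(sprintf("  %s: selected sub-K = %d\n", g, x$per_group[[g]]$selected_k))
  }
  invisible(x)
}
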