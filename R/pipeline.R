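#' Run the full germplasm analysis workflow
#'
#' Orchestrates the standard sequence on one genotype table: duplicate and
#' triploid resolution, diversity statistics on the unique diploid set,
#' admixture clustering with delta-K model choice and (optionally) nested
#' substructure, AMOVA and pairwise F_ST over the inferred groups, PCoA
#' and a neighbor-joining tree, and trio parentage. Stage toggles skip
#' stages; stages consuming a skipped stage's output are skipped
#' automatically (nested structure and the differentiation-by-cluster
#' stage require the structure stage). All downstream stages run on the
#' unique diploid genotypes produced by the dedup stage.
#'
#' @param gt A `genotype_tbl`.
#' @param k_range K values swept by the structure stage.
#' @param profile MCMC profile, see [structure_profile()].
#' @param burnin,iterations Optional chain-length overrides of the profile.
#' @param n_permutations Permutations for AMOVA / F_ST.
#' @param run_structure,run_nested,run_ordination,run_parentage Stage
#'   toggles.
#' @param parentage_sims Simulated offspring for confidence calibration.
#' @param max_mismatch_loci,min_shared_loci Duplicate-rule parameters.
#' @param output_dir Optional directory; when given, stage tables are
#'   written as CSVs (plus a Newick tree) with a `summary.txt`.
#' @param seed Master seed; per-stage seeds are derived from it.
#' @return A list of class `germplasm_analysis` with one element per
#'   stage and a `summary` tibble of filter counts.
#' @export
run_full_analysis <- function(gt, k_range = 1:5, profile = "desk",
                              burnin = NULL, iterations = NULL,
                              n_permutations = 199,
                              run_structure = TRUE, run_nested = FALSE,
                              run_ordination = TRUE, run_parentage = FALSE,
                              parentage_sims = 300,
                              max_mismatch_loci = 2, min_shared_loci = 12,
                              output_dir = NULL, seed = 1L) {
  res <- list(seed = seed)
  counts <- list(n_input = nrow(gt))

  # --- redundancy ---
  dedup <- find_duplicate_groups(gt, max_mismatch_loci = max_mismatch_loci,
                                 min_shared_loci = min_shared_loci,
                                 exclude_triploids = TRUE)
  res$duplicates <- dedup
  res$ploidy <- flag_triploids(gt)
  uniq <- dedup$unique
  counts$n_triploid <- length(dedup$excluded_triploids)
  counts$n_redundant <- counts$n_input - counts$n_triploid - nrow(uniq)
  counts$n_unique_diploid <- nrow(uniq)
  inform(sprintf("dedup: %d input, %d triploid excluded, %d redundant removed, %d unique diploid genotypes",
                 counts$n_input, counts$n_triploid, counts$n_redundant,
                 nrow(uniq)))

  # --- diversity ---
  freqs <- allele_frequencies(uniq)
  res$freqs <- freqs
  res$pid <- probability_of_identity(freqs)
  res$cumulative_pid <- unname(cumulative_pid_report(freqs))
  res$diversity <- diversity_stats(uniq)

  # --- structure ---
  assignments <- NULL
  if (run_structure) {
    sweep <- structure_sweep(uniq, k_range = k_range, profile = profile,
                             burnin = burnin, iterations = iterations,
                             seed = seed)
    dk <- delta_k(sweep)
    k_sel <- selected_k(dk)
    qm <- align_runs(sweep[[as.character(k_sel)]])
    assignments <- assign_groups(qm)
    res$structure <- list(delta_k = dk, selected_k = k_sel, qmatrix = qm,
                          assignments = assignments)
    inform(sprintf("structure: selected K = %d; %d/%d strongly assigned",
                   k_sel, sum(assignments$status == "strong"),
                   nrow(assignments)))
    if (run_nested) {
      res$nested <- nested_structure(uniq, assignments,
                                     k_range = seq_len(max(3, max(k_range) - 1)),
                                     profile = profile, burnin = burnin,
                                     iterations = iterations, seed = seed + 1L)
    }
    # --- differentiation over inferred groups ---
    grp_vec <- assignments$group[match(uniq$accession_id,
                                       assignments$accession_id)]
    res$amova <- amova(uniq, grp_vec, n_permutations = n_permutations,
                       seed = seed + 2L)
    res$fst <- pairwise_fst(uniq, grp_vec, n_permutations = n_permutations,
                            seed = seed + 3L)
  } else if (run_nested) {
    inform("nested structure skipped: structure stage disabled")
  }

  # --- ordination ---
  if (run_ordination) {
    dm <- simple_matching_dissimilarity(uniq)
    res$distance <- dm
    res$pcoa <- pcoa(dm)
    if (nrow(uniq) >= 3) res$nj_tree <- neighbor_joining(dm)
  }

  # --- parentage ---
  if (run_parentage) {
    cal <- calibrate_confidence(uniq, n_sims = parentage_sims,
                                seed = seed + 4L)
    res$parentage_calibration <- cal
    res$trios <- infer_trios(uniq, cal)
    inform(sprintf("parentage: %d trio(s) accepted at Delta >= %.2f",
                   nrow(res$trios), cal$delta_threshold))
  }

  res$summary <- tibble(metric = names(counts),
                        value = as.numeric(unlist(counts)))
  out <- structure(res, class = "germplasm_analysis")
  if (!is.null(output_dir)) write_analysis(out, output_dir)
  out
}

write_analysis <- function(res, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(res$duplicates$groups, file.path(dir, "duplicate_groups.csv"),
                   row.names = FALSE)
  utils::write.csv(res$ploidy, file.path(dir, "ploidy_flags.csv"), row.names = FALSE)
  utils::write.csv(res$diversity, file.path(dir, "diversity_per_locus.csv"),
                   row.names = FALSE)
  if (!is.null(res$structure)) {
    utils::write.csv(res$structure$delta_k, file.path(dir, "delta_k.csv"),
                     row.names = FALSE)
    utils::write.csv(res$structure$assignments, file.path(dir, "assignments.csv"),
                     row.names = FALSE)
    utils::write.csv(as.data.frame(res$structure$qmatrix$Q),
                     file.path(dir, "q_matrix.csv"))
    utils::write.csv(tidy(res$amova), file.path(dir, "amova.csv"), row.names = FALSE)
    utils::write.csv(res$fst, file.path(dir, "pairwise_fst.csv"), row.names = FALSE)
  }
  if (!is.null(res$nj_tree)) {
    ape::write.tree(res$nj_tree, file.path(dir, "nj_tree.nwk"))
  }
  if (!is.null(res$pcoa)) {
    utils::write.csv(res$pcoa$points, file.path(dir, "pcoa_coordinates.csv"),
                     row.names = FALSE)
  }
  if (!is.null(res$trios)) {
    utils::write.csv(res$trios, file.path(dir, "trios.csv"), row.names = FALSE)
  }
  writeLines(c(sprintf("seed: %d", res$seed),
               sprintf("%s: %s", res$summary$metric, res$summary$value),
               sprintf("cumulative P_ID: %.3e", res$cumulative_pid)),
             file.path(dir, "summary.txt"))
  invisible(dir)
}

#' @export
print.germplasm_analysis <- function(x, ...) {
  cat("<germplasm_analysis>\n")
  print(x$summary)
  if (!is.null(x$structure)) {
    cat(sprintf("selected K: %d\n", x$structure$selected_k))
  }
  if (!is.null(x$trios)) cat(sprintf("accepted trios: %d\n", nrow(x$trios)))
  invisible(x)
}
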