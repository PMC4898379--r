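# Small hand-built genotype tables used across the suite.

`%||%` <- function(a, b) if (is.null(a)) b else a

rdirichlet_test <- function(a) {
  g <- rgamma(length(a), a)
  g / sum(g)
}

# 3 accessions x 2 loci; A1/A2 identical, A3 distinct
tiny_gt <- function() {
  as_genotype_tbl(tibble::tibble(
    accession_id = c("A1", "A2", "A3"),
    L1 = list(c(228L, 230L), c(228L, 230L), c(240L, 242L)),
    L2 = list(c(100L, 104L), c(100L, 104L), c(110L, 110L))
  ))
}

# build a genotype_tbl from a list of per-accession call lists
gt_from_calls <- function(calls, loci = NULL) {
  loci <- loci %||% names(calls[[1]])
  tab <- tibble::tibble(accession_id = names(calls))
  for (l in loci) {
    tab[[l]] <- lapply(calls, function(cc) as.integer(cc[[l]]))
  }
  as_genotype_tbl(tab, loci = loci)
}

# random valid genotype table for round-trip property tests
random_gt <- function(n = 10, n_loci = 4, seed = 1) {
  set.seed(seed)
  tab <- tibble::tibble(accession_id = sprintf("R%03d", seq_len(n)))
  for (l in sprintf("L%d", seq_len(n_loci))) {
    tab[[l]] <- lapply(seq_len(n), function(i) {
      r <- runif(1)
      if (r < 0.1) integer(0)                               # missing
      else if (r < 0.2) sort(sample(100:120, 3))            # triallelic
      else sort(sample(100:120, 2, replace = TRUE))         # diploid
    })
  }
  as_genotype_tbl(tab)
}

# brute-force duplicate grouping: pairwise predicate + union-find
brute_force_groups <- function(gt, max_mismatch_loci = 2, min_shared_loci = 12) {
  loci <- gt_loci(gt)
  n <- nrow(gt)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    a <- setNames(lapply(loci, function(l) gt[[l]][[i]]), loci)
    b <- setNames(lapply(loci, function(l) gt[[l]][[j]]), loci)
    if (are_duplicates(a, b, max_mismatch_loci, min_shared_loci)) {
      ri <- find(i); rj <- find(j)
      if (ri != rj) parent[ri] <- rj
    }
  }
  roots <- vapply(seq_len(n), find, integer(1))
  split(gt$accession_id, roots)
}

# exhaustive P_ID at one locus: sum over genotype pairs of P(g)^2 under HWE
brute_force_pid <- function(p) {
  k <- length(p)
  tot <- 0
  for (i in seq_len(k)) for (j in i:k) {
    pg <- if (i == j) p[i]^2 else 2 * p[i] * p[j]
    tot <- tot + pg^2
  }
  tot
}
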