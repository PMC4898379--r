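#' Harmonize allele sizes between two collections
#'
#' SSR fragment sizes scored on different platforms or in different labs are
#' typically offset by a small constant number of base pairs per locus.
#' Given reference accessions genotyped in both collections, this estimates
#' one integer offset per locus as the mode of the pairwise size differences
#' (reference minus other) over all matched allele pairs of the shared
#' accessions, and applies it to every call of `other`. Matched pairs come
#' from positional alignment of the two sorted calls.
#'
#' Loci whose observed differences are not a single constant are flagged
#' `consistent = FALSE` in the report; the modal offset is still applied, so
#' rerunning the harmonization is a no-op (idempotence).
#'
#' @param reference,other Two `genotype_tbl`s sharing locus names.
#' @param shared_ids Accessions present in both tables to calibrate on;
#'   defaults to all common `accession_id`s.
#' @return An object of class `ssr_harmonization`: a list with `offsets`
#'   (tibble: `locus`, `offset`, `n_pairs`, `consistent`), `adjusted`
#'   (the shifted copy of `other`) and `shared_ids`.
#' @export
harmonize_allele_sizes <- function(reference, other, shared_ids = NULL) {
  loci <- intersect(gt_loci(reference), gt_loci(other))
  if (length(loci) == 0) abort("no loci in common")
  shared_ids <- shared_ids %||% intersect(reference$accession_id, other$accession_id)

  per_locus <- lapply(loci, function(loc) {
    diffs <- integer(0)
    for (id in shared_ids) {
      a <- reference[[loc]][[match(id, reference$accession_id)]]
      b <- other[[loc]][[match(id, other$accession_id)]]
      if (length(a) >= 2 && length(a) == length(b)) diffs <- c(diffs, a - b)
    }
    if (length(diffs) == 0) {
      return(tibble(locus = loc, offset = NA_integer_, n_pairs = 0L, consistent = NA))
    }
    tab <- sort(table(diffs), decreasing = TRUE)
    tibble(locus = loc,
           offset = as.integer(names(tab)[1]),
           n_pairs = length(diffs),
           consistent = length(tab) == 1)
  })
  offsets <- bind_rows(per_locus)
  if (all(offsets$n_pairs == 0)) {
    abort("harmonization failed: no shared accession scored in both tables at any locus")
  }

  adjusted <- other
  for (i in seq_len(nrow(offsets))) {
    off <- offsets$offset[i]
    if (is.na(off) || off == 0L) next
    loc <- offsets$locus[i]
    adjusted[[loc]] <- lapply(adjusted[[loc]], function(a) a + off)
  }
  adjusted <- structure(adjusted, loci = gt_loci(other),
                        class = c("genotype_tbl", class(tibble::tibble())))
  structure(list(offsets = offsets, adjusted = adjusted, shared_ids = shared_ids),
            class = "ssr_harmonization")
}

#' @export
print.ssr_harmonization <- function(x, ...) {
  cat(sprintf("<ssr_harmonization: %d shared accessions>\n", length(x$shared_ids)))
  shifted <- dplyr::filter(x$offsets, !is.na(.data$offset) & .data$offset != 0L)
  cat(sprintf("  loci shifted: %d; unresolved (non-constant differences): %d; uncalibrated: %d\n",
              nrow(shifted), sum(!x$offsets$consistent, na.rm = TRUE),
              sum(x$offsets$n_pairs == 0)))
  print(x$offsets, ...)
  invisible(x)
}

#' @rdname harmonize_allele_sizes
#' @param x An `ssr_harmonization` object.
#' @param ... Unused.
#' @export
tidy.ssr_harmonization <- function(x, ...) x$offsets
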