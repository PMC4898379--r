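#' Build a genotype table from a data frame
#'
#' A genotype table (`genotype_tbl`) is a tibble with one row per accession:
#' metadata columns (`accession_id`, optionally `collection`, `name`,
#' `country`, `region`) followed by one list-column per SSR locus, each cell
#' holding a sorted integer vector of 0--3 allele sizes (base pairs).
#' An empty vector encodes a missing call; diploid homozygotes are stored as
#' two identical sizes so every diploid call carries exactly two allele
#' copies.
#'
#' @param x A data frame. Locus columns may already be list-columns of
#'   integer vectors, or character vectors with alleles separated by `/`
#'   (e.g. `"228/230"`).
#' @param loci Character vector naming the locus columns. Defaults to every
#'   non-metadata column.
#' @param region_map Tibble with columns `country`, `region` used to check
#'   that stated regions agree with countries; see [default_region_map()].
#' @return A validated `genotype_tbl`.
#' @examples
#' gt <- as_genotype_tbl(data.frame(
#'   accession_id = c("A1", "A2"),
#'   L1 = c("228/230", "230"),
#'   L2 = c("100/104", NA)
#' ))
#' gt_loci(gt)
#' @export
as_genotype_tbl <- function(x, loci = NULL, region_map = default_region_map()) {
  x <- tibble::as_tibble(x)
  if (!"accession_id" %in% names(x)) {
    abort("genotype table needs an `accession_id` column")
  }
  x$accession_id <- as.character(x$accession_id)
  loci <- loci %||% setdiff(names(x), gt_meta_cols())
  if (length(loci) == 0) abort("no locus columns found")

  for (loc in loci) {
    col <- x[[loc]]
    if (!is.list(col)) col <- lapply(col, parse_allele_token, locus = loc)
    x[[loc]] <- lapply(col, normalize_call, locus = loc)
  }
  out <- structure(x, loci = loci,
                   class = c("genotype_tbl", class(tibble::tibble())))
  validate_genotype_tbl(out, region_map = region_map)
}

# "228/230" -> c(228L, 230L); "", "NA", NA -> integer(0)
parse_allele_token <- function(tok, locus) {
  if (length(tok) != 1 || is.na(tok) || identical(tok, "") || identical(tok, "NA")) {
    return(integer(0))
  }
  parts <- strsplit(as.character(tok), "/", fixed = TRUE)[[1]]
  parts <- parts[!parts %in% c("", "NA")]
  if (length(parts) == 0) return(integer(0))
  vals <- suppressWarnings(as.integer(parts))
  if (anyNA(vals)) abort(sprintf("non-integer allele '%s' at locus %s", tok, locus))
  vals
}

# sort ascending; duplicate a lone allele into a homozygous diploid call
normalize_call <- function(a, locus) {
  if (is.null(a) || length(a) == 0 || all(is.na(a))) return(integer(0))
  a <- as.integer(a[!is.na(a)])
  if (length(a) == 0) return(integer(0))
  if (length(a) == 1) a <- c(a, a)
  if (length(a) > 3) abort(sprintf("call with %d alleles at locus %s (max 3)", length(a), locus))
  if (any(a <= 0)) abort(sprintf("non-positive allele size at locus %s", locus))
  sort(a)
}

#' Validate a genotype table
#'
#' Checks the `genotype_tbl` invariants: unique accession ids, 0--3 sorted
#' positive integer alleles per call, and (when both are present) agreement
#' between `region` and `country` under `region_map`.
#'
#' @inheritParams as_genotype_tbl
#' @param gt A `genotype_tbl`.
#' @return `gt`, invisibly unchanged, or an error.
#' @export
validate_genotype_tbl <- function(gt, region_map = default_region_map()) {
  if (anyDuplicated(gt$accession_id)) {
    abort(sprintf("duplicated accession_id: %s",
                  paste(unique(gt$accession_id[duplicated(gt$accession_id)]), collapse = ", ")))
  }
  for (loc in gt_loci(gt)) {
    lens <- lengths(gt[[loc]])
    if (any(lens > 3)) abort(sprintf(">3 alleles at locus %s", loc))
    bad <- which(vapply(gt[[loc]], function(a) {
      length(a) > 0 && (anyNA(a) || any(a <= 0) || is.unsorted(a))
    }, logical(1)))
    if (length(bad)) {
      abort(sprintf("invalid call at locus %s, accession %s", loc, gt$accession_id[bad[1]]))
    }
  }
  if (all(c("country", "region") %in% names(gt)) && !is.null(region_map)) {
    chk <- dplyr::inner_join(
      dplyr::select(tibble::as_tibble(gt), "accession_id", "country", stated = "region"),
      region_map, by = "country"
    )
    chk <- dplyr::filter(chk, !is.na(.data$stated), .data$stated != "unknown",
                         .data$stated != .data$region)
    if (nrow(chk) > 0) {
      abort(sprintf("region/country mismatch for accession(s): %s",
                    paste(utils::head(chk$accession_id, 5), collapse = ", ")))
    }
  }
  gt
}

#' Locus names of a genotype table
#' @param gt A `genotype_tbl`.
#' @return Character vector of locus names in their canonical order.
#' @export
gt_loci <- function(gt) {
  attr(gt, "loci") %||% setdiff(names(gt), gt_meta_cols())
}

#' Number of accessions in a genotype table
#' @param gt A `genotype_tbl`.
#' @export
n_accessions <- function(gt) nrow(gt)

#' Per-accession missing-locus counts
#' @param gt A `genotype_tbl`.
#' @return Tibble with `accession_id` and `n_missing_loci`.
#' @export
missing_locus_counts <- function(gt) {
  loci <- gt_loci(gt)
  miss <- rowSums(vapply(loci, function(l) lengths(gt[[l]]) == 0, logical(nrow(gt))))
  tibble(accession_id = gt$accession_id, n_missing_loci = as.integer(miss))
}

#' Long view of allele calls
#'
#' @param gt A `genotype_tbl`.
#' @return Tibble with one row per allele copy: `accession_id`, `locus`,
#'   `allele`. Missing calls contribute no rows.
#' @export
gt_alleles_long <- function(gt) {
  loci <- gt_loci(gt)
  parts <- lapply(loci, function(l) {
    lens <- lengths(gt[[l]])
    tibble(
      accession_id = rep(gt$accession_id, lens),
      locus = l,
      allele = as.integer(unlist(gt[[l]], use.names = FALSE))
    )
  })
  bind_rows(parts)
}

# n x 2 integer matrix of allele sizes at one locus; NA rows for missing or
# triploid calls (diploid view used by frequency/likelihood machinery)
locus_diploid_matrix <- function(gt, locus) {
  calls <- gt[[locus]]
  out <- matrix(NA_integer_, nrow = length(calls), ncol = 2)
  ok <- lengths(calls) == 2
  if (any(ok)) out[ok, ] <- matrix(unlist(calls[ok], use.names = FALSE),
                                   ncol = 2, byrow = TRUE)
  out
}

#' Keep only strictly diploid accessions
#'
#' Drops accessions with any triallelic call. Missing calls are allowed.
#' @param gt A `genotype_tbl`.
#' @export
filter_diploid <- function(gt) {
  keep_rows(gt, diploid_rows(gt))
}

# logical: rows without any triallelic call
diploid_rows <- function(gt) {
  !Reduce(`|`, lapply(gt_loci(gt), function(l) lengths(gt[[l]]) == 3))
}

# subset rows preserving class/attributes
keep_rows <- function(gt, idx) {
  out <- tibble::as_tibble(gt)[idx, , drop = FALSE]
  structure(out, loci = gt_loci(gt),
            class = c("genotype_tbl", class(tibble::tibble())))
}

#' @export
print.genotype_tbl <- function(x, ...) {
  loci <- gt_loci(x)
  cat(sprintf("<genotype_tbl: %d accessions x %d loci>\n", nrow(x), length(loci)))
  shown <- tibble::as_tibble(x)
  for (l in loci) {
    shown[[l]] <- vapply(x[[l]], function(a) {
      if (length(a) == 0) "." else paste(a, collapse = "/")
    }, character(1))
  }
  print(shown, ...)
  invisible(x)
}
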