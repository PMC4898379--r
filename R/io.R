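#' Read an SSR genotype table from CSV
#'
#' Two layouts are supported. `wide`: one row per accession with columns
#' `accession_id[,collection,name,country,region]` and then `<locus>_1`,
#' `<locus>_2` (and optionally `<locus>_3`) per locus; empty cells or `NA`
#' denote missing alleles. `long`: one row per allele copy with columns
#' `accession_id,locus,allele`. In both layouts a locus observed with a
#' single allele for an accession is normalized to a homozygous diploid call
#' (two identical copies) and alleles are sorted ascending.
#'
#' @param path Path to a CSV file.
#' @param format `"wide"` or `"long"`.
#' @inheritParams as_genotype_tbl
#' @return A `genotype_tbl`.
#' @seealso [write_genotype_table()], [write_structure_file()]
#' @export
read_genotype_table <- function(path, format = c("wide", "long"),
                                region_map = default_region_map()) {
  format <- match.arg(format)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE,
                         colClasses = "character")
  if (format == "wide") {
    gt_from_wide(tibble::as_tibble(raw), region_map)
  } else {
    gt_from_long(tibble::as_tibble(raw), region_map)
  }
}

gt_from_wide <- function(raw, region_map) {
  allele_cols <- grep("_[0-9]+$", setdiff(names(raw), gt_meta_cols()), value = TRUE)
  if (length(allele_cols) == 0) abort("wide CSV: no `<locus>_<k>` allele columns found")
  loci <- unique(sub("_[0-9]+$", "", allele_cols))
  meta <- raw[intersect(gt_meta_cols(), names(raw))]
  for (loc in loci) {
    cols <- paste0(loc, "_", 1:3)
    cols <- cols[cols %in% names(raw)]
    mat <- as.matrix(raw[cols])
    meta[[loc]] <- lapply(seq_len(nrow(raw)), function(i) {
      vals <- mat[i, ]
      vals <- vals[!is.na(vals) & vals != "" & vals != "NA"]
      if (length(vals) == 0) return(integer(0))
      out <- suppressWarnings(as.integer(vals))
      if (anyNA(out)) {
        abort(sprintf("row %d, locus %s: non-integer allele '%s'",
                      i, loc, paste(vals, collapse = "/")))
      }
      out
    })
  }
  as_genotype_tbl(meta, loci = loci, region_map = region_map)
}

gt_from_long <- function(raw, region_map) {
  need <- c("accession_id", "locus", "allele")
  if (!all(need %in% names(raw))) {
    abort("long CSV needs columns accession_id, locus, allele")
  }
  raw$allele <- suppressWarnings(as.integer(raw$allele))
  if (anyNA(raw$allele)) abort("long CSV: non-integer allele value")
  loci <- unique(raw$locus)
  acc <- unique(raw$accession_id)
  wide <- tibble(accession_id = acc)
  for (loc in loci) {
    sub <- raw[raw$locus == loc, ]
    wide[[loc]] <- lapply(acc, function(a) sub$allele[sub$accession_id == a])
  }
  as_genotype_tbl(wide, loci = loci, region_map = region_map)
}

#' Write a genotype table to CSV
#'
#' Inverse of [read_genotype_table()]; a write/read round trip reproduces
#' the table exactly.
#'
#' @param gt A `genotype_tbl`.
#' @param path Output path.
#' @param format `"wide"` or `"long"`.
#' @export
write_genotype_table <- function(gt, path, format = c("wide", "long")) {
  format <- match.arg(format)
  loci <- gt_loci(gt)
  if (format == "wide") {
    out <- tibble::as_tibble(gt)[intersect(gt_meta_cols(), names(gt))]
    max_ploidy <- max(c(2L, unlist(lapply(loci, function(l) lengths(gt[[l]])))))
    for (loc in loci) {
      for (k in seq_len(max_ploidy)) {
        out[[paste0(loc, "_", k)]] <- vapply(gt[[loc]], function(a) {
          if (length(a) >= k) as.character(a[k]) else ""
        }, character(1))
      }
    }
    utils::write.csv(out, path, row.names = FALSE, quote = FALSE, na = "")
  } else {
    long <- gt_alleles_long(gt)
    utils::write.csv(long, path, row.names = FALSE, quote = FALSE)
  }
  invisible(path)
}

#' Export genotypes in Structure text format
#'
#' Writes two rows per individual and one integer column per locus, with
#' missing alleles coded `-9`; the first column is the accession id. Locus
#' order follows [gt_loci()] and is written in a header line. The format is
#' strictly diploid: with `diploids_only = TRUE` accessions carrying any
#' triallelic call are dropped (with a message); otherwise their presence is
#' an error.
#'
#' @param gt A `genotype_tbl`.
#' @param path Output path.
#' @param diploids_only Drop putative polyploid profiles instead of failing.
#' @return `path`, invisibly.
#' @export
write_structure_file <- function(gt, path, diploids_only = FALSE) {
  loci <- gt_loci(gt)
  tri <- Reduce(`|`, lapply(loci, function(l) lengths(gt[[l]]) == 3))
  if (any(tri)) {
    if (!diploids_only) {
      abort(sprintf("%d accession(s) carry triallelic calls; Structure format is diploid (set diploids_only = TRUE to drop them)",
                    sum(tri)))
    }
    inform(sprintf("dropping %d non-diploid accession(s)", sum(tri)))
    gt <- keep_rows(gt, !tri)
  }
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(loci, collapse = " "), con)
  for (i in seq_len(nrow(gt))) {
    for (copy in 1:2) {
      vals <- vapply(loci, function(l) {
        a <- gt[[l]][[i]]
        if (length(a) == 0) -9L else a[copy]
      }, integer(1))
      writeLines(paste(c(gt$accession_id[i], vals), collapse = " "), con)
    }
  }
  invisible(path)
}

#' Read back a Structure-format export
#'
#' Companion to [write_structure_file()]; mainly useful to verify exports.
#' @param path Path written by [write_structure_file()].
#' @return A `genotype_tbl` (metadata reduced to `accession_id`).
#' @export
read_structure_file <- function(path) {
  lines <- readLines(path)
  loci <- strsplit(lines[1], " ", fixed = TRUE)[[1]]
  body <- strsplit(lines[-1], " ", fixed = TRUE)
  ids <- vapply(body, `[[`, character(1), 1)
  vals <- t(vapply(body, function(x) as.integer(x[-1]), integer(length(loci))))
  if (length(loci) == 1) vals <- matrix(as.integer(vals), ncol = 1)
  acc <- unique(ids)
  out <- tibble(accession_id = acc)
  for (j in seq_along(loci)) {
    out[[loci[j]]] <- lapply(acc, function(a) {
      v <- vals[ids == a, j]
      v <- v[v != -9L]
      if (length(v) == 0) integer(0) else sort(v)
    })
  }
  as_genotype_tbl(out, loci = loci)
}
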