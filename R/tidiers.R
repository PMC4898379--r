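#' @importFrom generics tidy glance
NULL

#' @export
generics::tidy

#' @export
generics::glance

#' @export
ggplot2::autoplot

#' Tidy a structure run or aligned Q matrix into long format
#'
#' @param x A `structure_run` or `qmatrix`.
#' @param ... Unused.
#' @return Tibble: `accession_id`, `cluster`, `q`.
#' @export
tidy.structure_run <- function(x, ...) {
  as_tibble(x$Q) %>%
    mutate(accession_id = x$accession_id) %>%
    tidyr::pivot_longer(-"accession_id", names_to = "cluster", values_to = "q")
}

#' @rdname tidy.structure_run
#' @export
tidy.qmatrix <- tidy.structure_run

#' One-row summary of a structure run
#'
#' @param x A `structure_run`.
#' @param ... Unused.
#' @return Tibble with `k`, `lnpd`, `mean_lnl`, `sd_lnl`, `mean_alpha`,
#'   and the Metropolis acceptance rates.
#' @export
glance.structure_run <- function(x, ...) {
  tibble(k = x$K, lnpd = x$lnpd, mean_lnl = mean(x$lnl),
         sd_lnl = stats::sd(x$lnl), mean_alpha = mean(x$alpha),
         accept_alpha = x$accept[["alpha"]], accept_f = x$accept[["F"]],
         accept_pa = x$accept[["pA"]])
}

#' @export
tidy.fst_pairwise <- function(x, ...) tibble::as_tibble(x)

#' @export
tidy.trio_candidates <- function(x, ...) tibble::as_tibble(x)

#' @export
glance.parentage_calibration <- function(x, ...) {
  tibble(delta_threshold = x$delta_threshold, achieved_rate = x$achieved_rate,
         n_assignments = x$n_assignments, n_sims = x$n_sims,
         confidence = x$confidence, error_rate = x$error_rate)
}
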