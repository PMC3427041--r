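# broom-style tidiers for the package's result objects.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @exportS3Method generics::tidy
#' @rdname dnds_tidiers
#' @param x A `dnds_survey`.
#' @param ... Unused.
tidy.dnds_survey <- function(x, ...) x$per_contig

#' Tidiers for dN/dS surveys
#'
#' `tidy()` returns the per-contig estimates; `glance()` the one-row
#' summary (unweighted means and SDs over contigs).
#'
#' @name dnds_tidiers
#' @exportS3Method generics::glance
glance.dnds_survey <- function(x, ...) {
  x$summary |> mutate(pair = paste(x$pair, collapse = " vs "), .before = 1L)
}

#' @exportS3Method generics::tidy
#' @rdname reconciliation_tidiers
tidy.platform_reconciliation <- function(x, ...) x$snps

#' Tidiers for platform reconciliation
#'
#' `tidy()` returns the joined per-site table with agreement classes;
#' `glance()` the count summary.
#'
#' @name reconciliation_tidiers
#' @param x A `platform_reconciliation`.
#' @param ... Unused.
#' @exportS3Method generics::glance
glance.platform_reconciliation <- function(x, ...) {
  tibble(n_long = x$n_long, n_short = x$n_short, n_common = x$n_common,
         n_agree = x$n_agree, n_disagree = x$n_disagree, n_union = x$n_union)
}

#' @exportS3Method generics::tidy
#' @rdname lineage_tidiers
tidy.lineage_counts <- function(x, ...) x$counts

#' Tidiers for polarized lineage counts
#'
#' `tidy()` returns the per-lineage substitution counts; `glance()` the
#' alignment totals with the two tetraploid-vs-diploid exact binomial
#' p-values.
#'
#' @name lineage_tidiers
#' @param x A `lineage_counts`.
#' @param ... Unused.
#' @exportS3Method generics::glance
glance.lineage_counts <- function(x, ...) {
  cnt <- setNames(x$counts$substitutions, x$counts$lineage)
  tibble(
    n_contigs = x$n_contigs,
    n_nucleotides = x$n_nucleotides,
    p_A = exact_binomial(cnt[["AT"]], cnt[["A2"]]),
    p_D = exact_binomial(cnt[["DT"]], cnt[["D5"]])
  )
}
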