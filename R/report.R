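# Dataset accounting: species-membership Venn, assembly statistics, the
# coding-coverage estimate and the validation error rate.

#' Species-membership Venn counts
#'
#' Counts contigs by the exact combination of species contributing at least
#' one read, over all non-empty subsets of the configured species.
#'
#' @param memberships Long tibble with `contig_id` and `species` (one row
#'   per observed combination; duplicates are fine), e.g.
#'   `distinct(reads, contig_id, species)`.
#' @param species The full species set defining the cells.
#' @return Tibble `subset` (species joined by `+`, in `species` order),
#'   `n_species`, `n_contigs`; all `2^k - 1` cells are present, zeros
#'   included, and the cells partition the contig set.
#' @export
species_venn <- function(memberships, species = SPECIES) {
  combos <- unlist(lapply(seq_along(species), function(k) {
    apply(combn(species, k), 2L, paste, collapse = "+")
  }))
  observed <- memberships |>
    distinct(.data$contig_id, .data$species) |>
    group_by(.data$contig_id) |>
    summarise(subset = paste(intersect(!!species, .data$species), collapse = "+"),
              .groups = "drop") |>
    count(.data$subset, name = "n_contigs")
  tibble(subset = combos) |>
    left_join(observed, by = "subset") |>
    mutate(n_contigs = coalesce(.data$n_contigs, 0L),
           n_species = lengths(str_split(.data$subset, stringr::fixed("+"))),
           .after = "subset")
}

#' Coding-sequence coverage estimate
#'
#' Expresses the mean assembled coding length as a percentage of the mean
#' coding length of reference genomes, estimating how much of the average
#' coding sequence the assembly captures.
#'
#' @param mean_coding_len Mean predicted coding length of the assembly (bp).
#' @param reference_lens Mean coding lengths of reference species (bp).
#' @return Percentage (0-100 scale).
#' @export
coding_coverage <- function(mean_coding_len, reference_lens) {
  if (!length(reference_lens) || mean(reference_lens) <= 0) {
    abort("reference_lens must be non-empty with positive mean")
  }
  100 * mean_coding_len / mean(reference_lens)
}

#' Assembly validation error rate
#'
#' @param n_nucleotides Nucleotides compared against reference genes (> 0).
#' @param n_substitutions Substitutions observed.
#' @return Percent substitutions per nucleotide.
#' @export
validation_error_rate <- function(n_nucleotides, n_substitutions) {
  if (n_nucleotides <= 0) abort("n_nucleotides must be > 0")
  100 * n_substitutions / n_nucleotides
}

#' Assembly summary statistics
#'
#' @param aln A `contig_alignment`.
#' @return One-row tibble: `n_contigs`, `mean_len`, `min_len`, `max_len`,
#'   `median_reads_per_contig` (lower of the middle pair for even counts),
#'   `mean_depth` (total aligned bases over total contig length).
#' @export
assembly_stats <- function(aln) {
  stopifnot(inherits(aln, "contig_alignment"))
  per <- aln$reads |> count(.data$contig_id)
  per <- aln$contigs |>
    left_join(per, by = "contig_id") |>
    mutate(n = coalesce(.data$n, 0L))
  tibble(
    n_contigs = nrow(aln$contigs),
    mean_len = mean(aln$contigs$length),
    min_len = min(aln$contigs$length),
    max_len = max(aln$contigs$length),
    median_reads_per_contig = median_low(per$n),
    mean_depth = sum(nchar(aln$reads$bases)) / sum(aln$contigs$length)
  )
}
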