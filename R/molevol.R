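# Pairwise molecular evolution: Nei-Gojobori (1986) counting of synonymous
# and nonsynonymous sites and differences with Jukes-Cantor correction,
# four-taxon lineage polarization of substitutions, and the two tests used
# to compare diploid and allotetraploid rates.

perms_123 <- list(
  `1` = list(1L),
  `2` = list(c(1L, 2L), c(2L, 1L)),
  `3` = list(c(1L, 2L, 3L), c(1L, 3L, 2L), c(2L, 1L, 3L),
             c(2L, 3L, 1L), c(3L, 1L, 2L), c(3L, 2L, 1L))
)

#' Extract a paired in-frame codon alignment
#'
#' Takes the in-frame overlap of two consensus sequences on the same contig
#' coordinates; codons containing a masked, gapped or ambiguous base in
#' either sequence are removed, then alignments shorter than `min_len`
#' retained nucleotides are rejected.
#'
#' @param x,y Consensus sequences (strings with `N` masks, equal length) or
#'   `consensus` objects.
#' @param frame 0-based codon phase.
#' @param min_len Minimum retained length in bp (default 198).
#' @param contig_id,pair Optional identifiers carried through.
#' @return A `codon_alignment` (list with `codons` tibble of `codon_x`,
#'   `codon_y` and `n_sites`), or `NULL` when rejected.
#' @export
extract_codon_alignment <- function(x, y, frame = 0L, min_len = 198L,
                                    contig_id = NA_character_, pair = NULL) {
  if (inherits(x, "consensus")) x <- x$bases
  if (inherits(y, "consensus")) y <- y$bases
  stopifnot(nchar(x) == nchar(y))
  n <- nchar(x)
  ncod <- (n - frame) %/% 3L
  if (ncod < 1L) return(NULL)
  starts <- frame + 1L + 3L * (seq_len(ncod) - 1L)
  cx <- substring(x, starts, starts + 2L)
  cy <- substring(y, starts, starts + 2L)
  clean <- !grepl("[^ACGT]", cx) & !grepl("[^ACGT]", cy)
  cx <- cx[clean]
  cy <- cy[clean]
  if (3L * length(cx) < min_len) return(NULL)
  structure(list(contig_id = contig_id, pair = pair,
                 codons = tibble(codon_x = cx, codon_y = cy),
                 n_sites = 3L * length(cx)),
            class = "codon_alignment")
}

# average synonymous/nonsynonymous steps over all orderings of single-step
# pathways between two codons (equal weights, stop-passing paths included)
codon_pathway_diffs <- function(cx, cy) {
  chx <- strsplit(cx, "")[[1]]
  chy <- strsplit(cy, "")[[1]]
  dif <- which(chx != chy)
  k <- length(dif)
  if (k == 0L) return(c(sd = 0, nd = 0))
  sd_tot <- 0
  nd_tot <- 0
  orderings <- perms_123[[as.character(k)]]
  for (ord in orderings) {
    cur <- chx
    for (p in ord) {
      nxt <- cur
      nxt[dif[p]] <- chy[dif[p]]
      aa0 <- codon_table[[paste(cur, collapse = "")]]
      aa1 <- codon_table[[paste(nxt, collapse = "")]]
      if (identical(aa0, aa1)) sd_tot <- sd_tot + 1 else nd_tot <- nd_tot + 1
      cur <- nxt
    }
  }
  c(sd = sd_tot / length(orderings), nd = nd_tot / length(orderings))
}

#' Jukes-Cantor distance correction
#'
#' `d = -(3/4) ln(1 - (4/3) p)`: converts an observed proportion of
#' differences into an estimated per-site substitution distance. The
#' correction is monotone and never smaller than `p`.
#'
#' @param p Observed proportion of differences, `0 <= p < 0.75`.
#' @return Corrected distance.
#' @export
jc_correct <- function(p) {
  if (any(p < 0 | p >= 0.75)) {
    abort("p must lie in [0, 0.75): the correction diverges at 3/4")
  }
  -0.75 * log(1 - 4 / 3 * p)
}

jc_or_na <- function(p) ifelse(p >= 0 & p < 0.75, -0.75 * log(pmax(1 - 4 / 3 * p, .Machine$double.xmin)), NA_real_)

#' Nei-Gojobori (1986) substitution estimates
#'
#' Synonymous site counts per codon are the fractions of single-base changes
#' that preserve the amino acid, averaged over the two sequences; observed
#' differences in multi-difference codons are averaged over all orderings of
#' single-step pathways with equal weights. Proportions are Jukes-Cantor
#' corrected; a proportion at or above 3/4 gives an undefined (`NA`)
#' distance, and the dN/dS ratio is defined only when `dS > 0`.
#'
#' @param ca A `codon_alignment` from [extract_codon_alignment()].
#' @return One-row tibble: `n_sites`, `S`, `N`, `Sd`, `Nd`, `pS`, `pN`,
#'   `dS`, `dN`, `ratio`.
#' @export
ng86 <- function(ca) {
  stopifnot(inherits(ca, "codon_alignment"))
  cx <- ca$codons$codon_x
  cy <- ca$codons$codon_y
  sx <- unlist(syn_sites_table[cx], use.names = FALSE)
  sy <- unlist(syn_sites_table[cy], use.names = FALSE)
  S <- sum((sx + sy) / 2)
  N <- 3 * length(cx) - S
  Sd <- 0
  Nd <- 0
  for (i in which(cx != cy)) {
    d <- codon_pathway_diffs(cx[i], cy[i])
    Sd <- Sd + d[["sd"]]
    Nd <- Nd + d[["nd"]]
  }
  pS <- if (S > 0) Sd / S else NA_real_
  pN <- if (N > 0) Nd / N else NA_real_
  dS <- jc_or_na(pS)
  dN <- jc_or_na(pN)
  tibble(n_sites = ca$n_sites, S = S, N = N, Sd = Sd, Nd = Nd,
         pS = pS, pN = pN, dS = dS, dN = dN,
         ratio = ifelse(!is.na(dS) & dS > 0 & !is.na(dN), dN / dS, NA_real_))
}

#' Per-contig pairwise dN/dS survey
#'
#' Applies the alignment filters and NG86 to one genome pair across contigs,
#' and summarises with unweighted per-contig means and standard deviations
#' (each contig counts once regardless of length). Contigs named in
#' `exclude` -- typically those with a detected NRHR event -- are dropped
#' before alignment. Ratio summaries exclude contigs whose ratio is
#' undefined (`dS = 0` or out of the correction's domain).
#'
#' @param seqs Tibble with `contig_id`, `frame` (0-based phase; `NA` or a
#'   missing column falls back to [longest_orf_frame()]) and one column of
#'   sequence per lineage (masked positions as `N`).
#' @param pair Character vector of two column names to contrast.
#' @param exclude Contig ids to drop (e.g. NRHR-flagged).
#' @param min_len Minimum retained alignment length in bp.
#' @return A `dnds_survey`: list with `pair`, `per_contig` (one row per
#'   eligible contig) and `summary` (one-row tibble of means/SDs).
#' @export
pairwise_survey <- function(seqs, pair, exclude = character(), min_len = 198L) {
  stopifnot(length(pair) == 2L, all(pair %in% names(seqs)))
  if (!"frame" %in% names(seqs)) seqs$frame <- NA_integer_
  seqs <- seqs[!seqs$contig_id %in% exclude, ]
  missing_frame <- is.na(seqs$frame)
  if (any(missing_frame)) {
    # longest-ORF fallback for contigs lacking a predicted frame
    seqs$frame[missing_frame] <- map_int(
      which(missing_frame), ~ longest_orf_frame(seqs[[pair[1]]][.x]))
  }
  per <- map(seq_len(nrow(seqs)), function(i) {
    ca <- extract_codon_alignment(seqs[[pair[1]]][i], seqs[[pair[2]]][i],
                                  frame = seqs$frame[i], min_len = min_len,
                                  contig_id = seqs$contig_id[i], pair = pair)
    if (is.null(ca)) return(NULL)
    ng86(ca) |> mutate(contig_id = seqs$contig_id[i], .before = 1L)
  }) |> list_rbind()
  if (!nrow(per)) {
    summary <- tibble(n_contigs = 0L, total_sites = 0L)
  } else {
    ok_ratio <- !is.na(per$ratio)
    summary <- tibble(
      n_contigs = nrow(per),
      total_sites = sum(per$n_sites),
      mean_dS = mean(per$dS, na.rm = TRUE), sd_dS = sd(per$dS, na.rm = TRUE),
      mean_dN = mean(per$dN, na.rm = TRUE), sd_dN = sd(per$dN, na.rm = TRUE),
      mean_ratio = mean(per$ratio[ok_ratio]), sd_ratio = sd(per$ratio[ok_ratio]),
      n_ratio = sum(ok_ratio)
    )
  }
  structure(list(pair = pair, per_contig = per, summary = summary),
            class = "dnds_survey")
}

#' @export
print.dnds_survey <- function(x, ...) {
  cat(sprintf("<dnds_survey> %s vs %s: %d contigs, %d sites\n",
              x$pair[1], x$pair[2], x$summary$n_contigs, x$summary$total_sites))
  if (x$summary$n_contigs > 0) {
    cat(sprintf("  mean dS %.4f (%.4f)  mean dN %.4f (%.4f)  mean dN/dS %.3f (%.3f)\n",
                x$summary$mean_dS, x$summary$sd_dS, x$summary$mean_dN,
                x$summary$sd_dN, x$summary$mean_ratio, x$summary$sd_ratio))
  }
  invisible(x)
}

#' Phylogenetically polarized lineage-specific substitutions
#'
#' Over columns where all four lineages (diploid A2 and D5, tetraploid A and
#' D homoeologs of one species) carry unambiguous bases, a column increments
#' a lineage's count exactly when that lineage's base differs from the other
#' three and the other three are identical; columns with two or more derived
#' states are discarded.
#'
#' @param seqs Tibble with `contig_id` and sequence columns.
#' @param lineages Named character vector mapping the roles `A2`, `AT`,
#'   `D5`, `DT` to columns of `seqs`.
#' @return A `lineage_counts`: list with `counts` (tibble `lineage`,
#'   `substitutions`), `n_contigs`, `n_nucleotides`.
#' @export
polarize_substitutions <- function(seqs,
                                   lineages = c(A2 = "A2", AT = "AD1_A",
                                                D5 = "D5", DT = "AD1_D")) {
  stopifnot(all(c("A2", "AT", "D5", "DT") %in% names(lineages)),
            all(lineages %in% names(seqs)))
  tot <- c(A2 = 0L, AT = 0L, D5 = 0L, DT = 0L)
  n_nt <- 0L
  n_contigs <- 0L
  for (i in seq_len(nrow(seqs))) {
    m <- rbind(
      A2 = seq_chars(seqs[[lineages[["A2"]]]][i]),
      AT = seq_chars(seqs[[lineages[["AT"]]]][i]),
      D5 = seq_chars(seqs[[lineages[["D5"]]]][i]),
      DT = seq_chars(seqs[[lineages[["DT"]]]][i])
    )
    ok <- colSums(matrix(m %in% BASES, nrow = 4L)) == 4L
    if (!any(ok)) next
    m <- m[, ok, drop = FALSE]
    n_nt <- n_nt + ncol(m)
    n_contigs <- n_contigs + 1L
    for (f in rownames(m)) {
      others <- m[setdiff(rownames(m), f), , drop = FALSE]
      unanimous <- others[1, ] == others[2, ] & others[1, ] == others[3, ]
      tot[[f]] <- tot[[f]] + sum(unanimous & m[f, ] != others[1, ])
    }
  }
  structure(list(
    counts = tibble(lineage = names(tot), substitutions = as.integer(tot)),
    n_contigs = n_contigs, n_nucleotides = n_nt
  ), class = "lineage_counts")
}

#' @export
print.lineage_counts <- function(x, ...) {
  cat(sprintf("<lineage_counts> %d contigs, %d nucleotides\n",
              x$n_contigs, x$n_nucleotides))
  print(x$counts)
  invisible(x)
}

#' Two-sided exact binomial test
#'
#' Tests whether `k_tetra` successes among `k_tetra + k_diploid` trials are
#' consistent with success probability `p0`; the two-sided p-value doubles
#' the smaller tail, capped at 1.
#'
#' @param k_tetra,k_diploid Non-negative counts (e.g. tetraploid and diploid
#'   lineage-specific substitutions); their sum must be positive.
#' @param p0 Null success probability.
#' @return The p-value.
#' @export
exact_binomial <- function(k_tetra, k_diploid, p0 = 0.5) {
  n <- k_tetra + k_diploid
  if (n <= 0) abort("k_tetra + k_diploid must be > 0")
  lower <- pbinom(k_tetra, n, p0)
  upper <- pbinom(k_tetra - 1, n, p0, lower.tail = FALSE)
  min(1, 2 * min(lower, upper))
}

#' Wilcoxon signed-rank test on paired per-contig values
#'
#' Zero differences are dropped and ties mid-ranked; the null distribution
#' is exact for 25 or fewer non-zero differences (when free of ties) and a
#' normal approximation with continuity correction otherwise. A pair of
#' identical vectors returns p = 1.
#'
#' @param x,y Paired numeric vectors (e.g. per-contig dN/dS ratios of two
#'   contrasts matched by contig).
#' @param min_pairs Minimum non-zero differences required.
#' @return List with `statistic` (V), `n` (non-zero pairs) and `p_value`.
#' @export
wilcoxon_signed_rank <- function(x, y, min_pairs = 6L) {
  stopifnot(length(x) == length(y))
  keep <- !is.na(x) & !is.na(y)
  d <- x[keep] - y[keep]
  d <- d[d != 0]
  n <- length(d)
  if (n == 0L) {
    return(list(statistic = 0, n = 0L, p_value = 1))
  }
  if (n < min_pairs) {
    abort(sprintf("only %d non-zero differences; need >= %d", n, min_pairs))
  }
  ht <- suppressWarnings(
    stats::wilcox.test(d, exact = n <= 25L, correct = TRUE))
  list(statistic = unname(ht$statistic), n = n, p_value = ht$p.value)
}

#' Longest-ORF reading-frame fallback
#'
#' Picks the 0-based codon phase (0, 1 or 2) whose longest stop-free codon
#' run is maximal, a fallback for contigs without an externally predicted
#' coding frame. Masked/ambiguous codons break a run. Ties resolve to the
#' smallest phase.
#'
#' @param seq Nucleotide string (masks allowed).
#' @return Integer phase in `0:2`.
#' @export
longest_orf_frame <- function(seq) {
  n <- nchar(seq)
  best_frame <- 0L
  best_run <- -1L
  for (frame in 0:2) {
    ncod <- (n - frame) %/% 3L
    if (ncod < 1L) next
    starts <- frame + 1L + 3L * (seq_len(ncod) - 1L)
    cods <- substring(seq, starts, starts + 2L)
    ok <- !grepl("[^ACGT]", cods)
    ok[ok] <- codon_table[cods[ok]] != "*"
    r <- rle(ok)
    run <- if (any(r$values)) max(r$lengths[r$values]) else 0L
    if (run > best_run) {
      best_run <- run
      best_frame <- frame
    }
  }
  best_frame
}
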