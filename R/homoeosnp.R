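# Genome-diagnostic SNP discovery.
#
# Two routes mirror the two platforms: (1) assembly route -- majority-rule
# diploid consensuses, tetraploid read partitioning, tetraploid per-genome
# consensuses, SNPs where the genome consensuses differ and match the
# diploid alleles; (2) pileup route -- per-genome short-read columns scored
# with a binomial error model and a phred-style consensus quality.

#' Majority-rule consensus from column counts
#'
#' A column is masked (`N`) when its depth is below `min_depth`, the major
#' allele frequency is not strictly greater than `min_major_freq`, or the
#' major allele is tied.
#'
#' @param counts 4 x L count matrix from [pileup_counts()].
#' @param min_major_freq Strict lower bound on major-allele frequency
#'   (default 0.90: the major allele must exceed 90%).
#' @param min_depth Minimum covering reads per column.
#' @return List with `bases` (length-L character vector, `N` = masked),
#'   `depth` and `major_freq` numeric vectors.
#' @export
consensus_from_counts <- function(counts, min_major_freq = 0.90, min_depth = 2L) {
  depth <- colSums(counts)
  top <- apply(counts, 2L, max)
  tie <- colSums(counts == rep(top, each = 4L)) > 1L & top > 0L
  major <- BASES[max.col(t(counts), ties.method = "first")]
  freq <- ifelse(depth > 0, top / depth, 0)
  ok <- depth >= min_depth & freq > min_major_freq & !tie
  list(bases = ifelse(ok, major, "N"), depth = depth, major_freq = freq)
}

#' Build a per-group consensus for one contig
#'
#' @param aln A `contig_alignment`.
#' @param contig_id Contig.
#' @param group Species labels whose reads form the group.
#' @param platform Optional platform filter.
#' @inheritParams consensus_from_counts
#' @return A `consensus` list: `contig_id`, `group`, `bases` (string with
#'   `N` masks), `depth`, `major_freq`.
#' @export
build_consensus <- function(aln, contig_id, group, platform = NULL,
                            min_major_freq = 0.90, min_depth = 2L) {
  stopifnot(inherits(aln, "contig_alignment"))
  if (!any(aln$reads$species %in% group)) {
    abort(sprintf("no reads for group '%s'", paste(group, collapse = "+")))
  }
  clen <- aln$contigs$length[match(contig_id, aln$contigs$contig_id)]
  r <- aln$reads[aln$reads$contig_id == contig_id & aln$reads$species %in% group, ]
  if (!is.null(platform)) r <- r[r$platform %in% platform, ]
  cons <- consensus_from_counts(pileup_counts(r$bases, r$start, clen),
                                min_major_freq, min_depth)
  structure(list(contig_id = contig_id, group = paste(group, collapse = "+"),
                 bases = paste(cons$bases, collapse = ""),
                 depth = cons$depth, major_freq = cons$major_freq),
            class = "consensus")
}

# long tibble of (read x diagnostic site) observations for one or more
# contigs: read_id, species, platform, contig_id, pos, base, phred (NA if no
# qualities), a_allele, d_allele, state ("A"/"D"/NA)
read_site_observations <- function(reads, snps) {
  if (!nrow(reads) || !nrow(snps)) {
    return(tibble(read_id = character(), species = character(),
                  platform = character(), contig_id = character(),
                  pos = integer(), base = character(), phred = integer(),
                  a_allele = character(), d_allele = character(),
                  state = character()))
  }
  obs <- reads |>
    select("read_id", "species", "platform", "contig_id", "start", "bases", "quals") |>
    inner_join(snps |> select("contig_id", "pos", "a_allele", "d_allele"),
               by = "contig_id", relationship = "many-to-many") |>
    filter(.data$pos >= .data$start,
           .data$pos < .data$start + nchar(.data$bases)) |>
    mutate(
      off = .data$pos - .data$start + 1L,
      base = substr(.data$bases, .data$off, .data$off),
      state = case_when(.data$base == .data$a_allele ~ "A",
                        .data$base == .data$d_allele ~ "D",
                        TRUE ~ NA_character_)
    )
  # per-base phred (vectorised single-char substr on the quality strings)
  qc <- substr(ifelse(is.na(obs$quals), "!", obs$quals), obs$off, obs$off)
  qc[qc == ""] <- "!"
  obs$phred <- ifelse(is.na(obs$quals), NA_integer_,
                      if (nrow(obs)) utf8ToInt(paste(qc, collapse = "")) - 33L
                      else integer(0))
  obs |> select(-"start", -"bases", -"quals", -"off")
}

#' Partition tetraploid reads between the A and D genomes
#'
#' Each read is compared to the diagnostic alleles at the sites it covers:
#' bases matching the A (D) allele vote A (D); bases matching neither are
#' ignored. All-A votes give call `A`, all-D give `D`, mixed votes
#' `chimeric`, and no informative site `unassigned`.
#'
#' @param reads Reads tibble (tetraploid reads; other species are passed
#'   through as `unassigned` with zero votes if present).
#' @param snps Diagnostic SNP tibble (`contig_id`, `pos`, `a_allele`,
#'   `d_allele`).
#' @return Tibble `read_id`, `species`, `contig_id`, `genome_call`,
#'   `sites_seen`, `votes_A`, `votes_D`.
#' @export
assign_reads <- function(reads, snps) {
  obs <- read_site_observations(reads, snps)
  votes <- obs |>
    group_by(.data$read_id) |>
    summarise(sites_seen = n(),
              votes_A = sum(.data$state == "A", na.rm = TRUE),
              votes_D = sum(.data$state == "D", na.rm = TRUE),
              .groups = "drop")
  reads |>
    select("read_id", "species", "contig_id") |>
    left_join(votes, by = "read_id") |>
    mutate(
      sites_seen = coalesce(.data$sites_seen, 0L),
      votes_A = coalesce(.data$votes_A, 0L),
      votes_D = coalesce(.data$votes_D, 0L),
      genome_call = case_when(
        .data$votes_A > 0L & .data$votes_D == 0L ~ "A",
        .data$votes_D > 0L & .data$votes_A == 0L ~ "D",
        .data$votes_A > 0L & .data$votes_D > 0L ~ "chimeric",
        TRUE ~ "unassigned")
    ) |>
    select("read_id", "species", "contig_id", "genome_call",
           "sites_seen", "votes_A", "votes_D")
}

#' Call genome-diagnostic SNPs from the long-read assembly
#'
#' Per contig: build majority-rule consensuses for the A2 and D5 diploid
#' reads, take unmasked differing columns as candidate diagnostics,
#' categorise each tetraploid read as A- or D-genome by the majority of its
#' diagnostic-allele votes (ties are left out), build pooled tetraploid A-
#' and D-genome consensuses from the categorised reads, and emit a SNP where
#' the two tetraploid consensuses differ and each matches its diploid
#' allele. Contigs lacking reads from either diploid are skipped (with a
#' message) and yield no calls.
#'
#' Majority (rather than unanimous) vote matters: candidate columns include
#' diploid-private (autapomorphic) sites at which every tetraploid read
#' carries the opposite diploid's allele. Requiring unanimity would discard
#' nearly all reads on contigs carrying both an A2- and a D5-private site;
#' with majority categorisation such sites instead produce a tetraploid
#' consensus that contradicts the diploid allele and are filtered here,
#' which is exactly the desired behaviour.
#'
#' @param aln A `contig_alignment`.
#' @param min_major_freq,min_depth Consensus thresholds (see
#'   [consensus_from_counts()]).
#' @param tetraploids Tetraploid species labels.
#' @param diploids Named mapping of genome -> diploid species label.
#' @param quiet Suppress the skipped-contig message.
#' @return Diagnostic SNP tibble: `contig_id`, `pos` (0-based), `a_allele`,
#'   `d_allele`, `platform = "long"`, `qual = NA`.
#' @export
call_assembly_snps <- function(aln, min_major_freq = 0.90, min_depth = 2L,
                               tetraploids = c("AD1", "AD2"),
                               diploids = c(A = "A2", D = "D5"),
                               quiet = FALSE) {
  assembly_snp_engine(aln, min_major_freq, min_depth, tetraploids, diploids,
                      quiet)
}

#' Diagnostic-site set for NRHR screening
#'
#' Candidate diagnostics (unmasked differing diploid consensus columns)
#' kept when both parental alleles are observed among the allotetraploid
#' long reads (`min_allele_support` reads each). Unlike
#' [call_assembly_snps()], no tetraploid consensus is required, so sites
#' inside a species-specific homoeologous-exchange tract -- where the
#' recipient subgenome's reads all carry the donor allele -- remain
#' diagnostic and the tract stays visible to [detect_nrhr()]. Diploid-
#' private (autapomorphic) sites are monomorphic among tetraploid reads and
#' are excluded by the confirmation requirement.
#'
#' @inheritParams call_assembly_snps
#' @param min_allele_support Minimum tetraploid reads carrying each allele.
#' @return Diagnostic SNP tibble as in [call_assembly_snps()], with a
#'   `confirmed` column (all `TRUE`).
#' @export
nrhr_diagnostics <- function(aln, min_major_freq = 0.90, min_depth = 2L,
                             tetraploids = c("AD1", "AD2"),
                             diploids = c(A = "A2", D = "D5"),
                             min_allele_support = 2L) {
  stopifnot(inherits(aln, "contig_alignment"))
  long_reads <- aln$reads[aln$reads$platform == "long", ]
  cand <- map(seq_len(nrow(aln$contigs)), function(i) {
    cid <- aln$contigs$contig_id[i]
    clen <- aln$contigs$length[i]
    r <- long_reads[long_reads$contig_id == cid, ]
    ra <- r[r$species == diploids[["A"]], ]
    rd <- r[r$species == diploids[["D"]], ]
    if (!nrow(ra) || !nrow(rd)) return(NULL)
    cons_a <- consensus_from_counts(pileup_counts(ra$bases, ra$start, clen),
                                    min_major_freq, min_depth)
    cons_d <- consensus_from_counts(pileup_counts(rd$bases, rd$start, clen),
                                    min_major_freq, min_depth)
    hit <- which(cons_a$bases != "N" & cons_d$bases != "N" &
                   cons_a$bases != cons_d$bases)
    if (!length(hit)) return(NULL)
    tibble(contig_id = cid, pos = hit - 1L,
           a_allele = cons_a$bases[hit], d_allele = cons_d$bases[hit])
  }) |> list_rbind()
  if (!nrow(cand)) {
    return(tibble(contig_id = character(), pos = integer(),
                  a_allele = character(), d_allele = character(),
                  platform = character(), qual = double(), confirmed = logical()))
  }
  tet <- long_reads[long_reads$species %in% tetraploids, ]
  obs <- read_site_observations(tet, cand)
  support <- obs |>
    group_by(.data$contig_id, .data$pos) |>
    summarise(n_a = sum(.data$state == "A", na.rm = TRUE),
              n_d = sum(.data$state == "D", na.rm = TRUE), .groups = "drop")
  cand |>
    inner_join(support, by = c("contig_id", "pos")) |>
    filter(.data$n_a >= min_allele_support, .data$n_d >= min_allele_support) |>
    select(-"n_a", -"n_d") |>
    mutate(platform = "long", qual = NA_real_, confirmed = TRUE)
}

assembly_snp_engine <- function(aln, min_major_freq, min_depth, tetraploids,
                                diploids, quiet) {
  stopifnot(inherits(aln, "contig_alignment"))
  long_reads <- aln$reads[aln$reads$platform == "long", ]
  skipped <- character(0)
  res <- map(seq_len(nrow(aln$contigs)), function(i) {
    cid <- aln$contigs$contig_id[i]
    clen <- aln$contigs$length[i]
    r <- long_reads[long_reads$contig_id == cid, ]
    ra <- r[r$species == diploids[["A"]], ]
    rd <- r[r$species == diploids[["D"]], ]
    if (!nrow(ra) || !nrow(rd)) {
      skipped <<- c(skipped, cid)
      return(NULL)
    }
    cons_a <- consensus_from_counts(pileup_counts(ra$bases, ra$start, clen),
                                    min_major_freq, min_depth)
    cons_d <- consensus_from_counts(pileup_counts(rd$bases, rd$start, clen),
                                    min_major_freq, min_depth)
    cand <- which(cons_a$bases != "N" & cons_d$bases != "N" &
                    cons_a$bases != cons_d$bases)
    if (!length(cand)) return(NULL)
    snps <- tibble(contig_id = cid, pos = cand - 1L,
                   a_allele = cons_a$bases[cand], d_allele = cons_d$bases[cand])
    tet <- r[r$species %in% tetraploids, ]
    if (!nrow(tet)) return(NULL)
    # Vote sites start from the tetraploid-confirmed candidates (both
    # parental alleles observed among tetraploid reads): diploid-private
    # candidate columns are monomorphic in the tetraploids and would
    # otherwise attract systematic opposite votes that mis-categorise reads
    # near a cluster of them. Assignment and consensus are then iterated to
    # a fixed point, re-voting on the surviving sites.
    tp <- pileup_counts(tet$bases, tet$start, clen)
    n_a <- tp[cbind(match(snps$a_allele, BASES), snps$pos + 1L)]
    n_d <- tp[cbind(match(snps$d_allele, BASES), snps$pos + 1L)]
    vote_sites <- snps[n_a >= 2L & n_d >= 2L, ]
    out <- snps[0, ]
    for (pass in 1:4) {
      if (!nrow(vote_sites)) break
      asg <- assign_reads(tet, vote_sites)
      tet_a <- tet[tet$read_id %in% asg$read_id[asg$votes_A > asg$votes_D], ]
      tet_d <- tet[tet$read_id %in% asg$read_id[asg$votes_D > asg$votes_A], ]
      ta <- consensus_from_counts(pileup_counts(tet_a$bases, tet_a$start, clen),
                                  min_major_freq, min_depth)
      td <- consensus_from_counts(pileup_counts(tet_d$bases, tet_d$start, clen),
                                  min_major_freq, min_depth)
      ta_b <- ta$bases[snps$pos + 1L]
      td_b <- td$bases[snps$pos + 1L]
      prev <- out
      out <- snps[ta_b == snps$a_allele & td_b == snps$d_allele, ]
      if (nrow(out) == nrow(prev) && all(out$pos == prev$pos)) break
      vote_sites <- out
    }
    out
  }) |> list_rbind()
  if (length(skipped) && !quiet) {
    message(sprintf("skipped %d contig(s) lacking reads from both diploids",
                    length(skipped)))
  }
  if (!nrow(res)) {
    res <- tibble(contig_id = character(), pos = integer(),
                  a_allele = character(), d_allele = character())
  }
  res |> mutate(platform = "long", qual = NA_real_)
}

# Phred-scaled probability that the major base is not the column's single
# true base. The binomial model compares, under independent per-base errors
# at rate `err` and a uniform prior, the four pure-base hypotheses against
# the six equal-mixture hypotheses (two bases at 50:50 -- the signature of
# an unseparated homoeolog column or residual polymorphism). Low depth is
# penalised naturally: a clean column needs about nine reads to exclude a
# mixture at phred 20.
consensus_quals <- function(counts, err) {
  err <- min(max(err, 1e-6), 0.74)
  depth <- colSums(counts)
  nc <- ncol(counts)
  lp_hit <- log(1 - err)
  lp_miss <- log(err / 3)
  lp_mix_hit <- log(((1 - err) + err / 3) / 2)
  # 4 pure hypotheses then 6 mixture hypotheses
  ll <- matrix(0, nrow = 10L, ncol = nc)
  ll[1:4, ] <- lp_hit * counts + lp_miss * (rep(depth, each = 4L) - counts)
  pairs <- combn(4L, 2L)
  for (k in seq_len(ncol(pairs))) {
    nbc <- counts[pairs[1, k], ] + counts[pairs[2, k], ]
    ll[4L + k, ] <- lp_mix_hit * nbc + lp_miss * (depth - nbc)
  }
  m <- apply(ll, 2L, max)
  post <- exp(sweep(ll, 2L, m))
  post <- sweep(post, 2L, colSums(post), "/")
  major_idx <- max.col(t(counts), ties.method = "first")
  p_wrong <- 1 - post[cbind(major_idx, seq_len(nc))]
  qual <- -10 * log10(pmax(p_wrong, 1e-10))
  list(major = BASES[major_idx], qual = pmin(qual, 99), depth = depth)
}

#' Call genome-diagnostic SNPs from short-read pileups
#'
#' For each contig column and each diploid genome group, the major base is
#' scored with a phred-style quality, `-10 log10 P(consensus wrong)`, from a
#' binomial error model with uniform per-base error `err`. A SNP is emitted
#' where the two group consensuses differ and both qualities reach
#' `min_qual`.
#'
#' @param aln A `contig_alignment` (short reads are selected by platform).
#' @param min_qual Phred quality threshold (default 20).
#' @param err Per-base error rate of the quality model.
#' @param diploids Named mapping of genome -> diploid species label.
#' @return Diagnostic SNP tibble (`platform = "short"`, `qual` = the smaller
#'   of the two group qualities).
#' @export
call_pileup_snps <- function(aln, min_qual = 20, err = 0.01,
                             diploids = c(A = "A2", D = "D5")) {
  stopifnot(inherits(aln, "contig_alignment"))
  short_reads <- aln$reads[aln$reads$platform == "short", ]
  res <- map(seq_len(nrow(aln$contigs)), function(i) {
    cid <- aln$contigs$contig_id[i]
    clen <- aln$contigs$length[i]
    r <- short_reads[short_reads$contig_id == cid, ]
    ra <- r[r$species == diploids[["A"]], ]
    rd <- r[r$species == diploids[["D"]], ]
    if (!nrow(ra) || !nrow(rd)) return(NULL)
    qa <- consensus_quals(pileup_counts(ra$bases, ra$start, clen), err)
    qd <- consensus_quals(pileup_counts(rd$bases, rd$start, clen), err)
    keep <- qa$depth > 0 & qd$depth > 0 & qa$major != qd$major &
      qa$qual >= min_qual & qd$qual >= min_qual
    if (!any(keep)) return(NULL)
    tibble(contig_id = cid, pos = which(keep) - 1L,
           a_allele = qa$major[keep], d_allele = qd$major[keep],
           platform = "short", qual = pmin(qa$qual, qd$qual)[keep])
  }) |> list_rbind()
  if (!nrow(res)) {
    res <- tibble(contig_id = character(), pos = integer(),
                  a_allele = character(), d_allele = character(),
                  platform = character(), qual = double())
  }
  res
}

#' Confirm SNPs inside the allotetraploids
#'
#' A SNP is `confirmed` when at least one allotetraploid read carries the A
#' allele and at least one carries the D allele at the site; this guards
#' against diploid lineage-specific mutations and tetraploid gene loss
#' masquerading as diagnostic sites.
#'
#' @param snps Diagnostic SNP tibble.
#' @param aln A `contig_alignment` holding the allotetraploid reads.
#' @param tetraploids Tetraploid species labels.
#' @param platform Optional platform filter for the confirming reads.
#' @return `snps` with a logical `confirmed` column.
#' @export
confirm_in_tetraploid <- function(snps, aln, tetraploids = c("AD1", "AD2"),
                                  platform = NULL) {
  stopifnot(inherits(aln, "contig_alignment"))
  tet <- aln$reads[aln$reads$species %in% tetraploids, ]
  if (!is.null(platform)) tet <- tet[tet$platform %in% platform, ]
  obs <- read_site_observations(tet, snps)
  seen <- obs |>
    group_by(.data$contig_id, .data$pos) |>
    summarise(saw_a = any(.data$state == "A", na.rm = TRUE),
              saw_d = any(.data$state == "D", na.rm = TRUE),
              .groups = "drop")
  snps |>
    left_join(seen, by = c("contig_id", "pos")) |>
    mutate(confirmed = coalesce(.data$saw_a, FALSE) & coalesce(.data$saw_d, FALSE)) |>
    select(-"saw_a", -"saw_d")
}

#' Reconcile SNP calls across platforms
#'
#' Joins the two platform call sets on (contig, position). Sites present in
#' both agree when their (A allele, D allele) orientation is identical; the
#' union count follows inclusion-exclusion,
#' `n_union = n_long + n_short - n_common`.
#'
#' @param long_snps,short_snps Diagnostic SNP tibbles keyed by
#'   (`contig_id`, `pos`); duplicate keys within a platform are an error.
#' @return A `platform_reconciliation`: list with `snps` (joined tibble with
#'   an `agreement` column: `agree`, `disagree`, `long-only`, `short-only`)
#'   and the counts `n_long`, `n_short`, `n_common`, `n_agree`,
#'   `n_disagree`, `n_union`.
#' @export
reconcile_platforms <- function(long_snps, short_snps) {
  for (nm in c("long", "short")) {
    s <- if (nm == "long") long_snps else short_snps
    if (anyDuplicated(s[c("contig_id", "pos")])) {
      abort(sprintf("duplicate (contig, pos) keys in %s-platform SNPs", nm))
    }
  }
  j <- full_join(
    long_snps |> select("contig_id", "pos", la = "a_allele", ld = "d_allele"),
    short_snps |> select("contig_id", "pos", sa = "a_allele", sd = "d_allele"),
    by = c("contig_id", "pos")) |>
    mutate(agreement = case_when(
      !is.na(.data$la) & !is.na(.data$sa) &
        .data$la == .data$sa & .data$ld == .data$sd ~ "agree",
      !is.na(.data$la) & !is.na(.data$sa) ~ "disagree",
      !is.na(.data$la) ~ "long-only",
      TRUE ~ "short-only")) |>
    rename(a_allele_long = "la", d_allele_long = "ld",
           a_allele_short = "sa", d_allele_short = "sd") |>
    arrange(.data$contig_id, .data$pos)
  n_long <- nrow(long_snps)
  n_short <- nrow(short_snps)
  n_common <- sum(j$agreement %in% c("agree", "disagree"))
  structure(list(
    snps = j,
    n_long = n_long, n_short = n_short, n_common = n_common,
    n_agree = sum(j$agreement == "agree"),
    n_disagree = sum(j$agreement == "disagree"),
    n_union = n_long + n_short - n_common
  ), class = "platform_reconciliation")
}

#' @export
print.platform_reconciliation <- function(x, ...) {
  cat(sprintf(paste0("<platform_reconciliation> long %d, short %d, common %d ",
                     "(agree %d, disagree %d), union %d\n"),
              x$n_long, x$n_short, x$n_common, x$n_agree, x$n_disagree, x$n_union))
  invisible(x)
}

#' Write diagnostic SNPs as a minimal VCF
#'
#' 1-based positions; REF is the A-genome allele, ALT the D-genome allele;
#' INFO carries `PLAT` and, when present, `CONF`.
#'
#' @param snps Diagnostic SNP tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_snp_vcf <- function(snps, path) {
  hdr <- c("##fileformat=VCFv4.2",
           "##INFO=<ID=PLAT,Number=1,Type=String,Description=\"Calling platform\">",
           "##INFO=<ID=CONF,Number=0,Type=Flag,Description=\"Confirmed in allotetraploid reads\">",
           "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO")
  info <- paste0("PLAT=", snps$platform)
  if ("confirmed" %in% names(snps)) {
    info <- ifelse(snps$confirmed, paste0(info, ";CONF"), info)
  }
  qual <- if ("qual" %in% names(snps)) ifelse(is.na(snps$qual), ".",
                                              sprintf("%.0f", snps$qual)) else "."
  body <- sprintf("%s\t%d\t.\t%s\t%s\t%s\tPASS\t%s",
                  snps$contig_id, snps$pos + 1L, snps$a_allele, snps$d_allele,
                  qual, info)
  writeLines(c(hdr, body), path)
  invisible(path)
}
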