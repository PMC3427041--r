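# Synthetic allopolyploid transcriptome generator.
#
# Emulates four coding "genomes" per contig -- the diploid progenitors A2 and
# D5 plus the A and D homoeologs resident in two allotetraploid species (AD1,
# AD2) -- with calibrated synonymous divergence, nonreciprocal homoeologous
# recombination (NRHR) tracts, and two read platforms, all with complete
# truth records.

LINEAGES <- c("A2", "D5", "AD1_A", "AD1_D", "AD2_A", "AD2_D")
SPECIES <- c("A2", "D5", "AD1", "AD2")
TETRAPLOIDS <- c("AD1", "AD2")

#' Simulation configuration
#'
#' Parameters of the synthetic allopolyploid transcriptome. Defaults emulate
#' the cotton study conditions: inter-genome synonymous divergence near
#' dS = 0.036 under dN/dS = 0.3, short post-polyploid branches whose sums
#' reproduce the published pairwise diploid-tetraploid distances
#' (dS 0.005--0.010) and whose ratios reproduce the observed tetraploid
#' rate acceleration (lineage-specific substitution ratios near 1.7), NRHR
#' tracts on ~7% of contigs of which ~23% are shared by (ancestral to) both
#' allotetraploid species, long reads of 250--450 bp and 82-bp short reads
#' with base qualities.
#'
#' `target_ds_ad` is the total A2-vs-D5 synonymous distance; the divergence
#' applied between the A- and D-genome ancestors is `target_ds_ad` minus the
#' terminal A2 and D5 branch lengths, so the pairwise diploid contrast
#' recovers the target.
#'
#' @param n_contigs Number of contigs to simulate.
#' @param contig_len_mean,contig_len_sd Contig length distribution (bp);
#'   lengths are rounded to a multiple of 3 and floored at 300 bp.
#' @param target_ds_ad Total A2-vs-D5 synonymous divergence
#'   (substitutions per synonymous site).
#' @param target_dnds Nonsynonymous/synonymous rate ratio used as the
#'   acceptance probability for nonsynonymous changes.
#' @param branch_ds Named vector of post-divergence branch lengths (dS units)
#'   for lineages `A2`, `AT`, `D5`, `DT`; `AT`/`DT` apply to the homoeologs
#'   of both allotetraploid species.
#' @param nrhr_contig_frac Fraction of contigs receiving at least one NRHR
#'   tract.
#' @param nrhr_events_per_contig Number of tracts planted on each affected
#'   contig.
#' @param nrhr_tract_len_mean Mean tract length (bp); lengths are geometric.
#' @param nrhr_shared_frac Fraction of events that are ancestral (shared by
#'   both allotetraploid species at identical coordinates).
#' @param nrhr_species_weights Relative weights for assigning non-shared
#'   events to AD1 vs AD2.
#' @param long_read_range Long-read length range (bp, inclusive).
#' @param long_cov,short_cov Nominal fold coverage per genome lineage and
#'   platform.
#' @param short_read_len Short-read length (bp).
#' @param long_err,short_err Per-base substitution error probabilities.
#' @param seed Integer seed; identical configurations give byte-identical
#'   datasets.
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_contigs = 100L,
                       contig_len_mean = 1000,
                       contig_len_sd = 200,
                       target_ds_ad = 0.036,
                       target_dnds = 0.3,
                       branch_ds = c(A2 = 0.002, AT = 0.0035, D5 = 0.0035, DT = 0.006),
                       nrhr_contig_frac = 0.07,
                       nrhr_events_per_contig = 1L,
                       nrhr_tract_len_mean = 300,
                       nrhr_shared_frac = 0.23,
                       nrhr_species_weights = c(AD1 = 0.46, AD2 = 0.31),
                       long_read_range = c(250L, 450L),
                       long_cov = 20,
                       short_read_len = 82L,
                       short_cov = 20,
                       long_err = 0.001,
                       short_err = 0.005,
                       seed = 1L) {
  cfg <- list(
    n_contigs = as.integer(n_contigs),
    contig_len_mean = contig_len_mean, contig_len_sd = contig_len_sd,
    target_ds_ad = target_ds_ad, target_dnds = target_dnds,
    branch_ds = branch_ds,
    nrhr_contig_frac = nrhr_contig_frac,
    nrhr_events_per_contig = as.integer(nrhr_events_per_contig),
    nrhr_tract_len_mean = nrhr_tract_len_mean,
    nrhr_shared_frac = nrhr_shared_frac,
    nrhr_species_weights = nrhr_species_weights,
    long_read_range = as.integer(long_read_range),
    long_cov = long_cov, short_read_len = as.integer(short_read_len),
    short_cov = short_cov, long_err = long_err, short_err = short_err,
    seed = as.integer(seed)
  )
  fracs <- c(cfg$nrhr_contig_frac, cfg$nrhr_shared_frac, cfg$long_err,
             cfg$short_err, cfg$target_dnds)
  if (any(fracs < 0 | fracs > 1)) {
    abort("fractions and error rates must lie in [0, 1]")
  }
  if (cfg$target_ds_ad < 0 || any(cfg$branch_ds < 0)) {
    abort("divergence targets must be non-negative")
  }
  if (!all(c("A2", "AT", "D5", "DT") %in% names(cfg$branch_ds))) {
    abort("branch_ds must name lineages A2, AT, D5, DT")
  }
  if (cfg$target_ds_ad < cfg$branch_ds[["A2"]] + cfg$branch_ds[["D5"]]) {
    abort("target_ds_ad must be at least branch_ds[A2] + branch_ds[D5]")
  }
  if (cfg$n_contigs < 0 || cfg$contig_len_mean <= 0 ||
      cfg$nrhr_tract_len_mean <= 0 || any(cfg$long_read_range <= 0) ||
      cfg$short_read_len <= 0) {
    abort("counts and lengths must be positive")
  }
  structure(cfg, class = "sim_config")
}

# proposal probability per site whose Jukes-Cantor correction equals d
proposal_rate <- function(d) 0.75 * (1 - exp(-4 / 3 * d))

#' Mutate a coding sequence toward a target synonymous divergence
#'
#' Substitutions are proposed uniformly over sites with equal base exchange;
#' a proposal is accepted with probability 1 when synonymous and with
#' probability `dnds` when nonsynonymous. Changes creating a stop codon are
#' rejected. The per-site proposal probability is chosen so that the
#' Jukes-Cantor-corrected synonymous distance to the input has expectation
#' `target_ds`. Bases outside the in-frame complete-codon region are treated
#' as unconstrained (accepted like synonymous changes). Uses the current RNG
#' stream.
#'
#' @param seq Coding nucleotide string (ACGT only).
#' @param frame 0-based codon phase offset.
#' @param target_ds Target synonymous divergence from the input.
#' @param dnds Acceptance probability for nonsynonymous proposals, between 0 and 1.
#' @return The mutated nucleotide string.
#' @export
mutate_sequence <- function(seq, frame = 0L, target_ds = 0.036, dnds = 0.3) {
  assert_acgt(seq)
  if (target_ds < 0) abort("target_ds must be >= 0")
  if (dnds < 0 || dnds > 1) abort("dnds must lie in [0, 1]")
  if (nchar(seq) < 3L) abort("seq must be at least one codon long")
  chars <- seq_chars(seq)
  n <- length(chars)
  if (target_ds == 0) return(seq)
  q <- proposal_rate(target_ds)
  hit <- which(runif(n) < q)
  if (!length(hit)) return(seq)
  alt <- BASES[(match(chars[hit], BASES) - 1L +
                  sample.int(3L, length(hit), replace = TRUE)) %% 4L + 1L]
  cstart <- frame + 1L
  cend <- frame + 3L * ((n - frame) %/% 3L)
  for (k in seq_along(hit)) {
    i <- hit[k]
    b <- alt[k]
    if (i >= cstart && i <= cend) {
      c0 <- cstart + 3L * ((i - cstart) %/% 3L)
      cod <- chars[c0:(c0 + 2L)]
      aa0 <- codon_table[[paste(cod, collapse = "")]]
      cod[i - c0 + 1L] <- b
      aa1 <- codon_table[[paste(cod, collapse = "")]]
      if (identical(aa1, aa0)) {
        chars[i] <- b
      } else if (aa1 != "*" && runif(1) < dnds) {
        chars[i] <- b
      }
    } else {
      chars[i] <- b
    }
  }
  paste(chars, collapse = "")
}

random_coding_seq <- function(len) {
  stopifnot(len %% 3 == 0)
  sense <- names(codon_table)[codon_table != "*"]
  paste(sample(sense, len / 3, replace = TRUE), collapse = "")
}

#' Apply a nonreciprocal homoeologous recombination tract
#'
#' Overwrites the recipient homoeolog's tract with the donor homoeolog's
#' bases in the named allotetraploid species (both species when
#' `shared = TRUE`), and records the event in the truth table. Coordinates
#' are 0-based half-open on the contig. A zero-length tract changes nothing
#' and records no event.
#'
#' @param truth A `homeo_truth` object (see [sim_dataset()]).
#' @param contig_id Contig identifier.
#' @param species `"AD1"` or `"AD2"`; ignored when `shared = TRUE`.
#' @param direction `"D->A"` (D donor, A homoeolog overwritten) or `"A->D"`.
#' @param start,end Tract interval, 0-based half-open; clipped to the contig.
#' @param shared Apply to both allotetraploid species (ancestral event).
#' @return The updated `homeo_truth`.
#' @export
apply_nrhr <- function(truth, contig_id, species = "AD1",
                       direction = c("D->A", "A->D"),
                       start, end, shared = FALSE) {
  direction <- match.arg(direction)
  row <- which(truth$genomes$contig_id == contig_id)
  if (length(row) != 1L) abort(sprintf("unknown contig '%s'", contig_id))
  if (!shared && !species %in% TETRAPLOIDS) {
    abort(sprintf("unknown tetraploid species '%s'", species))
  }
  len <- truth$genomes$length[row]
  start <- max(0L, as.integer(start))
  end <- min(as.integer(end), len)
  if (end <= start) return(truth)
  sp <- if (shared) TETRAPLOIDS else species
  donor_g <- if (direction == "D->A") "D" else "A"
  recip_g <- if (direction == "D->A") "A" else "D"
  for (s in sp) {
    donor_col <- paste0(s, "_", donor_g)
    recip_col <- paste0(s, "_", recip_g)
    rec <- truth$genomes[[recip_col]][row]
    don <- truth$genomes[[donor_col]][row]
    substr(rec, start + 1L, end) <- substr(don, start + 1L, end)
    truth$genomes[[recip_col]][row] <- rec
  }
  ev <- tibble(
    contig_id = contig_id,
    event_id = sprintf("%s_ev%02d", contig_id, nrow(truth$nrhr[truth$nrhr$contig_id == contig_id, ]) + 1L),
    scope = if (shared) "shared" else species,
    direction = direction,
    start = start, end = end
  )
  truth$nrhr <- bind_rows(truth$nrhr, ev)
  truth
}

# diagnostic truth SNPs: sites unanimous within each genome lineage across
# species and differing between genomes (computed before NRHR is applied)
truth_snps_for_contig <- function(genome_row) {
  a <- rbind(seq_chars(genome_row$A2), seq_chars(genome_row$AD1_A),
             seq_chars(genome_row$AD2_A))
  d <- rbind(seq_chars(genome_row$D5), seq_chars(genome_row$AD1_D),
             seq_chars(genome_row$AD2_D))
  a_ok <- a[1, ] == a[2, ] & a[1, ] == a[3, ]
  d_ok <- d[1, ] == d[2, ] & d[1, ] == d[3, ]
  hit <- which(a_ok & d_ok & a[1, ] != d[1, ])
  tibble(
    contig_id = genome_row$contig_id,
    pos = hit - 1L,
    a_allele = a[1, hit],
    d_allele = d[1, hit]
  )
}

#' Generate a synthetic dataset with full truth records
#'
#' Simulates contig genomes for the six lineages (A2, D5 and the A/D
#' homoeologs of two allotetraploid species) on the study phylogeny (A2
#' sister to the tetraploid A homoeologs, D5 to the D homoeologs, star-like
#' within each genome), plants NRHR tracts, samples reads for both
#' platforms, and returns everything with truth tables.
#'
#' @param config A [sim_config()] object.
#' @return A `cotton_sim` list with elements `config`, `truth` (a
#'   `homeo_truth`: `genomes`, `snps`, `nrhr` tibbles) and `reads` (one
#'   tibble of all reads with species, subgenome of origin, platform,
#'   0-based start, bases and optional quality strings).
#' @export
sim_dataset <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  withr::with_seed(config$seed, {
    truth <- sim_truth_impl(config)
    reads <- bind_rows(
      sample_reads(truth, "long", config),
      sample_reads(truth, "short", config)
    )
    structure(list(config = config, truth = truth, reads = reads),
              class = "cotton_sim")
  })
}

#' Generate truth genomes only (no read sampling)
#'
#' The sequence-level half of [sim_dataset()]: lineage genomes, diagnostic
#' truth SNPs and NRHR tracts, without reads. Useful for molecular-evolution
#' calibration at scales where read sampling would dominate the cost. For a
#' given config the truth tables are identical to `sim_dataset(config)$truth`.
#'
#' @inheritParams sim_dataset
#' @return A `homeo_truth` list (`genomes`, `snps`, `nrhr`).
#' @export
sim_truth <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  withr::with_seed(config$seed, sim_truth_impl(config))
}

sim_truth_impl <- function(cfg) {
  n <- cfg$n_contigs
  lens <- pmax(300, round(rnorm(n, cfg$contig_len_mean, cfg$contig_len_sd)))
  lens <- as.integer(lens - lens %% 3L)
  ids <- sprintf("contig%04d", seq_len(n))

  b <- cfg$branch_ds
  inter_ds <- cfg$target_ds_ad - b[["A2"]] - b[["D5"]]
  dn <- cfg$target_dnds
  if (n == 0L) {
    genomes <- tibble(contig_id = character(), length = integer(),
                      frame = integer(), ancestor = character(),
                      A2 = character(), AD1_A = character(),
                      AD2_A = character(), D5 = character(),
                      AD1_D = character(), AD2_D = character())
    return(structure(list(
      genomes = genomes,
      snps = tibble(contig_id = character(), pos = integer(),
                    a_allele = character(), d_allele = character()),
      nrhr = tibble(contig_id = character(), event_id = character(),
                    scope = character(), direction = character(),
                    start = integer(), end = integer())
    ), class = "homeo_truth"))
  }
  genomes <- map(seq_len(n), function(i) {
    anc_a <- random_coding_seq(lens[i])
    anc_d <- mutate_sequence(anc_a, 0L, inter_ds, dn)
    tibble(
      contig_id = ids[i], length = lens[i], frame = 0L,
      ancestor = anc_a,
      A2 = mutate_sequence(anc_a, 0L, b[["A2"]], dn),
      AD1_A = mutate_sequence(anc_a, 0L, b[["AT"]], dn),
      AD2_A = mutate_sequence(anc_a, 0L, b[["AT"]], dn),
      D5 = mutate_sequence(anc_d, 0L, b[["D5"]], dn),
      AD1_D = mutate_sequence(anc_d, 0L, b[["DT"]], dn),
      AD2_D = mutate_sequence(anc_d, 0L, b[["DT"]], dn)
    )
  }) |> list_rbind()

  truth <- structure(
    list(
      genomes = genomes,
      snps = map(seq_len(n), ~ truth_snps_for_contig(genomes[.x, ])) |> list_rbind(),
      nrhr = tibble(contig_id = character(), event_id = character(),
                    scope = character(), direction = character(),
                    start = integer(), end = integer())
    ),
    class = "homeo_truth"
  )

  n_aff <- round(cfg$nrhr_contig_frac * n)
  if (n_aff > 0) {
    aff <- sample(ids, n_aff)
    w <- cfg$nrhr_species_weights
    for (cid in aff) {
      clen <- lens[match(cid, ids)]
      for (k in seq_len(cfg$nrhr_events_per_contig)) {
        tract_len <- rgeom(1, 1 / cfg$nrhr_tract_len_mean) + 1L
        start <- sample.int(clen, 1L) - 1L
        shared <- runif(1) < cfg$nrhr_shared_frac
        species <- sample(names(w), 1L, prob = w)
        direction <- sample(c("D->A", "A->D"), 1L)
        truth <- apply_nrhr(truth, cid, species, direction,
                            start, start + tract_len, shared = shared)
      }
    }
  }

  truth
}

empty_reads <- function() {
  tibble(read_id = character(), contig_id = character(), species = character(),
         subgenome = character(), platform = character(), start = integer(),
         bases = character(), quals = character())
}

lineage_species <- function(lineage) sub("_.*$", "", lineage)
lineage_subgenome <- function(lineage) {
  ifelse(grepl("_", lineage), sub("^.*_", "", lineage),
         ifelse(lineage == "A2", "A", "D"))
}

#' Sample reads from the truth genomes for one platform
#'
#' Read starts are drawn uniformly over the extended window
#' `[-(len-1), L-1]` and clipped to the contig, so expected depth is uniform
#' (within 10% of nominal) across every position including contig ends.
#' Substitution errors are independent per base at the configured rate.
#' Short reads carry constant phred qualities reflecting the error rate.
#' Uses the current RNG stream ([sim_dataset()] seeds it from the config).
#'
#' @param truth A `homeo_truth`.
#' @param platform `"long"` or `"short"`.
#' @param config A [sim_config()].
#' @return Tibble of reads (`read_id`, `contig_id`, `species`, `subgenome`,
#'   `platform`, `start`, `bases`, `quals`).
#' @export
sample_reads <- function(truth, platform = c("long", "short"), config) {
  platform <- match.arg(platform)
  cov <- if (platform == "long") config$long_cov else config$short_cov
  err <- if (platform == "long") config$long_err else config$short_err
  if (cov <= 0) abort("coverage must be > 0")
  mean_rl <- if (platform == "long") mean(config$long_read_range) else config$short_read_len
  g <- truth$genomes
  if (!nrow(g)) return(empty_reads())
  out <- vector("list", nrow(g) * length(LINEAGES))
  k <- 0L
  for (i in seq_len(nrow(g))) {
    clen <- g$length[i]
    n_reads <- max(1L, as.integer(round(cov * (clen + mean_rl - 1) / mean_rl)))
    for (lin in LINEAGES) {
      k <- k + 1L
      rl <- if (platform == "long") {
        sample(seq(config$long_read_range[1], config$long_read_range[2]),
               n_reads, replace = TRUE)
      } else {
        rep(config$short_read_len, n_reads)
      }
      s_raw <- floor(runif(n_reads, -(rl - 1L), clen))
      s0 <- pmax(0, s_raw)
      e0 <- pmin(clen, s_raw + rl)
      keep <- e0 > s0
      s0 <- as.integer(s0[keep]); e0 <- as.integer(e0[keep])
      seqs <- substring(g[[lin]][i], s0 + 1L, e0)
      out[[k]] <- tibble(
        read_id = sprintf("%s|%s|%s|%04d", g$contig_id[i], lin, platform,
                          seq_along(s0)),
        contig_id = g$contig_id[i],
        species = lineage_species(lin),
        subgenome = lineage_subgenome(lin),
        platform = platform,
        start = s0,
        bases = seqs
      )
    }
  }
  reads <- list_rbind(out)
  reads$bases <- inject_errors(reads$bases, err)
  reads$quals <- if (platform == "short") {
    q <- if (err > 0) min(40L, as.integer(round(-10 * log10(err)))) else 40L
    strrep(rawToChar(as.raw(q + 33L)), nchar(reads$bases))
  } else {
    NA_character_
  }
  reads
}

# independent per-base substitution errors over a character vector of reads
inject_errors <- function(bases, err) {
  if (err <= 0 || !length(bases)) return(bases)
  lens <- nchar(bases)
  big <- paste(bases, collapse = "")
  chars <- seq_chars(big)
  hit <- which(runif(length(chars)) < err)
  if (length(hit)) {
    chars[hit] <- BASES[(match(chars[hit], BASES) - 1L +
                           sample.int(3L, length(hit), replace = TRUE)) %% 4L + 1L]
    big <- paste(chars, collapse = "")
  }
  ends <- cumsum(lens)
  substring(big, ends - lens + 1L, ends)
}
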