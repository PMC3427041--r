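# Nonreciprocal homoeologous recombination (NRHR) detection.
#
# Allotetraploid reads carrying both A- and D-diagnostic alleles evidence a
# homoeologous exchange. Reads are binned into unique events by transitive
# closure of the share-or-extend relation (overlap at >= 1 diagnostic site
# and agreement at every shared site); events are then matched across the
# two allotetraploid species to separate lineage-specific exchanges from
# those inherited from the common allotetraploid ancestor.

#' Find chimeric allotetraploid reads
#'
#' Extracts, per tetraploid read, the ordered vector of diagnostic-site
#' states (A or D); bases matching neither parental allele, and states whose
#' base quality is below `min_phred` (when qualities are present), yield no
#' state. Only reads with at least `min_sites` informative sites and both an
#' A and a D state are returned: a single-site read cannot evidence
#' chimerism.
#'
#' @param aln A `contig_alignment`.
#' @param snps Diagnostic SNP tibble (`contig_id`, `pos`, `a_allele`,
#'   `d_allele`), sorted by position within contig.
#' @param tetraploids Tetraploid species labels.
#' @param min_phred Quality floor for a base to contribute a state.
#' @param min_sites Minimum informative sites per read (default 2).
#' @return Tibble `read_id`, `species`, `contig_id`, `n_sites`, and `states`
#'   (list column of tibbles with `snp_idx`, `pos`, `state`); `snp_idx`
#'   indexes the contig's diagnostic sites in position order.
#' @export
find_chimeric_reads <- function(aln, snps, tetraploids = c("AD1", "AD2"),
                                min_phred = 20L, min_sites = 2L) {
  stopifnot(inherits(aln, "contig_alignment"))
  snps <- snps |> arrange(.data$contig_id, .data$pos) |>
    group_by(.data$contig_id) |> mutate(snp_idx = row_number()) |> ungroup()
  tet <- aln$reads[aln$reads$species %in% tetraploids, ]
  obs <- read_site_observations(tet, snps |> select(-"snp_idx"))
  if (!nrow(obs)) return(empty_chimeric())
  obs <- obs |>
    left_join(snps |> select("contig_id", "pos", "snp_idx"),
              by = c("contig_id", "pos")) |>
    filter(!is.na(.data$state),
           is.na(.data$phred) | .data$phred >= min_phred)
  # cheap pre-screen before building per-read state tables: only reads with
  # both states and enough sites can be chimeric
  cand_ids <- obs |>
    group_by(.data$read_id) |>
    summarise(n = n(), both = any(.data$state == "A") && any(.data$state == "D"),
              .groups = "drop") |>
    filter(.data$n >= min_sites, .data$both) |>
    pull("read_id")
  obs <- obs[obs$read_id %in% cand_ids, ]
  if (!nrow(obs)) return(empty_chimeric())
  chim <- obs |>
    group_by(.data$read_id, .data$species, .data$contig_id) |>
    summarise(
      states = {
        o <- order(snp_idx)
        list(clean_read_states(
          tibble(snp_idx = snp_idx[o], pos = pos[o], state = state[o])))
      },
      .groups = "drop") |>
    mutate(n_sites = map_int(.data$states, nrow),
           has_both = map_lgl(.data$states,
                              ~ length(unique(.x$state)) == 2L)) |>
    filter(.data$n_sites >= min_sites, .data$has_both) |>
    select("read_id", "species", "contig_id", "n_sites", "states")
  if (!nrow(chim)) return(empty_chimeric())
  chim
}

# Drop interior isolated single-site states: one opposite-genome site flanked
# within the same read by the other state on both sides cannot come from an
# exchange tract covering two or more diagnostic sites (it is the signature
# of a parallel substitution or a sequencing error), whereas a single
# opposite site at the read's end may simply be where the read enters a
# tract.
clean_read_states <- function(st) {
  repeat {
    if (nrow(st) < 3L) return(st)
    r <- rle(st$state)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    drop_run <- which(r$lengths == 1L & starts > 1L & ends < nrow(st))
    if (!length(drop_run)) return(st)
    st <- st[-starts[drop_run], ]
  }
}

empty_chimeric <- function() {
  tibble(read_id = character(), species = character(), contig_id = character(),
         n_sites = integer(), states = list())
}

# union-find
uf_find <- function(parent, i) {
  while (parent[i] != i) i <- parent[i]
  i
}

#' Bin chimeric reads into unique NRHR events
#'
#' Reads from one contig and one species merge into an event when they
#' overlap at one or more diagnostic sites and agree at every shared site
#' ("share or extend"); merging is closed transitively. An event's haplotype
#' is the per-site consensus of its reads (majority vote; conflicting tied
#' sites, which can arise only through sequencing error, are dropped).
#' Closure classes whose haplotype retains both states and at least one
#' state switch are events; additionally every switch must be witnessed by
#' at least `min_switch_support` reads covering both flanking sites, a guard
#' against isolated sequencing errors.
#'
#' Donor-direction inference and homoplasy screening are applied afterwards
#' by [validate_events()]; events leave this step with `direction = NA`.
#'
#' @param chim Chimeric-read tibble from [find_chimeric_reads()], one
#'   species.
#' @param min_switch_support Reads required to witness each switch.
#' @return Event tibble: `contig_id`, `species`, `event_id`, `n_sites`,
#'   `n_switches`, `n_reads`, `direction` (`"D->A"`, `"A->D"` or `NA` when
#'   the donor state is ambiguous), `snp_idx_start`, `snp_idx_end`,
#'   `pos_start`, `pos_end` (bp extent of the haplotype, 0-based half-open),
#'   `haplotype` (list column of `snp_idx`, `pos`, `state`), and
#'   `read_ids` (list column).
#' @export
bin_events <- function(chim, min_switch_support = 2L) {
  if (!nrow(chim)) return(empty_events())
  stopifnot(length(unique(chim$species)) <= 1L)
  map(split(seq_len(nrow(chim)), chim$contig_id), function(rows) {
    bin_events_contig(chim[rows, ], min_switch_support)
  }) |> list_rbind()
}

bin_events_contig <- function(chim, min_switch_support) {
  n <- nrow(chim)
  vecs <- map(chim$states, ~ setNames(.x$state, .x$snp_idx))
  parent <- seq_len(n)
  if (n > 1) {
    for (i in 1:(n - 1)) {
      for (j in (i + 1):n) {
        shared <- intersect(names(vecs[[i]]), names(vecs[[j]]))
        if (length(shared) && all(vecs[[i]][shared] == vecs[[j]][shared])) {
          ri <- uf_find(parent, i)
          rj <- uf_find(parent, j)
          if (ri != rj) parent[rj] <- ri
        }
      }
    }
  }
  roots <- vapply(seq_len(n), function(i) uf_find(parent, i), integer(1))
  evs <- map(split(seq_len(n), roots), function(members) {
    st <- bind_rows(chim$states[members])
    hap <- st |>
      count(.data$snp_idx, .data$pos, .data$state) |>
      group_by(.data$snp_idx, .data$pos) |>
      filter(.data$n == max(.data$n)) |>
      filter(n() == 1L) |>   # tied (conflicting) sites are dropped
      ungroup() |>
      arrange(.data$snp_idx) |>
      select("snp_idx", "pos", "state")
    if (nrow(hap) < 2L || length(unique(hap$state)) < 2L) return(NULL)
    sw <- which(hap$state[-1] != hap$state[-nrow(hap)])
    if (!length(sw)) return(NULL)
    # every switch must be witnessed by >= min_switch_support reads
    support_ok <- all(vapply(sw, function(k) {
      i1 <- hap$snp_idx[k]; s1 <- hap$state[k]
      i2 <- hap$snp_idx[k + 1]; s2 <- hap$state[k + 1]
      wit <- sum(vapply(chim$states[members], function(v) {
        a <- v$state[v$snp_idx == i1]
        b <- v$state[v$snp_idx == i2]
        length(a) == 1L && length(b) == 1L && a == s1 && b == s2
      }, logical(1)))
      wit >= min_switch_support
    }, logical(1)))
    if (!support_ok) return(NULL)
    tibble(
      contig_id = chim$contig_id[1],
      species = chim$species[1],
      n_sites = nrow(hap),
      n_switches = length(sw),
      n_reads = length(members),
      direction = NA_character_,
      snp_idx_start = min(hap$snp_idx), snp_idx_end = max(hap$snp_idx),
      pos_start = min(hap$pos), pos_end = max(hap$pos) + 1L,
      haplotype = list(hap),
      read_ids = list(chim$read_id[members])
    )
  }) |> list_rbind()
  if (is.null(evs) || !nrow(evs)) return(empty_events())
  evs |>
    arrange(.data$snp_idx_start) |>
    mutate(event_id = sprintf("%s:%s:ev%02d", .data$contig_id, .data$species,
                              row_number()), .after = "species")
}



empty_events <- function() {
  tibble(contig_id = character(), species = character(), event_id = character(),
         n_sites = integer(), n_switches = integer(), n_reads = integer(),
         direction = character(), snp_idx_start = integer(),
         snp_idx_end = integer(), pos_start = integer(), pos_end = integer(),
         haplotype = list(), read_ids = list())
}

events_compatible <- function(h1, h2, d1, d2) {
  if (!is.na(d1) && !is.na(d2) && d1 != d2) return(FALSE)
  shared <- inner_join(h1, h2, by = "snp_idx", suffix = c("_1", "_2"))
  nrow(shared) >= 1L && all(shared$state_1 == shared$state_2)
}

#' Place events on the two-species phylogeny
#'
#' Events called independently in the two allotetraploid species are matched
#' as shared (ancestral) when they lie on the same contig, have the same
#' donor direction, and carry identical states at every diagnostic site
#' present in both haplotypes (at least one site must be shared); matching
#' is greedy one-to-one. Unmatched events are species-specific. Shared
#' events collapse to a single row.
#'
#' @param events Event tibble from [bin_events()] covering both species (or
#'   a list of two per-species tibbles).
#' @return Event tibble with a `placement` column (species label or
#'   `"shared"`) and per-species read support `n_reads_1`/`n_reads_2`
#'   following the species sort order.
#' @export
place_events <- function(events) {
  if (is.list(events) && !is.data.frame(events)) events <- bind_rows(events)
  if (!nrow(events)) {
    return(events |> mutate(placement = character(0),
                            n_reads_1 = integer(0), n_reads_2 = integer(0)))
  }
  sp <- sort(unique(events$species))
  if (length(sp) == 1L) {
    return(events |> mutate(placement = .data$species,
                            n_reads_1 = .data$n_reads, n_reads_2 = 0L))
  }
  e1 <- events[events$species == sp[1], ]
  e2 <- events[events$species == sp[2], ]
  used2 <- rep(FALSE, nrow(e2))
  match2 <- rep(NA_integer_, nrow(e1))
  for (i in seq_len(nrow(e1))) {
    cand <- which(!used2 & e2$contig_id == e1$contig_id[i])
    for (j in cand) {
      if (events_compatible(e1$haplotype[[i]], e2$haplotype[[j]],
                            e1$direction[i], e2$direction[j])) {
        match2[i] <- j
        used2[j] <- TRUE
        break
      }
    }
  }
  shared_rows <- which(!is.na(match2))
  out <- list()
  if (length(shared_rows)) {
    sh <- e1[shared_rows, ]
    sh$placement <- "shared"
    sh$n_reads_1 <- sh$n_reads
    sh$n_reads_2 <- e2$n_reads[match2[shared_rows]]
    sh$n_reads <- sh$n_reads_1 + sh$n_reads_2
    out <- c(out, list(sh))
  }
  only1 <- e1[is.na(match2), ]
  if (nrow(only1)) {
    only1$placement <- sp[1]
    only1$n_reads_1 <- only1$n_reads
    only1$n_reads_2 <- 0L
    out <- c(out, list(only1))
  }
  only2 <- e2[!used2, ]
  if (nrow(only2)) {
    only2$placement <- sp[2]
    only2$n_reads_1 <- 0L
    only2$n_reads_2 <- only2$n_reads
    out <- c(out, list(only2))
  }
  bind_rows(out) |> arrange(.data$contig_id, .data$snp_idx_start)
}

#' Detect and place NRHR events
#'
#' Convenience wrapper: find chimeric reads, bin them into events per
#' species, and place the events on the two-species phylogeny. When `snps`
#' is omitted the diagnostic set is computed with [nrhr_diagnostics()],
#' which keeps exchange-tract interiors diagnostic.
#'
#' @inheritParams find_chimeric_reads
#' @inheritParams bin_events
#' @return Placed event tibble (see [place_events()]).
#' @export
detect_nrhr <- function(aln, snps = NULL, tetraploids = c("AD1", "AD2"),
                        min_phred = 20L, min_sites = 2L,
                        min_switch_support = 2L, min_donor_run = 2L,
                        max_recipient_frac = 0.35) {
  if (is.null(snps)) snps <- nrhr_diagnostics(aln, tetraploids = tetraploids)
  chim <- find_chimeric_reads(aln, snps, tetraploids, min_phred, min_sites)
  per_sp <- map(split(chim, chim$species),
                bin_events, min_switch_support = min_switch_support)
  ev <- bind_rows(per_sp)
  ev <- validate_events(ev, aln, snps, tetraploids,
                        min_donor_run = min_donor_run,
                        max_recipient_frac = max_recipient_frac)
  place_events(ev)
}

#' Validate candidate events and infer donor direction
#'
#' A binned haplotype is accepted as an exchange event only under a donor
#' orientation that satisfies two conditions. Geometry: the donor (intruding)
#' state must form at least one run of `min_donor_run` consecutive
#' diagnostic sites -- a single opposite site is indistinguishable from a
#' parallel point mutation -- or a single donor site at the haplotype's edge
#' whose immediately following diagnostic site (beyond the read coverage)
#' also shows donor-allele dominance, i.e. the tract demonstrably continues.
#' Depletion: a genuine nonreciprocal exchange overwrites the recipient
#' homoeolog, so at donor-state sites the recipient's parental allele is
#' depleted among tetraploid reads (about one transcript class in four for a
#' single-species event, versus an even split at an ordinary diagnostic
#' site). The recipient-allele fraction is measured among the event's own
#' species' reads -- within the affected species the recipient allele drops
#' to about zero inside a tract, while an ordinary diagnostic site stays
#' near one half (and a tract in the other species leaves it untouched) --
#' and must not exceed `max_recipient_frac` pooled over donor sites. When
#' exactly one orientation passes it fixes the direction; when both pass
#' the direction is reported `NA`.
#'
#' @param events Event tibble from [bin_events()] (either species).
#' @param aln The `contig_alignment` the events came from.
#' @param snps The diagnostic set used.
#' @param tetraploids Tetraploid species labels.
#' @param min_donor_run Minimum consecutive donor-state sites.
#' @param max_recipient_frac Maximum tolerated recipient-allele fraction at
#'   donor sites (default 0.35, midway between the exchange expectation of
#'   0.25 and the no-exchange expectation of 0.5).
#' @return The validated event tibble with directions resolved.
#' @export
validate_events <- function(events, aln, snps,
                            tetraploids = c("AD1", "AD2"),
                            min_donor_run = 2L,
                            max_recipient_frac = 0.35) {
  if (!nrow(events)) return(events)
  snps <- snps |> arrange(.data$contig_id, .data$pos) |>
    group_by(.data$contig_id) |> mutate(snp_idx = row_number()) |> ungroup()
  tet <- aln$reads[aln$reads$species %in% tetraploids &
                     aln$reads$platform == "long", ]
  obs <- read_site_observations(tet, snps |> select(-"snp_idx"))
  support <- obs |>
    filter(!is.na(.data$state)) |>
    count(.data$species, .data$contig_id, .data$pos, .data$state) |>
    pivot_wider(names_from = "state", values_from = "n", values_fill = 0L)
  if (!"A" %in% names(support)) support$A <- 0L
  if (!"D" %in% names(support)) support$D <- 0L
  site_frac <- function(sp, contig, pos_set, recip_state) {
    sup <- support[support$species == sp & support$contig_id == contig &
                     support$pos %in% pos_set, ]
    tot <- sum(sup$A) + sum(sup$D)
    if (tot == 0) return(NA_real_)
    (if (recip_state == "A") sum(sup$A) else sum(sup$D)) / tot
  }
  check_orientation <- function(sp, contig, hap, donor) {
    recip <- setdiff(c("A", "D"), donor)
    r <- rle(hap$state)
    donor_runs <- r$lengths[r$values == donor]
    geom <- any(donor_runs >= min_donor_run)
    if (!geom && length(donor_runs)) {
      # single edge donor site: consult the next diagnostic site beyond the
      # haplotype for continued donor dominance
      ends <- cumsum(r$lengths)
      starts <- ends - r$lengths + 1L
      for (k in which(r$values == donor & r$lengths == 1L)) {
        csnp <- snps[snps$contig_id == contig, ]
        if (starts[k] == 1L) {
          beyond <- csnp$pos[csnp$snp_idx == hap$snp_idx[1] - 1L]
        } else if (ends[k] == nrow(hap)) {
          beyond <- csnp$pos[csnp$snp_idx == hap$snp_idx[nrow(hap)] + 1L]
        } else next
        if (length(beyond)) {
          f <- site_frac(sp, contig, beyond, recip)
          if (!is.na(f) && f <= max_recipient_frac) geom <- TRUE
        }
      }
    }
    if (!geom) return(FALSE)
    f <- site_frac(sp, contig, hap$pos[hap$state == donor], recip)
    !is.na(f) && f <= max_recipient_frac
  }
  keep <- logical(nrow(events))
  for (i in seq_len(nrow(events))) {
    hap <- events$haplotype[[i]]
    ok_a <- check_orientation(events$species[i], events$contig_id[i], hap, "A")
    ok_d <- check_orientation(events$species[i], events$contig_id[i], hap, "D")
    keep[i] <- ok_a || ok_d
    events$direction[i] <- if (ok_a && ok_d) NA_character_
    else if (ok_a) "A->D" else if (ok_d) "D->A" else NA_character_
  }
  events[keep, ]
}

#' Summarise NRHR events over contigs
#'
#' @param events Placed event tibble.
#' @return List with `n_events`, `n_contigs_with_events`, and `placements`
#'   (a tibble of per-placement event counts).
#' @export
summarize_contigs <- function(events) {
  list(
    n_events = nrow(events),
    n_contigs_with_events = length(unique(events$contig_id)),
    placements = if (nrow(events)) count(events, .data$placement)
    else tibble(placement = character(), n = integer())
  )
}

#' Validation-corrected genome-wide NRHR rate
#'
#' Scales the observed fraction of contigs bearing at least one event by an
#' independent laboratory validation rate, giving an estimate of the true
#' fraction of contigs affected by NRHR.
#'
#' @param n_contigs_with_events Contigs with >= 1 detected event.
#' @param n_total_contigs Total contigs in the assembly (> 0).
#' @param validation_rate Fraction of bioinformatic events expected to be
#'   real (default 0.70).
#' @return The corrected fraction (not a percentage).
#' @export
estimate_true_rate <- function(n_contigs_with_events, n_total_contigs,
                               validation_rate = 0.70) {
  if (n_total_contigs <= 0) abort("n_total_contigs must be > 0")
  if (n_contigs_with_events < 0) abort("counts must be >= 0")
  validation_rate * n_contigs_with_events / n_total_contigs
}

#' Compare detected events with simulation truth
#'
#' A truth event is detectable when its tract covers at least
#' `min_truth_sites` sites of the diagnostic set in use (an exchange tract
#' covering fewer diagnostic sites leaves no haplotype signal, and a tract
#' shared by both species erases the diagnostic status of its own interior
#' sites). A detected event matches a truth event when it lies on the same
#' contig, overlaps the tract in bp, and agrees in direction (ambiguous
#' directions match anything). Placement accuracy is the fraction of
#' matched events whose phylogenetic placement equals the truth scope.
#'
#' @param events Placed event tibble from [detect_nrhr()].
#' @param truth_nrhr Truth tract table (`contig_id`, `scope`, `direction`,
#'   `start`, `end`).
#' @param snps Diagnostic SNP set used for detection.
#' @param min_truth_sites Diagnostic sites a tract must cover to count as
#'   detectable.
#' @return One-row tibble: `n_truth`, `n_detectable`, `n_detected`,
#'   `recall`, `precision`, `placement_accuracy`.
#' @export
nrhr_performance <- function(events, truth_nrhr, snps, min_truth_sites = 2L) {
  n_sites <- map_int(seq_len(nrow(truth_nrhr)), function(i) {
    sum(snps$contig_id == truth_nrhr$contig_id[i] &
          snps$pos >= truth_nrhr$start[i] & snps$pos < truth_nrhr$end[i])
  })
  detectable <- truth_nrhr[n_sites >= min_truth_sites, ]
  match_one <- function(tr_row, ev) {
    hit <- ev$contig_id == tr_row$contig_id &
      ev$pos_start < tr_row$end & ev$pos_end > tr_row$start &
      (is.na(ev$direction) | ev$direction == tr_row$direction)
    which(hit)
  }
  matched_truth <- logical(nrow(detectable))
  placement_ok <- logical(0)
  for (i in seq_len(nrow(detectable))) {
    hit <- match_one(detectable[i, ], events)
    matched_truth[i] <- length(hit) > 0
    if (length(hit)) {
      placement_ok <- c(placement_ok,
                        any(events$placement[hit] == detectable$scope[i]))
    }
  }
  matched_det <- map_lgl(seq_len(nrow(events)), function(j) {
    any(truth_nrhr$contig_id == events$contig_id[j] &
          truth_nrhr$start < events$pos_end[j] &
          truth_nrhr$end > events$pos_start[j] &
          (is.na(events$direction[j]) |
             truth_nrhr$direction == events$direction[j]))
  })
  tibble(
    n_truth = nrow(truth_nrhr),
    n_detectable = nrow(detectable),
    n_detected = nrow(events),
    recall = if (nrow(detectable)) mean(matched_truth) else NA_real_,
    precision = if (nrow(events)) mean(matched_det) else NA_real_,
    placement_accuracy = if (length(placement_ok)) mean(placement_ok) else NA_real_
  )
}

#' Write placed events as TSV
#'
#' Flattens the list columns: the haplotype becomes `snp_idx:state` pairs
#' joined by commas, supporting reads a comma-joined id list.
#'
#' @param events Placed event tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_events_tsv <- function(events, path) {
  flat <- events |>
    mutate(
      haplotype = map_chr(.data$haplotype, function(h) {
        paste(sprintf("%d:%s", h$snp_idx, h$state), collapse = ",")
      }),
      read_ids = map_chr(.data$read_ids, paste, collapse = ",")
    )
  readr::write_tsv(flat, path)
  invisible(path)
}
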