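test_that("majority-rule consensus masks ties, low depth and weak majorities", {
  # all reads identical: consensus equals the read, nothing masked
  m <- pileup_counts(rep("ACGT", 4), rep(0L, 4), 4L)
  cons <- consensus_from_counts(m)
  expect_equal(paste(cons$bases, collapse = ""), "ACGT")

  # 5A/5C tie -> masked
  m2 <- pileup_counts(c(rep("A", 5), rep("C", 5)), rep(0L, 10), 1L)
  expect_equal(consensus_from_counts(m2)$bases, "N")

  # 10A/1C: frequency 10/11 = 0.909 strictly exceeds 0.90 -> 'A'
  m3 <- pileup_counts(c(rep("A", 10), "C"), rep(0L, 11), 1L)
  c3 <- consensus_from_counts(m3, min_major_freq = 0.90)
  expect_equal(c3$bases, "A")
  expect_equal(c3$major_freq, 10 / 11)

  # 9A/1C: frequency 0.9 is not strictly greater -> masked
  m4 <- pileup_counts(c(rep("A", 9), "C"), rep(0L, 10), 1L)
  expect_equal(consensus_from_counts(m4, min_major_freq = 0.90)$bases, "N")

  # single read is below the default depth floor
  m5 <- pileup_counts("G", 0L, 1L)
  expect_equal(consensus_from_counts(m5, min_depth = 2L)$bases, "N")
  expect_equal(consensus_from_counts(m5, min_depth = 1L)$bases, "G")
})

test_that("read assignment tallies diagnostic votes as specified", {
  snps <- tibble::tibble(contig_id = "c1", pos = c(2L, 5L, 8L),
                         a_allele = c("A", "C", "G"), d_allele = c("T", "G", "C"))
  reads <- make_reads("c1", "AD1", c(0, 0, 0, 12),
                      c("NNANNCNNG",   # A,A,A -> A
                        "NNTNNGNNC",   # D,D,D -> D
                        "NNANNCNNC",   # A,A,D -> chimeric (2,1)
                        "GGG"))        # covers no site -> unassigned
  asg <- assign_reads(reads, snps)
  asg <- asg[order(asg$read_id), ]
  expect_equal(asg$genome_call, c("A", "D", "chimeric", "unassigned"))
  expect_equal(asg$votes_A, c(3L, 0L, 2L, 0L))
  expect_equal(asg$votes_D, c(0L, 3L, 1L, 0L))
  # a base matching neither allele is ignored for voting
  r2 <- make_reads("c1", "AD2", 0, "NNGNNCNNN")
  a2 <- assign_reads(r2, snps)
  expect_equal(a2$genome_call, "A")
  expect_equal(a2$sites_seen, 3L)
  expect_equal(a2$votes_A, 1L)
})

test_that("assembly SNP calling recovers the truth on clean simulated data", {
  sim <- sim_dataset(sim_config(n_contigs = 6, long_err = 0, short_err = 0,
                                nrhr_contig_frac = 0, seed = 5))
  aln <- sim_alignment(sim)
  snps <- call_assembly_snps(aln, quiet = TRUE)
  expect_setequal(snp_key(snps), snp_key(sim$truth$snps))
  # alleles equal the diploid consensus bases by construction
  m <- match(snp_key(snps), snp_key(sim$truth$snps))
  expect_identical(snps$a_allele, sim$truth$snps$a_allele[m])
  expect_identical(snps$d_allele, sim$truth$snps$d_allele[m])
})

test_that("identical diploid consensuses yield no SNPs and skips are logged", {
  reads <- dplyr::bind_rows(
    make_reads("c1", "A2", c(0, 0), c("ACGTACGT", "ACGTACGT")),
    make_reads("c1", "D5", c(0, 0), c("ACGTACGT", "ACGTACGT")) |>
      dplyr::mutate(read_id = paste0(read_id, "d")),
    make_reads("c1", "AD1", c(0, 0), c("ACGTACGT", "ACGTACGT")) |>
      dplyr::mutate(read_id = paste0(read_id, "t"))
  )
  aln <- contig_alignment(reads)
  expect_equal(nrow(call_assembly_snps(aln, quiet = TRUE)), 0)

  # contig lacking a diploid genome: skipped with a message, empty result
  reads2 <- make_reads("c2", "A2", c(0, 0), c("AAAA", "AAAA"))
  aln2 <- contig_alignment(reads2)
  expect_message(res <- call_assembly_snps(aln2), "skipped")
  expect_equal(nrow(res), 0)
})

test_that("masked diploid columns never become SNPs", {
  # D5 has depth 1 at the differing column -> masked -> no call
  reads <- dplyr::bind_rows(
    make_reads("c1", "A2", c(0, 0, 0), rep("AAAA", 3)),
    make_reads("c1", "D5", 0, "AACA") |> dplyr::mutate(read_id = "d1"),
    make_reads("c1", "D5", c(0, 0), c("AA", "AA")) |>
      dplyr::mutate(read_id = c("d2", "d3")),
    make_reads("c1", "AD1", c(0, 0), c("AAAA", "AACA")) |>
      dplyr::mutate(read_id = c("t1", "t2"))
  )
  aln <- contig_alignment(reads, tibble::tibble(contig_id = "c1", length = 4L))
  expect_equal(nrow(call_assembly_snps(aln, quiet = TRUE)), 0)
})

test_that("raising the majority threshold never adds SNPs", {
  sim <- sim_dataset(sim_config(n_contigs = 6, long_err = 0.01, seed = 23))
  aln <- sim_alignment(sim)
  loose <- call_assembly_snps(aln, min_major_freq = 0.90, quiet = TRUE)
  strict <- call_assembly_snps(aln, min_major_freq = 0.97, quiet = TRUE)
  expect_true(all(snp_key(strict) %in% snp_key(loose)))
})

test_that("pileup SNP quality follows the binomial error model", {
  # 30xA vs 30xG: overwhelming evidence, qual capped high
  reads <- dplyr::bind_rows(
    make_reads("c1", "A2", rep(0, 30), rep("A", 30), platform = "short", quals = "I"),
    make_reads("c1", "D5", rep(0, 30), rep("G", 30), platform = "short", quals = "I") |>
      dplyr::mutate(read_id = paste0(read_id, "d"))
  )
  aln <- contig_alignment(reads, tibble::tibble(contig_id = "c1", length = 1L))
  out <- call_pileup_snps(aln)
  expect_equal(nrow(out), 1)
  expect_gte(out$qual, 20)
  expect_equal(out$a_allele, "A")

  # 2xA vs 2xG: two clean reads cannot exclude a 50:50 homoeolog mixture,
  # so each group quality sits far below 20 -> no call. Independent oracle:
  # posterior over 4 pure-base and 6 equal-mixture hypotheses at e = 0.01.
  e <- 0.01
  pure <- c((1 - e)^2, rep((e / 3)^2, 3))              # A clean twice
  mixes <- apply(combn(c("A", "C", "G", "T"), 2), 2, function(p) {
    per_read <- if ("A" %in% p) ((1 - e) + e / 3) / 2 else e / 3
    per_read^2
  })
  qual_expected <- -10 * log10(1 - pure[1] / (sum(pure) + sum(mixes)))
  expect_lt(qual_expected, 20)
  reads2 <- dplyr::bind_rows(
    make_reads("c2", "A2", rep(0, 2), rep("A", 2), platform = "short", quals = "I"),
    make_reads("c2", "D5", rep(0, 2), rep("G", 2), platform = "short", quals = "I") |>
      dplyr::mutate(read_id = paste0(read_id, "d"))
  )
  aln2 <- contig_alignment(reads2, tibble::tibble(contig_id = "c2", length = 1L))
  expect_equal(nrow(call_pileup_snps(aln2)), 0)

  # evenly mixed column -> group consensus ambiguous -> no call
  reads3 <- dplyr::bind_rows(
    make_reads("c3", "A2", rep(0, 20), rep(c("A", "G"), 10), platform = "short", quals = "I"),
    make_reads("c3", "D5", rep(0, 20), rep("G", 20), platform = "short", quals = "I") |>
      dplyr::mutate(read_id = paste0(read_id, "d"))
  )
  aln3 <- contig_alignment(reads3, tibble::tibble(contig_id = "c3", length = 1L))
  expect_equal(nrow(call_pileup_snps(aln3)), 0)
})

test_that("pileup SNP calls recover truth sites on simulated short reads", {
  sim <- sim_dataset(sim_config(n_contigs = 6, long_err = 0, short_err = 0,
                                nrhr_contig_frac = 0, short_cov = 30, seed = 9))
  aln <- sim_alignment(sim)
  out <- call_pileup_snps(aln)
  # all truth sites with adequate coverage are found; extra calls are
  # diploid-private sites, real consensus differences by construction
  expect_gt(mean(snp_key(sim$truth$snps) %in% snp_key(out)), 0.98)
})

test_that("tetraploid confirmation requires both parental alleles", {
  snps <- tibble::tibble(contig_id = "c1", pos = 0L,
                         a_allele = "A", d_allele = "G",
                         platform = "short", qual = 30)
  both <- dplyr::bind_rows(
    make_reads("c1", "AD1", 0, "A", platform = "short", quals = "I"),
    make_reads("c1", "AD2", 0, "G", platform = "short", quals = "I") |>
      dplyr::mutate(read_id = "x2"))
  aln <- contig_alignment(both, tibble::tibble(contig_id = "c1", length = 1L))
  expect_true(confirm_in_tetraploid(snps, aln)$confirmed)

  only_a <- make_reads("c1", "AD1", c(0, 0), c("A", "A"),
                       platform = "short", quals = "I")
  aln2 <- contig_alignment(only_a, tibble::tibble(contig_id = "c1", length = 1L))
  expect_false(confirm_in_tetraploid(snps, aln2)$confirmed)
})

test_that("loss of one homoeolog leaves SNPs unconfirmed", {
  sim <- sim_dataset(sim_config(n_contigs = 2, long_err = 0, short_err = 0,
                                nrhr_contig_frac = 0, seed = 41))
  aln <- sim_alignment(sim)
  snps <- call_assembly_snps(aln, quiet = TRUE)
  cid <- snps$contig_id[1]
  # simulate tetraploid loss of the D copy: drop all tetraploid D reads
  keep <- !(sim$reads$contig_id == cid & sim$reads$species %in% c("AD1", "AD2") &
              sim$reads$subgenome == "D")
  aln_loss <- contig_alignment(sim$reads[keep, ],
                               sim$truth$genomes[, c("contig_id", "length")])
  conf <- confirm_in_tetraploid(snps[snps$contig_id == cid, ], aln_loss)
  expect_false(any(conf$confirmed))
  conf_full <- confirm_in_tetraploid(snps[snps$contig_id == cid, ], aln)
  expect_true(all(conf_full$confirmed))
})

test_that("platform reconciliation accounting is exact", {
  # disjoint sets
  a <- tibble::tibble(contig_id = "c1", pos = 1:3,
                      a_allele = "A", d_allele = "G")
  b <- tibble::tibble(contig_id = "c1", pos = 4:5,
                      a_allele = "A", d_allele = "G")
  rec <- reconcile_platforms(a, b)
  expect_equal(rec$n_common, 0)
  expect_equal(rec$n_union, 5)

  # overlap with one orientation disagreement
  b2 <- tibble::tibble(contig_id = "c1", pos = c(2L, 3L, 9L),
                       a_allele = c("A", "G", "A"), d_allele = c("G", "A", "G"))
  rec2 <- reconcile_platforms(a, b2)
  expect_equal(rec2$n_common, 2)
  expect_equal(rec2$n_agree, 1)
  expect_equal(rec2$n_disagree, 1)
  expect_equal(rec2$n_agree + rec2$n_disagree, rec2$n_common)
  expect_equal(rec2$n_union, 3 + 3 - 2)
  expect_equal(sort(unique(tidy(rec2)$agreement)),
               c("agree", "disagree", "long-only", "short-only"))

  dup <- a[c(1, 1, 2), ]
  expect_error(reconcile_platforms(dup, b), "duplicate")
})
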