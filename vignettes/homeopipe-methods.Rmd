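---
title: "Homoeolog-diagnostic SNPs, nonreciprocal homoeologous recombination, and molecular evolution in allopolyploid transcriptomes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{homeopipe methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem

An allotetraploid such as cultivated cotton carries two diverged parental
genomes — the A- and D-subgenomes — in one nucleus. When expressed-sequence
reads from the two model diploid progenitors (A2, D5) and from two
allotetraploid species (AD1, AD2) are assembled jointly, each contig stacks
reads from up to six genome lineages: the two diploids and the A- and
D-homoeologs of each allotetraploid. Three questions follow, and this
package implements the computational chain that answers them:
genome-diagnostic SNP discovery, detection and phylogenetic placement of
nonreciprocal homoeologous recombination (NRHR), and pairwise and
lineage-polarized molecular-evolution statistics.

Everything is driven by tidy tables: reads, SNPs, events and per-contig
estimates are tibbles, and fitted-result objects carry `tidy()`, `glance()`
and `autoplot()` methods.

# Consensus calling and the diagnostic SNP model

A *genome-diagnostic SNP* is a column at which the A- and D-genomes carry
different fixed bases. The assembly route works per contig:

1. Majority-rule consensuses for the A2 and D5 diploid read stacks. A
   column is masked when depth < `min_depth` (default 2, the minimal
   evidence for a consensus) or when the major allele frequency does not
   strictly exceed `min_major_freq` (default 0.90); ties always mask.
2. Unmasked columns where the two diploid consensuses differ are candidate
   diagnostics.
3. Every allotetraploid read is compared to the candidates and categorised
   as A- or D-genome by the *majority* of its diagnostic-allele votes
   (ties drop the read from consensus building). Majority rather than
   unanimous voting matters: candidate columns unavoidably include
   diploid-private (autapomorphic) substitutions, at which *every*
   tetraploid read carries the opposite diploid's allele. Under a
   unanimity rule a contig containing both an A2-private and a D5-private
   column loses essentially all of its tetraploid reads to the "chimeric"
   class; under majority voting such columns instead produce a tetraploid
   consensus that contradicts the diploid allele and are filtered out,
   which is the desired outcome.
4. Pooled tetraploid A- and D-consensuses are rebuilt from the categorised
   reads, and a SNP is emitted only where they differ *and* each matches
   its diploid allele. The vote set is initialised with
   tetraploid-confirmed candidates (both parental alleles observed among
   tetraploid reads) and the categorise–rebuild cycle is iterated to a
   fixed point (at most four rounds); in practice the second round is
   already stable.

On error-free simulated data at ≥ 10× per genome this caller attains
recall and precision of 1.0 against the generator's truth table, and its
call set shrinks monotonically as `min_major_freq` rises.

The short-read route scores each genome's pileup column with a phred-style
quality, `-10 log10 P(consensus wrong)`. The binomial error model compares
the four pure-base hypotheses against the six equal (50:50) two-base
mixtures under independent per-base errors (`err`, default 0.01) and a
uniform prior. The mixture hypotheses represent the failure mode that
matters in this setting — an unseparated homoeolog column or residual
polymorphism — and give the model its depth dependence: a clean column
needs about nine concordant reads to exclude a mixture at the default
threshold `min_qual = 20`, so two reads of each allele never call a SNP no
matter how concordant. Sites where the two genome consensuses differ with
both qualities ≥ 20 are emitted, and both call sets are reconciled by
(contig, position): shared keys split into agreeing and disagreeing
orientation classes, and the union count follows inclusion–exclusion.
Disagreeing sites are retained and flagged rather than dropped.
Confirmation in the allotetraploids — at least one tetraploid read carrying
each parental allele — guards against diploid lineage-specific mutation and
tetraploid gene loss masquerading as diagnostics.

# NRHR detection

A nonreciprocal homoeologous exchange overwrites a tract of one homoeolog
with the other's sequence. Its read-level signature is chimerism: an
allotetraploid read carrying both A- and D-diagnostic alleles.

**Diagnostic set.** Detection uses the tetraploid-confirmed candidate set
(`nrhr_diagnostics()`), not the final SNP calls: inside an exchange tract
the recipient subgenome's reads all carry the donor allele, so the strict
caller necessarily drops those columns, which would blind the detector to
the very tracts it is looking for. Confirmation (≥ 2 reads per allele)
still removes diploid-private columns, which are monomorphic among
tetraploid reads.

**Read cleaning.** Within one read's ordered state vector, a single
opposite-genome site flanked on both sides by the other state cannot come
from a tract covering two or more diagnostic sites; it is the signature of
a parallel point substitution or a sequencing error and is dropped. A
single opposite site at the read's end is kept — it may be where the read
enters a tract. Reads must retain at least two informative sites and both
states (`min_sites = 2`): a one-site read cannot evidence chimerism. When
base qualities are present, states below phred 20 are discarded.

**Binning.** Chimeric reads from one contig and species merge when they
overlap at ≥ 1 diagnostic site and agree at every shared site
("share or extend"), closed transitively; the event haplotype is the
per-site majority over members (conflicts can arise only through
sequencing error; ties drop the site). Every switch in the haplotype must
be witnessed by ≥ `min_switch_support` reads (default 2) covering both
flanking sites — the guard against isolated errors. Binning is invariant
to read input order, and closure classes are reported as single events
even when internally complex; whether a multi-switch class is one complex
exchange or several unbridgeable ones is left to the user, as the data
cannot resolve it.

**Validation and direction.** A candidate event is accepted only under a
donor orientation passing two conditions. *Geometry*: the donor (intruding)
state forms a run of ≥ `min_donor_run` (default 2) consecutive diagnostic
sites — a single opposite site is observationally identical to a parallel
point mutation — or a single donor site at the haplotype edge whose next
diagnostic site beyond the read coverage also shows donor dominance (the
tract demonstrably continues). *Depletion*: within the event's own species,
conversion removes the recipient's parental allele, so the recipient-allele
fraction among that species' reads, pooled over donor sites, must not
exceed `max_recipient_frac` (default 0.35, midway between the exchange
expectation of ~0 and the no-exchange expectation of 0.5). Evaluating both
orientations fixes the direction, or reports `NA` when both pass.

**Placement.** Events called independently in the two species match as
shared (ancestral) when they lie on the same contig with the same donor
direction and identical states at every site present in both haplotypes
(at least one shared site required; sites covered in only one species are
ignored because read sampling differs). Matching is greedy one-to-one;
unmatched events are species-specific. The genome-wide rate multiplies the
affected-contig fraction by an independent laboratory validation rate
(default 0.70).

## Identifiability limits

Two limits are intrinsic, not implementation artifacts, and shape both the
filters above and what passing tests demonstrate:

* A column inside a tract converted in *both* species is observationally
  identical to a diploid-private substitution — either way the tetraploid
  reads are monomorphic for one diploid's allele. No honestly filtered
  diagnostic set can keep such columns, so a fully shared conversion erases
  the interior of its own detection signal; shared events are recoverable
  only in degenerate configurations. Event recovery is therefore assessed
  over truth tracts covering ≥ 2 sites of the diagnostic set actually in
  use, and the validation-rate correction absorbs what the detector cannot
  see, exactly as the corrected genome-wide rate is meant to.
* Two adjacent diagnostic columns carrying parallel substitutions to the
  opposite allele in the same tetraploid lineage are identical to a
  two-site conversion tract in every observable respect. Under the default
  branch lengths this is expected roughly once per 2,000 contigs; it is
  the residual false-positive class the parallel-mutation caveat refers
  to, and no filter here attempts to remove it.

# Molecular evolution

Pairwise coding alignments take the in-frame overlap of two consensus
sequences on shared contig coordinates, drop any codon containing a masked
or ambiguous base, and reject alignments retaining fewer than 198 bp
(the minimum is applied after ambiguous-codon removal — the stricter
ordering). The reading frame is supplied per contig, with a longest-ORF
fallback (`longest_orf_frame()`) when absent. Contigs with a detected NRHR
event are excluded upstream, since exchange homogenises the very
divergence being measured.

Counting is Nei–Gojobori (1986): per-codon synonymous site fractions over
single-base changes averaged across the two sequences; observed
differences in multi-difference codons averaged over all orderings of
single-step pathways with equal weights (pathways passing through stop
codons are included, and changes to stops count as nonsynonymous).
Distances use Jukes–Cantor, `d = -(3/4) ln(1 - (4/3) p)`, undefined at
p ≥ 3/4 and reported as `NA` there. Per-contig dN/dS is defined only when
dS > 0; survey means are unweighted over contigs (each contig counts once
regardless of length — a length-weighted pooled estimate can be formed from
the per-contig `Sd`/`S` columns of `tidy()`), and ratio means exclude
undefined ratios. The implementation is checked against an independent
brute-force pathway-enumeration oracle on a thousand random codon pairs.

Lineage polarization takes quartet columns (A2, A-homoeolog, D5,
D-homoeolog of one species) where all four bases are unambiguous, and
increments a lineage exactly when its base differs from the other three
*and* those three are unanimous; columns with two or more derived states
are discarded (the conservative reading of "compared to the remaining
lineages"). The tetraploid-vs-diploid count comparison uses a two-sided
exact binomial test at null proportion one half, doubling the smaller tail
capped at 1 (two-sided chosen as the conservative option). Ratio
distributions are compared by Wilcoxon signed-rank on per-contig pairs
matched by contig id: zero differences dropped, ties mid-ranked, exact
null up to 25 non-zero pairs and a continuity-corrected normal
approximation beyond, with ≥ 6 non-zero differences required (an all-zero
comparison returns p = 1).

# The synthetic-data generator

`sim_config()`/`sim_dataset()` emulate the study conditions end to end; the
defaults *are* those conditions and are not tuning knobs.

* **Phylogeny and rates.** An A-genome ancestor spawns a D-genome ancestor
  at divergence `target_ds_ad - branch_ds[A2] - branch_ds[D5]`, so the
  realized A2-vs-D5 synonymous distance has expectation `target_ds_ad`
  (default 0.036). Terminal branches are star-like within each genome with
  per-branch lengths `branch_ds = c(A2 = 0.002, AT = 0.0035, D5 = 0.0035,
  DT = 0.006)`, derived jointly from the published pairwise
  diploid–tetraploid distances (sums: 0.0055 and 0.0095) and the observed
  tetraploid excess of polarized lineage-specific substitutions (ratios
  near 1.7). These choices also place the tetraploid A-vs-D contrast near
  0.0395, matching the published 0.039–0.040.
* **Mutation model.** Substitutions are proposed uniformly over sites with
  equal base exchange at the per-site probability whose Jukes–Cantor
  correction equals the branch length; proposals are accepted with
  probability 1 when synonymous and `target_dnds` (default 0.3) when
  nonsynonymous, and stop-creating changes are rejected. Because every
  synonymous proposal is accepted, the expected realized pS equals the
  proposal rate and the NG86 estimate recovers the target (the pooled
  estimate sits within a few percent at 500 contigs). Indels are not
  simulated; the downstream analyses are substitution-based.
* **Truth SNPs** are columns where the three A-lineage sequences are
  unanimous, the three D-lineage sequences are unanimous, and the two
  genomes differ — i.e. the sites a perfect caller should report —
  computed before any exchange is applied.
* **NRHR tracts** are planted on `nrhr_contig_frac` (default 0.07) of
  contigs, one per affected contig by default; 23% of events are ancestral
  (applied to both species at identical coordinates) and the rest split
  46:31 between the two species, mirroring the published placement
  proportions. Tract lengths are geometric with mean
  `nrhr_tract_len_mean` (default 300 bp) — the source material gives no
  tract-length distribution, so this is an explicit modeling choice —
  with uniform start positions clipped to the contig.
* **Reads.** Long reads are uniform 250–450 bp without stored qualities
  (the archival platform range); short reads are 82 bp with constant
  phred qualities reflecting the configured error rate. Starts are drawn
  over the extended window `[-(len-1), L-1]` and clipped, making expected
  depth uniform across every position including contig ends; nominal
  coverage defaults to 20× per genome lineage and platform. Errors are
  independent per-base substitutions (defaults: 0.001 long — trimmed
  capillary/pyrosequencing quality — and 0.005 short). Identical
  configurations yield byte-identical datasets.

What the generator does **not** emulate: platform-specific error structure
(homopolymer indels, quality ramps), expression-level variation in
coverage, alternative splicing, allelic polymorphism within lineages, and
assembly artifacts (reads are placed at their true positions, so there is
no misassembly). Consequently, passing tests demonstrate the pipeline's
correctness given a sound alignment, not robustness to assembly error —
on real data the validation-rate correction carries that burden.

# Numerical and scale choices

Coordinates are 0-based half-open internally; only the VCF export is
1-based. Pileups are tabulation-based (no per-column loops); NG86 pathway
enumeration uses precomputed permutations (k ≤ 3). The test suite runs the
simulation-based checks at deliberately moderate scales — 200 contigs for
event recovery, 500 contigs for divergence calibration, and a
sequence-only quartet of 3,200 contigs (≈ 3.2 Mb) for the polarization
direction test, which skips read sampling entirely via `sim_truth()` —
sizes at which the measured quantities are statistically stable while the
whole suite stays fast. Fixed seeds make every simulated check
reproducible.

# Known limitations

* Shared (ancestral) exchanges are largely invisible for the structural
  reason above; the package reports what is detectable and corrects the
  rate, it does not conjure the missing signal.
* Direction inference can be ambiguous (`NA`) for boundary-only
  haplotypes where both orientations show depletion.
* The double-parallel false-positive class is irreducible and enters at
  the expected homoplasy rate.
* dN/dS ratios on short, weakly diverged alignments are noisy; the survey
  deliberately reports per-contig values so users can filter by `n_sites`
  before testing.
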