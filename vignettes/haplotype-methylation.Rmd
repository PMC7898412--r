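---
title: "Haplotype-resolved methylation from nanopore reads: models and design"
author: "haploMeth"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Haplotype-resolved methylation from nanopore reads: models and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of the science it implements: the
models, the parameters that matter, what the synthetic data generator does and
does not emulate, and the numerical and design choices made where the design
was genuinely open. It states no empirical result that the test suite or
`scripts/acceptance.R` does not itself compute.

# The workflow in one picture

A single nanopore library of a diploid sample yields (i) aligned long reads,
(ii) per-read CpG methylation calls, and (iii) candidate SNVs from a
single-sample caller. haploMeth turns these into per-haplotype methylation:

```
candidate SNVs --> [snv refinement] --> filtered het SNVs --> (external phaser)
                                                            |
aligned reads + phased het SNVs --> [haplotagging] --> HP1 / HP2 read sets
                                                            |
per-read CpG calls  ------------------------------> per-haplotype calls
     --> per-CpG frequencies --> [differential methylation] --> DMRs
     --> [mock bisulfite conversion] --> browser-ready BAM pair
```

SNV phasing itself (read-backed phasing of the refined SNVs) is deliberately
out of scope — it is a solved problem with dedicated tools — as are base
calling, the upstream variant caller, and signal-level methylation calling.
The package consumes their outputs in their standard formats.

# Coordinates and containers

All internal coordinates are 0-based, half-open, matching the methylation
call dialect; VCF positions are converted on read and write, and the 1-based
`GRanges`/SAM views are produced only at the boundary
(`dmrsAsGRanges()`, `writeSam()`). The central containers are S4 classes with
validity checks (`MethylCallSet`, `CpGCallSet`, `PhasedVariantSet`,
`ReadSet`, `SnvClassifier`); accessor functions (`methCalls()`,
`cpgCalls()`, `variants()`, `reads()`, ...) are the supported surface.

# Grouped methylation calls and the call threshold

HMM-based CpG callers score CpGs closer than 11 bp as one group: a single
log-likelihood ratio (LLR, log P(methylated) − log P(unmethylated)) is
assigned to every CpG of the group. `splitGroupedCalls()` only *expands*
groups — one call per `CG` in the record's sequence context, every call
carrying the group LLR — and never re-scores or re-splits them; the grouping
is upstream behaviour and re-deriving per-CpG evidence from it is impossible.

Calls are classified by a symmetric threshold on the LLR: methylated at
`LLR >= t`, unmethylated at `LLR <= -t`, uncalled otherwise, with `t = 2.0`
by default (the community default for this caller family; the boundary is
*inclusive*, a convention this package fixes explicitly since upstream
documentation does not). Reverse-strand records are normalized to the
forward-strand C (position − 1) so the palindromic CpG merges across strands.

A subtle consequence of grouped scoring, visible in the test suite: at an
intermediate methylation level *p*, a group of *k* CpGs with mixed true
states averages to an LLR near zero and is dropped as uncalled at `t = 2`.
Conditioning on "called" therefore biases per-site frequencies away from
intermediate values (toward `p^k / (p^k + (1-p)^k)` for unanimous groups). A
permissive threshold (e.g. `t = 0.5`) restores unbiasedness — mixed groups
then split their calls symmetrically — at the cost of noisier singleton
calls. The default stays at 2.0 for comparability; analyses of intermediate
methylation levels should be aware of the trade-off.

# The SNV refinement classifier

**Model.** If a candidate SNV is a false call, the base caller must have
mis-translated the 5-mers containing it, so the neighbourhood should show
excess mismatches/indels and depressed base qualities. Each base sits in five
5-mers, so each site yields five windows `[site−4, site] ... [site, site+4]`.
Per window position, four pileup statistics are computed: mean base quality of
aligned bases, and mismatch, deletion and insertion frequency, each as events
over spanning coverage (aligned bases plus deletions — a read deleted at a
position still spans it). That gives 20 features per window. Coverage itself
is only the denominator, not a feature: the classifier should transfer across
depths.

The network has four hidden ReLU layers; the first is six times the input
width and each later layer halves by integer division — `20 → 120 → 60 → 30 →
15 → 1` — with a sigmoid output. The site weight is the arithmetic mean of
the (up to five) window probabilities; sites within 4 bp of a contig edge
average over the realizable windows only, preserving the averaging contract.
The caller quality is multiplied by the weight (`normalizeQuality()`), so the
refined quality can only shrink, and the ordering of sites by weight is
independent of the raw quality scale.

**Training choices** (the upstream description fixes the architecture but not
the optimizer): binary cross-entropy, mini-batch Adam (rate 1e-3, batch 128,
30 epochs by default), He-scaled normal initialization, feature
standardization stored in the model, majority-class down-sampling for
balance, and a held-out fifth for validation loss and AUC. Everything is
driven by the model seed: one seed, one model, bit for bit. The model
serializes to a single JSON file carrying spec, seed, standardization and
weights.

**Threshold suggestion.** After re-weighting, false calls pile up near zero
quality and the distribution turns bimodal; `suggestThreshold()` fits a
kernel density (normal reference bandwidth) and returns the first local
minimum after the first local maximum. If the density has no such valley the
fallback is 17% of the observed range above the minimum — the regime in which
re-weighted nanopore call-quality cutoffs typically land — with a warning,
since a unimodal distribution means the suggestion machinery has nothing to
find. At least 1000 values are required; below that the valley location is
too unstable to automate and the error says to set a threshold manually.

# Haplotagging

A read is scored at each phased het SNV it covers, through its CIGAR: bases
aligned at the SNV position support the haplotype whose allele they match;
deletions and third alleles support neither; observations below the minimum
base quality are recorded but not counted. The assignment rule, with counts
`c1`, `c2` of counted supports:

* winner `W = argmax(c1, c2)`; ties are unassigned (conservative — the
  upstream description is silent on ties);
* assign iff `c1 + c2 >= min_snvs` **and** `c_W >= min_snvs` **and**
  `c_W / (c1 + c2) >= haplotype_ratio`.

Defaults: minimum base quality 7, haplotype ratio 0.75 (inclusive), minimum
SNVs 2, minimum MAPQ 20. The ratio is defined as the winner's *fraction* of
counted supports: a max/min odds ratio cannot have a 0.75 cutoff, so the
fraction reading is the only self-consistent one. Whether the minimum-SNV
rule binds the winner count or the total is ambiguous upstream; both are
enforced here (the stricter reading — for `min_snvs = 2` they differ only for
2:1 ties, which the ratio rule rejects anyway). The MAPQ cutoff is this
package's own addition: flag filters alone keep low-confidence primary
alignments that add noise at SNV positions. Duplicated, QC-failed, unmapped
and secondary reads are always ignored; supplementary alignments are ignored
unless requested.

Every read lands in exactly one of five bins — HP1, HP2,
unassigned-with-SNV, no-SNV, flag-filtered — and the bins must sum to the
input read count; this partition is asserted at run time, not just in tests.

**Trio mock phasing** operates on genotypes only: a child allele is paternal
iff the father carries it and the mother does not (and symmetrically);
both-informative sites must agree; sites where a child allele occurs in
neither parent are Mendelian violations, counted and left unphased. No
read-backed trio phasing is attempted.

**Regional concordance** between two phasings bins reads (10 kb by default),
keeps bins with at least three commonly phased reads, finds each bin's
majority mapping of one phasing's labels onto the other's, and counts reads
contradicting it. Haplotype labels from single-sample phasing are arbitrary
per phase block, so the mapping must be local; a global label swap scores
zero discordance by construction.

# Differential methylation

**Site statistic.** The upstream workflow delegates its test to an external
shrinkage-based package with default parameters; re-implementing that
package's empirical-Bayes dispersion machinery is explicitly out of scope.
Instead the per-site test is fully specified: a pooled two-proportion z on
the per-haplotype methylated counts, two-sided normal p-value, with
degenerate pools (pooled proportion 0 or 1) scored as no evidence (statistic
0, p 1). Sites must be covered on both haplotypes; zero-coverage sites are
the caller's to drop. Exact enumeration over the binomial outcome space puts
the rejection rate at nominal 0.05 between 0.046 and 0.055 for the coverages
this package targets (≥ 5 calls per haplotype), i.e. the statistic is
honestly calibrated at the site level — which the test suite verifies on 50k
null sites.

**Smoothing.** `smoothCounts()` provides a coverage-weighted moving average
of proportions over ±span/2 (500 bp window by default). It is *off* by
default in `siteStatistics()`/`diffMethylation()`: averaging proportions over
~20 neighbouring sites shrinks the null variance of the numerator by an
order of magnitude while the denominator still uses per-site counts, so
smoothed z-scores are wildly conservative at the site level and would
destroy the calibration above. It remains available (`smooth = TRUE`) for
exploratory use where regional trend matters more than per-site error.

**Region grammar.** Candidate DMRs are maximal runs of significant
(`p < 1e-3`) same-sign sites with inter-site gaps ≤ 100 bp. Two refinements
follow, both this package's design:

1. *Edge extension*: each candidate edge absorbs adjacent sites whose raw
   difference keeps the region's sign and at least half the region's mean
   |difference| (gap rule still applying). Rationale: at 15× coverage a true
   boundary site clears `p < 1e-3` only ~75% of the time, so pure
   significance runs clip an edge site at a ~25% rate per edge; the raw
   difference at a true member is far more reliable than its p-value, and
   delta-based trimming of region edges is standard practice in DMR callers.
2. *Merge repair*: same-sign regions closer than the merge distance are
   merged — which also heals candidates split by a short run of
   non-significant sites inside a true region.

Kept regions must span ≥ 50 bp, contain ≥ 3 CpGs, and have ≥ 50% of member
sites significant. The **area statistic** is the sum of member-site z values;
`filterDmrsByArea()` applies the `|areaStat| ≥ 100` confidence cutoff, kept
as a separate operation so the unfiltered region list remains inspectable.
Site-level p-values are deliberately not multiplicity-adjusted: region-level
filtering (percent-significant plus area statistic) is the control, matching
the delegated package's design. Antisymmetry under haplotype swap — sign
flips, magnitudes preserved — holds exactly at both site and region level.

**Annotation mapping** is a half-open interval intersection against intervals
expanded by a strand-aware flank, with a TSS-anchored mode for promoter
windows (e.g. 1 kb upstream, 200 bp downstream of the TSS).

# Mock bisulfite conversion

Bisulfite semantics require that a *methylated* C survive conversion —
that is what makes methylation visible in a browser's bisulfite mode — so the
mapping is: unmethylated → T at the CpG C of forward-strand reads (A at the
G for reverse-strand reads, whose sequenced strand carries the complementary
C), uncalled → N, methylated unchanged. A literal reading of the upstream
tool's one-line description lists the letters in a different order
("converted to a T, A, or N depending on the CpG being called as methylated,
unmethylated, or uncalled"), which contradicts bisulfite chemistry; this
package follows the chemistry, and flags the discrepancy here deliberately.
Only bases participating in a CpG are ever rewritten, base qualities are left
untouched (no upstream guidance; preserving them keeps browsers' quality
shading meaningful), CIGARs and coordinates never change, and conversion is
idempotent. Calls whose target base is deleted in the read are skipped and
counted.

# The synthetic data generator

The generator is first-class, tested code, and the defaults *are* the study
conditions used throughout the tests and the acceptance script:

| parameter | default | why |
|---|---|---|
| genome length | 1 Mb | large enough for ~1000 het SNVs and ~2000 reads |
| GC fraction | 0.42 | human-like; yields ~4% CpG density |
| het SNV rate | 1e-3 /bp | benchmark het density for phasing recovery |
| coverage | 20× | single-flow-cell regime the workflow targets |
| read length | log-normal, mean 10 kb, sd 5 kb | nanopore library scale |
| error rates | 6% mismatch, 2% ins, 2% del | ~10% total, nanopore-era profile |
| hotspot rate / multiplier / width | 2e-5 /bp, 6×, 10 bp | clustered-error loci that spawn false SNV candidates |
| ASM regions | three 1-kb regions, p = 0.85/0.15 | Δ = 0.7 imprinted-like contrast |
| background methylation | 0.75 | genome-wide CpG methylation level |
| LLR scale / noise | 6 / 2 | confident caller: ~2% uncalled at t = 2 |

Reads alternate between haplotypes, start uniformly, and are emitted
*pre-aligned*: the CIGAR is constructed from the injected edits, so truth
(haplotype of origin, error positions) is exact and no external aligner is
involved — the package tests phasing and feature logic, not alignment.
Error bases get low qualities (Phred ~10) and correct bases high (~30),
mirroring the quality signal the refinement stage exploits. Methylation
calls follow the upstream grouping rule: CpGs < 11 bp apart on one read are
emitted as one record whose LLR is the group mean; contexts are cut from the
reference so the motif-count invariant holds by construction. Candidate SNVs
are all truth SNVs (quality ~N(650, 120), clipped to [1, 999]) plus false
candidates inside hotspot windows (~N(480, 120)) — overlapping by design, so
raw quality is an imperfect discriminator with a closed-form AUC of
Φ(170/(120√2)) ≈ 0.84 that the refinement stage must beat.

The site-level generator `simulateHaplotypeCounts()` feeds the differential
stage directly: per-CpG Poisson coverage (floor 5 per haplotype — sites
below that would fail a coverage filter in practice), shared per-site null
proportions drawn from U(0.25, 0.75), and planted DMRs at CpG-island
spacing (mean 12 bp vs 25 bp background). The island spacing is a realism
decision, not a tuning knob: imprinting control regions *are* CpG islands,
and the detectable ones sit at 4–8% CpG density; at background spacing a
planted "ICR" would contain >100 bp CpG gaps that no 100-bp merge grammar
should be expected to bridge.

**What the generator does not emulate** — and therefore what passing tests do
not show about real data: alignment artefacts (reads are placed at their true
positions), reference bias, non-uniform coverage and mappability, the
caller's true LLR error structure (noise is Gaussian), non-CpG methylation,
structural variation, somatic mosaicism, and the biological clustering of
het SNVs. Results on real data depend on the upstream caller, aligner and
phaser in ways no simulation of this kind can certify.

# Problem sizes and determinism

The test suite and acceptance script run simulations at 15 kb–1 Mb and 1–20×
coverage — sizes chosen so the full suite completes in about two minutes
while keeping ≥ ~2000 reads or ≥ 50k sites behind every stochastic assertion.
Every random stage derives a child seed from the user seed and a stream label
(kept below 2³¹), so identical commands and seeds give identical text outputs
byte for byte; alignment outputs are identical up to their BAM container.

# Known limitations

* The classifier is trained per dataset (or loaded from a file); no
  pre-trained, coverage-stratified model bank ships with the package.
* The two-proportion z treats calls as independent Bernoulli draws; per-read
  correlation between neighbouring CpGs on the same molecule is ignored at
  the site level (region-level filters absorb some of it).
* Grouped-call expansion inherits the upstream caller's 11-bp grouping; ASM
  confined to a single CpG inside a dense group is invisible by
  construction.
* Trio phasing uses genotypes only; double-heterozygous trios stay
  uninformative even where read-backed phasing could resolve them.
* The frequency tables merge strands at the forward C; strand-specific
  (hemimethylation) analyses are out of scope.
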