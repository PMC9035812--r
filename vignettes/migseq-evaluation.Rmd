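---
title: "Evaluating MIG-seq genotyping: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Evaluating MIG-seq genotyping: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(migseqr)
```

## The problem

MIG-seq (multiplexed inter-simple-sequence-repeat genotyping by sequencing)
is a reduced-representation library method: a single multiplexed primer set
anneals to microsatellites (SSRs) of a few motif classes — here ACT, TTG,
GTG and GT — and amplifies the regions between neighbouring SSRs, which are
then sequenced and genotyped. Because no restriction digest or DNA
normalisation is needed, the method is attractive for large plant panels and
mapping populations, but its usefulness hinges on quantitative questions this
package makes computable:

* How many targeted SSRs does a genome offer, and how does the stably
  sequenced fraction of the genome (the *mapped base count*) scale with
  genome size?
* After depth masking and missingness filters, how many markers survive for
  linkage mapping, and what map do they produce?
* How reliable are *heterozygous* calls at a given read amount and
  minimum-depth threshold, given that a heterozygote whose reads all happen to
  come from one allele is miscalled homozygous?
* Given the nucleotide diversity between two candidate parents, how many
  polymorphic markers should a cross yield?

No sequencing data ships with this package. Every analysis is exercised on a
synthetic world with known truth tables, so each statistic can be validated
against either a closed form or an independent brute-force oracle.

## The synthetic world

`simulate_genome()` draws i.i.d. uniform A/C/G/T background and places perfect
SSR repeats of the four targeted families uniformly without overlap
(`ssr_density` per Mb, Poisson counts). Flanking bases are chosen so a placed
repeat cannot extend, which makes the truth table exact for a maximal-run
scanner. `simulate_panel()` uses an infinite-sites model: each inbred
accession independently accumulates `Poisson(pi/2 * L)` homozygous
substitutions at uniform positions, so the expected pairwise difference
density between any two accessions equals `pi`. `simulate_cross()` performs
interference-free meiosis (Poisson crossover counts on the cM scale, genetic
position = physical position × `cM_per_Mb`); F2 progeny are two F1 gametes,
RILs are selfed by single-seed descent so residual heterozygosity is
`0.5^(g-1)`. `simulate_migseq_depths()` anchors one amplicon downstream of
each SSR (insert length uniform on `insert_range`, default 350–800 bp — an
assumption, as only bead-cleanup ratios are conventionally reported, and
configurable), gives each locus a lognormal amplification weight
(`overdispersion` = log-scale SD) shared across samples, and draws per-sample
Poisson depths around `n_read_pairs × weight`. The marginal per-locus depth is
therefore negative-binomial-like and reproduces the heavy-tailed violin-shaped
DP distributions seen in real MIG-seq libraries; `overdispersion = 0` recovers
pure Poisson coverage. Heterozygous sites split reads `Binomial(DP, 1/2)`.

What the generator deliberately does **not** emulate: read-level artefacts
(PCR chimeras, index hopping), alignment error, linkage disequilibrium or
population structure beyond pairwise diversity, indels (off by default,
matching the SNP-based diversity definition), and a realistic genotype
caller — the emitted genotype matrix carries truth genotypes masked only where
depth is zero. A green test therefore establishes that the *statistics* are
computed correctly under the stated model, not that any wet-lab protocol will
achieve them.

## Statistics and their conventions

**SSR scanning.** `scan_ssrs()` reports maximal perfect runs of 2-bp motifs
(≥ 7 repeats) and 3-bp motifs (≥ 5 repeats) — common search defaults, both
configurable since the original tool's settings are not part of the package's
contract. Motif classes collapse rotations and reverse complements (a primer
anneals to either strand); `strand_collapse = FALSE` is available because
either counting convention is defensible. Overlaps are resolved greedily
left-to-right; a run partially overlapped by an already-reported locus is
trimmed to the first free position and kept if enough full copies remain. The
whole scanner is fuzz-tested for exact locus-set equality against an
independent lookahead-regex oracle.

**Mapped base count.** "Bases above DP 10" is read as `depth >= 10`
(`strict = TRUE` gives `>`), and the per-0.5-Gb normalisation is
`count / raw_read_gb * 0.5`, applied to summary counts (applying it per
position is algebraically identical for counts and is not separately exposed).

**Genotype QC.** The three population presets in `run_qc()` mirror the
conventional stacks: panel (mask `DP < 5`, keep fully genotyped biallelic
sites with quality ≥ 30 and zero heterozygous calls), F2 (mask `DP < 10`,
drop individuals missing > 5 %, keep sites genotyped in **more than** 97 % of
individuals — strict `>`), RIL (mask `DP <= 5`, drop individuals missing
> 10 %, convert residual heterozygotes to missing, rate > 95 %). The
"DP of 10 / DP of 5 or less" masking pair is interpreted as `<` vs `<=`; both
comparators are explicit arguments. Individual filtering removes samples whose
missingness *exceeds* the bound, the only direction consistent with removing
one bad individual per population.

**Pairwise diversity.** For each of the `C(n,2)` pairs,
`pi = snp_count / common_bases` with the denominator counting positions at
`DP >= 5` in *both* samples (position-wise intersection of the two depth
masks, the literal reading) and the numerator counting depth-passing
homozygous disagreements; heterozygous calls are excluded by default
(inbred-line semantics) with an optional half-difference mode. A pair with no
jointly covered bases is flagged rather than reported as zero. The linear
extrapolation `predict_min_diversity(target, ref_markers, ref_pi)` and its
inverse assume proportionality between polymorphism count and diversity,
which the acceptance suite verifies on simulated panels (regression
R² > 0.98 across a six-point diversity grid).

**Virtual F1.** Merging read data subsampled from two homozygous parents
yields an artificial F1 that is truth-heterozygous at every
parental-difference marker. Subsampling acts on marker-level depth counts by
joint multivariate-hypergeometric thinning (statistically equivalent to
subsampling reads without replacement, at desk scale). The minimal caller —
missing below `min_dp`, heterozygous iff both alleles seen, else homozygous —
replaces the production caller, which is why published error percentages are
targets of qualitative shape here, not exact reproduction. Under a 1:1 allele
split the closed form is `P(hom call | depth d) = 2^(1-d)`, so
`analytic_het_error()` gives exact expected error and missing rates for any
depth distribution; the Monte-Carlo curves agree within 3 MC σ when each
replicate is an independent library draw. (Thinning a single fixed library
for all replicates leaves a small systematic excess — asymmetric realized
parental depths at a marker persist across replicates — which is why the
package models replicates as independent preps, as replicate libraries are.)

**Linkage and QTL.** Two-point recombination fractions use an EM fit of the
3×3 F2 table (the double heterozygote contributes 0 or 2 recombinant gametes)
and the selfing-RIL correction `r = R / (2 - 2R)`. Distances use Kosambi's
function `d = 25 ln((1+2r)/(1-2r))`; average map spacing is
`length / markers`, the convention under which published totals and spacings
are mutually consistent. Marker grouping and ordering heuristics are out of
scope — maps are summarised over the physical order. The QTL scan is a
single-marker regression (additive coding +1/0/−1 with +1 for the first
parent's homozygote, so a positive effect means that parent's allele raises
the phenotype), `LOD = (n/2) log10(RSS0/RSS1)`, with a genome-wide threshold
from the empirical `(1-alpha)` quantile of max-LOD over label permutations.
Permutations draw from the *sorted* phenotype multiset, making the threshold
exactly invariant to phenotype relabeling without changing its distribution.
Composite interval mapping is deliberately replaced by this scan: cofactor
selection is the upstream package's algorithm, while the permutation
machinery — the part under test here — is structurally identical.

## Numerical choices and degenerate inputs

Monomorphic markers yield flagged `NA` recombination fractions and LOD 0;
`r >= 0.5` raises an infinite-distance error, and adjacent-pair estimates in
map building are capped at 0.4999 with a flag. Zero non-missing calls make
error rates and distortion tests `NA`, never silent zeros. Every stochastic
operation takes an explicit seed; per-sample and per-replicate streams derive
deterministically from `(seed, index)`, so enlarging a panel never perturbs
existing accessions, and `run_pipeline()` re-runs byte-identically under a
fixed config (verified by MD5 manifests).

## Limitations

Map totals from two-point estimates inflate when adjacent markers are
effectively unlinked (capped, flagged); diversity estimates are conditioned on
the amplified fraction of the genome and assume mutations are uniform; the
RIL formulas assume complete selfing without seed mixing; and all error-rate
results inherit the minimal caller's simplifications. The acceptance suite
(`tests/testthat/test-acceptance.R`) states precisely which properties are
checked and at what tolerance; no empirical claim is made beyond them.
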