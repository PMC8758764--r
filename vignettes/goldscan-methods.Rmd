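---
title: "Models and methods in goldscan"
author: "goldscan authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods in goldscan}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(goldscan)
```

# Scope

`goldscan` models the analysis chain that links an intronic,
transposon-derived inverted-repeat insertion to a dominant colour
polymorphism: split-read genotyping of the insertion at a known breakpoint,
mixed-model genotype–phenotype association with kinship, haplotype-pair
insertion discovery, inverted-repeat characterization, and
penetrance/phenocopy bookkeeping. Every stage can be exercised on data the
package simulates itself, with known truth. This vignette records the models,
the tunable parameters and their defaults, the numerical choices, and the
limits of what the simulations demonstrate.

# The locus model

`buildLocus()` constructs a reference ("d") haplotype of length `refLength`
and the recipe for an alternate ("G") haplotype that carries, after position
`breakpoint`, an insertion

```
arm + loop + reverse-complement(arm')
```

where `arm'` is the arm with `armEditCount` single-base deletions. The
insertion length is `2*armLength + loopLength - armEditCount`; the default
acceptance geometry (arm 4100 bp, loop 50 bp, 2 edits) gives 8248 bp — an
~8.2 kb element with a ~4.1 kb stem whose two copies differ at two positions
by single-base indels.

Three construction constraints keep the nominal geometry identifiable, i.e.
make "stem length = arm length" true of the generated molecule rather than
only of the recipe:

* **Loop termini cannot base-pair.** If the first loop base could pair with
  the last one, the maximal self-complementary run — the physically
  meaningful stem — would genuinely extend into the loop, and any correct
  detector would (and should) report a longer stem. The generator resamples
  one terminal loop base when needed.
* **Edits keep a 15 bp margin from the arm termini.** An indel at the very
  end of a stem is indistinguishable from a shorter stem plus an unpaired
  flap; placing edits interior keeps "arm length" well defined.
* **Edits are ≥ 16 bp apart.** Adjacent single-base deletions coalesce into
  one multi-base indel, contradicting the two-single-base-indel model.

Edits are implemented as deletions (rather than a random indel direction) so
the insertion length is deterministic given the parameters.

Because the inserted sequence may end with the same base as the reference
base at the breakpoint, the insertion placement can be ambiguous; the
canonical single-coordinate report is the left-most placement.
`leftAlignedBreakpoint()` normalizes a locus model's construction coordinate
to that convention, and `callInsertion()` reports left-aligned breakpoints by
design, so the two are directly comparable.

# The cohort and phenotype model

`simulateCohort()` draws genotypes at the gold locus under Hardy–Weinberg
equilibrium at the configured G-allele frequency. The phenotype follows
Mendelian dominance with incomplete, dosage-dependent penetrance:

* carriers are gold unless still "untransformed" at sampling —
  `pUntransformedHet` (default 0.08) for `Gd`, `pUntransformedHom` (default
  0.01) for `GG`, with `pUntransformedHom <= pUntransformedHet` enforced
  because homozygotes transition earlier in life;
* `dd` fish are gold only as phenocopies (`phenocopyRate`, default 0.01).

The defaults are chosen to reproduce the observed field situation — a few
percent of dark fish being young heterozygous carriers and phenocopies being
rare — not fitted to any dataset. The expected fraction of dark fish that
carry a G allele has the closed form

```
(2g(1-g)·p_het + g²·p_hom) / ((1-g)²(1-phenocopy) + 2g(1-g)·p_het + g²·p_hom)
```

which the test-suite checks by simulation at n = 20,000.

Background markers are independent biallelic variants with MAFs drawn
uniformly from `backgroundMafRange` and i.i.d. missingness; they provide
material for kinship estimation and null-calibration scans. They carry no
linkage structure (see Limitations).

# Simulated reads and the junction geometry

`simulateReads()` samples reads uniformly and independently from each of an
individual's two haplotypes at `coverage/2` each (Poisson counts); alignment
is emulated analytically rather than by running an aligner, so the evidence
is exact. A read from the insertion-bearing haplotype that crosses the left
junction is written as `mM nS` with the clip starting right after the
breakpoint; a read crossing the right junction is written `nS mM` at
position breakpoint+1. Both clip boundaries sit at the same reference
coordinate — exactly what a real aligner produces at a pure insertion. Reads
wholly inside the insertion are flagged unmapped (the transposon-derived
sequence would multi-map). Substitution errors are injected after the
alignment geometry is fixed, so they never move a clip boundary; duplicate
flags are independent.

This geometry fixes the expected composition of classifiable reads at a
heterozygote. With read length L and a minimum overlap of o aligned bases on
each side for reference support, the insertion haplotype offers 2(L−1)
start positions that produce a clip at the breakpoint while the reference
haplotype offers L−2o+1 positions that produce a reference-supporting read,
so the expected split fraction is

```
2(L-1) / (2(L-1) + (L-2o+1))  ≈ 0.685   (L = 100, o = 5)
```

— not 1/2, because an insertion presents two clip-producing junction edges.
The property suite asserts this closed form (pooled over individuals, four
binomial standard deviations) and that every simulated heterozygote falls
inside the het-calling band.

# Split-read genotyping

`classifyReads()` implements breakpoint classification: unmapped and
duplicate reads are excluded; a read is *split* when a soft- or hard-clip
boundary (the reference base immediately left of the clip junction) lies
within `clipWindow` (default ±5 bp, absorbing random matches at the
junction) of the breakpoint; it is *reference* when its aligned span covers
at least `minOverlap` (default 5) bases on each side with no qualifying
clip; anything else is excluded as uninformative. Hard clips are treated
like soft clips: both mark the same breakpoint signal and differ only in
whether the clipped sequence is stored.

`callGenotype()` applies the calling rule: `dd` when the split-read ratio is
below 0.1 *or* at most 2 split reads; `GG` when the ratio is above 0.9 *or*
at most 2 reference (total − split) reads; otherwise `Gd`. Boundary cases
are strict (a ratio of exactly 0.1 or 0.9 is heterozygous). When both
homozygote conditions fire at once — possible only at very low coverage —
or when no classifiable read exists, the result is an explicit no-call: a
pipeline cannot reproduce manual inspection of alignments, so it must
surface the ambiguity instead of guessing.

**Coverage and exactness.** The ≤2-read absolute overrides make *exact*
genotype recovery a tail event in coverage. At 30× total coverage the
expected reference-read count at a heterozygote's junction is ≈ 13.7, and
the probability that its lower Poisson tail (or the 0.9 ratio boundary)
flips a heterozygote is ≈ 6.5 × 10⁻⁴ — negligible for one fish, but an
exactness claim over thousands of simulated heterozygotes fails with high
probability. The per-heterozygote miscall probability under the rule,
computed exactly from the junction geometry, is 6.4 × 10⁻³ at 20×,
6.5 × 10⁻⁴ at 30×, 1.5 × 10⁻⁵ at 50× and 2.3 × 10⁻⁶ at 60×. The exactness
suites therefore simulate 60× breakpoint coverage, where the rule's error
probability is negligible at the tested sample sizes; lower, resequencing-
typical coverages (the pipeline default is 30×) still call correctly in all
but a fraction ~10⁻³ of heterozygotes.

# Mixed-model association

`lmmLRT()` fits, by maximum likelihood,

```
y = W a + x b + u + e,   u ~ N(0, sg² K),   e ~ N(0, se² I)
```

with `K` the centered kinship matrix (`computeKinship()`: per-variant mean
imputation of missing dosages, centering, average of outer products — the
standard centered relatedness matrix). Eigendecomposition `K = U D Uᵀ`
rotates the model to independent observations with variances
`se²(λ d_i + 1)`, `λ = sg²/se²`; for fixed λ the fixed effects and `se²`
profile out in closed form, and λ is maximized over a 21-point log₁₀ grid on
[10⁻⁵, 10⁵] followed by bounded refinement (`optimize`, tolerance 10⁻⁸). The
likelihood-ratio statistic compares against the null model without the
variant, λ re-estimated under each model, with p from χ²(1 df).

Choices worth recording:

* **ML, not REML** — the LRT compares models with different fixed effects,
  which is only valid under ML.
* **Binary phenotypes are analysed as quantitative 0/1**, the standard
  behaviour of mixed-model association tools for case/control traits.
* **Filters**: MAF ≥ 0.05 on non-missing calls and missingness ≤ 20%,
  applied per analysis; deliberately no Hardy–Weinberg filter, which could
  discard a causal variant that is out of equilibrium precisely because it
  is under selection or mis-genotyped in one morph.
* **Degenerate cases**: constant dosages are flagged `untestable` rather
  than tested; p-values below double-precision resolution are reported as
  5 × 10⁻³²⁴ with an `underflow` flag rather than 0 (a perfectly separating
  variant produces this limit).
* With `K = I` the rotated variances are constant and the fit reduces
  exactly to OLS; the test suite verifies agreement with an
  `lm()`-likelihood oracle to 10⁻⁶ on −log₁₀ p, and null calibration
  (empirical type-I error at α = 0.05 over 20 × 1000 null markers,
  n = 300).

# Insertion discovery and inverted-repeat characterization

`callInsertion()` compares two haplotypes via anchors — k-mers (default
k = 21) unique in both sequences — chained colinearly by longest increasing
subsequence. A between-anchor gap larger in the alternate than in the
reference is an insertion; the breakpoint is the reference base immediately
left of the gap (left-aligned automatically, because placement-ambiguous
junction k-mers are non-unique and drop out of the anchor set). Multiple
gaps are all reported and flagged. Unique-anchor chaining is exact for
unique flanks and avoids dynamic programming over megabase haplotypes.

`findInvertedRepeat()` matches k-mer seeds (default 15) between the sequence
and its reverse complement; a seed pair (i, y) means the words at i and y
are reverse complements, and all pairs of one inverted repeat share an
anti-diagonal i + y up to indel shifts. Seeds are clustered on anti-diagonal
within `bandWidth` (default 16, the indel-shift budget), and the widest
cluster defines the arms. Boundaries are then refined by contiguous
base-pair extension anchored on actual seed pairs (so extension starts from
an exactly paired frontier); at a stall, a single-base skip on either arm or
a joint substitution advance is accepted only when 12 subsequent bases pair
contiguously, making chance extension past the true stem a ~4⁻¹² event
while recovering arm differences that lie within one seed length of an arm
end. Finally the first arm is globally aligned against the reverse
complement of the second with unit edit costs (match 0, mismatch −1, gap
−1; N never matches) and the differences enumerated with positions on arm-1
coordinates. The reported stem length is the arm-1 length; the loop is the
separation between arms. `selfDotplot()` reports merged exact word-match
runs in both orientations, with both coordinates as interval starts so runs
come in symmetric pairs.

# Concordance bookkeeping

`concordanceTable()` cross-tabulates called genotype against morph, keeping
no-calls out of the table but counted. `conflictRates()` reports dark
carriers (untransformed candidates) and gold `dd` fish (phenocopies) as
percentages of the morph totals, rounded half-even to one decimal; an empty
morph yields an undefined (NA) percentage, never 0. One worked consistency
check: 8 carrier-dark fish of 185 dark is 4.3%; 1 phenocopy of 88 gold is
1.1% (the computed value is reported even where a source prints a different
number for the same counts). `peakDistance()` turns two `chrom:pos`
coordinates into a signed kb distance at one decimal, the format in which
breakpoint-to-peak offsets are quoted.

# Reproducibility and problem sizes

A single pipeline seed fans out to per-stage child seeds by fixed integer
arithmetic (`seed * 7919 + stage-hash mod 2³¹−1`), so stages can be re-run
in isolation; `runPipeline()` writes a manifest with the configuration,
stage seeds and md5 hashes of every output, and identical configurations
give byte-identical outputs. The shipped test and acceptance workloads use
desk-scale sizes chosen to keep the statistical claims meaningful: cohorts
of 60–300 individuals, 60–1000 background markers, 2 kb loci for read-level
work (read counts scale linearly in locus size and the genotyper only reads
a breakpoint window), the full 10 kb/8.2 kb geometry for structure
recovery, and 20 replicate null scans for calibration.

# Limitations

* Simulated reads are single-end with uniform coverage, no indel errors and
  no quality scores; there is no paired-end/insert-size evidence, so the
  genotyper's behaviour on discordant-pair-only signals is untested.
* Background markers are exchangeable and unlinked: scans demonstrate
  ranking and calibration, not fine-mapping under linkage disequilibrium,
  and the kinship matrix estimated from them reflects panmixia rather than
  the structured populations of real lake cohorts.
* The genotyper requires a known breakpoint; it does not discover
  breakpoints from reads.
* The inverted-repeat finder assumes few, small arm differences (seed
  clustering within a 16-diagonal band); heavily diverged arms would need a
  sensitivity-oriented aligner instead.
* Passing simulations show the machinery is correct under the stated
  models; they do not validate the models against real sequencing data.
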