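---
title: "Kindred-aware variant filtering on the male X chromosome: models and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Kindred-aware variant filtering on the male X chromosome}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(kindredX)
```

## The problem

Rare X-linked recessive disorders such as X-linked intellectual
disability (XLID) affect hemizygous males: one mutant copy of an
X-chromosome gene suffices for disease. Exome sequencing of an affected
male yields on the order of a thousand X-chromosome variant calls, of
which at most one is causal. Most of the rest are common polymorphisms,
and a non-trivial fraction are calling artifacts. kindredX implements a
filtering strategy built for small cohorts (under a hundred samples)
that contain *affected relative pairs* — two affected males from one
family (brothers, maternal half-brothers, maternal cousins, or an
uncle–nephew pair). Two premises drive the design:

1. A causal mutation segregates with disease in a family, so it must be
   present in both affected relatives, inside a chromosomal segment they
   inherited identical by descent (IBD) from their common ancestor.
2. Causal mutations of a rare, genetically heterogeneous disorder are
   essentially private to families. A variant observed in two or more
   *unrelated* affected samples is almost always a common polymorphism
   or a systematic sequencing artifact — with the rare exception of a
   recurrent known pathogenic allele, which is handled by an explicit
   rescue rule.

All calls are haploid (genotype 0 or 1): the male X outside the
pseudoautosomal regions has a single copy, and the pseudoautosomal
regions are excluded by an interval mask throughout.

## Stage order

`runCombined()` applies, in order:

1. **Universal pre-filters.** The strand filter retains a call only if
   at least one alternate-allele read was seen on each sequencing
   strand; one-sided support is a classic false-positive signature. The
   proximity filter rejects every call within 10 bp (inclusive) of
   another call of the same sample, because artifacts aggregate while
   true variants are sparse (roughly two per kilobase at the extreme).
   Distances are computed once on the original call set — both members
   of a close pair are rejected and the result is order-independent and
   idempotent.
2. **Shared-segment filter** (pairs only). For each declared pair a
   discordance track is built: every variant key present in either
   sample becomes a point, concordant (A|A) or discordant (A|R). IBD
   segments are detected as discordance-free stretches (below) and a
   call is retained only if it is concordant and falls inside a
   segment.
3. **Kindred/cross-cohort filter.** A variant key carried by two or
   more samples that are not declared kin is rejected in *every*
   carrier, including kindred pairs that share it with an outsider.
   Then, within a pair, a surviving variant absent in the kin is
   rejected unless the kin lacks adequate coverage at the site
   (depth below `minDepth`, default 4, served by an optional
   low-coverage interval track; without a track, absence counts as a
   confident reference call). Sporadic samples skip the concordance
   rule.
4. **Clinical rescue.** Cross-cohort rejections whose key is annotated
   probable-pathogenic or pathogenic with population MAF below 1% are
   re-introduced for all carriers and made immune to the database
   subtractions. This is the escape hatch for genuinely recurrent
   pathogenic alleles.
5. **Database subtractions.** Sequentially: a "non-clinical" dbSNP-like
   panel (pathogenic records removed first, then records with fewer
   than 12 observed copies — see the carrier model below), a male-only
   population panel, and a hemizygous-male EVS-like panel.
6. **Prioritization.** Genes are scored by mutation burden over the
   filtered cohort and the known-gene content of the resulting list is
   tested by the hypergeometric upper tail.

## IBD segment detection

A 5-Mb window slides across the chromosome at a configurable step
(default 1 Mb); windows containing at most `maxDiscordant` A|R points
(default 0) are flagged and overlapping or adjacent flagged windows
merge. Manual curation of segment ends is replaced by a deterministic
refinement: each merged region is extended to the nearest exterior A|R
point on each side, and the boundary is placed at the midpoint between
the outermost interior point and that exterior discordant point
(chromosome ends clamp). With `maxDiscordant = 0` and a sufficiently
fine step the detected segments provably equal the maximal
discordance-free intervals of at least window length — the test suite
checks this against brute-force enumeration on random tracks. A coarse
step can miss a stretch only slightly longer than the window (there may
be no aligned window fully inside it); the 1-Mb default is a
speed/sensitivity compromise, and the oracle-equivalence tests use a
1-bp step.

Two consequences are worth noting. First, the filter can only find
segments at least one window long; families whose causal variant sits
in a shorter IBD segment would need a smaller window at the cost of
false segments. Second, discordant errors inside a true segment
fragment it, which is why the pre-filters run first: the dominant error
classes (strand-biased and clustered artifacts) are removed before the
track is built.

## The cross-cohort rule and its carrier evidence

In the combined pipeline the cross-cohort rule counts carriers on the
*post-prefilter* cohort rather than on the callsets entering the stage.
The reason is subtle: the shared-segment filter may remove a
batch-systematic artifact from eleven of twelve carriers (it is outside
their segments) while it happens to fall inside the twelfth pair's
segment. Counting carriers after the segment filter would leave the
pair as the only witnesses and the artifact would masquerade as a
kindred-shared variant. Counting on the post-prefilter cohort restores
the full evidence and makes the batch-error self-neutralization
property hold with probability one. Standalone use of
`kindredCrossCohortFilter()` defaults to the callsets it is given.

## The MAF cutoff: a female-carrier probability model

The dbSNP-like subtraction panel must not contain rare variants,
because an unannotated pathogenic allele could hide there and be
subtracted from the cohort — a false negative. How rare is too rare?
In a sex-mixed reference panel with $M$ male X chromosomes and $F$
female individuals ($M + 2F$ chromosomes total), a variant observed in
$n$ copies could be invisible to affected males only if every copy sits
in a heterozygous female carrier. Drawing $n$ chromosomes without
replacement, that probability is

$$P(n) = \frac{\binom{F}{n} 2^n}{\binom{M+2F}{n}},$$

zero once $n > F$. With $M = 525$ and $F = 567$ (the 1000 Genomes
Phase 1 X-chromosome composition), $P(12) = 0.0096 \le 1\%$, and 12 is
the smallest such count, i.e. an allele-count cutoff of 12 of 1,659
chromosomes (MAF 0.72%). The package parameterizes the cutoff by count
rather than by the rounded percentage because the count form is exact.
A `model = "chromosome"` variant drops the heterozygous-carrier
restriction (female homozygotes allowed), giving $P(12) = 0.0102$ and a
cutoff of 13; the carrier model is the default because carrier status
is the biologically meaningful configuration for a recessive allele.

## Gene scoring and enrichment

Only splicing and non-synonymous coding changes qualify. The published
description of the scoring is ordinal (loss-of-function outranks
missense; pair-shared outranks singleton; synonymous and intronic carry
nothing), so the numeric weights are this package's choice, fully
configurable: nonsense/frameshift/splicing 2, missense 1,
synonymous/intronic/other 0, and a ×2 bonus for a variant retained in
both members of a pair (contributing once per family rather than once
per carrier). Ties break deterministically by loss-of-function
presence, qualifying-variant count, then gene id.

Enrichment of known disease genes in the prioritized list is the
hypergeometric upper tail $P(X \ge k)$ for $k$ known genes in a list of
$n$, drawn from $N$ targets of which $K$ are known — in R,
`1 - phyper(k-1, K, N-K, n)`. The mutation-rate-weighted baseline
(`weightedBaseline()`) is reported alongside, not substituted into the
test: genes mutate at different rates, and weighting the known-gene
fraction by control-cohort mutation counts shows how much of the
enrichment survives that correction.

## What the simulator emulates — and what it does not

`simulateReferencePanel()` / `simulateCohort()` generate: a master site
panel with Beta(1, 4) population-A allele frequencies (about 1,000
calls per sample at 5,000 sites — a deliberately scaled-down density
chosen for test speed; real X exomes in this setting carry about 1,800
calls), an independent population-B frequency column, sex-resolved
carrier counts binomially consistent with frequency, and a configurable
pathogenic fraction at low MAF. Cohorts follow the emulated study
design: 30 sporadic males plus 26 affected pairs (22 brother pairs, 2
half-brother pairs, 1 cousin pair, 1 uncle–nephew pair), sequenced at
mean depth 49 in libraries of 12.

Pair sharing is generated structurally: a Poisson number of
recombination breakpoints per meiosis (rate 1.8, roughly the 180-cM X
genetic map) over the number of meioses separating the pair (2 for
brothers and half-brothers, 3 for uncle–nephew, 4 for cousins), each
inter-breakpoint interval shared with the relationship's prior
probability (1/2, 1/2, 1/4, 1/8 respectively). Haplotypes are identical
inside shared segments and drawn independently outside. The sharing
structure is redrawn until the largest shared segment reaches 10 Mb,
and the causal variant (a novel nonsense key absent from every panel)
is planted centrally inside it — mapped families present with sizeable
linkage regions, and a causal variant in a segment shorter than the
detection window would be invisible to any 5-Mb method. The emitted
linkage intervals partition the chromosome at the union of all
breakpoints, so true segment boundaries coincide with linkage-interval
boundaries by construction.

Injected errors: strand-biased singletons (no reverse-strand support),
clustered call pairs within 10 bp, batch-systematic keys planted in
every sample of a library batch, and within-pair discordance noise
planted inside true shared segments as strand-biased calls — so the
pre-filters remove it, reproducing the observation that pre-filtering
clears discordant points from IBD segments. Error positions keep 25 bp
from all other variants so each class is removed by the filter that
targets it, keeping ground-truth attribution unambiguous.

The simulator does **not** model: read-level sequencing (depths and
strand splits are drawn, not piled up), capture design or coverage
heterogeneity beyond the low-coverage interval interface, de novo
mutation, linkage disequilibrium between panel sites, or population
substructure beyond a single admixture axis (five sporadic samples
carry a 30% population-B contribution by default, for the
stratification metrics). Passing tests therefore demonstrate the
filters' logic and their statistical behaviour under the stated error
model — not performance on real exomes, where error modes are richer
and sharing boundaries fuzzier.

## Numerical and degenerate-input choices

* Variant matching is exact on the `chrom:pos:ref:alt` string;
  multi-allelic records are split on read.
* Intervals (segments, masks, low-coverage tracks, linkage blocks) are
  0-based half-open; VCF positions are 1-based. A call at position $p$
  is inside $[s, e)$ iff $s \le p - 1 < e$.
* "Within ten nucleotides" is inclusive (distance ≤ 10 rejects).
* Identity of two call sets is $2|A \cap B| / (|A| + |B|)$; both-empty
  input is an error rather than a convention.
* The best-match outlier rule in `validatePairs()` is the Tukey box-plot
  fence (Q3 + 1.5 IQR of the sample's identity distribution), a
  documented stand-in for visual inspection; on small cohorts the
  empirical fence is noisy, so the structural check (declared pairs are
  mutual best matches) is the reliable one.
* A genotype-ploidy audit (`auditGenotypePloidy()`) classifies non-zero
  copy numbers into {1, 2, ambiguous}; `maleOnlySubset()` refuses to
  build a subtraction panel from a release whose male genotypes exceed
  a configurable ambiguous fraction, mirroring the decision to re-call
  such data rather than trust it.
* All simulation randomness derives from a single integer seed; cohort,
  panel and scenario streams use distinct fixed offsets so the same
  seed never reuses draws.

## Problem sizes used in the checks

The packaged checks run the default cohort (82 samples, 5,000 panel
sites) across 20 seeds for the retention/self-neutralization
properties, 100 random small tracks for the segment-detection oracle,
10^6 Monte-Carlo draws for the carrier probability, and 1,000 uniform
null draws for enrichment calibration. These sizes make the full suite
complete in minutes on one CPU while keeping binomial/Monte-Carlo
standard errors well below the asserted tolerances.

## Known limitations

* The kindred concordance rule trusts the declared design; a wrong
  pedigree silently becomes a wrong filter (`validatePairs()` exists to
  catch this first).
* Cross-cohort removal keys on exact variant identity; two different
  causal alleles in one gene across families are untouched (allelic
  heterogeneity is the favourable case), but the same causal allele in
  two families is removed unless clinically annotated — the rescue rule
  covers only annotated alleles.
* Segment detection assumes discordance-free IBD after pre-filtering;
  residual discordant errors fragment segments and can shrink coverage
  below the window length.
* The low-coverage accommodation treats absence-with-coverage as a
  confident reference call; mapping artifacts that suppress a true
  variant with good apparent depth will cause a false rejection in the
  kin.
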