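---
title: "Methods: decision-tree calling and analytic validity for a recessive-disease screening panel"
author: "recesscan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: decision-tree calling and analytic validity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(recesscan)
```

## Scope and model

`recesscan` implements the computational half of a targeted hybrid-capture
screening test for recessive childhood diseases: everything downstream of
read alignment. The pipeline consumes per-site read evidence (a
quality-binned pileup), applies an automated decision tree to retain and
genotype substitutions and small indels, detects gross deletions through two
independent evidence channels, interprets pathogenic genotypes against a
disease-gene panel, and quantifies analytic validity against simulated
truth. Enrichment, sequencing and alignment are out of scope; the pileup is
the contract with the upstream toolchain.

## The panel registry

The panel is a table of (OMIM accession, disease name, gene symbol)
associations. Disease identity is the *(accession, name)* pair: the printed
registry reuses one accession for clinically distinct sub-entries (e.g. the
maple-syrup-urine-disease types), while one disease may be served by several
genes (locus heterogeneity) and one gene by several diseases. Counting pairs
is the only convention under which "n genes, m diseases" summaries of such a
table are simultaneously consistent. The distributed registry in
`inst/extdata/table1_panel.tsv` has 507 entries over 437 unique genes and
447 unique diseases.

An optional fourth column (`AR`/`XL`) records inheritance; the printed
registry does not encode it machine-readably, so it defaults to autosomal
recessive and is supplied explicitly where hemizygote logic matters.

## The decision tree

Per site, with the default clinical profile:

1. total depth < 16-fold: the site is uncallable (`LowCov` no-call);
2. the top non-reference allele by quality-passing ("hq", base quality
   above Phred 25) read count is the candidate; ties break alphabetically
   for determinism;
3. fewer than 8 hq supporting reads: no variant (`LowSupport`);
4. the alternate allele fraction is banded: strictly above 0.86 homozygous,
   within [0.14, 0.86] heterozygous (both edges heterozygous, a literal
   reading of the "14–86%" band), strictly below 0.14 subthreshold
   (`SubthresholdFraction`, no variant).

Two further profiles are exposed: `research-v1` (at least 10 reads above
quality 20, at least 20-fold coverage) and `clinical-v2-improved` (more than
6 reads above quality 25, more than 16-fold coverage).

**Allele-fraction denominator.** The fraction is computed as hq alternate
reads over *all hq reads at the site* (`fractionDenominator = "hq"`), not
over total depth. The numerator is quality-filtered, so a quality-matched
denominator is the consistent estimator of the allele balance: with a
quality-pass probability around 0.9 and a 1% error rate, a homozygous site's
hq fraction concentrates near 0.99, safely above the 0.86 boundary, whereas
dividing hq reads by total depth centres homozygotes at 0.99 × 0.9 ≈ 0.89
— about one standard deviation above the boundary at 150-fold coverage — and
misgenotypes roughly a tenth of them. The total-depth convention remains
available as `fractionDenominator = "total"` for sensitivity analyses.

Coverage, by contrast, is total read depth (raw, not quality-filtered):
the coverage gate asks whether the site was sequenced deeply enough to be
assessed at all.

**No-call labelling.** Targets whose positions do not all reach the
coverage minimum are reported rather than silently dropped. A dropped-out
target with GC fraction at or above `gcThreshold` (default 0.75; "high GC"
is not quantified upstream, so the threshold is configurable) that fails in
*every* replicate is labelled `high_gc_reproducible` — the reproducibly
missed high-GC class — otherwise `low_coverage`.

## Gross deletions

Two channels, combined per allele:

- **Junction matching.** A read supports a deletion allele if it contains,
  as an exact substring, a window of the breakpoint-junction reference
  covering at least `minSpan` (default 10) bases on each side of the
  breakpoint midpoint. Any such window contains the central
  2 × `minSpan` window, so matching reduces to one exact substring scan;
  one mismatch anywhere in the window defeats the match. Presence requires
  `minSupport` reads (default 8, reusing the SNP support threshold so the
  caller has one support knob).
- **Normalized coverage.** Depths are rescaled by total sequence generated,
  and each capture target's mean coverage is divided by an unaffected
  baseline's. Ratios at or below 0.10 are banded homozygous, within
  [0.35, 0.65] heterozygous. The bands are this package's convention — the
  upstream description gives no numeric bands — placed symmetrically around
  the ideal ratios 0 and 0.5 with wide margins at typical target sizes.
  The unit of analysis is the whole capture target: targets are short
  relative to gross deletions, so "local decrease" is realized at target
  granularity.

When both channels speak, coverage decides zygosity and the evidence is
`both`; a junction without a banded ratio claims the minimum (heterozygous,
`junction`); a banded ratio without junction support is called from
`coverage` alone, flagged as a conflict when the band is homozygous but a
tested junction was absent (a homozygous deletion should have yielded
junction reads). How discordant channels should be reconciled is not
specified upstream; this rule table is a declared convention.

## Interpretation and reporting

Variants are classified by exact key lookup in a curated knowledge base
(`pathogenic`, `benign_common`, `misannotated`); anything absent is a VUS.
In-silico pathogenicity predictors are deliberately out of scope — the
knowledge base is the classification authority, motivated by the
observation that a large minority of literature-annotated mutations are
common polymorphisms or misannotated. `misannotated` entries are excluded
from genotype assembly but surfaced in a report appendix; `benign_common`
entries are simply excluded; VUS never contribute to affected status, and
one pathogenic heterozygote plus a VUS heterozygote in the same gene yields
carrier status with a review flag rather than a compound-het call.

Per (disease, gene): homozygous pathogenic → affected; two or more
heterozygous pathogenic variants → *presumed* compound heterozygote (the
pipeline has no phasing, and the status string carries that caveat); one →
carrier, except X-linked genes in males, where a single allele is
hemizygous and affected. With unknown sex, an X-linked single heterozygote
is reported as carrier with a flag — the safest default. Genes wholly
uncallable are `indeterminate`, distinct from `negative`.

Carrier mode reports every non-negative finding and summarizes the rest as
negative. Diagnostic mode reports positive *and* negative results for
genes relevant to the clinical presentation and suppresses — but counts —
carrier-level findings elsewhere, so suppression is auditable:
`suppressedCount` plus reported non-negative rows equals total non-negative
findings.

## The simulator

The simulator generates what the caller assumes: per site, depth is
Poisson with the configured mean; alternate reads are binomial in depth
with success probability 0.5 (het), 1 − error (hom) or error/3 (ref); hq
counts thin each allele binomially with `hqProb`. Defaults are the test's
stated operating point — 150-fold mean coverage (equivalently 3.0 GB of
sequence per sample, the anchor of the linear gigabase↔depth map, so
0.7 GB ↔ 35× and 2.7 GB ↔ 135×), and a site mix of 80/15/5 ref/het/hom.
`errorRate = 0.01` and `hqProb = 0.9` are not stated upstream and were
fixed once at values typical of sequencing-by-synthesis data after quality
trimming. Beta-binomial overdispersion is available behind a flag
(default off): capture data are overdispersed, but no parameters are given
upstream, so the default stays at the analytically transparent binomial.

Deletion simulation plants non-overlapping whole-target deletions (11 by
default, mirroring the known-boundary deletion fixture), emits
junction-spanning reads at full (hom) or half (het) depth plus decoy
reads, and produces affected and baseline coverage tracks.

What the simulator does *not* model: alignment artifacts, strand bias,
mapping ambiguity, indel realignment error, GC-dependent dropout, batch
effects. Passing simulation-based checks therefore demonstrates the
decision logic is correct under its own statistical assumptions — it does
not reproduce real-data error rates, which arise from exactly the
unmodelled effects.

## Analytic validity

Confusion counting is at genotype-site level: an exact genotype match at a
true variant site is a true positive; a spurious alternate allele is a
false positive; a het/hom zygosity error counts as a false *negative*
(missed true genotype), a declared convention — the upstream four-cell
comparison does not state one. No-calls are excluded from the four cells
and tallied separately. Sensitivity, specificity, PPV and NPV leave
zero-denominator ratios absent rather than zero.

The ROC sweeps a two-dimensional grid (hq support threshold × lower
het-band edge), because the upstream sweep varied "number and % reads".
A 2-D grid yields a point cloud, not a curve, so the curve is the Pareto
frontier (best TPR at each achievable FPR, made monotone) anchored at
(0,0) and (1,1), integrated by the trapezoid rule. In the noiseless limit
(`errorRate = 0`) evidence separates perfectly and the AUC is exactly 1.

The depth sweep re-simulates pileups for one fixed truth set at
35–135× (0.7–2.7 GB) and reports sensitivity and PPV per depth; sensitivity
rises with depth as sites clear the coverage and support gates while PPV
stays at ~100%, the qualitative shape of the published sweep.

Problem sizes used throughout the test-suite and acceptance computations
— 10,000 sites per simulated sample, 32 capture targets, five replicate
seeds for the depth sweep — were chosen as the smallest sizes at which the
binomial operating characteristics are measured with comfortably small
Monte-Carlo error at the 1% precision the checks assert.

## Numerical and degenerate-input conventions

- Band edges: het band closed on both sides; hom strictly above 0.86;
  deletion bands closed at their edges.
- Ties between alternate alleles break alphabetically; determinism is
  asserted by permutation tests.
- Pileups must be coordinate-sorted; positions outside all targets are
  masked, not errors.
- Allele totals must sum to site depth, and hq counts can never exceed
  totals; violations are row-level parse errors.
- All simulator output is a pure function of (configuration, seed); the
  command-line interface threads one `--seed` through every stage.

## Known limitations

- Genotype likelihood models, strand-bias and realignment filters are out
  of scope by design; the decision tree is deliberately threshold-based.
- Deletion breakpoint *discovery* is not attempted: only deletions with
  defined junction references, or coverage loss at target granularity, are
  detectable. Gross insertions and complex rearrangements are out of scope.
- The knowledge base is exact-key: representation drift (unnormalized
  indels) would miss; the pileup layer left-normalizes indel tokens to
  mitigate this.
- The distributed disease registry yields 447 unique (accession, name)
  diseases against the published summary count of 448; the registry is
  distributed verbatim and the discrepancy is surfaced rather than patched.
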