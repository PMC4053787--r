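---
title: "Methods: comparing mouse sub-strains at the genome and across phenotyping centers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: comparing mouse sub-strains at the genome and across phenotyping centers}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(substrain)
```

## The problem

C57BL/6J and C57BL/6N are the two most widely used laboratory mouse lines.
They descend from one inbred strain separated roughly 220 generations ago, so
their genomes are nearly identical — which makes both halves of a comparative
analysis unusual. On the genomic side, almost every raw variant call between
the two genomes is an artifact, so the analysis is dominated by filtering and
validation rather than by discovery. On the phenotypic side, individual
strain differences are small relative to husbandry and equipment effects, so
evidence must be replicated across independent phenotyping centers rather
than pooled into one model.

`substrain` implements both halves as a reusable pipeline: the variant
hard-filter cascade with consequence classification and validation
bookkeeping; a structural-variant (SV) triage ledger with gene-overlap and
ancestral-event annotation; and a multi-center phenotype comparison with
heat-map encoding, concordance classes, and a randomization null. The
published coding-variant and SV tables ship as plain-text fixtures so every
summary count can be replayed; synthetic generators provide inputs with
known ground truth for everything upstream of those tables.

## Variant filtering model

An inbred genome is homozygous, so at a true variant site essentially all
reads should carry the alternate allele. The cascade therefore removes:

1. **Reference-shared calls** — calls at the same normalized
   `(chrom, pos, ref, alt)` key in an independent short-read assembly of the
   reference strain. Agreement between the two strains' reads against the
   reference at such sites indicates a reference assembly error, not a
   sub-strain difference.
2. **Heterozygous-looking calls** — alternate-allele read fraction
   (`allele_ratio`) below 0.8.
3. **Depth outliers** — read depth below 3 (too little evidence) or above
   150 (collapsed repeats).

Boundary semantics follow the published wording ("less than 0.8", "less than
3 or greater than 150"): values of exactly 0.8, 3 and 150 all *pass*. Each
removed call is tagged with its first failing reason, allele ratio checked
before depth; the order is arbitrary but fixed and documented. The cascade is
order-invariant in outcome — subtraction and filtering commute — and the test
suite asserts this on synthetic inputs.

Because call sets carry no genome context, indels are keyed after a
minimal-representation normalization (trim the common allele suffix, then the
common prefix, advancing the position), which makes differently written but
identical indels compare equal. A full left-alignment against the reference
sequence would require the genome itself and is out of scope.

The published workflow also removed coding candidates sitting in homopolymer
runs or GC-rich windows during manual inspection. That step is exposed as an
optional, reproducible rule (`curate_context_artifacts()`: homopolymer run
length ≥ 8, or GC fraction > 0.8 in a 50 bp window) but is off by default,
since it needs reference sequence context and the published defaults were
judgement calls.

### Consequence classification

`classify_consequence()` works codon-wise against a minimal transcript model
(ordered CDS exons plus the spliced sense-strand CDS). A SNP inside the CDS
is translated strand-aware: gained stop → nonsense, amino-acid change →
missense, otherwise synonymous. Any variant within 2 intronic bases of an
exon boundary — the canonical splice donor/acceptor dinucleotide — is a
splice variant; the window size is a declared choice, since the source
analysis names donor/acceptor sites without a width. A CDS indel is a
frameshift when the allele length difference is not divisible by 3, else an
in-frame indel. Everything else, including positions outside the transcript
span, is non-coding — deliberately not an error, since genome-wide call sets
routinely overlap transcript boundaries. The classifier is validated against
a brute-force oracle that re-splices and translates both whole haplotypes on
1,000 random SNPs over random transcripts of both strands.

### Validation adjudication

Each candidate was genotyped on four samples per sub-strain. Adjudication
applies the panel rules in fixed precedence: missing call → PCR failure;
any heterozygous call → eliminated; within-strain disagreement →
inconsistent; both strains homozygous for the same allele → not a variant;
otherwise confirmed. Precedence matters only for doubly defective panels and
is fixed so the ledger is deterministic. `summarize_validation()` recomputes
the ledger arithmetic (assayed − eliminated = remaining; confirmed split by
coding/non-coding × SNP/indel), and the packaged seed counts replay the
published 931 − 363 → 568 → 236 bookkeeping exactly.

## The SV triage ledger

SV candidates merge across detection methods by reciprocal overlap ≥ 0.5
(the common SV benchmarking default; the source names no threshold), with
single-linkage clustering iterated to a fixed point so that merging a merged
set changes nothing. Insertions are near-zero-length reference intervals, so
they merge only at coinciding breakpoints.

Triage is a state machine with two legal steps:
`predicted → {false_pe_error, retained}` (visual inspection of paired-end
evidence) and `retained → {reference_error, validated}` (PCR/Sanger). The
transition graph makes it impossible to reach `validated` without passing
`retained`, and the packaged counts replay 551 → 81 → 43.

Gene overlap uses containment severity: `entire` when the SV contains the
gene's whole transcribed span, `exon` when it touches at least one exon base,
`intron` when it overlaps the span without touching an exon, else `none`.
When an SV hits several genes the most severe label is kept — the source does
not state its multi-gene rule, so reporting the strongest functional
consequence is this package's declared choice. Labels are invariant to
strand and to exon ordering.

Ancestral events use an outgroup (rat): the derived allele is the one absent
from the outgroup. A derived gain annotated with a retrotransposon class
(LINE, SINE, IAP, MaLR, MTA) is retrotransposition ("`LINE Ins`" etc.); an
unannotated gain is a plain insertion; a derived loss is a deletion; a
tandem-array copy-number change is a VNTR. The three-way rollup counts *all*
insertion labels together (27 on the packaged table), deletions as
non-repeat events (15), and the single VNTR — this is the only reading under
which the published 27/15/1 rollup is consistent with the published
per-event labels, which include plain "Ins" rows. Both alleles present in
the outgroup is an ambiguity error rather than a silent guess.

## Multi-center phenotype comparison

Comparisons are strictly within center and sex — never pooled across centers,
because equipment, diet and unmeasured environment differ between centers and
a pooled model would confound strain with site. Replication across centers,
not meta-analysis, is the evidence standard.

Per parameter × center × sex:

* **Group selection.** When metadata splits a parameter into several
  comparable measurement groups, the group maximizing the *smaller* of the
  two strain sample sizes is used (ties: larger total, then option order).
* **Time courses** are averaged to one scalar per animal before testing;
  missing time points are skipped and empty animals dropped with a warning.
* **Numeric parameters**: two-sided Mann-Whitney U. The exact distribution
  is enumerated when `min(n) ≤ 8` and the pooled sample is untied —
  enumeration is cheap there and removes any approximation concern at the
  small group sizes where it matters — otherwise the normal approximation
  with tie and continuity correction is used. Direction is the sign of the
  mean difference (the source states "greater" without naming a statistic);
  the rank-biserial correlation `2U/(n_N n_J) − 1` is reported alongside as
  a rank-based effect size.
* **Categorical parameters**: Fisher's exact test for 2×2 tables (two-sided
  as the sum of hypergeometric probabilities no larger than the observed
  table's), Pearson's χ² on (r−1)(c−1) degrees of freedom for larger tables.
  The "affected" level must be named per parameter — the source does not
  define it — and gives binary outcomes a direction; multi-level outcomes
  are unordered.

No multiple-testing correction is applied across parameters: multiplicity is
handled by the cross-center randomization null instead, mirroring the
published design.

### Heat-map encoding

Each result becomes a colored cell: blank (`null`) when p ≥ 0.05, otherwise
shade 1–3 counting the thresholds 0.05/0.01/0.001 passed (darker = more
significant; conventional levels, since the published key is graphical
only), hue red when B6N exceeds B6J, green for the opposite, blue for
differences with no order. Missing parameter × center × sex combinations are
filled in blank and flagged `absent`.

### Concordance classes

Per parameter, evaluated within each sex over the non-blank hues and
aggregated over sexes (the published rows are parameter × sex but classes are
stated per parameter):

* `contradictory` — some sex has ≥ 2 centers sharing an ordered hue while
  ≥ 1 center shows the opposite ordered hue (blue has no opposite);
* `concordant_3plus` — some sex has ≥ 3 centers sharing a hue;
* `concordant_2` — some sex has exactly 2 centers sharing a hue with every
  other center blank in that sex;
* `no_difference` — everything else.

Precedence is in that order, so a parameter that both replicates and
contradicts is flagged contradictory. Blue cells concord only with blue:
nulls never match each other, otherwise mostly-blank maps would trivially
"concord".

### The randomization null

To ask how often ≥ k centers would agree by chance, every repeat permutes
the full multiset of cell hues (blanks included) across all non-absent
cells and counts the parameters for which some sex still shows ≥ k cells of
one non-blank hue; the estimate is the total count over parameters ×
repeats. Choices made where the published description is silent:

* **Permutation, not resampling**: shuffling without replacement preserves
  the observed color composition the comparison implicitly conditions on;
  sampling with replacement is available behind a flag.
* **Hue only**: whether "same color" also matched shade is unstated; hue-only
  is implemented (shade encodes strength of the same evidence, not a
  different finding).
* **Global shuffle** across sexes and centers, the most conservative reading
  of "all squares were randomized".
* `observed_concordance_rate()` uses the *same* ≥ k counting rule as the
  null, so the two rates are directly comparable; the class roster (with
  contradictory precedence) is reported separately by
  `concordance_report()`. Using the classification rule on one side and the
  raw counting rule on the other would bias the comparison.

`exhaustive_null()` computes the same expectation exactly for maps of ≤ 16
cells by multivariate hypergeometric enumeration over the per-sex color
allocations, and serves as the oracle for the Monte-Carlo estimator: on the
canonical 6-cell map (2 parameters × 3 centers, hues {red×3, green×3}) the
exact chance rate is 0.1 and the estimator converges to it within
Monte-Carlo error.

Note one conditioning effect: because the null permutes the *observed*
colors, a small map dominated by strong true effects has a high null rate —
the null answers "how likely is this much cross-center agreement given this
many significant cells", not "given no effects". The per-class report, which
contrasts each class against its own randomization distribution, is the more
informative summary on small maps.

## What the synthetic generators emulate — and what they do not

`generate_phenotype_study()` draws numeric values as Gaussian around
`baseline + center offset`, shifts the B6N mean by a standardized effect
`d × noise_sd`, draws categorical outcomes as Bernoulli at per-strain (and
optionally per-center) prevalences, and emits time courses as repeated draws
around the shifted mean. The default configuration is parameterized from
published per-parameter summaries: visual acuity 0.314 vs 0.399
cycles/degree, retinal vein counts 4.8 vs 5.3 per eye, fundus flecking
prevalence 69.2%/44.6%/23.0% in B6N across three centers versus 0% in B6J
(absent at the fourth center, exercising the missing-data path), plus a
glucose-tolerance-style time course and a null control. Group sizes default
to 20 per center/sex/strain, in the range of the published per-center
cohorts.

Real phenotyping data have features the generator deliberately omits: skewed
and heavy-tailed distributions, batch and litter structure, correlated
parameters measured on the same animal, seasonal drift, and center-specific
variance. Passing tests therefore demonstrate that the pipeline recovers
known structure under clean assumptions and is honestly calibrated under its
own null — not that it is robust to every pathology of real data. The
nonparametric tests were chosen in the source precisely to reduce
sensitivity to the distributional part of that gap.

`generate_variant_callsets()` plants disjoint classes at distinct positions:
clean calls (ratio ≥ 0.8, depth in [3, 150]), reference-shared sites
appearing identically in both call sets, heterozygous artifacts with ratio
uniform in [0.3, 0.8), and depth outliers. Recovery is exact by
construction, which is the point: the test is that the cascade implements
its definition, not that the definition is optimal.

## Numerical and degenerate-input choices

* Exact Mann-Whitney p-values are twice the smaller tail of the enumerated U
  distribution, capped at 1; this matches full-enumeration oracles to
  1e-12 on every untied arrangement up to 6 per group.
* Fisher two-sided p-values sum hypergeometric probabilities ≤ the observed
  one with the conventional `1 + 1e-7` relative tolerance for floating-point
  ties.
* A χ² statistic on a table with no variation (identical rows) is defined as
  p = 1 rather than NaN.
* An all-zero contingency table, an empty comparison group, an empty
  comparison-option list, and a map with fewer than k centers are errors,
  not silent results.
* All simulators and the randomization null run under an explicit seed and
  restore the caller's RNG state; the same seed gives bit-identical output.

Problem sizes used by the packaged checks — 10^5 randomization repeats on
small maps, 200 replicate studies at d = 2 with n = 20 per group, 20
simulation seeds for cascade recovery, and enumeration sweeps to 6 values
per group (Mann-Whitney) and N ≤ 40 (Fisher) — were chosen so each check
pins its property with comfortable Monte-Carlo margin while the whole suite
stays quick to run routinely.

## Known limitations

* The genome-scale published counts (681,220 raw calls; 10,794 post-filter)
  derive from raw sequencing reads and cannot be recomputed here; the
  cascade is instead validated by exact recovery of planted truth.
* The published concordance rates (0.213 observed vs 0.074 null, and the
  companion class rates) derive from a cell matrix that exists only as
  figure images; the machinery that produced them is implemented and
  validated against exhaustive enumeration and calibration checks instead.
* Overlap annotation uses one transcript span per gene; isoform-level
  overlap is out of scope.
* The triage ledger replays recorded verdicts; it does not re-implement the
  four SV detectors or the visual-inspection step that generated them.
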