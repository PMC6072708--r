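---
title: "Methods: the pedigree-based variant prioritization funnel"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the pedigree-based variant prioritization funnel}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(varfunnel)
```

## The problem and the model

Whole-genome sequencing of a high-risk cancer family yields millions of
germline variants, of which at most a handful can plausibly explain the
familial aggregation. `varfunnel` implements a staged decision cascade
("funnel") that reduces an annotated multi-sample variant set to a ranked
shortlist, using the family structure itself as the strongest filter. The
stages run in a fixed order; each variant that disappears is attributed to
exactly one stage, so the funnel report is a conservation law: survivors
plus attributed drops always equal the previous stage's count.

1. **Site/sample quality.** A site is kept only when its calling quality
   exceeds QUAL 20 (strict). Coverage is enforced per sample, not per
   site: a genotype call backed by fewer than 5 reads is masked to
   `missing` rather than discarding the variant, because the segregation
   stage needs per-sample evidence and a badly covered sample should not
   veto the whole family. A variant whose every pedigree call is masked is
   removed.
2. **Population frequency.** A variant survives only if its allele
   frequency is *below 0.1%* in every population database where a value is
   present (`maf_<db>` columns). An absent frequency passes: rare variants
   are exactly the ones databases have not seen. The listed frequency is
   used directly as an alt-allele frequency, matching how exome-aggregation
   annotations are reported; no minor-allele folding is attempted.
3. **Pedigree segregation.** The hallmark stage. Carrying means a het or
   hom-alt call (a dominant-model carrier definition, appropriate for
   autosomal-dominant cancer predisposition). Individuals in required
   roles (`case`) must carry; individuals in forbidden roles (`control`,
   and `exclusion_case` for affected individuals known to be unrelated to
   the familial aggregation) must not. Two integer tolerances relax the
   rule (`max_noncarrier_cases`, `max_carrier_controls`, both 0 by
   default). A missing call at a case counts as non-carrying — under the
   strict defaults a missing case call removes the variant — and at least
   one case must actually carry, so a variant can never pass vacuously
   however far the tolerances are relaxed. The source protocol describes a
   per-individual "probability" of being a true case or control without
   quantifying it; we model that allowance as the two integer tolerances,
   which reproduce the described behaviour without inventing weights.
4. **Routing.** Survivors split by genomic location: exonic/splicing to
   the coding route, 5'/3' UTR to their regulatory routes, and
   ncRNA/upstream/downstream/intronic/intergenic to the non-coding route.
   When a record carries several transcript annotations the
   highest-precedence class wins (exonic > splicing > utr5 > utr3 >
   ncRNA > upstream > downstream > intronic > intergenic), applied at
   table-read time. Before any route-specific gate, indels whose footprint
   overlaps a supplied repeat-region set are excluded (`indel_in_repeat`):
   indel calls inside repetitive sequence are unreliable. SNVs are never
   excluded by this rule.
5. **Coding assessment.** Missense SNVs face four gates, evaluated in a
   fixed order for drop attribution:
   * *CADD tier*: scaled CADD PHRED above 10 (top 10% of predicted
     deleteriousness; above 20 the top 1%, above 30 the top 0.1%; all
     strict).
   * *Consensus*: at least 60% of the available predictors in a 12-tool
     missense panel (SIFT, PolyPhen-2 HDIV/HVAR, LRT, MutationTaster,
     MutationAssessor, FATHMM, MetaSVM, MetaLR, VEST3, PROVEAN, RI) must
     vote damaging, with at least 6 predictors scored; fewer scored
     predictors yields an `insufficient` verdict, which does not pass.
     The fraction is taken over *available* tools because predictors
     legitimately lack scores for some variants, and an absent score must
     not count as a tolerated vote.
   * *Intolerance*: at least one of five gene-level intolerance calls
     (three RVIS flavours < 0, pLI ≥ 0.9, missense Z > 0) must vote
     intolerant. Failing requires every available score to lean tolerant —
     this reproduces the published adjudication in which candidates
     "tolerated by all 5" scores were excluded while a 4-of-5 candidate
     passed.
   * *Conservation* (GERP > 2, phastCons > 0.3, phyloP ≥ 3) is reported
     as rankable evidence but is **not** a hard gate by default, because
     the evidence narrative we reproduce used it as supporting
     information; setting `conservation_is_hard_gate = TRUE` additionally
     requires `conservation_min_flags` (default 2) present-and-true flags.
   Grantham distances come from the embedded standard 1974 matrix
   (0–215; symmetric, zero diagonal, maximum 215 for Cys↔Trp) binned at
   50/100/150 into conservative / moderately conservative / moderately
   radical / radical.
6. **Regulatory assessment.** 3' UTR variants are flagged on a mirSVR
   score strictly below −0.1 (a good predicted miRNA target site) or a
   precomputed target-site indicator; 5' UTR variants on a validated
   TFBS-change pass-through column. Both UTR routes keep the CADD > 10
   gate. Non-coding variants bypass the CADD gate — regulatory variants
   need not score highly — and are reported when they hit at least one
   supplied regulatory region set (enhancer, promoter, super-enhancer,
   UCNE, ultrasensitive). Region files are opaque user inputs in BED
   coordinates; no merging is performed on read.
7. **Ranking.** Survivors order by: passing status, CADD PHRED, consensus
   fraction, intolerance votes, Grantham distance (all descending, absent
   values last), with an ascending (chromosome, position, alt) tie-break
   so reruns and input permutations are byte-identical. No numeric
   composite score is defined by the protocol we implement; this sort key
   is our engineering choice and each component remains visible in the
   output.

## Coordinate and missingness conventions

Variant records are 1-based (VCF convention); region sets are 0-based
half-open (BED convention). The intersection layer converts a variant at
position *p* with reference-allele length *L* to the half-open footprint
[*p*−1, *p*−1+*L*) and requires ≥ 1 base of overlap; the conversion lives
in one place (`variant_ranges()`). Chromosome-name dialects are handled by
a `chr_prefix` switch (keep/strip/add); if the two sides still share no
chromosome the intersection warns and returns zero hits rather than
silently failing.

Absent annotations are a distinct state throughout, never zero: an absent
MAF passes the frequency gate, an unscored predictor leaves the consensus
denominator, an absent conservation or intolerance score casts no vote,
and an absent CADD score is `unscored` (which fails CADD-gated routes but
not the non-coding route). Multi-allelic VCF sites are split one record
per alternate allele with genotype calls re-expressed as copies of the
split allele; the per-sample depth key is configurable (`DP`/`NR`)
because callers disagree.

All inequalities follow the published wording: QUAL and CADD cutpoints,
MAF, GERP, phastCons, mirSVR and the 60% consensus wordings are strict
where stated strict; "minimum 5 reads" is ≥ 5; phyloP, pLI ≥ 0.9, FATHMM
≤ −1.5, PROVEAN ≤ −2.5 and RI ≥ 5 are inclusive. VEST3 publishes no
cutoff (only that higher is more deleterious); the default rule votes
damaging above 0.5 and is exposed in the panel configuration.
MutationAssessor's labels map {H, M} damaging / {L, N} tolerated, LRT
{D} / {N, U}, MutationTaster {A, D} / {N, P}, and PolyPhen-2 uses the
published benign band boundary (damaging above 0.452, i.e. both probably
and possibly damaging); these mappings are conventional and overridable
in the shipped `tool_rules.yaml` panel file.

## The packaged family fixture

`table3_fixture()` loads a seven-variant table from a three-sample
thyroid-cancer family (two distantly related cases, one unrelated case
modelled as `exclusion_case`). Its printed fields — loci, region
annotations, exonic classes, CADD scores (25.1, 23.9, 23.1, 32, 3.11,
12.8, 1.7) and carrier counts (2 cases, 0 unknown) — are reproduced as
published. Fields the publication does not print are synthetic
reconstructions consistent with its narrative and are documented as such:
QUAL/depth/genotype values realizing the reported carrier pattern,
predictor scores realizing the reported verdict counts (9/12 damaging and
4/5 intolerant for the CPXM1 G573R candidate; 3/12 for ZBTB41;
all-tolerant intolerance profiles for C1orf27 and FAM129A), and a
synthetic repeat BED covering the three indel loci reported to lie in
repetitive sequence. Running the default pipeline on the fixture
reproduces the published adjudication: the three indels drop as repeat
indels, all four missense SNVs clear the top-1% CADD tier, ZBTB41 fails
consensus, C1orf27 and FAM129A fail intolerance, and the CPXM1 missense
variant (Grantham 125, moderately radical; conservation 5.3/1.0/7.6,
all three flags) is the single ranked candidate.

One known inconsistency of the source narrative is left unreconciled: the
prose says all seven top-ranked variants exceeded CADD 10, but the printed
table contains scores of 3.11 and 1.7. The engine gates on the configured
thresholds and reports what the data give.

## The synthetic-cohort generator

`generate_cohort()` builds annotated cohorts with planted ground truth so
the whole cascade is testable without external data. Its defaults *are*
the study conditions the engine assumes: a family of two cases, one
control and one unrelated (excluded) case; one planted variant
constructed to pass every gate; and seven decoy classes of which each
member fails exactly one named gate (quality, frequency, segregation,
CADD, consensus, intolerance, repeat-indel — 5,000 decoys in the default
mix). Scores are drawn uniformly inside each predictor's published range
on the intended side of its cutoff; passing CADD scores come from the
upper tail (above 22) of the right-skewed PHRED scale; rare-variant
frequencies concentrate below half the 0.1% ceiling and are absent half
the time. Decoys are placed adversarially close to their gate — QUAL
exactly 20, MAF exactly 0.1%, CADD exactly 10, consensus 7/12 (58.3%) —
because the mix of strict and inclusive inequalities is the likeliest bug
source. A single seeded generator drives all sampling and the caller's
RNG state is restored afterwards, so cohorts are byte-reproducible from
their seed.

What the generator does **not** emulate: linkage disequilibrium and
haplotype structure, realistic chromosome-level variant density,
correlated predictor scores (real predictors agree far more than
independent draws), read-level artefacts, or population stratification.
Passing the recovery suite therefore demonstrates that the decision logic
is faithful to its rules — every variant ends where its construction says
it must — not that the thresholds have any particular sensitivity or
specificity on real cohorts.

## Numerical and reporting choices

Funnel percentages are rounded half-up to one decimal (`funnel_fraction`),
matching the reporting style of the published counts (1,970 of 120,323
segregating variants is 1.6%; 28 coding among 1,970 is 1.4%; the four
route counts 28 + 1015 + 901 + 26 partition 1,970 exactly, which
`check_route_partition()` enforces before a report is written). Ties in
ranking are broken positionally; chromosome order is 1–22, X, Y, MT, then
lexical. Degenerate inputs fail loudly: an empty pedigree, a pedigree
without cases, zero-length BED intervals, frequencies or pLI outside
[0, 1], unknown region classes and unknown categorical predictor labels
are all errors, not silent drops.

Problem sizes in the shipped test-suite were chosen to exercise every
property at desk scale: 100-instance seeded sweeps for the interval
oracle, 200-variant random genotype tables for the segregation oracle,
and ten 5,001-variant cohorts for planted-truth recovery.

## Known limitations

* The engine consumes annotations; it never computes them. Predictor
  scores, CADD, conservation, intolerance, mirSVR and TFBS columns are
  inputs, and region sets are whatever BED files the user supplies.
* Only a dominant carrier model is implemented; recessive and
  compound-heterozygous designs are out of scope, as are kinship
  estimation (the concordance matrix is plain genotype identity) and any
  linkage/LOD computation.
* The unreconciled CADD-narrative inconsistency above means funnel counts
  on that fixture depend on whether the UTR/ncRNA records are gated by
  CADD (they are, per the configured thresholds).
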