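---
title: "Methods: translational-efficiency analysis of ribosome-profiling libraries"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: translational-efficiency analysis of ribosome-profiling libraries}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The measurement

Ribosome profiling pairs two libraries per sample: ribosome footprints (FP),
the ~26–34 nt mRNA fragments protected from nuclease digestion by a bound
ribosome, and a fragmented total-RNA control (CT) that measures transcript
abundance on the same size scale. Aligning both to a set of transcript
models and normalizing to RPKM (reads per kilobase of model per million
mapped reads) gives, per transcript and developmental stage,

$$\mathrm{TE} = \frac{\mathrm{FP\ RPKM}}{\mathrm{CT\ RPKM}}$$

the translational efficiency: the ribosome occupancy of a message relative
to its abundance. `riboTE` implements the full path from reads to classified
TE tables, together with a synthetic-data generator that provides ground
truth for every stage of the pipeline.

Assumptions inherited from the design:

* quantification is against cDNA (transcript) models, not the genome, so no
  spliced alignment is needed;
* reads are aligned exact-match only (zero mismatches) with a multi-mapping
  cap of 25, and a read over the cap is suppressed entirely;
* reads hitting rDNA-contaminated models are removed before any totals are
  formed — rRNA can be 20–80 % of mapped reads in footprint experiments, so
  the normalization denominator must exclude it;
* biological replicates are averaged on the RPKM scale, not the count scale.

# The count test

Per stage, raw CT and FP counts (2 + 2 libraries) enter a negative-binomial
exact test. Zero counts are first converted to 1 — this keeps transcripts
with empty cells inside the test and mirrors the standard practice for this
design; the conversion applies only to test inputs, never to RPKMs.

The test is the classic formulation: median-of-ratios size factors; a
common mean per transcript estimated from size-factor-normalized counts; a
per-transcript dispersion estimated by method of moments pooled across both
conditions; and a two-sided p-value equal to the probability, conditional on
the CT+FP total, of splits no more likely than the observed one. Exact
numerical agreement with any particular historical implementation is not
claimed; the contract is calibration (type-I error at the nominal level on
null data) and monotonicity, which the acceptance suite checks.

Numerical choices that matter:

* **Dispersion shrinkage.** With two replicates per condition the raw
  method-of-moments estimate has 2 residual degrees of freedom and is very
  noisy. When ≥ 100 transcripts are available, a loess mean–dispersion trend
  is fitted on the *raw* dispersion scale (the estimator is mean-unbiased
  there; fitting log-dispersions systematically underestimates the trend and
  inflates the false-positive rate) over all transcripts, negative estimates
  included, and each transcript's dispersion is the prior-weighted blend
  `(10 * trend + 2 * raw) / 12`, floored at 1e-8.
* **Log-space conditioning.** The conditional split distribution is
  computed from log NB densities normalized by their maximum. On the
  natural scale the joint probabilities underflow for transcripts whose
  CT/FP composition is far from the library average — exactly the
  interesting transcripts — and would erase their significance.
* **No multiple-testing correction in the filters.** The selection rules
  use the raw p < 0.05, as the classification was defined; a
  Benjamini–Hochberg column is emitted for information.

# Reporting conventions

All reported RPKM, TE and ratio values are rounded half-away-from-zero to
two decimals at the reporting layer only; internal computation is at full
precision. Replicate-averaged RPKMs are floored at 0.1 before TE is formed
(configurable): the floor guarantees TE is defined and makes TE exactly 1.00
when both members of the pair sit at the floor, the natural convention for
transcripts at the detection limit. Region ratios are CDS-normalized — the
FP/CT count ratio in a UTR divided by the same ratio in the CDS — so the CDS
row is 1.00 by construction and UTR values read directly as depletion
factors. A region with zero FP reads reports 0.00; a region with zero CT
reads but FP reads present is flagged undefined rather than invented.

Reads are assigned to 5'UTR/CDS/3'UTR by base majority, exact ties going to
the 5'-most tied region; a 5'-end-position rule is available behind a flag.
The majority rule is symmetric and stable for the 26–34 nt reads involved.

# The synthetic experiment

`simulation_config()` defines the study conditions the tests run under; its
defaults emulate the structure of the real libraries:

| parameter | default | rationale |
|---|---|---|
| stages × types × replicates | (C25, C100, C300) × (CT, FP) × 2 | the three-stage, two-replicate design |
| `n_genes` | 1500 | desk-scale transcriptome; large enough for the dispersion trend and the filters to behave as at full scale |
| `reads_per_library` | 150,000 | gives several hundred genes ≥ 300 expected reads, the regime where TE recovery is tested |
| `ct_length_dist` | mode 26–28 nt | control fragments are roughly uniform at the low end of the 26–34 nt selection |
| `fp_length_dist` | mode 31–33 nt | footprint-protected fragments peak there |
| `rrna_fraction` | 0.3 (0.2–0.8 realistic) | rRNA dominates footprint libraries; drawn binomially and sourced from rDNA-tagged models |
| `utr_leakage` | 0.05 | share of FP reads not confined to the CDS; produces the observed strong UTR depletion with CDS = 1.00 |
| abundance | log-normal, sdlog 1.6, rescaled per stage to RPKM units | spans ~4 orders of magnitude so the 1- and 10-RPKM filters are exercised on both sides |
| `error_rate` | 0 | the aligner admits no mismatches, so errors only discard reads; a nonzero rate exists to test that rejection |

Gene classes and their true-TE trajectories: `ordinary` (TE ≈ 1 with mild
log-normal spread), `high_te_early` (TE ~ 18 at the first stage, falling to
~1; the spread matches the 1–40 range seen among preferentially translated
transcripts), `low_te` (TE ≈ 0.05 with abundant mRNA), `storage_like`
(TE rising ~0.4 → ~1.3 while mRNA peaks mid-development), and
`organelle_homolog` (TE ≈ 0.05, CDS copied from a chloroplast gene at a
configurable identity). Organelle-copy models carry short UTRs (30–80 nt),
reflecting that organelle-to-nucleus transfers are predominantly coding
fragments; this also keeps the chloroplast-CDS TE estimator, which can only
see reads fully inside the CDS, commensurate with the truth.

Two identifiability conventions are built into the truth tables rather than
left implicit. First, `ct_abundance` is stored in expected-RPKM units
(relative abundances are rescaled per stage so the estimator is unbiased for
the stored value). Second, TE is only identified up to a global
library-depth factor — FP and CT libraries are normalized by their own
totals — so true TEs are rescaled per stage to make the abundance-weighted
mean exactly 1; `te_true` is the quantity the pipeline's TE estimator is
unbiased for.

What the generator deliberately does not model: sequencing-quality realism
(constant placeholder qualities), paired ends, introns, codon-level
periodicity or dwell times (the analysis uses region-level coverage only),
and between-replicate biological overdispersion — replicates are multinomial
resamples of the same latent abundances. Consequently a green recovery test
demonstrates that the estimators and filters are correct for data satisfying
the model's assumptions, not that the pipeline is robust to replicate-level
biological noise; the null-calibration test injects NB noise (dispersion
0.1) directly at the count level to cover the test's behavior under
overdispersion.

# Alignment

The aligner indexes every k-mer (k = 20, below the 26 nt minimum read
length) of every transcript and verifies full-length candidate matches, so
it finds *all* exact occurrences, overlapping ones included. A read with
1–25 occurrences contributes one hit per occurrence; beyond the cap it is
suppressed. Counting all occurrences (rather than one random placement per
multi-read) is deterministic and symmetric across paralogs; the brute-force
equivalence oracle in the test suite pins this semantics exactly. Sense
strand only by default, since footprints of mRNA are sense-strand;
reverse-complement search is a flag.

# Clustering

TE trajectories are clustered by Lloyd-style k-means under Pearson
correlation distance (d = 1 − r). Profiles are z-standardized per row, which
makes the member mean a valid centroid for correlation distance (the
centroid is re-standardized after averaging); assignment ties break to the
lowest cluster id, and an emptied cluster is re-seeded from the farthest
point. The iteration cap defaults to 5 × 10⁶, the conventional setting of
the clustering tool this mirrors — convergence at these problem sizes takes
a handful of iterations. k is a required user choice; `silhouette_scan()`
reports average silhouette widths over k = 2…10 as guidance but never
auto-applies them. Replicate reproducibility is checked by Pearson
correlation of per-replicate log RPKM vectors (`replicate_correlation()`),
with ~0.8–0.97 the expected range for well-behaved libraries.

# Organelle homology and chloroplast profiling

A nuclear gene is flagged against an organelle genome when its CDS reaches
≥ 90 % identity over ≥ 75 % of its length (both thresholds inclusive; "both"
requires passing each genome independently). Candidates are pre-screened for
at least one exact 20-mer shared with either strand of the genome — at 90 %
identity such anchors are abundant, while unrelated sequences essentially
never have one — and survivors get a gapped local alignment (match +1,
mismatch −2, gap −2.5 per base). Identity is matches over alignment columns
including gaps; coverage is aligned CDS bases over CDS length, from the
single best local alignment (summing multiple HSPs was the open
alternative; single-best is recorded in the output metadata by
construction). In the pipeline, flagging runs on the low-TE gene set, where
organelle homologs concentrate.

Chloroplast-CDS profiling aligns every library against the extracted CDS
sequences (minus-strand features reverse-complemented) with the same
exact-match engine, but normalizes RPKM by the *nuclear* mapped totals — the
organelle-mapped totals are tiny and would destroy comparability across
libraries. TE then follows with the same floor and rounding conventions.

# Problem sizes and limitations

The shipped test and acceptance runs use the default synthetic experiment
(1500 models, 12 × 150,000 reads), a size chosen so the full pipeline
completes in about a minute while leaving several hundred genes in the
well-covered regime; the statistical properties under test (calibration,
recovery, depletion, flagging) are scale-free above roughly this depth.
Known limitations: exact-match alignment only (mismatch tolerance is
reserved in the interface but unimplemented); no SAM/BAM emission (hits and
counts are TSV); gene-level aggregation beyond splice-variant collapsing is
out of scope, as quantification is per transcript model; and the NB test's
agreement with any specific historical software version is not claimed
beyond the calibration contract.
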