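---
title: "Surveying sulfur-metabolism genes in gut MAG cohorts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Surveying sulfur-metabolism genes in gut MAG cohorts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gutsulfur)
```

## The scientific problem

Hydrogen sulfide (H2S) produced by gut bacteria is genotoxic at the
millimolar concentrations found in the colon and has been repeatedly
implicated in colorectal cancer (CRC). Microbes make H2S from two kinds of
substrate: inorganic sulfate/sulfite, reduced by dissimilatory sulfite
reductase (dsrAB) or anaerobic sulfite reductase (asrABC), and organic
sulfur compounds — the amino acids cysteine and methionine, and the
sulfonate taurine, which is liberated from conjugated bile acids by bile
salt hydrolase (bsh).

`gutsulfur` implements a catalog-driven survey of these genes in
collections of metagenome-assembled genomes (MAGs) recovered from stool
metagenomes of healthy, adenoma and carcinoma participants, and the
statistics used to ask whether carriage of each gene is associated with
disease state or cancer stage. Every computational step is a package
function, so the whole analysis can be exercised end-to-end on synthetic
cohorts with known ground truth.

## The gene catalog

Detection is driven by a catalog of 79 sulfur-metabolism genes, each with a
symbol, substrate class (`inorganic`, `organic_cys_met`, `organic_taurine`,
`accessory`), a sulfidogenic flag (does the encoded reaction directly yield
H2S), an HMM profile id and an optional trusted bit-score cutoff. Symbols
follow the field's mixed-case convention (`dsrA`, `CBS`, `3MST`) verbatim —
no case normalization is applied, which avoids silent mismatches between
profile names and catalog symbols. Multi-subunit enzymes (dsrAB, asrABC,
islAB) are deliberately *not* catalog entries: detection happens per
subunit profile, and subunit AND-sets are expressed in the pathway grammar
instead.

The shipped catalog (`default_catalog()`) contains every gene named in the
survey literature's text and figures; because the complete published
supplement is not redistributable here, the remaining rows are a synthetic
reconstruction of a plausible complement (the file is named
`sulfur_gene_catalog_synthetic.tsv` for that reason), and their cutoffs are
representative values. Analyses of real data should load the authoritative
table with `load_catalog()`; everything downstream is parameterized by
whatever catalog is passed.

## Ingestion and filtering

Three filters reproduce the survey's inclusion rules exactly as stated:

* **Trusted cutoffs.** hmmsearch tblout rows are kept when the
  full-sequence bit score is `>=` the gene's trusted cutoff. The comparison
  is inclusive at equality, matching HMMER's own trusted-cutoff semantics.
  Genes without a curated cutoff (custom profiles) have their hits retained
  and flagged rather than dropped, so both plausible readings of
  "cutoff-less" profiles remain available downstream.
* **BLAST survey filter.** Identity must be strictly greater than 60%
  ("greater than" is strict), and alignment length at least 40 aa (a
  "minimum" is inclusive). Alignment length stands in for query coverage
  because the 12-column tabular format carries length, not percent
  coverage.
* **MAG quality.** High quality means completeness > 90%, contamination
  < 5%, strain heterogeneity < 0.5%; medium means completeness > 50% and
  contamination < 5%. All inequalities strict, as quoted; a MAG missing
  strain heterogeneity can never be high quality.

MAG ids are recovered from Prodigal-style protein ids by stripping a
trailing `_<orf-number>`; the pattern is an argument because that
convention is common but not guaranteed. TNM triples map to stages I-IV
through an editable wildcard lookup table shipping a simplified colorectal
rule (any M1 is IV; nodal disease without metastasis is III; node-negative
tumors split I/II on T); unmatched triples are reported `"unstaged"`,
never guessed, and unstaged participants are excluded from stage
denominators.

## Presence, participants, and dot-plot statistics

The core object is a MAG x gene count matrix (hits per MAG per gene);
presence is count >= 1. Copy number within a MAG is never used beyond
that threshold because all downstream statistics are presence-based.
Participants are binarized by the rule "at least one MAG with at least one
copy": `mags_with_gene` counts carrying MAGs, not copies. Participants
whose MAGs were all removed by quality filtering stay in the denominators
(as absences), because per-state proportions are normalized to the total
number of participants in that state.

The per-gene, per-state summary mirrors the survey's dot plots: the
proportion of the state's participants carrying the gene, and the mean
number of carrying MAGs among carriers only (undefined, not zero, when a
state has no carriers).

## The taurine pathway grammar

Pathway logic is data, not code. A grammar is an ordered list of steps;
each step is a set of alternative requirements; a requirement is an AND-set
of subunit symbols. The shipped YAML encodes the two reductive taurine
pathway families:

* 3-step: deamination (`tpa` | `toa`), sulfoacetaldehyde cleavage (`xsc`),
  terminal sulfite reduction (`dsrA`+`dsrB` | `asrA`+`asrB`+`asrC`) — 4
  variants;
* 4-step: deamination, reduction to isethionate (`isfD`), isethionate
  cleavage (`islA`+`islB`), terminal reduction — 4 variants.

These are the eight variants derivable from the survey's running text; the
full published figure describes twelve, and the extra alternatives can be
added by editing the YAML without touching code. Variant enumeration is
the Cartesian product over steps in declaration order (later steps vary
fastest), which makes output deterministic and diff-able.

A unit (MAG, genus, or participant — genus pools gene sets across all MAGs
sharing the label; participants pool across their own MAGs) is called
`complete` when every step has a satisfied alternative;
`first_and_last_only` when the first and last steps are satisfied but an
interior step is missing; `near_complete` when exactly one step is
missing; `absent` otherwise. `first_and_last_only` takes precedence over
`near_complete` whenever both apply — for 3-step grammars they always
collide, and we apply the same precedence to longer grammars because those
units are precisely the metabolic-cooperation / novel-enzyme candidates
reported separately. Completions are additionally annotated with the
terminal requirement satisfied (dsrAB- vs asrABC-terminated), which the
survey distinguishes. A participant-level completion with no single
complete MAG is flagged a *cooperation candidate*: the community, not any
one genome, carries the pathway.

## Association statistics

For each gene, participants are cross-tabulated as presence/absence by the
three disease states and tested with the plain 2x3 Pearson chi-squared
statistic (df 2; at df 2 the upper tail is exactly `exp(-chi2/2)`, used as
a cross-check of the incomplete-gamma tail). No Yates correction and no
small-count exclusion are applied, matching the survey; instead the
smallest expected cell count is reported so readers can judge the
approximation. A gene absent (or present) in every participant gives a
degenerate result (statistic 0, p 1, flagged) rather than NaN. All genes
tested in a run form a single Benjamini-Hochberg family, and the reported
`direction` is the state with maximal carrier proportion, ties broken
toward the more advanced state (a reporting convenience only).

The stage analysis fits the binomial logistic model
logit P(presence) = b0 + b1 * stage and tests b1 = 0 with the Rao score
test evaluated at the intercept-only fit, in closed form: U = sum x(y -
ybar), V = ybar(1 - ybar) sum (x - xbar)^2, statistic U^2/V against
chi-squared df 1. Stages are scored 1-4 equally spaced — the minimal
reading of a logistic regression "against stage" — and the coding is an
argument for sensitivity analyses. By default only carcinoma participants
with a known stage enter (staging is a carcinoma concept and mixing
disease states into a stage covariate would conflate the two tests);
pooling other states is exposed as an option.

## The synthetic cohort generator

The generator emulates the statistical structure the analysis assumes:
participants with disease states and (for carcinoma) stages; a negative
binomial number of MAGs per participant (default mean 25, matching the
published scale of 16,936 MAGs over 667 participants); per-MAG genus
labels drawn from a weighted pool; and gene carriage sampled per MAG from
its genus's carriage probabilities, so genes travel with genera as the
genus-mediated inference assumes (an independent per-MAG mode is just a
one-genus pool). Disease-state effects multiply the carriage *odds*, so
the logistic alternative of the score test is literally realizable and
planted odds ratios are interpretable. Closed-form truth
(`planted_effect_truth()`) gives the marginal carriage probabilities for
recovery checks.

What it does *not* emulate: sequencing, assembly and binning artifacts,
abundance/coverage structure, within-participant strain sharing across
genera, study-level batch effects. Passing calibration on these cohorts
shows the statistics and plumbing are correct under the model's own
assumptions; it cannot show robustness to real-data artifacts upstream of
the presence matrix.

Everything is seeded through an integer-state generator; fixed configs
give byte-identical output files (manifests deliberately contain no
timestamps). The tblout writer emits present genes at cutoff + 25 bits
and, optionally, decoy rows at exactly cutoff - 0.1 for every absent cell
whose gene has a cutoff, so round-trip tests exercise the filter boundary
everywhere.

## Numerical and design choices

* Chi-squared and score-test p-values come from `pchisq` (the regularized
  incomplete gamma); BH adjustment delegates to `p.adjust(method = "BH")`
  behind a validating wrapper.
* The permutation cross-check for the chi-squared test uses fixed-margin
  table sampling (`r2dtable`), i.e. the exact conditional null.
* Degenerate inputs are always explicit flags or errors, never NaN:
  zero-margin contingency rows, constant presence in the score test,
  participants with zero MAGs, unmatched TNM triples.
* Calibration study sizes, chosen once: 2,000 null cohorts of 60
  participants per state with 20 genes and ~6 MAGs per participant for the
  type-I error check (expected cell counts stay comfortably above 5 with
  the carriage range used, so the asymptotic test is in its comfort zone),
  and 200 cohorts of 200 per state for recovery of a planted odds-x3
  carcinoma effect. The analysis scripts run smaller versions of the same
  studies as a demonstration.

## Known limitations

* The shipped catalog completes the published 79-gene set with
  reconstructed entries; cutoffs for those entries are representative,
  not curated. Real analyses should supply the authoritative catalog.
* The grammar ships the eight text-derivable taurine variants of the
  published twelve; the remainder are a config edit away but are not
  asserted anywhere.
* The chi-squared test is asymptotic; with rare genes its small expected
  counts are surfaced but not acted on. An exact/permutation path exists
  only as a test oracle, not as a user-facing option.
* Stage analysis assumes equally spaced stage scores by default; genuinely
  ordinal alternatives (e.g. log-spaced) are supported only through the
  coding argument.
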