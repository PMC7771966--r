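---
title: "Methods: calling and profiling UGGT reglucosylation substrates"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: calling and profiling UGGT reglucosylation substrates}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(uggtquant)
```

## The measurement model

A reglucosylation pull-down experiment compares two affinity purifications
from the same lysate of glucosylation-deficient (ALG6-null) cells: a
wild-type GST-calreticulin bait that binds monoglucosylated glycoproteins,
and the lectin-dead Y109A mutant that captures only nonspecific
background. Both purifications are TMT-labeled and quantified together, so
for protein $i$ in replicate $r$ the data are two reporter intensities,
$I_{i,r}^{\mathrm{WT}}$ and $I_{i,r}^{\mathrm{Y109A}}$. The quantity of
interest is the fold increase

$$f_i = \frac{1}{R_i}\sum_{r} \frac{I_{i,r}^{\mathrm{WT}}}{I_{i,r}^{\mathrm{Y109A}}},$$

the mean of per-replicate ratios over the $R_i$ usable replicates.
Averaging ratios (rather than taking the ratio of summed intensities)
weights replicates equally and matches the per-replicate definition of the
measurement; the alternative aggregation is a one-line change and
`compute_fold_change()` documents the choice. A replicate with a zero or
missing control intensity contributes no ratio: we drop it rather than add
a pseudo-count, because any pseudo-count would manufacture a fold value
with no definition in the measurement model. A protein that loses all its
replicates is excluded with an explicit `ZERO_CONTROL` reason rather than
silently.

Substrates are proteins with $f_i \ge 3$. The cutoff is inclusive — the
boundary case is a deliberate, documented decision exposed as the
`inclusive` flag — and conservative by design: it trades sensitivity for a
low false-positive rate, which is the right trade for a discovery list
that feeds validation experiments. When annotation records are available,
an optional secretory filter (≥ 1 annotated N-glycosite, not
mitochondrial) is applied *after* the cutoff, and both the pre- and
post-filter counts are reported, so the effect of annotation on the call
set is always visible.

Paralog preference is summarized by the enrichment index
$\log_{10}(I^{(1)}_i / I^{(2)}_i)$ computed over proteins shared between
two knockout experiments, where $I^{(k)}_i$ is the mean wild-type-bait
intensity in experiment $k$. With the UGGT1-knockout experiment first,
positive values indicate UGGT2-dependent reglucosylation and negative
values UGGT1-dependent reglucosylation. Proteins with a zero numerator or
denominator are flagged and withheld instead of producing infinities.

No channel normalization is applied before ratio formation by default;
the bait and control purifications come from one split lysate and the
ratio itself cancels protein-level abundance. A median-centering switch
exists for designs where loading differences are a concern.

## N-glycoproteome curation

The reference population for substrate characterization is the curated
N-glycoproteome: records with at least one N-linked glycosite, not
predicted mitochondrial, at least 50 residues long, and collapsed to one
record per canonical accession. Each rule is a pure predicate and the
retained *set* does not depend on filter order; deduplication runs last by
contract. The dedup rule — canonical record preferred, otherwise the
longest isoform, ties broken lexicographically — is our operationalization:
sources describing such curations state that redundant isoforms were
removed without giving the rule. "Annotated as N-glycosylated" is
operationalized as ≥ 1 N-linked CARBOHYD feature regardless of evidence
level, since annotation-based queries do not distinguish experimental
from predicted sites. "Mitochondrial" means any localization term
containing "mitochondri" (case-insensitive) or the explicit flag; real
curation efforts also include manual passes that no rule set can
reproduce exactly, so small count differences against any published total
on a given annotation release are expected. The per-stage
`curation_report` makes every rule's effect auditable.

## Feature profiling

* **N-glycans** are counted either from annotation or by scanning the
  sequence for the acceptor sequon Asn-Xxx-Ser/Thr/Cys with Xxx ≠ Pro
  (overlapping matches all count). The two modes answer different
  questions — annotated sites reflect curated knowledge, sequons reflect
  potential — and are never mixed.
* **Theoretical pI** is the root of the Henderson–Hasselbalch net charge
  $Z(\mathrm{pH}) = \sum_{b}\frac{n_b}{1+10^{\mathrm{pH}-pK_b}} -
  \sum_{a}\frac{n_a}{1+10^{pK_a-\mathrm{pH}}}$,
  found by bisection on [0, 14]. $Z$ is strictly decreasing in pH, so the
  root is unique and bisection cannot miss it; the default tolerance is
  $10^{-3}$ pH units, far below any biological contrast of interest. The
  default pKa set (C-terminus 3.55, Asp 4.05, Glu 4.45, Cys 9.0, Tyr 10.0;
  N-terminus 7.5, His 5.98, Lys 10.0, Arg 12.0) follows the
  Bjellqvist-style constants used by the ExPASy pI/MW tool.
  Residue-specific N-terminal pKa refinements are deliberately not
  implemented; `pka_table()` is swappable, so exact emulation of any
  particular tool is a data change, not a code change. pI is computed on
  the full annotated sequence by default (that is what one gets by
  submitting a database sequence to such a tool); a `mature` flag strips
  the signal peptide first.
* **Topology** follows annotation arithmetic: zero transmembrane segments
  is soluble, two or more is multi-pass, and a single segment is oriented
  by the topological domains around it — luminal/extracellular before the
  segment (or cytoplasmic after) is type I, the reverse is type II.
  Orientation by domain order rather than "N-terminus" keywords keeps
  records with partial domain annotation classifiable; membrane proteins
  with no usable domain sides are reported as `UNDEFINED`, a real class
  in annotation databases, not an error.
* **Luminal exposure** sums the residues of luminal/extracellular domains
  for membrane proteins and uses the whole mature chain (length minus
  signal peptide) for soluble secretory proteins. "Extracellular" counts
  as luminal because every ectodomain was luminal in the ER, the
  compartment where reglucosylation happens. `UNDEFINED` proteins get
  `NA`, excluding them from distributions instead of contributing a
  fabricated zero.
* **Localization** is keyword-matched against a plain-TSV map shipped in
  `extdata` (editable without touching code) over six compartments;
  matching two or more distinct compartments yields `MULTIPLE`, matching
  none yields `OTHER`. Whether published "multiple localization" labels
  were keyword-derived or manual is unknowable; the keyword rule is our
  operationalization and the map is versioned data.

## Densitometry formulas

The immunoblot validation percentage is
$100\,(\mathrm{WT}-\mathrm{Y109A}) / (\mathrm{WCL}/f/n)$ where $f$ is the
fraction of lysate loaded in the whole-cell-lysate lane and $n$ the number
of pull-downs the remainder feeds. With the standard design ($f = 0.10$,
$n = 2$) the divisor is exactly WCL × 5; deriving the factor instead of
hard-coding "5" makes other split designs expressible while reproducing
the standard design exactly. Negative percentages (control above bait) are
returned unclamped — they are a background diagnostic, not noise to hide.
Maturation is simply $100 \cdot \mathrm{mature}/(\mathrm{mature} +
\mathrm{pro})$.

## What the synthetic generators emulate

`generate_tmt_experiment()` plants substrates with fold increases drawn
uniformly from a configurable range over a log-normal abundance
background, with per-channel multiplicative log-normal noise whose σ is
set from the requested coefficient of variation and mean-corrected so the
expected multiplier is 1. Multiplicative, positive noise is the natural
model for reporter intensities; at zero CV every observed ratio equals its
planted fold exactly, which anchors the whole fold pipeline to machine
precision. Background proteins have expected ratio 1; a nonspecific-bias
knob exists but defaults off.

`generate_proteome_cohort()` produces self-consistent annotation records:
a type I record really has a signal peptide, one membrane segment, a
luminal N-terminal domain and a cytoplasmic tail; glycosites land in
luminal regions; emitted sequences contain exactly the planted number of
cysteines and a valid sequon at every planted glycosite (the background
alphabet excludes Asn and Cys so planted counts are exact). The default
composition encodes the study conditions the pipeline is meant for: ~22%
of proteins glycosylated, glycan counts with median 2, log-normal lengths
with median 443 residues, a 2.5% per-residue Cys rate, localization
fractions of 37% plasma membrane / 20% secreted / 5% ER / 4% Golgi / 2%
lysosome, a 70/30 membrane/soluble split with half the membrane proteins
multi-pass, and small mitochondrial (2%), short (1%) and redundant-isoform
(1%) fractions. The generation truth travels with the records
(`attr(x, "truth")`), so curation, topology, luminal exposure and
sequence-feature code are all tested against planted values, not against
themselves.

What the generators do **not** emulate: peptide-to-protein roll-up,
isotope-impurity leakage between channels, missing-value structure from
low-abundance peptides, correlated annotation errors, and the long tail of
weird real annotations (overlapping domains, conflicting topologies).
Passing the synthetic-truth tests therefore demonstrates that the
arithmetic and rules are implemented correctly under the stated model; it
does not certify performance on any particular public annotation release.

Each generator uses a single RNG stream seeded explicitly per call and
restores the caller's RNG state on exit, so simulations are reproducible
and never perturb surrounding code.

## Statistics

Group summaries use type-7 (linear-interpolation) quantiles — the
convention matters only in ties, and it is stated so medians are
reproducible. Group comparisons default to the two-sided Mann–Whitney U
test with normal approximation and tie correction (without continuity
correction, so identical groups give p = 1 exactly); lengths, glycan and
Cys counts are skewed, which is why a rank test is the default, with
Welch's t and Kolmogorov–Smirnov as alternatives. Degenerate all-tied
comparisons return p = 1 with a warning instead of NaN. No
multiple-testing correction is applied by default because comparisons are
reported per feature; a Benjamini–Hochberg adjustment can be applied to
the comparison table with `stats::p.adjust` if many features are screened.

## Problem sizes and numerical choices

The test suite runs on cohorts of 100–1000 records and experiments of
30–200 proteins; the acceptance script uses a 20,353-record cohort
(mirroring the size of a reviewed human proteome) and a 200-protein
pull-down with 20 planted substrates at 5–10×, 10% channel noise and two
replicates — sizes chosen so every check is a property of the method, not
of a lucky draw, while a full run stays in the minutes range on one CPU.
The pI bisection is validated against an independent dense grid scan
(10^5 points) on random sequences, and the di-glycine closed form
$(pK_{\mathrm{N}}+pK_{\mathrm{C}})/2$ pins the implementation to an exact
value.

## Known limitations

* The curation pipeline reproduces rule-based filters; manual curation
  passes in published glycoproteome totals cannot be reproduced and
  release-dependent counts will differ.
* The pKa set omits residue-specific terminal corrections; pI values are
  comparable within the package but may differ from other tools in the
  second decimal.
* Topology classification trusts annotation; it performs no prediction
  and inherits annotation gaps (hence the `UNDEFINED` class).
* Fold-change calling uses a fixed cutoff, not a significance model; with
  many replicates a test-based caller would use more of the data.
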