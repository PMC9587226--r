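---
title: "Methods: differential O-glycoproteomics and site-occupancy estimation with oglyco"
author: "oglyco"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: differential O-glycoproteomics and site-occupancy estimation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## Scope and data model

`oglyco` implements the downstream, table-level analysis of a differential
O-glycoproteomics experiment: a multiplexed TMT panel comparing a wild-type
keratinocyte-like proteome against single knockouts of the expressed
GalNAc-transferase isoforms, plus an MS1 quantification experiment for
O-glycosylation site occupancy. Spectral searching and localization scoring
happen upstream; the package consumes their tabular exports.

All coordinates are 1-based inclusive protein coordinates (UniProt
convention), stated in every file's header comment. Missing intensities are
encoded as empty cells and read as `NA` — "not detected" is deliberately
distinct from a measured zero, because the occupancy `High` flag and the
pairwise-exclusion rules in testing both hinge on that distinction. TMT
channels are addressed as `condition:replicate` column names (e.g. `WT:1`,
`T2:3`), so the condition grouping travels with the table rather than with
channel order.

## Site catalog

Localization rests on ETD spectra only; HCD spectra carry reporter ions but
cannot place a glycan. A peptide-relative position with localization
probability strictly above the cutoff (default 95%) maps to protein
coordinate `pep_start + pos - 1` as an unambiguous site. Glycans on a PSM
that cannot be placed above the cutoff are **retained** as ambiguous sites
whose coordinate is the peptide's S/T/Y span — dropping them would bias
every downstream fraction, and reporting localization rates requires
keeping the denominator. Ambiguous sites are excluded from region mapping
and patch detection, whose logic needs point coordinates, but they keep
their reporter intensities and are tested for regulation under a range key
(`accession:start-end`).

Quantification per glycopeptide uses the HCD record of the same precursor
as the highest-scoring ETD PSM; score ties break by input order so the
operation is deterministic. "Highest quality" is interpreted as the search
engine's score column as given — the package deliberately does not invent
its own spectral quality model.

Site-level quantification is restricted to glycopeptides whose every
supporting PSM carries exactly one glycan. Peptides with mixed single/multi
evidence are excluded from site-level tables: when the same peptide is seen
with one and with two glycans, attributing its reporter signal to a single
site is unsafe. Multi-glycan peptides are routed to a peptide-level table
instead.

## Region mapping

Five categories are evaluated in the fixed precedence order

```
domain > stem > functional_region > terminus > linker
```

with `unassigned` as fallback. The categories are disjoint by construction;
the precedence resolves overlaps, with domain membership first because it
is the most specific structural claim. The order is a package decision
(exposed as a parameter) — the disjoint percentages it produces are the
quantity of interest, and the classifier is tested against an independent
oracle that builds explicit residue sets for every category.

* **stem**: the protein is a type-I or type-II single-pass membrane
  protein and the site lies on the extracellular side within 50 aa
  (`stem_window`) of the transmembrane boundary: N-terminal of the span for
  type-I, C-terminal for type-II. Distance is measured to the nearest
  transmembrane boundary residue.
* **terminus**: within 10 aa (`terminus_window`) of the mature N-terminus
  (first residue after the signal peptide, else residue 1) or of the
  C-terminus, counting the terminal residue as offset 1.
* **linker**: strictly between two annotated domains whose gap is
  < 100 aa (`linker_max`).

Domain statistics count domain *instances* (a protein with three FN-III
domains contributes three) over catalog glycoproteins only. Within-domain
site positions use the midpoint-offset convention
`(pos - start + 0.5) / width`, binned into 10 equal bins, so the first and
last residues of a domain fall symmetrically into bins 1 and 10.

## Glycan patches

A patch is a maximal cluster satisfying "≥ 5 sites within 25 consecutive
residues". Implementation: every qualifying window can be anchored at its
leftmost contained site, so only site-anchored windows are enumerated;
qualifying windows that share a member site are merged. Merging by shared
membership (not window overlap) is the package's choice where the counting
rule for overlapping windows is otherwise underdetermined: it prevents one
dense cluster from being reported as many shifted windows, and it is
exactly reproducible by a brute-force oracle that enumerates *all* windows
and merges connected components — the equivalence is asserted on 1000
random instances in the test suite. Patch extent is reported as
first-to-last member site, since window bounds are arbitrary by an offset.

## Differential testing

* **Normalization**: each channel is scaled by one factor so channel totals
  equal the grand mean of input totals (total-intensity normalization).
* **Protein-abundance correction**: sites on proteins whose own abundance
  changes between knockout and wild type (fold change outside 0.5–2 with
  adjusted p < 0.05 in the non-enriched proteome) are removed — an
  intensity drop there reflects protein loss, not deglycosylation.
  Sites whose protein was not quantified are retained and flagged.
* **Fold change** is the ratio of replicate *medians* (KO/WT); the t-test
  is a two-sided equal-variance test on log2 intensities (means), exactly
  separating the two statistics. Log2 stabilizes multiplicative noise.
  Zero-variance rows are handled deterministically (equal constants give
  p = 1, distinct constants p → 0).
* **FDR**: Benjamini–Hochberg across all sites tested in a contrast; the
  standard choice where only "FDR" is specified.
* **Calls**: down requires fold change < 0.5 *and* adjusted p < 0.05 (up:
  > 2). A raw-p variant (`use_raw_p`) reproduces the rank-plot convention
  (p < 0.05, |log2 FC| > 1); where the two conventions disagree the
  adjusted-p rule is the default. Missing intensities are excluded
  pairwise and never imputed; rows with fewer than two values in either
  condition are reported untested rather than silently dropped.
* **Isoform specificity**: a site is specific to a knockout when it is
  called down there and in no other knockout of the panel; down in two or
  more is flagged shared.

## Occupancy

Peak acceptance uses strict windows on mass error (|ppm| < 1.5), isotopic
dot product (> 0.85) and retention-time proximity (< 5 min), an inclusive
identification-score floor (≥ 200), and an isotopologue relative-abundance
floor (> 20) when isotopologue-level rows are supplied. Boundary semantics
are strict on the windows because the defining inequalities are strict;
rejected peaks carry reason codes so the filter is fully auditable.

Charge states are summed within glycoform before any ratio, since the
quantity of interest is per glycoform, not per charge state. Occupancy per
replicate is

```
ratio = sum(glycoform areas) / (sum(glycoform areas) + non-glycosylated area)
```

reported as mean ± SD over replicates. If the non-glycosylated form is
detected in *no* replicate the record is flagged `High` instead of given a
number; partial detection uses the detected replicates only and is flagged.
xTn percentages are each glycoform's share of the glycoform-only total,
integer-rounded in the report with full precision retained in the
machine-readable column. Occupancy classes follow the reporting convention
high > 0.75, medium 0.25–0.75, low 0.001–0.1; the 0.1–0.25 interval is not
assigned by that convention and is reported separately as `gap`, and ratios
below 0.001 as `below_floor`. Between-condition comparison regresses
ratios matched by identical peptide sequence, excluding `High` records
(they have no numeric ratio).

## Synthetic ground truth

The generator emulates the study design: a panel of wild type plus nine
knockouts (`T1, T2, T3, T6, T7, T10, T11, T14, T18`) with three replicates
each; knockout effect 0.1 (a targeted site keeps 10% of its intensity in
its knockout); lognormal multiplicative noise with CV 0.2 on reporter
intensities and MS1 areas (the standard proteomics error model — it keeps
intensities positive and makes log2 intensities exactly normal); 8% of ETD
PSMs drawn below the 95% localization cutoff (so roughly 92% of sites are
unambiguous); 10% of sites assigned to exactly one knockout's target set;
and an occupancy mixture with 60% of regions above 0.75, 11% between 0.25
and 0.75, and 29% between 0.001 and 0.1 (about a third of the high class
fully occupied, exercising the `High` flag). Each stage seeds its own
stream from the master seed plus a fixed offset, so outputs are
bit-identical per configuration and extending one stage never perturbs
another's draws. Out-of-spec decoy peaks are labeled in the ground truth so
the acceptance filter can be tested against exact accept/reject sets.

What the generator does **not** emulate: fragment spectra, isotope
envelopes, retention-time structure, missed cleavages, channel
interference/ratio compression in TMT, batch effects across plexes, or
ionization-efficiency differences between glycoforms. Passing recovery
tests therefore demonstrates correctness of the downstream arithmetic and
decision rules under the stated error model, not robustness to every
artifact of real LC-MS/MS data.

## Problem sizes and numerical choices

The test suite and the acceptance script run at deliberately moderate
sizes: 300-site panels for power and specificity recovery (about 200
single-isoform targets), 1000 sites for null-distribution checks
(Kolmogorov–Smirnov on raw p-values at α = 0.01; FDR-positive fraction
≤ 5%), 500 regions for occupancy class-mixture recovery (binomial
tolerance), and 1000 random instances for the patch-finder oracle. These
sizes give stable statistics while keeping a full run in tens of seconds.

Degenerate inputs are handled explicitly rather than by error where a
defined answer exists: empty FASTA files give empty proteomes; regions
with no glycoform peaks are skipped with a warning; glycopeptides without
ETD evidence are excluded from quantification with a signal, not a crash;
all-missing quantification rows are reported untested. Configuration
errors (windows < 1, fractions outside [0,1], more sites requested than
available S/T/Y residues) fail fast with named messages.

## Known limitations

* Localization re-scoring is out of scope; ptmRS-style probabilities are
  consumed as given.
* The stem rule requires annotated topology and a transmembrane feature;
  proteins with missing topology annotations can only reach stem via
  better annotation, not prediction.
* Ambiguous sites are tested for regulation at peptide resolution; their
  range keys cannot distinguish two co-eluting candidate residues.
* Occupancy assumes a single HexNAc has negligible effect on ionization
  efficiency; no correction is attempted.
* Moderated-variance testing (limma-style) and cross-plex batch correction
  are deliberately not implemented; the t-test/BH pipeline mirrors the
  analysis this package reproduces.
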