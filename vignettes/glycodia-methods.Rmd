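---
title: "Methods: glycopeptide DIA libraries and site-specific glycoform quantification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: glycopeptide DIA libraries and site-specific glycoform quantification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(glycodia)
library(dplyr)
```

## The problem

Data-independent acquisition (DIA / SWATH-MS) quantifies analytes by
extracting fragment-ion chromatograms against a pre-built library of
*transitions*: pairs of precursor m/z (Q1) and fragment m/z (Q3) with a
reference retention time and intensity. Glycopeptides break this model
in two ways. First, their fragment spectra contain ion classes that
peptide-centric library schemata have no names for: glycan oxonium
ions, intact-peptide Y ions (Y0 = bare peptide, Y1 = peptide + HexNAc,
Y2 = peptide + HexNAc~2~), and b/y ions that retain part or all of the
glycan. Second, glycopeptide identifications need evidence rules beyond
a search-engine score, because a glycan mass can be explained by many
composition/peptide combinations.

`glycodia` addresses both: it packs glycopeptide fragments into the
fixed ion-type slots of a PeakView-style transition list, and it
encodes the acceptance rules for glycopeptide spectrum matches as a
deterministic, testable rule engine. Everything downstream — window
schemes, extraction, rollup, normalization, glycoform fractions,
statistics — is ordinary DIA quantification, implemented on tidy data
frames.

## Mass model

All arithmetic is monoisotopic, from one fixed constants table
(`mass_constants()`, also shipped as
`inst/extdata/mass_constants.tsv`): 20 amino-acid residue masses to 5
decimals, glycan residue masses Hex 162.05282, HexNAc 203.07937, dHex
146.05791, Pent 132.04226, proton 1.0072765, water 18.010565. Stating
the constants once keeps ppm-level comparisons stable; a fifth-decimal
disagreement in a residue mass moves a 700 m/z precursor by ~0.05 ppm.

A peptide's neutral mass is the residue sum plus water; hydroxyproline
is written in-sequence as lowercase `p` (Pro + 15.99491), following the
display convention for plant O-glycopeptides, and all other
modifications are positional `(position, delta)` pairs (deamidation
+0.98402, oxidation +15.99491, dehydro −1.00783). Precursor m/z is
`(M + z·1.0072765)/z`; ppm error is `(obs − theo)/theo × 1e6`, reported
to two decimals with the sign convention that under-measured ions are
negative. Glycan compositions are count vectors over
Hex/HexNAc/dHex/Pent; their mass is linear in the counts, which is why
consecutive Hex glycoforms of one peptide are spaced 162.05282 Da and
Pent glycoforms 132.04226 Da.

One charge-state subtlety is worth recording: of the three worked
glycopeptides used throughout the examples, VNLVELGVYVSDIR + Hex~2~
observed at m/z 950.4798 is mass-consistent only with charge 2 (the 3+
ion would sit near 634), although accompanying material elsewhere
labels it 3+. The package treats the reported ppm error as
authoritative and computes this example at z = 2, where it reproduces
−14.4 ppm.

## Fragment model and slot allocation

`enumerate_fragments()` generates, at fragment charges 1+ and 2+:

| class | emitted for | library slot |
|---|---|---|
| plain b/y (glycan fully lost) | all glycopeptides, indices 1..n−1 | `bN` / `yN` |
| Y0 | O-linked | `a1` |
| Y0, Y1, Y2 | N-linked | `a1`, `a2`, `a3` |
| b/y + HexNAc~1~, index ≥ 4 | N-linked, fragment contains the site | `aN` |
| b/y + HexNAc~1~, index ≤ 3 | N-linked | excluded |
| b/y + intact glycan | site known, fragment contains the site | `cN` |

The `a`/`c` letters are repurposed slot names, not true a- or c-ions:
the point is that a peptide-centric library format accepts them.
b/y + HexNAc ions at positions 1–3 are excluded because their slots
would collide with the Y-ion slots `a1`–`a3`. Two design choices the
slot table forces: distinct fragments can collide on one `a`-slot above
a3 (e.g. b5 + HexNAc and y5 + HexNAc both map to `a5`) — at library
build the higher-intensity fragment wins and the collision is logged;
and "labile loss" is modeled as complete glycan loss only, with the
single +HexNAc~1~ class as the one partial-loss ladder, because those
are the classes the slot table can carry. Fragment charges beyond 2+
and internal/cross-ring fragments are out of scope. When the intact
glycan is itself a single HexNAc, the +HexNAc~1~ and intact-glycan
classes describe the same physical ion and are emitted once.

## Validation rule engine

`validate_psm()` encodes the acceptance criteria as a decision tree
over matched ion classes (fragment matching at 50 ppm by default,
20 ppm being the usual precursor tolerance):

1. Every *required* oxonium ion of the composition must be present:
   one oxonium per monosaccharide type (residue + proton, e.g. Hex⁺
   163.0601). dHex and Pent are exempt on N-glycans — their oxonium
   ions are often weak in plant-type N-glycan spectra.
2. Peptides from Lys/Arg–Pro or N-ragged cleavage take the strict
   path: the anchor Y ion (Y0 for O-, Y1 for N-linked) **and** ≥ 3 b
   **and** ≥ 3 y ions.
3. Otherwise, with the anchor Y ion present: ≥ 3 ions from the union
   of b and y.
4. Without the anchor: ≥ 3 b/y ions in total with both series
   represented. The source criteria are ambiguous between this reading
   and "≥ 3 of each"; the stricter reading is available as
   `strict_fallback = TRUE`.

Peak matching is greedy by absolute ppm with each peak consumed by at
most one target, so a single peak cannot impersonate two fragment
ions. Soft evidence (co-elution of other glycoforms, extra Y ions) is
recorded in `notes` but never decides acceptance — it is not
mechanizable as a spectral rule. The engine is monotone by
construction: adding peaks can only add evidence, never flip an
acceptance to a rejection. The test suite checks the engine against a
literal brute-force counter on 1,000 planted spectra; the harness
redraws the rare random peptides whose theoretical fragment lists
contain two masses within 150 ppm, where one planted peak would
legitimately speak for two targets and the two matchers differ by
design.

## Library construction

The identification report is a documented TSV dialect (one row per
fragment ion, PSMs grouped by scan number) carrying what a search
engine's debug export provides; the native formats of commercial tools
are proprietary. `build_library()`:

1. keeps, per (modified sequence, precursor charge), the best-scoring
   PSM, ties broken by lowest scan number;
2. sets Q1 to the *theoretical* precursor m/z of peptide + glycan —
   observed m/z never enters the library;
3. matches each reported fragment against the fragment model to get
   its theoretical Q3 and slot, dropping excluded slots;
4. resolves slot collisions by intensity and removes duplicate
   transitions (same modified sequence, precursor charge, slot,
   fragment charge), keeping the highest intensity.

Libraries round-trip through a fixed 14-column tab-delimited schema
(`write_peakview()` / `read_peakview()`, floats at 5 decimals; m/z, RT
and intensity values are rounded to 5 decimals at build so the
round-trip is exact). `merge_libraries()` unions a glycopeptide library
with a peptide-centric one; on key conflicts the glycopeptide record
wins, and displaced records are attached for inspection. Decoy and
shared flags are emitted for schema compatibility (always `FALSE` at
build; FDR control happens upstream in the search engines).

## Quantification

`make_windows(400, 1250, 26, 1)` reproduces the default acquisition
scheme: 34 isolation windows of 26 m/z with 1 m/z overlap. Window `i`
starts at `low + i·(width − overlap)`; the count is
`ceil((high − low − overlap)/(width − overlap))`.

`quantify_transitions()` accepts either pre-extracted transition tables
or raw peak streams. For peak streams, a transition's intensity is the
*sum* of all signal within ±75 ppm of Q3 and within ±3 min of the
library retention time (the 6-minute window is interpreted as total
width), restricted to the acquisition window containing Q1. Summation
rather than peak-shape integration is used; no chromatographic model
is fitted and no RT alignment is applied. Q1 values on a window
boundary (possible because of the 1 m/z overlap) are assigned to the
lower window with a warning.

Rollup: peptide-precursor intensity is the sum of its top-6 transitions
*selected by library reference intensity*, so the same transitions are
summed in every sample; protein intensity sums its peptide precursors,
and peptides shared between proteins (semicolon-separated accessions)
count fully toward every parent. Protein matrices are normalized to a
reference protein — trypsin, present in constant amount as the added
protease — making the normalization scale-invariant per sample. Zeros
propagate through rollup; downstream log transforms drop zeros rather
than add a pseudocount, and the count of dropped values is reported.

Glycoform relative abundance first sums all charge states of one
glycoform, then divides by the summed intensity of all detected forms
of the same site-peptide family — including the unmodified peptide
when detected. Families with zero total in a sample get `NA` fractions,
not 0/0. Peptide variants that differ only at the cleavage boundary
(e.g. ragged N-termini of one glycosite) cannot be pooled
automatically; an explicit grouping table maps modified sequences to
site-peptide families.

## Statistics

Differential testing is a per-analyte two-sided Welch t-test:
glycoforms on fractions (α = 0.05; a switch tests log fractions),
proteins on log~2~ normalized intensities with a stringent default
α = 10⁻⁵, the customary threshold for protein-level DIA contrasts with
technical replicates. A feature-level mixed model is deliberately not
re-implemented; the t-test is the documented, transparent substitute.
Raw p-values decide significance — no multiple-testing correction is
applied at this stage — and a Benjamini–Hochberg column is emitted for
information. If both groups have zero variance and equal means the
p-value is defined as 1. Swapping conditions negates log~2~ fold
changes and preserves p-values.

Two numerical notes. With three replicates per group the Welch test is
intrinsically conservative: its true type-I error under a Gaussian
null is ≈ 0.035 at a nominal 0.05, a property of the Satterthwaite
approximation at tiny degrees of freedom, visible in the package's
null simulations. And the type-I calibration check itself uses
Gaussian noise on fractions — the null under which the t-test's level
is meaningful — rather than skewed noise, which would additionally
measure robustness, not calibration.

PCA (`pca_scores()`) centers the samples-by-analytes matrix (optionally
log~2~ with an offset equal to the smallest positive value when zeros
are present), drops analytes with missing values (counted), and
reports per-component explained-variance fractions. Identical samples
are a degenerate case: scores are zeroed with a warning rather than
erroring, so screening pipelines keep running.

## Synthetic data: what it emulates, and what not

The generator (`sim_config()`, `simulate_identifications()`,
`simulate_spectra()`, `simulate_dia()`) emulates the structure of a
wine glycoproteome at desk scale:

* the default inventory holds a yeast O-glycopeptide series
  (VITGVPWYSSR, Hex~1–9~), a shared seripauperin peptide
  (VNLVELGVYVSDIR, unmodified + Hex~1–4~), a grape hydroxyproline
  O-glycopeptide (VVRPppTpKPpT, Pent~1–6~), a grape N-glycopeptide with
  plant-type compositions (HexNAc~1~, HexNAc~2~Hex~3~dHex~1~Pent~1~,
  HexNAc~3~Hex~3~dHex~1~Pent~1~) on the synthetic carrier sequence
  TGNLSEVLAK (constructed to hold an N-X-S/T sequon; so labelled
  because no real tryptic sequence is implied), and two real trypsin
  autolysis peptides as the unglycosylated reference;
* two conditions in technical triplicate; intensity noise is mean-one
  log-normal at CV 10%; precursor mass errors are drawn from
  N(−15, 3) ppm, matching the systematic negative offsets seen on
  TOF instruments;
* per-family base abundances are log-normal (σ~log~ = 0.5) and decline
  geometrically by 0.8 per step along the glycoform-size series —
  glycoform profiles are reproducible biology, so their shape is
  deterministic while overall abundance varies;
* planted effects multiply one glycoform's intensity in one condition,
  and spectra can be ablated class-by-class (oxonium, anchor Y, b, y)
  to construct known-reject validation cases.

Everything is a deterministic function of the integer seed
(`withr::with_seed`; sub-streams at seed, seed+1, seed+2 for
identifications, spectra, and DIA tables).

What the generator does **not** emulate: chromatographic peak shapes
and RT drift, isotope envelopes, interference between co-isolated
precursors, charge-state-dependent fragmentation efficiency, decoys
and false identifications, and missingness that correlates with
abundance. Passing tests therefore demonstrate that the *pipeline
logic* is correct — masses, slots, rules, joins, normalizations,
statistics — not that real-data chromatogram extraction is accurate;
on instrument data the extraction quality depends on PeakView-class
software upstream.

## Problem sizes and determinism

The test suite and the acceptance script run at desk scale by design:
the default inventory yields 25 precursors and ~690 transitions, the
validation-equivalence check uses 1,000 planted spectra, the type-I
simulation 1,000 null glycoforms, and the full suite completes in a
few minutes on one CPU. Fixture inputs are generated in code at run
time; no binary data ships with the package. The planted two-fold
recovery check runs at the default study conditions (n = 3, CV 10%)
and is expected to land within ±0.2 of log~2~FC = 1; the small
negative bias (typically −0.05 to −0.1) is the fraction
renormalization — boosting one glycoform inflates the family total
that all fractions share.

## Known limitations

* Site localization is not scored; when a report does not localize the
  glycan, a deterministic default site (first sequon for N-linked,
  first hydroxyproline or Ser/Thr for O-linked) anchors the fragment
  model.
* Average masses, isotope envelopes and charge deconvolution are out
  of scope; all arithmetic is monoisotopic.
* The `a`-slot collision rule (keep the more intense fragment) loses
  one transition when a b- and a y-ion + HexNAc coincide on a slot;
  the alternative — emitting both under one label — would corrupt
  downstream extraction.
* FDR estimation is consumed from upstream confidence fields, never
  computed.
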