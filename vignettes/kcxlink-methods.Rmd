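---
title: "Cleavable K-C cross-linking MS: models and methods in kcxlink"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cleavable K-C cross-linking MS: models and methods in kcxlink}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(kcxlink)
```

## The chemistry being modeled

Heterobifunctional lysine-cysteine (K-C) cross-linkers such as SIA (4.2 Å
spacer), SBAP (9.0 Å) and SIAB (10.6 Å) couple a lysine side-chain amine
(NHS ester chemistry) to a cysteine thiol (haloacetamide chemistry). The
product is a non-cleavable cross-link — until the alkylated cysteine is
oxidized to a sulfoxide. The C–S bond adjacent to that sulfoxide is MS-labile:
under collision-induced dissociation the cross-linked pair splits into two
single-peptide fragments, which makes proteome-scale identification tractable
because each side can then be sequenced independently.

`kcxlink` models this arithmetic exactly, from elemental compositions:

* The **bridge composition** of a linker is the net set of atoms left between
  the lysine Nζ and the cysteine Sγ after both couplings (one H is lost from
  the amine, one from the thiol). Shipped bridges: SIA `C2H2O`, SBAP
  `C5H7NO2`, SIAB `C9H7NO2`. These were derived from the reagent structures
  and are validated in the test suite against the worked-example precursor
  and fragment m/z values at the 10 ppm level.
* The **oxidized intact addition** is `bridge + O − 2H`.
* Cleavage yields the lysine-side fragment with a **sulfenic-acid remnant**
  (α~S~), its dehydrated **unsaturated-thiol** form (α~T~ = α~S~ − H₂O), and
  the cysteine-side fragment with an **alkene (dehydroalanine) remnant**
  (β~A~ = −H₂S, −33.9877 Da). The sulfur leaves with the α fragment, so β~A~
  is the same for every K-C linker, and
  `neutral(α_S) + neutral(β_A) = neutral(precursor)` holds exactly by
  construction.
* A free oxidized carbamidomethyl cysteine instead loses the neutral
  **RSOH** (R = carbamidomethyl), `C2H5NO2S` = 107.004 Da, a useful
  diagnostic ion.

All masses are monoisotopic (the data this models are high-resolution
Orbitrap spectra); charge arithmetic uses the proton mass 1.007276 Da. α~T~
is treated as optional corroborating evidence only: its abundance relative to
α~S~ is linker-dependent (the aromatic SIAB stabilizes the sulfenic acid
against dehydration) and is not modeled quantitatively.

```{r calc}
kcx_calc("Ac-SAKAYEHR:K3", "Ac-LADVCAHER:C5", "SIA")
```

## Identification

Two acquisition modes are supported.

**MSⁿ mode.** MS2 spectra of 4+ to 8+ precursors are scanned for
**signature pairs**: peak pairs, over fragment-charge hypotheses
`1..z−1` whose charges sum to at most `z`, whose neutral masses sum to the
precursor neutral within tolerance (the dehydrated α~T~/β~A~ pair, summing to
precursor − H₂O, is also searched). MS3 spectra of the selected fragments are
matched against an in-silico digest: candidates are peptides whose mass plus
the remnant (α~S~/α~T~ localized on an internal K, β~A~ on a C) matches the
MS3 precursor; each candidate is scored on its remnant-modified b/y ions. A
cross-link spectrum match (CSM) is emitted when the MS2 pair, the two MS3
identifications and the MS1 precursor mass are mutually consistent. The
precursor-consistency check compares the *theoretical* α + β + intact mass
against the measured MS1 precursor at the precursor tolerance, so its error
budget is just the MS1 measurement error. Single-sided MS3 evidence is
emitted but flagged and excluded from default FDR reporting.

**Stepped-HCD MS2 mode.** A single spectrum carries both signature fragments
and sequence ions. Candidate α(K) × β(C) peptide pairs are enumerated by
precursor mass (signature doublets, when present, constrain the α mass), and
both sides are scored in the same spectrum.

**Scoring.** The per-side score is −log₁₀ of a binomial tail probability:
the chance of matching at least `k` of `n` theoretical b/y ions when each
theoretical ion has probability `p` of matching by accident, with `p`
estimated from the spectrum peak density and the matching tolerance. It is
deterministic, intensity-free and self-contained; it is not a reimplementation
of any external search engine's scorer. Ties are broken by smaller absolute
precursor error, then lexicographic sequence, so results are reproducible.

**Digestion.** Trypsin (cleave after K/R, not before P), ≤2 missed
cleavages, peptide length 5–50. A cross-linked lysine blocks its own
cleavage, so cross-linkable lysines must be internal to their host peptide.
Fixed carbamidomethyl is applied to every non-cross-linked cysteine; the
cross-linked cysteine carries the remnant instead. Optional variable Met/Trp
oxidation is off by default. Protein N-terminal amines are not treated as
NHS-reactive sites by default (an opt-in extension point), keeping the search
space to lysines as the baseline.

**Target-decoy FDR.** Decoys are full-sequence reversals preserving the
C-terminal residue. CSMs are classed TT/TD/DD by side and
`FDR(t) = (TD(t) − DD(t)) / TT(t)`, floored at 0; q-values are the running
minimum over decreasing score. CSM-level FDR is the default reporting level;
linkage-level (best CSM per residue pair) is available. The estimator is
validated by entrapment: spectra simulated from proteome A are searched
against A plus an entrapment proteome B, and the observed proportion of
accepted CSMs touching B is compared with the nominal FDR.

**Default tolerances** (all configurable): precursor 10 ppm; MS2 fragments
20 ppm; MS3 fragments 0.6 Da absolute (ion-trap MS3 resolution).

## Aggregation, structures, networks

CSMs collapse to **unique linkages** keyed by (protein A, K residue,
protein B, C residue); peptides mapping to several proteins set an ambiguity
flag and a representative protein is chosen by sorted id. The
reproducibility filter keeps linkages seen in ≥2 biological replicates with
the same linker, the convention used for downstream structural analysis.

For structure mapping, distances are straight-line Cα–Cα in Å, computed in
every structure/chain combination that covers both residues, and the
**minimal** distance is recorded. For intra-protein linkages the inter-chain
distances of homo-oligomeric structures are also computed; a linkage
satisfied only through an inter-chain distance is counted as
**homomer rescue**, which by construction can only increase the satisfied
count. Satisfaction is strict (`distance < 30` Å by default). Structures
whose numbering disagrees with the protein sequence are excluded, flagged,
never silently used; residues without a Cα are unmapped, with no imputation.

Predicted models are gated on confidence. The pair PAE is symmetrized as the
**mean** of the two directed entries (the direction convention of the source
matrices is not fixed; mean is the symmetric choice and differs from min/max
by little at the cutoff scale), with a strict `PAE < 20` default. The pLDDT
of a pair is the min of the two residues, conventional cutoff 70,
configurable because published analyses rarely print it. Secondary-structure
labels are grouped H/G/I → helix, E/B → sheet, everything else → loop;
enrichment for cross-linked K and C is the observed class frequency over
satisfied linkages divided by the background class frequency of that residue
type over the model set, so it is invariant under duplication of the
background. A Cα-geometry fallback assigner (`assign_secstruct_ca()`) exists
for Cα-only fixtures; real analyses should use proper assignment output.

The PPI network has one edge per unordered inter-protein pair; intra-protein
linkages contribute nodes, not edges, and homodimer-supported self-evidence
is therefore reported separately from the edge count. Ambiguous linkages are
excluded from edge building by default. Reference edge sets and complex
definitions are consumed as local export files; identifier reconciliation is
an explicit mapping-table input — no silent fuzzy matching, no live API calls
in the core.

## The synthetic-data generator

The generator exists so that every stage is testable offline with known
ground truth. `sim_config()` defaults describe the validation conditions
used throughout: 50 proteins of length 200 with roughly human-like residue
frequencies (K ≈ 5.7%, C ≈ 2.3%), 100 planted K-C links (half intra-, half
inter-protein), precursor charges drawn from 4–8, 100 exponential-intensity
noise peaks per spectrum, 5 ppm Gaussian m/z error, and 0.9 fragment
detection probability. Signal intensities are log-normal; the scorer uses
counts, not intensities, so these distributions are deliberately simple.

Planted links are realizability-checked at planting time: both residues must
sit in tryptic peptides within the digest bounds, with the lysine internal.
The **fragment-detection probability applies to the sequence (b/y) ladder
ions only**: the signature α~S~/β~A~ fragments are the dominant products of
the cleavage event the method is built on, and precursor detection is a
precondition for acquiring the spectrum at all, so dropping them
independently would model an instrument failure mode rather than fragment
sampling. α~T~ emission is on for SIA/SBAP and off for SIAB, mirroring the
dehydration behavior above. Every generator is deterministic under the seed,
to the byte, for written MGF output.

What the simulation does **not** emulate: chromatography and co-isolation,
isotope envelopes, intensity-dependent peak picking, dynamic exclusion,
modified-peptide backgrounds, and realistic homology structure in the decoy
space. Passing the closed-loop tests therefore shows the arithmetic,
bookkeeping and statistics are correct — not that real-data sensitivity will
match the simulated recovery rates.

## Problem sizes and numerical choices

The shipped validation uses a 50-protein / 100-link proteome per condition
and three entrapment seeds, sizes at which the full pipeline runs in a few
minutes on one core; the identities it checks (mass conservation, recovery,
calibration, minimality of distances) are size-independent. Exact checks use
1e-9 Da tolerances; worked-example comparisons use 10 ppm, matching the
observed deviation of printed values from theory (≤ ~5 ppm). Degenerate
inputs are defined: empty runs produce empty (not error) results from the
detectors; an empty database or a database with no valid protein errors; FDR
estimation without any decoy classes errors, since the estimator is
undefined.

## Known limitations

* The MS3 fragment-selection logic of real instruments (how many MS2
  fragments are picked, intensity thresholds) is instrument-method-specific;
  the simulator emits the top signature candidates and makes the count
  configurable.
* Single-sided MS3 evidence is reported but never enters default FDR
  accounting; whether to accept it is left to the analyst.
* Isotope-error correction, chimeric-spectrum deconvolution and
  retention-time modeling are out of scope.
* The Cα-only secondary-structure heuristic is a fixture tool; it cannot see
  hydrogen bonds and should not be used for biological conclusions.
* Linkage mapping uses the canonical sequence supplied in the FASTA; isoform
  resolution is the caller's responsibility via the mapping table.
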