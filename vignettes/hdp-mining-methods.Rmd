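---
title: "Methods: mining host-defense peptides from a venom-gland secretome"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: mining host-defense peptides from a venom-gland secretome}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hdpminer)
```

## The discovery funnel

Host-defense peptides (HDPs) are short, cationic, usually amphipathic
α-helical peptides of innate immunity. `hdpminer` screens a venom-gland
secretome for HDP-like candidates through a four-criterion funnel:

1. **Toxin homology.** A transcript must hit a curated toxin/venom protein
   reference. Candidacy requires E-value ≤ 0.05 *and* query coverage ≥ 60 %;
   a second, stricter threshold (E ≤ 1e−5) merely labels the hit a confident
   functional annotation and is reported as metadata. Coverage is
   query-relative (alignment length over query length) and must be supplied
   as a precomputed column of the 13-column tabular hit format — the package
   never runs an aligner itself.
2. **Secretion.** A predicted N-terminal signal peptide, consumed as a
   boolean annotation table. Missing records count as failures: evidence
   absent is never evidence of secretion.
3. **Expression.** Abundance ≥ 40 transcripts per million (TPM). All three
   thresholds are inclusive, so a transcript at exactly 40 TPM passes.
4. **Helicity.** Among cascade survivors, only helix-enriched proteins
   (helical fraction ≥ 0.5 by default) proceed to window design. The source
   workflow selected "helix-enriched" transcripts without quantifying the
   rule; 0.5 is this package's declared default, exposed as `enrich_min`.

The candidate set is provably the intersection of the three tabular
filters — the cascade order never matters — and relaxing any threshold can
only grow it. Both properties are exercised in the test suite against
brute-force set arithmetic.

## Helix annotation and window design

Black-box tertiary-structure predictors are deliberately avoided so the
pipeline stays self-contained and auditable. Instead, each residue receives
its Chou–Fasman α-helix propensity (P~α~/100, where 1.0 is indifferent),
smoothed by a centred moving average of width `w = 6` residues (truncated at
the chain ends). Residues with smoothed propensity ≥ 1.03 form helical
segments; runs shorter than 8 residues are discarded as noise. Sequences
shorter than the smoothing window yield an empty, degenerate-flagged
annotation. Precomputed annotations can be supplied as a 1-based inclusive
TSV (`read_helix_tsv()`) to bypass the surrogate entirely, e.g. when a
structure predictor's output is available.

Helical segments are segmented into overlapping windows of `k = 18` residues
with stride `step = 1` — the 18-mer being the candidate unit of the source
workflow, which described a "series" of 18-mers without stating a stride. A
segment of length `L ≥ k` yields ⌊(L−k)/step⌋+1 windows; duplicated window
sequences are removed keeping the first occurrence in (parent, offset)
order, so extraction is idempotent. Internally all coordinates are 0-based
half-open; human-readable reports convert to 1-based inclusive.

## Physicochemical model

**Molecular weight** is the sum of average residue masses plus one water
(18.0153 g/mol), making weight additive under concatenation up to one
condensation.

**Net charge** follows the Henderson–Hasselbalch model: each basic group
(H, K, R side chains, N-terminus) contributes \(1/(1+10^{pH-pK_a})\), each
acidic group (D, E, C, Y side chains, C-terminus) \(-1/(1+10^{pK_a-pH})\).
The curve is strictly decreasing in pH, positive at pH → 0 and negative at
pH → 14 (the termini guarantee one group of each sign), so the isoelectric
point is the unique root, found by plain bisection on [0, 14] to
|Z| < 1e−6. A 0.001-step exhaustive grid search serves as the independent
oracle in the tests; the two agree within 0.01 pH units.

The default pKa set (N-term 9.0, C-term 3.1, D 3.65, E 4.25, H 6.0, C 8.14,
Y 10.07, K 11.1, R 12.5) is a calibrated compromise: web calculators used in
peptide papers do not disclose their constants, and no single textbook set
reproduces both the fractional pH-7 charges and the reported isoelectric
points of the validation peptides simultaneously. With this set all eight
validation net charges land within ±0.15 of their printed one-decimal
values, while the reference 18-mer's pI computes to ≈ 9.98 against a
reported 10.22 — a residual ~0.24 pH-unit misfit that is reported rather
than hidden, and sensitive to the Cys/Lys constants. Every constant is
overridable from a two-column key-value file (`pka_table(file)`). Cysteines
titrate as free thiols; no disulfide correction is applied, which matches
the fractional charges of Cys-rich validation peptides.

Display rounding is half-away-from-zero to one decimal, with integer-landing
values shown without a decimal ("+5").

**Hydrophobic moment** is Eisenberg's helical-wheel amphipathicity measure,
\(\mu_H = |\sum_k h_k e^{i\delta k}|/n\) with the consensus scale and
δ = 100°/residue, normalised per residue. Both scale and angle are
configurable.

**Solubility** is a deliberately transparent surrogate: `Good` when the
pH-7 net charge magnitude is ≥ 2, `Poor` otherwise. It stands in for
undocumented web-server labels and is documented as such, not claimed as a
physical aggregation model.

**The HDP gate** passes windows with net charge ≥ +2; the hydrophobic-moment
threshold defaults to 0 (off), because the moment of short random-ish
windows fluctuates widely and a nonzero default would silently drop genuine
cationic candidates — it is available (`min_moment`) for stricter
amphipathicity screens.

## Antioxidative composition

Three residue categories are counted: aromatic (Y, W), sulfur-bearing
(C, M) and nitrogen-rich basic (H, K, R), plus their total. Counts are
purely compositional — no positional weighting — since claims about residue
arrangement are biological interpretation, not a computable score. The
validation table for these counts is internally inconsistent for six of its
eight rows (printed counts contradict printed sequences); this package
counts from sequences and asserts only the two self-consistent rows, while a
test documents one discrepancy explicitly.

## Veto and composite ranking

External machine-learning predictors are consumed as a score table, never
re-implemented: anti-inflammatory (AIP) scores in [0, 1] from several tools,
one antioxidative (AOP) score, and categorical hemolysis calls. The
aggregation — unspecified in the source workflow — is this package's
declared, configurable surrogate:

* **Veto.** Any `active` hemolysis call excludes the peptide (policy
  switchable to all-active). Vetoed peptides receive no rank.
* **Composite.** Equal-weight mean of the AIP consensus (arithmetic mean of
  the AIP scores) and the AOP score. Monotone non-decreasing in every input,
  bounded in [0, 1].
* **Order.** Descending composite, ties broken lexicographically by id, so
  ranking is deterministic and permutation-invariant.

Per-tool pass thresholds (default 0.5) are reported as metadata
(`passes_aip`, `passes_aop`) and never affect the order.

## The synthetic study conditions

Because the original RNA-seq data are not deposited, the generator creates a
structurally faithful stand-in, not a statistical replica: 60 transcripts of
which 5 are planted positives (echoing the five helix-enriched transcripts
of the source funnel), with the 55 decoys split evenly across four classes
that each violate exactly one criterion — no qualifying homology hit, no
signal flag, sub-threshold TPM, or a coil body with no helix. Positives
carry a signal-like hydrophobic prefix, a coil linker, a helix-former block
of 26–40 residues hosting a cationic Cys/His-rich 18-mer (five basic
residues, two Cys, two His, the rest helix formers — net charge ≥ +2 by
construction, and verified at generation time to sit inside one annotated
helix segment), and a coil tail.

Evidence tables are drawn consistently with the class labels: qualifying
E-values log-uniform below 0.05 with coverage in [0.60, 0.98]; failing hits
violate exactly one of the two homology gates; passing TPM is 40 plus a
log-normal excess (meanlog 3, sdlog 1 — median ≈ 60 TPM), failing TPM
uniform below 39.5. Predictor scores are Beta-distributed with planted mean
0.80 and decoy mean 0.25 at concentration 30 (SDs ≈ 0.07–0.08), a strong but
not degenerate separation representing predictors that genuinely
discriminate; 20 % of decoy windows draw an `active` hemolysis call per
predictor, planted windows never do. All draws happen under an explicit
seed with the caller's RNG state restored afterwards, and reports use fixed
number formatting, so a rerun at the same seed is byte-identical.

What passing the recovery tests shows — and does not show. The tests
demonstrate that the funnel logic is correct: planted signals that satisfy
the stated criteria are recovered exactly, the top-ranked peptide is a
planted window in ≥ 90 % of 50 seeded replicates, and every file format
round-trips. They do not show that the thresholds are well-chosen for real
venom transcriptomes, where homology evidence is correlated with expression,
signal-peptide prediction errs systematically, helicity is context-dependent
and predictor scores are far noisier. The generator makes no attempt to
emulate assembly artifacts, chimeras, isoforms or shared k-mer content
between transcripts.

## Problem sizes and determinism

The shipped defaults keep every computation at desk scale: descriptor math
is closed-form per peptide; the bisection runs ≤ 200 halvings; the
recovery study in the acceptance tests runs 50 full pipeline replicates of
the 60-transcript scenario and the oracle comparisons use 100 random
peptides against a 14,000-point charge grid. Degenerate inputs are defined,
not crashed on: empty candidate sets propagate as empty reports with a
warning, sub-window sequences yield degenerate annotations, and an empty
hemolysis map vetoes nothing but warns.

## Known limitations

* The Chou–Fasman surrogate is a 1970s propensity model; it marks
  helix-former-rich blocks reliably but is no substitute for modern
  structure prediction on real proteins.
* The pKa calibration targets short, Cys-rich, disulfide-free peptides;
  proteins with structured microenvironments will deviate.
* The composite ranking is one defensible aggregation among many; with few
  predictors and no training labels, weights are a modelling choice, which
  is why they live entirely in configuration.
* Solubility classification by charge ignores hydrophobic clustering and
  aggregation propensity.
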