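---
title: "Methods and design notes for styscreen"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods and design notes for styscreen}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(styscreen)
```

This vignette explains the statistical models and procedures implemented
in styscreen, the assumptions they rest on, the defaults and why they
were chosen, and what the synthetic-data validations do and do not
demonstrate about real screens.

## Guide design for S/T/Y missense editing

An adenine base editor deaminates adenines on the protospacer strand
within an activity window, ultimately fixing A·T→G·C. On the coding
strand this reads as A→G for a sense-strand guide and T→C for an
antisense guide. The designer scans `flank5 + cds + flank3` on both
strands for protospacers with a matching PAM and emits one guide per
(protospacer, strand, S/T/Y residue) for which (i) at least one editable
base of the residue's codon lies inside the window and (ii) some
combination of window edits converts the residue to a different non-stop
amino acid. A brute-force enumerator over all 20-mers, PAMs and edit
subsets is kept in the test suite as an independent oracle; the two
agree exactly on randomized transcripts.

Editor defaults and their rationale:

- **Editing window 4–8** (1-based protospacer positions, PAM-distal
  numbering): the canonical high-activity window of ABEmax-class
  editors. Editors differ, so the window is a parameter of
  `editor_spec()`.
- **PAM `NGG`**, protospacer 20 nt: SpCas9 defaults. The PAM accepts any
  IUPAC pattern.
- **On-target consequence** is reported for the *all window adenines
  edited* outcome, because deep editing routinely converts every
  window adenine of the target codon; observed alleles in validation
  data are multi-edit products. Per-subset outcomes determine
  *eligibility* (a residue qualifies if any subset yields missense), and
  in the rare degenerate case where the all-edit product is not itself
  missense the largest missense-yielding subset is reported instead.
- **Bystander edits** — consequences at non-target codons overlapping
  the window — are reported under the same all-edits convention, as
  amino-acid labels (synonymous bystanders are suppressed).
- **Stop-gain outcomes are excluded from "missense"**. For the ABE
  chemistry this is nearly moot: neither A→G nor T→C can convert a
  non-stop codon into a stop, which is why the designer's stop-handling
  branch is defensive rather than load-bearing.
- **iBARs**: three 6-nt internal barcodes per guide, sampled uniformly
  from barcodes without homopolymer runs of four or more (such runs are
  both synthesis- and sequencing-hostile). Uniqueness is enforced
  within a guide only: the iBARs function as internal replicates of one
  sgRNA, so cross-guide collisions carry no information and per-guide
  distinctness is all the combination statistic needs.
- **Controls**: safe-harbor (AAVS1) spacers are appended identically to
  every sub-library present, so sense and antisense analyses share one
  control set.

Coordinates are 0-based half-open internally; protein positions are
1-based everywhere a human reads them.

## The iBAR enrichment statistic

Counts are normalized by median-of-ratios (size factor per sample =
median across rows of `(count + 1) / geometric mean across samples`),
the standard guard against sequencing-depth and composition effects.
Per-iBAR fold changes are `log2((t + 1)/(r + 1))` on normalized counts;
the pseudocount of 1 stabilizes low counts and bounds the statistic.

The per-sgRNA statistic combines *significance* and *inter-iBAR
consistency*:

1. A mean–variance trend σ(μ) is fitted on control-guide fold changes
   (all guides if fewer than 20 controls are available). For NB counts
   the variance of a log fold change is approximately `a + b/μ` — shot
   noise plus overdispersion — so binned variances are regressed on
   reciprocal abundance with bin-size weights. This parametric form
   proved markedly better calibrated in the far tail than interpolating
   binned SDs, which under fixed bin counts is noisy enough to inflate
   the false-discovery rate severalfold at the hit threshold.
2. Each iBAR fold change is standardized, `z = lfc / σ(μ_ref)`.
3. If the guide's iBAR fold changes are not sign-concordant with the
   tested direction, the combined variance is inflated by
   `penalty = max(1, var(z))` — the observed between-iBAR variance
   relative to the unit variance expected of honest replicates.
   Concordant guides are not penalized: with only three replicates,
   penalizing chance spread among concordant iBARs costs power without
   materially improving error control.
4. `z_comb = Σz / √(n · penalty)` (Stouffer), one-sided normal P for
   the tested direction, floored at machine epsilon.
5. BH adjustment across sgRNAs *within each direction*; the signed
   screen score is `−log10(p_adj)`, negated for depletion, and
   `|score| > 1` (strict) calls hits — equivalent to an adjusted P
   below 0.1.

The two sorted gates (marker-high, marker-low) are analyzed as separate
one-directional contrasts against the unsorted reference and
concatenated for reporting; ties in BH ranks resolve by stable row
order. Guides observed with fewer than three iBARs are scored with what
they have and flagged.

Assumptions worth stating: the normal tail is an approximation to the
NB log-ratio tail (slightly heavy; simulations put realized FDR at the
threshold within about twice nominal), replicate iBARs are treated as
independent, and no gene-level aggregation is attempted.

## Amplicon editing outcomes

Read pairs are merged by the best-scoring overlap (most matching bases,
minimum overlap 20 nt, mismatch fraction ≤ 0.1), with within-overlap
disagreements resolved toward the higher base quality; pre-merged input
is accepted. The sgRNA-targeted region is located by its 10-bp flanks,
allowing one mismatch per flank by default to tolerate sequencing error
(an exact mode is available); reads with no or ambiguous placements are
tallied, not guessed. Per-position A/C/G/T fractions are computed over
located reads whose extracted target matches the reference length;
length-discordant reads carry indels, are excluded from positional
composition (indels are rare in base-editor data) and are reported
separately. Haplotypes are translated in frame — codons straddling the
target boundary borrow reference bases — and labelled `WT`,
`synonymous`, `indel`, or a position-sorted list of amino-acid changes
(`Y98C`, `L512P/S513P`). Protein numbering is anchored by the residue
map in the amplicon specification. No quality trimming is applied by
default.

## Phenotype metrics

Relative MFI divides by the isotype control and optionally by the
safe-harbor control on the isotype scale: `(raw/iso)/(ctrl/iso)`.
Division (not background subtraction) is used, matching the
"normalized to" phrasing conventional for these ratios. The killing
indices are `100·(1 − odds(A)/odds(B))` with `odds(x) = x/(100−x)`,
applied to the tracked population (sensitivity) or its wild-type
competitor (resistance). The odds reading of the printed formula
`(A/100−A)` is the only one with the correct fixed points — 0 at A = B
and 100 at A = 0 — and it is strictly decreasing in A and increasing in
B on [0, 100). Replicate comparisons use the classical pooled-variance
two-sample t test by default (the convention of bench statistics
software), with Welch as an option.

## Signature scoring

From a differential-expression table the top `n_top = 250` upregulated
and downregulated genes by Wald statistic form the signature, with
weights `k_i = w_i / max|w|` over the selected genes so upregulated
genes carry positive weights, downregulated negative, and the strongest
gene has |k| = 1. Reading `max(w)` as `max|w|` keeps all weights in
[−1, 1]; the literal signed-maximum reading is available via
`max_signed = TRUE`. Ranking uses the Wald statistic (consistent with
Wald weights) rather than log2FC; that too is switchable. The sample
score is the plain weighted sum `S = Σ k_i·X_i` on log₂TPM as given —
no per-gene z-scoring by default, because the defining equation is an
unstandardized sum; a missing signature gene contributes zero (no
renormalization), with the count reported and scores built on fewer
than half the genes flagged. Marker composites are arithmetic means of
log₂TPM over HLA-A/HLA-B/HLA-C/B2M (MHC-I), CD274 (PD-L1) and
CD8A/CD8B/GZMA/GZMB/PRF1 (CTL), matched case-insensitively; Pearson
correlation and a responder (PR/CR) versus non-responder (PD/SD) t test
complete the analysis.

## What the simulators model — and what they do not

`simulate_screen` models sorting as multiplicative odds on gate
capture: a guide with per-round log2 effect *e* has its capture odds
multiplied by 2^e in each of `rounds = 2` rounds around a baseline gate
of `gate_fraction = 0.10`; expected sorted abundance is reference
abundance times capture probability, and counts are NB draws per iBAR
at `depth = 500` with dispersion 0.05 over lognormal (σ = 1) library
skew. These defaults mirror a two-round, 10%-gate screen sequenced at
~500× per iBAR. The model is count-level: infection stochastics (MOI),
single-cell sorting noise, editing mosaicism and guide-efficacy
variation are not simulated, so passing recovery tests demonstrates the
statistic's behaviour under the stated noise model, not robustness to
every artefact of a live screen. For screen-statistics work at 10⁴-guide
scale the sequence-free `make_synthetic_library` supplies the guide
table, since spacer sequences are irrelevant to count statistics.

`simulate_amplicon_reads` plants haplotype fractions and independent
per-position edit rates, then applies uniform per-base errors; real
sequencing error is position- and context-dependent, which the flank
mismatch allowance absorbs only partly. `simulate_expression_cohort`
adds `activation · k_i` plus Gaussian noise to a baseline (default
5 log₂TPM) for signature genes, with optional co-activation of marker
genes; real cohorts have correlated gene noise and batch structure that
this deliberately omits.

Every generator is deterministic under its seed and emits its ground
truth alongside the data.

## Numerical choices and degenerate inputs

- P values are floored at `.Machine$double.eps` before scoring and
  adjusted P at the smallest positive double before the log, so scores
  are always finite; a score's practical ceiling is ~308.
- Size factors require at least two samples and reject all-zero
  samples; with a positive pseudocount every row participates in the
  median.
- `build_signature` shrinks `n_top` with a warning when the table is
  small, breaks ties by gene identifier for determinism, and collapses
  the duplicate selections that arise only in degenerate all-tied
  tables.
- Zero-variance inputs to the Pearson correlation return `NA` with a
  flag rather than an error; identical groups in `compare_groups`
  return t = 0, p = 1.
- The barcode sampler rejects after a bounded number of retries so an
  over-constrained barcode space fails loudly.

## Validation problem sizes

The bundled tests and the acceptance script validate at desk scale:
20 randomized transcripts for designer–oracle equivalence; null screens
of 10,000 guides × 3 iBARs across multiple seeds and a planted-hit
screen (100 hits of |lfc| ≥ 2 among 10,000 at 500× per iBAR) for error
control and power; 50,000 reads for amplicon rate recovery; cohorts of
40–50 samples for signature separation and activation recovery. These
sizes keep the full suite under a couple of minutes while leaving the
statistics in their intended operating regime.

## Known limitations

- No off-target scoring or guide-efficacy prediction; design treats
  every windowed protospacer as equally editable.
- No gene-level aggregation of sgRNA results.
- The screen statistic's normal tail is mildly anti-conservative under
  heavy NB dispersion; interpret hits near |score| = 1 accordingly.
- The amplicon module is not a general variant caller: it quantifies
  substitutions within one located target region and only counts
  indel-bearing reads.
- Survival modelling and external cohort joins are out of scope;
  signature scores are handed to standard tools for those analyses.
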