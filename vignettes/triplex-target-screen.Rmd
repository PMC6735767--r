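---
title: "Screening promoters for lncRNA triplex target sites: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Screening promoters for lncRNA triplex target sites: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(triplexscreen)
```

## The model

A chromatin-associated lncRNA that contacts genomic DNA sequence-specifically
leaves a signature that can be abstracted as a short DNA word — a *binding
motif*. For the telomerase RNA component (TERC), ChIRP profiling of
RNA-associated chromatin identified the 12-nt word GGCCACCACCCC, which is
exactly the Watson–Crick complement (on the DNA level) of TERC nucleotides
25–36, 5′-GGGGUGGUGGCC-3′. The working hypothesis is that TERC engages duplex
promoter DNA at such sites, plausibly as an RNA–DNA triplex, and thereby
modulates transcription of the downstream gene.

The package implements the four desk-scale computations that flow from this
model:

1. **Partial-motif promoter screen.** A promoter is motif-positive if it
   contains at least `min_match` *contiguous* nucleotides of the motif word
   or of its reverse complement. Operationally we enumerate every distinct
   sub-word of length `min_match`..`length(word)` in both orientations
   (`enumerate_search_words()`), search each exactly, and keep *maximal*
   hits — occurrences not properly contained in a longer hit of the same
   orientation. Promoter-level positivity (the screen's headline count) is
   insensitive to the maximality filter; occurrence-level consumers can
   disable it (`maximal_only = FALSE`).
2. **Distance to TSS.** Each pulled-down genomic fragment is assigned the
   transcription start site minimizing absolute distance on its chromosome,
   and distances are binned to show promoter proximity.
3. **Candidate nomination.** Motif-positive genes are intersected with a
   differential-expression contrast (ectopic lncRNA expression vs control)
   thresholded at |log2FC| ≥ 2 and FDR < 0.01, and ranked by |log2FC|.
4. **Tm shift.** Duplex melting profiles with and without the RNA are
   reduced to melting temperatures; triplex formation is expected to lower
   Tm by roughly 1 °C.

## Parameters that matter

| parameter | default | units | rationale |
|---|---|---|---|
| `min_match` | 10 | nt | the published screening rule ("at least 10 continuous nucleotides") |
| motif word | GGCCACCACCCC | DNA | reverse complement of TERC sites 25–36 |
| `fc_threshold` | 2 | log2 units | published DE rule, inclusive (≥) |
| `fdr_threshold` | 0.01 | probability | published DE rule, exclusive (<) |
| TSS window | `+10` downstream | nt | EPD-style extraction window (see below) |
| distance `measure` | midpoint | bp | symmetric under fragment orientation |
| bin `edges` | ±1, ±5, ±10 kb | bp | conventional promoter-proximity layout |
| `smooth_span` | 5 | points | light smoothing at 0.2 °C grid resolution |

### Decisions where the method description was open

These choices are the package's own; each is configurable where it could
matter.

* **Contiguity is strict.** "10 continuous nucleotides" is read as one
  uninterrupted exact word; no mismatch-tolerant or IUPAC-degenerate
  matching, and `N` never matches anything. Degenerate matching would
  silently change which promoters screen positive.
* **One alphabet internally.** RNA input is normalized to the DNA alphabet
  (U→T) with an `alphabet` tag, because the screen constantly crosses
  between the RNA (the lncRNA segment) and DNA (promoters); duplicate
  RNA/DNA types would double every operation for no benefit.
* **Promoters are counted once** however many sites they carry: the
  published output is a per-gene table, not an occurrence list.
* **TSS anchoring.** The source promoter collection (Eukaryotic Promoter
  Database extracts) pins sequences to a window around the TSS, but the
  exact window used upstream is not stated; the published 60-mers place the
  motif at varying offsets. We default to a window ending +10 downstream of
  the TSS (`tss_index = length − 11`, 0-based), exposed as a single
  configurable rule (`tss_rule_epd()`, or any `function(length)`).
  Lowercase letters (upstream-of-TSS in the source convention) are kept as
  an annotation mask only — several published rows are fully uppercase, so
  case cannot be trusted to anchor coordinates.
* **Distance sign and measure.** Published "distance to TSS" axes state
  neither a sign convention nor whether distance is midpoint- or
  edge-based. We default to fragment *midpoint* (symmetric; the `edge`
  variant is behind a flag) and sign by gene strand with **upstream
  negative**, the convention that makes a promoter-proximity histogram
  interpretable. Ties in absolute distance break toward the smaller TSS
  coordinate. Histogram bin edges are configuration with documented
  defaults; no quantitative claim in this package depends on them.
* **Orientation is reported, not interpreted.** Which DNA strand a
  triplex-forming RNA reads is mechanistically open; hits carry a
  forward/reverse tag and equal-coordinate ties order forward first for
  determinism.
* **Tm definition.** The melting experiments report only fluorescence vs
  temperature; no extraction method is stated upstream. We use the standard
  derivative-peak definition: fluorescence is smoothed by a centered moving
  average (`smooth_span` points), −dF/dT is taken by central differences,
  and the peak is refined below grid resolution by a least-squares parabola
  fitted over the peak ± `smooth_span` derivative points. The wide
  quadratic window (rather than 3-point interpolation) is deliberate: on
  the package's own noise model (1% of amplitude) 3-point interpolation
  leaves a mean absolute error of ≈0.1 °C, too close to the ≈1 °C effect
  size; the least-squares fit brings it to ≈0.04 °C and is exactly
  unbiased on noiseless symmetric transitions (the window is symmetric
  about the peak, and the vertex of a symmetric fit is the true midpoint).
  Degenerate inputs (flat profiles, zero amplitude) return an explicit
  no-estimate (`ok = FALSE`) that `tm_shift()` propagates as `NA` rather
  than an error or a fabricated number.

## What the synthetic data emulates — and what it does not

`gen_promoters()` draws i.i.d. backgrounds at a chosen GC fraction and
overwrites planted motif sub-words of controlled length, orientation and
position; any sequence whose chance content would add an unplanted search
word is rejected and resampled (bounded attempts, loud failure). This makes
generator ground truth *exact*: a promoter has a hit if and only if its
plant is at least `min_match` long, so scanner sensitivity and specificity
tests are sharp rather than probabilistic. The cost is realism: real
promoters are GC-skewed, repeat-rich and autocorrelated, and a real screen
has a background hit rate. A green planted-recovery test therefore
establishes scanner correctness, not genome-scale specificity. A Markov
background is a noted extension, not implemented.

`gen_de_table()` plants `up`/`down` statuses with fold changes and FDRs
drawn from ranges that must sit strictly on their side of the thresholds
(straddling ranges are rejected — ground truth would otherwise be
ambiguous). Defaults mirror the scale of the published contrast (431
DE genes among thousands); no count-level noise model is implied.

`gen_fragments()` centers each fragment at its TSS plus a
Normal(0, 400 bp) strand-signed offset — the 400 bp default makes "most
fragments within ±1 kb of a TSS" true at the published rate
(Φ(2.5) − Φ(−2.5) ≈ 0.988), matching the qualitative claim the annotation
stage was built to reproduce. Fragments default to 500 bp, a typical
sonication scale. `gen_melt_curve()` produces a two-state sigmoid
F(T) = baseline + amplitude / (1 + exp((T − tm)/width)) on a 60–95 °C,
0.2 °C grid (the LightCycler-style readout) with additive Gaussian noise;
width defaults to 0.8 °C, a sharp duplex transition. Real melting profiles
have sloping baselines and occasionally multiple transitions; neither is
modelled, and the Tm estimator is correspondingly tested only against the
two-state world.

All generators take one explicit seed, use it via `withr::with_seed()`
(no global RNG state is touched), and record it in their ground truth.

## Numerical and degenerate-input choices

* Melting grids must be strictly increasing with spacing uniform to 1% and
  at least 25 points; anything else errors at construction.
* Records shorter than the TSS window clamp `tss_index` to 0 with a
  warning; empty FASTA yields an empty list with a warning; duplicate FASTA
  identifiers are suffixed with a warning.
* The packaged 30-promoter fixture is checksummed (md5) on every load and a
  mismatch is a hard error: silent transcription drift in the fixture would
  invalidate the headline reproduction.
* Pipeline outputs are plain BED/TSV plus a JSON manifest carrying
  parameters and md5 checksums of all inputs and outputs, with no
  timestamps, so a rerun from the same configuration is byte-identical and
  verifiable.

## Known limitations

* Exact-match screening only; no thermodynamic or Hoogsteen-pairing triplex
  score is computed (none is defined upstream), so a hit is a sequence
  match, not a binding prediction.
* Differential expression is consumed as a results table; read counting and
  dispersion modelling live upstream.
* Gene identifiers join exactly (case-insensitively); no alias resolution.
* Genome assembly liftover is out of scope: fragments and TSSs must share
  one assembly and chromosome namespace.
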