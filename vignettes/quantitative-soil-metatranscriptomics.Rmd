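---
title: "Absolute quantification of soil microbiomes from SSU rRNA profiles"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Absolute quantification of soil microbiomes from SSU rRNA profiles}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(soilRNAQuant)
```

## The problem

Metatranscriptomic SSU rRNA profiles are compositional: they tell you which
fraction of the sequenced reads each taxon contributed, not how many
ribosomes, cells or micrograms of biomass a gram of soil contained. Worse,
the bridge that usually restores absolute scale — the mass of RNA extracted
per gram of soil — is itself biased, because soils (clays, and especially
volcanic Andosols rich in allophanes) adsorb nucleic acids during
extraction, so the extract represents an unknown, soil-chemistry-dependent
fraction of the RNA that was actually present.

`soilRNAQuant` implements and cross-validates three chains from classified
read counts to absolute 16S rRNA transcript numbers per gram of dry soil,
plus the conversions that place them next to chloroform-fumigation biomass
measurements:

1. **NAE_std (spike-in) scaling.** A known mass of high-quality total RNA
   from a hyperthermophilic archaeon of the class *Thermoprotei* — an
   organism alien to temperate soils — is added to the soil–buffer slurry
   *before* lysis, so that it experiences the same soil chemistry as the
   community RNA. If the standard is retained at the same rate as the
   community RNA, its relative read abundance $a$ (in percent) measures the
   *pre-retention* RNA pool:
   $$\mathrm{RNA}_{total} = \frac{m_{spike}}{a} \times 100 - m_{spike}.$$
2. **qMeTra.** Quantitative metatranscriptomics from the measured extract:
   total extracted RNA per g dry soil $\times$ SSU mass fraction (0.32)
   $\times$ prokaryotic mass share $\times$ transcripts per ng. It
   quantifies the *extracted* pool and therefore scales with the retention
   fraction.
3. **qRT-PCR.** Standard-curve inversion of Cq values against a dilution
   series of in-vitro transcripts whose copy numbers follow
   $c = m / (340\,\mathrm{Da} \times L) \times N_A$.

Transcripts convert onward to cells (÷ 20,000 ribosomes per cell) and to
biomass (× $3\times10^{-13}$ g per cell, reported in µg), and MBC/MBN
fumigation differences convert to the same scale via extractability
corrections (0.45 for C, 0.40 for N) and elemental composition (C = 50%,
N = 14% of cell dry mass).

## Constants and parameters

Every fixed number lives in one `ConstantsSet` object and can be overridden
at construction or from a YAML/key=value file, so each assumption is
auditable:

| constant | default | why |
|---|---|---|
| `f_mrna` : `f_rrna` | 0.04 : 0.96 | theoretical mass ratio of mRNA to rRNA in a cell |
| `f_ssu_of_rrna` | 1/3 | SSU ≈ 1500 nt vs LSU ≈ 2900 nt |
| `len_16s_nt`, `len_18s_nt` | 1500, 1700 | average subunit lengths used for mass weighting |
| `mass_per_nt_da` + `mass_triphosphate_da` | 320.5 + 159 | RNA chain nucleotide mass and the 5' triphosphate |
| `ribosomes_per_cell` | 20,000 | laboratory *E. coli* reference value |
| `cell_mass_g` | 3e-13 | dry mass of one prokaryotic cell |
| `k_extraction_c`, `k_extraction_n` | 0.45, 0.40 | fumigation-extraction efficiency corrections |
| `c_fraction`, `n_fraction` | 0.50, 0.14 | C and N share of cell dry mass |
| `qpcr_mass_per_nt_da` | 340 | per-nucleotide mass convention of qPCR copy arithmetic |

One genuinely open numerical choice is the 16S molar mass. The exact
product of the defaults is 480,909 Da (→ $1.252\times10^9$ transcripts/ng);
the rounded convention of $4.5\times10^5$ Da gives $1.338\times10^9$/ng;
and the rate of $1.22\times10^9$/ng often quoted alongside these
conventions follows from neither (it implies ≈ $4.94\times10^5$ Da). The
three are mutually inconsistent, so `transcriptsPerNg()` exposes all three
(`"exact"`, `"rounded"`, `"printed"`) and defaults to the exact one: we
prefer a rate that is derivable from the stated constants over one that
must be taken on faith. Every estimate is linear in this rate, so switching
conventions rescales results by at most 9%.

The prokaryote share enters as a *mass* share. Read counts are molecule
counts, and an 18S molecule weighs 1700/1500 of a 16S molecule, so a read
share $p$ converts as $p \cdot 1500 / (p \cdot 1500 + (1-p) \cdot 1700)$
(`prokMassShare()`). The synthetic generator applies exactly the inverse
weighting (probabilities ∝ mass/length) so the conversion is testable as a
round trip.

## Spike identification and outlier handling

Spike reads are identified in classified profiles by exact label matching
at a fixed rank position (`class == "Thermoprotei"`,
`family == "Enterobacteriaceae"` for SSU; the family rule catches the
*E. coli* cloning vector carried by the culture). Exact-rank matching
removes everything classified to the clade *or deeper* while leaving taxa
whose names merely contain the label untouched. For non-rRNA profiles the
rules switch to phylum level (*Crenarchaeota*, plus the culture's virus
*Taleaviricota*).

Failed extractions surface as extreme spike abundances. Because no
principled fixed threshold exists, `flagSpikeOutliers()` uses an iterative
mean + 3 SD rule: flag everything above the threshold, re-estimate on the
unflagged set, repeat until stable. At realistic cohort sizes (tens of
samples) this cleanly isolates values like 50% or 5% against a background
of 0.9% ± 0.7%; at toy sizes (n ≈ 5) a single enormous value can inflate
the SD enough that nothing is flagged — the rule is honest about that, and
a fixed `high_pct` override is available. Flags are reported, never
silently dropped.

## The synthetic world

`WorldTruth` defines the generating process; its defaults describe the kind
of temperate volcanic grassland soil the methods target:

* true RNA content 20,000 ng per g dry soil with a between-sample lognormal
  CV of 0.4 — chosen so that at the default retention of 0.2 the *extracted*
  yield is ≈ 4 µg/g from 0.5 g fresh soil at 40% dry matter, matching
  reported extraction yields of ≈ 3.9 ± 1.7 µg/g from ≈ 0.5 g samples;
* a 30 ng spike, giving a spike read share near 1% (the observed regime);
* a 300-taxon lognormal community (log-SD 2), 95% prokaryotic by SSU mass
  (the nonAMP regime; AMP libraries enrich eukaryotes about twofold and
  shift the spike abundance by +0.4 percentage points);
* sequencing depth 2×10⁵ SSU reads — a deliberate desk-scale stand-in for
  ~2×10⁷-read libraries; all read-level statistics are binomial, so
  tolerances in tests are stated as multiples of binomial SEs at the depth
  used, and the vignette's and tests' problem sizes (typically 3–15 samples,
  depths 2×10⁴–10⁶) were chosen to keep the full suite fast while leaving
  those SEs far below the effect sizes being checked;
* a qRT-PCR detection efficiency of 0.02, reflecting that qPCR on soil RNA
  extracts detects on the order of 2% of the SSU rRNA implied by mass-based
  chains.

**Spike retention is coupled to community retention by default**
(`spike_retention = NA`). This is the package's central modelling decision.
The alternative — a fully recovered spike while community RNA is partially
retained — would make the spike-in estimate equal the *extracted* RNA, not
the true content, and could not reproduce the observed discrepancy between
expected (≈3.6%) and observed (≈0.9%) spike abundance. The coupled mode
encodes the mechanism the spike-in design relies on: the standard is added
to the slurry precisely so that it is exposed to the same adsorption
chemistry as the released community RNA. A fixed `spike_retention`
(including the idealised 1.0) remains available to explore violations of
that assumption; under violations the spike-in estimate is biased by the
ratio of the two retentions, and nothing in the data can detect this —
which is the honest limit of the method, not of the implementation.

The retention-invariance property, the repository's central test
(`recoveryExperiment()`): across retentions 0.1–1.0 the spike-in estimate
of true total RNA is unbiased (median |relative error| ≈ 2% at depth 2×10⁵,
driven by binomial noise in ~1500 spike reads plus a ≤ 0.7% length-weighting
bias from the eukaryotic community fraction), while the qMeTra estimate
divided by truth regresses on retention with slope 1. The two agree only at
full retention.

What the generator does **not** emulate: classifier error on environmental
reads (only the mock module's confusion model touches classification),
sequence-level artefacts (chimeras, quality), taxon-specific extraction or
amplification biases beyond the two AMP effects, RNA degradation, and
eukaryotic absolute quantification. Passing tests therefore demonstrate
correctness of the estimators *given* correct classification and the stated
retention model, not robustness to misclassification of real reads.

## Mock validation

The classification pipeline's job — removing the standard without touching
the community — is validated on in-silico mocks: labelled reads subsampled
without replacement (multivariate hypergeometric, mirroring finite read
sets) from a community pool and a spike pool, mixed at 10%, 1% and 0.1%
spiking plus unspiked controls (default design: 8 × 3 levels + 8 controls
= 32 mocks). Classification itself is replaced by a pluggable
confusion-model function, because database-backed read classification is
out of scope; the identity model scores the removal rules alone (recovery
exactly 1), and `mislabelClassifier(rate, target)` injects binomial
label noise. Recovery and contamination sum to 1 exactly by construction;
community loss equals the community's own content of rule-matching taxa
(e.g. natural Enterobacteriaceae) plus any injected confusion. When the
requested mock depth exceeds the per-source subsample, the community
composition is resampled multinomially from the subsample; spike reads are
always drawn without replacement.

## Numerical choices and degenerate inputs

* Zero-read profiles: relative abundance and Bray–Curtis refuse with an
  explicit error; spike splitting returns 0%.
* `naestdTotalRNA()` requires abundance in (0, 100]; at 100% (all-spike)
  it returns 0 ng.
* Negative fumigation differences clip to 0 with a warning rather than
  erroring — they are measurement noise, and a hard error would drop whole
  field campaigns.
* Standard curves are fitted by ordinary least squares of Cq on
  log10(copies); R² is computed directly from residuals. Rejected curves
  (R² outside [0.98, 1] or efficiency outside [0.9, 1.10]) refuse
  quantification rather than warn. Cq values outside the fitted range are
  extrapolated with a warning by default and refused in `strict` mode.
* Ratio summaries compute `mean(a)/mean(b)` unrounded and round only for
  display (one significant figure for detected fractions), because rounding
  order visibly changes "1:k" labels.
* All generation is deterministic under a single integer seed; derived
  seeds stay below 2³¹.

## Worked example

```{r example, eval = FALSE}
out <- runPipeline(list(seed = 1, n_samples = 12, out_dir = "run1"))
out$summaries
#    method         mean           sd       median  n
#  1 NAEstd 7.781610e+12 2.145516e+12 8.101872e+12 12
#  2 qMeTra 1.553304e+12 4.048624e+11 1.586082e+12 12
#  3 qRTPCR 3.106368e+10 8.095387e+09 3.170908e+10 12
```

The ordering NAE_std > qMeTra > qRT-PCR and their relative magnitudes are
the expected signature: qMeTra sees only the extracted fifth of the RNA,
and qPCR detects ~2% of what qMeTra sees.

## Known limitations

* The spike-in estimate is only as good as the equal-retention assumption;
  differential degradation or inhomogeneous mixing bias it undetectably.
* Cell and biomass conversions inherit laboratory *E. coli* reference
  values (20,000 ribosomes, 3×10⁻¹³ g); soil communities violate both in
  partially compensating directions.
* The 18S/eukaryote side is deliberately not quantified absolutely — the
  per-cell and per-mass parameters are far less constrained for eukaryotes.
* No error propagation beyond per-sample computation and mean/SD/median
  summaries.
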