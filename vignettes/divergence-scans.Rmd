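---
title: "Composite divergence scans across SNPs, SVs and STRs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Composite divergence scans across SNPs, SVs and STRs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(polyscan)
```

## The problem

Two recently diverged populations — say, two subspecies of a seabird
breeding a few thousand kilometres apart — are typically separated by very
little genome-wide differentiation. The loci that *do* differ, against that
near-zero background, are candidates for local adaptation. polyscan
implements a three-track scan for such loci:

1. **SNP track.** Five statistics are computed in 50 kb sliding windows
   (25 kb slide) from phased genotypes: nucleotide diversity
   $\pi$, Tajima's $D$ (both within the focal population), Hudson-style
   window $F_{ST}$, and the window means of $|iHS|$ and $|xpEHH|$. They are
   combined into the *decorrelated composite of multiple signals* (DCMS),
   which rewards windows that look extreme under several statistics at once
   while down-weighting statistics that are mutually redundant.
2. **SV track.** Per-locus Weir–Cockerham $\theta$ for biallelic structural
   variants, with outliers called from a normal fit at $q < 0.05$.
3. **STR track.** Per-locus Jost's $D$ for short tandem repeats (after a
   call-rate and minor-allele-frequency filter), same outlier rule.

Downstream, outliers from all three tracks are related to protein-coding
genes by a proximity rule, the gene-proximity counts are tested against a
permutation null, fixed homozygous SNP differences are detected and
classified (synonymous / missense / nonsense), and candidate genes are
cross-referenced against a curated list.

## The statistics

**Window diversity.** With $\hat p$ the alternate-allele frequency among
$n$ haplotypes at a site,

$$\pi = \frac{1}{L}\sum_{\text{sites}} 2\hat p(1-\hat p)\frac{n}{n-1},
\qquad
d_{XY} = \frac{1}{L}\sum_{\text{sites}} p_A(1-p_B) + p_B(1-p_A),$$

where $L$ is the accessible length of the window — the denominator counts
monomorphic sites, so both are per-bp quantities. Window
$F_{ST} = 1 - \bar\pi_{\text{within}}/d_{XY}$. Note that because $\pi$
carries the $n/(n-1)$ correction and $d_{XY}$ does not, two *identical*
panels give $F_{ST} = -1/(n-1)$, not 0; the estimator is slightly negative
under perfect panmixia at finite $n$. Per-locus FST (SVs) uses the Weir &
Cockerham (1984) variance components instead, which handle unequal sample
sizes and heterozygosity explicitly.

**Haplotype statistics.** EHH at distance $x$ from a core site is the
probability that two carrier haplotypes are identical at every site from
the core to $x$; iHH is the trapezoid integral of its decay curve,
truncated by linear interpolation where it crosses the 0.05 cutoff. iHS is
$\ln(iHH_A/iHH_D)$ standardised within 20 equal-width derived-frequency
bins; xpEHH is $\ln(iHH_{pop1}/iHH_{pop2})$ with pooled (both-allele) EHH
per population, standardised genome-wide. Physical distance substitutes for
genetic distance throughout — no recombination map is assumed.

**DCMS.** Each statistic's window values are converted to one-tailed
empirical p-values $p = r/(n+1)$ with the selection-oriented tails ($\pi$
and Tajima's $D$ lower; $F_{ST}$, $|iHS|$, $|xpEHH|$ upper — the directions
that look like a sweep in the focal population). Then

$$\mathrm{DCMS}_j = \sum_i w_i \ln\frac{1-p_{ij}}{p_{ij}},
\qquad w_i = \frac{1}{\sum_k |r_{ik}|},$$

with $r$ the Pearson correlation matrix of the p-value columns. A
duplicated (perfectly correlated) statistic halves its own weight, leaving
the composite unchanged — the "decorrelated" in the name.

**Significance.** DCMS scores are centred by a Huber M-estimate (tuning
constant 1.345) and scaled by $1.4826\cdot\mathrm{MAD}$ — a robust normal
model that a handful of genuinely selected windows cannot drag along —
converted to upper-tail p-values, BH-adjusted, and windows at $q<0.05$ are
merged (overlap or adjacency) into regions. Regions supported by at least
two overlapping windows form the primary call set.

**Per-locus outliers.** SV $\theta$ and STR $D$ values are fitted to a
normal by maximum likelihood and upper-tailed. This mirrors the
fitdistr-to-q-value lineage deliberately, bounded statistics and all: both
statistics are right-skewed under neutrality, so the normal null is mildly
anticonservative, and the scan prints a skewness/kurtosis diagnostic
instead of silently substituting a different null. On the default synthetic
conditions the neutral flag rate is a fraction of a percent when real
outliers are present (they inflate the fitted scale) and up to about 2% for
the SV track when nothing is planted — worth knowing before interpreting a
handful of marginal calls.

## The synthetic dataset

The generator (`simulate_dataset()`) does not attempt coalescent realism;
it creates exactly the statistical structure the scans consume, at desk
scale, with machine-readable truth.

* **Allele frequencies** follow the Balding–Nichols model: population
  frequencies are Beta-distributed around an ancestral frequency
  ($p_{\text{anc}} \sim U(0.05, 0.95)$) with variance $F\,p(1-p)$;
  the default background $F = 0.02$ represents weak differentiation (the
  emulated study reports no genome-wide value; the knob is exposed).
* **Haplotypes** are mosaics of 30 founder haplotypes per population with
  a switch probability of $10^{-6}$ per bp, so linkage decays over physical
  distance. Site density is calibrated analytically so that population A's
  expected per-bp heterozygosity equals $\theta_{\text{anc}} = 0.0035$:
  the Balding–Nichols draw shrinks per-site heterozygosity by $(1-F)$ and
  mosaic copying by $(1 - 1/n_{\text{founders}})$, and both factors enter
  the calibration. Population B's diversity is scaled to 0.94 of A's by a
  mixture: with probability 0.06 a site is fixed in B (preserving its mean
  frequency, hence leaving $d_{XY}$ untouched). The targets are window
  medians of $\pi_A \approx 0.0035$, $\pi_B \approx 0.0033$,
  $d_{XY} \approx 0.0035$; under this model $d_{XY}$ sits
  $1/((1-F)(1-1/n_f)) \approx 5\%$ above $\pi_A$, within the 10% band the
  recovery checks use.
* **Sweeps**: ten non-overlapping 100 kb regions in which each population-B
  haplotype is replaced by a designated founder with probability 0.8 —
  low $\pi_B$, elevated $F_{ST}$, negative Tajima's $D$ and long-range
  homozygosity in one stroke, with tunable strength (`f_sweep`).
* **Marker loci**: 2,000 SVs (DEL-dominant types, log-uniform lengths
  50 bp–100 kb) and 5,000 STRs (periods 1–6 weighted toward 1–2,
  discretised-Gaussian repeat-count distributions, s.d. 1.5 units, a small
  0.2-unit between-population jitter for neutral loci); 2% of each are
  divergent ($|\Delta p| \ge 0.6$ for SVs, mean shift $\ge 2$ repeat units
  for STRs).
* **Annotation**: genes placed left-to-right with exponential intergenic
  gaps (mean 16 kb, so half the mean gap reproduces the 8 kb proximity
  constant), 2–8 CDS segments each, and every spliced CDS a valid ORF
  written into the random reference on the gene's strand — which is what
  lets the coding-effect classifier run end-to-end on synthetic data.

What the generator does **not** emulate: coalescent linkage structure and
recombination-rate variation, sequencing error and genotype uncertainty,
SV-caller artefacts, STR mutation models, or gene-density correlation with
recombination. Passing recovery tests therefore demonstrates that the
inference machinery detects the signal it defines — not that real data of
this species would yield these precise numbers.

## Numerical choices and degenerate inputs

* EHH decay stops at the 0.05 cutoff (rehh's default), at a gap larger
  than 200 kb (core discarded, mirroring rehh's gap guard), or at 300 kb
  physical extension from the core (curve truncated). The extension cap is
  specific to the mosaic model: a rare pair of haplotypes copying the same
  founder can hold EHH marginally above the cutoff across an entire founder
  segment ($\sim 1/\rho$ bp), which is an artefact of the copying process,
  not selection signal; 300 kb comfortably exceeds the 100 kb sweeps.
  All three are configurable.
* The ancestral allele defaults to the reference allele (recorded as `AA`
  in the synthetic VCF); iHS flips sign if the designation is flipped.
* Windows with fewer than 10% accessible sites are nulled; windows missing
  some statistics are scored on the available ones with the total DCMS
  weight renormalised (and counted in a message).
* A constant statistic column gets zero off-diagonal correlation (with a
  warning) rather than poisoning the weight matrix; identical values give
  empirical p-values of 0.5 with a warning.
* Ties in empirical p-values count all equal values as equally extreme;
  `p = r/(n+1)` keeps p strictly inside (0,1) so the DCMS term is finite.
* Multi-allelic SNP sites are excluded at parse time (biallelic scans
  only); STR records whose allele lengths are not exact multiples of the
  repeat unit are dropped with a warning; SVs with unknown `SVTYPE`
  likewise.
* STR MAF for multi-allelic loci is one minus the frequency of the most
  common allele.
* The permutation null re-places features uniformly on their own
  chromosome, preserving length (overlaps between placed features are
  allowed); the p-value is two-sided with the add-one correction.

## Design choices that were genuinely open

* **Correlation on p-values, not raw statistics**, feeds the DCMS weights —
  the literal reading of the composite as specified; the two differ little
  in practice because the rank transform is monotone.
* **BH for q-values** everywhere; Storey's estimator would change little at
  these effect sizes and adds a tuning parameter.
* **Tajima's D and the window statistics for the composite come from
  population B** (the reduced-diversity population), configurable via
  `tajima_population`.
* **Pooled-allele EHH for xpEHH** (both alleles per population) rather than
  derived-only, the cross-population convention; negative scores mean
  longer homozygosity in population B.
* **Gene distance is measured from the gene span**, not the CDS, matching
  the "distance between protein-coding genes" definition of the 8 kb
  constant; STR positional densities are anchored on CDS starts and ends
  in transcript orientation, both emitted.
* **The hybrid (admixed) population** is available behind
  `include_hybrid = TRUE` — mosaics over the pooled founder panels —
  and is never scanned; it exists to exercise the popmap exclusion path.

## Problem sizes

The default dataset is two 5 Mb chromosomes with 20 diploids per
population (~50,000 segregating sites per chromosome), 2,000 SVs and 5,000
STRs — enough windows (~400) for stable empirical p-values and enough loci
for a meaningful FDR, while a full three-track scan runs in well under a
minute. The recovery checks in the test suite run the complete SNP pipeline
on five independent seeds of these conditions.

## Known limitations

* The normal-fit null for bounded, skewed statistics is anticonservative
  in the upper tail (see above); the diagnostic is printed, not acted on.
* Empirical p-values make DCMS a relative ranking: a genome with *no*
  divergent regions still has windows with small empirical p-values, and
  the robust-normal stage is what keeps those from becoming calls.
* Window $F_{ST}$ is undefined where $d_{XY} = 0$ and the Hudson form is
  sensitive to very low-diversity windows.
* The coding-effect classifier handles single-nucleotide substitutions in
  single-gene context only (first overlapping CDS wins); it is a minimal
  effect caller, not a full annotation engine.
* `load_dataset()` infers chromosome lengths from the FASTA; without a
  reference, lengths fall back to the last SNP position, which shortens
  the final window.
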