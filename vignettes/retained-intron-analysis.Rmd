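---
title: "Quantifying intron retention under stress: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying intron retention under stress: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ripsi)
```

## The problem

Cells under hypoxic stress remodel their transcriptome, and one recurrent
outcome is intron retention (RI): an intron that is normally spliced out
remains in the mature mRNA. A retained intron usually carries an in-frame
stop codon, so retention can convert a full-length protein into a truncated
isoform — or target the transcript for nonsense-mediated decay (NMD). The
motivating example is the translation-initiation factor gene *EIF2B5*: under
hypoxia one of its introns is strongly retained, the retained sequence
spells an in-frame premature termination codon (PTC) embedded in the 5'
splice-site consensus itself, and the product is a ~65 kDa C-terminally
truncated form of eIF2B-epsilon rather than the ~80 kDa full-length protein.

`ripsi` re-implements this analysis chain as a reusable, testable pipeline:

1. quantify percent spliced in (Psi) per condition from junction counts,
   with delta-Psi and a Bayes factor per event;
2. apply detection (read support) and significance filters;
3. annotate the intron-retained transcript for the first in-frame stop, its
   position relative to the retained intron, and NMD susceptibility under
   the 50-nt rule;
4. score 3' splice-site strength with a trainable first-order Markov model
   and extract simple cis features (GC differential, nearest upstream AG,
   motif and alternate-donor scans);
5. run the associated statistical decision procedures.

Because the original raw data are not needed to verify any of this
machinery, the package ships a synthetic-data generator that plants the
reported effect sizes in a toy genome; every stage can then be checked
against known truth.

## The Psi model

For one RI event, a supporting read either bridges the exon–exon junction
(exclusion, spliced isoform) or overlaps the intron (inclusion, retained
isoform). With read length $R$ and a minimum overhang $o$, the numbers of
distinct read-start positions are

$$L_\mathrm{exc} = R - 2o + 1, \qquad
  L_\mathrm{inc} = \ell + R - 2o + 1$$

for an intron of length $\ell$. If a fraction $\psi$ of transcripts retain
the intron, a supporting read comes from the inclusion isoform with
probability

$$w(\psi) = \frac{\psi L_\mathrm{inc}}{\psi L_\mathrm{inc} +
  (1-\psi) L_\mathrm{exc}},$$

and with $I$ inclusion and $E$ exclusion reads the likelihood is
$I \sim \mathrm{Binomial}(I+E,\ w(\psi))$. The posterior under a uniform
prior is evaluated on a 1001-point grid on $[0,1]$; the posterior mean is
the reported Psi. The length-corrected closed form
$\hat\psi = (I/L_\mathrm{inc}) / (I/L_\mathrm{inc} + E/L_\mathrm{exc})$
is reported alongside as a point estimate.

This is deliberately a *simplified two-isoform mixture*, not the full
multi-isoform generative model of exon-centric quantifiers: the downstream
analysis consumes only Psi, delta-Psi and a Bayes factor, and the two-isoform
model is fully specified, fast, and checkable against independent fine-grid
quadrature (the test suite verifies posterior means to $10^{-3}$ and Bayes
factors to 2% against $10^5$-point integration).

Replicates are pooled by summing counts per condition before estimation,
mirroring the original study's merging of replicate alignment files into a
single file per treatment.

## Delta-Psi, Bayes factor, and filters

The Bayes factor compares "independent Psi per condition" against "shared
Psi":

$$\mathrm{BF} = \frac{\int_0^1 L_A(\psi)\,d\psi \int_0^1 L_B(\psi)\,d\psi}
  {\int_0^1 L_A(\psi) L_B(\psi)\,d\psi},$$

with each integral by the trapezoid rule on the grid, in log space for
stability. The construction (grid marginalization under independent uniform
priors) is a design choice: the study states only the thresholds, not the
BF machinery.

Filters:

* **Detection** requires at least 20 pooled supporting reads ($I+E$) — and
  we apply this in *both* conditions, the conservative reading of a filter
  stated per event without condition detail.
* **Significance** requires $|\Delta\Psi| > 0.10$ *strictly* and
  $\mathrm{BF} \ge 20$ *inclusively*. The source reports both "$>$ 20" and
  "$\ge$ 20" for the Bayes factor in different places; we adopt the
  inclusive form. Ties at exactly 0.10 delta-Psi fail, ties at exactly BF 20
  pass.

Direction is summarized as the fraction of significant events with positive
delta-Psi (condition B minus condition A, i.e. hypoxia minus normoxia).
Event-type enrichment compares each category's significant/detected
proportion against the pooled complement of the other categories with a
chi-square test with Yates correction, BH-adjusted across categories;
category-vs-rest is our reading of "comparative enrichment", which the
source does not spell out.

## PTC and NMD annotation

The intron-retained transcript is the spliced transcript with the single
retained intron re-inserted (reverse-complemented handling for minus-strand
genes is exercised by the generator). Scanning codons from the CDS start,
the first triplet in {TAA, TAG, TGA} is the PTC; the scan works on the DNA
alphabet because inputs are genomic FASTA. NMD susceptibility follows the
50-nt rule: a stop more than 50 nt upstream of the *final* remaining
exon–exon junction is susceptible — strictly more, so 51 nt is susceptible
and 50 nt is not. Retention of intron $k$ removes only intron $k$'s
junction by default; the biological read-through of downstream exons is
observational, so callers can optionally name further junctions to drop
(`read_through`), and the distance is then computed against the remaining
junctions only.

A special case drives the designated gene: the 5' splice-site consensus
GURAGU can itself spell a stop. `detect_5ss_stop()` fires exactly when
window positions 2–4 read TAA or TGA *and* the upstream CDS phase is 2 (a
codon boundary falls immediately before position 2); the test suite
enumerates all $4^6 \times 3$ window/phase combinations against this rule.

Truncated-protein mass uses the standard 110 Da mean residue mass; at that
constant a 591-residue truncation of a 727-residue protein is ~65 vs ~80
kDa, matching the gel-based sizes the analysis is anchored to. This is an
estimate, not a prediction of migration.

## Splice-site strength

The 3' splice-site model is a position-specific first-order Markov chain
over a 23-mer window: intron positions −20..−1 (polypyrimidine tract plus
the terminal AG) and exon positions +1..+3. That window convention follows
the maximum-entropy splice-site framework's 3'SS definition; the cited
method family includes both a first-order Markov and a full maximum-entropy
variant, and we implement the first-order Markov reading. Counts are
smoothed with pseudocount $\alpha = 0.5$ per cell, and strength is the
log-odds in bits of the window under a foreground (true site) model versus
a background model trained on user-supplied decoy windows. No human
background tables are hard-coded — the package stays data-free — so
absolute scores depend on the training and decoy sets and are **not**
comparable to published human splice-site scores (the study's printed group
means of 7.6 vs 8.9 depend on unpublished site sets and model tables; the
package reproduces the comparison's *design and power* instead, which the
acceptance suite checks at the published group sizes of 101 vs 252 with a
planted 1.3-bit separation and a 2.5-bit score spread).

Group comparison is normality-gated (below). Simple cis features mirror the
study's observations about the retained intron: GC percentage of the intron
minus the adjacent downstream exon, the distance from the 3'SS AG to the
nearest upstream AG dinucleotide, IUPAC/PWM motif scans, and GTRAG
alternate-donor detection.

## Statistical decision procedures

`normality_gated_compare()` applies Shapiro–Wilk per group at
$\alpha = 0.05$ (the "all groups normal" conjunction; the source does not
state per-group vs pooled testing, and per-group is the common reading),
then a Welch t test or classic one-way ANOVA when normal, otherwise
Mann–Whitney (normal approximation with tie correction) or Kruskal–Wallis.
All tests are two-sided; the source never states sidedness. FDR control is
Benjamini–Hochberg — the source never names its FDR procedure, and BH is the
default of the upstream tools. The gene-level roll-up calls a gene
responsive when at least one transcript has $p < 0.05$ and FDR < 5%, with
direction from the qualifying transcripts' fold-change signs.

## What the generator emulates

`sim_config()` defaults *are* the study conditions: 4+4 replicates, a
designated event with delta-Psi 0.44 on a 0.10 baseline, 90% of responsive
events increasing retention, weakened acceptor windows and a 6-point GC
drop for responsive introns, and a PTC-creating GT(A/G)A donor in the
designated gene. Choices the study leaves open, fixed once here:

* **Designated baseline Psi = 0.10.** Only delta-Psi = 0.44 and a ">40%
  increase" are reported; a low normoxic baseline keeps
  $\psi_B = 0.54$ interior and mirrors the reported low normoxic retention.
* **Depth model.** Supporting reads per event and replicate are negative
  binomial with mean 500 and dispersion $k = 10$ (variance $m + m^2/k$),
  the standard over-dispersed RNA-seq depth model; 500 reads makes planted
  effects clearly detectable, which is the point of a verification dataset.
* **Non-designated effect sizes** are uniform on [0.15, 0.45] so that
  responsive events are detectable above the 0.10 delta-Psi gate at the
  simulated depth.
* **Direction planting.** The up/down split of responsive events is planted
  as an *exact proportion* (`direction_bias`, default 0.90), with the
  assignment of which events go up randomized and the designated event
  always up. Exact-count planting keeps the planted fraction itself from
  drifting several binomial standard errors at small event counts, so a
  recovered fraction can be compared against the parameter directly.
* **Counts, not reads.** The generator emits event-level junction/body
  count tables (the analysis' input contract), not FASTQ/SAM; the
  inclusion count is split into 5' junction, body and 3' junction reads
  multinomially by sub-region effective length.
* **Geometry.** One gene per chromosome, 4 exons of 90–210 nt, introns of
  150–600 nt, read length 100, overhang 8, random strands (minus-strand
  genes exercise the orientation handling end to end; the designated gene
  is kept on plus purely for readability of fixtures).
* **Composition.** Exonic CDS is built from stop-free sense codons (so the
  designated PTC is provably the first in-frame stop); strong acceptor
  tracts are pyrimidine-rich (49% T / 36% C), weak ones are per-base mixed
  toward background composition with probability `weak_ss_mix = 0.5`;
  responsive intron bodies target the downstream exon's realized GC minus
  `gc_shift`.

What the generator does **not** emulate — and hence what green tests do not
show about real data: alignment and mapping artefacts, positional read
bias, isoform complexity beyond the two-isoform mixture, correlated
replicates, NMD feedback on observed counts (retention is simulated at the
transcript level, not post-decay), non-canonical splice sites, and the
seven non-RI alternative-splicing categories (those enter only as count
tables for the enrichment test).

## Numerical choices

* Posterior grid 1001 points; integrals by trapezoid rule in log space
  (log-sum-exp scaling), so extreme Bayes factors may be `Inf` — the
  significance gate only needs $\ge 20$.
* Posterior mass is normalized by direct summation; the equal-tailed 95%
  credible interval is read off the discrete CDF.
* `estimate_psi()` refuses events with $I + E = 0$ (callers filter first);
  the detection filter, not the estimator, owns read-support policy.
* Internal coordinates are 0-based half-open everywhere; GTF I/O converts
  to 1-based inclusive at the boundary, and all sequence windows are in
  transcribed orientation downstream of I/O.
* Seeds: `generate_genome_annotation()` seeds from `config$seed`,
  `simulate_counts()` from `config$seed + 1`, so a truth table can be
  re-counted deterministically without regenerating the genome.

## Problem sizes used in the checks

The self-checks run at desk scale, chosen to keep the full suite in a few
minutes while leaving the statistical conclusions stable: delta-Psi
recovery averages 20 seeds of a 20-gene genome at depth 500; the direction
fraction uses 200 responsive events; null calibration uses 1,000 null
events; oracle equivalences use $10^5$-point quadrature, 500 random
transcripts, exhaustive $4^6 \times 3$ donor-window enumeration, and
exhaustive 4-mer$^5$ normalization at a reduced window of 5; the
splice-site power check runs 100 seeds at group sizes 101 vs 252.

## Known limitations

* The Bayes-factor construction is one reasonable choice; numbers are not
  comparable to those of samplers with different priors or isoform models.
* Splice-site scores are relative to the supplied training/decoy sets.
* NMD classification is rule-based; biological escape from NMD (as reported
  for the hypoxic *EIF2B5* transcript) is not modeled.
* The gene-level roll-up consumes an externally produced transcript table
  (fold change, p, FDR); differential-expression estimation itself is out
  of scope.

## A minimal run

```{r example, eval = FALSE}
cfg <- sim_config(n_genes = 40, fraction_responsive = 0.4, seed = 11)
summary <- run_pipeline(cfg, outdir = "ripsi_demo")
summary$n_significant
summary$direction_fraction
```
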