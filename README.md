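# ripsi

Retained-intron quantification, PTC/NMD annotation, and splice-site feature
analysis for two-condition RNA-seq.

## The problem

Stressed cells — the motivating case is hypoxic tumor cells — shift their
splicing programs, and one of the strongest signatures is **intron
retention (RI)**: introns that are normally excised remain in the mature
mRNA. A retained intron typically introduces an in-frame **premature
termination codon (PTC)**, so the outcome is either degradation by
nonsense-mediated decay (NMD) or translation of a truncated protein. In the
prototype event, retention of an intron in the translation-initiation
factor gene *EIF2B5* rises by ΔΨ = 0.44 under hypoxia, the PTC sits inside
the 5′ splice-site consensus itself (GURAGU, where URA can read UAA or
UGA), and the product is a ~65 kDa truncated eIF2Bε instead of the ~80 kDa
full-length protein.

`ripsi` is for computational biologists who want this analysis chain as
small, tested, reusable pieces rather than a one-off script stack: Psi /
ΔΨ / Bayes-factor quantification from junction-count tables, detection and
significance filters, direction and event-type enrichment summaries,
intron-retained transcript construction with first-stop scanning and the
50-nt NMD rule, a trainable first-order Markov 3′ splice-site strength
model, simple cis-feature extractors, and the study-style statistical
decision procedures. A synthetic-data generator plants all of the effects
above in a toy genome so every stage is verifiable offline.

## The model in brief

For an event with inclusion reads *I* and exclusion reads *E*, effective
lengths L<sub>inc</sub> = ℓ + R − 2o + 1 and L<sub>exc</sub> = R − 2o + 1
(intron length ℓ, read length R, overhang o):

- likelihood: I ~ Binomial(I + E, w(ψ)) with
  w(ψ) = ψ·L<sub>inc</sub> / (ψ·L<sub>inc</sub> + (1 − ψ)·L<sub>exc</sub>);
- posterior over ψ on a 1001-point grid, uniform prior; Ψ = posterior mean;
- Bayes factor = ∫L<sub>A</sub>·∫L<sub>B</sub> / ∫L<sub>A</sub>L<sub>B</sub>
  (independent vs shared ψ, trapezoid rule in log space);
- an event is significant when pooled support ≥ 20 reads in both
  conditions, |ΔΨ| > 0.10, and BF ≥ 20;
- NMD rule: the first in-frame stop is NMD-susceptible when it lies more
  than 50 nt upstream of the last remaining exon–exon junction.

See `vignettes/retained-intron-analysis.Rmd` for the full account,
including every place where the published description left a choice open.

## Worked example

```r
library(ripsi)

cfg <- sim_config(n_genes = 40, fraction_responsive = 0.4, seed = 11)
summary <- run_pipeline(cfg, outdir = "ripsi_demo")
#> [ripsi] simulate: 40 events, 16 responsive
#> [ripsi] quantify: 40 detected, 16 significant
#> [ripsi] annotate-ptc: 16 significant events annotated
#> [ripsi] score-ss: t-test p = 5.84e-07
```

The run writes `genome.fa`, `annotation.gtf`, `truth.tsv`, `counts.tsv`,
`ri_results.tsv`, `significant_ri.bed`, `ptc_annotation.tsv`,
`event_features.tsv`, `ss3_scores.tsv` and `summary.json`. The top of the
results table:

```r
res <- read_tsv_table("ripsi_demo/ri_results.tsv")
head(res[order(-abs(res$delta_psi)), c("event_id", "psi_a", "psi_b",
                                       "delta_psi", "log10_bf", "significant")], 4)
#>       event_id psi_a psi_b delta_psi log10_bf significant
#>    gene001.ri2 0.100 0.532     0.431    201.4        TRUE
#>    gene012.ri1 0.441 0.870     0.429     53.0        TRUE
#>    gene026.ri3 0.303 0.706     0.403     60.7        TRUE
#>    gene034.ri1 0.278 0.644     0.366     59.3        TRUE
```

`gene001.ri2` is the designated EIF2B5-like event: its planted ΔΨ is 0.44
(0.10 normoxia → 0.54 hypoxia) and the pipeline recovers 0.431 with an
overwhelming Bayes factor. Of the 16 significant events, 14 increase
retention under hypoxia (`summary$direction_fraction` = 0.875, the planted
~90% bias at this event count), all 16 intron-retained transcripts carry an
in-frame PTC (`summary$n_ptc`), 10 are NMD-susceptible under the 50-nt rule
(`summary$n_nmd_susceptible`), and the significant events' 3′ splice sites
score significantly weaker than the non-significant ones
(`summary$score_comparison$p_value` = 5.8e-07). The PTC table for the
designated event:

```r
read_tsv_table("ripsi_demo/ptc_annotation.tsv")[1, ]
#>      event_id stop_offset stop_codon in_intron dist_last_junction  nmd aa_len est_kda
#>   gene001.ri2         288        TAA      TRUE                634 TRUE     86     9.5
```

The stop is the retained intron's own 5′-splice-site TAA, in frame because
the upstream CDS phase is 2 — the signature the pipeline is built to
detect.

A thin command-line wrapper is included:

```sh
Rscript inst/scripts/run-ri-pipeline.R --outdir demo --n-genes 40 --seed 11
```

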