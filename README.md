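# regrec — comparative reconstruction of bacterial TF regulons

`regrec` implements the comparative-genomics workflow used to map the
regulon of a bacterial transcription factor from sequence alone, together
with the quantification math used to characterize the factor biochemically.
It was built around the reconstruction of the NagR regulon — the ROK-family
repressor that governs N-acetylglucosamine (GlcNAc) and human-milk
oligosaccharide utilization in bifidobacteria — but every stage is generic.

The workflow:

1. **PWM construction** from a curated alignment of operator sites, with the
   log-count weight convention of the classical bacterial regulon tools:
   `w(b,k) = ln(N(b,k)+0.5) − ¼ Σ_b' ln(N(b',k)+0.5)`, optional palindromic
   symmetrization (operators bound by symmetric dimers), WebLogo-style
   information content, and threshold calibration.
2. **Upstream scanning** of every gene's −500..+50 window (+1 = first base of
   the start codon) on both strands, with opposite-strand dedup of
   palindrome mirror hits and EMSA probe design (operator ± 14 bp flanks).
3. **Cross-genome consistency filtering** (phylogenetic footprinting):
   a candidate operator survives only if orthologs of its gene — found by
   bidirectional-best-hit protein alignment — carry above-threshold sites in
   enough other genomes.
4. **Operon and regulon assembly**: same-strand runs with ≤150 bp gaps form
   transcription units; every unit whose lead gene keeps an operator joins
   the regulon.
5. **Promoter architecture**: σ70 −35/−10 hexamer PWM search with 15–19 bp
   spacers; operators overlapping either element are classified
   repression-consistent.
6. **Quantification**: four-parameter logistic fits
   `y = c + (d−c)/(1+(x/e)^b)` with asymptotes fixed at c = 0, d = 1
   (EC50 `e`, slope `b`) for EMSA titrations; trapezoidal growth-curve AUC;
   Pearson correlation between operator affinity and expression response.
7. A **ground-truthed simulator** of genome clades with planted operators,
   single-genome decoy sites, titration curves and growth curves, used to
   benchmark every stage.

## Worked example

```r
library(regrec)

# a 5-genome clade, 50 genes each, 20-gene planted regulon, 10 decoys
sim <- simulate_clade(seed = 42)

cfg <- pipeline_config(
  genomes         = sim$genomes,
  training_sites  = sim$training_sites[["1"]],
  threshold_rule  = "min_training_site", allowance = 6,
  min_support     = 2, tf_name = "NagR")
res <- run_pipeline(cfg)

res$regulons$sim1
#> <regulon> NagR in sim1: 20 operator(s), 30 gene(s) in 30 TU(s)

setequal(res$regulons$sim1$genes, sim$truth$regulon_tags$sim1)
#> [1] TRUE

fit <- fit_4pl(simulate_titration(e = 0.33, b = 2, noise_sd = 0.03, seed = 1))
fit
#> <fourpl> EC50 = 0.3487 (95% CI 0.3232..0.3762), slope b = 2.145, SSE = 0.003219
```

The regulon object lists, per genome, the operator intervals with scores,
the member transcription units, and the member gene set; 30 genes here are
the 20 planted anchors plus the divergent-promoter partners their shared
intergenic operators also govern. The 4PL fit reads as: at ~0.35 mM
effector, half of the protein–DNA complex is disrupted (truth 0.33, within
the noise of a single simulated titration).

`run_pipeline(..., out_dir = "run/")` additionally writes per-genome site
tables (TSV/BED), `regulon.json`/`regulon.tsv`, a promoter-overlap TSV,
operator-anchored footprint alignments, logo data, the calibrated PWM and a
manifest. A thin CLI wrapping these functions ships in `inst/cli/regrec`
(subcommands `build-pwm`, `scan`, `reconstruct`, `simulate-clade`,
`fit-ec50`, `growth-auc`).

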