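# tmtpeca

Quantitative analysis of multi-batch isobaric (TMT) proteomics cohorts, as
used for mapping archival (FFPE) tumour tissue proteomes — for example
discriminating ovarian carcinoma histotypes (HGSC, CCC, ENOC) from 10-plex
reporter quantification with an E. coli spike-in standard and a pooled
reference channel.

The package implements the full analysis chain and a ground-truthed
synthetic cohort generator that emulates the study structure (10-plex
batches of 9 individuals + 1 pooled reference, spike-in peptides constant
across channels, per-channel affine distortion, mixed
multiplicative/additive noise, decoy and contaminant PSMs), so every stage
is validated end-to-end against known truth without any external download.

## The model in brief

**Calibration.** Reporter values follow a mixed noise model
`x_ps = b_s * signal + a_s + noise`. Per-sample affine parameters `(a_s, b_s)`
are estimated on spike-in peptides observed in all samples — material added
in equal amounts to every channel, so their variation is purely technical —
by minimizing the Jacobian-penalized profile negative log-likelihood of the
arsinh (generalized-log) model:

```
y_ps = arsinh((x_ps - a_s) / b_s) / ln 2
L(a, b) = (N/2) ln(RSS/N) - sum ln h'_s(x_ps),   h'_s(x) = 1/(ln2 b_s sqrt(1 + u^2))
```

The fitted transform is applied to all endogenous peptides; `y` approximates
log2 intensity at high signal and stays finite below background.

**Differential expression (PECA).** Statistics are computed per peptide:
`logFC = mean_A - mean_B`, pooled variance `s_g^2` with `d_g` residual df,
then empirical-Bayes moderation `s~_g^2 = (d0 s0^2 + d_g s_g^2)/(d0 + d_g)`
with the prior `(d0, s0^2)` fitted by method of moments on `ln s_g^2`.
Protein significance comes from the median peptide statistic: with `n`
peptides and sorted p-values, the lower median `p_(k)`, `k = ceil(n/2)`, is
referred to its exact null law, the `Beta(k, n-k+1)` distribution of a
uniform order statistic:

```
p_protein = pbeta(p_(k), k, n - k + 1)
```

followed by Benjamini-Hochberg FDR across proteins.

**Downstream.** Gene-set mean-difference scores and Wilcoxon rank
enrichment (with an exact tie-aware path for small problems), Fisher
over-representation of DE lists (`logFC > 0.5`, `q < 0.05`), per-gene
median-relative expression, PCA and eigenvalue-weighted top variance
contributors, correlation-distance average-linkage clustering, HPA-style
9/6/3/0 IHC block scores, duplicate-core TMA aggregation (disagreeing cores
score 1 = variable) and Mann-Whitney comparisons.

## Worked example

```r
library(tmtpeca)

design <- generate_design(2, 9, c("HGSC", "CCC", "ENOC"), seed = 1123)
truth  <- generate_truth(1500, de_fraction = 0.15, effect_size = 1.5,
                         n_spike_proteins = 50, seed = 1123)
psm    <- simulate_psm_table(truth, design, seed = 1123)

pm     <- collapse_to_peptides(filter_psms(psm, q_max = 0.05), design)
parts  <- split_spike(pm, "ECOLI")
model  <- fit_stabilizer(parts$anchor)
glog   <- apply_stabilizer(parts$endogenous, model)

de  <- differential_analysis(glog, design, "HGSC", "CCC")
head(de$protein_results[order(de$protein_results$p_peca), ], 3)
```

On this cohort the run prints (abridged):

```
       protein n_peptides logfc_median   t_median        p_peca          q_bh direction
1257 PROT01257         30    -1.436431 -11.616576 1.396570e-168 2.094855e-165        -1
1338 PROT01338         21     1.533190  12.457822 1.936757e-132 1.452568e-129         1
343  PROT00343         30    -1.182716  -8.517765 2.657035e-123 1.328518e-120        -1
```

i.e. the planted +/-1.5 log2 histotype effects are recovered with accurate
effect sizes and very small PECA p-values, while null proteins stay
non-significant. The numbered scripts under `analysis/` walk the same cohort
through every stage (simulation and filtering funnel, calibration,
differential expression and replicate fold-change correlation, gene-set
enrichment, PCA/clustering, IHC/TMA scoring), writing their tables under
`results/`:

```sh
Rscript analysis/01_simulate_cohort.R
Rscript analysis/02_calibrate_normalize.R   # ... through 06
```

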