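# adaptcall

Adaptive cluster-number genotype calling for two-channel SNP
microarrays.

## What problem this solves, and for whom

Two-channel genotyping arrays (e.g. Illumina Infinium-style BeadChips)
measure a fluorescence intensity pair per SNP per sample: X for allele A
and Y for allele B. On the log-ratio scale

    M = log2(X*) − log2(Y*),    S = ½·(log2(X*) + log2(Y*))

the diploid genotypes AA, AB, BB form up to three clusters along M. For
SNPs with a low minor allele frequency, some genotype classes are simply
absent from a finite cohort, and callers that always fit three clusters
misplace the missing ones. `adaptcall` is for analysts calling genotypes
from raw intensity exports (GenomeStudio-style final reports or plain
matrices) who need sensible calls on low-frequency content. It:

1. quantile-normalizes each channel between samples (optional per-cluster
   loess correction of intensity-dependent curvature);
2. predicts the number of clusters k ∈ {1,2,3} per SNP by logistic
   regression on eight cluster-quality features — residual sums of
   squares R_k, Mahalanobis distances D_k of the fitted centers to
   consensus cluster positions (x_k − μ)ᵀV⁻¹(x_k − μ), and
   Hardy–Weinberg goodness-of-fit statistics
   H_k = Σ_l (N_l − n·r_l)²/(n·r_l) with r = (p², 2p(1−p), (1−p)²);
3. calls genotypes by **exact** one-dimensional k-means (dynamic
   programming over contiguous partitions — deterministic, globally
   optimal) at the predicted k, mapping clusters to AA/AB/BB via the
   consensus centers;
4. scores every call with its silhouette width SW = (b−w)/max(w,b);
5. imputes sample sex from chromosome-Y average signal and calls X/Y
   SNPs with sex-restricted k (no chrY calls in females, no
   heterozygotes in hemizygous males);
6. ships a full synthetic-intensity simulator with known truth, so the
   entire pipeline is testable without array data.

## Worked example

```r
library(adaptcall)

sim  <- simulate_dataset(sim_config(n_snps = 1000, n_samples = 150, seed = 42))
sig  <- normalize_intensities(sim$dataset)          # quantile + M/S transform
cons <- estimate_consensus(sig$M, seed = 1)
cons
#> ConsensusModel (1000 SNPs)
#>   mu (AA, AB, BB): 2.023, 0.04384, -1.917

feats <- t(vapply(seq_len(1000),
                  function(i) compute_features(sig$M[i, ], cons),
                  numeric(8)))
pred <- train_k_predictor(feats[1:500, ], sim$truth$true_k[1:500], seed = 1)
calls <- call_genotypes(sig, cons, pred)
calls
#> GenotypeCalls: 1000 SNPs x 150 samples
#>   NC:0  AA:80225  AB:54293  BB:15482
#>   predicted k: 2:128  3:872

concordance_curve(calls, sim$truth$genotypes)$overall
#>   rate n_compared  accuracy
#> 1 0.00     150000 0.9312133
#> 2 0.01     148500 0.9349630
#> 3 0.02     147000 0.9375238
#> 4 0.05     142500 0.9435439
```

Reading: the consensus centers sit near the generative values (2, 0, −2);
128 SNPs realized only two genotype classes and were correctly fitted
with k = 2; concordance with the simulation truth rises as the
lowest-silhouette calls are dropped. The ~93% plateau at these noise
settings is a quantified property of k-means on imbalanced clusters, not
a bug — see the "known limitation" section of
`vignettes/methods.Rmd`.

## Command line

```sh
Rscript exec/adaptcall simulate --out-dir work --n-snps 2000 --n-samples 150 --seed 7
Rscript exec/adaptcall train    --x work/X.tsv --y work/Y.tsv --annot work/annotation.tsv \
                                --labels work/truth_k.tsv --out-predictor work/pred.txt --seed 7
Rscript exec/adaptcall call     --x work/X.tsv --y work/Y.tsv --annot work/annotation.tsv \
                                --predictor work/pred.txt --out work/calls.tsv --seed 7
Rscript exec/adaptcall evaluate --calls work/calls.tsv --truth work/truth_genotypes.tsv \
                                --out-dir work/eval
```

GenomeStudio-style final reports are read with
`--report report.txt --dialect tab` (or `csv`) instead of the matrix
trio; column names are configurable in `read_genomestudio_report()`.

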