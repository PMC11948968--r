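# loquaTE

Long-read-assisted, locus-specific quantification of transposable element
(TE) expression from short-read RNA-seq.

## The problem

Roughly half the human genome consists of TEs whose copies group into
subfamilies sharing a consensus sequence. Copies of young subfamilies are
nearly identical, so a 76-bp read fragment from one copy aligns equally
well to many copies, and locus-level expression estimates from short reads
alone are unreliable exactly where they are most interesting (young,
epigenetically de-repressed elements). Long-read RNA-seq resolves these
loci easily but is rarely sequenced deeply enough to quantify on its own.

`loquaTE` combines the two: short-read fragments carry the depth, and a
per-locus TPM table from a matched long-read sample enters the
fragment-reassignment mixture model as a prior. It is aimed at
transcriptomics researchers who have locus-level TE annotations
(RepeatMasker-style GTF), short-read alignments (BAM/SAM), and a
featureCounts-style long-read count table.

## The model

Fragments are assigned to annotated TE loci `t_1 … t_K`. Each fragment `a`
has candidate loci with alignment-evidence weights
`q_{a,i} = exp(λ (AS_{a,i} − max_i AS_{a,i}))` and a multi-mapping
indicator `y_a` (1 when it has two or more candidates). Two simplex
parameters are estimated by EM, as in Bayesian fragment-reassignment
models: `π_i`, the proportion of fragments originating from locus `i`, and
`θ_i`, the reassignment proportion for multi-mapped fragments.

- **E-step** — posterior assignment weights
  `E[t_i^{s_a}] ∝ q_{a,i} · π_i · θ_i^{y_a}`, normalized per fragment.
- **M-step (MAP)** — the long-read prior enters here. With `t_i^L` the
  long-read TPM of locus `i` and
  `t_i^{Lf} = t_i^L / Σ_{j ∈ subT(i)} t_j^L` its subfamily-normalized
  fraction, weight `w` (`long_read_weight`), `T = Σ_i Σ_a E[t_i^{s_a}]`
  and `M = Σ_a y_a`:

  ```
  π̂_i = (Σ_a E[t_i^{s_a}]      + (w·T)·t_i^Lf) / (T + (w·T)·Σ_i t_i^Lf)
  θ̂_i = (Σ_a E[t_i^{s_a}]·y_a + (w·M)·t_i^Lf) / (M + (w·M)·Σ_i t_i^Lf)
  ```

Iteration stops when the largest change across `π` and `θ` falls below
`ε = 0.001`. Converged posteriors become counts under a reassignment mode;
the default `long_read` mode assigns each fragment to its best posterior
locus and splits exactly tied fragments across the tied set in proportion
to raw long-read TPM. A `rescue_short` constant (e.g. `1e-50`) can replace
zero long-read TPM so loci seen only by short reads are not forced to
zero. TPM is reported against the TE total or a coding-gene library size.

The package also ships a self-contained simulator (`sim_config()`,
`simulate_bundle()`): a toy genome of TE subfamilies with controlled
within-subfamily divergence, a sparse ground-truth expression profile,
paired-end fragments, a string-matching aligner that writes ordinary SAM,
and a matched long-read table derived from the truth — everything needed
to exercise the full pipeline without external aligners or downloads.

## Worked example

```r
library(loquaTE)

cfg <- sim_config(seed = 42)                    # 2 subfamilies x 5 copies
b   <- simulate_bundle(cfg, "demo_bundle")      # writes GTF/SAM/TSV/FASTQ
res <- quantify_te(bam      = b$paths[["sam"]],
                   gtf      = b$paths[["gtf"]],
                   longread = b$paths[["longread"]],
                   seed     = 1)
#> annotation: 10 loci, 2 subfamilies
#> prior: 8 loci with long-read support
#> fragments: 5000 (5000 multi-mapped)
#> EM: 5 iterations, converged (max delta 0.00026)
#> report: 7 loci with nonzero counts

head(res$report[, c("locus_id", "final_count", "tpm")], 5)
#>     locus_id final_count    tpm
#> 1  SF1_copy1         670 134000
#> 2  SF1_copy2         100  20000
#> 3  SF1_copy3           0      0
#> 4  SF1_copy4         780 156000
#> 5  SF1_copy5         556 111200

est <- setNames(res$report$tpm, res$report$locus_id)
evaluate_confusion(est, b$truth$truth_tpm[names(est)])
#> te_confusion (n = 10): TP 7 TN 2 FP 0 FN 1 | precision 1.000 recall 0.875 F1 0.933
```

Every fragment here is multi-mapped (copies within a subfamily are 96–100%
identical over a fragment window), yet the prior-weighted EM calls no
silent locus expressed (precision 1.000) and recovers 7 of 8 expressed
copies. The two `SF2` copies with `em_count ~ 1e-57` show the prior at
work: their long-read TPM is zero, so their posterior mass collapses;
`rescue_short` exists for the opposite situation, when the long-read
sample is too shallow to trust its zeros.

A thin command-line wrapper is installed at
`inst/cli/loquate` (`loquate quantify …`, `loquate simulate …`).

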