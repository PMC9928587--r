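# gpvae: interpretable gene-program VAEs for single-cell RNA-seq

`gpvae` is an R package for analysts who want the batch integration and
reference mapping of conditional variational autoencoders *without giving up
interpretability*. Every latent dimension of the model is wired to a gene
program (GP) — a curated pathway or marker set — through a masked linear
decoder, so a cell's latent coordinates are directly readable as program
activity scores, and downstream questions ("which programs differ between
stimulated and control cells?") are answered in the latent space itself.

## The model

For cell *i* with raw counts `X_i`, one-hot batch label `C_i` and library
size `S_i`:

```
X_i | Z_i  ~  NB( softmax([Z_i, C_i] [W, L]^T) * S_i ,  C_i D )
Z_i        ~  N(0, I),   approximated by  q(Z_i | X_i, C_i)  (encoder)
```

* `W` (genes × programs) is masked by the binary membership matrix `B` from a
  GMT file: **hard** membership pins non-member weights to exactly zero;
  **soft** membership penalizes them through the mask complement `M = 1 − B`
  so programs can recruit genes missing from their annotation.
* Training is **proximal stochastic gradient descent**: after each SGD step
  on `W`, closed-form proximal operators apply a column-wise group lasso
  `α Σ_j ||W_:,j||₂` — which switches redundant programs off *exactly* (whole
  columns become zero) — and the soft-membership L1 `γ Σ_j ||W_:,j ⊙ M_:,j||₁`.
* A trained reference can be **extended** with new batches and new program
  nodes (constrained to a gene set, or unconstrained, L1-sparse and
  HSIC-decorrelated from existing dimensions) and fine-tuned on query data
  only, with all reference weights frozen bit-exactly.
* Differential program activity between cell groups is scored with a
  **log-Bayes factor**: `p(H0: Z_a > Z_b)` averaged over random cell pairs
  using the closed-form Gaussian exceedance probability
  `Φ((μ₁−μ₂)/√(σ₁²+σ₂²))`, with `|log K| ≥ 2.3` flagging enrichment.

## Worked example

Simulate counts with known program structure (10 signal programs, 10 decoy
programs, 2 batches, one program shifted by +2 SD in group "a"), fit the
model, and test:

```r
library(gpvae)

sim  <- simulate_gp_counts(seed = 1, group_effect = list(program = 1, shift = 2))
mask <- build_gp_mask(sim$gene_sets, sim$gene_names, soft = TRUE)
fit  <- gpvae(sim$counts, sim$conditions, mask, seed = 1)   # ~7 min, 1 CPU
fit
#> Gene-program conditional VAE (500 genes, 20 programs, 2 conditions)
#>   link: softmax | alpha_kl: 0.5 | group lasso alpha: 0.7
#>   epochs run: 400 | final loss: 1384.12
#>   deactivated programs: 10 of 20

deactivated_gps(fit)          # the exactly-zero columns: all 10 decoys
#>  [1] "prog_null_01" "prog_null_02" "prog_null_03" "prog_null_04" "prog_null_05"
#>  [6] "prog_null_06" "prog_null_07" "prog_null_08" "prog_null_09" "prog_null_10"

res <- rank_gps(fit, sim$counts, sim$conditions, sim$truth$group, seed = 1)
head(as.data.frame(res), 3)
#>          program log_bayes_factor      p_h0 direction enriched n_cells_a n_cells_b
#> 1 prog_active_01        2.5280939 0.9260880        -1     TRUE      1025       975
#> 2 prog_active_08       -0.1197337 0.4701023         1    FALSE      1025       975
#> 3 prog_active_05        0.1102248 0.5275283        -1    FALSE      1025       975
```

All 20 true programs are classified correctly in this run — the 10 decoys
are switched off exactly, all 10 signal programs retained — and the planted
group-effect program tops the ranking with `log K = 2.53 ≥ 2.3` (the sign of
a latent score is arbitrary; `gp_direction()` / directed scores resolve it).

Map a query batch carrying a novel 20-gene program absent from the
reference annotation:

```r
qsim <- simulate_query_counts(sim, n_cells = 1000, condition = "query1",
                              planted_query_program = list(n_genes = 20, shift = 2,
                                                           fraction = 0.5),
                              seed = 4)
ext    <- extend_gpvae(fit, new_conditions = "query1", n_new_unconstrained = 10)
mapped <- map_query(ext, qsim$counts, qsim$conditions)   # reference frozen
mapped
#> Gene-program conditional VAE (500 genes, 30 programs, 3 conditions)
#>   link: softmax | alpha_kl: 0.5 | group lasso alpha: 0.7
#>   epochs run: 148 | final loss: 1391.86
#>   deactivated programs: 10 of 30
#>   query-mapped model: 20 reference + 10 new programs
```

Early stopping halted the query fine-tuning after 148 of the 200 budgeted
epochs. One of the new unconstrained nodes separates the perturbed query
cells from the rest (AUC 0.993 against the planted labels in this run),
while the frozen reference latent space is bit-identical —
`frozen_checksum()` before and after mapping agrees.

A thin command-line interface wraps the same functions
(`inst/cli/gpvae simulate | train-reference | map-query | test-gps |
importance | latent`).

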