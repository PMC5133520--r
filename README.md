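# rvpredict

Benchmarking classifiers that predict a binary disease phenotype from
baseline covariates, per-gene rare-variant burden, and gene expression —
in the *replicated-phenotype* setting of family-based sequencing resources:
one fixed genotype matrix and many independent simulated disease calls per
individual, with known causal genes.

The package provides, as separately usable stages:

* a seeded **synthetic cohort generator** (pedigree gene-drop genotypes,
  expression optionally coupled to rare-allele carriage, covariates, and
  `R` independent phenotype replicates from one logistic disease model),
  plus plain-TSV readers/writers so real data can be substituted;
* **phenotype collapsing** of `m` replicates into a *specific* status
  (case iff hypertensive in at least half the replicates,
  `l/m >= 0.5`) or a *sensitive* status (case iff ever hypertensive,
  `l/m > 0`);
* **feature construction**: CMC-style burden indicator `S` (carrier of any
  minor allele at any variant of the gene with in-sample MAF < 5%),
  expression `G`, interaction `G·S`, and Uniform(−k, k) expression-noise
  perturbation of the selection data;
* **gene selection** by the joint likelihood-ratio test of
  `G + S + G·S` in the logistic model
  `logit P(Y=1) = Age + Sex + Smoke + Age×Sex + Pedigree + G + S + G·S`,
  ranking genes by p-value;
* three **probabilistic classifiers** — logistic regression, linear-kernel
  and radial-kernel SVMs (seeded stratified 10-fold CV tuning, Platt
  probability calibration) — scored by the Wilcoxon–Mann–Whitney **AUC**
  against held-out phenotype replicates;
* a factorial **evaluation grid** (gene lists × expression noise ×
  classification replicates × collapse depths; 315 cells by default), an
  OLS **meta-regression** of AUC on the grid factors, and two follow-up
  analyses (models without expression terms; sensitive vs specific
  phenotype).

## Worked example

```r
library(rvpredict)

cohort <- simulate_cohort(simulation_config(seed = 11))
cohort
#> <cohort> 637 individuals, 976 variants in 100 genes, 153 replicates
#>   pedigrees: 20; causal genes: 10

# collapse the first 150 replicates into the specific (majority) status
phen <- collapse_phenotype(cohort, "specific", m = 5,
                           replicate_ids = paste0("SIMPHEN.", 1:150))

# rank all genes with the joint expression-by-burden LRT
res <- test_genes(cohort, phen)
head(res[order(res$p_value), ], 3)
#>    gene_id      p_value df converged is_causal
#> 9  GENE009 1.074757e-06  3      TRUE      TRUE
#> 67 GENE067 1.580838e-06  3      TRUE      TRUE
#> 16 GENE016 8.739050e-05  3      TRUE      TRUE

# train on the selection data, score a held-out replicate
genes <- select_top_genes(res, "causal", 10)$gene_ids
design <- build_design(cohort, genes)
model <- fit_classifier(design, phen, classifier_spec("logistic"))
truth <- cohort$phenotype_replicates[, "SIMPHEN.153"]
compute_auc(predict_scores(model, design), truth)
#> [1] 0.882

# covariates-only baseline for comparison
base <- build_design(cohort)
base_model <- fit_classifier(base, phen, classifier_spec("logistic"))
compute_auc(predict_scores(base_model, base), truth)
#> [1] 0.583
```

The ten-causal-gene model lifts the held-out AUC from 0.58 (covariates
only) to 0.88 on this cohort — the causal burden and expression terms carry
real predictive signal beyond age, sex, smoking and pedigree.

The full factorial benchmark and the meta-regression of AUC on the design
factors:

```r
spec <- grid_spec(seed = 1)
cells <- run_grid(cohort, spec)   # 315 cells; ~10 min on one core
summarize_grid(cells)             # per-method AUC summary + win fractions
meta_regress(cells)               # AUC ~ n_causal + n_noncausal + k + m
```

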