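# kernelmix

Multiple kernel learning (MKL) for integrating clinical and omics data into
a single binary classifier — and, just as importantly, for *ranking* the
data sources, bandwidths, or gene sets that drive the prediction.

## The problem and who this is for

Prognostic modelling studies increasingly have several data sources per
patient: a handful of clinical variables (stage, age), a high-dimensional
expression profile, pathway annotations. Kernel methods put all of them on
one footing — each source becomes an *n × n* similarity (Gram) matrix — and
multiple kernel learning fits a soft-margin SVM on a learned convex
combination of candidate kernels,

```
K(η) = Σₘ ηₘ Kₘ,   ηₘ ≥ 0,  Σₘ ηₘ = 1,
```

so the weights ηₘ say how much each candidate contributes. The package is
aimed at biostatisticians who want this whole workflow in R: kernel
construction (including nominal/ordinal clinical kernels and per-gene-set
kernels from GMT files), an SVM core with stratified cross-validation,
three MKL solvers, screening of candidate kernels against the
no-information rate (NIR), survival dichotomization, and synthetic
generators for benchmarking.

The three solvers:

* `semkl_fit()` — closed-form weight updates (Cauchy–Schwarz), one SVM
  solve per iteration;
* `simplemkl_fit()` — reduced-gradient descent on the simplex with line
  search;
* `dalmkl_fit()` — a sparse solver (hinge or logistic loss) minimizing the
  dual augmented Lagrangian of a proximal formulation; inactive kernels are
  driven to *exactly* zero, and `estimate_wrapper_cost()` maps its solution
  to a comparable wrapper-method cost.

## Worked example

Simulate a two-source study (160 patients; stage and age acting on a binary
prognosis through a logistic link; 8 of 200 genes shifted between prognosis
groups), then run the full pipeline: split 70/30, rank genes on the training
rows, screen four candidate kernels against the NIR, fit SEMKL on the
survivors, evaluate held out.

```r
library(kernelmix)

d <- gen_multiomics(omics_sim_config(n = 160, p = 200, seed = 9))
dat <- list(tables = list(expression = as.data.frame(d$expression),
                          clinical   = d$clinical),
            labels = d$outcome)

res <- run_workflow(list(
  method = "semkl", seed = 42, top_features = 20, out_dir = "run1",
  kernels = list(
    list(kind = "linear",                            source = "expression"),
    list(kind = "radial", sigma = 0.01,              source = "expression"),
    list(kind = "clinical_ordinal", range = 3,
         features = "stage",                         source = "clinical"),
    list(kind = "radial", sigma = 0.5,
         features = "age",                           source = "clinical"))),
  data = dat)

res$screen
#>                      candidate best_C    cv_acc survived       nir
#>                         linear    0.1 0.8125000     TRUE 0.5089286
#>             radial(sigma=0.01)  100.0 0.8392857     TRUE 0.5089286
#>       ordinal(r=3)[1 features]    0.1 0.5892857     TRUE 0.5089286
#>  radial(sigma=0.5)[1 features]    1.0 0.5714286     TRUE 0.5089286

res$metrics$test_accuracy
#> [1] 0.6875
```

Every candidate beat the NIR (0.509) in 10-fold CV, so all four enter the
MKL fit. The learned weights (`run1/weights.csv`) are the kernel importance
scores:

```
"kernel","weight"
"linear",0.438054
"radial(sigma=0.01)",0
"ordinal(r=3)[1 features]",0.240268
"radial(sigma=0.5)[1 features]",0.321678
```

The linear expression kernel carries the largest weight, the two clinical
kernels contribute the rest, and the near-duplicate radial expression
kernel is zeroed — weights on redundant kernels are diluted or dropped
while predictions are unaffected. Held-out accuracy is 0.69 against a 0.51
baseline; with both sources the fit beats either source alone (the test
suite asserts this over 20 seeds). `run1/` also contains `model.json`,
`metrics.json`, `screening.csv`, a `log.txt` recording the label encoding,
NIR, eliminations and final weights, and a `manifest.yml` from which the
run can be reproduced exactly.

A command-line shim over the same functions ships in `inst/cli/mkl`
(subcommands: `simulate benchmark`, `simulate omics`, `kernels compute`,
`svm cv`, `mkl fit`, `pipeline run`).

## Method details

See the methods vignette (`vignettes/mkl-methods.Rmd`) for the models, the
solver internals and stopping rules, every tunable parameter with its
default and rationale, what the synthetic generators do and do not emulate,
and known limitations.
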