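# ploidyml

Classification-guided optimization of in vitro tetraploid induction.

Inducing polyploidy with an antimitotic agent such as oryzalin is a
routine step in plant breeding: tetraploids are often more vigorous and
larger-organed than their diploid progenitors, while chimeric mixoploids
are unstable and unwanted. The two protocol knobs are oryzalin
concentration *C* (µM) and exposure time *t* (h), and the outcome of a
treated explant is one of three classes — diploid (no conversion),
mixoploid (partial conversion), or tetraploid. Exhaustively testing the
dose × time factorial in tissue culture is slow and expensive, and the
best combination may fall between tested treatments. `ploidyml`
implements the data-driven alternative: learn the class structure from a
modest treatment–outcome table, then search the continuous treatment
rectangle for the condition that maximizes tetraploid induction.

The package is aimed at plant biotechnologists and method developers who
want a fully reproducible, dependency-light reference implementation of
this pipeline, including a calibrated synthetic-data generator so every
stage can be exercised and tested without laboratory data.

## What is inside

* **Synthetic data.** A generative dose–response model over the
  26-treatment design (10 concentrations 0–100 µM, exposures 10–36 h,
  4 replicates × 4 explants). Diploid escape follows a decreasing
  logistic in a latent score β₀ + β₁·log(1+C) + β₂·t + β₃·log(1+C)·t;
  among converted explants the tetraploid fraction is a unimodal
  exponential-power bump in (log C, t) centred at (33 µM, 18 h),
  multiplied by a completed-doubling saturation factor 1 − exp(−(t/τ(C))⁴)
  whose scale τ grows with dose — short pulses at high dose leave
  chimeras. Mixoploid takes the remainder.
* **Classifiers**, written from scratch with exact decision rules:
  * Probabilistic neural network (PNN): pattern layer
    f(x, xᵢ) = exp(−‖x−xᵢ‖² / 2σ²), per-class summation
    Sⱼ = Σᵢ∈ⱼ f(x, xᵢ), output posterior P(Cⱼ|x) = Sⱼ / Σₖ Sₖ; σ chosen
    by leave-one-out accuracy.
  * Soft-margin SVC with RBF kernel K(xᵢ,x) = exp(−γ‖x−xᵢ‖²), one-vs-one,
    each binary dual solved by a deterministic SMO; prediction by
    majority vote of f(x) = sign(Σ aᵢyᵢK(xᵢ,x) + b).
  * k-nearest neighbours under cosine distance 1 − u·v/(‖u‖‖v‖), with a
    positive-orthant offset on standardized features; k chosen by
    leave-one-out accuracy.
* **Evaluation**: confusion matrices in a fixed class order and the five
  headline criteria — accuracy (%), error rate (%), macro one-vs-rest
  precision and recall, and F1 as the harmonic mean of the two macro
  averages.
* **Optimizer**: a real-coded genetic algorithm (population 200, 1000
  generations, rank-scaled stochastic universal sampling, scattered
  crossover, adaptive feasible mutation, 5% elitism) maximizing the
  PNN's tetraploid posterior over the treatment rectangle
  [0, 100] µM × [0, 36] h.
* **Pipeline**: `run_pipeline()` chains simulate → balance → PCA outlier
  screen → stratified split (57/15) → standardize → train/evaluate all
  three classifiers → rank → optimize, persisting every artifact (CSV,
  JSON) with full seed control. A thin command-line wrapper lives in
  `inst/scripts/run_pipeline.R`.

## Worked example

```r
library(ploidyml)

class_probabilities(33, 18)
#>          diploid  mixoploid tetraploid
#> [1,] 0.001542345 0.04600546  0.9524522

cfg <- pipeline_config(seed = 1)
report <- run_pipeline(cfg)
print(report)
#> <run_report> dataset n = 72 | train 57 / test 15
#>   outliers removed: 0
#>   hyperparameters: sigma = 0.35 , k = 5 , C = 1 , gamma = 0.5
#>   model phase accuracy error_rate precision   recall       f1
#> 1   pnn train  75.4386    24.5614  0.786648 0.754386 0.770179
#> 2   pnn  test  80.0000    20.0000  0.833333 0.800000 0.816327
#> 3   knn train  71.9298    28.0702  0.775107 0.719298 0.746161
#> 4   knn  test  60.0000    40.0000  0.612698 0.600000 0.606283
#> 5   svc train  73.6842    26.3158  0.773946 0.736842 0.754939
#> 6   svc  test  73.3333    26.6667  0.771429 0.733333 0.751899
#>   ranking: pnn > svc > knn
#> <ga_result> best fitness 0.915113 after 1000 generations
#>   optimum: concentration_uM = 67.79, exposure_h = 36.00
```

Reading the output: the balanced 72-row dataset (24 per class) splits
into 57 training and 15 testing instances, so accuracies are exact
multiples of 1/57 and 1/15 (80% = 12/15). On this draw the PNN ranks
first on held-out accuracy and feeds the optimizer; the winner is
data-dependent and other seeds can rank differently. The genetic
algorithm returns the treatment maximizing the PNN's tetraploid
posterior; note that at this sample size the fitted posterior surface
peaks at longer exposures than the generative optimum at (33 µM, 18 h) —
the methods vignette discusses why, and what that implies for
classifier-coupled optimization generally.

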