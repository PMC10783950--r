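# segentropy

Bayesian evaluation of 2-D single-cell segmentation quality for multiplexed
tissue imaging (IMC, MIBI, CODEX, CycIF), using only the cell-by-marker
expression matrix the segmentation produced and a user-supplied prior belief
about cell-type marker profiles — no masks or images required.

## The problem and who this is for

Segmentation errors — partially captured cells, one cell split into two
masks, neighbouring cells merged into one — corrupt every downstream
single-cell analysis, and spotting them normally means a pathologist
inspecting images mask by mask. `segentropy` is for analysts running
multiplexed-imaging pipelines who want a quantitative, biologically informed
quality score per image: cleanly segmented cells should look like *one* cell
type, so the degree of cell-type *mixing* needed to explain each cell's
expression measures segmentation quality.

## The model

For an image with `I` segmented cells and `J` markers, observed intensities
`Y = (y_ij)`, and a user prior `P = (p_kj)` giving the expected relative
intensity of marker `j` in cell type `k` (`K` types):

```
mu_kj  ~ Normal(p_kj, precision tau0)
tau_j  ~ Gamma(alpha0, rate beta0)
rho_i  ~ Dirichlet(kappa * 1_K)            kappa = 0.1
y_ij | mu, tau, rho  ~  Normal( sum_k rho_ik * mu_kj , precision tau_j )
```

All Normals are parameterized by mean and precision. `rho_i` is cell `i`'s
vector of fractional contributions from the `K` type profiles; the sparse
Dirichlet prior (`kappa = 0.1`) encodes the assumption that masks are mostly
correct. The model is fitted by Metropolis-within-Gibbs MCMC (default
10 000 sweeps, first half discarded as burn-in), and each cell is scored by
the Shannon entropy of the posterior mean of `rho_i`:

```
H_i = - sum_k  rho_hat_ik * log rho_hat_ik        (0 <= H_i <= log K)
```

The **average entropy** over the image is the scalar quality score: near 0
for clean segmentation, higher when masks mix cell types. The package also
ships the forward simulator and the partial/split/merge error injectors used
to validate the method, so everything is testable without imaging data.

## Worked example

Simulate a 300-cell image from the generative model, corrupt a copy by
merging 25% of the cells, and score both:

```r
library(segentropy)

cfg <- sim_config(n_cells = 300, n_markers = 13, n_types = 4, seed = 17)
ds  <- simulate_well(cfg)
set.seed(17)
err <- inject_merge(ds, fraction = 0.25)

fit_well <- segfit(ds$expr,  ds$truth_prior,
                   seg_control(n_iterations = 2000, seed = 17))
fit_err  <- segfit(err$expr, err$truth_prior,
                   seg_control(n_iterations = 2000, seed = 18))
fit_well
#> Segmentation-quality model fit
#>   300 cells x 13 markers, K = 4 cell types
#>   2000 MCMC sweeps (conjugate mode), burn-in fraction 0.50
#>   average entropy: 0.2955 nats (max log K = 1.3863)
fit_err
#> Segmentation-quality model fit
#>   263 cells x 13 markers, K = 4 cell types
#>   2000 MCMC sweeps (conjugate mode), burn-in fraction 0.50
#>   average entropy: 0.3594 nats (max log K = 1.3863)

percent_increase(fit_err$entropy$average_entropy,
                 fit_well$entropy$average_entropy)
#> [1] 21.6
```

The merged image needs visibly more cell-type mixing to explain its cells:
its average entropy is 21.6% higher than the clean fit's. Note the merge
consumed 75 cells into 37 merged masks, so the corrupted image has 263
cells — error injection changes intensities *and* the total cell count,
exactly as real segmentation errors do. `summary(fit_well)` adds per-cell
entropy quantiles, the Metropolis acceptance rate and the posterior marker
precisions; `coef(fit, "rho")` returns the per-cell contribution matrix,
and `plot(fit)` shows convergence traces.

A command-line interface with `fit`, `evaluate`, `simulate`, `study` and
`compare` subcommands is available through `seg_main()` (see
`inst/scripts/segentropy`); every run writes a manifest with its seed,
configuration and input digests.

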