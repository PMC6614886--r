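# admixpaint

Fine-scale local ancestry inference for admixed genomes, **without assuming
that any reference panel is a direct surrogate for the mixing groups**.

When populations mix, recombination breaks the contributed chromosomes into
ancestry tracts whose lengths shrink with every generation (approximately
exponential with rate `g − 1` per Morgan after `g` generations). admixpaint
reconstructs those tracts from phased SNP haplotypes with a two-layer
haplotype-copying hidden Markov model: at every point of an even
genetic-distance grid (60 gridpoints/cM), the hidden state is the pair
*(latent ancestry `a`, donor haplotype `h` in panel `p`)*. The transition
kernel between successive gridpoints, for target individual `n`, is

```
a != b                : Pi[b,a](n) * mu[p,a]/N_p
a == b, h_p != h_q    : ((1 - Pi[a,.](n)) * rho + Pi[a,a](n)) * mu[p,a]/N_p
a == b, h_p == h_q    : the line above + (1 - Pi[a,.](n)) * (1 - rho)
```

and a copied marker is emitted with miscopy probability `theta`. The copying
matrix `mu` — the probability of copying from panel `p` given latent
ancestry `a` — is *learned* by Baum–Welch EM together with `Pi`, `rho` and
`theta`, so the method works even when the true mixing groups are only
indirectly represented in (or smeared across) the available panels.

Around the core model the package provides:

* donor **thinning** via an ancestry-unaware painting pass (top 100 donors
  per gridpoint per individual),
* **phase hunting**: hill-climbing correction of statistical phasing errors
  by exact single-gridpoint flip gains,
* **admixture dating** from exponential-decay coancestry curves
  `P(a,b,d) = delta*exp(-lambda*d) + tau` (`lambda` in generations), with
  chromosome-bootstrap uncertainty and event-order narration for multiway
  events,
* **drift summaries**: Weir–Cockerham-style ratio-of-averages Fst between
  reconstructed ancestral genomes and every panel, the panel-contrast
  statistic Rst in [0, 2], and the expected coefficient of determination
  E[r²] of the local ancestry estimates,
* a **mean-ancestry selection scan** with a `<10 markers / 1 Mb` mask,
* a full **synthetic admixture simulator** (drifted populations with
  within-population LD, exponential ancestry tracts with a known truth
  track, optional phase scrambling) so that every claim is testable from a
  seed.

## Worked example

```r
library(admixpaint)

# two populations diverged by drift; 10 admixed diploids, tracts at
# 50 breakpoints/Morgan (~51 generations), equal proportions; the true
# source haplotypes are withheld from the inference panels
study <- simulate_admixture_study(n_pops = 2, drift_F = 0.1,
                                  n_sites = 2000,
                                  chr_lengths_cM = c(chr1 = 100, chr2 = 100),
                                  lambda_gen = 50, n_targets = 10,
                                  seed = 11)

# the simulated targets are exactly phased, so phase hunting is disabled;
# the tracts share one event, so the joint switch matrix is the right model
fit <- run_pipeline(study$haps,
                    run_config(A = 2, shared_Pi = TRUE, rephase = FALSE,
                               n_boot = 50, final_rel_tol = 5e-7,
                               final_max_iter = 300, seed = 12))
fit
#> <ancestry_fit> A = 2 , 10 target(s), 2 chromosome(s)
#>   proportions: 49.5% / 50.5%
#>   date: 49.31 generations (+-2.34 [2 SE])
#>   E[r2]: 0.6655  Rst: 0.3066
#>   loglik: -14689.7 after 1 round(s)

score_vs_truth(fit, study$truth)$r2   # diploid r^2 against the truth track
#> [1] 0.7587938

round(fit$params$mu, 3)               # learned panel-ancestry copying matrix
#>       [,1]  [,2]
#> [1,] 0.065 0.952
#> [2,] 0.935 0.048
```

Reading the output: the mixing proportions come back at ~50/50; the fitted
coancestry decay puts the event at ≈ 49 generations (simulated: a 50/Morgan
breakpoint rate); each copying-matrix column concentrates ~94% of its mass
on one panel — and the two columns pick *different* panels, i.e. the model
discovered the panel–ancestry relationship on its own (ancestry labels are
arbitrary, here ancestry 1 matched the pop2 panel); E[r²] ≈ 0.67 estimates
the local-ancestry accuracy from the posterior alone (the realised r²
is 0.76). `tidy(fit)` gives per-pair dates with bootstrap intervals,
`glance(fit)` a one-row summary, `autoplot(fit)` the coancestry curves with
their fitted decays, `plot_local_ancestry(fit)` the painted chromosomes, and
`write_results(fit, dir)` the full results bundle (posteriors TSV, params /
dates / stats JSON, rephased phased VCF, provenance record).

A thin command-line front end with `simulate` / `paint` / `date` / `stats`
subcommands is installed at `inst/scripts/admixpaint`.

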