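# wmggmm

Robust fitting of **weighted multivariate generalized Gaussian mixture
models** (WMGGMM) and **rigid point-cloud registration** by minimizing a
Monte-Carlo Kullback–Leibler divergence between two fitted mixtures.

The package is for people who need to align 2-D point sets — scans,
detections, landmark clouds — in the presence of noise, outliers and
mismatched sampling rates, and for anyone fitting heavy-/sharp-tailed
elliptical mixtures where a plain Gaussian mixture over-smooths the dense
regions that carry the real structure.

## The model

A multivariate generalized Gaussian distribution (MGGD) has density

    p(x; mu, Sigma, beta, m) =
      beta Gamma(d/2) / ( Gamma(d/(2 beta)) pi^{d/2} 2^{d/(2 beta)}
                          m^{d/2} |Sigma|^{1/2} )
      * exp( - [ (x-mu)' Sigma^{-1} (x-mu) ]^beta / (2 m^beta) )

with shape `beta` (beta = 1 is Gaussian; beta < 1 sharper peak, heavier
tail), scale `m` and scatter `Sigma`. Every observation additionally carries
a weight, treated as a Gamma random variable with a conjugate posterior, so
that outliers and clutter are down-weighted automatically during EM.
Parameters are estimated by fixed-point iterations (mean, scatter), damped
Newton–Raphson (shape) and a closed form (scale); the number of components
is selected by a minimum-message-length (MML) criterion with component
annihilation. Registration fits one mixture per cloud, transforms the model
mixture in closed form under a rigid map (`mu' = R mu + t`,
`Sigma' = R Sigma R'`), and minimizes the Monte-Carlo KLD over rotation and
translation by simulated annealing. See the methods vignette
(`vignettes/wmggmm-methods.Rmd`) for the full account.

## Worked example

```r
library(wmggmm)

# a 1200-point benchmark cloud from a known 3-component mixture
cloud <- make_mixture_dataset(spec_three_component(), seed = 42)
fit <- wmggmm_fit(cloud, wmggmm_config(k_max = 8, seed = 42))
print(fit)
#> WMGGMM fit: K+ = 3 components after 90 sweeps (MML = 5255.07)
#> MGGD mixture: K = 3 components in 2-D
#>   [1] pi = 0.1894  mean = ( 7.847, 15.990)  beta = 0.886  m = 0.801
#>   [2] pi = 0.5463  mean = (1.155, 2.806)  beta = 0.843  m = 1.361
#>   [3] pi = 0.2643  mean = (14.902,  2.017)  beta = 0.655  m = 0.124
```

Starting from `k_max = 8`, the MML criterion prunes back to the true three
components; the fitted means sit within a few tenths of a unit of the
generating means (8,16), (1,3), (15,2). The mixing weight of the
heavy-tailed (8,16) component reads low (0.19 vs 0.25) — the weighting
mechanism reassigns part of its tail mass, a documented property of the
estimator — and `m` is shrunk toward the data core for the same reason.

```r
# registration: 1200-point scene vs 800-point cloud, known ground truth
pair <- make_registration_pair(spec_three_component(),
                               truth = rigid_transform(0.7, c(5, -3)),
                               seed = 42)
res <- register_clouds(pair$scene, pair$model_cloud,
                       wmggmm_config(k_max = 8, seed = 42),
                       registration_config(seed = 42))
print(res)
#> registration: KLD = 0.0260
#> rigid_transform (d = 2): angle = 0.6893 rad, t = ( 4.8801, -3.1292)

err <- evaluate_registration(res, pair$truth)
sprintf("rotation error: %.2f%%  translation error: %.2f%%",
        100 * err$rot_rel, 100 * err$trans_rel)
#> "rotation error: 1.53%  translation error: 3.02%"
```

The recovered transform (0.689 rad, (4.88, −3.13)) is within 1.5% / 3% of
the true (0.7 rad, (5, −3)) despite the 1200-vs-800 sampling-rate mismatch.

Other entry points: `add_uniform_noise()` (contamination experiments),
`make_trap_pair()` (a near-180°-symmetric scene with one small
disambiguating cluster), `read_point_cloud()` / `write_point_cloud()`
(CSV/TSV/XYZ/ASCII-PLY), `write_mixture_json()` / `write_transform_json()`
(serialization), and a thin command-line wrapper in
`inst/cli/wmggmm-cli.R` with `simulate`, `fit`, `register` and `evaluate`
subcommands.

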