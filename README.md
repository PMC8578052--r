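# fmtpk

Whole-body pharmacokinetic modeling for longitudinal hybrid micro-CT /
fluorescence-mediated tomography (uCT-FMT), with an explicit *mixing
matrix* that corrects the three ways organ-level fluorescence misreports
probe amounts: blur between neighboring organs (intensity diffusion), the
blood-borne signal inside each organ's vasculature (relative blood
volume), and the fusion of the liver's and kidneys' elimination and
retention pools into single imaged organs.

It is written for preclinical imaging groups who extract organ x time
%ID tables from uCT-FMT scans and want unbiased rate constants for the
hepatobiliary and renal elimination routes and the major retention sites
(liver, kidneys, bone, spleen, lung) — and for anyone who wants to
quantify, by simulation, when such rates are identifiable at all.

## Model

State: 11 compartments (Lung, Blood, LiverRet, LiverElim, Bone, Spleen,
Intestine, KidneyRet, KidneyElim, Bladder, Others), amounts in % injected
dose. Kinetics are linear and mass-balancing,

```
dI/dt = K I
```

with eight unknown blood-efflux rates (constrained to the physiological
box 0.001-0.02 min^-1) and a few fixed drainage rates. Measurements see
only 9 channels through the mixing operator `M` (9 x 11):

```
I_m = M I_c ,   M = IDV' * [ (1 - rBV) * Collapse + rBV * e_blood ]
```

where `IDV` is the 9 x 9 intensity-diffusion matrix (reference matrix
shipped with the package), `rBV` the per-organ relative blood volume and
`Collapse` the sub-compartment summation. Fitting minimizes

```
f(K) = sum( (I_m_hat - I_m)^2 ) + c * sum(K^2)
```

by Polak-Ribiere+ nonlinear conjugate gradient with exact adjoint
gradients of the discrete RK4 -> sampling -> mixing chain, under the box
constraint via logistic reparameterization. `runStudy()` reproduces the
parameter-recovery simulation: 100 random rate sets, 10 % multiplicative
noise, six temporal sampling schemes, corrected vs uncorrected arms,
relative errors and estimate-vs-truth regression slopes.

See `vignettes/mixing-matrix-pk.Rmd` for the full account of the model,
defaults and design choices.

## Worked example

Simulate one animal's worth of noisy measurements from known rates, then
recover them:

```r
library(fmtpk)
truth <- kineticParameters(c(
  kKidneyElimination = 0.015, kLiverElimination = 0.012,
  kKidney = 0.004, kLiver = 0.018, kBone = 0.006,
  kSpleen = 0.009, kLung = 0.007, kOthers = 0.011))
meas <- simulateMeasurements(truth, "7", noiseLevel = 0.10, seed = 42)
fit  <- pkFit(meas)
fit
#> FitResult: 121 CG iterations, converged (grad norm 0.00695)
#>   cost: sse 116.039 + penalty 9.47e-08 = 116.039
#>   estimates (min^-1 | %ID/min):
#>     kKidneyElimination   0.01501 | 1.501
#>     kLiverElimination    0.01234 | 1.234
#>     kKidney              0.00425 | 0.425
#>     kLiver               0.01793 | 1.793
#>     kBone                0.00549 | 0.549
#>     kSpleen              0.00832 | 0.832
#>     kLung                0.00648 | 0.648
#>     kOthers              0.00938 | 0.938
round(100 * mean(relativeError(estimates(fit), truth)), 1)
#> [1] 5.9
```

The seven 10 %-noisy time points leave a residual sum of squares of ~116
(%ID)^2 across the 63 measurements, and the eight rates come back with a
mean relative error of about 6 % — the hepatic retention rate `kLiver`,
the quantity most distorted without correction, is recovered to 0.4 %.
Refitting the same data with `pkFitUncorrected()` (no mixing correction)
illustrates the bias the correction removes.

A command-line wrapper covers the same ground from a shell
(`simulate`, `fit`, `study`, `idv` subcommands):

```sh
Rscript inst/cli/fmtpk.R fit --measurements meas.csv --scheme 7 --out report.json
```

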