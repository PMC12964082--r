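# handtrans

Gene-culture transmission models of human handedness: fitting, testing, and
evaluating a co-evolutionary model of hand preference on familial and twin
count data.

## The problem

About 90% of humans are right-handed, yet simple Mendelian models cannot
reproduce the weak parent–offspring resemblance or the ~80% concordance seen
in both monozygotic and dizygotic twins. A gene-culture model resolves this:
after a right-shift allele has gone to fixation, every individual carries a
genetic bias `rho` towards right-handedness, and parental phenotypes add a
cultural shift — `+alpha` for two right-handed parents, `+beta` for
mixed-handed parents, `-alpha` for two left-handed parents — so the
probability of a right-handed child is `1/2 + rho + alpha`, `1/2 + rho +
beta`, or `1/2 + rho - alpha` by mating class. The equilibrium of the
random-mating recursion fixes the population's *true incidence* of
left-handers, `t`.

Because studies measure handedness with different criteria, each study's
*measured* incidence deviates from `t` ("criterion shift"). The package
implements the misclassification adjustment `M = P T O`, which carries the
true transmission table `T` to the measured scale via a parental mating-class
transition matrix `P` and an offspring phenotype matrix `O`, with nuisance
proportions computed deterministically from the measured incidences — never
fitted.

On top of the model sit:

- binomial maximum-likelihood estimation (multi-start Nelder–Mead with
  grid-search validation) under three scenarios — A: estimate and test
  unadjusted; B: estimate unadjusted, test adjusted; C: both adjusted;
- G-test goodness of fit for familial data (combined df `2S - k`) and for
  held-out twin data;
- a sex-difference model family (maternal vs paternal effects, daughter vs
  son sensitivity; models I–V) compared by likelihood-ratio tests;
- a synthetic-data generator and an evaluation harness measuring estimator
  bias, MSE, and bootstrap confidence-interval coverage.

## Worked example

The package bundles a synthetic seventeen-study familial table (generated by
its own simulator; the historical literature counts are not redistributable
here) and a twin table reconstructed from published aggregate totals.

```r
library(handtrans)

fam <- read_familial_table(
  system.file("extdata", "synthetic_familial_17studies.csv",
              package = "handtrans"))
fit <- fit_mle(fam, scenario = "B", model = "two", n_starts = 100, seed = 1)
fit
#> Transmission-model fit (scenario B, model two)
#> Base transmission parameters
#>   rho = 0.2915  alpha = 0.1166  beta = 0.0000
#>   support = -10248.778   true incidence t = 0.1198
#>   100 start(s), best start 85, converged: TRUE, seed 1
```

The fitted genetic shift (`rho`) and cultural shift (`alpha`) imply a true
left-hander incidence of about 12%. Goodness of fit compares each study's
counts with its own criterion-shift-adjusted expected table:

```r
gof_familial(fam, fit)$combined
#>          G df            p
#> 1 63.05546 32 0.0008562111
```

and the same fit is tested, without refitting, on the held-out twin table:

```r
tw <- read_twin_table(
  system.file("extdata", "twin_pairs_reconstructed.csv",
              package = "handtrans"))
gof_twins(tw, fit)$combined
#>          G df           p
#> 1 10.68941  2 0.004773367
```

The simulation harness quantifies what estimating *without* the adjustment
(scenario B) costs: on shifted synthetic data generated at `rho = 0.277`,
`alpha = 0.138`, scenario-B estimates overestimate `rho`, underestimate
`alpha` by about 0.05, and their 95% bootstrap intervals cover the truth far
less often than 95%, while scenario C with the practical-identifiability
filters recovers both parameters accurately. See the vignette
(`vignettes/handedness-transmission.Rmd`) for the full account, including a
non-identifiability property of the adjusted likelihood that the package
documents and works around.

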