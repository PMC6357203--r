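# plateletdiv

Quantifying platelet division from two-colour doublet counts and dye
dilution.

## The problem

Platelets are anuclear blood particles, yet they can divide in culture.
Measuring *how many* divide is hard: Coulter counters cannot tell a
dividing platelet from a small clump, and ordinary flow-cytometric dye
dilution is blurred by the wide intensity spread of labelled platelets.
`plateletdiv` implements two complementary assays for researchers studying
platelet (or, more generally, small-particle) proliferation:

1. **Differential doublet counting.** Two platelet aliquots are labelled
   red and green, mixed in a viscous semisolid medium and cultured. A
   platelet that divides leaves its progeny beside it as a *same-colour
   doublet*; doublets formed by incidental contact during mixing
   ("happen-to-be" doublets) follow the binomial colour pattern
   RR : RG : GG = R² : 2RG : G² for R red and G green platelets. A deficit
   of red–green doublets is therefore evidence of division, and the size
   of the deficit measures it.
2. **Dye-dilution (CFSE) analysis.** Platelets sorted through a narrow
   fluorescence gate halve their dye content at each division; the
   package locates the reduced-fluorescence cluster on the log2 intensity
   axis and converts the event fraction *e* into the divided platelet
   fraction *q = e / (2 − e)*.

## The estimator

For field counts `n_red`, `n_green` (total platelets per colour) and
doublet counts `d_rr`, `d_gg`, `d_rg`, the unknown original inputs R₀, G₀
and division fractions F_r, F_g satisfy

    n_red  = R₀ (1 + F_r)            n_green = G₀ (1 + F_g)
    d_rr   = d_rg · R₀ / (2 G₀) + F_r R₀
    d_gg   = d_rg · G₀ / (2 R₀) + F_g G₀

(the first pair counts platelets, the second splits the observed
single-colour doublets into contact doublets — predicted from the
red–green count through the binomial ratio — plus division doublets).
With a = d_rg/2, A = n_red − d_rr, B = n_green − d_gg and
t = (A − a)/(B − a), the closed-form solution is

    R₀ = A + a·t        G₀ = B + a/t
    F_r = n_red/R₀ − 1  F_g = n_green/G₀ − 1

The tail test compares the observed red–green doublet count with its
binomial null `Binomial(T, 2RG/(R+G)²)` over the `T` observed doublets and
reports `P(RG ≤ observed)` by one-sided normal approximation. Confidence
intervals for F_r, F_g come from a percentile bootstrap that resamples the
five field totals as independent Poisson counts.

The package also ships a synthetic experiment generator (expectation-level
counts, stochastic counts, and spatially explicit fields rendered into
two-channel 16-bit images), a spot-detection/proximity-clustering imaging
front-end that turns such images into count tables, and the dye-dilution
quantifier, so the whole pipeline can be validated end to end against
known ground truth.

## Worked example

```r
library(plateletdiv)

mcx1 <- field_counts(171, 167, d_rr = 28, d_gg = 22, d_rg = 8,
                     experiment = "MCX1", condition = "cultured")
doublet_null_test(mcx1)
#> Doublet composition test [MCX1, cultured] (normal_approx)
#>   observed RR/RG/GG: 48.3 / 13.8 / 37.9 % of 58 doublets
#>   expected RR/RG/GG: 25.6 / 50.0 / 24.4 %
#>   P(RG <= observed) = 1.76e-08

est <- estimate_division_fractions(mcx1)
ci <- bootstrap_division_ci(mcx1, seed = 1)
est$ci_red <- ci$ci_red; est$ci_green <- ci$ci_green
est
#> Division fractions [MCX1, cultured]
#>   F_r = 16.4% (95% CI 9.7 to 23.5)
#>   F_g = 12.0% (95% CI 6.0 to 18.5)
#>   inferred inputs R0 = 146.9, G0 = 149.1; contact doublets RR 3.94, GG 4.06
```

Only 13.8% of the 58 doublets are red–green where chance contact predicts
50.0% — the odds of that under the no-division null are about 2 in 10⁸ —
and solving the count balances attributes the excess same-colour doublets
to division of 16.4% of the red and 12.0% of the green input platelets.

The dye-dilution side works the same way from an event list:

```r
ev <- simulate_dilution_events(1e5, divided_fraction = 0.3, seed = 1)
estimate_divided_fraction(ev)
#> Dye-dilution estimate (valley boundary, 130011 events)
#>   divided events:    46.2%
#>   divided platelets: 30.0%
#>   generation-0 mode at 1e+03, boundary at 712 (a.u.)
```

`analyze_counts(semisolid_culture_counts())` runs the full analysis on the
packaged count tables of the six two-colour culture experiments;
`cytoskeletal_counts()` provides the drug-inhibition series.

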