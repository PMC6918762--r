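# nestcamo

Camouflage scoring and egg-heating analysis for ground-nesting bird nests.

Ground-nesters such as the Kentish plover (*Charadrius alexandrinus*) line
their scrapes with pebbles, shells and plant fragments. Those materials pull
in two directions at once: pale materials keep eggs cooler under direct sun,
dark ones match the eggs and the surroundings better. `nestcamo` provides
the measurement half of that research programme for anyone working with
calibrated nest photographs and egg-temperature logs:

* **Background/pattern-matching camouflage** from multi-scale texture
  analysis of nest-scene photographs,
* **disruptive camouflage** (how much of the egg outline the texture
  analysis detects),
* **nest-material coverage** from close-up photographs via a digital grid,
* **characteristic egg-heating times** from thermocouple series via
  Newton's law of heating,
* and a fully **seeded synthetic-data generator** (scenes + heating curves)
  so every stage is testable without field data.

## The methods in brief

**Texture camouflage.** Each channel of the CIE L\*a\*b\* image (normalised
against an in-scene 18%-reflectance gray standard) is filtered with a bank
of 56 kernels — odd- and even-symmetric Gaussian-derivative pairs at five
orientations plus two Gaussian and two Laplacian-of-Gaussian
rotation-invariant members, at scales σ = {16, 24, 32, 48} px — giving 168
features per pixel. Features are clustered with K-means (k = 14), and each
region of interest (egg, nest, internal buffer, microhabitat) gets a
*clustering signature* g: the percentage of its pixels in each cluster.
Camouflage between regions with signatures g and h is the chi-squared
histogram distance

    chi2(g, h) = 1/2 * sum_i (g_i - h_i)^2 / (g_i + h_i),

from 0 (identical texture composition) to 100 (nothing in common); lower
values mean better camouflage.

**Disruptive score.** The egg outline is dilated with a cross-shaped
element of radius 1% of the mean egg length, intersected with the texture
frontiers, thinned to unit width; the score is the percentage of outline
pixels detected (lower = better-hidden outline).

**Coverage.** A 2 × 2 mm grid is embedded in the nest region; the score is
the percentage of squares in which experimental material covers more than
half the square.

**Heating.** For a logged series T(t), the shifted curve y = T − T_f is fit
by nonlinear least squares to y = a·e^{bt} with a = T_i − T_f, b = −1/Tc.
Tc is the characteristic heating time: 100·(1 − e⁻¹) ≈ 63.2% of the total
temperature change is complete at t = Tc. Field series that do not follow
the exponential are summarised by the mean of their last five records, and
material temperature is related to total reflectance by an exact
small-sample Spearman correlation.

## Worked example

Simulate the laboratory heating experiment (six materials, ten replicates
each) and fit every curve:

```r
library(nestcamo)

materials <- data.frame(
  material = c("white pebbles", "light gray pebbles", "ochre pebbles",
               "dried mud", "twigs", "dark gray pebbles"),
  Tc       = c(420, 360, 330, 310, 240, 290),
  T_final  = c(38, 42, 46, 48, 50, 52))

records <- do.call(rbind, lapply(seq_len(nrow(materials)), function(m)
  do.call(rbind, lapply(1:10, function(r) {
    hc <- make_heating_curve(
      curve_spec(T_i = 25, T_f = materials$T_final[m], Tc = materials$Tc[m],
                 noise_sd = 0.2, seed = 20260927L + 100L * m + r),
      material = materials$material[m], replicate = r)
    data.frame(time_s = hc$series$t, temp_C = hc$series$T,
               material = materials$material[m], replicate = r)
  }))))

res <- run_heating_pipeline(records)
res$summary[order(-res$summary$Tc_mean), ]
```

which prints (this is the output of `analysis/04_heating.R` on the same
simulated records):

```
            material n_replicates Tc_mean  Tc_se r2_mean T_final_mean
6      white pebbles           10   414.5 3.5345  0.9945        37.96
3 light gray pebbles           10   355.6 0.8107  0.9966        41.95
4      ochre pebbles           10   328.2 1.6872  0.9975        46.00
2          dried mud           10   313.6 2.4474  0.9973        48.07
1  dark gray pebbles           10   290.3 1.2818  0.9982        52.00
5              twigs           10   241.2 0.7940  0.9978        50.03
```

`Tc_mean` is the mean characteristic heating time in seconds: eggs on white
pebbles take the longest to complete 63.2% of their temperature change
(generated 420 s, recovered 414.5 s), eggs on twigs the shortest. `r2_mean`
is the mean coefficient of determination of the exponential fits.

The camouflage side runs the same way from generated scenes
(`analysis/01_simulate.R` + `analysis/02_camouflage.R`). On six simulated
nests the per-treatment means are:

```
  treatment score_egg_nest score_nest_external egg_border_pct
1         O           66.2                56.7           88.8
2         T           97.9                99.9           99.4
3         W           60.3                52.1           88.0
```

Adding a very pale material (treatment T) drives the nest–microhabitat
chi-squared score to near its maximum; after simulated removal of 85% of
the material (W) the scores return to the original (O) level — the
qualitative pattern the method is built to detect.

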