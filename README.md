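# magbee

Magnitude-cue models of numerosity discrimination in bees.

## The problem

Two-alternative "counting" tasks — displays with different numbers of black
elements, one side rewarded — are the workhorse of numerical-cognition
research in animals. But element count is almost never the only thing that
differs between such displays: at constant total black area, the total
edge length, the convex hull, and the spatial-frequency content of a
display all rise with the number of elements. An animal (or a very small
neural circuit) that learns any one of these *continuous* magnitude cues
will pass most tests that are usually read as evidence for a sense of
number, including ordering an empty display below all others.

`magbee` is for researchers who want to quantify that confound and to
simulate how far a minimal magnitude-only circuit gets on a numerosity
test battery. It provides:

* a **stimulus generator** for constant-area element displays (squares,
  diamonds, circles; counts 0–6 on a 120 × 120 px canvas representing a
  6 × 6 cm card), including test sets in which the continuous cues are
  equalized at fixed count, set in opposition to the numerical
  difference, or zeroed (the empty display);
* **cue measurement**: black area, total edge length, convex-hull area,
  and spatial-frequency power as the area under the radially averaged
  2-D Fourier power spectrum;
* a **nine-neuron magnitude network** and a reinforcement-gated online
  learning rule (below), simulated as populations of independently
  seeded "model bees" trained to the behavioural 80%-of-10-choices
  criterion;
* the **test batteries and statistics** used to summarise such
  experiments (Wilcoxon signed-rank z against chance, Kruskal–Wallis,
  Spearman rank correlations), tidyverse-style: data frames in, tibbles
  out, `autoplot()` everywhere.

## The model

Seven sensory neurons encode a scalar magnitude input $s$ (here: the
calibrated spatial-frequency power of a display, with the empty display
pinned at $s = 0$) through Gaussian tuning curves with preferred values
$f_i \in \{0, 1, \dots, 6\}$:

$$g_i(s) = R_0 + R_{max}\, e^{-\frac{(s - f_i)^2}{2\sigma^2}} + \mathcal{N}(0, \sigma_N),$$

with $R_0 = 50$, $R_{max} = 200$ spikes/s and $\sigma = 2.5$. A single
decision neuron reads the population through synaptic weights $W$:

$$D(s) = F\Big(\sum_k W_k\, g_k(s)\Big), \qquad
F(x) = \frac{A_0}{1 + e^{-a(x-b)}},$$

with $A_0 = 100$ spikes/s, $a = 0.05$, $b = 50$. A ninth, reinforcement
neuron gates online gradient ascent on the objective
$L = \sum_t \big[D(s_p^t) - D(s_n^t)\big]\, r^t$ (rewarded minus punished
response):

$$W_i \leftarrow W_i + \eta\, \Big[ g_i(s_p) F'\big(\textstyle\sum_k W_k g_k(s_p)\big) - g_i(s_n) F'\big(\textstyle\sum_k W_k g_k(s_n)\big) \Big]\, r .$$

The model never sees a count — only one continuous cue — yet reproduces
rule transfer to novel shapes, to counts beyond the trained range, and
the ordering of the empty display as the low end of the magnitude
continuum.

## Worked example

```r
library(magbee)

img <- generate_stimulus(3, "circle", target_area = 1024, seed = 42)
img
#> <stim_image> 120x120 px, 3 element(s) [circle], 1015 black px, cue_bias=none
cue_vector(img)
#> # A tibble: 1 × 4
#>    area edge_length convex_hull_area sf_power
#>   <int>       <dbl>            <dbl>    <dbl>
#> 1  1015        190.             3974   94010.
```

The display holds ~1024 px² of ink regardless of its element count; its
edge length (190 px), hull (3974 px²) and spatial-frequency power are the
cues that covary with count across a set.

A small population of model bees trained on 1–4 elements (more-than rule)
and probed beyond the trained range:

```r
cfg <- experiment_config("outside_range", rules = "more_than",
                         n_bees = 12, n_exemplars = 10, seed = 7)
res <- run_population(cfg)
dplyr::select(res$summary, rule, test, pair, n, mean_pref, sem, statistic, p)
#> # A tibble: 3 × 8
#>   rule      test     pair       n mean_pref   sem statistic      p
#>   <chr>     <chr>    <chr>  <int>     <dbl> <dbl>     <dbl>  <dbl>
#> 1 more_than conflict 0_vs_1    12     0.752 0.101    2.25   0.0243
#> 2 more_than learning 4_vs_5    12     0.43  0.145    0.0802 0.936
#> 3 more_than transfer 5_vs_6    12     0.676 0.109    1.79   0.0736
```

`mean_pref` is the mean per-bee fraction of choices for the display the
trained rule designates as correct (chance = 0.5); `statistic` is the
Wilcoxon signed-rank z of the per-bee fractions against chance. With only
12 bees the z values are small; the full design uses 50 bees per rule.
`autoplot(res)` draws the familiar bar-plus-points preference figure, and
`tidy(res)` returns the per-bee scores.

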