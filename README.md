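# vocalflock

Tools for studying open-ended vocal learning and social integration in small
captive flocks of budgerigars (*Melopsittacus undulatus*). Budgerigars keep
learning new contact calls as adults: when previously unfamiliar birds are
housed together in a novel flock, their frequency-modulated contact calls
converge over a few weeks. `vocalflock` implements the full analysis chain
for experiments of this design — four-bird, single-age-class flocks recorded
over five blocks (one pre-flock baseline, four post-flock) with concurrent
observation of affiliative, agonistic and proximity-based social behaviour —
and a synthetic-data generator so every stage can be exercised and validated
without any field recordings.

## What it computes

**Acoustic trait space.** Detected contact calls are summarized by 17
spectro-temporal features (duration; mean, sd, median and quartiles of the
time-aggregated magnitude spectrum; spectral skewness and kurtosis;
spectral, temporal and overall entropy; spectral flatness; dominant
frequency track mean/min/max/range; modulation index), z-scaled, and
jointly embedded in 2-D with exact t-SNE, so that acoustically similar
calls lie close together.

**Vocal-learning measures.** For each individual `i` and recording block
`k`, a Gaussian-kernel density is estimated on a shared grid and its 95%
highest-density region (HDR) extracted. Writing `A_ik` for the HDR area and
`P_ik` for the density, the package computes

- *vocal output*: the number of contact calls produced;
- *vocal diversity change*: `A_ik − A_i1`, the change in acoustic-space
  area relative to the pre-flock baseline;
- *vocal plasticity*: the pairwise mean overlap between block `k`'s space
  and the baseline space — the mean of the two directional overlaps
  `O(A→B) = P_A(hdr A ∩ hdr B) / P_A(hdr A)`, a density-weighted
  similarity to the starting self (lower = more plastic);
- *vocal convergence*: the same mean overlap between an individual's space
  and the pooled space of its three flockmates in the same block.

**Social networks.** Per flock and dimension (proximity, affiliation,
agonism) a symmetric weighted 4×4 adjacency matrix: proximity weights are
the proportion of valid snapshots with inter-individual distance ≤ 10 cm,
interaction weights are undirected event counts. Density is the share of
the 6 possible dyads with a nonzero edge; strength is each bird's summed
edge weights.

**Models.** The standard battery: negative-binomial (vocal output,
count-based strength), Gaussian (diversity change), beta (plasticity,
convergence), binomial (density) and Gamma (proximity strength) GLM(M)s
with age class, recording block and their interaction as fixed effects
(interaction dropped when nonsignificant) and individual/flock random
intercepts, reported broom-style via `tidy()` / `glance()`.

## Worked example

```r
library(vocalflock)
library(dplyr)

# two flocks per age class through the full acoustic pipeline
ex    <- simulate_experiment(n_flocks_per_age = 2, sessions_per_block = 2,
                             calls_per_session = 12, seed = 10)
calls <- synthesize_call_table(ex$calls, sample_rate = 19000, seed = 11)
feats <- scale_features(extract_features_table(calls))
emb   <- embed_features(feats, perplexity = 30, iterations = 600, seed = 12)
vm    <- vocal_metrics(emb, grid_resolution = 150)
vm |>
  filter(block > 1) |>
  group_by(age_class) |>
  summarise(diversity = mean(diversity_change),
            plasticity = mean(plasticity),
            convergence = mean(convergence))
#> # A tibble: 2 × 4
#>   age_class diversity plasticity convergence
#>   <chr>         <dbl>      <dbl>       <dbl>
#> 1 old          -131.       0.528       0.583
#> 2 young          16.7      0.296       0.558

# six flocks per age class, interactions and proximity only
social <- simulate_experiment(n_flocks_per_age = 6, calls_per_session = 0,
                              seed = 20)
nets <- network_metrics(social$events, social$snapshots, social$flocks)
nets$density |>
  filter(dimension == "affiliation") |>
  group_by(age_class) |>
  summarise(density = mean(density))
#> # A tibble: 2 × 2
#>   age_class density
#>   <chr>       <dbl>
#> 1 old         0.944
#> 2 young       1

nets$strength |>
  filter(dimension == "affiliation") |>
  group_by(age_class) |>
  summarise(strength = mean(strength))
#> # A tibble: 2 × 2
#>   age_class strength
#>   <chr>        <dbl>
#> 1 old           9.33
#> 2 young        25.2
```

The old cohort loses acoustic-space area after joining novel flocks
(mean diversity change −131 squared embedding units vs +16.7 for young)
and is less densely and less strongly connected affiliatively, while
convergence with flockmates is comparable between ages — the qualitative
pattern the generator's age presets encode. A single
`run_pipeline(config)` call chains all stages (simulate → detect →
features → space → metrics → network → models) into a run directory with
CSV outputs and a JSON manifest.

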