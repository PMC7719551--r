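# dichroma

Who drives the evolution of sexual dichromatism — males or females? When
the sexes of a species differ in color, the difference may have arisen by
directional selection elaborating male color (Darwin's model) or by
directional selection dulling female color (Wallace's model). Observing
that males are bright and females drab cannot distinguish the two; a
reconstruction of the *history* of color change can. `dichroma`
implements that reconstruction for comparative datasets: per-species,
per-sex color phenotypes on a time-calibrated phylogeny, analyzed in
CIELAB color space.

## The method

Each species and sex is summarized by its CIELAB centroid (the average
color of a pixel sample); dichromatism is the vector between the sexes'
centroids, `D = c_m − c_f`, with magnitude `‖D‖` (the color difference
ΔE). A phylogenetic ridge regression — tip traits regressed on
root-to-tip branch-length paths, with an L2 penalty on the per-branch
slopes chosen by leave-one-out cross-validation — is fitted to each sex,
yielding an ancestral color at every node and a 3-D rate vector on every
branch (`m` and `f`, in Lab units per Myr). The decomposition then asks
three questions:

* **Speed** — the rate ratio `mean‖m‖ / mean‖f‖`: does male color evolve
  faster?
* **Where** — the regression `log(‖m‖/‖f‖) ~ ‖D‖`: do rates become more
  male-biased on dichromatic branches? (Its slope equals the interaction
  term of the stacked model `log(rate) ~ dichromatism × sex`.)
* **Direction** — scalar projections onto the local dichromatism axis:
  `s_m = m·D̂`, `s_f = −f·D̂`, and the net effective rate of
  dichromatism change `s = s_m + s_f`, which to first order equals the
  change of `‖D‖` along the branch. The OLS slopes of `s_m ~ s` and
  `s_f ~ s` sum to exactly 1 and split the changes in dichromatism into
  male- and female-driven shares (0.5/0.5 = equal contributions).

Significance comes from refitting the entire pipeline on datasets with
sex labels randomly swapped within species; phylogenetic signal of
dichromatism is measured by Pagel's λ with a parametric-bootstrap CI. A
synthetic-data generator produces Darwinian (male-driven), Wallacean
(female-driven) and shared-null scenarios with known ground truth.

## Worked example

```r
library(dichroma)

tree <- simulate_tree(150, seed = 1)
sim  <- simulate_colors(tree, scenario_params(n_tips = 150,
                                              drive = "male", seed = 2))
dec  <- decompose_dichromatism(sim$tree, sim$centroids)
dec
#> Dichromatism decomposition (all branches)
#>   rate ratio ||m||/||f||: 1.175
#>   log-ratio ~ dichromatism slope: 0.0020
#>   contribution slopes: male 1.006, female -0.006
#>   ridge penalties: male 73.1, female 73.1
```

The simulated scenario drove male color away from female color in ~30%
of the tree: the decomposition recovers male color evolving ~18% faster
on average, rates growing more male-biased where dichromatism is high
(positive log-ratio slope), and changes in dichromatism attributed
essentially entirely to males (male contribution slope ≈ 1; the two
slopes always sum to 1, so values above 0.5 mean male-driven). A
permutation test and λ estimate complete the analysis:

```r
perm <- run_permutation_study(sim$tree, sim$centroids, R = 199, seed = 3)
d    <- species_dichromatism(sim$centroids)
lam  <- pagel_lambda(sim$tree, setNames(d$D_mag, d$species_id),
                     R_boot = 199, seed = 4)
```

For file-based end-to-end runs (CSV centroid table + Newick tree, all
intermediates and a JSON report written to disk) use
`run_full_analysis()` with a list or YAML configuration.

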