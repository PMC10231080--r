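# hollownet

Tree hollows are keystone microhabitats: a cavity with wood mould in a
veteran tree supports a whole community of saproxylic (deadwood-dependent)
beetles, and the hollow-by-species table of emergence counts from trapped
hollows forms a quantitative bipartite interaction network. `hollownet` is
an R package for analysing such networks -- and, more generally, any
site-by-species count web -- the way conservation studies of saproxylic
assemblages analyse them: structure, temporal change, and vulnerability to
microhabitat loss. It is aimed at community ecologists comparing paired-year
or multi-site emergence-trap designs.

## What it computes

For a network with hollows `h` (rows), beetle species `s` (columns), counts
`a_hs`, row/column totals `A_h.`, `A_.s` and grand total `A`:

* **Network indices** -- connectance `C = L/(R*S)`, links per species
  `L/(R+S)`, weighted linkage density
  `LD = 1/2 [ sum_s (A_.s/A) 2^{H_s} + sum_h (A_h./A) 2^{H_h} ]` (Shannon
  `H` in bits per row/column), interaction evenness `H/ln(R*S)`, the
  specialization index `H2'` standardized between its marginal-constrained
  entropy extremes, the V-ratio `Var(A_h.)/sum_s Var(a_hs)`, node degree and
  species strength (sum of partner dependencies `a_hs/A_.s`).
* **Nestedness and modularity** -- NODF on all row and column pairs with
  decreasing fill; Barber bipartite modularity
  `Q = (1/L) sum_hs (b_hs - k_h k_s/L) [module(h)=module(s)]` maximized by
  simulated annealing; both tested against a CE null model in which cell
  probability is the mean of row and column fill proportions,
  `p_hs = (k_h/S + k_s/R)/2`, with Monte-Carlo `z` and add-one p-values.
* **Temporal beta diversity of interactions** -- `beta_S` (species
  composition), `beta_WN` (whole-network link dissimilarity), `beta_OS`
  (rewiring among shared species) and `beta_ST = beta_WN - beta_OS`
  (turnover part), binary or Bray-Curtis weighted.
* **Extinction robustness** -- hollow-removal simulations under random,
  most-connected-first and least-first orders, with secondary beetle
  extinctions and robustness `R` = area under the survival curve
  (exhaustive over all orders for small webs).
* **Cores and threat scenarios** -- the generalist core
  `Gc = (k_i - k_mean)/sigma_k > 1`, quantitative cores by species strength
  (> 4 and > 5 tiers), and two degradation scenarios that replace core
  hollows' rows with those of the least-connected hollows and re-run the
  whole metric/robustness suite.
* **Diversity** -- Hill numbers `0D` (richness) and `1D` (exponential
  Shannon), sample coverage, and bias-corrected bootstrap confidence
  intervals with the non-overlap significance rule.
* **Synthetic study designs** -- a generator for nested, log-normal-count
  networks (16 hollows per woodland by default) and paired-year bundles with
  dial-controlled species turnover, link rewiring and abundance drift, so
  every stage above can be validated against known ground truth.

## A worked example

```r
library(hollownet)

net <- generate_network(synthetic_spec(n_hollows = 16, n_species = 60, seed = 42),
                        site = "riparian", year = "t1")
net
#> <interaction_matrix> 16 hollows x 60 species, 951 individuals [riparian, t1]

network_summary(net, null_replicates = 200, seed = 42)
#>    nodf nodf_p connectance links_per_species linkage_density
#> 1 47.35  0.005       0.192             2.421           9.619
#>   interaction_evenness h2prime v_ratio    RR    RM    RL
#> 1                0.704   0.488    6.91 0.689 0.373 0.886
```

The web is significantly nested (NODF 47.4, CE-null p = 0.005), moderately
specialized (`H2' = 0.49`), aggregated (V-ratio 6.9 > 1), and -- typically
for nested webs -- far more sensitive to losing its best-connected hollows
(RM = 0.37) than its marginal ones (RL = 0.89), with random loss in between
(RR = 0.69).

```r
pair <- generate_temporal_pair(net, temporal_spec(turnover = 0.5, rewiring = 0.3,
                                                  seed = 7))
decompose_beta(pair$t1, pair$t2)
#>      beta_S   beta_WN   beta_OS  beta_ST       scope weighting
#> 1 0.3947368 0.6956522 0.3488372 0.346815 both_levels    binary

head(dplyr::arrange(core_profile(net), -gc), 3)
#>   hollow degree       gc  strength qualitative_core strength_tier
#> 1    h01     33 1.961651 11.945979             TRUE           gt5
#> 2    h02     31 1.779172 11.617365             TRUE           gt5
#> 3    h03     26 1.322974  7.855378             TRUE           gt5
```

Half the species pool was replaced and a third of the surviving links
rewired, and the decomposition recovers exactly that: link dissimilarity
(`beta_WN = 0.70`) splits into a rewiring part (`beta_OS = 0.35`) and a
turnover part (`beta_ST = 0.35`). The three hollows with `Gc > 1` and
strength > 5 form the core that the threat scenarios
(`scenario_suite()`, `transform_cores()`) degrade.

`run_pipeline(generate_study_bundle(seed = 1), analysis_config(random_seed = 1))`
chains all of the above over three woodlands plus the pooled park scale and
two years, and `write_report()` lays the result out as metric-by-network
CSV tables.

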