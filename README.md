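# fragdiv

Quantitative structural-diversity analysis for fragment library design.

Fragment-based drug discovery screens small (MW ≤ 300 Da) compounds, and
the first decision of any campaign is which fragments — and how many — to
buy. `fragdiv` makes that decision quantitative. It implements a complete
pipeline for building and evaluating fragment libraries from SMILES
catalogues:

* **Filtering** — an adapted Rule-of-3 physicochemical filter
  (100 ≤ MW ≤ 300 Da, logP ≤ 3, rings ≤ 3, HBD ≤ 3, HBA ≤ 3, rotatable
  bonds ≤ 3, TPSA ≤ 60 Å²), a configurable reactive-group SMARTS filter,
  and a fluorine-count window (1–3 F) for ¹⁹F-NMR-oriented libraries.
* **Radial fingerprints** — extended-connectivity atom environments over
  bond radii 0–3, hashed into the full 64-bit identifier space (never
  folded, so hash collisions are negligible).
* **Selection** — directed sphere exclusion on Tanimoto distance
  (exclusion sphere 0.4: no two selected fragments more similar than 0.6)
  with a deterministic structure-decorrelated visit order, and seeded
  uniform random selection as the control, in triplicate.
* **Three diversity metrics** — mean nearest-neighbor Tanimoto similarity,
  richness `R` (number of distinct fingerprint features), and true
  diversity

  `D = 1 / ∏ᵢ pᵢ^pᵢ = exp(−Σᵢ pᵢ ln pᵢ)`,

  the effective number of equally common structural features, where `pᵢ`
  is the proportional abundance of feature `i` pooled over the library
  (`1 ≤ D ≤ R`, with `D = R` exactly for even feature usage).
* **Sizing** — natural cubic splines through (library size, metric) knots,
  evaluated on a step-1 grid (99,901 points for a 100–100,000 range), give
  the minimum library size achieving a diversity threshold and the size at
  which true diversity peaks.
* **A synthetic catalogue generator** — seeded, fully offline: analog
  families (shared scaffold + family substituent, members walking complete
  homolog ladders) plus unrelated singletons, reproducing the
  near-duplicate texture of commercial fragment catalogues so the whole
  pipeline is benchmarkable without any download.

## Worked example

```r
library(fragdiv)

# a 1,000-compound synthetic catalogue: 80 analog families + singletons
col <- generate_fixture(fixture_spec(n_total = 1000, n_families = 80,
                                     seed = 5))
fps <- radial_fingerprints(col)            # 64-bit radial features
ab  <- pooled_abundance(fps)
richness(ab)                               # 7509
true_diversity(ab)                         # 1793.813

# diversity-based selection vs triplicate random control
sphere <- sphere_exclusion_select(fps, radius = 0.4, max_size = 500)
random <- lapply(1:3, function(s) random_select(col, 500, s))
evaluate_ladder(fps, sphere, c(100, 200, 500))
#   size mean_nn_similarity richness true_diversity           method
# 1  100          0.3558269     2155       1044.311 sphere_exclusion
# 2  200          0.4101270     3467       1353.661 sphere_exclusion
# 3  500          0.4883346     5773       1708.333 sphere_exclusion
evaluate_ladder(fps, random, c(100, 200, 500))
#   size mean_nn_similarity richness true_diversity method
# 1  100          0.3764947  2209.33       1065.160 random
# 2  200          0.4511004  3392.67       1324.154 random
# 3  500          0.5264259  5552.33       1624.693 random
```

The diversity-based library is less self-similar (lower mean
nearest-neighbor similarity) at every ladder size, and from 200 compounds
on it is also structurally richer and more diverse than the random
control — the quantitative argument for diversity-driven fragment
purchasing. (The separation widens with pool size; on the package's
default 5,000-compound benchmark it holds at every ladder size.) Fitting
a spline through the sphere-exclusion ladder then answers "how many
fragments do I need?":

```r
curve <- fit_curve(c(100, 200, 500), c(2155, 3467, 5773))
min_size_for(curve, 0.5 * richness(ab), pool_total = nrow(col))
# size_estimate: threshold 3754.5 reached at size 226 (22.60% of pool)
```

## Command line

A thin Rscript front end covers the same pipeline stage by stage:

```sh
Rscript inst/cli/fraglib.R fixture  --outdir out --n-total 5000 --seed 1
Rscript inst/cli/fraglib.R filter   --input out/fixture.smi --outdir out
Rscript inst/cli/fraglib.R select   --input out/filtered.smi --outdir out \
        --method sphere --radius 0.4
Rscript inst/cli/fraglib.R evaluate --input out/filtered.smi --outdir out \
        --ladder 100,200,500,1000,2000 --seeds 1,2,3
```

Every command writes a JSON run manifest (parameters, seeds, input
checksums); identical configurations reproduce byte-identical CSVs.

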