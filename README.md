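# cpmtools

Connectome-based predictive modeling (CPM) of a behavioral severity score
from resting-state functional connectivity, as an installable, tested R
package. CPM is the standard protocol for turning a whole-brain connectome
into an individual-level prediction of a continuous trait — here an
Internet Addiction Test-like gaming-severity scale (range 20–100): edges
whose Fisher-z connectivity correlates with severity at a threshold
(default p < 0.01, optionally as partial correlation given age, sex and
head motion) are split by sign into a **positive network** and a
**negative network**; each subject's selected edges are summed into network
*strengths*; and ordinary least squares maps strengths to severity,
evaluated with leave-one-out cross-validation, permutation-test
significance, and fixed-model external validation. Selected edges are
summarized over ten canonical brain networks (medial frontal,
frontoparietal, default mode, motor/sensory, three visual systems,
salience, subcortical, cerebellum/brainstem).

For a training set with edge matrix $Z$ (subjects × edges), behavior $y$
and covariates $X$:

1. per edge $j$: $r_j = \mathrm{pcor}(Z_{\cdot j},\, y \mid X)$, kept if
   its two-sided $p < p_{thr}$, routed by $\mathrm{sign}(r_j)$;
2. strengths $s^{+}_i = \sum_{j \in M^{+}} Z_{ij}$,
   $s^{-}_i = \sum_{j \in M^{-}} Z_{ij}$;
3. models $y = a + b\,s^{+}$, $y = a + b\,s^{-}$, and the combined
   $y = a + b_{+} s^{+} + b_{-} s^{-}$;
4. out-of-fold predictions scored by Pearson $r$, parametric $p$, RMSE;
   headline significance from permuting $y$ and rerunning the entire
   cross-validated pipeline.

Because the kind of fMRI cohort this targets is rarely shareable, the
package ships a synthetic connectome generator with known ground truth
(planted positive/negative edges at a chosen population correlation,
optional covariate confounding that only partial correlation can reject),
so every stage is testable end to end. Intended users: neuroimaging /
biostatistics researchers who want a CPM reference implementation with
explicit contracts, and methodologists studying CPM's statistical behavior.

## Worked example

```r
library(cpmtools)

cfg <- generator_config(n_subjects = 120, n_nodes = 25, effect_r = 0.4,
                        seed = 7)
sim <- generate_dataset(cfg)          # dataset + ground-truth masks

cv <- run_cv(sim$dataset, threshold_p = 0.01, covariate_mode = "partial")
cv
#> cpm_cv: LOOCV over 120 subjects (threshold p < 0.01, partial selection)
#>   positive  r =  0.872  p = 2.08e-38  RMSE = 7.357
#>   negative  r =  0.874  p = 8.55e-39  RMSE = 7.355
#>   combined  r =  0.931  p = 2.57e-53  RMSE = 5.548

masks <- select_edges(sim$dataset, 0.01, "partial")
masks
#> edge_mask_pair (25 nodes, 300 edges): 21 positive, 20 negative (p < 0.01, partial)

head(rank_networks(summarize_mask(masks, sim$dataset$atlas, "positive")), 3)
#>   network total
#> 1     SAL     8
#> 2     CBL     7
#> 3      MF     5

permutation_test(sim$dataset, covariate_mode = "partial", n_perm = 100,
                 seed = 1)
#> cpm_perm: 100 permutations of the full LOOCV pipeline
#>   positive  observed r =  0.872  p_perm = 0.009901
#>   negative  observed r =  0.874  p_perm = 0.009901
#>   combined  observed r =  0.931  p_perm = 0.009901
```

Reading: with 20 + 20 edges planted at a population edge–behavior
correlation of 0.4, leave-one-out CPM recovers a strong cross-validated
prediction (combined r = 0.93 over 120 held-out subjects, RMSE ≈ 5.5 score
points on the 20–100 scale), every permutation p is at its minimum
(1/101 ≈ 0.0099), and the selected positive edges concentrate in a few
canonical networks. `validate_external()` applies such a model, frozen, to
an independent dataset; `run_pipeline()` wires simulate → QC → crossval →
permtest → external → summarize into a run directory with JSON manifests.

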