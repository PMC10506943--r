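# prmstrain

Strain imaging of the puborectal muscle (PRM) from dynamic 3D
transperineal ultrasound.

The PRM is a sling-shaped pelvic floor muscle whose two ends attach to
the pubic symphysis. During a voluntary contraction an intact muscle
shortens in its mid region (negative strain) while both anchored ends are
stretched (positive strain); after a unilateral avulsion the detached end
contracts along with the sling instead of elongating. `prmstrain` turns a
3D+t ultrasound volume sequence plus a rest-frame segmentation into that
functional picture:

1. dense inter-volume speckle tracking (normalized cross-correlation
   block matching with subvoxel refinement, implemented in C++),
2. Lagrangian accumulation of the inter-volume displacements and
   propagation of the segmentation through time,
3. extraction of the muscle centerline — the proxy for the local fiber
   direction — and projection of displacements onto its tangents,
4. fiber-direction strain from a 2×2×2 least-squares strain estimator
   (the window slope of tangential displacement against arc length, in
   percent),
5. regional summary at maximum contraction: median strain in the right
   end, mid, and left end regions (the ends together hold one third of
   the muscle volume), and the normalized strain ratio

   ```
   ratio = |eps_right − eps_left| / |eps_mid − (eps_right + eps_left)/2|
   ```

   which is below 1 for symmetric (intact) ends and above 1 under
   unilateral avulsion,
6. cohort comparison with an exact Mann–Whitney U test (full enumeration
   of group assignments at pilot-study sizes), Shapiro–Wilk normality
   checks and Welch t-tests.

Because no clinical volumes ship with the package, a seeded synthetic
phantom module generates sling-shaped speckle sequences with analytically
known displacement and strain everywhere — the validation suite runs the
entire pipeline against that ground truth.

## Worked example

Generate an intact phantom at the default study conditions (64³ voxels at
1 mm, 8 frames at 1.5 Hz, −10% peak mid strain) and run the full
per-subject pipeline:

```r
library(prmstrain)

pd  <- generate_phantom(phantom_spec(), seed = 1)
rec <- run_subject(pd$volumes, pd$rest_mask, run_config(),
                   condition_label = "intact")
rec$summary
#> subject strain summary (frame 8, intact):
#>   eps_right = +19.77 %  eps_left = +18.71 %  eps_mid = -8.95 %
#>   normalized strain ratio = 0.038
```

The mid region shortens by about 9% (true value −10%), both ends stretch
(true value +20%), and the near-identical end medians give a ratio far
below 1. The same call on an avulsed phantom flips the detached end
negative and pushes the ratio above 1:

```r
pa <- generate_phantom(phantom_spec(condition = "avulsed_right"), seed = 1)
run_subject(pa$volumes, pa$rest_mask, run_config())$summary
#> subject strain summary (frame 8):
#>   eps_right = -5.69 %  eps_left = +18.71 %  eps_mid = -10.33 %
#>   normalized strain ratio = 1.449
```

Cohort-level comparison of normalized strain ratios (here on synthetic
cohorts calibrated to group medians 0.36 and 1.54 at sizes 8 and 10):

```r
r   <- generate_cohort_ratios(cohort_spec(seed = 5))
cmp <- compare_cohorts(r$a, r$b)
cmp
#> group comparison of normalized strain ratios
#>   n = 8 vs 10, medians 0.234 vs 1.090
#>   Mann-Whitney U = 14.0, p = 0.02052 (exact_enumeration)
#>   Shapiro-Wilk p: 0.00399 / 0.00374; significant at alpha 0.05: yes
```

A thin command-line front end over the same functions is installed at
`system.file("cli", "prmstrain.R", package = "prmstrain")` with verbs
`phantom`, `track`, `subject` and `cohort`; inputs and outputs are 4D
NIfTI volumes, 3D NIfTI masks and label maps, CSV centerlines/summaries
and JSON reports. See the methods vignette
(`vignettes/prm-strain-methods.Rmd`) for the model, the estimator
design choices, and what phantom validation does and does not show.

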