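# bathydiv

Diversification, mass-extinction and phylogenetic-comparative analyses for
deep-sea mussel radiations — and for any similar clade-scale radiation on a
time-calibrated phylogeny.

Chemosymbiotic mussels (vent, seep and organic-fall Bathymodiolinae and
relatives) are a textbook marine adaptive radiation: a Late Cretaceous
origin, a burst of speciation in the Middle Eocene to Early Oligocene, a
possible mass-extinction scar near the Palaeocene/Eocene thermal maximum,
and later waves of diversification linked to symbiont innovations
(intracellular and methanotrophic symbioses), habitat shifts and body-size
trends. `bathydiv` packages the statistical machinery needed to interrogate
each of those claims on a chronogram plus a species-trait table:

* **Diversification models on branching times** — pure birth, birth-death
  (net rate *r* and extinction fraction *a* = μ/λ), density-dependent
  logistic (DDL) and exponential (DDX) variants, two- and three-rate Yule
  models with estimated shift ages, and a Weibull-shaped declining rate
  λ(t) = (β/b)(t/b)^(β−1); AIC/AICc model tables and a simulation-calibrated
  rate-shift test (null AICc differences from trees simulated under the
  constant-rate MLE, conditioned on crown age and tip count, with optional
  missing-species fractions).
* **Mass-extinction test** — birth-death likelihood with instantaneous
  events (each lineage survives with probability ρ), piecewise-analytic
  survival recursions, and an H0/H1 simulation comparison with
  lineages-through-time envelopes.
* **State-dependent speciation** — a BiSSE likelihood (adaptive Runge-Kutta
  pruning in C++) with state-specific sampling fractions, and the
  Yule-constrained model pair (single λ vs state-specific λ0, λ1) compared
  by likelihood-ratio test.
* **Ancestral states and comparative tests** — Mk marginal reconstruction
  with multistate (depth-bin) ambiguity, Brownian ancestral means for
  ln-shell-length, Pagel's correlation test with Monte-Carlo p-values,
  phylogenetic ANOVA, Brownian PGLS, 500-m depth discretization and
  Mann-Whitney depth comparisons.
* **Dating** — nonparametric rate smoothing (NPRS) with age constraints,
  and offset-exponential fossil-calibration utilities (soft maximum = 0.95
  quantile: 45 + 1.2 Myr → 48.6 Myr).
* **Simulators** — seeded, exactly conditioned tree simulators (constant,
  episodic, mass-extinction and BiSSE regimes; node ages by exact
  conditional sampling where theory permits, Gillespie + rejection
  elsewhere), discrete and Brownian trait simulators, and a "mussel-like"
  preset (62 tips, 85 Myr crown, speciation burst 0.17 events/Myr between
  41.2 and 33.8 Ma) that stands in for the unavailable empirical data.

## Worked example

```r
library(bathydiv)

# synthetic study-shaped data: 62-tip, 85-Myr chronogram with an
# Eocene-Oligocene speciation burst, plus a trait table
pre <- musselPreset(seed = 7)
bt  <- branchingTimes(pre$tree)

# Table-style diversification model selection
tab <- modelSelectionTable(bt)
tab[, c("model", "L", "r1", "r2", "r3", "s1", "s2", "AIC", "dAIC")]

# is the rate shift significant? (simulation-calibrated AICc difference)
shiftTest(pre$tree, replicates = 1000, seed = 1)

# mass extinction at 57 Ma with 5% survival?
meExtinctionTest(pre$tree, tME = 57, rho = 0.05, replicates = 500, seed = 2)

# do methanotrophic symbionts raise speciation rates?
meth <- setNames(pre$traits$methanotroph, pre$traits$species)
keep <- names(meth)[!is.na(meth)]
sub  <- asChronogram(ape::drop.tip(pre$tree, setdiff(pre$tree$tip.label, keep)))
fitSseModels(sub, meth)

# depth vs habitat
dmid <- setNames((pre$traits$depth_min_m + pre$traits$depth_max_m) / 2,
                 pre$traits$species)
grp  <- setNames(ifelse(pre$traits$habitat == "organic-fall",
                        "organic-fall", "vent/seep"), pre$traits$species)
mannWhitneyDepth(dmid, grp)
```

Output from this exact script (R 4.3, seed as shown):

```
       model        L     r1     r2    r3      s1      s2      AIC   dAIC
  pure_birth -50.7135 0.0470     NA    NA      NA      NA 103.4270 0.4450
 birth_death -50.6109 0.0420     NA    NA      NA      NA 105.2219 2.2399
         DDL -50.7135 0.0470     NA    NA      NA      NA 105.4270 2.4450
         DDX -50.6648 0.0403     NA    NA      NA      NA 105.3297 2.3477
  yule_2rate -49.3548 0.0236 0.0506    NA 40.3269      NA 104.7097 1.7277
  yule_3rate -46.4910 0.0236 0.5141 0.049 40.3269 39.8287 102.9820 0.0000

Rate-shift test: observed dAICc = -0.578, p = 0.8342 (1000 null simulations)

Mass-extinction test (event at 57.0 Ma, rho = 0.05):
  observed dlnL = -4.884, H0 5% rejection level = 0.858, p = 0.5409
  H0: lambda = 0.0519, mu = 0.0099; H1: lambda = 0.0502, mu = 0.0000

State-dependent speciation test (Yule-constrained BiSSE):
  lambda0 = 0.0362, lambda1 = 0.0388, lambda_Yule = 0.0370
  LR = 0.030 (1 d.f.), p = 0.8629  [sampling 1.00 : 1.00, 36 tips]

Mann-Whitney depth test (organic-fall: n = 5 vs vent/seep: n = 43): U = 11, p = 0.001195
```

Reading this: on *this particular* 62-tip simulated tree the three-rate
model edges out pure birth on raw AIC, but the calibrated shift test
(p = 0.83) correctly reports that the evidence is weak — a 62-tip tree
carries only a handful of branching events inside an 8-Myr burst window.
There is no support for a 57-Ma mass extinction that was never simulated
(observed ΔlnL far below the H0 rejection level), and no state-dependent
speciation signal for methanotrophy (the preset evolves traits neutrally
on the tree, so LR ≈ 0 is the correct answer), while the preset's built-in
habitat-depth contrast is picked up (vent/seep species deeper, p ≈ 0.001).
The recovery suites in `tests/testthat/test-acceptance.R` quantify what
*is* reliably estimable at this scale (shift ages to ~2 Myr median error;
the ordering λ1 > λ0 of state-dependent speciation rates in >90% of
replicates at strong simulated contrasts).

The full pipeline (prepare → diversification → extinction test → SSE →
comparative), with every table written as TSV/JSON plus a reproducible run
record, is one call:

```r
runPipeline(list(input = list(preset = "mussel"), seed = 7,
                 outDir = "mussel_run"))
```

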