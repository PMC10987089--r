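# affbound

Locating the body-size boundary in perceived object affordances.

Objects smaller than an agent's body afford hand-scale actions (grasping,
holding, throwing); objects larger afford whole-body actions (sitting,
standing, entering). `affbound` tests whether, in binary object-action
judgment data, the similarity structure of perceived affordances splits
abruptly at a boundary tracking the agent's body size — and where that
boundary sits. It is written for researchers in perception and embodied
cognition who collect object × action endorsement data (from people or from
language models) and want the complete, reproducible analysis chain.

## What it computes

Given a complete binary tensor of judgments (participant × action ×
object), the pipeline produces:

* **Affordance vectors** — per object *o*, the endorsement proportion
  `p(o, a)` for each of the 14 actions *a*.
* **Representational similarity matrix** — `R[i, j] = cor(p(i, ·), p(j, ·))`
  (Pearson), with hierarchical clustering (Euclidean, complete linkage) of
  the similarity profiles.
* **Rank curve** — `r_i = cor(v̄_i, v̄_{i+1})` between the mean affordance
  vectors of neighboring size ranks (ranks bin the object diagonal on a log
  scale), with SE `√((1 − r²)/(n − 2))`, `n = 14`.
* **Trough statistic** — `T = (r_{i−1} + r_{i+1})/2 − r_i`, the depth of
  the dip at site *i*, tested by permutation of the object-to-rank
  assignment: `p = (1/N) Σ I(T_perm ≥ T_obs)`.
* **Neighboring-pair contrasts** — Steiger's Z for dependent overlapping
  correlations (one-tailed), Zou's interval, and a closed-form normal-prior
  Bayes factor on the Fisher-z difference (H0 ~ N(0, 1), H1 ~ N(2, 1)).
* **Object-level boundary estimate** — scanning all same- and
  adjacent-rank object pairs in a rank window, the mean pair size (cm) of
  the rank composition with the lowest mean affordance similarity, with a
  percentile-bootstrap CI.
* **Size-similarity control curve** — `1 − (d_j − d_i)/d_i` across ranks,
  showing that physical size changes smoothly where affordance similarity
  collapses.

A synthetic generator (`simulate_judgments`) draws Bernoulli judgments
under a logistic boundary model for an agent of any body size (human ≈ 150
cm diagonal, cat 77, elephant 577), so every statistic can be validated
against known ground truth.

## Worked example

```r
library(affbound)

cfg <- analysis_config(n_permutations = 1000, seed = 42)
gen <- generator_config(n_participants = 200, agent_size_cm = 150, seed = 42)

tensor <- simulate_judgments(gen, cfg)   # 200 x 14 x 24 binary judgments
report <- run_analysis(tensor, cfg)
print(report)
```

```
<aff_report> affordance-boundary analysis
  24 objects x 14 actions, n = 200 participants
  neighboring-rank similarity curve:
    r(2,3) = +1.000 (se 0.007)
    r(3,4) = +0.999 (se 0.011)
    r(4,5) = -0.998 (se 0.016)
    r(5,6) = +0.999 (se 0.014)
    r(6,7) = +1.000 (se 0.005)
    r(7,8) = +1.000 (se 0.004)
  trough at ranks 4-5: T_obs = 1.998, permutation p = 0.012 (N = 1000)
  object-level boundary: 164.5 cm (composition (4,5))
```

Reading this: affordance similarity between neighboring size ranks is high
everywhere except between ranks 4 and 5, where it collapses — the trough.
Its depth (`T_obs = 1.998`) is far beyond what shuffled object-to-rank
assignments produce (`p = 0.012` at N = 1000 permutations), and the
object-pair scan puts the boundary at 164.5 cm, next to the simulated
agent's 150 cm body diagonal. Rerunning with `agent_size_cm = 77` (cat) or
`577` (elephant) moves the detected trough to ranks 3–4 or 6–7.

Per-contrast statistics live in `report$comparisons` (Z, one-tailed p,
BF10 per neighboring-pair contrast), and `write_report(report, dir)` writes
`report.json` plus CSV/JSON artifacts of every stage. Real data enter
through `read_responses("responses.csv", "objects.csv", "actions.csv")`. A
thin CLI wraps the same functions:

```sh
Rscript inst/cli/affbound.R run --out-dir out --seed 1 --agent-size 150
```

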