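---
title: "An individual-based model of sex-allocation evolution in a polyembryonic parasitoid"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{An individual-based model of sex-allocation evolution in a polyembryonic parasitoid}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(polywasp)
```

## The biological problem

*Copidosoma koehleri* is a polyembryonic, haplodiploid egg–larval
parasitoid of the potato tuber moth. Each egg laid into a host cleaves
into a clone of genetically identical, same-sex wasps; female clones are
larger than male clones (about 45.7 vs 32.4 emerging adults), and female
clones contain a sterile soldier larva that attacks unrelated
competitors inside the host. Hosts are often parasitized twice
(superparasitism), usually by different females, so a host can hold
male and female clones of different maternal origin. Mating can happen
among brood-mates at emergence and/or after dispersal.

These features pull sex allocation in opposite directions. Mating among
brood-mates creates Local Mate Competition, which favors daughters.
Soldier aggression and the smaller male clones create an asymmetric
within-host competition, which — by a Local-Resource-Competition
argument — can favor overproducing the weaker sex, i.e. sons. Because
the life history is too intricate for a clean analytical treatment, the
package takes the simulation route: it evolves the sex-allocation rule
itself, by competition among random candidate strategies, and lets the
population dynamics decide.

## Model structure

Generations are discrete and non-overlapping. One generation
([`step_generation()`]) consists of:

1. **Host presentation and acceptance.** A fresh cohort of
   `host_count` hosts is created. For each of `lifespan` time steps,
   every living female is shown one uniformly random host (females are
   processed in a fresh random order each step). A host's
   attractiveness is `max(0, 1 - egg_count_influence * eggs)`; the
   female lays one egg iff attractiveness *strictly* exceeds her
   `host_acceptance_threshold`. Low thresholds therefore admit
   already-parasitized hosts — the model's superparasitism dial.
2. **Sex choice.** A mated female senses the host state at her
   information level — `"none"` (empty/parasitized), `"relatedness"`,
   or the full `"sex_and_relatedness"` cross — and lays a male egg with
   the probability her heritable `sex_choice` assigns to that state.
   Virgin females, having no sperm, lay only male (haploid) eggs.
   Kinship is operationalized as shared natal clone: eggs laid by the
   observer or her clone-sisters count as related.
3. **Brood resolution.** A host with more than `host_limit` eggs dies
   prematurely with everything in it. Otherwise every egg proliferates
   into a clone whose adult count is drawn from a normal distribution
   (truncated below at zero, rounded) selected by the egg's sex and
   brood context: single-sex brood, mixed-sex brood of one lineage
   ("related", spared by soldiers), or mixed-sex brood with unrelated
   clones, where soldiers depress male emergence.
4. **Mating.** A fraction `in_host_mating_ratio` of emerging females
   mates with a brood-mate male, partner drawn uniformly over the
   males' remaining fertilization slots; if `dispersal_mating` is on,
   unmated females are then matched to males in the population-wide
   pool the same way. Each male fertilizes at most `virility` females
   (`virgin_son_virility` if his mother was virgin). Females left over
   stay virgin into the laying phase.
5. **Inheritance.** Daughters receive `w * father + (1 - w) * mother`
   of every sex-choice probability (`w` = `strategy_inheritance`);
   sons, haploid, copy their mother exactly. There is no mutation, so
   all evolved values stay inside the convex hull of the founders'.

## Parameter defaults and where they come from

| parameter | default | units | rationale |
|---|---|---|---|
| female / male single-sex clone size | 45.7 ± 10.9 / 32.4 ± 10.4 | adults/clone | field estimates for this species |
| related mixed clone sizes | same as single-sex | adults/clone | soldiers kill only unrelated competitors |
| unrelated mixed clone size | F 40 ± 10, M 20 ± 8 | adults/clone | stand-ins calibrated so males are ≈ 1/3 of mixed-brood adults, the observed proportion; the exact values are not published |
| `lifespan` | 20 | eggs (= time steps) | females parasitize ≈ 20 hosts in their first day |
| `host_limit` | 3 | eggs | stand-in; 4+ eggs kill the host |
| `egg_count_influence` | 0.3 | attractiveness/egg | with the default threshold grid this spans 1–4 accepted eggs per host |
| `host_acceptance_threshold` | 0.5 (sweeps: 0.05–0.85) | — | swept; low = heavy superparasitism |
| `virility` | 2 | females/male | see below |
| `virgin_son_virility` | 0 | females/male | "sons of virgins have lower virility"; 0 makes virginity costly across two generations |
| `strategy_inheritance` | 0.5 | — | symmetric parental blending |
| `initial_wasp_count` | 100 | females/strategy | tournament seeding convention |

The single-sex clone sizes are empirical; the mixed-brood values,
`host_limit`, and the mating capacities are modeling choices, stated
here so they can be challenged. They are all overridable through
[`strategy()`], [`survival_distributions()`] and the YAML configuration.

**Why a small virility matters.** If every male can fertilize
essentially unlimited females, the egg-level Fisher condition pins the
evolutionarily stable allocation at 1:1 no matter how asymmetric
post-investment survival is: halving a male clone halves each male
egg's paternity share and the loss cancels out of the equilibrium. For
the developmental asymmetry to feed back on the realized sex ratio,
male mating capacity must be able to run out. With `virility = 2` a
population at the observed mixed-brood adult ratio (1/3 male) sits at
the edge of mate limitation: any further soldier attrition of males
leaves part of the female pool virgin, and virgins can lay only male
eggs. Setting `virgin_son_virility = 0` makes those forced sons
reproductive dead ends, so virginity is genuinely costly and the
male-egg surplus it generates is self-limiting rather than explosive.
This pair of values is the package's calibration of an unpublished
parameter set; it is the regime in which soldier-driven male mortality
can express itself in the primary sex ratio at all.

## Evolving the allocation: tournament and ancestry accounting

[`tournament()`] draws `n_strategies` (default 125) random viable
candidates — `sex_choice` values i.i.d. uniform on `[0, 1]`, candidates
redrawn until a single-strategy population survives a 25-generation
screen — splits them into random subsets of 5, and lets each subset
compete in one shared environment ([`run_round()`]), each strategy
seeded with 100 mated females. Winners are re-split and re-run until
one strategy remains: 125 → 25 → 5 → 1. [`replicate_tournaments()`]
repeats this with derived seeds and reports mean ± SD.

Because inheritance is blending, "which strategy took over" needs care.
Every individual carries an ancestry vector over the founders, blended
by exactly the same rule as the strategy values (daughters: `w` from
the father, `1 - w` from the mother; sons: all from the mother). A
founder's population share in a generation is its mean ancestry weight
over adults — equivalently its weight in the population-mean strategy —
and the round's winner is the founder with the highest mean share
across generations (fitness as long-term population share). A
maternal-line head count would silently discard all transmission
through sons, which in a haplodiploid model biases selection toward
daughters. A round ends early once the population is homogeneous
(every founder's ancestry weight constant across adults to within
0.001 for 10 consecutive generations) — the blending analogue of
fixation — or at `max_generations`.

Because the model never defines a single scalar "allocation" of a
multi-state strategy, two summaries are reported side by side: the
winner's empty-host sex-choice value (`alloc_empty`) and the primary
sex ratio actually realized over the closing generations of the final
round (`realized_primary`, with `realized_secondary` alongside). The
realized ratios are the model's emergent outputs — the proportion of
male eggs laid and of adult males — and they include eggs that virgin
females were forced to lay; the scenario contrasts below act mostly
through that route.

## Scenarios and sweeps

[`scenario_config()`] builds the three canonical scenarios:
`symmetric` (all six survival contexts use the female single-sex
distribution; brood mating), `asymmetric_premating` (default survival;
brood mating) and `asymmetric_postmating` (default survival; dispersal
mating only). [`threshold_sweep()`] crosses a preset with a grid of
acceptance thresholds (default nine, 0.05–0.85), runs replicated
tournaments in every cell, and records instability (extinction during
a round, or no viable candidates — e.g. a threshold ≥ 1, where no host
is ever accepted, or ≤ 0.05, where hosts routinely exceed the egg
limit and die) as data rather than as an error.

## Numerical and procedural choices

* Clone sizes: normal draw, censored at 0, rounded half-to-even —
  `sd = 0` degenerates to a deterministic `round(mean)`.
* Acceptance is strict (`>`), so the egg load any threshold admits is
  the smallest count failing the test; the engine computes it in
  closed form and saturated hosts short-circuit the presentation loop.
* Mate choice is uniform over remaining fertilization slots, so a
  male's chance of a given mating is proportional to his remaining
  capacity; mating order among females is randomized.
* All randomness flows from one seed through R's RNG;
  [`derive_seed()`] fans it out to replicates and sweep cells, keeping
  every derived seed below 2^31. The generation kernel is implemented
  in C++ (Rcpp) against R's RNG, so runs are bit-reproducible under
  `set.seed()`.
* Founding females of a strategy are treated as fertilized by males of
  their own strategy; founders are mutually unrelated.

## The census estimators

The experiment-side module inverts brood sex compositions into sex
ratios. With brood counts `n_m`, `n_f`, `n_x` (all-male, all-female,
mixed), the mixed-brood proportion estimates the superparasitism
frequency. Assuming a fraction `p` of single-sex broods came from two
same-sex eggs and every mixed brood from one male plus one female egg,
each single-sex brood represents `1 + p` eggs in expectation, so

$$\hat r \;=\; \frac{(1+p)\,n_m + n_x}{(1+p)(n_m+n_f) + 2\,n_x}.$$

That expectation form is the default; an integer-allocation variant
(`ceiling(p * n)` broods counted as doubles) is available because the
defining sentence fixes the assumption but not the algebra. The
secondary (adult) ratio is `(wasps in all-male broods + 1/3 of wasps
in mixed broods) / all wasps`, the conventional 1/3 being the male
share of mixed-sex broods. [`generate_brood_census()`] produces
synthetic censuses with exactly the statistical structure these
estimators assume — one or two eggs per host, i.i.d. egg sexes,
context-matched emergence — and deliberately nothing else (no
evolution, no soldiers beyond the survival contexts, no host-quality
covariates), which is what makes the estimator-recovery tests
interpretable.

## What the tests do and do not show

The test suite checks the engine against an independent rule-by-rule
enumeration on degenerate configurations (zero-variance survival, 0/1
sex choices, fixed host presentation), the clone-size calibration
(sample means of 10,000 draws; male share of simulated unrelated mixed
broods ≈ 1/3), the 25/5/1 tournament structure at full candidate count,
estimator algebra on fixed censuses, generator→estimator recovery of a
true ratio, and the directional scenario contrasts at a reduced scale
chosen to keep the suite fast (20 candidate strategies, 200 hosts,
100-generation round cap, 3 replicates, 5 thresholds).

Two limitations deserve emphasis. First, blending inheritance without
mutation halves the strategy variance roughly every generation, so a
round exhausts its heritable variation within ~15–20 generations;
selection that is weak relative to that clock leaves the evolved blend
near the founders' mean of 0.5. The asymmetric-scenario male bias is
robust to this because it is generated by the virgin-forcing feedback
rather than by movement of the heritable allocation; the symmetric
scenario's female bias, in contrast, relies on that movement
(invasion analyses show selection at 0.5 is female-ward there), and at
the reduced test scale the evolved symmetric ratio typically lands
within noise of 0.5 rather than clearly below it. Second, the
synthetic data — both the simulator and the census generator — encode
the package's own assumptions; passing tests demonstrate internal
consistency and calibration, not that real *C. koehleri* populations
behave this way.

## A minimal session

```{r quick, eval = FALSE}
cfg <- simulation_config(host_count = 200, host_acceptance_threshold = 0.35)
sim <- run_simulation(cfg, strategy(0.5), seed = 1)
tail(sim$stats, 3)
sim_sex_ratios(sim)

sw <- threshold_sweep("asymmetric_premating", replicates = 3,
                      base_seed = 1, n_strategies = 20,
                      max_generations = 100)
sw$summary
```
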