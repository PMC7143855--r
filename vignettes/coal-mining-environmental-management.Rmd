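---
title: "Modelling environmental management of a coal mining area with minesd"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling environmental management of a coal mining area with minesd}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(minesd)
```

## The problem and the model

A coal mining area produces several kinds of environmental damage at roughly
constant monthly rates: airborne dust and waste gas, solid waste (coal
gangue, boiler ash, household garbage), polluted water (wastewater, mine
water, gangue leachate), destroyed vegetation (construction, waste-rock
piling, open-pit mining, roads) and damaged land (subsidence, excavation). A
fixed monthly environmental investment `E` (50, in units of ten thousand
yuan) must be split among five treatments. The question the package answers
is an allocation question: **given the budget, which split of `E` among the
five subsystems yields the best overall environmental quality over a
two-year horizon?**

Each subsystem is a one-stock system-dynamics model. Writing `S` for the
pollution stock of a subsystem, `P` for its (constant) monthly production
and `f` for its treatment's *technical factor*, the discrete level equation
is the classic DYNAMO/Vensim form

```
S[t + dt] = S[t] + dt * (inflow[t] - outflow[t]),   inflow[t] = P,
outflow[t] = S[t] * f            (default, "stock" removal basis)
outflow[t] = P * f               ("literal" removal basis; solid & water only)
```

integrated by fixed-step explicit Euler (`dt` = 1 month, horizon 24 months),
with every rate and auxiliary evaluated from the state at the start of the
step. The technical factor is the subsystem's share of the budget:
`investment = p * E`, `f = investment / E`, which cancels algebraically to
the allocation proportion `p`. The chain is kept in the model (as two
auxiliaries) rather than pre-simplified, because it is the point at which a
nonlinear investment-to-technology response could later be substituted;
`technical_factor()` computes both forms and asserts their equality.

The five subsystems are **independent by assumption**: no variable of one
appears in another's equations, and the budget `E` is the only shared
constant. This is a deliberate simplification — in reality, e.g., solid
waste leaches into water (the model does route coal gangue into both the
solid-waste and the water production sums, following the published
equations) — and it is what makes the scenario experiment interpretable:
changing one proportion provably cannot move any other subsystem's
trajectory, which the test suite checks bit-for-bit.

### The removal-basis switch

The published rate equations are inconsistent about what the treatment flow
is proportional to: the air treatment drains the *stock*
(`stock * factor`), while the solid-waste and water treatments as printed
drain the *production* (`production * factor`). The package defaults to the
stock basis for all five subsystems (`mine_config(removal_basis =
"stock")`): it is the only uniform reading under which treated stocks
saturate toward the equilibrium `P / p` instead of growing linearly forever,
which is the qualitative behaviour the study describes. The verbatim reading
is first-class as `removal_basis = "literal"` (under it a subsystem's net
inflow is the constant `(1 - p) * P`), and both are tested.

### Units and harmonization

Stocks and production constants are carried with their printed units as
inert labels; the package performs no dimensional analysis (the source data
itself measures air and water pollution in m², which we treat as abstract
nonnegative quantities). One correction is applied by default: the
vegetation and land production constants are printed in m² while their
stocks are in units of 10,000 m². With `unit_harmonization = TRUE` (default)
those constants are divided by 10⁴ (vegetation damage production becomes
4.1413, land damage 1.32 per month); without it the vegetation stock would
be swamped by a factor-10⁴ unit artifact within a month. `FALSE` reproduces
the raw printed magnitudes.

Two further data gaps are handled explicitly: *living garbage* appears in
the solid-waste production sum but has no published value — it defaults to
0 and is overridable; the waste-gas aggregate (1514) can be replaced by its
NO₂/SO₂/CO components when all three are supplied.

## The quality assessment

The source defines overall environmental quality as the average of five
per-subsystem qualities, but the per-subsystem formula itself is in an
appendix that is not available. The package therefore reconstructs it and
documents the choice: per-subsystem quality is the **relative stock
reduction against the zero-investment baseline**,

```
q_i(t) = (B_i(t) - S_i(t)) / B_i(t),
```

where `B_i` is the stock under the all-zero allocation. This maps "no
treatment" to 0, complete removal to 1, and — crucially — is scale-free, so
subsystems whose stocks differ by four orders of magnitude and carry
different units contribute comparably to the mean. Its consequence should be
understood before reading any ranking: `q_i` is *concave* in the subsystem's
own proportion (the first tenths of investment remove the most), so under
this formula spreading the budget evenly tends to beat concentrating it, and
the scenario report computed by the package ranks the equal split (case 6)
first at month 24, ahead of the five concentrated cases. A different
appendix formula could legitimately order the concentrated cases otherwise;
for that reason `rank_scenarios()` *records* the ordering together with the
active options (removal basis, unit harmonization, ranking time) and nothing
in the package asserts any particular overall ordering. The per-subsystem
verdicts are formula-independent and are asserted: the case that boosts a
subsystem to a 0.4 share holds that subsystem's minimal stock at every
month.

The ranking time is a second open choice: the report defaults to reading the
overall quality at the final month and also supports averaging it over the
horizon (`aggregate = "mean"`); both are pure functions of the scenario
results.

## The causal loop diagram

`mining_cld()` carries the system's signed influence diagram: 15 nodes and
24 edges linking GDP, the environmental investment, the five treatment
investments, the five quality/pollution indicators, pollution-control cost,
mining revenue and overall ecological quality. The printed loop listings of
the source contain three sign inconsistencies (the same edge appearing with
both signs in different loops); the fixture uses the unique semantically
consistent assignment — investments improve their indicator, good indicators
lower cost and raise ecological quality, pollution indices do the opposite,
cost lowers revenue, revenue raises GDP, GDP raises the budget, and a high
ecological quality relaxes it. Under that table the diagram has exactly ten
elementary loops: the five that close through the economy
(cost → revenue → GDP) are reinforcing, and the five that close through
ecological quality are balancing, matching the narrative classification.

Loop enumeration is a min-node-rooted depth-first search: cycles are found
rooted at their lexicographically smallest node (visiting only
not-smaller nodes), which yields each elementary cycle exactly once, already
in canonical rotation; the list is then sorted lexicographically by node
sequence, making the output deterministic. The economic side of the diagram
(GDP, revenue, cost) exists *only* as this signed graph — no equations are
available for it — so it is never simulated.

```{r loops}
print(enumerate_loops(mining_cld()))
```

## The scenario experiment and sensitivity analysis

`default_scenarios()` is the published six-case design: cases 1–5 each boost
one subsystem to a 0.4 share with the others at 0.15; case 6 splits the
budget evenly at 0.2. Every case sums to exactly 1. `run_scenarios()`
simulates all cases plus the shared zero-allocation baseline over the
24-month grid and scores them with the quality assessment;
`rank_scenarios()` produces the ranking report.

```{r scenarios}
res <- run_scenarios()
rank_scenarios(res)
```

`oat_sensitivity()` is the one-at-a-time scan: one subsystem's proportion
varies over a grid while the other four sit at a reference share (0.15).
Because the subsystems are independent, a grid point such as 0.5 is a
well-defined single-subsystem experiment even though 0.5 + 4 × 0.15 exceeds
the joint budget; `allocation_policy()` therefore exposes an
`enforce_budget` switch that the scan disables, while the budget constraint
remains enforced for ordinary policies. Along any increasing grid the final
stock falls and the final quality rises strictly — analytically, because the
one-step map `S ↦ S(1 − p) + P` is decreasing in `p` and its iterates
preserve the ordering for `p ≤ 1`.

```{r oat}
oat_sensitivity(subsystem = "air", proportion_grid = c(0.1, 0.25, 0.4))
```

## Numerical choices and degenerate inputs

* The expression language of the engine is deliberately tiny — `+ - * /`,
  parentheses, numbers and names — because the model needs nothing else; no
  conditionals, lookups or delays. Expressions are parsed once per
  simulation and validated structurally; `validate_model()` returns one
  diagnostic per violation (unknown name, duplicate, auxiliary cycle via
  topological sorting, missing stock) and never throws.
* Division by zero inside an expression surfaces as an evaluation error
  naming the variable and, during a simulation, the time step.
* Quality is undefined where a baseline stock is zero; with the default
  parameters every baseline is positive and nondecreasing, and the error is
  raised explicitly otherwise.
* Ranking ties break toward the lower case id; grid times are matched with
  a 1e-9 tolerance.
* `p = 1` is valid and means complete removal of the basis quantity each
  month: the stock then equals the fresh production from month 1 onward.
* Everything is deterministic — there is no randomness anywhere in the
  engine, the experiment, or the I/O (manifests can drop their timestamp for
  byte-identical reruns).

## What the defaults emulate, and limitations

The default parameter set reproduces the published Shanxi coal-mining-area
case study: all production constants, the budget, and the five initial
stocks are embedded, so `mine_config()` with no arguments *is* the study's
model, and an empty configuration file loads to exactly these values. The
simulations in the package's tests and the acceptance script run this full
model: a 25-point monthly grid, five stocks, six cases plus baseline —
small enough that every check runs in seconds.

What passing tests show is internal: the integrator matches the geometric
closed form, the subsystems are independent, treatment monotonically
improves its own subsystem, and the scenario machinery is deterministic.
What they cannot show is external validity: constant production rates, a
constant monthly budget (the source never states the investment's period; we
treat it as per-month for the whole horizon), a linear
investment-to-technology response, no cross-subsystem pollution transport,
and a reconstructed quality formula are all simplifications, and the model
is not calibrated against independent Shanxi monitoring data. Conclusions
about *which* concentrated allocation is best are sensitive to the quality
formula; conclusions about per-subsystem dose-response are not.
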