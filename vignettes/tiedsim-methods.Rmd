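---
title: "Modelling community climate-change vulnerability under environmental distancing and local knowledge"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling community climate-change vulnerability under environmental distancing and local knowledge}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tiedsim)
```

## The problem

Small remote communities that depend directly on their environment — for
example, on rivers, creeks and water tanks for freshwater — build a working
knowledge of their local climate through that dependence. When a technology
such as a piped municipal water system replaces the traditional practice, the
daily contact that produced this knowledge disappears. This *technology-induced
environmental distancing* (TIED) can leave a community confident in
perceptions of its climate that no longer match what is happening. Working
against it, the transfer of *local knowledge* (LK) — from elders to younger
community members, and between peers — can keep experience of past conditions
alive in people who never lived it.

`tiedsim` simulates this tension with an agent-based model. A community of
agents observes three monthly climate variables (temperature, precipitation,
runoff). Each agent compares the current month with the mean of that calendar
month over the years it has personally experienced — its *known history* —
and the community's individual perceptions are aggregated into a weighted
consensus. Community **vulnerability** for variable $x$ at a step is

$$v_x = q_x - P_{c,x},$$

the gap between the *recorded change* $q_x$ (current value minus the mean of
that calendar month over the full record up to the previous year) and the
*community perception* $P_{c,x}$. A community that misjudges how much its
climate has changed — in either direction — is vulnerable; trajectories of
$|v_x|$ over an 81-year simulation are the model's primary output.

## Agents, demographics and engagement

Each agent carries an age (18 or older), an age class (younger Y: 18–39,
middle-aged M: 40–59, older O: 60 and over; 60 is assigned to O so the
classes partition all adult ages), a behavioural type, and an engagement
fraction $t_{TRU} \in [0,1]$, the share of time spent in traditional resource
use. The three types reflect how individuals relate to community wellbeing:
*alpha* agents initiate and sustain community efforts, *beta* agents are
concerned but do not initiate, *gamma* agents are self-serving. Influence on
the consensus ($w_p$, from 1.0 for older alphas down to 0.0 for younger
gammas) and knowledge-transfer fidelity ($w_k$, from 1.0 between alphas to
0.0 for any gamma recipient) are both type-structured; `default_weights()`
prints the tables.

Mortality is evaluated once every twelve simulated months as

$$m = \left(\frac{\texttt{age}}{\max \texttt{age}}\right)^{e},$$

with the denominator the age of the community's current eldest member —
a proxy for local life expectancy — and Euler's number as the exponent. The
eldest agent therefore dies with certainty at each annual update. Because the
denominator is re-evaluated each year against a population whose maximum age
the rule itself keeps removing, the age distribution contracts over the first
simulated decades until the community is young and turnover is rapid. This is
a direct consequence of taking the mortality rule literally; we keep it as
the model's defining demographic assumption and expose the exponent
(`mortality_exponent`) so its effect can be studied. Each deceased agent is
replaced, the same simulated year, by an 18-year-old of the deceased's type
(a family successor) whose engagement equals the mean over surviving
younger-class agents and whose known history is empty — population size never
changes, by construction: the model isolates age/social structure from
population growth, which it deliberately does not represent.

Engagement follows the *age class*, not the individual: each scenario (A–F,
`default_scenarios()`) prescribes an initial $t_{TRU}$ and an annual decline
in percentage points per class, and every agent takes its current class's
scheduled value, clamped to $[0,1]$. We chose the class-level reading rather
than having each agent accumulate its own decrements across class
transitions for two reasons: the scenarios are defined as class trajectories
("engagement of the older class is held constant"), which only class-level
scheduling preserves once agents move between classes; and under the
individual-accumulation reading every trajectory collapses to zero
engagement for all classes within decades, making the six scenarios
asymptotically indistinguishable.

## Known histories and perception

A year enters an agent's known history only if the agent could have
experienced it (it falls within the record and within the agent's adult
lifetime — experience accrues from age 18) and if an exposure draw succeeds:
the year is admitted when $t_{TRU} > \delta$, $\delta \sim U[0,1)$, one draw
per agent-year at first eligibility. Admitted years are remembered
permanently; histories are shared across variables and months, since
exposure is physical presence in a year, not acquaintance with one variable.
The current month's observation is available to every agent regardless of
engagement (set `gate_current_observation = TRUE` to require an exposure
draw for it as well; we default to universal observation because the model's
distancing mechanism is about the *accumulated record*, not about being
outdoors this month).

An agent's perception of change is the current value minus its history mean
for that calendar month; an empty history leaves the perception undefined
and the agent out of the consensus. The consensus is the $w_p$-weighted mean
of defined perceptions (falling back to the unweighted mean if all
participating weights are zero, and to a flagged 0 if no perception is
defined). It is therefore always inside the convex hull of the individual
perceptions.

## Local-knowledge transfer

When LK is enabled, each agent annually selects at most one knowledge
provider: among agents whose known history covers a strictly longer period
(by default, more known years; a span-based alternative is available via
`lk_eligibility`), it picks the one maximising
$(\texttt{age}/\max\texttt{age}) \times t_{TRU}$ — experience defined jointly
by age and engagement — with ties going to the smallest agent id.
Transfer then has two components:

1. **Knowledge acquisition** (annual, persistent): each year known to the
   provider and unknown to the recipient is adopted with probability $w_k$.
   Two alphas share fully; a gamma recipient acquires nothing. Acquisition is
   simultaneous across the population (all transfers read the histories as
   they stood before the round) and acquired years are kept for life. This is
   what lets knowledge of the early record outlive the agents who
   experienced it: it cascades down generations even as every individual
   carrier dies.
2. **Perception blending** (monthly): the recipient's perception becomes
   $w_k\,p_{provider} + (1-w_k)\,p_{own}$; an agent with no perception of its
   own adopts $w_k\,p_{provider}$.

The blending rule alone was our initial design, but it proved insufficient:
because it is transient, a provider's death erases their influence
immediately, community knowledge of the early record still dies with the
last agent who lived it, and enabling LK then changes long-run vulnerability
by well under one percent — the mechanism cannot keep a community informed.
Persistent acquisition, which matches the model's description of transfer as
*knowledge passed* between agents, produces the expected qualitative
behaviour and is the default; blending is retained as the within-month
combination rule.

## Climate forcing

The bundled generator produces a dense monthly series for 1960–2090 per
variable as *linear trend + seasonal cycle + noise*:

* the trend is linear in the calendar year and anchored so that the
  noise-free annual means of the first and last five years average exactly to
  the configured endpoint targets (defaults: temperature −4.4 → 3.9 degrees,
  precipitation 23.9 → 45.0, runoff 5.6 → 13.0 depth per month — endpoint
  differences of 8.3, 21.1 and 7.4, a western-Alaska coastal profile);
* the seasonal cycle is a single sinusoid with period 12 that sums to zero
  over any calendar year (so it never perturbs annual means), peaking in
  July for temperature, August for precipitation and June for runoff
  (defaults; amplitudes 15, 12 and 5 units);
* noise is i.i.d. Gaussian per month (defaults: sd 2, 6 and 2 units),
  and precipitation and runoff are clipped at zero after summing.

Seasonal amplitudes and noise levels are package defaults chosen once to
give a realistic sub-arctic annual cycle and inter-annual spread relative to
the endpoint targets; the calibration anchors are the only externally given
quantities. Units are treated as abstract (degrees and depth per month). The
generator emulates the *structure* a climate-model forcing would have —
monthly resolution, seasonal cycle, upward trend in all three variables —
but not its spatial structure, autocorrelated weather regimes, or
non-sinusoidal seasonality. A user-supplied forcing can be dropped in as a
CSV (`load_climate_table()`, columns
`year,month,temperature,precipitation,runoff`), so conclusions that depend
on a particular realization can be checked against real data.

## Simulation design and numerical choices

A run steps monthly from January 2010 to December 2090 against a record
reaching back to 1960. Annual events fire at each January step in a fixed
order: aging (and age-class refresh), scheduled engagement update, mortality
(eldest age evaluated once, before any death), replacement, extension of
known histories by the newly completed year, then provider selection and
knowledge acquisition. The first simulated January initializes histories
(one exposure draw per candidate year) before any perception is computed.
The recorded-change baseline is every year from 1960 up to, but excluding,
the current year, so the "truth" each perception is compared against grows
with the simulation.

Replicates use seeds `base_seed + 0, 1, …`; every random element —
community initialization, exposure draws, mortality, acquisition — derives
from the replicate seed, so a (configuration, seed) pair fixes every output
value. By default the generated climate is frozen across replicates (one
realization, from the climate configuration's own seed), so replicate spread
isolates the social process; set `freeze_climate = FALSE` to let each
replicate draw its own realization. Results average the signed vulnerability
and its magnitude pointwise across replicates, with standard deviations; both
are reported because the two summaries answer different questions (bias of
the consensus versus typical size of the misperception).

Default study conditions: population 152; type proportions
alpha/beta/gamma = 0.35/0.45/0.20 and age-class proportions
Y/M/O = 0.45/0.35/0.20 with ages uniform within class up to 80 (the site
demographics behind the published model are not numerically available, so
these are package defaults, chosen once as plausible for a small remote
community and kept configurable); 30 replicates; weight tables as printed
above. The perfect-knowledge benchmark (scenario A with mortality disabled
and a community old enough to have experienced the whole record —
`min_initial_age = 68` in 2010) yields $v_x = 0$ at machine precision at
every step, with or without LK; it is the model's ground-truth check.

Degenerate-input rules are explicit: an empty year set raises a distinct
"no history" condition; all-undefined consensus is 0 and flagged; transfer
from an undefined provider is rejected at the operation level and skipped in
the engine (it can only arise when current-month observation is gated);
provider ties break to the smallest id; all engagement values clamp to
$[0,1]$.

## What the tests show — and what they do not

The test suite verifies the generator's exact endpoint calibration, the
zero-vulnerability benchmark, the weight tables, brute-force equivalence of
the vectorized consensus / provider-selection / recorded-change paths, the
structural invariants (constant population, engagement bounds, certain death
of the eldest, gamma-recipient invariance, consensus convexity, bit-level
determinism under a seed), and three directional findings at the default
conditions with 30 replicates: enabling LK lowers final-decade mean $|v|$
in scenario A; without LK, a youth decline (C) is worse than an elder
decline (D); with LK the ordering flips. The directional findings are
claims about these default conditions and seeds, not theorems: they
compare stochastic simulations at a fixed design, and the C/D contrast in
particular is a statement about which class's engagement matters once
knowledge can or cannot be passed on.

Because the forcing is synthetic and the site demographics are package
defaults, passing tests demonstrate the *mechanisms* — knowledge loss
through demographic turnover, distancing through exposure-gated memory,
mitigation through transfer — not a reproduction of any particular
community's published trajectories. One genuine non-finding is worth
stating: with LK off, long-run mean $|v|$ is *not* monotone in engagement
across its whole range. A sparse history is an unbiased subsample of the
same age window (it adds variance, not bias), and at very low engagement the
young, window-truncated agents drop out of the consensus entirely, which can
even reduce aggregate bias; the distancing penalty is clear only near full
disengagement. The relevant test asserts the contrast at that end.

## Known limitations

* The mortality rule's contracting age distribution (above) means long-run
  results describe a young, fast-turnover community; the elder-anchored
  dynamics dominate only the first few simulated decades.
* No migration, births, household or network structure; types change only by
  inheritance at replacement.
* Transfer moves year-knowledge and scalar perceptions, not richer content;
  there is no forgetting and no error in transmission.
* The generator's trend/seasonality/noise decomposition is deliberately
  minimal; studies sensitive to weather persistence or changing seasonality
  need a supplied forcing.

## Reproducing the headline numbers

`scripts/acceptance.R` (repository root) regenerates the calibrated forcing,
runs the perfect-knowledge benchmark, and computes final-decade mean $|v|$
for the six scenario/LK contrasts at 30 replicates, writing one JSON object;
see the README. A full 81-year, 152-agent run takes well under a second, so
the complete script is a few minutes of compute.
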