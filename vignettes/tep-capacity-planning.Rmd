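---
title: "Capacity and cost planning for tele-emergency physician services"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Capacity and cost planning for tele-emergency physician services}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tepcap)
```

## The planning problem

A tele-emergency physician (TEP) is a remote physician who supervises
paramedics over live data links — vital signs, structured assessments,
ECGs — and can, for example, delegate medication or clear a patient to
stay at home. In sparsely populated regions each district could run its
own 24/7 TEP unit, but demand per district is low: at the calibrated
defaults of 3.96 consultations per day with a mean duration of 24.6
minutes, a single-position unit carries an offered load of only

\[
a = \lambda \, E[S] = \frac{3.96 \times 24.6}{1440} \approx 0.0677
\ \text{Erlang},
\]

so the physician is idle about 93% of the time while the district still
pays for the full 24/7 position. `tepcap` quantifies this trade-off:
how many 24/7 TEP positions does a pooled, centralized service need to
keep waiting acceptably rare, and what does each deployment option cost
per district and per year?

## Queueing model

TEP demand is modeled as an M/M/k queue with infinite buffer and FIFO
discipline: Poisson arrivals at rate $\lambda$ (per day at the
interface, per minute internally; 1 day = 1440 min throughout), i.i.d.
exponential service with mean $E[S]$ minutes, and $k$ statistically
identical servers (staffed 24/7 physician positions). The key
performance quantity is the probability that an arriving case finds all
positions busy and must wait — Erlang's C formula,

\[
C(k, a) = \frac{k\,B(k,a)}{k - a\,(1 - B(k,a))},
\qquad
B(k, a) = \frac{a\,B(k-1,a)}{k + a\,B(k-1,a)},\ B(0,a)=1 ,
\]

where $B$ is the Erlang B blocking probability computed by its
numerically stable recursion (each iterate stays in $(0,1]$, so the
recursion is safe for thousands of servers where the naive factorial
sum overflows; the factorial sum serves as the independent oracle in
the test suite). Waiting and congestion measures follow from the
standard identities $W_q = C/(k\mu - \lambda)$, $W = W_q + E[S]$, and
Little's law $L = \lambda W$, $L_q = \lambda W_q$, which the
implementation satisfies exactly by construction.

A *service-level target* such as "delayed physician contact in at most
5% of cases" is formalized as $C(k,a) \le \tau$ with an inclusive
threshold — the standard call-center reading of a delay target. The
alternative reading $P(\text{wait} > t) \le \tau$ for some patience
$t > 0$ would need a patience parameter that no published figure pins
down; we therefore bound the probability of *any* wait, which is the
conservative choice (it implies any $P(\text{wait}>t)$ bound at the
same $\tau$). Two inverse problems are provided: `min_servers()` scans
$k$ upward from the stability bound $\lfloor a\rfloor + 1$ (Erlang C is
strictly decreasing in $k$, so the scan terminates at the first
compliant staffing), and `max_arrival_rate()` bisects on the offered
load (Erlang C is strictly increasing in $a$) to relative tolerance
$10^{-9}$. Saturated configurations ($a \ge k$) are never errors: they
return $C = 1$ with infinite waiting measures and a `saturated` flag,
so scenario sweeps cannot abort halfway.

The statement "one TEP center can support N ambulances" is a derived
quantity: it requires the TEP call rate *per ambulance*, which no
published account of the reference deployment prints. `tepcap`
therefore exposes it as a free parameter
(`max_supported_units(k, per_unit_rate, ...)`) rather than defaulting
it.

```{r}
performance(1, demand_model())
min_servers(aggregate_demand(demand_model(), 20), 0.05)
```

## Synthetic call logs

`generate_log()` emulates the EMS IT extract such an analysis would
start from: a homogeneous Poisson arrival process over the horizon,
i.i.d. service durations, and three Bernoulli case attributes at the
calibrated case-mix rates — 17.8% medication delegation, 24.3%
non-transport, 12.3% severe pain (NRS $\ge 7$). Design choices:

* **Stationarity.** Published demand figures give a daily average with
  no hour-of-day or seasonal profile, so a homogeneous Poisson process
  is assumed; calendar effects are deliberately out of scope.
* **Service family.** Exponential by default, matching the M/M/k
  declaration; lognormal (configurable coefficient of variation) and
  deterministic families are provided for M/G/k sensitivity runs with
  the simulator only.
* **Pain-score shape.** Only the severe-tail mass ($P(\mathrm{NRS}\ge 7)$)
  is calibrated; within each bin the score is uniform on $\{7..10\}$ or
  $\{0..6\}$. Any within-bin shape with the right tail mass would do;
  uniform is the minimal-assumption choice.
* **RNG contract.** One root seed is split into independent sub-stream
  seeds for arrivals, services and attributes, so changing a case-mix
  probability (or adding attributes later) never perturbs the arrival
  process — a property the test suite asserts byte-for-byte.

What passing the calibration tests shows is that the generator and the
estimators are mutually consistent at the configured parameters; it
does *not* validate the stationarity or independence assumptions
against real EMS data, which the package never sees.

## Discrete-event cross-validation

`simulate_queue()` re-derives the performance measures from a simulated
sample path instead of the closed forms: FIFO dispatch to the
earliest-free server via the multi-server Lindley recursion, so ties
between a simultaneous arrival and completion resolve deterministically.
Per-arrival statistics (waiting probability, mean wait) are averaged
over arrivals inside the measurement window; time-averaged statistics
(queue length, busy fraction) integrate the piecewise-constant
sample-path processes exactly over the window. Defaults: 7 simulated
warm-up days (three orders of magnitude above the relaxation scale of
the calibrated system) and 50 replications, both configurable;
`replicate_queue()` pools replication means with Student-t 95%
confidence half-widths, which is valid because replications use
independent derived seeds. With exponential service the simulator must
agree with Erlang C within Monte-Carlo error — the suite checks this in
light (a = 0.07), moderate (a = 1.35) and heavy (a = 4.5 on five
servers) traffic, at 60-day horizons chosen so the whole suite stays in
the seconds range — and with deterministic service it reproduces the
Pollaczek–Khinchine halving of M/D/1 waits.

## Cost model

Annual full costs are additive over components of three kinds: `fixed`
(EUR/year, capacity-independent), `jump_fixed` (EUR per staffed 24/7
position per year — the step costs of staffing one more position), and
`variable` (EUR per case). The calibrated decentralized configuration
books EUR 148,876 fixed plus EUR 548,073 per position, an exact
integer sum of EUR 696,949 at one position. The second block is not
split between per-case and step costs in the published accounts, so the
default books it entirely as jump-fixed — this reproduces the one-unit
total at any caseload — and `default_cost_model(variable_share = s)`
re-splits a share $s$ as per-case cost calibrated at the reference
caseload of 3.96 cases/day. Costs are annual; no discounting or
multi-year horizon.

## Scenario engine

`run_scenario()` composes the three modules. Districts are homogeneous
by default (superposition of D independent Poisson streams gives rate
$D\lambda$). The *decentral* mode prices D standalone single-position
units — one position per district by design, whether or not $k=1$ meets
the waiting target, because that is how a standalone unit is actually
operated. The *central* mode staffs one shared center with
`min_servers()` positions and shares the total equally. Variable costs
are priced at the expected annual caseload $D\lambda \times 365$, not a
simulated draw, keeping scenarios deterministic. The reduction column
always compares against the standalone baseline (EUR 696,949/year at
the defaults).

```{r}
sw <- sweep_districts(demand_model(), D_max = 20)
sw[c(1, 2, 5, 10, 20), c("districts", "servers", "p_wait",
                         "total_cost", "cost_per_district",
                         "reduction_vs_standalone")]
```

Because staffing scales sublinearly in D (five positions serve twenty
districts at the 5% target), the per-district cost falls steeply, with
a sawtooth at each staffing step. The published per-district figure of
EUR 57,300 for a 20-district center implies a central total of
EUR 1,146,000/year; the cost parameterization behind it (the center's
own overhead, its staffed positions, the sharing rule) is not printed,
so the engine does not hard-code it. Instead the center's cost model is
a free configuration: for example, central overhead of EUR 150,000
fixed plus EUR 199,200 per position yields exactly EUR 57,300 per
district at D = 20 and k = 5 — a 91.8% reduction — and the CLI test
suite exercises precisely that configuration as a YAML config file.

## Problem sizes and numerical choices

Calibration experiments use 50 replications of one-year logs
(about 72,000 records in total) and, for long-run recovery checks, 20
seeds of ten-year logs; simulator cross-checks use 8–10 replications of
60–90 day horizons. Waits below $10^{-9}$ minutes count as zero when
estimating the waiting probability (guarding against floating-point
ties in the Lindley recursion). Currency amounts are kept exact and
rounded to whole EUR only at report time. Monetary and probability
comparisons in the tests are exact or at $10^{-12}$; stochastic checks
use three confidence half-widths.

## Known limitations

* No time-varying arrival rates in the analytic module; heterogeneous
  hours or seasons would need the simulator plus a demand profile the
  calibration does not include.
* No abandonment, retrials, priorities, or shift-change dynamics; a
  "position" is a continuously staffed 24/7 server.
* The case-mix attributes are generated independently of each other and
  of service duration; real consultations likely correlate severity,
  duration and disposition.
* Clinical outcomes (resuscitation success, diagnostic concordance,
  documentation quality) are outside the model: the package plans
  capacity and cost, not care quality.
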