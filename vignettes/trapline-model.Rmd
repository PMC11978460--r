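---
title: "The traplinr model: route learning, memory and renewal"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The traplinr model: route learning, memory and renewal}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(traplinr)
```

## The question

Central-place nectarivores range from near-random samplers to strict
trapliners that repeat a fixed circuit of feeding sites. `traplinr`
implements a minimal mechanistic account of that continuum: foragers learn
the value of individual *transitions* between locations, choose their next
destination by a noisy value comparison, and carry a short-term inhibition
against immediate returns. Everything else — the routes themselves, their
stability, their collapse under competition — emerges.

## Model structure

**Environment.** A square arena of side $L$ (default 500 m) holds the nest
at the origin and $N$ feeding sites, either uniform over the arena or
clustered in a patch. Each site holds at most $n_{\max}$ µl of nectar
(default 20) and refills linearly from empty in $T_r$ seconds, clipped at
$n_{\max}$. Renewal is continuous and indifferent to bee presence;
depletion within a timestep is applied before renewal is credited.

For patches of density $d$ (sites m⁻²) we use radius
$r = \sqrt{N / (\pi d)}$, the radius at which the disc's area carries $N$
sites at density $d$; a literal reading $r = N/(\pi d)$ of the same
dimensional recipe is exposed as an option (`patch_radius(formula =
"literal")`) but is not the default because it does not have units of
length. Sites are placed area-uniformly on the disc (square-root radius
sampling); the patch centre is drawn uniformly with a one-radius buffer so
the patch always fits. Patch spacing is reported as the Monte-Carlo mean
pairwise inter-site distance (`mean_intersite_distance()`), for which the
uniform disc has the closed form $128r/45\pi$ used as a test oracle; a
nearest-neighbour variant is available since field studies often report
that instead.

**Valuation and learning.** A transition from A to B arriving at time $t$
is valued $v_t(A,B) = n_t(B)\,p_d(A,B)$ with
$p_d(A,B) \propto 1/d(A,B)^2$ row-normalised over destinations.
Expectations start at $Q_0 = \tfrac12 n_{\max} p_d$ and update as
$Q_t = \alpha v_t + (1-\alpha) Q_{t-1}$, only when the transition is
realised. Because the update is a convex combination and
$v_t \le n_{\max}$, every $Q$ stays in $[0, n_{\max}]$; with $\alpha = 0$
the table never moves, which doubles as the no-learning control
($\alpha = 0, \beta = 2$).

$n_t(B)$ is the nectar *standing* at arrival, not the amount collected; the
two differ only when the crop is nearly full. We default to the standing
crop — the site looks just as good even if the bee cannot carry all of it —
and expose `value_basis = "collected"` for the alternative reading.

**Choice.** The next destination is drawn from
$p_c(A,B) = e^{\beta Q(A,B)} / \sum_{B'} e^{\beta Q(A,B')}$ over the sites
not currently inhibited, computed with max-subtraction so that
$\beta Q$ up to $10^4$ is safe. The nest has its own outgoing $Q$-row (the
first leg of a bout is valued and learned like any other) but is never a
softmax destination: returns happen only through the bout-termination
rules. $\beta$ defaults to 20 everywhere; it sharpens or flattens routine
quantitatively without changing the direction of the environmental effects.

**Working memory.** Each bee remembers its site entry times and excludes
any site visited less than `wm_span` seconds ago (half-open window; the
nest is never excluded). The memory decays by time only — it is *not*
cleared at the nest, which is what couples successive bouts and produces
route alternation (below).

**Bouts and competition.** A bout ends when the crop (five full site
loads) is full, when the flight budget (3000 m) is exceeded — checked after
arrival, since the bee commits to a chosen transition — or when every site
is inhibited, a degenerate case the original description leaves open; we
return the bee to the nest. If all sites are inhibited already at
departure, the bee waits one timestep and retries rather than logging
empty bouts. After each bout the bee waits 300 s in the nest. Multiple
bees interact *only* through nectar depletion; same-timestep arrivals feed
in randomised order. There are no explicit encounter or displacement
events — the behavioural description defines none — though the arrival
hook is where one would add them.

**Time and randomness.** The clock is discrete with $dt = 1$ s, which
resolves every process in the model (travel legs, memory spans, renewal
times are all tens to thousands of seconds); travel times round up to
whole steps. Internally the engine is event-driven — renewal is analytic
between arrivals — which is exactly equivalent to stepping the clock and
much faster. All randomness flows from one master seed through named
streams (`derive_seed()`): each bee owns a stream, so adding a forager
does not perturb the others' draws, and tie-breaking uses a separate
engine stream. Simulations are reproducible bit-for-bit; tests replay the
event log against the incremental renewal rule to confirm nectar
conservation.

## Output metrics

The **similarity index** between two bouts decomposes each visit sequence
into length-3 sliding windows and marks every visitation covered by a
window occurring in both bouts:
$SI = S_{ab} / (2\,\max(p, q))$, 1 for identical bouts, 0 for bouts with no
shared window. Interpretation choices, verified against a brute-force
enumeration oracle: repeated visits count as positions (otherwise
identical bouts would not normalise to 1); every occurrence of a shared
window marks its positions; bouts shorter than the window contribute
nothing, giving $SI = 0$ unless both bouts are empty, which is reported as
`NA` and propagates honestly into aggregates. Comparing bouts $k$ and
$k+1$ (lag 1) measures route fidelity; lag 2 exposes alternation between
two routes (lag-2 high, lag-1 low). **Foraging success** is µl collected
per second of bout, nest to nest.

## Parameters that matter

| parameter | default | units | role |
|---|---|---|---|
| $\alpha$ | 0.5 | — | learning rate; 0 = no learning |
| $\beta$ | 20 | — | choice sharpness; 0 = random |
| `wm_span` | 30 or "matched" | s | inhibition of return |
| $n_{\max}$ | 20 | µl | site capacity; crop = $5 n_{\max}$ |
| $T_r$ | 100–2000 in sweeps | s | renewal duration |
| speed | 3 | m s⁻¹ | flight speed |
| flight budget | 3000 | m | bout cap |
| nest wait | 300 | s | inter-bout pause |

The physical and cognitive defaults are literature-scale placeholder
values chosen once for internal coherence — working memory, nest wait and
renewal sit on a common timescale of tens of seconds to ~1500 s — and are
all configurable. $\alpha = 0.5$ weighs experience and expectation
equally; nothing in the package's findings depends on its exact value.

## The three experiments

`spacing_sweep_spec()`, `renewal_sweep_spec()` and
`competition_sweep_spec()` package the study conditions: a single forager
on a patch (spacing × number of sites), a single forager on 25 uniform
sites (renewal × working memory), and a growing colony on 25 uniform
sites whose total capacity fills five crops (colony size × renewal).
Replication follows an environments × simulations design; cell summaries
are taken at a fixed reporting bout (10 for the spacing sweep, 15
otherwise), by which both metrics have plateaued under these conditions —
`plateau_bout()` automates the plateau check that would otherwise be done
by eye, flagging the earliest bout after which the per-bout mean stops
moving by more than a relative tolerance.

Desk-scale defaults (2–5 environments × 1–2 simulations per cell,
directional effects averaged over 5–10 master seeds) keep a full
verification run near a minute of CPU; the full-scale protocol (25
environments × 2 simulations, 7-h horizon) is a parameter change, not a
code change.

With the package defaults the sweeps reproduce the qualitative findings:
similarity rises with inter-site spacing when 25 sites are available and
the effect fades with 5 (which sit at the similarity ceiling); with a 30-s
working memory both similarity and success fall as renewal slows, while a
matched memory keeps success high; competition erodes both metrics, the
more steeply the slower the renewal; and learning beats the
no-learning/noisy-choice control only when sites are far apart. One
regime deserves a note: route alternation — lag-2 similarity above lag-1 —
requires the working-memory span to exceed one bout cycle but not much
more than two. With the placeholder speed, wait and arena defaults the
bout cycle is roughly 500–600 s, so alternation peaks at renewal durations
of 500–1000 s rather than at ~1500 s; the regime's location simply scales
with bout duration, which depends on physical parameters that are
configurable here.

## What the synthetic environments do and do not capture

Generated environments emulate spatial configuration (spacing, clustering,
site number) and temporal resource dynamics (standing crop under linear
renewal) — the drivers under study. They deliberately omit flower-level
structure within sites, heterogeneous per-site capacities, wind, obstacles,
energetic costs of flight, multi-day dynamics and inter-colony
competition. Passing the directional tests therefore shows the cognitive
mechanism produces the expected regimes *under these idealisations*, not
that real foragers match any quantitative value; the similarity metric
itself, however, applies unchanged to empirical visit sequences via
`similarity_index()` on recorded bouts.

## Numerical and degenerate-input choices

Coincident locations make $1/d^2$ undefined and are rejected by name.
Seeds derive from a 32-bit string hash reduced mod $2^{31}-1$, never 0,
and are frozen by golden tests. Softmax uses max-subtraction. Zero-length
bouts cannot produce a similarity value and zero-duration bouts are
refused rather than yielding infinite rates. Aggregation drops replicates
that never reach the reporting bout and reports the count kept.
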