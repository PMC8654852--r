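---
title: "Reputation dynamics and evolutionary stability under private assessment"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reputation dynamics and evolutionary stability under private assessment}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(privrep)
```

## The model

`privrep` analyses the donation game under indirect reciprocity when
reputations are *privately* assessed.  A well-mixed, effectively infinite
population plays one-shot donor/recipient interactions: cooperation costs the
donor $c$ and delivers $b > c$ to the recipient.  Every individual holds a
private binary opinion (good/bad) of every other individual.  A strategy has
ten bits:

* action rule $(a_1, a_0)$ — cooperate with a recipient deemed good ($a_1$)
  or bad ($a_0$);
* assessment rules $c_{ij}$ and $d_{ij}$ — the new opinion assigned to an
  observed donor who cooperated ($c$) or defected ($d$), indexed by the
  observer's current opinion of the donor ($i$) and of the recipient ($j$).
  The recipient's reputation is never updated.

Errors: with probability $\mu_e$ the donor executes the opposite action;
with probability $\mu_a$ the observer records the opposite opinion.  Both
live in $[0, 0.5)$.

Of the $2^{10} = 1024$ raw strategies, swapping the labels good/bad
everywhere (the *mirror* map: $a'_i = a_{1-i}$,
$x'_{ij} = 1 - x_{(1-i)(1-j)}$) gives a behaviourally identical strategy,
and strategies with $a_1 = a_0$ never read an opinion, so their assessment
bits are inert in every role — their own cooperation is unconditional and
the opinions they hold never change any payoff.  This leaves 258 canonical
strategies: all 256 discriminators $(a_1, a_0) = (1, 0)$, plus one
unconditional cooperator and one unconditional defector
(`canonical_set()`).  The canonical ALLC carries all-1 assessment bits and
ALLD all-0; the choice is behaviour-neutral and purely conventional.

## Mean-field h-score dynamics

The *h-score* of an individual is the fraction of the population currently
holding opinion good about it.  With random role assignment and independent
private opinions (the mean-field assumption for an infinite population), the
probability that a random observer judges a random donor good after one
interaction is a polynomial in the h-scores, and the monomorphic dynamics
are

$$\frac{dh}{dt} = p(o)(h) - h,$$

a polynomial of degree at most three (`derivative_poly()` exports the exact
coefficients).  Long-run behaviour is the forward flow from the shared
initial condition $h(t_0)$: results genuinely depend on $h(t_0)$ because
several strategies are bistable and a few (image scoring without errors)
have an identically zero derivative and stay wherever they start.

**Numerical choice.**  For a scalar autonomous ODE the limit of forward
integration is exactly the nearest root of the derivative in the direction
of motion, so `monomorphic_equilibrium()` computes that root directly from
the polynomial (bracketing on the monotone pieces between critical points,
which also catches tangent double roots).  This has no discretisation error
and still selects the correct basin.  An adaptive explicit integrator is
kept (`method = "integrate"`) and cross-checked in the tests.

## Resident plus rare mutant

The invasion analysis tracks three coordinates: $h_{r\bar r}$ (residents'
opinion of residents), $h_{m\bar r}$ (residents' opinion of the mutant) and
$h_{\bar r m}$ (the mutant's opinion of residents).  The resident equation
is autonomous and is equilibrated first; the remaining two equations are
then solved forward from $(h_0, h_0)$ with $h_{r\bar r}$ held at its
equilibrium.  The order matters: when the resident approaches its
equilibrium only algebraically (a double root, as for the $d_{11} = 1,
d_{01} = 0$ cooperators), joint integration would let $h_{m\bar r}$ drift
logarithmically and destroy the initial-condition dependence that the
$1/(1 - h(t_0))$ thresholds rely on.  Solving the two-equation system at
the resident equilibrium, as the fitness computation itself assumes, keeps
$h_{m\bar r}$ frozen at $h(t_0)$ in exactly those cases.

The system is triangular: $h_{\bar r m}$ is autonomous (solved by the same
exact flow method; it is quadratic), and $h_{m\bar r}$ is linear in itself
with coefficients driven by $h_{\bar r m}$.  Whenever its contraction rate
at the limit is positive the endpoint is a closed-form ratio, independent
of the transient; only the marginal cases need the coupled transient, which
is integrated with an RK4 step for the autonomous coordinate and the exact
frozen-coefficient update for the linear one, with a coarse/fine step pair
as error control.  Stability is read off the triangular Jacobian's
eigenvalues (labelled stable / marginal / unstable at $\pm 10^{-8}$).

## Invasion fitness and the ESS scan

With equilibrium cooperation probabilities $p^*(c_{m,r})$ (resident toward
mutant), $p^*(c_{r,m})$ and $p^*(c_{r,r})$, the mutant's fitness advantage
is

$$\Delta w = p^*(c_{m,r})\,b - p^*(c_{r,m})\,c - p^*(c_{r,r})\,(b - c).$$

Differences within $10^{-4}$ count as ties, and ties resist (no drift in an
infinite population).  Equilibria carry no payoffs, so each (resident,
mutant, $h_0$) triple is solved once and reused across the whole
benefit-to-cost axis; with cost normalised to 1, $\Delta w$ is affine in
$b$, so each mutant's critical ratio is solved exactly
(`min_bc_threshold()`), and the full scan of $258 \times 257 \times 3$
equilibria runs in well under a minute.

`ess_scan()` reports, per canonical resident: per-ratio verdicts on the
default grid $b/c \in \{1, 1.25, \dots, 20\}$ (the figures' axis; the
$b = c$ end is where exact ties sit), the exact tolerance-inclusive resist
window, the headline verdict "ESS at all three $h_0 \in \{0.1, 0.5, 0.9\}$
for at least one common grid ratio", and the class: *cooperator* if
$p^*(c_{r,r}) \ge 1 - 10^{-3}$ at every $h_0$, *defector* if
$\le 10^{-3}$, otherwise *intermediate* (intermediates are excluded from
both headline counts; they are stable only at isolated ratios).

Without errors this yields 15 cooperator ESSs — exactly the union of the
three rule families $C\,=\,111*$/$D\,=\,0*0*$ (stable for all $b > c$),
$111*/0*1*$ (stable for $b/c \ge 2$) and $110*/1*0*$ (stable for
$b/c > 1/(1 - h(t_0))$), with at most one (or two, middle family) wildcard
set to zero — and 38 defector ESSs, 16 of which are AllD-equivalent
($c_{10} = c_{00} = d_{10} = d_{00} = 0$) and stable over the whole range,
the rest only on narrow windows at or just above $b = c$.

## Errors and the collapse of stability

With $\mu_e = \mu_a = \mu > 0$ the discriminating rules judge and act on
noisy reputations, and the error-free ESS structure largely collapses:
at $\mu \le 0.005$ every error-free cooperator and defector ESS except the
unconditional defector loses stability, reproducing the headline collapse
result.  Two caveats, established numerically and kept visible rather than
smoothed over (the corresponding acceptance test is deliberately left
partially failing):

* at $\mu = 0.01$ one defector survives at $b/c = 1.5$ only because its
  worst invader's advantage ($\sim 5\times10^{-5}$) sits below the
  $10^{-4}$ tie tolerance — an artifact of carrying a tolerance chosen for
  a noisier pipeline into closed-form algebra accurate to $10^{-12}$;
* at $\mu \ge 0.01$ one member of the $110*/1*0*$ cooperator family
  genuinely resists all 257 mutants on a narrow ratio window (near
  $b/c \approx 12$ at $\mu = 0.01$), verified with an independent
  explicit integrator.  The collapse claim is therefore rate-sensitive;
  the error rate behind the published claim is not printed in the source
  material, and this package's default for "with errors" analyses is
  $\mu = 0.01$.

Intermediate-class residents additionally tie everything at $b = c$ and at
isolated tangency ratios at any error rate; as in the error-free analysis
they are set aside rather than counted.

## The agent-based simulator

`run_abm()` implements the finite-population protocol literally: $N = 100$
individuals, an $N \times N$ private-opinion matrix (diagonal unused,
i.i.d. Bernoulli($h_0$) start), one random donor/recipient pair per step,
one random observer drawn from the bystanders (excluding donor and
recipient; configurable), single-opinion update per step, $4\times10^5$
interactions with the final $10^5$ averaged, 30 replicates on independent
seeded substreams.  The compiled loop is bit-for-bit reproducible given
(seed, replicate); a pure-R `interaction_step()` defines the semantics and
is cross-checked statistically against the compiled engine.

What the generator emulates — and what it does not: it reproduces finite-N
sampling noise, opinion-matrix correlations, and finite observation time.
It does *not* emulate assortment, network structure, or payoff feedback on
the dynamics (reputations evolve independently of accumulated payoffs, as
in the analytic model).  A green comparison therefore establishes that the
mean-field polynomial dynamics approximate this exact protocol — not that
either describes any richer population process.

`compare_to_analytic()` runs the "absence of error" validation: simulation
at $\mu = 10^{-4}$ against error-free analytic equilibria started from the
same $h_0$.  The protocol leaves $h_0$ for this comparison unstated; the
package fixes $h_0 = 0.5$ (maximal prior uncertainty, symmetric between
the good and bad labels) once and for all.  At $4\times10^5$ total
interactions the effective mean-field time is only
$t \approx 4\times10^5 / (N(N-1)) \approx 40$, so strategies with
algebraic (double-root) convergence are still measurably short of their
fixed points; this finite-time gap, not Monte-Carlo noise, dominates the
mean absolute h-score discrepancy of $\approx 0.013$.  Because a
discriminator's realised cooperation frequency equals its mean opinion of
others, the cooperation-frequency discrepancy necessarily tracks the
h-score discrepancy in this protocol (both $\approx 0.013$ here, against
published values of 0.014 and 0.010 respectively with 30 replicates).

## Tunable parameters

| parameter | meaning | default | why |
|---|---|---|---|
| `b`, `c` | benefit, cost | 2, 1 | cost-normalised; scans sweep `b` |
| `mu_e`, `mu_a` | execution / assessment error | 0 | error-free baseline; 0.01 for "with errors" |
| `h0` | shared initial h-score | 0.5 | symmetric prior; scans use {0.1, 0.5, 0.9} |
| `tol` | fitness tie tolerance | 1e-4 | published value; ties resist |
| `eps_class` | cooperation-rate classification band | 1e-3 | rates are exactly 0/1 without errors |
| grid | benefit-to-cost axis | 1 to 20 by 0.25 | figures' axis and resolution |
| ABM | N, steps, window, replicates | 100, 4e5, 1e5, 30 | published protocol |

## Known limitations

* Mutant-mutant interactions are neglected (rare-mutant limit), so
  mutual-invasion "polymorphism" verdicts (`polymorphism_check()`) are
  qualitative.
* Second-order action rules (conditioning on one's own reputation) and
  strategy-encoded initial opinions are out of scope.
* The ABM supports monomorphic populations only; the dimorphic analysis is
  purely analytic.
* Finite-population evolutionary dynamics (fixation probabilities, weak
  selection) are not modelled; `invasion_fitness()` exposes the
  deterministic fitness differences only.
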