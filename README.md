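# privrep

Moral rules — how we judge others' actions toward third parties — can
sustain cooperation through indirect reciprocity: help is repaid not by the
recipient but by observers who adjust their opinion of the helper.  Most
theory assumes *public* assessment (everyone shares one opinion of each
individual).  `privrep` implements the full analysis for **private
assessment**, where every individual keeps its own opinion of every other,
and judges observed interactions with its own rules.

The package is for evolutionary game theorists and social-evolution
modellers who want to:

* enumerate the complete first-order strategy space of the donation game —
  an action pair $(a_1, a_0)$ plus assessment tables $c_{ij}$, $d_{ij}$ —
  and reduce its 1024 members to the 258 behaviourally distinct ones;
* track mean reputations ("h-scores") through exact polynomial mean-field
  dynamics $dh/dt = p(o) - h$, with execution errors $\mu_e$ and assessment
  errors $\mu_a$;
* run an exhaustive evolutionary-invasion (ESS) analysis: every canonical
  resident against every canonical mutant, at initial h-scores
  $h(t_0) \in \{0.1, 0.5, 0.9\}$, across benefit-to-cost ratios
  $b/c \in [1, 20]$, using the invasion fitness
  $\Delta w = p^*(c_{m,r}) b - p^*(c_{r,m}) c - p^*(c_{r,r})(b - c)$;
* validate the mean-field model against a compiled agent-based simulator of
  the exact finite-population protocol (N = 100, one observer per
  interaction).

See the vignette `vignettes/private-assessment-model.Rmd` for the model,
the numerical choices, and known limitations.

## Worked example

```r
library(privrep)

standing <- ir_catalog()$strategies$standing   # 1011110101, code 757
monomorphic_equilibrium(standing, model_params(h0 = 0.5))
#> <equilibrium h* = (1)  marginal  residual 0.00e+00  steps 0>

# a rare unconditional defector in a standing population earns nothing:
invasion_fitness(standing, "0000000000", model_params(b = 3, c = 1, h0 = 0.5))
#> <invasion dw = -2  resists  (p_mr 0, p_rm 0, p_rr 1)>

min_bc_threshold(standing, h0 = 0.5)$threshold          # 1  (any b > c)
min_bc_threshold("1011011101", h0 = 0.9)$threshold      # 10 (1 / (1 - h0))

scan <- ess_scan()          # full 258 x 257 x 3 scan, ~30 s
scan
#> <ess scan: 258 residents, h0 in {0.1, 0.5, 0.9}, b/c in [1, 20], mu_e=0 mu_a=0>
#>   ESS at all h0: 73  (cooperators 15, defectors 38)
```

The 15 cooperator ESSs are exactly the three rule families
`111*/0*0*` (stable for any `b > c`), `111*/0*1*` (stable for `b/c >= 2`)
and `110*/1*0*` (stable for `b/c > 1/(1 - h0)`); the 38 defector ESSs all
share `d10 = d00 = 0`, and the 16 stable over the whole range also have
`c10 = c00 = 0` (behaviourally equivalent to always-defect).  With errors
(`ess_scan(mu_e = 0.01, mu_a = 0.01)`) the cooperative ESS structure
collapses; see the vignette for the exact statement and its caveats.

Agent-based validation of the mean-field equilibria:

```r
cmp <- compare_to_analytic(config = sim_config(replicates = 10, seed = 1))
cmp
#> <abm vs analytic: 258 strategies  mean|dh| 0.0139  mean|dcoop| 0.0140>
```

## Command line

```sh
Rscript inst/cli/privrep.R ess-scan --bc-min 1 --bc-max 20 --bc-step 0.25 \
        --h0 0.1,0.5,0.9 --mu-e 0 --mu-a 0 --out scan.csv
Rscript inst/cli/privrep.R simulate --strategy standing --n 100 \
        --steps 400000 --window 100000 --reps 30 --h0 0.5 \
        --mu-e 1e-4 --mu-a 1e-4 --seed 7 --out sim.csv
```

Subcommands: `enumerate`, `equilibrium`, `ess-scan`, `simulate`, `compare`.
Every CSV is written with a `.manifest.json` (config, hash, seed, package
version) from which the run can be replayed.

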