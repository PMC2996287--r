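# zipfheaps

Zipf's law and Heaps' law co-occur across disparate complex systems: when
the frequency of the element ranked *r* decays as **z(r) ∝ r^−α** (Zipf),
the number of distinct elements grows sublinearly with system size as
**N(t) ∝ t^λ** (Heaps). The classical asymptotic link is

    λ = 1        for α ≤ 1
    λ = 1/α      for α > 1

but that rule only holds for infinite systems. `zipfheaps` implements the
finite-size relation that replaces it: assuming Zipf's law holds with a
stable exponent throughout growth, the total size and the vocabulary are
tied by

    t(N) = (N − N^α) / (1 − α)        (α ≠ 1;  t = N ln N at α = 1,
                                       inverted as N = t / W₀(t))

and the *effective* Heaps exponent — the log-log least-squares slope of
this curve up to the system's actual size — lies measurably below the
asymptotic value, most strongly for α near 1, where most real systems
live.

The package is aimed at anyone fitting heavy-tailed rank data or
vocabulary-growth curves: corpus linguists, scientometricians,
epidemiologists tracking the spread of an outbreak across regions, and
network scientists relating accelerated growth to scale-free degree
distributions (θ = 1/λ).

It provides:

* **Exponent algebra** — `beta_from_alpha()`, `alpha_from_beta()`,
  `asymptotic_heaps()`, `accelerating_exponent()`.
* **The finite-size relation and solvers** — `text_size_from_vocab()`,
  `vocab_from_text_size()` (Lambert-W branch at α = 1),
  `vocab_from_text_size_improved()` (discrete-normalization refinement),
  `heaps_exponent_numeric()`, `relation_curve()`, `sum_integral_error()`.
* **Estimators** — `fit_zipf_mle()` (discrete power-law MLE with optional
  KS-based cutoff selection), `fit_heaps_lsq()`, plus stream plumbing:
  `rank_frequency_from_stream()`, `growth_curve_from_stream()`,
  `cumulative_counts_to_stream()`.
* **A stochastic simulator** — the rank-driven occurrence process
  (`simulate_zipf_stream()`, with exponential-cutoff and pure-exponential
  variants, C++ core, fully seeded) and `make_fixture()` for reproducible
  plain-text test data.
* **A CLI** — `zipfheaps_cli()` with subcommands `fit`, `predict`,
  `simulate`, `table1`; thin wrapper in `inst/cli/zipfheaps.R`.

## Worked example

Simulate the rank-driven process at α = 1.2 for 50 000 steps, then recover
both exponents and compare with the model prediction:

```r
library(zipfheaps)

sim <- simulate_zipf_stream(alpha = 1.2, steps = 50000, seed = 42)
sim
#> Rank-driven simulation (zipf mode): 50000 steps, pool 50000, final N = 4811

fit_zipf_mle(sim$table, z_min = "auto")
#> Zipf MLE fit: alpha_hat = 1.1621 (beta_hat = 1.8605), z_min = 41, n_tail = 101

fit_heaps_lsq(growth_curve_from_stream(sim$stream, checkpoints = 1000))
#> Heaps fit: lambda_hat = 0.7735 (R^2 = 0.9978, 673 points, t in [1, 50000])

heaps_exponent_numeric(1.2, 5e4)   # finite-size prediction
#> [1] 0.7687
asymptotic_heaps(1.2)              # infinite-size prediction
#> [1] 0.8333
```

The recovered Zipf exponent (1.16) tracks the generating α = 1.2; the
simulated growth exponent (0.77) matches the finite-size prediction
(0.769) and falls well short of the asymptotic 0.833 — the finite-size
effect the package exists to quantify.

The packaged reference survey of 35 empirical systems can be re-evaluated
in one call:

```r
run_table1_suite(table1_reference()[c(1, 10, 34), ])
#>    no                           label alpha      T lambda_asym lambda_num lambda_emp
#> 1   1             Moby Dick (English) 1.323 206779       0.756      0.726      0.738
#> 10 10                   PNAS keywords 0.893 504610       1.000      0.937      0.863
#> 34 34 H1N1 confirmed cases by country 3.000   8829       0.333      0.326      0.350
```

For each row the finite-size column is recomputed from (α, T) alone; over
the full survey the finite-size prediction sits closer to the empirical
exponent than the asymptotic rule in all but a couple of systems.

From the shell:

```sh
Rscript inst/cli/zipfheaps.R simulate --mode zipf --alpha 1.2 --steps 50000 \
    --seed 42 --out-prefix /tmp/run
Rscript inst/cli/zipfheaps.R fit --input /tmp/run.events --input-kind events \
    --zmin auto --json /tmp/fit.json
Rscript inst/cli/zipfheaps.R predict --alpha 1.323 --size 206779 --out /tmp/curve.tsv
```

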