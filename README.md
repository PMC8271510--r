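# qpass

Multifactorial quality scoring of basketball passes from two arm-worn
gyroscopes.

Hit counts alone separate skilled from novice passers poorly: a pass can
reach the target slowly, or with an erratic arm action, and still "count".
`qpass` is for sport scientists and coaches who run wall-target passing
tests with inertial sensors and want a per-pass, 0–100 quality score — the
**Q-Pass index** — that combines three factors:

* **f1 — accuracy**: ball impact relative to a 0.61 m × 0.61 m wall target,
  discretised to the penalties {0, 25, 50, 75, 100} (0 = clean hit inside,
  100 = complete miss);
* **f2 — execution time**: deviation (in samples) of the pass duration from
  a reference execution time `Ex_Tr`, the mean duration of the quickest
  pass type in a skilled reference group;
* **f3 — pattern variability**: deviation of the pass's movement-pattern
  summary from its pass type's reference `ExPT_ir`. The pattern summary is
  the rectangle-rule integral of the filtered combined angular-speed
  magnitude of wrist and humerus gyroscopes over the pass window,
  Δt · Σ |gyr₁ + gyr₂| (4th-order zero-phase Butterworth, 25 Hz cutoff,
  128 Hz sampling).

Raw penalties are rounded to natural numbers, normalised so the worst
execution in the pool maps to 100, flipped to qualities q = 100 − p, and
combined with coach-configurable weights:

```
QPass = x1·q1 + x2·q2 + x3·q3,   x1 + x2 + x3 = 1,   QPass ∈ [0, 100].
```

Per player and pass type, repeated executions are aggregated with the
*modified mean* (drop one maximum, one minimum, one median). The package
also ships the companion statistics — SEM from a repeated-measures ANOVA,
CV = SEM/mean·100, pooled Student's t with 95% CI, Hedge's g with
qualitative labels — and a seeded generator of synthetic two-sensor
cohorts, so the whole pipeline is testable without raw recordings.

## Worked example

Simulate the default two-group study design (2 groups × 8 players × 5 pass
types × 25 executions at 128 Hz), build references from the experienced
group, score, and compare groups:

```r
library(qpass)
co  <- qp_simulate(seed = 42)
ref <- qp_reference(co$annotations, co$recordings, group = "A")
ref
#> <cohort_reference> from group 'A' @ 128 Hz
#>   Ex_Tr: 69 samples (0.539 s)
#>   ExPT_ir (deg):
#>     chest            166.20
#>     bounce           330.01
#>     crossover        395.67
#>     between_the_leg  474.56
#>     behind_the_back  524.75
```

The reference execution time is 69 samples (0.539 s, the chest pass — the
quickest type), and each pass type gets its own variability reference (the
mean pattern integral, e.g. 330 deg for the bounce pass). Scoring with
accuracy weighted at one half:

```r
sc <- qp_score(co$annotations, co$recordings, ref, weights = c(0.5, 0.25, 0.25))
head(sc$summary, 4)
#>   player_id group       pass_type       q1       q2       q3 qpass_index n_executions
#> 1       A01     A           chest 78.40909 96.59886 88.36364    85.07142           25
#> 2       A01     A          bounce 68.18182 67.29180 89.25620    73.14933           25
#> 3       A01     A       crossover 80.68182 56.38907 90.52574    76.89383           25
#> 4       A01     A between_the_leg 79.54545 45.89955 90.06917    73.54373           25
```

Each row is one player × pass type: the modified-mean factor qualities and
index over 25 executions. Player A01's chest passes score 85.1 — accurate
(q1 = 78), almost reference-fast (q2 = 97) and repeatable (q3 = 88) — while
the between-the-leg pass loses most of its score through the time factor
(q2 = 46: it is structurally slower than the chest-based reference).
Group comparison per pass type:

```r
rep <- qp_report(sc)
rep[rep$pass_type == "bounce", c("group","mean","sd","sem","cv_pct","mean_diff","p","hedges_g","label")]
#>   group mean   sd  sem cv_pct mean_diff        p hedges_g       label
#> 3     A 74.9 3.39 14.2   18.9      13.9 2.96e-06     3.54 extra-large
#> 4     B 61.0 4.00 17.6   28.8      13.9 2.96e-06     3.54 extra-large
```

The simulated experienced group scores 13.9 points higher on the bounce
pass (Hedge's g = 3.54, "extra-large"); `sem`/`cv_pct` quantify
within-player test-retest error from the players × trials repeated-measures
ANOVA. With this generator's strong injected skill contrast the synthetic
effects are larger than one would expect in field data.

A thin command-line wrapper over the same functions is installed at
`inst/cli/qpass.R` with subcommands `simulate | reference | score | report`:

```sh
Rscript "$(Rscript -e 'cat(system.file("cli/qpass.R", package="qpass"))')" \
    simulate --seed 42 --out cohort_dir
```

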