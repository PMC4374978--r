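# bsmi

Delayed movement coordination and biosonar interaction in echolocating bat
pairs.

`bsmi` is an R package for movement ecologists studying pairwise
coordination in trajectory data, built around the case of Daubenton's bats
(*Myotis daubentonii*) foraging low over water, where flight is effectively
two-dimensional and the interaction channel — active echolocation — is
physically quantifiable. It answers three questions about a pair of
co-flying animals:

1. **When is the pair interacting, and who leads?** From two uniformly
   sampled tracks it computes the *time-dependent delayed directional
   correlation* (TDDC)

   C<sub>ij</sub>(t, τ) = (2w+1)⁻¹ Σ<sub>k=−w..w</sub>
   v̂<sub>i</sub>(t + kΔt) · v̂<sub>j</sub>(t + τ + kΔt)

   and the analogous *time-dependent delayed separation* (TDDS)
   R<sub>ij</sub>(t, τ), over the whole (t, τ) lattice. A single
   interaction path τ(t) is then extracted by penalised dynamic
   programming under the time-ordering constraint Δτ/Δt ≥ −1 (a reactor's
   responses cannot reorder the actor's actions), with a cost `q` per
   delay change. Samples with C ≥ v<sub>c</sub> = 0.95 are *coordinated*;
   those that additionally have delayed separation R ≤ d<sub>c</sub> =
   0.15 m are *chases* (one bat retracing the other's path). The sign of
   the extracted delay assigns actor (leader) and reactor (follower), and
   −1-gradient propagation yields asymmetric per-time delay uncertainty
   bounds.

2. **Could the reactor perceive the actor?** A parametric biosonar field
   gives the echo amplitude returning from a conspecific at range ρ and
   off-axis angle ζ:

   α(ρ, ζ) = SL + TS + (A + 2)(cos ζ − 1) + 2·(20·log₁₀(0.1/ρ) + ρc)

   with source level SL = 110 dB, target strength TS = −10 dB, emission
   directionality asymmetry A (best fit 16), a 2 dB cosine hearing
   directionality, two-way spherical spreading from 0.1 m, and absorption
   c = −1.28 dB/m. Detection occurs when α reaches the hearing threshold
   B (≈ 10 dB), which closes the perception–action loop.

3. **Do delayed alignment plus this perception field explain the observed
   geometry?** An agent-based simulator (the biosonar movement
   interaction model, BSMI) flies bat pairs with Rician(4.81, 2.18)
   speeds, von Mises headings (κ = 557 independent, κ = 2473 while
   interacting), a 4 g lateral-acceleration clamp, a call every 100 ms,
   a reaction delay τ, and a 0.05-per-step escape probability. Simulated
   ensembles are pushed through the *same* classifier, their
   reactor-centred relative-position densities binned at 1.5 m, and the
   parameters (A, B, τ) fitted to an observed density by RMS grid search.

A synthetic-trajectory generator with exact ground truth (independent,
coordinated, chase, role-swap, piecewise-lag and deterministic geometric
scenarios) makes every stage testable without field data.

## Worked example

```r
library(bsmi)

# a ground-truth pair: the follower copies the leader's heading 0.3 s late
spec <- synth_spec("coordinated", lag = 0.3, duration = 8, seed = 42)
g <- generate_pair(spec)

cl <- classify_pair(g$pair)
cl
#> <bsmi_classified_pair> pair synth_coordinated_42: 390 times; 95.9% coordinated,
#>   4.1% chase, 0.0% unclassified

tab <- subset(cl$table, label != "unclassified")
median(tab$tau)
#> [1] 0.28            # true lag 0.30 s, recovered to one 20 ms sample
mean(tab$actor == "leader", na.rm = TRUE)
#> [1] 0.82            # the generating leader is identified as the actor

sonar_params()
#> <bsmi_sonar_params> SL = 110 dB, TS = -10 dB, A = 16, hearing = 2 dB,
#>   c = -1.28 dB/m, ref = 0.1 m, B = 10 dB
sonar_isocontour(sonar_params(), 10, n_angles = 5)$rho[3]
#> [1] 6.66            # on-axis 10 dB detection range in metres
```

The classifier reports 96% of samples coordinated with the leader as
actor and the delay recovered to within one sample; the default sonar
parameters give a ~6.7 m on-axis detection range that shrinks towards the
rear by 36 dB of cosine directionality.

Simulation and fitting follow the same grammar:

```r
sims <- simulate_ensemble(sim_config(tau = 0.3), n_pairs = 50, seed = 1)
fit  <- grid_search_fit(observed_density, sim_config(tau = 0.3),
                        A_values = c(8, 16, 24), B_values = c(-10, 10, 30),
                        tau_values = 0.3, n_pairs = 50, seed = 1)
```

File-based pipelines (`run_classify()`, `run_simulate()`, `run_fit()`)
read and write the delimited trajectory exchange format
(`pair_id,bat_id,t,x,y`) plus JSON summaries and run manifests.

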