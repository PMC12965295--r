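# psifret

Structural photosynthesis tools for photosystem I–light-harvesting
supercomplexes: pigment extraction and geometry from coordinate models,
Förster excitation-energy-transfer (EET) rate networks, cofactor censuses,
and global analysis of femtosecond transient-absorption (TA) surfaces.

The package targets the analysis workflow around large antenna–core
supercomplexes such as the *Euglena gracilis* PSI–LHCE assembly — hundreds of
chlorophylls and carotenoids ringing a reaction-center core — where the
questions are: which pigments are where (census, Chl a/b ratios, contact
distances, cis/trans carotenoid isomerism), how fast can excitation hop
between them (pairwise Förster rates, inter-subunit couplings, fastest
antenna-to-core pathways, candidate red-chlorophyll dimers), and what do the
ultrafast kinetics say about trapping (decay-associated spectra, trapping
time, quantum efficiency).

## The models

**Förster rate network.** For a donor/acceptor chlorin pair the transfer
rate is

```
k_FRET = C κ² / (n⁴ R⁶),        τ_transfer = 1 / k_FRET
```

with `R` the Mg–Mg distance (Å), `n` the refractive index, `C` an
overlap-integral factor per pigment-class pair, and the orientation factor

```
κ = μ̂_D·μ̂_A − 3 (μ̂_D·R̂)(μ̂_A·R̂),    κ² ∈ [0, 4],  ⟨κ²⟩_iso = 2/3
```

where `μ̂` are unit Qy transition dipoles (NB→ND macrocycle axis by
convention, configurable) anchored at the magnesium. With the default
`C = 1` the rates are *relative*; the network topology, rate rankings and
pathway structure are meaningful without a calibrated `C`.

**Parallel kinetic model.** TA surfaces ΔA(t, λ) are fitted as a sum of
independent exponential decays convolved with a Gaussian instrument
response,

```
ΔA(t, λ) = Σᵢ DADSᵢ(λ) · [exp(−t/τᵢ) ⊗ IRF(σ)](t)
```

by variable projection: nonlinear least squares over the lifetimes (in log
space), time zero and IRF width, with the decay-associated spectra (DADS)
eliminated exactly by a per-wavelength linear solve at each iterate.

Every stage has a seeded synthetic twin (`make_chlorin`, `make_polyene`,
`make_toy_complex`, `simulate_ta`) that carries its ground truth, so the
whole pipeline is testable without downloading any deposited model.

## Worked example

```r
library(psifret)

tc  <- make_toy_complex(n_chains = 3, chlorins_per_chain = c(14, 8, 8),
                        chl_b_per_chain = c(4, 0, 0), box = 55,
                        min_sep = 7, seed = 11)
cen <- cofactor_census(tc$model)
cen
#> <cofactor_census>
#>   totals: CHL_A=26, CHL_B=4
#>   chromophores (CHL_A+CHL_B+BCAR+DDX): 30
#>   cofactors (all mapped residues):     30
#>   protein chains: 0
chl_ab_ratio(cen, "A")$ratio
#> [1] 2.5

net <- build_network(extract_pigments(tc$model))
net
#> <eet_network> 30 chlorins, 368 directed edges (r_max = 30 A, n = 1.55)
signif(intersubunit_matrix(net), 3)
#>          A        B        C
#> A 0.00e+00 1.59e-07 7.45e-07
#> B 1.59e-07 0.00e+00 1.11e-06
#> C 7.45e-07 1.11e-06 0.00e+00
fastest_paths(net, "B", "C", k_paths = 3)
#>                                        path total_cost n_hops
#> 1                            B:606 -> C:604    1008268      1
#> 2 B:606 -> C:604 -> A:614 -> A:606 -> C:605   18812425      4
#> 3                   B:607 -> B:606 -> C:604   20040272      2
```

The census counts each chlorin by chain; chain A was planted with 10 Chl a
and 4 Chl b, hence the a/b ratio 2.5. The inter-subunit matrix sums the
directed pairwise rates between chains (relative units under `C = 1`), and
`fastest_paths` ranks inter-chain hopping routes by total transfer time
(here in the same relative units; with a calibrated `C` in ps⁻¹·Å⁶ the
costs are picoseconds).

Fitting a simulated five-component TA surface and reading off the trapping
kinetics:

```r
sim <- simulate_ta(seed = 1)                      # 0.36/3/15/72/2500 ps truth
fit <- fit_parallel_model(sim$surface, 5,
                          tau_init = c(0.2, 5, 30, 40, 5000))
fit
#> <dads_fit> 5 components, rss = 2.8255
#>   lifetimes (ps): 0.371, 3.023, 15.19, 72.31, 2474
#>   t0 = -0.0009644 ps, IRF sigma = 0.1013 ps
trapping_efficiency(fit$lifetimes[4], 2000)
#> [1] 0.963844
```

The fourth component (~72 ps) is the dominant antenna-to-trap component;
with a user-set intrinsic lifetime of 2 ns the implied photochemical
quantum efficiency is ~96%.

A thin command-line wrapper over these functions ships at
`inst/cli/pigment-eet.R` (subcommands `extract`, `census`, `geometry`,
`distances`, `fret`, `paths`, `tafit`, `simulate`).

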