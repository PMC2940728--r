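# difftrace

Is the dynamics projected onto your reaction coordinate really
sub-diffusive — or is the coordinate just bad?

When molecular dynamics (protein folding being the canonical case) is
projected onto a scalar reaction coordinate, the projected motion often
shows a mean square displacement growing as $t^{\gamma}$ with
$\gamma < 1$.  difftrace implements, in R, the trajectory-analysis
framework that decides between the two readings of that observation:

* **cut-based free-energy profiles**: alongside the conventional histogram
  profile $F_H = -\ln Z_H$, the cut partition function $Z_C(x;\Delta t)$ —
  half the number of times frames sampled $\Delta t$ apart straddle level
  $x$ — gives $F_C = -\ln Z_C$, which is exactly invariant under monotone
  reparametrizations of the coordinate ($kT = 1$ throughout);
* the **anomalous-diffusion exponent**
  $\alpha(x) = 1 + [\ln Z_C(x;k_2) - \ln Z_C(x;k_1)]/\ln(k_2/k_1)$,
  equal to 1/2 for diffusive, below 1/2 for sub-diffusive, 1 for ballistic
  dynamics;
* the **natural coordinate** transform
  $y = \int \mathrm{d}x/\sqrt{D(x)}$ making the diffusion coefficient 1,
  with $D(x)$ from the displacement relation
  $\langle|\Delta x|\rangle = 2 Z_C/\tilde Z_H = \sqrt{4D\Delta t/\pi}$;
* **Kramers kinetics**:
  $\mathrm{mfpt}(a\to b) = \int_a^b \Phi(y)/[D(y)\rho(y)]\,\mathrm{d}y$,
  transition-state location, and folding-event estimates
  $n = T/(\mathrm{mfpt}_\to + \mathrm{mfpt}_\leftarrow)$;
* **reaction-coordinate optimization**: stochastic coordinate ascent
  maximizing the Kramers mfpt over two families — contact coordinates
  $\sum_{ij} s_{ij}\,\theta(r^0_{ij} - d_{ij})$ generalizing the number of
  native contacts, and linear distance combinations
  $\sum_{ij} c_{ij} d_{ij}$;
* the two-line ballistic model of $Z_C(\Delta t)$ at the transition state,
  whose closed form
  $\alpha = 1 - [(-F_\mathrm{TS}) - \ln Z_\mathrm{bal}]/\ln(t_\mathrm{bal}/\Delta t_0)$
  links barrier height to diffusivity: the higher the cut free-energy
  barrier, the closer the dynamics to diffusive;
* seeded **synthetic generators** (quartic double-well Langevin, exact
  fractional Brownian motion, an 8-atom two-state toy trajectory with a
  known latent folding coordinate) so every stage is testable without any
  external data.

It is aimed at people analyzing long equilibrium trajectories — from
molecular simulation or single-molecule experiments — who need to judge
and improve reaction-coordinate quality.

## Worked example

Simulate the two-state toy system, deliberately scramble the
native-contact coordinate, and compare it with the optimized one:

```r
library(difftrace)

two   <- simulate_two_state_atoms(twostate_config())   # 1e6 frames, seed 7
truth <- count_transitions(two$latent, -0.5, 0.5)$n_forward
truth
#> [1] 106

native <- toy_structures()$a
bad <- scramble_signs(native_contact_init(native, cutoff = 7), seed = 99)
q_bad <- eval_coordinate(two$trajectory, bad)
objective_mfpt(q_bad,
               native_value = native_coordinate_value(bad, native))$n_events_est
#> [1] 1975.1

trace <- optimize_coordinate(two$trajectory, bad,
                             optimizer_config(n_sweeps = 2, seed = 11),
                             native = native)
trace
#> <opt_trace (contacts): 44 proposals, 26 accepted, objective 215.8 -> 5473>

q_opt <- eval_coordinate(two$trajectory, trace$best_spec)
ob <- objective_mfpt(q_opt,
                     native_value = native_coordinate_value(trace$best_spec,
                                                            native))
ob$n_events_est
#> [1] 91.8

ks <- recommend_strides(q_opt, ob$x_TS)
alpha_profile(q_opt, levels = ob$x_TS, k1 = ks[1], k2 = ks[2],
              n_boot = 30)$alpha
#> [1] 0.455
```

Reading: the scrambled coordinate hides the folding barrier, so Kramers
kinetics overestimates the 106 true folding events almost twentyfold (its
exponent at the transition state is 0.21 — strongly sub-diffusive), while
the mfpt-optimized coordinate estimates 92 events and is diffusive at its
transition state ($\alpha \approx 0.46$).  Sub-diffusion here is a
property of the projection, not of the dynamics.

`autoplot()` methods exist for every result type (profiles, exponent
profiles, stride scans with their two-line fits, MSD curves, optimization
traces), and `tidy()`/`glance()` give broom-style summaries.  A thin CLI
(`inst/cli/difftrace`) exposes the generators and the pipeline
(`simulate-doublewell`, `profile`, `alpha`, `scan`, `msd`, `mfpt`,
`optimize`, `pipeline`, ...).

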