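# tumorperf

Solid tumors raise their interstitial fluid pressure (IFP) far above that
of normal tissue, and that pressure barrier is a main reason drugs fail to
penetrate them. `tumorperf` is an R package for simulating tumor IFP
*together with* the blood flow of the tumor-induced capillary network that
feeds it, in a 2-D tissue domain. It is aimed at researchers in
computational tumor biophysics and microvascular fluid mechanics who want
a transparent, testable implementation of the full coupling chain:

* **Angiogenesis**: a discrete endothelial-tip lattice model (random
  motility + saturating chemotaxis toward tumor angiogenic factor +
  haptotaxis on fibronectin) grows a capillary network from a parent
  vessel toward a tumor, with TAF-dependent branching and anastomosis.
* **Network hemodynamics**: Poiseuille segment flow with nodal mass
  conservation, Q = pi D^4 dP / (128 mu L), transvascular filtration by
  Starling's law Q_t = Lp pi D L [(Pb - Pi) - sigma (piB - pii)].
* **Blood rheology**: the empirical apparent-viscosity law mu(D, H)
  (Fahraeus-Lindqvist effect) and plasma skimming of red cells at
  bifurcations with a critical velocity-ratio cut-off.
* **Structural adaptation**: diameters remodel under the total stimulus
  S = log10(tau_w + tau_ref) - kp log10(tau_e(P)) +
  km log10(Qref/(Q H) + 1) - ks, clamped to 4-24 um.
* **Interstitium**: a conservative finite-difference Darcy solver,
  -div(K grad Pi) = Phi_B(Pi), with Starling sources on vascularized
  cells, solved by successive over-relaxation.

Three solution approaches of increasing fidelity are provided: a
uniform-source baseline without a network (`run_approach1`), rigid-vessel
coupling (`run_approach2`), and fully adaptive non-Newtonian coupling
(`run_approach3`).

## Worked example

```r
library(tumorperf)

# no-network baseline: homogenized sources at constant Pb
r1 <- run_approach1(simulation_config(approach = 1))
r1
#> perfusion_result (approach 1): max P_i = 570.4 Pa after 1 outer iteration(s)

# fully adaptive coupled model, 5 sprouts
r3 <- run_approach3(simulation_config(approach = 3, n_sprouts = 5, seed = 10001))
round(r3$max_Pi)
#> [1] 1079
range(r3$net$segments$D[!r3$net$segments$is_parent]) * 1e6  # um
#> [1]  4 24
```

The baseline peaks at ~570 Pa inside the tumor: the tumor wall is leaky
(high Lp, low sigma) so fluid filters in faster than the low-conductivity
interstitium can drain it to the far-field boundary. With a discrete
network the maximum roughly doubles — the capillaries reaching the tumor
carry intravascular pressures of ~2.2-2.3 kPa, far above the homogenized
baseline value — and structural adaptation dilates the perfused
near-tumor bed (to the 24 um bound, while stagnant branches regress
toward 4 um), enlarging the exchange surface and pushing the maximum IFP
to ~1.1 kPa.

A command-line front end is included:

```sh
exec/tumorperf generate-network --sprouts 5 --seed 1
exec/tumorperf run --approach 3 --sprouts 5 --seed 1 --outdir out/
```

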