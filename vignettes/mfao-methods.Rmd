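---
title: "Kinetics, control and regulation of a promiscuous beta-oxidation network"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Kinetics, control and regulation of a promiscuous beta-oxidation network}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The model

Mitochondrial fatty-acid beta-oxidation (mFAO) shortens an activated fatty
acid by two carbons per cycle. A C16 substrate (palmitoyl-CoA) is imported
by the carnitine shuttle (CPT1, CACT, CPT2) and then passes up to seven
cycles of dehydrogenation (VLCAD/LCAD/MCAD/SCAD, FAD-linked), hydration
(crotonase), NAD+-linked dehydrogenation (M/SCHAD) and thiolysis (MCKAT),
with the trifunctional protein MTP lumping the last three steps for chains
of C8 and longer. Each enzyme is *promiscuous*: it converts substrates of
several chain lengths at one active site. `mfao` represents every reaction
with a generalized reversible Michaelis-Menten law

$$ v \;=\; sf_{Cn}\,\alpha\,V_{max}\;
\frac{\prod_s ([S]/K_{m,S})^{\sigma_S} \;-\;
      \prod_p [P]^{\sigma_P} \,/\, \big(\prod_s K_{m,S}^{\sigma_S}\,K_{eq}\big)}
     {\prod_g \Big(1 + \sum_{x \in g} [X]/K_{m,x}\Big)} $$

where the denominator factors over independent binding-site groups. The
acyl site group of an enzyme contains the CoA-ester substrates *and
products of every chain length the enzyme touches*, so each ester's
$K_m$ doubles as its competitive inhibition constant; NAD(H) or FAD(H$_2$)
form a second independent factor. For the thiolases, free CoA sits in its
own cofactor factor and acetyl-CoA in the acyl group. The rate vanishes
exactly when the mass-action ratio equals $K_{eq}$, whatever the
competitor concentrations; competitors only scale the denominator.

**Conservation.** Free mitochondrial CoA plus every variable CoA ester is
a conserved moiety, and matrix carnitine plus matrix acyl-carnitine a
second one. This forces one modelling decision the package makes
deliberately: acetyl-CoA is a *variable* member of the CoA moiety, drained
by an irreversible Michaelis-Menten consumption step (a Krebs-cycle
stand-in) that returns free CoA. Clamping acetyl-CoA instead would remove
one CoA from the moiety at every thiolase event and the conservation law
— on which the steady-state reduction and the drift tests rest — would be
broken. The sink plays exactly the boundary role a clamp would, a steady
state still exists, and acetyl-CoA still acts kinetically as a product and
competitive ligand of the thiolases.

## Parameters of the packaged instance

Units are uM and min throughout. Four constants are fixed by the
literature values printed for the rat-liver model: $K_{eq}$ of M/SCHAD
$= 2.17\cdot10^{-4}$ (strongly unfavourable forward), $K_{eq}$ of
crotonase $= 3.13$, $sf_{MCKAT,C4} = 0.49$ versus $sf_{MCKAT,C6} = 1$, and
$K_m$ of MCKAT for C4-/C6-ketoacyl-CoA $= 12.4/6.7$ uM. Everything else
(all other $V_{max}$, $K_m$, $sf$, $K_{eq}$, boundary pools, moiety
totals) is this package's own calibration, chosen once during model
construction so the instance exhibits the documented physiology, and
frozen before any test was written:

* **CPT1** ($V_{max}$ 150, $K_m$ for cytosolic palmitoyl-CoA 50 uM)
  carries full flux control at low substrate and keeps pushing substrate
  in well past the overload threshold.
* **MCKAT** ($V_{max}$ 5000, acyl-product $K_m$ 2.5 uM, CoA $K_m$ 25 uM)
  has ample nominal capacity but binds its acyl-CoA products tightly, so
  accumulating C4/C6-acyl-CoA esters choke it — the vicious-cycle
  ingredient.
* **M/SCHAD and crotonase** are fast, near-equilibrium steps
  ($V_{max}$ 3000/2000). With NAD$^+$/NADH fixed at 16, the M/SCHAD
  equilibrium amplifies every uM of ketoacyl-CoA into
  $(\mathrm{NADH}/\mathrm{NAD^+})/K_{eq} \approx 288$ uM of
  hydroxyacyl-CoA, which is what drains the CoA pool.
* **Moiety totals**: 8000 uM CoA, 1000 uM carnitine — the upper
  physiological range for liver matrix CoA, giving the pathway a
  realistic buffer before sequestration bites.

With these values the default instance shows: an interior maximum of the
uptake flux at ~53 uM cytosolic palmitoyl-CoA with steep decline and free
CoA collapse beyond it; MCKAT's acyl site at 60 uM occupied ~61% by
C4+C6-acyl-CoA, ~34% by other acyl-CoAs and ~3% by ketoacyl-CoA
substrates; and CPT1's flux control coefficient ~0.98 at 5 uM.

## What the synthetic generator emulates

`generate_ladder()` draws a full instance of the same topology with $K_m$
log-uniform on [1, 100] uM, $V_{max}$ log-uniform on [10, 1000] uM/min,
$sf$ uniform on (0.3, 1], the class equilibrium constants above and the
four printed MCKAT constants embedded. Same seed, same bits. These
instances exercise every analysis stage — conservation, steady states,
MCA theorems, regulation closure — without any downloaded file, and the
stoichiometric identity $J_{NADH}/J_{uptake} = n_0/2 - 1$ holds at any
converged steady state regardless of the drawn kinetics, which is what
makes it a parameter-free acceptance quantity. What generated instances
do **not** establish: agreement with the deposited rat-liver
parameterization's quantitative curves (peak location, occupancy
percentages, transition times). A green test on synthetic instances
certifies the machinery, not those digits.

`generate_linear_chain()` builds 2- and 3-enzyme reversible
Michaelis-Menten chains whose flux control coefficients follow in closed
form from the summation and connectivity theorems with hand-derived
elasticities; the finite-perturbation machinery is required to match this
independent oracle to 1e-4.

## Numerical choices

* **Integration**: an adaptive TR-BDF2 method (one-step, L-stable, with
  $\gamma = 2-\sqrt 2$ so both implicit stages share one iteration
  matrix), finite-difference Jacobians reused across steps, a
  stiffly-damped third-order embedded error estimate, and cubic-Hermite
  dense output. Runge-Kutta-type steps preserve the linear moiety
  invariants exactly up to Newton tolerance; the 400-min drift criterion
  (< 1e-6 relative) tests this end to end. No stiff integrator is
  available in the target R environment, which is why the package carries
  its own.
* **Steady states**: damped Newton on the moiety-reduced system (one
  species per moiety eliminated algebraically — free CoA, matrix
  carnitine — which removes the singular Jacobian directions), positivity
  safeguards in the line search, convergence to an absolute residual of
  1e-9 uM/min and then polished toward the machine floor. If Newton
  stalls, the state is relaxed by integration (200, 2000, 20000 min) and
  Newton retried. Scans seed every solve from the neighbouring solution
  and, when an interior flux maximum appears, re-scan the decline region
  descending: disagreements beyond 1e-6 are flagged as possible
  multistability, never averaged.
* **MCA**: control and response coefficients from central +/-1e-6
  relative perturbations (the published 0.0001%), each side re-solved
  from the reference state; an entry is accepted only when the one-sided
  estimates agree within 1%. This is why steady states are polished well
  below the perturbation signal. Response rankings use absolute value
  with lexicographic tie-break. The NAD$^+$/NADH ratio is perturbed
  jointly with the pool sum held fixed — a convention this package
  documents rather than inherits, since treating the ratio as one
  parameter requires one.
* **Regulation analysis**: $\Theta_j(t)$ uses analytic elasticities of
  the structured law and takes $d\ln X_j/dt$ exactly from the ODE
  right-hand side, never from differencing the trajectory; fixed pools
  contribute exactly zero. $|\bar\Theta|$ integrates $|\Theta|$ by
  trapezoid on a composite grid (geometric near $t=0$ for the fast
  transient, uniform across the relaxation) with sign-change
  subintervals split at the interpolated root, refined by doubling until
  the averages move < 0.05%. The 400-min horizon is extended (doubled,
  with a warning) when the endpoint is not within 1e-6 relative of the
  post-shift steady state — the packaged instance, with its large CoA
  buffer, genuinely relaxes more slowly than 400 min for large upshifts.
* **Degenerate inputs**: negative round-off concentrations are clipped to
  zero before rate evaluation (floor 1e-12, optional warning via
  `options(mfao.warn_clip = TRUE)`); zero rates make log-derivatives and
  elasticities undefined and are flagged, not silently propagated.

## Promiscuity surgery and occupancy conventions

`remove_promiscuity()` deletes the cross-chain competitor terms from each
treated reaction's denominator (own substrates and products stay) and
multiplies the rate by $\alpha = 1/n_{reactions}$ of the enzyme — the
even partition of the enzyme pool; the flux-proportional partition
variant reported to behave very similarly is noted but not implemented.
Surgery is idempotent and leaves single-reaction enzymes exactly alone.

The printed active-site occupancy formula counts the focal ligand twice
in its denominator, which breaks normalization; the package defaults to
the normalized convention $Occ_j = ([X_j]/K_j)/(1+\sum_k [X_k]/K_k)$, so
occupancies plus the free-site fraction sum to one, and keeps the literal
form behind `convention = "literal"` for comparison. The packaged
instance's occupancy shares at overload discriminate the two conventions
in favour of the normalized reading.

## Known limitations

* The deposited JWS Online parameterization of the rat-liver model is not
  redistributable with the package and the build environment is offline;
  `import_sbml()` is exercised against a hand-written synthetic SBML
  fixture instead. Digit-level reproduction of the published curves
  (critical concentration "about 50 uM", 66.4/30.4/1.6% occupancies,
  the 28-min rate peak, the 250-uM threshold of the MCKAT-depromiscuized
  variant) therefore depends on parameters the package had to choose
  itself; the packaged instance reproduces the mechanisms and orderings,
  not those digits.
* Two printed inter-variant orderings are not reproduced by the packaged
  calibration and are deliberately not asserted by the tests: the
  MCKAT-depromiscuized variant here declines above ~85 uM rather than
  250 uM, and the only-MCKAT-promiscuous variant declines slightly below,
  not above, the full model's critical concentration. Both hinge on the
  relative capacity margins of the alpha-partitioned enzymes in the
  deposited parameter set.
* SBML-imported models carry opaque expression rate laws: simulation,
  steady states and finite-difference MCA work unchanged, but surgery
  and analytic elasticities require the structured promiscuous form and
  refuse them explicitly.
* Only metabolic regulation is modelled; gene-expression
  (hierarchical) regulation, thioesterases, ketogenesis, CoA
  biosynthesis and enzyme channelling are out of scope.
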