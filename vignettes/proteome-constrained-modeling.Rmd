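---
title: "Proteome-constrained modeling of fermentative metabolism with pcfba"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Proteome-constrained modeling of fermentative metabolism with pcfba}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The model

`pcfba` implements metabolism-and-expression modeling: a conventional
stoichiometric network is extended with the reactions of gene expression
(transcription, mRNA degradation and dilution, tRNA synthesis and charging,
translation, protein degradation and dilution, enzyme complex formation,
ribosome and RNA polymerase assembly), and every catalysed flux is coupled
to the abundance of its catalyst:

* capacity: $v_j \le k_{cat,j}\,[E_j]$ for enzymes, and
  $\sum_p L_p\, v_{transl,p} \le k_{rib}\,[\mathrm{rib}]$ for shared
  machinery such as the ribosome (with $L_p$ the protein length in
  residues);
* steady state: synthesis of every catalyst balances its first-order
  degradation plus dilution by growth,
  $v_{syn} = (\mu + k_{deg})\,[X]$, with the dilution flux
  $v_{dil} = \mu\,[X]$;
* a fixed total modeled proteome: the summed mass of all
  protein-containing species equals a constant (g modeled protein per
  gCDW). When catalytic demand is below capacity the balance is filled by
  a pool of "dummy" protein of average amino-acid composition; the mass of
  all undersaturated catalysts plus free pools is the *inactive enzyme*,
  which is zero exactly when the proteome constraint is limiting.

At fixed growth rate $\mu$, substituting $[X] = v_{dil}/\mu$ makes every
constraint linear in fluxes, so each condition is a single linear program.
Because growth rate is an input, glucose-limited growth is simulated the
way a chemostat works: a binary search finds the minimal extracellular
glucose concentration $S_{min}(\mu)$ at which the program remains
feasible, where glucose uptake obeys Michaelis–Menten transporter
kinetics $q_S = k_{cat}[E]\,S/(K_M+S)$ with a fixed upper bound on the
transporter concentration $[E]$.

The linear program's objective maximizes the production of the dummy
protein. Feasibility is what defines the chemostat curve; the objective
makes the reported solution reproducible and forces the filler protein to
be actually synthesized — at full ribosome, amino-acid and ATP cost — so
that low growth rates carry a realistic substrate burden. We identify the
filler with the dummy protein: "inactive enzyme" is not a separate species
but the post-computed surplus
$\sum_c \mathrm{mass}_c\,([c] - [c]_{required})$ over all catalysts plus
free pools, which matches the interpretation of the quantity as the summed
inactive fraction of undersaturated enzymes.

## Sensitivity machinery

Two local, one-at-a-time analyses identify the active constraints:

* the scaled reduced cost of an amino-acid uptake bound,
  $R = (\Delta\mu/\Delta q)(q/\mu)$, computed by raising one bound by
  $\Delta q = 0.01$ mmol/gCDW/h and re-maximizing the growth rate at the
  condition's glucose setting. The increment is *absolute* for uptake
  bounds (matching the flux scale of the data) and *relative* (1%) for the
  two structural constraints — the transporter cap and the proteome size —
  whose sensitivity score is $S = (\Delta\mu/\Delta c)(c/\mu)$. Both
  interpretations are arguments, not constants.
* a robustness scan that multiplies each parameter (every $k_{cat}$,
  $k_{deg}$, machinery rate and the two budget terms) by 2 and by 1/2 and
  recomputes the maximal growth rate, flagging parameters that move it by
  more than 1%.

Reduced costs are computed by re-solving (finite differences), which is
robust to the degeneracy of these programs; the package also exposes the
LP-duality route (`min_glucose_uptake()` returns the duals of the bound
rows), and the test suite verifies that the two agree to within 10% for
all active bounds at several growth rates.

## The three-pathway allocation model

The switching behaviour has a closed-form core. Three ATP-producing
pathways — glycolysis with mixed-acid fermentation, glycolysis with
lactate formation, and arginine catabolism — are summarized by an ATP
yield $Y_i$ (mol ATP per mol substrate), a protein cost $p_i$ (g protein
per unit substrate flux) and a protein efficiency $e_i = Y_i/p_i$. These
are estimated from the metabolic layer by three linear programs (maximize
maintenance at glucose 1; maximize lactate at glucose 1 with maintenance
fixed at 2; maximize maintenance at arginine 1), with a flux-minimal
tie-break so the costs are reproducible. The allocation model then
maximizes $J_{ATP} = \sum_i Y_i J_i$ subject to $J_1 + J_2 = J_{glc}$,
$\sum_i p_i J_i \le P$ and $0 \le J_3 \le \alpha J_{glc} + \beta$.

On the bundled network the efficiency ordering is
$e_2 > e_1 > e_3$ (lactate > mixed acid > arginine), which produces three
phases as glucose uptake rises: (A) mixed acid plus arginine while the
proteome has slack, (B) arginine declines once the proteome is exhausted
(it is the least efficient ATP source), and (C) mixed acid is traded for
lactate. Phases are labeled from backward finite differences of the
pathway fluxes, so the first point of phase B is the first grid point at
which the inactive proteome is zero; slopes smaller than $10^{-9}$ times
the largest flux are treated as flat. A 3-variable vertex-enumeration
solver (`solve_small_model_analytic()`) provides an exact, independent
solution used to validate the LP route on randomized parameters; ties at
equal efficiency are broken toward lactate, deterministically. The
small-model sensitivities perturb the three constraint values
independently (the arginine bound is frozen at its base value during a
glucose perturbation), which makes the three relative scores sum to one by
Euler's relation for the degree-1-homogeneous optimum.

## The synthetic network

All computations run on a bundled fermentative network in the style of a
lactic acid bacterium. Design points that carry scientific content:

* **Arginine chemistry.** The ADI pathway is fully element- and
  charge-balanced: arginine/ornithine antiport, arginine deiminase,
  catabolic ornithine transcarbamylase and carbamate kinase, with both
  nitrogens leaving as ammonium. Written this way the pathway consumes
  three cytosolic protons gross, one of which is returned when its ATP is
  hydrolysed — a net consumption of two protons per arginine. With a
  reversible ATP synthase translocating 3 protons per ATP
  (`atpase_h_per_atp`, configurable) and weak acids leaving by proton
  symport, the linear program values those two protons at 2/3 ATP: the
  pathway's ATP yield is exactly $1 + 2/3 = 1.67$. Relaxing the cytosolic
  proton balance (and closing the synthase, which would otherwise become a
  free energy source) collapses the yield to the substrate-level 1.0 of
  carbamate kinase.
* **Side conditions found the hard way.** Net arginine assimilation is
  impossible through the antiport alone (each import trades an ornithine
  that only catabolism regenerates), so anabolic arginine enters through
  an ATP-driven importer. Biomass drains phosphorus and RNA dilution
  drains the adenylate moiety, so the medium supplies phosphate and
  adenosine (salvaged by adenosine kinase). All of these are real
  stoichiometric requirements that elastic-programming diagnosis of the
  early network versions exposed as exact conservation relations.
* **Study conditions.** The transporter cap (2.5e-5 mmol/gCDW), modeled
  proteome (0.13 g/gCDW with a 40% unmodeled share of average
  composition) and effective machinery rates (ribosome 2 aa/s, RNA
  polymerase 5 nt/s, 80 initiations per mRNA-hour, 6000 charging events
  per tRNA-hour — effective constants that fold initiation, maturation
  and idling overhead into a single number) place the proteome switch
  near $\mu \approx 0.45$–0.5/h and the maximal growth rate near 0.53/h,
  inside the dilution-rate window where the organism is usually grown.
  Amino-acid uptake bounds are linear in growth rate
  ($q \le a\mu + b$), with arginine by far the most generous — the
  configuration under which arginine overconsumption is optimal at low
  growth rates.
* **What the generator does not emulate.** Measurement error structure
  beyond Gaussian concentration noise; genome-scale coverage (the toy has
  ~20 genes, so the robustness scan cannot reproduce parameter *counts*,
  only the qualitative claim that parameters off the active constraints
  are inert); membrane crowding; kinetic regulation (NADH/NAD-mediated
  switching is out of scope by design). Passing tests on this network
  demonstrate the machinery and the mechanism, not organism-scale
  prediction.

The chemostat data generator simulates amino-acid measurements with
uptake linear in dilution rate (aspartate and glutamate get saturating
profiles as deliberate non-linear controls), back-computes supernatant
concentrations through $q = D\,(C_{sup} - C_{med})/X$, and adds 5%
Gaussian noise to concentrations. Ordinary least squares of uptake on
dilution rate recovers the bounds; negative intercepts are clipped at
zero before use as bounds.

## Numerical choices

These programs are nearly fully degenerate (almost every right-hand side
is zero) and mix turnover numbers (~1e5–1e6/h) with fluxes (~1
mmol/gCDW/h). Choices that matter:

* **Units.** Fluxes in mmol/gCDW/h; catalyst concentrations reported in
  mmol/gCDW; $k_{cat}$ stored in 1/h. Macromolecular species are carried
  in nmol internally (`macro_unit = 1e-6`) — except tRNAs, which stay in
  mmol because charging carries the amino-acid flux — so that all
  variables live within a few orders of magnitude of each other.
* **Solvers.** A revised simplex with an explicit basis inverse, LU
  refactorization, a Harris-type two-pass ratio test, a deterministic
  range-space right-hand-side perturbation against degeneracy
  (recovered against the unperturbed data at the end), and excision of
  artificial columns after phase 1; and a homogeneous self-dual
  interior-point method whose feasibility verdicts drive the bisections
  at scale. Tiny water/proton coefficients arising from float arithmetic
  in the automatic reaction balancing are snapped to zero — noise columns
  of magnitude 1e-16 are enough to derail pivoting.
* **Bisections.** Relative tolerance 1e-6 on the glucose concentration,
  1e-4 on growth rate, initial bracket S in [0, 1000] mM. Feasibility
  probes that fail numerically are retried at minutely perturbed growth
  rates (the verdict is continuous on a much coarser scale); a full
  optimization that cannot finish falls back to bisecting the objective's
  level set with pure feasibility probes.
* **Degenerate optima.** Reported solutions can be polished by a
  second pass minimizing total flux at the fixed objective
  (`minimize_total`), suppressing futile cycles and simultaneous
  forward/reverse flux.
* **Degenerate inputs.** A model with no expression layer at all is a
  valid degenerate case (used by the closed-form micro-model that
  validates the binary search); empty coupling tables, absent budgets and
  absent unmodeled-protein pins are all handled.

## Known limitations

* Floating-point feasibility near the growth-rate boundary is resolved to
  the bisection tolerance, not exactly; the package favours conservative
  verdicts.
* The interior-point duals carry the termination tolerance (~1e-6
  relative); exact vertex duals come from the simplex route.
* The robustness scan re-derives the growth rate per parameter and
  condition; on the full parameter set this is minutes of compute, so the
  default test-suite exercises a representative subset.
* Protein degradation of complexed enzymes uses a mass-weighted mean of
  the subunit constants; free-pool and complexed turnover are not
  distinguished kinetically.
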