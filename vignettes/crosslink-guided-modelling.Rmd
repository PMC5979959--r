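---
title: "Crosslink-guided structural modelling of oligomeric chaperones"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Crosslink-guided structural modelling of oligomeric chaperones}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(xlmod)
```

# Scope and model of the data

`xlmod` implements the computational chain behind an integrative structural
study of a homo-oligomeric chaperone (DNAJB6 is the worked system): the
protein resists crystallography and NMR because it forms polydisperse
oligomers, so the structure is approached sideways — candidate homology
models of the monomer are screened against chemical crosslinking data,
same-residue crosslinks prove inter-subunit contacts and seed dimer
docking, mixed-isotope crosslinking demonstrates subunit exchange,
elastic-network modes locate flexible loops, and SEC-SAXS sizes the
oligomer population. Each stage is an independent module with a synthetic
data generator, so the full chain is testable against closed-form or
constructed ground truth.

# Crosslink mass chemistry

All internal masses are neutral monoisotopic; m/z appears only at I/O
boundaries. The crosslinker constants are derived from the reagent
chemistry rather than copied from any table: BS3/DSS adds a suberate
bridge (C~8~H~10~O~2~ = 138.06808 Da), BS2G a glutarate bridge
(C~5~H~4~O~2~ = 96.02113 Da); a hydrolyzed deadend retains one
water-equivalent (+18.01056 Da); Tris-quenched deadends are supported via
a plain-text crosslinker config but disabled by default. Cysteine
carbamidomethylation is *not* applied by default (the workflow this
mirrors ran without fixed modifications). The ¹⁵N metabolic label shifts
each nitrogen by 0.997035 Da; labelling is treated as 100% efficient — the
~2% residual ¹⁴N in real ¹⁵N media affects isotope envelopes, which are
out of scope, not centroid arithmetic.

A reactive amine is a lysine side chain or the protein N-terminus.
Peptide N-termini created by digestion are *not* reactive, because
crosslinking precedes digestion in the protocol; for the same reason a
crosslinker-bearing lysine is treated as non-cleavable, which is why
crosslinked peptides show up with missed cleavages.

# Spectrum search

Digestion uses trypsin (after K/R) combined with low-specificity
chymotrypsin (after F/W/Y/L/M), both blocked before proline, with up to 2
missed cleavages. The chymotrypsin specificity set was chosen to match the
observed chymotryptic C-termini of the system's reported peptides (L and M
termini among them). Candidates comprise crosslinked pairs (including a
peptide with a second copy of itself — the homodimeric same-to-same link
that only an oligomer can produce), hydrolyzed deadends, and internal
looplinks.

Matching uses 10 ppm precursor and 0.05 Da fragment tolerances (0.2 Da
suits lower-resolution fragment spectra), considers precursors of charge
3+ and above (crosslinked pairs are rarely 2+), and filters each scan to
its 125 most intense peaks. With labelling enabled, all four isotope
states (14/14, 14/15, 15/14, 15/15) are matched; the states of a pair are
spaced by exactly 0.997035 Da times the nitrogen count of each peptide.

The fragment score is this package's own (laboratory practice pairs a
search-engine score with manual spectrum inspection): the share of total peak
intensity explained by theoretical b/y fragments multiplied by the
fraction of fragments matched. The manual acceptance criteria are encoded
as boolean flags — matched intensity above a threshold, fragments from
both peptides, and a bounded fraction of unexplained top-20 peaks — rather
than folded into the score. Fragments spanning a linked residue carry the
entire partner peptide plus bridge as a fixed mass; ring-opening fragments
of looplinks are not modelled. Candidate ranking ties break by smaller
absolute ppm error, then candidate id, for determinism.

Subunit exchange: hybrids (14/15 or 15/14) present in the
mixed-before-crosslinking arm and absent in the crosslinked-separately
control give `exchange = TRUE`. The synthetic exchange experiment draws
peptide labels independently per subunit (exchange) or per complex
(control), which is exactly the distinguishing statistic.

# Distance constraints and model selection

Constraints are evaluated as Cα–Cα distances (the convention of the data
this mirrors), with *satisfied* ≤ 30 Å — inclusive, so a constraint at
exactly 30 Å counts — and *violated* > 40 Å strictly; between the two the
constraint is *ambiguous*. On multi-chain models the reported distance is
the minimum over chain assignments, recording whether that minimum is
intra- or inter-chain; same-residue constraints are evaluated only across
distinct chains and are "inter-only, unevaluable" on a monomer.

Ranking: models with zero violations form the top tier; within a tier,
more satisfied constraints win; remaining ties break by lower mean
distance, then lexicographic model id. The tie-break chain beyond the
published outcome ("the only model without violations wins") is this
package's own deterministic rule. Residue addressing assumes PDB author
numbering equals 1-based sequence position.

Restraint export writes both a TSV (upper bound = the satisfied maximum)
and ambiguous-distance `assign` statements between Cα atoms of two
segments, the format information-driven docking engines consume. Running
a docking engine is out of scope.

# Elastic-network normal modes

The network is the full anisotropic model: one node per Cα, uniform
springs within a 10 Å cutoff, off-diagonal super-elements
\(-\gamma\,\Delta r \Delta r^{T}/d^{2}\), diagonal blocks closing each row
to zero. (The reference analysis used a rotation-translation-block solver
with one Cα per block, which in that limit coincides with the plain
Cα ANM; the block solver's exact spring convention is not published, so
the standard ANM convention is used and region-level claims are asserted
by window overlap rather than exact argmax.) Modes are numbered so that
1–6 are rigid-body and mode 7 is the first internal deformation; a
connected network must show exactly six numerically zero eigenvalues,
which the tests assert across 200 random synthetic structures.
Fluctuation profiles over a mode range are 1/λ-weighted means (thermal
amplitude proportionality) — a documented choice. Flexible regions are
called by an 11-residue sliding-window mean, ties to the lower residue
number.

# SAXS analysis

**Guinier.** The textbook prescription — the largest low-q window with
\(q_{max} R_g \le 1.3\) — systematically overestimates a sphere's
\(R_g\) by ~1.8% because the form factor's quadratic term in \(q^2\)
tilts the fitted slope. The window here is therefore additionally
curvature-limited: after expanding to the qRg bound, it shrinks while the
quadratic term's contribution at the window edge exceeds three times the
noise scale (supplied σ, or the quadratic-fit residual for noise-free
curves). On noiseless spheres this recovers \(R_g = R\sqrt{3/5}\) to
0.03–0.2%; at 2% multiplicative noise the median error is ~1.7%, because
the noise floor lets the window grow back to the qRg bound. A leading
low-q rise above the extrapolated Guinier line (and significant positive
curvature) raises the aggregation flag.

**Kratky.** The dimensionless transform \((qR_g)^2 I/I_0\) versus
\(qR_g\); the peak is located by bracketing the grid maximum and refining
on a cubic spline, so an exact-Guinier input reproduces
\((\sqrt3,\,3/e)\) to 1e-6.

**Porod.** \(Q=\int q^2[I-B]\,dq\) with an analytic Guinier piece below
the first data point and a \(K/q_{max}\) tail beyond the last. \(K\) and
the flat background \(B\) are estimated jointly by moment-matching over
the high-q tail (default: upper 35% of the q range) — a least-squares
slope of \(Iq^4\) on \(q^4\) is corrupted by form-factor oscillations,
while window means average across them. \(B\) is bounded above by the
smallest observed high-q intensity (a flat background cannot exceed an
intensity minimum) and below by zero; a negative estimate exceeding the
tail intensity is rejected. Noiseless spheres give \(V_p = 2\pi^2 I_0/Q\)
within 4.3% of \(\tfrac43\pi R^3\) across R = 20–50 Å, and truncating the
tail at \(qR_g = 8\) moves \(V_p\) by under 1%.

**P(r).** Regularized indirect transform on a fixed r grid with
\(P(0)=P(D_{max})=0\), non-negativity enforced by deterministic
active-set clipping, second-difference smoothness penalty, and the
regularization weight chosen as the largest of a fixed α grid that does
not degrade the misfit by more than 10%. \(D_{max}\) scans a trial grid
(default \(2.2\ldots4.2\times R_g\), step \(0.1 R_g\)); the misfit drops
off a cliff at the true \(D_{max}\) and then sits in a flat noisy basin,
so the chosen value is the smallest trial reaching the basin level
(within 3× of the upper-half median) without an abrupt P(r) edge (last
interior node below 10% of the peak). These numerical constants were
calibrated once against the closed-form sphere: \(D_{max}=2R\) within 5%,
shape correlation > 0.99, and P(r)-derived \(R_g\) within 2% of the
Guinier value. Zero-σ points are floored at 1e-6 of the curve maximum so
that form-factor minima cannot dominate the fit.

**Mass chain.** \(MW_p = V_p/1.6\) (kDa from nm³) and, when an ab-initio
excluded volume is available, \(MW_a = V_a/2\); the subunit count is
\(\mathrm{round}(MW_p/\text{monomer})\) with ties away from zero
(printed tables use commercial rounding; base R rounds half to even).
The published six-fraction table is reproduced exactly by this chain from
the Porod volumes alone, which also settles the ambiguity in the table's
"average MW~p~" footnote: each row's own MW~p~ is what the printed
subunit counts use.

# Synthetic data: what it does and does not emulate

Generators are pure functions of their seed (byte-identical outputs,
caller's RNG untouched) and every dataset ships a truth table. The toy
structures are an ideal α-helix (rise 1.5 Å, 100°/residue, radius
2.3 Å — consecutive Cα distance ≈ 3.8 Å), a hinged two-helix hairpin
whose turn is the known flexibility maximum, and a self-avoiding coil.
Decoys perturb Cα coordinates isotropically, rescaled to exact target
RMSDs (≥15 Å for selection-recovery experiments, i.e. decoys are
genuinely wrong folds). Crosslinks are sampled uniformly from lysine
pairs within 25 Å, so they are all satisfiable by construction. Spectra
carry exact b/y fragments with uniform intensities, optional ppm-scale
jitter, and exponential-intensity uniform-m/z noise peaks — the noise
model is this package's own, as no noise characterisation of the real
instrument data is available.

What passing these tests shows: the arithmetic, search logic, ranking
rule, eigen-solver and SAXS estimators are correct on data whose truth is
known. What it does not show: robustness to co-eluting contaminants,
chimeric spectra, isotope-envelope overlap, detector artefacts, or
inter-particle interference in concentrated SAXS samples — none of which
the generators emulate.

# Problem sizes and determinism

The shipped test suite uses 8–60-residue synthetic structures, a
46-residue toy protein (≈380 search candidates), 100-spectrum recovery
and 100-replicate selection experiments, and 500–2000-point scattering
curves; the whole suite runs in about a minute on one CPU. All
stochastic tests fix their seeds; the acceptance script seeds every RNG
from its `--seed` argument even though its reported quantities are
deterministic.

# Known limitations

* The published DNAJB6 monomer and dimer model PDB files (journal
  supplementary material) are not redistributable here; the checks that
  reproduce their published distances (K20–K25 = 8.7 Å;
  K189–K189 = 23.5 Å across the dimer interface) and the mode-7–11
  flexibility maximum at residues 195–205 activate only when those files
  are placed under `inst/extdata/supplementary/`.
* Search scores are not comparable to any external engine's score column;
  FDR estimation by decoy databases is out of scope.
* The dimer K232–K232 distance is printed inconsistently across the
  source material (30.6/20.6/31.3 Å) and is therefore not used as a
  reference value anywhere.
* No command-line wrapper is shipped: the package functions, this
  vignette and `scripts/acceptance.R` are the interface.
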