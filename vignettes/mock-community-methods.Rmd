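---
title: "Methods: genome-copy enumeration, mock design and QC statistics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: genome-copy enumeration, mock design and QC statistics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mockforge)
```

mockforge turns raw enumeration measurements into genome/cell
concentrations, concentrations into mixing recipes, assay outputs into
relative abundances, and abundances into quality scores. This vignette
records the models behind each step, the tunable parameters with their
defaults and rationale, what the simulator does and does not emulate, and
the design choices made where the design was genuinely open.

## 1. Enumeration models

### Adenine-HPLC (genome counting)

Acid depurination releases the adenine of genomic DNA, quantified by HPLC.
The package starts from the reported adenine amount in mol/mL (chromatogram
peak integration and calibration belong to the instrument, not to this
package). Two conversion routes are provided:

**Count route (reference).** One adenine per A:T pair in duplex DNA, so a
genome of $L$ bp at GC fraction $g$ holds $L(1-g)$ adenines and

$$C_\text{genomes} = \frac{A \cdot N_A}{L(1-g)} \cdot d$$

with $A$ the adenine molarity (mol/mL), $N_A = 6.02214076\times10^{23}$
(the 2019 SI exact value, a module constant) and $d$ the dilution factor of
the assayed solution relative to the initial cell resuspension.

**Mass route (cross-check).** Adenine is first converted to total DNA mass
via the base composition — adenine nucleotide fraction $f_A = (1-g)/2$,
mean nucleotide mass $\bar m = f_A(m_{dAMP}+m_{dTMP}) +
\tfrac{g}{2}(m_{dGMP}+m_{dCMP})$, DNA grams $= (A/f_A)\,\bar m$ — then
divided by the mass of one genome, $L \cdot 660 / N_A$.

The default dNMP masses are the free-acid values (331.22, 322.21, 347.22,
307.20 g/mol). Their pair sums (~654 g/mol) sit just below the conventional
660 g/mol/bp, so the two routes differ by $\bar m / 330 \approx 0.99$ —
about 1%, nearly independent of GC. This inconsistency is inherent to using
the 660 convention alongside physical dNMP masses; rather than resolving it
silently, the count route is designated the reference implementation, the
mass route is retained as a cross-check, and the test suite asserts 2%
agreement across the full GC range of the registry (28.8–65.0%).

### Flow cytometry (cell counting)

The stained sample is spiked with a volume ratio $r$ (protocol: 1/100) of
reference beads at known stock concentration $B$. In the measured mixture
the beads sit at $B\,r/(1+r)$; the cell concentration follows from the
event ratio, and the factor $(1+r)$ corrects the dilution of the sample by
the spike itself:

$$C_\text{cells} = \frac{n_\text{cell}}{n_\text{bead}} \cdot
  \frac{B\,r}{1+r} \cdot (1+r) \cdot d
  = \frac{n_\text{cell}}{n_\text{bead}} \, B\, r\, d.$$

At $r = 1/100$ the spike correction is a 1% effect; it is applied exactly
rather than ignored, and exactness matters for the simulator's round-trip
identities.

### Microscopy (cell counting)

Cells trapped on a filter of effective area $F$ are counted in $k \ge 1$
imaged fields of area $a$ (the reference protocol uses $\ge 30$):

$$C_\text{cells} = \overline{n}_\text{field} \cdot \frac{F}{a} \cdot
  \frac{1}{V_\text{filtered}} \cdot d.$$

The arithmetic mean over fields is used with no edge-of-field correction
(none is defined by the protocol being modelled).

All three conversions are linear in their raw signal and compose
multiplicatively in dilution factors; both properties are tested. Counts
can be expressed per OD$_{600}$ unit by plain division (`normalize_to_od`);
whether "adjusted to 1 OD unit" means division or re-dilution to OD 1 is
ambiguous in the source protocol — division is assumed, recorded here once.

## 2. Mixing recipes

**Cell mock.** The batch volume is `aliquot_volume × aliquot_count +
dead_volume` (defaults 100 µL × 100 + 0 = 10 mL). The target
4 × 10¹⁰ mL⁻¹ is interpreted as the *community total* by default — the
protocol sentence is ambiguous between total and per-strain, so the choice
is an explicit `concentration_mode` field, never silent, and both modes are
supported. Per-strain volumes are a mass balance
$v_i = c_\text{target}\,V / c_{\text{stock},i}$; diluent fills the rest.
A negative diluent is an `infeasible-design` error (you cannot concentrate
by diluting), checked *before* per-strain stock availability so the two
failure modes are distinguishable. Dead volume defaults to 0 because the
reference protocol is silent; real pipetting needs excess, hence the knob.

**DNA mock.** "Equimolar genomes" pins each strain's final *mass*
concentration to its genome size: $m_i = T \cdot L_i / \sum_j L_j$ with
$T = 50$ ng/µL total (defaults 30 µL × 50 aliquots). The implied genome
molarity, $m_i / (660 L_i / N_A)$, is then identical across strains by
construction; `verify_recipe` re-derives achieved concentrations from raw
volumes and stock concentrations — an independent mass balance, not a
read-back of the recipe's own bookkeeping — at relative tolerance 10⁻⁶.

Volumes are reported in µL (displayed at 4 dp); strain matching is exact on
`strain_id` with no fuzzy matching.

## 3. Readout models

**ddPCR.** Template molecules partition into ~20,000 droplets
approximately Poisson, so the negative-droplet fraction estimates
$e^{-\lambda}$ and $\hat\lambda = -\ln(1 - n_+/n)$. Saturated wells
($n_+ = n$) are an error, not infinity. Concentration scales by the
droplet volume (default 0.85 nL, instrument-nominal, overridable), the
template dilution, and `probe_copies_per_genome` (default 1, for
single-locus strain-specific probes; restriction digestion and template
loading arithmetic are bookkeeping inside `template_dilution_factor`).
Relative abundance normalises the genome-equivalent concentrations within
each (batch, replicate).

**Shotgun sequencing.** kallisto-layout count tables are parsed, targets
mapped to strains (summing replicons) and normalised either per genome
copy (`genome_normalized`, the default — counts divided by genome length,
putting shotgun on the same basis as ddPCR) or `raw`. Whether published
compositions used length normalisation is not stated in the protocol being
modelled; both modes are first-class.

## 4. QC statistics

Replicates are averaged within batch first; the percent CV (sample SD,
$n-1$, over mean) of each strain's batch means measures preparation
reproducibility across batches (≥ 2 required). AFD is the fold ratio
between measured and theoretical abundance folded to ≥ 1 (default), or
$|\log_2|$ as an alternative — the exact formula in the cited SOP lineage
is not restated in the source, so both candidates are implemented and the
report names its mode; they satisfy $\text{fold} = 2^{|\log_2|}$. Zero
observed abundances are excluded from AFD with a warning rather than mapped
to infinity. Welch's $t$ (unequal variances, Welch–Satterthwaite df,
two-sided) compares pooled per-strain CV or AFD sets between condition
labels — pooled across strains, matching boxplot-style presentation; the
degenerate zero-variance/equal-means case returns $t = 0, p = 1$.
Significance stars annotate reports only and never drive control flow.

## 5. What the simulator emulates — and what it does not

`simulate_study` reproduces the comparison design of the reference study:
two preparation conditions (`cell_hplc`, `cell_fcm`) differing only in
enumeration noise, three batches each, ddPCR + shotgun readout in
triplicate. The causal chain is the important part: per batch, stocks are
re-measured with channel noise, the recipe is computed from the *estimated*
concentrations, and the achieved composition follows from the *true*
concentrations — so enumeration error becomes batch-to-batch compositional
variability exactly as it does at the bench.

Noise models and defaults:

| parameter | default | rationale |
|---|---|---|
| `adenine_cv` | 0.03 | HPLC channel, low multiplicative noise |
| `cytometry_cv` | 0.15 | event counting, boundary/aggregation error |
| `droplet_total` | 20,000 | instrument-nominal droplet count |
| `template_copies_per_ul` | 3,500 | per-strain λ ≈ 0.2 for 15 strains: mid Poisson range |
| `sequencing_depth` | 10⁶ | desk-scale MiSeq-like replicate |
| `stock_copies_per_ml` | 10¹² | condensed glycerol stock |

Continuous channels use unit-mean lognormal multipliers (concentrations are
positive); discrete channels use binomial droplets and multinomial reads
with weights $f_i L_i b_i$ ($b_i$ = optional extraction bias, placed at the
template level where differential lysis acts). The channel CVs are stated
constants of the simulated world, not fitted to any published figure — the
source reports no numeric channel CVs — and they are never tuned against
test outcomes. A single root seed derives independent per-channel
substreams, so identical configs are byte-identical and adding a channel
never perturbs another.

Deliberately **not** emulated: cell-cycle genome replication (the reason
genome counts exceed cell counts ~1.1–1.4-fold in real cultures — the
package reports `basis = genomes` vs `cells` and leaves interpretation to
the user), aggregation/morphology-dependent undercounting, chromatogram and
fluorescence-amplitude shapes, and GC- or strain-specific assay bias beyond
the explicit `extraction_bias` knob. A green end-to-end test therefore
establishes that the *computational* pipeline is self-consistent and
propagates noise correctly — not that any real mock will achieve the
simulated CVs.

With all noise zero (`assay_stochastic = FALSE`), every channel inverts its
conversion exactly and the pipeline returns CV = 0 and AFD = 1 — this
round-trip identity is what forced two small representational choices:
simulated `cell_events` and deterministic `positive_droplets` are allowed
to be non-integral expectations (real instrument tables, which are
integers, are unaffected).

## 6. Numerical choices and degenerate inputs

* GC content is stored as a fraction but read/written as percent, making
  the 100× conversion explicit at the file boundary; registry loading
  rejects GC ∉ (0, 100) exclusive, duplicate strain ids, and non-integer
  genome sizes, naming the offending row.
* $N_A$ is fixed at the exact SI value; 660 g/mol/bp is a named constant.
* Recipes conserve volume to 10⁻⁶ relative; achieved-vs-target checks use
  relative error; equimolarity is verified to 10⁻⁹ relative.
* Abundance groups must sum to 1 within 10⁻⁹ (grouping keys are built so
  missing condition labels cannot silently drop groups).
* Errors are classed conditions (`mockforge_infeasible_error`,
  `mockforge_insufficient_stock`, `mockforge_saturation_error`, ...) and
  the CLI maps them to distinct exit codes (3, 4, 1-series).

## 7. Known limitations

* Multi-replicon genomes are represented only by their summed size.
* Registry GC values are taken as authoritative; the package never computes
  GC from sequence or fetches accessions.
* The mass/count route discrepancy (~1%) is documented, not resolved.
* Microscopy aggregation bias and ddPCR rain/threshold effects are out of
  scope; the simulator will not reproduce them.
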