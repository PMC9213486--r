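---
title: "Methods and models in alkaneSIP"
author: "alkaneSIP authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods and models in alkaneSIP}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(alkaneSIP)
```

# Scope

`alkaneSIP` implements the analysis chain used to identify bacteria that
actively assimilate gaseous alkanes (ethane, propane) in DNA
stable-isotope probing (SIP) experiments: headspace gas accounting,
CsCl-gradient fraction handling, a three-criterion classifier of
^13^C-labelled taxa, genome relatedness indices with species calls, MAG
quality filtering and dereplication, and a soluble di-iron monooxygenase
(SDIMO) marker screen with fragment-recruitment abundance estimation.  A
forward simulator of the whole SIP experiment, with full ground truth,
makes every stage testable without any sequencing data.

Upstream read QC, assembly, binning, and completeness/contamination
estimation are out of scope: quality metrics and count tables are consumed
as inputs.

# The gradient model

In an isopycnic CsCl gradient, DNA bands at a buoyant density that
increases with both GC content and ^13^C incorporation.  We use the
Schildkraut-type affine model

$$\rho(\mathrm{GC}, a) \;=\; \rho_0 + s\,\mathrm{GC} + a\,\Delta\rho_{max},$$

with intercept $\rho_0 = 1.660$ g/ml, slope $s = 0.098$ g/ml per GC
fraction, and a full-labelling shift $\Delta\rho_{max} = 0.036$ g/ml at
atom fraction excess $a = 1$.  Both coefficients are standard CsCl
literature values and are configurable in `gradientParams()`; the original
experiments measured density rather than modelling it, so these constants
are a modelling choice of this package.  Refractive index (the measured
proxy) converts to density by the affine calibration
$\rho = 10.9276\,\mathrm{RI} - 13.593$, also configurable because
refractometer calibrations are temperature-specific.

Each taxon's DNA is a Gaussian band centred at $\rho(\mathrm{GC}, a)$ with
standard deviation `band_sigma` (default 0.004 g/ml), integrated over 12
equal-width fraction intervals; band mass outside the gradient span is
truncated and renormalised so mass is conserved.  Fractions are numbered 1
= densest, matching heavy-first fraction collection.  Two refinements on
the pure Gaussian picture:

* **Background smear.** A small fraction of every taxon's DNA
  (`background`, default 2%) is spread uniformly across all fractions.
  Real SIP gradients always show a background of unlabelled DNA in the
  heavy fractions; without it the ^12^C-control heavy pool would be
  literally empty and the control-based labelling criterion would be
  undefined.  Setting `background = 0` recovers the pure Gaussian band
  (used in the band-width unit tests).
* **Gradient span.** The default span 1.696–1.756 g/ml places four
  fraction midpoints inside the heavy pooling window (1.7296–1.7491 g/ml)
  and two inside the light window (1.7123–1.7216 g/ml), matching the 3–4
  heavy and 2–3 light fractions typically pooled from a 12-fraction SIP
  gradient.

Sequencing counts per fraction are multinomial draws with size
proportional to the fraction's DNA mass share and probabilities
proportional to per-taxon mass in the fraction.  Each vial has its own RNG
stream derived deterministically from (seed, substrate, isotope,
replicate), so any vial is reproducible in isolation.

## The synthetic community

`simulateCommunity()` draws 30 taxa of which 3 are gaseous-alkane
consumers at 5–15% relative abundance each and 100 atom% excess when fed
the labelled gas; background abundances are Dirichlet(1).  GC contents are
uniform on 0.42–0.57.  That range is dictated by the physics of the fixed
pooling windows: under the affine model, fully labelled DNA bands inside
the heavy window only for GC between roughly 0.34 and 0.54 (plus the band
width), while unlabelled DNA of GC 0.53–0.63 bands in the light window.  A
community whose GC runs much higher would push fully labelled consumer DNA
*above* the heavy window, where it can never be pooled — a real limitation
of fixed-window SIP designs that users analysing high-GC communities (the
isolates in this field are often 63–67 mol% GC) should keep in mind, since
in practice partial labelling (atom excess well below 1) moves bands back
into the window.

What the simulator deliberately does not model: gradient relaxation
dynamics, per-fraction qPCR, chimeras, sequence-level reads for the SIP
stage (counts only), and cross-feeding of label — incubations in this
design are kept short precisely so cross-feeding is negligible.  Passing
tests therefore demonstrate correctness of the pipeline's logic under the
banding model, not robustness to those real-data effects.

# Heavy/light pooling and the labelling criteria

`poolFractions()` pools a fraction into the heavy (light) pool iff its
density lies inside the closed heavy (light) window; both window endpoints
are inclusive because the published endpoints are themselves densities of
pooled fractions.  Fractions between the windows are discarded.  A vial
with an empty pool is flagged unusable rather than silently dropped.

A taxon is called ^13^C-labelled iff all three criteria hold, with strict
inequalities throughout:

1. relative abundance in the heavy pool of the ^13^C incubation
   $> 1.0\%$;
2. heavy $>$ light abundance within the ^13^C incubation;
3. (heavy − light) of the ^13^C incubation $>$ (heavy − light) of the
   ^12^C control.

Relative abundances are computed within each pool independently (each
pool sums to 100%), matching amplicon profiling practice; taxa absent from
a pool get abundance 0.  Duplicate vials are averaged per pool before the
criteria are applied — the published description does not state how
duplicates enter the criteria, so averaging is the package default, with
`replicate_rule = "all"` available to require every replicate pairing to
pass.

A known property of the criteria worth stating plainly: in an experiment
with *no* labelling at all, criteria 1 and 2 can still hold for taxa whose
bands sit close to the heavy window, and criterion 3 then reduces to a
coin flip on sampling noise.  The control comparison constrains, but does
not eliminate, chance positives; the published workflow guards against
this by first confirming successful labelling in the density profiles.
With genuine labelling present, the classifier on the default design
recovers exactly the planted consumers (see the acceptance suite).

# Headspace gas accounting

Concentrations (% v/v) convert to amounts by the ideal gas law,
$n = P V_{gas} / (R T)$ at 25 °C and 1 atm by default (the incubation
temperature); dissolved-gas partitioning is ignored, a documented
approximation that understates total consumption by the (small) dissolved
fraction.  Carbon-normalised cumulative consumption divides by fresh
sample mass, and measurement noise is handled by running-maximum clipping
rather than smoothing, preserving the monotone contract without inventing
a filter.  Harvest points report the earliest time the cumulative
consumption reaches a target (the 100 and 200 µmol C g^-1^ rules).
Consumption rates are ordinary least-squares slopes of cumulative
consumption against time over the declining phase, cut off when substrate
first falls below 5% of its initial concentration (the source does not
state its fitting window; 5% is this package's default), with mean and
standard deviation across replicate vials.

# Alignment, e-values, and database search

`globalAlign()`/`localAlign()` expose optimal Needleman–Wunsch and
Smith–Waterman alignment with affine gaps (a gap of length $k$ costs
`gap_open` $+ k\,$`gap_extend`; defaults 5 and 2, +1/−2 nucleotide match
scores, BLOSUM62 for proteins), computed by Biostrings' dynamic
programming.  The test suite verifies the scores against an explicit
enumeration of every alignment path for short sequences.  E-values follow
the Karlin–Altschul form $E = K m n e^{-\lambda S}$ with standard
published parameters (nucleotide: $\lambda = 1.33$, $K = 0.621$; gapped
BLOSUM62: $\lambda = 0.267$, $K = 0.041$); they are comparable to, but not
bit-identical with, BLAST's internally fitted values.  Percent identity
defaults to the all-columns convention (matches / alignment length, as
BLAST reports); because the 95% recruitment cutoff is sensitive to this
choice, the mode is recorded in every output.

Genome-scale searches — fragment ANI, reciprocal-best-hit AAI, marker
screening, and read recruitment — run through the NCBI BLAST+ suite
(`makeblastdb`/`blastn`/`blastp`, required on the PATH), with
low-complexity masking disabled so identity estimates on arbitrary
sequence content are unbiased.  Best hits are by bitscore with a
deterministic tie-break on subject id.

# Relatedness indices and dereplication

* **ANI** follows the JSpecies fragment convention: 1020 bp consecutive
  fragments (tails < 100 bp dropped), fragments kept when their best hit
  reaches ≥ 30% identity over ≥ 70% of the fragment; ANI is the mean
  identity of kept fragments, symmetrised by averaging the two directions.
* **AAI** is the mean identity over reciprocal best hits (thresholds: 20%
  identity, e-value 1e-5, 50% query coverage — documented defaults, since
  the published workflow reports RBH AAI without thresholds).  The two
  directional identities of each RBH pair are averaged, making the index
  exactly symmetric.
* **TETRA** is the Pearson correlation of 256-component tetranucleotide
  z-score signatures, computed on both strands against a maximal-order
  Markov (trinucleotide) expectation with the Teeling variance
  approximation.
* **Species calls** use the recommended cut-offs, 95% ANI and ~70% AAI,
  inclusive at the boundary; ANI decides when defined, otherwise AAI.
* **Quality filter**: completeness strictly > 70% and contamination
  strictly < 5%, consumed as given (CheckM-style estimation is upstream).
* **Dereplication**: single-linkage clusters over pairs with ANI ≥ 95%;
  per cluster the highest score, completeness − 5 × contamination (the
  dRep formula; the published workflow says only "highest scoring"),
  is retained, with alphabetical tie-break.

# SDIMO marker screen

The screen searches each proteome against a reference panel of SDIMO
large-subunit and pMMO-like markers (*mmoX*, *bmoX*, *prmA*, *dmpN*,
*tmoA*, *pmoA*) and assigns candidates the group of their nearest
reference — Group I (aromatic/alkene), II (phenol), III (sMMO/butane), IV
(ethene/propene), V and VI (propane), or pMMO-like — when identity reaches
the 40% assignment floor, else `"undefined"` (mirroring alpha subunits
that do not cluster within a known group).  Nearest-reference assignment
is a deliberate surrogate for maximum-likelihood tree placement; it keeps
the screen dependency-free and deterministic, at the cost of ignoring
branch structure.  The bundled panel generator produces *synthetic*,
mutually unrelated reference sequences (clearly labelled as such), which
keeps groups separable under identity; real reference proteins can be
substituted by accession through `readMarkerPanel()`.

Fragment recruitment recruits a read/scaffold iff its best hit against
the MAG has identity strictly > 95% and e-value strictly < 1e-5; abundance
is the recruited percentage.  Queries under 100 bp are skipped and
counted, since e-values are unreliable there.  Whether recruitment runs on
raw reads or assembled scaffolds is the caller's choice; the result
records only counts and percentages.

# Numerical choices and degenerate inputs

* Strict inequalities exactly where the published rules print ">" or "<";
  inclusive window endpoints and species cut-offs as argued above.
* Pool totals of zero raise an explicit undefined-pool error; undefined
  ANI/AAI return `NA` with a reason string instead of a number.
* Multinomial sizes are `round(depth × mass share)`, so per-vial read
  totals can differ from `depth` by rounding; counts within a fraction
  always sum to the drawn size.
* All simulation seeds are 32-bit; per-vial streams are affine
  combinations of the base seed reduced mod $2^{31} - 1$.

# Problem sizes used by the test and acceptance suites

Simulated designs use 30 taxa × 12 fractions × 8 vials at 5 × 10^4^ reads
per fraction; ANI recovery uses a 200 kb genome at 1/5/10% substitution
divergence (unit tests use 60 kb); AAI recovery uses 100 proteins of
200–400 aa at 10% divergence; recruitment mixtures use 100 error-free
500 bp reads against a 50 kb genome; the alignment oracle enumerates all
alignments for 100 random pairs of length ≤ 8; the marker screen is
verified over 20 seeded replicates with 1–3 planted markers in
25-protein proteomes.  These sizes were chosen so that every quantity is
recomputed from scratch in well under a minute each on a single CPU while
leaving the statistical targets (±0.5 ANI, ±1 AAI, exact recruitment
percentages) comfortably resolvable.

# Known limitations

* The affine GC–density model and the fixed 0.036 g/ml full-label shift
  are idealisations; real gradients show run-to-run calibration drift,
  which is why every coefficient is exposed.
* Counts-only simulation cannot exercise amplicon-specific artefacts
  (chimeras, copy-number variation, primer bias).
* E-values from the internal Karlin–Altschul estimator and from BLAST+
  differ in their fitted constants; thresholds at 1e-5 are robust to this
  but exact e-values are not comparable across the two routes.
* Nearest-reference group assignment cannot discover novel SDIMO groups;
  it can only declare candidates `"undefined"`.
* With synthetic random marker references, inter-family identities are
  near the noise floor; real SDIMO families share 30–60% identity, so the
  40% assignment floor matters more on real panels than in the tests.
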