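---
title: "Methods: mining, mass prediction and MS annotation of MSDIN cyclic peptides"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: mining, mass prediction and MS annotation of MSDIN cyclic peptides}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(msdintools)
```

This vignette is the package's account of its science: the models it
implements, the parameters that matter, what the synthetic generator does
and does not emulate, and the design choices made where the design was
genuinely open. It states no empirical result that the test suite or the
acceptance script does not itself compute.

## The biological model

MSDIN genes of lethal *Amanita* mushrooms encode short precursor peptides
with a tripartite architecture: a highly conserved 10-residue leader
beginning with Met (the family is named after the typical first five
residues, Met-Ser-Asp-Ile-Asn), a hypervariable core of 5–12 residues,
and a 15–17-residue follower (recognition) sequence that runs to the end
of the protein. The macrocyclase POPB cleaves at the two prolyl junctions
and joins the core head-to-tail. Amatoxin products additionally carry a
tryptathionine Trp–Cys bridge, four hydroxylations and a sulfoxide;
cores lacking Trp or Cys cannot form the bridge and their products are
expected unmodified.

## Mass arithmetic

All masses derive from a fixed internal table of monoisotopic element
masses at 6 decimals (C 12.000000, H 1.007825, N 14.003074, O 15.994915,
S 31.972071), with proton 1.007276 Da and electron 0.000549 Da. Freezing
the constants makes the 4-decimal reported m/z values reproducible
independent of external tables; at the 4th decimal the choice of constant
set is immaterial but the proton-vs-hydrogen distinction is not:
`[M+H]+` must use the proton mass (the hydrogen-atom mass is 0.000549 Da
heavier and misses published 4-decimal values).

Residue masses are computed from residue formulas (amino acid minus one
water), never taken from a rounded literature table, so that the two mass
routes — residue-mass summation and formula-count summation — agree to
floating-point precision. `peptide_mass()` exposes both routes and the
tests assert their equivalence on 1000 random peptides (tolerance 1e-5
Da), which guards the element bookkeeping.

A head-to-tail cycle is simply the residue sum; the linear form adds one
water. Reporting rounds m/z and ppm to 4 decimals; internal arithmetic is
never rounded. One consequence, worth making explicit: a ppm deviation
computed against the full-precision theoretical m/z can differ from one
computed against the 4-decimal rounded value by up to ~0.08 ppm.
`screen_precursors()` works at full precision (so that a synthetic
spectrum generated at the theoretical mass screens at exactly 0 ppm);
published delta-ppm values are reproduced exactly by applying
`ppm_delta()` to the printed (measured, theoretical) pairs.

## The amatoxin modification state

The amatoxin template is an ordered list of element-count deltas:
tryptathionine −2 H (requires Trp and Cys), hydroxylation +4 O, sulfoxide
+1 O — net +5 O −2 H, +77.958925 Da. This is a *net composition* model:
intact-mass matching needs no placement of the modifications, and the net
delta reproduces both amanitin formulas (C39H54N10O14S and C39H53N9O15S)
and their `[M+H]+` values from the cores IWGIGCNP/IWGIGCDP alone. The
template applicability rule (Trp AND Cys present) is the only structural
check; hydroxylation-variant prediction and congeners are out of scope. A
phallotoxin template ships as a disabled configuration stub because
phallotoxins are absent in the target species. `candidate_mass_list()`
emits every core's unmodified candidate plus one modified candidate per
enabled, applicable template.

## Precursor mining

Mining is a position-specific motif scan, replacing homology search: the
pattern is fully determined by the published precursor set, requires no
external database, and is configurable (`precursor_model()`). Defaults:

* leader (10 positions): `M [ST] [DN] I N [AS] [TLSI] [RH] [LF] [PA]` —
  the terminal `[PA]` admits the Ala-terminal leaders of the α-/β-amanitin
  genes;
* follower start: `[CYF] [VIA] [GSDA]`;
* core length 5–12; follower length 15–17; precursor length 30–40.

Stop codons terminate candidate windows: a precursor must lie entirely
between stops, anchored at a Met whose 10-residue context matches the
leader. The core/follower boundary is genuinely ambiguous from the
pattern alone (cores may contain C/F residues), so the scanner takes the
*leftmost* candidate position whose follower-start pattern matches **and**
whose implied follower length — measured to the window end — falls in
15–17. This resolves, for example, the internal Cys of IWGIGCNP, whose
implied follower would be 20 residues. The rule splits all 21 published
precursors exactly into their printed leader/core/follower columns (tested
row-for-row).

Nucleotide input is translated in all six frames under the standard code
and each frame is scanned; hits carry the frame and the forward-strand
interval. Windows are assumed intronless — intron-containing MSDIN genes
(the real genes have four exons) must be supplied as transcripts or
proteins. Deduplication reports both keys: by core (the family-level
census; 17 for the published set) and by full precursor sequence (18 for
the published 21 rows — the source text's "17 unduplicated sequences"
does not match its own table, so the package reports both rather than
guessing).

## Fragment library

A macrocycle has no termini; fragments arise after ring opening. The
library is the union over the n ring openings (rotations) of the b/y
series, i.e. all contiguous *arcs* of the cycle of length 1..n−1, each
with b chemistry (arc sum + proton) and y chemistry (arc sum + H2O +
proton); plus immonium ions (residue − CO + H − e⁻) of the distinct
residues; plus neutral-loss variants (−NH3 for arcs containing K/R/N/Q,
−H2O for S/T/D/E — standard eligibility rules, consistent with the
reported NH3 loss "on Lys"); plus the precursor and its eligible loss
ions. Entries deduplicate by (kind, m/z rounded to 4 decimals), so
equal-composition arcs collapse. Only 1+ fragments are emitted, matching
the annotation practice for these compounds. A brute-force arc
enumeration (modular indexing, direct mass summation) serves as the test
oracle.

Two published daughter-ion labels are not contiguous arcs of their
cycles: "GGI" for cyclo(GFGFIP) and "KPP" for cyclo(GKVNPP) ({K,P,P}
cannot be contiguous in G-K-V-N-P-P). The library does not special-case
them; matching is mass-based. The CylK2 fixture preset keeps the reported
count of 11 matched fragments by carrying the arc model's corresponding
predicted ion `y:NPP` as the seventh y-type ion; the CylK1 preset carries
the 6 arc-consistent y ions plus the Ile/Phe immonium ions and omits
"GGI". Both substitutions are deliberate, documented modeling choices,
not attempts to reproduce the original labels.

## Spectrum matching

Matching is deterministic because the original annotation was manual:
each library entry is matched to its nearest peak, and the match stands
if the deviation is within `tol_ppm` (default 10 ppm for fragments, 5 ppm
for precursors) or within an absolute floor of 0.002 Da — the ppm window
at immonium masses (~70–130 m/z) is below realistic mass accuracy, so a
pure ppm rule would be overstrict exactly where diagnostic ions live. A
peak may annotate several isobaric entries; an entry never matches more
than one peak. Coverage is the fraction of arc lengths 1..n−1 with at
least one matched non-precursor ion, and the score is the intentionally
simple, monotone `n_matched + coverage`; no decoy/FDR model is attempted
because the workflow this package reproduces performs none. Tolerance
monotonicity of `n_matched` and the noise-robustness bound (expected
false matches per 50-noise-peak spectrum ≈ 1e-3 at 10 ppm; asserted as
at most 3 matches across 100 seeded replicates) are tested.

## Expression tiers

The tier scheme is zero (FPKM = 0), low (0–1), mid (1–100), high (>100).
Only the `<1` and `>100` boundaries are stated by the source study; the
mid tier fills the gap and all boundaries are configurable
(`tier_scheme()`). Gene copies sharing a core are summarized by per-core
maximum FPKM (per-copy values remain available); replicate statistics and
differential expression are out of scope — the package consumes a single
FPKM column.

## Synthetic data: what a green test establishes

The generator states a world and stays there:

* **Proteomes** — decoy proteins draw residues uniformly from the 20
  letters (not proteome-realistic composition; a motif this specific has
  a per-window match probability around 1e-10, so uniform decoys give a
  tractable, conservative null). Each embedded precursor is flanked by
  `*` terminators, as it would be in the six-frame translation of its
  gene — without a terminator the follower length measured to the
  sequence end would leave the window unparseable, which is the correct
  behavior of the window model, not a miner defect.
* **Contigs** — precursors are reverse-translated with random synonymous
  codons, flanked by in-frame TAA stops, and inserted on a random strand
  into background DNA of configurable GC (default 0.5).
* **Spectra** — one 1+ spectrum per core: precursor at theoretical
  `[M+H]+`, a configurable ion subset (default: the full non-precursor
  library; presets for the two published annotation sets), Gaussian m/z
  jitter of σ = 2 ppm (well inside a 10 ppm window), and 50 uniform noise
  peaks over the 500–1700 m/z scan range with intensities below the true
  ions. Intensities are cosmetic: matching ignores them by default.
* **FPKM tables** — default: the published 24-row table verbatim;
  alternatively log-normal draws with a zero point mass, whose tier
  counts are checked against analytic tail probabilities.

Everything is a pure function of the seed (byte-identical files), and
every fixture carries ground truth sufficient to score recovery. A green
round-trip therefore establishes internal consistency of miner, mass
model, library and matcher under stated noise — not performance on real
proteomes (non-uniform composition, homologs near the motif boundary),
real spectra (isotope envelopes, multiply charged ions, intensity
structure) or real expression data (replicates, length biases).

## Numerical choices and degenerate inputs

* Formula subtraction errors on negative counts; template requirements
  are checked before any arithmetic.
* Cyclic peptides need length ≥ 2; `AA`-type symmetric cycles collapse to
  single library entries by the dedup rule.
* Rounding for deduplication and for reports is 4 decimals, the printed
  precision of the values this package reproduces.
* Ties in nearest-peak matching are resolved by `which.min` (first
  minimum); with 4-decimal theoretical values, exact ties require peaks
  closer than any realistic peak spacing.
* The miner's output order is (source id, start), independent of input
  order.

## Known limitations

Splice-aware gene structure, homology/HMM search, isotope envelopes,
multiply-charged fragment prediction, intensity modeling, FDR control and
transcript quantification are deliberately absent. The amatoxin model is
a net-composition inference validated only by mass agreement; it cannot
distinguish positional hydroxylation variants, and it will accept any
Trp/Cys-containing core whether or not the bridge forms in reality.
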