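# msdintools

Genome-guided discovery of MSDIN cyclic peptides in R.

Lethal *Amanita* mushrooms make their toxins (α-/β-amanitin, phallotoxins)
and many other macrocyclic peptides ribosomally, from a family of short
precursor genes named **MSDIN** after the first five residues of the
precursor. Each precursor is tripartite: a conserved 10-aa **leader**, a
variable 5–12-aa **core**, and a 15–17-aa **follower** (recognition)
sequence. The prolyl oligopeptidase POPB excises the core and joins its
ends head-to-tail into a macrocycle, which may then be further modified —
in amatoxins by a tryptathionine (Trp–Cys) bridge, four hydroxylations and
a sulfoxide.

`msdintools` implements the desk-scale analysis that links such a genome
to its peptide products, for natural-product and proteomics researchers:

* **Mining** (`find_msdin_precursors`, `mine_fasta`,
  `translate_six_frames`): position-specific motif scan for the
  leader/core/follower architecture in protein or six-frame-translated
  nucleotide FASTA, with deduplication (`deduplicate`) and known/novel
  classification (`classify_cores`).
* **Mass prediction** (`peptide_formula`, `peptide_mass`, `mz_protonated`,
  `candidate_mass_list`): exact monoisotopic arithmetic for linear and
  cyclic peptides. A head-to-tail cycle of residues r₁…rₙ has formula
  Σ residue formulas (the linear form adds one H₂O) and
  [M+H]⁺ = Σ mᵢ + m_p with the proton mass m_p = 1.007276 Da. The amatoxin
  modification state is a net formula delta +5 O −2 H applied when the
  core contains both Trp and Cys (`apply_template`, `amatoxin_template`).
* **Fragment prediction** (`build_library`, `ring_openings`, `by_series`,
  `immonium_mz`): ring opening at each of the n amides yields the n
  rotations; y-type arcs carry Σ(arc) + H₂O + proton, b-type arcs
  Σ(arc) + proton, immonium ions residue − CO + H − e⁻, with −NH₃
  (K/R/N/Q) and −H₂O (S/T/D/E) neutral-loss variants.
* **Spectrum matching** (`read_mgf`, `screen_precursors`,
  `annotate_fragments`, `build_report`): ppm-tolerance precursor screening
  (δppm = (measured − theoretical)/theoretical × 10⁶), deterministic
  nearest-peak fragment annotation, and a theoretical-vs-measured report
  with the N/A convention.
* **Expression tiers** (`load_expression_table`, `tier_classify`,
  `expression_ratio`): FPKM tier classification (zero / <1 / 1–100 / >100)
  and pathway-gene contrasts.
* **Synthetic data** (`make_proteome`, `make_contigs`, `make_spectra`,
  `make_fpkm_table`): fully seeded fixtures with machine-readable ground
  truth.

## Worked example

```r
library(msdintools)

# mine the 21 published precursor proteins
hits <- find_msdin_precursors(msdin_precursor_seqs())
census <- classify_cores(deduplicate(hits))
census
#> <msdin_census> 21 precursor(s), 17 group(s) by core, 17 unique core(s), 14 novel

# theoretical masses of all candidate cyclic peptides
cands <- candidate_mass_list(census$unique_cores)
subset(cands, core %in% c("IWGIGCNP", "GFGFIP"))
#>       core modification       formula neutral_mass       mz
#> 1 IWGIGCNP         none  C39H56N10O9S     840.3952 841.4025
#> 2 IWGIGCNP     amatoxin C39H54N10O14S     918.3542 919.3614
#> 5   GFGFIP         none    C33H42N6O6     618.3166 619.3239
```

The amatoxin-modified IWGIGCNP candidate is α-amanitin: its [M+H]⁺,
919.3614, is the value a 1⁺ ESI measurement should match within a few
ppm. Fragment annotation of a spectrum of cyclo(GKVNPP):

```r
lib <- build_library("GKVNPP")
sim <- make_spectra("GKVNPP", sim_config(seed = 1, spectrum_jitter_ppm = 0,
                                         n_noise_peaks = 0),
                    ion_spec = ion_preset("cylk2"))
annotate_fragments(sim$spectra[[1]], lib)
#> <spectrum_match> sim_GKVNPP vs cyclo(GKVNPP): 11 matched ion(s), coverage 1.00, score 12.00
```

11 matched ions — the Pro immonium (70.0651), seven y-type arcs and three
NH₃-loss variants of the Lys-containing arcs; coverage 1.0 means every arc
length 1–5 of the 6-ring has at least one matched ion.

Expression tiers of the published FPKM table:

```r
tier_classify(ref_expression_table()[1:21, ])$counts
#> zero  low  mid high
#>    5   10    4    2
expression_ratio(ref_expression_table(), "POPB", "POPA")
#> [1] 25.52647
```

A command-line front end covering the same operations is installed at
`system.file("cli", "msdin-tools.R", package = "msdintools")`.

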