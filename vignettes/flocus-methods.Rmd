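---
title: "Modelling copy-number dynamics at the cucumber F locus"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling copy-number dynamics at the cucumber F locus}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(flocus)
```

## The model

Gynoecious (all-female) sex expression in cucumber is controlled by the
dominant, dosage-dependent *F* locus, a copy-number variant built from a
~30.2-kb tandem-repeat unit. A monecious haplotype carries one unit with
three genes (*CsACS1*, *CsMYB*, and the downstream *CsBCAT*); a gynoecious
haplotype carries two units in tandem, the second bearing *CsACS1G* — a
duplicate of the ethylene-biosynthesis gene *CsACS1* whose distal promoter is
a 1504-bp recombinant block of *CsBCAT* parts (intron 8 truncated to 928 of
984 bp, exon 9, intron 9, exon 10, reverse-complemented), reaching −1914 from
the transcription start while the proximal −410 to 3' UTR region is
essentially identical to *CsACS1*.

`flocus` implements this structure and its two consequences:

1. **Dosage genetics.** Total *CsACS1G* dosage *d* across the diploid maps
   deterministically to phenotype: *d* = 0 monecious (M), *d* = 1
   subgynoecious (SubG), *d* ≥ 2 gynoecious (G)
   (`dosage_phenotype()`).
2. **Meiotic instability.** Because the units are near-identical tandem
   repeats, bivalents can misalign and undergo unequal crossing over (UCO),
   producing reciprocal deletion and duplication gametes
   (`simulate_meiosis()`, `enumerate_gametes()`). Rare UCO in a two-unit
   homozygote explains the "gynoecy loss" monecious mutants found at ~0.12%
   in selfed gynoecious inbreds, and the duplication product explains
   natural triple-repeat gynoecious lines.

## The UCO model and its parameters

A meiosis has at most one crossover opportunity in the F-locus interval
(the interval is short on the genetic map, which also keeps the rate
parameter interpretable as a per-meiosis event probability). With
probability 1 − μ, or whenever no misaligned register exists, the gamete is
a uniformly chosen parental haplotype — a single-unit homozygote
(`[A]/[A]`) therefore never mutates. With probability μ the arrays misalign
by an offset drawn from `offset_weights` (default: offset 1 only, single
register slippage) and registers *i* ≠ *j* recombine as
`hap1[1..i] + hap2[j+1..]`, each reciprocal product recovered with
probability ½. Unit identity travels with its 5' promoter. Reciprocal
conservation (the two products sum to the parental unit total) is a tested
invariant.

μ is not directly observable. `calibrate_uco_rate()` inverts the screen
design by monotone bisection: it computes the exact expected frequency of
*confirmed* mutants (dosage < 2 offspring whose selfed progeny segregate
monecious plants, with the progeny-test power term `1 − (1 − P(M))^n`)
under the gamete enumeration, composed over any prior single-plant selfing
generations. For the pooled observation of 6 confirmed mutants among 4809
plants the inversion gives μ ≈ 1.25 × 10⁻³ per meiosis, the package
default. Whether the three Gy14 mutants arose in the observed generation or
the two preceding selfings is not identifiable from the screen; the default
design assumes the observed generation (`prior_selfing_generations = 0`),
and the alternative is exposed. The generation chain caps haplotypes at
`max_units = 5`; the truncated mass is O(μ²) and immaterial at calibrated
rates.

Population simulation (`self_population()`) samples offspring counts from
the exact genotype distribution (multinomial over `cross()` probabilities)
rather than looping per-plant meioses — the same law, at screen scale.
Intermediate generations follow a single-plant lineage, matching screens
grown from one founder plant.

Transient male flowers on truly gynoecious plants are observation noise,
not phenotype state: `p_transient` (default 63/2236, the screens'
tagged-minus-confirmed fraction) controls spurious tagging only, and
tagged true-G plants are rejected by the progeny test. Because this
parameter is set from the same counts it emulates, it is never used as a
recovery target.

## Synthetic loci

`assemble_locus_sequence()` builds `flank5 | units | CsBCAT | flank3` on a
seeded random background (GC = 0.35, cucumber-like). The A and G unit cores
are byte-identical (optionally diverged by two injected SNPs, mirroring the
two SNPs observed between the *CsACS1* and *CsACS1G* cores; their
positions are configurable because the published alignment does not place
them). The A unit's "native distal promoter" is simply the sequence
upstream of its −410 boundary — the tail of the preceding unit or flank —
so the G-unit length exceeds the A-unit length by exactly the 1504-bp
recombinant block, and a unit boundary sits at the 5' end of each distal
promoter. That boundary convention is what makes the UCO concatenation rule
well-defined.

The default G unit is 30,200 bp. Everything scales by a `scale` factor
except the length-derived constants (1504-bp block, 410-bp proximal
promoter, 111-bp junction amplicon), so tests and examples run at
`scale = 0.1` (~3-kb units) with unchanged structural targets. Coordinates
are 0-based half-open internally; GFF3 output is 1-based inclusive via
`rtracklayer`; promoter positions are additionally reported as negative
offsets from the transcription start (−410, −1914).

In-silico PCR (`insilico_pcr()`) uses exact matching on both strands
(primers were designed against known sequence; no mismatch model) and
reports every facing plus/minus site pair within `max_product` (default
1000 bp, small enough that a junction primer never pairs with the next
unit's proximal promoter even on a down-scaled locus). The junction pair
(`junction_primer_pair()`) sits with the left primer in the
reverse-complemented exon-10 segment of the promoter block and the right
primer just inside the proximal promoter: one 111-bp product per G unit,
and on a monecious locus both sites exist only in opposing orientations
(the left primer's sequence occurs solely reverse-complemented inside the
trailing *CsBCAT*), so no product forms — missing primers and opposing
orientations are reported distinctly.

## Copy-number estimation

**Read depth.** `simulate_depth()` draws independent per-window counts
(Poisson by default; a negative-binomial option with dispersion 0.1 exists
because real resequencing is overdispersed, but no dispersion estimate is
available to justify a different default) with expectation proportional to
`coverage × window / read_length × copies / 2`; flanks have diploid copy 2
and the CNV interval carries the genotype's total unit count, since all
units of a tandem array map onto the single-unit reference.
`call_cnv_from_depth()` takes the ratio of 10%-trimmed mean window depths
(CNV / flank), excluding boundary-straddling windows — trimming damps the
edge and mapping artifacts such profiles show in practice. Calls snap to
the half-integer grid with exact ties going to the nearest even half
(IEC 60559). The CNV interval is given, as in the underlying experiment; no
segmentation is attempted.

**Genomic qPCR.** `simulate_qpcr()` writes
`Ct = base − log_E(copies/2) + N(0, σ)` with efficiency E = 2 by default
(no standard curve; efficiencies were not reported) and σ = 0.15 cycles,
k = 7 replicates. Template copies follow the locus structure: *CsACS1* and
*CsMYB* count all units; BCAT9–10 counts G units plus the trailing
*CsBCAT*; BCAT1–8 is the single-copy normaliser; the junction amplicon
counts G units only, and zero template records the "no amplification"
sentinel (`NA`), propagated as 0 copies rather than a large Ct.
`estimate_copy_qpcr()` averages per-replicate `E^(Ct_ref − Ct_target)`
values (within-sample ΔCt; a calibrator-based ΔΔCt variant exists for
expression data, where the published normalisation strategy is explicit).

A consequence worth stating: with σ = 0.15 and k = 7, the ΔCt estimate has
standard deviation σ√(2/k) ≈ 0.080 log2 units, a floor no estimator of
this design can beat. The half-integer call window is ±0.25 copies in
absolute terms, so its width *relative* to the estimate shrinks with copy
number: calls at 1, 1.5 and 2 copies are correct in ≈100%, ≈99.6% and ≈97%
of replicate tables, but at 3 copies the window spans only about ±1.5
standard deviations and the per-table call accuracy tops out near 87%. The
*modal* call over repeated tables is still 3 essentially always, which is
how multi-table summaries report the triple-repeat class; single-table
half-integer calls above ~2.5 copies should be treated as indicative, a
limitation inherited by any ΔCt design with this replicate budget.

**Expression.** `simulate_expression_ct()` models 3 biological × 3
technical replicates (biological σ = 0.15, technical σ = σ/3);
`relative_expression()` averages technical replicates within biological
ones before ΔΔCt, so downstream Welch tests (`welch_t()`) run on n = 3
biological folds, the unit of replication in the assay it emulates. The
generator's knockdown scenario uses a 4-fold reduction for *CsACS1* and
*CsACS2* — the published comparison reports significance at P < 0.01 but
no fold change, and 4-fold gives comfortable power at these noise levels
without being trivial — and fold 1 for *CsMYB*.

## Segregation statistics

`chisq_gof()` uses the uncorrected Pearson statistic (the printed 3:1 F2
p-value matches the uncorrected form, so no continuity correction is
applied) with closed-form upper tails for df 1 (`erfc(√(x/2))`) and df 2
(`exp(−x/2)`); these agree with the incomplete-gamma survival function to
10⁻¹⁰ in the tests. Each test is reported standalone; no multiplicity
correction, matching the source analyses. `mutation_rate()` uses
Clopper–Pearson intervals (success counts are ≤ 3, where Wald intervals
misbehave) and prints percentages truncated to two decimals — the printed
screen rates (0.13%, 0.11%, 0.12%) are reproduced exactly only under
truncation, which the source also applies to its p-values (0.6976 vs the
computed 0.69768). Welch's unequal-variance t test is the default for
k = 3 replicate groups; the degenerate all-constant case returns p = 1 by
convention.

## What the generator does and does not emulate

`generate_scenario()` produces deterministic, seed-keyed bundles (files plus
a `truth.json` of every latent quantity) for six scenarios: the two
gynoecy-loss screens, the segregation table of crosses, six read-depth
profiles (three gynoecious at ratio 2, three monecious at 1), the 30-line
qPCR panel (5 hermaphroditic + 13 gynoecious at 2 copies, one triple-repeat
line at 3, 8 monecious at 1, 3 SubG F1 at 1.5 — class counts emulated,
line identities synthetic), and the mutant expression comparison. Bundle
manifests record the configuration, seed and package version but no
timestamp, so identical runs are byte-identical.

The generator reproduces the *statistical structure* of the study's data,
not its biology: no read-level errors, mapping bias or GC bias in depth
profiles; no qPCR efficiency drift, plate effects or inhibition; phenotypes
are noiseless given dosage (environmental sex modification enters only as
tagging noise); no other sex-determination loci (*M*/*m*, *A*/*a*) and no
genome-wide recombination. Passing recovery tests therefore demonstrates
that the estimators are correct under the stated noise model — not that
they are robust to artifacts real data may add. Problem sizes in the test
suite (3-kb loci, 10⁵-meiosis frequency checks, 50-replicate screen
round-trips, 100–1000-table qPCR summaries) were chosen so the full suite
documents every claim at desk scale.

## Known limitations

- The published assembly spans (35,572 bp in one reference, 94,849 bp in
  the other) have endpoints that differ between assemblies and no
  per-feature coordinates, so the synthetic locus targets the 30.2-kb unit
  size rather than either span.
- UCO offsets beyond ±1 are configurable but default-off; nothing in the
  screens constrains them.
- The per-meiosis rate μ is identifiable only jointly with the screen
  design; both design assumptions are implemented but cannot be
  distinguished from the published counts.
- Half-integer qPCR calls above ~2.5 copies hit the accuracy ceiling
  described above.
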