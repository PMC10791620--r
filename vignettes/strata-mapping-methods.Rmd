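---
title: "Methods: mapping evolutionary strata from cross and population variant data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: mapping evolutionary strata from cross and population variant data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## Overview

`ystrata` infers where recombination between a young X and Y chromosome has
ceased, gene by gene, using only transcriptome-derived variant calls and
reads mapped to X-linked coding sequences. The pipeline has four inferential
stages — Y-linked SNP detection, Y gametolog consensus assembly, per-gene
population-genetic statistics, and boundary/gradient inference — plus a
synthetic-data generator that provides ground truth for all of them. This
vignette records the model assumptions, the tunable parameters, the
numerical conventions, and the design decisions taken where more than one
reasonable choice existed.

## Detection model and its assumptions

A Y-linked allele in a dioecious species is transmitted from father to sons
and never to daughters, and in the wild appears only in males. Two filters
operationalise this:

* **Cross segregation.** Candidate sites are father-heterozygous and
  mother-homozygous-reference (`candidate_parental_sites`): with RNA reads
  from X and Y co-mapping onto the X CDS, a fixed X:Y difference looks
  heterozygous in the father. A candidate passes `segregation_filter` when
  missing genotypes among the 53 progeny number strictly fewer than
  `max_missing = 10`, no daughter genotype contains the alternate allele,
  and at least `min_males_with_alt = 10` of the 21 sons do. "Contains" means
  het or hom-alt: sons are hemizygous for the Y allele, but X reads make the
  call appear heterozygous, and coverage noise can push it to hom-alt, so
  containment is the robust reading.
* **Wild population.** A site passes `population_filter` for a species when
  at least `min_males = 6` of its 7 wild males carry the alternate allele
  and none of its 7 wild females does.

Both cohorts are pre-filtered at caller quality strictly greater than 500
(`quality_filter`). The placement of this threshold is ambiguous between
cohorts in the source protocol; we apply it to both and expose `min_qual` as
a parameter. Grandparents of the cross are deliberately unused: no stated
criterion involves them.

The two classes fail differently near the PAR boundary, and that asymmetry
is the mapping signal: segregation in a finite cross cannot detect *rare*
recombination, so pseudoautosomal genes close to the boundary can masquerade
as Y-linked, whereas male-specificity across unrelated wild individuals
cannot be mimicked by a recombining gene. The segregation-based boundary is
therefore read as a detection limit, and the wild-data boundary as the real
PAR edge.

## Y gametolog assembly

`select_y_reads` assigns a read to the Y if it overlaps at least one
Y-linked SNP and shows the alternate allele at at least one of them — whole
reads, no per-base posterior phasing, exactly mirroring the read-separation
design the filters imply. `call_consensus` takes a per-position majority
over the selected reads. Numerical conventions:

* zero coverage, or coverage below `min_depth`, gives `N`;
* an exact tie gives `N` — the original workflow resolved such cases by
  visual inspection, which cannot be automated, so the conservative call is
  "neither allele trusted";
* `min_depth` defaults to 1 because selected read sets are small (only reads
  physically overlapping a Y-SNP qualify); raise it when depth allows.

Completeness is 100 × (non-N positions)/(X-CDS length), and premature stops
are sought in-frame with N-containing codons skipped. A premature stop in a
Y consensus indicates either genuine pseudogenisation or a consensus error;
it is reported, never silently dropped.

## Statistics

**Divergence.** The X:Y divergence estimator is Nei–Gojobori (1986) counting
with Jukes–Cantor correction, d = −(3/4)·ln(1 − (4/3)p). Fractional
synonymous site counts are averaged over the two sequences; difference
counts at multi-hit codons are averaged over minimal mutational pathways,
excluding pathways through stop codons (if every ordering is blocked, all
are used). Codons containing N in either sequence are excluded; p ≥ 3/4 is
flagged saturated rather than extrapolated. The original analyses used a
desktop tool whose exact formulas are unpublished, so equivalence with that
tool is *not* claimed — NG86+JC is adopted as the standard simple estimator
and all reported values should be interpreted under it. An independent
brute-force implementation (translation table from Biostrings, recursive
pathway enumeration) lives in the test suite as an oracle and agrees to
1e-12 on random codon pairs.

**Diversity.** π is the mean over masked sites of pairwise differences per
pair compared, with pairwise deletion of N. The fourfold mask keeps a
third-codon position only when every sequence with a resolved codon there
shares identical first two bases *and* those bases form a fourfold family —
polymorphic codon context drops the column, preventing mis-scored sites.
Male and female cohorts should be summarised separately: in males,
"diversity" at sex-linked genes is inflated by fixed X:Y differences.

**Linkage disequilibrium.** Kelly's Z<sub>nS</sub> is the mean r² over all
pairs of segregating sites. On simulated data it is computed on true
haplotype indicators; on field data, where phase is unknown, the alt-allele
dosage (0/1/2) per individual is the r² proxy. Both routes go through the
same `kelly_zns`; monomorphic input columns are an error, not a silent 0.

**Boundaries.** `infer_boundary` returns the distal-most (smallest
coordinate; the PAR occupies the low-coordinate end) gene whose count for
the evidence class reaches `min_count = 1` — a single qualifying gene moves
the boundary, exactly as a per-gene evidence table is read. An optional
robustness mode (`robust = c(k, m)`: require k of the next m proximal genes
to also qualify) is provided but off by default, since the default must
reproduce the table-reading convention. Stratum length is reported with
whole-Mb truncation of both boundary positions (floor(b/1000) difference),
matching the headline convention that calls a 41,574 kb boundary "41.5 Mb"
and the bracketed length "14 Mb"; exact kb lengths are attached as an
attribute. Note the bracket: between ~34.7 and ~41.5 Mb the reference
annotation contains only weakly expressed genes (FPKM < 1), which are
invisible to transcriptome-based evidence, so the strata-3/2 boundary is
bracketed by (34.7, 41.5) Mb rather than pinpointed.

**Gradient.** `gradient_test` fits an ordinary least-squares slope of
K<sub>s</sub> on position within a stratum and permutes the K<sub>s</sub>
values across positions (one-sided, ≥ 999 permutations, mandatory seed):
p = (1 + #{permuted ≥ observed})/(1 + n). A positive, significant slope —
divergence increasing proximally — is the signature of gradual recombination
cessation; a step change would instead suggest a single inversion.

## The synthetic world

`sim_config` defaults state the study design the package targets, and they
are not dials to be tuned per test:

| parameter | default | meaning |
|---|---|---|
| `n_sons`, `n_daughters` | 21, 32 | cross progeny |
| `n_wild_males`, `n_wild_females` | 7, 7 | wild samples per species |
| `boundaries_kb` | 24843, 27082, 41500 | segregation detection limit, PAR/Str3, Str3/Str2 |
| `theta_per_site` | 0.02 | PAR-like neutral diversity |
| `divergence_profile` | PAR 0; Str3 0.01→0.08 linear; Str2 0.064 | expected synonymous X:Y divergence |
| `par_recomb_prob` | 0.5 | free recombination, distal PAR |
| `par_recomb_prob_near` | 0.02 | rare recombination between the detection limit and the PAR boundary |
| `depth`, `read_len`, `err` | 30, 100, 0.001 | sequencing model |
| `frac_silent_genes` | 0.2 | genes with FPKM < 1 (emit no reads) |

X haplotypes come from a standard neutral coalescent without intragenic
recombination (exponential coalescence at rate k(k−1)/2 in units of 2N;
Poisson mutations at θL/2 per lineage per unit time; infinite-sites placement
onto L positions), so E[π] = θ and E[S] = θL·Σ1/i serve as analytic oracles.
The Y is one extra pool draw; in non-recombining strata Poisson(d·S)
substitutions are added on the Y branch at synonymous-capable positions with
probability proportional to each site's synonymous fraction, choosing a
synonymous target base. Parameterising divergence directly as expected
synonymous divergence d (rather than time × rate) makes recovery targets
well-defined: a downstream K<sub>s</sub> estimate should return d.

Two deliberate deviations from the most literal transmission model:

* **Symmetric paternal transmission.** A crossover in the PAR moves alleles
  off the Y background into daughters as well as onto sons' X. If daughters
  could never receive the paternal "Y-side" allele, a Y-private coalescent
  allele at a freely recombining PAR gene would pass the segregation filter
  with probability ≈ 0.67 (≥ 10 of 21 sons keep Y; daughters silent), and
  the filter could not reject free recombination — contradicting both the
  biology and the filter's purpose. So each daughter's paternal allele swaps
  from X<sub>f</sub> to Y with the same `par_recomb_prob`. With
  `par_recomb_prob = 0`, no daughter can ever carry a Y-specific allele, by
  construction.
* **Two PAR recombination regimes.** A single per-gene swap probability
  cannot express both "freely recombining distal PAR" and "rare
  recombination near the boundary"; `par_recomb_prob_near` (0.02) applies to
  PAR genes proximal to the segregation detection limit and produces the
  qualitative phenomenon the detection limit exists to flag: genes that pass
  segregation yet fail the wild population filter.

What the generator does **not** emulate — so a green test does not establish
robustness to it: allele-specific or variable expression (beyond the silent
flag), intragenic recombination, gene conversion, selection and demography,
Y diversity (all wild males share one species Y), indels/splicing artefacts,
mapping and duplicate-read artefacts, base-quality structure, and species
divergence between the two simulated species beyond their different
sex-linkage profiles. Wild genotype tables are perfect calls from the true
haplotypes; caller noise enters only through the read-level path
(`emit_reads` → `naive_genotype_caller`), whose thresholds (site emitted on
≥ 2 alt reads making ≥ 20% of a sample's coverage; het in 20–80%; missing
below coverage 5) mirror a conventional mpileup-style workflow at desk
scale.

## The bundled evidence table

`inst/extdata/table1_evidence.tsv` is a hand-transcribed per-gene evidence
table for the distal arm of the *S. latifolia* X reference: 64 genes, three
Y-SNP evidence classes, X:Y K<sub>s</sub> and Y-CDS completeness. The source
typography runs some numeric cells together; cells with more than one
defensible split are flagged in an `uncertain` column (an addition to the
column contract) and nothing downstream leans on a flagged K<sub>s</sub> or
Y-CDS value — boundary and census quantities use only positions, stratum
labels and count presence/absence, which are unambiguous. Two border
annotations in the source are kept as comments, not data rows. Positions
stay in kb exactly as printed and are divided by 1000 only at reporting
time; the one-decimal Mb report for the strata-3/2 boundary *truncates*
(41,574 kb → 41.5 Mb), because that is demonstrably the source's own
convention (it also truncates 41.5 → "41 Mb" for the length arithmetic).

## Limitations

* Transcriptome-based: silent genes (FPKM < 1) are invisible, so boundaries
  through low-expression regions are brackets, not points.
* The K<sub>s</sub> estimator is NG86+JC; codon-model (ML) estimates will
  differ, especially at high divergence.
* Boundary inference with `min_count = 1` is exactly as sensitive to a
  single spurious evidence count as the table-reading convention it mirrors;
  use the robustness mode to probe stability.
* ZnS from unphased genotypes is a dosage-correlation proxy, not haplotype
  r²; simulated and field values are comparable only route-for-route.
* The naive genotype caller exists to close the simulation loop; it is not a
  replacement for a production caller on real data.
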