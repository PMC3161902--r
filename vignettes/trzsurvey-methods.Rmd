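---
title: "Classifying green plant tRNase Z proteins by motif architecture"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifying green plant tRNase Z proteins by motif architecture}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(trzsurvey)
```

## The biological problem

tRNase Z (RNase Z; the homolog of the human prostate-cancer susceptibility
protein ELAC2) is the endonuclease that removes the 3'-trailer of precursor
tRNAs by cleaving immediately after the discriminator nucleotide (N73, the
first unpaired base after the acceptor stem), a prerequisite for addition of
the 3'-CCA. The enzyme belongs to the metallo-β-lactamase (MBL) superfamily
and carries its five conserved motifs: Motif II (`HxHxDH`, the "His motif")
is the superfamily signature, Motifs I and IV carry invariant Asp residues,
Motifs III and V conserved His residues. What distinguishes tRNase Z from
other MBL proteins is the flexible arm (exosite), a substrate-binding
insertion between Motif II and Motif III, and a set of accessory motifs
(PxKxRN, HEAT, HST) implicated in CCA anti-determination and terminal proton
transfer.

Green plants carry multiple tRNase Zs falling into three architectures:

* **TM-type short form** (~300-400 aa): a short (~30 aa) flexible arm with
  the Lys/Leu-rich **KL motif** (`KLKxxYxxLxGxxIxxLK`) and no GP motif; a
  Gly-rich **EGxSxxG** motif in the position where other types carry
  PxKxRN; and variant catalytic motifs **xExT** and **HxH** in place of
  HEAT and HST.
* **Bacterial-type short form**: a ~55 aa GP-motif (`GxPxGP`) arm, a
  PxKxRN motif (in plants, the Lys→Leu variant `Px[KL]xRN`), and canonical
  HEAT and HST.
* **Eukaryotic long form** (~700-1000 aa): a tandem duplication whose
  C-terminal half retains the full catalytic architecture (PxKxRN, Motifs
  I-V, HEAT, HST) and whose N-terminal half keeps only degenerate
  pseudo-motifs (pseudo-PxKxRN, pseudo-Motifs I/II) plus a longer (~62 aa)
  GP arm.

Proteins resembling tRNase Z but missing one or more required motifs are
tRNase Z-like proteins (**TLPs**), subtyped S or L by size. The package
also implements the related chloroplast observation: many chloroplast tRNA
genes encode part of the 3'-CCA, quantified as the census of the
trinucleotide at positions 74-76 immediately downstream of the
discriminator (categories `CCA`, `CCN`, `CNN`, `OTHER`).

## Motif models and scanning

Motifs are degenerate consensus patterns, not profile HMMs or PSSMs: each
position is an exact residue, a bracketed residue set, or a wildcard, and a
window is a hit when its mismatch count over non-wildcard positions does
not exceed the model's tolerance. This is deliberately the same level of
description at which the family's motifs are communicated; it keeps every
scan exhaustively checkable against brute-force window enumeration (the
suite does exactly that on randomized cases).

Default tolerances: 0 mismatches for patterns of length ≤ 6, 1 for longer
patterns (the 18-residue KL motif is variable in practice), with two
explicit exceptions: `HEAT` is scanned with 1 tolerated mismatch (its
variants are common) and `HST` with 0 (it is short enough that one
mismatch would make it vacuous). All values are overridable through the
plain-text catalog format (`read_catalog()`).

Motifs I, III, IV and V have no published full consensus — only their
invariant Asp/His anchors — so the default catalog ships minimal anchored
patterns (`xxDx`, `xHxx`, `xDxx`, `xHxx`). These are intentionally weak;
their placement is disciplined by the chain step below, and the
classification weight rests on the fully specified motifs.

Pseudo-motifs of the long form's N-half are modeled as the parent pattern
with the mismatch tolerance raised by 2 and the catalytically critical
position *required to mismatch* the consensus (they differ from their
parents at critical residues). A consequence accepted by design: the
pseudo-Motif I model (`xxDx` with the Asp required to differ) matches any
Asp-free window, so it is treated strictly as weak corroborating evidence
and never drives a call.

## Motif chains: order consistency

The family's motifs occur in the same relative N-to-C order in every
member in which they are present. `find_motif_chain()` turns that into the
central inference step: among all candidate hits of an architecture's
motifs it selects, by dynamic programming, the set of non-overlapping hits
with strictly increasing motif rank that maximizes total matched residues.
Ties are resolved by (1) greater total pattern specificity — the count of
non-wildcard positions, so a fully specified motif is never displaced by a
minimal Asp/His anchor at equal coverage — then (2) fewer total
mismatches, then (3) leftmost starts. The specificity tie-break matters in
practice: without it, after a Motif V knockout the `xHxx` anchor can
relocate onto the window overlapping HEAT at equal coverage and misreport
the missing-motif set.

A chain is *complete* when every required motif of the tested architecture
is placed. Completeness, not raw hit presence, is what classification
consumes.

## The decision scheme

* **Form** from length: `S` ≤ 450 aa, `L` ≥ 600 aa, otherwise
  `AMBIGUOUS`. The nominal ranges are 300-400 and 700-800 aa, but surveyed
  candidates include ~425-445 aa short-like and ~731 aa long-like
  proteins; the cutoffs sit between the ranges and an ambiguous band plus
  evidence-based override (complete long-form architecture ⇒ `L`) absorbs
  the borderline cases.
* **Arm** between the end of Motif II and the start of Motif III (the
  structural placement of the exosite; the anchors are configurable).
  Typing: KL-bearing arm of ≤ 45 aa → TM; GP-bearing ≤ 58 aa → bacterial;
  GP-bearing > 58 aa → eukaryotic. The 45/58 cutoffs sit midway between
  the nominal ~30/~55/~62 lengths. For the long form's N-half, which has
  no Motif III, the arm region is anchored between pseudo-Motif II and the
  duplication junction.
* **Type**: a short candidate completing the TM architecture is `TM_S`, one
  completing the bacterial architecture `BACTERIAL_S`; if both complete,
  fewer total mismatches wins and a KL arm breaks residual ties toward
  TM (KL is TM-diagnostic, and PxKxRN absence is read jointly with
  EGxSxxG presence). Anything short and incomplete is `TLP_S` with the
  missing required motifs recorded; candidates without even a His-motif
  hit list `MOTIF_II` among them. A long candidate is split at the start
  of the best full-architecture chain (fallback: midpoint); a complete
  C-half plus a eukaryotic GP arm in the N-half gives `EUKARYOTIC_L`,
  anything else `TLP_L`. TLP subtype follows the whole-protein form call.

Whether the original survey demanded all five MBL motifs for a positive
call is not recoverable from its text; this package makes the requirement
explicit (all required motifs of the architecture) and configurable via
the catalog's architecture blocks.

## The CCA census

Gene spans are assumed to *include* the discriminator as their last base,
so positions 74-76 are the first three bases downstream of the span on the
coding strand (minus-strand genes read the reverse complement upstream of
the span); a `discriminator_included = FALSE` flag shifts the window by one
for annotation conventions that stop at N72. Categories partition all
inputs (`CCA` / `CCN` / `CNN` / `OTHER`, with `TRUNCATED` for windows
clipped at contig edges — reported separately and excluded from totals by
default, while `OTHER` counts toward the total examined). The per-genome
percentage uses round-half-up to the integer, the unique convention that
reproduces all 15 published per-genome percentages from their printed
counts; the suite asserts 15/15. (The prose companion of that table says
"31%" for *A. thaliana* where the table's counts give 12/37 = 32.4% → 32;
the package follows the table.)

GFF3 (1-based closed) and BED (0-based half-open) are both normalized on
read to the package-wide internal convention, 0-based half-open.

## Pairwise conservation, logos, trees

`global_align()` is textbook Needleman-Wunsch with a linear gap penalty
(match +1, mismatch 0, gap −1) and a fixed diagonal-up-left traceback
preference — parameters chosen for exact oracle testability (the suite
compares against exhaustive enumeration of all alignments for short
sequences) rather than biological scoring realism; affine-gap scoring is a
non-goal. Percent identity/similarity use the gapless-column denominator
by default (selectable: shorter-sequence or full-alignment length), with
similarity defined by the standard strong conservation groups. The
published 93%/95% identity/similarity of the closest sorghum/foxtail
millet pair depends on Clustal W's internal conventions and two remote
accessions, so it is not a gating check here.

`logo_matrix()` computes per-column residue frequencies and information
content `log2(20) − H` in bits with no small-sample correction — the
numeric matrix behind a sequence logo, not a rendering. `nj_tree()`
delegates to `ape::nj()` after validating the distance matrix and fixing
the taxon order; it exists to express the qualitative phylogenetic
expectation — TM-type short forms form one clan, separate from the long
forms and bacterial-type short forms — as a reproducible property on
synthetic data (p-distance over motif regions), not to re-run the original
Bayesian inference, which is out of scope.

## What the synthetic generators do and do not emulate

`synth_protein()` assembles proteins from concrete instances of the
catalog patterns joined by random linkers, motifs in canonical order, the
arm of nominal length (30/55/62 aa by type) between its anchors, and for
the long form a duplication junction recorded in the truth. Linkers (and
wildcard fills) are drawn from the *linker-safe alphabet*: the residues
that appear nowhere as exact requirements in the catalog (C, F, M, Q, V, W
for the default catalog). Every catalog pattern requires at least one
excluded residue, so linkers cannot complete any motif by chance — planted
recovery is exact by construction, and the suite verifies that linker-only
sequences never complete an architecture. Knockouts produce TLPs either by
overwriting an instance with safe residues (`delete`) or by mutating its
first `max_mismatches + 1` invariant residues to Gln (`corrupt`; for the
His motif this reduces to the single His→Gln substitution observed in a
natural TLP).

`synth_genome()` plants non-overlapping tRNA-sized (70-90 bp) genes on
both strands of a random contig and writes each gene's downstream
trinucleotide from its assigned category's string set, with ≥ 10 bp
spacers so neighbouring windows cannot collide.

What this deliberately does **not** emulate: evolutionary divergence
(substitution/indel processes), motif variants beyond the modeled
tolerance, compositional bias, intron misannotation, or genuinely
ambiguous domain arrangements. Perfect recovery on these fixtures
therefore demonstrates correctness of the scanning/chaining/decision
machinery under the stated motif grammar — not expected accuracy on real,
divergent proteomes, where motif tolerances (and Motifs I/III/IV/V
definitions, known only from alignment figures) would need refinement
against curated alignments.

## Numerical and reproducibility choices

* Coordinates: 0-based half-open everywhere (hits, genes, truth JSON).
* Rounding: census percent round-half-up to integer; identity/similarity
  to one decimal.
* Determinism: generators take explicit seeds and restore the caller's RNG
  state; reruns are byte-identical, and data files carry no timestamps.
* Degenerate inputs: empty scans return empty hit tables (not errors);
  chains with zero hits are valid and incomplete; a featureless long
  sequence splits at its midpoint; zero usable census records is an error.
* Problem sizes in the shipped checks: 200 balanced proteins for
  classifier recovery, 1000 random scanner-oracle cases, 20 synthetic
  genomes of 20-200 genes for the census properties, 25
  alignment-enumeration cases at length ≤ 7, 10 random 8-taxon trees, and
  5 replicate 15-taxon clan checks — sizes at which the oracles are exact
  and the whole suite runs in about a minute on one CPU.

## Worked example

```{r}
p <- synth_protein(protein_spec("TM_S", seed = 1))
classify_type(p$sequence)

g <- synth_genome(mixture = c(cca = 3, ccn = 2, cnn = 5, other = 10), seed = 42)
census_pipeline(g$genome, g$genes, label = "synthetic chloroplast")$row
```

## Known limitations

* Motifs I, III, IV, V are placeholder anchors; real-data use should
  refine them from curated alignments via the catalog file.
* The mismatch tolerance the original surveyors implicitly applied when
  calling a motif "present" in divergent species is unstated; the defaults
  here are explicit but not calibrated to that unstated standard.
* Subcellular localization is bookkept (targeting-signal records), never
  predicted; localization is orthogonal to type (a TM-type protein can be
  chloroplast-targeted).
* No BLAST-based candidate discovery: the package classifies given
  sequences, it does not find them in genomes.
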