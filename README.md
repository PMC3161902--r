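# trzsurvey

Motif-based survey tools for the tRNase Z protein family in green plants,
plus a census of chloroplast tRNA genes encoding parts of the 3'-CCA.

## What it does

tRNase Z (RNase Z; the ELAC2 homolog) removes the 3'-trailer of pre-tRNAs
by cleaving immediately after the discriminator nucleotide N73. Green
plants carry several tRNase Zs whose types are recognizable purely from
motif architecture — degenerate consensus motifs of the
metallo-β-lactamase domain (Motif II `HxHxDH` being the signature "His
motif") plus type-specific elements:

| type | form | diagnostic architecture |
|---|---|---|
| TM-type | short (~300-400 aa) | `EGxSxxG`, Motifs I-V, ~30 aa arm with KL motif `KLKxxYxxLxGxxIxxLK`, `xExT`, `HxH` |
| bacterial-type | short | `Px[KL]xRN`, Motifs I-V, ~55 aa arm with GP motif `GxPxGP`, `HEAT`, `HST` |
| eukaryotic | long (~700-1000 aa) | C-half: `PxKxRN`, Motifs I-V, `HEAT`, `HST`; N-half: pseudo-motifs + ~62 aa GP arm |

Candidates missing required motifs are tRNase Z-like proteins (TLPs). The
package provides:

* **Motif engine** — `compile_motif()`, `scan_motif()` (mismatch-tolerant,
  brute-force-equivalent), `find_motif_chain()` (order-consistent
  maximum-coverage chains by dynamic programming).
* **Classifier** — `classify_type()` / `trz_classify()` / `run_survey()`:
  form, type and missing-motif evidence per protein; flexible-arm
  delineation (`delineate_arm()`) and long-form half splitting
  (`split_halves()`).
* **CCA census** — `census_pipeline()`: for each annotated chloroplast
  tRNA gene, the trinucleotide at positions 74-76 downstream of the
  discriminator, binned CCA/CCN/CNN/OTHER and summarized per genome with
  round-half-up percentages (FASTA + GFF3/BED/TSV input).
* **Conservation utilities** — Needleman-Wunsch `global_align()` with
  percent identity/similarity, sequence-logo matrices (`logo_matrix()`),
  neighbor-joining trees (`nj_tree()`), targeting-signal bookkeeping
  (`validate_signal()`).
* **Synthetic data** — seeded generators with planted ground truth
  (`synth_protein()`, `synth_genome()`, `mutate_to_tlp()`), used by the
  test suite and benchmark checks.

All coordinates exposed by the package are 0-based half-open.

## Worked example

```r
library(trzsurvey)

# a synthetic TM-type protein with planted motifs, then classify it
p <- synth_protein(protein_spec("TM_S", seed = 1))
classify_type(p$sequence)
#> <trz_typing_result> (unnamed)  length=300  form=S  type=TM_S  arm=TM(30 aa)

# knock out the HEAT motif of a bacterial-type candidate -> TLP
pk <- synth_protein(protein_spec("BACTERIAL_S", knockouts = "HEAT", seed = 4))
classify_type(pk$sequence)
#> <trz_typing_result> (unnamed)  length=340  form=S  type=TLP_S  arm=BACTERIAL(55 aa)
#>   missing required: HEAT

# chloroplast CCA census on a synthetic genome with a known mixture
g <- synth_genome(mixture = c(cca = 3, ccn = 2, cnn = 5, other = 10), seed = 42)
census_pipeline(g$genome, g$genes, label = "synthetic")$row
#> <trz_census_row> synthetic: CCA=3 CCN=2 CNN=5 other=10 (trunc=0) / 20 genes, 50%
```

The typing result reports the form (S/L by length with an ambiguous band),
the type call from architecture completeness, the delineated flexible arm
(type and length), and the exact set of missing required motifs for TLPs.
The census row gives category counts, the total genes examined and the
integer percentage of genes encoding the whole or a leading part of the
CCA.

A thin command-line wrapper is installed under
`system.file("scripts", "trz", package = "trzsurvey")` with subcommands
`scan`, `classify`, `census`, `survey` and `simulate`.

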