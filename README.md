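# tnfusion

Design and simulation toolkit for markerless mariner (Himar) transposons
that create in-frame internal fluorescent protein fusions.

Himar transposases insert their cargo at a TA dinucleotide and duplicate the
TA. A transposon carrying a promoterless, stop-codon-free reporter between
its two inverted terminal repeats (ITRs) can therefore drop a fluorophore
into the middle of any expressed gene — an internal "sandwich" fusion — but
only if the reading frame survives the trip through the cargo. Which
architecture preserves the frame depends on the codon phase of the target
TA:

| phase | TA position on the codon grid | architecture | spacers (5′/3′) |
|-------|-------------------------------|--------------|-----------------|
| P23   | positions 2–3 of one codon (`XTA`)   | `open1` | 0 / 1 |
| P31   | position 3 + position 1 of the next (`XXT-AXX`) | `open2` | 2 / 2 |
| P12   | positions 1–2 of one codon (`TAX`)   | `open3` | 1 / 3 |

with the frame-balance invariant
`(|ITR| + s5 + |reporter| + s3 + |ITR| + 2) mod 3 = 0`, the `+2` being the
TA target-site duplication. A P12 junction is special: the duplicated TA
occupies codon positions 1–2, and an unmodified ITR starting with A
immediately forms a UAA stop — the package reports this hazard instead of
hiding it.

The package covers, for whom this matters (bacterial cell-biology groups
building fluorescent fusion or BiFC screens, and anyone simulating such
screens):

* TA site enumeration and codon-phase classification (`enumerate_ta_sites`,
  `classify_phase`), with BED/TSV export;
* transposon architecture modelling and validation (`transposon_variant`,
  `validate_variant`, `build_cargo`, `scan_itr_stops`,
  `generate_itr_variants`);
* insertion construction with TA duplication and exact excision
  (`apply_insertion`, `excise_insertion`);
* fusion prediction with a target/linker/reporter segment map and
  gene/genome scanning (`predict_fusion_protein`, `verify_orf`, `scan_gene`,
  `scan_genome`, `dedup_candidates`);
* junction-tag mapping back to insertion sites (`extract_tag`, `map_tag`,
  `batch_map`);
* split-fluorophore BiFC construct design (`split_fluorophore`,
  `build_bait`, `build_prey_transposon`, `detect_self_insertion`);
* a stochastic FACS gene-trap enrichment simulator (`sim_config`,
  `simulate_library`, `apply_gate`, `run_trap_protocol`).

A command-line wrapper with subcommands `scan`, `insert`, `predict`,
`map-tags`, `design-bifc`, `simulate-trap` and `fixtures` is installed at
`system.file("cli", "tnfusion", package = "tnfusion")`.

## Worked example

Build a P23-compatible transposon with an 80-codon reporter, plant a P23
site in a synthetic 60-codon gene, and predict the fusion:

```r
library(tnfusion)

v    <- transposon_variant("open1", reporter = synthetic_reporter(80, seed = 3))
gene <- generate_fixture_gene(60, sites = data.frame(codon = 20, phase = "P23"),
                              seed = 2)
gene$sites
#>   t_coord cds_offset phase
#> 1      59         59   P23

fus <- predict_fusion_protein(gene$seq, gene$sites$t_coord, v,
                              gene_id = "fixture_gene")
fus
#> <fusion_construct fixture_gene> internal insertion at offset 59 (P23) by open1: productive, 158 aa
fus$segments
#>           segment start end
#> 1        target_N     1  20
#> 2   itr_up_linker    21  29
#> 3        reporter    30 109
#> 4 itr_down_linker   110 119
#> 5        target_C   120 158
```

Reading the output: the TA site sits at offset 59 (codon 20, positions 2–3,
hence P23), and the `open1` insertion is *productive* — cooriented, phase
matched, and stop-free through the whole cargo. The 158-residue fusion
protein is the 20 N-terminal target residues, a 9-residue linker translated
from the 27-bp upstream ITR, the intact 80-residue reporter, a 10-residue
linker from the 3′ spacer + downstream ITR + duplicated TA, and the
unchanged 39 C-terminal target residues — the downstream frame is restored
exactly.

`validate_variant(v)` shows the rule-by-rule report (reporter length,
internal/terminal stops, spacer lengths, frame balance: cargo + TA
duplication = 297 bp ≡ 0 mod 3).

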