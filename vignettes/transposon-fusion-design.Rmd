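---
title: "Frame-preserving transposon fusion design: models and assumptions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Frame-preserving transposon fusion design: models and assumptions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tnfusion)
```

## The problem

Mariner-family (Himar) transposases insert their cargo at TA dinucleotides
and duplicate the TA on insertion. A transposon whose cargo is a
promoterless, stop-codon-free fluorescent reporter flanked by the two
inverted terminal repeats (ITRs) can therefore create an internal, in-frame
"sandwich" fusion in any expressed gene — provided the reading frame runs
continuously from the target's N-terminal portion, through the upstream ITR,
the reporter, the downstream ITR and the duplicated TA, and back into the
target.

Whether that works depends on where the target TA sits on the codon grid.
`tnfusion` names the three cases by the codon positions the TA occupies:

* **P23** (`XTA`): TA at positions 2–3 of one codon,
* **P31** (`XXT-AXX`): T at position 3 of one codon, A at position 1 of the
  next,
* **P12** (`TAX`): TA at positions 1–2 of one codon.

One transposon architecture per phase keeps the frame intact. All three
share the layout `ITR + 5' spacer + reporter + 3' spacer + ITR`, and differ
only in spacer lengths: `open1` (0/1, for P23), `open2` (2/2, for P31) and
`open3` (1/3, for P12).

## Frame arithmetic

Let $I$, $s_5$, $R$, $s_3$ be the lengths of an ITR, the spacers and the
reporter. The insertion adds the cargo plus the 2-bp TA duplication, so the
frame-balance invariant is

$$(I + s_5 + R + s_3 + I + 2) \bmod 3 = 0,$$

which all three stock architectures satisfy (with $I = 27$ and $R \equiv 0
\bmod 3$: $57 + R$, $60 + R$, $60 + R$). An important consequence, easy to
miss: because the inserted material is always a multiple of 3, the
*downstream target frame is restored for every architecture at every phase*.
What distinguishes a phase-matched insertion from a mismatched one is the
frame in which the **reporter itself** is translated: only the matched
architecture places the reporter's own codons on the reading grid. The
package's productivity predicate therefore requires (i) coorientation,
(ii) phase match, and (iii) stop-free translation through the whole cargo;
the test suite's independent oracle verifies the same thing by brute force —
translating the fully constructed sequence and demanding no premature stop,
the reporter peptide intact, and wild-type residues downstream.

### The P12 junction stop

For a P12 insertion the duplicated TA occupies codon positions 1–2, so the
first ITR base completes that codon. The canonical Himar ITR starts with A:
the junction reads TAA immediately. This is why the P12-compatible
architecture requires ITR modification, why `scan_itr_stops()` reports the
hazard rather than hiding it, and why `generate_itr_variants()` enumerates
substitution combinations and re-scans each one. The package models `open3`
fully but `build_prey_transposon()` refuses it by default (overridable),
reflecting its failure to transpose functionally in vivo.

## Coordinate and orientation conventions

* `t_coord` is the 1-based position of the T of a TA on the forward strand.
  TA is its own reverse complement, so forward enumeration covers both
  strands; orientation is a property of the insertion event, not the site.
* `cds_offset` anchors on the T, with the first base of the ATG at +1 and
  the base immediately 5' of it at −1 (no zero). Negative offsets are
  classified by extending the reading frame leftward, which makes the
  classification continuous across the start codon. The exact anchoring
  convention used for published insertion labels cannot be verified without
  the construct sequences, so the convention here is documented and applied
  uniformly rather than asserted to match.
* ITRs are inverted repeats: the default downstream ITR (in cargo
  orientation) is the reverse complement of the upstream ITR. Both slots are
  configurable, and any configured ITR is validated by `scan_itr_stops()`
  rather than assumed stop-free — the published constructs' exact ITR and
  spacer base identities are not available, only the spacer lengths, so
  spacer defaults were chosen once to be junction-safe with the canonical
  ITR pair and are recorded in the variant objects.

## Upstream (N-terminal) insertions

An insertion upstream of a start codon can still yield a fusion — reporter
first, then the downstream ITR linker, then the intact target — when the
distance from the duplicated TA to the ATG puts the target in the reporter's
frame with no intervening stop. `predict_fusion_protein()` supports this
`n_terminal` topology without modelling translation initiation: it simply
requires an in-frame, stop-free path from the reporter into the ATG. The
linker length of any particular recovered fusion depends on construct
details the sequence record alone does not fix, so the package reports the
computed linker rather than asserting a specific published length.

## The gene-trap enrichment simulator

The simulator reduces the two-round FACS protocol to the quantities that
drive it. Each cell independently:

1. acquires an insertion with probability `p_transposition` (default 0.003,
   a rare-transposition library);
2. lands in the target gene, an expressed off-target locus, or a silent
   locus in proportion to the genome model (defaults: 260,000 TA sites
   genome-wide — a *B. subtilis*-scale genome — of which 70 lie in the
   ~1-kb target gene, and half of the rest in expressed genes);
3. is productive with probability 1/2 × 1/3 (coorientation × phase match
   for a single-variant library), and fluorescence-capable with probability
   `p_inframe_fluorescent` (default 0.8, fusions that fold);
4. draws a per-sort fluorescence value from one of two log-normal
   components: dark autofluorescence (meanlog log 100, sdlog 0.4) or bright
   (meanlog log 10 000, sdlog 0.6), gated at 1000 arbitrary units.

Under these defaults the bright fraction of a mutagenized library is about
1:5,000 cells — the regime the protocol was designed for. That calibration
is a default, not a claim the simulator is tested against. Target-locus
fluorescence is inducer-dependent (the gene trap); expressed off-target
insertions fluoresce regardless of inducer. Round 1 sorts the induced
library above the gate; the kept cells are resampled with replacement back
to `n_cells` (this multinomial regrowth also reproduces sibling expansion —
the reason enriched candidate pools contain redundant insertions and are
deduplicated with `dedup_candidates()`); round 2 sorts the uninduced
culture below the gate. A per-round dropout probability (default 0) covers
cells dark for reasons other than induction.

What the simulator deliberately omits: instrument physics (scatter gates,
sort purity), growth-rate fitness effects of insertions, lineage tracking,
and any sequence-level coupling — locus classes are sampled from counts,
not from a genome. Conclusions about sorting *strategy* (monotone
enrichment, the value of the inducer-coupled second round, the zero-noise
closed form `enrichment = 1 / initial target fraction`) transfer to real
experiments; absolute yields do not.

## Numerical and design choices

* Translation uses the standard bacterial code via a base-R codon lookup
  built from Biostrings' `GENETIC_CODE`; stops render `*` and scanning
  continues (full-frame semantics), codons containing N render `X`, and
  trailing partial codons are dropped. Only ATG anchors a frame; GTG/TTG
  starts are not modelled.
* Internal coordinates are 0-based half-open only inside the I/O layer;
  everything user-facing is 1-based inclusive (GFF convention).
* The fixture generator fills unconstrained codons from a {C,G}-only,
  stop-free, TA-free codon set, so a fixture gene contains exactly the
  requested TA sites — including across codon boundaries — and the stop
  codon is TGA to avoid an accidental P12 site. P31 requests consume the
  following codon (it must start with A); requests that touch the start or
  stop codon are rejected as unsatisfiable.
* Phase-class uniformity (≈1/3 each) holds on sequence uniform over
  {A,C,G,T} and is tested there; a stop-free CDS depletes P12 sites because
  TAA/TAG are excluded from sense codons.
* Tag mapping is exact matching on both strands, no mismatches: junction
  tags are short Sanger-derived sequence, and ambiguity (a tag with several
  genomic matches) is surfaced per hit, never resolved by heuristics. Tags
  must begin with the target TA; accepted length is 8–12 for external tags.
* Simulation problem sizes in the test suite (libraries of 2,000–50,000
  cells, 100 paired seeds for the monotonicity comparison, 10,000
  (site, variant) pairs for the oracle sweep) were chosen as the smallest
  sizes at which the binomial standard errors are far below the effect
  sizes being checked.

## Known limitations

* Productivity is a statement about reading frames, not biology: the
  package does not predict folding, fluorophore maturation, localization,
  or function of a fusion — the read-outs that require a microscope.
* The supplied ITR default is the canonical Himar1 mariner ITR, not the
  (unavailable) exact sequence of any published construct; conclusions that
  depend on specific ITR bases should configure the true sequence.
* BiFC design covers the construct arithmetic (split, bait, prey,
  self-insertion topology); complementation efficiency and interaction
  strength are out of scope — "interaction gives fluorescence" exists only
  as a boolean in the simulator layer.
* Partial CDS annotations (length not a multiple of 3) are flagged and
  excluded from phase analysis rather than guessed at.
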