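---
title: "Matching base editors to point mutations: model, conventions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Matching base editors to point mutations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(becorrect)
```

# The model

`becorrect` answers a single question: given a pathogenic single-nucleotide
variant (SNV) inside a coding sequence, which base editors can restore the
coding sequence — either exactly at the DNA level or synonymously at the
protein level?

The model has three deterministic stages.

**Placement.** A base editor is described by its conversion chemistry (C>T
for CBEs, A>G for ABEs, always stated on the protospacer strand), an IUPAC
PAM pattern, the PAM side (3' of the protospacer for type II Cas, 5' for
type V such as Cas12a), a gRNA length (20 nt, or 21 nt for Sa guides), a
major activity window and zero or more minor windows, and optionally a
5'-context rule (eA3A-type deaminases convert C only in a TC context).
Windows are inclusive distance-from-PAM intervals with the PAM-adjacent
protospacer base at distance 1; for a 3'-PAM 20-nt editor, distance *d*
corresponds to 5'-counted protospacer position 21 − *d*, so the canonical
CBE window 13–17 is protospacer positions 4–8. For every editor, both
strands, and every protospacer start that (i) fits in the sequence together
with its PAM, (ii) matches the PAM pattern on the protospacer strand, and
(iii) puts the SNV inside the major or a minor window, a placement is
emitted. All editors are tried regardless of the SNV's substitution type:
a CBE cannot touch a T-to-A variant directly, but its bystander edits may
still rescue the codon, which is precisely the mechanism that makes some
transversions correctable.

**Simulation.** Editing is all-or-nothing inside the major window: every
source base (C or A on the protospacer strand, subject to the context rule)
converts. This mirrors the co-editing assumption behind the scenario
definitions — if a target base is flanked by another of the same type in the
window, both are edited. Minor windows are never simulated; source bases
found there raise `minor_bystander_flag` (some low-rate editing may occur),
and a placement that reaches the SNV only through a minor window is carried
with `minor_window_match = TRUE` rather than dropped. Partial-edit
enumeration (subsets of window targets) is deliberately out of scope: the
scenario classification is about the deterministic co-editing product.

**Classification.** With `reference` = the input sequence with the variant
base replaced by the reference base, the decision order is:

1. edited DNA == reference DNA → `precise`;
2. else, if the edited protein equals the reference protein over the *full*
   in-frame translation:
   - SNV restored but bystanders changed → `multiple_bases_synonymous`;
   - SNV converted to a third base → `on_target_synonymous`;
   - SNV untouched → `bystander_synonymous`;
3. otherwise `none` (the placement is rejected).

The partition is exhaustive and mutually exclusive, and the comparison spans
the whole provided sequence, so a window edit that lands in a neighboring
codon and changes its amino acid disqualifies the placement. The entire
input is treated as coding in the given frame; callers must trim non-coding
flanks. Only the standard nuclear genetic code is supported — mitochondrial
variants are excluded upstream precisely because their code differs.

# Parameters that matter

| parameter | units | default | why |
|---|---|---|---|
| `major_window`, `minor_windows` | distance from PAM, nt | per editor | transcribed from the published per-editor characterizations |
| `grna_length` | nt | 20 (21 for Sa editors) | determines the distance↔position mapping |
| `context_5prime` | base | none (T for eA3A) | narrows conversion to TC dinucleotides |
| `frame_offset` | 0–2 | 0 | index of the first complete codon in the input |
| `include_minor` | flag | TRUE | carry minor-window SNV matches, flagged |
| flank length | nt | caller-supplied | ≥ gRNA length + PAM length on each side keeps the scan untruncated; shorter flanks silently yield fewer placements |

The built-in registry holds 26 editors (17 CBEs, 9 ABEs). Published
constructs that share every parameter are stored as one aliased entry, so
looking up `"BE4-Gam"` resolves to the `BE3` entry. Two ABE rows carry PAMs
as published even though their assignment to construct names looks swapped
(`Sa(KKH)-ABE`: NGA; `VQR-ABE`: NNNRRT); the `notes` field flags this rather
than silently "fixing" the table. The circular-permutant note ("may exhibit
editing upstream of the protospacer") is likewise recorded as a note, not
modeled as editable positions, since no window coordinates exist for it.

# Cohort statistics

`summarize_cohort()` counts a record as *repairable* when at least one
major-window correction exists, and *synonymous-only* when none of those is
precise. Minor-window-only matches are tallied separately
(`n_minor_only`) and do not count as repairable: the repairability claim is
about windows where editing is efficient. For transversions, occurrences
and repairs are additionally keyed by (reference AA, variant AA).

`recoverable_substitution_table()` provides the PAM-free theoretical upper
bound: for every sense codon and each of its nine single-base transversions,
it asks whether any one-chemistry transition edit set can restore the
reference amino acid. Because an activity window intersects a codon in a
contiguous stretch and converts *all* source bases inside it, the achievable
edit sets are exactly "all source positions within some interval of the
codon" — not arbitrary subsets. The enumeration yields exactly five
recoverable substitution classes (I>M, L>F, R>G, R>W, R>\*) and none for
serine, whose TCN and AGY codon families cannot be crossed by transitions.
Placement constraints can only shrink this set, an invariant the test suite
checks against observed cohorts.

One consequence of the placement rule deserves note. An L>F variant
(e.g. TTT from TTA) is rescued by converting the codon's first T to C
*without* touching the second — which forces the bystander to sit at the top
edge of an ABE major window with the SNV two positions beyond it. Among the
built-in editors only ABE 7.10\*'s minor window 18–19 admits that geometry,
so L>F rescues surface as minor-window matches and are excluded from the
major-only repairable counts. This is a real, documented asymmetry of the
window model, not an oversight.

# The synthetic-data generator

`generate_fixture()` builds cohorts with known ground truth: each record is
a random in-frame sequence of sense codons (no internal stops) into which a
codon-aligned cassette is implanted at a random position. The cassette pins
the protospacer, PAM and the entire major-window content of one planted
placement, so the intended scenario is guaranteed by construction:

- **precise** — a T>C transition as the only window cytosine of a BE3 site;
- **multiple_bases_synonymous** — the Thr/Ile co-editing cassette
  (`ACT CTA` → `ATT TTA`) under a BE3 PAM; a fixed 9-nt guard 5' of the
  protospacer plus a protective window cytosine make an unplanned precise
  hit impossible, so synonymous-only counts are exact;
- **on_target_synonymous** — an R>G transversion (CGA→GGA) with a
  minus-strand CBE restoring an Arg codon (AGA) on target;
- **bystander_synonymous** — an L>F transversion (TTA→TTT) rescued through
  the ABE 7.10\* minor-window geometry described above;
- **unrepairable** — an A>D transversion (GCC→GAC), which the codon-level
  enumeration proves unrescuable, so `find_corrections()` is provably empty
  regardless of the random flanks.

Incidental extra corrections from the random flanks are tolerated — ground
truth is "the planted correction exists", not "it is unique" — but the
cassette analysis guarantees the per-class cohort counts exactly, which is
what the planted-count tests assert. Generation is seeded and reproducible;
the caller's RNG state is restored afterwards.

What the generator does *not* emulate: real human genomic context
(GC content, codon usage, repeat structure), mutation-rate spectra,
intron/exon boundaries, or variant frames other than 0. Passing tests
demonstrate the correctness of the search/simulate/classify machinery under
controlled geometry, not population-level repairability fractions of real
pathogenic variants — those depend on the empirical distribution of PAM
availability around disease alleles.

# Numerical and interface choices

- Internal coordinates are 1-based inclusive throughout (R convention);
  file and CLI coordinates are likewise 1-based.
- Input normalization: lowercase is upcased, U becomes T, and any ambiguity
  code in a target sequence is rejected — the method requires concrete
  alleles; IUPAC codes are legal only in PAM patterns.
- Result ordering is fully deterministic: registry order, then strand
  (+ before −), then 5'→3' protospacer start; precise results are listed
  before synonymous ones. Repeated runs are byte-identical.
- Placements are deduplicated by (editor entry, strand, protospacer start);
  aliases collapse onto their entry.
- Truncated flanks skip placements rather than padding sequence ends.
- Empty TSV fields are written as `.`; malformed batch rows are logged to
  stderr and skipped, and a batch aborts only when every row is malformed.

# Verification strategy and problem sizes

The placement search is verified against an independent brute-force oracle
that slides every start position on both strands with its own IUPAC table
and complement code (500 random fixtures in the acceptance suite, plus
per-position checks on constructed single-PAM sequences). Strand symmetry —
mirroring the input yields mirrored outcomes with strands swapped — and
one-chemistry purity of every outcome are checked as properties. The
classification rules are unit-tested on hand-built outcomes covering all
four scenarios and the rejection path. Cohort counts are validated exactly
on planted synthetic cohorts (n = 40–200 in tests; n = 400 in
`scripts/acceptance.R`), sizes chosen to exercise every scenario class many
times while keeping the default suite quick to run.

# Known limitations

- No editing-efficiency model: all major-window placements are reported as
  equals, and no ranking among candidate editors is attempted.
- No off-target assessment; dedicated gRNA off-target tools should be used
  downstream.
- Single editing event only: sequential application of two editors is out
  of scope.
- The whole input is treated as one coding exon in a fixed frame.
- Minor-window matches are flagged but their (low-rate) conversions are not
  simulated, so a rescue that would require an actual minor-window edit is
  never claimed.
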