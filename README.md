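# becorrect

Match CRISPR base editors to pathogenic point mutations — including
mutations that can only be corrected at the protein level.

## The problem

Base editors (BEs) are dCas–deaminase fusions that install single-nucleotide
transitions without a double-strand break: cytosine base editors (CBEs)
convert C→T and adenine base editors (ABEs) convert A→G on the protospacer
strand (and, by targeting the complementary strand, G→A and T→C). Each
editor only works where its PAM sits at the right distance from the target:
deamination is efficient inside a *major activity window* of
distance-from-PAM positions (the protospacer base adjacent to the PAM is
distance 1) and weak inside *minor* windows. Within the major window every
same-type base is co-edited, so bystander conversions are unavoidable.

Two consequences follow for therapeutic design:

1. A transition SNV is correctable only if some editor's PAM places it in an
   activity window — and a *precise* correction additionally requires that
   no bystander base in the window is altered.
2. Because the genetic code is degenerate, an edit that does **not** restore
   the reference DNA can still restore the reference protein. Such
   *synonymous corrections* even rescue some transversion-derived missense
   mutations, which no transition chemistry can reverse at the DNA level.

`becorrect` searches a registry of 26 published base editors (17 CBEs,
9 ABEs; user-defined editors are supported) for every placement covering a
given SNV, deterministically simulates the window edit on either strand, and
classifies each outcome as:

- **precise** — edited DNA equals the reference allele;
- **multiple-bases synonymous** — SNV restored, bystanders co-edited
  synonymously;
- **on-target synonymous** — SNV converted to a third base encoding the
  reference amino acid;
- **bystander synonymous** — SNV untouched, a bystander edit restores the
  reference amino acid.

Synonymous scenarios require the full in-frame translation of the edited
sequence to equal the reference protein; an edit that damages a neighboring
codon disqualifies the placement. A codon-level enumeration over all sense
codons and their nine single-base transversions shows that exactly five
amino-acid substitution classes are rescuable by one-chemistry transition
edits — I>M, L>F, R>G, R>W and R>\* — and that serine, despite its six
codons, is not (its TCN and AGY families are separated by transversions).

## Worked example

The classic co-editing case: the variant codon pair `ACT CTA` (Thr, Leu)
whose reference is `ATT CTA` (Ile, Leu). The pathogenic T→C transition sits
at distance 16 from an AGG PAM, inside the canonical CBE window, together
with a bystander C at distance 14:

```r
library(becorrect)
s <- "GAAGAAGAAGCCACTCTAGAAGATTTTTTAGGAGAAGAA"
snv <- snv_record("rs_demo", s, 14, "T", "C", frame_offset = 0)
find_corrections(snv, builtin_registry())
#> SNV rs_demo: T>C at position 14 (transition)
#> Precise corrections: 0
#> Synonymous corrections: 11
#>       id            editor strand protospacer  pam snv_distance_from_pam window
#>  rs_demo               BE3      +       10-29  AGG                    16  major
#>  rs_demo           YE1-BE3      +       10-29  AGG                    16  major
#>  ...
#>                   scenario edited_window_sequence bystander_count
#>  multiple_bases_synonymous   GCCATTTTAGAAGATTTTTT               1
#>  ...
```

Every matching CBE must co-edit the bystander C, so no precise correction
exists; the simulated product `ATT TTA` (Ile, Leu) differs from the
reference DNA but encodes the reference protein — an 11-way
multiple-bases-synonymous correction. `bystander_count` is the number of
changed positions besides the SNV, and `minor_bystander_flag` marks
additional target bases sitting in minor windows, where weak editing may
occur.

Batch and cohort runs, plus registry management and fixture generation, are
available both as functions (`run_batch()`, `run_cohort()`,
`generate_fixture()`, `load_custom_editors()`) and through the thin CLI at
`inst/cli/becorrect.R` (subcommands `match`, `batch`, `cohort`, `editors`,
`fixtures`).

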