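---
title: "Encoding and analysing chemically modified miRNA mimics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Encoding and analysing chemically modified miRNA mimics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, message = FALSE}
library(mirmimic)
library(dplyr)
```

## The problem

Synthetic microRNA mimics are short double-stranded RNAs designed to restore
the activity of a downregulated endogenous miRNA. Unlike an siRNA, a mimic
must keep the promiscuous, multi-target profile of its natural counterpart, so
its chemical stabilisation (2'-sugar modifications, phosphorothioate
linkages) and its duplex geometry (mismatches, deletions, overhangs,
asymmetric or hairpin passengers) have to be balanced against potency and
strand-selection fidelity. `mirmimic` formalises this design space: it models
modified strands at per-residue resolution, encodes whole design series as
declarative *modification templates* that can be re-applied to any miRNA
sequence, and implements the desk-side analyses used to characterise mimics —
oligonucleotide mass calculation, seed-complementary 3'UTR site scanning
intersected with differential-expression results, comparative 2^-ddCt qPCR
quantification and dual-luciferase percent activity.

## Domain model and conventions

A strand is an ordered table of residues, 1-based and 5' to 3'. Each residue
carries a base (`A C G U T`), a sugar chemistry (`RIBO`, `OME` = 2'-O-methyl,
`FLU` = 2'-fluoro, `DEOXY`), and the linkage on its 3' side (`PO` or `PS`;
the 3'-terminal residue has none). `U` and `T` are distinct bases and `T` is
restricted to deoxy residues: the designs modelled here use `U` overhangs,
never dT, and silently coercing one into the other would misreport both
composition and mass.

Two conventions are fixed package-wide and deserve emphasis:

* **Coordinates.** All positions are per-strand, 1-based, 5' to 3'. The
  *facing position* map connects the two strands: in a blunt duplex of equal
  length `n`, guide position `g` faces passenger position `n - g + 1`
  (`facing_position()`). For the reference 23 + 23 duplex this puts guide
  position 17 opposite passenger position 7, and maps the guide-coordinate
  mismatch set {1, 4, 10, 20, 22, 23} onto passenger coordinates
  {23, 20, 14, 4, 2, 1}.
* **G:U wobbles are mismatches.** The pairing classifier recognises strict
  Watson-Crick pairs only. Wobbles do arise in the reference duplex (e.g.
  guide G22 opposite passenger U2), and counting them as pairs would change
  mismatch tallies; nothing in the source design series counts a wobble as a
  match, so the strict rule is the safer default. This is a package decision,
  not an inference from data.

`derive_passenger()` constructs a passenger as the reverse complement of the
guide, optionally truncated and edited by a *mismatch specification*: a table
of substitutions and deletions in passenger coordinates (pre-deletion
numbering; substitutions are applied first, then deletions shift downstream
positions). The default substitution base is a **copy of the facing guide
base**, because the one mismatch identity the design series states explicitly
is a U-U pair at guide 17 / passenger 7, which is exactly what copying
produces. Entries may override the base — the reference duplex needs `U` at
passenger 2 and `G` at passenger 4 to reproduce the published passenger seed
`UCGUCAU`.

Asymmetric (shortened) passengers are truncated from the passenger 3' end, so
a 16-mer passenger stays complementary to guide positions 8–23 and guide
positions 1–7 are reported `UNPAIRED`. Deletion positions always come from
the design specification, never from alignment: the pairing map does
coordinate arithmetic only and never performs gapped alignment, which keeps
`DELETION` (design intent) distinct from `UNPAIRED` (geometry).

```{r pairing}
guide <- make_strand("UAAUACUGCCGGGUAAUGAUGGA")
spec <- rbind(
  mismatch_spec(c(1, 2, 4, 14, 20, 23), "SUBSTITUTION", c(NA, "U", "G", NA, NA, NA)),
  mismatch_spec(7, "DELETION", NA)
)
native <- assemble_duplex(guide, derive_passenger(guide, spec))
count_pairing_states(native)
```

## The template registry

A `MimicTemplate` is a declarative rule set: alternating-sugar rules,
base-class rules (pyrimidine/purine selective), positional overrides,
terminal or positional PS rules, passenger length, overhang, hairpin loop,
nick and 5'-phosphate rules, plus a mismatch specification and an
architecture. Rules are applied in a fixed order — sugar chemistry, then
backbone, then architecture, then 5'-phosphate — and positional rules
override class/alternating rules. The fixed order makes hybrid designs
(a base pattern plus "extra PS") expressible as a template with one extra
rule, and makes `apply_template()` deterministic and idempotent.

The built-in registry (`load_registry()`) transcribes a 44-design series: the
unmodified miR-200c reference duplex `M1`, 37 modified variants `M2`–`M38`
(alternating 2'-F/2'-OMe patterns, terminal-PS variants, mismatch/deletion
variants, published siRNA chemistries, pyrimidine-selective patterns, hairpin
/ asymmetric / nicked architectures), and the two best patterns re-applied to
miR-155 (`MA1`–`MA3`) and miR-34a (`MB1`–`MB3`). Eight designs are flagged
`shortlisted`. Where a design's per-position pattern is only published
graphically (exact PS placement in `M6`/`M7`, the per-position chemistry of
`M12`–`M17`, hairpin loop sequences, the translated designs' mismatch maps),
the registry entry is a documented reconstruction consistent with the series
text and with the published siRNA patterns it names; each such entry says so
in its `provenance` field. The engine itself never guesses: everything it
applies is written in the registry JSON, which users can replace with their
own file validated against the shipped schema (`template.schema.json`).

```{r registry}
reg <- load_registry()
tidy(reg) |> count(architecture)
m23 <- apply_template(get_template(reg, "M23"))
m23
```

`translate_template()` re-evaluates a rule set against a new sequence:
base-class rules re-select positions, terminal-PS and length rules re-anchor,
and positional entries beyond the new length are dropped with a warning.
Translation with the original guide and spec reproduces `apply_template()`
exactly. When no mismatch specification is given the passenger defaults to
the full complement **with a loud warning**: full complementarity is known to
abolish mimic-like activity, so the tool refuses to fabricate mismatches
silently.

## Oligonucleotide properties

`strand_formula()` composes the elemental formula of a modified strand from
nucleoside compositions plus one HPO3-less-H2O bridge per linkage; a PS
linkage swaps one oxygen for sulfur, a 5'-phosphate adds HPO3. Masses use
IUPAC standard atomic weights (average) or principal-isotope masses
(monoisotopic) for the neutral free acid — the deconvoluted-neutral-mass
convention used when checking synthesised strands against LC-MS data. No
adducts, counter-ions, isotope envelopes or charge states are modelled.
Useful identities follow exactly: +CH2 (≈ +14.0157 Da monoisotopic) per
2'-OMe relative to ribose, and S-for-O (≈ +15.9772 Da) per PS linkage.

```{r mass}
g14 <- apply_template(get_template(reg, "M14"))$guide
format_formula(strand_formula(g14))
strand_mass(g14, "MONOISOTOPIC")
```

## Seed scanning and DEG intersection

`extract_seed()` takes positions 2–8 of a strand; `target_site()` forms the
reverse-complement DNA motif; `scan_utr()` counts exact occurrences
(overlaps included, `N` never matches) via Biostrings pattern matching; and
`summarize_deg_matches()` intersects per-gene site indicators with the
downregulated fraction of a differential-expression table (log2 fold change
≤ −1.3, FDR < 0.05 by default — the fold-change boundary is inclusive, the
FDR boundary strict, since the published thresholds do not state boundary
semantics and a fixed, documented convention beats an ambiguous one).

The search orientation is a flag: by default the reverse complement of the
seed is searched in sense-strand UTR DNA ("regions fully complementary to the
seed"); `orientation = "seed"` searches the transliterated seed itself.
Because only the gene-level "has at least one site" indicator feeds the
summary, the overlap-counting choice cannot change the reported gene counts.
A gene with several UTR records counts as matched if any record has a site.

## qPCR and luciferase quantification

`ddct_ratio()` is the comparative Ct formula
`2^-((Ct_tgt,trt - Ct_ref,trt) - (Ct_tgt,ctl - Ct_ref,ctl))`.
`summarize_knockdown()` averages technical replicates at the Ct level,
computes per-replicate dCt against the reference gene of the same cDNA
sample, takes ddCt against the mean control dCt, and averages the
per-replicate ratios per gene and condition. Averaging ratios (rather than
ddCt values) is a choice the published methods leave open; it is the more
common reporting convention and gives a control-condition mean of exactly 1
on noise-free data (with noisy Ct the arithmetic control mean is only
approximately 1 — the geometric mean would be exact, and the per-replicate
table is returned so callers can aggregate differently).
`luciferase_percent()` normalises R-Luc to F-Luc per well and expresses each
well as a percentage of the mean normalised ratio of the negative-control
wells, so the control baseline is 100% by construction.

## Synthetic fixtures

Every analysis operation is testable offline through generators that emit
data together with its ground truth, all pure functions of their arguments
including the seed (R's Mersenne-Twister, inversion normals, caller RNG state
restored):

* `gen_utr_set()` builds per-gene background DNA free of every scanned site
  by rejection sampling, then inserts the requested sites at non-overlapping
  positions and re-verifies the final counts, so planted counts are exact —
  truth assertions are equalities, not tolerances. Defaults emulate 3'UTR
  scan inputs: 500-nt sequences and the miR-200c guide/passenger seeds.
* `gen_ct_table()` plants fold changes as −log2(ratio) offsets on the treated
  target Ct with the reference gene unshifted, adding Gaussian noise per
  record (default sd 0.2 cycles, a typical qPCR spread; 3 biological
  replicates).
* `gen_deg_table()` draws fold changes and FDRs from ranges straddling the
  1.3/0.05 thresholds and records which rows each filter direction keeps.

What the fixtures do *not* emulate: real 3'UTR base composition and length
distributions, isoform structure, correlated expression noise, amplification-
efficiency differences between genes, or plate effects. Passing tests
therefore demonstrate the correctness of the arithmetic and bookkeeping on
inputs with known truth, not the biological performance of any design.

## Numerical and scale choices

The test suite and examples run at deliberately small problem sizes — strand
lengths ≤ 30 for property tests, 10^4 random sequence/site pairs for the
scan-oracle equivalence, hundreds of genes for fixture suites — chosen so
exactness, not throughput, is what is being exercised; the operations are
linear-time and scale to genome-annotation-sized inputs. Edge cases are
rejected loudly rather than coerced: empty strands, `T` on non-deoxy sugars,
malformed notation (with column numbers), tables missing required columns,
luciferase plates without negative controls, infeasible fixture packings.

## Known limitations

* No thermodynamics: duplex stability, melting temperature, RNA folding and
  annealing behaviour are out of scope; `HAIRPIN` records loop boundaries
  without predicting secondary structure.
* No activity prediction: the package encodes and analyses designs; it does
  not score RISC loading, strand selection or knockdown potency.
* Base analogues (inosine, abasic sites), conjugates (GalNAc, cholesterol)
  and LNA/cEt sugars are not representable.
* Figure-only registry content is a reconstruction (flagged in provenance);
  users with access to the original per-position diagrams can and should
  supply a corrected registry JSON.
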