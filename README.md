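# mirmimic

Design and analysis of chemically modified microRNA mimics in R.

microRNA mimics are synthetic double-stranded RNAs that restore the activity
of a downregulated endogenous miRNA. Designing one means choosing, per
residue, a sugar chemistry (2'-OH, 2'-O-methyl, 2'-fluoro, 2'-deoxy) and a
backbone linkage (phosphodiester or phosphorothioate, PS), and choosing a
duplex geometry — which positions mismatch, whether the passenger strand is
shortened, nicked, carries a 3' overhang or extends into a hairpin. These
choices trade nuclease stability against potency and against keeping the
mimic's activity on the intended guide (antisense) strand rather than the
discarded passenger (sense) strand.

`mirmimic` is a toolkit for working in that design space, tidyverse-style
(data frames in, tibbles out, `tidy()`/`glance()`/`autoplot()` methods):

* **Strand/duplex model** — per-residue chemistry, 1-based 5'→3'
  coordinates, a facing-position map between strands
  (`facing_position(g) = n - g + 1` for a blunt n + n duplex), and a pairing
  classifier (`PAIRED` / `MISMATCH` / `DELETION` / `UNPAIRED`; G:U wobbles
  count as mismatches). A compact text notation (`"P-mU*fA*mA"`: `m/f/d`
  sugar codes, `*` = PS, `P-` = 5'-phosphate) round-trips losslessly.
* **Template registry + engine** — 44 mimic designs (`M1`–`M38` on miR-200c,
  `MA1`–`MA3` on miR-155, `MB1`–`MB3` on miR-34a) encoded as declarative rule
  sets (alternating, base-class, positional, terminal-PS, length, overhang,
  hairpin, nick, 5'-phosphate rules). `apply_template()` realises a design on
  its miRNA; `translate_template()` re-evaluates the same rules on any other
  miRNA sequence.
* **Oligo properties** — elemental composition and neutral average /
  monoisotopic mass of modified strands (free-acid convention, as compared
  against deconvoluted LC-MS masses).
* **Seed scanning** — seed (nt 2–8) extraction, reverse-complement DNA target
  sites, exact overlapping-occurrence counting in 3'UTR FASTA sets, and
  intersection with downregulated DEGs (log2FC ≤ −1.3, FDR < 0.05 defaults)
  to compare antisense- versus sense-strand off-target footprints.
* **Quantification** — comparative `2^-ddCt` qPCR ratios
  (`ratio = 2^-((Ct_tgt,trt − Ct_ref,trt) − (Ct_tgt,ctl − Ct_ref,ctl))`),
  DEG threshold filtering, and dual-luciferase percent activity (R-Luc/F-Luc
  per well, 100% = negative-control mean).
* **Synthetic fixtures** — deterministic generators (UTR sets with exactly
  planted sites, Ct tables with known fold changes, DEG tables with known
  filter outcomes) so every analysis is testable offline against emitted
  ground truth.

## Worked example

Realise the pyrimidine-selective design M23 (guide pyrimidines 2'-F,
passenger pyrimidines 2'-OMe) on its native miR-200c guide:

```r
library(mirmimic)
reg <- load_registry()
m23 <- apply_template(get_template(reg, "M23"))
m23
#> <mimic_duplex [M23]> BLUNT_SYMMETRIC, guide 23 nt + 1 passenger segment(s)
#>   guide:     fUAAfUAfCfUGfCfCGGGfUAAfUGAfUGGA
#>   passenger: AmUmCGmUmCmUmUmUAmCmCmCmCGmCAGmUmUmUmUmU
#>   pairing:   PAIRED=16 MISMATCH=7 DELETION=0 UNPAIRED=0
```

The notation shows every pyrimidine (`U`, `C`) fluorinated (`f`) on the
guide and methylated (`m`) on the passenger; the pairing line counts the six
designed duplex mismatches plus the U-U mismatch at guide position 17 /
passenger position 7. Seed and target site:

```r
extract_seed(m23$guide)$heptamer   # "AAUACUG"  (guide nt 2-8)
target_site("AAUACUG")             # "CAGTATT"  (DNA motif searched in 3'UTRs)
```

Mass of the modified guide, neutral free acid:

```r
format_formula(strand_formula(m23$guide))   # "C221H262N91O149P22F9"
strand_mass(m23$guide, "MONOISOTOPIC")      # 7425.981
strand_mass(m23$guide, "AVERAGE")           # 7429.423
```

Simulate a qPCR experiment with known knockdown and recover it:

```r
truth <- tibble::tibble(gene = c("ZEB1", "ZEB2"), condition = "M23",
                        ratio = c(0.40, 0.22))
fx <- gen_ct_table(truth, noise_sd = 0.2, n_reps = 3, seed = 7)
summarize_knockdown(fx$ct, ref_gene = "HPRT1", control_condition = "control")
#> # A tibble: 4 × 5
#>   gene  condition ratio_mean ratio_sd     n
#>   <chr> <chr>          <dbl>    <dbl> <int>
#> 1 ZEB1  M23            0.369   0.0461     3
#> 2 ZEB1  control        1.00    0.105      3
#> 3 ZEB2  M23            0.171   0.0204     3
#> 4 ZEB2  control        1.01    0.125      3
```

Ratios are expression relative to the untreated control (= 1), so
`ratio_mean` 0.37 for ZEB1 means ~63% knockdown; with 0.2-cycle Ct noise and
n = 3 the planted ratios 0.40/0.22 are recovered within the expected spread.

A thin CLI wraps the same functions
(`exec/mimicforge design|translate|annotate|mass|seedscan|ddct|luc|fixtures`).

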