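---
title: "Distinguishing imprinting-associated from developmentally-associated histone-mark profiles"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Distinguishing imprinting-associated from developmentally-associated histone-mark profiles}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(imprintmarks)
```

## The scientific question

Imprinted genes are expressed from only one parental allele, under the control
of a germline differentially methylated region (DMR) at the imprinting control
region (ICR). Their *normally active* allele is additionally subject to
ordinary developmental regulation. These two repression mechanisms — imprinting
repression of the normally inactive allele and developmental repression of the
normally active one — could in principle use the same chromatin marks or
different ones. This package implements a mined-data analysis strategy for
telling them apart: integrate per-gene histone-modification enrichment calls
at transcription start sites (TSSs) with expression status and promoter-DMR
status, and ask which combinatorial mark profiles track the DMR (imprinting)
axis and which track the expression (developmental) axis. A mark enriched
equally at developmentally expressed and repressed imprinted genes, but only
at genes with a promoter DMR, is an imprinting mark; a mark whose presence
follows expression status is a developmental mark. On mouse data this
strategy associates H3K9me3+H4K20me3 (together with H3K4me3, a tri-mark) with
germline DMRs and ICRs, and H3K27me3 — often in a bivalent H3K4me3/H3K27me3
configuration — with developmental repression.

## The pipeline

1. **Input reading and gene resolution** (`parse_enrichment_intervals`,
   `resolve_gene_records`). Enrichment call sets are BED-like interval files,
   one per mark x cell type x calling method; intervals are unioned (merged,
   including book-ended neighbours) so downstream counts are deterministic.
   Query gene lists are resolved against an annotation table through exact,
   case-insensitive alias lookup. We deliberately formalized what mined-data
   studies often do with `grep`: exact alias matching removes the substring
   false-positive hazard of pattern matching, unresolved queries are reported
   as *not present*, and aliases hitting more than one record are reported as
   *ambiguous* rather than silently assigned. Records missing from every
   source (e.g. imprinted non-coding RNAs) can be appended manually with a
   provenance flag (`add_manual_records`).
2. **TSS-window enrichment** (`tss_window`, `is_enriched_at`, `mark_matrix`).
   A gene is called enriched for a mark when any called interval overlaps a
   symmetric window around its strand-aware TSS by at least 1 bp under
   0-based half-open semantics. The flank defaults to 1,000 bp per side; the
   sources this emulates do not state their intersection window, so the value
   is an explicit, report-echoed parameter rather than a hidden constant.
3. **Combinatorial profile classification** (`classify_profile`,
   `profile_distribution`). A taxonomy maps every subset of the assessed
   marks to exactly one label; unnamed non-empty subsets fall back to
   `Other`, the empty subset to `None`, so distributions always partition the
   gene set. Two presets ship: a three-mark taxonomy
   (H3K4me3/H3K27me3/H3K9me3) for comparing imprinted genes against the
   genome-wide background, and a two-mark bivalency taxonomy for
   cross-cell-type and expression-stratified analyses.
4. **State integration** (`build_state_table`, `stratify`). Expression status
   comes either from a microarray intensity threshold — strictly below 25 is
   *repressed*, at or above is *expressed*, so 25.0 itself is expressed —
   or from consolidating binary calls across assays, where any disagreement
   yields *unknown*. Genes missing from a layer are retained with unknown
   status and reported, never silently dropped: per-analysis effective *n*
   must stay auditable.
5. **Signatures and dynamics** (`detect_tri_mark`, `scan_icr_signature`,
   `bivalency_state`, `classify_transition`). The ICR signature is the
   conjunction of H3K4me3, H3K9me3 and H4K20me3 at the region evaluated *as a
   region* (ICRs can be intergenic, so TSS windows would be wrong); H3K27me3
   is excluded from the signature, since it is not present at all ICRs, but
   can be reported as an annotation column. Bivalency resolution between two
   cell types is classified into
   `resolved_to_K4 / resolved_to_K27 / resolved_to_none / retained_bivalent`,
   crossed with an expression outcome.
6. **Statistics** (`yates_chi2_2x2`, `contingency_chi2`, `check_conditions`).
   2x2 single-profile comparisons use the Yates-corrected chi-square;
   multi-profile comparisons use the uncorrected Pearson statistic on r x c
   tables. Every test carries an applicability verdict (below).
   `proportions_from_percentages` / `two_group_table` rebuild count tables
   from published percentages and group sizes so printed comparisons can be
   re-run exactly.

## Design choices where the design was genuinely open

**Coordinate and merge conventions.** All interval I/O is 0-based half-open
(BED); a `one_based` reader flag converts 1-based dialects. Book-ended
intervals (`end == next start`) merge, because enrichment calls represent
unions of covered basepairs. Both choices are arbitrary but must be fixed for
counts to be reproducible.

**Alias matching.** Case-insensitive by default (gene-symbol casing differs
across sources), exact-match only, with a `case_sensitive` flag. Ambiguity is
a reported outcome, not an error and not an auto-resolution, because silently
picking a record corrupts gene counts in ways no downstream check can catch.

**TSS flank = 1,000 bp.** Promoter-proximal histone-mark domains at CpG-island
promoters typically span roughly a kilobase around the TSS; with typical
called-peak widths of 1-3 kb, a 1 kb flank makes the enrichment decision
insensitive to small peak-boundary jitter without bleeding into neighbouring
genes. It is a configuration knob, recorded in every report header, precisely
because the mined sources leave it unstated.

**Chi-square applicability: a two-tier Cochran-style rule.** A table is
`invalid` if any expected count falls below 1 (no statistic is reported) and
`valid_with_warning` if all are at least 1 but any falls below 5. A strict
"all expected at least 5" rule would be self-inconsistent for this analysis
family: the 20%-vs-0% H3K4me3+H3K9me3 comparison (smallest expected about
0.03) must be refused, while the NPC 7%-vs-2% comparison (smallest expected
about 1.1) is legitimately testable and was tested. The two-tier rule draws
the line between those cases and is invariant under row/column permutation.

**Yates correction clamps at zero.** The statistic is
$\sum \max(|O-E| - 0.5,\, 0)^2 / E$: on near-null tables where $|O-E| < 0.5$,
an unclamped correction would *inflate* the statistic. This matches base R's
`chisq.test` behaviour on 2x2 tables (the test suite cross-checks both
operations against `chisq.test` and an independently coded direct formula to
1e-9 on 1,000 random tables).

**Group definition in genome-background comparisons.** Tables compare the
imprinted set against the all-genes set as the two printed groups, without
subtracting the imprinted genes from the genome-wide group, because published
group sizes (54 and 17,761) are reported that way. With 54 of 17,761 the
difference is negligible.

**Transition-classifier totality.** Genes not bivalent in the starting cell
type are outside the resolution question; they are classed `not_applicable`,
except that a strict gain of marks (e.g. `neither` to `bivalent`) is classed
`gained_marks`. Totality over all 4x4 state pairs is required for
property-based testing and for real data, where such paths occur even though
a resolution-focused table would omit them.

**H4K20me3 caveat.** H4K20me3 call sets derive from a more stringent HMM
calling method than the window-interval calls used for the other marks, so
reports carry a fixed caveat string that the mark may be slightly
underrepresented. No numerical adjustment is applied — we propagate the
warning, not a correction.

## The synthetic-data generator

No raw data ships with the package; `generate_bundle()` emits complete input
bundles from a parameterized generative model with retained ground truth, so
every stage is testable end to end. What it emulates:

* a genome of `n_genes` (default 17,761) genes on 19 chromosomes with evenly
  spaced TSSs, of which `n_imprinted` (default 54) are imprinted;
* promoter-DMR classes for imprinted genes (default 18 germline / 8 somatic /
  28 none, i.e. 26 of 54 with a promoter DMR), with all germline-DMR genes
  confirmed ICRs except one, which carries the `non_icr_germline_flag` —
  mirroring the one germline DMR known not to act as an ICR;
* the H3K9me3+H4K20me3 pair drawn conditional on DMR class (default 0.67
  given a germline DMR, 0 otherwise — the observed exclusivity), realized in
  the pluripotent cell type only and always accompanied by H3K4me3, forming
  the tri-mark at the gene level;
* expression drawn per cell type (default P(expressed) 0.71 with a promoter
  DMR vs 0.48 without, matching the reported 71%/48% split);
* H3K4me3/H3K27me3 states conditional on expression status: bivalency
  probability per cell type (default ESC 0.53 repressed / 0.25 expressed,
  the reported ESC fractions; NPC 0.18/0; MEF 0.33/0.20), and, when not
  bivalent, exactly one of `K4_only` / `K27_only` / `neither`. Making the
  non-bivalent states mutually exclusive keeps each configured probability
  identifiable as a plain conditional frequency;
* for genes bivalent in the pluripotent state, the differentiated-cell state
  is drawn from an explicit resolution distribution (default 0.2/0.3/0.2/0.3
  over resolve-to-K4 / resolve-to-K27 / resolve-to-none / retain, the
  proportions of the ten published worked examples);
* ICR regions as their own intervals carrying the tri-mark with probability
  `p_signature_icr` (default 1 — the signature holds at all ICRs);
* a second calling method for the pluripotent cell type whose per-gene calls
  flip with probability 0.019 (the reported ~1.9% method discordance);
* per-layer missingness (annotation / expression / DMR), emulating genes
  absent from individual source studies ("gene not present").

True mark states are realized as enrichment peaks whose centre jitters less
than the flank around the TSS, so a peak always overlaps the TSS window and
the pipeline can recover every latent state exactly; TSS spacing is large
enough that peaks never reach a neighbouring gene's window. ICR regions are
placed *outside* every TSS flank so that region-level signature probability
and gene-level mark conditionals remain independently parameterized and
independently recoverable.

What the generator does **not** emulate: read-level noise and peak-calling
errors (mark booleans are realized exactly); correlated mark domains spanning
multiple genes; distance-dependent promoter effects; allele-specific signal
(all calls are non-allelic, as in the mined sources); and any real genome
geometry. Passing recovery tests therefore demonstrates that the pipeline's
bookkeeping — interval intersection, joining, stratification, counting — is
correct, not that the biological conclusions would survive noisy enrichment
calling.

`recover_parameters()` compares each configured conditional probability with
the pipeline's empirical estimate and a binomial standard error; the test
suite requires every estimate within 3 SE on a 5,000-gene bundle whose
conditioning groups all exceed 200 genes (imprinted count raised to 1,600 for
that purpose — at the realistic 54, per-stratum groups of 10-25 genes make
3-SE bands nearly vacuous, which is itself a faithful property of the
original study sizes).

## Numerical and degenerate-input conventions

* `flank = 0` degenerates to a 1-bp window covering the TSS base, never an
  empty window; windows clamp at coordinate 0.
* Overlap requires at least 1 bp under half-open semantics, so book-ended
  intervals do not overlap.
* An empty call set or an absent chromosome yields `FALSE`, not an error.
* Intensity exactly at the threshold is *expressed* (repressed is *strictly
  below* 25); negative intensities are validation errors; missing
  intensities are *unknown*.
* Tables with an all-zero row or column are `invalid` with the statistic
  omitted rather than `NaN`.
* Percentage-to-count reconstruction uses `round()` to the nearest integer.
* All randomness flows through a single integer seed; identical
  configuration and seed reproduce bundles and report files byte for byte.

## Problem sizes used by the tests

The suite exercises brute-force overlap equivalence on up to 800 random
intervals x 150 genes across multiple seeds, chi-square oracle agreement on
1,000 random tables, taxonomy totality over all subsets of up to 5 marks,
transition totality over all 144 state x expression pairs, and full-pipeline
parameter recovery on a 5,000-gene bundle — sizes chosen so the whole suite
runs in a few minutes on one CPU while leaving no code path untested at a
scale where failures could hide.

## Known limitations

* Enrichment is binary per mark; no signal strength or peak score is
  retained, matching the mined call-set format but discarding information a
  re-analysis from raw reads would have.
* The multi-assay consolidation rule is strict unanimity; a majority rule
  would classify more genes at the cost of manufacturing certainty the
  assays do not provide.
* No liftover: all call sets and annotations must share one genome build.
* The chi-square machinery is asymptotic; for tables flagged
  `valid_with_warning` an exact test would be preferable, but the point here
  is to reproduce the published statistical practice, verdicts included.
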