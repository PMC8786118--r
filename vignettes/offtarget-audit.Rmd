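---
title: "Auditing CRISPR/Cas9 off-targets across populations: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Auditing CRISPR/Cas9 off-targets across populations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(crisprAudit)
```

## The problem and the procedure

SpCas9 directed by a 20-nt spacer cleaves genomic sites that resemble the
guide, provided an NGG PAM sits immediately 3' of the protospacer. A
guide-safety audit therefore asks three questions in sequence:

1. **Which sites resemble the guide?** Candidates come from external
   predictors (this package consumes their outputs through one unified
   TSV schema, plus its own exhaustive scanner for desk-scale genomes) and
   are re-aligned to the guide with a small dynamic program that permits
   bulges, since cleavage has been observed at sites one or two bases
   longer or shorter than the 23-nt guide+PAM.
2. **How likely is each to be cut?** Each alignment is scored with the
   CFD model: every mismatch, bulge and non-canonical PAM multiplies an
   empirically measured activity fraction in [0, 1]. The final score is
   the product of the mismatch factor and the bulge factor — the two are
   treated as independent events.
3. **Does population variation change the answer?** Variants with
   per-population allele frequencies are substituted into each candidate
   and the site re-aligned and re-scored; effects are classified
   (mismatch count up/down, bulge count up, SEED broken, PAM destroyed,
   PAM created) and polymorphic sites are summarised per population,
   including which risks are private to a single population.

### Assumptions inherited from the model

* CFD factors combine multiplicatively and independently; epistasis
  between simultaneous mismatches is not modelled.
* Each variant is evaluated alone. Haplotype combinations of several
  variants inside one site are out of scope, matching the per-variant
  layout of the source tables the audit reproduces.
* Variants are supplied on the genomic plus strand; minus-strand
  candidates are reverse-complemented into guide orientation before
  comparison, and re-oriented when substituting alleles.
* Chromatin state, cell type and 3D-genome context are not considered.

## Alignment: objective, band, ties

`align_candidate()` aligns the candidate (minus its final three PAM
bases, which may never be gapped) to the spacer, minimising
lexicographically **(bulge count, mismatch count)** within a band of 2
around the diagonal — sufficient for the supported candidate lengths of
21–25 nt, i.e. at most two bulges. Ties are resolved by preferring the
diagonal during traceback from the PAM end, which pushes bulges
PAM-distal (toward guide position 1); this matches the empirical
observation that tolerated bulges sit well away from the PAM. `N` bases
in genomic sequence count as mismatches, never as matches
(conservative). Degenerate inputs — lengths outside 21–25, gaps inside
the PAM, gapped notation that would additionally imply insertions — are
rejected with explicit errors rather than guessed at.

The aligner is verified against an exhaustive oracle that enumerates
every legal gap placement. One consequence of *minimising* is worth
stating plainly: when a published table was produced from a predictor's
own, non-minimal alignment, this package can find a strictly better
alignment for the same sequence and will report the better one (its score
then differs from the printed value). The bundled golden tests pin both
paths: the minimal alignments reproduce four of the five published bulge
scores exactly, and the fifth is reproduced from its published alignment
via the explicit-pair constructor.

## CFD penalties and the bulge-key convention

The activity fractions are the published Doench et al. (2016)
measurements, shipped as `inst/extdata/cfd_penalties.tsv` (md5 checksum
recorded in every run log). Match entries are 1.0 by construction and NGG
PAMs score 1.0. Two conventions for pricing bulges are possible a priori
(count positions from the 5' end or from the PAM; key insertions by the
inserted base or its complement). The convention was fixed *empirically*
against the worked examples published with the indel extension:

* an **insertion in the target** is keyed by the inserted base and the
  gapped-guide coordinate of the gap column;
* a **deletion in the target** is keyed by the deleted guide base and its
  guide position.

Published bulge activities exist for positions 2–20 only. A bulge at
position 1 is not a physical bulge — it is indistinguishable from
choosing a shorter window — so scoring one raises an explicit
missing-key error (the spec'd default), and the variant-overlay path
reports such scores as `NA` with the reason attached rather than
aborting an audit.

Thresholds (0.2 "probable", 0.023 "possible") are compared against
**unrounded** scores; three-decimal rounding is display-only. This
matters: one published final score (0.138) is only reproducible from the
unrounded factors — the printed three-decimal factors multiply to 0.137.

## Tunable parameters

| parameter | default | units | why |
|---|---|---|---|
| `max_mismatches` | 6 | bases | GUIDE-seq evidence of cleavage at 6 mismatches |
| `max_indels` | 2 | bulges | cleavage observed with up to 2 bulges |
| `seed_len` | 5 | bases | experimental SEED-conservation evidence |
| `pam_pattern` | NGG | IUPAC | wild-type SpCas9 |
| score thresholds | 0.2 / 0.023 | probability | published cut-offs for probable / possible cleavage |
| `af_threshold` | 0.01 | allele fraction | the >= 1%-in-any-population polymorphic rule |
| repeat `flank` | 200 | bp | the flanking window used for "near repeat" calls |
| populations | E, LA, A (+W) | — | the three audited populations; worldwide reported but never a trigger |

All are overridable per run (`filter_policy()`, `run_config()`); defaults
reproduce the audited study's criteria.

## The synthetic world

`make_genome()` draws i.i.d. background sequence at a requested GC
fraction (default 0.41, the human-like value; observed GC converges
within 2 percentage points above 10 kb). Planted off-targets emulate the
statistical structure of the audited candidate set: 4–6 mismatches and
0–2 bulges confined to the 15 PAM-distal positions (so SEED stays
conserved), canonical NGG PAMs, both strands. Population variants are
emitted as small VCFs in the 1000 Genomes INFO dialect (`AF`, `EUR_AF`,
`AMR_AF`, `AFR_AF`, Number=A) with REF alleles read back from the genome.

Two honesty notes about what a green test does and does not establish:

* A planted bulge can be *shadowed*: the same PAM position may admit a
  mismatch-only window that the lexicographic objective prefers.
  `synthesize_offtarget_genome()` therefore verifies every planted site
  in genomic context and redraws shadowed specs, so truth tables are
  exact by construction — the tests then demonstrate correct recovery of
  a *recoverable* world, not that shadowing never happens in real
  genomes.
* The background has no repeat structure, no linkage disequilibrium and
  no realistic site-frequency spectrum. Repeat flagging is exercised with
  hand-written interval fixtures; population realism is limited to
  frequencies straddling the 1% threshold in designed patterns.

The genome scan is anchored on exact SEED + PAM occurrences, which is
both what makes it fast and a real restriction: sites with a broken SEED
are invisible to it by design (they fail the inclusion filters anyway).
The near-PAM scan (NNG/NGN sites convertible to NGG by a variant) is
exhaustive over mismatch-only 20-mers and is intended for desk-scale
genomes; for real genomes the documented path is ingesting external
alignments.

## Numerical and interface choices

* Coordinates are 0-based half-open internally (BED/VCF interop);
  reports render 1-based inclusive intervals.
* Scores render at 3 decimals, frequencies at one decimal percent, "-"
  marks a not-applicable bulge score, `**`/`*` mark the score tiers.
* Run configs are JSON (`jsonlite`), not YAML: no YAML parser is part of
  the supported dependency stack, and the config surface is flat enough
  that the format choice is cosmetic.
* VCF ingestion is a minimal purpose-built text parser (multiallelic
  split, Number=A INFO alignment, absent population = absent key — never
  zero). Malformed records are skipped with a warning; a REF allele that
  contradicts the stored site sequence is a hard data-integrity error.
* Variant substitution re-derives the candidate window from stored
  flanks when an indel changes its length, anchoring the PAM-proximal
  end; length-changing REF alleles that cross the site boundary are
  skipped with an explicit reason.
* Two runs with identical config and inputs produce byte-identical
  reports; input checksums, the penalty-table checksum and the seed are
  recorded in the run log.

## Known limitations

* Only NGG-family PAM patterns; no non-SpCas9 nucleases.
* No aggregate per-guide specificity score (MIT-style) — per-site
  probabilities only.
* The effect classifier has no category for "alignment changed but no
  count moved" (e.g. a mismatch swapped for a different mismatch at the
  same position); such overlays carry an empty effect set, while
  `no_change` is reserved for column-identical alignments.
* Bulge-bearing re-alignments after variant substitution can differ in
  placement from the pre-variant alignment; counts are always taken from
  the minimal alignment, which is self-consistent but can disagree with
  tables produced from fixed predictor alignments.
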