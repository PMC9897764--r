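---
title: "How trnacurate decides: rules, screens and triage"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{How trnacurate decides: rules, screens and triage}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(trnacurate)
```

`trnacurate` post-processes predicted prokaryotic tRNA gene sets to separate
canonical tRNA genes from tRNA-like artifacts. This vignette is the
package's account of how each decision is made, why the defaults are what
they are, and what the synthetic test bed does and does not establish.

## The structural model

A canonical tRNA gene is recognized by a fixed set of cloverleaf elements.
The annotator locates them with anchored rules applied in a fixed order,
each element sought relative to the previous one (3′ to 5′):

1. **CCA, discriminator, acceptor stem.** If the last three bases are CCA
   they are taken as the genomically encoded 3′ terminus and the
   discriminator is the base before them; otherwise the discriminator is
   the final base and a `NO_CCA` *warning* is recorded. Many prokaryotic
   tRNA genes do not encode CCA, so its absence must not be disqualifying.
   The acceptor stem pairs positions 1–7 against the seven bases preceding
   the discriminator (simplified Sprinzl positions 72–66).
2. **T-arm.** A 17-nt stem-loop whose loop matches `T-T-C-{A,G}-A-N-N`
   and whose 5-bp stem sides pair. It is sought strictly 5′ of the acceptor
   3′ side, and the match *nearest the acceptor* (3′-most) wins, because the
   T-arm directly precedes position 66; a more 5′ chance match would leave
   unexplained sequence between T-arm and acceptor.
3. **Variable region and anticodon arm.** Candidate variable-region lengths
   are tried in the order 5, 4 (the common short forms), then 10–24 nt (the
   long "extra arm" of Leu/Ser-type genes). The first length for which a
   5-bp anticodon stem pairs is accepted; the anticodon is loop positions
   3–5 (Sprinzl 34–36). A loop not starting C-T earns a
   `NON_CU_LOOP_START` warning only — it is common enough in real genes
   that it must not be fatal.
4. **D-arm.** A stem of 4 then 3 bp (longer preferred) with a loop of
   4–12 nt, ending one or two bases 5′ of the anticodon arm (position 26
   connector). The wide loop range reflects the genuine length flexibility
   of D-loops.
5. **Connectors.** Positions 8–9 (acceptor stem to D-arm) and 26; lengths
   outside 1–3 nt yield a `BAD_CONNECTOR` warning.

Element order, not absolute index, is authoritative: genes with long
variable arms shift all downstream absolute positions, but the anchored
search is indifferent to that.

**Pairing rule.** All stems accept Watson–Crick pairs plus the G:U wobble
(G:T at the DNA level). `N` pairs with anything for structure purposes, but
every `N` is tallied and handed to the ambiguity screen — treating unknown
bases as structure-compatible while flagging the gene keeps the two
concerns (can it fold? / can we trust the base calls?) separate.

**Tolerances.** The acceptor stem tolerates one mispair by default
(reported as an `ACCEPTOR_MISPAIR` warning); beyond that the stem is called
absent (`NO_ACCEPTOR_STEM`, fatal). The precedent is a known canonical,
essential single-copy gene whose only blemish is a single acceptor-stem
point defect: a rule that rejected it would be wrong. T-arm and anticodon
stems default to zero tolerance — their motifs are what anchors everything
else, and loosening them measurably inflates false anchors on random
sequence. Sequences under 50 nt receive a fatal `TRUNCATED` defect but are
still annotated as far as possible, so that fragments report *which*
elements they do contain (typically a T-arm and one acceptor side).

A structure is **canonical** iff it has no fatal defects; warnings never
disqualify.

## Genomic-context screens

**attR pairs.** The screen is anchored on predicted genes rather than
hunting repeats genome-wide: (a) every pair of same-isotype (or
undetermined-isotype) predictions on a contig within 250 kb is compared at
both terminals of their oriented sequences, reporting the maximal shared
terminal segment with at most 1 mismatch when it reaches 20 bp; (b) each
structurally intact prediction's 3′-terminal segment (up to 100 bp) is
additionally scanned against the whole contig, catching partial copies the
gene finder never called. Fragment-like predictions are not used as scan
anchors — their termini are element sequence, not tRNA sequence, and using
them re-discovers the array or element they sit in. The 20-bp minimum is a
configurable floor well below the 44-bp repeats of the motivating cases;
the 250-kb separation cap leaves headroom over the largest observed
rearranged case (~179 kb) while bounding the pair search. Element size is
reported (distance between the inner repeat edges) but never filtered on:
the integration mechanism is size-agnostic. Which copy is the *partial* one
is decided by fewer located structural elements, then by lower isotype
score, and otherwise left uncertain — only a copy positively identified as
partial can be called a fragment.

**CRISPR arrays.** A minimal periodic direct-repeat finder: exact 13-mer
seeds recurring at admissible periods (repeat 20–50 bp plus spacer
20–60 bp) are chained, anchored copies are extended to their maximal common
length, and overlapping candidates are merged; arrays need at least 3
repeat copies with at most 1 mismatch between them. This is deliberately
not a full CRISPR annotator (no leader detection, no degenerate terminal
repeats) — externally detected arrays can be supplied as a BED track
instead. Any prediction intersecting an array span by ≥ 1 bp is flagged,
with the covered repeat/spacer counts recorded.

**Ambiguity and tmRNA.** A prediction whose sequence contains `N` produces
an ambiguity record (count, and whether an `N` sits in the anticodon); a
user-supplied tmRNA BED track flags overlapping predictions, since tmRNA
3′ ends carry enough tRNA-like structure to be called as spurious tRNA
genes. The package does not detect tmRNA genes itself.

## Triage

Isotype-score bands use the thresholds 60 and 90 (below: likely
non-canonical; above: likely canonical; between: uncertain), with a
separate 85 reporting flag ("scrutinize this gene") that deliberately does
not influence the verdict — it exists so that downstream users can apply
the stricter screen without the package pre-judging borderline genes.

The per-gene precedence is: CRISPR overlap → attR partial copy →
ambiguous-isotype rescue → tmRNA overlap → score band and structure →
canonical. Context evidence outranks scores because every known fragment
case carries both, and the context explains *why* the score is low.
Decisions taken where the procedure was genuinely open:

* **Uncertain band, intact structure → `CANONICAL`**, with a
  "manual review recommended" rationale and the band preserved. The
  precedent is the essential single-copy gene at score 88.1; the
  alternative (an `UNCERTAIN` category) would push every borderline but
  structurally perfect gene out of the canonical set.
* **Pseudogene flags are advisory.** A flagged gene is demoted only when
  fatal structural defects concur. Upstream flags are valuable but were
  produced by a different model; a high-scoring, structurally clean gene
  should not be removed on the flag alone.
* **Rescue is a two-pass computation.** The per-genome deficit of missing
  standard types is computed from the confidently canonical calls *first*
  (fragments excluded), and an ambiguous gene is reassigned only when
  exactly one missing type matches its anticodon at every non-N position
  (and its isotype, when determined). Requiring uniqueness makes rescue
  conservative: `N-A-G` against a deficit of {Leu-CAG} rescues; against
  {Leu-CAG, Leu-TAG} it does not.
* **Duplicates.** A canonical call whose type is already satisfied becomes
  `LEGITIMATE_DUPLICATE` — counted in the canonical set, flagged in the
  anomaly table. Copies are ranked in genomic order within a genome, so the
  verdict is deterministic.

In curated-mode set comparison, fragments and other non-canonical calls
are excluded, rescued genes count under their reassigned type, and
duplicates count under their own type. Raw mode counts every record as
predicted. Comparison emits one anomaly record per unit of deviation, so
the anomaly count equals the L1 distance between the observed and expected
count vectors.

## The packaged reference data

* `inst/extdata/archaea46.tsv` — the archaeal standard set: 46 tRNA types,
  each expected once, with initiator Met, elongator Met and Ile2 (all CAT)
  distinct. The composition is reconstructed from the field's standard
  archaeal set (three anticodons per family box; split boxes per archaeal
  wobble rules) and shipped as editable configuration, not code.
* `inst/extdata/thermococcaceae_anomalies.tsv` — a transcription of a
  published 15-anomaly accounting across 20 Thermococcaceae genomes
  (12 gene records; paired additional/missing anomalies share a record).
  `thermococcaceae_listing()` reconstitutes the full 929-gene listing from
  it; the 13 genomes that carry exact standard sets get synthetic
  placeholder identifiers and a typical canonical score (115) for their
  unremarkable genes, since the published per-gene scores exist only for
  the anomalous records. Every counting result (929 genes, 15 raw and 1
  curated anomaly, 7 of 20 deviant genomes, 8 genes under the 85 flag) is
  exact; per-gene score distributions for the full listing are
  illustrative only.

## The synthetic test bed

`generate_fixture()` builds genomes from uniform random background
(default 50 % GC, configurable across the 40–56 % range typical of the
emulated genomes) and plants, at non-overlapping positions chosen by
rejection sampling: canonical genes produced by `make_canonical_gene()`
(sampled stems and loops satisfying every annotator rule, validated by the
annotator itself and resampled on failure); integration events (the
target gene's terminal segment duplicated with a chosen mismatch count at a
chosen element distance, optionally inverted); CRISPR arrays (optionally
with one spacer carrying a T-arm/acceptor-side fragment of a planted
gene); and N-masked genes. Two deliberate generator details keep planted
truth exact: the base flanking a planted repeat is forced to differ from
its counterpart, and spacer edge bases cycle, so chance flank agreement can
never extend a detected repeat beyond its planted length. Synthetic
isotype scores are drawn uniformly: 95–135 for intact genes, 2–40 for
fragments — emulating the empirical separation, not its shape.

What the fixtures do **not** emulate: covariance-model scoring (scores are
assigned, not computed from sequence), modified nucleotides, introns,
compositional heterogeneity, real element cargo (interiors are random
sequence), or degenerate CRISPR end repeats. Passing tests therefore
establish that the rule engine, the screens and the triage logic are
correct and mutually consistent on sequence that satisfies the stated
model — they do not measure recall on real genomes, where structural
idiosyncrasy beyond the rules is the binding constraint.

Problem sizes used by the test suite and the acceptance script: 100
generated genes for the annotator check; 20 seeded fixture genomes of
8 kb for screen recall/precision and brute-force-oracle equivalence; one
30-kb genome for the 21.4-kb element geometry; one 200-kb genome for the
inverted 179-kb geometry; one 8-kb genome for the 41-repeat array. These
sizes make every detector decision exhaustively checkable against
quadratic oracles while keeping a full run in minutes.

## Numerical and degenerate-input choices

All internal coordinates are 1-based inclusive (the convention of the
upstream gene tables); conversion to 0-based half-open happens only at BED
boundaries. Minus-strand records (begin > end in tRNAscan-SE output) are
normalized at parse time with the orientation kept in an explicit strand
column. Empty inputs are values, not errors: an empty prediction table
curates to an empty call table, an empty tmRNA track produces no evidence,
an all-header input file parses to zero records. Missing isotype scores
band as `UNCERTAIN` with a warning. There is no unseeded randomness
anywhere in the pipeline; identical inputs and configuration reproduce
byte-identical outputs.

## Known limitations

* The annotator is a rule engine, not a covariance model; unusual but
  genuine structures (severely non-standard D-arms, permuted genes) will
  accrue fatal defects. The score bands and context evidence, not the
  structure alone, drive the verdict for exactly this reason.
* attR detection assumes the partial copy retains a terminal segment of
  the full gene; integrations that erode both termini below 20 bp are
  invisible to it.
* The CRISPR finder requires near-identical repeats (≤ 1 mismatch by
  default) and at least one exact 13-mer shared across copies; degraded
  arrays should be supplied externally.
* Intra-genomic duplications are reported, not adjudicated: a
  `LEGITIMATE_DUPLICATE` may still be an assembly artifact (long
  near-identical repeats are exactly what assemblers struggle with), and
  the rationale says so.
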