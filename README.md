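# trnacurate

Curation of predicted prokaryotic tRNA gene sets: distinguishing canonical
tRNA genes from tRNA gene fragments.

## The problem

Automated tRNA gene finders (tRNAscan-SE, surfaced through GtRNAdb) are very
good at finding tRNA-like sequence, and that is exactly the problem: a
prokaryotic genome contains tRNA-like sequence that is *not* a functional
tRNA gene. Two biological processes routinely plant such decoys:

* **Mobile genetic element integration.** Phages and integrative/conjugative
  elements preferentially integrate into tRNA genes, leaving one complete
  and one partial copy of the target gene at opposite ends of the element,
  joined by a direct repeat (the attachment site, *attR*). The partial copy
  is then listed as an extra "standard" tRNA gene.
* **CRISPR-Cas spacer acquisition.** A spacer derived from a viral tRNA gene
  can carry enough structure (a T-arm and one side of an acceptor stem) to
  be called as a tRNA gene inside a repeat–spacer array.

A third, purely technical source of error is ambiguous sequence: an `N` in
the anticodon makes the finder mis-assign the isotype, producing a spurious
"additional" gene of one type and a matching spurious "missing" gene of
another.

In Archaea the expectation is sharp — a standard set of 46 tRNA types, each
encoded by a single gene — so every one of these artifacts shows up as an
apparent deviation from the standard set. `trnacurate` automates the manual
triage a careful annotator would perform: it parses tRNAscan-SE output,
re-annotates each predicted gene's cloverleaf structure with an explicit
rule set, screens the genomic context for attR pairs, CRISPR arrays,
ambiguous bases and (optionally) tmRNA genes, and emits one audited verdict
per gene.

## What it computes

For each predicted gene (score *s* = tRNAscan-SE isotype bit score):

* a **triage band**: *s* < 60 likely non-canonical, 60 ≤ *s* ≤ 90 uncertain,
  *s* > 90 likely canonical, plus a separate *s* < 85 "scrutinize" flag;
* a **structural annotation**: the seven cloverleaf elements (acceptor stem
  1–7/66–72, discriminator 73, CCA 74–76, T-arm with loop consensus
  UUCRANN, variable region, anticodon arm with the anticodon at 34–36,
  D-arm, connectors 8–9 and 26), located by anchored rules with
  Watson–Crick + G:U pairing, and a defect list;
* **context evidence**: shared-terminal-repeat attR pairs (which copy is
  partial), CRISPR repeat–spacer array overlaps, N counts, tmRNA-track
  overlaps;
* a **category**: `CANONICAL`, `FRAGMENT_ATTR`, `FRAGMENT_CRISPR`,
  `MISASSIGNED_AMBIGUOUS` (with the rescued isotype/anticodon),
  `NONCANONICAL_OTHER`, or `LEGITIMATE_DUPLICATE`.

Gene sets (raw or curated) are then compared against a standard set — the
packaged archaeal 46-type set by default — yielding per-unit anomaly
records and a genomes × types count matrix.

A seeded fixture generator (`generate_fixture()`) builds synthetic genomes
with planted canonical genes, integration events, CRISPR arrays and
N-masked genes, with machine-readable ground truth; it is how the package
tests itself without any downloads.

## Worked example

The package ships a transcription of a published 15-anomaly accounting for
the 20 Thermococcaceae gene sets listed in GtRNAdb, and a builder that
reconstitutes the corresponding 929-gene listing:

```r
library(trnacurate)
library(dplyr)

std     <- standard_archaea46()
listing <- thermococcaceae_listing(std)

raw <- compare_to_standard(listing, std, mode = "raw")
nrow(raw)
#> [1] 15
table(raw$direction)
#> ADDITIONAL    MISSING
#>         12          3
```

Fifteen apparent deviations (twelve additional genes, three missing) across
7 of the 20 genomes. Running the triage with the table's context evidence:

```r
cur <- curate_thermococcaceae(std)
glance(cur) |> filter(n_genes != 46)
#> # A tibble: 7 × 9
#>   genome_id          n_genes n_canonical n_fragment_attr n_fragment_crispr n_misassigned ...
#> 1 Ppacificus_DY20341      47          47               0                 0             0
#> 2 Pyayanosii_CH1          47          46               1                 0             0
#> 3 Tgammatolerans_EJ3      47          46               1                 0             0
#> 4 Tkodakarensis_KOD1      48          46               2                 0             0
#> 5 Tlitoralis_DSM5473      47          43               1                 0             3
#> 6 Tnautili_30-1           47          46               0                 1             0
#> 7 Tsp_ES1                 48          46               2                 0             0

compare_to_standard(cur, std, mode = "curated")
#> # A tibble: 1 × 6
#>   genome_id          isotype anticodon direction  observed expected
#> 1 Ppacificus_DY20341 Ala     TGC       ADDITIONAL        2        1
```

After curation, seven integration fragments and one CRISPR-embedded
fragment are removed, three ambiguous genes are rescued to the types they
apparently displaced (Leu-CAG, Pro-GGG, Gln-CTG), and a single genuine
deviation remains: a duplicated Ala-TGC gene, retained as
`LEGITIMATE_DUPLICATE`. The error rate attributable to automated
annotation is (15 − 1) / 929 ≈ 1.5 %.

On a genome + predictions of your own:

```r
res <- run_pipeline("genome.fa", "trnascan_output.tsv", "out/")
```

or from a shell, via the bundled wrapper (subcommands `curate`, `compare`,
`fixtures`, `histogram`):

```sh
Rscript $(Rscript -e 'cat(system.file("scripts/trnacurate.R", package="trnacurate"))') \
  curate --genome genome.fa --predictions trnascan_output.tsv --out out/
```

`out/` then contains the curation table (TSV + JSON), raw and curated
anomaly tables, the count matrix, a score histogram, BED/GFF3 tracks and a
text summary, each with a provenance header recording every threshold used.

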