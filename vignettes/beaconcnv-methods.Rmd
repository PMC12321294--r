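---
title: "Methods: federated Beacon v2 queries, CNV frequencies, and survival estimation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: federated Beacon v2 queries, CNV frequencies, and survival estimation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(beaconcnv)
```

## What the package computes

`beaconcnv` connects three things that cancer-genomics analysts routinely
chain together: discovery queries against GA4GH Beacon v2 endpoints,
harmonization of the nested JSON answers into rectangular tables, and two
downstream analyses that run on the retrieved (or locally stored) data —
cohort copy-number-variation (CNV) frequency profiles and Kaplan–Meier
survival comparison. Everything is testable offline: the package ships a
synthetic-cohort generator and a mock beacon that speaks the same protocol
envelope as a live server.

## The Beacon v2 query model

A beacon exposes four default-model entities — individuals, biosamples,
analyses, and genomic variations — under REST endpoints
`/{entry_point}/{individuals|biosamples|analyses|g_variants}`, plus an
informational `/filtering_terms` inventory. Queries constrain records with
CURIE-valued filters (for example `NCIT:C3512`, lung adenocarcinoma, from
the NCI Thesaurus). Two semantics matter and are enforced throughout:

* **AND over filters.** Multiple filters on one request are combined
  conjunctively; on a GET request they travel as a single comma-separated
  `filters` parameter. Adding a filter can therefore only shrink a result
  set, a property the test suite checks against direct set computation on
  the generator's truth.
* **OR over term patterns.** Keyword search across the filtering-term
  inventory matches a term when *any* pattern occurs case-insensitively in
  its id or label. This makes `"male"` match both `Male` and `Female`; that
  is deliberate, documented behavior of substring matching, and the test
  suite pins it.

Responses arrive at one of three granularities — boolean, count, record —
and the client preserves the distinction rather than coercing: a boolean
answer is kept as exists/not-exists with a granularity tag, a count answer
carries `numTotalResults` and no records. Failures (HTTP errors, timeouts,
malformed JSON, unreachable hosts) are captured *inside* the per-domain
response envelope. This is the backbone of federation: a query fanned out
over several domains returns every domain's envelope, the merged table of
the domains that answered, and never throws because one of them did not.

Federated fetches run in a worker pool (`parallel::mclapply`) with no
shared state between domain tasks, so the merged table is identical
whatever the worker count — an invariant under test. Records returned by
two domains are *not* deduplicated; each row keeps a `domain` provenance
column and identity resolution is left to the analyst, who alone can say
whether two records denote one specimen.

Transport policy defaults to a 30 s timeout and 2 retries with exponential
backoff, all tunable through `http_transport()`. The same client code runs
against canned response files (`fixture_transport()`) and an in-process
dataset transport, which is how the suite exercises the full client path
without sockets.

## Declarative JSON flattening

Beacon entity documents are nested. The mapping engine converts them to
tables using per-entity YAML configurations: each output column names a
dot-separated path (`histologicalDiagnosis.id`), optionally with a `[]`
marker that collects a value across list elements
(`externalReferences[].id`). This tiny dialect — deliberately not full
JSONPath — keeps flattening auditable. List values are handled by a
per-column cardinality: `first`, `join` (delimiter `;`, the common
convention of tabular bioinformatics exports), or `explode`, which
multiplies a record into one row per element. At most one column may
explode so row multiplication stays unambiguous; a record with an empty
exploded list still yields one (null-filled) row. Resolution is total:
missing keys at any depth give nulls, never errors, so arbitrarily sparse
documents flatten cleanly. Row-count conservation — one row per record
without explode, $\sum \max(1, |list|)$ with it — is a tested invariant.

Tables from beacons with different column inventories are merged by taking
the ordered union of columns (first-seen order) with `NA` fill; a column
that is character-typed on any domain is promoted to character everywhere
rather than failing the bind. The shipped entity configs mirror a
Progenetix-style document layout; they are best-effort defaults, and any
beacon with a different shape can be accommodated by passing a custom
config.

## Segment files and coordinates

CNV segment data arrives as `.seg` (the classic circular-binary-
segmentation output: TAB-separated, 1-based inclusive coordinates) or
`.pgxseg`, which prepends `#key=value;key=value` per-sample metadata lines
to the segment table and uses interbase (0-based half-open) coordinates.
Internally everything is interbase; `.seg` input is shifted on read and
re-shifted on write. Header spellings vary across exporters, so the parser
accepts documented synonym sets (`sample_id`/`biosample_id`,
`log2`/`value`/`seg.mean`, ...). Parsing is strict where it matters —
missing mandatory columns and non-numeric or inverted coordinates fail
with the offending line named — and lenient where reality is messy:
segments whose sample lacks a metadata line are a warning, unparseable `#`
lines are preserved verbatim as comments. Writing then re-reading a file
reproduces the object exactly on its canonical form (chromosomes ordered
1–22, X, Y, then by start), which the suite verifies field-by-field on a
seeded 1000-segment fixture.

The parser does not interpret state labels beyond lower-casing the three
canonical ones; mapping CURIEs or `DUP`/`DEL` tags to states is the
classifier's job.

## CNV statistics

**Classification.** Segments become `gain`/`loss`/`neutral` by precedence:
an explicit canonical state or a vocabulary-mapped label (EFO copy-number
terms, Sequence Ontology terms, `DUP`/`DEL`) wins over the log2 ratio;
otherwise log2 $\ge$ +0.15 is a gain and log2 $\le$ −0.15 a loss. The
±0.15 defaults are a common convention for array-resolution calls, not a
protocol constant, and both thresholds and vocabulary are arguments. Only
the three-state model is used; high-level amplifications and homozygous
deletions are not distinguished.

**Binned frequency.** The genome is tiled into fixed-size bins (default
1 Mb, the Progenetix-style convention; the terminal bin of each chromosome
absorbs the remainder so bin lengths sum exactly to chromosome lengths).
For bin $b$ and state $s$,

$$ f_s(b) = 100 \cdot \frac{\#\{\text{samples with} \ge 1\; s\text{-segment overlapping } b \text{ by} \ge m \text{ bases}\}}{n_{\text{samples}}} $$

with `min_overlap` $m = 1$ by default (any overlap counts — the simplest
defensible rule, and the one that matches a per-base oracle exactly). A
sample counts at most once per bin per state; a sample carrying both a
gain and a loss in one bin counts toward both numerators; samples without
any CNV still count in the denominator. Every reported percentage is
therefore an integer multiple of $100/n_{\text{samples}}$. The production
path uses IRanges overlap machinery; an independent per-base counter
(`per_base_freq()`, pure coverage vectors, no interval algebra) is exported
as the reference implementation and the two must agree exactly — the suite
checks 10 seeded cohorts of 20 samples over the five-chromosome fixture
genome.

**Genome fraction.** Per sample, the gain (loss) fraction is the length of
the union of its gain (loss) intervals divided by the genome length, so
the measure is invariant to how calls are split into adjacent or
overlapping pieces; `total_fraction` uses the union of both state sets and
equals the sum only when gains and losses are disjoint. A per-chromosome
scope divides by each chromosome's length instead. GRCh38 chromosome
lengths are bundled as the default denominator; any assembly table can be
supplied.

**Rendering.** Frequency plots mirror gains upward and losses downward on
a fixed −100..100 axis, with a genome-cumulative x axis or per-chromosome
panels. Every plot function has a corresponding `*_plot_data()` that emits
the exact coordinates drawn, so rendering is tested by table inspection
rather than pixel comparison.

## Survival estimation

The product-limit estimator is implemented directly:
$S(t) = \prod_{t_i \le t} (1 - d_i/n_i)$ over distinct event times, with
censorings reducing later risk sets only; at tied times, subjects censored
at $t$ remain at risk for the events at $t$ (the standard convention).
Confidence intervals use the Greenwood variance on the log scale,
$\widehat{\operatorname{Var}}[\log S] = \sum d_i / (n_i(n_i-d_i))$. The
log-rank test accumulates, at each event time, observed minus expected
events per group (expected proportional to at-risk share) and the
hypergeometric covariance
$V_{jl} = \frac{d(n-d)}{n-1}\,\frac{n_j}{n}\left(\delta_{jl}-\frac{n_l}{n}\right)$;
the statistic is the quadratic form over $k-1$ groups with $k-1$ degrees
of freedom. Both are authored in the package and cross-checked in the test
suite against `survival::survfit` / `survival::survdiff` (agreement to
1e-9 on $S(t)$, 1e-6 on the statistic, over seeded random datasets), and
the test's calibration check verifies the nominal 5% type-I error rate
within [0.03, 0.07] over 500 two-group null replicates. A singular
covariance (no events at all) yields a statistic of 0 by convention rather
than an error.

The bridge from flattened individual tables to survival records maps
status text through a configurable vocabulary (`"dead"` → event,
`"alive"` → censored, ...) because beacons do not agree on field encodings;
rows with missing or unmapped values are dropped and counted in a warning,
and grouping is either a metadata column or a numeric threshold split.
Time units are the caller's responsibility — no calendar parsing.

## The synthetic cohort generator

`generate_cohort()` draws a referentially consistent mock dataset:
individuals (one biosample and one analysis each), CURIE terms assigned
independently per individual with stated probabilities, CNV segments
generated bin-wise (per sample and bin: gain with probability $p_g$, loss
with $p_l$, $p_g + p_l \le 1$) and merged into maximal same-state runs,
log2 values drawn from N(0.35, 0.08) for gains and N(−0.45, 0.08) for
losses, and survival times from per-group exponential event and censoring
hazards. Defaults are $p_g = p_l = 0.1$, a 50-individual cohort, and an
event hazard of 0.02 with censoring hazard 0.01 — cohort-scale choices a
CNV analyst would call unremarkable for array-era tumor panels. Because
bin states are i.i.d., the expected per-bin gain frequency equals $p_g$
exactly, which is what makes the parameter-recovery check meaningful.

The fixture genome is five synthetic chromosomes of 4.0/3.5/3.0/2.5/2.2 Mb
at 1 Mb bins (17 bins): small enough that the per-base reference counter
and the brute-force fraction oracle run in seconds, with non-multiple
lengths so partial terminal bins are always exercised. Randomness is
confined to the dataset's own seed (the caller's RNG state is saved and
restored), so identical specs give byte-identical fixture exports.

What the generator does *not* emulate: realistic genome-wide CNV
landscapes (no length distribution over focal vs arm-level events, no
recurrent driver loci, no correlation between nearby samples), ontology
hierarchies (terms are flat tags, not a DAG), boolean-only access-policy
beacons beyond the granularity tag, and non-exponential survival. Passing
tests therefore demonstrate protocol and algorithmic correctness, not
biological realism.

The mock server (`serve_mock()`) runs the same answer function as the
in-process transport inside a background httpuv process, so every HTTP
answer is reproducible by direct computation on the dataset; fault
injection (HTTP 500, stalled response, malformed JSON) is configured per
request count, making retry behavior deterministic to test.

## Command-line interface

`inst/cli/beaconcnv.R` is a thin Rscript over the exported functions:
subcommands `query`, `counts`, `filters`, `freq`, `fraction`, `survival`,
`mock`, with exit codes 0 (success), 1 (usage error), 2 (partial
federation failure), 3 (runtime error). Every CLI output is produced by
the corresponding library call, and the suite asserts byte parity.

## Numerical and design choices

* Interbase coordinates internally, everywhere; dialect shifts happen only
  at file boundaries.
* `limit = 0` means "server default page size"; paging is pass-through.
* GET with query parameters only; POST query grammars, authentication
  flows, and sequence-level variant matching are out of scope.
* Default join delimiter `;`; values keep native JSON scalar types until
  file export, where nulls become empty strings.
* Problem sizes in the checks — 10 cohorts × 20 samples for the frequency
  oracle, 500 replicates for the log-rank calibration, 1000 segments for
  the round-trip — were chosen so the whole suite completes in about two
  minutes on one core while leaving each estimate well-powered.

## Known limitations

The shipped mapping configs are reconstructions of a Progenetix-style
layout and will under-extract beacons with materially different document
shapes (supply a custom YAML). The `.pgxseg` header synonym list is a
documented superset of spellings seen in the wild, pending revision
against more exporters. The log-rank implementation is the unweighted
statistic only — no stratification, no Fleming–Harrington weights — and
Cox regression is deliberately out of scope.
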