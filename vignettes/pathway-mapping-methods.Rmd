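---
title: "EC-centric pathway mapping and two-group differential abundance: methods"
author: "MetaPathDA"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{EC-centric pathway mapping and two-group differential abundance: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(MetaPathDA)
```

## The problem

Metaproteomics identifies peptides (or infers proteins) from the collective
proteome of a microbial community. To turn long identification lists into
biochemical insight, the identifications must be placed onto metabolic
pathway maps and, in comparative designs, contrasted between sample groups.
MetaPathDA implements that computational core offline: it resolves peptides
or UniProtKB accessions to Enzyme Commission (EC) numbers and taxa through a
pluggable batch resolver, joins them transitively onto EC-labelled pathway
graph nodes, ranks and filters pathways by match counts, contrasts two
groups per node, and exports tables and SVG overlays.

EC numbers are the single join key. Pathway maps annotate their enzyme
boxes with EC numbers (sometimes partial, e.g. `2.8.3.-`), and annotation
services report EC numbers per peptide or protein, so the item → EC →
node → pathway chain needs no other identifier system. KO (KEGG Orthology)
ids are carried through the model for display but never used for matching.

## Data model

Five S4 classes carry the state:

* `PathwayGraph` — one map parsed from KGML-dialect XML: compound nodes,
  enzyme boxes (with EC/KO sets and box geometry) and links to
  neighbouring maps; reaction edges (one per substrate/product pair,
  bidirectional when the reaction is reversible) and maplink edges.
* `EcLinkTable` — EC → map / reaction / compound multimaps from
  two-column link TSVs.
* `SampleGroupSet` — parsed entries of all samples with the group
  partition and per-group totals (the denominators below).
* `MappingIndex` — the interlinked item↔EC↔node↔pathway↔taxon store,
  built once per upload; every later interaction reads from it.
* `Taxonomy` — a rooted NCBI-style flat taxonomy for per-node summaries.

## Matching semantics

**Wildcard ECs.** A trailing `-` field matches any value in that and all
later positions, in either operand: an item annotated `2.8.3.-` reaches a
node labelled `2.8.3.8`, and a query `2.8.3.-` collects every `2.8.3.*`
node. This mirrors how partial ECs appear both on maps and in annotation
output.

**Counting.** Pathway-level match counts weight each item once per pathway
(not once per node or per EC): an item whose several ECs hit three nodes of
one map still contributes its weight once to that map's count. Per-node
counts for the differential-abundance view weight each item once per node.
Item weight is its occurrence count (multiplicity) in peptide mode — the
package keeps repeated peptide lines by default, with a `unique` switch to
collapse them — and 1 per accession in protein mode, with abundances
carried separately.

**Case-study enzyme lookup.** The bundled 32-enzyme reference table keeps
`2.8.3.-`, `2.8.3.1`, `2.8.3.8` and `2.8.3.12` as distinct enzymes, so the
case-study runner joins reference ECs to item annotations by exact string
equality (a partial EC matches only an identical partial annotation). Were
it wildcard-aware, one CoA-transferase peptide would feed four reference
rows at once and the concordance bookkeeping would double-count.

## Differential abundance

For two groups with totals $P_1$ and $P_2$ (summed peptide multiplicities,
or summed protein abundances, per the active mode) and per-node matched
quantities $X$ and $Y$:

* peptide mode: $DA = Y/P_2 - X/P_1$, bounded in $[-1, 1]$;
* protein mode: $DA = \log_2\big((Y/P_2)\,/\,(X/P_1)\big)$, computed on
  abundance sums.

Dividing by the group totals prevents bias toward the larger group. The
sign convention follows the formulas as printed: positive means
proportionally more signal in the *second* group. (Prose descriptions of
the peptide formula sometimes state the opposite orientation; the formula
is authoritative here and the accessors document the convention.)

Protein mode adds a pseudocount (default 0) to $X$ and $Y$ before the
ratio. With the default, zero numerators yield explicit sentinels —
$+\infty$ when only group 2 has abundance, $-\infty$ when only group 1
has, undefined when neither does — rather than silently clamped values, so
zero-abundance nodes saturate the colour scale instead of disappearing.
Sentinels serialize as `+inf` / `-inf` / `NA` in exports.

## Diverging normalization

Colour ranges driven by the raw minimum and maximum mislead whenever one
side of the critical midpoint dwarfs the other. `normalizeDiverging`
therefore rescales each side independently — positive deviations by the
maximum positive deviation, negative by the maximum negative — joining two
sequential scales at the midpoint (0 for both DA modes). Infinite
sentinels pin to ±1 and are excluded from scale estimation. Normalization
scope is the selected pathway's node set: the set of values shown together
in one view defines its own scale.

## Ranking, filtering, taxonomy

Pathways are ranked by aggregate match count, descending, ties broken by
map id; zero-match pathways stay at the tail so the exported ordered list
covers every loaded pathway. Filters conjoin: a case-insensitive substring
over category, id and name; required ECs; required compounds — the content
filters test what the pathway *contains*, not what the user matched, and
only options leading to at least one result are offered. A node's taxonomy
summary is the lowest common ancestor of the taxon ids of all items
matching that node, absent when no matched item carries a taxon.

## Synthetic data: what it emulates and what it does not

The generators make every stage testable offline and define the conditions
under which the pipeline's statistical behaviour is checked:

* `generatePathway(nEnzymes, nCompounds, seed)` emits an alternating
  compound–enzyme chain with synthetic ECs in class 9 (unused by real
  enzymes, so synthetic annotations cannot collide with genuine ones),
  grid geometry, and matching link-table rows. One reaction joins each
  enzyme's flanking compounds, giving one compound-to-compound reaction
  edge per enzyme.
* `generateSamples(nPerSample, effects, seed, ...)` draws peptides
  i.i.d. from disjoint EC-labelled pools of unique random 8–12-mers over
  the canonical alphabet; remaining probability mass produces unannotated
  background. A planted effect multiplies one EC's group-2 rate by an
  enrichment factor, after which the probability vector renormalizes.

Default study conditions for the recovery checks: baseline draw rate 0.1
for the target EC, enrichment factor 3, 1000 peptides per group, 100
seeded replicates (null calibration: factor 1, 200 replicates). At those
sizes the target node's expected peptide-mode DA under enrichment is
$0.3/1.2 - 0.1 = 0.15$ with a per-replicate standard deviation near 0.013,
so sign recovery is expected in essentially all replicates and the null
mean sits well inside ±0.02.

What the generator does **not** emulate: real spectral properties, shared
peptides between taxa or functions, database incompleteness, I/L ambiguity
(the fixture resolver can equate I and L on request, off by default), or
correlated abundances across enzymes of one pathway. Passing the recovery
checks therefore demonstrates that the mapping and contrast machinery is
correct and well-calibrated under clean sampling — not that any particular
real dataset will separate.

## Numerical and design choices

* **Parsing is total.** Upload validation never aborts early; every
  malformed line is reported with its 1-based number and a reason, so a
  bad last line is caught before any work starts. Blank lines skip
  silently; a single protein-table header is auto-detected (first line
  whose second field is non-numeric and whose first field is not
  accession-shaped).
* **Group designs.** Exactly 1 or 2 groups; the DA view requires 2 and
  refuses otherwise (the presence view stays available). Group order
  follows first occurrence across the sample list: the first group is
  "group 1" of the formulas.
* **Tie-breaks.** Ranking ties break by map id ascending; CSV ordering is
  byte-order (C locale) radix sort, making re-exports byte-identical.
* **Degenerate inputs.** Empty files parse to empty entry sets; an EC
  absent from a link table or node index returns an empty set; a pathway
  whose values all equal the midpoint normalizes to all zeros; nodes
  without geometry render nothing but warn.
* **Resolver contract.** Batches of at most `batchSize` items; one record
  per item found; unannotated items absent (counted, not errors); results
  independent of batch size; memoization per analysis session only, keyed
  by (mode, item), with no on-disk cache to avoid staleness. The JSON wire
  contract mirrored by the offline table resolver is
  `{"peptides": [...]}` or `{"proteins": [...]}` in, and per-item records
  with EC and taxon fields out; only the table-backed implementation
  ships.
* **Overlay.** The SVG is a standalone overlay on a white canvas sized to
  the pathway's bounding box (no raster background is fetched); KGML
  centre coordinates convert to top-left corners at render time. The
  diverging colormap is blue–white–red (`#2166AC`/`#FFFFFF`/`#B2182B`),
  conventional for fold-change displays; the DA view adds a linear
  gradient legend.

## Problem sizes used by the checks

The shipped checks run the formula oracles on 200 random tuples plus an
exhaustive small-integer grid, the closure oracle on 500 random instances
(≤10 items, ≤5 ECs, ≤3 pathways), the recovery study at 100 enrichment
and 200 null replicates of 1000 peptides per group, and the normalization
contract on 200 randomized value sets. These sizes were chosen so the
whole battery completes in about a minute while keeping the Monte-Carlo
standard errors an order of magnitude below the asserted tolerances.

## Known limitations

* Only metabolic-pathway EC annotation is supported — no GO or InterPro.
* At most two groups; no longitudinal designs.
* No significance testing of DA values; the contrast is descriptive, as
  defined.
* KO-only nodes (no EC) are never matched, since EC is the only join key.
* The live annotation service and pathway image proxy are out of scope;
  the resolver contract is satisfied by the offline table implementation.
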