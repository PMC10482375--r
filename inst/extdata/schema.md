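# File dialects

All tables are UTF-8, tab-separated, with a header line; lines starting
with `#` are comments. All coordinates are 0-based half-open (BED
convention). Converters from 1-based inclusive (GFF-like) dialects must
subtract 1 from start coordinates at the boundary.

## Hit table (`read_hits()`)

Long format: one row per gene, rows grouped by `hit_id`. A hit (one
detected defence system or BGC) must keep `genome_id`, `replicon_id` and
`system_type` constant across its rows.

| column      | type   | notes                                             |
|-------------|--------|---------------------------------------------------|
| hit_id      | string | unique per detected system/BGC                    |
| genome_id   | string | must exist in the metadata                        |
| replicon_id | string | must exist in the metadata                        |
| system_type | string | e.g. `RM`, `Wadjet`, or an antiSMASH class        |
| gene_start  | int    | 0-based inclusive                                 |
| gene_end    | int    | 0-based exclusive; `start < end <= replicon length` |
| strand      | `+`/`-`| carried, ignored by all statistics                |
| gene_gc     | real   | GC fraction of the gene, in \[0, 1\]              |
| subtype     | string | optional                                          |
| gene_index  | int    | optional CDS ordinal; required for island calls   |

The hit's `category` (`defence` or `bgc`) is supplied by the reader
argument, not a column.

## Replicon metadata (`read_replicon_metadata()`)

One row per replicon; a genome's taxonomy is repeated on each of its
replicons.

| column       | type   | notes                              |
|--------------|--------|------------------------------------|
| genome_id    | string |                                    |
| phylum       | string |                                    |
| genus        | string |                                    |
| species      | string |                                    |
| replicon_id  | string | unique within the cohort           |
| replicon_type| enum   | `chromosome` / `plasmid`           |
| topology     | enum   | `linear` / `circular`              |
| length       | int    | bp, > 0                            |
| gc           | real   | fraction in \[0, 1\]               |

## Prophage intervals (`read_intervals()`)

BED-style, no header: `replicon_id`, `start`, `end` (0-based half-open);
extra columns ignored. Intervals are merged per replicon on read.

## Trees (`read_tree()`)

Newick with branch lengths; leaf labels are `genome_id`s and must be
unique; branch lengths must be non-negative.
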