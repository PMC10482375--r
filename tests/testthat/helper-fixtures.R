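# Shared fixture builders: tiny hand-written tables and small synthetic
# cohorts used across the module tests.

# One-replicon metadata row.
meta_row <- function(genome_id = "g1", replicon_id = "g1_chr",
                     replicon_type = "chromosome", topology = "linear",
                     length = 1e6, gc = 0.6, genus = "GenusA",
                     phylum = "Actinobacteria") {
  tibble::tibble(
    genome_id = genome_id, phylum = phylum, genus = genus,
    species = paste0(genus, "_sp"), replicon_id = replicon_id,
    replicon_type = replicon_type, topology = topology,
    length = length, gc = gc
  )
}

# A hit with genes given as a list of c(start, end) pairs.
make_hit <- function(hit_id, genes, genome_id = "g1", replicon_id = "g1_chr",
                     system_type = "RM", category = "defence", gc = 0.6,
                     gene_index = NA_integer_) {
  tibble::tibble(
    hit_id = hit_id, genome_id = genome_id, replicon_id = replicon_id,
    category = category, system_type = system_type, subtype = NA_character_,
    gene_start = vapply(genes, `[`, numeric(1), 1),
    gene_end = vapply(genes, `[`, numeric(1), 2),
    strand = "+", gene_gc = gc,
    gene_index = if (length(gene_index) == 1 && is.na(gene_index)) {
      NA_integer_
    } else {
      as.integer(gene_index)
    }
  )
}

# Prophage interval table on the default chromosome.
pp <- function(...) {
  iv <- list(...)
  tibble::tibble(
    replicon_id = "g1_chr",
    start = vapply(iv, `[`, numeric(1), 1),
    end = vapply(iv, `[`, numeric(1), 2)
  )
}

# Per-base brute-force overlap oracle on small replicons: bp of [qs, qe)
# covered by the union of intervals (possibly overlapping).
overlap_oracle <- function(qs, qe, starts, ends, repl_len) {
  covered <- logical(repl_len)
  for (i in seq_along(starts)) {
    if (ends[i] > starts[i]) covered[(starts[i] + 1):ends[i]] <- TRUE
  }
  if (qe <= qs) {
    return(0L)
  }
  sum(covered[(qs + 1):qe])
}

write_lines_tmp <- function(lines, ext = ".tsv") {
  path <- tempfile(fileext = ext)
  writeLines(lines, path)
  path
}
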