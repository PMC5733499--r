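# Small in-code fixtures shared across test files.

# A fixed 3-record library with hand-written guides (pairwise Hamming >= 3).
tiny_library <- function(backbone = default_backbone()) {
  shrna_library(data.frame(
    shrna_id = c("s1", "s2", "s3"),
    gene_symbol = c("GENEA", "GENEA", "GENEB"),
    guide_sequence = c("ACGTACGTACGTACGTACGTAC",
                       "TTGCAGGTCCATAAGGCTAGCA",
                       "GGATCCTTAGACGTTCACGGTA"),
    stringsAsFactors = FALSE
  ), backbone = backbone)
}

# A hairpin read for record `i`: window of the expressed transcript fully
# covering the sense guide, with `left` scaffold bases upstream and `right`
# downstream.
hairpin_read <- function(lib, i, left = 15L, right = 15L) {
  ref <- lib$expressed_refs[i]
  f5 <- nchar(lib$backbone$flank5)
  glen <- nchar(lib$records$guide_sequence[i])
  substr(ref, f5 + 1L - left, f5 + glen + right)
}

# Long-format per-cell calls from an in-memory simulate_sc_reads() result.
call_cells_from_memory <- function(sim, ...) {
  rows <- lapply(names(sim$cells), function(cid) {
    cnt <- call_shrna_reads(sim$cells[[cid]], sim$lib, ...)$counts
    nz <- which(cnt > 0L)
    if (!length(nz)) return(NULL)
    data.frame(cell_id = cid, shrna_id = names(cnt)[nz],
               reads = unname(cnt[nz]), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) out <- data.frame(cell_id = character(0),
                                      shrna_id = character(0),
                                      reads = integer(0))
  out
}

write_tsv_lines <- function(lines, path) {
  writeLines(lines, path)
  path
}
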