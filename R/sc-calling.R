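# Single-cell shRNA calling: identify which hairpin(s) each cell carries
# from its transcriptome reads. A read supports an shRNA only when its guide
# match extends contiguously into the miR-E scaffold backbone -- this is
# what separates vector-derived hairpin transcripts from the endogenous
# mRNA of the target gene, which contains the guide-complementary sequence
# but no scaffold.

#' Call shRNA-supporting reads for one cell
#'
#' A read supports shRNA `s` iff, on either strand, it contains `s`'s guide
#' with at most `max_mismatch` mismatches and the alignment extends
#' contiguously into the scaffold (flank5, or loop/flank3; either hairpin
#' arm) by at least `min_backbone_overlap` exactly matching bases. Reads
#' matching a guide without backbone support (endogenous-transcript mimics)
#' are never counted; reads supporting several distinct shRNAs are discarded
#' as ambiguous.
#'
#' @param cell_reads Read data frame (from [read_fastq()]) or character
#'   vector of sequences for one cell.
#' @param lib A [shrna_library()].
#' @param backbone Scaffold; defaults to the library's backbone.
#' @param min_backbone_overlap Minimum exactly matching scaffold bases
#'   (default 8).
#' @param max_mismatch Mismatches tolerated over the guide (default 1).
#' @return List: `counts` (named integer vector over library shRNAs),
#'   `total_reads`, `ambiguous`, `unmatched_hairpin` (guide matches rejected
#'   for lack of backbone support).
#' @export
call_shrna_reads <- function(cell_reads, lib, backbone = lib$backbone,
                             min_backbone_overlap = 8L, max_mismatch = 1L) {
  stopifnot(inherits(lib, "shrna_library"))
  if (min_backbone_overlap < 1L) stop("min_backbone_overlap must be >= 1")
  if (!identical(backbone, lib$backbone)) {
    lib <- shrna_library(lib$records, backbone = backbone, k = lib$k)
  }
  seqs <- if (is.data.frame(cell_reads)) cell_reads$seq else cell_reads
  ids <- lib$records$shrna_id
  counts <- stats::setNames(integer(length(ids)), ids)
  if (!length(seqs)) {
    return(list(counts = counts, total_reads = 0L, ambiguous = 0L,
                unmatched_hairpin = 0L))
  }
  anch <- .match_reads(seqs, lib, max_mismatch = max_mismatch,
                       orient = "both", anchor = TRUE,
                       min_backbone_overlap = min_backbone_overlap)
  bare <- .match_reads(seqs, lib, max_mismatch = max_mismatch,
                       orient = "both", anchor = FALSE)
  tab <- table(factor(anch$assign, levels = seq_along(ids)))
  counts[] <- as.integer(tab)
  matched_anch <- !is.na(anch$assign) | anch$ambiguous
  matched_bare <- !is.na(bare$assign) | bare$ambiguous
  list(counts = counts,
       total_reads = length(seqs),
       ambiguous = sum(anch$ambiguous),
       unmatched_hairpin = sum(matched_bare & !matched_anch))
}

#' Call shRNA reads for every cell in a manifest
#'
#' Runs [call_shrna_reads()] over each cell's FASTQ.
#'
#' @param manifest Data frame from [read_manifest()] (columns `cell_id`,
#'   `fastq_path`, optional `condition`).
#' @inheritParams call_shrna_reads
#' @return Object of class `cell_shrna_counts`: long-format
#'   `data.frame(cell_id, shrna_id, reads)` of nonzero counts, with per-cell
#'   totals, unmatched-hairpin counts and conditions as attributes.
#' @export
call_cells <- function(manifest, lib, backbone = lib$backbone,
                       min_backbone_overlap = 8L, max_mismatch = 1L) {
  rows <- vector("list", nrow(manifest))
  totals <- integer(nrow(manifest))
  unmatched <- integer(nrow(manifest))
  for (i in seq_len(nrow(manifest))) {
    reads <- read_fastq(manifest$fastq_path[i])
    cc <- call_shrna_reads(reads, lib, backbone,
                           min_backbone_overlap, max_mismatch)
    totals[i] <- cc$total_reads
    unmatched[i] <- cc$unmatched_hairpin
    nz <- which(cc$counts > 0L)
    if (length(nz)) {
      rows[[i]] <- data.frame(cell_id = manifest$cell_id[i],
                              shrna_id = names(cc$counts)[nz],
                              reads = unname(cc$counts[nz]),
                              stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(cell_id = character(0), shrna_id = character(0),
                      reads = integer(0))
  }
  structure(out,
            cells = manifest$cell_id,
            condition = stats::setNames(manifest$condition,
                                        manifest$cell_id),
            total_reads = stats::setNames(totals, manifest$cell_id),
            unmatched_hairpin = stats::setNames(unmatched,
                                                manifest$cell_id),
            class = c("cell_shrna_counts", "data.frame"))
}

#' Assign cells to shRNAs by read-count cutoff
#'
#' Per cell, every shRNA whose supporting read count reaches `min_reads` is
#' assigned. The default `min_reads = 11` encodes the ">10 shRNA reads"
#' cutoff. Status is `none` (no shRNA reaches the cutoff), `single`
#' (exactly one) or `multiple`.
#'
#' @param counts A `cell_shrna_counts` object from [call_cells()], or a long
#'   `data.frame(cell_id, shrna_id, reads)`.
#' @param min_reads Minimum supporting reads for assignment (default 11,
#'   i.e. strictly more than 10).
#' @param cells Optional character vector of all cell ids (so cells without
#'   any counted read still appear with status `none`); defaults to the
#'   `cells` attribute of `counts`.
#' @return Data frame: `cell_id`, `status`, `shrna_ids` (comma-separated),
#'   `reads` (comma-separated, matching order), `threshold`.
#' @export
assign_cells <- function(counts, min_reads = 11L, cells = NULL) {
  if (is.null(cells)) cells <- attr(counts, "cells")
  if (is.null(cells)) cells <- unique(counts$cell_id)
  df <- as.data.frame(counts)
  df <- df[df$reads >= min_reads, , drop = FALSE]
  sp <- split(df, factor(df$cell_id, levels = cells))
  out <- do.call(rbind, lapply(cells, function(cid) {
    d <- sp[[cid]]
    n <- if (is.null(d)) 0L else nrow(d)
    status <- if (n == 0L) "none" else if (n == 1L) "single" else "multiple"
    ord <- if (n) order(-d$reads) else integer(0)
    data.frame(cell_id = cid, status = status,
               shrna_ids = if (n) paste(d$shrna_id[ord], collapse = ",")
                           else "",
               reads = if (n) paste(d$reads[ord], collapse = ",") else "",
               threshold = min_reads, stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Summarize assignment structure across cells
#'
#' @param assignments Data frame from [assign_cells()].
#' @return List: `multiplicity` (named integer vector: number of cells with
#'   0, 1, 2, ... assigned shRNAs), `per_shrna_cells` (named integer vector:
#'   cells in which each detected shRNA occurs), `fraction_detected`
#'   (fraction of cells with >= 1 assigned shRNA), `n_cells`.
#' @export
occurrence_summary <- function(assignments) {
  if (!nrow(assignments)) stop("no assignments")
  idlists <- strsplit(assignments$shrna_ids, ",", fixed = TRUE)
  idlists <- lapply(idlists, function(x) x[nzchar(x)])
  mult <- lengths(idlists)
  hist <- table(factor(mult, levels = 0:max(c(mult, 1L))))
  occ <- table(unlist(idlists, use.names = FALSE))
  occ <- stats::setNames(as.integer(occ), names(occ))
  list(multiplicity = stats::setNames(as.integer(hist), names(hist)),
       per_shrna_cells = occ,
       fraction_detected = mean(mult >= 1L),
       n_cells = nrow(assignments))
}

#' Check never-transduced control cells
#'
#' Runs the hairpin caller over control cells that were never exposed to
#' shRNA vectors and flags any control cell with a nonzero shRNA-supporting
#' read count. Because calling requires backbone-anchored matches, reads
#' from endogenous target-gene transcripts (guide sequence without scaffold)
#' do not trigger flags.
#'
#' @param control_reads Named list of per-cell read sets (data frames or
#'   sequence vectors), or a manifest data frame for [call_cells()].
#' @inheritParams call_shrna_reads
#' @return Data frame: `cell_id`, `shrna_reads` (total supporting reads),
#'   `flagged`.
#' @export
negative_control_check <- function(control_reads, lib,
                                   backbone = lib$backbone,
                                   min_backbone_overlap = 8L,
                                   max_mismatch = 1L) {
  if (is.data.frame(control_reads) && "fastq_path" %in% names(control_reads)) {
    cc <- call_cells(control_reads, lib, backbone,
                     min_backbone_overlap, max_mismatch)
    tot <- tapply(cc$reads, factor(cc$cell_id,
                                   levels = attr(cc, "cells")), sum)
    tot[is.na(tot)] <- 0L
    cells <- attr(cc, "cells")
  } else {
    cells <- names(control_reads)
    if (is.null(cells)) cells <- paste0("control_", seq_along(control_reads))
    tot <- vapply(control_reads, function(r) {
      sum(call_shrna_reads(r, lib, backbone, min_backbone_overlap,
                           max_mismatch)$counts)
    }, numeric(1))
  }
  data.frame(cell_id = cells, shrna_reads = as.integer(tot),
             flagged = as.integer(tot) > 0L, stringsAsFactors = FALSE)
}
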