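# Seed-and-extend matching of reads against the guide set of a
# shrna_library. Shared by screen amplicon counting (reads are reverse
# complemented, then the sense guide is located) and by single-cell hairpin
# calling (both read strands are searched and matches must extend into the
# scaffold backbone).

# Locate candidate guide placements in oriented read strings via exact
# k-mer seeds. Returns a data.frame(read, rec, start) with `start` the
# 1-based guide start in the oriented string; full guide must fit.
.find_guide_candidates <- function(strs, lib) {
  k <- lib$k
  idx <- lib$seed_index
  glen <- nchar(lib$records$guide_sequence)
  lens <- nchar(strs)
  maxoff <- max(lens) - k + 1L
  if (is.na(maxoff) || maxoff < 1L) {
    return(data.frame(read = integer(0), rec = integer(0), start = integer(0)))
  }
  reads <- integer(0); keys <- integer(0); offs <- integer(0)
  for (o in seq_len(maxoff)) {
    live <- which(lens >= o + k - 1L)
    if (!length(live)) next
    km <- substring(strs[live], o, o + k - 1L)
    m <- match(km, idx$keys)
    hit <- which(!is.na(m))
    if (length(hit)) {
      reads <- c(reads, live[hit])
      keys <- c(keys, m[hit])
      offs <- c(offs, rep.int(o, length(hit)))
    }
  }
  if (!length(reads)) {
    return(data.frame(read = integer(0), rec = integer(0), start = integer(0)))
  }
  rows <- idx$rows[keys]
  nrep <- lengths(rows)
  rowv <- unlist(rows, use.names = FALSE)
  read <- rep.int(reads, nrep)
  off <- rep.int(offs, nrep)
  rec <- idx$rec[rowv]
  start <- off - idx$off[rowv]          # 1-based guide start in read
  ok <- start >= 1L & start + glen[rec] - 1L <= lens[read]
  cand <- data.frame(read = read[ok], rec = rec[ok], start = start[ok])
  unique(cand)
}

# Contiguous exactly-matching run lengths to the left and right of the
# guide placement, comparing the oriented read against a reference string.
# rs/fs: 1-based guide starts in read/reference; glen: guide length.
.contig_runs <- function(strs, refs, rs, fs, glen, max_run = 60L) {
  n <- length(strs)
  left <- integer(n); right <- integer(n)
  rlen <- nchar(strs); flen <- nchar(refs)
  alive <- rep(TRUE, n)
  for (d in seq_len(max_run)) {
    pr <- rs - d; pf <- fs - d
    alive <- alive & pr >= 1L & pf >= 1L
    if (!any(alive)) break
    eq <- alive
    eq[alive] <- substring(strs[alive], pr[alive], pr[alive]) ==
      substring(refs[alive], pf[alive], pf[alive])
    left[eq] <- d
    alive <- eq
  }
  alive <- rep(TRUE, n)
  for (d in seq_len(max_run)) {
    pr <- rs + glen - 1L + d; pf <- fs + glen - 1L + d
    alive <- alive & pr <= rlen & pf <= flen
    if (!any(alive)) break
    eq <- alive
    eq[alive] <- substring(strs[alive], pr[alive], pr[alive]) ==
      substring(refs[alive], pf[alive], pf[alive])
    right[eq] <- d
    alive <- eq
  }
  list(left = left, right = right)
}

# Match reads to guides.
#
# orient:
#   "revcomp" - align the reverse complement of each read (screen amplicons)
#   "both"    - search read and its reverse complement (transcriptome reads)
# anchor: if TRUE, a match is only kept when the alignment extends
#   contiguously into the scaffold (flank5 on the left, or loop/flank3 on
#   the right, on either hairpin arm) by >= min_backbone_overlap exactly
#   matching bases.
#
# Returns list(assign = integer vector, per read: record index or NA;
#              ambiguous = logical vector; mm = best mismatch count or NA).
.match_reads <- function(bodies, lib, max_mismatch = 1L,
                         orient = c("revcomp", "both"),
                         anchor = FALSE, min_backbone_overlap = 8L) {
  orient <- match.arg(orient)
  n <- length(bodies)
  guides <- lib$records$guide_sequence
  glen <- nchar(guides)
  oriented <- if (orient == "revcomp") list(revcomp(bodies))
              else list(bodies, revcomp(bodies))

  cand <- NULL
  for (s in seq_along(oriented)) {
    ci <- .find_guide_candidates(oriented[[s]], lib)
    if (nrow(ci)) {
      ci$strand <- s
      cand <- rbind(cand, ci)
    }
  }
  assign <- rep(NA_integer_, n)
  mmbest <- rep(NA_integer_, n)
  ambiguous <- rep(FALSE, n)
  if (is.null(cand) || !nrow(cand)) {
    return(list(assign = assign, ambiguous = ambiguous, mm = mmbest))
  }

  str <- oriented[[1L]][cand$read]
  if (length(oriented) > 1L) {
    i2 <- cand$strand == 2L
    str[i2] <- oriented[[2L]][cand$read[i2]]
  }
  gl <- glen[cand$rec]
  obs <- substring(str, cand$start, cand$start + gl - 1L)
  mm <- .mismatch_counts(obs, guides[cand$rec])
  keep <- mm <= max_mismatch
  cand <- cand[keep, , drop = FALSE]
  str <- str[keep]; mm <- mm[keep]; gl <- gl[keep]
  if (!nrow(cand)) {
    return(list(assign = assign, ambiguous = ambiguous, mm = mmbest))
  }

  if (anchor) {
    bb <- lib$backbone
    refs <- lib$expressed_refs[cand$rec]
    # sense-arm hypothesis: guide begins after flank5
    fs1 <- rep.int(nchar(bb$flank5) + 1L, nrow(cand))
    r1 <- .contig_runs(str, refs, cand$start, fs1, gl)
    # antisense-arm hypothesis: the guide appears on the reverse complement
    # of the transcript, preceded by revcomp(flank3)
    refs2 <- revcomp(lib$expressed_refs)[cand$rec]
    fs2 <- rep.int(nchar(bb$flank3) + 1L, nrow(cand))
    r2 <- .contig_runs(str, refs2, cand$start, fs2, gl)
    overlap <- pmax(r1$left, r1$right, r2$left, r2$right)
    keep <- overlap >= min_backbone_overlap
    cand <- cand[keep, , drop = FALSE]
    mm <- mm[keep]
    if (!nrow(cand)) {
      return(list(assign = assign, ambiguous = ambiguous, mm = mmbest))
    }
  }

  # resolve per read: unique best-mismatch record wins, ties are ambiguous
  best <- tapply(mm, cand$read, min)
  bread <- as.integer(names(best))
  is_best <- mm == best[match(as.character(cand$read), names(best))]
  brec <- cand$rec[is_best]
  brd <- cand$read[is_best]
  nrec <- tapply(brec, brd, function(r) length(unique(r)))
  one <- names(nrec)[nrec == 1L]
  amb <- names(nrec)[nrec > 1L]
  if (length(one)) {
    first <- !duplicated(brd)
    sel <- first & as.character(brd) %in% one
    assign[brd[sel]] <- brec[sel]
    mmbest[bread] <- as.integer(best)
  }
  if (length(amb)) {
    ai <- as.integer(amb)
    ambiguous[ai] <- TRUE
    assign[ai] <- NA_integer_
  }
  list(assign = assign, ambiguous = ambiguous, mm = mmbest)
}
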