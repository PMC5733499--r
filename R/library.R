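#' Build a searchable shRNA library index
#'
#' Validates the library records, builds the expressed hairpin transcript
#' reference for each shRNA (`flank5 + guide + loop + revcomp(guide) +
#' flank3`) and a k-mer seed index over the sense guides used by the
#' seed-and-extend read matching.
#'
#' @param records Data frame with columns `shrna_id`, `gene_symbol`,
#'   `guide_sequence` and optionally `oligo_97mer`, `library_name`.
#' @param backbone A [mire_backbone()] scaffold.
#' @param k Seed k-mer length (default 12).
#' @return An object of class `shrna_library` with elements `records`,
#'   `backbone`, `expressed_refs` (named character vector), `k` and the seed
#'   index.
#' @export
shrna_library <- function(records, backbone = default_backbone(), k = 12L) {
  stopifnot(is.data.frame(records), inherits(backbone, "mire_backbone"))
  need <- c("shrna_id", "gene_symbol", "guide_sequence")
  miss <- setdiff(need, names(records))
  if (length(miss)) stop("library records lack columns: ",
                         paste(miss, collapse = ", "))
  records <- as.data.frame(records, stringsAsFactors = FALSE)
  if (!"oligo_97mer" %in% names(records)) records$oligo_97mer <- NA_character_
  if (!"library_name" %in% names(records)) records$library_name <- "custom"

  ids <- as.character(records$shrna_id)
  dup <- ids[duplicated(ids)]
  if (length(dup)) stop("duplicate shrna_id: ", dup[1L])
  guides <- toupper(as.character(records$guide_sequence))
  bad <- grep("[^ACGT]", guides)
  if (length(bad)) stop("non-ACGT character in guide_sequence, row ", bad[1L])
  glen <- nchar(guides)
  if (any(glen < 18L | glen > 25L)) {
    stop("guide length outside [18, 25] in row ",
         which(glen < 18L | glen > 25L)[1L])
  }
  if (any(k > glen)) stop("seed k exceeds shortest guide length")
  has97 <- !is.na(records$oligo_97mer)
  if (any(has97)) {
    ol <- toupper(records$oligo_97mer[has97])
    if (any(nchar(ol) != 97L)) {
      stop("oligo_97mer not 97 nt in row ", which(has97)[nchar(ol) != 97L][1L])
    }
    gg <- guides[has97]
    ok <- mapply(function(o, g) {
      grepl(g, o, fixed = TRUE) && grepl(revcomp(g), o, fixed = TRUE)
    }, ol, gg)
    if (!all(ok)) {
      stop("oligo_97mer missing guide or its reverse complement in row ",
           which(has97)[!ok][1L])
    }
    records$oligo_97mer[has97] <- ol
  }
  records$shrna_id <- ids
  records$guide_sequence <- guides

  refs <- paste0(backbone$flank5, guides, backbone$loop, revcomp(guides),
                 backbone$flank3)
  names(refs) <- ids

  lib <- structure(
    list(records = records, backbone = backbone, expressed_refs = refs,
         k = as.integer(k), seed_index = .build_seed_index(guides, k)),
    class = "shrna_library")
  lib
}

# Seed index: for every guide, all k-mers with their 0-based offset in the
# guide. Stored as a named list kmer -> integer matrix (record, offset).
.build_seed_index <- function(guides, k) {
  glen <- nchar(guides)
  nk <- glen - k + 1L
  rec <- rep.int(seq_along(guides), nk)
  off <- unlist(lapply(nk, function(m) 0:(m - 1L)), use.names = FALSE)
  kmer <- substring(guides[rec], off + 1L, off + k)
  keys <- unique(kmer)
  rows <- split(seq_along(kmer), factor(kmer, levels = keys))
  list(keys = keys, rows = rows, rec = rec, off = off)
}

#' Parse an shRNA library table
#'
#' Tab-separated, UTF-8, header row with columns `shrna_id`, `gene_symbol`,
#' `guide_sequence` and optionally `oligo_97mer`; lines starting with `#`
#' are ignored. Row order is preserved (records are indexed in file order).
#'
#' @param path Path to the TSV file.
#' @inheritParams shrna_library
#' @return A `shrna_library` index.
#' @export
parse_library_table <- function(path, backbone = default_backbone(), k = 12L) {
  if (!file.exists(path)) stop("library table not found: ", path)
  df <- utils::read.delim(path, header = TRUE, comment.char = "#",
                          stringsAsFactors = FALSE, colClasses = "character")
  shrna_library(df, backbone = backbone, k = k)
}

#' Write an shRNA library table
#'
#' @param lib A `shrna_library` or its `records` data frame.
#' @param path Output TSV path.
#' @export
write_library_table <- function(lib, path) {
  df <- if (inherits(lib, "shrna_library")) lib$records else lib
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Expressed hairpin transcript reference for one record
#'
#' `flank5 + guide + loop + revcomp(guide) + flank3`: the transcript model
#' against which both screen amplicons and poly-A-primed transcriptome reads
#' are matched.
#'
#' @param record One-row data frame (or list) with a `guide_sequence` field.
#' @param backbone A [mire_backbone()].
#' @return Character scalar.
#' @export
build_expressed_reference <- function(record, backbone = default_backbone()) {
  g <- toupper(record$guide_sequence)
  if (length(g) != 1L || grepl("[^ACGT]", g)) stop("invalid guide_sequence")
  paste0(backbone$flank5, g, backbone$loop, revcomp(g), backbone$flank3)
}

#' Extract the sense guide from a 97-mer library oligo
#'
#' The 97-mer oligos used for hairpin cloning contain
#' `context5 + guide + loop + revcomp(guide) + context3`. Given the loop,
#' the guide is recovered as the maximal reverse-complement palindrome around
#' the loop: the longest `L` in `[18, 25]` such that the `L` bases ending at
#' the loop equal the reverse complement of the `L` bases following it.
#'
#' @param oligo_97mer 97-nt oligo sequence.
#' @param backbone A [mire_backbone()]; only the loop is used.
#' @param guide_length Optional known guide length; skips the palindrome
#'   search.
#' @return The sense guide sequence.
#' @export
extract_guide_from_97mer <- function(oligo_97mer, backbone = default_backbone(),
                                     guide_length = NULL) {
  o <- toupper(oligo_97mer)
  if (nchar(o) != 97L) stop("oligo must be 97 nt, got ", nchar(o))
  loop <- backbone$loop
  hits <- gregexpr(loop, o, fixed = TRUE)[[1L]]
  if (hits[1L] == -1L || length(hits) != 1L) {
    stop("ambiguous hairpin structure: loop absent or not unique in oligo")
  }
  p <- hits[1L]                       # 1-based loop start
  llen <- nchar(loop)
  arm_at <- function(L) {
    if (p - L < 1L || p + llen + L - 1L > 97L) return(FALSE)
    s <- substr(o, p - L, p - 1L)
    a <- substr(o, p + llen, p + llen + L - 1L)
    identical(a, revcomp(s))
  }
  if (!is.null(guide_length)) {
    L <- as.integer(guide_length)
    if (!arm_at(L)) stop("ambiguous hairpin structure: arms do not pair at ",
                         "guide_length ", L)
    return(substr(o, p - L, p - 1L))
  }
  best <- NA_integer_
  for (L in 18:25) if (arm_at(L)) best <- L
  if (is.na(best)) stop("ambiguous hairpin structure: no paired arm of ",
                        "length 18-25 around the loop")
  substr(o, p - best, p - 1L)
}

#' @export
print.shrna_library <- function(x, ...) {
  cat(sprintf("shrna_library: %d shRNAs, %d genes, guide %d-%d nt, seed k=%d\n",
              nrow(x$records), length(unique(x$records$gene_symbol)),
              min(nchar(x$records$guide_sequence)),
              max(nchar(x$records$guide_sequence)), x$k))
  invisible(x)
}

#' @export
length.shrna_library <- function(x) nrow(x$records)
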