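# Shared readers and writers: FASTQ, count tables, matrices (TSV or
# MatrixMarket triplet), GMT gene-set collections, sample sheets and cell
# manifests. All text formats; gzip is handled transparently by extension.

.open_text <- function(path) {
  if (grepl("\\.gz$", path)) gzfile(path, "rt") else file(path, "rt")
}

#' Read a FASTQ file
#'
#' Four-line records; gzip input supported (`.gz` extension). Returns a data
#' frame preserving id (without the leading `@`), sequence and quality so
#' that `write_fastq()` round-trips losslessly.
#'
#' @param path FASTQ path (optionally gzipped).
#' @return `data.frame(id, seq, qual)`.
#' @export
read_fastq <- function(path) {
  if (!file.exists(path)) stop("FASTQ not found: ", path)
  con <- .open_text(path)
  on.exit(close(con))
  lines <- readLines(con, warn = FALSE)
  if (length(lines) %% 4L != 0L) {
    stop("truncated FASTQ record ", length(lines) %/% 4L + 1L, " in ", path)
  }
  n <- length(lines) %/% 4L
  if (n == 0L) {
    return(data.frame(id = character(0), seq = character(0),
                      qual = character(0)))
  }
  hd <- lines[seq(1L, by = 4L, length.out = n)]
  sq <- lines[seq(2L, by = 4L, length.out = n)]
  pl <- lines[seq(3L, by = 4L, length.out = n)]
  qu <- lines[seq(4L, by = 4L, length.out = n)]
  bad <- which(!startsWith(hd, "@") | !startsWith(pl, "+"))
  if (length(bad)) stop("malformed FASTQ record ", bad[1L], " in ", path)
  bad <- which(nchar(sq) != nchar(qu))
  if (length(bad)) stop("sequence/quality length mismatch in record ", bad[1L])
  data.frame(id = sub("^@", "", hd), seq = sq, qual = qu)
}

#' @param reads `data.frame(id, seq, qual)`; a missing `qual` column is
#'   filled with `"I"` per base.
#' @rdname read_fastq
#' @export
write_fastq <- function(reads, path) {
  if (is.null(reads$qual)) {
    reads$qual <- strrep("I", nchar(reads$seq))
  }
  con <- if (grepl("\\.gz$", path)) gzfile(path, "wt") else file(path, "wt")
  on.exit(close(con))
  writeLines(paste0("@", reads$id, "\n", reads$seq, "\n+\n", reads$qual), con)
  invisible(path)
}

#' Read / write a cell-by-gene expression matrix
#'
#' TSV (row names in the first column) or MatrixMarket triplet; for a
#' `foo.mtx` file the row and column names are read from `foo.rownames.txt`
#' and `foo.colnames.txt`. The returned matrix is always oriented cells in
#' rows, genes in columns; `orientation` states how the file is laid out.
#'
#' @param path Matrix path (`.tsv`/`.txt` or `.mtx`).
#' @param orientation `"cells_by_genes"` or `"genes_by_cells"` (file layout).
#' @return Numeric matrix, cells x genes.
#' @export
read_matrix <- function(path, orientation = c("cells_by_genes",
                                              "genes_by_cells")) {
  orientation <- match.arg(orientation)
  if (!file.exists(path)) stop("matrix not found: ", path)
  if (grepl("\\.mtx$", path)) {
    m <- as.matrix(Matrix::readMM(path))
    rn <- readLines(sub("\\.mtx$", ".rownames.txt", path))
    cn <- readLines(sub("\\.mtx$", ".colnames.txt", path))
    if (length(rn) != nrow(m) || length(cn) != ncol(m)) {
      stop("matrix name/dimension mismatch: ", nrow(m), "x", ncol(m),
           " vs ", length(rn), "/", length(cn), " names")
    }
    dimnames(m) <- list(rn, cn)
  } else {
    df <- utils::read.delim(path, header = TRUE, row.names = 1L,
                            check.names = FALSE)
    m <- as.matrix(df)
  }
  if (orientation == "genes_by_cells") m <- t(m)
  m
}

#' @param mat Matrix oriented cells x genes.
#' @rdname read_matrix
#' @export
write_matrix <- function(mat, path, orientation = c("cells_by_genes",
                                                    "genes_by_cells")) {
  orientation <- match.arg(orientation)
  out <- if (orientation == "genes_by_cells") t(mat) else mat
  if (grepl("\\.mtx$", path)) {
    Matrix::writeMM(Matrix::Matrix(out, sparse = TRUE), path)
    writeLines(rownames(out), sub("\\.mtx$", ".rownames.txt", path))
    writeLines(colnames(out), sub("\\.mtx$", ".colnames.txt", path))
  } else {
    df <- data.frame(id = rownames(out), out, check.names = FALSE)
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}

#' Read / write an shRNA count table
#'
#' TSV with `shrna_id` rows and one integer column per sample.
#'
#' @param path TSV path.
#' @return Integer matrix, shRNAs x samples.
#' @export
read_counts_tsv <- function(path) {
  df <- utils::read.delim(path, header = TRUE, row.names = 1L,
                          check.names = FALSE)
  m <- as.matrix(df)
  if (any(m < 0) || any(m != round(m))) {
    stop("count table must contain nonnegative integers")
  }
  storage.mode(m) <- "integer"
  m
}

#' @param counts shRNA x sample integer matrix.
#' @rdname read_counts_tsv
#' @export
write_counts_tsv <- function(counts, path) {
  df <- data.frame(shrna_id = rownames(counts), counts, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a screen sample sheet
#'
#' TSV with columns `sample_id`, `barcode`, `day`, `replicate`, `screen`.
#'
#' @param path TSV path.
#' @return Data frame with those columns (`day` integer).
#' @export
read_sample_sheet <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          colClasses = "character")
  need <- c("sample_id", "barcode", "day", "replicate", "screen")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("sample sheet lacks columns: ",
                         paste(miss, collapse = ", "))
  df$day <- as.integer(df$day)
  df
}

#' Read a single-cell manifest
#'
#' TSV with columns `cell_id`, `fastq_path` and optionally `condition`.
#'
#' @param path TSV path.
#' @param base_dir Directory against which relative `fastq_path` entries are
#'   resolved (defaults to the manifest's directory).
#' @return Data frame with absolute `fastq_path`.
#' @export
read_manifest <- function(path, base_dir = dirname(path)) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          colClasses = "character")
  need <- c("cell_id", "fastq_path")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("manifest lacks columns: ",
                         paste(miss, collapse = ", "))
  if (!"condition" %in% names(df)) df$condition <- "sample"
  rel <- !grepl("^/", df$fastq_path)
  df$fastq_path[rel] <- file.path(base_dir, df$fastq_path[rel])
  df
}

#' Read / write gene-set collections (GMT)
#'
#' Standard GMT: one set per line, `name<TAB>description<TAB>gene1<TAB>...`.
#' Duplicate genes within a set are removed with a warning.
#'
#' @param path GMT path.
#' @return Named list of character vectors; set descriptions in
#'   `attr(,"description")`.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  short <- which(lengths(parts) < 3L)
  if (length(short)) {
    stop("GMT line ", short[1L], " has fewer than 3 fields")
  }
  sets <- lapply(seq_along(parts), function(i) {
    genes <- parts[[i]][-(1:2)]
    genes <- genes[nzchar(genes)]
    if (!length(genes)) stop("GMT line ", i, " has an empty gene list")
    if (anyDuplicated(genes)) {
      warning("duplicate genes in set '", parts[[i]][1L], "' deduplicated")
      genes <- unique(genes)
    }
    genes
  })
  names(sets) <- vapply(parts, `[[`, character(1), 1L)
  attr(sets, "description") <- vapply(parts, `[[`, character(1), 2L)
  sets
}

#' @param sets Named list of character vectors.
#' @rdname read_gmt
#' @export
write_gmt <- function(sets, path) {
  desc <- attr(sets, "description")
  if (is.null(desc)) desc <- rep("na", length(sets))
  lines <- vapply(seq_along(sets), function(i) {
    paste(c(names(sets)[i], desc[i], sets[[i]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}
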