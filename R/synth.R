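# Seeded simulators with planted ground truth for every input type the
# pipeline consumes: shRNA libraries, barcoded screen reads/count tables
# over a time course, per-cell transcriptome reads containing miR-E
# hairpins, and cell x gene matrices with perturbation-specific modules.
# Every simulator is a pure function of its configuration and seed, and
# returns a `truth` record for parameter-recovery testing.

#' Simulate an shRNA library
#'
#' Guides are sampled uniformly over ACGT with a minimum pairwise Hamming
#' distance of 3 enforced by rejection. 97-mer oligos are built as
#' `context5 + guide + loop + revcomp(guide) + context3`, with boundary
#' bases constrained so the hairpin palindrome does not extend past the
#' guide (making guide extraction exact).
#'
#' @param n_shrnas Library size.
#' @param guide_length Guide length in nt (default 22).
#' @param shrnas_per_gene Average shRNAs per target gene (default 6).
#' @param backbone A [mire_backbone()].
#' @param seed RNG seed (mandatory).
#' @param out_dir If given, writes `library.tsv` and `backbone.yaml` there.
#' @return A [shrna_library()] index; the output paths (if any) are attached
#'   as attribute `files`.
#' @export
simulate_library <- function(n_shrnas = 100L, guide_length = 22L,
                             shrnas_per_gene = 6L,
                             backbone = default_backbone(), seed,
                             out_dir = NULL) {
  if (missing(seed)) stop("seed is mandatory")
  llen <- nchar(backbone$loop)
  ctx_total <- 97L - 2L * guide_length - llen
  if (ctx_total < 2L) {
    stop("cannot build 97-mers: guide_length ", guide_length, " with a ",
         llen, " nt loop leaves no oligo context; shorten the guide or loop")
  }
  c5 <- ctx_total %/% 2L
  c3 <- ctx_total - c5
  lib <- .with_seed(seed, {
    guides <- .sample_distant_guides(n_shrnas, guide_length, min_dist = 3L)
    ctx5 <- random_dna(n_shrnas, c5)
    ctx3 <- random_dna(n_shrnas, c3)
    oligo <- paste0(ctx5, guides, backbone$loop, revcomp(guides), ctx3)
    # forbid palindrome extension across the guide boundary and require a
    # unique loop occurrence
    for (i in seq_len(n_shrnas)) {
      tries <- 0L
      repeat {
        ext <- substr(ctx3[i], 1L, 1L) ==
          chartr("ACGT", "TGCA", substr(ctx5[i], c5, c5))
        nloop <- length(gregexpr(backbone$loop, oligo[i],
                                 fixed = TRUE)[[1L]]) -
          (regexpr(backbone$loop, oligo[i], fixed = TRUE) == -1L)
        if (!ext && nloop == 1L) break
        tries <- tries + 1L
        if (tries > 100L) stop("cannot satisfy oligo constraints")
        ctx3[i] <- random_dna(1L, c3)
        oligo[i] <- paste0(ctx5[i], guides[i], backbone$loop,
                           revcomp(guides[i]), ctx3[i])
      }
    }
    ngene <- ceiling(n_shrnas / shrnas_per_gene)
    gene <- sprintf("GENE%04d", rep(seq_len(ngene),
                                    each = shrnas_per_gene)[seq_len(n_shrnas)])
    records <- data.frame(
      shrna_id = sprintf("sh%04d", seq_len(n_shrnas)),
      gene_symbol = gene, guide_sequence = guides, oligo_97mer = oligo,
      library_name = "synthetic", stringsAsFactors = FALSE)
    shrna_library(records, backbone = backbone)
  })
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    f1 <- file.path(out_dir, "library.tsv")
    f2 <- file.path(out_dir, "backbone.yaml")
    write_library_table(lib, f1)
    write_backbone_config(backbone, f2)
    attr(lib, "files") <- c(library = f1, backbone = f2)
  }
  lib
}

# Sample n guides of length L with all pairwise Hamming distances >= min_dist.
.sample_distant_guides <- function(n, L, min_dist = 3L, max_rounds = 50L) {
  guides <- random_dna(n, L)
  for (round in seq_len(max_rounds)) {
    d <- .pairwise_hamming(guides)
    bad <- unique(which(d < min_dist, arr.ind = TRUE)[, 2L])
    if (!length(bad)) return(guides)
    guides[bad] <- random_dna(length(bad), L)
  }
  stop("cannot satisfy pairwise Hamming distance >= ", min_dist,
       " for ", n, " guides of length ", L,
       "; increase guide_length or reduce n_shrnas")
}

# Pairwise Hamming distances via per-base indicator cross-products.
# Diagonal is set to L (self-distances never flag).
.pairwise_hamming <- function(guides) {
  L <- nchar(guides[1L])
  M <- matrix(unlist(strsplit(guides, "", fixed = TRUE), use.names = FALSE),
              ncol = L, byrow = TRUE)
  match_ct <- matrix(0, length(guides), length(guides))
  for (b in c("A", "C", "G", "T")) {
    I <- M == b
    match_ct <- match_ct + tcrossprod(I)
  }
  d <- L - match_ct
  diag(d) <- L
  d
}

.make_barcodes <- function(n, len) {
  bases <- c("A", "C", "G", "T")
  grids <- do.call(expand.grid, rep(list(bases), len))
  all <- apply(grids, 1L, paste, collapse = "")
  if (n > length(all)) stop("too many samples for barcode length ", len)
  all[seq_len(n)]
}

#' Simulate a pooled enrichment screen
#'
#' Per shRNA and sample, counts follow a negative binomial whose mean is a
#' baseline multiplied, for planted enriched shRNAs, by `fold^(day/max_day)`
#' (log-linear enrichment in time). Two independent screen batches with
#' duplicate samples per timepoint by default. `mode = "reads"` additionally
#' emits barcoded amplicon reads (sample barcode + reverse complement of the
#' hairpin context, uniform per-base substitution errors on the read body).
#'
#' @param lib A [shrna_library()]; by default a fresh simulated library of
#'   `n_shrnas` guides.
#' @param n_shrnas Library size when `lib` is not supplied.
#' @param n_enriched Number of planted enriched shRNAs (default 20).
#' @param fold Planted abundance fold gain at the final day (default 6).
#' @param timepoints Sampling days (default `c(0, 37)`).
#' @param n_screens Independent screen batches (default 2).
#' @param n_replicates Samples per timepoint per screen (default 2).
#' @param nb_mean,nb_dispersion Baseline negative-binomial mean (default 300)
#'   and dispersion (default 0.2).
#' @param mode `"counts"` (count table) or `"reads"` (barcoded FASTQ-style
#'   reads).
#' @param barcode_length Sample barcode length (default 3).
#' @param read_length Total read length including barcode (default 50).
#' @param error_rate Per-base substitution rate on read bodies (default
#'   0.01).
#' @param seed RNG seed (mandatory).
#' @param out_dir If given, writes `screen_counts.tsv`, `samples.tsv`,
#'   `truth.json` (and `screen_reads.fq.gz` in reads mode).
#' @return List: `counts` (shRNA x sample), `samples` (sample sheet with
#'   barcodes), `reads` (data frame, reads mode only), `truth`
#'   (`enriched_ids`, `fold`), `lib`.
#' @export
simulate_screen <- function(lib = NULL, n_shrnas = 1000L, n_enriched = 20L,
                            fold = 6, timepoints = c(0L, 37L),
                            n_screens = 2L, n_replicates = 2L,
                            nb_mean = 300, nb_dispersion = 0.2,
                            mode = c("counts", "reads"),
                            barcode_length = 3L, read_length = 50L,
                            error_rate = 0.01, seed, out_dir = NULL) {
  mode <- match.arg(mode)
  if (missing(seed)) stop("seed is mandatory")
  if (length(timepoints) < 2L) stop("need >= 2 timepoints")
  out <- .with_seed(seed, {
    if (is.null(lib)) {
      lib <- simulate_library(n_shrnas, seed = sample.int(2^31 - 1L, 1L))
    }
    n <- length(lib)
    ids <- lib$records$shrna_id
    enriched <- sort(sample.int(n, n_enriched))
    foldvec <- rep(1, n)
    foldvec[enriched] <- fold
    samples <- expand.grid(replicate = seq_len(n_replicates),
                           day = sort(timepoints),
                           screen = seq_len(n_screens))
    samples$sample_id <- sprintf("S%d_d%02d_r%d", samples$screen,
                                 samples$day, samples$replicate)
    samples$barcode <- .make_barcodes(nrow(samples), barcode_length)
    samples <- samples[, c("sample_id", "barcode", "day", "replicate",
                           "screen")]
    dmax <- max(timepoints)
    counts <- vapply(seq_len(nrow(samples)), function(j) {
      mu <- nb_mean * foldvec^(samples$day[j] / dmax)
      as.integer(stats::rnbinom(n, size = 1 / nb_dispersion, mu = mu))
    }, integer(n))
    dimnames(counts) <- list(ids, samples$sample_id)
    reads <- NULL
    if (mode == "reads") {
      reads <- .emit_screen_reads(counts, samples, lib, read_length,
                                  barcode_length, error_rate)
    }
    list(counts = counts, samples = samples, reads = reads,
         truth = list(enriched_ids = ids[enriched], fold = fold),
         lib = lib)
  })
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_library_table(out$lib, file.path(out_dir, "library.tsv"))
    write_backbone_config(out$lib$backbone,
                          file.path(out_dir, "backbone.yaml"))
    write_counts_tsv(out$counts, file.path(out_dir, "screen_counts.tsv"))
    utils::write.table(out$samples, file.path(out_dir, "samples.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    if (!is.null(out$reads)) {
      write_fastq(out$reads, file.path(out_dir, "screen_reads.fq.gz"))
    }
    jsonlite::write_json(out$truth, file.path(out_dir, "truth.json"),
                         auto_unbox = TRUE)
  }
  out
}

.emit_screen_reads <- function(counts, samples, lib, read_length,
                               barcode_length, error_rate) {
  body_len <- read_length - barcode_length
  refs <- lib$expressed_refs
  f5 <- nchar(lib$backbone$flank5)
  glen <- nchar(lib$records$guide_sequence)
  all <- vector("list", nrow(samples))
  for (j in seq_len(nrow(samples))) {
    c_j <- counts[, j]
    rec <- rep.int(seq_along(c_j), c_j)
    gstart <- f5 + 1L
    lo <- pmax(1L, gstart + glen[rec] - body_len)
    hi <- pmin(gstart, nchar(refs[rec]) - body_len + 1L)
    start <- lo + floor(stats::runif(length(rec)) * (hi - lo + 1L))
    window <- substring(refs[rec], start, start + body_len - 1L)
    body <- .mutate_reads(revcomp(window), error_rate)
    all[[j]] <- data.frame(
      id = sprintf("%s_read%06d", samples$sample_id[j], seq_along(rec)),
      seq = paste0(samples$barcode[j], body),
      stringsAsFactors = FALSE)
  }
  reads <- do.call(rbind, all)
  reads <- reads[sample.int(nrow(reads)), , drop = FALSE]
  reads$qual <- strrep("I", nchar(reads$seq))
  rownames(reads) <- NULL
  reads
}

#' Simulate per-cell transcriptome reads with embedded hairpins
#'
#' Each cell is assigned 0 shRNAs with probability `capture_fail`, otherwise
#' `1 + Poisson(extra_lambda)` distinct shRNAs (extra lentiviral
#' integrations). Hairpin reads per assigned shRNA are Poisson with mean
#' `hairpin_rate` scaled by a log-normal per-cell depth factor; each hairpin
#' read is a window of the expressed hairpin transcript fully covering the
#' guide, on a random strand, with uniform substitution errors. Background
#' reads are random sequence; optional decoy reads carry a guide without any
#' scaffold (endogenous-transcript mimics). Control cells (never exposed to
#' hairpin vectors) contain only background (and decoys, if requested).
#'
#' @param lib A [shrna_library()]; default a fresh simulated 100-guide
#'   library.
#' @param n_cells Number of transduced cells (default 300).
#' @param capture_fail Probability a cell carries no detectable shRNA
#'   (default 0.18).
#' @param extra_lambda Poisson mean of extra integrations (default 0.15).
#' @param hairpin_rate Mean hairpin reads per assigned shRNA at unit depth
#'   (default 30).
#' @param depth_sdlog Log-normal sd of the per-cell depth factor (default
#'   0.3).
#' @param n_background Background reads per cell (default 200).
#' @param n_decoys Decoy (guide-without-scaffold) reads per cell (default 0).
#' @param n_controls Never-transduced control cells (default 0).
#' @param read_length Read length (default 60).
#' @param error_rate Per-base substitution rate (default 0.01).
#' @param seed RNG seed (mandatory).
#' @param out_dir If given, writes `cells/<cell>.fq`, `manifest.tsv`,
#'   `truth.json`.
#' @return List: `cells` (named list of read data frames), `manifest`,
#'   `truth` (per-cell `assigned` list, `planted_reads` list, `condition`).
#' @export
simulate_sc_reads <- function(lib = NULL, n_cells = 300L,
                              capture_fail = 0.18, extra_lambda = 0.15,
                              hairpin_rate = 30, depth_sdlog = 0.3,
                              n_background = 200L, n_decoys = 0L,
                              n_controls = 0L, read_length = 60L,
                              error_rate = 0.01, seed, out_dir = NULL) {
  if (missing(seed)) stop("seed is mandatory")
  out <- .with_seed(seed, {
    if (is.null(lib)) {
      lib <- simulate_library(100L, seed = sample.int(2^31 - 1L, 1L))
    }
    ids <- lib$records$shrna_id
    refs <- lib$expressed_refs
    f5 <- nchar(lib$backbone$flank5)
    glen <- nchar(lib$records$guide_sequence)
    cond <- c(rep("transduced", n_cells), rep("control", n_controls))
    cell_id <- sprintf("%s_%03d", ifelse(cond == "control", "CTRL", "CELL"),
                       c(seq_len(n_cells),
                         if (n_controls) seq_len(n_controls) else integer(0)))
    assigned <- vector("list", length(cell_id))
    planted <- vector("list", length(cell_id))
    cells <- vector("list", length(cell_id))
    names(cells) <- cell_id
    depth <- stats::rlnorm(length(cell_id), 0, depth_sdlog)
    for (i in seq_along(cell_id)) {
      reads <- character(0)
      if (cond[i] == "transduced" &&
          stats::runif(1) >= capture_fail) {
        m <- 1L + stats::rpois(1L, extra_lambda)
        m <- min(m, length(ids))
        recs <- sample.int(length(ids), m)
        assigned[[i]] <- ids[recs]
        nr <- stats::rpois(m, hairpin_rate * depth[i])
        planted[[i]] <- stats::setNames(nr, ids[recs])
        for (j in seq_len(m)) {
          if (nr[j] == 0L) next
          gstart <- f5 + 1L
          lo <- max(1L, gstart + glen[recs[j]] - read_length)
          hi <- min(gstart, nchar(refs[recs[j]]) - read_length + 1L)
          start <- lo + floor(stats::runif(nr[j]) * (hi - lo + 1L))
          w <- substring(refs[recs[j]], start, start + read_length - 1L)
          flip <- stats::runif(nr[j]) < 0.5
          w[flip] <- revcomp(w[flip])
          reads <- c(reads, .mutate_reads(w, error_rate))
        }
      } else {
        assigned[[i]] <- character(0)
        planted[[i]] <- stats::setNames(integer(0), character(0))
      }
      if (n_decoys > 0L) {
        drec <- sample.int(length(ids), n_decoys, replace = TRUE)
        g <- lib$records$guide_sequence[drec]
        pad <- read_length - nchar(g)
        left <- floor(stats::runif(n_decoys) * (pad + 1L))
        decoy <- paste0(random_dna(n_decoys, left), g,
                        random_dna(n_decoys, pad - left))
        reads <- c(reads, .mutate_reads(decoy, error_rate))
      }
      nb <- stats::rpois(1L, n_background * depth[i])
      reads <- c(reads, random_dna(nb, read_length))
      reads <- reads[sample.int(length(reads))]
      cells[[i]] <- data.frame(
        id = sprintf("%s_r%05d", cell_id[i], seq_along(reads)),
        seq = reads, qual = strrep("I", read_length),
        stringsAsFactors = FALSE)
    }
    manifest <- data.frame(cell_id = cell_id,
                           fastq_path = file.path("cells",
                                                  paste0(cell_id, ".fq")),
                           condition = cond, stringsAsFactors = FALSE)
    list(cells = cells, manifest = manifest, lib = lib,
         truth = list(assigned = stats::setNames(assigned, cell_id),
                      planted_reads = stats::setNames(planted, cell_id),
                      condition = stats::setNames(cond, cell_id),
                      depth = stats::setNames(depth, cell_id)))
  })
  if (!is.null(out_dir)) {
    dir.create(file.path(out_dir, "cells"), recursive = TRUE,
               showWarnings = FALSE)
    write_library_table(out$lib, file.path(out_dir, "library.tsv"))
    write_backbone_config(out$lib$backbone,
                          file.path(out_dir, "backbone.yaml"))
    for (cid in names(out$cells)) {
      write_fastq(out$cells[[cid]],
                  file.path(out_dir, "cells", paste0(cid, ".fq")))
    }
    utils::write.table(out$manifest, file.path(out_dir, "manifest.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    jsonlite::write_json(
      list(assigned = out$truth$assigned,
           condition = as.list(out$truth$condition)),
      file.path(out_dir, "truth.json"), auto_unbox = FALSE)
  }
  out
}

#' Simulate a cell-by-gene matrix with perturbation-specific modules
#'
#' Counts are negative binomial per gene with group-specific mean shifts:
#' each group up-shifts its own module of genes by `module_fold`, and (if
#' `knockdown_fold` is set) down-shifts one designated target gene,
#' emulating perturbation signatures layered over shared noise. Dropout is
#' applied as depth-dependent zero inflation (low expected counts are the
#' most likely to drop).
#'
#' @param n_genes Number of genes (default 2000).
#' @param n_groups Number of perturbation groups (default 5).
#' @param cells_per_group Cells per group (default 40).
#' @param module_size Marker genes per group module (default 30).
#' @param module_fold Fold up-shift of module genes (default 2).
#' @param nb_dispersion NB dispersion (default 0.4).
#' @param base_meanlog,base_sdlog Log-normal parameters of gene baseline
#'   means (defaults log(5) and 1).
#' @param depth_sdlog Per-cell depth factor log-sd (default 0.3).
#' @param dropout_rate Maximal zero-inflation probability (default 0.3);
#'   the realized probability is `dropout_rate * exp(-mu / dropout_scale)`.
#' @param dropout_scale Mean scale of the dropout decay (default 10).
#' @param knockdown_fold If set (e.g. 4), each group's designated target
#'   gene is down-shifted by this fold.
#' @param n_empty_cells All-zero cells appended for QC testing (default 0).
#' @param seed RNG seed (mandatory).
#' @param out_dir If given, writes `matrix.tsv`, `annotations.tsv`,
#'   `modules.gmt`, `truth.json`.
#' @return List: `counts` (cells x genes), `annotations` (`cell_id`,
#'   `group`), `modules` (named list, GMT-ready), `truth` (`group`,
#'   `modules`, `target_genes`).
#' @export
simulate_expression <- function(n_genes = 2000L, n_groups = 5L,
                                cells_per_group = 40L, module_size = 30L,
                                module_fold = 2, nb_dispersion = 0.4,
                                base_meanlog = log(5), base_sdlog = 1,
                                depth_sdlog = 0.3, dropout_rate = 0.3,
                                dropout_scale = 10, knockdown_fold = NULL,
                                n_empty_cells = 0L, seed, out_dir = NULL) {
  if (missing(seed)) stop("seed is mandatory")
  if (n_groups < 2L) stop("need >= 2 groups")
  out <- .with_seed(seed, {
    genes <- sprintf("G%05d", seq_len(n_genes))
    mu0 <- stats::rlnorm(n_genes, base_meanlog, base_sdlog)
    # marker modules are planted in robustly detected genes, as the marker
    # panels of real perturbation heat maps are
    expressed <- which(mu0 >= 10)
    if (length(expressed) < n_groups * (module_size + 1L)) {
      stop("not enough well-expressed genes for the requested modules")
    }
    pick <- sample(expressed, n_groups * module_size)
    modules <- split(genes[pick], rep(seq_len(n_groups), each = module_size))
    names(modules) <- sprintf("module_G%d", seq_len(n_groups))
    target <- NULL
    if (!is.null(knockdown_fold)) {
      pool <- setdiff(expressed, pick)
      pool <- pool[mu0[pool] >= 20]
      if (length(pool) < n_groups) pool <- setdiff(expressed, pick)
      target <- sample(pool, n_groups)
    }
    grp <- rep(seq_len(n_groups), each = cells_per_group)
    n_cells <- length(grp)
    depth <- stats::rlnorm(n_cells, 0, depth_sdlog)
    foldmat <- matrix(1, n_groups, n_genes)
    for (g in seq_len(n_groups)) {
      foldmat[g, pick[(g - 1L) * module_size + seq_len(module_size)]] <-
        module_fold
      if (!is.null(target)) foldmat[g, target[g]] <- 1 / knockdown_fold
    }
    counts <- matrix(0L, n_cells, n_genes)
    for (i in seq_len(n_cells)) {
      mu <- mu0 * foldmat[grp[i], ] * depth[i]
      y <- stats::rnbinom(n_genes, size = 1 / nb_dispersion, mu = mu)
      pdrop <- dropout_rate * exp(-mu / dropout_scale)
      y[stats::runif(n_genes) < pdrop] <- 0L
      counts[i, ] <- y
    }
    if (n_empty_cells > 0L) {
      counts <- rbind(counts, matrix(0L, n_empty_cells, n_genes))
      grp <- c(grp, rep(NA_integer_, n_empty_cells))
    }
    cell_id <- sprintf("cell%04d", seq_len(nrow(counts)))
    dimnames(counts) <- list(cell_id, genes)
    ann <- data.frame(cell_id = cell_id,
                      group = ifelse(is.na(grp), "empty",
                                     sprintf("G%d", grp)),
                      stringsAsFactors = FALSE)
    list(counts = counts, annotations = ann, modules = modules,
         truth = list(group = stats::setNames(ann$group, cell_id),
                      modules = modules,
                      target_genes = if (is.null(target)) NULL
                                     else stats::setNames(genes[target],
                                                          names(modules))))
  })
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_matrix(out$counts, file.path(out_dir, "matrix.tsv"))
    utils::write.table(out$annotations, file.path(out_dir,
                                                  "annotations.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    write_gmt(out$modules, file.path(out_dir, "modules.gmt"))
    jsonlite::write_json(list(group = as.list(out$truth$group)),
                         file.path(out_dir, "truth.json"),
                         auto_unbox = TRUE)
  }
  out
}
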