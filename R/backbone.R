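#' miR-E scaffold backbone
#'
#' The expression cassette model used throughout the package: an shRNA hairpin
#' (sense guide, loop, antisense guide) embedded between two scaffold flanks
#' and transcribed from a Pol II promoter. Reads from poly-A-primed
#' single-cell protocols can capture the hairpin together with scaffold
#' sequence, which is what makes vector-derived hairpin reads distinguishable
#' from the endogenous target mRNA.
#'
#' The scaffold sequence itself is configurable: any flank5/loop/flank3
#' triplet can be supplied, and all matching parameters are expressed
#' relative to backbone coordinates, so different scaffold dialects work
#' unchanged.
#'
#' @param flank5 Scaffold sequence upstream of the sense guide arm.
#' @param loop Hairpin loop between the two guide arms.
#' @param flank3 Scaffold sequence downstream of the antisense arm; for
#'   poly-A-primed capture this region carries candidate poly-A motifs
#'   (`ATTAAA`).
#' @param name Backbone label.
#' @return An object of class `mire_backbone`.
#' @seealso [default_backbone()], [read_backbone_config()]
#' @export
mire_backbone <- function(flank5, loop, flank3, name = "custom") {
  for (f in list(flank5 = flank5, loop = loop, flank3 = flank3)) {
    if (!is.character(f) || length(f) != 1L || nchar(f) == 0L) {
      stop("backbone fields must be nonempty strings")
    }
    if (grepl("[^ACGT]", f)) stop("backbone fields must be over ACGT")
  }
  structure(list(flank5 = flank5, loop = loop, flank3 = flank3,
                 name = as.character(name)),
            class = "mire_backbone")
}

#' Packaged default backbone
#'
#' A synthetic default scaffold shipped with the package (miR-30-style flank
#' and loop layout; the 3' flank carries two `ATTAAA` poly-A motifs so that
#' poly-A-primed protocols can capture hairpin transcripts). Real analyses
#' should supply the scaffold actually used for library construction via
#' [mire_backbone()] or [read_backbone_config()].
#'
#' @return A `mire_backbone` object.
#' @export
default_backbone <- function() {
  mire_backbone(
    flank5 = "TGCTGTTGACAGTGAGCGACGGTACCGAAC",
    loop   = "TAGTGAAGCCACAGATGTA",
    flank3 = "TGCCTACTGCCTCGGAATTAAAGGCTATTAAACCTCAGGA",
    name   = "synthetic-mirE-default"
  )
}

#' Read / write a backbone configuration file
#'
#' YAML or JSON with keys `flank5`, `loop`, `flank3` and optionally `name`.
#' The format is chosen by extension (`.json` vs anything else = YAML).
#'
#' @param path File path.
#' @return `read_backbone_config()` returns a `mire_backbone`;
#'   `write_backbone_config()` returns `path` invisibly.
#' @export
read_backbone_config <- function(path) {
  if (!file.exists(path)) stop("backbone config not found: ", path)
  cfg <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  need <- c("flank5", "loop", "flank3")
  if (!all(need %in% names(cfg))) {
    stop("backbone config must define: ", paste(need, collapse = ", "))
  }
  mire_backbone(cfg$flank5, cfg$loop, cfg$flank3,
                name = if (is.null(cfg$name)) "custom" else cfg$name)
}

#' @param backbone A `mire_backbone` object.
#' @rdname read_backbone_config
#' @export
write_backbone_config <- function(backbone, path) {
  stopifnot(inherits(backbone, "mire_backbone"))
  x <- unclass(backbone)
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(x, path, auto_unbox = TRUE)
  } else {
    yaml::write_yaml(x, path)
  }
  invisible(path)
}

#' @export
print.mire_backbone <- function(x, ...) {
  cat(sprintf("miR-E backbone '%s': flank5 %d nt | loop %d nt | flank3 %d nt\n",
              x$name, nchar(x$flank5), nchar(x$loop), nchar(x$flank3)))
  invisible(x)
}
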