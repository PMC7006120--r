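#' Detect retained introns from an alignment file
#'
#' End-to-end intron-retention detection: read the independent introns,
#' stream the alignments, count total and exon–intron junction fragments and
#' the 8-bin positional profile per intron, score each intron with FPKM and
#' the normalized entropy (coverage-uniformity) score, and call retention
#' with the four inclusive filters.
#'
#' @param bam Path to a coordinate-sorted BAM (or SAM) file of poly-A
#'   RNA-seq alignments, single- or paired-end.
#' @param introns Path to a BED file of independent introns (or an intron
#'   data.frame from [read_intron_bed()] / [derive_independent_introns()]).
#' @param library_size Total fragments in the library.  When \code{NULL}
#'   (default) all primary mapped fragments in the file are counted.
#' @param min_total,min_junction,min_fpkm,min_ne Retention thresholds; see
#'   [filter_config()].  Defaults 20 / 1 / 3 / 0.9.
#' @param min_mapq Minimum mapping quality for a record to be counted.
#'   Default 0.
#' @return An object of class \code{ir_result}: a list with \code{calls}
#'   (the per-intron data.frame from [classify_introns()]),
#'   \code{library_size}, \code{config} (the [filter_config()]),
#'   \code{n_introns}, \code{n_retained} and \code{input}.
#' @examples
#' cfg <- sim_config(n_genes = 8, seed = 7)
#' sim <- simulate_ir_dataset(cfg, dir = tempdir(), basename = "toy")
#' res <- ir_detect(sim$sam, sim$intron_bed, library_size = cfg$library_size)
#' res
#' head(retained_introns(res))
#' @export
ir_detect <- function(bam, introns, library_size = NULL,
                      min_total = 20, min_junction = 1,
                      min_fpkm = 3, min_ne = 0.9, min_mapq = 0L) {
  if (is.character(introns)) introns <- read_intron_bed(introns)
  prof <- count_profiles(bam, introns, min_mapq = min_mapq)
  if (is.null(library_size)) library_size <- prof$library_total
  cfg <- filter_config(min_total = min_total, min_junction = min_junction,
                       min_fpkm = min_fpkm, min_ne = min_ne,
                       library_size = library_size)
  calls <- classify_introns(prof, introns, cfg)
  structure(list(calls = calls,
                 library_size = library_size,
                 config = cfg,
                 n_introns = nrow(introns),
                 n_retained = sum(calls$retained),
                 input = if (is.character(bam)) bam else NA_character_),
            class = "ir_result")
}

#' Retained introns of a detection result
#'
#' @param x An \code{ir_result} from [ir_detect()].
#' @return The subset of the calls data.frame flagged retained.
#' @export
retained_introns <- function(x) {
  stopifnot(inherits(x, "ir_result"))
  x$calls[x$calls$retained, , drop = FALSE]
}

#' @export
print.ir_result <- function(x, ...) {
  cat("Intron retention detection\n")
  cat("  input:        ", x$input, "\n", sep = "")
  cat("  introns:      ", x$n_introns, "\n", sep = "")
  cat("  library size: ", format(x$library_size, big.mark = ","),
      " fragments\n", sep = "")
  cfg <- x$config
  cat(sprintf("  filters:      T>=%g, J>=%g, FPKM>=%g, NE>=%g\n",
              cfg$min_total, cfg$min_junction, cfg$min_fpkm, cfg$min_ne))
  cat("  retained:     ", x$n_retained, "\n", sep = "")
  invisible(x)
}

#' @export
summary.ir_result <- function(object, ...) {
  calls <- object$calls
  covered <- calls[calls$T > 0, , drop = FALSE]
  ret <- calls[calls$retained, , drop = FALSE]
  out <- list(n_introns = nrow(calls),
              n_covered = nrow(covered),
              n_retained = nrow(ret),
              library_size = object$library_size,
              fpkm_retained = if (nrow(ret)) summary(ret$fpkm) else NULL,
              ne_retained = if (nrow(ret)) summary(ret$ne_score) else NULL)
  class(out) <- "summary.ir_result"
  out
}

#' @export
print.summary.ir_result <- function(x, ...) {
  cat("introns scored:   ", x$n_introns, "\n")
  cat("introns with T>0: ", x$n_covered, "\n")
  cat("retained:         ", x$n_retained, "\n")
  if (!is.null(x$fpkm_retained)) {
    cat("FPKM of retained introns:\n")
    print(x$fpkm_retained)
    cat("NE-score of retained introns:\n")
    print(x$ne_retained)
  }
  invisible(x)
}
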