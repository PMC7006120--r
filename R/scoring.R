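#' Normalized entropy score of an 8-bin count vector
#'
#' The per-bin counts are normalized to a probability mass function
#' \eqn{p_i = n_i / \sum n_i}, its Shannon entropy (base 2, with
#' \eqn{0 \log 0 = 0}) is computed, and the entropy is divided by 3 — the
#' maximal entropy of 8 bins — giving a score in [0, 1].  A score of 1 means
#' perfectly uniform intronic coverage; a point mass scores 0.  An all-zero
#' vector is degenerate and returns entropy 0, score 0 (such introns have
#' \code{T = 0} and fail the read-count filter anyway).
#'
#' @param r Numeric vector of 8 non-negative bin counts.
#' @return A list with \code{entropy} (bits) and \code{ne} (in [0, 1]).
#' @export
ne_score <- function(r) {
  stopifnot(length(r) == 8L, all(r >= 0))
  tot <- sum(r)
  if (tot == 0) return(list(entropy = 0, ne = 0))
  p <- r / tot
  h <- -sum(ifelse(p > 0, p * log2(p), 0))
  list(entropy = h, ne = h / 3)
}

# vectorized: mat is n x 8 counts; returns cbind(entropy, ne)
.entropy8 <- function(mat) {
  tot <- rowSums(mat)
  p <- mat / ifelse(tot > 0, tot, 1)
  terms <- ifelse(p > 0, p * log2(p), 0)
  h <- -rowSums(terms)
  h[tot == 0] <- 0
  cbind(entropy = h, ne = h / 3)
}

#' FPKM of an intron
#'
#' Fragments per kilobase of intron per million library fragments:
#' \code{fpkm = T * 1e9 / (length * library_size)}.
#'
#' @param T Fragment count(s) overlapping the intron.
#' @param length Intron length(s), bp (> 0).
#' @param library_size Total fragments in the library (> 0).
#' @return Numeric FPKM value(s).
#' @export
intron_fpkm <- function(T, length, library_size) {
  stopifnot(all(length > 0), all(library_size > 0))
  T * 1e9 / (length * library_size)
}

#' Retention-filter configuration
#'
#' The four thresholds of the retention call plus the library size.  The
#' defaults (\code{T >= 20}, \code{J >= 1}, \code{FPKM >= 3},
#' \code{NE >= 0.9}) are deliberately strict, selecting conservative,
#' high-confidence retention events; all comparisons are inclusive.
#'
#' @param min_total Minimum total fragments T.  Default 20.
#' @param min_junction Minimum exon–intron junction fragments J.  Default 1.
#' @param min_fpkm Minimum intron FPKM.  Default 3.
#' @param min_ne Minimum normalized entropy score.  Default 0.9.  Values
#'   above 1 are allowed and reject everything (NE never exceeds 1).
#' @param library_size Total fragments in the library (> 0).
#' @return A list of class \code{filter_config}.
#' @export
filter_config <- function(min_total = 20, min_junction = 1, min_fpkm = 3,
                          min_ne = 0.9, library_size) {
  stopifnot(min_total >= 0, min_junction >= 0, min_fpkm >= 0,
            min_ne >= 0,
            is.numeric(library_size), length(library_size) == 1L,
            library_size > 0)
  structure(list(min_total = min_total, min_junction = min_junction,
                 min_fpkm = min_fpkm, min_ne = min_ne,
                 library_size = library_size),
            class = "filter_config")
}

#' Score and classify intron read profiles
#'
#' Computes FPKM, entropy and NE-score for every intron profile and flags an
#' intron as retained iff all four thresholds are met (inclusively):
#' \code{T >= min_total & J >= min_junction & fpkm >= min_fpkm &
#' ne >= min_ne}.
#'
#' @param profiles An \code{intron_profiles} object from [count_profiles()]
#'   (or its \code{$profiles} data.frame).
#' @param introns The intron data.frame the profiles were counted against.
#' @param config A [filter_config()].
#' @return A data.frame of calls, one row per intron, ordered by
#'   (chrom, start): \code{intron_id}, \code{chrom}, \code{start},
#'   \code{end}, \code{gene_id}, \code{T}, \code{J}, \code{fpkm},
#'   \code{entropy}, \code{ne_score}, \code{retained} (logical).
#' @export
classify_introns <- function(profiles, introns, config) {
  stopifnot(inherits(config, "filter_config"))
  if (inherits(profiles, "intron_profiles")) profiles <- profiles$profiles
  stopifnot(identical(profiles$intron_id, introns$intron_id))
  ent <- .entropy8(as.matrix(profiles[, paste0("n", 1:8)]))
  fpkm <- intron_fpkm(profiles$T, introns$length, config$library_size)
  retained <- profiles$T >= config$min_total &
    profiles$J >= config$min_junction &
    fpkm >= config$min_fpkm &
    ent[, "ne"] >= config$min_ne &
    profiles$T > 0
  calls <- data.frame(intron_id = profiles$intron_id,
                      chrom = introns$chrom,
                      start = introns$start,
                      end = introns$end,
                      gene_id = introns$gene_id,
                      T = profiles$T, J = profiles$J,
                      fpkm = fpkm,
                      entropy = ent[, "entropy"],
                      ne_score = ent[, "ne"],
                      retained = retained,
                      stringsAsFactors = FALSE)
  calls <- calls[order(calls$chrom, calls$start, calls$end), , drop = FALSE]
  rownames(calls) <- NULL
  calls
}

#' Write the 7-column retention table
#'
#' Writes one row per intron with the columns \code{intron_id},
#' \code{fragments} (T), \code{junction_reads} (J), \code{fpkm},
#' \code{entropy}, \code{ne_score} and \code{retained} ("yes"/"no"),
#' tab-delimited with a header, sorted by (chrom, start).  Real-valued
#' columns are formatted to 6 significant digits.
#'
#' @param calls A calls data.frame from [classify_introns()] or an
#'   [ir_detect()] result.
#' @param file Output path.
#' @return Invisibly, \code{file}.
#' @export
write_ir_table <- function(calls, file) {
  if (inherits(calls, "ir_result")) calls <- calls$calls
  fmt <- function(x) format(signif(x, 6L), trim = TRUE, scientific = FALSE)
  df <- data.frame(intron_id = calls$intron_id,
                   fragments = calls$T,
                   junction_reads = calls$J,
                   fpkm = fmt(calls$fpkm),
                   entropy = fmt(calls$entropy),
                   ne_score = fmt(calls$ne_score),
                   retained = ifelse(calls$retained, "yes", "no"),
                   stringsAsFactors = FALSE)
  utils::write.table(df, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}

#' Read a retention table written by [write_ir_table()]
#'
#' @param file Path to a \code{.ir} file.
#' @return A data.frame with columns \code{intron_id}, \code{T}, \code{J},
#'   \code{fpkm}, \code{entropy}, \code{ne_score}, \code{retained}
#'   (logical).
#' @export
read_ir_table <- function(file) {
  df <- utils::read.table(file, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE,
                          colClasses = c("character", "integer", "integer",
                                         "numeric", "numeric", "numeric",
                                         "character"))
  names(df)[names(df) == "fragments"] <- "T"
  names(df)[names(df) == "junction_reads"] <- "J"
  df$retained <- df$retained == "yes"
  df
}

# <input_basename>.ir inside the output directory
.ir_output_path <- function(input, outdir) {
  base <- sub("\\.(bam|sam)$", "", basename(input), ignore.case = TRUE)
  file.path(outdir, paste0(base, ".ir"))
}
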