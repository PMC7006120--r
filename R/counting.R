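#' Extract aligned reference blocks from CIGAR strings
#'
#' Walks each CIGAR from its 1-based POS and returns the aligned reference
#' blocks in 0-based half-open coordinates.  \code{N} (skipped region /
#' splice gap) splits blocks; \code{M}, \code{=}, \code{X} extend the current
#' block; \code{D} extends it too (a deletion still covers the reference);
#' \code{I}, \code{S}, \code{H}, \code{P} consume no reference.
#'
#' @param pos Integer vector of 1-based leftmost mapped positions.
#' @param cigar Character vector of CIGAR strings (same length as
#'   \code{pos}).
#' @return A list (one element per record) of two-column integer matrices
#'   with columns \code{start}, \code{end} (0-based half-open).
#' @export
fragment_blocks <- function(pos, cigar) {
  stopifnot(length(pos) == length(cigar))
  rl <- GenomicAlignments::extractAlignmentRangesOnReference(
    cigar, pos = pos, drop.D.ranges = FALSE)
  lapply(seq_along(rl), function(i) {
    r <- rl[[i]]
    cbind(start = IRanges::start(r) - 1L, end = IRanges::end(r))
  })
}

#' Classify the overlap of a fragment with an intron
#'
#' A fragment is a set of aligned blocks (both mates of a pair, or the single
#' read).  The classification is:
#' \describe{
#'   \item{\code{"none"}}{no block intersects the intron — in particular a
#'     spliced fragment whose N-gap spans the intron;}
#'   \item{\code{"junction"}}{at least one block intersects the intron and
#'     straddles one of its boundaries (at least 1 aligned bp on each side);}
#'   \item{\code{"internal"}}{blocks intersect the intron and every
#'     intersecting block lies fully inside it.}
#' }
#'
#' @param blocks Two-column matrix of aligned blocks, 0-based half-open
#'   (as from [fragment_blocks()]), assumed on the intron's chromosome.
#' @param start,end Intron interval, 0-based half-open.
#' @return One of \code{"none"}, \code{"internal"}, \code{"junction"}.
#' @export
overlaps_intron <- function(blocks, start, end) {
  bs <- blocks[, 1L]
  be <- blocks[, 2L]
  hit <- be > start & bs < end
  if (!any(hit)) return("none")
  straddle <- hit & (bs < start | be > end)
  if (any(straddle)) "junction" else "internal"
}

#' Read aligned fragments from a BAM or SAM file
#'
#' Loads primary, mapped alignment records (secondary and supplementary
#' alignments are excluded; duplicates are kept), groups them into fragments
#' by query name — so a read pair becomes a single fragment carrying both
#' mates' blocks — and extracts splice-aware aligned blocks (N gaps split
#' blocks, D is covered).  SAM input is converted to BAM on the fly; the
#' whole file is streamed, so no index is required.
#'
#' @param file Path to a coordinate-sorted BAM (or plain SAM) file.
#' @param min_mapq Minimum mapping quality; records below it are dropped.
#'   Default 0 (no filter).
#' @return A list of class \code{aligned_fragments}:
#'   \code{blocks} (a \code{GRanges} of aligned blocks with a \code{frag}
#'   integer column identifying the fragment), \code{n_fragments} (number of
#'   distinct primary mapped fragments — the library total when none is
#'   supplied), and \code{n_unmapped} (records skipped as unmapped).
#' @export
read_fragments <- function(file, min_mapq = 0L) {
  bam <- .as_bam(file)
  flag <- Rsamtools::scanBamFlag(isUnmappedQuery = FALSE,
                                 isSecondaryAlignment = FALSE,
                                 isSupplementaryAlignment = FALSE)
  param <- Rsamtools::ScanBamParam(
    flag = flag,
    mapqFilter = if (min_mapq > 0L) as.integer(min_mapq) else NA_integer_)
  gal <- GenomicAlignments::readGAlignments(bam, param = param,
                                            use.names = TRUE)
  n_unmapped <- Rsamtools::countBam(
    bam, param = Rsamtools::ScanBamParam(
      flag = Rsamtools::scanBamFlag(isUnmappedQuery = TRUE)))$records

  qn <- names(gal)
  frag <- match(qn, unique(qn))
  grl <- GenomicAlignments::grglist(gal)  # N splits, D covered
  blocks <- unlist(grl, use.names = FALSE)
  S4Vectors::mcols(blocks)$frag <- rep(frag, S4Vectors::elementNROWS(grl))
  structure(list(blocks = blocks,
                 n_fragments = length(unique(frag)),
                 n_unmapped = n_unmapped),
            class = "aligned_fragments")
}

.as_bam <- function(file) {
  if (grepl("\\.sam$", file, ignore.case = TRUE)) {
    dest <- tempfile(fileext = "")
    bam <- Rsamtools::asBam(file, dest, overwrite = TRUE,
                            indexDestination = FALSE)
    return(bam)
  }
  file
}

#' Count intronic and junction fragments per independent intron
#'
#' Assigns every primary mapped fragment to the independent introns it
#' physically overlaps (a spliced fragment whose N-gap spans an intron does
#' not overlap it) and accumulates, per intron: \code{T}, the total number of
#' overlapping fragments; \code{J}, the number of fragments with an aligned
#' block straddling an exon–intron boundary; and the 8-bin positional count
#' vector \code{n1..n8}.  A fragment increments every intron it overlaps
#' (independently), but exactly one bin per (fragment, intron) pair — the bin
#' containing the midpoint of the fragment's intersection with the intron —
#' so that \code{n1 + ... + n8 == T}.
#'
#' @param x A BAM/SAM path or an \code{aligned_fragments} object from
#'   [read_fragments()].
#' @param introns Intron data.frame ([read_intron_bed()] /
#'   [derive_independent_introns()]).
#' @param min_mapq Passed to [read_fragments()] when \code{x} is a path.
#' @return A list of class \code{intron_profiles}: \code{profiles}, a
#'   data.frame with one row per intron (columns \code{intron_id}, \code{T},
#'   \code{J}, \code{n1}..\code{n8}, in the order of \code{introns}), and
#'   \code{library_total}, the number of primary mapped fragments in the file
#'   (\code{NA} when \code{x} was a pre-parsed object without it).
#' @export
count_profiles <- function(x, introns, min_mapq = 0L) {
  if (is.character(x)) x <- read_fragments(x, min_mapq = min_mapq)
  stopifnot(inherits(x, "aligned_fragments"))

  prof <- data.frame(intron_id = introns$intron_id,
                     T = 0L, J = 0L, stringsAsFactors = FALSE)
  bins <- matrix(0L, nrow(introns), 8L,
                 dimnames = list(NULL, paste0("n", 1:8)))

  if (nrow(introns) > 0L && length(x$blocks) > 0L) {
    igr <- .introns_granges(introns)
    hits <- GenomicRanges::findOverlaps(x$blocks, igr, ignore.strand = TRUE)
    if (length(hits) > 0L) {
      q <- S4Vectors::queryHits(hits)
      s <- S4Vectors::subjectHits(hits)
      bs <- GenomicRanges::start(x$blocks)[q]
      be <- GenomicRanges::end(x$blocks)[q]
      is_ <- GenomicRanges::start(igr)[s]
      ie_ <- GenomicRanges::end(igr)[s]
      dt <- data.table::data.table(
        frag = S4Vectors::mcols(x$blocks)$frag[q],
        intron = s,
        straddle = bs < is_ | be > ie_,
        a = pmax(bs, is_),   # 1-based closed intersection
        b = pmin(be, ie_))
      frag <- intron <- straddle <- a <- b <- junction <- NULL  # NSE names
      per <- dt[, list(junction = any(straddle), a = min(a), b = max(b)),
                by = list(frag, intron)]
      # midpoint of the intersection, 0-based; then the floor-boundary bin
      m0 <- (per$a - 1L + per$b) %/% 2L
      ist <- introns$start[per$intron]
      len <- introns$length[per$intron]
      o <- m0 - ist
      bin <- rep(1L, nrow(per))
      for (k in 1:7) bin <- bin + (o >= (k * len) %/% 8L)
      tj <- per[, list(T = .N, J = sum(junction)), by = intron]
      prof$T[tj$intron] <- tj$T
      prof$J[tj$intron] <- as.integer(tj$J)
      tab <- data.table::data.table(intron = per$intron, bin = bin)
      cnt <- tab[, .N, by = list(intron, bin)]
      bins[cbind(cnt$intron, cnt$bin)] <- cnt$N
    }
  }
  structure(list(profiles = cbind(prof, as.data.frame(bins)),
                 library_total = x$n_fragments),
            class = "intron_profiles")
}

#' 8-bin boundaries of an intron
#'
#' The intron \code{[start, end)} is tiled by 8 bins of near-equal width:
#' bin \code{k} covers \code{[start + floor((k-1)L/8), start + floor(kL/8))}
#' with \code{L = end - start}.  The widths differ by at most 1 bp and sum
#' exactly to \code{L}.
#'
#' @param start,end Intron interval, 0-based half-open.
#' @return Integer vector of the 9 bin boundaries.
#' @export
bin_boundaries <- function(start, end) {
  L <- end - start
  start + vapply(0:8, function(k) (k * L) %/% 8L, numeric(1))
}

#' Bin of a fragment within an intron
#'
#' Implements the midpoint rule used by [count_profiles()]: the fragment is
#' assigned to the single bin containing the midpoint of its intersection
#' with the intron.
#'
#' @param blocks Aligned blocks of the fragment (0-based half-open matrix).
#' @param start,end Intron interval, 0-based half-open.
#' @return Integer bin index in 1..8 (or \code{NA} if the fragment does not
#'   overlap the intron).
#' @export
bin_assign <- function(blocks, start, end) {
  bs <- pmax(blocks[, 1L], start)
  be <- pmin(blocks[, 2L], end)
  hit <- be > bs
  if (!any(hit)) return(NA_integer_)
  a <- min(bs[hit])
  b <- max(be[hit])
  m <- (a + b) %/% 2L
  L <- end - start
  o <- m - start
  bin <- 1L
  for (k in 1:7) bin <- bin + (o >= (k * L) %/% 8L)
  as.integer(bin)
}
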