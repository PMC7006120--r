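#' Configuration of the synthetic RNA-seq simulator
#'
#' Defines a toy genome of multi-isoform genes, a designated subset of
#' independent introns that are retained, and sequencing geometry.  Retained
#' introns emit contiguous (unspliced) fragments placed uniformly across the
#' intron — so coverage is flat and boundary-straddling junction fragments
#' arise naturally — while spliced transcripts emit gapped alignments whose
#' N-gaps exactly span their introns.
#'
#' @param n_genes Number of genes.  Default 500.
#' @param isoforms_per_gene Integer range (lo, hi) of isoforms per gene.
#'   Isoforms beyond the first skip random internal exons.  Default c(1, 3).
#' @param exons_per_gene Integer range of exons per gene.  Default c(3, 7).
#' @param exon_length,intron_length Ranges (bp) for exon and intron lengths.
#'   Defaults c(100, 300) and c(250, 2500).
#' @param retained_fraction Fraction of independent introns designated
#'   retained.  Default 0.3.
#' @param retained_fpkm FPKM range of retained introns (log-uniform).
#'   Default c(0.2, 30).
#' @param transcript_fpkm FPKM range of spliced transcripts (log-uniform).
#'   Default c(1, 20).
#' @param library_size Declared library total (fragments) against which
#'   FPKM targets are realized; pass it to the detector as its library size,
#'   as one would for an alignment subset of a larger run.  Default 2e7.
#' @param read_length Read length, bp.  Must not exceed the minimum exon
#'   length (so a read spans at most one junction) nor the minimum
#'   exon + intron span.  Default 75.
#' @param fragment_length Mean and sd (bp) of fragment length.  Default
#'   c(200, 30).
#' @param paired Paired-end if TRUE (default); single-end otherwise.
#' @param clumped If TRUE, retained-intron fragments are confined to the
#'   first quarter of the intron instead of spread uniformly, producing
#'   low-entropy coverage that the NE-score filter should reject.
#'   Default FALSE.
#' @param n_chrom Number of chromosomes genes are spread over.  Default 4.
#' @param intergenic_gap Gap between consecutive genes, bp.  Default 2000.
#' @param seed RNG seed; fixed seed gives byte-identical output.  Default 1.
#' @return A list of class \code{sim_config}.
#' @export
sim_config <- function(n_genes = 500L,
                       isoforms_per_gene = c(1L, 3L),
                       exons_per_gene = c(3L, 7L),
                       exon_length = c(100L, 300L),
                       intron_length = c(250L, 2500L),
                       retained_fraction = 0.3,
                       retained_fpkm = c(0.2, 30),
                       transcript_fpkm = c(1, 20),
                       library_size = 2e7,
                       read_length = 75L,
                       fragment_length = c(200, 30),
                       paired = TRUE,
                       clumped = FALSE,
                       n_chrom = 4L,
                       intergenic_gap = 2000L,
                       seed = 1L) {
  stopifnot(n_genes >= 1, all(isoforms_per_gene >= 1),
            all(exons_per_gene >= 2), all(exon_length > 0),
            all(intron_length > 0),
            retained_fraction >= 0, retained_fraction <= 1,
            all(retained_fpkm > 0), all(transcript_fpkm > 0),
            library_size > 0, read_length > 0, fragment_length[1] > 0)
  if (read_length > min(exon_length) + min(intron_length)) {
    stop("infeasible geometry: read_length exceeds the minimum ",
         "exon + intron span")
  }
  if (read_length > min(exon_length)) {
    stop("infeasible geometry: read_length exceeds the minimum exon length")
  }
  structure(list(n_genes = as.integer(n_genes),
                 isoforms_per_gene = as.integer(isoforms_per_gene),
                 exons_per_gene = as.integer(exons_per_gene),
                 exon_length = as.integer(exon_length),
                 intron_length = as.integer(intron_length),
                 retained_fraction = retained_fraction,
                 retained_fpkm = retained_fpkm,
                 transcript_fpkm = transcript_fpkm,
                 library_size = library_size,
                 read_length = as.integer(read_length),
                 fragment_length = fragment_length,
                 paired = isTRUE(paired),
                 clumped = isTRUE(clumped),
                 n_chrom = as.integer(n_chrom),
                 intergenic_gap = as.integer(intergenic_gap),
                 seed = as.integer(seed)),
            class = "sim_config")
}

.runif_log <- function(n, range) {
  exp(stats::runif(n, log(range[1]), log(range[2])))
}

.sample_range <- function(n, range) {
  if (range[1] == range[2]) rep(range[1], n)
  else sample(seq(range[1], range[2]), n, replace = TRUE)
}

#' Simulate an RNA-seq dataset with known retained introns
#'
#' Generates a toy genome annotation (GTF), a coordinate-sorted SAM of
#' synthetic alignments and a ground-truth table, all deterministic for a
#' fixed seed.  Per-intron truth counts (\code{frags}, \code{junction}) are
#' derived directly from the coordinates of the emitted reads — every
#' fragment with an aligned segment intersecting the intron counts once, and
#' is a junction fragment when a segment straddles an intron boundary —
#' independently of the BAM-parsing detection path.  Truth FPKM is computed
#' from those counts and the declared library size.
#'
#' @param cfg A [sim_config()].
#' @param dir Output directory (created if absent).
#' @param basename Stem for the output files.  Default \code{"sim"}.
#' @return A list with paths \code{gtf}, \code{sam}, \code{intron_bed},
#'   \code{truth_file}, plus in-memory \code{models} (gene models),
#'   \code{introns} (independent-intron data.frame), \code{truth}
#'   (data.frame: \code{intron_id}, coordinates, \code{retained},
#'   \code{fpkm_target}, \code{frags}, \code{junction}, \code{fpkm_true}),
#'   \code{library_size}, \code{n_fragments} (fragments actually emitted)
#'   and \code{config}.
#' @export
simulate_ir_dataset <- function(cfg, dir, basename = "sim") {
  stopifnot(inherits(cfg, "sim_config"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old_seed))
    assign(".Random.seed", old_seed, envir = globalenv()), add = TRUE)
  set.seed(cfg$seed)

  chroms <- paste0("chr", seq_len(cfg$n_chrom))
  cursor <- stats::setNames(rep(3000L, cfg$n_chrom), chroms)

  models <- vector("list", cfg$n_genes)
  for (i in seq_len(cfg$n_genes)) {
    chrom <- chroms[(i - 1L) %% cfg$n_chrom + 1L]
    n_ex <- .sample_range(1L, cfg$exons_per_gene)
    ex_len <- .sample_range(n_ex, cfg$exon_length)
    in_len <- .sample_range(n_ex - 1L, cfg$intron_length)
    starts <- cursor[chrom] + c(0L, cumsum(ex_len[-n_ex] + in_len))
    exons <- cbind(start = as.integer(starts),
                   end = as.integer(starts + ex_len))
    cursor[chrom] <- exons[n_ex, 2L] + cfg$intergenic_gap
    strand <- sample(c("+", "-"), 1L)
    gid <- sprintf("G%04d", i)
    n_iso <- .sample_range(1L, cfg$isoforms_per_gene)
    txs <- list(exons)
    if (n_iso > 1L && n_ex > 2L) {
      for (k in seq_len(n_iso - 1L)) {
        keep <- c(1L, which(stats::runif(n_ex - 2L) < 0.6) + 1L, n_ex)
        txs[[k + 1L]] <- exons[keep, , drop = FALSE]
      }
    }
    names(txs) <- sprintf("%s.T%d", gid, seq_along(txs))
    models[[i]] <- list(gene_id = gid, chrom = chrom, strand = strand,
                        start = exons[1L, 1L], end = exons[n_ex, 2L],
                        transcripts = txs)
  }
  names(models) <- vapply(models, `[[`, character(1), "gene_id")
  class(models) <- "gene_models"

  introns <- derive_independent_introns(models)
  n_int <- nrow(introns)
  retained <- rep(FALSE, n_int)
  if (cfg$retained_fraction > 0 && n_int > 0) {
    retained[sample.int(n_int, round(cfg$retained_fraction * n_int))] <- TRUE
  }
  fpkm_target <- rep(0, n_int)
  fpkm_target[retained] <- .runif_log(sum(retained), cfg$retained_fpkm)

  rl <- cfg$read_length
  L <- cfg$library_size
  paired <- cfg$paired
  frag_parts <- list()

  # retained-intron fragments: contiguous, uniform across the intron
  for (j in which(retained)) {
    len <- introns$length[j]
    n <- stats::rpois(1L, fpkm_target[j] * len * L / 1e9)
    if (n == 0L) next
    fl <- pmax(rl, round(stats::rnorm(n, cfg$fragment_length[1],
                                      cfg$fragment_length[2])))
    if (cfg$clumped) {
      hi <- introns$start[j] + max(1L, len %/% 4L - max(fl))
      s <- introns$start[j] +
        (sample.int(max(1L, hi - introns$start[j] + 1L), n, replace = TRUE) - 1L)
    } else {
      lo <- introns$start[j] - fl + 1L
      s <- lo + floor(stats::runif(n) * (introns$end[j] - 1L - lo + 1L))
    }
    frag_parts[[length(frag_parts) + 1L]] <- data.table::data.table(
      chrom = introns$chrom[j], s = as.integer(s), fl = as.integer(fl),
      tx = NA_integer_)
  }

  # spliced-transcript fragments: placed in transcript coordinates
  tx_tab <- list()
  for (g in models) {
    for (t in names(g$transcripts)) {
      tx_tab[[t]] <- list(chrom = g$chrom, exons = g$transcripts[[t]])
    }
  }
  tx_names <- names(tx_tab)
  tx_fpkm <- .runif_log(length(tx_tab), cfg$transcript_fpkm)
  for (ti in seq_along(tx_tab)) {
    ex <- tx_tab[[ti]]$exons
    elen <- ex[, 2L] - ex[, 1L]
    S <- sum(elen)
    if (S < rl) stop("infeasible geometry: transcript shorter than a read")
    n <- stats::rpois(1L, tx_fpkm[ti] * S * L / 1e9)
    if (n == 0L) next
    fl <- pmin(S, pmax(rl, round(stats::rnorm(n, cfg$fragment_length[1],
                                              cfg$fragment_length[2]))))
    ts <- floor(stats::runif(n) * (S - fl + 1L))
    frag_parts[[length(frag_parts) + 1L]] <- data.table::data.table(
      chrom = tx_tab[[ti]]$chrom, s = as.integer(ts), fl = as.integer(fl),
      tx = ti)
  }

  frags <- if (length(frag_parts)) data.table::rbindlist(frag_parts)
  else data.table::data.table(chrom = character(), s = integer(),
                              fl = integer(), tx = integer())
  n_frag <- nrow(frags)

  # per-mate (or single-read) intervals, then genomic blocks + CIGARs
  mates <- .sim_mates(frags, tx_tab, rl, paired)

  # ground truth from read coordinates: map every aligned segment to introns
  truth_cnt <- .truth_counts(mates, introns)
  truth <- data.frame(intron_id = introns$intron_id,
                      chrom = introns$chrom, start = introns$start,
                      end = introns$end, gene_id = introns$gene_id,
                      length = introns$length,
                      retained = retained,
                      fpkm_target = fpkm_target,
                      frags = truth_cnt$T, junction = truth_cnt$J,
                      stringsAsFactors = FALSE)
  truth$fpkm_true <- truth$frags * 1e9 / (truth$length * L)

  gtf <- file.path(dir, paste0(basename, ".gtf"))
  sam <- file.path(dir, paste0(basename, ".sam"))
  bed <- file.path(dir, paste0(basename, "_introns.bed"))
  truth_file <- file.path(dir, paste0(basename, "_truth.tsv"))
  .write_sim_gtf(models, gtf)
  .write_sim_sam(mates, chroms, cursor, rl, paired, sam)
  write_intron_bed(introns, bed)
  utils::write.table(truth, truth_file, sep = "\t", quote = FALSE,
                     row.names = FALSE)

  list(gtf = gtf, sam = sam, intron_bed = bed, truth_file = truth_file,
       models = models, introns = introns, truth = truth,
       library_size = L, n_fragments = n_frag, config = cfg)
}

# Expand fragments into mate alignment records with genomic blocks.
# Returns a data.table: frag, chrom, mate (1/2), blocks encoded as
# bs1,be1,bs2,be2 (second block NA when contiguous), pos (1-based), cigar.
.sim_mates <- function(frags, tx_tab, rl, paired) {
  n <- nrow(frags)
  if (n == 0L) {
    return(data.table::data.table(frag = integer(), chrom = character(),
                                  mate = integer(), bs1 = integer(),
                                  be1 = integer(), bs2 = integer(),
                                  be2 = integer(), pos = integer(),
                                  cigar = character()))
  }
  frag_id <- seq_len(n)
  if (paired) {
    frag <- rep(frag_id, 2L)
    chrom <- rep(frags$chrom, 2L)
    tx <- rep(frags$tx, 2L)
    mate <- rep(1:2, each = n)
    a <- c(frags$s, frags$s + frags$fl - rl)
    b <- c(frags$s + rl, frags$s + frags$fl)
  } else {
    frag <- frag_id; chrom <- frags$chrom; tx <- frags$tx; mate <- rep(1L, n)
    a <- frags$s; b <- frags$s + rl
  }

  bs1 <- a; be1 <- b
  bs2 <- rep(NA_integer_, length(a))
  be2 <- rep(NA_integer_, length(a))
  # transcript-coordinate records: map [a, b) through the exon chain
  tx_rows <- which(!is.na(tx))
  idx_by_tx <- split(tx_rows, tx[tx_rows])
  for (ti_chr in names(idx_by_tx)) {
    ti <- as.integer(ti_chr)
    idx <- idx_by_tx[[ti_chr]]
    ex <- tx_tab[[ti]]$exons
    elen <- ex[, 2L] - ex[, 1L]
    cstart <- cumsum(c(0L, elen))[seq_len(nrow(ex))]
    ai <- a[idx]; bi <- b[idx]
    ja <- findInterval(ai, cstart)
    jb <- findInterval(bi - 1L, cstart)
    g_a <- ex[ja, 1L] + (ai - cstart[ja])
    one <- ja == jb
    bs1[idx] <- as.integer(g_a)
    be1[idx] <- as.integer(ifelse(one, g_a + (bi - ai), ex[ja, 2L]))
    bs2[idx] <- as.integer(ifelse(one, NA, ex[jb, 1L]))
    be2[idx] <- as.integer(ifelse(one, NA, ex[jb, 1L] + (bi - cstart[jb])))
  }
  pos <- bs1 + 1L
  w1 <- be1 - bs1
  two <- !is.na(bs2)
  cigar <- paste0(w1, "M")
  cigar[two] <- paste0(w1[two], "M", bs2[two] - be1[two], "N",
                       be2[two] - bs2[two], "M")
  data.table::data.table(frag = frag, chrom = chrom, mate = mate,
                         bs1 = bs1, be1 = be1, bs2 = bs2, be2 = be2,
                         pos = pos, cigar = cigar)
}

# Count, per intron, fragments whose aligned segments intersect it and how
# many of those have a segment straddling a boundary — pure coordinate
# arithmetic on the generator's own placements.
.truth_counts <- function(mates, introns) {
  out <- list(T = rep(0L, nrow(introns)), J = rep(0L, nrow(introns)))
  if (nrow(mates) == 0L || nrow(introns) == 0L) return(out)
  seg <- data.table::data.table(
    frag = c(mates$frag, mates$frag[!is.na(mates$bs2)]),
    chrom = c(mates$chrom, mates$chrom[!is.na(mates$bs2)]),
    bs = c(mates$bs1, mates$bs2[!is.na(mates$bs2)]),
    be = c(mates$be1, mates$be2[!is.na(mates$bs2)]))
  sg <- GenomicRanges::GRanges(seg$chrom,
                               IRanges::IRanges(seg$bs + 1L, seg$be))
  ig <- .introns_granges(introns)
  hits <- GenomicRanges::findOverlaps(sg, ig, ignore.strand = TRUE)
  if (length(hits) == 0L) return(out)
  q <- S4Vectors::queryHits(hits)
  s <- S4Vectors::subjectHits(hits)
  dt <- data.table::data.table(
    frag = seg$frag[q], intron = s,
    straddle = seg$bs[q] < introns$start[s] | seg$be[q] > introns$end[s])
  frag <- intron <- straddle <- junction <- NULL
  per <- dt[, list(junction = any(straddle)), by = list(frag, intron)]
  tj <- per[, list(T = .N, J = sum(junction)), by = intron]
  out$T[tj$intron] <- tj$T
  out$J[tj$intron] <- as.integer(tj$J)
  out
}

.write_sim_gtf <- function(models, file) {
  lines <- character(0)
  for (g in models) {
    attr_g <- sprintf('gene_id "%s";', g$gene_id)
    lines <- c(lines, paste(g$chrom, "sim", "gene", g$start + 1L, g$end,
                            ".", g$strand, ".", attr_g, sep = "\t"))
    for (t in names(g$transcripts)) {
      ex <- g$transcripts[[t]]
      attr_t <- sprintf('gene_id "%s"; transcript_id "%s";', g$gene_id, t)
      lines <- c(lines,
                 paste(g$chrom, "sim", "transcript", ex[1L, 1L] + 1L,
                       ex[nrow(ex), 2L], ".", g$strand, ".", attr_t,
                       sep = "\t"),
                 paste(g$chrom, "sim", "exon", ex[, 1L] + 1L, ex[, 2L],
                       ".", g$strand, ".", attr_t, sep = "\t"))
    }
  }
  writeLines(lines, file)
}

.write_sim_sam <- function(mates, chroms, cursor, rl, paired, file) {
  chrom_len <- cursor + 1000L
  header <- c("@HD\tVN:1.6\tSO:coordinate",
              sprintf("@SQ\tSN:%s\tLN:%d", chroms, chrom_len))
  if (nrow(mates) == 0L) {
    writeLines(header, file)
    return(invisible(file))
  }
  qname <- sprintf("frag%07d", mates$frag)
  seq_ <- strrep("A", rl)
  qual <- strrep("I", rl)
  if (paired) {
    flag <- ifelse(mates$mate == 1L, 99L, 147L)
    # mate coordinates for RNEXT/PNEXT/TLEN
    ord_pair <- order(mates$frag, mates$mate)
    mm <- mates[ord_pair, ]
    pos1 <- mm$pos[mm$mate == 1L][match(mates$frag,
                                        mm$frag[mm$mate == 1L])]
    pos2 <- mm$pos[mm$mate == 2L][match(mates$frag,
                                        mm$frag[mm$mate == 2L])]
    end2 <- mm$be2[mm$mate == 2L]
    end2[is.na(end2)] <- mm$be1[mm$mate == 2L][is.na(end2)]
    end2 <- end2[match(mates$frag, mm$frag[mm$mate == 2L])]
    tlen_abs <- end2 - (pos1 - 1L)
    pnext <- ifelse(mates$mate == 1L, pos2, pos1)
    tlen <- ifelse(mates$mate == 1L, tlen_abs, -tlen_abs)
    rnext <- "="
  } else {
    flag <- rep(0L, nrow(mates))
    rnext <- "*"; pnext <- 0L; tlen <- 0L
  }
  rec <- paste(qname, flag, mates$chrom, mates$pos, 255L, mates$cigar,
               rnext, pnext, tlen, seq_, qual, sep = "\t")
  ci <- match(mates$chrom, chroms)
  ord <- order(ci, mates$pos, qname, flag)
  writeLines(c(header, rec[ord]), file)
  invisible(file)
}

#' Build a gold-standard set of retained introns from simulation truth
#'
#' A gold standard collects the introns whose coordinate-derived truth meets
#' three floors: minimum true FPKM, minimum fragment count (default 10) and
#' minimum junction fragments (default 1).  The tiers GS1, GS2 and GS3 use
#' FPKM floors 0.1, 0.3 and 0.5: GS3 collects the highest-confidence
#' retention events and is nested inside GS2, which is nested inside GS1.
#'
#' @param truth Truth data.frame from [simulate_ir_dataset()].
#' @param min_fpkm Minimum true FPKM.
#' @param min_fragments Minimum true fragment count.  Default 10.
#' @param min_junction Minimum true junction fragments.  Default 1.
#' @return Character vector of qualifying intron ids.
#' @export
build_gold_standard <- function(truth, min_fpkm, min_fragments = 10,
                                min_junction = 1) {
  keep <- truth$fpkm_true >= min_fpkm &
    truth$frags >= min_fragments &
    truth$junction >= min_junction
  truth$intron_id[keep]
}

#' @rdname build_gold_standard
#' @export
gold_standard_tiers <- function(truth, min_fragments = 10,
                                min_junction = 1) {
  list(GS1 = build_gold_standard(truth, 0.1, min_fragments, min_junction),
       GS2 = build_gold_standard(truth, 0.3, min_fragments, min_junction),
       GS3 = build_gold_standard(truth, 0.5, min_fragments, min_junction))
}
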