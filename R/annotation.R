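#' Parse gene models from a GTF file
#'
#' Reads gene, transcript and exon features from an ENSEMBL-dialect GTF file
#' and assembles one gene model per \code{gene_id}.  Exon coordinates are
#' converted from GTF's 1-based closed convention to the package-internal
#' 0-based half-open convention on parse.  When a gene has no explicit
#' \code{gene} feature line, its span is taken as the union span of its
#' transcripts (minimum exon start to maximum exon end).
#'
#' @param gtf Path to a GTF file with \code{gene_id "X"; transcript_id "Y";}
#'   style attributes.
#' @return An object of class \code{gene_models}: a named list with one
#'   element per gene, each a list with fields \code{gene_id}, \code{chrom},
#'   \code{strand}, \code{start}, \code{end} (0-based half-open span) and
#'   \code{transcripts} (a named list of two-column integer matrices of exon
#'   \code{start}/\code{end}, 0-based half-open, sorted by start).
#' @seealso [derive_independent_introns()]
#' @export
parse_gene_models <- function(gtf) {
  lines <- readLines(gtf)
  keep <- !grepl("^#", lines) & nzchar(lines)
  lineno <- which(keep)
  lines <- lines[keep]
  if (length(lines) == 0L) stop("no feature lines in GTF: ", gtf)

  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf != 9L)) {
    bad <- lineno[which(nf != 9L)[1L]]
    stop("malformed GTF line ", bad, ": expected 9 tab-separated fields")
  }
  m <- matrix(unlist(fields), ncol = 9L, byrow = TRUE)
  feat <- m[, 3L]
  sel <- feat %in% c("gene", "transcript", "exon")
  m <- m[sel, , drop = FALSE]
  feat <- feat[sel]
  lineno <- lineno[sel]
  if (nrow(m) == 0L) stop("GTF contains no gene/transcript/exon features")

  start1 <- suppressWarnings(as.integer(m[, 4L]))
  end1 <- suppressWarnings(as.integer(m[, 5L]))
  bad <- which(is.na(start1) | is.na(end1) | end1 < start1)
  if (length(bad)) {
    stop("malformed GTF line ", lineno[bad[1L]], ": invalid coordinates")
  }
  # 1-based closed -> 0-based half-open
  start0 <- start1 - 1L
  end0 <- end1

  attr_field <- m[, 9L]
  gid <- .gtf_attr(attr_field, "gene_id")
  tid <- .gtf_attr(attr_field, "transcript_id")
  if (anyNA(gid)) {
    stop("malformed GTF line ", lineno[which(is.na(gid))[1L]],
         ": missing gene_id attribute")
  }
  is_exon <- feat == "exon"
  if (any(is_exon & is.na(tid))) {
    stop("malformed GTF line ", lineno[which(is_exon & is.na(tid))[1L]],
         ": exon without transcript_id")
  }

  chrom <- m[, 1L]
  strand <- m[, 7L]
  models <- vector("list", length(unique(gid)))
  names(models) <- unique(gid)
  for (g in names(models)) {
    i <- which(gid == g)
    ch <- unique(chrom[i])
    st <- unique(strand[i])
    if (length(ch) != 1L) stop("gene ", g, " spans multiple chromosomes")
    if (length(st) != 1L) st <- st[1L]
    ie <- i[is_exon[i]]
    if (length(ie) == 0L) stop("gene ", g, " has no exon features")
    txs <- split(ie, tid[ie])
    transcripts <- lapply(txs, function(j) {
      ex <- cbind(start = start0[j], end = end0[j])
      ex <- ex[order(ex[, 1L], ex[, 2L]), , drop = FALSE]
      if (nrow(ex) > 1L && any(ex[-1L, 1L] < ex[-nrow(ex), 2L])) {
        stop("gene ", g, ": overlapping exons within one transcript")
      }
      ex
    })
    igene <- i[feat[i] == "gene"]
    if (length(igene)) {
      gs <- start0[igene[1L]]
      ge <- end0[igene[1L]]
    } else {
      gs <- min(vapply(transcripts, function(ex) min(ex[, 1L]), integer(1)))
      ge <- max(vapply(transcripts, function(ex) max(ex[, 2L]), integer(1)))
    }
    if (any(vapply(transcripts, function(ex) {
      min(ex[, 1L]) < gs || max(ex[, 2L]) > ge
    }, logical(1)))) {
      stop("gene ", g, ": exon outside the declared gene span")
    }
    models[[g]] <- list(gene_id = g, chrom = ch, strand = st,
                        start = gs, end = ge, transcripts = transcripts)
  }
  structure(models, class = "gene_models")
}

.gtf_attr <- function(x, key) {
  pat <- paste0(key, "\\s+\"([^\"]*)\"")
  m <- regexpr(pat, x, perl = TRUE)
  out <- rep(NA_character_, length(x))
  hit <- m > 0L
  out[hit] <- sub(pat, "\\1", regmatches(x, m), perl = TRUE)
  out
}

#' Derive independent introns from gene models
#'
#' An independent intron is an intronic interval that overlaps no exon of any
#' transcript of any gene, so that reads falling inside it are unambiguous
#' evidence of intron retention.  The exons of all isoforms of all genes are
#' merged into one union and subtracted from each gene's span; the remaining
#' maximal disjoint intervals, attributed to their parent gene, are the
#' independent introns.
#'
#' By default the exon union is strand-blind (an exon on the opposite strand
#' also excludes), reflecting that unstranded poly-A libraries cannot
#' attribute reads to a strand.  With \code{stranded = TRUE} only same-strand
#' exons exclude.
#'
#' @param models A \code{gene_models} object from [parse_gene_models()].
#' @param stranded If \code{TRUE}, subtract only exons on the gene's own
#'   strand.  Default \code{FALSE} (strand-blind).
#' @param min_length Introns shorter than this many bp are dropped (they
#'   cannot support the 8-bin coverage profile).  Default 8.
#' @return A data.frame with columns \code{chrom}, \code{start}, \code{end}
#'   (0-based half-open), \code{intron_id}, \code{strand}, \code{gene_id},
#'   \code{length}, ordered by (chrom, start, end).  Intron ids have the form
#'   \code{"<gene_id>-<chrom>:<start>-<end>"}.
#' @export
derive_independent_introns <- function(models, stranded = FALSE,
                                       min_length = 8L) {
  stopifnot(inherits(models, "gene_models"), length(models) > 0L)

  exon_list <- lapply(models, function(g) {
    ex <- do.call(rbind, g$transcripts)
    data.frame(chrom = g$chrom, start = ex[, 1L], end = ex[, 2L],
               strand = g$strand, stringsAsFactors = FALSE)
  })
  exons <- do.call(rbind, exon_list)
  exon_gr <- GenomicRanges::GRanges(
    exons$chrom,
    IRanges::IRanges(exons$start + 1L, exons$end),
    strand = if (stranded) exons$strand else "*")
  exon_union <- GenomicRanges::reduce(exon_gr, ignore.strand = !stranded)

  gchrom <- vapply(models, `[[`, character(1), "chrom")
  gstrand <- vapply(models, `[[`, character(1), "strand")
  gstart <- vapply(models, function(g) g$start, integer(1))
  gend <- vapply(models, function(g) g$end, integer(1))
  gid <- vapply(models, `[[`, character(1), "gene_id")
  spans <- GenomicRanges::GRanges(
    gchrom, IRanges::IRanges(gstart + 1L, gend),
    strand = if (stranded) gstrand else "*")

  # complement of the merged exon union within each gene span, as a single
  # vectorized gap walk (the union is disjoint, so per gene the clipped
  # pieces are disjoint and sorted)
  hits <- GenomicRanges::findOverlaps(spans, exon_union,
                                      ignore.strand = !stranded)
  q <- S4Vectors::queryHits(hits)
  cs <- pmax(GenomicRanges::start(exon_union)[S4Vectors::subjectHits(hits)] - 1L,
             gstart[q])
  ce <- pmin(GenomicRanges::end(exon_union)[S4Vectors::subjectHits(hits)],
             gend[q])
  ord <- order(q, cs)
  q <- q[ord]; cs <- cs[ord]; ce <- ce[ord]
  first <- !duplicated(q)
  last <- !duplicated(q, fromLast = TRUE)
  gap_start <- ifelse(first, gstart[q], c(NA_integer_, ce[-length(ce)]))
  gap_end <- cs
  res <- data.frame(chrom = gchrom[q], start = gap_start, end = gap_end,
                    strand = gstrand[q], gene_id = gid[q],
                    stringsAsFactors = FALSE)
  trail <- data.frame(chrom = gchrom[q[last]], start = ce[last],
                      end = gend[q[last]], strand = gstrand[q[last]],
                      gene_id = gid[q[last]], stringsAsFactors = FALSE)
  nocov <- setdiff(seq_along(models), unique(q))
  full <- data.frame(chrom = gchrom[nocov], start = gstart[nocov],
                     end = gend[nocov], strand = gstrand[nocov],
                     gene_id = gid[nocov], stringsAsFactors = FALSE)
  res <- rbind(res, trail, full)
  res <- res[!is.na(res$start) & res$end > res$start, , drop = FALSE]
  if (nrow(res) == 0L) {
    return(.empty_introns())
  }
  res$length <- res$end - res$start
  res <- res[res$length >= min_length, , drop = FALSE]
  res$intron_id <- intron_id(res$gene_id, res$chrom, res$start, res$end)
  res <- res[order(res$chrom, res$start, res$end, res$gene_id), , drop = FALSE]
  rownames(res) <- NULL
  res[, c("chrom", "start", "end", "intron_id", "strand", "gene_id", "length")]
}

.empty_introns <- function() {
  data.frame(chrom = character(), start = integer(), end = integer(),
             intron_id = character(), strand = character(),
             gene_id = character(), length = integer(),
             stringsAsFactors = FALSE)
}

#' Compose / decompose intron identifiers
#'
#' Intron ids are self-describing: \code{"<gene_id>-<chrom>:<start>-<end>"}
#' with coordinates as in the BED file (0-based half-open).
#'
#' @param gene_id,chrom,start,end Vectors describing the introns.
#' @return For \code{intron_id}, a character vector of ids; for
#'   \code{parse_intron_id}, a data.frame with the four components (fields
#'   are \code{NA} where an id does not match the scheme).
#' @export
intron_id <- function(gene_id, chrom, start, end) {
  sprintf("%s-%s:%s-%s", gene_id, chrom, start, end)
}

#' @rdname intron_id
#' @param id Character vector of intron ids.
#' @export
parse_intron_id <- function(id) {
  pat <- "^(.*)-([^:-]+):([0-9]+)-([0-9]+)$"
  ok <- grepl(pat, id)
  data.frame(
    gene_id = ifelse(ok, sub(pat, "\\1", id), NA_character_),
    chrom = ifelse(ok, sub(pat, "\\2", id), NA_character_),
    start = ifelse(ok, as.integer(sub(pat, "\\3", id)), NA_integer_),
    end = ifelse(ok, as.integer(sub(pat, "\\4", id)), NA_integer_),
    stringsAsFactors = FALSE)
}

#' Write independent introns to a BED6 file
#'
#' @param introns Intron data.frame as returned by
#'   [derive_independent_introns()].
#' @param file Output path.
#' @return Invisibly, \code{file}.
#' @export
write_intron_bed <- function(introns, file) {
  df <- data.frame(introns$chrom, introns$start, introns$end,
                   introns$intron_id, rep(0L, nrow(introns)),
                   introns$strand)
  utils::write.table(df, file, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(file)
}

#' Read independent introns from a BED file
#'
#' Coordinates are interpreted as 0-based half-open (BED standard).  The
#' parent gene id is recovered from the name field when it follows the
#' \code{"<gene_id>-<chrom>:<start>-<end>"} scheme; otherwise the name is
#' used as-is for both id and gene.
#'
#' @param file Path to a BED file with at least 3 columns (chrom, start,
#'   end); columns 4 and 6 are used as name and strand when present.
#' @return An intron data.frame as from [derive_independent_introns()].
#' @export
read_intron_bed <- function(file) {
  lines <- readLines(file)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) return(.empty_introns())
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 3L)) {
    stop("malformed BED line ", which(nf < 3L)[1L], ": fewer than 3 columns")
  }
  chrom <- vapply(fields, `[[`, character(1), 1L)
  start <- suppressWarnings(as.integer(vapply(fields, `[[`, character(1), 2L)))
  end <- suppressWarnings(as.integer(vapply(fields, `[[`, character(1), 3L)))
  bad <- which(is.na(start) | is.na(end) | end <= start)
  if (length(bad)) {
    stop("invalid interval at BED line ", bad[1L],
         ": end must be greater than start")
  }
  name <- ifelse(nf >= 4L, vapply(fields, function(f) f[min(4L, length(f))],
                                  character(1)), NA_character_)
  strand <- ifelse(nf >= 6L, vapply(fields, function(f) f[min(6L, length(f))],
                                    character(1)), "+")
  strand[!strand %in% c("+", "-")] <- "+"
  name[is.na(name)] <- paste0(chrom[is.na(name)], ":", start[is.na(name)],
                              "-", end[is.na(name)])
  parsed <- parse_intron_id(name)
  gene_id <- ifelse(is.na(parsed$gene_id), name, parsed$gene_id)
  res <- data.frame(chrom = chrom, start = start, end = end,
                    intron_id = name, strand = strand, gene_id = gene_id,
                    length = end - start, stringsAsFactors = FALSE)
  res[order(res$chrom, res$start, res$end), , drop = FALSE]
}

# Introns as GRanges (1-based closed, internal use)
.introns_granges <- function(introns) {
  GenomicRanges::GRanges(introns$chrom,
                         IRanges::IRanges(introns$start + 1L, introns$end))
}
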