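# Fixture builders and independent brute-force oracles.
# All coordinates in fixture specs are 0-based half-open (converted to the
# 1-based conventions of GTF/SAM only at write time).

# genes: list of list(gene_id, chrom, strand, transcripts = list of 2-col
# matrices of exon start/end). Writes an ENSEMBL-dialect GTF.
write_toy_gtf <- function(genes, file = tempfile(fileext = ".gtf"),
                          gene_feature = TRUE) {
  lines <- character(0)
  for (g in genes) {
    ex_all <- do.call(rbind, g$transcripts)
    gs <- min(ex_all[, 1L]); ge <- max(ex_all[, 2L])
    if (gene_feature) {
      lines <- c(lines, paste(g$chrom, "toy", "gene", gs + 1L, ge, ".",
                              g$strand, ".",
                              sprintf('gene_id "%s";', g$gene_id),
                              sep = "\t"))
    }
    for (ti in seq_along(g$transcripts)) {
      ex <- g$transcripts[[ti]]
      tid <- sprintf("%s.t%d", g$gene_id, ti)
      at <- sprintf('gene_id "%s"; transcript_id "%s";', g$gene_id, tid)
      lines <- c(lines,
                 paste(g$chrom, "toy", "transcript", min(ex[, 1L]) + 1L,
                       max(ex[, 2L]), ".", g$strand, ".", at, sep = "\t"),
                 paste(g$chrom, "toy", "exon", ex[, 1L] + 1L, ex[, 2L],
                       ".", g$strand, ".", at, sep = "\t"))
    }
  }
  writeLines(lines, file)
  file
}

# Per-base oracle for independent introns: mark every base covered by any
# exon (of any gene; same strand only if stranded), then report maximal
# unmarked runs inside each gene span.
oracle_independent_introns <- function(genes, stranded = FALSE,
                                       min_length = 8L) {
  res <- list()
  for (g in genes) {
    span <- range(do.call(rbind, g$transcripts))
    gs <- min(span); ge <- max(span)
    covered <- rep(FALSE, ge - gs)
    for (h in genes) {
      if (h$chrom != g$chrom) next
      if (stranded && h$strand != g$strand) next
      for (ex in h$transcripts) {
        for (r in seq_len(nrow(ex))) {
          lo <- max(ex[r, 1L], gs); hi <- min(ex[r, 2L], ge)
          if (hi > lo) covered[(lo - gs + 1L):(hi - gs)] <- TRUE
        }
      }
    }
    r <- rle(covered)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths
    free <- which(!r$values)
    for (i in free) {
      st <- gs + starts[i]; en <- gs + ends[i]
      if (en - st >= min_length) {
        res[[length(res) + 1L]] <- data.frame(
          chrom = g$chrom, start = st, end = en, gene_id = g$gene_id,
          stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(res)) {
    return(data.frame(chrom = character(), start = integer(),
                      end = integer(), gene_id = character()))
  }
  out <- do.call(rbind, res)
  out[order(out$chrom, out$start, out$end, out$gene_id), , drop = FALSE]
}

# Random small multi-gene annotations for property tests (coordinates fit
# in a few kb).
random_toy_genes <- function(n_genes = 3L, chroms = c("c1", "c2")) {
  genes <- list()
  for (i in seq_len(n_genes)) {
    chrom <- sample(chroms, 1L)
    origin <- sample(0:2000, 1L)
    n_ex <- sample(2:5, 1L)
    ex_len <- sample(30:120, n_ex, replace = TRUE)
    in_len <- sample(20:400, n_ex - 1L, replace = TRUE)
    starts <- origin + c(0L, cumsum(ex_len[-n_ex] + in_len))
    exons <- cbind(starts, starts + ex_len)
    txs <- list(exons)
    if (n_ex > 2L && stats::runif(1) < 0.7) {
      keep <- sort(c(1L, sample(2:(n_ex - 1L), sample(n_ex - 2L, 1L)), n_ex))
      txs[[2L]] <- exons[unique(keep), , drop = FALSE]
    }
    genes[[i]] <- list(gene_id = sprintf("g%d", i), chrom = chrom,
                       strand = sample(c("+", "-"), 1L), transcripts = txs)
  }
  genes
}

# Minimal SAM writer for constructed alignment fixtures.
# records: data.frame with qname, flag, chrom, pos (1-based), cigar and
# optionally rnext/pnext/tlen; seq/qual synthesized to match the CIGAR.
write_toy_sam <- function(records, file = tempfile(fileext = ".sam"),
                          chrom_len = c(chr1 = 100000L, chr2 = 100000L)) {
  header <- c("@HD\tVN:1.6\tSO:coordinate",
              sprintf("@SQ\tSN:%s\tLN:%d", names(chrom_len), chrom_len))
  qlen <- vapply(records$cigar, function(cg) {
    ops <- regmatches(cg, gregexpr("[0-9]+[MIDNSHP=X]", cg))[[1]]
    sum(vapply(ops, function(o) {
      n <- as.integer(sub("[A-Z=]", "", o))
      if (grepl("[MIS=X]", o)) n else 0L
    }, integer(1)))
  }, integer(1))
  rnext <- if ("rnext" %in% names(records)) records$rnext else "*"
  pnext <- if ("pnext" %in% names(records)) records$pnext else 0L
  tlen <- if ("tlen" %in% names(records)) records$tlen else 0L
  lines <- paste(records$qname, records$flag, records$chrom, records$pos,
                 255L, records$cigar, rnext, pnext, tlen,
                 strrep("A", qlen), strrep("I", qlen), sep = "\t")
  writeLines(c(header, lines), file)
  file
}

# Single-end record helper
se_rec <- function(qname, chrom, pos0, cigar, flag = 0L) {
  data.frame(qname = qname, flag = flag, chrom = chrom, pos = pos0 + 1L,
             cigar = cigar, stringsAsFactors = FALSE)
}

# Exhaustive base-level oracle for fragment/intron overlap classification.
oracle_overlap <- function(blocks, start, end) {
  intron_bases <- if (end > start) seq(start, end - 1L) else integer(0)
  cls <- "none"
  for (r in seq_len(nrow(blocks))) {
    bases <- seq(blocks[r, 1L], blocks[r, 2L] - 1L)
    inside <- bases %in% intron_bases
    if (any(inside)) {
      if (any(!inside)) return("junction")
      cls <- "internal"
    }
  }
  cls
}

# Brute-force AUC: mean over all positive-negative pairs, ties count half.
oracle_auc <- function(scores, labels) {
  pos <- scores[as.logical(labels)]
  neg <- scores[!as.logical(labels)]
  tot <- 0
  for (p in pos) for (n in neg) {
    tot <- tot + if (p > n) 1 else if (p == n) 0.5 else 0
  }
  tot / (length(pos) * length(neg))
}

# Small simulated dataset shared across tests (cheap: ~10 genes).
toy_sim <- function(n_genes = 10L, seed = 11L, ...) {
  cfg <- sim_config(n_genes = n_genes, seed = seed, ...)
  simulate_ir_dataset(cfg, dir = tempfile("sim"), basename = "toy")
}

# Comparison harness: package derivation vs the per-base oracle, with the
# oracle result lifted into the package's column layout.
oracle_vs_pkg <- function(genes, stranded = FALSE) {
  models <- parse_gene_models(write_toy_gtf(genes))
  pkg <- derive_independent_introns(models, stranded = stranded)
  orc <- oracle_independent_introns(genes, stranded = stranded)
  rownames(orc) <- NULL
  ids <- intron_id(orc$gene_id, orc$chrom, orc$start, orc$end)
  list(pkg = pkg[, c("chrom", "start", "end", "gene_id")],
       oracle_as_pkg = data.frame(
         chrom = orc$chrom, start = orc$start, end = orc$end,
         intron_id = ids,
         strand = pkg$strand[match(ids, pkg$intron_id)],
         gene_id = orc$gene_id, length = orc$end - orc$start,
         stringsAsFactors = FALSE))
}
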