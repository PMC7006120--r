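test_that("GTF parsing builds one model per gene with converted coordinates", {
  genes <- list(list(
    gene_id = "gA", chrom = "c1", strand = "+",
    transcripts = list(cbind(c(100L, 300L, 500L), c(200L, 400L, 600L)),
                       cbind(c(100L, 500L), c(200L, 600L)))))
  gtf <- write_toy_gtf(genes)
  models <- parse_gene_models(gtf)
  expect_length(models, 1L)
  expect_length(models$gA$transcripts, 2L)
  # GTF 1-based closed [101,200] -> internal [100,200)
  expect_equal(unname(models$gA$transcripts[[1]][1, ]), c(100L, 200L))
  expect_equal(models$gA$start, 100L)
  expect_equal(models$gA$end, 600L)
})

test_that("strands are preserved and gene span falls back to exon range", {
  genes <- list(
    list(gene_id = "gP", chrom = "c1", strand = "+",
         transcripts = list(cbind(c(0L, 200L), c(100L, 300L)))),
    list(gene_id = "gM", chrom = "c1", strand = "-",
         transcripts = list(cbind(c(1000L, 1200L), c(1100L, 1300L)))))
  models <- parse_gene_models(write_toy_gtf(genes, gene_feature = FALSE))
  expect_equal(vapply(models, `[[`, character(1), "strand"),
               c(gP = "+", gM = "-"))
  expect_equal(models$gM$start, 1000L)
  expect_equal(models$gM$end, 1300L)
})

test_that("malformed GTF input fails with a line-numbered error", {
  f <- tempfile(fileext = ".gtf")
  writeLines(c("c1\ttoy\texon\t1\t100\t.\t+\t.\tgene_id \"g\"; transcript_id \"t\";",
               "c1\ttoy\texon\tnot\tenough"), f)
  expect_error(parse_gene_models(f), "line 2")

  writeLines(c("c1\ttoy\texon\t1\t100\t.\t+\t.\tgene_id \"g\";"), f)
  expect_error(parse_gene_models(f), "transcript_id")
})

test_that("textbook exon subtraction yields the single gap", {
  genes <- list(list(gene_id = "g", chrom = "c1", strand = "+",
                     transcripts = list(cbind(c(0L, 200L), c(100L, 300L)))))
  introns <- derive_independent_introns(
    parse_gene_models(write_toy_gtf(genes)))
  expect_equal(nrow(introns), 1L)
  expect_equal(introns$start, 100L)
  expect_equal(introns$end, 200L)
  expect_equal(introns$gene_id, "g")
  expect_equal(introns$length, 100L)
  expect_equal(introns$intron_id, "g-c1:100-200")
})

test_that("an exon of an overlapping gene suppresses the intron", {
  genes <- list(
    list(gene_id = "gA", chrom = "c1", strand = "+",
         transcripts = list(cbind(c(0L, 200L), c(100L, 300L)))),
    list(gene_id = "gB", chrom = "c1", strand = "+",
         transcripts = list(cbind(50L, 250L))))
  introns <- derive_independent_introns(
    parse_gene_models(write_toy_gtf(genes)))
  expect_false(any(introns$gene_id == "gA" &
                     introns$start < 250L & introns$end > 50L))
  expect_equal(introns, oracle_vs_pkg(genes)$oracle_as_pkg)
})

test_that("an internal exon of a second isoform splits the intron", {
  genes <- list(list(
    gene_id = "g", chrom = "c1", strand = "+",
    transcripts = list(cbind(c(0L, 200L), c(100L, 300L)),
                       cbind(c(0L, 120L, 200L), c(100L, 180L, 300L)))))
  introns <- derive_independent_introns(
    parse_gene_models(write_toy_gtf(genes)))
  expect_equal(introns$start, c(100L, 180L))
  expect_equal(introns$end, c(120L, 200L))
})

test_that("derivation matches the per-base oracle on random annotations", {
  set.seed(402)
  for (rep in 1:8) {
    genes <- random_toy_genes(n_genes = sample(2:4, 1L))
    cmp <- oracle_vs_pkg(genes)
    orc <- cmp$oracle_as_pkg[, c("chrom", "start", "end", "gene_id")]
    rownames(cmp$pkg) <- rownames(orc) <- NULL
    expect_equal(cmp$pkg, orc)
  }
})

test_that("strand-blind subtraction excludes antisense exons, stranded mode relaxes", {
  genes <- list(
    list(gene_id = "gF", chrom = "c1", strand = "+",
         transcripts = list(cbind(c(0L, 500L), c(100L, 600L)))),
    list(gene_id = "gR", chrom = "c1", strand = "-",
         transcripts = list(cbind(c(200L, 700L), c(300L, 800L)))))
  blind <- derive_independent_introns(parse_gene_models(write_toy_gtf(genes)))
  aware <- derive_independent_introns(parse_gene_models(write_toy_gtf(genes)),
                                      stranded = TRUE)
  gf_blind <- blind[blind$gene_id == "gF", ]
  gf_aware <- aware[aware$gene_id == "gF", ]
  # antisense exon [200,300) cuts gF's intron only in strand-blind mode
  expect_true(all(gf_blind$end <= 200L | gf_blind$start >= 300L))
  expect_true(any(gf_aware$start <= 200L & gf_aware$end >= 300L))
  # both modes agree with their oracle
  expect_equal(aware[, c("chrom", "start", "end", "gene_id")],
               oracle_vs_pkg(genes, stranded = TRUE)$oracle_as_pkg[
                 , c("chrom", "start", "end", "gene_id")])
})

test_that("output intervals are disjoint within a gene and shrink monotonically", {
  set.seed(77)
  for (rep in 1:5) {
    genes <- random_toy_genes(n_genes = 2L)
    base <- derive_independent_introns(parse_gene_models(write_toy_gtf(genes)))
    for (g in unique(base$gene_id)) {
      sub <- base[base$gene_id == g, ]
      if (nrow(sub) > 1L) {
        expect_true(all(sub$start[-1L] >= sub$end[-nrow(sub)]))
      }
    }
    if (nrow(base) == 0L) next
    # add a transcript covering part of the first intron of gene 1
    tgt <- base[base$gene_id == genes[[1]]$gene_id, ][1, ]
    if (is.na(tgt$start)) next
    mid <- (tgt$start + tgt$end) %/% 2L
    genes[[1]]$transcripts <- c(genes[[1]]$transcripts,
                                list(cbind(tgt$start, mid)))
    after <- derive_independent_introns(
      parse_gene_models(write_toy_gtf(genes)))
    # every new interval is contained in some old interval
    for (i in seq_len(nrow(after))) {
      container <- base$chrom == after$chrom[i] &
        base$start <= after$start[i] & base$end >= after$end[i]
      expect_true(any(container))
    }
  }
})

test_that("intron BED round-trips losslessly", {
  genes <- random_toy_genes(n_genes = 3L)
  introns <- derive_independent_introns(parse_gene_models(write_toy_gtf(genes)))
  f <- tempfile(fileext = ".bed")
  write_intron_bed(introns, f)
  back <- read_intron_bed(f)
  rownames(back) <- rownames(introns) <- NULL
  expect_equal(back, introns)

  line1 <- readLines(f)[1]
  expect_match(line1, "^\\S+\t[0-9]+\t[0-9]+\t\\S+\t0\t[+-]$")

  # empty collection -> empty file -> empty collection
  empty <- introns[0, ]
  write_intron_bed(empty, f)
  expect_identical(readLines(f), character(0))
  expect_equal(nrow(read_intron_bed(f)), 0L)
})

test_that("invalid BED intervals fail with a line number", {
  f <- tempfile(fileext = ".bed")
  writeLines(c("c1\t10\t20\tok\t0\t+", "c1\t30\t30\tbad\t0\t+"), f)
  expect_error(read_intron_bed(f), "line 2")
})
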