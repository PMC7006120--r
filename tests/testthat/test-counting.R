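test_that("CIGAR walks produce the expected aligned blocks", {
  # simple match (0-based start 100)
  expect_equal(fragment_blocks(101L, "50M")[[1]],
               cbind(start = 100L, end = 150L))
  # N splits blocks, the gap is uncovered
  expect_equal(fragment_blocks(101L, "20M1000N30M")[[1]],
               cbind(start = c(100L, 1120L), end = c(120L, 1150L)))
  # D extends the current block (reference is covered through a deletion)
  expect_equal(fragment_blocks(1L, "10M5D10M")[[1]],
               cbind(start = 0L, end = 25L))
  # soft clips and insertions consume no reference
  expect_equal(fragment_blocks(11L, "5S10M2I10M")[[1]],
               cbind(start = 10L, end = 30L))
})

test_that("overlap classification distinguishes none/internal/junction", {
  intron <- c(0L, 1000L)
  expect_equal(overlaps_intron(cbind(100L, 150L), 0L, 1000L), "internal")
  # block straddles the 3' boundary
  expect_equal(overlaps_intron(cbind(990L, 1040L), 0L, 1000L), "junction")
  # spliced fragment whose N-gap exactly spans the intron
  blocks <- cbind(c(0L, 1120L), c(20L, 1150L))
  expect_equal(overlaps_intron(blocks, 20L, 1120L), "none")
})

test_that("overlap classification matches the exhaustive base-level oracle", {
  intron <- c(100L, 200L)
  fixtures <- list(
    cbind(120L, 170L),                      # internal
    cbind(95L, 130L),                       # straddles start
    cbind(180L, 230L),                      # straddles end
    cbind(95L, 230L),                       # spans whole intron
    cbind(c(60L, 200L), c(100L, 260L)),     # gap exactly spans intron
    cbind(c(60L, 199L), c(100L, 260L)),     # second block 1 bp inside
    cbind(c(60L, 150L), c(99L, 170L)),      # one out, one internal
    cbind(10L, 60L),                        # entirely upstream
    cbind(100L, 200L),                      # exact cover
    cbind(c(100L, 150L), c(120L, 200L)))    # two internal blocks
  for (b in fixtures) {
    expect_equal(overlaps_intron(b, intron[1], intron[2]),
                 oracle_overlap(b, intron[1], intron[2]),
                 info = paste(deparse(b), collapse = ""))
  }
})

test_that("profiles count internal and junction fragments per intron", {
  introns <- read_intron_bed(local({
    f <- tempfile(fileext = ".bed")
    writeLines(c("chr1\t1000\t2000\tg-chr1:1000-2000\t0\t+",
                 "chr1\t3000\t4000\tg-chr1:3000-4000\t0\t+"), f)
    f
  }))
  recs <- rbind(
    se_rec("r1", "chr1", 1100L, "50M"),      # internal intron 1
    se_rec("r2", "chr1", 1980L, "50M"),      # junction (straddles end)
    se_rec("r3", "chr1", 950L, "20M1130N50M"),  # gap spans intron 1 -> none
    se_rec("r4", "chr1", 2500L, "50M"))      # between introns -> none
  prof <- count_profiles(write_toy_sam(recs), introns)
  expect_equal(prof$profiles$T, c(2L, 0L))
  expect_equal(prof$profiles$J, c(1L, 0L))
  expect_equal(prof$library_total, 4L)
})

test_that("a fragment overlapping two adjacent introns increments both", {
  f <- tempfile(fileext = ".bed")
  writeLines(c("chr1\t100\t200\ta-chr1:100-200\t0\t+",
               "chr1\t200\t300\tb-chr1:200-300\t0\t+"), f)
  introns <- read_intron_bed(f)
  sam <- write_toy_sam(se_rec("r1", "chr1", 150L, "100M"))  # [150,250)
  prof <- count_profiles(sam, introns)$profiles
  expect_equal(prof$T, c(1L, 1L))
  expect_equal(prof$J, c(1L, 1L))
})

test_that("paired mates are one fragment; junction is the OR of the mates", {
  f <- tempfile(fileext = ".bed")
  writeLines("g\t1000\t2000\tg-chr1:1000-2000\t0\t+", f)
  # malformed name field on purpose: external BED, name used verbatim
  introns <- read_intron_bed(f)
  introns$chrom <- "chr1"
  recs <- data.frame(
    qname = c("p1", "p1", "p2", "p2"),
    flag = c(99L, 147L, 99L, 147L),
    chrom = "chr1",
    pos = c(1101L, 1301L, 981L, 1501L),  # p2 mate1 straddles start
    cigar = "50M", stringsAsFactors = FALSE)
  prof <- count_profiles(write_toy_sam(recs), introns)
  expect_equal(prof$profiles$T, 2L)   # two fragments, not four reads
  expect_equal(prof$profiles$J, 1L)   # only p2 straddles
  expect_equal(prof$library_total, 2L)
})

test_that("secondary and supplementary records are excluded, mapq filter works", {
  f <- tempfile(fileext = ".bed")
  writeLines("chr1\t1000\t2000\tg-chr1:1000-2000\t0\t+", f)
  introns <- read_intron_bed(f)
  recs <- rbind(se_rec("r1", "chr1", 1100L, "50M", flag = 0L),
                se_rec("r2", "chr1", 1100L, "50M", flag = 256L),   # secondary
                se_rec("r3", "chr1", 1100L, "50M", flag = 2048L))  # supplementary
  prof <- count_profiles(write_toy_sam(recs), introns)
  expect_equal(prof$profiles$T, 1L)
  expect_equal(prof$library_total, 1L)

  # MAPQ 255 records survive a low threshold, die above it
  prof2 <- count_profiles(read_fragments(write_toy_sam(recs),
                                         min_mapq = 256L), introns)
  expect_equal(prof2$profiles$T, 0L)
})

test_that("counting is invariant to record order and conserves totals", {
  set.seed(5)
  sim <- toy_sim(n_genes = 6L, seed = 21L, paired = FALSE)
  introns <- sim$introns
  prof <- count_profiles(sim$sam, introns)$profiles

  # conservation: sum of bins == T, J <= T
  expect_equal(rowSums(prof[, paste0("n", 1:8)]), as.numeric(prof$T),
               ignore_attr = TRUE)
  expect_true(all(prof$J <= prof$T))

  # shuffle the alignment records
  lines <- readLines(sim$sam)
  hdr <- grepl("^@", lines)
  shuf <- c(lines[hdr], sample(lines[!hdr]))
  f2 <- tempfile(fileext = ".sam")
  writeLines(shuf, f2)
  prof2 <- count_profiles(f2, introns)$profiles
  expect_equal(prof2, prof)
})

test_that("removing junction fragments zeroes J without touching internals", {
  f <- tempfile(fileext = ".bed")
  writeLines("chr1\t1000\t2000\tg-chr1:1000-2000\t0\t+", f)
  introns <- read_intron_bed(f)
  internal <- rbind(se_rec("i1", "chr1", 1100L, "50M"),
                    se_rec("i2", "chr1", 1500L, "50M"))
  junction <- rbind(se_rec("j1", "chr1", 980L, "50M"),
                    se_rec("j2", "chr1", 1970L, "50M"))
  both <- count_profiles(write_toy_sam(rbind(internal, junction)),
                         introns)$profiles
  only_int <- count_profiles(write_toy_sam(internal), introns)$profiles
  expect_equal(both$T, 4L)
  expect_equal(both$J, 2L)
  expect_equal(only_int$J, 0L)
  expect_equal(only_int$T, 2L)
})

test_that("bin boundaries tile the intron exactly", {
  b <- bin_boundaries(0L, 801L)
  w <- diff(b)
  expect_true(all(w %in% c(100L, 101L)))
  expect_equal(sum(w), 801L)
  expect_equal(b[1], 0L)
  expect_equal(b[9], 801L)
  # short intron: boundaries may repeat but still tile
  b2 <- bin_boundaries(10L, 15L)
  expect_equal(sum(diff(b2)), 5L)
})

test_that("midpoint rule assigns boundary fragments to outer bins", {
  expect_equal(bin_assign(cbind(0L, 50L), 0L, 800L), 1L)
  expect_equal(bin_assign(cbind(750L, 800L), 0L, 800L), 8L)
  # fragment extending past the end still lands in bin 8
  expect_equal(bin_assign(cbind(780L, 900L), 0L, 800L), 8L)
  expect_true(is.na(bin_assign(cbind(900L, 950L), 0L, 800L)))
})
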