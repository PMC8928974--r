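# brute-force overlap oracle: try every overlap length, count matches
brute_merge <- function(r1, r2_as_sequenced, min_overlap, max_rate = 0.1) {
  r2 <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(r2_as_sequenced)))
  best <- list(len = 0L, matches = -1L, mm = 0L)
  for (L in min_overlap:min(nchar(r1), nchar(r2))) {
    a <- substr(r1, nchar(r1) - L + 1, nchar(r1))
    b <- substr(r2, 1, L)
    mm <- hamming(a, b)
    if (mm <= floor(max_rate * L) && (L - mm) > best$matches)
      best <- list(len = L, matches = L - mm, mm = mm)
  }
  best
}

test_that("pair merging matches the brute-force overlap oracle", {
  res <- merge_pair("ACGTACGT", as.character(Biostrings::reverseComplement(
    Biostrings::DNAString("GTACGTTT"))), min_overlap = 4)
  expect_equal(res$sequence, "ACGTACGTTT")
  expect_equal(res$overlap, 6L)
  expect_equal(res$mismatches, 0L)
  set.seed(31)
  for (i in 1:25) {
    frag <- random_dna(60)
    r1 <- substr(frag, 1, 40)
    r2 <- as.character(Biostrings::reverseComplement(
      Biostrings::DNAString(substr(frag, 21, 60))))
    got <- merge_pair(r1, r2, min_overlap = 10)
    oracle <- brute_merge(r1, r2, 10L)
    expect_equal(got$overlap, oracle$len)
    expect_equal(got$mismatches, oracle$mm)
    if (oracle$len == 20L) expect_equal(got$sequence, frag)
  }
})

test_that("full-length identical pairs merge to a single read length", {
  r1 <- random_dna(30, seed = 7)
  r2 <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(r1)))
  res <- merge_pair(r1, r2)
  expect_equal(res$overlap, 30L)
  expect_equal(res$sequence, r1)
  expect_equal(nchar(res$sequence), 30L)
})

test_that("pairs without an admissible overlap are rejected, not errors", {
  res <- merge_pair(strrep("A", 30), strrep("A", 30), min_overlap = 20)
  # r2 revcomps to poly-T: no >= 20 nt window within the mismatch cap
  expect_false(res$merged)
  expect_true(is.na(res$sequence))
})

test_that("consensus takes the higher-quality base at disagreements", {
  # 10 nt fragment, full overlap, conflicting center base
  r1 <- "ACGTACGTAC"
  r2_seq <- "ACGTTCGTAC"  # disagree at position 5 (A vs T)
  r2 <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(r2_seq)))
  hi <- strrep("I", 10); lo <- strrep("#", 10)
  res_hi2 <- merge_pair(r1, r2, q1 = lo, q2 = hi, min_overlap = 5)
  expect_equal(substr(res_hi2$sequence, 5, 5), "T")
  res_hi1 <- merge_pair(r1, r2, q1 = hi, q2 = lo, min_overlap = 5)
  expect_equal(substr(res_hi1$sequence, 5, 5), "A")
  expect_equal(res_hi1$mismatches, 1L)
})

test_that("demultiplexing assigns by primer/index within tolerances", {
  samples <- expand.grid(cell_line = c("A", "B", "C"),
                         fraction = c("DNA", "RNA"), replicate = 1:3,
                         stringsAsFactors = FALSE)
  sheet <- build_sample_sheet(samples)
  primers <- default_primers(); indexes <- default_indexes()
  layout <- amplicon_layout()
  mk <- function(p, i) paste0(primers[p], indexes[i], random_dna(100))
  set.seed(2)
  target <- sheet[sheet$primer_set == 3 & sheet$index == 1, "sample_id"]
  r <- mk(3, 1)
  expect_equal(demultiplex(r, sheet, layout)$sample, target)
  # one substitution in the primer is tolerated by default
  r_mut <- r
  substr(r_mut, 5, 5) <- setdiff(c("A","C","G","T"), substr(r, 5, 5))[1]
  expect_equal(demultiplex(r_mut, sheet, layout)$sample, target)
  # one substitution in the index is not (max_index_mm = 0)
  r_idx <- r
  substr(r_idx, 22, 22) <- setdiff(c("A","C","G","T"), substr(r, 22, 22))[1]
  expect_true(is.na(demultiplex(r_idx, sheet, layout)$sample))
  expect_equal(demultiplex(r_idx, sheet, layout, max_index_mm = 1)$sample,
               target)
  # unknown (primer, index) combination -> unassigned
  r_na <- paste0(strrep("N", 28), random_dna(100))
  expect_true(is.na(demultiplex(r_na, sheet, layout)$sample))
})

test_that("equidistant primer matches are ambiguous and unassigned", {
  p1 <- paste0("AA", random_dna(18, seed = 5))
  p2 <- p1; substr(p2, 1, 2) <- "CC"
  query <- p1; substr(query, 1, 2) <- "AC"  # distance 1 from both
  sheet <- data.frame(sample_id = c("s1", "s2"), cell_line = "X",
                      fraction = "DNA", replicate = 1:2,
                      primer_set = 1:2, index = 1L)
  layout <- amplicon_layout()
  idx <- default_indexes()
  read <- paste0(query, idx[1], random_dna(100))
  dm <- demultiplex(read, sheet, layout, primers = c(p1, p2),
                    max_primer_mm = 1)
  expect_true(is.na(dm$sample))
  expect_true(dm$ambiguous)
})

test_that("duplicate (primer, index) pairs in the sheet are a config error", {
  sheet <- data.frame(sample_id = c("s1", "s2"), cell_line = "X",
                      fraction = "DNA", replicate = 1:2,
                      primer_set = 1L, index = 1L)
  expect_error(demultiplex("ACGT", sheet), "duplicate")
})

test_that("barcode counting is exact by default and mismatch-aware on request", {
  lib <- make_library(3)
  layout <- amplicon_layout()
  head28 <- paste0(default_primers()[1], default_indexes()[1])
  mk <- function(bc) paste0(head28, bc, strrep("T", 30))
  reads <- c(rep(mk(lib$barcode[1]), 10), rep(mk(lib$barcode[2]), 5))
  bc <- count_barcodes(reads, lib, layout)
  expect_equal(sum(bc$construct == lib$construct_id[1]), 10L)
  expect_equal(sum(bc$construct == lib$construct_id[2]), 5L)
  # one substitution: unassigned at mm 0, assigned at mm 1
  mut <- lib$barcode[1]
  substr(mut, 3, 3) <- setdiff(c("A","C","G","T"), substr(mut, 3, 3))[1]
  expect_true(is.na(count_barcodes(mk(mut), lib, layout)$construct))
  expect_equal(count_barcodes(mk(mut), lib, layout,
                              max_barcode_mm = 1)$construct,
               lib$construct_id[1])
  # a read within distance 1 of two barcodes is ambiguous
  bmap <- data.frame(barcode = c("AAAAAAAAAAAAAAA", "AAAAAAAAAAAAACC"),
                     construct_id = c("c1", "c2"))
  q <- "AAAAAAAAAAAAAAC"  # distance 1 from both
  r <- count_barcodes(paste0(head28, q, strrep("T", 30)), bmap, layout,
                      max_barcode_mm = 1)
  expect_true(is.na(r$construct))
  expect_true(r$ambiguous)
  dup <- data.frame(barcode = c("AAA", "AAA"), construct_id = c("a", "b"))
  expect_error(count_barcodes("x", dup, layout), "duplicate")
})

test_that("read accounting is conserved and order-independent", {
  lib <- make_library(8)
  cfg <- sim_config(n_snps = 8, read_depth = 1500, seed = 12,
                    per_base_error_rate = 0.02)
  tr <- plant_truth(lib, cfg)
  cnt <- simulate_counts(tr, cfg)
  sheet <- build_sample_sheet(attr(cnt, "sample_info"))
  r1 <- tempfile(fileext = ".fastq"); r2 <- tempfile(fileext = ".fastq")
  simulate_fastq(cnt, lib, sheet, cfg, r1, r2)
  cc <- suppressWarnings(count_reads(r1, r2, lib, sheet, max_barcode_mm = 1))
  # conservation: per-sample assigned + unassigned = reads routed there
  expect_equal(cc$qc$assigned + cc$qc$barcode_unassigned, cc$qc$reads)
  expect_equal(sum(cc$qc$reads) + cc$run_qc$merge_rejected +
                 cc$run_qc$demux_unassigned, cc$run_qc$pairs)
  # order independence: shuffle the FASTQ records
  fq1 <- suppressWarnings(read_fastq(r1)); fq2 <- suppressWarnings(read_fastq(r2))
  set.seed(1); perm <- sample(length(fq1$seq))
  r1s <- tempfile(fileext = ".fastq"); r2s <- tempfile(fileext = ".fastq")
  writeLines(as.vector(rbind(paste0("@", fq1$id[perm]), fq1$seq[perm],
                             "+", fq1$qual[perm])), r1s)
  writeLines(as.vector(rbind(paste0("@", fq2$id[perm]), fq2$seq[perm],
                             "+", fq2$qual[perm])), r2s)
  cc2 <- suppressWarnings(count_reads(r1s, r2s, lib, sheet, max_barcode_mm = 1))
  expect_identical(cc$counts, cc2$counts)
})

test_that("count tables round-trip through TSV", {
  lib <- make_library(4)
  cfg <- sim_config(n_snps = 4, read_depth = 800, seed = 2)
  cnt <- simulate_counts(plant_truth(lib, cfg), cfg)
  tf <- tempfile(fileext = ".tsv")
  write_count_table(cnt, tf)
  back <- read_count_table(tf)
  expect_equal(unname(back), unname(cnt + 0L), ignore_attr = TRUE)
  expect_equal(rownames(back), rownames(cnt))
})
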