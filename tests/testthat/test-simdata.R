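test_that("plant_truth honors the regulatory fraction exactly", {
  lib <- make_library(300)
  cfg <- sim_config(n_snps = 300, fraction_regulatory = 0.1, seed = 5)
  tr <- plant_truth(lib, cfg)
  expect_equal(sum(tr$snps$is_regulatory), 30L)
  cfg0 <- sim_config(n_snps = 300, fraction_regulatory = 0, seed = 5)
  tr0 <- plant_truth(lib, cfg0)
  expect_true(all(tr0$snps$true_fold == 1))
  expect_false(any(tr0$snps$is_regulatory))
})

test_that("fully regulatory panel with fixed fold is planted as configured", {
  lib <- make_library(20)
  cfg <- sim_config(n_snps = 20, fraction_regulatory = 1,
                    fold_range = c(2, 2), regulatory_anchor = 1.0,
                    fraction_up = 1, seed = 2)
  tr <- plant_truth(lib, cfg)
  expect_true(all(tr$snps$is_regulatory))
  expect_equal(tr$snps$true_fold, rep(2, 20))
  expect_equal(tr$snps$activity_normal, rep(1, 20))
  expect_equal(tr$snps$activity_risk, rep(2, 20))
  # blank activity is exactly 1 by definition
  expect_equal(tr$constructs$true_activity[
    tr$constructs$allele_class == "blank"], 1)
})

test_that("regulatory folds must lie strictly above 1", {
  lib <- make_library(5)
  cfg <- sim_config(n_snps = 5, fraction_regulatory = 0.5,
                    fold_range = c(1, 2))
  expect_error(plant_truth(lib, cfg), "strictly above 1")
})

test_that("count columns sum to the configured depth and are reproducible", {
  lib <- make_library(30)
  cfg <- sim_config(n_snps = 30, read_depth = 50000, seed = 8)
  tr <- plant_truth(lib, cfg)
  c1 <- simulate_counts(tr, cfg)
  c2 <- simulate_counts(tr, cfg)
  expect_identical(c1, c2)
  expect_equal(unname(colSums(c1)), rep(50000, 6))
  expect_equal(ncol(c1), 2L * cfg$n_replicates)
})

test_that("null counts give RNA/DNA CPM ratios near 1 for every construct", {
  lib <- make_library(20)
  cfg <- sim_config(n_snps = 20, fraction_regulatory = 0,
                    baseline_sdlog = 0, replicate_noise_cv = 1e-9,
                    read_depth = 1e5, seed = 4)
  tr <- plant_truth(lib, cfg)
  cnt <- simulate_counts(tr, cfg)
  cpm <- normalize_cpm(cnt)
  ratio <- cpm[, "SIM_RNA_rep1"] / cpm[, "SIM_DNA_rep1"]
  # binomial error at ~2400 counts/construct: 5 sigma ~ 0.15
  expect_true(all(abs(ratio - 1) < 0.15))
})

test_that("a planted activity-2 construct doubles its RNA:DNA ratio", {
  lib <- make_library(20)
  cfg <- sim_config(n_snps = 20, fraction_regulatory = 0,
                    baseline_sdlog = 0, replicate_noise_cv = 1e-9,
                    read_depth = 2e5, seed = 6)
  tr <- plant_truth(lib, cfg)
  hot <- which(tr$constructs$construct_id == "rs0003_risk")
  tr$constructs$true_activity[hot] <- 2
  cnt <- simulate_counts(tr, cfg)
  cpm <- normalize_cpm(cnt)
  ratio <- rowMeans(cpm[, c(2, 4, 6)] / cpm[, c(1, 3, 5)])
  others <- ratio[-c(hot, which(names(ratio) == "blank"))]
  expect_gt(ratio[hot] / median(others), 1.85)
  expect_lt(ratio[hot] / median(others), 2.15)
})

test_that("Monte-Carlo fold recovery is unbiased for a planted fold-2 SNP", {
  lib <- make_library(50)
  folds <- vapply(1:200, function(s) {
    cfg <- sim_config(n_snps = 50, fraction_regulatory = 0,
                      read_depth = 1e5, seed = s)
    tr <- plant_truth(lib, cfg)
    i_n <- which(tr$constructs$construct_id == "rs0001_normal")
    i_r <- which(tr$constructs$construct_id == "rs0001_risk")
    tr$constructs$true_activity[i_n] <- 0.75
    tr$constructs$true_activity[i_r] <- 1.5
    cnt <- simulate_counts(tr, cfg)
    res <- allelic_results(compute_activity(cnt), lib)
    res$fold_change[res$rs_id == "rs0001"]
  }, numeric(1))
  expect_lt(abs(mean(folds) - 2), 3 * sd(folds) / sqrt(length(folds)))
})

test_that("simulated FASTQ is deterministic and shaped as configured", {
  lib <- make_library(5)
  cfg <- sim_config(n_snps = 5, read_depth = 500, seed = 10,
                    per_base_error_rate = 0.01)
  tr <- plant_truth(lib, cfg)
  cnt <- simulate_counts(tr, cfg)
  sheet <- build_sample_sheet(attr(cnt, "sample_info"))
  f <- replicate(2, {
    r1 <- tempfile(fileext = "_R1.fastq"); r2 <- tempfile(fileext = "_R2.fastq")
    simulate_fastq(cnt, lib, sheet, cfg, r1, r2)
    paste(c(readLines(r1), readLines(r2)), collapse = "\n")
  })
  expect_identical(f[1], f[2])
  r1 <- tempfile(fileext = "_R1.fastq"); r2 <- tempfile(fileext = "_R2.fastq")
  n <- simulate_fastq(cnt, lib, sheet, cfg, r1, r2)
  expect_equal(n, sum(cnt))
  fq <- suppressWarnings(read_fastq(r1))
  expect_true(all(nchar(fq$seq) == 150L))
  # merged first-half amplicon is 271 bp
  fq2 <- suppressWarnings(read_fastq(r2))
  m <- merge_pairs(fq$seq[1:50], fq2$seq[1:50])
  expect_true(all(nchar(m$sequence[m$merged]) == 271L))
})

test_that("zero counts produce an empty FASTQ pair", {
  lib <- make_library(2)
  cfg <- sim_config(n_snps = 2, read_depth = 100, seed = 1)
  cnt <- matrix(0L, nrow = nrow(lib), ncol = 2,
                dimnames = list(lib$construct_id, c("a", "b")))
  sheet <- build_sample_sheet(data.frame(cell_line = "X",
                                         fraction = c("DNA", "RNA"),
                                         replicate = 1))
  r1 <- tempfile(fileext = ".fastq"); r2 <- tempfile(fileext = ".fastq")
  expect_equal(simulate_fastq(cnt, lib, sheet, cfg, r1, r2), 0L)
  expect_equal(length(readLines(r1)), 0L)
})

test_that("round trip at error 0 recovers the simulated counts exactly", {
  lib <- make_library(10)
  cfg <- sim_config(n_snps = 10, read_depth = 2000, seed = 3,
                    per_base_error_rate = 0)
  tr <- plant_truth(lib, cfg)
  cnt <- simulate_counts(tr, cfg)
  sheet <- build_sample_sheet(attr(cnt, "sample_info"))
  r1 <- tempfile(fileext = "_R1.fastq.gz"); r2 <- tempfile(fileext = "_R2.fastq.gz")
  simulate_fastq(cnt, lib, sheet, cfg, r1, r2)
  cc <- suppressWarnings(count_reads(r1, r2, lib, sheet))
  expect_true(all(cc$counts[rownames(cnt), colnames(cnt)] == cnt))
  expect_equal(cc$run_qc$merge_rejected, 0L)
  expect_equal(cc$run_qc$demux_unassigned, 0L)
})

test_that("simulated peaks cover exactly the supported SNPs", {
  panel <- make_panel(20)
  sup <- panel$rs_id[c(2, 5, 9)]
  pk <- simulate_peaks(panel, sup, n_decoys = 3, seed = 1)
  expect_setequal(names(pk), c("ATAC", "DNase", "H3K27ac", "H3K4me3"))
  for (a in names(pk)) {
    hit <- snp_in_peaks(panel, pk[[a]])
    expect_equal(panel$rs_id[hit], sup)
  }
  # empty support, no decoys -> empty BED
  td <- tempfile(); dir.create(td)
  simulate_peaks(panel, character(0), n_decoys = 0, dir = td)
  expect_equal(length(readLines(file.path(td, "ATAC.bed"))), 0L)
  expect_error(simulate_peaks(panel, "rs_nonexistent"), "not in panel")
})

test_that("a supported SNP's BED interval contains its 0-based coordinate", {
  panel <- data.frame(rs_id = "rs1", chrom = "chr9", pos = 150L,
                      normal_allele = "A", risk_allele = "G")
  td <- tempfile(); dir.create(td)
  simulate_peaks(panel, "rs1", assays = "ATAC", n_decoys = 0, dir = td)
  bed <- read.delim(file.path(td, "ATAC.bed"), header = FALSE)
  expect_true(any(bed$V2 <= 149 & 149 < bed$V3))
})

test_that("simulated Ct tables encode planted abundances on the log2 scale", {
  flat <- simulate_ct_table("chip", planted = 1, noise_sd = 0, seed = 1)
  expect_equal(length(unique(round(flat$ct, 10))), 1L)
  chip <- simulate_ct_table("chip", planted = 4, noise_sd = 0, seed = 1)
  target_ip <- mean(chip$ct[chip$region == "target" & chip$fraction == "IP"])
  target_in <- mean(chip$ct[chip$region == "target" & chip$fraction == "input"])
  expect_equal(target_ip - target_in, -2)
  expect_equal(chip_enrichment_table(chip), 4)
})
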