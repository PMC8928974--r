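#' Simulation configuration
#'
#' Bundles the parameters of the synthetic screen generator. Defaults mirror
#' the screen geometry the package targets: a 288-SNP panel (576 allele
#' constructs plus one blank), three biological replicates, one million reads
#' per sub-library, and a 450-bp barcode region sequenced as a 271/270-bp
#' amplicon pair with 150-bp paired-end reads.
#'
#' @param n_snps number of SNPs in the panel.
#' @param fraction_regulatory fraction of SNPs planted with a true allelic
#'   effect.
#' @param fold_range range (min, max) of planted fold changes between allele
#'   activities; must lie strictly above 1.
#' @param regulatory_anchor activity of the weaker allele of a planted
#'   regulatory SNP; the stronger allele sits at `anchor * fold` (default
#'   0.75, so a fold-2 SNP shows activities 0.75 vs 1.5).
#' @param fraction_up probability that the risk allele is the stronger one.
#' @param baseline_sdlog log-SD of the per-SNP baseline activity shared by
#'   both alleles of non-regulatory SNPs.
#' @param n_replicates biological replicates per cell line.
#' @param read_depth reads per sub-library.
#' @param dna_dirichlet_concentration symmetric Dirichlet concentration for
#'   the plasmid-pool (DNA) proportions of the allele constructs.
#' @param blank_proportion fixed fraction of the plasmid pool occupied by the
#'   blank calibrator construct (spiked at a defined abundance so the
#'   activity-1 reference is measured with low counting error).
#' @param replicate_noise_cv coefficient of variation of the lognormal
#'   replicate noise on each SNP construct's realized activity.
#' @param per_base_error_rate substitution sequencing-error rate per base.
#' @param barcode_region_length,read_length,amplicon_split amplicon geometry:
#'   length of the barcode region, read length of each mate, and the
#'   (first, second) amplicon lengths it is split into for paired-end
#'   sequencing.
#' @param seed integer seed; every simulation drawing randomness threads it.
#' @return a `dir_sim_config` list.
#' @export
sim_config <- function(n_snps = 288L,
                       fraction_regulatory = 0.1,
                       fold_range = c(2, 2),
                       regulatory_anchor = 0.75,
                       fraction_up = 0.5,
                       baseline_sdlog = 0.15,
                       n_replicates = 3L,
                       read_depth = 1e6,
                       dna_dirichlet_concentration = 10,
                       blank_proportion = 0.01,
                       replicate_noise_cv = 0.1,
                       per_base_error_rate = 0.001,
                       barcode_region_length = 450L,
                       read_length = 150L,
                       amplicon_split = c(271L, 270L),
                       seed = 1L) {
  cfg <- list(n_snps = as.integer(n_snps),
              fraction_regulatory = fraction_regulatory,
              fold_range = range(fold_range),
              regulatory_anchor = regulatory_anchor,
              fraction_up = fraction_up,
              baseline_sdlog = baseline_sdlog,
              n_replicates = as.integer(n_replicates),
              read_depth = read_depth,
              dna_dirichlet_concentration = dna_dirichlet_concentration,
              blank_proportion = blank_proportion,
              replicate_noise_cv = replicate_noise_cv,
              per_base_error_rate = per_base_error_rate,
              barcode_region_length = as.integer(barcode_region_length),
              read_length = as.integer(read_length),
              amplicon_split = as.integer(amplicon_split),
              seed = as.integer(seed))
  stopifnot(cfg$n_snps >= 1, cfg$n_replicates >= 1, cfg$read_depth > 0,
            cfg$fraction_regulatory >= 0, cfg$fraction_regulatory <= 1,
            cfg$blank_proportion > 0, cfg$blank_proportion < 1)
  layout <- amplicon_layout(cfg$barcode_region_length, cfg$amplicon_split,
                            cfg$read_length)
  if (2L * cfg$read_length < layout$amplicon_len[1] + 20L)
    stop("reads too short to merge across the first amplicon with >= 20 bp overlap")
  class(cfg) <- "dir_sim_config"
  cfg
}

#' Amplicon layout used by the simulator and by default counting
#'
#' Simulated amplicons have the fixed structure
#' `[primer (20 nt) | index (8 nt) | barcode-region slice]`: the first
#' amplicon carries the start of the barcode region, whose first 15 nt are
#' the construct barcode; the second amplicon covers the tail of the region
#' and carries no barcode. Offsets here are the contract between
#' `simulate_fastq()` and the read-processing chain.
#'
#' @param barcode_region_length,amplicon_split,read_length see [sim_config()].
#' @param primer_len,index_len,barcode_len sequence element lengths.
#' @return list of offsets and lengths (1-based inclusive coordinates on the
#'   merged first-amplicon sequence).
#' @export
amplicon_layout <- function(barcode_region_length = 450L,
                            amplicon_split = c(271L, 270L),
                            read_length = 150L,
                            primer_len = 20L, index_len = 8L,
                            barcode_len = 15L) {
  overhead <- primer_len + index_len
  if (any(amplicon_split <= overhead + barcode_len))
    stop("amplicon lengths must exceed primer+index+barcode overhead")
  if (amplicon_split[1] - overhead > barcode_region_length)
    stop("first amplicon exceeds the barcode region")
  list(primer_len = primer_len, index_len = index_len,
       barcode_len = barcode_len,
       primer_at = c(1L, primer_len),
       index_at = c(primer_len + 1L, overhead),
       barcode_at = c(overhead + 1L, overhead + barcode_len),
       region_len = as.integer(barcode_region_length),
       amplicon_len = as.integer(amplicon_split),
       read_length = as.integer(read_length))
}

# Fixed internal sequences: 24 first-round primers (20 nt, pairwise Hamming
# >= 5), 12 indexes (8 nt, pairwise Hamming >= 3) and the constant barcode-
# region filler. Generated once from a fixed seed independent of user seeds
# so demultiplexing sequences never drift between simulation and counting.
default_primers <- function(n = 24L) {
  local_rng(990001L, sample_barcodes(n, 20L, min_dist = 5L))
}

default_indexes <- function(n = 12L) {
  local_rng(990002L, sample_barcodes(n, 8L, min_dist = 3L))
}

region_filler <- function(len) {
  local_rng(990003L, paste(sample(c("A", "C", "G", "T"), len, replace = TRUE),
                           collapse = ""))
}

#' Plant ground-truth allelic activities on a construct registry
#'
#' A configured fraction of SNPs receives a true allelic effect: the weaker
#' allele is set to `regulatory_anchor` and the stronger to `anchor * fold`,
#' with the fold drawn from `fold_range` and the favored allele chosen with
#' probability `fraction_up`. Remaining SNPs get both alleles at a common
#' lognormal baseline; the blank construct's activity is exactly 1 by
#' definition.
#'
#' @param constructs registry from [build_library()].
#' @param cfg [sim_config()].
#' @return `dir_truth` list with `$constructs` (per-construct true_activity),
#'   `$snps` (true_fold, direction, is_regulatory) and `$cfg`.
#' @export
plant_truth <- function(constructs, cfg = sim_config()) {
  if (!"blank" %in% constructs$allele_class)
    stop("constructs must include the blank calibrator")
  snp_ids <- unique(constructs$rs_id[constructs$allele_class != "blank"])
  n <- length(snp_ids)
  if (cfg$fraction_regulatory > 0 && min(cfg$fold_range) <= 1)
    stop("fold_range must lie strictly above 1 for regulatory SNPs")
  local_rng(cfg$seed + 101L, {
    n_reg <- round(cfg$fraction_regulatory * n)
    reg <- rep(FALSE, n)
    reg[sample.int(n, n_reg)] <- TRUE
    fold <- runif(n, cfg$fold_range[1], cfg$fold_range[2])
    up <- runif(n) < cfg$fraction_up
    baseline <- rlnorm(n, meanlog = -cfg$baseline_sdlog^2 / 2,
                       sdlog = cfg$baseline_sdlog)
  })
  a_normal <- a_risk <- baseline
  lo <- cfg$regulatory_anchor
  hi <- lo * fold
  a_normal[reg] <- ifelse(up, lo, hi)[reg]
  a_risk[reg] <- ifelse(up, hi, lo)[reg]
  snps <- data.frame(rs_id = snp_ids,
                     activity_normal = a_normal,
                     activity_risk = a_risk,
                     true_fold = ifelse(reg, a_risk / a_normal, 1),
                     direction = ifelse(!reg, "none",
                                        ifelse(up, "increased", "decreased")),
                     is_regulatory = reg &
                       (pmin(a_normal, a_risk) < 0.8 |
                          pmax(a_normal, a_risk) > 1.2),
                     stringsAsFactors = FALSE)
  act <- rep(1, nrow(constructs))
  idx <- match(constructs$rs_id, snps$rs_id)
  is_n <- constructs$allele_class == "normal"
  is_r <- constructs$allele_class == "risk"
  act[is_n] <- snps$activity_normal[idx[is_n]]
  act[is_r] <- snps$activity_risk[idx[is_r]]
  ctruth <- constructs[, c("construct_id", "rs_id", "allele_class", "barcode")]
  ctruth$true_activity <- act
  structure(list(constructs = ctruth, snps = snps, cfg = cfg),
            class = "dir_truth")
}

#' Simulate the construct x sample barcode count table
#'
#' Plasmid-pool (DNA) proportions are drawn once from a symmetric Dirichlet,
#' with the blank held at a fixed spike-in proportion. Each replicate's DNA
#' column is a multinomial draw at the configured depth; RNA expected
#' proportions are DNA proportion x true activity x lognormal replicate noise
#' (blank: activity exactly 1, no activity noise), renormalized and sampled
#' multinomially.
#'
#' @param truth from [plant_truth()].
#' @param cfg [sim_config()]; defaults to the config stored in `truth`.
#' @param cell_line label used in sample ids.
#' @return integer matrix constructs x samples with a `sample_info`
#'   attribute (data.frame: sample_id, cell_line, fraction, replicate).
#' @export
simulate_counts <- function(truth, cfg = truth$cfg, cell_line = "SIM") {
  ctab <- truth$constructs
  n_c <- nrow(ctab)
  if (cfg$read_depth < n_c)
    warning("read depth ", cfg$read_depth, " below number of constructs ",
            n_c, "; counts will be sparse")
  blank_i <- which(ctab$allele_class == "blank")
  local_rng(cfg$seed + 202L, {
    w <- rgamma(n_c - 1L, shape = cfg$dna_dirichlet_concentration, rate = 1)
    p_dna <- numeric(n_c)
    p_dna[-blank_i] <- (1 - cfg$blank_proportion) * w / sum(w)
    p_dna[blank_i] <- cfg$blank_proportion
    sdlog <- sqrt(log(1 + cfg$replicate_noise_cv^2))
    counts <- matrix(0L, nrow = n_c, ncol = 2L * cfg$n_replicates)
    info <- data.frame(sample_id = character(0), cell_line = character(0),
                       fraction = character(0), replicate = integer(0),
                       stringsAsFactors = FALSE)
    for (r in seq_len(cfg$n_replicates)) {
      dna <- rmultinom(1L, cfg$read_depth, p_dna)[, 1L]
      noise <- rlnorm(n_c, meanlog = -sdlog^2 / 2, sdlog = sdlog)
      noise[blank_i] <- 1
      p_rna <- p_dna * ctab$true_activity * noise
      rna <- rmultinom(1L, cfg$read_depth, p_rna / sum(p_rna))[, 1L]
      counts[, 2L * r - 1L] <- dna
      counts[, 2L * r] <- rna
      info <- rbind(info, data.frame(
        sample_id = paste(cell_line, c("DNA", "RNA"), paste0("rep", r),
                          sep = "_"),
        cell_line = cell_line, fraction = c("DNA", "RNA"),
        replicate = r, stringsAsFactors = FALSE))
    }
  })
  dimnames(counts) <- list(ctab$construct_id, info$sample_id)
  attr(counts, "sample_info") <- info
  counts
}

#' Simulate paired-end FASTQ reads for sub-libraries
#'
#' For each counted molecule the first-half amplicon is emitted:
#' `[primer | index | barcode | filler]` of the configured first-amplicon
#' length, read as mate 1 from the 5' end and mate 2 reverse-complemented
#' from the 3' end, each exactly `read_length` bases, with independent
#' per-base substitution errors. Read names encode the true sample and
#' construct (`sim|<sample>|<construct>|<serial>`) so recovery can be scored.
#' All sub-libraries are pooled into one R1/R2 file pair, as in a real
#' multiplexed run.
#'
#' @param counts count matrix from [simulate_counts()] (or any integer
#'   matrix with construct rownames).
#' @param constructs registry carrying the barcodes.
#' @param sheet sample sheet from [build_sample_sheet()]; rows must match
#'   the columns of `counts`.
#' @param cfg [sim_config()].
#' @param r1_path,r2_path output FASTQ paths (gzip if ending in `.gz`).
#' @param include_second_half also emit read pairs for the barcode-free
#'   second-half amplicon (default FALSE; such reads demultiplex but carry
#'   no barcode and are tallied as unassigned by the counter).
#' @return invisibly, the number of read pairs written.
#' @export
simulate_fastq <- function(counts, constructs, sheet, cfg,
                           r1_path, r2_path, include_second_half = FALSE) {
  layout <- amplicon_layout(cfg$barcode_region_length, cfg$amplicon_split,
                            cfg$read_length)
  counts <- as.matrix(counts)
  if (ncol(counts) != nrow(sheet))
    stop("counts columns and sample sheet rows do not match")
  primers <- default_primers()
  indexes <- default_indexes()
  bc <- constructs$barcode[match(rownames(counts), constructs$construct_id)]
  if (anyNA(bc)) stop("counts rownames not all present in construct registry")
  filler <- region_filler(layout$region_len - layout$barcode_len)
  region <- paste0(bc, filler)
  amp1_region_len <- layout$amplicon_len[1] -
    (layout$primer_len + layout$index_len)
  amp2_region_len <- layout$amplicon_len[2] -
    (layout$primer_len + layout$index_len)
  rl <- layout$read_length
  seqs1 <- character(0); seqs2 <- character(0); ids <- character(0)
  for (s in seq_len(nrow(sheet))) {
    n_per <- counts[, s]
    tot <- sum(n_per)
    if (tot == 0L) next
    head28 <- paste0(primers[sheet$primer_set[s]], indexes[sheet$index[s]])
    amp1 <- paste0(head28, substr(region, 1L, amp1_region_len))
    amps <- rep(amp1, n_per)
    which_c <- rep(rownames(counts), n_per)
    if (include_second_half) {
      amp2 <- paste0(head28,
                     substr(region, layout$region_len - amp2_region_len + 1L,
                            layout$region_len))
      amps <- c(amps, rep(amp2, n_per))
      which_c <- c(which_c, rep(rownames(counts), n_per))
    }
    alen <- nchar(amps)
    seqs1 <- c(seqs1, substr(amps, 1L, rl))
    seqs2 <- c(seqs2, revcomp(substr(amps, alen - rl + 1L, alen)))
    ids <- c(ids, paste("sim", sheet$sample_id[s], which_c,
                        seq_along(amps), sep = "|"))
  }
  if (length(seqs1) > 0 && cfg$per_base_error_rate > 0) {
    local_rng(cfg$seed + 303L, {
      seqs1 <- cpp_add_errors(seqs1, cfg$per_base_error_rate)
      seqs2 <- cpp_add_errors(seqs2, cfg$per_base_error_rate)
    })
  }
  write_fastq(ids, seqs1, r1_path)
  write_fastq(ids, seqs2, r2_path)
  invisible(length(seqs1))
}

revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

# Constant Q37 qualities; the simulator models errors through the
# substitution rate, not through the quality string.
write_fastq <- function(ids, seqs, path) {
  qs <- vapply(nchar(seqs), function(n) strrep("F", n), character(1))
  x <- Biostrings::QualityScaledDNAStringSet(
    Biostrings::DNAStringSet(seqs), Biostrings::PhredQuality(qs))
  names(x) <- ids
  Biostrings::writeQualityScaledXStringSet(
    x, path, compress = grepl("\\.gz$", path))
  invisible(path)
}

#' Simulate chromatin-assay peak sets covering a chosen SNP subset
#'
#' Every SNP in `supported_rsids` is covered by one interval in every
#' requested assay; all other panel SNPs are covered by none. Optional decoy
#' intervals are placed beyond the panel's coordinate range.
#'
#' @param panel SNP panel.
#' @param supported_rsids rs_ids to cover (subset of the panel).
#' @param assays assay names.
#' @param half_width peak half-width in bp around the SNP.
#' @param n_decoys decoy peaks per assay, placed clear of all panel SNPs.
#' @param dir if non-NULL, write one `<assay>.bed` per assay into this
#'   directory (0-based half-open BED).
#' @param seed seed for decoy placement.
#' @return named list of [GenomicRanges::GRanges] (1-based internal
#'   representation), invisibly also written as BED when `dir` is given.
#' @export
simulate_peaks <- function(panel, supported_rsids,
                           assays = c("ATAC", "DNase", "H3K27ac", "H3K4me3"),
                           half_width = 100L, n_decoys = 5L, dir = NULL,
                           seed = 1L) {
  panel <- validate_snp_panel(panel)
  bad <- setdiff(supported_rsids, panel$rs_id)
  if (length(bad) > 0)
    stop("supported_rsids not in panel: ", paste(bad, collapse = ", "))
  sup <- panel[panel$rs_id %in% supported_rsids, , drop = FALSE]
  far <- if (nrow(panel)) max(panel$pos) + 100000L else 100000L
  out <- list()
  local_rng(seed + 404L, {
    for (a in assays) {
      chroms <- sup$chrom
      starts <- pmax(1L, sup$pos - half_width)
      ends <- sup$pos + half_width
      if (n_decoys > 0 && nrow(panel) > 0) {
        dstart <- far + sort(sample.int(1000000L, n_decoys))
        chroms <- c(chroms, sample(unique(panel$chrom), n_decoys,
                                   replace = TRUE))
        starts <- c(starts, dstart)
        ends <- c(ends, dstart + 2L * half_width)
      }
      out[[a]] <- sort(GenomicRanges::GRanges(
        chroms, IRanges::IRanges(starts, ends)))
    }
  })
  if (!is.null(dir)) {
    for (a in assays) write_bed(out[[a]], file.path(dir, paste0(a, ".bed")))
  }
  out
}

#' Simulate qPCR Ct tables for the allelic quantification formulas
#'
#' Ct values follow `baseline - log2(abundance) + N(0, noise_sd)`. Three
#' scenario types are supported: `chip` (target/control region x IP/input,
#' planted `fold` enrichment), `asqpcr` (allele A/B x sample/gdna, planted
#' allelic `ratio`, optional per-allele primer offset removed by gDNA
#' calibration) and `getpcr` (watch/control amplicon x edited/mock, planted
#' `wt_fraction`).
#'
#' @param type one of "chip", "asqpcr", "getpcr".
#' @param planted planted value: fold enrichment, allelic ratio, or
#'   wild-type fraction respectively.
#' @param n_replicates technical replicates.
#' @param noise_sd Gaussian Ct noise SD (cycles).
#' @param baseline baseline Ct at unit abundance.
#' @param primer_offset extra cycles on allele B in both sample and gDNA
#'   (asqpcr only); mimics unequal allele-specific primer efficiency.
#' @param seed seed.
#' @param path optional TSV output path.
#' @return tidy data.frame of Ct measurements.
#' @export
simulate_ct_table <- function(type = c("chip", "asqpcr", "getpcr"),
                              planted, n_replicates = 3L, noise_sd = 0.1,
                              baseline = 20, primer_offset = 0, seed = 1L,
                              path = NULL) {
  type <- match.arg(type)
  grid <- switch(type,
    chip = expand.grid(region = c("target", "control"),
                       fraction = c("IP", "input"),
                       stringsAsFactors = FALSE),
    asqpcr = expand.grid(allele = c("A", "B"),
                         template = c("sample", "gdna"),
                         stringsAsFactors = FALSE),
    getpcr = expand.grid(amplicon = c("watch", "control"),
                         condition = c("edited", "mock"),
                         stringsAsFactors = FALSE))
  abundance <- switch(type,
    chip = ifelse(grid$region == "target" & grid$fraction == "IP",
                  planted, 1),
    asqpcr = ifelse(grid$allele == "A" & grid$template == "sample",
                    planted, 1),
    getpcr = ifelse(grid$amplicon == "watch" & grid$condition == "edited",
                    planted, 1))
  offset <- if (type == "asqpcr") ifelse(grid$allele == "B", primer_offset, 0)
            else 0
  df <- grid[rep(seq_len(nrow(grid)), each = n_replicates), , drop = FALSE]
  df$replicate <- rep(seq_len(n_replicates), times = nrow(grid))
  mu <- rep(baseline - log2(abundance) + offset, each = n_replicates)
  local_rng(seed + 505L, df$ct <- mu + rnorm(nrow(df), 0, noise_sd))
  rownames(df) <- NULL
  if (!is.null(path))
    write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  df
}
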