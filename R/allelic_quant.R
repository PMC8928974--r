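#' ChIP / FAIRE qPCR fold enrichment (delta-delta-Ct)
#'
#' Enrichment of a target region over input, normalized to a control
#' region: `E ^ -[(Ct_target_IP - Ct_target_input) -
#' (Ct_ctrl_IP - Ct_ctrl_input)]`. All arguments are vectorized.
#'
#' @param ct_target_ip,ct_target_input,ct_ctrl_ip,ct_ctrl_input Ct values
#'   (cycles).
#' @param efficiency amplification efficiency per cycle, in (1, 2]
#'   (default 2, perfect doubling).
#' @return fold enrichment (1 = no enrichment).
#' @export
chip_enrichment <- function(ct_target_ip, ct_target_input,
                            ct_ctrl_ip, ct_ctrl_input, efficiency = 2.0) {
  check_efficiency(efficiency)
  ddct <- (ct_target_ip - ct_target_input) - (ct_ctrl_ip - ct_ctrl_input)
  efficiency^(-ddct)
}

#' Allele-specific qPCR ratio calibrated to genomic DNA
#'
#' The A:B allelic abundance ratio from allele-specific primers (the
#' discriminating base at the 3' end), calibrated against a heterozygous
#' genomic-DNA template so unequal primer efficiencies cancel:
#' `E ^ -[(CtA - CtB)_sample - (CtA - CtB)_gdna]`. Pass `ct_alleleA_gdna =
#' ct_alleleB_gdna = 0` for the uncalibrated form.
#'
#' @param ct_alleleA_sample,ct_alleleB_sample sample Cts per allele.
#' @param ct_alleleA_gdna,ct_alleleB_gdna heterozygous genomic-DNA Cts.
#' @param efficiency amplification efficiency (default 2).
#' @return A:B ratio (1 = balanced alleles).
#' @export
allele_ratio_asqpcr <- function(ct_alleleA_sample, ct_alleleB_sample,
                                ct_alleleA_gdna, ct_alleleB_gdna,
                                efficiency = 2.0) {
  check_efficiency(efficiency)
  ddct <- (ct_alleleA_sample - ct_alleleB_sample) -
    (ct_alleleA_gdna - ct_alleleB_gdna)
  efficiency^(-ddct)
}

#' Wild-type percentage after genome editing (getPCR)
#'
#' Quantifies the intact (wild-type) fraction remaining after editing from
#' a "watch" amplicon spanning the cut site and a control amplicon nearby,
#' each measured in edited and mock (unedited) DNA:
#' `100 * E ^ -[(Ct_watch - Ct_ctrl)_edited - (Ct_watch - Ct_ctrl)_mock]`.
#' Values outside `[0, 100]` (possible under noise) are clamped with a
#' warning; the indel percentage is `100 - WT%`.
#'
#' @param ct_watch_edited,ct_ctrl_edited,ct_watch_mock,ct_ctrl_mock Cts.
#' @param efficiency amplification efficiency (default 2).
#' @return list: `wt_percent`, `indel_percent`, `clamped` (logical).
#' @export
getpcr_wt_fraction <- function(ct_watch_edited, ct_ctrl_edited,
                               ct_watch_mock, ct_ctrl_mock,
                               efficiency = 2.0) {
  check_efficiency(efficiency)
  ddct <- (ct_watch_edited - ct_ctrl_edited) - (ct_watch_mock - ct_ctrl_mock)
  wt <- 100 * efficiency^(-ddct)
  clamped <- wt > 100 | wt < 0
  if (any(clamped))
    warning(sum(clamped), " wild-type percentage(s) outside [0, 100]; ",
            "clamped")
  wt <- pmin(pmax(wt, 0), 100)
  list(wt_percent = wt, indel_percent = 100 - wt, clamped = clamped)
}

check_efficiency <- function(efficiency) {
  if (any(efficiency <= 1) || any(efficiency > 2))
    stop("amplification efficiency must be in (1, 2]")
}

# Mean Ct per group from a tidy replicate table; cols = grouping columns.
mean_ct <- function(df, ...) {
  sel <- df
  args <- list(...)
  for (nm in names(args)) sel <- sel[sel[[nm]] == args[[nm]], , drop = FALSE]
  if (nrow(sel) == 0) stop("no Ct rows match ", deparse(args))
  mean(sel$ct)
}

#' ChIP enrichment from a tidy Ct table
#'
#' @param df Ct table with columns region (target/control), fraction
#'   (IP/input), replicate, ct — as written by [simulate_ct_table()].
#' @param efficiency amplification efficiency.
#' @return fold enrichment from replicate-mean Cts.
#' @export
chip_enrichment_table <- function(df, efficiency = 2.0) {
  chip_enrichment(mean_ct(df, region = "target", fraction = "IP"),
                  mean_ct(df, region = "target", fraction = "input"),
                  mean_ct(df, region = "control", fraction = "IP"),
                  mean_ct(df, region = "control", fraction = "input"),
                  efficiency)
}

#' AS-qPCR allele ratio from a tidy Ct table
#'
#' @param df Ct table with columns allele (A/B), template (sample/gdna),
#'   replicate, ct.
#' @param efficiency amplification efficiency.
#' @return A:B ratio from replicate-mean Cts.
#' @export
allele_ratio_table <- function(df, efficiency = 2.0) {
  allele_ratio_asqpcr(mean_ct(df, allele = "A", template = "sample"),
                      mean_ct(df, allele = "B", template = "sample"),
                      mean_ct(df, allele = "A", template = "gdna"),
                      mean_ct(df, allele = "B", template = "gdna"),
                      efficiency)
}

#' getPCR wild-type percentage from a tidy Ct table
#'
#' @param df Ct table with columns amplicon (watch/control), condition
#'   (edited/mock), replicate, ct.
#' @param efficiency amplification efficiency.
#' @return list as in [getpcr_wt_fraction()], from replicate-mean Cts.
#' @export
getpcr_table <- function(df, efficiency = 2.0) {
  getpcr_wt_fraction(mean_ct(df, amplicon = "watch", condition = "edited"),
                     mean_ct(df, amplicon = "control", condition = "edited"),
                     mean_ct(df, amplicon = "watch", condition = "mock"),
                     mean_ct(df, amplicon = "control", condition = "mock"),
                     efficiency)
}

#' Count allele-carrying reads at a heterozygous SNP
#'
#' Raw-read mode: anchors each read on the exact `(2k + 1)`-mer context
#' around the SNP (from the allele window sequences), on either strand, and
#' tallies which allele base it carries; reads matching the context but
#' neither allele go to `n_other`. A two-sided exact binomial test against
#' 0.5 is run on the two allele counts.
#'
#' @param reads character vector of read sequences (or a FASTQ path).
#' @param snp one-row SNP panel record.
#' @param context window sequence centered on the SNP (either allele; e.g.
#'   a 55-bp insert). Must be odd-length with the SNP at the center.
#' @param context_k half-width of the anchor context (default 5).
#' @return list of class `dir_allele_count`: rs_id, counts (named by
#'   allele), n_other, p_value.
#' @export
count_alleles_at_snp <- function(reads, snp, context, context_k = 5L) {
  if (length(reads) == 1L && file.exists(reads) &&
      grepl("\\.(fastq|fq)(\\.gz)?$", reads))
    reads <- read_fastq(reads)$seq
  n <- nchar(context)
  center <- (n + 1L) %/% 2L
  k <- as.integer(context_k)
  if (center - k < 1L || center + k > n)
    stop("context_k = ", k, " too large for the provided context")
  left <- substr(context, center - k, center - 1L)
  right <- substr(context, center + 1L, center + k)
  alleles <- c(snp$normal_allele, snp$risk_allele)
  hit_base <- function(seqs) {
    # base at the SNP slot of the first anchor occurrence, plus strand
    pat_l <- regexpr(left, seqs, fixed = TRUE)
    out <- rep(NA_character_, length(seqs))
    cand <- which(pat_l > 0)
    if (length(cand) > 0) {
      posn <- pat_l[cand] + k  # SNP slot right after the left anchor
      ok <- substr(seqs[cand], posn + 1L, posn + k) == right
      out[cand[ok]] <- substr(seqs[cand[ok]], posn, posn)
    }
    out
  }
  fwd <- hit_base(reads)
  rev_needed <- is.na(fwd)
  if (any(rev_needed)) {
    rc <- hit_base(revcomp(reads[rev_needed]))
    fwd[rev_needed] <- rc
  }
  observed <- fwd[!is.na(fwd)]
  counts <- c(sum(observed == alleles[1]), sum(observed == alleles[2]))
  names(counts) <- alleles
  n_other <- length(observed) - sum(counts)
  p <- if (sum(counts) == 0) NA_real_ else
    binom.test(counts[1], sum(counts), p = 0.5)$p.value
  structure(list(rs_id = snp$rs_id, counts = counts, n_other = n_other,
                 p_value = unname(p)),
            class = "dir_allele_count")
}

#' Count alleles at a SNP from aligned reads (SAM/BAM)
#'
#' Alignment mode of [count_alleles_at_snp()]: a pileup at the SNP position
#' tallies the mapped base of every overlapping record. Requires the
#' Rsamtools package; SAM input is converted on the fly.
#'
#' @param path SAM or BAM file (indexed BAM not required; SAM is sorted and
#'   converted in a temporary directory).
#' @param snp one-row SNP panel record.
#' @return list as in [count_alleles_at_snp()].
#' @export
count_alleles_sam <- function(path, snp) {
  if (!requireNamespace("Rsamtools", quietly = TRUE))
    stop("count_alleles_sam requires the Rsamtools package")
  if (grepl("\\.sam$", path)) {
    bam <- Rsamtools::asBam(path, tempfile(), overwrite = TRUE,
                            indexDestination = TRUE)
  } else bam <- path
  rng <- GenomicRanges::GRanges(snp$chrom,
                                IRanges::IRanges(snp$pos, snp$pos))
  pp <- Rsamtools::PileupParam(distinguish_strands = FALSE,
                               min_base_quality = 0L,
                               min_mapq = 0L,
                               max_depth = 1000000L)
  res <- Rsamtools::pileup(bam,
                           scanBamParam = Rsamtools::ScanBamParam(which = rng),
                           pileupParam = pp)
  res <- res[res$pos == snp$pos, , drop = FALSE]
  alleles <- c(snp$normal_allele, snp$risk_allele)
  get_n <- function(b) {
    i <- which(res$nucleotide == b)
    if (length(i) == 0) 0L else sum(res$count[i])
  }
  counts <- setNames(c(get_n(alleles[1]), get_n(alleles[2])), alleles)
  n_other <- sum(res$count) - sum(counts)
  p <- if (sum(counts) == 0) NA_real_ else
    binom.test(counts[1], sum(counts), p = 0.5)$p.value
  structure(list(rs_id = snp$rs_id, counts = counts, n_other = n_other,
                 p_value = unname(p)),
            class = "dir_allele_count")
}

#' Read a tidy qPCR Ct table from TSV
#'
#' @param path TSV with a `ct` column plus grouping columns.
#' @return data.frame.
#' @export
read_ct_table <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  if (!"ct" %in% names(df)) stop("Ct table needs a 'ct' column")
  if (any(!is.finite(df$ct))) stop("non-finite Ct values")
  df
}
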