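#' Counts-per-million normalization
#'
#' Scales every sample (column) to a total of one million so sub-libraries
#' sequenced to different depths are comparable.
#'
#' @param counts count matrix (constructs x samples) or a single column.
#' @return matrix (or vector) of CPM values; each column sums to 1e6.
#' @export
normalize_cpm <- function(counts) {
  if (is.null(dim(counts))) {
    tot <- sum(counts)
    if (tot <= 0) stop("all-zero count column cannot be CPM-normalized")
    return(counts * 1e6 / tot)
  }
  tot <- colSums(counts)
  if (any(tot <= 0))
    stop("all-zero count column(s): ",
         paste(colnames(counts)[tot <= 0], collapse = ", "))
  sweep(counts, 2L, tot / 1e6, "/")
}

#' Blank-calibrated reporter activities per replicate
#'
#' For each replicate the raw expression ratio is RNA CPM / DNA CPM; the
#' activity divides this ratio by the same replicate's blank-construct
#' ratio, so the promoter-only vector defines activity 1 in every replicate.
#' Constructs with zero DNA CPM in a replicate are flagged excluded there.
#'
#' @param counts count matrix whose columns are described by `sample_info`.
#' @param sample_info data.frame with sample_id, cell_line, fraction
#'   (DNA/RNA), replicate; defaults to the matrix's `sample_info` attribute.
#' @param blank_id construct_id of the blank calibrator (default "blank").
#' @param calibrate divide ratios by the replicate blank ratio (default
#'   TRUE); FALSE analyses raw RNA/DNA ratios.
#' @return data.frame of class `dir_activity`: construct_id, cell_line,
#'   replicate, cpm_dna, cpm_rna, ratio, activity, excluded.
#' @export
compute_activity <- function(counts, sample_info = attr(counts, "sample_info"),
                             blank_id = "blank", calibrate = TRUE) {
  if (is.null(sample_info))
    stop("sample_info required (attach as attribute or pass explicitly)")
  if (!blank_id %in% rownames(counts))
    stop("blank construct '", blank_id, "' not in count table")
  cpm <- normalize_cpm(counts)
  out <- list()
  for (cl in unique(sample_info$cell_line)) {
    reps <- sort(unique(sample_info$replicate[sample_info$cell_line == cl]))
    for (r in reps) {
      dna_col <- sample_info$sample_id[sample_info$cell_line == cl &
                                         sample_info$replicate == r &
                                         sample_info$fraction == "DNA"]
      rna_col <- sample_info$sample_id[sample_info$cell_line == cl &
                                         sample_info$replicate == r &
                                         sample_info$fraction == "RNA"]
      if (length(dna_col) != 1L || length(rna_col) != 1L)
        stop("need exactly one DNA and one RNA sample for ", cl,
             " replicate ", r)
      d <- cpm[, dna_col]; rn <- cpm[, rna_col]
      ratio <- ifelse(d > 0, rn / d, NA_real_)
      blank_ratio <- ratio[blank_id]
      if (calibrate && (is.na(blank_ratio) || blank_ratio <= 0))
        stop("blank construct has zero DNA or RNA CPM in ", cl,
             " replicate ", r)
      out[[length(out) + 1L]] <- data.frame(
        construct_id = rownames(cpm), cell_line = cl, replicate = r,
        cpm_dna = d, cpm_rna = rn, ratio = ratio,
        activity = if (calibrate) ratio / blank_ratio else ratio,
        excluded = d == 0, stringsAsFactors = FALSE, row.names = NULL)
    }
  }
  res <- do.call(rbind, out)
  class(res) <- c("dir_activity", "data.frame")
  res
}

#' Pooled-variance two-sample t-test of allele activities
#'
#' Classic Student's t with pooled variance on the replicate activities of
#' the two alleles, two-tailed, df = n1 + n2 - 2. The fold change is
#' mean(risk) / mean(normal). Degenerate zero-variance inputs return p = 1
#' (equal means) or p = 0 (unequal means, flagged).
#'
#' @param activities_normal,activities_risk numeric vectors (each length
#'   >= 2) of replicate activities.
#' @param welch use Welch's unequal-variance form instead (default FALSE).
#' @return list: p_value, fold_change, t, df, degenerate.
#' @export
allelic_test <- function(activities_normal, activities_risk, welch = FALSE) {
  x <- activities_normal; y <- activities_risk
  if (length(x) < 2L || length(y) < 2L)
    stop("need >= 2 replicates per allele")
  fold <- mean(y) / mean(x)
  n1 <- length(x); n2 <- length(y)
  v1 <- stats::var(x); v2 <- stats::var(y)
  if (v1 + v2 == 0) {
    eq <- isTRUE(all.equal(mean(x), mean(y)))
    return(list(p_value = if (eq) 1 else 0, fold_change = fold,
                t = if (eq) 0 else Inf, df = n1 + n2 - 2L,
                degenerate = TRUE))
  }
  if (welch) {
    ht <- stats::t.test(y, x, var.equal = FALSE)
  } else {
    ht <- stats::t.test(y, x, var.equal = TRUE)
  }
  list(p_value = unname(ht$p.value), fold_change = fold,
       t = unname(ht$statistic), df = unname(ht$parameter),
       degenerate = FALSE)
}

#' Per-SNP allelic results from replicate activities
#'
#' Aggregates a `dir_activity` table to one row per SNP and cell line:
#' replicate-mean activity per allele, fold change (risk / normal), pooled
#' t-test p-value, BH q-value (reported alongside, not used for the
#' two-stage call), and the two-stage regulatory classification from
#' [classify()]. SNPs whose constructs lack DNA coverage in more than
#' `max_excluded` replicates are dropped (flagged in the `dropped`
#' attribute) since a one-sided allele estimate would bias the fold change.
#'
#' @param activity `dir_activity` data.frame from [compute_activity()].
#' @param constructs registry mapping construct_id to rs_id / allele_class.
#' @param p_thresh,low,high classification thresholds (defaults 0.05, 0.8,
#'   1.2).
#' @param max_excluded maximum replicates a construct may miss DNA coverage
#'   in before its SNP is dropped (default 1).
#' @param welch use Welch's t-test (default FALSE, classic Student).
#' @return data.frame of class `dir_allelic`: rs_id, cell_line,
#'   mean_normal, mean_risk, fold_change, p_value, q_value, passes_stage1,
#'   passes_stage2, regulatory, direction.
#' @export
allelic_results <- function(activity, constructs, p_thresh = 0.05,
                            low = 0.8, high = 1.2, max_excluded = 1L,
                            welch = FALSE) {
  amap <- constructs[constructs$allele_class %in% c("normal", "risk"),
                     c("construct_id", "rs_id", "allele_class")]
  act <- merge(activity, amap, by = "construct_id")
  out <- list()
  for (cl in unique(act$cell_line)) {
    a <- act[act$cell_line == cl, ]
    reps <- sort(unique(a$replicate))
    # wide matrices: SNPs x replicates, one per allele
    key <- function(cls) {
      w <- a[a$allele_class == cls, ]
      m <- matrix(NA_real_, nrow = length(unique(amap$rs_id)),
                  ncol = length(reps),
                  dimnames = list(unique(amap$rs_id), reps))
      m[cbind(w$rs_id, as.character(w$replicate))] <-
        ifelse(w$excluded, NA_real_, w$activity)
      m
    }
    mn <- key("normal"); mr <- key("risk")
    n_missing <- rowSums(is.na(mn)) + rowSums(is.na(mr))
    keep <- rowSums(is.na(mn)) <= max_excluded &
      rowSums(is.na(mr)) <= max_excluded &
      rowSums(!is.na(mn)) >= 2 & rowSums(!is.na(mr)) >= 2
    res <- vectorized_t(mn[keep, , drop = FALSE],
                        mr[keep, , drop = FALSE], welch = welch)
    df <- data.frame(rs_id = rownames(mn)[keep], cell_line = cl,
                     mean_normal = res$mean_x, mean_risk = res$mean_y,
                     fold_change = res$mean_y / res$mean_x,
                     p_value = res$p, stringsAsFactors = FALSE,
                     row.names = NULL)
    df$q_value <- p.adjust(df$p_value, method = "BH")
    df <- classify(df, p_thresh = p_thresh, low = low, high = high)
    attr_drop <- rownames(mn)[!keep]
    attr(df, "dropped") <- attr_drop
    out[[cl]] <- df
  }
  res <- do.call(rbind, c(out, list(make.row.names = FALSE)))
  attr(res, "dropped") <- unlist(lapply(out, attr, "dropped"))
  class(res) <- c("dir_allelic", "data.frame")
  res
}

# Row-wise pooled-variance (or Welch) two-sample t on matrices with possible
# NAs; equivalent to allelic_test() row by row but vectorized.
vectorized_t <- function(mx, my, welch = FALSE) {
  n1 <- rowSums(!is.na(mx)); n2 <- rowSums(!is.na(my))
  m1 <- rowMeans(mx, na.rm = TRUE); m2 <- rowMeans(my, na.rm = TRUE)
  v1 <- rowSums((mx - m1)^2, na.rm = TRUE) / pmax(n1 - 1, 1)
  v2 <- rowSums((my - m2)^2, na.rm = TRUE) / pmax(n2 - 1, 1)
  if (welch) {
    se2 <- v1 / n1 + v2 / n2
    df <- se2^2 / (v1^2 / (n1^2 * (n1 - 1)) + v2^2 / (n2^2 * (n2 - 1)))
  } else {
    sp2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2)
    se2 <- sp2 * (1 / n1 + 1 / n2)
    df <- n1 + n2 - 2
  }
  t <- (m2 - m1) / sqrt(se2)
  p <- 2 * pt(-abs(t), df)
  # degenerate zero-variance rows
  zero <- se2 == 0
  p[zero] <- ifelse(m1[zero] == m2[zero], 1, 0)
  list(mean_x = m1, mean_y = m2, t = t, df = df, p = p)
}

#' Two-stage regulatory classification
#'
#' Stage 1 requires the alleles to drive reporter expression differently
#' (p < `p_thresh`); stage 2 requires at least one allele's replicate-mean
#' activity to fall below `low` or above `high` relative to the blank.
#' A SNP is called regulatory only if it passes both stages; the direction
#' is increased when fold change (risk / normal) exceeds 1.
#'
#' @param results data.frame with mean_normal, mean_risk, fold_change,
#'   p_value columns.
#' @param p_thresh,low,high thresholds (defaults 0.05, 0.8, 1.2).
#' @return `results` with passes_stage1, passes_stage2, regulatory and
#'   direction columns (re)computed.
#' @export
classify <- function(results, p_thresh = 0.05, low = 0.8, high = 1.2) {
  results$passes_stage1 <- results$p_value < p_thresh
  results$passes_stage2 <-
    pmin(results$mean_normal, results$mean_risk) < low |
    pmax(results$mean_normal, results$mean_risk) > high
  results$regulatory <- results$passes_stage1 & results$passes_stage2
  results$direction <- ifelse(results$fold_change > 1, "increased",
                              "decreased")
  results
}

#' Volcano-plot table of allelic results
#'
#' @param results `dir_allelic` data.frame.
#' @param p_thresh significance threshold for the summary counts.
#' @param path optional TSV output; a summary footer with the counts of
#'   increased/decreased SNPs at `p < p_thresh` is appended as comment
#'   lines.
#' @return data.frame: rs_id, cell_line, log2_fold, neg_log10_p, direction,
#'   significant; `summary` attribute holds the per-direction counts.
#' @export
volcano_table <- function(results, p_thresh = 0.05, path = NULL) {
  v <- data.frame(rs_id = results$rs_id, cell_line = results$cell_line,
                  log2_fold = log2(results$fold_change),
                  neg_log10_p = -log10(results$p_value),
                  direction = results$direction,
                  significant = results$p_value < p_thresh,
                  stringsAsFactors = FALSE)
  summ <- data.frame(
    cell_line = sort(unique(v$cell_line)),
    increased = vapply(sort(unique(v$cell_line)), function(cl)
      sum(v$significant & v$direction == "increased" & v$cell_line == cl),
      integer(1)),
    decreased = vapply(sort(unique(v$cell_line)), function(cl)
      sum(v$significant & v$direction == "decreased" & v$cell_line == cl),
      integer(1)),
    row.names = NULL, stringsAsFactors = FALSE)
  attr(v, "summary") <- summ
  if (!is.null(path)) {
    write.table(v, path, sep = "\t", quote = FALSE, row.names = FALSE)
    cat(paste0("# ", summ$cell_line, ": increased=", summ$increased,
               " decreased=", summ$decreased, " at p<", p_thresh, "\n"),
        file = path, append = TRUE, sep = "")
  }
  v
}
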