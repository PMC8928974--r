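#' Read a BED peak file
#'
#' Parses 3+ column BED (0-based, half-open), skipping `track`, `browser`
#' and `#` comment lines, validating coordinates with the offending line
#' number on error, and returning sorted 1-based [GenomicRanges::GRanges]
#' (the internal convention; BED output converts back).
#'
#' @param path BED file.
#' @return sorted GRanges with an optional `score` column.
#' @export
read_bed <- function(path) {
  lines <- readLines(path)
  keep <- !grepl("^(track|browser|#)", lines) & nzchar(trimws(lines))
  lineno <- which(keep)
  lines <- lines[keep]
  if (length(lines) == 0)
    return(GenomicRanges::GRanges())
  parts <- strsplit(lines, "\t", fixed = TRUE)
  ncols <- lengths(parts)
  if (any(ncols < 3L))
    stop(path, " line ", lineno[which(ncols < 3L)[1]],
         ": fewer than 3 tab-separated columns")
  chrom <- vapply(parts, `[`, character(1), 1L)
  start <- suppressWarnings(as.numeric(vapply(parts, `[`, character(1), 2L)))
  end <- suppressWarnings(as.numeric(vapply(parts, `[`, character(1), 3L)))
  bad <- which(is.na(start) | is.na(end))
  if (length(bad) > 0)
    stop(path, " line ", lineno[bad[1]], ": non-numeric coordinates")
  bad <- which(start >= end)
  if (length(bad) > 0)
    stop(path, " line ", lineno[bad[1]], ": start >= end (BED is 0-based, ",
         "half-open)")
  gr <- GenomicRanges::GRanges(chrom, IRanges::IRanges(start + 1, end))
  if (all(ncols >= 5L)) {
    sc <- suppressWarnings(as.numeric(vapply(parts, `[`, character(1), 5L)))
    S4Vectors::mcols(gr)$score <- sc
  }
  sort(gr)
}

#' Write GRanges intervals as BED (0-based half-open)
#'
#' @param gr GRanges (1-based internal representation).
#' @param path output path.
#' @export
write_bed <- function(gr, path) {
  df <- data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
                   start = GenomicRanges::start(gr) - 1L,
                   end = GenomicRanges::end(gr))
  write.table(df, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

# Harmonize "chr" prefixes between a peak set and the panel convention.
normalize_chroms <- function(chroms, target_has_chr) {
  has_chr <- grepl("^chr", chroms)
  if (target_has_chr) ifelse(has_chr, chroms, paste0("chr", chroms))
  else sub("^chr", "", chroms)
}

#' Which panel SNPs fall inside a peak set?
#'
#' A SNP at 1-based position `pos` is supported when the 0-based coordinate
#' `pos - 1` lies within some peak interval. Chromosome "chr" prefixes are
#' harmonized to the panel's convention.
#'
#' @param panel SNP panel (or a one-row SNP record).
#' @param peaks GRanges from [read_bed()] / [simulate_peaks()].
#' @return logical vector along the panel rows.
#' @export
snp_in_peaks <- function(panel, peaks) {
  panel <- validate_snp_panel(panel)
  if (length(peaks) == 0) return(rep(FALSE, nrow(panel)))
  target_has_chr <- any(grepl("^chr", panel$chrom))
  peak_chroms <- normalize_chroms(as.character(GenomicRanges::seqnames(peaks)),
                                  target_has_chr)
  peaks2 <- GenomicRanges::GRanges(peak_chroms, IRanges::ranges(peaks))
  snps <- GenomicRanges::GRanges(panel$chrom,
                                 IRanges::IRanges(panel$pos, panel$pos))
  GenomicRanges::countOverlaps(snps, peaks2) > 0
}

#' Chromatin-assay support matrix for a SNP panel
#'
#' @param panel SNP panel.
#' @param peaksets named list of GRanges, one per assay.
#' @return logical matrix rs_id x assay.
#' @export
support_matrix <- function(panel, peaksets) {
  panel <- validate_snp_panel(panel)
  if (is.null(names(peaksets)) || any(!nzchar(names(peaksets))))
    stop("peaksets must be a named list (assay names)")
  m <- vapply(peaksets, function(p) snp_in_peaks(panel, p),
              logical(nrow(panel)))
  m <- matrix(m, nrow = nrow(panel),
              dimnames = list(panel$rs_id, names(peaksets)))
  m
}

#' Nominate screen-positive SNPs with active chromatin support
#'
#' Applies a boolean support rule over the assay support matrix of the
#' screen's positive SNPs. The default rule requires open chromatin
#' (ATAC or DNase peak) and an active histone mark (H3K27ac or H3K4me3
#' peak) at the SNP. The rule is a configurable boolean expression over
#' assay names using `&`, `|`, `!` and parentheses.
#'
#' @param dir_hits character vector of screen-positive rs_ids (must be
#'   present in `panel`).
#' @param panel SNP panel giving coordinates.
#' @param peaksets named list of GRanges keyed by assay.
#' @param rule boolean expression string over assay names; default
#'   `"(ATAC | DNase) & (H3K27ac | H3K4me3)"`.
#' @return list of class `dir_omics`: `support` (logical matrix hits x
#'   assay), `nominated` (rs_ids satisfying the rule), `rule`.
#' @export
nominate_active <- function(dir_hits, panel, peaksets,
                            rule = "(ATAC | DNase) & (H3K27ac | H3K4me3)") {
  if (length(dir_hits) == 0) stop("dir_hits is empty")
  panel <- validate_snp_panel(panel)
  missing <- setdiff(dir_hits, panel$rs_id)
  if (length(missing) > 0)
    stop("dir_hits not in panel: ", paste(missing, collapse = ", "))
  hits_panel <- panel[match(dir_hits, panel$rs_id), , drop = FALSE]
  supp <- support_matrix(hits_panel, peaksets)
  expr <- str2lang(rule)
  vars <- all.vars(expr)
  bad <- setdiff(vars, colnames(supp))
  if (length(bad) > 0)
    stop("rule references assay(s) not provided: ",
         paste(bad, collapse = ", "))
  env <- as.data.frame(supp)
  ok <- eval(expr, envir = env, enclos = baseenv())
  structure(list(support = supp, nominated = dir_hits[ok], rule = rule),
            class = "dir_omics")
}

#' Write an omics-support result to TSV
#'
#' @param x `dir_omics` from [nominate_active()].
#' @param support_path,nominated_path output TSVs.
#' @export
write_omics <- function(x, support_path, nominated_path = NULL) {
  df <- data.frame(rs_id = rownames(x$support), x$support,
                   nominated = rownames(x$support) %in% x$nominated,
                   check.names = FALSE, stringsAsFactors = FALSE)
  write.table(df, support_path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(nominated_path))
    writeLines(x$nominated, nominated_path)
  invisible(support_path)
}
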