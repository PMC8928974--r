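#' Read a FASTQ file into id / sequence / quality vectors
#'
#' @param path FASTQ path (plain or gzip).
#' @return list with character vectors `id`, `seq`, `qual`.
#' @export
read_fastq <- function(path) {
  x <- Biostrings::readQualityScaledDNAStringSet(path)
  list(id = names(x),
       seq = as.character(x),
       qual = as.character(Biostrings::quality(x)))
}

#' Merge read pairs by maximum-agreement overlap
#'
#' Mate 2 is given as sequenced (reverse strand) and is reverse-complemented
#' before the scan. The overlap length maximizing the number of matching
#' bases is chosen, subject to a mismatch-rate cap and a minimum length;
#' ties go to the longer overlap. At disagreeing positions the consensus
#' takes the higher-quality base (mate 1 wins quality ties). Pairs with no
#' admissible overlap are returned as rejected, not errors.
#'
#' @param r1,r2 character vectors of mate sequences.
#' @param q1,q2 Phred+33 quality strings; default constant high quality.
#' @param min_overlap minimum admissible overlap (default 20).
#' @param max_mismatch_rate maximum mismatch fraction in the overlap
#'   (default 0.1).
#' @return data.frame with sequence, quality, overlap, mismatches and
#'   logical `merged`; rejected pairs have `merged = FALSE` and NA sequence.
#' @export
merge_pairs <- function(r1, r2, q1 = NULL, q2 = NULL,
                        min_overlap = 20L, max_mismatch_rate = 0.1) {
  if (length(r1) != length(r2)) stop("r1 and r2 differ in length")
  if (any(nchar(r1) == 0L) || any(nchar(r2) == 0L))
    stop("empty reads cannot be merged")
  if (is.null(q1)) q1 <- vapply(nchar(r1), strrep, character(1), x = "F")
  if (is.null(q2)) q2 <- vapply(nchar(r2), strrep, character(1), x = "F")
  r2rc <- revcomp(r2)
  q2r <- vapply(strsplit(q2, ""), function(q)
    paste(rev(q), collapse = ""), character(1))
  res <- cpp_merge_pairs(r1, r2rc, q1, q2r,
                         as.integer(min_overlap), max_mismatch_rate)
  data.frame(sequence = res$sequence, quality = res$quality,
             overlap = res$overlap, mismatches = res$mismatches,
             merged = res$overlap > 0L, stringsAsFactors = FALSE)
}

#' Merge a single read pair
#'
#' Scalar convenience wrapper around [merge_pairs()].
#'
#' @inheritParams merge_pairs
#' @return list(sequence, quality, overlap, mismatches, merged) or, for an
#'   inadmissible pair, `merged = FALSE` with NA sequence.
#' @export
merge_pair <- function(r1, r2, q1 = NULL, q2 = NULL,
                       min_overlap = 20L, max_mismatch_rate = 0.1) {
  as.list(merge_pairs(r1, r2, q1, q2, min_overlap, max_mismatch_rate)[1L, ])
}

#' Demultiplex merged reads by primer set and index
#'
#' Matches the primer window and index window of each merged read against
#' the primer/index sequence sets within the given mismatch tolerances. A
#' read maps to a sample only if both matches are unique and the
#' (primer_set, index) pair occurs in the sample sheet; ties at the best
#' distance are ambiguous and left unassigned.
#'
#' @param seqs character vector of merged sequences (NA allowed).
#' @param sheet sample sheet from [build_sample_sheet()].
#' @param layout [amplicon_layout()] giving the primer/index windows.
#' @param primers,indexes primer and index sequence sets; defaults are the
#'   package's fixed simulation sets.
#' @param max_primer_mm,max_index_mm mismatch tolerances (defaults 1 and 0).
#' @return list: `sample` (sample_id or NA per read), `ambiguous` (logical).
#' @export
demultiplex <- function(seqs, sheet, layout = amplicon_layout(),
                        primers = default_primers(), indexes = default_indexes(),
                        max_primer_mm = 1L, max_index_mm = 0L) {
  if (anyDuplicated(sheet[, c("primer_set", "index")]))
    stop("sample sheet has duplicate (primer_set, index) pairs")
  pw <- substr(seqs, layout$primer_at[1], layout$primer_at[2])
  iw <- substr(seqs, layout$index_at[1], layout$index_at[2])
  p_hit <- cpp_hamming_assign(pw, primers, as.integer(max_primer_mm))
  i_hit <- cpp_hamming_assign(iw, indexes, as.integer(max_index_mm))
  key <- paste(p_hit, i_hit)
  sheet_key <- paste(sheet$primer_set, sheet$index)
  row <- match(key, sheet_key)
  sample <- sheet$sample_id[row]
  ambiguous <- (p_hit == -1L | i_hit == -1L) & !is.na(seqs)
  sample[ambiguous] <- NA_character_
  list(sample = sample, ambiguous = ambiguous)
}

#' Read a barcode map from TSV
#'
#' @param path TSV with columns `barcode`, `construct_id`.
#' @return validated barcode map data.frame.
#' @export
read_barcode_map <- function(path) {
  bm <- read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("barcode", "construct_id") %in% names(bm)))
    stop("barcode map needs columns barcode, construct_id")
  validate_barcode_map(bm)
}

validate_barcode_map <- function(barcode_map) {
  if (anyDuplicated(barcode_map$barcode))
    stop("duplicate barcodes in barcode map")
  if (anyDuplicated(barcode_map$construct_id))
    stop("duplicate construct ids in barcode map")
  barcode_map
}

#' Assign merged reads to constructs by barcode
#'
#' Extracts the barcode window and matches it against the barcode map,
#' exactly by default. With `max_barcode_mm = 1` a read within distance 1 of
#' two barcodes is left unassigned (ambiguous).
#'
#' @param seqs merged sequences (NA allowed).
#' @param barcode_map data.frame with `barcode`, `construct_id` (e.g. the
#'   registry from [build_library()]).
#' @param layout [amplicon_layout()].
#' @param max_barcode_mm barcode mismatch tolerance (default 0).
#' @return list: `construct` (construct_id or NA), `ambiguous` (logical).
#' @export
count_barcodes <- function(seqs, barcode_map, layout = amplicon_layout(),
                           max_barcode_mm = 0L) {
  validate_barcode_map(barcode_map)
  bw <- substr(seqs, layout$barcode_at[1], layout$barcode_at[2])
  hit <- match(bw, barcode_map$barcode)
  ambiguous <- rep(FALSE, length(seqs))
  if (max_barcode_mm > 0L) {
    todo <- which(is.na(hit) & !is.na(seqs))
    if (length(todo) > 0) {
      h <- cpp_hamming_assign(bw[todo], barcode_map$barcode,
                              as.integer(max_barcode_mm))
      ambiguous[todo] <- h == -1L
      h[h <= 0L] <- NA_integer_
      hit[todo] <- h
    }
  }
  list(construct = barcode_map$construct_id[hit], ambiguous = ambiguous)
}

#' Count barcode reads per construct and sample from paired FASTQ
#'
#' The full read-processing chain: merge pairs by overlap, demultiplex by
#' primer/index, extract and match barcodes, and tabulate counts. Per
#' sample, assigned counts plus unassigned tallies equal the reads routed to
#' that sample; pairs failing merge or demultiplexing are tallied globally.
#'
#' @param r1_path,r2_path paired FASTQ files (or character vectors of
#'   sequences via `reads =`).
#' @param barcode_map barcode-to-construct map.
#' @param sheet sample sheet.
#' @param layout [amplicon_layout()].
#' @param min_overlap,max_mismatch_rate merge parameters.
#' @param max_primer_mm,max_index_mm,max_barcode_mm matching tolerances.
#' @param primers,indexes demultiplexing sequence sets.
#' @return list of class `dir_counts`: `counts` (integer matrix constructs x
#'   samples), `qc` (per-sample totals, assigned, barcode-unassigned,
#'   ambiguous) and `run_qc` (pairs read, merge rejections, demux failures).
#' @export
count_reads <- function(r1_path, r2_path, barcode_map, sheet,
                        layout = amplicon_layout(),
                        min_overlap = 20L, max_mismatch_rate = 0.1,
                        max_primer_mm = 1L, max_index_mm = 0L,
                        max_barcode_mm = 0L,
                        primers = default_primers(),
                        indexes = default_indexes()) {
  validate_barcode_map(barcode_map)
  fq1 <- read_fastq(r1_path)
  fq2 <- read_fastq(r2_path)
  if (length(fq1$seq) != length(fq2$seq))
    stop("R1 and R2 contain different numbers of reads")
  merged <- merge_pairs(fq1$seq, fq2$seq, fq1$qual, fq2$qual,
                        min_overlap, max_mismatch_rate)
  dm <- demultiplex(merged$sequence, sheet, layout, primers, indexes,
                    max_primer_mm, max_index_mm)
  bc <- count_barcodes(merged$sequence, barcode_map, layout, max_barcode_mm)
  counts <- matrix(0L, nrow = nrow(barcode_map), ncol = nrow(sheet),
                   dimnames = list(barcode_map$construct_id,
                                   sheet$sample_id))
  in_sample <- !is.na(dm$sample)
  assigned <- in_sample & !is.na(bc$construct)
  if (any(assigned)) {
    tab <- table(factor(bc$construct[assigned],
                        levels = barcode_map$construct_id),
                 factor(dm$sample[assigned], levels = sheet$sample_id))
    counts <- counts + unclass(tab)
    storage.mode(counts) <- "integer"
  }
  per_sample <- data.frame(
    sample_id = sheet$sample_id,
    reads = as.integer(table(factor(dm$sample, levels = sheet$sample_id))),
    assigned = as.integer(colSums(counts)),
    stringsAsFactors = FALSE)
  per_sample$barcode_unassigned <- per_sample$reads - per_sample$assigned
  per_sample$barcode_ambiguous <- as.integer(
    table(factor(dm$sample[bc$ambiguous], levels = sheet$sample_id)))
  run_qc <- data.frame(
    pairs = length(fq1$seq),
    merge_rejected = sum(!merged$merged),
    demux_unassigned = sum(merged$merged & is.na(dm$sample)),
    demux_ambiguous = sum(dm$ambiguous, na.rm = TRUE))
  structure(list(counts = counts, qc = per_sample, run_qc = run_qc,
                 read_ids = fq1$id, sample = dm$sample,
                 construct = bc$construct),
            class = "dir_counts")
}

#' @export
print.dir_counts <- function(x, ...) {
  cat("dir_counts:", nrow(x$counts), "constructs x", ncol(x$counts),
      "samples;", x$run_qc$pairs, "read pairs (",
      x$run_qc$merge_rejected, "merge-rejected,",
      x$run_qc$demux_unassigned, "demux-unassigned )\n")
  invisible(x)
}

#' Write a count table and its per-sample QC to TSV
#'
#' @param x `dir_counts` from [count_reads()] or a bare count matrix.
#' @param counts_path,qc_path output TSVs (`qc_path` ignored for matrices).
#' @export
write_count_table <- function(x, counts_path, qc_path = NULL) {
  counts <- if (inherits(x, "dir_counts")) x$counts else x
  df <- data.frame(construct_id = rownames(counts), counts,
                   check.names = FALSE, stringsAsFactors = FALSE)
  write.table(df, counts_path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(qc_path) && inherits(x, "dir_counts"))
    write.table(x$qc, qc_path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(counts_path)
}

#' Read a count table written by [write_count_table()]
#'
#' @param path TSV with a construct_id column and one column per sample.
#' @return integer count matrix.
#' @export
read_count_table <- function(path) {
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, setdiff(names(df), "construct_id"), drop = FALSE])
  rownames(m) <- df$construct_id
  storage.mode(m) <- "integer"
  m
}
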