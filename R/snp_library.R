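#' Validate a SNP panel
#'
#' A SNP panel is a data frame with one row per candidate SNP and columns
#' `rs_id`, `chrom`, `pos` (1-based), `normal_allele`, `risk_allele`, and
#' optionally `pvalue` (the GWAS association p-value the SNP was enlisted
#' under). Only biallelic single-nucleotide substitutions are supported;
#' indel alleles are rejected.
#'
#' @param panel data.frame of SNPs.
#' @return the validated panel (invisibly unchanged), with `pos` as integer.
#' @export
validate_snp_panel <- function(panel) {
  required <- c("rs_id", "chrom", "pos", "normal_allele", "risk_allele")
  missing <- setdiff(required, names(panel))
  if (length(missing) > 0)
    stop("SNP panel is missing column(s): ", paste(missing, collapse = ", "))
  if (nrow(panel) == 0) stop("SNP panel is empty")
  panel$rs_id <- as.character(panel$rs_id)
  panel$chrom <- as.character(panel$chrom)
  panel$pos <- as.integer(panel$pos)
  panel$normal_allele <- toupper(as.character(panel$normal_allele))
  panel$risk_allele <- toupper(as.character(panel$risk_allele))
  if (anyDuplicated(panel$rs_id))
    stop("duplicate rs_id in panel: ",
         paste(unique(panel$rs_id[duplicated(panel$rs_id)]), collapse = ", "))
  bad_nt <- !(panel$normal_allele %in% c("A", "C", "G", "T")) |
    !(panel$risk_allele %in% c("A", "C", "G", "T"))
  if (any(bad_nt))
    stop("non-SNV alleles (only single-base A/C/G/T substitutions supported): ",
         paste(panel$rs_id[bad_nt], collapse = ", "))
  if (any(panel$normal_allele == panel$risk_allele))
    stop("normal and risk allele identical for: ",
         paste(panel$rs_id[panel$normal_allele == panel$risk_allele],
               collapse = ", "))
  if (any(is.na(panel$pos)) || any(panel$pos < 1))
    stop("SNP positions must be 1-based integers >= 1")
  invisible(panel)
}

#' Read a SNP panel from TSV
#'
#' @param path TSV with header columns rs_id, chrom, pos, normal_allele,
#'   risk_allele and optionally pvalue.
#' @return validated SNP panel data.frame.
#' @export
read_snp_panel <- function(path) {
  panel <- read.delim(path, stringsAsFactors = FALSE)
  validate_snp_panel(panel)
  panel$pos <- as.integer(panel$pos)
  panel$normal_allele <- toupper(panel$normal_allele)
  panel$risk_allele <- toupper(panel$risk_allele)
  panel
}

#' Extract the SNP-centered insert window for both alleles
#'
#' Pulls the plus-strand sequence window of `2 * flank + 1` bases centered on
#' the SNP from a reference and returns one insert per allele, identical
#' except at the center base. With the default 27-nt flanks this yields the
#' 55-bp SNP-centered inserts used for reporter cloning.
#'
#' @param ref a named [Biostrings::DNAStringSet] (names are chromosome names),
#'   or the path to a FASTA file.
#' @param snp one-row SNP panel data.frame (or a list with the same fields).
#' @param flank flank length on each side of the SNP (default 27).
#' @return named character vector `c(normal = ..., risk = ...)`, each of
#'   length `2 * flank + 1`. If the reference base at the SNP position matches
#'   neither allele a warning is raised and both alleles are substituted in.
#' @export
extract_snp_window <- function(ref, snp, flank = 27L) {
  ref <- as_reference(ref)
  chrom <- as.character(snp$chrom)
  pos <- as.integer(snp$pos)
  if (!chrom %in% names(ref))
    stop("chromosome '", chrom, "' not present in reference")
  chr_seq <- ref[[chrom]]
  if (pos - flank < 1L || pos + flank > length(chr_seq))
    stop("window [", pos - flank, ", ", pos + flank, "] for ", snp$rs_id,
         " out of reference bounds (contig length ", length(chr_seq), ")")
  window <- as.character(Biostrings::subseq(chr_seq, pos - flank, pos + flank))
  center <- flank + 1L
  ref_base <- substr(window, center, center)
  if (!ref_base %in% c(snp$normal_allele, snp$risk_allele))
    warning("reference base '", ref_base, "' at ", snp$rs_id,
            " matches neither allele (", snp$normal_allele, "/",
            snp$risk_allele, "); substituting both alleles")
  normal <- risk <- window
  substr(normal, center, center) <- as.character(snp$normal_allele)
  substr(risk, center, center) <- as.character(snp$risk_allele)
  c(normal = normal, risk = risk)
}

as_reference <- function(ref) {
  if (is.character(ref) && length(ref) == 1L && file.exists(ref))
    ref <- Biostrings::readDNAStringSet(ref)
  if (is.character(ref)) ref <- Biostrings::DNAStringSet(ref)
  if (!methods::is(ref, "DNAStringSet"))
    stop("reference must be a DNAStringSet, named character vector, or FASTA path")
  if (is.null(names(ref))) stop("reference sequences must be named by chromosome")
  names(ref) <- sub("\\s.*$", "", names(ref))
  ref
}

#' Build the reporter construct registry for a SNP panel
#'
#' Emits two constructs (normal and risk allele) per SNP plus exactly one
#' promoter-only blank construct, each carrying a unique barcode. Simulated
#' barcodes are rejection-sampled to keep every pair at Hamming distance >= 3
#' so that single sequencing errors cannot convert one barcode into another.
#'
#' @param panel validated SNP panel.
#' @param ref optional reference (see [extract_snp_window()]); when `NULL`,
#'   synthetic flanking context is generated deterministically from `seed` so
#'   that simulated libraries are self-contained.
#' @param barcode_length barcode length in nt (default 15).
#' @param flank insert flank (default 27, i.e. 55-bp inserts).
#' @param seed integer seed controlling barcode assignment (and synthetic
#'   flanks when `ref` is `NULL`).
#' @param adapter5,adapter3 optional cloning-adapter sequence added to the
#'   oligo output only (never to `insert_seq`); default empty.
#' @return data.frame of constructs with columns construct_id, rs_id,
#'   allele_class (normal/risk/blank), insert_seq, barcode. The blank
#'   construct has empty insert_seq and `rs_id == "blank"`.
#' @export
build_library <- function(panel, ref = NULL, barcode_length = 15L,
                          flank = 27L, seed = 1L,
                          adapter5 = "", adapter3 = "") {
  panel <- validate_snp_panel(panel)
  n_snps <- nrow(panel)
  n_constructs <- 2L * n_snps + 1L
  if (4^barcode_length < n_constructs)
    stop("barcode space 4^", barcode_length, " too small for ",
         n_constructs, " constructs")
  local_rng(seed, {
    if (is.null(ref)) {
      inserts <- synthetic_windows(panel, flank)
    } else {
      inserts <- t(vapply(seq_len(n_snps), function(i)
        extract_snp_window(ref, panel[i, , drop = FALSE], flank),
        character(2)))
      colnames(inserts) <- c("normal", "risk")
    }
    barcodes <- sample_barcodes(n_constructs, barcode_length, min_dist = 3L)
  })
  out <- data.frame(
    construct_id = c(paste0(rep(panel$rs_id, each = 2L),
                            c("_normal", "_risk")), "blank"),
    rs_id = c(rep(panel$rs_id, each = 2L), "blank"),
    allele_class = c(rep(c("normal", "risk"), n_snps), "blank"),
    insert_seq = c(as.vector(t(inserts)), ""),
    barcode = barcodes,
    stringsAsFactors = FALSE
  )
  attr(out, "adapter5") <- adapter5
  attr(out, "adapter3") <- adapter3
  out
}

# Deterministic synthetic context: random flanks per SNP, center fixed to the
# allele. Used when no reference genome is supplied (simulation studies).
synthetic_windows <- function(panel, flank) {
  n <- nrow(panel)
  mk <- function() vapply(seq_len(n), function(i)
    paste(sample(c("A", "C", "G", "T"), flank, replace = TRUE), collapse = ""),
    character(1))
  left <- mk(); right <- mk()
  cbind(normal = paste0(left, panel$normal_allele, right),
        risk = paste0(left, panel$risk_allele, right))
}

# Rejection-sample n barcodes of the given length with pairwise Hamming
# distance >= min_dist. Candidates are drawn uniformly; each is kept only if
# it clears every already-accepted barcode.
sample_barcodes <- function(n, len, min_dist = 3L, max_tries = 1000L * n) {
  accepted <- matrix(0L, nrow = n, ncol = len)
  n_acc <- 0L
  tries <- 0L
  while (n_acc < n) {
    tries <- tries + 1L
    if (tries > max_tries)
      stop("barcode space exhausted after ", tries, " draws (",
           n_acc, "/", n, " accepted)")
    cand <- sample.int(4L, len, replace = TRUE)
    if (n_acc > 0L) {
      dists <- rowSums(accepted[seq_len(n_acc), , drop = FALSE] !=
                         matrix(cand, nrow = n_acc, ncol = len, byrow = TRUE))
      if (min(dists) < min_dist) next
    }
    n_acc <- n_acc + 1L
    accepted[n_acc, ] <- cand
  }
  apply(accepted, 1L, function(r)
    paste(c("A", "C", "G", "T")[r], collapse = ""))
}

#' Build a sample sheet addressing sub-libraries by primer set and index
#'
#' A pooled run addresses up to 24 first-round primer sets x 12 second-round
#' sequencing indexes = 288 sub-libraries. Samples are assigned (primer_set,
#' index) pairs deterministically, index-major: the primer set cycles fastest,
#' the index advances after every 24 samples.
#'
#' @param samples data.frame with columns cell_line, fraction (`"DNA"` or
#'   `"RNA"`), replicate; an optional sample_id column is preserved.
#' @param n_primers,n_indexes pool geometry (defaults 24 and 12).
#' @return sample sheet data.frame with sample_id, cell_line, fraction,
#'   replicate, primer_set, index.
#' @export
build_sample_sheet <- function(samples, n_primers = 24L, n_indexes = 12L) {
  capacity <- n_primers * n_indexes
  n <- nrow(samples)
  if (n > capacity)
    stop("cannot address ", n, " samples: pool capacity is ", n_primers,
         " primer sets x ", n_indexes, " indexes = ", capacity,
         " sub-libraries")
  if (!all(samples$fraction %in% c("DNA", "RNA")))
    stop("fraction must be 'DNA' or 'RNA'")
  i <- seq_len(n)
  sheet <- data.frame(
    sample_id = if ("sample_id" %in% names(samples)) samples$sample_id else
      paste(samples$cell_line, samples$fraction,
            paste0("rep", samples$replicate), sep = "_"),
    cell_line = samples$cell_line,
    fraction = samples$fraction,
    replicate = as.integer(samples$replicate),
    primer_set = as.integer((i - 1L) %% n_primers + 1L),
    index = as.integer((i - 1L) %/% n_primers + 1L),
    stringsAsFactors = FALSE
  )
  if (anyDuplicated(sheet$sample_id))
    stop("duplicate sample_id in sheet")
  sheet
}

#' Write constructs to TSV and the cloning oligos to FASTA
#'
#' @param constructs construct registry from [build_library()].
#' @param tsv,fasta output paths; either may be `NULL` to skip.
#' @return invisibly, the oligo sequences (insert with any cloning adapters).
#' @export
write_constructs <- function(constructs, tsv = NULL, fasta = NULL) {
  if (!is.null(tsv))
    write.table(constructs, tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  a5 <- attr(constructs, "adapter5") %||% ""
  a3 <- attr(constructs, "adapter3") %||% ""
  snp_rows <- constructs$allele_class != "blank"
  oligos <- paste0(a5, constructs$insert_seq[snp_rows], a3)
  names(oligos) <- constructs$construct_id[snp_rows]
  if (!is.null(fasta))
    Biostrings::writeXStringSet(Biostrings::DNAStringSet(oligos), fasta)
  invisible(oligos)
}

`%||%` <- function(x, y) if (is.null(x)) y else x

# Run code under a temporary RNG state seeded with `seed`, restoring the
# caller's RNG afterwards.
local_rng <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  code
}
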