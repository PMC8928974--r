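#' Parse JASPAR-format position frequency matrices
#'
#' Accepts the JASPAR PFM text format: a `>ID NAME` header followed by four
#' base rows, either bracketed (`A [ 4 19 0 ]`) or bare counts. Multiple
#' motifs per file are supported. Counts are converted to probabilities
#' with a pseudocount and to log2-odds scores against the background.
#'
#' @param path file path, or raw PFM text via `text =`.
#' @param text PFM text (overrides `path`).
#' @param pseudocount added to every matrix cell (default 0.5).
#' @param background background base probabilities, A/C/G/T (default
#'   uniform).
#' @return list of `dir_pwm` objects (id, name, counts, prob, log2odds,
#'   pseudocount, background), one per motif.
#' @export
parse_jaspar <- function(path = NULL, text = NULL, pseudocount = 0.5,
                         background = rep(0.25, 4)) {
  lines <- if (!is.null(text)) strsplit(text, "\n")[[1]] else readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  headers <- grep("^>", lines)
  if (length(headers) == 0) stop("no '>' motif header found")
  out <- list()
  for (h in seq_along(headers)) {
    from <- headers[h] + 1L
    to <- if (h < length(headers)) headers[h + 1L] - 1L else length(lines)
    block <- lines[from:to]
    if (length(block) != 4L)
      stop("motif block must have 4 base rows, got ", length(block))
    hdr <- sub("^>\\s*", "", lines[headers[h]])
    hdr_parts <- strsplit(trimws(hdr), "\\s+")[[1]]
    rows <- lapply(block, function(l) {
      l <- gsub("^[ACGTacgt]\\s*", "", trimws(l))
      l <- gsub("\\[|\\]", " ", l)
      v <- suppressWarnings(as.numeric(strsplit(trimws(l), "\\s+")[[1]]))
      if (anyNA(v)) stop("non-numeric count in PFM row: ", l)
      v
    })
    lens <- lengths(rows)
    if (length(unique(lens)) != 1L)
      stop("PFM rows have unequal lengths: ", paste(lens, collapse = ", "))
    counts <- do.call(rbind, rows)
    rownames(counts) <- c("A", "C", "G", "T")
    if (any(counts < 0)) stop("negative count in PFM")
    out[[length(out) + 1L]] <- pwm_from_counts(
      counts, id = hdr_parts[1],
      name = if (length(hdr_parts) > 1) hdr_parts[2] else hdr_parts[1],
      pseudocount = pseudocount, background = background)
  }
  out
}

#' Build a PWM from a count matrix
#'
#' @param counts 4 x L matrix (rows A, C, G, T).
#' @param id,name motif identifier and name.
#' @param pseudocount,background see [parse_jaspar()].
#' @return a `dir_pwm` object.
#' @export
pwm_from_counts <- function(counts, id = "motif", name = id,
                            pseudocount = 0.5, background = rep(0.25, 4)) {
  counts <- as.matrix(counts)
  if (nrow(counts) != 4L) stop("PFM must have 4 rows (A, C, G, T)")
  rownames(counts) <- c("A", "C", "G", "T")
  padded <- counts + pseudocount
  prob <- sweep(padded, 2L, colSums(padded), "/")
  log2odds <- log2(prob / background)
  structure(list(id = id, name = name, L = ncol(counts), counts = counts,
                 prob = prob, log2odds = log2odds,
                 pseudocount = pseudocount, background = background),
            class = "dir_pwm")
}

#' Write a PWM back to JASPAR PFM text
#'
#' @param pwm `dir_pwm` object.
#' @param path output path (or NULL to return the text).
#' @return the PFM text, invisibly when written to file.
#' @export
write_jaspar <- function(pwm, path = NULL) {
  rows <- vapply(c("A", "C", "G", "T"), function(b)
    paste0(b, " [ ", paste(pwm$counts[b, ], collapse = " "), " ]"),
    character(1))
  txt <- paste(c(paste0(">", pwm$id, " ", pwm$name), rows), collapse = "\n")
  if (is.null(path)) return(txt)
  writeLines(txt, path)
  invisible(txt)
}

# log2-odds of one window (character vector of bases) under the PWM; bases
# outside A/C/G/T contribute the background (score 0).
score_window <- function(bases, log2odds) {
  idx <- match(bases, c("A", "C", "G", "T"))
  s <- log2odds[cbind(idx, seq_along(bases))]
  sum(s, na.rm = TRUE)
}

# Reverse-complemented PWM: scanning the plus strand with it equals
# scanning the minus strand with the original.
revcomp_pwm_matrix <- function(log2odds) {
  log2odds[c("T", "G", "C", "A"), rev(seq_len(ncol(log2odds))), drop = FALSE]
}

#' Score both alleles of a SNP window with a PWM
#'
#' Scans all motif placements that cover the center (SNP) base, on both
#' strands, and reports each allele's best log2-odds score, placement and
#' strand, plus `delta = best(risk) - best(normal)`. Placements not
#' covering the SNP cannot distinguish the alleles and are excluded by
#' design.
#'
#' @param seq_normal,seq_risk equal-length sequences differing only at the
#'   center base (e.g. the 55-bp inserts).
#' @param pwm `dir_pwm`.
#' @param strands "both" (default), "plus" or "minus".
#' @return list of class `dir_motif_score`: motif id, per-allele best
#'   score / offset (1-based window start) / strand, and delta.
#' @export
score_alleles <- function(seq_normal, seq_risk, pwm,
                          strands = c("both", "plus", "minus")) {
  strands <- match.arg(strands)
  n <- nchar(seq_normal)
  if (nchar(seq_risk) != n)
    stop("allele sequences differ in length")
  L <- pwm$L
  if (L > n) stop("motif length ", L, " exceeds sequence length ", n)
  center <- (n + 1L) %/% 2L
  bn <- strsplit(toupper(seq_normal), "")[[1]]
  br <- strsplit(toupper(seq_risk), "")[[1]]
  if (any(bn[-center] != br[-center]))
    stop("allele sequences differ away from the center base")
  offsets <- max(1L, center - L + 1L):min(center, n - L + 1L)
  mats <- switch(strands,
    both = list(plus = pwm$log2odds, minus = revcomp_pwm_matrix(pwm$log2odds)),
    plus = list(plus = pwm$log2odds),
    minus = list(minus = revcomp_pwm_matrix(pwm$log2odds)))
  best <- function(bases) {
    top <- list(score = -Inf, offset = NA_integer_, strand = NA_character_)
    for (st in names(mats)) {
      for (o in offsets) {
        s <- score_window(bases[o:(o + L - 1L)], mats[[st]])
        if (s > top$score)
          top <- list(score = s, offset = o,
                      strand = if (st == "plus") "+" else "-")
      }
    }
    top
  }
  tn <- best(bn); tr <- best(br)
  structure(list(motif = pwm$id, name = pwm$name,
                 best_normal = tn$score, offset_normal = tn$offset,
                 strand_normal = tn$strand,
                 best_risk = tr$score, offset_risk = tr$offset,
                 strand_risk = tr$strand,
                 delta = tr$score - tn$score),
            class = "dir_motif_score")
}

#' Scan a construct panel against a motif set
#'
#' Scores every SNP's allele pair against every PWM and ranks rows by
#' absolute allelic score difference.
#'
#' @param constructs registry from [build_library()] (insert sequences for
#'   both alleles of each SNP).
#' @param pwms list of `dir_pwm` (e.g. from [parse_jaspar()]).
#' @return data.frame: rs_id, motif, name, best_normal, best_risk, delta,
#'   offset_risk, strand_risk, ordered by decreasing `abs(delta)` (ties by
#'   rs_id then motif for determinism).
#' @export
scan_panel <- function(constructs, pwms) {
  snps <- unique(constructs$rs_id[constructs$allele_class != "blank"])
  rows <- list()
  for (rs in snps) {
    sn <- constructs$insert_seq[constructs$rs_id == rs &
                                  constructs$allele_class == "normal"]
    sr <- constructs$insert_seq[constructs$rs_id == rs &
                                  constructs$allele_class == "risk"]
    for (p in pwms) {
      sc <- score_alleles(sn, sr, p)
      rows[[length(rows) + 1L]] <- data.frame(
        rs_id = rs, motif = sc$motif, name = sc$name,
        best_normal = sc$best_normal, best_risk = sc$best_risk,
        delta = sc$delta, offset_risk = sc$offset_risk,
        strand_risk = sc$strand_risk, stringsAsFactors = FALSE)
    }
  }
  if (length(rows) == 0)
    return(data.frame(rs_id = character(0), motif = character(0),
                      name = character(0), best_normal = numeric(0),
                      best_risk = numeric(0), delta = numeric(0),
                      offset_risk = integer(0), strand_risk = character(0),
                      stringsAsFactors = FALSE))
  out <- do.call(rbind, rows)
  out[order(-abs(out$delta), out$rs_id, out$motif), , drop = FALSE]
}
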