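# Shared fixture builders; everything is generated in code at test time.

make_panel <- function(n, chrom = "chr1", spacing = 10000L) {
  alleles <- matrix(c("A", "G", "C", "T", "G", "C", "T", "A"),
                    ncol = 2, byrow = TRUE)
  i <- ((seq_len(n) - 1L) %% 4L) + 1L
  data.frame(rs_id = sprintf("rs%04d", seq_len(n)), chrom = chrom,
             pos = 1000L + spacing * seq_len(n),
             normal_allele = alleles[i, 1], risk_allele = alleles[i, 2],
             stringsAsFactors = FALSE)
}

make_library <- function(n, seed = 42L) {
  build_library(make_panel(n), seed = seed)
}

random_dna <- function(n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

hamming <- function(a, b) {
  sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
}
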