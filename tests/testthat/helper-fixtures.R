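# Shared fixtures: a small hand-checkable design, a FASTQ writer, and the
# hand-built read set whose truth table is computed by hand below.

# 5-mer backbone, reactive Gln at 2, NNK at positions 1 and 3 (rel -1, +1).
mini_design <- function(tags = c(s1 = "AAAAACCCCC")) {
  library_design(
    name = "mini",
    backbone_peptide = "HQSYV",
    reactive_index = 2L,
    randomized_indices = c(1L, 3L),
    upstream_anchor = "ACGTACGTAC",
    downstream_anchor = "GTCAGTCAGT",
    tags = tags,
    min_count_after = 100L
  )
}

write_fastq_lines <- function(path, seqs, quals, ids = NULL) {
  if (is.null(ids)) ids <- sprintf("read%d", seq_along(seqs))
  writeLines(
    as.vector(rbind(paste0("@", ids), seqs, "+", quals)),
    path
  )
  path
}

# Hand-built 12-read-pair fixture for the mini design. Codons chosen by hand:
#   p1 HQSYV = CAT CAG TCT TAT GTT
#   p2 AQSYV = GCT CAG TCT TAT GTT
#   p3 HQCYV = CAT CAG TGT TAT GTT
#   Q2A HASYV = CAT GCT TCT TAT GTT   -> no_reactive_gln
#   Q2N HNSYV = CAT AAT TCT TAT GTT   -> no_reactive_gln
#   stop HQ*YV = CAT CAG TAA TAT GTT  -> stop_codon
# Layout: 12 pairs = 3x p1 + 2x p2 + 1x p3 (accepted)
#   + 2 low-quality (p1 construct, Phred 2)
#   + 1 untagged (leading GGGGGGGGGG, p1 construct)
#   + 1 Q2A + 1 Q2N + 1 stop.
# Hand truth: counts {p1: 3, p2: 2, p3: 1};
# rejections {low_quality: 2, no_tag: 1, no_reactive_gln: 2, stop_codon: 1}.
hand_fixture <- function(dir = withr::local_tempdir(.local_envir = parent.frame())) {
  d <- mini_design()
  tag <- unname(d$tags[["s1"]])
  con <- function(dna, lead = tag) {
    paste0(lead, d$upstream_anchor, dna, d$downstream_anchor)
  }
  p1 <- "CATCAGTCTTATGTT"
  p2 <- "GCTCAGTCTTATGTT"
  p3 <- "CATCAGTGTTATGTT"
  q2a <- "CATGCTTCTTATGTT"
  q2n <- "CATAATTCTTATGTT"
  stp <- "CATCAGTAATATGTT"
  r1 <- c(
    rep(con(p1), 3), rep(con(p2), 2), con(p3),
    rep(con(p1), 2), # low quality
    con(p1, lead = "GGGGGGGGGG"), # untagged
    con(q2a), con(q2n), con(stp)
  )
  hi <- strrep("I", nchar(r1[1])) # Phred 40
  lo <- strrep("#", nchar(r1[1])) # Phred 2
  q1 <- c(rep(hi, 6), lo, lo, rep(hi, 4))
  r2 <- as.character(
    Biostrings::reverseComplement(Biostrings::DNAStringSet(r1))
  )
  r1_path <- file.path(dir, "fix_R1.fastq")
  r2_path <- file.path(dir, "fix_R2.fastq")
  write_fastq_lines(r1_path, r1, q1)
  write_fastq_lines(r2_path, r2, q1)
  list(
    design = d, r1 = r1_path, r2 = r2_path,
    expected_counts = c(HQSYV = 3L, AQSYV = 2L, HQCYV = 1L),
    expected_rejections = c(
      adapter_only = 0L, low_quality = 2L, no_tag = 1L, no_anchor = 0L,
      frame_fail = 0L, no_reactive_gln = 2L, stop_codon = 1L
    )
  )
}

# Random peptides over the 20-letter alphabet, fixed length.
random_peptides <- function(n, len) {
  m <- matrix(
    sample(pepselect:::AA_ALPHABET, n * len, replace = TRUE),
    nrow = n
  )
  do.call(paste0, as.data.frame(m, stringsAsFactors = FALSE))
}
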