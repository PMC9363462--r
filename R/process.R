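## Fast-path anchor check at a fixed offset: do both anchors sit within
## `mm` substitutions of their expected windows?
.anchored_at <- function(seq, design, off, mm) {
  upl <- nchar(design$upstream_anchor)
  dnl <- nchar(design$downstream_anchor)
  L3 <- 3L * design$length
  need <- off + upl + L3 + dnl
  ok <- nchar(seq) >= need
  res <- rep(FALSE, length(seq))
  if (any(ok)) {
    up_win <- substr(seq[ok], off + 1L, off + upl)
    dn_win <- substr(seq[ok], off + upl + L3 + 1L, need)
    res[ok] <- .hamming_fixed(up_win, design$upstream_anchor) <= mm &
      .hamming_fixed(dn_win, design$downstream_anchor) <= mm
  }
  res
}

## General anchor search (substitution-tolerant, any offset) for reads the
## fixed-offset fast path missed.
.extract_general <- function(seq, design, mm) {
  n <- length(seq)
  dna <- rep(NA_character_, n)
  status <- rep("no_anchor", n)
  if (n == 0) {
    return(list(dna = dna, status = status))
  }
  clean <- gsub("[^ACGTN]", "N", seq)
  ss <- Biostrings::DNAStringSet(clean)
  mu <- Biostrings::vmatchPattern(design$upstream_anchor, ss,
    max.mismatch = mm
  )
  md <- Biostrings::vmatchPattern(design$downstream_anchor, ss,
    max.mismatch = mm
  )
  su <- Biostrings::startIndex(mu)
  sdn <- Biostrings::startIndex(md)
  upl <- nchar(design$upstream_anchor)
  L3 <- 3L * design$length
  for (i in seq_len(n)) {
    us <- su[[i]]
    if (is.null(us) || !length(us)) next
    up_end <- us[1] + upl - 1L
    ds <- sdn[[i]]
    if (is.null(ds)) next
    ds <- ds[ds > up_end]
    if (!length(ds)) next
    extracted <- substr(seq[i], up_end + 1L, ds[1] - 1L)
    if (nchar(extracted) == L3) {
      dna[i] <- extracted
      status[i] <- "ok"
    } else {
      status[i] <- "frame_fail"
    }
  }
  list(dna = dna, status = status)
}

.extract_one_orientation <- function(seq, design, mm) {
  n <- length(seq)
  dna <- rep(NA_character_, n)
  status <- rep(NA_character_, n)
  upl <- nchar(design$upstream_anchor)
  L3 <- 3L * design$length
  ## fixed-offset fast path: anchors at their designed positions (with or
  ## without a leading tag); covers substitution-only data
  offs <- unique(c(0L, unique(nchar(design$tags))))
  pending <- seq_len(n)
  for (off in offs) {
    if (!length(pending)) break
    hit <- .anchored_at(seq[pending], design, off, mm)
    if (any(hit)) {
      i <- pending[hit]
      dna[i] <- substr(seq[i], off + upl + 1L, off + upl + L3)
      status[i] <- "ok"
      pending <- pending[!hit]
    }
  }
  if (length(pending)) {
    gen <- .extract_general(seq[pending], design, mm)
    dna[pending] <- gen$dna
    status[pending] <- gen$status
  }
  list(dna = dna, status = status)
}

#' Extract the peptide-coding DNA from read pairs
#'
#' Locates the upstream and downstream anchors (tolerating up to
#' `max_anchor_mismatch` substitutions, no indels) in read 1 — after any
#' leading tag — and returns the DNA between them. When read 1 fails, the
#' reverse complement of read 2 is tried. Failures are reported per read, not
#' raised: `"no_anchor"` when an anchor cannot be found, `"frame_fail"` when
#' the extracted region is not exactly `3 * L` nt.
#'
#' @param r1 Character vector of read-1 sequences.
#' @param r2 Optional read-2 sequences (same length as `r1`).
#' @param design A [library_design()].
#' @param max_anchor_mismatch Substitutions tolerated per anchor.
#' @return A tibble with columns `dna` (`NA` on failure) and `status`
#'   (`"ok"`, `"no_anchor"` or `"frame_fail"`).
#' @export
extract_coding_dna <- function(r1, r2 = NULL, design,
                               max_anchor_mismatch = 1L) {
  res <- .extract_one_orientation(r1, design, max_anchor_mismatch)
  if (!is.null(r2)) {
    stopifnot(length(r2) == length(r1))
    fail <- which(res$status != "ok")
    if (length(fail)) {
      res2 <- .extract_one_orientation(
        .revcomp(r2[fail]), design, max_anchor_mismatch
      )
      got <- res2$status == "ok"
      res$dna[fail[got]] <- res2$dna[got]
      res$status[fail[got]] <- "ok"
    }
  }
  tibble::tibble(dna = res$dna, status = res$status)
}

#' Apply the library-design peptide filters
#'
#' Rejects peptides lacking glutamine at a fixed backbone position that the
#' design expects to be the reactive glutamine (`"no_reactive_gln"`; this
#' filter is active only where the reactive position is fixed — e.g. Lib4 —
#' and is skipped where it is itself randomized, as in LibQ), then peptides
#' with a stop anywhere (`"stop_codon"`). Peptides whose non-randomized
#' backbone differs from the template elsewhere are accepted: such variants
#' carry the reactive glutamine and can be genuine substrates.
#'
#' @param peptides Character vector of peptides of the design's length.
#' @param design A [library_design()].
#' @return Character vector: `"ok"`, `"no_reactive_gln"` or `"stop_codon"`.
#' @export
#' @examples
#' d <- preset_design("Lib4")
#' accept_peptide(c("HQSYVDPWMLDH", "HASYVDPWMLDH", "HQSYVDPWMLD*"), d)
accept_peptide <- function(peptides, design) {
  if (any(nchar(peptides) != design$length)) {
    stop("peptides must have the design's length", call. = FALSE)
  }
  out <- rep("ok", length(peptides))
  for (i in .fixed_gln_positions(design)) {
    out[substr(peptides, i, i) != "Q" & out == "ok"] <- "no_reactive_gln"
  }
  out[out == "ok" & grepl("*", peptides, fixed = TRUE)] <- "stop_codon"
  out
}

.REJECT_REASONS <- c(
  "adapter_only", "low_quality", "no_tag", "no_anchor", "frame_fail",
  "no_reactive_gln", "stop_codon"
)

#' Count accepted peptides from paired-end FASTQ
#'
#' Streams read pairs through the full processing chain: adapter trimming,
#' mean-quality filter (a pair is kept only when both mates pass),
#' tag demultiplexing (when the design carries tags), anchor-based extraction
#' of the coding region (read 1, falling back to the reverse complement of
#' read 2), translation, and the design filters of [accept_peptide()].
#' Every rejected pair is tallied under exactly one reason, so accepted plus
#' rejected always equals the number of input pairs.
#'
#' @param r1_path,r2_path FASTQ paths (`r2_path` optional).
#' @param design A [library_design()].
#' @param quality_threshold Mean Phred threshold (default 25).
#' @param tag_max_mismatch Tag substitutions tolerated (default 1).
#' @param anchor_max_mismatch Anchor substitutions tolerated (default 1).
#' @param adapters Optional adapter sequences to trim before filtering.
#' @param min_overlap,max_mismatch_rate Adapter-trim parameters, see
#'   [trim_adapter()].
#' @param sample_name Sample label used when the design has no tags.
#' @return An object of class `processed_counts`: a list with tibbles
#'   `counts` (`sample`, `peptide`, `count`), `rejections` (`reason`, `n`),
#'   a one-row `qc` tibble over all input bases, and `n_pairs`.
#' @export
count_peptides <- function(r1_path, r2_path = NULL, design,
                           quality_threshold = 25,
                           tag_max_mismatch = 1L,
                           anchor_max_mismatch = 1L,
                           adapters = character(),
                           min_overlap = 5L,
                           max_mismatch_rate = 0.2,
                           sample_name = "sample1") {
  fq1 <- read_fastq(r1_path, allow_empty = TRUE)
  paired <- !is.null(r2_path)
  fq2 <- if (paired) read_fastq(r2_path, allow_empty = TRUE) else NULL
  n <- nrow(fq1)
  if (paired && nrow(fq2) != n) {
    stop(sprintf(
      "mate files disagree: %d vs %d reads (%s)", n, nrow(fq2), r2_path
    ), call. = FALSE)
  }
  empty_qc <- tibble::tibble(
    n_reads = 0L, n_bases = 0L, q20_pct = NA_real_, q30_pct = NA_real_,
    n_pass_quality = 0L, pass_pct = NA_real_
  )
  if (n == 0) {
    return(structure(
      list(
        counts = tibble::tibble(
          sample = character(0), peptide = character(0), count = integer(0)
        ),
        rejections = tibble::tibble(reason = .REJECT_REASONS, n = 0L),
        qc = empty_qc,
        n_pairs = 0L
      ),
      class = "processed_counts"
    ))
  }
  v1 <- utf8ToInt(paste0(fq1$qual, collapse = ""))
  v2 <- if (paired) utf8ToInt(paste0(fq2$qual, collapse = "")) else integer(0)
  raw_means1 <- .phred_means(fq1$qual, v1)
  raw_means2 <- if (paired) .phred_means(fq2$qual, v2)
  n_q20 <- sum(v1 >= 53L) + sum(v2 >= 53L) # Phred 20 + 33
  n_q30 <- sum(v1 >= 63L) + sum(v2 >= 63L)
  qc <- tibble::tibble(
    n_reads = n * (1L + paired),
    n_bases = length(v1) + length(v2),
    q20_pct = 100 * n_q20 / (length(v1) + length(v2)),
    q30_pct = 100 * n_q30 / (length(v1) + length(v2)),
    n_pass_quality = sum(raw_means1 >= quality_threshold),
    pass_pct = 100 * mean(raw_means1 >= quality_threshold)
  )

  seq1 <- fq1$seq
  qual1 <- fq1$qual
  seq2 <- if (paired) fq2$seq else NULL
  qual2 <- if (paired) fq2$qual else NULL
  status <- rep("ok", n)

  if (length(adapters)) {
    tr1 <- trim_adapter(seq1, qual1, adapters, min_overlap, max_mismatch_rate)
    seq1 <- tr1$seq
    qual1 <- tr1$qual
    if (paired) {
      tr2 <- trim_adapter(
        seq2, qual2, adapters, min_overlap, max_mismatch_rate
      )
      seq2 <- tr2$seq
      qual2 <- tr2$qual
    }
    gone <- nchar(seq1) == 0L | (paired & nchar(seq2) == 0L)
    status[gone] <- "adapter_only"
  }

  live <- status == "ok"
  trimmed <- length(adapters) > 0
  means1 <- if (trimmed) .phred_means(qual1) else raw_means1
  pass <- means1 >= quality_threshold
  if (paired) {
    means2 <- if (trimmed) .phred_means(qual2) else raw_means2
    pass <- pass & means2 >= quality_threshold
  }
  status[live & !pass] <- "low_quality"

  sample <- rep(sample_name, n)
  if (length(design$tags)) {
    live <- status == "ok"
    lab <- demultiplex(seq1[live], design$tags, tag_max_mismatch)
    sample[live] <- lab
    status[live][lab == "unassigned"] <- "no_tag"
  }

  live <- which(status == "ok")
  peptide <- rep(NA_character_, n)
  if (length(live)) {
    ext <- extract_coding_dna(
      seq1[live], if (paired) seq2[live], design, anchor_max_mismatch
    )
    status[live] <- ifelse(ext$status == "ok", "ok", ext$status)
    okx <- which(ext$status == "ok")
    if (length(okx)) {
      dna <- ext$dna[okx]
      ## reads with ambiguous bases in the coding region cannot be placed in
      ## frame-correct translation; tally them with the frame failures
      clean <- !grepl("[^ACGT]", dna)
      status[live[okx[!clean]]] <- "frame_fail"
      if (any(clean)) {
        u <- unique(dna[clean])
        pep_u <- translate_dna(u)
        pep <- pep_u[match(dna[clean], u)]
        acc <- accept_peptide(pep, design)
        keep <- acc == "ok"
        idx <- live[okx[clean]]
        status[idx] <- ifelse(keep, "ok", acc)
        peptide[idx[keep]] <- pep[keep]
      }
    }
  }

  accepted <- which(status == "ok")
  counts <- dplyr::count(
    tibble::tibble(sample = sample[accepted], peptide = peptide[accepted]),
    .data$sample, .data$peptide,
    name = "count"
  )
  rej <- table(factor(status[status != "ok"], levels = .REJECT_REASONS))
  rejections <- tibble::tibble(
    reason = .REJECT_REASONS, n = as.integer(rej)
  )
  structure(
    list(counts = counts, rejections = rejections, qc = qc, n_pairs = n),
    class = "processed_counts"
  )
}

#' @export
print.processed_counts <- function(x, ...) {
  cat(sprintf(
    "<processed_counts> %d read pairs: %d accepted, %d rejected\n",
    x$n_pairs, sum(x$counts$count), sum(x$rejections$n)
  ))
  rej <- x$rejections[x$rejections$n > 0, ]
  if (nrow(rej)) {
    cat(paste(sprintf("  %s: %d", rej$reason, rej$n), collapse = "\n"), "\n")
  }
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.processed_counts <- function(x, ...) {
  x$counts
}

#' @exportS3Method generics::glance
glance.processed_counts <- function(x, ...) {
  dplyr::bind_cols(
    tibble::tibble(
      n_pairs = x$n_pairs,
      n_accepted = sum(x$counts$count),
      n_rejected = sum(x$rejections$n)
    ),
    x$qc
  )
}
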