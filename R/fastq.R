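#' Read a FASTQ file into a tibble
#'
#' Plain or gzipped, Phred+33, 4-line records.
#'
#' @param path FASTQ path.
#' @param allow_empty Return a 0-row tibble for an empty file instead of
#'   raising a parse error?
#' @return A tibble with columns `id`, `seq`, `qual`.
#' @export
read_fastq <- function(path, allow_empty = FALSE) {
  if (!file.exists(path)) {
    stop(sprintf("FASTQ file not found: %s", path), call. = FALSE)
  }
  lines <- if (file.size(path) == 0) {
    character(0)
  } else if (grepl("\\.gz$", path)) {
    con <- gzfile(path, "rt")
    on.exit(close(con))
    readLines(con)
  } else {
    dt <- data.table::fread(
      file = path, sep = "\n", header = FALSE, quote = "",
      colClasses = "character", blank.lines.skip = FALSE
    )
    if (nrow(dt)) dt[[1]] else character(0)
  }
  if (length(lines) == 0) {
    if (allow_empty) {
      return(tibble::tibble(
        id = character(0), seq = character(0), qual = character(0)
      ))
    }
    stop(sprintf("empty FASTQ file: %s", path), call. = FALSE)
  }
  if (length(lines) %% 4L != 0L) {
    stop(sprintf(
      "malformed FASTQ %s: %d lines, not a multiple of 4", path, length(lines)
    ), call. = FALSE)
  }
  n <- length(lines) %/% 4L
  id <- lines[seq.int(1L, by = 4L, length.out = n)]
  seqs <- lines[seq.int(2L, by = 4L, length.out = n)]
  plus <- lines[seq.int(3L, by = 4L, length.out = n)]
  qual <- lines[seq.int(4L, by = 4L, length.out = n)]
  bad <- which(!startsWith(id, "@") | !startsWith(plus, "+") |
    nchar(seqs) != nchar(qual))
  if (length(bad)) {
    stop(sprintf(
      "malformed FASTQ record %d in %s", bad[1], path
    ), call. = FALSE)
  }
  tibble::tibble(id = sub("^@", "", id), seq = seqs, qual = qual)
}

#' Base-quality report for a FASTQ file
#'
#' Q20/Q30 are the percentages of bases with Phred quality at or above 20 and
#' 30; `n_pass_quality` counts reads whose mean Phred quality reaches
#' `threshold` (see [pass_quality()]).
#'
#' @param path FASTQ path (non-empty; an empty file is a parse error).
#' @param threshold Mean-quality threshold for the pass count.
#' @return A one-row tibble: `n_reads`, `n_bases`, `q20_pct`, `q30_pct`,
#'   `n_pass_quality`, `pass_pct`.
#' @export
assess_quality <- function(path, threshold = 25) {
  fq <- read_fastq(path)
  v <- utf8ToInt(paste0(fq$qual, collapse = "")) - 33L
  means <- .phred_means(fq$qual)
  n_pass <- sum(means >= threshold)
  tibble::tibble(
    n_reads = nrow(fq),
    n_bases = length(v),
    q20_pct = 100 * mean(v >= 20L),
    q30_pct = 100 * mean(v >= 30L),
    n_pass_quality = n_pass,
    pass_pct = 100 * n_pass / nrow(fq)
  )
}

#' Mean-quality read filter
#'
#' A read passes when its mean Phred quality is at least `threshold`
#' (inclusive). This is the average-quality semantics of the common
#' command-line filters; a read pair should be kept only if both mates pass.
#'
#' @param qual Character vector of Phred+33 quality strings.
#' @param threshold Mean Phred threshold (default 25).
#' @return Logical vector.
#' @export
pass_quality <- function(qual, threshold = 25) {
  .phred_means(qual) >= threshold
}

#' Trim 3' adapter overlap from reads
#'
#' Removes the longest read suffix that matches a prefix of any adapter with
#' at least `min_overlap` bases and a mismatch rate no greater than
#' `max_mismatch_rate`; qualities are trimmed alongside. Reads with no such
#' overlap are returned unchanged. Substitution-only matching, no indels.
#'
#' @param seq Character vector of read sequences.
#' @param qual Optional matching quality strings.
#' @param adapters Non-empty character vector of adapter sequences.
#' @param min_overlap Minimum overlap length.
#' @param max_mismatch_rate Maximum fraction of mismatches in the overlap.
#' @return A tibble with columns `seq` and `qual` (the latter `NA` when no
#'   qualities were given).
#' @export
trim_adapter <- function(seq, qual = NULL, adapters,
                         min_overlap = 5L, max_mismatch_rate = 0.2) {
  if (length(adapters) == 0) {
    stop("adapter list must be non-empty", call. = FALSE)
  }
  n <- length(seq)
  best_trim <- integer(n) # number of bases removed
  for (ad in adapters) {
    kmax <- nchar(ad)
    if (kmax < min_overlap) next
    for (k in seq.int(kmax, min_overlap)) {
      cand <- which(nchar(seq) >= k & best_trim < k)
      if (!length(cand)) next
      tails <- substr(seq[cand], nchar(seq[cand]) - k + 1L, nchar(seq[cand]))
      mism <- .hamming_fixed(tails, substr(ad, 1L, k))
      hit <- mism / k <= max_mismatch_rate
      best_trim[cand[hit]] <- pmax(best_trim[cand[hit]], k)
    }
  }
  new_len <- nchar(seq) - best_trim
  out_seq <- substr(seq, 1L, new_len)
  out_qual <- if (is.null(qual)) NA_character_ else substr(qual, 1L, new_len)
  tibble::tibble(seq = out_seq, qual = out_qual)
}

#' Assign reads to samples by their leading in-read tag
#'
#' Compares the first `nchar(tag)` bases of each read against every tag and
#' assigns the label of the unique tag within `max_mismatch` substitutions;
#' reads with no tag close enough, or with two tags tied at the minimum
#' distance, are `"unassigned"`.
#'
#' @param seq Character vector of read sequences.
#' @param tags Named character vector of pairwise-distinct tags (equal
#'   length).
#' @param max_mismatch Maximum substitutions tolerated (default 1).
#' @return Character vector of tag labels or `"unassigned"`.
#' @export
demultiplex <- function(seq, tags, max_mismatch = 1L) {
  stopifnot(length(tags) >= 1, !is.null(names(tags)))
  tlen <- unique(nchar(tags))
  if (length(tlen) != 1) {
    stop("tags must all have the same length", call. = FALSE)
  }
  if (anyDuplicated(tags)) {
    stop("tags must be pairwise distinct", call. = FALSE)
  }
  n <- length(seq)
  out <- rep("unassigned", n)
  long_enough <- nchar(seq) >= tlen
  if (!any(long_enough)) {
    return(out)
  }
  lead <- substr(seq[long_enough], 1L, tlen)
  d <- vapply(unname(tags), function(tg) .hamming_fixed(lead, tg),
    integer(sum(long_enough))
  )
  d <- matrix(d, ncol = length(tags))
  dmin <- do.call(pmin, as.data.frame(d))
  ties <- rowSums(d == dmin) > 1L
  label <- names(tags)[max.col(-d, ties.method = "first")]
  label[ties | dmin > max_mismatch] <- "unassigned"
  out[long_enough] <- label
  out
}
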