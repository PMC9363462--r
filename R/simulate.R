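#' Sequencing model for simulated read emission
#'
#' @param reads_per_sample Number of read pairs emitted per sample.
#' @param read_length Read length in nt; `NULL` means exactly the construct
#'   length. Reads longer than the construct are padded with `G` (the
#'   no-signal base call of two-channel instruments).
#' @param per_base_error Substitution probability per sequenced base.
#' @param quality_mean,quality_sd Mean and spread of the emitted Phred
#'   qualities (per base, clamped to `[2, 41]`).
#' @param paired Emit a second read (reverse complement, independent errors)?
#' @return An object of class `sequencing_model`.
#' @export
sequencing_model <- function(reads_per_sample,
                             read_length = NULL,
                             per_base_error = 0.005,
                             quality_mean = 36,
                             quality_sd = 3,
                             paired = TRUE) {
  stopifnot(
    reads_per_sample >= 1,
    per_base_error >= 0, per_base_error < 1,
    quality_sd >= 0
  )
  structure(
    list(
      reads_per_sample = as.integer(reads_per_sample),
      read_length = if (is.null(read_length)) NULL else as.integer(read_length),
      per_base_error = per_base_error,
      quality_mean = quality_mean,
      quality_sd = quality_sd,
      paired = isTRUE(paired)
    ),
    class = "sequencing_model"
  )
}

#' Sample a display library pool
#'
#' Draws `n_molecules` molecules from the design: backbone codons are fixed
#' (the design's `backbone_dna`) and every randomized position draws uniformly
#' from the 32 NNK codons, so each residue appears with probability
#' proportional to its NNK codon multiplicity and the amber stop TAG appears
#' at rate 1/32 per randomized site.
#'
#' @param design A [library_design()].
#' @param n_molecules Number of molecules to draw.
#' @param seed Integer seed; identical seeds give identical pools.
#' @return A tibble with columns `dna` (coding region only, no anchors),
#'   `peptide` and `count`, one row per distinct molecule.
#' @export
sample_library <- function(design, n_molecules, seed = 1L) {
  stopifnot(n_molecules >= 1)
  nnk <- enumerate_nnk()
  pos <- design$randomized_indices
  k <- length(pos)
  draws <- .with_seed(seed, {
    matrix(sample.int(32L, n_molecules * k, replace = TRUE), ncol = k)
  })
  ## splice variable codons into the fixed backbone DNA
  bb <- design$backbone_dna
  res <- strsplit(design$backbone_peptide, "")[[1]]
  dna_segs <- vector("list", 2L * k + 1L)
  pep_segs <- vector("list", 2L * k + 1L)
  prev <- 0L
  for (j in seq_len(k)) {
    fixed <- setdiff(seq_len(pos[j] - 1L), seq_len(prev))
    dna_segs[[2L * j - 1L]] <- if (length(fixed)) {
      substr(bb, 3L * min(fixed) - 2L, 3L * max(fixed))
    } else {
      ""
    }
    pep_segs[[2L * j - 1L]] <- paste0(res[fixed], collapse = "")
    dna_segs[[2L * j]] <- nnk$codon[draws[, j]]
    pep_segs[[2L * j]] <- nnk$residue[draws[, j]]
    prev <- pos[j]
  }
  tail_idx <- setdiff(seq_len(design$length), seq_len(prev))
  dna_segs[[2L * k + 1L]] <- if (length(tail_idx)) {
    substr(bb, 3L * min(tail_idx) - 2L, 3L * design$length)
  } else {
    ""
  }
  pep_segs[[2L * k + 1L]] <- paste0(res[tail_idx], collapse = "")
  pool <- tibble::tibble(
    dna = do.call(paste0, dna_segs),
    peptide = do.call(paste0, pep_segs)
  )
  dplyr::count(pool, .data$dna, .data$peptide, name = "count")
}

#' Simulate one round of selection over a pool
#'
#' Every molecule of peptide `x` is captured independently with probability
#' `p_x` from [capture_probability()], so
#' `count_after[x] ~ Binomial(count_before[x], p_x)`.
#'
#' @param pool A pool tibble from [sample_library()] (columns `dna`,
#'   `peptide`, `count`).
#' @param model A [selection_model()].
#' @param design The matching [library_design()].
#' @param seed Integer seed.
#' @return A tibble with columns `dna`, `peptide`, `count_before`,
#'   `count_after` and the ground-truth capture probability `p`.
#' @export
simulate_selection <- function(pool, model, design, seed = 1L) {
  stopifnot(nrow(pool) > 0)
  p <- capture_probability(pool$peptide, model, design)
  after <- .with_seed(seed, rbinom(nrow(pool), pool$count, p))
  tibble::tibble(
    dna = pool$dna,
    peptide = pool$peptide,
    count_before = pool$count,
    count_after = after,
    p = p
  )
}

## Substitute bases in `reads` at rate `rate`, uniformly over the other three
## bases. Operates on one concatenated raw vector for speed.
.inject_errors <- function(reads, rate) {
  if (rate <= 0 || length(reads) == 0) {
    return(reads)
  }
  widths <- nchar(reads)
  big <- charToRaw(paste0(reads, collapse = ""))
  ## draw the total error count, then uniform error positions: jointly
  ## equivalent to iid per-base Bernoulli(rate), far cheaper at this scale
  n_err <- rbinom(1L, length(big), rate)
  hit <- sample.int(length(big), n_err)
  if (length(hit)) {
    bases <- charToRaw("ACGT")
    ## alternatives per base, laid out as a 3 x 4 lookup
    alts <- vapply(
      1:4,
      function(i) bases[-i],
      raw(3)
    )
    cur <- match(big[hit], bases)
    ok <- !is.na(cur)
    pick <- sample.int(3L, sum(ok), replace = TRUE)
    big[hit[ok]] <- alts[cbind(pick, cur[ok])]
  }
  s <- rawToChar(big)
  ends <- cumsum(widths)
  substring(s, ends - widths + 1L, ends)
}

## Random Phred+33 quality strings: n strings of width len, per-base normal
## qualities clamped to [2, 41].
.random_quals <- function(n, len, mean, sd) {
  ## discretized normal over Phred 2..41 (round-to-integer with clamped
  ## tails), drawn from the precomputed table
  vals <- 2:41
  if (sd > 0) {
    pr <- diff(pnorm(c(-Inf, vals[-length(vals)] + 0.5, Inf), mean, sd))
    q <- vals[sample.int(length(vals), n * len, replace = TRUE, prob = pr)]
  } else {
    q <- rep.int(as.integer(max(2, min(41, round(mean)))), n * len)
  }
  s <- rawToChar(as.raw(q + 33L))
  starts <- seq.int(1L, by = len, length.out = n)
  substring(s, starts, starts + len - 1L)
}

.write_fastq <- function(path, ids, seqs, quals) {
  con <- if (grepl("\\.gz$", path)) gzfile(path, "wb") else file(path, "wb")
  on.exit(close(con))
  writeLines(as.vector(rbind(paste0("@", ids), seqs, "+", quals)), con)
  invisible(path)
}

#' Emit paired-end FASTQ reads from molecule counts
#'
#' Reads are allocated to molecules by a multinomial draw proportional to
#' their counts. Each read-1 is `[tag] + upstream_anchor + coding DNA +
#' downstream_anchor` (padded with `G` up to the read length); read-2 is the
#' reverse complement of the construct with independent errors. Substitution
#' errors are applied at the model's per-base rate and Phred+33 qualities are
#' drawn from the quality profile. Output is gzipped when the path ends in
#' `.gz`. Emission is byte-deterministic under a fixed seed.
#'
#' @param counts A tibble with columns `dna` and `count` (e.g. a pool from
#'   [sample_library()], or [simulate_selection()] output renamed).
#' @param design A [library_design()].
#' @param seq_model A [sequencing_model()].
#' @param r1_path,r2_path Output FASTQ paths (`r2_path` required when the
#'   model is paired).
#' @param tag_label Optional name of a design tag to prepend to read 1.
#' @param sample_name Prefix for read identifiers.
#' @param seed Integer seed.
#' @return Invisibly, a tibble with `dna` and `n_reads`: the exact read
#'   allocation (the ground truth for zero-noise round trips).
#' @export
emit_fastq <- function(counts, design, seq_model,
                       r1_path, r2_path = NULL,
                       tag_label = NULL, sample_name = "sample",
                       seed = 1L) {
  stopifnot(
    inherits(seq_model, "sequencing_model"),
    all(c("dna", "count") %in% names(counts)),
    nrow(counts) > 0, sum(counts$count) > 0
  )
  if (seq_model$paired && is.null(r2_path)) {
    stop("paired sequencing model needs r2_path", call. = FALSE)
  }
  tag <- ""
  if (!is.null(tag_label)) {
    if (!tag_label %in% names(design$tags)) {
      stop(sprintf("design has no tag '%s'", tag_label), call. = FALSE)
    }
    tag <- unname(design$tags[[tag_label]])
  }
  construct <- paste0(
    tag, design$upstream_anchor, counts$dna, design$downstream_anchor
  )
  clen <- unique(nchar(construct))
  if (length(clen) != 1) {
    stop("all constructs must have equal length", call. = FALSE)
  }
  rl <- seq_model$read_length %||% clen
  if (rl < clen) {
    stop(sprintf(
      "read_length %d is shorter than the construct (%d nt)", rl, clen
    ), call. = FALSE)
  }
  if (rl > clen) {
    construct <- paste0(construct, strrep("G", rl - clen))
  }
  n_reads <- seq_model$reads_per_sample
  .with_seed(seed, {
    alloc <- as.integer(rmultinom(1, n_reads, prob = counts$count))
    idx <- sample(rep.int(seq_along(alloc), alloc))
    ids <- sprintf("%s.%d", sample_name, seq_len(n_reads))
    r1 <- .inject_errors(construct[idx], seq_model$per_base_error)
    q1 <- .random_quals(
      n_reads, rl, seq_model$quality_mean, seq_model$quality_sd
    )
    .write_fastq(r1_path, paste0(ids, " 1"), r1, q1)
    if (seq_model$paired) {
      rc <- .revcomp(construct)
      r2 <- .inject_errors(rc[idx], seq_model$per_base_error)
      q2 <- .random_quals(
        n_reads, rl, seq_model$quality_mean, seq_model$quality_sd
      )
      .write_fastq(r2_path, paste0(ids, " 2"), r2, q2)
    }
    invisible(tibble::tibble(dna = counts$dna, n_reads = alloc))
  })
}
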