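#' Normalize counts to within-sample frequencies
#'
#' @param x A tibble with a `count` column.
#' @param count_col Name of the count column.
#' @return `x` with an added `freq` column summing to 1.
#' @export
normalize_counts <- function(x, count_col = "count") {
  total <- sum(x[[count_col]])
  if (!is.finite(total) || total <= 0) {
    stop("sample total must be positive (empty sample)", call. = FALSE)
  }
  x$freq <- x[[count_col]] / total
  x
}

#' Assemble a before/after count table
#'
#' Joins before- and after-selection peptide counts into one table, the pivot
#' between read processing and the enrichment statistics. Accepts either a
#' long tibble (`sample`, `peptide`, `count`) — e.g. `tidy()` of a
#' [count_peptides()] result, or two such results — or a pair of per-sample
#' tibbles (`peptide`, `count`).
#'
#' @param x Long counts tibble, or a [count_peptides()] result, or a
#'   `peptide`/`count` tibble for the before sample.
#' @param after When `x` is a before-sample tibble: the matching after-sample
#'   tibble. Otherwise ignored.
#' @param before_label,after_label Sample labels identifying the two samples
#'   in long input.
#' @return A tibble with columns `peptide`, `count_before`, `count_after`
#'   (missing peptides filled with 0).
#' @export
count_table <- function(x, after = NULL,
                        before_label = "before", after_label = "after") {
  if (inherits(x, "processed_counts")) x <- x$counts
  if (!is.null(after)) {
    if (inherits(after, "processed_counts")) after <- after$counts
    bef <- x
    if ("sample" %in% names(bef)) bef$sample <- NULL
    if ("sample" %in% names(after)) after$sample <- NULL
    out <- dplyr::full_join(
      dplyr::rename(bef, count_before = "count"),
      dplyr::rename(after, count_after = "count"),
      by = "peptide"
    )
  } else {
    stopifnot(all(c("sample", "peptide", "count") %in% names(x)))
    wide <- tidyr::pivot_wider(
      x[x$sample %in% c(before_label, after_label), ],
      names_from = "sample", values_from = "count"
    )
    for (lbl in c(before_label, after_label)) {
      if (!lbl %in% names(wide)) wide[[lbl]] <- 0L
    }
    out <- dplyr::rename(
      wide,
      count_before = dplyr::all_of(before_label),
      count_after = dplyr::all_of(after_label)
    )
  }
  out$count_before <- as.integer(dplyr::coalesce(out$count_before, 0L))
  out$count_after <- as.integer(dplyr::coalesce(out$count_after, 0L))
  dplyr::arrange(out[, c("peptide", "count_before", "count_after")],
    .data$peptide)
}

#' Per-peptide enrichment factors
#'
#' The enrichment factor of a peptide is the quotient of its total-normalized
#' read frequencies after and before selection:
#' \deqn{EF(x) = \frac{c_{after}(x) / N_{after}}{c_{before}(x) / N_{before}}}
#' so `EF > 1` marks enrichment by the selection. An optional pseudocount is
#' added to both counts (and to the totals, once per peptide) for exploratory
#' use; with the default pseudocount of 0, peptides absent before selection
#' have no defined EF — they are flagged `zero_before` and excluded from
#' ranking rather than reported as infinite.
#'
#' @param tbl A [count_table()] tibble (`peptide`, `count_before`,
#'   `count_after`).
#' @param pseudocount Non-negative pseudocount (default 0).
#' @return A tibble with `peptide`, `count_before`, `count_after`,
#'   `freq_before`, `freq_after`, `ef` and the flags `zero_before`,
#'   `below_min_count` (filled by [rank_top()]'s threshold, here `NA`).
#' @export
#' @examples
#' tbl <- tibble::tibble(
#'   peptide = c("A", "B"), count_before = c(10, 30), count_after = c(30, 10)
#' )
#' peptide_ef(tbl)
peptide_ef <- function(tbl, pseudocount = 0) {
  stopifnot(
    all(c("peptide", "count_before", "count_after") %in% names(tbl)),
    pseudocount >= 0
  )
  cb <- tbl$count_before + pseudocount
  ca <- tbl$count_after + pseudocount
  nb <- sum(cb)
  na <- sum(ca)
  if (nb <= 0 || na <= 0) {
    stop("sample total must be positive (empty sample)", call. = FALSE)
  }
  zero_before <- cb == 0
  fb <- cb / nb
  fa <- ca / na
  ef <- ifelse(zero_before, NA_real_, fa / fb)
  tibble::tibble(
    peptide = tbl$peptide,
    count_before = tbl$count_before,
    count_after = tbl$count_after,
    freq_before = fb,
    freq_after = fa,
    ef = ef,
    zero_before = zero_before
  )
}

#' Rank peptides by enrichment factor
#'
#' Drops peptides whose after-selection count falls below `min_count_after`
#' (strictly: a count equal to the threshold is eligible) and peptides with
#' no defined EF, sorts by EF descending — ties broken by higher
#' after-selection count, then lexicographically by peptide — and returns the
#' first `top_n` with 1-based ranks.
#'
#' @param etable A [peptide_ef()] tibble.
#' @param min_count_after Minimum after-selection count (default 100).
#' @param top_n Number of peptides to return (default 100).
#' @return The ranked tibble with an added `rank` column.
#' @export
rank_top <- function(etable, min_count_after = 100L, top_n = 100L) {
  eligible <- etable[
    !etable$zero_before & !is.na(etable$ef) &
      etable$count_after >= min_count_after,
  ]
  ord <- order(-eligible$ef, -eligible$count_after, eligible$peptide)
  out <- eligible[head(ord, top_n), ]
  out$rank <- seq_len(nrow(out))
  out
}

#' Per-position amino-acid enrichment factors
#'
#' For each randomized position and each residue, the EF of the residue class
#' is the quotient of the class's total-normalized counts after and before
#' selection, aggregated over all peptides carrying that residue at that
#' position. Residues unseen before selection are flagged `undefined` (EF
#' `NA`) rather than reported as infinite. The result is the long form of the
#' position-EF heatmap; see [ef_matrix()] and [plot_position_ef()].
#'
#' @param tbl A [count_table()] tibble.
#' @param design A [library_design()].
#' @return A tibble with `rel_pos` (factor in relative-position order),
#'   `residue`, `count_before`, `count_after`, `ef`, `undefined`.
#' @export
position_aa_ef <- function(tbl, design) {
  stopifnot(nrow(tbl) > 0)
  nb <- sum(tbl$count_before)
  na <- sum(tbl$count_after)
  if (nb <= 0 || na <= 0) {
    stop("sample total must be positive (empty sample)", call. = FALSE)
  }
  labs <- rel_labels(design)
  pos <- design$randomized_indices
  out <- vector("list", length(pos))
  for (j in seq_along(pos)) {
    res <- substr(tbl$peptide, pos[j], pos[j])
    agg <- dplyr::summarise(
      dplyr::group_by(
        tibble::tibble(
          residue = factor(res, levels = AA_ALPHABET),
          cb = tbl$count_before, ca = tbl$count_after
        ),
        .data$residue,
        .drop = FALSE
      ),
      count_before = sum(.data$cb),
      count_after = sum(.data$ca),
      .groups = "drop"
    )
    agg$rel_pos <- labs[j]
    out[[j]] <- agg
  }
  out <- dplyr::bind_rows(out)
  out$undefined <- out$count_before == 0
  out$ef <- ifelse(
    out$undefined, NA_real_,
    (out$count_after / na) / (out$count_before / nb)
  )
  out$rel_pos <- factor(out$rel_pos, levels = labs)
  out$residue <- as.character(out$residue)
  out[, c(
    "rel_pos", "residue", "count_before", "count_after", "ef", "undefined"
  )]
}

#' Pivot a long position-EF table into a residue-by-position matrix
#'
#' @param pos_ef A [position_aa_ef()] tibble.
#' @return A 20 x k numeric matrix (residues by relative positions).
#' @export
ef_matrix <- function(pos_ef) {
  wide <- tidyr::pivot_wider(
    pos_ef[, c("rel_pos", "residue", "ef")],
    names_from = "rel_pos", values_from = "ef"
  )
  m <- as.matrix(wide[, -1, drop = FALSE])
  rownames(m) <- wide$residue
  m[AA_ALPHABET, , drop = FALSE]
}

#' Heatmap-derived consensus sequence
#'
#' For each randomized position, the residue with the maximal defined EF;
#' ties are broken alphabetically and flagged.
#'
#' @param pos_ef A [position_aa_ef()] tibble.
#' @param tol Relative tolerance within which two EFs count as tied.
#' @return A tibble with `rel_pos`, `residue`, `ef`, `tie`; the consensus
#'   string (residues joined by `-`) is attached as attribute `"consensus"`.
#' @export
heatmap_consensus <- function(pos_ef, tol = 0) {
  pick <- function(df) {
    def <- df[!df$undefined & !is.na(df$ef), ]
    if (!nrow(def)) {
      stop(sprintf(
        "no defined EF at position %s (consensus error)", df$rel_pos[1]
      ), call. = FALSE)
    }
    best <- max(def$ef)
    at_top <- def[def$ef >= best * (1 - tol), ]
    at_top <- at_top[order(at_top$residue), ]
    tibble::tibble(
      rel_pos = df$rel_pos[1],
      residue = at_top$residue[1],
      ef = at_top$ef[1],
      tie = nrow(at_top) > 1
    )
  }
  out <- dplyr::bind_rows(lapply(
    split(pos_ef, pos_ef$rel_pos),
    pick
  ))
  out <- out[order(match(out$rel_pos, levels(pos_ef$rel_pos))), ]
  attr(out, "consensus") <- paste(out$residue, collapse = "-")
  out
}

#' Per-position residue frequency matrix (logo export)
#'
#' After-selection residue frequencies per position over a peptide set
#' (typically the top-ranked peptides), for sequence-logo rendering
#' elsewhere. Columns (positions) each sum to 1.
#'
#' @param peptides Character vector of equal-length peptides (or a ranked
#'   tibble with a `peptide` column).
#' @param weights Optional per-peptide weights (default: unweighted).
#' @return A tibble with `position` (1-based), `residue`, `freq`.
#' @export
logo_matrix <- function(peptides, weights = NULL) {
  if (is.data.frame(peptides)) peptides <- peptides$peptide
  stopifnot(length(peptides) > 0)
  L <- unique(nchar(peptides))
  if (length(L) != 1) {
    stop("peptides must have uniform length", call. = FALSE)
  }
  w <- weights %||% rep(1, length(peptides))
  out <- vector("list", L)
  for (i in seq_len(L)) {
    res <- factor(substr(peptides, i, i), levels = AA_ALPHABET)
    f <- tapply(w, res, sum, default = 0)
    out[[i]] <- tibble::tibble(
      position = i,
      residue = AA_ALPHABET,
      freq = as.vector(f) / sum(w)
    )
  }
  dplyr::bind_rows(out)
}
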