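#' Build a zero position-weight matrix for a design
#'
#' Rows are the 20 amino acids (alphabetical), columns the randomized
#' positions labelled relative to the reactive glutamine ("-1", "0", "+1",
#' ...). Entries are in log-odds units.
#'
#' @param design A [library_design()].
#' @param ... Named weight assignments of the form
#'   `"Q@-1" = 2, "I@+3" = 1` (residue, `@`, relative position).
#' @return A 20 x k numeric matrix with dimnames.
#' @export
#' @examples
#' W <- selection_weights(preset_design("Lib4"), "Q@-1" = 2, "F@+2" = -1.5)
selection_weights <- function(design, ...) {
  labs <- rel_labels(design)
  W <- matrix(0,
    nrow = length(AA_ALPHABET), ncol = length(labs),
    dimnames = list(AA_ALPHABET, labs)
  )
  assign <- list(...)
  for (nm in names(assign)) {
    parts <- strsplit(nm, "@", fixed = TRUE)[[1]]
    if (length(parts) != 2 || !parts[1] %in% AA_ALPHABET ||
      !parts[2] %in% labs) {
      stop(sprintf("cannot parse weight assignment '%s'", nm), call. = FALSE)
    }
    W[parts[1], parts[2]] <- assign[[nm]]
  }
  W
}

#' Ground-truth capture model for simulated selections
#'
#' The simulator's selection step captures each displayed molecule
#' independently with probability
#' \deqn{p = \beta + (1 - \beta)\,\sigma(b_0 + \sum_r W[r, a_r])}
#' where \eqn{\sigma} is the logistic function, \eqn{W} a position-weight
#' matrix over the randomized positions, \eqn{b_0} a baseline log-odds and
#' \eqn{\beta} the rate of nonspecific capture (bead background). If
#' `requires_reactive_gln` is set, peptides without glutamine at the reactive
#' position fall back to the background rate \eqn{\beta}, as do peptides with
#' a stop at any scored position. An optional artifact rule adds a fixed
#' capture-probability boost to peptides matching a motif regex, emulating
#' bead-binding false positives (e.g. His/Trp-rich streptavidin binders).
#'
#' @param weights Position-weight matrix as from [selection_weights()].
#' @param baseline Baseline log-odds \eqn{b_0}.
#' @param background Nonspecific capture probability \eqn{\beta} in `[0, 1)`.
#' @param artifact `NULL`, or `list(pattern = <regex on the peptide>,
#'   boost = <added capture probability>)`.
#' @param requires_reactive_gln Should specific capture require glutamine at
#'   the reactive position?
#' @return An object of class `selection_model`.
#' @export
selection_model <- function(weights,
                            baseline = -2,
                            background = 0.002,
                            artifact = NULL,
                            requires_reactive_gln = TRUE) {
  stopifnot(is.matrix(weights), all(is.finite(weights)))
  if (!identical(rownames(weights), AA_ALPHABET)) {
    stop("weights must have the 20 amino acids as rownames", call. = FALSE)
  }
  if (background < 0 || background >= 1) {
    stop("background must be in [0, 1)", call. = FALSE)
  }
  if (!is.null(artifact)) {
    stopifnot(
      is.list(artifact), !is.null(artifact$pattern),
      is.numeric(artifact$boost), artifact$boost >= 0
    )
  }
  structure(
    list(
      weights = weights,
      baseline = baseline,
      background = background,
      artifact = artifact,
      requires_reactive_gln = isTRUE(requires_reactive_gln)
    ),
    class = "selection_model"
  )
}

#' Default planted selection model for a design
#'
#' For the Lib4-style designs the defaults plant a strong preference for
#' glutamine at -1 (the Gln-Gln motif), moderate preferences for isoleucine
#' and valine at +3, and a penalty for phenylalanine at +2, over a weak
#' baseline (`b0 = -2`) with a small nonspecific background (`beta = 0.002`).
#' For single-position designs (LibQ-style) the glutamine at the reactive
#' position gets weight +2. These are the ground-truth conditions the
#' package's recovery tests run under.
#'
#' @param design A [library_design()].
#' @inheritParams selection_model
#' @return A [selection_model()].
#' @export
default_selection_model <- function(design, baseline = -2,
                                    background = 0.002) {
  labs <- rel_labels(design)
  if (all(c("-1", "+1", "+2", "+3") %in% labs)) {
    W <- selection_weights(design,
      "Q@-1" = 2, "I@+3" = 1, "V@+3" = 1, "F@+2" = -1.5
    )
  } else if ("0" %in% labs) {
    W <- selection_weights(design, "Q@0" = 2)
  } else {
    W <- selection_weights(design)
  }
  selection_model(W, baseline = baseline, background = background)
}

#' Capture probability of peptides under a selection model
#'
#' @param peptides Character vector of peptides of the design's length
#'   (`"*"` allowed; stop-containing peptides are never specifically
#'   captured).
#' @param model A [selection_model()].
#' @param design The [library_design()] the model refers to.
#' @return Numeric vector of probabilities in `[0, 1]`.
#' @export
#' @examples
#' d <- preset_design("Lib4")
#' m <- default_selection_model(d)
#' capture_probability("HQSYVDPWMLDH", m, d)
capture_probability <- function(peptides, model, design) {
  stopifnot(inherits(model, "selection_model"))
  if (any(nchar(peptides) != design$length)) {
    stop("peptide length does not match the design", call. = FALSE)
  }
  beta <- model$background
  labs <- rel_labels(design)
  pos <- design$randomized_indices
  n <- length(peptides)
  score <- rep(model$baseline, n)
  valid <- rep(TRUE, n)
  for (j in seq_along(pos)) {
    res <- substr(peptides, pos[j], pos[j])
    known <- res %in% AA_ALPHABET
    valid <- valid & known
    w <- numeric(n)
    w[known] <- model$weights[cbind(res[known], rep(labs[j], sum(known)))]
    score <- score + w
  }
  if (model$requires_reactive_gln) {
    valid <- valid &
      substr(peptides, design$reactive_index, design$reactive_index) == "Q"
  }
  p <- rep(beta, n)
  p[valid] <- beta + (1 - beta) * stats::plogis(score[valid])
  if (!is.null(model$artifact)) {
    hit <- grepl(model$artifact$pattern, peptides)
    p[hit] <- pmin(1, p[hit] + model$artifact$boost)
  }
  p
}

#' Analytic expected position enrichment factors under a model
#'
#' Computes, by exact enumeration over the NNK-induced residue distribution at
#' the randomized positions, the expected enrichment factor of each residue at
#' each randomized position:
#' \deqn{EF(r, a) = E[p \mid a \text{ at } r] / E[p]}
#' The enumeration conditions on stop-free peptides (residue weights are NNK
#' codon multiplicities over the 31 sense codons), matching the population the
#' read-processing filters retain. This is the oracle the parameter-recovery
#' tests compare empirical heatmaps against.
#'
#' @param model A [selection_model()].
#' @param design A [library_design()].
#' @return A tibble with columns `rel_pos`, `residue`, `ef` and the
#'   conditional means `e_p_given` and `e_p`.
#' @export
true_position_ef <- function(model, design) {
  labs <- rel_labels(design)
  k <- length(labs)
  counts <- .nnk_residue_counts()
  frac <- counts / sum(counts)
  grid <- do.call(
    expand.grid,
    c(rep(list(AA_ALPHABET), k), list(stringsAsFactors = FALSE))
  )
  w <- Reduce(`*`, lapply(seq_len(k), function(j) frac[grid[[j]]]))
  ## assemble full peptides so artifact motifs and the reactive-Gln rule see
  ## exactly what the simulator's capture step sees
  res <- strsplit(design$backbone_peptide, "")[[1]]
  segs <- vector("list", 2L * k + 1L)
  prev <- 0L
  for (j in seq_len(k)) {
    at <- design$randomized_indices[j]
    segs[[2L * j - 1L]] <- paste0(res[seq_len(at - 1L)[seq_len(at - 1L) > prev]],
      collapse = ""
    )
    segs[[2L * j]] <- grid[[j]]
    prev <- at
  }
  segs[[2L * k + 1L]] <- paste0(res[seq_len(design$length) > prev],
    collapse = ""
  )
  peptides <- do.call(paste0, segs)
  p <- capture_probability(peptides, model, design)
  e_p <- sum(w * p) / sum(w)
  out <- vector("list", k)
  for (j in seq_len(k)) {
    wp <- rowsum(w * p, grid[[j]], reorder = TRUE)
    ww <- rowsum(w, grid[[j]], reorder = TRUE)
    cond <- as.vector(wp / ww)
    out[[j]] <- tibble::tibble(
      rel_pos = labs[j],
      residue = rownames(wp),
      e_p_given = cond,
      e_p = e_p,
      ef = cond / e_p
    )
  }
  dplyr::bind_rows(out)
}
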