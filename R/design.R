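#' Describe a display-library design
#'
#' A library design is the coordinate system the whole pipeline works in: the
#' backbone peptide, which positions carry degenerate NNK codons, where the
#' reactive glutamine sits, the fixed anchor DNA flanking the peptide-coding
#' region, and any in-read sample tags. All peptide indices are 1-based;
#' positions relative to the reactive glutamine use the signed convention
#' -1 / 0 / +1 / +2 / +3 (0 is the reactive position itself).
#'
#' @param name Label for the design.
#' @param backbone_peptide Backbone peptide as one-letter amino-acid codes.
#' @param reactive_index 1-based index of the reactive glutamine.
#' @param randomized_indices Integer vector of 1-based peptide indices carrying
#'   NNK codons.
#' @param upstream_anchor,downstream_anchor Fixed DNA immediately 5' and 3' of
#'   the peptide-coding region (non-empty, over `{A,C,G,T}`).
#' @param tags Named character vector of 10-nt DNA sample tags (may be empty).
#' @param min_count_after Default after-selection count threshold used when
#'   ranking peptides.
#' @param backbone_dna Optional DNA encoding of the backbone peptide; derived
#'   deterministically from the peptide if omitted.
#' @return An object of class `library_design`.
#' @seealso [preset_design()] for the shipped T26-based presets.
#' @export
library_design <- function(name,
                           backbone_peptide,
                           reactive_index = 2L,
                           randomized_indices,
                           upstream_anchor,
                           downstream_anchor,
                           tags = character(),
                           min_count_after = 100L,
                           backbone_dna = NULL) {
  L <- nchar(backbone_peptide)
  reactive_index <- as.integer(reactive_index)
  randomized_indices <- sort(unique(as.integer(randomized_indices)))
  if (L < 1L) stop("backbone peptide must be non-empty", call. = FALSE)
  if (grepl(paste0("[^", paste(AA_ALPHABET, collapse = ""), "]"),
    backbone_peptide
  )) {
    stop("backbone peptide contains non-standard residues", call. = FALSE)
  }
  if (reactive_index < 1L || reactive_index > L) {
    stop("reactive_index outside the peptide", call. = FALSE)
  }
  if (any(randomized_indices < 1L | randomized_indices > L)) {
    stop("randomized_indices outside the peptide", call. = FALSE)
  }
  for (a in c(upstream_anchor, downstream_anchor)) {
    if (!nzchar(a) || grepl("[^ACGT]", a)) {
      stop("anchors must be non-empty DNA over {A,C,G,T}", call. = FALSE)
    }
  }
  if (length(tags)) {
    if (is.null(names(tags)) || any(!nzchar(names(tags)))) {
      stop("tags must be named", call. = FALSE)
    }
    if (any(nchar(tags) != 10L)) {
      stop("all tags must be 10 nt long", call. = FALSE)
    }
    if (anyDuplicated(tags)) {
      stop("tags must be pairwise distinct", call. = FALSE)
    }
    if (any(grepl("[^ACGT]", tags))) {
      stop("tags must be DNA over {A,C,G,T}", call. = FALSE)
    }
  }
  if (is.null(backbone_dna)) {
    backbone_dna <- encode_peptide(backbone_peptide)
  } else {
    if (nchar(backbone_dna) != 3L * L ||
      translate_dna(backbone_dna) != backbone_peptide) {
      stop("backbone_dna does not encode backbone_peptide", call. = FALSE)
    }
  }
  structure(
    list(
      name = name,
      backbone_peptide = backbone_peptide,
      length = L,
      reactive_index = reactive_index,
      randomized_indices = randomized_indices,
      upstream_anchor = upstream_anchor,
      downstream_anchor = downstream_anchor,
      tags = tags,
      min_count_after = as.integer(min_count_after),
      backbone_dna = backbone_dna
    ),
    class = "library_design"
  )
}

#' @export
print.library_design <- function(x, ...) {
  cat(sprintf(
    "<library_design '%s'>\n  backbone: %s (L = %d)\n", x$name,
    x$backbone_peptide, x$length
  ))
  cat(sprintf(
    "  reactive Gln at %d; randomized at %s (rel %s)\n",
    x$reactive_index,
    paste(x$randomized_indices, collapse = ", "),
    paste(rel_labels(x), collapse = ", ")
  ))
  cat(sprintf(
    "  anchors: 5' %s / 3' %s\n", x$upstream_anchor, x$downstream_anchor
  ))
  if (length(x$tags)) {
    cat(sprintf(
      "  tags: %s\n",
      paste(sprintf("%s=%s", names(x$tags), x$tags), collapse = ", ")
    ))
  }
  invisible(x)
}

## Synthetic flanking construct pieces used by the shipped presets. The true
## construct DNA for the published T26 libraries is not available in machine-
## readable form, so these anchors and tags are synthetic stand-ins; for real
## data they must come from the experiment's config.
.T26_UP_ANCHOR <- "CATATGGGTTCTGGTTCCGG"
.T26_DOWN_ANCHOR <- "GGCAGCGGCAGCCACCATCA"
.T26_TAGS <- c(before = "ACACACGTGT", after = "TGTGTGCACA")

#' Shipped T26-backbone library designs
#'
#' Two presets built on the 12-mer T26 backbone peptide `HQSYVDPWMLDH`
#' (residues 1-7, `HQSYVDP`, are literature-confirmed; residues 8-12 are a
#' literature-derived completion) with the reactive glutamine at position 2:
#'
#' * `"LibQ"`: only the reactive position itself carries an NNK codon
#'   (control library used to verify that selection enriches glutamine).
#' * `"Lib4"`: NNK codons at the four positions surrounding the reactive
#'   glutamine, relative positions -1, +1, +2 and +3.
#'
#' Anchor DNA and the 10-nt before/after tags shipped with the presets are
#' synthetic stand-ins (see [library_design()]); real analyses should supply
#' the construct sequences actually used.
#'
#' @param name `"Lib4"` or `"LibQ"`.
#' @param tags Named tag vector; defaults to the shipped synthetic pair for
#'   LibQ (the published experiment pooled before/after LibQ samples with
#'   in-read tags) and none for Lib4 (sequenced as separate samples).
#' @return A [library_design()].
#' @export
#' @examples
#' preset_design("Lib4")
preset_design <- function(name = c("Lib4", "LibQ"), tags = NULL) {
  name <- match.arg(name)
  backbone <- "HQSYVDPWMLDH"
  if (name == "Lib4") {
    library_design(
      name = "Lib4",
      backbone_peptide = backbone,
      reactive_index = 2L,
      randomized_indices = c(1L, 3L, 4L, 5L),
      upstream_anchor = .T26_UP_ANCHOR,
      downstream_anchor = .T26_DOWN_ANCHOR,
      tags = tags %||% character()
    )
  } else {
    library_design(
      name = "LibQ",
      backbone_peptide = backbone,
      reactive_index = 2L,
      randomized_indices = 2L,
      upstream_anchor = .T26_UP_ANCHOR,
      downstream_anchor = .T26_DOWN_ANCHOR,
      tags = tags %||% .T26_TAGS
    )
  }
}

#' Convert a position relative to the reactive glutamine to an absolute index
#'
#' @param design A [library_design()].
#' @param rel Signed integer position(s) relative to the reactive glutamine
#'   (0 is the reactive position).
#' @return 1-based peptide indices.
#' @export
#' @examples
#' d <- preset_design("Lib4")
#' rel_to_abs(d, -1) # 1
#' rel_to_abs(d, +3) # 5
rel_to_abs <- function(design, rel) {
  idx <- design$reactive_index + as.integer(rel)
  if (any(idx < 1L | idx > design$length)) {
    stop(sprintf(
      "relative position %s falls outside the peptide (coordinate error)",
      paste(rel[idx < 1L | idx > design$length], collapse = ", ")
    ), call. = FALSE)
  }
  idx
}

## Relative positions (signed integers) of the randomized sites.
rel_positions <- function(design) {
  design$randomized_indices - design$reactive_index
}

## Printable labels for relative positions: "-1", "0", "+1", ...
rel_labels <- function(design) {
  r <- rel_positions(design)
  ifelse(r > 0, paste0("+", r), as.character(r))
}

## Fixed (non-randomized) positions whose backbone residue is Gln; the
## reactive-Gln read filter applies exactly at these positions, so it is
## active for Lib4 (reactive Gln fixed) and skipped for LibQ (reactive
## position itself randomized).
.fixed_gln_positions <- function(design) {
  res <- strsplit(design$backbone_peptide, "")[[1]]
  setdiff(which(res == "Q"), design$randomized_indices)
}

#' Read or write a library design as YAML
#'
#' The YAML document mirrors the fields of [library_design()].
#'
#' @param path File path.
#' @param design A [library_design()].
#' @return `read_design()` returns a [library_design()]; `write_design()`
#'   returns `path` invisibly.
#' @export
read_design <- function(path) {
  x <- yaml::read_yaml(path)
  required <- c(
    "name", "backbone_peptide", "reactive_index", "randomized_indices",
    "upstream_anchor", "downstream_anchor"
  )
  missing <- setdiff(required, names(x))
  if (length(missing)) {
    stop(sprintf(
      "design file is missing fields: %s", paste(missing, collapse = ", ")
    ), call. = FALSE)
  }
  library_design(
    name = x$name,
    backbone_peptide = x$backbone_peptide,
    reactive_index = x$reactive_index,
    randomized_indices = unlist(x$randomized_indices),
    upstream_anchor = x$upstream_anchor,
    downstream_anchor = x$downstream_anchor,
    tags = if (length(x$tags)) unlist(x$tags) else character(),
    min_count_after = x$min_count_after %||% 100L,
    backbone_dna = x$backbone_dna
  )
}

#' @rdname read_design
#' @export
write_design <- function(design, path) {
  stopifnot(inherits(design, "library_design"))
  x <- design
  x$tags <- as.list(x$tags)
  class(x) <- NULL
  x$length <- NULL
  yaml::write_yaml(x, path)
  invisible(path)
}
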