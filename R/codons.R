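#' Standard genetic code as a tibble
#'
#' All 64 codons of the standard genetic code, with stop codons rendered as
#' `"*"`.
#'
#' @return A tibble with columns `codon` and `aa` (64 rows).
#' @export
#' @examples
#' codon_table()
codon_table <- function() {
  gc <- Biostrings::GENETIC_CODE
  tibble::tibble(codon = names(gc), aa = unname(gc))
}

#' Enumerate the NNK degenerate codon set
#'
#' NNK codons (N = any base, K = G or T) are the 32 codons whose third base is
#' G or T. They cover all 20 amino acids and contain a single stop codon, the
#' amber codon TAG. Saturation libraries randomized with NNK therefore sample
#' every residue with between one and three codons per residue.
#'
#' @return A tibble with columns `codon` and `residue` (32 rows; `residue` is
#'   `"*"` for TAG).
#' @export
#' @examples
#' nnk <- enumerate_nnk()
#' nrow(nnk) # 32
#' nnk[nnk$residue == "L", ] # three leucine codons
enumerate_nnk <- function() {
  ct <- codon_table()
  out <- ct[substr(ct$codon, 3, 3) %in% c("G", "T"), ]
  names(out) <- c("codon", "residue")
  out
}

## NNK codon multiplicity per residue (named integer over the 20 residues).
.nnk_residue_counts <- function() {
  nnk <- enumerate_nnk()
  nnk <- nnk[nnk$residue != "*", ]
  tab <- table(factor(nnk$residue, levels = AA_ALPHABET))
  setNames(as.integer(tab), AA_ALPHABET)
}

#' Translate frame-aligned DNA to peptide sequence
#'
#' Applies the standard genetic code codon by codon. Stop codons are rendered
#' in-band as `"*"` so that downstream filters can act on the translated
#' string.
#'
#' @param dna Character vector of DNA sequences over `{A,C,G,T}`, each with
#'   length divisible by 3.
#' @return Character vector of peptides, one per input sequence.
#' @export
#' @examples
#' translate_dna("CAG") # "Q"
#' translate_dna("CATCAGTCT") # "HQS"
#' translate_dna("TAG") # "*"
translate_dna <- function(dna) {
  if (!is.character(dna)) {
    stop("`dna` must be a character vector", call. = FALSE)
  }
  if (length(dna) == 0) {
    return(character(0))
  }
  bad <- regexpr("[^ACGT]", dna)
  if (any(bad > 0L)) {
    i <- which(bad > 0L)[1]
    stop(sprintf(
      "invalid base '%s' at offset %d of sequence %d",
      substr(dna[i], bad[i], bad[i]), bad[i], i
    ), call. = FALSE)
  }
  n <- nchar(dna)
  if (any(n %% 3L != 0L)) {
    i <- which(n %% 3L != 0L)[1]
    stop(sprintf(
      "sequence %d has length %d, not divisible by 3 (frame error)", i, n[i]
    ), call. = FALSE)
  }
  gc <- Biostrings::GENETIC_CODE
  L <- n[1]
  if (all(n == L)) {
    if (L == 0L) {
      return(rep("", length(dna)))
    }
    ## equal-length bulk path: arithmetic codon indexing over one big
    ## integer vector instead of per-codon name lookup
    base_code <- integer(128)
    base_code[utf8ToInt("ACGT") + 1L] <- 0:3
    v <- base_code[utf8ToInt(paste0(dna, collapse = "")) + 1L]
    b <- matrix(v, nrow = L) # L x n, bases as 0..3
    nc <- L %/% 3L
    aa64 <- character(64)
    codon_bases <- vapply(names(gc), function(cd) {
      base_code[utf8ToInt(cd) + 1L]
    }, integer(3))
    aa64[16L * codon_bases[1, ] + 4L * codon_bases[2, ] +
      codon_bases[3, ] + 1L] <- unname(gc)
    cols <- vector("list", nc)
    for (j in seq_len(nc)) {
      idx <- 16L * b[3L * j - 2L, ] + 4L * b[3L * j - 1L, ] + b[3L * j, ] + 1L
      cols[[j]] <- aa64[idx]
    }
    return(do.call(paste0, cols))
  }
  vapply(dna, function(s) {
    if (nchar(s) == 0L) {
      return("")
    }
    st <- seq.int(1L, nchar(s), 3L)
    paste0(unname(gc[substring(s, st, st + 2L)]), collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

## Deterministic DNA encoding of a peptide: alphabetically first codon per
## residue. Used to derive backbone coding DNA for shipped presets.
encode_peptide <- function(peptide) {
  ct <- codon_table()
  first_codon <- vapply(
    split(ct$codon, ct$aa),
    function(x) sort(x)[1],
    character(1)
  )
  vapply(peptide, function(p) {
    res <- strsplit(p, "")[[1]]
    if (!all(res %in% names(first_codon))) {
      stop("peptide contains residues outside the standard alphabet",
        call. = FALSE
      )
    }
    paste0(first_codon[res], collapse = "")
  }, character(1), USE.NAMES = FALSE)
}
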