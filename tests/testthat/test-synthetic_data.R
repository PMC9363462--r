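test_that("library sampling draws NNK codons uniformly", {
  d <- preset_design("LibQ")
  pool <- sample_library(d, 32000, seed = 21)
  # randomized codon is the reactive position's codon (bases 4-6)
  codon <- substr(pool$dna, 4, 6)
  frac_tag <- sum(pool$count[codon == "TAG"]) / sum(pool$count)
  tol <- 3 * sqrt((1 / 32) * (31 / 32) / 32000)
  expect_lt(abs(frac_tag - 1 / 32), tol)

  d4 <- preset_design("Lib4")
  pool4 <- sample_library(d4, 1e5, seed = 22)
  for (pos in d4$randomized_indices) {
    res <- substr(pool4$peptide, pos, pos)
    frac_leu <- sum(pool4$count[res == "L"]) / sum(pool4$count)
    tol <- 4 * sqrt((3 / 32) * (29 / 32) / 1e5)
    expect_lt(abs(frac_leu - 3 / 32), tol)
  }
})

test_that("library sampling is reproducible under a seed", {
  d <- preset_design("Lib4")
  expect_identical(
    sample_library(d, 10, seed = 5),
    sample_library(d, 10, seed = 5)
  )
})

test_that("capture probabilities follow the logistic-additive model", {
  d <- preset_design("Lib4")
  W0 <- selection_weights(d)
  pep_q <- d$backbone_peptide # reactive Gln present
  m <- selection_model(W0, baseline = 0, background = 0)
  expect_equal(capture_probability(pep_q, m, d), 0.5)

  pep_a <- sub("Q", "A", pep_q) # reactive position mutated
  m2 <- selection_model(W0, baseline = 0, background = 0.01)
  expect_equal(capture_probability(pep_a, m2, d), 0.01)

  W <- selection_weights(d, "Q@-1" = 2)
  m3 <- selection_model(W, baseline = -1, background = 0)
  pep_qq <- paste0("Q", substr(pep_q, 2, nchar(pep_q)))
  expect_equal(capture_probability(pep_qq, m3, d), plogis(1),
    tolerance = 1e-12
  )
  # stop at a scored position falls back to background
  pep_stop <- paste0("*", substr(pep_q, 2, nchar(pep_q)))
  expect_equal(capture_probability(pep_stop, m2, d), 0.01)
})

test_that("artifact boosts add capture probability and stay clamped", {
  d <- preset_design("Lib4")
  m <- selection_model(selection_weights(d),
    baseline = -2, background = 0.001,
    artifact = list(pattern = "^H.[HW]", boost = 0.3)
  )
  pep <- d$backbone_peptide
  pep_hit <- paste0("H", substr(pep, 2, 2), "W", substr(pep, 4, nchar(pep)))
  base_m <- selection_model(selection_weights(d),
    baseline = -2, background = 0.001
  )
  expect_equal(
    capture_probability(pep_hit, m, d),
    capture_probability(pep_hit, base_m, d) + 0.3
  )
  m_big <- selection_model(selection_weights(d),
    baseline = 10, background = 0, artifact = list(pattern = ".", boost = 0.9)
  )
  expect_lte(max(capture_probability(pep, m_big, d)), 1)
})

test_that("selection is binomial thinning of the pool", {
  d <- preset_design("Lib4")
  pool <- sample_library(d, 2000, seed = 31)
  # p = 0 for every peptide: no specific capture, no background
  m0 <- selection_model(selection_weights(d),
    baseline = -1e3, background = 0
  )
  s0 <- simulate_selection(pool, m0, d, seed = 32)
  expect_true(all(s0$count_after == 0))
  # p = 1 for every Gln-bearing peptide
  m1 <- selection_model(selection_weights(d),
    baseline = 1e3, background = 1 - 1e-12
  )
  s1 <- simulate_selection(pool, m1, d, seed = 33)
  expect_identical(s1$count_after, s1$count_before)
  # single peptide at p = 0.3
  b0 <- log(0.3 / 0.7)
  m3 <- selection_model(selection_weights(d), baseline = b0, background = 0)
  one <- tibble::tibble(
    dna = pepselect:::encode_peptide(d$backbone_peptide),
    peptide = d$backbone_peptide, count = 1e5
  )
  s3 <- simulate_selection(one, m3, d, seed = 34)
  se <- sqrt(0.3 * 0.7 / 1e5)
  expect_lt(abs(s3$count_after / 1e5 - 0.3), 3 * se)
  # conservation on every simulation
  for (s in list(s0, s1, s3)) {
    expect_true(all(s$count_after <= s$count_before))
  }
})

test_that("zero-error emission reconstructs the construct exactly", {
  d <- mini_design(tags = character())
  counts <- tibble::tibble(dna = "CATCAGTCTTATGTT", count = 10)
  sm <- sequencing_model(reads_per_sample = 5, per_base_error = 0)
  dir <- withr::local_tempdir()
  r1 <- file.path(dir, "r1.fastq")
  r2 <- file.path(dir, "r2.fastq")
  emit_fastq(counts, d, sm, r1, r2, seed = 41)
  construct <- paste0(d$upstream_anchor, counts$dna, d$downstream_anchor)
  fq1 <- read_fastq(r1)
  fq2 <- read_fastq(r2)
  expect_identical(nrow(fq1), 5L)
  expect_true(all(fq1$seq == construct))
  expect_true(all(
    fq2$seq == as.character(Biostrings::reverseComplement(
      Biostrings::DNAStringSet(construct)
    ))
  ))
  expect_true(all(nchar(fq1$qual) == nchar(construct)))
})

test_that("reads are allocated proportionally to molecule counts", {
  d <- mini_design(tags = character())
  counts <- tibble::tibble(
    dna = c("CATCAGTCTTATGTT", "GCTCAGTCTTATGTT"),
    count = c(900, 100)
  )
  sm <- sequencing_model(
    reads_per_sample = 1e4, per_base_error = 0, paired = FALSE
  )
  dir <- withr::local_tempdir()
  alloc <- emit_fastq(counts, d, sm, file.path(dir, "r1.fastq"), seed = 43)
  share <- alloc$n_reads[1] / sum(alloc$n_reads)
  expect_lt(abs(share - 0.9), 3 * sqrt(0.9 * 0.1 / 1e4))
  expect_identical(sum(alloc$n_reads), 10000L)
})

test_that("emission is byte-identical under a fixed seed", {
  d <- mini_design()
  counts <- tibble::tibble(
    dna = c("CATCAGTCTTATGTT", "GCTCAGTCTTATGTT"),
    count = c(3, 7)
  )
  sm <- sequencing_model(reads_per_sample = 50, per_base_error = 0.01)
  dir <- withr::local_tempdir()
  f <- file.path(dir, c("a1.fq", "a2.fq", "b1.fq", "b2.fq"))
  emit_fastq(counts, d, sm, f[1], f[2], tag_label = "s1", seed = 47)
  emit_fastq(counts, d, sm, f[3], f[4], tag_label = "s1", seed = 47)
  expect_identical(unname(tools::md5sum(f[1])), unname(tools::md5sum(f[3])))
  expect_identical(unname(tools::md5sum(f[2])), unname(tools::md5sum(f[4])))
})

test_that("emission rejects reads shorter than the construct", {
  d <- mini_design(tags = character())
  counts <- tibble::tibble(dna = "CATCAGTCTTATGTT", count = 1)
  sm <- sequencing_model(reads_per_sample = 5, read_length = 20)
  expect_error(
    emit_fastq(counts, d, sm, tempfile(), tempfile(), seed = 1),
    "read_length"
  )
})

test_that("analytic position EFs match their closed forms and a simulation", {
  d <- preset_design("Lib4")
  # no selection signal: every EF is exactly 1
  m0 <- selection_model(selection_weights(d), baseline = -2,
    background = 0.002)
  t0 <- true_position_ef(m0, d)
  expect_equal(t0$ef, rep(1, nrow(t0)), tolerance = 1e-12)

  # LibQ with background only: enrichment exclusively at the reactive Gln
  dq <- preset_design("LibQ")
  mq <- selection_model(selection_weights(dq), baseline = -2, background = 0)
  tq <- true_position_ef(mq, dq)
  expect_true(all(tq$ef[tq$residue == "Q"] > 1))
  expect_true(all(tq$ef[tq$residue != "Q"] < 1))

  # single planted weight: enumeration agrees with a large simulation
  m1 <- selection_model(selection_weights(d, "Q@-1" = 2),
    baseline = -1, background = 0
  )
  t1 <- true_position_ef(m1, d)
  pool <- sample_library(d, 3e5, seed = 51)
  sim <- simulate_selection(pool, m1, d, seed = 52)
  sim <- sim[accept_peptide(sim$peptide, d) == "ok", ]
  tbl <- dplyr::summarise(
    dplyr::group_by(sim, peptide),
    count_before = sum(count_before), count_after = sum(count_after),
    .groups = "drop"
  )
  pe <- position_aa_ef(tbl, d)
  emp <- pe$ef[pe$rel_pos == "-1" & pe$residue == "Q"]
  ana <- t1$ef[t1$rel_pos == "-1" & t1$residue == "Q"]
  expect_lt(abs(emp / ana - 1), 0.04)
})

test_that("raising a planted weight never lowers its analytic EF", {
  d <- preset_design("Lib4")
  set.seed(61)
  for (i in 1:4) {
    res <- sample(pepselect:::AA_ALPHABET, 1)
    rel <- sample(c("-1", "+1", "+2", "+3"), 1)
    w_lo <- do.call(
      selection_weights,
      c(list(d), setNames(list(0.5), paste0(res, "@", rel)))
    )
    w_hi <- do.call(
      selection_weights,
      c(list(d), setNames(list(1.5), paste0(res, "@", rel)))
    )
    lo <- selection_model(w_lo, baseline = -1, background = 0.01)
    hi <- selection_model(w_hi, baseline = -1, background = 0.01)
    ef_lo <- true_position_ef(lo, d)
    ef_hi <- true_position_ef(hi, d)
    pick <- ef_lo$rel_pos == rel & ef_lo$residue == res
    expect_gte(ef_hi$ef[pick], ef_lo$ef[pick])
  }
})
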