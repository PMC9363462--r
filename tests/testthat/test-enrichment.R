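test_that("normalization divides by the sample total", {
  x <- tibble::tibble(peptide = c("A", "B"), count = c(10, 30))
  expect_equal(normalize_counts(x)$freq, c(0.25, 0.75))
  one <- tibble::tibble(peptide = "x", count = 5)
  expect_equal(normalize_counts(one)$freq, 1)
  expect_error(
    normalize_counts(tibble::tibble(peptide = "x", count = 0)),
    "empty"
  )
  set.seed(3)
  big <- tibble::tibble(
    peptide = as.character(1:1000),
    count = sample(1:500, 1000, replace = TRUE)
  )
  expect_lt(abs(sum(normalize_counts(big)$freq) - 1), 1e-12)
})

test_that("peptide EF is the after/before quotient of normalized counts", {
  tbl <- tibble::tibble(
    peptide = c("A", "B"),
    count_before = c(10L, 30L), count_after = c(30L, 10L)
  )
  ef <- peptide_ef(tbl)
  expect_equal(ef$ef[ef$peptide == "A"], 3)
  expect_equal(ef$ef[ef$peptide == "B"], 1 / 3)

  same <- tibble::tibble(
    peptide = letters[1:5],
    count_before = c(5L, 10L, 1L, 7L, 3L),
    count_after = c(5L, 10L, 1L, 7L, 3L)
  )
  expect_equal(peptide_ef(same)$ef, rep(1, 5))

  # zero before-count: flagged, not infinite
  zb <- tibble::tibble(
    peptide = c("a", "b"), count_before = c(0L, 10L),
    count_after = c(5L, 5L)
  )
  efz <- peptide_ef(zb)
  expect_true(efz$zero_before[efz$peptide == "a"])
  expect_true(is.na(efz$ef[efz$peptide == "a"]))
  # pseudocount defines it
  efp <- peptide_ef(zb, pseudocount = 0.5)
  expect_false(any(efp$zero_before))
  expect_true(all(is.finite(efp$ef)))
})

test_that("ranking enforces the count threshold and deterministic ties", {
  tbl <- tibble::tibble(
    peptide = c("deep", "shallow"),
    count_before = c(10L, 10L),
    count_after = c(100L, 99L)
  )
  ranked <- rank_top(peptide_ef(tbl), min_count_after = 100)
  expect_identical(ranked$peptide, "deep") # 100 passes, 99 does not

  # EF ties break by higher after-count, then peptide
  tie <- tibble::tibble(
    peptide = c("X", "Y", "Z"),
    count_before = c(40L, 60L, 200L),
    count_after = c(200L, 300L, 400L)
  )
  r <- rank_top(peptide_ef(tie), min_count_after = 100, top_n = 100)
  expect_identical(r$peptide, c("Y", "X", "Z"))
  expect_identical(r$rank, 1:3)

  # higher EF ranks above lower EF regardless of counts
  two <- tibble::tibble(
    peptide = c("p", "q"),
    count_before = c(100L, 100L),
    count_after = c(700L, 200L)
  )
  r2 <- rank_top(peptide_ef(two), min_count_after = 100)
  expect_identical(r2$peptide[1], "p")
})

test_that("position EFs aggregate residue classes correctly", {
  d2 <- library_design(
    name = "toy", backbone_peptide = "QA", reactive_index = 2L,
    randomized_indices = 1L,
    upstream_anchor = "ACGT", downstream_anchor = "ACGT"
  )
  tbl <- tibble::tibble(
    peptide = c("QA", "HA"),
    count_before = c(50L, 50L), count_after = c(90L, 10L)
  )
  pe <- position_aa_ef(tbl, d2)
  expect_equal(pe$ef[pe$residue == "Q"], 1.8)
  expect_equal(pe$ef[pe$residue == "H"], 0.2)
  expect_true(all(pe$undefined[!pe$residue %in% c("Q", "H")]))

  same <- tibble::tibble(
    peptide = c("QA", "HA"), count_before = c(5L, 7L),
    count_after = c(5L, 7L)
  )
  pe1 <- position_aa_ef(same, d2)
  expect_equal(pe1$ef[!pe1$undefined], c(1, 1))
})

test_that("EFs are invariant to rescaling one sample's depth", {
  set.seed(9)
  tbl <- tibble::tibble(
    peptide = random_peptides(50, 5),
    count_before = sample(1:100, 50, replace = TRUE),
    count_after = sample(1:100, 50, replace = TRUE)
  )
  scaled <- tbl
  scaled$count_after <- scaled$count_after * 7L
  expect_equal(peptide_ef(tbl)$ef, peptide_ef(scaled)$ef, tolerance = 1e-14)
  d <- mini_design()
  pe <- position_aa_ef(tbl, d)
  pe7 <- position_aa_ef(scaled, d)
  expect_equal(pe$ef, pe7$ef, tolerance = 1e-14)
})

test_that("consensus picks the per-position EF maximum with tie flags", {
  d <- preset_design("Lib4")
  # counts crafted so maxima are Q at -1, C at +1, Y at +2, I at +3
  peps <- c("QQCYIDPWMLDH", "HQSYVDPWMLDH", "AQAAADPWMLDH")
  tbl <- tibble::tibble(
    peptide = peps,
    count_before = c(10L, 10L, 10L),
    count_after = c(60L, 20L, 10L)
  )
  cons <- heatmap_consensus(position_aa_ef(tbl, d))
  expect_identical(cons$residue, c("Q", "C", "Y", "I"))
  expect_identical(attr(cons, "consensus"), "Q-C-Y-I")
  expect_false(any(cons$tie))

  # flat table: alphabetical first residue per position, ties flagged
  flat <- tibble::tibble(
    peptide = peps, count_before = c(5L, 5L, 5L), count_after = c(5L, 5L, 5L)
  )
  cflat <- heatmap_consensus(position_aa_ef(flat, d))
  expect_identical(cflat$residue, c("A", "A", "A", "A"))
  expect_true(all(cflat$tie))

  # single defined residue per column
  solo <- tibble::tibble(
    peptide = "HQSYVDPWMLDH", count_before = 10L, count_after = 30L
  )
  csolo <- heatmap_consensus(position_aa_ef(solo, d))
  expect_identical(csolo$residue, c("H", "S", "Y", "V"))
})

test_that("logo matrices are per-position frequency columns", {
  lm1 <- logo_matrix(rep("HQSYV", 100))
  expect_equal(lm1$freq[lm1$position == 1 & lm1$residue == "H"], 1)
  expect_equal(sum(lm1$freq[lm1$position == 3]), 1)

  lm2 <- logo_matrix(c(rep("HQSYV", 50), rep("HQCYV", 50)))
  expect_equal(lm2$freq[lm2$position == 3 & lm2$residue == "S"], 0.5)
  expect_equal(lm2$freq[lm2$position == 3 & lm2$residue == "C"], 0.5)
  expect_equal(lm2$freq[lm2$position == 1 & lm2$residue == "H"], 1)

  set.seed(13)
  lm3 <- logo_matrix(random_peptides(200, 6))
  sums <- tapply(lm3$freq, lm3$position, sum)
  expect_true(all(abs(sums - 1) < 1e-9))

  expect_error(logo_matrix(c("AA", "AAA")), "uniform length")
})

test_that("count tables assemble from long and paired inputs", {
  long <- tibble::tibble(
    sample = c("before", "before", "after"),
    peptide = c("AA", "BB", "AA"),
    count = c(5L, 3L, 9L)
  )
  tbl <- count_table(long)
  expect_identical(tbl$count_after[tbl$peptide == "BB"], 0L)
  expect_identical(tbl$count_before[tbl$peptide == "AA"], 5L)
  tbl2 <- count_table(
    tibble::tibble(peptide = "AA", count = 5L),
    tibble::tibble(peptide = c("AA", "CC"), count = c(9L, 2L))
  )
  expect_identical(tbl2$count_before[tbl2$peptide == "CC"], 0L)
  expect_identical(tbl2$count_after[tbl2$peptide == "AA"], 9L)
})
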