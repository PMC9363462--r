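#' One-hot encode peptides at the randomized positions
#'
#' Builds the indicator matrix the random-forest model is trained on: one
#' column per (relative position, residue) pair, positions in relative order
#' and residues alphabetical within each position, so the column layout is
#' deterministic. Each peptide's block per position sums to exactly 1.
#'
#' @param peptides Character vector of peptides of the design's length, with
#'   standard residues at the randomized positions.
#' @param design A [library_design()].
#' @return A list with `x` (numeric 0/1 matrix, named columns like `"Q@-1"`)
#'   and `features` (tibble `feature`, `rel_pos`, `residue`, `column`).
#' @export
one_hot_encode <- function(peptides, design) {
  if (any(nchar(peptides) != design$length)) {
    stop("peptides must have the design's length", call. = FALSE)
  }
  labs <- rel_labels(design)
  pos <- design$randomized_indices
  k <- length(pos)
  p <- 20L * k
  feature <- paste0(
    rep(AA_ALPHABET, times = k), "@", rep(labs, each = 20L)
  )
  x <- matrix(0, nrow = length(peptides), ncol = p,
    dimnames = list(NULL, feature))
  for (j in seq_len(k)) {
    res <- substr(peptides, pos[j], pos[j])
    m <- match(res, AA_ALPHABET)
    if (anyNA(m)) {
      stop(sprintf(
        "residue '%s' outside the 20-letter alphabet at position %s",
        res[which(is.na(m))[1]], labs[j]
      ), call. = FALSE)
    }
    x[cbind(seq_along(peptides), (j - 1L) * 20L + m)] <- 1
  }
  features <- tibble::tibble(
    feature = feature,
    rel_pos = rep(labs, each = 20L),
    residue = rep(AA_ALPHABET, times = k),
    column = seq_len(p)
  )
  list(x = x, features = features)
}

#' Cross-validated random-forest regression
#'
#' Fits `k` regression forests, each trained on the other `k - 1` folds, and
#' records per-fold held-out predictions and mean squared errors. Fold
#' assignment and tree growing are deterministic under `seed`.
#'
#' @param x Numeric feature matrix (e.g. [one_hot_encode()]'s `x`).
#' @param y Numeric response (enrichment factors).
#' @param k Number of folds (default 10).
#' @param num_trees Trees per forest (default 200).
#' @param mtry Features tried per split; default `max(floor(p / 3), 1)`, the
#'   classical regression-forest choice.
#' @param min_node_size Minimal node size (default 5).
#' @param max_depth Maximal tree depth, 0 = unlimited.
#' @param seed Integer seed.
#' @return An object of class `rf_cv`.
#' @export
fit_rf_cv <- function(x, y, k = 10L, num_trees = 200L, mtry = NULL,
                      min_node_size = 5L, max_depth = 0L, seed = 1L) {
  stopifnot(nrow(x) == length(y), all(is.finite(y)))
  n <- nrow(x)
  if (n < k) {
    stop(sprintf("%d rows cannot form %d folds (fold error)", n, k),
      call. = FALSE
    )
  }
  mtry <- mtry %||% max(floor(ncol(x) / 3), 1L)
  fold <- .with_seed(seed, sample(rep_len(seq_len(k), n)))
  models <- vector("list", k)
  mse_fold <- numeric(k)
  pred <- numeric(n)
  for (f in seq_len(k)) {
    tr <- fold != f
    models[[f]] <- ranger::ranger(
      x = x[tr, , drop = FALSE], y = y[tr],
      num.trees = num_trees, mtry = min(mtry, ncol(x)),
      min.node.size = min_node_size, max.depth = max_depth,
      seed = seed + f, num.threads = 1L, verbose = FALSE
    )
    p <- predict(models[[f]],
      data = x[!tr, , drop = FALSE], num.threads = 1L
    )$predictions
    pred[!tr] <- p
    mse_fold[f] <- mean((p - y[!tr])^2)
  }
  structure(
    list(
      models = models, fold = fold, mse_fold = mse_fold,
      predictions = pred, x = x, y = y,
      params = list(
        k = k, num_trees = num_trees, mtry = mtry,
        min_node_size = min_node_size, max_depth = max_depth, seed = seed
      )
    ),
    class = "rf_cv"
  )
}

#' @export
print.rf_cv <- function(x, ...) {
  cat(sprintf(
    "<rf_cv> %d folds x %d trees on %d x %d; CV MSE %.4g (sd %.3g)\n",
    x$params$k, x$params$num_trees, nrow(x$x), ncol(x$x),
    mean(x$mse_fold), sd(x$mse_fold)
  ))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.rf_cv <- function(x, ...) {
  tibble::tibble(fold = seq_along(x$mse_fold), mse = x$mse_fold)
}

#' @exportS3Method generics::glance
glance.rf_cv <- function(x, ...) {
  tibble::tibble(
    n = nrow(x$x), p = ncol(x$x), k = x$params$k,
    num_trees = x$params$num_trees, mtry = x$params$mtry,
    cv_mse = mean(x$mse_fold), cv_mse_sd = sd(x$mse_fold)
  )
}

#' Randomized hyper-parameter search for the forest
#'
#' Samples `n_iter` parameter sets from a documented grid (`mtry`, minimal
#' node size, maximal depth), scores each by k-fold cross-validated MSE and
#' returns the best. Candidates and their evaluations are drawn sequentially
#' from one seeded stream, so the best score over a larger `n_iter` can never
#' be worse than over a smaller one with the same seed.
#'
#' @param x,y Features and response as in [fit_rf_cv()].
#' @param n_iter Number of sampled candidates.
#' @param k Folds per evaluation.
#' @param num_trees Trees per evaluation forest.
#' @param grid Named list of candidate values for `mtry`, `min_node_size`,
#'   `max_depth`.
#' @param seed Integer seed.
#' @return A list with `best` (one-row tibble) and `results` (all candidates
#'   with their CV MSE, in evaluation order).
#' @export
hypertune_rf <- function(x, y, n_iter = 25L, k = 10L, num_trees = 200L,
                         grid = list(
                           mtry = unique(pmax(
                             1L, floor(ncol(x) * c(1 / 10, 1 / 3, 2 / 3, 1))
                           )),
                           min_node_size = c(1L, 3L, 5L, 10L, 20L),
                           max_depth = c(0L, 4L, 8L, 16L)
                         ),
                         seed = 1L) {
  stopifnot(n_iter >= 1)
  ## candidates are drawn one at a time so the candidate sequence is a
  ## prefix of any longer run with the same seed
  pick1 <- function(v) v[sample.int(length(v), 1L)]
  cand <- .with_seed(seed, {
    dplyr::bind_rows(lapply(seq_len(n_iter), function(i) {
      tibble::tibble(
        mtry = pick1(grid$mtry),
        min_node_size = pick1(grid$min_node_size),
        max_depth = pick1(grid$max_depth)
      )
    }))
  })
  cand$cv_mse <- NA_real_
  for (i in seq_len(n_iter)) {
    fit <- fit_rf_cv(
      x, y,
      k = k, num_trees = num_trees, mtry = cand$mtry[i],
      min_node_size = cand$min_node_size[i], max_depth = cand$max_depth[i],
      seed = seed + i
    )
    cand$cv_mse[i] <- mean(fit$mse_fold)
  }
  list(best = cand[which.min(cand$cv_mse), ], results = cand)
}

#' Held-out permutation importance with Pearson signs
#'
#' For every feature, the importance is the mean increase in held-out mean
#' squared error when that feature's column is randomly permuted in the
#' held-out fold, averaged over all folds and `n_repeats` permutations per
#' fold; the spread is the standard deviation over those fold-by-repeat
#' values. Permuting a constant column leaves predictions unchanged, so its
#' importance is exactly zero. Each feature also gets a sign from the Pearson
#' correlation of its raw column with the response, indicating whether the
#' feature is associated with an increase (`+`) or decrease (`-`) of
#' enrichment.
#'
#' @param fit An [fit_rf_cv()] object.
#' @param n_repeats Permutations per fold per feature (default 10).
#' @param seed Integer seed.
#' @return An `importance_report`: a tibble with `feature`, `importance`
#'   (mean MSE increase), `sd`, `pearson`, `sign`, `rank`, plus `rel_pos` and
#'   `residue` parsed from the feature name.
#' @export
permutation_importance <- function(fit, n_repeats = 10L, seed = 1L) {
  stopifnot(inherits(fit, "rf_cv"))
  x <- fit$x
  y <- fit$y
  p <- ncol(x)
  k <- fit$params$k
  imp <- array(NA_real_, dim = c(k, n_repeats, p))
  .with_seed(seed, {
    for (f in seq_len(k)) {
      te <- which(fit$fold == f)
      xte <- x[te, , drop = FALSE]
      yte <- y[te]
      base <- fit$mse_fold[f]
      m <- length(te)
      block <- rep(seq_len(p), each = m)
      for (r in seq_len(n_repeats)) {
        ## one big prediction per repeat: p stacked copies of the held-out
        ## fold, the j-th copy with column j permuted
        xbig <- xte[rep.int(seq_len(m), p), , drop = FALSE]
        for (j in seq_len(p)) {
          rows <- ((j - 1L) * m + 1L):(j * m)
          xbig[rows, j] <- xte[sample.int(m), j]
        }
        pb <- predict(fit$models[[f]], data = xbig,
          num.threads = 1L)$predictions
        err <- (pb - rep.int(yte, p))^2
        imp[f, r, ] <- as.vector(rowsum(err, block, reorder = TRUE)) / m -
          base
      }
    }
  })
  means <- apply(imp, 3, mean)
  sds <- apply(imp, 3, sd)
  pearson <- suppressWarnings(as.vector(cor(x, y)))
  out <- tibble::tibble(
    feature = colnames(x) %||% paste0("x", seq_len(p)),
    importance = means,
    sd = sds,
    pearson = pearson,
    sign = dplyr::case_when(
      is.na(pearson) ~ NA_character_,
      pearson >= 0 ~ "+",
      TRUE ~ "-"
    ),
    rank = rank(-means, ties.method = "first")
  )
  if (all(grepl("@", out$feature))) {
    parts <- strsplit(out$feature, "@", fixed = TRUE)
    out$residue <- vapply(parts, `[`, "", 1)
    out$rel_pos <- vapply(parts, `[`, "", 2)
  }
  class(out) <- c("importance_report", class(out))
  out
}

#' Welch's unequal-variance t-test
#'
#' Two-sided Welch test. When both samples have zero variance, the test is
#' degenerate: equal means give `p = 1` (statistic 0) by convention, unequal
#' means give `p = 0` (infinite statistic).
#'
#' @param a,b Numeric samples with at least 2 observations each.
#' @return A one-row tibble: `statistic`, `df`, `p_value`.
#' @export
welch_t <- function(a, b) {
  stopifnot(length(a) >= 2, length(b) >= 2)
  if (var(a) == 0 && var(b) == 0) {
    if (mean(a) == mean(b)) {
      return(tibble::tibble(statistic = 0, df = NA_real_, p_value = 1))
    }
    return(tibble::tibble(
      statistic = sign(mean(a) - mean(b)) * Inf, df = NA_real_, p_value = 0
    ))
  }
  tt <- t.test(a, b, var.equal = FALSE)
  tibble::tibble(
    statistic = unname(tt$statistic),
    df = unname(tt$parameter),
    p_value = tt$p.value
  )
}

.quartile_summary <- function(v) {
  q <- quantile(v, c(0.25, 0.5, 0.75), names = FALSE, type = 7)
  tibble::tibble(n = length(v), q1 = q[1], median = q[2], q3 = q[3])
}

#' Enrichment by number of hydrophobic residues
#'
#' Groups peptides by how many of their randomized positions carry a
#' hydrophobic residue, summarises each group's enrichment (median and
#' quartiles) and runs all pairwise Welch t-tests between groups with at
#' least two members.
#'
#' @param etable A [peptide_ef()] tibble (rows with `NA` EF are dropped).
#' @param design A [library_design()].
#' @param hydrophobic Hydrophobic residue set.
#' @param alpha Significance level for flagging (default 0.01).
#' @return A `group_comparison` object: list with `groups` and `tests`
#'   tibbles, the grouping label and `alpha`.
#' @export
hydrophobic_count_analysis <- function(etable, design,
                                       hydrophobic = HYDROPHOBIC_AA,
                                       alpha = 0.01) {
  df <- etable[!is.na(etable$ef), ]
  pos <- design$randomized_indices
  cnt <- rowSums(vapply(
    pos,
    function(i) substr(df$peptide, i, i) %in% hydrophobic,
    logical(nrow(df))
  ))
  groups <- dplyr::bind_rows(lapply(
    sort(unique(cnt)),
    function(g) {
      dplyr::bind_cols(
        tibble::tibble(n_hydrophobic = g),
        .quartile_summary(df$ef[cnt == g])
      )
    }
  ))
  testable <- groups$n_hydrophobic[groups$n >= 2]
  tests <- NULL
  if (length(testable) >= 2) {
    pairs <- utils::combn(testable, 2)
    tests <- dplyr::bind_rows(lapply(seq_len(ncol(pairs)), function(i) {
      g1 <- pairs[1, i]
      g2 <- pairs[2, i]
      tt <- welch_t(df$ef[cnt == g1], df$ef[cnt == g2])
      dplyr::bind_cols(tibble::tibble(group1 = g1, group2 = g2), tt)
    }))
    tests$significant <- tests$p_value < alpha
  } else {
    tests <- tibble::tibble(
      group1 = integer(0), group2 = integer(0), statistic = numeric(0),
      df = numeric(0), p_value = numeric(0), significant = logical(0)
    )
  }
  structure(
    list(
      groups = groups, tests = tests,
      grouping = "hydrophobic_count", alpha = alpha
    ),
    class = "group_comparison"
  )
}

#' Enrichment by residue polarity at each randomized position
#'
#' At each randomized position, splits peptides into polar versus nonpolar
#' residue carriers and compares their enrichment with a Welch t-test.
#' Positions where one side has fewer than two peptides are skipped with a
#' notice.
#'
#' @param etable A [peptide_ef()] tibble.
#' @param design A [library_design()].
#' @param polar Polar residue set.
#' @param alpha Significance level (default 0.01).
#' @return A `group_comparison` object; `tests` has one row per position
#'   with medians for both sides and a `skipped` flag.
#' @export
polarity_by_position <- function(etable, design, polar = POLAR_AA,
                                 alpha = 0.01) {
  df <- etable[!is.na(etable$ef), ]
  labs <- rel_labels(design)
  pos <- design$randomized_indices
  groups <- list()
  tests <- list()
  for (j in seq_along(pos)) {
    is_polar <- substr(df$peptide, pos[j], pos[j]) %in% polar
    a <- df$ef[is_polar]
    b <- df$ef[!is_polar]
    gp <- dplyr::bind_cols(
      tibble::tibble(rel_pos = labs[j], group = c("P", "NP")),
      dplyr::bind_rows(
        if (length(a)) .quartile_summary(a) else
          tibble::tibble(n = 0L, q1 = NA_real_, median = NA_real_,
            q3 = NA_real_),
        if (length(b)) .quartile_summary(b) else
          tibble::tibble(n = 0L, q1 = NA_real_, median = NA_real_,
            q3 = NA_real_)
      )
    )
    groups[[j]] <- gp
    if (length(a) < 2 || length(b) < 2) {
      message(sprintf(
        "position %s skipped: degenerate polar/nonpolar split", labs[j]
      ))
      tests[[j]] <- tibble::tibble(
        rel_pos = labs[j], n_polar = length(a), n_nonpolar = length(b),
        median_polar = if (length(a)) median(a) else NA_real_,
        median_nonpolar = if (length(b)) median(b) else NA_real_,
        statistic = NA_real_, df = NA_real_, p_value = NA_real_,
        significant = NA, skipped = TRUE
      )
    } else {
      tt <- welch_t(a, b)
      tests[[j]] <- tibble::tibble(
        rel_pos = labs[j], n_polar = length(a), n_nonpolar = length(b),
        median_polar = median(a), median_nonpolar = median(b),
        statistic = tt$statistic, df = tt$df, p_value = tt$p_value,
        significant = tt$p_value < alpha, skipped = FALSE
      )
    }
  }
  structure(
    list(
      groups = dplyr::bind_rows(groups), tests = dplyr::bind_rows(tests),
      grouping = "polarity_by_position", alpha = alpha
    ),
    class = "group_comparison"
  )
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf(
    "<group_comparison: %s> alpha = %g\n", x$grouping, x$alpha
  ))
  print(x$tests)
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.group_comparison <- function(x, ...) {
  x$tests
}

#' @exportS3Method generics::glance
glance.group_comparison <- function(x, ...) {
  tibble::tibble(
    grouping = x$grouping,
    n_groups = nrow(x$groups),
    n_tests = sum(!is.na(x$tests$p_value)),
    n_significant = sum(x$tests$significant, na.rm = TRUE),
    alpha = x$alpha
  )
}
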