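## 32-bit FNV-1a hash of a string, kept below 2^31 for use as an RNG seed.
.fnv1a <- function(s) {
  h <- 2166136261
  for (b in utf8ToInt(s)) {
    h <- bitwXor(as.integer(h %% 2^31), as.integer(b))
    h <- (h * 16777619) %% 2^31
  }
  as.integer(h %% (2^31 - 1))
}

#' Derive a stage seed from the master seed
#'
#' Every stochastic stage derives its own seed deterministically from the
#' run's master seed and the stage name, so one knob controls the whole run
#' while stages stay decorrelated.
#'
#' @param master Integer master seed.
#' @param stage Stage name.
#' @return An integer seed below 2^31 - 1.
#' @export
derive_seed <- function(master, stage) {
  as.integer((as.numeric(.fnv1a(stage)) + as.numeric(master) * 48271) %%
    (2^31 - 1))
}

.default_config <- function() {
  list(
    design = "Lib4",
    out_dir = "pepselect_run",
    seed = 1L,
    simulate = list(
      enabled = TRUE,
      n_molecules = 20000L,
      reads_per_sample = 50000L,
      read_length = NULL,
      per_base_error = 0.005,
      quality_mean = 36,
      quality_sd = 3,
      baseline = -2,
      background = 0.002,
      weights = NULL
    ),
    inputs = list(
      r1_before = NULL, r2_before = NULL,
      r1_after = NULL, r2_after = NULL
    ),
    process = list(
      quality_threshold = 25,
      tag_max_mismatch = 1L,
      anchor_max_mismatch = 1L,
      adapters = character()
    ),
    enrich = list(
      min_count_after = 100L,
      top_n = 100L,
      pseudocount = 0
    ),
    analyze = list(
      enabled = TRUE,
      folds = 10L,
      num_trees = 200L,
      n_repeats = 10L,
      max_rows = 2500L,
      max_depth = 8L,
      pseudocount = 0.5,
      log_response = TRUE
    )
  )
}

.check_range <- function(errors, value, name, lo = -Inf, hi = Inf,
                         lo_open = FALSE, hi_open = FALSE) {
  if (is.null(value)) {
    return(errors)
  }
  bad <- !is.numeric(value) || length(value) != 1 || is.na(value) ||
    (if (lo_open) value <= lo else value < lo) ||
    (if (hi_open) value >= hi else value > hi)
  if (bad) {
    errors <- c(errors, sprintf(
      "%s = %s out of range [%s, %s%s", name, format(value),
      lo, hi, if (hi_open) ")" else "]"
    ))
  }
  errors
}

.unknown_key_errors <- function(given, known, prefix) {
  unknown <- setdiff(names(given), known)
  vapply(unknown, function(k) {
    d <- adist(k, known)
    hint <- known[which.min(d)]
    sprintf(
      "unknown key '%s%s'%s", prefix, k,
      if (min(d) <= 3) sprintf(" (did you mean '%s'?)", hint) else ""
    )
  }, character(1))
}

#' Validate and normalize a run configuration
#'
#' Accepts a YAML file path or a nested list, fills every default
#' (quality threshold 25, after-count threshold 100, top-100 ranking, ...),
#' and aggregates all problems — unknown keys (with a nearest-key
#' suggestion), range violations, missing inputs — into a single error
#' instead of stopping at the first.
#'
#' @param config Path to a YAML config or a nested list.
#' @return A normalized list of class `run_config`.
#' @export
validate_config <- function(config) {
  if (is.character(config)) {
    if (!file.exists(config)) {
      stop(sprintf("config file not found: %s", config), call. = FALSE)
    }
    config <- yaml::read_yaml(config)
  }
  stopifnot(is.list(config))
  def <- .default_config()
  errors <- character()
  errors <- c(errors, .unknown_key_errors(config, names(def), ""))
  for (sec in c("simulate", "inputs", "process", "enrich", "analyze")) {
    if (!is.null(config[[sec]])) {
      if (!is.list(config[[sec]])) {
        errors <- c(errors, sprintf("section '%s' must be a mapping", sec))
        config[[sec]] <- NULL
      } else {
        errors <- c(errors, .unknown_key_errors(
          config[[sec]], names(def[[sec]]), paste0(sec, ".")
        ))
      }
    }
  }
  cfg <- def
  for (nm in intersect(names(config), names(def))) {
    if (is.list(def[[nm]]) && !is.null(config[[nm]])) {
      cfg[[nm]] <- modifyList(def[[nm]], config[[nm]])
    } else {
      cfg[[nm]] <- config[[nm]]
    }
  }
  errors <- .check_range(errors, cfg$process$quality_threshold,
    "process.quality_threshold", 0, 41)
  errors <- .check_range(errors, cfg$process$tag_max_mismatch,
    "process.tag_max_mismatch", 0, 10)
  errors <- .check_range(errors, cfg$process$anchor_max_mismatch,
    "process.anchor_max_mismatch", 0, 10)
  errors <- .check_range(errors, cfg$enrich$min_count_after,
    "enrich.min_count_after", 0)
  errors <- .check_range(errors, cfg$enrich$top_n, "enrich.top_n", 1)
  errors <- .check_range(errors, cfg$enrich$pseudocount,
    "enrich.pseudocount", 0)
  errors <- .check_range(errors, cfg$simulate$n_molecules,
    "simulate.n_molecules", 1)
  errors <- .check_range(errors, cfg$simulate$reads_per_sample,
    "simulate.reads_per_sample", 1)
  errors <- .check_range(errors, cfg$simulate$per_base_error,
    "simulate.per_base_error", 0, 1, hi_open = TRUE)
  errors <- .check_range(errors, cfg$simulate$background,
    "simulate.background", 0, 1, hi_open = TRUE)
  errors <- .check_range(errors, cfg$analyze$folds, "analyze.folds", 2)
  errors <- .check_range(errors, cfg$analyze$num_trees,
    "analyze.num_trees", 1)
  errors <- .check_range(errors, cfg$analyze$n_repeats,
    "analyze.n_repeats", 1)
  errors <- .check_range(errors, cfg$seed, "seed", 0, 2^31 - 1)
  ## design: preset name or readable file
  if (is.character(cfg$design) && length(cfg$design) == 1) {
    if (!cfg$design %in% c("Lib4", "LibQ") && !file.exists(cfg$design)) {
      errors <- c(errors, sprintf(
        "design '%s' is neither a preset (Lib4, LibQ) nor an existing file",
        cfg$design
      ))
    }
  } else if (!inherits(cfg$design, "library_design")) {
    errors <- c(errors, "design must be a preset name, file path or design")
  }
  if (!isTRUE(cfg$simulate$enabled)) {
    for (f in c("r1_before", "r1_after")) {
      if (is.null(cfg$inputs[[f]]) || !file.exists(cfg$inputs[[f]])) {
        errors <- c(errors, sprintf(
          "simulate disabled but inputs.%s is missing", f
        ))
      }
    }
  }
  if (length(errors)) {
    stop(paste0(
      "invalid configuration:\n",
      paste0("  - ", errors, collapse = "\n")
    ), call. = FALSE)
  }
  class(cfg) <- c("run_config", "list")
  cfg
}

.load_design <- function(cfg) {
  d <- cfg$design
  if (inherits(d, "library_design")) {
    return(d)
  }
  if (d %in% c("Lib4", "LibQ")) {
    return(preset_design(d))
  }
  read_design(d)
}

.build_model <- function(cfg, design) {
  W <- selection_weights(design)
  if (!is.null(cfg$simulate$weights)) {
    for (nm in names(cfg$simulate$weights)) {
      parts <- strsplit(nm, "@", fixed = TRUE)[[1]]
      W[parts[1], parts[2]] <- cfg$simulate$weights[[nm]]
    }
    selection_model(W,
      baseline = cfg$simulate$baseline,
      background = cfg$simulate$background
    )
  } else {
    default_selection_model(design,
      baseline = cfg$simulate$baseline,
      background = cfg$simulate$background
    )
  }
}

.write_tsv <- function(x, path) {
  data.table::fwrite(x, path, sep = "\t", quote = FALSE, na = "NA")
  path
}

#' Run the full pipeline: simulate, qc, process, enrich, analyze
#'
#' Executes every stage on one configuration and writes plain TSV/CSV/JSON
#' outputs plus a run manifest into the output directory. All randomness is
#' derived from the master seed per stage, so a rerun with an unchanged
#' configuration reproduces every table byte for byte.
#'
#' Outputs under `out_dir`: simulated FASTQ and a `truth.tsv` ground-truth
#' table (when simulating), `qc.json`, `counts.tsv`, `rejections.tsv`,
#' `enrichment.tsv`, `top_ranked.tsv`, `position_ef.csv`, `consensus.json`,
#' `logo_matrix.csv`, `importance.tsv`, `hydrophobic_groups.tsv`,
#' `polarity_tests.tsv`, and `manifest.json`.
#'
#' @param config A config accepted by [validate_config()].
#' @return Invisibly, the manifest as a list.
#' @export
run_all <- function(config) {
  cfg <- validate_config(config)
  design <- .load_design(cfg)
  out <- cfg$out_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(
    tool = "pepselect",
    version = as.character(utils::packageVersion("pepselect")),
    seed = cfg$seed,
    config_hash = .fnv1a(jsonlite::toJSON(
      unclass(cfg), auto_unbox = TRUE, force = TRUE, null = "null"
    )),
    stages = list()
  )
  timed <- function(name, code) {
    t0 <- proc.time()[["elapsed"]]
    res <- tryCatch(force(code), error = function(e) {
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
        call. = FALSE
      )
    })
    manifest$stages[[name]] <<- c(
      res, list(wall_time_s = round(proc.time()[["elapsed"]] - t0, 3))
    )
    res
  }

  ## --- simulate ------------------------------------------------------
  paths <- cfg$inputs
  if (isTRUE(cfg$simulate$enabled)) {
    sim_info <- timed("simulate", {
      model <- .build_model(cfg, design)
      pool <- sample_library(
        design, cfg$simulate$n_molecules, derive_seed(cfg$seed, "pool")
      )
      sim <- simulate_selection(
        pool, model, design, derive_seed(cfg$seed, "selection")
      )
      sm <- sequencing_model(
        reads_per_sample = cfg$simulate$reads_per_sample,
        read_length = cfg$simulate$read_length,
        per_base_error = cfg$simulate$per_base_error,
        quality_mean = cfg$simulate$quality_mean,
        quality_sd = cfg$simulate$quality_sd,
        paired = TRUE
      )
      paths <- list(
        r1_before = file.path(out, "before_R1.fastq"),
        r2_before = file.path(out, "before_R2.fastq"),
        r1_after = file.path(out, "after_R1.fastq"),
        r2_after = file.path(out, "after_R2.fastq")
      )
      emit_fastq(
        dplyr::rename(sim[, c("dna", "count_before")],
          count = "count_before"),
        design, sm, paths$r1_before, paths$r2_before,
        tag_label = if ("before" %in% names(design$tags)) "before",
        sample_name = "before", seed = derive_seed(cfg$seed, "emit_before")
      )
      emit_fastq(
        dplyr::rename(
          sim[sim$count_after > 0, c("dna", "count_after")],
          count = "count_after"
        ),
        design, sm, paths$r1_after, paths$r2_after,
        tag_label = if ("after" %in% names(design$tags)) "after",
        sample_name = "after", seed = derive_seed(cfg$seed, "emit_after")
      )
      .write_tsv(sim, file.path(out, "truth.tsv"))
      list(n_molecules = sum(sim$count_before),
        n_captured = sum(sim$count_after))
    })
  }

  ## --- qc ------------------------------------------------------------
  timed("qc", {
    qc <- dplyr::bind_rows(
      before = assess_quality(paths$r1_before,
        cfg$process$quality_threshold),
      after = assess_quality(paths$r1_after, cfg$process$quality_threshold),
      .id = "sample"
    )
    jsonlite::write_json(qc, file.path(out, "qc.json"),
      dataframe = "rows", auto_unbox = TRUE, digits = NA
    )
    list(n_reads = sum(qc$n_reads))
  })

  ## --- process -------------------------------------------------------
  counts <- timed("process", {
    pc_before <- count_peptides(
      paths$r1_before, paths$r2_before, design,
      quality_threshold = cfg$process$quality_threshold,
      tag_max_mismatch = cfg$process$tag_max_mismatch,
      anchor_max_mismatch = cfg$process$anchor_max_mismatch,
      adapters = cfg$process$adapters %||% character(),
      sample_name = "before"
    )
    pc_after <- count_peptides(
      paths$r1_after, paths$r2_after, design,
      quality_threshold = cfg$process$quality_threshold,
      tag_max_mismatch = cfg$process$tag_max_mismatch,
      anchor_max_mismatch = cfg$process$anchor_max_mismatch,
      adapters = cfg$process$adapters %||% character(),
      sample_name = "after"
    )
    long <- dplyr::bind_rows(pc_before$counts, pc_after$counts)
    .write_tsv(long, file.path(out, "counts.tsv"))
    rej <- dplyr::bind_rows(
      before = pc_before$rejections, after = pc_after$rejections,
      .id = "sample"
    )
    .write_tsv(rej, file.path(out, "rejections.tsv"))
    long
  })

  ## --- enrich --------------------------------------------------------
  ef <- timed("enrich", {
    tbl <- count_table(counts)
    ef <- peptide_ef(tbl, pseudocount = cfg$enrich$pseudocount)
    .write_tsv(ef, file.path(out, "enrichment.tsv"))
    top <- rank_top(ef,
      min_count_after = cfg$enrich$min_count_after,
      top_n = cfg$enrich$top_n
    )
    .write_tsv(top, file.path(out, "top_ranked.tsv"))
    pos_ef <- position_aa_ef(tbl, design)
    data.table::fwrite(pos_ef, file.path(out, "position_ef.csv"))
    cons <- heatmap_consensus(pos_ef)
    jsonlite::write_json(
      list(
        consensus = attr(cons, "consensus"),
        positions = cons
      ),
      file.path(out, "consensus.json"),
      dataframe = "rows", auto_unbox = TRUE, digits = NA
    )
    if (nrow(top)) {
      data.table::fwrite(logo_matrix(top), file.path(out, "logo_matrix.csv"))
    }
    ef
  })

  ## --- analyze -------------------------------------------------------
  if (isTRUE(cfg$analyze$enabled)) {
    timed("analyze", {
      ## RF response: pseudocount-regularized EF of peptides seen before
      ## selection (log scale by default); at desk-scale coverage this
      ## avoids the zero-after truncation artifact (see vignette)
      ef_rf <- peptide_ef(
        count_table(counts),
        pseudocount = cfg$analyze$pseudocount
      )
      dat <- ef_rf[
        ef_rf$count_before > 0 & !is.na(ef_rf$ef) & ef_rf$ef > 0,
      ]
      seed_rf <- derive_seed(cfg$seed, "rf")
      if (nrow(dat) > cfg$analyze$max_rows) {
        keep <- .with_seed(
          seed_rf, sample.int(nrow(dat), cfg$analyze$max_rows)
        )
        dat <- dat[sort(keep), ]
      }
      enc <- one_hot_encode(dat$peptide, design)
      y <- if (isTRUE(cfg$analyze$log_response)) log(dat$ef) else dat$ef
      fit <- fit_rf_cv(enc$x, y,
        k = cfg$analyze$folds, num_trees = cfg$analyze$num_trees,
        max_depth = cfg$analyze$max_depth,
        seed = seed_rf
      )
      imp <- permutation_importance(fit,
        n_repeats = cfg$analyze$n_repeats,
        seed = derive_seed(cfg$seed, "perm")
      )
      .write_tsv(
        imp[order(imp$rank), ], file.path(out, "importance.tsv")
      )
      ## group comparisons use the raw enrichment factors (all peptides
      ## with a defined EF), matching the enrichment-module statistics
      ef_groups <- ef[!is.na(ef$ef), ]
      hyd <- hydrophobic_count_analysis(ef_groups, design)
      .write_tsv(hyd$groups, file.path(out, "hydrophobic_groups.tsv"))
      .write_tsv(hyd$tests, file.path(out, "hydrophobic_tests.tsv"))
      pol <- polarity_by_position(ef_groups, design)
      .write_tsv(pol$tests, file.path(out, "polarity_tests.tsv"))
      list(n_rows = nrow(dat), cv_mse = mean(fit$mse_fold))
    })
  }

  ## --- manifest (written atomically) ---------------------------------
  manifest$outputs <- as.list(tools::md5sum(
    list.files(out, pattern = "\\.(tsv|csv|json)$", full.names = TRUE)
  ))
  tmp <- file.path(out, ".manifest.json.tmp")
  jsonlite::write_json(manifest, tmp, auto_unbox = TRUE, digits = NA)
  file.rename(tmp, file.path(out, "manifest.json"))
  invisible(manifest)
}
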