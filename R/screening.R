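# In-silico stabilizer discovery workflow: compound property pre-filtering,
# reproducible sampling, pluggable docking adapters, docking-score cuts,
# dual-binding evaluation and the orchestrated pipeline.

#' Read a compound roster
#'
#' @param path CSV/TSV with at least `compound_id`; descriptor columns
#'   `molecular_weight` (Da), `logp`, `complexity` (BertzCT-type) and
#'   `docking_score` (kcal/mol) are used when present; all other columns are
#'   carried through as opaque annotations (e.g. SMILES, potency).
#' @return A tibble.
#' @export
read_compounds <- function(path) {
  if (!file.exists(path)) {
    stop(sprintf("compound roster '%s' does not exist", path), call. = FALSE)
  }
  delim <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  out <- readr::read_delim(path, delim = delim, show_col_types = FALSE,
                           comment = "#", progress = FALSE)
  if (!"compound_id" %in% names(out)) {
    stop("compound roster needs a `compound_id` column", call. = FALSE)
  }
  dplyr::mutate(out, compound_id = as.character(.data$compound_id))
}

#' Pre-filter compounds by drug-likeness descriptors
#'
#' Keeps compounds inside the molecular-weight and LogP windows with a
#' structural complexity at or below `max_complexity` (overly complex
#' molecules are removed as hard to parametrise for force fields). The
#' default windows, 375-425 Da and LogP 2-4.5 with BertzCT complexity <= 700,
#' describe the physicochemical envelope typical of known interface
#' stabilizers. Criteria are applied in declared order (weight, LogP,
#' complexity), which affects only the audit attribution, not the kept set.
#' Compounds missing any required descriptor are routed to a
#' `needs_descriptors` bin rather than silently dropped.
#'
#' @param compounds Tibble with `compound_id`, `molecular_weight`, `logp`,
#'   `complexity`.
#' @param mw_window Length-2 numeric, Da (inclusive).
#' @param logp_window Length-2 numeric (inclusive).
#' @param max_complexity Scalar; compounds with complexity strictly above it
#'   are removed.
#' @return A list of class `filter_result`: `kept`, `needs_descriptors`,
#'   and `audit` (tibble `stage`, `removed`, `remaining`; removals sum with
#'   the kept count to the input size).
#' @export
property_filter <- function(compounds, mw_window = c(375, 425),
                            logp_window = c(2, 4.5), max_complexity = 700) {
  compounds <- tibble::as_tibble(compounds)
  need <- c("molecular_weight", "logp", "complexity")
  present <- intersect(need, names(compounds))
  if (length(present) < 3L) {
    for (nm in setdiff(need, present)) compounds[[nm]] <- NA_real_
  }
  n0 <- nrow(compounds)
  incomplete <- !stats::complete.cases(
    compounds[, c("molecular_weight", "logp", "complexity")])
  bin <- compounds[incomplete, , drop = FALSE]
  pool <- compounds[!incomplete, , drop = FALSE]
  audit <- tibble::tibble(stage = "needs_descriptors",
                          removed = nrow(bin), remaining = nrow(pool))
  steps <- list(
    weight = function(d) d$molecular_weight >= mw_window[1] &
      d$molecular_weight <= mw_window[2],
    logp = function(d) d$logp >= logp_window[1] & d$logp <= logp_window[2],
    complexity = function(d) d$complexity <= max_complexity
  )
  for (nm in names(steps)) {
    ok <- steps[[nm]](pool)
    audit <- dplyr::bind_rows(audit, tibble::tibble(
      stage = nm, removed = sum(!ok), remaining = sum(ok)))
    pool <- pool[ok, , drop = FALSE]
  }
  stopifnot(sum(audit$removed) + nrow(pool) == n0)
  structure(list(kept = pool, needs_descriptors = bin, audit = audit),
            class = "filter_result")
}

#' @export
print.filter_result <- function(x, ...) {
  cat(sprintf("Property filter: %d kept, %d need descriptors\n",
              nrow(x$kept), nrow(x$needs_descriptors)))
  print(x$audit)
  invisible(x)
}

# Run code with a temporary RNG state so callers' streams are untouched.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

#' Sample compounds uniformly without replacement
#'
#' @param compounds Tibble with one row per compound.
#' @param n Number to draw (<= roster size).
#' @param seed Integer seed; identical seeds give identical subsets.
#' @return A tibble of `n` rows.
#' @export
sample_compounds <- function(compounds, n, seed) {
  compounds <- tibble::as_tibble(compounds)
  if (n > nrow(compounds)) {
    stop(sprintf("cannot sample %d from a roster of %d", n, nrow(compounds)),
         call. = FALSE)
  }
  idx <- with_seed(seed, sample.int(nrow(compounds), n))
  compounds[idx, , drop = FALSE]
}

# Deterministic hash of a string to [0, 1).
unit_hash <- function(x) {
  vapply(x, function(s) {
    h <- 0
    for (v in utf8ToInt(s)) h <- (h * 131 + v) %% 1e9
    (h %% 1e6) / 1e6
  }, numeric(1), USE.NAMES = FALSE)
}

#' Deterministic mock docking adapter
#'
#' Returns an adapter function suitable for [docking_stage()]: scores are a
#' pure deterministic function of the compound id (uniform over
#' `score_range`), and ids listed in `fail_ids` produce failure records.
#' Used for testing the pipeline without a docking engine.
#'
#' @param score_range Length-2 numeric, kcal/mol (default -10 to -4).
#' @param fail_ids Compound ids the adapter should fail on.
#' @return A function `(compounds) -> tibble(compound_id, docking_score,
#'   status, message)`.
#' @export
mock_docking_adapter <- function(score_range = c(-10, -4),
                                 fail_ids = character()) {
  force(score_range); force(fail_ids)
  function(compounds) {
    ids <- compounds$compound_id
    u <- unit_hash(ids)
    tibble::tibble(
      compound_id = ids,
      docking_score = ifelse(ids %in% fail_ids, NA_real_,
                             score_range[1] + u * diff(score_range)),
      status = ifelse(ids %in% fail_ids, "failed", "ok"),
      message = ifelse(ids %in% fail_ids, "mock failure", "")
    )
  }
}

#' Make a docking adapter from a shell command template
#'
#' The template is expanded per compound (`{id}` and `{smiles}`
#' placeholders), executed, and the last numeric token of its standard
#' output is parsed as the docking score in kcal/mol. Non-zero exit or
#' unparsable output produces a per-compound failure record; other compounds
#' are unaffected.
#'
#' @param template Command template, e.g. `"dock.sh --ligand {smiles}"`.
#' @return An adapter function for [docking_stage()].
#' @export
command_docking_adapter <- function(template) {
  force(template)
  function(compounds) {
    purrr::map_dfr(seq_len(nrow(compounds)), function(i) {
      id <- compounds$compound_id[i]
      cmd <- gsub("{id}", id, template, fixed = TRUE)
      if ("smiles" %in% names(compounds)) {
        cmd <- gsub("{smiles}", compounds$smiles[i], cmd, fixed = TRUE)
      }
      out <- tryCatch(
        system(cmd, intern = TRUE, ignore.stderr = TRUE),
        warning = function(w) NULL, error = function(e) NULL
      )
      score <- NA_real_
      if (!is.null(out) && length(out)) {
        toks <- unlist(strsplit(paste(out, collapse = " "), "\\s+"))
        nums <- suppressWarnings(as.numeric(toks))
        if (any(is.finite(nums))) score <- nums[which(is.finite(nums))[
          sum(is.finite(nums))]]
      }
      tibble::tibble(
        compound_id = id, docking_score = score,
        status = if (is.finite(score)) "ok" else "failed",
        message = if (is.finite(score)) "" else
          paste("no score parsed from:", paste(out, collapse = " "))
      )
    })
  }
}

#' Run the docking stage through an adapter, resumably
#'
#' Scores every compound through the adapter (or reuses cached scores),
#' merging scores into the roster. Compounds already present in the cache
#' are skipped, making the stage resumable after an interrupt; every input
#' compound ends with either a score or an explicit failure record.
#'
#' @param compounds Compound tibble.
#' @param adapter Adapter function (see [mock_docking_adapter()],
#'   [command_docking_adapter()]).
#' @param cache Optional path to a TSV provenance ledger of scored
#'   compounds; read if it exists, updated after scoring.
#' @return The roster with a `docking_score` column; failures in
#'   `attr(, "failures")`, the full score ledger in `attr(, "ledger")`.
#' @export
docking_stage <- function(compounds, adapter, cache = NULL) {
  compounds <- tibble::as_tibble(compounds)
  prior <- NULL
  if (!is.null(cache) && file.exists(cache)) {
    prior <- readr::read_tsv(cache, show_col_types = FALSE,
                             progress = FALSE) |>
      dplyr::mutate(compound_id = as.character(.data$compound_id))
  }
  todo <- compounds
  if (!is.null(prior)) {
    done <- prior$compound_id[prior$status == "ok"]
    todo <- compounds[!compounds$compound_id %in% done, , drop = FALSE]
  }
  fresh <- if (nrow(todo)) adapter(todo) else NULL
  ledger <- dplyr::bind_rows(
    if (!is.null(prior)) dplyr::filter(prior, !.data$compound_id %in%
                                         (fresh$compound_id %||% character())),
    fresh
  ) |>
    dplyr::distinct(.data$compound_id, .keep_all = TRUE)
  if (!is.null(cache)) readr::write_tsv(ledger, cache, progress = FALSE)
  scored <- dplyr::left_join(
    dplyr::select(compounds, -dplyr::any_of("docking_score")),
    dplyr::select(ledger, "compound_id", "docking_score"),
    by = "compound_id"
  )
  attr(scored, "failures") <- dplyr::filter(ledger, .data$status != "ok")
  attr(scored, "ledger") <- ledger
  scored
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Cut compounds at a docking-score threshold
#'
#' Keeps compounds whose docking score is better than (at or below) the
#' cutoff; "better than -6 kcal/mol" means more negative. Unscored compounds
#' are excluded and counted separately, never silently kept.
#'
#' @param compounds Tibble with a `docking_score` column.
#' @param cutoff kcal/mol (default -6).
#' @return A list: `kept`, `fraction_passing` (of scored compounds;
#'   `NaN` when none are scored), `n_scored`, `n_unscored`, `unscored`.
#' @export
score_cut <- function(compounds, cutoff = -6) {
  compounds <- tibble::as_tibble(compounds)
  if (!"docking_score" %in% names(compounds)) {
    stop("`docking_score` column is absent", call. = FALSE)
  }
  scored <- compounds[is.finite(compounds$docking_score), , drop = FALSE]
  unscored <- compounds[!is.finite(compounds$docking_score), , drop = FALSE]
  keep <- scored[scored$docking_score <= cutoff, , drop = FALSE]
  list(
    kept = keep,
    fraction_passing = nrow(keep) / nrow(scored),
    n_scored = nrow(scored),
    n_unscored = nrow(unscored),
    unscored = unscored
  )
}

#' Evaluate shortlisted compounds for dual binding
#'
#' Aggregates the candidates' per-frame interaction energies and applies the
#' dual-binding selector, emitting the weaker-side versus balance table that
#' underlies the selection scatter plot plus a shortlist ranked by
#' weaker-side strength.
#'
#' @param compounds Tibble of candidate compounds (`compound_id`).
#' @param frames Wide per-frame energy table whose `complex_id` matches the
#'   candidates' `compound_id`.
#' @param max_weaker,max_balance Selector cutoffs, kcal/mol (see
#'   [select_dual_binding()]).
#' @return A list of class `dual_binding_report`: `report` (per-candidate
#'   weaker side, balance and `selected` flag) and `shortlist`.
#' @export
evaluate_candidates <- function(compounds, frames, max_weaker = -15,
                                max_balance = 10) {
  ids <- unique(compounds$compound_id)
  frames <- frames[frames$complex_id %in% ids, , drop = FALSE]
  if (nrow(frames) == 0L) {
    stop("no energy frames found for the candidate compounds", call. = FALSE)
  }
  agg <- aggregate_energetics(frames)
  sel <- select_dual_binding(agg, max_weaker = max_weaker,
                             max_balance = max_balance)
  report <- attr(sel, "all") |>
    dplyr::rename(compound_id = "complex_id") |>
    dplyr::select("compound_id", "weaker_side",
                  dplyr::any_of(c("balance_mean", "mean_gap")), "selected")
  shortlist <- report |>
    dplyr::filter(.data$selected) |>
    dplyr::arrange(.data$weaker_side, .data$compound_id)
  structure(list(report = report, shortlist = shortlist,
                 max_weaker = max_weaker, max_balance = max_balance),
            class = "dual_binding_report")
}

#' @export
print.dual_binding_report <- function(x, ...) {
  cat(sprintf(
    "Dual-binding evaluation: %d of %d candidates selected\n",
    nrow(x$shortlist), nrow(x$report)))
  cat(sprintf("  (weaker side < %g kcal/mol, balance < %g kcal/mol)\n",
              x$max_weaker, x$max_balance))
  invisible(x)
}

stage_seed <- function(seed, stage) {
  (as.integer(seed) + sum(utf8ToInt(stage)) * 7919L) %% 2147483647L
}

#' Build and validate a discovery-pipeline configuration
#'
#' @param out_dir Run directory (created by [run_pipeline()]).
#' @param seed Top-level integer seed; stage seeds are derived
#'   deterministically from it by stage name.
#' @param compounds Compound roster: a tibble or a CSV/TSV path.
#' @param structure,side_map Optional complex structure (PDB path) and
#'   chain-to-side map for the pocket stage.
#' @param probes,pocket_scores Optional probe file and scores sidecar paths.
#' @param mw_window,logp_window,max_complexity Property-filter parameters.
#' @param sample_n Optional roster subsample size before docking.
#' @param adapter Docking adapter: `"mock"`, an adapter function, a command
#'   template string, or `NULL` to skip docking and use a `docking_score`
#'   column already present in the roster.
#' @param scores_table Optional TSV of precomputed docking scores
#'   (`compound_id`, `docking_score`); when given, docking is skipped.
#' @param score_cutoff Docking-score cut, kcal/mol.
#' @param energy_tables Optional per-frame energy table (path or tibble) for
#'   the dual-binding evaluation of surviving candidates.
#' @param max_weaker,max_balance Dual-binding selector cutoffs, kcal/mol.
#' @param min_atoms Interface-pocket thresholds.
#' @return A validated list of class `pipeline_config`.
#' @export
pipeline_config <- function(out_dir, seed = 1L, compounds,
                            structure = NULL, side_map = NULL,
                            probes = NULL, pocket_scores = NULL,
                            mw_window = c(375, 425),
                            logp_window = c(2, 4.5), max_complexity = 700,
                            sample_n = NULL, adapter = "mock",
                            scores_table = NULL, score_cutoff = -6,
                            energy_tables = NULL, max_weaker = -15,
                            max_balance = 10, min_atoms = c(5L, 10L, 20L)) {
  for (p in c(if (is.character(compounds)) compounds, structure, probes,
              pocket_scores, scores_table,
              if (is.character(energy_tables)) energy_tables)) {
    if (!is.null(p) && !file.exists(p)) {
      stop(sprintf("configured path '%s' does not exist", p), call. = FALSE)
    }
  }
  stopifnot(is.finite(score_cutoff), is.finite(max_weaker),
            is.finite(max_balance))
  structure(
    list(out_dir = out_dir, seed = as.integer(seed), compounds = compounds,
         structure = structure, side_map = side_map, probes = probes,
         pocket_scores = pocket_scores, mw_window = mw_window,
         logp_window = logp_window, max_complexity = max_complexity,
         sample_n = sample_n, adapter = adapter,
         scores_table = scores_table, score_cutoff = score_cutoff,
         energy_tables = energy_tables, max_weaker = max_weaker,
         max_balance = max_balance, min_atoms = min_atoms),
    class = "pipeline_config"
  )
}

#' Read a pipeline configuration from YAML
#'
#' @param path YAML file whose keys are the arguments of
#'   [pipeline_config()]; `side_map` is a chain-to-side mapping.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (!is.null(cfg$side_map)) cfg$side_map <- unlist(cfg$side_map)
  do.call(pipeline_config, cfg)
}

#' Run the stabilizer-discovery pipeline
#'
#' Executes the configured stages in order -- structure/pocket intake,
#' interface-pocket statistics and ranking, property filter, optional
#' subsampling, docking (adapter or precomputed scores), docking-score cut,
#' dual-binding evaluation -- writing every table plus a provenance manifest
#' into the run directory. With a fixed configuration and seed all outputs
#' are deterministic.
#'
#' @param config A [pipeline_config()] (or path to a YAML config).
#' @return A list of class `pipeline_run` with each stage's result and the
#'   run directory.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_pipeline_config(config)
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  log_path <- file.path(config$out_dir, "log.txt")
  logf <- function(...) {
    cat(sprintf("[%s] %s\n", format(Sys.time(), "%H:%M:%S"),
                sprintf(...)), file = log_path, append = TRUE)
  }
  save_tsv <- function(x, name) {
    readr::write_tsv(x, file.path(config$out_dir, name), progress = FALSE)
  }
  results <- list(out_dir = config$out_dir)

  logf("stage intake")
  compounds <- if (is.character(config$compounds)) {
    read_compounds(config$compounds)
  } else tibble::as_tibble(config$compounds)

  if (!is.null(config$probes) && !is.null(config$structure)) {
    logf("stage pockets")
    atoms <- read_structure(config$structure, side_map = config$side_map,
                            allow_unmapped = TRUE)
    probes <- read_pockets(config$probes, scores = config$pocket_scores)
    stats <- interface_pocket_stats(
      probes, atoms[atoms$side == "R", ], atoms[atoms$side == "L", ],
      min_atoms = config$min_atoms)
    save_tsv(stats$per_pocket, "pocket_stats.tsv")
    save_tsv(stats$thresholds, "pocket_thresholds.tsv")
    results$pockets <- stats
    sc <- pocket_scores(probes)
    if (!is.null(sc)) {
      ranked <- rank_pockets(sc, "drug_score")
      save_tsv(ranked, "pocket_ranking.tsv")
      results$pocket_ranking <- ranked
    }
  }

  logf("stage filter")
  filt <- property_filter(compounds, mw_window = config$mw_window,
                          logp_window = config$logp_window,
                          max_complexity = config$max_complexity)
  save_tsv(filt$audit, "filter_audit.tsv")
  save_tsv(filt$kept, "filtered_compounds.tsv")
  results$filter <- filt
  pool <- filt$kept

  if (!is.null(config$sample_n)) {
    logf("stage sample (n = %d)", config$sample_n)
    pool <- sample_compounds(pool, config$sample_n,
                             seed = stage_seed(config$seed, "sample"))
    save_tsv(pool, "sampled_compounds.tsv")
  }

  logf("stage dock")
  if (is.null(config$adapter) && is.null(config$scores_table)) {
    if (!"docking_score" %in% names(pool)) {
      stop("no docking adapter or scores table configured and the roster ",
           "has no `docking_score` column", call. = FALSE)
    }
  } else if (!is.null(config$scores_table)) {
    scores <- readr::read_tsv(config$scores_table, show_col_types = FALSE,
                              progress = FALSE) |>
      dplyr::mutate(compound_id = as.character(.data$compound_id))
    pool <- dplyr::left_join(
      dplyr::select(pool, -dplyr::any_of("docking_score")),
      dplyr::select(scores, "compound_id", "docking_score"),
      by = "compound_id")
  } else {
    adapter <- config$adapter
    if (is.character(adapter)) {
      adapter <- if (identical(adapter, "mock")) mock_docking_adapter()
                 else command_docking_adapter(adapter)
    }
    pool <- docking_stage(pool, adapter,
                          cache = file.path(config$out_dir,
                                            "docking_ledger.tsv"))
  }
  save_tsv(pool, "docked_compounds.tsv")

  logf("stage cut (cutoff = %g)", config$score_cutoff)
  cut <- score_cut(pool, cutoff = config$score_cutoff)
  save_tsv(cut$kept, "score_cut.tsv")
  results$docked <- pool
  results$cut <- cut

  if (!is.null(config$energy_tables)) {
    logf("stage evaluate")
    frames <- if (is.character(config$energy_tables)) {
      read_energy_frames(config$energy_tables)
    } else validate_energy_frames(config$energy_tables)
    eval_res <- evaluate_candidates(cut$kept, frames,
                                    max_weaker = config$max_weaker,
                                    max_balance = config$max_balance)
    save_tsv(eval_res$report, "dual_binding_report.tsv")
    save_tsv(eval_res$shortlist, "shortlist.tsv")
    results$evaluation <- eval_res
  }

  manifest <- list(
    package = "dualbind",
    version = as.character(utils::packageVersion("dualbind")),
    seed = config$seed,
    parameters = config[setdiff(names(config),
                                c("compounds", "adapter", "energy_tables"))],
    inputs = list(
      compounds = if (is.character(config$compounds)) config$compounds
                  else sprintf("<in-memory: %d rows>", nrow(compounds)),
      n_compounds = nrow(compounds)
    ),
    counts = list(
      filtered = nrow(filt$kept),
      after_cut = nrow(cut$kept),
      shortlisted = if (!is.null(results$evaluation)) {
        nrow(results$evaluation$shortlist)
      } else NA_integer_
    )
  )
  yaml::write_yaml(manifest, file.path(config$out_dir, "manifest.yaml"))
  results$manifest <- manifest
  logf("done")
  structure(results, class = "pipeline_run")
}

#' @export
print.pipeline_run <- function(x, ...) {
  cat("Stabilizer-discovery pipeline run\n")
  cat(sprintf("  run directory: %s\n", x$out_dir))
  cat(sprintf("  filtered: %d, after score cut: %d\n",
              x$manifest$counts$filtered, x$manifest$counts$after_cut))
  if (!is.null(x$evaluation)) {
    cat(sprintf("  shortlisted dual binders: %d\n",
                nrow(x$evaluation$shortlist)))
  }
  invisible(x)
}
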