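# Compound pre-filtering, sampling, docking adapters, score cuts,
# dual-binding evaluation and the orchestrated pipeline.

test_that("property filter applies windows in order with a complete audit", {
  roster <- tibble::tibble(
    compound_id = c("in", "heavy", "greasy", "baroque", "nodata"),
    molecular_weight = c(400, 450, 400, 400, NA),
    logp = c(3, 3, 5, 3, 3),
    complexity = c(500, 500, 500, 900, 500)
  )
  fr <- property_filter(roster)
  expect_equal(fr$kept$compound_id, "in")
  expect_equal(fr$needs_descriptors$compound_id, "nodata")
  expect_equal(sum(fr$audit$removed) + nrow(fr$kept), nrow(roster))
  expect_equal(fr$audit$stage,
               c("needs_descriptors", "weight", "logp", "complexity"))
  expect_equal(fr$audit$removed, c(1L, 1L, 1L, 1L))
  # boundary semantics: windows inclusive, complexity > max removed
  edge <- tibble::tibble(compound_id = c("lo", "hi", "cx"),
                         molecular_weight = c(375, 425, 400),
                         logp = c(2, 4.5, 3), complexity = c(700, 700, 701))
  fe <- property_filter(edge)
  expect_setequal(fe$kept$compound_id, c("lo", "hi"))
})

test_that("planted filter pass counts are recovered exactly", {
  rr <- make_compound_roster(n = 300, n_pass_filter = 117,
                             n_candidates = 20, n_dual_pass = 9, seed = 4)
  fr <- property_filter(rr$compounds)
  expect_equal(nrow(fr$kept), 117)
})

test_that("compound sampling is uniform, seeded and bounded", {
  roster <- tibble::tibble(compound_id = sprintf("c%03d", 1:40))
  all40 <- sample_compounds(roster, 40, seed = 1)
  expect_setequal(all40$compound_id, roster$compound_id)
  a <- sample_compounds(roster, 10, seed = 99)
  b <- sample_compounds(roster, 10, seed = 99)
  expect_equal(a, b)
  expect_error(sample_compounds(roster, 41, seed = 1), "cannot sample")
  # inclusion frequency ~ n/N over reseeded draws
  hits <- 0L
  for (s in 1:400) {
    hits <- hits + ("c001" %in% sample_compounds(roster, 10, s)$compound_id)
  }
  p_hat <- hits / 400
  expect_lt(abs(p_hat - 0.25), 3 * sqrt(0.25 * 0.75 / 400))
})

test_that("docking stage isolates failures and resumes from its ledger", {
  roster <- tibble::tibble(compound_id = sprintf("c%02d", 1:6))
  fixed <- function(compounds) tibble::tibble(
    compound_id = compounds$compound_id, docking_score = -7.5,
    status = "ok", message = "")
  out <- docking_stage(roster, fixed)
  expect_equal(out$docking_score, rep(-7.5, 6))
  # one failing compound leaves the others untouched
  flaky <- mock_docking_adapter(fail_ids = "c03")
  out2 <- docking_stage(roster, flaky)
  expect_equal(sum(is.na(out2$docking_score)), 1)
  expect_equal(attr(out2, "failures")$compound_id, "c03")
  # resumption: an interrupted run's ledger short-circuits re-scoring
  cache <- withr::local_tempfile(fileext = ".tsv")
  calls <- new.env(); calls$ids <- character()
  counting <- function(compounds) {
    calls$ids <- c(calls$ids, compounds$compound_id)
    fixed(compounds)
  }
  docking_stage(roster[1:4, ], counting, cache = cache)
  docking_stage(roster, counting, cache = cache)
  expect_equal(sort(unique(calls$ids)), sort(roster$compound_id))
  expect_equal(sum(calls$ids %in% sprintf("c%02d", 1:4)), 4)  # no re-scoring
})

test_that("command adapters parse scores from stdout and record failures", {
  ad <- command_docking_adapter("echo score {id} -7.25")
  out <- ad(tibble::tibble(compound_id = c("a1", "a2")))
  expect_equal(out$docking_score, c(-7.25, -7.25))
  bad <- command_docking_adapter("false")
  out2 <- bad(tibble::tibble(compound_id = "a1"))
  expect_equal(out2$status, "failed")
})

test_that("score cut keeps better-than-cutoff scores and reports fractions", {
  comp <- tibble::tibble(compound_id = c("a", "b", "c"),
                         docking_score = c(-7, -5, NA))
  sc <- score_cut(comp, cutoff = -6)
  expect_equal(sc$kept$compound_id, "a")
  expect_equal(sc$fraction_passing, 0.5)
  expect_equal(sc$n_unscored, 1)
  # all unscored: empty kept, full exclusion count
  allna <- tibble::tibble(compound_id = "x", docking_score = NA_real_)
  sna <- score_cut(allna)
  expect_equal(nrow(sna$kept), 0)
  expect_equal(sna$n_unscored, 1)
  # monotone in the cutoff
  set.seed(2)
  comp2 <- tibble::tibble(compound_id = as.character(1:200),
                          docking_score = runif(200, -10, -2))
  fr <- vapply(c(-4, -6, -8), function(cut) {
    score_cut(comp2, cut)$fraction_passing
  }, numeric(1))
  expect_true(!is.unsorted(rev(fr)))
  # planted tail mass is recovered
  rr <- make_compound_roster(n = 400, n_pass_filter = 150,
                             score_pass_fraction = 0.75,
                             n_candidates = 30, n_dual_pass = 10, seed = 6)
  expect_equal(score_cut(rr$compounds)$fraction_passing, 0.75)
})

test_that("candidate evaluation shortlists exactly the planted dual binders", {
  rr <- make_compound_roster(n = 200, n_pass_filter = 90, n_candidates = 50,
                             n_dual_pass = 34, seed = 10)
  cands <- tibble::tibble(compound_id = rr$manifest$candidate_ids)
  ev <- evaluate_candidates(cands, rr$frames)
  expect_equal(nrow(ev$shortlist), 34)
  expect_setequal(ev$shortlist$compound_id, rr$manifest$dual_pass_ids)
  # trivial threshold checks
  strong <- constant_frames("hit", -24, -26)
  weak <- constant_frames("miss", -40, -10)
  both <- dplyr::bind_rows(strong, weak)
  ev2 <- evaluate_candidates(tibble::tibble(compound_id = c("hit", "miss")),
                             both)
  expect_equal(ev2$shortlist$compound_id, "hit")
})

test_that("the pipeline runs end to end, recovers planted truths and is deterministic", {
  base <- withr::local_tempdir()
  rr <- make_compound_roster(n = 200, n_pass_filter = 80, n_candidates = 40,
                             n_dual_pass = 21, seed = 7,
                             dir = file.path(base, "roster"))
  tc <- make_toy_complex(seed = 3, path = file.path(base, "cx.pdb"))
  pf <- make_pocket_fixture(tc, dir = file.path(base, "pockets"))
  cfg <- function(out) pipeline_config(
    out_dir = file.path(base, out), seed = 11,
    compounds = file.path(base, "roster", "compounds.csv"),
    structure = tc$path, side_map = c(R = "R", L = "L", S = "S"),
    probes = file.path(base, "pockets", "pockets.pqr"),
    pocket_scores = file.path(base, "pockets", "pocket_scores.tsv"),
    scores_table = file.path(base, "roster", "docking_scores.tsv"),
    energy_tables = file.path(base, "roster", "candidate_energies.tsv"))
  run <- run_pipeline(cfg("run1"))
  expect_equal(nrow(run$filter$kept), 80)
  expect_setequal(run$evaluation$shortlist$compound_id,
                  rr$manifest$dual_pass_ids)
  # planted best pocket ranked first
  expect_equal(run$pocket_ranking$pocket_id[1], "1")
  # manifest + all stage tables written
  files <- list.files(run$out_dir)
  expect_true(all(c("manifest.yaml", "filter_audit.tsv", "score_cut.tsv",
                    "shortlist.tsv", "pocket_stats.tsv") %in% files))
  # rerun determinism: identical outputs byte for byte (log excepted)
  run2 <- run_pipeline(cfg("run2"))
  for (f in c("shortlist.tsv", "filter_audit.tsv", "score_cut.tsv",
              "dual_binding_report.tsv", "pocket_ranking.tsv")) {
    expect_equal(readLines(file.path(base, "run1", f)),
                 readLines(file.path(base, "run2", f)))
  }
  # stage equivalence: docking disabled with scores supplied via the roster
  cfg3 <- pipeline_config(
    out_dir = file.path(base, "run3"), seed = 11,
    compounds = file.path(base, "roster", "compounds.csv"),
    adapter = NULL,
    energy_tables = file.path(base, "roster", "candidate_energies.tsv"))
  run3 <- run_pipeline(cfg3)
  expect_equal(readLines(file.path(base, "run1", "shortlist.tsv")),
               readLines(file.path(base, "run3", "shortlist.tsv")))
})

test_that("pipeline configs validate paths and parse from YAML", {
  expect_error(pipeline_config(out_dir = tempdir(), compounds = "no.csv"),
               "does not exist")
  dir <- withr::local_tempdir()
  roster <- file.path(dir, "c.csv")
  readr::write_csv(tibble::tibble(compound_id = "a", molecular_weight = 400,
                                  logp = 3, complexity = 100,
                                  docking_score = -7), roster)
  yml <- file.path(dir, "cfg.yaml")
  yaml::write_yaml(list(out_dir = file.path(dir, "out"), seed = 5,
                        compounds = roster, adapter = NULL), yml)
  cfg <- read_pipeline_config(yml)
  expect_s3_class(cfg, "pipeline_config")
  run <- run_pipeline(cfg)
  expect_equal(nrow(run$cut$kept), 1)
})
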