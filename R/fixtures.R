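# Self-verifying synthetic fixtures: toy complexes, pocket probes, per-frame
# energy tables and compound rosters, each with planted ground truth recorded
# in a manifest and re-checked by brute force before writing. Fixtures
# exercise contracts; they make no attempt at physically realistic protein
# geometry or energetics.

#' Write an atom table as fixed-width PDB text
#'
#' @param atoms Atom tibble (`serial`, `name`, `element`, `chain`, `resno`,
#'   `resname`, `x`, `y`, `z`, optional logical `het`).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_pdb_atoms <- function(atoms, path) {
  het <- if ("het" %in% names(atoms)) atoms$het else rep(FALSE, nrow(atoms))
  name4 <- vapply(seq_len(nrow(atoms)), function(i) {
    nm <- atoms$name[i]
    if (nchar(atoms$element[i]) == 1L && nchar(nm) < 4L) {
      sprintf(" %-3s", nm)
    } else {
      sprintf("%-4s", nm)
    }
  }, character(1))
  lines <- sprintf(
    "%-6s%5d %4s %-3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
    ifelse(het, "HETATM", "ATOM"), atoms$serial, name4, atoms$resname,
    atoms$chain, as.integer(atoms$resno), atoms$x, atoms$y, atoms$z,
    1, 0, toupper(atoms$element)
  )
  writeLines(c(lines, "END"), path)
  invisible(path)
}

#' Generate a toy protein-protein-stabilizer complex
#'
#' Builds two atom clusters (chains `R` and `L`) facing each other across a
#' planned interface gap, plus an optional stabilizer HETATM group (chain
#' `S`) between them. The first `n_face` residues of each chain sit exactly
#' on the interface plane (pairs of atoms exactly `gap` apart, laid out on a
#' 3 Angstrom grid); the remaining residues are placed well behind the
#' plane. The planted interface residue ids are recorded in the manifest and
#' are exactly what [interface_residues()] recovers for any cutoff between
#' `gap` and the back-row distance.
#'
#' @param n_atoms_per_chain Total atoms per protein chain.
#' @param gap Interface gap, Angstrom (> 0).
#' @param n_face Facing (interface) residues per chain; one atom each.
#' @param n_ligand Stabilizer atoms (0 for none), spaced 4 Angstrom apart at
#'   the interface midplane.
#' @param seed Integer seed (element composition and back-row jitter).
#' @param path Optional path to also write the complex as PDB text.
#' @return A list of class `toy_complex`: `atoms` (tibble), `manifest`
#'   (planted truths: interface residue ids per side, chain plan, seed) and
#'   `path` (or `NULL`).
#' @export
make_toy_complex <- function(n_atoms_per_chain = 36, gap = 4, n_face = 6,
                             n_ligand = 8, seed = 1, path = NULL) {
  if (!is.numeric(gap) || gap <= 0) stop("`gap` must be > 0", call. = FALSE)
  stopifnot(n_face >= 1, n_atoms_per_chain >= n_face)
  elements <- c("C", "N", "O", "S")
  build_chain <- function(chain, sign) {
    # facing atoms: on the plane x = sign*gap/2, 3 A grid in y
    face <- tibble::tibble(
      chain = chain,
      resno = seq_len(n_face),
      x = sign * gap / 2,
      y = 3 * (seq_len(n_face) - 1L),
      z = 0
    )
    n_back <- n_atoms_per_chain - n_face
    back <- tibble::tibble(
      chain = chain,
      resno = n_face + seq_len(n_back),
      x = sign * (gap / 2 + 8 + stats::runif(n_back, 0, 4)),
      y = stats::runif(n_back, -2, 3 * n_face),
      z = stats::runif(n_back, -3, 3)
    )
    dplyr::bind_rows(face, back)
  }
  atoms <- with_seed(seed, {
    prot <- dplyr::bind_rows(build_chain("R", -1), build_chain("L", +1))
    prot$element <- sample(elements, nrow(prot), replace = TRUE)
    if (n_ligand > 0) {
      lig <- tibble::tibble(
        chain = "S", resno = 1L,
        # z-offset keeps ligand atoms clear of probes planted on the
        # interface plane (fixture self-check relies on it)
        x = 0, y = 4 * (seq_len(n_ligand) - 1L), z = 2.5,
        element = sample(c("C", "N", "O"), n_ligand, replace = TRUE)
      )
      prot <- dplyr::bind_rows(prot, lig)
    }
    prot
  })
  atoms <- atoms |>
    dplyr::mutate(
      serial = dplyr::row_number(),
      name = paste0(.data$element, ifelse(.data$chain == "S",
                                          seq_len(dplyr::n()), "A")),
      name = substr(.data$name, 1, 4),
      resname = ifelse(.data$chain == "S", "LIG", "ALA"),
      side = ifelse(.data$chain %in% c("R", "L", "S"), .data$chain, "other"),
      radius = assign_radius(.data$element),
      het = .data$chain == "S",
      resno = as.character(.data$resno), insert = ""
    ) |>
    dplyr::select("serial", "name", "element", "chain", "resno", "insert",
                  "resname", "x", "y", "z", "side", "radius", "het")
  manifest <- list(
    kind = "toy_complex", seed = seed, gap = gap,
    n_atoms_per_chain = n_atoms_per_chain, n_face = n_face,
    n_ligand = n_ligand,
    interface_r = residue_id("R", seq_len(n_face)),
    interface_l = residue_id("L", seq_len(n_face)),
    chain_plan = c(R = "R", L = "L", S = "S")
  )
  if (!is.null(path)) {
    write_pdb_atoms(atoms, path)
    yaml::write_yaml(manifest, paste0(path, ".manifest.yaml"))
  }
  structure(list(atoms = atoms, manifest = manifest, path = path),
            class = "toy_complex")
}

#' Generate a pocket-probe fixture with planted contact truths
#'
#' Places one pocket whose probes sit exactly on chosen atom centers so that
#' a planted number of receptor-side atoms, ligand-side atoms and stabilizer
#' atoms are in probe contact (probe radius 0.5 Angstrom; the toy complex
#' spaces atoms more than 2.2 Angstrom apart on the interface plane, so each
#' probe touches exactly its target atom). Optional decoy pockets are placed
#' far from all atoms. Planted truths are re-checked by brute force before
#' writing; a scores sidecar makes the planted pocket the best ranked.
#'
#' @param complex A `toy_complex` (see [make_toy_complex()]).
#' @param planted_coverage Target ligand coverage fraction of the planted
#'   pocket; must be a multiple of `1/n_ligand` within tolerance and <= 1.
#' @param side_counts Length-2 integer, planted R-side and L-side contact
#'   atom counts (each <= the complex's `n_face`).
#' @param n_decoys Decoy pockets with no contacts.
#' @param dir Optional directory to write `pockets.pqr`,
#'   `pocket_scores.tsv` and the manifest.
#' @return A list of class `pocket_fixture`: `probes`, `scores`, `manifest`,
#'   `dir`.
#' @export
make_pocket_fixture <- function(complex, planted_coverage = 0.75,
                                side_counts = c(5L, 4L), n_decoys = 2L,
                                dir = NULL) {
  stopifnot(inherits(complex, "toy_complex"))
  atoms <- complex$atoms
  lig <- atoms[atoms$side == "S", ]
  n_lig <- nrow(lig)
  if (planted_coverage < 0 || planted_coverage > 1) {
    stop("planted coverage must be within [0, 1]", call. = FALSE)
  }
  k_lig <- round(planted_coverage * n_lig)
  if (abs(k_lig / n_lig - planted_coverage) > 1e-9) {
    stop(sprintf("coverage %.3f not representable with %d ligand atoms",
                 planted_coverage, n_lig), call. = FALSE)
  }
  n_face <- complex$manifest$n_face
  if (any(side_counts > n_face)) {
    stop("side counts exceed the number of facing atoms", call. = FALSE)
  }
  face_r <- atoms[atoms$side == "R", ][seq_len(side_counts[1]), ]
  face_l <- atoms[atoms$side == "L", ][seq_len(side_counts[2]), ]
  targets <- dplyr::bind_rows(face_r, face_l, lig[seq_len(k_lig), ])
  probes <- tibble::tibble(
    pocket_id = "1",
    x = targets$x, y = targets$y, z = targets$z,
    radius = 0.5,
    polarity = rep_len(c("polar", "apolar"), nrow(targets))
  )
  if (n_decoys > 0) {
    decoys <- purrr::map_dfr(seq_len(n_decoys), function(d) {
      tibble::tibble(pocket_id = as.character(1L + d),
                     x = 500 + 50 * d, y = 500, z = 500,
                     radius = 1.5,
                     polarity = c("polar", "apolar", "apolar"))
    })
    probes <- dplyr::bind_rows(probes, decoys)
  }
  # brute-force self-check of every planted truth before anything is written
  p1 <- probes[probes$pocket_id == "1", ]
  stopifnot(
    sum(rowSums(contact_matrix(atoms[atoms$side == "R", ], p1)) > 0) ==
      side_counts[1],
    sum(rowSums(contact_matrix(atoms[atoms$side == "L", ], p1)) > 0) ==
      side_counts[2],
    isTRUE(all.equal(ligand_coverage(lig, p1)$fraction, planted_coverage))
  )
  scores <- tibble::tibble(
    pocket_id = as.character(seq_len(1L + n_decoys)),
    pocket_score = seq(0.9, by = -0.2, length.out = 1L + n_decoys),
    drug_score = seq(0.95, by = -0.25, length.out = 1L + n_decoys)
  )
  manifest <- list(
    kind = "pocket_fixture",
    planted_coverage = planted_coverage,
    side_counts = as.integer(side_counts),
    n_decoys = as.integer(n_decoys),
    best_pocket = "1"
  )
  if (!is.null(dir)) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    pqr <- sprintf(
      "ATOM  %5d %4s STP  %4s    %8.3f%8.3f%8.3f %6.2f %6.2f",
      seq_len(nrow(probes)),
      ifelse(probes$polarity == "polar", "O", "C"),
      probes$pocket_id, probes$x, probes$y, probes$z, 0, probes$radius
    )
    writeLines(pqr, file.path(dir, "pockets.pqr"))
    readr::write_tsv(scores, file.path(dir, "pocket_scores.tsv"),
                     progress = FALSE)
    yaml::write_yaml(manifest, file.path(dir, "pockets.manifest.yaml"))
  }
  structure(list(probes = probes, scores = scores, manifest = manifest,
                 dir = dir),
            class = "pocket_fixture")
}

#' Generate per-frame interaction-energy tables with planted statistics
#'
#' Draws Gaussian frame energies around planted per-term means, per replica,
#' mirroring an ensemble of independent simulations (default 5 replicas of
#' 75 frames). The manifest records the *realized* per-replica sample means,
#' so [aggregate_energetics()] can be checked exactly against bookkeeping
#' rather than against nominal values. With `sd = 0` the frames are
#' constant and aggregation returns the planted means exactly.
#'
#' @param truth Long tibble with columns `complex_id`, `term` (one of
#'   `ddg_rs`, `ddg_ls`, `ddg_rls`, `ddg_rl`), `mean`, `sd` (frame-level
#'   spread, >= 0).
#' @param n_replicas,n_frames Replica/frame counts.
#' @param seed Integer seed.
#' @param path Optional path for the long-format TSV (+ manifest YAML).
#' @return A list of class `energy_fixture`: `frames` (wide per-frame
#'   table), `manifest` (with `replica_means`), `path`.
#' @export
make_energy_tables <- function(truth, n_replicas = 5L, n_frames = 75L,
                               seed = 1, path = NULL) {
  truth <- tibble::as_tibble(truth)
  stopifnot(all(c("complex_id", "term", "mean", "sd") %in% names(truth)))
  if (any(truth$sd < 0)) stop("planted sds must be >= 0", call. = FALSE)
  bad <- setdiff(unique(truth$term), ENERGY_TERMS)
  if (length(bad)) {
    stop("unknown term(s) in truth: ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  long <- with_seed(seed, {
    purrr::pmap_dfr(truth, function(complex_id, term, mean, sd, ...) {
      purrr::map_dfr(seq_len(n_replicas), function(rep_i) {
        tibble::tibble(
          complex_id = complex_id,
          replica_id = paste0("rep", rep_i),
          frame = seq_len(n_frames),
          term = term,
          value = mean + stats::rnorm(n_frames, 0, sd)
        )
      })
    })
  })
  frames <- tidyr::pivot_wider(long, names_from = "term",
                               values_from = "value")
  replica_means <- long |>
    dplyr::group_by(.data$complex_id, .data$replica_id, .data$term) |>
    dplyr::summarise(mean = mean(.data$value), .groups = "drop")
  manifest <- list(
    kind = "energy_tables", seed = seed,
    n_replicas = as.integer(n_replicas), n_frames = as.integer(n_frames),
    truth = as.list(truth),
    replica_means = as.list(replica_means)
  )
  if (!is.null(path)) {
    readr::write_tsv(long, path, progress = FALSE)
    yaml::write_yaml(manifest, paste0(path, ".manifest.yaml"))
  }
  structure(list(frames = validate_energy_frames(frames),
                 manifest = manifest, path = path),
            class = "energy_fixture")
}

#' Generate a compound roster with planted screening outcomes
#'
#' Builds a descriptor roster in which exactly `n_pass_filter` compounds lie
#' inside the property-filter windows (the rest violate the weight, LogP or
#' complexity criterion in rotation), docking scores put exactly
#' `round(score_pass_fraction * n)` compounds at or below the score cutoff,
#' and the `n_candidates` best-scored compounds receive per-frame energy
#' tables of which exactly `n_dual_pass` pass the dual-binding selector.
#' Every planted count is re-verified by running the corresponding package
#' operation before the fixture is accepted.
#'
#' @param n Roster size.
#' @param n_pass_filter Planted number of property-filter survivors.
#' @param score_pass_fraction Planted fraction of compounds at or below the
#'   docking-score cutoff.
#' @param score_cutoff Docking-score cutoff used for planting, kcal/mol.
#' @param n_candidates Compounds given energy tables (the best docked among
#'   the filter survivors).
#' @param n_dual_pass Planted dual-binding passers among the candidates.
#' @param n_replicas,n_frames,frame_sd Energy-table shape and frame noise.
#' @param seed Integer seed.
#' @param dir Optional output directory (`compounds.csv`,
#'   `candidate_energies.tsv`, `roster.manifest.yaml`).
#' @return A list of class `compound_fixture`: `compounds`, `frames`,
#'   `manifest`, `dir`.
#' @export
make_compound_roster <- function(n = 1000L, n_pass_filter = 372L,
                                 score_pass_fraction = 0.75,
                                 score_cutoff = -6,
                                 n_candidates = 50L, n_dual_pass = 34L,
                                 n_replicas = 5L, n_frames = 75L,
                                 frame_sd = 1, seed = 1, dir = NULL) {
  stopifnot(n_pass_filter <= n, n_dual_pass <= n_candidates,
            n_candidates <= n_pass_filter)
  ids <- sprintf("CPD%05d", seq_len(n))
  pass <- seq_len(n) <= n_pass_filter
  compounds <- with_seed(seed, {
    mw <- ifelse(pass, stats::runif(n, 375, 425), NA_real_)
    lp <- ifelse(pass, stats::runif(n, 2, 4.5), NA_real_)
    cx <- ifelse(pass, stats::runif(n, 200, 700), NA_real_)
    fail_mode <- rep_len(c("weight", "logp", "complexity"), n)
    for (i in which(!pass)) {
      mw[i] <- if (fail_mode[i] == "weight") {
        if (i %% 2L) stats::runif(1, 200, 374) else stats::runif(1, 426, 600)
      } else stats::runif(1, 375, 425)
      lp[i] <- if (fail_mode[i] == "logp") {
        if (i %% 2L) stats::runif(1, -2, 1.9) else stats::runif(1, 4.6, 8)
      } else stats::runif(1, 2, 4.5)
      cx[i] <- if (fail_mode[i] == "complexity") {
        stats::runif(1, 701, 1200)
      } else stats::runif(1, 200, 700)
    }
    # docking scores: exact planted pass count at the cutoff
    n_good <- round(score_pass_fraction * n)
    score <- numeric(n)
    good <- with_seed(seed + 1L, sample.int(n, n_good))
    score[good] <- stats::runif(n_good, score_cutoff - 4, score_cutoff)
    score[-good] <- stats::runif(n - n_good, score_cutoff + 0.1,
                                 score_cutoff + 4)
    tibble::tibble(compound_id = ids, molecular_weight = mw, logp = lp,
                   complexity = cx, docking_score = score)
  })
  # candidates: best-docked filter survivors; plant their energetics
  survivors <- compounds[pass, ]
  cand <- survivors[order(survivors$docking_score,
                          survivors$compound_id), ][seq_len(n_candidates), ]
  dual_pass <- seq_len(n_candidates) <= n_dual_pass
  truth <- purrr::map_dfr(seq_len(n_candidates), function(i) {
    id <- cand$compound_id[i]
    if (dual_pass[i]) {
      rs <- -24 - (i %% 7); ls <- rs + 4  # weaker = ls ~ -20s, gap 4
    } else if (i %% 2L) {
      rs <- -30; ls <- -8                 # weaker side too weak
    } else {
      rs <- -40; ls <- -20                # strong both but unbalanced (20)
    }
    tibble::tibble(complex_id = id, term = c("ddg_rs", "ddg_ls"),
                   mean = c(rs, ls), sd = frame_sd)
  })
  energies <- make_energy_tables(truth, n_replicas = n_replicas,
                                 n_frames = n_frames, seed = seed + 2L)
  # brute-force verification of all planted outcomes
  filt <- property_filter(compounds)
  stopifnot(nrow(filt$kept) == n_pass_filter)
  cut <- score_cut(compounds, cutoff = score_cutoff)
  stopifnot(nrow(cut$kept) == round(score_pass_fraction * n))
  sel <- select_dual_binding(aggregate_energetics(energies$frames))
  if (nrow(sel) != n_dual_pass ||
      !setequal(sel$complex_id, cand$compound_id[dual_pass])) {
    stop("planted dual-binding outcome failed verification; ",
         "reduce `frame_sd` or widen the planted margins", call. = FALSE)
  }
  manifest <- list(
    kind = "compound_roster", seed = seed, n = as.integer(n),
    n_pass_filter = as.integer(n_pass_filter),
    score_pass_fraction = score_pass_fraction,
    score_cutoff = score_cutoff,
    n_candidates = as.integer(n_candidates),
    n_dual_pass = as.integer(n_dual_pass),
    candidate_ids = cand$compound_id,
    dual_pass_ids = cand$compound_id[dual_pass]
  )
  if (!is.null(dir)) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    readr::write_csv(compounds, file.path(dir, "compounds.csv"),
                     progress = FALSE)
    readr::write_tsv(compounds[, c("compound_id", "docking_score")],
                     file.path(dir, "docking_scores.tsv"), progress = FALSE)
    readr::write_tsv(
      tidyr::pivot_longer(energies$frames, dplyr::any_of(ENERGY_TERMS),
                          names_to = "term", values_to = "value"),
      file.path(dir, "candidate_energies.tsv"), progress = FALSE)
    yaml::write_yaml(manifest, file.path(dir, "roster.manifest.yaml"))
  }
  structure(list(compounds = compounds, frames = energies$frames,
                 manifest = manifest, dir = dir),
            class = "compound_fixture")
}
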