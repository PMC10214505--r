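# Pocket analysis: PQR-style probe files, interface-pocket criteria, ligand
# coverage fractions, druggability ranking and pocket-volume series.

#' Read a pocket probe file (PQR dialect)
#'
#' Reads pocket probes from the PQR-style format emitted by pocket-detection
#' tools: whitespace-separated `ATOM`/`HETATM` records whose residue number
#' groups probes into pockets and whose last two numeric fields are charge
#' and probe radius. Polarity is taken from the atom name: `O`/`POL` mark
#' polar probes, anything else (`C`/`APOL`) apolar. Example record:
#'
#' ```
#' ATOM      1    O STP     1      10.000  11.500   9.250    0.00  3.40
#' ```
#'
#' @param path Path to the probe file.
#' @param scores Optional path to a scores sidecar TSV with columns
#'   `pocket_id`, `pocket_score`, `drug_score` (attached as the
#'   `"scores"` attribute and available via [pocket_scores()]).
#' @return A tibble of probes: `pocket_id`, `x`, `y`, `z`, `radius`,
#'   `polarity`.
#' @export
read_pockets <- function(path, scores = NULL) {
  if (!file.exists(path)) {
    stop(sprintf("probe file '%s' does not exist", path), call. = FALSE)
  }
  lines <- readLines(path, warn = FALSE)
  lines <- lines[grepl("^(ATOM|HETATM)", lines)]
  if (!length(lines)) stop("no probe records found", call. = FALSE)
  fields <- strsplit(trimws(lines), "\\s+")
  probes <- purrr::map_dfr(fields, function(f) {
    if (length(f) < 10L) {
      stop("malformed probe record: ", paste(f, collapse = " "),
           call. = FALSE)
    }
    tibble::tibble(
      pocket_id = f[5L],
      name = f[3L],
      x = as.numeric(f[6L]), y = as.numeric(f[7L]), z = as.numeric(f[8L]),
      radius = as.numeric(f[10L])
    )
  })
  if (any(!is.finite(probes$x) | !is.finite(probes$y) |
            !is.finite(probes$z) | !is.finite(probes$radius))) {
    stop("non-numeric coordinate or radius in probe file", call. = FALSE)
  }
  if (any(probes$radius <= 0)) {
    stop("probe radii must be positive", call. = FALSE)
  }
  out <- probes |>
    dplyr::mutate(
      polarity = ifelse(toupper(.data$name) %in% c("O", "POL"),
                        "polar", "apolar")
    ) |>
    dplyr::select("pocket_id", "x", "y", "z", "radius", "polarity")
  if (!is.null(scores)) {
    attr(out, "scores") <- read_pocket_scores(scores)
  }
  out
}

#' Read a pocket scores sidecar table
#'
#' @param path TSV with columns `pocket_id`, `pocket_score`, `drug_score`
#'   (externally supplied druggability scores; never recomputed here).
#' @return A tibble.
#' @export
read_pocket_scores <- function(path) {
  out <- readr::read_tsv(path, show_col_types = FALSE, comment = "#",
                         progress = FALSE)
  need <- c("pocket_id", "pocket_score", "drug_score")
  missing <- setdiff(need, names(out))
  if (length(missing)) {
    stop("scores sidecar is missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  dplyr::mutate(out, pocket_id = as.character(.data$pocket_id))
}

#' @rdname read_pockets
#' @param probes A probe tibble returned by [read_pockets()].
#' @export
pocket_scores <- function(probes) attr(probes, "scores")

#' Interface-pocket statistics
#'
#' A pocket is an interface pocket at threshold `m` when at least `m`
#' distinct receptor atoms *and* at least `m` distinct ligand atoms are in
#' contact with its probes (contact = distance strictly below the sum of
#' atom and probe radii; atoms are counted once however many probes they
#' touch).
#'
#' @param probes Probe tibble (see [read_pockets()]).
#' @param r_atoms,l_atoms Atom tibbles for the two protein sides.
#' @param min_atoms Integer thresholds to evaluate (default 5, 10, 20).
#' @return A list: `per_pocket` (tibble `pocket_id`, `n_contact_r`,
#'   `n_contact_l`, one `pass_m<threshold>` column per threshold) and
#'   `thresholds` (tibble `min_atoms`, `n_pockets`, `any_pocket`). An empty
#'   probe table yields zero counts.
#' @export
interface_pocket_stats <- function(probes, r_atoms, l_atoms,
                                   min_atoms = c(5L, 10L, 20L)) {
  min_atoms <- sort(as.integer(min_atoms))
  if (is.null(probes) || nrow(probes) == 0L) {
    per_pocket <- tibble::tibble(pocket_id = character(),
                                 n_contact_r = integer(),
                                 n_contact_l = integer())
    for (m in min_atoms) per_pocket[[paste0("pass_m", m)]] <- logical()
    return(list(
      per_pocket = per_pocket,
      thresholds = tibble::tibble(min_atoms = min_atoms, n_pockets = 0L,
                                  any_pocket = FALSE)
    ))
  }
  per_pocket <- probes |>
    dplyr::group_by(.data$pocket_id) |>
    dplyr::group_modify(function(p, key) {
      tibble::tibble(
        n_contact_r = sum(rowSums(contact_matrix(r_atoms, p)) > 0),
        n_contact_l = sum(rowSums(contact_matrix(l_atoms, p)) > 0)
      )
    }) |>
    dplyr::ungroup()
  for (m in min_atoms) {
    per_pocket[[paste0("pass_m", m)]] <-
      per_pocket$n_contact_r >= m & per_pocket$n_contact_l >= m
  }
  thresholds <- tibble::tibble(
    min_atoms = min_atoms,
    n_pockets = vapply(min_atoms, function(m) {
      sum(per_pocket[[paste0("pass_m", m)]])
    }, integer(1))
  ) |>
    dplyr::mutate(any_pocket = .data$n_pockets > 0L)
  list(per_pocket = per_pocket, thresholds = thresholds)
}

#' Ligand coverage fraction of pockets
#'
#' Fraction of stabilizer (ligand molecule) atoms in contact with at least
#' one probe of a pocket -- the measure of how well a detected pocket
#' explains a known binding site. Every atom present in the input counts in
#' the denominator (hydrogens included when present); each atom counts once
#' however many probes it touches.
#'
#' @param ligand_atoms Non-empty atom tibble of the ligand molecule.
#' @param probes Probe tibble; may cover several pockets.
#' @return A tibble per pocket: `pocket_id`, `n_ligand`,
#'   `n_in_contact`, `fraction`, `no_probes`. With an empty probe table a
#'   single row with `fraction = 0` and `no_probes = TRUE` is returned.
#' @export
ligand_coverage <- function(ligand_atoms, probes) {
  if (is.null(ligand_atoms) || nrow(ligand_atoms) == 0L) {
    stop("ligand atom set is empty", call. = FALSE)
  }
  n_lig <- nrow(ligand_atoms)
  if (is.null(probes) || nrow(probes) == 0L) {
    return(tibble::tibble(pocket_id = NA_character_, n_ligand = n_lig,
                          n_in_contact = 0L, fraction = 0,
                          no_probes = TRUE))
  }
  probes |>
    dplyr::group_by(.data$pocket_id) |>
    dplyr::group_modify(function(p, key) {
      hit <- sum(rowSums(contact_matrix(ligand_atoms, p)) > 0)
      tibble::tibble(n_ligand = n_lig, n_in_contact = hit,
                     fraction = hit / n_lig, no_probes = FALSE)
    }) |>
    dplyr::ungroup()
}

#' Rank pockets by an external druggability score
#'
#' Orders pockets descending by the chosen score with deterministic ties
#' broken by pocket id. When a known (`truth`) pocket is designated its rank
#' is attached, supporting coverage-versus-rank benchmarking of the scoring.
#'
#' @param scores Tibble with `pocket_id` and score columns (see
#'   [read_pocket_scores()]).
#' @param by `"pocket_score"` or `"drug_score"`.
#' @param truth Optional pocket id of the known stabilizer-binding pocket.
#' @return The scores tibble sorted with a `rank` column; when `truth` is
#'   given, the truth rank is in `attr(, "truth_rank")`.
#' @export
rank_pockets <- function(scores, by = c("pocket_score", "drug_score"),
                         truth = NULL) {
  by <- match.arg(by)
  scores <- tibble::as_tibble(scores)
  if (!by %in% names(scores)) {
    stop(sprintf("score column '%s' is absent", by), call. = FALSE)
  }
  ord <- order(-scores[[by]], scores$pocket_id)
  out <- scores[ord, , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  if (!is.null(truth)) {
    attr(out, "truth_rank") <- out$rank[match(truth, out$pocket_id)]
  }
  out
}

#' Read a pocket-volume time series
#'
#' @param path TSV with columns `frame` and `volume` (Angstrom^3), optionally
#'   `pocket_id`.
#' @return A tibble.
#' @export
read_volume_series <- function(path) {
  out <- readr::read_tsv(path, show_col_types = FALSE, comment = "#",
                         progress = FALSE)
  missing <- setdiff(c("frame", "volume"), names(out))
  if (length(missing)) {
    stop("volume series is missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  out
}

#' Summarise a pocket-volume distribution
#'
#' Summarises the per-frame pocket volume and reports the fraction of frames
#' in which the pocket is at least as large as the stabilizer molecule (the
#' "can accommodate the stabilizer" fraction: transiently breathing pockets
#' can open enough to admit a ligand even when the mean volume is smaller).
#'
#' @param series Tibble with a `volume` column (Angstrom^3), one row per
#'   frame (e.g. from [read_volume_series()]).
#' @param ligand_volume Stabilizer molecular volume, Angstrom^3.
#' @return A one-row tibble: `n_frames`, `mean`, `sd`, `min`, `max`,
#'   `accommodation_fraction`.
#' @export
volume_summary <- function(series, ligand_volume) {
  series <- tibble::as_tibble(series)
  if (!"volume" %in% names(series) || nrow(series) == 0L) {
    stop("need a non-empty series with a `volume` column", call. = FALSE)
  }
  stopifnot(all(series$volume >= 0), ligand_volume >= 0)
  tibble::tibble(
    n_frames = nrow(series),
    mean = mean(series$volume),
    sd = if (nrow(series) >= 2L) stats::sd(series$volume) else 0,
    min = min(series$volume),
    max = max(series$volume),
    accommodation_fraction = mean(series$volume >= ligand_volume)
  )
}
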