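# Structure geometry: PDB/probe parsing, atomic radii, atom-probe contacts,
# interface residues, accessible/buried surface area, superposition and
# interface RMSD.

# Atomic radii (Angstrom) used for atom-probe contact tests.
ATOM_RADII <- c(H = 1.2, C = 1.7, N = 1.55, O = 1.52, F = 1.47,
                B = 1.92, P = 1.8, S = 1.8, Cl = 1.75)

#' Radius assigned to an element for contact tests
#'
#' Tabulated contact radii: H 1.2, C 1.7, N 1.55, O 1.52, F 1.47, B 1.92,
#' P 1.8, S 1.8 Angstrom. Chlorine defaults to 1.75 Angstrom; some published
#' radii tables list 0.2 Angstrom for Cl, which is physically implausible
#' (it would suppress every Cl contact) and is treated here as a typo --
#' set `cl_radius = 0.2` to reproduce that convention exactly. Unknown
#' elements receive `default` with a warning (or an error when
#' `unknown = "error"`).
#'
#' @param element Character vector of element symbols.
#' @param default Radius for unknown elements, Angstrom.
#' @param cl_radius Chlorine radius override, Angstrom.
#' @param unknown `"warn"` (default) or `"error"` for unknown elements.
#' @return Numeric radii, Angstrom.
#' @examples
#' assign_radius(c("H", "C", "Cl"))
#' @export
assign_radius <- function(element, default = 1.7, cl_radius = 1.75,
                          unknown = c("warn", "error")) {
  unknown <- match.arg(unknown)
  radii <- ATOM_RADII
  radii[["Cl"]] <- cl_radius
  element <- normalize_element(element)
  r <- unname(radii[element])
  miss <- is.na(r)
  if (any(miss)) {
    msg <- sprintf("unknown element(s) %s assigned default radius %.2f A",
                   paste(unique(element[miss]), collapse = ", "), default)
    if (unknown == "error") stop(msg, call. = FALSE)
    warning(msg, call. = FALSE)
    r[miss] <- default
  }
  r
}

normalize_element <- function(element) {
  e <- trimws(element)
  substr(e, 1, 1) <- toupper(substr(e, 1, 1))
  if (any(nchar(e) > 1)) {
    tail <- substring(e, 2)
    e <- paste0(substr(e, 1, 1), tolower(tail))
    e[e == ""] <- ""
  }
  e
}

#' Infer an element symbol from a PDB atom name
#'
#' Used when the element column of a PDB file is blank. Strips digits and
#' primes, recognises two-letter halogens (Cl, Br) and otherwise takes the
#' first letter of the stripped name (so `" CA "` is carbon, `"1HB2"` is
#' hydrogen).
#'
#' @param name Atom name(s) as they appear in PDB columns 13-16.
#' @return Character element symbols.
#' @export
infer_element <- function(name) {
  vapply(name, function(nm) {
    s <- gsub("[0-9' ]", "", nm)
    if (s == "") return("")
    two <- substr(paste0(toupper(substr(s, 1, 1)), tolower(substring(s, 2))),
                  1, 2)
    if (two %in% c("Cl", "Br")) return(two)
    toupper(substr(s, 1, 1))
  }, character(1), USE.NAMES = FALSE)
}

#' Read a structure file into a labeled atom table
#'
#' Parses a (fixed-width) PDB file and returns a tidy atom table with element
#' symbols (taken from the element column when present, else inferred from
#' the atom-name convention), contact radii and a side tag (`R` receptor,
#' `L` ligand, `S` stabilizer, `other`) assigned from a chain-to-side map.
#'
#' @param path Path to a PDB file.
#' @param side_map Named character vector mapping chain ids to side tags,
#'   e.g. `c(R = "R", L = "L", S = "S")`. Chains absent from the map are an
#'   error unless `allow_unmapped = TRUE` (tagged `"other"`).
#' @param allow_unmapped Tag unmapped chains `"other"` instead of erroring.
#' @param ... Passed to [assign_radius()].
#' @return A tibble with columns `serial`, `name`, `element`, `chain`,
#'   `resno`, `insert`, `resname`, `x`, `y`, `z`, `side`, `radius`, `het`.
#' @export
read_structure <- function(path, side_map = NULL, allow_unmapped = FALSE,
                           ...) {
  if (!file.exists(path)) {
    stop(sprintf("structure file '%s' does not exist", path), call. = FALSE)
  }
  pdb <- tryCatch(bio3d::read.pdb(path, verbose = FALSE),
                  error = function(e) {
                    stop(sprintf("cannot read '%s' as PDB: %s", path,
                                 conditionMessage(e)), call. = FALSE)
                  })
  atoms_from_bio3d(pdb, side_map = side_map,
                   allow_unmapped = allow_unmapped, ...)
}

atoms_from_bio3d <- function(pdb, side_map = NULL, allow_unmapped = FALSE,
                             ...) {
  a <- pdb$atom
  if (is.null(a) || nrow(a) == 0L) {
    stop("structure contains no atoms", call. = FALSE)
  }
  element <- a$elesy
  blank <- is.na(element) | trimws(element) == ""
  element[blank] <- infer_element(a$elety[blank])
  element <- normalize_element(element)
  chain <- as.character(a$chain)
  chain[is.na(chain)] <- " "
  side <- rep("other", nrow(a))
  if (!is.null(side_map)) {
    unmapped <- setdiff(unique(chain), names(side_map))
    if (length(unmapped) && !allow_unmapped) {
      stop("chain(s) not in side_map: ",
           paste(sprintf("'%s'", unmapped), collapse = ", "), call. = FALSE)
    }
    mapped <- chain %in% names(side_map)
    side[mapped] <- unname(side_map[chain[mapped]])
  }
  insert <- as.character(a$insert)
  insert[is.na(insert)] <- ""
  tibble::tibble(
    serial = a$eleno,
    name = a$elety,
    element = element,
    chain = chain,
    resno = paste0(a$resno, insert),
    insert = insert,
    resname = a$resid,
    x = a$x, y = a$y, z = a$z,
    side = side,
    radius = assign_radius(element, ...),
    het = a$type == "HETATM"
  )
}

coords_matrix <- function(atoms) {
  m <- as.matrix(atoms[, c("x", "y", "z")])
  if (any(!is.finite(m))) stop("non-finite coordinates", call. = FALSE)
  m
}

#' Atom-probe contact test
#'
#' An atom and a pocket probe are in contact when the Euclidean distance
#' between their centers is strictly smaller than the sum of their radii.
#' Vectorised elementwise over paired rows.
#'
#' @param atoms Atom tibble (needs `x`, `y`, `z`, `radius`).
#' @param probes Probe tibble (needs `x`, `y`, `z`, `radius`), recycled to
#'   the length of `atoms` if it has one row (and vice versa).
#' @return Logical vector.
#' @export
in_contact <- function(atoms, probes) {
  n <- max(nrow(atoms), nrow(probes))
  if (nrow(atoms) == 1L) atoms <- atoms[rep(1L, n), ]
  if (nrow(probes) == 1L) probes <- probes[rep(1L, n), ]
  stopifnot(nrow(atoms) == nrow(probes))
  d2 <- (atoms$x - probes$x)^2 + (atoms$y - probes$y)^2 +
    (atoms$z - probes$z)^2
  d2 < (atoms$radius + probes$radius)^2
}

# n_atoms x n_probes logical contact matrix (strict inequality).
contact_matrix <- function(atoms, probes) {
  am <- coords_matrix(atoms)
  pm <- coords_matrix(probes)
  d2 <- outer(rowSums(am^2), rowSums(pm^2), "+") - 2 * am %*% t(pm)
  rsum <- outer(atoms$radius, probes$radius, "+")
  d2 < rsum^2
}

#' Interface residues of a protein-protein complex
#'
#' A residue is interfacial when any of its atoms lies within `cutoff` of any
#' atom of the partner protein; the definition is applied symmetrically to
#' both sides. Distances are evaluated with a cell-list spatial grid (cell
#' edge = cutoff, 27-cell neighbourhoods), which is exactly equivalent to the
#' all-pairs double loop.
#'
#' @param r_atoms,l_atoms Atom tibbles for the two sides.
#' @param cutoff Distance cutoff in Angstrom (default 5).
#' @return A tibble with columns `side` (`"R"`/`"L"`), `chain`, `resno`,
#'   `resname`, `residue` (canonical `chain:resno` id), one row per
#'   interfacial residue.
#' @export
interface_residues <- function(r_atoms, l_atoms, cutoff = 5) {
  if (nrow(r_atoms) == 0L || nrow(l_atoms) == 0L) {
    stop("both atom sets must be non-empty", call. = FALSE)
  }
  pairs <- grid_pairs(r_atoms, l_atoms, cutoff)
  res_tab <- function(atoms, idx, side) {
    atoms[unique(idx), c("chain", "resno", "resname")] |>
      dplyr::distinct(.data$chain, .data$resno, .keep_all = TRUE) |>
      dplyr::mutate(side = side,
                    residue = residue_id(.data$chain, .data$resno),
                    .before = 1L)
  }
  dplyr::bind_rows(
    res_tab(r_atoms, pairs$i, "R"),
    res_tab(l_atoms, pairs$j, "L")
  ) |>
    dplyr::arrange(.data$side, .data$chain, .data$resno)
}

# Index pairs (i into a, j into b) with distance <= cutoff, via cell lists.
grid_pairs <- function(a, b, cutoff) {
  am <- coords_matrix(a); bm <- coords_matrix(b)
  cell <- function(m) floor(m / cutoff)
  ca <- cell(am); cb <- cell(bm)
  off <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  key <- function(m) paste(m[, 1], m[, 2], m[, 3], sep = ",")
  b_idx <- split(seq_len(nrow(bm)), key(cb))
  out_i <- integer(0); out_j <- integer(0)
  a_keys <- lapply(seq_len(27L), function(k) {
    key(sweep(ca, 2L, off[k, ], "+"))
  })
  for (i in seq_len(nrow(am))) {
    cand <- unlist(lapply(a_keys, function(kk) b_idx[[kk[i]]]),
                   use.names = FALSE)
    if (is.null(cand) || !length(cand)) next
    d2 <- (bm[cand, 1] - am[i, 1])^2 + (bm[cand, 2] - am[i, 2])^2 +
      (bm[cand, 3] - am[i, 3])^2
    hit <- cand[d2 <= cutoff^2]
    if (length(hit)) {
      out_i <- c(out_i, rep.int(i, length(hit)))
      out_j <- c(out_j, hit)
    }
  }
  list(i = out_i, j = out_j)
}

# Deterministic quasi-uniform points on the unit sphere (Fibonacci lattice).
sphere_points <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- pi * (3 - sqrt(5)) * (seq_len(n) - 1L)
  z <- 1 - 2 * i / n
  r <- sqrt(pmax(1 - z^2, 0))
  cbind(x = r * cos(phi), y = r * sin(phi), z = z)
}

#' Solvent-accessible surface area (Shrake-Rupley)
#'
#' Computes the accessible surface area of an atom set by sampling a
#' deterministic Fibonacci-lattice point set on each atom's solvent-expanded
#' sphere and counting points not buried inside any neighbouring sphere.
#' Results are bit-stable (no randomness). Hydrogens are excluded by default,
#' the usual convention for protein SASA.
#'
#' @param atoms Atom tibble with `x`, `y`, `z`, `radius` (and `element` when
#'   `include_hydrogens = FALSE`).
#' @param probe_radius Solvent probe radius, Angstrom (default 1.4, a water
#'   probe).
#' @param n_points Points per atom (>= 16; default 960).
#' @param include_hydrogens Keep hydrogen atoms in the computation.
#' @return A list: `total` (Angstrom^2) and `per_atom`, a tibble with the
#'   atoms used and their `sasa` column (summing to `total`).
#' @export
sasa <- function(atoms, probe_radius = 1.4, n_points = 960,
                 include_hydrogens = FALSE) {
  if (n_points < 16L) stop("`n_points` must be >= 16", call. = FALSE)
  if (!include_hydrogens && "element" %in% names(atoms)) {
    atoms <- atoms[atoms$element != "H", , drop = FALSE]
  }
  if (nrow(atoms) == 0L) stop("no atoms to compute SASA for", call. = FALSE)
  m <- coords_matrix(atoms)
  rad <- atoms$radius + probe_radius
  pts <- sphere_points(n_points)
  n <- nrow(m)
  area <- numeric(n)
  # neighbour prefilter: spheres that can occlude atom i
  d2all <- outer(rowSums(m^2), rowSums(m^2), "+") - 2 * m %*% t(m)
  for (i in seq_len(n)) {
    nb <- which(d2all[i, ] < (rad[i] + rad)^2 & seq_len(n) != i)
    full <- 4 * pi * rad[i]^2
    if (!length(nb)) {
      area[i] <- full
      next
    }
    p <- sweep(pts * rad[i], 2L, m[i, ], "+")
    free <- rep(TRUE, n_points)
    for (j in nb) {
      if (!any(free)) break
      dj2 <- (p[free, 1] - m[j, 1])^2 + (p[free, 2] - m[j, 2])^2 +
        (p[free, 3] - m[j, 3])^2
      free[free] <- dj2 >= rad[j]^2
    }
    area[i] <- full * sum(free) / n_points
  }
  per_atom <- dplyr::mutate(atoms, sasa = area)
  list(total = sum(area), per_atom = per_atom)
}

#' Buried surface area between each protein partner and the stabilizer
#'
#' Computes component and pairwise-complex accessible surface areas and the
#' buried surface areas \eqn{BSA_{RS} = (SASA_R + SASA_S - SASA_{RS})/2}
#' (and the LS analogue), plus the ratio \eqn{BSA_{LS}/BSA_{RS}} that gauges
#' how evenly a stabilizer contacts the two partners (ratio near 1 = even
#' dual contact; near 0 = one-sided binding).
#'
#' @param r_atoms,l_atoms,s_atoms Atom tibbles for receptor, ligand and
#'   stabilizer. The stabilizer set must be non-empty.
#' @param ... Passed to [sasa()].
#' @return A one-row tibble: `sasa_r`, `sasa_l`, `sasa_s`, `sasa_rs`,
#'   `sasa_ls`, `sasa_rls`, `bsa_rs`, `bsa_ls`, `ratio`,
#'   `ratio_undefined`.
#' @export
buried_surface <- function(r_atoms, l_atoms, s_atoms, ...) {
  if (is.null(s_atoms) || nrow(s_atoms) == 0L) {
    stop("stabilizer atom set is empty", call. = FALSE)
  }
  s_r <- sasa(r_atoms, ...)$total
  s_l <- sasa(l_atoms, ...)$total
  s_s <- sasa(s_atoms, ...)$total
  s_rs <- sasa(dplyr::bind_rows(r_atoms, s_atoms), ...)$total
  s_ls <- sasa(dplyr::bind_rows(l_atoms, s_atoms), ...)$total
  s_rls <- sasa(dplyr::bind_rows(r_atoms, l_atoms, s_atoms), ...)$total
  bsa_rs <- (s_r + s_s - s_rs) / 2
  bsa_ls <- (s_l + s_s - s_ls) / 2
  undef <- bsa_rs <= .Machine$double.eps * s_s
  tibble::tibble(
    sasa_r = s_r, sasa_l = s_l, sasa_s = s_s,
    sasa_rs = s_rs, sasa_ls = s_ls, sasa_rls = s_rls,
    bsa_rs = bsa_rs, bsa_ls = bsa_ls,
    ratio = if (undef) NA_real_ else bsa_ls / bsa_rs,
    ratio_undefined = undef
  )
}

#' Least-squares rigid-body superposition (Kabsch)
#'
#' Finds the proper rotation and translation minimising the RMSD between two
#' paired coordinate sets, via singular value decomposition of the covariance
#' matrix with the determinant correction that forbids reflections.
#'
#' @param mobile,reference n x 3 coordinate matrices (or atom tibbles with
#'   `x`, `y`, `z`), n >= 3, not collinear.
#' @return An object of class `superposition`: `rotation` (3 x 3, det +1),
#'   `translation` (length 3), `rmsd` (Angstrom) and `transformed` (the
#'   fitted mobile coordinates).
#' @export
superpose <- function(mobile, reference) {
  as_m <- function(x) if (is.matrix(x)) x else coords_matrix(x)
  X <- as_m(mobile); Y <- as_m(reference)
  if (nrow(X) != nrow(Y)) stop("coordinate sets differ in size",
                               call. = FALSE)
  if (nrow(X) < 3L) stop("need at least 3 points", call. = FALSE)
  cx <- colMeans(X); cy <- colMeans(Y)
  X0 <- sweep(X, 2L, cx); Y0 <- sweep(Y, 2L, cy)
  sv_x <- svd(X0)$d
  if (sv_x[2] <= max(sv_x[1], 1) * 1e-10) {
    stop("degenerate (collinear) coordinate set", call. = FALSE)
  }
  C <- t(X0) %*% Y0
  s <- svd(C)
  d <- sign(det(s$u %*% t(s$v)))
  R <- s$u %*% diag(c(1, 1, d)) %*% t(s$v)
  fit <- X0 %*% R
  rmsd <- sqrt(mean(rowSums((fit - Y0)^2)))
  structure(
    list(rotation = R,
         translation = as.numeric(cy - cx %*% R),
         rmsd = rmsd,
         transformed = sweep(fit, 2L, cy, "+")),
    class = "superposition"
  )
}

#' @export
print.superposition <- function(x, ...) {
  cat(sprintf("Superposition: rmsd = %.4f A\n", x$rmsd))
  invisible(x)
}

#' @rdname tidy.dose_optimum
#' @export
tidy.superposition <- function(x, ...) {
  tibble::tibble(rmsd = x$rmsd, det_rotation = det(x$rotation))
}

#' Interface RMSD series over trajectory frames
#'
#' For each frame, superposes the interface atoms onto the corresponding
#' reference interface atoms and reports the post-fit RMSD. The interface
#' residue set is determined once, on the reference. Heavy atoms are used by
#' default; `selection = "backbone"` restricts to N/CA/C/O. An optional
#' sliding-window mean (e.g. a 2 ns window given the frame spacing) smooths
#' the series.
#'
#' @param frames List of atom tibbles, each with the same atoms as
#'   `reference` in the same order.
#' @param reference Atom tibble of the starting structure.
#' @param interface Character vector of residue ids (`chain:resno`) defining
#'   the interface (e.g. from [interface_residues()]).
#' @param selection `"heavy"` (default) or `"backbone"`.
#' @param window,dt Optional sliding-window width and frame spacing (same
#'   time units); when both are given an `irmsd_smooth` column is added.
#' @return A tibble `frame`, `irmsd` (Angstrom), optionally `irmsd_smooth`.
#' @export
irmsd_series <- function(frames, reference, interface,
                         selection = c("heavy", "backbone"),
                         window = NULL, dt = NULL) {
  selection <- match.arg(selection)
  ids <- residue_id(reference$chain, reference$resno)
  sel <- ids %in% interface
  if (selection == "heavy") {
    sel <- sel & reference$element != "H"
  } else {
    sel <- sel & trimws(reference$name) %in% c("N", "CA", "C", "O")
  }
  if (!any(sel)) stop("no interface atoms selected", call. = FALSE)
  ref_m <- coords_matrix(reference[sel, ])
  vals <- purrr::imap_dbl(frames, function(fr, k) {
    if (nrow(fr) != nrow(reference)) {
      stop(sprintf("frame %s has %d atoms, reference has %d", k, nrow(fr),
                   nrow(reference)), call. = FALSE)
    }
    superpose(coords_matrix(fr[sel, ]), ref_m)$rmsd
  })
  out <- tibble::tibble(frame = seq_along(frames), irmsd = vals)
  if (!is.null(window) && !is.null(dt)) {
    k <- max(1L, round(window / dt))
    out$irmsd_smooth <- as.numeric(
      stats::filter(out$irmsd, rep(1 / k, k), sides = 2)
    )
  }
  out
}
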