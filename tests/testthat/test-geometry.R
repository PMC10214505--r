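# Structure parsing, radii, contacts, interface residues, SASA/BSA,
# superposition and interface RMSD.

hand_pdb <- function() {
  # minimal fixed-width PDB: two protein atoms (one with a blank element
  # column) and one HETATM
  lines <- c(
    "ATOM      1  N   ALA R   1       0.000   0.000   0.000  1.00  0.00           N",
    "ATOM      2  CA  ALA R   1       1.450   0.000   0.000  1.00  0.00",
    "HETATM    3  O1  LIG S   1       5.000   5.000   5.000  1.00  0.00           O"
  )
  path <- withr::local_tempfile(fileext = ".pdb",
                                .local_envir = parent.frame())
  writeLines(c(lines, "END"), path)
  path
}

test_that("structures parse with element inference, radii and side tags", {
  path <- hand_pdb()
  atoms <- read_structure(path, side_map = c(R = "R", S = "S"))
  expect_equal(nrow(atoms), 3)
  expect_equal(atoms$element, c("N", "C", "O"))  # " CA " inferred as carbon
  expect_equal(atoms$radius, c(1.55, 1.7, 1.52))
  expect_equal(atoms$side, c("R", "R", "S"))
  expect_true(atoms$het[3])
  # chain absent from side_map is an error unless explicitly allowed
  expect_error(read_structure(path, side_map = c(R = "R")), "side_map")
  expect_equal(
    read_structure(path, side_map = c(R = "R"),
                   allow_unmapped = TRUE)$side[3], "other")
  expect_error(read_structure(tempfile()), "exist")
})

test_that("radius table matches the tabulated values with a sane chlorine default", {
  expect_equal(assign_radius("H"), 1.2)
  expect_equal(assign_radius("C"), 1.7)
  expect_equal(assign_radius(c("N", "O", "F", "B", "P", "S")),
               c(1.55, 1.52, 1.47, 1.92, 1.8, 1.8))
  expect_equal(assign_radius("Cl"), 1.75)
  expect_equal(assign_radius("Cl", cl_radius = 0.2), 0.2)
  expect_warning(r <- assign_radius("X"), "unknown")
  expect_equal(r, 1.7)
  expect_error(assign_radius("X", unknown = "error"), "unknown")
})

test_that("contact rule is strict distance-below-sum-of-radii", {
  at <- function(x, r) tibble::tibble(x = x, y = 0, z = 0, radius = r)
  expect_true(in_contact(at(0, 1.2), at(0, 3)))          # coincident
  expect_false(in_contact(at(0, 1.2), at(4.3, 3)))       # 4.3 > 4.2
  expect_false(in_contact(at(0, 1.2), at(4.2, 3)))       # boundary: strict
  set.seed(3)
  a <- random_atoms(200); p <- random_probes(5)[rep(1:5, 40), ]
  got <- in_contact(a, p)
  d <- sqrt((a$x - p$x)^2 + (a$y - p$y)^2 + (a$z - p$z)^2)
  expect_equal(got, d < a$radius + p$radius)
})

test_that("interface residues match the all-pairs double loop", {
  two <- function(d) {
    list(r = tibble::tibble(chain = "R", resno = "1", resname = "ALA",
                            x = 0, y = 0, z = 0),
         l = tibble::tibble(chain = "L", resno = "9", resname = "GLY",
                            x = d, y = 0, z = 0))
  }
  near <- two(4.9)
  ir <- interface_residues(near$r, near$l)
  expect_setequal(ir$residue, c("R:1", "L:9"))
  far <- two(5.1)
  expect_equal(nrow(interface_residues(far$r, far$l)), 0)
  expect_error(interface_residues(near$r[0, ], near$l), "non-empty")

  set.seed(17)
  for (i in 1:5) {
    r <- random_atoms(100, "R", box = 25, resno = rep(1:25, 4))
    l <- random_atoms(100, "L", box = 25, resno = rep(1:25, 4))
    l$x <- l$x + runif(1, -5, 5)
    got <- interface_residues(r, l, cutoff = 5)
    want <- oracle_interface(r, l, 5)
    expect_setequal(got$residue[got$side == "R"], want$r)
    expect_setequal(got$residue[got$side == "L"], want$l)
  }
})

test_that("SASA reproduces analytic spheres and a high-density oracle", {
  one <- tibble::tibble(x = 0, y = 0, z = 0, radius = 1.7, element = "C")
  s <- sasa(one, n_points = 960)
  expect_equal(s$total, 4 * pi * (1.7 + 1.4)^2, tolerance = 0.02)
  # two far atoms: additivity, per-atom areas sum to total
  two_far <- tibble::tibble(x = c(0, 50), y = 0, z = 0, radius = 1.7,
                            element = "C")
  s2 <- sasa(two_far)
  expect_equal(s2$total, 2 * 4 * pi * 3.1^2, tolerance = 0.02)
  expect_equal(sum(s2$per_atom$sasa), s2$total)
  # overlapping pair vs a refined 10^4-point evaluation
  pair <- tibble::tibble(x = c(0, 2.5), y = 0, z = 0,
                         radius = c(1.7, 1.52), element = c("C", "O"))
  coarse <- sasa(pair, n_points = 960)$total
  fine <- sasa(pair, n_points = 10000)$total
  expect_equal(coarse, fine, tolerance = 0.01)
  expect_error(sasa(one, n_points = 8), ">= 16")
  # hydrogens excluded by default
  withH <- dplyr::bind_rows(one,
    tibble::tibble(x = 1.1, y = 0, z = 0, radius = 1.2, element = "H"))
  expect_equal(sasa(withH)$total, s$total)
  expect_gt(sasa(withH, include_hydrogens = TRUE)$total, 0)
})

test_that("adding atoms can only bury surface", {
  set.seed(29)
  base <- random_atoms(15, box = 8) |> dplyr::mutate(element = "C")
  extra <- dplyr::bind_rows(base,
    random_atoms(5, box = 8) |> dplyr::mutate(element = "C"))
  s_base <- sasa(base, n_points = 240)
  s_more <- sasa(extra, n_points = 240)
  # per-atom area of the original atoms cannot increase
  expect_true(all(s_more$per_atom$sasa[1:15] <= s_base$per_atom$sasa + 1e-9))
})

test_that("buried surface area detects one-sided and symmetric stabilizers", {
  blob <- function(cx, n = 8, chain = "R") {
    set.seed(abs(cx) + n)
    tibble::tibble(chain = chain, resno = "1", resname = "ALA",
                   element = "C", radius = 1.7,
                   x = cx + runif(n, -1.5, 1.5), y = runif(n, -1.5, 1.5),
                   z = runif(n, -1.5, 1.5))
  }
  r <- blob(-6); l <- blob(6, chain = "L")
  s_far <- blob(100, n = 4, chain = "S")
  far <- buried_surface(r, l, s_far, n_points = 240)
  expect_equal(far$bsa_rs, 0, tolerance = 1e-6)
  expect_equal(far$bsa_ls, 0, tolerance = 1e-6)
  expect_true(far$ratio_undefined)
  # stabilizer contacting only R: ratio 0
  s_r <- blob(-6, n = 4, chain = "S") |> dplyr::mutate(z = z + 2.5)
  only_r <- buried_surface(r, l, s_r, n_points = 240)
  expect_gt(only_r$bsa_rs, 0)
  expect_equal(only_r$ratio, 0, tolerance = 1e-6)
  # stabilizer exactly between two mirror-image chains: ratio ~ 1
  rm_ <- tibble::tibble(chain = "R", resno = "1", resname = "A",
                        element = "C", radius = 1.7,
                        x = c(-3, -3), y = c(-1, 1), z = 0)
  lm_ <- dplyr::mutate(rm_, chain = "L", x = -x)
  sm_ <- tibble::tibble(chain = "S", resno = "1", resname = "L",
                        element = "C", radius = 1.7, x = 0, y = 0, z = 0)
  mid <- buried_surface(rm_, lm_, sm_, n_points = 960)
  expect_equal(mid$ratio, 1, tolerance = 0.02)
  expect_error(buried_surface(r, l, s_far[0, ]), "empty")
  # invariance under a global rigid motion
  rot <- function(df) dplyr::mutate(df, x2 = y, y2 = -x) |>
    dplyr::mutate(x = x2 + 10, y = y2 - 4, z = z + 2) |>
    dplyr::select(-x2, -y2)
  moved <- buried_surface(rot(r), rot(l), rot(s_r), n_points = 240)
  expect_equal(moved$bsa_rs, only_r$bsa_rs, tolerance = 0.05)
})

test_that("Kabsch superposition recovers rigid motions and matches bio3d", {
  set.seed(31)
  X <- matrix(rnorm(30), ncol = 3)
  id <- superpose(X, X)
  expect_equal(id$rmsd, 0, tolerance = 1e-10)
  expect_equal(id$rotation, diag(3), tolerance = 1e-8)
  # pure translation
  tr <- superpose(sweep(X, 2, c(3, -2, 7), "+"), X)
  expect_equal(tr$rmsd, 0, tolerance = 1e-10)
  # rotation + translation + planted noise: rmsd matches direct formula
  th <- 0.7
  R <- matrix(c(cos(th), sin(th), 0, -sin(th), cos(th), 0, 0, 0, 1), 3)
  noise <- matrix(rnorm(30, 0, 0.1), ncol = 3)
  Y <- X %*% R + 5
  fit <- superpose(Y + noise, X)
  direct <- superpose(Y + noise, X)$transformed
  expect_equal(fit$rmsd, sqrt(mean(rowSums((direct - X)^2))),
               tolerance = 1e-10)
  expect_lt(fit$rmsd, 0.25)
  expect_equal(det(fit$rotation), 1, tolerance = 1e-10)
  # superposed rmsd never exceeds the unfitted rmsd
  expect_lte(fit$rmsd, sqrt(mean(rowSums((Y + noise - X)^2))))
  # independent cross-check against bio3d's least-squares fit
  b3d <- suppressWarnings(
    bio3d::fit.xyz(fixed = as.vector(t(X)), mobile = as.vector(t(Y))))
  b3d_rmsd <- sqrt(mean(colSums((matrix(b3d, ncol = 3, byrow = TRUE) -
                                   X)^2)))
  expect_equal(superpose(Y, X)$rmsd, b3d_rmsd, tolerance = 1e-6)
  expect_error(superpose(X[1:2, ], X[1:2, ]), "3 points")
  line <- cbind(1:5, 1:5, 1:5)
  expect_error(superpose(line, line), "collinear")
})

test_that("interface RMSD is zero under rigid motion and tracks planted drift", {
  tc <- make_toy_complex(seed = 11)
  ref <- tc$atoms
  interface <- c(tc$manifest$interface_r, tc$manifest$interface_l)
  same <- irmsd_series(list(ref, ref), ref, interface)
  expect_equal(same$irmsd, c(0, 0), tolerance = 1e-10)
  th <- 0.5
  R <- matrix(c(cos(th), 0, sin(th), 0, 1, 0, -sin(th), 0, cos(th)), 3)
  m <- as.matrix(ref[, c("x", "y", "z")]) %*% R
  rot <- dplyr::mutate(ref, x = m[, 1] + 2, y = m[, 2], z = m[, 3] - 1)
  expect_equal(irmsd_series(list(rot), ref, interface)$irmsd, 0,
               tolerance = 1e-8)
  # planted per-atom drift of the interface atoms: monotone series
  drift <- function(k) {
    fr <- ref
    sel <- paste0(fr$chain, ":", fr$resno) %in% interface
    fr$z[sel] <- fr$z[sel] + k * rep_len(c(0.3, -0.3), sum(sel))
    fr
  }
  ser <- irmsd_series(lapply(1:4, drift), ref, interface)
  expect_true(all(diff(ser$irmsd) > 0))
  # atom-count mismatch names the frame
  expect_error(irmsd_series(list(ref[-1, ]), ref, interface), "frame")
  # sliding-window smoothing
  sm <- irmsd_series(lapply(1:6, drift), ref, interface,
                     window = 2, dt = 1)
  expect_true("irmsd_smooth" %in% names(sm))
})
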