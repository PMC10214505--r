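# Independent oracles used by the tests. These deliberately avoid the
# package's internal solution paths: the equilibrium oracle scans free
# stabilizer on a dense log grid with fixed-point inner iteration and
# bisection polish; geometry oracles are direct double loops.

# Brute-force ternary equilibrium: returns species concentrations.
oracle_equilibrium <- function(k_rs, k_ls, phi, r0, l0, s0) {
  if (s0 == 0) {
    return(list(r = r0, l = l0, s = 0, rs = 0, ls = 0, rls = 0))
  }
  free_rl <- function(s) {
    r <- r0; l <- l0
    for (i in 1:200) {
      r_new <- r0 / (1 + s / k_rs + phi * s * l / (k_rs * k_ls))
      l_new <- l0 / (1 + s / k_ls + phi * s * r_new / (k_rs * k_ls))
      if (abs(r_new - r) < 1e-16 * r0 && abs(l_new - l) < 1e-16 * l0) {
        r <- r_new; l <- l_new
        break
      }
      r <- r_new; l <- l_new
    }
    list(r = r, l = l)
  }
  total_s <- function(s) {
    rl <- free_rl(s)
    s * (1 + rl$r / k_rs + rl$l / k_ls + phi * rl$r * rl$l / (k_rs * k_ls))
  }
  # dense log grid for the bracket
  grid <- s0 * 10^seq(-14, 0, length.out = 600)
  vals <- vapply(grid, total_s, numeric(1)) - s0
  i <- which(vals >= 0)[1]
  lo <- if (i > 1) grid[i - 1] else 0
  hi <- grid[i]
  for (it in 1:200) {
    mid <- (lo + hi) / 2
    if (total_s(mid) - s0 > 0) hi <- mid else lo <- mid
  }
  s <- (lo + hi) / 2
  rl <- free_rl(s)
  list(r = rl$r, l = rl$l, s = s,
       rs = rl$r * s / k_rs, ls = rl$l * s / k_ls,
       rls = phi * rl$r * rl$l * s / (k_rs * k_ls))
}

# All-pairs interface residues (double loop), returning sorted residue ids.
oracle_interface <- function(r_atoms, l_atoms, cutoff) {
  rid <- character(0); lid <- character(0)
  for (i in seq_len(nrow(r_atoms))) {
    for (j in seq_len(nrow(l_atoms))) {
      d <- sqrt((r_atoms$x[i] - l_atoms$x[j])^2 +
                  (r_atoms$y[i] - l_atoms$y[j])^2 +
                  (r_atoms$z[i] - l_atoms$z[j])^2)
      if (d <= cutoff) {
        rid <- c(rid, paste0(r_atoms$chain[i], ":", r_atoms$resno[i]))
        lid <- c(lid, paste0(l_atoms$chain[j], ":", l_atoms$resno[j]))
      }
    }
  }
  list(r = sort(unique(rid)), l = sort(unique(lid)))
}

# Random atom tibble on a box, with radii drawn from the tabulated elements.
random_atoms <- function(n, chain = "R", box = 20, resno = NULL) {
  el <- sample(c("C", "N", "O", "S", "H"), n, replace = TRUE)
  tibble::tibble(
    serial = seq_len(n),
    name = paste0(el, "X"),
    element = el,
    chain = chain,
    resno = as.character(if (is.null(resno)) seq_len(n) else resno),
    resname = "ALA",
    x = runif(n, 0, box), y = runif(n, 0, box), z = runif(n, 0, box),
    side = chain,
    radius = dualbind::assign_radius(el)
  )
}

random_probes <- function(n, pocket_id = "1", box = 20) {
  tibble::tibble(
    pocket_id = pocket_id,
    x = runif(n, 0, box), y = runif(n, 0, box), z = runif(n, 0, box),
    radius = runif(n, 0.5, 3.5),
    polarity = sample(c("polar", "apolar"), n, replace = TRUE)
  )
}

# Constant-energy frame table: one value per (complex, replica, term).
constant_frames <- function(complex_id, ddg_rs, ddg_ls, n_replicas = 5,
                            n_frames = 4) {
  tidyr::expand_grid(
    complex_id = complex_id,
    replica_id = paste0("r", seq_len(n_replicas)),
    frame = seq_len(n_frames)
  ) |>
    dplyr::mutate(ddg_rs = ddg_rs, ddg_ls = ddg_ls)
}
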