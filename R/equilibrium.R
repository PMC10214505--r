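# Ternary R + L + S binding equilibrium: exact mass-action solution, dilute
# closed form, optimal stabilizer dose, effective dissociation constant,
# titration (hook-effect) curves and binding-energy grid scans.

#' Gas constant in kcal/(mol K)
#'
#' Value used throughout for the Boltzmann relation between binding free
#' energies and dissociation constants.
#' @keywords internal
GAS_CONSTANT_KCAL <- 1.9872e-3

#' Convert a binding free energy to a dissociation constant
#'
#' Applies the Boltzmann relation \eqn{K_D = \exp(\Delta\Delta G / (RT))} with
#' the gas constant \eqn{R = 1.9872 \times 10^{-3}} kcal/(mol K). A binding
#' free energy of 0 kcal/mol maps to 1 M; more negative energies map to
#' tighter (smaller) dissociation constants.
#'
#' @param ddg Binding free energy in kcal/mol (vectorised).
#' @param temperature Absolute temperature in kelvin. Defaults to 298.15 K,
#'   the standard-state convention for reporting \eqn{K_D}.
#' @return Dissociation constant(s) in molar.
#' @seealso [kd_to_dg()] for the inverse transform.
#' @examples
#' dg_to_kd(-5)            # ~2.16e-4 M: micromolar-range binder
#' kd_to_dg(dg_to_kd(-5))  # round-trips to -5
#' @export
dg_to_kd <- function(ddg, temperature = 298.15) {
  if (!is.numeric(ddg) || any(!is.finite(ddg))) {
    stop("`ddg` must be finite numeric (kcal/mol); got non-finite value(s)",
         call. = FALSE)
  }
  stopifnot(is.numeric(temperature), temperature > 0)
  exp(ddg / (GAS_CONSTANT_KCAL * temperature))
}

#' Convert a dissociation constant to a binding free energy
#'
#' @param kd Dissociation constant in molar, > 0 (vectorised).
#' @inheritParams dg_to_kd
#' @return Binding free energy in kcal/mol.
#' @export
kd_to_dg <- function(kd, temperature = 298.15) {
  if (!is.numeric(kd) || any(!is.finite(kd)) || any(kd <= 0)) {
    stop("`kd` must be finite positive numeric (molar)", call. = FALSE)
  }
  stopifnot(is.numeric(temperature), temperature > 0)
  GAS_CONSTANT_KCAL * temperature * log(kd)
}

#' Thermodynamic parameters of one receptor/ligand/stabilizer system
#'
#' Bundles the two binary dissociation constants, the cooperativity factor and
#' the temperature that define a ternary R + L + S binding system. The
#' cooperativity factor `phi` multiplies the ternary association step (i.e. it
#' divides the dissociation constant of the RS + L and LS + R steps equally,
#' so the thermodynamic cycle closes); `phi > 1` is positive cooperativity.
#'
#' @param k_rs Dissociation constant of the receptor-stabilizer pair, molar.
#' @param k_ls Dissociation constant of the ligand-stabilizer pair, molar.
#' @param phi Dimensionless cooperativity factor, > 0. Default 1
#'   (non-cooperative).
#' @param temperature Kelvin, > 0.
#' @return An object of class `binding_parameters`.
#' @examples
#' binding_parameters(k_rs = dg_to_kd(-5), k_ls = dg_to_kd(-5))
#' @export
binding_parameters <- function(k_rs, k_ls, phi = 1, temperature = 298.15) {
  for (nm in c("k_rs", "k_ls", "phi", "temperature")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v <= 0) {
      stop(sprintf("`%s` must be a single finite positive number", nm),
           call. = FALSE)
    }
  }
  structure(
    list(k_rs = k_rs, k_ls = k_ls, phi = phi, temperature = temperature),
    class = "binding_parameters"
  )
}

#' @rdname binding_parameters
#' @param ddg_rs,ddg_ls Binding free energies in kcal/mol, converted with
#'   [dg_to_kd()] at `temperature`.
#' @export
binding_parameters_dg <- function(ddg_rs, ddg_ls, phi = 1,
                                  temperature = 298.15) {
  binding_parameters(
    k_rs = dg_to_kd(ddg_rs, temperature),
    k_ls = dg_to_kd(ddg_ls, temperature),
    phi = phi, temperature = temperature
  )
}

#' @export
print.binding_parameters <- function(x, ...) {
  cat("Ternary binding parameters\n")
  cat(sprintf("  K_RS: %.4g M (%.2f kcal/mol)\n", x$k_rs,
              kd_to_dg(x$k_rs, x$temperature)))
  cat(sprintf("  K_LS: %.4g M (%.2f kcal/mol)\n", x$k_ls,
              kd_to_dg(x$k_ls, x$temperature)))
  cat(sprintf("  phi:  %.4g   T: %.2f K\n", x$phi, x$temperature))
  invisible(x)
}

check_totals <- function(r0, l0, s0) {
  stopifnot(is.numeric(r0), length(r0) == 1L, is.finite(r0), r0 > 0,
            is.numeric(l0), length(l0) == 1L, is.finite(l0), l0 > 0,
            is.numeric(s0), all(is.finite(s0)), all(s0 >= 0))
  invisible(TRUE)
}

# Free R and L given free stabilizer s, from the pair of conservation
# equations; reduces to a quadratic in r (stable root, no cancellation).
free_rl_given_s <- function(params, r0, l0, s) {
  krs <- params$k_rs; kls <- params$k_ls; phi <- params$phi
  A <- 1 + s / krs
  B <- 1 + s / kls
  a <- phi * s / (krs * kls)
  if (a == 0) {
    return(list(r = r0 / A, l = l0 / B))
  }
  b <- A * B + a * (l0 - r0)
  disc <- sqrt(b * b + 4 * a * A * r0 * B)
  r <- if (b >= 0) 2 * r0 * B / (b + disc) else (disc - b) / (2 * a * A)
  l <- l0 / (B + a * r)
  list(r = r, l = l)
}

# Total stabilizer implied by free stabilizer s (strictly increasing in s).
total_s_given_free <- function(params, r0, l0, s) {
  rl <- free_rl_given_s(params, r0, l0, s)
  krs <- params$k_rs; kls <- params$k_ls; phi <- params$phi
  s * (1 + rl$r / krs + rl$l / kls + phi * rl$r * rl$l / (krs * kls))
}

species_from_free_s <- function(params, r0, l0, s0, s) {
  rl <- free_rl_given_s(params, r0, l0, s)
  krs <- params$k_rs; kls <- params$k_ls; phi <- params$phi
  tibble::tibble(
    s0 = s0,
    r_free = rl$r,
    l_free = rl$l,
    s_free = s,
    rs = rl$r * s / krs,
    ls = rl$l * s / kls,
    rls = phi * rl$r * rl$l * s / (krs * kls)
  )
}

#' Solve the ternary binding equilibrium exactly
#'
#' Finds the unique physical equilibrium of the coupled mass-action system
#' R + S = RS (constant `k_rs`), L + S = LS (constant `k_ls`) and the ternary
#' association step whose dissociation constant is reduced by the
#' cooperativity factor `phi`. The system is reduced to a single monotone
#' equation in the free-stabilizer concentration, bracketed on `[0, s0]` and
#' solved by safeguarded bisection with a Newton polish, so convergence is
#' guaranteed for valid inputs and no spurious roots can occur.
#'
#' @param params A [binding_parameters()] object.
#' @param r0,l0 Total receptor and ligand concentrations, molar, > 0.
#' @param s0 Total stabilizer concentration, molar, >= 0.
#' @param tol Relative tolerance on the free-stabilizer root.
#' @return A one-row tibble with columns `s0`, `r_free`, `l_free`, `s_free`,
#'   `rs`, `ls`, `rls` (all molar), satisfying mass conservation and the
#'   mass-action laws to within `tol`.
#' @examples
#' p <- binding_parameters_dg(-5, -5)
#' solve_equilibrium(p, r0 = 1e-6, l0 = 1e-6, s0 = 2e-4)
#' @export
solve_equilibrium <- function(params, r0, l0, s0, tol = 1e-12) {
  stopifnot(inherits(params, "binding_parameters"))
  check_totals(r0, l0, s0)
  stopifnot(length(s0) == 1L)
  if (s0 == 0) {
    return(tibble::tibble(s0 = 0, r_free = r0, l_free = l0, s_free = 0,
                          rs = 0, ls = 0, rls = 0))
  }
  f <- function(s) total_s_given_free(params, r0, l0, s) - s0
  # f(0) = -s0 < 0 and f(s0) >= 0: the bracket always holds.
  root <- stats::uniroot(f, lower = 0, upper = s0,
                         tol = max(s0 * tol * 1e-3, .Machine$double.xmin),
                         maxiter = 2000L)
  s <- root$root
  # One Newton polish on the monotone residual (numeric derivative).
  h <- max(s * 1e-8, s0 * 1e-14)
  dfds <- (f(s + h) - f(max(s - h, 0))) / (h + min(h, s))
  if (is.finite(dfds) && dfds > 0) {
    s_new <- s - f(s) / dfds
    if (is.finite(s_new) && s_new >= 0 && s_new <= s0) s <- s_new
  }
  out <- species_from_free_s(params, r0, l0, s0, s)
  rel_err <- abs(out$s_free + out$rs + out$ls + out$rls - s0) / s0
  if (!is.finite(rel_err) || rel_err > 1e-6) {
    stop("equilibrium solver failed to reach tolerance (relative mass error ",
         format(rel_err), ")", call. = FALSE)
  }
  out
}

#' Dilute closed form of the ternary complex concentration
#'
#' Closed-form ternary complex concentration as a function of the *free*
#' stabilizer concentration under negligible receptor/ligand depletion:
#' \deqn{[RLS] = \phi [R_0][L_0][S_f] / ((K_{RS}+[S_f])(K_{LS}+[S_f]))}
#' The curve rises with \eqn{[S_f]}, peaks at
#' \eqn{[S_f] = \sqrt{K_{RS} K_{LS}}} and falls again as the binary RS and LS
#' complexes saturate (the hook effect). Agrees with [solve_equilibrium()]
#' when `r0` and `l0` are far below both dissociation constants.
#'
#' @inheritParams solve_equilibrium
#' @param s_free Free stabilizer concentration(s), molar, >= 0 (vectorised).
#' @return Ternary complex concentration(s), molar.
#' @export
rls_dilute <- function(params, r0, l0, s_free) {
  stopifnot(inherits(params, "binding_parameters"))
  stopifnot(is.numeric(s_free), all(is.finite(s_free)), all(s_free >= 0))
  check_totals(r0, l0, 0)
  params$phi * r0 * l0 * s_free /
    ((params$k_rs + s_free) * (params$k_ls + s_free))
}

#' Optimal stabilizer dose and effective dissociation constant
#'
#' Maximises the ternary complex concentration over the total stabilizer dose
#' using golden-section search (on a log dose scale) over the exact solver,
#' and reports the effective dissociation constant
#' \eqn{K_{RL,eff} = [R_0][L_0]/[RLS^{opt}]}. In the dilute limit the free
#' stabilizer at the optimum approaches \eqn{\sqrt{K_{RS} K_{LS}}} and
#' \eqn{K_{RL,eff} \to (\sqrt{K_{RS}} + \sqrt{K_{LS}})^2 / \phi}; both limits
#' are properties of the solution, not assumptions of this routine.
#'
#' @inheritParams solve_equilibrium
#' @return An object of class `dose_optimum`: a list with `s0_opt`, `rls_opt`,
#'   `k_rl_eff` (all molar; `k_rl_eff` is `Inf` when the ternary optimum
#'   underflows), `flat` (logical flag: degenerate, essentially flat
#'   objective; the left-most maximiser is returned), and the `species` tibble
#'   at the optimum. Use [tidy()] / [glance()] for tabular forms.
#' @examples
#' p <- binding_parameters_dg(-5, -5)
#' optimal_dose(p, r0 = 1e-6, l0 = 1e-6)$k_rl_eff  # ~8.6e-4 M
#' @export
optimal_dose <- function(params, r0, l0, tol = 1e-10) {
  stopifnot(inherits(params, "binding_parameters"))
  check_totals(r0, l0, 0)
  s_geo <- sqrt(params$k_rs) * sqrt(params$k_ls)
  lo <- log10(s_geo) - 6
  hi <- log10(s_geo * 1e6 + 100 * (r0 + l0))
  obj <- function(u) solve_equilibrium(params, r0, l0, 10^u)$rls
  opt <- stats::optimize(obj, interval = c(lo, hi), maximum = TRUE, tol = tol)
  # Degenerate/flat objective: maximum indistinguishable across the bracket.
  probe <- vapply(c(lo, (lo + hi) / 2, hi), obj, numeric(1))
  flat <- isTRUE(max(opt$objective, probe) - min(probe) <=
                   .Machine$double.eps * max(abs(probe), opt$objective))
  u_opt <- if (flat) lo else opt$maximum
  if (flat) {
    warning("objective is flat over the dose bracket; returning the ",
            "left-most maximiser", call. = FALSE)
  }
  s0_opt <- 10^u_opt
  species <- solve_equilibrium(params, r0, l0, s0_opt)
  rls_opt <- species$rls
  structure(
    list(
      s0_opt = s0_opt,
      rls_opt = rls_opt,
      k_rl_eff = if (rls_opt > 0) r0 * l0 / rls_opt else Inf,
      flat = flat,
      r0 = r0, l0 = l0, params = params,
      species = species
    ),
    class = "dose_optimum"
  )
}

#' @export
print.dose_optimum <- function(x, ...) {
  cat("Optimal stabilizer dose\n")
  cat(sprintf("  s0_opt:   %.4g M\n", x$s0_opt))
  cat(sprintf("  [RLS]opt: %.4g M\n", x$rls_opt))
  cat(sprintf("  K_RL,eff: %.4g M\n", x$k_rl_eff))
  if (isTRUE(x$flat)) cat("  (flat objective: left-most maximiser)\n")
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a dose optimum
#'
#' @param x A `dose_optimum` object.
#' @param ... Unused.
#' @return A one-row tibble with the optimum dose, ternary complex
#'   concentration and effective dissociation constant.
#' @export
tidy.dose_optimum <- function(x, ...) {
  tibble::tibble(
    s0_opt = x$s0_opt, rls_opt = x$rls_opt, k_rl_eff = x$k_rl_eff,
    flat = x$flat
  )
}

#' @rdname tidy.dose_optimum
#' @export
glance.dose_optimum <- function(x, ...) {
  tibble::tibble(
    k_rl_eff = x$k_rl_eff,
    k_rs = x$params$k_rs, k_ls = x$params$k_ls, phi = x$params$phi,
    temperature = x$params$temperature, r0 = x$r0, l0 = x$l0
  )
}

#' Titration curve of the ternary system over total stabilizer
#'
#' Solves the exact equilibrium at each total-stabilizer dose of a grid and
#' returns all species concentrations. The ternary complex traces the
#' characteristic hook-effect shape: it rises with dose, peaks near the
#' optimum and falls as binary complexes saturate.
#'
#' @inheritParams solve_equilibrium
#' @param s0 Numeric vector of total stabilizer doses, molar (>= 0); emitted
#'   in input order.
#' @return A tibble of class `titration_curve` with one row per dose and the
#'   same columns as [solve_equilibrium()].
#' @examples
#' p <- binding_parameters_dg(-5, -5)
#' tc <- titration_curve(p, 1e-6, 1e-6, s0 = 10^seq(-8, -1, length.out = 25))
#' @export
titration_curve <- function(params, r0, l0, s0) {
  stopifnot(inherits(params, "binding_parameters"))
  if (length(s0) < 1L) stop("`s0` grid must be non-empty", call. = FALSE)
  check_totals(r0, l0, s0)
  out <- purrr::map_dfr(s0, function(x) solve_equilibrium(params, r0, l0, x))
  class(out) <- c("titration_curve", class(out))
  attr(out, "params") <- params
  attr(out, "r0") <- r0
  attr(out, "l0") <- l0
  out
}

#' Scan effective dissociation constants over a binding-energy grid
#'
#' Converts each (ddg_rs, ddg_ls) grid pair to dissociation constants and
#' computes the optimal-dose effective dissociation constant, reproducing the
#' theoretical landscape that links per-partner binding free energies to
#' stabilization efficiency. The surface is symmetric under swapping the two
#' axes when `r0 == l0` and improves (decreases) monotonically toward more
#' negative energies.
#'
#' @param ddg_rs,ddg_ls Strictly monotone numeric axes, kcal/mol.
#' @param r0,l0 Total concentrations, molar.
#' @param phi Cooperativity factor.
#' @param temperature Kelvin.
#' @return A long tibble of class `energy_grid_scan` with columns `ddg_rs`,
#'   `ddg_ls`, `k_rl_eff`.
#' @export
energy_grid_scan <- function(ddg_rs, ddg_ls, r0 = 1e-6, l0 = 1e-6, phi = 1,
                             temperature = 298.15) {
  check_axis <- function(x, nm) {
    if (length(x) > 1L) {
      d <- diff(x)
      if (!(all(d > 0) || all(d < 0))) {
        stop(sprintf("`%s` axis must be strictly monotone", nm), call. = FALSE)
      }
    }
  }
  check_axis(ddg_rs, "ddg_rs"); check_axis(ddg_ls, "ddg_ls")
  grid <- tidyr::expand_grid(ddg_rs = ddg_rs, ddg_ls = ddg_ls)
  grid$k_rl_eff <- purrr::map2_dbl(grid$ddg_rs, grid$ddg_ls, function(a, b) {
    p <- binding_parameters_dg(a, b, phi = phi, temperature = temperature)
    optimal_dose(p, r0, l0)$k_rl_eff
  })
  class(grid) <- c("energy_grid_scan", class(grid))
  attr(grid, "conditions") <- list(r0 = r0, l0 = l0, phi = phi,
                                   temperature = temperature)
  grid
}

#' Minimum symmetric binding free energy reaching a target affinity
#'
#' Scans symmetric per-partner binding free energies (ddg applied to both the
#' RS and LS pair) from least negative to most negative and returns the first
#' value whose optimal-dose effective dissociation constant reaches the
#' `boundary`. With the defaults (1 uM of each protein, no cooperativity,
#' 298.15 K, millimolar/micromolar boundary) this is the minimum per-partner
#' interaction strength a dual-binding stabilizer needs to pull the effective
#' protein-protein affinity into the micromolar range.
#'
#' @param ddg_grid Numeric grid of symmetric binding free energies, kcal/mol;
#'   scanned from least negative to most negative.
#' @param r0,l0 Total concentrations, molar.
#' @param phi Cooperativity factor.
#' @param temperature Kelvin.
#' @param boundary Target effective dissociation constant, molar. Default
#'   1e-3 M, the millimolar/micromolar divide.
#' @return A list of class `threshold_scan`: `threshold` (kcal/mol, `NA` when
#'   not reached), `reached` (logical), `boundary`, and `scan`, a tibble with
#'   `ddg` and `k_rl_eff` for every grid point evaluated.
#' @examples
#' threshold_scan(seq(-1, -10, by = -0.5))$threshold  # -5 kcal/mol
#' @export
threshold_scan <- function(ddg_grid = seq(-1, -10, by = -0.5), r0 = 1e-6,
                           l0 = 1e-6, phi = 1, temperature = 298.15,
                           boundary = 1e-3) {
  stopifnot(is.numeric(ddg_grid), length(ddg_grid) >= 1L,
            all(is.finite(ddg_grid)),
            is.numeric(boundary), length(boundary) == 1L, boundary > 0)
  ddg_grid <- sort(ddg_grid, decreasing = TRUE)  # least negative first
  k <- vapply(ddg_grid, function(g) {
    p <- binding_parameters_dg(g, g, phi = phi, temperature = temperature)
    optimal_dose(p, r0, l0)$k_rl_eff
  }, numeric(1))
  hit <- which(k <= boundary)
  structure(
    list(
      threshold = if (length(hit)) ddg_grid[hit[1L]] else NA_real_,
      reached = length(hit) > 0L,
      boundary = boundary,
      scan = tibble::tibble(ddg = ddg_grid, k_rl_eff = k)
    ),
    class = "threshold_scan"
  )
}

#' @export
print.threshold_scan <- function(x, ...) {
  if (x$reached) {
    cat(sprintf(
      "Minimum symmetric binding free energy: %.2f kcal/mol (K_RL,eff <= %.3g M)\n",
      x$threshold, x$boundary))
  } else {
    cat(sprintf("Boundary %.3g M not reached on the scanned grid\n",
                x$boundary))
  }
  invisible(x)
}

#' Parse a concentration string with unit suffix
#'
#' Accepts plain numbers (molar) or numbers suffixed with `M`, `mM`, `uM`
#' (or the micro-sign form), `nM`, `pM`.
#'
#' @param x Character or numeric scalar/vector.
#' @return Concentration(s) in molar.
#' @examples
#' parse_concentration("1uM")   # 1e-6
#' @export
parse_concentration <- function(x) {
  if (is.numeric(x)) return(x)
  scale <- c(M = 1, mM = 1e-3, uM = 1e-6, nM = 1e-9, pM = 1e-12)
  scale[[paste0("\u00b5", "M")]] <- 1e-6
  vapply(as.character(x), function(s) {
    s <- trimws(s)
    m <- regmatches(s, regexec("^([0-9.eE+-]+)\\s*([mun\u00b5p]?M)?$", s))[[1]]
    if (length(m) == 0L || m[2] == "") {
      stop(sprintf("cannot parse concentration '%s'", s), call. = FALSE)
    }
    val <- as.numeric(m[2])
    if (!is.finite(val)) {
      stop(sprintf("cannot parse concentration '%s'", s), call. = FALSE)
    }
    unit <- if (m[3] == "") "M" else m[3]
    val * scale[[unit]]
  }, numeric(1), USE.NAMES = FALSE)
}
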