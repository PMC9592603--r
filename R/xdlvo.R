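#' Geometry of an interacting pair
#'
#' Colloidal geometries used by the energy engine: two spheres (NP–vesicle)
#' or a sphere approaching a flat plate (vesicle–cell membrane).  Within the
#' Derjaguin approximation the geometry enters every energy term only through
#' the effective radius \eqn{R_{eff} = r_1 r_2/(r_1+r_2)} (sphere–sphere) or
#' \eqn{R_{eff} = r_1} (sphere–plate).
#'
#' @param kind `"sphere_sphere"` or `"sphere_plate"`.
#' @param radius1 Radius of the first sphere, nm.
#' @param radius2 Radius of the second sphere, nm; ignored for sphere–plate.
#' @return Object of class `geometry_pair` with an `effective_radius` field
#'   (nm).
#' @examples
#' geometry_pair("sphere_sphere", 25, 25)$effective_radius  # 12.5 nm
#' geometry_pair("sphere_plate", 25)$effective_radius       # 25 nm
#' @export
geometry_pair <- function(kind = c("sphere_sphere", "sphere_plate"),
                          radius1, radius2 = NA_real_) {
  kind <- match.arg(kind)
  if (!is.numeric(radius1) || length(radius1) != 1L || !is.finite(radius1) ||
      radius1 <= 0)
    stop("`radius1` must be a positive radius in nm", call. = FALSE)
  if (kind == "sphere_sphere") {
    if (!is.numeric(radius2) || length(radius2) != 1L || !is.finite(radius2) ||
        radius2 <= 0)
      stop("`radius2` must be a positive radius in nm for sphere_sphere",
           call. = FALSE)
    r_eff <- radius1 * radius2 / (radius1 + radius2)
  } else {
    r_eff <- radius1
  }
  structure(list(kind = kind, radius1 = as.numeric(radius1),
                 radius2 = as.numeric(radius2), effective_radius = r_eff),
            class = "geometry_pair")
}

#' Numerical parameters of the energy engine
#'
#' @param d0 Minimum contact separation, nm (default 0.157, the conventional
#'   minimum equilibrium cut-off of the van Oss framework).
#' @param lambda_ab Decay length of the acid–base interaction in water, nm
#'   (default 0.6).
#' @param d_max Upper bound of the separation grid, nm (default 25, chosen
#'   so every component is below 1 kJ/mol at the grid edge even for the
#'   largest 100 nm particles; the slowest-decaying term is the 1/d van der
#'   Waals tail).
#' @param n_grid Number of grid points (default 2000).
#' @return Object of class `xdlvo_parameters`.
#' @export
xdlvo_parameters <- function(d0 = 0.157, lambda_ab = 0.6, d_max = 25,
                             n_grid = 2000) {
  if (!is.numeric(d0) || d0 <= 0 || !is.numeric(d_max) || d_max <= d0)
    stop("need 0 < d0 < d_max", call. = FALSE)
  if (!is.numeric(lambda_ab) || lambda_ab <= 0)
    stop("`lambda_ab` must be > 0", call. = FALSE)
  if (!is.numeric(n_grid) || n_grid < 100)
    stop("`n_grid` must be >= 100", call. = FALSE)
  structure(list(d0 = as.numeric(d0), lambda_ab = as.numeric(lambda_ab),
                 d_max = as.numeric(d_max), n_grid = as.integer(n_grid)),
            class = "xdlvo_parameters")
}

#' Distance-resolved extended-DLVO interaction-energy profile
#'
#' Computes the Lifshitz–van der Waals (LW), electrostatic double-layer (EL)
#' and Lewis acid–base (AB) interaction energies of a material pair across a
#' medium on a separation grid \eqn{[d_0, d_{max}]}, in kJ per mole of
#' particle pairs.  The distance laws are the standard extended-DLVO forms in
#' the Derjaguin approximation:
#' \deqn{U^{LW}(d) = 2\pi R_{eff} d_0^2\, \Delta G^{LW}(d_0)/d}
#' \deqn{U^{AB}(d) = 2\pi R_{eff} \lambda\, \Delta G^{AB}(d_0)\,
#'   e^{(d_0-d)/\lambda}}
#' and the constant-potential Hogg–Healy–Fuerstenau double-layer energy
#' \deqn{U^{EL}(d) = \pi \varepsilon_0 \varepsilon_r R_{eff}
#'   [\,2\psi_1\psi_2 \ln\frac{1+e^{-\kappa d}}{1-e^{-\kappa d}} +
#'   (\psi_1^2+\psi_2^2)\ln(1-e^{-2\kappa d})\,].}
#' Per-particle energies (J) are converted to kJ/mol with Avogadro's number.
#'
#' @param pair [geometry_pair()].
#' @param material1,material2 [surface_chemistry()] objects; their `psi0`
#'   fields (mV) feed the EL term.
#' @param medium [medium_spec()] supplying the medium chemistry, relative
#'   permittivity and Debye length.
#' @param params [xdlvo_parameters()].
#' @return Object of class `interaction_profile`: list with `distance` (nm)
#'   and `lw`, `el`, `ab`, `total` (kJ/mol) vectors, where
#'   `total = lw + el + ab` at every grid point.
#' @examples
#' cell <- surface_chemistry("cell", 39, 2.6, 71, psi0 = -40)
#' prof <- energy_profile(geometry_pair("sphere_plate", 25),
#'                        cell, cell, medium_spec())
#' prof
#' @export
energy_profile <- function(pair, material1, material2, medium = medium_spec(),
                           params = xdlvo_parameters()) {
  stopifnot(inherits(pair, "geometry_pair"),
            inherits(params, "xdlvo_parameters"))
  if (!inherits(medium, "medium_spec"))
    stop("`medium` must be a medium_spec (the EL term needs permittivity ",
         "and Debye length)", call. = FALSE)
  d <- seq(params$d0, params$d_max, length.out = params$n_grid)

  g_lw <- contact_lw(material1, material2, medium) * .const$mJ_per_m2 # J/m^2
  g_ab <- contact_ab(material1, material2, medium) * .const$mJ_per_m2
  r_eff <- pair$effective_radius * .const$nm                          # m
  d0_m  <- params$d0 * .const$nm
  lam_m <- params$lambda_ab * .const$nm

  to_kJ_mol <- .const$avogadro / 1000

  lw <- 2 * pi * r_eff * d0_m^2 * g_lw / (d * .const$nm) * to_kJ_mol
  ab <- 2 * pi * r_eff * lam_m * g_ab * exp((params$d0 - d) / params$lambda_ab) *
    to_kJ_mol

  psi1 <- material1$psi0 / 1000  # V
  psi2 <- material2$psi0 / 1000
  if (psi1 == 0 && psi2 == 0) {
    el <- numeric(length(d))
  } else {
    kd <- d / medium$debye_length
    e1 <- exp(-kd)
    el <- pi * .const$epsilon0 * medium$relative_permittivity * r_eff *
      (2 * psi1 * psi2 * log((1 + e1) / (1 - e1)) +
         (psi1^2 + psi2^2) * log(1 - e1^2)) * to_kJ_mol
  }

  structure(list(distance = d, lw = lw, el = el, ab = ab,
                 total = lw + el + ab, pair = pair, params = params),
            class = "interaction_profile")
}

#' @export
print.interaction_profile <- function(x, ...) {
  cat(sprintf("XDLVO interaction profile (%s, R_eff = %.2f nm)\n",
              x$pair$kind, x$pair$effective_radius))
  cat(sprintf("  grid: %d points on [%.3f, %.1f] nm\n",
              length(x$distance), min(x$distance), max(x$distance)))
  i <- which.max(x$total)
  cat(sprintf("  max total = %.1f kJ/mol at d = %.3f nm (LW %.1f, EL %.1f, AB %.1f)\n",
              x$total[i], x$distance[i], x$lw[i], x$el[i], x$ab[i]))
  invisible(x)
}

#' NP–vesicle interaction energy from a profile
#'
#' The interaction energy between a nanoparticle and its transport vesicle is
#' taken as the maximum of the total energy profile over the separation grid
#' (the contact value for monotonically decaying repulsive profiles).  Ties
#' resolve to the smallest separation.
#'
#' @param profile [energy_profile()] result.
#' @return Maximum total energy, kJ/mol.
#' @export
np_vesicle_energy <- function(profile) {
  stopifnot(inherits(profile, "interaction_profile"))
  if (length(profile$total) == 0L) stop("empty profile", call. = FALSE)
  profile$total[which.max(profile$total)]
}

#' Vesicle–membrane energy-barrier height
#'
#' The barrier a vesicle must overcome to fuse with the cell membrane: the
#' maximum of the total profile, floored at zero for purely attractive
#' profiles (the activation term of the exocytosis energy change cannot be
#' negative).  Ties resolve to the smallest separation.
#'
#' @param profile [energy_profile()] result.
#' @return Barrier height in kJ/mol, with attributes `distance` (nm, barrier
#'   position; NA when no barrier) and `no_barrier` (logical).
#' @export
barrier_height <- function(profile) {
  stopifnot(inherits(profile, "interaction_profile"))
  if (length(profile$total) == 0L) stop("empty profile", call. = FALSE)
  i <- which.max(profile$total)
  if (profile$total[i] <= 0)
    structure(0, distance = NA_real_, no_barrier = TRUE)
  else
    structure(profile$total[i], distance = profile$distance[i],
              no_barrier = FALSE)
}

#' Exocytosis energy summary for one NP–cell pair
#'
#' Runs the energy engine twice — NP against its transport vesicle
#' (sphere–sphere) and vesicle against the cell membrane (sphere–plate) —
#' and combines the two into the exocytosis energy change
#' \deqn{\Delta G(d) = \Delta G^{\ddagger}_{v/m} - \Delta G_{np/v},}
#' the covariate of the Arrhenius regression.  Vesicles are assumed to share
#' the surface chemistry of the cell membrane (they fuse with it during
#' exocytosis); by default a vesicle tightly wraps a single NP, so the
#' vesicle radius equals the NP radius plus an optional membrane offset.
#'
#' @param np [surface_chemistry()] of the NP coating.
#' @param np_radius NP radius, nm.
#' @param cell [surface_chemistry()] of the cell membrane (and vesicle).
#' @param medium [medium_spec()].
#' @param params [xdlvo_parameters()].
#' @param vesicle_radius Vesicle radius, nm; default `np_radius +
#'   vesicle_offset`.
#' @param vesicle_offset Additive membrane offset, nm (default 0).
#' @param keep_profiles Keep the two profiles in the result (default FALSE).
#' @return Object of class `interaction_summary`: `dg_np_v`,
#'   `dg_barrier_v_m`, `dg_change` (all kJ/mol, with
#'   `dg_change = dg_barrier_v_m - dg_np_v` exactly), `no_barrier`,
#'   `barrier_distance`.
#' @examples
#' cell <- surface_chemistry("cell", 39, 2.6, 71, psi0 = -40)
#' np <- surface_chemistry("coating", 35, 0.5, 30)
#' interaction_summary(np, np_radius = 10, cell = cell)
#' @export
interaction_summary <- function(np, np_radius, cell, medium = medium_spec(),
                                params = xdlvo_parameters(),
                                vesicle_radius = NULL, vesicle_offset = 0,
                                keep_profiles = FALSE) {
  stopifnot(inherits(np, "surface_chemistry"),
            inherits(cell, "surface_chemistry"))
  if (is.null(vesicle_radius)) vesicle_radius <- np_radius + vesicle_offset
  p_nv <- energy_profile(geometry_pair("sphere_sphere", np_radius,
                                       vesicle_radius),
                         np, cell, medium, params)
  p_vm <- energy_profile(geometry_pair("sphere_plate", vesicle_radius),
                         cell, cell, medium, params)
  dg_np_v <- np_vesicle_energy(p_nv)
  bar <- barrier_height(p_vm)
  out <- list(dg_np_v = dg_np_v,
              dg_barrier_v_m = as.numeric(bar),
              dg_change = as.numeric(bar) - dg_np_v,
              no_barrier = attr(bar, "no_barrier"),
              barrier_distance = attr(bar, "distance"),
              np = np$name, np_radius = np_radius,
              vesicle_radius = vesicle_radius, cell = cell$name)
  if (keep_profiles) out$profiles <- list(np_vesicle = p_nv,
                                          vesicle_membrane = p_vm)
  structure(out, class = "interaction_summary")
}

#' @export
print.interaction_summary <- function(x, ...) {
  cat(sprintf("Exocytosis energetics: %s (R = %.1f nm) / %s\n",
              x$np, x$np_radius, x$cell))
  cat(sprintf("  dG_np/v       = %8.1f kJ/mol\n", x$dg_np_v))
  cat(sprintf("  dG^barrier_v/m = %7.1f kJ/mol%s\n", x$dg_barrier_v_m,
              if (isTRUE(x$no_barrier)) "  (no barrier)" else ""))
  cat(sprintf("  dG(d)         = %8.1f kJ/mol\n", x$dg_change))
  invisible(x)
}

#' Batch interaction energies for an NP property table
#'
#' Applies [interaction_summary()] to every nanoparticle of a dataset,
#' producing a table shaped like the packaged interaction-energy fixture.
#'
#' @param dataset An `np_dataset` from [read_np_table()] or
#'   [generate_np_panel()].
#' @param cell [surface_chemistry()] of the cell membrane; default the
#'   packaged generic cell surface.
#' @param medium [medium_spec()].
#' @param params [xdlvo_parameters()].
#' @param ... Passed on to [interaction_summary()] (vesicle rule).
#' @return data.frame with columns `no`, `np`, `cell`,
#'   `dg_np_v_kJ_mol`, `dg_barrier_v_m_kJ_mol`, `dg_change_kJ_mol` and
#'   `np_id`.
#' @export
energy_table <- function(dataset, cell = load_fixture("generic_cell"),
                         medium = medium_spec(), params = xdlvo_parameters(),
                         ...) {
  tab <- as.data.frame(dataset)
  rows <- lapply(seq_len(nrow(tab)), function(i) {
    chem <- surface_chemistry(tab$coating[i], tab$gamma_lw[i],
                              tab$gamma_plus[i], tab$gamma_minus[i],
                              psi0 = tab$psi0_mv[i])
    s <- interaction_summary(chem, np_radius = tab$diameter_nm[i] / 2,
                             cell = cell, medium = medium, params = params,
                             ...)
    data.frame(no = i, np = tab$coating[i], cell = tab$cell_line[i],
               dg_np_v_kJ_mol = s$dg_np_v,
               dg_barrier_v_m_kJ_mol = s$dg_barrier_v_m,
               dg_change_kJ_mol = s$dg_change,
               np_id = tab$np_id[i])
  })
  do.call(rbind, rows)
}
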