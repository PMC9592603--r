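#' Packaged fixtures
#'
#' Three fixtures ship with the package:
#' \describe{
#'   \item{`table1`}{The 64-row reference table of NP–vesicle interaction
#'     energies and vesicle–membrane barrier heights (kJ/mol) for
#'     organically coated gold NPs across six cell lines.  Rows sharing an
#'     NP/cell label but differing in energy correspond to different
#'     particle sizes and carry a `size_rank` column (1 = smallest); the
#'     underlying diameters are not part of the table.}
#'   \item{`generic_cell`}{The generic cell-surface chemistry used for all
#'     cell lines: gamma_LW 39, gamma+ 2.6, gamma- 71 mJ/m^2 (so gamma_AB
#'     ~ 27) and surface potential -40 mV.}
#'   \item{`water`}{The default aqueous physiological medium as a
#'     [medium_spec()].}
#' }
#'
#' @param name `"table1"`, `"generic_cell"` or `"water"`.
#' @return A data.frame (`table1`), [surface_chemistry()] (`generic_cell`)
#'   or [medium_spec()] (`water`).
#' @examples
#' tab <- load_fixture("table1")
#' tab[tab$no %in% c(63, 64), ]
#' @export
load_fixture <- function(name = c("table1", "generic_cell", "water")) {
  name <- match.arg(name)
  switch(name,
    table1 = {
      path <- system.file("extdata", "table1_interaction_energies.csv",
                          package = "nanoexo", mustWork = TRUE)
      tab <- utils::read.csv(path, stringsAsFactors = FALSE)
      tab$dg_change_kJ_mol <- tab$dg_barrier_v_m_kJ_mol - tab$dg_np_v_kJ_mol
      tab
    },
    generic_cell = surface_chemistry("generic cell", 39, 2.6, 71, psi0 = -40),
    water = medium_spec())
}

#' Read a cell/medium configuration from YAML
#'
#' The YAML schema (version 1) surfaces every physics default:
#' ```yaml
#' schema_version: 1
#' cell: {gamma_lw: 39, gamma_plus: 2.6, gamma_minus: 71, psi0_mv: -40}
#' medium:
#'   gamma_lw: 21.8
#'   gamma_plus: 25.5
#'   gamma_minus: 25.5
#'   relative_permittivity: 74
#'   debye_length_nm: 0.78
#'   temperature_k: 310
#' xdlvo: {d0_nm: 0.157, lambda_ab_nm: 0.6, d_max_nm: 20, n_grid: 2000}
#' vesicle_rule: {offset_nm: 0}
#' ```
#' Missing blocks fall back to these defaults.  A packaged copy lives at
#' `system.file("extdata", "generic_cell_config.yaml", package = "nanoexo")`.
#'
#' @param path YAML file path; `NULL` (default) loads the packaged generic
#'   configuration.
#' @return List with `cell` ([surface_chemistry()]), `medium`
#'   ([medium_spec()]), `params` ([xdlvo_parameters()]) and `vesicle_offset`
#'   (nm).
#' @export
read_cell_config <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "generic_cell_config.yaml",
                        package = "nanoexo", mustWork = TRUE)
  if (!file.exists(path)) stop("config not found: ", path, call. = FALSE)
  cfg <- yaml::read_yaml(path)
  pick <- function(block, key, default) {
    if (!is.null(block[[key]])) block[[key]] else default
  }
  cellb <- cfg$cell
  cell <- surface_chemistry(pick(cellb, "name", "cell"),
                            pick(cellb, "gamma_lw", 39),
                            pick(cellb, "gamma_plus", 2.6),
                            pick(cellb, "gamma_minus", 71),
                            psi0 = pick(cellb, "psi0_mv", -40))
  medb <- cfg$medium
  med_chem <- surface_chemistry(pick(medb, "name", "water"),
                                pick(medb, "gamma_lw", 21.8),
                                pick(medb, "gamma_plus", 25.5),
                                pick(medb, "gamma_minus", 25.5))
  medium <- medium_spec(med_chem,
                        relative_permittivity = pick(medb, "relative_permittivity", 74),
                        debye_length = pick(medb, "debye_length_nm", 0.78),
                        temperature = pick(medb, "temperature_k", 310))
  xb <- cfg$xdlvo
  params <- xdlvo_parameters(d0 = pick(xb, "d0_nm", 0.157),
                             lambda_ab = pick(xb, "lambda_ab_nm", 0.6),
                             d_max = pick(xb, "d_max_nm", 20),
                             n_grid = pick(xb, "n_grid", 2000))
  list(cell = cell, medium = medium, params = params,
       vesicle_offset = pick(cfg$vesicle_rule, "offset_nm", 0))
}
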