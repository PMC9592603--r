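#' Surface chemistry of one material phase
#'
#' Bundles the van Oss–Chaudhury–Good surface free-energy components of a
#' material phase — a nanoparticle coating, a cell or vesicle surface, or the
#' suspending medium — together with its surface potential.  The acid–base
#' (polar) component is derived, not stored: \eqn{\gamma^{AB} =
#' 2\sqrt{\gamma^+\gamma^-}}.
#'
#' @param name Label for the phase.
#' @param gamma_lw Lifshitz–van der Waals (apolar) component, mJ/m^2.
#' @param gamma_plus Electron-acceptor (Lewis acid) component, mJ/m^2.
#' @param gamma_minus Electron-donor (Lewis base) component, mJ/m^2.
#' @param psi0 Surface potential, mV.  0 for neutral surfaces (default).
#' @return An object of class `surface_chemistry` with fields `name`,
#'   `gamma_lw`, `gamma_plus`, `gamma_minus`, `gamma_ab` (derived) and
#'   `psi0`.
#' @examples
#' cell <- surface_chemistry("generic cell", 39, 2.6, 71, psi0 = -40)
#' cell$gamma_ab   # ~27 mJ/m^2
#' @seealso [gamma_ab()], [water_chemistry()], [medium_spec()]
#' @export
surface_chemistry <- function(name, gamma_lw, gamma_plus, gamma_minus,
                              psi0 = 0) {
  for (comp in c("gamma_lw", "gamma_plus", "gamma_minus")) {
    val <- get(comp)
    if (!is.numeric(val) || length(val) != 1L || is.na(val))
      stop("`", comp, "` must be a single numeric value", call. = FALSE)
    if (val < 0)
      stop("surface free-energy component `", comp,
           "` must be non-negative (got ", val, ")", call. = FALSE)
  }
  stopifnot(is.numeric(psi0), length(psi0) == 1L, is.finite(psi0))
  structure(
    list(name = as.character(name)[1L],
         gamma_lw = as.numeric(gamma_lw),
         gamma_plus = as.numeric(gamma_plus),
         gamma_minus = as.numeric(gamma_minus),
         gamma_ab = gamma_ab(gamma_plus, gamma_minus),
         psi0 = as.numeric(psi0)),
    class = "surface_chemistry")
}

#' @export
print.surface_chemistry <- function(x, ...) {
  cat("Surface chemistry:", x$name, "\n")
  cat(sprintf("  gamma_LW = %.2f  gamma+ = %.2f  gamma- = %.2f  (gamma_AB = %.2f) mJ/m^2\n",
              x$gamma_lw, x$gamma_plus, x$gamma_minus, x$gamma_ab))
  cat(sprintf("  psi0 = %.1f mV\n", x$psi0))
  invisible(x)
}

#' Acid–base surface free-energy component
#'
#' The van Oss combining rule for the polar (Lewis acid–base) component from
#' its electron-acceptor and electron-donor parts:
#' \eqn{\gamma^{AB} = 2\sqrt{\gamma^+ \gamma^-}}.  Symmetric in its
#' arguments and zero for any monopolar material.
#'
#' @param gamma_plus Electron-acceptor component, mJ/m^2 (>= 0).
#' @param gamma_minus Electron-donor component, mJ/m^2 (>= 0).
#' @return gamma_AB in mJ/m^2.  Vectorised.
#' @examples
#' gamma_ab(2.6, 71)    # generic cell surface, ~27 mJ/m^2
#' gamma_ab(25.5, 25.5) # water, 51 mJ/m^2
#' @export
gamma_ab <- function(gamma_plus, gamma_minus) {
  if (!is.numeric(gamma_plus) || anyNA(gamma_plus) || any(gamma_plus < 0))
    stop("`gamma_plus` must be non-negative", call. = FALSE)
  if (!is.numeric(gamma_minus) || anyNA(gamma_minus) || any(gamma_minus < 0))
    stop("`gamma_minus` must be non-negative", call. = FALSE)
  2 * sqrt(gamma_plus * gamma_minus)
}

#' Water surface chemistry (van Oss convention)
#'
#' Standard reference values \eqn{\gamma^{LW} = 21.8},
#' \eqn{\gamma^+ = \gamma^- = 25.5} mJ/m^2, so the total surface tension is
#' 72.8 mJ/m^2.
#'
#' @return A [surface_chemistry()] object for water.
#' @export
water_chemistry <- function() {
  surface_chemistry("water", 21.8, 25.5, 25.5, psi0 = 0)
}

#' Suspending-medium specification
#'
#' Couples a medium's surface chemistry with the dielectric and screening
#' parameters used by the electrostatic double-layer term.  Defaults describe
#' an aqueous physiological medium: relative permittivity 74 at 310 K and a
#' Debye length of 0.78 nm (0.154 M 1:1 electrolyte).
#'
#' @param chemistry [surface_chemistry()] of the medium (default water).
#' @param relative_permittivity Dimensionless dielectric constant.
#' @param debye_length Electrostatic screening length 1/kappa, nm.
#' @param temperature Absolute temperature, K.
#' @return Object of class `medium_spec`.
#' @export
medium_spec <- function(chemistry = water_chemistry(),
                        relative_permittivity = 74,
                        debye_length = 0.78,
                        temperature = 310) {
  stopifnot(inherits(chemistry, "surface_chemistry"))
  if (!is.numeric(debye_length) || debye_length <= 0)
    stop("`debye_length` must be > 0", call. = FALSE)
  if (!is.numeric(temperature) || temperature <= 0)
    stop("`temperature` must be > 0", call. = FALSE)
  stopifnot(is.numeric(relative_permittivity), relative_permittivity > 0)
  structure(
    list(chemistry = chemistry,
         relative_permittivity = as.numeric(relative_permittivity),
         debye_length = as.numeric(debye_length),
         temperature = as.numeric(temperature)),
    class = "medium_spec")
}

#' @export
print.medium_spec <- function(x, ...) {
  cat("Medium:", x$chemistry$name, "\n")
  cat(sprintf("  eps_r = %.1f  Debye length = %.3f nm  T = %.1f K\n",
              x$relative_permittivity, x$debye_length, x$temperature))
  invisible(x)
}

# Accept either a surface_chemistry or a medium_spec where a medium chemistry
# is needed.
.medium_chem <- function(medium) {
  if (inherits(medium, "medium_spec")) medium$chemistry
  else if (inherits(medium, "surface_chemistry")) medium
  else stop("`medium` must be a surface_chemistry or medium_spec",
            call. = FALSE)
}

#' Contact-plane Lifshitz–van der Waals free energy per unit area
#'
#' van Oss combining rule for the LW interaction free energy of two flat
#' material surfaces (1, 2) at minimum contact separation across a medium
#' (3): \deqn{\Delta G^{LW}(d_0) = 2(\sqrt{\gamma_3^{LW}} -
#' \sqrt{\gamma_1^{LW}})(\sqrt{\gamma_2^{LW}} - \sqrt{\gamma_3^{LW}}).}
#' Symmetric under swapping materials 1 and 2; zero when either material
#' matches the medium; never positive for two identical materials.
#'
#' @param material1,material2 [surface_chemistry()] objects.
#' @param medium [surface_chemistry()] or [medium_spec()].
#' @return Free energy per unit area at contact, mJ/m^2.
#' @examples
#' cell <- surface_chemistry("cell", 39, 2.6, 71)
#' contact_lw(cell, cell, water_chemistry())  # -4.97 mJ/m^2
#' @export
contact_lw <- function(material1, material2, medium) {
  stopifnot(inherits(material1, "surface_chemistry"),
            inherits(material2, "surface_chemistry"))
  m <- .medium_chem(medium)
  s1 <- sqrt(material1$gamma_lw)
  s2 <- sqrt(material2$gamma_lw)
  s3 <- sqrt(m$gamma_lw)
  2 * (s3 - s1) * (s2 - s3)
}

#' Contact-plane Lewis acid–base free energy per unit area
#'
#' van Oss dual-parameter combining rule for the polar (electron
#' acceptor/donor) interaction free energy of materials 1 and 2 at contact
#' across medium 3: \deqn{\Delta G^{AB}(d_0) = 2[\sqrt{\gamma_3^+}
#' (\sqrt{\gamma_1^-}+\sqrt{\gamma_2^-}-\sqrt{\gamma_3^-}) +
#' \sqrt{\gamma_3^-}(\sqrt{\gamma_1^+}+\sqrt{\gamma_2^+}-\sqrt{\gamma_3^+})
#' - \sqrt{\gamma_1^+\gamma_2^-} - \sqrt{\gamma_1^-\gamma_2^+}].}
#' Positive values denote hydrophilic repulsion, negative values hydrophobic
#' attraction.
#'
#' @inheritParams contact_lw
#' @return Free energy per unit area at contact, mJ/m^2.
#' @examples
#' cell <- surface_chemistry("cell", 39, 2.6, 71)
#' contact_ab(cell, cell, water_chemistry())  # +46.4 mJ/m^2, hydrophilic
#' @export
contact_ab <- function(material1, material2, medium) {
  stopifnot(inherits(material1, "surface_chemistry"),
            inherits(material2, "surface_chemistry"))
  m <- .medium_chem(medium)
  p1 <- sqrt(material1$gamma_plus); n1 <- sqrt(material1$gamma_minus)
  p2 <- sqrt(material2$gamma_plus); n2 <- sqrt(material2$gamma_minus)
  p3 <- sqrt(m$gamma_plus);         n3 <- sqrt(m$gamma_minus)
  2 * (p3 * (n1 + n2 - n3) + n3 * (p1 + p2 - p3) - p1 * n2 - n1 * p2)
}
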