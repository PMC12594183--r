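# Sedimentation-velocity post-processing: buffer standardisation of s,
# Svedberg/Stokes mass, hydrodynamic radius. CGS units internally;
# s in Svedberg (1 S = 1e-13 s), vbar in mL/g, masses in Da, R_H in nm.

.RHO_W20 <- 0.99823   # g/mL, water at 20 C
.ETA_W20 <- 1.002     # cP, water at 20 C
.N_AVOGADRO <- 6.02214076e23

#' Solvent conditions for sedimentation standardisation
#'
#' @param density g/mL.
#' @param viscosity numeric; centipoise by default. A 10% glycerol buffer is
#'   around 1.44 cP (= 0.0144 poise).
#' @param viscosity_unit "cP" or "P".
#' @param temperature °C (recorded only).
#' @return object of class `solvent_conditions` with viscosity in cP.
#' @export
solvent_conditions <- function(density, viscosity, viscosity_unit = c("cP", "P"),
                               temperature = 20) {
  viscosity_unit <- match.arg(viscosity_unit)
  if (viscosity_unit == "P") viscosity <- viscosity * 100
  stopifnot(density > 0, viscosity > 0)
  structure(list(density = density, viscosity_cP = viscosity,
                 temperature = temperature), class = "solvent_conditions")
}

#' @rdname solvent_conditions
#' @export
water_20C <- function() solvent_conditions(.RHO_W20, .ETA_W20)

#' Standardise a sedimentation coefficient to water at 20 °C
#'
#' `s20,w = s_b * (eta_b / eta_20,w) * (1 - vbar * rho_20,w) /
#' (1 - vbar * rho_b)`: the observed coefficient corrected for buffer
#' viscosity and buoyancy so species measured in different buffers are
#' comparable. A buffer equal to standard water returns the input unchanged.
#'
#' @param s_obs observed sedimentation coefficient, Svedberg.
#' @param vbar partial specific volume, mL/g.
#' @param buffer a [solvent_conditions()].
#' @param standard standard conditions (default water at 20 °C,
#'   rho 0.99823 g/mL, eta 1.002 cP).
#' @return s20,w in Svedberg.
#' @export
s_to_s20w <- function(s_obs, vbar, buffer, standard = water_20C()) {
  stopifnot(s_obs > 0, vbar > 0)
  buoy_b <- 1 - vbar * buffer$density
  if (buoy_b <= 0)
    stop("flotation: 1 - vbar * rho_buffer <= 0")
  s_obs * (buffer$viscosity_cP / standard$viscosity_cP) *
    (1 - vbar * standard$density) / buoy_b
}

#' Molar mass from a standardised sedimentation coefficient
#'
#' Combines the Svedberg equation `s = M (1 - vbar rho) / (N_A f)` with the
#' Stokes friction of the equivalent sphere, `f = (f/f0) 6 pi eta R0`,
#' `R0 = (3 M vbar / 4 pi N_A)^(1/3)`, and solves for the unique positive
#' root: `M = [s N_A^(2/3) (f/f0) 6 pi eta (3 vbar / 4 pi)^(1/3) /
#' (1 - vbar rho)]^(3/2)` at water-20 °C conditions.
#'
#' @param s20w Svedberg.
#' @param vbar mL/g.
#' @param f_over_f0 frictional ratio (>= 1); a single experimental value
#'   (e.g. 1.37) is typically applied to all species of a run.
#' @param standard solvent (default water 20 °C).
#' @return molar mass in Da.
#' @export
mass_from_s <- function(s20w, vbar, f_over_f0, standard = water_20C()) {
  stopifnot(s20w > 0, vbar > 0, f_over_f0 >= 1)
  buoy <- 1 - vbar * standard$density
  if (buoy <= 0) stop("flotation: 1 - vbar * rho <= 0")
  eta_P <- standard$viscosity_cP / 100          # poise = g/(cm s)
  m23 <- (s20w * 1e-13) * .N_AVOGADRO^(2 / 3) * f_over_f0 * 6 * pi * eta_P *
    (3 * vbar / (4 * pi))^(1 / 3) / buoy
  m23^(3 / 2)
}

#' @rdname mass_from_s
#' @param mass molar mass in Da.
#' @return `s_from_mass`: the forward map, Svedberg (internal consistency
#'   check for the inversion).
#' @export
s_from_mass <- function(mass, vbar, f_over_f0, standard = water_20C()) {
  stopifnot(mass > 0, vbar > 0, f_over_f0 >= 1)
  eta_P <- standard$viscosity_cP / 100
  r0 <- (3 * mass * vbar / (4 * pi * .N_AVOGADRO))^(1 / 3)   # cm
  f <- f_over_f0 * 6 * pi * eta_P * r0
  s <- mass * (1 - vbar * standard$density) / (.N_AVOGADRO * f)
  s / 1e-13
}

#' Hydrodynamic radius from mass, vbar and frictional ratio
#'
#' `R_H = (f/f0) * (3 M vbar / 4 pi N_A)^(1/3)`: the Stokes radius of the
#' hydrated, shaped particle.
#'
#' @inheritParams mass_from_s
#' @param mass Da.
#' @return R_H in nm.
#' @export
rh_from_mass <- function(mass, vbar, f_over_f0) {
  stopifnot(mass > 0, vbar > 0, f_over_f0 >= 1)
  f_over_f0 * (3 * mass * vbar / (4 * pi * .N_AVOGADRO))^(1 / 3) * 1e7
}

#' Hydrodynamic table for a set of sedimenting species
#'
#' Applies [s_to_s20w()], [mass_from_s()] and [rh_from_mass()] to each row,
#' mirroring the standard AUC-SV results table (species, s_w, s_w20, R_H,
#' M_w).
#'
#' @param species data.frame with columns `species`, `s_obs` (S), `vbar`
#'   (mL/g), and optionally `f_over_f0` (otherwise `f_over_f0` argument).
#' @param buffer a [solvent_conditions()].
#' @param f_over_f0 default frictional ratio applied where the table has
#'   none.
#' @return data.frame: species, s_obs, s20w (S), mass_kda, rh_nm.
#' @export
hydro_table <- function(species, buffer, f_over_f0 = 1.37) {
  ff <- if ("f_over_f0" %in% names(species)) species$f_over_f0
        else rep(f_over_f0, nrow(species))
  s20 <- mapply(s_to_s20w, species$s_obs, species$vbar,
                MoreArgs = list(buffer = buffer))
  mass <- mapply(mass_from_s, s20, species$vbar, ff)
  rh <- mapply(rh_from_mass, mass, species$vbar, ff)
  data.frame(species = species$species, s_obs = species$s_obs,
             s20w = s20, mass_kda = mass / 1e3, rh_nm = rh)
}
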