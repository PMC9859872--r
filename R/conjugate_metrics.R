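AVOGADRO <- 6.02214076e23

# supplier-nominal particle number concentrations at OD 1 (particles/ml);
# overridable per recipe
AUNP_NUMBER_CONC <- c("20" = 7.0e11, "40" = 9.0e10)

#' Nominal gold-nanoparticle number concentration at OD 1
#'
#' Built-in supplier-nominal values: 7.0e11 particles/ml for 20 nm and
#' 9.0e10 particles/ml for 40 nm particles.
#'
#' @param diameter_nm core particle diameter, nm (20 or 40 for the
#'   built-in table).
#' @return Particles per ml at OD 1.
#' @export
aunp_number_concentration <- function(diameter_nm) {
  key <- as.character(diameter_nm)
  if (!key %in% names(AUNP_NUMBER_CONC))
    stop("no built-in number concentration for ", diameter_nm,
         " nm particles; supply 'particle_number_concentration' explicitly")
  unname(AUNP_NUMBER_CONC[key])
}

#' Conjugate coupling recipe
#'
#' Volumes and concentrations defining an antibody-gold-nanoparticle
#' coupling reaction, e.g. 5 ul of 1.2 mg/ml IgG added to 1 ml of OD 1
#' 20-nm gold colloid.
#'
#' @param antibody_volume_ul antibody solution volume, ul.
#' @param antibody_concentration_mg_ml antibody concentration, mg/ml.
#' @param antibody_molar_mass molar mass of the antibody, g/mol
#'   (default 150 kDa, whole IgG).
#' @param particle_diameter_nm core particle diameter, nm.
#' @param particle_od optical density of the colloid.
#' @param particle_volume_ml colloid volume, ml.
#' @param particle_number_concentration particles/ml at OD 1; defaults to
#'   the built-in nominal table via [aunp_number_concentration()].
#' @return Object of class `conjugate_recipe`.
#' @examples
#' antibodies_per_particle(conjugate_recipe())  # 34
#' @export
conjugate_recipe <- function(antibody_volume_ul = 5,
                             antibody_concentration_mg_ml = 1.2,
                             antibody_molar_mass = 150000,
                             particle_diameter_nm = 20,
                             particle_od = 1,
                             particle_volume_ml = 1,
                             particle_number_concentration = NULL) {
  if (is.null(particle_number_concentration))
    particle_number_concentration <-
      aunp_number_concentration(particle_diameter_nm)
  vals <- c(antibody_concentration_mg_ml, antibody_molar_mass,
            particle_diameter_nm, particle_od, particle_volume_ml,
            particle_number_concentration)
  if (any(!is.finite(vals)) || any(vals <= 0) || antibody_volume_ul < 0)
    stop("recipe quantities must be positive (antibody volume >= 0)")
  structure(list(
    antibody_volume_ul = antibody_volume_ul,
    antibody_concentration_mg_ml = antibody_concentration_mg_ml,
    antibody_molar_mass = antibody_molar_mass,
    particle_diameter_nm = particle_diameter_nm,
    particle_od = particle_od,
    particle_volume_ml = particle_volume_ml,
    particle_number_concentration = particle_number_concentration
  ), class = "conjugate_recipe")
}

#' Antibodies added per gold nanoparticle
#'
#' Reaction stoichiometry of a coupling recipe: the number of antibody
#' molecules added (mass / molar mass x Avogadro) divided by the number
#' of particles in the colloid (number concentration at OD 1 x OD x
#' volume), rounded to the nearest integer. With the default recipe
#' (5 ul of 1.2 mg/ml IgG into 1 ml OD 1 of 20-nm colloid) this is 34.
#'
#' @param recipe a [conjugate_recipe()].
#' @param round round to the nearest whole antibody (default TRUE).
#' @return Integer ratio (or the exact real ratio when `round = FALSE`).
#' @export
antibodies_per_particle <- function(recipe, round = TRUE) {
  stopifnot(inherits(recipe, "conjugate_recipe"))
  ab_mass_g <- recipe$antibody_volume_ul * 1e-3 *
    recipe$antibody_concentration_mg_ml * 1e-3
  n_ab <- ab_mass_g / recipe$antibody_molar_mass * AVOGADRO
  n_np <- recipe$particle_number_concentration * recipe$particle_od *
    recipe$particle_volume_ml
  if (n_np <= 0) stop("division error: zero particle count")
  ratio <- n_ab / n_np
  if (round) round(ratio) else ratio
}

#' Antibody footprint on the particle surface
#'
#' Projected area one IgG occupies on the gold surface; default
#' 14.5 x 8.5 nm^2.
#'
#' @param length_nm,width_nm footprint edge lengths, nm.
#' @return Object of class `antibody_footprint` with `length_nm`,
#'   `width_nm`, `area_nm2`.
#' @export
antibody_footprint <- function(length_nm = 14.5, width_nm = 8.5) {
  if (length_nm <= 0 || width_nm <= 0) stop("footprint edges must be > 0")
  structure(list(length_nm = length_nm, width_nm = width_nm,
                 area_nm2 = length_nm * width_nm),
            class = "antibody_footprint")
}

#' Monolayer capacity of a spherical particle
#'
#' Number of whole antibodies that fit as a monolayer on the bare core
#' sphere: `floor(pi * d^2 / footprint area)`. The floor reflects that a
#' fractional antibody cannot bind; the bare core diameter (not the
#' hydrodynamic diameter) is used. 20 nm cores accommodate 10 IgG, 40 nm
#' cores 40, with the default footprint.
#'
#' @param particle_diameter_nm bare core diameter, nm; > 0.
#' @param footprint an [antibody_footprint()].
#' @return Integer capacity.
#' @export
monolayer_capacity <- function(particle_diameter_nm,
                               footprint = antibody_footprint()) {
  if (particle_diameter_nm <= 0) stop("'particle_diameter_nm' must be > 0")
  stopifnot(inherits(footprint, "antibody_footprint"))
  floor(pi * particle_diameter_nm^2 / footprint$area_nm2)
}

#' Excess of added antibodies over the monolayer capacity
#'
#' Ratio of antibodies added per particle ([antibodies_per_particle()])
#' to the monolayer capacity ([monolayer_capacity()]); values above 1
#' indicate a saturating excess, values below 1 a sub-saturating load.
#'
#' @param recipe a [conjugate_recipe()].
#' @param footprint an [antibody_footprint()].
#' @return Real excess factor.
#' @export
excess_factor <- function(recipe, footprint = antibody_footprint()) {
  cap <- monolayer_capacity(recipe$particle_diameter_nm, footprint)
  if (cap <= 0) stop("monolayer capacity must be > 0")
  antibodies_per_particle(recipe) / cap
}

#' Wavelength and height of the absorbance maximum
#'
#' Global maximum of a spectrum; ties resolved towards the lower
#' wavelength. A maximum on the grid boundary of a monotone spectrum is
#' reported with a warning (the true peak lies outside the window), as is
#' a flat spectrum.
#'
#' @param spectrum data frame with columns `wavelength_nm`, `absorbance`.
#' @return List `wavelength_nm`, `absorbance`.
#' @export
lambda_max <- function(spectrum) {
  stopifnot(is.data.frame(spectrum), nrow(spectrum) > 0,
            all(c("wavelength_nm", "absorbance") %in% names(spectrum)))
  ab <- spectrum$absorbance
  if (diff(range(ab)) == 0)
    warning("degenerate spectrum: flat absorbance")
  i <- which.max(ab)  # first index = lowest wavelength on ties
  if (i == 1L || i == nrow(spectrum))
    if (diff(range(ab)) > 0)
      warning("maximum at the edge of the acquisition window")
  list(wavelength_nm = spectrum$wavelength_nm[i], absorbance = ab[i])
}

#' Conjugate synthesis yield from UV-Vis maxima
#'
#' Fraction of nanoparticles surviving the synthesis, estimated as the
#' ratio of the final to the initial peak optical density (absorbance is
#' proportional to particle concentration at fixed size).
#'
#' @param initial,final spectra (data frames `wavelength_nm`,
#'   `absorbance`).
#' @return Yield fraction.
#' @export
synthesis_yield <- function(initial, final) {
  od0 <- suppressWarnings(lambda_max(initial)$absorbance)
  od1 <- suppressWarnings(lambda_max(final)$absorbance)
  if (od0 <= 0) stop("division error: initial spectrum has zero peak OD")
  od1 / od0
}

# FWHM by linear interpolation at half maximum; NA if not bracketed
spectrum_fwhm <- function(spectrum) {
  wl <- spectrum$wavelength_nm; ab <- spectrum$absorbance
  i <- which.max(ab)
  half <- ab[i] / 2
  cross <- function(idx_range) {
    a <- ab[idx_range]; w <- wl[idx_range]
    below <- which(a < half)
    if (length(below) == 0L) return(NA_real_)
    # nearest crossing towards the peak
    if (idx_range[1L] < i) {       # left flank: last below before peak
      j <- max(below)
      if (j == length(a)) return(NA_real_)
      w[j] + (half - a[j]) / (a[j + 1L] - a[j]) * (w[j + 1L] - w[j])
    } else {                       # right flank: first below after peak
      j <- min(below)
      if (j == 1L) return(NA_real_)
      w[j - 1L] + (half - a[j - 1L]) / (a[j] - a[j - 1L]) * (w[j] - w[j - 1L])
    }
  }
  left <- if (i > 1L) cross(1L:(i - 1L)) else NA_real_
  right <- if (i < length(ab)) cross((i + 1L):length(ab)) else NA_real_
  if (is.na(left) || is.na(right)) {
    warning("width undefined: half maximum not bracketed in the window")
    return(NA_real_)
  }
  right - left
}

#' Plasmon peak shift and width change between two spectra
#'
#' Reports the red-shift of the absorbance maximum of a conjugate
#' relative to the bare particle, and the change in full width at half
#' maximum (linear interpolation between grid points). Protein coating
#' red-shifts and broadens the plasmon band.
#'
#' @param bare,conjugate spectra (data frames `wavelength_nm`,
#'   `absorbance`).
#' @return List `shift_nm`, `fwhm_bare_nm`, `fwhm_conjugate_nm`,
#'   `widening_nm`.
#' @export
peak_shift_and_width <- function(bare, conjugate) {
  shift <- lambda_max(conjugate)$wavelength_nm -
    lambda_max(bare)$wavelength_nm
  f0 <- spectrum_fwhm(bare)
  f1 <- spectrum_fwhm(conjugate)
  list(shift_nm = shift, fwhm_bare_nm = f0, fwhm_conjugate_nm = f1,
       widening_nm = f1 - f0)
}

#' Adsorbed-layer thickness from hydrodynamic diameters
#'
#' Half the difference between the conjugate and core hydrodynamic
#' diameters: a 42 nm conjugate on a 22 nm core corresponds to a 10 nm
#' protein layer.
#'
#' @param conjugate_diameter_nm,core_diameter_nm hydrodynamic diameters,
#'   nm; the conjugate must not be smaller than the core.
#' @return Layer thickness, nm.
#' @export
layer_thickness <- function(conjugate_diameter_nm, core_diameter_nm) {
  if (conjugate_diameter_nm < core_diameter_nm)
    stop("ordering error: conjugate diameter below core diameter")
  (conjugate_diameter_nm - core_diameter_nm) / 2
}

#' Number-mean diameter of the main peak of a size distribution
#'
#' Weight-averaged diameter over the main peak only, where the main peak
#' is the contiguous run of bins above 5% of the modal weight carrying
#' the largest total weight. Small agglomerate shoulders are thereby
#' excluded, mirroring how DLS number distributions are read.
#'
#' @param dist data frame with columns `diameter_nm`, `weight`.
#' @param peak_floor fraction of the modal weight below which bins do not
#'   belong to a peak (default 0.05).
#' @return Number-mean diameter, nm.
#' @export
number_mean_diameter <- function(dist, peak_floor = 0.05) {
  stopifnot(is.data.frame(dist),
            all(c("diameter_nm", "weight") %in% names(dist)))
  d <- dist$diameter_nm; w <- dist$weight
  if (length(d) == 0L || sum(w) <= 0)
    stop("domain error: empty size distribution")
  w <- w / sum(w)
  above <- w >= peak_floor * max(w)
  runs <- rle(above)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  keep <- which(runs$values)
  totals <- vapply(keep, function(k) sum(w[starts[k]:ends[k]]), 0)
  main <- keep[which.max(totals)]
  i <- starts[main]:ends[main]
  sum(d[i] * w[i]) / sum(w[i])
}
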