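# Composable scattering models and sample phantoms.  Scattering is treated
# as elastic: the cross-section profile S depends on q alone, not separately
# on energy; the smooth background term absorbs inelastic contributions.

#' Scattering-model components
#'
#' A scattering model is a sum of non-negative components evaluated on the
#' momentum-transfer axis:
#' * `bragg_peak(center, width, amplitude)` — Gaussian Bragg reflection
#'   (`width` is the Gaussian sigma, nm^-1);
#' * `broad_peak(center, width, amplitude)` — same functional form, used for
#'   broad diffuse maxima such as the lipid signal near 13 nm^-1;
#' * `power_law_background(amplitude, slope, offset)` — smooth falling
#'   background `amplitude * (q + offset)^-slope`; the soft offset
#'   (default 0.5 nm^-1) keeps the model finite at q = 0.
#'
#' @param center Peak position, nm^-1.
#' @param width Gaussian sigma, nm^-1.
#' @param amplitude Non-negative relative intensity.
#' @param slope Power-law exponent (> 0 falls with q).
#' @param offset Soft offset, nm^-1.
#' @return A component list with a `kind` field.
#' @name scattering_components
NULL

#' @rdname scattering_components
#' @export
bragg_peak <- function(center, width = 1.0, amplitude = 1.0) {
  stopifnot(center > 0, width > 0, amplitude >= 0)
  list(kind = "bragg-peak", center = center, width = width, amplitude = amplitude)
}

#' @rdname scattering_components
#' @export
broad_peak <- function(center, width = 3.0, amplitude = 1.0) {
  c2 <- bragg_peak(center, width, amplitude)
  c2$kind <- "broad-peak"
  c2
}

#' @rdname scattering_components
#' @export
power_law_background <- function(amplitude, slope = 1.5, offset = 0.5) {
  stopifnot(amplitude >= 0, offset > 0)
  list(kind = "power-law-background", amplitude = amplitude, slope = slope,
       offset = offset)
}

#' Build a scattering model from components
#'
#' @param components List of components from [bragg_peak()], [broad_peak()]
#'   or [power_law_background()].
#' @return An object of class `scattering_model`.
#' @export
scattering_model <- function(components) {
  stopifnot(is.list(components))
  kinds <- vapply(components, function(cc) cc$kind, "")
  ok <- kinds %in% c("bragg-peak", "broad-peak", "power-law-background")
  if (!all(ok)) stop("unknown scattering component kind: ", kinds[!ok][1])
  structure(list(components = components), class = "scattering_model")
}

#' Evaluate a scattering model S(q)
#'
#' @param model A [scattering_model()] (or a phantom, whose model is used).
#' @param q Momentum transfer, nm^-1 (vector); must be >= 0.
#' @return S(q), non-negative, same length as `q`.
#' @export
s_of_q <- function(model, q) {
  if (inherits(model, "phantom")) model <- model$scattering_model
  stopifnot(inherits(model, "scattering_model"), all(q >= 0))
  s <- numeric(length(q))
  for (cc in model$components) {
    s <- s + switch(cc$kind,
      "bragg-peak" = ,
      "broad-peak" = cc$amplitude * exp(-0.5 * ((q - cc$center) / cc$width)^2),
      "power-law-background" = cc$amplitude * (q + cc$offset)^(-cc$slope)
    )
  }
  s
}

#' Sample phantom: scattering model + thickness + attenuation
#'
#' Attenuation is a single effective linear coefficient with a power-law
#' energy dependence typical of soft materials in the 30-45 keV band:
#' `mu(E) = mu_30 * (E / 30)^-mu_exponent` in mm^-1 with E in keV.
#'
#' @param scattering_model A [scattering_model()].
#' @param thickness Sample thickness along the beam, mm.
#' @param mu_30 Linear attenuation coefficient at 30 keV, mm^-1.
#' @param mu_exponent Power-law exponent of the energy dependence.
#' @param plaque_density Dimensionless amyloid burden scalar (>= 0).
#' @param id Character label carried into stack metadata.
#' @param density_mg_cm3 Optional material packing density metadata.
#' @return An object of class `phantom`.
#' @export
phantom <- function(scattering_model, thickness, mu_30 = 0.037,
                    mu_exponent = 1.0, plaque_density = 0,
                    id = "phantom", density_mg_cm3 = NA_real_) {
  stopifnot(inherits(scattering_model, "scattering_model"))
  if (thickness <= 0) stop("thickness must be positive")
  if (mu_30 < 0) stop("attenuation must be non-negative")
  if (plaque_density < 0) stop("plaque_density must be non-negative")
  structure(list(scattering_model = scattering_model, thickness = thickness,
                 mu_30 = mu_30, mu_exponent = mu_exponent,
                 plaque_density = plaque_density, id = id,
                 density_mg_cm3 = density_mg_cm3),
            class = "phantom")
}

#' Attenuation coefficient of a phantom at given energies
#'
#' @param ph A [phantom()].
#' @param energy Energies in keV.
#' @return mu(E) in mm^-1.
#' @export
attenuation <- function(ph, energy) {
  stopifnot(inherits(ph, "phantom"), all(energy > 0))
  ph$mu_30 * (energy / 30)^(-ph$mu_exponent)
}

#' BSA amyloid phantom
#'
#' Packed bovine serum albumin powder is a standard amyloid surrogate: its
#' cross-beta sheet structure produces two Bragg reflections, the
#' inter-sheet peak at 6.04 nm^-1 and a broad inter-strand peak at
#' 13.24 nm^-1, on a smooth falling background.  The default phantom models
#' a 6.4-mm column of powder packed to 758 mg/cm^3.
#'
#' @param thickness Powder column thickness, mm.
#' @return A [phantom()] whose S(q) has local maxima at 6.04 and
#'   13.24 nm^-1.
#' @export
make_bsa_phantom <- function(thickness = 6.4) {
  model <- scattering_model(list(
    bragg_peak(center = 6.04, width = 1.0, amplitude = 1.0),
    broad_peak(center = 13.24, width = 3.0, amplitude = 0.8),
    power_law_background(amplitude = 0.8, slope = 1.5)
  ))
  phantom(model, thickness = thickness, mu_30 = 0.027, mu_exponent = 1.0,
          plaque_density = 1, id = "bsa", density_mg_cm3 = 758)
}

# background components shared by all brain phantoms (tissue + lipid)
.brain_background_components <- function() {
  list(
    power_law_background(amplitude = 2.0, slope = 1.3),
    broad_peak(center = 13.2, width = 3.0, amplitude = 0.6)
  )
}

# amplitude k of the 6.04 nm^-1 component per unit plaque density, chosen so
# that density 1 adds exactly 15% to the background area under the
# 3.6-8.4 nm^-1 window (the largest excess observed over wild type).
.brain_peak_coupling <- function(window = c(3.6, 8.4), center = 6.04,
                                 width = 1.0, excess = 0.15) {
  bg <- scattering_model(.brain_background_components())
  aup_bg <- stats::integrate(function(q) s_of_q(bg, q),
                             window[1], window[2])$value
  gauss_int <- width * sqrt(2 * pi) *
    (stats::pnorm((window[2] - center) / width) -
     stats::pnorm((window[1] - center) / width))
  excess * aup_bg / gauss_int
}

#' Brain-tissue phantom with adjustable amyloid plaque density
#'
#' Tissue background (power-law plus a broad lipid maximum near 13 nm^-1)
#' with a cross-beta Bragg component at 6.04 nm^-1 whose amplitude scales
#' linearly with `plaque_density`.  The coupling constant is fixed so that
#' `plaque_density = 1` yields a 15% excess of the 3.6-8.4 nm^-1 area over
#' the plaque-free (wild-type) background — the anchor for the burden scale.
#'
#' @param plaque_density Dimensionless burden scalar (>= 0); 0 gives a
#'   wild-type phantom with no 6.04 nm^-1 component.
#' @param thickness Tissue path length, mm (head diameter scale).
#' @return A [phantom()].
#' @export
make_brain_phantom <- function(plaque_density, thickness = 10) {
  if (plaque_density < 0) stop("plaque_density must be non-negative")
  comps <- .brain_background_components()
  if (plaque_density > 0) {
    k <- .brain_peak_coupling()
    comps <- c(comps, list(bragg_peak(center = 6.04, width = 1.0,
                                      amplitude = k * plaque_density)))
  }
  phantom(scattering_model(comps), thickness = thickness, mu_30 = 0.037,
          mu_exponent = 1.0, plaque_density = plaque_density,
          id = sprintf("brain_d%.4g", plaque_density))
}
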