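#' Bending strain of a thin film in a bent sheet
#'
#' Strain in a thin conductive film embedded in an elastomer sheet bent to
#' radius `BR` is `d_N / BR`, where `d_N` is the (signed) distance of the film
#' from the neutral plane of the sheet. Negative values denote compression.
#'
#' @param d_N Distance of the film from the neutral plane (um). Signed:
#'   films on the concave side of the bend are in compression.
#' @param BR Bending radius (um). Must be positive.
#' @return Dimensionless strain (same sign as `d_N`).
#' @examples
#' bending_strain(d_N = 2.5, BR = 250)  # 0.01
#' @export
bending_strain <- function(d_N, BR) {
  if (any(!is.finite(BR)) || any(BR <= 0)) {
    stop("bending radius 'BR' must be positive and finite", call. = FALSE)
  }
  d_N / BR
}

#' Layer stack of a bi-layer stretchable electrode array
#'
#' Describes an elastomer membrane with two thin metal layers: a substrate,
#' metal layer L1, a first encapsulation, metal layer L2, and a second
#' encapsulation. Metal layers are treated as zero-thickness markers; the
#' defaults are a 45 um substrate and two 30 um encapsulations.
#'
#' @param substrate,encap1,encap2 Polymer layer thicknesses (um), all > 0.
#' @return An object of class `layer_stack` with elements `thicknesses`,
#'   `metal_positions` (distance of L1 and L2 from the stack bottom, um) and
#'   `total` (um).
#' @export
layer_stack <- function(substrate = 45, encap1 = 30, encap2 = 30) {
  th <- c(substrate = substrate, encap1 = encap1, encap2 = encap2)
  if (any(!is.finite(th)) || any(th <= 0)) {
    stop("all polymer layer thicknesses must be positive", call. = FALSE)
  }
  structure(
    list(
      thicknesses = th,
      metal_positions = c(L1 = unname(substrate),
                          L2 = unname(substrate + encap1)),
      total = unname(substrate + encap1 + encap2)
    ),
    class = "layer_stack"
  )
}

#' @export
print.layer_stack <- function(x, ...) {
  cat("Layer stack (", x$total, " um total):\n", sep = "")
  cat("  substrate ", x$thicknesses[["substrate"]], " um | L1 | encap ",
      x$thicknesses[["encap1"]], " um | L2 | encap ",
      x$thicknesses[["encap2"]], " um\n", sep = "")
  invisible(x)
}

#' Distance of each metal layer from the neutral plane
#'
#' Under a uniform-modulus assumption (metal layers as zero-thickness
#' markers in a homogeneous elastomer), the neutral plane of the stack sits
#' at half its total thickness; each metal layer's `d_N` is its unsigned
#' distance from that plane.
#'
#' @param stack A [layer_stack()].
#' @return Named numeric vector of `d_N` values (um), one per metal layer.
#' @examples
#' neutral_plane_offsets(layer_stack())  # L1: 7.5, L2: 22.5
#' @export
neutral_plane_offsets <- function(stack) {
  if (!inherits(stack, "layer_stack")) {
    stop("'stack' must be a layer_stack", call. = FALSE)
  }
  abs(stack$metal_positions - stack$total / 2)
}

#' Thickness of a stretched elastomer sheet under Poisson compression
#'
#' First-order transverse contraction of an incompressible (or nearly so)
#' elastomer under uniaxial in-plane strain: `t = t0 * (1 - nu * strain)`.
#'
#' @param t0 Unstrained thickness (um).
#' @param nu Poisson ratio, in \[0, 0.5\]; default 0.5 (incompressible
#'   elastomer).
#' @param axial_strain Applied in-plane engineering strain (fraction, >= 0).
#' @return Thickness under strain (um).
#' @examples
#' poisson_thickness(105, 0.5, 0.20)  # 94.5
#' @export
poisson_thickness <- function(t0, nu = 0.5, axial_strain) {
  if (any(nu < 0) || any(nu > 0.5)) {
    stop("Poisson ratio 'nu' must lie in [0, 0.5]", call. = FALSE)
  }
  if (any(axial_strain < 0)) {
    stop("'axial_strain' must be non-negative", call. = FALSE)
  }
  t <- t0 * (1 - nu * axial_strain)
  if (any(t <= 0)) {
    stop("strain produces non-positive thickness", call. = FALSE)
  }
  t
}

#' Geometric surface area of a disc electrode
#'
#' @param diameter Electrode diameter (um); default 80.
#' @return Area (um^2).
#' @examples
#' disc_area(80)  # 5026.548
#' @export
disc_area <- function(diameter = 80) {
  if (any(diameter <= 0)) stop("'diameter' must be positive", call. = FALSE)
  pi * (diameter / 2)^2
}

#' Current density and charge per phase of a disc electrode
#'
#' Converts a commanded current into a geometric current density. For a
#' biphasic constant-current pulse the charge per phase (`I * phase
#' duration`) is reported alongside.
#'
#' 1 uA / um^2 equals 1000 mA / mm^2, so a 110 uA pulse on an 80 um disc
#' gives 21.9 mA/mm^2.
#'
#' @param I Current (uA).
#' @param diameter Electrode diameter (um); default 80.
#' @param phase_us Phase duration (us) for the charge-per-phase figure;
#'   default 200.
#' @return List with `density` (mA/mm^2), `charge_per_phase` (nC) and
#'   `area` (um^2).
#' @examples
#' current_density(110)$density  # 21.9
#' @export
current_density <- function(I, diameter = 80, phase_us = 200) {
  area <- disc_area(diameter)
  list(
    density = I / area * 1000,
    charge_per_phase = I * phase_us / 1000,
    area = area
  )
}

#' Fold change of a summary value (e.g. impedance before/after plating)
#'
#' @param pre_mean,post_mean Values in the same units; `post_mean` > 0.
#' @return `pre_mean / post_mean`.
#' @examples
#' fold_change(465, 20)  # 23.25
#' @export
fold_change <- function(pre_mean, post_mean) {
  if (any(post_mean <= 0)) {
    stop("'post_mean' must be positive", call. = FALSE)
  }
  pre_mean / post_mean
}

#' Ohmic voltage across an electrode impedance
#'
#' `V = I * Z`, used to check that a commanded stimulation current through a
#' measured (1 kHz) impedance stays within a stimulator's compliance limit.
#'
#' @param I Current (uA).
#' @param Z Impedance magnitude (kOhm), >= 0.
#' @return Voltage (V); uA x kOhm = mV, so the result is `I * Z / 1000`.
#' @examples
#' ohmic_voltage(100, 75)  # 7.5 V
#' @export
ohmic_voltage <- function(I, Z) {
  if (any(Z < 0)) stop("'Z' must be non-negative", call. = FALSE)
  I * Z / 1000
}
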