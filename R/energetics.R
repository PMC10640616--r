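#' Optical absorbed-energy parameters
#'
#' Inputs of the molecule-count absorption model: a single light pulse of
#' `power_density` and `pulse_width` illuminates a cell sheet whose cells
#' each carry `molecules_per_cell` membrane-bound photoswitch molecules of
#' absorption cross-section `cross_section` over a footprint area
#' `cell_footprint`. In the optically thin limit the areal energy absorbed
#' by the sheet is `fluence * sigma * N / A_cell`.
#'
#' The closure constants `molecules_per_cell = 1e5` and
#' `cell_footprint = 1e-5` cm^2 (a ~30 um x 300 um myotube footprint) are
#' documented model assumptions and can be overridden.
#'
#' @param power_density Light power density, mW/mm^2.
#' @param pulse_width Pulse duration, s.
#' @param cross_section Molecular absorption cross-section, cm^2
#'   (default 2e-15).
#' @param molecules_per_cell Photoswitch molecules per cell; membrane
#'   loading estimates span 1e3 to 1e5.
#' @param cell_footprint Projected cell area, cm^2.
#' @return A list of class `optical_energy_params`.
#' @export
optical_energy_params <- function(power_density,
                                  pulse_width = 0.2,
                                  cross_section = 2e-15,
                                  molecules_per_cell = 1e5,
                                  cell_footprint = 1e-5) {
  stopifnot(power_density > 0, pulse_width > 0, cross_section > 0,
            molecules_per_cell >= 0, cell_footprint > 0)
  structure(
    list(power_density = power_density, pulse_width = pulse_width,
         cross_section = cross_section,
         molecules_per_cell = molecules_per_cell,
         cell_footprint = cell_footprint),
    class = "optical_energy_params"
  )
}

#' Electrical Joule-dissipation parameters
#'
#' Inputs of the uniform-field Joule model for bath-electrode stimulation:
#' two wires a distance `electrode_gap` apart hold a voltage pulse across
#' the electrolyte; assuming a constant, uniform field `V/d`, the power
#' dissipated per unit volume in the resistive cell layer is `(V/d)^2 /
#' rho`, and the areal energy seen by a cell sheet of height `layer_height`
#' during one pulse follows by multiplying by `pulse_width * h`.
#' `wire_length` and `cell_distance` describe the electrode geometry and
#' are carried for fidelity to the setup sketch but do not enter the
#' uniform-field formula.
#'
#' @param voltage Applied voltage, V.
#' @param electrode_gap Distance between the electrodes, m (default 7e-3).
#' @param wire_length Horizontal electrode length, m (default 2.4e-2).
#' @param cell_distance Electrode-to-cell distance, m (default 1e-3).
#' @param layer_height Height of the cell layer, m (default 1e-5, i.e.
#'   10 um; a closure assumption).
#' @param resistivity Resistivity of the myotube film, Ohm m (default
#'   5.8e-1).
#' @param pulse_width Pulse duration, s (default 0.02).
#' @return A list of class `electrical_energy_params`.
#' @export
electrical_energy_params <- function(voltage,
                                     electrode_gap = 7e-3,
                                     wire_length = 2.4e-2,
                                     cell_distance = 1e-3,
                                     layer_height = 1e-5,
                                     resistivity = 5.8e-1,
                                     pulse_width = 0.02) {
  stopifnot(voltage >= 0, electrode_gap > 0, wire_length > 0,
            cell_distance > 0, layer_height > 0, resistivity > 0,
            pulse_width > 0)
  structure(
    list(voltage = voltage, electrode_gap = electrode_gap,
         wire_length = wire_length, cell_distance = cell_distance,
         layer_height = layer_height, resistivity = resistivity,
         pulse_width = pulse_width),
    class = "electrical_energy_params"
  )
}

#' Incident fluence of one light pulse
#'
#' `power_density * pulse_width`, converted to J/cm^2
#' (1 mW/mm^2 = 0.1 W/cm^2).
#'
#' @param power_density mW/mm^2.
#' @param pulse_width s.
#' @return Fluence in J/cm^2.
#' @export
incident_fluence <- function(power_density, pulse_width) {
  stopifnot(power_density > 0, pulse_width > 0)
  power_density * 0.1 * pulse_width
}

#' Areal energy absorbed by the cell sheet under optical stimulation
#'
#' Optically thin limit: `fluence * sigma * N / A_cell`. Refuses inputs
#' where the total molecular cross-section exceeds 10% of the cell
#' footprint, where the thin-sheet approximation breaks down.
#'
#' @param p An [optical_energy_params()].
#' @return Absorbed areal energy, J/cm^2.
#' @export
optical_absorbed_energy <- function(p) {
  stopifnot(inherits(p, "optical_energy_params"))
  opacity <- p$cross_section * p$molecules_per_cell / p$cell_footprint
  if (opacity > 0.1) {
    stop(sprintf(
      "optically thick input (sigma*N/A_cell = %.3g > 0.1): reduce the molecule count or use a Beer-Lambert model",
      opacity
    ))
  }
  incident_fluence(p$power_density, p$pulse_width) * opacity
}

#' Areal energy dissipated in the cell layer under electrical stimulation
#'
#' Uniform-field Joule model: field `E = V/d`, volumetric power
#' `E^2 / rho`, areal energy `E^2 / rho * pulse_width * h`, converted from
#' J/m^2 to J/cm^2.
#'
#' @param p An [electrical_energy_params()].
#' @return Dissipated areal energy, J/cm^2.
#' @export
electrical_dissipated_energy <- function(p) {
  stopifnot(inherits(p, "electrical_energy_params"))
  e_field <- p$voltage / p$electrode_gap                 # V/m
  areal_j_m2 <- e_field^2 / p$resistivity * p$pulse_width * p$layer_height
  areal_j_m2 / 1e4
}

#' Photoswitch molecules per cell from solution depletion
#'
#' The membrane loading is estimated by comparing the photoswitch
#' concentration in the loading solution before and after incubation
#' ("washing"): the depleted amount, in molecules, divided by the number of
#' cells.
#'
#' @param c_initial Initial concentration, mol/L.
#' @param c_recovered Concentration recovered after washing, mol/L.
#' @param volume Solution volume, L.
#' @param n_cells Number of cells exposed.
#' @return Molecules per cell.
#' @export
molecules_from_depletion <- function(c_initial, c_recovered, volume,
                                     n_cells) {
  stopifnot(c_initial >= 0, c_recovered >= 0, volume > 0, n_cells > 0)
  if (c_recovered > c_initial) {
    stop("recovered concentration exceeds the initial concentration")
  }
  avogadro <- 6.02214076e23
  (c_initial - c_recovered) * volume * avogadro / n_cells
}
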