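#' Magnetic and RF properties of stent materials
#'
#' Returns the per-material constants the simulator needs: the volume magnetic
#' susceptibility difference against soft tissue (`delta_chi`, dimensionless SI
#' units) and the RF-shielding factor applied multiplicatively to the nominal
#' flip angle inside the stented lumen (`shielding_factor`).
#'
#' Susceptibility differences for tantalum (190e-6), nitinol (255e-6) and
#' platinum (290e-6) are literature values for 1.5 T soft-tissue imaging;
#' austenitic 316L steel is one to two orders of magnitude larger and is
#' represented by 3e-3. No literature value is adopted for the drawn-wire
#' cobalt superalloy of braided Wallstent-type cages: its voxel-scale
#' effective susceptibility is a calibration constant (20e-6) reflecting the
#' small metal filling fraction of the thin braid.
#' Shielding factors are calibration constants, not
#' measured quantities: eddy currents in a closed wire cage attenuate B1 in
#' the lumen (factor < 1), but certain braided designs concentrate flux so the
#' effective flip angle moves *towards* the Ernst angle and the lumen signal
#' exceeds the unstented reference (factor > 1, as for braided cobalt-alloy
#' Wallstent-type devices). Factors are therefore allowed in (0, 1.5].
#'
#' @param material Character vector of material keys. Recognised:
#'   `"tantalum"`, `"nitinol"`, `"platinum_alloy"`, `"316L"`,
#'   `"cobalt_superalloy"`, `"cobalt_superalloy_pet"`, `"none"`.
#' @param delta_chi,shielding_factor Optional overrides (recycled).
#' @return A tibble with columns `name`, `delta_chi`, `shielding_factor`.
#' @examples
#' material_properties(c("tantalum", "316L"))
#' @export
material_properties <- function(material, delta_chi = NULL, shielding_factor = NULL) {
  defaults <- tibble::tribble(
    ~name,                   ~delta_chi, ~shielding_factor,
    "tantalum",              190e-6,     0.90,
    "nitinol",               255e-6,     0.75,
    "platinum_alloy",        290e-6,     0.45,
    "316L",                  3e-3,       0.30,
    "cobalt_superalloy",     20e-6,      1.40,
    "cobalt_superalloy_pet", 20e-6,      0.85,
    "none",                  0,          1.00
  )
  idx <- match(material, defaults$name)
  if (anyNA(idx)) {
    abort(paste0("Unknown stent material(s): ",
                 paste(unique(material[is.na(idx)]), collapse = ", ")))
  }
  out <- defaults[idx, ]
  if (!is.null(delta_chi)) out$delta_chi <- rep_len(delta_chi, nrow(out))
  if (!is.null(shielding_factor)) {
    out$shielding_factor <- rep_len(shielding_factor, nrow(out))
  }
  if (any(!is.finite(out$delta_chi)) || any(out$delta_chi < 0)) {
    abort("delta_chi must be finite and >= 0")
  }
  if (any(out$shielding_factor <= 0) || any(out$shielding_factor > 1.5)) {
    abort("shielding_factor must lie in (0, 1.5]")
  }
  out
}

#' Describe one stent
#'
#' Builds the geometric and material description of a single stent. Strut
#' micro-geometry (wire radius, number of helical wires, cell design) is not
#' part of published stent tables, so plausible defaults are used: mesh
#' designs are modelled as `n_helical_wires` counter-wound helices of
#' 0.1 mm strut radius with a pitch of one turn per sixth of the stent
#' length; balloon-expandable slotted-tube designs as a perforated metal
#' shell. Artifact severity is tuned through the material constants, not the
#' micro-geometry.
#'
#' @param id Integer identifier (row in the packaged stent table).
#' @param name Human-readable stent name.
#' @param material Material key (see [material_properties()]) or a one-row
#'   tibble as returned by it.
#' @param nominal_diameter Nominal (expanded) diameter in mm.
#' @param length Stent length in mm.
#' @param strut_radius Wire/strut radius in mm (< 0.3).
#' @param n_helical_wires Number of helical wires for mesh/covered designs;
#'   0 gives a "ghost" stent with no struts.
#' @param design One of `"mesh"`, `"slotted_tube"`, `"coil"`, `"covered"`.
#' @return An object of class `stent_spec`.
#' @export
stent_spec <- function(id, name, material, nominal_diameter, length,
                       strut_radius = 0.1, n_helical_wires = 8,
                       design = c("mesh", "slotted_tube", "coil", "covered")) {
  design <- match.arg(design)
  if (is.character(material)) material <- material_properties(material)
  stopifnot(is.data.frame(material), nrow(material) == 1)
  if (!nominal_diameter %in% c(5, 6, 7, 8, 10, 13)) {
    abort("nominal_diameter must be one of 5, 6, 7, 8, 10, 13 mm")
  }
  if (length <= 0) abort("stent length must be positive")
  if (strut_radius >= 0.3) abort("strut_radius must be < 0.3 mm")
  structure(
    list(id = as.integer(id), name = as.character(name),
         material = material, nominal_diameter = nominal_diameter,
         length = length, strut_radius = strut_radius,
         n_helical_wires = as.integer(n_helical_wires), design = design),
    class = "stent_spec")
}

#' @export
print.stent_spec <- function(x, ...) {
  cat(sprintf("<stent_spec> #%d %s (%s, %s)\n", x$id, x$name,
              x$material$name, x$design))
  cat(sprintf("  diameter %g mm, length %g mm, %d wires, strut r %g mm\n",
              x$nominal_diameter, x$length, x$n_helical_wires, x$strut_radius))
  cat(sprintf("  delta_chi %.3g, shielding %.2f\n",
              x$material$delta_chi, x$material$shielding_factor))
  invisible(x)
}

#' Describe the carrier tube and its contents
#'
#' The phantom tube: a plastic cylinder embedded in gel, filled with a
#' gadolinium chelate solution. Relaxation times of the filling follow from
#' the Gd concentration through [lumen_T1_from_concentration()]; the gel is
#' given muscle-like relaxation. Small tubes (inner diameter <= 8 mm) have
#' thin walls (< 0.3 mm), large tubes (>= 10 mm) walls of about 1 mm.
#'
#' @param inner_diameter Inner diameter in mm (5, 7, 8, 10 or 13 in the
#'   reference setup; any positive value accepted).
#' @param length Tube length in mm. Must leave room for an unstented
#'   reference segment on both sides of the stent.
#' @param wall_thickness Wall thickness in mm; default picked by diameter.
#' @param gd_concentration Gd-DTPA concentration in mmol/L (default 25).
#' @param r1_relaxivity Longitudinal relaxivity in L/(mmol s) at 1.5 T.
#' @param T1_solvent T1 of the solvent (water) in ms.
#' @param lumen_T2star,background_T1,background_T2star Relaxation defaults in
#'   ms (before any susceptibility effect).
#' @return An object of class `tube_spec`; `lumen_T1` is precomputed.
#' @export
tube_spec <- function(inner_diameter, length,
                      wall_thickness = if (inner_diameter <= 8) 0.25 else 1,
                      gd_concentration = 25, r1_relaxivity = 4.5,
                      T1_solvent = 3000, lumen_T2star = 100,
                      background_T1 = 900, background_T2star = 50) {
  if (inner_diameter <= 0 || length <= 0) abort("tube dimensions must be positive")
  if (inner_diameter <= 8 && wall_thickness >= 0.3) {
    warn("small tubes (<= 8 mm) have wall thickness < 0.3 mm in the reference setup")
  }
  structure(
    list(inner_diameter = inner_diameter, wall_thickness = wall_thickness,
         length = length, gd_concentration = gd_concentration,
         r1_relaxivity = r1_relaxivity, T1_solvent = T1_solvent,
         lumen_T1 = lumen_T1_from_concentration(gd_concentration,
                                                r1_relaxivity, T1_solvent),
         lumen_T2star = lumen_T2star, background_T1 = background_T1,
         background_T2star = background_T2star),
    class = "tube_spec")
}

#' Pick the carrier tube for a stent
#'
#' Maps a stent's nominal diameter onto the discrete set of available tube
#' sizes (5, 7, 8, 10, 13 mm). A 6 mm stent goes into the 5 mm tube
#' (oversized deployment); otherwise the match is exact. Tube length leaves
#' `reference_length` mm of unstented lumen on each side of the stent.
#'
#' @param stent A `stent_spec`.
#' @param reference_length Unstented segment length per side, mm.
#' @param ... Passed to [tube_spec()].
#' @return A `tube_spec`.
#' @export
tube_for_stent <- function(stent, reference_length = 20, ...) {
  d <- stent$nominal_diameter
  inner <- if (d == 6) 5 else d
  tube_spec(inner_diameter = inner,
            length = stent$length + 2 * reference_length, ...)
}

# design convention for the packaged stent table: balloon-expandable 316L
# devices are slotted tubes, the covered Wallgraft keeps its braided-mesh
# cage, everything else is a wire mesh
infer_design <- function(material) {
  dplyr::case_when(
    material == "316L" ~ "slotted_tube",
    material == "cobalt_superalloy_pet" ~ "covered",
    TRUE ~ "mesh")
}

#' Stent specs from a stent table row
#'
#' Convenience constructor turning rows of [stent_table1()] (or any table
#' with the same columns) into a list of [stent_spec()] objects.
#'
#' @param table A data frame with columns `stent_id`, `name`, `material`,
#'   `diameter_mm`, `length_mm`.
#' @param ids Optional integer vector restricting which stents to build.
#' @return A named list of `stent_spec` objects.
#' @export
stent_specs_from_table <- function(table = stent_table1(), ids = NULL) {
  if (!is.null(ids)) {
    missing <- setdiff(ids, table$stent_id)
    if (length(missing)) {
      abort(paste0("Unknown stent id(s): ", paste(missing, collapse = ", ")))
    }
    table <- table[table$stent_id %in% ids, , drop = FALSE]
  }
  specs <- purrr::pmap(
    list(table$stent_id, table$name, table$material,
         table$diameter_mm, table$length_mm),
    function(id, name, material, d, len) {
      stent_spec(id, name, material, d, len,
                 design = infer_design(material))
    })
  setNames(specs, table$name)
}
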