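#' Write a volume as NIfTI
#'
#' Writes a `label_volume` (integer datatype), `field_map` or
#' `phantom_image` (float) with the voxel size in the header.
#'
#' @param volume The 3D array object.
#' @param path Output `.nii` / `.nii.gz` path.
#' @return `path`, invisibly.
#' @export
write_volume_nifti <- function(volume, path) {
  vs <- attr(volume, "voxel_size")
  arr <- array(as.numeric(volume), dim = dim(volume))
  dt <- if (inherits(volume, "label_volume")) "int16" else "float"
  attr(arr, "pixdim") <- vs
  attr(arr, "pixunits") <- c("mm", "s")
  img <- RNifti::asNifti(arr, datatype = dt)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read a phantom description from YAML or JSON
#'
#' A config file mirrors the in-code constructors: a `stent:` block
#' (fields of [stent_spec()], with `material` a key or an inline mapping
#' with `name`, `delta_chi`, `shielding_factor`), an optional `tube:` block
#' ([tube_spec()] fields), and an optional `acquisition:` block
#' ([acquisition_params()] fields).
#'
#' @param path Path to a `.yaml`/`.yml`/`.json` file.
#' @return A list with elements `stent`, `tube`, `acq`.
#' @export
read_phantom_config <- function(path) {
  cfg <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  if (is.null(cfg$stent)) abort("config must contain a 'stent' block")
  s <- cfg$stent
  mat <- if (is.character(s$material)) {
    material_properties(s$material)
  } else {
    material_properties(s$material$name %||% "none",
                        delta_chi = s$material$delta_chi,
                        shielding_factor = s$material$shielding_factor)
  }
  stent <- stent_spec(id = s$id %||% 0L, name = s$name %||% "unnamed",
                      material = mat,
                      nominal_diameter = s$nominal_diameter,
                      length = s$length,
                      strut_radius = s$strut_radius %||% 0.1,
                      n_helical_wires = s$n_helical_wires %||% 8,
                      design = s$design %||% "mesh")
  tube <- if (is.null(cfg$tube)) {
    tube_for_stent(stent)
  } else {
    do.call(tube_spec, cfg$tube)
  }
  acq <- if (is.null(cfg$acquisition)) {
    acquisition_params()
  } else {
    do.call(acquisition_params, cfg$acquisition)
  }
  list(stent = stent, tube = tube, acq = acq)
}

# provenance comment header prepended to CSV outputs
provenance_header <- function(seed, config_hash) {
  c(sprintf("# stentmra %s", packageVersion("stentmra")),
    sprintf("# seed: %s", seed %||% "none"),
    sprintf("# config: %s", config_hash))
}

write_csv_with_provenance <- function(df, path, seed, config_hash) {
  writeLines(provenance_header(seed, config_hash), path)
  readr::write_csv(df, path, append = TRUE, col_names = TRUE)
  invisible(path)
}

#' Read a measurements CSV
#'
#' Reads a measurement table in the standard schema (`stent_id`, `name`,
#' `si_percent`, `vis_min_percent`, optionally `vis_max_percent`,
#' `sd_over_mean`), skipping `#` provenance comments.
#'
#' @param path CSV path.
#' @return A tibble.
#' @export
read_measurements_csv <- function(path) {
  readr::read_csv(path, comment = "#", show_col_types = FALSE, progress = FALSE)
}
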