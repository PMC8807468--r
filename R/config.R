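# Simulation configuration: defaults, validation, (de)serialization, hashing.

#' Default simulation configuration
#'
#' Nested list of configuration blocks with documented defaults: geometry
#' (mm), mesh resolution, fluid/rheology, inlet waveform, Windkessel outlet,
#' thrombosis constants, flap model and run control. Every thrombosis
#' constant carries its model default and can be overridden; overrides are
#' echoed to the run log by [run_simulation()].
#'
#' @param ... named overrides as `block$key` replacements, e.g.
#'   `flap = list(preset = "rigid")`, `run = list(cycles = 4)`. Unnamed
#'   blocks keep their defaults; within a block only the supplied keys are
#'   replaced.
#' @return An object of class `simulation_config`.
#' @export
simulation_config <- function(...) {
  cfg <- list(
    geometry = list(
      tl_width = 19.4, fl_width = 23.0, flap_thickness = 0.8,
      tear_length = 10.0, dissected_length = 200,
      inlet_extension = 40, outlet_extension = 40,
      entry_tear_center = NULL, reentry_tear_center = NULL),
    mesh = list(target_edge_length = 0.8, dx_axial = 1.25,
                dy_channel = NULL, wall_layers = 0),
    fluid = list(density = 1060, rheology = "quemada",
                 mu_const = NULL, hematocrit = 0.45),
    waveform = list(frequency = 1.02, mean_velocity = 0.10,
                    systole_fraction = 0.33, reverse_fraction = 0.15,
                    reverse_strength = 0.15, n_harmonics = 12),
    windkessel = list(C = 2.15e-7, R_p = 6.5e6, R_c = 3.4e5, P0 = 10600),
    thrombosis = list(
      enabled = TRUE,
      D_RP = 1.6e-13, D_AP = 1.6e-11, D_C_base = 1.0e-8,
      k_RP = -0.15, k_AP = 3.0, k_C1 = 16.0, k_C2 = -6.0, k_BP = 12.0,
      k_c_wall = 16.0, gamma_t = 50.0, AP_t = 15.0, C_t = 10.0, BP_t = 20.0,
      TAWSS_threshold = 0.15, wall_relative_concentration = 2,
      literal_shear_switch = FALSE, c_wall_delta = 1e-3),
    flap = list(preset = "flexible", E_flap = NULL, poisson = 0.45,
                foundation = NULL, relax = 0.02, cap_fraction = 0.4),
    hemodynamics = list(k_M = 1e7, k_pen = 1e8,
                        cg_rtol = 1e-9, re_warn = 4000),
    run = list(pre_cycles = 3, cycles = 12, steps_per_cycle = 2400,
               chunks_per_cycle = 8, growth_tol = 1e-3,
               checkpoint_every = 0, vtk_every = 0, seed = 1,
               output_dir = NULL)
  )
  dots <- list(...)
  for (blk in names(dots)) {
    if (!blk %in% names(cfg)) stop("unknown configuration block: ", blk)
    for (key in names(dots[[blk]])) {
      if (!key %in% names(cfg[[blk]]))
        stop("unknown key '", key, "' in block '", blk, "'")
      cfg[[blk]][[key]] <- dots[[blk]][[key]]
    }
  }
  structure(cfg, class = "simulation_config")
}

#' @exportS3Method base::print
print.simulation_config <- function(x, ...) {
  cat("fltsim simulation configuration\n")
  g <- x$geometry
  cat(sprintf("  geometry : TL %.3g / flap %.3g / FL %.3g mm, dissected %.3g mm, tears %.3g mm\n",
              g$tl_width, g$flap_thickness, g$fl_width, g$dissected_length,
              g$tear_length))
  cat(sprintf("  mesh     : h %.3g mm (axial %.3g mm)\n",
              x$mesh$target_edge_length, x$mesh$dx_axial))
  cat(sprintf("  flap     : %s\n", if (!is.null(x$flap$E_flap))
    paste0("E = ", x$flap$E_flap, " Pa") else x$flap$preset))
  cat(sprintf("  run      : %d pre-cycles + %d cycles at %d steps/cycle, f = %.3g Hz\n",
              x$run$pre_cycles, x$run$cycles, x$run$steps_per_cycle,
              x$waveform$frequency))
  invisible(x)
}

#' Write a configuration to file
#'
#' JSON (default) preserves full double precision, so
#' parse-serialize-parse round-trips are lossless; `.yaml` output is also
#' supported for hand editing.
#'
#' @param config a [simulation_config()].
#' @param path output path; format chosen by extension (`.json` / `.yaml`).
#' @return `path`, invisibly.
#' @export
write_config <- function(config, path) {
  stopifnot(inherits(config, "simulation_config"))
  if (grepl("\\.ya?ml$", path)) {
    yaml::write_yaml(unclass(config), path, precision = 15L)
  } else {
    jsonlite::write_json(unclass(config), path, auto_unbox = TRUE,
                         digits = NA, null = "null", pretty = TRUE)
  }
  invisible(path)
}

#' Read a configuration from file
#'
#' @param path a `.json` or `.yaml` file written by [write_config()] (or
#'   hand-authored with the same block structure).
#' @return A validated `simulation_config`.
#' @export
read_config <- function(path) {
  raw <- if (grepl("\\.ya?ml$", path)) yaml::read_yaml(path)
         else jsonlite::read_json(path, simplifyVector = TRUE)
  args <- raw[lengths(raw) > 0]
  # drop explicit nulls inside blocks (JSON null -> R NULL handled by default)
  args <- lapply(args, function(b) b[!vapply(b, is.null, logical(1))])
  do.call(simulation_config, args)
}

#' Hash a configuration
#'
#' MD5 of the canonical (full-precision, sorted) JSON serialization; used
#' for checkpoint/manifest provenance. Output-routing fields
#' (`run$output_dir`) are excluded so that relocating outputs does not
#' invalidate checkpoints.
#'
#' @param config a `simulation_config`.
#' @return Character MD5 hash.
#' @export
config_hash <- function(config) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  blocks <- unclass(config)
  blocks$run$output_dir <- NULL
  blocks <- blocks[order(names(blocks))]
  jsonlite::write_json(blocks, tmp, auto_unbox = TRUE, digits = NA,
                       null = "null")
  unname(tools::md5sum(tmp))
}
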