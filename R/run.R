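# Orchestration: assemble a configured simulation, run the coupled time
# loop cycle by cycle, keep the cycle ledger and traces, write outputs and
# the run manifest, and drive the rigid/stiffer/flexible comparison.

# build all model objects from a configuration
assemble_simulation <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  g <- config$geometry
  geo <- dissection_geometry(
    tl_width = g$tl_width, fl_width = g$fl_width,
    flap_thickness = g$flap_thickness, tear_length = g$tear_length,
    dissected_length = g$dissected_length,
    inlet_extension = g$inlet_extension,
    outlet_extension = g$outlet_extension,
    entry_tear_center = g$entry_tear_center,
    reentry_tear_center = g$reentry_tear_center)
  domain <- build_dissection_geometry(geo)
  mesh <- generate_mesh(domain, config$mesh$target_edge_length,
                        wall_layers = config$mesh$wall_layers,
                        dx_axial = config$mesh$dx_axial,
                        dy_channel = config$mesh$dy_channel)
  rheo <- if (identical(config$fluid$rheology, "quemada"))
    quemada_params(hematocrit = config$fluid$hematocrit)
  else config$fluid$mu_const
  fluid <- fluid_properties(density = config$fluid$density, rheology = rheo)
  th <- config$thrombosis
  thromb <- thrombosis_params(
    D_RP = th$D_RP, D_AP = th$D_AP, D_C_base = th$D_C_base,
    k_RP = th$k_RP, k_AP = th$k_AP, k_C1 = th$k_C1, k_C2 = th$k_C2,
    k_BP = th$k_BP, k_c_wall = th$k_c_wall, gamma_t = th$gamma_t,
    AP_t = th$AP_t, C_t = th$C_t, BP_t = th$BP_t,
    TAWSS_threshold = th$TAWSS_threshold,
    wall_relative_concentration = th$wall_relative_concentration,
    literal_shear_switch = th$literal_shear_switch)
  wf <- config$waveform
  waveform <- inlet_waveform(frequency = wf$frequency,
                             mean_velocity = wf$mean_velocity,
                             systole_fraction = wf$systole_fraction,
                             reverse_fraction = wf$reverse_fraction,
                             reverse_strength = wf$reverse_strength,
                             n_harmonics = wf$n_harmonics)
  wkc <- config$windkessel
  wk <- windkessel_params(C = wkc$C, R_p = wkc$R_p, R_c = wkc$R_c,
                          P0 = wkc$P0)
  fl <- config$flap
  E <- if (!is.null(fl$E_flap)) fl$E_flap else fl$preset
  fp <- flap_params(E_flap = E, thickness = g$flap_thickness * 1e-3,
                    span = g$dissected_length * 1e-3,
                    foundation = 0, relax = fl$relax,
                    cap = fl$cap_fraction * min(g$tl_width, g$fl_width) * 1e-3)
  if (is.null(fl$foundation)) {
    fp$foundation <- foundation_from_plate(fp$E_flap,
                                           thickness = fp$thickness,
                                           width = g$fl_width * 1e-3,
                                           poisson = fl$poisson)
  } else fp$foundation <- fl$foundation
  flap <- build_flap_system(mesh, fp)
  bc <- list(west = list(type = "velocity", waveform = waveform),
             east = list(type = "windkessel", wk = wk))
  state <- flow_state(mesh, fluid = fluid, thromb = thromb, bc = bc,
                      flap = flap, k_M = config$hemodynamics$k_M,
                      k_pen = config$hemodynamics$k_pen)
  list(state = state, mesh = mesh, domain = domain, waveform = waveform,
       config = config)
}

# publish cycle averages from the raw accumulators and reset them
publish_cycle <- function(state) {
  Tc <- state$acc_t
  nx <- state$mesh$nx; ny <- state$mesh$ny
  state$cycle_avg <- list(
    tawss = state$acc_wss / Tc,
    avg_gamma = matrix(state$acc_gamma / Tc, nx, ny),
    avg_AP = matrix(state$acc_AP / Tc, nx, ny),
    avg_mu = matrix(state$acc_mu / Tc, nx, ny))
  state$tawss_prev <- state$cycle_avg$tawss
  state$acc_wss[] <- 0; state$acc_gamma[] <- 0
  state$acc_AP[] <- 0; state$acc_mu[] <- 0
  state$acc_t <- 0
  state
}

#' Run a configured dissection simulation
#'
#' Executes the flow-only pre-cycles followed by the coupled
#' flow-flap-thrombosis cycles, with the per-step order: inlet/Windkessel
#' update, flap load/solve/mesh update, momentum + projection with the
#' thrombus sink, species transport/reaction, ledger accumulation. The run
#' stops after the configured cycles or as soon as per-cycle thrombus
#' growth falls below `growth_tol` of the FL reference volume.
#'
#' @param config a [simulation_config()].
#' @param restart path to a checkpoint written by a previous run with
#'   identical configuration; the run resumes from the stored cycle.
#' @param quiet suppress progress messages.
#' @return An object of class `flt_run`: final `state`, `volume` trace
#'   (time, volume_cm3, fl_fraction), `flap_history` (times x stations, m),
#'   per-cycle `cycles` summary, `manifest` and `termination`.
#' @export
run_simulation <- function(config = simulation_config(), restart = NULL,
                           quiet = FALSE) {
  t_wall0 <- proc.time()[["elapsed"]]
  sim <- assemble_simulation(config)
  state <- sim$state
  period <- 1 / config$waveform$frequency
  nsub <- config$run$steps_per_cycle
  dt <- period / nsub
  chunks <- max(1L, config$run$chunks_per_cycle)
  per_chunk <- nsub %/% chunks
  leftover <- nsub - per_chunk * chunks
  fl_mask <- fl_region_mask(sim$mesh)
  areas <- cell_areas(sim$mesh)
  fl_vol_cm3 <- sum(areas[fl_mask]) * 1e6
  # axial thirds of the dissected FL, for growth-pattern bookkeeping
  dz <- sim$mesh$domain$dissected * 1e-3
  xc <- sim$mesh$x_centers
  third_of <- function(lo, hi) {
    m <- matrix(xc > lo & xc <= hi, sim$mesh$nx, sim$mesh$ny) & fl_mask
    m
  }
  thirds <- list(prox = third_of(dz[1], dz[1] + diff(dz) / 3),
                 mid = third_of(dz[1] + diff(dz) / 3, dz[2] - diff(dz) / 3),
                 dist = third_of(dz[2] - diff(dz) / 3, dz[2]))
  thromb_on <- isTRUE(config$thrombosis$enabled)
  say <- function(...) if (!quiet) message(...)

  # overrides echoed to the log
  defaults <- simulation_config()
  for (blk in names(defaults)) for (key in names(defaults[[blk]])) {
    dv <- defaults[[blk]][[key]]; cv <- config[[blk]][[key]]
    if (!identical(dv, cv))
      say(sprintf("config override: %s$%s = %s (default %s)", blk, key,
                  paste(format(cv), collapse = ","),
                  paste(format(dv), collapse = ",")))
  }

  volume <- data.frame(time = numeric(0), volume_cm3 = numeric(0),
                       fl_fraction = numeric(0), frac_prox = numeric(0),
                       frac_mid = numeric(0), frac_dist = numeric(0))
  flap_history <- NULL
  flap_times <- numeric(0)
  cycles <- list()
  cycle0 <- 0L
  if (!is.null(restart)) {
    ck <- readRDS(restart)
    if (!identical(ck$hash, config_hash(config)))
      stop("checkpoint was written with a different configuration")
    state <- ck$state; volume <- ck$volume
    flap_history <- ck$flap_history; flap_times <- ck$flap_times
    cycles <- ck$cycles; cycle0 <- ck$cycle
    say("restarting from checkpoint at cycle ", cycle0)
  }

  total_cycles <- config$run$pre_cycles + config$run$cycles
  termination <- "cycles done"
  prev_vol <- if (nrow(volume)) volume$volume_cm3[nrow(volume)] else 0

  for (cyc in seq_len(total_cycles)) {
    if (cyc <= cycle0) next
    is_pre <- cyc <= config$run$pre_cycles
    t_cyc0 <- proc.time()[["elapsed"]]
    steps <- c(rep(per_chunk, chunks), if (leftover > 0) leftover)
    for (k in seq_along(steps)) {
      if (steps[k] == 0L) next
      # advance one chunk; on solver divergence retry the chunk with a
      # halved time step (the state is untouched by a failed attempt)
      halvings <- 0L
      repeat {
        res <- tryCatch(
          advance(state, steps[k] * 2L^halvings, dt / 2^halvings,
                  species_on = thromb_on && !is_pre, flap_on = TRUE,
                  cg_rtol = config$hemodynamics$cg_rtol),
          error = function(e) e)
        if (!inherits(res, "error")) { state <- res; break }
        halvings <- halvings + 1L
        if (halvings > 3L)
          stop("flow solver diverged at cycle ", cyc,
               " even after halving dt three times: ",
               conditionMessage(res))
        say(sprintf("cycle %d chunk %d: solver diverged, retrying with dt/%d",
                    cyc, k, 2L^halvings))
      }
      tm <- thrombus_mask(state$BP, areas, state$thromb$BP_t)
      thromb <- state$BP >= state$thromb$BP_t
      fl_thromb <- sum(thromb * areas * fl_mask) * 1e6
      tfrac <- vapply(thirds, function(m)
        sum(thromb * areas * m) / max(sum(areas[m]), 1e-300), numeric(1))
      volume <- rbind(volume, data.frame(
        time = state$t, volume_cm3 = tm$volume_cm3,
        fl_fraction = fl_thromb / fl_vol_cm3,
        frac_prox = tfrac[["prox"]], frac_mid = tfrac[["mid"]],
        frac_dist = tfrac[["dist"]]))
      if (length(state$flap_w)) {
        flap_history <- rbind(flap_history, state$flap_w)
        flap_times <- c(flap_times, state$t)
      }
    }
    state <- publish_cycle(state)
    dg <- state$diag
    mass_err <- max(abs(dg$Qin - dg$Qout)) /
      max(max(abs(dg$Qin)), 1e-12)
    vol_now <- volume$volume_cm3[nrow(volume)]
    cycles[[length(cycles) + 1L]] <- data.frame(
      cycle = cyc, phase = if (is_pre) "pre" else "thrombosis",
      t_end = state$t, volume_cm3 = vol_now,
      fl_fraction = volume$fl_fraction[nrow(volume)],
      flap_max_mm = if (length(state$flap_w)) max(abs(state$flap_w)) / 1e-3 else 0,
      KE = dg$KE[nrow(dg)], umax = max(dg$umax),
      cg_iters = mean(dg$cg_iters), mass_err = mass_err,
      wall_s = proc.time()[["elapsed"]] - t_cyc0)
    say(sprintf("cycle %d (%s): V = %.4g cm^3 (FL %.1f%%), flap %.3g mm, umax %.3g m/s [%.1f s]",
                cyc, if (is_pre) "pre" else "thromb", vol_now,
                100 * volume$fl_fraction[nrow(volume)],
                if (length(state$flap_w)) max(abs(state$flap_w)) / 1e-3 else 0,
                max(dg$umax),
                proc.time()[["elapsed"]] - t_cyc0))
    if (!is.finite(dg$KE[nrow(dg)]))
      stop("kinetic energy non-finite at cycle ", cyc)

    # checkpoint / outputs
    out_dir <- config$run$output_dir
    if (!is.null(out_dir)) {
      dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
      if (config$run$checkpoint_every > 0 &&
          cyc %% config$run$checkpoint_every == 0L) {
        ck_path <- file.path(out_dir, sprintf("checkpoint_c%03d.rds", cyc))
        saveRDS(list(hash = config_hash(config), state = state,
                     volume = volume, flap_history = flap_history,
                     flap_times = flap_times, cycles = cycles, cycle = cyc),
                ck_path)
      }
      if (config$run$vtk_every > 0 && cyc %% config$run$vtk_every == 0L) {
        write_vtk(sim$mesh, file.path(out_dir, sprintf("fields_c%03d.vtk", cyc)),
                  fields = list(p = state$p, BP = state$BP, AP = state$AP,
                                mu = state$mu, gamma = state$gamma))
      }
      manifest_rows <- do.call(rbind, cycles)
      manifest <- list(config_hash = config_hash(config),
                       code_version = as.character(utils::packageVersion("fltsim")),
                       cycles = manifest_rows,
                       termination = "running")
      tmp <- file.path(out_dir, ".manifest.json.tmp")
      jsonlite::write_json(manifest, tmp, auto_unbox = TRUE, digits = NA,
                           dataframe = "rows")
      file.rename(tmp, file.path(out_dir, "manifest.json"))
    }

    # convergence: no further growth
    if (!is_pre && thromb_on) {
      if (abs(vol_now - prev_vol) < config$run$growth_tol * fl_vol_cm3 &&
          cyc > config$run$pre_cycles + 2L) {
        termination <- "converged (no further growth)"
        prev_vol <- vol_now
        break
      }
      prev_vol <- vol_now
    }
  }

  cycles_df <- do.call(rbind, cycles)
  manifest <- list(config_hash = config_hash(config),
                   code_version = as.character(utils::packageVersion("fltsim")),
                   termination = termination,
                   wall_s = proc.time()[["elapsed"]] - t_wall0)
  out_dir <- config$run$output_dir
  if (!is.null(out_dir)) {
    utils::write.csv(volume, file.path(out_dir, "volume_trace.csv"),
                     row.names = FALSE)
    utils::write.csv(cycles_df, file.path(out_dir, "cycles.csv"),
                     row.names = FALSE)
    m2 <- c(manifest, list(cycles = cycles_df))
    tmp <- file.path(out_dir, ".manifest.json.tmp")
    jsonlite::write_json(m2, tmp, auto_unbox = TRUE, digits = NA,
                         dataframe = "rows")
    file.rename(tmp, file.path(out_dir, "manifest.json"))
  }
  structure(list(state = state, config = config, volume = volume,
                 flap_history = flap_history, flap_times = flap_times,
                 cycles = cycles_df, manifest = manifest,
                 period = period, termination = termination),
            class = "flt_run")
}

#' @exportS3Method base::print
print.flt_run <- function(x, ...) {
  cat("fltsim run:", x$termination, "\n")
  n <- nrow(x$volume)
  if (n) {
    cat(sprintf("  final thrombus volume: %.4g cm^3 (FL fraction %.1f%%) at t = %.3g s\n",
                x$volume$volume_cm3[n], 100 * x$volume$fl_fraction[n],
                x$volume$time[n]))
  }
  if (!is.null(x$flap_history))
    cat(sprintf("  max flap displacement: %.3g mm\n",
                max(abs(x$flap_history)) / 1e-3))
  invisible(x)
}

#' Run the flap-stiffness comparison
#'
#' Runs the same base configuration under several flap presets (the
#' rigid-wall comparator plus stiffer and flexible mobile flaps), then
#' summarizes plateau thrombus volumes, maximum flap displacements and the
#' displacement-volume regression.
#'
#' @param config base [simulation_config()] (its flap block is overridden
#'   per preset).
#' @param presets character vector of flap presets.
#' @param quiet passed to [run_simulation()].
#' @return An object of class `flt_comparison`: per-preset `runs`, the
#'   `summary` data frame and the `regression` (NULL if fewer than two
#'   usable runs). Failed presets are reported in `errors`.
#' @export
run_comparison <- function(config = simulation_config(),
                           presets = c("rigid", "stiffer", "flexible"),
                           quiet = FALSE) {
  runs <- list(); errors <- list()
  for (pr in presets) {
    cfg <- config
    cfg$flap$preset <- pr
    cfg$flap$E_flap <- NULL
    res <- tryCatch(run_simulation(cfg, quiet = quiet),
                    error = function(e) e)
    if (inherits(res, "error")) {
      errors[[pr]] <- conditionMessage(res)
      warning("preset '", pr, "' failed: ", conditionMessage(res))
    } else runs[[pr]] <- res
  }
  summary <- do.call(rbind, lapply(names(runs), function(pr) {
    r <- runs[[pr]]
    n <- nrow(r$volume)
    data.frame(preset = pr,
               max_displacement_mm = if (!is.null(r$flap_history))
                 max(abs(r$flap_history)) / 1e-3 else 0,
               plateau_volume_cm3 = r$volume$volume_cm3[n],
               fl_fraction = r$volume$fl_fraction[n],
               termination = r$termination)
  }))
  regression <- NULL
  if (!is.null(summary) && nrow(summary) >= 2 &&
      length(unique(summary$max_displacement_mm)) >= 2) {
    regression <- displacement_volume_regression(
      summary$max_displacement_mm, summary$plateau_volume_cm3)
  }
  structure(list(runs = runs, summary = summary, regression = regression,
                 errors = errors),
            class = "flt_comparison")
}

#' @exportS3Method base::print
print.flt_comparison <- function(x, ...) {
  cat("fltsim flap-stiffness comparison\n")
  if (!is.null(x$summary)) print(x$summary, row.names = FALSE)
  if (!is.null(x$regression))
    cat(sprintf("  volume = %.4g + %.4g * displacement  (R^2 = %.4f)\n",
                x$regression$intercept, x$regression$slope,
                x$regression$r_squared))
  if (length(x$errors))
    cat("  failed presets:", paste(names(x$errors), collapse = ", "), "\n")
  invisible(x)
}

#' Desk-scale mini dissection configuration
#'
#' A reduced problem size for minutes-scale end-to-end runs: a 90 mm
#' dissected segment with 15 mm extensions, coarsened channel rows and a
#' shortened cycle protocol. The model constants are untouched; only
#' domain size and resolution shrink.
#'
#' @param ... overrides forwarded to [simulation_config()].
#' @return A `simulation_config`.
#' @export
mini_dissection_config <- function(...) {
  # tears keep the full geometry's proportional inset (12.5% of the
  # dissected length from each FL extremity)
  base <- list(
    geometry = list(dissected_length = 90, inlet_extension = 15,
                    outlet_extension = 15,
                    entry_tear_center = 15 + 11.25,
                    reentry_tear_center = 15 + 90 - 11.25),
    mesh = list(target_edge_length = 0.8, dx_axial = 1.25, dy_channel = 1.6),
    run = list(pre_cycles = 2, cycles = 12, steps_per_cycle = 2400))
  dots <- list(...)
  for (blk in names(dots)) {
    if (blk %in% names(base)) {
      for (key in names(dots[[blk]])) base[[blk]][[key]] <- dots[[blk]][[key]]
    } else base[[blk]] <- dots[[blk]]
  }
  do.call(simulation_config, base)
}

#' Generate deterministic verification fixtures
#'
#' Programmatically built inputs for the test suite; identical invocations
#' produce identical objects (and files, when `dir` is given).
#'
#' * `benchmark_channel`: a 10 x 1 (dimensionless) structured channel mesh.
#' * `manufactured_solution`: closed-form advected/diffusing Gaussian with
#'   its exact solution and source, for CDR convergence tests.
#' * `frozen_flow_thrombosis`: a quiescent-FL dissection state with a
#'   prescribed TL plug flow, so the thrombosis stepper can be exercised
#'   without the flow solver.
#' * `mini_dissection`: the coarse end-to-end mesh (a few thousand cells).
#'
#' @param kind fixture name.
#' @param dir optional directory; when given, a VTK/CSV snapshot of the
#'   fixture is written there.
#' @return The fixture object (mesh, list, or state).
#' @export
generate_fixtures <- function(kind = c("benchmark_channel",
                                       "manufactured_solution",
                                       "frozen_flow_thrombosis",
                                       "mini_dissection"),
                              dir = NULL) {
  kind <- match.arg(kind)
  fx <- switch(kind,
    benchmark_channel = benchmark_channel(10, 1, 0.1, unit = "m"),
    manufactured_solution = {
      # Gaussian advected by (u0, 0) and diffused with D, plus linear decay
      u0 <- 0.5; D <- 1e-3; lam <- 0.2; s0 <- 0.05
      list(u0 = u0, D = D, lambda = lam, sigma0 = s0,
           exact = function(x, y, t) {
             s2 <- s0^2 + 2 * D * t
             exp(-lam * t) * (s0^2 / s2) *
               exp(-((x - 0.3 - u0 * t)^2 + (y - 0.5)^2) / (2 * s2))
           },
           source = function(x, y, t) {
             # reaction term consistent with the exact solution: S = -lam*c
             s2 <- s0^2 + 2 * D * t
             -lam * exp(-lam * t) * (s0^2 / s2) *
               exp(-((x - 0.3 - u0 * t)^2 + (y - 0.5)^2) / (2 * s2))
           })
    },
    frozen_flow_thrombosis = {
      cfg <- mini_dissection_config()
      sim <- assemble_simulation(cfg)
      st <- sim$state
      # prescribed TL plug flow, FL quiescent; shear field as computed
      tl <- sim$mesh$tl_rows
      st$u[, tl] <- 0.2
      st
    },
    mini_dissection = {
      cfg <- mini_dissection_config()
      sim <- assemble_simulation(cfg)
      sim$mesh
    })
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    if (inherits(fx, "flt_mesh"))
      write_vtk(fx, file.path(dir, paste0(kind, ".vtk")))
    if (inherits(fx, "flt_state"))
      write_vtk(fx$mesh, file.path(dir, paste0(kind, ".vtk")),
                fields = list(u_cell = (fx$u[-1, ] + fx$u[-nrow(fx$u), ]) / 2))
  }
  fx
}
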