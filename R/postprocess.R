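# Derived quantities: vorticity and lambda2 vortex identification, cut-plane
# pressure differences, thrombus growth-phase segmentation, the
# displacement-volume regression and per-cycle field summaries.

# cell-centered velocity gradients with the solver's discrete operators
velocity_gradients <- function(state) {
  mesh <- state$mesh
  nx <- mesh$nx; ny <- mesh$ny
  dx <- mesh$dx[1]; dy <- mesh$dy
  yc <- mesh$y_centers
  u <- state$u; v <- state$v
  ux <- (u[-1, , drop = FALSE] - u[-(nx + 1), , drop = FALSE]) / dx
  vy <- sweep(v[, -1, drop = FALSE] - v[, -(ny + 1), drop = FALSE],
              2, dy, "/")
  ubar <- (u[-(nx + 1), , drop = FALSE] + u[-1, , drop = FALSE]) / 2
  vbar <- (v[, -(ny + 1), drop = FALSE] + v[, -1, drop = FALSE]) / 2
  uy <- matrix(0, nx, ny); vx <- matrix(0, nx, ny)
  for (j in seq_len(ny)) {       # d(ubar)/dy, no-slip ghosts at walls
    if (j == 1) {
      uy[, j] <- (ubar[, 2] + ubar[, 1]) / (yc[2] - yc[1] + dy[1])
    } else if (j == ny) {
      uy[, j] <- (-ubar[, ny] - ubar[, ny - 1]) / (yc[ny] - yc[ny - 1] + dy[ny])
    } else {
      uy[, j] <- (ubar[, j + 1] - ubar[, j - 1]) / (yc[j + 1] - yc[j - 1])
    }
  }
  vx[1, ] <- (vbar[2, ] - vbar[1, ]) / dx
  vx[nx, ] <- (vbar[nx, ] - vbar[nx - 1, ]) / dx
  if (nx > 2)
    vx[2:(nx - 1), ] <- (vbar[3:nx, ] - vbar[1:(nx - 2), ]) / (2 * dx)
  list(ux = ux, uy = uy, vx = vx, vy = vy)
}

#' Out-of-plane vorticity field
#'
#' \eqn{\omega = \partial v/\partial x - \partial u/\partial y} at cell
#' centers, using the same discrete gradients as the solver. Rigid rotation
#' at angular rate \eqn{\Omega} gives \eqn{\omega = 2\Omega}; uniform flow
#' gives zero.
#'
#' @param state an `flt_state`.
#' @return nx-by-ny matrix of vorticity, 1/s.
#' @export
vorticity_field <- function(state) {
  g <- velocity_gradients(state)
  g$vx - g$uy
}

#' Vortex identification by the 2D lambda2 criterion
#'
#' Computes the lower eigenvalue of \eqn{S^2 + \Omega^2} (the 2D analog of
#' the lambda2 criterion, equal to \eqn{-Q}), flags cells below the
#' threshold and labels 4-connected regions. Galilean invariant: adding a
#' uniform translation leaves the velocity-gradient tensor unchanged.
#'
#' @param state an `flt_state`.
#' @param threshold flag cells with \eqn{\lambda_2 <} `threshold`, 1/s^2.
#' @return List: `lambda2` (matrix, 1/s^2), `labels` (integer matrix, 0 =
#'   unflagged), `regions` (data frame: label, n_cells, area_m2).
#' @export
vortex_regions <- function(state, threshold = -10) {
  g <- velocity_gradients(state)
  # sym(J^2) for J = [[ux, uy], [vx, vy]]
  a <- g$ux^2 + g$uy * g$vx
  d <- g$vx * g$uy + g$vy^2
  bc <- (g$ux * g$uy + g$uy * g$vy + g$vx * g$ux + g$vy * g$vx) / 2
  lam2 <- (a + d) / 2 - sqrt(((a - d) / 2)^2 + bc^2)
  flag <- lam2 < threshold & state$mesh$cell_type == 1L
  labels <- matrix(0L, nrow(flag), ncol(flag))
  nx <- nrow(flag); ny <- ncol(flag)
  lab <- 0L
  idx <- which(flag)
  for (c0 in idx) {
    if (labels[c0] != 0L) next
    lab <- lab + 1L
    queue <- c0
    labels[c0] <- lab
    while (length(queue)) {
      c1 <- queue[1]; queue <- queue[-1]
      i <- (c1 - 1L) %% nx + 1L; j <- (c1 - 1L) %/% nx + 1L
      for (nb in c(if (i > 1) c1 - 1L, if (i < nx) c1 + 1L,
                   if (j > 1) c1 - nx, if (j < ny) c1 + nx)) {
        if (flag[nb] && labels[nb] == 0L) {
          labels[nb] <- lab
          queue <- c(queue, nb)
        }
      }
    }
  }
  areas <- cell_areas(state$mesh)
  regions <- if (lab == 0L) {
    data.frame(label = integer(0), n_cells = integer(0), area_m2 = numeric(0))
  } else {
    do.call(rbind, lapply(seq_len(lab), function(l) {
      sel <- labels == l
      data.frame(label = l, n_cells = sum(sel), area_m2 = sum(areas[sel]))
    }))
  }
  list(lambda2 = lam2, labels = labels, regions = regions)
}

#' Default cut-plane locations for a dissection domain
#'
#' Proximal at the entry-tear level, distal at the re-entry-tear level and
#' middle halfway between the tears (the relative placement of the paper's
#' fixed middle cut, scaled to this domain).
#'
#' @param domain a [build_dissection_geometry()] result.
#' @return Data frame: `name`, `x` (m).
#' @export
cut_planes <- function(domain) {
  g <- domain$params
  data.frame(
    name = c("proximal", "middle", "distal"),
    x = c(g$entry_tear_center,
          (g$entry_tear_center + g$reentry_tear_center) / 2,
          g$reentry_tear_center) * 1e-3
  )
}

#' Cut-plane TL-FL pressure difference
#'
#' Spatially averaged pressure over the TL and FL cross-sections at each
#' cut's axial position; \eqn{\Delta P = \bar P_{TL} - \bar P_{FL}}.
#'
#' @param state an `flt_state` on a dissection mesh.
#' @param cuts data frame with columns `name` and `x` (m), e.g. from
#'   [cut_planes()].
#' @return Data frame: `name`, `x`, `dp` (Pa).
#' @export
cut_plane_dp <- function(state, cuts = cut_planes(state$mesh$domain)) {
  mesh <- state$mesh
  if (mesh$kind != "dissection") stop("cut planes require a dissection mesh")
  rng <- range(mesh$x_centers)
  out <- cuts
  out$dp <- NA_real_
  for (k in seq_len(nrow(cuts))) {
    x <- cuts$x[k]
    if (x < rng[1] || x > rng[2])
      stop("cut '", cuts$name[k], "' at x = ", x, " m lies outside the domain")
    i <- which.min(abs(mesh$x_centers - x))
    tl <- mesh$tl_rows[mesh$cell_type[i, mesh$tl_rows] == 1L]
    fl <- mesh$fl_rows[mesh$cell_type[i, mesh$fl_rows] == 1L]
    if (!length(tl) || !length(fl))
      stop("cut '", cuts$name[k], "' does not intersect both lumens")
    wtl <- mesh$dy[tl]; wfl <- mesh$dy[fl]
    out$dp[k] <- sum(state$p[i, tl] * wtl) / sum(wtl) -
                 sum(state$p[i, fl] * wfl) / sum(wfl)
  }
  out
}

#' Segment a thrombus volume trace into growth phases
#'
#' Splits the (non-decreasing) volume trace into time-lag, accelerated and
#' plateau phases using a 10%-of-peak-rate rule: the lag ends when the
#' growth rate first exceeds 10% of its maximum, the plateau starts when it
#' last falls below that level, and the accelerated phase is the interval
#' between. Rates are central differences over a one-window span.
#'
#' @param time time vector, s.
#' @param volume thrombus volume trace, cm^3 (non-decreasing).
#' @param window rate-estimation window, s (typically one cardiac cycle).
#' @param rate_fraction phase-boundary threshold as a fraction of the peak
#'   rate.
#' @return List of class `growth_phases`: `lag_end`, `accelerated_end`,
#'   `plateau_value`, `phase_rates` (cm^3/s), `degenerate`.
#' @export
growth_phase_segmentation <- function(time, volume, window = NULL,
                                      rate_fraction = 0.1) {
  stopifnot(length(time) == length(volume), length(time) >= 3)
  if (any(diff(volume) < -1e-9 * max(abs(volume), 1)))
    stop("volume trace is not non-decreasing; upstream monotonicity bug")
  if (is.null(window)) window <- diff(range(time)) / 10
  tmid <- time
  rate <- numeric(length(time))
  for (k in seq_along(time)) {
    t0 <- max(min(time), time[k] - window / 2)
    t1 <- min(max(time), time[k] + window / 2)
    v0 <- stats::approx(time, volume, t0)$y
    v1 <- stats::approx(time, volume, t1)$y
    rate[k] <- (v1 - v0) / (t1 - t0)
  }
  rmax <- max(rate)
  if (rmax <= 0) {
    return(structure(list(lag_end = NA_real_, accelerated_end = NA_real_,
                          plateau_value = volume[length(volume)],
                          phase_rates = c(lag = NA, accelerated = NA,
                                          plateau = NA),
                          degenerate = TRUE), class = "growth_phases"))
  }
  above <- which(rate > rate_fraction * rmax)
  lag_end <- tmid[min(above)]
  accelerated_end <- tmid[max(above)]
  seg_rate <- function(t0, t1) {
    if (t1 <= t0) return(NA_real_)
    (stats::approx(time, volume, t1)$y - stats::approx(time, volume, t0)$y) /
      (t1 - t0)
  }
  structure(list(
    lag_end = lag_end, accelerated_end = accelerated_end,
    plateau_value = volume[length(volume)],
    phase_rates = c(lag = seg_rate(min(time), lag_end),
                    accelerated = seg_rate(lag_end, accelerated_end),
                    plateau = seg_rate(accelerated_end, max(time))),
    degenerate = FALSE), class = "growth_phases")
}

#' @exportS3Method base::print
print.growth_phases <- function(x, ...) {
  if (x$degenerate) {
    cat("Growth phases: degenerate (no growth)\n")
  } else {
    cat(sprintf("Growth phases: lag to %.3g s, accelerated to %.3g s, plateau %.4g cm^3\n",
                x$lag_end, x$accelerated_end, x$plateau_value))
  }
  invisible(x)
}

#' Regression of plateau thrombus volume on maximum flap displacement
#'
#' Ordinary least squares of volume (cm^3) on displacement (mm) across
#' flap-stiffness runs.
#'
#' @param displacement_mm maximum flap displacement per run, mm.
#' @param volume_cm3 plateau thrombus volume per run, cm^3.
#' @return List: `slope` (cm^3/mm), `intercept` (cm^3), `r_squared`, `n`,
#'   `underdetermined` (TRUE for exactly two points).
#' @export
displacement_volume_regression <- function(displacement_mm, volume_cm3) {
  stopifnot(length(displacement_mm) == length(volume_cm3))
  if (length(displacement_mm) < 2)
    stop("need at least two runs for the regression")
  if (length(unique(displacement_mm)) < 2)
    stop("identical displacement values: regression undefined")
  fit <- stats::lm(volume_cm3 ~ displacement_mm)
  # exact fits trigger a harmless "perfect fit" note from summary.lm
  s <- suppressWarnings(summary(fit))
  list(slope = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]),
       r_squared = s$r.squared,
       n = length(displacement_mm),
       underdetermined = length(displacement_mm) == 2L)
}

#' Region means of the cycle-averaged fields
#'
#' Area-weighted means of cycle-averaged viscosity, shear rate and activated
#' platelets over the TL, the FL and the thrombosed region.
#'
#' @param state an `flt_state` holding published cycle averages (populated
#'   by [run_simulation()] at each cycle boundary in `state$cycle_avg`).
#' @param regions named list of logical cell masks; defaults to TL, FL and
#'   thrombus (\eqn{BP \ge BP_t}).
#' @return Data frame: `region`, `area_m2`, `mean_mu`, `mean_gamma`,
#'   `mean_AP`; empty regions yield NA (reported as missing, not zero).
#' @export
field_cycle_summary <- function(state, regions = NULL) {
  if (is.null(state$cycle_avg))
    stop("no completed cycle: cycle averages unavailable")
  ca <- state$cycle_avg
  if (is.null(regions)) {
    regions <- list(TL = tl_region_mask(state$mesh),
                    FL = fl_region_mask(state$mesh),
                    thrombus = state$BP >= state$thromb$BP_t &
                               state$mesh$cell_type == 1L)
  }
  areas <- cell_areas(state$mesh)
  do.call(rbind, lapply(names(regions), function(nm) {
    m <- regions[[nm]]
    A <- sum(areas[m])
    if (A == 0) {
      return(data.frame(region = nm, area_m2 = 0, mean_mu = NA_real_,
                        mean_gamma = NA_real_, mean_AP = NA_real_))
    }
    wmean <- function(f) sum(f[m] * areas[m]) / A
    data.frame(region = nm, area_m2 = A,
               mean_mu = wmean(ca$avg_mu),
               mean_gamma = wmean(ca$avg_gamma),
               mean_AP = wmean(ca$avg_AP))
  }))
}
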