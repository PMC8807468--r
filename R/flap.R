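# Reduced-order mobile intimal flap: a quasi-static, pressure-loaded
# clamped-clamped Euler-Bernoulli beam (optionally on an elastic foundation
# standing in for the circumferential plate stiffness lost in the planar
# reduction), loosely coupled to the flow through under-relaxed displacement
# updates and a moving penalized solid band.

#' Flap model parameters
#'
#' The flap is a linearly elastic strip of thickness `thickness` clamped at
#' both extremities of the dissected segment, deflecting transversally under
#' the transmural pressure difference:
#' \deqn{E I w'''' + k_f w = \Delta P(x), \qquad I = t^3/12}
#' (per unit depth). `k_f` is an optional Winkler-foundation stiffness that
#' restores the circumferential bending restraint a real flap strip has in
#' three dimensions (see [foundation_from_plate()]); without it a
#' 200 mm-span, 0.8 mm-thick beam would be orders of magnitude too soft.
#' Presets: `"rigid"` (no motion), `"stiffer"` (E = 60 MPa), `"flexible"`
#' (E = 6.75 MPa).
#'
#' @param E_flap Young's modulus in Pa, `Inf`, or one of the preset names.
#' @param thickness flap thickness, m.
#' @param span clamped span (dissected length), m.
#' @param foundation Winkler foundation stiffness, Pa/m (0 = pure beam;
#'   `NULL` in [simulation_config()] derives it from the plate analogy).
#' @param cap displacement cap, m (mesh-safety bound, well above the
#'   physical excursions).
#' @param relax under-relaxation factor in (0, 1] for the partitioned
#'   flow-flap coupling.
#' @return An object of class `flap_params`.
#' @export
flap_params <- function(E_flap = "flexible", thickness = 0.8e-3,
                        span = 0.2, foundation = 0,
                        cap = NULL, relax = 0.02) {
  presets <- c(rigid = Inf, stiffer = 60e6, flexible = 6.75e6)
  if (is.character(E_flap)) {
    E_flap <- match.arg(E_flap, names(presets))
    E <- unname(presets[E_flap])
  } else E <- E_flap
  if (!is.numeric(E) || length(E) != 1L || is.na(E) || E <= 0)
    stop("E_flap must be a positive modulus in Pa, Inf, or a preset name")
  stopifnot(thickness > 0, span > 0, relax > 0, relax <= 1,
            is.null(foundation) || foundation >= 0)
  if (is.null(cap)) cap <- 0.4 * 19.4e-3   # 40% of the narrower lumen
  structure(list(E_flap = E, thickness = thickness, span = span,
                 I = thickness^3 / 12,
                 foundation = if (is.null(foundation)) 0 else foundation,
                 cap = cap, relax = relax, rigid = !is.finite(E)),
            class = "flap_params")
}

#' Foundation stiffness from the circumferential plate analogy
#'
#' In the 3D vessel the flap strip is clamped along its longitudinal edges
#' and bends mainly across its width b; a clamped strip under uniform load q
#' deflects \eqn{q b^4 / (384 D)} with plate rigidity
#' \eqn{D = E t^3 / (12 (1 - \nu^2))}. The equivalent distributed stiffness
#' \eqn{k_f = 384 D / b^4} reintroduces that restraint in the planar model.
#'
#' @param E_flap Young's modulus, Pa.
#' @param thickness flap thickness, m.
#' @param width transverse strip width (the FL width), m.
#' @param poisson Poisson ratio of the flap tissue.
#' @return Foundation stiffness, Pa/m.
#' @export
foundation_from_plate <- function(E_flap, thickness = 0.8e-3,
                                  width = 23e-3, poisson = 0.45) {
  if (!is.finite(E_flap)) return(Inf)
  D <- E_flap * thickness^3 / (12 * (1 - poisson^2))
  384 * D / width^4
}

# clamped-clamped beam operator on n stations with spacing h; clamped ends
# sit one spacing outside the first/last station (w = w' = 0 there)
beam_matrix <- function(n, h, EI, kf = 0) {
  K <- matrix(0, n, n)
  add <- function(k, m, val) {
    if (m >= 1 && m <= n) K[k, m] <<- K[k, m] + val
  }
  c4 <- EI / h^4
  for (k in seq_len(n)) {
    # stencil w_{k-2} - 4 w_{k-1} + 6 w_k - 4 w_{k+1} + w_{k+2}
    add(k, k - 2, c4); add(k, k - 1, -4 * c4); add(k, k, 6 * c4)
    add(k, k + 1, -4 * c4); add(k, k + 2, c4)
    # clamped ghosts: w_0ghost = 0, w_{-1}ghost mirrors station 1
    if (k == 1) add(k, 1, c4)       # w_{-1} = w_1
    if (k == n) add(k, n, c4)       # w_{n+2} = w_n
    K[k, k] <- K[k, k] + kf
  }
  K
}

#' Solve the clamped flap beam for a given load
#'
#' Quasi-static deflection of the clamped-clamped Euler-Bernoulli beam
#' (optionally on an elastic foundation) under a distributed transmural
#' load. With `foundation = 0` and uniform load q the midspan deflection
#' approaches the classical \eqn{q L^4 / (384 E I)}.
#'
#' @param load per-station transmural load, Pa (positive pushes toward the
#'   FL); length defines the number of stations.
#' @param params a [flap_params()] object. Rigid short-circuits to zero.
#' @param tears optional logical vector flagging stations inside a tear
#'   (no material: zero load there and zero reported displacement).
#' @return Displacement per station, m (positive toward the FL).
#' @export
solve_flap <- function(load, params, tears = NULL) {
  stopifnot(inherits(params, "flap_params"))
  n <- length(load)
  if (n < 3) stop("need at least 3 flap stations")
  if (any(!is.finite(load))) stop("non-finite flap load")
  if (params$rigid) return(numeric(n))
  if (!is.null(tears)) load[tears] <- 0
  h <- params$span / (n + 1)
  K <- beam_matrix(n, h, params$E_flap * params$I, params$foundation)
  w <- solve(K, load)
  if (!is.null(tears)) w[tears] <- 0
  w
}

#' Assemble the flap system for a dissection mesh
#'
#' Locates the flap columns, precomputes the beam-operator inverse used by
#' the in-loop quasi-static update, and flags tear stations.
#'
#' @param mesh a dissection `flt_mesh`.
#' @param params a [flap_params()] object; its `span` is overridden by the
#'   meshed dissected length.
#' @return A list consumed by [flow_state()]: `cols` (1-based mesh columns),
#'   `x` (station coordinates, m), `tear` (logical), `Minv` (load-to-
#'   displacement matrix), `y0`, `y1` (rest flap faces, m), `cap`, `rigid`,
#'   `params`.
#' @export
build_flap_system <- function(mesh, params = flap_params()) {
  stopifnot(inherits(mesh, "flt_mesh"))
  if (mesh$kind != "dissection") stop("flap system requires a dissection mesh")
  dom <- mesh$domain
  xmm <- mesh$x_centers / 1e-3
  cols <- which(xmm > dom$flap$x0 & xmm < dom$flap$x1)
  if (length(cols) < 3) stop("dissected segment too short for the flap model")
  te <- dom$flap$tears
  tear <- (xmm[cols] > te$entry[1] & xmm[cols] < te$entry[2]) |
          (xmm[cols] > te$reentry[1] & xmm[cols] < te$reentry[2])
  span <- (dom$flap$x1 - dom$flap$x0) * 1e-3
  params$span <- span
  n <- length(cols)
  Minv <- if (params$rigid) matrix(0, 0, 0) else {
    h <- span / (n + 1)
    solve(beam_matrix(n, h, params$E_flap * params$I, params$foundation))
  }
  cap <- min(params$cap,
             0.4 * min(dom$params$tl_width, dom$params$fl_width) * 1e-3)
  list(cols = cols, x = mesh$x_centers[cols], tear = tear, Minv = Minv,
       y0 = dom$flap$y0 * 1e-3, y1 = dom$flap$y1 * 1e-3,
       cap = cap, rigid = params$rigid, params = params)
}

#' Transmural pressure load on the flap
#'
#' Samples the pressure on the two flap faces (cell rows immediately below
#' and above the flap band) and returns their difference per station,
#' zeroed over the tear gaps where there is no material.
#'
#' @param state an `flt_state` on a dissection mesh with a flap system.
#' @return Data frame: `x` (station, m), `dp` (P_TL - P_FL, Pa), `tear`.
#' @export
transmural_load <- function(state) {
  stopifnot(inherits(state, "flt_state"))
  flap <- state$flap
  if (is.null(flap)) stop("state has no flap system")
  mesh <- state$mesh
  jlo <- min(mesh$flap_rows) - 1L
  jhi <- max(mesh$flap_rows) + 1L
  dp <- state$p[cbind(flap$cols, jlo)] - state$p[cbind(flap$cols, jhi)]
  dp[flap$tear] <- 0
  data.frame(x = flap$x, dp = dp, tear = flap$tear)
}

#' Apply a flap displacement to the mesh (penalized-interface update)
#'
#' The flap is realized as a movable penalized solid band on the fixed
#' grid: this updates the per-cell flap occupancy fraction for the given
#' station displacements and reports the interface velocity that the
#' momentum penalization imposes on the fluid. Zero displacement returns
#' the mesh unchanged. Displacement increments that would exceed the cap
#' are halved until admissible (and flagged).
#'
#' @param mesh a dissection `flt_mesh`.
#' @param displacement per-station flap displacement, m (positive toward
#'   the FL), aligned with `flap$cols`.
#' @param flap the [build_flap_system()] list describing the stations.
#' @param dt time increment, s (for the interface velocity).
#' @param prev_displacement previous displacement (defaults to zero).
#' @return List: `mesh` (occupancy-updated), `w` (interface velocity per
#'   station, m/s), `halvings` (number of cap-enforcement halvings).
#' @export
move_mesh <- function(mesh, displacement, flap, dt,
                      prev_displacement = NULL) {
  stopifnot(inherits(mesh, "flt_mesh"), dt > 0)
  n <- length(flap$cols)
  stopifnot(length(displacement) == n)
  if (is.null(prev_displacement)) prev_displacement <- numeric(n)
  halvings <- 0L
  d <- displacement
  while (any(abs(d) > flap$cap) && halvings < 30L) {
    d <- prev_displacement + (d - prev_displacement) / 2
    halvings <- halvings + 1L
  }
  if (any(abs(d) > flap$cap))
    stop("flap displacement exceeds the cap even after repeated halving")
  if (all(d == prev_displacement) && all(d == 0))
    return(list(mesh = mesh, w = numeric(n), halvings = halvings))
  frac <- mesh$flap_frac
  frac[flap$cols, ] <- 0
  yf <- mesh$y_faces
  dy <- mesh$dy
  for (k in seq_len(n)) {
    if (flap$tear[k]) next
    i <- flap$cols[k]
    lo <- flap$y0 + d[k]; hi <- flap$y1 + d[k]
    jj <- which(yf[-length(yf)] < hi & yf[-1] > lo)
    ov <- pmin(hi, yf[jj + 1]) - pmax(lo, yf[jj])
    frac[i, jj] <- pmin(1, ov / dy[jj])
  }
  mesh$flap_frac <- frac
  list(mesh = mesh, w = (d - prev_displacement) / dt, halvings = halvings)
}

#' Per-cycle maxima of flap displacement
#'
#' @param times time vector, s.
#' @param W displacement history, matrix `length(times)` x n_stations, m.
#' @param period cycle period, s.
#' @param cuts named list of station indices to report individually (e.g.
#'   `list(proximal = 5, distal = 120)`); the global maximum is always
#'   included as station `"global"`.
#' @return Data frame: `cycle`, `station`, `max_mm`.
#' @export
max_flap_displacement <- function(times, W, period, cuts = list()) {
  stopifnot(length(times) == nrow(W), period > 0)
  cyc <- floor((times - min(times)) / period * (1 - 1e-12)) + 1L
  out <- list()
  for (cy in sort(unique(cyc))) {
    rows <- which(cyc == cy)
    block <- abs(W[rows, , drop = FALSE])
    out[[length(out) + 1L]] <-
      data.frame(cycle = cy, station = "global",
                 max_mm = max(block) / 1e-3)
    for (nm in names(cuts))
      out[[length(out) + 1L]] <-
        data.frame(cycle = cy, station = nm,
                   max_mm = max(block[, cuts[[nm]]]) / 1e-3)
  }
  do.call(rbind, out)
}
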