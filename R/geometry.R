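# Planar two-channel dissection analog and structured meshing.
#
# Layout (transverse y, axial x, all geometry inputs in mm):
#   y = 0 ............ outer wall (TL side)
#   0 .. tl_width .................. true lumen, open from inlet to outlet
#   tl_width .. +flap_thickness .... intimal flap strip (solid, torn at the
#                                    entry and re-entry tears)
#   .. +fl_width ................... false lumen, closed at both extremities
# The FL and flap exist only over the dissected axial extent; proximal and
# distal of it the vessel is a plain TL-width channel. The solver works in SI
# meters; conversion happens once, at mesh build.

MM <- 1e-3

#' Dissection geometry parameters (2D analog)
#'
#' Channel widths stand in for the lumen diameters of the tube-in-tube
#' dissection; the two tears are axial gaps of length `tear_length` in the
#' flap strip. Axial positions are measured from the inlet.
#'
#' @param tl_width true-lumen channel width, mm.
#' @param fl_width false-lumen channel width, mm.
#' @param flap_thickness intimal flap thickness, mm.
#' @param tear_length axial extent of each tear (2D analog of the tear
#'   diameter), mm.
#' @param dissected_length axial extent of the dissected segment, mm.
#' @param inlet_extension,outlet_extension plain-channel lengths proximal and
#'   distal of the dissected segment, mm.
#' @param entry_tear_center,reentry_tear_center axial tear centers, mm from
#'   the inlet. Defaults place each tear 25 mm inside the corresponding FL
#'   extremity.
#' @return An object of class `dissection_geometry` (lengths in mm).
#' @export
#' @examples
#' geo <- dissection_geometry()
#' dom <- build_dissection_geometry(geo)
#' dom$height_mm   # 19.4 + 0.8 + 23.0 = 43.2 between the outer walls
dissection_geometry <- function(tl_width = 19.4,
                                fl_width = 23.0,
                                flap_thickness = 0.8,
                                tear_length = 10.0,
                                dissected_length = 200,
                                inlet_extension = 40,
                                outlet_extension = 40,
                                entry_tear_center = NULL,
                                reentry_tear_center = NULL) {
  if (is.null(entry_tear_center))
    entry_tear_center <- inlet_extension + 25
  if (is.null(reentry_tear_center))
    reentry_tear_center <- inlet_extension + dissected_length - 25
  g <- structure(list(tl_width = tl_width, fl_width = fl_width,
                      flap_thickness = flap_thickness,
                      tear_length = tear_length,
                      dissected_length = dissected_length,
                      inlet_extension = inlet_extension,
                      outlet_extension = outlet_extension,
                      entry_tear_center = entry_tear_center,
                      reentry_tear_center = reentry_tear_center),
                 class = "dissection_geometry")
  validate_dissection_geometry(g)
  g
}

validate_dissection_geometry <- function(g) {
  lens <- unlist(g[c("tl_width", "fl_width", "flap_thickness", "tear_length",
                     "dissected_length", "inlet_extension", "outlet_extension")])
  if (any(!is.finite(lens)) || any(lens <= 0))
    stop("invalid geometry: all lengths must be strictly positive (",
         paste(names(lens)[lens <= 0 | !is.finite(lens)], collapse = ", "), ")")
  if (g$entry_tear_center >= g$reentry_tear_center)
    stop("invalid geometry: entry_tear_center (", g$entry_tear_center,
         " mm) must lie proximal of reentry_tear_center (",
         g$reentry_tear_center, " mm)")
  x0 <- g$inlet_extension
  x1 <- g$inlet_extension + g$dissected_length
  e <- g$entry_tear_center + c(-0.5, 0.5) * g$tear_length
  r <- g$reentry_tear_center + c(-0.5, 0.5) * g$tear_length
  if (e[1] <= x0 || r[2] >= x1)
    stop("invalid geometry: tears must lie strictly inside the dissected ",
         "segment [", x0, ", ", x1, "] mm (entry [", e[1], ", ", e[2],
         "], re-entry [", r[1], ", ", r[2], "])")
  if (e[2] >= r[1])
    stop("invalid geometry: tear extents overlap (entry [", e[1], ", ", e[2],
         "] mm vs re-entry [", r[1], ", ", r[2], "] mm)")
  invisible(g)
}

#' Build the planar dissection domain
#'
#' Assembles the fluid region (TL strip, FL strip, two tear openings through
#' the flap) as a set of disjoint axis-aligned rectangles, plus the flap
#' strip description used for meshing and the reduced-order flap model.
#'
#' @param params a [dissection_geometry()] object.
#' @return An object of class `dissection_domain` with elements
#'   `rects` (data frame of fluid rectangles, mm), `height_mm`, `length_mm`,
#'   `flap` (flap band and tear intervals), `area_mm2`.
#' @export
build_dissection_geometry <- function(params = dissection_geometry()) {
  g <- validate_dissection_geometry(params)
  Ltot <- g$inlet_extension + g$dissected_length + g$outlet_extension
  x0 <- g$inlet_extension; x1 <- x0 + g$dissected_length
  yf0 <- g$tl_width                       # flap lower face (TL side)
  yf1 <- g$tl_width + g$flap_thickness    # flap upper face (FL side)
  H <- g$tl_width + g$flap_thickness + g$fl_width
  e <- g$entry_tear_center + c(-0.5, 0.5) * g$tear_length
  r <- g$reentry_tear_center + c(-0.5, 0.5) * g$tear_length
  rects <- data.frame(
    name = c("tl", "fl", "entry_tear", "reentry_tear"),
    x0 = c(0, x0, e[1], r[1]),
    x1 = c(Ltot, x1, e[2], r[2]),
    y0 = c(0, yf1, yf0, yf0),
    y1 = c(g$tl_width, H, yf1, yf1)
  )
  area <- sum((rects$x1 - rects$x0) * (rects$y1 - rects$y0))
  structure(list(
    params = g, rects = rects,
    height_mm = H, length_mm = Ltot, area_mm2 = area,
    flap = list(y0 = yf0, y1 = yf1, x0 = x0, x1 = x1,
                tears = list(entry = e, reentry = r)),
    dissected = c(x0, x1)
  ), class = "dissection_domain")
}

# --- structured mesh --------------------------------------------------------

# y faces for one band of width w starting at y0, target size h, optional
# boundary-layer refinement rows at the side(s) touching a wall/flap
band_faces <- function(y0, w, h, layers = 0L, refine_lo = FALSE, refine_hi = FALSE) {
  n <- max(1L, ceiling(w / h - 1e-9))
  f <- y0 + w * (0:n) / n
  if (layers > 0L && length(f) >= 3) {
    # geometric subdivision of [a, b] into layers+1 rows shrinking toward a
    subdiv_lo <- function(a, b, k) {
      wts <- 0.7^(k:0); wts <- wts / sum(wts)
      a + cumsum(c(0, wts)) * (b - a)
    }
    extra <- c(
      if (refine_lo) subdiv_lo(f[1], f[2], layers),
      if (refine_hi) {
        m <- length(f)
        rev(f[m] - (subdiv_lo(f[m - 1], f[m], layers) - f[m - 1]))
      })
    f <- c(f, extra)
  }
  sort(unique(f))
}

#' Generate a structured mesh of the dissection domain
#'
#' Builds a tensor-product quad mesh (uniform axial spacing, banded
#' transverse spacing) whose y-lines are snapped to the flap faces so the
#' flap strip is resolved by at least 3 cell rows. Cells are classified as
#' fluid, flap (movable solid) or exterior solid; boundary facets between
#' fluid and non-fluid carry exactly one tag from \{inlet, tl_outlet,
#' fl_endwall, outer_wall, flap_tl_side, flap_fl_side, tear_edge\}.
#'
#' @param domain a [build_dissection_geometry()] result.
#' @param target_edge_length target cell size, mm; must not exceed the flap
#'   thickness so the flap strip and tears are resolved.
#' @param wall_layers number of geometric refinement rows added next to each
#'   outer wall and flap face (0 disables).
#' @param dx_axial optional axial spacing override, mm (anisotropic cells for
#'   long domains); defaults to `target_edge_length`.
#' @param dy_channel optional transverse spacing for the channel interiors,
#'   mm (the flap band always keeps at least 3 rows of at most
#'   `target_edge_length`); defaults to `target_edge_length`.
#' @return An object of class `flt_mesh` (coordinates in meters).
#' @export
generate_mesh <- function(domain, target_edge_length, wall_layers = 0L,
                          dx_axial = NULL, dy_channel = NULL) {
  stopifnot(inherits(domain, "dissection_domain"))
  h <- target_edge_length
  if (!is.finite(h) || h <= 0) stop("target_edge_length must be positive")
  g <- domain$params
  if (h > g$flap_thickness + 1e-12)
    stop("target_edge_length (", h, " mm) must not exceed flap_thickness (",
         g$flap_thickness, " mm): the flap strip would be unresolved")
  if (wall_layers < 0) stop("wall_layers must be >= 0")
  if (is.null(dx_axial)) dx_axial <- h
  if (is.null(dy_channel)) dy_channel <- h
  if (dx_axial > g$tear_length / 3 + 1e-12)
    stop("axial spacing (", dx_axial, " mm) too coarse for the ",
         g$tear_length, " mm tears (need >= 3 cells across each tear)")

  Ltot <- domain$length_mm
  nx <- max(3L, round(Ltot / dx_axial))
  x_faces <- Ltot * (0:nx) / nx

  # transverse bands: TL | flap (>= 3 rows) | FL, y-lines snapped to the
  # flap faces so flap occupancy is exact at rest
  h_flap <- min(h, g$flap_thickness / 3)
  y_tl <- band_faces(0, g$tl_width, dy_channel, wall_layers,
                     refine_lo = wall_layers > 0, refine_hi = wall_layers > 0)
  y_fl <- band_faces(domain$flap$y1, g$fl_width, dy_channel, wall_layers,
                     refine_lo = wall_layers > 0, refine_hi = wall_layers > 0)
  n_fr <- max(3L, ceiling(g$flap_thickness / h_flap - 1e-9))
  y_flap <- domain$flap$y0 + g$flap_thickness * (0:n_fr) / n_fr
  y_faces <- sort(unique(c(y_tl, y_flap, y_fl)))
  ny <- length(y_faces) - 1L

  xc <- (x_faces[-1] + x_faces[-(nx + 1)]) / 2
  yc <- (y_faces[-1] + y_faces[-(ny + 1)]) / 2

  in_rect <- function(r, X, Y) X > r$x0 & X < r$x1 & Y > r$y0 & Y < r$y1
  X <- matrix(xc, nx, ny); Y <- matrix(yc, nx, ny, byrow = TRUE)
  fluid <- matrix(FALSE, nx, ny)
  for (k in seq_len(nrow(domain$rects)))
    fluid <- fluid | in_rect(domain$rects[k, ], X, Y)
  flap_band <- Y > domain$flap$y0 & Y < domain$flap$y1
  in_dissected <- X > domain$flap$x0 & X < domain$flap$x1
  flap_cell <- flap_band & in_dissected & !fluid       # flap material
  exterior <- !fluid & !flap_cell                      # outside the vessel
  cell_type <- matrix(0L, nx, ny)                      # 0 exterior solid
  cell_type[fluid] <- 1L                               # 1 fluid
  cell_type[flap_cell] <- 2L                           # 2 flap material

  mesh <- structure(list(
    nx = nx, ny = ny,
    x_faces = x_faces * MM, y_faces = y_faces * MM,
    x_centers = xc * MM, y_centers = yc * MM,
    dx = diff(x_faces) * MM, dy = diff(y_faces) * MM,
    cell_type = cell_type,
    domain = domain,
    flap_rows = which(yc > domain$flap$y0 & yc < domain$flap$y1),
    fl_rows = which(yc > domain$flap$y1),
    tl_rows = which(yc < domain$flap$y0),
    x_faces_ref = x_faces * MM, y_faces_ref = y_faces * MM,
    kind = "dissection"
  ), class = "flt_mesh")
  mesh$facets <- tag_boundary_facets(mesh)
  mesh$flap_frac <- (cell_type == 2L) * 1   # rest-position flap occupancy
  mesh
}

#' Rectangular benchmark channel mesh
#'
#' A plain structured channel used by the flow-solver verification suite,
#' with `inlet` (x = 0), `outlet` (x = L) and `wall` (y = 0, W) tags.
#'
#' @param length,width channel dimensions (same unit; meters if
#'   `unit = "m"`, millimeters if `unit = "mm"`).
#' @param target_edge_length target cell size, same unit.
#' @param unit `"mm"` (default, converted to meters) or `"m"` (taken as is).
#' @param nx,ny optional explicit cell counts (override the target size).
#' @return An object of class `flt_mesh`.
#' @export
benchmark_channel <- function(length, width, target_edge_length,
                              unit = c("mm", "m"), nx = NULL, ny = NULL) {
  unit <- match.arg(unit)
  if (!is.finite(length) || length <= 0 || !is.finite(width) || width <= 0)
    stop("channel length and width must be positive")
  if (!is.finite(target_edge_length) || target_edge_length <= 0)
    stop("target_edge_length must be positive")
  scale <- if (unit == "mm") MM else 1
  if (is.null(nx)) nx <- max(2L, round(length / target_edge_length))
  if (is.null(ny)) ny <- max(2L, round(width / target_edge_length))
  x_faces <- length * (0:nx) / nx * scale
  y_faces <- width * (0:ny) / ny * scale
  xc <- (x_faces[-1] + x_faces[-(nx + 1)]) / 2
  yc <- (y_faces[-1] + y_faces[-(ny + 1)]) / 2
  mesh <- structure(list(
    nx = nx, ny = ny, x_faces = x_faces, y_faces = y_faces,
    x_centers = xc, y_centers = yc,
    dx = diff(x_faces), dy = diff(y_faces),
    cell_type = matrix(1L, nx, ny),
    domain = NULL, flap_rows = integer(0),
    fl_rows = integer(0), tl_rows = seq_len(ny),
    x_faces_ref = x_faces, y_faces_ref = y_faces,
    kind = "channel"
  ), class = "flt_mesh")
  mesh$facets <- tag_boundary_facets(mesh)
  mesh
}

# Enumerate all boundary facets of the fluid region with exactly one tag each.
# A facet is a face of a fluid cell whose neighbour is non-fluid or outside
# the computational rectangle. Columns: i, j (fluid cell), side (W/E/S/N),
# tag, length (m), x, y (facet midpoint, m).
tag_boundary_facets <- function(mesh) {
  nx <- mesh$nx; ny <- mesh$ny
  ct <- mesh$cell_type
  dom <- mesh$domain
  res <- list(); n <- 0L
  xc <- mesh$x_centers; yc <- mesh$y_centers
  dxv <- mesh$dx; dyv <- mesh$dy
  xf <- mesh$x_faces; yf <- mesh$y_faces
  neighbour <- function(i, j, side)
    switch(side,
           W = if (i == 1L) -1L else ct[i - 1L, j],
           E = if (i == nx) -1L else ct[i + 1L, j],
           S = if (j == 1L) -1L else ct[i, j - 1L],
           N = if (j == ny) -1L else ct[i, j + 1L])
  classify <- function(i, j, side, nb) {
    if (mesh$kind == "channel")
      return(switch(side, W = "inlet", E = "outlet", S = "wall", N = "wall"))
    y <- yc[j] / MM; x <- xc[i] / MM   # domain description is in mm
    tl <- y < dom$flap$y0; fl <- y > dom$flap$y1
    in_flap_band <- !tl && !fl
    if (nb == -1L) {   # computational-rectangle edge
      if (side == "W") return(if (tl) "inlet" else "fl_endwall")
      if (side == "E") return(if (tl) "tl_outlet" else "fl_endwall")
      return("outer_wall")
    }
    if (nb == 2L) {    # flap material neighbour
      if (side == "N" && tl) return("flap_tl_side")
      if (side == "S" && fl) return("flap_fl_side")
      return("tear_edge")  # horizontal neighbour inside the flap band
    }
    # exterior solid neighbour: FL extremities end in walls; anything else
    # (e.g. the TL upper wall outside the dissected extent) is outer wall
    if (fl && side %in% c("W", "E")) return("fl_endwall")
    if (in_flap_band) return("fl_endwall")
    "outer_wall"
  }
  for (j in seq_len(ny)) for (i in seq_len(nx)) {
    if (ct[i, j] != 1L) next
    for (side in c("W", "E", "S", "N")) {
      nb <- neighbour(i, j, side)
      if (!identical(nb, 1L)) {
        n <- n + 1L
        len <- if (side %in% c("W", "E")) dyv[j] else dxv[i]
        px <- switch(side, W = xf[i], E = xf[i + 1L], S = xc[i], N = xc[i])
        py <- switch(side, W = yc[j], E = yc[j], S = yf[j], N = yf[j + 1L])
        res[[n]] <- data.frame(i = i, j = j, side = side,
                               tag = classify(i, j, side, nb),
                               length = len, x = px, y = py,
                               stringsAsFactors = FALSE)
      }
    }
  }
  do.call(rbind, res)
}

#' @exportS3Method base::print
print.flt_mesh <- function(x, ...) {
  cat(sprintf("flt_mesh (%s): %d x %d cells (%d fluid, %d flap, %d exterior)\n",
              x$kind, x$nx, x$ny, sum(x$cell_type == 1L),
              sum(x$cell_type == 2L), sum(x$cell_type == 0L)))
  cat(sprintf("  extent: %.4g x %.4g mm, dx %.3g mm, dy %.3g..%.3g mm\n",
              diff(range(x$x_faces)) / MM, diff(range(x$y_faces)) / MM,
              mean(x$dx) / MM, min(x$dy) / MM, max(x$dy) / MM))
  if (!is.null(x$facets))
    cat("  boundary facets:",
        paste(sprintf("%s=%d", names(table(x$facets$tag)),
                      as.integer(table(x$facets$tag))), collapse = ", "), "\n")
  invisible(x)
}

#' Per-cell areas of a mesh
#'
#' @param mesh an `flt_mesh`.
#' @return nx-by-ny matrix of cell areas, m^2.
#' @export
cell_areas <- function(mesh) outer(mesh$dx, mesh$dy)

#' Fluid-region area of a mesh
#'
#' @param mesh an `flt_mesh`.
#' @return Total fluid area, m^2.
#' @export
mesh_fluid_area <- function(mesh) sum(cell_areas(mesh)[mesh$cell_type == 1L])

#' Logical false-lumen cell mask
#'
#' @param mesh an `flt_mesh` (dissection kind).
#' @return nx-by-ny logical matrix, TRUE on FL fluid cells.
#' @export
fl_region_mask <- function(mesh) {
  m <- matrix(FALSE, mesh$nx, mesh$ny)
  if (length(mesh$fl_rows)) m[, mesh$fl_rows] <- TRUE
  m & mesh$cell_type == 1L
}

#' Logical true-lumen cell mask
#'
#' @param mesh an `flt_mesh` (dissection kind).
#' @return nx-by-ny logical matrix, TRUE on TL fluid cells.
#' @export
tl_region_mask <- function(mesh) {
  m <- matrix(FALSE, mesh$nx, mesh$ny)
  if (length(mesh$tl_rows)) m[, mesh$tl_rows] <- TRUE
  m & mesh$cell_type == 1L
}

#' Export mesh and cell fields to a legacy-VTK rectilinear file
#'
#' Writes an ASCII `RECTILINEAR_GRID` file with the cell-type mask and any
#' supplied per-cell fields, for inspection in ParaView or similar.
#'
#' @param mesh an `flt_mesh`.
#' @param path output file path (`.vtk`).
#' @param fields named list of nx-by-ny matrices of cell data.
#' @return `path`, invisibly.
#' @export
write_vtk <- function(mesh, path, fields = list()) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# vtk DataFile Version 3.0",
               "fltsim fields", "ASCII",
               "DATASET RECTILINEAR_GRID",
               sprintf("DIMENSIONS %d %d 1", mesh$nx + 1L, mesh$ny + 1L)), con)
  writeLines(sprintf("X_COORDINATES %d double", mesh$nx + 1L), con)
  writeLines(paste(format(mesh$x_faces, digits = 10), collapse = " "), con)
  writeLines(sprintf("Y_COORDINATES %d double", mesh$ny + 1L), con)
  writeLines(paste(format(mesh$y_faces, digits = 10), collapse = " "), con)
  writeLines("Z_COORDINATES 1 double", con)
  writeLines("0", con)
  writeLines(sprintf("CELL_DATA %d", mesh$nx * mesh$ny), con)
  fields <- c(list(cell_type = mesh$cell_type + 0), fields)
  for (nm in names(fields)) {
    writeLines(sprintf("SCALARS %s double 1", nm), con)
    writeLines("LOOKUP_TABLE default", con)
    writeLines(paste(format(as.numeric(fields[[nm]]), digits = 8),
                     collapse = " "), con)
  }
  invisible(path)
}
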