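# Dissection geometry and structured meshing

test_that("default dissection geometry spans 43.2 mm between outer walls", {
  dom <- build_dissection_geometry(dissection_geometry())
  expect_equal(dom$height_mm, 19.4 + 0.8 + 23.0)
  expect_equal(dom$length_mm, 40 + 200 + 40)
  # fluid area: TL strip + FL strip + two tears
  expect_equal(dom$area_mm2,
               280 * 19.4 + 200 * 23.0 + 2 * 10 * 0.8)
})

test_that("invalid geometries are rejected with informative errors", {
  expect_error(dissection_geometry(tear_length = 0), "strictly positive")
  expect_error(dissection_geometry(entry_tear_center = 100,
                                   reentry_tear_center = 100),
               "proximal")
  # overlapping tear extents
  expect_error(dissection_geometry(entry_tear_center = 100,
                                   reentry_tear_center = 105),
               "overlap")
  # tear outside the dissected segment
  expect_error(dissection_geometry(entry_tear_center = 42), "inside")
  expect_error(dissection_geometry(fl_width = -1), "strictly positive")
})

test_that("benchmark channel meshing is structured and counts cells exactly", {
  mesh <- benchmark_channel(10, 1, 0.1, unit = "m")
  expect_equal(c(mesh$nx, mesh$ny), c(100L, 10L))
  expect_equal(sum(cell_areas(mesh)), 10 * 1, tolerance = 1e-12)
  # boundary facet lengths sum to the perimeter 2(L + W)
  expect_equal(sum(mesh$facets$length), 2 * (10 + 1), tolerance = 1e-12)
  expect_error(benchmark_channel(10, 0, 0.1), "positive")
  expect_error(benchmark_channel(10, 1, -0.1), "positive")
})

test_that("dissection mesh resolves the flap and partitions the boundary", {
  dom <- build_dissection_geometry(dissection_geometry())
  mesh <- generate_mesh(dom, 0.25)
  # at least 3 rows across the flap strip
  expect_gte(length(mesh$flap_rows), 3L)
  expect_equal(sum(mesh$cell_type == 2L) > 0, TRUE)
  # fluid area matches the domain polygon area to well under 0.1%
  expect_lt(abs(mesh_fluid_area(mesh) * 1e6 - dom$area_mm2) / dom$area_mm2,
            1e-3)
  # every tag is among the documented set; both flap sides and both
  # endwalls present
  tags <- table(mesh$facets$tag)
  expect_true(all(names(tags) %in%
    c("inlet", "tl_outlet", "fl_endwall", "outer_wall",
      "flap_tl_side", "flap_fl_side", "tear_edge")))
  expect_true(all(c("flap_fl_side", "flap_tl_side", "fl_endwall",
                    "tear_edge") %in% names(tags)))
  # tag partition: no facet appears twice
  key <- paste(mesh$facets$i, mesh$facets$j, mesh$facets$side)
  expect_equal(anyDuplicated(key), 0L)
  expect_error(generate_mesh(dom, -0.1), "positive")
  expect_error(generate_mesh(dom, 2), "flap_thickness")
})

test_that("meshing is deterministic", {
  dom <- build_dissection_geometry(dissection_geometry())
  m1 <- generate_mesh(dom, 0.8, dx_axial = 1.25, dy_channel = 1.6)
  m2 <- generate_mesh(dom, 0.8, dx_axial = 1.25, dy_channel = 1.6)
  expect_identical(m1, m2)
})

test_that("region masks split the fluid into disjoint TL and FL", {
  mesh <- generate_fixtures("mini_dissection")
  tl <- tl_region_mask(mesh); fl <- fl_region_mask(mesh)
  expect_false(any(tl & fl))
  expect_true(all(mesh$cell_type[tl] == 1L))
  expect_true(all(mesh$cell_type[fl] == 1L))
  # FL area equals fl_width x dissected_length within mesh tolerance
  g <- mesh$domain$params
  expect_equal(sum(cell_areas(mesh)[fl]) * 1e6,
               g$fl_width * g$dissected_length, tolerance = 0.01)
})

test_that("VTK export writes a readable rectilinear file", {
  mesh <- benchmark_channel(10, 1, 0.5, unit = "mm")
  f <- tempfile(fileext = ".vtk")
  write_vtk(mesh, f, fields = list(p = matrix(1, mesh$nx, mesh$ny)))
  lines <- readLines(f)
  expect_equal(lines[4], "DATASET RECTILINEAR_GRID")
  expect_true(any(grepl("^CELL_DATA", lines)))
  expect_true(any(grepl("SCALARS p double", lines)))
  unlink(f)
})
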