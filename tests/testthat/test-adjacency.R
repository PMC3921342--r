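test_that("rook and queen contiguity on small grids match combinatorics", {
  m22 <- grid_map(2, 2)
  rook <- build_adjacency(m22, "rook")
  expect_equal(rook$num, rep(2L, 4))
  expect_equal(rook$sumNumNeigh, 8L)
  queen <- build_adjacency(m22, "queen")
  expect_equal(queen$num, rep(3L, 4))   # corner touches count under queen

  m33 <- grid_map(3, 3)
  rook33 <- build_adjacency(m33, "rook")
  oracle <- grid_rook_oracle(3, 3)
  expect_equal(rook33$neighbours, lapply(oracle, as.integer))
  expect_equal(length(rook33$adj), 24L)
  expect_equal(rook33$num[5], 4L)       # centre
  expect_equal(sort(rook33$num), c(rep(2L, 4), rep(3L, 4), 4L))
})

test_that("queen edge set contains the rook edge set", {
  spec <- simulation_spec(n_areas = 40, lattice_kind = "voronoi", seed = 3)
  map <- make_lattice(spec)
  rook <- build_adjacency(map, "rook")
  queen <- build_adjacency(map, "queen")
  for (i in seq_len(rook$n))
    expect_true(all(rook$neighbours[[i]] %in% queen$neighbours[[i]]))
})

test_that("adjacency validation catches islands, asymmetry, disconnection", {
  expect_error(adjacency_matrix(list(2L, 1L, integer(0))), "island")
  expect_error(
    adjacency_matrix(list(c(2L), c(1L, 3L), c(1L))),   # 3 lists 1, not mutual
    "asymmetric")
  expect_error(adjacency_matrix(list(2L, 1L, 4L, 3L)), "disconnected")
  expect_error(adjacency_matrix(list(c(1L, 2L), 1L)), "itself")
  # two separated blocks of polygons
  far <- area_map(c("a", "b", "c", "d"), list(
    cbind(c(0, 1, 1, 0), c(0, 0, 1, 1)), cbind(c(1, 2, 2, 1), c(0, 0, 1, 1)),
    cbind(c(10, 11, 11, 10), c(0, 0, 1, 1)),
    cbind(c(11, 12, 12, 11), c(0, 0, 1, 1))))
  expect_error(build_adjacency(far, "rook"), "disconnected")
})

test_that("GeoBUGS adjacency files round-trip and are validated", {
  adj <- build_adjacency(grid_map(2, 2), "rook")
  path <- withr::local_tempfile(fileext = ".txt")
  write_geobugs_adjacency(adj, path)
  back <- read_geobugs_adjacency(path)
  expect_equal(back$num, adj$num)
  expect_equal(back$adj, adj$adj)
  expect_equal(back$sumNumNeigh, adj$sumNumNeigh)
  expect_true(all(back$adj >= 1 & back$adj <= 4))
  expect_equal(length(back$adj), 8L)

  # a larger irregular graph round-trips too
  adj2 <- build_adjacency(make_lattice(
    simulation_spec(n_areas = 25, lattice_kind = "voronoi", seed = 9)), "queen")
  write_geobugs_adjacency(adj2, path)
  expect_equal(read_geobugs_adjacency(path)$neighbours, adj2$neighbours)

  writeLines(c("list(", "num = c(1, 1),", "adj = c(2, 1),",
               "sumNumNeigh = 3", ")"), path)
  expect_error(read_geobugs_adjacency(path), "sumNumNeigh")
  writeLines(c("list(", "num = c(1, 1, 1),", "adj = c(2, 3, 1),",
               "sumNumNeigh = 3", ")"), path)
  expect_error(read_geobugs_adjacency(path), "asymmetric")
})

test_that("GeoJSON areal maps round-trip with properties", {
  map <- grid_map(2, 3)
  path <- withr::local_tempfile(fileext = ".geojson")
  props <- data.frame(smr = seq(0.5, 3, by = 0.5))
  write_geojson_areas(map, path, properties = props)
  back <- read_geojson_areas(path, id_property = "area_id")
  expect_equal(back$area_id, map$area_id)
  expect_equal(back$polygons, map$polygons)
  g <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  expect_equal(vapply(g$features, function(f) f$properties$smr, numeric(1)),
               props$smr)
})
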