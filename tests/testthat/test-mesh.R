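test_that("cylinder builder reproduces the inscribed-polygon cross-section", {
  mesh <- build_cylinder_domain(400, 200, extracellular_margin = 200,
                                resolution = 50, resolution_axial = 100,
                                n_seg = 16)
  v_in <- sum(tet_volumes(mesh)[mesh$subdomain == "INTRA"])
  a_polygon <- 0.5 * 16 * 100^2 * sin(2 * pi / 16)
  expect_equal(v_in, a_polygon * 400, tolerance = 1e-10)
  # within the polyhedral deficit of the ideal cylinder
  expect_lt(v_in, pi * 100^2 * 400)
  expect_gt(v_in, 0.9 * pi * 100^2 * 400)
  expect_named(mesh$markers, c("end_stim", "mid", "end_far"))
})

test_that("membrane triangles separate the subdomains with outward normals", {
  for (mesh in list(small_sphere(),
                    build_cylinder_domain(200, 40, 60, resolution = 12))) {
    mg <- membrane_geometry(mesh)
    # stored orientation: normal . (triangle barycenter - intra barycenter) > 0
    it <- mesh$intra_tet_of_tri
    expect_true(all(mesh$subdomain[it] == "INTRA"))
    ib <- (mesh$vertices[mesh$tets[it, 1], ] + mesh$vertices[mesh$tets[it, 2], ] +
           mesh$vertices[mesh$tets[it, 3], ] + mesh$vertices[mesh$tets[it, 4], ]) / 4
    expect_true(all(rowSums(mg$normal * (mg$bary - ib)) > 0))
  }
})

test_that("sphere domain: membrane vertices at radius R, icosphere counts", {
  for (s in 0:2) expect_equal(nrow(icosphere(s)$tris), 20 * 4^s)
  expect_equal(max(abs(sqrt(rowSums(icosphere(2)$vertices^2)) - 1)), 0,
               tolerance = 1e-12)
  mesh <- small_sphere()
  mv <- unique(as.vector(mesh$membrane_tris))
  expect_equal(sqrt(rowSums(mesh$vertices[mv, ]^2)),
               rep(10, length(mv)), tolerance = 1e-12)
  mg <- membrane_geometry(mesh)
  # triangulated area below but near 4 pi R^2
  expect_gt(sum(mg$area), 0.9 * 4 * pi * 100)
  expect_lt(sum(mg$area), 4 * pi * 100)
  expect_error(build_sphere_domain(10, 5), "extracellular_radius")
})

test_that("builder preconditions are enforced", {
  expect_error(build_cylinder_domain(100, 20, resolution = 30),
               "resolution larger than diameter")
  expect_error(nc_mesh(rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(0.5, 0.5, 0)),
                       matrix(1:4, 1), "INTRA"),
               "degenerate")
})

test_that("dual grid: single-tet control volumes match the brute-force corner pieces", {
  ut <- unit_tet()
  # oracle: subdivide the corner hexahedron of each vertex into tetrahedra
  oracle <- vapply(1:4, function(k) corner_piece_volume(ut$vertices, k),
                   numeric(1))
  expect_equal(oracle, rep(1 / 6 / 4, 4), tolerance = 1e-14)
  # a skewed tet as well
  v2 <- rbind(c(0, 0, 0), c(2, 0.3, 0), c(-0.4, 1.5, 0.2), c(0.3, 0.2, 1.7))
  vol <- abs(det(rbind(v2[2, ] - v2[1, ], v2[3, ] - v2[1, ],
                       v2[4, ] - v2[1, ]))) / 6
  oracle2 <- vapply(1:4, function(k) corner_piece_volume(v2, k), numeric(1))
  expect_equal(oracle2, rep(vol / 4, 4), tolerance = 1e-12)
})

test_that("dual grid partitions volume and membrane area to 1e-10", {
  for (mesh in list(small_sphere(),
                    build_cylinder_domain(200, 40, 60, resolution = 12))) {
    dual <- build_dual_grid(mesh)
    vt <- tet_volumes(mesh)
    v_in <- sum(vt[mesh$subdomain == "INTRA"])
    v_ex <- sum(vt[mesh$subdomain == "EXTRA"])
    expect_equal(sum(dual$volume_intra), v_in, tolerance = 1e-10)
    expect_equal(sum(dual$volume_extra), v_ex, tolerance = 1e-10)
    mg <- membrane_geometry(mesh)
    expect_equal(sum(dual$membrane$area), sum(mg$area), tolerance = 1e-10)
    # aggregated sub-face normals are stored once per edge (k < j), oriented
    # k -> j; the reversed edge has the negated normal by construction, and
    # every edge's normal has positive projection on the edge vector
    sf <- dual$subface_normals
    ev <- mesh$vertices[sf$j, ] - mesh$vertices[sf$k, ]
    proj <- rowSums(cbind(sf$nx, sf$ny, sf$nz) * ev)
    expect_true(all(proj > 0))
  }
})

test_that("uniform refinement multiplies tets by 8 and preserves volume and patches", {
  mesh <- small_sphere()
  ref <- refine_mesh(mesh)
  expect_equal(nrow(ref$tets), 8 * nrow(mesh$tets))
  expect_equal(sum(tet_volumes(ref)), sum(tet_volumes(mesh)), tolerance = 1e-10)
  expect_equal(nrow(ref$membrane_tris), 4 * nrow(mesh$membrane_tris))
  # per-patch membrane area preserved exactly (children inherit labels)
  area_by_patch <- function(m) {
    mg <- membrane_geometry(m)
    tapply(mg$area, m$patch_of_tri, sum)
  }
  a0 <- area_by_patch(mesh); a1 <- area_by_patch(ref)
  expect_equal(as.numeric(a1[names(a0)]), as.numeric(a0), tolerance = 1e-10)
  # intra volume preserved too
  expect_equal(sum(tet_volumes(ref)[ref$subdomain == "INTRA"]),
               sum(tet_volumes(mesh)[mesh$subdomain == "INTRA"]),
               tolerance = 1e-10)
})

test_that("mesh files round-trip through vtu and msh and agree across formats", {
  mesh <- build_cylinder_domain(200, 40, 60, resolution = 14)
  td <- withr::local_tempdir()
  p_vtu <- file.path(td, "m.vtu")
  p_msh <- file.path(td, "m.msh")
  write_mesh(mesh, p_vtu)
  write_mesh(mesh, p_msh)
  r_vtu <- read_mesh(p_vtu)
  r_msh <- read_mesh(p_msh)
  expect_equal(r_vtu$vertices, mesh$vertices, tolerance = 1e-12)
  expect_identical(r_vtu$tets, mesh$tets)
  expect_identical(r_vtu$subdomain, mesh$subdomain)
  expect_identical(r_vtu$patch_of_tri, mesh$patch_of_tri)
  # formats agree with each other
  expect_equal(r_msh$vertices, r_vtu$vertices, tolerance = 1e-12)
  expect_identical(nrow(r_msh$tets), nrow(r_vtu$tets))
  expect_identical(table(r_msh$subdomain), table(r_vtu$subdomain))
  expect_identical(sort(table(r_msh$patch_of_tri)),
                   sort(table(r_vtu$patch_of_tri)))
})

test_that("unlabeled or unknown mesh files are rejected", {
  mesh <- small_sphere()
  td <- withr::local_tempdir()
  p <- file.path(td, "m.vtu")
  write_mesh(mesh, p)
  txt <- readLines(p)
  txt <- txt[!grepl("subdomain", txt)]
  # drop the subdomain array entirely
  drop <- grep("Name=\"subdomain\"", readLines(p))
  txt <- readLines(p)[-c(drop, drop + 1, drop + 2)]
  p2 <- file.path(td, "bad.vtu")
  writeLines(txt, p2)
  expect_error(read_mesh(p2), "subdomain")
  expect_error(read_mesh(file.path(td, "nope.vtu")), "not found")
  expect_error(write_mesh(mesh, file.path(td, "m.stl")), "unknown mesh format")
})

test_that("network builder labels cells, synapses and stimuli as specified", {
  spec <- neuron_geometry_spec()
  m4 <- build_network_domain(spec, n_cells = 4, separation = 40, margin = 20,
                             h = 5)
  expect_setequal(unique(m4$cell_of_tri), 1:4)
  pre_cells <- unique(m4$cell_of_tri[m4$patch_of_tri == "SYNAPSE_PRE"])
  post_cells <- unique(m4$cell_of_tri[m4$patch_of_tri == "SYNAPSE_POST"])
  expect_true(length(intersect(pre_cells + 1L, post_cells)) >= 1)

  m1 <- build_network_domain(spec, n_cells = 1, separation = 40, margin = 20,
                             h = 5)
  expect_equal(sum(grepl("SYNAPSE", m1$patch_of_tri)), 0)

  m2 <- build_network_domain(spec, n_cells = 2, separation = 40, margin = 20,
                             h = 5)
  expect_setequal(unique(m2$cell_of_tri[m2$patch_of_tri == "SYNAPSE_PRE"]), 1L)
  expect_setequal(unique(m2$cell_of_tri[m2$patch_of_tri == "SYNAPSE_POST"]), 2L)
  expect_error(build_network_domain(spec, n_cells = 2, separation = 0),
               "overlap")
  expect_error(neuron_geometry_spec(axon_diameter = -1), "positive")
})
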