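test_that("semicylinder volume matches the closed form and refines", {
  p <- geometry_params("SEMICYLINDER", thickness_T = 0.02,
                       boundary_length_L = 1, resolution = c(24, 12),
                       through_thickness_layers = 3)
  mesh <- build_semicylinder_sheet(p)
  exact <- pi * 0.5^2 / 2 * 0.02
  expect_equal(sum(mesh$volumes), exact, tolerance = 0.01)
  # measured thickness deviates < 2% from T
  z <- mesh$nodes[, 3]
  expect_equal(max(z) - min(z), 0.02, tolerance = 0.02)
  p2 <- geometry_params("SEMICYLINDER", thickness_T = 0.02,
                        boundary_length_L = 1, resolution = c(48, 24),
                        through_thickness_layers = 3)
  v2 <- sum(build_semicylinder_sheet(p2)$volumes)
  expect_lt(abs(v2 - exact) / exact, abs(sum(mesh$volumes) - exact) / exact)
})

test_that("gel-analog scaling: T/L = 0.01 at L = 84.62", {
  p <- geometry_params("SEMICYLINDER", thickness_T = 0.8462,
                       boundary_length_L = 84.62, resolution = c(16, 8))
  mesh <- build_semicylinder_sheet(p)
  expect_equal(mesh$thickness_T / mesh$inner_boundary_length_L, 0.01)
  expect_equal(sum(mesh$volumes), pi * (84.62 / 2)^2 / 2 * 0.8462,
               tolerance = 0.02)
})

test_that("curved lobe: volume, crease planarity, convergence under refinement", {
  L <- 0.047 / 0.014
  p <- geometry_params("CURVED_LOBE", thickness_T = 0.047,
                       boundary_length_L = L, resolution = c(24, 16),
                       through_thickness_layers = 2)
  mesh <- build_curved_lobe_sheet(p)
  Phi <- 120 * pi / 180
  R0 <- L / Phi
  exact <- Phi / 2 * ((R0 + L)^2 - R0^2) * 0.047
  # linear tets under-integrate the circular arc; closed form within 1%
  expect_equal(sum(mesh$volumes), exact, tolerance = 0.01)
  # crease nodes lie in the y-z plane
  cr <- mesh$node_sets$CREASE
  expect_lt(max(abs(mesh$nodes[cr, 1])), 1e-9 * L)
  expect_equal(sqrt(sum(mesh$crease_direction^2)), 1, tolerance = 1e-12)
  # doubling resolution changes total volume by < 0.5%
  p2 <- geometry_params("CURVED_LOBE", thickness_T = 0.047,
                        boundary_length_L = L, resolution = c(48, 32),
                        through_thickness_layers = 2)
  v2 <- sum(build_curved_lobe_sheet(p2)$volumes)
  expect_lt(abs(v2 / sum(mesh$volumes) - 1), 0.005)
  expect_error(geometry_params("CURVED_LOBE", 0.047, L, arc_angle_deg = 200),
               "arc_angle")
})

test_that("bilayer frill: conforming interface, layer volumes, node sets", {
  L <- 0.047 / 0.014
  p <- geometry_params("BILAYER_FRILL", thickness_T = 0.047,
                       boundary_length_L = L, resolution = c(20, 12),
                       through_thickness_layers = 2, substrate_layers = 4,
                       substrate_depth_ratio = 10)
  mesh <- build_bilayer_frill(p)
  skin <- mesh$region == "SKIN"
  # skin region thickness = T within 2%
  zskin <- mesh$nodes[unique(as.vector(mesh$tets[skin, ])), 3]
  expect_equal(max(zskin) - min(zskin), 0.047, tolerance = 0.02)
  # substrate volume ~ 10x skin volume
  expect_equal(sum(mesh$volumes[!skin]) / sum(mesh$volumes[skin]), 10,
               tolerance = 0.05)
  # every interface node belongs to at least one SKIN and one SUBSTRATE tet
  iface <- which(abs(mesh$nodes[, 3]) < 1e-12)
  in_skin <- unique(as.vector(mesh$tets[skin, ]))
  in_sub <- unique(as.vector(mesh$tets[!skin, ]))
  expect_true(all(iface %in% in_skin) && all(iface %in% in_sub))
  # crease spans both layers
  cr_z <- mesh$nodes[mesh$node_sets$CREASE, 3]
  expect_lt(min(cr_z), 0)
  expect_gt(max(cr_z), 0)
  expect_error(geometry_params("BILAYER_FRILL", 0.047, L,
                               substrate_depth_ratio = 2), ">= 5")
})

test_that("node sets are valid and disjoint where required", {
  mesh <- small_semicylinder()
  ns <- mesh$node_sets
  expect_length(intersect(ns$FIXED_INNER, ns$FREE_EDGE), 0)
  expect_true(all(unlist(ns) >= 1) && all(unlist(ns) <= nrow(mesh$nodes)))
  expect_true(all(tet_volumes(mesh$nodes, mesh$tets) > 0))
  # reference normals are unit and orthogonal to the flat mid-surface
  expect_equal(rowSums(mesh$normal_of_tet^2), rep(1, nrow(mesh$tets)),
               tolerance = 1e-12)
  expect_true(all(abs(mesh$normal_of_tet %*% c(1, 0, 0)) < 1e-9))
  expect_true(all(abs(mesh$normal_of_tet %*% c(0, 1, 0)) < 1e-9))
})

test_that("semicylinder construction is mirror-symmetric in x", {
  mesh <- small_semicylinder(res = c(12, 6))
  key <- function(m) paste(round(m[, 1], 12), round(m[, 2], 12),
                           round(m[, 3], 12))
  refl <- mesh$nodes
  refl[, 1] <- -refl[, 1]
  expect_setequal(key(refl), key(mesh$nodes))
})

test_that("depth fields: slab geometry and exhaustive point-triangle oracle", {
  mesh <- small_semicylinder(T_over_L = 0.05, res = c(8, 4), layers = 2)
  depth <- compute_depth_fields(mesh)
  expect_true(all(depth$x_s >= 0))
  # tets with a face on the anterior surface sit within a/2 of it
  surf_nodes <- mesh$node_sets$ANTERIOR_SURFACE
  on_surf <- rowSums(matrix(mesh$tets %in% surf_nodes,
                            nrow(mesh$tets), 4)) >= 3
  expect_true(all(depth$x_s[on_surf] <= mesh$spacing_a / 2))
  # deepest centroids of the slab lie within [T - a, T]
  expect_true(max(depth$x_s) <= mesh$thickness_T)
  expect_true(max(depth$x_s) >= mesh$thickness_T - mesh$spacing_a)
  # brute-force oracle: independent point-to-triangle distance
  cen <- morphofrill:::tet_centroids(mesh)
  ref <- vapply(seq_len(nrow(cen)), function(i) {
    min(vapply(seq_len(nrow(mesh$surface_tris)), function(s) {
      tri <- mesh$surface_tris[s, ]
      ref_point_tri_dist(cen[i, ], mesh$nodes[tri[1], ],
                         mesh$nodes[tri[2], ], mesh$nodes[tri[3], ])
    }, numeric(1)))
  }, numeric(1))
  expect_equal(depth$x_s, ref, tolerance = 1e-9)
  # no crease on the semicylinder: x_c infinite, and requiring it errors
  expect_true(all(is.infinite(depth$x_c)))
  expect_error(compute_depth_fields(mesh, require_crease = TRUE), "CREASE")
  # crease-touching tets of a lobe sit within a/2 of the crease plane
  lobe <- small_lobe(res = c(12, 8))
  dl <- compute_depth_fields(lobe, require_crease = TRUE)
  cr_nodes <- lobe$node_sets$CREASE
  touching <- rowSums(matrix(lobe$tets %in% cr_nodes,
                             nrow(lobe$tets), 4)) >= 3
  expect_true(all(dl$x_c[touching] <= lobe$spacing_a / 2))
})

test_that("validate_mesh reports and flags constructed defects", {
  mesh <- small_semicylinder(res = c(8, 4))
  rep0 <- validate_mesh(mesh)
  expect_equal(rep0$n_inverted, 0)
  expect_equal(unname(rep0$node_set_sizes["ANTERIOR_SURFACE"]),
               (8 + 1) * (4 + 1))
  # swapping two node indices in one tet inverts exactly that tet
  bad <- mesh
  bad$tets[5, c(3, 4)] <- bad$tets[5, c(4, 3)]
  rep1 <- validate_mesh(bad)
  expect_equal(rep1$n_inverted, 1)
  expect_output(print(rep0), "inverted tets: 0")
})

test_that("degenerate geometry parameters are rejected", {
  expect_error(geometry_params("SEMICYLINDER", -1, 1), "positive")
  expect_error(geometry_params("SEMICYLINDER", 0.02, 1, resolution = 1),
               "degenerate")
  expect_error(geometry_params("SEMICYLINDER", 0.3, 1), "thin sheet")
  expect_error(geometry_params("SEMICYLINDER", 0.02, 1,
                               through_thickness_layers = 1), "layers")
  p <- geometry_params("CURVED_LOBE", 0.02, 1)
  expect_error(build_semicylinder_sheet(p), "SEMICYLINDER")
})

test_that("mesh export writes readable VTK and PLY", {
  mesh <- small_semicylinder(res = c(6, 3))
  vtk <- tempfile(fileext = ".vtk")
  write_vtk(mesh, vtk)
  lines <- readLines(vtk)
  expect_identical(lines[1], "# vtk DataFile Version 3.0")
  expect_true(any(grepl("^POINTS", lines)))
  expect_true(any(grepl("^CELLS", lines)))
  expect_true(any(grepl("SCALARS region", lines)))
  ply <- tempfile(fileext = ".ply")
  write_ply(mesh, ply)
  expect_identical(readLines(ply, n = 1), "ply")
})
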