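#' Geometry parameters for the parametric frill meshes
#'
#' Bundles the geometric quantities shared by all mesh builders: the skin
#' sheet thickness `T`, the length `L` of the fixed boundary (the straight
#' edge of the semicylinder, or the inner circular arc of the lobe models),
#' the substrate depth (bilayer only) and the lattice resolution.
#'
#' @param kind one of `"SEMICYLINDER"`, `"CURVED_LOBE"`, `"BILAYER_FRILL"`,
#'   `"BILAYER_STRIP"` (the last is a flat film-on-substrate strip used to
#'   validate the wrinkling-wavelength law).
#' @param thickness_T skin sheet thickness (mm).
#' @param boundary_length_L length of the fixed boundary (mm): the diameter of
#'   the semicylinder, the inner-arc length of the lobe models, or the strip
#'   length.
#' @param substrate_depth_ratio substrate thickness as a multiple of
#'   `thickness_T` (bilayer kinds only; must be >= 5).
#' @param resolution integer vector `c(n1, n2)`: lattice cells along the
#'   band/arc direction and along the inradial (or width) direction. A scalar
#'   is expanded to `c(n, ceiling(n/2))`.
#' @param through_thickness_layers tet layers through the skin thickness
#'   (>= 2).
#' @param substrate_layers tet layers through the substrate (bilayer kinds).
#' @param arc_angle_deg opening angle of the inner arc of the lobe models,
#'   in degrees, within (0, 180].
#' @param lobe_extent radial extent of the lobe as a multiple of
#'   `boundary_length_L`.
#' @param strip_width width of the `BILAYER_STRIP` (mm); defaults to
#'   `0.15 * boundary_length_L`.
#' @return an object of class `geometry_params`.
#' @export
geometry_params <- function(kind = c("SEMICYLINDER", "CURVED_LOBE",
                                     "BILAYER_FRILL", "BILAYER_STRIP"),
                            thickness_T, boundary_length_L,
                            substrate_depth_ratio = 10,
                            resolution = NULL,
                            through_thickness_layers = 3,
                            substrate_layers = 5,
                            arc_angle_deg = 120,
                            lobe_extent = 1,
                            strip_width = NULL) {
  kind <- match.arg(kind)
  stopifnot(is.numeric(thickness_T), length(thickness_T) == 1,
            is.numeric(boundary_length_L), length(boundary_length_L) == 1)
  if (thickness_T <= 0 || boundary_length_L <= 0)
    stop("thickness_T and boundary_length_L must be positive")
  ratio <- thickness_T / boundary_length_L
  if (ratio > 0.1)
    stop("thickness_T / boundary_length_L = ", signif(ratio, 3),
         " is outside (0, 0.1]: not a thin sheet")
  if (through_thickness_layers < 2)
    stop("through_thickness_layers must be >= 2 for the skin region")
  if (kind %in% c("BILAYER_FRILL", "BILAYER_STRIP") && substrate_depth_ratio < 5)
    stop("substrate_depth_ratio must be >= 5")
  if (kind %in% c("CURVED_LOBE", "BILAYER_FRILL") &&
      (arc_angle_deg <= 0 || arc_angle_deg > 180))
    stop("arc_angle_deg must lie in (0, 180]")
  if (is.null(resolution)) resolution <- 40L
  if (length(resolution) == 1) resolution <- c(resolution, ceiling(resolution / 2))
  resolution <- as.integer(resolution)
  if (any(resolution < 2))
    stop("degenerate resolution: need at least 2 cells along each dimension")
  if (is.null(strip_width)) strip_width <- 0.15 * boundary_length_L
  structure(list(kind = kind, thickness_T = thickness_T,
                 boundary_length_L = boundary_length_L,
                 substrate_depth_ratio = substrate_depth_ratio,
                 resolution = resolution,
                 through_thickness_layers = as.integer(through_thickness_layers),
                 substrate_layers = as.integer(substrate_layers),
                 arc_angle_deg = arc_angle_deg, lobe_extent = lobe_extent,
                 strip_width = strip_width),
            class = "geometry_params")
}

# ---- internal lattice machinery ---------------------------------------------

# 6-tet decomposition of each hexahedral cell around the c000-c111 diagonal;
# identical in every cell, so shared faces are conforming.
lattice_tets <- function(n1, n2, nz) {
  lin <- function(i, j, k) 1L + i + (n1 + 1L) * (j + (n2 + 1L) * k)
  cells <- expand.grid(i = 0:(n1 - 1L), j = 0:(n2 - 1L), k = 0:(nz - 1L))
  i <- cells$i; j <- cells$j; k <- cells$k
  c000 <- lin(i, j, k);         c100 <- lin(i + 1L, j, k)
  c010 <- lin(i, j + 1L, k);    c110 <- lin(i + 1L, j + 1L, k)
  c001 <- lin(i, j, k + 1L);    c101 <- lin(i + 1L, j, k + 1L)
  c011 <- lin(i, j + 1L, k + 1L); c111 <- lin(i + 1L, j + 1L, k + 1L)
  tets <- rbind(cbind(c000, c100, c101, c111),
                cbind(c000, c101, c001, c111),
                cbind(c000, c001, c011, c111),
                cbind(c000, c011, c010, c111),
                cbind(c000, c010, c110, c111),
                cbind(c000, c110, c100, c111))
  layer <- rep(k, times = 6L)  # z-layer of the parent cell, for region labels
  list(tets = tets, layer = layer)
}

#' Signed volumes of tetrahedra
#' @param nodes N x 3 node coordinate matrix.
#' @param tets M x 4 node-index matrix.
#' @return numeric vector of signed volumes (positive for the package's
#'   node-ordering convention).
#' @export
tet_volumes <- function(nodes, tets) {
  a <- nodes[tets[, 2], , drop = FALSE] - nodes[tets[, 1], , drop = FALSE]
  b <- nodes[tets[, 3], , drop = FALSE] - nodes[tets[, 1], , drop = FALSE]
  cc <- nodes[tets[, 4], , drop = FALSE] - nodes[tets[, 1], , drop = FALSE]
  cx <- b[, 2] * cc[, 3] - b[, 3] * cc[, 2]
  cy <- b[, 3] * cc[, 1] - b[, 1] * cc[, 3]
  cz <- b[, 1] * cc[, 2] - b[, 2] * cc[, 1]
  (a[, 1] * cx + a[, 2] * cy + a[, 3] * cz) / 6
}

mean_edge_length <- function(nodes, tets) {
  combs <- rbind(c(1, 2), c(1, 3), c(1, 4), c(2, 3), c(2, 4), c(3, 4))
  e <- do.call(rbind, lapply(seq_len(nrow(combs)), function(r)
    cbind(tets[, combs[r, 1]], tets[, combs[r, 2]])))
  e <- cbind(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  e <- unique(e)
  d <- nodes[e[, 1], , drop = FALSE] - nodes[e[, 2], , drop = FALSE]
  mean(sqrt(rowSums(d^2)))
}

# boundary faces (occurring in exactly one tet), as an S x 3 index matrix
boundary_faces <- function(tets) {
  f <- rbind(tets[, c(2, 3, 4)], tets[, c(1, 3, 4)],
             tets[, c(1, 2, 4)], tets[, c(1, 2, 3)])
  key <- apply(f, 1L, function(r) paste(sort(r), collapse = "_"))
  tab <- table(key)
  f[key %in% names(tab)[tab == 1L], , drop = FALSE]
}

# Shared assembly: map the (u, v, z) lattice through `xy_of_uv`, build tets,
# orient them positively, and compute derived fields.
build_from_lattice <- function(params, xy_of_uv, zlevels, region_of_layer,
                               tag_sets, crease_direction = NULL,
                               crease_plane_normal = NULL) {
  n1 <- params$resolution[1]; n2 <- params$resolution[2]
  nz <- length(zlevels) - 1L
  u <- (0:n1) / n1; v <- (0:n2) / n2
  uv <- expand.grid(u = u, v = v)
  xy <- xy_of_uv(uv$u, uv$v)
  nxy <- nrow(xy)
  nodes <- cbind(x = rep(xy[, 1], nz + 1L),
                 y = rep(xy[, 2], nz + 1L),
                 z = rep(zlevels, each = nxy))
  lt <- lattice_tets(n1, n2, nz)
  tets <- lt$tets
  vol <- tet_volumes(nodes, tets)
  neg <- vol < 0
  if (any(neg)) {  # restore positive orientation after the parametric map
    tmp <- tets[neg, 3]
    tets[neg, 3] <- tets[neg, 4]
    tets[neg, 4] <- tmp
    vol <- abs(vol)
  }
  if (any(vol <= 0)) stop("degenerate lattice cell: zero-volume tetrahedron")
  region <- region_of_layer[lt$layer + 1L]

  # lattice index helpers for node-set tagging
  lin <- function(i, j, k) 1L + i + (n1 + 1L) * (j + (n2 + 1L) * k)
  sets <- tag_sets(lin, n1, n2, nz)
  sets$FIXED_INNER <- sort(unique(sets$FIXED_INNER))
  sets$CREASE <- sort(setdiff(unique(sets$CREASE), sets$FIXED_INNER))
  if (!is.null(sets$PLANE_CONFINED))
    sets$PLANE_CONFINED <- sort(setdiff(unique(sets$PLANE_CONFINED),
                                        sets$FIXED_INNER))
  sets$ANTERIOR_SURFACE <- sort(unique(sets$ANTERIOR_SURFACE))
  sets$FREE_EDGE <- sort(setdiff(unique(sets$FREE_EDGE),
                                 c(sets$FIXED_INNER, sets$CREASE)))

  bf <- boundary_faces(tets)
  on_surf <- rowSums(matrix(bf %in% sets$ANTERIOR_SURFACE, nrow(bf), 3)) == 3L
  surface_tris <- bf[on_surf, , drop = FALSE]

  surface_param <- matrix(NA_real_, nrow(nodes), 2,
                          dimnames = list(NULL, c("u", "v")))
  top <- lin(rep(0:n1, n2 + 1L), rep(0:n2, each = n1 + 1L), nz)
  surface_param[top, 1] <- rep(u, n2 + 1L)
  surface_param[top, 2] <- rep(v, each = n1 + 1L)

  mesh <- structure(list(
    nodes = nodes, tets = tets, region = region,
    node_sets = sets,
    normal_of_tet = matrix(rep(c(0, 0, 1), each = nrow(tets)), ncol = 3),
    crease_direction = crease_direction,
    crease_plane_normal = crease_plane_normal,
    spacing_a = mean_edge_length(nodes, tets),
    inner_boundary_length_L = params$boundary_length_L,
    thickness_T = params$thickness_T,
    volumes = vol,
    surface_tris = surface_tris,
    surface_param = surface_param,
    lattice_dims = c(n1 = n1, n2 = n2, nz = nz),
    params = params), class = "tet_mesh")
  mesh
}

substrate_zlevels <- function(T, depth_ratio, n_sub, grading = 1.6) {
  D <- depth_ratio * T
  -D * ((n_sub:1) / n_sub)^grading
}

# ---- public builders --------------------------------------------------------

#' Thin semicircular sheet clamped along its straight edge
#'
#' Builds a flat half-disc plate of diameter `L` and uniform thickness `T`,
#' meshed as a structured lattice (a smooth square-to-half-disc map, each hex
#' split into 6 tets). The straight (diameter) edge is tagged `FIXED_INNER`
#' and the circular rim `FREE_EDGE`; all elements are skin. Under uniform
#' tangential growth with the straight edge held, this geometry develops the
#' boundary-confined ("curtain") wrinkling instability.
#'
#' @param params a [geometry_params()] with `kind = "SEMICYLINDER"`.
#' @return a `tet_mesh`.
#' @export
build_semicylinder_sheet <- function(params) {
  stopifnot(inherits(params, "geometry_params"))
  if (params$kind != "SEMICYLINDER") stop("params$kind must be SEMICYLINDER")
  R <- params$boundary_length_L / 2
  Tt <- params$thickness_T
  map <- function(u, v) {
    a <- 2 * u - 1
    cbind(a * sqrt(1 - v^2 / 2) * R, v * sqrt(1 - a^2 / 2) * R)
  }
  zlev <- seq(0, Tt, length.out = params$through_thickness_layers + 1L)
  tag <- function(lin, n1, n2, nz) {
    allk <- 0:nz
    list(
      FIXED_INNER = unlist(lapply(allk, function(k) lin(0:n1, 0L, k))),
      CREASE = integer(0),
      ANTERIOR_SURFACE = lin(rep(0:n1, n2 + 1L), rep(0:n2, each = n1 + 1L), nz),
      FREE_EDGE = unlist(lapply(allk, function(k)
        c(lin(0L, 0:n2, k), lin(n1, 0:n2, k), lin(0:n1, n2, k)))))
  }
  build_from_lattice(params, map, zlev, rep("SKIN", length(zlev) - 1L), tag)
}

lobe_map <- function(params) {
  Phi <- params$arc_angle_deg * pi / 180
  R0 <- params$boundary_length_L / Phi
  ext <- params$lobe_extent * params$boundary_length_L
  function(u, v) {
    phi <- u * Phi
    rho <- R0 + v * ext
    cbind(rho * sin(phi), rho * cos(phi))
  }
}

lobe_tags <- function() {
  function(lin, n1, n2, nz) {
    allk <- 0:nz
    fixed <- unlist(lapply(allk, function(k) lin(0:n1, 0L, k)))
    crease <- unlist(lapply(allk, function(k) lin(0L, 0:n2, k)))
    free <- unlist(lapply(allk, function(k) c(lin(n1, 0:n2, k), lin(0:n1, n2, k))))
    list(FIXED_INNER = fixed, CREASE = crease,
         ANTERIOR_SURFACE = lin(rep(0:n1, n2 + 1L), rep(0:n2, each = n1 + 1L), nz),
         FREE_EDGE = free)
  }
}

#' Single-lobe sheet with a curved fixed inner boundary and a sagittal crease
#'
#' One lobe of the frill as a thin annular-sector plate: the inner circular
#' arc (length `L`, opening angle `arc_angle_deg`) is the attachment to the
#' neck (`FIXED_INNER`); the straight radial edge lying in the y-z plane is
#' the central crease (`CREASE`), with crease direction `C = (0, 1, 0)`.
#'
#' @inheritParams build_semicylinder_sheet
#' @return a `tet_mesh` whose tets are all skin.
#' @export
build_curved_lobe_sheet <- function(params) {
  stopifnot(inherits(params, "geometry_params"))
  if (params$kind != "CURVED_LOBE") stop("params$kind must be CURVED_LOBE")
  zlev <- seq(0, params$thickness_T,
              length.out = params$through_thickness_layers + 1L)
  build_from_lattice(params, lobe_map(params), zlev,
                     rep("SKIN", length(zlev) - 1L), lobe_tags(),
                     crease_direction = c(0, 1, 0),
                     crease_plane_normal = c(1, 0, 0))
}

#' Bilayer frill lobe: stiff skin sheet on a soft substrate
#'
#' The curved lobe of [build_curved_lobe_sheet()] with a conforming substrate
#' region (loose connective tissue) of depth `substrate_depth_ratio * T`
#' below the skin. Nodes on the skin-substrate interface are shared; the
#' inner arc of both layers is `FIXED_INNER` and the crease spans both
#' layers. Substrate layers are graded, finer near the interface.
#'
#' @inheritParams build_semicylinder_sheet
#' @return a `tet_mesh` with regions `"SKIN"` and `"SUBSTRATE"`.
#' @export
build_bilayer_frill <- function(params) {
  stopifnot(inherits(params, "geometry_params"))
  if (params$kind != "BILAYER_FRILL") stop("params$kind must be BILAYER_FRILL")
  Tt <- params$thickness_T
  zsub <- substrate_zlevels(Tt, params$substrate_depth_ratio,
                            params$substrate_layers)
  zskin <- seq(0, Tt, length.out = params$through_thickness_layers + 1L)
  zlev <- c(zsub, zskin)
  region <- ifelse(zlev[-length(zlev)] < 0, "SUBSTRATE", "SKIN")
  build_from_lattice(params, lobe_map(params), zlev, region, lobe_tags(),
                     crease_direction = c(0, 1, 0),
                     crease_plane_normal = c(1, 0, 0))
}

#' Flat film-on-substrate strip
#'
#' A rectangular stiff film of thickness `T` bonded to a soft substrate with
#' a fixed bottom face, used to validate the classical wrinkling-wavelength
#' law \eqn{\lambda = 2\pi T (\mu_k / 3\mu_s)^{1/3}}. The bottom nodes are
#' tagged `FIXED_INNER` (they play the role of the rigid base), the top
#' surface `ANTERIOR_SURFACE`.
#'
#' @inheritParams build_semicylinder_sheet
#' @return a `tet_mesh` with regions `"SKIN"` and `"SUBSTRATE"`.
#' @export
build_bilayer_strip <- function(params) {
  stopifnot(inherits(params, "geometry_params"))
  if (params$kind != "BILAYER_STRIP") stop("params$kind must be BILAYER_STRIP")
  Tt <- params$thickness_T
  Len <- params$boundary_length_L
  Wd <- params$strip_width
  map <- function(u, v) cbind(u * Len, v * Wd)
  zsub <- substrate_zlevels(Tt, params$substrate_depth_ratio,
                            params$substrate_layers)
  zskin <- seq(0, Tt, length.out = params$through_thickness_layers + 1L)
  zlev <- c(zsub, zskin)
  region <- ifelse(zlev[-length(zlev)] < 0, "SUBSTRATE", "SKIN")
  # the end faces are held in their planes (lateral confinement, so the film
  # cannot shed its growth by elongating); they carry no crease growth
  tag <- function(lin, n1, n2, nz) {
    ends <- unlist(lapply(0:nz, function(k) c(lin(0L, 0:n2, k),
                                              lin(n1, 0:n2, k))))
    list(FIXED_INNER = lin(rep(0:n1, n2 + 1L), rep(0:n2, each = n1 + 1L), 0L),
         CREASE = integer(0),
         PLANE_CONFINED = ends,
         ANTERIOR_SURFACE = lin(rep(0:n1, n2 + 1L), rep(0:n2, each = n1 + 1L), nz),
         FREE_EDGE = integer(0))
  }
  build_from_lattice(params, map, zlev, region, tag,
                     crease_plane_normal = c(1, 0, 0))
}

#' Per-element depth fields
#'
#' Distance of each tet centroid to the anterior surface (`x_s`) and to the
#' crease plane (`x_c`). These drive the depth attenuation of the growth
#' factors. `x_s` is the exact minimum point-to-triangle distance over the
#' anterior surface triangulation; `x_c` is the distance to the plane spanned
#' by the crease nodes. Meshes without a crease get `x_c = Inf` (no crease
#' growth anywhere).
#'
#' @param mesh a `tet_mesh`.
#' @param require_crease error if the mesh has no crease nodes.
#' @return list with numeric vectors `x_s` and `x_c` (mm, one per tet).
#' @export
compute_depth_fields <- function(mesh, require_crease = FALSE) {
  stopifnot(inherits(mesh, "tet_mesh"))
  if (length(mesh$node_sets$ANTERIOR_SURFACE) == 0 ||
      nrow(mesh$surface_tris) == 0)
    stop("ANTERIOR_SURFACE node set is empty")
  cree <- mesh$node_sets$CREASE
  if (require_crease && length(cree) == 0) stop("CREASE node set is empty")
  cen <- tet_centroids(mesh)
  x_s <- .point_tri_min_dist_cpp(cen, mesh$nodes, mesh$surface_tris)
  if (length(cree) > 0 && !is.null(mesh$crease_plane_normal)) {
    p0 <- mesh$nodes[cree[1], ]
    n <- mesh$crease_plane_normal
    x_c <- abs((cen[, 1] - p0[1]) * n[1] + (cen[, 2] - p0[2]) * n[2] +
                 (cen[, 3] - p0[3]) * n[3])
  } else {
    x_c <- rep(Inf, nrow(cen))
  }
  list(x_s = x_s, x_c = x_c)
}

tet_centroids <- function(mesh) {
  (mesh$nodes[mesh$tets[, 1], , drop = FALSE] +
     mesh$nodes[mesh$tets[, 2], , drop = FALSE] +
     mesh$nodes[mesh$tets[, 3], , drop = FALSE] +
     mesh$nodes[mesh$tets[, 4], , drop = FALSE]) / 4
}

#' Mesh diagnostic report
#'
#' Pure report: tet volume range, inverted-tet count, edge aspect-ratio
#' distribution, node-set sizes, spacing, and whether the mean node spacing
#' resolves the sheet thickness.
#'
#' @param mesh a `tet_mesh`.
#' @return an object of class `mesh_validation`.
#' @export
validate_mesh <- function(mesh) {
  stopifnot(inherits(mesh, "tet_mesh"))
  vol <- tet_volumes(mesh$nodes, mesh$tets)
  edge_ratio <- function(tet) {
    p <- mesh$nodes[tet, , drop = FALSE]
    d <- stats::dist(p)
    max(d) / min(d)
  }
  ar <- apply(mesh$tets, 1L, edge_ratio)
  structure(list(
    n_nodes = nrow(mesh$nodes), n_tets = nrow(mesh$tets),
    min_volume = min(vol), max_volume = max(vol),
    n_inverted = sum(vol <= 0),
    aspect_ratio = stats::quantile(ar, c(0, 0.5, 0.9, 1)),
    node_set_sizes = vapply(mesh$node_sets, length, integer(1)),
    spacing_a = mesh$spacing_a,
    spacing_resolves_thickness = mesh$spacing_a <= mesh$thickness_T,
    total_volume = sum(abs(vol))), class = "mesh_validation")
}

#' @export
print.mesh_validation <- function(x, ...) {
  cat("tet mesh:", x$n_nodes, "nodes,", x$n_tets, "tets\n")
  cat("  volume range [", signif(x$min_volume, 4), ",",
      signif(x$max_volume, 4), "], total", signif(x$total_volume, 5), "\n")
  cat("  inverted tets:", x$n_inverted, "\n")
  cat("  edge aspect ratio (min/median/q90/max):",
      paste(signif(x$aspect_ratio, 3), collapse = " / "), "\n")
  cat("  node sets:", paste(names(x$node_set_sizes), x$node_set_sizes,
                            sep = "=", collapse = ", "), "\n")
  cat("  spacing a =", signif(x$spacing_a, 4),
      if (x$spacing_resolves_thickness) "(<= T)" else "(> T)", "\n")
  invisible(x)
}

#' @export
print.tet_mesh <- function(x, ...) {
  cat("tet_mesh (", x$params$kind, "): ", nrow(x$nodes), " nodes, ",
      nrow(x$tets), " tets, T = ", x$thickness_T, " mm, L = ",
      x$inner_boundary_length_L, " mm\n", sep = "")
  invisible(x)
}
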