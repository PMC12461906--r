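# PLM: turn an oriented mesh into a two-leaflet point folder.

# Offset a mid-surface point table into outer/inner leaflets at +-t/2 along
# the normal, applying the parallel-surface transforms
#   c_i' = c_i / (1 + s c_i),  area' = area (1 + s c1)(1 + s c2)
# with s = +t/2 (outer) and s = -t/2 (inner). Inner-leaflet curvatures are
# then negated (the surface seen from the flipped normal) and the frame
# flipped to stay right-handed.
offset_leaflets <- function(mid, thickness) {
  s <- thickness / 2
  f1 <- 1 + s * mid$c1
  f2 <- 1 + s * mid$c2
  g1 <- 1 - s * mid$c1
  g2 <- 1 - s * mid$c2
  bad <- which(f1 <= 1e-9 | f2 <= 1e-9 | g1 <= 1e-9 | g2 <= 1e-9)
  if (length(bad))
    stop("leaflet offset t/2 reaches the curvature radius at point id(s) ",
         paste(utils::head(mid$id[bad], 5), collapse = ", "),
         "; use a finer mesh or a thinner bilayer")
  n <- as.matrix(mid[, c("nx", "ny", "nz")])
  pos <- as.matrix(mid[, c("x", "y", "z")])
  outer <- mid
  outer[, c("x", "y", "z")] <- pos + s * n
  outer$c1 <- mid$c1 / f1
  outer$c2 <- mid$c2 / f2
  outer$area <- mid$area * f1 * f2
  inner <- mid
  inner[, c("x", "y", "z")] <- pos - s * n
  inner[, c("nx", "ny", "nz")] <- -n
  ct1 <- mid$c1 / g1
  ct2 <- mid$c2 / g2
  inner$c1 <- -ct2   # negation swaps the (c1 >= c2) order ...
  inner$c2 <- -ct1
  inner[, c("p1x", "p1y", "p1z")] <- mid[, c("p2x", "p2y", "p2z")]  # ... and the directions
  inner[, c("p2x", "p2y", "p2z")] <- mid[, c("p1x", "p1y", "p1z")]
  inner$area <- mid$area * g1 * g2
  list(outer = outer, inner = inner)
}

#' Discretize a mesh into a two-leaflet point folder (PLM)
#'
#' Converts a triangulated surface into the discrete point representation
#' the builder works with: one surface element per mesh vertex, carrying
#' position, area, normal, principal curvatures and directions. The mesh is
#' oriented (and cut, if nonorientable) first, then scaled by `rescale`;
#' outer and inner leaflet points are placed at +-t/2 along the vertex
#' normal with parallel-surface area/curvature transforms so both leaflets
#' honour area-per-lipid on curved membranes. Boundary vertices are flagged
#' `edge = TRUE` on both leaflets; mesh inclusion/exclusion marks map to the
#' corresponding points and mesh edges are retained so geodesic domain
#' operations work on the folder.
#'
#' @param mesh a [tri_mesh()].
#' @param thickness bilayer thickness t (nm); default 3.8, a typical
#'   coarse-grained bilayer.
#' @param rescale isotropic scale factor applied to the mesh before
#'   discretization.
#' @return A [point_folder()] with `2 * n_vertices` points.
#' @export
discretize <- function(mesh, thickness = 3.8, rescale = 1) {
  stopifnot(thickness > 0, rescale > 0)
  om <- orient_mesh(mesh)
  mesh <- om$mesh
  mesh$vertices <- mesh$vertices * rescale
  mesh$box <- mesh$box * rescale
  nv <- nrow(mesh$vertices)
  fr <- principal_curvatures(mesh)
  boundary <- detect_open_edges(mesh)
  mid <- data.frame(
    id = seq_len(nv) - 1L,
    domain = mesh$vertex_domain %||% rep(0L, nv),
    area = fr$area,
    x = mesh$vertices[, 1], y = mesh$vertices[, 2], z = mesh$vertices[, 3],
    nx = fr$normal[, 1], ny = fr$normal[, 2], nz = fr$normal[, 3],
    p1x = fr$t1[, 1], p1y = fr$t1[, 2], p1z = fr$t1[, 3],
    p2x = fr$t2[, 1], p2y = fr$t2[, 2], p2z = fr$t2[, 3],
    c1 = fr$c1, c2 = fr$c2,
    edge = seq_len(nv) %in% boundary)
  leaf <- offset_leaflets(mid, thickness)
  inc <- NULL
  if (nrow(mesh$inclusions)) {
    rows <- lapply(seq_len(nrow(mesh$inclusions)), function(k) {
      vtx <- mesh$inclusions$vertex[k]
      n <- fr$normal[vtx, ]
      u <- c(mesh$inclusions$dx[k], mesh$inclusions$dy[k], 0)
      u <- u - sum(u * n) * n           # project onto the tangent plane
      if (sqrt(sum(u^2)) < 1e-9) u <- fr$t1[vtx, ]
      u <- u / sqrt(sum(u^2))
      data.frame(id = k - 1L, type_id = mesh$inclusions$type_id[k],
                 point_id = vtx - 1L, ux = u[1], uy = u[2], uz = u[3])
    })
    inc <- do.call(rbind, rows)
  }
  exc <- NULL
  if (nrow(mesh$exclusions)) {
    exc <- data.frame(id = seq_len(nrow(mesh$exclusions)) - 1L,
                      point_id = mesh$exclusions$vertex - 1L,
                      radius = mesh$exclusions$radius)
  }
  ei <- mesh_edge_index(mesh)
  edges <- unique(cbind(ei$lo, ei$hi)) - 1L
  point_folder(leaf$outer, leaf$inner, mesh$box,
               inclusions = inc, exclusions = exc, edges = edges)
}
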