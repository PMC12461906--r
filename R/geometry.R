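# Per-vertex discrete differential geometry. The sign convention throughout:
# a sphere with outward normals has c1 = c2 = +1/R, and mean curvature
# H = (c1 + c2)/2 is positive on convex regions seen along the normal.

vertex_adjacency <- function(mesh) {
  tr <- mesh$triangles
  a <- c(tr[, 1], tr[, 2], tr[, 3], tr[, 2], tr[, 3], tr[, 1])
  b <- c(tr[, 2], tr[, 3], tr[, 1], tr[, 1], tr[, 2], tr[, 3])
  adj <- split(b, factor(a, levels = seq_len(nrow(mesh$vertices))))
  lapply(adj, function(x) sort(unique(x)))
}

tri_geometry <- function(mesh) {
  v <- mesh$vertices
  t <- mesh$triangles
  e1 <- v[t[, 2], , drop = FALSE] - v[t[, 1], , drop = FALSE]
  e2 <- v[t[, 3], , drop = FALSE] - v[t[, 1], , drop = FALSE]
  fn <- cross3(e1, e2)
  area <- 0.5 * vnorm(fn)
  list(fn = fn, area = area)
}

#' Per-vertex unit normals
#'
#' Angle-weighted average of incident triangle normals (the weight of each
#' triangle at a vertex is the wedge angle there), normalized. Boundary
#' vertices use their one-sided fan.
#'
#' @param mesh an oriented [tri_mesh()].
#' @return A numeric matrix of unit normals, one row per vertex.
#' @export
vertex_normals <- function(mesh) {
  v <- mesh$vertices
  tr <- mesh$triangles
  tg <- tri_geometry(mesh)
  fn_unit <- normalize_rows(tg$fn)
  acc <- matrix(0, nrow(v), 3)
  corner_angle <- function(p, q, r) {
    u <- normalize_rows(v[q, , drop = FALSE] - v[p, , drop = FALSE])
    w <- normalize_rows(v[r, , drop = FALSE] - v[p, , drop = FALSE])
    acos(pmin(1, pmax(-1, rowSums(u * w))))
  }
  for (corner in 1:3) {
    p <- tr[, corner]
    q <- tr[, corner %% 3L + 1L]
    r <- tr[, (corner + 1L) %% 3L + 1L]
    w <- corner_angle(p, q, r)
    for (d in 1:3) acc[, d] <- acc[, d] +
        as.numeric(tapply(w * fn_unit[, d], factor(p, levels = seq_len(nrow(v))),
                          sum, default = 0))
  }
  nrm <- vnorm(acc)
  isolated <- which(nrm < 1e-300)
  if (length(isolated))
    stop("isolated vertex with no incident triangle: ",
         paste(isolated, collapse = ", "))
  acc / nrm
}

#' Per-vertex areas (barycentric rule)
#'
#' Each triangle contributes one third of its area to each of its vertices,
#' so the vertex areas sum to the total mesh area exactly.
#'
#' @param mesh an oriented [tri_mesh()].
#' @return Numeric vector of per-vertex areas (nm^2).
#' @export
vertex_areas <- function(mesh) {
  tg <- tri_geometry(mesh)
  if (any(tg$area == 0)) warning("zero-area triangle contributes no area")
  tr <- mesh$triangles
  acc <- numeric(nrow(mesh$vertices))
  third <- tg$area / 3
  for (corner in 1:3) {
    s <- tapply(third, factor(tr[, corner], levels = seq_len(nrow(mesh$vertices))),
                sum, default = 0)
    acc <- acc + as.numeric(s)
  }
  acc
}

local_tangent_basis <- function(n) {
  h <- if (abs(n[1]) <= abs(n[2]) && abs(n[1]) <= abs(n[3])) c(1, 0, 0)
       else if (abs(n[2]) <= abs(n[3])) c(0, 1, 0) else c(0, 0, 1)
  b1 <- cross3(h, n)[1, ]
  b1 <- b1 / sqrt(sum(b1^2))
  b2 <- cross3(n, b1)[1, ]
  list(b1 = b1, b2 = b2)
}

#' Principal curvatures and directions by local quadric fitting
#'
#' For each vertex, its neighbor ring (1-ring, escalated to the 2-ring when
#' fewer than 5 neighbors are available, e.g. at open edges) is expressed in
#' the local frame as tangent offsets (u, v) and normal heights h, and the
#' quadratic height function h(u,v) = (a u^2 + 2 b u v + c v^2)/2 is fitted
#' by least squares. The shape operator -[[a,b],[b,c]] is eigen-decomposed
#' into principal curvatures c1 >= c2 (nm^-1) and orthonormal principal
#' directions t1, t2 completing a right-handed frame with the normal.
#' A rank-deficient fit (collinear neighbors) degrades to zero curvature
#' with `degenerate = TRUE`.
#'
#' @param mesh an oriented [tri_mesh()].
#' @param normals optional precomputed [vertex_normals()].
#' @return A list with matrices `normal`, `t1`, `t2` (one row per vertex),
#'   vectors `c1`, `c2`, `area`, and logical `degenerate`.
#' @export
principal_curvatures <- function(mesh, normals = NULL) {
  v <- mesh$vertices
  nv <- nrow(v)
  normals <- normals %||% vertex_normals(mesh)
  adj <- vertex_adjacency(mesh)
  area <- vertex_areas(mesh)
  c1 <- numeric(nv); c2 <- numeric(nv)
  t1 <- matrix(0, nv, 3); t2 <- matrix(0, nv, 3)
  degenerate <- logical(nv)
  for (i in seq_len(nv)) {
    nb <- adj[[i]]
    if (length(nb) < 5L)
      nb <- setdiff(sort(unique(c(nb, unlist(adj[nb])))), i)
    n <- normals[i, ]
    tb <- local_tangent_basis(n)
    d <- sweep(v[nb, , drop = FALSE], 2, v[i, ])
    u <- drop(d %*% tb$b1)
    w <- drop(d %*% tb$b2)
    h <- drop(d %*% n)
    A <- cbind(u^2 / 2, u * w, w^2 / 2)
    qrA <- qr(A)
    if (length(nb) < 3L || qrA$rank < 3L) {
      degenerate[i] <- TRUE
      t1[i, ] <- tb$b1; t2[i, ] <- tb$b2
      next
    }
    coef <- qr.coef(qrA, h)
    S <- -matrix(c(coef[1], coef[2], coef[2], coef[3]), 2, 2)
    ee <- eigen(S, symmetric = TRUE)  # values in decreasing order
    c1[i] <- ee$values[1]
    c2[i] <- ee$values[2]
    d1 <- ee$vectors[1, 1] * tb$b1 + ee$vectors[2, 1] * tb$b2
    d2 <- ee$vectors[1, 2] * tb$b1 + ee$vectors[2, 2] * tb$b2
    d1 <- d1 / sqrt(sum(d1^2))
    d2 <- d2 / sqrt(sum(d2^2))
    if (sum(cross3(d1, d2)[1, ] * n) < 0) d2 <- -d2
    t1[i, ] <- d1; t2[i, ] <- d2
  }
  if (any(degenerate))
    warning(sum(degenerate), " vertex/vertices had a rank-deficient curvature",
            " fit; zero curvature assumed there")
  list(normal = normals, t1 = t1, t2 = t2, c1 = c1, c2 = c2,
       area = area, degenerate = degenerate)
}
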