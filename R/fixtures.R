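# Deterministic synthetic geometry and toy structures: every module is
# testable (and demoable) offline. The shapes have known analytic
# curvature, which is what makes them useful oracles.

#' Synthetic test meshes
#'
#' Deterministic generators for the geometries the pipeline has to handle:
#' * `icosphere`: icosahedron subdivision projected to radius `r`
#'   (closed, orientable; `10 * 4^subdiv + 2` vertices).
#' * `cylinder`: parametric side wall plus cap fans (closed).
#' * `torus`: ring radius `r_major`, tube radius `r_minor` (closed).
#' * `moebius`: `(u,v) -> ((1 + v cos(u/2)) cos u, (1 + v cos(u/2)) sin u,
#'   v sin(u/2))` scaled by `r` — nonorientable, one continuous rim;
#'   [orient_mesh()] will cut it.
#' * `sine_sheet` / `flat_grid`: open sheets, `z = amplitude *
#'   sin(2 pi periods x / lx)`.
#'
#' @param shape one of the shapes above.
#' @param r,r_major,r_minor radii (nm).
#' @param subdiv icosphere subdivision level (>= 0).
#' @param lx,ly sheet extent (nm); `l` cylinder length.
#' @param nu,nv,nx,ny resolution parameters (vertex counts per direction).
#' @param amplitude,periods sine parameters.
#' @param width Moebius half-width (nm), in units of `r`.
#' @return A [tri_mesh()].
#' @export
make_mesh <- function(shape = c("icosphere", "cylinder", "torus", "moebius",
                                "sine_sheet", "flat_grid"),
                      r = 10, subdiv = 2, l = 20, r_major = 10, r_minor = 3,
                      lx = 16, ly = 16, nx = 17, ny = 17, nu = 40, nv = 5,
                      amplitude = 2, periods = 1, width = 0.35) {
  shape <- match.arg(shape)
  switch(shape,
         icosphere = mesh_icosphere(r, subdiv),
         cylinder = mesh_cylinder(r, l, nu, max(3L, nv)),
         torus = mesh_torus(r_major, r_minor, nu, max(3L, nv)),
         moebius = mesh_moebius(r, width, nu, nv),
         sine_sheet = mesh_sheet(lx, ly, nx, ny, amplitude, periods),
         flat_grid = mesh_sheet(lx, ly, nx, ny, 0, 1))
}

sheet_triangles <- function(nx, ny, wrap_i = FALSE, wrap_j = FALSE) {
  idx <- function(i, j) (j - 1L) * nx + i
  tris <- list()
  imax <- if (wrap_i) nx else nx - 1L
  jmax <- if (wrap_j) ny else ny - 1L
  for (j in seq_len(jmax)) for (i in seq_len(imax)) {
    i2 <- if (i == nx) 1L else i + 1L
    j2 <- if (j == ny) 1L else j + 1L
    tris[[length(tris) + 1L]] <- c(idx(i, j), idx(i2, j), idx(i2, j2))
    tris[[length(tris) + 1L]] <- c(idx(i, j), idx(i2, j2), idx(i, j2))
  }
  do.call(rbind, tris)
}

mesh_sheet <- function(lx, ly, nx, ny, amplitude, periods) {
  g <- expand.grid(i = seq_len(nx), j = seq_len(ny))
  x <- (g$i - 1) * lx / (nx - 1)
  y <- (g$j - 1) * ly / (ny - 1)
  lz <- max(2 * amplitude, 1) + 8
  z <- lz / 2 + amplitude * sin(2 * pi * periods * x / lx)
  tri_mesh(cbind(x, y, z), sheet_triangles(nx, ny), c(lx, ly, lz))
}

mesh_icosphere <- function(r, subdiv) {
  phi <- (1 + sqrt(5)) / 2
  v <- rbind(c(-1, phi, 0), c(1, phi, 0), c(-1, -phi, 0), c(1, -phi, 0),
             c(0, -1, phi), c(0, 1, phi), c(0, -1, -phi), c(0, 1, -phi),
             c(phi, 0, -1), c(phi, 0, 1), c(-phi, 0, -1), c(-phi, 0, 1))
  f <- rbind(c(1, 12, 6), c(1, 6, 2), c(1, 2, 8), c(1, 8, 11), c(1, 11, 12),
             c(2, 6, 10), c(6, 12, 5), c(12, 11, 3), c(11, 8, 7), c(8, 2, 9),
             c(4, 10, 5), c(4, 5, 3), c(4, 3, 7), c(4, 7, 9), c(4, 9, 10),
             c(5, 10, 6), c(3, 5, 12), c(7, 3, 11), c(9, 7, 8), c(10, 9, 2))
  v <- v / sqrt(rowSums(v^2))
  for (s in seq_len(subdiv)) {
    cache <- new.env()
    midpoint <- function(a, b) {
      key <- paste(min(a, b), max(a, b))
      if (!is.null(cache[[key]])) return(cache[[key]])
      m <- (v[a, ] + v[b, ]) / 2
      m <- m / sqrt(sum(m^2))
      v <<- rbind(v, m)
      cache[[key]] <- nrow(v)
      nrow(v)
    }
    f2 <- list()
    for (t in seq_len(nrow(f))) {
      a <- f[t, 1]; b <- f[t, 2]; c_ <- f[t, 3]
      ab <- midpoint(a, b); bc <- midpoint(b, c_); ca <- midpoint(c_, a)
      f2[[length(f2) + 1L]] <- rbind(c(a, ab, ca), c(b, bc, ab),
                                     c(c_, ca, bc), c(ab, bc, ca))
    }
    f <- do.call(rbind, f2)
  }
  half <- r + 3
  tri_mesh(sweep(v * r, 2, rep(half, 3), "+"), f, rep(2 * half, 3))
}

mesh_cylinder <- function(r, l, nu, nz) {
  th <- 2 * pi * (seq_len(nu) - 1) / nu
  g <- expand.grid(i = seq_len(nu), j = seq_len(nz))
  thg <- th[g$i]
  z <- (g$j - 1) * l / (nz - 1)
  half <- r + 3
  v <- cbind(half + r * cos(thg), half + r * sin(thg), 1 + z)
  tris <- sheet_triangles(nu, nz, wrap_i = TRUE)
  bot <- nrow(v) + 1L
  top <- nrow(v) + 2L
  v <- rbind(v, c(half, half, 1), c(half, half, 1 + l))
  caps <- list()
  for (i in seq_len(nu)) {
    i2 <- if (i == nu) 1L else i + 1L
    caps[[length(caps) + 1L]] <- c(bot, i2, i)                       # bottom ring
    caps[[length(caps) + 1L]] <- c(top, (nz - 1L) * nu + i, (nz - 1L) * nu + i2)
  }
  tri_mesh(v, rbind(tris, do.call(rbind, caps)), c(2 * half, 2 * half, l + 2))
}

mesh_torus <- function(r_major, r_minor, nu, nv) {
  g <- expand.grid(i = seq_len(nu), j = seq_len(nv))
  u <- 2 * pi * (g$i - 1) / nu
  w <- 2 * pi * (g$j - 1) / nv
  half <- r_major + r_minor + 2
  v <- cbind(half + (r_major + r_minor * cos(w)) * cos(u),
             half + (r_major + r_minor * cos(w)) * sin(u),
             r_minor + 1 + r_minor * sin(w))
  tri_mesh(v, sheet_triangles(nu, nv, wrap_i = TRUE, wrap_j = TRUE),
           c(2 * half, 2 * half, 2 * (r_minor + 1)))
}

mesh_moebius <- function(r, width, nu, nv) {
  stopifnot(nu >= 8, nv >= 2)
  g <- expand.grid(i = seq_len(nu), j = seq_len(nv))
  u <- 2 * pi * (g$i - 1) / nu
  vv <- width * (2 * (g$j - 1) / (nv - 1) - 1)
  pos <- r * cbind((1 + vv * cos(u / 2)) * cos(u),
                   (1 + vv * cos(u / 2)) * sin(u),
                   vv * sin(u / 2))
  half <- r * (1 + width) + 2
  pos <- sweep(pos, 2, c(half, half, r * width + 2), "+")
  idx <- function(i, j) {
    # closing the band identifies column nu+1 with column 1, v reversed
    wrapped <- i > nu
    i <- ifelse(wrapped, i - nu, i)
    j <- ifelse(wrapped, nv + 1L - j, j)
    (j - 1L) * nu + i
  }
  tris <- list()
  for (j in seq_len(nv - 1L)) for (i in seq_len(nu)) {
    tris[[length(tris) + 1L]] <- c(idx(i, j), idx(i + 1L, j), idx(i + 1L, j + 1L))
    tris[[length(tris) + 1L]] <- c(idx(i, j), idx(i + 1L, j + 1L), idx(i, j + 1L))
  }
  tri_mesh(pos, do.call(rbind, tris),
           c(2 * half, 2 * half, 2 * (r * width + 2)))
}

#' Toy structures: mini lipid library, rigid protein, water template
#'
#' Writes three deterministic files into `dir`: `toy.LIB` (four toy lipid
#' templates with POPC/CDL/CHOL/DLPC-like bead geometries), `protein.gro`
#' (a rigid 50-bead helical rod with a defined +z axis, centroid at the
#' origin) and `water.gro` (a 3 nm cube of 216 jittered single-bead
#' waters, i.e. 8 beads/nm^3). Byte-identical for the same seed.
#'
#' @param dir output directory.
#' @param seed integer seed for the water jitter.
#' @return Named list of the three file paths.
#' @export
make_toy_structures <- function(dir, seed = 1) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  lib_path <- file.path(dir, "toy.LIB")
  file.copy(toy_lib_path(), lib_path, overwrite = TRUE)
  # 50-bead helical rod, axis +z, centroid at origin
  i <- seq_len(50)
  z <- seq(-2, 2, length.out = 50)
  prot <- membrane_model(
    data.frame(resid = 1L, resname = "PROT", atom = sprintf("B%d", i),
               x = 0.3 * cos(i), y = 0.3 * sin(i), z = z, mol = "PROT"),
    box = c(5, 5, 5))
  prot$beads$x <- prot$beads$x - mean(prot$beads$x)
  prot$beads$y <- prot$beads$y - mean(prot$beads$y)
  prot$beads$z <- prot$beads$z - mean(prot$beads$z)
  prot_path <- file.path(dir, "protein.gro")
  write_gro(prot, prot_path, title = "toy rigid protein (synthetic)")
  wat_path <- file.path(dir, "water.gro")
  with_seed(seed, {
    g <- expand.grid(i = 1:6, j = 1:6, k = 1:6)
    jit <- matrix(stats::runif(3 * 216, -0.05, 0.05), ncol = 3)
    wat <- membrane_model(
      data.frame(resid = seq_len(216), resname = "W", atom = "W",
                 x = (g$i - 0.5) * 0.5 + jit[, 1],
                 y = (g$j - 0.5) * 0.5 + jit[, 2],
                 z = (g$k - 0.5) * 0.5 + jit[, 3], mol = "W"),
      box = c(3, 3, 3))
    write_gro(wat, wat_path, title = "toy water template (synthetic)")
  })
  list(lib = lib_path, protein = prot_path, water = wat_path)
}
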