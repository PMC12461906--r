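# PCG: analytical membranes, lipid/protein placement into 3D coordinates,
# wall beads, and GRO/TOP serialization.

#' Membrane models: placed beads with residue bookkeeping
#'
#' A `membrane_model` holds an ordered bead table (`resid` = residue
#' instance, `resname`, `atom`, position in nm, `mol` = molecule name used
#' for the topology), an anchor table mapping each lipid residue back to
#' its surface point, and the box. Molecule counts for the topology are
#' derived from the bead order (first-appearance / run-length over residue
#' instances, the GROMACS contract).
#'
#' @param beads data.frame with columns `resid`, `resname`, `atom`,
#'   `x`, `y`, `z`, `mol`.
#' @param box numeric length-3 (nm).
#' @param anchors optional data.frame (`resid`, `mol`, `leaflet`,
#'   `point_id`, `ax`, `ay`, `az`).
#' @return An object of class `membrane_model`.
#' @export
membrane_model <- function(beads, box, anchors = NULL) {
  structure(list(beads = beads, box = as.numeric(box),
                 anchors = anchors %||%
                   data.frame(resid = integer(), mol = character(),
                              leaflet = character(), point_id = integer(),
                              ax = numeric(), ay = numeric(), az = numeric())),
            class = "membrane_model")
}

#' @export
print.membrane_model <- function(x, ...) {
  mc <- molecule_counts(x)
  cat(sprintf("<membrane_model> %d beads, %d residues, box %.3g x %.3g x %.3g nm\n",
              nrow(x$beads), length(unique(x$beads$resid)),
              x$box[1], x$box[2], x$box[3]))
  if (nrow(mc)) cat(paste(sprintf("  %-8s %d", mc$name, mc$count), collapse = "\n"), "\n")
  invisible(x)
}

#' Molecule counts in bead (first-appearance) order
#'
#' Run-length encoding of the molecule names over residue instances, i.e.
#' exactly the `[ molecules ]` section GROMACS expects for the bead order
#' of the model.
#'
#' @param model a [membrane_model()].
#' @return data.frame with columns `name`, `count`.
#' @export
molecule_counts <- function(model) {
  b <- model$beads
  if (!nrow(b)) return(data.frame(name = character(), count = integer()))
  first <- !duplicated(b$resid)
  r <- rle(b$mol[first])
  data.frame(name = r$values, count = r$lengths)
}

#' Analytical point folders: flat, vesicle, cylinder, sine
#'
#' Generates a two-leaflet point folder directly from an analytical shape,
#' with exact frames (no discrete curvature estimation):
#' * `flat`: `lx` x `ly` nm periodic sheet; grid spacing `sqrt(apl_hint)`
#'   rounded to a commensurate grid, H = 0.
#' * `vesicle`: radius `r`; Fibonacci-sphere sampling with
#'   `N = round(4 pi r^2 / apl_hint)` points of equal area, c1 = c2 = 1/r.
#' * `cylinder`: radius `r`, length `l` (periodic tube along z);
#'   (c1, c2) = (1/r, 0).
#' * `sine`: sheet with `z = amplitude * sin(2 pi periods x / lx)`;
#'   curvature from the exact parametric formula and metric-corrected
#'   per-point areas.
#'
#' When the box is not commensurate with `apl_hint` the spacing is rounded
#' and the realized area per point reported via a message. Grid shapes
#' carry 4-neighbor adjacency so geodesic operations work; analytical
#' shapes are periodic, so no point is edge-flagged.
#'
#' @param kind one of `"flat"`, `"vesicle"`, `"cylinder"`, `"sine"`.
#' @param lx,ly sheet dimensions (nm), for `flat`/`sine`.
#' @param r radius (nm), for `vesicle`/`cylinder`.
#' @param l cylinder length (nm).
#' @param amplitude,periods sine amplitude (nm) and number of periods.
#' @param apl_hint target area per point = area per lipid (nm^2).
#' @param thickness bilayer thickness (nm).
#' @param lz box height (nm); default accommodates shape + bilayer + margin.
#' @return A [point_folder()].
#' @export
analytical_folder <- function(kind = c("flat", "vesicle", "cylinder", "sine"),
                              lx = 16, ly = 16, r = 10, l = 20,
                              amplitude = 2, periods = 1,
                              apl_hint = 0.64, thickness = 3.8, lz = NULL) {
  kind <- match.arg(kind)
  a <- sqrt(apl_hint)
  grid_sheet <- function(zfun, lz) {
    nx <- max(1L, round(lx / a))
    ny <- max(1L, round(ly / a))
    ax <- lx / nx; ay <- ly / ny
    if (abs(ax * ay - apl_hint) > 1e-9)
      message(sprintf("grid rounded: realized area per point %.4f nm^2", ax * ay))
    g <- expand.grid(i = seq_len(nx), j = seq_len(ny))
    x <- (g$i - 0.5) * ax
    y <- (g$j - 0.5) * ay
    zf <- zfun(x)
    w <- sqrt(1 + zf$dz^2)
    n <- cbind(-zf$dz, 0, 1) / w
    t1 <- cbind(1, 0, zf$dz) / w
    t2 <- cbind(0, 1, 0)[rep(1, length(x)), , drop = FALSE]
    kx <- -zf$d2z / w^3
    mid <- data.frame(
      id = seq_along(x) - 1L, domain = 0L, area = ax * ay * w,
      x = x, y = y, z = lz / 2 + zf$z,
      nx = n[, 1], ny = n[, 2], nz = n[, 3],
      p1x = ifelse(kx >= 0, t1[, 1], t2[, 1]),
      p1y = ifelse(kx >= 0, t1[, 2], t2[, 2]),
      p1z = ifelse(kx >= 0, t1[, 3], t2[, 3]),
      p2x = ifelse(kx >= 0, t2[, 1], t1[, 1]),
      p2y = ifelse(kx >= 0, t2[, 2], t1[, 2]),
      p2z = ifelse(kx >= 0, t2[, 3], t1[, 3]),
      c1 = pmax(kx, 0), c2 = pmin(kx, 0),
      edge = FALSE)
    idx <- function(i, j) (j - 1L) * nx + i
    g2 <- expand.grid(i = seq_len(nx), j = seq_len(ny))
    right <- cbind(idx(g2$i, g2$j), idx(g2$i %% nx + 1L, g2$j))
    up <- cbind(idx(g2$i, g2$j), idx(g2$i, g2$j %% ny + 1L))
    edges <- unique(rbind(right, up))
    edges <- edges[edges[, 1] != edges[, 2], , drop = FALSE]
    if (nrow(edges)) {
      edges <- unique(cbind(pmin(edges[, 1], edges[, 2]),
                            pmax(edges[, 1], edges[, 2]))) - 1L
    } else edges <- NULL
    list(mid = mid, edges = edges, box = c(lx, ly, lz))
  }
  if (kind == "flat") {
    lz <- lz %||% (thickness + 6)
    sh <- grid_sheet(function(x) list(z = 0 * x, dz = 0 * x, d2z = 0 * x), lz)
  } else if (kind == "sine") {
    lz <- lz %||% (2 * amplitude + thickness + 6)
    om <- 2 * pi * periods / lx
    sh <- grid_sheet(function(x) list(z = amplitude * sin(om * x),
                                      dz = amplitude * om * cos(om * x),
                                      d2z = -amplitude * om^2 * sin(om * x)), lz)
  } else if (kind == "cylinder") {
    nu <- max(3L, round(2 * pi * r / a))
    nz <- max(2L, round(l / a))
    du <- 2 * pi / nu
    az <- l / nz
    g <- expand.grid(i = seq_len(nu), j = seq_len(nz))
    th <- (g$i - 0.5) * du
    z <- (g$j - 0.5) * az
    half <- r + thickness / 2 + 2
    n <- cbind(cos(th), sin(th), 0)
    mid <- data.frame(
      id = seq_len(nrow(g)) - 1L, domain = 0L, area = r * du * az,
      x = half + r * cos(th), y = half + r * sin(th), z = z,
      nx = n[, 1], ny = n[, 2], nz = n[, 3],
      p1x = -sin(th), p1y = cos(th), p1z = 0,
      p2x = 0, p2y = 0, p2z = 1,
      c1 = 1 / r, c2 = 0, edge = FALSE)
    idx <- function(i, j) (j - 1L) * nu + i
    around <- cbind(idx(g$i, g$j), idx(g$i %% nu + 1L, g$j))
    along <- cbind(idx(g$i, g$j), idx(g$i, g$j %% nz + 1L))
    edges <- unique(rbind(around, along))
    edges <- unique(cbind(pmin(edges[, 1], edges[, 2]),
                          pmax(edges[, 1], edges[, 2]))) - 1L
    sh <- list(mid = mid, edges = edges, box = c(2 * half, 2 * half, l))
  } else { # vesicle
    N <- max(4L, round(4 * pi * r^2 / apl_hint))
    i <- seq_len(N) - 1L
    zs <- 1 - 2 * (i + 0.5) / N
    phi <- i * pi * (3 - sqrt(5))
    rxy <- sqrt(pmax(0, 1 - zs^2))
    n <- cbind(cos(phi) * rxy, sin(phi) * rxy, zs)
    half <- r + thickness / 2 + 2
    t1 <- cross3(matrix(rep(c(0, 0, 1), N), ncol = 3, byrow = TRUE), n)
    deg <- vnorm(t1) < 1e-6
    t1[deg, ] <- matrix(rep(c(1, 0, 0), sum(deg)), ncol = 3, byrow = TRUE)
    t1 <- normalize_rows(t1)
    t2 <- cross3(n, t1)
    mid <- data.frame(
      id = i, domain = 0L, area = 4 * pi * r^2 / N,
      x = half + r * n[, 1], y = half + r * n[, 2], z = half + r * n[, 3],
      nx = n[, 1], ny = n[, 2], nz = n[, 3],
      p1x = t1[, 1], p1y = t1[, 2], p1z = t1[, 3],
      p2x = t2[, 1], p2y = t2[, 2], p2z = t2[, 3],
      c1 = 1 / r, c2 = 1 / r, edge = FALSE)
    sh <- list(mid = mid, edges = NULL, box = rep(2 * half, 3))
  }
  leaf <- offset_leaflets(sh$mid, thickness)
  point_folder(leaf$outer, leaf$inner, sh$box, edges = sh$edges)
}

rotation_to_frame <- function(n, t1, t2, phi) {
  xp <- cos(phi) * t1 + sin(phi) * t2
  yp <- cross3(n, xp)[1, ]
  cbind(xp, yp, n)
}

#' Place lipids onto a point folder (PCG)
#'
#' One lipid per non-excluded point: the template beads (local frame, head
#' first and at the top) are anchored with the head bead at the point,
#' rotated so local +z maps onto the point normal (tails extend toward the
#' mid-surface) with a seeded random azimuthal spin, and translated into
#' place. Bead order is grouped by lipid type (outer leaflet first within
#' each type), so the topology compresses to one molecule line per type.
#'
#' @param folder a [point_folder()] with domains assigned.
#' @param lib a lipid library from [parse_lib()].
#' @param domain_map named character vector: names are domain ids, values
#'   lipid (library entry) names. Every domain present must be mapped.
#' @param seed integer seed for the azimuthal spins.
#' @param apl optional named numeric (lipid -> nm^2): warn when a point's
#'   area deviates from the lipid's area per lipid by more than 20%.
#' @return A [membrane_model()].
#' @export
place_lipids <- function(folder, lib, domain_map, seed = NULL, apl = NULL) {
  doms <- sort(unique(c(folder$outer$domain[!folder$outer$excluded],
                        folder$inner$domain[!folder$inner$excluded])))
  missing <- setdiff(as.character(doms), names(domain_map))
  if (length(missing))
    stop("unmapped domain id(s): ", paste(missing, collapse = ", "))
  absent <- setdiff(unique(domain_map), names(lib))
  if (length(absent))
    stop("lipid(s) not in library: ", paste(absent, collapse = ", "))
  lipid_order <- unique(unname(domain_map))
  with_seed(seed, {
    bead_chunks <- list()
    anchor_chunks <- list()
    resid <- 0L
    for (lname in lipid_order) {
      tpl <- lib[[lname]]
      B <- as.matrix(tpl$beads[, c("x", "y", "z")])
      Brel <- sweep(B, 2, B[1, ])  # head bead at the anchor
      nb <- nrow(B)
      for (lf in c("outer", "inner")) {
        df <- folder[[lf]]
        sel <- which(!df$excluded &
                       as.character(df$domain) %in%
                         names(domain_map)[domain_map == lname])
        if (!length(sel)) next
        sel <- sel[order(df$id[sel])]
        if (!is.null(apl) && lname %in% names(apl)) {
          rel <- abs(df$area[sel] - apl[[lname]]) / apl[[lname]]
          if (any(rel > 0.2))
            warning(sprintf("%d %s point(s) deviate >20%% from APL %.2f nm^2",
                            sum(rel > 0.2), lname, apl[[lname]]))
        }
        for (i in sel) {
          resid <- resid + 1L
          R <- rotation_to_frame(as.numeric(df[i, c("nx", "ny", "nz")]),
                                 as.numeric(df[i, c("p1x", "p1y", "p1z")]),
                                 as.numeric(df[i, c("p2x", "p2y", "p2z")]),
                                 stats::runif(1, 0, 2 * pi))
          pos <- Brel %*% t(R)
          pos <- sweep(pos, 2, as.numeric(df[i, c("x", "y", "z")]), "+")
          bead_chunks[[length(bead_chunks) + 1L]] <-
            list(resid = rep(resid, nb), pos = pos)
          anchor_chunks[[length(anchor_chunks) + 1L]] <-
            data.frame(resid = resid, mol = lname, leaflet = lf,
                       point_id = df$id[i], ax = df$x[i], ay = df$y[i],
                       az = df$z[i])
        }
      }
    }
    if (!length(bead_chunks)) stop("no lipids to place (all points excluded?)")
    anchors <- do.call(rbind, anchor_chunks)
    nper <- vapply(bead_chunks, function(ch) length(ch$resid), integer(1))
    pos <- do.call(rbind, lapply(bead_chunks, `[[`, "pos"))
    resids <- unlist(lapply(bead_chunks, `[[`, "resid"))
    mol <- rep(anchors$mol, nper)
    atom_names <- unlist(lapply(seq_len(nrow(anchors)), function(j)
      lib[[anchors$mol[j]]]$beads$name))
    beads <- data.frame(resid = resids,
                        resname = substr(mol, 1, 5),
                        atom = atom_names,
                        x = pos[, 1], y = pos[, 2], z = pos[, 3],
                        mol = mol)
    membrane_model(beads, folder$box, anchors)
  })
}

#' Describe one protein for placement
#'
#' @param name molecule name (also the topology name).
#' @param structure a [membrane_model()] or path to a GRO file holding the
#'   pre-oriented protein (its own +z must match the desired membrane
#'   normal direction).
#' @param z_offset placement height (nm): the protein's geometric center is
#'   put at the mid-surface point plus `z_offset` along the local normal;
#'   0 centers it in the membrane.
#' @param count copies to place when no inclusions of this type exist
#'   (random fallback).
#' @param collision_radius lipids whose anchor lies within this projected
#'   radius (nm) of the inclusion are removed.
#' @param type_id inclusion type tag this spec consumes; defaults to its
#'   position in the spec list.
#' @return A `protein_spec` list.
#' @export
protein_spec <- function(name, structure, z_offset = 0, count = 1,
                         collision_radius = 0, type_id = NULL) {
  if (is.character(structure)) structure <- read_gro(structure)
  if (!nrow(structure$beads)) stop("protein structure is empty")
  structure(list(name = name, structure = structure, z_offset = z_offset,
                 count = count, collision_radius = collision_radius,
                 type_id = type_id), class = "protein_spec")
}

#' Place proteins at inclusion sites
#'
#' Each protein copy is rotated so its +z axis aligns with the local
#' membrane normal (azimuth from the inclusion's in-plane orientation) and
#' translated so its geometric center sits at the inclusion's mid-surface
#' position plus `z_offset` along the normal. Lipids whose anchor point
#' lies within the spec's `collision_radius` of the inclusion axis
#' (distance projected onto the tangent plane) are removed; no relaxation
#' is performed. Specs without matching inclusions fall back to seeded
#' random placement of `count` copies.
#'
#' @param model a [membrane_model()] from [place_lipids()].
#' @param folder the [point_folder()] the model was built from.
#' @param specs list of [protein_spec()]s.
#' @param seed integer seed (random fallback placement and azimuths).
#' @return The updated [membrane_model()].
#' @export
place_proteins <- function(model, folder, specs, seed = NULL) {
  if (inherits(specs, "protein_spec")) specs <- list(specs)
  mid <- mid_positions(folder)
  df <- folder$outer
  with_seed(seed, {
    for (si in seq_along(specs)) {
      spec <- specs[[si]]
      tid <- spec$type_id %||% si
      inc <- folder$inclusions[folder$inclusions$type_id == tid, , drop = FALSE]
      if (!nrow(inc)) {
        cand <- which(!df$excluded)
        pick <- sample(cand, spec$count)
        inc <- do.call(rbind, lapply(pick, function(i) {
          phi <- stats::runif(1, 0, 2 * pi)
          u <- cos(phi) * as.numeric(df[i, c("p1x", "p1y", "p1z")]) +
               sin(phi) * as.numeric(df[i, c("p2x", "p2y", "p2z")])
          data.frame(id = NA, type_id = tid, point_id = df$id[i],
                     ux = u[1], uy = u[2], uz = u[3])
        }))
      }
      P <- as.matrix(spec$structure$beads[, c("x", "y", "z")])
      Pc <- sweep(P, 2, colMeans(P))
      ext <- 2 * max(vnorm(Pc))
      if (ext > min(folder$box[1:2]))
        warning(spec$name, " is wider than the membrane patch; placed anyway",
                " (no post-placement relaxation)")
      for (k in seq_len(nrow(inc))) {
        i <- match(inc$point_id[k], df$id)
        n <- as.numeric(df[i, c("nx", "ny", "nz")])
        u <- c(inc$ux[k], inc$uy[k], inc$uz[k])
        u <- u - sum(u * n) * n
        if (sqrt(sum(u^2)) < 1e-9) u <- as.numeric(df[i, c("p1x", "p1y", "p1z")])
        u <- u / sqrt(sum(u^2))
        R <- cbind(u, cross3(n, u)[1, ], n)
        center <- mid[i, ] + spec$z_offset * n
        pos <- sweep(Pc %*% t(R), 2, center, "+")
        # clear lipids inside the projected collision radius
        if (spec$collision_radius > 0 && nrow(model$anchors)) {
          rel <- sweep(as.matrix(model$anchors[, c("ax", "ay", "az")]), 2, mid[i, ])
          lat <- rel - outer(drop(rel %*% n), n)
          gone <- model$anchors$resid[vnorm(lat) <= spec$collision_radius]
          if (length(gone)) {
            model$beads <- model$beads[!model$beads$resid %in% gone, , drop = FALSE]
            model$anchors <- model$anchors[!model$anchors$resid %in% gone, ,
                                           drop = FALSE]
          }
        }
        resid <- max(model$beads$resid, 0L) + 1L
        model$beads <- rbind(model$beads, data.frame(
          resid = resid, resname = substr(spec$name, 1, 5),
          atom = spec$structure$beads$atom,
          x = pos[, 1], y = pos[, 2], z = pos[, 3],
          mol = spec$name))
      }
    }
    renumber_model(model)
  })
}

# Compact residue instances to 1..K in current bead order.
renumber_model <- function(model) {
  old <- model$beads$resid
  new <- match(old, unique(old))
  map <- stats::setNames(new[!duplicated(old)], unique(old))
  model$beads$resid <- new
  if (nrow(model$anchors)) {
    model$anchors$resid <- as.integer(map[as.character(model$anchors$resid)])
    model$anchors <- model$anchors[!is.na(model$anchors$resid), , drop = FALSE]
  }
  model
}

#' Wall beads: a restrained scaffold of the membrane shape
#'
#' Emits one virtual bead per `stride`-th mid-surface point plus the index
#' group and a position-restraint stanza template referencing those beads,
#' so the analytical geometry can be preserved throughout a simulation.
#'
#' @param folder a [point_folder()].
#' @param stride keep every `stride`-th point (default 1 = all).
#' @param first_index atom index of the first wall bead in the final
#'   structure (for the index group).
#' @return A list with `beads` (data.frame `resname`, `atom`, `x`, `y`,
#'   `z`), `ndx` (character lines of a `[ WALL ]` index group) and `posre`
#'   (character lines of a position-restraint stanza template).
#' @export
wall_beads <- function(folder, stride = 1, first_index = 1) {
  mid <- mid_positions(folder)
  n <- nrow(mid)
  if (stride >= n) {
    warning("stride >= point count; emitting a single wall bead")
    stride <- n
  }
  sel <- seq(1, n, by = stride)
  beads <- data.frame(resname = "WALL", atom = "WL",
                      x = mid[sel, 1], y = mid[sel, 2], z = mid[sel, 3])
  idx <- first_index + seq_along(sel) - 1L
  ndx <- c("[ WALL ]",
           vapply(split(idx, ceiling(seq_along(idx) / 12)),
                  function(g) paste(g, collapse = " "), character(1)))
  posre <- c("[ position_restraints ]",
             "; ai  funct  fcx    fcy    fcz",
             sprintf("%d 1 1000 1000 1000", seq_along(sel)))
  list(beads = beads, ndx = unname(ndx), posre = posre)
}

#' Append wall beads to a model
#'
#' @param model a [membrane_model()].
#' @param folder the folder the model was built from.
#' @param stride see [wall_beads()].
#' @return List with the updated `model`, `ndx` and `posre` text.
#' @export
add_wall_beads <- function(model, folder, stride = 1) {
  wb <- wall_beads(folder, stride, first_index = nrow(model$beads) + 1L)
  start <- max(model$beads$resid, 0L)
  n <- nrow(wb$beads)
  model$beads <- rbind(model$beads, data.frame(
    resid = start + seq_len(n), resname = wb$beads$resname,
    atom = wb$beads$atom, x = wb$beads$x, y = wb$beads$y, z = wb$beads$z,
    mol = "WALL"))
  list(model = model, ndx = wb$ndx, posre = wb$posre)
}

#' Write a GROMACS structure file
#'
#' Fixed-width GRO: title, atom count, one
#' `%5d%-5s%5s%5d%8.3f%8.3f%8.3f` line per bead (residue and atom numbers
#' wrap modulo 100,000), free-format box line. Coordinates are in nm with
#' three decimals (C's round-half-even). Velocities are never written.
#'
#' @param model a [membrane_model()].
#' @param path output path.
#' @param title title line.
#' @return `path`, invisibly.
#' @export
write_gro <- function(model, path, title = "built by membuildr") {
  b <- model$beads
  resname <- substr(b$resname, 1, 5)
  atom <- substr(b$atom, 1, 5)
  if (any(nchar(b$resname) > 5) || any(nchar(b$atom) > 5))
    warning("residue/atom names longer than 5 characters were truncated")
  lines <- sprintf("%5d%-5s%5s%5d%8.3f%8.3f%8.3f",
                   b$resid %% 100000L, resname, atom,
                   seq_len(nrow(b)) %% 100000L,
                   b$x, b$y, b$z)
  writeLines(c(title, sprintf("%d", nrow(b)), lines,
               sprintf("%10.5f%10.5f%10.5f", model$box[1], model$box[2],
                       model$box[3])), path)
  invisible(path)
}

#' Read a GROMACS structure file
#'
#' Inverse of [write_gro()] within 0.001 nm. Velocities, if present, are
#' ignored; molecule names are taken from residue names.
#'
#' @param path path to a .gro file.
#' @return A [membrane_model()].
#' @export
read_gro <- function(path) {
  lines <- readLines(path, warn = FALSE)
  n <- as.integer(trimws(lines[2]))
  rec <- lines[3:(2 + n)]
  resnr <- as.integer(substr(rec, 1, 5))
  resname <- trimws(substr(rec, 6, 10))
  atom <- trimws(substr(rec, 11, 15))
  x <- as.numeric(substr(rec, 21, 28))
  y <- as.numeric(substr(rec, 29, 36))
  z <- as.numeric(substr(rec, 37, 44))
  box <- as.numeric(strsplit(trimws(lines[3 + n]), "\\s+")[[1]])[1:3]
  newres <- c(TRUE, resnr[-1] != resnr[-n] | resname[-1] != resname[-n])
  membrane_model(data.frame(resid = cumsum(newres), resname = resname,
                            atom = atom, x = x, y = y, z = z, mol = resname),
                 box)
}

#' Write a GROMACS topology
#'
#' `#include` lines, `[ system ]`, and `[ molecules ]` in first-appearance
#' order with exact counts derived from the model's bead order.
#'
#' @param model a [membrane_model()].
#' @param path output path.
#' @param includes character vector of topology files to `#include`.
#' @param system system title.
#' @return `path`, invisibly.
#' @export
write_top <- function(model, path, includes = character(),
                      system = "membuildr membrane") {
  mc <- molecule_counts(model)
  if (!nrow(mc)) stop("refusing to write a topology for an empty model")
  nb <- nrow(model$beads)
  per_res <- table(model$beads$resid)
  if (sum(per_res) != nb)
    stop("molecule counts inconsistent with beads; refusing to write")
  writeLines(c(sprintf('#include "%s"', includes),
               "", "[ system ]", system, "", "[ molecules ]",
               sprintf("%-10s %d", mc$name, mc$count)), path)
  invisible(path)
}
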