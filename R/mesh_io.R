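#' Triangulated surface meshes
#'
#' A `tri_mesh` holds a triangulated surface: an `n x 3` matrix of vertex
#' positions (nm), an `m x 3` integer matrix of triangle vertex indices
#' (1-based internally; counter-clockwise winding = outward normal), a
#' periodic box, and optional per-vertex domain tags plus inclusion marks
#' (abstract protein anchors: type, vertex, in-plane direction) and
#' exclusion marks (abstract membrane holes: vertex, radius).
#'
#' On disk the `.tsi` dialect and OBJ use 0-based vertex ids; indices are
#' converted on read/write so the two conventions never mix.
#'
#' @param vertices numeric matrix, one row per vertex (nm).
#' @param triangles integer matrix, one row per triangle (1-based indices).
#' @param box numeric length-3, strictly positive box lengths (nm).
#' @param vertex_domain optional integer vector of per-vertex domain tags.
#' @param inclusions optional data.frame with columns `type_id`, `vertex`
#'   (1-based), `dx`, `dy` (in-plane direction).
#' @param exclusions optional data.frame with columns `vertex` (1-based) and
#'   `radius` (nm).
#' @return An object of class `tri_mesh`.
#' @export
tri_mesh <- function(vertices, triangles, box, vertex_domain = NULL,
                     inclusions = NULL, exclusions = NULL) {
  vertices <- as.matrix(vertices)
  storage.mode(vertices) <- "double"
  triangles <- as.matrix(triangles)
  storage.mode(triangles) <- "integer"
  dimnames(vertices) <- NULL
  dimnames(triangles) <- NULL
  mesh <- structure(
    list(vertices = vertices, triangles = triangles, box = as.numeric(box),
         vertex_domain = vertex_domain,
         inclusions = inclusions %||%
           data.frame(type_id = integer(), vertex = integer(),
                      dx = numeric(), dy = numeric()),
         exclusions = exclusions %||%
           data.frame(vertex = integer(), radius = numeric())),
    class = "tri_mesh")
  validate_tri_mesh(mesh)
}

validate_tri_mesh <- function(mesh) {
  nv <- nrow(mesh$vertices)
  tr <- mesh$triangles
  if (ncol(mesh$vertices) != 3L) stop("vertices must have 3 columns")
  if (ncol(tr) != 3L) stop("triangles must have 3 columns")
  if (length(mesh$box) != 3L || any(mesh$box <= 0))
    stop("box must be 3 strictly positive lengths")
  if (nrow(tr) > 0L) {
    if (any(tr < 1L) || any(tr > nv))
      stop("triangle index out of range: vertex ids must be < vertex count")
    if (any(tr[, 1] == tr[, 2] | tr[, 2] == tr[, 3] | tr[, 1] == tr[, 3]))
      stop("degenerate triangle with a repeated vertex index")
  }
  bad_inc <- mesh$inclusions$vertex
  if (length(bad_inc) && (any(bad_inc < 1L) || any(bad_inc > nv)))
    stop("inclusion references an out-of-range vertex id")
  bad_exc <- mesh$exclusions$vertex
  if (length(bad_exc) && (any(bad_exc < 1L) || any(bad_exc > nv)))
    stop("exclusion references an out-of-range vertex id")
  mesh
}

#' @export
print.tri_mesh <- function(x, ...) {
  cat(sprintf("<tri_mesh> %d vertices, %d triangles, box %.3g x %.3g x %.3g nm\n",
              nrow(x$vertices), nrow(x$triangles),
              x$box[1], x$box[2], x$box[3]))
  if (nrow(x$inclusions)) cat(sprintf("  %d inclusion mark(s)\n", nrow(x$inclusions)))
  if (nrow(x$exclusions)) cat(sprintf("  %d exclusion mark(s)\n", nrow(x$exclusions)))
  invisible(x)
}

tokenize_lines <- function(path) {
  lines <- readLines(path, warn = FALSE)
  toks <- strsplit(trimws(lines), "\\s+")
  keep <- vapply(toks, function(t) length(t) > 0 && nzchar(t[1]), logical(1))
  list(tokens = toks[keep], lineno = which(keep))
}

#' Read a triangulated surface in the .tsi dialect
#'
#' The dialect (FreeDTS-style) is: `version <x>`; `box <Lx> <Ly> <Lz>`;
#' `vertex <N>` followed by N lines `<id> <x> <y> <z> [domain]`;
#' `triangle <M>` followed by M lines `<id> <v1> <v2> <v3>`; then optional
#' `inclusion <K>` (`<id> <type> <vertex_id> <dx> <dy>`) and
#' `exclusion <J>` (`<id> <vertex_id> <radius>`) sections. Vertex ids are
#' 0-based on disk. A version other than 1.1 only warns: tolerant parsing
#' aids interoperability with mesh exporters.
#'
#' @param path path to a .tsi file.
#' @return A [tri_mesh()].
#' @export
read_tsi <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  tk <- tokenize_lines(path)
  toks <- tk$tokens
  ln <- tk$lineno
  i <- 1L
  expect <- function(word) {
    if (i > length(toks) || tolower(toks[[i]][1]) != word)
      stop(sprintf("malformed .tsi: expected '%s' at line %d", word,
                   if (i <= length(toks)) ln[i] else NA_integer_))
  }
  expect("version")
  if (!identical(toks[[i]][2], "1.1"))
    warning("tsi version '", toks[[i]][2], "' differs from 1.1; parsing anyway")
  i <- i + 1L
  expect("box")
  box <- suppressWarnings(as.numeric(toks[[i]][2:4]))
  if (any(is.na(box)) || any(box <= 0))
    stop(sprintf("malformed box at line %d", ln[i]))
  i <- i + 1L
  expect("vertex")
  nv <- as.integer(toks[[i]][2]); i <- i + 1L
  vid <- integer(nv); verts <- matrix(NA_real_, nv, 3); dom <- integer(nv)
  has_dom <- FALSE
  for (k in seq_len(nv)) {
    t <- toks[[i]]
    if (length(t) < 4) stop(sprintf("malformed vertex record at line %d", ln[i]))
    vid[k] <- as.integer(t[1])
    verts[k, ] <- as.numeric(t[2:4])
    if (length(t) >= 5) { dom[k] <- as.integer(t[5]); has_dom <- TRUE }
    i <- i + 1L
  }
  ord <- order(vid)
  verts <- verts[ord, , drop = FALSE]
  dom <- dom[ord]
  if (!identical(sort(vid), 0:(nv - 1L)))
    stop("vertex ids must be the 0-based range 0..N-1")
  expect("triangle")
  nt <- as.integer(toks[[i]][2]); i <- i + 1L
  tris <- matrix(NA_integer_, nt, 3)
  for (k in seq_len(nt)) {
    t <- toks[[i]]
    if (length(t) < 4) stop(sprintf("malformed triangle record at line %d", ln[i]))
    tris[k, ] <- as.integer(t[2:4]) + 1L
    i <- i + 1L
  }
  inc <- data.frame(type_id = integer(), vertex = integer(),
                    dx = numeric(), dy = numeric())
  exc <- data.frame(vertex = integer(), radius = numeric())
  while (i <= length(toks)) {
    head <- tolower(toks[[i]][1])
    n <- as.integer(toks[[i]][2]); i <- i + 1L
    if (head == "inclusion") {
      rows <- lapply(seq_len(n), function(k) {
        t <- toks[[i + k - 1L]]
        if (length(t) < 5) stop(sprintf("malformed inclusion at line %d", ln[i + k - 1L]))
        data.frame(type_id = as.integer(t[2]), vertex = as.integer(t[3]) + 1L,
                   dx = as.numeric(t[4]), dy = as.numeric(t[5]))
      })
      inc <- do.call(rbind, c(list(inc), rows))
      i <- i + n
    } else if (head == "exclusion") {
      rows <- lapply(seq_len(n), function(k) {
        t <- toks[[i + k - 1L]]
        if (length(t) < 3) stop(sprintf("malformed exclusion at line %d", ln[i + k - 1L]))
        data.frame(vertex = as.integer(t[2]) + 1L, radius = as.numeric(t[3]))
      })
      exc <- do.call(rbind, c(list(exc), rows))
      i <- i + n
    } else {
      stop(sprintf("unknown .tsi section '%s' at line %d", head, ln[i - 1L]))
    }
  }
  tri_mesh(verts, tris, box,
           vertex_domain = if (has_dom) dom else NULL,
           inclusions = inc, exclusions = exc)
}

#' Write a mesh in the .tsi dialect
#'
#' @param mesh a [tri_mesh()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_tsi <- function(mesh, path) {
  validate_tri_mesh(mesh)
  dom <- mesh$vertex_domain %||% rep(0L, nrow(mesh$vertices))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("version 1.1",
               paste("box", paste(fmt_num(mesh$box), collapse = " ")),
               paste("vertex", nrow(mesh$vertices))), con)
  writeLines(sprintf("%d %s %s %s %d", seq_len(nrow(mesh$vertices)) - 1L,
                     fmt_num(mesh$vertices[, 1]), fmt_num(mesh$vertices[, 2]),
                     fmt_num(mesh$vertices[, 3]), dom), con)
  writeLines(paste("triangle", nrow(mesh$triangles)), con)
  if (nrow(mesh$triangles))
    writeLines(sprintf("%d %d %d %d", seq_len(nrow(mesh$triangles)) - 1L,
                       mesh$triangles[, 1] - 1L, mesh$triangles[, 2] - 1L,
                       mesh$triangles[, 3] - 1L), con)
  if (nrow(mesh$inclusions)) {
    writeLines(paste("inclusion", nrow(mesh$inclusions)), con)
    writeLines(sprintf("%d %d %d %s %s", seq_len(nrow(mesh$inclusions)) - 1L,
                       mesh$inclusions$type_id, mesh$inclusions$vertex - 1L,
                       fmt_num(mesh$inclusions$dx), fmt_num(mesh$inclusions$dy)), con)
  }
  if (nrow(mesh$exclusions)) {
    writeLines(paste("exclusion", nrow(mesh$exclusions)), con)
    writeLines(sprintf("%d %d %s", seq_len(nrow(mesh$exclusions)) - 1L,
                       mesh$exclusions$vertex - 1L,
                       fmt_num(mesh$exclusions$radius)), con)
  }
  invisible(path)
}

#' Read a triangulated OBJ file
#'
#' Only `v` and `f` records are supported and all faces must already be
#' triangles (pre-triangulate in your modelling software otherwise). OBJ has
#' no box; a bounding box with a 10% margin is synthesized.
#'
#' @param path path to an OBJ file.
#' @return A [tri_mesh()].
#' @export
read_obj <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  tk <- tokenize_lines(path)
  verts <- list(); faces <- list()
  for (j in seq_along(tk$tokens)) {
    t <- tk$tokens[[j]]
    if (t[1] == "v") {
      verts[[length(verts) + 1L]] <- as.numeric(t[2:4])
    } else if (t[1] == "f") {
      ids <- sub("/.*$", "", t[-1])
      if (length(ids) != 3L)
        stop(sprintf(paste0("face with %d vertices at line %d: only triangles",
                            " are supported; pre-triangulate the mesh"),
                     length(ids), tk$lineno[j]))
      faces[[length(faces) + 1L]] <- as.integer(ids)  # OBJ is 1-based already
    }
  }
  v <- do.call(rbind, verts)
  f <- do.call(rbind, faces)
  span <- apply(v, 2, function(x) diff(range(x)))
  tri_mesh(v, f, pmax(span * 1.2, 1))
}

# Undirected edge bookkeeping: key, incident triangles, traversal direction.
mesh_edge_index <- function(mesh) {
  tr <- mesh$triangles
  m <- nrow(tr)
  a <- c(tr[, 1], tr[, 2], tr[, 3])
  b <- c(tr[, 2], tr[, 3], tr[, 1])
  tri <- rep(seq_len(m), 3L)
  lo <- pmin(a, b); hi <- pmax(a, b)
  key <- (as.numeric(lo) - 1) * nrow(mesh$vertices) + (as.numeric(hi) - 1)
  asc <- a < b  # TRUE when the triangle traverses the edge as (lo -> hi)
  list(key = key, tri = tri, asc = asc, lo = lo, hi = hi)
}

#' Boundary (open-edge) vertices of a mesh
#'
#' An edge is a boundary edge iff it belongs to exactly one triangle; the
#' returned vertices are exactly those touching at least one boundary edge.
#'
#' @param mesh a [tri_mesh()].
#' @return Sorted integer vector of 1-based boundary vertex ids (empty for a
#'   closed surface).
#' @export
detect_open_edges <- function(mesh) {
  ei <- mesh_edge_index(mesh)
  cnt <- table(ei$key)
  if (any(cnt > 2L))
    stop("non-manifold mesh: an edge is shared by more than two triangles")
  open_keys <- names(cnt)[cnt == 1L]
  sel <- ei$key %in% as.numeric(open_keys)
  sort(unique(c(ei$lo[sel], ei$hi[sel])))
}

#' Orient a mesh consistently, cutting nonorientable surfaces
#'
#' Orientation is propagated by breadth-first traversal over triangle
#' adjacency, flipping windings where needed. If a conflict cycle is found
#' the surface is nonorientable; the conflicting edges (discovered in
#' deterministic sorted order) form a cut seam whose vertices are duplicated,
#' yielding an orientable surface with open edges (a Moebius strip becomes an
#' open band). For closed meshes the global orientation is chosen so the
#' signed volume is non-negative (outward normals).
#'
#' @param mesh a [tri_mesh()]; must be manifold (each edge in at most two
#'   triangles).
#' @return A list with elements `mesh` (the oriented mesh) and `report`
#'   (list with `flipped`, `cut_vertices`, `orientable`).
#' @export
orient_mesh <- function(mesh) {
  validate_tri_mesh(mesh)
  m <- nrow(mesh$triangles)
  if (m == 0L) return(list(mesh = mesh,
                           report = list(flipped = 0L, cut_vertices = 0L,
                                         orientable = TRUE)))
  ei <- mesh_edge_index(mesh)
  by_key <- split(seq_along(ei$key), ei$key)
  if (any(lengths(by_key) > 2L))
    stop("non-manifold mesh: an edge is shared by more than two triangles")
  interior <- by_key[lengths(by_key) == 2L]
  # adjacency list: per triangle, the (other triangle, my asc, other asc, key)
  adj <- vector("list", m)
  for (rows in interior) {
    t1 <- ei$tri[rows[1]]; t2 <- ei$tri[rows[2]]
    adj[[t1]] <- rbind(adj[[t1]], c(t2, ei$asc[rows[1]], ei$asc[rows[2]],
                                    ei$key[rows[1]]))
    adj[[t2]] <- rbind(adj[[t2]], c(t1, ei$asc[rows[2]], ei$asc[rows[1]],
                                    ei$key[rows[2]]))
  }
  flip <- rep(NA, m)
  seam_keys <- numeric(0)
  for (root in seq_len(m)) {
    if (!is.na(flip[root])) next
    flip[root] <- FALSE
    queue <- root
    while (length(queue)) {
      t <- queue[1]; queue <- queue[-1]
      nb <- adj[[t]]
      if (is.null(nb)) next
      nb <- nb[order(nb[, 1]), , drop = FALSE]  # deterministic traversal
      for (r in seq_len(nrow(nb))) {
        o <- nb[r, 1]
        eff_t <- xor(as.logical(nb[r, 2]), flip[t])
        want_o <- !eff_t  # the neighbor must traverse the edge oppositely
        if (is.na(flip[o])) {
          flip[o] <- xor(as.logical(nb[r, 3]), want_o)
          queue <- c(queue, o)
        } else if (xor(as.logical(nb[r, 3]), flip[o]) != want_o) {
          seam_keys <- c(seam_keys, nb[r, 4])
        }
      }
    }
  }
  seam_keys <- sort(unique(seam_keys))
  orientable <- length(seam_keys) == 0L
  tr <- mesh$triangles
  verts <- mesh$vertices
  dom <- mesh$vertex_domain
  cut_added <- 0L
  if (!orientable) {
    nv0 <- nrow(verts)
    seam_lo <- floor(seam_keys / nv0) + 1
    seam_hi <- (seam_keys %% nv0) + 1
    seam_vertices <- sort(unique(c(seam_lo, seam_hi)))
    tr_cut <- tr
    orig_tr <- mesh$triangles
    is_seam <- function(u, v) {
      k <- (pmin(u, v) - 1) * nv0 + (pmax(u, v) - 1)
      k %in% seam_keys
    }
    for (v in seam_vertices) {
      tv <- which(orig_tr[, 1] == v | orig_tr[, 2] == v | orig_tr[, 3] == v)
      # connect two incident triangles if they share a non-seam edge through v
      comp <- seq_along(tv)
      find <- function(i) { while (comp[i] != i) i <- comp[i]; i }
      for (ii in seq_along(tv)) for (jj in seq_along(tv)) {
        if (jj <= ii) next
        sh <- intersect(orig_tr[tv[ii], ], orig_tr[tv[jj], ])
        sh <- setdiff(sh, v)
        if (length(sh) && any(!is_seam(v, sh))) {
          a <- find(ii); b <- find(jj)
          if (a != b) comp[max(a, b)] <- min(a, b)
        }
      }
      roots <- vapply(seq_along(tv), find, integer(1))
      groups <- split(seq_along(tv), roots)
      groups <- groups[order(vapply(groups, function(g) min(tv[g]), integer(1)))]
      if (length(groups) > 1L) {
        for (g in groups[-1]) {
          new_id <- nrow(verts) + 1L
          verts <- rbind(verts, verts[v, , drop = FALSE])
          if (!is.null(dom)) dom <- c(dom, dom[v])
          cut_added <- cut_added + 1L
          for (t in tv[g]) tr_cut[t, orig_tr[t, ] == v] <- new_id
        }
      }
    }
    tr <- tr_cut
  }
  tr[flip, ] <- tr[flip, c(1L, 3L, 2L), drop = FALSE]
  out <- tri_mesh(verts, tr, mesh$box, vertex_domain = dom,
                  inclusions = mesh$inclusions, exclusions = mesh$exclusions)
  flipped <- sum(flip)
  if (length(detect_open_edges(out)) == 0L && signed_volume(out) < 0) {
    out$triangles <- out$triangles[, c(1L, 3L, 2L), drop = FALSE]
    flipped <- m - flipped
  }
  list(mesh = out,
       report = list(flipped = as.integer(flipped),
                     cut_vertices = cut_added, orientable = orientable))
}

#' Signed volume enclosed by a closed oriented mesh
#'
#' Positive for outward (counter-clockwise) winding.
#'
#' @param mesh a [tri_mesh()].
#' @return Signed volume in nm^3.
#' @export
signed_volume <- function(mesh) {
  v <- mesh$vertices
  t <- mesh$triangles
  a <- v[t[, 1], , drop = FALSE]
  b <- v[t[, 2], , drop = FALSE]
  c_ <- v[t[, 3], , drop = FALSE]
  sum(rowSums(a * cross3(b, c_))) / 6
}

# TRUE when every interior edge is traversed once in each direction.
is_consistently_oriented <- function(mesh) {
  ei <- mesh_edge_index(mesh)
  ok <- TRUE
  for (rows in split(seq_along(ei$key), ei$key)) {
    if (length(rows) == 2L && ei$asc[rows[1]] == ei$asc[rows[2]]) ok <- FALSE
    if (length(rows) > 2L) return(FALSE)
  }
  ok
}
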