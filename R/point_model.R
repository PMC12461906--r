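#' Point folders: the discretized membrane
#'
#' A `point_folder` is the central currency of the builder: two per-leaflet
#' tables of surface points (outer and inner), inclusion marks (abstract
#' protein anchors), exclusion marks (pores), the periodic box and, when the
#' folder was derived from a mesh or analytical grid, the point adjacency
#' edges that make geodesic operations possible.
#'
#' Each leaflet table has one row per surface point with columns `id`
#' (0-based on-disk id, an opaque key), `domain`, `area` (nm^2), position
#' `x,y,z`, unit normal `nx,ny,nz`, principal directions `p1x..p1z`,
#' `p2x..p2z`, principal curvatures `c1 >= c2` (nm^-1), logical `edge`
#' (open-edge flag) and logical `excluded` (recomputed from the exclusion
#' marks; excluded points get no lipid). The two leaflets share ids: outer
#' point i and inner point i stem from the same surface element, so the
#' (leaflet, id) pair is the external key.
#'
#' @param outer,inner per-leaflet point data.frames (see Details).
#' @param box numeric length-3 box (nm).
#' @param inclusions data.frame with columns `id`, `type_id`, `point_id`,
#'   `ux`, `uy`, `uz` (unit in-plane orientation).
#' @param exclusions data.frame with columns `id`, `point_id`, `radius`.
#' @param edges optional 2-column matrix of point-id pairs (0-based), the
#'   adjacency inherited from the triangulation or analytical grid.
#' @return An object of class `point_folder`.
#' @export
point_folder <- function(outer, inner, box, inclusions = NULL,
                         exclusions = NULL, edges = NULL) {
  inclusions <- inclusions %||%
    data.frame(id = integer(), type_id = integer(), point_id = integer(),
               ux = numeric(), uy = numeric(), uz = numeric())
  exclusions <- exclusions %||%
    data.frame(id = integer(), point_id = integer(), radius = numeric())
  folder <- structure(
    list(outer = outer, inner = inner, box = as.numeric(box),
         inclusions = inclusions, exclusions = exclusions, edges = edges),
    class = "point_folder")
  validate_point_folder(folder)
  apply_exclusions(folder)
}

validate_point_folder <- function(folder) {
  for (lf in c("outer", "inner")) {
    df <- folder[[lf]]
    if (anyDuplicated(df$id))
      stop("duplicate point ids in ", lf, " leaflet")
  }
  known <- folder$outer$id
  bad <- setdiff(folder$inclusions$point_id, known)
  if (length(bad))
    stop("inclusion references unknown point id(s): ",
         paste(utils::head(bad, 5), collapse = ", "))
  bad <- setdiff(folder$exclusions$point_id, known)
  if (length(bad))
    stop("exclusion references unknown point id(s): ",
         paste(utils::head(bad, 5), collapse = ", "))
  if (length(folder$box) != 3L || any(folder$box <= 0))
    stop("box must be 3 positive lengths")
  invisible(folder)
}

#' @export
print.point_folder <- function(x, ...) {
  cat(sprintf("<point_folder> %d outer + %d inner points, box %.3g x %.3g x %.3g nm\n",
              nrow(x$outer), nrow(x$inner), x$box[1], x$box[2], x$box[3]))
  cat(sprintf("  %d inclusion(s), %d exclusion(s), domains: %s; %d edge point(s)\n",
              nrow(x$inclusions), nrow(x$exclusions),
              paste(sort(unique(c(x$outer$domain, x$inner$domain))), collapse = ","),
              sum(x$outer$edge)))
  invisible(x)
}

point_cols <- c("id", "domain", "area", "x", "y", "z", "nx", "ny", "nz",
                "p1x", "p1y", "p1z", "p2x", "p2y", "p2z", "c1", "c2", "edge")

# Mark points inside pores. Geodesic metric when edges are available,
# straight-line otherwise; flags are recomputed from scratch on every call.
apply_exclusions <- function(folder) {
  for (lf in c("outer", "inner")) {
    df <- folder[[lf]]
    df$excluded <- rep(FALSE, nrow(df))
    folder[[lf]] <- df
  }
  if (!nrow(folder$exclusions)) return(folder)
  for (k in seq_len(nrow(folder$exclusions))) {
    pid <- folder$exclusions$point_id[k]
    r <- folder$exclusions$radius[k]
    for (lf in c("outer", "inner")) {
      df <- folder[[lf]]
      d <- point_distances(folder, lf, pid)
      df$excluded <- df$excluded | (d <= r)
      folder[[lf]] <- df
    }
  }
  folder
}

# Distance from one source point to all points of a leaflet: geodesic along
# the folder's adjacency when present, Euclidean otherwise.
point_distances <- function(folder, leaflet, source_id) {
  df <- folder[[leaflet]]
  pos <- as.matrix(df[, c("x", "y", "z")])
  if (!is.null(folder$edges) && nrow(folder$edges) > 0L) {
    idx <- match(c(folder$edges[, 1], folder$edges[, 2]), df$id)
    ii <- idx[seq_len(nrow(folder$edges))]
    jj <- idx[-seq_len(nrow(folder$edges))]
    w <- vnorm(pos[ii, , drop = FALSE] - pos[jj, , drop = FALSE])
    g <- igraph::make_graph(rbind(ii, jj), n = nrow(df), directed = FALSE)
    drop(igraph::distances(g, v = match(source_id, df$id), weights = w))
  } else {
    vnorm(sweep(pos, 2, pos[match(source_id, df$id), ]))
  }
}

#' Save a point folder to disk
#'
#' Writes `OuterBM.dat` and `InnerBM.dat` (header `< Point NoPoints N >`,
#' `< Box Lx Ly Lz >`, then one row per point), `IncPoint.dat`,
#' `ExcPoint.dat` and, when adjacency is present, `Edges.dat`. All ids are
#' 0-based on disk.
#'
#' @param folder a [point_folder()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
save_point_folder <- function(folder, dir) {
  validate_point_folder(folder)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_leaflet <- function(df, path) {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(c(sprintf("< Point NoPoints %d >", nrow(df)),
                 sprintf("< Box %s >", paste(fmt_num(folder$box), collapse = " "))),
               con)
    num <- df[, setdiff(point_cols, c("id", "domain", "edge"))]
    writeLines(paste(df$id, df$domain,
                     do.call(paste, lapply(num, fmt_num)),
                     as.integer(df$edge)), con)
  }
  write_leaflet(folder$outer, file.path(dir, "OuterBM.dat"))
  write_leaflet(folder$inner, file.path(dir, "InnerBM.dat"))
  inc <- folder$inclusions
  writeLines(c(sprintf("< Inclusion NoInc %d >", nrow(inc)),
               if (nrow(inc)) sprintf("%d %d %d %s %s %s", inc$id, inc$type_id,
                                      inc$point_id, fmt_num(inc$ux),
                                      fmt_num(inc$uy), fmt_num(inc$uz))),
             file.path(dir, "IncPoint.dat"))
  exc <- folder$exclusions
  writeLines(c(sprintf("< Exclusion NoExc %d >", nrow(exc)),
               if (nrow(exc)) sprintf("%d %d %s", exc$id, exc$point_id,
                                      fmt_num(exc$radius))),
             file.path(dir, "ExcPoint.dat"))
  if (!is.null(folder$edges) && nrow(folder$edges)) {
    writeLines(c("[ outer ]",
                 sprintf("%d %d", folder$edges[, 1], folder$edges[, 2]),
                 "[ inner ]",
                 sprintf("%d %d", folder$edges[, 1], folder$edges[, 2])),
               file.path(dir, "Edges.dat"))
  }
  invisible(dir)
}

#' Load a point folder from disk
#'
#' Inverse of [save_point_folder()]; a missing `IncPoint.dat`,
#' `ExcPoint.dat` or `Edges.dat` yields empty inclusions/exclusions or
#' absent adjacency (geodesic operations then refuse to run).
#'
#' @param dir a directory written by [save_point_folder()].
#' @return A [point_folder()].
#' @export
load_point_folder <- function(dir) {
  read_leaflet <- function(path) {
    lines <- readLines(path, warn = FALSE)
    n <- as.integer(sub(".*NoPoints\\s+(\\d+).*", "\\1", lines[1]))
    box <- as.numeric(strsplit(trimws(gsub("[<>]|Box", "", lines[2])), "\\s+")[[1]])
    if (n == 0L) {
      df <- as.data.frame(matrix(numeric(0), 0, length(point_cols)))
      names(df) <- point_cols
      return(list(df = df, box = box))
    }
    m <- matrix(as.numeric(unlist(strsplit(trimws(lines[3:(2 + n)]), "\\s+"))),
                nrow = n, byrow = TRUE)
    df <- as.data.frame(m)
    names(df) <- point_cols
    df$id <- as.integer(df$id)
    df$domain <- as.integer(df$domain)
    df$edge <- as.logical(df$edge)
    list(df = df, box = box)
  }
  outer <- read_leaflet(file.path(dir, "OuterBM.dat"))
  inner <- read_leaflet(file.path(dir, "InnerBM.dat"))
  inc_path <- file.path(dir, "IncPoint.dat")
  inc <- NULL
  if (file.exists(inc_path)) {
    lines <- readLines(inc_path, warn = FALSE)
    n <- as.integer(sub(".*NoInc\\s+(\\d+).*", "\\1", lines[1]))
    if (n > 0L) {
      m <- matrix(as.numeric(unlist(strsplit(trimws(lines[2:(1 + n)]), "\\s+"))),
                  nrow = n, byrow = TRUE)
      inc <- data.frame(id = as.integer(m[, 1]), type_id = as.integer(m[, 2]),
                        point_id = as.integer(m[, 3]), ux = m[, 4],
                        uy = m[, 5], uz = m[, 6])
    }
  }
  exc_path <- file.path(dir, "ExcPoint.dat")
  exc <- NULL
  if (file.exists(exc_path)) {
    lines <- readLines(exc_path, warn = FALSE)
    n <- as.integer(sub(".*NoExc\\s+(\\d+).*", "\\1", lines[1]))
    if (n > 0L) {
      m <- matrix(as.numeric(unlist(strsplit(trimws(lines[2:(1 + n)]), "\\s+"))),
                  nrow = n, byrow = TRUE)
      exc <- data.frame(id = as.integer(m[, 1]), point_id = as.integer(m[, 2]),
                        radius = m[, 3])
    }
  }
  edges <- NULL
  edges_path <- file.path(dir, "Edges.dat")
  if (file.exists(edges_path)) {
    lines <- trimws(readLines(edges_path, warn = FALSE))
    lines <- lines[nzchar(lines) & !grepl("^\\[", lines)]
    if (length(lines)) {
      m <- matrix(as.integer(unlist(strsplit(lines, "\\s+"))),
                  ncol = 2, byrow = TRUE)
      edges <- unique(cbind(pmin(m[, 1], m[, 2]), pmax(m[, 1], m[, 2])))
    }
  }
  point_folder(outer$df, inner$df, outer$box, inclusions = inc,
               exclusions = exc, edges = edges)
}

#' Select points by predicate
#'
#' The predicate receives the leaflet's point table augmented with a mean
#' curvature column `H = (c1 + c2)/2` and must return a logical vector; any
#' geometric or domain criterion can be expressed this way. Selection never
#' mutates the folder.
#'
#' @param folder a [point_folder()].
#' @param predicate `function(df) -> logical`.
#' @param leaflet `"outer"` or `"inner"`.
#' @return Sorted integer vector of selected point ids.
#' @export
select_points <- function(folder, predicate, leaflet = "outer") {
  leaflet <- match.arg(leaflet, c("outer", "inner"))
  df <- folder[[leaflet]]
  df$H <- (df$c1 + df$c2) / 2
  keep <- predicate(df)
  if (!is.logical(keep) || length(keep) != nrow(df))
    stop("predicate must return one logical per point")
  sort(df$id[keep & !is.na(keep)])
}

#' Assign a domain to a set of points
#'
#' Later calls overwrite earlier assignments (last write wins), which is the
#' documented semantics when circular domains overlap.
#'
#' @param folder a [point_folder()].
#' @param ids point ids to modify.
#' @param domain_id non-negative integer domain tag.
#' @param leaflet `"outer"`, `"inner"` or `"both"`.
#' @return The modified folder.
#' @export
set_domain <- function(folder, ids, domain_id, leaflet = "both") {
  stopifnot(domain_id >= 0)
  if (!length(ids)) return(folder)
  for (lf in leaflet_set(leaflet)) {
    df <- folder[[lf]]
    idx <- match(ids, df$id)
    if (anyNA(idx))
      stop("unknown point id(s): ", paste(utils::head(ids[is.na(idx)], 5),
                                          collapse = ", "))
    df$domain[idx] <- as.integer(domain_id)
    folder[[lf]] <- df
  }
  folder
}

leaflet_set <- function(leaflet) {
  leaflet <- match.arg(leaflet, c("both", "outer", "inner"))
  if (leaflet == "both") c("outer", "inner") else leaflet
}
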