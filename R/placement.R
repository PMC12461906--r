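# Lateral organization: curvature-biased lipid sorting (DOP), circular
# domains (DAI, Euclidean and geodesic), curvature-biased protein insertion
# (INU), pores, edge lipids and enrichment analysis.

#' Describe one lipid species for placement
#'
#' @param name lipid identifier (also the residue/molecule name).
#' @param fraction target fraction of the composition, in `[0, 1]`; the
#'   fractions of a spec set must sum to 1.
#' @param apl area per lipid (nm^2).
#' @param c0 intrinsic curvature preference C0 (nm^-1): the preferred value
#'   of twice the mean curvature, 2H.
#' @param k bias sharpness, dimensionless (nm^2 once area-scaled); `k = 0`
#'   means no curvature preference.
#' @param domain integer domain tag this lipid is assigned to; defaults to
#'   the position in the spec set minus one.
#' @return One-row data.frame; `rbind()` several to form a spec set.
#' @export
lipid_spec <- function(name, fraction, apl = 0.64, c0 = 0, k = 0, domain = NA) {
  stopifnot(fraction >= 0, fraction <= 1, apl > 0, k >= 0)
  data.frame(name = name, fraction = fraction, apl = apl, c0 = c0, k = k,
             domain = as.integer(domain))
}

check_specs <- function(specs) {
  if (abs(sum(specs$fraction) - 1) > 1e-9)
    stop("lipid fractions must sum to 1 (got ", sum(specs$fraction), ")")
  if (any(is.na(specs$domain))) specs$domain <- seq_len(nrow(specs)) - 1L
  if (anyDuplicated(specs$domain)) stop("lipid specs must have distinct domains")
  specs
}

# Largest-remainder rounding of fraction*N, ties broken by spec order, so
# the realized composition is exact for every N.
largest_remainder_quota <- function(fractions, N) {
  exact <- fractions * N
  base <- floor(exact)
  left <- N - sum(base)
  if (left > 0) {
    ord <- order(-(exact - base), seq_along(fractions))
    base[ord[seq_len(left)]] <- base[ord[seq_len(left)]] + 1
  }
  as.integer(base)
}

#' Boltzmann weight of a lipid at a surface point
#'
#' The unnormalized placement probability `P(l) = exp(-k (2H - C0)^2)`,
#' where H is the local mean curvature and C0 the lipid's intrinsic
#' curvature preference. With `area_scaled = TRUE`, k is replaced by
#' `k * area`, which makes the exponent proportional to the Helfrich
#' bending energy of the surface element. The weight is 1 exactly when
#' `2H = C0` or `k = 0`.
#'
#' @param H mean curvature (nm^-1), vectorized.
#' @param c0 intrinsic curvature preference (nm^-1).
#' @param k bias sharpness (>= 0).
#' @param area point area (nm^2), used when `area_scaled`.
#' @param area_scaled logical.
#' @return Weights in `(0, 1]`.
#' @export
boltzmann_weight <- function(H, c0, k, area = 1, area_scaled = FALSE) {
  keff <- if (area_scaled) k * area else k
  exp(-keff * (2 * H - c0)^2)
}

#' Curvature-biased lipid assignment (DOP)
#'
#' Assigns each non-excluded point a lipid domain so that the realized
#' composition equals the largest-remainder quotas of the requested
#' fractions exactly, while biasing individual assignments by local mean
#' curvature. Points are visited in seeded random order (preventing
#' systematic bias); at each point the Boltzmann weights of the lipid types
#' that still have quota are normalized (`P(l) / sum P(l')`) and one type is
#' drawn. When all remaining weights underflow to zero the draw falls back
#' to uniform over the remaining types.
#'
#' @param folder a [point_folder()].
#' @param specs a spec set built from [lipid_spec()] rows; fractions must
#'   sum to 1.
#' @param leaflet `"both"` (default), `"outer"` or `"inner"`; each leaflet
#'   gets its own exact quotas.
#' @param area_scaled passed to [boltzmann_weight()].
#' @param seed integer seed for reproducible assignment.
#' @return The folder with point domains set to the specs' domain tags.
#' @export
dop_assign <- function(folder, specs, leaflet = "both", area_scaled = FALSE,
                       seed = NULL) {
  specs <- check_specs(specs)
  with_seed(seed, {
    for (lf in leaflet_set(leaflet)) {
      df <- folder[[lf]]
      idx <- which(!df$excluded)
      N <- length(idx)
      if (N == 0L) next
      quota <- largest_remainder_quota(specs$fraction, N)
      H <- (df$c1[idx] + df$c2[idx]) / 2
      keff <- if (area_scaled) outer(df$area[idx], specs$k) else
        matrix(specs$k, N, nrow(specs), byrow = TRUE)
      # log weights; the per-point normalization is shift-invariant, so
      # subtracting the row maximum keeps exact ratios at any k
      LW <- -keff * sweep(outer(2 * H, rep(1, nrow(specs))), 2, specs$c0)^2
      choice <- integer(N)
      for (i in sample.int(N)) {
        open <- which(quota > 0L)
        stopifnot(length(open) > 0L)  # guaranteed by quota arithmetic
        if (length(open) == 1L) {
          l <- open
        } else {
          w <- exp(LW[i, open] - max(LW[i, open]))
          l <- open[sample.int(length(open), 1L, prob = w / sum(w))]
        }
        choice[i] <- l
        quota[l] <- quota[l] - 1L
      }
      stopifnot(all(quota == 0L))
      df$domain[idx] <- specs$domain[choice]
      folder[[lf]] <- df
    }
    folder
  })
}

resolve_centers <- function(folder, centers) {
  mid <- mid_positions(folder)
  if (is.matrix(centers) || is.data.frame(centers)) {
    as.matrix(centers)
  } else {
    idx <- match(centers, folder$outer$id)
    if (anyNA(idx)) stop("unknown center point id(s)")
    mid[idx, , drop = FALSE]
  }
}

mid_positions <- function(folder) {
  (as.matrix(folder$outer[, c("x", "y", "z")]) +
     as.matrix(folder$inner[, c("x", "y", "z")])) / 2
}

#' Circular domains by straight-line distance (DAI, Euclidean)
#'
#' Every point whose minimum Euclidean distance to any center is at most
#' `radius` gets `domain_id`; other points are untouched. Fast, but on
#' strongly folded membranes the straight-line metric can bleed a domain
#' onto nearby but geodesically distant membrane regions; use
#' [dai_geodesic()] to avoid that artifact.
#'
#' @param folder a [point_folder()].
#' @param centers point ids, or a matrix/data.frame of xyz coordinates.
#' @param radius domain radius (nm), positive.
#' @param domain_id domain tag to assign.
#' @param leaflet `"both"`, `"outer"` or `"inner"`.
#' @return The modified folder.
#' @export
dai_euclidean <- function(folder, centers, radius, domain_id, leaflet = "both") {
  stopifnot(radius > 0)
  if (!length(centers)) {
    warning("no centers given; nothing assigned")
    return(folder)
  }
  for (lf in leaflet_set(leaflet)) {
    df <- folder[[lf]]
    pos <- as.matrix(df[, c("x", "y", "z")])
    C <- if (is.matrix(centers) || is.data.frame(centers)) {
      as.matrix(centers)
    } else {
      idx <- match(centers, df$id)
      if (anyNA(idx)) stop("unknown center point id(s)")
      pos[idx, , drop = FALSE]  # the leaflet's own position of the center
    }
    mind <- rep(Inf, nrow(pos))
    for (k in seq_len(nrow(C)))
      mind <- pmin(mind, vnorm(sweep(pos, 2, C[k, ])))
    df$domain[mind <= radius] <- as.integer(domain_id)
    folder[[lf]] <- df
  }
  folder
}

#' Circular domains by geodesic distance (DAI, Dijkstra)
#'
#' Builds a graph over the folder's points with mesh edges weighted by their
#' Euclidean length and runs multi-source Dijkstra from the centers; points
#' within geodesic distance `radius` get `domain_id`. Because paths run
#' along the membrane surface, domains stay contiguous and never leak onto
#' other membranes of a multi-membrane system.
#'
#' @inheritParams dai_euclidean
#' @param centers point ids (geodesic sources must be points).
#' @return The modified folder.
#' @export
dai_geodesic <- function(folder, centers, radius, domain_id, leaflet = "both") {
  stopifnot(radius > 0)
  if (is.null(folder$edges) || nrow(folder$edges) == 0L)
    stop("folder has no mesh adjacency (Edges.dat); regenerate it with ",
         "discretize() or an analytical grid to use geodesic domains")
  if (!length(centers)) {
    warning("no centers given; nothing assigned")
    return(folder)
  }
  for (lf in leaflet_set(leaflet)) {
    df <- folder[[lf]]
    pos <- as.matrix(df[, c("x", "y", "z")])
    ii <- match(folder$edges[, 1], df$id)
    jj <- match(folder$edges[, 2], df$id)
    w <- vnorm(pos[ii, , drop = FALSE] - pos[jj, , drop = FALSE])
    g <- igraph::make_graph(rbind(ii, jj), n = nrow(df), directed = FALSE)
    src <- match(centers, df$id)
    if (anyNA(src)) stop("unknown center point id(s)")
    d <- igraph::distances(g, v = src, weights = w)
    mind <- apply(d, 2, min)
    df$domain[mind <= radius] <- as.integer(domain_id)
    folder[[lf]] <- df
  }
  folder
}

#' Curvature-biased collision-free protein placement (INU)
#'
#' Candidate points are weighted by [boltzmann_weight()] with the protein's
#' preferred curvature `c0` and sharpness `k`; placements are drawn without
#' replacement, rejecting any draw within `collision_radius` (Euclidean, on
#' the mid-surface) of an already placed or pre-existing inclusion, until
#' `n_copies` are placed or the candidates are exhausted (then an error
#' reports how many were placed). Each accepted inclusion receives a seeded
#' random in-plane orientation.
#'
#' @param folder a [point_folder()].
#' @param type_id integer protein type tag recorded with each inclusion.
#' @param n_copies number of copies to place (>= 1).
#' @param c0,k curvature preference and sharpness, as in [boltzmann_weight()].
#' @param collision_radius minimum center-to-center distance (nm, >= 0).
#' @param seed integer seed.
#' @return The folder with `n_copies` inclusions appended.
#' @export
inu_place <- function(folder, type_id, n_copies, c0 = 0, k = 0,
                      collision_radius = 0, seed = NULL) {
  stopifnot(n_copies >= 1, collision_radius >= 0)
  df <- folder$outer
  mid <- mid_positions(folder)
  cand <- which(!df$excluded)
  H <- (df$c1[cand] + df$c2[cand]) / 2
  lw <- -k * (2 * H - c0)^2  # softmax across points, shifted before each draw
  existing <- folder$inclusions$point_id
  exist_pos <- if (length(existing)) mid[match(existing, df$id), , drop = FALSE]
               else matrix(numeric(0), 0, 3)
  placed <- integer(0)
  with_seed(seed, {
    while (length(placed) < n_copies) {
      if (!length(cand))
        stop("could not place ", n_copies, " copies collision-free; placed ",
             length(placed))
      w <- exp(lw - max(lw))
      pick <- sample.int(length(cand), 1L, prob = w / sum(w))
      p <- mid[cand[pick], ]
      others <- rbind(exist_pos,
                      mid[placed, , drop = FALSE])
      clash <- nrow(others) > 0 &&
        min(vnorm(sweep(others, 2, p))) < collision_radius
      if (!clash) {
        placed <- c(placed, cand[pick])
        # prune candidates that can no longer be accepted
        keep <- vnorm(sweep(mid[cand, , drop = FALSE], 2, p)) >= collision_radius
        keep[pick] <- FALSE  # drawn without replacement even at radius 0
        lw <- lw[keep]; cand <- cand[keep]
      } else {
        lw <- lw[-pick]; cand <- cand[-pick]
      }
    }
    next_id <- if (nrow(folder$inclusions)) max(folder$inclusions$id) + 1L else 0L
    rows <- lapply(seq_along(placed), function(j) {
      i <- placed[j]
      phi <- stats::runif(1, 0, 2 * pi)
      u <- cos(phi) * as.numeric(df[i, c("p1x", "p1y", "p1z")]) +
           sin(phi) * as.numeric(df[i, c("p2x", "p2y", "p2z")])
      data.frame(id = next_id + j - 1L, type_id = as.integer(type_id),
                 point_id = df$id[i], ux = u[1], uy = u[2], uz = u[3])
    })
    folder$inclusions <- rbind(folder$inclusions, do.call(rbind, rows))
    folder
  })
}

#' Punch a pore into the membrane
#'
#' Records an exclusion mark at the point nearest `center` and flags all
#' points within `radius` of it (geodesic when mesh adjacency is available,
#' Euclidean otherwise) as excluded, so the builder places no lipid there.
#'
#' @param folder a [point_folder()].
#' @param center a point id or an xyz coordinate.
#' @param radius pore radius (nm), positive.
#' @return The modified folder.
#' @export
make_pore <- function(folder, center, radius) {
  stopifnot(radius > 0)
  mid <- mid_positions(folder)
  if (length(center) == 3L) {
    d <- vnorm(sweep(mid, 2, as.numeric(center)))
    i <- which.min(d)
    if (d[i] > radius) {
      warning("pore center is off-membrane (nearest point at ",
              signif(d[i], 3), " nm > radius); empty pore")
      return(folder)
    }
  } else {
    i <- match(center[1], folder$outer$id)
    if (is.na(i)) stop("unknown center point id")
  }
  next_id <- if (nrow(folder$exclusions)) max(folder$exclusions$id) + 1L else 0L
  folder$exclusions <- rbind(folder$exclusions,
                             data.frame(id = next_id,
                                        point_id = folder$outer$id[i],
                                        radius = radius))
  apply_exclusions(folder)
}

#' Assign a dedicated domain to open-edge points
#'
#' Exactly the edge-flagged points (mesh boundary and cut-seam vertices) are
#' set to `domain_id`, so edge-stabilizing lipids (e.g. short-tailed
#' species) can be mapped onto the membrane rim. On a closed surface this
#' is a warning no-op.
#'
#' @param folder a [point_folder()].
#' @param domain_id domain tag for the edge points.
#' @return The modified folder.
#' @export
edge_domain <- function(folder, domain_id) {
  ids <- folder$outer$id[folder$outer$edge]
  if (!length(ids)) {
    warning("closed surface: no edge-flagged points; nothing to assign")
    return(folder)
  }
  set_domain(folder, ids, domain_id, leaflet = "both")
}

#' Relative lipid distribution across curvature bins
#'
#' Bins the mean curvature H of a leaflet's (non-excluded) points into
#' equal-width bins over the observed range and tabulates, per bin, the
#' relative occurrence of each assigned domain (rows normalized per bin).
#' Empty bins are dropped. This reproduces the "relative distribution as a
#' function of membrane curvature" view used to validate curvature-biased
#' placement.
#'
#' @param folder a [point_folder()] with domains assigned.
#' @param leaflet `"outer"` or `"inner"`.
#' @param bins number of equal-width curvature bins (default 20).
#' @return A data.frame with columns `H_mid`, `domain`, `count`, `fraction`.
#' @export
curvature_enrichment <- function(folder, leaflet = "outer", bins = 20) {
  leaflet <- match.arg(leaflet, c("outer", "inner"))
  df <- folder[[leaflet]]
  df <- df[!df$excluded, ]
  H <- (df$c1 + df$c2) / 2
  rng <- range(H)
  if (diff(rng) < 1e-12) {
    tab <- table(df$domain)
    return(data.frame(H_mid = rng[1], domain = as.integer(names(tab)),
                      count = as.integer(tab),
                      fraction = as.numeric(tab) / sum(tab)))
  }
  breaks <- seq(rng[1], rng[2], length.out = bins + 1)
  bin <- cut(H, breaks, include.lowest = TRUE, labels = FALSE)
  out <- list()
  for (b in sort(unique(bin))) {
    sel <- bin == b
    tab <- table(df$domain[sel])
    out[[length(out) + 1L]] <- data.frame(
      H_mid = (breaks[b] + breaks[b + 1]) / 2,
      domain = as.integer(names(tab)),
      count = as.integer(tab),
      fraction = as.numeric(tab) / sum(tab))
  }
  do.call(rbind, out)
}
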