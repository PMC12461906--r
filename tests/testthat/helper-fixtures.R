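# Shared fixture builders. Everything is generated in code; no binary data.

# internal helpers exercised by tests
is_consistently_oriented <- membuildr:::is_consistently_oriented
largest_remainder_quota <- membuildr:::largest_remainder_quota
within_cutoff_periodic <- membuildr:::within_cutoff_periodic
mid_positions <- membuildr:::mid_positions
normalize_rows_test <- membuildr:::normalize_rows
vnorm_test <- membuildr:::vnorm

tetra_mesh <- function() {
  v <- rbind(c(1, 1, 1), c(1, 3, 3), c(3, 1, 3), c(3, 3, 1))
  f <- rbind(c(1, 3, 2), c(1, 2, 4), c(1, 4, 3), c(2, 3, 4))
  tri_mesh(v, f, box = c(4, 4, 4))
}

# two parallel flat sheets `gap` nm apart in one mesh (multi-membrane case)
stacked_sheets_mesh <- function(gap = 3, lx = 16, n = 17) {
  m1 <- make_mesh("flat_grid", lx = lx, ly = lx, nx = n, ny = n)
  v2 <- m1$vertices
  v2[, 3] <- v2[, 3] + gap
  tri_mesh(rbind(m1$vertices, v2),
           rbind(m1$triangles, m1$triangles + nrow(m1$vertices)),
           m1$box + c(0, 0, gap))
}

toy_lib <- function() parse_lib(toy_lib_path())

popc_chol_specs <- function() {
  rbind(lipid_spec("POPC", 0.9, apl = 0.64),
        lipid_spec("CHOL", 0.1, apl = 0.77))
}

# id of the point closest to an xyz coordinate, on the outer leaflet
nearest_point_id <- function(folder, xyz) {
  d2 <- (folder$outer$x - xyz[1])^2 + (folder$outer$y - xyz[2])^2 +
    (folder$outer$z - xyz[3])^2
  folder$outer$id[which.min(d2)]
}

mean_curvature <- function(df) (df$c1 + df$c2) / 2

# minimum distance between beads belonging to different residues
min_intermolecular_distance <- function(model) {
  pos <- as.matrix(model$beads[, c("x", "y", "z")])
  res <- model$beads$resid
  best <- Inf
  # cell-assisted: examine pairs within 1 nm only
  for (i in seq_len(nrow(pos))) {
    d2 <- rowSums(sweep(pos, 2, pos[i, ])^2)
    cand <- which(d2 < 1 & res != res[i])
    if (length(cand)) best <- min(best, sqrt(min(d2[cand])))
  }
  best
}
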