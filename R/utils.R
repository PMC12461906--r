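# Internal numerics shared across modules. All lengths in nm.

# Row-wise cross product of 3-column matrices (or plain 3-vectors).
cross3 <- function(a, b) {
  if (is.null(dim(a))) a <- matrix(a, ncol = 3)
  if (is.null(dim(b))) b <- matrix(b, ncol = 3)
  cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
        a[, 3] * b[, 1] - a[, 1] * b[, 3],
        a[, 1] * b[, 2] - a[, 2] * b[, 1])
}

vnorm <- function(x) {
  if (is.null(dim(x))) return(sqrt(sum(x^2)))
  sqrt(rowSums(x^2))
}

normalize_rows <- function(x) {
  if (is.null(dim(x))) return(x / sqrt(sum(x^2)))
  x / pmax(vnorm(x), .Machine$double.xmin)
}

# Evaluate `code` under a temporary RNG state seeded with `seed`.
# seed = NULL uses (and advances) the ambient RNG.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  env <- globalenv()
  if (exists(".Random.seed", envir = env, inherits = FALSE)) {
    old <- get(".Random.seed", envir = env)
    on.exit(assign(".Random.seed", old, envir = env), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = env)), add = TRUE)
  }
  set.seed(seed)
  force(code)
}

# Minimum-image displacement under an orthorhombic periodic box.
min_image <- function(d, box) {
  d - sweep(round(sweep(d, 2, box, "/")), 2, box, "*")
}

# For each query point, is any reference point within `cutoff` under the
# periodic metric? Cell-list search with cells >= cutoff.
within_cutoff_periodic <- function(query, ref, cutoff, box) {
  if (nrow(ref) == 0L || nrow(query) == 0L) return(rep(FALSE, nrow(query)))
  ncell <- pmax(1L, floor(box / cutoff))
  clen <- box / ncell
  cell_of <- function(p) {
    idx <- floor(sweep(p, 2, clen, "/"))
    idx <- sweep(idx, 2, ncell, "%%")  # wrap points outside the box
    idx
  }
  key_of <- function(idx) {
    1 + idx[, 1] + ncell[1] * (idx[, 2] + ncell[2] * idx[, 3])
  }
  rkey <- key_of(cell_of(ref))
  rsplit <- split(seq_len(nrow(ref)), rkey)
  qidx <- cell_of(query)
  hits <- rep(FALSE, nrow(query))
  shifts <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  cut2 <- cutoff^2
  for (q in seq_len(nrow(query))) {
    for (s in seq_len(nrow(shifts))) {
      nb <- (qidx[q, ] + shifts[s, ]) %% ncell
      ids <- rsplit[[as.character(1 + nb[1] + ncell[1] * (nb[2] + ncell[2] * nb[3]))]]
      if (is.null(ids)) next
      d <- min_image(sweep(ref[ids, , drop = FALSE], 2, query[q, ]), box)
      if (any(rowSums(d^2) <= cut2)) {
        hits[q] <- TRUE
        break
      }
    }
  }
  hits
}

`%||%` <- function(a, b) if (is.null(a)) b else a

fmt_num <- function(x) sprintf("%.6f", x)
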