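# Lipid template library (LIB dialect) and libmaker.
#
# LIB grammar (normative for this package): a "[ NAME ]" header line opens
# an entry; each following "bead <name> <x> <y> <z>" line adds one bead in
# the lipid's local frame (nm; head bead first and at maximal z, tails
# extending toward -z); a blank line or the next header terminates the
# entry.

#' Parse a lipid template library
#'
#' @param path path to a LIB file.
#' @return A named list of entries, each a list with `name` and a `beads`
#'   data.frame (`name`, `x`, `y`, `z`). Duplicate entry names keep the
#'   last occurrence with a warning; an empty file yields an empty library
#'   with a warning.
#' @export
parse_lib <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path, warn = FALSE)
  lib <- list()
  current <- NULL
  beads <- NULL
  flush <- function() {
    if (is.null(current)) return()
    if (!is.null(lib[[current]]))
      warning("duplicate LIB entry '", current, "': last definition wins")
    lib[[current]] <<- list(name = current, beads = do.call(rbind, beads))
  }
  for (j in seq_along(lines)) {
    ln <- trimws(lines[j])
    if (!nzchar(ln) || startsWith(ln, ";")) next
    hdr <- regmatches(ln, regexec("^\\[\\s*(\\S+)\\s*\\]$", ln))[[1]]
    if (length(hdr) == 2L) {
      flush()
      current <- hdr[2]
      beads <- list()
      next
    }
    tok <- strsplit(ln, "\\s+")[[1]]
    if (is.null(current))
      stop("LIB parse error at line ", j, ": bead line before any [ NAME ] header")
    if (tok[1] != "bead" || length(tok) != 5L)
      stop("LIB parse error at line ", j,
           ": expected 'bead <name> <x> <y> <z>' (4 fields)")
    beads[[length(beads) + 1L]] <-
      data.frame(name = tok[2], x = as.numeric(tok[3]),
                 y = as.numeric(tok[4]), z = as.numeric(tok[5]))
  }
  flush()
  if (!length(lib)) warning("empty lipid library: ", path)
  lib
}

#' Write a lipid template library
#'
#' @param lib a library as returned by [parse_lib()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_lib <- function(lib, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (entry in lib) {
    writeLines(sprintf("[ %s ]", entry$name), con)
    writeLines(sprintf("bead %s %s %s %s", entry$beads$name,
                       fmt_num(entry$beads$x), fmt_num(entry$beads$y),
                       fmt_num(entry$beads$z)), con)
    writeLines("", con)
  }
  invisible(path)
}

#' Build a library entry from a single-lipid structure (libmaker)
#'
#' Reads a GRO file containing exactly one residue, translates the beads to
#' their centroid, and aligns the principal axis of the bead cloud with +z,
#' choosing the sign so the first bead (the head, by coarse-grained file
#' convention) ends up at z >= 0.
#'
#' @param gro_path path to a single-residue GRO file.
#' @param name entry name; defaults to the residue name.
#' @return A library entry (list with `name`, `beads`).
#' @export
libmaker <- function(gro_path, name = NULL) {
  model <- read_gro(gro_path)
  b <- model$beads
  if (length(unique(b$resid)) != 1L)
    stop("libmaker needs a single-residue structure; found ",
         length(unique(b$resid)), " residues")
  X <- as.matrix(b[, c("x", "y", "z")])
  X <- sweep(X, 2, colMeans(X))
  if (nrow(X) > 1L && sum(X^2) > 1e-18) {
    ee <- eigen(crossprod(X), symmetric = TRUE)  # full 3x3 basis
    V <- ee$vectors
    if (det(V) < 0) V[, 3] <- -V[, 3]
    R <- V[, c(2, 3, 1)]          # principal axis -> +z
    if (det(R) < 0) R[, 2] <- -R[, 2]
    X <- X %*% R
    if (X[1, 3] < 0) X[, 2:3] <- -X[, 2:3]  # pi-rotation about x: head up
  }
  list(name = name %||% b$resname[1],
       beads = data.frame(name = b$atom, x = X[, 1], y = X[, 2], z = X[, 3]))
}

#' Path to the bundled toy Martini-3-style mini library
#'
#' Four toy templates (POPC-, CDL-, CHOL- and DLPC-like bead geometries,
#' not force-field parameters) used by the examples, fixtures and CLI
#' defaults.
#'
#' @return File path.
#' @export
toy_lib_path <- function() {
  system.file("extdata", "toy_martini3.LIB", package = "membuildr",
              mustWork = TRUE)
}
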