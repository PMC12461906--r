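# Fast solvent propagation: tile a small equilibrated water box through the
# system box, delete waters near solute, substitute ions.

#' Solvate a model by tiling a water template
#'
#' The template box is tiled `ceiling(L/l)` times per axis and clipped to
#' the model box; solvent beads within `cutoff` of any existing bead
#' (cell-list neighbor search under the periodic metric) are deleted.
#' Requested ions replace seeded-random solvent beads one-for-one. The
#' template is treated as single-bead solvent residues (Martini-style W).
#' Molecule counts are extended with the solvent first, then the ions in
#' the order given.
#'
#' @param model a [membrane_model()] (may be empty apart from its box).
#' @param template a [membrane_model()] or GRO path: the equilibrated small
#'   water box.
#' @param cutoff solute-solvent exclusion distance (nm), positive.
#' @param ions named integer vector, e.g. `c(NA. = 5, CL = 5)`, of ion
#'   names and counts; each ion replaces one solvent bead.
#' @param seed integer seed for ion substitution.
#' @return The solvated [membrane_model()].
#' @export
solvate_box <- function(model, template, cutoff = 0.4, ions = NULL,
                        seed = NULL) {
  stopifnot(cutoff > 0)
  if (is.character(template)) template <- read_gro(template)
  box <- model$box
  tb <- template$box
  reps <- pmax(1L, ceiling(box / tb))
  tpos <- as.matrix(template$beads[, c("x", "y", "z")])
  offs <- as.matrix(expand.grid(x = (seq_len(reps[1]) - 1L) * tb[1],
                                y = (seq_len(reps[2]) - 1L) * tb[2],
                                z = (seq_len(reps[3]) - 1L) * tb[3]))
  pos <- do.call(rbind, lapply(seq_len(nrow(offs)), function(k)
    sweep(tpos, 2, offs[k, ], "+")))
  names_rep <- rep(template$beads$atom, nrow(offs))
  res_rep <- rep(template$beads$resname, nrow(offs))
  keep_box <- pos[, 1] < box[1] & pos[, 2] < box[2] & pos[, 3] < box[3]
  pos <- pos[keep_box, , drop = FALSE]
  names_rep <- names_rep[keep_box]
  res_rep <- res_rep[keep_box]
  solute <- as.matrix(model$beads[, c("x", "y", "z")])
  clash <- within_cutoff_periodic(pos, solute, cutoff, box)
  pos <- pos[!clash, , drop = FALSE]
  names_rep <- names_rep[!clash]
  res_rep <- res_rep[!clash]
  n_w <- nrow(pos)
  ion_names <- names(ions %||% integer(0))
  ion_counts <- as.integer(ions %||% integer(0))
  if (sum(ion_counts) > n_w)
    stop("more ions (", sum(ion_counts), ") than surviving solvent beads (",
         n_w, ")")
  with_seed(seed, {
    is_ion <- integer(0)
    if (sum(ion_counts) > 0) is_ion <- sample.int(n_w, sum(ion_counts))
    wat_idx <- setdiff(seq_len(n_w), is_ion)
    start <- max(model$beads$resid, 0L)
    sol_beads <- data.frame(resid = start + seq_along(wat_idx),
                            resname = res_rep[wat_idx],
                            atom = names_rep[wat_idx],
                            x = pos[wat_idx, 1], y = pos[wat_idx, 2],
                            z = pos[wat_idx, 3],
                            mol = res_rep[wat_idx])
    ion_beads <- NULL
    if (length(is_ion)) {
      lab <- rep(ion_names, ion_counts)
      ion_beads <- data.frame(resid = start + length(wat_idx) + seq_along(is_ion),
                              resname = lab, atom = lab,
                              x = pos[is_ion, 1], y = pos[is_ion, 2],
                              z = pos[is_ion, 3], mol = lab)
      ion_beads <- ion_beads[order(match(ion_beads$mol, ion_names)), ,
                             drop = FALSE]
      ion_beads$resid <- start + length(wat_idx) + seq_along(is_ion)
    }
    model$beads <- rbind(model$beads, sol_beads, ion_beads)
    model
  })
}
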