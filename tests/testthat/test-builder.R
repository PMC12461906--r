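test_that("analytical flat folder realizes the requested area per lipid", {
  f <- analytical_folder("flat", lx = 16, ly = 16, apl_hint = 0.64)
  expect_equal(nrow(f$outer), 400L)  # 16/sqrt(0.64) = 20 per side
  expect_equal(unique(f$outer$area), 0.64)
  expect_equal(unique(mean_curvature(f$outer)), 0)
  # incommensurate box: spacing rounded, realized APL reported
  expect_message(g <- analytical_folder("flat", lx = 10, ly = 10,
                                        apl_hint = 0.64), "realized")
  expect_equal(sum(g$outer$area), 100)
})

test_that("analytical vesicle and cylinder carry exact frames", {
  R <- 8
  v <- analytical_folder("vesicle", r = R, apl_hint = 0.64, thickness = 4)
  N <- round(4 * pi * R^2 / 0.64)
  expect_equal(nrow(v$outer), N)
  expect_equal(sum(v$outer$area), 4 * pi * (R + 2)^2, tolerance = 1e-9)
  expect_equal(unique(v$outer$c1), 1 / (R + 2), tolerance = 1e-12)
  cy <- analytical_folder("cylinder", r = 5, l = 20, thickness = 4)
  expect_equal(unique(cy$outer$c1), 1 / 7, tolerance = 1e-12)
  expect_equal(unique(cy$outer$c2), 0)
  # seen from the flipped inner normal the tube is concave: (0, -1/(r - t/2))
  expect_equal(unique(cy$inner$c1), 0)
  expect_equal(unique(cy$inner$c2), -1 / 3, tolerance = 1e-12)
})

test_that("sine folder with zero amplitude degenerates to flat", {
  s <- analytical_folder("sine", lx = 16, ly = 16, amplitude = 0, periods = 3,
                         lz = 9.8)
  f <- analytical_folder("flat", lx = 16, ly = 16)
  expect_equal(s$outer[, c("x", "y", "z", "c1", "c2", "area")],
               f$outer[, c("x", "y", "z", "c1", "c2", "area")])
})

test_that("place_lipids instantiates one lipid per point with oriented frames", {
  lib <- toy_lib()
  one <- analytical_folder("flat", lx = 0.8, ly = 0.8)
  expect_equal(nrow(one$outer), 1L)
  m1 <- place_lipids(one, lib, c("0" = "POPC"), seed = 1)
  expect_equal(nrow(m1$beads), 2L * 10L)
  expect_equal(m1$beads$resid[1:10], rep(1L, 10))
  f <- analytical_folder("flat", lx = 8, ly = 8)
  m <- place_lipids(f, lib, c("0" = "POPC"), seed = 1)
  outer_res <- m$anchors$resid[m$anchors$leaflet == "outer"]
  b <- m$beads[m$beads$resid %in% outer_res, ]
  heads <- b$z[b$atom == "NC3"]
  tails <- b$z[b$atom %in% c("C3A", "C3B")]
  expect_gt(min(heads), max(tails))  # outer heads above outer tails
  inner_res <- m$anchors$resid[m$anchors$leaflet == "inner"]
  bi <- m$beads[m$beads$resid %in% inner_res, ]
  expect_lt(max(bi$z[bi$atom == "NC3"]), min(bi$z[bi$atom %in% c("C3A", "C3B")]))
  expect_error(place_lipids(set_domain(f, f$outer$id[1], 9), lib,
                            c("0" = "POPC")), "unmapped domain")
})

test_that("pores remove lipids; composition bookkeeping stays exact", {
  lib <- toy_lib()
  f <- analytical_folder("flat", lx = 8, ly = 8)
  midz <- mean(c(f$outer$z[1], f$inner$z[1]))
  f <- make_pore(f, c(4, 4, midz), radius = 1.5)
  excl <- sum(f$outer$excluded) + sum(f$inner$excluded)
  expect_gt(excl, 0)
  m <- place_lipids(f, lib, c("0" = "POPC"), seed = 1)
  expect_equal(nrow(m$beads), (200L - excl) * 10L)
  # no lipid anchored inside the pore (surface metric = L1 on the grid)
  ctr <- unlist(f$outer[match(f$exclusions$point_id, f$outer$id),
                        c("x", "y")])
  d <- abs(m$anchors$ax - ctr[1]) + abs(m$anchors$ay - ctr[2])
  expect_true(all(d > 1.5))
})

test_that("protein height semantics: center at midplane + z_offset", {
  toys <- make_toy_structures(withr::local_tempdir(), seed = 1)
  lib <- toy_lib()
  f <- analytical_folder("flat", lx = 16, ly = 16, lz = 24)
  f <- dop_assign(f, lipid_spec("POPC", 1.0), seed = 2)
  f <- inu_place(f, type_id = 1, n_copies = 1, seed = 3)
  model <- place_lipids(f, lib, c("0" = "POPC"), seed = 4)
  midz <- mean(c(f$outer$z[1], f$inner$z[1]))
  for (zoff in c(0, 5)) {
    spec <- protein_spec("PROT", toys$protein, z_offset = zoff,
                         collision_radius = 1.2, type_id = 1)
    m2 <- place_proteins(model, f, list(spec), seed = 5)
    pz <- mean(m2$beads$z[m2$beads$mol == "PROT"])
    expect_equal(pz, midz + zoff, tolerance = 1e-3)
    # cleared zone: no lipid anchor within the projected collision radius
    i <- match(f$inclusions$point_id[1], f$outer$id)
    d <- sqrt((m2$anchors$ax - f$outer$x[i])^2 +
                (m2$anchors$ay - f$outer$y[i])^2)
    expect_true(all(d >= 1.2))
  }
})

test_that("wall beads scaffold the mid-surface at the requested stride", {
  f <- analytical_folder("flat", lx = 8, ly = 8)
  N <- nrow(f$outer)
  wb1 <- wall_beads(f, stride = 1)
  expect_equal(nrow(wb1$beads), N)
  wb4 <- wall_beads(f, stride = 4)
  expect_equal(nrow(wb4$beads), ceiling(N / 4))
  idx <- as.integer(unlist(strsplit(wb4$ndx[-1], " ")))
  expect_length(idx, nrow(wb4$beads))
  expect_warning(wall_beads(f, stride = N + 1), "single wall bead")
  model <- place_lipids(f, toy_lib(), c("0" = "POPC"), seed = 1)
  aw <- add_wall_beads(model, f, stride = 4)
  expect_equal(nrow(aw$model$beads), nrow(model$beads) + ceiling(N / 4))
  idx2 <- as.integer(unlist(strsplit(aw$ndx[-1], " ")))
  expect_equal(idx2, nrow(model$beads) + seq_len(ceiling(N / 4)))
})

test_that("GRO writer: fixed widths, rounding, wrap, round trip", {
  m <- membrane_model(data.frame(resid = 1L, resname = "POPC", atom = "NC3",
                                 x = 1.2345, y = 0, z = 0, mol = "POPC"),
                      box = c(5, 5, 5))
  path <- withr::local_tempfile(fileext = ".gro")
  write_gro(m, path)
  line <- readLines(path)[3]
  expect_equal(substr(line, 21, 28), "   1.234")  # round-half-even
  expect_equal(substr(line, 1, 10), "    1POPC ")
  # residue/atom numbers wrap modulo 100000
  big <- membrane_model(data.frame(resid = c(100000L, 100001L),
                                   resname = "W", atom = "W",
                                   x = 0, y = 0, z = 0, mol = "W"),
                        box = c(5, 5, 5))
  write_gro(big, path)
  expect_equal(as.integer(substr(readLines(path)[3:4], 1, 5)), c(0L, 1L))
  f <- analytical_folder("flat", lx = 8, ly = 8)
  model <- place_lipids(f, toy_lib(), c("0" = "POPC"), seed = 1)
  write_gro(model, path)
  back <- read_gro(path)
  expect_equal(nrow(back$beads), nrow(model$beads))
  expect_lt(max(abs(back$beads$x - model$beads$x)), 1e-3 + 1e-9)
  expect_lt(max(abs(back$beads$z - model$beads$z)), 1e-3 + 1e-9)
  expect_equal(back$box, model$box)
  expect_warning(write_gro(membrane_model(
    data.frame(resid = 1L, resname = "TOOLONGNAME", atom = "A",
               x = 0, y = 0, z = 0, mol = "X"), c(5, 5, 5)), path),
    "truncated")
})

test_that("topology counts follow first-appearance order exactly", {
  f <- analytical_folder("flat", lx = 16, ly = 16)
  f <- dop_assign(f, popc_chol_specs(), seed = 1)
  model <- place_lipids(f, toy_lib(), c("0" = "POPC", "1" = "CHOL"), seed = 1)
  path <- withr::local_tempfile(fileext = ".top")
  write_top(model, path, includes = "martini.itp")
  lines <- readLines(path)
  mol_i <- which(lines == "[ molecules ]")
  mols <- lines[(mol_i + 1):length(lines)]
  expect_match(mols[1], "^POPC\\s+720$")
  expect_match(mols[2], "^CHOL\\s+80$")
  # a protein between lipid blocks shows up between them
  mixed <- model
  prot_beads <- data.frame(resid = 0L, resname = "PROT", atom = "BB",
                           x = 1, y = 1, z = 1, mol = "PROT")
  b <- mixed$beads
  cut <- max(which(b$mol == "POPC"))
  mixed$beads <- rbind(b[1:cut, ], prot_beads, b[(cut + 1):nrow(b), ])
  mc <- molecule_counts(mixed)
  expect_equal(mc$name, c("POPC", "PROT", "CHOL"))
  expect_equal(mc$count, c(720L, 1L, 80L))
  expect_error(write_top(membrane_model(model$beads[0, ], model$box), path),
               "empty")
})

test_that("built membranes are overlap-free and bit-reproducible", {
  lib <- toy_lib()
  f <- analytical_folder("flat", lx = 8, ly = 8)
  f <- dop_assign(f, popc_chol_specs(), seed = 7)
  m1 <- place_lipids(f, lib, c("0" = "POPC", "1" = "CHOL"), seed = 7)
  m2 <- place_lipids(f, lib, c("0" = "POPC", "1" = "CHOL"), seed = 7)
  expect_identical(m1$beads, m2$beads)
  expect_gte(min_intermolecular_distance(m1), 0.1)
  # total bead count = sum over molecules of count * beads per molecule
  mc <- molecule_counts(m1)
  per <- vapply(mc$name, function(nm) nrow(lib[[nm]]$beads), integer(1))
  expect_equal(nrow(m1$beads), sum(mc$count * per))
})
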