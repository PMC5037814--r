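test_that("PDB files are parsed into a structure model", {
  p <- write_pdb_fixture(c(
    pdb_atom_line(serial = 1, name = "N", x = 0, y = 0, z = 0),
    pdb_atom_line(serial = 2, name = "CA", x = 1.5, y = 0, z = 0),
    pdb_atom_line(serial = 3, name = "C", x = 2.4, y = 1.1, z = 0)))
  m <- read_structure(p)
  expect_s3_class(m, "structure_model")
  expect_equal(nrow(m$atoms), 3)
  expect_equal(unique(m$atoms$chain), "A")
  expect_equal(unique(m$atoms$resno), 1)

  empty <- tempfile(fileext = ".pdb"); writeLines("END", empty)
  expect_error(read_structure(empty), "no ATOM")

  bad <- write_pdb_fixture(sub("  1.500", "  x.500",
    pdb_atom_line(serial = 1, name = "CA", x = 1.5)))
  expect_error(read_structure(bad), "line")
})

test_that("altloc resolution keeps the highest-occupancy conformer", {
  p <- write_pdb_fixture(c(
    pdb_atom_line(serial = 1, name = "CA", alt = "A", x = 1, o = 0.4),
    pdb_atom_line(serial = 2, name = "CA", alt = "B", x = 2, o = 0.6)))
  m <- read_structure(p)
  expect_equal(nrow(m$atoms), 1)
  expect_equal(m$atoms$x, 2)

  # occupancy tie -> altloc 'A'
  p2 <- write_pdb_fixture(c(
    pdb_atom_line(serial = 1, name = "CA", alt = "B", x = 2, o = 0.5),
    pdb_atom_line(serial = 2, name = "CA", alt = "A", x = 1, o = 0.5)))
  m2 <- read_structure(p2)
  expect_equal(m2$atoms$x, 1)
})

test_that("CRYST1 and REMARK 290 operators are captured", {
  lines <- c(
    "REMARK 290   SMTRY1   1  1.000000  0.000000  0.000000        0.00000",
    "REMARK 290   SMTRY2   1  0.000000  1.000000  0.000000        0.00000",
    "REMARK 290   SMTRY3   1  0.000000  0.000000  1.000000        0.00000",
    "REMARK 290   SMTRY1   2 -1.000000  0.000000  0.000000       10.00000",
    "REMARK 290   SMTRY2   2  0.000000 -1.000000  0.000000        0.00000",
    "REMARK 290   SMTRY3   2  0.000000  0.000000  1.000000        5.00000",
    "CRYST1   60.342   92.994  101.849  71.12  84.57  73.49 P 1           1",
    pdb_atom_line(serial = 1, name = "CA", x = 1, y = 2, z = 3))
  m <- read_structure(write_pdb_fixture(lines))
  expect_length(m$symmetry, 2)
  expect_equal(m$symmetry[[1]][, 1:3], diag(3))
  expect_equal(m$symmetry[[2]][, 4], c(10, 0, 5))
  expect_equal(m$cell$lengths, c(60.342, 92.994, 101.849))
  expect_equal(m$cell$spacegroup, "P 1")
})

test_that("C-alpha selection honours ranges, exclusions and gaps", {
  xyz <- matrix(runif(60), ncol = 3)
  m <- read_structure(ca_trace_fixture(xyz, resno = 1:20))
  sel <- select_calpha(m, "A", range = c(7, 18))
  expect_equal(nrow(sel), 12)
  expect_equal(attr(sel, "resno"), 7:18)

  sel_ex <- select_calpha(m, "A", range = c(7, 18),
                          excluded = list(c(10, 12)))
  expect_equal(attr(sel_ex, "resno"), c(7:9, 13:18))

  # residue 10 missing from the file: skipped and reported
  m2 <- read_structure(ca_trace_fixture(xyz[-10, ], resno = (1:20)[-10]))
  sel2 <- select_calpha(m2, "A", range = c(1, 20))
  expect_equal(nrow(sel2), 19)
  expect_equal(attr(sel2, "missing"), 10)

  expect_error(select_calpha(m, "Z"), "chain")
  expect_error(select_calpha(m, "A", range = c(100, 200)), "empty")
})

test_that("Kabsch superposition recovers exact rigid motions", {
  set.seed(5)
  A <- matrix(runif(45, 0, 50), ncol = 3)
  sp <- kabsch_superpose(A, A)
  expect_equal(sp$rmsd, 0, tolerance = 1e-10)
  expect_equal(sp$rotation, diag(3), tolerance = 1e-9)

  for (i in 1:20) {
    R <- random_rotation()
    tv <- runif(3, -30, 30)
    B <- A %*% t(R) + matrix(tv, nrow(A), 3, byrow = TRUE)
    sp <- kabsch_superpose(A, B)
    expect_lt(sp$rmsd, 1e-9)
    # recovered motion is the inverse of the applied one
    expect_equal(sp$rotation, t(R), tolerance = 1e-6)
    # orthonormal, proper
    expect_equal(crossprod(sp$rotation), diag(3), tolerance = 1e-9)
    expect_equal(det(sp$rotation), 1, tolerance = 1e-9)
  }

  expect_error(kabsch_superpose(A, A[-1, ]), "size")
  expect_error(kabsch_superpose(A[1:2, ], A[1:2, ]), "at least 3")
  line <- cbind(1:5, 2 * (1:5), 3 * (1:5))
  expect_error(kabsch_superpose(line, line), "collinear")
})

test_that("Kabsch agrees with the quaternion oracle and rmsd is symmetric and motion-invariant", {
  set.seed(9)
  for (i in 1:25) {
    n <- sample(4:40, 1)
    A <- matrix(runif(3 * n, 0, 50), ncol = 3)
    B <- A %*% t(random_rotation()) + matrix(rnorm(3 * n, 0, 2), ncol = 3)
    r1 <- kabsch_superpose(A, B)$rmsd
    expect_equal(r1, horn_rmsd(A, B), tolerance = 1e-6)
    expect_equal(r1, kabsch_superpose(B, A)$rmsd, tolerance = 1e-9)
    # joint rigid motion leaves rmsd unchanged
    R <- random_rotation(); tv <- runif(3, -10, 10)
    move <- function(X) X %*% t(R) + matrix(tv, n, 3, byrow = TRUE)
    expect_equal(kabsch_superpose(move(A), move(B))$rmsd, r1,
                 tolerance = 1e-9)
  }
})

test_that("rmsd matrices are symmetric with zero diagonal over common residues", {
  set.seed(13)
  xyz <- matrix(runif(90, 0, 30), ncol = 3)
  mA <- read_structure(ca_trace_fixture(xyz, chain = "A", resno = 1:30))
  R <- random_rotation()
  moved <- xyz %*% t(R) + matrix(c(5, 5, 5), 30, 3, byrow = TRUE) +
    matrix(rnorm(90, 0, 0.5), ncol = 3)
  mB <- read_structure(ca_trace_fixture(moved, chain = "A", resno = 1:30))
  entries <- list(list(model = mA, chain = "A", label = "one"),
                  list(model = mB, chain = "A", label = "two"),
                  list(model = mA, chain = "A", label = "one-again"))
  mat <- rmsd_matrix(entries)
  expect_equal(diag(mat), c(one = 0, two = 0, `one-again` = 0))
  expect_equal(mat, t(mat))
  expect_equal(mat["one", "one-again"], 0, tolerance = 1e-10)
  expect_gt(mat["one", "two"], 0)
})

test_that("normalized B-factor profiles average to one and ignore uniform rescaling", {
  m <- read_structure(backbone_fixture(list(A = rep(50, 6))))
  prof <- normalized_bfactor_profile(m)
  expect_equal(prof$rel_b, rep(1, 6))

  # two chains, one hot loop at residues 3-4 of each
  bs <- c(20, 20, 80, 80, 20, 20)
  m2 <- read_structure(backbone_fixture(list(A = bs, B = bs)))
  prof2 <- normalized_bfactor_profile(m2)
  expect_equal(mean(prof2$rel_b), 1, tolerance = 1e-9)
  expect_equal(attr(prof2, "averaged_over"), c("A", "B"))
  # hand arithmetic: mean B = 40; hot residues 80/40 = 2, cold 20/40 = 0.5
  expect_equal(prof2$rel_b, c(0.5, 0.5, 2, 2, 0.5, 0.5))

  m3 <- read_structure(backbone_fixture(list(A = 3 * bs, B = 3 * bs)))
  expect_equal(normalized_bfactor_profile(m3)$rel_b, prof2$rel_b,
               tolerance = 1e-12)

  expect_error(normalized_bfactor_profile(m, atom_names = "ZZ"),
               "no backbone")
})

test_that("symmetry expansion applies operators exactly and is involutive for 2-folds", {
  xyz <- matrix(runif(30, 0, 20), ncol = 3)
  m <- read_structure(ca_trace_fixture(xyz, resno = 1:10))

  ident <- cbind(diag(3), 0)
  asm_id <- expand_symmetry(m, operators = list(ident))
  expect_equal(asm_id$atoms[, c("x", "y", "z")],
               m$atoms[, c("x", "y", "z")])
  expect_equal(unique(asm_id$atoms$chain), "A")

  # 180-degree rotation about the z axis through (5, 5, .)
  twofold <- cbind(diag(c(-1, -1, 1)), c(10, 10, 0))
  asm <- expand_symmetry(m, operators = list(ident, twofold))
  expect_equal(sort(unique(asm$atoms$chain)), c("A", "A'"))
  prime <- asm$atoms[asm$atoms$chain == "A'", c("x", "y", "z")]
  # applying the operator twice restores the original coordinates
  back <- as.matrix(prime) %*% t(twofold[, 1:3])
  back <- sweep(back, 2, twofold[, 4], "+")
  orig <- as.matrix(m$atoms[, c("x", "y", "z")])  # file-precision coords
  expect_equal(unname(back), unname(orig), tolerance = 1e-6)

  expect_error(expand_symmetry(m), "no symmetry operators")
})

test_that("ion counting is element-specific and optionally occupancy-weighted", {
  lines <- c(
    vapply(1:5, function(i)
      pdb_atom_line(type = "HETATM", serial = i, name = "CA",
                    resid = "CA", chain = "A", resno = 400 + i,
                    x = i, y = i, z = i, o = 0.5, elesy = "CA"),
      character(1)),
    pdb_atom_line(type = "HETATM", serial = 6, name = "CL",
                  resid = "CL", chain = "A", resno = 410,
                  x = 9, y = 9, z = 9, elesy = "CL"),
    pdb_atom_line(serial = 7, name = "CA", resid = "GLY", chain = "B",
                  resno = 1, x = 0, y = 0, z = 0))
  m <- read_structure(write_pdb_fixture(lines))
  expect_equal(count_ions(m, "CA"), 5)
  expect_equal(count_ions(m, "ca"), 5)
  expect_equal(count_ions(m, "CL"), 1)
  expect_equal(count_ions(m, "CA", chains = "B"), 0)
  expect_equal(count_ions(m, "CA", occupancy_weighted = TRUE), 2.5)

  # ions double with a two-operator expansion
  asm <- expand_symmetry(m, operators = list(cbind(diag(3), 0),
                                             cbind(diag(c(-1, -1, 1)),
                                                   c(10, 10, 0))))
  expect_equal(count_ions(asm, "CA"), 10)
})

test_that("assemblies can be written back out as parseable PDB", {
  xyz <- matrix(runif(30, 0, 20), ncol = 3)
  m <- read_structure(ca_trace_fixture(xyz, resno = 1:10))
  asm <- expand_symmetry(m, operators = list(cbind(diag(3), 0),
                                             cbind(diag(c(-1, -1, 1)),
                                                   c(4, 4, 0))))
  out <- tempfile(fileext = ".pdb")
  write_structure(asm, out)
  back <- read_structure(out)
  expect_equal(nrow(back$atoms), 20)
  expect_length(unique(back$atoms$chain), 2)
  expect_equal(sort(back$atoms$x), sort(asm$atoms$x), tolerance = 1e-3)
})
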