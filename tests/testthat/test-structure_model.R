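# parsing, the coordinate model, and the symmetry-aware radius query

minimal_pdb <- function(path, extra_lines = character()) {
  writeLines(c(
    "EXPDTA    X-RAY DIFFRACTION",
    "REMARK   2 RESOLUTION.    1.70 ANGSTROMS.",
    "CRYST1   20.000   20.000   20.000  90.00  90.00  90.00 P 1           1",
    extra_lines,
    "ATOM      1  P     G A   5       1.000   2.000   3.000  1.00 20.00           P",
    "ATOM      2  OP1   G A   5       2.400   2.000   3.000  1.00 21.00           O",
    "ATOM      3  O2*   G A   5       3.000   4.000   5.000  1.00 22.00           O",
    "HETATM    4 MG    MG A 101       0.000   0.000   0.000  1.00 15.00          MG",
    "HETATM    5  O   HOH A 201       2.080   0.000   0.000  1.00 18.00           O",
    "END"), path)
  path
}

minimal_cif <- function(path) {
  writeLines(c(
    "data_test",
    "_cell.length_a 20.000", "_cell.length_b 20.000", "_cell.length_c 20.000",
    "_cell.angle_alpha 90.00", "_cell.angle_beta 90.00",
    "_cell.angle_gamma 90.00",
    "_symmetry.space_group_name_H-M 'P 1'",
    "_refine.ls_d_res_high 1.70",
    "loop_", "_atom_site.group_PDB", "_atom_site.id",
    "_atom_site.type_symbol", "_atom_site.label_atom_id",
    "_atom_site.label_alt_id", "_atom_site.label_comp_id",
    "_atom_site.label_asym_id", "_atom_site.label_entity_id",
    "_atom_site.label_seq_id", "_atom_site.pdbx_PDB_ins_code",
    "_atom_site.Cartn_x", "_atom_site.Cartn_y", "_atom_site.Cartn_z",
    "_atom_site.occupancy", "_atom_site.B_iso_or_equiv",
    "_atom_site.pdbx_formal_charge", "_atom_site.auth_seq_id",
    "_atom_site.auth_comp_id", "_atom_site.auth_asym_id",
    "_atom_site.auth_atom_id", "_atom_site.pdbx_PDB_model_num",
    "ATOM 1 P P . G A 1 5 ? 1.000 2.000 3.000 1.00 20.00 ? 5 G A P 1",
    "ATOM 2 O OP1 . G A 1 5 ? 2.400 2.000 3.000 1.00 21.00 ? 5 G A OP1 1",
    paste("ATOM 3 O \"O2'\" . G A 1 5 ? 3.000 4.000 5.000 1.00 22.00 ?",
          "5 G A \"O2'\" 1"),
    "HETATM 4 MG MG . MG A 2 . ? 0.000 0.000 0.000 1.00 15.00 ? 101 MG A MG 1",
    "HETATM 5 O O . HOH A 3 . ? 2.080 0.000 0.000 1.00 18.00 ? 201 HOH A O 1"
  ), path)
  path
}

test_that("PDB parsing captures atoms, cell, resolution, flags and names", {
  f <- minimal_pdb(tempfile(fileext = ".pdb"))
  m <- read_structure(f)
  expect_s3_class(m, "mg_structure")
  expect_equal(nrow(m$atoms), 5)
  expect_false(is.null(m$cell))
  expect_equal(m$cell$spacegroup, "P 1")
  expect_equal(m$resolution, 1.7)
  # asterisk ribose naming unified to primes
  expect_true("O2'" %in% m$atoms$elety)
  expect_false(any(grepl("\\*", m$atoms$elety)))
  expect_equal(sum(m$atoms$is_metal), 1)
  expect_equal(sum(m$atoms$is_water), 1)
})

test_that("mmCIF parsing yields the same atom list and cell as PDB", {
  fp <- minimal_pdb(tempfile(fileext = ".pdb"))
  fc <- minimal_cif(tempfile(fileext = ".cif"))
  mp <- read_structure(fp)
  mc <- read_structure(fc)
  cols <- c("elety", "resid", "chain", "resno", "x", "y", "z", "o", "b",
            "elesy")
  expect_equal(mc$atoms[, cols], mp$atoms[, cols], ignore_attr = TRUE)
  expect_equal(mc$cell$a, mp$cell$a)
  expect_equal(mc$resolution, mp$resolution)
})

test_that("missing CRYST1 gives an absent cell; search degrades with warning", {
  f <- tempfile(fileext = ".pdb")
  writeLines(c(
    "HETATM    1 MG    MG A   1       0.000   0.000   0.000  1.00 10.00          MG",
    "HETATM    2  O   HOH A   2       2.000   0.000   0.000  1.00 10.00           O",
    "END"), f)
  m <- read_structure(f)
  expect_null(m$cell)
  expect_warning(ct <- neighbor_search(m, 1, 3, use_symmetry = TRUE),
                 "asymmetric unit")
  expect_equal(nrow(ct), 1)
  expect_equal(ct$distance, 2)
})

test_that("alternate locations keep the highest-occupancy conformer", {
  f <- tempfile(fileext = ".pdb")
  writeLines(c(
    "ATOM      1  OP1A  G A   5     1.000   0.000   0.000  0.40 20.00           O",
    "ATOM      2  OP1B  G A   5     2.000   0.000   0.000  0.60 20.00           O",
    "END"), f)
  m <- read_structure(f)
  expect_equal(nrow(m$atoms), 1)
  expect_equal(m$atoms$x, 2)
})

test_that("write/read round trip preserves counts, names, B and occupancy", {
  d <- tempfile(); dir.create(d)
  make_site_fixture("gphos", file.path(d, "a.pdb"))
  m1 <- read_structure(file.path(d, "a.pdb"))
  write_structure(m1, file.path(d, "b.pdb"))
  m2 <- read_structure(file.path(d, "b.pdb"))
  expect_equal(nrow(m2$atoms), nrow(m1$atoms))
  expect_equal(m2$atoms$elety, m1$atoms$elety)
  expect_equal(m2$atoms$b, m1$atoms$b)
  expect_equal(m2$atoms$o, m1$atoms$o)
  expect_equal(m2$atoms$x, m1$atoms$x, tolerance = 1e-3)
  expect_equal(m2$cell$spacegroup, m1$cell$spacegroup)
})

test_that("neighbor search: direct geometry and periodic images", {
  at <- data.frame(elety = c("O", "O"), resid = "HOH", chain = "W",
                   resno = 1:2, x = c(0, 2), y = 0, z = 0)
  m <- mg_structure(at, cell = NULL)
  expect_warning(ct <- neighbor_search(m, 1, 3), "asymmetric unit")
  expect_equal(nrow(ct), 1)
  expect_equal(ct$distance, 2)

  cl <- unit_cell(10, 10, 10, 90, 90, 90, "P 1")
  at2 <- data.frame(elety = c("O", "O"), resid = "HOH", chain = "W",
                    resno = 1:2, x = c(0.1, 9.9), y = 0, z = 0)
  m2 <- mg_structure(at2, cell = cl)
  ct2 <- neighbor_search(m2, 1, 2)
  expect_equal(nrow(ct2), 1)
  expect_equal(ct2$distance, 0.2, tolerance = 1e-9)
  # the image of atom 2 seen from atom 1 sits one cell down in a
  expect_equal(ct2$s1, -1L)
})

test_that("cell-aware search equals the brute-force expanded-copy oracle", {
  set.seed(11)
  for (k in 1:25) {
    sg <- if (k %% 2 == 0) "P 1" else "P 21 21 21"
    m <- random_sym_model(sg, n = 35)
    ci <- sample(nrow(m$atoms), 1)
    r <- stats::runif(1, 2.5, 4)
    got <- neighbor_search(m, ci, r)
    want <- brute_neighbors(m, c(m$atoms$x[ci], m$atoms$y[ci], m$atoms$z[ci]), r)
    expect_same_contacts(got, want)
  }
})

test_that("neighbor search is invariant under whole-model translation", {
  set.seed(12)
  m <- random_sym_model("P 21 21 21", n = 30)
  got1 <- neighbor_search(m, 1, 4)
  t <- c(3.1, -2.2, 5.7)
  m2 <- m
  m2$atoms$x <- m$atoms$x + t[1]
  m2$atoms$y <- m$atoms$y + t[2]
  m2$atoms$z <- m$atoms$z + t[3]
  got2 <- neighbor_search(m2, 1, 4, use_symmetry = FALSE)
  got1b <- neighbor_search(m, 1, 4, use_symmetry = FALSE)
  expect_equal(got2$atom, got1b$atom)
  expect_equal(got2$distance, got1b$distance, tolerance = 1e-9)
})

test_that("dataset selection applies the three full-dataset criteria", {
  d <- tempfile(); dir.create(d)
  # accepted: linked scaffold of 4 + Mg
  make_site_fixture("hexaaqua_bout", file.path(d, "ok.pdb"))
  # no Mg: scaffold only
  sc <- mg_structure(mgrna:::fx_scaffold(), id = "nomg",
                     meta = list(expdta = "X-RAY DIFFRACTION", title = ""))
  write_structure(sc, file.path(d, "nomg.pdb"))
  # only 2 linked nucleotides + Mg
  two <- mgrna:::fx_scaffold(resnames = c("G", "A"))
  two <- rbind(two, data.frame(elety = "MG", resid = "MG", chain = "M",
                               resno = 1L, x = 0, y = 0, z = 0, o = 1, b = 10,
                               elesy = "MG"))
  write_structure(mg_structure(two, id = "two"), file.path(d, "two.pdb"))
  sel <- select_structures(file.path(d, c("ok.pdb", "nomg.pdb", "two.pdb")))
  expect_equal(sel$accepted, c(TRUE, FALSE, FALSE))
  expect_match(sel$reasons[2], "no_mg")
  expect_match(sel$reasons[3], "fewer_than_3")
  expect_true(all(sel$subset == "non-ribosome"))
})

test_that("ribosome tagging matches title keywords and explicit id lists", {
  d <- tempfile(); dir.create(d)
  f <- file.path(d, "rib.pdb")
  make_site_fixture("hexaaqua_bout", f)
  lines <- readLines(f)
  writeLines(c("TITLE     30S RIBOSOMAL SUBUNIT", lines), f)
  sel <- select_structures(f)
  expect_equal(sel$subset, "ribosome")
  f2 <- file.path(d, "plain.pdb")
  make_site_fixture("hexaaqua_bout", f2)
  sel2 <- select_structures(f2, ribosome_ids = "plain")
  expect_equal(sel2$subset, "ribosome")
})
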