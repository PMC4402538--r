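# water-mediated hydrogen bonds and outer-sphere moiety assignment

# one Mg, six waters, plus acceptor atoms placed radially off chosen waters
hb_model <- function(acceptors) {
  dirs <- rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0),
                c(0, -1, 0), c(0, 0, 1), c(0, 0, -1))
  at <- data.frame(elety = "MG", resid = "MG", chain = "M", resno = 900L,
                   x = 0, y = 0, z = 0, o = 1, b = 20, elesy = "MG")
  for (v in 1:6) {
    p <- 2.08 * dirs[v, ]
    at <- rbind(at, data.frame(elety = "O", resid = "HOH", chain = "W",
                               resno = 500L + v, x = p[1], y = p[2], z = p[3],
                               o = 1, b = 20, elesy = "O"))
  }
  for (a in acceptors) at <- rbind(at, a$df)
  mg_structure(at, id = "hb")
}

acc <- function(elety, resid, resno, pos, chain = "B", elesy = NULL) {
  if (is.null(elesy)) elesy <- toupper(substr(gsub("[^A-Za-z]", "", elety), 1, 1))
  list(df = data.frame(elety = elety, resid = resid, chain = chain,
                       resno = resno, x = pos[1], y = pos[2], z = pos[3],
                       o = 1, b = 20, elesy = elesy))
}

test_that("hydrogen bonds require the distance window and the angle rule", {
  # OP1 2.8 A from the +x water on the far side: angle 180 -> bond
  m <- hb_model(list(acc("OP1", "G", 7, c(2.08 + 2.8, 0, 0))))
  inner <- find_inner_sphere(m, 1)
  hb <- find_water_rna_hbonds(m, inner)
  expect_equal(nrow(hb), 1)
  expect_equal(hb$elety, "OP1")
  expect_equal(hb$distance, 2.8, tolerance = 1e-9)

  # same distance but on the magnesium-facing side: angle 60 -> no bond
  p <- c(2.08, 0, 0) + 2.8 * c(cos(120 * pi / 180), sin(120 * pi / 180), 0)
  m2 <- hb_model(list(acc("OP1", "G", 7, p)))
  hb2 <- find_water_rna_hbonds(m2, find_inner_sphere(m2, 1))
  expect_equal(nrow(hb2), 0)

  # outside the window: 3.8 A -> no bond; 2.3 A -> too close, no bond
  m3 <- hb_model(list(acc("OP1", "G", 7, c(2.08 + 3.8, 0, 0))))
  expect_equal(nrow(find_water_rna_hbonds(m3, find_inner_sphere(m3, 1))), 0)
  m4 <- hb_model(list(acc("N7", "G", 7, c(0, 2.08 + 2.35, 0))))
  expect_equal(nrow(find_water_rna_hbonds(m4, find_inner_sphere(m4, 1))), 0)

  # only O/N of standard nucleotides qualify
  m5 <- hb_model(list(acc("OD1", "ASP", 7, c(2.08 + 2.8, 0, 0), chain = "P")))
  expect_equal(nrow(find_water_rna_hbonds(m5, find_inner_sphere(m5, 1))), 0)
})

test_that("an inner-sphere atom is never an outer-sphere partner of the same site", {
  # G-O6 as inner ligand at +x; a water at +y within 3.4 A of that O6
  at <- data.frame(elety = "MG", resid = "MG", chain = "M", resno = 900L,
                   x = 0, y = 0, z = 0, o = 1, b = 20, elesy = "MG")
  at <- rbind(at, data.frame(elety = "O6", resid = "G", chain = "B",
                             resno = 7L, x = 2.08, y = 0, z = 0, o = 1, b = 20,
                             elesy = "O"))
  at <- rbind(at, data.frame(elety = "O", resid = "HOH", chain = "W",
                             resno = 501L, x = 0, y = 2.08, z = 0, o = 1,
                             b = 20, elesy = "O"))
  m <- mg_structure(at, id = "excl")
  inner <- find_inner_sphere(m, 1)
  expect_equal(inner$cn, 2)
  hb <- find_water_rna_hbonds(m, inner)
  # O6 is 2.94 A from the water and at 45 degrees... angle Mg-Ow-O6 = 45,
  # below 90 anyway; move the check to the explicit exclusion instead:
  expect_false(any(hb$elety == "O6" & hb$resno == 7))
})

test_that("moieties are counted once per residue part and kept separate across residues", {
  # two waters each bonded to O6 and N7 of the same guanine -> one B_out
  g1 <- acc("O6", "G", 8, c(2.08 + 2.8, 0, 0))
  g2 <- acc("N7", "G", 8, c(0, 2.08 + 2.8, 0))
  m <- hb_model(list(g1, g2))
  inner <- find_inner_sphere(m, 1)
  mo <- assign_moieties(find_water_rna_hbonds(m, inner), inner, m)
  expect_equal(nrow(mo), 1)
  expect_equal(mo$kind, "B_out")
  expect_equal(mo$n_bonds, 2)
  expect_setequal(strsplit(mo$atoms, ",")[[1]], c("N7", "O6"))

  # one water bonded to OP1 of residue 7 and O6 of residue 8 -> two moieties
  p <- c(2.08, 0, 0)
  b1 <- acc("OP1", "G", 7, p + 2.8 * unitv2(c(1, 0.35, 0)))
  b2 <- acc("O6", "G", 8, p + 2.8 * unitv2(c(1, -0.35, 0)))
  m2 <- hb_model(list(b1, b2))
  inner2 <- find_inner_sphere(m2, 1)
  mo2 <- assign_moieties(find_water_rna_hbonds(m2, inner2), inner2, m2)
  expect_equal(nrow(mo2), 2)
  expect_setequal(mo2$kind, c("P_out", "B_out"))
})

test_that("bridging O5'/O3' fold into a contributing phosphate", {
  # O5'(9) H-bonded while OP1(9) is also outer-sphere: folded into P_out(9)
  d <- tempfile(); dir.create(d)
  make_site_fixture("o5_fold", file.path(d, "f.pdb"))
  s <- analyze_structure(file.path(d, "f.pdb"))[[1]]
  expect_equal(nrow(s$moieties), 1)
  expect_equal(s$moieties$kind, "P_out")
  expect_setequal(strsplit(s$moieties$atoms, ",")[[1]], c("O5'", "OP1"))

  # O3' of residue 8 is covalently bonded to P of residue 9 (the
  # 3'-neighbor): when that phosphate also receives a bond, the O3'
  # belongs to P_out(9), not R_out(8)
  w <- c(2.08, 0, 0)
  o3 <- w + 2.7 * unitv2(c(cos(25 * pi / 180), sin(25 * pi / 180), 0))
  op1 <- w + 2.7 * unitv2(c(cos(25 * pi / 180), -sin(25 * pi / 180), 0))
  P <- w + c(2.7 * cos(25 * pi / 180) + 1.05, 0, 0)
  m3 <- hb_model(list(acc("O3'", "G", 8, o3), acc("OP1", "G", 9, op1),
                      acc("P", "G", 9, P)))
  inner3 <- find_inner_sphere(m3, 1)
  mo3 <- assign_moieties(find_water_rna_hbonds(m3, inner3), inner3, m3)
  expect_equal(nrow(mo3), 1)
  expect_equal(mo3$kind, "P_out")
  expect_equal(mo3$resno, 9)

  # without the contributing phosphate the same O3' stays ribose
  m4 <- hb_model(list(acc("O3'", "G", 8, c(2.08 + 2.8, 0, 0))))
  inner4 <- find_inner_sphere(m4, 1)
  mo4 <- assign_moieties(find_water_rna_hbonds(m4, inner4), inner4, m4)
  expect_equal(mo4$kind, "R_out")
  expect_equal(mo4$resno, 8)
})

test_that("a moiety never contains an inner-sphere part of the same site", {
  # G-O6 inner ligand; a water H-bonds N7 of the same guanine: the base
  # already coordinates inner-sphere, so no B_out for that residue
  at <- data.frame(elety = "MG", resid = "MG", chain = "M", resno = 900L,
                   x = 0, y = 0, z = 0, o = 1, b = 20, elesy = "MG")
  at <- rbind(at,
              data.frame(elety = "O6", resid = "G", chain = "B", resno = 7L,
                         x = 2.08, y = 0, z = 0, o = 1, b = 20, elesy = "O"),
              data.frame(elety = "O", resid = "HOH", chain = "W", resno = 501L,
                         x = 0, y = 2.08, z = 0, o = 1, b = 20, elesy = "O"),
              data.frame(elety = "N7", resid = "G", chain = "B", resno = 7L,
                         x = 0, y = 2.08 + 2.8, z = 0, o = 1, b = 20,
                         elesy = "N"))
  m <- mg_structure(at, id = "drop")
  inner <- find_inner_sphere(m, 1)
  hb <- find_water_rna_hbonds(m, inner)
  expect_equal(nrow(hb), 1)  # the N7 bond itself is geometric and valid
  mo <- assign_moieties(hb, inner, m)
  expect_equal(nrow(mo), 0)  # but the base part already binds inner-sphere
})

test_that("the moiety multiset is independent of water enumeration order", {
  d <- tempfile(); dir.create(d)
  make_site_fixture("gg_full", file.path(d, "g.pdb"))
  m <- read_structure(file.path(d, "g.pdb"))
  inner <- find_inner_sphere(m, 1)
  mo1 <- assign_moieties(find_water_rna_hbonds(m, inner), inner, m)
  at <- m$atoms
  wat <- which(at$is_water)
  perm <- seq_len(nrow(at))
  perm[wat] <- rev(wat)
  m2 <- mg_structure(at[perm, ], cell = m$cell, id = "perm")
  mg2 <- which(m2$atoms$elesy == "MG")[1]
  inner2 <- find_inner_sphere(m2, mg2)
  mo2 <- assign_moieties(find_water_rna_hbonds(m2, inner2), inner2, m2)
  expect_equal(sort(paste(mo1$kind, mo1$chain, mo1$resno)),
               sort(paste(mo2$kind, mo2$chain, mo2$resno)))
})
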