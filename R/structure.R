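# structure parsing, the coordinate model, and symmetry-aware radius queries

WATER_RESIDUES <- c("HOH", "WAT", "H2O", "DOD")
METAL_ELEMENTS <- c("LI", "NA", "K", "RB", "CS", "MG", "CA", "SR", "BA",
                    "MN", "FE", "CO", "NI", "CU", "ZN", "CD", "HG", "AL",
                    "PB", "PT", "AU", "AG", "TL", "V", "CR", "MO", "W",
                    "OS", "IR", "RU", "RH", "PD", "SM", "EU", "GD", "TB",
                    "YB", "LU")
RNA_RESIDUES <- c("A", "G", "C", "U")

#' Build a structure model from an atom table
#'
#' Low-level constructor used by [read_structure()] and by the synthetic
#' fixture generator. The atom table must have columns `elety` (atom name),
#' `resid`, `chain`, `resno`, `x`, `y`, `z`; optional columns `insert`,
#' `alt`, `o` (occupancy), `b`, `elesy` (element) are filled with defaults.
#' Hydrogens are dropped; atom names are normalized (asterisk ribose
#' naming to primes, O1P/O2P to OP1/OP2); waters and metals are flagged.
#'
#' @param atoms data.frame of atoms (see Details).
#' @param cell optional [unit_cell()] object.
#' @param resolution resolution in Angstrom, or `NA`.
#' @param id identifier string.
#' @param meta optional list of free-form metadata (title, expdta, ...).
#' @return an object of class `mg_structure`: a list with elements
#'   `atoms`, `cell`, `resolution`, `id`, `meta`.
#' @export
mg_structure <- function(atoms, cell = NULL, resolution = NA_real_,
                         id = "structure", meta = list()) {
  need <- c("elety", "resid", "chain", "resno", "x", "y", "z")
  miss <- setdiff(need, names(atoms))
  if (length(miss)) stop("atom table lacks column(s): ", paste(miss, collapse = ", "))
  n <- nrow(atoms)
  if (is.null(atoms$insert)) atoms$insert <- ""
  if (is.null(atoms$alt)) atoms$alt <- ""
  if (is.null(atoms$o)) atoms$o <- 1
  if (is.null(atoms$b)) atoms$b <- 0
  atoms$insert[is.na(atoms$insert)] <- ""
  atoms$alt[is.na(atoms$alt)] <- ""
  atoms$o[is.na(atoms$o)] <- 1
  atoms$b[is.na(atoms$b)] <- 0
  atoms$elety <- normalize_atom_name(atoms$elety)
  if (is.null(atoms$elesy)) atoms$elesy <- NA_character_
  atoms$elesy <- toupper(atoms$elesy)
  fix <- is.na(atoms$elesy) | atoms$elesy == ""
  atoms$elesy[fix] <- infer_element(atoms$elety[fix], atoms$resid[fix])
  stopifnot(all(is.finite(atoms$x)), all(is.finite(atoms$y)),
            all(is.finite(atoms$z)))
  if (any(atoms$o < 0 | atoms$o > 1)) stop("occupancy outside [0, 1]")
  if (any(atoms$b < 0)) stop("negative B-factor")
  if (any(atoms$elesy == "")) stop("empty element symbol")
  # hydrogens are ignored everywhere
  atoms <- atoms[!atoms$elesy %in% c("H", "D"), , drop = FALSE]
  # alternate locations: keep the highest-occupancy conformer, ties by alt id
  atoms <- resolve_altlocs(atoms)
  atoms$is_water <- atoms$resid %in% WATER_RESIDUES
  atoms$is_metal <- atoms$elesy %in% METAL_ELEMENTS
  rownames(atoms) <- NULL
  structure(list(atoms = atoms, cell = cell, resolution = resolution,
                 id = id, meta = meta), class = "mg_structure")
}

#' @export
print.mg_structure <- function(x, ...) {
  cat("mg_structure '", x$id, "': ", nrow(x$atoms), " atoms, ",
      sum(x$atoms$elesy == "MG"), " Mg",
      if (!is.null(x$cell)) paste0(", cell ", x$cell$spacegroup) else ", no cell",
      if (!is.na(x$resolution)) paste0(", ", x$resolution, " A") else "",
      "\n", sep = "")
  invisible(x)
}

# prime-vs-asterisk ribose naming, legacy phosphate oxygen names, CIF quoting
normalize_atom_name <- function(x) {
  x <- gsub('"', "", trimws(x))
  x <- gsub("\\*", "'", x)
  x[x == "O1P"] <- "OP1"
  x[x == "O2P"] <- "OP2"
  x[x == "O3P"] <- "OP3"
  x
}

infer_element <- function(elety, resid) {
  out <- character(length(elety))
  for (i in seq_along(elety)) {
    nm <- gsub("[^A-Za-z]", "", elety[i])
    two <- toupper(substr(nm, 1, 2))
    if (toupper(resid[i]) == two || two %in% METAL_ELEMENTS) out[i] <- two
    else out[i] <- toupper(substr(nm, 1, 1))
  }
  out
}

resolve_altlocs <- function(atoms) {
  alt <- atoms$alt
  if (all(alt == "")) return(atoms)
  key <- paste(atoms$chain, atoms$resno, atoms$insert, atoms$resid, atoms$elety)
  keep <- rep(TRUE, nrow(atoms))
  for (k in unique(key[alt != ""])) {
    idx <- which(key == k)
    if (length(idx) < 2) next
    ord <- idx[order(-atoms$o[idx], atoms$alt[idx])]
    keep[setdiff(idx, ord[1])] <- FALSE
  }
  atoms[keep, , drop = FALSE]
}

#' Read a crystal structure from PDB or mmCIF
#'
#' Parses coordinates (via bio3d), the unit cell, space-group symmetry
#' operators (REMARK 290 when present, otherwise a Hermann-Mauguin symbol
#' lookup), resolution and basic metadata. Hydrogens are dropped, alternate
#' locations collapsed to the highest-occupancy conformer, and ribose
#' asterisk names normalized to primes.
#'
#' @param path file path.
#' @param format `"auto"` (default, by extension), `"pdb"` or `"cif"`.
#' @return an `mg_structure`; `cell` is `NULL` when no cell is recorded
#'   (symmetry queries then degrade to the asymmetric unit with a warning).
#' @export
#' @examples
#' f <- tempfile(fileext = ".pdb")
#' writeLines(c(
#'   "CRYST1   20.000   20.000   20.000  90.00  90.00  90.00 P 1",
#'   "HETATM    1 MG    MG A   1       0.000   0.000   0.000  1.00 10.00          MG",
#'   "END"), f)
#' read_structure(f)
read_structure <- function(path, format = c("auto", "pdb", "cif")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- if (ext %in% c("cif", "mmcif")) "cif" else "pdb"
  }
  id <- sub("\\.(pdb|ent|cif|mmcif)$", "", basename(path), ignore.case = TRUE)
  if (format == "pdb") read_structure_pdb(path, id) else read_structure_cif(path, id)
}

read_structure_pdb <- function(path, id) {
  pdb <- tryCatch(bio3d::read.pdb(path, verbose = FALSE, rm.alt = FALSE),
                  error = function(e) stop("cannot parse PDB file '", path,
                                           "': ", conditionMessage(e)))
  if (is.null(pdb$atom) || nrow(pdb$atom) == 0)
    stop("no ATOM/HETATM records in '", path, "'")
  lines <- readLines(path, warn = FALSE)
  cl <- grep("^CRYST1", lines, value = TRUE)
  cell <- NULL
  if (length(cl)) {
    a <- as.numeric(substr(cl[1], 7, 15)); b <- as.numeric(substr(cl[1], 16, 24))
    c_ <- as.numeric(substr(cl[1], 25, 33))
    al <- as.numeric(substr(cl[1], 34, 40)); be <- as.numeric(substr(cl[1], 41, 47))
    ga <- as.numeric(substr(cl[1], 48, 54))
    sg <- trimws(substr(cl[1], 56, 66))
    # placeholder cell written by some software for non-crystal coordinates
    dummy <- isTRUE(all.equal(c(a, b, c_), c(1, 1, 1))) &&
      isTRUE(all.equal(c(al, be, ga), c(90, 90, 90)))
    if (!any(is.na(c(a, b, c_, al, be, ga))) && !dummy) {
      mats <- cell_matrices(a, b, c_, al, be, ga)
      ops <- parse_remark290(lines, mats)
      cell <- unit_cell(a, b, c_, al, be, ga, spacegroup = sg, ops = ops)
    }
  }
  res <- NA_real_
  rl <- grep("^REMARK   2 RESOLUTION", lines, value = TRUE)
  if (length(rl)) {
    tail_ <- sub(".*RESOLUTION\\.?", "", rl[1])
    m <- regmatches(tail_, regexpr("[0-9]+\\.?[0-9]*", tail_))
    if (length(m)) res <- as.numeric(m)
  }
  meta <- list(
    expdta = paste(trimws(sub("^EXPDTA", "", grep("^EXPDTA", lines, value = TRUE))),
                   collapse = " "),
    title = paste(trimws(sub("^(TITLE|KEYWDS)\\s*\\d*", "",
                             grep("^(TITLE|KEYWDS)", lines, value = TRUE))),
                  collapse = " ")
  )
  mg_structure(pdb$atom, cell = cell, resolution = res, id = id, meta = meta)
}

read_structure_cif <- function(path, id) {
  cif <- withCallingHandlers(
    tryCatch(bio3d::read.cif(path, verbose = FALSE, rm.alt = FALSE),
             error = function(e) stop("cannot parse mmCIF file '", path,
                                      "': ", conditionMessage(e))),
    warning = function(w) {
      if (grepl("beta version|helix/sheet", conditionMessage(w)))
        invokeRestart("muffleWarning")
    })
  lines <- readLines(path, warn = FALSE)
  getval <- function(key) {
    l <- grep(paste0("^", key, "\\s"), lines, value = TRUE)
    if (!length(l)) return(NA_character_)
    v <- trimws(sub(paste0("^", key, "\\s+"), "", l[1]))
    gsub("^['\"]|['\"]$", "", v)
  }
  cell <- NULL
  a <- suppressWarnings(as.numeric(getval("_cell.length_a")))
  if (!is.na(a)) {
    b <- as.numeric(getval("_cell.length_b")); c_ <- as.numeric(getval("_cell.length_c"))
    al <- as.numeric(getval("_cell.angle_alpha")); be <- as.numeric(getval("_cell.angle_beta"))
    ga <- as.numeric(getval("_cell.angle_gamma"))
    sg <- getval("_symmetry.space_group_name_H-M")
    if (is.na(sg)) sg <- getval("_space_group.name_H-M_alt")
    if (is.na(sg)) sg <- "P 1"
    ops <- parse_cif_symops(lines)
    cell <- unit_cell(a, b, c_, al, be, ga, spacegroup = sg, ops = ops)
  }
  res <- suppressWarnings(as.numeric(getval("_refine.ls_d_res_high")))
  if (is.na(res)) res <- suppressWarnings(as.numeric(getval("_reflns.d_resolution_high")))
  meta <- list(expdta = getval("_exptl.method") %||% "",
               title = paste(getval("_struct.title"), getval("_struct_keywords.text")))
  meta$expdta[is.na(meta$expdta)] <- ""
  mg_structure(cif$atom, cell = cell, resolution = res, id = id, meta = meta)
}

# operator strings from _symmetry_equiv_pos_as_xyz / _space_group_symop loops
parse_cif_symops <- function(lines) {
  key <- grep("_symmetry_equiv[._]pos_as_xyz|_space_group_symop[._]operation_xyz",
              lines)
  if (!length(key)) return(NULL)
  out <- character()
  i <- key[1] + 1
  while (i <= length(lines)) {
    l <- trimws(lines[i])
    if (l == "" || startsWith(l, "_") || startsWith(l, "loop_") ||
        startsWith(l, "#") || startsWith(l, "data_")) break
    f <- regmatches(l, gregexpr("'[^']+'|\\S+", l))[[1]]
    xyz <- grep("[xyz]", f, value = TRUE)
    if (length(xyz)) out <- c(out, gsub("'", "", xyz[length(xyz)]))
    i <- i + 1
  }
  if (!length(out)) return(NULL)
  lapply(out, parse_symop)
}

#' Write a structure model to a PDB file
#'
#' Emits CRYST1 (when a cell is present), resolution and experiment
#' remarks, and fixed-width ATOM/HETATM records. Round-trips atom names,
#' B-factors and occupancies at output precision.
#'
#' @param model an `mg_structure`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_structure <- function(model, path) {
  at <- model$atoms
  lines <- character()
  if (!is.null(model$meta$title) && nzchar(model$meta$title))
    lines <- c(lines, sprintf("TITLE     %s", toupper(model$meta$title)))
  expd <- model$meta$expdta %||% ""
  if (nzchar(expd)) lines <- c(lines, sprintf("EXPDTA    %s", toupper(expd)))
  if (!is.na(model$resolution))
    lines <- c(lines, sprintf(
      "REMARK   2 RESOLUTION.    %4.2f ANGSTROMS.", model$resolution))
  if (!is.null(model$cell)) {
    cl <- model$cell
    lines <- c(lines, sprintf(
      "CRYST1%9.3f%9.3f%9.3f%7.2f%7.2f%7.2f %-11s%4d",
      cl$a, cl$b, cl$c, cl$alpha, cl$beta, cl$gamma, cl$spacegroup,
      length(cl$ops)))
  }
  het <- at$is_water | at$is_metal | !(at$resid %in% RNA_RESIDUES)
  rec <- ifelse(het, "HETATM", "ATOM  ")
  name4 <- ifelse(nchar(at$elesy) >= 2 | nchar(at$elety) >= 4,
                  sprintf("%-4s", at$elety), sprintf(" %-3s", at$elety))
  lines <- c(lines, sprintf(
    "%s%5d %s%1s%3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
    rec, seq_len(nrow(at)) %% 100000, name4, substr(at$alt, 1, 1),
    at$resid, at$chain, at$resno, substr(at$insert, 1, 1),
    at$x, at$y, at$z, at$o, at$b, at$elesy), "END")
  writeLines(lines, path)
  invisible(path)
}

#' Symmetry-aware radius query
#'
#' Returns every atom within `radius` of a center, including symmetry
#' mates and periodic images when the model carries a unit cell and
#' `use_symmetry` is `TRUE`. The center atom itself (and its images at
#' zero distance, i.e. special positions) is excluded. Results are sorted
#' by distance, with deterministic tie-breaking.
#'
#' @param model an `mg_structure`.
#' @param center an atom index into `model$atoms`, or a numeric xyz triple.
#' @param radius search radius in Angstrom, in (0, 10].
#' @param use_symmetry include crystallographic symmetry mates and lattice
#'   translations (default `TRUE`); ignored with a warning when the model
#'   has no cell.
#' @return data.frame with one row per contact: `atom` (index), `elety`,
#'   `resid`, `chain`, `resno`, `insert`, `elesy`, `is_water`, `is_metal`,
#'   `distance`, `sym_op` (1 = identity), `s1`,`s2`,`s3` (lattice shift),
#'   `cx`,`cy`,`cz` (transformed Cartesian coordinates).
#' @export
neighbor_search <- function(model, center, radius, use_symmetry = TRUE) {
  stopifnot(radius > 0, radius <= 10)
  at <- model$atoms
  n <- nrow(at)
  if (n == 0) return(empty_contacts())
  if (length(center) == 1) {
    ci <- as.integer(center)
    cxyz <- c(at$x[ci], at$y[ci], at$z[ci])
  } else {
    cxyz <- as.numeric(center)
    stopifnot(length(cxyz) == 3)
  }
  X <- cbind(at$x, at$y, at$z)
  cell <- model$cell
  if (use_symmetry && is.null(cell)) {
    warning("no unit cell in '", model$id,
            "'; neighbor search restricted to the asymmetric unit",
            call. = FALSE)
    use_symmetry <- FALSE
  }
  if (!use_symmetry || is.null(cell)) {
    d <- sqrt((X[, 1] - cxyz[1])^2 + (X[, 2] - cxyz[2])^2 + (X[, 3] - cxyz[3])^2)
    keep <- which(d <= radius & d > 1e-6)
    out <- contact_frame(at, keep, d[keep], 1L,
                         matrix(0L, length(keep), 3), X[keep, , drop = FALSE])
  } else {
    Fm <- cell$frac; M <- cell$orth
    fc <- as.numeric(Fm %*% cxyz)
    Fa <- X %*% t(Fm)
    kmax <- ceiling(radius * sqrt(rowSums(Fm^2)) + 0.5)
    pieces <- list()
    for (oi in seq_along(cell$ops)) {
      op <- cell$ops[[oi]]
      Ft <- Fa %*% t(op$R)
      Ft <- sweep(Ft, 2, op$t, "+")
      diff <- sweep(Ft, 2, fc)
      n0 <- round(diff)
      base <- diff - n0
      for (s1 in -kmax[1]:kmax[1]) for (s2 in -kmax[2]:kmax[2])
        for (s3 in -kmax[3]:kmax[3]) {
          fr <- sweep(base, 2, c(s1, s2, s3), "+")
          cart <- fr %*% t(M)
          d <- sqrt(rowSums(cart^2))
          keep <- which(d <= radius & d > 1e-6)
          if (!length(keep)) next
          shifts <- sweep(-n0[keep, , drop = FALSE], 2, c(s1, s2, s3), "+")
          pos <- sweep(cart[keep, , drop = FALSE], 2, cxyz, "+")
          pieces[[length(pieces) + 1]] <-
            contact_frame(at, keep, d[keep], oi, shifts, pos)
        }
    }
    out <- if (length(pieces)) do.call(rbind, pieces) else empty_contacts()
    # atoms on special positions map onto themselves under several
    # operators; keep one copy per physical position
    if (nrow(out) > 1) {
      ord <- order(out$sym_op, abs(out$s1) + abs(out$s2) + abs(out$s3))
      out <- out[ord, , drop = FALSE]
      poskey <- paste(out$atom, round(out$cx, 3), round(out$cy, 3),
                      round(out$cz, 3))
      out <- out[!duplicated(poskey), , drop = FALSE]
    }
  }
  out <- out[order_contacts(out), , drop = FALSE]
  rownames(out) <- NULL
  out
}

contact_frame <- function(at, idx, d, op, shifts, pos) {
  if (!length(idx)) return(empty_contacts())
  data.frame(atom = idx, elety = at$elety[idx], resid = at$resid[idx],
             chain = at$chain[idx], resno = at$resno[idx],
             insert = at$insert[idx], elesy = at$elesy[idx],
             is_water = at$is_water[idx], is_metal = at$is_metal[idx],
             distance = d, sym_op = as.integer(op),
             s1 = as.integer(round(shifts[, 1])),
             s2 = as.integer(round(shifts[, 2])),
             s3 = as.integer(round(shifts[, 3])),
             cx = pos[, 1], cy = pos[, 2], cz = pos[, 3],
             stringsAsFactors = FALSE)
}

empty_contacts <- function() {
  data.frame(atom = integer(), elety = character(), resid = character(),
             chain = character(), resno = integer(), insert = character(),
             elesy = character(), is_water = logical(), is_metal = logical(),
             distance = numeric(), sym_op = integer(), s1 = integer(),
             s2 = integer(), s3 = integer(), cx = numeric(), cy = numeric(),
             cz = numeric(), stringsAsFactors = FALSE)
}

#' Apply dataset selection criteria to a set of structures
#'
#' Keeps structures that (i) are X-ray structures when the experiment
#' metadata is available, (ii) contain at least three common
#' ribonucleotides (A/G/C/U) covalently linked by phosphodiester bonds
#' (operationalized as O3'-P distance <= `linkage_max`), and (iii) contain
#' at least one Mg. Kept structures are tagged ribosome / non-ribosome by
#' a case-insensitive keyword match on title metadata, overridable with an
#' explicit id list.
#'
#' @param paths character vector of structure files.
#' @param config a [mg_config()] list.
#' @param ribosome_ids optional character vector of structure ids to force
#'   into the ribosome subset.
#' @return data.frame with columns `path`, `id`, `accepted`, `reasons`
#'   (semicolon-joined failed criteria, `""` when accepted), `subset`.
#' @export
select_structures <- function(paths, config = mg_config(),
                              ribosome_ids = character()) {
  rows <- lapply(paths, function(p) {
    m <- tryCatch(read_structure(p), error = function(e) e)
    if (inherits(m, "error")) {
      return(data.frame(path = p, id = basename(p), accepted = FALSE,
                        reasons = paste0("unreadable: ", conditionMessage(m)),
                        subset = NA_character_))
    }
    reasons <- character()
    expd <- toupper(m$meta$expdta %||% "")
    if (nzchar(expd) && !grepl("X-RAY", expd)) reasons <- c(reasons, "not_xray")
    if (max_linked_run(m, config$linkage_max) < 3)
      reasons <- c(reasons, "fewer_than_3_linked_ribonucleotides")
    if (!any(m$atoms$elesy == "MG")) reasons <- c(reasons, "no_mg")
    subset <- if (m$id %in% ribosome_ids ||
                  grepl(paste(config$ribosome_keywords, collapse = "|"),
                        m$meta$title %||% "", ignore.case = TRUE))
      "ribosome" else "non-ribosome"
    data.frame(path = p, id = m$id, accepted = length(reasons) == 0,
               reasons = paste(reasons, collapse = ";"), subset = subset)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# size of the largest connected component of A/G/C/U residues linked by
# O3'(i)-P(j) covalent bonds
max_linked_run <- function(model, linkage_max = 2.0) {
  at <- model$atoms
  rna <- at[at$resid %in% RNA_RESIDUES, , drop = FALSE]
  if (nrow(rna) == 0) return(0L)
  rk <- res_key(rna$chain, rna$resno, rna$insert)
  resl <- unique(rk)
  if (length(resl) < 3) return(length(resl))
  o3 <- rna[rna$elety == "O3'", , drop = FALSE]
  pp <- rna[rna$elety == "P", , drop = FALSE]
  parent <- seq_along(resl)
  find <- function(i) { while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }; i }
  if (nrow(o3) && nrow(pp)) {
    for (i in seq_len(nrow(o3))) {
      d <- sqrt((pp$x - o3$x[i])^2 + (pp$y - o3$y[i])^2 + (pp$z - o3$z[i])^2)
      for (j in which(d <= linkage_max)) {
        a <- find(match(res_key(o3$chain[i], o3$resno[i], o3$insert[i]), resl))
        b <- find(match(res_key(pp$chain[j], pp$resno[j], pp$insert[j]), resl))
        if (a != b) parent[a] <- b
      }
    }
  }
  comp <- vapply(seq_along(resl), find, integer(1))
  max(table(comp))
}
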