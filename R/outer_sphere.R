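# hydrogen bonds from inner-sphere waters to RNA, and outer-sphere moieties

#' Hydrogen bonds from inner-sphere waters to RNA
#'
#' A purely geometric criterion stands in for dot-based contact programs:
#' for each inner-sphere water oxygen, every O or N atom of a standard
#' ribonucleotide with heavy-atom distance inside
#' `[config$hbond_min, config$hbond_max]` (2.4-3.5 A) and
#' Mg-Owater-acceptor angle of at least `config$hbond_angle_min`
#' (90 degrees, i.e. on the far side of the water) counts as
#' hydrogen-bonded. The magnesium's own inner-sphere atoms are excluded;
#' symmetry mates are included.
#'
#' @param model an `mg_structure`.
#' @param inner an `mg_inner`.
#' @param config a [mg_config()] list.
#' @return data.frame with one row per bond: `water_atom`, `water_sym`,
#'   `rna_atom`, `elety`, `resid`, `chain`, `resno`, `insert`,
#'   `distance`, `angle`, `cx`,`cy`,`cz`, `sym` (image key of the
#'   acceptor), `via_symmetry`.
#' @export
find_water_rna_hbonds <- function(model, inner, config = mg_config()) {
  lg <- inner$ligands
  waters <- lg[!is.na(lg$class) & lg$class == "water_O", , drop = FALSE]
  out <- list()
  if (nrow(waters) == 0) return(empty_hbonds())
  mg_xyz <- inner$mg_xyz
  # positions of every inner-sphere atom, to exclude them as acceptors
  inner_pos <- cbind(lg$cx, lg$cy, lg$cz)
  for (i in seq_len(nrow(waters))) {
    w <- waters[i, ]
    wpos <- c(w$cx, w$cy, w$cz)
    cont <- neighbor_search(model, wpos, config$hbond_max,
                            use_symmetry = config$use_symmetry &&
                              !is.null(model$cell))
    if (!nrow(cont)) next
    cont <- cont[cont$distance >= config$hbond_min &
                   cont$elesy %in% c("O", "N") &
                   cont$resid %in% RNA_RESIDUES, , drop = FALSE]
    if (!nrow(cont)) next
    keep <- logical(nrow(cont))
    ang <- numeric(nrow(cont))
    for (j in seq_len(nrow(cont))) {
      apos <- c(cont$cx[j], cont$cy[j], cont$cz[j])
      # not this Mg's own inner-sphere atom (match by physical position)
      dd <- sqrt(rowSums((inner_pos - matrix(apos, nrow(inner_pos), 3,
                                             byrow = TRUE))^2))
      if (any(dd < 0.1) || vnorm(apos - mg_xyz) < 0.1) next
      ang[j] <- vertex_angle(mg_xyz, wpos, apos)
      keep[j] <- ang[j] >= config$hbond_angle_min
    }
    cont <- cont[keep, , drop = FALSE]
    ang <- ang[keep]
    if (!nrow(cont)) next
    wsym <- sym_key(w$sym_op, w$s1, w$s2, w$s3)
    out[[length(out) + 1]] <- data.frame(
      water_atom = w$atom, water_sym = wsym,
      rna_atom = cont$atom, elety = cont$elety, resid = cont$resid,
      chain = cont$chain, resno = cont$resno, insert = cont$insert,
      distance = cont$distance, angle = ang,
      cx = cont$cx, cy = cont$cy, cz = cont$cz,
      sym = sym_key(cont$sym_op, cont$s1, cont$s2, cont$s3),
      via_symmetry = wsym != "" |
        sym_key(cont$sym_op, cont$s1, cont$s2, cont$s3) != "",
      stringsAsFactors = FALSE)
  }
  if (!length(out)) return(empty_hbonds())
  res <- do.call(rbind, out)
  # the same physical (water, acceptor) pair can be seen from several
  # frames; keep one row per physical pair
  key <- paste(res$water_atom, res$water_sym, res$rna_atom, res$sym)
  res <- res[!duplicated(key), , drop = FALSE]
  res <- res[order(res$chain, res$resno, res$elety, res$water_atom), , drop = FALSE]
  rownames(res) <- NULL
  res
}

empty_hbonds <- function() {
  data.frame(water_atom = integer(), water_sym = character(),
             rna_atom = integer(), elety = character(), resid = character(),
             chain = character(), resno = integer(), insert = character(),
             distance = numeric(), angle = numeric(), cx = numeric(),
             cy = numeric(), cz = numeric(), sym = character(),
             via_symmetry = logical(), stringsAsFactors = FALSE)
}

# moiety part of an RNA atom: "P" (phosphate), "R" (ribose), "B" (base),
# "bridge" for O3'/O5' pending the connected-phosphate rule
moiety_part <- function(resid, elety) {
  cls <- classify_atom(resid, elety)
  part <- rep(NA_character_, length(cls))
  part[elety %in% c("OP1", "OP2", "OP3", "P")] <- "P"
  part[elety %in% c("O2'", "O4'")] <- "R"
  part[elety %in% c("O3'", "O5'")] <- "bridge"
  part[cls %in% c("O_b", "N_b")] <- "B"
  part
}

#' Aggregate hydrogen bonds into outer-sphere moieties
#'
#' Maps each hydrogen-bonded RNA atom to its phosphate (P_out), ribose
#' (R_out) or nucleobase (B_out) moiety, counted once per (kind, residue,
#' symmetry image) per site. Bridging O3'/O5' atoms belong to the ribose
#' unless their covalently connected phosphate already contributes to the
#' inner or outer sphere of the same magnesium, in which case they fold
#' into that phosphate moiety (O3' connects to the 3'-neighbor residue's
#' phosphate; the bond, not the numbering, decides). Moieties whose
#' residue part already coordinates the magnesium inner-sphere are
#' dropped for that part only.
#'
#' @param bonds hydrogen bonds from [find_water_rna_hbonds()].
#' @param inner the site's `mg_inner`.
#' @param model the `mg_structure`.
#' @param config a [mg_config()] list.
#' @return data.frame with one row per moiety: `kind` (`P_out`, `R_out`,
#'   `B_out`), `chain`, `resno`, `insert`, `resid`, `sym`, `n_bonds`,
#'   `atoms` (comma-joined atom names).
#' @export
assign_moieties <- function(bonds, inner, model, config = mg_config()) {
  if (nrow(bonds) == 0) return(empty_moieties())
  at <- model$atoms
  lg <- inner$ligands

  # inner-sphere contributions per (part, residue, image)
  inner_parts <- character()
  if (nrow(lg)) {
    ip <- moiety_part(lg$resid, lg$elety)
    isym <- sym_key(lg$sym_op, lg$s1, lg$s2, lg$s3)
    # an inner bridging O3'/O5' counts as a ribose-part contribution
    ip[!is.na(ip) & ip == "bridge"] <- "R"
    ok <- !is.na(ip)
    inner_parts <- unique(paste(ip[ok], res_key(lg$chain[ok], lg$resno[ok],
                                                lg$insert[ok]), isym[ok]))
    # phosphate groups contributing inner-sphere O_ph, by P-atom identity
    inner_phos <- character()
    for (k in which(!is.na(lg$class) & lg$class == "O_ph")) {
      pg <- phosphate_group_of(model, lg$atom[k], config$bond_PO_max)
      if (!is.na(pg)) inner_phos <- c(inner_phos, paste(pg, isym[k]))
    }
  } else inner_phos <- character()

  b <- bonds
  b$part <- moiety_part(b$resid, b$elety)
  b <- b[!is.na(b$part), , drop = FALSE]
  if (!nrow(b)) return(empty_moieties())

  # phosphate moieties directly bonded via OP1/OP2/P, keyed by residue+image
  direct_P <- unique(paste(res_key(b$chain, b$resno, b$insert)[b$part == "P"],
                           b$sym[b$part == "P"]))

  # resolve bridging O3'/O5' through their covalent phosphate
  for (i in which(b$part == "bridge")) {
    pg <- phosphate_group_of(model, b$rna_atom[i], config$bond_PO_max)
    if (is.na(pg)) { b$part[i] <- "R"; next }
    pkey <- paste(res_key(at$chain[pg], at$resno[pg], at$insert[pg]), b$sym[i])
    if (pkey %in% direct_P || paste(pg, b$sym[i]) %in% inner_phos) {
      b$part[i] <- "P"
      # the atom belongs to the connected phosphate's residue
      b$chain[i] <- at$chain[pg]; b$resno[i] <- at$resno[pg]
      b$insert[i] <- at$insert[pg]; b$resid[i] <- at$resid[pg]
    } else {
      b$part[i] <- "R"
    }
  }

  # drop parts that already coordinate the inner sphere
  pkey <- paste(b$part, res_key(b$chain, b$resno, b$insert), b$sym)
  phos_by_atom <- vapply(seq_len(nrow(b)), function(i) {
    if (b$part[i] != "P") return("")
    pg <- phosphate_group_of(model, b$rna_atom[i], config$bond_PO_max)
    if (is.na(pg)) "" else paste(pg, b$sym[i])
  }, character(1))
  drop <- pkey %in% inner_parts | (phos_by_atom != "" & phos_by_atom %in% inner_phos)
  b <- b[!drop, , drop = FALSE]
  if (!nrow(b)) return(empty_moieties())

  grp <- paste(b$part, res_key(b$chain, b$resno, b$insert), b$sym, sep = "~")
  rows <- lapply(unique(grp), function(g) {
    sub <- b[grp == g, , drop = FALSE]
    data.frame(kind = paste0(sub$part[1], "_out"),
               chain = sub$chain[1], resno = sub$resno[1],
               insert = sub$insert[1], resid = sub$resid[1],
               sym = sub$sym[1], n_bonds = nrow(sub),
               atoms = paste(sort(unique(sub$elety)), collapse = ","),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$kind, out$chain, out$resno, out$sym), , drop = FALSE]
  rownames(out) <- NULL
  out
}

empty_moieties <- function() {
  data.frame(kind = character(), chain = character(), resno = integer(),
             insert = character(), resid = character(), sym = character(),
             n_bonds = integer(), atoms = character(),
             stringsAsFactors = FALSE)
}
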