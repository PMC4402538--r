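# ligand-atom typing, the two-step inner-sphere search, CN and isomerism

# nucleobase atom inventories for the four common ribonucleotides
BASE_OXYGENS <- list(A = character(), G = "O6", C = "O2", U = c("O2", "O4"))
BASE_NITROGENS <- list(A = c("N1", "N3", "N6", "N7", "N9"),
                       G = c("N1", "N2", "N3", "N7", "N9"),
                       C = c("N1", "N3", "N4"),
                       U = c("N1", "N3"))
# endocyclic nitrogens with an in-plane lone pair (-N=): the only base
# nitrogens that can coordinate Mg2+
LONE_PAIR_N <- c("A-N1", "A-N3", "A-N7", "G-N3", "G-N7", "C-N3")

RIBOSE_OXYGENS <- c("O2'", "O4'", "O3'", "O5'")

#' Classify a potential ligand atom
#'
#' Maps an atom to one of the ligand classes used throughout: `O_ph`
#' (phosphate oxygen OP1/OP2 of a standard nucleotide), `O_r` (ribose or
#' bridging oxygen O2'/O4'/O3'/O5'), `O_b` (nucleobase oxygen), `N_b`
#' (nucleobase nitrogen), `water_O`, or `other_O`/`other_N` for oxygens
#' and nitrogens of non-RNA or modified residues. Non-O/N elements return
#' `NA`.
#'
#' @param resid residue name(s) (vectorized).
#' @param elety atom name(s).
#' @param elesy optional element symbol(s); inferred from the atom name
#'   when missing.
#' @return character vector of class labels.
#' @export
#' @examples
#' classify_atom("G", "OP2")  # "O_ph"
#' classify_atom("U", "O4")   # "O_b"
#' classify_atom("A", "N6")   # "N_b" (exocyclic amino, not -N=)
classify_atom <- function(resid, elety, elesy = NULL) {
  elety <- normalize_atom_name(elety)
  if (is.null(elesy)) elesy <- infer_element(elety, resid)
  n <- max(length(resid), length(elety))
  resid <- rep_len(resid, n); elety <- rep_len(elety, n)
  elesy <- rep_len(toupper(elesy), n)
  out <- rep(NA_character_, n)
  isO <- elesy == "O"; isN <- elesy == "N"
  water <- resid %in% WATER_RESIDUES
  out[isO & water] <- "water_O"
  std <- resid %in% RNA_RESIDUES
  out[isO & std & elety %in% c("OP1", "OP2")] <- "O_ph"
  out[isO & std & elety %in% RIBOSE_OXYGENS] <- "O_r"
  for (r in RNA_RESIDUES) {
    out[isO & resid == r & elety %in% BASE_OXYGENS[[r]]] <- "O_b"
    out[isN & resid == r & elety %in% BASE_NITROGENS[[r]]] <- "N_b"
  }
  out[isO & is.na(out)] <- "other_O"
  out[isN & is.na(out)] <- "other_N"
  out
}

#' Is a nucleobase nitrogen an in-plane lone-pair nitrogen (-N=)?
#'
#' @param resid residue name(s).
#' @param elety atom name(s).
#' @return logical vector; `TRUE` only for A-N1, A-N3, A-N7, G-N3, G-N7
#'   and C-N3.
#' @export
is_lone_pair_N <- function(resid, elety) {
  paste(resid, normalize_atom_name(elety), sep = "-") %in% LONE_PAIR_N
}

# index (plus image key) of the P atom covalently bonded to an oxygen, or
# NA when the oxygen has none; bonded partners live in the same symmetry
# image, so the plain-coordinate search suffices
phosphate_group_of <- function(model, atom_idx, bond_PO_max = 1.9) {
  at <- model$atoms
  o <- c(at$x[atom_idx], at$y[atom_idx], at$z[atom_idx])
  pidx <- which(at$elesy == "P")
  if (!length(pidx)) return(NA_integer_)
  d <- sqrt((at$x[pidx] - o[1])^2 + (at$y[pidx] - o[2])^2 + (at$z[pidx] - o[3])^2)
  hit <- pidx[d <= bond_PO_max]
  if (!length(hit)) return(NA_integer_)
  hit[which.min(d[d <= bond_PO_max])]
}

#' Two-step inner-sphere search
#'
#' Step 1 accepts every oxygen within `d_ideal_O + step1_margin`
#' (default 2.58 A) and nitrogen within `d_ideal_N + step1_margin`
#' (2.70 A) of the magnesium. Step 2 runs only when step 1 found fewer
#' than six ligands; it scans the extended shell (O: up to 3.08 A,
#' N: up to 3.20 A) in ascending distance order and accepts a candidate
#' only if (i) it is not a second oxygen of a phosphate group that already
#' contributes a ligand, (ii) a nucleobase nitrogen is an in-plane
#' lone-pair nitrogen (-N=), and (iii) its angle at Mg with every
#' already-accepted ligand exceeds `step2_angle_min` (50 degrees). The
#' coordination number is the total count; CN > 6 is retained and flagged.
#'
#' @param model an `mg_structure`.
#' @param mg index of a magnesium atom in `model$atoms`.
#' @param config a [mg_config()] list.
#' @return an object of class `mg_inner`: list with `mg`, `mg_xyz`,
#'   `ligands` (data.frame: contact columns plus `class`, `step`,
#'   `valence`, `ux`,`uy`,`uz`, `lone_pair`), `cn`, `isomerism`,
#'   `cn_gt6`.
#' @export
find_inner_sphere <- function(model, mg, config = mg_config()) {
  at <- model$atoms
  stopifnot(at$elesy[mg] == "MG")
  mg_xyz <- c(at$x[mg], at$y[mg], at$z[mg])
  rmax <- max(config$d_ideal_O, config$d_ideal_N) + config$step2_margin
  cand <- neighbor_search(model, mg, rmax,
                          use_symmetry = config$use_symmetry &&
                            !is.null(model$cell))
  cand <- cand[cand$elesy %in% c("O", "N"), , drop = FALSE]
  if (nrow(cand)) {
    cand$class <- classify_atom(cand$resid, cand$elety, cand$elesy)
    cand$lone_pair <- cand$class == "N_b" &
      is_lone_pair_N(cand$resid, cand$elety)
    d1 <- ifelse(cand$elesy == "O", config$d_ideal_O, config$d_ideal_N) +
      config$step1_margin
    d2 <- ifelse(cand$elesy == "O", config$d_ideal_O, config$d_ideal_N) +
      config$step2_margin
    cand$in_step1 <- cand$distance <= d1
    cand$in_step2 <- !cand$in_step1 & cand$distance <= d2
  } else {
    cand$class <- character(); cand$lone_pair <- logical()
    cand$in_step1 <- logical(); cand$in_step2 <- logical()
  }
  cand <- cand[order_contacts(cand), , drop = FALSE]

  accepted <- cand[cand$in_step1, , drop = FALSE]
  accepted$step <- rep(1L, nrow(accepted))

  if (nrow(accepted) < 6) {
    pool <- cand[cand$in_step2, , drop = FALSE]
    for (i in seq_len(nrow(pool))) {
      lig <- pool[i, , drop = FALSE]
      if (accept_step2(model, lig, accepted, mg_xyz, config)) {
        lig$step <- 2L
        accepted <- rbind(accepted, lig)
      }
    }
  }

  lg <- accepted
  if (nrow(lg)) {
    u <- cbind(lg$cx - mg_xyz[1], lg$cy - mg_xyz[2], lg$cz - mg_xyz[3])
    u <- u / lg$distance
    lg$ux <- u[, 1]; lg$uy <- u[, 2]; lg$uz <- u[, 3]
    lg$valence <- bond_valence(lg$distance, lg$elesy, config$bv)
  } else {
    lg$step <- integer()
    lg$ux <- lg$uy <- lg$uz <- lg$valence <- numeric()
  }
  lg$in_step1 <- lg$in_step2 <- NULL
  rownames(lg) <- NULL
  inner <- structure(list(mg = mg, mg_xyz = mg_xyz, ligands = lg,
                          cn = nrow(lg), isomerism = NA_character_,
                          cn_gt6 = nrow(lg) > 6), class = "mg_inner")
  inner$isomerism <- geometric_isomerism(inner, config)
  inner
}

# the three chemical rules for a step-2 candidate against the accepted set
accept_step2 <- function(model, lig, accepted, mg_xyz, config) {
  # (ii) nucleobase nitrogens must be -N=
  if (lig$class == "N_b" && !lig$lone_pair) return(FALSE)
  # (i) no second oxygen from an already-contributing phosphate group
  if (lig$elesy == "O") {
    pg <- phosphate_group_of(model, lig$atom, config$bond_PO_max)
    if (!is.na(pg) && nrow(accepted)) {
      ox <- accepted[accepted$elesy == "O", , drop = FALSE]
      for (j in seq_len(nrow(ox))) {
        pg_j <- phosphate_group_of(model, ox$atom[j], config$bond_PO_max)
        if (!is.na(pg_j) && pg_j == pg &&
            identical(sym_key(ox$sym_op[j], ox$s1[j], ox$s2[j], ox$s3[j]),
                      sym_key(lig$sym_op, lig$s1, lig$s2, lig$s3)))
          return(FALSE)
      }
    }
  }
  # (iii) angle at Mg with every previously accepted ligand > threshold
  if (nrow(accepted)) {
    v <- c(lig$cx, lig$cy, lig$cz) - mg_xyz
    for (j in seq_len(nrow(accepted))) {
      w <- c(accepted$cx[j], accepted$cy[j], accepted$cz[j]) - mg_xyz
      if (dir_angle(v, w) <= config$step2_angle_min) return(FALSE)
    }
  }
  TRUE
}

#' @export
print.mg_inner <- function(x, ...) {
  cat("Mg inner sphere: CN =", x$cn,
      if (!is.na(x$isomerism)) paste0("(", x$isomerism, ")") else "",
      if (x$cn_gt6) "[flag: CN > 6]" else "", "\n")
  if (x$cn) print(x$ligands[, c("elety", "resid", "chain", "resno",
                                "class", "distance", "step")])
  invisible(x)
}

#' Geometric isomerism of phosphate-oxygen ligands
#'
#' For sites with 2, 3 or 4 inner-sphere O_ph ligands, reports the
#' octahedral isomer: a pair of O_ph with a ligand-Mg-ligand angle above
#' `trans_angle` (135 degrees) makes the site trans- (2 or 4 O_ph) or
#' mer- (3 O_ph); otherwise cis- or fac-.
#'
#' @param inner an `mg_inner`.
#' @param config a [mg_config()] list.
#' @return `"cis"`, `"trans"`, `"fac"`, `"mer"`, or `NA` when the O_ph
#'   count is not 2-4.
#' @export
geometric_isomerism <- function(inner, config = mg_config()) {
  lg <- inner$ligands
  ph <- lg[!is.na(lg$class) & lg$class == "O_ph", , drop = FALSE]
  n <- nrow(ph)
  if (!n %in% 2:4) return(NA_character_)
  has_trans_pair <- FALSE
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    ang <- dir_angle(c(ph$ux[i], ph$uy[i], ph$uz[i]),
                     c(ph$ux[j], ph$uy[j], ph$uz[j]))
    if (ang > config$trans_angle) has_trans_pair <- TRUE
  }
  if (n == 3) {
    if (has_trans_pair) "mer" else "fac"
  } else {
    if (has_trans_pair) "trans" else "cis"
  }
}
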