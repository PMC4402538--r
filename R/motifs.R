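# the thirteen binding-motif queries over classified sites

# sequence relations used by motif definitions; symmetry copies of a
# chain count as different chains
seq_distant <- function(c1, r1, c2, r2, max_sep = 7) {
  c1 != c2 | abs(r1 - r2) > max_sep
}
seq_consecutive <- function(c1, r1, c2, r2) c1 == c2 & abs(r1 - r2) == 1
seq_one_apart <- function(c1, r1, c2, r2) c1 == c2 & abs(r1 - r2) == 2

# inner O_ph ligand residues (phosphate = the ligand's own residue for
# OP1/OP2) with symmetry-aware chain ids
inner_phos_residues <- function(site) {
  lg <- site$inner$ligands
  ph <- lg[!is.na(lg$class) & lg$class == "O_ph", , drop = FALSE]
  data.frame(chain = eff_chain(ph$chain, sym_key(ph$sym_op, ph$s1, ph$s2, ph$s3)),
             resno = ph$resno, stringsAsFactors = FALSE)
}

inner_ligands_of_class <- function(site, cls) {
  lg <- site$inner$ligands
  lg[!is.na(lg$class) & lg$class == cls, , drop = FALSE]
}

moieties_of_kind <- function(site, kind) {
  m <- site$moieties
  m <- m[m$kind == kind, , drop = FALSE]
  m$echain <- eff_chain(m$chain, m$sym)
  m
}

has_counts <- function(site, sphere, counts) {
  tp <- site$type
  !is.null(tp) && !is.na(tp$sphere) && tp$sphere == sphere &&
    all(tp$counts == counts)
}

# a consecutive pair among phosphate residues; returns index pairs
consecutive_pairs <- function(res) {
  out <- list()
  n <- nrow(res)
  if (n < 2) return(out)
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    if (seq_consecutive(res$chain[i], res$resno[i], res$chain[j], res$resno[j]))
      out[[length(out) + 1]] <- c(i, j)
  }
  out
}

#' Motif definitions
#'
#' The six literature-derived motifs (I-VI) and seven novel motifs (A-G)
#' as named predicate functions over a processed site. "Distant" means
#' different chains or a sequence separation greater than seven residues;
#' "consecutive" means residues i and i+1 of the same chain.
#'
#' @return named list of definitions; each has `id`, `name` and `predicate`
#'   (a function of a `mg_site` returning `NULL` or a hit record).
#' @export
motif_definitions <- function() {
  defs <- list(
    list(id = "I", name = "magnesium clamp", predicate = motif_I),
    list(id = "II", name = "10-member ring", predicate = motif_II),
    list(id = "III", name = "G-phosphate", predicate = motif_III),
    list(id = "IV", name = "G-G metal-binding site", predicate = motif_IV),
    list(id = "V", name = "triple-G", predicate = motif_V),
    list(id = "VI", name = "metal ion zipper", predicate = motif_VI),
    list(id = "A", name = "Y-clamp", predicate = motif_A),
    list(id = "B", name = "U-phosphate", predicate = motif_B),
    list(id = "C", name = "12-member ring", predicate = motif_C),
    list(id = "D", name = "purine-N7 seat", predicate = motif_D),
    list(id = "E", name = "G-N7 macrochelate I", predicate = motif_E),
    list(id = "F", name = "G-N7 macrochelate II", predicate = motif_F),
    list(id = "G", name = "10-member ring with purine-N7", predicate = motif_G)
  )
  setNames(defs, vapply(defs, `[[`, character(1), "id"))
}

hit <- function(variant = NA_character_, residues = character()) {
  list(variant = variant, residues = residues)
}

res_label <- function(chain, resno) paste0(chain, resno)

# I: cis/trans-2O_ph, the two O_ph from distant phosphates
motif_I <- function(site) {
  if (!has_counts(site, "inner", c(O_ph = 2, O_r = 0, O_b = 0, N_b = 0)))
    return(NULL)
  ph <- inner_phos_residues(site)
  if (!seq_distant(ph$chain[1], ph$resno[1], ph$chain[2], ph$resno[2]))
    return(NULL)
  hit(site$inner$isomerism, res_label(ph$chain, ph$resno))
}

# II: 10-member ring family (consecutive phosphates), four variants
motif_II <- function(site) {
  tp <- site$type
  if (is.null(tp) || tp$sphere != "inner") return(NULL)
  if (sum(tp$counts[c("O_r", "O_b", "N_b")]) != 0) return(NULL)
  ph <- inner_phos_residues(site)
  n <- tp$counts[["O_ph"]]
  pairs <- consecutive_pairs(ph)
  if (n == 2 && identical(site$inner$isomerism, "cis") && length(pairs) >= 1)
    return(hit("2O_ph-consecutive", res_label(ph$chain, ph$resno)))
  if (n == 3 && site$inner$isomerism %in% c("fac", "mer")) {
    ord <- order(ph$chain, ph$resno)
    po <- ph[ord, ]
    all_consec <- po$chain[1] == po$chain[2] && po$chain[2] == po$chain[3] &&
      po$resno[2] == po$resno[1] + 1 && po$resno[3] == po$resno[2] + 1
    if (all_consec)
      return(hit(paste0(site$inner$isomerism, "-3O_ph-consecutive"),
                 res_label(po$chain, po$resno)))
    # ring plus an extra phosphate separated by one residue from either
    # ring phosphate
    for (p in pairs) {
      k <- setdiff(1:3, p)
      if (any(seq_one_apart(ph$chain[p], ph$resno[p], ph$chain[k], ph$resno[k])))
        return(hit(paste0(site$inner$isomerism, "-ring+1-separated-O_ph"),
                   res_label(ph$chain, ph$resno)))
    }
  }
  if (n == 4 && length(pairs) >= 2) {
    # two disjoint consecutive pairs = two unrelated 10-member rings
    for (a in seq_along(pairs)) for (b in seq_along(pairs)) {
      if (a < b && !length(intersect(pairs[[a]], pairs[[b]])))
        return(hit("double-ring", res_label(ph$chain, ph$resno)))
    }
  }
  NULL
}

# III: O_ph•O_b with the base oxygen from guanine
motif_III <- function(site) {
  if (!has_counts(site, "inner", c(O_ph = 1, O_r = 0, O_b = 1, N_b = 0)))
    return(NULL)
  ob <- inner_ligands_of_class(site, "O_b")
  if (ob$resid[1] != "G") return(NULL)
  ph <- inner_phos_residues(site)
  hit(NA_character_, c(res_label(ph$chain, ph$resno),
                       res_label(ob$chain, ob$resno)))
}

# IV: outer-sphere G•G family
motif_IV <- function(site) {
  tp <- site$type
  if (is.null(tp) || tp$sphere != "outer") return(NULL)
  b <- moieties_of_kind(site, "B_out")
  g <- b[b$resid == "G", , drop = FALSE]
  gp <- consecutive_pairs(data.frame(chain = g$echain, resno = g$resno))
  if (!length(gp)) return(NULL)
  p <- moieties_of_kind(site, "P_out")
  if (all(tp$counts == c(P_out = 2, R_out = 0, B_out = 2))) {
    for (pr in gp) {
      n_low <- min(g$resno[pr])
      ch <- g$echain[pr][1]
      want <- c(n_low, n_low - 1)
      if (all(want %in% p$resno[p$echain == ch]))
        return(hit("2P_out+2B_out", c(res_label(g$echain[pr], g$resno[pr]),
                                      res_label(ch, want))))
    }
  }
  if (all(tp$counts == c(P_out = 0, R_out = 0, B_out = 2))) {
    pr <- gp[[1]]
    return(hit("2B_out", res_label(g$echain[pr], g$resno[pr])))
  }
  if (all(tp$counts == c(P_out = 1, R_out = 0, B_out = 2))) {
    for (pr in gp) {
      far <- seq_distant(p$echain[1], p$resno[1], g$echain[pr], g$resno[pr])
      if (all(far))
        return(hit("P_out+2B_out", c(res_label(g$echain[pr], g$resno[pr]),
                                     res_label(p$echain[1], p$resno[1]))))
    }
  }
  NULL
}

# V: three sequentially consecutive guanine bases, outer sphere only
motif_V <- function(site) {
  if (!has_counts(site, "outer", c(P_out = 0, R_out = 0, B_out = 3)))
    return(NULL)
  b <- moieties_of_kind(site, "B_out")
  if (!all(b$resid == "G")) return(NULL)
  ord <- order(b$echain, b$resno)
  bo <- b[ord, ]
  if (bo$echain[1] == bo$echain[3] && bo$resno[2] == bo$resno[1] + 1 &&
      bo$resno[3] == bo$resno[2] + 1)
    return(hit(NA_character_, res_label(bo$echain, bo$resno)))
  NULL
}

# VI: two distant phosphates bound through the outer sphere
motif_VI <- function(site) {
  if (!has_counts(site, "outer", c(P_out = 2, R_out = 0, B_out = 0)))
    return(NULL)
  p <- moieties_of_kind(site, "P_out")
  if (seq_distant(p$echain[1], p$resno[1], p$echain[2], p$resno[2]))
    return(hit(NA_character_, res_label(p$echain, p$resno)))
  NULL
}

# A: mer-3O_ph = 10-member ring plus one distant O_ph
motif_A <- function(site) {
  if (!has_counts(site, "inner", c(O_ph = 3, O_r = 0, O_b = 0, N_b = 0)))
    return(NULL)
  if (!identical(site$inner$isomerism, "mer")) return(NULL)
  ph <- inner_phos_residues(site)
  for (p in consecutive_pairs(ph)) {
    k <- setdiff(1:3, p)
    if (all(seq_distant(ph$chain[p], ph$resno[p], ph$chain[k], ph$resno[k])))
      return(hit(NA_character_, res_label(ph$chain, ph$resno)))
  }
  NULL
}

# B: O_ph•O_b with the base oxygen from uracil
motif_B <- function(site) {
  if (!has_counts(site, "inner", c(O_ph = 1, O_r = 0, O_b = 1, N_b = 0)))
    return(NULL)
  ob <- inner_ligands_of_class(site, "O_b")
  if (ob$resid[1] != "U") return(NULL)
  ph <- inner_phos_residues(site)
  hit(NA_character_, c(res_label(ph$chain, ph$resno),
                       res_label(ob$chain, ob$resno)))
}

# C: two consecutive outer-sphere phosphates (12 non-hydrogen atom ring)
motif_C <- function(site) {
  if (!has_counts(site, "outer", c(P_out = 2, R_out = 0, B_out = 0)))
    return(NULL)
  p <- moieties_of_kind(site, "P_out")
  if (seq_consecutive(p$echain[1], p$resno[1], p$echain[2], p$resno[2]))
    return(hit(NA_character_, res_label(p$echain, p$resno)))
  NULL
}

# D: two purine N7 in the inner sphere, capped by 3-4 downstream P_out
motif_D <- function(site) {
  if (!has_counts(site, "inner", c(O_ph = 0, O_r = 0, O_b = 0, N_b = 2)))
    return(NULL)
  nb <- inner_ligands_of_class(site, "N_b")
  if (!all(nb$elety == "N7" & nb$resid %in% c("G", "A"))) return(NULL)
  echain <- eff_chain(nb$chain, sym_key(nb$sym_op, nb$s1, nb$s2, nb$s3))
  low <- which.min(nb$resno)
  p <- moieties_of_kind(site, "P_out")
  down <- p[p$echain == echain[low] & p$resno > nb$resno[low], , drop = FALSE]
  if (nrow(down) %in% c(3L, 4L))
    return(hit(NA_character_, c(res_label(echain, nb$resno),
                                res_label(down$echain, down$resno))))
  NULL
}

# E: inner-sphere G-N7 macrochelated by its own phosphate in the outer sphere
motif_E <- function(site) {
  if (!has_counts(site, "inner", c(O_ph = 0, O_r = 0, O_b = 0, N_b = 1)))
    return(NULL)
  nb <- inner_ligands_of_class(site, "N_b")
  if (!(nb$resid[1] == "G" && nb$elety[1] == "N7")) return(NULL)
  echain <- eff_chain(nb$chain[1], sym_key(nb$sym_op[1], nb$s1[1], nb$s2[1],
                                           nb$s3[1]))
  p <- moieties_of_kind(site, "P_out")
  if (any(p$echain == echain & p$resno == nb$resno[1]))
    return(hit(NA_character_, res_label(echain, nb$resno[1])))
  NULL
}

# F: outer-sphere G-N7 plus the phosphate of the same residue
motif_F <- function(site) {
  if (!has_counts(site, "outer", c(P_out = 1, R_out = 0, B_out = 1)))
    return(NULL)
  b <- moieties_of_kind(site, "B_out")
  if (!(b$resid[1] == "G" && grepl("(^|,)N7(,|$)", b$atoms[1]))) return(NULL)
  p <- moieties_of_kind(site, "P_out")
  if (p$echain[1] == b$echain[1] && p$resno[1] == b$resno[1])
    return(hit(NA_character_, res_label(b$echain[1], b$resno[1])))
  NULL
}

# G: 10-member ring plus purine N7 one residue away from either ring phosphate
motif_G <- function(site) {
  if (!has_counts(site, "inner", c(O_ph = 2, O_r = 0, O_b = 0, N_b = 1)))
    return(NULL)
  ph <- inner_phos_residues(site)
  if (!length(consecutive_pairs(ph))) return(NULL)
  nb <- inner_ligands_of_class(site, "N_b")
  if (!(nb$elety[1] == "N7" && nb$resid[1] %in% c("G", "A"))) return(NULL)
  nchain <- eff_chain(nb$chain[1], sym_key(nb$sym_op[1], nb$s1[1], nb$s2[1],
                                           nb$s3[1]))
  if (any(seq_one_apart(ph$chain, ph$resno, nchain, nb$resno[1])))
    return(hit(NA_character_, c(res_label(ph$chain, ph$resno),
                                res_label(nchain, nb$resno[1]))))
  NULL
}

#' Detect motifs at a site
#'
#' Evaluates every motif definition against a classified, typed site.
#' Overlapping hits are all reported (the queries are independent).
#'
#' @param site an `mg_site`.
#' @param definitions list from [motif_definitions()].
#' @return data.frame with columns `motif_id`, `name`, `variant`,
#'   `residues` (comma-joined labels); zero rows when nothing matches.
#' @export
detect_motifs <- function(site, definitions = motif_definitions()) {
  rows <- list()
  for (d in definitions) {
    h <- d$predicate(site)
    if (!is.null(h)) {
      rows[[length(rows) + 1]] <- data.frame(
        motif_id = d$id, name = d$name, variant = h$variant,
        residues = paste(h$residues, collapse = ","),
        stringsAsFactors = FALSE)
    }
  }
  if (!length(rows))
    return(data.frame(motif_id = character(), name = character(),
                      variant = character(), residues = character(),
                      stringsAsFactors = FALSE))
  do.call(rbind, rows)
}

#' Motif census over a set of sites
#'
#' @param sites list of `mg_site` objects.
#' @return data.frame of per-motif, per-variant counts with per-structure
#'   provenance (`structures`, comma-joined ids); all 13 motifs appear,
#'   zero-count rows included.
#' @export
motif_census <- function(sites) {
  defs <- motif_definitions()
  rows <- list()
  hits <- lapply(sites, function(s) {
    h <- s$motifs
    if (is.null(h) || nrow(h) == 0) return(NULL)
    h$structure <- s$structure_id
    h
  })
  hits <- do.call(rbind, hits[!vapply(hits, is.null, logical(1))])
  for (d in defs) {
    sub <- if (is.null(hits)) NULL else hits[hits$motif_id == d$id, , drop = FALSE]
    if (is.null(sub) || nrow(sub) == 0) {
      rows[[length(rows) + 1]] <- data.frame(
        motif_id = d$id, name = d$name, variant = NA_character_, n = 0L,
        structures = "", stringsAsFactors = FALSE)
    } else {
      for (v in unique(sub$variant)) {
        vs <- sub[if (is.na(v)) is.na(sub$variant) else
          !is.na(sub$variant) & sub$variant == v, , drop = FALSE]
        rows[[length(rows) + 1]] <- data.frame(
          motif_id = d$id, name = d$name, variant = v, n = nrow(vs),
          structures = paste(sort(unique(vs$structure)), collapse = ","),
          stringsAsFactors = FALSE)
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
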