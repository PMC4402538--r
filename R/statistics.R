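# dataset-level statistics: normalized interaction frequencies, summaries

#' Ligand-capable atom census of a set of structures
#'
#' Counts, per atom identity (`G-O6`, `U-OP1`, ...), the atoms of the
#' four RNA ligand classes (O_ph, O_r, O_b, N_b) across all standard
#' ribonucleotides; with `background = "all_rna_atoms"` every atom of a
#' standard ribonucleotide is counted instead.
#'
#' @param models list of `mg_structure` objects.
#' @param background `"ligand_capable"` (default) or `"all_rna_atoms"`.
#' @return named integer vector of counts keyed by `resid-elety`.
#' @export
atom_census <- function(models, background = c("ligand_capable",
                                               "all_rna_atoms")) {
  background <- match.arg(background)
  keys <- character()
  for (m in models) {
    at <- m$atoms
    rna <- at[at$resid %in% RNA_RESIDUES, , drop = FALSE]
    if (!nrow(rna)) next
    if (background == "ligand_capable") {
      cls <- classify_atom(rna$resid, rna$elety, rna$elesy)
      rna <- rna[cls %in% RNA_LIGAND_CLASSES, , drop = FALSE]
    }
    if (!nrow(rna)) next
    keys <- c(keys, paste(rna$resid, rna$elety, sep = "-"))
  }
  tb <- table(keys)
  setNames(as.integer(tb), names(tb))
}

#' Normalized interaction frequencies F_atom
#'
#' F_atom(X) = p(Mg-X) / p(X): the share of Mg-X interactions among all
#' RNA coordinating interactions in the benchmark sites, divided by the
#' share of type-X atoms in the background census of the full dataset.
#' Inner-sphere interactions are coordination bonds; outer-sphere
#' interactions are (water, RNA atom) hydrogen bonds. F = 1 means the
#' atom type is bound exactly as often as its abundance predicts.
#'
#' @param sites list of benchmark `mg_site` objects.
#' @param census background counts from [atom_census()] on the full
#'   dataset.
#' @param sphere `"inner"` or `"outer"`.
#' @return data.frame with columns `identity`, `n` (interaction count),
#'   `background`, `f_atom` (ratio; `Inf`, flagged in `flag`, when
#'   interactions are observed for an identity absent from the
#'   background).
#' @export
f_atom <- function(sites, census, sphere = c("inner", "outer")) {
  sphere <- match.arg(sphere)
  ints <- character()
  for (s in sites) {
    if (sphere == "inner") {
      lg <- s$inner$ligands
      lg <- lg[!is.na(lg$class) & lg$class %in% RNA_LIGAND_CLASSES, ,
               drop = FALSE]
      if (nrow(lg)) ints <- c(ints, paste(lg$resid, lg$elety, sep = "-"))
    } else {
      hb <- s$hbonds
      if (!is.null(hb) && nrow(hb))
        ints <- c(ints, paste(hb$resid, hb$elety, sep = "-"))
    }
  }
  ids <- sort(union(names(census), unique(ints)))
  n_tot <- length(ints)
  m_tot <- sum(census)
  rows <- lapply(ids, function(id) {
    n <- sum(ints == id)
    m <- if (id %in% names(census)) census[[id]] else 0L
    f <- if (n == 0) 0
         else if (m == 0 || m_tot == 0) Inf
         else (n / n_tot) / (m / m_tot)
    data.frame(identity = id, n = n, background = m, f_atom = f,
               flag = is.infinite(f), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Dataset summary
#'
#' Class and type census, CN histogram by resolution bin, and per-site
#' distributions of inner-sphere RNA ligand counts and outer-sphere
#' moiety counts.
#'
#' @param sites list of `mg_site` objects.
#' @param meta optional data.frame with `structure_id` and `resolution`
#'   used for the resolution bins (taken from the sites' source models).
#' @param config a [mg_config()] list.
#' @return list with `n_sites`, `class_census`, `type_census`,
#'   `cn_by_resolution`, `inner_rna_count_dist`, `moiety_count_dist`.
#' @export
summarize_sites <- function(sites, meta = NULL, config = mg_config()) {
  if (!length(sites)) {
    return(list(n_sites = 0L, class_census = table(character()),
                type_census = table(character()),
                cn_by_resolution = table(character(), character()),
                inner_rna_count_dist = table(integer()),
                moiety_count_dist = table(integer())))
  }
  cls <- vapply(sites, function(s) {
    cl <- s$class
    if (is.null(cl) || is.na(cl)) "unbound" else cl
  }, character(1))
  tps <- vapply(sites, function(s)
    if (is.null(s$type)) NA_character_ else s$type$name, character(1))
  cn <- vapply(sites, function(s) s$inner$cn, integer(1))
  inner_rna <- vapply(sites, function(s)
    sum(s$inner$ligands$class %in% RNA_LIGAND_CLASSES, na.rm = TRUE),
    integer(1))
  nmo <- vapply(sites, function(s) nrow(s$moieties), integer(1))
  resn <- rep(NA_real_, length(sites))
  if (!is.null(meta)) {
    sid <- vapply(sites, `[[`, character(1), "structure_id")
    resn <- meta$resolution[match(sid, meta$structure_id)]
  }
  bin <- cut(resn, breaks = config$resolution_bins)
  list(n_sites = length(sites),
       class_census = table(class = cls, useNA = "ifany"),
       type_census = table(type = tps[!is.na(tps)]),
       cn_by_resolution = table(cn = cn, resolution = bin, useNA = "ifany"),
       inner_rna_count_dist = table(inner_rna_ligands = inner_rna),
       moiety_count_dist = table(outer_moieties = nmo))
}
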