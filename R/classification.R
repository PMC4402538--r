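# the four mutually exclusive site classes and hierarchical site typing

BULLET <- "•"
RNA_LIGAND_CLASSES <- c("O_ph", "O_r", "O_b", "N_b")

#' Assign the site class
#'
#' Four mutually exclusive classes, first match wins:
#' `metal_within_4A` (another metal atom within 4 A, symmetry included),
#' `non_rna_inner` (a non-RNA, non-water inner-sphere ligand),
#' `rna_inner` (at least one RNA inner-sphere ligand),
#' `rna_outer` (water-only inner sphere with at least one outer-sphere
#' RNA moiety). Sites bound to neither RNA sphere are not RNA-bound and
#' return `NA`.
#'
#' @param model an `mg_structure`.
#' @param inner the site's `mg_inner`.
#' @param moieties the site's moiety table from [assign_moieties()].
#' @param config a [mg_config()] list.
#' @return one of the four class labels, or `NA_character_`.
#' @export
assign_class <- function(model, inner, moieties, config = mg_config()) {
  near <- neighbor_search(model, inner$mg, 4.0,
                          use_symmetry = config$use_symmetry &&
                            !is.null(model$cell))
  if (any(near$is_metal)) return("metal_within_4A")
  lg <- inner$ligands
  non_rna <- lg$class %in% c("other_O", "other_N")
  if (any(non_rna)) return("non_rna_inner")
  if (any(lg$class %in% RNA_LIGAND_CLASSES)) return("rna_inner")
  if (nrow(moieties) > 0) return("rna_outer")
  NA_character_
}

#' Type an RNA-inner site
#'
#' Builds the canonical site-type name from the inner-sphere composition:
#' the number of phosphate oxygens (with the cis/trans/fac/mer prefix
#' when 2-4 O_ph are present), then O_r, O_b and N_b tokens with
#' multiplicities, joined by a bullet. The most populated branch
#' (one O_ph, no other RNA ligand) is subdivided by the number of
#' outer-sphere phosphate moieties, encoded as a `(+nP_out)` suffix.
#'
#' @param inner the site's `mg_inner` (class must be `rna_inner`).
#' @param moieties the site's moiety table.
#' @return a `mg_site_type` list: `sphere = "inner"`, `name`, `counts`
#'   (named O_ph/O_r/O_b/N_b), `prefix`, `n_pout` (only for the
#'   subdivided branch).
#' @export
type_rna_inner <- function(inner, moieties = empty_moieties()) {
  lg <- inner$ligands
  counts <- vapply(RNA_LIGAND_CLASSES,
                   function(k) sum(lg$class == k, na.rm = TRUE), integer(1))
  if (sum(counts) == 0) stop("site has no RNA inner-sphere ligand; not rna_inner")
  prefix <- if (counts["O_ph"] >= 2) inner$isomerism else NA_character_
  toks <- character()
  for (k in RNA_LIGAND_CLASSES) {
    if (counts[k] > 0)
      toks <- c(toks, paste0(if (counts[k] > 1) counts[k] else "", k))
  }
  name <- paste(toks, collapse = BULLET)
  if (!is.na(prefix)) name <- paste0(prefix, "-", name)
  n_pout <- NA_integer_
  if (counts["O_ph"] == 1 && sum(counts[c("O_r", "O_b", "N_b")]) == 0) {
    n_pout <- sum(moieties$kind == "P_out")
    name <- paste0(name, "(+", n_pout, "P_out)")
  }
  structure(list(sphere = "inner", name = name, counts = counts,
                 prefix = prefix, n_pout = n_pout), class = "mg_site_type")
}

#' Type an RNA-outer site
#'
#' Name from the moiety census (#P_out, #R_out, #B_out) as tokens with
#' multiplicities joined by a bullet, e.g. `"2P_out•2B_out"`.
#'
#' @param moieties the site's moiety table (class must be `rna_outer`).
#' @return a `mg_site_type` list: `sphere = "outer"`, `name`, `counts`
#'   (named P_out/R_out/B_out).
#' @export
type_rna_outer <- function(moieties) {
  kinds <- c("P_out", "R_out", "B_out")
  counts <- vapply(kinds, function(k) sum(moieties$kind == k), integer(1))
  if (sum(counts) == 0) stop("site has no outer-sphere moiety; not rna_outer")
  toks <- character()
  for (k in kinds) {
    if (counts[k] > 0)
      toks <- c(toks, paste0(if (counts[k] > 1) counts[k] else "", k))
  }
  structure(list(sphere = "outer", name = paste(toks, collapse = BULLET),
                 counts = counts, prefix = NA_character_,
                 n_pout = NA_integer_), class = "mg_site_type")
}

#' @export
print.mg_site_type <- function(x, ...) {
  cat("site type (", x$sphere, "): ", x$name, "\n", sep = "")
  invisible(x)
}

#' Parse a site-type name
#'
#' Inverse of [type_rna_inner()] / [type_rna_outer()]: recovers the
#' sphere, counts, isomer prefix and outer-phosphate subdivision from a
#' canonical name. Round-trips exactly with the typing functions.
#'
#' @param name canonical type name, e.g. `"cis-2O_ph"` or
#'   `"2P_out•2B_out"`.
#' @return a `mg_site_type` list.
#' @export
#' @examples
#' parse_type_name("cis-2O_ph")$counts
parse_type_name <- function(name) {
  stopifnot(is.character(name), length(name) == 1, nzchar(name))
  orig <- name
  prefix <- NA_character_
  m <- regmatches(name, regexec("^(cis|trans|fac|mer)-", name))[[1]]
  if (length(m)) {
    prefix <- m[2]
    name <- sub("^(cis|trans|fac|mer)-", "", name)
  }
  n_pout <- NA_integer_
  m <- regmatches(name, regexec("\\(\\+(\\d+)P_out\\)$", name))[[1]]
  if (length(m)) {
    n_pout <- as.integer(m[2])
    name <- sub("\\(\\+\\d+P_out\\)$", "", name)
  }
  toks <- strsplit(name, BULLET, fixed = TRUE)[[1]]
  inner_kinds <- RNA_LIGAND_CLASSES
  outer_kinds <- c("P_out", "R_out", "B_out")
  pat <- "^(\\d*)(O_ph|O_r|O_b|N_b|P_out|R_out|B_out)$"
  kinds <- character(length(toks)); mult <- integer(length(toks))
  for (i in seq_along(toks)) {
    m <- regmatches(toks[i], regexec(pat, toks[i]))[[1]]
    if (!length(m)) stop("malformed site-type name: ", orig)
    mult[i] <- if (nzchar(m[2])) as.integer(m[2]) else 1L
    kinds[i] <- m[3]
  }
  if (anyDuplicated(kinds)) stop("malformed site-type name: ", orig)
  if (any(mult == 1 & grepl("^1", toks))) stop("malformed site-type name: ", orig)
  sphere <- if (all(kinds %in% inner_kinds)) "inner"
            else if (all(kinds %in% outer_kinds)) "outer"
            else stop("malformed site-type name (mixed spheres): ", orig)
  if (sphere == "outer" && (!is.na(prefix) || !is.na(n_pout)))
    stop("malformed site-type name: ", orig)
  all_kinds <- if (sphere == "inner") inner_kinds else outer_kinds
  counts <- setNames(integer(length(all_kinds)), all_kinds)
  counts[kinds] <- mult
  # token order must be canonical
  if (!identical(kinds, all_kinds[all_kinds %in% kinds]))
    stop("malformed site-type name (token order): ", orig)
  if (sphere == "inner") {
    if (!is.na(prefix) && counts["O_ph"] < 2)
      stop("malformed site-type name (prefix without 2-4 O_ph): ", orig)
    if (!is.na(n_pout) &&
        !(counts["O_ph"] == 1 && sum(counts[c("O_r", "O_b", "N_b")]) == 0))
      stop("malformed site-type name (subdivision outside its branch): ", orig)
  }
  structure(list(sphere = sphere, name = orig, counts = counts,
                 prefix = prefix, n_pout = n_pout), class = "mg_site_type")
}
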