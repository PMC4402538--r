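# run configuration: every tunable constant of the analysis in one place

#' Analysis configuration
#'
#' Collects every numeric constant of the pipeline. Defaults are the
#' values used throughout the method: ideal Mg-O / Mg-N distances from
#' small-molecule surveys, the two-step search margins, the step-2 angle
#' rule, the trans/mer angle, bond-valence parameters, the hydrogen-bond
#' window, quality thresholds, and the benchmark CN range.
#'
#' @param d_ideal_O,d_ideal_N ideal Mg-ligand distances (Angstrom).
#' @param step1_margin,step2_margin distance margins added to the ideal
#'   distance for search steps 1 and 2 (Angstrom).
#' @param step2_angle_min minimum ligand-Mg-ligand angle (degrees) a
#'   step-2 candidate must make with every already-accepted ligand.
#' @param trans_angle ligand-Mg-ligand angle (degrees) above which an
#'   O_ph pair counts as trans (trans/mer isomer assignment).
#' @param bv bond-valence parameters: `r0_O`, `r0_N`, `b` (Angstrom),
#'   used in V(d) = exp((r0 - d)/b). Replaceable with a custom table-backed
#'   parameterization via `r0_O`/`r0_N`.
#' @param qe_radius environment radius for Qe (Angstrom).
#' @param hbond_min,hbond_max heavy-atom hydrogen-bond distance window
#'   (Angstrom).
#' @param hbond_angle_min minimum Mg-Owater-acceptor angle (degrees).
#' @param qv_min,qs_min,qe_min benchmark quality thresholds.
#' @param cn_range benchmark coordination-number range (inclusive).
#' @param linkage_max O3'-P distance (Angstrom) counting as a
#'   phosphodiester linkage.
#' @param bond_PO_max P-O distance (Angstrom) counting as a covalent bond
#'   when identifying an oxygen's phosphate group.
#' @param use_symmetry include crystallographic symmetry in all searches.
#' @param resolution_bins breakpoints (Angstrom) for resolution-binned
#'   summaries.
#' @param ribosome_keywords case-insensitive keywords tagging ribosome
#'   structures.
#' @param fatom_background background census convention for normalized
#'   interaction frequencies: `"ligand_capable"` (atoms of the four RNA
#'   ligand classes) or `"all_rna_atoms"`.
#' @param seed integer seed for any stochastic helper (fixture jitter).
#' @return a named list of class `mg_config`.
#' @export
mg_config <- function(d_ideal_O = 2.08, d_ideal_N = 2.20,
                      step1_margin = 0.5, step2_margin = 1.0,
                      step2_angle_min = 50, trans_angle = 135,
                      bv = list(r0_O = 1.693, r0_N = 1.85, b = 0.37),
                      qe_radius = 4.0,
                      hbond_min = 2.4, hbond_max = 3.5, hbond_angle_min = 90,
                      qv_min = 0.5, qs_min = 0.6, qe_min = 0.5,
                      cn_range = c(4L, 6L),
                      linkage_max = 2.0, bond_PO_max = 1.9,
                      use_symmetry = TRUE,
                      resolution_bins = c(-Inf, 1.5, 2.0, 2.4, 2.9, 3.7, Inf),
                      ribosome_keywords = "ribosom",
                      fatom_background = c("ligand_capable", "all_rna_atoms"),
                      seed = 1L) {
  structure(list(
    d_ideal_O = d_ideal_O, d_ideal_N = d_ideal_N,
    step1_margin = step1_margin, step2_margin = step2_margin,
    step2_angle_min = step2_angle_min, trans_angle = trans_angle,
    bv = bv, qe_radius = qe_radius,
    hbond_min = hbond_min, hbond_max = hbond_max,
    hbond_angle_min = hbond_angle_min,
    qv_min = qv_min, qs_min = qs_min, qe_min = qe_min,
    cn_range = as.integer(cn_range),
    linkage_max = linkage_max, bond_PO_max = bond_PO_max,
    use_symmetry = use_symmetry, resolution_bins = resolution_bins,
    ribosome_keywords = ribosome_keywords,
    fatom_background = match.arg(fatom_background),
    seed = as.integer(seed)
  ), class = "mg_config")
}

#' Serialize / restore a configuration
#'
#' Configurations round-trip through JSON so a run's parameters can be
#' archived alongside its report.
#' @param config a [mg_config()] list.
#' @param path file path.
#' @return `read_config` returns an `mg_config`; `write_config` returns
#'   `path` invisibly.
#' @export
write_config <- function(config, path) {
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  x$fatom_background <- match.arg(x$fatom_background,
                                  c("ligand_capable", "all_rna_atoms"))
  do.call(mg_config, x[setdiff(names(x), character())])
}

# short stable hash of a configuration, embedded in reports
config_hash <- function(config) {
  s <- jsonlite::toJSON(unclass(config), auto_unbox = TRUE, digits = 10)
  # small polynomial rolling hash over the serialized text; factors kept
  # below 2^53 so double arithmetic stays exact
  h <- 0
  for (b in utf8ToInt(s)) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", h)
}
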