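# bond valence and the three site-quality parameters

#' Bond valence of a Mg-ligand contact
#'
#' Exponential bond-valence form V(d) = exp((r0 - d)/b) with standard
#' Mg parameters (r0 = 1.693 A for Mg-O, 1.85 A for Mg-N, b = 0.37 A).
#' Elements other than nitrogen use the oxygen parameterization. The
#' parameters live in `config$bv` so an alternative distance-valence
#' table can be dropped in.
#'
#' @param d distance(s) in Angstrom.
#' @param elesy element symbol(s), same length as `d` (or length 1).
#' @param bv list with `r0_O`, `r0_N`, `b`.
#' @return numeric vector of valences (dimensionless, > 0).
#' @export
#' @examples
#' bond_valence(2.08, "O")  # about 0.351
bond_valence <- function(d, elesy = "O", bv = mg_config()$bv) {
  elesy <- rep_len(toupper(elesy), length(d))
  r0 <- ifelse(elesy == "N", bv$r0_N, bv$r0_O)
  exp((r0 - d) / bv$b)
}

#' Valence-sum quality Qv
#'
#' Agreement of the inner-sphere bond-valence sum with the +2 oxidation
#' state of magnesium: Qv = 1 - |sum(V_i) - 2| / 2, clamped to [0, 1].
#' All inner-sphere ligands (waters included) contribute.
#'
#' @param inner an `mg_inner` from [find_inner_sphere()].
#' @param bv bond-valence parameters (see [bond_valence()]).
#' @return Qv in [0, 1].
#' @export
q_v <- function(inner, bv = mg_config()$bv) {
  if (inner$cn < 1) stop("q_v undefined for an empty inner sphere")
  v <- bond_valence(inner$ligands$distance, inner$ligands$elesy, bv)
  max(0, min(1, 1 - abs(sum(v) - 2) / 2))
}

#' Ligand-symmetry quality Qs
#'
#' Amplitude of the vector sum of bond-valence vectors, complemented so
#' that a perfectly symmetric (e.g. octahedral) ligand arrangement scores
#' 1: Qs = 1 - |sum(V_i u_i)| / sum(V_i), with u_i the unit vector from
#' Mg to ligand i.
#'
#' @inheritParams q_v
#' @return Qs in [0, 1]; a single ligand gives exactly 0.
#' @export
q_s <- function(inner, bv = mg_config()$bv) {
  if (inner$cn < 1) stop("q_s undefined for an empty inner sphere")
  lg <- inner$ligands
  v <- bond_valence(lg$distance, lg$elesy, bv)
  s <- c(sum(v * lg$ux), sum(v * lg$uy), sum(v * lg$uz))
  max(0, min(1, 1 - vnorm(s) / sum(v)))
}

#' Environment quality Qe
#'
#' Agreement of the magnesium B-factor (B_m) and occupancy (O_m) with a
#' valence-weighted average over all non-hydrogen atoms within
#' `config$qe_radius` (4 A), symmetry mates included:
#' B_e = sum(V_i B_i)/sum(V_i) and O_e = sum(V_i O_i)/sum(V_i), with
#' weights from the bond-valence form at each neighbor's distance
#' (non-O/N neighbors use the oxygen parameterization). The score is
#' min(O_m, O_e) * min((B_m/O_m)/(B_e/O_e), (B_e/O_e)/(B_m/O_m)), which
#' reduces to min(B_m, B_e)/max(B_m, B_e) at full occupancy.
#'
#' @param model an `mg_structure`.
#' @param mg magnesium atom index.
#' @param config a [mg_config()] list.
#' @return a list with `q_e`, `b_m`, `b_env`, `o_m`, `occ_env`; `q_e` is
#'   0 (with a warning) when the 4 A environment is empty.
#' @export
q_e <- function(model, mg, config = mg_config()) {
  at <- model$atoms
  env <- neighbor_search(model, mg, config$qe_radius,
                         use_symmetry = config$use_symmetry &&
                           !is.null(model$cell))
  b_m <- at$b[mg]; o_m <- at$o[mg]
  if (nrow(env) == 0) {
    warning("empty ", config$qe_radius, " A environment around Mg atom ", mg,
            call. = FALSE)
    return(list(q_e = 0, b_m = b_m, b_env = NA_real_, o_m = o_m,
                occ_env = NA_real_))
  }
  w <- bond_valence(env$distance, env$elesy, config$bv)
  b_e <- sum(w * at$b[env$atom]) / sum(w)
  o_e <- sum(w * at$o[env$atom]) / sum(w)
  rm_ <- if (o_m > 0) b_m / o_m else Inf
  re_ <- if (o_e > 0) b_e / o_e else Inf
  ratio <- if (rm_ == 0 && re_ == 0) 1
           else if (rm_ == 0 || re_ == 0 || !is.finite(rm_) || !is.finite(re_)) 0
           else min(rm_ / re_, re_ / rm_)
  list(q_e = max(0, min(1, min(o_m, o_e) * ratio)),
       b_m = b_m, b_env = b_e, o_m = o_m, occ_env = o_e)
}

#' All three quality scores for a site
#'
#' @param model an `mg_structure`.
#' @param inner an `mg_inner`.
#' @param config a [mg_config()] list.
#' @return list with `q_v`, `q_s`, `q_e`, `valence_sum`, `b_m`, `b_env`,
#'   `o_m`, `occ_env`. `q_v`/`q_s` are `NA` for an empty inner sphere
#'   (the site fails validation upstream).
#' @export
site_quality <- function(model, inner, config = mg_config()) {
  qe <- q_e(model, inner$mg, config)
  if (inner$cn >= 1) {
    vs <- sum(bond_valence(inner$ligands$distance, inner$ligands$elesy,
                           config$bv))
    qv <- q_v(inner, config$bv)
    qs <- q_s(inner, config$bv)
  } else {
    vs <- 0; qv <- NA_real_; qs <- NA_real_
  }
  c(list(q_v = qv, q_s = qs), qe["q_e"], list(valence_sum = vs),
    qe[c("b_m", "b_env", "o_m", "occ_env")])
}

#' Benchmark filter
#'
#' Accepts a fully processed site into the benchmark set only if (i) it
#' is RNA-bound through the inner or outer sphere, (ii) CN is within
#' `config$cn_range` (4-6), (iii) Qv, Qs and Qe meet their thresholds
#' (0.5 / 0.6 / 0.5), and (iv) no inner-sphere nucleobase nitrogen other
#' than an in-plane lone-pair nitrogen (-N=) is present. Rejections list
#' every failed criterion.
#'
#' @param site an `mg_site` from [analyze_structure()].
#' @param config a [mg_config()] list.
#' @return list with `accept` (logical) and `reasons` (character vector,
#'   empty when accepted).
#' @export
benchmark_filter <- function(site, config = mg_config()) {
  reasons <- character()
  lg <- site$inner$ligands
  rna_classes <- c("O_ph", "O_r", "O_b", "N_b")
  rna_bound <- any(lg$class %in% rna_classes) || nrow(site$moieties) > 0
  if (!rna_bound) reasons <- c(reasons, "not_rna_bound")
  if (site$inner$cn < config$cn_range[1] || site$inner$cn > config$cn_range[2])
    reasons <- c(reasons, "cn_out_of_range")
  q <- site$scores
  if (is.na(q$q_v) || q$q_v < config$qv_min) reasons <- c(reasons, "qv_below_threshold")
  if (is.na(q$q_s) || q$q_s < config$qs_min) reasons <- c(reasons, "qs_below_threshold")
  if (is.na(q$q_e) || q$q_e < config$qe_min) reasons <- c(reasons, "qe_below_threshold")
  bad_n <- lg$class == "N_b" & !lg$lone_pair
  if (any(bad_n)) reasons <- c(reasons, "non_lone_pair_base_nitrogen")
  list(accept = length(reasons) == 0, reasons = reasons)
}
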