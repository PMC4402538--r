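# the seven representative sites used by the worked-example checks:
# structure id, chain, Mg residue number, expected Qv/Qs/Qe (one decimal)
# and the motif expected at that site
figure6_sites <- function() {
  data.frame(
    id = c("2Z75", "2YIE", "2AVY", "2QBA", "3V29", "2AW7", "3V23"),
    chain = c("B", "Z", "A", "B", "A", "A", "A"),
    resno = c(301, 1116, 1566, 3321, 3359, 1569, 3540),
    qv = c(0.8, 0.7, 1.0, 1.0, 0.8, 1.0, 0.6),
    qs = c(0.9, 0.8, 1.0, 0.9, 0.9, 1.0, 0.9),
    qe = c(0.9, 1.0, 1.0, 0.9, 0.8, 0.5, 0.9),
    motif = c("A", "B", "C", "D", "E", "F", "G"),
    stringsAsFactors = FALSE)
}

# locate a PDB entry: local cache directory first, then the wwPDB mirror
fetch_entry <- function(id, cache = testthat::test_path("pdb_cache")) {
  for (ext in c(".pdb", ".ent", ".cif")) {
    f <- file.path(cache, paste0(tolower(id), ext))
    if (file.exists(f)) return(f)
    f <- file.path(cache, paste0(toupper(id), ext))
    if (file.exists(f)) return(f)
  }
  dl <- file.path(tempdir(), paste0(tolower(id), ".pdb"))
  if (file.exists(dl) && file.size(dl) > 1000) return(dl)
  url <- paste0("https://files.rcsb.org/download/", toupper(id), ".pdb")
  ok <- tryCatch({
    utils::download.file(url, dl, quiet = TRUE, mode = "wb")
    TRUE
  }, error = function(e) FALSE, warning = function(w) FALSE)
  if (!ok || !file.exists(dl) || file.size(dl) < 1000)
    stop("entry ", id, " unavailable: not in the local cache (",
         cache, ") and not downloadable", call. = FALSE)
  dl
}

# analyze a single magnesium site of a (possibly large) structure
analyze_one_site <- function(model, chain, resno, config = mg_config()) {
  at <- model$atoms
  mg <- which(at$elesy == "MG" & at$chain == chain & at$resno == resno)
  if (!length(mg)) stop("no Mg ", chain, resno, " in ", model$id)
  mg <- mg[1]
  inner <- find_inner_sphere(model, mg, config)
  scores <- site_quality(model, inner, config)
  hbonds <- find_water_rna_hbonds(model, inner, config)
  moieties <- assign_moieties(hbonds, inner, model, config)
  cls <- assign_class(model, inner, moieties, config)
  site <- structure(list(structure_id = model$id, mg = mg,
                         mg_id = paste0(chain, resno), inner = inner,
                         scores = scores, hbonds = hbonds,
                         moieties = moieties, class = cls, type = NULL,
                         motifs = NULL, benchmark = NULL),
                    class = "mg_site")
  if (!is.na(cls) && cls == "rna_inner")
    site$type <- type_rna_inner(inner, moieties)
  if (!is.na(cls) && cls == "rna_outer")
    site$type <- type_rna_outer(moieties)
  site$motifs <- detect_motifs(site)
  site$benchmark <- benchmark_filter(site, config)
  site
}
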