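# small shared helpers (geometry, keys, formatting)

vnorm <- function(v) sqrt(sum(v^2))

unitv <- function(v) {
  n <- vnorm(v)
  if (n < 1e-12) stop("cannot normalize zero vector")
  v / n
}

#' Angle at a vertex in degrees
#'
#' Angle a-b-c (vertex at b) between two points seen from `b`.
#' @param a,b,c numeric xyz triples.
#' @return angle in degrees in [0, 180].
#' @keywords internal
vertex_angle <- function(a, b, c) {
  u <- a - b
  v <- c - b
  cosang <- sum(u * v) / (vnorm(u) * vnorm(v))
  acos(max(-1, min(1, cosang))) * 180 / pi
}

# angle between two direction vectors (degrees)
dir_angle <- function(u, v) {
  cosang <- sum(u * v) / (vnorm(u) * vnorm(v))
  acos(max(-1, min(1, cosang))) * 180 / pi
}

# residue key: one string per (chain, resno, insert) identity
res_key <- function(chain, resno, insert = "") {
  insert[is.na(insert)] <- ""
  paste(chain, resno, insert, sep = "|")
}

# symmetry-image key: identifies the physical copy an atom was reached in
sym_key <- function(sym_op, s1, s2, s3) {
  ifelse(sym_op == 1L & s1 == 0L & s2 == 0L & s3 == 0L, "",
         paste(sym_op, s1, s2, s3, sep = ","))
}

# effective chain id: symmetry copies of a chain are distinct molecules
eff_chain <- function(chain, sym) ifelse(sym == "", chain, paste0(chain, "@", sym))

`%||%` <- function(x, y) if (is.null(x)) y else x

# deterministic ordering used whenever ties in distance must be broken
order_contacts <- function(df) {
  order(df$distance, df$chain, df$resno, df$elety, df$sym_op, df$s1, df$s2, df$s3)
}
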