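# unit cells, space-group operators and the fractional/orthogonal transforms

#' Construct a unit cell with symmetry operators
#'
#' Builds the cell description used by [neighbor_search()]. Operators are
#' stored in fractional coordinates as (R, t) pairs; the identity operator
#' is always first. When `ops` is `NULL` the Hermann-Mauguin symbol is
#' looked up in a built-in table of common RNA space groups; an unknown
#' symbol falls back to the identity with a warning (symmetry then reduces
#' to pure lattice translations).
#'
#' @param a,b,c cell lengths in Angstrom (must be > 0).
#' @param alpha,beta,gamma cell angles in degrees, each in (0, 180).
#' @param spacegroup Hermann-Mauguin symbol, e.g. `"P 21 21 21"`.
#' @param ops optional list of operators, each `list(R = 3x3, t = length-3)`
#'   in fractional coordinates; overrides the symbol lookup.
#' @return an object of class `mg_cell`.
#' @export
#' @examples
#' cl <- unit_cell(20, 20, 20, 90, 90, 90, "P 1")
#' length(cl$ops)
unit_cell <- function(a, b, c, alpha = 90, beta = 90, gamma = 90,
                      spacegroup = "P 1", ops = NULL) {
  stopifnot(a > 0, b > 0, c > 0,
            alpha > 0, alpha < 180, beta > 0, beta < 180,
            gamma > 0, gamma < 180)
  mats <- cell_matrices(a, b, c, alpha, beta, gamma)
  if (is.null(ops)) {
    xyz <- spacegroup_xyz(spacegroup)
    if (is.null(xyz)) {
      warning("unknown space group '", spacegroup,
              "'; using identity operator only", call. = FALSE)
      xyz <- "x,y,z"
    }
    ops <- lapply(xyz, parse_symop)
  }
  # identity must be present and first
  is_ident <- vapply(ops, function(o) {
    max(abs(o$R - diag(3))) < 1e-8 && max(abs(o$t %% 1)) < 1e-8
  }, logical(1))
  if (!any(is_ident)) {
    ops <- c(list(list(R = diag(3), t = c(0, 0, 0))), ops)
  } else {
    ops <- c(ops[which(is_ident)[1]], ops[!seq_along(ops) %in% which(is_ident)[1]])
  }
  structure(list(a = a, b = b, c = c,
                 alpha = alpha, beta = beta, gamma = gamma,
                 spacegroup = spacegroup, ops = ops,
                 orth = mats$orth, frac = mats$frac),
            class = "mg_cell")
}

# orthogonalization (frac -> cart) and fractionalization matrices,
# PDB convention: a along x, b in the xy plane
cell_matrices <- function(a, b, c, alpha, beta, gamma) {
  ca <- cos(alpha * pi / 180); cb <- cos(beta * pi / 180)
  cg <- cos(gamma * pi / 180); sg <- sin(gamma * pi / 180)
  v <- sqrt(max(0, 1 - ca^2 - cb^2 - cg^2 + 2 * ca * cb * cg))
  M <- matrix(c(a, b * cg, c * cb,
                0, b * sg, c * (ca - cb * cg) / sg,
                0, 0, c * v / sg), nrow = 3, byrow = TRUE)
  list(orth = M, frac = solve(M))
}

#' Parse a symmetry operator in xyz notation
#'
#' Converts strings such as `"-x+1/2,-y,z+1/2"` into a fractional rotation
#' matrix and translation vector.
#'
#' @param s operator string with three comma-separated terms.
#' @return `list(R = 3x3 matrix, t = numeric(3))`.
#' @export
parse_symop <- function(s) {
  parts <- strsplit(gsub("[[:space:]]", "", tolower(s)), ",")[[1]]
  if (length(parts) != 3) stop("malformed symmetry operator: ", s)
  R <- matrix(0, 3, 3)
  t <- numeric(3)
  for (i in 1:3) {
    expr <- parts[i]
    # tokenize into signed terms
    toks <- regmatches(expr, gregexpr("[+-]?[^+-]+", expr))[[1]]
    for (tok in toks) {
      sign <- if (startsWith(tok, "-")) -1 else 1
      body <- sub("^[+-]", "", tok)
      if (body %in% c("x", "y", "z")) {
        R[i, match(body, c("x", "y", "z"))] <- sign
      } else if (grepl("^\\d+/\\d+$", body)) {
        nm <- as.numeric(strsplit(body, "/")[[1]])
        t[i] <- t[i] + sign * nm[1] / nm[2]
      } else if (grepl("^\\d*\\.?\\d+$", body)) {
        t[i] <- t[i] + sign * as.numeric(body)
      } else {
        stop("cannot parse symmetry term '", tok, "' in: ", s)
      }
    }
  }
  list(R = R, t = t)
}

# built-in operator table for common RNA crystal space groups; PDB entries
# additionally carry REMARK 290, which takes precedence when parsed
spacegroup_xyz <- function(symbol) {
  key <- toupper(gsub("[[:space:]]+", " ", trimws(symbol)))
  tbl <- list(
    "P 1" = c("x,y,z"),
    "P 1 2 1" = c("x,y,z", "-x,y,-z"),
    "P 2" = c("x,y,z", "-x,y,-z"),
    "P 1 21 1" = c("x,y,z", "-x,y+1/2,-z"),
    "P 21" = c("x,y,z", "-x,y+1/2,-z"),
    "C 1 2 1" = c("x,y,z", "-x,y,-z", "x+1/2,y+1/2,z", "-x+1/2,y+1/2,-z"),
    "C 2" = c("x,y,z", "-x,y,-z", "x+1/2,y+1/2,z", "-x+1/2,y+1/2,-z"),
    "P 2 2 2" = c("x,y,z", "-x,-y,z", "-x,y,-z", "x,-y,-z"),
    "P 21 21 2" = c("x,y,z", "-x,-y,z", "x+1/2,-y+1/2,-z", "-x+1/2,y+1/2,-z"),
    "P 21 21 21" = c("x,y,z", "x+1/2,-y+1/2,-z", "-x,y+1/2,-z+1/2",
                     "-x+1/2,-y,z+1/2"),
    "I 2 2 2" = c("x,y,z", "-x,-y,z", "-x,y,-z", "x,-y,-z",
                  "x+1/2,y+1/2,z+1/2", "-x+1/2,-y+1/2,z+1/2",
                  "-x+1/2,y+1/2,-z+1/2", "x+1/2,-y+1/2,-z+1/2")
  )
  tbl[[key]]
}

# parse REMARK 290 SMTRY records (operators in orthogonal Angstrom frame)
# into fractional (R, t) pairs; returns NULL when none present
parse_remark290 <- function(lines, mats) {
  sm <- grep("^REMARK 290\\s+SMTRY[123]", lines, value = TRUE)
  if (length(sm) == 0) return(NULL)
  rows <- lapply(sm, function(l) {
    f <- strsplit(trimws(sub("^REMARK 290\\s+", "", l)), "\\s+")[[1]]
    # SMTRYn  opno  r1 r2 r3  t
    list(row = as.integer(substring(f[1], 6, 6)), op = as.integer(f[2]),
         r = as.numeric(f[3:5]), t = as.numeric(f[6]))
  })
  opnos <- sort(unique(vapply(rows, `[[`, integer(1), "op")))
  ops <- lapply(opnos, function(k) {
    Rc <- matrix(0, 3, 3); tc <- numeric(3)
    for (r in rows) {
      if (r$op == k) { Rc[r$row, ] <- r$r; tc[r$row] <- r$t }
    }
    # convert Cartesian-frame operator to fractional frame
    Rf <- mats$frac %*% Rc %*% mats$orth
    tf <- as.numeric(mats$frac %*% tc)
    list(R = round(Rf, 10), t = round(tf, 10))
  })
  ops
}
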