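# independent oracles and small model builders used across the suite

# brute-force symmetry neighbor search: explicitly generates every
# symmetry copy in a block of cells and measures distances directly
brute_neighbors <- function(model, center_xyz, radius, block = 2) {
  at <- model$atoms
  cell <- model$cell
  X <- cbind(at$x, at$y, at$z)
  hits <- list()
  if (is.null(cell)) {
    d <- sqrt(rowSums(sweep(X, 2, center_xyz)^2))
    keep <- which(d <= radius & d > 1e-6)
    return(data.frame(atom = keep, distance = d[keep]))
  }
  Fa <- X %*% t(cell$frac)
  for (oi in seq_along(cell$ops)) {
    op <- cell$ops[[oi]]
    Ft <- sweep(Fa %*% t(op$R), 2, op$t, "+")
    for (s1 in -block:block) for (s2 in -block:block) for (s3 in -block:block) {
      Fs <- sweep(Ft, 2, c(s1, s2, s3), "+")
      P <- Fs %*% t(cell$orth)
      d <- sqrt(rowSums(sweep(P, 2, center_xyz)^2))
      keep <- which(d <= radius & d > 1e-6)
      if (length(keep))
        hits[[length(hits) + 1]] <- data.frame(atom = keep, distance = d[keep],
                                               px = P[keep, 1], py = P[keep, 2],
                                               pz = P[keep, 3])
    }
  }
  if (!length(hits)) return(data.frame(atom = integer(), distance = numeric()))
  out <- do.call(rbind, hits)
  # duplicates from special positions: one copy per physical position
  key <- paste(out$atom, round(out$px, 3), round(out$py, 3), round(out$pz, 3))
  out <- out[!duplicated(key), c("atom", "distance")]
  out[order(out$distance, out$atom), ]
}

# independent two-step inner-sphere oracle: step 1 by thresholds, then
# subset enumeration over step-2 candidates verified against the greedy
# rule semantics (candidate accepted iff rules hold against step-1 plus
# all earlier-accepted candidates, in ascending distance order)
oracle_inner <- function(model, mg, config = mg_config()) {
  at <- model$atoms
  mgp <- c(at$x[mg], at$y[mg], at$z[mg])
  don <- which(at$elesy %in% c("O", "N"))
  don <- setdiff(don, mg)
  d <- sqrt((at$x[don] - mgp[1])^2 + (at$y[don] - mgp[2])^2 +
              (at$z[don] - mgp[3])^2)
  lim1 <- ifelse(at$elesy[don] == "O", config$d_ideal_O, config$d_ideal_N) +
    config$step1_margin
  lim2 <- ifelse(at$elesy[don] == "O", config$d_ideal_O, config$d_ideal_N) +
    config$step2_margin
  step1 <- don[d <= lim1]
  cand <- don[d > lim1 & d <= lim2]
  cand <- cand[order(d[match(cand, don)])]
  if (length(step1) >= 6 || !length(cand)) return(sort(step1))

  posv <- function(i) c(at$x[i], at$y[i], at$z[i]) - mgp
  angdeg <- function(i, j) {
    u <- posv(i); v <- posv(j)
    acos(max(-1, min(1, sum(u * v) / sqrt(sum(u^2) * sum(v^2))))) * 180 / pi
  }
  bonded_P <- function(i) {
    ps <- which(at$elesy == "P")
    if (!length(ps)) return(NA_integer_)
    dd <- sqrt((at$x[ps] - at$x[i])^2 + (at$y[ps] - at$y[i])^2 +
                 (at$z[ps] - at$z[i])^2)
    if (min(dd) > config$bond_PO_max) NA_integer_ else ps[which.min(dd)]
  }
  rules_ok <- function(i, accepted) {
    if (at$elesy[i] == "N") {
      cls <- classify_atom(at$resid[i], at$elety[i], at$elesy[i])
      if (cls == "N_b" && !is_lone_pair_N(at$resid[i], at$elety[i]))
        return(FALSE)
    }
    if (at$elesy[i] == "O") {
      pg <- bonded_P(i)
      if (!is.na(pg)) {
        for (j in accepted[at$elesy[accepted] == "O"]) {
          pj <- bonded_P(j)
          if (!is.na(pj) && pj == pg) return(FALSE)
        }
      }
    }
    for (j in accepted) if (angdeg(i, j) <= config$step2_angle_min) return(FALSE)
    TRUE
  }
  nC <- length(cand)
  solution <- NULL
  for (mask in 0:(2^nC - 1)) {
    S <- cand[bitwAnd(mask, 2^(seq_len(nC) - 1)) > 0]
    consistent <- TRUE
    acc <- step1
    for (i in cand) {
      ok <- rules_ok(i, acc)
      inS <- i %in% S
      if (ok != inS) { consistent <- FALSE; break }
      if (inS) acc <- c(acc, i)
    }
    if (consistent) { solution <- S; break }
  }
  sort(c(step1, solution))
}

# bare model with an octahedral Mg site built directly in code
oct_model <- function(dists = rep(2.08, 6), kinds = rep("HOH", 6),
                      atoms = rep("O", 6), resnos = 501:506,
                      chains = rep("W", 6), bs = rep(20, 7), os = rep(1, 7),
                      mg_pos = c(0, 0, 0), extra = NULL) {
  dirs <- rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0),
                c(0, -1, 0), c(0, 0, 1), c(0, 0, -1))
  rows <- data.frame(elety = "MG", resid = "MG", chain = "M", resno = 900L,
                     x = mg_pos[1], y = mg_pos[2], z = mg_pos[3],
                     o = os[1], b = bs[1], elesy = "MG",
                     stringsAsFactors = FALSE)
  for (i in seq_along(dists)) {
    p <- mg_pos + dists[i] * dirs[i, ]
    rows <- rbind(rows, data.frame(
      elety = atoms[i], resid = kinds[i], chain = chains[i],
      resno = resnos[i], x = p[1], y = p[2], z = p[3],
      o = os[i + 1], b = bs[i + 1],
      elesy = toupper(substr(gsub("[^A-Za-z]", "", atoms[i]), 1, 1)),
      stringsAsFactors = FALSE))
  }
  if (!is.null(extra)) rows <- rbind(rows, extra)
  mg_structure(rows, cell = NULL, id = "inline")
}

# random rotation matrix (uniform via QR of a Gaussian matrix)
random_rotation <- function() {
  M <- matrix(stats::rnorm(9), 3, 3)
  qr_ <- qr(M)
  Q <- qr.Q(qr_)
  if (det(Q) < 0) Q[, 1] <- -Q[, 1]
  Q
}

# randomized inner-sphere test case generator (no unit cell); returns a
# model whose Mg is atom 1
random_inner_case <- function() {
  rows <- data.frame(elety = "MG", resid = "MG", chain = "M", resno = 900L,
                     x = 0, y = 0, z = 0, o = 1, b = 20, elesy = "MG",
                     stringsAsFactors = FALSE)
  rdir <- function() unitv2(stats::rnorm(3))
  n1 <- sample(0:5, 1)
  resno <- 500L
  for (i in seq_len(n1)) {
    resno <- resno + 1L
    p <- stats::runif(1, 1.9, 2.55) * rdir()
    rows <- rbind(rows, data.frame(elety = "O", resid = "HOH", chain = "W",
                                   resno = resno, x = p[1], y = p[2], z = p[3],
                                   o = 1, b = 20, elesy = "O"))
  }
  n2 <- sample(1:7, 1)
  i <- 0
  while (i < n2) {
    i <- i + 1
    resno <- resno + 1L
    kind <- sample(c("waterO", "oph", "oph_pair", "aminoN", "loneN"), 1)
    u <- rdir()
    if (kind == "waterO") {
      p <- stats::runif(1, 2.60, 3.05) * u
      rows <- rbind(rows, data.frame(elety = "O", resid = "HOH", chain = "W",
                                     resno = resno, x = p[1], y = p[2],
                                     z = p[3], o = 1, b = 20, elesy = "O"))
    } else if (kind == "oph") {
      p <- stats::runif(1, 2.60, 3.05) * u
      P <- p + 1.55 * u
      rows <- rbind(rows,
                    data.frame(elety = "OP1", resid = "G", chain = "B",
                               resno = resno, x = p[1], y = p[2], z = p[3],
                               o = 1, b = 20, elesy = "O"),
                    data.frame(elety = "P", resid = "G", chain = "B",
                               resno = resno, x = P[1], y = P[2], z = P[3],
                               o = 1, b = 20, elesy = "P"))
    } else if (kind == "oph_pair") {
      # OP1 and OP2 of one phosphate, both in the extended shell
      a <- stats::runif(1, 26, 35) * pi / 180
      v <- unitv2(stats::rnorm(3)); w <- unitv2(pracma_null(v))
      d1 <- stats::runif(1, 2.60, 3.0); d2 <- stats::runif(1, 2.60, 3.0)
      o1 <- d1 * (cos(a) * v + sin(a) * w)
      o2 <- d2 * (cos(a) * v - sin(a) * w)
      if (sqrt(sum((o1 - o2)^2)) > 2.9) next
      P <- (o1 + o2) / 2 + 0.8 * v
      if (sqrt(sum((P - o1)^2)) > 1.85 || sqrt(sum((P - o2)^2)) > 1.85) next
      rows <- rbind(rows,
                    data.frame(elety = "OP1", resid = "G", chain = "B",
                               resno = resno, x = o1[1], y = o1[2], z = o1[3],
                               o = 1, b = 20, elesy = "O"),
                    data.frame(elety = "OP2", resid = "G", chain = "B",
                               resno = resno, x = o2[1], y = o2[2], z = o2[3],
                               o = 1, b = 20, elesy = "O"),
                    data.frame(elety = "P", resid = "G", chain = "B",
                               resno = resno, x = P[1], y = P[2], z = P[3],
                               o = 1, b = 20, elesy = "P"))
      i <- i + 1
    } else if (kind == "aminoN") {
      p <- stats::runif(1, 2.75, 3.15) * u
      rows <- rbind(rows, data.frame(elety = "N6", resid = "A", chain = "B",
                                     resno = resno, x = p[1], y = p[2],
                                     z = p[3], o = 1, b = 20, elesy = "N"))
    } else {
      p <- stats::runif(1, 2.75, 3.15) * u
      rows <- rbind(rows, data.frame(elety = "N7", resid = "G", chain = "B",
                                     resno = resno, x = p[1], y = p[2],
                                     z = p[3], o = 1, b = 20, elesy = "N"))
    }
  }
  mg_structure(rows, cell = NULL, id = "rand_inner")
}

unitv2 <- function(v) v / sqrt(sum(v^2))

# rbind a short atom row onto a full-width model atom table
bind_atoms <- function(at, df) {
  for (cn in setdiff(names(at), names(df))) {
    df[[cn]] <- switch(cn, insert = "", alt = "", is_water = FALSE,
                       is_metal = FALSE, type = "ATOM", NA)
  }
  rbind(at, df[names(at)])
}
pracma_null <- function(v) {
  # any vector perpendicular to v
  ref <- if (abs(v[3]) < 0.9) c(0, 0, 1) else c(1, 0, 0)
  w <- c(v[2] * ref[3] - v[3] * ref[2],
         v[3] * ref[1] - v[1] * ref[3],
         v[1] * ref[2] - v[2] * ref[1])
  unitv2(w)
}

# random symmetry fixture for the neighbor-search oracle
random_sym_model <- function(spacegroup = "P 1", n = 40) {
  a <- stats::runif(1, 9, 16)
  cl <- unit_cell(a, a * stats::runif(1, 0.9, 1.3), a * stats::runif(1, 0.9, 1.3),
                  90, 90, 90, spacegroup)
  rows <- data.frame(
    elety = "O", resid = "HOH", chain = "W", resno = seq_len(n),
    x = stats::runif(n, 0, cl$a), y = stats::runif(n, 0, cl$b),
    z = stats::runif(n, 0, cl$c), o = 1, b = 20, elesy = "O",
    stringsAsFactors = FALSE)
  mg_structure(rows, cell = cl, id = "rand_sym")
}

# compare a neighbor_search result with the brute-force oracle
expect_same_contacts <- function(got, want) {
  expect_equal(nrow(got), nrow(want))
  if (nrow(got)) {
    og <- order(got$distance, got$atom)
    ow <- order(want$distance, want$atom)
    expect_equal(got$atom[og], want$atom[ow])
    expect_equal(got$distance[og], want$distance[ow], tolerance = 1e-9)
  }
}
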