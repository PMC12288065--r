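# Analytic reference surfaces with closed-form energy / gradient / Hessian.
#
# Three families:
#   * morse_bond_network -- 3-D "molecules": Morse terms on a bonded pair
#     list. Proton-transfer topologies (a shared H between two scaffold
#     atoms) give genuine double wells with an index-1 saddle, the stand-in
#     for elementary reactions.
#   * quartic_double_well_1d -- one particle, V = s*(x^4 - 2 x^2); exact
#     barrier s, saddle curvature -4s at x = 0.
#   * mueller_brown_2d -- the classic two-saddle 2-D surface (one particle in
#     the xy plane).
# All labels are exact; gradient and Hessian are hand-derived closed forms.

#' Construct an analytic reference force field
#'
#' @param kind `"morse_bond_network"`, `"quartic_double_well_1d"` or
#'   `"mueller_brown_2d"`.
#' @param species character vector of element symbols.
#' @param bonds for Morse networks: data frame with columns `i`, `j`
#'   (atom indices), `D` (kcal/mol), `a` (1/A), `r0` (A).
#' @param scale overall energy scale for the model surfaces (default 1).
#' @param repulsion_A,repulsion_rho soft exponential repulsion
#'   `A exp(-r/rho)` applied to every non-bonded pair of a Morse network
#'   (prevents unphysical atom overlap; `repulsion_A = 0` disables).
#' @return object of class `reference_ff`.
#' @export
reference_ff <- function(kind = c("morse_bond_network", "quartic_double_well_1d",
                                  "mueller_brown_2d"),
                         species = "X", bonds = NULL, scale = 1,
                         repulsion_A = 500, repulsion_rho = 0.35) {
  kind <- match.arg(kind)
  nonbonded <- NULL
  if (kind == "morse_bond_network") {
    stopifnot(is.data.frame(bonds),
              all(c("i", "j", "D", "a", "r0") %in% names(bonds)))
    n <- length(species)
    if (any(bonds$i < 1 | bonds$i > n | bonds$j < 1 | bonds$j > n |
            bonds$i == bonds$j)) {
      stop("bond indices out of range", call. = FALSE)
    }
    if (repulsion_A > 0 && n >= 2L) {
      bonded <- matrix(FALSE, n, n)
      bonded[cbind(bonds$i, bonds$j)] <- TRUE
      bonded[cbind(bonds$j, bonds$i)] <- TRUE
      idx <- which(upper.tri(bonded) & !bonded, arr.ind = TRUE)
      if (nrow(idx) > 0L) {
        nonbonded <- data.frame(i = idx[, 1], j = idx[, 2])
      }
    }
  } else if (length(species) != 1L) {
    stop("model surfaces are single-particle", call. = FALSE)
  }
  structure(list(kind = kind, species = species, bonds = bonds, scale = scale,
                 nonbonded = nonbonded, repulsion_A = repulsion_A,
                 repulsion_rho = repulsion_rho),
            class = "reference_ff")
}

#' @export
print.reference_ff <- function(x, ...) {
  cat(sprintf("<reference_ff: %s, %d atoms%s>\n", x$kind, length(x$species),
              if (!is.null(x$bonds)) sprintf(", %d bonds", nrow(x$bonds)) else ""))
  invisible(x)
}

# first/second derivatives of r_ij w.r.t. the 6 involved coordinates,
# accumulated into gradient g (3n) and hessian H (3n x 3n) with weights
# w1 = dV/dr, w2 = d2V/dr2.
.acc_pair <- function(g, H, X, i, j, w1, w2) {
  d <- X[j, ] - X[i, ]
  r <- sqrt(sum(d * d))
  u <- d / r
  ii <- (3 * (i - 1) + 1):(3 * i)
  jj <- (3 * (j - 1) + 1):(3 * j)
  g[jj] <- g[jj] + w1 * u
  g[ii] <- g[ii] - w1 * u
  P <- (diag(3) - tcrossprod(u)) / r           # d2r, same-atom block
  blk <- w2 * tcrossprod(u) + w1 * P
  H[jj, jj] <- H[jj, jj] + blk
  H[ii, ii] <- H[ii, ii] + blk
  H[ii, jj] <- H[ii, jj] - blk
  H[jj, ii] <- H[jj, ii] - blk
  list(g = g, H = H)
}

# Mueller-Brown parameter table (standard constants)
.mb_par <- list(
  A = c(-200, -100, -170, 15),
  a = c(-1, -1, -6.5, 0.7),
  b = c(0, 0, 11, 0.6),
  c = c(-10, -10, -6.5, 0.7),
  x0 = c(1, 0, -0.5, -1),
  y0 = c(0, 0.5, 1.5, 1)
)

#' Evaluate a reference force field
#'
#' Closed-form energy, forces (negative gradient) and symmetric Hessian.
#'
#' @param ff a [reference_ff()].
#' @param structure a [labeled_structure()] or an n x 3 coordinate matrix.
#' @return list with `energy` (kcal/mol), `forces` (n x 3, kcal/mol/A) and
#'   `hessian` (3n x 3n, kcal/mol/A^2).
#' @export
eval_reference <- function(ff, structure) {
  X <- if (inherits(structure, "labeled_structure")) structure$coordinates
       else as.matrix(structure)
  n <- length(ff$species)
  if (nrow(X) != n || ncol(X) != 3L) {
    stop(sprintf("structure has %d atoms, force field expects %d",
                 nrow(X), n), call. = FALSE)
  }
  g <- numeric(3 * n)
  H <- matrix(0, 3 * n, 3 * n)
  E <- 0
  if (ff$kind == "morse_bond_network") {
    for (b in seq_len(nrow(ff$bonds))) {
      i <- ff$bonds$i[b]; j <- ff$bonds$j[b]
      D <- ff$bonds$D[b]; a <- ff$bonds$a[b]; r0 <- ff$bonds$r0[b]
      r <- sqrt(sum((X[j, ] - X[i, ])^2))
      ex <- exp(-a * (r - r0))
      E <- E + D * (1 - ex)^2
      w1 <- 2 * D * a * ex * (1 - ex)
      w2 <- 2 * D * a^2 * ex * (2 * ex - 1)
      upd <- .acc_pair(g, H, X, i, j, w1, w2)
      g <- upd$g; H <- upd$H
    }
    if (!is.null(ff$nonbonded)) {
      Ar <- ff$repulsion_A; rho <- ff$repulsion_rho
      for (b in seq_len(nrow(ff$nonbonded))) {
        i <- ff$nonbonded$i[b]; j <- ff$nonbonded$j[b]
        r <- sqrt(sum((X[j, ] - X[i, ])^2))
        er <- Ar * exp(-r / rho)
        E <- E + er
        upd <- .acc_pair(g, H, X, i, j, -er / rho, er / rho^2)
        g <- upd$g; H <- upd$H
      }
    }
  } else if (ff$kind == "quartic_double_well_1d") {
    s <- ff$scale
    x <- X[1, 1]
    E <- s * (x^4 - 2 * x^2)
    g[1] <- s * (4 * x^3 - 4 * x)
    H[1, 1] <- s * (12 * x^2 - 4)
  } else { # mueller_brown_2d
    p <- .mb_par
    s <- ff$scale
    x <- X[1, 1]; y <- X[1, 2]
    for (k in 1:4) {
      dx <- x - p$x0[k]; dy <- y - p$y0[k]
      ek <- p$A[k] * exp(p$a[k] * dx^2 + p$b[k] * dx * dy + p$c[k] * dy^2)
      E <- E + s * ek
      gx <- (2 * p$a[k] * dx + p$b[k] * dy)
      gy <- (p$b[k] * dx + 2 * p$c[k] * dy)
      g[1] <- g[1] + s * ek * gx
      g[2] <- g[2] + s * ek * gy
      H[1, 1] <- H[1, 1] + s * ek * (gx^2 + 2 * p$a[k])
      H[2, 2] <- H[2, 2] + s * ek * (gy^2 + 2 * p$c[k])
      H[1, 2] <- H[1, 2] + s * ek * (gx * gy + p$b[k])
    }
    H[2, 1] <- H[1, 2]
  }
  list(energy = E,
       forces = matrix(-g, n, 3L, byrow = TRUE),
       hessian = (H + t(H)) / 2)
}

# gradient as a flat 3n vector (row-major per atom: x1 y1 z1 x2 ...)
.ref_grad <- function(ff, X) {
  ev <- eval_reference(ff, X)
  -as.numeric(t(ev$forces))
}

# count eigenvalues below -neg_tol; |lambda| <= null_tol treated as the
# trans/rot (or flat-coordinate) null space.
hessian_index <- function(hessian, neg_tol = 1e-4) {
  sum(eigen(hessian, symmetric = TRUE, only.values = TRUE)$values < -neg_tol)
}

#' Locate a minimum or first-order saddle of a reference surface
#'
#' Newton search with eigenvector following: eigenmodes of the Hessian are
#' stepped downhill except, for `kind = "saddle1"`, the lowest mode which is
#' followed uphill. Near-singular modes (trans/rot null space) are frozen.
#' Steps are clipped to a trust radius.
#'
#' @param ff a [reference_ff()].
#' @param x0 starting n x 3 coordinates (must lie in the basin of attraction).
#' @param kind `"minimum"` or `"saddle1"`.
#' @param gtol convergence threshold on the max abs gradient component,
#'   kcal/mol/A. Default 1e-3 (much tighter than the common 0.53 electronic
#'   structure criterion; labels here are analytic).
#' @param trust trust radius, A.
#' @param max_iter iteration cap.
#' @param follow for saddle searches: optional 3n vector giving the intended
#'   reaction-coordinate direction; the uphill eigenmode is chosen by
#'   maximum overlap with it (mode tracking thereafter) instead of always
#'   taking the lowest mode.
#' @return [labeled_structure()] at the critical point with exact labels.
#' @export
find_critical_point <- function(ff, x0, kind = c("minimum", "saddle1"),
                                gtol = 1e-3, trust = 0.1, max_iter = 500L,
                                follow = NULL) {
  kind <- match.arg(kind)
  X <- as.matrix(x0)
  n <- length(ff$species)
  stopifnot(nrow(X) == n, ncol(X) == 3L)
  if (!is.null(follow)) {
    follow <- as.numeric(follow)
    stopifnot(length(follow) == 3L * n)
    follow <- follow / sqrt(sum(follow^2))
  }
  for (it in seq_len(max_iter)) {
    ev <- eval_reference(ff, X)
    g <- -as.numeric(t(ev$forces))
    if (!all(is.finite(g)) || !all(is.finite(X))) {
      stop("search left the finite region (non-finite gradient)", call. = FALSE)
    }
    if (max(abs(g)) <= gtol) {
      idx <- hessian_index(ev$hessian)
      want <- if (kind == "minimum") 0L else 1L
      if (idx != want) {
        stop(sprintf(
          "converged (|g|max = %.2e) but Hessian index is %d, wanted %d",
          max(abs(g)), idx, want), call. = FALSE)
      }
      return(labeled_structure(ff$species, X, energy = ev$energy,
                               forces = ev$forces, hessian = ev$hessian))
    }
    es <- eigen(ev$hessian, symmetric = TRUE)
    lam <- es$values
    gt <- drop(crossprod(es$vectors, g))
    step_t <- numeric(length(lam))
    floor_lam <- 1e-2
    null_lam <- 1e-6 * max(abs(lam), 1)
    up_mode <- if (kind != "saddle1") 0L
    else if (is.null(follow)) which.min(lam)
    else {
      m <- which.max(abs(drop(crossprod(es$vectors, follow))))
      follow <- es$vectors[, m]          # track the followed mode
      m
    }
    for (m in seq_along(lam)) {
      if (m == up_mode) {
        step_t[m] <- gt[m] / max(abs(lam[m]), floor_lam)  # uphill Newton
      } else if (abs(lam[m]) <= null_lam) {
        step_t[m] <- 0
      } else {
        step_t[m] <- -gt[m] / max(abs(lam[m]), floor_lam) # downhill
      }
    }
    step <- drop(es$vectors %*% step_t)
    nrm <- sqrt(sum(step^2))
    if (nrm > trust) step <- step * (trust / nrm)
    X <- X + matrix(step, n, 3L, byrow = TRUE)
  }
  ev <- eval_reference(ff, X)
  stop(sprintf("critical point search did not converge in %d iterations (|g|max = %.2e)",
               max_iter, max(abs(.ref_grad(ff, X)))), call. = FALSE)
}

#' Trace the intrinsic reaction coordinate through a saddle
#'
#' Steepest descent in mass-weighted coordinates, seeded at +/- `seed_eps`
#' along the negative-curvature eigenvector of the saddle Hessian. Descent
#' uses fixed-step Euler with backtracking near the endpoints; each branch
#' ends when the max gradient component falls below `gtol_end`. Arc length is
#' the signed cumulative mass-weighted path length with the transition state
#' at zero (reactant branch negative).
#'
#' @param ff a [reference_ff()].
#' @param saddle [labeled_structure()] with an index-1 Hessian.
#' @param step Euler step, amu^1/2 A.
#' @param seed_eps initial displacement along the unstable mode, amu^1/2 A.
#' @param gtol_end branch termination gradient threshold, kcal/mol/A.
#' @param keep_every thinning stride for stored images.
#' @param max_steps per-branch step cap.
#' @return object of class `irc_path`: `images` (labeled, exact), `arc`
#'   (amu^1/2 A), `tangents` (unit mass-weighted descent direction per image,
#'   pointing from reactant to product), `ts_index`.
#' @export
trace_irc <- function(ff, saddle, step = 0.01, seed_eps = 0.01,
                      gtol_end = 1e-3, keep_every = 10L, max_steps = 20000L) {
  stopifnot(inherits(saddle, "labeled_structure"), !is.null(saddle$hessian))
  if (hessian_index(saddle$hessian) != 1L) {
    stop("saddle must have exactly one negative Hessian eigenvalue", call. = FALSE)
  }
  n <- length(ff$species)
  m3 <- rep(saddle$masses, each = 3L)
  sqm <- sqrt(m3)
  Hmw <- saddle$hessian / tcrossprod(sqm)
  es <- eigen(Hmw, symmetric = TRUE)
  v <- es$vectors[, which.min(es$values)]          # unit, mass-weighted
  x_ts <- as.numeric(t(saddle$coordinates))
  y_ts <- x_ts * sqm

  descend <- function(dir_sign) {
    y <- y_ts + dir_sign * seed_eps * v
    pts <- list(); arcs <- numeric(0); tans <- list()
    arc <- seed_eps
    h <- step
    for (k in seq_len(max_steps)) {
      g <- .ref_grad(ff, matrix(y / sqm, n, 3L, byrow = TRUE))
      if (max(abs(g)) <= gtol_end) break
      gmw <- g / sqm
      gn <- sqrt(sum(gmw^2))
      t_hat <- gmw / gn
      e_here <- eval_reference(ff, matrix(y / sqm, n, 3L, byrow = TRUE))$energy
      repeat {
        y_new <- y - h * t_hat
        e_new <- eval_reference(ff, matrix(y_new / sqm, n, 3L, byrow = TRUE))$energy
        if (e_new <= e_here + 1e-12 || h < 1e-7) break
        h <- h / 2
      }
      y <- y_new
      arc <- arc + h
      if (k %% keep_every == 0L) {
        pts[[length(pts) + 1L]] <- y
        arcs <- c(arcs, arc)
        tans[[length(tans) + 1L]] <- -t_hat * dir_sign  # reactant->product
      }
      h <- min(h * 2, step)
      if (k == max_steps) {
        stop("IRC branch failed to reach a minimum", call. = FALSE)
      }
    }
    # always include the branch endpoint
    pts[[length(pts) + 1L]] <- y
    arcs <- c(arcs, arc)
    g <- .ref_grad(ff, matrix(y / sqm, n, 3L, byrow = TRUE))
    gmw <- g / sqm
    tn <- if (sqrt(sum(gmw^2)) > 1e-12) -gmw / sqrt(sum(gmw^2)) * dir_sign else -v * dir_sign
    tans[[length(tans) + 1L]] <- tn
    list(pts = pts, arcs = arcs, tans = tans)
  }

  minus <- descend(-1) # reactant side
  plus <- descend(+1)  # product side
  mk <- function(y) {
    X <- matrix(y / sqm, n, 3L, byrow = TRUE)
    ev <- eval_reference(ff, X)
    labeled_structure(ff$species, X, energy = ev$energy, forces = ev$forces,
                      hessian = ev$hessian)
  }
  n_m <- length(minus$pts)
  images <- c(lapply(rev(minus$pts), mk), list(saddle), lapply(plus$pts, mk))
  arc <- c(-rev(minus$arcs), 0, plus$arcs)
  tangents <- c(rev(minus$tans), list(v), plus$tans)
  structure(list(images = images, arc = arc, tangents = tangents,
                 ts_index = n_m + 1L, ff = ff),
            class = "irc_path")
}

#' @export
print.irc_path <- function(x, ...) {
  cat(sprintf("<irc_path: %d images, arc [%.3f, %.3f] amu^1/2 A, TS at index %d>\n",
              length(x$images), min(x$arc), max(x$arc), x$ts_index))
  invisible(x)
}

# ---- reaction family: shared-proton Morse networks -------------------------

# Fixed "universe" bond-parameter table: one global force field over element
# pairs, so the union of all reactions is a single consistent surface (as a
# real PES is). D kcal/mol, a 1/A, r0 A. Scaffold X..Y bonds are long and
# stiff enough that the shared H has two wells with an index-1 saddle between.
.pair_table <- function() {
  tab <- rbind(
    data.frame(e1 = "H", e2 = "O", D = 105, a = 2.8, r0 = 0.97),
    data.frame(e1 = "H", e2 = "N", D = 95,  a = 2.6, r0 = 1.02),
    data.frame(e1 = "H", e2 = "S", D = 85,  a = 2.2, r0 = 1.34),
    data.frame(e1 = "O", e2 = "O", D = 150, a = 2.3, r0 = 2.75),
    data.frame(e1 = "O", e2 = "N", D = 150, a = 2.3, r0 = 2.85),
    data.frame(e1 = "N", e2 = "N", D = 150, a = 2.2, r0 = 2.95),
    data.frame(e1 = "O", e2 = "S", D = 140, a = 2.0, r0 = 3.25),
    data.frame(e1 = "N", e2 = "S", D = 140, a = 2.0, r0 = 3.35),
    data.frame(e1 = "S", e2 = "S", D = 130, a = 1.9, r0 = 3.70),
    # spectator anchor bonds: long coordination-style attachments that keep
    # bridging spectators well off the proton-transfer axis
    data.frame(e1 = "C", e2 = "O", D = 150, a = 2.0, r0 = 2.45),
    data.frame(e1 = "C", e2 = "N", D = 150, a = 2.0, r0 = 2.50),
    data.frame(e1 = "C", e2 = "S", D = 140, a = 1.8, r0 = 2.85),
    data.frame(e1 = "C", e2 = "C", D = 150, a = 1.9, r0 = 2.60)
  )
  tab
}

.pair_params <- function(e1, e2) {
  tab <- .pair_table()
  hit <- which((tab$e1 == e1 & tab$e2 == e2) | (tab$e1 == e2 & tab$e2 == e1))
  if (length(hit) != 1L) {
    stop(sprintf("no bond parameters for pair %s-%s", e1, e2), call. = FALSE)
  }
  tab[hit, ]
}

# Build the reference_ff and a starting geometry for one proton-transfer
# "reaction". Topology: donor A (atom 1), shared H (atom 2), acceptor B
# (atom 3); optional bridging spectators each bonded to two earlier heavy
# atoms so the frame is rigid under pair terms alone.
.make_reaction_ff <- function(elem_A, elem_B, spectators) {
  species <- c(elem_A, "H", elem_B)
  p_AH <- .pair_params("H", elem_A)
  p_HB <- .pair_params("H", elem_B)
  p_AB <- .pair_params(elem_A, elem_B)
  bonds <- data.frame(
    i = c(1L, 2L, 1L), j = c(2L, 3L, 3L),
    D = c(p_AH$D, p_HB$D, p_AB$D),
    a = c(p_AH$a, p_HB$a, p_AB$a),
    r0 = c(p_AH$r0, p_HB$r0, p_AB$r0)
  )
  d <- p_AB$r0
  # small fixed off-axis offsets break the collinear symmetry so critical
  # point searches are not trapped on a symmetric ridge
  X <- rbind(c(0, 0, 0), c(p_AH$r0, 0.05, 0.02), c(d, 0, 0))
  # bridging spectators: element + the two heavy anchor indices
  for (sp in spectators) {
    k <- length(species) + 1L
    species <- c(species, sp$elem)
    p1 <- .pair_params(sp$elem, species[sp$anchor[1]])
    p2 <- .pair_params(sp$elem, species[sp$anchor[2]])
    bonds <- rbind(bonds, data.frame(
      i = c(sp$anchor[1], sp$anchor[2]), j = c(k, k),
      D = c(p1$D, p2$D), a = c(p1$a, p2$a), r0 = c(p1$r0, p2$r0)
    ))
    # place the spectator at the triangle apex over its two anchors
    x1 <- X[sp$anchor[1], ]; x2 <- X[sp$anchor[2], ]
    base <- sqrt(sum((x2 - x1)^2))
    r1 <- p1$r0; r2 <- p2$r0
    if (r1 + r2 <= base * 1.02) { # anchors too far apart: stretch bonds evenly
      r1 <- base * 0.6; r2 <- base * 0.6
    }
    along <- (base^2 + r1^2 - r2^2) / (2 * base)
    h <- sqrt(max(r1^2 - along^2, 0.25))
    e1 <- (x2 - x1) / base
    # apex direction: off the A..B axis, alternating sides per spectator
    side <- if (k %% 2L == 0L) 1 else -1
    e2 <- c(0, side, 0)
    e2 <- e2 - sum(e2 * e1) * e1
    if (sqrt(sum(e2^2)) < 1e-8) e2 <- c(0, 0, side)
    e2 <- e2 / sqrt(sum(e2^2))
    X <- rbind(X, x1 + along * e1 + h * e2)
  }
  list(ff = reference_ff("morse_bond_network", species = species, bonds = bonds),
       X0 = X, d_AB = d, r_AH = p_AH$r0, r_HB = p_HB$r0)
}

# Geometry sanity check for generated critical points: pair potentials have
# no non-bonded repulsion, so a spectator can collapse onto another atom and
# still satisfy the stationarity conditions. Such geometries are unphysical
# (and pathological for any descriptor), so their reactions are rejected.
.geometry_sane <- function(s, bonds) {
  n <- length(s$species)
  dm <- as.matrix(stats::dist(s$coordinates))
  bonded <- matrix(FALSE, n, n)
  for (b in seq_len(nrow(bonds))) {
    bonded[bonds$i[b], bonds$j[b]] <- TRUE
    bonded[bonds$j[b], bonds$i[b]] <- TRUE
  }
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    lim <- if (bonded[i, j]) 0.6 * bonds$r0[which(
      (bonds$i == i & bonds$j == j) | (bonds$i == j & bonds$j == i))[1]]
    else if (s$species[i] == "H" || s$species[j] == "H") 1.1
    else 1.6
    if (dm[i, j] < lim) return(FALSE)
  }
  TRUE
}

# enumerate the reaction family: donor/acceptor pairs x spectator motifs
.reaction_family <- function() {
  pairs <- list(c("O", "O"), c("O", "N"), c("N", "N"),
                c("O", "S"), c("N", "S"), c("S", "S"))
  motifs <- list(
    list(),                                                # 3 atoms
    list(list(elem = "C", anchor = c(1L, 3L))),            # 4 atoms
    list(list(elem = "O", anchor = c(1L, 3L))),            # 4 atoms
    list(list(elem = "C", anchor = c(1L, 3L)),
         list(elem = "C", anchor = c(1L, 4L))),            # 5 atoms
    list(list(elem = "C", anchor = c(1L, 3L)),
         list(elem = "O", anchor = c(3L, 4L))),            # 5 atoms
    list(list(elem = "C", anchor = c(1L, 3L)),
         list(elem = "C", anchor = c(3L, 4L))),            # 5 atoms
    list(list(elem = "O", anchor = c(1L, 3L)),
         list(elem = "C", anchor = c(1L, 4L)))             # 5 atoms
  )
  fam <- list()
  for (p in pairs) for (m in motifs) {
    fam[[length(fam) + 1L]] <- list(elem_A = p[1], elem_B = p[2], spectators = m)
  }
  fam
}

#' Generate a reactant / transition-state / product dataset
#'
#' Builds `n_reactions` shared-proton reactions on Morse bond networks drawn
#' (without replacement, in seeded random order) from a fixed family of
#' donor-acceptor element pairs and bridging-spectator motifs. Each reaction
#' contributes the reactant, index-1 saddle and product located on its
#' surface, labeled with exact energies, forces and Hessians. Reactions whose
#' critical-point searches fail are skipped with a warning.
#'
#' @param n_reactions number of reactions requested (max 42, the family size).
#' @param seed integer seed; the dataset is a deterministic function of it.
#' @param min_success_fraction error if fewer than this fraction succeed.
#' @param gtol gradient tolerance passed to [find_critical_point()].
#' @return object of class `rtp_dataset`: `reactions` (list of
#'   `list(reactant, ts, product, ff)`), `provenance`.
#' @export
build_rtp_dataset <- function(n_reactions, seed,
                              min_success_fraction = 0.75, gtol = 1e-3) {
  stopifnot(n_reactions >= 1L)
  fam <- .reaction_family()
  if (n_reactions > length(fam)) {
    stop(sprintf("family has %d distinct reactions; %d requested",
                 length(fam), n_reactions), call. = FALSE)
  }
  # seeded order without disturbing the caller's RNG state
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  set.seed(seed)
  idx <- sample(length(fam), n_reactions)
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()) else
    rm(".Random.seed", envir = globalenv())

  reactions <- list()
  failed <- 0L
  for (k in idx) {
    spec <- fam[[k]]
    built <- .make_reaction_ff(spec$elem_A, spec$elem_B, spec$spectators)
    ff <- built$ff
    # deterministic retry ladder: perturbed starts / tighter trust radius
    search <- function(X0, kind, follow = NULL) {
      n <- nrow(X0)
      jit <- function(a) {
        if (a == 1L) return(matrix(0, n, 3L))
        0.03 * (a - 1) * cbind(sin(seq_len(n) + a), cos(2 * seq_len(n) - a),
                               sin(3 * seq_len(n) * a))
      }
      last <- NULL
      for (a in 1:4) {
        out <- tryCatch(
          find_critical_point(ff, X0 + jit(a), kind, gtol = gtol,
                              trust = if (a <= 2) 0.1 else 0.05,
                              max_iter = 1500L, follow = follow),
          error = function(e) e)
        if (inherits(out, "labeled_structure") &&
            .geometry_sane(out, ff$bonds)) return(out)
        last <- if (inherits(out, "error")) conditionMessage(out)
                else "degenerate geometry (atom overlap) at a critical point"
      }
      stop(last, call. = FALSE)
    }
    res <- tryCatch({
      X_r <- built$X0
      reactant <- search(X_r, "minimum")
      X_p <- built$X0
      X_p[2, ] <- X_p[3, ] - c(built$r_HB, -0.05, -0.02)  # H near acceptor
      product <- search(X_p, "minimum")
      X_t <- built$X0
      X_t[2, ] <- (X_r[1, ] + X_r[3, ]) / 2 + c(0, 0.05, 0.02)  # H midway
      rc <- matrix(0, nrow(X_t), 3L)
      rc[2, ] <- (X_t[3, ] - X_t[1, ])       # H along donor->acceptor
      ts <- search(X_t, "saddle1", follow = as.numeric(t(rc)))
      list(reactant = reactant, ts = ts, product = product, ff = ff,
           family_index = k)
    }, error = function(e) {
      warning(sprintf("reaction %d skipped: %s", k, conditionMessage(e)),
              call. = FALSE)
      NULL
    })
    if (is.null(res)) failed <- failed + 1L else {
      reactions[[length(reactions) + 1L]] <- res
    }
  }
  if (length(reactions) < min_success_fraction * n_reactions) {
    stop(sprintf("only %d of %d reactions succeeded", length(reactions),
                 n_reactions), call. = FALSE)
  }
  structure(
    list(reactions = reactions,
         provenance = list(seed = seed, family_indices = idx,
                           n_requested = n_reactions, n_failed = failed)),
    class = "rtp_dataset"
  )
}

#' @export
print.rtp_dataset <- function(x, ...) {
  cat(sprintf("<rtp_dataset: %d reactions (seed %d)>\n",
              length(x$reactions), x$provenance$seed))
  invisible(x)
}

#' Flatten an RTP dataset into a list of labeled structures
#'
#' @param dataset an `rtp_dataset`.
#' @return list of [labeled_structure()] (reactant, ts, product per reaction).
#' @export
rtp_structures <- function(dataset) {
  stopifnot(inherits(dataset, "rtp_dataset"))
  unlist(lapply(dataset$reactions, function(r) {
    list(r$reactant, r$ts, r$product)
  }), recursive = FALSE)
}
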