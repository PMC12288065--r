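# Atomic environment vectors (modified Behler-Parrinello symmetry functions)
# with exact analytic first and second derivatives w.r.t. Cartesian
# coordinates.
#
# Radial part (per neighbor element e, per shift R_s):
#     G = sum_j exp(-eta_r (r_ij - R_s)^2) * f_c(r_ij)
# Angular part (per neighbor element pair, per Bernstein index b, per
# pair-distance shift R_s):
#     G = sum_{j<k} B_b(t) * exp(-eta_a (rbar - R_s)^2) * f_c(r_ij) f_c(r_ik)
# with t = (1 - cos theta_jik)/2 and rbar = (r_ij + r_ik)/2. The angular
# shape functions B_b are Bernstein polynomials in cos theta: unlike the
# classic (1 + cos(theta - theta_s))^zeta form, they are polynomial in
# cos theta and therefore C-infinity in the coordinates away from r = 0
# (the trigonometric form has second-derivative singularities at collinear
# geometries, which is hostile to Hessian labels).
#
# Every term is a function of interatomic distances only (cos theta via the
# law of cosines), so Cartesian derivatives flow through the distance map
# r_pq(x), whose first/second derivatives have one uniform closed form.

#' Descriptor specification
#'
#' @param elements element alphabet (character).
#' @param r_cut cutoff radius, A.
#' @param radial_shifts Gaussian centers for the radial block, A.
#' @param eta_r radial Gaussian width parameter, 1/A^2.
#' @param radial_moments exponents k for low-order radial moment features
#'   `sum_j r_ij^k f_c(r_ij)` per neighbor element (coordination-count and
#'   bond-length moments). These let locally quadratic surface shape be
#'   represented with small readout weights, which keeps the model's
#'   higher-order behavior tame when Hessian labels are fit. Empty vector
#'   disables.
#' @param n_angular number of Bernstein angular shape functions (polynomial
#'   degree + 1); these peak on an even grid of angles between 0 and pi.
#' @param angular_r_shifts Gaussian centers for the mean pair distance, A.
#' @param eta_a angular-block radial width parameter, 1/A^2.
#' @param cutoff_fn `"smooth_poly"` ((1-(r/Rc)^2)^3, C2 at Rc) or
#'   `"cosine"` (C1 at Rc; kept for lineage comparison only).
#' @return object of class `aev_spec`; `$length` is the descriptor length.
#' @export
aev_spec <- function(elements,
                     r_cut = 4.6,
                     radial_shifts = seq(0.7, 4.0, length.out = 8),
                     eta_r = 8,
                     radial_moments = c(0L, 1L, 2L),
                     n_angular = 4,
                     angular_r_shifts = seq(1.0, 3.1, length.out = 4),
                     eta_a = 4,
                     cutoff_fn = c("smooth_poly", "cosine")) {
  cutoff_fn <- match.arg(cutoff_fn)
  elements <- as.character(elements)
  stopifnot(length(elements) >= 1L, !anyDuplicated(elements),
            r_cut > 0, eta_r > 0, eta_a > 0, n_angular >= 1L,
            all(radial_shifts < r_cut), all(radial_moments >= 0))
  nE <- length(elements)
  pairs <- which(upper.tri(matrix(0, nE, nE), diag = TRUE), arr.ind = TRUE)
  pairs <- pairs[order(pairs[, "row"], pairs[, "col"]), , drop = FALSE]
  n_rad <- length(radial_shifts) + length(radial_moments)
  len <- nE * n_rad +
    nrow(pairs) * n_angular * length(angular_r_shifts)
  structure(
    list(elements = elements, r_cut = r_cut, radial_shifts = radial_shifts,
         eta_r = eta_r, radial_moments = radial_moments,
         n_angular = n_angular,
         angular_r_shifts = angular_r_shifts, eta_a = eta_a,
         cutoff_fn = cutoff_fn, element_pairs = pairs, length = len),
    class = "aev_spec"
  )
}

#' @export
print.aev_spec <- function(x, ...) {
  cat(sprintf("<aev_spec: %d elements (%s), L = %d, Rc = %.2f A, %s cutoff>\n",
              length(x$elements), paste(x$elements, collapse = " "),
              x$length, x$r_cut, x$cutoff_fn))
  invisible(x)
}

# cutoff function and its first two derivatives in r; zero at and beyond rc
.cutoff <- function(r, rc, variant) {
  inside <- r < rc
  f <- d1 <- d2 <- numeric(length(r))
  if (any(inside)) {
    x <- r[inside] / rc
    if (variant == "smooth_poly") {
      q <- 1 - x^2
      f[inside] <- q^3
      d1[inside] <- -6 * x * q^2 / rc
      d2[inside] <- (-6 * q^2 + 24 * x^2 * q) / rc^2
    } else { # cosine
      f[inside] <- 0.5 * (cos(pi * x) + 1)
      d1[inside] <- -0.5 * pi * sin(pi * x) / rc
      d2[inside] <- -0.5 * pi^2 * cos(pi * x) / rc^2
    }
  }
  list(f = f, d1 = d1, d2 = d2)
}

# Bernstein basis of size n (degree n-1) at t, with first two derivatives
.bernstein <- function(t, n) {
  m <- n - 1L
  b <- d1 <- d2 <- numeric(n)
  for (k in 0:m) {
    ch <- choose(m, k)
    b[k + 1] <- ch * t^k * (1 - t)^(m - k)
    # d/dt [t^k (1-t)^(m-k)]
    p1 <- if (k >= 1) k * t^(k - 1) * (1 - t)^(m - k) else 0
    p2 <- if (m - k >= 1) -(m - k) * t^k * (1 - t)^(m - k - 1) else 0
    d1[k + 1] <- ch * (p1 + p2)
    q1 <- if (k >= 2) k * (k - 1) * t^(k - 2) * (1 - t)^(m - k) else 0
    q2 <- if (k >= 1 && m - k >= 1) -2 * k * (m - k) * t^(k - 1) * (1 - t)^(m - k - 1) else 0
    q3 <- if (m - k >= 2) (m - k) * (m - k - 1) * t^k * (1 - t)^(m - k - 2) else 0
    d2[k + 1] <- ch * (q1 + q2 + q3)
  }
  list(b = b, d1 = d1, d2 = d2)
}

# dr/dx as a full 3n vector for the pair (i, j); u is the unit vector i -> j
.pair_D <- function(i, j, u, n) {
  D <- numeric(3 * n)
  D[(3 * j - 2):(3 * j)] <- u
  D[(3 * i - 2):(3 * i)] <- -u
  D
}

# d2r/dx dx as a full 3n x 3n matrix for the pair (i, j)
.pair_S <- function(i, j, u, r, n) {
  S <- matrix(0, 3 * n, 3 * n)
  B <- (diag(3) - tcrossprod(u)) / r
  ii <- (3 * i - 2):(3 * i); jj <- (3 * j - 2):(3 * j)
  S[ii, ii] <- B; S[jj, jj] <- B
  S[ii, jj] <- -B; S[jj, ii] <- -B
  S
}

#' Atomic environment vectors for one structure
#'
#' Computes the per-atom descriptor matrix and, on request, its exact
#' analytic Jacobian and Hessian with respect to all Cartesian coordinates.
#'
#' @param coordinates n x 3 matrix (A) or a [labeled_structure()].
#' @param species element symbols (ignored when a structure is given).
#' @param spec an [aev_spec()].
#' @param deriv 0 (values), 1 (+ Jacobians), or 2 (+ Hessians).
#' @return list with `G` (n x L), and when requested `J` (list per atom of
#'   L x 3n matrices) and `H` (list per atom of L x (3n)^2 matrices holding
#'   the column-major vec of each entry's 3n x 3n Hessian).
#' @export
aev_structure <- function(coordinates, species = NULL, spec, deriv = 0L) {
  if (inherits(coordinates, "labeled_structure")) {
    species <- coordinates$species
    coordinates <- coordinates$coordinates
  }
  X <- as.matrix(coordinates)
  n <- nrow(X)
  ei <- match(species, spec$elements)
  if (anyNA(ei)) {
    stop(sprintf("element(s) not in AEV alphabet: %s",
                 paste(unique(species[is.na(ei)]), collapse = ", ")),
         call. = FALSE)
  }
  L <- spec$length
  nRs <- length(spec$radial_shifts) + length(spec$radial_moments)
  nB <- spec$n_angular
  nAs <- length(spec$angular_r_shifts)
  nE <- length(spec$elements)
  A0 <- nE * nRs
  # index of unordered element pair (e1, e2) in spec$element_pairs order
  pair_idx <- matrix(0L, nE, nE)
  for (p in seq_len(nrow(spec$element_pairs))) {
    a <- spec$element_pairs[p, 1]; b <- spec$element_pairs[p, 2]
    pair_idx[a, b] <- p; pair_idx[b, a] <- p
  }

  G <- matrix(0, n, L)
  J <- if (deriv >= 1L) lapply(seq_len(n), function(i) matrix(0, L, 3 * n))
  H <- if (deriv >= 2L) lapply(seq_len(n), function(i) matrix(0, L, (3 * n)^2))
  if (n == 1L) {
    return(list(G = G, J = J, H = H, spec = spec))
  }

  # pair geometry cache, indexed by a dense pair-id matrix
  rc <- spec$r_cut
  pid <- matrix(0L, n, n)
  pr <- vector("list", n * (n - 1L) / 2L)
  np <- 0L
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    np <- np + 1L
    pid[i, j] <- np; pid[j, i] <- np
    d <- X[j, ] - X[i, ]
    r <- sqrt(sum(d * d))
    u <- d / r
    pr[[np]] <- list(r = r, u = u,
                     fc = .cutoff(r, rc, spec$cutoff_fn),
                     D = if (deriv >= 1L) .pair_D(i, j, u, n),
                     S = if (deriv >= 2L) .pair_S(i, j, u, r, n))
  }
  getp <- function(i, j) pr[[pid[i, j]]]
  # ---- radial block ----
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    p <- getp(i, j)
    if (p$r >= rc) next
    fc <- p$fc
    dr <- p$r - spec$radial_shifts
    tg <- exp(-spec$eta_r * dr^2)
    tg1 <- -2 * spec$eta_r * dr * tg
    tg2 <- (-2 * spec$eta_r + 4 * spec$eta_r^2 * dr^2) * tg
    h <- tg * fc$f
    h1 <- tg1 * fc$f + tg * fc$d1
    h2 <- tg2 * fc$f + 2 * tg1 * fc$d1 + tg * fc$d2
    if (length(spec$radial_moments) > 0L) {
      k <- spec$radial_moments
      rk <- p$r^k
      rk1 <- k * p$r^(k - 1)                 # d r^k / dr (0 when k = 0)
      rk2 <- k * (k - 1) * p$r^(k - 2)
      rk1[k == 0] <- 0; rk2[k <= 1] <- 0
      h <- c(h, rk * fc$f)
      h1 <- c(h1, rk1 * fc$f + rk * fc$d1)
      h2 <- c(h2, rk2 * fc$f + 2 * rk1 * fc$d1 + rk * fc$d2)
    }
    for (ord in list(c(i, j), c(j, i))) {
      a <- ord[1]; b <- ord[2]             # center a sees neighbor b
      lr <- ((ei[b] - 1) * nRs + 1):((ei[b] - 1) * nRs + nRs)
      G[a, lr] <- G[a, lr] + h
      if (deriv >= 1L) J[[a]][lr, ] <- J[[a]][lr, ] + outer(h1, p$D)
      if (deriv >= 2L) {
        vDD <- as.numeric(tcrossprod(p$D))
        H[[a]][lr, ] <- H[[a]][lr, ] + outer(h2, vDD) + outer(h1, as.numeric(p$S))
      }
    }
  }

  # ---- angular block ----
  if (n >= 3L) {
    for (a in seq_len(n)) {
      nb <- setdiff(seq_len(n), a)
      nb <- nb[vapply(nb, function(j) getp(a, j)$r < rc, logical(1))]
      if (length(nb) < 2L) next
      for (ji in seq_len(length(nb) - 1)) for (ki in (ji + 1):length(nb)) {
        j <- nb[ji]; k <- nb[ki]
        p1 <- getp(a, j); p2 <- getp(a, k); p3 <- getp(j, k)
        r1 <- p1$r; r2 <- p2$r; r3 <- p3$r
        u_cos <- (r1^2 + r2^2 - r3^2) / (2 * r1 * r2)
        tt <- (1 - u_cos) / 2
        tt <- min(max(tt, 0), 1)                 # round-off guard
        rbar <- (r1 + r2) / 2
        fc1 <- p1$fc
        fc2 <- p2$fc
        Bb <- .bernstein(tt, nB)
        drb <- rbar - spec$angular_r_shifts
        Rg <- exp(-spec$eta_a * drb^2)
        Rg1 <- -2 * spec$eta_a * drb * Rg
        Rg2 <- (-2 * spec$eta_a + 4 * spec$eta_a^2 * drb^2) * Rg
        pidx <- pair_idx[ei[j], ei[k]]
        base <- A0 + (pidx - 1) * nB * nAs
        lr <- (base + 1):(base + nB * nAs)       # order: b fastest (outer())
        C0 <- fc1$f * fc2$f
        BR <- as.numeric(outer(Bb$b, Rg))
        G[a, lr] <- G[a, lr] + BR * C0
        if (deriv == 0L) next
        # partials of u (cos theta) w.r.t. (r1, r2, r3)
        u1 <- (r1^2 - r2^2 + r3^2) / (2 * r1^2 * r2)
        u2 <- (r2^2 - r1^2 + r3^2) / (2 * r1 * r2^2)
        u3 <- -r3 / (r1 * r2)
        tA <- -c(u1, u2, u3) / 2                  # dt/dr_alpha
        rbA <- c(0.5, 0.5, 0)
        Cc <- c(fc1$d1 * fc2$f, fc1$f * fc2$d1, 0) # dC/dr_alpha
        B1R <- as.numeric(outer(Bb$d1, Rg))
        BR1 <- as.numeric(outer(Bb$b, Rg1))
        # dh/dr_alpha, one column per alpha (rbar_3 = 0, C_3 = 0)
        hA <- cbind(B1R * (tA[1] * C0) + BR1 * (0.5 * C0) + BR * Cc[1],
                    B1R * (tA[2] * C0) + BR1 * (0.5 * C0) + BR * Cc[2],
                    B1R * (tA[3] * C0))
        Dm <- rbind(p1$D, p2$D, p3$D)
        J[[a]][lr, ] <- J[[a]][lr, ] + hA %*% Dm
        if (deriv >= 2L) {
          u11 <- (r2^2 - r3^2) / (r1^3 * r2)
          u22 <- (r1^2 - r3^2) / (r2^3 * r1)
          u33 <- -1 / (r1 * r2)
          u12 <- -(r1^2 + r2^2 + r3^2) / (2 * r1^2 * r2^2)
          u13 <- r3 / (r1^2 * r2)
          u23 <- r3 / (r1 * r2^2)
          uAB <- matrix(c(u11, u12, u13, u12, u22, u23, u13, u23, u33), 3, 3)
          tAB <- -uAB / 2
          CAB <- matrix(0, 3, 3)
          CAB[1, 1] <- fc1$d2 * fc2$f
          CAB[2, 2] <- fc1$f * fc2$d2
          CAB[1, 2] <- CAB[2, 1] <- fc1$d1 * fc2$d1
          B2R <- as.numeric(outer(Bb$d2, Rg))
          BR2 <- as.numeric(outer(Bb$b, Rg2))
          B1R1 <- as.numeric(outer(Bb$d1, Rg1))
          hab <- function(al, be) {
            B2R * tA[al] * tA[be] * C0 +
              B1R * tAB[al, be] * C0 +
              B1R1 * (tA[al] * rbA[be] + tA[be] * rbA[al]) * C0 +
              B1R * (tA[al] * Cc[be] + tA[be] * Cc[al]) +
              BR2 * rbA[al] * rbA[be] * C0 +
              BR1 * (rbA[al] * Cc[be] + rbA[be] * Cc[al]) +
              BR * CAB[al, be]
          }
          Ds <- list(p1$D, p2$D, p3$D)
          Ss <- list(p1$S, p2$S, p3$S)
          # rows of V: vec(D_a D_a'), sym cross terms, vec(S_a);
          # matching coefficient columns per feature
          V <- rbind(
            as.numeric(tcrossprod(Ds[[1]])),
            as.numeric(tcrossprod(Ds[[2]])),
            as.numeric(tcrossprod(Ds[[3]])),
            as.numeric(tcrossprod(Ds[[1]], Ds[[2]]) + tcrossprod(Ds[[2]], Ds[[1]])),
            as.numeric(tcrossprod(Ds[[1]], Ds[[3]]) + tcrossprod(Ds[[3]], Ds[[1]])),
            as.numeric(tcrossprod(Ds[[2]], Ds[[3]]) + tcrossprod(Ds[[3]], Ds[[2]])),
            as.numeric(Ss[[1]]), as.numeric(Ss[[2]]), as.numeric(Ss[[3]])
          )
          Cf <- cbind(hab(1, 1), hab(2, 2), hab(3, 3),
                      hab(1, 2), hab(1, 3), hab(2, 3),
                      hA[, 1], hA[, 2], hA[, 3])
          H[[a]][lr, ] <- H[[a]][lr, ] + Cf %*% V
        }
      }
    }
  }
  list(G = G, J = J, H = H, spec = spec)
}

#' Atomic environment vectors for a padded batch
#'
#' @param batch a `padded_batch`.
#' @param spec an [aev_spec()]; the batch element alphabet must be a subset
#'   of the spec alphabet.
#' @param deriv derivative order passed to [aev_structure()].
#' @return object of class `aev_batch`: `G` (M x N x L grid, padded rows
#'   exactly zero), `atom_mask`, and `per_molecule` (the per-structure
#'   results, carrying Jacobians/Hessians when requested).
#' @export
compute_aev <- function(batch, spec, deriv = 0L) {
  stopifnot(inherits(batch, "padded_batch"), inherits(spec, "aev_spec"))
  missing_el <- setdiff(batch$elements, spec$elements)
  if (length(missing_el) > 0L) {
    stop(sprintf("element(s) not in AEV alphabet: %s",
                 paste(missing_el, collapse = ", ")), call. = FALSE)
  }
  structs <- unbatch_structures(batch)
  per <- lapply(structs, function(s) aev_structure(s, spec = spec, deriv = deriv))
  M <- length(structs)
  N <- ncol(batch$species)
  Garr <- array(0, c(M, N, spec$length))
  for (i in seq_len(M)) {
    Garr[i, seq_len(batch$n_atoms[i]), ] <- per[[i]]$G
  }
  structure(list(G = Garr, atom_mask = batch$atom_mask, per_molecule = per,
                 spec = spec),
            class = "aev_batch")
}
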