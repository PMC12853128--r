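# Low-level geometric primitives: torsions, vector angles, 3-D convex hull
# surface area, and Shrake-Rupley solvent-accessible surface area.

vnorm <- function(v) sqrt(sum(v * v))

unit <- function(v) {
  n <- vnorm(v)
  if (n < 1e-12) return(c(0, 0, 0))
  v / n
}

#' Angle between two vectors
#' @param u,v Numeric length-3 vectors.
#' @return Angle in radians in `[0, pi]`; 0 if either vector is degenerate.
#' @export
vector_angle <- function(u, v) {
  nu <- vnorm(u); nv <- vnorm(v)
  if (nu < 1e-12 || nv < 1e-12) return(0)
  cosang <- sum(u * v) / (nu * nv)
  acos(max(-1, min(1, cosang)))
}

#' Torsion (dihedral) angle of four points
#'
#' Signed dihedral about the b-c axis, by the atan2 formulation; radians in
#' `(-pi, pi]`.
#'
#' @param a,b,c,d Numeric length-3 coordinate vectors.
#' @return Angle in radians; 0 when the construction is degenerate.
#' @export
torsion_angle <- function(a, b, c, d) {
  b1 <- b - a; b2 <- c - b; b3 <- d - c
  n1 <- c(b1[2] * b2[3] - b1[3] * b2[2],
          b1[3] * b2[1] - b1[1] * b2[3],
          b1[1] * b2[2] - b1[2] * b2[1])
  n2 <- c(b2[2] * b3[3] - b2[3] * b3[2],
          b2[3] * b3[1] - b2[1] * b3[3],
          b2[1] * b3[2] - b2[2] * b3[1])
  if (vnorm(n1) < 1e-12 || vnorm(n2) < 1e-12) return(0)
  m1 <- c(n1[2] * b2[3] - n1[3] * b2[2],
          n1[3] * b2[1] - n1[1] * b2[3],
          n1[1] * b2[2] - n1[2] * b2[1])
  x <- sum(n1 * n2)
  y <- sum(m1 * n2) / vnorm(b2)
  ang <- -atan2(y, x)   # IUPAC sign convention
  if (ang <= -pi) ang <- ang + 2 * pi
  ang
}

tri_area <- function(p1, p2, p3) {
  u <- p2 - p1; v <- p3 - p1
  cr <- c(u[2] * v[3] - u[3] * v[2],
          u[3] * v[1] - u[1] * v[3],
          u[1] * v[2] - u[2] * v[1])
  0.5 * vnorm(cr)
}

#' Surface area of the 3-D convex hull of a point set
#'
#' Incremental hull construction.  Point sets with fewer than four affinely
#' independent points (collinear, coplanar, or < 4 points) report area 0 by
#' convention.
#'
#' @param pts Numeric matrix, one row per point, three columns.
#' @return Hull surface area (same squared units as the coordinates).
#' @export
convex_hull_area <- function(pts) {
  pts <- as.matrix(pts)
  pts <- unique(round(pts, 10))
  n <- nrow(pts)
  if (n < 4) return(0)
  eps <- 1e-9

  # seed tetrahedron: four affinely independent points
  i1 <- 1
  d <- rowSums(sweep(pts, 2, pts[i1, ])^2)
  i2 <- which.max(d)
  if (d[i2] < eps) return(0)
  v1 <- pts[i2, ] - pts[i1, ]
  cr <- function(u, v) c(u[2] * v[3] - u[3] * v[2],
                         u[3] * v[1] - u[1] * v[3],
                         u[1] * v[2] - u[2] * v[1])
  a2 <- apply(pts, 1, function(p) vnorm(cr(v1, p - pts[i1, ])))
  i3 <- which.max(a2)
  if (a2[i3] < eps) return(0)
  nrm <- cr(v1, pts[i3, ] - pts[i1, ])
  h <- abs(as.numeric(pts %*% nrm) - sum(nrm * pts[i1, ])) / vnorm(nrm)
  i4 <- which.max(h)
  if (h[i4] < eps) return(0)

  # faces as index triples, oriented outward (away from tetra centroid)
  centroid <- colMeans(pts[c(i1, i2, i3, i4), ])
  orient <- function(f) {
    nrm <- cr(pts[f[2], ] - pts[f[1], ], pts[f[3], ] - pts[f[1], ])
    if (sum(nrm * (centroid - pts[f[1], ])) > 0) f[c(1, 3, 2)] else f
  }
  faces <- list(orient(c(i1, i2, i3)), orient(c(i1, i2, i4)),
                orient(c(i1, i3, i4)), orient(c(i2, i3, i4)))

  face_normal <- function(f) cr(pts[f[2], ] - pts[f[1], ], pts[f[3], ] - pts[f[1], ])

  rest <- setdiff(seq_len(n), c(i1, i2, i3, i4))
  for (p in rest) {
    vis <- vapply(faces, function(f) {
      nrm <- face_normal(f)
      sum(nrm * (pts[p, ] - pts[f[1], ])) > eps * vnorm(nrm)
    }, logical(1))
    if (!any(vis)) next   # inside or on the current hull: no area contribution
    # horizon = edges of visible faces bordering an invisible face
    edges <- do.call(rbind, lapply(faces[vis], function(f) {
      rbind(f[c(1, 2)], f[c(2, 3)], f[c(3, 1)])
    }))
    ekey <- paste(pmin(edges[, 1], edges[, 2]), pmax(edges[, 1], edges[, 2]))
    horizon <- edges[ekey %in% names(which(table(ekey) == 1)), , drop = FALSE]
    faces <- faces[!vis]
    for (k in seq_len(nrow(horizon))) {
      # keep the winding of the visible face so the new face points outward
      faces[[length(faces) + 1]] <- c(horizon[k, 1], horizon[k, 2], p)
    }
  }
  sum(vapply(faces, function(f) tri_area(pts[f[1], ], pts[f[2], ], pts[f[3], ]),
             numeric(1)))
}

# Deterministic quasi-uniform unit-sphere points (Fibonacci lattice).
sphere_points <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  theta <- pi * (1 + sqrt(5)) * i
  cbind(cos(theta) * sin(phi), sin(theta) * sin(phi), cos(phi))
}

VDW_RADII <- c(C = 1.70, N = 1.55, O = 1.52, S = 1.80, P = 1.80,
               SE = 1.90, F = 1.47, CL = 1.75, BR = 1.85, I = 1.98)

vdw_radius <- function(element) {
  r <- VDW_RADII[toupper(element)]
  r[is.na(r)] <- 1.70
  unname(r)
}

#' Shrake-Rupley solvent-accessible surface area
#'
#' Per-atom SASA by test points on each atom's solvent-expanded sphere; a
#' point is accessible when it lies outside every neighbouring atom's
#' expanded sphere.
#'
#' @param coords Numeric matrix (atoms x 3), heavy atoms only.
#' @param elements Character vector of element symbols (for van der Waals
#'   radii; unknown elements fall back to carbon).
#' @param probe Probe radius in Angstrom (default 1.4, water).
#' @param n_points Test points per atom (default 960).
#' @return Numeric vector of per-atom SASA in squared Angstrom.
#' @export
shrake_rupley <- function(coords, elements, probe = 1.4, n_points = 960) {
  coords <- as.matrix(coords)
  n <- nrow(coords)
  if (n == 0) return(numeric(0))
  radii <- vdw_radius(elements) + probe
  sp <- sphere_points(n_points)
  out <- numeric(n)
  maxr <- max(radii)
  for (i in seq_len(n)) {
    d2 <- rowSums(sweep(coords, 2, coords[i, ])^2)
    nbr <- which(d2 < (radii[i] + maxr)^2 & seq_len(n) != i)
    nbr <- nbr[d2[nbr] < (radii[i] + radii[nbr])^2]
    pts <- sweep(sp * radii[i], 2, coords[i, ], "+")
    if (length(nbr)) {
      acc <- rep(TRUE, n_points)
      for (j in nbr) {
        if (!any(acc)) break
        dj <- rowSums(sweep(pts[acc, , drop = FALSE], 2, coords[j, ])^2)
        acc[acc] <- dj > radii[j]^2
      }
      frac <- mean(acc)
    } else {
      frac <- 1
    }
    out[i] <- 4 * pi * radii[i]^2 * frac
  }
  out
}
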