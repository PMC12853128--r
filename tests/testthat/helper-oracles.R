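# Independent oracles, deliberately implemented differently from the
# package code paths they check.

# hull area by supporting-plane enumeration over all point triples:
# a plane through three points supports the hull iff every point lies on one
# closed side; the area of each unique supporting plane is the 2-D polygon
# area of the points on it.
oracle_hull_area <- function(pts) {
  pts <- unique(round(as.matrix(pts), 10))
  n <- nrow(pts)
  if (n < 4) return(0)
  cross3 <- function(u, v) c(u[2]*v[3]-u[3]*v[2], u[3]*v[1]-u[1]*v[3], u[1]*v[2]-u[2]*v[1])
  planes <- list()
  for (i in 1:(n-2)) for (j in (i+1):(n-1)) for (k in (j+1):n) {
    nrm <- cross3(pts[j,]-pts[i,], pts[k,]-pts[i,])
    if (sqrt(sum(nrm^2)) < 1e-9) next
    nrm <- nrm / sqrt(sum(nrm^2))
    d <- as.numeric(pts %*% nrm) - sum(nrm * pts[i,])
    if (all(d <= 1e-8)) {
      planes[[length(planes)+1]] <- list(nrm = nrm, p0 = pts[i,], on = which(abs(d) <= 1e-8))
    } else if (all(d >= -1e-8)) {
      planes[[length(planes)+1]] <- list(nrm = -nrm, p0 = pts[i,], on = which(abs(d) <= 1e-8))
    }
  }
  if (!length(planes)) return(0)
  keys <- vapply(planes, function(pl) paste(round(c(pl$nrm, sum(pl$nrm*pl$p0)), 6), collapse=","), "")
  planes <- planes[!duplicated(keys)]
  total <- 0
  for (pl in planes) {
    P <- pts[pl$on, , drop = FALSE]
    # project to 2-D in-plane coordinates
    a <- if (abs(pl$nrm[1]) < 0.9) c(1,0,0) else c(0,1,0)
    e1 <- cross3(pl$nrm, a); e1 <- e1 / sqrt(sum(e1^2))
    e2 <- cross3(pl$nrm, e1)
    xy <- cbind(P %*% e1, P %*% e2)
    h <- grDevices::chull(xy)
    poly <- xy[h, , drop = FALSE]
    m <- nrow(poly)
    if (m < 3) next
    total <- total + abs(sum(poly[,1]*poly[c(2:m,1),2] - poly[c(2:m,1),1]*poly[,2])) / 2
  }
  total
}

# torsion via explicit Gram-Schmidt projection (not atan2 of cross products):
# angle between b->a and c->d after removing their components along the
# b->c axis; sign positive when w1 x w3 points along the axis (IUPAC)
oracle_torsion <- function(a, b, c, d) {
  axis <- c - b
  proj <- function(v) v - sum(v*axis)/sum(axis*axis) * axis
  w1 <- proj(a - b); w3 <- proj(d - c)
  cosang <- sum(w1*w3) / sqrt(sum(w1^2)*sum(w3^2))
  ang <- acos(max(-1, min(1, cosang)))
  cr <- c(w1[2]*w3[3]-w1[3]*w3[2], w1[3]*w3[1]-w1[1]*w3[3], w1[1]*w3[2]-w1[2]*w3[1])
  s <- sign(sum(axis * cr))
  if (s == 0) s <- 1
  s * ang
}

# Shrake-Rupley with a different, randomised point set (high resolution)
oracle_sasa <- function(coords, elements, probe = 1.4, n_points = 2000, seed = 99) {
  set.seed(seed)
  z <- matrix(rnorm(n_points * 3), n_points, 3)
  sp <- z / sqrt(rowSums(z^2))
  radii <- glycobind:::vdw_radius(elements) + probe
  n <- nrow(coords)
  out <- numeric(n)
  for (i in seq_len(n)) {
    pts <- sweep(sp * radii[i], 2, coords[i, ], "+")
    acc <- rep(TRUE, n_points)
    for (j in seq_len(n)) {
      if (j == i) next
      dj <- rowSums(sweep(pts, 2, coords[j, ])^2)
      acc <- acc & dj > radii[j]^2
    }
    out[i] <- 4 * pi * radii[i]^2 * mean(acc)
  }
  out
}

# triple-loop DPC, straight off the definition
oracle_dpc <- function(pssm) {
  L <- nrow(pssm)
  out <- matrix(0, L, 400)
  for (k in 1:L) for (i in 1:20) for (j in 1:20) {
    v <- 0
    if (k > 1) v <- v + pssm[k, i] * pssm[k - 1, j]
    if (k < L) v <- v + pssm[k, i] * pssm[k + 1, j]
    out[k, (i - 1) * 20 + j] <- v
  }
  out
}

# brute-force confusion counting and metric formulas
oracle_metrics <- function(prob, labels, thr = 0.5) {
  tp <- fp <- tn <- fn <- 0
  for (i in seq_along(prob)) {
    pred <- if (prob[i] >= thr) 1 else 0
    if (pred == 1 && labels[i] == 1) tp <- tp + 1
    if (pred == 1 && labels[i] == 0) fp <- fp + 1
    if (pred == 0 && labels[i] == 0) tn <- tn + 1
    if (pred == 0 && labels[i] == 1) fn <- fn + 1
  }
  list(TP = tp, FP = fp, TN = tn, FN = fn,
       SN = tp / (tp + fn), SP = tn / (tn + fp),
       ACC = (tp + tn) / length(prob),
       PREC = tp / (tp + fp), F1 = 2 * tp / (2 * tp + fp + fn))
}

# AUC as the Mann-Whitney U statistic scaled by n_pos * n_neg
oracle_auc_mw <- function(scores, labels) {
  pos <- scores[labels == 1]; neg <- scores[labels == 0]
  mean(outer(pos, neg, ">") + 0.5 * outer(pos, neg, "=="))
}

# brute-force binding annotation: all residue-atom x carb-atom pairs
oracle_annotate <- function(chain, carb_atoms, cutoff = 3.5) {
  at <- chain$atoms[chain$atoms$is_heavy, ]
  carb <- carb_atoms[carb_atoms$is_heavy, ]
  pos <- integer(0)
  for (i in unique(at$res_index)) {
    a <- at[at$res_index == i, ]
    hit <- FALSE
    for (r in seq_len(nrow(a))) for (s in seq_len(nrow(carb))) {
      d <- sqrt((a$x[r]-carb$x[s])^2 + (a$y[r]-carb$y[s])^2 + (a$z[r]-carb$z[s])^2)
      if (d <= cutoff) { hit <- TRUE; break }
    }
    if (hit) pos <- c(pos, i)
  }
  pos
}
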