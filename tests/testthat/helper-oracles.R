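# Independent oracles used across the suite. These deliberately use
# naive algorithms (enumeration, grids, O(n^2) scans) so they stay
# independent of the implementation paths they check.

# random monomer of n residues, one CA atom each
random_ca_monomer <- function(n, chain = "A", spread = 15, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  monomer_structure(chain, data.frame(
    res_index = seq_len(n), aa = "A", name = "CA", element = "C",
    x = runif(n, 0, spread), y = runif(n, 0, spread),
    z = runif(n, 0, spread)))
}

# O(n^2) heavy-atom residue-contact scan, pure R
contacts_bruteforce <- function(conf, cutoff = 5.5) {
  a <- conf$monomer_a$atoms[conf$monomer_a$atoms$is_heavy, ]
  b <- conf$monomer_b$atoms[conf$monomer_b$atoms$is_heavy, ]
  out <- list()
  for (ra in unique(a$res_index)) for (rb in unique(b$res_index)) {
    xa <- as.matrix(a[a$res_index == ra, c("x", "y", "z")])
    xb <- as.matrix(b[b$res_index == rb, c("x", "y", "z")])
    d2 <- outer(rowSums(xa^2), rowSums(xb^2), "+") - 2 * xa %*% t(xb)
    if (min(d2) <= cutoff^2) {
      out[[length(out) + 1]] <- data.frame(res_a = ra, res_b = rb,
                                           min_dist = sqrt(max(0, min(d2))))
    }
  }
  if (length(out) == 0L) {
    return(data.frame(res_a = integer(0), res_b = integer(0),
                      min_dist = numeric(0)))
  }
  res <- do.call(rbind, out)
  res[order(res$res_a, res$res_b), ]
}

# brute-force minimum RMSD over rotations: coarse Euler-angle grid plus
# local refinement with optim
rmsd_bruteforce <- function(a, b) {
  ac <- sweep(a, 2, colMeans(a))
  bc <- sweep(b, 2, colMeans(b))
  rot <- function(ang) {
    cx <- cos(ang[1]); sx <- sin(ang[1])
    cy <- cos(ang[2]); sy <- sin(ang[2])
    cz <- cos(ang[3]); sz <- sin(ang[3])
    Rx <- matrix(c(1, 0, 0, 0, cx, sx, 0, -sx, cx), 3)
    Ry <- matrix(c(cy, 0, -sy, 0, 1, 0, sy, 0, cy), 3)
    Rz <- matrix(c(cz, sz, 0, -sz, cz, 0, 0, 0, 1), 3)
    Rz %*% Ry %*% Rx
  }
  obj <- function(ang) sqrt(mean(rowSums((bc - ac %*% t(rot(ang)))^2)))
  grid <- seq(0, 2 * pi, length.out = 9)[-9]
  best <- Inf; best_ang <- c(0, 0, 0)
  for (p in grid) for (q in grid) for (r in grid) {
    v <- obj(c(p, q, r))
    if (v < best) { best <- v; best_ang <- c(p, q, r) }
  }
  opt <- optim(best_ang, obj, method = "Nelder-Mead",
               control = list(reltol = 1e-14, maxit = 5000))
  opt$value
}

# minimum-image distance by explicit enumeration of the 27 images
min_image_bruteforce <- function(x1, x2, box) {
  best <- Inf
  for (i in -1:1) for (j in -1:1) for (k in -1:1) {
    d <- sqrt(sum((x1 - (x2 + box * c(i, j, k)))^2))
    best <- min(best, d)
  }
  best
}

# dense-sample SASA oracle: Fibonacci-sphere surface samples per atom
sasa_grid_oracle <- function(xyz, radii, probe = 1.4, n_samples = 1e5) {
  n <- nrow(xyz)
  er <- radii + probe
  k <- seq_len(n_samples) - 0.5
  z <- 1 - 2 * k / n_samples
  r <- sqrt(pmax(0, 1 - z^2))
  th <- pi * (3 - sqrt(5)) * k
  pts <- cbind(r * cos(th), r * sin(th), z)
  total <- 0
  for (i in seq_len(n)) {
    p <- sweep(pts * er[i], 2, xyz[i, ], "+")
    free <- rep(TRUE, n_samples)
    for (j in seq_len(n)) {
      if (j == i) next
      d2 <- (p[, 1] - xyz[j, 1])^2 + (p[, 2] - xyz[j, 2])^2 +
        (p[, 3] - xyz[j, 3])^2
      free <- free & d2 >= er[j]^2
    }
    total <- total + 4 * pi * er[i]^2 * mean(free)
  }
  total
}

# rigid transform helper
apply_rigid <- function(xyz, angle = 0.7, axis = c(1, 2, 3),
                        shift = c(5, -3, 2)) {
  ax <- axis / sqrt(sum(axis^2))
  K <- matrix(c(0, ax[3], -ax[2], -ax[3], 0, ax[1], ax[2], -ax[1], 0), 3)
  R <- diag(3) + sin(angle) * K + (1 - cos(angle)) * (K %*% K)
  sweep(xyz %*% t(R), 2, -shift)
}

transform_monomer <- function(mon, ...) {
  xyz <- apply_rigid(as.matrix(mon$atoms[, c("x", "y", "z")]), ...)
  mon$atoms[, c("x", "y", "z")] <- xyz
  mon
}
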