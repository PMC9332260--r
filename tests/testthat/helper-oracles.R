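# Independent numerical oracles used by the test suite. These deliberately
# avoid the package's own code paths.

# Rotation matrix from a rotation vector (Rodrigues formula).
rotvec_to_matrix <- function(v) {
  th <- sqrt(sum(v^2))
  if (th < 1e-12) return(diag(3))
  k <- v / th
  K <- matrix(c(0, -k[3], k[2], k[3], 0, -k[1], -k[2], k[1], 0), 3, 3,
              byrow = TRUE)
  diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
}

# Brute-force minimum RMSD over rotations: multi-start Nelder-Mead over the
# rotation-vector parameterisation, centroids aligned beforehand.
oracle_min_rmsd <- function(moving, target, starts = 12) {
  X <- sweep(moving, 2, colMeans(moving))
  Y <- sweep(target, 2, colMeans(target))
  f <- function(v) {
    R <- rotvec_to_matrix(v)
    sqrt(mean(rowSums((X %*% R - Y)^2)))
  }
  best <- Inf
  set.seed(99)
  for (s in seq_len(starts)) {
    v0 <- if (s == 1) c(0, 0, 0) else stats::runif(3, -pi, pi)
    op <- stats::optim(v0, f, method = "Nelder-Mead",
                       control = list(maxit = 2000, reltol = 1e-14))
    best <- min(best, op$value)
  }
  best
}

# Dense latitude-band sphere grid (independent of the Fibonacci lattice used
# by the implementation). Bands of equal z-width have equal area; each point
# carries the weight of its band's share, area_band / m_points.
latband_sphere <- function(n_bands = 100) {
  pts <- NULL; w <- NULL
  for (b in seq_len(n_bands)) {
    z <- -1 + (2 * b - 1) / n_bands
    r <- sqrt(max(1 - z^2, 0))
    m <- max(1, round(2 * n_bands * r))
    phi <- 2 * pi * (seq_len(m) - 0.5) / m
    pts <- rbind(pts, cbind(r * cos(phi), r * sin(phi), z))
    w <- c(w, rep(1 / (n_bands * m), m))  # fractions of total sphere area
  }
  list(pts = pts, w = w)
}

# Dense-grid SASA oracle (~10^4 weighted test points per atom).
oracle_sasa <- function(xyz, radii, probe = 1.4, n_bands = 70) {
  g <- latband_sphere(n_bands)
  rs <- radii + probe
  total <- 0
  for (i in seq_len(nrow(xyz))) {
    sphere <- g$pts * rs[i] + matrix(xyz[i, ], nrow(g$pts), 3, byrow = TRUE)
    exposed <- rep(TRUE, nrow(sphere))
    for (j in seq_len(nrow(xyz))) {
      if (j == i) next
      dj <- sweep(sphere, 2, xyz[j, ])
      exposed <- exposed & rowSums(dj^2) >= rs[j]^2
    }
    total <- total + sum(g$w[exposed]) * 4 * pi * rs[i]^2
  }
  total
}

# Exhaustive per-molecule minimum-distance histogram (plain loops, minimum
# image), the brute-force counterpart of the MDDF counting step.
oracle_mddf_counts <- function(traj, breaks) {
  counts <- numeric(length(breaks) - 1)
  grp <- traj$cosolvent_group
  for (f in seq_along(traj$frames)) {
    solute <- traj$frames[[f]]
    cs <- traj$cosolvent[[f]]
    for (g in unique(grp)) {
      rows <- which(grp == g)
      dmin <- Inf
      for (a in rows) for (s in seq_len(nrow(solute))) {
        d <- cs[a, ] - solute[s, ]
        if (is.finite(traj$box)) d <- d - traj$box * round(d / traj$box)
        dmin <- min(dmin, sqrt(sum(d^2)))
      }
      for (b in seq_len(length(breaks) - 1)) {
        if (dmin > breaks[b] && dmin <= breaks[b + 1]) counts[b] <- counts[b] + 1
      }
    }
  }
  counts
}
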