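# Trajectory statistics: Kabsch superposition, RMSD, radius of gyration,
# Shrake-Rupley SASA, per-residue RMSF and temperature differences, MDDF and
# residue-cosolvent density maps.

#' Optimal rigid superposition (Kabsch algorithm)
#'
#' Finds the proper rotation (determinant +1; the reflection branch of the
#' SVD solution is corrected) and translation minimising the (weighted) RMSD
#' between two congruent point sets. Points are rows; the transform maps
#' \code{moving} onto \code{target} as \code{moving \%*\% rotation + translation}.
#'
#' @param moving n x 3 coordinate matrix to transform.
#' @param target n x 3 coordinate matrix to match.
#' @param weights optional non-negative per-point weights.
#' @return list with \code{rotation} (3 x 3), \code{translation} (length 3),
#'   \code{rmsd}, and \code{transformed} (the superposed moving set).
#' @export
kabsch_superpose <- function(moving, target, weights = NULL) {
  moving <- as.matrix(moving); target <- as.matrix(target)
  if (!all(dim(moving) == dim(target)) || ncol(moving) != 3)
    stop("moving and target must be congruent n x 3 matrices")
  n <- nrow(moving)
  if (n < 3) stop("need at least 3 points")
  if (is.null(weights)) weights <- rep(1, n)
  if (length(weights) != n || any(weights < 0) || sum(weights) == 0)
    stop("weights must be non-negative with positive sum")
  w <- weights / sum(weights)
  cm <- colSums(moving * w); ct <- colSums(target * w)
  X <- sweep(moving, 2, cm); Y <- sweep(target, 2, ct)
  A <- t(X * w) %*% Y
  sv <- svd(A)
  # degenerate sets (coincident or collinear) leave the rotation underdetermined
  scale <- max(sqrt(sum(w * rowSums(X^2))), sqrt(sum(w * rowSums(Y^2))))
  if (scale == 0 || sv$d[2] / scale^2 < 1e-10)
    stop("degenerate point set: superposition underdetermined")
  d <- sign(det(sv$v %*% t(sv$u)))
  R <- sv$u %*% diag(c(1, 1, d)) %*% t(sv$v)
  tr <- ct - as.numeric(cm %*% R)
  transformed <- moving %*% R + matrix(tr, n, 3, byrow = TRUE)
  rmsd <- sqrt(sum(w * rowSums((transformed - target)^2)))
  list(rotation = R, translation = tr, rmsd = rmsd, transformed = transformed)
}

#' Per-frame RMSD after optimal superposition
#'
#' Each frame is superposed onto the reference on the given selection and the
#' RMSD is reported on that selection. The mean over the trailing
#' \code{last_frac} of frames is reported separately, the usual
#' end-of-production summary.
#'
#' @param traj an [md_trajectory()].
#' @param selection atom selection (see [select_atoms()]), default backbone.
#' @param last_frac trailing fraction of frames for the summary mean.
#' @return list with \code{rmsd} (per frame, Angstrom), \code{mean},
#'   \code{mean_last} and \code{frame_times}.
#' @export
rmsd_series <- function(traj, selection = "backbone", last_frac = 0.1) {
  stopifnot(inherits(traj, "md_trajectory"))
  idx <- select_atoms(traj$reference, selection)
  ref <- coords(traj$reference)[idx, , drop = FALSE]
  r <- vapply(traj$frames, function(f)
    kabsch_superpose(f[idx, , drop = FALSE], ref)$rmsd, numeric(1))
  n <- length(r)
  last <- seq(max(1L, n - ceiling(last_frac * n) + 1L), n)
  list(rmsd = r, mean = mean(r), mean_last = mean(r[last]),
       frame_times = traj$frame_times)
}

#' Mass-weighted radius of gyration
#'
#' @param frame n x 3 coordinate matrix (or an [md_structure()]).
#' @param masses atomic masses in Da; taken from the structure if omitted.
#' @return radius of gyration in Angstrom.
#' @export
radius_of_gyration <- function(frame, masses = NULL) {
  if (inherits(frame, "md_structure")) {
    if (is.null(masses)) masses <- frame$atoms$mass
    frame <- coords(frame)
  }
  frame <- as.matrix(frame)
  if (is.null(masses)) masses <- rep(1, nrow(frame))
  if (length(masses) != nrow(frame)) stop("one mass per atom required")
  M <- sum(masses)
  if (M <= 0) stop("total mass must be positive")
  com <- colSums(frame * masses) / M
  sqrt(sum(masses * rowSums(sweep(frame, 2, com)^2)) / M)
}

# Deterministic Fibonacci lattice on the unit sphere.
.fibonacci_sphere <- function(n) {
  i <- seq_len(n) - 0.5
  z <- 1 - 2 * i / n
  phi <- pi * (3 - sqrt(5)) * (i - 0.5)
  s <- sqrt(pmax(1 - z^2, 0))
  cbind(s * cos(phi), s * sin(phi), z)
}

#' Solvent-accessible surface area (Shrake-Rupley)
#'
#' Each atom's accessible sphere (radius = vdW radius + probe) is sampled
#' with a deterministic Fibonacci point lattice; a test point is exposed if
#' it lies outside every other atom's accessible sphere. Per-atom area is the
#' exposed fraction times the sphere area, so results are bit-reproducible
#' at a fixed \code{n_points}.
#'
#' @param frame an [md_structure()], or an n x 3 coordinate matrix with
#'   \code{radii} supplied.
#' @param probe probe radius in Angstrom (water: 1.4).
#' @param n_points lattice points per atom (>= 32).
#' @param radii per-atom van der Waals radii (required for a bare matrix).
#' @return list with \code{total} (Angstrom^2) and \code{per_atom}.
#' @export
sasa <- function(frame, probe = 1.4, n_points = 256, radii = NULL) {
  if (inherits(frame, "md_structure")) {
    if (is.null(radii)) radii <- frame$atoms$radius
    frame <- coords(frame)
  }
  frame <- as.matrix(frame)
  if (is.null(radii)) stop("van der Waals radii required")
  if (length(radii) != nrow(frame)) stop("one radius per atom required")
  if (n_points < 32) stop("n_points below the accuracy floor of 32")
  n <- nrow(frame)
  pts <- .fibonacci_sphere(n_points)
  rs <- radii + probe
  per_atom <- numeric(n)
  d2 <- as.matrix(stats::dist(frame))^2
  for (i in seq_len(n)) {
    nb <- which(d2[i, ] < (rs[i] + rs)^2 & seq_len(n) != i)
    sphere <- pts * rs[i] + matrix(frame[i, ], n_points, 3, byrow = TRUE)
    exposed <- rep(TRUE, n_points)
    for (j in nb) {
      if (!any(exposed)) break
      dj <- sweep(sphere, 2, frame[j, ])
      exposed <- exposed & rowSums(dj^2) >= rs[j]^2
    }
    per_atom[i] <- mean(exposed) * 4 * pi * rs[i]^2
  }
  list(total = sum(per_atom), per_atom = per_atom)
}

#' Per-residue root-mean-square fluctuations
#'
#' Frames are superposed onto the reference on the selection and a mean
#' structure is formed; a second pass then superposes every frame onto that
#' running mean with inverse-variance weights (1 over the first-pass mean
#' squared displacement), which keeps highly mobile atoms from dragging the
#' fit and inflating the apparent fluctuation of quiet ones. RMSF_i is the
#' root of the mean squared displacement of atom i about its mean position
#' after the second pass.
#'
#' @param traj an [md_trajectory()] with at least 2 frames.
#' @param selection atom selection; default the C-alpha trace.
#' @param label optional temperature/condition label carried in the profile.
#' @return an object of class \code{fluct_profile}: \code{resid},
#'   \code{rmsf} (Angstrom), \code{selection}, \code{label}.
#' @export
rmsf <- function(traj, selection = "CA", label = NA_character_) {
  stopifnot(inherits(traj, "md_trajectory"))
  if (length(traj$frames) < 2) stop("need at least 2 frames for fluctuations")
  idx <- select_atoms(traj$reference, selection)
  raw <- lapply(traj$frames, function(f) f[idx, , drop = FALSE])
  ref <- coords(traj$reference)[idx, , drop = FALSE]
  p1 <- lapply(raw, function(f) kabsch_superpose(f, ref)$transformed)
  mn <- Reduce(`+`, p1) / length(p1)
  msd1 <- Reduce(`+`, lapply(p1, function(f) rowSums((f - mn)^2))) /
    length(p1)
  w <- 1 / pmax(msd1, 1e-6)
  p2 <- lapply(raw, function(f)
    kabsch_superpose(f, mn, weights = w)$transformed)
  mn2 <- Reduce(`+`, p2) / length(p2)
  msd <- Reduce(`+`, lapply(p2, function(f) rowSums((f - mn2)^2))) /
    length(p2)
  structure(list(resid = traj$reference$atoms$resid[idx], rmsf = sqrt(msd),
                 selection = paste(selection, collapse = ","), label = label),
            class = "fluct_profile")
}

#' @export
print.fluct_profile <- function(x, ...) {
  cat(sprintf("Fluctuation profile (%s%s): %d residues, RMSF %.3g-%.3g A\n",
              x$selection,
              if (is.na(x$label)) "" else paste0(", ", x$label),
              length(x$resid), min(x$rmsf), max(x$rmsf)))
  invisible(x)
}

#' @export
plot.fluct_profile <- function(x, ...) {
  graphics::plot(x$resid, x$rmsf, type = "l", xlab = "residue",
                 ylab = "RMSF (A)", ...)
  invisible(x)
}

#' Flexibility difference between two fluctuation profiles
#'
#' Elementwise RMSF difference, profile-at-temperature minus reference
#' profile (conventionally the 27 C run). Positive values mark segments that
#' are more flexible than in the reference condition, negative values more
#' rigid ones.
#'
#' @param p_T \code{fluct_profile} at the temperature of interest.
#' @param p_ref reference-condition \code{fluct_profile}; residue ids must
#'   match exactly.
#' @return a \code{fluct_profile} whose \code{rmsf} holds the difference.
#' @export
delta_rmsf <- function(p_T, p_ref) {
  stopifnot(inherits(p_T, "fluct_profile"), inherits(p_ref, "fluct_profile"))
  if (!identical(p_T$resid, p_ref$resid))
    stop("profiles cover different residues")
  structure(list(resid = p_T$resid, rmsf = p_T$rmsf - p_ref$rmsf,
                 selection = p_T$selection,
                 label = paste0("delta(", p_T$label, " - ", p_ref$label, ")")),
            class = "fluct_profile")
}

#' Pearson correlation between two per-residue profiles
#'
#' @param p,q \code{fluct_profile} objects (or bare numeric vectors of equal
#'   length).
#' @param window optional residue-id range (length-2) restricting the
#'   comparison, e.g. a mobile-loop window such as residues 262-291.
#' @return Pearson correlation coefficient.
#' @export
profile_correlation <- function(p, q, window = NULL) {
  if (inherits(p, "fluct_profile") && inherits(q, "fluct_profile")) {
    if (!identical(p$resid, q$resid)) stop("profiles cover different residues")
    keep <- if (is.null(window)) TRUE
            else p$resid >= window[1] & p$resid <= window[2]
    a <- p$rmsf[keep]; b <- q$rmsf[keep]
  } else {
    a <- as.numeric(p); b <- as.numeric(q)
    if (length(a) != length(b)) stop("profiles must have equal length")
  }
  if (length(a) < 3) stop("need at least 3 residues to correlate")
  if (stats::sd(a) == 0 || stats::sd(b) == 0)
    stop("zero variance: correlation undefined")
  stats::cor(a, b)
}

# Minimum-image squared distances between two coordinate sets (cubic box).
.min_image_dist <- function(a, b, box) {
  out <- matrix(0, nrow(a), nrow(b))
  for (k in 1:3) {
    d <- outer(a[, k], b[, k], `-`)
    if (is.finite(box)) d <- d - box * round(d / box)
    out <- out + d * d
  }
  sqrt(out)
}

# Per-molecule minimum distance to a solute selection for one frame.
.frame_min_dist <- function(cos_xyz, group, solute_xyz, box) {
  if (nrow(cos_xyz) == 0) return(numeric(0))
  d <- .min_image_dist(cos_xyz, solute_xyz, box)
  dmin_atom <- apply(d, 1, min)
  as.numeric(tapply(dmin_atom, group, min))
}

#' Minimum-distance distribution function of a cosolvent
#'
#' For every frame and cosolvent molecule the minimum distance between any
#' of its atoms and any solute-selection atom is histogrammed. Counts are
#' normalised bin-wise by the expected counts of the same number of
#' molecules placed uniformly at random in the box (seeded random insertion
#' with \code{oversample}-fold oversampling, one insertion batch per frame
#' against that frame's solute coordinates), so a uniformly distributed
#' cosolvent gives a profile of 1.
#'
#' @param traj an [md_trajectory()] with cosolvent and a finite box.
#' @param solute_selection atom selection of the solute, default "all".
#' @param bin_width histogram bin width in Angstrom.
#' @param r_max histogram range in Angstrom; must not exceed half the box
#'   edge (minimum-image ambiguity beyond).
#' @param oversample uniform-insertion oversampling factor (>= 1).
#' @param seed seed for the insertion sampler.
#' @return an object of class \code{mddf_profile}: \code{r} (bin centres),
#'   \code{mddf}, \code{counts}, \code{expected}, \code{bin_width}.
#' @export
mddf <- function(traj, solute_selection = "all", bin_width = 0.1, r_max = 10,
                 oversample = 10, seed = 1L) {
  stopifnot(inherits(traj, "md_trajectory"))
  if (is.null(traj$cosolvent)) stop("trajectory has no cosolvent")
  if (!is.finite(traj$box)) stop("MDDF needs a periodic box edge")
  if (r_max > traj$box / 2)
    stop("r_max exceeds half the box edge: minimum image ambiguous")
  idx <- select_atoms(traj$reference, solute_selection)
  grp <- traj$cosolvent_group
  n_mol <- length(unique(grp))
  breaks <- seq(0, r_max, by = bin_width)
  if (max(breaks) < r_max) breaks <- c(breaks, max(breaks) + bin_width)
  nb <- length(breaks) - 1L
  counts <- numeric(nb); expected <- numeric(nb)
  n_ins <- oversample * n_mol
  sim <- .with_seed(seed, {
    for (f in seq_along(traj$frames)) {
      solute <- traj$frames[[f]][idx, , drop = FALSE]
      dmin <- .frame_min_dist(traj$cosolvent[[f]], grp, solute, traj$box)
      counts <- counts + graphics::hist(dmin[dmin <= max(breaks)],
                                        breaks = breaks, plot = FALSE)$counts
      ins <- matrix(stats::runif(n_ins * 3, 0, traj$box), ncol = 3)
      dins <- .frame_min_dist(ins, seq_len(n_ins), solute, traj$box)
      expected <- expected +
        graphics::hist(dins[dins <= max(breaks)], breaks = breaks,
                       plot = FALSE)$counts / oversample
    }
    list(counts = counts, expected = expected)
  })
  m <- ifelse(sim$expected > 0, sim$counts / sim$expected, 0)
  structure(list(r = (breaks[-1] + breaks[-length(breaks)]) / 2, mddf = m,
                 counts = sim$counts, expected = sim$expected,
                 bin_width = bin_width),
            class = "mddf_profile")
}

#' @export
print.mddf_profile <- function(x, ...) {
  cat(sprintf("MDDF: %d bins of %.3g A, %g molecule-frames\n",
              length(x$r), x$bin_width, sum(x$counts)))
  invisible(x)
}

#' @export
plot.mddf_profile <- function(x, ...) {
  graphics::plot(x$r, x$mddf, type = "l", xlab = "minimum distance (A)",
                 ylab = "MDDF", ...)
  graphics::abline(h = 1, lty = 3)
  invisible(x)
}

#' Residue-cosolvent density map
#'
#' For each listed residue and each distance bin, the per-frame probability
#' that at least one cosolvent atom's minimum distance to that residue's
#' atoms falls inside the bin. The default 1.5-3.5 Angstrom range maps the
#' first solvation shell, the representation used for cosolvent occupancy
#' around mobile-loop residues.
#'
#' @param traj an [md_trajectory()] with cosolvent.
#' @param residues residue ids (rows of the output, in input order).
#' @param r_range length-2 distance range in Angstrom.
#' @param bin_width bin width in Angstrom.
#' @return an object of class \code{density_map}: \code{map} (residues x
#'   bins probability matrix), \code{r} (bin centres), \code{residues}.
#' @export
residue_density_map <- function(traj, residues, r_range = c(1.5, 3.5),
                                bin_width = 0.25) {
  stopifnot(inherits(traj, "md_trajectory"))
  if (is.null(traj$cosolvent)) stop("trajectory has no cosolvent")
  if (length(residues) == 0) stop("empty residue list")
  res_atoms <- lapply(residues, function(r) {
    ix <- which(traj$reference$atoms$resid == r)
    if (length(ix) == 0) stop("residue not in structure: ", r)
    ix
  })
  breaks <- seq(r_range[1], r_range[2], by = bin_width)
  if (max(breaks) < r_range[2]) breaks <- c(breaks, r_range[2])
  nb <- length(breaks) - 1L
  hits <- matrix(0, length(residues), nb)
  for (f in seq_along(traj$frames)) {
    fr <- traj$frames[[f]]; cs <- traj$cosolvent[[f]]
    if (nrow(cs) == 0) next
    for (j in seq_along(residues)) {
      d <- .min_image_dist(cs, fr[res_atoms[[j]], , drop = FALSE], traj$box)
      dmin <- apply(d, 1, min)  # per cosolvent atom
      bin <- findInterval(dmin, breaks, rightmost.closed = TRUE)
      present <- unique(bin[bin >= 1 & bin <= nb])
      hits[j, present] <- hits[j, present] + 1
    }
  }
  map <- hits / length(traj$frames)
  rownames(map) <- residues
  structure(list(map = map, r = (breaks[-1] + breaks[-length(breaks)]) / 2,
                 residues = residues, bin_width = bin_width),
            class = "density_map")
}

#' @export
print.density_map <- function(x, ...) {
  cat(sprintf("Cosolvent density map: %d residues x %d bins (%.3g-%.3g A)\n",
              nrow(x$map), ncol(x$map), min(x$r) - x$bin_width / 2,
              max(x$r) + x$bin_width / 2))
  invisible(x)
}
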