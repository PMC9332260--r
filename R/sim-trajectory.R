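# Synthetic trajectory generators: harmonic (Gaussian) atomic fluctuations
# about a reference with optional whole-frame rigid-body motion, and
# cosolvent placement with residue-targeted enrichment.

#' Build a small helical toy structure
#'
#' An idealised alpha-helical C-alpha trace (2.3 A radius, 1.5 A rise,
#' 100 degrees per residue), optionally with N, C, O backbone atoms placed at
#' fixed offsets from each C-alpha. Intended as the reference for synthetic
#' trajectories and unit tests; it is not a real protein fold.
#'
#' @param n_res number of residues (>= 1).
#' @param backbone logical; add N, C, O atoms per residue.
#' @param chain chain id.
#' @return an [md_structure()].
#' @export
toy_structure <- function(n_res, backbone = FALSE, chain = "A") {
  if (n_res < 1) stop("need at least one residue")
  i <- seq_len(n_res)
  theta <- (i - 1) * 100 * pi / 180
  ca <- cbind(2.3 * cos(theta), 2.3 * sin(theta), 1.5 * (i - 1))
  if (!backbone) {
    at <- data.frame(name = "CA", elem = "C", resid = i, resname = "ALA",
                     chain = chain, x = ca[, 1], y = ca[, 2], z = ca[, 3],
                     stringsAsFactors = FALSE)
    return(md_structure(at))
  }
  off <- list(N = c(-1.2, 0.5, -0.4), CA = c(0, 0, 0),
              C = c(1.2, 0.4, 0.5), O = c(1.6, 1.3, 1.1))
  rows <- lapply(i, function(r) {
    do.call(rbind, lapply(names(off), function(nm) {
      data.frame(name = nm, elem = substr(nm, 1, 1), resid = r,
                 resname = "ALA", chain = chain,
                 x = ca[r, 1] + off[[nm]][1], y = ca[r, 2] + off[[nm]][2],
                 z = ca[r, 3] + off[[nm]][3], stringsAsFactors = FALSE)
    }))
  })
  md_structure(do.call(rbind, rows))
}

# Uniform random rotation matrix (quaternion method).
.random_rotation <- function() {
  q <- stats::rnorm(4); q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
           2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
           2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
         nrow = 3, byrow = TRUE)
}

#' Simulate a harmonic-fluctuation trajectory
#'
#' Each frame displaces every atom of the reference by an isotropic Gaussian
#' with per-coordinate standard deviation rmsf_target / sqrt(3), so the
#' sample RMSF of each atom converges to its target. Optionally every frame
#' is additionally rotated by a uniform random rotation and translated
#' (rigid-body motion a superposition step must remove).
#'
#' @param reference an [md_structure()].
#' @param rmsf_targets per-atom target fluctuations in Angstrom (>= 0);
#'   recycled if scalar.
#' @param n_frames number of frames (>= 2).
#' @param rigid_motion logical; apply random per-frame rotation+translation.
#' @param translation_sd sd of each rigid translation component, Angstrom.
#' @param box cubic box edge in Angstrom (metadata).
#' @param seed integer random seed.
#' @return an [md_trajectory()].
#' @export
sim_trajectory <- function(reference, rmsf_targets = 1, n_frames = 100,
                           rigid_motion = FALSE, translation_sd = 2,
                           box = NA_real_, seed = 1L) {
  stopifnot(inherits(reference, "md_structure"))
  n_at <- nrow(reference$atoms)
  rmsf_targets <- rep_len(rmsf_targets, n_at)
  if (any(rmsf_targets < 0)) stop("rmsf_targets must be non-negative")
  if (n_frames < 2) stop("need at least 2 frames")
  ref <- coords(reference)
  sd_xyz <- rmsf_targets / sqrt(3)
  frames <- .with_seed(seed, lapply(seq_len(n_frames), function(i) {
    m <- ref + matrix(stats::rnorm(n_at * 3, sd = sd_xyz), ncol = 3)
    if (rigid_motion) {
      R <- .random_rotation()
      tv <- stats::rnorm(3, sd = translation_sd)
      m <- m %*% R + matrix(tv, n_at, 3, byrow = TRUE)
    }
    m
  }))
  md_trajectory(reference, frames, box = box)
}

#' Simulate cosolvent-solvated frames with residue-targeted enrichment
#'
#' Point-particle cosolvent molecules are placed in a cubic box around the
#' (static or fluctuating) solute. Most particles are uniform in the box; for
#' each residue with an enrichment factor e > 1, extra particles are placed
#' in its first solvation shell (radii \code{r_shell}) so that the expected
#' shell occupancy is e times the uniform expectation. Shell positions are
#' drawn at a distance r from a random atom of the residue with density
#' proportional to r^2.
#'
#' @param reference an [md_structure()]; it is centred in the box.
#' @param n_frames number of frames.
#' @param cosolvent_count cosolvent particles per frame (> 0).
#' @param enrichment named numeric vector, residue id -> factor (>= 1).
#' @param box cubic box edge in Angstrom; must hold the solute.
#' @param r_shell length-2 shell radii in Angstrom.
#' @param rmsf_targets optional per-atom fluctuation of the solute (default
#'   0: static solute).
#' @param seed integer random seed.
#' @return an [md_trajectory()] with cosolvent.
#' @export
sim_solvated_trajectory <- function(reference, n_frames = 100,
                                    cosolvent_count = 50,
                                    enrichment = numeric(0), box = 50,
                                    r_shell = c(1.5, 3.5), rmsf_targets = 0,
                                    seed = 1L) {
  stopifnot(inherits(reference, "md_structure"))
  if (cosolvent_count <= 0) stop("cosolvent_count must be positive")
  if (length(enrichment) > 0) {
    if (any(enrichment < 1)) stop("enrichment factors must be >= 1")
    if (is.null(names(enrichment))) stop("enrichment must be named by residue id")
  }
  ref <- coords(reference)
  ctr <- colMeans(ref)
  ref <- sweep(ref, 2, ctr) + box / 2  # centre solute in the box
  if (any(ref < 0) || any(ref > box))
    stop("box too small to hold the solute")
  n_at <- nrow(ref)
  rmsf_targets <- rep_len(rmsf_targets, n_at)
  # expected uniform occupancy of one residue's shell
  v_shell <- 4 / 3 * pi * (r_shell[2]^3 - r_shell[1]^3)
  mu <- cosolvent_count * v_shell / box^3
  enr_res <- as.integer(names(enrichment))
  for (rj in enr_res)
    if (!any(reference$atoms$resid == rj))
      stop("enriched residue not in structure: ", rj)
  # each particle is placed in residue j's shell with probability
  # (e_j - 1) mu / N, else uniformly; shell occupancy expectation = e_j mu
  p_shell <- (enrichment - 1) * mu / cosolvent_count
  if (sum(p_shell) >= 1)
    stop("enrichment demands more particles than cosolvent_count")
  out <- .with_seed(seed, {
    frames <- vector("list", n_frames); cosolvent <- vector("list", n_frames)
    for (f in seq_len(n_frames)) {
      fr <- ref + matrix(stats::rnorm(n_at * 3, sd = rmsf_targets / sqrt(3)),
                         ncol = 3)
      dest <- if (length(enr_res) > 0)
        sample(c(0L, enr_res), cosolvent_count, replace = TRUE,
               prob = c(1 - sum(p_shell), p_shell))
      else rep(0L, cosolvent_count)
      pos <- matrix(stats::runif(cosolvent_count * 3, 0, box), ncol = 3)
      for (rj in enr_res) {
        sel <- which(dest == rj)
        if (length(sel) == 0) next
        res_at <- which(reference$atoms$resid == rj)
        anchor <- fr[res_at[sample.int(length(res_at), length(sel),
                                       replace = TRUE)], , drop = FALSE]
        u <- stats::runif(length(sel))
        r <- (u * (r_shell[2]^3 - r_shell[1]^3) + r_shell[1]^3)^(1 / 3)
        dir <- matrix(stats::rnorm(length(sel) * 3), ncol = 3)
        dir <- dir / sqrt(rowSums(dir^2))
        pos[sel, ] <- (anchor + r * dir) %% box
      }
      cosolvent[[f]] <- pos
      frames[[f]] <- fr
    }
    list(frames = frames, cosolvent = cosolvent)
  })
  centred <- reference$atoms
  centred$x <- ref[, 1]; centred$y <- ref[, 2]; centred$z <- ref[, 3]
  md_trajectory(md_structure(centred), out$frames,
                cosolvent = out$cosolvent, box = box)
}
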