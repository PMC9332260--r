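test_that("Kabsch superposition recovers constructed rigid transforms", {
  set.seed(1)
  pts <- matrix(rnorm(12), 4, 3)
  idk <- kabsch_superpose(pts, pts)
  expect_equal(idk$rotation, diag(3), tolerance = 1e-10)
  expect_equal(idk$translation, c(0, 0, 0), tolerance = 1e-10)
  expect_lt(idk$rmsd, 1e-12)

  Rz <- matrix(c(0, -1, 0, 1, 0, 0, 0, 0, 1), 3, 3, byrow = TRUE)  # 90 deg z
  tgt <- pts %*% Rz + matrix(c(1, 2, 3), 4, 3, byrow = TRUE)
  k <- kabsch_superpose(pts, tgt)
  expect_lt(k$rmsd, 1e-12)
  expect_equal(k$rotation, Rz, tolerance = 1e-10)
  expect_equal(k$translation, c(1, 2, 3), tolerance = 1e-10)
  expect_equal(det(k$rotation), 1, tolerance = 1e-10)
})

test_that("Kabsch RMSD equals the brute-force rotational minimum", {
  for (s in 1:8) {
    set.seed(s)
    a <- matrix(rnorm(15), 5, 3)
    b <- matrix(rnorm(15), 5, 3)
    expect_equal(kabsch_superpose(a, b)$rmsd, oracle_min_rmsd(a, b),
                 tolerance = 1e-6)
  }
})

test_that("degenerate point sets are rejected", {
  line <- cbind(1:5, 2 * (1:5), -1 * (1:5))
  expect_error(kabsch_superpose(line, line + 1), "degenerate")
  pt <- matrix(1, 4, 3)
  expect_error(kabsch_superpose(pt, pt), "degenerate")
  expect_error(kabsch_superpose(matrix(0, 2, 3), matrix(0, 2, 3)), "3 points")
})

test_that("RMSD series is zero for rigid motion and bounded for a defect", {
  st <- toy_structure(20, backbone = TRUE)
  trr <- sim_trajectory(st, 0, n_frames = 10, rigid_motion = TRUE, seed = 5)
  rs <- rmsd_series(trr)
  expect_lt(max(rs$rmsd), 1e-9)
  # one atom displaced by 1 A: full-fit RMSD <= 1/sqrt(n) and matches oracle
  n <- nrow(st$atoms)
  fr <- coords(st); fr[7, 1] <- fr[7, 1] + 1
  tr1 <- md_trajectory(st, list(fr, fr))
  rs1 <- rmsd_series(tr1, selection = "all")
  expect_lte(rs1$rmsd[1], 1 / sqrt(n) + 1e-12)
  expect_equal(rs1$rmsd[1], oracle_min_rmsd(fr, coords(st)), tolerance = 1e-6)
  # stationary input: trailing-window summary equals the full mean
  trs <- sim_trajectory(st, 1, n_frames = 400, seed = 6)
  rss <- rmsd_series(trs)
  expect_equal(rss$mean_last, rss$mean, tolerance = 0.05)
  expect_error(rmsd_series(trr, selection = "ZZ"), "empty")
})

test_that("radius of gyration matches hand-computed geometries", {
  expect_equal(radius_of_gyration(rbind(c(1, 0, 0), c(-1, 0, 0)), c(1, 1)), 1)
  expect_equal(radius_of_gyration(matrix(c(3, 4, 5), 1, 3), 2), 0)
  cube <- as.matrix(expand.grid(c(-1, 1), c(-1, 1), c(-1, 1)))
  expect_equal(radius_of_gyration(cube, rep(1, 8)), sqrt(3))
  # translation invariance, mass weighting
  expect_equal(radius_of_gyration(cube + 5, rep(2, 8)), sqrt(3))
  expect_error(radius_of_gyration(cube, rep(0, 8)), "mass")
})

test_that("SASA matches closed forms and the dense-grid oracle", {
  one <- sasa(matrix(0, 1, 3), radii = 1.7)
  expect_equal(one$total, 4 * pi * 3.1^2, tolerance = 1e-10)
  two_far <- sasa(rbind(c(0, 0, 0), c(100, 0, 0)), radii = c(1.7, 1.7))
  expect_equal(two_far$total, 2 * one$total, tolerance = 1e-10)
  # partial overlap against the dense-grid oracle
  xyz <- rbind(c(0, 0, 0), c(2.5, 0, 0))
  s <- sasa(xyz, radii = c(1.7, 1.5))
  expect_equal(s$total, oracle_sasa(xyz, c(1.7, 1.5)), tolerance = 0.02)
  # a small cluster too
  set.seed(3)
  cl <- matrix(rnorm(15, sd = 2), 5, 3)
  sc <- sasa(cl, radii = rep(1.7, 5))
  expect_equal(sc$total, oracle_sasa(cl, rep(1.7, 5)), tolerance = 0.02)
  # per-atom areas sum to the total and respect sphere bounds
  expect_equal(sum(sc$per_atom), sc$total)
  expect_true(all(sc$per_atom >= 0 & sc$per_atom <= 4 * pi * 3.1^2 + 1e-9))
  expect_error(sasa(xyz, radii = c(1.7, 1.5), n_points = 16), "floor")
})

test_that("RMSF is zero for static input and matches the chi moment", {
  st <- toy_structure(25)
  static <- md_trajectory(st, list(coords(st), coords(st), coords(st)))
  expect_equal(max(rmsf(static)$rmsf), 0)
  # isotropic per-coordinate sd 0.5 => RMSF = 0.5 sqrt(3)
  tr <- sim_trajectory(toy_structure(60), 0.5 * sqrt(3), n_frames = 2000,
                       seed = 8)
  pr <- rmsf(tr)
  expect_lt(mean(abs(pr$rmsf - 0.866)) / 0.866, 0.05)
})

test_that("generator RMSF targets are recovered despite rigid-body motion", {
  st <- toy_structure(100)
  set.seed(21)
  targets <- runif(100, 0.5, 3.0)
  tr <- sim_trajectory(st, targets, n_frames = 2000, rigid_motion = TRUE,
                       seed = 9)
  pr <- rmsf(tr)
  expect_lt(mean(abs(pr$rmsf - targets) / targets), 0.05)
})

test_that("flexibility differences subtract profiles residue-wise", {
  st <- toy_structure(40)
  base <- runif(40, 0.6, 1.4)
  p27 <- rmsf(sim_trajectory(st, base, n_frames = 1500, seed = 10),
              label = "27C")
  pT <- rmsf(sim_trajectory(st, 2 * base, n_frames = 1500, seed = 11),
             label = "45C")
  d0 <- delta_rmsf(p27, p27)
  expect_true(all(d0$rmsf == 0))
  d <- delta_rmsf(pT, p27)
  # doubling the targets adds ~one reference RMSF everywhere
  expect_lt(mean(abs(d$rmsf - p27$rmsf) / p27$rmsf), 0.10)
  # antisymmetry
  expect_equal(delta_rmsf(p27, pT)$rmsf, -d$rmsf)
  bad <- p27; bad$resid <- bad$resid + 1
  expect_error(delta_rmsf(pT, bad), "residues")
})

test_that("profile correlation behaves as a Pearson coefficient", {
  expect_equal(profile_correlation(c(1, 2, 3), c(3, 2, 1)), -1)
  p <- structure(list(resid = 1:30, rmsf = runif(30), selection = "CA",
                      label = NA_character_), class = "fluct_profile")
  expect_equal(profile_correlation(p, p), 1)
  expect_error(profile_correlation(c(1, 1, 1), c(1, 2, 3)), "variance")
  # null distribution: independent profiles rarely exceed |r| = 0.5
  set.seed(12)
  hits <- mean(replicate(1000, {
    abs(cor(rnorm(30), rnorm(30))) < 0.5
  }))
  expect_gte(hits, 0.95)
  # window restriction picks out the loop segment
  q <- p; q$rmsf <- p$rmsf + c(rep(0, 15), rep(10, 15)) * seq(0, 1, length.out = 30)
  expect_equal(profile_correlation(p, q, window = c(1, 15)), 1, tolerance = 0.2)
})

test_that("MDDF counting equals exhaustive enumeration on a toy system", {
  st <- toy_structure(4)
  ref <- coords(st) + 10
  stc <- st; stc$atoms[, c("x", "y", "z")] <- ref
  stc <- md_structure(stc$atoms)
  set.seed(13)
  cosolvent <- list(matrix(runif(9, 0, 25), 3, 3),
                    matrix(runif(9, 0, 25), 3, 3))
  traj <- md_trajectory(stc, list(ref, ref), cosolvent = cosolvent, box = 25)
  breaks <- seq(0, 12, 0.5)
  m <- mddf(traj, bin_width = 0.5, r_max = 12, seed = 14)
  expect_equal(m$counts, oracle_mddf_counts(traj, breaks))
  expect_error(mddf(traj, r_max = 20), "half the box")
})

test_that("uniform cosolvent gives a flat MDDF near 1 at large distance", {
  solv <- sim_solvated_trajectory(toy_structure(10), n_frames = 300,
                                  cosolvent_count = 120, box = 40, seed = 15)
  m <- mddf(solv, bin_width = 0.5, r_max = 12, seed = 16)
  far <- m$r > 6
  expect_lt(abs(mean(m$mddf[far]) - 1), 0.10)
  # no cosolvent anywhere near the solute: empty bins
  st <- toy_structure(4)
  ctr <- sweep(coords(st), 2, colMeans(coords(st))) + 20
  stc <- md_structure(within(st$atoms, { x <- ctr[, 1]; y <- ctr[, 2]; z <- ctr[, 3] }))
  # two corner particles whose minimum-image distance to the solute exceeds r_max
  traj <- md_trajectory(stc, list(ctr),
                        cosolvent = list(matrix(5, 2, 3)), box = 40)
  m0 <- mddf(traj, bin_width = 1, r_max = 10, seed = 17)
  expect_true(all(m0$counts == 0))
  expect_true(all(m0$mddf == 0))
})

test_that("density maps report the programmed shell enrichment", {
  en <- c("5" = 5)
  solv <- sim_solvated_trajectory(toy_structure(10), n_frames = 500,
                                  cosolvent_count = 40, enrichment = en,
                                  box = 50, seed = 18)
  dm <- residue_density_map(solv, residues = 1:10)
  tot <- rowSums(dm$map)
  expect_equal(unname(tot[5] / median(tot[-5])), 5, tolerance = 0.30)
  expect_true(all(dm$map >= 0 & dm$map <= 1))
  # probabilities are frequencies: more frames, same expectation
  solv2 <- sim_solvated_trajectory(toy_structure(10), n_frames = 1000,
                                   cosolvent_count = 40, enrichment = en,
                                   box = 50, seed = 19)
  dm2 <- residue_density_map(solv2, residues = 1:10)
  expect_equal(sum(dm2$map), sum(dm$map), tolerance = 0.15)
  expect_error(residue_density_map(solv, residues = integer(0)), "empty")
  expect_error(residue_density_map(solv, residues = 99), "not in structure")
})

test_that("statistics are invariant under a global rigid transform", {
  st <- toy_structure(15)
  tr <- sim_trajectory(st, 1, n_frames = 200, seed = 20)
  R <- rotvec_to_matrix(c(0.3, -1.1, 0.7))
  moved <- lapply(tr$frames, function(f) f %*% R + 3)
  tr2 <- md_trajectory(st, moved)
  expect_equal(rmsf(tr2)$rmsf, rmsf(tr)$rmsf, tolerance = 1e-8)
  expect_equal(rmsd_series(tr2, "CA")$rmsd, rmsd_series(tr, "CA")$rmsd,
               tolerance = 1e-8)
  expect_equal(radius_of_gyration(tr$frames[[1]] %*% R + 3,
                                  st$atoms$mass),
               radius_of_gyration(tr$frames[[1]], st$atoms$mass),
               tolerance = 1e-10)
  f <- tr$frames[[1]]
  # SASA is exactly translation invariant; rotations move the deterministic
  # point lattice relative to the atoms, so agreement is at sampling accuracy
  expect_equal(sasa(f + 3, radii = st$atoms$radius)$total,
               sasa(f, radii = st$atoms$radius)$total, tolerance = 1e-10)
  expect_equal(sasa(f %*% R + 3, radii = st$atoms$radius)$total,
               sasa(f, radii = st$atoms$radius)$total, tolerance = 0.02)
  # superposed RMSD never exceeds the unsuperposed RMSD
  raw <- sqrt(mean(rowSums((moved[[1]] - coords(st))^2)))
  expect_lte(rmsd_series(tr2, "CA")$rmsd[1], raw + 1e-12)
})

test_that("mobile-loop residue windows follow the two enzymes", {
  expect_equal(mobile_loop_residues("V.harveyi"), 262:291)
  expect_equal(mobile_loop_residues("P.leiognathi"), 261:290)
})

test_that("PDB and XYZ trajectory files round-trip through bio3d and text", {
  st <- toy_structure(6, backbone = TRUE)
  tr <- sim_trajectory(st, 0.4, n_frames = 3, seed = 22)
  f <- withr::local_tempfile(fileext = ".pdb")
  write_trajectory_pdb(tr, f)
  tr2 <- read_trajectory_pdb(f)
  expect_equal(length(tr2$frames), 3)
  expect_equal(tr2$frames[[3]], tr$frames[[3]], tolerance = 1e-3,
               ignore_attr = TRUE)
  expect_equal(tr2$reference$atoms$name, st$atoms$name)

  solv <- sim_solvated_trajectory(toy_structure(5), n_frames = 2,
                                  cosolvent_count = 8, box = 40, seed = 23)
  g <- withr::local_tempfile(fileext = ".pdb")
  write_trajectory_pdb(solv, g)
  s2 <- read_trajectory_pdb(g, cosolvent_resnames = "SUC", box = 40)
  expect_equal(nrow(s2$cosolvent[[1]]), 8)
  expect_equal(s2$cosolvent[[2]], solv$cosolvent[[2]], tolerance = 1e-3,
               ignore_attr = TRUE)

  h <- withr::local_tempfile(fileext = ".xyz")
  write_trajectory_xyz(solv, h)
  s3 <- read_trajectory_xyz(h)
  expect_equal(s3$box, 40)
  expect_equal(s3$cosolvent[[2]], solv$cosolvent[[2]], tolerance = 1e-5,
               ignore_attr = TRUE)
  # bio3d cross-check: superposed RMSD agrees with an independent fit
  pdb_rmsd <- bio3d::rmsd(as.numeric(t(tr$frames[[1]])),
                          as.numeric(t(tr$frames[[2]])), fit = TRUE)
  ours <- kabsch_superpose(tr$frames[[2]], tr$frames[[1]])$rmsd
  expect_equal(ours, pdb_rmsd, tolerance = 1e-3)
})
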