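test_that("RMSD kymographs vanish for identical or rigidly moved frames", {
  h <- ideal_helix(strrep("A", 20))
  ky <- rmsd_kymograph(list(h, h, h), 7)
  expect_true(all(ky < 1e-6))
  expect_equal(attr(ky, "centers"), 4:17)
  # whole-frame rigid motion is absorbed by superposition (local and global)
  th <- 0.7
  Rz <- rbind(c(cos(th), -sin(th), 0), c(sin(th), cos(th), 0), c(0, 0, 1))
  h2 <- h
  for (at in c("N", "CA", "C", "O")) h2[[at]] <- h[[at]] %*% t(Rz) + 5
  expect_true(all(rmsd_kymograph(list(h, h2), 7) < 1e-6))
  expect_true(all(rmsd_kymograph(list(h, h2), 7,
                                 superposition = "global") < 1e-6))
  expect_error(rmsd_kymograph(list(h), 7), "2 frames")
  expect_error(rmsd_kymograph(list(h, h), 8), "odd")
  expect_error(rmsd_kymograph(list(h, h), 21), "longer")
})

test_that("local deformation registers only in windows crossing the perturbed residues", {
  n <- 30
  phi <- rep(-57, n)
  psi <- rep(-47, n)
  f0 <- build_backbone(strrep("A", n), dihedral_state(phi, psi))
  phi2 <- phi
  psi2 <- psi
  phi2[10:16] <- phi2[10:16] + 25
  psi2[10:16] <- psi2[10:16] - 20
  f1 <- build_backbone(strrep("A", n), dihedral_state(phi2, psi2))
  ky <- rmsd_kymograph(list(f0, f1), 7)
  centers <- attr(ky, "centers")
  # windows entirely outside the perturbed span are internally rigid.
  # phi_10 leaves CA_10 itself fixed, so windows ending at residue 10
  # can also stay rigid; windows strictly inside see deformation.
  outside <- centers < 10 - 3 | centers > 16 + 3
  expect_true(all(ky[outside, 2] < 1e-6))
  expect_true(any(ky[!outside, 2] > 0.5))
  # brute-force per-window Kabsch oracle (absolute agreement)
  half <- 3
  for (ci in seq_along(centers)) {
    idx <- (centers[ci] - half):(centers[ci] + half)
    expect_lt(abs(ky[ci, 2] - oracle_kabsch(f0$CA[idx, ], f1$CA[idx, ])),
              1e-6)
  }
})

test_that("delta-Rg kymographs measure windowed expansion against frame 0", {
  h <- ideal_helix(strrep("A", 20))
  expect_true(all(delta_rg_kymograph(list(h, h), 7) == 0))
  # uniform doubling of coordinates adds exactly Rg0 per window
  h2 <- h
  for (at in c("N", "CA", "C", "O")) h2[[at]] <- 2 * h[[at]]
  ky <- delta_rg_kymograph(list(h, h2), 7)
  rg <- function(X) {
    X0 <- sweep(X, 2, colMeans(X))
    sqrt(mean(rowSums(X0^2)))
  }
  centers <- attr(ky, "centers")
  want <- vapply(centers, function(r) rg(h$CA[(r - 3):(r + 3), ]),
                 numeric(1))
  expect_equal(unname(ky[, 2]), want, tolerance = 1e-9)
  # the helix-to-extended pair expands every window
  e <- ideal_extended(strrep("A", 20))
  ky2 <- delta_rg_kymograph(list(h, e), 7)
  expect_true(all(ky2[, 2] > 0))
})

test_that("backbone hydrogen bonds follow the distance and linearity cutoffs", {
  h <- ideal_helix(strrep("A", 20))
  hb <- helix2beta:::backbone_hbonds(h)
  # every i,i+4 donor present in the helix interior
  expect_true(all((5:20) %in% hb$donor))
  expect_equal(hb$acceptor, hb$donor - 4L)
  # an extended single strand has no internal backbone bonds
  e <- ideal_extended(strrep("A", 20))
  expect_equal(nrow(helix2beta:::backbone_hbonds(e)), 0L)
  # pushing all donors past 3.0 A removes every bond (same geometry,
  # scaled 1.2x: angles preserved, distances over the cutoff)
  far <- h
  for (at in c("N", "CA", "C", "O")) far[[at]] <- 1.2 * h[[at]]
  expect_equal(nrow(helix2beta:::backbone_hbonds(far)), 0L)
  # kymograph: every interior window of the helix holds >= 3 bonds
  ky <- hbond_kymograph(list(h, h), 7)
  interior <- attr(ky, "centers") >= 8 & attr(ky, "centers") <= 14
  expect_true(all(ky[interior, ] >= 3))
})

test_that("the hydrogen-bond counter agrees with an O(n^2) pair scan", {
  tr <- short_run()
  for (i in c(1, n_frames(tr) %/% 2, n_frames(tr))) {
    fr <- trajectory_frame(tr, i)
    got <- helix2beta:::backbone_hbonds(fr)
    # independent direct scan
    n <- nrow(fr$N)
    unit <- function(v) v / sqrt(sum(v^2))
    found <- 0L
    for (d in 2:n) {
      H <- fr$N[d, ] + 1.01 * unit(unit(fr$N[d, ] - fr$C[d - 1, ]) +
                                   unit(fr$N[d, ] - fr$CA[d, ]))
      for (a in 1:n) {
        if (abs(d - a) < 2) next
        if (sqrt(sum((fr$N[d, ] - fr$O[a, ])^2)) > 3.0) next
        v1 <- unit(fr$N[d, ] - H)
        v2 <- unit(fr$O[a, ] - H)
        ang <- acos(max(-1, min(1, sum(v1 * v2)))) * 180 / pi
        if (180 - ang <= 20) found <- found + 1L
      }
    }
    expect_equal(nrow(got), found)
  }
})

test_that("dihedral series round-trip and flag chain breaks", {
  tr <- short_run()
  ser <- extract_dihedral_series(tr)
  expect_true(all(is.na(ser$phi[, 1])))
  expect_true(all(is.na(ser$psi[, ncol(ser$psi)])))
  # extraction from rebuilt structures reproduces the stored angles
  frames <- lapply(c(1, n_frames(tr)), function(i) trajectory_frame(tr, i))
  ser2 <- extract_dihedral_series(frames)
  expect_equal(ser2$phi[1, -1], tr$phi[1, -1], tolerance = 1e-3)
  expect_equal(ser2$psi[2, -20], tr$psi[n_frames(tr), -20],
               tolerance = 1e-3)
  # a torn chain is an error naming the frame
  broken <- frames[[1]]
  broken$CA[11:20, ] <- broken$CA[11:20, ] + 50
  expect_error(extract_dihedral_series(list(broken)), "chain break")
})

test_that("helical frames live in the helical Ramachandran basin", {
  s <- strrep("A", 12)
  tr <- toy_tmd_simulate(s, ideal_helix(s), ideal_extended(s),
                         tmd_schedule(K = 0, steps = 300,
                                      temperature = 0.05, seed = 2,
                                      flexibility = 0.1, save_every = 50))
  ser <- extract_dihedral_series(tr)
  b <- default_basins()$helix
  ph <- ser$phi[, -1]
  ps <- ser$psi[, -12]
  expect_true(all(ph >= b[1] & ph <= b[2]))
  expect_true(all(ps >= b[3] & ps <= b[4]))
})

test_that("basin occupancies are frame fractions with an explicit outside remainder", {
  ser <- structure(list(
    phi = matrix(c(NA, NA, -57, -139), 2, 2),
    psi = matrix(c(-47, 135, NA, NA), 2, 2),
    step = 0:1), class = "dihedral_series")
  # residue 1: psi defined only; residue 2: phi only -> both all-NA pairs
  occ <- ramachandran_occupancy(ser)
  expect_true(all(is.na(occ)))
  ser2 <- structure(list(
    phi = matrix(rep(c(-57, -139), 3), 2, 3),
    psi = matrix(rep(c(-47, 135), 3), 2, 3),
    step = 0:1), class = "dihedral_series")
  occ2 <- ramachandran_occupancy(ser2)
  expect_equal(unname(occ2[2, ]), c(0.5, 0.5, 0))
  expect_error(ramachandran_occupancy(
    ser2, list(a = c(-100, 0, -100, 0), b = c(-50, 50, -50, 50))),
    "overlap")
})

test_that("thermal breadth in the dihedral space grows with temperature", {
  s <- strrep("A", 12)
  run_at <- function(kT) {
    tr <- toy_tmd_simulate(s, ideal_helix(s), ideal_extended(s),
                           tmd_schedule(K = 0, steps = 800,
                                        temperature = kT, seed = 4,
                                        save_every = 10))
    occ <- ramachandran_occupancy(extract_dihedral_series(tr))
    mean(occ[2:11, "outside"])
  }
  expect_gt(run_at(30), run_at(0.1))
})

test_that("hot-site detection ranks constructed early-opening regions first", {
  # residues 10-17 cross their half-deformation at frame 100, the rest at
  # frame 800 (1000-frame kymograph)
  n <- 34
  mat <- matrix(0, n, 1000)
  for (r in 1:n) {
    at <- if (r + 3 >= 10 && r + 3 <= 17) 100 else 800
    mat[r, at:1000] <- 1
  }
  ky <- make_kymo(mat)
  rep <- detect_hot_sites(ky)
  expect_equal(nrow(rep), 1L)
  expect_equal(rep$priority, 1L)
  expect_equal(c(rep$start, rep$end), c(10L, 17L))
  # two tiers are ranked by opening time
  mat2 <- mat
  for (r in which(seq_len(n) + 3 >= 25 & seq_len(n) + 3 <= 30)) {
    mat2[r, ] <- 0
    mat2[r, 180:1000] <- 1
  }
  rep2 <- detect_hot_sites(make_kymo(mat2), early_frac = 0.4)
  expect_equal(nrow(rep2), 2L)
  expect_equal(rep2$start[rep2$priority == 1], 10L)
  expect_equal(rep2$start[rep2$priority == 2], 25L)
})

test_that("degenerate kymographs yield empty reports, not errors", {
  # all residues identical: no earliest-quartile run
  uni <- matrix(rep(c(0, 0.2, 0.6, 1, 1), times = 10), 10, 5, byrow = TRUE)
  rep1 <- detect_hot_sites(make_kymo(uni))
  expect_equal(nrow(rep1), 0L)
  # all-zero kymograph
  rep0 <- detect_hot_sites(make_kymo(matrix(0, 10, 5)))
  expect_equal(nrow(rep0), 0L)
  # residues with zero final deformation are never hot
  m <- matrix(0, 10, 6)
  m[1:6, 2:6] <- 1
  m[1:3, 2] <- 0.2
  rep2 <- detect_hot_sites(make_kymo(m), min_len = 2, early_frac = 0.5,
                           smooth_radius = 0)
  expect_equal(nrow(rep2), 1L)
  expect_equal(c(rep2$start, rep2$end), c(7L, 9L))
})

test_that("kymographs serialise as annotated TSV matrices", {
  h <- ideal_helix(strrep("A", 15))
  e <- ideal_extended(strrep("A", 15))
  ky <- rmsd_kymograph(list(h, e), 7)
  f <- withr::local_tempfile(fileext = ".tsv")
  write_kymograph(ky, f)
  expect_match(readLines(f, n = 1), "metric=RMSD window=7")
  back <- read.table(f, sep = "\t", header = TRUE, comment.char = "#")
  expect_equal(back$residue, 4:12)
  expect_equal(back[[3]], unname(ky[, 2]), tolerance = 1e-6)
})
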