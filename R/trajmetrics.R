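new_kymograph <- function(mat, metric, window, centers, steps) {
  structure(mat, metric = metric, window = as.integer(window),
            centers = as.integer(centers), steps = as.integer(steps),
            class = c("kymograph", "matrix"))
}

#' @export
print.kymograph <- function(x, ...) {
  cat(sprintf("kymograph '%s': %d centers (residues %d-%d) x %d frames, window %d\n",
              attr(x, "metric"), nrow(x), min(attr(x, "centers")),
              max(attr(x, "centers")), ncol(x), attr(x, "window")))
  invisible(x)
}

#' @export
plot.kymograph <- function(x, ...) {
  image(x = attr(x, "steps"), y = attr(x, "centers"), z = t(unclass(x)),
        xlab = "step", ylab = "residue", col = hcl.colors(64, "viridis"),
        main = attr(x, "metric"), ...)
  invisible(x)
}

window_centers <- function(n, window) {
  half <- (window - 1L) %/% 2L
  (half + 1L):(n - half)
}

# Kabsch rotation aligning B onto A (both centered); returns aligned B
align_onto <- function(A, B) {
  ca <- colMeans(A); cb <- colMeans(B)
  A0 <- sweep(A, 2, ca); B0 <- sweep(B, 2, cb)
  s <- svd(crossprod(B0, A0))
  d <- sign(det(s$v %*% t(s$u)))
  Rm <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  sweep(B0 %*% t(Rm), 2, ca, "+")
}

#' Windowed local-RMSD kymograph
#'
#' For each center residue r and frame t, the best-fit CA RMSD of the
#' window of residues centered at r between frame t and frame 0, with each
#' window superposed locally (default) so that rigid motion of the whole
#' segment does not register - only internal deformation does.  With
#' \code{superposition = "global"} each whole frame is first superposed on
#' frame 0 and window RMSDs are then taken without refitting.
#'
#' @param traj a \code{tmd_trajectory} or a list of \code{chain_structure}
#'   frames.
#' @param window odd window size (default 7).
#' @param superposition \code{"local"} (per window) or \code{"global"}.
#' @return a \code{kymograph} (rows = center residues, columns = frames,
#'   Angstrom).
#' @export
rmsd_kymograph <- function(traj, window = 7,
                           superposition = c("local", "global")) {
  superposition <- match.arg(superposition)
  cas <- frames_ca_list(traj)
  window <- as.integer(window)
  if (window %% 2L == 0L) stop("window must be odd")
  nf <- length(cas)
  if (nf < 2L) stop("need at least 2 frames")
  n <- nrow(cas[[1]])
  if (window > n) stop("window longer than the chain")
  centers <- window_centers(n, window)
  half <- (window - 1L) %/% 2L
  ref <- cas[[1]]
  mat <- matrix(0, nrow = length(centers), ncol = nf)
  for (t in 2:nf) {
    cur <- cas[[t]]
    if (superposition == "global") cur <- align_onto(ref, cur)
    for (ci in seq_along(centers)) {
      idx <- (centers[ci] - half):(centers[ci] + half)
      if (superposition == "local") {
        mat[ci, t] <- cpp_kabsch_rmsd(ref[idx, , drop = FALSE],
                                      cur[idx, , drop = FALSE])
      } else {
        mat[ci, t] <- sqrt(mean(rowSums((cur[idx, ] - ref[idx, ])^2)))
      }
    }
  }
  new_kymograph(mat, "RMSD", window, centers, frame_steps(traj, nf))
}

#' Windowed radius-of-gyration-change kymograph
#'
#' Cell (r, t) is Rg of the CA atoms in the window centered at r in frame t
#' minus the same window's Rg in frame 0, where Rg is the root-mean-square
#' distance of the CA atoms from their centroid.  Positive values mean
#' local expansion (helix opening).
#'
#' @inheritParams rmsd_kymograph
#' @return a \code{kymograph} (Angstrom).
#' @export
delta_rg_kymograph <- function(traj, window = 7) {
  cas <- frames_ca_list(traj)
  window <- as.integer(window)
  if (window %% 2L == 0L) stop("window must be odd")
  nf <- length(cas)
  if (nf < 2L) stop("need at least 2 frames")
  n <- nrow(cas[[1]])
  if (window > n) stop("window longer than the chain")
  centers <- window_centers(n, window)
  half <- (window - 1L) %/% 2L
  rg <- function(X) {
    X0 <- sweep(X, 2, colMeans(X))
    sqrt(mean(rowSums(X0^2)))
  }
  rgmat <- vapply(cas, function(ca)
    vapply(centers, function(r) rg(ca[(r - half):(r + half), ]), numeric(1)),
    numeric(length(centers)))
  mat <- rgmat - rgmat[, 1]
  new_kymograph(mat, "dRg", window, centers, frame_steps(traj, nf))
}

# backbone H-bond list of one frame: data.frame(donor, acceptor)
# criteria: donor N to acceptor O distance <= dist_cut, and the
# N-H...O angle within ang_cut degrees of linearity; amide H inferred at
# 1.01 A along the bisector of (N - C_prev) and (N - CA); |donor -
# acceptor| >= 2 to exclude covalent neighbours; donor 1 has no amide H.
backbone_hbonds <- function(frame, dist_cut = 3.0, ang_cut = 20) {
  stopifnot(inherits(frame, "chain_structure"))
  N <- frame$N; CA <- frame$CA; C <- frame$C; O <- frame$O
  if (anyNA(N) || anyNA(CA) || anyNA(C) || anyNA(O)) {
    bad <- which(apply(is.na(N) | is.na(CA) | is.na(C) | is.na(O), 1, any))
    stop("missing backbone atoms at residue ", paste(bad, collapse = ", "))
  }
  n <- nrow(N)
  unit <- function(v) v / sqrt(sum(v^2))
  H <- matrix(NA_real_, n, 3)
  for (i in 2:n)
    H[i, ] <- N[i, ] + 1.01 * unit(unit(N[i, ] - C[i - 1, ]) +
                                   unit(N[i, ] - CA[i, ]))
  don <- integer(0); acc <- integer(0)
  for (d in 2:n) {
    dv <- sqrt(colSums((t(O) - N[d, ])^2))
    for (a in which(dv <= dist_cut)) {
      if (abs(d - a) < 2L) next
      hd <- unit(N[d, ] - H[d, ])
      ha <- unit(O[a, ] - H[d, ])
      ang <- acos(pmin(1, pmax(-1, sum(hd * ha)))) * 180 / pi
      if (180 - ang <= ang_cut) {
        don <- c(don, d); acc <- c(acc, a)
      }
    }
  }
  data.frame(donor = don, acceptor = acc)
}

#' Windowed backbone hydrogen-bond kymograph
#'
#' Cell (r, t) counts the backbone N-H...O hydrogen bonds whose donor
#' residue lies in the window centered at r in frame t.  Geometric
#' criteria: donor(N)-acceptor(O) distance at most 3.0 Angstrom and
#' deviation of the N-H...O angle from linearity at most 20 degrees; the
#' amide hydrogen is inferred geometrically (the model carries no explicit
#' hydrogens).
#'
#' @inheritParams rmsd_kymograph
#' @param dist_cut donor-acceptor distance cutoff (Angstrom).
#' @param ang_cut angular deviation cutoff from linearity (degrees).
#' @return a \code{kymograph} of counts.
#' @export
hbond_kymograph <- function(traj, window = 7, dist_cut = 3.0, ang_cut = 20) {
  frames <- frames_structure_list(traj)
  window <- as.integer(window)
  if (window %% 2L == 0L) stop("window must be odd")
  nf <- length(frames)
  n <- nrow(frames[[1]]$CA)
  if (window > n) stop("window longer than the chain")
  centers <- window_centers(n, window)
  half <- (window - 1L) %/% 2L
  mat <- matrix(0L, nrow = length(centers), ncol = nf)
  for (t in seq_len(nf)) {
    hb <- backbone_hbonds(frames[[t]], dist_cut, ang_cut)
    if (nrow(hb) == 0L) next
    cnt <- tabulate(hb$donor, nbins = n)
    cs <- cumsum(c(0L, cnt))
    mat[, t] <- cs[centers + half + 1L] - cs[centers - half]
  }
  new_kymograph(mat, "HB", window, centers, frame_steps(traj, nf))
}

frames_ca_list <- function(traj) {
  if (inherits(traj, "tmd_trajectory")) return(ca_frames(traj))
  if (is.list(traj) && all(vapply(traj, inherits, TRUE, "chain_structure")))
    return(lapply(traj, `[[`, "CA"))
  stop("expected a tmd_trajectory or a list of chain_structure frames")
}

frames_structure_list <- function(traj) {
  if (inherits(traj, "tmd_trajectory"))
    return(lapply(seq_len(n_frames(traj)), function(i)
      trajectory_frame(traj, i)))
  if (is.list(traj) && all(vapply(traj, inherits, TRUE, "chain_structure")))
    return(traj)
  stop("expected a tmd_trajectory or a list of chain_structure frames")
}

frame_steps <- function(traj, nf) {
  if (inherits(traj, "tmd_trajectory")) traj$step else seq_len(nf) - 1L
}

#' Per-residue dihedral time series of a trajectory
#'
#' @param traj a \code{tmd_trajectory} (whose dihedrals are stored) or a
#'   list of \code{chain_structure} frames (dihedrals extracted; a CA-CA
#'   distance above 4.5 Angstrom is treated as a chain break and is an
#'   error).
#' @return a \code{dihedral_series}: matrices \code{phi}, \code{psi}
#'   (frames x residues, degrees, terminal undefined angles \code{NA}).
#' @export
extract_dihedral_series <- function(traj) {
  if (inherits(traj, "tmd_trajectory")) {
    phi <- traj$phi; psi <- traj$psi
    phi[, 1] <- NA_real_
    psi[, ncol(psi)] <- NA_real_
    return(structure(list(phi = phi, psi = psi, step = traj$step),
                     class = "dihedral_series"))
  }
  frames <- frames_structure_list(traj)
  for (f in seq_along(frames)) {
    ca <- frames[[f]]$CA
    gap <- sqrt(rowSums((ca[-1, , drop = FALSE] -
                         ca[-nrow(ca), , drop = FALSE])^2))
    if (any(gap > 4.5))
      stop("chain break (CA-CA > 4.5 A) in frame ", f, " after residue ",
           which(gap > 4.5)[1])
  }
  ds <- lapply(frames, extract_dihedrals)
  structure(list(phi = do.call(rbind, lapply(ds, `[[`, "phi")),
                 psi = do.call(rbind, lapply(ds, `[[`, "psi")),
                 step = seq_along(frames) - 1L),
            class = "dihedral_series")
}

#' Canonical Ramachandran basins
#'
#' Rectangular (phi, psi) boxes for the alpha-helical and extended regions
#' of the Ramachandran plot, in degrees.
#'
#' @return named list of c(phi_min, phi_max, psi_min, psi_max) vectors.
#' @export
default_basins <- function() {
  list(helix = c(-100, -30, -80, -5),
       extended = c(-180, -90, 90, 180))
}

#' Per-residue Ramachandran basin occupancy
#'
#' Fraction of frames each residue spends in each named (phi, psi)
#' rectangle; the remainder (per residue) lies outside all basins.
#'
#' @param series a \code{dihedral_series}.
#' @param basins named list of c(phi_min, phi_max, psi_min, psi_max)
#'   rectangles (degrees); must be pairwise disjoint.
#' @return matrix residues x (basins + "outside"); rows sum to 1 for
#'   residues with defined dihedrals, NA for terminal residues.
#' @export
ramachandran_occupancy <- function(series, basins = default_basins()) {
  stopifnot(inherits(series, "dihedral_series"))
  bn <- names(basins)
  for (i in seq_along(basins)) for (j in seq_along(basins)) {
    if (i >= j) next
    a <- basins[[i]]; b <- basins[[j]]
    if (a[1] < b[2] && b[1] < a[2] && a[3] < b[4] && b[3] < a[4])
      stop("basins '", bn[i], "' and '", bn[j], "' overlap")
  }
  n <- ncol(series$phi)
  out <- matrix(NA_real_, n, length(basins) + 1L,
                dimnames = list(NULL, c(bn, "outside")))
  for (r in seq_len(n)) {
    ph <- series$phi[, r]; ps <- series$psi[, r]
    if (all(is.na(ph)) || all(is.na(ps))) next
    ok <- !is.na(ph) & !is.na(ps)
    fr <- vapply(basins, function(b)
      mean(ph[ok] >= b[1] & ph[ok] <= b[2] &
           ps[ok] >= b[3] & ps[ok] <= b[4]), numeric(1))
    out[r, ] <- c(fr, 1 - sum(fr))
  }
  out
}

#' First frame at which a residue leaves a dihedral basin
#'
#' @param series a \code{dihedral_series}.
#' @param basin c(phi_min, phi_max, psi_min, psi_max) rectangle (degrees).
#' @return integer vector (per residue) of the first frame index outside
#'   the basin; NA if the residue never leaves (or has undefined angles).
#' @export
first_exit_frame <- function(series, basin = default_basins()$helix) {
  stopifnot(inherits(series, "dihedral_series"))
  n <- ncol(series$phi)
  vapply(seq_len(n), function(r) {
    ph <- series$phi[, r]; ps <- series$psi[, r]
    if (all(is.na(ph)) || all(is.na(ps))) return(NA_integer_)
    ok <- !is.na(ph) & !is.na(ps)
    outside <- which(ok & !(ph >= basin[1] & ph <= basin[2] &
                            ps >= basin[3] & ps <= basin[4]))
    if (length(outside) == 0L) NA_integer_ else outside[1]
  }, integer(1))
}

#' Detect hot sites (earliest-opening regions) from an RMSD kymograph
#'
#' Each center residue's opening time is the first frame at which its cell
#' exceeds \code{threshold_frac} of that residue's final-frame value
#' (residues with zero final deformation never open).  Hot regions are
#' contiguous runs, at least \code{min_len} residues long, of residues
#' whose opening time lies strictly below the \code{early_frac} quantile
#' of all finite opening times; regions are ranked into priorities by
#' their median opening time (priority 1 = earliest).  A kymograph in
#' which every residue opens at the same time yields no regions.
#'
#' @param kymo an RMSD-type \code{kymograph}.
#' @param threshold_frac fraction of the final deformation that defines
#'   "opened" (default 0.5).
#' @param min_len minimum region length in residues (default 4).
#' @param early_frac quantile of opening times considered "early"
#'   (default 0.25).
#' @param smooth_radius moving-median half-width (in center residues)
#'   applied to the opening times before thresholding (default 3,
#'   matching the 7-residue kymograph window; 0 disables smoothing).
#' @return a \code{hot_site_report}: data.frame(priority, start, end,
#'   opening_frame) with attribute \code{opening_time} (per-center vector;
#'   smoothed values are used for selection, raw values are reported).
#' @export
detect_hot_sites <- function(kymo, threshold_frac = 0.5, min_len = 4,
                             early_frac = 0.25, smooth_radius = 3) {
  stopifnot(inherits(kymo, "kymograph"))
  mat <- unclass(kymo)
  centers <- attr(kymo, "centers")
  nf <- ncol(mat)
  final <- mat[, nf]
  opening <- rep(Inf, nrow(mat))
  for (i in seq_len(nrow(mat))) {
    if (final[i] <= 0) next
    at <- which(mat[i, ] >= threshold_frac * final[i])
    if (length(at) > 0L) opening[i] <- at[1]
  }
  empty <- data.frame(priority = integer(0), start = integer(0),
                      end = integer(0), opening_frame = numeric(0))
  # window-matched median filter: kymograph columns are already averaged
  # over the window, so the derived opening-time statistic is smoothed at
  # the same scale; stops single noisy centers fragmenting a region
  smoothed <- opening
  if (smooth_radius > 0) {
    for (i in seq_along(opening)) {
      lo <- max(1L, i - smooth_radius)
      hi <- min(length(opening), i + smooth_radius)
      smoothed[i] <- median(opening[lo:hi])
    }
  }
  fin <- smoothed[is.finite(smoothed)]
  if (length(fin) == 0L)
    return(structure(empty, opening_time = setNames(opening, centers),
                     class = c("hot_site_report", "data.frame")))
  # at or below the early quantile but strictly before the last opener:
  # a flat opening-time profile (all residues opening together) selects
  # nothing, while integer-valued ties at the quantile are kept
  q <- quantile(fin, early_frac, names = FALSE, type = 7)
  sel <- which(is.finite(smoothed) & smoothed <= q & smoothed < max(fin))
  runs <- runs_of(sel, min_len)
  if (nrow(runs) == 0L)
    return(structure(empty, opening_time = setNames(opening, centers),
                     class = c("hot_site_report", "data.frame")))
  med <- vapply(seq_len(nrow(runs)), function(i)
    median(opening[runs$start[i]:runs$end[i]]), numeric(1))
  ord <- order(med)
  rep_df <- data.frame(priority = seq_along(ord),
                       start = centers[runs$start[ord]],
                       end = centers[runs$end[ord]],
                       opening_frame = med[ord])
  structure(rep_df, opening_time = setNames(opening, centers),
            class = c("hot_site_report", "data.frame"))
}

#' @export
print.hot_site_report <- function(x, ...) {
  if (nrow(x) == 0L) {
    cat("hot_site_report: no hot regions detected\n")
  } else {
    cat("hot_site_report:", nrow(x), "region(s)\n")
    print.data.frame(x, row.names = FALSE)
  }
  invisible(x)
}

#' Write a kymograph as a TSV matrix
#'
#' Rows = center residues, columns = frames; the header line declares the
#' metric, window and coordinate convention.
#'
#' @param kymo a \code{kymograph}.
#' @param path output path.
#' @export
write_kymograph <- function(kymo, path) {
  stopifnot(inherits(kymo, "kymograph"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# kymograph metric=%s window=%d residues=1-based inclusive",
                     attr(kymo, "metric"), attr(kymo, "window")), con)
  df <- data.frame(residue = attr(kymo, "centers"),
                   unclass(kymo), check.names = FALSE)
  names(df)[-1] <- paste0("step", attr(kymo, "steps"))
  suppressWarnings(write.table(df, con, sep = "\t", row.names = FALSE,
                               quote = FALSE))
  invisible(path)
}
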