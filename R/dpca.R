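#' Dihedral principal component analysis
#'
#' PCA on the circular embedding of the backbone dihedrals: every defined
#' angle theta contributes the pair (cos theta, sin theta) as columns, the
#' columns are mean-centered, and the covariance matrix is
#' eigendecomposed (via the singular value decomposition of the centered
#' data).  The embedding removes the periodicity artifacts of raw angles.
#' Angles that are undefined in every frame (the first residue's phi, the
#' last residue's psi) are dropped.
#'
#' @param series a \code{dihedral_series} (see
#'   \code{\link{extract_dihedral_series}}) or a \code{tmd_trajectory}.
#' @param n_components_kept number of leading components retained for
#'   downstream clustering (default 3).
#' @return a \code{dpca} object: \code{eigenvalues} (non-increasing),
#'   \code{variance_fractions} (summing to 1 when total variance is
#'   positive, all zero for a constant trajectory), \code{projections}
#'   (frames x components), \code{loadings}, \code{center} and
#'   \code{n_components_kept}.
#' @export
dihedral_pca <- function(series, n_components_kept = 3) {
  if (inherits(series, "tmd_trajectory"))
    series <- extract_dihedral_series(series)
  stopifnot(inherits(series, "dihedral_series"))
  nf <- nrow(series$phi)
  if (nf < 2L) stop("need at least 2 frames for dPCA")
  ang <- cbind(series$phi, series$psi) * pi / 180
  defined <- colSums(!is.na(ang)) == nf
  if (!any(defined)) stop("no defined dihedrals")
  ang <- ang[, defined, drop = FALSE]
  X <- cbind(cos(ang), sin(ang))
  pr <- prcomp(X, center = TRUE, scale. = FALSE)
  ev <- pr$sdev^2
  tot <- sum(ev)
  vf <- if (tot > 0) ev / tot else rep(0, length(ev))
  structure(list(eigenvalues = ev, variance_fractions = vf,
                 projections = pr$x, loadings = pr$rotation,
                 center = pr$center,
                 n_components_kept = as.integer(n_components_kept),
                 step = series$step),
            class = "dpca")
}

#' @export
print.dpca <- function(x, ...) {
  cat(sprintf("dpca: %d frames, %d embedded coordinates\n",
              nrow(x$projections), length(x$center)))
  k <- min(5L, length(x$eigenvalues))
  cat("leading variance fractions:",
      paste(sprintf("%.3f", x$variance_fractions[1:k]), collapse = " "), "\n")
  invisible(x)
}

#' @export
summary.dpca <- function(object, ...) {
  k <- min(10L, length(object$eigenvalues))
  data.frame(component = seq_len(k),
             eigenvalue = object$eigenvalues[1:k],
             variance_fraction = object$variance_fractions[1:k],
             cumulative = cumsum(object$variance_fractions)[1:k])
}

#' @export
plot.dpca <- function(x, components = c(1, 2), ...) {
  plot(x$projections[, components[1]], x$projections[, components[2]],
       xlab = paste0("dPC", components[1]),
       ylab = paste0("dPC", components[2]), pch = 16,
       col = "#00000040", ...)
  invisible(x)
}

# separable gaussian smoothing of a k-dimensional count array
# (zero-padded borders; kernel truncated at 3 sigma)
smooth_array <- function(arr, sigma) {
  if (sigma <= 0) return(arr)
  half <- max(1L, ceiling(3 * sigma))
  kern <- exp(-((-half):half)^2 / (2 * sigma^2))
  kern <- kern / sum(kern)
  dims <- dim(arr)
  nd <- length(dims)
  for (d in seq_len(nd)) {
    perm <- c(d, setdiff(seq_len(nd), d))
    m <- matrix(aperm(arr, perm), nrow = dims[d])
    n <- nrow(m)
    padded <- rbind(matrix(0, half, ncol(m)), m, matrix(0, half, ncol(m)))
    sm <- matrix(0, n, ncol(m))
    for (j in seq_along(kern))
      sm <- sm + kern[j] * padded[j:(j + n - 1L), , drop = FALSE]
    arr <- aperm(array(sm, dims[perm]), order(perm))
  }
  arr
}

# neighbour offsets (3^k - 1 surrounding cells) for a k-dim grid
neighbour_offsets <- function(k) {
  g <- as.matrix(expand.grid(rep(list(-1:1), k)))
  g[rowSums(g != 0) > 0, , drop = FALSE]
}

#' Peak-picking density clustering of dPCA projections
#'
#' Histograms the first k principal-component projections on a regular
#' k-dimensional grid, smooths the counts with a separable Gaussian
#' kernel, and finds the local maxima of the smoothed density that rise
#' above \code{floor_frac} of the global maximum - these are the peaks
#' (clusters).  Every occupied cell is then assigned by steepest ascent
#' through its 3^k - 1 neighbourhood; frames whose ascent terminates in a
#' local maximum below the floor remain unassigned.  Cluster ids are
#' ordered by decreasing peak height.
#'
#' @param projections a \code{dpca} object or a numeric frames x
#'   components matrix.
#' @param k number of leading components used (default 3).
#' @param grid_bins histogram bins per axis (default 32).
#' @param floor_frac peak-eligibility floor as a fraction of the global
#'   smoothed maximum (default 0.1).
#' @param smooth_sigma Gaussian smoothing width in grid cells (default
#'   2); smoothing suppresses the spurious local maxima of a sparse
#'   histogram.
#' @return a \code{cluster_set}: per-frame integer \code{labels} (NA =
#'   unassigned), \code{populations} (percent of all frames per cluster),
#'   \code{n_clusters}, \code{unassigned_percent} and the grid metadata.
#' @export
peak_pick_clusters <- function(projections, k = 3, grid_bins = 32,
                               floor_frac = 0.1, smooth_sigma = 2) {
  if (inherits(projections, "dpca")) {
    k <- min(k, ncol(projections$projections))
    P <- projections$projections[, seq_len(k), drop = FALSE]
  } else {
    P <- as.matrix(projections)
    k <- min(k, ncol(P))
    P <- P[, seq_len(k), drop = FALSE]
  }
  nf <- nrow(P)
  if (nf < 2L) stop("need at least 2 frames")
  grid_bins <- as.integer(grid_bins)

  # bin assignment per dimension (equal-width over the data range)
  bin_idx <- matrix(1L, nf, k)
  for (d in seq_len(k)) {
    rng <- range(P[, d])
    if (diff(rng) == 0) next
    w <- diff(rng) / grid_bins
    bin_idx[, d] <- pmin(grid_bins, pmax(1L, 1L + floor((P[, d] - rng[1]) / w)))
  }
  dims <- rep(grid_bins, k)
  cell_of_frame <- as.integer(1 +
    (bin_idx - 1) %*% cumprod(c(1, dims[-k])))
  counts <- array(0, dim = dims)
  tab <- table(cell_of_frame)
  counts[as.integer(names(tab))] <- as.integer(tab)

  if (length(tab) == 1L) {
    warning("all frames fall in a single grid cell; returning one cluster")
    labels <- rep(1L, nf)
    return(new_cluster_set(labels, nf, grid_bins, floor_frac, k))
  }

  dens <- smooth_array(counts, smooth_sigma)
  gmax <- max(dens)
  floor_val <- floor_frac * gmax

  offs <- neighbour_offsets(k)
  stride <- cumprod(c(1, dims[-k]))
  lin_off <- as.integer(offs %*% stride)

  # coordinates of every cell we must route (occupied cells)
  occ <- as.integer(names(tab))
  coord_of <- function(lin) {
    lin0 <- lin - 1L
    sapply(seq_len(k), function(d) (lin0 %/% stride[d]) %% dims[d] + 1L)
  }

  # steepest-ascent successor of each cell (0 = self is a local max)
  succ <- new.env(hash = TRUE)
  ascend <- function(lin) {
    path <- integer(0)
    cur <- lin
    repeat {
      key <- as.character(cur)
      memo <- succ[[key]]
      if (!is.null(memo)) { top <- memo; break }
      path <- c(path, cur)
      co <- coord_of(cur)
      nb <- sweep(offs, 2, co, "+")
      inside <- rowSums(nb >= 1 & sweep(nb, 2, dims, "<=")) == k
      cand <- cur + lin_off[inside]
      best <- cand[which.max(dens[cand])]
      if (length(best) == 0L || dens[best] <= dens[cur]) { top <- cur; break }
      cur <- best
    }
    for (p in path) succ[[as.character(p)]] <- top
    top
  }
  top_of <- vapply(occ, ascend, integer(1))

  peaks <- sort(unique(top_of))
  peaks <- peaks[dens[peaks] >= floor_val]
  if (length(peaks) == 0L) peaks <- unique(top_of)[which.max(dens[unique(top_of)])]
  peaks <- peaks[order(-dens[peaks])]

  lab_of_cell <- setNames(rep(NA_integer_, length(occ)), occ)
  for (i in seq_along(peaks))
    lab_of_cell[as.character(occ[top_of == peaks[i]])] <- i
  labels <- unname(lab_of_cell[as.character(cell_of_frame)])
  new_cluster_set(labels, nf, grid_bins, floor_frac, k)
}

new_cluster_set <- function(labels, nf, grid_bins, floor_frac, k) {
  ids <- sort(unique(labels[!is.na(labels)]))
  pop <- vapply(ids, function(i) 100 * sum(labels == i, na.rm = TRUE) / nf,
                numeric(1))
  structure(list(labels = labels,
                 populations = setNames(pop, paste0("cluster", ids)),
                 n_clusters = length(ids),
                 unassigned_percent = 100 * mean(is.na(labels)),
                 grid_bins = grid_bins, floor_frac = floor_frac, k = k,
                 representatives = NULL),
            class = "cluster_set")
}

#' @export
print.cluster_set <- function(x, ...) {
  cat(sprintf("cluster_set: %d cluster(s), %.1f%% of frames unassigned\n",
              x$n_clusters, x$unassigned_percent))
  print(round(x$populations, 2))
  if (!is.null(x$representatives)) {
    cat("representative frames:\n")
    print(x$representatives)
  }
  invisible(x)
}

#' Centroid-nearest representative frame of each cluster
#'
#' The representative of a cluster is the assigned frame whose projection
#' is closest (Euclidean) to the cluster's projection centroid; ties break
#' to the lowest frame index.
#'
#' @param clusters a \code{cluster_set}.
#' @param projections the \code{dpca} object (or matrix) the clusters were
#'   derived from.
#' @return the \code{cluster_set} with a named integer vector
#'   \code{representatives} of frame indices.
#' @export
cluster_representatives <- function(clusters, projections) {
  stopifnot(inherits(clusters, "cluster_set"))
  if (inherits(projections, "dpca"))
    projections <- projections$projections
  P <- as.matrix(projections)[, seq_len(clusters$k), drop = FALSE]
  ids <- seq_len(clusters$n_clusters)
  reps <- vapply(ids, function(i) {
    member <- which(!is.na(clusters$labels) & clusters$labels == i)
    if (length(member) == 0L) stop("cluster ", i, " is empty")
    ctr <- colMeans(P[member, , drop = FALSE])
    d2 <- rowSums((P[member, , drop = FALSE] -
                   matrix(ctr, length(member), length(ctr), byrow = TRUE))^2)
    member[which.min(d2)]  # which.min takes the first (lowest index) tie
  }, integer(1))
  clusters$representatives <- setNames(reps, paste0("cluster", ids))
  clusters
}

#' Pairwise best-fit RMSD matrix between structures
#'
#' @param structures named list of \code{chain_structure}s or CA
#'   coordinate matrices with equal CA counts (e.g. the helical start, the
#'   extended target and the cluster representatives).
#' @return symmetric matrix of CA RMSDs (Angstrom) with zero diagonal.
#' @export
rmsd_matrix <- function(structures) {
  mats <- lapply(structures, as_ca_matrix)
  n <- length(mats)
  if (n < 2L) stop("need at least 2 structures")
  counts <- vapply(mats, nrow, 1L)
  if (length(unique(counts)) != 1L)
    stop("CA counts differ across structures: ",
         paste(counts, collapse = ", "))
  nm <- names(structures)
  if (is.null(nm)) nm <- paste0("structure", seq_len(n))
  M <- matrix(0, n, n, dimnames = list(nm, nm))
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    M[i, j] <- M[j, i] <- kabsch_rmsd(mats[[i]], mats[[j]])
  }
  M
}

#' Write dPCA projections and cluster labels as CSV
#'
#' @param dpca a \code{dpca} object.
#' @param clusters optional \code{cluster_set}.
#' @param path output path.
#' @export
write_dpca_csv <- function(dpca, clusters = NULL, path) {
  stopifnot(inherits(dpca, "dpca"))
  k <- dpca$n_components_kept
  df <- data.frame(frame = seq_len(nrow(dpca$projections)),
                   dpca$projections[, seq_len(k), drop = FALSE])
  names(df)[-1] <- paste0("dPC", seq_len(k))
  if (!is.null(clusters)) df$cluster <- clusters$labels
  write.table(df, path, sep = ",", row.names = FALSE, quote = FALSE)
  invisible(path)
}
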