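# Shared fixtures built in code.  Expensive toy-TMD runs are memoised so
# several test files can analyse the same trajectories.

sim_cache <- new.env(parent = emptyenv())

toy_seq40 <- function() strrep("AEKVAGLK", 5)

planted_segments <- function() list(c(8, 14), c(24, 30))

planted_flexibility <- function(n = 40) {
  flex <- rep(0.1, n)
  for (seg in planted_segments()) flex[seg[1]:seg[2]] <- 1
  flex
}

# full-scale planted run (40-mer, 5000 steps) used by the recovery tests
planted_run <- function(seed) {
  key <- paste0("planted", seed)
  if (is.null(sim_cache[[key]])) {
    s <- toy_seq40()
    sim_cache[[key]] <- toy_tmd_simulate(
      s, ideal_helix(s), ideal_extended(s),
      tmd_schedule(seed = seed, flexibility = planted_flexibility()))
  }
  sim_cache[[key]]
}

# short uniform-flexibility run for cheap structural checks
short_run <- function(seed = 3, steps = 600, n = 20) {
  key <- paste0("short", seed, "_", steps, "_", n)
  if (is.null(sim_cache[[key]])) {
    s <- strrep("AEKV", n %/% 4)
    sim_cache[[key]] <- toy_tmd_simulate(
      s, ideal_helix(s), ideal_extended(s),
      tmd_schedule(steps = steps, seed = seed, save_every = max(1, steps %/% 60)))
  }
  sim_cache[[key]]
}

jaccard_span <- function(a, b) {
  ia <- seq(a[1], a[2])
  ib <- seq(b[1], b[2])
  length(intersect(ia, ib)) / length(union(ia, ib))
}

# mean over planted loci of the best-matching detected region's Jaccard
recovery_jaccard <- function(report) {
  mean(vapply(planted_segments(), function(p) {
    if (nrow(report) == 0L) return(0)
    max(vapply(seq_len(nrow(report)), function(i)
      jaccard_span(c(report$start[i], report$end[i]), p), numeric(1)))
  }, numeric(1)))
}

random_ss_dataset <- function(n_entries = 10, len_range = c(5, 40)) {
  seqs <- character(n_entries)
  labs <- character(n_entries)
  for (i in seq_len(n_entries)) {
    len <- sample(len_range[1]:len_range[2], 1)
    seqs[i] <- paste(sample(c("A", "C", "D", "E", "F", "G", "H", "I", "K",
                              "L", "M", "N", "P", "Q", "R", "S", "T", "V",
                              "W", "Y"), len, replace = TRUE), collapse = "")
    labs[i] <- paste(sample(c("H", "E", "C"), len, replace = TRUE),
                     collapse = "")
  }
  ss_dataset(seqs, labs)
}

# brute-force propensity oracle: direct tallying of F(R,S), F(R), N_S, N
oracle_propensities <- function(dataset) {
  aa <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
          "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")
  cls <- c("H", "E", "C")
  F_RS <- matrix(0, 20, 3, dimnames = list(aa, cls))
  for (e in dataset$entries) {
    for (j in seq_along(e$sequence)) {
      r <- e$sequence[j]
      if (!r %in% aa) next
      F_RS[r, e$labels[j]] <- F_RS[r, e$labels[j]] + 1
    }
  }
  N_S <- colSums(F_RS)
  N <- sum(N_S)
  P <- matrix(NA_real_, 20, 3, dimnames = list(aa, cls))
  for (r in aa) {
    F_R <- sum(F_RS[r, ])
    if (F_R == 0) next
    for (s in cls) P[r, s] <- (F_RS[r, s] / F_R) / (N_S[s] / N)
  }
  P
}

# independent R-side Kabsch RMSD (SVD route, proper rotation)
oracle_kabsch <- function(A, B) {
  A0 <- sweep(A, 2, colMeans(A))
  B0 <- sweep(B, 2, colMeans(B))
  s <- svd(crossprod(A0, B0))
  d <- sign(det(s$v %*% t(s$u)))
  tr <- sum(s$d * c(1, 1, d))
  sqrt(max(0, (sum(A0^2) + sum(B0^2) - 2 * tr) / nrow(A)))
}

# make a bare kymograph object from a matrix (for detector unit tests)
make_kymo <- function(mat, metric = "RMSD", window = 7,
                      centers = seq_len(nrow(mat)) + 3L) {
  structure(mat, metric = metric, window = as.integer(window),
            centers = as.integer(centers),
            steps = seq_len(ncol(mat)) - 1L,
            class = c("kymograph", "matrix"))
}

wrap_deg <- function(x) {
  w <- x - 360 * ceiling((x - 180) / 360)
  w[w <= -180] <- w[w <= -180] + 360
  w
}
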