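#' Sliding-window scan configuration
#'
#' @param window odd window size in residues (3..11).  A 7-residue window is
#'   the default: small fragments have a low probability of seeding amyloid
#'   at biological concentration, so the larger end of the usual 3-10
#'   residue range is preferred.
#' @param chameleon_beta_threshold windowed extended-state propensity above
#'   which a center residue is chameleon-eligible (default 1: enriched over
#'   background).
#' @param hydrophobic_threshold windowed hydropathy above which a center
#'   residue counts as hydrophobic (default 0).
#' @param min_region_len minimum chameleon region length in residues
#'   (default 2).  Hydrophobic regions use a minimum of 1 so that short
#'   two-residue cores are not lost.
#' @return a \code{scan_config} list.
#' @export
scan_config <- function(window = 7, chameleon_beta_threshold = 1,
                        hydrophobic_threshold = 0, min_region_len = 2) {
  window <- as.integer(window)
  if (window %% 2L == 0L) stop("window must be odd, got ", window)
  if (window < 3L || window > 11L)
    stop("window must be in [3, 11], got ", window)
  stopifnot(is.finite(chameleon_beta_threshold),
            is.finite(hydrophobic_threshold), min_region_len >= 1)
  structure(list(window = window,
                 chameleon_beta_threshold = chameleon_beta_threshold,
                 hydrophobic_threshold = hydrophobic_threshold,
                 min_region_len = as.integer(min_region_len)),
            class = "scan_config")
}

new_profile <- function(values, start_residue, metric, window) {
  structure(list(start_residue = as.integer(start_residue),
                 values = as.numeric(values),
                 metric = metric, window = as.integer(window)),
            class = "ss_profile")
}

#' Residue indices covered by a profile
#' @param profile an \code{ss_profile}.
#' @return integer vector of center-residue indices (1-based).
#' @export
profile_residues <- function(profile) {
  profile$start_residue + seq_along(profile$values) - 1L
}

#' @export
print.ss_profile <- function(x, ...) {
  r <- profile_residues(x)
  cat(sprintf("ss_profile '%s': window %d, residues %d-%d (%d values)\n",
              x$metric, x$window, r[1], r[length(r)], length(r)))
  invisible(x)
}

#' @export
plot.ss_profile <- function(x, ...) {
  plot(profile_residues(x), x$values, type = "l", xlab = "residue",
       ylab = x$metric, ...)
  invisible(x)
}

#' Sliding-window average of a per-residue series
#'
#' The mean over each full window is assigned to the window's middle
#' residue; the chain ends are not padded, so a length-N series with window
#' w yields N - w + 1 values covering residues (w+1)/2 .. N - (w-1)/2 (for
#' N = 140, w = 7: residues 4-137).
#'
#' @param values numeric per-residue series.
#' @param window odd window length, at most \code{length(values)}.
#' @param metric label stored in the profile.
#' @return an \code{ss_profile}.
#' @export
window_average <- function(values, window, metric = "windowed mean") {
  window <- as.integer(window)
  if (window %% 2L == 0L) stop("window must be odd, got ", window)
  n <- length(values)
  if (n < window) stop("series length ", n, " is shorter than window ", window)
  if (anyNA(values)) stop("series contains NA values")
  cs <- cumsum(c(0, values))
  out <- (cs[(window + 1L):(n + 1L)] - cs[1L:(n - window + 1L)]) / window
  new_profile(out, (window + 1L) %/% 2L, metric, window)
}

#' Windowed secondary-structure propensity profile of a sequence
#'
#' Looks up the per-residue propensity P(R, klass) and averages it over the
#' sliding window.
#'
#' @param seq amino-acid sequence (string or character vector).
#' @param table a \code{propensity_table}.
#' @param klass structure class (\code{"H"}, \code{"E"} or \code{"C"}).
#' @param cfg a \code{\link{scan_config}}.
#' @return an \code{ss_profile}.
#' @examples
#' p <- propensity_profile(alpha_synuclein_seq(), load_builtin_table(), "E")
#' @export
propensity_profile <- function(seq, table, klass, cfg = scan_config()) {
  s <- split_seq(seq)
  klass <- toupper(klass)
  vals <- vapply(seq_along(s), function(i) {
    v <- tryCatch(lookup_propensity(table, s[i], klass),
                  error = function(e)
                    stop("position ", i, " ('", s[i], "'): ",
                         conditionMessage(e), call. = FALSE))
    v
  }, numeric(1))
  window_average(vals, cfg$window, metric = paste0("P", klass))
}

#' Roseman side-chain hydropathy scale
#'
#' Per-residue hydrophobicity constants (kcal/mol free energy of transfer;
#' positive = hydrophobic) from Roseman, J. Mol. Biol. 200:513-522 (1988),
#' which corrects polar side-chain hydrophilicity for flanking peptide
#' bonds.
#'
#' @return named numeric vector over the 20 amino acids.
#' @export
roseman_scale <- function() {
  c(A = 0.39, R = -3.95, N = -1.91, D = -3.81, C = 0.25,
    Q = -1.30, E = -2.91, G = 0.00, H = -0.64, I = 1.82,
    L = 1.82, K = -2.77, M = 0.96, F = 2.27, P = 0.99,
    S = -1.24, T = -1.00, W = 2.13, Y = 1.47, V = 1.30)
}

#' Windowed hydropathy profile of a sequence
#'
#' @inheritParams propensity_profile
#' @param scale named per-residue hydropathy constants (default
#'   \code{\link{roseman_scale}}).
#' @return an \code{ss_profile}.
#' @export
hydropathy_profile <- function(seq, scale = roseman_scale(),
                               cfg = scan_config()) {
  s <- split_seq(seq)
  miss <- setdiff(unique(s), names(scale))
  if (length(miss) > 0L)
    stop("residues missing from the hydropathy scale: ",
         paste(miss, collapse = ", "))
  window_average(unname(scale[s]), cfg$window, metric = "hydropathy")
}

# maximal runs of TRUE at positions pos (sorted residue indices);
# returns data.frame(start, end) of runs with length >= min_len
runs_of <- function(pos, min_len = 1L) {
  if (length(pos) == 0L)
    return(data.frame(start = integer(0), end = integer(0)))
  brk <- c(0L, which(diff(pos) != 1L), length(pos))
  out <- do.call(rbind, lapply(seq_len(length(brk) - 1L), function(i) {
    p <- pos[(brk[i] + 1L):brk[i + 1L]]
    data.frame(start = p[1], end = p[length(p)])
  }))
  out[(out$end - out$start + 1L) >= min_len, , drop = FALSE]
}

region_frame <- function(runs, kind, profile) {
  res <- profile_residues(profile)
  score <- vapply(seq_len(nrow(runs)), function(i) {
    mean(profile$values[res >= runs$start[i] & res <= runs$end[i]])
  }, numeric(1))
  df <- data.frame(kind = rep(kind, nrow(runs)), start = runs$start,
                   end = runs$end, score = score)
  rownames(df) <- NULL
  df
}

#' Detect chameleon regions from a beta-propensity profile
#'
#' A chameleon segment can adopt either helical or extended structure: the
#' calling rule is windowed extended-state propensity above the threshold
#' (default Pbeta > 1) while the residue's observed secondary-structure
#' context is helix or coil (i.e. not already strand).  Maximal runs of
#' qualifying center residues of at least \code{min_region_len} residues
#' are reported.
#'
#' @param beta_profile an \code{ss_profile} of windowed extended-state
#'   propensity.
#' @param ss_context per-residue H/E/C annotation of the whole chain
#'   (string or character vector), e.g. derived from the helical start
#'   structure.
#' @param cfg a \code{\link{scan_config}}.
#' @return data.frame with columns kind, start, end, score (mean windowed
#'   propensity over the region); 1-based inclusive residue indices.
#' @export
detect_chameleon_regions <- function(beta_profile, ss_context,
                                     cfg = scan_config()) {
  stopifnot(inherits(beta_profile, "ss_profile"))
  ctx <- toupper(split_seq(ss_context))
  res <- profile_residues(beta_profile)
  if (max(res) > length(ctx))
    stop("ss_context (length ", length(ctx),
         ") does not cover profile residues up to ", max(res))
  bad <- setdiff(unique(ctx), SS_CLASSES)
  if (length(bad) > 0L)
    stop("unknown context labels: ", paste(bad, collapse = ", "))
  ok <- beta_profile$values > cfg$chameleon_beta_threshold &
    ctx[res] %in% c("H", "C")
  region_frame(runs_of(res[ok], cfg$min_region_len), "chameleon",
               beta_profile)
}

#' Detect hydrophobic regions from a hydropathy profile
#'
#' Maximal runs of center residues whose windowed hydropathy exceeds the
#' threshold (default 0).  Minimum length 1: genuine two-residue
#' hydrophobic cores occur and are kept.
#'
#' @param hydro_profile an \code{ss_profile} of windowed hydropathy.
#' @param cfg a \code{\link{scan_config}}.
#' @param min_region_len minimum run length (default 1 for this kind).
#' @return data.frame with columns kind, start, end, score.
#' @export
detect_hydrophobic_regions <- function(hydro_profile, cfg = scan_config(),
                                       min_region_len = 1L) {
  stopifnot(inherits(hydro_profile, "ss_profile"))
  res <- profile_residues(hydro_profile)
  ok <- hydro_profile$values > cfg$hydrophobic_threshold
  region_frame(runs_of(res[ok], min_region_len), "hydrophobic",
               hydro_profile)
}

#' Find adjacent glycine-valine sites in a sequence
#'
#' G-V pairs (the tail of the KTKEGV repeat) act as local flexibility
#' hinges: glycine samples a wide dihedral range while valine carries the
#' highest extended-state propensity of all residues.
#'
#' @param seq amino-acid sequence.
#' @param order which pair order to report: \code{"GV"} (G then V),
#'   \code{"VG"}, or \code{"both"}.
#' @return data.frame with 1-based pair positions \code{start}, \code{end}
#'   (= start + 1) and the matched \code{motif}.
#' @examples
#' find_gv_sites("KTKEGV")  # one GV pair at (5, 6)
#' @export
find_gv_sites <- function(seq, order = c("GV", "VG", "both")) {
  order <- match.arg(toupper(order[1]), c("GV", "VG", "BOTH"))
  s <- split_seq(seq)
  n <- length(s)
  if (n < 2L)
    return(data.frame(start = integer(0), end = integer(0),
                      motif = character(0)))
  pair <- paste0(s[-n], s[-1])
  want <- switch(order, GV = "GV", VG = "VG", BOTH = c("GV", "VG"))
  at <- which(pair %in% want)
  data.frame(start = at, end = at + 1L, motif = pair[at])
}

#' Valine-to-alanine scanning mutation
#'
#' Replaces valine with alanine at the given positions (e.g. the valines of
#' G-V sites), modelling the suppression of local extended-state propensity:
#' alanine has the highest helix propensity while valine has the highest
#' extended propensity, so the windowed Pbeta profile can only decrease.
#'
#' @param seq amino-acid sequence.
#' @param sites 1-based positions; every site must hold a valine.
#' @return mutated sequence as a single string.
#' @export
alanine_scan <- function(seq, sites) {
  s <- split_seq(seq)
  sites <- as.integer(sites)
  if (length(sites) > 0L) {
    if (any(sites < 1L | sites > length(s)))
      stop("site out of range: ",
           paste(sites[sites < 1L | sites > length(s)], collapse = ", "))
    notv <- sites[s[sites] != "V"]
    if (length(notv) > 0L)
      stop("site(s) not valine: position ",
           paste(sprintf("%d (%s)", notv, s[notv]), collapse = ", "))
    s[sites] <- "A"
  }
  paste(s, collapse = "")
}

#' Pearson correlation between two aligned profiles
#'
#' @param a,b \code{ss_profile}s with identical residue coverage.
#' @return list with \code{r} (Pearson correlation), \code{p} (two-sided
#'   p-value) and \code{n}.
#' @export
profile_correlation <- function(a, b) {
  stopifnot(inherits(a, "ss_profile"), inherits(b, "ss_profile"))
  if (a$start_residue != b$start_residue ||
      length(a$values) != length(b$values))
    stop("profiles do not cover the same residues (",
         a$start_residue, "+", length(a$values), " vs ",
         b$start_residue, "+", length(b$values), ")")
  if (sd(a$values) == 0 || sd(b$values) == 0)
    stop("zero-variance profile: correlation undefined")
  ct <- cor.test(a$values, b$values, method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value, n = length(a$values))
}

#' Write region calls as TSV (optionally BED-like)
#'
#' Default output is 1-based inclusive (start, end); with
#' \code{zero_based = TRUE} a BED-like 0-based half-open convention is used.
#' The coordinate convention is declared in the header line.
#'
#' @param regions data.frame from a \code{detect_*} function.
#' @param path output path.
#' @param zero_based write 0-based half-open coordinates.
#' @export
write_regions <- function(regions, path, zero_based = FALSE) {
  df <- regions
  hdr <- "# coordinates: 1-based inclusive"
  if (zero_based) {
    df$start <- df$start - 1L
    hdr <- "# coordinates: 0-based half-open"
  }
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  suppressWarnings(write.table(df, con, sep = "\t", row.names = FALSE,
                               quote = FALSE))
  invisible(path)
}
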