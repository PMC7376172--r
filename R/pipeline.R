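#' Configuration for an end-to-end hot-site analysis run
#'
#' Validates and freezes every knob of the pipeline: the sequence, the
#' sequence-scan settings, the coarse-grained targeted-MD schedule with its
#' per-residue flexibility, the kymograph window, hot-site detection and
#' dPCA/clustering parameters.  Validation happens here, before any
#' compute: an even window, for instance, is rejected immediately.
#'
#' @param seq amino-acid sequence (default: a 40-mer test chain).
#' @param flexible list of c(start, end) segments given full flexibility
#'   (1.0); all other residues get \code{base_flexibility}.
#' @param base_flexibility flexibility outside the flexible segments
#'   (default 0.1, i.e. stiff).
#' @param window sliding window for scans and kymographs (odd, default 7).
#' @param schedule a \code{\link{tmd_schedule}} (flexibility is filled in
#'   from \code{flexible}).
#' @param ss_context per-residue H/E/C context for chameleon calls
#'   (default: all helix, matching a helical start structure).
#' @param threshold_frac,min_len,early_frac hot-site detection knobs, see
#'   \code{\link{detect_hot_sites}}.
#' @param grid_bins,floor_frac,smooth_sigma clustering knobs, see
#'   \code{\link{peak_pick_clusters}}.
#' @param seed master RNG seed for the run.
#' @return a \code{pipeline_config}.
#' @export
pipeline_config <- function(seq = strrep("AEKVAGLK", 5),
                            flexible = list(c(8, 14), c(24, 30)),
                            base_flexibility = 0.1,
                            window = 7,
                            schedule = tmd_schedule(),
                            ss_context = NULL,
                            threshold_frac = 0.5, min_len = 4,
                            early_frac = 0.25,
                            grid_bins = 32, floor_frac = 0.1,
                            smooth_sigma = 2,
                            seed = 1) {
  s <- split_seq(seq)
  n <- length(s)
  window <- as.integer(window)
  if (window %% 2L == 0L)
    stop("window must be odd, got ", window)
  if (window < 3L || window > min(11L, n))
    stop("window out of range for a ", n, "-residue chain")
  flex <- rep(base_flexibility, n)
  for (seg in flexible) {
    if (length(seg) != 2L || seg[1] > seg[2] || seg[1] < 1 || seg[2] > n)
      stop("invalid flexible segment: ", paste(seg, collapse = "-"))
    flex[seg[1]:seg[2]] <- 1.0
  }
  if (is.null(ss_context)) ss_context <- rep("H", n)
  schedule$flexibility <- flex
  schedule$seed <- as.integer(seed)
  structure(list(seq = paste(s, collapse = ""), flexible = flexible,
                 window = window, schedule = schedule,
                 ss_context = paste(ss_context, collapse = ""),
                 threshold_frac = threshold_frac, min_len = min_len,
                 early_frac = early_frac, grid_bins = grid_bins,
                 floor_frac = floor_frac, smooth_sigma = smooth_sigma,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Run the full hot-site analysis pipeline
#'
#' Chains every stage: sequence scans (beta-propensity chameleon regions,
#' hydropathy cores, G-V sites), a coarse-grained targeted-MD run from the
#' ideal helix to the ideal extended chain, the three kymographs (RMSD,
#' delta-Rg, H-bonds), hot-site detection, dihedral PCA, peak-picking
#' clustering with representatives, and the endpoint/representative RMSD
#' matrix.  With \code{out_dir} set, all tables are written as TSV/CSV
#' together with a JSON run manifest (effective config, seed, package
#' version).  Runs are deterministic under a fixed seed.
#'
#' @param config a \code{\link{pipeline_config}}.
#' @param out_dir optional output directory (created if missing).
#' @param table propensity table for the scans (default the bundled
#'   reference table).
#' @return a list with elements \code{profiles}, \code{regions},
#'   \code{gv_sites}, \code{trajectory}, \code{kymographs},
#'   \code{hot_sites}, \code{dpca}, \code{clusters}, \code{rmsd_matrix}
#'   and \code{manifest}.
#' @export
run_pipeline <- function(config, out_dir = NULL,
                         table = load_builtin_table()) {
  stopifnot(inherits(config, "pipeline_config"))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }
  seq <- config$seq
  cfg <- scan_config(window = config$window)

  beta <- stage("scan", propensity_profile(seq, table, "E", cfg))
  alpha <- stage("scan", propensity_profile(seq, table, "H", cfg))
  hydro <- stage("scan", hydropathy_profile(seq, cfg = cfg))
  regions <- stage("scan", rbind(
    detect_chameleon_regions(beta, config$ss_context, cfg),
    detect_hydrophobic_regions(hydro, cfg)))
  gv <- stage("scan", find_gv_sites(seq, "both"))

  helix <- stage("simulate", ideal_helix(seq))
  ext <- stage("simulate", ideal_extended(seq))
  traj <- stage("simulate",
                toy_tmd_simulate(seq, helix, ext, config$schedule))

  kymo_rmsd <- stage("kymograph", rmsd_kymograph(traj, config$window))
  kymo_drg <- stage("kymograph", delta_rg_kymograph(traj, config$window))
  kymo_hb <- stage("kymograph", hbond_kymograph(traj, config$window))

  hot <- stage("hotsites",
               detect_hot_sites(kymo_rmsd, config$threshold_frac,
                                config$min_len, config$early_frac))

  pca <- stage("dpca", dihedral_pca(traj))
  clus <- stage("cluster",
                peak_pick_clusters(pca, k = 3, grid_bins = config$grid_bins,
                                   floor_frac = config$floor_frac,
                                   smooth_sigma = config$smooth_sigma))
  clus <- stage("cluster", cluster_representatives(clus, pca))

  reps <- lapply(clus$representatives, function(i)
    trajectory_frame(traj, i))
  names(reps) <- names(clus$representatives)
  structures <- c(list(helical = helix), reps, list(extended = ext))
  rmat <- stage("rmsd_matrix", rmsd_matrix(structures))

  manifest <- list(
    package = "helix2beta",
    version = as.character(packageVersion("helix2beta")),
    seed = config$seed,
    config = config[setdiff(names(config), "schedule")],
    schedule = config$schedule[c("K", "rho0", "steps", "temperature",
                                 "dt", "k_dih", "fd_step", "save_every")],
    coordinate_convention = "1-based inclusive residue numbering")

  out <- list(profiles = list(beta = beta, alpha = alpha, hydro = hydro),
              regions = regions, gv_sites = gv, trajectory = traj,
              kymographs = list(rmsd = kymo_rmsd, drg = kymo_drg,
                                hb = kymo_hb),
              hot_sites = hot, dpca = pca, clusters = clus,
              rmsd_matrix = rmat, manifest = manifest)

  if (!is.null(out_dir)) {
    if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
    fp <- function(f) file.path(out_dir, f)
    write_regions(regions, fp("regions.tsv"))
    write_dihedral_tsv(traj, fp("trajectory_dihedrals.tsv"))
    write_kymograph(kymo_rmsd, fp("kymograph_rmsd.tsv"))
    write_kymograph(kymo_drg, fp("kymograph_drg.tsv"))
    write_kymograph(kymo_hb, fp("kymograph_hb.tsv"))
    write.table(data.frame(priority = hot$priority, start = hot$start,
                           end = hot$end, opening_frame = hot$opening_frame),
                fp("hot_sites.tsv"),
                sep = "\t", row.names = FALSE, quote = FALSE)
    write_dpca_csv(pca, clus, fp("dpca_clusters.csv"))
    write.table(data.frame(structure = rownames(rmat), round(rmat, 3)),
                fp("rmsd_matrix.tsv"), sep = "\t", row.names = FALSE,
                quote = FALSE)
    jsonlite::write_json(manifest, fp("manifest.json"), auto_unbox = TRUE,
                         pretty = TRUE, digits = NA)
  }
  out
}
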