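#' Backbone dihedral state
#'
#' Per-residue (phi, psi) torsions in degrees, wrapped to (-180, 180].  The
#' first residue's phi and the last residue's psi are undefined for a chain
#' and stored as \code{NA}.
#'
#' @param phi,psi numeric vectors of equal length (degrees).
#' @return a \code{dihedral_state}.
#' @export
dihedral_state <- function(phi, psi) {
  if (length(phi) != length(psi)) stop("phi and psi lengths differ")
  n <- length(phi)
  if (n < 2L) stop("a chain needs at least 2 residues")
  phi <- wrap_angle(as.numeric(phi))
  psi <- wrap_angle(as.numeric(psi))
  phi[1] <- NA_real_
  psi[n] <- NA_real_
  if (anyNA(phi[-1]) || anyNA(psi[-n]))
    stop("interior dihedrals must be finite")
  structure(list(phi = phi, psi = psi), class = "dihedral_state")
}

# wrap degrees to (-180, 180]
wrap_angle <- function(x) {
  w <- x - 360 * ceiling((x - 180) / 360)
  w[w <= -180] <- w[w <= -180] + 360
  w
}

#' @export
print.dihedral_state <- function(x, ...) {
  cat(sprintf("dihedral_state: %d residues (phi[1], psi[n] undefined)\n",
              length(x$phi)))
  invisible(x)
}

new_chain_structure <- function(N, CA, C, O, seq, chain = "A") {
  structure(list(N = N, CA = CA, C = C, O = O, seq = seq, chain = chain),
            class = "chain_structure")
}

#' @export
print.chain_structure <- function(x, ...) {
  cat(sprintf("chain_structure: %d residues, chain %s\n",
              nrow(x$CA), x$chain))
  invisible(x)
}

#' Build an idealised backbone from dihedral angles
#'
#' Reconstructs N/CA/C/O coordinates with fixed ideal bond lengths and
#' angles (N-CA 1.458, CA-C 1.525, C-N 1.329 Angstrom; omega fixed at 180
#' degrees), so the dihedrals are the only degrees of freedom.  Extracting
#' dihedrals from the built chain returns the inputs to well below 1e-3
#' degrees.
#'
#' @param seq amino-acid sequence (string or character vector).
#' @param dihedrals a \code{\link{dihedral_state}} covering the sequence.
#' @return a \code{chain_structure} with N, CA, C, O coordinate matrices
#'   (Angstrom).
#' @export
build_backbone <- function(seq, dihedrals) {
  s <- split_seq(seq)
  stopifnot(inherits(dihedrals, "dihedral_state"))
  if (length(s) != length(dihedrals$phi))
    stop("sequence length ", length(s), " != dihedral count ",
         length(dihedrals$phi))
  b <- cpp_build_backbone(dihedrals$phi, dihedrals$psi)
  new_chain_structure(b$N, b$CA, b$C, b$O, s)
}

#' Extract backbone dihedrals from a structure
#'
#' @param structure a \code{chain_structure}.
#' @return a \code{\link{dihedral_state}} (degrees; terminal undefined
#'   angles are \code{NA}).
#' @export
extract_dihedrals <- function(structure) {
  stopifnot(inherits(structure, "chain_structure"))
  d <- cpp_extract_dihedrals(structure$N, structure$CA, structure$C)
  structure(list(phi = d$phi, psi = d$psi), class = "dihedral_state")
}

#' Ideal helical / extended reference backbones
#'
#' Canonical alpha-helix at (phi, psi) = (-57, -47) and extended strand at
#' (-139, 135) degrees, used as synthetic stand-ins for experimentally
#' determined start and target structures of the helix-to-extended
#' transition.
#'
#' @param seq amino-acid sequence.
#' @return a \code{chain_structure}.
#' @export
ideal_helix <- function(seq) {
  s <- split_seq(seq)
  n <- length(s)
  build_backbone(s, dihedral_state(rep(-57, n), rep(-47, n)))
}

#' @rdname ideal_helix
#' @export
ideal_extended <- function(seq) {
  s <- split_seq(seq)
  n <- length(s)
  build_backbone(s, dihedral_state(rep(-139, n), rep(135, n)))
}

# coerce a chain_structure or bare matrix to an n x 3 CA coordinate matrix
as_ca_matrix <- function(x) {
  if (inherits(x, "chain_structure")) return(x$CA)
  if (is.matrix(x) && ncol(x) == 3) return(x)
  stop("expected a chain_structure or an n x 3 coordinate matrix")
}

#' Best-fit (Kabsch) RMSD between two coordinate sets
#'
#' Minimal root-mean-square deviation over proper rotations and
#' translations (reflections excluded).
#'
#' @param a,b \code{chain_structure}s or n x 3 coordinate matrices with
#'   equal point counts (n >= 3).
#' @return RMSD in Angstrom.
#' @export
kabsch_rmsd <- function(a, b) {
  A <- as_ca_matrix(a)
  B <- as_ca_matrix(b)
  if (nrow(A) != nrow(B))
    stop("point counts differ: ", nrow(A), " vs ", nrow(B))
  if (nrow(A) < 3L) stop("need at least 3 points")
  if (collinear(A) || collinear(B))
    stop("degenerate input: all points are collinear")
  cpp_kabsch_rmsd(A, B)
}

collinear <- function(X) {
  X0 <- sweep(X, 2, colMeans(X))
  s <- svd(X0, nu = 0, nv = 0)$d
  s[2] < 1e-8 * max(s[1], 1e-12)
}

#' Targeted-MD harmonic restraint energy
#'
#' The time-dependent bias applied to the alpha carbons:
#' \deqn{U_{TMD} = \frac{1}{2} N K (R - \rho(t))^2}
#' with N the number of CA atoms, K the harmonic force constant, R the
#' current best-fit CA RMSD to the target and rho the reference RMSD at
#' time t.
#'
#' @param current,target \code{chain_structure}s or CA coordinate matrices.
#' @param K harmonic force constant (energy per Angstrom^2).
#' @param rho reference RMSD (Angstrom).
#' @return restraint energy (same units as K times Angstrom^2).
#' @export
restraint_energy <- function(current, target, K, rho) {
  A <- as_ca_matrix(current)
  B <- as_ca_matrix(target)
  if (nrow(A) != nrow(B))
    stop("CA counts differ: ", nrow(A), " vs ", nrow(B))
  R <- cpp_kabsch_rmsd(A, B)
  0.5 * nrow(A) * K * (R - rho)^2
}

#' Schedule for a coarse-grained targeted-MD run
#'
#' The restraint reference RMSD decreases linearly,
#' rho(t) = rho0 * (1 - t/steps), reaching 0 at the final step.  Per-residue
#' \code{flexibility} values f in (0, 1] scale the local dihedral well:
#' stiffness k_i = k_dih / f_i, so f = 1 marks a fully flexible residue that
#' leaves its starting basin easily and f near 0 a stiff one.  All energies
#' are in reduced units (kT = 1 corresponds to \code{temperature = 1}).
#'
#' @param K restraint force constant (default 200, reduced energy/A^2).
#' @param rho0 initial reference RMSD (Angstrom); \code{NULL} = compute
#'   from the start and target structures when the run begins.
#' @param steps number of integration steps (default 5000).
#' @param temperature reduced kT (default 1).
#' @param seed RNG seed.
#' @param flexibility per-residue values in (0, 1], or a single value
#'   recycled; \code{NULL} = 1 for every residue.
#' @param dt integration time step (default 1e-5 reduced time; the
#'   restraint stiffness N K |grad R|^2 sets the stable step size).
#' @param k_dih base dihedral well stiffness (default 40).
#' @param fd_step finite-difference step for the restraint gradient
#'   (degrees, default 0.5, central differences).
#' @param max_dr trust region: maximum per-step restraint-driven
#'   displacement of any single dihedral (radians, default 0.1); keeps
#'   the linearised restraint update stable when the tracking lag is
#'   large.
#' @param save_every store every this-many-th frame (default steps/200).
#' @return a \code{tmd_schedule}.
#' @export
tmd_schedule <- function(K = 200, rho0 = NULL, steps = 5000,
                         temperature = 1, seed = 1, flexibility = NULL,
                         dt = 1e-5, k_dih = 40, fd_step = 0.5,
                         max_dr = 0.1, save_every = NULL) {
  if (K < 0) stop("K must be non-negative")
  steps <- as.integer(steps)
  if (steps < 1L) stop("steps must be positive")
  if (!is.null(rho0) && rho0 < 0) stop("rho0 must be non-negative")
  if (!is.null(flexibility) &&
      (any(flexibility <= 0) || any(flexibility > 1)))
    stop("flexibility values must lie in (0, 1]")
  if (is.null(save_every)) save_every <- max(1L, steps %/% 200L)
  structure(list(K = K, rho0 = rho0, steps = steps,
                 temperature = temperature, seed = as.integer(seed),
                 flexibility = flexibility, dt = dt, k_dih = k_dih,
                 fd_step = fd_step, max_dr = max_dr,
                 save_every = as.integer(save_every)),
            class = "tmd_schedule")
}

#' @export
print.tmd_schedule <- function(x, ...) {
  cat(sprintf(
    "tmd_schedule: K = %g, steps = %d, kT = %g, seed = %d, rho0 = %s\n",
    x$K, x$steps, x$temperature, x$seed,
    if (is.null(x$rho0)) "auto" else sprintf("%.2f A", x$rho0)))
  invisible(x)
}

#' Simulate a coarse-grained targeted-MD trajectory
#'
#' Overdamped Langevin dynamics of a single chain in (phi, psi) dihedral
#' space.  Every torsion sits in a double-minimum cosine potential
#' anchored at its start-state and target-state values (nearest-well
#' form); the ridge between the minima is the residue's local opening
#' barrier, whose height is k_dih / flexibility (see
#' \code{\link{tmd_schedule}}).  On top of this acts the targeted-MD
#' restraint
#' U = (N K / 2)(R - rho(t))^2 on the best-fit CA RMSD R to the target,
#' whose reference rho(t) decreases linearly to zero.  Restraint gradients
#' are taken by 0.5-degree central finite differences through backbone
#' rebuilding.  Runs are deterministic for a fixed seed.
#'
#' @param seq amino-acid sequence.
#' @param start a \code{\link{dihedral_state}} (starting conformation) or a
#'   \code{chain_structure} whose dihedrals are extracted.
#' @param target a \code{chain_structure} (or CA matrix) the restraint
#'   pulls towards.
#' @param schedule a \code{\link{tmd_schedule}}.
#' @return a \code{tmd_trajectory}: saved-frame phi/psi matrices (degrees),
#'   per-frame step numbers, realized best-fit CA RMSD to the target, and
#'   the reference rho(t).
#' @examples
#' \donttest{
#' seq <- strrep("A", 20)
#' tr <- toy_tmd_simulate(seq, ideal_helix(seq), ideal_extended(seq),
#'                        tmd_schedule(steps = 500, seed = 7))
#' }
#' @export
toy_tmd_simulate <- function(seq, start, target, schedule = tmd_schedule()) {
  s <- split_seq(seq)
  n <- length(s)
  stopifnot(inherits(schedule, "tmd_schedule"))
  if (inherits(start, "chain_structure")) start <- extract_dihedrals(start)
  stopifnot(inherits(start, "dihedral_state"))
  if (length(start$phi) != n)
    stop("start state covers ", length(start$phi), " residues, sequence ", n)
  if (!inherits(target, "chain_structure"))
    stop("target must be a chain_structure (CA restraint target and well anchors)")
  target_ca <- target$CA
  if (nrow(target_ca) != n)
    stop("target has ", nrow(target_ca), " CA atoms, sequence ", n)
  target_dih <- extract_dihedrals(target)
  flex <- schedule$flexibility
  if (is.null(flex)) flex <- rep(1, n)
  if (length(flex) == 1L) flex <- rep(flex, n)
  if (length(flex) != n)
    stop("flexibility vector covers ", length(flex), " residues, need ", n)
  if (any(flex <= 0) || any(flex > 1))
    stop("flexibility values must lie in (0, 1]")
  rho0 <- schedule$rho0
  if (is.null(rho0)) {
    start_ca <- cpp_build_backbone(start$phi, start$psi)$CA
    rho0 <- cpp_kabsch_rmsd(start_ca, target_ca)
  }
  set.seed(schedule$seed)
  run <- cpp_tmd_run(start$phi, start$psi, target_dih$phi, target_dih$psi,
                     target_ca, schedule$K, rho0,
                     schedule$steps, schedule$temperature, schedule$dt,
                     schedule$k_dih / flex, schedule$fd_step,
                     schedule$max_dr, schedule$save_every)
  sched <- schedule
  sched$rho0 <- rho0
  sched$flexibility <- flex
  structure(list(phi = run$phi, psi = run$psi, step = as.integer(run$step),
                 rmsd_to_target = run$rmsd, rho = run$rho, seq = s,
                 start = start, target_ca = target_ca, schedule = sched),
            class = "tmd_trajectory")
}

#' Reverse a targeted-MD schedule
#'
#' Returns a schedule for the reversed transition (start and target
#' swapped by the caller of \code{\link{toy_tmd_simulate}}); the initial
#' reference RMSD is recomputed from the swapped pair, which by the
#' symmetry of the RMSD equals the forward rho0.  Reversed runs follow
#' their own stochastic path: they are not time-reversed copies of the
#' forward run.
#'
#' @param schedule a \code{\link{tmd_schedule}}.
#' @return a \code{tmd_schedule} with \code{rho0} reset for recomputation.
#' @export
reversed_schedule <- function(schedule) {
  stopifnot(inherits(schedule, "tmd_schedule"))
  schedule$rho0 <- NULL
  schedule
}

#' Number of saved frames in a trajectory
#' @param traj a \code{tmd_trajectory}.
#' @return integer frame count.
#' @export
n_frames <- function(traj) {
  stopifnot(inherits(traj, "tmd_trajectory"))
  nrow(traj$phi)
}

#' Rebuild the full backbone of one saved frame
#'
#' @param traj a \code{tmd_trajectory}.
#' @param i frame index (1-based).
#' @return a \code{chain_structure}.
#' @export
trajectory_frame <- function(traj, i) {
  stopifnot(inherits(traj, "tmd_trajectory"))
  i <- as.integer(i)
  if (i < 1L || i > n_frames(traj))
    stop("frame index ", i, " out of range 1..", n_frames(traj))
  b <- cpp_build_backbone(traj$phi[i, ], traj$psi[i, ])
  new_chain_structure(b$N, b$CA, b$C, b$O, traj$seq)
}

# CA coordinates of every saved frame as a list of n x 3 matrices
ca_frames <- function(traj) {
  stopifnot(inherits(traj, "tmd_trajectory"))
  lapply(seq_len(n_frames(traj)), function(i)
    cpp_build_backbone(traj$phi[i, ], traj$psi[i, ])$CA)
}

#' @export
print.tmd_trajectory <- function(x, ...) {
  cat(sprintf(
    "tmd_trajectory: %d residues, %d saved frames (%d steps), final RMSD to target %.2f A\n",
    length(x$seq), n_frames(x), x$schedule$steps,
    x$rmsd_to_target[n_frames(x)]))
  invisible(x)
}

#' @export
plot.tmd_trajectory <- function(x, ...) {
  plot(x$step, x$rmsd_to_target, type = "l", xlab = "step",
       ylab = "CA RMSD to target [A]", ...)
  lines(x$step, x$rho, lty = 2)
  legend("topright", legend = c("realized R(t)", "reference rho(t)"),
         lty = c(1, 2), bty = "n")
  invisible(x)
}
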