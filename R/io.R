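#' Wild-type human alpha-synuclein sequence
#'
#' The 140-residue sequence of human alpha-synuclein (UniProt P37840):
#' amphipathic N-terminal region (1-60) with the imperfect KTKEGV repeats,
#' the hydrophobic NAC region, and the acidic C-terminal tail.  Also
#' shipped as a FASTA fixture under \code{extdata/}.
#'
#' @return single string of 140 one-letter codes.
#' @export
alpha_synuclein_seq <- function() {
  paste0("MDVFMKGLSKAKEGVVAAAEKTKQGVAEAAGKTKEGVLYVGSKTKEGVVHGVATVAEKTK",
         "EQVTNVGGAVVTGVTAVAQKTVEGAGSIAAATGFVKKDQLGKNEEGAPQEGILEDMPVDP",
         "DNEAYEMPSEEGYQDYEPEA")
}

#' Read sequences from a FASTA file
#'
#' @param path FASTA file path.
#' @return named character vector of sequences.
#' @export
read_fasta <- function(path) {
  fa <- seqinr::read.fasta(path, seqtype = "AA", as.string = TRUE,
                           forceDNAtolower = FALSE)
  out <- toupper(vapply(fa, function(x) as.character(x)[1], character(1)))
  names(out) <- names(fa)
  out
}

#' Read one model/chain of a PDB file as a backbone structure
#'
#' Extracts the N/CA/C/O backbone of the requested model and chain.  A
#' missing carbonyl O is rebuilt from the peptide plane with a warning.
#'
#' @param path PDB file path.
#' @param model model number for multi-model (NMR) files (default 1).
#' @param chain chain identifier; default: the first chain present.
#' @return a \code{chain_structure}.
#' @export
read_pdb_chain <- function(path, model = 1, chain = NULL) {
  pdb <- bio3d::read.pdb(path, multi = TRUE)
  nmod <- dim(pdb$xyz)[1]
  if (model < 1 || model > nmod)
    stop("model ", model, " not present (file has ", nmod, " model",
         if (nmod == 1) "" else "s", ")")
  chains <- unique(pdb$atom$chain)
  if (is.null(chain)) chain <- chains[1]
  if (!chain %in% chains)
    stop("chain '", chain, "' not present; available: ",
         paste(chains, collapse = ", "))
  xyz <- pdb$xyz[model, ]
  sel_res <- pdb$atom$chain == chain & pdb$atom$type == "ATOM"
  resno <- unique(pdb$atom$resno[sel_res])
  n <- length(resno)
  get_atom <- function(elety) {
    m <- matrix(NA_real_, n, 3)
    idx <- which(sel_res & pdb$atom$elety == elety)
    ri <- match(pdb$atom$resno[idx], resno)
    keep <- !duplicated(ri)
    idx <- idx[keep]; ri <- ri[keep]
    for (j in seq_along(idx)) {
      at <- idx[j]
      m[ri[j], ] <- xyz[(3 * at - 2):(3 * at)]
    }
    m
  }
  N <- get_atom("N"); CA <- get_atom("CA"); C <- get_atom("C")
  O <- get_atom("O")
  if (anyNA(N) || anyNA(CA) || anyNA(C))
    stop("incomplete backbone (N/CA/C) in ", path, " chain ", chain)
  if (anyNA(O)) {
    warning("rebuilding ", sum(apply(is.na(O), 1, any)),
            " missing O atom(s) from the peptide plane")
    for (i in which(apply(is.na(O), 1, any))) {
      if (i < n) {
        u1 <- (N[i + 1, ] - C[i, ]); u1 <- u1 / sqrt(sum(u1^2))
        u2 <- (CA[i, ] - C[i, ]); u2 <- u2 / sqrt(sum(u2^2))
        d <- -(u1 + u2); d <- d / sqrt(sum(d^2))
      } else {
        u2 <- (CA[i, ] - C[i, ]); d <- -u2 / sqrt(sum(u2^2))
      }
      O[i, ] <- C[i, ] + 1.231 * d
    }
  }
  aa3 <- pdb$atom$resid[sel_res][match(resno, pdb$atom$resno[sel_res])]
  seq1 <- suppressWarnings(bio3d::aa321(aa3))
  seq1[is.na(seq1) | seq1 == ""] <- "X"
  new_chain_structure(N, CA, C, O, seq1, chain)
}

fmt_atom <- function(serial, name, resname, chain, resno, xyz) {
  sprintf("ATOM  %5d %-4s %3s %1s%4d    %8.3f%8.3f%8.3f  1.00  0.00",
          serial, if (nchar(name) < 4) paste0(" ", name) else name,
          resname, chain, resno, xyz[1], xyz[2], xyz[3])
}

AA_123 <- c(A = "ALA", C = "CYS", D = "ASP", E = "GLU", F = "PHE",
            G = "GLY", H = "HIS", I = "ILE", K = "LYS", L = "LEU",
            M = "MET", N = "ASN", P = "PRO", Q = "GLN", R = "ARG",
            S = "SER", T = "THR", V = "VAL", W = "TRP", Y = "TYR")

chain_pdb_lines <- function(structure, serial0 = 0L) {
  s <- structure
  n <- nrow(s$CA)
  res3 <- AA_123[s$seq]
  res3[is.na(res3)] <- "UNK"
  lines <- character(0)
  serial <- serial0
  for (i in seq_len(n)) {
    for (at in c("N", "CA", "C", "O")) {
      serial <- serial + 1L
      lines <- c(lines, fmt_atom(serial, at, res3[i], s$chain, i,
                                 s[[at]][i, ]))
    }
  }
  lines
}

#' Write structures as a (multi-model) PDB file
#'
#' A single \code{chain_structure} is written as one model; a list of
#' structures or a \code{tmd_trajectory} as MODEL/ENDMDL blocks.
#' Coordinates survive the round trip through
#' \code{\link{read_pdb_chain}} / \code{\link{read_pdb_trajectory}} to the
#' PDB format resolution of 1e-3 Angstrom.
#'
#' @param x a \code{chain_structure}, list of them, or
#'   \code{tmd_trajectory}.
#' @param path output path.
#' @export
write_pdb <- function(x, path) {
  if (inherits(x, "chain_structure")) x <- list(x)
  if (inherits(x, "tmd_trajectory"))
    x <- lapply(seq_len(n_frames(x)), function(i) trajectory_frame(x, i))
  con <- file(path, "w")
  on.exit(close(con))
  for (m in seq_along(x)) {
    writeLines(sprintf("MODEL     %4d", m), con)
    writeLines(chain_pdb_lines(x[[m]]), con)
    writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(path)
}

#' Read every model of a multi-model PDB file
#'
#' @param path PDB file path.
#' @param chain chain id (default: first).
#' @return list of \code{chain_structure}s, one per model.
#' @export
read_pdb_trajectory <- function(path, chain = NULL) {
  pdb <- bio3d::read.pdb(path, multi = TRUE)
  nmod <- dim(pdb$xyz)[1]
  lapply(seq_len(nmod), function(m) read_pdb_chain(path, m, chain))
}

#' Write / read a trajectory as a dihedral TSV table
#'
#' Wide text format: one row per saved frame with columns \code{step},
#' \code{rmsd}, \code{rho}, then \code{phi_1..phi_n} and
#' \code{psi_1..psi_n} in degrees (6 decimal places, lossless well below
#' the 1e-3 degree level).  The header comment records the sequence so the
#' trajectory can be rebuilt.
#'
#' @param traj a \code{tmd_trajectory}.
#' @param path file path.
#' @return \code{read_dihedral_tsv}: a \code{tmd_trajectory} (without the
#'   original schedule; rmsd/rho restored from the table).
#' @export
write_dihedral_tsv <- function(traj, path) {
  stopifnot(inherits(traj, "tmd_trajectory"))
  n <- length(traj$seq)
  df <- data.frame(step = traj$step,
                   rmsd = sprintf("%.6f", traj$rmsd_to_target),
                   rho = sprintf("%.6f", traj$rho))
  ph <- apply(traj$phi, 2, function(x) sprintf("%.6f", x))
  ps <- apply(traj$psi, 2, function(x) sprintf("%.6f", x))
  colnames(ph) <- paste0("phi_", seq_len(n))
  colnames(ps) <- paste0("psi_", seq_len(n))
  out <- cbind(df, ph, ps)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# seq=", paste(traj$seq, collapse = "")), con)
  writeLines("# angles in degrees; residues 1-based", con)
  suppressWarnings(write.table(out, con, sep = "\t", row.names = FALSE,
                               quote = FALSE))
  invisible(path)
}

#' @rdname write_dihedral_tsv
#' @export
read_dihedral_tsv <- function(path) {
  lines <- readLines(path, n = 5)
  seqline <- grep("^# seq=", lines, value = TRUE)
  if (length(seqline) == 0L) stop("missing '# seq=' header in ", path)
  s <- split_seq(sub("^# seq=", "", seqline[1]))
  df <- read.table(path, sep = "\t", header = TRUE, comment.char = "#")
  n <- length(s)
  phi <- as.matrix(df[, paste0("phi_", seq_len(n))])
  psi <- as.matrix(df[, paste0("psi_", seq_len(n))])
  dimnames(phi) <- dimnames(psi) <- NULL
  structure(list(phi = phi, psi = psi, step = as.integer(df$step),
                 rmsd_to_target = df$rmsd, rho = df$rho, seq = s,
                 start = NULL, target_ca = NULL, schedule = NULL),
            class = "tmd_trajectory")
}
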