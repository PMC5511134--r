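# Geometric hydrogen-bond detection between candidate residues and
# persistence of those bonds along mode-interpolated trajectories.
#
# Criterion is a heavy-atom donor-acceptor distance strictly below a
# cutoff (default 3.2 A); no hydrogen placement, no angle term. The
# structures carry no hydrogens, so this is the strongest criterion
# available, and it is reported as such.

# polar heavy atoms considered donor/acceptor capable
BACKBONE_POLAR <- c("N", "O")

#' Detect candidate hydrogen bonds between residues
#'
#' Enumerates polar heavy-atom pairs (backbone and side-chain N/O) between
#' distinct residues at least two positions apart in sequence, and keeps
#' pairs strictly closer than `cutoff`. Nitrogen atoms are reported on the
#' donor side and oxygens on the acceptor side where the pair allows;
#' otherwise the closer-to-N convention is moot and atoms are reported in
#' file order.
#'
#' @param struct a `structure` with side-chain heavy atoms present.
#' @param residues integer vector of residue numbers (structure
#'   numbering); only pairs with at least one atom in these residues are
#'   kept. `NULL` scans all residue pairs.
#' @param cutoff heavy-atom distance cutoff in angstrom (strict `<`;
#'   default 3.2).
#' @param numbering optional [numbering_map()] so reported residue labels
#'   are in mature numbering.
#' @return data frame of class `hbond_table`: `donor_resno`,
#'   `donor_resname`, `donor_atom`, `acceptor_resno`, `acceptor_resname`,
#'   `acceptor_atom`, `distance` (A), sorted by distance.
#' @export
detect_hbonds <- function(struct, residues = NULL, cutoff = 3.2,
                          numbering = numbering_map()) {
  stopifnot(inherits(struct, "structure"))
  at <- struct$atoms
  polar <- at[at$element %in% c("N", "O"), , drop = FALSE]
  if (!is.null(residues)) {
    miss <- setdiff(residues, at$resno)
    if (length(miss)) {
      stop("candidate residues absent from structure: ",
           paste(miss, collapse = ", "))
    }
  }
  sel <- polar
  if (nrow(sel) < 2L) {
    return(empty_hbond_table())
  }
  xyz <- as.matrix(sel[, c("x", "y", "z")])
  d <- as.matrix(dist(xyz))
  sep_ok <- abs(outer(sel$resno, sel$resno, "-")) >= 2 |
    outer(sel$chain, sel$chain, "!=")
  cand_ok <- if (is.null(residues)) TRUE else
    outer(sel$resno %in% residues, sel$resno %in% residues, "|")
  hit <- which(upper.tri(d) & d < cutoff & sep_ok & cand_ok, arr.ind = TRUE)
  if (!nrow(hit)) return(empty_hbond_table())

  rows <- lapply(seq_len(nrow(hit)), function(p) {
    i <- hit[p, 1]; j <- hit[p, 2]
    # nitrogen donates, oxygen accepts, when the pair decides it
    if (sel$element[j] == "N" && sel$element[i] == "O") { tmp <- i; i <- j; j <- tmp }
    data.frame(
      donor_resno = apply_numbering(numbering, sel$resno[i], sel$ins[i]),
      donor_resname = sel$resname[i], donor_atom = sel$atom[i],
      donor_pdb_resno = sel$resno[i],
      acceptor_resno = apply_numbering(numbering, sel$resno[j], sel$ins[j]),
      acceptor_resname = sel$resname[j], acceptor_atom = sel$atom[j],
      acceptor_pdb_resno = sel$resno[j],
      distance = d[hit[p, 1], hit[p, 2]],
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$distance), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("hbond_table", "data.frame")
  out
}

empty_hbond_table <- function() {
  out <- data.frame(donor_resno = integer(), donor_resname = character(),
                    donor_atom = character(), donor_pdb_resno = integer(),
                    acceptor_resno = integer(),
                    acceptor_resname = character(),
                    acceptor_atom = character(),
                    acceptor_pdb_resno = integer(), distance = numeric(),
                    stringsAsFactors = FALSE)
  class(out) <- c("hbond_table", "data.frame")
  out
}

#' Persistence of a hydrogen bond along a C-alpha trajectory
#'
#' The trajectory is coarse-grained (one bead per residue), so each heavy
#' atom is displaced rigidly with its residue's C-alpha: atom position in
#' frame f = reference atom position + (CA_f - CA_ref). Persistence is the
#' fraction of frames in which the displaced donor-acceptor distance stays
#' strictly below the cutoff. This rigid-residue rule captures backbone
#' separation at a hinge but not side-chain reorientation.
#'
#' @param struct the reference `structure` holding the bond's atoms.
#' @param bond one row of a [detect_hbonds()] table (or a list with
#'   `donor_pdb_resno`, `donor_atom`, `acceptor_pdb_resno`,
#'   `acceptor_atom`).
#' @param traj a `trajectory` whose beads correspond to `model`'s
#'   residues.
#' @param model the `calpha_model` defining the bead order of `traj`.
#' @param cutoff distance cutoff (strict `<`; default 3.2 A).
#' @return list: `persistence` (fraction in \[0, 1\]), `distances`
#'   (per-frame donor-acceptor distances), `reference_distance`.
#' @export
hbond_persistence <- function(struct, bond, traj, model, cutoff = 3.2) {
  stopifnot(inherits(traj, "trajectory"), inherits(model, "calpha_model"))
  da <- atom_xyz(struct, bond$donor_pdb_resno, bond$donor_atom)
  aa <- atom_xyz(struct, bond$acceptor_pdb_resno, bond$acceptor_atom)
  bi <- match(bond$donor_pdb_resno, model$labels$pdb_resno)
  bj <- match(bond$acceptor_pdb_resno, model$labels$pdb_resno)
  if (is.na(bi) || is.na(bj)) {
    stop("bond residue has no bead in the model: ",
         bond$donor_pdb_resno, " / ", bond$acceptor_pdb_resno)
  }
  ca_ref_i <- model$xyz[bi, ]
  ca_ref_j <- model$xyz[bj, ]
  nf <- dim(traj$coords)[1]
  dists <- vapply(seq_len(nf), function(f) {
    di <- traj$coords[f, bi, ] - ca_ref_i
    dj <- traj$coords[f, bj, ] - ca_ref_j
    sqrt(sum(((da + di) - (aa + dj))^2))
  }, numeric(1))
  list(persistence = mean(dists < cutoff), distances = dists,
       reference_distance = sqrt(sum((da - aa)^2)))
}

atom_xyz <- function(struct, resno, atom) {
  at <- struct$atoms
  hit <- which(at$resno == resno & at$atom == atom)
  if (!length(hit)) {
    stop("atom ", atom, " of residue ", resno, " not found in structure")
  }
  as.numeric(at[hit[1], c("x", "y", "z")])
}
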