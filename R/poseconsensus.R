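#' Construct a structure model
#'
#' Minimal heavy-atom protein representation used for contact analysis:
#' one row per atom with chain, residue number and name, atom name and
#' Cartesian coordinates in Angstrom.
#'
#' @param atoms Data frame with columns `chain`, `resno`, `resname`,
#'   `elety` (atom name) and `x`, `y`, `z`.
#' @return A `structure_model` object.
#' @export
structure_model <- function(atoms) {
  need <- c("chain", "resno", "resname", "elety", "x", "y", "z")
  miss <- setdiff(need, names(atoms))
  if (length(miss))
    stop("missing atom columns: ", paste(miss, collapse = ", "), call. = FALSE)
  if (nrow(atoms) == 0) stop("structure has no atoms", call. = FALSE)
  if (any(!is.finite(atoms$x) | !is.finite(atoms$y) | !is.finite(atoms$z)))
    stop("non-finite atom coordinates", call. = FALSE)
  atoms <- atoms[, need]
  atoms$chain <- as.character(atoms$chain)
  atoms$resno <- as.integer(atoms$resno)
  rownames(atoms) <- NULL
  structure(list(atoms = atoms), class = "structure_model")
}

#' @export
print.structure_model <- function(x, ...) {
  rid <- unique(paste(x$atoms$chain, x$atoms$resno))
  cat(sprintf("Structure model: %d atoms, %d residues, chains %s\n",
              nrow(x$atoms), length(rid),
              paste(unique(x$atoms$chain), collapse = ",")))
  invisible(x)
}

#' Residues of a structure as a data frame
#' @param structure A `structure_model`.
#' @return Data frame with one row per residue: `chain`, `resno`,
#'   `resname`, in chain then sequence order.
#' @export
structure_residues <- function(structure) {
  a <- structure$atoms
  key <- paste(a$chain, a$resno, sep = "\r")
  res <- a[!duplicated(key), c("chain", "resno", "resname")]
  res <- res[order(res$chain, res$resno), ]
  rownames(res) <- NULL
  res
}

#' Construct a docking-pose ensemble
#'
#' @param poses List of ligand-pose coordinate matrices (n_atoms x 3,
#'   Angstrom). All poses must have at least one atom.
#' @param energies Numeric vector of docking energies, one per pose;
#'   lower is better.
#' @param ligand_label Ligand name.
#' @return A `pose_ensemble` object.
#' @export
pose_ensemble <- function(poses, energies, ligand_label = "LIG") {
  if (length(poses) != length(energies))
    stop("one energy per pose required", call. = FALSE)
  if (length(poses) == 0) stop("ensemble has no poses", call. = FALSE)
  poses <- lapply(poses, function(p) {
    p <- as.matrix(p)
    if (nrow(p) < 1 || ncol(p) != 3 || any(!is.finite(p)))
      stop("each pose must be a finite n x 3 coordinate matrix", call. = FALSE)
    dimnames(p) <- NULL
    p
  })
  structure(list(poses = poses, energies = as.numeric(energies),
                 ligand_label = ligand_label),
            class = "pose_ensemble")
}

#' @export
print.pose_ensemble <- function(x, ...) {
  cat(sprintf("Pose ensemble: %s, %d poses (%d atoms each), energies [%.3g, %.3g]\n",
              x$ligand_label, length(x$poses), nrow(x$poses[[1]]),
              min(x$energies), max(x$energies)))
  invisible(x)
}

# All-pairs minimum squared distance per structure atom to any pose
# atom, computed elementwise (no expansion trick) so the grid and brute
# routes evaluate identical arithmetic at the cutoff boundary.
.min_d2_brute <- function(xyz, pose) {
  best <- rep(Inf, nrow(xyz))
  for (j in seq_len(nrow(pose))) {
    dx <- xyz[, 1] - pose[j, 1]
    dy <- xyz[, 2] - pose[j, 2]
    dz <- xyz[, 3] - pose[j, 3]
    best <- pmin(best, dx * dx + dy * dy + dz * dz)
  }
  best
}

# Cell-list acceleration: bin structure atoms into cubic cells of edge
# `cutoff`; only atoms in the 27-cell neighborhood of a pose atom's cell
# can be within `cutoff`. Exact (no approximation) by construction.
.contact_atoms_grid <- function(xyz, pose, cutoff) {
  cell_of <- function(m) floor(sweep(m, 2, apply(rbind(xyz, pose), 2, min)) / cutoff)
  sc <- cell_of(xyz)
  pc <- cell_of(pose)
  key <- function(c3) paste(c3[, 1], c3[, 2], c3[, 3], sep = ",")
  idx <- split(seq_len(nrow(xyz)), key(sc))
  hit <- logical(nrow(xyz))
  offsets <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  c2 <- cutoff^2
  for (j in seq_len(nrow(pose))) {
    neigh <- sweep(offsets, 2, as.numeric(pc[j, ]), "+")
    cand <- unlist(idx[key(neigh)], use.names = FALSE)
    cand <- cand[!hit[cand]]
    if (!length(cand)) next
    dx <- xyz[cand, 1] - pose[j, 1]
    dy <- xyz[cand, 2] - pose[j, 2]
    dz <- xyz[cand, 3] - pose[j, 3]
    hit[cand[dx * dx + dy * dy + dz * dz <= c2]] <- TRUE
  }
  hit
}

#' Contact surface of one ligand pose
#'
#' A residue belongs to the contact surface when any of its heavy atoms
#' lies within `cutoff` Angstrom (default 3.6) of any ligand atom
#' (minimum over all atom pairs, boundary included). Detection uses a
#' cell-list spatial grid that agrees exactly with the all-pairs
#' definition; `method = "brute"` forces the O(N*M) route.
#'
#' @param structure A [structure_model()] (heavy atoms).
#' @param pose Ligand coordinates, n x 3 matrix in the structure frame.
#' @param cutoff Contact distance in Angstrom, > 0.
#' @param method `"grid"` (default) or `"brute"`.
#' @return A `contact_surface`: data frame of contact residues
#'   (`chain`, `resno`, `resname`) with attribute `cutoff`.
#' @export
contact_residues <- function(structure, pose, cutoff = 3.6,
                             method = c("grid", "brute")) {
  method <- match.arg(method)
  if (cutoff <= 0) stop("`cutoff` must be positive", call. = FALSE)
  pose <- as.matrix(pose)
  if (nrow(pose) == 0) stop("pose has no atoms", call. = FALSE)
  a <- structure$atoms
  xyz <- as.matrix(a[, c("x", "y", "z")])
  hit <- if (method == "grid") {
    .contact_atoms_grid(xyz, pose, cutoff)
  } else {
    .min_d2_brute(xyz, pose) <= cutoff^2
  }
  key <- paste(a$chain, a$resno, sep = "\r")
  res <- unique(a[key %in% key[hit], c("chain", "resno", "resname")])
  res <- res[order(res$chain, res$resno), ]
  rownames(res) <- NULL
  structure(res, cutoff = cutoff, class = c("contact_surface", "data.frame"))
}

#' Per-residue conservation scores over the lowest-energy poses
#'
#' Poses are ranked by energy (ascending, ties kept in input order) and
#' the `top_k` best are retained (K = 50 by default). Each retained
#' pose contributes its contact surface; a residue's conservation score
#' is the fraction of retained poses whose contact surface contains it.
#' Residues scoring at or above `region_threshold` are segmented into
#' sequence-consecutive runs (gaps of up to `bridge_gap` residues
#' bridged), and the runs are ranked by mean score — the consensus
#' pocket regions.
#'
#' @param structure A [structure_model()].
#' @param ensemble A [pose_ensemble()].
#' @param top_k Number of lowest-energy poses to keep (>= 1).
#' @param cutoff Contact distance in Angstrom.
#' @param region_threshold Minimum score for a residue to seed a region.
#' @param bridge_gap Maximum number of below-threshold residues bridged
#'   inside one region.
#' @return A `consensus_pocket` list: `scores` (per-residue data frame
#'   with `chain`, `resno`, `resname`, `score`), `regions` (ranked data
#'   frame with `region`, `chain`, `start`, `end`, `n_residues`,
#'   `mean_score`), `n_poses_used`, `cutoff`, `threshold`.
#' @export
conservation_scores <- function(structure, ensemble, top_k = 50, cutoff = 3.6,
                                region_threshold = 0.5, bridge_gap = 2) {
  if (top_k <= 0) stop("`top_k` must be at least 1", call. = FALSE)
  o <- order(ensemble$energies)  # stable: input order breaks ties
  keep <- o[seq_len(min(top_k, length(o)))]
  res <- structure_residues(structure)
  key <- paste(res$chain, res$resno, sep = "\r")
  counts <- integer(nrow(res))
  for (i in keep) {
    cs <- contact_residues(structure, ensemble$poses[[i]], cutoff = cutoff)
    counts <- counts + (key %in% paste(cs$chain, cs$resno, sep = "\r"))
  }
  score <- counts / length(keep)
  scores <- cbind(res, score = score)
  regions <- .segment_regions(scores, region_threshold, bridge_gap)
  structure(list(scores = scores, regions = regions,
                 n_poses_used = length(keep), cutoff = cutoff,
                 threshold = region_threshold),
            class = "consensus_pocket")
}

# Runs of above-threshold residues per chain; gaps in sequence number of
# at most `bridge_gap` residues are bridged. Ranked by mean score of the
# above-threshold members.
.segment_regions <- function(scores, threshold, bridge_gap) {
  empty <- data.frame(region = integer(0), chain = character(0),
                      start = integer(0), end = integer(0),
                      n_residues = integer(0), mean_score = numeric(0),
                      stringsAsFactors = FALSE)
  hi <- scores[scores$score >= threshold, , drop = FALSE]
  if (nrow(hi) == 0) return(empty)
  out <- list()
  for (ch in unique(hi$chain)) {
    h <- hi[hi$chain == ch, , drop = FALSE]
    h <- h[order(h$resno), , drop = FALSE]
    brk <- c(0, cumsum(diff(h$resno) > bridge_gap + 1))
    for (g in split(seq_len(nrow(h)), brk)) {
      seg <- h[g, , drop = FALSE]
      out[[length(out) + 1L]] <- data.frame(
        chain = ch, start = min(seg$resno), end = max(seg$resno),
        n_residues = nrow(seg), mean_score = mean(seg$score),
        stringsAsFactors = FALSE)
    }
  }
  reg <- do.call(rbind, out)
  reg <- reg[order(-reg$mean_score, reg$chain, reg$start), , drop = FALSE]
  reg <- cbind(region = seq_len(nrow(reg)), reg)
  rownames(reg) <- NULL
  reg
}

#' @export
print.consensus_pocket <- function(x, ...) {
  cat(sprintf(
    "Consensus pocket from %d poses (cutoff %.1f A, region threshold %.2f): %d region(s)\n",
    x$n_poses_used, x$cutoff, x$threshold, nrow(x$regions)))
  if (nrow(x$regions)) print(x$regions, ...)
  invisible(x)
}

#' Residue pairs at a two-chain interface
#'
#' A residue of chain A pairs with a residue of chain B when any atom
#' of one lies within `cutoff` Angstrom of any atom of the other. The
#' output is the symmetric pair set: `interface_residues(s, "B", "A")`
#' is the column-swapped mirror of `interface_residues(s, "A", "B")`.
#'
#' @param structure A [structure_model()] with both chains.
#' @param chain_a,chain_b Chain identifiers.
#' @param cutoff Contact distance in Angstrom.
#' @return Data frame of residue pairs: `chain_a`, `resno_a`,
#'   `resname_a`, `chain_b`, `resno_b`, `resname_b`.
#' @export
interface_residues <- function(structure, chain_a, chain_b, cutoff = 3.6) {
  a <- structure$atoms
  for (ch in c(chain_a, chain_b))
    if (!ch %in% a$chain)
      stop(sprintf("chain '%s' not in structure", ch), call. = FALSE)
  aa <- a[a$chain == chain_a, , drop = FALSE]
  ab <- a[a$chain == chain_b, , drop = FALSE]
  xa <- as.matrix(aa[, c("x", "y", "z")])
  xb <- as.matrix(ab[, c("x", "y", "z")])
  d2 <- outer(rowSums(xa^2), rowSums(xb^2), "+") - 2 * xa %*% t(xb)
  close_idx <- which(d2 <= cutoff^2 + 1e-12, arr.ind = TRUE)
  if (nrow(close_idx) == 0) {
    return(data.frame(chain_a = character(0), resno_a = integer(0),
                      resname_a = character(0), chain_b = character(0),
                      resno_b = integer(0), resname_b = character(0),
                      stringsAsFactors = FALSE))
  }
  pairs <- unique(data.frame(
    chain_a = chain_a, resno_a = aa$resno[close_idx[, 1]],
    resname_a = aa$resname[close_idx[, 1]],
    chain_b = chain_b, resno_b = ab$resno[close_idx[, 2]],
    resname_b = ab$resname[close_idx[, 2]],
    stringsAsFactors = FALSE))
  pairs <- pairs[order(pairs$resno_a, pairs$resno_b), ]
  rownames(pairs) <- NULL
  pairs
}

#' Overlap between two ligand binding sites
#'
#' Compares two contact surfaces on the same structure frame: shared
#' residues, the Jaccard index of the residue sets, and the Euclidean
#' distance between the two ligands' unweighted geometric centers
#' (mean atom position).
#'
#' @param site_a,site_b `contact_surface` objects (or data frames with
#'   `chain`, `resno` columns).
#' @param ligand_a,ligand_b Coordinate matrices of the two ligands.
#' @return A `site_overlap` list: `shared` (residue data frame),
#'   `n_shared`, `jaccard` (`NA` when both sites are empty),
#'   `center_distance` (Angstrom).
#' @export
site_overlap <- function(site_a, site_b, ligand_a, ligand_b) {
  ka <- paste(site_a$chain, site_a$resno, sep = "\r")
  kb <- paste(site_b$chain, site_b$resno, sep = "\r")
  shared <- site_a[ka %in% kb, , drop = FALSE]
  rownames(shared) <- NULL
  uni <- union(ka, kb)
  jac <- if (length(uni) == 0) NA_real_ else length(intersect(ka, kb)) / length(uni)
  ca <- colMeans(as.matrix(ligand_a))
  cb <- colMeans(as.matrix(ligand_b))
  structure(list(shared = as.data.frame(shared), n_shared = nrow(shared),
                 jaccard = jac,
                 center_distance = sqrt(sum((ca - cb)^2))),
            class = "site_overlap")
}

#' @export
print.site_overlap <- function(x, ...) {
  cat(sprintf("Site overlap: %d shared residues, Jaccard = %s, center distance = %.3f A\n",
              x$n_shared,
              if (is.na(x$jaccard)) "undefined" else sprintf("%.3f", x$jaccard),
              x$center_distance))
  invisible(x)
}
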