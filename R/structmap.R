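#' Residue contact map with region partitioning
#'
#' Computes minimum heavy-atom distances between residue pairs and
#' retains pairs at or below `cutoff` (8 angstrom by default), excluding
#' trivial backbone neighbours (`|i - j| >= 2`). Retained pairs are
#' partitioned by the supplied region definition: pairs within the N3A
#' motif, between the N3A motif and the B/C helix, between the N3A motif
#' and the CNB-B domain, and everything else.
#'
#' @param coords Either a path to a PDB file (read with
#'   `bio3d::read.pdb()`) or a data frame with columns `resno`, `x`, `y`,
#'   `z`, `elety` (hydrogens are dropped by element symbol / atom-name
#'   prefix).
#' @param cutoff Contact distance cutoff, angstrom.
#' @param regions A [region_def()] (optional; without it all pairs are
#'   labelled `"other"`).
#' @return A `contact_map` tibble: `res_i`, `res_j` (`res_i < res_j`),
#'   `min_dist` (angstrom), `partition`.
#' @export
contact_map <- function(coords, cutoff = 8, regions = NULL) {
  if (cutoff <= 0) {
    abort("`cutoff` must be positive.", class = "tweezfold_invalid_input")
  }
  atoms <- .coerce_atoms(coords)
  if (nrow(atoms) == 0) {
    abort("No heavy atoms found: empty structure.",
          class = "tweezfold_invalid_input")
  }
  if (!is.null(regions)) .check_regions(regions, atoms$resno)

  res <- sort(unique(atoms$resno))
  xyz <- as.matrix(atoms[, c("x", "y", "z")])
  groups <- split(seq_len(nrow(atoms)), atoms$resno)
  # two-stage min-distance aggregation: atoms -> (residue, atom) -> pairs
  d2 <- as.matrix(stats::dist(xyz))^2
  res_atom_min <- vapply(groups, function(ix)
    apply(d2[, ix, drop = FALSE], 1, min), numeric(nrow(atoms)))
  pair_min <- vapply(groups, function(ix)
    apply(res_atom_min[ix, , drop = FALSE], 2, min),
    numeric(length(groups)))
  dimnames(pair_min) <- list(res, res)

  idx <- which(upper.tri(pair_min), arr.ind = TRUE)
  ri <- res[idx[, 1]]
  rj <- res[idx[, 2]]
  md <- sqrt(pair_min[idx])
  keep <- abs(rj - ri) >= 2 & md <= cutoff
  out <- tibble::tibble(res_i = ri[keep], res_j = rj[keep],
                        min_dist = md[keep])
  out$partition <- .partition_pairs(out$res_i, out$res_j, regions)
  out <- dplyr::arrange(out, .data$res_i, .data$res_j)
  attr(out, "cutoff") <- cutoff
  class(out) <- c("contact_map", class(out))
  out
}

.coerce_atoms <- function(coords) {
  if (is.character(coords) && length(coords) == 1) {
    if (!requireNamespace("bio3d", quietly = TRUE)) {
      abort("Reading PDB files requires the bio3d package.",
            class = "tweezfold_io_error")
    }
    pdb <- bio3d::read.pdb(coords)
    atoms <- pdb$atom
  } else if (is.data.frame(coords)) {
    atoms <- coords
  } else {
    abort("`coords` must be a PDB path or an atom data frame.",
          class = "tweezfold_invalid_input")
  }
  need <- c("resno", "x", "y", "z")
  if (!all(need %in% names(atoms))) {
    abort(paste("Atom table needs columns:", paste(need, collapse = ", ")),
          class = "tweezfold_invalid_input")
  }
  # heavy atoms only: drop hydrogens by element symbol when present,
  # otherwise by the atom-name convention (H*, 1H*, 2H*, 3H*)
  if ("elesy" %in% names(atoms)) {
    atoms <- atoms[!atoms$elesy %in% c("H", "D"), ]
  } else if ("elety" %in% names(atoms)) {
    atoms <- atoms[!grepl("^[123]?H", atoms$elety), ]
  }
  tibble::as_tibble(atoms[stats::complete.cases(atoms[, need]), ])
}

#' Named residue-range definitions for contact partitioning
#'
#' @param n3a Residue range (length-2 integer) of the N3A motif.
#' @param bc_helix Residue range of the B/C helix.
#' @param cnb_b Residue range of the CNB-B domain.
#' @param ... Further named ranges (kept, but not used by the default
#'   partition labels).
#' @return A named list of ranges of class `region_def`.
#' @examples
#' region_def(n3a = c(119, 148), bc_helix = c(226, 244),
#'            cnb_b = c(245, 376))
#' @export
region_def <- function(n3a = NULL, bc_helix = NULL, cnb_b = NULL, ...) {
  regions <- c(list(n3a = n3a, bc_helix = bc_helix, cnb_b = cnb_b),
               list(...))
  regions <- regions[!vapply(regions, is.null, logical(1))]
  for (nm in names(regions)) {
    r <- regions[[nm]]
    if (length(r) != 2 || r[1] > r[2]) {
      abort(sprintf("Region '%s' must be a length-2 ascending range.", nm),
            class = "tweezfold_invalid_input")
    }
  }
  structure(regions, class = "region_def")
}

.check_regions <- function(regions, resno) {
  lo <- min(resno); hi <- max(resno)
  for (nm in names(regions)) {
    r <- regions[[nm]]
    if (r[2] < lo || r[1] > hi) {
      abort(sprintf("Region '%s' [%d, %d] lies outside residue numbering [%d, %d].",
                    nm, r[1], r[2], lo, hi), class = "tweezfold_range_error")
    }
  }
}

.partition_pairs <- function(res_i, res_j, regions) {
  if (is.null(regions)) return(rep("other", length(res_i)))
  in_reg <- function(r, w) !is.null(w) && r >= w[1] & r <= w[2]
  mapply(function(i, j) {
    i_n3a <- in_reg(i, regions$n3a); j_n3a <- in_reg(j, regions$n3a)
    if (i_n3a && j_n3a) return("intra-N3A")
    one_n3a <- xor(i_n3a, j_n3a)
    other <- if (i_n3a) j else i
    if (one_n3a && in_reg(other, regions$bc_helix)) return("N3A-B/C-helix")
    if (one_n3a && in_reg(other, regions$cnb_b)) return("N3A-CNB-B")
    "other"
  }, res_i, res_j, USE.NAMES = FALSE)
}

#' Structure-based expected contour-length change
#'
#' The contour released by unfolding a domain of `n_residues` residues is
#' `n_residues * l_aa - d_nc`: the stretched-chain contour minus the
#' folded end-to-end distance already spanned before unfolding.
#'
#' @param n_residues Residues in the folded unit.
#' @param l_aa Contour length per residue, nm (default 0.365).
#' @param d_nc Folded N-to-C distance, nm.
#' @return Expected contour-length change, nm.
#' @examples
#' expected_delta_lc(133, d_nc = 3.5) # about 45 nm
#' @export
expected_delta_lc <- function(n_residues, l_aa = 0.365, d_nc = 0) {
  if (n_residues <= 0 || l_aa <= 0 || d_nc < 0) {
    abort("n_residues and l_aa must be positive; d_nc >= 0.",
          class = "tweezfold_invalid_input")
  }
  out <- n_residues * l_aa - d_nc
  if (any(out <= 0)) {
    abort("Folded end-to-end distance exceeds the chain contour: invalid geometry.",
          class = "tweezfold_invalid_geometry")
  }
  out
}
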