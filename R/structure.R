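#' Minimum-atom distance matrix between nucleotides
#'
#' For every pair of nucleotides, the minimum Euclidean distance over all
#' heavy-atom pairs (hydrogens are excluded). Modified residues are mapped to
#' their parent A/C/G/U base; residues with no heavy atoms are masked
#' (sentinel `Inf` rows/columns, diagonal kept at 0).
#'
#' @param x a PDB/mmCIF file path, a `bio3d` `pdb` object, or a data frame
#'   with columns `residue` (integer grouping), `x`, `y`, `z` and optionally
#'   `element`.
#' @param chain chain identifier (required for structure files with several
#'   chains).
#' @param prefilter centroid-distance prefilter in Angstroms: atom-level
#'   distances are only computed for residue pairs whose centroids are within
#'   `prefilter` plus both residue radii (exact for min distances).
#' @return a `distance_matrix` list: `D` (square numeric, Angstroms),
#'   `labels` (residue identifiers), `residues` (one-letter sequence),
#'   `mask` (TRUE for structured positions).
#' @export
min_atom_distance_matrix <- function(x, chain = NULL, prefilter = 40) {
  at <- structure_atoms(x, chain)
  res_ids <- unique(at$residue)
  n <- length(res_ids)
  if (n < 2) abort("chain must contain at least two nucleotides")
  coords <- lapply(res_ids, function(r) {
    as.matrix(at[at$residue == r, c("x", "y", "z"), drop = FALSE])
  })
  present <- vapply(coords, nrow, 0L) > 0
  cent <- t(vapply(coords, function(m) {
    if (nrow(m) == 0) c(NA_real_, NA_real_, NA_real_) else colMeans(m)
  }, numeric(3)))
  rad <- vapply(seq_len(n), function(i) {
    if (!present[i]) return(0)
    sqrt(max(rowSums(sweep(coords[[i]], 2, cent[i, ])^2)))
  }, 0)
  D <- matrix(Inf, n, n)
  diag(D) <- 0
  for (i in seq_len(n - 1)) {
    if (!present[i]) next
    for (j in (i + 1):n) {
      if (!present[j]) next
      cd <- sqrt(sum((cent[i, ] - cent[j, ])^2))
      if (cd - rad[i] - rad[j] > prefilter) next
      A <- coords[[i]]; B <- coords[[j]]
      # |a-b|^2 = |a|^2 + |b|^2 - 2 a.b, minimized over all atom pairs
      cross <- outer(rowSums(A^2), rowSums(B^2), "+") - 2 * tcrossprod(A, B)
      D[i, j] <- D[j, i] <- sqrt(max(min(cross), 0))
    }
  }
  seqs <- attr(at, "residue_letters")
  structure(list(D = D, labels = res_ids, residues = seqs,
                 mask = present),
            class = "distance_matrix")
}

# mapping of common modified nucleotides to their parent base
MODIFIED_NT <- c(PSU = "U", `5MU` = "U", `4SU` = "U", H2U = "U", UR3 = "U",
                 OMU = "U", `3MU` = "U", `1MA` = "A", A2M = "A", MA6 = "A",
                 `2MA` = "A", `6MA` = "A", `5MC` = "C", OMC = "C", `4OC` = "C",
                 `2MG` = "G", M2G = "G", `7MG` = "G", OMG = "G", G7M = "G",
                 `1MG` = "G")

structure_atoms <- function(x, chain) {
  if (is.data.frame(x)) {
    stopifnot(all(c("residue", "x", "y", "z") %in% names(x)))
    at <- x
    if ("element" %in% names(at)) at <- at[toupper(at$element) != "H", ]
    letters <- attr(x, "residue_letters") %||%
      rep("N", length(unique(at$residue)))
    attr(at, "residue_letters") <- letters
    return(at)
  }
  pdb <- if (inherits(x, "pdb")) x else {
    if (grepl("\\.cif$", x)) bio3d::read.cif(x) else bio3d::read.pdb(x)
  }
  a <- pdb$atom
  if (!is.null(chain)) a <- a[a$chain == chain, ]
  if (nrow(a) == 0) abort("no atoms in the selected chain")
  base_map <- c(A = "A", C = "C", G = "G", U = "U", DT = "U", T = "U",
                MODIFIED_NT)
  a$resid_up <- toupper(trimws(a$resid))
  a <- a[a$resid_up %in% names(base_map), ]
  if (nrow(a) == 0) abort("selected chain contains no nucleotides")
  elem <- toupper(trimws(a$elesy %||% substr(trimws(a$elety), 1, 1)))
  a <- a[elem != "H" & !grepl("^H", trimws(a$elety)), ]
  key <- paste(a$chain, a$resno, a$insert %||% "", sep = "|")
  res_ids <- unique(key)
  letters <- vapply(res_ids, function(k) {
    base_map[[a$resid_up[match(k, key)]]]
  }, "")
  out <- data.frame(residue = key, x = a$x, y = a$y, z = a$z)
  attr(out, "residue_letters") <- unname(letters)
  out
}

#' Place a distance matrix into projected alignment coordinates
#'
#' Three-step adjustment: (1) the structure-resolved sequence is globally
#' aligned to the molecule's full sequence and sentinel (masked) rows and
#' columns are inserted at unresolved positions; (2) the matrix is placed
#' into alignment coordinates through the family row carrying the full
#' sequence; (3) columns where the reference row is gapped are dropped,
#' mirroring [project_to_reference()], so the output matches the projected
#' family width.
#'
#' @param dm a `distance_matrix` (its residues are the resolved sequence).
#' @param full_sequence the molecule's complete sequence (what the family row
#'   contains, ungapped).
#' @param family an [aligned_family()] containing `row_id`.
#' @param ref_row_id reference row defining the final coordinates.
#' @param row_id family row holding `full_sequence`; defaults to
#'   `ref_row_id`.
#' @return a `distance_matrix` in projected reference coordinates; inserted
#'   positions are masked.
#' @export
align_distance_matrix_to_msa <- function(dm, full_sequence, family,
                                         ref_row_id, row_id = ref_row_id) {
  stopifnot(inherits(dm, "distance_matrix"))
  pdb_seq <- paste(dm$residues, collapse = "")
  full_sequence <- canonicalize_rna(full_sequence, allow_gap = FALSE)
  # step 1: align resolved sequence into the full sequence
  if (nchar(pdb_seq) == nchar(full_sequence) && pdb_seq == full_sequence) {
    pos_in_full <- seq_len(nchar(full_sequence))
  } else {
    aln <- Biostrings::pairwiseAlignment(
      pdb_seq, full_sequence, type = "global",
      substitutionMatrix = Biostrings::nucleotideSubstitutionMatrix(
        match = 1, mismatch = -2, baseOnly = FALSE, type = "RNA"),
      gapOpening = 0, gapExtension = 1)
    pat <- seq_chars(as.character(Biostrings::alignedPattern(aln)))
    sub <- seq_chars(as.character(Biostrings::alignedSubject(aln)))
    if (any(sub == "-")) {
      abort("resolved residues outside the full sequence: unalignable structure")
    }
    pos_in_full <- which(pat != "-")
    if (length(pos_in_full) != nrow(dm$D)) {
      abort("alignment of the resolved sequence to the full sequence failed")
    }
  }
  Lf <- nchar(full_sequence)
  D1 <- matrix(Inf, Lf, Lf); diag(D1) <- 0
  D1[pos_in_full, pos_in_full] <- dm$D
  mask1 <- rep(FALSE, Lf); mask1[pos_in_full] <- dm$mask
  # step 2: place into MSA coordinates via the family row
  if (!row_id %in% family$ids) abort(sprintf("row '%s' not in family", row_id))
  row_ch <- seq_chars(family$rows[[row_id]])
  row_pos <- which(row_ch != "-")
  if (length(row_pos) != Lf) {
    abort("full sequence length does not match its (ungapped) family row")
  }
  L2 <- family$n_columns
  D2 <- matrix(Inf, L2, L2); diag(D2) <- 0
  D2[row_pos, row_pos] <- D1
  mask2 <- rep(FALSE, L2); mask2[row_pos] <- mask1
  # step 3: drop reference-specific gap columns
  keep <- which(seq_chars(family$rows[[ref_row_id]]) != "-")
  if (length(keep) == 0) abort("reference row is all gaps")
  structure(list(D = D2[keep, keep, drop = FALSE],
                 labels = as.character(keep),
                 residues = rep(NA_character_, length(keep)),
                 mask = mask2[keep]),
            class = "distance_matrix")
}

#' Wrap a plain square matrix as a distance matrix
#' @param D square numeric matrix (Angstroms) or an existing
#'   `distance_matrix` (returned unchanged).
#' @param mask optional logical vector of structured positions.
#' @return a `distance_matrix`.
#' @export
as_distance_matrix <- function(D, mask = NULL) {
  if (inherits(D, "distance_matrix")) return(D)
  stopifnot(is.matrix(D), nrow(D) == ncol(D))
  structure(list(D = D, labels = as.character(seq_len(nrow(D))),
                 residues = rep(NA_character_, nrow(D)),
                 mask = mask %||% rep(TRUE, nrow(D))),
            class = "distance_matrix")
}

#' Binary contact map from a distance matrix
#'
#' Either thresholding (`cutoff`: contact when distance < d, symmetric) or
#' per-row k-nearest neighbors (`knn`: the k smallest finite distances per
#' row, self excluded, distance ties broken toward the lower column index;
#' possibly asymmetric). Masked positions give all-zero rows and columns.
#'
#' @param D a `distance_matrix` or plain square matrix (Angstroms).
#' @param method `"cutoff"` or `"knn"`.
#' @param d distance cutoff in Angstroms (cutoff method).
#' @param k neighbors per row (knn method); must be smaller than the number
#'   of positions.
#' @return a `contact_map` list: binary matrix `M`, `method`, and the
#'   parameter used.
#' @export
contact_map <- function(D, method = c("cutoff", "knn"), d = 12, k = 50) {
  method <- match.arg(method)
  dm <- as_distance_matrix(D)
  n <- nrow(dm$D)
  Dm <- dm$D
  Dm[!dm$mask, ] <- Inf; Dm[, !dm$mask] <- Inf
  if (method == "cutoff") {
    M <- (Dm < d) * 1
    diag(M) <- 0
  } else {
    if (k >= n) abort(sprintf("k (%d) must be smaller than the number of positions (%d)", k, n))
    M <- matrix(0, n, n)
    for (i in seq_len(n)) {
      if (!dm$mask[i]) next
      di <- Dm[i, ]; di[i] <- Inf
      finite <- which(is.finite(di))
      if (length(finite) == 0) next
      take <- finite[order(di[finite], finite)][seq_len(min(k, length(finite)))]
      M[i, take] <- 1
    }
  }
  structure(list(M = M, method = method,
                 param = if (method == "cutoff") c(d = d) else c(k = k)),
            class = "contact_map")
}

as_contact_matrix <- function(x) {
  if (inherits(x, "contact_map")) x$M else x
}

#' Symmetrize a k-NN contact map by support union
#' @param map a `contact_map` or binary matrix.
#' @return binary matrix `M | t(M)`.
#' @export
symmetrize_contacts <- function(map) {
  M <- as_contact_matrix(map)
  (M + t(M) > 0) * 1
}

#' Structural correlation between two contact maps
#'
#' The normalized inner product
#' `Corr(A, B) = sum(A * B) / sqrt(sum(A^2) * sum(B^2))` -- cosine similarity
#' of contact supports, 1 for identical nonzero maps and 0 for disjoint ones.
#'
#' @param A,B `contact_map`s or binary matrices of equal dimension.
#' @return correlation in \[0,1\]; `NA` with attribute `undefined = TRUE`
#'   when either map has no contacts.
#' @export
structural_correlation <- function(A, B) {
  MA <- as_contact_matrix(A); MB <- as_contact_matrix(B)
  stopifnot(all(dim(MA) == dim(MB)))
  na2 <- sum(MA^2); nb2 <- sum(MB^2)
  if (na2 == 0 || nb2 == 0) {
    return(structure(NA_real_, undefined = TRUE))
  }
  sum(MA * MB) / sqrt(na2 * nb2)
}

#' Smallest distance not covered by a k-NN contact map
#'
#' Builds the symmetrized (union) k-nearest-neighbor map and returns the
#' minimum distance among pairs absent from it: the coverage radius below
#' which every contact is included. `Inf` when all pairs are covered.
#'
#' @param D a `distance_matrix` or square matrix.
#' @param k neighbors per row.
#' @return distance in Angstroms.
#' @export
min_uncovered_distance <- function(D, k) {
  dm <- as_distance_matrix(D)
  M <- symmetrize_contacts(contact_map(dm, "knn", k = k))
  Dm <- dm$D
  Dm[!dm$mask, ] <- Inf; Dm[, !dm$mask] <- Inf
  diag(Dm) <- Inf
  unc <- Dm[M == 0]
  unc <- unc[is.finite(unc)]
  if (length(unc) == 0) Inf else min(unc)
}

#' Write a contact map as a TSV edge list
#' @param map a `contact_map`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_contact_edges <- function(map, path) {
  M <- as_contact_matrix(map)
  idx <- which(M == 1, arr.ind = TRUE)
  utils::write.table(
    tibble(i = idx[, 1], j = idx[, 2]),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
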