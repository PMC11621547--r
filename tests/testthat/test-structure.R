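res_df <- function(...) {
  # build an atom data frame from residue: list(x,y,z) triples
  args <- list(...)
  out <- do.call(rbind, lapply(seq_along(args), function(i) {
    m <- matrix(args[[i]], ncol = 3, byrow = TRUE)
    data.frame(residue = i, x = m[, 1], y = m[, 2], z = m[, 3])
  }))
  out
}

test_that("minimum-atom distances follow the geometry", {
  # two single-atom residues at a 3-4-5 triangle
  dm <- min_atom_distance_matrix(res_df(c(0, 0, 0), c(3, 4, 0)))
  expect_equal(dm$D[1, 2], 5)
  # residues sharing an identical atom coordinate touch at 0
  dm0 <- min_atom_distance_matrix(res_df(c(1, 1, 1, 9, 9, 9), c(1, 1, 1)))
  expect_equal(dm0$D[1, 2], 0)
})

test_that("minimum-atom distances match the exhaustive all-atom oracle", {
  set.seed(21)
  coords <- lapply(1:4, function(i) matrix(runif(9, 0, 30), 3, 3))
  df <- do.call(rbind, lapply(1:4, function(i) {
    data.frame(residue = i, x = coords[[i]][, 1], y = coords[[i]][, 2],
               z = coords[[i]][, 3])
  }))
  dm <- min_atom_distance_matrix(df)
  for (i in 1:3) for (j in (i + 1):4) {
    best <- Inf
    for (a in 1:3) for (b in 1:3) {
      best <- min(best, sqrt(sum((coords[[i]][a, ] - coords[[j]][b, ])^2)))
    }
    expect_equal(dm$D[i, j], best)
    expect_equal(dm$D[j, i], best)
  }
  expect_equal(diag(dm$D), rep(0, 4))
})

test_that("PDB input maps modified residues and drops hydrogens", {
  f <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c(
    "ATOM      1  P     A A   1       0.000   0.000   0.000  1.00  0.00           P",
    "ATOM      2  H1    A A   1      50.000  50.000  50.000  1.00  0.00           H",
    "ATOM      3  P   PSU A   2       3.000   4.000   0.000  1.00  0.00           P",
    "ATOM      4  O2' PSU A   2       3.000   4.000   1.000  1.00  0.00           O",
    "END"), f)
  dm <- min_atom_distance_matrix(f, chain = "A")
  expect_equal(dm$residues, c("A", "U")) # PSU -> parent U
  expect_equal(dm$D[1, 2], 5)            # hydrogen at (50,50,50) excluded
})

test_that("distance matrices project into alignment coordinates", {
  set.seed(5)
  full <- "ACGUGG"
  # identity case: resolved == full, ungapped reference row
  D <- matrix(runif(36, 1, 20), 6, 6); D <- (D + t(D)) / 2; diag(D) <- 0
  dm <- as_distance_matrix(D)
  dm$residues <- strsplit(full, "")[[1]]
  fam1 <- aligned_family(c("ref", "x"), c("ACGUGG", "ACGUGG"))
  out1 <- align_distance_matrix_to_msa(dm, full, fam1, "ref")
  expect_equal(out1$D, D)

  # one unresolved residue inserts one masked row/column
  dm5 <- as_distance_matrix(D[-3, -3])
  dm5$residues <- strsplit("ACUGG", "")[[1]]
  out2 <- align_distance_matrix_to_msa(dm5, full, fam1, "ref")
  expect_equal(dim(out2$D), c(6, 6))
  expect_false(out2$mask[3])
  expect_true(all(is.infinite(out2$D[3, -3])))

  # round trip through a gapped alignment: surviving entries unchanged
  fam2 <- aligned_family(c("ref", "other"),
                         c("AC-GUG-G", "ACAGUGAG"))
  out3 <- align_distance_matrix_to_msa(dm, full, fam2, "ref")
  expect_equal(out3$D, D) # reference projection restores original coordinates
})

test_that("contact maps implement cutoff and k-NN selection", {
  D <- matrix(c(0, 5, 20,
                5, 0, 8,
                20, 8, 0), 3, 3)
  cu <- contact_map(D, "cutoff", d = 12)
  expect_equal(cu$M, bf_cutoff_map(D, 12))
  expect_equal(which(cu$M == 1, arr.ind = TRUE)[, 1], c(2, 1, 3, 2),
               ignore_attr = TRUE)
  kn <- contact_map(D, "knn", k = 1)
  expect_equal(kn$M[1, ], c(0, 1, 0)) # row 1 -> column 2
  expect_equal(kn$M[3, ], c(0, 1, 0)) # row 3 -> column 2
  expect_equal(kn$M, bf_knn_map(D, 1))
  full <- contact_map(D, "knn", k = 2)
  expect_true(all(full$M[row(full$M) != col(full$M)] == 1)) # k = n-1
  expect_error(contact_map(D, "knn", k = 3), "smaller")
  # distance ties break toward the lower column index
  Dt <- matrix(c(0, 3, 3, 3, 0, 9, 3, 9, 0), 3, 3)
  expect_equal(contact_map(Dt, "knn", k = 1)$M[1, ], c(0, 1, 0))
})

test_that("contact maps are monotone in their parameter", {
  set.seed(31)
  D <- matrix(runif(100, 1, 30), 10, 10); D <- (D + t(D)) / 2; diag(D) <- 0
  for (pair in list(c(5, 10), c(10, 20))) {
    A <- contact_map(D, "cutoff", d = pair[1])$M
    B <- contact_map(D, "cutoff", d = pair[2])$M
    expect_true(all(B[A == 1] == 1)) # support grows with d
  }
  for (pair in list(c(1, 3), c(3, 7))) {
    A <- contact_map(D, "knn", k = pair[1])$M
    B <- contact_map(D, "knn", k = pair[2])$M
    expect_true(all(B[A == 1] == 1)) # support grows with k
  }
  ks <- c(1, 3, 5, 8)
  mud <- vapply(ks, function(k) min_uncovered_distance(D, k), 0)
  expect_true(all(diff(mud) >= 0)) # non-decreasing in k
})

test_that("structural correlation is the normalized contact inner product", {
  A <- matrix(0, 4, 4); A[1, 2] <- A[2, 1] <- A[3, 4] <- A[4, 3] <- 1
  expect_equal(structural_correlation(A, A), 1)
  B <- matrix(0, 4, 4); B[1, 3] <- B[3, 1] <- 1
  expect_equal(structural_correlation(A, B), 0)
  # |A ∩ B| = 2, |A| = 2, |B| = 4
  A2 <- matrix(0, 4, 4); A2[1, 2] <- A2[2, 3] <- 1
  B2 <- matrix(0, 4, 4); B2[1, 2] <- B2[2, 3] <- B2[3, 4] <- B2[4, 1] <- 1
  expect_equal(structural_correlation(A2, B2), 2 / sqrt(8))
  expect_equal(structural_correlation(A2, B2), bf_corr(A2, B2))
  expect_equal(structural_correlation(A2, B2), structural_correlation(B2, A2))
  z <- matrix(0, 4, 4)
  res <- structural_correlation(A, z)
  expect_true(is.na(res))
  expect_true(attr(res, "undefined"))
})

test_that("min_uncovered_distance finds the first gap in k-NN coverage", {
  D <- matrix(c(0, 5, 20,
                5, 0, 8,
                20, 8, 0), 3, 3)
  expect_equal(min_uncovered_distance(D, 1), 20) # pair (1,3) uncovered
  expect_equal(min_uncovered_distance(D, 2), Inf) # k = n-1 covers everything
})

test_that("graph features carry RBF and relative-position structure", {
  set.seed(41)
  D <- matrix(runif(64, 1, 25), 8, 8); D <- (D + t(D)) / 2; diag(D) <- 0
  cfg <- gnn_config(k = 3)
  gf <- build_graph_features(D, cfg)
  expect_true(all(table(gf$edges$i) == 3)) # k outgoing edges per node
  expect_equal(ncol(gf$features), cfg$rbf_count + cfg$relpos_features)
  # an RBF activation peaks when the distance sits on its center
  centers <- seq(0, 20, length.out = 16)
  act <- rnaforge:::rbf_activations(centers[5], cfg)
  expect_equal(which.max(act), 5)
  expect_equal(max(act), 1)
})
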