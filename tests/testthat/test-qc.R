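test_that("noncanonical_bp_fraction scores pairs against the canonical set", {
  pairs <- tibble::tibble(i = c(1, 2, 3), j = c(6, 5, 4))
  # (G,C) canonical; (C,U) and (G,A) not
  expect_equal(as.numeric(noncanonical_bp_fraction("GCGAUC", pairs)), 2 / 3)
  # perfect Watson-Crick helix
  expect_equal(as.numeric(noncanonical_bp_fraction("GCAUGC", pairs)), 0)
  # pairs touching gaps or N are excluded entirely
  allgap <- noncanonical_bp_fraction("--N-N-", pairs)
  expect_equal(as.numeric(allgap), 0)
  expect_equal(attr(allgap, "n_scorable"), 0L)
  expect_error(noncanonical_bp_fraction("GC", tibble::tibble(i = 1, j = 5)),
               "out of range")
})

test_that("noncanonical_bp_fraction matches the brute-force oracle and is swap-invariant", {
  set.seed(3)
  for (rep in 1:20) {
    L <- 30
    row <- paste(sample(c("A", "C", "G", "U", "-", "N"), L, replace = TRUE,
                        prob = c(.2, .2, .2, .2, .1, .1)), collapse = "")
    idx <- sample(L, 10)
    pairs <- tibble::tibble(i = pmin(idx[1:5], idx[6:10]),
                            j = pmax(idx[1:5], idx[6:10]))
    pairs <- pairs[pairs$i != pairs$j, ]
    expect_equal(as.numeric(noncanonical_bp_fraction(row, pairs)),
                 bf_noncanonical(row, pairs))
    swapped <- tibble::tibble(i = pairs$i, j = pairs$j) # orientation i<j kept;
    # swap check via reversed complement positions: value must not depend on
    # which member of the pair is listed first
    rev_pairs <- pairs[rev(seq_len(nrow(pairs))), ]
    expect_equal(as.numeric(noncanonical_bp_fraction(row, rev_pairs)),
                 as.numeric(noncanonical_bp_fraction(row, pairs)))
  }
})

make_qc_fixture <- function() {
  # 10 rows x 50 consensus columns; rows 1-2 carry 3 Ns (6% ambiguity),
  # row 3 covers only 40/50 consensus columns (0.80), rest are clean
  base <- rand_rna(50, seed = 9)
  rows <- rep(base, 10)
  ch <- strsplit(base, "")[[1]]
  amb <- ch; amb[c(5, 15, 25)] <- "N"
  rows[1] <- paste(amb, collapse = "")
  amb2 <- ch; amb2[c(6, 16, 26)] <- "N"
  rows[2] <- paste(amb2, collapse = "")
  gap <- ch; gap[41:50] <- "-"
  rows[3] <- paste(gap, collapse = "")
  aligned_family(paste0("s", 1:10), rows)
}

test_that("quality filters remove ambiguity and coverage failures in order", {
  fam <- make_qc_fixture()
  res <- apply_qc_filters(fam, tibble::tibble(i = integer(), j = integer()),
                          qc_params(mode = "rrna"))
  expect_equal(length(res$family$ids), 7)
  rep <- res$report
  expect_equal(rep$failed_filters[1:3], c("ambiguity", "ambiguity", "coverage"))
  expect_true(all(rep$pass[4:10]))
  expect_equal(rep$ambiguity_fraction[1], 3 / 50)
  expect_equal(rep$consensus_coverage[3], 0.8)
  # survivors all share one length, so sd = 0 and the z-filters remove nothing
  st <- attr(rep, "stats")
  expect_equal(st$length_sd, 0)
})

test_that("quality filters: edge cases and idempotence", {
  fam <- make_qc_fixture()
  # zero tolerance for ambiguity
  res0 <- apply_qc_filters(fam, tibble::tibble(i = integer(), j = integer()),
                           qc_params(max_ambiguity_fraction = 0))
  expect_true(all(grepl("ambiguity", res0$report$failed_filters[1:2])))
  # all identical rows pass everything
  same <- aligned_family(paste0("s", 1:5), rep(rand_rna(30, seed = 1), 5))
  resid <- apply_qc_filters(same, tibble::tibble(i = 1, j = 30))
  expect_equal(length(resid$family$ids), 5)
  # single-row family: z-filters skipped and noted
  one <- aligned_family("only", rand_rna(30, seed = 2))
  res1 <- apply_qc_filters(one, tibble::tibble(i = integer(), j = integer()))
  expect_true(attr(res1$report, "stats")$zscore_filters_skipped)
  # idempotence when means/sds are reused from the first report
  full <- apply_qc_filters(fam, tibble::tibble(i = integer(), j = integer()))
  again <- apply_qc_filters(full$family,
                            tibble::tibble(i = integer(), j = integer()),
                            stats = attr(full$report, "stats"))
  expect_equal(length(again$family$ids), length(full$family$ids))
})

test_that("qc_params presets switch coverage and length thresholds", {
  expect_equal(qc_params(mode = "rrna")$min_consensus_coverage, 0.85)
  expect_equal(qc_params(mode = "rrna")$length_sd_multiplier, 1.0)
  expect_equal(qc_params(mode = "rfam228")$min_consensus_coverage, 0.90)
  expect_equal(qc_params(mode = "rfam228")$length_sd_multiplier, 2.0)
})

test_that("greedy clustering recovers designed identity groups", {
  seqs <- identity_group_fixture()
  res <- greedy_identity_split(seqs, identity_threshold = 0.8,
                               test_token_fraction = 0.25, rng_seed = 1)
  expect_equal(max(res$clusters$cluster), 4)
  expect_equal(bf_identity_components(unname(seqs), 0.8), 4)
  # groups never straddle the split
  by_cluster <- split(res$clusters$set, res$clusters$cluster)
  expect_true(all(vapply(by_cluster, function(s) length(unique(s)) == 1, TRUE)))
  # union/intersection and token-fraction contracts
  expect_setequal(c(res$train$id, res$test$id), names(seqs))
  expect_length(intersect(res$train$id, res$test$id), 0)
  tok <- function(t) sum(nchar(t$seq))
  expect_gte(tok(res$test), 0.25 * (tok(res$train) + tok(res$test)))
})

test_that("greedy clustering degenerate cases", {
  same3 <- setNames(rep("ACGUACGUAC", 3), c("a", "b", "c"))
  r <- greedy_identity_split(same3, 0.9, 0.5, rng_seed = 0)
  expect_equal(max(r$clusters$cluster), 1)
  expect_true(nrow(r$train) == 0 || nrow(r$test) == 0) # one cluster, never split

  disjoint <- c(x = "AAAAAAAA", y = "GGGGGGGG")
  r2 <- greedy_identity_split(disjoint, 0.6, 0, rng_seed = 0)
  expect_equal(max(r2$clusters$cluster), 2)

  r3 <- greedy_identity_split(character(0), 0.6, 0.5)
  expect_equal(nrow(r3$train) + nrow(r3$test), 0)
})

test_that("diversity_curve matches brute-force counts and is monotone", {
  seqs <- identity_group_fixture(per_group = 4)
  th <- c(0.95, 0.8, 0.3)
  curve <- diversity_curve(seqs, th)
  expect_equal(curve$n_clusters[curve$threshold == 0.8], 4)
  # at clearly separated thresholds greedy matches all-pairs components
  expect_equal(curve$n_clusters[curve$threshold == 0.8],
               bf_identity_components(unname(seqs), 0.8))
  expect_equal(curve$n_clusters[curve$threshold == 0.3],
               bf_identity_components(unname(seqs), 0.3))
  expect_true(all(diff(curve$n_clusters[order(-curve$threshold)]) <= 0))

  ident <- setNames(rep("ACGUACGU", 4), paste0("i", 1:4))
  expect_true(all(diversity_curve(ident, th)$n_clusters == 1))
  set.seed(1)
  distinct <- rand_rna_set(6, 40)
  expect_equal(diversity_curve(distinct, 0.99)$n_clusters, 6)
})
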