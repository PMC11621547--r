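#' Quality-control parameters for aligned RNA families
#'
#' Thresholds for the four sequential alignment filters: ambiguity fraction,
#' consensus coverage, length outliers, and non-canonical base-pair outliers.
#' The `rrna` mode uses the ribosomal-RNA defaults (85% coverage, 1 s.d.
#' length filter); the `rfam228` mode uses 90% coverage and 2 s.d.
#'
#' @param max_ambiguity_fraction maximum tolerated fraction of ambiguous
#'   residues (N after canonicalization).
#' @param min_consensus_coverage minimum fraction of consensus columns covered.
#' @param length_sd_multiplier sequences longer than mean + multiplier * s.d.
#'   are removed (one-sided; population s.d.).
#' @param bp_fraction_sd_multiplier same rule for the non-canonical base-pair
#'   fraction.
#' @param mode preset: `"rrna"` or `"rfam228"`.
#' @return a `qc_params` list.
#' @export
qc_params <- function(max_ambiguity_fraction = 0.05,
                      min_consensus_coverage = NULL,
                      length_sd_multiplier = NULL,
                      bp_fraction_sd_multiplier = 2,
                      mode = c("rrna", "rfam228")) {
  mode <- match.arg(mode)
  if (is.null(min_consensus_coverage)) {
    min_consensus_coverage <- if (mode == "rrna") 0.85 else 0.90
  }
  if (is.null(length_sd_multiplier)) {
    length_sd_multiplier <- if (mode == "rrna") 1.0 else 2.0
  }
  stopifnot(max_ambiguity_fraction >= 0, max_ambiguity_fraction <= 1,
            min_consensus_coverage > 0, min_consensus_coverage <= 1,
            length_sd_multiplier > 0, bp_fraction_sd_multiplier > 0)
  structure(list(max_ambiguity_fraction = max_ambiguity_fraction,
                 min_consensus_coverage = min_consensus_coverage,
                 length_sd_multiplier = length_sd_multiplier,
                 bp_fraction_sd_multiplier = bp_fraction_sd_multiplier,
                 mode = mode),
            class = "qc_params")
}

CANONICAL_PAIRS <- c("GC", "CG", "AU", "UA", "GU", "UG")

#' Fraction of non-canonical base pairs in an aligned row
#'
#' Scores the consensus pairs of a row against the canonical set
#' (Watson-Crick-Franklin GC/CG/AU/UA plus wobble GU/UG). Pairs with a gap or
#' N at either position are excluded from both numerator and denominator.
#'
#' @param row an aligned residue string.
#' @param pairs a pair tibble (`i`, `j`), e.g. from [pairs_from_wuss()].
#' @return fraction in \[0,1\]; 0 when no pair is scorable. The number of
#'   scorable pairs is attached as attribute `n_scorable`.
#' @export
noncanonical_bp_fraction <- function(row, pairs) {
  ch <- seq_chars(row)
  if (nrow(pairs) == 0) return(structure(0, n_scorable = 0L))
  if (max(pairs$j) > length(ch) || min(pairs$i) < 1) {
    abort("pair index out of range for this row")
  }
  a <- ch[pairs$i]; b <- ch[pairs$j]
  scorable <- a %in% RNA_ALPHABET & b %in% RNA_ALPHABET
  if (!any(scorable)) return(structure(0, n_scorable = 0L))
  frac <- mean(!paste0(a[scorable], b[scorable]) %in% CANONICAL_PAIRS)
  structure(frac, n_scorable = sum(scorable))
}

# population (ddof 0) standard deviation; fixed for reproducibility
pop_sd <- function(x) sqrt(mean((x - mean(x))^2))

#' Apply the sequence quality filters to an aligned family
#'
#' The four filters run in order -- ambiguity fraction, consensus coverage,
#' length z-score, non-canonical base-pair z-score -- with the mean/s.d. of
#' each z-score filter computed over the sequences that survived the previous
#' filters (population s.d.). Both z-score filters are one-sided: only values
#' above mean + multiplier * s.d. fail. With fewer than two survivors the
#' z-score filters are skipped and noted in the report.
#'
#' @param family an [aligned_family()].
#' @param pairs consensus pair tibble in the family's coordinates.
#' @param params a [qc_params()] object.
#' @param stats optional list with `length_mean`, `length_sd`, `bp_mean`,
#'   `bp_sd` to reuse (e.g. from a previous report) instead of recomputing.
#' @return a list with `family` (survivors) and `report`, a tibble with one
#'   row per input sequence: id, ambiguity_fraction, consensus_coverage,
#'   length, noncanonical_bp_fraction, n_scorable_pairs, pass, failed_filters.
#'   Family-level statistics are attached as attribute `stats`.
#' @export
apply_qc_filters <- function(family, pairs, params = qc_params(),
                             stats = NULL) {
  m <- family_matrix(family)
  nongap <- m != "-"
  amb <- rowSums(m == "N") / pmax(rowSums(nongap), 1)
  cons_cols <- which(family$consensus_mask)
  coverage <- rowSums(nongap[, cons_cols, drop = FALSE]) / length(cons_cols)
  len <- rowSums(nongap)
  bp <- vapply(family$rows, function(r) {
    as.numeric(noncanonical_bp_fraction(r, pairs))
  }, 0)
  n_scor <- vapply(family$rows, function(r) {
    attr(noncanonical_bp_fraction(r, pairs), "n_scorable")
  }, 0L)

  fail <- vector("list", length(family$ids))
  alive <- rep(TRUE, length(family$ids))

  mark <- function(idx, label) {
    for (k in idx) fail[[k]] <<- c(fail[[k]], label)
    alive[idx] <<- FALSE
  }
  mark(which(alive & amb > params$max_ambiguity_fraction), "ambiguity")
  mark(which(alive & coverage < params$min_consensus_coverage), "coverage")

  zskipped <- FALSE
  zfilter <- function(vals, mult, mean_in, sd_in, label) {
    idx <- which(alive)
    if (is.null(mean_in)) {
      if (length(idx) < 2) { zskipped <<- TRUE; return(c(NA_real_, NA_real_)) }
      mean_in <- mean(vals[idx]); sd_in <- pop_sd(vals[idx])
    }
    if (is.na(sd_in) || sd_in == 0) return(c(mean_in, sd_in))
    mark(idx[vals[idx] > mean_in + mult * sd_in], label)
    c(mean_in, sd_in)
  }
  ls <- zfilter(len, params$length_sd_multiplier,
                stats$length_mean, stats$length_sd, "length")
  bs <- zfilter(bp, params$bp_fraction_sd_multiplier,
                stats$bp_mean, stats$bp_sd, "bp_fraction")

  report <- tibble(
    id = family$ids,
    ambiguity_fraction = unname(amb),
    consensus_coverage = unname(coverage),
    length = unname(len),
    noncanonical_bp_fraction = unname(bp),
    n_scorable_pairs = unname(n_scor),
    pass = alive,
    failed_filters = vapply(fail, function(f) {
      if (is.null(f)) "" else paste(f, collapse = ",")
    }, ""))
  attr(report, "stats") <- list(length_mean = ls[1], length_sd = ls[2],
                                bp_mean = bs[1], bp_sd = bs[2],
                                zscore_filters_skipped = zskipped)
  keep <- which(alive)
  if (length(keep) == 0) abort("no sequences survive the quality filters")
  surv <- aligned_family(family$ids[keep], unname(family$rows[keep]),
                         ss_cons = family$ss_cons,
                         consensus_mask = family$consensus_mask,
                         labels = family$labels[keep])
  list(family = surv, report = report)
}

#' Pairwise fractional identity between two sequences
#'
#' For unaligned input, identity is the number of identical aligned residues
#' in a deterministic global alignment divided by the shorter sequence
#' length. For pre-aligned rows (`aligned = TRUE`), identity is the fraction
#' of identical residues over columns where both rows are non-gap.
#'
#' @param a,b residue strings.
#' @param aligned are `a` and `b` rows of the same alignment?
#' @return identity in \[0,1\].
#' @export
pairwise_identity <- function(a, b, aligned = FALSE) {
  if (aligned) {
    ca <- seq_chars(a); cb <- seq_chars(b)
    stopifnot(length(ca) == length(cb))
    both <- ca != "-" & cb != "-"
    if (!any(both)) return(0)
    return(mean(ca[both] == cb[both]))
  }
  aln <- Biostrings::pairwiseAlignment(
    a, b, type = "global",
    substitutionMatrix = Biostrings::nucleotideSubstitutionMatrix(
      match = 1, mismatch = -1, baseOnly = FALSE, type = "RNA"),
    gapOpening = 4, gapExtension = 1)
  Biostrings::nmatch(aln) / min(nchar(a), nchar(b))
}

greedy_identity_clusters <- function(tbl, identity_threshold, aligned = FALSE) {
  ord <- order(-nchar(gsub("-", "", tbl$seq, fixed = TRUE)), tbl$id)
  centroids <- integer()
  assignment <- integer(nrow(tbl))
  for (k in ord) {
    hit <- 0L
    for (ci in centroids) {
      if (pairwise_identity(tbl$seq[k], tbl$seq[ci], aligned = aligned) >=
          identity_threshold) { hit <- ci; break }
    }
    if (hit == 0L) { centroids <- c(centroids, k); hit <- k }
    assignment[k] <- hit
  }
  tibble(id = tbl$id, cluster = match(assignment, centroids),
         centroid = tbl$id[assignment])
}

#' Greedy identity clustering and train/test split
#'
#' Clusters sequences greedily (longest first, assigned to the first centroid
#' at or above the identity threshold), then assigns whole clusters to the
#' test set by a seeded shuffle until it holds at least the requested fraction
#' of nucleotides. No cluster is split across the two sets.
#'
#' @param sequences tibble with `id`/`seq`, or a named character vector.
#' @param identity_threshold fractional identity in (0,1).
#' @param test_token_fraction target fraction of nucleotides in the test set.
#' @param rng_seed integer seed for the cluster shuffle.
#' @param aligned treat sequences as rows of one alignment (identity on
#'   shared columns)?
#' @return list with tibbles `train`, `test` and `clusters`
#'   (id, cluster, centroid, set).
#' @export
greedy_identity_split <- function(sequences, identity_threshold,
                                  test_token_fraction = 0.1, rng_seed = 0,
                                  aligned = FALSE) {
  tbl <- as_seq_tbl(sequences)
  if (nrow(tbl) == 0) {
    empty <- tbl[0, ]
    return(list(train = empty, test = empty,
                clusters = tibble(id = character(), cluster = integer(),
                                  centroid = character(), set = character())))
  }
  stopifnot(identity_threshold > 0, identity_threshold < 1,
            test_token_fraction >= 0, test_token_fraction < 1)
  cl <- greedy_identity_clusters(tbl, identity_threshold, aligned = aligned)
  ntok <- nchar(gsub("-", "", tbl$seq, fixed = TRUE))
  total <- sum(ntok)
  cluster_ids <- sort(unique(cl$cluster))
  shuffled <- withr::with_seed(rng_seed, sample(cluster_ids))
  test_clusters <- integer(); test_tok <- 0
  for (c0 in shuffled) {
    if (test_tok >= test_token_fraction * total) break
    test_clusters <- c(test_clusters, c0)
    test_tok <- test_tok + sum(ntok[cl$cluster == c0])
  }
  in_test <- cl$cluster %in% test_clusters
  cl$set <- ifelse(in_test, "test", "train")
  list(train = tbl[!in_test, ], test = tbl[in_test, ], clusters = cl)
}

#' Cluster counts across identity thresholds
#'
#' Greedy-clusters the input at each threshold and reports the number of
#' clusters, a simple diversity curve for an alignment or sequence set.
#'
#' @inheritParams greedy_identity_split
#' @param thresholds numeric vector of identity thresholds in (0,1).
#' @return tibble with columns `threshold` and `n_clusters`.
#' @export
diversity_curve <- function(sequences, thresholds, aligned = FALSE) {
  tbl <- as_seq_tbl(sequences)
  stopifnot(all(thresholds > 0 & thresholds < 1))
  tibble(threshold = thresholds,
         n_clusters = vapply(thresholds, function(th) {
           max(greedy_identity_clusters(tbl, th, aligned = aligned)$cluster)
         }, 0L))
}
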