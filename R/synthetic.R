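#' Specification of a synthetic RNA family
#'
#' Describes a simulated aligned family with a fixed consensus, helical
#' (paired) columns drawn jointly from canonical pair frequencies, a
#' hyperthermophile subpopulation carrying planted compositional shifts at
#' unpaired columns, per-position substitution noise, optional gap
#' injection, and growth-temperature labels (thermophiles >= 60 degrees C).
#' The defaults describe the reference experiment used throughout the
#' package: 200 columns, 2,500 rows of which 20% are thermophiles, five
#' planted U-to-C shifts of strength 0.9.
#'
#' @param length number of alignment columns.
#' @param helices pair tibble (`i`, `j`) of paired columns; default: three
#'   10-bp hairpins.
#' @param background_freqs named frequencies over A,C,G,U for unpaired
#'   consensus columns.
#' @param pair_freqs named frequencies over the six canonical pairs for
#'   consensus helices.
#' @param mutation_rate per-position probability that a row deviates from
#'   the consensus (substitution to a uniformly random other nucleotide).
#' @param pair_turnover per-row, per-helix-pair probability that the pair is
#'   re-drawn jointly from `pair_freqs` (a compensatory double substitution):
#'   this gives the family its covariation, so paired columns carry mutual
#'   information while staying canonical.
#' @param planted_columns tibble with `column`, `from`, `to`, `delta`: at
#'   each planted (unpaired) column, thermophile rows carry `to` with
#'   probability `delta`, otherwise `from`; mesophiles carry `from`. The
#'   consensus is forced to `from` there.
#' @param thermophile_fraction probability a row is a thermophile.
#' @param gc_shift_thermo extra probability weight added to the G-C and C-G
#'   pairs (split evenly) when a thermophile row re-draws a helix pair: the
#'   thermophile GC-content shift.
#' @param ogt_mesophile,ogt_thermophile label means in degrees C (labels are
#'   normal around these, thermophiles truncated to >= 60).
#' @param gap_injection_rate per-position gap probability.
#' @param n_sequences rows to sample.
#' @param rng_seed seed; sampling is bit-reproducible under it.
#' @return a `synthetic_family_spec` list.
#' @export
synthetic_family_spec <- function(length = 200,
                                  helices = default_helices(),
                                  background_freqs = c(A = 0.25, C = 0.25,
                                                       G = 0.25, U = 0.25),
                                  pair_freqs = c(GC = 0.3, CG = 0.3,
                                                 AU = 0.15, UA = 0.15,
                                                 GU = 0.05, UG = 0.05),
                                  mutation_rate = 0.05,
                                  pair_turnover = 0.3,
                                  planted_columns = default_planted_columns(),
                                  thermophile_fraction = 0.2,
                                  gc_shift_thermo = 0.15,
                                  ogt_mesophile = 37, ogt_thermophile = 75,
                                  gap_injection_rate = 0,
                                  n_sequences = 2500, rng_seed = 0) {
  stopifnot(length >= 2, n_sequences >= 1,
            mutation_rate >= 0, mutation_rate < 1,
            pair_turnover >= 0, pair_turnover <= 1,
            thermophile_fraction >= 0, thermophile_fraction <= 1,
            gc_shift_thermo >= 0, gc_shift_thermo <= 1,
            gap_injection_rate >= 0, gap_injection_rate < 1)
  background_freqs <- background_freqs[RNA_ALPHABET] / sum(background_freqs)
  pair_freqs <- pair_freqs[CANONICAL_PAIRS] / sum(pair_freqs)
  if (anyNA(background_freqs) || anyNA(pair_freqs)) {
    abort("background_freqs must cover A,C,G,U and pair_freqs the six canonical pairs")
  }
  if (nrow(helices) > 0) {
    stopifnot(all(helices$i < helices$j), all(helices$j <= length))
    paired_cols <- c(helices$i, helices$j)
    if (anyDuplicated(paired_cols)) abort("a column appears in more than one pair")
  } else paired_cols <- integer()
  if (nrow(planted_columns) > 0) {
    stopifnot(all(planted_columns$column >= 1),
              all(planted_columns$column <= length),
              all(planted_columns$delta >= 0), all(planted_columns$delta <= 1),
              !anyDuplicated(planted_columns$column))
    if (any(planted_columns$column %in% paired_cols)) {
      abort("planted columns must be unpaired (outside all helices)")
    }
  }
  structure(list(length = as.integer(length), helices = helices,
                 background_freqs = background_freqs, pair_freqs = pair_freqs,
                 mutation_rate = mutation_rate, pair_turnover = pair_turnover,
                 planted_columns = planted_columns,
                 thermophile_fraction = thermophile_fraction,
                 gc_shift_thermo = gc_shift_thermo,
                 ogt_mesophile = ogt_mesophile,
                 ogt_thermophile = ogt_thermophile,
                 gap_injection_rate = gap_injection_rate,
                 n_sequences = as.integer(n_sequences),
                 rng_seed = rng_seed),
            class = "synthetic_family_spec")
}

#' Default helix layout: three 10-bp hairpins in a 200-column family
#' @return pair tibble (`i`, `j`).
#' @export
default_helices <- function() {
  hp <- function(a, b) tibble(i = a:(a + 9), j = b:(b - 9))
  dplyr::bind_rows(hp(31, 60), hp(81, 110), hp(131, 160))
}

#' Default planted thermophile shifts: five U-to-C columns
#' @return tibble with `column`, `from`, `to`, `delta`.
#' @export
default_planted_columns <- function() {
  tibble(column = c(45, 70, 95, 120, 170),
         from = "U", to = "C", delta = 0.9)
}

#' Consensus WUSS string of a synthetic spec
#' @param spec a [synthetic_family_spec()].
#' @return WUSS string with `(`/`)` at helix columns.
#' @export
spec_ss_cons <- function(spec) {
  ch <- rep(".", spec$length)
  ch[spec$helices$i] <- "("
  ch[spec$helices$j] <- ")"
  paste(ch, collapse = "")
}

#' Sample a synthetic RNA family
#'
#' Draws a consensus once (helix pairs jointly from the canonical pair
#' frequencies, unpaired columns from the background, planted columns fixed
#' to their `from` nucleotide), then samples rows: thermophile status,
#' thermophile GC re-draws in helices, planted-column emission, uniform
#' substitution noise, gap injection, and a growth-temperature label.
#'
#' @param spec a [synthetic_family_spec()].
#' @return a `family_sample` list: `family` (an [aligned_family()] with OGT
#'   labels and consensus structure), `consensus`, `is_thermophile`,
#'   `truth` ([planted_truth()]), `distance` ([synthetic_distance_matrix()]).
#' @export
sample_family <- function(spec) {
  stopifnot(inherits(spec, "synthetic_family_spec"))
  L <- spec$length; n <- spec$n_sequences
  withr::with_seed(spec$rng_seed, {
    consensus <- character(L)
    unpaired <- setdiff(seq_len(L), c(spec$helices$i, spec$helices$j))
    consensus[unpaired] <- sample(RNA_ALPHABET, length(unpaired),
                                  replace = TRUE, prob = spec$background_freqs)
    if (nrow(spec$helices) > 0) {
      pk <- sample(CANONICAL_PAIRS, nrow(spec$helices), replace = TRUE,
                   prob = spec$pair_freqs)
      consensus[spec$helices$i] <- substr(pk, 1, 1)
      consensus[spec$helices$j] <- substr(pk, 2, 2)
    }
    if (nrow(spec$planted_columns) > 0) {
      consensus[spec$planted_columns$column] <- spec$planted_columns$from
    }
    thermo <- runif(n) < spec$thermophile_fraction
    rows <- matrix(rep(consensus, each = n), n, L)
    # per-row joint pair re-draws: covariation with a thermophile GC shift
    if (nrow(spec$helices) > 0 && spec$pair_turnover > 0) {
      thermo_freqs <- spec$pair_freqs
      thermo_freqs[c("GC", "CG")] <- thermo_freqs[c("GC", "CG")] +
        spec$gc_shift_thermo / 2
      thermo_freqs <- thermo_freqs / sum(thermo_freqs)
      for (hk in seq_len(nrow(spec$helices))) {
        redraw <- which(runif(n) < spec$pair_turnover)
        if (length(redraw) == 0) next
        is_t <- thermo[redraw]
        pk <- character(length(redraw))
        if (any(!is_t)) {
          pk[!is_t] <- sample(CANONICAL_PAIRS, sum(!is_t), replace = TRUE,
                              prob = spec$pair_freqs)
        }
        if (any(is_t)) {
          pk[is_t] <- sample(CANONICAL_PAIRS, sum(is_t), replace = TRUE,
                             prob = thermo_freqs)
        }
        rows[redraw, spec$helices$i[hk]] <- substr(pk, 1, 1)
        rows[redraw, spec$helices$j[hk]] <- substr(pk, 2, 2)
      }
    }
    # planted shifts in thermophiles
    for (pk in seq_len(nrow(spec$planted_columns))) {
      pc <- spec$planted_columns[pk, ]
      ti <- which(thermo)
      hit <- ti[runif(length(ti)) < pc$delta]
      rows[hit, pc$column] <- pc$to
    }
    # substitution noise: uniformly one of the three other nucleotides
    if (spec$mutation_rate > 0) {
      noise <- which(matrix(runif(n * L) < spec$mutation_rate, n, L))
      if (length(noise) > 0) {
        cur <- rows[noise]
        shift <- sample.int(3, length(noise), replace = TRUE)
        rows[noise] <- RNA_ALPHABET[
          ((match(cur, RNA_ALPHABET) - 1L + shift) %% 4L) + 1L]
      }
    }
    if (spec$gap_injection_rate > 0) {
      rows[matrix(runif(n * L) < spec$gap_injection_rate, n, L)] <- "-"
    }
    labels <- ifelse(thermo,
                     pmax(60, rnorm(n, spec$ogt_thermophile, 7)),
                     pmin(59, rnorm(n, spec$ogt_mesophile, 5)))
    ids <- sprintf("%s%04d", ifelse(thermo, "thermo", "meso"), seq_len(n))
    fam <- aligned_family(ids, apply(rows, 1, paste, collapse = ""),
                          ss_cons = spec_ss_cons(spec), labels = labels)
  })
  structure(list(family = fam, consensus = paste(consensus, collapse = ""),
                 is_thermophile = thermo,
                 truth = planted_truth(spec),
                 distance = synthetic_distance_matrix(spec)),
            class = "family_sample")
}

#' Toy distance matrix consistent with a spec's helices
#'
#' Backbone neighbors sit at 6 Angstroms and helix partners at 5; every
#' other distance is the shortest-path length through this graph (edge
#' weights 6 and 5), so the matrix is symmetric with zero diagonal and
#' satisfies the triangle inequality by construction.
#'
#' @param spec a [synthetic_family_spec()].
#' @return a `distance_matrix`.
#' @export
synthetic_distance_matrix <- function(spec) {
  L <- spec$length
  from <- c(seq_len(L - 1), spec$helices$i)
  to <- c(seq_len(L - 1) + 1L, spec$helices$j)
  w <- c(rep(6, L - 1), rep(5, nrow(spec$helices)))
  g <- igraph::graph_from_data_frame(
    data.frame(from = from, to = to, weight = w),
    directed = FALSE, vertices = data.frame(name = seq_len(L)))
  D <- igraph::distances(g)
  o <- order(as.integer(rownames(D)))
  as_distance_matrix(unname(D[o, o]))
}

#' Ground truth for the planted shifts of a synthetic spec
#'
#' The per-column nucleotide distributions expected in the mesophile
#' ("pretraining") population and the thermophile ("finetuning") population
#' at each planted column -- accounting for the substitution noise -- the
#' closed-form Jensen-Shannon divergence between them, and the expected
#' positive [mutation_spec()]s.
#'
#' @param spec a [synthetic_family_spec()].
#' @return tibble with column, from, to, delta, expected frequency of `to`
#'   in each population, and `expected_jsd`; the mutation specs are in
#'   attribute `mutations`.
#' @export
planted_truth <- function(spec) {
  pc <- spec$planted_columns
  mu <- spec$mutation_rate
  # emission before noise -> after noise: stay w.p. (1-mu), else uniform other 3
  smear <- function(p_to, from, to) {
    base <- setNames(rep(0, 4), RNA_ALPHABET)
    base[to] <- p_to; base[from] <- 1 - p_to
    (1 - mu) * base + mu * (1 - base) / 3
  }
  ft_to <- numeric(nrow(pc)); pt_to <- numeric(nrow(pc)); ejsd <- numeric(nrow(pc))
  thermo_w <- spec$thermophile_fraction
  for (r in seq_len(nrow(pc))) {
    d_ft <- smear(pc$delta[r], pc$from[r], pc$to[r])
    # the full (pretraining) population mixes thermophiles and mesophiles
    d_pt <- thermo_w * d_ft + (1 - thermo_w) * smear(0, pc$from[r], pc$to[r])
    ft_to[r] <- d_ft[pc$to[r]]; pt_to[r] <- d_pt[pc$to[r]]
    ejsd[r] <- jsd(d_pt, d_ft)
  }
  out <- tibble(column = pc$column, from = pc$from, to = pc$to,
                delta = pc$delta, expected_ft_freq = ft_to,
                expected_pt_freq = pt_to, expected_jsd = ejsd)
  attr(out, "mutations") <- lapply(seq_len(nrow(pc)), function(r) {
    mutation_spec(pc$column[r], pc$from[r], pc$to[r])
  })
  out
}
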