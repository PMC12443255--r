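#' @name synthetic_data
#' @title Offline fixture generators
#' @description
#' Seeded generators for every statistical structure the pipeline
#' assumes: imbalanced two-class Gaussian feature matrices (mirroring
#' the canonical 487-positive / 1,479-negative training imbalance) and
#' random peptide sequences whose positive class is enriched in
#' designated residues, so residue-attribution recovery is testable
#' without any external model or dataset.
NULL

#' Two-class Gaussian blob specification
#'
#' @param n_minority minority (positive) count, default 487.
#' @param n_majority majority (negative) count, default 1479.
#' @param dim feature dimensionality, default 16.
#' @param class_separation Euclidean distance between the two class
#'   means, default 3.
#' @param within_class_spread isotropic within-class standard
#'   deviation, default 1.
#' @param seed integer seed.
#' @return A `blob_spec` list.
#' @export
blob_spec <- function(n_minority = 487L, n_majority = 1479L, dim = 16L,
                      class_separation = 3, within_class_spread = 1,
                      seed = 1L) {
  stopifnot(n_minority >= 2L, n_majority >= 2L, dim >= 1L,
            within_class_spread > 0)
  structure(list(n_minority = as.integer(n_minority),
                 n_majority = as.integer(n_majority),
                 dim = as.integer(dim),
                 class_separation = class_separation,
                 within_class_spread = within_class_spread,
                 seed = as.integer(seed)),
            class = "blob_spec")
}

#' Generate imbalanced Gaussian blobs
#'
#' Two isotropic Gaussian clusters: the majority (label 0) centered at
#' the origin, the minority (label 1) displaced by `class_separation`
#' along the first axis. A pure function of its specification object,
#' seed included.
#'
#' @param spec a [blob_spec()].
#' @return A [labeled_matrix] with minority rows first.
#' @export
make_blobs <- function(spec = blob_spec()) {
  stopifnot(inherits(spec, "blob_spec"))
  with_seed(spec$seed, {
    mu <- c(spec$class_separation, rep(0, spec$dim - 1L))
    Xmin <- matrix(stats::rnorm(spec$n_minority * spec$dim,
                                sd = spec$within_class_spread),
                   spec$n_minority, spec$dim)
    Xmin <- sweep(Xmin, 2, mu, "+")
    Xmaj <- matrix(stats::rnorm(spec$n_majority * spec$dim,
                                sd = spec$within_class_spread),
                   spec$n_majority, spec$dim)
    labeled_matrix(rbind(Xmin, Xmaj),
                   c(rep(1L, spec$n_minority), rep(0L, spec$n_majority)))
  })
}

#' Planted-signal sequence specification
#'
#' @param n_pos,n_neg per-class counts.
#' @param length_range inclusive sequence length range, default
#'   `c(5, 50)`.
#' @param enriched_residues letters upweighted in positives, default
#'   `c("K", "L", "F", "G")` — the residues most consistently implicated
#'   in anticancer activity (basicity, hydrophobicity, flexibility).
#' @param enrichment_factor multiplicative weight on enriched letters
#'   in the positive class, default 3; a factor of 1 gives the null
#'   case where both classes share the uniform composition.
#' @param seed integer seed.
#' @return A `sequence_spec` list.
#' @export
sequence_spec <- function(n_pos = 500L, n_neg = 500L,
                          length_range = c(5L, 50L),
                          enriched_residues = c("K", "L", "F", "G"),
                          enrichment_factor = 3, seed = 1L) {
  stopifnot(n_pos >= 1L, n_neg >= 1L, enrichment_factor >= 1,
            length_range[1] >= 5L, length_range[2] <= 50L,
            length_range[1] <= length_range[2],
            all(enriched_residues %in% AA_ALPHABET20))
  structure(list(n_pos = as.integer(n_pos), n_neg = as.integer(n_neg),
                 length_range = as.integer(length_range),
                 enriched_residues = enriched_residues,
                 enrichment_factor = enrichment_factor,
                 seed = as.integer(seed)),
            class = "sequence_spec")
}

#' Generate planted-signal peptide sequences
#'
#' Negatives draw residues i.i.d. uniform over the 20 letters;
#' positives draw from a multinomial in which the enriched letters'
#' probabilities are multiplied by `enrichment_factor` and
#' renormalized. Lengths are uniform over `length_range`. Output passes
#' [validate_alphabet()] and [filter_by_length()] unchanged.
#'
#' @param spec a [sequence_spec()].
#' @return A [peptide_set] (positives first, labels attached).
#' @export
make_sequences <- function(spec = sequence_spec()) {
  stopifnot(inherits(spec, "sequence_spec"))
  with_seed(spec$seed, {
    p_neg <- rep(1 / 20, 20)
    w <- ifelse(AA_ALPHABET20 %in% spec$enriched_residues,
                spec$enrichment_factor, 1)
    p_pos <- w / sum(w)
    draw <- function(n, prob, prefix) {
      len <- sample(seq(spec$length_range[1], spec$length_range[2]),
                    n, replace = TRUE)
      seqs <- vapply(len, function(L) {
        paste(sample(AA_ALPHABET20, L, replace = TRUE, prob = prob),
              collapse = "")
      }, character(1))
      list(id = sprintf("%s_%04d", prefix, seq_len(n)), sequence = seqs)
    }
    pos <- draw(spec$n_pos, p_pos, "pos")
    neg <- draw(spec$n_neg, p_neg, "neg")
    peptide_set(c(pos$id, neg$id), c(pos$sequence, neg$sequence),
                c(rep(1L, spec$n_pos), rep(0L, spec$n_neg)))
  })
}
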