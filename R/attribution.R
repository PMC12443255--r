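#' @name attribution
#' @title SHAP-Res residue-level attribution
#' @description
#' Explains classifier decisions at single-residue resolution. A global
#' SHAP weight vector (one signed weight per embedding dimension,
#' estimated over a background set) is projected onto each residue's
#' embedding row by an inner product, giving a raw per-residue score;
#' min-max normalization maps the scores of a peptide to `[0, 1]` for
#' visualization and cross-model comparison. Per-amino-acid aggregation
#' averages normalized scores over every occurrence of each letter.
NULL

# resolve a model argument into f(X) -> positive-class probability
as_prob_fun <- function(model) {
  if (is.function(model)) return(model)
  if (inherits(model, "trained_ensemble")) {
    return(function(X) predict(model, X)$prob)
  }
  stop("model must be a trained_ensemble or a function(X) -> numeric")
}

# Shapley values for one instance x against a background matrix, by
# permutation sampling. When d! <= n_samples every permutation is
# enumerated once, making the estimate exact for the given background.
# Marginal contributions are always averaged over the full background.
shapley_instance <- function(f, x, background, n_samples) {
  d <- length(x)
  nb <- nrow(background)
  perms <- if (factorial(d) <= n_samples) {
    all_permutations(d)
  } else {
    lapply(seq_len(n_samples), function(i) sample.int(d))
  }
  phi <- numeric(d)
  for (perm in perms) {
    # walk the permutation: start from background rows, switch features
    # to x one at a time; d+1 states x nb rows, evaluated in one batch
    states <- matrix(NA_real_, (d + 1L) * nb, d)
    cur <- background
    states[seq_len(nb), ] <- cur
    for (j in seq_len(d)) {
      cur[, perm[j]] <- x[perm[j]]
      states[j * nb + seq_len(nb), ] <- cur
    }
    preds <- f(states)
    stage_mean <- vapply(seq_len(d + 1L),
                         function(j) mean(preds[(j - 1L) * nb + seq_len(nb)]),
                         numeric(1))
    phi[perm] <- phi[perm] + diff(stage_mean)
  }
  phi / length(perms)
}

all_permutations <- function(d) {
  if (d == 1L) return(list(1L))
  out <- list()
  for (i in seq_len(d)) {
    rest <- all_permutations(d - 1L)
    out <- c(out, lapply(rest, function(p) c(i, setdiff(seq_len(d), i)[p])))
  }
  out
}

#' Global SHAP weight vector
#'
#' Estimates, for every feature dimension, the mean signed Shapley
#' value of the model's positive-class probability over a set of
#' explained instances, using a seeded permutation sampler with the
#' background set as the reference distribution. When the number of
#' feature dimensions is small enough that all permutations fit within
#' `n_samples`, the enumeration is exhaustive and the estimate is exact
#' for the given background. Mean signed values (not mean absolute) are
#' used so that the inner-product projection onto residue embeddings
#' retains the direction of each dimension's contribution;
#' `method = "absolute"` gives magnitude-style rankings instead.
#'
#' @param model a `trained_ensemble`, or any `function(X) -> numeric`
#'   scoring positive-class probability (e.g. a surrogate model).
#' @param background reference feature matrix (non-empty, model
#'   dimensionality).
#' @param X instances to explain (default: the background itself).
#' @param n_samples permutations per instance (default 32).
#' @param seed integer seed.
#' @param method `"signed"` (default) or `"absolute"`.
#' @return A `shap_weights` list: `w` (d-vector), `background_size`,
#'   `method`, `seed`.
#' @export
global_shap_weights <- function(model, background, X = background,
                                n_samples = 32L, seed = 1L,
                                method = c("signed", "absolute")) {
  method <- match.arg(method)
  f <- as_prob_fun(model)
  background <- as.matrix(background); X <- as.matrix(X)
  stopifnot(nrow(background) >= 1L, ncol(X) == ncol(background))
  if (inherits(model, "trained_ensemble") && ncol(X) != model$d) {
    stop("dimensionality mismatch with model")
  }
  phis <- with_seed(seed, {
    t(vapply(seq_len(nrow(X)), function(i) {
      shapley_instance(f, X[i, ], background, n_samples)
    }, numeric(ncol(X))))
  })
  w <- if (method == "signed") colMeans(phis) else colMeans(abs(phis))
  structure(list(w = w, background_size = nrow(background),
                 method = paste0("permutation-", method),
                 seed = as.integer(seed)),
            class = "shap_weights")
}

#' Residue-level attribution (SHAP-Res)
#'
#' Scores residue `i` as the inner product of its embedding row with
#' the global SHAP weight vector, then min-max normalizes the scores of
#' the peptide to `[0, 1]`. A constant raw-score vector (min == max,
#' e.g. a length-1 peptide) normalizes to all zeros, since min-max
#' scaling is undefined there.
#'
#' @param embedding a `residue_embedding` (see [embed_residues()]).
#' @param weights a `shap_weights` whose length matches the embedding
#'   dimensionality, or a bare numeric d-vector.
#' @return An `attribution_result`: list with `sequence`, `raw_scores`,
#'   `norm_scores` and `weights_provenance`.
#' @export
shap_res <- function(embedding, weights) {
  stopifnot(inherits(embedding, "residue_embedding"))
  w <- if (inherits(weights, "shap_weights")) weights$w else as.numeric(weights)
  prov <- if (inherits(weights, "shap_weights")) weights$method else "vector"
  if (ncol(embedding$matrix) != length(w)) {
    stop("embedding dim (", ncol(embedding$matrix),
         ") does not match weight length (", length(w), ")")
  }
  s <- as.numeric(embedding$matrix %*% w)
  rng <- range(s)
  norm <- if (rng[1] == rng[2]) rep(0, length(s)) else
    (s - rng[1]) / (rng[2] - rng[1])
  structure(list(sequence = embedding$sequence, raw_scores = s,
                 norm_scores = norm, weights_provenance = prov),
            class = "attribution_result")
}

#' Aggregate attributions per amino acid
#'
#' For each canonical letter, averages the normalized residue scores
#' over every occurrence across all supplied peptides. Letters that
#' never occur are flagged (`present = FALSE`, `mean_score = NA`)
#' rather than zero-filled. Rows are sorted by descending mean score,
#' absent letters last.
#'
#' @param results list of `attribution_result` objects.
#' @return Data frame with columns `residue`, `mean_score`, `n`
#'   (occurrences) and `present`.
#' @export
aggregate_by_residue <- function(results) {
  stopifnot(length(results) >= 1L)
  letters_all <- unlist(lapply(results, function(r) strsplit(r$sequence, "")[[1]]))
  scores_all <- unlist(lapply(results, function(r) r$norm_scores))
  stopifnot(length(letters_all) == length(scores_all))
  tab <- data.frame(residue = AA_ALPHABET20,
                    mean_score = NA_real_, n = 0L, present = FALSE,
                    stringsAsFactors = FALSE)
  for (i in seq_along(AA_ALPHABET20)) {
    hit <- letters_all == AA_ALPHABET20[i]
    if (any(hit)) {
      tab$mean_score[i] <- mean(scores_all[hit])
      tab$n[i] <- sum(hit)
      tab$present[i] <- TRUE
    }
  }
  key <- ifelse(tab$present, tab$mean_score, -Inf)
  tab <- tab[order(-key, tab$residue), , drop = FALSE]
  rownames(tab) <- NULL
  tab
}

#' Rank per-letter importances from a classical encoder
#'
#' Entry point for frequency-feature models: takes a per-dimension
#' importance vector whose names include the 20 amino-acid letters
#' (e.g. SHAP weights or tree importances of an AAC model) and returns
#' the per-letter ranking table directly.
#'
#' @param weights named numeric vector; names matching
#'   [AA_ALPHABET20] are used.
#' @return Data frame `residue`, `score`, sorted descending.
#' @export
rank_letter_weights <- function(weights) {
  w <- if (inherits(weights, "shap_weights")) weights$w else weights
  stopifnot(!is.null(names(w)))
  keep <- names(w) %in% AA_ALPHABET20
  tab <- data.frame(residue = names(w)[keep], score = unname(w[keep]),
                    stringsAsFactors = FALSE)
  tab <- tab[order(-tab$score), , drop = FALSE]
  rownames(tab) <- NULL
  tab
}

#' Write per-residue attribution reports
#'
#' Tab-delimited: id, position, residue letter, raw score, normalized
#' score.
#'
#' @param results list of `attribution_result` objects.
#' @param ids peptide ids, one per result.
#' @param path output path.
#' @return `path` invisibly.
#' @export
write_attribution_report <- function(results, ids, path) {
  stopifnot(length(results) == length(ids))
  rows <- lapply(seq_along(results), function(i) {
    r <- results[[i]]
    ch <- strsplit(r$sequence, "")[[1]]
    data.frame(id = ids[i], position = seq_along(ch), residue = ch,
               raw_score = r$raw_scores, norm_score = r$norm_scores)
  })
  utils::write.table(do.call(rbind, rows), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}
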