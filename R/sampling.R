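#' @name sampling
#' @title Class-imbalance correction: ADASYN and ANBS
#' @description
#' Reference implementation of adaptive synthetic oversampling (ADASYN)
#' and the boundary-aware iterative variant ANBS (adaptive
#' neighborhood-based sampling). ADASYN scores each minority sample's
#' difficulty as the fraction of majority points among its k nearest
#' neighbors, allocates synthetic points proportionally, and
#' interpolates between minority neighbors. ANBS additionally prunes,
#' once per iteration, the majority sample closest to the minority set,
#' then tops the minority class up to the target ratio, iterating until
#' the ratio is reached or the iteration cap is hit.
#'
#' Features are used as-is: no internal standardization is applied, so
#' callers wanting scaled distances must scale before sampling.
NULL

#' Labeled feature matrix
#'
#' The substrate for sampling, training and evaluation: an n x d real
#' matrix with binary row labels.
#'
#' @param X numeric matrix (n x d), no missing values.
#' @param y binary label vector of length n (0/1).
#' @param provenance optional character vector per row (default
#'   `"original"`).
#' @return A `labeled_matrix` (list with `X`, `y`, `minority_label`,
#'   `provenance`).
#' @export
labeled_matrix <- function(X, y, provenance = NULL) {
  X <- as.matrix(X)
  y <- as.integer(y)
  stopifnot(nrow(X) == length(y), !anyNA(X), all(y %in% c(0L, 1L)))
  counts <- c(`0` = sum(y == 0L), `1` = sum(y == 1L))
  minority_label <- as.integer(names(counts)[which.min(counts)])
  if (is.null(provenance)) provenance <- rep("original", nrow(X))
  stopifnot(length(provenance) == nrow(X))
  structure(list(X = X, y = y, minority_label = minority_label,
                 provenance = provenance),
            class = "labeled_matrix")
}

#' @export
print.labeled_matrix <- function(x, ...) {
  cat(sprintf("labeled_matrix: %d x %d, class 0: %d, class 1: %d (minority: %d)\n",
              nrow(x$X), ncol(x$X), sum(x$y == 0L), sum(x$y == 1L),
              x$minority_label))
  invisible(x)
}

#' Euclidean distance between two points
#'
#' @param p1,p2 numeric vectors of equal length.
#' @return `sqrt(sum((p1 - p2)^2))`.
#' @export
euclidean_distance <- function(p1, p2) {
  if (length(p1) != length(p2)) stop("dimension mismatch")
  sqrt(sum((p1 - p2)^2))
}

# squared cross-distances between row sets A (m x d) and B (n x d)
cross_dist2 <- function(A, B) {
  d2 <- matrix(rowSums(A^2), nrow(A), nrow(B)) +
        matrix(rowSums(B^2), nrow(A), nrow(B), byrow = TRUE) -
        2 * tcrossprod(A, B)
  pmax(d2, 0)
}

#' ANBS configuration
#'
#' @param max_ratio target minority/majority ratio at which iteration
#'   stops (default 1.0, i.e. full balance).
#' @param max_iter iteration cap (default 10).
#' @param k neighbor count for difficulty scoring and synthesis
#'   (default 5); internally capped at `|minority| - 1`.
#' @param seed integer seed for the synthesis randomness.
#' @return An `anbs_config` list.
#' @export
anbs_config <- function(max_ratio = 1.0, max_iter = 10L, k = 5L, seed = 1L) {
  stopifnot(max_ratio > 0, max_iter >= 1L, k >= 1L)
  structure(list(max_ratio = max_ratio, max_iter = as.integer(max_iter),
                 k = as.integer(k), seed = as.integer(seed)),
            class = "anbs_config")
}

#' ADASYN difficulty scores
#'
#' For each minority row, finds its `k` nearest neighbors in the full
#' dataset (self excluded, ties broken by lowest row index) and scores
#' difficulty as `r_i = Delta_i / k`, the fraction of majority points
#' among them. Scores are then normalized to sum to 1; when every
#' `r_i` is zero (no minority point has a majority neighbor) the
#' normalized vector falls back to uniform, since the normalization is
#' otherwise undefined.
#'
#' @param data a [labeled_matrix] with at least 2 minority rows.
#' @param k neighbor count, `k <= n - 1`.
#' @return An `adasyn_plan`: list with `k`, `minority_idx`, `r`,
#'   `r_norm` (and later `G`, `G_alloc` from [adasyn_allocate()]).
#' @export
adasyn_difficulty <- function(data, k = 5L) {
  stopifnot(inherits(data, "labeled_matrix"))
  n <- nrow(data$X)
  if (k > n - 1L) stop("k must be at most n - 1")
  min_idx <- which(data$y == data$minority_label)
  if (length(min_idx) < 2L) stop("need at least 2 minority rows")
  d2 <- cross_dist2(data$X[min_idx, , drop = FALSE], data$X)
  is_maj <- data$y != data$minority_label
  r <- vapply(seq_along(min_idx), function(i) {
    d <- d2[i, ]
    d[min_idx[i]] <- Inf  # exclude self
    nn <- order(d, seq_len(n))[seq_len(k)]
    sum(is_maj[nn]) / k
  }, numeric(1))
  r_norm <- if (sum(r) > 0) r / sum(r) else rep(1 / length(r), length(r))
  structure(list(k = as.integer(k), minority_idx = min_idx,
                 r = r, r_norm = r_norm),
            class = "adasyn_plan")
}

#' Allocate synthetic counts per minority row
#'
#' Turns the normalized difficulty scores into integer per-row synthetic
#' counts `G_i ~ r_norm_i * G`, rounded by the largest-remainder method
#' so the allocations sum exactly to `G` (ties broken by lower row
#' index).
#'
#' @param plan an `adasyn_plan` from [adasyn_difficulty()].
#' @param G total number of synthetic samples, `G >= 0`.
#' @return The plan with `G` and integer `G_alloc` filled in.
#' @export
adasyn_allocate <- function(plan, G) {
  stopifnot(inherits(plan, "adasyn_plan"), G >= 0)
  G <- as.integer(G)
  real <- plan$r_norm * G
  base <- floor(real)
  rem <- real - base
  deficit <- G - sum(base)
  alloc <- as.integer(base)
  if (deficit > 0) {
    top <- order(-rem, seq_along(rem))[seq_len(deficit)]
    alloc[top] <- alloc[top] + 1L
  }
  plan$G <- G
  plan$G_alloc <- alloc
  plan
}

#' Synthesize minority samples by neighbor interpolation
#'
#' For each minority row `i` with allocation `G_i > 0`, draws a uniform
#' neighbor `x_z` among its k nearest minority neighbors and an
#' independent `delta ~ U(0, 1)` per point, producing
#' `x_new = x_i + delta * (x_z - x_i)`. Synthetic rows are appended with
#' the minority label and provenance `"synthetic"`.
#'
#' @param data a [labeled_matrix] with at least 2 minority rows.
#' @param plan an allocated `adasyn_plan` (after [adasyn_allocate()]).
#' @param seed integer seed.
#' @param delta optional fixed interpolation factor overriding the
#'   uniform draw (test hook; e.g. `0.5` yields parent midpoints).
#' @return A [labeled_matrix] with synthetics appended; attribute
#'   `"parents"` records each synthetic point's two parent row indices
#'   (in the input matrix).
#' @export
adasyn_synthesize <- function(data, plan, seed = 1L, delta = NULL) {
  stopifnot(inherits(data, "labeled_matrix"), inherits(plan, "adasyn_plan"),
            !is.null(plan$G_alloc))
  min_idx <- plan$minority_idx
  if (length(min_idx) < 2L) stop("need at least 2 minority rows")
  k_eff <- min(plan$k, length(min_idx) - 1L)
  Xmin <- data$X[min_idx, , drop = FALSE]
  d2 <- cross_dist2(Xmin, Xmin)

  with_seed(seed, {
    new_rows <- vector("list", length(min_idx))
    parents <- vector("list", length(min_idx))
    for (i in seq_along(min_idx)) {
      gi <- plan$G_alloc[i]
      if (gi == 0L) next
      d <- d2[i, ]
      d[i] <- Inf
      nn <- order(d, seq_along(d))[seq_len(k_eff)]
      z <- nn[sample.int(k_eff, gi, replace = TRUE)]
      del <- if (is.null(delta)) stats::runif(gi) else rep(delta, gi)
      xi <- Xmin[i, ]
      new_rows[[i]] <- Xmin[z, , drop = FALSE] * del +
        matrix(xi, gi, ncol(Xmin), byrow = TRUE) * (1 - del)
      parents[[i]] <- cbind(parent1 = rep(min_idx[i], gi),
                            parent2 = min_idx[z])
    }
    newX <- do.call(rbind, new_rows[!vapply(new_rows, is.null, logical(1))])
    par <- do.call(rbind, parents[!vapply(parents, is.null, logical(1))])
    if (is.null(newX)) {
      out <- data
      attr(out, "parents") <- matrix(integer(0), 0, 2)
      return(out)
    }
    out <- labeled_matrix(
      rbind(data$X, newX),
      c(data$y, rep(data$minority_label, nrow(newX))),
      c(data$provenance, rep("synthetic", nrow(newX))))
    attr(out, "parents") <- par
    out
  })
}

#' Adaptive neighborhood-based sampling (ANBS)
#'
#' Iteratively balances a two-class dataset. Each iteration: (a) stop if
#' the minority/majority ratio has reached `max_ratio`; (b) *boundary
#' step* — remove the single majority row at minimal Euclidean distance
#' to any minority row (ties: lowest row index); (c) *synthesis step* —
#' top the minority class up to `ceil(max_ratio * |majority|)` samples
#' via the ADASYN difficulty/allocation/interpolation chain on the
#' current sets; (d) re-check the ratio. On the canonical imbalanced
#' training split (487 positives, 1,479 negatives) the default
#' `max_ratio = 1` yields 1,478 samples in each class.
#'
#' @param data a [labeled_matrix] with at least 2 rows in each class.
#' @param config an [anbs_config()].
#' @return A [labeled_matrix] with retained originals first (input
#'   order) and synthetics appended. Attributes: `"removed"` (input row
#'   indices of pruned majority samples), `"trace"` (per-iteration data
#'   frame of removed/added counts), `"status"` (`"converged"` or
#'   `"max_iter"`). Exhausting `max_iter` before reaching the ratio
#'   warns, never fails silently.
#' @export
anbs <- function(data, config = anbs_config()) {
  stopifnot(inherits(data, "labeled_matrix"), inherits(config, "anbs_config"))
  min_lab <- data$minority_label
  if (sum(data$y == min_lab) < 2L || sum(data$y != min_lab) < 2L) {
    stop("both classes need at least 2 rows")
  }

  cur <- data
  orig_idx <- seq_len(nrow(data$X))   # input row index per current row
  removed <- integer(0)
  trace <- list()
  status <- "max_iter"

  for (t in seq_len(config$max_iter)) {
    n_min <- sum(cur$y == min_lab)
    n_maj <- sum(cur$y != min_lab)
    if (n_min / n_maj >= config$max_ratio) { status <- "converged"; break }

    # boundary step: prune the majority row closest to the minority set
    maj_pos <- which(cur$y != min_lab)
    min_pos <- which(cur$y == min_lab)
    d2 <- cross_dist2(cur$X[maj_pos, , drop = FALSE],
                      cur$X[min_pos, , drop = FALSE])
    nearest <- apply(d2, 1, min)
    drop_pos <- maj_pos[order(nearest, seq_along(nearest))[1]]
    if (!is.na(orig_idx[drop_pos])) removed <- c(removed, orig_idx[drop_pos])
    orig_idx <- orig_idx[-drop_pos]
    cur <- labeled_matrix(cur$X[-drop_pos, , drop = FALSE],
                          cur$y[-drop_pos],
                          cur$provenance[-drop_pos])
    cur$minority_label <- min_lab
    n_maj <- n_maj - 1L

    # synthesis step: top up to the target count
    need <- max(0L, as.integer(ceiling(config$max_ratio * n_maj)) - n_min)
    if (need > 0L) {
      k_eff <- min(config$k, n_min - 1L)
      plan <- adasyn_difficulty(cur, k = k_eff)
      plan <- adasyn_allocate(plan, need)
      n_before <- length(orig_idx)
      cur <- adasyn_synthesize(cur, plan,
                               seed = derive_seed(config$seed, t))
      cur$minority_label <- min_lab
      orig_idx <- c(orig_idx, rep(NA_integer_, nrow(cur$X) - n_before))
    }
    n_min <- sum(cur$y == min_lab)
    trace[[t]] <- data.frame(iteration = t, removed = 1L, added = need,
                             n_minority = n_min, n_majority = n_maj)
    if (n_min / n_maj >= config$max_ratio) { status <- "converged"; break }
  }

  if (status != "converged") {
    warning("anbs: max_iter reached before attaining max_ratio")
  }
  attr(cur, "removed") <- removed
  attr(cur, "trace") <- do.call(rbind, trace)
  attr(cur, "status") <- status
  cur
}

#' Write a resampled dataset as delimited text
#'
#' Tab-delimited export with the feature columns, the label and a
#' provenance column (`original` / `synthetic`).
#'
#' @param data a [labeled_matrix].
#' @param path output path.
#' @return `path` invisibly.
#' @export
write_resampled <- function(data, path) {
  X <- data$X
  if (is.null(colnames(X))) colnames(X) <- paste0("f", seq_len(ncol(X)))
  df <- data.frame(X, label = data$y, provenance = data$provenance,
                   check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
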