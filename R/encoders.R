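#' @name encoders
#' @title Classical peptide feature encoders
#' @description
#' Hand-crafted sequence encoders used as comparison baselines against
#' language-model embeddings: amino-acid composition (AAC, 20 dims),
#' dipeptide composition (DC, 400 dims), pseudo amino-acid composition
#' (PAAC, 20 + lambda dims) and composition/transition/distribution
#' descriptors (CTD). Feature ordering is fixed alphabetical over
#' [AA_ALPHABET20] so encoded matrices are bit-reproducible.
NULL

seq_chars <- function(sequence) {
  ch <- strsplit(toupper(sequence), "")[[1]]
  if (length(ch) == 0L) stop("empty sequence")
  if (!all(ch %in% AA_ALPHABET20)) {
    stop("sequence contains non-canonical residues; validate first")
  }
  ch
}

#' Amino-acid composition (AAC)
#'
#' Frequency of each of the 20 canonical residues: component for letter
#' `a` is `count(a) / length`.
#'
#' @param sequence a validated amino-acid sequence (length >= 1).
#' @return Named numeric 20-vector in alphabetical letter order,
#'   summing to 1.
#' @examples
#' encode_aac("KLAKLAK")
#' @export
encode_aac <- function(sequence) {
  ch <- seq_chars(sequence)
  counts <- table(factor(ch, levels = AA_ALPHABET20))
  v <- as.numeric(counts) / length(ch)
  names(v) <- AA_ALPHABET20
  v
}

#' Dipeptide composition (DC)
#'
#' Frequency of each ordered residue pair among the `L - 1` adjacent
#' pairs, in row-major (first letter, second letter) order over the
#' alphabetical alphabet.
#'
#' @param sequence a validated sequence of length >= 2.
#' @return Named numeric 400-vector summing to 1.
#' @export
encode_dc <- function(sequence) {
  ch <- seq_chars(sequence)
  if (length(ch) < 2L) stop("dipeptide composition needs length >= 2")
  pairs <- paste0(ch[-length(ch)], ch[-1])
  lv <- as.vector(t(outer(AA_ALPHABET20, AA_ALPHABET20, paste0)))
  counts <- table(factor(pairs, levels = lv))
  v <- as.numeric(counts) / (length(ch) - 1L)
  names(v) <- lv
  v
}

# Chou-style PAAC property scales (hydrophobicity, Hopp-Woods
# hydrophilicity, side-chain mass), alphabetical letter order
paac_scales <- function() {
  hydrophobicity <- c(
    A = 0.62, C = 0.29, D = -0.90, E = -0.74, F = 1.19, G = 0.48,
    H = -0.40, I = 1.38, K = -1.50, L = 1.06, M = 0.64, N = -0.78,
    P = 0.12, Q = -0.85, R = -2.53, S = -0.18, T = -0.05, V = 1.08,
    W = 0.81, Y = 0.26)
  hydrophilicity <- c(
    A = -0.5, C = -1.0, D = 3.0, E = 3.0, F = -2.5, G = 0.0,
    H = -0.5, I = -1.8, K = 3.0, L = -1.8, M = -1.3, N = 0.2,
    P = 0.0, Q = 0.2, R = 3.0, S = 0.3, T = -0.4, V = -1.5,
    W = -3.4, Y = -2.3)
  side_chain_mass <- c(
    A = 15.0, C = 47.0, D = 59.0, E = 73.0, F = 91.0, G = 1.0,
    H = 82.0, I = 57.0, K = 73.0, L = 57.0, M = 75.0, N = 58.0,
    P = 42.0, Q = 72.0, R = 101.0, S = 31.0, T = 45.0, V = 43.0,
    W = 130.0, Y = 107.0)
  # standardize each scale to zero mean / unit population SD over the
  # 20 letters (Chou's convention)
  lapply(list(hydrophobicity = hydrophobicity,
              hydrophilicity = hydrophilicity,
              side_chain_mass = side_chain_mass), function(h) {
    (h - mean(h)) / sqrt(mean((h - mean(h))^2))
  })
}

#' Pseudo amino-acid composition (PAAC)
#'
#' Chou-style PAAC: the first 20 components carry weighted residue
#' frequencies, the next `lam` components carry sequence-order
#' correlation factors computed from three standardized property scales
#' (hydrophobicity, hydrophilicity, side-chain mass). The correlation
#' factor at tier `j` averages, over all residue pairs `j` apart, the
#' mean squared property difference. The full vector is normalized to
#' sum to 1.
#'
#' @param sequence a validated sequence with `length > lam`.
#' @param lam number of correlation tiers (default 4; the shortest
#'   admissible peptide has 5 residues, so `lam <= 4` keeps every valid
#'   input encodable).
#' @param w weight of the sequence-order terms (default 0.05).
#' @return Named numeric `(20 + lam)`-vector summing to 1.
#' @export
encode_paac <- function(sequence, lam = 4L, w = 0.05) {
  ch <- seq_chars(sequence)
  L <- length(ch)
  stopifnot(lam >= 1L, w > 0)
  if (lam >= L) stop("lam must be smaller than the sequence length")
  scales <- paac_scales()
  props <- vapply(scales, function(h) unname(h[ch]), numeric(L))

  theta <- vapply(seq_len(lam), function(j) {
    d2 <- (props[seq_len(L - j) + j, , drop = FALSE] -
           props[seq_len(L - j), , drop = FALSE])^2
    mean(rowMeans(d2))
  }, numeric(1))

  f <- as.numeric(table(factor(ch, levels = AA_ALPHABET20))) / L
  denom <- sum(f) + w * sum(theta)
  v <- c(f / denom, w * theta / denom)
  names(v) <- c(AA_ALPHABET20, paste0("lambda", seq_len(lam)))
  v
}

#' Default CTD property grouping (7 physicochemical properties, 3
#' classes each)
#'
#' The Dubchak grouping: hydrophobicity, normalized van der Waals
#' volume, polarity, polarizability, charge, secondary structure and
#' solvent accessibility, each partitioning the 20 letters into three
#' classes.
#'
#' @return Named list of 7 properties; each property is a list of three
#'   character vectors partitioning [AA_ALPHABET20].
#' @export
ctd_default_groups <- function() {
  list(
    hydrophobicity = list(
      polar = c("R", "K", "E", "D", "Q", "N"),
      neutral = c("G", "A", "S", "T", "P", "H", "Y"),
      hydrophobic = c("C", "L", "V", "I", "M", "F", "W")),
    vdw_volume = list(
      small = c("G", "A", "S", "T", "P", "D", "C"),
      medium = c("N", "V", "E", "Q", "I", "L"),
      large = c("M", "H", "K", "F", "R", "Y", "W")),
    polarity = list(
      low = c("L", "I", "F", "W", "C", "M", "V", "Y"),
      medium = c("P", "A", "T", "G", "S"),
      high = c("H", "Q", "R", "K", "N", "E", "D")),
    polarizability = list(
      low = c("G", "A", "S", "D", "T"),
      medium = c("C", "P", "N", "V", "E", "Q", "I", "L"),
      high = c("K", "M", "H", "F", "R", "Y", "W")),
    charge = list(
      positive = c("K", "R"),
      neutral = c("A", "N", "C", "Q", "G", "H", "I", "L", "M", "F",
                  "P", "S", "T", "W", "Y", "V"),
      negative = c("D", "E")),
    secondary_structure = list(
      helix = c("E", "A", "L", "M", "Q", "K", "R", "H"),
      strand = c("V", "I", "Y", "C", "W", "F", "T"),
      coil = c("G", "N", "P", "S", "D")),
    solvent_accessibility = list(
      buried = c("A", "L", "F", "C", "G", "I", "V", "W"),
      exposed = c("R", "K", "Q", "E", "N", "D"),
      intermediate = c("M", "S", "P", "T", "H", "Y"))
  )
}

check_partition <- function(groups) {
  for (p in names(groups)) {
    g <- groups[[p]]
    if (length(g) != 3L) stop("property '", p, "' must have 3 classes")
    all_letters <- sort(unlist(g, use.names = FALSE))
    if (!identical(all_letters, sort(AA_ALPHABET20))) {
      stop("property '", p, "' grouping is not a partition of the alphabet")
    }
  }
  invisible(TRUE)
}

#' Composition/transition/distribution (CTD) descriptors
#'
#' For each physicochemical property the sequence is recoded into three
#' classes, then three blocks are computed: composition (fraction of
#' residues per class, 3 values), transition (fraction of adjacent pairs
#' crossing each class pair, 3 values), and distribution (for each
#' class, the position of the first, 25%, 50%, 75% and 100% occurrence,
#' reported as a fraction of sequence length; 15 values). A class absent
#' from the sequence contributes zeros to its distribution block.
#'
#' @param sequence a validated sequence of length >= 2.
#' @param groups property grouping table, a named list of 3-class
#'   partitions of the alphabet (default [ctd_default_groups()]).
#' @return List with numeric blocks `composition`, `transition` and
#'   `distribution` (with the default 7 properties: 21, 21 and 105
#'   values) plus `full`, their concatenation.
#' @export
encode_ctd <- function(sequence, groups = ctd_default_groups()) {
  ch <- seq_chars(sequence)
  if (length(ch) < 2L) stop("CTD needs length >= 2")
  check_partition(groups)
  L <- length(ch)

  comp <- c(); trans <- c(); distr <- c()
  for (p in names(groups)) {
    g <- groups[[p]]
    cls <- integer(L)
    for (k in 1:3) cls[ch %in% g[[k]]] <- k

    cv <- vapply(1:3, function(k) sum(cls == k) / L, numeric(1))
    names(cv) <- paste0(p, ".C", 1:3)
    comp <- c(comp, cv)

    a <- cls[-L]; b <- cls[-1]
    pairs <- rbind(c(1, 2), c(1, 3), c(2, 3))
    tv <- apply(pairs, 1, function(rs) {
      sum((a == rs[1] & b == rs[2]) | (a == rs[2] & b == rs[1])) / (L - 1)
    })
    names(tv) <- paste0(p, ".T", c("12", "13", "23"))
    trans <- c(trans, tv)

    for (k in 1:3) {
      pos <- which(cls == k)
      n <- length(pos)
      dv <- if (n == 0L) rep(0, 5) else {
        idx <- pmax(1L, ceiling(c(0, 0.25, 0.5, 0.75, 1) * n))
        idx[1] <- 1L
        pos[idx] / L
      }
      names(dv) <- paste0(p, ".D", k, ".", c("first", "25", "50", "75", "100"))
      distr <- c(distr, dv)
    }
  }
  list(composition = comp, transition = trans, distribution = distr,
       full = c(comp, trans, distr))
}

#' Encode a peptide set into a feature matrix
#'
#' Applies one of the classical encoders to every record and stacks the
#' results into an n x d matrix with feature names and row ids, tagged
#' with encoder provenance.
#'
#' @param records a [peptide_set].
#' @param encoder one of `"aac"`, `"dc"`, `"paac"`, `"ctd"`.
#' @param ... passed to the encoder (e.g. `lam`, `w` for PAAC).
#' @return Numeric matrix with rownames = record ids, colnames = feature
#'   names, and attributes `provenance` (encoder name + parameters) and
#'   `labels` (the records' label column).
#' @export
encode_peptides <- function(records, encoder = c("aac", "dc", "paac", "ctd"),
                            ...) {
  encoder <- match.arg(encoder)
  fn <- switch(encoder,
    aac = encode_aac,
    dc = encode_dc,
    paac = encode_paac,
    ctd = function(s, ...) encode_ctd(s, ...)$full)
  rows <- lapply(records$sequence, fn, ...)
  X <- do.call(rbind, rows)
  rownames(X) <- records$id
  stopifnot(!anyNA(X))
  attr(X, "provenance") <- paste0(encoder,
    if (length(list(...))) paste0("(", paste(names(list(...)),
      unlist(list(...)), sep = "=", collapse = ","), ")") else "")
  attr(X, "labels") <- records$label
  X
}

#' Write / read a feature matrix as delimited text
#'
#' Tab-delimited interchange with a header row of feature names and an
#' `id` first column (plus a `label` column when labels are attached).
#'
#' @param X feature matrix from [encode_peptides()].
#' @param path output path.
#' @return `path` invisibly; `read_feature_matrix` returns the matrix
#'   with `labels` attribute restored.
#' @export
write_feature_matrix <- function(X, path) {
  df <- data.frame(id = rownames(X), X, check.names = FALSE)
  lab <- attr(X, "labels")
  if (!is.null(lab) && !all(is.na(lab))) df$label <- lab
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_feature_matrix
#' @export
read_feature_matrix <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          check.names = FALSE, stringsAsFactors = FALSE)
  lab <- if ("label" %in% names(df)) as.integer(df$label) else NULL
  keep <- setdiff(names(df), c("id", "label", "provenance"))
  X <- as.matrix(df[, keep, drop = FALSE])
  if ("id" %in% names(df)) rownames(X) <- df$id
  attr(X, "labels") <- lab
  if ("provenance" %in% names(df)) attr(X, "provenance_flags") <- df$provenance
  X
}
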