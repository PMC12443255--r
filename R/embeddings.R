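#' @name embeddings
#' @title Per-residue embedding backends
#' @description
#' Contract for turning a validated peptide sequence into an L x d
#' residue embedding matrix (one row per residue, special tokens
#' stripped). Two backends exist: a fully deterministic offline mock
#' used throughout the test suite, and a declared adapter slot for a
#' pretrained protein language model, which raises a capability error
#' unless an embedding function is supplied by the caller.
NULL

LCG_M <- 2147483647
LCG_A <- 48271

# minimal multiplicative LCG stream in (-1, 1); fully specified so a
# test can reimplement it independently
lcg_stream <- function(key, n) {
  x <- (key %% (LCG_M - 1)) + 1
  out <- numeric(n)
  for (i in seq_len(n)) {
    x <- (LCG_A * x) %% LCG_M
    out[i] <- 2 * x / LCG_M - 1
  }
  out
}

#' Deterministic mock embedding backend
#'
#' Produces reproducible residue embeddings keyed by (residue letter,
#' position mod `period`). Each row is the sum of a sparse non-negative
#' identity component — pseudo-random magnitudes on the dimensions
#' assigned to the residue's letter (dimension `j` belongs to letter
#' `l` when `(j - 1) mod 20 == l - 1`) — and a small dense positional
#' jitter, so identical letters at nearby positions get related rows.
#' The sparse identity component guarantees the property attribution
#' relies on in real protein language-model embeddings: residue
#' identity is linearly decodable from the embedding. All values come
#' from a fixed multiplicative congruential stream, making the whole
#' matrix a pure function of `(dim, seed)`.
#'
#' @param dim embedding width (default 1152, the width of the 600M
#'   protein language model this backend stands in for).
#' @param seed integer seed.
#' @param period positional period P; jitter is keyed by `pos mod P`
#'   (default 7).
#' @param jitter amplitude of the dense positional component
#'   (default 0.1).
#' @return An `embedding_backend` handle for [embed_residues()].
#' @export
mock_backend <- function(dim = 1152L, seed = 1L, period = 7L,
                         jitter = 0.1) {
  stopifnot(dim >= 1L, period >= 1L, jitter >= 0)
  structure(list(type = "mock", dim = as.integer(dim),
                 seed = as.integer(seed), period = as.integer(period),
                 jitter = jitter),
            class = "embedding_backend")
}

#' External language-model backend adapter
#'
#' Declares a pretrained protein language model as the embedding source.
#' The model itself is never bundled: the caller must supply `fun`, a
#' function `(sequence) -> L x d matrix`. Without it, embedding raises
#' an explicit capability error rather than falling back silently.
#'
#' @param model_name configuration string naming the external model.
#' @param dim embedding width the model produces.
#' @param fun optional embedding function provided by the caller.
#' @return An `embedding_backend` handle.
#' @export
external_backend <- function(model_name, dim, fun = NULL) {
  structure(list(type = "external", model_name = model_name,
                 dim = as.integer(dim), fun = fun),
            class = "embedding_backend")
}

mock_row <- function(backend, letter, pos) {
  li <- match(letter, AA_ALPHABET20)
  key_base <- ((backend$seed + 1) * 1000003 + li * 101) %% LCG_M
  key_pos <- ((backend$seed + 1) * 1000003 + li * 101 +
              (1 + (pos - 1) %% backend$period) * 7919) %% LCG_M
  # identity component: magnitudes in [0.5, 1] on this letter's dims
  idx <- seq_len(backend$dim)
  own <- (idx - 1L) %% 20L == (li - 1L)
  base <- numeric(backend$dim)
  base[own] <- 0.75 + 0.25 * lcg_stream(key_base, sum(own))
  base + backend$jitter * lcg_stream(key_pos, backend$dim)
}

#' Embed the residues of one peptide
#'
#' @param backend an `embedding_backend` from [mock_backend()] or
#'   [external_backend()].
#' @param sequence a validated amino-acid sequence.
#' @return A `residue_embedding`: list with `sequence`, `matrix` (L x d,
#'   one row per residue, any begin/end marker rows stripped), `backend`
#'   provenance string and `dim`.
#' @export
embed_residues <- function(backend, sequence) {
  stopifnot(inherits(backend, "embedding_backend"))
  ch <- seq_chars(sequence)
  L <- length(ch)
  if (backend$type == "mock") {
    E <- t(vapply(seq_len(L),
                  function(i) mock_row(backend, ch[i], i),
                  numeric(backend$dim)))
    prov <- sprintf("mock(dim=%d,seed=%d,period=%d)",
                    backend$dim, backend$seed, backend$period)
  } else {
    if (is.null(backend$fun)) {
      stop("backend '", backend$model_name,
           "' is not available: no embedding function supplied")
    }
    E <- backend$fun(sequence)
    # strip begin/end marker rows if the model emitted them
    if (nrow(E) == L + 2L) E <- E[2:(L + 1L), , drop = FALSE]
    if (nrow(E) != L) stop("backend returned ", nrow(E),
                           " rows for a length-", L, " sequence")
    prov <- backend$model_name
  }
  dimnames(E) <- NULL
  structure(list(sequence = paste(ch, collapse = ""), matrix = E,
                 backend = prov, dim = ncol(E)),
            class = "residue_embedding")
}

#' Pool a residue embedding into a sequence-level vector
#'
#' Arithmetic mean over the L residue rows. Mean pooling is linear, so
#' the SHAP-Res per-residue decomposition of a pooled-feature model is
#' exact up to the constant factor L.
#'
#' @param embedding a `residue_embedding`.
#' @return Numeric d-vector of column means.
#' @export
pool_sequence <- function(embedding) {
  stopifnot(inherits(embedding, "residue_embedding"))
  colMeans(embedding$matrix)
}

#' Embed and pool a whole peptide set
#'
#' @param backend an `embedding_backend`.
#' @param records a [peptide_set].
#' @return n x d matrix of pooled embeddings (rownames = ids, `labels`
#'   attribute carried over).
#' @export
embed_peptides <- function(backend, records) {
  X <- t(vapply(records$sequence,
                function(s) pool_sequence(embed_residues(backend, s)),
                numeric(backend$dim)))
  rownames(X) <- records$id
  colnames(X) <- paste0("e", seq_len(ncol(X)))
  attr(X, "labels") <- records$label
  X
}

#' Write residue embeddings as plain text
#'
#' Interchange fallback: one row per residue with id, position, residue
#' letter and the embedding values, tab-delimited.
#'
#' @param embeddings list of `residue_embedding` objects.
#' @param ids character vector of peptide ids.
#' @param path output path.
#' @return `path` invisibly.
#' @export
write_residue_embeddings <- function(embeddings, ids, path) {
  stopifnot(length(embeddings) == length(ids))
  rows <- lapply(seq_along(embeddings), function(i) {
    e <- embeddings[[i]]
    ch <- strsplit(e$sequence, "")[[1]]
    data.frame(id = ids[i], position = seq_along(ch), residue = ch,
               e$matrix, check.names = FALSE)
  })
  utils::write.table(do.call(rbind, rows), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}
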