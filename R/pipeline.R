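#' @name pipeline
#' @title End-to-end pipeline runner
#' @description
#' Declarative configuration and a staged runner tying the toolkit
#' together: simulate -> encode/embed -> balance -> train -> evaluate
#' -> explain. Every stage writes its output to a file in the run
#' directory so each step is independently re-usable, and the run log
#' records seeds and per-stage class counts (including the ANBS
#' iteration trace) for auditability.
NULL

#' Pipeline run configuration
#'
#' All values are echoed into the run log; a run is fully reproducible
#' from its configuration plus inputs. Configurations can be loaded
#' from a YAML file with [load_run_config()].
#'
#' @param out_dir run directory (created if missing).
#' @param seed master seed; every stage derives its own seed from it.
#' @param feature_source `"aac"`, `"dc"`, `"paac"`, `"ctd"` (classical
#'   encoders) or `"embedding"` (mock backend pooled embeddings).
#' @param embedding_dim mock backend width when
#'   `feature_source = "embedding"` (default 32).
#' @param simulate list of [sequence_spec()] overrides (set to `NULL`
#'   and provide `fasta` to use real input).
#' @param fasta optional input FASTA path (used when `simulate` is
#'   `NULL`).
#' @param sampler list of [anbs_config()] overrides.
#' @param ensemble list of [ensemble_config()] overrides.
#' @param cv list with `folds` (default 5) and `mode`
#'   (default `"safe"`).
#' @param explain list with `n_background`, `n_explain`, `n_samples`
#'   controlling the SHAP estimator budget.
#' @return A `run_config` list.
#' @export
run_config <- function(out_dir, seed = 1L, feature_source = "aac",
                       embedding_dim = 32L, simulate = list(),
                       fasta = NULL, sampler = list(), ensemble = list(),
                       cv = list(folds = 5L, mode = "safe"),
                       explain = list(n_background = 25L, n_explain = 40L,
                                      n_samples = 8L)) {
  structure(list(out_dir = out_dir, seed = as.integer(seed),
                 feature_source = feature_source,
                 embedding_dim = as.integer(embedding_dim),
                 simulate = simulate, fasta = fasta, sampler = sampler,
                 ensemble = ensemble, cv = cv, explain = explain),
            class = "run_config")
}

#' Load a run configuration from YAML
#'
#' @param path YAML file whose keys mirror the [run_config()]
#'   arguments.
#' @return A `run_config`.
#' @export
load_run_config <- function(path) {
  vals <- yaml::read_yaml(path)
  do.call(run_config, vals)
}

stage <- function(name, log_con, expr) {
  tryCatch(expr, error = function(e) {
    stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE)
  })
}

#' Run the full pipeline
#'
#' Executes the configured stages in order and writes all artifacts
#' (FASTA, feature matrix, balanced data with provenance flags, model
#' archive, metric report, attribution report, run log) into the run
#' directory. Any stage error aborts with a stage-named message;
#' artifacts from completed stages are retained.
#'
#' @param config a [run_config()].
#' @return Invisibly, a list with the main in-memory results
#'   (`records`, `features`, `balanced`, `model`, `cv`, `importance`)
#'   and `paths` of the written artifacts.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  log_path <- file.path(config$out_dir, "run_log.txt")
  logf <- function(...) cat(sprintf(...), "\n", sep = "", file = log_path,
                            append = TRUE)
  cat("acpkit pipeline run\n", file = log_path)
  logf("R version: %s", R.version.string)
  logf("master seed: %d", config$seed)
  logf("config: %s", paste(utils::capture.output(utils::str(
    unclass(config))), collapse = " "))
  paths <- list(log = log_path)

  # --- simulate / load ---
  records <- stage("simulate", log_path, {
    if (!is.null(config$simulate)) {
      spec <- do.call(sequence_spec, utils::modifyList(
        list(seed = as.integer(derive_seed(config$seed, 1L))),
        config$simulate))
      r <- make_sequences(spec)
    } else {
      r <- read_fasta(config$fasta)
    }
    r <- validate_alphabet(r, "reject")
    r <- filter_by_length(r)
    paths$fasta <- file.path(config$out_dir, "sequences.fasta")
    write_fasta(r, paths$fasta)
    logf("simulate: %d records (%d positive, %d negative)",
         nrow(r), sum(r$label == 1L), sum(r$label == 0L))
    r
  })

  # --- encode / embed ---
  features <- stage("encode", log_path, {
    X <- if (config$feature_source == "embedding") {
      backend <- mock_backend(dim = config$embedding_dim,
                              seed = as.integer(derive_seed(config$seed, 2L)))
      embed_peptides(backend, records)
    } else {
      encode_peptides(records, config$feature_source)
    }
    paths$features <- file.path(config$out_dir, "features.tsv")
    write_feature_matrix(X, paths$features)
    logf("encode: %s -> %d x %d matrix", config$feature_source,
         nrow(X), ncol(X))
    X
  })
  data <- labeled_matrix(features, attr(features, "labels"))

  # --- balance ---
  balanced <- stage("balance", log_path, {
    sampler <- do.call(anbs_config, utils::modifyList(
      list(seed = as.integer(derive_seed(config$seed, 3L))),
      config$sampler))
    logf("balance: pre-balance counts minority=%d majority=%d",
         sum(data$y == data$minority_label),
         sum(data$y != data$minority_label))
    b <- anbs(data, sampler)
    tr <- attr(b, "trace")
    if (!is.null(tr)) for (i in seq_len(nrow(tr))) {
      logf("balance: iteration %d removed=%d added=%d -> %d/%d",
           tr$iteration[i], tr$removed[i], tr$added[i],
           tr$n_minority[i], tr$n_majority[i])
    }
    logf("balance: post-balance counts minority=%d majority=%d (status %s)",
         sum(b$y == b$minority_label), sum(b$y != b$minority_label),
         attr(b, "status"))
    paths$balanced <- file.path(config$out_dir, "balanced.tsv")
    write_resampled(b, paths$balanced)
    b
  })

  # --- train ---
  model <- stage("train", log_path, {
    cfg <- do.call(ensemble_config, utils::modifyList(
      list(seed = as.integer(derive_seed(config$seed, 4L))),
      config$ensemble))
    m <- train_ensemble(balanced, cfg)
    paths$model <- file.path(config$out_dir, "model.rds")
    save_ensemble(m, paths$model)
    logf("train: members [%s], d=%d", paste(cfg$members, collapse = ", "),
         m$d)
    m
  })

  # --- evaluate ---
  cv <- stage("evaluate", log_path, {
    res <- cross_validate(data, folds = config$cv$folds %||% 5L,
                          resample_mode = config$cv$mode %||% "safe",
                          config = do.call(ensemble_config, utils::modifyList(
                            list(seed = 1L), config$ensemble)),
                          sampler = do.call(anbs_config, config$sampler),
                          seed = as.integer(derive_seed(config$seed, 5L)))
    paths$cv <- file.path(config$out_dir, "cv_report.tsv")
    write_cv_report(res, paths$cv)
    logf("evaluate: %d-fold (%s) mean ACC=%.4f AUC=%.4f MCC=%.4f",
         config$cv$folds %||% 5L, config$cv$mode %||% "safe",
         res$mean["ACC"], res$mean["AUC"], res$mean["MCC"])
    res
  })

  # --- explain ---
  importance <- stage("explain", log_path, {
    ex <- config$explain
    bg_n <- min(ex$n_background %||% 25L, nrow(balanced$X))
    ex_n <- min(ex$n_explain %||% 40L, nrow(features))
    set <- with_seed(derive_seed(config$seed, 6L), {
      list(bg = sample(nrow(balanced$X), bg_n),
           xp = sample(nrow(features), ex_n))
    })
    weights <- global_shap_weights(
      model, balanced$X[set$bg, , drop = FALSE],
      X = features[set$xp, , drop = FALSE],
      n_samples = ex$n_samples %||% 8L,
      seed = as.integer(derive_seed(config$seed, 7L)))

    if (config$feature_source == "embedding") {
      backend <- mock_backend(dim = config$embedding_dim,
                              seed = as.integer(derive_seed(config$seed, 2L)))
      expl <- records[set$xp, , drop = FALSE]
      results <- lapply(expl$sequence,
                        function(s) shap_res(embed_residues(backend, s),
                                             weights))
      paths$attribution <- file.path(config$out_dir, "attribution.tsv")
      write_attribution_report(results, expl$id, paths$attribution)
      imp <- aggregate_by_residue(results)
    } else {
      names(weights$w) <- colnames(features)
      imp <- rank_letter_weights(weights)
    }
    paths$importance <- file.path(config$out_dir, "letter_importance.tsv")
    utils::write.table(imp, paths$importance, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    logf("explain: top residues %s",
         paste(utils::head(imp$residue, 4), collapse = ", "))
    imp
  })

  invisible(list(records = records, features = features,
                 balanced = balanced, model = model, cv = cv,
                 importance = importance, paths = paths))
}
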