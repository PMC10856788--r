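#' One-hot encode the variable region of a sensor sequence
#'
#' 4 bits per variable-region position in base order A, C, G, T; the fixed
#' poly-C flanks carry no information and are not encoded. A standard 18-nt
#' variable region gives a 72-bit vector with exactly 18 ones (one per
#' 4-block).
#'
#' @param seq a `sensor_seq`.
#' @return named numeric 0/1 vector of length `4 * variable-region length`.
#' @export
encode_onehot <- function(seq) {
  stopifnot(inherits(seq, "sensor_seq"))
  drop(encode_onehot_many(seq$bases, seq$flank_len, nchar(seq$var_region)))
}

# vectorised encoder: rows = sequences, cols = pos1.A, pos1.C, ...
encode_onehot_many <- function(bases_chr, flank_len, var_len) {
  n <- length(bases_chr)
  var_str <- substr(bases_chr, flank_len + 1L, flank_len + var_len)
  ch <- matrix(match(unlist(strsplit(var_str, "", fixed = TRUE)), DNA_BASES),
               nrow = n, ncol = var_len, byrow = TRUE)
  X <- matrix(0, nrow = n, ncol = 4L * var_len,
              dimnames = list(NULL, paste0("pos", rep(seq_len(var_len), each = 4L),
                                           ".", rep(DNA_BASES, var_len))))
  for (j in seq_len(var_len)) {
    X[cbind(seq_len(n), 4L * (j - 1L) + ch[, j])] <- 1
  }
  X
}

#' Configuration for the surrogate screening ensemble
#'
#' @param high_threshold dF/F0 cutoff defining the classifiers' "high
#'   response" training label; `NULL` (default) uses the top quartile of the
#'   training labels.
#' @param svm_cost,svm_gamma hyperparameters shared by the two kernel
#'   regressors (radial-basis and sigmoid kernels).
#' @param classifier_sizes hidden-layer widths cycled over the nine
#'   classifiers.
#' @param n_classifiers number of classifiers (default 9).
#' @param seed seed controlling classifier initialisation draws.
#' @return config list for [fit_ensemble()].
#' @export
ensemble_config <- function(high_threshold = NULL, svm_cost = 10,
                            svm_gamma = NULL,
                            classifier_sizes = c(4L, 6L, 8L),
                            n_classifiers = 9L, seed = 1L) {
  list(high_threshold = high_threshold, svm_cost = svm_cost,
       svm_gamma = svm_gamma, classifier_sizes = classifier_sizes,
       n_classifiers = as.integer(n_classifiers), seed = as.integer(seed))
}

#' Fit the surrogate screening ensemble
#'
#' Two support-vector regressors (radial-basis and sigmoid kernels) are fit
#' to (one-hot features -> dF/F0), and nine small single-hidden-layer binary
#' classifiers are fit to the high/low response label (dF/F0 >= threshold,
#' default top quartile), each with a distinct seed and hidden width.
#' Deterministic given the config seed.
#'
#' @param sequences character vector of full sensor sequence strings (or a
#'   `mutant_library`); >= 20 training pairs required.
#' @param labels measured/true dF/F0 per sequence; must be finite and not
#'   all identical.
#' @param config see [ensemble_config()].
#' @param flank_len,var_len sequence layout (defaults: standard 30-mer).
#' @return object of class `surrogate_ensemble`.
#' @export
fit_ensemble <- function(sequences, labels, config = ensemble_config(),
                         flank_len = 6L, var_len = 18L) {
  if (inherits(sequences, "mutant_library")) sequences <- sequences$members
  if (length(sequences) < 20L) {
    stop(sensevo_error("insufficient_training",
      sprintf("need >= 20 training pairs, got %d", length(sequences))))
  }
  stopifnot(length(labels) == length(sequences), all(is.finite(labels)))
  if (max(labels) - min(labels) < 1e-12) {
    stop(sensevo_error("degenerate_labels",
      "all training labels identical; classifiers cannot be trained"))
  }
  X <- encode_onehot_many(sequences, flank_len, var_len)
  thr <- config$high_threshold %||%
    unname(stats::quantile(labels, 0.75, type = 7))
  ybin <- as.integer(labels >= thr)
  if (length(unique(ybin)) < 2L) {
    stop(sensevo_error("degenerate_labels",
      "high-response threshold separates no classes; adjust high_threshold"))
  }
  gamma <- config$svm_gamma %||% (1 / ncol(X))
  regressors <- list(
    rbf = e1071::svm(X, labels, type = "eps-regression", kernel = "radial",
                     cost = config$svm_cost, gamma = gamma, scale = FALSE),
    sigmoid = e1071::svm(X, labels, type = "eps-regression", kernel = "sigmoid",
                         cost = config$svm_cost, gamma = gamma, scale = FALSE))
  sizes <- rep_len(config$classifier_sizes, config$n_classifiers)
  classifiers <- lapply(seq_len(config$n_classifiers), function(i) {
    withr::with_seed(hash_seed(config$seed, "classifier", i),
      nnet::nnet(X, ybin, size = sizes[i], decay = 1e-3, maxit = 200,
                 entropy = TRUE, trace = FALSE))
  })
  structure(
    list(type = "ml", regressors = regressors, classifiers = classifiers,
         high_response_threshold = thr, flank_len = flank_len,
         var_len = var_len, config = config),
    class = "surrogate_ensemble")
}

#' Exact-oracle ensemble backed by the true landscape
#'
#' Replaces the trained regressors with the ground-truth landscape response
#' itself (both regressor slots return the exact value, so min = mean = max)
#' and the classifiers with a threshold rule on the true response. Used to
#' isolate the selection machinery from surrogate error.
#'
#' @param model a calibrated `landscape`.
#' @param analyte analyte whose response is predicted (default "5HT").
#' @param high_threshold true-response cutoff for the classifier votes
#'   (default `-Inf`: everything is classified high).
#' @return object of class `surrogate_ensemble` with `type = "oracle"`.
#' @export
make_oracle_ensemble <- function(model, analyte = "5HT",
                                 high_threshold = -Inf) {
  check_analyte(model, analyte)
  structure(
    list(type = "oracle", model = model, analyte = analyte,
         high_response_threshold = high_threshold,
         flank_len = model$flank_len, var_len = model$var_len),
    class = "surrogate_ensemble")
}

#' Predict with the surrogate ensemble
#'
#' Per sequence: `pred_min`/`pred_max`/`mean_r` over the regressor outputs
#' (mean_r is the ranking indicator), the nine classifier votes, and
#' `consistent_high` — TRUE when a majority of the classifiers label the
#' sequence high-response.
#'
#' @param ens a `surrogate_ensemble`.
#' @param sequences character vector of full sequence strings or a
#'   `mutant_library`.
#' @return data.frame: `sequence`, `pred_min`, `mean_r`, `pred_max`,
#'   `votes_high` (0-9), `consistent_high`; the 0/1 vote matrix is attached
#'   as attribute `"votes"`.
#' @export
predict_ensemble <- function(ens, sequences) {
  if (!inherits(ens, "surrogate_ensemble")) {
    stop(sensevo_error("untrained_ensemble",
      "predict_ensemble requires a fitted surrogate_ensemble"))
  }
  if (inherits(sequences, "mutant_library")) sequences <- sequences$members
  if (ens$type == "oracle") {
    r <- true_response_many(ens$model, sequences, ens$analyte)
    votes <- matrix(as.integer(r >= ens$high_response_threshold),
                    nrow = length(r), ncol = 9L)
    preds <- cbind(r, r)
  } else {
    X <- encode_onehot_many(sequences, ens$flank_len, ens$var_len)
    preds <- vapply(ens$regressors,
                    function(m) as.numeric(stats::predict(m, X)),
                    numeric(length(sequences)))
    if (is.null(dim(preds))) preds <- matrix(preds, nrow = 1L)
    votes <- vapply(ens$classifiers,
                    function(m) as.integer(stats::predict(m, X) > 0.5),
                    integer(length(sequences)))
    if (is.null(dim(votes))) votes <- matrix(votes, nrow = 1L)
  }
  out <- data.frame(
    sequence = sequences,
    pred_min = apply(preds, 1L, min),
    mean_r = rowMeans(preds),
    pred_max = apply(preds, 1L, max),
    votes_high = rowSums(votes),
    stringsAsFactors = FALSE)
  out$consistent_high <- out$votes_high > ncol(votes) / 2
  attr(out, "votes") <- votes
  out
}

#' Select the top-k screening candidates
#'
#' Sorts predictions descending by `mean_r` (ties broken lexicographically
#' by sequence string for reproducibility), drops sequences the classifier
#' consensus does not label high-response (the next-ranked are promoted),
#' and returns at most `k` records with a `rank` column.
#'
#' @param preds prediction data.frame from [predict_ensemble()].
#' @param k number of candidates (>= 1).
#' @return data.frame of `min(k, eligible)` rows, `mean_r` non-increasing.
#' @export
select_top_k <- function(preds, k) {
  stopifnot(k >= 1)
  eligible <- preds[preds$consistent_high, , drop = FALSE]
  ord <- order(-eligible$mean_r, eligible$sequence, method = "radix")
  out <- eligible[ord, , drop = FALSE][seq_len(min(k, nrow(eligible))), ,
                                       drop = FALSE]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}

#' Save / load a fitted ensemble
#'
#' Versioned archive contract: `load_ensemble(save_ensemble(m, path))`
#' yields identical predictions.
#'
#' @param ens a `surrogate_ensemble`.
#' @param path archive path.
#' @return `path` (save) / the restored ensemble (load).
#' @export
save_ensemble <- function(ens, path) {
  stopifnot(inherits(ens, "surrogate_ensemble"))
  saveRDS(list(format_version = 1L, ensemble = ens), path)
  invisible(path)
}

#' @rdname save_ensemble
#' @export
load_ensemble <- function(path) {
  obj <- readRDS(path)
  if (!identical(obj$format_version, 1L)) {
    stop(sensevo_error("unsupported_archive",
      "unrecognised ensemble archive version"))
  }
  obj$ensemble
}
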