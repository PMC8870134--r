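#' Per-trial statistical features of EMG envelopes
#'
#' Summarises each envelope trace by its quartiles, interquartile range,
#' variance, skewness and kurtosis — the distributional fingerprint used to
#' decide how many sub-models the library needs.
#'
#' @param trials List of preprocessed envelope `signal_trace`s, or of trial
#'   records with an `$envelope` element; optionally named.
#' @param profile Optional character vector of profile kinds, one per trial.
#' @return A data frame with one row per trial: `trial_id`, `profile`, `q1`,
#'   `median`, `q3`, `iqr`, `variance`, `skewness`, `kurtosis`.
#' @export
trial_statistics <- function(trials, profile = NULL) {
  if (inherits(trials, "signal_trace")) trials <- list(trials)
  if (length(trials) == 0L) stop("trial_statistics: no trials given")
  rows <- lapply(seq_along(trials), function(i) {
    tr <- trials[[i]]
    x <- if (inherits(tr, "signal_trace")) tr$samples
         else if (!is.null(tr$envelope)) tr$envelope$samples
         else stop("trial_statistics: trial ", i, " is not a signal_trace")
    if (length(x) == 0L) stop("trial_statistics: empty trial ", i)
    q <- stats::quantile(x, c(0.25, 0.5, 0.75), names = FALSE)
    data.frame(
      trial_id = if (!is.null(names(trials))) names(trials)[i] else
        as.character(i),
      profile = if (!is.null(profile)) profile[i] else NA_character_,
      q1 = q[1], median = q[2], q3 = q[3], iqr = q[3] - q[1],
      variance = stats::var(x),
      skewness = e1071::skewness(x),
      kurtosis = e1071::kurtosis(x)
    )
  })
  do.call(rbind, rows)
}

feature_matrix <- function(features) {
  cols <- c("q1", "median", "q3", "iqr", "variance", "skewness", "kurtosis")
  X <- as.matrix(features[, cols])
  X[!is.finite(X)] <- 0
  keep <- apply(X, 2, function(c) stats::sd(c) > 1e-12)
  X <- X[, keep, drop = FALSE]
  if (ncol(X) > 0) X <- scale(X)
  X
}

#' Suggest the number of sub-models from trial features
#'
#' Operationalises the distribution-based choice of library size: k-means
#' over standardised trial features for each candidate N, scored by the mean
#' silhouette width; the best-scoring N is suggested. When the features
#' carry no variation (all trials alike) the silhouette is undefined and the
#' fallback suggestion is N = 1. Deterministic under a fixed seed.
#'
#' @param features Data frame from [trial_statistics()].
#' @param candidates Candidate sub-model counts (default 2:5).
#' @param seed Seed for the k-means restarts.
#' @return A `library_plan`: `suggested_n`, `assignment` (cluster id per
#'   trial for the suggested N), `silhouette` (named mean silhouette per
#'   candidate), `features`.
#' @export
suggest_submodel_count <- function(features, candidates = 2:5, seed = 1L) {
  n_trials <- nrow(features)
  if (n_trials < 3L) stop("suggest_submodel_count: need at least 3 trials")
  candidates <- candidates[candidates >= 2L & candidates <= n_trials - 1L]
  if (length(candidates) == 0L)
    stop("suggest_submodel_count: fewer trials than the smallest candidate")
  X <- feature_matrix(features)
  if (ncol(X) == 0L || nrow(unique(X)) == 1L) {
    return(structure(list(suggested_n = 1L,
                          assignment = rep(1L, n_trials),
                          silhouette = stats::setNames(numeric(0),
                                                       character(0)),
                          features = features),
                     class = "library_plan"))
  }
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  d <- stats::dist(X)
  sil <- stats::setNames(rep(NA_real_, length(candidates)),
                         as.character(candidates))
  assignments <- list()
  for (ci in seq_along(candidates)) {
    k <- candidates[ci]
    if (k > nrow(unique(X))) next
    set.seed(seed)
    km <- stats::kmeans(X, centers = k, nstart = 10L, iter.max = 50L)
    assignments[[as.character(k)]] <- km$cluster
    if (length(unique(km$cluster)) < 2L) next
    sil[ci] <- mean(cluster::silhouette(km$cluster, d)[, "sil_width"])
  }
  if (all(is.na(sil))) {
    return(structure(list(suggested_n = 1L,
                          assignment = rep(1L, n_trials),
                          silhouette = sil, features = features),
                     class = "library_plan"))
  }
  best <- candidates[which.max(sil)]
  structure(list(suggested_n = as.integer(best),
                 assignment = assignments[[as.character(best)]],
                 silhouette = sil, features = features),
            class = "library_plan")
}

#' @export
print.library_plan <- function(x, ...) {
  cat(sprintf("<library_plan: suggested N = %d over %d trials>\n",
              x$suggested_n, nrow(x$features)))
  if (length(x$silhouette))
    cat("  mean silhouette:",
        paste(sprintf("N=%s: %.3f", names(x$silhouette), x$silhouette),
              collapse = ", "), "\n")
  invisible(x)
}

#' Build a sub-model library from training couples
#'
#' One sub-model per cluster of the plan, each identified on the couple
#' whose features lie nearest the cluster centroid (in standardised feature
#' space). With `n_override`, clustering is bypassed and the first
#' `n_override` couples are used directly.
#'
#' @param couples List of training couples, each a list with `emg`
#'   (preprocessed envelope `signal_trace`), `force` (preprocessed force
#'   `signal_trace`), and optional `id`, `profile`.
#' @param plan A `library_plan` from [suggest_submodel_count()] (ignored
#'   when `n_override` is given).
#' @param config A [hw_config()] passed to [identify_hw()].
#' @param n_override Optional explicit number of sub-models.
#' @return A `model_library`.
#' @export
build_library <- function(couples, plan = NULL, config = hw_config(),
                          n_override = NULL) {
  ids <- vapply(seq_along(couples), function(i) {
    if (!is.null(couples[[i]]$id)) as.character(couples[[i]]$id)
    else as.character(i)
  }, character(1))
  chosen <- if (!is.null(n_override)) {
    n_override <- as.integer(n_override)
    if (n_override < 1L || n_override > length(couples))
      stop("build_library: n_override out of range")
    seq_len(n_override)
  } else if (!is.null(plan)) {
    if (plan$suggested_n == 1L) 1L
    else {
      X <- feature_matrix(plan$features)
      vapply(seq_len(plan$suggested_n), function(cl) {
        members <- which(plan$assignment == cl)
        centroid <- colMeans(X[members, , drop = FALSE])
        d2 <- rowSums((X[members, , drop = FALSE] -
                         matrix(centroid, length(members), ncol(X),
                                byrow = TRUE))^2)
        members[which.min(d2)]
      }, integer(1))
    }
  } else seq_along(couples)

  entries <- vector("list", length(chosen))
  for (e in seq_along(chosen)) {
    i <- chosen[e]
    model <- tryCatch(
      identify_hw(couples[[i]]$emg, couples[[i]]$force, config),
      error = function(err)
        stop("build_library: identification failed for couple '", ids[i],
             "': ", conditionMessage(err)))
    entries[[e]] <- list(
      id = e, model = model, training_ref = ids[i],
      profile_kind = if (!is.null(couples[[i]]$profile))
        couples[[i]]$profile else NA_character_)
  }
  model_library(entries, fs = couples[[chosen[1]]]$emg$fs)
}
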