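#' Decoder configuration
#'
#' The decoder is a linear logistic model with L1 (lasso) penalty
#' `lambda = 0.01`, trained one-vs-all per class at each time window and
#' evaluated with leave-one-trial-out cross-validation. Per-class "scores"
#' are the linear decision values; the two-class posterior is the softmax
#' `exp(s_i) / sum(exp(s_i))` over the pair.
#'
#' @param lambda L1 penalty (default 0.01).
#' @param intercept include an intercept (unpenalized)?
#' @param thresh solver convergence tolerance.
#' @param maxit maximum solver iterations.
#' @param fold_safe_zscore when the rate matrix is not already z-scored,
#'   compute z-scoring statistics on the training folds only and apply them
#'   to the held-out trial. Pass an already z-scored matrix to reproduce
#'   whole-set z-scoring instead.
#' @param engine `"builtin"` (compiled FISTA proximal-gradient solver, the
#'   default: the many small fits of leave-one-out pipelines dominate run
#'   time) or `"glmnet"` (coordinate descent); both minimize the identical
#'   objective `(1/n) negloglik + lambda ||beta||_1` and agree to solver
#'   tolerance.
#' @return list of class `decoder_config`.
#' @export
decoder_config <- function(lambda = 0.01, intercept = TRUE, thresh = 1e-6,
                           maxit = 10000, fold_safe_zscore = TRUE,
                           engine = c("builtin", "glmnet")) {
  if (lambda <= 0) stop("lambda must be positive")
  structure(list(lambda = lambda, intercept = intercept, thresh = thresh,
                 maxit = maxit, fold_safe_zscore = fold_safe_zscore,
                 engine = match.arg(engine)),
            class = "decoder_config")
}

## One-vs-all linear scores. Xtr: n x p, ytr: factor, Xte: m x p.
## Returns m x nlevels matrix of linear decision values.
ova_scores <- function(Xtr, ytr, Xte, config) {
  classes <- levels(ytr)
  Xte <- rbind(Xte)  # ensure matrix
  if (ncol(Xtr) == 1) {  # glmnet needs >= 2 columns; pad an inert one
    Xtr <- cbind(Xtr, 0)
    Xte <- cbind(Xte, 0)
  }
  one_fit <- function(y01) {
    use_glmnet <- identical(config$engine, "glmnet") &&
      min(tabulate(y01 + 1L, 2L)) >= 2   # glmnet rejects singleton classes
    if (use_glmnet) {
      fit <- suppressWarnings(
        glmnet::glmnet(Xtr, y01, family = "binomial", alpha = 1,
                       lambda = config$lambda, standardize = FALSE,
                       intercept = config$intercept,
                       thresh = config$thresh, maxit = config$maxit))
      drop(predict(fit, newx = Xte, type = "link"))
    } else {
      b <- cpp_l1_logistic(Xtr, y01, config$lambda, config$intercept,
                           config$thresh, config$maxit)
      drop(b[1] + Xte %*% b[-1])
    }
  }
  if (length(classes) == 2) {
    ## the two one-vs-all problems are exact sign flips of each other
    eta <- one_fit(as.integer(ytr == classes[2]))
    cbind(-eta, eta, deparse.level = 0)
  } else {
    sc <- vapply(classes, function(cl) one_fit(as.integer(ytr == cl)),
                 numeric(nrow(Xte)))
    matrix(sc, nrow = nrow(Xte), dimnames = list(NULL, classes))
  }
}

#' Softmax posterior over per-class decision scores
#'
#' `Posterior(i) = exp(score_i) / sum_j exp(score_j)`, computed stably.
#'
#' @param scores numeric vector of per-class linear scores.
#' @return probabilities summing to 1.
#' @export
softmax_scores <- function(scores) {
  es <- exp(scores - max(scores))
  es / sum(es)
}

## Leave-one-out z-scoring statistics from training trials only.
## x: trials x units at one window. Returns function(i) -> list(mu, sd).
loo_zstats <- function(x) {
  n <- nrow(x)
  s1 <- colSums(x); s2 <- colSums(x^2)
  function(i) {
    mu <- (s1 - x[i, ]) / (n - 1)
    vr <- pmax((s2 - x[i, ]^2) / (n - 1) - mu^2, 0) * (n - 1) / (n - 2)
    list(mu = mu, sd = sqrt(vr))
  }
}

apply_z <- function(x, st) {
  z <- sweep(rbind(x), 2, st$mu)
  ok <- st$sd > 0
  z[, ok] <- sweep(z[, ok, drop = FALSE], 2, st$sd[ok], "/")
  z[, !ok] <- 0
  z
}

#' Cross-temporal 8-way decoding with leave-one-trial-out
#'
#' For every training window, `n` leave-one-out folds are run: eight
#' one-vs-all lasso-logistic classifiers are trained on the remaining trials
#' and the held-out trial is scored at every test window (classes tied in
#' the argmax break toward the lowest class index). Accuracy per (train,
#' test) window pair is the fraction of correctly classified held-out
#' trials; per-cue-condition accuracy matrices use the corresponding trial
#' subsets.
#'
#' @param rate_matrix a `rate_matrix` (z-scored, or raw with fold-safe
#'   z-scoring per the config).
#' @param cue_labels per-trial cue locations (defaults to the matrix labels).
#' @param config a [decoder_config()].
#' @param train_windows,test_windows window indices (default all).
#' @return list of class `crosstemporal_accuracy`: `accuracy` (train x test
#'   windows), `per_cue` (list of matrices), `n_trials`, `window_centers`.
#' @export
train_crosstemporal <- function(rate_matrix, cue_labels = NULL,
                                config = decoder_config(),
                                train_windows = NULL, test_windows = NULL) {
  stopifnot(inherits(rate_matrix, "rate_matrix"))
  labs <- as.numeric(cue_labels %||% attr(rate_matrix, "cue_location_deg"))
  lab <- factor(labs, levels = sort(unique(labs)))  # argmax ties -> lowest angle
  if (any(table(lab) < 2)) stop("every class needs at least 2 trials")
  nt <- dim(rate_matrix)[1]
  nw <- dim(rate_matrix)[3]
  tw <- train_windows %||% seq_len(nw)
  sw <- test_windows %||% seq_len(nw)
  prez <- isTRUE(attr(rate_matrix, "zscored")) || !config$fold_safe_zscore
  slices <- lapply(seq_len(nw), function(w) rate_slice(rate_matrix, w))
  zstats <- if (!prez) lapply(slices, loo_zstats)

  correct <- array(0, dim = c(length(tw), length(sw), nt))
  for (ti in seq_along(tw)) {
    w <- tw[ti]
    for (i in seq_len(nt)) {
      if (prez) {
        Xtr <- slices[[w]][-i, , drop = FALSE]
        Xte_list <- lapply(sw, function(v) slices[[v]][i, , drop = FALSE])
      } else {
        st <- zstats[[w]](i)
        Xtr <- apply_z(slices[[w]][-i, , drop = FALSE], st)
        Xte_list <- lapply(sw, function(v)
          apply_z(slices[[v]][i, , drop = FALSE], zstats[[v]](i)))
      }
      sc <- ova_scores(Xtr, droplevels(lab[-i]), do.call(rbind, Xte_list), config)
      cls <- levels(droplevels(lab[-i]))
      pred <- cls[max.col(sc, ties.method = "first")]
      correct[ti, , i] <- as.integer(pred == as.character(lab[i]))
    }
  }
  acc <- apply(correct, c(1, 2), mean)
  ctr <- attr(rate_matrix, "window_centers")
  dimnames(acc) <- list(sprintf("%.3f", ctr[tw]), sprintf("%.3f", ctr[sw]))
  per_cue <- lapply(levels(lab), function(cl) {
    idx <- which(lab == cl)
    m <- apply(correct[, , idx, drop = FALSE], c(1, 2), mean)
    dimnames(m) <- dimnames(acc)
    m
  })
  names(per_cue) <- levels(lab)
  structure(list(accuracy = acc, per_cue = per_cue, n_trials = nt,
                 train_centers = ctr[tw], test_centers = ctr[sw]),
            class = "crosstemporal_accuracy")
}

#' @export
print.crosstemporal_accuracy <- function(x, ...) {
  cat(sprintf("<crosstemporal_accuracy> %d train x %d test windows, %d trials\n",
              nrow(x$accuracy), ncol(x$accuracy), x$n_trials))
  cat(sprintf("  diagonal accuracy %.3f (mean), off-diagonal %.3f (mean)\n",
              mean(diag(x$accuracy)),
              mean(x$accuracy[row(x$accuracy) != col(x$accuracy)])))
  invisible(x)
}

#' Binary diametric decoding with posterior-probability confidence
#'
#' Restricts trials to one diametric cue pair (180 degrees apart), trains a
#' lasso-logistic classifier per window with leave-one-trial-out, and
#' returns for every held-out trial and window the softmax posterior
#' probability of the trial's true cue versus its diametric alternative,
#' computed from the two one-vs-all linear scores. With `shuffle_training`,
#' the training labels are randomly permuted independently on each fold
#' (chance calibration); with `training_labels`, the supplied (e.g. globally
#' permuted) labels are used for training while evaluation stays against the
#' true labels.
#'
#' @param rate_matrix a `rate_matrix`.
#' @param pair two cue angles 180 degrees apart, e.g. `c(0, 180)`.
#' @param config a [decoder_config()].
#' @param windows window indices to decode (default all).
#' @param shuffle_training permute training labels per fold?
#' @param training_labels optional label vector (length = all trials in the
#'   matrix) used for training only.
#' @param seed seed for training-label permutations.
#' @return list of class `confidence_series`: `posterior` and `correct`
#'   (trials x windows), `trial_ids`, `labels`, `pair`, `window_centers`.
#' @export
binary_confidence <- function(rate_matrix, pair, config = decoder_config(),
                              windows = NULL, shuffle_training = FALSE,
                              training_labels = NULL, seed = 1) {
  stopifnot(inherits(rate_matrix, "rate_matrix"))
  pair <- sort(pair %% 360)
  if (circ_dist_deg(pair[1], pair[2]) != 180)
    stop("pair must be diametric (180 degrees apart)")
  all_lab <- attr(rate_matrix, "cue_location_deg")
  keep <- which(all_lab %in% pair)
  if (length(keep) < 3) stop("need at least 3 trials of the diametric pair")
  lab <- factor(all_lab[keep], levels = pair)
  if (any(table(lab) < 1)) stop("both pair locations must be present")
  tr_lab <- if (!is.null(training_labels)) factor(training_labels[keep], levels = pair)
            else lab
  nw <- dim(rate_matrix)[3]
  win <- windows %||% seq_len(nw)
  prez <- isTRUE(attr(rate_matrix, "zscored")) || !config$fold_safe_zscore
  nt <- length(keep)
  seeds <- derive_seeds(seed, nt)

  post <- matrix(NA_real_, nt, length(win))
  corr <- matrix(NA_real_, nt, length(win))
  for (wi in seq_along(win)) {
    w <- win[wi]
    x <- rate_slice(rate_matrix, w)[keep, , drop = FALSE]
    zs <- if (!prez) loo_zstats(x)
    for (i in seq_len(nt)) {
      ytr <- droplevels(tr_lab[-i])
      if (shuffle_training) {
        ## draw from the full-session label multiset (not the fold's), so the
        ## held-out class is not systematically in the training minority
        ytr <- with_seed(seeds[i] + w,
                         factor(sample(as.character(lab), length(ytr)),
                                levels = levels(lab)))
        ytr <- droplevels(ytr)
      }
      if (nlevels(ytr) < 2) { post[i, wi] <- 0.5; corr[i, wi] <- 0.5; next }
      if (prez) { Xtr <- x[-i, , drop = FALSE]; Xte <- x[i, , drop = FALSE] }
      else {
        st <- zs(i)
        Xtr <- apply_z(x[-i, , drop = FALSE], st)
        Xte <- apply_z(x[i, , drop = FALSE], st)
      }
      sc <- ova_scores(Xtr, ytr, Xte, config)
      true_col <- match(as.character(lab[i]), levels(ytr))
      post[i, wi] <- softmax_scores(sc[1, ])[true_col]
      pred <- levels(ytr)[max.col(rbind(sc[1, ]), ties.method = "first")]
      corr[i, wi] <- as.integer(pred == as.character(lab[i]))
    }
  }
  ctr <- attr(rate_matrix, "window_centers")[win]
  dimnames(post) <- dimnames(corr) <-
    list(dimnames(rate_matrix)[[1]][keep], sprintf("%.3f", ctr))
  structure(list(posterior = post, correct = corr,
                 trial_ids = dimnames(rate_matrix)[[1]][keep],
                 labels = as.numeric(as.character(lab)), pair = pair,
                 window_centers = ctr, trial_index = keep),
            class = "confidence_series")
}

#' @export
print.confidence_series <- function(x, ...) {
  cat(sprintf("<confidence_series> pair %g/%g deg: %d trials x %d windows\n",
              x$pair[1], x$pair[2], nrow(x$posterior), ncol(x$posterior)))
  cat(sprintf("  mean posterior of true cue %.3f, mean accuracy %.3f\n",
              mean(x$posterior), mean(x$correct)))
  invisible(x)
}

#' Per-window leave-one-out decoding accuracy (train = test window)
#'
#' The diagonal decoding trace used for simultaneous vs pseudo-population
#' comparisons.
#'
#' @param rate_matrix a `rate_matrix`.
#' @param scheme `"8way"` or `"binary"`.
#' @param pair diametric pair for the binary scheme.
#' @param config a [decoder_config()].
#' @param windows window indices (default all).
#' @return numeric vector of accuracies named by window center.
#' @export
decode_trace <- function(rate_matrix, scheme = c("8way", "binary"),
                         pair = c(0, 180), config = decoder_config(),
                         windows = NULL) {
  scheme <- match.arg(scheme)
  if (scheme == "binary") {
    cs <- binary_confidence(rate_matrix, pair, config = config, windows = windows)
    return(colMeans(cs$correct))
  }
  nw <- dim(rate_matrix)[3]
  win <- windows %||% seq_len(nw)
  ct <- train_crosstemporal(rate_matrix, config = config,
                            train_windows = win, test_windows = win)
  setNames(diag(ct$accuracy), sprintf("%.3f", ct$train_centers))
}
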