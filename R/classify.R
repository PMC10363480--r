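#' @include physchem.R
NULL

#' Configuration for the mTP/cTP classification protocol
#'
#' Parameters of the balanced, resampled, cross-validated penalized
#' logistic-regression protocol. The penalty is an elastic net with mixing
#' parameter \code{l1_ratio} (0 = pure ridge, the default, so all 36 ACC
#' features take part in the model) and inverse regularization strength
#' \code{C} = 1/lambda (default 0.1). Internally the fit is performed with
#' \pkg{glmnet}; \code{C} is mapped onto glmnet's per-observation penalty
#' scale as \code{lambda = 1 / (C * n_train)}, so the optimised objective
#' matches the usual sum-loglikelihood-plus-penalty formulation.
#'
#' @param l1_ratio elastic-net mixing parameter in [0, 1]
#' @param C inverse regularization strength (> 0)
#' @param n_runs number of resampling runs (default 100)
#' @param n_folds folds per run (default 5)
#' @param balanced_n rows drawn per class and run; default the smaller
#'   class size
#' @param tune_folds folds used by \code{\link{tuneHyperparameters}}
#' @param standardize standardize features using training-fold statistics
#'   (regularized models are scale-sensitive, so this defaults to TRUE)
#' @param seed seed controlling subsampling and fold assignment
#' @return a named list
#' @export
classifierConfig <- function(l1_ratio = 0, C = 0.1, n_runs = 100L,
                             n_folds = 5L, balanced_n = NULL,
                             tune_folds = 10L, standardize = TRUE,
                             seed = NULL) {
  stopifnot(l1_ratio >= 0, l1_ratio <= 1, C > 0, n_folds >= 2L)
  list(l1_ratio = l1_ratio, C = C, n_runs = as.integer(n_runs),
       n_folds = as.integer(n_folds),
       balanced_n = if (is.null(balanced_n)) NULL else as.integer(balanced_n),
       tune_folds = as.integer(tune_folds), standardize = standardize,
       seed = seed)
}

# Penalized binomial logistic fit; returns a predict(newx) closure giving
# the probability of the second factor level.
.fitPenalized <- function(x, y, l1_ratio, C, standardize) {
  if (standardize) {
    ctr <- colMeans(x)
    scl <- apply(x, 2L, stats::sd)
    scl[scl == 0 | is.na(scl)] <- 1
  } else {
    ctr <- rep(0, ncol(x)); scl <- rep(1, ncol(x))
  }
  xs <- sweep(sweep(x, 2L, ctr), 2L, scl, "/")
  lambda <- 1 / (C * nrow(x))
  fit <- glmnet::glmnet(xs, y, family = "binomial", alpha = l1_ratio,
                        lambda = lambda, standardize = FALSE,
                        thresh = 1e-10, maxit = 1e6L)
  if (fit$jerr != 0L || fit$npasses >= 1e6L)
    stop("penalized logistic fit did not converge")
  list(
    predict = function(newx) {
      ns <- sweep(sweep(newx, 2L, ctr), 2L, scl, "/")
      as.numeric(stats::predict(fit, ns, type = "response"))
    },
    coefficients = {
      b <- as.numeric(stats::coef(fit))
      # map back to the original feature scale
      w <- b[-1L] / scl
      stats::setNames(c(b[1L] - sum(w * ctr), w),
                      c("(Intercept)", colnames(x)))
    })
}

# Stratified fold labels: every fold receives a near-equal share of each
# class. Re-draws (counted) if a fold ends up single-class, which can only
# happen when a class has fewer rows than folds.
.stratifiedFolds <- function(y, k) {
  f <- integer(length(y))
  for (lv in levels(y)) {
    idx <- which(y == lv)
    f[idx] <- sample(rep_len(seq_len(k), length(idx)))
  }
  f
}

#' Featurize peptide N-termini for classification
#'
#' Computes the ACC representation of each peptide's first \code{n}
#' residues (default 15, the N-terminal region carrying localization
#' information), dropping peptides shorter than \code{n} with a warning.
#' Labels are taken from the peptide roles.
#'
#' @param peptides a \code{PeptideSet}
#' @param n N-terminal length
#' @param ... passed to \code{\link{accMatrix}}
#' @return list with \code{X} (feature matrix, 36 columns at the default
#'   lag), \code{role} (character vector) and \code{peptide_id}
#' @export
featurizeNTermini <- function(peptides, n = 15L, ...) {
  stopifnot(is(peptides, "PeptideSet"))
  w <- nchar(aaSequences(peptides))
  short <- w < n
  if (any(short)) {
    warning("dropping ", sum(short), " peptide(s) shorter than ", n,
            " residues: ", paste(peptideIds(peptides)[short], collapse = ", "))
    peptides <- peptides[!short]
  }
  if (length(peptides) == 0L) stop("no peptide of length >= ", n)
  nt <- extractNElement(peptides, n)
  X <- accMatrix(nt, ...)
  rownames(X) <- peptideIds(peptides)
  list(X = X, role = unname(peptideRoles(peptides)),
       peptide_id = peptideIds(peptides))
}

#' Balanced resampled cross-validated classification accuracy
#'
#' The discrimination protocol for mTP-like versus cTP-like feature
#' matrices: in each of \code{n_runs} runs, draw the same number of rows
#' from each class without replacement (\code{balanced_n}, default the
#' smaller class size), split them into stratified folds, fit the
#' penalized binomial logistic model on the training folds (features
#' standardized with training-fold statistics only) and record the
#' held-out accuracy; the run's accuracy is the mean over folds and the
#' report aggregates over runs. Coefficients come from a final fit on all
#' rows of both classes. With a fixed \code{seed} in the config the whole
#' report is reproducible exactly.
#'
#' @param X_mtp,X_ctp feature matrices (rows = peptides), same columns
#' @param config a \code{\link{classifierConfig}}
#' @return a \linkS4class{ClassifierReport}
#' @examples
#' d <- generateLabeledDataset(list(
#'   generatorSpec("MTP_LIKE", n = 20, seed = 1),
#'   generatorSpec("CTP_LIKE", n = 20, seed = 2)))
#' f <- featurizeNTermini(do.call(c, unname(d$peptides)))
#' rep <- balancedCVAccuracy(f$X[f$role == "mTP", ], f$X[f$role == "cTP", ],
#'                           classifierConfig(n_runs = 5, seed = 1))
#' meanAccuracy(rep)
#' @export
balancedCVAccuracy <- function(X_mtp, X_ctp, config = classifierConfig()) {
  stopifnot(is.matrix(X_mtp), is.matrix(X_ctp),
            ncol(X_mtp) == ncol(X_ctp))
  bn <- config$balanced_n %||% min(nrow(X_mtp), nrow(X_ctp))
  if (bn > nrow(X_mtp) || bn > nrow(X_ctp))
    stop("balanced_n exceeds a class size")
  k <- config$n_folds
  redraws <- 0L
  run_acc <- withSeed(config$seed, {
    vapply(seq_len(config$n_runs), function(run) {
      X <- rbind(X_mtp[sample(nrow(X_mtp), bn), , drop = FALSE],
                 X_ctp[sample(nrow(X_ctp), bn), , drop = FALSE])
      y <- factor(rep(c("mTP", "cTP"), each = bn), levels = c("mTP", "cTP"))
      repeat {
        folds <- .stratifiedFolds(y, k)
        ok <- all(vapply(seq_len(k), function(f)
          length(unique(y[folds == f])) == 2L, logical(1)))
        if (ok) break
        redraws <<- redraws + 1L
      }
      accs <- vapply(seq_len(k), function(f) {
        tr <- folds != f
        fit <- .fitPenalized(X[tr, , drop = FALSE], y[tr],
                             config$l1_ratio, config$C, config$standardize)
        p <- fit$predict(X[!tr, , drop = FALSE])
        pred <- ifelse(p >= 0.5, "cTP", "mTP")
        mean(pred == as.character(y[!tr]))
      }, numeric(1))
      mean(accs)
    }, numeric(1))
  })
  X_all <- rbind(X_mtp, X_ctp)
  y_all <- factor(rep(c("mTP", "cTP"), c(nrow(X_mtp), nrow(X_ctp))),
                  levels = c("mTP", "cTP"))
  final <- .fitPenalized(X_all, y_all, config$l1_ratio, config$C,
                         config$standardize)
  new("ClassifierReport", run_accuracies = run_acc,
      coefficients = final$coefficients, config = config,
      seed = if (is.null(config$seed)) NA_integer_ else
        as.integer(config$seed),
      n_redraws = redraws)
}

#' @rdname ClassifierReport-class
#' @export
setMethod("runAccuracies", "ClassifierReport",
          function(object) object@run_accuracies)

#' @rdname ClassifierReport-class
#' @export
setMethod("meanAccuracy", "ClassifierReport",
          function(object) mean(object@run_accuracies))

#' @rdname ClassifierReport-class
#' @export
setMethod("modelCoefficients", "ClassifierReport",
          function(object) object@coefficients)

#' @rdname ClassifierReport-class
#' @export
setMethod("show", "ClassifierReport", function(object) {
  a <- object@run_accuracies
  cat(sprintf("ClassifierReport: %d run(s), mean accuracy %.3f (sd %.3f)\n",
              length(a), mean(a), stats::sd(a)))
  cat(sprintf("  l1_ratio = %g, C = %g, %d-fold CV, balanced_n = %s, seed = %s\n",
              object@config$l1_ratio, object@config$C, object@config$n_folds,
              object@config$balanced_n %||% "min class size",
              ifelse(is.na(object@seed), "none", object@seed)))
  if (object@n_redraws > 0L)
    cat("  degenerate folds re-drawn:", object@n_redraws, "\n")
  invisible(object)
})

#' Exhaustive hyperparameter grid evaluation
#'
#' Evaluates every (l1_ratio, C) pair of a grid by stratified k-fold
#' cross-validation (one shared fold assignment, drawn under \code{seed},
#' so points are comparable) and reports the full accuracy table. Ties for
#' the best accuracy are reported, never silently broken: the
#' \code{"best"} attribute holds every row attaining the maximum.
#'
#' @param X feature matrix
#' @param y two-level factor of labels
#' @param grid data.frame with columns \code{l1_ratio} and \code{C}
#' @param tune_folds number of folds
#' @param standardize as in \code{\link{classifierConfig}}
#' @param seed fold-assignment seed
#' @return data.frame \code{l1_ratio}, \code{C}, \code{accuracy}, with
#'   attribute \code{"best"}
#' @export
tuneHyperparameters <- function(X, y, grid, tune_folds = 10L,
                                standardize = TRUE, seed = NULL) {
  stopifnot(is.data.frame(grid), nrow(grid) >= 1L,
            all(c("l1_ratio", "C") %in% names(grid)))
  y <- droplevels(as.factor(y))
  stopifnot(nlevels(y) == 2L)
  folds <- withSeed(seed, .stratifiedFolds(y, tune_folds))
  acc <- vapply(seq_len(nrow(grid)), function(g) {
    mean(vapply(seq_len(tune_folds), function(f) {
      tr <- folds != f
      if (length(unique(y[!tr])) == 0L) return(NA_real_)
      fit <- .fitPenalized(X[tr, , drop = FALSE], y[tr],
                           grid$l1_ratio[g], grid$C[g], standardize)
      p <- fit$predict(X[!tr, , drop = FALSE])
      pred <- levels(y)[1L + (p >= 0.5)]
      mean(pred == as.character(y[!tr]))
    }, numeric(1)), na.rm = TRUE)
  }, numeric(1))
  out <- data.frame(l1_ratio = grid$l1_ratio, C = grid$C, accuracy = acc)
  attr(out, "best") <- out[out$accuracy == max(out$accuracy), , drop = FALSE]
  out
}

#' Score candidate peptides for targeting-peptide similarity
#'
#' Fits an elastic-net logistic model (default mixing 0.15) separating
#' HA-RAMPs from targeting peptides on whole-peptide ACC vectors, then
#' scores each candidate by its fitted probability of the TP class, a
#' value in [0, 1] where higher means more TP-like. Whole peptides (not
#' N-termini) are featurized, since HA-RAMPs carry no cleavage sites.
#'
#' @param candidates,ha_ramps,tps \code{PeptideSet}s
#' @param l1_ratio elastic-net mixing parameter
#' @param C inverse regularization strength
#' @param standardize standardize features on the training data
#' @param ... passed to \code{\link{accMatrix}}
#' @return data.frame \code{peptide_id}, \code{score}
#' @export
tpSimilarityScore <- function(candidates, ha_ramps, tps, l1_ratio = 0.15,
                              C = 1, standardize = TRUE, ...) {
  stopifnot(length(ha_ramps) > 0L, length(tps) > 0L)
  X <- rbind(accMatrix(ha_ramps, ...), accMatrix(tps, ...))
  y <- factor(rep(c("HA_RAMP", "TP"), c(length(ha_ramps), length(tps))),
              levels = c("HA_RAMP", "TP"))
  fit <- .fitPenalized(X, y, l1_ratio, C, standardize)
  Xq <- accMatrix(candidates, ...)
  data.frame(peptide_id = rownames(Xq), score = fit$predict(Xq),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Principal-component projection of a feature matrix
#'
#' Mean-centred PCA used to visualize peptides in ACC space.
#'
#' @param X numeric matrix, rows = peptides
#' @param n_components components to return (at most \code{min(dim(X))})
#' @return list with \code{coordinates} (rows x n_components) and
#'   \code{explained_variance} (non-increasing fractions summing to at
#'   most 1)
#' @export
pcaProjection <- function(X, n_components = 2L) {
  stopifnot(is.matrix(X), nrow(X) >= 2L)
  if (n_components > min(dim(X)))
    stop("n_components exceeds min(dim(X)) = ", min(dim(X)))
  pc <- stats::prcomp(X, center = TRUE, scale. = FALSE)
  ev <- pc$sdev^2
  k <- seq_len(n_components)
  list(coordinates = pc$x[, k, drop = FALSE],
       explained_variance = (ev / sum(ev))[k],
       rotation = pc$rotation[, k, drop = FALSE],
       center = pc$center)
}
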