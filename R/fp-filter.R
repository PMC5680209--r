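#' Artifact features for candidate variant sites
#'
#' Computes the false-positive features used by the regression filter:
#' proximity to an indel, the number of other candidate mutations in a
#' small neighborhood, strand bias, and clustering of the variant base
#' position within supporting reads.
#'
#' Strand bias is the two-sided Fisher exact test on the 2x2 table
#' `[[ref_fwd, ref_rev], [alt_fwd, alt_rev]]`, reported as
#' `-log10(p)`. Read-position clustering is `1 - sd(offsets)/sd_uniform`
#' clipped to `[0, 1]`, where `sd_uniform` is the standard deviation of
#' a discrete uniform over the read; fewer than two offsets give 0 (a
#' single read carries no clustering evidence).
#'
#' @param sites pileup data.frame of candidate variants.
#' @param indel_positions optional data.frame (`chrom`, `pos`) of indel
#'   candidates.
#' @param candidate_positions optional data.frame (`chrom`, `pos`) of
#'   all candidate mutations; defaults to `sites` itself.
#' @param indel_window bp window for indel proximity (default 25).
#' @param neighbor_window bp window for neighborhood mutation count
#'   (default 50).
#' @param read_length read length used for the uniform-offset reference
#'   dispersion.
#' @return data.frame with columns `indel_proximity` (0/1 indicator),
#'   `neighborhood_mutation_count`, `strand_bias_score`,
#'   `read_position_clustering`.
#' @export
compute_fp_features <- function(sites, indel_positions = NULL,
                                candidate_positions = NULL,
                                indel_window = 25L, neighbor_window = 50L,
                                read_length = 100L) {
  n <- nrow(sites)
  if (is.null(candidate_positions))
    candidate_positions <- sites[, c("chrom", "pos")]
  near_count <- function(chrom, pos, tab, w, exclude_self = FALSE) {
    if (is.null(tab) || nrow(tab) == 0L) return(integer(length(pos)))
    vapply(seq_along(pos), function(i) {
      hit <- tab$chrom == chrom[i] & abs(tab$pos - pos[i]) <= w
      k <- sum(hit)
      if (exclude_self) k <- k - sum(hit & tab$pos == pos[i])
      as.integer(max(k, 0L))
    }, integer(1))
  }
  indel_prox <- as.integer(
    near_count(sites$chrom, sites$pos, indel_positions, indel_window) > 0L)
  neigh <- near_count(sites$chrom, sites$pos, candidate_positions,
                      neighbor_window, exclude_self = TRUE)
  sb <- vapply(seq_len(n), function(i) {
    tab <- matrix(c(sites$ref_fwd[i], sites$ref_rev[i],
                    sites$alt_fwd[i], sites$alt_rev[i]),
                  nrow = 2, byrow = TRUE)
    if (any(rowSums(tab) == 0L)) return(0)
    p <- stats::fisher.test(tab)$p.value
    max(0, -log10(min(p, 1)))
  }, numeric(1))
  sd_unif <- sqrt((read_length^2 - 1) / 12)
  clus <- vapply(seq_len(n), function(i) {
    o <- sites$alt_read_offsets[[i]]
    if (length(o) < 2L) return(0)
    min(1, max(0, 1 - stats::sd(o) / sd_unif))
  }, numeric(1))
  data.frame(indel_proximity = indel_prox,
             neighborhood_mutation_count = neigh,
             strand_bias_score = sb,
             read_position_clustering = clus)
}

.FP_FEATURES <- c("indel_proximity", "neighborhood_mutation_count",
                  "strand_bias_score", "read_position_clustering")

#' Train the logistic-regression artifact filter
#'
#' Fits a logistic regression of the artifact label on the four
#' false-positive features, reports a cross-validated AUC, and picks a
#' decision threshold on the ROC curve by the maximal Youden index.
#' Perfectly separable training data are flagged and refit with a small
#' ridge penalty so the weights stay finite.
#'
#' @param features data.frame holding the feature columns of
#'   [compute_fp_features()] plus a 0/1 `label` column (1 = artifact).
#' @param seed optional seed for the cross-validation folds.
#' @param nfolds folds for the cross-validated AUC.
#' @return object of class `lr_filter_model`: coefficients, decision
#'   `threshold`, `auc` (in-sample), `auc_cv`, ROC curve points, and a
#'   `regularized` flag.
#' @export
train_fp_filter <- function(features, seed = NULL, nfolds = 5L) {
  if (!is.null(seed)) set.seed(seed)
  stopifnot("label" %in% names(features),
            all(.FP_FEATURES %in% names(features)))
  y <- features$label
  if (length(unique(y)) < 2L)
    stop("both classes must be present in the training data")
  x <- features[, .FP_FEATURES]
  fml <- stats::as.formula(paste("label ~", paste(.FP_FEATURES, collapse = " + ")))
  fit_one <- function(dat) {
    sep <- FALSE
    fit <- withCallingHandlers(
      stats::glm(fml, data = dat, family = stats::binomial()),
      warning = function(w) {
        if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w)))
          sep <<- TRUE
        invokeRestart("muffleWarning")
      })
    if (sep || !fit$converged || any(abs(stats::coef(fit)[-1]) > 25,
                                     na.rm = TRUE)) {
      xm <- as.matrix(dat[, .FP_FEATURES])
      rf <- glmnet::glmnet(xm, dat$label, family = "binomial", alpha = 0,
                           lambda = 1e-3)
      co <- as.numeric(stats::coef(rf))
      names(co) <- c("(Intercept)", .FP_FEATURES)
      list(coef = co, regularized = TRUE,
        predict = function(newx)
          as.numeric(stats::predict(rf, as.matrix(newx[, .FP_FEATURES]),
                                    type = "response")))
    } else {
      list(coef = stats::coef(fit), regularized = FALSE,
        predict = function(newx)
          as.numeric(stats::predict(fit, newx, type = "response")))
    }
  }
  full <- fit_one(features)
  prob <- full$predict(features)
  roc <- pROC::roc(response = y, predictor = prob, quiet = TRUE,
                   direction = "<", levels = c(0, 1))
  best <- pROC::coords(roc, "best", best.method = "youden",
                       ret = c("threshold", "sensitivity", "specificity"),
                       transpose = FALSE)
  thr <- best$threshold[1]
  if (!is.finite(thr)) thr <- 0.5
  thr <- min(max(thr, 1e-6), 1 - 1e-6)
  # cross-validated AUC
  folds <- sample(rep_len(seq_len(nfolds), length(y)))
  cv_auc <- rep(NA_real_, nfolds)
  for (k in seq_len(nfolds)) {
    tr <- features[folds != k, ]
    te <- features[folds == k, ]
    if (length(unique(tr$label)) < 2L || length(unique(te$label)) < 2L) next
    fk <- fit_one(tr)
    pk <- fk$predict(te)
    cv_auc[k] <- as.numeric(pROC::auc(pROC::roc(
      response = te$label, predictor = pk, quiet = TRUE,
      direction = "<", levels = c(0, 1))))
  }
  structure(list(coef = full$coef, threshold = thr,
                 auc = as.numeric(pROC::auc(roc)),
                 auc_cv = mean(cv_auc, na.rm = TRUE),
                 roc = data.frame(fpr = 1 - roc$specificities,
                                  tpr = roc$sensitivities),
                 regularized = full$regularized,
                 predict_fun = full$predict),
            class = "lr_filter_model")
}

#' @method print lr_filter_model
#' @export
print.lr_filter_model <- function(x, ...) {
  cat("Logistic-regression artifact filter\n")
  cat(sprintf("  AUC %.3f (cv %.3f), threshold %.3f%s\n", x$auc, x$auc_cv,
              x$threshold, if (x$regularized) " [ridge-regularized]" else ""))
  print(round(x$coef, 4))
  invisible(x)
}

#' Artifact probabilities from a trained filter
#'
#' @param object an `lr_filter_model`.
#' @param newdata data.frame holding the feature columns.
#' @param ... unused.
#' @return numeric vector of artifact probabilities.
#' @export
predict.lr_filter_model <- function(object, newdata, ...) {
  object$predict_fun(newdata)
}
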