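#' Region-wise linear-model screen for cortical thinning
#'
#' The classical univariate baseline: for each region separately, ordinary
#' least squares of thickness on a group indicator plus age and sex within
#' the two groups of the contrast; regions with a negative group
#' coefficient and two-sided p < `alpha` are selected as thinning regions.
#'
#' @param ds A `thickness_dataset`.
#' @param contrast Character pair `c(target, reference)`, e.g.
#'   `c("LTLE", "HC")`; the indicator is 1 for the target group.
#' @param alpha Two-sided significance level (default 0.05).
#' @return A tibble: `region`, `hemisphere`, `estimate` (mm), `p_value`,
#'   `selected`.
#' @export
regionwise_glm <- function(ds, contrast, alpha = 0.05) {
  stopifnot(inherits(ds, "thickness_dataset"), length(contrast) == 2L)
  keep <- ds$cohort$group %in% contrast
  if (sum(ds$cohort$group == contrast[1]) == 0L ||
      sum(ds$cohort$group == contrast[2]) == 0L) {
    stop("both contrast groups must be present in the cohort")
  }
  cohort <- ds$cohort[keep, , drop = FALSE]
  Y <- ds$thickness[keep, , drop = FALSE]
  X <- cbind(1, as.numeric(cohort$group == contrast[1]),
             cohort$age - mean(cohort$age),
             as.numeric(cohort$sex == "M"))
  colnames(X) <- c("(Intercept)", "grp", "age", "sexM")
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) stop("singular design in region-wise regression")
  res <- purrr::map_dfr(seq_len(ncol(Y)), function(j) {
    y <- Y[, j]
    if (stats::sd(y) == 0) {
      stop("degenerate fit: zero-variance thickness at region ",
           colnames(Y)[j])
    }
    fit <- stats::lm.fit(X, y)
    rss <- sum(fit$residuals^2)
    dfr <- length(y) - ncol(X)
    XtXinv <- chol2inv(qr.R(qrX))
    se <- sqrt(rss / dfr * XtXinv[2, 2])
    est <- fit$coefficients["grp"]
    p <- 2 * stats::pt(abs(est / se), dfr, lower.tail = FALSE)
    tibble::tibble(region = colnames(Y)[j], estimate = unname(est),
                   p_value = p)
  })
  res$hemisphere <- ds$atlas$hemisphere[match(res$region, ds$atlas$region)]
  res$selected <- res$estimate < 0 & res$p_value < alpha
  dplyr::select(res, "region", "hemisphere", "estimate", "p_value",
                "selected")
}

#' Multilayer perceptron specification
#'
#' A small feed-forward network with one hidden layer of logistic-sigmoid
#' units and a linear output, the standard shallow classifier for
#' region-feature benchmarks.
#'
#' @param hidden Hidden units (`>= 1`, default 3).
#' @param max_epochs Training iteration cap (default 500).
#' @param seed Seed for weight initialization.
#' @param standardize Standardize features with training-fold statistics?
#' @return A list of class `mlp_spec`.
#' @export
mlp_spec <- function(hidden = 3L, max_epochs = 500L, seed = 1L,
                     standardize = TRUE) {
  if (hidden < 1L) stop("hidden units must be >= 1")
  structure(list(hidden = as.integer(hidden),
                 max_epochs = as.integer(max_epochs),
                 seed = as.integer(seed),
                 standardize = isTRUE(standardize)),
            class = "mlp_spec")
}

#' Leave-one-out MLP classification scores
#'
#' For each subject in turn, trains the perceptron on all other subjects
#' and records the held-out subject's continuous network output. Features
#' are standardized with training-fold statistics only, so no information
#' leaks into the held-out prediction. Deterministic given the seed in
#' `spec`.
#'
#' @param features Subjects x features numeric matrix (selected regions).
#' @param labels Binary vector (0/1 or logical), one per subject; both
#'   classes must appear at least twice.
#' @param spec An [mlp_spec()].
#' @return Numeric vector of held-out scores, one per subject.
#' @export
mlp_loocv_scores <- function(features, labels, spec = mlp_spec()) {
  stopifnot(inherits(spec, "mlp_spec"))
  features <- as.matrix(features)
  labels <- as.numeric(labels)
  if (!all(labels %in% c(0, 1))) stop("labels must be binary 0/1")
  if (min(table(labels)) < 2L) stop("need at least 2 subjects per class")
  m <- nrow(features)
  scores <- numeric(m)
  for (i in seq_len(m)) {
    xtr <- features[-i, , drop = FALSE]
    ytr <- labels[-i]
    if (length(unique(ytr)) < 2L) stop("single-class training fold at row ", i)
    if (spec$standardize) {
      mu <- colMeans(xtr)
      sg <- apply(xtr, 2, stats::sd)
      sg[sg == 0] <- 1
      xtr <- sweep(sweep(xtr, 2, mu), 2, sg, "/")
      xte <- (features[i, ] - mu) / sg
    } else {
      xte <- features[i, ]
    }
    net <- withr_seed(spec$seed + i, {
      nnet::nnet(xtr, ytr, size = spec$hidden, linout = TRUE,
                 maxit = spec$max_epochs, trace = FALSE, decay = 1e-3)
    })
    scores[i] <- as.numeric(stats::predict(net, matrix(xte, nrow = 1)))
  }
  scores
}

#' ROC curve and AUC
#'
#' The AUC is the Mann-Whitney probability that a random positive scores
#' above a random negative, ties counted one half; the curve is traced by
#' thresholding the scores.
#'
#' @param scores Numeric classifier scores, larger = more positive.
#' @param labels Binary labels (0/1 or logical), both classes present.
#' @return An object of class `roc_curve`: tibble of `(fpr, tpr)` points
#'   from (0,0) to (1,1) with attribute `auc`.
#' @examples
#' roc_auc(c(1, 2, 3, 4), c(0, 0, 1, 1))  # AUC 1
#' @export
roc_auc <- function(scores, labels) {
  labels <- as.numeric(labels)
  if (!all(labels %in% c(0, 1))) stop("labels must be binary 0/1")
  if (length(unique(labels)) < 2L) stop("both classes must be present")
  pos <- scores[labels == 1]; neg <- scores[labels == 0]
  cmp <- outer(pos, neg, ">") + 0.5 * outer(pos, neg, "==")
  auc <- mean(cmp)
  thr <- c(Inf, sort(unique(scores), decreasing = TRUE))
  pts <- purrr::map_dfr(thr, function(t) {
    tibble::tibble(fpr = mean(neg >= t), tpr = mean(pos >= t))
  })
  pts <- dplyr::distinct(pts)
  structure(pts, class = c("roc_curve", class(pts)), auc = auc)
}

#' @export
print.roc_curve <- function(x, ...) {
  cat("<roc_curve> AUC =", format(attr(x, "auc"), digits = 4), "\n")
  NextMethod()
}

#' @rdname roc_auc
#' @param x A `roc_curve`.
#' @param ... Unused.
#' @export
glance.roc_curve <- function(x, ...) {
  tibble::tibble(auc = attr(x, "auc"), n_points = nrow(x))
}

#' @rdname roc_auc
#' @param object A `roc_curve`.
#' @export
autoplot.roc_curve <- function(object, ...) {
  ggplot2::ggplot(tibble::as_tibble(object),
                  ggplot2::aes(x = .data$fpr, y = .data$tpr)) +
    ggplot2::geom_step() +
    ggplot2::geom_abline(linetype = "dotted", color = "grey60") +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "False positive rate", y = "True positive rate",
                  subtitle = sprintf("AUC = %.3f", attr(object, "auc"))) +
    ggplot2::theme_minimal()
}

#' Classification benchmark for a group contrast
#'
#' End-to-end comparison of region-selection strategies: build MLP
#' classifiers from (a) regions flagged by the Bayesian FDR map and (b)
#' regions selected by the region-wise linear screen, score both by
#' leave-one-out cross-validation and compare ROC/AUC.
#'
#' @param ds A `thickness_dataset`.
#' @param fit A `spectral_fit` of the same dataset.
#' @param contrast Character pair `c(target, reference)` naming groups; the
#'   target group's covariate surface supplies the Bayesian map.
#' @param q Bayesian FDR rate for region selection.
#' @param spec An [mlp_spec()].
#' @return A tibble with one row per method (`bayes`, `glm`): selected
#'   region count, AUC, and list-columns of regions, scores and the
#'   `roc_curve`.
#' @export
classification_benchmark <- function(ds, fit, contrast = c("LTLE", "HC"),
                                     q = 0.01, spec = mlp_spec()) {
  fdr <- fdr_map(fit, contrast[1], q = q)
  bayes_regions <- fdr$region[fdr$rejected]
  glm_tab <- regionwise_glm(ds, contrast)
  glm_regions <- glm_tab$region[glm_tab$selected]
  keep <- ds$cohort$group %in% contrast
  labels <- as.numeric(ds$cohort$group[keep] == contrast[1])
  one <- function(method, regions) {
    if (length(regions) == 0L) {
      return(tibble::tibble(method = method, n_regions = 0L,
                            auc = NA_real_, regions = list(character()),
                            scores = list(numeric()), roc = list(NULL)))
    }
    feats <- ds$thickness[keep, regions, drop = FALSE]
    scores <- mlp_loocv_scores(feats, labels, spec)
    roc <- roc_auc(scores, labels)
    tibble::tibble(method = method, n_regions = length(regions),
                   auc = attr(roc, "auc"), regions = list(regions),
                   scores = list(scores), roc = list(roc))
  }
  dplyr::bind_rows(one("bayes", bayes_regions), one("glm", glm_regions))
}
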