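# L1 (LASSO) and L2 (Ridge) penalized linear models of cleavage efficiency.
#
# Objective convention (the per-sample scale used by glmnet and by the
# common Python solvers):
#
#   (1/(2n)) * sum_i (y_i - alpha - beta . z_i)^2 + lambda * P(beta)
#
# with P(beta) = |beta|_1 for L1 and |beta|_2^2 / 2 for L2; the intercept is
# unpenalized and features are z-scored on training statistics, so
# coefficients are comparable across categories. Under this convention the
# L2 solution equals the closed form (Z'Z + n*lambda*I)^{-1} Z'y on the
# centered standardized design (i.e. lambda' = n * lambda).
#
# L1 fits are delegated to glmnet (coordinate descent, convergence
# threshold 1e-12); L2 fits use an in-package SVD of the standardized
# design, which reaches the closed form to machine precision.

#' Model configuration
#'
#' @param penalty `"l1"` (LASSO) or `"l2"` (Ridge).
#' @param lambda_grid Penalty grid, default log-spaced over 1e-10..1e-1.
#' @param cv_folds Cross-validation folds (default 10).
#' @param seed Seed for fold assignment.
#' @param features `"all"` or `"sequence_only"` (drops structure and
#'   occupancy features before fitting).
#' @param transform Objective transform: `"log10"` (default; CS_site is a
#'   heavy-tailed ratio of counts) or `"raw"`.
#' @param standardize Z-score features on training statistics (default
#'   TRUE).
#' @return A `cf_model_config` list.
#' @export
model_config <- function(penalty = c("l1", "l2"),
                         lambda_grid = 10^seq(-10, -1, by = 0.5),
                         cv_folds = 10, seed = 1,
                         features = c("all", "sequence_only"),
                         transform = c("log10", "raw"),
                         standardize = TRUE) {
  penalty <- match.arg(penalty)
  features <- match.arg(features)
  transform <- match.arg(transform)
  stopifnot(all(lambda_grid >= 0), cv_folds >= 2)
  structure(list(penalty = penalty,
                 lambda_grid = sort(unique(lambda_grid)),
                 cv_folds = as.integer(cv_folds), seed = as.integer(seed),
                 features = features, transform = transform,
                 standardize = isTRUE(standardize)),
            class = "cf_model_config")
}

transform_y <- function(y, transform) {
  if (transform == "log10") log10(y) else y
}

#' Drop structure and occupancy columns (sequence-only mode)
#' @param fm A `cf_feature_matrix`.
#' @return The `cf_feature_matrix` restricted to sequence categories.
#' @export
sequence_only <- function(fm) {
  subset_features(fm, fm$specs$category %in%
                    c("nucleotide", "codon", "amino_acid"))
}

select_rows <- function(fm, rows) {
  if (identical(rows, "all")) return(rep(TRUE, nrow(fm$sites)))
  sel <- fm$sites$split == rows
  if (!any(sel)) stop("no rows with split label '", rows, "'")
  sel
}

standardize_train <- function(X, standardize) {
  center <- colMeans(X)
  scl <- apply(X, 2, sd)
  const <- !is.finite(scl) | scl == 0
  scl[const] <- 1
  if (!standardize) {
    center[] <- 0
    scl[] <- 1
  }
  Z <- sweep(sweep(X, 2, center, "-"), 2, scl, "/")
  list(Z = Z, center = center, scale = scl, constant = const)
}

solve_l2_svd <- function(Z, y, lambda) {
  n <- nrow(Z)
  yc <- y - mean(y)
  Zc <- sweep(Z, 2, colMeans(Z), "-")
  sv <- svd(Zc)
  d <- sv$d
  shrink <- d / (d^2 + n * lambda)
  beta <- sv$v %*% (shrink * crossprod(sv$u, yc))
  as.numeric(beta)
}

solve_l1_glmnet <- function(Z, y, lambda) {
  p <- ncol(Z)
  padded <- p == 1L
  if (padded) Z <- cbind(Z, 0)
  # glmnet wants a decreasing path; warm-start into the target lambda
  path <- sort(unique(c(lambda, if (lambda > 0) lambda * c(100, 10, 3)
                        else c(0.1, 0.01, 0.001))), decreasing = TRUE)
  fit <- glmnet::glmnet(Z, y, alpha = 1, lambda = path,
                        standardize = FALSE, intercept = TRUE,
                        thresh = 1e-12, maxit = 1e7)
  # suppressWarnings: glmnet's lambda interpolation warns harmlessly when
  # refitting at an exact s already on the path
  cf <- as.numeric(suppressWarnings(
    coef(fit, s = lambda, exact = TRUE, x = Z, y = y,
         thresh = 1e-12, maxit = 1e7)))
  if (anyNA(cf)) stop("fit_penalized: glmnet did not converge")
  beta <- cf[-1]
  if (padded) beta <- beta[1]
  list(intercept = cf[1], beta = beta)
}

#' Fit a penalized linear model of cleavage efficiency
#'
#' Minimizes `(1/(2n)) RSS + lambda * P(beta)` over the selected rows of
#' the feature matrix, with P the L1 or L2 penalty, the intercept
#' unpenalized, and features z-scored on the training statistics. At
#' `lambda = 0` either penalty reduces to ordinary least squares.
#'
#' @param fm A `cf_feature_matrix`.
#' @param config A `cf_model_config`.
#' @param lambda Penalty strength (>= 0).
#' @param rows Which rows to fit on: `"train"` (default) or `"all"`.
#' @return A `cf_model`: intercept, named coefficient vector `beta` (on the
#'   standardized scale), `lambda`, `penalty`, training centers/scales, the
#'   objective transform and training metadata.
#' @export
fit_penalized <- function(fm, config = model_config(), lambda,
                          rows = "train") {
  stopifnot(inherits(fm, "cf_feature_matrix"), lambda >= 0)
  if (config$features == "sequence_only") fm <- sequence_only(fm)
  sel <- select_rows(fm, rows)
  X <- fm$X[sel, , drop = FALSE]
  y <- transform_y(fm$sites$y[sel], config$transform)
  if (!all(is.finite(X)) || !all(is.finite(y))) {
    stop("fit_penalized: non-finite values in design or objective")
  }
  st <- standardize_train(X, config$standardize)
  if (config$penalty == "l2") {
    beta <- solve_l2_svd(st$Z, y, lambda)
    intercept <- mean(y) - sum(beta * colMeans(st$Z))
  } else {
    sol <- solve_l1_glmnet(st$Z, y, lambda)
    beta <- sol$beta
    intercept <- sol$intercept
  }
  beta[st$constant] <- 0
  structure(list(
    intercept = intercept, beta = setNames(beta, fm$specs$name),
    lambda = lambda, penalty = config$penalty,
    center = setNames(st$center, fm$specs$name),
    scale = setNames(st$scale, fm$specs$name),
    transform = config$transform, n_train = nrow(X),
    config = config), class = "cf_model")
}

#' @export
print.cf_model <- function(x, ...) {
  cat(sprintf("<cf_model %s: lambda=%g, %d/%d nonzero, n_train=%d>\n",
              toupper(x$penalty), x$lambda, sum(x$beta != 0),
              length(x$beta), x$n_train))
  invisible(x)
}

#' Predict on a feature matrix
#' @param object A `cf_model`.
#' @param fm A `cf_feature_matrix` with matching feature columns.
#' @param rows `"all"`, `"train"` or `"test"`.
#' @param ... Unused.
#' @return Numeric vector of predictions on the transform scale.
#' @export
predict.cf_model <- function(object, fm, rows = "all", ...) {
  stopifnot(inherits(fm, "cf_feature_matrix"))
  idx <- match(names(object$beta), fm$specs$name)
  if (anyNA(idx)) stop("predict: feature columns do not match the model")
  sel <- select_rows(fm, rows)
  X <- fm$X[sel, idx, drop = FALSE]
  Z <- sweep(sweep(X, 2, object$center, "-"), 2, object$scale, "/")
  as.numeric(object$intercept + Z %*% object$beta)
}

#' Cross-validation over the penalty grid
#'
#' Ten-fold (by default) cross-validation with folds assigned at the gene
#' level (all sites of a gene share a fold, consistent with the gene-level
#' train/test split). For each lambda in the grid the mean held-out MSE
#' over folds is reported together with the nonzero-coefficient count of
#' the full-train fit. Degenerate folds (constant objective or fewer than
#' two rows) are skipped with a log message.
#'
#' @param fm A `cf_feature_matrix` with a train split.
#' @param config A `cf_model_config`.
#' @return data.frame (`cf_cv_table`) with columns lambda, mse, nonzero.
#' @export
cv_lambda <- function(fm, config = model_config()) {
  stopifnot(inherits(fm, "cf_feature_matrix"))
  if (config$features == "sequence_only") fm <- sequence_only(fm)
  sel <- select_rows(fm, if (any(fm$sites$split == "train")) "train"
                     else "all")
  X <- fm$X[sel, , drop = FALSE]
  y <- transform_y(fm$sites$y[sel], config$transform)
  gene <- fm$sites$gene[sel]
  if (nrow(X) < 2 * config$cv_folds) stop("cv_lambda: too few rows")
  genes <- sort(unique(gene))
  set.seed(config$seed)
  fold_of_gene <- setNames(sample(rep(seq_len(config$cv_folds),
                                      length.out = length(genes))), genes)
  fold <- fold_of_gene[gene]
  grid <- sort(config$lambda_grid, decreasing = TRUE)
  mse <- matrix(NA_real_, config$cv_folds, length(grid))
  for (f in seq_len(config$cv_folds)) {
    tr <- fold != f
    if (sum(!tr) < 1 || sum(tr) < 2 || sd(y[tr]) == 0) {
      cf_log("cv_lambda: skipping degenerate fold %d", f)
      next
    }
    st <- standardize_train(X[tr, , drop = FALSE], config$standardize)
    Zte <- sweep(sweep(X[!tr, , drop = FALSE], 2, st$center, "-"),
                 2, st$scale, "/")
    if (config$penalty == "l1") {
      Ztr <- st$Z
      padded <- ncol(Ztr) == 1L
      if (padded) { Ztr <- cbind(Ztr, 0); Zte <- cbind(Zte, 0) }
      fit <- glmnet::glmnet(Ztr, y[tr], alpha = 1, lambda = grid,
                            standardize = FALSE, intercept = TRUE,
                            thresh = 1e-10, maxit = 1e7)
      pred <- suppressWarnings(predict(fit, newx = Zte, s = grid))
      mse[f, ] <- colMeans((pred - y[!tr])^2)
    } else {
      for (li in seq_along(grid)) {
        beta <- solve_l2_svd(st$Z, y[tr], grid[li])
        a <- mean(y[tr]) - sum(beta * colMeans(st$Z))
        pred <- a + Zte %*% beta
        mse[f, li] <- mean((pred - y[!tr])^2)
      }
    }
  }
  mean_mse <- colMeans(mse, na.rm = TRUE)
  # nonzero counts of the full-train fit at each lambda
  full <- lapply(grid, function(l) fit_penalized(fm, config, l,
                                                 rows = if (any(fm$sites$split == "train")) "train" else "all"))
  nonzero <- vapply(full, function(m) sum(m$beta != 0), 0L)
  out <- data.frame(lambda = grid, mse = mean_mse, nonzero = nonzero)
  out <- out[order(out$lambda), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "fold_of_gene") <- fold_of_gene
  class(out) <- c("cf_cv_table", "data.frame")
  out
}

#' Choose the penalty strength from a CV table
#'
#' The largest lambda whose mean CV MSE stays within `(1 + tolerance)` of
#' the minimum — i.e. the sparsest model that maintains MSE. A fixed
#' `override` (e.g. the published 0.01) bypasses selection.
#'
#' @param cv_table Output of [cv_lambda()].
#' @param tolerance Relative MSE slack (default 0.05).
#' @param override Optional fixed lambda.
#' @return The selected lambda.
#' @export
select_lambda <- function(cv_table, tolerance = 0.05, override = NULL) {
  if (!is.null(override)) return(override)
  stopifnot(nrow(cv_table) >= 1)
  ok <- cv_table$mse <= (1 + tolerance) * min(cv_table$mse, na.rm = TRUE)
  max(cv_table$lambda[ok], na.rm = TRUE)
}

#' Evaluate a fitted model on held-out sites
#'
#' @param model A `cf_model`.
#' @param fm A `cf_feature_matrix`.
#' @param rows Rows to evaluate on (default `"test"`).
#' @return List (`cf_eval`) with `mse`, Pearson `r` between predicted and
#'   measured objective (0 with `constant_prediction = TRUE` when the
#'   prediction has no variance), and `n`.
#' @export
predict_and_evaluate <- function(model, fm, rows = "test") {
  sel <- select_rows(fm, rows)
  yhat <- predict(model, fm, rows = rows)
  y <- transform_y(fm$sites$y[sel], model$transform)
  constant <- sd(yhat) == 0 || sd(y) == 0
  r <- if (constant) 0 else cor(yhat, y)
  structure(list(mse = mean((yhat - y)^2), r = r, n = length(y),
                 constant_prediction = constant), class = "cf_eval")
}

#' @export
print.cf_eval <- function(x, ...) {
  cat(sprintf("<cf_eval: n=%d, MSE=%.4g, Pearson r=%.3f%s>\n", x$n, x$mse,
              x$r, if (x$constant_prediction) " (constant prediction)"
              else ""))
  invisible(x)
}

#' Signed coefficient report
#'
#' Nonzero coefficients are split into positive and negative groups;
#' within each group, coefficients are summed per scope (around-site vs
#' whole-RNA) and per category, with each sum's proportion of the group
#' total, plus a top-k table by coefficient magnitude.
#'
#' @param model A `cf_model`.
#' @param specs Feature metadata (the `specs` of the feature matrix the
#'   model was fit on).
#' @param top_k Rows of the top-coefficient tables (default 5).
#' @return A `cf_coef_report`: list with `positive` and `negative`, each
#'   holding `total`, `by_scope`, `by_category` and `top`.
#' @export
coefficient_report <- function(model, specs, top_k = 5) {
  stopifnot(inherits(model, "cf_model"))
  i <- match(names(model$beta), specs$name)
  if (anyNA(i)) stop("coefficient_report: specs do not cover the model")
  d <- cbind(specs[i, , drop = FALSE],
             beta = unname(model$beta))
  d <- d[d$beta != 0, , drop = FALSE]
  group <- function(dd) {
    if (!nrow(dd)) return(list(total = 0, by_scope = NULL,
                               by_category = NULL, top = dd))
    total <- sum(dd$beta)
    agg <- function(key) {
      s <- tapply(dd$beta, dd[[key]], sum)
      data.frame(level = names(s), sum = as.numeric(s),
                 proportion = as.numeric(s) / total, row.names = NULL)
    }
    list(total = total, by_scope = agg("scope"),
         by_category = agg("category"),
         top = head(dd[order(-abs(dd$beta)), , drop = FALSE], top_k))
  }
  structure(list(positive = group(d[d$beta > 0, , drop = FALSE]),
                 negative = group(d[d$beta < 0, , drop = FALSE])),
            class = "cf_coef_report")
}

#' @export
print.cf_coef_report <- function(x, ...) {
  for (s in c("positive", "negative")) {
    g <- x[[s]]
    cat(sprintf("%s group: total %.4g\n", s, g$total))
    if (!is.null(g$by_scope)) {
      for (i in seq_len(nrow(g$by_scope))) {
        cat(sprintf("  %-12s %.4g (%.1f%%)\n", g$by_scope$level[i],
                    g$by_scope$sum[i], 100 * g$by_scope$proportion[i]))
      }
    }
  }
  invisible(x)
}

#' Write a coefficient report to TSV
#' @param report A `cf_coef_report`.
#' @param path Output path.
#' @export
write_coefficient_report <- function(report, path) {
  rows <- list()
  for (s in c("positive", "negative")) {
    g <- report[[s]]
    if (is.null(g$by_scope)) next
    rows[[s]] <- data.frame(group = s,
                            table = "by_scope", level = g$by_scope$level,
                            sum = g$by_scope$sum,
                            proportion = g$by_scope$proportion)
    rows[[paste0(s, "_cat")]] <- data.frame(group = s,
                                            table = "by_category",
                                            level = g$by_category$level,
                                            sum = g$by_category$sum,
                                            proportion = g$by_category$proportion)
  }
  d <- if (length(rows)) do.call(rbind, rows) else
    data.frame(group = character(), table = character(),
               level = character(), sum = numeric(),
               proportion = numeric())
  write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
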