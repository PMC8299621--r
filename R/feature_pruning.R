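# Rank-correlation pruning of the feature space: drop features uncorrelated
# with the objective, then greedily collapse multi-collinear groups.
#
# Both thresholds are interpreted on |Spearman rho|: the published negative
# predictors rule out signed filtering, and Spearman's invariance to
# monotone transforms means the raw CS_site can be used as the target even
# when the model is fit on log10 CS_site.

#' Spearman correlation of every feature with the objective
#'
#' Computed on training rows only (when split labels exist) to avoid test
#' leakage. Ties are handled by average ranks (the `cor` default).
#' Constant columns get correlation 0 and are flagged.
#'
#' @param fm A `cf_feature_matrix`.
#' @param rows `"train"` (default; falls back to all rows when no split
#'   labels are present) or `"all"`.
#' @return Named numeric vector of correlations, with attribute
#'   `constant` (logical vector).
#' @export
target_correlations <- function(fm, rows = c("train", "all")) {
  stopifnot(inherits(fm, "cf_feature_matrix"))
  rows <- match.arg(rows)
  sel <- if (rows == "train" && any(fm$sites$split == "train")) {
    fm$sites$split == "train"
  } else rep(TRUE, nrow(fm$sites))
  if (sum(sel) < 3) stop("target_correlations: fewer than 3 rows")
  X <- fm$X[sel, , drop = FALSE]
  y <- fm$sites$y[sel]
  r <- suppressWarnings(as.numeric(cor(X, y, method = "spearman")))
  const <- is.na(r)
  r[const] <- 0
  structure(setNames(r, fm$specs$name), constant = const)
}

#' Drop features uncorrelated with the objective
#'
#' Keeps features with `|rho| >= threshold` (so a feature at exactly the
#' threshold is kept, and strong negative predictors are kept).
#'
#' @param fm A `cf_feature_matrix`.
#' @param correlations Output of [target_correlations()].
#' @param threshold Default 0.1.
#' @return The filtered `cf_feature_matrix`.
#' @export
drop_uncorrelated <- function(fm, correlations, threshold = 0.1) {
  stopifnot(inherits(fm, "cf_feature_matrix"))
  subset_features(fm, abs(correlations) >= threshold)
}

#' Greedy decorrelation of the feature space
#'
#' Features are visited in order of decreasing `|target correlation|`
#' (ties broken by column order); a feature is accepted iff its pairwise
#' Spearman correlation with every already-accepted feature stays below
#' `pair_threshold`. This realizes the rule "when two features correlate at
#' >= 0.6, keep the one more correlated with the objective".
#'
#' @param fm A `cf_feature_matrix`.
#' @param correlations Target correlations for the (current) columns.
#' @param pair_threshold Default 0.6 on `|Spearman|`.
#' @param rows Rows used for pairwise correlations ("train" or "all").
#' @return List with `matrix` (pruned `cf_feature_matrix`) and `report`
#'   (per-feature data.frame: name, target_cor, kept, reason).
#' @export
decorrelate <- function(fm, correlations, pair_threshold = 0.6,
                        rows = c("train", "all")) {
  stopifnot(inherits(fm, "cf_feature_matrix"),
            length(correlations) == ncol(fm$X))
  rows <- match.arg(rows)
  sel <- if (rows == "train" && any(fm$sites$split == "train")) {
    fm$sites$split == "train"
  } else rep(TRUE, nrow(fm$sites))
  X <- fm$X[sel, , drop = FALSE]
  p <- ncol(X)
  # standardized ranks: pairwise Spearman becomes a cross product
  Rk <- apply(X, 2, rank)
  Rk <- scale(Rk)
  Rk[, is.na(colSums(Rk))] <- 0  # constant columns
  ord <- order(-abs(correlations), seq_len(p))
  kept <- logical(p)
  blocker <- rep(NA_character_, p)
  for (j in ord) {
    acc <- which(kept)
    if (length(acc)) {
      rho <- abs(crossprod(Rk[, acc, drop = FALSE], Rk[, j])) /
        (sum(sel) - 1)
      hit <- which(rho >= pair_threshold)
      if (length(hit)) {
        blocker[j] <- fm$specs$name[acc[hit[1]]]
        next
      }
    }
    kept[j] <- TRUE
  }
  report <- data.frame(
    name = fm$specs$name,
    target_cor = as.numeric(correlations),
    kept = kept,
    reason = ifelse(kept, "",
                    paste0("pairwise>=", pair_threshold, " with ",
                           blocker)),
    stringsAsFactors = FALSE)
  list(matrix = subset_features(fm, kept), report = report)
}

#' Full pruning pass (target filter then decorrelation)
#'
#' @param fm A `cf_feature_matrix`.
#' @param target_threshold `|rho|` threshold against the objective
#'   (default 0.1).
#' @param pair_threshold Pairwise `|rho|` threshold (default 0.6).
#' @param rows Rows used for all correlations.
#' @return List with `matrix` and `report` (a `cf_prune_report`: counts at
#'   each stage plus the per-feature table).
#' @export
prune_features <- function(fm, target_threshold = 0.1,
                           pair_threshold = 0.6,
                           rows = c("train", "all")) {
  rows <- match.arg(rows)
  r <- target_correlations(fm, rows)
  fm1 <- drop_uncorrelated(fm, r, target_threshold)
  n_input <- ncol(fm$X)
  n_target <- ncol(fm1$X)
  r1 <- r[abs(r) >= target_threshold]
  dec <- decorrelate(fm1, r1, pair_threshold, rows)
  per_feature <- data.frame(
    name = fm$specs$name, target_cor = as.numeric(r),
    kept = fm$specs$name %in% dec$matrix$specs$name,
    reason = "", stringsAsFactors = FALSE)
  below <- abs(r) < target_threshold
  per_feature$reason[below] <- paste0("|target_cor|<", target_threshold)
  i <- match(dec$report$name, per_feature$name)
  per_feature$reason[i[!dec$report$kept]] <-
    dec$report$reason[!dec$report$kept]
  report <- structure(list(
    n_input = n_input, n_after_target_filter = n_target,
    n_after_decorrelation = ncol(dec$matrix$X),
    per_feature = per_feature), class = "cf_prune_report")
  list(matrix = dec$matrix, report = report)
}

#' @export
print.cf_prune_report <- function(x, ...) {
  cat(sprintf(
    "<cf_prune_report: %d -> %d (target filter) -> %d (decorrelation)>\n",
    x$n_input, x$n_after_target_filter, x$n_after_decorrelation))
  invisible(x)
}

#' Write a prune report to TSV
#' @param report A `cf_prune_report`.
#' @param path Output path.
#' @export
write_prune_report <- function(report, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# n_input=%d n_after_target_filter=%d n_after_decorrelation=%d",
                     report$n_input, report$n_after_target_filter,
                     report$n_after_decorrelation), con)
  write.table(report$per_feature, con, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}
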