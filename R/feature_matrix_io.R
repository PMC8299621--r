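# Persistence for feature matrices (TSV with a commented metadata header)
# and fitted-model reports (JSON).

FEATURE_CATEGORIES <- c("nucleotide", "codon", "amino_acid", "structure",
                        "occupancy")
FEATURE_SCOPES <- c("around_site", "whole_rna")

#' Assemble a feature matrix object
#'
#' Rows are cleavage sites, columns are features; `specs` carries one row of
#' metadata per column (name, category, scope, region, block, window
#' offsets, token).
#'
#' @param sites data.frame with columns `gene`, `position`, `y`, `split`.
#' @param X Numeric matrix, `nrow(sites)` x `nrow(specs)`.
#' @param specs data.frame of feature metadata.
#' @return A `cf_feature_matrix`.
#' @export
feature_matrix <- function(sites, X, specs) {
  stopifnot(is.data.frame(sites), is.matrix(X), is.data.frame(specs),
            nrow(X) == nrow(sites), ncol(X) == nrow(specs))
  if (anyNA(X)) stop("feature matrix contains missing values")
  if (!all(specs$category %in% FEATURE_CATEGORIES)) {
    stop("unknown feature category: ",
         paste(setdiff(specs$category, FEATURE_CATEGORIES), collapse = ","))
  }
  colnames(X) <- specs$name
  structure(list(sites = sites, X = X, specs = specs),
            class = "cf_feature_matrix")
}

#' @export
print.cf_feature_matrix <- function(x, ...) {
  cat(sprintf("<cf_feature_matrix: %d sites x %d features>\n",
              nrow(x$sites), ncol(x$X)))
  invisible(x)
}

#' Subset the columns of a feature matrix
#' @param fm A `cf_feature_matrix`.
#' @param keep Logical or integer index over columns.
#' @return The subsetted `cf_feature_matrix`.
#' @export
subset_features <- function(fm, keep) {
  stopifnot(inherits(fm, "cf_feature_matrix"))
  feature_matrix(fm$sites, fm$X[, keep, drop = FALSE],
                 fm$specs[keep, , drop = FALSE])
}

#' Write a feature matrix to TSV
#'
#' The file starts with one `#%` metadata line per feature
#' (name/category/scope/region/block/offset_start/offset_end/token), then a
#' TSV table with site columns (gene, position, y, split) followed by one
#' column per feature. Values are written with full precision so a
#' write/read round trip is lossless to < 1e-9.
#'
#' @param fm A `cf_feature_matrix`.
#' @param path Output path.
#' @export
write_feature_matrix <- function(fm, path) {
  stopifnot(inherits(fm, "cf_feature_matrix"))
  s <- fm$specs
  meta <- sprintf("#%%\t%s\t%s\t%s\t%s\t%s\t%s\t%s\t%s",
                  s$name, s$category, s$scope, s$region, s$block,
                  s$offset_start, s$offset_end, s$token)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(meta, con)
  d <- cbind(fm$sites[, c("gene", "position", "y", "split")],
             as.data.frame(fm$X, check.names = FALSE))
  # full-precision numeric formatting for lossless round trip
  for (j in seq_along(d)) {
    if (is.numeric(d[[j]])) d[[j]] <- format(d[[j]], digits = 17,
                                             trim = TRUE, scientific = TRUE)
  }
  write.table(d, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a feature matrix written by [write_feature_matrix()]
#' @param path Path to the TSV.
#' @return A `cf_feature_matrix`.
#' @export
read_feature_matrix <- function(path) {
  if (!file.exists(path)) stop("feature matrix not found: ", path)
  lines <- readLines(path)
  is_meta <- startsWith(lines, "#%")
  meta <- lines[is_meta]
  if (!length(meta) && !length(lines)) stop("empty feature matrix file")
  parse_meta <- function(x) strsplit(x, "\t", fixed = TRUE)[[1]][-1]
  mm <- do.call(rbind, lapply(meta, parse_meta))
  specs <- if (is.null(mm)) empty_specs() else data.frame(
    name = mm[, 1], category = mm[, 2], scope = mm[, 3], region = mm[, 4],
    block = mm[, 5], offset_start = as.integer(mm[, 6]),
    offset_end = as.integer(mm[, 7]), token = mm[, 8],
    stringsAsFactors = FALSE
  )
  if (!all(specs$category %in% FEATURE_CATEGORIES)) {
    stop("unknown feature category tag in ", path)
  }
  body <- lines[!is_meta]
  d <- read.delim(text = paste(body, collapse = "\n"),
                  stringsAsFactors = FALSE, check.names = FALSE)
  need <- c("gene", "position", "y", "split")
  if (!all(need %in% names(d))) stop("feature matrix header mismatch")
  extra <- setdiff(names(d), need)
  if (!identical(extra, specs$name)) {
    stop("feature matrix columns do not match metadata header")
  }
  X <- as.matrix(d[, extra, drop = FALSE])
  if (nrow(d) == 0L) X <- matrix(numeric(), 0L, nrow(specs))
  storage.mode(X) <- "double"
  sites <- d[, need, drop = FALSE]
  sites$gene <- as.character(sites$gene)
  sites$split <- as.character(sites$split)
  feature_matrix(sites, X, specs)
}

empty_specs <- function() {
  data.frame(name = character(), category = character(), scope = character(),
             region = character(), block = character(),
             offset_start = integer(), offset_end = integer(),
             token = character(), stringsAsFactors = FALSE)
}

#' Write a machine-readable model report
#'
#' The JSON report records the penalty, lambda, intercept, the nonzero
#' coefficients sorted by decreasing value, evaluation metrics, and the full
#' model payload (feature names, centers, scales) needed to re-apply the
#' model to new transcripts.
#'
#' @param model A fitted `cf_model` (see [fit_penalized()]).
#' @param eval An evaluation list from [predict_and_evaluate()], or NULL.
#' @param path Output path.
#' @export
write_model_report <- function(model, eval = NULL, path) {
  if (!inherits(model, "cf_model") || is.null(model$intercept)) {
    stop("write_model_report: model is not a fitted cf_model")
  }
  nz <- model$beta[model$beta != 0]
  nz <- nz[order(nz, decreasing = TRUE)]
  report <- list(
    penalty = model$penalty,
    lambda = model$lambda,
    intercept = model$intercept,
    transform = model$transform,
    n_train = model$n_train,
    coefficients = if (length(nz)) {
      list(name = names(nz), value = unname(nz))
    } else list(name = character(), value = numeric()),
    evaluation = eval,
    model = list(feature_names = names(model$beta),
                 beta = unname(model$beta),
                 center = unname(model$center),
                 scale = unname(model$scale))
  )
  jsonlite::write_json(report, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' Read a model report back into a fitted model object
#' @param path Path to a JSON report written by [write_model_report()].
#' @return A list with elements `model` (a `cf_model`) and `report` (the raw
#'   parsed JSON).
#' @export
read_model_report <- function(path) {
  r <- jsonlite::read_json(path, simplifyVector = TRUE)
  beta <- setNames(as.numeric(r$model$beta), r$model$feature_names)
  model <- structure(list(
    intercept = r$intercept, beta = beta, lambda = r$lambda,
    penalty = r$penalty, transform = r$transform,
    center = setNames(as.numeric(r$model$center), r$model$feature_names),
    scale = setNames(as.numeric(r$model$scale), r$model$feature_names),
    n_train = r$n_train
  ), class = "cf_model")
  list(model = model, report = r)
}
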