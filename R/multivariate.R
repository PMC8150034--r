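#' Assemble a specimen-by-variable feature table
#'
#' Joins per-specimen metric CSVs (or data.frames) on a shared
#' `specimen` column and attaches locomotor group labels. Columns with
#' more than 50% missing values are dropped with a warning; remaining
#' missing cells are mean-imputed within column and flagged in the
#' imputation mask.
#'
#' @param metric_tables list of data.frames or CSV paths, each with a
#'   `specimen` column.
#' @param groups named character vector or data.frame
#'   (`specimen`, `group`) with values in `aquatic`, `semi-aquatic`,
#'   `terrestrial`, `fossil`.
#' @return a `feature_table`: `data` (numeric columns), `group`,
#'   `specimen`, `imputed` (logical mask).
#' @export
assemble_features <- function(metric_tables, groups) {
  tabs <- lapply(metric_tables, function(t) {
    if (is.character(t)) t <- read.csv(t, check.names = FALSE)
    stopifnot("specimen" %in% names(t))
    t
  })
  merged <- Reduce(function(a, b) merge(a, b, by = "specimen", all = FALSE),
                   tabs)
  if (anyDuplicated(merged$specimen))
    stop("duplicate specimen identifiers", call. = FALSE)
  if (is.data.frame(groups))
    groups <- setNames(as.character(groups$group), groups$specimen)
  vocab <- c("aquatic", "semi-aquatic", "terrestrial", "fossil")
  grp <- unname(groups[merged$specimen])
  if (any(is.na(grp)) || !all(grp %in% vocab))
    stop("every specimen needs a group label from the fixed vocabulary",
         call. = FALSE)
  num <- merged[, vapply(merged, is.numeric, logical(1)), drop = FALSE]
  frac_na <- vapply(num, function(x) mean(is.na(x)), numeric(1))
  drop <- names(num)[frac_na > 0.5]
  if (length(drop)) {
    warning(sprintf("dropping column(s) with >50%% missing: %s",
                    paste(drop, collapse = ", ")), call. = FALSE)
    num <- num[, setdiff(names(num), drop), drop = FALSE]
  }
  imputed <- as.data.frame(lapply(num, is.na))
  for (j in names(num)) {
    if (anyNA(num[[j]])) num[[j]][is.na(num[[j]])] <- mean(num[[j]], na.rm = TRUE)
  }
  structure(list(data = num, group = grp, specimen = merged$specimen,
                 imputed = as.matrix(imputed)),
            class = "feature_table")
}

#' Correlation-matrix principal component analysis
#'
#' Columns are z-scored (so the decomposition is of the correlation
#' matrix); zero-variance columns are dropped with a warning.
#' Eigenvalues therefore sum to the number of retained variables.
#' Component signs are fixed so the largest-magnitude loading of each
#' component is positive.
#'
#' @param table a `feature_table` (or plain numeric data.frame).
#' @return a `pca_result`: `loadings` (variables x components,
#'   orthonormal), `scores` (specimens x components),
#'   `explained_variance` (fractions summing to 1), `eigenvalues`,
#'   `group`.
#' @export
pca_correlation <- function(table) {
  x <- if (inherits(table, "feature_table")) table$data else table
  grp <- if (inherits(table, "feature_table")) table$group else NULL
  x <- as.data.frame(x)
  v <- vapply(x, function(c) var(c), numeric(1))
  if (any(v == 0 | !is.finite(v))) {
    bad <- names(x)[v == 0 | !is.finite(v)]
    warning(sprintf("dropping zero-variance column(s): %s",
                    paste(bad, collapse = ", ")), call. = FALSE)
    x <- x[, setdiff(names(x), bad), drop = FALSE]
  }
  if (ncol(x) < 2L || nrow(x) < 2L)
    stop("PCA needs at least 2 specimens and 2 variables", call. = FALSE)
  z <- scale(as.matrix(x))
  cm <- cor(as.matrix(x))
  eg <- eigen(cm, symmetric = TRUE)
  load <- eg$vectors
  # sign convention: largest |loading| per component positive
  for (j in seq_len(ncol(load))) {
    k <- which.max(abs(load[, j]))
    if (load[k, j] < 0) load[, j] <- -load[, j]
  }
  rownames(load) <- colnames(x)
  colnames(load) <- paste0("PC", seq_len(ncol(load)))
  scores <- z %*% load
  structure(list(loadings = load, scores = scores,
                 eigenvalues = eg$values,
                 explained_variance = eg$values / sum(eg$values),
                 group = grp),
            class = "pca_result")
}

#' @export
print.pca_result <- function(x, ...) {
  cat(sprintf("<pca_result> %d specimens x %d variables\n",
              nrow(x$scores), nrow(x$loadings)))
  ev <- round(100 * x$explained_variance[seq_len(min(4, length(x$explained_variance)))], 1)
  cat("  explained variance (%):", paste(ev, collapse = ", "), "...\n")
  invisible(x)
}

#' Axis-range overlap between groups in PC space
#'
#' For each group pair, reports whether the axis-aligned score ranges
#' intersect on each of the two requested components and on both at once
#' (the "overlap in both axes" criterion). Singleton groups contribute a
#' point range and are flagged.
#'
#' @param result a `pca_result` with group labels.
#' @param axes length-2 integer vector of component indices (e.g.
#'   `c(2, 4)`).
#' @param groups optional subset of groups to compare.
#' @return data.frame with one row per group pair: per-axis overlap,
#'   `overlap_both`, and singleton flags.
#' @export
group_overlap <- function(result, axes = c(1, 2), groups = NULL) {
  stopifnot(length(axes) == 2L, !is.null(result$group))
  g <- result$group
  if (is.null(groups)) groups <- unique(g)
  pairs <- utils::combn(groups, 2)
  rng <- function(grp, ax) range(result$scores[g == grp, ax])
  rows <- lapply(seq_len(ncol(pairs)), function(i) {
    a <- pairs[1, i]; b <- pairs[2, i]
    o <- vapply(axes, function(ax) {
      ra <- rng(a, ax); rb <- rng(b, ax)
      ra[1] <= rb[2] && rb[1] <= ra[2]
    }, logical(1))
    data.frame(group_a = a, group_b = b,
               axis_1 = axes[1], axis_2 = axes[2],
               overlap_axis_1 = o[1], overlap_axis_2 = o[2],
               overlap_both = all(o),
               singleton_a = sum(g == a) == 1L,
               singleton_b = sum(g == b) == 1L)
  })
  do.call(rbind, rows)
}
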