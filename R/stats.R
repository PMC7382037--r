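#' Pearson correlation screen over feature pairs
#'
#' Product-moment correlation with a two-sided p-value from the t
#' transform on n - 2 degrees of freedom, computed from the standard
#' formulas (the test suite cross-checks against `stats::cor.test`).
#' Zero-variance features yield NA with a note in the output.
#'
#' @param matrix Numeric data.frame/matrix (rows = species clusters).
#' @param pairs List of length-2 character vectors of column names; by
#'   default all column pairs.
#' @return data.frame: feature_a, feature_b, n, r, p.
#' @export
pearson_screen <- function(matrix, pairs = NULL) {
  m <- as.data.frame(matrix)
  if (is.null(pairs)) {
    cn <- colnames(m)
    pairs <- utils::combn(cn, 2, simplify = FALSE)
  }
  rows <- lapply(pairs, function(p) {
    x <- m[[p[1]]]; y <- m[[p[2]]]
    ok <- is.finite(x) & is.finite(y)
    x <- x[ok]; y <- y[ok]
    n <- length(x)
    if (n < 3 || stats::sd(x) == 0 || stats::sd(y) == 0) {
      return(data.frame(feature_a = p[1], feature_b = p[2], n = n,
                        r = NA_real_, p = NA_real_,
                        stringsAsFactors = FALSE))
    }
    r <- sum((x - mean(x)) * (y - mean(y))) /
      sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
    if (abs(r) >= 1) {
      pval <- 0
    } else {
      tstat <- r * sqrt((n - 2) / (1 - r^2))
      pval <- 2 * stats::pt(-abs(tstat), df = n - 2)
    }
    data.frame(feature_a = p[1], feature_b = p[2], n = n, r = r, p = pval,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Two-sample t test of one phylum against the rest
#'
#' Student's pooled-variance two-sided t test (the convention used for
#' spreadsheet-style T.DIST comparisons) of a feature between the rows of
#' one phylum and all other rows; `welch = TRUE` switches to the
#' unequal-variance form. Degenerate variance is flagged.
#'
#' @param matrix Numeric data.frame/matrix with features as columns.
#' @param feature Column name.
#' @param phylum_col Character vector (length nrow) of phylum labels.
#' @param phylum Phylum forming the focal group.
#' @param welch Use Welch's correction (default FALSE).
#' @return List: estimate (group means), t, df, p, flag.
#' @export
group_t_test <- function(matrix, feature, phylum_col, phylum, welch = FALSE) {
  m <- as.data.frame(matrix)
  x <- m[[feature]][phylum_col == phylum]
  y <- m[[feature]][phylum_col != phylum]
  if (length(x) < 2 || length(y) < 2) {
    stop("both groups need at least two rows")
  }
  vx <- stats::var(x); vy <- stats::var(y)
  flag <- if (vx == 0 && vy == 0) "degenerate variance" else ""
  if (vx == 0 && vy == 0) {
    p <- if (mean(x) == mean(y)) 1 else 0
    return(list(estimate = c(mean(x), mean(y)), t = NA_real_, df = NA_real_,
                p = p, flag = flag))
  }
  nx <- length(x); ny <- length(y)
  if (welch) {
    se2 <- vx / nx + vy / ny
    tstat <- (mean(x) - mean(y)) / sqrt(se2)
    df <- se2^2 / ((vx / nx)^2 / (nx - 1) + (vy / ny)^2 / (ny - 1))
  } else {
    sp2 <- ((nx - 1) * vx + (ny - 1) * vy) / (nx + ny - 2)
    tstat <- (mean(x) - mean(y)) / sqrt(sp2 * (1 / nx + 1 / ny))
    df <- nx + ny - 2
  }
  list(estimate = c(mean(x), mean(y)), t = tstat, df = df,
       p = 2 * stats::pt(-abs(tstat), df = df), flag = flag)
}

#' PCA ordination with per-phylum 95% confidence ellipses
#'
#' Centered (optionally unit-variance scaled) principal component
#' analysis of the feature matrix. Component signs are fixed by the
#' largest-absolute-loading-positive convention so that output is
#' invariant to row order. Normal-theory 95% ellipses (chi-square
#' quantile on the 2x2 score covariance) are returned per phylum with at
#' least 3 rows.
#'
#' @param matrix Numeric data.frame/matrix (>= 3 rows, >= 2 columns).
#' @param phylum_col Optional phylum label per row (for ellipses).
#' @param scale. Unit-variance scaling (default TRUE; constant columns
#'   are dropped with a note).
#' @param level Ellipse confidence level.
#' @return List: scores (n x 2), loadings, var_explained (all
#'   components), ellipses (per phylum: center, radii, angle).
#' @export
pca_ordinate <- function(matrix, phylum_col = NULL, scale. = TRUE,
                         level = 0.95) {
  m <- as.matrix(matrix)
  stopifnot(nrow(m) >= 3, ncol(m) >= 2)
  if (scale.) {
    keep <- apply(m, 2, stats::sd) > 0
    if (!all(keep)) {
      message("dropping constant column(s): ",
              paste(colnames(m)[!keep], collapse = ", "))
      m <- m[, keep, drop = FALSE]
    }
  }
  pc <- stats::prcomp(m, center = TRUE, scale. = scale.)
  # sign convention: the loading with the largest magnitude is positive
  for (j in seq_len(ncol(pc$rotation))) {
    k <- which.max(abs(pc$rotation[, j]))
    if (pc$rotation[k, j] < 0) {
      pc$rotation[, j] <- -pc$rotation[, j]
      pc$x[, j] <- -pc$x[, j]
    }
  }
  var_exp <- pc$sdev^2 / sum(pc$sdev^2)
  scores <- pc$x[, 1:2, drop = FALSE]
  ellipses <- NULL
  if (!is.null(phylum_col)) {
    ellipses <- list()
    for (ph in unique(phylum_col)) {
      s <- scores[phylum_col == ph, , drop = FALSE]
      if (nrow(s) < 3) next
      ctr <- colMeans(s)
      cv <- stats::cov(s)
      ei <- eigen(cv, symmetric = TRUE)
      r2 <- stats::qchisq(level, df = 2)
      ellipses[[ph]] <- list(
        center = ctr,
        radii = sqrt(pmax(ei$values, 0) * r2),
        angle = atan2(ei$vectors[2, 1], ei$vectors[1, 1]))
    }
  }
  list(scores = scores, loadings = pc$rotation,
       var_explained = var_exp, ellipses = ellipses)
}

#' Screen binary functions for group enrichment
#'
#' For each function (binary presence column), tests whether its frequency
#' in the focal group exceeds that in the remaining rows (group-vs-rest
#' Student's t test on the 0/1 indicator, the spreadsheet convention; a
#' Fisher exact option is provided). Returns the functions significant at
#' `alpha` with their direction.
#'
#' @param presence Binary matrix/data.frame (rows = clusters,
#'   columns = functions).
#' @param group Logical vector (length nrow): focal group membership.
#' @param alpha Significance level (default 0.05).
#' @param method "t" (default) or "fisher".
#' @return data.frame: fn, freq_group, freq_rest, p, enriched
#'   (TRUE when significantly more frequent in the group).
#' @export
function_frequency_screen <- function(presence, group, alpha = 0.05,
                                      method = c("t", "fisher")) {
  method <- match.arg(method)
  m <- as.matrix(presence)
  stopifnot(all(m %in% c(0, 1)), is.logical(group), length(group) == nrow(m))
  rows <- lapply(colnames(m), function(fn) {
    x <- m[group, fn]; y <- m[!group, fn]
    fg <- mean(x); fr <- mean(y)
    p <- NA_real_
    if (stats::var(x) == 0 && stats::var(y) == 0) {
      p <- if (fg == fr) 1 else 0
    } else if (method == "t") {
      p <- group_t_test(data.frame(v = c(x, y)), "v",
                        rep(c("g", "r"), c(length(x), length(y))), "g")$p
    } else {
      tab <- matrix(c(sum(x), length(x) - sum(x),
                      sum(y), length(y) - sum(y)), nrow = 2)
      p <- stats::fisher.test(tab)$p.value
    }
    data.frame(fn = fn, freq_group = fg, freq_rest = fr, p = p,
               enriched = !is.na(p) && p < alpha && fg > fr,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
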