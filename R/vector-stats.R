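## Vector-comparison statistics for log-odds enrichment vectors.

as_lov_values <- function(x) {
  if (inherits(x, "log_odds_vector")) stats::setNames(x$log_odds, x$codon) else x
}

align_vectors <- function(x, y) {
  xv <- as_lov_values(x); yv <- as_lov_values(y)
  if (!is.null(names(xv)) && !is.null(names(yv))) {
    common <- intersect(names(xv), names(yv))
    xv <- xv[common]; yv <- yv[common]
  }
  if (length(xv) != length(yv)) stop("vectors of unequal length and no shared names")
  ok <- is.finite(xv) & is.finite(yv)
  list(x = xv[ok], y = yv[ok])
}

#' Correlate two log-odds vectors
#'
#' Pearson product-moment (default) or Spearman rank correlation with a
#' two-sided p-value. Accepts `log_odds_vector` objects (aligned by
#' codon, undefined entries pairwise-dropped) or plain numeric vectors.
#'
#' @param x,y numeric vectors or `log_odds_vector`s
#' @param method `"pearson"` or `"spearman"`
#' @return list of class `correlation_result`: `method`, `estimate`,
#'   `p_value`, `n`
#' @export
correlate_vectors <- function(x, y, method = c("pearson", "spearman")) {
  method <- match.arg(method)
  al <- align_vectors(x, y)
  if (length(al$x) < 3) stop("need at least 3 paired finite values")
  if (stats::sd(al$x) == 0 || stats::sd(al$y) == 0)
    stop("zero variance: correlation undefined")
  ct <- suppressWarnings(stats::cor.test(al$x, al$y, method = method,
                                         alternative = "two.sided", exact = FALSE))
  structure(
    list(method = method, estimate = unname(ct$estimate),
         p_value = ct$p.value, n = length(al$x)),
    class = "correlation_result"
  )
}

#' @export
print.correlation_result <- function(x, ...) {
  cat(sprintf("%s correlation: %s = %.4f, p = %.3g, n = %d\n", x$method,
              if (x$method == "pearson") "r" else "rho", x$estimate,
              x$p_value, x$n))
  invisible(x)
}

#' Orthogonal (total least squares) regression line via PCA
#'
#' Fits the line through the centroid along the first principal axis of
#' the centered, unscaled two-column data. The slope sign follows the
#' covariance sign.
#'
#' @param x,y numeric vectors
#' @return list with `slope` and `intercept`
#' @export
orthogonal_fit <- function(x, y) {
  al <- align_vectors(x, y)
  x <- al$x; y <- al$y
  if (length(x) < 2) stop("need at least 2 points")
  S <- stats::cov(cbind(x, y))
  e <- eigen(S, symmetric = TRUE)
  if (abs(e$values[1] - e$values[2]) <= 1e-12 * max(abs(e$values), 1))
    stop("isotropic point cloud: principal axis is not unique")
  v <- e$vectors[, 1]
  if (v[1] == 0) stop("principal axis is vertical: slope undefined")
  slope <- v[2] / v[1]
  list(slope = slope, intercept = mean(y) - slope * mean(x))
}

#' Oriented within-block pairwise synonymous differences
#'
#' For every unordered pair of codons in the same synonymous block,
#' takes the difference of the two vectors' entries, oriented so the
#' x-vector difference is non-negative: `dx = x[hi] - x[lo] >= 0`, with
#' the same orientation applied to `dy`. This removes the within-block
#' non-independence of log-odds entries (for a 2-fold block the two
#' entries are exact negations). The standard partition yields 87 pairs.
#' Exact `dx = 0` ties are oriented alphabetically; pairs with an
#' undefined member are dropped.
#'
#' @param x_vec,y_vec `log_odds_vector`s over the same partition
#' @param code the shared [genetic_code_partition()]
#' @return data.frame of class `pairwise_diff_set` with columns
#'   `codon_hi`, `codon_lo`, `block`, `dx`, `dy`
#' @export
pairwise_synonym_diffs <- function(x_vec, y_vec, code = genetic_code_partition()) {
  xv <- as_lov_values(x_vec); yv <- as_lov_values(y_vec)
  if (!setequal(names(xv), code$scored_codons) ||
      !setequal(names(yv), code$scored_codons))
    stop("vectors do not cover the partition's scored codons")
  rows <- list()
  for (bname in names(code$blocks)) {
    blk <- sort(code$blocks[[bname]])
    if (length(blk) < 2) next
    cmb <- utils::combn(blk, 2)
    for (j in seq_len(ncol(cmb))) {
      a <- cmb[1, j]; b <- cmb[2, j]      # a < b alphabetically
      if (!is.finite(xv[a]) || !is.finite(xv[b]) ||
          !is.finite(yv[a]) || !is.finite(yv[b])) next
      if (xv[a] >= xv[b]) { hi <- a; lo <- b } else { hi <- b; lo <- a }
      rows[[length(rows) + 1L]] <- data.frame(
        codon_hi = hi, codon_lo = lo, block = bname,
        dx = xv[hi] - xv[lo], dy = yv[hi] - yv[lo],
        stringsAsFactors = FALSE
      )
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("pairwise_diff_set", "data.frame")
  out
}

#' Exact two-sided binomial sign test on a codon subset
#'
#' Counts how many entries of a log-odds vector in a codon subset fall
#' strictly on the requested side of zero and tests the count against a
#' fair coin: two-sided p = `min(1, 2 * min(P(X <= k), P(X >= k)))` at
#' success probability 0.5, by exact pmf summation. Zero-valued entries
#' count as non-matching and are reported separately.
#'
#' @param vec a `log_odds_vector` or named numeric vector
#' @param subset character vector of codons, or a predicate function on
#'   codon strings (e.g. `function(c) third_base(c) %in% c("A","T")`)
#' @param direction `"positive"` or `"negative"`
#' @return list: `k` matching entries, `n` subset size, `p_value`,
#'   `n_zero` zero-valued entries
#' @export
sign_binomial_test <- function(vec, subset, direction = c("positive", "negative")) {
  direction <- match.arg(direction)
  v <- as_lov_values(vec)
  codons <- names(v)
  sel <- if (is.function(subset)) codons[vapply(codons, subset, logical(1))]
         else intersect(codons, subset)
  if (!length(sel)) stop("empty codon subset")
  vals <- v[sel]
  if (any(!is.finite(vals))) stop("undefined entries in subset")
  k <- if (direction == "positive") sum(vals > 0) else sum(vals < 0)
  n <- length(vals)
  p <- min(1, 2 * min(sum(stats::dbinom(0:k, n, 0.5)),
                      sum(stats::dbinom(k:n, n, 0.5))))
  list(k = k, n = n, p_value = p, n_zero = sum(vals == 0))
}

#' Multivariate ordinary least squares across aligned vectors
#'
#' Fits `response ~ predictors` (intercept always included) after
#' aligning all vectors by codon and dropping codons with any undefined
#' entry. Optional quadratic terms (squares of named predictors) serve
#' the GC3 models.
#'
#' @param response numeric vector or `log_odds_vector`
#' @param predictors named list of vectors / `log_odds_vector`s
#' @param include_quadratic character vector of predictor names whose
#'   squares are appended as `<name>2`
#' @return list of class `fit_result`: `coefficients`, `se`, `p_values`
#'   (named, including `(Intercept)`), `adj_r_squared`, `n`, and the
#'   underlying `lm` object as `model`
#' @export
multivariate_fit <- function(response, predictors, include_quadratic = NULL) {
  stopifnot(is.list(predictors), !is.null(names(predictors)))
  yv <- as_lov_values(response)
  pv <- lapply(predictors, as_lov_values)
  if (!is.null(names(yv))) {
    common <- Reduce(intersect, c(list(names(yv)), lapply(pv, names)))
    yv <- yv[common]
    pv <- lapply(pv, `[`, common)
  }
  df <- data.frame(.response = yv, pv, check.names = FALSE)
  for (q in include_quadratic) {
    if (!q %in% names(predictors)) stop("unknown quadratic term: ", q)
    df[[paste0(q, "2")]] <- df[[q]]^2
  }
  df <- df[stats::complete.cases(df), , drop = FALSE]
  if (nrow(df) <= ncol(df)) stop("too few complete cases for the model")
  fit <- stats::lm(.response ~ ., data = df)
  if (any(is.na(stats::coef(fit)))) {
    bad <- names(stats::coef(fit))[is.na(stats::coef(fit))]
    stop("rank-deficient design; collinear columns: ", paste(bad, collapse = ", "))
  }
  sm <- summary(fit)
  structure(
    list(
      coefficients = stats::coef(fit),
      se = sm$coefficients[, "Std. Error"],
      p_values = sm$coefficients[, "Pr(>|t|)"],
      adj_r_squared = sm$adj.r.squared,
      n = nrow(df),
      model = fit
    ),
    class = "fit_result"
  )
}

#' @export
print.fit_result <- function(x, ...) {
  cat("OLS fit, n =", x$n, ", adj r^2 =", round(x$adj_r_squared, 4), "\n")
  print(data.frame(estimate = x$coefficients, se = x$se, p = x$p_values))
  invisible(x)
}

#' Cronbach's alpha with Feldt confidence interval
#'
#' Internal-consistency coefficient for a subjects-by-items matrix:
#' `alpha = k/(k-1) * (1 - sum(item variances) / var(subject totals))`
#' with sample (n-1) variances. The confidence interval follows Feldt's
#' F method with `n - 1` and `(n - 1)(k - 1)` degrees of freedom.
#'
#' @param m numeric matrix, subjects in rows, items in columns
#' @param conf_level confidence level (default 0.95)
#' @return list of class `alpha_result`: `alpha`, `ci_low`, `ci_high`,
#'   `k`, `n`
#' @export
cronbach_alpha <- function(m, conf_level = 0.95) {
  m <- as.matrix(m)
  n <- nrow(m); k <- ncol(m)
  if (k < 2 || n < 3) stop("need >= 2 items and >= 3 subjects")
  totals <- rowSums(m)
  vt <- stats::var(totals)
  if (!is.finite(vt) || vt == 0) stop("zero total variance: alpha undefined")
  alpha <- k / (k - 1) * (1 - sum(apply(m, 2, stats::var)) / vt)
  a <- 1 - conf_level
  df1 <- n - 1
  df2 <- (n - 1) * (k - 1)
  ci_low <- 1 - (1 - alpha) * stats::qf(1 - a / 2, df1, df2)
  ci_high <- 1 - (1 - alpha) * stats::qf(a / 2, df1, df2)
  structure(list(alpha = alpha, ci_low = ci_low, ci_high = ci_high,
                 k = k, n = n),
            class = "alpha_result")
}

#' @export
print.alpha_result <- function(x, ...) {
  cat(sprintf("Cronbach's alpha = %.3f (95%% CI %.3f-%.3f), k = %d items, n = %d\n",
              x$alpha, x$ci_low, x$ci_high, x$k, x$n))
  invisible(x)
}
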