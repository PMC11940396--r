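#' Normality gate for choosing parametric vs nonparametric tests
#'
#' Shapiro-Wilk per sample at level \code{alpha}; any non-normal (or
#' degenerate, or too small) sample routes the comparison to the
#' nonparametric branch.
#'
#' @param ... One or more numeric samples (the groups entering a test).
#' @param alpha Gate level.
#' @return \code{"parametric"} or \code{"nonparametric"}, with attribute
#'   \code{"shapiro_p"} (per-sample p values; NA when not computable).
#' @export
normality_gate <- function(..., alpha = 0.05) {
  samples <- list(...)
  ps <- vapply(samples, function(x) {
    x <- x[is.finite(x)]
    if (length(x) < 3) {
      warning("sample with n < 3: nonparametric by default")
      return(NA_real_)
    }
    if (stats::sd(x) == 0) {
      warning("constant sample (degenerate input): nonparametric")
      return(NA_real_)
    }
    stats::shapiro.test(x)$p.value
  }, numeric(1))
  choice <- if (any(is.na(ps)) || any(ps < alpha)) "nonparametric"
            else "parametric"
  structure(choice, shapiro_p = ps)
}

test_result <- function(method, statistic, df, p, summaries, gate = NA) {
  structure(list(method = method, statistic = statistic, df = df, p = p,
                 summaries = summaries, gate = gate),
            class = "test_result")
}

#' @export
print.test_result <- function(x, ...) {
  dfs <- paste(round(unlist(x$df), 2), collapse = ", ")
  cat(sprintf("%s: statistic = %.4g, df = %s, p = %.4g\n",
              x$method, x$statistic, dfs, x$p))
  invisible(x)
}

group_summary <- function(x) {
  n <- sum(is.finite(x))
  list(n = n, mean = mean(x), sem = stats::sd(x) / sqrt(n),
       median = stats::median(x),
       iqr = unname(stats::quantile(x, c(0.25, 0.75))))
}

#' Welch's unequal-variance t test
#'
#' Two-sided Welch-corrected unpaired t test (Welch-Satterthwaite degrees
#' of freedom), as used for between-group comparisons of normally
#' distributed outcomes.
#'
#' @param x,y Numeric samples, each of size >= 2.
#' @return A \code{test_result} (method \code{"welch_t"}) with mean +/- SEM
#'   group summaries.
#' @export
welch_t <- function(x, y) {
  stopifnot(length(x) >= 2, length(y) >= 2)
  if (stats::sd(x) == 0 && stats::sd(y) == 0)
    stop("both samples have zero variance")
  ht <- stats::t.test(x, y, var.equal = FALSE)
  test_result("welch_t", unname(ht$statistic), unname(ht$parameter),
              ht$p.value, list(x = group_summary(x), y = group_summary(y)))
}

# Exact null distribution of the Mann-Whitney U statistic under random
# group assignment, honouring ties through mid-ranks: enumerate all
# choose(nx+ny, nx) assignments of the pooled mid-ranks to group x.
mw_exact_distribution <- function(ranks, nx) {
  combos <- utils::combn(length(ranks), nx)
  u <- apply(combos, 2, function(ix) sum(ranks[ix])) - nx * (nx + 1) / 2
  u
}

#' Exact Mann-Whitney U test with mid-rank ties
#'
#' Computes U from pooled mid-ranks. For total sample sizes up to
#' \code{exact_max} the two-sided p value is exact, by full enumeration of
#' all group assignments of the observed (possibly tied) ranks -- the
#' regime of a 5-vs-7 animal study; larger samples use the normal
#' approximation with tie correction.
#'
#' @param x,y Numeric samples, each of size >= 2.
#' @param exact_max Largest \code{nx + ny} for which full enumeration is
#'   used (default 14).
#' @return A \code{test_result} (method \code{"mann_whitney_exact"} or
#'   \code{"mann_whitney_normal"}) with median [IQR] group summaries; the
#'   statistic is U for group x.
#' @examples
#' mann_whitney(c(1, 2, 3), c(4, 5, 6))$p  # exact: 2/20 = 0.1
#' @export
mann_whitney <- function(x, y, exact_max = 14) {
  nx <- length(x); ny <- length(y)
  stopifnot(nx >= 2, ny >= 2)
  pooled <- c(x, y)
  rk <- rank(pooled)  # mid-ranks for ties
  u_obs <- sum(rk[seq_len(nx)]) - nx * (nx + 1) / 2
  if (nx + ny <= exact_max) {
    u_all <- mw_exact_distribution(rk, nx)
    tol <- 1e-9
    p_le <- mean(u_all <= u_obs + tol)
    p_ge <- mean(u_all >= u_obs - tol)
    p <- min(1, 2 * min(p_le, p_ge))
    method <- "mann_whitney_exact"
  } else {
    mu <- nx * ny / 2
    nties <- table(rk)
    ntot <- nx + ny
    sigma2 <- nx * ny / 12 *
      (ntot + 1 - sum(nties^3 - nties) / (ntot * (ntot - 1)))
    z <- (u_obs - mu - sign(u_obs - mu) * 0.5) / sqrt(sigma2)
    p <- 2 * stats::pnorm(-abs(z))
    method <- "mann_whitney_normal"
  }
  test_result(method, u_obs, NA_real_, p,
              list(x = group_summary(x), y = group_summary(y)))
}

#' One-way repeated-measures ANOVA
#'
#' Omnibus within-group test across periods with the subject effect
#' removed: F = MS_period / MS_error on ((k-1), (n-1)(k-1)) degrees of
#' freedom, fitted via \code{aov} with an error stratum per subject.
#' Missing cells are rejected (no imputation).
#'
#' @param m Numeric matrix, subjects x periods (complete, >= 3 subjects,
#'   >= 2 periods).
#' @return A \code{test_result} (method \code{"rm_anova"}).
#' @export
rm_anova <- function(m) {
  m <- as.matrix(m)
  if (any(!is.finite(m))) stop("missing cells: repeated-measures ANOVA needs a complete matrix")
  n <- nrow(m); k <- ncol(m)
  stopifnot(n >= 3, k >= 2)
  d <- data.frame(y = as.vector(m),
                  subject = factor(rep(seq_len(n), k)),
                  period = factor(rep(seq_len(k), each = n)))
  fit <- stats::aov(y ~ period + Error(subject), data = d)
  tab <- summary(fit)[["Error: Within"]][[1]]
  fval <- tab["period", "F value"]
  p <- tab["period", "Pr(>F)"]
  ss_period <- tab["period", "Sum Sq"]
  ss_resid <- tab["Residuals", "Sum Sq"]
  tol <- 1e-12 * max(sum(m^2), 1)
  if (ss_resid <= tol) {  # zero within-subject error variance
    if (ss_period <= tol) { fval <- 0; p <- 1 }     # fully degenerate
    else { fval <- Inf; p <- 0 }                    # perfect period effect
  }
  test_result("rm_anova", unname(fval), c(df1 = k - 1, df2 = (n - 1) * (k - 1)),
              unname(p), lapply(seq_len(k), function(j) group_summary(m[, j])))
}

#' Friedman rank test
#'
#' Nonparametric within-group omnibus test across periods: within-subject
#' mid-ranks, tie-corrected chi-squared statistic on k-1 degrees of
#' freedom (via \code{friedman.test}).
#'
#' @param m Numeric matrix, subjects x periods (complete, >= 2 subjects,
#'   >= 3 periods).
#' @return A \code{test_result} (method \code{"friedman"}). A fully tied
#'   matrix (all columns identical) is flagged degenerate with statistic 0
#'   and p = 1.
#' @export
friedman <- function(m) {
  m <- as.matrix(m)
  if (any(!is.finite(m))) stop("missing cells: Friedman test needs a complete matrix")
  n <- nrow(m); k <- ncol(m)
  if (k < 3) stop("Friedman test needs >= 3 periods")
  stopifnot(n >= 2)
  ranks <- t(apply(m, 1, rank))
  if (all(apply(ranks, 2, stats::sd) == 0) &&
      stats::sd(colMeans(ranks)) == 0) {
    res <- test_result("friedman", 0, c(df = k - 1), 1,
                       lapply(seq_len(k), function(j) group_summary(m[, j])))
    res$degenerate <- TRUE
    return(res)
  }
  ht <- stats::friedman.test(m)
  test_result("friedman", unname(ht$statistic), unname(ht$parameter),
              ht$p.value, lapply(seq_len(k), function(j) group_summary(m[, j])))
}

#' Normality-gated two-group comparison
#'
#' Welch t when both groups pass the Shapiro-Wilk gate, Mann-Whitney U
#' otherwise; the chosen branch is recorded on the result.
#'
#' @param x,y Numeric samples.
#' @param alpha Gate level.
#' @return A \code{test_result} with \code{gate} set.
#' @export
compare_groups <- function(x, y, alpha = 0.05) {
  gate <- suppressWarnings(normality_gate(x, y, alpha = alpha))
  res <- if (gate == "parametric") welch_t(x, y) else mann_whitney(x, y)
  res$gate <- as.character(gate)
  res
}

#' Normality-gated within-group trend test
#'
#' Repeated-measures ANOVA when every period passes the Shapiro-Wilk
#' gate, Friedman otherwise.
#'
#' @param m Subjects x periods matrix.
#' @param alpha Gate level.
#' @return A \code{test_result} with \code{gate} set.
#' @export
within_group_trend <- function(m, alpha = 0.05) {
  m <- as.matrix(m)
  gate <- suppressWarnings(
    do.call(normality_gate,
            c(lapply(seq_len(ncol(m)), function(j) m[, j]), alpha = alpha)))
  res <- if (gate == "parametric") rm_anova(m) else friedman(m)
  res$gate <- as.character(gate)
  res
}
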