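#' One-sample or paired t-test
#'
#' Thin wrapper over [stats::t.test()] returning just (t, df, p),
#' two-sided, with the degenerate zero-variance case defined by
#' convention: p = 0 (t = +/-Inf) if the mean differs from `mu0`, else
#' p = 1 (t = 0).
#'
#' @param x Numeric values (or first member of the pairs).
#' @param y Optional second member; when given the test is paired.
#' @param mu0 Null value for the (difference in) means.
#' @return List: `t`, `df`, `p`.
#' @export
t_test <- function(x, y = NULL, mu0 = 0) {
  d <- if (is.null(y)) x - mu0 else (x - y) - mu0
  if (length(d) < 2L) stop("need n >= 2")
  if (stats::sd(d) == 0) {
    m <- mean(d)
    message("zero-variance t-test input; conventional p returned")
    return(list(t = if (m == 0) 0 else sign(m) * Inf,
                df = length(d) - 1L, p = if (m == 0) 1 else 0))
  }
  tt <- stats::t.test(d)
  list(t = unname(tt$statistic), df = unname(tt$parameter),
       p = tt$p.value)
}

#' One-way repeated-measures ANOVA with Greenhouse-Geisser correction
#'
#' Within-subject one-way ANOVA from the definitional sums of squares
#' (subjects x conditions, complete design), with the Greenhouse-Geisser
#' epsilon estimated from the sample covariance of the within-subject
#' measures: `eps = tr(S~)^2 / ((k-1) * tr(S~^2))` for the double-centred
#' covariance `S~`. Corrected degrees of freedom are `eps*(k-1)` and
#' `eps*(k-1)*(n-1)`; epsilon is bounded to \[1/(k-1), 1\] and forced to 1
#' when k = 2, where the F-test reproduces the paired t (F = t^2).
#'
#' @param table Numeric matrix, subjects x conditions (no missing cells).
#' @return List: `F`, `df1`, `df2` (GG-corrected), `p_uncorrected`,
#'   `epsilon`, `p_gg`, plus uncorrected dfs `df1_unc`, `df2_unc`.
#' @export
rm_anova_gg <- function(table) {
  table <- as.matrix(table)
  n <- nrow(table); k <- ncol(table)
  if (k < 2L) stop("need k >= 2 conditions")
  if (n < k) stop("need n >= k subjects")
  if (anyNA(table)) stop("complete within-subject design required")
  grand <- mean(table)
  subj_m <- rowMeans(table); cond_m <- colMeans(table)
  ss_cond <- n * sum((cond_m - grand)^2)
  ss_subj <- k * sum((subj_m - grand)^2)
  ss_tot <- sum((table - grand)^2)
  ss_err <- ss_tot - ss_cond - ss_subj
  df1 <- k - 1L; df2 <- (k - 1L) * (n - 1L)
  Fv <- (ss_cond / df1) / (ss_err / df2)

  if (k == 2L) {
    eps <- 1
  } else {
    S <- stats::cov(table)
    C <- diag(k) - 1 / k           # centring matrix
    St <- C %*% S %*% C
    tr <- sum(diag(St)); tr2 <- sum(St * St)
    eps <- if (tr2 <= .Machine$double.eps) {
      warning("rank-deficient within-subject covariance; epsilon at lower bound")
      1 / (k - 1)
    } else tr^2 / ((k - 1) * tr2)
    eps <- min(1, max(1 / (k - 1), eps))
  }
  p_unc <- stats::pf(Fv, df1, df2, lower.tail = FALSE)
  p_gg <- stats::pf(Fv, eps * df1, eps * df2, lower.tail = FALSE)
  list(F = Fv, df1 = eps * df1, df2 = eps * df2,
       df1_unc = df1, df2_unc = df2,
       p_uncorrected = p_unc, epsilon = eps, p_gg = p_gg)
}

#' Within-subject (repeated-measures adjusted) SEM
#'
#' Cousineau subject-centring (subtract the subject mean, add the grand
#' mean) followed by Morey's `sqrt(k/(k-1))` bias correction: the
#' per-condition SD of the centred values over sqrt(n), scaled by the
#' correction. Additive between-subject offsets contribute nothing.
#'
#' @param table Numeric matrix, subjects x conditions.
#' @return Named numeric vector of per-condition SEMs.
#' @export
within_subject_sem <- function(table) {
  table <- as.matrix(table)
  n <- nrow(table); k <- ncol(table)
  centred <- table - rowMeans(table) + mean(table)
  apply(centred, 2, stats::sd) / sqrt(n) * sqrt(k / (k - 1))
}

#' Group statistics for a subject x condition metric table
#'
#' The comparisons applied to each metric: one-sample t against a
#' reference (e.g. chance 0.25 for accuracies), the omnibus
#' repeated-measures ANOVA with GG correction over the visual conditions,
#' and pairwise paired t-tests between them.
#'
#' @param table Numeric matrix, subjects x conditions (named columns).
#' @param mu0 Reference value for per-condition one-sample tests (or
#'   `NULL` to skip).
#' @param omnibus_conditions Columns entering the ANOVA and pairwise tests
#'   (default: all).
#' @return List: `one_sample` (data frame), `anova` (list), `pairwise`
#'   (data frame), `sem` (vector).
#' @export
group_metric_stats <- function(table, mu0 = NULL,
                               omnibus_conditions = colnames(table)) {
  table <- as.matrix(table)
  one <- NULL
  if (!is.null(mu0)) {
    one <- do.call(rbind, lapply(colnames(table), function(cc) {
      r <- t_test(table[, cc], mu0 = mu0)
      data.frame(condition = cc, t = r$t, df = r$df, p = r$p,
                 stringsAsFactors = FALSE)
    }))
  }
  sub <- table[, omnibus_conditions, drop = FALSE]
  an <- if (ncol(sub) >= 2L && nrow(sub) >= ncol(sub))
    rm_anova_gg(sub) else NULL
  pw <- NULL
  if (ncol(sub) >= 2L) {
    prs <- utils::combn(colnames(sub), 2)
    pw <- do.call(rbind, lapply(seq_len(ncol(prs)), function(i) {
      a <- prs[1, i]; b <- prs[2, i]
      r <- t_test(sub[, a], sub[, b])
      data.frame(a = a, b = b, t = r$t, df = r$df, p = r$p,
                 stringsAsFactors = FALSE)
    }))
  }
  list(one_sample = one, anova = an, pairwise = pw,
       sem = within_subject_sem(table))
}
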