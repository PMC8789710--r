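# Cohort statistics: exact small-sample nonparametric tests (paired
# Wilcoxon signed-rank by sign-pattern enumeration, Mann-Whitney U by
# assignment enumeration, Kendall tau-b with tie corrections) and the
# mean +/- SD pre/post and subgroup-delta table builders.
#
# The exact enumerations are implemented here because the classical exact
# routines decline small samples with ties or zeros, while at n = 8 the
# tied/zero cases are exactly the ones that occur.

statResult <- function(test, statistic, p, n, estimate = NA_real_,
                       note = NA_character_) {
  structure(list(test = test, statistic = statistic, p = p, n = n,
                 estimate = estimate, note = note),
            class = "StatResult")
}

#' @export
print.StatResult <- function(x, ...) {
  cat(sprintf("%s: statistic = %.4g, p = %.4g (n = %d)\n",
              x$test, x$statistic, x$p, x$n))
  if (is.finite(x$estimate)) cat(sprintf("  estimate = %.4g\n", x$estimate))
  if (!is.na(x$note)) cat("  note:", x$note, "\n")
  invisible(x)
}

#' Exact paired Wilcoxon signed-rank test
#'
#' Two-sided paired comparison. Zero differences are discarded (classical
#' convention; the discarded count is reported). For n (non-zero pairs)
#' up to \code{exact_max} the null distribution of the signed-rank sum W+
#' is enumerated over all 2^n sign assignments of the (tie-averaged)
#' absolute-difference ranks; beyond that, the normal approximation with
#' tie correction is used. Two-sided p = min(1, 2 min(P(W <= w), P(W >= w))).
#'
#' @param pre,post Equal-length numeric vectors of paired measurements.
#' @param exact_max Largest n for full enumeration (default 15).
#' @return A \code{StatResult} with the W+ statistic, two-sided p, n after
#'   zero removal, and the median difference as estimate.
#' @examples
#' pairedWilcoxon(c(1, 2, 3), c(2, 3, 5))$p  # 0.25
#' @export
pairedWilcoxon <- function(pre, post, exact_max = 15L) {
  stopifnot(length(pre) == length(post))
  d <- post - pre
  n_zero <- sum(d == 0)
  d <- d[d != 0]
  n <- length(d)
  if (n < 3L) stop("degenerate pairs: fewer than 3 non-zero differences")
  r <- rank(abs(d))
  w <- sum(r[d > 0])
  if (n <= exact_max) {
    signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
    wdist <- as.numeric(signs %*% r)
    p <- min(1, 2 * min(mean(wdist <= w), mean(wdist >= w)))
    method <- "exact Wilcoxon signed-rank (enumeration)"
  } else {
    mu <- n * (n + 1) / 4
    ties <- table(r)
    sigma2 <- n * (n + 1) * (2 * n + 1) / 24 -
      sum(ties^3 - ties) / 48
    z <- (w - mu) / sqrt(sigma2)
    p <- 2 * stats::pnorm(-abs(z))
    method <- "Wilcoxon signed-rank (normal approximation, tie-corrected)"
  }
  statResult(method, w, p, n, estimate = stats::median(d),
             note = if (n_zero) paste(n_zero, "zero differences discarded")
                    else NA_character_)
}

#' Exact Mann-Whitney U test on two independent samples
#'
#' Two-sided rank-sum comparison of two groups (here: per-patient pre-to-
#' post deltas of two subgroups). For combined n up to \code{exact_max} the
#' null distribution of U is enumerated over all assignments of the
#' (tie-averaged) combined ranks to group A; beyond that, the tie-corrected
#' normal approximation is used.
#'
#' @param a,b Numeric vectors, both non-empty.
#' @param exact_max Largest combined n for full enumeration (default 20).
#' @return A \code{StatResult} with the U statistic of group \code{a},
#'   two-sided p, combined n, and the difference of group medians as
#'   estimate.
#' @examples
#' mannWhitneyU(1:4, 5:8)$p  # 2/70
#' @export
mannWhitneyU <- function(a, b, exact_max = 20L) {
  na <- length(a); nb <- length(b)
  if (!na || !nb) stop("both groups must be non-empty")
  n <- na + nb
  r <- rank(c(a, b))
  u <- sum(r[seq_len(na)]) - na * (na + 1) / 2
  if (n <= exact_max) {
    sel <- utils::combn(n, na)
    udist <- colSums(matrix(r[sel], nrow = na)) - na * (na + 1) / 2
    p <- min(1, 2 * min(mean(udist <= u), mean(udist >= u)))
    method <- "exact Mann-Whitney U (enumeration)"
  } else {
    mu <- na * nb / 2
    ties <- table(r)
    sigma2 <- na * nb / 12 *
      ((n + 1) - sum(ties^3 - ties) / (n * (n - 1)))
    z <- (u - mu) / sqrt(sigma2)
    p <- 2 * stats::pnorm(-abs(z))
    method <- "Mann-Whitney U (normal approximation, tie-corrected)"
  }
  statResult(method, u, p, n,
             estimate = stats::median(a) - stats::median(b))
}

#' Subgroup comparison of pre-to-post changes
#'
#' Computes per-patient deltas (post - pre) of one index and compares the
#' two subgroups defined by a patient label with the exact Mann-Whitney U
#' test.
#'
#' @param cohort A \linkS4class{CohortTable}.
#' @param index Column name of the index (e.g. \code{"ef"}).
#' @param grouping One of \code{"ef_class"}, \code{"af"}, \code{"mi"}, or
#'   any logical/two-level column of the patient table.
#' @return A \code{StatResult}.
#' @export
subgroupDeltaTest <- function(cohort, index, grouping = "ef_class") {
  stopifnot(is(cohort, "CohortTable"))
  if (!index %in% colnames(cohort@pre))
    stop("unknown index: ", index)
  g <- cohort@patients[[grouping]]
  if (is.null(g)) stop("unknown grouping label: ", grouping)
  g <- as.factor(g)
  if (nlevels(g) != 2L || any(table(g) == 0L))
    stop("grouping must split the cohort into two non-empty groups")
  delta <- cohort@post[, index] - cohort@pre[, index]
  lv <- levels(g)
  res <- mannWhitneyU(delta[g == lv[1L]], delta[g == lv[2L]])
  res$note <- paste0(index, " delta: ", lv[1L], " vs ", lv[2L])
  res
}

#' Kendall's tau-b rank correlation with tie correction
#'
#' Tau-b from concordant/discordant pair counts with the standard tie
#' corrections in the denominator; two-sided p from the tie-corrected
#' normal approximation of the S = C - D statistic. A constant input
#' vector makes tau-b undefined: the estimate is returned as NA with an
#' explanatory note (flagged, not hidden).
#'
#' @param x,y Equal-length numeric vectors (n >= 3).
#' @return A \code{StatResult}; \code{estimate} holds tau-b.
#' @examples
#' kendallTauB(1:5, c(2, 4, 6, 8, 10))$estimate  # 1
#' @export
kendallTauB <- function(x, y) {
  n <- length(x)
  stopifnot(length(y) == n, n >= 3L)
  dx <- sign(outer(x, x, "-")); dy <- sign(outer(y, y, "-"))
  up <- upper.tri(dx)
  s <- sum(dx[up] * dy[up])                    # C - D
  tx <- table(x); ty <- table(y)
  n0 <- n * (n - 1) / 2
  n1 <- sum(tx * (tx - 1) / 2); n2 <- sum(ty * (ty - 1) / 2)
  if (n0 - n1 <= 0 || n0 - n2 <= 0)
    return(statResult("Kendall tau-b", s, NA_real_, n,
                      estimate = NA_real_,
                      note = "constant input: tau-b undefined"))
  tau <- s / sqrt((n0 - n1) * (n0 - n2))
  v0 <- n * (n - 1) * (2 * n + 5)
  vt <- sum(tx * (tx - 1) * (2 * tx + 5))
  vu <- sum(ty * (ty - 1) * (2 * ty + 5))
  v1 <- sum(tx * (tx - 1)) * sum(ty * (ty - 1)) / (2 * n * (n - 1))
  v2 <- sum(tx * (tx - 1) * (tx - 2)) * sum(ty * (ty - 1) * (ty - 2)) /
    (9 * n * (n - 1) * (n - 2))
  sigma2 <- (v0 - vt - vu) / 18 + v1 + v2
  p <- if (sigma2 <= 0) NA_real_ else 2 * stats::pnorm(-abs(s / sqrt(sigma2)))
  statResult("Kendall tau-b", s, p, n, estimate = tau)
}

#' Pearson product-moment correlation
#'
#' Standard correlation with a two-sided p from the t distribution on
#' n - 2 degrees of freedom.
#'
#' @param x,y Equal-length numeric vectors (n >= 3), neither constant.
#' @return A \code{StatResult}; \code{estimate} holds r.
#' @examples
#' pearsonR(1:3, c(2, 4, 6))$estimate  # 1
#' @export
pearsonR <- function(x, y) {
  n <- length(x)
  stopifnot(length(y) == n, n >= 3L)
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("constant input: Pearson correlation undefined")
  ct <- stats::cor.test(x, y, method = "pearson")
  statResult("Pearson correlation", unname(ct$statistic), ct$p.value, n,
             estimate = unname(ct$estimate))
}

# display-ordered index rows mirroring the clinical summary tables:
# global hemodynamics, myocardial contractility, afterload/interaction
tableRowOrder <- function() {
  c("hr", "ef", "sv", "svi", "sw", "co", "ci",
    "edv", "esv", "edp", "esp", "prsw", "dpdt_max", "dpdt_min",
    "tau_half", "ees", "sci",
    "ea", "zva", "eed", "vac_ea_ees", "vac_ees_ea")
}

#' Build the cohort summary and subgroup-delta tables
#'
#' Mean +/- SD of every index pre and post, the exact paired Wilcoxon p per
#' index with a significance marker at \code{alpha}, and per-subgroup
#' mean +/- SD of the pre-to-post deltas with the exact Mann-Whitney p.
#' With a single patient, SDs are reported as NA and no tests are run.
#' No multiple-testing correction is applied by default (exploratory
#' pilot-style reporting); \code{holm = TRUE} adjusts the paired p-values.
#'
#' @param cohort A \linkS4class{CohortTable}.
#' @param groupings Patient-table columns to build delta tables for.
#' @param alpha Significance marker level.
#' @param holm Apply a Holm adjustment to the paired p-values.
#' @return List with \code{summary} (data.frame: index, units omitted,
#'   pre/post mean and SD, p, sig) and \code{deltas} (one data.frame per
#'   grouping).
#' @examples
#' \donttest{
#' ch <- simulateCohort(n_patients = 4, seed = 7, duration = 14)
#' tb <- buildCohortTables(ch$cohort)
#' head(tb$summary)
#' }
#' @export
buildCohortTables <- function(cohort,
                              groupings = c("ef_class", "af", "mi"),
                              alpha = 0.05, holm = FALSE) {
  stopifnot(is(cohort, "CohortTable"))
  idx <- intersect(tableRowOrder(), colnames(cohort@pre))
  npat <- nrow(cohort@patients)
  one <- npat < 2L
  summ <- do.call(rbind, lapply(idx, function(j) {
    pre <- cohort@pre[, j]; post <- cohort@post[, j]
    p <- if (one || all(post - pre == 0)) NA_real_ else
      tryCatch(pairedWilcoxon(pre, post)$p, error = function(e) NA_real_)
    data.frame(index = j,
               pre_mean = mean(pre), pre_sd = if (one) NA else stats::sd(pre),
               post_mean = mean(post),
               post_sd = if (one) NA else stats::sd(post),
               p = p)
  }))
  if (holm && any(is.finite(summ$p)))
    summ$p <- stats::p.adjust(summ$p, method = "holm")
  summ$sig <- is.finite(summ$p) & summ$p < alpha
  deltas <- list()
  if (!one) {
    for (g in groupings) {
      gv <- as.factor(cohort@patients[[g]])
      if (nlevels(gv) != 2L || any(table(gv) == 0L)) next
      lv <- levels(gv)
      deltas[[g]] <- do.call(rbind, lapply(idx, function(j) {
        d <- cohort@post[, j] - cohort@pre[, j]
        p <- tryCatch(mannWhitneyU(d[gv == lv[1]], d[gv == lv[2]])$p,
                      error = function(e) NA_real_)
        data.frame(index = j,
                   g1 = lv[1], g1_mean = mean(d[gv == lv[1]]),
                   g1_sd = stats::sd(d[gv == lv[1]]),
                   g2 = lv[2], g2_mean = mean(d[gv == lv[2]]),
                   g2_sd = stats::sd(d[gv == lv[2]]),
                   p = p, sig = is.finite(p) && p < alpha)
      }))
    }
  }
  list(summary = summ, deltas = deltas)
}
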