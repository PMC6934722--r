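#' Shapiro-Wilk normality screen per group
#'
#' Advisory only: the pipeline always proceeds nonparametrically, the screen
#' records why. Groups with fewer than 3 values or zero variance are flagged
#' untestable.
#'
#' @param values numeric vector.
#' @param groups grouping vector of the same length.
#' @return data.frame with columns \code{group}, \code{n}, \code{shapiro_p},
#'   \code{testable}.
#' @export
normalityScreen <- function(values, groups) {
  stopifnot(length(values) == length(groups))
  parts <- split(values, groups)
  out <- lapply(names(parts), function(g) {
    v <- parts[[g]][is.finite(parts[[g]])]
    testable <- length(v) >= 3L && length(v) <= 5000L && stats::sd(v) > 0
    data.frame(group = g, n = length(v),
               shapiro_p = if (testable) stats::shapiro.test(v)$p.value
                           else NA_real_,
               testable = testable, stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Dunn's post-hoc test for all pairwise group comparisons
#'
#' Rank-based z tests on the joint mid-ranks with the standard tie
#' correction, the customary follow-up to a significant Kruskal-Wallis
#' omnibus. Two-sided p-values are adjusted for multiplicity
#' (Bonferroni by default); adjusted p-values are never smaller than the
#' unadjusted ones.
#'
#' @param values numeric vector.
#' @param groups grouping vector.
#' @param adjust multiplicity adjustment: \code{"bonferroni"} (default),
#'   \code{"holm"} or \code{"sidak"}.
#' @return data.frame with one row per group pair: \code{group1},
#'   \code{group2}, \code{z}, \code{p}, \code{p_adjusted}.
#' @references Dunn, O.J. (1964) Multiple comparisons using rank sums.
#'   Technometrics 6, 241-252.
#' @export
dunnTest <- function(values, groups, adjust = c("bonferroni", "holm", "sidak")) {
  adjust <- match.arg(adjust)
  ok <- is.finite(values)
  values <- values[ok]
  groups <- as.character(groups)[ok]
  lev <- unique(groups)
  if (length(lev) < 2L) stop("need at least 2 groups")
  N <- length(values)
  r <- rank(values)                       # mid-ranks
  tieSizes <- table(values)
  tieSum <- sum(tieSizes^3 - tieSizes)
  meanRank <- tapply(r, groups, mean)
  n <- tapply(r, groups, length)
  pairs <- utils::combn(lev, 2L)
  z <- p <- numeric(ncol(pairs))
  for (k in seq_len(ncol(pairs))) {
    i <- pairs[1L, k]; j <- pairs[2L, k]
    se <- sqrt((N * (N + 1) / 12 - tieSum / (12 * (N - 1))) *
               (1 / n[[i]] + 1 / n[[j]]))
    z[k] <- if (se > 0) (meanRank[[i]] - meanRank[[j]]) / se else 0
    p[k] <- 2 * stats::pnorm(-abs(z[k]))
  }
  m <- length(p)
  pAdj <- switch(adjust,
    bonferroni = pmin(1, p * m),
    holm       = stats::p.adjust(p, "holm"),
    sidak      = pmin(1, 1 - (1 - p)^m))
  pAdj <- pmax(pAdj, p)
  data.frame(group1 = pairs[1L, ], group2 = pairs[2L, ],
             z = z, p = p, p_adjusted = pAdj, stringsAsFactors = FALSE)
}

#' Compare groups for one quantity
#'
#' The pipeline's testing scheme: Shapiro-Wilk normality screen per group
#' (advisory), Kruskal-Wallis omnibus on ranks with the standard tie
#' correction, and — when the omnibus is significant at \code{alpha} — all
#' pairwise Dunn post-hoc tests with multiplicity adjustment. With exactly
#' two groups the omnibus is itself the rank-sum comparison.
#'
#' @param table data.frame of quantification records.
#' @param quantity column to compare.
#' @param groupCol grouping column (default \code{"group"}; created from
#'   tissue and condition by [groupTable()]).
#' @param alpha significance level (default 0.05).
#' @param adjust Dunn multiplicity adjustment, see [dunnTest()].
#' @return object of class \code{"GroupComparison"}: a list with the
#'   quantity, group sizes, normality screen, omnibus statistic/df/p-value,
#'   significance flag, and the Dunn table (\code{NULL} when the omnibus is
#'   not significant).
#' @export
compareGroups <- function(table, quantity, groupCol = "group", alpha = 0.05,
                          adjust = "bonferroni") {
  stopifnot(quantity %in% names(table), groupCol %in% names(table))
  values <- table[[quantity]]
  groups <- as.character(table[[groupCol]])
  ok <- is.finite(values)
  values <- values[ok]; groups <- groups[ok]
  sizes <- base::table(groups)
  if (sum(sizes >= 2L) < 2L)
    stop("need at least 2 groups with at least 2 values each")
  norm <- normalityScreen(values, groups)
  if (stats::var(values) == 0) {
    kwStat <- 0; kwDf <- length(sizes) - 1L; kwP <- 1
  } else {
    kw <- stats::kruskal.test(values, factor(groups))
    kwStat <- unname(kw$statistic); kwDf <- unname(kw$parameter)
    kwP <- kw$p.value
  }
  significant <- kwP < alpha
  dunn <- if (significant && length(sizes) >= 2L)
    dunnTest(values, groups, adjust = adjust) else NULL
  structure(list(quantity = quantity, group_sizes = sizes,
                 normality = norm, statistic = kwStat, df = kwDf,
                 p_value = kwP, alpha = alpha, significant = significant,
                 dunn = dunn),
            class = "GroupComparison")
}

#' @export
print.GroupComparison <- function(x, ...) {
  cat(sprintf("Group comparison of %s (%d groups)\n", x$quantity,
              length(x$group_sizes)))
  cat(sprintf("  Kruskal-Wallis chi-squared = %.4g, df = %d, p = %.4g%s\n",
              x$statistic, x$df, x$p_value,
              if (x$significant) sprintf(" (significant at %.2g)", x$alpha)
              else ""))
  if (!is.null(x$dunn)) {
    cat("  Dunn post-hoc (adjusted p):\n")
    for (k in seq_len(nrow(x$dunn)))
      cat(sprintf("    %s vs %s: z = %.3f, p_adj = %.4g\n",
                  x$dunn$group1[k], x$dunn$group2[k], x$dunn$z[k],
                  x$dunn$p_adjusted[k]))
  }
  invisible(x)
}
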