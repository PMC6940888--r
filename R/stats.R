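# Nonparametric statistical battery used on the kinematic records: Spearman
# rank correlation, Mood's median test, chi-square frequency test, plus the
# descriptive (mean, SE, median) and catch-and-throw summaries.

stat_result <- function(test, statistic, df, p_value, n, extra = list(),
                        flags = character(0)) {
  structure(list(test = test, statistic = statistic, df = df,
                 p_value = p_value, n = n, extra = extra, flags = flags),
            class = "stat_result")
}

#' @export
print.stat_result <- function(x, ...) {
  cat(x$test, "\n")
  cat("  statistic =", format(x$statistic), " df =", format(x$df),
      " p =", format.pval(x$p_value), "\n")
  if (length(x$flags)) cat("  flags:", paste(x$flags, collapse = ", "), "\n")
  invisible(x)
}

#' Spearman rank correlation
#'
#' Average ranks are assigned to ties; rho is the Pearson correlation of
#' the rank vectors. The two-sided p-value uses the t approximation with
#' n - 2 degrees of freedom (the standard choice at the sample sizes
#' kinematic records produce); for n <= 8 an exact permutation p-value is
#' available via `exact = TRUE`.
#'
#' @param x,y Paired numeric vectors, n >= 4, finite.
#' @param exact Use full-enumeration permutation p-value (n <= 8 only).
#' @return A `stat_result` with `extra$rho`.
#' @export
spearman_test <- function(x, y, exact = FALSE) {
  stopifnot(length(x) == length(y), length(x) >= 4,
            all(is.finite(x)), all(is.finite(y)))
  n <- length(x)
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    return(stat_result("Spearman rank correlation", NA_real_, NA_real_,
                       NA_real_, n, extra = list(rho = NA_real_),
                       flags = "constant input: rho undefined"))
  rx <- rank(x); ry <- rank(y)
  rho <- stats::cor(rx, ry)
  if (exact) {
    if (n > 8) stop("exact permutation p-value supported for n <= 8")
    perms <- permutations_of(n)
    rhos <- apply(perms, 1, function(p) stats::cor(rx, ry[p]))
    p_value <- mean(abs(rhos) >= abs(rho) - 1e-12)
    return(stat_result("Spearman rank correlation (exact)", rho, NA_real_,
                       p_value, n, extra = list(rho = rho)))
  }
  if (abs(rho) >= 1 - 1e-15) {
    p_value <- 0
  } else {
    tstat <- rho * sqrt((n - 2) / (1 - rho^2))
    p_value <- 2 * stats::pt(-abs(tstat), df = n - 2)
  }
  stat_result("Spearman rank correlation", rho, n - 2, p_value, n,
              extra = list(rho = rho))
}

permutations_of <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- permutations_of(n - 1L)
  out <- matrix(0L, nrow(sub) * n, n)
  for (k in seq_len(n)) {
    rows <- (k - 1L) * nrow(sub) + seq_len(nrow(sub))
    out[rows, ] <- cbind(sub + (sub >= k), k)
  }
  out
}

pearson_chisq <- function(tab) {
  E <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  list(statistic = sum((tab - E)^2 / E),
       df = (nrow(tab) - 1) * (ncol(tab) - 1),
       expected = E)
}

#' Mood's median test
#'
#' k-sample nonparametric comparison of medians: the pooled grand median is
#' computed, each group's counts above versus at-or-below it form a 2 x k
#' contingency table, and a Pearson chi-square with k - 1 degrees of
#' freedom is applied. Values tied with the grand median count in the
#' at-or-below row by default (`ties = "discard"` drops them instead). A
#' flag is raised when any expected count is below 5, and the test is
#' degenerate (NA statistic) when all pooled values are identical or a
#' table margin is empty.
#'
#' @param groups List of numeric vectors (>= 2 groups, pooled n >= 4).
#' @param ties `"below"` (count values equal to the grand median as below)
#'   or `"discard"`.
#' @return A `stat_result`; `extra` carries the grand median, the 2 x k
#'   table and per-group medians.
#' @export
moods_median_test <- function(groups, ties = c("below", "discard")) {
  ties <- match.arg(ties)
  stopifnot(length(groups) >= 2, all(lengths(groups) >= 1))
  pooled <- unlist(groups)
  stopifnot(length(pooled) >= 4, all(is.finite(pooled)))
  med <- stats::median(pooled)
  k <- length(groups)
  above <- vapply(groups, function(g) sum(g > med), numeric(1))
  below <- if (ties == "below")
    vapply(groups, function(g) sum(g <= med), numeric(1))
  else
    vapply(groups, function(g) sum(g < med), numeric(1))
  tab <- rbind(above = above, at_or_below = below)
  colnames(tab) <- names(groups) %||% paste0("group", seq_len(k))
  n <- colSums(tab)
  flags <- character(0)
  if (all(pooled == pooled[1]) || any(rowSums(tab) == 0) || any(n == 0)) {
    return(stat_result("Mood's median test", NA_real_, k - 1, NA_real_, n,
                       extra = list(grand_median = med, table = tab,
                                    group_medians = vapply(groups, stats::median,
                                                           numeric(1))),
                       flags = "degenerate: no variation around the grand median"))
  }
  cs <- pearson_chisq(tab)
  if (any(cs$expected < 5)) flags <- c(flags, "expected count < 5")
  stat_result("Mood's median test", cs$statistic, k - 1,
              stats::pchisq(cs$statistic, k - 1, lower.tail = FALSE), n,
              extra = list(grand_median = med, table = tab,
                           expected = cs$expected,
                           group_medians = vapply(groups, stats::median,
                                                  numeric(1))),
              flags = flags)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Pearson chi-square test of independence on a 2 x k count table
#'
#' Expected counts come from the table margins; the statistic is
#' `sum((O - E)^2 / E)` on `(r - 1)(k - 1)` degrees of freedom, without
#' continuity correction. Zero margins are a hard error.
#'
#' @param table Matrix of nonnegative integer counts.
#' @return A `stat_result` with `extra$expected` and `extra$table`.
#' @export
chi_square_independence <- function(table) {
  table <- as.matrix(table)
  stopifnot(all(table >= 0), all(table == round(table)),
            nrow(table) >= 2, ncol(table) >= 2)
  if (any(rowSums(table) == 0) || any(colSums(table) == 0))
    stop("zero margin in contingency table")
  cs <- pearson_chisq(table)
  stat_result("Chi-square test of independence", cs$statistic, cs$df,
              stats::pchisq(cs$statistic, cs$df, lower.tail = FALSE),
              sum(table),
              extra = list(expected = cs$expected, table = table))
}

#' Descriptive summary (mean, SE, median) of kinematic variables
#'
#' One row per variable x mandibulation order x feed type: sample size,
#' mean, standard error (sd / sqrt(n), NA when n < 2) and median
#' (average-of-middle-two convention). Cells with no records appear with
#' `n = 0` and NA summaries rather than zeros.
#'
#' @param records data.frame of mandibulation records (needs `order`,
#'   `feed_type` and the value columns).
#' @param variables Character vector of value columns to summarise.
#' @return data.frame: variable, order, feed_type, n, mean, se, median.
#' @export
descriptive_table <- function(records,
                              variables = c("max_gape_mm", "displacement_mm",
                                            "duration_ms", "speed_mm_s")) {
  stopifnot(nrow(records) > 0, all(variables %in% names(records)))
  grid <- expand.grid(variable = variables,
                      order = sort(unique(records$order)),
                      feed_type = sort(unique(records$feed_type)),
                      stringsAsFactors = FALSE)
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    v <- grid$variable[i]
    sel <- records$order == grid$order[i] &
      records$feed_type == grid$feed_type[i]
    x <- records[[v]][sel]
    n <- length(x)
    data.frame(variable = v, order = grid$order[i],
               feed_type = grid$feed_type[i], n = n,
               mean = if (n) mean(x) else NA_real_,
               se = if (n >= 2) stats::sd(x) / sqrt(n) else NA_real_,
               median = if (n) stats::median(x) else NA_real_)
  })
  do.call(rbind, rows)
}

#' Catch-and-throw percentages
#'
#' Percentage of mandibulations flagged as catch-and-throw, per feed type
#' and per mandibulation order within feed type.
#'
#' @param records data.frame with `feed_type`, `order` and a logical
#'   `catch_and_throw` column.
#' @return List with `per_feed` and `per_order_feed` data.frames
#'   (percentages on the 0-100 scale; feeds without records are absent).
#' @export
catch_and_throw_summary <- function(records) {
  stopifnot("catch_and_throw" %in% names(records))
  pf <- do.call(rbind, lapply(split(records, records$feed_type), function(d)
    data.frame(feed_type = d$feed_type[1], n = nrow(d),
               percent = 100 * mean(d$catch_and_throw))))
  po <- do.call(rbind, lapply(
    split(records, list(records$feed_type, records$order), drop = TRUE),
    function(d)
      data.frame(feed_type = d$feed_type[1], order = d$order[1], n = nrow(d),
                 percent = 100 * mean(d$catch_and_throw))))
  po <- po[order(po$feed_type, po$order), ]
  rownames(pf) <- rownames(po) <- NULL
  list(per_feed = pf, per_order_feed = po)
}
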