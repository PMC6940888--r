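# The statistical battery, checked against independent textbook oracles.

# textbook Spearman rho via the sum-of-squared-rank-differences formula with
# tie correction (independent of cor())
rho_textbook <- function(x, y) {
  rx <- rank(x); ry <- rank(y)
  n <- length(x)
  tie_term <- function(r) {
    t <- table(r); sum(t^3 - t) / 12
  }
  Tx <- tie_term(rx); Ty <- tie_term(ry)
  S <- (n^3 - n) / 6
  d2 <- sum((rx - ry)^2)
  (S - d2 - Tx - Ty) / (2 * sqrt((S / 2 - Tx) * (S / 2 - Ty)))
}

test_that("Spearman handles monotone, antitone and tied data", {
  x <- c(1, 2, 3, 5, 8, 13)
  expect_equal(spearman_test(x, x^3 + 1)$extra$rho, 1.0)
  expect_equal(spearman_test(x, rev(x))$extra$rho, -1.0)
  y <- c(2, 2, 5, 1, 9, 7)   # one tie pair
  r <- spearman_test(x, y)
  expect_equal(r$extra$rho, rho_textbook(x, y), tolerance = 1e-12)
  set.seed(5)
  for (i in 1:25) {
    a <- sample(1:8, 12, replace = TRUE)   # plenty of ties
    b <- sample(1:8, 12, replace = TRUE)
    if (sd(a) == 0 || sd(b) == 0) next
    expect_equal(spearman_test(a, b)$extra$rho, rho_textbook(a, b),
                 tolerance = 1e-12)
  }
  flagged <- spearman_test(rep(1, 5), 1:5)
  expect_true(is.na(flagged$extra$rho))
  expect_match(flagged$flags, "constant")
})

test_that("Spearman is invariant under strictly increasing transforms", {
  set.seed(9)
  x <- rnorm(40); y <- rnorm(40)
  r0 <- spearman_test(x, y)$extra$rho
  expect_equal(spearman_test(exp(x), y)$extra$rho, r0, tolerance = 1e-12)
  expect_equal(spearman_test(x, y^3)$extra$rho, r0, tolerance = 1e-12)
  expect_equal(spearman_test(x, x)$extra$rho, 1)
})

test_that("exact permutation p-value agrees with the t approximation at small n", {
  set.seed(13)
  x <- rnorm(7); y <- rnorm(7)
  pe <- spearman_test(x, y, exact = TRUE)$p_value
  pt_ <- spearman_test(x, y)$p_value
  expect_true(abs(pe - pt_) < 0.15)
  expect_error(spearman_test(rnorm(9), rnorm(9), exact = TRUE), "n <= 8")
})

test_that("Mood's median test matches hand-computed tables", {
  same <- moods_median_test(list(c(1, 2, 3, 4), c(1, 2, 3, 4)))
  expect_equal(same$statistic, 0)
  expect_equal(same$p_value, 1)
  r <- moods_median_test(list(rep(1, 4), rep(9, 4)))
  expect_equal(r$statistic, 8)
  expect_equal(r$df, 1)
  expect_true("expected count < 5" %in% r$flags)
  deg <- moods_median_test(list(rep(2, 4), rep(2, 3)))
  expect_true(is.na(deg$statistic))
  expect_match(deg$flags, "degenerate")
})

test_that("Mood's median test equals the explicit-count + chi-square oracle", {
  set.seed(17)
  for (i in 1:100) {
    g <- lapply(1:3, function(k) rnorm(sample(10:30, 1), mean = k / 2))
    r <- moods_median_test(g)
    med <- median(unlist(g))
    tab <- rbind(sapply(g, function(v) sum(v > med)),
                 sapply(g, function(v) sum(v <= med)))
    o <- suppressWarnings(chisq.test(tab, correct = FALSE))
    expect_equal(r$statistic, unname(o$statistic), tolerance = 1e-12)
    expect_equal(r$p_value, unname(o$p.value), tolerance = 1e-12)
    expect_equal(r$df, unname(o$parameter))
  }
})

test_that("tie policy 'discard' drops values equal to the grand median", {
  g <- list(c(1, 2, 2, 3), c(2, 4, 5, 6))
  r <- moods_median_test(g, ties = "discard")
  med <- median(unlist(g))
  expect_equal(unname(colSums(r$extra$table)),
               sapply(g, function(v) sum(v != med)))
})

test_that("chi-square independence follows the hand formula", {
  tab <- matrix(c(10, 20, 20, 10), 2)
  r <- chi_square_independence(tab)
  expect_equal(r$statistic, 20 / 3, tolerance = 1e-12)   # 4 * 25 / 15
  expect_equal(r$df, 1)
  # a table equal to its own expected counts scores zero
  tab0 <- matrix(c(10, 20, 30, 60, 5, 10), 2)
  e <- outer(rowSums(tab0), colSums(tab0)) / sum(tab0)
  expect_equal(chi_square_independence(e)$statistic, 0, tolerance = 1e-12)
  expect_equal(chi_square_independence(matrix(1:6, 2))$df, 2)
  expect_error(chi_square_independence(matrix(c(0, 0, 2, 3), 2)), "margin")
  o <- suppressWarnings(chisq.test(tab, correct = FALSE))
  expect_equal(r$p_value, unname(o$p.value), tolerance = 1e-12)
})

test_that("descriptive table matches a brute-force two-pass computation", {
  rec <- data.frame(order = c(1, 1, 2, 2, 2), feed_type = "F1",
                    max_gape_mm = c(2, 4, 3, 5, 7))
  d <- descriptive_table(rec, "max_gape_mm")
  r1 <- d[d$order == 1, ]
  expect_equal(r1$mean, 3); expect_equal(r1$se, 1); expect_equal(r1$median, 3)
  # single-value cell: SE missing
  rec2 <- rbind(rec, data.frame(order = 3, feed_type = "F1", max_gape_mm = 9))
  d2 <- descriptive_table(rec2, "max_gape_mm")
  expect_true(is.na(d2$se[d2$order == 3]))
  # brute-force check on random records
  set.seed(23)
  big <- data.frame(order = sample(1:4, 200, TRUE),
                    feed_type = sample(c("F1", "F2"), 200, TRUE),
                    max_gape_mm = rnorm(200, 3))
  db <- descriptive_table(big, "max_gape_mm")
  for (i in seq_len(nrow(db))) {
    v <- big$max_gape_mm[big$order == db$order[i] &
                           big$feed_type == db$feed_type[i]]
    m <- sum(v) / length(v)
    s <- sqrt(sum((v - m)^2) / (length(v) - 1)) / sqrt(length(v))
    expect_equal(db$mean[i], m, tolerance = 1e-12)
    expect_equal(db$se[i], s, tolerance = 1e-12)
  }
})

test_that("catch-and-throw percentages are flagged fractions per feed", {
  rec <- data.frame(feed_type = rep(c("F1", "F2"), c(100, 50)),
                    order = 1,
                    catch_and_throw = c(rep(c(TRUE, FALSE), c(26, 74)),
                                        rep(TRUE, 50)))
  s <- catch_and_throw_summary(rec)
  expect_equal(s$per_feed$percent[s$per_feed$feed_type == "F1"], 26)
  expect_equal(s$per_feed$percent[s$per_feed$feed_type == "F2"], 100)
})
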