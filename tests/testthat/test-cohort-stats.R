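mkRecord <- function(id, class, resp = "neither") {
  data.frame(cell_id = as.character(id), sample_id = "s1", gsmtx4 = FALSE,
             yoda1 = FALSE, class = class, response_PIII = resp,
             stringsAsFactors = FALSE)
}

test_that("sample summaries count classes and split responses by activity type", {
  recs <- do.call(rbind, c(
    lapply(1:5, mkRecord, class = "SPONTANEOUS", resp = "oscillating"),
    lapply(6:9, mkRecord, class = "STRETCH_ACTIVATED", resp = "sustained"),
    list(mkRecord(10, "NO_PEAKS"))))
  s <- summarizeSample(recs)
  expect_equal(s$n_cells, 10L)
  expect_equal(unname(s$class_percent),  c(50, 40, 0, 10))
  expect_equal(sum(s$class_percent), 100)
  expect_equal(unname(s$response_percent["SPONTANEOUS", "oscillating"]), 100)
  expect_equal(unname(s$response_percent["STRETCH_ACTIVATED", "sustained"]), 100)

  one <- do.call(rbind, lapply(1:4, mkRecord, class = "SPONTANEOUS"))
  expect_equal(unname(summarizeSample(one)$class_percent["SPONTANEOUS"]), 100)

  empty <- summarizeSample(recs[0, ])
  expect_equal(empty$n_cells, 0L)

  expect_error(summarizeSample(rbind(recs, within(mkRecord(11, "NO_PEAKS"),
                                                  sample_id <- "s2"))),
               "single sample")
})

test_that("boxplot summaries use quartiles with 5-95% whiskers", {
  b <- boxplotSummary(1:100)
  expect_equal(unname(b[c("median", "q1", "q3")]), c(50.5, 25.75, 75.25))
  expect_equal(unname(b["whisker_low"]), 5.95)
  expect_equal(unname(b["whisker_high"]), 95.05)
  expect_equal(unname(b["n"]), 100)

  const <- boxplotSummary(rep(3.2, 10))
  expect_true(all(const[1:5] == 3.2))
  single <- boxplotSummary(7)
  expect_true(all(single[1:5] == 7))
  expect_true(is.na(boxplotSummary(numeric())[["median"]]))
  ## ordering invariant
  set.seed(5)
  x <- rexp(40)
  b2 <- boxplotSummary(x)
  expect_true(b2["whisker_low"] <= b2["q1"] && b2["q1"] <= b2["median"] &&
              b2["median"] <= b2["q3"] && b2["q3"] <= b2["whisker_high"])
})

test_that("the comparison gate picks ANOVA for normal groups and Kruskal-Wallis otherwise", {
  set.seed(8)
  a <- rnorm(40); b <- rnorm(40, 0.2)
  cmp <- compareGroups(a, b)
  expect_equal(cmp$test, "anova")
  expect_true(all(cmp$normality_p > 0.05))

  e <- rexp(50)
  cmp2 <- compareGroups(e, rnorm(50, 1))
  expect_equal(cmp2$test, "kruskal")

  ## identical groups are never significant
  x <- rnorm(20)
  cmp3 <- compareGroups(x, x)
  expect_false(cmp3$significant)
  expect_error(compareGroups(rnorm(2), rnorm(10)), "at least 3")
})

test_that("two-group Kruskal-Wallis equals the rank-sum chi-square transform", {
  set.seed(9)
  for (case in 1:20) {
    n1 <- sample(5:30, 1L); n2 <- sample(5:30, 1L)
    a <- rnorm(n1); b <- rexp(n2)     # continuous: no ties
    H <- kruskal.test(c(a, b), factor(rep(1:2, c(n1, n2))))$statistic
    N <- n1 + n2
    R1 <- sum(rank(c(a, b))[seq_len(n1)])
    Hmanual <- 12 / (N * (N + 1)) *
      (R1 - n1 * (N + 1) / 2)^2 * N / (n1 * n2)
    expect_equal(unname(H), Hmanual, tolerance = 1e-10)
  }
})

test_that("pairwise comparison tables carry stars and optional Holm correction", {
  set.seed(10)
  g <- list(a = rnorm(20), b = rnorm(20, 3), c = rnorm(20))
  tab <- compareAllPairs(g)
  expect_equal(nrow(tab), 3L)
  ab <- tab[tab$group_a == "a" & tab$group_b == "b", ]
  expect_true(ab$significant)
  expect_true(ab$stars %in% c("*", "**", "***"))
  tabH <- compareAllPairs(g, holm = TRUE)
  expect_true(all(tabH$p_adjusted >= tab$p_adjusted))
})
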