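#' Summarise one sample's cell records
#'
#' Computes, for one sample (replicate), the fraction of cells in each
#' activity class and — separately for the spontaneously-active and the
#' stretch-activated subsets, which may represent different physiological
#' states — the fraction of cells in each stretch/release response category.
#' Percentages are assessed per sample before any pooling across replicates.
#'
#' @param records cell-record data.frame from \code{\link{classifyCells}};
#'   all rows must share \code{sample_id}.
#' @return A list: \code{sample_id}, \code{n_cells}, \code{condition},
#'   \code{class_percent} (named numeric over the four activity classes,
#'   computed over classified cells), and \code{response_percent} (matrix:
#'   rows \code{SPONTANEOUS}/\code{STRETCH_ACTIVATED}, columns response
#'   categories of \code{PIII}).
#' @export
summarizeSample <- function(records) {
  if (is.null(records) || nrow(records) == 0L)
    return(list(sample_id = NA_character_, n_cells = 0L,
                condition = c(gsmtx4 = NA, yoda1 = NA),
                class_percent = setNames(rep(NA_real_, 4L), ACTIVITY_CLASSES[1:4]),
                response_percent = NULL))
  sid <- unique(records$sample_id)
  if (length(sid) != 1L) stop("records must come from a single sample")
  classified <- records[records$class != "INCOMPLETE", , drop = FALSE]
  n <- nrow(classified)
  classPct <- setNames(vapply(ACTIVITY_CLASSES[1:4], function(k)
    if (n) 100 * sum(classified$class == k) / n else NA_real_, numeric(1L)),
    ACTIVITY_CLASSES[1:4])
  respCats <- c("sustained", "oscillating", "neither")
  respPct <- matrix(NA_real_, 2L, 3L,
                    dimnames = list(c("SPONTANEOUS", "STRETCH_ACTIVATED"), respCats))
  for (g in rownames(respPct)) {
    sub <- classified[classified$class == g, , drop = FALSE]
    if (nrow(sub))
      respPct[g, ] <- vapply(respCats, function(k)
        100 * sum(sub$response_PIII == k, na.rm = TRUE) / nrow(sub), numeric(1L))
  }
  list(sample_id = sid, n_cells = n,
       condition = c(gsmtx4 = isTRUE(records$gsmtx4[1L]),
                     yoda1 = isTRUE(records$yoda1[1L])),
       class_percent = classPct, response_percent = respPct)
}

#' Five-number boxplot summary
#'
#' Order statistics used for per-sample summary plots: quartile box with
#' whiskers at the 5th and 95th percentiles (linear-interpolation
#' percentiles, type 7).
#'
#' @param values numeric vector.
#' @return A named numeric vector: \code{whisker_low} (5th percentile),
#'   \code{q1}, \code{median}, \code{q3}, \code{whisker_high} (95th
#'   percentile), \code{n}; all statistics \code{NA} for empty input.
#' @examples
#' boxplotSummary(1:100)
#' @export
boxplotSummary <- function(values) {
  values <- values[is.finite(values)]
  if (!length(values))
    return(c(whisker_low = NA_real_, q1 = NA_real_, median = NA_real_,
             q3 = NA_real_, whisker_high = NA_real_, n = 0))
  q <- quantile(values, c(0.05, 0.25, 0.5, 0.75, 0.95), type = 7, names = FALSE)
  c(whisker_low = q[1L], q1 = q[2L], median = q[3L], q3 = q[4L],
    whisker_high = q[5L], n = length(values))
}

#' Normality-gated two-group comparison
#'
#' Implements the gated testing protocol: both groups are first checked for
#' normality with the Shapiro-Wilk test. If both pass (p > alpha), a one-way
#' ANOVA compares the group means; if either fails, the nonparametric
#' Kruskal-Wallis H test is applied. Significance is declared at
#' p < alpha (default 0.05).
#'
#' @param a,b numeric vectors, each with at least 3 values.
#' @param alpha significance level for both the normality gate and the
#'   comparison (default 0.05).
#' @return A list: \code{groups} (sizes), \code{normality_p} (two
#'   Shapiro-Wilk p-values), \code{test} (\code{"anova"} or
#'   \code{"kruskal"}), \code{statistic}, \code{p_value},
#'   \code{significant}.
#' @examples
#' compareGroups(rnorm(20), rnorm(20, 1))
#' @export
compareGroups <- function(a, b, alpha = 0.05) {
  a <- as.numeric(a); b <- as.numeric(b)
  if (length(a) < 3L || length(b) < 3L)
    stop("each group needs at least 3 values for the normality gate")
  swP <- function(x) {
    if (length(unique(x)) < 3L) return(0)   # degenerate: treat as non-normal
    shapiro.test(x)$p.value
  }
  normP <- c(swP(a), swP(b))
  values <- c(a, b)
  group <- factor(rep(c("a", "b"), c(length(a), length(b))))
  if (all(normP > alpha)) {
    fit <- oneway.test(values ~ group, var.equal = TRUE)
    test <- "anova"; stat <- unname(fit$statistic); p <- fit$p.value
  } else {
    fit <- kruskal.test(values, group)
    test <- "kruskal"; stat <- unname(fit$statistic); p <- fit$p.value
  }
  list(groups = c(n_a = length(a), n_b = length(b)), normality_p = normP,
       test = test, statistic = stat, p_value = p,
       significant = is.finite(p) && p < alpha)
}

#' Compare a metric between conditions across many pairs
#'
#' Applies \code{\link{compareGroups}} to each requested pair of groups and
#' assembles a comparison table with significance stars
#' (\code{*} p < 0.05, \code{**} p < 0.01, \code{***} p < 0.001). An
#' optional Holm correction over the set of pairs can be switched on; the
#' default follows the two-groups-at-a-time protocol without multiplicity
#' correction.
#'
#' @param groups named list of numeric vectors.
#' @param pairs list of character pairs to compare; defaults to all pairs.
#' @param alpha significance level.
#' @param holm apply a Holm correction across the pairs (default
#'   \code{FALSE}).
#' @return A data.frame: group_a, group_b, test, statistic, p_value,
#'   p_adjusted, significant, stars.
#' @export
compareAllPairs <- function(groups, pairs = NULL, alpha = 0.05, holm = FALSE) {
  if (is.null(pairs)) {
    nm <- names(groups)
    pairs <- if (length(nm) >= 2L)
      utils::combn(nm, 2L, simplify = FALSE) else list()
  }
  rows <- lapply(pairs, function(pr) {
    cmp <- compareGroups(groups[[pr[1L]]], groups[[pr[2L]]], alpha)
    data.frame(group_a = pr[1L], group_b = pr[2L], test = cmp$test,
               statistic = cmp$statistic, p_value = cmp$p_value,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) return(NULL)
  out$p_adjusted <- if (holm) stats::p.adjust(out$p_value, "holm") else out$p_value
  out$significant <- out$p_adjusted < alpha
  out$stars <- vapply(out$p_adjusted, function(p)
    if (!is.finite(p)) "" else if (p < 0.001) "***" else if (p < 0.01) "**"
    else if (p < 0.05) "*" else "", character(1L))
  out
}
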