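#' Standardized mean difference for a continuous covariate
#'
#' `|mean1 - mean2| / sqrt((sd1^2 + sd2^2) / 2)` — the absolute difference in
#' group means scaled by the pooled (unweighted average) standard deviation.
#'
#' @param mean1,sd1 Mean and standard deviation in group 1.
#' @param mean2,sd2 Mean and standard deviation in group 2.
#' @return Non-negative scalar.
#' @export
smd_continuous <- function(mean1, sd1, mean2, sd2) {
  if (sd1 <= 0 || sd2 <= 0) {
    stop_domain("standard deviations must be strictly positive")
  }
  abs(mean1 - mean2) / sqrt((sd1^2 + sd2^2) / 2)
}

#' Standardized mean difference for a binary covariate
#'
#' With group proportions `p1 = x1/n1`, `p2 = x2/n2`:
#' `|p1 - p2| / sqrt((p1(1-p1) + p2(1-p2)) / 2)`. Degenerate groups with
#' identical proportions of 0 or 1 return 0 (the 0/0 case).
#'
#' @param x1,n1 Count with the attribute and group size, group 1.
#' @param x2,n2 Same for group 2.
#' @return Non-negative scalar.
#' @export
smd_binary <- function(x1, n1, x2, n2) {
  if (n1 <= 0 || n2 <= 0) stop_domain("group sizes must be positive")
  if (x1 < 0 || x1 > n1 || x2 < 0 || x2 > n2) {
    stop_domain("counts must satisfy 0 <= x <= n")
  }
  p1 <- x1 / n1
  p2 <- x2 / n2
  pooled <- (p1 * (1 - p1) + p2 * (1 - p2)) / 2
  if (pooled == 0) {
    if (p1 == p2) return(0)
    stop_domain("degenerate groups with unequal proportions have undefined SMD")
  }
  abs(p1 - p2) / sqrt(pooled)
}

#' Mahalanobis-type standardized mean difference for a multicategory covariate
#'
#' The Yang-Dalton generalization: with category proportion vectors `p1`,
#' `p2` over K categories, drop one category, form the difference vector
#' `T = p1[-K] - p2[-K]` and the averaged multinomial covariance matrix `S`
#' (diagonal `(p1k(1-p1k) + p2k(1-p2k))/2`, off-diagonal
#' `-(p1k p1l + p2k p2l)/2`), and return `sqrt(T' S^-1 T)`. A Moore-Penrose
#' pseudo-inverse is used when `S` is singular (e.g. empty categories). The
#' result does not depend on which category is dropped.
#'
#' @param counts1,counts2 Equal-length (K >= 2) vectors of category counts.
#' @return Non-negative scalar.
#' @export
smd_multicategory <- function(counts1, counts2) {
  if (length(counts1) != length(counts2)) {
    stop_domain("category count vectors must have equal length")
  }
  k <- length(counts1)
  if (k < 2) stop_domain("need at least 2 categories")
  if (sum(counts1) <= 0 || sum(counts2) <= 0) {
    stop_domain("each group must have a positive total count")
  }
  p1 <- counts1 / sum(counts1)
  p2 <- counts2 / sum(counts2)
  t_vec <- (p1 - p2)[-k]
  s <- matrix(0, k - 1, k - 1)
  for (i in seq_len(k - 1)) {
    for (j in seq_len(k - 1)) {
      s[i, j] <- if (i == j) {
        (p1[i] * (1 - p1[i]) + p2[i] * (1 - p2[i])) / 2
      } else {
        -(p1[i] * p1[j] + p2[i] * p2[j]) / 2
      }
    }
  }
  s_inv <- tryCatch(solve(s), error = function(e) MASS::ginv(s))
  value <- sqrt(max(0, drop(t(t_vec) %*% s_inv %*% t_vec)))
  value
}

smd_from_logical <- function(x1, x2) {
  smd_binary(sum(x1), length(x1), sum(x2), length(x2))
}

smd_from_numeric <- function(x1, x2) {
  x1 <- x1[!is.na(x1)]
  x2 <- x2[!is.na(x2)]
  s1 <- sd(x1)
  s2 <- sd(x2)
  if (s1 == 0 && s2 == 0) {
    if (mean(x1) == mean(x2)) return(0)
    return(Inf)
  }
  # a single zero-variance arm still has a defined pooled scale
  abs(mean(x1) - mean(x2)) / sqrt((s1^2 + s2^2) / 2)
}

median_iqr <- function(x) {
  x <- x[!is.na(x)]
  q <- quantile(x, c(0.25, 0.5, 0.75), names = FALSE, type = 7)
  sprintf("%.2f (%.2f-%.2f)", q[2], q[1], q[3])
}

n_pct <- function(x) sprintf("%d (%.1f)", sum(x), 100 * mean(x))

covariate_types <- function() {
  tibble(
    covariate = COVARIATE_NAMES,
    type = c("continuous", "binary", "multicategory", "continuous",
             "continuous", "multicategory", "binary", "multicategory",
             "multicategory", rep("binary", 5), "multicategory",
             "continuous", "continuous", rep("binary", 5))
  )
}

#' Covariate balance between fillers and non-fillers
#'
#' Dispatches each of the 22 contextual covariates to the matching SMD
#' routine ([smd_continuous()], [smd_binary()], [smd_multicategory()]) and
#' summarizes each group (median (IQR) for continuous covariates, n (%) for
#' categorical ones). An SMD above 0.10 flags imbalance.
#'
#' @param rows Covariate table from [build_covariate_table()].
#' @param threshold Imbalance threshold on the SMD scale (default 0.10).
#' @return An `smd_report` tibble: `covariate`, `type`, `summary_filled`,
#'   `summary_not_filled`, `smd`, `imbalance`; group sizes are attached as
#'   attributes `n_filled` / `n_not_filled`.
#' @export
balance_table <- function(rows, threshold = 0.10) {
  check_columns(rows, c("fill_status", COVARIATE_NAMES), "covariate table")
  g1 <- rows |> filter(.data$fill_status)
  g2 <- rows |> filter(!.data$fill_status)
  if (nrow(g1) == 0 || nrow(g2) == 0) {
    stop_analysis("both fill-status groups must be nonempty")
  }
  spec <- covariate_types()
  report <- purrr::pmap_dfr(spec, function(covariate, type) {
    x1 <- g1[[covariate]]
    x2 <- g2[[covariate]]
    if (type == "continuous") {
      value <- smd_from_numeric(x1, x2)
      s1 <- median_iqr(x1)
      s2 <- median_iqr(x2)
    } else if (type == "binary") {
      if (is.factor(x1)) {  # two-level factor: second level counted
        lev <- levels(x1)[2]
        x1 <- x1 == lev
        x2 <- x2 == lev
      }
      value <- smd_from_logical(x1, x2)
      s1 <- n_pct(x1)
      s2 <- n_pct(x2)
    } else {
      c1 <- table(x1)
      c2 <- table(x2)
      value <- smd_multicategory(as.numeric(c1), as.numeric(c2))
      s1 <- paste(sprintf("%s %d", names(c1), as.integer(c1)), collapse = "; ")
      s2 <- paste(sprintf("%s %d", names(c2), as.integer(c2)), collapse = "; ")
    }
    tibble(covariate = covariate, type = type,
           summary_filled = s1, summary_not_filled = s2, smd = value,
           imbalance = value > threshold)
  })
  attr(report, "n_filled") <- nrow(g1)
  attr(report, "n_not_filled") <- nrow(g2)
  class(report) <- c("smd_report", class(report))
  report
}
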