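#' D'Agostino-Pearson omnibus normality test
#'
#' Combines the transformed sample skewness Z(sqrt(b1)) and kurtosis
#' Z(b2) into K2 = Z1^2 + Z2^2, referred to a chi-squared distribution
#' with 2 df (D'Agostino, Belanger & D'Agostino Jr, 1990). Requires
#' n >= 8.
#'
#' @param x numeric sample.
#' @return list `statistic` (K2), `p_value`, `z_skewness`, `z_kurtosis`.
#' @export
dagostino_pearson <- function(x) {
  x <- x[is.finite(x)]
  n <- length(x)
  abort_if(n < 8, "D'Agostino-Pearson test requires n >= 8")
  m <- mean(x)
  m2 <- mean((x - m)^2); m3 <- mean((x - m)^3); m4 <- mean((x - m)^4)
  abort_if(m2 <= 0, "sample has zero variance")
  b1 <- m3 / m2^1.5
  b2 <- m4 / m2^2

  # skewness: Johnson SU transformation
  Y <- b1 * sqrt((n + 1) * (n + 3) / (6 * (n - 2)))
  beta2 <- 3 * (n^2 + 27 * n - 70) * (n + 1) * (n + 3) /
    ((n - 2) * (n + 5) * (n + 7) * (n + 9))
  W2 <- -1 + sqrt(2 * (beta2 - 1))
  delta <- 1 / sqrt(log(sqrt(W2)))
  alpha <- sqrt(2 / (W2 - 1))
  Z1 <- delta * asinh(Y / alpha)

  # kurtosis: Anscombe-Glynn transformation
  Eb2 <- 3 * (n - 1) / (n + 1)
  Vb2 <- 24 * n * (n - 2) * (n - 3) / ((n + 1)^2 * (n + 3) * (n + 5))
  xk <- (b2 - Eb2) / sqrt(Vb2)
  sqbeta1 <- 6 * (n^2 - 5 * n + 2) / ((n + 7) * (n + 9)) *
    sqrt(6 * (n + 3) * (n + 5) / (n * (n - 2) * (n - 3)))
  A <- 6 + 8 / sqbeta1 * (2 / sqbeta1 + sqrt(1 + 4 / sqbeta1^2))
  Z2 <- ((1 - 2 / (9 * A)) -
           ((1 - 2 / A) / (1 + xk * sqrt(2 / (A - 4))))^(1 / 3)) /
    sqrt(2 / (9 * A))

  K2 <- Z1^2 + Z2^2
  list(statistic = K2, p_value = stats::pchisq(K2, 2, lower.tail = FALSE),
       z_skewness = Z1, z_kurtosis = Z2)
}

p_stars <- function(p) {
  dplyr::case_when(p < 0.001 ~ "***", p < 0.01 ~ "**",
                   p < 0.05 ~ "*", TRUE ~ "ns")
}

#' Compare two groups with the normality-gated test choice
#'
#' Both groups are tested for normality with the D'Agostino-Pearson
#' test; if both pass at `alpha`, a two-tailed Welch's t-test (no equal
#' variance assumption) is used, otherwise the two-tailed Mann-Whitney U
#' test. Groups smaller than 8 cannot be normality-tested, so the
#' nonparametric test is forced. The Mann-Whitney p-value is exact for
#' small tie-free samples and uses the tie-corrected normal
#' approximation otherwise.
#'
#' @param a,b numeric samples (each n >= 3).
#' @param alpha normality-test level.
#' @return one-row tibble of class `group_comparison`: group sizes,
#'   normality p-values, chosen `test`, `statistic`, two-tailed
#'   `p_value`, `stars`.
#' @export
compare_groups <- function(a, b, alpha = 0.05) {
  a <- a[is.finite(a)]; b <- b[is.finite(b)]
  abort_if(length(a) < 3 || length(b) < 3, "each group needs n >= 3")
  can_test <- length(a) >= 8 && length(b) >= 8
  p_norm_a <- if (can_test) dagostino_pearson(a)$p_value else NA_real_
  p_norm_b <- if (can_test) dagostino_pearson(b)$p_value else NA_real_
  use_welch <- can_test && p_norm_a > alpha && p_norm_b > alpha
  if (use_welch) {
    ht <- stats::t.test(a, b, var.equal = FALSE)
    test <- "welch_t"
  } else {
    ht <- suppressWarnings(
      stats::wilcox.test(a, b, exact = length(a) <= 8 && length(b) <= 8,
                         correct = FALSE))
    test <- "mann_whitney_u"
  }
  out <- tibble::tibble(
    n_a = length(a), n_b = length(b),
    normality_p_a = p_norm_a, normality_p_b = p_norm_b,
    test = test,
    statistic = unname(ht$statistic),
    p_value = ht$p.value,
    stars = p_stars(ht$p.value))
  class(out) <- c("group_comparison", class(out))
  out
}

#' Boxplot statistics (25th-75th percentiles, median, min-max whiskers)
#'
#' Quartiles use linear interpolation (type 7).
#'
#' @param x numeric sample.
#' @return one-row tibble `n, min, q25, median, q75, max, mean`.
#' @export
box_stats <- function(x) {
  x <- x[is.finite(x)]
  q <- stats::quantile(x, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
  tibble::tibble(n = length(x), min = min(x), q25 = q[1], median = q[2],
                 q75 = q[3], max = max(x), mean = mean(x))
}

#' Figure-ready group summary with pairwise comparisons
#'
#' @param data data frame with a value column and a grouping column.
#' @param value,group column names (strings).
#' @param comparisons list of 2-vectors of group labels to compare;
#'   default: every group against the first.
#' @return list: `summary` tibble (box stats per group), `comparisons`
#'   tibble ([compare_groups()] rows with labels). Empty groups are
#'   dropped with a warning.
#' @export
build_report <- function(data, value, group, comparisons = NULL) {
  vals <- split(data[[value]], data[[group]])
  sizes <- purrr::map_int(vals, ~ sum(is.finite(.x)))
  if (any(sizes == 0)) {
    rlang::warn(paste("dropping empty group(s):",
                      paste(names(vals)[sizes == 0], collapse = ", ")))
    vals <- vals[sizes > 0]
  }
  abort_if(length(vals) == 0, "no non-empty groups")
  summary <- purrr::imap_dfr(vals, ~ dplyr::bind_cols(tibble::tibble(group = .y),
                                                      box_stats(.x)))
  comp <- NULL
  if (length(vals) >= 2) {
    if (is.null(comparisons)) {
      comparisons <- purrr::map(names(vals)[-1], ~ c(names(vals)[1], .x))
    }
    comp <- purrr::map_dfr(comparisons, function(pr) {
      dplyr::bind_cols(tibble::tibble(group_a = pr[1], group_b = pr[2]),
                       compare_groups(vals[[pr[1]]], vals[[pr[2]]]))
    })
  }
  list(summary = summary, comparisons = comp)
}

#' Boxplot of a grouped report
#'
#' @inheritParams build_report
#' @return a ggplot object (boxes: quartiles and median; whiskers:
#'   min-max).
#' @export
plot_report <- function(data, value, group) {
  ggplot2::ggplot(data, ggplot2::aes(.data[[group]], .data[[value]])) +
    ggplot2::geom_boxplot(coef = Inf) +
    ggplot2::geom_jitter(width = 0.15, alpha = 0.4, size = 0.8) +
    ggplot2::theme_classic()
}
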