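#' Normality gate for choosing the statistical branch
#'
#' Kolmogorov-Smirnov test of the sample against a normal distribution with
#' the sample's own mean and standard deviation. Non-normal samples (p below
#' `alpha`, or constant samples by convention) are routed to the
#' nonparametric branch (Friedman / Wilcoxon).
#'
#' @param values numeric sample, n >= 5.
#' @param alpha significance level.
#' @return list with `normal` (logical), `p_value`, `n`.
#' @export
normality_gate <- function(values, alpha = 0.05) {
  values <- values[!is.na(values)]
  if (length(values) < 5) stop("normality gate needs n >= 5", call. = FALSE)
  if (stats::sd(values) == 0) {
    return(list(normal = FALSE, p_value = 0, n = length(values)))
  }
  p <- suppressWarnings(
    stats::ks.test(values, "pnorm", mean(values), stats::sd(values))$p.value
  )
  list(normal = p >= alpha, p_value = p, n = length(values))
}

# Exact null distribution of the (untied) Friedman statistic for k = 3:
# dynamic programme over the joint distribution of the first two rank sums,
# each subject contributing a uniformly random permutation of (1, 2, 3).
# Cached per n.
friedman_exact_cache <- new.env(parent = emptyenv())
friedman_exact_null <- function(n) {
  key <- as.character(n)
  hit <- friedman_exact_cache[[key]]
  if (!is.null(hit)) return(hit)
  perms <- rbind(c(1, 2), c(1, 3), c(2, 1), c(2, 3), c(3, 1), c(3, 2))
  sz <- 3 * n + 1
  P <- matrix(0, sz, sz)
  P[1, 1] <- 1
  for (i in seq_len(n)) {
    Q <- matrix(0, sz, sz)
    for (j in seq_len(6)) {
      a <- perms[j, 1]; b <- perms[j, 2]
      Q[(a + 1):sz, (b + 1):sz] <- Q[(a + 1):sz, (b + 1):sz] +
        P[seq_len(sz - a), seq_len(sz - b)] / 6
    }
    P <- Q
  }
  idx <- which(P > 0, arr.ind = TRUE)
  r1 <- idx[, 1] - 1
  r2 <- idx[, 2] - 1
  r3 <- 6 * n - r1 - r2
  s <- 12 / (n * 3 * 4) * ((r1 - 2 * n)^2 + (r2 - 2 * n)^2 + (r3 - 2 * n)^2)
  out <- list(s = s, prob = P[idx])
  friedman_exact_cache[[key]] <- out
  out
}

#' Friedman test with Dunn's multiple comparisons
#'
#' Omnibus Friedman test on within-subject midranks, followed by Dunn's
#' pairwise z-tests on mean ranks with a Bonferroni adjustment over the
#' condition pairs (the "Dunn's multiple comparisons" convention of common
#' graphing software). For the three-condition design without ties and up
#' to 30 subjects the omnibus p-value is computed from the exact
#' permutation null distribution of the statistic (the chi-square
#' approximation is visibly miscalibrated at these sizes); with ties or
#' larger samples the tie-corrected chi-square approximation is used.
#' Rows (subjects) with any missing value are dropped (complete cases
#' only).
#'
#' @param values numeric matrix or data frame, one row per subject, one
#'   column per condition (>= 3 subjects, >= 3 conditions).
#' @return a `friedman_dunn` list: `omnibus` tibble (`statistic`, `df`,
#'   `p_value`, `n`, `method`), `pairwise` tibble (`comparison`, `z`,
#'   `p_raw`, `p_adj`, `n`).
#' @export
friedman_dunn <- function(values) {
  m <- as.matrix(values)
  m <- m[stats::complete.cases(m), , drop = FALSE]
  n <- nrow(m); k <- ncol(m)
  if (n < 3 || k < 3) stop("need >= 3 subjects and >= 3 conditions", call. = FALSE)
  cn <- colnames(m)
  if (is.null(cn)) cn <- paste0("cond", seq_len(k))
  r <- t(apply(m, 1, rank))  # midranks within subject
  col_sums <- colSums(r)
  has_ties <- any(apply(m, 1, function(row) anyDuplicated(row) > 0))
  # tie-robust form: chi2 = (k-1) * SS_treatment / SS_total of the ranks
  ss_t <- sum((col_sums - n * (k + 1) / 2)^2) / n
  ss_tot <- sum(r^2) - n * k * (k + 1)^2 / 4
  if (ss_tot == 0) {
    stat <- 0; p <- 1; method <- "degenerate"
  } else {
    stat <- (k - 1) * n * ss_t / ss_tot
    if (!has_ties && k == 3 && n <= 30) {
      null_dist <- friedman_exact_null(n)
      p <- sum(null_dist$prob[null_dist$s >= stat - 1e-9])
      method <- "exact"
    } else {
      p <- stats::pchisq(stat, df = k - 1, lower.tail = FALSE)
      method <- "chisq"
    }
  }
  pairs <- utils::combn(k, 2)
  n_comp <- ncol(pairs)
  se <- sqrt(k * (k + 1) / (6 * n))
  pw <- lapply(seq_len(n_comp), function(i) {
    a <- pairs[1, i]; b <- pairs[2, i]
    z <- (col_sums[a] / n - col_sums[b] / n) / se
    p_raw <- 2 * stats::pnorm(-abs(z))
    tibble(comparison = paste(cn[a], "vs", cn[b]), z = unname(z),
           p_raw = p_raw, p_adj = min(1, p_raw * n_comp), n = n)
  })
  structure(list(
    omnibus = tibble(statistic = stat, df = k - 1, p_value = p, n = n,
                     method = method),
    pairwise = dplyr::bind_rows(pw)
  ), class = "friedman_dunn")
}

#' Wilcoxon signed-rank test
#'
#' Two-sided signed-rank test of paired samples (`x` vs `y`) or of one
#' sample against a reference value `mu`. Zero differences are dropped
#' (standard signed-rank convention); if all differences are zero the
#' p-value is 1. The exact distribution is used for n <= 25 without ties,
#' the tie-corrected normal approximation otherwise.
#'
#' @param x numeric sample.
#' @param y optional paired sample.
#' @param mu reference value for the one-sample form.
#' @return list with `statistic` (V), `p_value`, `n` (non-zero differences),
#'   `test`.
#' @export
wilcoxon_signed_rank <- function(x, y = NULL, mu = 0) {
  d <- if (is.null(y)) x - mu else x - y
  d <- d[!is.na(d)]
  d <- d[d != 0]
  n <- length(d)
  if (n == 0) {
    return(list(statistic = NA_real_, p_value = 1, n = 0,
                test = "wilcoxon_signed_rank"))
  }
  exact <- n <= 25 && !any(duplicated(abs(d)))
  wt <- suppressWarnings(stats::wilcox.test(d, exact = exact, correct = TRUE))
  list(statistic = unname(wt$statistic), p_value = wt$p.value, n = n,
       test = "wilcoxon_signed_rank")
}

#' Paired t-test
#'
#' Standard paired t-test with conventions for degenerate input: identical
#' samples (all differences exactly zero) give p = 1 — identical values
#' carry no evidence of a difference rather than producing 0/0 — while a
#' constant non-zero difference is the infinite-t limit and gives p = 0.
#'
#' @param x,y paired numeric samples (n >= 2).
#' @return list with `statistic`, `p_value`, `df`, `n`, `mean_difference`,
#'   `test`.
#' @export
paired_t <- function(x, y) {
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 2) stop("paired t-test needs n >= 2", call. = FALSE)
  d <- x - y
  if (stats::sd(d) == 0) {
    zero <- mean(d) == 0
    return(list(statistic = if (zero) 0 else sign(mean(d)) * Inf,
                p_value = if (zero) 1 else 0,
                df = n - 1, n = n, mean_difference = mean(d),
                test = "paired_t"))
  }
  tt <- stats::t.test(x, y, paired = TRUE)
  list(statistic = unname(tt$statistic), p_value = tt$p.value,
       df = unname(tt$parameter), n = n, mean_difference = mean(d),
       test = "paired_t")
}

#' Condition comparison of a paired metric table
#'
#' The package's standard comparison path for a metric measured per subject
#' under every condition: normality gate on the pooled residuals, then a
#' Friedman omnibus with Dunn's pairwise comparisons (the design's three
#' within-subject conditions are never assumed normal). Returns a tidy
#' stats table.
#'
#' @param tbl tibble with columns `subject`, `condition`, `value`.
#' @param metric metric name recorded in the output.
#' @return tibble with `metric`, `comparison`, `statistic`, `p_raw`,
#'   `p_adj`, `n` — the omnibus row first, then the Dunn's pairs.
#' @export
compare_conditions <- function(tbl, metric = "metric") {
  wide <- tbl |>
    dplyr::select("subject", "condition", "value") |>
    tidyr::pivot_wider(names_from = "condition", values_from = "value") |>
    dplyr::select(-"subject")
  fd <- friedman_dunn(wide)
  dplyr::bind_rows(
    tibble(metric = metric, comparison = "omnibus",
           statistic = fd$omnibus$statistic, p_raw = fd$omnibus$p_value,
           p_adj = fd$omnibus$p_value, n = fd$omnibus$n),
    tibble(metric = metric, comparison = fd$pairwise$comparison,
           statistic = fd$pairwise$z, p_raw = fd$pairwise$p_raw,
           p_adj = fd$pairwise$p_adj, n = fd$pairwise$n)
  )
}
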