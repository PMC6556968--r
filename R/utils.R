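# shared input checks and small helpers

check_binary_z <- function(z) {
  if (is.logical(z)) z <- as.integer(z)
  if (is.factor(z)) z <- as.integer(z) - 1L
  if (!all(z %in% c(0, 1))) stop("group labels must be binary 0/1")
  as.integer(z)
}

as_numeric_covariate <- function(x) {
  if (is.logical(x)) return(as.numeric(x))
  if (is.factor(x)) {
    if (nlevels(x) != 2) stop("only binary factors supported as covariates")
    return(as.numeric(x) - 1)
  }
  if (is.character(x)) {
    u <- sort(unique(x))
    if (length(u) != 2) stop("only binary character covariates supported")
    return(as.numeric(x == u[2]))
  }
  as.numeric(x)
}

# Pearson correlation that returns NA (instead of erroring/warning) when
# either argument is constant
safe_cor <- function(x, y) {
  if (stats::sd(x) == 0 || stats::sd(y) == 0) return(NA_real_)
  stats::cor(x, y)
}

#' Adjusted Rand index between two labelings
#'
#' Chance-corrected agreement between two partitions of the same samples;
#' 1 for identical partitions (up to relabeling), ~0 for independent ones.
#' Used to compare recovered module/subtype labels with planted truth.
#'
#' @param a,b label vectors of equal length.
#' @return adjusted Rand index.
#' @export
adjusted_rand_index <- function(a, b) {
  if (length(a) != length(b)) stop("label vectors must have equal length")
  tab <- table(a, b)
  n <- length(a)
  sum_ij <- sum(choose(tab, 2))
  sum_a <- sum(choose(rowSums(tab), 2))
  sum_b <- sum(choose(colSums(tab), 2))
  expected <- sum_a * sum_b / choose(n, 2)
  max_index <- (sum_a + sum_b) / 2
  if (max_index == expected) return(ifelse(sum_ij == expected, 1, 0))
  (sum_ij - expected) / (max_index - expected)
}

# z-score rows of a features x samples matrix; constant rows become 0
zscore_rows <- function(m) {
  mu <- rowMeans(m)
  s <- apply(m, 1, stats::sd)
  s[s == 0] <- 1
  (m - mu) / s
}
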