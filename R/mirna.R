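#' Aggregate miRNA targets across databases
#'
#' Per miRNA, the final target set is (miRanda intersect miRDB) union
#' miRtarBase. miRNA identifiers are normalized (lower-cased,
#' version-stripped) before matching; miRNAs absent from all three sources
#' get an empty set with a message.
#'
#' @param mirtarbase,miranda,mirdb data.frames with columns `mirna`, `gene`.
#' @param mirnas optional character vector of miRNAs to report; defaults to
#'   the union across sources.
#' @return named list mapping miRNA -> character vector of target genes.
#' @export
aggregate_targets <- function(mirtarbase, miranda, mirdb, mirnas = NULL) {
  norm <- function(x) sub("\\.[0-9]+$", "", tolower(trimws(x)))
  split_tab <- function(tab) {
    stopifnot(all(c("mirna", "gene") %in% names(tab)))
    split(as.character(tab$gene), norm(tab$mirna))
  }
  tb <- split_tab(mirtarbase)
  md <- split_tab(miranda)
  db <- split_tab(mirdb)
  if (is.null(mirnas)) mirnas <- sort(unique(c(names(tb), names(md),
                                               names(db))))
  keys <- norm(mirnas)
  out <- lapply(keys, function(k) {
    if (is.null(tb[[k]]) && is.null(md[[k]]) && is.null(db[[k]])) {
      message("miRNA absent from all target sources: ", k)
      return(character(0))
    }
    sort(unique(c(intersect(md[[k]], db[[k]]), tb[[k]])))
  })
  names(out) <- mirnas
  out
}

#' Filter targets hit by multiple miRNAs
#'
#' Keeps genes targeted by at least `min_hits_up` miRNAs when
#' `direction = "up"` or at least `min_hits_down` when `direction = "down"`
#' (the down group is larger in practice, hence the higher bar).
#'
#' @param target_map named list miRNA -> target gene vector.
#' @param direction "up" or "down".
#' @param min_hits_up,min_hits_down hit thresholds (defaults 2 and 4).
#' @return character vector of kept genes.
#' @export
filter_multi_hit_targets <- function(target_map, direction = c("up", "down"),
                                     min_hits_up = 2L, min_hits_down = 4L) {
  direction <- match.arg(direction)
  if (length(target_map) == 0) return(character(0))
  hits <- table(unlist(lapply(target_map, unique)))
  thr <- if (direction == "up") min_hits_up else min_hits_down
  sort(names(hits)[hits >= thr])
}

#' Correlation between the first principal components of two feature sets
#'
#' Each set is per-feature z-scored; its PC1 across samples is extracted and
#' sign-oriented to correlate positively with the set's mean profile; the
#' Pearson correlation (two-sided p) between the two PC1s is returned.
#'
#' @param set_a_expr,set_b_expr features x samples matrices with aligned
#'   sample columns.
#' @return list with `r`, `p`, `pc1_a`, `pc1_b`.
#' @export
pc1_correlation <- function(set_a_expr, set_b_expr) {
  a <- as.matrix(set_a_expr)
  b <- as.matrix(set_b_expr)
  if (ncol(a) != ncol(b)) stop("sample columns must align")
  if (nrow(a) < 1 || nrow(b) < 1) stop("each set needs >= 1 feature")
  if (all(apply(a, 1, stats::sd) == 0) || all(apply(b, 1, stats::sd) == 0)) {
    stop("zero-variance feature set")
  }
  pa <- oriented_pc1(a)
  pb <- oriented_pc1(b)
  ct <- stats::cor.test(pa, pb)
  list(r = unname(ct$estimate), p = ct$p.value, pc1_a = pa, pc1_b = pb)
}

# PC1 across samples, oriented to correlate positively with the set's mean
# profile
oriented_pc1 <- function(m) {
  zs <- zscore_rows(m)
  if (nrow(zs) == 1) return(as.numeric(zs))
  sv <- La.svd(zs, nu = 0, nv = 1)
  pc <- as.numeric(sv$vt[1, ])
  ref <- colMeans(m)
  orient <- safe_cor(pc, ref)
  if (!is.na(orient) && orient < 0) pc <- -pc
  pc
}

#' Mean expression score of a miRNA cluster
#'
#' Per-sample arithmetic mean of the member miRNAs' log2(RSEM + 1) values.
#' Missing members are reported with a message; at least one member must be
#' present. Defaults to the miR-17-92 cluster members.
#'
#' @param mirna_expr miRNAs x samples matrix (log2 scale).
#' @param members character member names (matched case-insensitively,
#'   version-stripped).
#' @return list with `score` (per sample), `members_used`,
#'   `members_missing`.
#' @export
mirna_cluster_score <- function(mirna_expr,
                                members = c("hsa-mir-17", "hsa-mir-18a",
                                            "hsa-mir-19a", "hsa-mir-20a",
                                            "hsa-mir-19b-1",
                                            "hsa-mir-92a-1")) {
  m <- as.matrix(mirna_expr)
  norm <- function(x) sub("\\.[0-9]+$", "", tolower(trimws(x)))
  idx <- match(norm(members), norm(rownames(m)))
  missing <- members[is.na(idx)]
  if (length(missing) > 0) {
    message("cluster members absent from matrix: ",
            paste(missing, collapse = ", "))
  }
  idx <- idx[!is.na(idx)]
  if (length(idx) == 0) stop("no cluster members present in the matrix")
  score <- colMeans(m[idx, , drop = FALSE])
  list(score = score, members_used = rownames(m)[idx],
       members_missing = missing)
}

#' Wilcoxon rank-sum comparison of a score between groups
#'
#' Exact two-sided p by enumeration of all group assignments of the ranks
#' (ties handled through midranks) when both groups have 10 or fewer
#' samples; normal approximation with tie correction otherwise.
#'
#' @param score numeric values.
#' @param z 0/1 group labels (statistic is the rank sum of group 1).
#' @param exact_max both groups at or below this size use exact enumeration
#'   (default 10).
#' @return list with `statistic` (rank sum of group Z = 1), `p`,
#'   `method`.
#' @export
group_score_test <- function(score, z, exact_max = 10L) {
  z <- check_binary_z(z)
  if (length(score) != length(z)) stop("score and z lengths differ")
  n1 <- sum(z == 1L); n0 <- sum(z == 0L)
  if (n1 < 1 || n0 < 1) stop("both groups must be non-empty")
  r <- rank(score)
  w_obs <- sum(r[z == 1L])
  if (n1 <= exact_max && n0 <= exact_max) {
    combos <- utils::combn(length(z), n1)
    w_all <- colSums(matrix(r[combos], nrow = n1))
    mu <- n1 * (length(z) + 1) / 2
    p <- mean(abs(w_all - mu) >= abs(w_obs - mu) - 1e-12)
    return(list(statistic = w_obs, p = p, method = "exact"))
  }
  n <- length(z)
  mu <- n1 * (n + 1) / 2
  ties <- table(r)
  sigma2 <- n1 * n0 / 12 * ((n + 1) - sum(ties^3 - ties) / (n * (n - 1)))
  if (sigma2 <= 0) return(list(statistic = w_obs, p = 1,
                               method = "normal"))
  zstat <- (w_obs - mu) / sqrt(sigma2)
  p <- 2 * stats::pnorm(abs(zstat), lower.tail = FALSE)
  list(statistic = w_obs, p = min(1, p), method = "normal")
}

#' Correlation of a score with the tumor/normal telomere-length ratio
#'
#' Pearson correlation with two-sided p over pairwise-complete observations.
#'
#' @param score per-sample score.
#' @param tl_ratio per-sample telomere-length ratio (NAs allowed).
#' @return list with `r`, `p`, `n` (complete pairs).
#' @export
telomere_ratio_correlation <- function(score, tl_ratio) {
  if (length(score) != length(tl_ratio)) stop("lengths differ")
  ok <- is.finite(score) & is.finite(tl_ratio)
  if (sum(ok) < 3) stop("need >= 3 complete pairs")
  ct <- stats::cor.test(score[ok], tl_ratio[ok])
  list(r = unname(ct$estimate), p = ct$p.value, n = sum(ok))
}
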