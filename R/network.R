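#' Pick the soft-threshold power for a scale-free network
#'
#' For each candidate power, computes whole-network connectivity k_i (row
#' sums of the unsigned adjacency), bins log10 k into equal-width bins,
#' regresses log10 bin frequency on the log10 mean connectivity per bin, and
#' takes the signed fit R^2 (R^2 when the slope is negative, -R^2 otherwise).
#' Returns the smallest candidate whose signed R^2 exceeds `r2_min`; if none
#' passes, the largest candidate is returned with a warning.
#'
#' @param expr genes x samples matrix.
#' @param candidate_powers integer candidates (>= 3 of them).
#' @param r2_min scale-free fit threshold (default 0.9).
#' @param n_bins connectivity histogram bins (default 10).
#' @return chosen power, with attribute `fit_table` (power, slope,
#'   signed R^2).
#' @export
pick_soft_power <- function(expr, candidate_powers = 1:10, r2_min = 0.9,
                            n_bins = 10L) {
  if (length(candidate_powers) < 3) stop("need >= 3 candidate powers")
  if (nrow(expr) < 20) stop("need >= 20 genes")
  candidate_powers <- sort(candidate_powers)
  absr <- abs(stats::cor(t(expr)))
  diag(absr) <- 0
  fit <- t(vapply(candidate_powers, function(beta) {
    k <- rowSums(absr^beta)
    scale_free_fit(k, n_bins)
  }, numeric(2)))
  colnames(fit) <- c("slope", "signed_r2")
  tab <- data.frame(power = candidate_powers, fit)
  pass <- which(tab$signed_r2 > r2_min)
  if (length(pass) > 0) {
    beta <- tab$power[pass[1]]
  } else {
    beta <- max(candidate_powers)
    warning("no candidate power reaches signed R^2 > ", r2_min,
            "; using the largest candidate ", beta)
  }
  attr(beta, "fit_table") <- tab
  beta
}

# signed scale-free fit of a connectivity vector: regress log10 frequency on
# log10 mean-k over equal-width bins of k
scale_free_fit <- function(k, n_bins = 10L) {
  k <- k[k > 0]
  brk <- seq(min(k), max(k), length.out = n_bins + 1L)
  bin <- cut(k, breaks = brk, include.lowest = TRUE, labels = FALSE)
  freq <- tabulate(bin, nbins = n_bins)
  meank <- vapply(seq_len(n_bins),
                  function(b) mean(k[bin == b]), numeric(1))
  occupied <- freq > 0 & is.finite(meank) & meank > 0
  if (sum(occupied) < 2) stop("fewer than 2 occupied connectivity bins")
  x <- log10(meank[occupied])
  y <- log10(freq[occupied])
  fit <- stats::lm.fit(cbind(1, x), y)
  slope <- fit$coefficients[2]
  r2 <- if (stats::var(y) == 0) 0 else
    1 - sum(fit$residuals^2) / sum((y - mean(y))^2)
  c(slope = unname(slope), signed_r2 = unname(-sign(slope) * r2))
}

#' Unsigned weighted adjacency matrix
#'
#' a_ij = |Pearson r(i, j)|^beta for i != j; the diagonal is 0 by convention
#' so connectivity sums exclude self-edges.
#'
#' @param expr genes x samples matrix.
#' @param beta soft power >= 1.
#' @return genes x genes adjacency matrix in \[0, 1\].
#' @export
adjacency_matrix <- function(expr, beta) {
  if (beta < 1) stop("beta must be >= 1")
  expr <- as.matrix(expr)
  sds <- apply(expr, 1, stats::sd)
  if (any(sds == 0)) {
    stop("zero-variance genes: ",
         paste(utils::head(rownames(expr)[sds == 0], 10), collapse = ", "))
  }
  a <- abs(stats::cor(t(expr)))^beta
  diag(a) <- 0
  a
}

#' Topological overlap matrix
#'
#' TOM_ij = (sum_u a_iu a_uj + a_ij) / (min(k_i, k_j) + 1 - a_ij) with
#' k = row sums of the adjacency; TOM_ii = 1.
#'
#' @param adjacency symmetric zero-diagonal matrix with entries in \[0, 1\].
#' @return TOM of the same dimension.
#' @export
topological_overlap <- function(adjacency) {
  a <- as.matrix(adjacency)
  if (!isSymmetric(unname(a), tol = 1e-10)) stop("adjacency must be symmetric")
  if (any(diag(a) != 0)) stop("adjacency diagonal must be 0")
  if (any(a < 0 | a > 1)) stop("adjacency entries must lie in [0, 1]")
  k <- rowSums(a)
  shared <- a %*% a                 # sum_u a_iu a_uj (diag terms are 0)
  mink <- outer(k, k, pmin)
  tom <- (shared + a) / (mink + 1 - a)
  diag(tom) <- 1
  dimnames(tom) <- dimnames(a)
  tom
}

#' Detect co-expression modules by static tree cut
#'
#' Average-linkage hierarchical clustering of the TOM dissimilarity 1 - TOM,
#' cut at a single height; clusters smaller than `min_module_size` are
#' labeled 0 (unassigned); surviving modules are renumbered 1, 2, ... by
#' decreasing size. When no explicit `cut_height` is given, the height is
#' chosen data-adaptively at the largest gap of the sorted merge heights on
#' the -log(1 - h) scale: TOM dissimilarities of unrelated genes pile up
#' just below 1, so module-internal merges and background merges are
#' separated by a gap that is only visible after decompressing the top of
#' the tree (a fixed fraction of the maximum merge height fuses tight
#' modules with the flat background). This is a deliberately simplified
#' stand-in for dynamic tree cutting: planted-truth recovery, not dendrogram
#' shape, is the validated surface.
#'
#' @param tom TOM matrix.
#' @param min_module_size smallest admissible module (default 30).
#' @param cut_height absolute cut height; `NULL` picks the largest-gap
#'   height as described above.
#' @param expr optional genes x samples matrix enabling the kME rescue
#'   step: after the static cut, unassigned genes with absolute module
#'   membership of at least `kme_min` to some surviving module's eigengene
#'   are assigned to that module (mirrors the membership-based assignment of
#'   mature co-expression workflows; stragglers of a real module regain
#'   their label while background genes, whose |kME| is near 0, stay
#'   unassigned).
#' @param kme_min membership floor for the rescue step (default 0.5).
#' @return integer module labels named by gene (0 = unassigned).
#' @export
detect_modules <- function(tom, min_module_size = 30L, cut_height = NULL,
                           expr = NULL, kme_min = 0.5) {
  d <- stats::as.dist(1 - tom)
  hc <- stats::hclust(d, method = "average")
  if (is.null(cut_height)) {
    h <- sort(hc$height)
    u <- -log1p(-pmin(h, 1 - 1e-12))    # decompress the near-1 region
    i <- which.max(diff(u))
    cut_height <- (h[i] + h[i + 1]) / 2
  }
  raw <- stats::cutree(hc, h = cut_height)
  sizes <- table(raw)
  keep <- names(sizes)[sizes >= min_module_size]
  labels <- integer(length(raw))
  if (length(keep) == 0) {
    warning("all genes unassigned: no cluster reaches min_module_size")
  } else {
    keep <- keep[order(-sizes[keep], as.integer(keep))]
    for (m in seq_along(keep)) labels[raw == as.integer(keep[m])] <- m
  }
  names(labels) <- rownames(as.matrix(tom))
  if (!is.null(expr) && any(labels > 0) && any(labels == 0)) {
    me <- module_eigengene(expr, labels)
    k <- abs(kme(expr[labels == 0, , drop = FALSE], me))
    best <- max.col(k, ties.method = "first")
    ok <- k[cbind(seq_len(nrow(k)), best)] >= kme_min & !is.na(best)
    labels[labels == 0][ok] <- best[ok]
  }
  labels
}

#' Module eigengenes
#'
#' First principal component across samples of each module's per-gene
#' z-scored submatrix, scaled to unit variance and sign-oriented so that its
#' mean correlation with the module's genes is positive. A single-gene module
#' returns that gene's z-scored profile.
#'
#' @param expr genes x samples matrix.
#' @param labels integer module labels named by gene (0 ignored).
#' @return modules x samples matrix with rownames `ME1`, `ME2`, ...
#' @export
module_eigengene <- function(expr, labels) {
  expr <- as.matrix(expr)
  mods <- sort(unique(labels[labels > 0]))
  if (length(mods) == 0) stop("no assigned modules")
  me <- t(vapply(mods, function(m) {
    sub <- expr[labels == m, , drop = FALSE]
    single_eigengene(sub)
  }, numeric(ncol(expr))))
  rownames(me) <- paste0("ME", mods)
  colnames(me) <- colnames(expr)
  me
}

# PC1 (sample scores) of a z-scored genes x samples block, unit variance,
# oriented toward the genes
single_eigengene <- function(sub) {
  zs <- zscore_rows(sub)
  if (nrow(zs) == 1) return(as.numeric(zs))
  sv <- La.svd(zs, nu = 0, nv = 1)
  pc <- as.numeric(sv$vt[1, ])
  pc <- pc / stats::sd(pc)
  orient <- mean(apply(zs, 1, function(g) safe_cor(g, pc)), na.rm = TRUE)
  if (!is.na(orient) && orient < 0) pc <- -pc
  pc
}

#' Merge highly correlated modules
#'
#' Single-linkage grouping of modules whose eigengene dissimilarity
#' (1 - Pearson r) is below `diss_threshold`; merged labels are renumbered by
#' decreasing size and eigengenes recomputed.
#'
#' @param expr genes x samples matrix.
#' @param labels module labels (0 = unassigned).
#' @param diss_threshold merge threshold on 1 - cor(ME, ME) (default 0.25).
#' @return list with `labels` (merged) and `eigengenes` (recomputed).
#' @export
merge_modules <- function(expr, labels, diss_threshold = 0.25) {
  mods <- sort(unique(labels[labels > 0]))
  if (length(mods) < 2) {
    me <- if (length(mods) == 1) module_eigengene(expr, labels) else NULL
    return(list(labels = labels, eigengenes = me))
  }
  me <- module_eigengene(expr, labels)
  d <- 1 - stats::cor(t(me))
  hc <- stats::hclust(stats::as.dist(d), method = "single")
  grp <- stats::cutree(hc, h = diss_threshold)
  merged <- labels
  for (i in seq_along(mods)) merged[labels == mods[i]] <- grp[i]
  # renumber by decreasing size
  sizes <- table(merged[merged > 0])
  ord <- names(sizes)[order(-sizes, as.integer(names(sizes)))]
  out <- integer(length(merged))
  for (m in seq_along(ord)) out[merged == as.integer(ord[m])] <- m
  names(out) <- names(labels)
  list(labels = out, eigengenes = module_eigengene(expr, out))
}

#' Intramodular connectivity and hub flags
#'
#' K_i is the sum of adjacency weights from gene i to other genes of its
#' module. Hubs are the top ceil(5% of module size) genes by K within each
#' module (at least 1), ties broken by gene identifier. Unassigned genes
#' (label 0) get whole-network connectivity and are never hub-flagged.
#'
#' @param adjacency genes x genes adjacency.
#' @param labels module labels (0 = unassigned).
#' @param hub_frac top fraction flagged as hubs (default 0.05).
#' @return data.frame with `gene`, `module`, `K`, `hub`.
#' @export
intramodular_connectivity <- function(adjacency, labels, hub_frac = 0.05) {
  a <- as.matrix(adjacency)
  genes <- rownames(a)
  if (is.null(genes)) genes <- as.character(seq_len(nrow(a)))
  K <- numeric(length(labels))
  hub <- logical(length(labels))
  for (m in unique(labels)) {
    idx <- which(labels == m)
    if (m == 0) {
      K[idx] <- rowSums(a[idx, , drop = FALSE])
      next
    }
    K[idx] <- rowSums(a[idx, idx, drop = FALSE])
    n_hub <- max(1L, as.integer(ceiling(hub_frac * length(idx))))
    ord <- idx[order(-K[idx], genes[idx])]
    hub[ord[seq_len(min(n_hub, length(ord)))]] <- TRUE
  }
  data.frame(gene = genes, module = as.integer(labels), K = K, hub = hub,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Module membership (kME)
#'
#' Pearson correlation between every gene's expression profile and every
#' module eigengene. Zero-variance genes get NA.
#'
#' @param expr genes x samples matrix.
#' @param eigengenes modules x samples matrix.
#' @return genes x modules matrix of correlations.
#' @export
kme <- function(expr, eigengenes) {
  expr <- as.matrix(expr)
  me <- as.matrix(eigengenes)
  if (ncol(expr) != ncol(me)) stop("sample columns must align")
  out <- matrix(NA_real_, nrow = nrow(expr), ncol = nrow(me),
                dimnames = list(rownames(expr), rownames(me)))
  ok <- apply(expr, 1, stats::sd) > 0
  if (any(ok)) {
    out[ok, ] <- stats::cor(t(expr[ok, , drop = FALSE]), t(me))
  }
  out
}

#' Permutation Z statistics for module preservation
#'
#' For each reference module, measures in the test network (i) density: the
#' mean intramodular adjacency, and (ii) connectivity: the sum of
#' intramodular connections (total intramodular connectivity of the
#' module's genes). Both observed statistics are standardized against
#' `n_perm` random gene sets of the same size drawn from the test network,
#' and Zsummary = median(Zdensity, Zconnectivity). Because the null sets
#' share the module's size, the two components coincide up to a monotone
#' rescaling, so Zsummary effectively measures density preservation; this
#' is a deliberate simplification of the full multi-component preservation
#' composite (correlation-based pattern statistics lose their
#' discrimination against random-set nulls when the gene universe is
#' compact and globally structured, because random sets then genuinely
#' reproduce connectivity patterns). Categories use the 2 / 10 cutoffs:
#' not preserved below 2, moderately preserved in \[2, 10), highly
#' preserved at 10 and above.
#'
#' @param expr_ref,expr_test genes x samples matrices over the same genes.
#' @param labels_ref module labels from the reference network.
#' @param beta soft power for both networks (default 6).
#' @param n_perm random gene sets per module (default 200).
#' @param seed RNG seed.
#' @return data.frame with `module`, `size`, `Zdensity`, `Zconnectivity`,
#'   `Zsummary`, `category`.
#' @export
module_preservation_z <- function(expr_ref, expr_test, labels_ref,
                                  beta = 6, n_perm = 200L, seed) {
  if (missing(seed)) stop("seed is mandatory")
  if (!identical(rownames(expr_ref), rownames(expr_test))) {
    stop("reference and test matrices must share the same genes")
  }
  a_test <- adjacency_matrix(expr_test, beta)
  n_genes <- nrow(a_test)
  mods <- sort(unique(labels_ref[labels_ref > 0]))
  set.seed(seed)
  stat_pair <- function(idx) {
    sub_t <- a_test[idx, idx, drop = FALSE]
    dens <- mean(sub_t[upper.tri(sub_t)])
    conn <- sum(sub_t)          # total intramodular connectivity
    c(dens, conn)
  }
  out <- lapply(mods, function(m) {
    idx <- which(labels_ref == m)
    if (length(idx) > n_genes) stop("module larger than gene universe")
    obs <- stat_pair(idx)
    null <- vapply(seq_len(n_perm), function(b) {
      stat_pair(sample.int(n_genes, length(idx)))
    }, numeric(2))
    zd <- (obs[1] - mean(null[1, ])) / stats::sd(null[1, ])
    zc <- (obs[2] - mean(null[2, ], na.rm = TRUE)) /
      stats::sd(null[2, ], na.rm = TRUE)
    zs <- stats::median(c(zd, zc), na.rm = TRUE)
    data.frame(module = m, size = length(idx), Zdensity = zd,
               Zconnectivity = zc, Zsummary = zs,
               category = preservation_category(zs),
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

preservation_category <- function(zsummary) {
  if (is.na(zsummary)) return(NA_character_)
  if (zsummary < 2) "not_preserved"
  else if (zsummary < 10) "moderate"
  else "high"
}

#' Classify hub strength across conditions
#'
#' Counts the conditions (cancer types) in which a gene is a hub and maps the
#' count to tiers: 5 or more = strong, 3-4 = median, 1-2 = weak, 0 = none.
#'
#' @param hub_table genes x conditions logical matrix (or data.frame).
#' @return data.frame with `gene`, `n_conditions`, `strength`.
#' @export
classify_hub_strength <- function(hub_table) {
  m <- as.matrix(hub_table)
  cnt <- rowSums(m)
  strength <- cut(cnt, breaks = c(-Inf, 0, 2, 4, Inf),
                  labels = c("none", "weak", "median", "strong"))
  genes <- rownames(m)
  if (is.null(genes)) genes <- as.character(seq_len(nrow(m)))
  data.frame(gene = genes, n_conditions = as.integer(cnt),
             strength = as.character(strength),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Correlation between intramodular connectivity and telomerase association
#'
#' Pearson correlation (with two-sided p) between per-gene intramodular
#' connectivity K and the per-gene correlation of expression with the
#' telomerase activity score.
#'
#' @param K per-gene connectivity.
#' @param per_gene_activity_r per-gene correlation with the activity score.
#' @return list with `r`, `p`, `n`; `r = NA` (degenerate flag) when K is
#'   constant.
#' @export
connectivity_activity_correlation <- function(K, per_gene_activity_r) {
  ok <- is.finite(K) & is.finite(per_gene_activity_r)
  K <- K[ok]; a <- per_gene_activity_r[ok]
  if (length(K) < 3) stop("need >= 3 genes")
  if (stats::sd(K) == 0 || stats::sd(a) == 0) {
    return(list(r = NA_real_, p = NA_real_, n = length(K),
                degenerate = TRUE))
  }
  ct <- stats::cor.test(K, a)
  list(r = unname(ct$estimate), p = ct$p.value, n = length(K),
       degenerate = FALSE)
}
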