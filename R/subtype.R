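#' Assemble the multi-omics marker profile for subtyping
#'
#' Per layer, significant features are ranked by |Delta MW| (descending) and
#' the top 20 (mRNA, methylation) or top 5 (miRNA, mutation, SCNA) are taken;
#' TERT is appended to the gene markers if absent; global markers (consensus
#' hub genes and the miR-17-92 members) are appended. Layers with fewer
#' significant features than requested contribute all of them with a
#' warning. Binary layers (mutation, SCNA calls) enter as numerics. Missing
#' values are imputed by column median (continuous) or mode (binary) with a
#' message.
#'
#' @param diff_results named list (layer -> data.frame with `feature`,
#'   `delta_mw`, `significant`); recognised layers: mrna, methylation,
#'   mirna, mutation, scna.
#' @param layers named list of features x samples matrices for the same
#'   layers.
#' @param hub_genes character global hub genes (may be empty).
#' @param mirna_cluster character global miRNA markers (may be empty).
#' @param top_n named vector of per-layer marker counts.
#' @return list with `profile` (samples x markers numeric matrix) and
#'   `provenance` (data.frame marker/layer/source).
#' @export
assemble_marker_profile <- function(diff_results, layers,
                                    hub_genes = character(0),
                                    mirna_cluster = character(0),
                                    top_n = c(mrna = 20L, methylation = 20L,
                                              mirna = 5L, mutation = 5L,
                                              scna = 5L)) {
  pick <- list()
  prov <- list()
  n_sig_total <- 0L
  for (layer in names(diff_results)) {
    res <- diff_results[[layer]]
    if (is.null(res) || is.null(layers[[layer]])) next
    sig <- res[res$significant, , drop = FALSE]
    n_sig_total <- n_sig_total + nrow(sig)
    want <- if (layer %in% names(top_n)) top_n[[layer]] else 5L
    sig <- sig[order(-abs(sig$delta_mw), sig$feature), , drop = FALSE]
    if (nrow(sig) < want) {
      warning("layer ", layer, ": only ", nrow(sig),
              " significant features available (", want, " requested)")
    }
    chosen <- utils::head(sig$feature, want)
    if (layer == "mrna" && "TERT" %in% rownames(layers$mrna) &&
        !("TERT" %in% chosen)) {
      chosen <- c(chosen, "TERT")
    }
    pick[[layer]] <- chosen
    if (length(chosen) > 0) {
      prov[[layer]] <- data.frame(marker = chosen, layer = layer,
                                  source = paste0("top_", layer),
                                  stringsAsFactors = FALSE)
    }
  }
  if (n_sig_total == 0L && length(hub_genes) == 0 &&
      length(mirna_cluster) == 0) {
    stop("no significant features in any layer and no global markers")
  }
  if (length(hub_genes) > 0 && !is.null(layers$mrna)) {
    extra <- setdiff(intersect(hub_genes, rownames(layers$mrna)),
                     pick$mrna)
    pick$mrna <- c(pick$mrna, extra)
    if (length(extra) > 0) {
      prov$global_hub <- data.frame(marker = extra, layer = "mrna",
                                    source = "global_hub",
                                    stringsAsFactors = FALSE)
    }
  }
  if (length(mirna_cluster) > 0 && !is.null(layers$mirna)) {
    extra <- setdiff(intersect(mirna_cluster, rownames(layers$mirna)),
                     pick$mirna)
    pick$mirna <- c(pick$mirna, extra)
    if (length(extra) > 0) {
      prov$global_mirna <- data.frame(marker = extra, layer = "mirna",
                                      source = "global_mirna",
                                      stringsAsFactors = FALSE)
    }
  }
  if (all(vapply(pick, length, integer(1)) == 0)) {
    stop("no significant features in any layer and no global markers")
  }
  cols <- list()
  for (layer in names(pick)) {
    feats <- intersect(pick[[layer]], rownames(layers[[layer]]))
    if (length(feats) == 0) next
    block <- t(layers[[layer]][feats, , drop = FALSE])
    colnames(block) <- paste(layer, feats, sep = ":")
    cols[[layer]] <- block
  }
  profile <- do.call(cbind, cols)
  profile <- impute_columns(profile)
  provenance <- do.call(rbind, prov)
  rownames(provenance) <- NULL
  list(profile = profile, provenance = provenance)
}

# median (continuous) / mode (binary) column imputation
impute_columns <- function(m) {
  n_imputed <- 0L
  for (j in seq_len(ncol(m))) {
    nas <- is.na(m[, j])
    if (!any(nas)) next
    obs <- m[!nas, j]
    fill <- if (all(obs %in% c(0, 1))) {
      as.numeric(names(which.max(table(obs))))
    } else {
      stats::median(obs)
    }
    m[nas, j] <- fill
    n_imputed <- n_imputed + sum(nas)
  }
  if (n_imputed > 0) message(n_imputed, " missing marker values imputed")
  m
}

#' Synthesize null data from empirical marginals
#'
#' Each column of the output is drawn independently, with replacement, from
#' the observed values of the same column: the product of the empirical
#' marginal distributions, destroying all between-marker dependence.
#'
#' @param x samples x markers numeric matrix.
#' @param seed RNG seed.
#' @return matrix of the same shape.
#' @export
synthesize_null_data <- function(x, seed) {
  if (missing(seed)) stop("seed is mandatory")
  x <- as.matrix(x)
  if (anyNA(x)) stop("missing values must be imputed before synthesis")
  set.seed(seed)
  apply(x, 2, function(col) sample(col, length(col), replace = TRUE))
}

#' Unsupervised random-forest dissimilarity
#'
#' Trains a random-forest classifier to distinguish the observed samples
#' (class 1) from marginally resampled synthetic samples (class 2); the
#' similarity between two observed samples is the fraction of trees in which
#' they land in the same terminal node (all samples propagated down every
#' tree); dissimilarity D_ij = sqrt(1 - S_ij) with zero diagonal.
#'
#' @param x samples x markers numeric matrix (no missing values).
#' @param n_trees forest size (default 2000).
#' @param seed RNG seed (drives both synthesis and the forest).
#' @param mtry candidate markers per split; default floor(sqrt(#markers)).
#' @return list with `dissimilarity` (samples x samples), `similarity`,
#'   `n_trees`, `oob_error`.
#' @export
rf_dissimilarity <- function(x, n_trees = 2000L, seed, mtry = NULL) {
  if (missing(seed)) stop("seed is mandatory")
  x <- as.matrix(x)
  if (nrow(x) < 10) stop("need >= 10 samples")
  if (ncol(x) < 2) stop("need >= 2 markers")
  if (anyNA(x)) stop("impute missing values upstream")
  x_synth <- synthesize_null_data(x, seed = seed)
  combined <- rbind(x, x_synth)
  y <- factor(rep(c("observed", "synthetic"), each = nrow(x)))
  if (nlevels(droplevels(y)) < 2) stop("degenerate synthetic class")
  if (is.null(mtry)) mtry <- max(1L, floor(sqrt(ncol(x))))
  set.seed(seed)
  fit <- randomForest::randomForest(x = combined, y = y, ntree = n_trees,
                                    mtry = mtry, proximity = TRUE,
                                    nodesize = 1L)
  s <- fit$proximity[seq_len(nrow(x)), seq_len(nrow(x))]
  s <- (s + t(s)) / 2
  s <- pmin(pmax(s, 0), 1)
  d <- sqrt(1 - s)
  diag(d) <- 0
  dimnames(d) <- list(rownames(x), rownames(x))
  list(dissimilarity = d, similarity = s, n_trees = n_trees,
       oob_error = mean(fit$err.rate[n_trees, "OOB"]))
}

#' Partition around medoids on a precomputed dissimilarity
#'
#' BUILD + SWAP k-medoids (via [cluster::pam()]) on the dissimilarity
#' matrix; deterministic given the matrix, with ties resolved by sample
#' order.
#'
#' @param d samples x samples dissimilarity matrix.
#' @param k number of clusters (2 <= k < n).
#' @param seed accepted for interface uniformity; PAM is deterministic given
#'   the dissimilarity, so the seed is unused.
#' @return list with `labels` (integer per sample), `medoids` (sample IDs),
#'   `total_cost` (sum of dissimilarity to assigned medoid).
#' @export
pam_cluster <- function(d, k = 2L, seed = NULL) {
  d <- as.matrix(d)
  n <- nrow(d)
  if (k < 2 || k >= n) stop("require 2 <= k < number of samples")
  fit <- cluster::pam(stats::as.dist(d), k = k, diss = TRUE)
  labels <- as.integer(fit$clustering)
  medoid_idx <- match(fit$medoids, rownames(d))
  if (anyNA(medoid_idx)) medoid_idx <- as.integer(fit$id.med)
  cost <- sum(d[cbind(seq_len(n), medoid_idx[labels])])
  list(labels = labels, medoids = fit$medoids, total_cost = cost)
}

#' Telomerase activity score from a gene signature
#'
#' Per-sample mean of the per-gene z-scored log2 expression over the
#' signature genes present in the matrix.
#'
#' @param expr genes x samples log2 expression matrix.
#' @param signature_genes character gene list.
#' @return named per-sample score vector.
#' @export
telomerase_activity_score <- function(expr, signature_genes) {
  expr <- as.matrix(expr)
  present <- intersect(signature_genes, rownames(expr))
  if (length(present) == 0) stop("no signature genes present")
  if (length(present) < length(signature_genes)) {
    message(length(signature_genes) - length(present),
            " signature gene(s) absent from the matrix")
  }
  colMeans(zscore_rows(expr[present, , drop = FALSE]))
}

#' Two-group log-rank test
#'
#' Standard log-rank statistic over the distinct event times (chi-square,
#' 1 df), via [survival::survdiff()].
#'
#' @param time positive follow-up times.
#' @param event 1 = death, 0 = censored.
#' @param labels binary group labels.
#' @return list with `chi_square`, `p`.
#' @export
logrank_test <- function(time, event, labels) {
  if (any(time <= 0)) stop("times must be > 0")
  if (!all(event %in% c(0, 1))) stop("event must be 0/1")
  if (sum(event) == 0) stop("no events")
  g <- check_binary_z(as.integer(factor(labels)) - 1L)
  sd <- survival::survdiff(survival::Surv(time, event) ~ g)
  chi <- sd$chisq
  list(chi_square = unname(chi),
       p = stats::pchisq(chi, df = 1, lower.tail = FALSE))
}

#' Univariate Cox proportional-hazards model
#'
#' Newton-Raphson maximization of the Cox partial likelihood with Breslow
#' tie handling (via [survival::coxph()]); returns the hazard ratio and the
#' Wald p-value, with a flag for monotone likelihood (perfect separation).
#'
#' @param time,event survival outcome as in [logrank_test()].
#' @param x numeric or binary covariate.
#' @return list with `hazard_ratio`, `coef`, `p`, `monotone` flag.
#' @export
cox_univariate <- function(time, event, x) {
  if (any(time <= 0)) stop("times must be > 0")
  if (!all(event %in% c(0, 1))) stop("event must be 0/1")
  x <- as.numeric(x)
  if (stats::sd(x) == 0) stop("covariate constant: no information")
  monotone <- FALSE
  fit <- withCallingHandlers(
    survival::coxph(survival::Surv(time, event) ~ x,
                    ties = "breslow",
                    control = survival::coxph.control(iter.max = 100L)),
    warning = function(w) {
      if (grepl("infinite|did not converge|beta may be infinite",
                conditionMessage(w))) {
        monotone <<- TRUE
        invokeRestart("muffleWarning")
      }
    }
  )
  if (is.na(stats::coef(fit))) stop("Cox fit failed to converge")
  s <- summary(fit)
  list(hazard_ratio = unname(exp(stats::coef(fit))),
       coef = unname(stats::coef(fit)),
       p = unname(s$coefficients[1, "Pr(>|z|)"]),
       monotone = monotone)
}

#' Compare subtypes by telomerase activity and survival
#'
#' Orients the cluster labels so that cluster 1 has the higher median
#' telomerase score, then compares the two clusters by Wilcoxon rank-sum on
#' the score, the log-rank test, and a univariate Cox model on the cluster-2
#' indicator.
#'
#' @param labels cluster labels (two non-empty clusters).
#' @param score per-sample telomerase activity score.
#' @param time,event survival outcome.
#' @return list of class `subtype_result`: `labels` (oriented: 1 = higher
#'   median score), `wilcoxon_p`, `logrank_chi_square`, `logrank_p`,
#'   `cox_hazard_ratio` (cluster 2 vs 1), `cox_p`, `medians`.
#' @export
compare_subtypes <- function(labels, score, time, event) {
  labels <- as.integer(factor(labels))
  if (length(unique(labels)) != 2) stop("exactly two non-empty clusters required")
  if (length(score) != length(labels) || length(time) != length(labels)) {
    stop("labels, score and survival must be aligned")
  }
  med <- tapply(score, labels, stats::median)
  if (med[["1"]] < med[["2"]]) labels <- 3L - labels
  wil <- group_score_test(score, as.integer(labels == 1L))
  lr <- logrank_test(time, event, labels)
  cx <- cox_univariate(time, event, as.integer(labels == 2L))
  structure(list(labels = labels,
                 wilcoxon_p = wil$p,
                 logrank_chi_square = lr$chi_square,
                 logrank_p = lr$p,
                 cox_hazard_ratio = cx$hazard_ratio,
                 cox_p = cx$p,
                 medians = tapply(score, labels, stats::median)),
            class = "subtype_result")
}
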