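# Marker assembly, RF dissimilarity, PAM, survival comparisons

test_that("marker assembly ranks by |Delta MW|, appends TERT and globals", {
  layers <- list(
    mrna = matrix(rnorm(5 * 6), nrow = 5,
                  dimnames = list(c("TERT", "A", "B", "C", "HUB1"),
                                  paste0("s", 1:6))),
    mirna = matrix(rnorm(2 * 6), nrow = 2,
                   dimnames = list(c("hsa-mir-17", "hsa-mir-18a"),
                                   paste0("s", 1:6))))
  diff_results <- list(
    mrna = data.frame(feature = c("A", "B", "C"),
                      delta_mw = c(0.5, -2, 1),
                      significant = c(TRUE, TRUE, TRUE)),
    mirna = data.frame(feature = "hsa-mir-18a", delta_mw = 1,
                       significant = TRUE))
  expect_warning(
    prof <- assemble_marker_profile(diff_results, layers,
                                    hub_genes = "HUB1",
                                    mirna_cluster = "hsa-mir-17",
                                    top_n = c(mrna = 2L, mirna = 5L)),
    "significant features available")
  cols <- colnames(prof$profile)
  # top-2 by |delta|: B then C; TERT appended; HUB1 global
  expect_true(all(c("mrna:B", "mrna:C", "mrna:TERT", "mrna:HUB1",
                    "mirna:hsa-mir-18a", "mirna:hsa-mir-17") %in% cols))
  expect_false("mrna:A" %in% cols)
  expect_setequal(prof$provenance$source[prof$provenance$marker == "HUB1"],
                  "global_hub")
  # brute-force sort oracle
  sig <- diff_results$mrna
  expect_identical(sig$feature[order(-abs(sig$delta_mw))][1:2], c("B", "C"))
  # no significant features anywhere and no globals: error
  none <- lapply(diff_results, transform, significant = FALSE)
  expect_error(suppressWarnings(assemble_marker_profile(none, layers)),
               "no significant features")
})

test_that("marginal synthesis preserves support and moments", {
  set.seed(20)
  x <- cbind(a = rnorm(1000), b = rep(3, 1000),
             c = rbinom(1000, 1, 0.3))
  xs <- synthesize_null_data(x, seed = 1)
  expect_identical(dim(xs), dim(x))
  expect_identical(unname(xs[, "b"]), rep(3, 1000))   # one-point marginal
  expect_true(all(xs[, "a"] %in% x[, "a"]))
  expect_true(all(xs[, "c"] %in% c(0, 1)))
  se <- sd(x[, "a"]) / sqrt(1000)
  expect_lt(abs(mean(xs[, "a"]) - mean(x[, "a"])), 3 * se)
  # determinism
  expect_identical(xs, synthesize_null_data(x, seed = 1))
})

test_that("RF dissimilarity is a bounded, symmetric, zero-diagonal metric", {
  set.seed(21)
  shift <- rep(c(0, 3), each = 30)
  x <- cbind(m1 = rnorm(60) + shift, m2 = rnorm(60) + shift,
             m3 = rnorm(60), m4 = rbinom(60, 1, 0.2 + 0.5 * (shift > 0)))
  rownames(x) <- paste0("s", 1:60)
  for (s in 1:3) {
    rf <- rf_dissimilarity(x, n_trees = 500, seed = s)
    d <- rf$dissimilarity
    expect_equal(unname(diag(d)), rep(0, 60))
    expect_true(isSymmetric(d))
    expect_true(all(d >= 0 & d <= 1))
    grp <- rep(c(1, 2), each = 30)
    within <- mean(d[outer(grp, grp, "==") & upper.tri(d)])
    between <- mean(d[outer(grp, grp, "!=") & upper.tri(d)])
    expect_lt(within, between)
  }
  expect_error(rf_dissimilarity(x[1:5, ], seed = 1), ">= 10 samples")
  expect_error(rf_dissimilarity(x[, 1, drop = FALSE], seed = 1),
               ">= 2 markers")
})

test_that("RF dissimilarity is deterministic and Monte-Carlo stable", {
  set.seed(22)
  x <- cbind(rnorm(30, rep(c(0, 2), each = 15)), rnorm(30))
  rownames(x) <- paste0("s", 1:30)
  d1 <- rf_dissimilarity(x, n_trees = 400, seed = 7)$dissimilarity
  d2 <- rf_dissimilarity(x, n_trees = 400, seed = 7)$dissimilarity
  expect_identical(d1, d2)
  d4 <- rf_dissimilarity(x, n_trees = 800, seed = 7)$dissimilarity
  expect_lt(max(abs(d4 - d1)), 0.15)
})

test_that("PAM equals the exhaustive medoid optimum on small instances", {
  pts <- c(0, 1, 10, 11)
  d <- abs(outer(pts, pts, "-"))
  dimnames(d) <- list(paste0("s", 1:4), paste0("s", 1:4))
  res <- pam_cluster(d, 2)
  expect_equal(res$labels, c(1, 1, 2, 2))
  expect_equal(res$total_cost, 2)
  expect_error(pam_cluster(d, 4), "k <")
  # duplicated points co-cluster
  pts2 <- c(0, 0, 5, 5, 9)
  d2 <- abs(outer(pts2, pts2, "-"))
  res2 <- pam_cluster(d2, 2)
  expect_equal(res2$labels[1], res2$labels[2])
  expect_equal(res2$labels[3], res2$labels[4])
  # exhaustive-search optimum for random instances with n <= 8, k = 2
  set.seed(23)
  for (rep in 1:15) {
    n <- sample(4:8, 1)
    p <- matrix(rnorm(2 * n), ncol = 2)
    dm <- as.matrix(dist(p))
    res <- pam_cluster(dm, 2)
    combos <- combn(n, 2)
    best <- min(apply(combos, 2, function(med) {
      sum(pmin(dm[, med[1]], dm[, med[2]]))
    }))
    expect_equal(res$total_cost, best, tolerance = 1e-10)
  }
})

test_that("telomerase activity score is a mean of z-scored signature genes", {
  set.seed(24)
  expr <- matrix(rnorm(4 * 30, 6), nrow = 4,
                 dimnames = list(c("g1", "g2", "g3", "g4"), NULL))
  s1 <- telomerase_activity_score(expr, "g2")
  expect_equal(unname(s1), as.numeric(scale(expr["g2", ])), tolerance = 1e-10)
  # gene-order invariance
  expect_equal(telomerase_activity_score(expr, c("g1", "g3")),
               telomerase_activity_score(expr, c("g3", "g1")))
  expect_message(telomerase_activity_score(expr, c("g1", "nope")), "absent")
  expect_error(telomerase_activity_score(expr, "nope"), "no signature")
  # planted construct: score tracks the generating latent factor
  coh <- default_cohort()
  act <- telomerase_activity_score(coh$layers$mrna,
                                   coh$truth$signature_genes)
  expect_gt(cor(act, coh$truth$activity_latent), 0.9)
})

test_that("log-rank statistic matches hand tabulation and the 1-df identity", {
  # identical survival in both groups: statistic 0, p 1
  tm <- c(2, 4, 6, 2, 4, 6); ev <- c(1, 1, 0, 1, 1, 0)
  res0 <- logrank_test(tm, ev, c(1, 1, 1, 2, 2, 2))
  expect_equal(res0$chi_square, 0, tolerance = 1e-10)
  expect_equal(res0$p, 1, tolerance = 1e-10)
  # 6-subject toy: manual risk-set tabulation oracle
  time <- c(1, 2, 3, 4, 5, 6)
  event <- c(1, 1, 1, 1, 0, 1)
  grp <- c(1, 2, 1, 2, 1, 2)
  oracle <- function(time, event, grp) {
    ut <- sort(unique(time[event == 1]))
    O <- E <- V <- 0
    for (t in ut) {
      at_risk <- time >= t
      n <- sum(at_risk); n1 <- sum(at_risk & grp == 2)
      d <- sum(time == t & event == 1)
      d1 <- sum(time == t & event == 1 & grp == 2)
      O <- O + d1
      E <- E + d * n1 / n
      V <- V + d * (n1 / n) * (1 - n1 / n) * (n - d) / max(n - 1, 1)
    }
    (O - E)^2 / V
  }
  res <- logrank_test(time, event, grp)
  expect_equal(res$chi_square, oracle(time, event, grp), tolerance = 1e-8)
  # identity holds on random inputs too
  set.seed(25)
  for (rep in 1:5) {
    tm <- rexp(40); ev <- rbinom(40, 1, 0.8); gr <- rbinom(40, 1, 0.5) + 1
    if (sum(ev) == 0 || length(unique(gr)) < 2) next
    expect_equal(logrank_test(tm, ev, gr)$chi_square, oracle(tm, ev, gr),
                 tolerance = 1e-6)
  }
  expect_error(logrank_test(c(1, 2), c(0, 0), c(1, 2)), "no events")
  expect_error(logrank_test(c(0, 2), c(1, 1), c(1, 2)), "> 0")
})

test_that("planted hazard ratio yields a decisive log-rank separation", {
  st <- rep(c(1, 2), each = 200)
  sv <- generate_survival(st, 3, 0.2, seed = 31)
  expect_lt(logrank_test(sv$time, sv$event, st)$p, 0.001)
})

test_that("Cox fit matches a golden-section partial-likelihood oracle", {
  # symmetric duplicated data: coefficient exactly 0, HR 1
  tm <- c(2, 4, 6, 8, 2, 4, 6, 8)
  ev <- c(1, 1, 1, 0, 1, 1, 1, 0)
  x <- rep(c(0, 1), each = 4)
  res0 <- cox_univariate(tm, ev, x)
  expect_equal(res0$coef, 0, tolerance = 1e-8)
  expect_equal(res0$hazard_ratio, 1, tolerance = 1e-8)
  # 8-subject toy without ties vs direct partial-likelihood maximization
  set.seed(26)
  tm2 <- sort(rexp(8)) * c(1.1, 1.3, 0.9, 1.7, 1.2, 0.8, 1.5, 1.0)
  tm2 <- tm2 + seq(0, 0.7, 0.1)            # guarantee no ties
  ev2 <- c(1, 1, 0, 1, 1, 1, 0, 1)
  x2 <- c(0.2, 1.5, -0.3, 0.8, 2.1, -1.0, 0.5, 1.2)
  res <- cox_univariate(tm2, ev2, x2)
  pl <- function(beta) {
    ll <- 0
    for (i in which(ev2 == 1)) {
      risk <- tm2 >= tm2[i]
      ll <- ll + beta * x2[i] - log(sum(exp(beta * x2[risk])))
    }
    ll
  }
  lo <- -5; hi <- 5; phi <- (sqrt(5) - 1) / 2
  for (it in 1:200) {
    m1 <- hi - phi * (hi - lo); m2 <- lo + phi * (hi - lo)
    if (pl(m1) < pl(m2)) lo <- m1 else hi <- m2
  }
  beta_oracle <- (lo + hi) / 2
  expect_equal(res$coef, beta_oracle, tolerance = 1e-6)
  expect_error(cox_univariate(tm2, ev2, rep(1, 8)), "constant")
})

test_that("Cox hazard ratio recovers the planted value", {
  st <- rep(c(1, 2), each = 200)
  sv <- generate_survival(st, 3, 0.2, seed = 32)
  res <- cox_univariate(sv$time, sv$event, as.integer(st == 2))
  expect_gt(res$hazard_ratio, 2)
  expect_lt(res$hazard_ratio, 4.5)
  expect_lt(res$p, 1e-6)
})

test_that("subtype comparison orients cluster 1 to the higher score", {
  set.seed(27)
  labels <- rep(c(1, 2), each = 50)
  score <- rnorm(100) + 2 * (labels == 2)   # cluster 2 scores higher
  sv <- generate_survival(labels, 3, 0.1, seed = 3)
  res <- compare_subtypes(labels, score, sv$time, sv$event)
  # labels re-oriented: cluster 1 now has the higher median score
  expect_gt(median(score[res$labels == 1]), median(score[res$labels == 2]))
  # orientation invariance: swapping input labels changes nothing
  res_sw <- compare_subtypes(3 - labels, score, sv$time, sv$event)
  expect_equal(res_sw$labels, res$labels)
  expect_equal(res_sw$wilcoxon_p, res$wilcoxon_p)
  expect_equal(res_sw$logrank_p, res$logrank_p)
  expect_lt(res$wilcoxon_p, 1e-10)
  expect_error(compare_subtypes(rep(1, 100), score, sv$time, sv$event),
               "two non-empty")
})

test_that("planted two-subtype cohorts are recovered end to end", {
  hits <- 0
  for (s in 1:5) {
    coh <- generate_cohort(cohort_config(seed = 6000 + s, n_samples = 100))
    tr <- coh$truth
    markers <- rbind(coh$layers$mrna[tr$subtype_markers$mrna, ],
                     coh$layers$mirna[tr$subtype_markers$mirna, ],
                     coh$layers$methylation[tr$subtype_markers$methylation, ],
                     coh$layers$mutation[tr$subtype_markers$mutation, ],
                     coh$layers$scna[tr$subtype_markers$scna, ])
    rf <- rf_dissimilarity(t(markers), n_trees = 1000, seed = s)
    pam <- pam_cluster(rf$dissimilarity, 2)
    if (adjusted_rand_index(pam$labels, tr$subtype) >= 0.8) hits <- hits + 1
  }
  expect_gte(hits, 4)
})
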