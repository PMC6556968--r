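#' Write a features x samples matrix as TSV
#'
#' First column `feature`, remaining columns one per sample.
#'
#' @param m matrix with row and column names.
#' @param path output file.
#' @export
write_layer_tsv <- function(m, path) {
  df <- data.frame(feature = rownames(m), as.data.frame(m),
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Read a features x samples TSV into a matrix
#'
#' @param path TSV with a `feature` first column.
#' @return numeric matrix with feature rownames.
#' @export
read_layer_tsv <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE,
                          stringsAsFactors = FALSE)
  feats <- df[[1]]
  if (anyDuplicated(feats)) {
    stop("duplicate feature IDs in ", path, ": ",
         paste(utils::head(feats[duplicated(feats)], 5), collapse = ", "))
  }
  m <- as.matrix(df[, -1, drop = FALSE])
  if (!is.numeric(m)) stop("non-numeric cells in ", path)
  rownames(m) <- feats
  m
}

#' Validate cross-layer input consistency
#'
#' Checks sample-ID alignment between every layer and the clinical table,
#' duplicate feature IDs, non-numeric cells, and missing-value rates.
#' Alignment failures and duplicates are errors; missingness is a warning.
#'
#' @param layers named list of features x samples matrices.
#' @param clinical data.frame with a `sample` column.
#' @return data.frame report with `check`, `level` ("ok"|"warning"|"error"),
#'   `detail`; attribute `n_errors` counts errors. All problems are
#'   enumerated before any error is raised by [run_pipeline()].
#' @export
validate_inputs <- function(layers, clinical) {
  rep_rows <- list()
  add <- function(check, level, detail) {
    rep_rows[[length(rep_rows) + 1]] <<- data.frame(
      check = check, level = level, detail = detail,
      stringsAsFactors = FALSE)
  }
  if (!"sample" %in% names(clinical)) {
    add("clinical", "error", "clinical table lacks a 'sample' column")
  } else {
    cs <- clinical$sample
    for (nm in names(layers)) {
      ls <- colnames(layers[[nm]])
      miss <- setdiff(ls, cs)
      extra <- setdiff(cs, ls)
      if (length(miss) > 0 || length(extra) > 0) {
        add(paste0("alignment:", nm), "error",
            paste0("symmetric difference of sample sets: ",
                   paste(utils::head(c(miss, extra), 10), collapse = ", ")))
      } else {
        add(paste0("alignment:", nm), "ok", "samples aligned")
      }
    }
  }
  for (nm in names(layers)) {
    m <- layers[[nm]]
    if (anyDuplicated(rownames(m))) {
      add(paste0("duplicates:", nm), "error",
          paste("duplicate feature IDs:",
                paste(utils::head(rownames(m)[duplicated(rownames(m))], 5),
                      collapse = ", ")))
    }
    if (!is.numeric(m)) {
      add(paste0("numeric:", nm), "error", "non-numeric cells")
    }
    na_rate <- mean(is.na(m))
    if (na_rate > 0) {
      add(paste0("missing:", nm), "warning",
          sprintf("missing-value rate %.3f", na_rate))
    }
  }
  out <- do.call(rbind, rep_rows)
  attr(out, "n_errors") <- sum(out$level == "error")
  out
}

#' Run the full telomerase-association pipeline on a cohort
#'
#' Orchestrates group assignment from TERT reads, layer filters (expression
#' filter, methylation probe selection, mutation binarization), per-layer
#' confounder-balanced differential analysis, co-expression network and hub
#' discovery, miRNA cluster scoring and target-axis correlation, marker
#' assembly, random-forest dissimilarity subtyping, and survival comparison.
#' Any stage failure aborts with the stage name. Layers absent from
#' `cohort$layers` are skipped and marked in the report.
#'
#' @param cohort a `synthetic_cohort` (or a list with the same structure:
#'   `layers`, `clinical`, `probe_map`).
#' @param seed top-level seed; stage seeds are derived deterministically.
#' @param n_perm permutations for the differential stage (default 200).
#' @param beta soft power for the network stage (default 6).
#' @param min_module_size module size floor (default 30).
#' @param n_trees forest size for subtyping (default 2000).
#' @param fdr_alpha,perm_alpha strict significance thresholds.
#' @param outdir optional directory; when given, stage outputs are written
#'   as TSV/JSON.
#' @return list of class `pipeline_run`: `groups`, `differential` (per
#'   layer), `network`, `mirna`, `subtyping`, `report` (run summary with
#'   seeds, per-layer significant counts, subtype sizes, test statistics).
#' @export
run_pipeline <- function(cohort, seed, n_perm = 200L, beta = 6,
                         min_module_size = 30L, n_trees = 2000L,
                         fdr_alpha = 0.05, perm_alpha = 0.05,
                         outdir = NULL) {
  if (missing(seed)) stop("seed is mandatory")
  stage <- "validate_inputs"
  result <- tryCatch({
    layers <- cohort$layers
    clinical <- cohort$clinical
    val <- validate_inputs(layers, clinical)
    if (attr(val, "n_errors") > 0) {
      stop(paste(val$detail[val$level == "error"], collapse = "; "))
    }

    stage <- "assign_groups"
    grp <- assign_tert_groups(
      stats::setNames(clinical$tert_reads, clinical$sample), clinical$alt)
    keep <- grp$label %in% c("high", "low")
    z <- as.integer(grp$label[keep] == "high")
    samples <- grp$sample[keep]
    clinical <- clinical[match(samples, clinical$sample), , drop = FALSE]
    covars <- clinical[, grep("^conf", names(clinical)), drop = FALSE]
    layers <- lapply(layers, function(m) m[, samples, drop = FALSE])

    stage <- "layer_filters"
    skipped <- character(0)
    if (!is.null(layers$mrna)) {
      kept <- filter_expressed_mrna(layers$mrna, z)
      mrna_f <- layers$mrna[kept, , drop = FALSE]
    } else {
      mrna_f <- NULL; skipped <- c(skipped, "mrna")
    }
    if (!is.null(layers$methylation) && !is.null(mrna_f)) {
      sel <- select_methylation_probe(layers$methylation, cohort$probe_map,
                                      layers$mrna)
      meth_f <- layers$methylation[sel$probe, , drop = FALSE]
    } else {
      meth_f <- NULL; skipped <- c(skipped, "methylation")
    }

    stage <- "differential"
    diff_layers <- list(mrna = mrna_f, methylation = meth_f,
                        mirna = layers$mirna, mutation = layers$mutation,
                        scna = layers$scna)
    diff <- list()
    for (i in seq_along(diff_layers)) {
      nm <- names(diff_layers)[i]
      if (is.null(diff_layers[[nm]])) {
        skipped <- unique(c(skipped, nm)); next
      }
      diff[[nm]] <- psm_differential(diff_layers[[nm]], z, covars,
                                     n_perm = n_perm, seed = seed + i,
                                     fdr_alpha = fdr_alpha,
                                     perm_alpha = perm_alpha)
    }

    stage <- "coexpr_network"
    network <- NULL
    if (!is.null(mrna_f)) {
      adj <- adjacency_matrix(mrna_f, beta)
      tom <- topological_overlap(adj)
      labels <- detect_modules(tom, min_module_size = min_module_size)
      me <- if (any(labels > 0)) module_eigengene(mrna_f, labels) else NULL
      conn <- intramodular_connectivity(adj, labels)
      network <- list(beta = beta, module_labels = labels,
                      eigengenes = me, connectivity = conn,
                      kme = if (!is.null(me)) kme(mrna_f, me) else NULL)
    }

    stage <- "mirna"
    mirna_res <- NULL
    if (!is.null(layers$mirna)) {
      cl <- mirna_cluster_score(layers$mirna)
      cl_test <- group_score_test(cl$score, z)
      tl <- if ("tl_ratio" %in% names(clinical)) {
        telomere_ratio_correlation(cl$score, clinical$tl_ratio)
      } else NULL
      mirna_res <- list(cluster_score = cl$score, cluster_test = cl_test,
                        tl_correlation = tl)
    }

    stage <- "subtyping"
    sub_res <- NULL
    if (length(diff) > 0) {
      hub_genes <- if (!is.null(network)) {
        with(network$connectivity, gene[hub])
      } else character(0)
      diff_tabs <- lapply(diff, function(d) d$results)
      profile <- assemble_marker_profile(
        diff_tabs, diff_layers, hub_genes = hub_genes,
        mirna_cluster = if (!is.null(layers$mirna))
          intersect(mirna_cluster_names(6L), rownames(layers$mirna))
        else character(0))
      rf <- rf_dissimilarity(profile$profile, n_trees = n_trees,
                             seed = seed + 100L)
      pam <- pam_cluster(rf$dissimilarity, k = 2L)
      act <- if (!is.null(mrna_f)) {
        sig <- utils::head(significant_features(
          diff$mrna$results)$feature, 50)
        if (length(sig) == 0) sig <- rownames(mrna_f)[1:20]
        telomerase_activity_score(layers$mrna, sig)
      } else NULL
      cmp <- if (!is.null(act) && "time" %in% names(clinical)) {
        compare_subtypes(pam$labels, act, clinical$time, clinical$event)
      } else NULL
      sub_res <- list(marker_profile = profile, dissimilarity =
                        rf$dissimilarity, pam = pam,
                      activity_score = act, comparison = cmp)
    }

    stage <- "report"
    report <- list(
      seed = seed, n_perm = n_perm, n_trees = n_trees,
      n_samples = length(samples),
      group_sizes = as.list(table(ifelse(z == 1, "high", "low"))),
      skipped_layers = skipped,
      significant_per_layer = lapply(diff, function(d)
        sum(d$results$significant)),
      n_modules = if (!is.null(network))
        length(unique(network$module_labels[network$module_labels > 0]))
      else NA_integer_,
      subtype_sizes = if (!is.null(sub_res))
        as.list(table(sub_res$comparison$labels)) else NULL,
      stats = if (!is.null(sub_res) && !is.null(sub_res$comparison)) list(
        wilcoxon_p = sub_res$comparison$wilcoxon_p,
        logrank_p = sub_res$comparison$logrank_p,
        cox_hazard_ratio = sub_res$comparison$cox_hazard_ratio
      ) else NULL
    )
    list(groups = grp, differential = diff, network = network,
         mirna = mirna_res, subtyping = sub_res, report = report)
  }, error = function(e) {
    stop("pipeline stage '", stage, "' failed: ", conditionMessage(e),
         call. = FALSE)
  })

  if (!is.null(outdir)) write_pipeline_outputs(result, outdir)
  structure(result, class = "pipeline_run")
}

write_pipeline_outputs <- function(run, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  for (nm in names(run$differential)) {
    utils::write.table(run$differential[[nm]]$results,
                       file.path(outdir, paste0("differential_", nm,
                                                ".tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(run$differential[[nm]]$balance,
                       file.path(outdir, paste0("balance_", nm, ".tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  if (!is.null(run$network)) {
    utils::write.table(run$network$connectivity,
                       file.path(outdir, "module_assignment.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    if (!is.null(run$network$eigengenes)) {
      write_layer_tsv(run$network$eigengenes,
                      file.path(outdir, "eigengenes.tsv"))
    }
  }
  if (!is.null(run$subtyping)) {
    utils::write.table(
      data.frame(sample = rownames(run$subtyping$dissimilarity),
                 cluster = run$subtyping$comparison$labels),
      file.path(outdir, "subtype_labels.tsv"),
      sep = "\t", quote = FALSE, row.names = FALSE)
    write_layer_tsv(run$subtyping$dissimilarity,
                    file.path(outdir, "rf_dissimilarity.tsv"))
  }
  jsonlite::write_json(run$report, file.path(outdir, "run_report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(outdir)
}
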