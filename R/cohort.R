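#' Configuration for the synthetic multi-omics cohort
#'
#' Collects and validates every knob of the generator. Defaults describe the
#' study conditions the downstream stages are validated under: a cohort of
#' 200 tumors whose TERT-high/low label is confounded with clinical
#' covariates, 10% planted differential features at a 1.5 within-group-SD
#' shift, three factor-model co-expression modules of 50 genes with
#' designated hubs, a 6-member miRNA cluster negatively coupled to its mRNA
#' targets and to the tumor/normal telomere-length ratio, and two planted
#' subtypes with a mixed-type marker profile and an exponential survival
#' hazard ratio of 3.
#'
#' @param n_samples number of tumors.
#' @param n_confounders number of clinical confounders (the first is binary,
#'   the rest standard normal).
#' @param confounder_effect log-odds effect of each (centered) confounder on
#'   TERT-high membership.
#' @param n_mrna,n_methylation,n_mirna,n_mutation,n_scna features per layer.
#' @param frac_differential fraction of continuous-layer features planted as
#'   group-differential.
#' @param effect_size planted mean shift in within-group SD units (also sets
#'   the log-odds/latent contrast for mutation and SCNA layers); 0 disables
#'   all planted differential signal.
#' @param confounded_frac fraction of non-differential mRNA features that
#'   depend on the confounders (the source of spurious naive associations).
#' @param confounded_coef per-confounder coefficient on confounded features.
#' @param n_modules,module_size co-expression module count and size.
#' @param hub_loading,nonhub_loading factor loadings in \[0, 1\] for hub and
#'   non-hub module genes (hubs must load harder).
#' @param mirna_cluster_size members of the planted miR-17-92-like cluster.
#' @param n_mirna_targets mRNA genes negatively coupled to the cluster.
#' @param target_coupling negative coupling coefficient.
#' @param n_signature_genes telomerase-activity signature genes sharing the
#'   activity latent factor.
#' @param subtype_effect subtype marker shift in SD units.
#' @param subtype_hazard_ratio hazard multiplier for subtype 2.
#' @param survival_censor_rate fraction of samples censored.
#' @param hypermutator_samples samples spiked with >= 1000 passenger
#'   mutations in the MAF output (exercises the mutation-count filter).
#' @param seed mandatory integer seed; identical config + seed gives
#'   bit-identical output.
#' @return validated list of class `cohort_config`.
#' @export
cohort_config <- function(n_samples = 200L,
                          n_confounders = 3L,
                          confounder_effect = 0.8,
                          n_mrna = 600L,
                          n_methylation = 250L,
                          n_mirna = 120L,
                          n_mutation = 80L,
                          n_scna = 80L,
                          frac_differential = 0.1,
                          effect_size = 1.5,
                          confounded_frac = 0.1,
                          confounded_coef = 0.6,
                          n_modules = 3L,
                          module_size = 50L,
                          hub_loading = 0.9,
                          nonhub_loading = 0.6,
                          mirna_cluster_size = 6L,
                          n_mirna_targets = 30L,
                          target_coupling = -0.8,
                          n_signature_genes = 20L,
                          subtype_effect = 2,
                          subtype_hazard_ratio = 3,
                          survival_censor_rate = 0.2,
                          hypermutator_samples = 0L,
                          seed) {
  if (missing(seed)) stop("seed is mandatory")
  cfg <- list(n_samples = as.integer(n_samples),
              n_confounders = as.integer(n_confounders),
              confounder_effect = confounder_effect,
              n_mrna = as.integer(n_mrna),
              n_methylation = as.integer(n_methylation),
              n_mirna = as.integer(n_mirna),
              n_mutation = as.integer(n_mutation),
              n_scna = as.integer(n_scna),
              frac_differential = frac_differential,
              effect_size = effect_size,
              confounded_frac = confounded_frac,
              confounded_coef = confounded_coef,
              n_modules = as.integer(n_modules),
              module_size = as.integer(module_size),
              hub_loading = hub_loading,
              nonhub_loading = nonhub_loading,
              mirna_cluster_size = as.integer(mirna_cluster_size),
              n_mirna_targets = as.integer(n_mirna_targets),
              target_coupling = target_coupling,
              n_signature_genes = as.integer(n_signature_genes),
              subtype_effect = subtype_effect,
              subtype_hazard_ratio = subtype_hazard_ratio,
              survival_censor_rate = survival_censor_rate,
              hypermutator_samples = as.integer(hypermutator_samples),
              seed = as.integer(seed))
  counts <- c("n_samples", "n_confounders", "n_mrna", "n_methylation",
              "n_mirna", "n_mutation", "n_scna", "n_modules", "module_size",
              "mirna_cluster_size", "n_signature_genes")
  for (f in counts) {
    if (cfg[[f]] < 1L) stop("config error: ", f, " must be >= 1")
  }
  for (f in c("frac_differential", "confounded_frac",
              "survival_censor_rate")) {
    if (cfg[[f]] < 0 || cfg[[f]] > 1) {
      stop("config error: ", f, " must lie in [0, 1]")
    }
  }
  for (f in c("hub_loading", "nonhub_loading")) {
    if (cfg[[f]] < 0 || cfg[[f]] > 1) {
      stop("config error: ", f, " must lie in [0, 1]")
    }
  }
  if (cfg$subtype_hazard_ratio <= 0) {
    stop("config error: subtype_hazard_ratio must be > 0")
  }
  if (cfg$hub_loading <= cfg$nonhub_loading) {
    stop("config error: hub_loading must exceed nonhub_loading")
  }
  if (cfg$n_modules * cfg$module_size > cfg$n_mrna) {
    stop("config error: module_size x n_modules exceeds n_mrna")
  }
  layout <- mrna_layout(cfg)
  if (layout$used > cfg$n_mrna) {
    stop("config error: planted mRNA blocks (", layout$used,
         " genes) exceed n_mrna (", cfg$n_mrna, ")")
  }
  structure(cfg, class = "cohort_config")
}

# disjoint gene-index blocks within the mRNA layer
mrna_layout <- function(cfg) {
  n_diff <- if (cfg$effect_size == 0) 0L else
    as.integer(round(cfg$frac_differential * cfg$n_mrna))
  n_conf <- as.integer(round(cfg$confounded_frac * cfg$n_mrna))
  n_mod <- cfg$n_modules * cfg$module_size
  n_sig <- cfg$n_signature_genes
  n_tgt <- cfg$n_mirna_targets
  n_sub <- min(20L, as.integer(floor(cfg$n_mrna / 10)))
  n_low <- min(20L, as.integer(floor(cfg$n_mrna / 10)))
  starts <- cumsum(c(1L, n_diff, n_conf, n_mod, n_sig, n_tgt, n_sub))
  blk <- function(a, len) if (len == 0L) integer(0) else seq(a, a + len - 1L)
  list(diff = blk(starts[1], n_diff),
       confounded = blk(starts[2], n_conf),
       modules = blk(starts[3], n_mod),
       signature = blk(starts[4], n_sig),
       targets = blk(starts[5], n_tgt),
       subtype = blk(starts[6], n_sub),
       low = blk(starts[7], n_low),
       used = starts[7] + n_low - 1L)
}

# canonical miR-17-92 member names, extended if a larger cluster is asked for
mirna_cluster_names <- function(k) {
  canonical <- c("hsa-mir-17", "hsa-mir-18a", "hsa-mir-19a", "hsa-mir-20a",
                 "hsa-mir-19b-1", "hsa-mir-92a-1")
  if (k <= 6L) return(canonical[seq_len(k)])
  c(canonical, sprintf("hsa-mir-x%02d", seq_len(k - 6L)))
}

#' Generate a synthetic multi-omics cohort with planted ground truth
#'
#' Draws a confounded TERT-high/low cohort: the group label follows a
#' logistic model on the clinical confounders; a subset of non-differential
#' mRNAs depends on the same confounders (so naive tests pick up spurious
#' associations that correct weighting must remove); differential features in
#' every layer carry the configured shift; co-expression modules are
#' factor-model blocks with harder-loading hubs; a designated miRNA cluster
#' is negatively coupled to designated mRNA targets and to the
#' telomere-length ratio; two planted subtypes shift a mixed-type marker
#' panel and drive exponential survival with the configured hazard ratio.
#' All continuous layers are emitted directly on log2 scale.
#'
#' @param config a [cohort_config()].
#' @return list of class `synthetic_cohort` with elements `layers` (named
#'   list of features x samples matrices: mrna, methylation, mirna, mutation,
#'   scna), `clinical` (data.frame: sample, confounders, z, tert_reads,
#'   alt, time, event, tl_ratio), `probe_map` (probe -> gene), `maf`
#'   (MAF-like data.frame), and `truth` (planted ground truth).
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  cfg <- config
  set.seed(cfg$seed)
  n <- cfg$n_samples
  samples <- sprintf("S%04d", seq_len(n))

  ## clinical confounders and confounded group label
  conf <- matrix(stats::rnorm(n * cfg$n_confounders), nrow = n)
  conf[, 1] <- stats::rbinom(n, 1, 0.5)
  colnames(conf) <- sprintf("conf%d", seq_len(cfg$n_confounders))
  centered <- sweep(conf, 2, colMeans(conf))
  lp <- drop(centered %*% rep(cfg$confounder_effect, cfg$n_confounders))
  z <- stats::rbinom(n, 1, stats::plogis(lp))
  tries <- 0L
  while (min(sum(z), n - sum(z)) < max(5L, round(0.15 * n)) && tries < 100L) {
    z <- stats::rbinom(n, 1, stats::plogis(lp))
    tries <- tries + 1L
  }
  if (min(sum(z), n - sum(z)) < 2L) stop("degenerate group draw")

  ## subtype labels and latent factors; the TERT-association of the
  ## subtype, activity and cluster latents scales with effect_size
  ## (0 = fully null). Subtype 1 is enriched among TERT-high tumors, the
  ## way telomerase-active subtypes track TERT expression.
  subtype <- stats::rbinom(n, 1,
                           stats::plogis(0.6 * cfg$effect_size *
                                           (2 * z - 1))) + 1L
  subtype <- 3L - subtype   # subtype 1 = the z-enriched, high-activity arm
  z_coup <- 0.5 * cfg$effect_size
  lat_act <- stats::rnorm(n) + z_coup * z + 0.75 * (subtype == 1L)
  lat_mod <- cbind(lat_act,
                   matrix(stats::rnorm(n * max(0, cfg$n_modules - 1L)),
                          nrow = n))
  lat_clust <- stats::rnorm(n) + z_coup * z

  ## mRNA layer
  lay <- mrna_layout(cfg)
  genes <- sprintf("GENE%04d", seq_len(cfg$n_mrna))
  if (length(lay$diff) > 0) genes[lay$diff[1]] <- "TERT"
  mrna <- matrix(stats::rnorm(cfg$n_mrna * n), nrow = cfg$n_mrna,
                 dimnames = list(genes, samples))
  base_mrna <- stats::runif(cfg$n_mrna, 2, 8)
  mrna <- mrna + base_mrna
  diff_dir <- integer(0)
  sub_coupled_mrna <- character(0)
  if (length(lay$diff) > 0) {
    half <- ceiling(length(lay$diff) / 2)
    diff_dir <- c(rep(1L, half), rep(-1L, length(lay$diff) - half))
    mrna[lay$diff, ] <- mrna[lay$diff, ] +
      cfg$effect_size * diff_dir %o% z
    # a handful of differential genes also separate the planted subtypes,
    # so subtype structure is visible through the TERT-marker panel
    if (length(lay$diff) > 2) {
      cp <- lay$diff[2:min(11L, length(lay$diff))]   # skip TERT itself
      mrna[cp, ] <- mrna[cp, ] +
        cfg$subtype_effect * rep(1, length(cp)) %o% (subtype == 1L)
      sub_coupled_mrna <- genes[cp]
    }
  }
  if (length(lay$confounded) > 0) {
    mrna[lay$confounded, ] <- mrna[lay$confounded, ] +
      rep(1, length(lay$confounded)) %o% drop(centered %*%
        rep(cfg$confounded_coef, cfg$n_confounders))
  }
  module_labels <- integer(cfg$n_mrna)
  hub_genes <- character(0)
  n_hub <- as.integer(ceiling(0.05 * cfg$module_size))
  for (m in seq_len(cfg$n_modules)) {
    idx <- lay$modules[seq((m - 1L) * cfg$module_size + 1L,
                           m * cfg$module_size)]
    module_labels[idx] <- m
    loading <- rep(cfg$nonhub_loading, cfg$module_size)
    loading[seq_len(n_hub)] <- cfg$hub_loading
    hub_genes <- c(hub_genes, genes[idx[seq_len(n_hub)]])
    mrna[idx, ] <- base_mrna[idx] +
      loading %o% lat_mod[, m] +
      sqrt(1 - loading^2) * matrix(stats::rnorm(cfg$module_size * n),
                                   nrow = cfg$module_size)
  }
  if (length(lay$signature) > 0) {
    mrna[lay$signature, ] <- base_mrna[lay$signature] +
      rep(0.7, length(lay$signature)) %o% lat_act +
      sqrt(1 - 0.49) * matrix(stats::rnorm(length(lay$signature) * n),
                              nrow = length(lay$signature))
  }
  if (length(lay$targets) > 0) {
    mrna[lay$targets, ] <- base_mrna[lay$targets] +
      rep(cfg$target_coupling, length(lay$targets)) %o% lat_clust +
      matrix(stats::rnorm(length(lay$targets) * n),
             nrow = length(lay$targets))
  }
  if (length(lay$subtype) > 0) {
    mrna[lay$subtype, ] <- mrna[lay$subtype, ] +
      cfg$subtype_effect * rep(1, length(lay$subtype)) %o% (subtype == 1L)
  }
  if (length(lay$low) > 0) {
    mrna[lay$low, ] <- pmax(0, 0.4 +
      0.3 * matrix(stats::rnorm(length(lay$low) * n),
                   nrow = length(lay$low)))
  }

  ## methylation layer: functional probes anti-correlated with half of the
  ## differential mRNAs, plus competing and background noise probes
  n_func <- min(floor(length(lay$diff) / 2), floor(cfg$n_methylation / 3))
  func_gene_idx <- if (n_func > 0) lay$diff[seq_len(n_func)] else integer(0)
  probes <- sprintf("cg%07d", seq_len(cfg$n_methylation))
  probe_gene <- rep(NA_character_, cfg$n_methylation)
  meth <- matrix(0, nrow = cfg$n_methylation, ncol = n,
                 dimnames = list(probes, samples))
  pos <- 1L
  meth_diff_probes <- character(0)
  meth_diff_dir <- integer(0)
  sub_coupled_meth <- character(0)
  if (n_func > 0) {
    for (k in seq_len(n_func)) {
      g <- func_gene_idx[k]
      expr_sc <- as.numeric(scale(mrna[g, ]))
      beta_lin <- 0.5 - 0.22 * expr_sc + 0.06 * stats::rnorm(n)
      if (k <= 3L) {   # subtype-coupled probes
        beta_lin <- beta_lin + 0.05 * cfg$subtype_effect * (subtype == 1L)
        sub_coupled_meth <- c(sub_coupled_meth, probes[pos])
      }
      meth[pos, ] <- pmin(pmax(beta_lin, 0.01), 0.99)
      probe_gene[pos] <- genes[g]
      meth_diff_probes <- c(meth_diff_probes, probes[pos])
      meth_diff_dir <- c(meth_diff_dir, -diff_dir[k])
      pos <- pos + 1L
    }
    # a competing noise probe for each functional gene (probe selection must
    # prefer the anti-correlated one)
    for (k in seq_len(n_func)) {
      meth[pos, ] <- pmin(pmax(0.5 + 0.12 * stats::rnorm(n), 0.01), 0.99)
      probe_gene[pos] <- genes[func_gene_idx[k]]
      pos <- pos + 1L
    }
  }
  sub_meth_probes <- character(0)
  n_sub_meth <- min(5L, cfg$n_methylation - pos + 1L)
  if (n_sub_meth > 0) {
    for (k in seq_len(n_sub_meth)) {
      meth[pos, ] <- pmin(pmax(0.4 + 0.1 * cfg$subtype_effect / 2 *
                                 (subtype == 1L) + 0.08 * stats::rnorm(n),
                               0.01), 0.99)
      probe_gene[pos] <- genes[lay$subtype[min(k, length(lay$subtype))]]
      sub_meth_probes <- c(sub_meth_probes, probes[pos])
      pos <- pos + 1L
    }
  }
  other_genes <- setdiff(seq_len(cfg$n_mrna), func_gene_idx)
  while (pos <= cfg$n_methylation) {
    meth[pos, ] <- pmin(pmax(stats::rbeta(n, 2, 2), 0.01), 0.99)
    probe_gene[pos] <- genes[other_genes[(pos %% length(other_genes)) + 1L]]
    pos <- pos + 1L
  }
  probe_map <- data.frame(probe = probes, gene = probe_gene,
                          stringsAsFactors = FALSE)

  ## miRNA layer
  k_cl <- cfg$mirna_cluster_size
  mirnas <- sprintf("hsa-mir-%04d", seq_len(cfg$n_mirna))
  mirnas[seq_len(k_cl)] <- mirna_cluster_names(k_cl)
  mirna <- matrix(stats::rnorm(cfg$n_mirna * n), nrow = cfg$n_mirna,
                  dimnames = list(mirnas, samples))
  base_mirna <- stats::runif(cfg$n_mirna, 2, 7)
  mirna <- mirna + base_mirna
  mirna[seq_len(k_cl), ] <- base_mirna[seq_len(k_cl)] +
    rep(0.8, k_cl) %o% lat_clust +
    0.6 * matrix(stats::rnorm(k_cl * n), nrow = k_cl)
  n_diff_mir <- if (cfg$effect_size == 0) 0L else
    as.integer(round(cfg$frac_differential * cfg$n_mirna))
  mir_diff_idx <- integer(0)
  mir_diff_dir <- integer(0)
  if (n_diff_mir > 0) {
    mir_diff_idx <- seq(k_cl + 1L, min(k_cl + n_diff_mir, cfg$n_mirna))
    half <- ceiling(length(mir_diff_idx) / 2)
    mir_diff_dir <- c(rep(1L, half), rep(-1L, length(mir_diff_idx) - half))
    mirna[mir_diff_idx, ] <- mirna[mir_diff_idx, ] +
      cfg$effect_size * mir_diff_dir %o% z
    cp <- mir_diff_idx[seq_len(min(3L, length(mir_diff_idx)))]
    mirna[cp, ] <- mirna[cp, ] +
      cfg$subtype_effect * rep(1, length(cp)) %o% (subtype == 1L)
    sub_coupled_mirna <- mirnas[cp]
  } else sub_coupled_mirna <- character(0)
  sub_mir_idx <- integer(0)
  if (cfg$n_mirna >= k_cl + n_diff_mir + 5L) {
    sub_mir_idx <- seq(k_cl + n_diff_mir + 1L, k_cl + n_diff_mir + 5L)
    mirna[sub_mir_idx, ] <- mirna[sub_mir_idx, ] +
      cfg$subtype_effect * rep(1, 5L) %o% (subtype == 1L)
  }

  ## mutation layer (binary gene x sample)
  mut_genes <- sprintf("MT%04d", seq_len(cfg$n_mutation))
  base_rate <- stats::runif(cfg$n_mutation, 0.03, 0.12)
  n_diff_mut <- if (cfg$effect_size == 0) 0L else
    max(2L, as.integer(round(cfg$frac_differential * cfg$n_mutation)))
  n_diff_mut <- min(n_diff_mut, cfg$n_mutation)
  mut_dir <- integer(0)
  rate_mat <- matrix(rep(base_rate, n), nrow = cfg$n_mutation)
  sub_coupled_mut <- character(0)
  if (n_diff_mut > 0) {
    half <- ceiling(n_diff_mut / 2)
    mut_dir <- c(rep(1L, half), rep(-1L, n_diff_mut - half))
    for (k in seq_len(n_diff_mut)) {
      p0 <- 0.12
      lg <- stats::qlogis(p0) + mut_dir[k] * cfg$effect_size * z
      if (k <= 3L) {   # subtype-coupled mutation genes
        lg <- lg + 1.2 * (subtype == 1L)
        sub_coupled_mut <- c(sub_coupled_mut, mut_genes[k])
      }
      rate_mat[k, ] <- stats::plogis(lg)
    }
  }
  sub_mut_idx <- integer(0)
  if (cfg$n_mutation >= n_diff_mut + 5L) {
    sub_mut_idx <- seq(n_diff_mut + 1L, n_diff_mut + 5L)
    for (k in sub_mut_idx) {
      rate_mat[k, ] <- ifelse(subtype == 1L, 0.45, 0.08)
    }
  }
  mutation <- matrix(stats::rbinom(cfg$n_mutation * n, 1,
                                   as.vector(rate_mat)),
                     nrow = cfg$n_mutation,
                     dimnames = list(mut_genes, samples))

  ## SCNA layer: latent normal cut into GISTIC-style calls -2..2
  scna_feats <- sprintf("SC%04d", seq_len(cfg$n_scna))
  lat_scna <- matrix(stats::rnorm(cfg$n_scna * n), nrow = cfg$n_scna)
  n_diff_scna <- if (cfg$effect_size == 0) 0L else
    max(2L, as.integer(round(cfg$frac_differential * cfg$n_scna)))
  n_diff_scna <- min(n_diff_scna, cfg$n_scna)
  scna_dir <- integer(0)
  if (n_diff_scna > 0) {
    half <- ceiling(n_diff_scna / 2)
    scna_dir <- c(rep(1L, half), rep(-1L, n_diff_scna - half))
    lat_scna[seq_len(n_diff_scna), ] <- lat_scna[seq_len(n_diff_scna), ] +
      0.8 * cfg$effect_size * scna_dir %o% z
    cp <- seq_len(min(3L, n_diff_scna))
    lat_scna[cp, ] <- lat_scna[cp, ] +
      0.6 * cfg$subtype_effect * rep(1, length(cp)) %o% (subtype == 1L)
    sub_coupled_scna <- scna_feats[cp]
  } else sub_coupled_scna <- character(0)
  sub_scna_idx <- integer(0)
  if (cfg$n_scna >= n_diff_scna + 5L) {
    sub_scna_idx <- seq(n_diff_scna + 1L, n_diff_scna + 5L)
    lat_scna[sub_scna_idx, ] <- lat_scna[sub_scna_idx, ] +
      0.8 * cfg$subtype_effect * rep(1, 5L) %o% (subtype == 1L)
  }
  scna <- matrix(as.integer(cut(lat_scna,
                                breaks = c(-Inf, -1.5, -0.5, 0.5, 1.5, Inf),
                                labels = FALSE)) - 3L,
                 nrow = cfg$n_scna, dimnames = list(scna_feats, samples))

  ## telomere-length ratio anti-coupled to the miRNA cluster latent
  tl_ratio <- 1 + 0.2 * cfg$target_coupling * lat_clust +
    0.1 * stats::rnorm(n)

  ## TERT read counts consistent with the group label; no ALT samples
  tert_reads <- ifelse(z == 1L, 2L + stats::rpois(n, 5),
                       stats::rbinom(n, 1, 0.4))
  alt <- rep(FALSE, n)

  ## survival from the planted subtypes
  surv <- generate_survival(subtype, cfg$subtype_hazard_ratio,
                            cfg$survival_censor_rate,
                            seed = cfg$seed + 1L)

  clinical <- data.frame(sample = samples,
                         as.data.frame(conf),
                         z = z, tert_reads = tert_reads, alt = alt,
                         time = surv$time, event = surv$event,
                         tl_ratio = tl_ratio,
                         stringsAsFactors = FALSE)

  ## MAF representation of the mutation layer (+ optional hypermutators)
  maf <- mutation_to_maf(mutation)
  if (cfg$hypermutator_samples > 0L) {
    hyper <- samples[seq_len(min(cfg$hypermutator_samples, n))]
    extra <- do.call(rbind, lapply(hyper, function(s) {
      data.frame(Hugo_Symbol = sprintf("PSG%05d", seq_len(1200L)),
                 Tumor_Sample_Barcode = s,
                 Variant_Classification = "Missense_Mutation",
                 stringsAsFactors = FALSE)
    }))
    maf <- rbind(maf, extra)
  }

  truth <- list(
    differential = list(
      mrna = data.frame(feature = genes[lay$diff],
                        direction = ifelse(diff_dir > 0, "high-specific",
                                           "low-specific"),
                        stringsAsFactors = FALSE),
      methylation = data.frame(feature = meth_diff_probes,
                               direction = ifelse(meth_diff_dir > 0,
                                                  "high-specific",
                                                  "low-specific"),
                               stringsAsFactors = FALSE),
      mirna = data.frame(feature = mirnas[mir_diff_idx],
                         direction = ifelse(mir_diff_dir > 0,
                                            "high-specific", "low-specific"),
                         stringsAsFactors = FALSE),
      mutation = data.frame(feature = mut_genes[seq_len(n_diff_mut)],
                            direction = ifelse(mut_dir > 0, "high-specific",
                                               "low-specific"),
                            stringsAsFactors = FALSE),
      scna = data.frame(feature = scna_feats[seq_len(n_diff_scna)],
                        direction = ifelse(scna_dir > 0, "high-specific",
                                           "low-specific"),
                        stringsAsFactors = FALSE)
    ),
    module_labels = stats::setNames(module_labels, genes),
    hub_genes = hub_genes,
    signature_genes = genes[lay$signature],
    mirna_cluster = mirnas[seq_len(k_cl)],
    mirna_targets = genes[lay$targets],
    confounded_features = genes[lay$confounded],
    # features carrying real group signal through the activity/cluster
    # latents or the z-enriched subtype, without being on the explicit
    # differential list; recovery tests exclude them from the negative
    # universe
    group_coupled = list(
      mrna = if (z_coup != 0)
        genes[c(lay$modules[seq_len(min(cfg$module_size,
                                        length(lay$modules)))],
                lay$signature, lay$targets, lay$subtype)] else character(0),
      methylation = if (z_coup != 0) sub_meth_probes else character(0),
      mirna = if (z_coup != 0) c(mirnas[seq_len(k_cl)],
                                 mirnas[sub_mir_idx]) else character(0),
      mutation = if (z_coup != 0) mut_genes[sub_mut_idx] else character(0),
      scna = if (z_coup != 0) scna_feats[sub_scna_idx] else character(0)),
    confounder_coefficients = rep(cfg$confounder_effect, cfg$n_confounders),
    subtype = stats::setNames(subtype, samples),
    subtype_markers = list(mrna = genes[lay$subtype],
                           methylation = sub_meth_probes,
                           mirna = mirnas[sub_mir_idx],
                           mutation = mut_genes[sub_mut_idx],
                           scna = scna_feats[sub_scna_idx]),
    # differential features that additionally separate the subtypes (the
    # route by which the TERT-marker panel carries subtype signal)
    subtype_coupled = list(mrna = sub_coupled_mrna,
                           methylation = sub_coupled_meth,
                           mirna = sub_coupled_mirna,
                           mutation = sub_coupled_mut,
                           scna = sub_coupled_scna),
    activity_latent = stats::setNames(lat_act, samples),
    cluster_latent = stats::setNames(lat_clust, samples)
  )

  structure(list(layers = list(mrna = mrna, methylation = meth,
                               mirna = mirna, mutation = mutation,
                               scna = scna),
                 clinical = clinical, probe_map = probe_map, maf = maf,
                 truth = truth, config = cfg),
            class = "synthetic_cohort")
}

#' Exponential survival times for planted subtypes
#'
#' Event times are exponential with baseline rate 0.1, multiplied by
#' `hazard_ratio` for subtype 2. Censoring is independent: each sample is
#' censored with probability `censor_rate`, and censored samples report a
#' uniform fraction of their (unobserved) event time.
#'
#' @param subtype_labels vector in \{1, 2\}.
#' @param hazard_ratio positive hazard multiplier for subtype 2.
#' @param censor_rate fraction censored in \[0, 1\].
#' @param seed RNG seed.
#' @return list with `time` (> 0) and `event` (1 = death, 0 = censored).
#' @export
generate_survival <- function(subtype_labels, hazard_ratio, censor_rate,
                              seed) {
  if (missing(seed)) stop("seed is mandatory")
  if (!all(subtype_labels %in% c(1, 2))) stop("labels must be 1 or 2")
  if (hazard_ratio <= 0) stop("hazard_ratio must be > 0")
  if (censor_rate < 0 || censor_rate > 1) stop("censor_rate in [0,1]")
  set.seed(seed)
  n <- length(subtype_labels)
  rate <- 0.1 * ifelse(subtype_labels == 2, hazard_ratio, 1)
  t_event <- stats::rexp(n, rate = rate)
  event <- stats::rbinom(n, 1, 1 - censor_rate)
  time <- ifelse(event == 1L, t_event, t_event * stats::runif(n))
  time <- pmax(time, .Machine$double.eps)
  list(time = time, event = as.integer(event))
}

# MAF-like table from a binary gene x sample matrix
mutation_to_maf <- function(mutation) {
  hits <- which(mutation == 1L, arr.ind = TRUE)
  data.frame(Hugo_Symbol = rownames(mutation)[hits[, 1]],
             Tumor_Sample_Barcode = colnames(mutation)[hits[, 2]],
             Variant_Classification = "Missense_Mutation",
             stringsAsFactors = FALSE)
}

#' Write a synthetic cohort to plain-text files
#'
#' Each layer as TSV (feature rows x sample columns, first column `feature`),
#' clinical and probe map as TSV, MAF as TSV, truth as JSON.
#'
#' @param cohort a `synthetic_cohort`.
#' @param dir output directory (created if absent).
#' @return invisibly, the written file paths.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  for (nm in names(cohort$layers)) {
    p <- file.path(dir, paste0(nm, ".tsv"))
    write_layer_tsv(cohort$layers[[nm]], p)
    paths <- c(paths, p)
  }
  p <- file.path(dir, "clinical.tsv")
  utils::write.table(cohort$clinical, p, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  paths <- c(paths, p)
  p <- file.path(dir, "probe_map.tsv")
  utils::write.table(cohort$probe_map, p, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  paths <- c(paths, p)
  p <- file.path(dir, "mutations.maf.tsv")
  utils::write.table(cohort$maf, p, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  paths <- c(paths, p)
  p <- file.path(dir, "truth.json")
  truth <- cohort$truth
  truth$module_labels <- as.list(truth$module_labels)
  truth$subtype <- as.list(truth$subtype)
  truth$activity_latent <- as.list(truth$activity_latent)
  truth$cluster_latent <- as.list(truth$cluster_latent)
  jsonlite::write_json(truth, p, auto_unbox = TRUE, digits = NA)
  paths <- c(paths, p)
  invisible(paths)
}
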