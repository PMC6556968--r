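# shared fixtures, generated once per test run

.fixtures <- new.env(parent = emptyenv())

# default-condition cohort (n = 200), reused by several test files
default_cohort <- function() {
  if (is.null(.fixtures$default)) {
    .fixtures$default <- generate_cohort(cohort_config(seed = 7))
  }
  .fixtures$default
}

# small, fast cohort for pipeline-level tests
small_cohort <- function() {
  if (is.null(.fixtures$small)) {
    .fixtures$small <- generate_cohort(cohort_config(
      n_samples = 120L, n_mrna = 250L, n_methylation = 60L, n_mirna = 40L,
      n_mutation = 30L, n_scna = 30L, n_modules = 2L, module_size = 40L,
      seed = 11))
  }
  .fixtures$small
}

cohort_covariates <- function(cohort) {
  cohort$clinical[, grep("^conf", names(cohort$clinical)), drop = FALSE]
}

# gene universe over which planted module labels are exhaustive: module
# genes plus unstructured background (other planted blocks are genuinely
# co-correlated but not part of module truth)
module_truth_universe <- function(cohort) {
  tr <- cohort$truth
  mod <- names(tr$module_labels)[tr$module_labels > 0]
  planted <- unique(c(tr$differential$mrna$feature, tr$confounded_features,
                      tr$signature_genes, tr$mirna_targets,
                      tr$subtype_markers$mrna))
  c(mod, setdiff(names(tr$module_labels), c(mod, planted)))
}

# negatives for differential-recovery checks: everything except features
# that carry real group signal through the shared latents
differential_universe <- function(cohort, layer = "mrna") {
  feats <- rownames(cohort$layers[[layer]])
  coupled <- cohort$truth$group_coupled[[layer]]
  if (is.null(coupled)) coupled <- character(0)
  setdiff(feats, coupled)
}
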