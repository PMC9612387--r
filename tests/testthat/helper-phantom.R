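# Shared desk-scale fixtures. The reduced 36x36x26 phantom keeps the same
# 15 mm tumor and zero ventricle exclusion (tumor and mirrored VOI have
# identical shape, as in the clinical design) while simulating fast.
# Expensive cohort tables are memoised for the whole test run.

.fixture_cache <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, force(expr), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

small_spec <- function(noise_scale = 1) {
  phantom_spec(grid_shape = c(36, 36, 26), tumor_center = c(28, 17, 13),
               ventricle_center = c(16, 21, 13),
               ventricle_radii_mm = c(8, 16, 12),
               noise_scale = noise_scale)
}

iso_cohort_table <- function() {
  memo("iso_table", extract_cohort(
    plan = cohort_plan(29, c(isometabolic = 1, photopenic = 0),
                       base_seed = 101),
    spec = small_spec()))
}

pho_cohort_table <- function() {
  memo("pho_table", extract_cohort(
    plan = cohort_plan(17, c(isometabolic = 0, photopenic = 1),
                       base_seed = 202),
    spec = small_spec()))
}

# union of the two phenotype cohorts: a 46-patient FET-negative cohort
whole_cohort_table <- function() {
  memo("whole_table", {
    iso <- iso_cohort_table()
    pho <- pho_cohort_table()
    iso$patient_id <- paste0("I", iso$patient_id)
    pho$patient_id <- paste0("F", pho$patient_id)
    rbind(iso, pho)
  })
}

# small synthetic feature table with iid noise features (no signal)
noise_feature_table <- function(n_patients = 20, n_features = 5,
                                seed = 1) {
  set.seed(seed)
  rows <- expand.grid(patient_id = sprintf("P%03d", seq_len(n_patients)),
                      voi_label = c("tumor", "mirrored"),
                      image_kind = image_kinds(),
                      stringsAsFactors = FALSE)
  rows$phenotype <- "isometabolic"
  rows$n_degenerate <- 0L
  f <- matrix(rnorm(nrow(rows) * n_features), nrow(rows))
  colnames(f) <- sprintf("feat%02d", seq_len(n_features))
  cbind(rows, f)
}
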