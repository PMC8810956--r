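#' Run the full pipeline on a synthetic phantom cohort
#'
#' Generates a cohort of post-ablation phantoms, windows each case into
#' the three-channel representation, samples labelled patches under the
#' rule-based scheme, augments the training positives, trains the 3D CNN,
#' selects the operating threshold on the validation split, evaluates the
#' held-out test patches and derives bounding-box proposals, reporting the
#' fraction of test lesions whose true centre is covered by at least one
#' proposal box (the lesion hit rate).
#'
#' The default cohort composition and split are [generate_cohort()]'s
#' defaults — 34 lesion-bearing cases with 49 lesions plus 40 controls,
#' case splits 21/5/8 and 27/5/8, lesion split 36/5/8 — which with the
#' default sampling rates yields 2,640 training, 500 validation and 800
#' test patches (160 positive / 640 negative in the test split). The
#' default training budget (8 epochs, patience 3) keeps the whole run in
#' the ten-minute range on one CPU; see the vignette.
#'
#' @param n_ltp,n_noltp,n_lesions Cohort composition.
#' @param ltp_split,noltp_split,lesion_split Per-split counts
#'   (train/validation/test); see [generate_cohort()].
#' @param phantom A [phantom_params()] shared by all cases.
#' @param sampling A [sampling_config()].
#' @param training A [train_config()].
#' @param seed Master seed; cohort, sampling, augmentation and training
#'   seeds are all derived from it.
#' @param verbose Print progress messages.
#' @return List of class `phantom_experiment` with elements `cohort`
#'   (manifest only), `model`, `threshold`, `report` (a
#'   [evaluate_model()] result on the test patches), `proposals`,
#'   `hit_rate`, `n_test_lesions` and `patch_counts`.
#' @export
run_phantom_experiment <- function(n_ltp = 34L, n_noltp = 40L,
                                   n_lesions = 49L,
                                   ltp_split = c(21L, 5L, 8L),
                                   noltp_split = c(27L, 5L, 8L),
                                   lesion_split = c(36L, 5L, 8L),
                                   phantom = phantom_params(),
                                   sampling = sampling_config(),
                                   training = train_config(epochs = 8L,
                                                           patience = 3L),
                                   seed = 1L, verbose = FALSE) {
  say <- function(...) if (verbose) message(sprintf(...))
  seeds <- withr::with_seed(seed, sample.int(.Machine$integer.max, 4L))

  say("generating %d phantom cases ...", n_ltp + n_noltp)
  cohort <- generate_cohort(n_ltp, n_noltp, n_lesions, ltp_split, noltp_split,
                            lesion_split, params = phantom, seed = seeds[1])

  say("sampling patches ...")
  sampling$seed <- seeds[2]
  smp <- sample_cohort_patches(cohort, sampling)
  idx <- smp$index
  patches <- smp$patches

  counts <- table(idx$label, idx$split)

  split_of <- function(s) which(idx$split == s)
  train_ids <- split_of("train")
  val_ids <- split_of("validation")
  test_ids <- split_of("test")

  train_patches <- patches[train_ids]

  say("training the 3D CNN on %d patches (positives re-augmented each epoch) ...",
      length(train_patches))
  training$seed <- seeds[4]
  model <- train_cnn(structure(train_patches, class = "patch_set"),
                     structure(patches[val_ids], class = "patch_set"),
                     config = training, augment_fn = augment_patch)

  say("selecting the operating threshold on the validation split ...")
  val_probs <- predict_proba(model, patches[val_ids])
  threshold <- select_threshold(val_probs, idx$label[val_ids])

  say("evaluating on %d held-out test patches ...", length(test_ids))
  test_patches <- structure(patches[test_ids], class = "patch_set")
  test_probs <- predict_proba(model, test_patches)
  report <- evaluate_model(test_probs, idx$label[test_ids], threshold)

  index <- build_candidate_index(test_patches)
  proposals <- propose_regions(model, index, test_patches, threshold)

  # lesion hit rate on held-out cases: a lesion is hit when some proposal
  # box contains its (x, y) with its z inside the proposal's slice stack
  test_cases <- cohort$manifest$case_id[cohort$manifest$split == "test" &
                                          cohort$manifest$group == "LTP"]
  hits <- 0L; total <- 0L
  for (cid in test_cases) {
    case <- cohort$cases[[match(cid, cohort$manifest$case_id)]]
    pr <- proposals[proposals$case_id == cid, ]
    for (l in seq_len(nrow(case$lesion_centers))) {
      total <- total + 1L
      ctr <- case$lesion_centers[l, ]
      hit <- any(pr$box_x0 <= ctr[1] & ctr[1] <= pr$box_x1 &
                   pr$box_y0 <= ctr[2] & ctr[2] <= pr$box_y1 &
                   pr$z_first <= ctr[3] & ctr[3] <= pr$z_last)
      hits <- hits + as.integer(hit)
    }
  }

  structure(
    list(cohort = cohort$manifest, model = model, threshold = threshold,
         report = report, proposals = proposals,
         hit_rate = if (total > 0) hits / total else NA_real_,
         n_test_lesions = total, patch_counts = counts),
    class = "phantom_experiment"
  )
}

#' @export
print.phantom_experiment <- function(x, ...) {
  cat("<phantom_experiment>\n")
  cat("  patch counts by split:\n")
  print(x$patch_counts)
  cat(sprintf("  threshold: %.4f\n", x$threshold))
  cat(sprintf("  test AUC: %.4f, AP: %.4f\n", x$report$auc,
              x$report$average_precision))
  cat(sprintf("  lesion hit rate: %.2f (%d test lesions)\n", x$hit_rate,
              x$n_test_lesions))
  invisible(x)
}
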