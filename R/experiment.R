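# Desk-scale reproduction of the master -> calibrated transfer-learning
# experiment on synthetic patches from two center styles.

#' Default styles for the two synthetic centers
#'
#' The reference center is a mildly randomized classic HES appearance; the
#' target center differs by a +30 degree hue rotation, a x0.8 brightness
#' drop, stronger scanner noise, and independently drawn stain tones — a
#' shift large enough that a linear probe on mean patch color separates
#' the centers, emulating the inter-center appearance gap.
#' @return list with `reference` and `target` `center_style`s.
#' @export
experiment_styles <- function() {
  list(
    reference = make_center_style(list(name = "reference"), seed = 101L),
    target = make_center_style(list(name = "target", hue_shift_deg = 30,
                                    brightness_scale = 0.8, noise_sd = 8),
                               seed = 202L)
  )
}

#' Master/calibrated transfer-learning experiment on synthetic patches
#'
#' Renders labeled x5 context patches for a reference and a target center,
#' trains the master classifier on the reference train set, calibrates it
#' on a target train set at most one tenth the size, and evaluates both
#' bundles on both test sets. The expected qualitative pattern: master
#' strong on reference, degraded on target; calibrated recovers on target
#' and gives back some reference performance.
#'
#' @param n_ref,n_target train-set sizes (target <= n_ref / 10 by
#'   protocol; the default is exactly tenfold less).
#' @param n_test per-center test-set size.
#' @param styles list with `reference` and `target` styles.
#' @param cfg a [train_config()].
#' @param seed integer.
#' @param patch_px rendered patch side in pixels (stem-pooled to the
#'   network input size).
#' @return list with the four patch-level `eval_metrics`
#'   (`master_ref`, `master_target`, `calibrated_ref`,
#'   `calibrated_target`), the two bundles, and the set sizes.
#' @export
calibration_experiment <- function(n_ref = 2000L, n_target = 200L,
                                   n_test = 400L, styles = experiment_styles(),
                                   cfg = NULL, seed = 1L, patch_px = 128L) {
  # 6 epochs suffice on the synthetic task (validated on a scaled-down dry
  # run); the cap keeps the full experiment inside a desk-scale CPU budget.
  cfg <- cfg %||% train_config(max_epochs = 6L, patience = 2L,
                               seed = child_seed(seed, "train"))
  mk <- function(n, style, stream) {
    synth_patch_set(n, ic_fraction = 0.5, style = style,
                    seed = child_seed(seed, stream), size = patch_px)
  }
  ref_train <- mk(n_ref, styles$reference, "ref-train")
  ref_val <- mk(max(50L, n_ref %/% 8L), styles$reference, "ref-val")
  ref_test <- mk(n_test, styles$reference, "ref-test")
  tgt_train <- mk(n_target, styles$target, "tgt-train")
  tgt_val <- mk(max(50L, n_target %/% 2L), styles$target, "tgt-val")
  tgt_test <- mk(n_test, styles$target, "tgt-test")

  master <- train_bundle(ref_train$images, ref_train$labels,
                         ref_val$images, ref_val$labels, cfg,
                         provenance = "master")
  calibrated <- calibrate(master, tgt_train$images, tgt_train$labels,
                          tgt_val$images, tgt_val$labels, cfg)

  eval_on <- function(bundle, set) {
    scores <- predict_scores(bundle, set$images)
    evaluate(ifelse(scores > bundle$p0, "IC", "Rest"),
             as.character(set$labels), level = "patch")
  }
  list(master_ref = eval_on(master, ref_test),
       master_target = eval_on(master, tgt_test),
       calibrated_ref = eval_on(calibrated, ref_test),
       calibrated_target = eval_on(calibrated, tgt_test),
       master = master, calibrated = calibrated,
       n_ref_train = n_ref, n_target_train = n_target, n_test = n_test)
}
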