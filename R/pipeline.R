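# Orchestration: patient-exclusive dataset splitting, end-to-end slide
# inference, and the two-phase master -> calibrated workflow.

#' Split a cohort by patient
#'
#' Assigns whole patients to train/test so that the realized train-slide
#' fraction is as close as possible to `ratio` (exact subset-sum dynamic
#' program over patient slide counts; deterministic under `seed`, which
#' shuffles the patient order and hence tie-breaking). A patient's slides
#' are never split across partitions; both partitions are nonempty.
#'
#' @param manifest data.frame with at least `patient_id` and `slide_id`.
#' @param ratio target train-slide fraction (default 0.8).
#' @param seed integer.
#' @return an object of class `dataset_split`: `assignment` (named vector
#'   patient -> "train"/"test"), `realized_ratio`, `ratio`, `seed`.
#' @export
split_by_patient <- function(manifest, ratio = 0.8, seed = 1L) {
  if (!nrow(manifest)) stop("split error: empty manifest", call. = FALSE)
  counts <- table(manifest$patient_id)
  patients <- names(counts)
  k <- length(patients)
  if (k < 2L) stop("split error: need at least 2 patients", call. = FALSE)
  ord <- with_seed(child_seed(seed, "split"), sample.int(k))
  patients <- patients[ord]
  cnt <- as.integer(counts[patients])
  total <- sum(cnt)
  target <- ratio * total

  # reach[i + 1, s + 1]: can the first i patients sum to s train slides?
  reach <- matrix(FALSE, k + 1L, total + 1L)
  reach[1L, 1L] <- TRUE
  for (i in seq_len(k)) {
    reach[i + 1L, ] <- reach[i, ]
    from <- which(reach[i, ])
    reach[i + 1L, pmin(from + cnt[i], total + 1L)] <- TRUE
  }
  sums <- which(reach[k + 1L, ]) - 1L
  sums <- sums[sums > 0L & sums < total]  # both partitions nonempty
  if (!length(sums)) stop("split error: no nonempty split exists", call. = FALSE)
  best <- sums[which.min(abs(sums - target))]

  assignment <- stats::setNames(rep("test", k), patients)
  s <- best
  for (i in rev(seq_len(k))) {
    if (s >= cnt[i] && reach[i, s - cnt[i] + 1L]) {
      assignment[patients[i]] <- "train"
      s <- s - cnt[i]
    }
  }
  structure(list(assignment = assignment, realized_ratio = best / total,
                 ratio = ratio, seed = as.integer(seed)),
            class = "dataset_split")
}

#' @export
print.dataset_split <- function(x, ...) {
  cat(sprintf("<dataset_split> %d train / %d test patients, slide ratio %.3f (target %.2f)\n",
              sum(x$assignment == "train"), sum(x$assignment == "test"),
              x$realized_ratio, x$ratio))
  invisible(x)
}

# Label a set of patch records from ROI annotations: IC if the patch
# center lies in an IC polygon, Rest if in any other polygon, NA outside
# all annotations.
label_records <- function(records, annotations) {
  if (!nrow(records)) return(records)
  lab <- rep(NA_character_, nrow(records))
  for (a in annotations) {
    hit <- points_in_polygon(records$center_x, records$center_y, a$polygon)
    if (a$binary_class == "IC") {
      lab[hit] <- "IC"
    } else {
      lab[hit & is.na(lab)] <- "Rest"
    }
  }
  records$label <- lab
  records
}

# Run filtering on one cohort slide and return its labeled, kept patches
# with their x5 context images.
extract_slide_patches <- function(slide_path, annotation_path, cfg_filter) {
  slide <- open_slide(slide_path)
  regions <- detect_epithelial_regions(slide, cfg_filter)
  records <- parse_patches(slide, regions, cfg_filter)
  fl <- filter_patches(records, slide, cfg_filter)
  kept <- label_records(fl$kept, load_annotations(annotation_path))
  kept <- kept[!is.na(kept$label), , drop = FALSE]
  images <- lapply(seq_len(nrow(kept)), function(i) {
    read_patch(slide, c(kept$center_x[i], kept$center_y[i]), "x5")
  })
  list(records = kept, images = images)
}

# Gather labeled patches for every slide of the given patients.
extract_cohort_patches <- function(manifest, patients, cfg_filter) {
  rows <- manifest[manifest$patient_id %in% patients, , drop = FALSE]
  images <- list(); records <- NULL
  for (i in seq_len(nrow(rows))) {
    ex <- extract_slide_patches(rows$slide_path[i], rows$annotation_path[i], cfg_filter)
    images <- c(images, ex$images)
    records <- rbind(records, ex$records)
  }
  if (is.null(records)) records <- new_patch_records(character(0), integer(0), integer(0))
  list(images = images,
       labels = factor(records$label, levels = c("IC", "Rest")),
       records = records)
}

#' End-to-end inference on one slide
#'
#' Fig-1 pipeline: epithelial filtering, x20/x5 pair extraction, quality
#' rejection, patch scoring, slide score, binary call, heatmap. A slide
#' with zero kept patches yields an explicit no-epithelium report rather
#' than a Rest call.
#'
#' @param slide_path slide pyramid directory.
#' @param bundle a `classifier_bundle` with `p0` and `slide_threshold`
#'   set.
#' @param cfg_filter a [filter_config()].
#' @param out_dir if non-NULL, writes `<slide>_report.json` and
#'   `<slide>_heatmap.png` here.
#' @return an object of class `slide_score_report`.
#' @export
run_inference <- function(slide_path, bundle, cfg_filter = filter_config(),
                          out_dir = NULL) {
  if (is.na(bundle$p0) || is.na(bundle$slide_threshold)) {
    stop("bundle must carry P0 and a slide threshold before inference", call. = FALSE)
  }
  timings <- c()
  tic <- function() Sys.time()
  toc <- function(t0, what) {
    timings[[what]] <<- as.numeric(difftime(Sys.time(), t0, units = "secs"))
  }

  t0 <- tic()
  slide <- open_slide(slide_path)
  regions <- detect_epithelial_regions(slide, cfg_filter)
  records <- parse_patches(slide, regions, cfg_filter)
  fl <- filter_patches(records, slide, cfg_filter)
  toc(t0, "filtering")

  report <- list(slide_id = slide$slide_id, p0 = bundle$p0,
                 slide_threshold = bundle$slide_threshold,
                 filter_report = fl$report, config = unclass(cfg_filter))
  if (!nrow(fl$kept)) {
    report$status <- "no_epithelium"
    report$s_ic <- NA_real_
    report$slide_call <- NA_character_
    report$n_patches <- 0L
    report$timings <- timings
    class(report) <- "slide_score_report"
    if (!is.null(out_dir)) write_slide_report(report, slide, out_dir)
    return(report)
  }

  t0 <- tic()
  scores <- predict_scores(bundle, fl$kept, slide)
  toc(t0, "inference")
  kept <- fl$kept
  kept$score <- scores

  report$status <- "scored"
  report$patches <- kept[, c("center_x", "center_y", "score")]
  report$n_patches <- nrow(kept)
  report$s_ic <- slide_score(scores, bundle$p0)
  report$slide_call <- classify_slide(report$s_ic, bundle$slide_threshold)
  report$timings <- timings
  class(report) <- "slide_score_report"
  if (!is.null(out_dir)) {
    write_slide_report(report, slide, out_dir)
    render_heatmap(slide, kept, file.path(out_dir, paste0(slide$slide_id, "_heatmap.png")))
  }
  report
}

#' @export
print.slide_score_report <- function(x, ...) {
  if (x$status == "no_epithelium") {
    cat(sprintf("<slide_score_report '%s'> no epithelium detected\n", x$slide_id))
  } else {
    cat(sprintf("<slide_score_report '%s'> %d patches, S_IC = %.4f (P0 %.3f) -> %s\n",
                x$slide_id, x$n_patches, x$s_ic, x$p0, x$slide_call))
  }
  invisible(x)
}

write_slide_report <- function(report, slide, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  out <- unclass(report)
  out$filter_report <- unclass(out$filter_report)
  jsonlite::write_json(out, file.path(out_dir, paste0(slide$slide_id, "_report.json")),
                       auto_unbox = TRUE, digits = NA, na = "null", dataframe = "columns")
  invisible(out_dir)
}

# Patient-level carve-out of a validation subset from a train partition.
carve_validation <- function(manifest, train_patients, seed) {
  sub <- manifest[manifest$patient_id %in% train_patients, , drop = FALSE]
  if (length(unique(sub$patient_id)) < 2L) {
    return(list(train = train_patients, val = train_patients))
  }
  sp <- split_by_patient(sub, ratio = 0.9, seed = child_seed(seed, "val"))
  list(train = names(sp$assignment)[sp$assignment == "train"],
       val = names(sp$assignment)[sp$assignment == "test"])
}

#' Two-phase master/calibrated training on two cohorts
#'
#' Phase one trains the master classifier on the reference cohort's train
#' split; phase two calibrates it on the (much smaller) target cohort
#' train split. Both bundles are evaluated at patch level on both test
#' splits, reproducing the 2x2 degradation/recovery grid.
#'
#' @param ref_manifest,target_manifest cohort manifests (from
#'   [generate_cohort()] or equivalent).
#' @param cfg_train a [train_config()].
#' @param cfg_filter a [filter_config()].
#' @param ratio train fraction for the patient split.
#' @param seed integer.
#' @param max_target_frac the target train set must be at most this
#'   fraction of the reference train set (data-efficiency constraint of
#'   the calibration protocol).
#' @return list with `master`, `calibrated` (bundles), `grid` (named list
#'   of four patch-level `eval_metrics`), `splits`, and patch counts.
#' @export
run_two_phase <- function(ref_manifest, target_manifest,
                          cfg_train = train_config(),
                          cfg_filter = filter_config(), ratio = 0.8,
                          seed = 1L, max_target_frac = 0.2) {
  sp_ref <- split_by_patient(ref_manifest, ratio, seed = child_seed(seed, "ref"))
  sp_tgt <- split_by_patient(target_manifest, ratio, seed = child_seed(seed, "tgt"))
  tr_ref <- names(sp_ref$assignment)[sp_ref$assignment == "train"]
  te_ref <- names(sp_ref$assignment)[sp_ref$assignment == "test"]
  tr_tgt <- names(sp_tgt$assignment)[sp_tgt$assignment == "train"]
  te_tgt <- names(sp_tgt$assignment)[sp_tgt$assignment == "test"]
  cv_ref <- carve_validation(ref_manifest, tr_ref, child_seed(seed, "cvref"))
  cv_tgt <- carve_validation(target_manifest, tr_tgt, child_seed(seed, "cvtgt"))

  ref_train <- extract_cohort_patches(ref_manifest, cv_ref$train, cfg_filter)
  ref_val <- extract_cohort_patches(ref_manifest, cv_ref$val, cfg_filter)
  ref_test <- extract_cohort_patches(ref_manifest, te_ref, cfg_filter)
  tgt_train <- extract_cohort_patches(target_manifest, cv_tgt$train, cfg_filter)
  tgt_val <- extract_cohort_patches(target_manifest, cv_tgt$val, cfg_filter)
  tgt_test <- extract_cohort_patches(target_manifest, te_tgt, cfg_filter)

  if (length(tgt_train$images) > max_target_frac * length(ref_train$images)) {
    stop(sprintf(
      "data error: target train set (%d patches) exceeds %.0f%% of reference (%d)",
      length(tgt_train$images), 100 * max_target_frac, length(ref_train$images)),
      call. = FALSE)
  }

  master <- train_bundle(ref_train$images, ref_train$labels,
                         ref_val$images, ref_val$labels, cfg_train,
                         provenance = "master")
  calibrated <- calibrate(master, tgt_train$images, tgt_train$labels,
                          tgt_val$images, tgt_val$labels, cfg_train)

  eval_on <- function(bundle, set) {
    scores <- predict_scores(bundle, set$images)
    pred <- ifelse(scores > bundle$p0, "IC", "Rest")
    evaluate(pred, as.character(set$labels), level = "patch")
  }
  grid <- list(master_ref = eval_on(master, ref_test),
               master_target = eval_on(master, tgt_test),
               calibrated_ref = eval_on(calibrated, ref_test),
               calibrated_target = eval_on(calibrated, tgt_test))
  list(master = master, calibrated = calibrated, grid = grid,
       splits = list(reference = sp_ref, target = sp_tgt),
       n_ref_train = length(ref_train$images),
       n_target_train = length(tgt_train$images))
}
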