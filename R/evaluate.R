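#' Matching criterion for "properly segmented"
#'
#' A predicted seed box counts as properly segmented when it matches a
#' ground-truth seed with intersection-over-union at or above the
#' threshold, one truth seed per prediction (greedy matching by
#' descending IoU). Merged clusters and fragments fall below the
#' threshold for every single seed and therefore fail.
#'
#' @param iou_threshold minimum IoU in `(0, 1]` (default 0.5).
#' @param one_to_one if `TRUE` each truth seed can absorb at most one
#'   prediction.
#' @return a `match_criterion` list.
#' @export
match_criterion <- function(iou_threshold = 0.5, one_to_one = TRUE) {
  if (iou_threshold <= 0 || iou_threshold > 1)
    stop_parameter("iou_threshold must be in (0, 1]")
  structure(list(iou_threshold = iou_threshold, one_to_one = one_to_one),
            class = "match_criterion")
}

#' Intersection-over-union of axis-aligned boxes
#'
#' @param a,b boxes data frames (columns `x, y, w, h`); all of `a` is
#'   compared against all of `b`.
#' @return `nrow(a) x nrow(b)` IoU matrix.
#' @export
box_iou <- function(a, b) {
  out <- matrix(0, nrow(a), nrow(b))
  for (j in seq_len(nrow(b))) {
    ix <- pmin(a$x + a$w, b$x[j] + b$w[j]) - pmax(a$x, b$x[j])
    iy <- pmin(a$y + a$h, b$y[j] + b$h[j]) - pmax(a$y, b$y[j])
    inter <- pmax(ix, 0) * pmax(iy, 0)
    union <- as.numeric(a$w) * a$h + as.numeric(b$w[j]) * b$h[j] - inter
    out[, j] <- inter / union
  }
  out
}

#' Match predicted boxes against ground truth
#'
#' Greedy one-to-one matching by descending IoU: pairs are consumed from
#' the highest IoU down, each prediction and (under `one_to_one`) each
#' truth seed used at most once; a prediction is proper iff its match
#' reaches the IoU threshold.
#'
#' @param pred predicted boxes data frame.
#' @param truth a `scene_truth` (from [generate_scene()]) or a boxes
#'   data frame of true seed boxes.
#' @param crit a [match_criterion()].
#' @return list: `proper` (logical per prediction), `matched_truth`
#'   (truth index per prediction, `NA` if unmatched), `iou` (IoU of the
#'   match), `n_truth`, `recall` (matched truth seeds / truth seeds — a
#'   diagnostic, not part of the accuracy numerator or denominator).
#' @export
match_boxes <- function(pred, truth, crit = match_criterion()) {
  tb <- if (inherits(truth, "scene_truth")) truth$boxes else truth
  np <- nrow(pred); nt <- nrow(tb)
  proper <- logical(np)
  matched <- rep(NA_integer_, np)
  iou_of <- numeric(np)
  if (np > 0 && nt > 0) {
    iou <- box_iou(pred, tb)
    cand <- which(iou >= crit$iou_threshold, arr.ind = TRUE)
    if (nrow(cand) > 0) {
      # order by descending IoU; ties broken by prediction then truth
      # index so the result is permutation-stable after reordering
      ord <- order(-iou[cand], cand[, 1], cand[, 2])
      used_t <- logical(nt)
      for (k in ord) {
        i <- cand[k, 1]; j <- cand[k, 2]
        if (proper[i] || (crit$one_to_one && used_t[j])) next
        proper[i] <- TRUE
        matched[i] <- j
        iou_of[i] <- iou[i, j]
        used_t[j] <- TRUE
      }
    }
  }
  list(proper = proper, matched_truth = matched, iou = iou_of,
       n_truth = nt,
       recall = if (nt > 0) sum(!is.na(matched)) / nt else NA_real_)
}

#' Segmentation accuracy
#'
#' Accuracy is the number of properly segmented individual-seed outputs
#' divided by the total number of segmented outputs. Missed seeds do not
#' enter the denominator; report recall from [match_boxes()] separately
#' when that matters.
#'
#' @param proper logical vector of per-output proper flags (or a
#'   [match_boxes()] result).
#' @return an `accuracy_report` list: `n_proper`, `n_total`, `acc`.
#' @export
seg_accuracy <- function(proper) {
  if (is.list(proper)) proper <- proper$proper
  n_total <- length(proper)
  if (n_total == 0L)
    stop_degenerate("accuracy undefined: no segmented outputs")
  n_proper <- sum(proper)
  structure(list(n_proper = n_proper, n_total = n_total,
                 acc = n_proper / n_total),
            class = "accuracy_report")
}

#' @export
print.accuracy_report <- function(x, ...) {
  cat(sprintf("segmentation accuracy: %d / %d = %.4f (%.2f%%)\n",
              x$n_proper, x$n_total, x$acc, 100 * x$acc))
  invisible(x)
}

#' Sweep separation methods and kernel sizes over a benchmark
#'
#' Runs the full pipeline under each separation configuration over all
#' scenes and aggregates segmentation accuracy per configuration. The
#' MSRCR enhancement does not depend on the separation configuration, so
#' it is computed once per scene and shared.
#'
#' @param scenes list of `list(scene = , truth = )` pairs, e.g. from
#'   [load_benchmark()]. An element may also be a zero-argument function
#'   returning such a pair; it is called once when its scene is needed,
#'   which keeps only one scene in memory at a time for large benchmarks.
#' @param configs list of [separation_config()] objects.
#' @param crit a [match_criterion()].
#' @param retinex [retinex_params()].
#' @param rule [contact_rule()].
#' @param ... further arguments passed to [run_pipeline()].
#' @return a `sweep_report` data frame: one row per configuration with
#'   `method`, `kernel` (`NA` for WA), `acc`, `n_proper`, `n_total`,
#'   `n_scenes`, `n_seeds`, `recall`.
#' @export
sweep_separation <- function(scenes, configs, crit = match_criterion(),
                             retinex = retinex_params(),
                             rule = contact_rule(), ...) {
  if (length(configs) == 0L) stop_parameter("need at least one configuration")
  if (length(scenes) == 0L) stop_parameter("need at least one scene")
  nc <- length(configs)
  n_proper <- integer(nc); n_total <- integer(nc)
  n_truth <- 0L; n_matched <- numeric(nc)
  for (sc in scenes) {
    if (is.function(sc)) sc <- sc()
    enh <- msrcr(sc$scene, retinex)
    n_truth <- n_truth + nrow(sc$truth$boxes)
    for (ci in seq_len(nc)) {
      res <- run_pipeline(sc$scene, retinex = retinex, rule = rule,
                          sep = configs[[ci]], crops = FALSE,
                          enhanced = enh, ...)
      m <- match_boxes(res$boxes, sc$truth, crit)
      n_proper[ci] <- n_proper[ci] + sum(m$proper)
      n_total[ci] <- n_total[ci] + length(m$proper)
      n_matched[ci] <- n_matched[ci] + sum(!is.na(m$matched_truth))
    }
  }
  out <- data.frame(
    method = vapply(configs, function(cf) cf$method, character(1)),
    kernel = vapply(configs, function(cf)
      if (cf$method == "EOP") as.integer(cf$kernel) else NA_integer_,
      integer(1)),
    acc = n_proper / n_total,
    n_proper = n_proper, n_total = n_total,
    n_scenes = length(scenes), n_seeds = n_truth,
    recall = n_matched / n_truth,
    stringsAsFactors = FALSE)
  class(out) <- c("sweep_report", "data.frame")
  out
}

#' @export
print.sweep_report <- function(x, ...) {
  cat("separation sweep over", x$n_scenes[1], "scene(s),",
      x$n_seeds[1], "seed(s):\n")
  for (i in seq_len(nrow(x))) {
    lab <- if (x$method[i] == "EOP")
      sprintf("EOP %2dx%-2d", x$kernel[i], x$kernel[i]) else "WA      "
    cat(sprintf("  %s  acc %6.2f%%  (%d / %d proper, recall %.3f)\n",
                lab, 100 * x$acc[i], x$n_proper[i], x$n_total[i],
                x$recall[i]))
  }
  invisible(x)
}

#' Write a sweep report to CSV
#'
#' @param report a [sweep_separation()] result.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_sweep_csv <- function(report, path) {
  write.csv(as.data.frame(report)[, c("method", "kernel", "acc",
                                      "n_proper", "n_total")],
            path, row.names = FALSE)
  invisible(path)
}
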