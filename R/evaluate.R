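#' One stratified holdout evaluation of a linear SVM
#'
#' Splits the samples at random into a training and a held-out part
#' (stratified by class, `split_fraction` of each class to training),
#' standardizes each feature to zero mean / unit variance using
#' statistics of the *training* part only, fits a linear maximum-margin
#' classifier (SVM, fixed regularization `cost`), and scores it on the
#' held-out part.
#'
#' @param features `n x p` numeric matrix, one sample per row.
#' @param labels vector of 0/1 class labels (both classes must be
#'   present, at least 2 samples each).
#' @param split_fraction fraction of each class used for training
#'   (default 0.5).
#' @param seed integer seed controlling the split.
#' @param cost SVM regularization constant (default 1).
#' @return a list: `accuracy` (fraction correct on the held-out part),
#'   `predictions` (integer 0/1 on the held-out part), `truth`,
#'   `test_idx` (row indices of the held-out part).
#' @examples
#' x <- rbind(matrix(rnorm(60, -10), 30), matrix(rnorm(60, 10), 30))
#' y <- rep(0:1, each = 30)
#' evaluate_once(x, y, seed = 1)$accuracy
#' @export
evaluate_once <- function(features, labels, split_fraction = 0.5,
                          seed = NULL, cost = 1) {
  labels <- as.integer(labels)
  if (nrow(features) != length(labels))
    stop("features row count must equal label count", call. = FALSE)
  cls <- sort(unique(labels))
  if (length(cls) != 2L || any(table(labels) < 2L))
    stop("need two classes with at least 2 samples each", call. = FALSE)
  train_idx <- with_seed(seed, {
    unlist(lapply(cls, function(cl) {
      idx <- which(labels == cl)
      sample(idx, floor(length(idx) * split_fraction))
    }), use.names = FALSE)
  })
  test_idx <- setdiff(seq_along(labels), train_idx)
  mu <- colMeans(features[train_idx, , drop = FALSE])
  sdv <- apply(features[train_idx, , drop = FALSE], 2, stats::sd)
  sdv[sdv == 0] <- 1
  xtr <- scale(features[train_idx, , drop = FALSE], mu, sdv)
  xte <- scale(features[test_idx, , drop = FALSE], mu, sdv)
  fit <- e1071::svm(xtr, factor(labels[train_idx], levels = cls),
                    kernel = "linear", cost = cost, scale = FALSE)
  pred <- as.integer(as.character(stats::predict(fit, xte)))
  list(accuracy = mean(pred == labels[test_idx]),
       predictions = pred, truth = labels[test_idx], test_idx = test_idx)
}

#' Run the motion-blur linear-separability benchmark
#'
#' For each blur size: builds the labelled horizontal/vertical dataset,
#' computes each requested representation (thalamic LGN vectors and/or
#' Layer-4 steady states) for every window, and runs `n_repetitions`
#' stratified 50/50 linear-SVM holdout evaluations with seeds derived
#' from `seed`, the blur size, the representation and the repetition
#' index.  Defaults reproduce the reference protocol: 4000 windows of
#' 25x25 pixels, blur sizes 1-8, 10 repetitions.
#'
#' @param images a [gray_image()] or list of them (e.g. five 500x335
#'   surrogates from [generate_surrogate_image()]).
#' @param network a trained [l4_network()]; required when `"l4"` is
#'   among `representations`.
#' @param n_windows number of windows sampled for the benchmark.
#' @param window_size window side in pixels.
#' @param blur_sizes integer vector of blur sizes to sweep.
#' @param representations subset of `c("thalamic", "l4")`.
#' @param n_repetitions holdout repetitions per condition.
#' @param split_fraction,cost passed to [evaluate_once()].
#' @param mosaic,profile thalamic model components.
#' @param seed master seed; all stage seeds derive from it.
#' @param reference_size blur size whose first-repetition predictions
#'   and windows are retained for [misclassification_gallery()]
#'   (default: the largest blur size).
#' @return a `blur_benchmark` object: `runs` (long data frame of
#'   per-repetition accuracies), `summary` (mean/sd per condition),
#'   `reference_size`, and `gallery` internals.
#' @export
run_benchmark <- function(images, network = NULL, n_windows = 4000L,
                          window_size = 25L, blur_sizes = 1:8,
                          representations = c("thalamic", "l4"),
                          n_repetitions = 10L, split_fraction = 0.5,
                          cost = 1, mosaic = hex_mosaic(),
                          profile = dog_profile(), seed = 1L,
                          reference_size = max(blur_sizes)) {
  representations <- match.arg(representations, several.ok = TRUE)
  if ("l4" %in% representations && is.null(network))
    stop("a trained l4_network is required for the 'l4' representation",
         call. = FALSE)
  margin <- max(blur_sizes)          # blur never needs padded pixels
  windows <- sample_windows(images, n_windows, window_size, margin,
                            seed = derive_seed(seed, "windows"))
  weights <- lgn_weights(mosaic, profile)
  runs <- list()
  gallery <- list()
  for (bs in blur_sizes) {
    ds <- build_dataset(windows, bs, seed = derive_seed(seed, "assign", bs))
    feats <- list()
    feats$thalamic <- lgn_represent(ds$x, mosaic, profile, weights)
    if ("l4" %in% representations)
      feats$l4 <- l4_represent(network, feats$thalamic)
    for (rep_name in representations) {
      acc <- numeric(n_repetitions)
      for (r in seq_len(n_repetitions)) {
        ev <- evaluate_once(feats[[rep_name]], ds$labels, split_fraction,
                            seed = derive_seed(seed, "split", bs, rep_name, r),
                            cost = cost)
        acc[r] <- ev$accuracy
        if (r == 1L && bs == reference_size)
          gallery[[rep_name]] <- list(
            dataset = ds, evaluation = ev, blur_size = bs)
      }
      runs[[length(runs) + 1L]] <- data.frame(
        representation = rep_name, blur_size = bs,
        repetition = seq_len(n_repetitions), accuracy = acc)
    }
  }
  runs <- do.call(rbind, runs)
  summ <- do.call(rbind, lapply(
    split(runs, list(runs$representation, runs$blur_size), drop = TRUE),
    function(d) data.frame(
      representation = d$representation[1], blur_size = d$blur_size[1],
      mean_accuracy = mean(d$accuracy),
      sd_accuracy = stats::sd(d$accuracy),
      n_repetitions = nrow(d))))
  summ <- summ[order(summ$representation, summ$blur_size), ]
  rownames(summ) <- NULL
  structure(list(runs = runs, summary = summ,
                 reference_size = reference_size,
                 n_windows = n_windows, window_size = window_size,
                 seed = seed, gallery = gallery),
            class = "blur_benchmark")
}

#' @export
print.blur_benchmark <- function(x, ...) {
  cat(sprintf(
    "<blur_benchmark: %d windows, blur sizes %s, %d repetitions>\n",
    x$n_windows, paste(sort(unique(x$runs$blur_size)), collapse = ","),
    max(x$runs$repetition)))
  print(summary(x))
  invisible(x)
}

#' @export
summary.blur_benchmark <- function(object, ...) {
  s <- object$summary
  s$mean_accuracy_pct <- round(100 * s$mean_accuracy, 2)
  s
}

#' @export
plot.blur_benchmark <- function(x, ...) {
  s <- x$summary
  reps <- unique(s$representation)
  cols <- stats::setNames(c("firebrick", "steelblue")[seq_along(reps)], reps)
  graphics::plot(NULL, xlim = range(s$blur_size), ylim = c(0.4, 1),
                 xlab = "motion blur size (pixels)",
                 ylab = "mean held-out accuracy",
                 main = "Linear separability of blur orientation", ...)
  graphics::abline(h = 0.5, lty = 3, col = "grey50")
  for (rp in reps) {
    d <- s[s$representation == rp, ]
    d <- d[order(d$blur_size), ]
    graphics::lines(d$blur_size, d$mean_accuracy, type = "b", pch = 16,
                    col = cols[[rp]])
    has_sd <- !is.na(d$sd_accuracy) & d$sd_accuracy > 0
    if (any(has_sd))
      graphics::arrows(d$blur_size[has_sd],
                       (d$mean_accuracy - d$sd_accuracy)[has_sd],
                       d$blur_size[has_sd],
                       (d$mean_accuracy + d$sd_accuracy)[has_sd],
                       angle = 90, code = 3, length = 0.03, col = cols[[rp]])
  }
  graphics::legend("topleft", legend = reps, col = cols[reps], lty = 1,
                   pch = 16, bty = "n")
  invisible(x)
}

#' Performance-threshold report at the reference blur size
#'
#' Compares each representation's mean accuracy at the reference blur
#' size against a performance threshold (default 80%, the score level
#' against which future human test results are to be judged), and
#' returns the full accuracy curve for context.
#'
#' @param result a [run_benchmark()] result.
#' @param reference_size blur size to evaluate at (default: the
#'   result's reference size).
#' @param threshold accuracy threshold as a fraction (default 0.80).
#' @return a `threshold_report` object: `at_reference` data frame
#'   (representation, mean/sd accuracy, pass flag) and `curve` (the
#'   full summary table).
#' @export
threshold_report <- function(result, reference_size = result$reference_size,
                             threshold = 0.80) {
  s <- result$summary
  if (nrow(s) == 0L) stop("empty benchmark result", call. = FALSE)
  at <- s[s$blur_size == reference_size, , drop = FALSE]
  if (nrow(at) == 0L)
    stop(sprintf("reference blur size %d not present in the result",
                 reference_size), call. = FALSE)
  at$threshold <- threshold
  at$pass <- at$mean_accuracy >= threshold
  rownames(at) <- NULL
  structure(list(at_reference = at, curve = s,
                 reference_size = reference_size, threshold = threshold),
            class = "threshold_report")
}

#' @export
print.threshold_report <- function(x, ...) {
  cat(sprintf("Threshold report (reference blur size %d px, threshold %.0f%%)\n",
              x$reference_size, 100 * x$threshold))
  at <- x$at_reference
  for (i in seq_len(nrow(at)))
    cat(sprintf("  %-9s %6.2f%% +/- %.2f%%  -> %s\n",
                at$representation[i], 100 * at$mean_accuracy[i],
                100 * at$sd_accuracy[i],
                if (at$pass[i]) "above threshold" else "below threshold"))
  invisible(x)
}

#' Misclassification gallery of held-out windows
#'
#' Samples `k` misclassified and `k` correctly classified held-out
#' windows from the retained reference-size evaluation and (optionally)
#' writes original/blurred PNG panels — the qualitative check that
#' errors concentrate on windows with little oriented structure.
#'
#' @param result a [run_benchmark()] result.
#' @param representation which retained representation to inspect.
#' @param k panels per group (misclassified / correct).
#' @param seed integer seed for the selection.
#' @param dir optional output directory for PNG panels.
#' @return a `misclassification_report`: data frame with sample id,
#'   true and predicted label, correctness; plus the selected window
#'   matrices in `panels`.
#' @export
misclassification_gallery <- function(result, representation = "l4", k = 8L,
                                      seed = NULL, dir = NULL) {
  g <- result$gallery[[representation]]
  if (is.null(g))
    stop("no retained predictions for representation '", representation,
         "'", call. = FALSE)
  ev <- g$evaluation; ds <- g$dataset
  wrong <- ev$test_idx[ev$predictions != ev$truth]
  right <- ev$test_idx[ev$predictions == ev$truth]
  take <- function(pool, k) pool[sample.int(length(pool), min(k, length(pool)))]
  with_seed(seed, {
    if (length(wrong) < k)
      warning(sprintf("only %d misclassified samples available", length(wrong)),
              call. = FALSE)
    sel <- c(take(wrong, k), take(right, k))
  })
  pred_of <- stats::setNames(ev$predictions, ev$test_idx)
  report <- data.frame(
    sample_id = sel,
    true_label = ds$labels[sel],
    predicted_label = as.integer(pred_of[as.character(sel)]),
    blur_size = rep(g$blur_size, length(sel)))
  report$correct <- report$true_label == report$predicted_label
  ws <- ds$window_size
  panels <- lapply(sel, function(i)
    list(original = matrix(ds$orig[i, ], ws, ws),
         blurred = matrix(ds$x[i, ], ws, ws)))
  names(panels) <- sel
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    for (j in seq_along(sel)) {
      i <- sel[j]
      panel <- cbind(panels[[j]]$original, matrix(1, ws, 2L),
                     panels[[j]]$blurred)
      png::writePNG(panel, file.path(dir, sprintf(
        "%s_true%d_pred%d_%05d.png",
        if (report$correct[j]) "correct" else "miss",
        report$true_label[j], report$predicted_label[j], i)))
    }
    utils::write.csv(report, file.path(dir, "gallery.csv"),
                     row.names = FALSE)
  }
  structure(list(report = report, panels = panels,
                 representation = representation),
            class = "misclassification_report")
}

#' @export
print.misclassification_report <- function(x, ...) {
  cat(sprintf(
    "<misclassification_report (%s): %d misclassified, %d correct panels>\n",
    x$representation, sum(!x$report$correct), sum(x$report$correct)))
  invisible(x)
}
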