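#' Match predicted cones to ground truth under the chi-cone-width rule
#'
#' Predicted and ground-truth cones strictly within `chi * coneWidthPx` of
#' any image edge are first excluded from evaluation (a cone exactly on the
#' margin boundary is retained). One-to-one pairs are then formed greedily
#' over all candidate pairs with distance at most `chi * coneWidthPx`,
#' taken in globally ascending distance order (ties broken by predicted
#' then truth index), so each truth cone is paired with the closest
#' still-available prediction. Unpaired predictions are false positives;
#' unpaired truths are false negatives.
#'
#' @param predicted n x 2 matrix of predicted (x, y), 0-based pixels
#' @param truth m x 2 matrix of ground-truth (x, y), 0-based pixels
#' @param coneWidthPx local cone width, pixels (> 0)
#' @param chi matching tolerance as a fraction of a cone width (> 0)
#' @param imageShape integer c(width, height) of the evaluated image
#' @return a [MatchResult-class]
#' @examples
#' truth <- cbind(c(20, 40), c(20, 20))
#' pred <- cbind(c(20.5, 41), c(20, 19))
#' matchCones(pred, truth, coneWidthPx = 6, chi = 0.75,
#'            imageShape = c(96L, 96L))
#' @export
matchCones <- function(predicted, truth, coneWidthPx, chi, imageShape) {
  if (chi <= 0 || coneWidthPx <= 0)
    stop("chi and coneWidthPx must be > 0", call. = FALSE)
  if (is.null(predicted) || length(predicted) == 0L)
    predicted <- matrix(0, 0L, 2L)
  if (is.null(truth) || length(truth) == 0L) truth <- matrix(0, 0L, 2L)
  margin <- chi * coneWidthPx
  w <- imageShape[1L]; h <- imageShape[2L]
  interior <- function(p) {
    if (!nrow(p)) return(p)
    keep <- p[, 1L] >= margin & p[, 1L] <= (w - 1) - margin &
            p[, 2L] >= margin & p[, 2L] <= (h - 1) - margin
    p[keep, , drop = FALSE]
  }
  predicted <- interior(predicted)
  truth <- interior(truth)
  np <- nrow(predicted); nt <- nrow(truth)

  pairs <- data.frame(predicted = integer(), truth = integer(),
                      distance = numeric())
  if (np && nt) {
    d <- sqrt(outer(predicted[, 1L], truth[, 1L], `-`)^2 +
              outer(predicted[, 2L], truth[, 2L], `-`)^2)
    cand <- which(d <= margin, arr.ind = TRUE)
    if (nrow(cand)) {
      dd <- d[cand]
      o <- order(dd, cand[, 1L], cand[, 2L])
      cand <- cand[o, , drop = FALSE]
      dd <- dd[o]
      usedP <- logical(np); usedT <- logical(nt)
      sel <- integer()
      for (i in seq_len(nrow(cand))) {
        p <- cand[i, 1L]; t <- cand[i, 2L]
        if (!usedP[p] && !usedT[t]) {
          usedP[p] <- TRUE; usedT[t] <- TRUE
          sel <- c(sel, i)
        }
      }
      pairs <- data.frame(predicted = cand[sel, 1L], truth = cand[sel, 2L],
                          distance = dd[sel])
    }
  }
  new("MatchResult", pairs = pairs, tp = nrow(pairs),
      fp = as.integer(np - nrow(pairs)), fn = as.integer(nt - nrow(pairs)),
      chi = chi, coneWidthPx = coneWidthPx, excludedMarginPx = margin)
}

#' Compute Dice, true positive rate and false discovery rate
#'
#' `Dice = 2 TP / (2 TP + FP + FN)`, `TPR = TP / (TP + FN)`,
#' `FDR = FP / (TP + FP)`. Conventions for empty denominators: Dice is 1
#' when everything is empty (tp = fp = fn = 0), TPR is 1 when there are no
#' truth cones, FDR is 0 when there are no predictions.
#'
#' @param match a [MatchResult-class], or an integer TP count
#' @param fp,fn counts when `match` is given as a TP count
#' @return a [ConeMetrics-class]
#' @export
computeMetrics <- function(match, fp = NULL, fn = NULL) {
  if (is(match, "MatchResult")) {
    tp <- match@tp; fp <- match@fp; fn <- match@fn
  } else {
    tp <- as.integer(match); fp <- as.integer(fp); fn <- as.integer(fn)
  }
  if (any(c(tp, fp, fn) < 0)) stop("negative counts", call. = FALSE)
  dice <- if (tp + fp + fn == 0L) 1 else 2 * tp / (2 * tp + fp + fn)
  tpr <- if (tp + fn == 0L) 1 else tp / (tp + fn)
  fdr <- if (tp + fp == 0L) 0 else fp / (tp + fp)
  new("ConeMetrics", dice = dice, tpr = tpr, fdr = fdr)
}

#' Evaluate detections against ground truth across a dataset
#'
#' Matches each image's detections to its ground truth and reports
#' per-image metrics plus the mean and sample (n - 1) standard deviation
#' across images.
#'
#' @param detections named list of [DetectionResult-class] (or n x 2 centre
#'   matrices), keyed by image id
#' @param truths named list of ground-truth centre matrices with the same
#'   keys
#' @param chi matching tolerance
#' @param coneWidths per-image cone widths in pixels: a single number or a
#'   named vector keyed like `detections`
#' @param imageShape integer c(width, height)
#' @return list with `perImage` (data.frame: image_id, tp, fp, fn, dice,
#'   tpr, fdr) and `summary` (data.frame of mean and sd per metric)
#' @export
evaluateDataset <- function(detections, truths, chi, coneWidths, imageShape) {
  ids <- names(detections)
  if (is.null(ids)) stop("detections must be a named list", call. = FALSE)
  missing <- setdiff(ids, names(truths))
  if (length(missing))
    stop("missing ground truth for: ", paste(missing, collapse = ", "),
         call. = FALSE)
  widths <- if (length(coneWidths) == 1L)
    stats::setNames(rep(coneWidths, length(ids)), ids) else coneWidths
  rows <- lapply(ids, function(id) {
    det <- detections[[id]]
    cen <- if (is(det, "DetectionResult")) det@centres else det
    m <- matchCones(cen, truths[[id]], widths[[id]], chi, imageShape)
    met <- computeMetrics(m)
    data.frame(image_id = id, tp = m@tp, fp = m@fp, fn = m@fn,
               dice = met@dice, tpr = met@tpr, fdr = met@fdr)
  })
  perImage <- do.call(rbind, rows)
  summ <- data.frame(
    metric = c("dice", "tpr", "fdr"),
    mean = c(mean(perImage$dice), mean(perImage$tpr), mean(perImage$fdr)),
    sd = c(sampleSD(perImage$dice), sampleSD(perImage$tpr),
           sampleSD(perImage$fdr)))
  list(perImage = perImage, summary = summ)
}

#' Operating points reported for the two real datasets
#'
#' Validated threshold/tolerance presets: `T = 120`, `chi = 0.75` for the
#' Milwaukee confocal dataset and `T = 45`, `chi = 0.5` for the Oxford
#' dataset.
#'
#' @param dataset `"milwaukee"` or `"oxford"`
#' @return list with elements `T` and `chi`
#' @export
operatingPoint <- function(dataset = c("milwaukee", "oxford")) {
  switch(match.arg(dataset),
         milwaukee = list(T = 120, chi = 0.75),
         oxford = list(T = 45, chi = 0.5))
}

#' Tune the detection threshold and matching tolerance on validation data
#'
#' Exhaustively evaluates every (T, chi) grid point on the validation
#' images — predicting probability maps, detecting cones and matching them
#' to the manual/ground-truth labels — and returns the pair maximising the
#' mean Dice coefficient. Ties are broken toward larger T, then smaller
#' chi, favouring precision.
#'
#' @param model a trained [ConeUNet-class]
#' @param valSet list of validation cases, each a list with `image`
#'   (matrix) and `centres` (truth matrix); optionally `coneWidthPx`
#' @param tGrid candidate thresholds
#' @param chiGrid candidate tolerances
#' @param coneWidthPx default cone width when a case carries none
#' @param minDistanceFactor peak minimum distance as a fraction of cone
#'   width
#' @return list with `T`, `chi`, `dice` (best mean Dice) and the full
#'   `grid` data.frame
#' @export
tuneThresholds <- function(model, valSet, tGrid = seq(30, 210, by = 30),
                           chiGrid = c(0.5, 0.75, 1.0), coneWidthPx = 6,
                           minDistanceFactor = 0.5) {
  if (!length(valSet)) stop("empty validation set", call. = FALSE)
  if (!length(tGrid) || !length(chiGrid)) stop("empty grid", call. = FALSE)
  maps <- lapply(valSet, function(case) predictMap(model, case$image))
  widths <- vapply(valSet, function(case)
    if (!is.null(case$coneWidthPx)) case$coneWidthPx else coneWidthPx,
    numeric(1))
  shape <- c(ncol(valSet[[1L]]$image), nrow(valSet[[1L]]$image))
  grid <- expand.grid(T = tGrid, chi = chiGrid)
  grid$dice <- vapply(seq_len(nrow(grid)), function(g) {
    dv <- vapply(seq_along(valSet), function(i) {
      det <- detectCones(maps[[i]], grid$T[g],
                         minDistanceFactor * widths[i])
      m <- matchCones(det@centres, valSet[[i]]$centres, widths[i],
                      grid$chi[g], shape)
      computeMetrics(m)@dice
    }, numeric(1))
    mean(dv)
  }, numeric(1))
  best <- grid[order(-grid$dice, -grid$T, grid$chi), ][1L, ]
  list(T = best$T, chi = best$chi, dice = best$dice, grid = grid)
}
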