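# Evaluation metrics: Dice overlap, boundary Hausdorff distance, and the
# confusion-matrix rates (accuracy, precision, specificity). Semantics are
# deliberately simple enough to verify against brute-force oracles:
#   Dice  = 2|T&P| / (|T| + |P|),       Dice(empty, empty) = 1
#   H(A,B) = max(max_a min_b d(a,b), max_b min_a d(b,a)) over boundary pixels
#   AC = (TP+TN)/total, PR = TP/(TP+FP), SP = TN/(TN+FP)

as_binary_mask <- function(m) {
  if (is.logical(m)) storage.mode(m) <- "integer"
  m != 0L
}

#' Dice similarity coefficient
#'
#' Overlap between two binary masks, `2|T & P| / (|T| + |P|)`. Two empty
#' masks are defined to agree perfectly (Dice 1).
#'
#' @param pred_mask,true_mask binary (logical or 0/1) arrays of equal shape.
#' @return Dice fraction in `[0, 1]`.
#' @examples
#' a <- matrix(c(1, 1, 0, 0), 2)
#' dice_coefficient(a, a)  # 1
#' @export
dice_coefficient <- function(pred_mask, true_mask) {
  if (!identical(dim(pred_mask), dim(true_mask))) {
    stop("mask shapes differ")
  }
  p <- as_binary_mask(pred_mask)
  t <- as_binary_mask(true_mask)
  denom <- sum(p) + sum(t)
  if (denom == 0L) return(1.0)
  2 * sum(p & t) / denom
}

#' Boundary pixels of a binary mask
#'
#' Foreground pixels with at least one 4-adjacent background pixel; pixels
#' on the image border count as adjacent to background. For a 3-D stack the
#' extraction is per slice (in-plane adjacency).
#'
#' @param mask binary matrix or 3-D array (rows, cols, slices).
#' @return integer matrix of coordinates, one row per boundary pixel
#'   (`row, col` or `row, col, slice`), 1-based.
#' @export
boundary_pixels <- function(mask) {
  m <- as_binary_mask(mask)
  d <- dim(m)
  if (length(d) == 2L) {
    H <- d[1]; W <- d[2]
    padded <- matrix(FALSE, H + 2L, W + 2L)
    padded[2:(H + 1L), 2:(W + 1L)] <- m
    inner <- padded[2:(H + 1L), 2:(W + 1L)]
    up <- padded[1:H, 2:(W + 1L)]
    down <- padded[3:(H + 2L), 2:(W + 1L)]
    left <- padded[2:(H + 1L), 1:W]
    right <- padded[2:(H + 1L), 3:(W + 2L)]
    b <- inner & !(up & down & left & right)
    return(which(b, arr.ind = TRUE))
  }
  if (length(d) == 3L) {
    out <- lapply(seq_len(d[3]), function(s) {
      co <- boundary_pixels(m[, , s])
      if (nrow(co) == 0L) return(NULL)
      cbind(co, slice = s)
    })
    out <- do.call(rbind, out)
    if (is.null(out)) out <- matrix(integer(), 0L, 3L)
    return(out)
  }
  stop("mask must be 2-D or 3-D")
}

directed_hd <- function(A, B) {
  # max over rows of A of the min distance to rows of B (coordinates already
  # scaled); vectorised all-pairs distances
  a2 <- rowSums(A^2)
  b2 <- rowSums(B^2)
  d2 <- outer(a2, b2, `+`) - 2 * A %*% t(B)
  d2[d2 < 0] <- 0
  max(sqrt(apply(d2, 1L, min)))
}

#' Hausdorff distance between two masks
#'
#' Symmetric Hausdorff distance over boundary-pixel coordinates, Euclidean
#' norm, with per-axis spacing. The full maximum is used (not a percentile).
#'
#' @param A_mask,B_mask nonempty binary arrays of equal shape (2-D, or 3-D
#'   slice stacks with per-slice boundary extraction).
#' @param spacing positive per-axis pixel spacing, recycled to the array
#'   dimensionality (e.g. mm per pixel); default 1.
#' @return nonnegative distance in spacing units.
#' @examples
#' a <- matrix(0, 5, 6); a[1, 1] <- 1
#' b <- matrix(0, 5, 6); b[4, 5] <- 1
#' hausdorff_distance(a, b)  # 5: a 3-4-5 triangle
#' @export
hausdorff_distance <- function(A_mask, B_mask, spacing = 1) {
  if (!identical(dim(A_mask), dim(B_mask))) stop("mask shapes differ")
  if (sum(A_mask != 0) == 0L || sum(B_mask != 0) == 0L) {
    stop("Hausdorff distance undefined for an empty mask")
  }
  nd <- length(dim(A_mask))
  spacing <- rep_len(as.numeric(spacing), nd)
  if (any(spacing <= 0)) stop("spacing must be positive")
  A <- boundary_pixels(A_mask)
  B <- boundary_pixels(B_mask)
  A <- sweep(A, 2L, spacing, `*`)
  B <- sweep(B, 2L, spacing, `*`)
  max(directed_hd(A, B), directed_hd(B, A))
}

#' Confusion counts and derived rates
#'
#' @param pred_mask,true_mask binary arrays of equal shape.
#' @return list with `counts` (TP, TN, FP, FN) and `AC`, `PR`, `SP`
#'   fractions; a rate with zero denominator is `NA` (undefined).
#' @examples
#' confusion_metrics(c(1, 1, 1, 1, 0, 0, 0, 0, 0, 1),
#'                   c(1, 1, 1, 0, 0, 0, 0, 0, 0, 1))
#' @export
confusion_metrics <- function(pred_mask, true_mask) {
  if (!identical(dim(pred_mask), dim(true_mask)) ||
      length(pred_mask) != length(true_mask)) {
    stop("mask shapes differ")
  }
  p <- as_binary_mask(pred_mask)
  t <- as_binary_mask(true_mask)
  TP <- sum(p & t); TN <- sum(!p & !t)
  FP <- sum(p & !t); FN <- sum(!p & t)
  rate <- function(num, den) if (den == 0L) NA_real_ else num / den
  list(counts = c(TP = TP, TN = TN, FP = FP, FN = FN),
       AC = rate(TP + TN, TP + TN + FP + FN),
       PR = rate(TP, TP + FP),
       SP = rate(TN, TN + FP))
}

#' Evaluate segmentation cases
#'
#' Computes per-class Dice and Hausdorff distance per case (slice stacks are
#' treated as one 3-D point set with the given spacing), averaged over the
#' cases in which the class appears in the ground truth, plus pooled
#' accuracy/precision/specificity over all pixels and classes (one-vs-rest,
#' micro-pooled).
#'
#' @param cases list of cases; each case is a list with integer label arrays
#'   `pred` and `truth` (matching shapes, 2-D or 3-D) and optionally its own
#'   `spacing`.
#' @param classes integer class labels to evaluate; defaults to every
#'   non-background (nonzero) label present in any ground truth.
#' @param spacing default per-axis spacing for cases that do not carry one.
#' @return a `metrics_report`: list with `per_class` (tibble with class,
#'   mean_dsc, mean_hd, n_cases), `mean_dsc`, `mean_hd`, `AC`, `PR`, `SP`
#'   and pooled `counts`.
#' @export
evaluate_cases <- function(cases, classes = NULL, spacing = 1) {
  stopifnot(length(cases) > 0)
  for (cs in cases) {
    if (!identical(dim(cs$pred), dim(cs$truth))) {
      stop("pred/truth shapes differ within a case")
    }
  }
  if (is.null(classes)) {
    classes <- sort(unique(unlist(lapply(cases, function(cs) {
      unique(as.integer(cs$truth))
    }))))
    classes <- classes[classes != 0L]
  }
  if (length(classes) == 0L) stop("no non-background classes to evaluate")
  pool <- c(TP = 0, TN = 0, FP = 0, FN = 0)
  rows <- lapply(classes, function(k) {
    dscs <- c(); hds <- c()
    for (cs in cases) {
      t <- cs$truth == k
      p <- cs$pred == k
      cm <- confusion_metrics(p, t)
      pool <<- pool + cm$counts
      if (!any(t)) next                 # class absent from this case
      dscs <- c(dscs, dice_coefficient(p, t))
      sp <- cs$spacing %||% spacing
      hds <- c(hds, if (any(p)) hausdorff_distance(p, t, sp) else NA_real_)
    }
    tibble::tibble(class = k,
                   mean_dsc = if (length(dscs)) mean(dscs) else NA_real_,
                   mean_hd = if (length(hds) && any(!is.na(hds))) {
                     mean(hds, na.rm = TRUE)
                   } else NA_real_,
                   n_cases = length(dscs))
  })
  per_class <- do.call(rbind, rows)
  rate <- function(num, den) if (den == 0) NA_real_ else num / den
  out <- list(
    per_class = per_class,
    mean_dsc = mean(per_class$mean_dsc[is.finite(per_class$mean_dsc)]),
    mean_hd = mean(per_class$mean_hd[is.finite(per_class$mean_hd)]),
    AC = rate(pool[["TP"]] + pool[["TN"]], sum(pool)),
    PR = rate(pool[["TP"]], pool[["TP"]] + pool[["FP"]]),
    SP = rate(pool[["TN"]], pool[["TN"]] + pool[["FP"]]),
    counts = pool
  )
  class(out) <- "metrics_report"
  out
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf("<metrics_report: mean DSC %.4f | mean HD %.3f | AC %.4f PR %.4f SP %.4f>\n",
              x$mean_dsc, x$mean_hd, x$AC, x$PR, x$SP))
  print(x$per_class)
  invisible(x)
}

#' Write a metrics report to JSON and CSV
#'
#' @param report a `metrics_report`.
#' @param dir output directory (created if missing).
#' @param prefix file name prefix.
#' @return invisibly, the paths written.
#' @export
write_metrics <- function(report, dir, prefix = "metrics") {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  json_path <- file.path(dir, paste0(prefix, ".json"))
  csv_path <- file.path(dir, paste0(prefix, ".csv"))
  jsonlite::write_json(list(
    per_class = report$per_class,
    summary = list(mean_dsc = report$mean_dsc, mean_hd = report$mean_hd,
                   AC = report$AC, PR = report$PR, SP = report$SP,
                   counts = as.list(report$counts))
  ), json_path, auto_unbox = TRUE, digits = NA, na = "null")
  summary_row <- tibble::tibble(class = NA_integer_,
                                mean_dsc = report$mean_dsc,
                                mean_hd = report$mean_hd,
                                n_cases = sum(report$per_class$n_cases))
  utils::write.csv(rbind(report$per_class, summary_row), csv_path,
                   row.names = FALSE)
  invisible(c(json = json_path, csv = csv_path))
}
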