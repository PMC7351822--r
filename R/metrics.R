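# Similarity, distance and classical metrics between a test occupancy grid
# and the reference grid, plus mesh-space RMSE. The reference grid defines
# the positive class for the directional metrics.

#' Voxelwise confusion counts
#'
#' 2x2 contingency of the two occupancy grids; the reference grid defines
#' positives.
#'
#' @param test,ref [voxel_grid()] objects sharing the same frame.
#' @return an object of class `confusion_counts` with TP, FP, FN, TN.
#' @export
confusion <- function(test, ref) {
  if (!frames_equal(test$frame, ref$frame))
    stop("grids are not comparable: different grid frames; build both from ",
         "one make_common_frame() result")
  a <- test$occupancy; b <- ref$occupancy
  tp <- sum(a & b); fp <- sum(a & !b); fn <- sum(!a & b)
  tn <- length(a) - tp - fp - fn
  structure(list(TP = tp, FP = fp, FN = fn, TN = tn),
            class = "confusion_counts")
}

#' Jaccard index from confusion counts
#'
#' `TP / (TP + FP + FN)`; `NA` (undefined marker) when both grids are empty.
#'
#' @param cc a [confusion()] result.
#' @return numeric in `[0, 1]`, or `NA` when undefined.
#' @export
jaccard <- function(cc) {
  den <- cc$TP + cc$FP + cc$FN
  if (den == 0) return(NA_real_)
  cc$TP / den
}

#' Sensitivity, specificity and precision
#'
#' Directional ratios with the reference grid as the positive class.
#' Undefined ratios (zero denominator) are reported as `NA`, never coerced
#' to 0.
#'
#' @param cc a [confusion()] result.
#' @return named numeric vector `(sensitivity, specificity, precision)`.
#' @export
sens_spec_prec <- function(cc) {
  rat <- function(num, den) if (den == 0) NA_real_ else num / den
  c(sensitivity = rat(cc$TP, cc$TP + cc$FN),
    specificity = rat(cc$TN, cc$TN + cc$FP),
    precision = rat(cc$TP, cc$TP + cc$FP))
}

#' Adjusted Rand index of the foreground/background partitions
#'
#' Chance-corrected pair-counting agreement between the two binary
#' partitions of the voxel set, computed from the 2x2 contingency table via
#' the closed form `(index - expected) / (max - expected)`. Undefined (NA)
#' when both partitions are constant.
#'
#' @param cc a [confusion()] result.
#' @return numeric `<= 1`, or `NA` when undefined.
#' @export
adjusted_rand <- function(cc) {
  n <- cc$TP + cc$FP + cc$FN + cc$TN
  if (n < 2) stop("adjusted Rand index needs at least 2 voxels")
  ch2 <- function(x) x * (x - 1) / 2
  sum_ij <- ch2(cc$TP) + ch2(cc$FP) + ch2(cc$FN) + ch2(cc$TN)
  a1 <- ch2(cc$TP + cc$FP) + ch2(cc$FN + cc$TN)   # test partition
  b1 <- ch2(cc$TP + cc$FN) + ch2(cc$FP + cc$TN)   # reference partition
  expected <- a1 * b1 / ch2(n)
  maxi <- (a1 + b1) / 2
  if (maxi == expected) return(NA_real_)
  (sum_ij - expected) / (maxi - expected)
}

#' Mutual information of the joint occupancy distribution
#'
#' MI of the 2x2 joint histogram normalized by the voxel count, in bits
#' (base-2 logarithm); `0 log 0` terms are 0.
#'
#' @param cc a [confusion()] result.
#' @return mutual information in bits (>= 0).
#' @export
mutual_information <- function(cc) {
  n <- cc$TP + cc$FP + cc$FN + cc$TN
  p <- c(cc$TP, cc$FP, cc$FN, cc$TN) / n
  px <- c(p[1] + p[2], p[3] + p[4])   # test: occupied, empty
  py <- c(p[1] + p[3], p[2] + p[4])   # reference: occupied, empty
  marg <- c(px[1] * py[1], px[1] * py[2], px[2] * py[1], px[2] * py[2])
  terms <- ifelse(p > 0, p * log2(p / marg), 0)
  max(sum(terms), 0)
}

edt3d <- function(mask) {
  d2 <- .edt3d_cpp(as.logical(mask), as.integer(dim(mask)))
  array(sqrt(d2), dim(mask))
}

#' Symmetric Hausdorff distance between voxel grids
#'
#' `max(h(A, B), h(B, A))` with `h(A, B)` the maximum over surface voxels of
#' A of the Euclidean center distance to the nearest surface voxel of B,
#' reported in voxel units (pitch = 1). Computed via an exact Euclidean
#' distance transform of each surface voxel set. With `mode = "solid"` the
#' full occupied sets are compared instead.
#'
#' @param test,ref [voxel_grid()] objects sharing the same frame, each with
#'   at least one occupied voxel.
#' @param mode `"surface"` (boundary-distance reading, default) or
#'   `"solid"`.
#' @return Hausdorff distance in voxels.
#' @export
hausdorff <- function(test, ref, mode = c("surface", "solid")) {
  mode <- match.arg(mode)
  if (!frames_equal(test$frame, ref$frame))
    stop("grids are not comparable: different grid frames")
  if (!any(test$occupancy) || !any(ref$occupancy))
    stop("Hausdorff distance is undefined for an empty grid")
  ma <- if (mode == "surface") surface_mask(test) else test$occupancy
  mb <- if (mode == "surface") surface_mask(ref) else ref$occupancy
  da <- edt3d(ma)  # distance to nearest voxel of A
  db <- edt3d(mb)
  max(max(db[ma]), max(da[mb]))
}

#' Vertexwise RMSE between corresponding meshes
#'
#' Root-mean-square Euclidean distance over index-corresponding vertices.
#' Meshes with different vertex counts have no correspondence and raise an
#' error (they are never silently resampled).
#'
#' @param test,ref [triangle_mesh()] objects with identical vertex counts.
#' @return named numeric vector `(rmse, mse)` in mm and mm^2.
#' @export
rmse_vertices <- function(test, ref) {
  if (nrow(test$vertices) != nrow(ref$vertices))
    stop("no vertex correspondence: meshes have different vertex counts (",
         nrow(test$vertices), " vs ", nrow(ref$vertices), "); RMSE cannot be calculated")
  d2 <- rowSums((test$vertices - ref$vertices)^2)
  mse <- mean(d2)
  c(rmse = sqrt(mse), mse = mse)
}

#' Full metric panel between a test grid and the reference grid
#'
#' @param test,ref [voxel_grid()] objects sharing one frame.
#' @param test_mesh,ref_mesh optional corresponding surface meshes for the
#'   vertexwise RMSE; when correspondence fails the RMSE is reported as `NA`
#'   with a note.
#' @return an object of class `metric_report` (named list).
#' @export
metric_report <- function(test, ref, test_mesh = NULL, ref_mesh = NULL) {
  cc <- confusion(test, ref)
  ssp <- sens_spec_prec(cc)
  rmse <- c(rmse = NA_real_, mse = NA_real_)
  rmse_note <- NULL
  if (!is.null(test_mesh) && !is.null(ref_mesh)) {
    rr <- tryCatch(rmse_vertices(test_mesh, ref_mesh), error = function(e) e)
    if (inherits(rr, "error")) rmse_note <- conditionMessage(rr) else rmse <- rr
  }
  structure(list(hausdorff_vox = hausdorff(test, ref),
                 jaccard = jaccard(cc),
                 adjusted_rand = adjusted_rand(cc),
                 mutual_information_bits = mutual_information(cc),
                 sensitivity = unname(ssp["sensitivity"]),
                 specificity = unname(ssp["specificity"]),
                 precision = unname(ssp["precision"]),
                 rmse_mm = unname(rmse["rmse"]),
                 mse_mm2 = unname(rmse["mse"]),
                 rmse_note = rmse_note,
                 confusion = cc),
            class = "metric_report")
}

#' @export
print.metric_report <- function(x, ...) {
  for (k in c("hausdorff_vox", "jaccard", "adjusted_rand",
              "mutual_information_bits", "sensitivity", "specificity",
              "precision", "rmse_mm", "mse_mm2"))
    cat(sprintf("%s: %s\n", k, format(x[[k]], digits = 6)))
  if (!is.null(x$rmse_note)) cat("note:", x$rmse_note, "\n")
  invisible(x)
}
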