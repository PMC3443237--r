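#' Volumetric statistic image
#'
#' Lightweight container for a 3-D statistic image (e.g. a beamformer
#' pseudo-t difference image) together with its voxel-to-mm affine and an
#' optional analysis mask. All coordinates exposed by the package are mm in
#' the image's world space; voxel indices are never exposed.
#'
#' @param values 3-D numeric array of statistic values. Non-finite voxels are
#'   treated as outside the mask.
#' @param affine 4x4 matrix mapping 0-based voxel indices to mm world
#'   coordinates (NIfTI convention). Must be invertible.
#' @param mask optional logical array of the same dimension; `TRUE` marks
#'   voxels inside the analysis volume.
#' @return An object of class `volimg`.
#' @export
volumetric_image <- function(values, affine, mask = NULL) {
  if (length(dim(values)) != 3L)
    stop("`values` must be a 3-D array")
  affine <- as.matrix(affine)
  if (!all(dim(affine) == c(4L, 4L)) || abs(det(affine)) < .Machine$double.eps)
    stop("`affine` must be an invertible 4x4 matrix")
  if (!is.null(mask)) {
    if (!identical(dim(mask), dim(values)))
      stop("`mask` must have the same dimensions as `values`")
    mask <- array(as.logical(mask), dim(values))
  }
  structure(list(values = values, affine = affine, mask = mask),
            class = "volimg")
}

#' @export
print.volimg <- function(x, ...) {
  d <- dim(x$values)
  nin <- if (is.null(x$mask)) sum(is.finite(x$values)) else
    sum(x$mask & is.finite(x$values))
  cat(sprintf("Volumetric image: %d x %d x %d voxels, %d in mask\n",
              d[1], d[2], d[3], nin))
  invisible(x)
}

#' Construct a ranked peak list
#'
#' @param participant participant identifier (scalar).
#' @param loc_mm numeric matrix (peaks x 3) of mm coordinates.
#' @param value numeric vector of statistic values, one per peak.
#' @param sign `"positive"` or `"negative"`: which tail the ranking favours.
#'   Peaks are ordered by descending value for positive, ascending for
#'   negative; rank 1 is the most extreme peak in the chosen direction.
#' @return An object of class `peaklist` with peaks in rank order.
#' @export
peak_list <- function(participant, loc_mm, value,
                      sign = c("positive", "negative")) {
  sign <- match.arg(sign)
  loc_mm <- matrix(as.numeric(loc_mm), ncol = 3L,
                   dimnames = list(NULL, c("x", "y", "z")))
  value <- as.numeric(value)
  if (nrow(loc_mm) != length(value))
    stop("`loc_mm` and `value` lengths disagree")
  ord <- if (sign == "positive") order(-value) else order(value)
  structure(list(participant = as.character(participant)[1],
                 loc_mm = loc_mm[ord, , drop = FALSE],
                 value = value[ord],
                 rank = seq_along(value),
                 sign = sign),
            class = "peaklist")
}

#' @export
print.peaklist <- function(x, ...) {
  cat(sprintf("Peak list '%s' (%s sign): %d peaks\n",
              x$participant, x$sign, length(x$value)))
  if (length(x$value)) {
    show <- head(seq_along(x$value), 5L)
    df <- data.frame(rank = x$rank[show],
                     round(x$loc_mm[show, , drop = FALSE], 1),
                     value = signif(x$value[show], 4))
    print(df, row.names = FALSE)
    if (length(x$value) > 5L) cat("...\n")
  }
  invisible(x)
}

# 18-connected neighbour offsets: faces + edges of the 3x3x3 cube
neighbour_offsets_18 <- function() {
  g <- expand.grid(dx = -1:1, dy = -1:1, dz = -1:1)
  d2 <- g$dx^2 + g$dy^2 + g$dz^2
  as.matrix(g[d2 >= 1 & d2 <= 2, ])
}

#' Extract rank-ordered local maxima from a volumetric image
#'
#' A voxel is a local maximum when its value strictly exceeds all of its
#' 18-connected neighbours that lie inside the mask (the rule used by SPM's
#' `spm_max`); neighbours outside the array or mask are ignored, so maxima on
#' the mask edge are reportable, and two maxima separated by a single
#' non-maximal voxel are both reported. Plateaus (neighbouring equal values)
#' are not maxima. For `sign = "negative"` the negated image is scanned.
#'
#' @param img a [volumetric_image()].
#' @param sign which peaks to extract and how to rank them.
#' @param participant identifier stored in the returned list.
#' @param require_sign_consistent drop peaks whose value does not have the
#'   requested sign (default keeps them: rank order alone drives the
#'   statistic, values are never thresholded).
#' @return A [peak_list()] with every local maximum, ranked by extremity.
#' @export
find_local_maxima <- function(img, sign = c("positive", "negative"),
                              participant = "p1",
                              require_sign_consistent = FALSE) {
  stopifnot(inherits(img, "volimg"))
  sign <- match.arg(sign)
  v <- img$values
  inmask <- is.finite(v)
  if (!is.null(img$mask)) inmask <- inmask & img$mask
  if (!any(inmask)) stop("mask is empty: no voxels to scan")
  work <- if (sign == "positive") v else -v
  work[!inmask] <- -Inf

  d <- dim(work)
  # pad with -Inf so out-of-volume neighbours never beat a candidate
  pad <- array(-Inf, d + 2L)
  pad[2:(d[1] + 1L), 2:(d[2] + 1L), 2:(d[3] + 1L)] <- work
  ismax <- inmask
  for (r in seq_len(nrow(off <- neighbour_offsets_18()))) {
    o <- off[r, ]
    nb <- pad[(2:(d[1] + 1L)) + o[1],
              (2:(d[2] + 1L)) + o[2],
              (2:(d[3] + 1L)) + o[3]]
    ismax <- ismax & (work > nb)
  }
  idx <- which(ismax, arr.ind = TRUE)
  if (nrow(idx) == 0L)
    return(peak_list(participant, matrix(numeric(0), ncol = 3), numeric(0),
                     sign = sign))
  vals <- v[ismax]
  if (require_sign_consistent) {
    keep <- if (sign == "positive") vals > 0 else vals < 0
    idx <- idx[keep, , drop = FALSE]
    vals <- vals[keep]
    if (nrow(idx) == 0L)
      return(peak_list(participant, matrix(numeric(0), ncol = 3),
                       numeric(0), sign = sign))
  }
  # 0-based voxel indices through the affine
  vox <- cbind(idx - 1, 1)
  loc <- vox %*% t(img$affine)
  peak_list(participant, loc[, 1:3, drop = FALSE], vals, sign = sign)
}

#' Keep the top M peaks of a peak list
#'
#' Returns the first `min(m, available)` peaks in rank order. When a
#' participant has fewer than `m` peaks the result carries a `"shortfall"`
#' attribute giving the deficit.
#'
#' @param pl a [peak_list()].
#' @param m positive number of peaks to keep.
#' @export
top_m <- function(pl, m) {
  stopifnot(inherits(pl, "peaklist"), m >= 1)
  m <- as.integer(m)
  keep <- seq_len(min(m, length(pl$value)))
  out <- pl
  out$loc_mm <- pl$loc_mm[keep, , drop = FALSE]
  out$value <- pl$value[keep]
  out$rank <- pl$rank[keep]
  attr(out, "shortfall") <- max(0L, m - length(pl$value))
  out
}

#' Read and write peak tables
#'
#' Peak tables are tab-separated text with header
#' `participant  x_mm  y_mm  z_mm  value`, one row per peak. Ranks are
#' recomputed on read from the values (they are not stored), so
#' write-then-read round-trips locations and values losslessly.
#'
#' @param path file path.
#' @param sign ranking direction applied on read.
#' @return `read_peak_table()`: a list of [peak_list()] objects, one per
#'   participant in first-appearance order.
#' @export
read_peak_table <- function(path, sign = c("positive", "negative")) {
  sign <- match.arg(sign)
  df <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("participant", "x_mm", "y_mm", "z_mm", "value")
  if (!all(need %in% names(df)))
    stop("peak table must have columns: ", paste(need, collapse = ", "))
  num <- c("x_mm", "y_mm", "z_mm", "value")
  if (!all(vapply(df[num], is.numeric, logical(1))))
    stop("columns x_mm, y_mm, z_mm, value must be numeric")
  ids <- unique(df$participant)
  lapply(ids, function(id) {
    sub <- df[df$participant == id, , drop = FALSE]
    peak_list(id, as.matrix(sub[, c("x_mm", "y_mm", "z_mm")]), sub$value,
              sign = sign)
  })
}

#' @param pls list of [peak_list()] objects to write.
#' @rdname read_peak_table
#' @export
write_peak_table <- function(pls, path) {
  if (inherits(pls, "peaklist")) pls <- list(pls)
  rows <- lapply(pls, function(pl) {
    data.frame(participant = rep(pl$participant, length(pl$value)),
               x_mm = pl$loc_mm[, 1], y_mm = pl$loc_mm[, 2],
               z_mm = pl$loc_mm[, 3], value = pl$value)
  })
  write.table(do.call(rbind, rows), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' Read or write a statistic image as NIfTI-1
#'
#' Thin adapters around RNifti preserving the mm affine. Non-finite voxels on
#' read become masked-out voxels.
#'
#' @param path NIfTI file path.
#' @export
read_stat_image <- function(path) {
  nii <- RNifti::readNifti(path)
  aff <- matrix(as.numeric(RNifti::xform(nii)), 4, 4)
  volumetric_image(array(as.numeric(nii), dim(nii)[1:3]), aff)
}

#' @param img a [volumetric_image()]; masked-out voxels are written as NA.
#' @rdname read_stat_image
#' @export
write_stat_image <- function(img, path) {
  stopifnot(inherits(img, "volimg"))
  v <- img$values
  if (!is.null(img$mask)) v[!img$mask] <- NA_real_
  nii <- RNifti::asNifti(v)
  nii <- RNifti::`sform<-`(nii, structure(img$affine, code = 2L))
  RNifti::writeNifti(nii, path)
  invisible(path)
}
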