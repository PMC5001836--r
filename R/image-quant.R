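#' Otsu threshold of an intensity image
#'
#' Classic between-class-variance maximization on a 256-bin histogram of
#' the image's intensity range. Returns a threshold on the original
#' intensity scale; pixels strictly above it are foreground.
#'
#' @param image numeric matrix.
#' @param n_bins histogram bins (default 256).
#' @return numeric threshold.
#' @export
otsu_threshold <- function(image, n_bins = 256L) {
  v <- as.numeric(image)
  rng <- range(v)
  if (diff(rng) == 0) return(rng[1])  # flat image: nothing above threshold
  breaks <- seq(rng[1], rng[2], length.out = n_bins + 1L)
  counts <- tabulate(findInterval(v, breaks, all.inside = TRUE), n_bins)
  p <- counts / sum(counts)
  mids <- (breaks[-1] + breaks[-length(breaks)]) / 2
  omega <- cumsum(p)
  mu <- cumsum(p * mids)
  mu_t <- mu[n_bins]
  sigma_b <- (mu_t * omega - mu)^2 / (omega * (1 - omega))
  sigma_b[!is.finite(sigma_b)] <- -Inf
  breaks[which.max(sigma_b) + 1L]
}

# 4-connected component labeling by iterative vectorized minimum-label
# propagation. Adequate for fields of this size (converges in O(object
# diameter) sweeps).
label_components <- function(mask) {
  stopifnot(is.matrix(mask), is.logical(mask))
  nr <- nrow(mask); nc <- ncol(mask)
  lab <- matrix(seq_len(nr * nc), nr, nc)
  lab[!mask] <- NA_integer_
  repeat {
    up    <- rbind(lab[-1, , drop = FALSE], NA)
    down  <- rbind(NA, lab[-nr, , drop = FALSE])
    left  <- cbind(NA, lab[, -nc, drop = FALSE])
    right <- cbind(lab[, -1, drop = FALSE], NA)
    new <- pmin(lab, up, down, left, right, na.rm = TRUE)
    new[!mask] <- NA_integer_
    if (identical(new, lab)) break
    lab <- new
  }
  out <- matrix(0L, nr, nc)
  if (any(mask)) {
    ids <- lab[mask]
    out[mask] <- match(ids, sort(unique(ids)))
  }
  out
}

#' Segment nuclei from the nuclear-stain channel
#'
#' Thresholds the nuclear channel (Otsu by default), labels 4-connected
#' components, and discards components that touch the image border or fall
#' below a minimum area. The result is the "DAPI mask" from which nuclear
#' and cytoplasmic-ring ROIs are derived.
#'
#' @param image single-channel numeric matrix, nonnegative intensities.
#' @param threshold either \code{"otsu"} (default) or a numeric threshold;
#'   pixels strictly above it are nuclear stain.
#' @param min_area_px minimum component area in pixels (default 20).
#' @return integer label matrix (0 = background, 1..K = nuclei), with the
#'   threshold used stored in attribute \code{"threshold"}.
#' @examples
#' f <- generate_field(n_cells = 2, ratio_sd = 0, seed = 3)
#' labs <- segment_nuclei(f$nuclear)
#' max(labs)  # 2
#' @export
segment_nuclei <- function(image, threshold = "otsu", min_area_px = 20L) {
  stopifnot(is.matrix(image))
  thr <- if (identical(threshold, "otsu")) otsu_threshold(image)
         else as.numeric(threshold)
  mask <- image > thr
  labs <- label_components(mask)
  if (max(labs) > 0) {
    # drop border-touching and undersized components
    border_ids <- unique(c(labs[1, ], labs[nrow(labs), ],
                           labs[, 1], labs[, ncol(labs)]))
    areas <- tabulate(labs[labs > 0], max(labs))
    drop <- union(border_ids[border_ids > 0],
                  which(areas < min_area_px))
    if (length(drop)) labs[labs %in% drop] <- 0L
    if (max(labs) > 0) {
      keep <- sort(unique(labs[labs > 0]))
      relab <- labs
      relab[labs > 0] <- match(labs[labs > 0], keep)
      labs <- relab
    }
  }
  attr(labs, "threshold") <- thr
  labs
}

#' Centroids of labeled components
#'
#' @param labels integer label matrix from \code{\link{segment_nuclei}}.
#' @return data.frame with columns \code{label, row, col} (centroid
#'   coordinates, 1-based pixel units).
#' @export
label_centroids <- function(labels) {
  ids <- sort(unique(labels[labels > 0]))
  if (!length(ids))
    return(data.frame(label = integer(0), row = numeric(0), col = numeric(0)))
  idx <- which(labels > 0, arr.ind = TRUE)
  lab <- labels[labels > 0]
  data.frame(
    label = ids,
    row = tapply(idx[, 1], lab, mean)[as.character(ids)],
    col = tapply(idx[, 2], lab, mean)[as.character(ids)],
    row.names = NULL
  )
}

#' Build nuclear and cytoplasmic-ring ROIs for every segmented cell
#'
#' The nuclear ROI is the stain mask eroded by \code{erosion_px} (the
#' "circle two pixels inside the outermost stain signal", implemented as
#' morphological erosion with a Euclidean disk so that it stays valid for
#' non-circular nuclei). The cytoplasmic ROI is a \code{ring_width_px}-wide
#' ring around the stain mask, offset outward by \code{gap_px} pixels:
#' pixels whose Euclidean distance d to the mask satisfies
#' \code{gap_px < d <= gap_px + ring_width_px}. A zero gap matches the
#' HEK293A analysis convention and a one-pixel gap the HT1080 convention.
#' Ring pixels claimed by several cells go to the nearest nucleus (ties to
#' the lower label). Cells whose nuclear ROI erodes away entirely are
#' flagged and excluded from measurement.
#'
#' @param labels integer label matrix from \code{\link{segment_nuclei}}.
#' @param erosion_px nuclear erosion radius in pixels (default 2).
#' @param ring_width_px ring width in pixels (default 3).
#' @param gap_px gap between stain boundary and ring, 0 or 1 (default 0).
#' @param metric \code{"euclidean"} (default) or \code{"chessboard"}
#'   distance for both operations.
#' @param min_nuclear_px minimum surviving nuclear-ROI size; smaller ROIs
#'   (tiny nuclei essentially erased by the erosion) are flagged (default 4).
#' @return list of per-cell ROI pairs; each element has \code{label},
#'   \code{nuclear_idx} and \code{ring_idx} (linear pixel indices into the
#'   image matrix), and \code{flagged} (TRUE when the nuclear ROI erodes
#'   away).
#' @export
build_rois <- function(labels, erosion_px = 2L, ring_width_px = 3L,
                       gap_px = 0L, metric = c("euclidean", "chessboard"),
                       min_nuclear_px = 4L) {
  stopifnot(is.matrix(labels), erosion_px >= 0, ring_width_px >= 1,
            gap_px >= 0)
  metric <- match.arg(metric)
  nr <- nrow(labels); nc <- ncol(labels)
  ids <- sort(unique(labels[labels > 0]))
  if (!length(ids)) return(list())

  outer_r <- gap_px + ring_width_px
  pad <- ceiling(outer_r) + 1L

  dist_fun <- if (metric == "euclidean") {
    function(dr, dc) sqrt(dr^2 + dc^2)
  } else {
    function(dr, dc) pmax(abs(dr), abs(dc))
  }

  # candidate ring pixels near any mask, with distance to each nearby cell
  ring_claim <- vector("list", length(ids))
  rois <- vector("list", length(ids))
  for (k in seq_along(ids)) {
    id <- ids[k]
    px <- which(labels == id, arr.ind = TRUE)
    r0 <- max(1L, min(px[, 1]) - pad); r1 <- min(nr, max(px[, 1]) + pad)
    c0 <- max(1L, min(px[, 2]) - pad); c1 <- min(nc, max(px[, 2]) + pad)
    box <- expand.grid(row = r0:r1, col = c0:c1)
    # distance from every box pixel to this cell's mask
    dmat <- outer(box$row, px[, 1], "-")
    dmat2 <- outer(box$col, px[, 2], "-")
    d_to_mask <- apply(dist_fun(dmat, dmat2), 1, min)
    in_mask <- labels[cbind(box$row, box$col)] == id

    # erosion: distance from mask pixel to nearest non-mask pixel > erosion
    nuclear_keep <- rep(FALSE, nrow(box))
    if (erosion_px == 0) {
      nuclear_keep <- in_mask
    } else {
      bg <- box[!in_mask, , drop = FALSE]
      if (nrow(bg)) {
        mrows <- which(in_mask)
        dbg <- dist_fun(outer(box$row[mrows], bg$row, "-"),
                        outer(box$col[mrows], bg$col, "-"))
        d_bg <- apply(dbg, 1, min)
        nuclear_keep[mrows] <- d_bg > erosion_px
      } else {
        nuclear_keep <- in_mask
      }
    }

    is_ring <- !in_mask & labels[cbind(box$row, box$col)] == 0 &
      d_to_mask > gap_px & d_to_mask <= outer_r
    rois[[k]] <- list(
      label = id,
      nuclear_idx = (box$col[nuclear_keep] - 1L) * nr + box$row[nuclear_keep],
      ring_idx = integer(0),
      flagged = sum(nuclear_keep) < min_nuclear_px
    )
    ring_claim[[k]] <- data.frame(
      cell = k,
      idx = (box$col[is_ring] - 1L) * nr + box$row[is_ring],
      dist = d_to_mask[is_ring]
    )
  }

  claims <- do.call(rbind, ring_claim)
  if (!is.null(claims) && nrow(claims)) {
    # nearest nucleus wins contested pixels; ties to the lower label
    ord <- order(claims$idx, claims$dist, claims$cell)
    claims <- claims[ord, ]
    winner <- claims[!duplicated(claims$idx), ]
    for (k in seq_along(ids)) {
      rois[[k]]$ring_idx <- winner$idx[winner$cell == k]
    }
  }
  rois
}

#' Measure reporter intensity over each cell's ROI pair
#'
#' The per-cell statistic of the assay: mean reporter intensity over the
#' (eroded) nuclear ROI divided by the mean over the perinuclear ring.
#' Cells with an empty or zero-intensity ring, or an empty nuclear ROI, are
#' flagged and excluded from well aggregation.
#'
#' @param rois list from \code{\link{build_rois}}.
#' @param reporter reporter-channel numeric matrix (same dimensions as the
#'   segmented label matrix).
#' @return data.frame with one row per cell: \code{cell_id,
#'   nuclear_mean, ring_mean, ratio, n_pixels_nuc, n_pixels_ring, flagged}.
#' @export
measure_cells <- function(rois, reporter) {
  stopifnot(is.matrix(reporter))
  if (!length(rois)) {
    return(data.frame(cell_id = integer(0), nuclear_mean = numeric(0),
                      ring_mean = numeric(0), ratio = numeric(0),
                      n_pixels_nuc = integer(0), n_pixels_ring = integer(0),
                      flagged = logical(0)))
  }
  out <- lapply(rois, function(roi) {
    nm <- if (length(roi$nuclear_idx)) mean(reporter[roi$nuclear_idx]) else NA_real_
    rm_ <- if (length(roi$ring_idx)) mean(reporter[roi$ring_idx]) else NA_real_
    flagged <- roi$flagged || !length(roi$ring_idx) ||
      is.na(rm_) || rm_ <= 0 || is.na(nm)
    data.frame(
      cell_id = roi$label,
      nuclear_mean = nm,
      ring_mean = rm_,
      ratio = if (flagged) NA_real_ else nm / rm_,
      n_pixels_nuc = length(roi$nuclear_idx),
      n_pixels_ring = length(roi$ring_idx),
      flagged = flagged
    )
  })
  do.call(rbind, out)
}

#' Quantify one field end to end
#'
#' Convenience wrapper: segment the nuclear channel, build ROI pairs,
#' measure the reporter channel.
#'
#' @param nuclear,reporter the two channel matrices.
#' @inheritParams build_rois
#' @inheritParams segment_nuclei
#' @return the \code{\link{measure_cells}} data.frame.
#' @export
quantify_field <- function(nuclear, reporter, erosion_px = 2L,
                           ring_width_px = 3L, gap_px = 0L,
                           threshold = "otsu", min_area_px = 20L) {
  labs <- segment_nuclei(nuclear, threshold = threshold,
                         min_area_px = min_area_px)
  rois <- build_rois(labs, erosion_px = erosion_px,
                     ring_width_px = ring_width_px, gap_px = gap_px)
  measure_cells(rois, reporter)
}

#' Aggregate per-cell ratios into a well score
#'
#' The well score is the median (default) or mean of the non-flagged
#' per-cell ratios. Wells with fewer than \code{min_cells} measurable cells
#' are reported missing, matching the quality rule applied before plate
#' normalization.
#'
#' @param ratios numeric vector of per-cell ratios (NAs = flagged cells).
#' @param min_cells minimum number of measurable cells (default 20).
#' @param method \code{"median"} (default) or \code{"mean"}.
#' @return list with \code{well_score} (NA when below \code{min_cells}),
#'   \code{n_cells}, and \code{missing} flag.
#' @examples
#' aggregate_well(c(1, 2, 3), min_cells = 1)$well_score  # 2
#' @export
aggregate_well <- function(ratios, min_cells = 20L,
                           method = c("median", "mean")) {
  method <- match.arg(method)
  ratios <- ratios[!is.na(ratios)]
  n <- length(ratios)
  if (n < min_cells) {
    return(list(well_score = NA_real_, n_cells = n, missing = TRUE))
  }
  score <- if (method == "median") stats::median(ratios) else mean(ratios)
  list(well_score = score, n_cells = n, missing = FALSE)
}
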