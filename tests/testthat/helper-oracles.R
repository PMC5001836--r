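# Independent oracles used across the suite.

# Brute-force two-way median polish: stats::medpolish with early stopping
# disabled (eps = 0 forces the full fixed number of sweeps). Note the
# native stopping rule (eps > 0) is NOT usable as an oracle: the residual
# L1 norm can plateau while the decomposition is still moving, and
# medpolish then freezes mid-trajectory.
brute_polish <- function(x, sweeps = 100L) {
  suppressWarnings(
    stats::medpolish(x, eps = 0, maxiter = sweeps, trace.iter = FALSE,
                     na.rm = TRUE)
  )
}

# Ratio measurement from ground-truth geometry, independent of the
# segmentation/ROI code path: exact disk masks centered on the true cell
# centers.
truth_mask_ratio <- function(field, cell, erosion_px = 2, ring_width_px = 3,
                             gap_px = 0) {
  img <- field$reporter
  nr <- nrow(img)
  xg <- matrix(rep(seq_len(ncol(img)), each = nr), nr)   # column coord
  yg <- matrix(rep(seq_len(nr), times = ncol(img)), nr)  # row coord
  d <- sqrt((xg - cell$cx)^2 + (yg - cell$cy)^2)
  r <- cell$nuclear_radius_px
  nuc <- d <= r - erosion_px
  ring <- d > r + gap_px & d <= r + gap_px + ring_width_px
  mean(img[nuc]) / mean(img[ring])
}

# Brute-force Euclidean distance from every pixel to a mask, restricted to
# a window; used to verify ring-distance invariants independently of
# build_rois.
brute_dist_to_mask <- function(mask_idx, nr, query_idx) {
  mr <- (mask_idx - 1L) %% nr + 1L
  mc <- (mask_idx - 1L) %/% nr + 1L
  qr <- (query_idx - 1L) %% nr + 1L
  qc <- (query_idx - 1L) %/% nr + 1L
  vapply(seq_along(query_idx), function(i)
    min(sqrt((qr[i] - mr)^2 + (qc[i] - mc)^2)), numeric(1))
}

# Hand delta-delta-Ct arithmetic (efficiency 2), independent of
# ddct_fold_change.
hand_ddct <- function(ct) {
  dct <- ct$ct_target - ct$ct_reference
  2^-(mean(dct[ct$treated]) - mean(dct[!ct$treated]))
}
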