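#' Generate a synthetic two-channel microscopy field
#'
#' Renders \code{n_cells} non-overlapping cells on a square field. Each cell
#' is a bright nuclear disk in the nuclear-stain channel and, in the
#' reporter channel, a nuclear disk of intensity \code{true_ratio * cyto}
#' surrounded by a cytoplasmic annulus of intensity \code{cyto}, so that the
#' mean nuclear intensity divided by the mean perinuclear-ring intensity
#' equals that cell's \code{true_ratio} exactly at zero noise. Geometry
#' follows the ROI convention used downstream: the cytoplasmic annulus
#' (outer radius \code{cyto_radius_px}) is wide enough to contain a
#' three-pixel measurement ring with up to a one-pixel gap.
#'
#' @param n_cells number of cells to place (0 allowed).
#' @param ratio_mean mean of the per-cell true nucleus:cytoplasm ratio
#'   (must be > 0).
#' @param ratio_sd SD of the per-cell true ratio (truncated below at 0.05).
#' @param image_size side length in pixels (default 256).
#' @param nuclear_radius_px nuclear disk radius (default 8).
#' @param cyto_radius_px cytoplasm outer radius (default 14).
#' @param background_level background intensity outside cells in both
#'   channels (default 200, 16-bit scale). Cell interiors carry pure
#'   signal so the ratio contract holds exactly at zero noise.
#' @param cyto_intensity mean cytoplasmic reporter intensity above
#'   background (default 3000).
#' @param nuclear_stain_intensity nuclear-stain intensity above background
#'   (default 20000).
#' @param noise_sd additive Gaussian pixel noise SD (default 0; the
#'   pipeline's recovery guarantees are stated for the noiseless case).
#' @param seed RNG seed.
#' @param max_tries placement retries before giving up.
#' @return list with \code{nuclear} and \code{reporter} image matrices
#'   (numeric, clamped to [0, 65535]) and \code{truth}, a data.frame with
#'   columns \code{cell_id, cx, cy, nuclear_radius_px, cyto_radius_px,
#'   true_ratio} plus attribute-style columns \code{background_level}.
#' @examples
#' f <- generate_field(n_cells = 3, ratio_mean = 2, ratio_sd = 0, seed = 1)
#' dim(f$nuclear); nrow(f$truth)
#' @export
generate_field <- function(n_cells,
                           ratio_mean = 2.0,
                           ratio_sd = 0.3,
                           image_size = 256L,
                           nuclear_radius_px = 8L,
                           cyto_radius_px = 14L,
                           background_level = 200,
                           cyto_intensity = 3000,
                           nuclear_stain_intensity = 20000,
                           noise_sd = 0,
                           seed,
                           max_tries = 2000L) {
  stopifnot(n_cells >= 0, ratio_mean > 0, ratio_sd >= 0,
            cyto_radius_px > nuclear_radius_px)
  image_size <- as.integer(image_size)

  truth <- data.frame(cell_id = integer(0), cx = numeric(0), cy = numeric(0),
                      nuclear_radius_px = numeric(0),
                      cyto_radius_px = numeric(0),
                      true_ratio = numeric(0),
                      background_level = numeric(0))
  nuclear <- matrix(background_level, image_size, image_size)
  reporter <- matrix(background_level, image_size, image_size)
  if (n_cells == 0) {
    return(list(nuclear = nuclear, reporter = reporter, truth = truth))
  }

  with_seed(seed, {
    margin <- cyto_radius_px + 2L
    lo <- margin + 1L; hi <- image_size - margin
    if (hi <= lo)
      stop("image_size ", image_size, " too small for cell radius ",
           cyto_radius_px)
    centers <- matrix(NA_real_, 0, 2)
    min_dist <- 2 * cyto_radius_px + 2  # no overlap, per-design guarantee
    tries <- 0L
    while (nrow(centers) < n_cells) {
      tries <- tries + 1L
      if (tries > max_tries)
        stop("could not place ", n_cells, " non-overlapping cells of outer ",
             "radius ", cyto_radius_px, " on a ", image_size, "px field ",
             "after ", max_tries, " tries; reduce density")
      cand <- runif(2, lo, hi)
      if (nrow(centers) == 0 ||
          all(sqrt(rowSums(sweep(centers, 2, cand)^2)) > min_dist)) {
        centers <- rbind(centers, cand)
      }
    }
    ratios <- pmax(rnorm(n_cells, ratio_mean, ratio_sd), 0.05)

    xg <- matrix(rep(seq_len(image_size), each = image_size), image_size)
    yg <- matrix(rep(seq_len(image_size), times = image_size), image_size)
    for (i in seq_len(n_cells)) {
      d2 <- (xg - centers[i, 1])^2 + (yg - centers[i, 2])^2
      nuc <- d2 <= nuclear_radius_px^2
      ann <- !nuc & d2 <= cyto_radius_px^2
      # cell interiors carry pure signal (background applies outside cells
      # only) so that the nuclear/ring mean ratio equals true_ratio exactly
      # in the noiseless limit
      nuclear[nuc] <- background_level + nuclear_stain_intensity
      reporter[nuc] <- ratios[i] * cyto_intensity
      reporter[ann] <- cyto_intensity
    }
    if (noise_sd > 0) {
      nuclear <- nuclear + rnorm(length(nuclear), 0, noise_sd)
      reporter <- reporter + rnorm(length(reporter), 0, noise_sd)
    }
    nuclear <- pmin(pmax(nuclear, 0), 65535)
    reporter <- pmin(pmax(reporter, 0), 65535)
    truth <- data.frame(
      cell_id = seq_len(n_cells),
      cx = centers[, 1], cy = centers[, 2],
      nuclear_radius_px = nuclear_radius_px,
      cyto_radius_px = cyto_radius_px,
      true_ratio = ratios,
      background_level = background_level
    )
  })
  list(nuclear = nuclear, reporter = reporter, truth = truth)
}

#' Write a single-channel image as plain-text PGM
#'
#' Images are exchanged as ASCII PGM (P2) with a 16-bit maxval. PGM is used
#' in place of TIFF because the toolchain is restricted to text formats and
#' pure-R dependencies; the container is lossless for the integer-valued
#' synthetic channels.
#'
#' @param image numeric matrix (values in [0, 65535]; rounded on write).
#' @param path output file path.
#' @export
write_image_pgm <- function(image, path) {
  stopifnot(is.matrix(image))
  vals <- round(t(image))  # PGM is row-major scanline order
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("P2", paste(ncol(image), nrow(image)), "65535"), con)
  write(as.integer(vals), file = con, ncolumns = 16L)
  invisible(path)
}

#' Read a plain-text PGM image
#'
#' @param path file written by \code{\link{write_image_pgm}}.
#' @return numeric matrix.
#' @export
read_image_pgm <- function(path) {
  tokens <- scan(path, what = character(), quiet = TRUE,
                 comment.char = "#")
  if (tokens[1] != "P2") stop("not a plain (P2) PGM file: ", path)
  w <- as.integer(tokens[2]); h <- as.integer(tokens[3])
  vals <- as.numeric(tokens[-(1:4)])
  if (length(vals) != w * h) stop("corrupt PGM pixel count in ", path)
  t(matrix(vals, nrow = w, ncol = h))
}
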