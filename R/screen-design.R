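#' Construct a synthetic screen design
#'
#' A \code{screen_design} states the world a synthetic screen is drawn from:
#' plate geometry, control layout, planted hits, positional gradients and
#' noise levels. All downstream generators (\code{\link{generate_plate_scores}},
#' \code{\link{generate_field}}, \code{\link{generate_ct_table}}) consume it,
#' and with a fixed \code{seed} generation is bit-reproducible.
#'
#' Well scores are nucleus-to-cytoplasm reporter intensity ratios. The
#' defaults describe a bortezomib-induced translocation assay: untreated-like
#' (positive-control, translocation-blocked) wells sit near 0.8 and
#' negative-control / typical sample wells near 2.0, with 12 control wells
#' per class per plate. Planted hits lower the well score (cytoplasmic
#' retention reduces the nuclear:cytoplasmic ratio), so true hits surface as
#' strongly negative B scores.
#'
#' @param n_plates number of plates.
#' @param plate_shape integer vector \code{c(rows, cols)}; default 16 x 24
#'   (384-well).
#' @param n_control_wells number of control wells per class per plate
#'   (default 12).
#' @param baseline_ratio mean well score of an unperturbed sample well
#'   (default 2.0).
#' @param positional_gradient numeric \code{c(row_slope, col_slope)}: additive
#'   well-score drift per well index, injected to exercise the median-polish
#'   correction (default \code{c(0.02, 0.01)}).
#' @param noise_sd standard deviation of additive Gaussian noise on sample
#'   well scores (default 0.1).
#' @param neg_control_sd,pos_control_sd noise SD of negative / positive
#'   control wells (defaults 0.08 and 0.06).
#' @param pos_control_shift additive score shift of positive-control wells
#'   (translocation abolished; default -1.2, i.e. mean score 0.8).
#' @param planted_hits data.frame with columns \code{gene_id} and
#'   \code{shift} (translocation shift in ratio units, negative for true
#'   hits), or NULL for none. Gene ids must refer to sample wells that exist
#'   in the design.
#' @param seed master RNG seed (mandatory).
#' @return an object of class \code{screen_design}.
#' @examples
#' design <- screen_design(n_plates = 2, seed = 1)
#' design
#' @export
screen_design <- function(n_plates = 1L,
                          plate_shape = c(16L, 24L),
                          n_control_wells = 12L,
                          baseline_ratio = 2.0,
                          positional_gradient = c(0.02, 0.01),
                          noise_sd = 0.1,
                          neg_control_sd = 0.08,
                          pos_control_sd = 0.06,
                          pos_control_shift = -1.2,
                          planted_hits = NULL,
                          seed) {
  if (missing(seed)) stop("screen_design(): 'seed' is mandatory")
  stopifnot(length(plate_shape) == 2L, all(plate_shape >= 2L))
  stopifnot(n_plates >= 1L, n_control_wells >= 2L)
  if (2L * n_control_wells > plate_shape[1L] * 2L) {
    stop("control layout uses the last two columns; need n_control_wells <= ",
         plate_shape[1L], " per class")
  }
  stopifnot(length(positional_gradient) == 2L, noise_sd >= 0,
            neg_control_sd >= 0, pos_control_sd >= 0)
  if (!is.null(planted_hits)) {
    stopifnot(is.data.frame(planted_hits),
              all(c("gene_id", "shift") %in% names(planted_hits)))
    if (anyDuplicated(planted_hits$gene_id))
      stop("planted_hits gene ids must be unique")
  }
  design <- structure(list(
    n_plates = as.integer(n_plates),
    plate_shape = as.integer(plate_shape),
    n_control_wells = as.integer(n_control_wells),
    baseline_ratio = baseline_ratio,
    positional_gradient = as.numeric(positional_gradient),
    noise_sd = noise_sd,
    neg_control_sd = neg_control_sd,
    pos_control_sd = pos_control_sd,
    pos_control_shift = pos_control_shift,
    planted_hits = planted_hits,
    seed = as.integer(seed)
  ), class = "screen_design")
  # validate hit placement against the realized plate maps
  if (!is.null(planted_hits)) {
    genes <- unlist(lapply(seq_len(design$n_plates) - 1L, function(p)
      plate_map(design, p)$gene_id))
    missing_genes <- setdiff(planted_hits$gene_id, genes)
    if (length(missing_genes))
      stop("planted_hits reference unknown gene ids: ",
           paste(missing_genes, collapse = ", "))
  }
  design
}

#' @export
print.screen_design <- function(x, ...) {
  cat(sprintf("screen_design: %d plate(s) of %d x %d wells\n",
              x$n_plates, x$plate_shape[1], x$plate_shape[2]))
  cat(sprintf("  controls: %d/class (neg sd %.3g, pos sd %.3g, pos shift %.3g)\n",
              x$n_control_wells, x$neg_control_sd, x$pos_control_sd,
              x$pos_control_shift))
  cat(sprintf("  baseline %.3g, gradient (%.3g, %.3g), noise sd %.3g, seed %d\n",
              x$baseline_ratio, x$positional_gradient[1],
              x$positional_gradient[2], x$noise_sd, x$seed))
  n_hits <- if (is.null(x$planted_hits)) 0L else nrow(x$planted_hits)
  cat(sprintf("  planted hits: %d\n", n_hits))
  invisible(x)
}

#' Plate map for one plate of a design
#'
#' Controls occupy the last two plate columns: negative controls fill the
#' top \code{n_control_wells} rows of the second-to-last column, positive
#' controls the top rows of the last column. Every remaining well is a
#' sample well with a unique gene id (\code{GENE<plate><index>}) targeted by
#' one pooled siRNA. This fixed layout keeps positional-effect tests
#' interpretable; real screens randomize control placement.
#'
#' @param design a \code{\link{screen_design}}.
#' @param plate_index 0-based plate index.
#' @return data.frame with columns \code{plate, row, col, well, gene_id,
#'   sirna_id, class} (row/col 1-based; \code{well} like \code{"A01"}).
#' @export
plate_map <- function(design, plate_index) {
  stopifnot(inherits(design, "screen_design"))
  plate_index <- as.integer(plate_index)
  if (plate_index < 0L || plate_index >= design$n_plates)
    stop("plate_index must be in [0, ", design$n_plates - 1L, "]")
  nr <- design$plate_shape[1L]; nc <- design$plate_shape[2L]
  grid <- expand.grid(row = seq_len(nr), col = seq_len(nc))
  class <- rep("sample", nrow(grid))
  neg_col <- nc - 1L; pos_col <- nc
  class[grid$col == neg_col & grid$row <= design$n_control_wells] <-
    "negative_control"
  class[grid$col == pos_col & grid$row <= design$n_control_wells] <-
    "positive_control"
  is_sample <- class == "sample"
  gene_id <- rep(NA_character_, nrow(grid))
  gene_id[is_sample] <- sprintf("GENE%02d_%03d", plate_index + 1L,
                                seq_len(sum(is_sample)))
  gene_id[class == "negative_control"] <- "NEG_CTRL"
  gene_id[class == "positive_control"] <- "POS_CTRL"
  sirna_id <- ifelse(is_sample, paste0("POOL_", gene_id), gene_id)
  data.frame(
    plate = plate_index + 1L,
    row = grid$row,
    col = grid$col,
    well = sprintf("%s%02d", row_letter(grid$row), grid$col),
    gene_id = gene_id,
    sirna_id = sirna_id,
    class = class,
    stringsAsFactors = FALSE
  )
}
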