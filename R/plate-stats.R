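#' Two-way median polish of a plate matrix
#'
#' Tukey's iterative decomposition of a plate of well scores into
#' \code{grand + row_effects[r] + col_effects[c] + residuals[r, c]},
#' alternately sweeping row and column medians (rows first) and folding the
#' median of each effect vector back into the grand effect. Removing the
#' fitted row and column effects strips smooth positional artifacts
#' (edge evaporation, dispenser gradients) from 384-well plates; the
#' residual is the positionally corrected well value that feeds the B-score
#' standardization.
#'
#' Missing wells are ignored by every median and carry no residual. The
#' reconstruction identity \code{x = grand + row + col + residual} holds
#' exactly (to machine precision) at every non-missing well, by
#' construction.
#'
#' @param x numeric matrix (>= 2 rows and columns with data); NAs allowed.
#' @param max_iter maximum full sweeps (default 100).
#' @param tol convergence tolerance on the maximum absolute change of any
#'   effect between sweeps (default 1e-12). The tight default matters: the
#'   L1 norm of the residuals can plateau for a few sweeps while effects
#'   are still drifting, so a looser early stop leaves residual error well
#'   above double-precision agreement with a fixed-sweep reference run.
#' @return object of class \code{median_polish_fit}: list with
#'   \code{grand_effect}, \code{row_effects}, \code{col_effects},
#'   \code{residuals}, \code{n_iterations}, \code{converged}.
#' @examples
#' x <- outer(c(0, 1, 2, 4), c(0, 10, 20)) * 0 + 5 +
#'   c(0, 1, 2, 4) + rep(c(0, 10, 20), each = 4)
#' fit <- median_polish(matrix(x, 4, 3))
#' max(abs(fit$residuals))  # 0: exactly additive input
#' @export
median_polish <- function(x, max_iter = 100L, tol = 1e-12) {
  stopifnot(is.matrix(x), is.numeric(x))
  nr <- nrow(x); nc <- ncol(x)
  if (sum(rowSums(!is.na(x)) > 0) < 2 || sum(colSums(!is.na(x)) > 0) < 2)
    stop("median_polish(): need at least 2 rows and 2 columns with data")

  grand <- 0
  row_eff <- rep(0, nr)
  col_eff <- rep(0, nc)
  res <- x
  converged <- FALSE
  iter <- 0L
  for (iter in seq_len(max_iter)) {
    old <- c(grand, row_eff, col_eff)

    rmed <- apply(res, 1, stats::median, na.rm = TRUE)
    rmed[!is.finite(rmed)] <- 0  # all-missing row: effect pinned at 0
    res <- res - rmed
    row_eff <- row_eff + rmed
    cmed <- stats::median(col_eff)
    col_eff <- col_eff - cmed
    grand <- grand + cmed

    cmed <- apply(res, 2, stats::median, na.rm = TRUE)
    cmed[!is.finite(cmed)] <- 0
    res <- sweep(res, 2, cmed)
    col_eff <- col_eff + cmed
    rmed2 <- stats::median(row_eff)
    row_eff <- row_eff - rmed2
    grand <- grand + rmed2

    if (max(abs(c(grand, row_eff, col_eff) - old)) < tol) {
      converged <- TRUE
      break
    }
  }
  # enforce the exact reconstruction identity against accumulated
  # floating-point drift in the sweeps
  fitted <- grand + outer(row_eff, col_eff, "+")
  res <- x - fitted
  structure(list(
    grand_effect = grand,
    row_effects = row_eff,
    col_effects = col_eff,
    residuals = res,
    n_iterations = iter,
    converged = converged
  ), class = "median_polish_fit")
}

#' @export
print.median_polish_fit <- function(x, ...) {
  cat(sprintf("median_polish_fit: %d x %d, grand effect %.4g, %d iteration(s)%s\n",
              length(x$row_effects), length(x$col_effects), x$grand_effect,
              x$n_iterations, if (x$converged) "" else " (not converged)"))
  invisible(x)
}

#' B scores from a median-polish fit
#'
#' Standardizes the polish residuals on a per-plate basis:
#' \deqn{B_{rc} = (X_{rc} - Median) / MAD}
#' where \eqn{X_{rc}} is the residual of well (r, c), and Median and MAD
#' (median absolute deviation, scaled by \code{mad_scale}) are computed over
#' the plate's sample wells only, so that control-well separation cannot
#' inflate the spread estimate. Control wells still receive scores.
#' Strongly negative B scores flag wells whose nuclear translocation is
#' blocked.
#'
#' @param fit a \code{\link{median_polish_fit}} (or, with
#'   \code{use_residuals = FALSE}, any such fit whose raw input should be
#'   standardized unpolished).
#' @param sample_mask logical matrix, TRUE at sample wells used for the
#'   Median/MAD estimate; NULL means all non-missing wells.
#' @param mad_scale MAD consistency factor (default 1.4826, which makes the
#'   MAD estimate the SD under normality; set 1 for the unscaled MAD).
#' @param use_residuals if FALSE, standardize \code{fit$residuals +
#'   fitted} i.e. the raw values (the literal "measured value" reading).
#' @param min_sample_wells minimum non-missing sample wells (default 8).
#' @return object of class \code{b_score_matrix}: list with \code{b_scores}
#'   matrix, \code{median_used}, \code{mad_used} (unscaled), \code{mad_scale},
#'   \code{wells_used} mask.
#' @examples
#' m <- matrix(rnorm(96, 2, 0.1), 8, 12)
#' bs <- b_score(median_polish(m))
#' abs(stats::median(bs$b_scores)) < 1e-12
#' @export
b_score <- function(fit, sample_mask = NULL, mad_scale = 1.4826,
                    use_residuals = TRUE, min_sample_wells = 8L) {
  stopifnot(inherits(fit, "median_polish_fit"))
  values <- if (use_residuals) {
    fit$residuals
  } else {
    fit$residuals + fit$grand_effect +
      outer(fit$row_effects, fit$col_effects, "+")
  }
  if (is.null(sample_mask)) {
    sample_mask <- !is.na(values)
  }
  stopifnot(is.logical(sample_mask), all(dim(sample_mask) == dim(values)))
  used <- sample_mask & !is.na(values)
  if (sum(used) < min_sample_wells)
    stop("b_score(): plate unusable, only ", sum(used),
         " non-missing sample wells (need >= ", min_sample_wells, ")")
  med <- stats::median(values[used])
  mad_raw <- stats::median(abs(values[used] - med))
  if (mad_raw == 0)
    stop("b_score(): degenerate plate, MAD of sample residuals is zero")
  structure(list(
    b_scores = (values - med) / (mad_scale * mad_raw),
    median_used = med,
    mad_used = mad_raw,
    mad_scale = mad_scale,
    wells_used = used
  ), class = "b_score_matrix")
}

#' @export
print.b_score_matrix <- function(x, ...) {
  cat(sprintf("b_score_matrix: %d x %d, Median %.4g, MAD %.4g (scale %.4g), %d wells used\n",
              nrow(x$b_scores), ncol(x$b_scores), x$median_used, x$mad_used,
              x$mad_scale, sum(x$wells_used)))
  invisible(x)
}

#' Z'-factor plate quality control
#'
#' Assay-window statistic computed from a plate's control wells:
#' \deqn{Z' = 1 - \frac{3 (s_{neg} + s_{pos})}{|\bar x_{neg} - \bar x_{pos}|}}
#' with sample standard deviations. Values above 0.5 indicate an excellent
#' separation between the negative (translocation intact) and positive
#' (translocation blocked) controls; screening plates are typically
#' accepted at Z' > 0.5.
#'
#' @param neg_scores,pos_scores numeric vectors of control well scores
#'   (>= 2 wells each).
#' @return object of class \code{z_prime_report}: list with
#'   \code{mean_neg, sd_neg, mean_pos, sd_pos, n_neg, n_pos, z_prime,
#'   undefined}. \code{z_prime} is NA (and \code{undefined} TRUE) when the
#'   control means coincide.
#' @examples
#' z_prime(rnorm(12, 2, 0.08), rnorm(12, 0.8, 0.06))$z_prime
#' @export
z_prime <- function(neg_scores, pos_scores) {
  neg_scores <- neg_scores[!is.na(neg_scores)]
  pos_scores <- pos_scores[!is.na(pos_scores)]
  if (length(neg_scores) < 2L || length(pos_scores) < 2L)
    stop("z_prime(): need >= 2 wells per control class")
  mn <- mean(neg_scores); mp <- mean(pos_scores)
  sn <- stats::sd(neg_scores); sp <- stats::sd(pos_scores)
  undefined <- mn == mp
  z <- if (undefined) NA_real_ else 1 - 3 * (sn + sp) / abs(mn - mp)
  structure(list(
    mean_neg = mn, sd_neg = sn, mean_pos = mp, sd_pos = sp,
    n_neg = length(neg_scores), n_pos = length(pos_scores),
    z_prime = z, undefined = undefined
  ), class = "z_prime_report")
}

#' @export
print.z_prime_report <- function(x, ...) {
  cat(sprintf("z_prime_report: Z' = %s (neg %.3g +/- %.3g, n=%d; pos %.3g +/- %.3g, n=%d)\n",
              if (x$undefined) "undefined" else sprintf("%.3f", x$z_prime),
              x$mean_neg, x$sd_neg, x$n_neg, x$mean_pos, x$sd_pos, x$n_pos))
  invisible(x)
}
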