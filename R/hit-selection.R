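#' Primary hit calling by B-score cutoff
#'
#' A gene is a primary hit when its pooled-siRNA well has
#' \code{b_score < cutoff} (strict inequality; default -3.2), or when it
#' appears on an explicit override list — the machine-readable stand-in for
#' rescue by visual inspection of raw images. Hits are returned ordered by
#' ascending B score.
#'
#' @param bscores data.frame with columns \code{gene_id} and \code{b_score}
#'   (one row per gene-well of the pooled primary screen).
#' @param cutoff primary threshold (default -3.2).
#' @param overrides character vector of gene ids rescued by inspection.
#' @return data.frame with columns \code{gene_id, b_score, is_hit,
#'   rescued_by_inspection}, hits first, ordered by ascending B score.
#' @examples
#' call_primary(data.frame(gene_id = c("A", "B"), b_score = c(-4, -1)))
#' @export
call_primary <- function(bscores, cutoff = -3.2, overrides = character(0)) {
  stopifnot(is.data.frame(bscores),
            all(c("gene_id", "b_score") %in% names(bscores)))
  rescued <- bscores$gene_id %in% overrides
  below <- !is.na(bscores$b_score) & bscores$b_score < cutoff
  out <- data.frame(
    gene_id = bscores$gene_id,
    b_score = bscores$b_score,
    is_hit = below | rescued,
    rescued_by_inspection = rescued & !below,
    stringsAsFactors = FALSE
  )
  out[order(-out$is_hit, out$b_score), , drop = FALSE]
}

#' Secondary screen: per-siRNA deconvolution across cell lines
#'
#' Retests each primary candidate with the four individual siRNAs of its
#' pool in each cell line. An individual siRNA confirms when its well score
#' falls strictly below \code{threshold} (a score-scale cutoff, typically
#' the midpoint between the plate's negative- and positive-control means; a
#' per-cell-line named vector is accepted). A gene passes when the number
#' of confirming siRNAs in at least one cell line reaches
#' \code{min_hits}. Missing siRNA measurements count as non-confirming.
#'
#' @param scores data.frame with columns \code{gene_id, sirna_id,
#'   cell_line, score}.
#' @param threshold numeric confirmation cutoff; either a single value or a
#'   named vector keyed by cell line.
#' @param min_hits confirming siRNAs required in some cell line (default 2;
#'   the stricter literal reading of "more than two" is \code{min_hits = 3}).
#' @return data.frame with one row per gene: \code{gene_id}, one
#'   \code{hits_<cell_line>} count column per cell line, \code{max_hits},
#'   \code{passes}.
#' @examples
#' s <- generate_secondary_scores("G1", n_active = 3, noise_sd = 0, seed = 1)
#' call_secondary(s, threshold = 1.4)
#' @export
call_secondary <- function(scores, threshold, min_hits = 2L) {
  stopifnot(is.data.frame(scores),
            all(c("gene_id", "sirna_id", "cell_line", "score") %in%
                  names(scores)))
  cell_lines <- sort(unique(scores$cell_line))
  thr <- if (length(threshold) == 1L && is.null(names(threshold))) {
    stats::setNames(rep(threshold, length(cell_lines)), cell_lines)
  } else {
    if (!all(cell_lines %in% names(threshold)))
      stop("call_secondary(): threshold missing for cell line(s): ",
           paste(setdiff(cell_lines, names(threshold)), collapse = ", "))
    threshold
  }
  confirm <- !is.na(scores$score) &
    scores$score < thr[scores$cell_line]
  counts <- stats::aggregate(confirm,
                             by = list(gene_id = scores$gene_id,
                                       cell_line = scores$cell_line),
                             FUN = sum)
  genes <- unique(scores$gene_id)
  out <- data.frame(gene_id = genes, stringsAsFactors = FALSE)
  for (cl in cell_lines) {
    sub <- counts[counts$cell_line == cl, ]
    v <- sub$x[match(genes, sub$gene_id)]
    v[is.na(v)] <- 0L
    if (any(v > 4L))
      stop("call_secondary(): more than 4 siRNA wells for a gene in ", cl)
    out[[paste0("hits_", cl)]] <- as.integer(v)
  }
  absent <- vapply(genes, function(g)
    length(setdiff(cell_lines, scores$cell_line[scores$gene_id == g])) > 0,
    logical(1))
  if (any(absent))
    warning("call_secondary(): gene(s) absent from a cell line (count 0): ",
            paste(genes[absent], collapse = ", "))
  hit_cols <- paste0("hits_", cell_lines)
  out$max_hits <- do.call(pmax, out[hit_cols])
  out$passes <- out$max_hits >= min_hits
  out
}

#' Delta-delta-Ct fold induction for one gene
#'
#' Relative qPCR quantification with amplification efficiency 2:
#' per replicate \eqn{\Delta Ct = Ct_{target} - Ct_{reference}}; then
#' \eqn{\Delta\Delta Ct = \overline{\Delta Ct}_{treated} -
#' \overline{\Delta Ct}_{untreated}} and fold induction
#' \eqn{2^{-\Delta\Delta Ct}}. Target is the proteasome bounce-back
#' reporter (PSMA3 in this assay), reference the housekeeping gene (GUSB).
#'
#' @param ct data.frame rows for one gene, columns \code{treated}
#'   (logical), \code{replicate}, \code{ct_target}, \code{ct_reference}.
#' @return list with \code{fold_induction}, \code{ddct},
#'   \code{dct_treated}, \code{dct_untreated}.
#' @examples
#' ct <- generate_ct_table("X", attenuation = 0.5, base_induction = 4,
#'                         noise_sd = 0, seed = 1)
#' ddct_fold_change(ct[ct$gene_id == "X", ])$fold_induction  # 2
#' @export
ddct_fold_change <- function(ct) {
  stopifnot(is.data.frame(ct),
            all(c("treated", "ct_target", "ct_reference") %in% names(ct)))
  if (length(unique(ct$gene_id)) > 1)
    stop("ddct_fold_change(): pass rows for a single gene")
  if (anyNA(ct$ct_reference))
    stop("ddct_fold_change(): missing reference Ct for gene ",
         unique(ct$gene_id)[1])
  if (anyNA(ct$ct_target))
    stop("ddct_fold_change(): missing target Ct for gene ",
         unique(ct$gene_id)[1])
  if (!any(ct$treated) || !any(!ct$treated))
    stop("ddct_fold_change(): need both treated and untreated rows")
  dct <- ct$ct_target - ct$ct_reference
  dct_t <- mean(dct[ct$treated])
  dct_u <- mean(dct[!ct$treated])
  ddct <- dct_t - dct_u
  list(fold_induction = 2^(-ddct), ddct = ddct,
       dct_treated = dct_t, dct_untreated = dct_u)
}

#' Tertiary screen: bounce-back attenuation filter
#'
#' Compares the inhibitor-induced fold induction of the proteasome reporter
#' gene under knockdown against the non-targeting control. A gene passes
#' when the knockdown attenuates the induction:
#' \code{attenuation_ratio = fold_knockdown / fold_control <
#' tertiary_max_ratio}.
#'
#' @param fold_control fold induction with non-targeting siRNA (> 0).
#' @param fold_knockdown fold induction with the candidate knocked down.
#' @param tertiary_max_ratio pass threshold on the ratio (default 0.7; the
#'   source screen applied the criterion qualitatively).
#' @return data.frame row: \code{fold_induction_control,
#'   fold_induction_knockdown, attenuation_ratio, passes}.
#' @examples
#' call_tertiary(4, 1.2)$passes  # TRUE: induction reduced to 30%
#' @export
call_tertiary <- function(fold_control, fold_knockdown,
                          tertiary_max_ratio = 0.7) {
  stopifnot(fold_control > 0, fold_knockdown >= 0)
  ratio <- fold_knockdown / fold_control
  data.frame(
    fold_induction_control = fold_control,
    fold_induction_knockdown = fold_knockdown,
    attenuation_ratio = ratio,
    passes = ratio < tertiary_max_ratio
  )
}

#' Assemble the per-stage hit table
#'
#' Joins the three funnel stages into one row per gene carrying every stage
#' outcome. Stage order is enforced: a gene may appear in the secondary
#' results only if it was a primary hit, and in the tertiary results only
#' if it passed deconvolution. Final hits are the genes passing all three
#' stages.
#'
#' @param primary output of \code{\link{call_primary}}.
#' @param secondary output of \code{\link{call_secondary}}, or NULL if the
#'   funnel stopped after the primary stage.
#' @param tertiary data.frame with \code{gene_id} plus the
#'   \code{\link{call_tertiary}} columns, or NULL.
#' @return data.frame (class \code{hit_table}) with per-stage columns and
#'   \code{final_hit}; attribute \code{"final_hits"} carries the hit gene
#'   ids.
#' @export
assemble_hit_table <- function(primary, secondary = NULL, tertiary = NULL) {
  stopifnot(is.data.frame(primary),
            all(c("gene_id", "is_hit") %in% names(primary)))
  primary_hits <- primary$gene_id[primary$is_hit]
  if (!is.null(secondary)) {
    extra <- setdiff(secondary$gene_id, primary_hits)
    if (length(extra))
      stop("stage-order violation: secondary results for non-primary-hit ",
           "gene(s): ", paste(extra, collapse = ", "))
  }
  secondary_pass <- if (is.null(secondary)) character(0)
                    else secondary$gene_id[secondary$passes]
  if (!is.null(tertiary)) {
    stopifnot("gene_id" %in% names(tertiary))
    extra <- setdiff(tertiary$gene_id, secondary_pass)
    if (length(extra))
      stop("stage-order violation: tertiary results for gene(s) that did ",
           "not pass deconvolution: ", paste(extra, collapse = ", "))
  }

  out <- primary
  if (!is.null(secondary)) {
    out <- merge(out, secondary, by = "gene_id", all.x = TRUE, sort = FALSE)
  } else {
    out$passes <- NA
  }
  names(out)[names(out) == "passes"] <- "secondary_passes"
  if (!is.null(tertiary)) {
    out <- merge(out, tertiary, by = "gene_id", all.x = TRUE, sort = FALSE)
    names(out)[names(out) == "passes"] <- "tertiary_passes"
  } else {
    out$tertiary_passes <- NA
  }
  out$final_hit <- !is.na(out$is_hit) & out$is_hit &
    !is.na(out$secondary_passes) & out$secondary_passes &
    !is.na(out$tertiary_passes) & out$tertiary_passes
  out <- out[order(-out$final_hit, out$b_score), , drop = FALSE]
  rownames(out) <- NULL
  structure(out, final_hits = out$gene_id[out$final_hit],
            class = c("hit_table", "data.frame"))
}
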