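#' Generate raw well scores for one plate
#'
#' Draws one plate of raw nucleus:cytoplasm well scores from the additive
#' model
#' \deqn{raw(r,c) = baseline + row\_slope (r-1) + col\_slope (c-1) +
#'   hit\_shift + control\_shift + \epsilon}
#' where \eqn{\epsilon} is Gaussian with a class-specific SD. Every
#' ground-truth component is returned alongside the realized scores, so
#' tests can assert exact decomposability at zero noise and recover planted
#' effects at any noise level.
#'
#' @param design a \code{\link{screen_design}}.
#' @param plate_index 0-based plate index; each plate uses a seed derived
#'   from \code{design$seed} via \code{\link{split_seed}}, so plates can be
#'   regenerated independently and bit-identically.
#' @return list with elements:
#'   \item{scores}{rows x cols numeric matrix of raw well scores}
#'   \item{map}{the \code{\link{plate_map}} data.frame with ground-truth
#'     component columns \code{baseline, gradient, hit_shift, control_shift,
#'     noise} and the realized \code{raw} score}
#' @examples
#' d <- screen_design(n_plates = 1, noise_sd = 0, positional_gradient = c(0, 0),
#'                    seed = 7)
#' p <- generate_plate_scores(d, 0)
#' unique(p$scores[p$map$class == "sample"])  # all at baseline
#' @export
generate_plate_scores <- function(design, plate_index) {
  stopifnot(inherits(design, "screen_design"))
  map <- plate_map(design, plate_index)
  nr <- design$plate_shape[1L]; nc <- design$plate_shape[2L]

  gradient <- design$positional_gradient[1L] * (map$row - 1L) +
    design$positional_gradient[2L] * (map$col - 1L)
  control_shift <- ifelse(map$class == "positive_control",
                          design$pos_control_shift, 0)
  hit_shift <- rep(0, nrow(map))
  if (!is.null(design$planted_hits)) {
    idx <- match(map$gene_id, design$planted_hits$gene_id)
    hit_shift[!is.na(idx)] <- design$planted_hits$shift[idx[!is.na(idx)]]
  }
  noise_sd <- c(sample = design$noise_sd,
                negative_control = design$neg_control_sd,
                positive_control = design$pos_control_sd)[map$class]
  noise <- with_seed(split_seed(design$seed, plate_index),
                     rnorm(nrow(map), mean = 0, sd = noise_sd))

  map$baseline <- design$baseline_ratio
  map$gradient <- gradient
  map$hit_shift <- hit_shift
  map$control_shift <- control_shift
  map$noise <- noise
  map$raw <- map$baseline + gradient + hit_shift + control_shift + noise

  scores <- matrix(NA_real_, nr, nc)
  scores[cbind(map$row, map$col)] <- map$raw
  list(scores = scores, map = map)
}

#' Generate raw well scores for every plate of a design
#'
#' @param design a \code{\link{screen_design}}.
#' @return data.frame stacking the per-plate maps (see
#'   \code{\link{generate_plate_scores}}).
#' @export
generate_screen_scores <- function(design) {
  stopifnot(inherits(design, "screen_design"))
  do.call(rbind, lapply(seq_len(design$n_plates) - 1L, function(p)
    generate_plate_scores(design, p)$map))
}

#' Generate per-siRNA deconvolution well scores
#'
#' Emulates the secondary screen: each candidate gene is retested with four
#' individual siRNAs (the members of the primary pool) in two cell lines.
#' An "active" siRNA reproduces the translocation block (low score near the
#' positive-control level); an inactive one leaves the well at baseline.
#' Off-target pool artifacts are modeled by giving decoy genes fewer active
#' siRNAs than the confirmation threshold.
#'
#' @param genes character vector of gene ids to deconvolute.
#' @param n_active named or unnamed integer vector (recycled) giving the
#'   number of active siRNAs (0..4) per gene, applied in both cell lines.
#' @param cell_lines character vector of cell-line labels.
#' @param baseline_ratio,active_shift,noise_sd score model parameters;
#'   active wells score \code{baseline_ratio + active_shift}.
#' @param seed RNG seed.
#' @return data.frame with columns \code{gene_id, sirna_id, cell_line,
#'   score, active} (\code{active} is ground truth).
#' @export
generate_secondary_scores <- function(genes,
                                      n_active,
                                      cell_lines = c("HEK293A", "HT1080"),
                                      baseline_ratio = 2.0,
                                      active_shift = -1.2,
                                      noise_sd = 0.1,
                                      seed) {
  stopifnot(length(genes) >= 1L, all(n_active >= 0L), all(n_active <= 4L))
  n_active <- rep_len(as.integer(n_active), length(genes))
  rows <- expand.grid(sirna = 1:4, cell_line = cell_lines, gene = genes,
                      stringsAsFactors = FALSE)
  active <- rows$sirna <= n_active[match(rows$gene, genes)]
  noise <- with_seed(seed, rnorm(nrow(rows), 0, noise_sd))
  data.frame(
    gene_id = rows$gene,
    sirna_id = sprintf("%s_si%d", rows$gene, rows$sirna),
    cell_line = rows$cell_line,
    score = baseline_ratio + ifelse(active, active_shift, 0) + noise,
    active = active,
    stringsAsFactors = FALSE
  )
}

#' Generate a synthetic qPCR Ct table
#'
#' Emulates the tertiary screen readout: expression of the proteasome
#' subunit gene PSMA3 (target), normalized to GUSB (reference), with and
#' without proteasome inhibitor. In control (non-targeting siRNA) cells the
#' inhibitor induces the target \code{base_induction}-fold (the bounce-back
#' response); knocking down a true regulator attenuates the induction to
#' \code{base_induction * attenuation[gene]}. Ct values are constructed so
#' that delta-delta-Ct arithmetic recovers exactly those fold changes at
#' zero noise.
#'
#' @param genes character vector of knockdown gene ids. A control row with
#'   \code{gene_id = "NTC"} (non-targeting control, attenuation 1) is always
#'   included.
#' @param attenuation numeric in [0, 1], recycled over \code{genes}:
#'   1 = full bounce-back (no attenuation), 0 = induction fully blocked.
#' @param base_induction fold induction of the target in control cells
#'   (default 4).
#' @param n_replicates replicates per condition (default 3).
#' @param noise_sd Gaussian SD added independently to every Ct value
#'   (cycles; default 0).
#' @param ct_reference_base,ct_target_base baseline Ct of the reference and
#'   target assays in untreated cells (cycles).
#' @param seed RNG seed.
#' @return data.frame with columns \code{gene_id, treated (logical:
#'   +inhibitor), replicate, ct_target, ct_reference}.
#' @examples
#' ct <- generate_ct_table("DDI2", attenuation = 0.5, base_induction = 4,
#'                         noise_sd = 0, seed = 1)
#' ddct_fold_change(ct[ct$gene_id == "DDI2", ])  # 2.0
#' @export
generate_ct_table <- function(genes,
                              attenuation,
                              base_induction = 4,
                              n_replicates = 3L,
                              noise_sd = 0,
                              ct_reference_base = 22,
                              ct_target_base = 25,
                              seed) {
  stopifnot(all(attenuation >= 0), all(attenuation <= 1),
            base_induction > 0, n_replicates >= 1L, noise_sd >= 0)
  attenuation <- rep_len(attenuation, length(genes))
  genes <- c("NTC", genes)
  attenuation <- c(1, attenuation)

  rows <- expand.grid(replicate = seq_len(n_replicates),
                      treated = c(FALSE, TRUE),
                      gene = genes, stringsAsFactors = FALSE)
  att <- attenuation[match(rows$gene, genes)]
  fold <- base_induction * att
  # delta-Ct untreated is the assay offset; treatment lowers the target Ct
  # by log2(fold) cycles relative to the reference
  dct <- ifelse(rows$treated,
                (ct_target_base - ct_reference_base) - log2(pmax(fold, 1e-12)),
                ct_target_base - ct_reference_base)
  noise <- with_seed(seed, rnorm(2L * nrow(rows), 0, noise_sd))
  data.frame(
    gene_id = rows$gene,
    treated = rows$treated,
    replicate = rows$replicate,
    ct_target = ct_reference_base + dct + noise[seq_len(nrow(rows))],
    ct_reference = ct_reference_base + noise[nrow(rows) + seq_len(nrow(rows))],
    stringsAsFactors = FALSE
  )
}
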