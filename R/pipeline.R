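#' Build and validate a pipeline configuration
#'
#' Collects every tunable of the screen pipeline in one validated list.
#' Unknown keys are rejected so that config typos fail loudly, and the
#' config (with its hash) is echoed into the provenance header of every
#' file the pipeline writes.
#'
#' @param seed master RNG seed (mandatory; all stage seeds derive from it
#'   via \code{\link{split_seed}}).
#' @param n_plates,plate_shape screen geometry (defaults 1 plate, 16 x 24).
#' @param n_control_wells control wells per class per plate (default 12).
#' @param erosion_px,ring_width_px,gap_px ROI geometry (defaults 2, 3, 0).
#' @param min_cells minimum measurable cells per well (default 20).
#' @param aggregation \code{"median"} or \code{"mean"} per-cell
#'   aggregation (default median).
#' @param mad_scale MAD consistency factor for B scores (default 1.4826).
#' @param primary_cutoff primary B-score cutoff (default -3.2).
#' @param secondary_min_hits confirming siRNAs required (default 2).
#' @param tertiary_max_ratio attenuation pass threshold (default 0.7).
#' @param n_planted_hits,hit_shift planted true hits for the simulate
#'   stage (defaults 0 and -1.0).
#' @param n_decoys decoy genes: strong pooled effect but a single active
#'   siRNA on deconvolution (default 0).
#' @param noise_sd sample-well noise SD (default 0.1).
#' @param positional_gradient c(row, col) slope injected by simulate
#'   (default c(0.02, 0.01)).
#' @param base_induction,hit_attenuation tertiary-stage ground truth
#'   (defaults 4 and 0.2).
#' @return validated list of class \code{pipeline_config} with a
#'   \code{config_hash} field.
#' @export
pipeline_config <- function(seed,
                            n_plates = 1L,
                            plate_shape = c(16L, 24L),
                            n_control_wells = 12L,
                            erosion_px = 2L,
                            ring_width_px = 3L,
                            gap_px = 0L,
                            min_cells = 20L,
                            aggregation = "median",
                            mad_scale = 1.4826,
                            primary_cutoff = -3.2,
                            secondary_min_hits = 2L,
                            tertiary_max_ratio = 0.7,
                            n_planted_hits = 0L,
                            hit_shift = -1.0,
                            n_decoys = 0L,
                            noise_sd = 0.1,
                            positional_gradient = c(0.02, 0.01),
                            base_induction = 4,
                            hit_attenuation = 0.2) {
  if (missing(seed)) stop("pipeline_config(): 'seed' is mandatory")
  cfg <- list(seed = as.integer(seed), n_plates = as.integer(n_plates),
              plate_shape = as.integer(plate_shape),
              n_control_wells = as.integer(n_control_wells),
              erosion_px = as.integer(erosion_px),
              ring_width_px = as.integer(ring_width_px),
              gap_px = as.integer(gap_px),
              min_cells = as.integer(min_cells),
              aggregation = match.arg(aggregation, c("median", "mean")),
              mad_scale = mad_scale,
              primary_cutoff = primary_cutoff,
              secondary_min_hits = as.integer(secondary_min_hits),
              tertiary_max_ratio = tertiary_max_ratio,
              n_planted_hits = as.integer(n_planted_hits),
              hit_shift = hit_shift,
              n_decoys = as.integer(n_decoys),
              noise_sd = noise_sd,
              positional_gradient = as.numeric(positional_gradient),
              base_induction = base_induction,
              hit_attenuation = hit_attenuation)
  stopifnot(cfg$gap_px %in% c(0L, 1L), cfg$mad_scale > 0,
            cfg$tertiary_max_ratio > 0, cfg$secondary_min_hits >= 1L,
            cfg$noise_sd >= 0)
  cfg$config_hash <- config_hash(cfg)
  structure(cfg, class = "pipeline_config")
}

#' Load a pipeline configuration from a JSON file
#'
#' Unknown keys are rejected; \code{seed} is mandatory in the file.
#'
#' @param path JSON file whose keys are \code{\link{pipeline_config}}
#'   arguments.
#' @return a \code{pipeline_config}.
#' @export
read_pipeline_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  known <- names(formals(pipeline_config))
  unknown <- setdiff(names(raw), known)
  if (length(unknown))
    stop("unknown config key(s) in ", path, ": ",
         paste(unknown, collapse = ", "))
  if (is.null(raw$seed)) stop("config ", path, " must set 'seed'")
  do.call(pipeline_config, raw)
}

# ---- provenance-stamped CSV I/O ------------------------------------------

#' Write a data.frame as CSV with a provenance header
#'
#' Provenance lines are '#'-prefixed comments (key: value) recording the
#' config hash, the seed, the writing stage and package version, so every
#' artifact is traceable to the run that produced it.
#'
#' @param df data.frame.
#' @param path output path.
#' @param config a \code{\link{pipeline_config}} or NULL.
#' @param stage character stage name for the header.
#' @param sep field separator (default ","; use "\\t" for .tsv).
#' @export
write_screen_csv <- function(df, path, config = NULL, stage = "unknown",
                             sep = ",") {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# screenpolish: %s", stage), con)
  if (!is.null(config)) {
    writeLines(sprintf("# config_hash: %s", config$config_hash), con)
    writeLines(sprintf("# seed: %d", config$seed), con)
  }
  utils::write.table(df, con, sep = sep, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a provenance-stamped CSV
#'
#' @param path file written by \code{\link{write_screen_csv}}.
#' @param sep field separator.
#' @return data.frame; provenance header returned in attribute
#'   \code{"provenance"}.
#' @export
read_screen_csv <- function(path, sep = ",") {
  if (!file.exists(path)) stop("input file not found: ", path)
  lines <- readLines(path, n = 10L)
  prov <- grep("^#", lines, value = TRUE)
  df <- utils::read.table(path, header = TRUE, sep = sep, comment.char = "#",
                          stringsAsFactors = FALSE)
  attr(df, "provenance") <- prov
  df
}

# ---- stages ---------------------------------------------------------------

simulate_stage <- function(config, out_dir) {
  n_samples_per_plate <- prod(config$plate_shape) - 2L * config$n_control_wells
  n_special <- config$n_planted_hits + config$n_decoys
  if (n_special > n_samples_per_plate * config$n_plates)
    stop("simulate: more planted hits + decoys than sample wells")
  # planted hits and decoys get the same pooled-well shift; they separate
  # at deconvolution (hits: 4 active siRNAs, decoys: 1)
  all_genes <- unlist(lapply(seq_len(config$n_plates) - 1L, function(p) {
    m <- plate_map(screen_design(n_plates = config$n_plates,
                                 plate_shape = config$plate_shape,
                                 n_control_wells = config$n_control_wells,
                                 seed = config$seed), p)
    m$gene_id[m$class == "sample"]
  }))
  special <- with_seed(split_seed(config$seed, 900L),
                       sample(all_genes, n_special))
  hit_genes <- special[seq_len(config$n_planted_hits)]
  decoy_genes <- special[config$n_planted_hits + seq_len(config$n_decoys)]
  planted <- if (n_special) {
    data.frame(gene_id = special, shift = config$hit_shift)
  } else NULL

  design <- screen_design(
    n_plates = config$n_plates,
    plate_shape = config$plate_shape,
    n_control_wells = config$n_control_wells,
    positional_gradient = config$positional_gradient,
    noise_sd = config$noise_sd,
    planted_hits = planted,
    seed = config$seed
  )
  wells <- generate_screen_scores(design)
  wells$n_cells <- NA_integer_
  write_screen_csv(
    wells[c("plate", "row", "col", "well", "gene_id", "sirna_id", "class",
            "raw")],
    file.path(out_dir, "wells.csv"), config, stage = "simulate")

  candidates <- c(hit_genes, decoy_genes)
  if (length(candidates)) {
    sec <- generate_secondary_scores(
      candidates,
      n_active = c(rep(4L, length(hit_genes)), rep(1L, length(decoy_genes))),
      noise_sd = config$noise_sd,
      seed = split_seed(config$seed, 901L))
    # each retest plate carries its own control wells; the hits stage
    # derives the per-siRNA confirmation threshold from these
    ctrl_noise <- with_seed(split_seed(config$seed, 903L),
                            rnorm(4L * config$n_control_wells, 0, 1))
    ctrl <- data.frame(
      gene_id = rep(rep(c("NEG_CTRL", "POS_CTRL"),
                        each = config$n_control_wells), 2L),
      sirna_id = rep(rep(c("NEG_CTRL", "POS_CTRL"),
                         each = config$n_control_wells), 2L),
      cell_line = rep(c("HEK293A", "HT1080"),
                      each = 2L * config$n_control_wells),
      score = rep(rep(c(2.0, 0.8), each = config$n_control_wells), 2L) +
        ctrl_noise * rep(rep(c(0.08, 0.06),
                             each = config$n_control_wells), 2L),
      stringsAsFactors = FALSE)
    write_screen_csv(rbind(sec[c("gene_id", "sirna_id", "cell_line",
                                 "score")], ctrl),
                     file.path(out_dir, "secondary_wells.csv"),
                     config, stage = "simulate")
    ct <- generate_ct_table(
      candidates,
      attenuation = c(rep(config$hit_attenuation, length(hit_genes)),
                      rep(1, length(decoy_genes))),
      base_induction = config$base_induction,
      noise_sd = 0.05,
      seed = split_seed(config$seed, 902L))
    write_screen_csv(ct, file.path(out_dir, "qpcr.csv"), config,
                     stage = "simulate")
  }
  truth <- data.frame(gene_id = c(hit_genes, decoy_genes),
                      role = c(rep("hit", length(hit_genes)),
                               rep("decoy", length(decoy_genes))))
  write_screen_csv(truth, file.path(out_dir, "truth.csv"), config,
                   stage = "simulate")
  invisible(design)
}

normalize_stage <- function(config, out_dir) {
  wells <- read_screen_csv(file.path(out_dir, "wells.csv"))
  need <- c("plate", "row", "col", "gene_id", "class", "raw")
  miss <- setdiff(need, names(wells))
  if (length(miss))
    stop("normalize: wells.csv missing column(s): ",
         paste(miss, collapse = ", "))
  out <- list(); qc <- list()
  for (p in sort(unique(wells$plate))) {
    w <- wells[wells$plate == p, ]
    nr <- max(w$row); nc <- max(w$col)
    m <- matrix(NA_real_, nr, nc)
    m[cbind(w$row, w$col)] <- w$raw
    smask <- matrix(FALSE, nr, nc)
    smask[cbind(w$row, w$col)] <- w$class == "sample"
    fit <- median_polish(m)
    bs <- b_score(fit, sample_mask = smask, mad_scale = config$mad_scale)
    w$residual <- fit$residuals[cbind(w$row, w$col)]
    w$b_score <- bs$b_scores[cbind(w$row, w$col)]
    out[[as.character(p)]] <- w
    zp <- z_prime(w$raw[w$class == "negative_control"],
                  w$raw[w$class == "positive_control"])
    qc[[as.character(p)]] <- data.frame(
      plate = p, n_neg = zp$n_neg, n_pos = zp$n_pos,
      mean_neg = zp$mean_neg, sd_neg = zp$sd_neg,
      mean_pos = zp$mean_pos, sd_pos = zp$sd_pos,
      z_prime = zp$z_prime)
  }
  bs_df <- do.call(rbind, out)
  write_screen_csv(bs_df, file.path(out_dir, "bscores.csv"), config,
                   stage = "normalize")
  write_screen_csv(do.call(rbind, qc), file.path(out_dir, "zprime.csv"),
                   config, stage = "normalize")
  invisible(bs_df)
}

hits_stage <- function(config, out_dir) {
  bs <- read_screen_csv(file.path(out_dir, "bscores.csv"))
  samples <- bs[bs$class == "sample", ]
  primary <- call_primary(samples[c("gene_id", "b_score")],
                          cutoff = config$primary_cutoff)
  primary_hits <- primary$gene_id[primary$is_hit]

  secondary <- tertiary <- NULL
  sec_path <- file.path(out_dir, "secondary_wells.csv")
  if (file.exists(sec_path) && length(primary_hits)) {
    sec_all <- read_screen_csv(sec_path)
    sec <- sec_all[sec_all$gene_id %in% primary_hits, ]
    if (nrow(sec)) {
      # confirmation cutoff: midpoint between the retest plate's own
      # control means, per cell line; fall back to the primary plates'
      # controls when the retest file carries none
      has_ctrl <- sec_all$gene_id %in% c("NEG_CTRL", "POS_CTRL")
      if (any(has_ctrl)) {
        ctrl <- sec_all[has_ctrl, ]
        thr <- tapply(ctrl$score,
                      list(ctrl$cell_line, ctrl$gene_id), mean)
        threshold <- (thr[, "NEG_CTRL"] + thr[, "POS_CTRL"]) / 2
      } else {
        neg_mean <- mean(bs$raw[bs$class == "negative_control"])
        pos_mean <- mean(bs$raw[bs$class == "positive_control"])
        threshold <- (neg_mean + pos_mean) / 2
      }
      secondary <- call_secondary(sec, threshold = threshold,
                                  min_hits = config$secondary_min_hits)
    }
  }
  qpcr_path <- file.path(out_dir, "qpcr.csv")
  if (!is.null(secondary) && file.exists(qpcr_path)) {
    qp <- read_screen_csv(qpcr_path)
    fold_control <- ddct_fold_change(
      qp[qp$gene_id == "NTC", ])$fold_induction
    sec_pass <- secondary$gene_id[secondary$passes]
    sec_pass <- sec_pass[sec_pass %in% qp$gene_id]
    if (length(sec_pass)) {
      tertiary <- do.call(rbind, lapply(sec_pass, function(g) {
        fk <- ddct_fold_change(qp[qp$gene_id == g, ])$fold_induction
        cbind(gene_id = g,
              call_tertiary(fold_control, fk,
                            tertiary_max_ratio = config$tertiary_max_ratio))
      }))
    }
  }
  table <- assemble_hit_table(primary, secondary, tertiary)
  write_screen_csv(as.data.frame(table), file.path(out_dir, "hits.tsv"),
                   config, stage = "hits", sep = "\t")
  invisible(table)
}

#' Run the screen pipeline
#'
#' Executes the requested stages in order — \code{simulate} (synthetic
#' wells, secondary scores, qPCR tables with ground truth), \code{normalize}
#' (per-plate median polish, B scores, Z'-factor QC) and \code{hits} (the
#' three-stage funnel) — writing provenance-stamped artifacts plus a JSON
#' run manifest into \code{out_dir}. Reruns with an identical config are
#' bit-identical. Image-level quantification (\code{\link{quantify_field}})
#' is exposed separately; the score-level simulate stage is the tractable
#' default for whole-screen runs.
#'
#' @param config a \code{\link{pipeline_config}}.
#' @param out_dir output directory (created if needed).
#' @param stages character subset of \code{c("simulate", "normalize",
#'   "hits")}, in pipeline order. Later stages require the earlier stages'
#'   artifacts to exist in \code{out_dir}.
#' @return invisibly, the final \code{hit_table} if the \code{hits} stage
#'   ran, else NULL.
#' @examples
#' \donttest{
#' cfg <- pipeline_config(seed = 11, n_plates = 1, n_planted_hits = 2,
#'                        n_decoys = 2)
#' run_pipeline(cfg, tempfile("run"))
#' }
#' @export
run_pipeline <- function(config, out_dir,
                         stages = c("simulate", "normalize", "hits")) {
  stopifnot(inherits(config, "pipeline_config"))
  stages <- match.arg(stages, c("simulate", "normalize", "hits"),
                      several.ok = TRUE)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  result <- NULL
  for (stage in c("simulate", "normalize", "hits")) {
    if (!stage %in% stages) next
    result <- switch(stage,
      simulate = simulate_stage(config, out_dir),
      normalize = normalize_stage(config, out_dir),
      hits = hits_stage(config, out_dir))
  }
  manifest <- list(
    package = "screenpolish",
    version = as.character(utils::packageVersion("screenpolish")),
    config = unclass(config),
    stages = stages,
    outputs = list.files(out_dir),
    timestamp = format(Sys.time(), tz = "UTC")
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(if ("hits" %in% stages) result else NULL)
}
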