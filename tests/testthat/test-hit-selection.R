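test_that("call_primary applies a strict cutoff plus overrides", {
  bs <- data.frame(gene_id = c("A", "B", "C", "D"),
                   b_score = c(-3.5, -3.2, -1.0, -4.1))
  calls <- call_primary(bs)
  expect_true(calls$is_hit[calls$gene_id == "A"])
  expect_false(calls$is_hit[calls$gene_id == "B"])  # boundary: strict <
  expect_false(calls$is_hit[calls$gene_id == "C"])
  # hits ordered by ascending B score
  expect_equal(calls$gene_id[1:2], c("D", "A"))

  resc <- call_primary(bs, overrides = "C")
  expect_true(resc$is_hit[resc$gene_id == "C"])
  expect_true(resc$rescued_by_inspection[resc$gene_id == "C"])
  expect_false(resc$rescued_by_inspection[resc$gene_id == "A"])
})

test_that("call_secondary counts confirming siRNAs per cell line", {
  mk <- function(gene, hek, ht) {
    do.call(rbind, lapply(1:4, function(i) data.frame(
      gene_id = gene, sirna_id = paste0(gene, "_si", i),
      cell_line = c("HEK293A", "HT1080"),
      score = c(if (i <= hek) 0.8 else 2.0, if (i <= ht) 0.8 else 2.0))))
  }
  scores <- rbind(mk("G1", 3, 0), mk("G2", 0, 0), mk("G3", 2, 2))
  res <- call_secondary(scores, threshold = 1.4, min_hits = 2)
  expect_equal(res$hits_HEK293A[res$gene_id == "G1"], 3)
  expect_true(res$passes[res$gene_id == "G1"])    # {3, 0} passes at 2
  expect_false(res$passes[res$gene_id == "G2"])   # {0, 0} fails
  expect_true(res$passes[res$gene_id == "G3"])
  # stricter literal reading: {2, 2} fails at min_hits = 3
  res3 <- call_secondary(scores, threshold = 1.4, min_hits = 3)
  expect_false(res3$passes[res3$gene_id == "G3"])
  expect_true(res3$passes[res3$gene_id == "G1"])

  # per-cell-line thresholds and missing-cell-line handling
  res_named <- call_secondary(scores,
                              threshold = c(HEK293A = 1.4, HT1080 = 0.5),
                              min_hits = 2)
  expect_equal(res_named$hits_HT1080[res_named$gene_id == "G3"], 0)
  one_line <- mk("G9", 2, 0)
  one_line <- one_line[one_line$cell_line == "HEK293A", ]
  expect_warning(res9 <- call_secondary(rbind(scores, one_line),
                                        threshold = 1.4),
                 "absent")
  expect_equal(res9$hits_HT1080[res9$gene_id == "G9"], 0)
  # missing measurements count as non-hits
  na_scores <- mk("G1", 4, 4)
  na_scores$score[c(1, 3)] <- NA
  resna <- call_secondary(na_scores, threshold = 1.4)
  expect_equal(resna$hits_HEK293A + resna$hits_HT1080, 8 - 2)
})

test_that("ddct_fold_change implements efficiency-2 delta-delta-Ct", {
  mk_ct <- function(dct_untreated, dct_treated, ref = 22) {
    data.frame(gene_id = "G", treated = c(FALSE, TRUE),
               replicate = 1L,
               ct_target = ref + c(dct_untreated, dct_treated),
               ct_reference = ref)
  }
  # identical delta-Ct across conditions: fold 1
  expect_equal(ddct_fold_change(mk_ct(3, 3))$fold_induction, 1)
  # dCt(+) = 4, dCt(-) = 6: ddCt = -2, fold 4
  r <- ddct_fold_change(mk_ct(6, 4))
  expect_equal(r$ddct, -2)
  expect_equal(r$fold_induction, 4)
  # matches the independent hand oracle on generated data
  ct <- generate_ct_table("X", attenuation = 0.5, base_induction = 4,
                          noise_sd = 0, seed = 3)
  x <- ct[ct$gene_id == "X", ]
  expect_equal(ddct_fold_change(x)$fold_induction, 2.0)
  expect_equal(ddct_fold_change(x)$fold_induction, hand_ddct(x))

  # shifting every Ct by a constant leaves the fold unchanged
  shifted <- x
  shifted$ct_target <- shifted$ct_target + 1.7
  shifted$ct_reference <- shifted$ct_reference + 1.7
  expect_equal(ddct_fold_change(shifted)$fold_induction,
               ddct_fold_change(x)$fold_induction)

  bad <- mk_ct(3, 3); bad$ct_reference[1] <- NA
  expect_error(ddct_fold_change(bad), "reference")
  expect_error(ddct_fold_change(mk_ct(3, 3)[1, ]), "treated")
})

test_that("call_tertiary passes only attenuated bounce-back", {
  expect_false(call_tertiary(4, 4)$passes)              # ratio 1
  expect_true(call_tertiary(4, 1.2)$passes)             # ratio 0.3
  expect_equal(call_tertiary(4, 1.2)$attenuation_ratio, 0.3)
  expect_false(call_tertiary(2, 2, tertiary_max_ratio = 0.99)$passes)
  expect_error(call_tertiary(0, 1))
})

test_that("assemble_hit_table enforces the funnel order and monotonicity", {
  primary <- call_primary(data.frame(
    gene_id = c("H1", "H2", "M1"), b_score = c(-5, -4, -1)))
  secondary <- data.frame(gene_id = c("H1", "H2"),
                          hits_HEK293A = c(4L, 1L), hits_HT1080 = c(3L, 0L),
                          max_hits = c(4L, 1L), passes = c(TRUE, FALSE))
  tertiary <- cbind(gene_id = "H1", call_tertiary(4, 1))

  tab <- assemble_hit_table(primary, secondary, tertiary)
  expect_s3_class(tab, "hit_table")
  expect_equal(attr(tab, "final_hits"), "H1")
  expect_false(tab$final_hit[tab$gene_id == "H2"])  # failed deconvolution
  expect_false(tab$final_hit[tab$gene_id == "M1"])
  # funnel monotonicity
  final <- tab$gene_id[tab$final_hit]
  sec_pass <- secondary$gene_id[secondary$passes]
  expect_true(all(final %in% sec_pass))
  expect_true(all(sec_pass %in% primary$gene_id[primary$is_hit]))

  # stage-order violations
  expect_error(assemble_hit_table(primary,
    data.frame(gene_id = "M1", passes = TRUE)), "stage-order")
  expect_error(assemble_hit_table(primary, secondary,
    cbind(gene_id = "H2", call_tertiary(4, 1))), "stage-order")
})

test_that("the funnel recovers planted hits and rejects decoys", {
  # 6 true hits (4 active siRNAs, attenuated bounce-back) vs 6 decoys
  # (pooled effect only: 1 active siRNA, full bounce-back)
  set.seed(40)
  genes <- c(paste0("HIT", 1:6), paste0("DEC", 1:6))
  primary <- call_primary(data.frame(gene_id = genes,
                                     b_score = rnorm(12, -5, 0.3)))
  sec <- generate_secondary_scores(genes, n_active = rep(c(4L, 1L), each = 6),
                                   noise_sd = 0.1, seed = 41)
  secondary <- call_secondary(sec, threshold = 1.4, min_hits = 2)
  ct <- generate_ct_table(genes, attenuation = rep(c(0.2, 1), each = 6),
                          base_induction = 4, noise_sd = 0.05, seed = 42)
  fold_ntc <- ddct_fold_change(ct[ct$gene_id == "NTC", ])$fold_induction
  passed <- secondary$gene_id[secondary$passes]
  tertiary <- do.call(rbind, lapply(passed, function(g)
    cbind(gene_id = g,
          call_tertiary(fold_ntc,
                        ddct_fold_change(ct[ct$gene_id == g, ])$fold_induction))))
  tab <- assemble_hit_table(primary, secondary, tertiary)
  expect_setequal(attr(tab, "final_hits"), paste0("HIT", 1:6))
})
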