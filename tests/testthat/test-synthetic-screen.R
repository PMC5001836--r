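test_that("generate_field handles empty and single-cell cases", {
  f0 <- generate_field(n_cells = 0, seed = 1)
  expect_equal(nrow(f0$truth), 0)
  expect_true(all(f0$nuclear == 200) && all(f0$reporter == 200))

  f1 <- generate_field(n_cells = 1, ratio_mean = 2.0, ratio_sd = 0, seed = 5)
  expect_equal(f1$truth$true_ratio, 2.0)
  # ratio measured with ground-truth masks, independent of the ROI code
  r <- truth_mask_ratio(f1, f1$truth[1, ])
  expect_equal(r, 2.0, tolerance = 1e-9)
})

test_that("generate_field draws per-cell ratios around ratio_mean", {
  f <- generate_field(n_cells = 50, ratio_mean = 2.0, ratio_sd = 0.3,
                      image_size = 512, seed = 11)
  expect_equal(nrow(f$truth), 50)
  se <- 0.3 / sqrt(50)
  expect_lt(abs(mean(f$truth$true_ratio) - 2.0), 3 * se)
  expect_true(all(f$truth$true_ratio > 0))
  # no overlap guarantee in default generation mode
  d <- as.matrix(dist(f$truth[, c("cx", "cy")]))
  diag(d) <- Inf
  expect_true(all(d > 2 * f$truth$cyto_radius_px[1]))
})

test_that("generate_field is bit-reproducible and errors on overcrowding", {
  a <- generate_field(n_cells = 12, seed = 99)
  b <- generate_field(n_cells = 12, seed = 99)
  expect_identical(a, b)
  expect_error(generate_field(n_cells = 200, image_size = 128, seed = 1),
               "density")
  expect_error(generate_field(n_cells = 1, image_size = 20, seed = 1),
               "too small")
})

test_that("PGM image round-trip is lossless for integer channels", {
  f <- generate_field(n_cells = 3, ratio_sd = 0, seed = 2, image_size = 128)
  path <- withr::local_tempfile(fileext = ".pgm")
  write_image_pgm(f$nuclear, path)
  expect_equal(read_image_pgm(path), round(f$nuclear))
})

test_that("plate scores decompose exactly into ground-truth components", {
  # noiseless flat plate: all sample wells at baseline
  d0 <- screen_design(noise_sd = 0, neg_control_sd = 0, pos_control_sd = 0,
                      positional_gradient = c(0, 0), seed = 3)
  p0 <- generate_plate_scores(d0, 0)
  expect_equal(unique(p0$map$raw[p0$map$class == "sample"]), 2.0)
  expect_equal(unique(p0$map$raw[p0$map$class == "positive_control"]), 0.8)

  # constructed row gradient: strictly increasing down rows by 0.05
  d1 <- screen_design(noise_sd = 0, neg_control_sd = 0, pos_control_sd = 0,
                      positional_gradient = c(0.05, 0), seed = 3)
  m1 <- generate_plate_scores(d1, 0)$scores
  expect_equal(diff(m1[, 1]), rep(0.05, 15))
  expect_equal(m1[1, 2] - m1[1, 1], 0)

  # decomposability at any noise level: raw = sum of emitted components
  d2 <- screen_design(noise_sd = 0.1,
                      planted_hits = data.frame(gene_id = "GENE01_100",
                                                shift = -1.0),
                      seed = 17)
  map <- generate_plate_scores(d2, 0)$map
  expect_equal(map$raw,
               map$baseline + map$gradient + map$hit_shift +
                 map$control_shift + map$noise)
  expect_equal(map$hit_shift[map$gene_id == "GENE01_100"], -1.0)
})

test_that("a planted hit sits below the sample median by about its shift", {
  d <- screen_design(noise_sd = 0.1, positional_gradient = c(0, 0),
                     planted_hits = data.frame(gene_id = "GENE01_050",
                                               shift = -1.0),
                     seed = 23)
  map <- generate_plate_scores(d, 0)$map
  samples <- map[map$class == "sample", ]
  hit <- samples$raw[samples$gene_id == "GENE01_050"]
  # oracle: regenerate and subtract known components
  expect_equal(hit - samples$noise[samples$gene_id == "GENE01_050"],
               median(samples$raw) - 1.0, tolerance = 0.05)
  expect_lt(hit, median(samples$raw) - 0.5)
})

test_that("screen design validates control layout and planted hits", {
  expect_error(screen_design(seed = 1, n_control_wells = 20),
               "n_control_wells")
  expect_error(screen_design(
    seed = 1,
    planted_hits = data.frame(gene_id = "NOT_A_GENE", shift = -1)),
    "unknown gene ids")
  expect_error(screen_design(n_plates = 1), "seed")
  m <- plate_map(screen_design(seed = 1), 0)
  expect_setequal(unique(m$class),
                  c("sample", "negative_control", "positive_control"))
  expect_equal(sum(m$class == "negative_control"), 12)
  expect_equal(sum(m$class == "positive_control"), 12)
  expect_false(any(duplicated(m$gene_id[m$class == "sample"])))
})

test_that("plate generation is bit-reproducible and plates independent", {
  d <- screen_design(n_plates = 3, seed = 7)
  expect_identical(generate_plate_scores(d, 1), generate_plate_scores(d, 1))
  # regenerating plate 2 alone matches its slice of the full screen
  all_scores <- generate_screen_scores(d)
  expect_identical(all_scores[all_scores$plate == 3, ]$raw,
                   generate_plate_scores(d, 2)$map$raw)
})

test_that("generate_ct_table encodes fold inductions recoverable by hand", {
  # attenuation 1, no noise: hand delta-delta-Ct gives base induction exactly
  ct <- generate_ct_table("G1", attenuation = 1, base_induction = 4,
                          noise_sd = 0, seed = 1)
  expect_equal(hand_ddct(ct[ct$gene_id == "G1", ]), 4.0)
  # attenuation 0.5, base 4: fold 2.0 by hand arithmetic
  ct2 <- generate_ct_table("G1", attenuation = 0.5, base_induction = 4,
                           noise_sd = 0, seed = 1)
  expect_equal(hand_ddct(ct2[ct2$gene_id == "G1", ]), 2.0)
  # the non-targeting control always carries the full induction
  expect_equal(hand_ddct(ct2[ct2$gene_id == "NTC", ]), 4.0)
  # determinism with replicates and noise
  a <- generate_ct_table(c("A", "B"), attenuation = c(0.2, 1),
                         noise_sd = 0.1, seed = 12)
  b <- generate_ct_table(c("A", "B"), attenuation = c(0.2, 1),
                         noise_sd = 0.1, seed = 12)
  expect_identical(a, b)
  expect_equal(nrow(a), 3 * 2 * 3)  # 3 genes x 2 conditions x 3 replicates
})

test_that("generate_secondary_scores marks exactly n_active siRNAs active", {
  s <- generate_secondary_scores(c("G1", "G2"), n_active = c(4, 1),
                                 noise_sd = 0, seed = 5)
  counts <- tapply(s$active, list(s$gene_id, s$cell_line), sum)
  expect_true(all(counts["G1", ] == 4))
  expect_true(all(counts["G2", ] == 1))
  expect_equal(unique(s$score[s$active]), 0.8)
  expect_equal(unique(s$score[!s$active]), 2.0)
})
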