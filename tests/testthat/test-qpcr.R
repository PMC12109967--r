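# Ct quantitation: replicate collapse, ddCt fold change, CV utilities.

test_that("technical replicates collapse to mean Ct over amplified wells", {
  tbl <- data.frame(
    sample_id = "s1", condition = "T",
    gene = rep(c("CD36", "HMOX1", "LBR"), each = 2),
    replicate = rep(1:2, 3),
    ct = c(24.0, 24.2,   # both amplified -> mean
           41.0, NA,     # both beyond cutoff / missing -> not amplified
           39.9, 41.2))  # one surviving replicate
  out <- collapse_replicates(tbl)
  get <- function(g) out[out$gene == g, ]
  expect_equal(get("CD36")$ct_mean, 24.1)
  expect_true(get("CD36")$amplified)
  expect_false(get("HMOX1")$amplified)
  expect_true(is.na(get("HMOX1")$ct_mean))
  expect_equal(get("LBR")$ct_mean, 39.9)
  expect_true(get("LBR")$amplified)
})

test_that("fold_change implements 2^-ddCt", {
  expect_equal(fold_change(24, 20, 24, 20), 1.0)
  expect_equal(fold_change(24, 20, 25, 20), 2.0)
  # closed form, independently recomputed on the natural-log scale
  ddct <- (26.5 - 20.0) - (25.0 - 20.0)
  expect_equal(fold_change(26.5, 20.0, 25.0, 20.0), exp(-log(2) * ddct))
  expect_equal(fold_change(26.5, 20.0, 25.0, 20.0), 0.35355339, tolerance = 1e-7)
})

test_that("fold_change is shift-invariant and monotone in treated Ct", {
  set.seed(42)
  for (i in 1:25) {
    cts <- runif(4, 15, 35)
    shift <- runif(1, -5, 5)
    expect_equal(fold_change(cts[1], cts[2], cts[3], cts[4]),
                 fold_change(cts[1] + shift, cts[2] + shift,
                             cts[3] + shift, cts[4] + shift))
  }
  r <- fold_change(seq(20, 30, by = 0.5), 20, 25, 20)
  expect_true(all(diff(r) < 0))
  expect_true(all(r > 0))
})

test_that("profiles from zero-noise simulation reproduce effect sizes", {
  cfg <- sim_config(n_activators = 2, n_nonactivators = 2,
                    effect_size_activator = 1.5,
                    effect_size_nonactivator = 1.0,
                    ratio_cv = 0, dropout_prob = 0, seed = 3)
  co <- simulate_cohort(cfg)
  prof <- build_profiles(co$ct_table)$profiles
  act <- co$truth$sample_id[co$truth$status == "Activator"]
  expect_equal(prof$ratio[prof$sample_id %in% act],
               rep(1.5, 14))
  expect_equal(prof$ratio[!prof$sample_id %in% act],
               rep(1.0, 14))
  expect_true(all(prof$evaluable))
})

test_that("a dropped-out gene is non-evaluable and lowers the Nrf2 count", {
  base <- expand.grid(gene = assay_panel(), condition = c("T", "NT"),
                      stringsAsFactors = FALSE)
  base$ct <- 24
  base$ct[base$gene == "GAPDH"] <- 20
  base$ct[base$gene == "HMOX1" & base$condition == "T"] <- 42  # dropout
  prof <- build_profiles(make_ct("s1", base))
  expect_false(prof$profiles$evaluable[prof$profiles$gene == "HMOX1"])
  expect_true(is.na(prof$profiles$ratio[prof$profiles$gene == "HMOX1"]))
  expect_equal(prof$n_evaluable_nrf2$n_evaluable_nrf2, 5L)
})

test_that("a sample without GAPDH in one condition is invalid", {
  base <- expand.grid(gene = assay_panel(), condition = c("T", "NT"),
                      stringsAsFactors = FALSE)
  base$ct <- 24
  base$ct[base$gene == "GAPDH" & base$condition == "NT"] <- NA
  prof <- build_profiles(make_ct("s1", base))
  expect_equal(nrow(prof$profiles), 0L)
  expect_equal(prof$invalid$sample_id, "s1")
  expect_match(prof$invalid$reason, "GAPDH")

  # missing condition entirely
  only_t <- base[base$condition == "T", ]
  only_t$ct <- 24
  prof2 <- build_profiles(make_ct("s2", only_t))
  expect_match(prof2$invalid$reason, "missing condition")
})

test_that("empty Ct table yields empty profiles with a warning", {
  empty <- data.frame(sample_id = character(), condition = character(),
                      gene = character(), replicate = integer(),
                      ct = numeric())
  expect_warning(out <- build_profiles(empty), "empty")
  expect_equal(nrow(out$profiles), 0L)
})

test_that("coefficient_of_variation is SD/mean with input validation", {
  expect_equal(coefficient_of_variation(c(1, 1, 1)), 0)
  expect_equal(coefficient_of_variation(c(0.9, 1.1)), sd(c(0.9, 1.1)))
  expect_equal(coefficient_of_variation(c(0.9, 1.1)), 0.14142136,
               tolerance = 1e-7)
  expect_error(coefficient_of_variation(1.0), "at least 2")
  expect_error(coefficient_of_variation(c(-1, 1)), "zero")
})

test_that("a 94-repeat calibration series recovers the configured CV", {
  cfg <- sim_config(n_activators = 94, n_nonactivators = 0,
                    ratio_cv = 0.06, dropout_prob = 0, seed = 3)
  prof <- build_profiles(simulate_cohort(cfg)$ct_table)$profiles
  cv <- coefficient_of_variation(prof$ratio[prof$gene == "CD36"])
  expect_lt(abs(cv - 0.06) / 0.06, 0.20)
})

test_that("cv_band is symmetric about 1 and validates its input", {
  expect_equal(unname(cv_band(0.06)), c(0.94, 1.06))
  expect_equal(unname(cv_band(0.10)), c(0.90, 1.10))
  for (cv in c(0.01, 0.06, 0.3, 0.9)) {
    b <- cv_band(cv)
    expect_equal(1 - b[["lower"]], b[["upper"]] - 1)
  }
  b <- cv_band(1e-9)
  expect_equal(unname(b), c(1, 1), tolerance = 1e-8)
  expect_error(cv_band(0))
  expect_error(cv_band(1))
  expect_error(cv_band(-0.1))
})

test_that("gene spelling variants are normalized on ingest", {
  expect_equal(normalize_gene(c("FBX030", "hmox-1", "gabara", "gapdh")),
               c("FBXO30", "HMOX1", "GABARA", "GAPDH"))
  tbl <- data.frame(sample_id = "s", condition = "t", gene = "fbx030",
                    replicate = 1, ct = 24)
  expect_equal(collapse_replicates(tbl)$gene, "FBXO30")
})
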