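# Activation-status decision algorithm.

test_that("the CD36 gate and Nrf2 majority rule fire as specified", {
  band <- cv_band(0.06)
  call1 <- classify_activation(make_profile("d1", 0.90, rep(1.5, 6)), band)
  expect_equal(call1$status, "NonActivator")
  expect_equal(call1$rule, "cd36_below_band")

  call2 <- classify_activation(
    make_profile("d2", 1.20, c(1.10, 1.08, 1.12, 0.90, 1.00, 1.02)), band)
  expect_equal(call2$status, "Activator")    # 3/6 hits meets >= 50%
  expect_equal(call2$nrf2_hits, 3L)

  call3 <- classify_activation(
    make_profile("d3", 1.20, c(1.10, 1.08, 0.90, 1.00, 1.02, 0.95)), band)
  expect_equal(call3$status, "NonActivator") # 2/6 hits

  call4 <- classify_activation(make_profile("d4", 1.00, rep(1.5, 6)), band)
  expect_equal(call4$status, "Uncertain")
  expect_equal(call4$rule, "cd36_within_band")
})

test_that("missing genes shrink the denominator; boundaries are strict", {
  band <- cv_band(0.06)
  # 4 evaluable Nrf2 genes, 2 hits -> exactly 50% -> Activator
  call <- classify_activation(
    make_profile("d1", 1.20, c(1.10, 1.10, 1.00, 1.00, NA, NA),
                 nrf2_evaluable = c(rep(TRUE, 4), FALSE, FALSE)), band)
  expect_equal(call$status, "Activator")
  expect_equal(call$n_evaluable_nrf2, 4L)

  # band edges resolve to Uncertain for CD36, to non-hit for Nrf2
  expect_equal(classify_activation(
    make_profile("e1", 0.94, rep(1.5, 6)), band)$status, "Uncertain")
  expect_equal(classify_activation(
    make_profile("e2", 1.06, rep(1.5, 6)), band)$status, "Uncertain")
  exact_upper <- classify_activation(
    make_profile("e3", 1.20, c(1.06, 1.06, 1.06, 1.06, 1.06, 1.06)), band)
  expect_equal(exact_upper$nrf2_hits, 0L)
  expect_equal(exact_upper$status, "NonActivator")
})

test_that("degenerate profiles are refused or deferred with a reason", {
  band <- cv_band(0.06)
  refused <- classify_activation(
    make_profile("d1", NA, rep(1.5, 6), cd36_evaluable = FALSE), band)
  expect_true(is.na(refused$status))
  expect_equal(refused$rule, "refused_cd36_not_evaluable")

  no_nrf2 <- classify_activation(
    make_profile("d2", 1.20, rep(NA_real_, 6),
                 nrf2_evaluable = rep(FALSE, 6)), band)
  expect_equal(no_nrf2$status, "Uncertain")
  expect_equal(no_nrf2$rule, "no_evaluable_nrf2")

  expect_error(classify_activation(make_profile("d3", 1.2, rep(1.5, 6)),
                                   c(1.1, 1.2)), "lower < 1 < upper")
})

test_that("classification is invariant to gene and sample ordering", {
  set.seed(7)
  prof <- do.call(rbind, lapply(1:40, function(i)
    make_profile(sprintf("s%02d", i), runif(1, 0.5, 2),
                 runif(6, 0.5, 2))))
  ref <- classify_activation(prof)
  shuffled <- prof[sample(nrow(prof)), ]
  out <- classify_activation(shuffled)
  out <- out[match(ref$sample_id, out$sample_id), ]
  expect_equal(ref$status, out$status)
  expect_equal(ref$nrf2_hits, out$nrf2_hits)
})

test_that("widening the band never creates new Activators", {
  set.seed(11)
  prof <- do.call(rbind, lapply(1:200, function(i)
    make_profile(sprintf("s%03d", i), runif(1, 0.7, 1.4),
                 runif(6, 0.7, 1.4))))
  narrow <- classify_activation(prof, cv_band(0.03))
  wide <- classify_activation(prof, cv_band(0.12))
  newly_active <- wide$status == "Activator" & narrow$status != "Activator"
  expect_equal(sum(newly_active), 0)
})

test_that("classify agrees with the brute-force rule restatement", {
  set.seed(19)
  cases <- lapply(1:400, function(i) {
    n_eval <- sample(0:6, 1)
    list(cd36 = round(runif(1, 0.5, 2), 3),
         nrf2 = round(runif(n_eval, 0.5, 2), 3))
  })
  prof <- do.call(rbind, lapply(seq_along(cases), function(i) {
    x <- cases[[i]]
    nrf2_all <- c(x$nrf2, rep(NA_real_, 6 - length(x$nrf2)))
    make_profile(sprintf("s%03d", i), x$cd36, nrf2_all,
                 nrf2_evaluable = !is.na(nrf2_all))
  }))
  got <- classify_activation(prof, cv_band(0.06))$status
  want <- vapply(cases, function(x) oracle_classify(x$cd36, x$nrf2),
                 character(1))
  expect_equal(got, want)
})

test_that("replicate consensus follows majority of decisive calls", {
  expect_equal(consensus_call(c("Activator", "Activator", "Activator")),
               "Activator")
  expect_equal(consensus_call(c("Uncertain", "Activator", "Activator")),
               "Activator")
  expect_equal(consensus_call(c("Activator", "NonActivator")), "Uncertain")
  expect_equal(consensus_call(c("Uncertain", "Uncertain")), "Uncertain")
  expect_equal(consensus_call("NonActivator"), "NonActivator")
  expect_error(consensus_call(character(0)), "at least one")
  expect_error(consensus_call("Positive"), "unknown status")
})

test_that("repeat assays of the same zero-noise donor give identical calls", {
  cfg <- sim_config(ratio_cv = 0, dropout_prob = 0)
  day0 <- simulate_donor("Activator", cfg, seed = 4, sample_id = "d")
  day7 <- simulate_donor("Activator", cfg, seed = 44, sample_id = "d")
  call0 <- classify_activation(build_profiles(day0)$profiles)
  call7 <- classify_activation(build_profiles(day7)$profiles)
  expect_equal(call0$status, call7$status)
  expect_equal(consensus_call(c(call0$status, call7$status)), call0$status)
})
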