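test_that("MTT normalization follows the percent-of-control form", {
  # treated blank-corrected 0.25 against control mean 0.50 -> 50 %
  plate <- make_mtt_plate(control = c(0.50, 0.55, 0.45),
                          treated = data.frame(conc_um = 5, signal = 0.25))
  out <- mtt_percent_viability(plate)
  expect_equal(out$response, 50, tolerance = 1e-12)
  expect_false("DMSO" %in% out$compound)

  # treated equal to the control mean -> 100 %; dead well -> 0 %
  plate2 <- make_mtt_plate(treated = data.frame(conc_um = c(1, 50),
                                                signal = c(0.50, 0)))
  out2 <- mtt_percent_viability(plate2)
  expect_equal(out2$response[out2$conc_um == 1], 100, tolerance = 1e-12)
  expect_equal(out2$response[out2$conc_um == 50], 0, tolerance = 1e-12)

  # the 650 nm reference is subtracted per well before normalization
  plate3 <- make_mtt_plate(blank = 0.05)
  expect_equal(mtt_percent_viability(plate3)$response, 50, tolerance = 1e-12)
})

test_that("MTT normalization errors are classified", {
  plate <- make_mtt_plate()
  no_ctrl <- plate[plate$treatment != "DMSO", ]
  expect_error(mtt_percent_viability(no_ctrl),
               class = "pcbtox_validation_error")
  neg <- plate
  neg$signal[neg$treatment == "DMSO"] <- -0.2
  expect_error(mtt_percent_viability(neg),
               class = "pcbtox_data_quality_error")
})

test_that("technical replicates are averaged within biological replicate", {
  p1 <- make_mtt_plate(treated = data.frame(conc_um = c(5, 5, 5),
                                            signal = c(0.2, 0.3, 0.4)),
                       plate_id = "b1", bio_rep = 1)
  p2 <- make_mtt_plate(treated = data.frame(conc_um = c(5, 5, 5),
                                            signal = c(0.1, 0.1, 0.1)),
                       plate_id = "b2", bio_rep = 2)
  out <- mtt_percent_viability(rbind(p1, p2))
  expect_equal(nrow(out), 2)  # one row per biological replicate
  expect_equal(out$response[out$bio_rep == 1], 100 * 0.3 / 0.5,
               tolerance = 1e-12)
  expect_equal(out$n_tech, c(3, 3))
})

test_that("normalization is invariant to scaling all signals on a plate", {
  set.seed(7)
  treated <- data.frame(conc_um = rep(c(0.5, 1, 5, 10, 20, 50), each = 2),
                        signal = runif(12, 0.05, 0.6))
  plate <- make_mtt_plate(control = runif(3, 0.4, 0.6), treated = treated)
  scaled <- plate
  scaled$signal <- scaled$signal * 3.7
  scaled$signal_ref <- scaled$signal_ref * 3.7
  expect_equal(mtt_percent_viability(scaled)$response,
               mtt_percent_viability(plate)$response, tolerance = 1e-12)
})

test_that("LDH cytotoxicity uses the low/high-control scaling", {
  mk <- function(signals, conc = c(5, 10, 20)) {
    data.frame(plate_id = "L1", assay = "LDH", row = "A",
               col = seq_len(6 + length(signals)),
               treatment = c(rep("low_control", 3), rep("high_control", 3),
                             rep("cmpA", length(signals))),
               conc_um = c(rep(0, 6), conc),
               bio_rep = 1, tech_rep = c(1:3, 1:3, seq_along(signals)),
               signal = c(rep(0.1, 3), rep(1.1, 3), signals),
               stringsAsFactors = FALSE)
  }
  out <- ldh_percent_cytotoxicity(mk(c(0.1, 1.1, 0.6)))
  expect_equal(sort(out$response), c(0, 50, 100), tolerance = 1e-12)

  bad <- mk(c(0.5, 0.6, 0.7))
  bad$signal[bad$treatment == "high_control"] <- 0.05  # high <= low
  expect_error(ldh_percent_cytotoxicity(bad),
               class = "pcbtox_data_quality_error")
  # scaling invariance holds for the LDH form too
  p <- mk(c(0.3, 0.6, 0.9))
  ps <- p; ps$signal <- ps$signal * 2.5
  expect_equal(ldh_percent_cytotoxicity(ps)$response,
               ldh_percent_cytotoxicity(p)$response, tolerance = 1e-12)
})

test_that("fit_four_pl recovers noiseless 4PL parameters", {
  dat <- make_4pl_dataset(top = 100, bottom = 0, hill = -1, ic50 = 10)
  fit <- fit_four_pl(dat)
  expect_true(fit$converged)
  expect_false(fit$censored)
  expect_equal(fit$ic50, 10, tolerance = 1e-6)
  expect_equal(fit$top, 100, tolerance = 1e-6)
  expect_equal(fit$bottom, 0, tolerance = 1e-4)
  expect_equal(fit$hill, -1, tolerance = 1e-6)

  # steeper curve with a non-zero floor
  dat2 <- make_4pl_dataset(top = 95, bottom = 12, hill = -2.2, ic50 = 4.7)
  fit2 <- fit_four_pl(dat2)
  expect_equal(fit2$ic50, 4.7, tolerance = 1e-5)
  expect_equal(fit2$bottom, 12, tolerance = 1e-4)
})

test_that("flat and insufficient data are handled without exceptions", {
  flat <- make_4pl_dataset(top = 100, bottom = 100, hill = -1, ic50 = 10)
  fit <- fit_four_pl(flat)
  expect_true(fit$censored)

  short <- data.frame(conc_um = c(1, 5, 10), response = c(90, 60, 30))
  expect_error(fit_four_pl(short), class = "pcbtox_validation_error")
})

test_that("the fitted midpoint agrees with an exhaustive grid-search oracle", {
  set.seed(33)
  for (true_ic50 in c(3, 12)) {
    dat <- make_4pl_dataset(ic50 = true_ic50)
    dat$response <- dat$response * rlnorm(nrow(dat), 0, 0.1)
    fit <- fit_four_pl(dat)
    oracle <- oracle_grid_4pl(dat$conc_um, dat$response)
    expect_lt(abs(fit$log10_ic50 - oracle$log10_ic50), 0.1)
  }
})

test_that("report_ic50 applies the range-censoring convention", {
  dat <- make_4pl_dataset(ic50 = 8.8)
  fit <- fit_four_pl(dat)
  rep <- report_ic50(fit, max_tested = 50)
  expect_identical(rep$cmp, "=")
  expect_identical(rep$display, "8.8")
  expect_equal(rep$value, 8.8, tolerance = 1e-5)

  # midpoint beyond the tested range: ">50"
  far <- fit_four_pl(make_4pl_dataset(ic50 = 72,
                                      conc = c(0.5, 1, 5, 10, 20, 50)),
                     max_tested = 50)
  rep2 <- report_ic50(far, max_tested = 50)
  expect_identical(rep2$cmp, ">")
  expect_identical(rep2$display, ">50")

  # censoring holds in noiseless simulation whenever truth > max tested
  for (true_ic50 in c(120, 200, 1000)) {
    f <- fit_four_pl(make_4pl_dataset(ic50 = true_ic50), max_tested = 50)
    expect_identical(report_ic50(f, 50)$cmp, ">")
  }

  # a non-converged fit reports the bound and is flagged approximate
  flat <- fit_four_pl(make_4pl_dataset(top = 100, bottom = 100, ic50 = 10))
  rep3 <- report_ic50(flat, max_tested = 50)
  expect_identical(rep3$cmp, ">")
})

test_that("exact rank-sum enumeration matches known and oracle p-values", {
  # identical samples: no evidence, p = 1
  expect_equal(exact_rank_sum(c(5, 5, 5), c(5, 5, 5))$p.value, 1)
  # fully separated n = 3 vs 3: 2 of the 20 assignments are as extreme
  expect_equal(exact_rank_sum(c(1, 2, 3), c(10, 11, 12))$p.value, 0.1,
               tolerance = 1e-12)
  expect_equal(exact_rank_sum(c(10, 11, 12), c(1, 2, 3))$p.value, 0.1,
               tolerance = 1e-12)
  # cross-check against the reference exact distribution on tie-free data
  set.seed(99)
  for (i in 1:25) {
    nx <- sample(3:6, 1); ny <- sample(3:6, 1)
    x <- rnorm(nx); y <- rnorm(ny, mean = runif(1, -1, 1))
    mine <- exact_rank_sum(x, y)$p.value
    ref <- suppressWarnings(stats::wilcox.test(x, y, exact = TRUE))$p.value
    expect_equal(mine, ref, tolerance = 1e-12)
  }
})

test_that("compare_groups adjusts across the concentration grid", {
  conc <- c(0.5, 1, 5, 10, 20, 50)
  mk <- function(values) {
    df <- expand.grid(conc_um = conc, bio_rep = 1:3)
    df$response <- values
    df
  }
  # identical groups: adjusted p = 1 everywhere, verdict negative
  a <- mk(rep(80, 18))
  res <- compare_groups(a, a, alpha = 0.05)
  expect_true(all(res$p_adj == 1))
  expect_false(any(res$significant))
  expect_match(attr(res, "verdict"), "no significant")
  expect_true(all(res$p_adj >= res$p_raw))

  # one fully separated concentration: raw p = 0.1, Holm keeps it
  # non-significant across the 6-point grid
  set.seed(5)
  b <- a
  b$response[b$conc_um == 10] <- c(120, 121, 122)
  res2 <- compare_groups(a, b, alpha = 0.05)
  expect_equal(res2$p_raw[res2$conc_um == 10], 0.1, tolerance = 1e-12)
  expect_false(any(res2$significant))

  # mismatched grids are rejected
  c_short <- a[a$conc_um != 50, ]
  expect_error(compare_groups(a, c_short), class = "pcbtox_validation_error")
})
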