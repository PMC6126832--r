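test_that("risk-adjusted output matches hand arithmetic and flags zero expectations", {
  p <- hospital_panel(tiny_panel_df())
  rates <- c("2006" = 0.148, "2008" = 0.148)
  out <- build_risk_adjusted_output(p, wave_rates = rates)
  # hospital exactly at the wave-average risk level sits at y = 0
  p0 <- p
  p0$exp_mortality[1] <- 0.148
  out0 <- build_risk_adjusted_output(p0, wave_rates = rates)
  expect_equal(out0$y[1], 0)
  # expected deaths 2.0 against a 14.8% wave rate
  expect_equal(exp(out$y[1]), 13.5135, tolerance = 1e-4)
  expect_equal(out$y[1], 2.6037, tolerance = 1e-4)
  # all-equal expectations within a wave give zero output variance
  pc <- p
  pc$exp_mortality <- ifelse(pc$year == 2006, 1.7, pc$exp_mortality)
  outc <- build_risk_adjusted_output(pc, wave_rates = rates)
  expect_equal(var(outc$y[outc$year == 2006]), 0)
  # zero expected deaths: flagged, excluded, warned about
  pz <- p
  pz$exp_mortality[2] <- 0
  expect_warning(outz <- build_risk_adjusted_output(pz, wave_rates = rates),
                 "excluded")
  expect_true(outz$frontier_excluded[2])
  expect_true(is.na(outz$y[2]))
  # missing wave rate names the wave
  expect_error(build_risk_adjusted_output(p, wave_rates = c("2006" = 0.15)),
               "2008")
})

test_that("risk-adjusted output is scale-equivariant within waves", {
  p <- hospital_panel(tiny_panel_df())
  rates <- c("2006" = 0.16, "2008" = 0.14)
  base <- build_risk_adjusted_output(p, wave_rates = rates)
  p2 <- p
  cc <- 3.7
  p2$exp_mortality[p2$year == 2008] <- p2$exp_mortality[p2$year == 2008] * cc
  out <- build_risk_adjusted_output(p2, wave_rates = rates)
  i <- p$year == 2008
  expect_equal(out$y[i] - base$y[i], rep(log(cc), sum(i)))
  expect_equal(out$y[!i], base$y[!i])
})

test_that("wave rates can come from volumes, unweighted or volume-weighted", {
  p <- hospital_panel(tiny_panel_df())
  p$qsr_volume <- c(40, 30, 60, 50, 20, 25)
  out <- build_risk_adjusted_output(p, volume = "qsr_volume")
  r2006 <- mean((p$obs_mortality / p$qsr_volume)[p$year == 2006])
  expect_equal(unname(attr(out, "wave_rates")["2006"]), r2006)
  outw <- build_risk_adjusted_output(p, volume = "qsr_volume", weighted = TRUE)
  r2006w <- sum(p$obs_mortality[p$year == 2006]) /
    sum(p$qsr_volume[p$year == 2006])
  expect_equal(unname(attr(outw, "wave_rates")["2006"]), r2006w)
})

test_that("zero-input encoding implements the dummy and +0.5 devices", {
  p <- hospital_panel(tiny_panel_df())
  enc <- encode_zero_inputs(p, "dummy")
  expect_equal(nrow(enc), nrow(p))
  expect_equal(enc$d_mort, as.numeric(p$obs_mortality == 0))
  expect_equal(sum(enc$d_mort), sum(p$obs_mortality == 0))
  # a zero count becomes (D = 1, x* = 1, log x* = 0)
  i <- which(p$obs_mortality == 0)
  expect_equal(enc$obs_mortality_star[i], rep(1, length(i)))
  expect_equal(enc$log_mort_star[i], rep(0, length(i)))
  # a positive count is passed through
  j <- which(p$obs_mortality == 5)
  expect_equal(enc$d_mort[j], 0)
  expect_equal(enc$obs_mortality_star[j], 5)
  # rescale mode: +0.5 everywhere, dummies switched off
  enc2 <- encode_zero_inputs(p, "rescale_half")
  expect_equal(enc2$obs_mortality_star, p$obs_mortality + 0.5)
  expect_equal(enc2$log_mort_star[i], rep(-log(2), length(i)))
  expect_true(all(enc2$d_mort == 0))
  # negative counts are rejected
  pn <- p
  pn$obs_mortality[1] <- -1
  expect_error(hospital_panel(pn), "non-negative")
  pn2 <- p
  pn2$obs_readmissions[2] <- -3
  expect_error(encode_zero_inputs(pn2), "negative")
})

test_that("centering is exactly invertible and preserves differences", {
  p <- hospital_panel(tiny_panel_df())
  p$v <- c(1, 2, 3, 4, 5, 6)
  cen <- center_variables(p, "v")
  expect_equal(cen$v, p$v - mean(p$v))
  expect_equal(mean(cen$v), 0, tolerance = 1e-12)
  expect_equal(diff(cen$v), diff(p$v))
  back <- uncenter_variables(cen)
  expect_identical(back$v, p$v)   # bitwise round trip
  # constant column becomes all zeros
  p$const_col <- 7
  expect_equal(center_variables(p, "const_col")$const_col, rep(0, 6))
  # binary dummies are allowed but flagged
  expect_warning(center_variables(p, "SUCert"), "binary")
  expect_error(center_variables(p, "nope"), "Unknown")
})

test_that("panel files round-trip and report malformed input with rows", {
  p <- hospital_panel(tiny_panel_df())
  f <- withr::local_tempfile(fileext = ".csv")
  write_panel(p, f)
  p2 <- read_panel(f)
  expect_equal(nrow(p2), nrow(p))
  expect_equal(p2$exp_mortality, p$exp_mortality)
  f2 <- withr::local_tempfile(fileext = ".csv")
  write_panel(p2, f2)
  expect_identical(readLines(f), readLines(f2))
  # duplicate (hospital, year) keys are named
  bad <- tiny_panel_df()
  bad$year[2] <- 2006L
  fb <- withr::local_tempfile(fileext = ".csv")
  utils::write.table(bad, fb, sep = ",", row.names = FALSE, quote = FALSE)
  expect_error(read_panel(fb), "a/2006")
  # unknown district against a graph
  expect_error(hospital_panel(tiny_panel_df(),
                              graph = region_graph("d1", data.frame(
                                from = character(0), to = character(0)))),
               "d2")
  # non-numeric values are located
  txt <- readLines(f)
  txt[2] <- sub("^a,2006,d1,2", "a,2006,d1,oops", txt[2])
  fx <- withr::local_tempfile(fileext = ".csv")
  writeLines(txt, fx)
  expect_error(read_panel(fx), "exp_mortality")
  # header mapping via config
  cfg <- withr::local_tempfile(fileext = ".json")
  jsonlite::write_json(list(rename = list(ExpMor = "exp_mortality")), cfg,
                       auto_unbox = TRUE)
  txt2 <- readLines(f)
  txt2[1] <- sub("exp_mortality", "ExpMor", txt2[1])
  fy <- withr::local_tempfile(fileext = ".csv")
  writeLines(txt2, fy)
  p3 <- read_panel(fy, config = cfg)
  expect_equal(p3$exp_mortality, p$exp_mortality)
})

test_that("prepare_panel centers the output and log inputs", {
  sim <- get_small_sim()
  pp <- prepare_panel(sim$panel)
  for (v in c("y", "log_mort_star", "log_readm_star", "log_phys",
              "log_nurse")) {
    expect_lt(abs(mean(pp[[v]], na.rm = TRUE)), 1e-10)
  }
  offs <- attr(pp, "offsets")
  expect_true(all(c("y", "log_phys") %in% names(offs)))
})
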