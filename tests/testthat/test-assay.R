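well <- function(A6, A12, A14, N12, N14, N17, construct = "c",
                 replicate = 1L) {
  data.frame(construct = construct, replicate = replicate,
             A6 = A6, A12 = A12, A14 = A14, N12 = N12, N14 = N14, N17 = N17,
             stringsAsFactors = FALSE)
}

test_that("production rate chains the three interval rates per well", {
  expect_equal(production_rate(well(4, 4, 4, 4, 4, 4)), 3.0)
  expect_equal(production_rate(well(4, 2, 2, 4, 2, 1)), 2.5)  # 1 + 1 + 0.5
  expect_equal(production_rate(well(4, 4, 2, 8, 2, 3)), 2 + 0.5 + 1.5)
})

test_that("wells with no surviving adults at a count day are excluded", {
  expect_true(is.na(production_rate(well(0, 0, 0, 0, 0, 0))))
  expect_true(is.na(production_rate(well(4, 0, 0, 5, 0, 0))))
  expect_true(is.na(production_rate(well(4, 2, 0, 5, 3, 0))))
  expect_error(production_rate(well(4, 2, 2, -1, 0, 0)), "negative")
  expect_error(production_rate(well(2, 4, 4, 1, 1, 1)), "non-increasing")
})

test_that("production rate is exactly linear in the nymph counts", {
  set.seed(41)
  for (rep in 1:25) {
    a <- sort(sample(1:4, 3))
    w <- well(a[3], a[2], a[1], sample(0:8, 1), sample(0:8, 1),
              sample(0:8, 1))
    k <- sample(2:5, 1)
    w2 <- w
    w2[c("N12", "N14", "N17")] <- k * w[c("N12", "N14", "N17")]
    expect_equal(production_rate(w2), k * production_rate(w))
  }
})

test_that("construct summaries: mean, SE, exclusions, degenerate n = 1", {
  wells <- rbind(well(4, 4, 4, 8, 4, 0), well(4, 4, 4, 4, 4, 4),
                 well(4, 4, 4, 4, 8, 4))
  # rates 3, 3... compute: 8/4+4/4+0 = 3; 1+1+1 = 3; 1+2+1 = 4
  s <- summarize_constructs(wells)
  expect_equal(s$n_wells, 3L)
  r <- c(3, 3, 4)
  expect_equal(s$mean_rate, mean(r))
  expect_equal(s$se, sd(r) / sqrt(3))
  # the quoted three-well example: rates 2, 3, 4
  w2 <- rbind(well(4, 4, 4, 8, 0, 0), well(4, 4, 4, 4, 4, 4),
              well(2, 2, 2, 4, 2, 2))
  s2 <- summarize_constructs(w2)
  expect_equal(s2$mean_rate, 3)
  expect_equal(s2$se, sd(2:4) / sqrt(3), tolerance = 1e-12)
  # single well: SE 0, flagged
  s3 <- summarize_constructs(well(4, 4, 4, 4, 4, 4))
  expect_equal(s3$se, 0)
  expect_true(s3$single_well)
  # permutation invariance
  expect_equal(summarize_constructs(w2[c(3, 1, 2), ]), s2)
  # all wells excluded is an error
  expect_error(summarize_constructs(well(0, 0, 0, 0, 0, 0)), "no data")
})

test_that("the one-standard-error screen rule flags by construct SE", {
  summ <- data.frame(construct = c("EV", "a", "b"),
                     n_wells = c(18, 18, 18),
                     mean_rate = c(2.5, 3.0, 2.6),
                     se = c(0.1, 0.4, 0.4),
                     single_well = FALSE, stringsAsFactors = FALSE)
  scr <- initial_screen(summ, control = "EV")
  expect_equal(scr$hit, c(TRUE, FALSE))        # 0.5 >= 0.4; 0.1 < 0.4
  expect_equal(scr$direction, c("enhanced", "none"))
  summ$mean_rate[2] <- 2.0
  expect_equal(initial_screen(summ, "EV")$direction[1], "reduced")
  expect_error(initial_screen(summ, control = "missing"), "control")
  # pooled and control variants move the threshold as specified
  scr_p <- initial_screen(summ, "EV", se_rule = "pooled")
  expect_equal(scr_p$threshold, sqrt(c(0.4, 0.4)^2 + 0.1^2))
})

test_that("blocked ANOVA reproduces a hand-worked two-treatment table", {
  # 2 treatments x 3 blocks, one observation per cell:
  #   T1: 10, 12, 14   T2: 13, 14, 18
  # SS_treatment = 13.5 (df 1), SS_block = 21 (df 2), SS_error = 1 (df 2)
  # F = 13.5 / (1/2) = 27
  df <- data.frame(construct = rep(c("T1", "T2"), each = 3),
                   replicate = rep(1:3, 2),
                   rate = c(10, 12, 14, 13, 14, 18))
  a <- blocked_anova(df)
  expect_equal(a$statistic, 27, tolerance = 1e-10)
  expect_equal(a$df, c(1, 2))
  expect_equal(a$p_value, pf(27, 1, 2, lower.tail = FALSE),
               tolerance = 1e-10)
})

test_that("blocked ANOVA: degenerate and invalid designs", {
  same <- data.frame(construct = rep(c("a", "b"), each = 4),
                     replicate = rep(1:2, 4), rate = 5)
  a <- blocked_anova(same)
  expect_equal(a$statistic, 0)
  expect_equal(a$p_value, 1)
  miss <- data.frame(construct = c("a", "a", "b"), replicate = c(1, 2, 1),
                     rate = c(1, 2, 3))
  expect_error(blocked_anova(miss), "singular design: construct b")
  expect_error(blocked_anova(data.frame(construct = "a", replicate = 1:4,
                                        rate = 1:4)), "2 constructs")
})

test_that("blocked ANOVA F is invariant to constant shifts and block relabeling", {
  set.seed(42)
  df <- data.frame(construct = rep(c("a", "b", "c"), each = 6),
                   replicate = rep(rep(1:3, each = 2), 3),
                   rate = rnorm(18, 5, 1))
  f0 <- blocked_anova(df)$statistic
  df_shift <- transform(df, rate = rate + 100)
  expect_equal(blocked_anova(df_shift)$statistic, f0)
  relab <- c("3" = "x", "1" = "y", "2" = "z")
  df_relab <- transform(df, replicate = relab[as.character(replicate)])
  expect_equal(blocked_anova(df_relab)$statistic, f0)
  # well-order permutation invariance
  expect_equal(blocked_anova(df[sample(nrow(df)), ])$statistic, f0)
})

test_that("ROS summary takes per-disc maxima and runs Welch t-tests", {
  mk <- function(construct, maxima) {
    do.call(rbind, lapply(seq_along(maxima), function(d) {
      data.frame(construct = construct, disc = paste0(construct, d),
                 time = c(10, 20, 30),
                 counts = c(maxima[d] / 2, maxima[d], maxima[d] / 3))
    }))
  }
  # hand-worked Welch: (5..12) vs (1..8); var = 6 each, n = 8
  # t = 4 / sqrt(12/8) = 3.2660, df = 14
  ros <- rbind(mk("EV", 1:8), mk("eff", 5:12))
  rs <- ros_summary(ros, control = "EV")
  expect_equal(rs$summary$mean_max[rs$summary$construct == "eff"], 8.5)
  tt <- rs$tests[rs$tests$construct == "eff", ]
  expect_equal(tt$t, 4 / sqrt(1.5), tolerance = 1e-10)
  expect_equal(tt$df, 14, tolerance = 1e-10)
  expect_equal(tt$p_value, 2 * pt(-4 / sqrt(1.5), 14), tolerance = 1e-10)
  # identical constant groups: difference 0, p 1 by convention
  ros2 <- rbind(mk("EV", rep(10, 8)), mk("eff", rep(10, 8)))
  rs2 <- ros_summary(ros2, "EV")
  expect_equal(rs2$tests$t, 0)
  expect_equal(rs2$tests$p_value, 1)
  expect_match(rs2$tests$note, "identical")
})
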