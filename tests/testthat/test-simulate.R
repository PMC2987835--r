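test_that("library generation is deterministic and counts add up", {
  cfg <- library_sim_config(seed = 5, n_true = 5, n_tm_decoys = 0,
                            n_nonsecreted_decoys = 0,
                            n_monomorphic_decoys = 0,
                            redundancy_multiplicity = 3,
                            ortholog_fraction = 0, n_background = 7,
                            extra_all_copies = 1, gut_copies = 0)
  sim <- simulate_library(cfg)
  # 5 proteins x 3 salivary copies + 7 background reads
  expect_equal(nrow(sim$ests$mp_salivary), 5 * 3 + 7)
  # the full collection adds 1 whole-body copy per protein + extra background
  expect_equal(nrow(sim$ests$mp_all), 5 * 3 + 7 + 5 * 1 + 7)
  expect_equal(nrow(sim$truth$proteins), 5L)
  sim2 <- simulate_library(cfg)
  expect_identical(sim$ests, sim2$ests)
  expect_identical(sim$truth, sim2$truth)
  expect_identical(sim$reports, sim2$reports)
  # a different seed changes the sequences
  sim3 <- simulate_library(library_sim_config(seed = 6, n_true = 5,
                                              n_tm_decoys = 0,
                                              n_nonsecreted_decoys = 0,
                                              n_monomorphic_decoys = 0,
                                              ortholog_fraction = 0,
                                              n_background = 7,
                                              extra_all_copies = 1,
                                              gut_copies = 0))
  expect_false(identical(sim$ests$mp_salivary$seq,
                         sim3$ests$mp_salivary$seq))
})

test_that("generators do not disturb the caller's RNG stream", {
  set.seed(99)
  a <- runif(3)
  set.seed(99)
  invisible(simulate_library(library_sim_config(seed = 1, n_true = 2,
                                                n_tm_decoys = 0,
                                                n_nonsecreted_decoys = 0,
                                                n_monomorphic_decoys = 0,
                                                n_background = 2,
                                                gut_copies = 0)))
  invisible(simulate_plate(c(EV = 1), seed = 2))
  invisible(simulate_ros(seed = 3))
  b <- runif(3)
  expect_identical(a, b)
})

test_that("implanted classes pass/fail their defining gate by construction", {
  sim <- simulate_library(library_sim_config(seed = 11, n_true = 6,
                                             n_tm_decoys = 6,
                                             n_nonsecreted_decoys = 6,
                                             n_monomorphic_decoys = 6,
                                             n_background = 5))
  tp <- sim$truth$proteins
  for (i in seq_len(nrow(tp))) {
    call <- predict_signal_peptide(tp$seq[i], id = tp$protein_id[i])
    if (tp$class[i] == "nonsecreted_decoy") {
      expect_lte(call$score, 0.9)
    } else {
      expect_gt(call$score, 0.9)
      expect_equal(call$cleavage_site, tp$sp_len[i])
      topo <- detect_tm_builtin(tp$seq[i], call$cleavage_site)
      if (tp$class[i] == "tm_decoy") {
        expect_true(topo$has_tm_in_mature)
      } else {
        expect_false(topo$has_tm_in_mature)
      }
    }
  }
  # monomorphic decoys differ from their ortholog by exactly one residue
  mono <- tp[tp$class == "monomorphic_decoy" & tp$species == "mp", ]
  for (i in seq_len(nrow(mono))) {
    ap <- tp[tp$protein_id == mono$ortholog_partner[i], ]
    diffs <- sum(strsplit(mono$seq[i], "")[[1]] !=
                   strsplit(ap$seq, "")[[1]])
    expect_equal(diffs, 1L)
  }
  # every generated EST maps to exactly one implanted protein
  expect_true(all(sim$truth$ests$protein_id %in% tp$protein_id))
  expect_equal(anyDuplicated(sim$truth$ests$est_id), 0L)
  # emitted predictor reports agree with the builtin predictors on the
  # pipeline's own ORF ids
  orfs <- call_orfs_library(sim$ests$mp_salivary)
  expect_true(all(orf_ids(orfs) %in% sim$reports$signalp$protein_id))
})

test_that("report-driven and builtin screens agree on synthetic data", {
  sim <- simulate_library(library_sim_config(seed = 12, n_true = 4,
                                             n_tm_decoys = 2,
                                             n_nonsecreted_decoys = 2,
                                             n_monomorphic_decoys = 2,
                                             n_background = 5,
                                             ortholog_fraction = 0.5))
  scr_b <- mine_effectors(sim$ests$mp_salivary, sim$ests$mp_all,
                          sim$ests$mp_gut, sim$ests$ap_salivary)
  scr_r <- mine_effectors(sim$ests$mp_salivary, sim$ests$mp_all,
                          sim$ests$mp_gut, sim$ests$ap_salivary,
                          signalp_report = sim$reports$signalp,
                          tmhmm_report = sim$reports$tmhmm)
  expect_identical(unclass(scr_b$funnel), unclass(scr_r$funnel))
  expect_identical(scr_b$candidates$id, scr_r$candidates$id)
})

test_that("plate simulation: no deaths and unit multiplier give R near 3", {
  p <- simulate_plate(c(EV = 1), death_prob = 0, wells_per_replicate = 2000,
                      replicates = 5, seed = 51)
  expect_true(all(p$A6 == 4 & p$A12 == 4 & p$A14 == 4))
  r <- production_rate(p)
  expect_equal(length(r), 10000L)
  se <- sd(r) / sqrt(length(r))
  expect_lt(abs(mean(r) - 3), 3 * se)
  # multiplier 0: nothing is produced
  p0 <- simulate_plate(c(dead = 0), death_prob = 0, seed = 52)
  expect_true(all(p0[, c("N12", "N14", "N17")] == 0))
  expect_true(all(production_rate(p0) == 0))
})

test_that("plate simulation recovers the implanted multiplier ratio", {
  ratios <- vapply(1:500, function(s) {
    p <- simulate_plate(c(EV = 1, eff = 1.3), death_prob = 0.05,
                        wells_per_replicate = 6, replicates = 3, seed = s)
    s_ <- summarize_constructs(p)
    s_$mean_rate[s_$construct == "eff"] /
      s_$mean_rate[s_$construct == "EV"]
  }, 0)
  expect_lt(abs(mean(ratios) - 1.3) / 1.3, 0.1)
})

test_that("ROS curves: exact peak without noise, suppression scales the group", {
  r0 <- simulate_ros(n_discs = 4, peak_mean = 800, suppression_factor = 0.5,
                     noise_sd = 0, seed = 61)
  mx <- tapply(r0$counts, r0$construct, max)
  expect_equal(unname(mx["EV"]), 800)
  expect_equal(unname(mx["effector"]), 400)
  rs <- ros_summary(r0, "EV")
  expect_equal(rs$summary$se, c(0, 0))
})

test_that("under the null the ROS t-test p-values are uniform", {
  ps <- vapply(1:500, function(s) {
    r <- simulate_ros(n_discs = 8, suppression_factor = 1, seed = s)
    ros_summary(r, "EV")$tests$p_value
  }, 0)
  ks <- suppressWarnings(ks.test(ps, "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("simulated suppression is detected with high power", {
  hits <- vapply(1:500, function(s) {
    r <- simulate_ros(n_discs = 8, suppression_factor = 0.5, seed = s)
    ros_summary(r, "EV")$tests$p_value < 0.05
  }, TRUE)
  expect_gte(mean(hits), 0.8)
})
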