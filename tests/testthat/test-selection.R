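# helpers to build small labelled protein sets and EST fixtures in code

codon_of <- c(A = "GCT", R = "CGT", N = "AAT", D = "GAT", C = "TGT",
              Q = "CAA", E = "GAA", G = "GGT", H = "CAT", I = "ATT",
              L = "CTT", K = "AAA", M = "ATG", F = "TTT", P = "CCT",
              S = "TCT", T = "ACT", W = "TGG", Y = "TAT", V = "GTT")

encode <- function(aa, utr5 = "", utr3 = "") {
  paste0(utr5, paste(codon_of[strsplit(aa, "")[[1]]], collapse = ""),
         "TAA", utr3)
}

mutate_at <- function(seq, pos, to) {
  substr(seq, pos, pos) <- to
  seq
}

test_that("identical proteins cluster; dissimilar proteins stay apart", {
  set.seed(31)
  p <- random_protein(100)
  prots <- data.frame(id = c("a", "b"), seq = c(p, p),
                      stringsAsFactors = FALSE)
  cl <- cluster_redundant(prots)
  expect_equal(length(cl$clusters), 1L)
  expect_equal(sort(cl$clusters[[1]]$members), c("a", "b"))
  # ~50% identity: two singletons
  q <- random_protein(100)
  cl2 <- cluster_redundant(data.frame(id = c("a", "b"), seq = c(p, q)))
  expect_equal(length(cl2$clusters), 2L)
})

test_that("single linkage merges chains and output partitions the input", {
  set.seed(32)
  base <- random_protein(120)
  # a ~ b (2 diffs), b ~ c (2 more diffs), a vs c 4 diffs (still linked
  # through b regardless of the a-c relation)
  b <- mutate_at(mutate_at(base, 10, "W"), 50, "W")
  c_ <- mutate_at(mutate_at(b, 70, "W"), 100, "W")
  prots <- data.frame(id = c("a", "b", "c"), seq = c(base, b, c_))
  cl <- cluster_redundant(prots)
  expect_equal(length(cl$clusters), 1L)
  # partition property on a larger random mix
  prots2 <- data.frame(
    id = sprintf("p%02d", 1:12),
    seq = c(replicate(6, random_protein(90)),
            vapply(1:6, function(i) mutate_at(base, i * 10, "W"), "")))
  cl2 <- cluster_redundant(prots2)
  expect_setequal(unlist(lapply(cl2$clusters, `[[`, "members")), prots2$id)
  expect_equal(anyDuplicated(unlist(lapply(cl2$clusters, `[[`, "members"))),
               0L)
  # representatives: longest member, ties by smallest id; no two
  # representatives satisfy the redundancy edge
  reps <- vapply(cl2$clusters, `[[`, "", "representative")
  for (i in seq_along(reps)) {
    for (j in seq_len(i - 1L)) {
      ra <- prots2$seq[prots2$id == reps[i]]
      rb <- prots2$seq[prots2$id == reps[j]]
      al <- align_local(ra, rb)
      cov <- if (nchar(ra) <= nchar(rb)) al$coverage_query else
        al$coverage_subject
      expect_false(al$identity_pct > 95 && al$evalue < 1e-10 && cov >= 0.8)
    }
  }
})

test_that("short truncated copies cluster with their full-length source", {
  set.seed(33)
  full <- random_protein(120)
  frag <- substr(full, 31, 120)  # 5'-truncated copy
  cl <- cluster_redundant(data.frame(id = c("full", "frag"),
                                     seq = c(full, frag)))
  expect_equal(length(cl$clusters), 1L)
  expect_equal(cl$clusters[[1]]$representative, "full")
})

test_that("full-length criteria follow the supporting EST evidence", {
  set.seed(34)
  cand <- paste0("M", random_protein(80))
  cfg <- pipeline_config()
  ests_support <- data.frame(
    id = c("e1", "e2", "e3"),
    seq = c(encode(cand, utr5 = "CCTCCT", utr3 = "CCTAAC"),
            encode(cand, utr5 = "T", utr3 = ""),
            encode(cand, utr5 = "CCACCA", utr3 = "AACCAA")),
    stringsAsFactors = FALSE)
  hits <- aphidmine:::.translated_hits(cand, aphidmine:::.frame_table(ests_support),
                                       blosum62_matrix(), ka_params())
  fl <- assess_full_length(cand, hits, NULL, cfg, id = "cand")
  expect_true(fl$criterion1_start_stop)   # 3 ESTs conserve start and stop
  expect_true(fl$criterion2_no_upstream_met)
  expect_false(fl$criterion3_ap_support)  # no other-species evidence
  expect_true(fl$is_full_length)

  # an EST with an in-frame upstream methionine breaks criterion 2
  up <- encode(paste0("MGSTV", cand))     # Met 5 codons upstream, in frame
  hits_up <- aphidmine:::.translated_hits(
    cand, aphidmine:::.frame_table(
      data.frame(id = "eu", seq = up, stringsAsFactors = FALSE)),
    blosum62_matrix(), ka_params())
  fl_up <- assess_full_length(cand, hits_up, NULL, cfg)
  expect_false(fl_up$criterion2_no_upstream_met)

  # truncated support only: one stop-conserving EST is not enough
  ests_trunc <- data.frame(
    id = c("e1", "e2"),
    seq = c(encode(cand), substr(encode(cand), 1, 150)),
    stringsAsFactors = FALSE)
  hits_tr <- aphidmine:::.translated_hits(
    cand, aphidmine:::.frame_table(ests_trunc), blosum62_matrix(),
    ka_params())
  fl_tr <- assess_full_length(cand, hits_tr, NULL, cfg)
  expect_false(fl_tr$criterion1_start_stop)

  # criterion 3: a full-length other-species subject covered over 90%
  ap_hits <- data.frame(evalue = 1e-30, coverage_subject = 0.95,
                        subject_full_length = TRUE)
  fl3 <- assess_full_length(cand, hits_tr, ap_hits, cfg)
  expect_true(fl3$criterion3_ap_support)
  expect_true(fl3$is_full_length)  # criterion2 AND criterion3

  # no hits at all: everything false
  no_hits <- hits[0, , drop = FALSE]
  fl0 <- assess_full_length(cand, no_hits, NULL, cfg)
  expect_false(fl0$criterion1_start_stop)
  expect_false(fl0$criterion2_no_upstream_met)
  expect_false(fl0$is_full_length)
})

test_that("polymorphism filter boundaries: zero variation and the one-residue rule", {
  cfg <- pipeline_config()
  set.seed(35)
  cand <- paste0("M", random_protein(60))
  perfect <- data.frame(evalue = c(1e-40, 1e-38), identity_pct = c(100, 100),
                        aligned_query = c(cand, cand),
                        aligned_subject = c(cand, cand),
                        stringsAsFactors = FALSE)
  # monomorphic, other-species mature differs by exactly 1 -> drop
  pf <- polymorphism_filter("c", perfect, list(evalue = 1e-30, n_diff = 1),
                            cfg)
  expect_equal(pf$action, "drop")
  expect_equal(pf$reason, "monomorphic_conserved")
  # other-species differs by 2 -> keep
  pf2 <- polymorphism_filter("c", perfect, list(evalue = 1e-30, n_diff = 2),
                             cfg)
  expect_equal(pf2$action, "keep")
  # same-species variation -> keep regardless
  varied <- perfect
  varied$aligned_subject[2] <- mutate_at(cand, 30, "W")
  pf3 <- polymorphism_filter("c", varied, list(evalue = 1e-30, n_diff = 0),
                             cfg)
  expect_equal(pf3$action, "keep")
  expect_true(pf3$variation)
  # no other-species hit: kept only with variation
  expect_equal(polymorphism_filter("c", perfect, NULL, cfg)$action, "drop")
  expect_equal(polymorphism_filter("c", varied, NULL, cfg)$action, "keep")
  # low-identity hits to other genes are not variation evidence
  foreign <- data.frame(evalue = 1e-8, identity_pct = 55,
                        aligned_query = substr(cand, 1, 30),
                        aligned_subject = random_protein(30),
                        stringsAsFactors = FALSE)
  pf4 <- polymorphism_filter("c", rbind(perfect, foreign),
                             list(evalue = 1e-30, n_diff = 0), cfg)
  expect_equal(pf4$action, "drop")
})

test_that("CSP motif scan matches the regular-expression oracle", {
  set.seed(36)
  # constructed positive at a known offset
  pos <- paste0(strrep("A", 10), "C", strrep("A", 6), "C", strrep("A", 18),
                "C", strrep("A", 2), "C", strrep("A", 5))
  expect_equal(scan_csp_motif(pos), 11L)
  expect_equal(scan_csp_motif(paste0("CCC", strrep("A", 40))), NA_integer_)
  for (rep in 1:1000) {
    s <- paste(sample(c(AA20, rep("C", 8)), sample(20:80, 1),
                      replace = TRUE), collapse = "")
    expect_identical(scan_csp_motif(s, all = TRUE),
                     csp_regex_oracle(s, all = TRUE))
    expect_identical(scan_csp_motif(s), csp_regex_oracle(s))
  }
})

test_that("cross-species reconciliation pairs orthologs and adds via EST search", {
  set.seed(37)
  cfg <- pipeline_config()
  # two gate-passing signal-peptide designs with near-zero cross-score, so
  # that the ortholog pairs and the extras cannot cross-match through a
  # shared N-terminus (cleavage at 18, builtin score 0.993 for both)
  sp_pair <- "MKKKLLLLLLLLLLQAHA"
  sp_extra <- "MRRRVVVVVVVVVVNSPS"
  make_secreted <- function(sp) {
    repeat {
      p <- paste0(sp, random_protein(70))
      if (!detect_tm_builtin(p, nchar(sp))$has_tm_in_mature) return(p)
    }
  }
  mk_pair <- function() {
    mp <- make_secreted(sp_pair)
    ap <- mp
    for (p in sample(nchar(mp) - 50 + seq_len(50), 8)) {
      ap <- mutate_at(ap, p, sample(AA20, 1))
    }
    list(mp = mp, ap = ap)
  }
  pairs <- replicate(3, mk_pair(), simplify = FALSE)
  extras <- replicate(2, make_secreted(sp_extra))
  mp_cands <- data.frame(id = sprintf("mp%d", 1:3),
                         seq = vapply(pairs, `[[`, "", "mp"),
                         stringsAsFactors = FALSE)
  ap_cands <- data.frame(id = sprintf("ap%d", 1:5),
                         seq = c(vapply(pairs, `[[`, "", "ap"), extras),
                         stringsAsFactors = FALSE)
  # the extras' source ESTs exist in the full collection but not among the
  # focal candidates
  mp_all <- data.frame(
    id = c(sprintf("est_mp%d", 1:3), sprintf("est_x%d", 1:2)),
    seq = c(vapply(pairs, function(p) encode(p$mp, "CCT", "AAC"), ""),
            vapply(extras, function(e) encode(e, "CCT", "AAC"), "")),
    stringsAsFactors = FALSE)
  rec <- reconcile_cross_species(mp_cands, ap_cands, mp_all, cfg)
  expect_equal(sort(unique(rec$shared$ap_id)), c("ap1", "ap2", "ap3"))
  expect_equal(nrow(rec$added), 2L)
  expect_setequal(rec$added$source_est, c("est_x1", "est_x2"))
  expect_equal(sort(rec$added$via_ap_id), c("ap4", "ap5"))
  # an ap candidate with no EST hit anywhere adds nothing (third distinct
  # signal-peptide design, so not even the N-terminus matches anything)
  lone <- data.frame(id = "ap9", seq = make_secreted("MKRKIIIIIIIIIIHGQG"))
  rec2 <- reconcile_cross_species(mp_cands, lone, mp_all, cfg)
  expect_equal(nrow(rec2$added), 0L)
  # excluded sequences cannot re-enter as additions
  rec3 <- reconcile_cross_species(mp_cands, ap_cands, mp_all, cfg,
                                  exclude = data.frame(
                                    id = c("x1", "x2"), seq = extras,
                                    stringsAsFactors = FALSE))
  expect_equal(nrow(rec3$added), 0L)
})

test_that("gut flagging is exact-match driven and order invariant", {
  set.seed(38)
  cand <- data.frame(id = "c1", seq = paste0("M", random_protein(80)),
                     stringsAsFactors = FALSE)
  gut <- data.frame(
    id = c("g1", "g2", "g3"),
    seq = c(encode(cand$seq, "CCT", "AAC"), random_dna(400), random_dna(300)),
    stringsAsFactors = FALSE)
  expect_true(flag_gut_matches(cand, gut)[["c1"]])
  expect_false(flag_gut_matches(cand, gut[-1, ])[["c1"]])
  expect_equal(flag_gut_matches(cand, gut),
               flag_gut_matches(cand, gut[c(3, 1, 2), ]))
  expect_false(flag_gut_matches(cand, NULL)[["c1"]])
})

test_that("candidate naming is serial with legacy overrides", {
  ids <- c("orf_a", "orf_b", "orf_c")
  nm <- name_candidates(ids, "mp")
  expect_equal(unname(nm), c("Mp1", "Mp2", "Mp3"))
  nm2 <- name_candidates(ids, "mp", legacy = c(orf_b = "MpC002"))
  expect_equal(unname(nm2), c("Mp1", "MpC002", "Mp3"))
  expect_equal(unname(name_candidates("z", "ap")), "Ap1")
  expect_error(name_candidates(ids, "mp",
                               legacy = c(orf_b = "Mp1")),
               "not unique")
})

test_that("funnel report validates stages and monotonicity", {
  counts <- c(ests_in = 170, orfs_called = 300,
              with_signal_peptide_nonredundant = 40, with_tm_removed = 30,
              predicted_secreted = 30, full_length = 28,
              after_polymorphism_filter = 20, added_cross_species = 22,
              final_candidates = 22)
  f <- build_funnel_report(counts)
  expect_s3_class(f, "funnel_report")
  expect_true(funnel_is_monotone(f))
  bad <- counts
  bad["full_length"] <- 35  # filter stage may not increase
  expect_false(funnel_is_monotone(build_funnel_report(bad)))
  expect_error(build_funnel_report(counts[-3]), "stage missing")
  js <- jsonlite::fromJSON(funnel_to_json(f))
  expect_equal(js$stage[1], "ests_in")
  expect_equal(js$count, unname(as.integer(f)))
})
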