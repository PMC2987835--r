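# Ground-truth synthetic data: two-species EST libraries with implanted
# candidate structure, matching predictor reports, fecundity plates and
# ROS time series. All generators are pure functions of their
# configuration: the caller's RNG state is saved and restored, and the
# same seed reproduces identical output.

.AA20 <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I", "L", "K",
           "M", "F", "P", "S", "T", "W", "Y", "V")

# one fixed codon per amino acid (no codon-usage model; nucleotide realism
# only matters for start/stop placement)
.CODON_OF <- c(A = "GCT", R = "CGT", N = "AAT", D = "GAT", C = "TGT",
               Q = "CAA", E = "GAA", G = "GGT", H = "CAT", I = "ATT",
               L = "CTT", K = "AAA", M = "ATG", F = "TTT", P = "CCT",
               S = "TCT", T = "ACT", W = "TGG", Y = "TAT", V = "GTT")

.with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

#' Configuration for the synthetic EST library generator
#'
#' Defaults define the benchmark conditions used throughout the package's
#' tests: 20 implanted true candidates, 10 transmembrane-anchored decoys,
#' 10 non-secreted decoys and 10 monomorphic conserved decoys, each
#' represented by 3 redundant EST copies carrying 2 mature-region
#' amino-acid substitutions per extra copy (the monomorphic decoys carry
#' none); 60% of true candidates have an ortholog in the second species at
#' 15% mature divergence, and every monomorphic decoy has a near-identical
#' (one-residue) ortholog; reads get 40/120 nt untranslated ends, are
#' truncated with probability 0.3 (losing 10-50% of their length from one
#' end) and reverse-complemented with probability 0.5.
#'
#' @param seed mandatory RNG seed.
#' @param n_true,n_tm_decoys,n_nonsecreted_decoys,n_monomorphic_decoys
#'   numbers of implanted proteins per class.
#' @param redundancy_multiplicity EST copies per implanted protein.
#' @param polymorphism_rate mature-region amino-acid substitutions per
#'   extra same-species copy (true candidates and TM decoys).
#' @param ortholog_fraction fraction of true candidates with an ortholog
#'   in the second species.
#' @param ortholog_divergence percent of mature residues substituted in
#'   the ortholog.
#' @param utr5_len,utr3_len untranslated-region lengths (nt).
#' @param truncation_prob probability an EST copy loses one end.
#' @param revcomp_prob probability an EST copy is reverse-complemented.
#' @param n_background random background ESTs added per library.
#' @param extra_all_copies additional whole-body EST copies per
#'   focal-species implanted protein present only in the full EST
#'   collection (the real whole-species collection is many times the size
#'   of the salivary library and re-samples the same transcripts).
#' @param gut_copies number of true candidates implanted verbatim in the
#'   gut library.
#' @param mature_len_range mature-protein length range (residues).
#' @return A list of class `"library_sim_config"`.
#' @export
library_sim_config <- function(seed,
                               n_true = 20L, n_tm_decoys = 10L,
                               n_nonsecreted_decoys = 10L,
                               n_monomorphic_decoys = 10L,
                               redundancy_multiplicity = 3L,
                               polymorphism_rate = 2L,
                               ortholog_fraction = 0.6,
                               ortholog_divergence = 15,
                               utr5_len = 40L, utr3_len = 120L,
                               truncation_prob = 0.3, revcomp_prob = 0.5,
                               n_background = 20L, extra_all_copies = 2L,
                               gut_copies = 2L,
                               mature_len_range = c(60L, 120L)) {
  if (missing(seed)) stop("seed is mandatory")
  stopifnot(n_true >= 0, n_tm_decoys >= 0, n_nonsecreted_decoys >= 0,
            n_monomorphic_decoys >= 0, redundancy_multiplicity >= 1,
            polymorphism_rate >= 0,
            ortholog_fraction >= 0, ortholog_fraction <= 1,
            ortholog_divergence >= 0, ortholog_divergence <= 100,
            truncation_prob >= 0, truncation_prob <= 1,
            revcomp_prob >= 0, revcomp_prob <= 1,
            n_background >= 0, extra_all_copies >= 0, gut_copies >= 0,
            gut_copies <= max(n_true, 0),
            length(mature_len_range) == 2L,
            mature_len_range[1] >= 40L)
  structure(as.list(environment()), class = "library_sim_config")
}

# a mature region with no 19-window Kyte-Doolittle mean near the TM
# threshold, so built-in TM detection on true candidates is quiet by
# construction
.sim_mature <- function(len) {
  repeat {
    aa <- sample(.AA20, len, replace = TRUE)
    mm <- .window_means(unname(kyte_doolittle()[aa]), 19L)
    if (length(mm) == 0L || max(mm) <= 1.45) return(aa)
  }
}

# a signal peptide scoring > 0.9 under the built-in heuristic: basic
# n-region, hydrophobic h-region, small residues at -1/-3 of the cleavage
# site (= the signal-peptide length)
.sim_signal_peptide <- function() {
  small <- c("A", "S", "G")
  n_reg <- c("M", sample(c("K", "R"), 3L, replace = TRUE))
  h_reg <- sample(c("L", "I", "V"), sample(8:12, 1L), replace = TRUE)
  c_reg <- c(sample(c("Q", "N", "H"), 1L), sample(small, 1L),
             sample(c("H", "Q", "N", "P"), 1L), sample(small, 1L))
  c(n_reg, h_reg, c_reg)
}

.sim_mutate <- function(aa, positions, n_sub) {
  if (n_sub == 0L || length(positions) == 0L) return(aa)
  pos <- sample(positions, min(n_sub, length(positions)))
  for (p in pos) {
    aa[p] <- sample(setdiff(.AA20, aa[p]), 1L)
  }
  aa
}

.back_translate <- function(aa) {
  paste0(paste(.CODON_OF[aa], collapse = ""), "TAA")
}

.sim_utr <- function(len) {
  # A/C/T only: an untranslated region that can never contribute an
  # upstream in-frame ATG
  paste(sample(c("A", "C", "T"), len, replace = TRUE), collapse = "")
}

.sim_background <- function(n, prefix) {
  if (n == 0L) {
    return(data.frame(id = character(0), seq = character(0),
                      stringsAsFactors = FALSE))
  }
  data.frame(
    id = sprintf("%s_bg%03d", prefix, seq_len(n)),
    seq = vapply(seq_len(n), function(i) {
      paste(sample(c("A", "C", "G", "T"), sample(300:700, 1L),
                   replace = TRUE), collapse = "")
    }, ""),
    stringsAsFactors = FALSE)
}

#' Simulate two-species EST libraries with known ground truth
#'
#' Implants four classes of proteins (true secreted candidates,
#' transmembrane-anchored decoys, non-secreted decoys, monomorphic
#' conserved decoys) as redundant, polymorphic, UTR-flanked,
#' strand-randomized and end-truncated EST reads across the four libraries
#' the mining pipeline consumes (focal-species salivary gland, full
#' collection, gut; second-species salivary gland), and emits matching
#' signal-peptide and topology reports computed with the built-in
#' predictors so the parsed-report path can be exercised too.
#'
#' @param config a [library_sim_config()].
#' @return A list: `ests` (data frames `mp_salivary`, `mp_all`, `mp_gut`,
#'   `ap_salivary`), `reports` (`signalp`, `tmhmm` data frames in the
#'   dialects of [read_predictor_report()]), `truth` (`proteins`: one row
#'   per implanted protein with class/species/ortholog/cleavage; `ests`:
#'   one row per generated read with its source protein and whether start
#'   and stop survived truncation), and `config`.
#' @export
simulate_library <- function(config) {
  stopifnot(inherits(config, "library_sim_config"))
  .with_seed(config$seed, {
    prot <- list()
    add_prot <- function(id, class, species, aa, sp_len, partner = NA) {
      prot[[id]] <<- list(id = id, class = class, species = species,
                          aa = aa, sp_len = sp_len,
                          ortholog_partner = partner)
    }
    mlen <- function() sample(config$mature_len_range[1]:
                                config$mature_len_range[2], 1L)
    for (i in seq_len(config$n_true)) {
      sp <- .sim_signal_peptide()
      add_prot(sprintf("mp_true%02d", i), "true_candidate", "mp",
               c(sp, .sim_mature(mlen())), length(sp))
    }
    for (i in seq_len(config$n_tm_decoys)) {
      sp <- .sim_signal_peptide()
      m <- .sim_mature(mlen())
      m <- c(m[1:4], rep("L", 21L), m[5:length(m)])
      add_prot(sprintf("mp_tm%02d", i), "tm_decoy", "mp",
               c(sp, m), length(sp))
    }
    for (i in seq_len(config$n_nonsecreted_decoys)) {
      add_prot(sprintf("mp_ns%02d", i), "nonsecreted_decoy", "mp",
               c("M", sample(c("D", "E"), 4L, replace = TRUE),
                 .sim_mature(mlen())), NA_integer_)
    }
    for (i in seq_len(config$n_monomorphic_decoys)) {
      sp <- .sim_signal_peptide()
      add_prot(sprintf("mp_mono%02d", i), "monomorphic_decoy", "mp",
               c(sp, .sim_mature(mlen())), length(sp))
    }
    # second-species orthologs
    n_orth <- round(config$ortholog_fraction * config$n_true)
    orth_of <- if (n_orth > 0) {
      sort(sample(seq_len(config$n_true), n_orth))
    } else integer(0)
    for (i in orth_of) {
      mp_id <- sprintf("mp_true%02d", i)
      p <- prot[[mp_id]]
      mat_pos <- (p$sp_len + 1L):length(p$aa)
      n_sub <- max(1L, round(config$ortholog_divergence / 100 *
                               length(mat_pos)))
      ap_id <- sprintf("ap_true%02d", i)
      add_prot(ap_id, "true_candidate", "ap",
               .sim_mutate(p$aa, mat_pos, n_sub), p$sp_len, mp_id)
      prot[[mp_id]]$ortholog_partner <- ap_id
    }
    for (i in seq_len(config$n_monomorphic_decoys)) {
      mp_id <- sprintf("mp_mono%02d", i)
      p <- prot[[mp_id]]
      mat_pos <- (p$sp_len + 1L):length(p$aa)
      ap_id <- sprintf("ap_mono%02d", i)
      add_prot(ap_id, "monomorphic_decoy", "ap",
               .sim_mutate(p$aa, mat_pos, 1L), p$sp_len, mp_id)
      prot[[mp_id]]$ortholog_partner <- ap_id
    }

    # EST copies: `redundancy_multiplicity` salivary reads per protein,
    # plus (focal species only) `extra_all_copies` whole-body reads that
    # appear only in the full EST collection
    make_copies <- function(p) {
      polymorphic <- p$class %in% c("true_candidate", "tm_decoy")
      n_sal <- config$redundancy_multiplicity
      n_extra <- if (p$species == "mp") config$extra_all_copies else 0L
      lapply(seq_len(n_sal + n_extra), function(cp) {
        aa <- p$aa
        if (cp > 1L && polymorphic && config$polymorphism_rate > 0) {
          mat_pos <- if (is.na(p$sp_len)) seq_along(aa) else
            (p$sp_len + 1L):length(aa)
          aa <- .sim_mutate(aa, mat_pos, config$polymorphism_rate)
        }
        nt <- paste0(.sim_utr(config$utr5_len), .back_translate(aa),
                     .sim_utr(config$utr3_len))
        full_start <- TRUE; full_stop <- TRUE; truncated <- FALSE
        if (runif(1) < config$truncation_prob) {
          truncated <- TRUE
          L <- nchar(nt)
          cut <- round(runif(1, 0.1, 0.5) * L)
          if (runif(1) < 0.5) {
            nt <- substring(nt, cut + 1L)
            full_start <- cut <= config$utr5_len
          } else {
            nt <- substring(nt, 1L, L - cut)
            full_stop <- cut <= config$utr3_len
          }
        }
        rc <- runif(1) < config$revcomp_prob
        if (rc) nt <- .revcomp(nt)
        list(id = sprintf("%s_c%d", p$id, cp), seq = nt,
             protein_id = p$id,
             library = if (cp <= n_sal) "salivary" else "all_extra",
             is_full_length = full_start && full_stop,
             truncated = truncated, revcomp = rc)
      })
    }
    copies <- unlist(lapply(prot, make_copies), recursive = FALSE)
    cp_df <- data.frame(
      id = vapply(copies, `[[`, "", "id"),
      seq = vapply(copies, `[[`, "", "seq"),
      protein_id = vapply(copies, `[[`, "", "protein_id"),
      library = vapply(copies, `[[`, "", "library"),
      is_full_length = vapply(copies, `[[`, TRUE, "is_full_length"),
      truncated = vapply(copies, `[[`, TRUE, "truncated"),
      revcomp = vapply(copies, `[[`, TRUE, "revcomp"),
      stringsAsFactors = FALSE)
    cp_df$species <- vapply(cp_df$protein_id,
                            function(id) prot[[id]]$species, "")

    as_lib <- function(df, species, tissue) {
      out <- data.frame(id = df$id, desc = "", seq = df$seq,
                        species = species, tissue = tissue,
                        stringsAsFactors = FALSE)
      attr(out, "alphabet") <- "nt"
      out
    }
    mp_cp <- cp_df[cp_df$species == "mp" & cp_df$library == "salivary", ,
                   drop = FALSE]
    mp_extra <- cp_df[cp_df$species == "mp" & cp_df$library == "all_extra", ,
                      drop = FALSE]
    ap_cp <- cp_df[cp_df$species == "ap", , drop = FALSE]
    bg_sal <- .sim_background(config$n_background, "mp_sal")
    bg_all <- .sim_background(config$n_background, "mp_all")
    bg_ap <- .sim_background(ceiling(config$n_background / 2), "ap_sal")
    bg_gut <- .sim_background(max(5L, ceiling(config$n_background / 2)),
                              "mp_gut")
    mp_salivary <- as_lib(rbind(mp_cp[, c("id", "seq")], bg_sal),
                          "mp", "salivary_gland")
    mp_all <- as_lib(rbind(mp_cp[, c("id", "seq")],
                           mp_extra[, c("id", "seq")], bg_sal, bg_all),
                     "mp", "whole")
    ap_salivary <- as_lib(rbind(ap_cp[, c("id", "seq")], bg_ap),
                          "ap", "salivary_gland")
    gut_imp <- if (config$gut_copies > 0) {
      ids <- sprintf("mp_true%02d", seq_len(config$gut_copies))
      data.frame(
        id = paste0(ids, "_gut"),
        seq = vapply(ids, function(id) {
          paste0(.sim_utr(config$utr5_len), .back_translate(prot[[id]]$aa),
                 .sim_utr(config$utr3_len))
        }, "", USE.NAMES = FALSE),
        stringsAsFactors = FALSE)
    } else {
      data.frame(id = character(0), seq = character(0),
                 stringsAsFactors = FALSE)
    }
    mp_gut <- as_lib(rbind(gut_imp, bg_gut), "mp", "gut")

    # predictor reports from the built-in heuristics over every called ORF
    all_ests <- rbind(mp_all[, c("id", "seq")],
                      ap_salivary[, c("id", "seq")],
                      mp_gut[, c("id", "seq")])
    orfs <- call_orfs_library(all_ests, min_len = 70L)
    op <- orf_proteins(orfs)
    sp_rows <- lapply(seq_len(nrow(op)), function(i) {
      cl <- predict_signal_peptide(op$seq[i], id = op$id[i])
      k <- if (is.na(cl$cleavage_site)) 1L else cl$cleavage_site
      segs <- if (k < nchar(op$seq[i])) {
        detect_tm_builtin(op$seq[i], k, id = op$id[i])$tm_segments
      } else {
        matrix(integer(0), ncol = 2,
               dimnames = list(NULL, c("start", "end")))
      }
      list(sp = data.frame(protein_id = op$id[i], score = cl$score,
                           cleavage_site = k, stringsAsFactors = FALSE),
           tm = segs)
    })
    signalp <- do.call(rbind, lapply(sp_rows, `[[`, "sp"))
    tmhmm <- data.frame(protein_id = op$id,
                        n_segments = vapply(sp_rows, function(r) {
                          nrow(r$tm)
                        }, 0L),
                        stringsAsFactors = FALSE)
    tmhmm$tm_segments <- lapply(sp_rows, `[[`, "tm")

    truth_prot <- data.frame(
      protein_id = vapply(prot, `[[`, "", "id"),
      class = vapply(prot, `[[`, "", "class"),
      species = vapply(prot, `[[`, "", "species"),
      sp_len = vapply(prot, function(p) as.integer(p$sp_len), 0L),
      ortholog_partner = vapply(prot, function(p) {
        as.character(p$ortholog_partner)
      }, ""),
      seq = vapply(prot, function(p) paste(p$aa, collapse = ""), ""),
      stringsAsFactors = FALSE)
    rownames(truth_prot) <- NULL
    truth_est <- cp_df[, c("id", "protein_id", "species", "library",
                           "is_full_length", "truncated", "revcomp")]
    names(truth_est)[1] <- "est_id"
    rownames(truth_est) <- NULL

    list(ests = list(mp_salivary = mp_salivary, mp_all = mp_all,
                     mp_gut = mp_gut, ap_salivary = ap_salivary),
         reports = list(signalp = signalp, tmhmm = tmhmm),
         truth = list(proteins = truth_prot, ests = truth_est),
         config = config)
  })
}

#' Evaluate a screen against synthetic ground truth
#'
#' Maps every final candidate back to its source protein through the EST
#' it was called from and scores recovery.
#'
#' @param screen an `"effector_screen"` from [mine_effectors()].
#' @param truth the `truth` element of [simulate_library()] output (or the
#'   whole simulation object).
#' @return A list: `sensitivity` (distinct true candidates recovered /
#'   implanted), `precision` (candidates mapping to a true candidate /
#'   all candidates), `rejection` (named vector, per decoy class),
#'   `candidate_classes` (per-candidate mapping).
#' @export
evaluate_screen <- function(screen, truth) {
  if (!is.null(truth$truth)) truth <- truth$truth
  est2prot <- setNames(truth$ests$protein_id, truth$ests$est_id)
  # the focal species' proteins (candidate ESTs are focal-species reads)
  cls <- setNames(truth$proteins$class, truth$proteins$protein_id)
  cand <- screen$candidates
  pid <- unname(est2prot[cand$source_est])
  ccls <- ifelse(is.na(pid), "background", unname(cls[pid]))
  mp_prot <- truth$proteins[truth$proteins$species == "mp", , drop = FALSE]
  n_true <- sum(mp_prot$class == "true_candidate")
  recovered <- unique(pid[!is.na(pid) & ccls == "true_candidate"])
  sens <- if (n_true > 0) length(recovered) / n_true else NA_real_
  prec <- if (nrow(cand) > 0) mean(ccls == "true_candidate") else NA_real_
  rejection <- vapply(c(tm_decoy = "tm_decoy",
                        nonsecreted_decoy = "nonsecreted_decoy",
                        monomorphic_decoy = "monomorphic_decoy"),
                      function(k) {
    n <- sum(mp_prot$class == k)
    if (n == 0) return(NA_real_)
    present <- length(unique(pid[!is.na(pid) & ccls == k]))
    1 - present / n
  }, 0)
  list(sensitivity = sens, precision = prec, rejection = rejection,
       candidate_classes = data.frame(name = cand$name,
                                      source_est = cand$source_est,
                                      protein_id = pid, class = ccls,
                                      stringsAsFactors = FALSE))
}

#' Simulate a 24-well leaf-disc fecundity experiment
#'
#' Four first-instar nymphs start in each well; adults survive each
#' count-to-count interval with independent probability `1 - death_prob`,
#' and nymph counts are Poisson with mean equal to the surviving adults
#' times the baseline per-interval production times the construct's rate
#' multiplier. Wells in which every adult dies are still emitted;
#' exclusion is the analysis' job.
#'
#' @param constructs named numeric vector of per-construct rate
#'   multipliers (the empty-vector control is 1).
#' @param baseline nymphs per adult per interval under multiplier 1.
#' @param death_prob per-adult per-interval death probability.
#' @param wells_per_replicate wells per construct per replicate
#'   experiment.
#' @param replicates number of replicate experiments (blocks).
#' @param initial_n nymphs placed per well.
#' @param seed mandatory RNG seed.
#' @return Data frame: `construct`, `replicate`, `well`, `A6`, `A12`,
#'   `A14`, `N12`, `N14`, `N17`, with attribute `"multipliers"`.
#' @export
simulate_plate <- function(constructs = c(EV = 1.0), baseline = 1.0,
                           death_prob = 0.05, wells_per_replicate = 6L,
                           replicates = 3L, initial_n = 4L, seed) {
  if (missing(seed)) stop("seed is mandatory")
  stopifnot(!is.null(names(constructs)), all(constructs >= 0),
            death_prob >= 0, death_prob <= 1, baseline >= 0)
  .with_seed(seed, {
    grid <- expand.grid(well = seq_len(wells_per_replicate),
                        replicate = seq_len(replicates),
                        construct = names(constructs),
                        stringsAsFactors = FALSE)
    n <- nrow(grid)
    mult <- constructs[grid$construct]
    A6 <- rbinom(n, initial_n, 1 - death_prob)
    A12 <- rbinom(n, A6, 1 - death_prob)
    A14 <- rbinom(n, A12, 1 - death_prob)
    out <- data.frame(construct = grid$construct,
                      replicate = grid$replicate, well = grid$well,
                      A6 = A6, A12 = A12, A14 = A14,
                      N12 = rpois(n, A6 * baseline * mult),
                      N14 = rpois(n, A12 * baseline * mult),
                      N17 = rpois(n, A14 * baseline * mult),
                      stringsAsFactors = FALSE)
    attr(out, "multipliers") <- constructs
    out
  })
}

#' Simulate ROS (oxidative burst) time series
#'
#' A smooth unimodal photon-count curve peaking at `peak_mean`
#' (`peak * (t/tp)^2 * exp(2 * (1 - t/tp))`, peak time 20 min), scaled by
#' `suppression_factor` for the effector group, with per-timepoint
#' Gaussian noise truncated at zero.
#'
#' @param n_discs leaf discs per group.
#' @param peak_mean control-group peak photon count.
#' @param suppression_factor multiplicative scaling of the effector
#'   group's curve (1 = no suppression).
#' @param noise_sd per-timepoint Gaussian noise standard deviation.
#' @param seed mandatory RNG seed.
#' @param times measurement times (minutes).
#' @return Long-format data frame `construct` (`"EV"` control /
#'   `"effector"`), `disc`, `time`, `counts`, as consumed by
#'   [ros_summary()].
#' @export
simulate_ros <- function(n_discs = 8L, peak_mean = 1000,
                         suppression_factor = 0.5, noise_sd = 25,
                         seed, times = seq(2, 60, by = 2)) {
  if (missing(seed)) stop("seed is mandatory")
  stopifnot(n_discs >= 1, peak_mean >= 0, suppression_factor >= 0,
            noise_sd >= 0)
  .with_seed(seed, {
    tp <- 20
    shape <- (times / tp)^2 * exp(2 * (1 - times / tp))
    rows <- lapply(c(EV = 1, effector = suppression_factor),
                   function(scale) {
      do.call(rbind, lapply(seq_len(n_discs), function(d) {
        mu <- peak_mean * scale * shape
        data.frame(disc = d, time = times,
                   counts = pmax(0, mu + rnorm(length(times), 0, noise_sd)))
      }))
    })
    out <- rbind(cbind(construct = "EV", rows[[1]]),
                 cbind(construct = "effector", rows[[2]]))
    out$disc <- paste0(out$construct, out$disc)
    rownames(out) <- NULL
    out
  })
}
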