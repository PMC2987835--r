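# End-to-end orchestration of the mining cascade.

# apply the secretion gate to one protein, using parsed reports when
# supplied and the built-in predictors otherwise
.gate_protein <- function(seq, id, config, signalp_report = NULL,
                          tmhmm_report = NULL) {
  call <- if (is.null(signalp_report)) {
    predict_signal_peptide(seq, id = id)
  } else {
    predict_signal_peptide(list(id = id, seq = seq), backend = "report",
                           report = signalp_report)
  }
  g1 <- passes_secretion_gate(call, NULL, config)
  if (!g1$pass) {
    return(list(pass = FALSE, reason = g1$reason, call = call, topo = NULL))
  }
  topo <- if (is.null(tmhmm_report)) {
    if (call$cleavage_site < nchar(seq)) {
      detect_tm_builtin(seq, call$cleavage_site, id = id)
    } else NULL
  } else {
    i <- match(id, tmhmm_report$protein_id)
    if (is.na(i)) stop("protein id missing from topology report: ", id)
    topology_from_report(id, tmhmm_report$tm_segments[[i]],
                         call$cleavage_site)
  }
  g <- passes_secretion_gate(call, topo, config)
  list(pass = g$pass, reason = g$reason, call = call, topo = topo)
}

# one species side of the cascade, through the full-length stage
.mine_side <- function(ests_sal, ests_all, config, matrix, params,
                       signalp_report = NULL, tmhmm_report = NULL,
                       other_orf_proteins = NULL) {
  orfs <- call_orfs_library(ests_sal, min_len = config$min_orf_len)
  prot <- orf_proteins(orfs)
  side <- list(orfs = orfs, proteins = prot)
  empty_cand <- data.frame(id = character(0), seq = character(0),
                           source_est = character(0),
                           cleavage_site = integer(0), sp_score = numeric(0),
                           mature_seq = character(0),
                           stringsAsFactors = FALSE)
  if (nrow(prot) == 0L) {
    side$sp_pos <- empty_cand
    side$clusters <- NULL
    side$secreted <- empty_cand
    side$fl_calls <- list()
    side$candidates <- empty_cand
    side$est_hits <- list()
    side$counts <- c(nonredundant = 0L, tm_removed = 0L, full_length = 0L)
    return(side)
  }
  # signal-peptide clauses (score, cleavage) before clustering
  calls <- lapply(seq_len(nrow(prot)), function(i) {
    if (is.null(signalp_report)) {
      predict_signal_peptide(prot$seq[i], id = prot$id[i])
    } else {
      predict_signal_peptide(list(id = prot$id[i], seq = prot$seq[i]),
                             backend = "report", report = signalp_report)
    }
  })
  sp_ok <- vapply(calls, function(cl) {
    passes_secretion_gate(cl, NULL, config)$pass
  }, TRUE)
  sp_pos <- prot[sp_ok, , drop = FALSE]
  sp_pos$sp_score <- vapply(calls[sp_ok], `[[`, 0, "score")
  sp_pos$cleavage_site <- vapply(calls[sp_ok], function(cl) {
    as.integer(cl$cleavage_site)
  }, 0L)
  side$sp_pos <- sp_pos
  if (nrow(sp_pos) == 0L) {
    side$clusters <- NULL
    side$secreted <- empty_cand
    side$fl_calls <- list()
    side$candidates <- empty_cand
    side$est_hits <- list()
    side$counts <- c(nonredundant = 0L, tm_removed = 0L, full_length = 0L)
    return(side)
  }
  clusters <- cluster_redundant(sp_pos, config, matrix, params)
  side$clusters <- clusters
  reps <- sp_pos[clusters$membership$is_representative, , drop = FALSE]
  # transmembrane gate on the nonredundant representatives
  keep_tm <- vapply(seq_len(nrow(reps)), function(i) {
    topo <- if (is.null(tmhmm_report)) {
      if (reps$cleavage_site[i] < nchar(reps$seq[i])) {
        detect_tm_builtin(reps$seq[i], reps$cleavage_site[i],
                          id = reps$id[i])
      } else NULL
    } else {
      j <- match(reps$id[i], tmhmm_report$protein_id)
      if (is.na(j)) stop("protein id missing from topology report: ",
                         reps$id[i])
      topology_from_report(reps$id[i], tmhmm_report$tm_segments[[j]],
                           reps$cleavage_site[i])
    }
    is.null(topo) || !topo$has_tm_in_mature
  }, TRUE)
  secreted <- reps[keep_tm, , drop = FALSE]
  secreted$mature_seq <- vapply(seq_len(nrow(secreted)), function(i) {
    cleave(secreted$seq[i], secreted$cleavage_site[i])$mature_seq
  }, "")
  side$n_nonredundant <- nrow(reps)
  side$secreted <- secreted
  # supporting-evidence hits against the full same-species EST collection
  frames_all <- .frame_table(ests_all)
  side$frames_all <- frames_all
  est_hits <- lapply(seq_len(nrow(secreted)), function(i) {
    .translated_hits(secreted$seq[i], frames_all, matrix, params,
                     detail = TRUE)
  })
  names(est_hits) <- secreted$id
  side$est_hits <- est_hits
  # full-length assessment (criterion 3 against the other species' ORFs)
  fl_calls <- lapply(seq_len(nrow(secreted)), function(i) {
    ap_hits <- NULL
    if (!is.null(other_orf_proteins) && nrow(other_orf_proteins)) {
      res <- .align_many(secreted$seq[i], other_orf_proteins$seq,
                         matrix, params)
      ap_hits <- data.frame(
        subject_id = other_orf_proteins$id,
        evalue = res$evalue,
        coverage_subject = res$coverage_subject,
        subject_full_length = other_orf_proteins$terminated_by_stop,
        stringsAsFactors = FALSE)
    }
    assess_full_length(list(id = secreted$id[i], seq = secreted$seq[i]),
                       est_hits[[i]], ap_hits, config)
  })
  names(fl_calls) <- secreted$id
  side$fl_calls <- fl_calls
  is_fl <- vapply(fl_calls, `[[`, TRUE, "is_full_length")
  side$candidates <- secreted[is_fl, , drop = FALSE]
  side$counts <- c(nonredundant = nrow(reps), tm_removed = nrow(secreted),
                   full_length = sum(is_fl))
  side
}

#' Mine candidate effectors from EST libraries
#'
#' Runs the full selection cascade on a salivary-gland EST library:
#' six-frame ORF calling, the secretion gate (signal peptide plus
#' transmembrane exclusion, via the built-in predictors or parsed external
#' reports), redundancy clustering, full-length assessment against the full
#' same-species EST collection, the polymorphism filter against the other
#' species, cross-species reconciliation (shared candidates and additions
#' recovered through the other species), gut-contamination flagging,
#' chemosensory-motif annotation and naming, with stage-by-stage funnel
#' reports for both species.
#'
#' @param mp_salivary salivary-gland EST data frame of the focal species
#'   (from [read_fasta()]).
#' @param mp_all full EST collection of the focal species used as
#'   supporting evidence; defaults to `mp_salivary`.
#' @param mp_gut gut EST data frame for contamination flagging, or `NULL`.
#' @param ap_salivary salivary-gland ESTs of the other species, or `NULL`
#'   to run single-species.
#' @param config a [pipeline_config()].
#' @param signalp_report,tmhmm_report optional parsed predictor reports
#'   ([read_predictor_report()]); when `NULL` the built-in predictors are
#'   used.
#' @param legacy_names optional named character vector mapping candidate
#'   ids to historically established names.
#' @param matrix a [blosum62_matrix()].
#' @param params a [ka_params()].
#' @return An object of class `"effector_screen"`: a list with
#'   `candidates` (one row per named final candidate with provenance,
#'   cleavage, flags and motif annotation), `funnel` and `ap_funnel`
#'   ([build_funnel_report()] objects), `shared` (cross-species pairs),
#'   `mp_side` / `ap_side` (per-stage intermediates), and `config`.
#' @export
mine_effectors <- function(mp_salivary, mp_all = NULL, mp_gut = NULL,
                           ap_salivary = NULL,
                           config = pipeline_config(),
                           signalp_report = NULL, tmhmm_report = NULL,
                           legacy_names = NULL,
                           matrix = blosum62_matrix(),
                           params = ka_params()) {
  stopifnot(is.data.frame(mp_salivary), nrow(mp_salivary) >= 1L)
  if (is.null(mp_all)) mp_all <- mp_salivary
  # other-species ORF corpus for full-length criterion 3
  ap_orfp <- NULL
  mp_orfp_for_ap <- NULL
  if (!is.null(ap_salivary) && nrow(ap_salivary)) {
    ap_orfp <- orf_proteins(call_orfs_library(ap_salivary,
                                              min_len = config$min_orf_len))
  }
  mp_side <- .mine_side(mp_salivary, mp_all, config, matrix, params,
                        signalp_report, tmhmm_report,
                        other_orf_proteins = ap_orfp)
  ap_side <- NULL
  if (!is.null(ap_salivary) && nrow(ap_salivary)) {
    mp_orfp_for_ap <- mp_side$proteins
    ap_side <- .mine_side(ap_salivary, ap_salivary, config, matrix, params,
                          signalp_report, tmhmm_report,
                          other_orf_proteins = mp_orfp_for_ap)
  }

  # polymorphism filter on the focal species (the other species' secreted
  # mature proteins are the comparison corpus)
  mp_cands <- mp_side$candidates
  ap_mature <- if (!is.null(ap_side)) ap_side$secreted else NULL
  poly <- list()
  keep <- rep(TRUE, nrow(mp_cands))
  for (i in seq_len(nrow(mp_cands))) {
    ap_best <- NULL
    if (!is.null(ap_mature) && nrow(ap_mature)) {
      res <- .align_many(mp_cands$mature_seq[i], ap_mature$mature_seq,
                         matrix, params, detail = TRUE)
      res <- res[!res$flagged, , drop = FALSE]
      if (nrow(res)) {
        b <- which.min(res$evalue)
        ap_best <- list(
          evalue = res$evalue[b],
          n_diff = .alignment_diffs(res$aligned_query[b],
                                    res$aligned_subject[b]))
      }
    }
    pf <- polymorphism_filter(mp_cands$id[i],
                              mp_side$est_hits[[mp_cands$id[i]]],
                              ap_best, config)
    poly[[mp_cands$id[i]]] <- pf
    keep[i] <- pf$action == "keep"
  }
  mp_kept <- mp_cands[keep, , drop = FALSE]

  # cross-species reconciliation
  ap_cands <- if (!is.null(ap_side)) ap_side$candidates else NULL
  gate_fun <- function(seq, id) {
    .gate_protein(seq, id, config, signalp_report, tmhmm_report)
  }
  rec <- reconcile_cross_species(mp_kept, ap_cands, mp_all, config,
                                 gate_fun,
                                 exclude = mp_cands[!keep, , drop = FALSE],
                                 matrix = matrix, params = params)

  # additions recovered through the other species are held to the same
  # polymorphism criterion as pipeline candidates
  if (nrow(rec$added)) {
    frames_all <- mp_side$frames_all
    if (is.null(frames_all)) frames_all <- .frame_table(mp_all)
    keep_add <- vapply(seq_len(nrow(rec$added)), function(i) {
      hits <- .translated_hits(rec$added$seq[i], frames_all, matrix, params,
                               detail = TRUE)
      ap_best <- NULL
      if (!is.null(ap_mature) && nrow(ap_mature)) {
        mseq <- cleave(rec$added$seq[i],
                       rec$added$cleavage_site[i])$mature_seq
        res <- .align_many(mseq, ap_mature$mature_seq, matrix, params,
                           detail = TRUE)
        res <- res[!res$flagged, , drop = FALSE]
        if (nrow(res)) {
          b <- which.min(res$evalue)
          ap_best <- list(evalue = res$evalue[b],
                          n_diff = .alignment_diffs(res$aligned_query[b],
                                                    res$aligned_subject[b]))
        }
      }
      pf <- polymorphism_filter(rec$added$id[i], hits, ap_best, config)
      poly[[rec$added$id[i]]] <<- pf
      pf$action == "keep"
    }, TRUE)
    rec$added <- rec$added[keep_add, , drop = FALSE]
  }

  # final candidate table
  final <- mp_kept
  final$provenance <- rep("pipeline", nrow(final))
  final$via_ap_id <- NA_character_
  if (nrow(rec$added)) {
    add <- rec$added
    add$mature_seq <- vapply(seq_len(nrow(add)), function(i) {
      cleave(add$seq[i], add$cleavage_site[i])$mature_seq
    }, "")
    add$desc <- ""
    add$terminated_by_stop <- NA
    add$provenance <- "cross_species_addition"
    final <- rbind(final[, c("id", "seq", "source_est", "cleavage_site",
                             "sp_score", "mature_seq", "provenance",
                             "via_ap_id")],
                   add[, c("id", "seq", "source_est", "cleavage_site",
                           "sp_score", "mature_seq", "provenance",
                           "via_ap_id")])
  } else {
    final <- final[, c("id", "seq", "source_est", "cleavage_site",
                       "sp_score", "mature_seq", "provenance", "via_ap_id")]
  }
  rownames(final) <- NULL

  gut <- flag_gut_matches(final, mp_gut, config, matrix, params)
  final$gut_match <- unname(gut)
  final$shared_with_other_species <- final$id %in% rec$shared$mp_id |
    !is.na(final$via_ap_id)
  final$polymorphic <- vapply(final$id, function(id) {
    if (!is.null(poly[[id]])) poly[[id]]$variation else NA
  }, TRUE)
  final$full_length <- vapply(final$id, function(id) {
    if (!is.null(mp_side$fl_calls[[id]])) {
      mp_side$fl_calls[[id]]$is_full_length
    } else NA
  }, TRUE)
  final$csp_motif <- vapply(final$mature_seq, function(s) {
    scan_csp_motif(s)
  }, 0L, USE.NAMES = FALSE)
  final$name <- unname(name_candidates(final$id, species = "mp",
                                       legacy = legacy_names))
  final <- final[, c("name", setdiff(names(final), "name"))]

  funnel <- build_funnel_report(c(
    ests_in = nrow(mp_salivary),
    orfs_called = nrow(mp_side$orfs),
    with_signal_peptide_nonredundant = mp_side$counts[["nonredundant"]],
    with_tm_removed = mp_side$counts[["tm_removed"]],
    predicted_secreted = mp_side$counts[["tm_removed"]],
    full_length = mp_side$counts[["full_length"]],
    after_polymorphism_filter = nrow(mp_kept),
    added_cross_species = nrow(mp_kept) + nrow(rec$added),
    final_candidates = nrow(final)))
  ap_funnel <- NULL
  if (!is.null(ap_side)) {
    nfl <- ap_side$counts[["full_length"]]
    ap_funnel <- build_funnel_report(c(
      ests_in = nrow(ap_salivary),
      orfs_called = nrow(ap_side$orfs),
      with_signal_peptide_nonredundant = ap_side$counts[["nonredundant"]],
      with_tm_removed = ap_side$counts[["tm_removed"]],
      predicted_secreted = ap_side$counts[["tm_removed"]],
      full_length = nfl,
      after_polymorphism_filter = nfl,  # not applied to the other species
      added_cross_species = nfl,
      final_candidates = nfl))
  }

  structure(list(candidates = final, funnel = funnel, ap_funnel = ap_funnel,
                 shared = rec$shared, added = rec$added,
                 polymorphism = poly, mp_side = mp_side, ap_side = ap_side,
                 config = config), class = "effector_screen")
}

#' @export
print.effector_screen <- function(x, ...) {
  cat(sprintf("effector screen: %d final candidate(s)\n",
              nrow(x$candidates)))
  if (nrow(x$candidates)) {
    cat("  ", paste(utils::head(x$candidates$name, 12), collapse = ", "),
        if (nrow(x$candidates) > 12) ", ..." else "", "\n", sep = "")
  }
  print(x$funnel)
  invisible(x)
}

#' @export
summary.effector_screen <- function(object, ...) {
  print(object)
  if (!is.null(object$ap_funnel)) {
    cat("other-species ")
    print(object$ap_funnel)
  }
  cat(sprintf("shared across species: %d pair(s); added via other species: %d\n",
              nrow(object$shared), nrow(object$added)))
  flags <- object$candidates
  if (nrow(flags)) {
    cat(sprintf("gut matches: %d; CSP motif: %d\n",
                sum(flags$gut_match), sum(!is.na(flags$csp_motif))))
  }
  invisible(object)
}

#' Write the candidate table as TSV
#'
#' @param x an `"effector_screen"`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_candidates <- function(x, path) {
  stopifnot(inherits(x, "effector_screen"))
  df <- x$candidates
  df$length <- nchar(df$seq)
  cols <- c("name", "id", "source_est", "length", "cleavage_site",
            "sp_score", "full_length", "polymorphic",
            "shared_with_other_species", "gut_match", "csp_motif",
            "provenance")
  utils::write.table(df[, cols], path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
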