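# The candidate-selection cascade: redundancy clustering, full-length
# assessment, polymorphism filter, cross-species reconciliation,
# gut-contamination flagging, motif annotation, naming and the funnel
# report.

# columns at which two aligned (gapped) strings differ; gap columns count
.alignment_diffs <- function(aligned_a, aligned_b) {
  a <- strsplit(aligned_a, "", fixed = TRUE)[[1]]
  b <- strsplit(aligned_b, "", fixed = TRUE)[[1]]
  sum(a != b)
}

.FUNNEL_STAGES <- c("ests_in", "orfs_called",
                    "with_signal_peptide_nonredundant", "with_tm_removed",
                    "predicted_secreted", "full_length",
                    "after_polymorphism_filter", "added_cross_species",
                    "final_candidates")

#' Cluster redundant proteins
#'
#' Builds the redundancy graph (an edge joins two proteins when their local
#' alignment exceeds the identity cutoff at an E-value below the cutoff and
#' spans at least the configured fraction of the shorter sequence) and
#' returns its connected components (single linkage). The representative of
#' each cluster is its longest member, ties broken by lexicographically
#' smallest id.
#'
#' @param proteins protein data frame (`id`, `seq`).
#' @param config a [pipeline_config()].
#' @param matrix a [blosum62_matrix()].
#' @param params a [ka_params()].
#' @return A list of class `"redundancy_clusters"`: `membership` (data
#'   frame `id`, `cluster`, `is_representative`), `clusters` (list of
#'   `representative` / `members`), `edges` (the accepted pair table, one
#'   row per edge with the alignment statistics behind the decision).
#' @export
cluster_redundant <- function(proteins, config = pipeline_config(),
                              matrix = blosum62_matrix(),
                              params = ka_params()) {
  stopifnot(is.data.frame(proteins), nrow(proteins) >= 1L,
            !anyDuplicated(proteins$id))
  n <- nrow(proteins)
  lens <- nchar(proteins$seq)
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  edges <- vector("list", n)
  for (i in seq_len(n - 1L)) {
    if (n - i < 1L) break
    js <- (i + 1L):n
    res <- .align_many(proteins$seq[i], proteins$seq[js], matrix, params)
    cov_shorter <- ifelse(lens[i] <= lens[js],
                          res$coverage_query, res$coverage_subject)
    hit <- res$identity_pct > config$redundancy_identity &
      res$evalue < config$redundancy_evalue &
      cov_shorter >= config$redundancy_coverage
    if (any(hit)) {
      edges[[i]] <- data.frame(
        id_a = proteins$id[i], id_b = proteins$id[js[hit]],
        identity_pct = res$identity_pct[hit], evalue = res$evalue[hit],
        coverage_shorter = cov_shorter[hit], stringsAsFactors = FALSE)
      for (j in js[hit]) {
        ri <- find(i); rj <- find(j)
        if (ri != rj) parent[rj] <- ri
      }
    }
  }
  comp <- vapply(seq_len(n), find, 0L)
  comp <- match(comp, unique(comp))
  reps <- vapply(split(seq_len(n), comp), function(ix) {
    ix[order(-lens[ix], proteins$id[ix])][1]
  }, 0L)
  membership <- data.frame(id = proteins$id, cluster = comp,
                           is_representative =
                             seq_len(n) %in% reps,
                           stringsAsFactors = FALSE)
  clusters <- lapply(seq_along(reps), function(cl) {
    list(representative = proteins$id[reps[cl]],
         members = proteins$id[comp == cl])
  })
  edges <- if (any(!vapply(edges, is.null, TRUE))) {
    do.call(rbind, edges)
  } else {
    data.frame(id_a = character(0), id_b = character(0),
               identity_pct = numeric(0), evalue = numeric(0),
               coverage_shorter = numeric(0), stringsAsFactors = FALSE)
  }
  structure(list(membership = membership, clusters = clusters,
                 edges = edges), class = "redundancy_clusters")
}

#' @export
print.redundancy_clusters <- function(x, ...) {
  cat(sprintf("redundancy clustering: %d proteins in %d clusters (%d edges)\n",
              nrow(x$membership), length(x$clusters), nrow(x$edges)))
  invisible(x)
}

#' Assess whether a candidate is full length
#'
#' Applies the three full-length criteria to the supporting evidence:
#' (1) at least two same-species ESTs align over the candidate's entire
#' length with its start methionine matched and a stop codon conserved
#' immediately after the aligned end; (2) no supporting alignment shows an
#' in-frame methionine upstream of the predicted start (scanning the frame
#' translation upstream until a stop); (3) some other-species protein
#' annotated full-length is hit over at least 90% of its length. The
#' combining rule defaults to criterion 1 OR (criterion 2 AND criterion 3)
#' and is configurable (`fulllength_rule`).
#'
#' @param protein candidate protein (character sequence or record with
#'   `id`, `seq`).
#' @param est_hits per-EST best translated hits of the candidate against
#'   all same-species ESTs, as produced by the pipeline (data frame with
#'   `evalue`, `q_start`, `q_end`, `s_start`, `s_end`, `aligned_query`,
#'   `aligned_subject`, `frame_aa` columns).
#' @param ap_hits alignments against other-species proteins: data frame
#'   with `evalue`, `coverage_subject` and logical `subject_full_length`
#'   (may have zero rows).
#' @param config a [pipeline_config()].
#' @param id record id when `protein` is a bare sequence.
#' @return A list of class `"fulllength_call"`: `protein_id`,
#'   `criterion1_start_stop`, `criterion2_no_upstream_met`,
#'   `criterion3_ap_support`, `n_supporting_ests`, `is_full_length`.
#' @export
assess_full_length <- function(protein, est_hits, ap_hits = NULL,
                               config = pipeline_config(), id = "protein") {
  p <- .as_protein(protein, id)
  qlen <- nchar(.clean_aa(p$seq))
  sup <- est_hits[!is.na(est_hits$evalue) &
                    est_hits$evalue < config$homolog_evalue, , drop = FALSE]
  c1 <- FALSE; c2 <- FALSE
  n1 <- 0L
  if (nrow(sup)) {
    full_span <- sup$q_start == 1L & sup$q_end == qlen
    start_met <- substr(sup$aligned_subject, 1L, 1L) == "M"
    stop_after <- sup$s_end + 1L <= nchar(sup$frame_aa) &
      substr(sup$frame_aa, sup$s_end + 1L, sup$s_end + 1L) == "*"
    n1 <- sum(full_span & start_met & stop_after)
    c1 <- n1 >= 2L
    covers_start <- sup$q_start == 1L
    upstream_met <- vapply(which(covers_start), function(i) {
      up <- substr(sup$frame_aa[i], 1L, sup$s_start[i] - 1L)
      # only the stretch after the last in-frame stop is candidate coding
      seg <- sub(".*\\*", "", up)
      grepl("M", seg, fixed = TRUE)
    }, TRUE)
    c2 <- !any(upstream_met)
  }
  c3 <- FALSE
  if (!is.null(ap_hits) && nrow(ap_hits)) {
    c3 <- any(ap_hits$evalue < config$homolog_evalue &
                ap_hits$subject_full_length &
                ap_hits$coverage_subject >= 0.9)
  }
  is_fl <- switch(config$fulllength_rule,
                  c1_or_c2and3 = c1 || (c2 && c3),
                  any = c1 || c2 || c3,
                  all = c1 && c2 && c3)
  structure(list(protein_id = p$id, criterion1_start_stop = c1,
                 criterion2_no_upstream_met = c2,
                 criterion3_ap_support = c3, n_supporting_ests = n1,
                 is_full_length = is_fl), class = "fulllength_call")
}

#' Polymorphism (diversifying-selection) filter
#'
#' A candidate is removed when its same-species EST alignments show no
#' amino-acid variation at all and its best other-species mature-region
#' alignment differs by at most `max_ap_mature_diff` residues. Candidates
#' with no other-species hit are kept only when same-species variation
#' exists (conserved orphans offer no evidence of diversifying selection).
#' Only alignments at or above `variation_min_identity` percent identity
#' count as same-gene evidence; weaker hits (e.g. shared signal peptides
#' of unrelated proteins) are not sequence variation.
#'
#' @param candidate_id candidate id (for the returned record).
#' @param mp_hits same-species translated-hit table as in
#'   [assess_full_length()] (aligned strings required).
#' @param ap_best best other-species mature-region alignment: a list with
#'   `evalue` and `n_diff` (mismatch plus gap columns), or `NULL` when no
#'   hit exists.
#' @param config a [pipeline_config()].
#' @return A list: `protein_id`, `action` (`"keep"`/`"drop"`), `reason`,
#'   `variation` (logical), `ap_diff` (integer or `NA`).
#' @export
polymorphism_filter <- function(candidate_id, mp_hits, ap_best = NULL,
                                config = pipeline_config()) {
  sup <- mp_hits[!is.na(mp_hits$evalue) &
                   mp_hits$evalue < config$homolog_evalue &
                   mp_hits$identity_pct >= config$variation_min_identity, ,
                 drop = FALSE]
  variation <- FALSE
  if (nrow(sup)) {
    diffs <- vapply(seq_len(nrow(sup)), function(i) {
      .alignment_diffs(sup$aligned_query[i], sup$aligned_subject[i])
    }, 0)
    variation <- any(diffs > 0)
  }
  ap_ok <- !is.null(ap_best) && !is.na(ap_best$evalue) &&
    ap_best$evalue < config$homolog_evalue
  ap_diff <- if (ap_ok) as.integer(ap_best$n_diff) else NA_integer_
  if (ap_ok) {
    drop <- !variation && ap_diff <= config$max_ap_mature_diff
    reason <- if (drop) "monomorphic_conserved" else
      if (variation) "same_species_variation" else "other_species_divergent"
  } else {
    drop <- !variation
    reason <- if (drop) "no_other_species_hit_no_variation" else
      "same_species_variation"
  }
  list(protein_id = candidate_id,
       action = if (drop) "drop" else "keep",
       reason = reason, variation = variation, ap_diff = ap_diff)
}

#' Scan for the chemosensory-protein cysteine motif
#'
#' Finds occurrences of the conserved four-cysteine spacing
#' C-x6-C-x18-C-x2-C characteristic of insect chemosensory proteins.
#'
#' @param seq amino-acid sequence.
#' @param all return all match start positions rather than the first.
#' @return 1-based start position(s) of the motif; `NA_integer_` (or an
#'   empty vector with `all = TRUE`) when absent.
#' @export
#' @examples
#' scan_csp_motif(paste0(strrep("A", 10), "C", strrep("A", 6), "C",
#'                       strrep("A", 18), "C", strrep("A", 2), "C"))
scan_csp_motif <- function(seq, all = FALSE) {
  res <- strsplit(toupper(seq), "", fixed = TRUE)[[1]]
  n <- length(res)
  hits <- integer(0)
  if (n >= 30L) {
    p <- which(res == "C")
    p <- p[p + 29L <= n]
    hits <- p[res[p + 7L] == "C" & res[p + 26L] == "C" & res[p + 29L] == "C"]
  }
  if (all) hits else if (length(hits)) hits[1] else NA_integer_
}

#' Flag candidates matching gut ESTs
#'
#' A candidate whose best translated hit against the gut EST library has an
#' E-value below `gut_evalue` is flagged as a possible salivary-gland
#' contaminant of the gut libraries (or vice versa) rather than removed.
#'
#' @param candidates candidate data frame (`id`, `seq`).
#' @param gut_ests gut EST data frame (`id`, `seq`), or `NULL`.
#' @param config a [pipeline_config()].
#' @param matrix,params alignment settings.
#' @return Named logical vector, one entry per candidate.
#' @export
flag_gut_matches <- function(candidates, gut_ests,
                             config = pipeline_config(),
                             matrix = blosum62_matrix(),
                             params = ka_params()) {
  out <- setNames(rep(FALSE, nrow(candidates)), candidates$id)
  if (is.null(gut_ests) || nrow(gut_ests) == 0L || nrow(candidates) == 0L) {
    return(out)
  }
  frames <- .frame_table(gut_ests)
  for (i in seq_len(nrow(candidates))) {
    hits <- .translated_hits(candidates$seq[i], frames, matrix, params,
                             detail = FALSE)
    out[i] <- nrow(hits) > 0L && min(hits$evalue) < config$gut_evalue
  }
  out
}

#' Reconcile candidate sets across the two species
#'
#' Pairs candidates of the two species whose local alignment E-value falls
#' below `overlap_evalue` ("shared" candidates). Each unmatched
#' other-species candidate is then translated-searched against the full
#' same-species EST collection; when a hit EST carries an ORF overlapping
#' the hit whose translation passes the secretion gate, that protein is
#' added to the same-species candidate set.
#'
#' @param mp_candidates same-species candidate data frame (`id`, `seq`).
#' @param ap_candidates other-species candidate data frame (`id`, `seq`).
#' @param mp_all_ests full same-species EST data frame.
#' @param config a [pipeline_config()].
#' @param gate_fun function(seq, id) applying the secretion gate to a
#'   candidate protein, returning a list with `pass`, `call` (signal
#'   peptide) and `topo`; defaults to the built-in predictors.
#' @param exclude optional protein data frame (`id`, `seq`) of sequences
#'   that must not re-enter as additions (e.g. candidates already removed
#'   by the polymorphism filter); an addition redundant with any of them
#'   is skipped.
#' @param matrix,params alignment settings.
#' @return A list: `shared` (data frame `ap_id`, `mp_id`, `evalue`),
#'   `added` (data frame of added candidates: `id`, `seq`, `source_est`,
#'   `cleavage_site`, `sp_score`, `via_ap_id`).
#' @export
reconcile_cross_species <- function(mp_candidates, ap_candidates,
                                    mp_all_ests,
                                    config = pipeline_config(),
                                    gate_fun = NULL, exclude = NULL,
                                    matrix = blosum62_matrix(),
                                    params = ka_params()) {
  if (is.null(gate_fun)) {
    gate_fun <- function(seq, id) {
      call <- predict_signal_peptide(seq, id = id)
      topo <- if (!is.na(call$cleavage_site) &&
                  call$cleavage_site < nchar(seq)) {
        detect_tm_builtin(seq, call$cleavage_site, id = id)
      } else NULL
      g <- passes_secretion_gate(call, topo, config)
      list(pass = g$pass, call = call, topo = topo)
    }
  }
  empty_shared <- data.frame(ap_id = character(0), mp_id = character(0),
                             evalue = numeric(0), stringsAsFactors = FALSE)
  empty_added <- data.frame(id = character(0), seq = character(0),
                            source_est = character(0),
                            cleavage_site = integer(0),
                            sp_score = numeric(0), via_ap_id = character(0),
                            stringsAsFactors = FALSE)
  if (is.null(ap_candidates) || nrow(ap_candidates) == 0L) {
    return(list(shared = empty_shared, added = empty_added))
  }
  shared <- empty_shared
  matched <- rep(FALSE, nrow(ap_candidates))
  if (nrow(mp_candidates)) {
    for (i in seq_len(nrow(ap_candidates))) {
      res <- .align_many(ap_candidates$seq[i], mp_candidates$seq,
                         matrix, params)
      hit <- which(res$evalue < config$overlap_evalue)
      if (length(hit)) {
        matched[i] <- TRUE
        shared <- rbind(shared, data.frame(
          ap_id = ap_candidates$id[i], mp_id = mp_candidates$id[hit],
          evalue = res$evalue[hit], stringsAsFactors = FALSE))
      }
    }
  }
  added <- empty_added
  un <- which(!matched)
  if (length(un) && !is.null(mp_all_ests) && nrow(mp_all_ests)) {
    frames <- .frame_table(mp_all_ests)
    for (i in un) {
      hits <- .translated_hits(ap_candidates$seq[i], frames, matrix, params,
                               detail = FALSE)
      hits <- hits[hits$evalue < config$homolog_evalue, , drop = FALSE]
      if (!nrow(hits)) next
      hits <- hits[order(hits$evalue), , drop = FALSE]
      for (h in seq_len(nrow(hits))) {
        est <- mp_all_ests[mp_all_ests$id == hits$est_id[h], , drop = FALSE]
        nt <- .aa_span_to_nt(hits$s_start[h], hits$s_end[h],
                             hits$strand[h], hits$frame[h],
                             nchar(est$seq))
        orfs <- call_orfs(est, min_len = config$min_orf_len)
        if (!nrow(orfs)) next
        ov <- orfs$strand == hits$strand[h] &
          orfs$start_nt < nt[2] & orfs$end_nt > nt[1]
        orfs <- orfs[ov, , drop = FALSE]
        if (!nrow(orfs)) next
        orfs <- orfs[order(-(nchar(orfs$aa_seq))), , drop = FALSE]
        done <- FALSE
        for (o in seq_len(nrow(orfs))) {
          oid <- orf_ids(orfs[o, , drop = FALSE])
          g <- gate_fun(orfs$aa_seq[o], oid)
          if (!isTRUE(g$pass)) next
          # skip proteins redundant with existing candidates, with anything
          # already rejected, or with earlier additions
          pool <- rbind(mp_candidates[, c("id", "seq")],
                        if (!is.null(exclude) && nrow(exclude)) {
                          exclude[, c("id", "seq")]
                        },
                        added[, c("id", "seq")])
          if (nrow(pool)) {
            res <- .align_many(orfs$aa_seq[o], pool$seq, matrix, params)
            lens <- nchar(pool$seq)
            cov_shorter <- ifelse(nchar(orfs$aa_seq[o]) <= lens,
                                  res$coverage_query, res$coverage_subject)
            if (any(res$identity_pct > config$redundancy_identity &
                      res$evalue < config$redundancy_evalue &
                      cov_shorter >= config$redundancy_coverage)) {
              done <- TRUE  # already represented; stop searching this ap cand
              break
            }
          }
          added <- rbind(added, data.frame(
            id = oid, seq = orfs$aa_seq[o], source_est = est$id,
            cleavage_site = g$call$cleavage_site, sp_score = g$call$score,
            via_ap_id = ap_candidates$id[i], stringsAsFactors = FALSE))
          done <- TRUE
          break
        }
        if (done) break
      }
    }
  }
  rownames(shared) <- rownames(added) <- NULL
  list(shared = shared, added = added)
}

#' Assign candidate names
#'
#' Names are the species prefix (`Mp` / `Ap`) followed by a serial number
#' in input order. Historically established names can be supplied as a
#' mapping from candidate id to legacy name and take precedence.
#'
#' @param ids candidate ids, in the order names are to be assigned.
#' @param species `"mp"` or `"ap"`.
#' @param legacy optional named character vector mapping ids to legacy
#'   names (e.g. `c("est42|+|0|12-330|complete:1" = "MpC002")`).
#' @return Character vector of unique names, parallel to `ids`.
#' @export
name_candidates <- function(ids, species = c("mp", "ap"), legacy = NULL) {
  species <- match.arg(species)
  prefix <- c(mp = "Mp", ap = "Ap")[species]
  nm <- paste0(prefix, seq_along(ids))
  if (!is.null(legacy)) {
    hit <- ids %in% names(legacy)
    nm[hit] <- unname(legacy[ids[hit]])
  }
  if (anyDuplicated(nm)) stop("candidate names are not unique")
  setNames(nm, ids)
}

#' Build the funnel report
#'
#' Records the per-stage candidate counts of the mining cascade in pipeline
#' order. Every filter stage must not increase the count; the cross-species
#' addition stage is the only one allowed to.
#'
#' @param stages named list or vector containing every stage count:
#'   `ests_in`, `orfs_called`, `with_signal_peptide_nonredundant`,
#'   `with_tm_removed`, `predicted_secreted`, `full_length`,
#'   `after_polymorphism_filter`, `added_cross_species`,
#'   `final_candidates`.
#' @return A named integer vector of class `"funnel_report"`.
#' @export
build_funnel_report <- function(stages) {
  stages <- unlist(stages)
  missing <- setdiff(.FUNNEL_STAGES, names(stages))
  if (length(missing)) {
    stop("stage missing from funnel report: ",
         paste(missing, collapse = ", "))
  }
  out <- as.integer(stages[.FUNNEL_STAGES])
  if (any(out < 0)) stop("funnel counts must be non-negative")
  names(out) <- .FUNNEL_STAGES
  class(out) <- "funnel_report"
  out
}

#' Check funnel monotonicity
#'
#' @param x a `"funnel_report"`.
#' @return `TRUE` when no stage after ORF calling increases the count
#'   except the cross-species addition stage.
#' @export
funnel_is_monotone <- function(x) {
  v <- unclass(x)
  filt <- .FUNNEL_STAGES[-(1:2)]  # counts from nonredundant SP+ onwards
  v <- v[filt]
  d <- diff(v)
  inc_ok <- names(v)[-1] == "added_cross_species"
  all(d <= 0 | inc_ok)
}

#' @export
print.funnel_report <- function(x, ...) {
  cat("candidate-mining funnel\n")
  v <- unclass(x)
  for (nm in names(v)) cat(sprintf("  %-34s %6d\n", nm, v[[nm]]))
  invisible(x)
}

#' Write a funnel report as JSON
#'
#' An ordered array of `{stage, count}` objects.
#'
#' @param x a `"funnel_report"`.
#' @param path output path, or `NULL` to return the JSON string.
#' @return The path (invisibly) or the JSON string.
#' @export
funnel_to_json <- function(x, path = NULL) {
  df <- data.frame(stage = names(unclass(x)), count = as.integer(x),
                   stringsAsFactors = FALSE)
  js <- jsonlite::toJSON(df, auto_unbox = TRUE, pretty = TRUE)
  if (is.null(path)) return(as.character(js))
  writeLines(as.character(js), path)
  invisible(path)
}
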