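# Local protein alignment, E-value surrogate, and translated search.
#
# Pairwise alignment is Smith-Waterman with affine gaps, delegated to
# Biostrings::pairwiseAlignment (a C implementation) with the published
# BLOSUM62 matrix and BLASTP-default gap costs (open 11, extend 1). The
# E-value is the Karlin-Altschul surrogate E = K * m * n * exp(-lambda * S)
# with the published gapped-BLOSUM62 constants; it carries the semantics of
# the printed BLAST thresholds, not their exact values. The exhaustive
# all-vs-all strategy replaces heuristic BLAST seeding: at the scale of
# these datasets (thousands of proteins at most) that is tractable and
# removes an external binary.

.B62_CACHE <- NULL

#' BLOSUM62 substitution matrix with BLAST-default gap costs
#'
#' The published BLOSUM62 scores (including the X row) with the stop
#' sentinel `*` rescored to -4 against everything (including itself), so
#' that frame translations crossing a stop can never gain score through it.
#'
#' @param gap_open positive gap-opening cost (default 11).
#' @param gap_extend positive gap-extension cost (default 1); a gap of
#'   length L costs `gap_open + L * gap_extend`.
#' @return A list of class `"subst_matrix"`: `name`, `scores` (integer
#'   matrix), `gap_open`, `gap_extend`.
#' @export
blosum62_matrix <- function(gap_open = 11L, gap_extend = 1L) {
  stopifnot(gap_open > 0, gap_extend > 0)
  if (is.null(.B62_CACHE)) {
    e <- new.env()
    utils::data("BLOSUM62", package = "Biostrings", envir = e)
    m <- e$BLOSUM62
    m["*", ] <- -4L
    m[, "*"] <- -4L
    utils::assignInMyNamespace(".B62_CACHE", m)
  }
  structure(list(name = "BLOSUM62", scores = .B62_CACHE,
                 gap_open = as.integer(gap_open),
                 gap_extend = as.integer(gap_extend)),
            class = "subst_matrix")
}

#' Karlin-Altschul parameters for the E-value surrogate
#'
#' Defaults are the published constants for gapped BLOSUM62 with gap costs
#' 11/1 (lambda = 0.267, K = 0.041).
#'
#' @param lambda positive scale parameter.
#' @param K positive search-space constant.
#' @return A list of class `"ka_params"`.
#' @export
ka_params <- function(lambda = 0.267, K = 0.041) {
  stopifnot(lambda > 0, K > 0)
  structure(list(lambda = lambda, K = K), class = "ka_params")
}

#' Karlin-Altschul E-value surrogate
#'
#' `E = K * m * n * exp(-lambda * S)`: the expected number of chance local
#' alignments scoring at least S between a query of length m and a subject
#' search space of length n. Monotone decreasing in S and exactly linear in
#' both lengths.
#'
#' @param score raw alignment score S (non-negative).
#' @param m query length (residues).
#' @param n subject (search-space) length.
#' @param params a [ka_params()] object.
#' @return The E-value (positive real), vectorized over `score`.
#' @export
#' @examples
#' evalue(100, 200, 1e5)
evalue <- function(score, m, n, params = ka_params()) {
  stopifnot(all(score >= 0), m >= 1, n >= 1)
  params$K * m * n * exp(-params$lambda * score)
}

.as_protein <- function(x, id) {
  if (is.data.frame(x)) {
    stopifnot(nrow(x) == 1L)
    list(id = x$id, seq = x$seq)
  } else if (is.list(x)) {
    list(id = x$id, seq = x$seq)
  } else {
    list(id = id, seq = x)
  }
}

# strip a single trailing stop, uppercase
.clean_aa <- function(seq) sub("\\*$", "", toupper(seq))

# core vectorized local alignment of one query against many subjects;
# returns a data.frame, plus aligned strings when detail = TRUE
.align_many <- function(query_seq, subject_seqs, matrix, params,
                        detail = FALSE) {
  qs <- .clean_aa(query_seq)
  ss <- .clean_aa(subject_seqs)
  m <- nchar(qs)
  ns <- nchar(ss)
  pa <- Biostrings::pairwiseAlignment(
    pattern = Biostrings::AAStringSet(ss),
    subject = Biostrings::AAString(qs),
    type = "local", substitutionMatrix = matrix$scores,
    gapOpening = matrix$gap_open, gapExtension = matrix$gap_extend)
  sc <- Biostrings::score(pa)
  flagged <- sc <= 0
  sc <- pmax(sc, 0)
  # "pattern" side = subjects, "subject" side = query
  q_start <- BiocGenerics::start(Biostrings::subject(pa))
  q_end <- BiocGenerics::end(Biostrings::subject(pa))
  s_start <- BiocGenerics::start(Biostrings::pattern(pa))
  s_end <- BiocGenerics::end(Biostrings::pattern(pa))
  ident <- Biostrings::pid(pa, type = "PID1")
  ident[flagged] <- 0
  out <- data.frame(
    score = sc,
    identity_pct = ident,
    coverage_query = ifelse(flagged, 0, (q_end - q_start + 1) / m),
    coverage_subject = ifelse(flagged, 0, (s_end - s_start + 1) / ns),
    q_start = ifelse(flagged, NA_integer_, q_start),
    q_end = ifelse(flagged, NA_integer_, q_end),
    s_start = ifelse(flagged, NA_integer_, s_start),
    s_end = ifelse(flagged, NA_integer_, s_end),
    evalue = evalue(sc, m, pmax(ns, 1L), params),
    flagged = flagged,
    stringsAsFactors = FALSE)
  if (detail) {
    out$aligned_query <- as.character(Biostrings::subject(pa))
    out$aligned_subject <- as.character(Biostrings::pattern(pa))
  }
  out
}

#' Local pairwise protein alignment
#'
#' Optimal Smith-Waterman alignment with affine gaps. Percent identity is
#' computed over all alignment columns including gaps; coverage is the
#' aligned span divided by the full sequence length. Sequences consisting
#' only of X (or any pair admitting no positive-scoring alignment) yield a
#' flagged score-0 result.
#'
#' @param a,b proteins: character sequences, or records with `id`, `seq`.
#' @param matrix a [blosum62_matrix()] (or compatible `"subst_matrix"`).
#' @param params a [ka_params()] for the E-value.
#' @return A one-row data frame: `query_id`, `subject_id`, `score`,
#'   `identity_pct`, `coverage_query`, `coverage_subject`, `q_start`,
#'   `q_end`, `s_start`, `s_end` (1-based inclusive spans), `evalue`,
#'   `flagged`.
#' @export
#' @examples
#' align_local("MKVLHEAGRS", "MKVLHEAGRS")
align_local <- function(a, b, matrix = blosum62_matrix(),
                        params = ka_params()) {
  pa <- .as_protein(a, "query")
  pb <- .as_protein(b, "subject")
  stopifnot(nzchar(pa$seq), nzchar(pb$seq))
  out <- .align_many(pa$seq, pb$seq, matrix, params)
  cbind(data.frame(query_id = pa$id, subject_id = pb$id,
                   stringsAsFactors = FALSE), out)
}

# six frame translations of a nucleotide sequence; strand/frame/aa plus the
# forward-strand nt offset bookkeeping needed to map aa spans back
.six_frames <- function(seq) {
  seq <- toupper(seq)
  n <- nchar(seq)
  rows <- vector("list", 6L)
  i <- 0L
  for (strand in c("+", "-")) {
    s <- if (strand == "+") seq else .revcomp(seq)
    for (off in 0:2) {
      i <- i + 1L
      tr <- .translate_frame(s, off)
      rows[[i]] <- list(strand = strand, frame = off,
                        aa = paste(tr$aa, collapse = ""))
    }
  }
  rows
}

# map an aa interval [a1, a2] (1-based, within a frame translation) to a
# forward-strand 0-based half-open nt interval
.aa_span_to_nt <- function(a1, a2, strand, frame, n) {
  s0 <- frame + 3L * (a1 - 1L)
  s1 <- frame + 3L * a2
  if (strand == "+") c(s0, s1) else c(n - s1, n - s0)
}

#' Translated (protein versus six-frame nucleotide) search
#'
#' Aligns a protein query against all six frame translations of a
#' nucleotide subject (stops translated as the sentinel `*`, which scores
#' -4 against everything) and reports the best frame. The E-value uses the
#' subject's nucleotide length as the search-space size.
#'
#' @param query protein: character sequence or record with `id`, `seq`.
#' @param subject EST: character sequence or record with `id`, `seq`.
#' @param matrix a [blosum62_matrix()].
#' @param params a [ka_params()].
#' @return A one-row data frame as for [align_local()] plus `strand`,
#'   `frame` (of the best-scoring frame), with `s_start`/`s_end` giving the
#'   1-based inclusive span within that frame translation and
#'   `s_nt_start`/`s_nt_end` the corresponding 0-based half-open interval
#'   on the subject's forward strand.
#' @export
translated_search <- function(query, subject, matrix = blosum62_matrix(),
                              params = ka_params()) {
  pq <- .as_protein(query, "query")
  ps <- .as_protein(subject, "subject")
  stopifnot(nchar(ps$seq) >= 3L)
  frames <- .six_frames(ps$seq)
  aa <- vapply(frames, `[[`, "", "aa")
  nonempty <- nzchar(aa)
  res <- .align_many(pq$seq, aa[nonempty], matrix, params)
  # E-value against the nucleotide length, not the frame length
  res$evalue <- evalue(res$score, nchar(.clean_aa(pq$seq)),
                       nchar(ps$seq), params)
  best <- which.max(res$score)  # ties -> first frame in fixed order
  fr <- frames[nonempty][[best]]
  row <- res[best, , drop = FALSE]
  nt <- if (row$flagged) c(NA_integer_, NA_integer_) else
    .aa_span_to_nt(row$s_start, row$s_end, fr$strand, fr$frame,
                   nchar(ps$seq))
  out <- cbind(data.frame(query_id = pq$id, subject_id = ps$id,
                          strand = fr$strand, frame = fr$frame,
                          stringsAsFactors = FALSE), row)
  out$s_nt_start <- nt[1]
  out$s_nt_end <- nt[2]
  rownames(out) <- NULL
  out
}

# --- batch machinery used by the pipeline ---------------------------------

# precompute frame translations for a whole EST library
.frame_table <- function(ests) {
  rows <- lapply(seq_len(nrow(ests)), function(i) {
    frames <- .six_frames(ests$seq[i])
    data.frame(est_id = ests$id[i],
               est_len = nchar(ests$seq[i]),
               strand = vapply(frames, `[[`, "", "strand"),
               frame = vapply(frames, function(f) f$frame, 0L),
               aa = vapply(frames, `[[`, "", "aa"),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out[nzchar(out$aa), , drop = FALSE]
}

# best translated hit of one query against every EST in a frame table;
# returns one row per EST that has any positive alignment, with aligned
# strings and the frame translation retained for downstream inspection
.translated_hits <- function(query_seq, frame_table, matrix, params,
                             detail = TRUE) {
  res <- .align_many(query_seq, frame_table$aa, matrix, params,
                     detail = detail)
  res$evalue <- evalue(res$score, nchar(.clean_aa(query_seq)),
                       frame_table$est_len, params)
  res$est_id <- frame_table$est_id
  res$strand <- frame_table$strand
  res$frame <- frame_table$frame
  res$frame_aa <- frame_table$aa
  res$est_len <- frame_table$est_len
  res <- res[!res$flagged, , drop = FALSE]
  if (nrow(res) == 0L) return(res)
  # best frame per EST (ties: first in the fixed frame order)
  res <- res[order(match(res$est_id, unique(frame_table$est_id)),
                   -res$score), , drop = FALSE]
  res <- res[!duplicated(res$est_id), , drop = FALSE]
  rownames(res) <- NULL
  res
}
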