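# Secretion gate: signal-peptide scoring, transmembrane detection, cleavage.
#
# The built-in predictors are deliberately simple, fully specified scoring
# rules so the pipeline is buildable and deterministic without licensed
# binaries; they make no claim of equivalence to SignalP or TMHMM. Real
# reproductions should feed parsed external reports (see
# read_predictor_report), which are interchangeable with the built-ins at
# the type level.

#' Kyte-Doolittle hydropathy scale
#'
#' The standard published per-residue hydropathy values; `X` and `*` score
#' 0.
#'
#' @return Named numeric vector over the amino-acid alphabet.
#' @export
kyte_doolittle <- function() {
  c(A = 1.8, R = -4.5, N = -3.5, D = -3.5, C = 2.5, Q = -3.5, E = -3.5,
    G = -0.4, H = -3.2, I = 4.5, L = 3.8, K = -3.9, M = 1.9, F = 2.8,
    P = -1.6, S = -0.8, T = -0.7, W = -0.9, Y = -1.3, V = 4.2,
    X = 0, "*" = 0)
}

.kd_values <- function(seq) {
  v <- kyte_doolittle()[strsplit(seq, "", fixed = TRUE)[[1]]]
  v[is.na(v)] <- 0
  unname(v)
}

.window_means <- function(v, w) {
  n <- length(v)
  if (n < w) return(numeric(0))
  cs <- cumsum(c(0, v))
  (cs[(w + 1):(n + 1)] - cs[1:(n - w + 1)]) / w
}

.SMALL_RES <- c("A", "G", "S", "C", "T")

#' Predict a signal peptide
#'
#' With `backend = "builtin"`, scores the N-terminus with a deterministic
#' heuristic: the product of three sub-scores in \[0,1\] --
#' (i) n-region charge, the count of K/R minus D/E in residues 1-5 passed
#' through a logistic centred at +1; (ii) h-region hydrophobicity, the
#' maximum mean Kyte-Doolittle hydropathy over length-8 windows within
#' residues 3-25, rescaled so 1.6 maps to 0.5 and 3.0 to 1.0 (clamped to
#' \[0,1\]); and (iii) the (-3,-1) cleavage rule, the presence of small
#' residues (A/G/S/C/T) at positions -1 and -3 relative to the best
#' cleavage position in 16-30 (1.0 both, 0.6 one, 0.2 none; ties broken
#' towards the smallest position). Proteins shorter than 25 residues score
#' 0. With `backend = "report"`, score and cleavage site are copied
#' verbatim from a parsed `signalp3_short` report.
#'
#' @param protein a protein: character sequence, or a one-row data frame /
#'   list with `id` and `seq`.
#' @param backend `"builtin"` or `"report"`.
#' @param report parsed report data frame (required for
#'   `backend = "report"`).
#' @param id record id used when `protein` is a bare sequence.
#' @return A list of class `"sp_call"`: `protein_id`, `score`,
#'   `cleavage_site` (1-based index of the last signal-peptide residue),
#'   `source`.
#' @export
#' @examples
#' predict_signal_peptide(paste0("MKKLLLLLLLLLLLLLAHAAS", strrep("G", 60)))
predict_signal_peptide <- function(protein,
                                   backend = c("builtin", "report"),
                                   report = NULL, id = "protein") {
  backend <- match.arg(backend)
  if (is.data.frame(protein) || is.list(protein)) {
    id <- protein$id
    seq <- protein$seq
  } else {
    seq <- protein
  }
  if (backend == "report") {
    stopifnot(is.data.frame(report))
    i <- match(id, report$protein_id)
    if (is.na(i)) stop("protein id missing from signal-peptide report: ", id)
    return(structure(list(protein_id = id, score = report$score[i],
                          cleavage_site = report$cleavage_site[i],
                          source = "parsed_report"), class = "sp_call"))
  }
  n <- nchar(seq)
  if (n < 25L) {
    return(structure(list(protein_id = id, score = 0,
                          cleavage_site = NA_integer_,
                          source = "builtin_heuristic"), class = "sp_call"))
  }
  res <- strsplit(seq, "", fixed = TRUE)[[1]]
  # (i) n-region charge
  net <- sum(res[1:5] %in% c("K", "R")) - sum(res[1:5] %in% c("D", "E"))
  s_charge <- 1 / (1 + exp(-2.5 * (net - 1)))
  # (ii) h-region hydrophobicity
  kd <- .kd_values(seq)
  h <- max(.window_means(kd[3:25], 8L))
  s_hydro <- min(max(0.5 + 0.5 * (h - 1.6) / 1.4, 0), 1)
  # (iii) (-3,-1) cleavage rule
  cand <- 16:min(30L, n - 1L)
  cscore <- vapply(cand, function(c) {
    hits <- sum(res[c] %in% .SMALL_RES, res[c - 2L] %in% .SMALL_RES)
    c(0.2, 0.6, 1.0)[hits + 1L]
  }, 0)
  best <- which.max(cscore)  # ties -> smallest position
  structure(list(protein_id = id,
                 score = s_charge * s_hydro * cscore[best],
                 cleavage_site = cand[best],
                 source = "builtin_heuristic"), class = "sp_call")
}

#' @export
print.sp_call <- function(x, ...) {
  cat(sprintf("signal-peptide call for %s: score %.3f, cleavage %s (%s)\n",
              x$protein_id, x$score,
              ifelse(is.na(x$cleavage_site), "NA", x$cleavage_site),
              x$source))
  invisible(x)
}

#' Detect transmembrane segments in the mature region
#'
#' Slides a 19-residue window over the mature region (positions strictly
#' after the cleavage site); any window with mean Kyte-Doolittle hydropathy
#' above 1.6 seeds a segment, overlapping seeds are merged, and merged
#' segments shorter than 15 residues are discarded. Signal peptides are
#' hydrophobic by design, so the signal region is excluded by construction.
#'
#' @param protein protein sequence (character) or record with `id`, `seq`.
#' @param cleavage_site 1-based index of the last signal-peptide residue.
#' @param id record id when `protein` is a bare sequence.
#' @return A list of class `"topology_call"`: `protein_id`, `tm_segments`
#'   (two-column matrix of 1-based inclusive intervals in full-protein
#'   coordinates), `has_tm_in_mature`.
#' @export
detect_tm_builtin <- function(protein, cleavage_site, id = "protein") {
  if (is.data.frame(protein) || is.list(protein)) {
    id <- protein$id
    seq <- protein$seq
  } else {
    seq <- protein
  }
  n <- nchar(seq)
  k <- as.integer(cleavage_site)
  stopifnot(k >= 1L, k < n)
  kd <- .kd_values(seq)
  mature_kd <- kd[(k + 1L):n]
  means <- .window_means(mature_kd, 19L)
  seeds <- which(means > 1.6)
  segs <- matrix(integer(0), ncol = 2,
                 dimnames = list(NULL, c("start", "end")))
  if (length(seeds)) {
    # merge overlapping seed windows
    starts <- k + seeds          # window covers [start, start+18]
    ends <- starts + 18L
    brk <- c(TRUE, starts[-1] > ends[-length(ends)] + 0L)
    grp <- cumsum(brk)
    segs <- cbind(start = tapply(starts, grp, min),
                  end = tapply(ends, grp, max))
    segs <- segs[segs[, 2] - segs[, 1] + 1L >= 15L, , drop = FALSE]
    rownames(segs) <- NULL
  }
  structure(list(protein_id = id, tm_segments = segs,
                 has_tm_in_mature = nrow(segs) > 0L),
            class = "topology_call")
}

#' Build a topology call from a parsed report row
#'
#' A transmembrane domain "in addition to the signal peptide" is any
#' reported segment ending strictly after the cleavage site.
#'
#' @param protein_id protein id.
#' @param tm_segments two-column (start, end) matrix of 1-based inclusive
#'   intervals.
#' @param cleavage_site 1-based index of the last signal-peptide residue.
#' @return A `"topology_call"` list as for [detect_tm_builtin()].
#' @export
topology_from_report <- function(protein_id, tm_segments, cleavage_site) {
  stopifnot(is.matrix(tm_segments), ncol(tm_segments) == 2L)
  has <- nrow(tm_segments) > 0L &&
    any(tm_segments[, 2] > as.integer(cleavage_site))
  structure(list(protein_id = protein_id, tm_segments = tm_segments,
                 has_tm_in_mature = has), class = "topology_call")
}

#' Apply the secretion gate
#'
#' A protein passes iff its signal-peptide score is strictly above the
#' cutoff, the predicted cleavage site lies within the configured window
#' (residues 1-30 by default), and no transmembrane segment remains in the
#' mature region.
#'
#' @param call signal-peptide call ([predict_signal_peptide()]).
#' @param topo topology call ([detect_tm_builtin()] /
#'   [topology_from_report()]), or `NULL` to test the signal-peptide
#'   clauses only.
#' @param config a [pipeline_config()].
#' @return A list with `pass` (logical) and `reason` (`"ok"`, `"score"`,
#'   `"cleavage"`, or `"tm"`; the first failing clause).
#' @export
passes_secretion_gate <- function(call, topo = NULL,
                                  config = pipeline_config()) {
  if (!is.null(topo) && !identical(call$protein_id, topo$protein_id)) {
    stop("signal-peptide and topology calls refer to different proteins: ",
         call$protein_id, " vs ", topo$protein_id)
  }
  if (!isTRUE(call$score > config$sp_score_cutoff)) {
    return(list(pass = FALSE, reason = "score"))
  }
  k <- call$cleavage_site
  if (is.na(k) || k < config$cleavage_window[1] ||
      k > config$cleavage_window[2]) {
    return(list(pass = FALSE, reason = "cleavage"))
  }
  if (!is.null(topo) && isTRUE(topo$has_tm_in_mature)) {
    return(list(pass = FALSE, reason = "tm"))
  }
  list(pass = TRUE, reason = "ok")
}

#' Cleave a signal peptide
#'
#' @param protein protein sequence (character) or record with `id`, `seq`.
#' @param call signal-peptide call, or an integer cleavage site.
#' @param id record id when `protein` is a bare sequence.
#' @return A list of class `"mature_protein"`: `protein_id`, `full_seq`,
#'   `cleavage_site`, `mature_seq` (residues `cleavage_site + 1` to the
#'   end).
#' @export
cleave <- function(protein, call, id = "protein") {
  if (is.data.frame(protein) || is.list(protein)) {
    id <- protein$id
    seq <- protein$seq
  } else {
    seq <- protein
  }
  k <- if (is.list(call)) call$cleavage_site else call
  k <- as.integer(k)
  stopifnot(!is.na(k), k >= 1L)
  if (k >= nchar(seq)) stop("empty mature protein")
  structure(list(protein_id = id, full_seq = seq, cleavage_site = k,
                 mature_seq = substring(seq, k + 1L)),
            class = "mature_protein")
}
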