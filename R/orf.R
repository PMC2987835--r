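# Six-frame ORF calling.
#
# An ORF runs from an ATG to the next in-frame stop (TAA/TAG/TGA, standard
# nuclear code) or to the end of the sequence. Codons containing N (or any
# non-ACGT character) translate to X and never count as start or stop.
# Coordinates are reported 0-based half-open on the forward strand of the
# EST regardless of ORF strand, and never include the stop codon.

.GENETIC_CODE <- NULL

.genetic_code <- function() {
  # cached copy of the standard code from Biostrings
  if (is.null(.GENETIC_CODE)) {
    gc <- Biostrings::GENETIC_CODE
    utils::assignInMyNamespace(".GENETIC_CODE", setNames(as.character(gc), names(gc)))
  }
  .GENETIC_CODE
}

.revcomp <- function(seq) {
  paste(rev(strsplit(chartr("ACGTN", "TGCAN", seq), "", fixed = TRUE)[[1]]),
        collapse = "")
}

# translate one frame; returns list(codons, aa); aa uses "X" for fuzzy
# codons and "*" for stops
.translate_frame <- function(seq, offset) {
  n <- nchar(seq)
  k <- (n - offset) %/% 3L
  if (k < 1L) return(list(codons = character(0), aa = character(0)))
  starts <- offset + 1L + 3L * (seq_len(k) - 1L)
  codons <- substring(seq, starts, starts + 2L)
  aa <- unname(.genetic_code()[codons])
  aa[is.na(aa)] <- "X"
  list(codons = codons, aa = aa)
}

#' Call open reading frames on both strands of an EST
#'
#' Scans all six reading frames. Within each stop-free stretch of a frame
#' the default reports the single ORF starting at the 5'-most ATG (the
#' longest-ORF convention, which the downstream full-length rule presumes);
#' `all_starts = TRUE` reports one ORF per in-frame ATG. ORFs reaching the
#' sequence end without a stop are reported with
#' `terminated_by_stop = FALSE`.
#'
#' @param est a single EST: either a character sequence, or a one-row data
#'   frame with columns `id` and `seq` (as from [read_fasta()]).
#' @param min_len minimum ORF length in residues (default 70).
#' @param all_starts report every in-frame ATG rather than the 5'-most per
#'   stop-free stretch.
#' @param id record id used when `est` is a bare character sequence.
#' @return A data frame with one row per ORF: `est_id`, `strand` (`"+"` or
#'   `"-"`), `frame` (0-2, offset on the reported strand), `start_nt`,
#'   `end_nt` (0-based half-open on the forward strand, stop codon
#'   excluded), `aa_seq` (begins with M, no stop), `terminated_by_stop`,
#'   `min_len`. Sorted by (strand, frame, start_nt).
#' @export
#' @examples
#' est <- paste0("ATG", strrep("GCT", 80), "TAA")
#' call_orfs(est, min_len = 70)
call_orfs <- function(est, min_len = 70L, all_starts = FALSE, id = "est") {
  if (is.data.frame(est)) {
    stopifnot(nrow(est) == 1L)
    id <- est$id
    seq <- est$seq
  } else {
    seq <- est
  }
  if (!is.character(seq) || length(seq) != 1L || !nzchar(seq)) {
    stop("empty sequence")
  }
  if (min_len < 1L) stop("min_len must be >= 1")
  seq <- toupper(seq)
  n <- nchar(seq)
  if (n < 3L) stop("sequence shorter than one codon")

  rows <- vector("list", 6L)
  r <- 0L
  for (strand in c("+", "-")) {
    s <- if (strand == "+") seq else .revcomp(seq)
    for (off in 0:2) {
      tr <- .translate_frame(s, off)
      k <- length(tr$aa)
      if (k == 0L) next
      stop_idx <- which(tr$aa == "*")
      start_idx <- which(tr$codons == "ATG")
      if (length(start_idx) == 0L) next
      # stretch id for each codon: number of stops strictly before it
      stretch <- findInterval(start_idx, stop_idx + 0.5)
      if (!all_starts) {
        start_idx <- start_idx[!duplicated(stretch)]
        stretch <- unique(stretch)
      }
      for (j in seq_along(start_idx)) {
        a <- start_idx[j]
        nxt <- stop_idx[stop_idx > a]
        if (length(nxt)) {
          b <- nxt[1] - 1L
          term <- TRUE
        } else {
          b <- k
          term <- FALSE
        }
        len <- b - a + 1L
        if (len < min_len) next
        # local (reported-strand) 0-based half-open nt interval
        s0 <- off + 3L * (a - 1L)
        s1 <- off + 3L * b
        if (strand == "+") {
          fwd <- c(s0, s1)
        } else {
          fwd <- c(n - s1, n - s0)
        }
        r <- r + 1L
        rows[[r]] <- data.frame(
          est_id = id, strand = strand, frame = off,
          start_nt = fwd[1], end_nt = fwd[2],
          aa_seq = paste(tr$aa[a:b], collapse = ""),
          terminated_by_stop = term, min_len = as.integer(min_len),
          stringsAsFactors = FALSE)
        if (r == length(rows)) rows <- c(rows, vector("list", length(rows)))
      }
    }
  }
  rows <- rows[!vapply(rows, is.null, TRUE)]
  if (length(rows) == 0L) {
    return(data.frame(est_id = character(0), strand = character(0),
                      frame = integer(0), start_nt = integer(0),
                      end_nt = integer(0), aa_seq = character(0),
                      terminated_by_stop = logical(0), min_len = integer(0),
                      stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, rows)
  out <- out[order(out$strand, out$frame, out$start_nt), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Call ORFs over a whole EST library
#'
#' @param ests EST data frame from [read_fasta()] (columns `id`, `seq`).
#' @inheritParams call_orfs
#' @return Row-bound [call_orfs()] output for every record.
#' @export
call_orfs_library <- function(ests, min_len = 70L, all_starts = FALSE) {
  res <- lapply(seq_len(nrow(ests)), function(i) {
    call_orfs(ests$seq[i], min_len = min_len, all_starts = all_starts,
              id = ests$id[i])
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Identifier for a called ORF
#'
#' `estid|strand|frame|start-end|complete:{0,1}`, the header format used
#' when exporting called ORFs as amino-acid FASTA.
#'
#' @param orfs ORF data frame from [call_orfs()].
#' @return Character vector of ids.
#' @export
orf_ids <- function(orfs) {
  sprintf("%s|%s|%d|%d-%d|complete:%d", orfs$est_id, orfs$strand,
          orfs$frame, orfs$start_nt, orfs$end_nt,
          as.integer(orfs$terminated_by_stop))
}

#' Turn called ORFs into a protein record set
#'
#' @param orfs ORF data frame from [call_orfs()] / [call_orfs_library()].
#' @return Protein data frame (`id`, `desc`, `seq`, `source_est`,
#'   `terminated_by_stop`) suitable for the secretion gate and alignment
#'   stages.
#' @export
orf_proteins <- function(orfs) {
  out <- data.frame(id = orf_ids(orfs), desc = "", seq = orfs$aa_seq,
                    source_est = orfs$est_id,
                    terminated_by_stop = orfs$terminated_by_stop,
                    stringsAsFactors = FALSE)
  attr(out, "alphabet") <- "aa"
  out
}

#' Write called ORFs as amino-acid FASTA
#'
#' @param orfs ORF data frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_orfs_fasta <- function(orfs, path) {
  write_fasta(data.frame(id = orf_ids(orfs), seq = orfs$aa_seq,
                         stringsAsFactors = FALSE), path)
}
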