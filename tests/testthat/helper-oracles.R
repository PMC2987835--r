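# Independent reference implementations ("oracles") used by the tests.
# They share only data (the genetic code, the substitution matrix) with
# the package, never its code paths.

AA20 <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I", "L", "K",
          "M", "F", "P", "S", "T", "W", "Y", "V")

random_dna <- function(len, with_n = FALSE) {
  ab <- if (with_n) c("A", "C", "G", "T", "N") else c("A", "C", "G", "T")
  paste(sample(ab, len, replace = TRUE), collapse = "")
}

random_protein <- function(len) {
  paste(sample(AA20, len, replace = TRUE), collapse = "")
}

oracle_revcomp <- function(seq) {
  paste(rev(strsplit(chartr("ACGTN", "TGCAN", seq), "")[[1]]), collapse = "")
}

# --- brute-force ORF oracle ----------------------------------------------
# Tests every ATG position in all six frames and extends codon by codon to
# the next stop or the sequence end; the default (longest-ORF) convention
# keeps the 5'-most ATG per shared stop anchor.
orf_oracle <- function(seq, min_len = 70L, all_starts = FALSE,
                       id = "est") {
  gc_tab <- as.character(Biostrings::GENETIC_CODE)
  names(gc_tab) <- names(Biostrings::GENETIC_CODE)
  seq <- toupper(seq)
  n <- nchar(seq)
  rows <- list()
  for (strand in c("+", "-")) {
    s <- if (strand == "+") seq else oracle_revcomp(seq)
    for (i in seq_len(max(n - 2L, 0L))) {
      if (substr(s, i, i + 2L) != "ATG") next
      aa <- character(0)
      j <- i
      term <- FALSE
      anchor <- "end"
      while (j + 2L <= n) {
        cod <- substr(s, j, j + 2L)
        a <- if (grepl("[^ACGT]", cod)) "X" else gc_tab[[cod]]
        if (a == "*") {
          term <- TRUE
          anchor <- as.character(j)
          break
        }
        aa <- c(aa, a)
        j <- j + 3L
      }
      s0 <- i - 1L                      # local 0-based start
      s1 <- s0 + 3L * length(aa)        # local end, stop excluded
      fwd <- if (strand == "+") c(s0, s1) else c(n - s1, n - s0)
      rows[[length(rows) + 1L]] <- data.frame(
        est_id = id, strand = strand, frame = (i - 1L) %% 3L,
        start_nt = fwd[1], end_nt = fwd[2],
        aa_seq = paste(aa, collapse = ""), terminated_by_stop = term,
        min_len = as.integer(min_len), local_start = s0, anchor = anchor,
        stringsAsFactors = FALSE)
    }
  }
  if (!length(rows)) {
    return(data.frame(est_id = character(0), strand = character(0),
                      frame = integer(0), start_nt = integer(0),
                      end_nt = integer(0), aa_seq = character(0),
                      terminated_by_stop = logical(0),
                      min_len = integer(0), stringsAsFactors = FALSE))
  }
  df <- do.call(rbind, rows)
  if (!all_starts) {
    key <- paste(df$strand, df$frame, df$anchor)
    keep <- unlist(lapply(split(seq_len(nrow(df)), key), function(ix) {
      ix[which.min(df$local_start[ix])]
    }), use.names = FALSE)
    df <- df[sort(keep), , drop = FALSE]
  }
  df <- df[nchar(df$aa_seq) >= min_len, , drop = FALSE]
  df <- df[order(df$strand, df$frame, df$start_nt),
           c("est_id", "strand", "frame", "start_nt", "end_nt", "aa_seq",
             "terminated_by_stop", "min_len"), drop = FALSE]
  rownames(df) <- NULL
  df
}

# --- alignment oracles ----------------------------------------------------
# Exhaustive maximization over all gapped local alignments via an
# independent plain-R dynamic program (affine gaps: a gap of length L
# costs go + L * ge). Shares only the substitution matrix (data) with the
# implementation under test.
sw_score_oracle <- function(a, b, scores, go = 11, ge = 1) {
  av <- strsplit(a, "")[[1]]
  bv <- strsplit(b, "")[[1]]
  m <- length(av)
  n <- length(bv)
  H <- matrix(0, m + 1, n + 1)
  E <- matrix(-Inf, m + 1, n + 1)  # gap in a (consumes b)
  F <- matrix(-Inf, m + 1, n + 1)  # gap in b (consumes a)
  best <- 0
  for (i in seq_len(m)) {
    for (j in seq_len(n)) {
      E[i + 1, j + 1] <- max(H[i + 1, j] - go - ge, E[i + 1, j] - ge)
      F[i + 1, j + 1] <- max(H[i, j + 1] - go - ge, F[i, j + 1] - ge)
      H[i + 1, j + 1] <- max(0,
                             H[i, j] + scores[av[i], bv[j]],
                             E[i + 1, j + 1], F[i + 1, j + 1])
      best <- max(best, H[i + 1, j + 1])
    }
  }
  best
}

# True path enumeration (no memoization): recursion over the last aligned
# column of every local alignment ending at (i, j). Exponential -- only
# for tiny sequences; used to validate the dynamic program above.
enum_score_oracle <- function(a, b, scores, go = 11, ge = 1) {
  av <- strsplit(a, "")[[1]]
  bv <- strsplit(b, "")[[1]]
  rec <- function(i, j, state) {
    if (i < 1 || j < 1) return(-Inf)
    if (state == "M") {
      s <- scores[av[i], bv[j]]
      s + max(0, rec(i - 1, j - 1, "M"), rec(i - 1, j - 1, "X"),
              rec(i - 1, j - 1, "Y"))
    } else if (state == "X") {        # gap in a, consumes b[j]
      max(rec(i, j - 1, "M") - go - ge,
          rec(i, j - 1, "X") - ge,
          rec(i, j - 1, "Y") - go - ge)
    } else {                          # gap in b, consumes a[i]
      max(rec(i - 1, j, "M") - go - ge,
          rec(i - 1, j, "Y") - ge,
          rec(i - 1, j, "X") - go - ge)
    }
  }
  best <- 0
  for (i in seq_along(av)) {
    for (j in seq_along(bv)) {
      best <- max(best, rec(i, j, "M"), rec(i, j, "X"), rec(i, j, "Y"))
    }
  }
  best
}

# --- motif oracle ---------------------------------------------------------
csp_regex_oracle <- function(seq, all = FALSE) {
  m <- gregexpr("(?=C.{6}C.{18}C.{2}C)", seq, perl = TRUE)[[1]]
  hits <- as.integer(m[m > 0])
  if (all) hits else if (length(hits)) hits[1] else NA_integer_
}
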