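# Sequence and predictor-report I/O.
#
# Record containers are plain data frames:
#   EST libraries:  id, desc, seq, species, tissue   (attr "alphabet" = "nt")
#   protein sets:   id, desc, seq [, source_est]     (attr "alphabet" = "aa")

.NT_CHARS <- c("A", "C", "G", "T", "N", "U")
.AA_CHARS <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I", "L", "K",
               "M", "F", "P", "S", "T", "W", "Y", "V", "X", "*")

# IUPAC ambiguity codes other than N are mapped to N on ingest (with a
# warning); the published screen is silent on ambiguity handling.
.IUPAC_AMBIG <- c("R", "Y", "S", "W", "K", "M", "B", "D", "H", "V")

.detect_alphabet <- function(seqs) {
  chars <- strsplit(paste(seqs, collapse = ""), "", fixed = TRUE)[[1]]
  if (length(chars) == 0L) return("nt")
  frac_nt <- mean(chars %in% .NT_CHARS)
  if (frac_nt >= 0.95) "nt" else "aa"
}

#' Read a FASTA file of ESTs or proteins
#'
#' Parses a (possibly line-wrapped) FASTA file into a record data frame.
#' Sequences are uppercased; the alphabet is auto-detected (nucleotide when
#' at least 95% of all characters are A/C/G/T/N/U, in which case U is mapped
#' to T and any other IUPAC ambiguity code to N with a warning). Record ids
#' are the first whitespace-delimited token of each header; the remainder is
#' kept as a free-text description. Species and tissue tags are supplied by
#' the caller, not parsed from headers.
#'
#' @param path path to a FASTA file.
#' @param species species tag, e.g. `"mp"`, `"ap"`, `"other"`.
#' @param tissue tissue tag, e.g. `"salivary_gland"`, `"gut"`, `"whole"`,
#'   `"unknown"`.
#' @return A data frame with columns `id`, `desc`, `seq` and, for nucleotide
#'   input, `species` and `tissue`; attribute `"alphabet"` is `"nt"` or
#'   `"aa"`.
#' @export
read_fasta <- function(path, species = "other", tissue = "unknown") {
  stopifnot(file.exists(path))
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  hdr <- grepl("^>", lines)
  if (!any(hdr)) stop("no records in FASTA file: ", path)
  if (!hdr[1]) stop("FASTA file does not start with a header line: ", path)
  grp <- cumsum(hdr)
  headers <- sub("^>", "", lines[hdr])
  ids <- sub("\\s.*$", "", headers)
  desc <- ifelse(grepl("\\s", headers), sub("^\\S+\\s+", "", headers), "")
  seqs <- vapply(split(lines[!hdr], grp[!hdr]), paste, "", collapse = "")
  # headers with no sequence lines yield missing groups
  full <- character(length(ids))
  full[as.integer(names(seqs))] <- seqs
  seqs <- toupper(gsub("\\s", "", full))
  if (any(!nzchar(seqs))) {
    stop("record with empty sequence: ", ids[!nzchar(seqs)][1])
  }
  if (anyDuplicated(ids)) {
    stop("duplicate record id: ", ids[duplicated(ids)][1])
  }
  alphabet <- .detect_alphabet(seqs)
  if (alphabet == "nt") {
    seqs <- chartr("U", "T", seqs)
    bad <- gsub("[ACGTN]", "", seqs)
    if (any(nzchar(bad))) {
      amb <- unique(strsplit(paste(bad, collapse = ""), "")[[1]])
      if (all(amb %in% .IUPAC_AMBIG)) {
        warning("IUPAC ambiguity codes (", paste(amb, collapse = ","),
                ") mapped to N")
        seqs <- gsub(paste0("[", paste(.IUPAC_AMBIG, collapse = ""), "]"),
                     "N", seqs)
      } else {
        i <- which(nzchar(bad))[1]
        pos <- regexpr("[^ACGTN]", seqs[i])
        stop("illegal character '", substr(seqs[i], pos, pos),
             "' in record ", ids[i], " at position ", pos)
      }
    }
    out <- data.frame(id = ids, desc = desc, seq = seqs,
                      species = species, tissue = tissue,
                      stringsAsFactors = FALSE)
  } else {
    ok <- paste(.AA_CHARS, collapse = "")
    bad <- gsub(paste0("[", gsub("\\*", "\\\\*", ok), "]"), "", seqs)
    if (any(nzchar(bad))) {
      i <- which(nzchar(bad))[1]
      pos <- regexpr("[^ARNDCQEGHILKMFPSTWYVX*]", seqs[i])
      stop("illegal character '", substr(seqs[i], pos, pos),
           "' in record ", ids[i], " at position ", pos)
    }
    if (any(grepl("\\*.", seqs))) {
      stop("internal stop ('*') in record ",
           ids[grepl("\\*.", seqs)][1])
    }
    out <- data.frame(id = ids, desc = desc, seq = seqs,
                      stringsAsFactors = FALSE)
  }
  rownames(out) <- NULL
  attr(out, "alphabet") <- alphabet
  out
}

#' Write records to a FASTA file
#'
#' Inverse of [read_fasta()]: `read_fasta(write_fasta(x, p))` restores ids,
#' descriptions and sequences.
#'
#' @param x record data frame with columns `id`, `seq` and optionally
#'   `desc`.
#' @param path output path.
#' @param width line-wrap width for sequences.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(x, path, width = 60L) {
  stopifnot(is.data.frame(x), all(c("id", "seq") %in% names(x)))
  desc <- if ("desc" %in% names(x)) x$desc else rep("", nrow(x))
  hdr <- ifelse(nzchar(desc), paste0(">", x$id, " ", desc), paste0(">", x$id))
  wrap <- function(s) {
    starts <- seq(1L, nchar(s), by = width)
    substring(s, starts, pmin(starts + width - 1L, nchar(s)))
  }
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_len(nrow(x))) {
    writeLines(c(hdr[i], wrap(x$seq[i])), con)
  }
  invisible(path)
}

#' Read an external predictor report
#'
#' Parses whitespace-delimited signal-peptide or membrane-topology reports.
#' The `signalp3_short` dialect has one row per protein:
#' `protein_id score cleavage_site`; the `tmhmm_short` dialect has
#' `protein_id n_segments start1-end1[,start2-end2...]`, with `-` standing
#' for zero segments. Lines starting with `#` are comments.
#'
#' @param path path to the report file.
#' @param dialect `"signalp3_short"` or `"tmhmm_short"`.
#' @return For `signalp3_short`, a data frame with `protein_id`, `score`,
#'   `cleavage_site`; for `tmhmm_short`, a data frame with `protein_id`,
#'   `n_segments` and a list column `tm_segments` of two-column
#'   (start, end) matrices.
#' @export
read_predictor_report <- function(path,
                                  dialect = c("signalp3_short", "tmhmm_short")) {
  dialect <- match.arg(dialect)
  stopifnot(file.exists(path))
  lines <- readLines(path, warn = FALSE)
  keep <- nzchar(trimws(lines)) & !grepl("^\\s*#", lines)
  lineno <- which(keep)
  lines <- trimws(lines[keep])
  toks <- strsplit(lines, "\\s+")
  if (dialect == "signalp3_short") {
    bad <- which(lengths(toks) != 3L)
    if (length(bad)) {
      stop("malformed signalp3_short line(s): ",
           paste(lineno[bad], collapse = ", "))
    }
    score <- as.numeric(vapply(toks, `[`, "", 2L))
    cleav <- as.integer(vapply(toks, `[`, "", 3L))
    if (anyNA(score) || anyNA(cleav)) {
      bad <- which(is.na(score) | is.na(cleav))
      stop("malformed signalp3_short line(s): ",
           paste(lineno[bad], collapse = ", "))
    }
    if (any(score < 0 | score > 1)) {
      stop("signal-peptide score outside [0,1] on line(s): ",
           paste(lineno[score < 0 | score > 1], collapse = ", "))
    }
    if (any(cleav < 1L)) {
      stop("cleavage site < 1 on line(s): ",
           paste(lineno[cleav < 1L], collapse = ", "))
    }
    data.frame(protein_id = vapply(toks, `[`, "", 1L),
               score = score, cleavage_site = cleav,
               stringsAsFactors = FALSE)
  } else {
    bad <- which(lengths(toks) != 3L)
    if (length(bad)) {
      stop("malformed tmhmm_short line(s): ",
           paste(lineno[bad], collapse = ", "))
    }
    n_seg <- as.integer(vapply(toks, `[`, "", 2L))
    seg_f <- vapply(toks, `[`, "", 3L)
    segs <- lapply(seq_along(toks), function(i) {
      if (n_seg[i] == 0L) {
        if (seg_f[i] != "-") {
          stop("tmhmm_short line ", lineno[i],
               ": zero segments must be written '-'")
        }
        return(matrix(integer(0), ncol = 2,
                      dimnames = list(NULL, c("start", "end"))))
      }
      parts <- strsplit(seg_f[i], ",", fixed = TRUE)[[1]]
      if (length(parts) != n_seg[i]) {
        stop("tmhmm_short line ", lineno[i],
             ": segment count does not match segment list")
      }
      m <- t(vapply(strsplit(parts, "-", fixed = TRUE),
                    function(p) as.integer(p), integer(2)))
      colnames(m) <- c("start", "end")
      if (anyNA(m) || any(m[, 1] > m[, 2]) || any(m < 1L)) {
        stop("tmhmm_short line ", lineno[i], ": malformed segment interval")
      }
      if (nrow(m) > 1L &&
          (is.unsorted(m[, 1]) || any(m[-1, 1] <= m[-nrow(m), 2]))) {
        stop("tmhmm_short line ", lineno[i],
             ": segments must be sorted and non-overlapping")
      }
      m
    })
    out <- data.frame(protein_id = vapply(toks, `[`, "", 1L),
                      n_segments = n_seg, stringsAsFactors = FALSE)
    out$tm_segments <- segs
    out
  }
}

#' Write a predictor report
#'
#' Inverse of [read_predictor_report()] for both dialects.
#'
#' @param x report data frame as returned by [read_predictor_report()].
#' @param path output path.
#' @param dialect `"signalp3_short"` or `"tmhmm_short"`.
#' @return `path`, invisibly.
#' @export
write_predictor_report <- function(x, path,
                                   dialect = c("signalp3_short",
                                               "tmhmm_short")) {
  dialect <- match.arg(dialect)
  if (dialect == "signalp3_short") {
    lines <- sprintf("%s %s %d", x$protein_id,
                     format(x$score, trim = TRUE, digits = 15),
                     x$cleavage_site)
  } else {
    seg_f <- vapply(x$tm_segments, function(m) {
      if (nrow(m) == 0L) "-" else
        paste(sprintf("%d-%d", m[, 1], m[, 2]), collapse = ",")
    }, "")
    lines <- sprintf("%s %d %s", x$protein_id,
                     vapply(x$tm_segments, nrow, 0L), seg_f)
  }
  writeLines(c(paste0("# ", dialect), lines), path)
  invisible(path)
}
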