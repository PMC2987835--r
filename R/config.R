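#' Pipeline configuration
#'
#' Collects every tunable threshold of the mining cascade in one validated
#' object. Defaults follow the published screen: ORFs of at least 70
#' residues, a signal-peptide score strictly above 0.9 with a predicted
#' cleavage site within residues 1-30, redundancy defined as >95% identity
#' at E < 1e-10 over at least 80% of the shorter sequence, homology searches
#' at E < 1e-5, gut-contamination flagging at E < 1e-15, and removal of
#' candidates with no within-species variation whose other-species mature
#' region differs by at most one residue.
#'
#' @param min_orf_len minimum ORF length in residues.
#' @param sp_score_cutoff signal-peptide score cutoff; the gate is strict
#'   (`score > sp_score_cutoff`).
#' @param cleavage_window inclusive residue window for the predicted
#'   cleavage site, length-2 integer.
#' @param redundancy_identity percent-identity cutoff (strict `>`) for the
#'   redundancy edge.
#' @param redundancy_evalue E-value cutoff (strict `<`) for the redundancy
#'   edge.
#' @param redundancy_coverage minimum fraction of the shorter sequence the
#'   alignment must span for the redundancy edge ("throughout most of the
#'   alignment", operationalized).
#' @param overlap_evalue E-value cutoff for calling two candidates from the
#'   two species the same protein.
#' @param homolog_evalue E-value cutoff for supporting-homolog searches
#'   (full-length assessment, polymorphism alignments, cross-species
#'   additions).
#' @param gut_evalue E-value cutoff for flagging a candidate as matched in
#'   gut ESTs.
#' @param max_ap_mature_diff maximum number of mature-region amino-acid
#'   differences versus the other species under which a monomorphic
#'   candidate is removed.
#' @param variation_min_identity minimum percent identity for a
#'   same-species EST alignment to count as same-gene evidence in the
#'   polymorphism filter (alignments below it are treated as hits to other
#'   genes, not as sequence variation).
#' @param fulllength_rule logical connective combining the three
#'   full-length criteria: `"c1_or_c2and3"` (default), `"any"`, or `"all"`.
#' @return A list of class `"pipeline_config"`.
#' @export
#' @examples
#' cfg <- pipeline_config()
#' cfg$sp_score_cutoff
pipeline_config <- function(min_orf_len = 70L,
                            sp_score_cutoff = 0.9,
                            cleavage_window = c(1L, 30L),
                            redundancy_identity = 95,
                            redundancy_evalue = 1e-10,
                            redundancy_coverage = 0.8,
                            overlap_evalue = 1e-5,
                            homolog_evalue = 1e-5,
                            gut_evalue = 1e-15,
                            max_ap_mature_diff = 1L,
                            variation_min_identity = 90,
                            fulllength_rule = c("c1_or_c2and3", "any", "all")) {
  fulllength_rule <- match.arg(fulllength_rule)
  stopifnot(
    length(min_orf_len) == 1L, min_orf_len >= 1,
    length(sp_score_cutoff) == 1L, sp_score_cutoff >= 0, sp_score_cutoff <= 1,
    length(cleavage_window) == 2L, cleavage_window[1] >= 1,
    cleavage_window[2] >= cleavage_window[1],
    redundancy_identity > 0, redundancy_identity <= 100,
    redundancy_evalue > 0, overlap_evalue > 0, homolog_evalue > 0,
    gut_evalue > 0,
    redundancy_coverage > 0, redundancy_coverage <= 1,
    max_ap_mature_diff >= 0,
    variation_min_identity >= 0, variation_min_identity <= 100
  )
  structure(list(
    min_orf_len = as.integer(min_orf_len),
    sp_score_cutoff = sp_score_cutoff,
    cleavage_window = as.integer(cleavage_window),
    redundancy_identity = redundancy_identity,
    redundancy_evalue = redundancy_evalue,
    redundancy_coverage = redundancy_coverage,
    overlap_evalue = overlap_evalue,
    homolog_evalue = homolog_evalue,
    gut_evalue = gut_evalue,
    max_ap_mature_diff = as.integer(max_ap_mature_diff),
    variation_min_identity = variation_min_identity,
    fulllength_rule = fulllength_rule
  ), class = "pipeline_config")
}

#' @export
print.pipeline_config <- function(x, ...) {
  cat("Effector-mining pipeline configuration\n")
  for (nm in names(x)) {
    cat(sprintf("  %-22s %s\n", nm, paste(format(x[[nm]]), collapse = "-")))
  }
  invisible(x)
}
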