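# Leaf-disc fecundity and ROS assay statistics.
#
# Wells hold 4 first-instar nymphs on day 1; adults are counted on days 6,
# 12 and 14 and newly produced nymphs on days 12, 14 and 17. The per-well
# statistic chains the three interval production rates:
#   R = N12/A6 + N14/A12 + N17/A14
# Wells in which the denominator of any term is zero (all adults dead by
# that count day) are excluded from analysis.

.WELL_COUNT_COLS <- c("A6", "A12", "A14", "N12", "N14", "N17")

.check_wells <- function(wells) {
  stopifnot(is.data.frame(wells),
            all(.WELL_COUNT_COLS %in% names(wells)))
  cnt <- as.matrix(wells[, .WELL_COUNT_COLS])
  if (any(cnt < 0)) stop("negative count in well data")
  if (any(cnt != round(cnt))) stop("non-integer count in well data")
  if (any(wells$A12 > wells$A6 | wells$A14 > wells$A12)) {
    stop("adult counts must be non-increasing (A6 >= A12 >= A14)")
  }
  invisible(wells)
}

#' Per-well nymph production rate
#'
#' `R = N12/A6 + N14/A12 + N17/A14`, the sum of the three interval
#' production rates computed per well. Wells whose denominator is zero at
#' any count day are excluded (`NA`): this covers the all-four-died
#' exclusion rule and its natural extension to later count days.
#'
#' @param wells data frame with columns `A6`, `A12`, `A14` (adult counts)
#'   and `N12`, `N14`, `N17` (newly produced nymph counts); extra columns
#'   (e.g. `construct`, `replicate`) are ignored.
#' @return Numeric vector of per-well rates, `NA` for excluded wells.
#' @export
#' @examples
#' production_rate(data.frame(A6 = 4, A12 = 2, A14 = 2,
#'                            N12 = 4, N14 = 2, N17 = 1))  # 2.5
production_rate <- function(wells) {
  if (!is.data.frame(wells)) wells <- as.data.frame(as.list(wells))
  .check_wells(wells)
  excluded <- wells$A6 == 0 | wells$A12 == 0 | wells$A14 == 0
  r <- wells$N12 / wells$A6 + wells$N14 / wells$A12 + wells$N17 / wells$A14
  r[excluded] <- NA_real_
  r
}

#' Summarize per-construct production rates
#'
#' Mean and standard error of the per-well rates over non-excluded wells,
#' per construct. A single-well construct is reported with SE 0 and
#' flagged.
#'
#' @param wells well data frame with a `construct` column and the count
#'   columns of [production_rate()].
#' @return Data frame: `construct`, `n_wells` (non-excluded), `mean_rate`,
#'   `se`, `single_well`.
#' @export
summarize_constructs <- function(wells) {
  stopifnot("construct" %in% names(wells))
  r <- production_rate(wells)
  out <- lapply(split(r, wells$construct), function(x) {
    x <- x[!is.na(x)]
    if (length(x) == 0L) return(NULL)
    data.frame(n_wells = length(x), mean_rate = mean(x),
               se = if (length(x) > 1L) sd(x) / sqrt(length(x)) else 0,
               single_well = length(x) == 1L)
  })
  if (all(vapply(out, is.null, TRUE))) stop("no data: all wells excluded")
  keep <- !vapply(out, is.null, TRUE)
  res <- do.call(rbind, out[keep])
  res <- cbind(data.frame(construct = names(out)[keep],
                          stringsAsFactors = FALSE), res)
  rownames(res) <- NULL
  res
}

#' Summarize one construct
#'
#' @param wells well data frame.
#' @param construct construct label to summarize.
#' @return One-row data frame as in [summarize_constructs()].
#' @export
summarize_construct <- function(wells, construct) {
  sub <- wells[wells$construct == construct, , drop = FALSE]
  if (nrow(sub) == 0L) stop("no wells for construct ", construct)
  r <- production_rate(sub)
  if (all(is.na(r))) stop("no data: all wells excluded for ", construct)
  summarize_constructs(sub)
}

#' Initial one-standard-error screen
#'
#' Flags a construct as a (liberal) initial hit when its mean production
#' rate differs from the empty-vector control mean by at least one
#' standard error. Whose standard error enters the rule is configurable;
#' the default is the candidate's own (the error bars of the screen
#' figure are per-construct).
#'
#' @param summaries construct summary data frame
#'   ([summarize_constructs()]), including the control.
#' @param control label of the empty-vector control construct.
#' @param se_rule which SE the threshold uses: `"candidate"`, `"control"`,
#'   or `"pooled"` (sqrt of the sum of squared SEs).
#' @return Data frame with `construct`, `mean_rate`, `se`, `diff` (versus
#'   control), `threshold`, `hit`, `direction` (`"enhanced"`, `"reduced"`
#'   or `"none"`); the control row is omitted.
#' @export
initial_screen <- function(summaries, control = "EV",
                           se_rule = c("candidate", "control", "pooled")) {
  se_rule <- match.arg(se_rule)
  i <- match(control, summaries$construct)
  if (is.na(i)) stop("control construct not found: ", control)
  ev <- summaries[i, ]
  cand <- summaries[-i, , drop = FALSE]
  thr <- switch(se_rule,
                candidate = cand$se,
                control = rep(ev$se, nrow(cand)),
                pooled = sqrt(cand$se^2 + ev$se^2))
  d <- cand$mean_rate - ev$mean_rate
  hit <- abs(d) >= thr
  data.frame(construct = cand$construct, mean_rate = cand$mean_rate,
             se = cand$se, diff = d, threshold = thr, hit = hit,
             direction = ifelse(!hit, "none",
                                ifelse(d > 0, "enhanced", "reduced")),
             stringsAsFactors = FALSE)
}

#' Blocked one-way ANOVA on production rates
#'
#' Two-way additive decomposition with the construct as treatment and the
#' replicate experiment as block (classic sequential sums of squares,
#' block fitted first); the F statistic tests the treatment against the
#' residual. Excluded wells are dropped first; a construct absent from a
#' block is an error (singular design).
#'
#' @param wells well data frame with `construct`, `replicate` and the
#'   count columns, or with a precomputed `rate` column.
#' @return A list of class `"blocked_anova"`: `statistic` (F for the
#'   treatment), `df` (treatment, residual), `p_value`, `table` (the full
#'   ANOVA table).
#' @export
blocked_anova <- function(wells) {
  stopifnot(all(c("construct", "replicate") %in% names(wells)))
  rate <- if ("rate" %in% names(wells)) wells$rate else production_rate(wells)
  keep <- !is.na(rate)
  df <- data.frame(rate = rate[keep],
                   construct = factor(wells$construct[keep]),
                   replicate = factor(wells$replicate[keep]))
  if (nlevels(df$construct) < 2L) stop("need at least 2 constructs")
  if (nlevels(df$replicate) < 2L) stop("need at least 2 blocks")
  cells <- table(df$construct, df$replicate)
  if (any(cells == 0L)) {
    miss <- which(cells == 0L, arr.ind = TRUE)[1, ]
    stop("singular design: construct ", rownames(cells)[miss[1]],
         " absent from replicate ", colnames(cells)[miss[2]])
  }
  if (stats::var(df$rate) == 0) {
    # all values identical: no treatment signal by convention
    df1 <- nlevels(df$construct) - 1L
    df2 <- nrow(df) - nlevels(df$construct) - nlevels(df$replicate) + 1L
    return(structure(list(statistic = 0, df = c(df1, df2), p_value = 1,
                          table = NULL), class = "blocked_anova"))
  }
  fit <- aov(rate ~ replicate + construct, data = df)
  tab <- summary(fit)[[1]]
  i <- grep("^construct", trimws(rownames(tab)))
  res <- grep("^Residuals", trimws(rownames(tab)))
  f <- tab[i, "F value"]
  p <- tab[i, "Pr(>F)"]
  if (is.na(f)) { # zero residual variance
    f <- if (tab[i, "Sum Sq"] > 0) Inf else 0
    p <- if (tab[i, "Sum Sq"] > 0) 0 else 1
  }
  structure(list(statistic = f,
                 df = c(tab[i, "Df"], tab[res, "Df"]),
                 p_value = p, table = tab), class = "blocked_anova")
}

#' @export
print.blocked_anova <- function(x, ...) {
  cat(sprintf("blocked one-way ANOVA: F(%d, %d) = %.4g, p = %.4g\n",
              x$df[1], x$df[2], x$statistic, x$p_value))
  invisible(x)
}

#' ROS max-photon summary with Welch t-tests against a control
#'
#' Takes the maximum photon count over time per leaf disc, averages across
#' discs per construct, and compares each construct to the named control
#' with a Welch (unequal-variance) two-sample t-test. When both groups are
#' constant and identical the t statistic is undefined; the comparison is
#' reported with `t = 0`, `p = 1` and a note.
#'
#' @param ros long-format data frame: `construct`, `disc`, `time`,
#'   `counts`.
#' @param control control construct label.
#' @return A list of class `"ros_summary"`: `summary` (per-construct
#'   `n_discs`, `mean_max`, `se`) and `tests` (per non-control construct
#'   `t`, `df`, `p_value`, `note`).
#' @export
ros_summary <- function(ros, control = "EV") {
  stopifnot(all(c("construct", "disc", "time", "counts") %in% names(ros)),
            all(ros$counts >= 0))
  maxima <- tapply(ros$counts, list(ros$construct, ros$disc), max)
  per <- lapply(rownames(maxima), function(cn) {
    v <- maxima[cn, ]
    v <- v[!is.na(v)]
    if (length(v) < 2L) stop("need at least 2 discs per construct: ", cn)
    list(construct = cn, maxima = unname(v))
  })
  names(per) <- rownames(maxima)
  if (!control %in% names(per)) stop("control construct not found: ", control)
  sum_df <- do.call(rbind, lapply(per, function(p) {
    data.frame(construct = p$construct, n_discs = length(p$maxima),
               mean_max = mean(p$maxima),
               se = sd(p$maxima) / sqrt(length(p$maxima)),
               stringsAsFactors = FALSE)
  }))
  rownames(sum_df) <- NULL
  ctrl <- per[[control]]$maxima
  tests <- lapply(per[setdiff(names(per), control)], function(p) {
    x <- p$maxima
    if (sd(x) == 0 && sd(ctrl) == 0) {
      if (isTRUE(all.equal(mean(x), mean(ctrl)))) {
        return(data.frame(construct = p$construct, t = 0,
                          df = NA_real_, p_value = 1,
                          note = "identical constant groups",
                          stringsAsFactors = FALSE))
      }
      return(data.frame(construct = p$construct, t = Inf * sign(mean(x) - mean(ctrl)),
                        df = NA_real_, p_value = 0,
                        note = "constant groups, different means",
                        stringsAsFactors = FALSE))
    }
    tt <- t.test(x, ctrl, var.equal = FALSE)
    data.frame(construct = p$construct, t = unname(tt$statistic),
               df = unname(tt$parameter), p_value = tt$p.value,
               note = "", stringsAsFactors = FALSE)
  })
  tests <- do.call(rbind, tests)
  rownames(tests) <- NULL
  structure(list(summary = sum_df, tests = tests, control = control),
            class = "ros_summary")
}

#' @export
print.ros_summary <- function(x, ...) {
  cat("ROS max-photon summary (control: ", x$control, ")\n", sep = "")
  print(x$summary, row.names = FALSE)
  cat("Welch t-tests vs control:\n")
  print(x$tests, row.names = FALSE)
  invisible(x)
}
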