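#' Summarise one session into the group-level scalars
#'
#' Computes the 40-Hz ASSR band summaries (MTP and PLF averaged over the
#' configured band x window, 35-45 Hz x 50-550 ms by default) from the
#' click-train set and the negative/positive T/C ratios from the
#' sound-pair set. Only frequencies inside the summary band are
#' decomposed, since the band mean does not depend on the rest of the
#' grid.
#'
#' @param click click-train [EpochSet-class].
#' @param pair sound-pair [EpochSet-class] from the same session.
#' @param config a [RunConfig-class].
#' @return one-row data.frame: `session_id`, `region`, `condition`,
#'   `mtp40`, `plf40`, `tc_neg`, `tc_pos`
#' @export
summarizeSession <- function(click, pair, config = runConfig()) {
  stopifnot(click@sessionId == pair@sessionId)
  band_freqs <- config@freqGrid[config@freqGrid >= config@assrBand[1] &
                                config@freqGrid <= config@assrBand[2]]
  maps <- assrMaps(click, band_freqs, config@nCycles)
  ig <- computeIG(pair, config)
  data.frame(
    session_id = click@sessionId, region = click@region,
    condition = click@condition,
    mtp40 = bandWindowMean(maps$mtp, config@assrBand, config@assrWindow),
    plf40 = bandWindowMean(maps$plf, config@assrBand, config@assrWindow),
    tc_neg = ig$tc_ratio[grepl("^N", ig$label)][1],
    tc_pos = ig$tc_ratio[grepl("^P", ig$label)][1])
}

#' One-way ANOVA across brain regions with Tukey HSD contrasts
#'
#' Classic (homoskedastic) one-way ANOVA of one summary measure across
#' regions within one condition, followed by Tukey honest-significant-
#' difference adjusted pairwise contrasts over all six region pairs.
#' Regions with fewer than two sessions are excluded with a warning.
#'
#' @param summaries data.frame of session summaries (see
#'   [summarizeSession()]).
#' @param measure column to analyse, e.g. `"mtp40"` or `"tc_neg"`.
#' @param cond condition to restrict to (`NULL` uses all rows).
#' @return list with `anova` (data.frame: F, df1, df2, p) and `tukey`
#'   (data.frame: contrast, diff, p_adj)
#' @export
regionAnova <- function(summaries, measure, cond = "conscious") {
  df <- summaries
  if (!is.null(cond)) df <- df[df$condition == cond, ]
  df <- df[is.finite(df[[measure]]), ]
  counts <- table(df$region)
  small <- names(counts)[counts < 2L]
  if (length(small)) {
    warning("excluding region(s) with < 2 sessions: ",
            paste(small, collapse = ", "))
    df <- df[!df$region %in% small, ]
  }
  if (length(unique(df$region)) < 2L)
    stop("need at least 2 regions with >= 2 sessions")
  df$region <- factor(df$region)
  if (stats::var(df[[measure]]) == 0) {
    ## identical values within and across groups: no variance to partition
    k <- nlevels(df$region)
    pairs <- utils::combn(levels(df$region), 2)
    return(list(
      anova = data.frame(F = 0, df1 = k - 1L, df2 = nrow(df) - k, p = 1),
      tukey = data.frame(contrast = paste(pairs[2, ], pairs[1, ], sep = "-"),
                         diff = 0, p_adj = 1)))
  }
  fit <- stats::aov(stats::reformulate("region", measure), data = df)
  an <- summary(fit)[[1]]
  Fv <- an$`F value`[1]; pv <- an$`Pr(>F)`[1]
  if (!is.finite(Fv) && an$`Sum Sq`[1] == 0) { Fv <- 0; pv <- 1 }  # no variance at all
  tk <- stats::TukeyHSD(fit)$region
  list(
    anova = data.frame(F = Fv, df1 = an$Df[1], df2 = an$Df[2], p = pv),
    tukey = data.frame(contrast = rownames(tk), diff = tk[, "diff"],
                       p_adj = tk[, "p adj"], row.names = NULL))
}

#' Paired conscious-versus-anesthetized t-test within one region
#'
#' Two-sided paired t-test on within-session differences of one summary
#' measure. Sessions present in only one condition are dropped with a
#' warning count.
#'
#' @inheritParams regionAnova
#' @param reg region to test.
#' @return data.frame with `region`, `measure`, `t`, `df`, `p`, `n_pairs`
#' @export
pairedConditionTest <- function(summaries, reg, measure) {
  df <- summaries[summaries$region == reg, ]
  co <- df[df$condition == "conscious", c("session_id", measure)]
  an <- df[df$condition == "anesthetized", c("session_id", measure)]
  m <- merge(co, an, by = "session_id", suffixes = c("_co", "_an"))
  m <- m[is.finite(m[[2]]) & is.finite(m[[3]]), ]
  dropped <- length(unique(df$session_id)) - nrow(m)
  if (dropped > 0L)
    warning(dropped, " unmatched or incomplete session(s) dropped for ",
            reg, "/", measure)
  if (nrow(m) < 2L) stop("need at least 2 paired sessions")
  d <- m[[2]] - m[[3]]
  if (stats::sd(d) == 0) {
    ## constant differences: the t statistic degenerates
    tv <- if (mean(d) == 0) 0 else sign(mean(d)) * Inf
    return(data.frame(region = reg, measure = measure, t = tv,
                      df = nrow(m) - 1L, p = if (tv == 0) 1 else 0,
                      n_pairs = nrow(m)))
  }
  ht <- stats::t.test(m[[2]], m[[3]], paired = TRUE)
  data.frame(region = reg, measure = measure,
             t = unname(ht$statistic), df = unname(ht$parameter),
             p = ht$p.value, n_pairs = nrow(m))
}
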