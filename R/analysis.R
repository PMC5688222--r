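#' PREE index
#'
#' `(mean_crf - mean_prf) / (mean_crf + mean_prf)`: negative values indicate a
#' partial reinforcement extinction effect (the partially reinforced component
#' outperforms the continuously reinforced one), positive values a reversed
#' effect.
#'
#' @param mean_crf mean correct proportion of the continuous (high-density)
#'   component.
#' @param mean_prf mean correct proportion of the partial (low-density)
#'   component.
#' @return index in `[-1, 1]`; `NA` with a warning if both means are zero.
#' @export
#' @examples
#' pree_index(0.8, 0.4)   #  1/3 (reversed effect)
#' pree_index(0.3, 0.6)   # -1/3 (partial reinforcement extinction effect)
pree_index <- function(mean_crf, mean_prf) {
  s <- mean_crf + mean_prf
  out <- ifelse(s > 0, (mean_crf - mean_prf) / s, NA_real_)
  if (anyNA(out))
    warning("PREE index undefined where both means are zero", call. = FALSE)
  out
}

#' Extinction curve as log proportion of baseline
#'
#' Expresses per-block extinction proportions relative to the responding level
#' reached at the end of acquisition: `log(prop_block / baseline)`.
#'
#' @param props per-block extinction proportions (numeric vector).
#' @param baseline final-acquisition-block proportion (> 0).
#' @param base logarithm base (default natural log).
#' @param eps floor applied to zero proportions before taking the log.
#' @return numeric vector of log proportions to baseline.
#' @export
log_baseline_curve <- function(props, baseline, base = exp(1), eps = 1e-3) {
  if (!is.numeric(baseline) || length(baseline) != 1L || baseline <= 0)
    stop("baseline must be a single positive proportion", call. = FALSE)
  if (any(props < 0)) stop("block proportions must be non-negative", call. = FALSE)
  log(pmax(props, eps) / baseline, base = base)
}

#' Paired t test between two components
#'
#' Standard paired two-sided t test on per-run means (wraps [stats::t.test()];
#' the test suite cross-checks it against the closed-form textbook statistic).
#' Pairs with zero difference variance are flagged as degenerate rather than
#' returning an infinite statistic.
#'
#' @param a,b equal-length paired samples (per-run means of the two
#'   components).
#' @return list with `t`, `df`, `p`, `ci` (95% CI of the mean difference),
#'   `mean_diff` and `degenerate`.
#' @export
paired_ttest <- function(a, b) {
  if (length(a) != length(b)) stop("paired samples differ in length", call. = FALSE)
  if (length(a) < 2L) stop("need at least two pairs", call. = FALSE)
  d <- a - b
  if (stats::sd(d) == 0) {
    if (mean(d) == 0) {
      # no difference anywhere: t is 0 by convention, nothing to test
      return(list(t = 0, df = length(d) - 1L, p = 1,
                  ci = c(0, 0), mean_diff = 0, degenerate = FALSE))
    }
    return(list(t = NA_real_, df = length(d) - 1L, p = NA_real_,
                ci = c(NA_real_, NA_real_), mean_diff = mean(d),
                degenerate = TRUE))
  }
  tt <- stats::t.test(a, b, paired = TRUE)
  list(t = unname(tt$statistic), df = unname(tt$parameter),
       p = tt$p.value, ci = unname(tt$conf.int), mean_diff = mean(d),
       degenerate = FALSE)
}

#' Mixed ANOVA (one within-run factor, one between-run factor)
#'
#' Fits the classical mixed-design ANOVA with subjects (runs) nested in the
#' between factor and crossed with the within factor, via [stats::aov()] with
#' an `Error(subject)` stratum, and reports F, dfs, p and partial eta squared
#' for the between effect, the within effect and their interaction.
#'
#' @param data data frame in long format.
#' @param dv name of the response column.
#' @param within name of the within-run factor column.
#' @param between name of the between-run factor column.
#' @param subject name of the run/subject identifier column (must be unique
#'   across conditions).
#' @return data frame with rows `between`, `within`, `interaction` and columns
#'   `effect`, `F`, `df1`, `df2`, `p`, `eta_p2`.
#' @export
mixed_anova <- function(data, dv = "mean_correct", within = "component",
                        between = "condition", subject = "run") {
  d <- data.frame(
    y = data[[dv]],
    w = factor(data[[within]]),
    b = factor(data[[between]]),
    id = factor(data[[subject]])
  )
  counts <- table(d$b, d$w)
  if (length(unique(as.vector(counts))) != 1L)
    stop("mixed_anova requires a balanced design (equal runs per condition ",
         "and one observation per run x component)", call. = FALSE)
  fit <- stats::aov(y ~ b * w + Error(id), data = d)
  sm <- summary(fit)
  tab_b <- sm[["Error: id"]][[1]]
  tab_w <- sm[["Error: Within"]][[1]]
  pull <- function(tab, term) {
    i <- match(term, trimws(rownames(tab)))
    ie <- match("Residuals", trimws(rownames(tab)))
    ss <- tab[i, "Sum Sq"]; sse <- tab[ie, "Sum Sq"]
    data.frame(F = tab[i, "F value"], df1 = tab[i, "Df"], df2 = tab[ie, "Df"],
               p = tab[i, "Pr(>F)"], eta_p2 = ss / (ss + sse))
  }
  out <- rbind(
    cbind(effect = "between", pull(tab_b, "b")),
    cbind(effect = "within", pull(tab_w, "w")),
    cbind(effect = "interaction", pull(tab_w, "b:w"))
  )
  rownames(out) <- NULL
  out
}

#' Extinction-window inferential statistics across conditions
#'
#' Runs the full extinction analysis used for the single-rule (high/low
#' density) experiment: per-run means over the analysis window (extinction
#' blocks 2-3 by default) feed a paired t test (within the multiple-schedule
#' condition) and a mixed ANOVA across all supplied conditions.
#'
#' @param results named list of `atp_result` objects, one per condition; the
#'   first is treated as the multiple-schedule (within-subjects) condition for
#'   the paired t test.
#' @param which_blocks extinction blocks entering the analysis window.
#' @return list with `means` (per-condition component means), `ttest`
#'   (paired t within the first condition), `control_ttests` and `anova`.
#' @export
extinction_stats <- function(results, which_blocks = 2:3) {
  stopifnot(length(results) >= 1)
  if (is.null(names(results)))
    names(results) <- vapply(results, function(r) r$spec$name, character(1))
  long <- do.call(rbind, lapply(names(results), function(nm) {
    bl <- results[[nm]]$blocks
    d <- bl[bl$phase == "extinction" & bl$block %in% which_blocks, ]
    agg <- stats::aggregate(cbind(mean_correct = d$prop_correct),
                            by = list(run = d$run, stimulus = d$stimulus),
                            FUN = mean)
    agg$condition <- nm
    agg$component <- factor(agg$stimulus, levels = 1:2,
                            labels = c("s1", "s2"))
    agg
  }))
  long$uid <- interaction(long$condition, long$run, drop = TRUE)
  ttests <- lapply(names(results), function(nm) {
    d <- long[long$condition == nm, ]
    wide <- stats::reshape(d[, c("run", "component", "mean_correct")],
                           idvar = "run", timevar = "component",
                           direction = "wide", sep = "_")
    paired_ttest(wide$mean_correct_s1, wide$mean_correct_s2)
  })
  names(ttests) <- names(results)
  means <- stats::aggregate(cbind(mean_correct = long$mean_correct),
                            by = list(condition = long$condition,
                                      component = long$component),
                            FUN = mean)
  an <- mixed_anova(long, dv = "mean_correct", within = "component",
                    between = "condition", subject = "uid")
  list(means = means, ttest = ttests[[1]],
       control_ttests = ttests[-1], anova = an)
}
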