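# Uniqueness-versus-originality decomposition: per tree, how strongly each
# non-redundant metric tracks the pendant edge (uniqueness) versus the mean
# pairwise distance (originality), and the linear trade-off between the two.

# the eight non-redundant metrics (FP, VW and CHR are duplicates of ED, MVW
# and APD respectively and are dropped)
axis_metrics <- function() c("PE", "SV", "ES", "MVW", "NWU", "NWW", "APD", "QE")

#' Spearman correlations with the uniqueness and originality axes
#'
#' For each of the eight non-redundant metrics, computes the Spearman rank
#' correlation (average ranks for ties) between its tip scores and (a) the
#' pendant-edge scores ("uniqueness") and (b) the average pairwise distance
#' scores ("originality"). PE and APD anchor the two ends with
#' self-correlation 1. A metric that is constant across tips has undefined
#' correlations; these are recorded as `NA` with a warning.
#'
#' @param tab A `score_table` from [compute_all()] containing all needed
#'   metrics, for a tree with at least 3 tips.
#' @return A `data.frame` with columns `metric`, `rho_unique`, `rho_orig`.
#' @export
axis_correlations <- function(tab) {
  mets <- axis_metrics()
  if (!all(mets %in% names(tab)))
    stop("score table lacks metric(s): ",
         paste(setdiff(mets, names(tab)), collapse = ", "))
  if (nrow(tab) < 3L) stop("need at least 3 tips")
  spear <- function(x, y) {
    if (stats::sd(x) == 0 || stats::sd(y) == 0) return(NA_real_)
    stats::cor(x, y, method = "spearman")
  }
  ru <- vapply(mets, function(m) spear(tab[[m]], tab$PE), 0)
  ro <- vapply(mets, function(m) spear(tab[[m]], tab$APD), 0)
  if (anyNA(c(ru, ro)))
    warning("constant score vector(s): correlation recorded as NA")
  data.frame(metric = mets, rho_unique = unname(ru), rho_orig = unname(ro),
             stringsAsFactors = FALSE)
}

#' Linear trade-off between the two isolation axes
#'
#' OLS fit of the uniqueness correlations on the originality correlations
#' across the eight metrics of one tree: the slope says how much a metric's
#' alignment with the pendant edge drops per unit of alignment with the
#' mean pairwise distance. A strongly negative slope means metrics aligned
#' with one axis are unaligned with the other.
#'
#' @param corrs Output of [axis_correlations()].
#' @return A list (class `"tradeoff_fit"`) with `slope`, `intercept`,
#'   `r2_adj` (adjusted R-squared, n - 2 denominator) and `n` points used.
#' @export
fit_axis_tradeoff <- function(corrs) {
  ok <- stats::complete.cases(corrs[, c("rho_unique", "rho_orig")])
  if (sum(ok) < 3L) stop("need at least 3 non-missing correlation pairs")
  x <- corrs$rho_orig[ok]
  y <- corrs$rho_unique[ok]
  if (stats::var(x) == 0) stop("degenerate fit: no variance in rho_orig")
  fit <- stats::lm(y ~ x)
  s <- summary(fit)
  structure(list(slope = unname(stats::coef(fit)[2L]),
                 intercept = unname(stats::coef(fit)[1L]),
                 r2_adj = s$adj.r.squared,
                 n = sum(ok)),
            class = "tradeoff_fit")
}

#' Aggregate trade-off fits over trees
#'
#' @param fits A list of `"tradeoff_fit"` objects (one per tree).
#' @return A `data.frame` with one row: mean and s.d. of the slopes and of
#'   the adjusted R-squared values, plus the number of trees.
#' @export
aggregate_over_trees <- function(fits) {
  if (length(fits) == 0L) stop("no fits supplied")
  sl <- vapply(fits, function(f) f$slope, 0)
  r2 <- vapply(fits, function(f) f$r2_adj, 0)
  data.frame(mean_slope = mean(sl),
             sd_slope = stats::sd(sl),
             mean_r2_adj = mean(r2),
             sd_r2_adj = stats::sd(r2),
             n_trees = length(fits))
}
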