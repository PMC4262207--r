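# The redundancy study machinery: standardisation, inter-metric Euclidean
# distances, average-linkage clustering, 50% majority-rule consensus,
# variation-captured subset analysis, and clade-size scaling profiles.

#' Standardise a score table by metric means
#'
#' Divides each metric's scores by its mean over tips, so that every metric
#' has mean 1 and metrics become comparable across trees. Idempotent.
#'
#' @param tab A `score_table` from [compute_all()] (or any data.frame with a
#'   `species` column and metric columns).
#' @return The standardised table, with attribute `standardised = TRUE`.
#' @export
standardize_scores <- function(tab) {
  cols <- metric_columns(tab)
  if (length(cols) == 0L) stop("no metric columns found")
  for (m in cols) {
    mu <- mean(tab[[m]])
    if (!is.finite(mu) || mu <= 0)
      stop("cannot standardise metric '", m, "': mean score is ", mu)
    tab[[m]] <- tab[[m]] / mu
  }
  attr(tab, "standardised") <- TRUE
  tab
}

#' Euclidean distance matrix among metrics
#'
#' Treats each metric's tip-score vector as a point and forms the matrix of
#' pairwise Euclidean distances among metrics. With the default
#' `scale = "sd"` every metric is first reduced to a common dispersion
#' (centred, unit variance), so the distances reflect how differently two
#' metrics order and space the species, not how wide their score
#' distributions happen to be; two metrics related by a positive affine map
#' (such as VW and MVW on bifurcating trees) are then at distance zero.
#' `scale = "mean"` instead divides each metric by its mean only
#' (the raw standardised scores), in which case dispersion differences
#' dominate the distances. With `normalise = TRUE` (default) the matrix is
#' divided by its mean off-diagonal entry, so the expected pairwise
#' distance is 1 and matrices are comparable across trees.
#'
#' @param tab A score table ([compute_all()]); standardisation state is
#'   irrelevant under `scale = "sd"`, and raw tables are mean-standardised
#'   first under `scale = "mean"`.
#' @param normalise Scale so the mean off-diagonal entry equals 1?
#' @param scale `"sd"` (default) or `"mean"`, see above.
#' @return A symmetric matrix with zero diagonal, dimnames = metric ids.
#' @export
metric_distance_matrix <- function(tab, normalise = TRUE,
                                   scale = c("sd", "mean")) {
  scale <- match.arg(scale)
  if (!isTRUE(attr(tab, "standardised"))) tab <- standardize_scores(tab)
  cols <- metric_columns(tab)
  if (length(cols) < 2L) stop("need at least 2 metrics")
  X <- as.matrix(as.data.frame(tab)[, cols, drop = FALSE])
  if (scale == "sd") {
    sds <- apply(X, 2L, stats::sd)
    if (any(sds == 0))
      stop("cannot scale constant metric(s): ",
           paste(cols[sds == 0], collapse = ", "))
    X <- base::scale(X)
  }
  D <- as.matrix(stats::dist(t(X)))
  dimnames(D) <- list(cols, cols)
  if (normalise) {
    off <- mean(D[row(D) != col(D)])
    if (off <= 0) stop("cannot normalise: all metrics identical")
    D <- D / off
  }
  D
}

#' Average-linkage hierarchical clustering of metrics
#'
#' @param dist_mat A symmetric distance matrix with dimnames (e.g. from
#'   [metric_distance_matrix()]).
#' @return An `hclust` object (average linkage). Rows are taken in the
#'   canonical metric order when recognised, so output is deterministic.
#' @export
hierarchical_cluster <- function(dist_mat) {
  if (!isSymmetric(unname(dist_mat))) stop("distance matrix not symmetric")
  lab <- rownames(dist_mat)
  canon <- intersect(c(metric_ids(), "APDPD"), lab)
  if (length(canon) == length(lab))
    dist_mat <- dist_mat[canon, canon, drop = FALSE]
  stats::hclust(stats::as.dist(dist_mat), method = "average")
}

# hclust -> rooted phylo over the same labels
as_dendro_phylo <- function(x) {
  if (inherits(x, "phylo")) return(x)
  if (inherits(x, "hclust")) return(ape::as.phylo(x))
  stop("expected an hclust or phylo object")
}

#' 50% majority-rule consensus of metric dendrograms
#'
#' Retains exactly those rooted clades present in more than half of the
#' input trees; merge heights are discarded, only topology is counted.
#' Clade support proportions are attached as node labels.
#'
#' @param dendrograms A list of `hclust` or rooted `phylo` objects over the
#'   same leaf set.
#' @param p Majority threshold (clades kept when support > `p`; default 0.5).
#' @return A rooted `phylo` object; `$node.label` holds the support
#'   proportion of each internal node (1 for the root).
#' @export
majority_consensus <- function(dendrograms, p = 0.5) {
  if (length(dendrograms) < 1L) stop("need at least one dendrogram")
  trees <- lapply(dendrograms, as_dendro_phylo)
  labs <- lapply(trees, function(t) sort(t$tip.label))
  if (!all(vapply(labs, identical, TRUE, labs[[1L]])))
    stop("dendrograms have mismatched leaf sets")
  class(trees) <- "multiPhylo"
  cons <- ape::consensus(trees, p = p, rooted = TRUE)
  counts <- ape::prop.clades(cons, trees, rooted = TRUE)
  counts[is.na(counts)] <- 0L
  cons$node.label <- counts / length(trees)
  cons
}

#' Does a rooted tree contain a given clade?
#'
#' @param phy A rooted `phylo` object.
#' @param tips Character vector of tip labels.
#' @return `TRUE` iff some node's complete descendant tip set equals `tips`.
#' @export
contains_clade <- function(phy, tips) {
  phy <- as_dendro_phylo(phy)
  tips <- sort(unique(tips))
  if (!all(tips %in% phy$tip.label)) return(FALSE)
  sets <- clade_tip_sets(phy)
  any(vapply(sets, function(s) identical(s, tips), TRUE))
}

# sorted descendant tip label set for every internal node
clade_tip_sets <- function(phy) {
  ix <- tree_index(phy)
  sets <- vector("list", ix$ntip + ix$nnode)
  for (i in seq_len(ix$ntip)) sets[[i]] <- phy$tip.label[i]
  for (nd in ix$postorder_nodes)
    sets[[nd]] <- sort(unlist(sets[ix$children[[nd]]], use.names = FALSE))
  sets[(ix$ntip + 1L):(ix$ntip + ix$nnode)]
}

#' Proportion of dendrograms containing a clade
#'
#' @param dendrograms List of `hclust`/`phylo` objects over one leaf set.
#' @param tips Tip labels of the clade of interest.
#' @return Fraction of input trees in which `tips` forms a complete clade.
#' @export
clade_support <- function(dendrograms, tips) {
  mean(vapply(dendrograms, contains_clade, TRUE, tips = tips))
}

# ---- variation captured --------------------------------------------------

# covariance matrix of the standardised metric columns of one table
score_covariance <- function(tab) {
  if (!isTRUE(attr(tab, "standardised"))) tab <- standardize_scores(tab)
  cols <- metric_columns(tab)
  stats::cov(as.matrix(as.data.frame(tab)[, cols, drop = FALSE]))
}

# variance-weighted mean R^2 of all metrics regressed on subset A,
# computed from a covariance matrix; var-0 metrics drop out of both sums
captured_from_cov <- function(S, subset) {
  A <- match(subset, colnames(S))
  if (anyNA(A)) stop("subset metric(s) absent from covariance matrix")
  SAA <- S[A, A, drop = FALSE]
  SAAi <- tryCatch(solve(SAA), error = function(e) MASS::ginv(SAA))
  P <- S[A, , drop = FALSE]
  num <- sum(P * (SAAi %*% P))
  den <- sum(diag(S))
  num / den
}

#' Fraction of total score variation captured by a metric subset
#'
#' Total variation is the summed per-metric variance of the
#' mean-standardised scores. Two notions of "captured" are provided.
#' `method = "share"` (default): the fraction of that total carried by the
#' subset's own score variances; redundant information in the unselected
#' metrics is deliberately not credited, so the fraction measures how much
#' of the raw spread of isolation scores the subset itself holds.
#' `method = "r2"`: every metric's standardised score vector is regressed
#' (OLS, intercept included) on the subset's score vectors and the fraction
#' is the variance-weighted mean R-squared, sum_j var_j R2_j / sum_j var_j
#' (R2 = 1 for subset members); because most metrics are strongly
#' correlated, this saturates quickly with subset size. Collinear subsets
#' are handled by the pseudo-inverse. Per-tree fractions are averaged over
#' trees.
#'
#' @param tables A standardised `score_table` or a list of them (raw tables
#'   are standardised internally); per-tree covariance matrices of
#'   standardised scores are also accepted.
#' @param subset Character vector of metric ids (aliases allowed).
#' @param method `"share"` or `"r2"`, see above.
#' @return Mean captured fraction in `[0, 1]`.
#' @export
variation_captured <- function(tables, subset, method = c("share", "r2")) {
  method <- match.arg(method)
  if (length(subset) == 0L) stop("'subset' must be non-empty")
  subset <- unique(resolve_metric(subset))
  if (inherits(tables, "data.frame")) tables <- list(tables)
  covs <- lapply(tables, function(t)
    if (is.matrix(t)) t else score_covariance(t))
  if (method == "share") {
    frac <- vapply(covs, function(S) {
      A <- match(subset, colnames(S))
      if (anyNA(A)) stop("subset metric(s) absent from covariance matrix")
      sum(diag(S)[A]) / sum(diag(S))
    }, 0)
  } else {
    frac <- vapply(covs, captured_from_cov, 0, subset = subset)
  }
  mean(frac)
}

#' Select a maximally informative metric subset
#'
#' Three selection modes. `"one-per-group"` (how the study picks its "k
#' most different metrics"): draw (seeded) one metric at random from each
#' of the supplied groups; `k` must equal the number of groups (see
#' [major_groups()], which cuts the metric clustering into `k` groups).
#' `"greedy"`: forward selection, at each step adding the metric that
#' maximises the mean captured variation ([variation_captured()], with the
#' given `method`) over the supplied trees.
#'
#' @param tables List of standardised score tables (or covariance matrices).
#' @param k Subset size, 1 <= k <= number of metrics.
#' @param mode `"one-per-group"` or `"greedy"`.
#' @param groups List of character vectors partitioning the metric ids
#'   (required for `"one-per-group"`).
#' @param seed Optional seed for the random per-group draw.
#' @param method Captured-variation method for `"greedy"` (see
#'   [variation_captured()]).
#' @return Character vector of selected metric ids.
#' @export
select_dissimilar_subset <- function(tables, k,
                                     mode = c("one-per-group", "greedy"),
                                     groups = NULL, seed = NULL,
                                     method = c("share", "r2")) {
  mode <- match.arg(mode)
  method <- match.arg(method)
  if (mode == "one-per-group") {
    if (is.null(groups)) stop("'groups' required for one-per-group mode")
    if (k != length(groups))
      stop("k = ", k, " but ", length(groups), " groups supplied")
    if (!is.null(seed)) set.seed(seed)
    return(vapply(groups, function(g) g[sample.int(length(g), 1L)], ""))
  }
  if (inherits(tables, "data.frame")) tables <- list(tables)
  covs <- lapply(tables, function(t)
    if (is.matrix(t)) t else score_covariance(t))
  all_m <- colnames(covs[[1L]])
  if (k < 1L || k > length(all_m)) stop("'k' out of range")
  chosen <- character(0)
  for (step in seq_len(k)) {
    cand <- setdiff(all_m, chosen)
    gain <- vapply(cand, function(m)
      variation_captured(covs, c(chosen, m), method = method), 0)
    # deterministic tie-break: canonical metric order (cand is in it)
    chosen <- c(chosen, cand[which.max(gain)])
  }
  chosen
}

#' Major metric groups from a pooled distance matrix
#'
#' Cuts the average-linkage clustering of a (mean, normalised) inter-metric
#' distance matrix into `k` groups. Used to operationalise the "major
#' groups" of the consensus clustering when drawing one metric per group.
#'
#' @param dist_mat Symmetric inter-metric distance matrix (typically the
#'   mean of per-tree normalised matrices).
#' @param k Number of groups (default 3).
#' @return List of `k` character vectors of metric ids.
#' @export
major_groups <- function(dist_mat, k = 3L) {
  hc <- hierarchical_cluster(dist_mat)
  grp <- stats::cutree(hc, k = k)
  unname(split(names(grp), grp))
}

# ---- clade-size scaling --------------------------------------------------

#' Isolation scores of one species across nested clades
#'
#' For each complete clade containing the target tip (smallest to full
#' tree), computes the tip's score under every metric plus APD/PD. With
#' `scale_by_max = TRUE` (default) each metric's sequence is divided by its
#' maximum, which makes the asymptotic behaviour across clade sizes
#' comparable among metrics.
#'
#' @param phy A `phylo` object.
#' @param tip Target tip label.
#' @param chr [chr_params()] for the character-rarity metric.
#' @param scale_by_max Scale each metric column by its maximum?
#' @return A `data.frame` with `clade_size` and one column per metric
#'   (including `APDPD`).
#' @export
clade_scaling_profile <- function(phy, tip, chr = chr_params(),
                                  scale_by_max = TRUE) {
  clades <- nested_clades(phy, tip)
  mets <- c(metric_ids(), "APDPD")
  rows <- lapply(clades, function(cl) {
    sc <- vapply(mets, function(m) isolation_score(cl, m, chr)[[tip]], 0)
    c(clade_size = length(cl$tip.label), sc)
  })
  out <- as.data.frame(do.call(rbind, rows))
  if (scale_by_max) {
    for (m in mets) {
      mx <- max(out[[m]])
      if (mx > 0) out[[m]] <- out[[m]] / mx
    }
  }
  out
}

#' OLS slope of scaled score against clade size over a window
#'
#' Fits, for every metric column of a [clade_scaling_profile()], the
#' ordinary least-squares slope of score against clade size restricted to
#' clade sizes within `window`. Quantifies how close to its asymptote each
#' metric is over that range of clade sizes.
#'
#' @param profile Output of [clade_scaling_profile()].
#' @param window Numeric `c(lo, hi)` clade-size window (inclusive).
#' @return Named numeric vector of slopes (per unit clade size).
#' @export
asymptote_slope <- function(profile, window) {
  if (length(window) != 2L || window[1L] > window[2L])
    stop("'window' must be c(lo, hi)")
  keep <- profile$clade_size >= window[1L] & profile$clade_size <= window[2L]
  if (sum(keep) < 2L) stop("fewer than 2 clades inside the window")
  x <- profile$clade_size[keep]
  mets <- setdiff(names(profile), "clade_size")
  vapply(mets, function(m) {
    y <- profile[[m]][keep]
    stats::cov(x, y) / stats::var(x)
  }, 0)
}
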