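# The eleven species-level evolutionary isolation metrics, each a map from a
# rooted tree (with branch lengths) to one non-negative score per tip.
# All path conventions are made explicit per metric; the conventions are
# chosen so that the documented identities hold exactly:
#   sum(FP) = PD,  sum(ES) = PD on bifurcating trees,
#   sum(SV) = total (unrooted) tree length,  MVW = VW/2 on bifurcating trees.

#' Canonical metric identifiers
#'
#' The canonical eleven-metric set used throughout the comparison machinery.
#' `"FP"` (fair proportion) is accepted everywhere as an alias of `"ED"`
#' (evolutionary distinctiveness): they are the same computation.
#'
#' @return Character vector of the eleven metric ids, in canonical order.
#' @export
metric_ids <- function() {
  c("PE", "ED", "SV", "ES", "VW", "MVW", "NWU", "NWW", "APD", "QE", "CHR")
}

# resolve user-supplied metric names (FP -> ED), with validation
resolve_metric <- function(metric) {
  m <- toupper(metric)
  m[m == "FP"] <- "ED"
  ok <- m %in% c(metric_ids(), "APDPD")
  if (!all(ok))
    stop("unknown metric id(s): ", paste(metric[!ok], collapse = ", "))
  m
}

#' Character-rarity parameters
#'
#' Parameters of the expected character-rarity score [character_rarity()]:
#' `nu`, the origination rate of novel characters per unit branch length,
#' and `rho`, the per-edge probability that a character is retained
#' (inherited) across one edge of the tree.
#'
#' @param nu Character origination rate per unit branch length (> 0).
#' @param rho Per-edge retention probability, in (0, 1]. The default is
#'   high: on macroevolutionary timescales a derived character is rarely
#'   lost across a single branch, and in the high-retention limit the score
#'   becomes an affine function of the average pairwise distance (see
#'   [character_rarity()]).
#' @return An object of class `"chr_params"`.
#' @export
chr_params <- function(nu = 1, rho = 0.99) {
  if (!is.numeric(nu) || length(nu) != 1L || nu <= 0)
    stop("'nu' must be a single positive number")
  if (!is.numeric(rho) || length(rho) != 1L || rho <= 0 || rho > 1)
    stop("'rho' must be a single number in (0, 1]")
  structure(list(nu = nu, rho = rho), class = "chr_params")
}

#' Pendant edge length (PE)
#'
#' The length of the terminal branch separating each species from the rest
#' of the tree: the "uniqueness" end of the isolation spectrum.
#'
#' @param phy A `phylo` object.
#' @return Named numeric vector of scores, one per tip.
#' @export
pendant_edge <- function(phy) {
  validate_tree(phy)
  ix <- tree_index(phy)
  stats::setNames(ix$elen[seq_len(ix$ntip)], phy$tip.label)
}

#' Fair proportion / evolutionary distinctiveness (FP, ED)
#'
#' Each branch's length is divided equally among the tips that descend from
#' it; a species' score is the sum of its shares along its root-to-tip path.
#' Scores over all tips partition total tree length (PD).
#'
#' @param phy A `phylo` object.
#' @return Named numeric vector of scores, one per tip.
#' @export
fair_proportion <- function(phy) {
  validate_tree(phy)
  ix <- tree_index(phy)
  acc <- numeric(ix$ntip + ix$nnode)
  pre <- ix$preorder
  for (k in seq_len(nrow(pre))) {
    p <- pre[k, 1L]; v <- pre[k, 2L]
    acc[v] <- acc[p] + ix$elen[v] / ix$ndesc[v]
  }
  stats::setNames(acc[seq_len(ix$ntip)], phy$tip.label)
}

#' Equal splits (ES)
#'
#' Like fair proportion, but a branch's credit is divided by the number of
#' daughter lineages at every node passed on the way down to the tip (so by
#' 2 per node on strictly bifurcating trees).
#'
#' @param phy A `phylo` object.
#' @return Named numeric vector of scores, one per tip.
#' @export
equal_splits <- function(phy) {
  validate_tree(phy)
  ix <- tree_index(phy)
  acc <- numeric(ix$ntip + ix$nnode)
  pre <- ix$preorder
  for (k in seq_len(nrow(pre))) {
    p <- pre[k, 1L]; v <- pre[k, 2L]
    acc[v] <- acc[p] / ix$nkids[p] + ix$elen[v]
  }
  stats::setNames(acc[seq_len(ix$ntip)], phy$tip.label)
}

#' Shapley value of the spanning-length game (SV)
#'
#' The cooperative-game allocation of total tree length: a species' score is
#' its expected marginal contribution to the spanning branch length of a
#' random subset of species, on the unrooted tree (the root is suppressed).
#' Closed form: for each edge e with a_e tips on species i's side,
#' i receives l_e (N - a_e) / (N a_e); summing the complementary share for
#' edges on the far side gives the full allocation. The scores over tips sum
#' to the total tree length (Shapley efficiency).
#'
#' @param phy A `phylo` object with N >= 2 tips.
#' @return Named numeric vector of scores, one per tip.
#' @seealso [shapley_bruteforce()] for the exact enumeration oracle.
#' @export
shapley_value <- function(phy) {
  validate_tree(phy)
  ix <- tree_index(phy)
  N <- ix$ntip
  nodes <- seq_len(N + ix$nnode)[-ix$root]
  a <- ix$ndesc[nodes]
  l <- ix$elen[nodes]
  # share received by tips NOT below the edge, summed over all edges
  base <- sum(l * a / (N * (N - a)))
  # walking down to a tip converts each on-path edge's share to the
  # below-the-edge form; accumulate the difference along root-to-tip paths
  diffv <- numeric(N + ix$nnode)
  pre <- ix$preorder
  for (k in seq_len(nrow(pre))) {
    p <- pre[k, 1L]; v <- pre[k, 2L]
    av <- ix$ndesc[v]
    diffv[v] <- diffv[p] +
      ix$elen[v] * ((N - av) / (N * av) - av / (N * (N - av)))
  }
  stats::setNames(base + diffv[seq_len(N)], phy$tip.label)
}

#' Exact Shapley value by subset enumeration
#'
#' Independent brute-force computation of the spanning-length Shapley value,
#' enumerating all subsets of tips with the combinatorial Shapley weights.
#' Intended as a correctness oracle for [shapley_value()]; refuses trees with
#' more than `max_tips` tips.
#'
#' @param phy A `phylo` object.
#' @param max_tips Enumeration cap (default 10).
#' @return Named numeric vector of exact Shapley values.
#' @export
shapley_bruteforce <- function(phy, max_tips = 10L) {
  validate_tree(phy)
  ix <- tree_index(phy)
  N <- ix$ntip
  if (N > max_tips)
    stop("brute-force enumeration refused for N = ", N, " > ", max_tips)
  nodes <- seq_len(N + ix$nnode)[-ix$root]
  # bitmask of tips below each edge (edge indexed by its child node)
  below <- integer(length(nodes))
  mask <- integer(N + ix$nnode)
  mask[seq_len(N)] <- bitwShiftL(1L, seq_len(N) - 1L)
  pe <- ix$postorder
  for (k in seq_len(nrow(pe)))
    mask[pe[k, 1L]] <- bitwOr(mask[pe[k, 1L]], mask[pe[k, 2L]])
  below <- mask[nodes]
  lens <- ix$elen[nodes]
  full <- bitwShiftL(1L, N) - 1L
  # spanning length of a tip subset S (as bitmask) on the unrooted tree:
  # an edge counts iff S has members on both of its sides
  vS <- function(S) {
    inS <- bitwAnd(below, S)
    sum(lens[inS != 0L & inS != S])
  }
  lf <- lfactorial(0:N)
  sv <- numeric(N)
  allS <- 0:(full)
  vals <- vapply(allS, vS, 0)
  for (i in seq_len(N)) {
    bi <- bitwShiftL(1L, i - 1L)
    for (S in allS) {
      if (bitwAnd(S, bi) != 0L) next
      s <- sum(bitwAnd(S, mask[seq_len(N)]) != 0L)
      w <- exp(lf[s + 1L] + lf[N - s] - lf[N + 1L])
      sv[i] <- sv[i] + w * (vals[bitwOr(S, bi) + 1L] - vals[S + 1L])
    }
  }
  stats::setNames(sv, phy$tip.label)
}

#' Vane-Wright node count index (VW)
#'
#' The reciprocal of the number of interior nodes on the path between a
#' species and the root (root included, tip excluded).
#'
#' @param phy A `phylo` object.
#' @return Named numeric vector of scores, one per tip.
#' @export
vane_wright <- function(phy) {
  validate_tree(phy)
  ix <- tree_index(phy)
  cnt <- path_accumulate(ix, rep(1, ix$ntip + ix$nnode))
  stats::setNames(1 / cnt[seq_len(ix$ntip)], phy$tip.label)
}

#' May's variant of the Vane-Wright index (MVW)
#'
#' The reciprocal of the summed daughter-lineage counts over the interior
#' nodes on the root-to-tip path (2 per node on bifurcating trees, so that
#' MVW = VW / 2 there; the variant exists to handle polytomies).
#'
#' @param phy A `phylo` object.
#' @return Named numeric vector of scores, one per tip.
#' @export
may_vane_wright <- function(phy) {
  validate_tree(phy)
  ix <- tree_index(phy)
  s <- path_accumulate(ix, ix$nkids)
  stats::setNames(1 / s[seq_len(ix$ntip)], phy$tip.label)
}

#' Nixon-Wheeler unweighted index (NWU)
#'
#' On the path from a tip to the root (tip included, root excluded) each
#' node's clade is compared with its sister clade(s): it contributes 1 when
#' it holds strictly more tips than every sister, otherwise 0. The score is
#' `1 / (1 + sum of contributions)`, so a maximally isolated species (never
#' on the larger side) scores 1.
#'
#' @param phy A `phylo` object.
#' @return Named numeric vector of scores, one per tip.
#' @export
nixon_wheeler_unweighted <- function(phy) {
  validate_tree(phy)
  ix <- tree_index(phy)
  n <- ix$ntip + ix$nnode
  b <- numeric(n)
  for (p in which(ix$nkids > 0L)) {
    ch <- ix$children[[p]]
    sz <- ix$ndesc[ch]
    if (length(ch) > 1L) {
      mx <- max(sz)
      # strictly larger than every sister: unique maximum
      b[ch] <- as.numeric(sz == mx & vapply(seq_along(ch), function(j)
        all(sz[j] > sz[-j]), TRUE))
    }
  }
  tot <- numeric(n)
  pre <- ix$preorder
  for (k in seq_len(nrow(pre))) {
    v <- pre[k, 2L]
    tot[v] <- tot[pre[k, 1L]] + b[v]
  }
  stats::setNames(1 / (1 + tot[seq_len(ix$ntip)]), phy$tip.label)
}

#' Nixon-Wheeler weighted index (NWW)
#'
#' The reciprocal of the summed descendant-species counts over the interior
#' nodes on the root-to-tip path (root included, tip excluded).
#'
#' @param phy A `phylo` object.
#' @return Named numeric vector of scores, one per tip.
#' @export
nixon_wheeler_weighted <- function(phy) {
  validate_tree(phy)
  ix <- tree_index(phy)
  s <- path_accumulate(ix, ix$ndesc)
  stats::setNames(1 / s[seq_len(ix$ntip)], phy$tip.label)
}

#' Average pairwise (patristic) distance (APD)
#'
#' A species' mean patristic distance to all other species: the
#' "originality" end of the isolation spectrum. With
#' `standardise_by_pd = TRUE` the scores are divided by total tree length,
#' giving the scale-free APD/PD variant used in clade-size scaling.
#'
#' @param phy A `phylo` object with N >= 2 tips.
#' @param standardise_by_pd Divide by total tree length? Default `FALSE`.
#' @return Named numeric vector of scores, one per tip.
#' @export
average_pairwise_distance <- function(phy, standardise_by_pd = FALSE) {
  D <- patristic_matrix(phy)
  apd <- rowSums(D) / (nrow(D) - 1L)
  if (standardise_by_pd) apd <- apd / tree_length(phy)
  apd
}

#' Rao quadratic entropy maximising weights (QE)
#'
#' The species weight vector p (non-negative, summing to 1) that maximises
#' Rao's quadratic entropy Q(p) = sum_ij p_i p_j d_ij over the patristic
#' distance matrix. Solved by an active-set scheme: the stationarity
#' condition D p = c 1 is solved on the current support, negative weights
#' are dropped to zero (which can genuinely occur for non-ultrametric
#' trees), and dropped species are re-admitted if they violate the KKT
#' optimality bound. On the support the KKT certificate (D p)_i = c holds.
#'
#' @param phy A `phylo` object with N >= 2 tips.
#' @return Named numeric vector of weights (summing to 1).
#' @export
qe_index <- function(phy) {
  D <- patristic_matrix(phy)
  if (all(D == 0)) stop("degenerate patristic matrix: all distances zero")
  p <- qe_weights(D)
  stats::setNames(p, rownames(D))
}

# active-set solver on an arbitrary distance matrix
qe_weights <- function(D, max_iter = 200L) {
  n <- nrow(D)
  act <- rep(TRUE, n)
  best <- NULL
  for (iter in seq_len(max_iter)) {
    idx <- which(act)
    A <- D[idx, idx, drop = FALSE]
    q <- tryCatch(solve(A, rep(1, length(idx))),
                  error = function(e) as.vector(MASS::ginv(A) %*%
                                                  rep(1, length(idx))))
    if (abs(sum(q)) < 1e-14) stop("singular system in QE active set")
    p <- q / sum(q)
    if (min(p) < -1e-12) {
      act[idx[which.min(p)]] <- FALSE
      next
    }
    full <- numeric(n)
    full[idx] <- pmax(p, 0)
    cval <- as.numeric(full %*% D %*% full)
    grad <- as.vector(D %*% full)
    viol <- which(!act & grad > cval + 1e-9 * max(cval, 1))
    if (length(viol) == 0L) return(full / sum(full))
    act[viol[which.max(grad[viol])]] <- TRUE
    best <- full / sum(full)
  }
  best
}

#' Expected character rarity (CHR)
#'
#' Models neutral character evolution: novel characters originate along each
#' branch at rate `nu` per unit length and are retained (inherited) across
#' each subsequent edge with probability `rho`. A species' score is the
#' expected number of characters it possesses, weighted by their rarity: it
#' sums, over the nodes k on its root-to-tip path, the expected number of
#' characters that arose on the edge above k, times the probability the
#' species retains them (`rho^(edges from k to the tip)`), times their
#' expected rarity in the extant assemblage (one minus the expected fraction
#' of all N species carrying them). A deterministic expectation; no
#' characters are simulated.
#'
#' In the perfect-retention limit `rho = 1` the score is, on an ultrametric
#' tree, an exactly affine function of the average pairwise distance (every
#' character separating a species from j marks patristic path length), which
#' is why CHR behaves as a close proxy of APD at high retention rates.
#'
#' @param phy A `phylo` object.
#' @param params A [chr_params()] object (defaults: `nu = 1`, `rho = 0.99`).
#' @return Named numeric vector of scores, one per tip.
#' @export
character_rarity <- function(phy, params = chr_params()) {
  validate_tree(phy)
  if (!inherits(params, "chr_params")) stop("'params' must be chr_params()")
  ix <- tree_index(phy)
  nu <- params$nu; rho <- params$rho
  n <- ix$ntip + ix$nnode
  # s[v] = sum over tips j below v of rho^(edge count v -> j)
  s <- numeric(n)
  s[seq_len(ix$ntip)] <- 1
  pe <- ix$postorder
  for (k in seq_len(nrow(pe)))
    s[pe[k, 1L]] <- s[pe[k, 1L]] + rho * s[pe[k, 2L]]
  # expected rarity among all N extant species of a character that arose on
  # the edge above v (species outside v cannot carry it)
  rarity <- 1 - s / ix$ntip
  # g[v] = score if v were the focal species; each step down multiplies the
  # accumulated expected-rarity mass by the retention probability
  g <- numeric(n)
  pre <- ix$preorder
  for (k in seq_len(nrow(pre))) {
    v <- pre[k, 2L]
    g[v] <- rho * g[pre[k, 1L]] + nu * ix$elen[v] * rarity[v]
  }
  stats::setNames(g[seq_len(ix$ntip)], phy$tip.label)
}

#' Compute one isolation metric by id
#'
#' @param phy A `phylo` object.
#' @param metric A metric id (see [metric_ids()]; `"FP"` is an alias of
#'   `"ED"`, `"APDPD"` is APD divided by total tree length).
#' @param chr [chr_params()] used when `metric = "CHR"`.
#' @return Named numeric vector of scores.
#' @export
isolation_score <- function(phy, metric, chr = chr_params()) {
  m <- resolve_metric(metric)
  switch(m,
         PE   = pendant_edge(phy),
         ED   = fair_proportion(phy),
         SV   = shapley_value(phy),
         ES   = equal_splits(phy),
         VW   = vane_wright(phy),
         MVW  = may_vane_wright(phy),
         NWU  = nixon_wheeler_unweighted(phy),
         NWW  = nixon_wheeler_weighted(phy),
         APD  = average_pairwise_distance(phy),
         APDPD = average_pairwise_distance(phy, standardise_by_pd = TRUE),
         QE   = qe_index(phy),
         CHR  = character_rarity(phy, chr))
}

#' Compute all eleven isolation metrics for a tree
#'
#' @param phy A `phylo` object.
#' @param chr [chr_params()] for the character-rarity metric.
#' @param standardise Divide each metric by its mean over tips? Default
#'   `FALSE`.
#' @return A `data.frame` (class `"score_table"`) with a `species` column
#'   and one column per metric id, plus a `"standardised"` attribute.
#' @export
compute_all <- function(phy, chr = chr_params(), standardise = FALSE) {
  validate_tree(phy)
  tab <- data.frame(species = phy$tip.label, stringsAsFactors = FALSE)
  for (m in metric_ids()) tab[[m]] <- unname(isolation_score(phy, m, chr))
  class(tab) <- c("score_table", "data.frame")
  attr(tab, "standardised") <- FALSE
  if (standardise) tab <- standardize_scores(tab)
  tab
}

# columns of a score table holding metric scores
metric_columns <- function(tab) intersect(c(metric_ids(), "APDPD"), names(tab))

# root-to-tip accumulation of a per-node weight over interior path nodes
# (root included, tip excluded)
path_accumulate <- function(ix, w) {
  acc <- numeric(ix$ntip + ix$nnode)
  pre <- ix$preorder
  for (k in seq_len(nrow(pre))) {
    p <- pre[k, 1L]
    acc[pre[k, 2L]] <- acc[p] + w[p]
  }
  acc
}
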