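# Homogeneous birth-death tree simulation conditioned on the number of
# extant tips, plus random threat-category assignment. These generate the
# study inputs: sets of ultrametric trees with birth rate lambda and death
# rate mu, pruned to extant lineages.

#' Birth-death simulation configuration
#'
#' @param n_tips Target number of extant tips (>= 2).
#' @param birth Speciation rate lambda per lineage per unit time (> 0).
#' @param death Extinction rate mu, with 0 <= mu < lambda.
#' @param replicates Number of trees to simulate.
#' @param seed Optional RNG seed for reproducibility.
#' @return An object of class `"bd_config"`.
#' @export
bd_config <- function(n_tips = 100L, birth = 0.5, death = 0,
                      replicates = 1000L, seed = NULL) {
  if (n_tips < 2L) stop("'n_tips' must be >= 2")
  if (birth <= 0) stop("'birth' must be positive")
  if (death < 0 || death >= birth)
    stop("'death' must satisfy 0 <= death < birth")
  structure(list(n_tips = as.integer(n_tips), birth = birth, death = death,
                 replicates = as.integer(replicates), seed = seed),
            class = "bd_config")
}

#' Simulate one birth-death tree with a fixed number of extant tips
#'
#' Forward simulation in continuous time from a crown split (two lineages at
#' time zero). Events occur at combined rate k(lambda + mu) for k extant
#' lineages; when the extant count first reaches `n_tips` the process is
#' stopped and truncated at a time drawn just before the next would-be event
#' (so no pendant edge has length zero). Extinct lineages are pruned and
#' degree-2 nodes collapsed, yielding an ultrametric tree with exactly
#' `n_tips` tips labelled `t1..tn`. Whole-tree extinction triggers a fresh
#' attempt, up to `max_retries`.
#'
#' @param n_tips Number of extant tips.
#' @param birth Speciation rate lambda.
#' @param death Extinction rate mu.
#' @param seed Optional RNG seed (set once at entry).
#' @param max_retries Attempts before giving up after repeated whole-tree
#'   extinction (default 1000).
#' @return An ultrametric `phylo` object with `n_tips` tips.
#' @export
simulate_bd_tree <- function(n_tips = 100L, birth = 0.5, death = 0,
                             seed = NULL, max_retries = 1000L) {
  if (!is.null(seed)) set.seed(seed)
  cfg <- bd_config(n_tips, birth, death, 1L)
  for (try in seq_len(max_retries)) {
    phy <- sim_bd_once(cfg$n_tips, cfg$birth, cfg$death)
    if (!is.null(phy)) return(phy)
  }
  stop("whole-tree extinction in all ", max_retries, " attempts")
}

#' Simulate a replicate set of birth-death trees
#'
#' @param config A [bd_config()] object. Its `seed` (when non-NULL) is set
#'   once, so the whole set is reproducible and each replicate differs.
#' @return A list of `phylo` objects of length `config$replicates`, with
#'   class `"multiPhylo"`.
#' @export
simulate_bd_trees <- function(config) {
  if (!inherits(config, "bd_config")) stop("'config' must be a bd_config()")
  if (!is.null(config$seed)) set.seed(config$seed)
  out <- vector("list", config$replicates)
  for (i in seq_len(config$replicates))
    out[[i]] <- simulate_bd_tree(config$n_tips, config$birth, config$death)
  class(out) <- "multiPhylo"
  out
}

# one forward pass; returns NULL on whole-tree extinction
sim_bd_once <- function(n_tips, birth, death) {
  rate <- birth + death
  pbirth <- birth / rate
  cap <- 4L * n_tips + 16L
  parent <- integer(cap)
  tb <- numeric(cap)
  te <- numeric(cap)
  live <- c(1L, 2L)
  nlin <- 2L
  t <- 0
  repeat {
    k <- length(live)
    if (k == 0L) return(NULL)
    if (k == n_tips) {
      present <- t + stats::rexp(1L, k * rate)
      break
    }
    t <- t + stats::rexp(1L, k * rate)
    j <- sample.int(k, 1L)
    i <- live[j]
    te[i] <- t
    if (stats::runif(1L) < pbirth) {
      if (nlin + 2L > cap) {
        cap <- cap * 2L
        length(parent) <- cap; length(tb) <- cap; length(te) <- cap
      }
      c1 <- nlin + 1L; c2 <- nlin + 2L
      parent[c(c1, c2)] <- i
      tb[c(c1, c2)] <- t
      nlin <- nlin + 2L
      live <- c(live[-j], c1, c2)
    } else {
      live <- live[-j]
    }
  }
  te[live] <- present
  build_bd_phylo(parent[seq_len(nlin)], tb[seq_len(nlin)], te[seq_len(nlin)],
                 live, n_tips)
}

# assemble the lineage records into a pruned, relabelled phylo object
build_bd_phylo <- function(parent, tb, te, live, n_tips) {
  nlin <- length(parent)
  has_kids <- tabulate(parent[parent > 0L], nbins = nlin) > 0L
  tipsL <- which(!has_kids)
  intL <- which(has_kids)
  ntip <- length(tipsL)
  node_of <- integer(nlin)
  node_of[tipsL] <- seq_len(ntip)
  node_of[intL] <- ntip + 1L + seq_along(intL)   # ntip+1 is the crown root
  from <- integer(nlin)
  from[parent == 0L] <- ntip + 1L
  from[parent > 0L] <- node_of[parent[parent > 0L]]
  edge <- cbind(from, node_of)
  dimnames(edge) <- NULL
  storage.mode(edge) <- "integer"
  phy <- list(edge = edge,
              edge.length = te - tb,
              tip.label = paste0("x", seq_len(ntip)),
              Nnode = length(intL) + 1L)
  class(phy) <- "phylo"
  phy <- ape::reorder.phylo(phy, "cladewise")
  extinct <- setdiff(tipsL, live)
  if (length(extinct))
    phy <- ape::drop.tip(phy, paste0("x", node_of[extinct]))
  phy$root.edge <- NULL
  phy$tip.label <- paste0("t", seq_len(n_tips))
  phy
}

#' Randomly assign IUCN-style threat categories
#'
#' Assigns each species a category from LC, NT, VU, EN, CR with the given
#' probabilities. A synthetic stand-in for real red-list data, used to
#' exercise the EDGE ranking machinery.
#'
#' @param species Character vector of species labels (non-empty, unique).
#' @param probs Named or positional probabilities for LC, NT, VU, EN, CR
#'   (default uniform); need not sum to 1 (they are normalised).
#' @param seed Optional RNG seed.
#' @return A `data.frame` with columns `species` and `category` (factor with
#'   levels LC, NT, VU, EN, CR).
#' @export
simulate_threat_categories <- function(species,
                                       probs = c(LC = 0.2, NT = 0.2,
                                                 VU = 0.2, EN = 0.2,
                                                 CR = 0.2),
                                       seed = NULL) {
  if (length(species) == 0L) stop("'species' must be non-empty")
  if (anyDuplicated(species)) stop("duplicate species labels")
  if (length(probs) != 5L || any(probs < 0) || sum(probs) <= 0)
    stop("'probs' must be 5 non-negative values with positive sum")
  if (!is.null(seed)) set.seed(seed)
  lv <- c("LC", "NT", "VU", "EN", "CR")
  cat <- sample(lv, length(species), replace = TRUE, prob = probs)
  data.frame(species = as.character(species),
             category = factor(cat, levels = lv),
             stringsAsFactors = FALSE)
}
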