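# Shared fixtures (built in code) and independent oracles.

tree_T2 <- function() parse_newick("(A:1,B:1);")
tree_T3 <- function() parse_newick("((A:1,B:1):1,C:2);")
tree_S4 <- function() parse_newick("(A:1,B:1,C:1,D:1);")
tree_cat4 <- function() parse_newick("(((A:1,B:1):1,C:2):1,D:3);")

# small random ultrametric trees for property runs
random_trees <- function(n, n_tips = 8L, death = 0.25, seed = 1L) {
  set.seed(seed)
  lapply(seq_len(n), function(i) simulate_bd_tree(n_tips, 0.5, death))
}

# independent patristic oracle: explicit root-path edge sets, the path i-j
# is their symmetric difference
patristic_oracle <- function(phy) {
  nt <- length(phy$tip.label)
  parent <- integer(nt + phy$Nnode)
  parent[phy$edge[, 2]] <- phy$edge[, 1]
  elen <- numeric(nt + phy$Nnode)
  elen[phy$edge[, 2]] <- phy$edge.length
  path_nodes <- lapply(seq_len(nt), function(i) {
    out <- integer(0)
    nd <- i
    while (nd != nt + 1L) {
      out <- c(out, nd)
      nd <- parent[nd]
    }
    out
  })
  d <- matrix(0, nt, nt, dimnames = list(phy$tip.label, phy$tip.label))
  for (i in seq_len(nt - 1L)) for (j in (i + 1L):nt) {
    sym <- c(setdiff(path_nodes[[i]], path_nodes[[j]]),
             setdiff(path_nodes[[j]], path_nodes[[i]]))
    d[i, j] <- d[j, i] <- sum(elen[sym])
  }
  d
}

# grid-search oracle for the Rao-QE maximising weights (3 or 4 tips)
qe_grid_oracle <- function(D, step = 0.001) {
  n <- nrow(D)
  stopifnot(n %in% c(3L, 4L))
  g <- seq(0, 1, by = step)
  best <- NULL
  bestq <- -Inf
  if (n == 3L) {
    for (p1 in g) {
      p2 <- seq(0, 1 - p1, by = step)
      p3 <- 1 - p1 - p2
      q <- 2 * (p1 * p2 * D[1, 2] + p1 * p3 * D[1, 3] + p2 * p3 * D[2, 3])
      k <- which.max(q)
      if (q[k] > bestq) {
        bestq <- q[k]
        best <- c(p1, p2[k], p3[k])
      }
    }
  } else {
    for (p1 in g) for (p2 in seq(0, 1 - p1, by = step)) {
      p3 <- seq(0, 1 - p1 - p2, by = step)
      p4 <- 1 - p1 - p2 - p3
      q <- 2 * (p1 * p2 * D[1, 2] + p1 * p3 * D[1, 3] + p1 * p4 * D[1, 4] +
                  p2 * p3 * D[2, 3] + p2 * p4 * D[2, 4] + p3 * p4 * D[3, 4])
      k <- which.max(q)
      if (q[k] > bestq) {
        bestq <- q[k]
        best <- c(p1, p2, p3[k], p4[k])
      }
    }
  }
  best
}
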