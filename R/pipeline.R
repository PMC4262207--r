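# Seeded experiment runners: the end-to-end redundancy study over sets of
# simulated birth-death trees, plus CSV-emitting experiment wrappers.

#' Run the full metric-redundancy study on simulated trees
#'
#' For each death rate in `deaths`, simulates `n_trees` birth-death trees
#' with `n_tips` tips, computes and standardises all eleven isolation
#' metrics per tree, forms the normalised inter-metric distance matrix and
#' its average-linkage dendrogram, and accumulates per-tree score
#' covariances. For the set with death rate `axis_death` it additionally
#' runs the uniqueness-originality decomposition (per-tree trade-off fits).
#' A single seed drives one sequential RNG stream, so the whole study is
#' reproducible.
#'
#' @param n_trees Replicate trees per death-rate set.
#' @param n_tips Tips per tree.
#' @param birth Speciation rate lambda.
#' @param deaths Vector of extinction rates mu, one simulation set each.
#' @param chr [chr_params()] for the character-rarity metric.
#' @param seed RNG seed (set once).
#' @param axis_death The death rate whose set carries the axis
#'   decomposition (`NA` to skip).
#' @param verbose Print per-set progress?
#' @return An object of class `"evoiso_study"`: a list with `sets` (one
#'   entry per death rate: `death`, `mean_dist` (dispersion-equalised,
#'   normalised), `mean_dist_raw` (mean-standardised only, normalised),
#'   `dendrograms`, `covs`, `consensus`), `axis` (data.frame of per-tree
#'   slope and adjusted R^2, or NULL) and the call parameters.
#' @export
run_redundancy_study <- function(n_trees = 1000L, n_tips = 100L,
                                 birth = 0.5,
                                 deaths = c(0, 0.125, 0.25, 0.4),
                                 chr = chr_params(), seed = 1L,
                                 axis_death = 0.25, verbose = FALSE) {
  set.seed(seed)
  sets <- vector("list", length(deaths))
  axis <- NULL
  for (si in seq_along(deaths)) {
    mu <- deaths[si]
    if (verbose)
      message("simulating set ", si, "/", length(deaths), " (mu = ", mu, ")")
    dend <- vector("list", n_trees)
    covs <- vector("list", n_trees)
    dsum <- dsum_mean <- 0
    do_axis <- !is.na(axis_death) && isTRUE(all.equal(mu, axis_death))
    ax_slope <- ax_r2 <- if (do_axis) numeric(n_trees) else NULL
    for (i in seq_len(n_trees)) {
      phy <- simulate_bd_tree(n_tips, birth, mu)
      tab <- compute_all(phy, chr = chr, standardise = TRUE)
      D <- metric_distance_matrix(tab)
      dsum <- dsum + D
      dsum_mean <- dsum_mean + metric_distance_matrix(tab, scale = "mean")
      dend[[i]] <- ape::as.phylo(hierarchical_cluster(D))
      covs[[i]] <- score_covariance(tab)
      if (do_axis) {
        f <- fit_axis_tradeoff(axis_correlations(tab))
        ax_slope[i] <- f$slope
        ax_r2[i] <- f$r2_adj
      }
    }
    sets[[si]] <- list(death = mu,
                       mean_dist = dsum / n_trees,
                       mean_dist_raw = dsum_mean / n_trees,
                       dendrograms = dend,
                       covs = covs,
                       consensus = majority_consensus(dend))
    if (do_axis)
      axis <- data.frame(tree = seq_len(n_trees),
                         slope = ax_slope, r2_adj = ax_r2)
  }
  structure(list(sets = sets, axis = axis,
                 n_trees = n_trees, n_tips = n_tips, birth = birth,
                 deaths = deaths, seed = seed),
            class = "evoiso_study")
}

#' Mean normalised distance between two metrics across a study
#'
#' @param study An `"evoiso_study"` object.
#' @param a,b Metric ids (aliases allowed).
#' @return Mean, over all trees of all simulation sets, of the normalised
#'   inter-metric distance matrix entry (a, b).
#' @export
mean_metric_distance <- function(study, a, b) {
  a <- resolve_metric(a); b <- resolve_metric(b)
  mean(vapply(study$sets, function(s) s$mean_dist[a, b], 0))
}

# pooled per-tree covariance matrices of a study
study_covariances <- function(study)
  unlist(lapply(study$sets, `[[`, "covs"), recursive = FALSE)

# pooled mean normalised inter-metric distance matrix of a study;
# scale = "sd" (dispersion-equalised) or "mean" (mean-standardised only)
study_mean_dist <- function(study, scale = c("sd", "mean")) {
  scale <- match.arg(scale)
  field <- if (scale == "sd") "mean_dist" else "mean_dist_raw"
  Reduce(`+`, lapply(study$sets, `[[`, field)) / length(study$sets)
}

#' Captured variation for the k most different metrics, k = 1..k_max
#'
#' For each subset size k, the metric clustering (average linkage on the
#' study's pooled mean-standardised inter-metric distances) is cut into k
#' groups, one metric is drawn at random from each group, and the captured
#' fraction of total score variation is computed ([variation_captured()]);
#' draws are repeated and averaged. This operationalises "selecting the k
#' most different metrics": every selected metric represents one cluster of
#' mutually similar metrics.
#'
#' @param study An `"evoiso_study"` object.
#' @param k_max Largest subset size.
#' @param n_draws Seeded random draws per k to average (default 20).
#' @param seed Seed for the draws.
#' @param method Captured-variation method (see [variation_captured()]).
#' @return A `data.frame` with columns `k` and `captured`.
#' @export
captured_variation_curve <- function(study, k_max = 5L, n_draws = 20L,
                                     seed = 1L, method = "share") {
  covs <- study_covariances(study)
  md <- study_mean_dist(study, scale = "mean")
  set.seed(seed)
  cap <- vapply(seq_len(k_max), function(k) {
    groups <- major_groups(md, k = k)
    mean(vapply(seq_len(n_draws), function(d) {
      pick <- vapply(groups, function(g) g[sample.int(length(g), 1L)], "")
      variation_captured(covs, pick, method = method)
    }, 0))
  }, 0)
  data.frame(k = seq_len(k_max), captured = cap)
}

#' Captured variation for one random metric per major group
#'
#' Identifies `n_groups` major metric groups by cutting the clustering of
#' the study's pooled mean-standardised inter-metric distances
#' ([major_groups()]), then repeatedly draws one metric per group and
#' computes the mean captured variation; the draws are averaged.
#'
#' @param study An `"evoiso_study"` object.
#' @param n_groups Number of major groups (default 3).
#' @param n_draws Number of seeded random draws to average (default 20).
#' @param seed Seed for the draws.
#' @param method Captured-variation method (see [variation_captured()]).
#' @return A list with `groups`, `mean_captured`, and the per-draw values.
#' @export
group_sample_captured <- function(study, n_groups = 3L, n_draws = 20L,
                                  seed = 1L, method = "share") {
  groups <- major_groups(study_mean_dist(study, scale = "mean"),
                         k = n_groups)
  covs <- study_covariances(study)
  set.seed(seed)
  vals <- vapply(seq_len(n_draws), function(d) {
    pick <- vapply(groups, function(g) g[sample.int(length(g), 1L)], "")
    variation_captured(covs, pick, method = method)
  }, 0)
  list(groups = groups, mean_captured = mean(vals), draws = vals)
}

#' Summary of the uniqueness-originality trade-off in a study
#'
#' @param study An `"evoiso_study"` object run with a non-`NA`
#'   `axis_death`.
#' @return A one-row `data.frame`: mean/s.d. of per-tree slopes and of
#'   adjusted R-squared values.
#' @export
axis_summary <- function(study) {
  if (is.null(study$axis)) stop("study was run without an axis set")
  data.frame(mean_slope = mean(study$axis$slope),
             sd_slope = stats::sd(study$axis$slope),
             mean_r2_adj = mean(study$axis$r2_adj),
             sd_r2_adj = stats::sd(study$axis$r2_adj),
             n_trees = nrow(study$axis))
}

#' Run a named experiment and write its outputs
#'
#' Seeded, file-emitting wrappers over the package's analysis stages.
#' Experiments: `"redundancy"` (mean inter-metric distances and per-set
#' consensus trees), `"variation"` (greedy captured-variation curve),
#' `"axis"` (per-tree trade-off fits and summary), `"edge"` (EDGE lists for
#' every metric on one simulated tree with random threat categories, plus
#' top-k comparison against the ED list), `"clade_scaling"` (nested-clade
#' profile of one tip on one large tree). All outputs are CSV or newick; a
#' `manifest.txt` records the configuration, so identical configurations
#' give identical outputs.
#'
#' @param experiment One of `"redundancy"`, `"variation"`, `"axis"`,
#'   `"edge"`, `"clade_scaling"`.
#' @param out_dir Output directory (created if needed).
#' @param n_trees,n_tips,birth,deaths Simulation grid (see
#'   [run_redundancy_study()]).
#' @param chr [chr_params()].
#' @param seed RNG seed.
#' @param top_k Top-k size for the `"edge"` experiment.
#' @return Invisibly, the list of files written.
#' @export
run_experiment <- function(experiment = c("redundancy", "variation", "axis",
                                          "edge", "clade_scaling"),
                           out_dir, n_trees = 1000L, n_tips = 100L,
                           birth = 0.5, deaths = c(0, 0.125, 0.25, 0.4),
                           chr = chr_params(), seed = 1L, top_k = 100L) {
  experiment <- match.arg(experiment)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  files <- character(0)
  emit <- function(df, name) {
    path <- file.path(out_dir, name)
    utils::write.csv(format(df, digits = 10), path,
                     row.names = FALSE, quote = FALSE)
    files <<- c(files, path)
  }
  if (experiment %in% c("redundancy", "variation", "axis")) {
    study <- run_redundancy_study(n_trees, n_tips, birth,
                                  deaths = if (experiment == "axis") 0.25
                                           else deaths,
                                  chr = chr, seed = seed)
    if (experiment == "redundancy") {
      md <- study_mean_dist(study)
      emit(data.frame(metric = rownames(md), round(md, 10)),
           "mean_metric_distances.csv")
      for (s in study$sets) {
        path <- file.path(out_dir, paste0("consensus_mu", s$death, ".nwk"))
        cons <- s$consensus
        cons$node.label <- formatC(cons$node.label, digits = 4,
                                   format = "g")
        ape::write.tree(cons, path)
        files <- c(files, path)
      }
    } else if (experiment == "variation") {
      emit(captured_variation_curve(study, k = 5L), "captured_variation.csv")
    } else {
      emit(study$axis, "axis_fits.csv")
      emit(axis_summary(study), "axis_summary.csv")
    }
  } else if (experiment == "edge") {
    set.seed(seed)
    phy <- simulate_bd_tree(n_tips, birth, deaths[1L])
    threat <- simulate_threat_categories(phy$tip.label)
    ref <- build_edge_list(phy, threat, "ED", chr)
    emit(ref, "edge_ED.csv")
    k <- min(top_k, n_tips)
    comp <- lapply(setdiff(metric_ids(), "ED"), function(m) {
      el <- build_edge_list(phy, threat, m, chr)
      emit(el, paste0("edge_", m, ".csv"))
      cc <- compare_top_k(ref, el, k)
      data.frame(metric = m, shared = cc$shared,
                 rank_similarity = cc$rank_similarity,
                 unique_scores = cc$unique_scores_other)
    })
    emit(do.call(rbind, comp), "edge_comparison.csv")
  } else {  # clade_scaling
    set.seed(seed)
    phy <- simulate_bd_tree(n_tips, birth, deaths[1L])
    tip <- phy$tip.label[1L]
    prof <- clade_scaling_profile(phy, tip, chr)
    emit(prof, "clade_scaling_profile.csv")
  }
  manifest <- file.path(out_dir, "manifest.txt")
  writeLines(c(paste("experiment:", experiment),
               paste("n_trees:", n_trees),
               paste("n_tips:", n_tips),
               paste("birth:", birth),
               paste("deaths:", paste(deaths, collapse = ",")),
               paste("chr_nu:", chr$nu),
               paste("chr_rho:", chr$rho),
               paste("seed:", seed)),
             manifest)
  invisible(c(files, manifest))
}
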