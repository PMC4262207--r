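# EDGE-style prioritisation: combine a standardised isolation score with an
# ordinal threat category, rank species, and compare ranked lists.

# IUCN-style ordinal threat coding used by the EDGE formula
ge_levels <- c(LC = 0, NT = 1, VU = 2, EN = 3, CR = 4)

# accept factors/characters (LC..CR) or integers 0..4
resolve_ge <- function(ge) {
  if (is.numeric(ge)) {
    if (any(ge < 0 | ge > 4)) stop("numeric GE must be in 0..4")
    return(as.numeric(ge))
  }
  g <- ge_levels[as.character(ge)]
  if (anyNA(g)) stop("unknown threat category: ",
                     paste(unique(as.character(ge)[is.na(g)]), collapse = ", "))
  unname(g)
}

#' EDGE score
#'
#' `EDGE = ln(1 + isolation) + GE * ln(2)`, where GE encodes the threat
#' category LC..CR as 0..4. One threat-category step adds exactly ln 2.
#'
#' @param isolation Non-negative (standardised) isolation score(s).
#' @param ge Threat categories: characters/factors among LC, NT, VU, EN, CR
#'   or integers 0..4.
#' @return Numeric EDGE score(s).
#' @export
edge_score <- function(isolation, ge) {
  if (any(isolation < 0)) stop("'isolation' must be non-negative")
  log1p(isolation) + resolve_ge(ge) * log(2)
}

#' Build a ranked EDGE list from a tree and threat table
#'
#' Computes the chosen isolation metric on the tree, standardises it by its
#' mean, combines it with the threat categories via [edge_score()], and
#' ranks species by descending EDGE score (ties get average ranks; rows are
#' ordered by rank, then species label).
#'
#' @param phy A `phylo` object.
#' @param threat A `data.frame` with columns `species` and `category`
#'   covering every tip (e.g. from [simulate_threat_categories()] or
#'   [read_threat_table()]).
#' @param metric Isolation metric id (default `"ED"`).
#' @param chr [chr_params()] for the character-rarity metric.
#' @return A `data.frame` (class `"edge_list"`) with columns `species`,
#'   `isolation` (standardised), `GE`, `EDGE`, `rank`.
#' @export
build_edge_list <- function(phy, threat, metric = "ED", chr = chr_params()) {
  validate_tree(phy)
  missing <- setdiff(phy$tip.label, threat$species)
  if (length(missing))
    stop("no threat category for: ",
         paste(utils::head(missing, 5L), collapse = ", "),
         if (length(missing) > 5L) ", ...")
  iso <- isolation_score(phy, metric, chr)
  iso <- iso / mean(iso)
  ge <- resolve_ge(threat$category[match(phy$tip.label, threat$species)])
  edge <- edge_score(iso, ge)
  rk <- rank(-edge, ties.method = "average")
  out <- data.frame(species = phy$tip.label,
                    isolation = unname(iso),
                    GE = ge,
                    EDGE = unname(edge),
                    rank = rk,
                    stringsAsFactors = FALSE)
  out <- out[order(out$rank, out$species), ]
  rownames(out) <- NULL
  class(out) <- c("edge_list", "data.frame")
  out
}

#' Compare the top k of two EDGE lists
#'
#' @param reference,other `edge_list` objects over the same species
#'   universe.
#' @param k Size of the head of each list to compare.
#' @return A list with `shared` (species in both top-k sets),
#'   `rank_similarity` (Spearman correlation, over the reference's top-k
#'   species, of the two lists' full ranks) and `unique_scores_other`
#'   (number of distinct isolation values in `other` across all species).
#' @export
compare_top_k <- function(reference, other, k) {
  if (!setequal(reference$species, other$species))
    stop("the two lists cover different species sets")
  if (k > nrow(reference)) stop("'k' exceeds list length")
  topk <- function(el) el$species[order(el$rank, el$species)][seq_len(k)]
  ref_top <- topk(reference)
  shared <- length(intersect(ref_top, topk(other)))
  r1 <- reference$rank[match(ref_top, reference$species)]
  r2 <- other$rank[match(ref_top, other$species)]
  rho <- if (stats::sd(r1) == 0 || stats::sd(r2) == 0) NA_real_
         else stats::cor(r1, r2, method = "spearman")
  list(shared = shared,
       rank_similarity = rho,
       unique_scores_other = length(unique(other$isolation)))
}

#' Read / write a threat-category table
#'
#' CSV with columns `species,category`, categories among LC, NT, VU, EN,
#' CR.
#'
#' @param file Path to a CSV file.
#' @return For `read_threat_table`, a `data.frame` with `species` and
#'   `category` (factor).
#' @export
read_threat_table <- function(file) {
  d <- utils::read.csv(file, stringsAsFactors = FALSE)
  if (!all(c("species", "category") %in% names(d)))
    stop("threat CSV must have columns 'species' and 'category'")
  bad <- setdiff(unique(d$category), names(ge_levels))
  if (length(bad)) stop("unknown categories: ", paste(bad, collapse = ", "))
  d$category <- factor(d$category, levels = names(ge_levels))
  d
}

#' @rdname read_threat_table
#' @param threat A threat table.
#' @export
write_threat_table <- function(threat, file) {
  utils::write.csv(threat, file, row.names = FALSE, quote = FALSE)
  invisible(file)
}
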