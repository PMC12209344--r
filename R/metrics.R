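# Diet composition summaries: FOO and wPOO.

#' Frequency of occurrence (FOO)
#'
#' The proportion of scats whose diet contains each prey taxon. Support is
#' sparse: taxa detected in no scat are absent from the result rather than
#' zero-valued.
#'
#' @param compositions nonempty list of assigned `scat_composition` objects.
#' @return named numeric vector, taxon -> proportion in (0, 1].
#' @export
compute_foo <- function(compositions) {
  compositions <- check_assigned(compositions)
  n <- length(compositions)
  counts <- table(unlist(lapply(compositions, function(c) unique(c$diet_items$taxon_id))))
  out <- as.numeric(counts) / n
  stats::setNames(out, names(counts))[order(names(counts))]
}

#' Weighted percent of occurrence (wPOO)
#'
#' Each scat contributes total weight `1/N`, split uniformly among the `T_i`
#' prey taxa it contains, so a taxon's wPOO reflects the proportion of diet
#' it represents per scat, combined across scats; the vector sums to 1.
#' With `weighting = "rra"` a scat's weight is split by within-scat read
#' share instead of uniformly (sensitivity analysis; occurrence-based
#' weighting is the default and the reported statistic).
#'
#' @param compositions nonempty list of assigned `scat_composition` objects,
#'   each with at least one diet item (run [apply_exclusions()] first).
#' @param weighting `"presence"` (default) or `"rra"`.
#' @return named numeric vector, taxon -> proportion; sums to 1.
#' @export
compute_wpoo <- function(compositions, weighting = c("presence", "rra")) {
  weighting <- match.arg(weighting)
  compositions <- check_assigned(compositions)
  n <- length(compositions)
  empty <- vapply(compositions, function(c) nrow(c$diet_items) == 0L, TRUE)
  if (any(empty))
    stop("scat(s) with empty diet reached compute_wpoo; run apply_exclusions first: ",
         paste(vapply(compositions[empty], `[[`, "", "scat_id"), collapse = ", "),
         call. = FALSE)
  acc <- new.env(parent = emptyenv())
  for (c in compositions) {
    items <- c$diet_items
    w <- if (weighting == "presence") {
      rep(1 / nrow(items), nrow(items))
    } else {
      items$share / sum(items$share)
    }
    for (i in seq_len(nrow(items))) {
      k <- items$taxon_id[i]
      acc[[k]] <- (acc[[k]] %||% 0) + w[i] / n
    }
  }
  taxa <- sort(ls(acc))
  stats::setNames(vapply(taxa, function(k) acc[[k]], numeric(1)), taxa)
}

#' @noRd
check_assigned <- function(compositions) {
  if (inherits(compositions, "scat_composition"))
    compositions <- list(compositions)
  if (length(compositions) == 0L)
    stop("no assigned scats to summarize", call. = FALSE)
  ok <- vapply(compositions, function(c)
    inherits(c, "scat_composition") && c$status == "assigned", TRUE)
  if (!all(ok))
    stop("all compositions must be assigned scat_composition objects",
         call. = FALSE)
  compositions
}

#' Diet profile of one defecator species
#'
#' @param compositions assigned `scat_composition` objects, all with the same
#'   defecator.
#' @param species_label label for the profile; defaults to the common
#'   defecator taxon.
#' @param config a [filter_config()]; `wpoo_weighting` is honoured.
#' @return object of class `diet_profile` with `species_label`, `n_scats`,
#'   `foo` and `wpoo` (sparse named vectors on a common support).
#' @export
build_diet_profile <- function(compositions, species_label = NULL,
                               config = filter_config()) {
  compositions <- check_assigned(compositions)
  defs <- unique(vapply(compositions, `[[`, "", "defecator"))
  if (length(defs) > 1L)
    stop("compositions span several defecators: ",
         paste(defs, collapse = ", "), call. = FALSE)
  structure(list(
    species_label = species_label %||% defs,
    n_scats = length(compositions),
    foo = compute_foo(compositions),
    wpoo = compute_wpoo(compositions, weighting = config$wpoo_weighting)
  ), class = "diet_profile")
}

#' @export
print.diet_profile <- function(x, ...) {
  cat(sprintf("Diet profile of %s (%d scats, %d taxa)\n",
              x$species_label, x$n_scats, length(x$foo)))
  ord <- order(-x$wpoo)
  for (k in names(x$wpoo)[ord])
    cat(sprintf("  %-30s FOO %3.0f%%  wPOO %3.0f%%\n",
                k, 100 * x$foo[[k]], 100 * x$wpoo[[k]]))
  invisible(x)
}

#' Aggregate scat compositions to a coarser taxonomic rank
#'
#' Diet items are re-keyed by their label at the requested rank (empty labels
#' roll up to the nearest nonempty coarser rank) and merged within each scat:
#' reads and shares add, presence merges. FOO/wPOO are then recomputable on
#' the aggregated compositions.
#'
#' @param compositions assigned `scat_composition` objects.
#' @param rank one of `"species"`, `"genus"`, `"family"`, `"order"`,
#'   `"class"`.
#' @param taxonomy a [taxonomy_table()] resolving every diet taxon.
#' @return list of re-keyed `scat_composition` objects.
#' @export
aggregate_rank <- function(compositions, rank, taxonomy) {
  compositions <- check_assigned(compositions)
  lapply(compositions, function(c) {
    items <- c$diet_items
    if (nrow(items) == 0L) return(c)
    lbl <- rank_label(taxonomy, items$taxon_id, rank)
    agg <- data.frame(
      taxon_id = sort(unique(lbl)),
      stringsAsFactors = FALSE)
    agg$combined_reads <- vapply(agg$taxon_id, function(g)
      sum(items$combined_reads[lbl == g]), numeric(1))
    agg$share <- vapply(agg$taxon_id, function(g)
      sum(items$share[lbl == g]), numeric(1))
    agg <- agg[order(-agg$combined_reads, agg$taxon_id), , drop = FALSE]
    rownames(agg) <- NULL
    c$diet_items <- agg
    c
  })
}

#' Summary comparison of two diet profiles
#'
#' Richness of each profile, union/intersection sizes of their supports and
#' the shared fraction `|A intersect B| / |A union B|`; with a taxonomy,
#' per-rank richness is added for both species.
#'
#' @param profile_a,profile_b `diet_profile` objects on a common taxonomy.
#' @param taxonomy optional [taxonomy_table()] for per-rank richness.
#' @return list with `richness_a`, `richness_b`, `union_size`,
#'   `intersection_size`, `shared_fraction`, `shared_taxa`, and optionally
#'   `rank_richness` (data.frame).
#' @export
diet_summary <- function(profile_a, profile_b, taxonomy = NULL) {
  a <- names(profile_a$foo); b <- names(profile_b$foo)
  u <- union(a, b); i <- intersect(a, b)
  out <- list(
    species = c(profile_a$species_label, profile_b$species_label),
    richness_a = length(a), richness_b = length(b),
    union_size = length(u), intersection_size = length(i),
    shared_fraction = if (length(u)) length(i) / length(u) else NA_real_,
    shared_taxa = sort(i))
  if (!is.null(taxonomy)) {
    ranks <- c("species", "family", "order", "class")
    out$rank_richness <- data.frame(
      rank = ranks,
      richness_a = vapply(ranks, function(r)
        length(unique(rank_label(taxonomy, a, r))), integer(1)),
      richness_b = vapply(ranks, function(r)
        length(unique(rank_label(taxonomy, b, r))), integer(1)),
      union = vapply(ranks, function(r)
        length(unique(rank_label(taxonomy, u, r))), integer(1)),
      stringsAsFactors = FALSE)
    rownames(out$rank_richness) <- NULL
  }
  out
}

# Metric vector of a composition set, used by overlap code.
#' @noRd
profile_vector <- function(compositions, metric = c("wpoo", "foo"),
                           config = filter_config()) {
  metric <- match.arg(metric)
  if (metric == "foo") compute_foo(compositions)
  else compute_wpoo(compositions, weighting = config$wpoo_weighting)
}
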