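#' Relative read abundance within one PCR replicate
#'
#' RRA is a taxon's read count divided by the replicate's total reads; the
#' retention thresholds of the consensus filter are expressed on this scale.
#'
#' @param replicate_counts named numeric vector, taxon -> reads, for one
#'   replicate; at least one count must be positive.
#' @return named numeric vector of proportions summing to 1.
#' @export
#' @examples
#' compute_rra(c(A = 60, B = 40))
compute_rra <- function(replicate_counts) {
  if (length(replicate_counts) == 0L || is.null(names(replicate_counts)))
    stop("replicate_counts must be a named taxon -> reads vector", call. = FALSE)
  if (any(replicate_counts < 0)) stop("negative read count", call. = FALSE)
  total <- sum(replicate_counts)
  if (total == 0) stop("all-zero replicate has no relative read abundance",
                       call. = FALSE)
  replicate_counts / total
}

#' Replicate-consensus filtering of one scat
#'
#' Collapses a scat's PCR replicates into a single retained composition. A
#' replicate is *valid* iff its total reads strictly exceed
#' `config$min_reads_per_replicate`; with fewer than `config$min_replicates`
#' valid replicates the scat fails amplification. A taxon is *retained* iff
#' its RRA reaches `config$min_rra` in at least `config$min_replicates` valid
#' replicates (the 2-of-3 consensus rule under the defaults); its combined
#' reads are summed over valid replicates only. Taxa meeting the same rule at
#' the looser `exploration_rra` but not at `min_rra` are returned as
#' exploration-only flags and never enter downstream summaries.
#'
#' With `config$rra_scope = "pooled"` the RRA threshold is instead evaluated
#' on reads pooled across valid replicates, while detection (any reads) in
#' `min_replicates` valid replicates is still required.
#'
#' @param scat_records rows of a [read_count_table()] for a single scat.
#' @param config a [filter_config()].
#' @return list with elements `status` (`"ok"` or `"failed_amplification"`),
#'   `retained` (named integer, taxon -> combined reads across valid
#'   replicates), `exploration` (character vector of exploration-only taxa),
#'   `valid_replicates` (integer ids) and `replicate_totals`.
#' @export
filter_scat <- function(scat_records, config = filter_config()) {
  stopifnot(inherits(config, "filter_config"))
  scat_records <- as.data.frame(scat_records)
  if (nrow(scat_records) == 0L)
    return(list(status = "failed_amplification",
                retained = stats::setNames(integer(0), character(0)),
                exploration = character(0),
                valid_replicates = integer(0),
                replicate_totals = stats::setNames(numeric(0), character(0))))
  if (length(unique(scat_records$scat_id)) > 1L)
    stop("filter_scat expects records of a single scat", call. = FALSE)

  reps <- sort(unique(scat_records$replicate))
  totals <- vapply(reps, function(r)
    sum(scat_records$reads[scat_records$replicate == r]), numeric(1))
  names(totals) <- reps
  valid <- reps[totals > config$min_reads_per_replicate]

  empty <- stats::setNames(integer(0), character(0))
  if (length(valid) < config$min_replicates)
    return(list(status = "failed_amplification", retained = empty,
                exploration = character(0), valid_replicates = integer(0),
                replicate_totals = totals))

  taxa <- sort(unique(scat_records$taxon_id))
  # reads matrix: taxa x valid replicates
  reads <- vapply(valid, function(r) {
    v <- replicate_counts(scat_records, scat_records$scat_id[1], r)
    out <- stats::setNames(numeric(length(taxa)), taxa)
    out[names(v)] <- v
    out
  }, numeric(length(taxa)))
  reads <- matrix(reads, nrow = length(taxa),
                  dimnames = list(taxa, as.character(valid)))
  combined <- rowSums(reads)

  if (config$rra_scope == "replicate") {
    rra <- sweep(reads, 2, colSums(reads), "/")
    qual_main <- rowSums(rra >= config$min_rra) >= config$min_replicates
    qual_expl <- rowSums(rra >= config$exploration_rra) >= config$min_replicates
  } else {
    pooled_rra <- combined / sum(combined)
    detected <- rowSums(reads > 0) >= config$min_replicates
    qual_main <- detected & pooled_rra >= config$min_rra
    qual_expl <- detected & pooled_rra >= config$exploration_rra
  }

  retained <- combined[qual_main]
  exploration <- taxa[qual_expl & !qual_main]
  list(status = "ok",
       retained = stats::setNames(as.integer(round(retained)), names(retained)),
       exploration = exploration,
       valid_replicates = as.integer(valid),
       replicate_totals = totals)
}

#' Filter every scat of a read-count table
#'
#' @param counts a [read_count_table()].
#' @param config a [filter_config()].
#' @return named list of [filter_scat()] results, one per scat (input order
#'   of first appearance).
#' @export
filter_all_scats <- function(counts, config = filter_config()) {
  scats <- unique(counts$scat_id)
  out <- lapply(scats, function(s)
    filter_scat(counts[counts$scat_id == s, , drop = FALSE], config))
  stats::setNames(out, scats)
}
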