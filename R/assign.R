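# Defecator identification and scat-level exclusions.
#
# A scat contains the depositing carnivore's own DNA alongside prey DNA, so
# the defecator must be identified from the read counts themselves before
# its reads can be separated from diet.

#' @noRd
new_scat_composition <- function(scat_id, status, defecator = NA_character_,
                                 diet_items = empty_diet_items(),
                                 exploration = character(0),
                                 total_retained_reads = 0) {
  structure(list(scat_id = scat_id, status = status, defecator = defecator,
                 diet_items = diet_items, exploration = exploration,
                 total_retained_reads = total_retained_reads),
            class = "scat_composition")
}

#' @noRd
empty_diet_items <- function() {
  data.frame(taxon_id = character(0), combined_reads = integer(0),
             share = numeric(0), stringsAsFactors = FALSE)
}

#' @export
print.scat_composition <- function(x, ...) {
  cat(sprintf("Scat %s: %s", x$scat_id, x$status))
  if (!is.na(x$defecator)) cat(sprintf(" (defecator: %s)", x$defecator))
  cat("\n")
  if (nrow(x$diet_items)) {
    cat(sprintf("  %d diet item(s):\n", nrow(x$diet_items)))
    for (i in seq_len(nrow(x$diet_items)))
      cat(sprintf("    %-30s %6d reads  %5.1f%%\n", x$diet_items$taxon_id[i],
                  x$diet_items$combined_reads[i], 100 * x$diet_items$share[i]))
  }
  if (length(x$exploration))
    cat("  exploration-only:", paste(x$exploration, collapse = ", "), "\n")
  invisible(x)
}

#' Assign the defecating carnivore of a filtered scat
#'
#' Applies the two read-count rules: (1) if exactly one candidate carnivore
#' is among the retained taxa, it is the defecator; (2) with several
#' carnivores, the one with the most combined reads is the defecator provided
#' the remaining carnivores' reads make up less than
#' `config$max_other_carnivore_share` of the total retained reads of the
#' sample — those sub-threshold carnivores are treated as contamination and
#' removed, not counted as diet (override with `config$carnivores_as_prey`).
#' Otherwise the scat is `ambiguous_defecator`; a read-count tie for the
#' dominant carnivore is always ambiguous, never broken arbitrarily. Scats
#' with no retained carnivore get status `no_carnivore`.
#'
#' Diet-item shares are computed against the one common sample total: the
#' summed combined reads of all retained taxa (defecator and removed
#' carnivores included).
#'
#' @param filtered result of [filter_scat()] (status `"ok"`), or a named
#'   taxon -> combined reads vector.
#' @param taxonomy a [taxonomy_table()].
#' @param config a [filter_config()].
#' @param scat_id scat label carried into the result.
#' @return A `scat_composition` with status one of `assigned`,
#'   `ambiguous_defecator`, `no_carnivore`.
#' @export
assign_defecator <- function(filtered, taxonomy, config = filter_config(),
                             scat_id = "scat") {
  stopifnot(inherits(config, "filter_config"))
  if (is.list(filtered) && !is.null(filtered$status)) {
    if (filtered$status == "failed_amplification")
      stop("cannot assign a defecator to a failed-amplification scat",
           call. = FALSE)
    exploration <- filtered$exploration
    retained <- filtered$retained
  } else {
    exploration <- character(0)
    retained <- filtered
  }
  if (is.null(names(retained)))
    stop("retained must be a named taxon -> reads vector", call. = FALSE)
  unknown <- setdiff(names(retained), taxonomy$taxon_id)
  if (length(unknown))
    stop("taxon absent from taxonomy: ", paste(unknown, collapse = ", "),
         call. = FALSE)

  total <- sum(retained)
  carn <- intersect(names(retained), carnivore_ids(taxonomy))

  if (length(carn) == 0L)
    return(new_scat_composition(scat_id, "no_carnivore",
                                exploration = exploration,
                                total_retained_reads = total))

  removed <- character(0)
  if (length(carn) == 1L) {
    defecator <- carn
  } else {
    creads <- retained[carn]
    top <- max(creads)
    if (sum(creads == top) > 1L)
      return(new_scat_composition(scat_id, "ambiguous_defecator",
                                  exploration = exploration,
                                  total_retained_reads = total))
    defecator <- carn[which.max(creads)]
    others <- setdiff(carn, defecator)
    ok <- if (config$other_carnivore_scope == "combined") {
      sum(retained[others]) / total < config$max_other_carnivore_share
    } else {
      all(retained[others] / total < config$max_other_carnivore_share)
    }
    if (!ok)
      return(new_scat_composition(scat_id, "ambiguous_defecator",
                                  exploration = exploration,
                                  total_retained_reads = total))
    if (!config$carnivores_as_prey) removed <- others
  }

  diet_taxa <- setdiff(names(retained), c(defecator, removed))
  items <- data.frame(taxon_id = diet_taxa,
                      combined_reads = as.integer(retained[diet_taxa]),
                      share = as.numeric(retained[diet_taxa]) / total,
                      stringsAsFactors = FALSE)
  items <- items[order(-items$combined_reads, items$taxon_id), , drop = FALSE]
  rownames(items) <- NULL
  new_scat_composition(scat_id, "assigned", defecator = defecator,
                       diet_items = items, exploration = exploration,
                       total_retained_reads = total)
}

#' Apply the no-diet exclusion rule to an assigned scat
#'
#' A scat that only contains defecator DNA, or whose diet items all fall
#' below `config$min_item_share` of sample reads, is excluded
#' (`excluded_no_diet`). Otherwise items individually below the threshold are
#' dropped and the scat kept; shares are not renormalized (they remain
#' fractions of the one sample total). Idempotent; non-`assigned` scats pass
#' through unchanged.
#'
#' @param comp a `scat_composition`.
#' @param config a [filter_config()].
#' @return The updated `scat_composition`.
#' @export
apply_exclusions <- function(comp, config = filter_config()) {
  stopifnot(inherits(comp, "scat_composition"))
  if (comp$status != "assigned") return(comp)
  keep <- comp$diet_items$share >= config$min_item_share
  if (nrow(comp$diet_items) == 0L || !any(keep)) {
    comp$status <- "excluded_no_diet"
    comp$diet_items <- empty_diet_items()
    return(comp)
  }
  comp$diet_items <- comp$diet_items[keep, , drop = FALSE]
  rownames(comp$diet_items) <- NULL
  comp
}

#' Per-scat status table of a composition collection
#'
#' @param compositions list of `scat_composition` objects.
#' @return data.frame with `scat_id`, `status`, `defecator`.
#' @export
composition_status_table <- function(compositions) {
  data.frame(
    scat_id = vapply(compositions, `[[`, "", "scat_id"),
    status = vapply(compositions, `[[`, "", "status"),
    defecator = vapply(compositions, `[[`, "", "defecator"),
    stringsAsFactors = FALSE)
}

#' @noRd
assigned_only <- function(compositions) {
  Filter(function(c) c$status == "assigned", compositions)
}
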