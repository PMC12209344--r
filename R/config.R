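#' Filtering and analysis thresholds
#'
#' Bundles every tunable threshold of the pipeline. Defaults reproduce the
#' field-standard protocol this package implements: a PCR replicate counts as
#' successfully amplified only when its total reads exceed
#' `min_reads_per_replicate` (strict `>`); a taxon is retained when it reaches
#' `min_rra` relative read abundance in at least `min_replicates` valid
#' replicates; taxa passing only the looser `exploration_rra` are flagged for
#' manual examination and excluded from every summary; a scat is assigned to
#' the dominant carnivore when all other carnivore reads jointly make up less
#' than `max_other_carnivore_share` of the sample; diet items below
#' `min_item_share` of sample reads are dropped, and scats left with no diet
#' are excluded.
#'
#' @param min_reads_per_replicate integer; replicate valid iff total reads
#'   strictly exceed this (default 1000).
#' @param min_rra minimum relative read abundance for retention (default 0.01).
#' @param exploration_rra looser RRA bound defining exploration-only taxa
#'   (default 0.005); must satisfy `0 < exploration_rra <= min_rra < 1`.
#' @param min_replicates number of valid replicates a taxon must qualify in
#'   (default 2, the 2-of-3 rule).
#' @param max_other_carnivore_share non-dominant carnivore reads must be below
#'   this share of total retained sample reads (default 0.10).
#' @param min_item_share diet items below this share of sample reads are
#'   dropped (default 0.01).
#' @param null_iterations randomization-null iterations (default 10000).
#' @param bootstrap_iterations scat-bootstrap replicates (default 10000).
#' @param seed integer seed for the stochastic stages.
#' @param rra_scope `"replicate"` evaluates `min_rra` within each replicate
#'   (default); `"pooled"` evaluates it on reads pooled across valid
#'   replicates (detection in `min_replicates` replicates still required).
#' @param other_carnivore_scope `"combined"` compares the summed reads of all
#'   non-dominant carnivores against `max_other_carnivore_share` (default);
#'   `"each"` requires every non-dominant carnivore to be individually below
#'   it.
#' @param carnivores_as_prey keep sub-threshold non-defecator carnivores as
#'   diet items instead of discarding them as contamination (default FALSE).
#' @param wpoo_weighting `"presence"` gives each of a scat's items weight
#'   `1/T_i` (default); `"rra"` weights items by their read share within the
#'   scat.
#'
#' @return An object of class `filter_config` (a validated named list).
#' @seealso [read_filter_config()] to load one from a key-value file.
#' @export
#' @examples
#' cfg <- filter_config(min_rra = 0.01, min_replicates = 2)
#' cfg$min_reads_per_replicate
filter_config <- function(min_reads_per_replicate = 1000L,
                          min_rra = 0.01,
                          exploration_rra = 0.005,
                          min_replicates = 2L,
                          max_other_carnivore_share = 0.10,
                          min_item_share = 0.01,
                          null_iterations = 10000L,
                          bootstrap_iterations = 10000L,
                          seed = 1L,
                          rra_scope = c("replicate", "pooled"),
                          other_carnivore_scope = c("combined", "each"),
                          carnivores_as_prey = FALSE,
                          wpoo_weighting = c("presence", "rra")) {
  rra_scope <- match.arg(rra_scope)
  other_carnivore_scope <- match.arg(other_carnivore_scope)
  wpoo_weighting <- match.arg(wpoo_weighting)

  if (!is.numeric(min_reads_per_replicate) || min_reads_per_replicate < 0)
    stop("min_reads_per_replicate must be a nonnegative count", call. = FALSE)
  assert_proportion(min_rra, "min_rra")
  assert_proportion(exploration_rra, "exploration_rra")
  if (exploration_rra > min_rra)
    stop("exploration_rra must satisfy 0 < exploration_rra <= min_rra",
         call. = FALSE)
  if (!is.numeric(min_replicates) || min_replicates < 1)
    stop("min_replicates must be >= 1", call. = FALSE)
  assert_proportion(max_other_carnivore_share, "max_other_carnivore_share")
  assert_proportion(min_item_share, "min_item_share")
  if (null_iterations < 1 || bootstrap_iterations < 1)
    stop("iteration counts must be >= 1", call. = FALSE)

  structure(list(
    min_reads_per_replicate = as.numeric(min_reads_per_replicate),
    min_rra = min_rra,
    exploration_rra = exploration_rra,
    min_replicates = as.integer(min_replicates),
    max_other_carnivore_share = max_other_carnivore_share,
    min_item_share = min_item_share,
    null_iterations = as.integer(null_iterations),
    bootstrap_iterations = as.integer(bootstrap_iterations),
    seed = as.integer(seed),
    rra_scope = rra_scope,
    other_carnivore_scope = other_carnivore_scope,
    carnivores_as_prey = isTRUE(carnivores_as_prey),
    wpoo_weighting = wpoo_weighting
  ), class = "filter_config")
}

#' Read a flat key-value configuration file
#'
#' One `key = value` (or `key: value`) pair per line; keys are exactly the
#' arguments of [filter_config()]. Blank lines and `#` comments are ignored.
#' Unknown keys are an error, so typos never silently fall back to defaults.
#'
#' @param path path to the configuration file.
#' @return A `filter_config` object.
#' @export
read_filter_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) return(filter_config())
  m <- regmatches(lines, regexec("^([A-Za-z_][A-Za-z0-9_]*)\\s*[=:]\\s*(.+)$", lines))
  bad <- vapply(m, length, 1L) != 3L
  if (any(bad))
    stop("unparseable config line(s): ", paste(lines[bad], collapse = "; "),
         call. = FALSE)
  keys <- vapply(m, `[`, "", 2L)
  vals <- trimws(vapply(m, `[`, "", 3L))
  allowed <- names(formals(filter_config))
  unknown <- setdiff(keys, allowed)
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  parse1 <- function(v) {
    if (tolower(v) %in% c("true", "false")) return(tolower(v) == "true")
    n <- suppressWarnings(as.numeric(v))
    if (!is.na(n)) return(n)
    v
  }
  args <- stats::setNames(lapply(vals, parse1), keys)
  do.call(filter_config, args)
}

#' Write a configuration to a flat key-value file
#'
#' @param config a `filter_config` object.
#' @param path destination path.
#' @return `path`, invisibly.
#' @export
write_filter_config <- function(config, path) {
  stopifnot(inherits(config, "filter_config"))
  writeLines(sprintf("%s = %s", names(config),
                     vapply(config, function(v) format(v, digits = 15), "")),
             path)
  invisible(path)
}

#' @export
print.filter_config <- function(x, ...) {
  cat("Filtering and analysis configuration:\n")
  for (k in names(x)) cat(sprintf("  %-26s %s\n", k, format(x[[k]])))
  invisible(x)
}
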