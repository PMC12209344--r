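#' Build a validated taxonomy table
#'
#' The taxonomy maps each reported taxon to its Linnaean ranks and flags the
#' mammalian carnivores that could have deposited a scat (candidate
#' defecators). Finer ranks may be empty for items only identifiable to a
#' coarser rank (e.g. a chipmunk reported as "Tamias sp." has an empty
#' species label).
#'
#' @param df data.frame with columns `taxon_id`, `class_name`, `order_name`,
#'   `family_name`, `genus_name`, `species_name`, `candidate_defecator`.
#' @return The validated data.frame with class `taxonomy_table`.
#' @export
taxonomy_table <- function(df) {
  required <- c("taxon_id", "class_name", "order_name", "family_name",
                "genus_name", "species_name", "candidate_defecator")
  missing <- setdiff(required, names(df))
  if (length(missing))
    stop("taxonomy is missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  df <- df[required]
  for (col in required[1:6]) {
    df[[col]] <- as.character(df[[col]])
    df[[col]][is.na(df[[col]])] <- ""
  }
  df$candidate_defecator <- parse_flag(df$candidate_defecator)

  dup <- df$taxon_id[duplicated(df$taxon_id)]
  if (length(dup))
    stop("duplicate taxon_id in taxonomy: ", paste(unique(dup), collapse = ", "),
         call. = FALSE)
  if (any(!nzchar(df$taxon_id)))
    stop("empty taxon_id in taxonomy", call. = FALSE)
  if (any(!nzchar(df$class_name)))
    stop("class_name must be nonempty for every taxon; offending taxon: ",
         df$taxon_id[!nzchar(df$class_name)][1], call. = FALSE)
  bad <- df$candidate_defecator & df$order_name != "Carnivora"
  if (any(bad))
    stop("candidate_defecator set on non-Carnivora taxon: ",
         paste(df$taxon_id[bad], collapse = ", "), call. = FALSE)

  rownames(df) <- NULL
  class(df) <- c("taxonomy_table", "data.frame")
  df
}

#' @noRd
parse_flag <- function(x) {
  if (is.logical(x)) {
    if (anyNA(x)) stop("candidate_defecator must not be NA", call. = FALSE)
    return(x)
  }
  v <- tolower(trimws(as.character(x)))
  out <- v %in% c("true", "t", "1", "yes")
  okfalse <- v %in% c("false", "f", "0", "no")
  if (any(!out & !okfalse))
    stop("unparseable candidate_defecator value(s): ",
         paste(unique(v[!out & !okfalse]), collapse = ", "), call. = FALSE)
  out
}

#' Read a taxonomy table from CSV/TSV
#'
#' The delimiter (comma or tab) is sniffed from the header line. Column names
#' other than the canonical seven can be supplied via `col_map`, so deposited
#' tables with their own headers load without editing.
#'
#' @param path path to a delimited text file.
#' @param col_map optional named character vector mapping canonical column
#'   names (names of the vector) to the file's column names (values), e.g.
#'   `c(taxon_id = "Taxon", class_name = "Class", ...)`.
#' @return A `taxonomy_table`.
#' @export
read_taxonomy_table <- function(path, col_map = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- read_delim_sniffed(path)
  df <- apply_col_map(df, col_map)
  taxonomy_table(df)
}

#' Write a taxonomy table to CSV
#' @param taxonomy a `taxonomy_table`.
#' @param path destination path.
#' @return `path`, invisibly.
#' @export
write_taxonomy_table <- function(taxonomy, path) {
  utils::write.csv(as.data.frame(taxonomy), path, row.names = FALSE)
  invisible(path)
}

#' @noRd
apply_col_map <- function(df, col_map) {
  if (is.null(col_map)) return(df)
  if (is.null(names(col_map)) || any(!nzchar(names(col_map))))
    stop("col_map must be a named character vector", call. = FALSE)
  absent <- setdiff(unname(col_map), names(df))
  if (length(absent))
    stop("col_map refers to absent column(s): ",
         paste(absent, collapse = ", "), call. = FALSE)
  for (canonical in names(col_map))
    names(df)[names(df) == col_map[[canonical]]] <- canonical
  df
}

# Rank label with roll-up: an empty label at the requested rank falls back to
# the nearest nonempty coarser rank (species -> genus -> family -> order ->
# class), so genus-level items like "Tamias sp." aggregate sensibly.
#' @noRd
rank_label <- function(taxonomy, taxon_ids, rank) {
  ladder <- c(species = "species_name", genus = "genus_name",
              family = "family_name", order = "order_name",
              class = "class_name")
  if (!rank %in% names(ladder))
    stop("unknown rank: ", rank, "; use one of ",
         paste(names(ladder), collapse = ", "), call. = FALSE)
  idx <- match(taxon_ids, taxonomy$taxon_id)
  if (anyNA(idx))
    stop("taxon not in taxonomy: ",
         paste(taxon_ids[is.na(idx)], collapse = ", "), call. = FALSE)
  cols <- ladder[which(names(ladder) == rank):length(ladder)]
  out <- rep("", length(idx))
  for (col in cols) {
    fill <- !nzchar(out)
    if (!any(fill)) break
    out[fill] <- taxonomy[[col]][idx[fill]]
  }
  out
}

#' @noRd
carnivore_ids <- function(taxonomy) taxonomy$taxon_id[taxonomy$candidate_defecator]
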