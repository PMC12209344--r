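#' Build a validated per-replicate read-count table
#'
#' Long (tidy) format: one row per (scat, PCR replicate, taxon) with the raw
#' read count. Replicate structure is kept first-class because the consensus
#' filter operates across replicates of the same extract. Zero-read rows are
#' legal input (dense exporters emit them) and dropped with a message.
#'
#' @param df data.frame with columns `scat_id`, `replicate`, `taxon_id`,
#'   `reads`.
#' @param taxonomy optional `taxonomy_table`; when supplied every `taxon_id`
#'   must resolve in it.
#' @return data.frame of class `read_count_table` with integer `replicate`
#'   and `reads`, zero rows removed.
#' @export
read_count_table <- function(df, taxonomy = NULL) {
  required <- c("scat_id", "replicate", "taxon_id", "reads")
  missing <- setdiff(required, names(df))
  if (length(missing))
    stop("counts table missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  df <- df[required]
  df$scat_id <- as.character(df$scat_id)
  df$taxon_id <- as.character(df$taxon_id)

  rep_num <- suppressWarnings(as.numeric(df$replicate))
  if (anyNA(rep_num) || any(rep_num != round(rep_num)) || any(rep_num < 1))
    stop("replicate ids must be positive integers", call. = FALSE)
  df$replicate <- as.integer(rep_num)

  reads_num <- suppressWarnings(as.numeric(df$reads))
  if (anyNA(reads_num))
    stop("non-numeric read count(s)", call. = FALSE)
  if (any(reads_num < 0))
    stop("negative read count(s)", call. = FALSE)
  if (any(reads_num != round(reads_num)))
    stop("non-integer read count(s)", call. = FALSE)
  df$reads <- as.integer(round(reads_num))

  key <- paste(df$scat_id, df$replicate, df$taxon_id, sep = "\r")
  if (anyDuplicated(key)) {
    d <- df[duplicated(key), , drop = FALSE][1, ]
    stop(sprintf("duplicate (scat_id, replicate, taxon_id) key: (%s, %d, %s)",
                 d$scat_id, d$replicate, d$taxon_id), call. = FALSE)
  }

  if (!is.null(taxonomy)) {
    unknown <- setdiff(unique(df$taxon_id), taxonomy$taxon_id)
    if (length(unknown))
      stop("taxon absent from taxonomy: ", paste(unknown, collapse = ", "),
           call. = FALSE)
  }

  n_zero <- sum(df$reads == 0L)
  if (n_zero > 0L) {
    message("dropping ", n_zero, " zero-read row(s)")
    df <- df[df$reads > 0L, , drop = FALSE]
  }
  rownames(df) <- NULL
  class(df) <- c("read_count_table", "data.frame")
  df
}

#' Read a per-replicate read-count table from CSV/TSV
#'
#' @inheritParams read_count_table
#' @param path path to a comma- or tab-delimited long table with columns
#'   `scat_id`, `replicate`, `taxon_id`, `reads` (delimiter sniffed).
#' @param col_map optional named character vector mapping canonical column
#'   names to the file's column names (see [read_taxonomy_table()]).
#' @return A `read_count_table`.
#' @export
read_read_count_table <- function(path, taxonomy = NULL, col_map = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- read_delim_sniffed(path)
  df <- apply_col_map(df, col_map)
  read_count_table(df, taxonomy = taxonomy)
}

#' Write a read-count table to CSV
#' @param counts a `read_count_table`.
#' @param path destination path.
#' @return `path`, invisibly.
#' @export
write_read_count_table <- function(counts, path) {
  utils::write.csv(as.data.frame(counts), path, row.names = FALSE)
  invisible(path)
}

# Named read vector (taxon -> reads) for one replicate of one scat.
#' @noRd
replicate_counts <- function(counts, scat, rep) {
  sub <- counts[counts$scat_id == scat & counts$replicate == rep, , drop = FALSE]
  stats::setNames(sub$reads, sub$taxon_id)
}
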