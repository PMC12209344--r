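# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @noRd
sniff_delimiter <- function(path) {
  header <- readLines(path, n = 1L, warn = FALSE)
  if (length(header) == 0L) stop("empty file: ", path, call. = FALSE)
  has_tab <- grepl("\t", header, fixed = TRUE)
  has_comma <- grepl(",", header, fixed = TRUE)
  if (has_tab && has_comma)
    stop("mixed comma/tab delimiters in header of ", path, call. = FALSE)
  if (has_tab) return("\t")
  if (has_comma) return(",")
  stop("could not detect a comma or tab delimiter in ", path, call. = FALSE)
}

#' @noRd
read_delim_sniffed <- function(path) {
  utils::read.table(path, header = TRUE, sep = sniff_delimiter(path),
                    stringsAsFactors = FALSE, comment.char = "",
                    quote = "\"", check.names = FALSE)
}

# Single Dirichlet draw via normalized gammas.
#' @noRd
rdirichlet1 <- function(k, alpha) {
  g <- stats::rgamma(k, shape = alpha, rate = 1)
  s <- sum(g)
  if (s == 0) return(rep(1 / k, k))  # numerically degenerate alpha
  g / s
}

# Deterministic per-unit substream seeds: drawing n + m seeds leaves the
# first n unchanged, so enlarging a simulation never perturbs earlier scats.
#' @noRd
substream_seeds <- function(seed, n) {
  old <- if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  sample.int(.Machine$integer.max - 1L, n)
}

#' @noRd
assert_proportion <- function(x, name, open_lower = TRUE, open_upper = TRUE) {
  bad <- !is.numeric(x) || length(x) != 1L || is.na(x) ||
    (open_lower && x <= 0) || (!open_lower && x < 0) ||
    (open_upper && x >= 1) || (!open_upper && x > 1)
  if (bad) stop(name, " must be a proportion in ",
                if (open_lower) "(" else "[", "0,1",
                if (open_upper) ")" else "]", call. = FALSE)
  invisible(x)
}

#' @noRd
sanitize_label <- function(x) gsub("[^A-Za-z0-9]+", "_", x)
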