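# Incidence-based (sample-based) rarefaction and extrapolation of diet
# taxonomic richness. The sampling unit is the scat; a taxon's incidence
# frequency Y_i is the number of scats containing it.

#' Incidence frequencies of a composition collection
#'
#' @param compositions nonempty list of assigned `scat_composition` objects.
#' @return object of class `incidence_freq`: `T` (number of scats), `Y`
#'   (named integer, taxon -> number of scats containing it), `S_obs`, `Q1`
#'   and `Q2` (numbers of taxa found in exactly one / two scats).
#' @export
incidence_frequencies <- function(compositions) {
  compositions <- check_assigned(compositions)
  n <- length(compositions)
  tab <- table(unlist(lapply(compositions, function(c) unique(c$diet_items$taxon_id))))
  Y <- stats::setNames(as.integer(tab), names(tab))
  Y <- Y[order(names(Y))]
  structure(list(T = n, Y = Y, S_obs = length(Y),
                 Q1 = sum(Y == 1L), Q2 = sum(Y == 2L)),
            class = "incidence_freq")
}

#' Interpolated (rarefied) expected richness
#'
#' Expected number of taxa detected in a random subset of `t` of the `T`
#' scats: `S(t) = sum_i [1 - C(T - Y_i, t) / C(T, t)]`, with the binomial
#' coefficient zero when `T - Y_i < t`. Computed in log space; `S(T)` equals
#' the observed richness exactly.
#'
#' @param freqs an [incidence_frequencies()] result.
#' @param t integer vector of unit counts, each in `1..T`.
#' @return numeric vector of expected richness values.
#' @export
rarefy_interpolate <- function(freqs, t) {
  stopifnot(inherits(freqs, "incidence_freq"))
  if (any(t < 1 | t > freqs$T))
    stop("t must lie in 1..T; use rarefaction_curve for extrapolation",
         call. = FALSE)
  if (any(t != round(t))) stop("t must be integer", call. = FALSE)
  vapply(t, function(tt) {
    # log C(T-Y, t) - log C(T, t); lchoose is -Inf when T-Y < t, giving 0
    frac <- exp(lchoose(freqs$T - freqs$Y, tt) - lchoose(freqs$T, tt))
    sum(1 - frac)
  }, numeric(1))
}

#' Chao2 asymptotic richness
#'
#' Incidence-based lower bound for total richness:
#' `Q0_hat = ((T-1)/T) * Q1^2 / (2 Q2)` when `Q2 > 0`, else the
#' bias-corrected `((T-1)/T) * Q1 (Q1 - 1) / (2 (Q2 + 1))`;
#' `chao2 = S_obs + Q0_hat`.
#'
#' @param freqs an [incidence_frequencies()] result with `T >= 2`.
#' @return list with `chao2`, `Q0_hat`, `S_obs`.
#' @export
chao2 <- function(freqs) {
  stopifnot(inherits(freqs, "incidence_freq"))
  if (freqs$T < 2) stop("Chao2 requires at least two sampling units",
                        call. = FALSE)
  Tn <- freqs$T; Q1 <- freqs$Q1; Q2 <- freqs$Q2
  Q0 <- if (Q2 > 0) {
    (Tn - 1) / Tn * Q1^2 / (2 * Q2)
  } else {
    (Tn - 1) / Tn * Q1 * (Q1 - 1) / (2 * (Q2 + 1))
  }
  list(chao2 = freqs$S_obs + Q0, Q0_hat = Q0, S_obs = freqs$S_obs)
}

# Extrapolated richness at T + t_star additional units.
#' @noRd
extrapolate_richness <- function(freqs, t_star) {
  ch <- chao2(freqs)
  Q0 <- ch$Q0_hat; Q1 <- freqs$Q1; Tn <- freqs$T
  if (Q0 <= 0) return(rep(ch$S_obs, length(t_star)))
  ch$S_obs + Q0 * (1 - (1 - Q1 / (Q1 + Tn * Q0))^t_star)
}

#' Sample-based rarefaction/extrapolation curve with bootstrap bands
#'
#' Expected diet richness as a function of the number of scats: hypergeometric
#' interpolation up to the observed `T`, Chao2-based extrapolation beyond it
#' (up to `2T` by default). Confidence bands come from resampling scats with
#' replacement and recomputing the whole curve per replicate (percentile
#' 2.5/97.5).
#'
#' @param compositions nonempty list of assigned `scat_composition` objects.
#' @param t_grid integer unit counts; default `1..2T`.
#' @param n_boot bootstrap replicates for the bands (default 200).
#' @param seed optional integer seed.
#' @return object of class `rarefaction_curve`: `T`, `S_obs`, `chao2`,
#'   `Q0_hat`, `Q1`, `Q2`, and `grid` (data.frame `t`, `s_hat`, `ci_lo`,
#'   `ci_hi`, `method`).
#' @export
rarefaction_curve <- function(compositions, t_grid = NULL, n_boot = 200L,
                              seed = NULL) {
  compositions <- check_assigned(compositions)
  freqs <- incidence_frequencies(compositions)
  Tn <- freqs$T
  if (is.null(t_grid)) t_grid <- seq_len(2L * Tn)
  if (length(t_grid) == 0L) stop("t_grid must be nonempty", call. = FALSE)
  t_grid <- sort(unique(as.integer(t_grid)))
  if (any(t_grid < 1)) stop("t_grid must be >= 1", call. = FALSE)

  curve_of <- function(fr) {
    interp <- t_grid[t_grid <= fr$T]
    extra <- t_grid[t_grid > fr$T]
    c(if (length(interp)) rarefy_interpolate(fr, interp),
      if (length(extra)) extrapolate_richness(fr, extra - fr$T))
  }
  s_hat <- curve_of(freqs)

  if (!is.null(seed)) set.seed(seed)
  boot <- matrix(NA_real_, nrow = n_boot, ncol = length(t_grid))
  for (b in seq_len(n_boot)) {
    res <- compositions[sample.int(Tn, Tn, replace = TRUE)]
    boot[b, ] <- curve_of(incidence_frequencies(res))
  }
  ci <- apply(boot, 2, stats::quantile, probs = c(0.025, 0.975), names = FALSE)

  ch <- if (Tn >= 2) chao2(freqs) else
    list(chao2 = freqs$S_obs, Q0_hat = 0, S_obs = freqs$S_obs)
  structure(list(
    T = Tn, S_obs = freqs$S_obs, chao2 = ch$chao2, Q0_hat = ch$Q0_hat,
    Q1 = freqs$Q1, Q2 = freqs$Q2,
    grid = data.frame(t = t_grid, s_hat = s_hat,
                      ci_lo = ci[1, ], ci_hi = ci[2, ],
                      method = ifelse(t_grid <= Tn, "interpolated",
                                      "extrapolated"),
                      stringsAsFactors = FALSE)
  ), class = "rarefaction_curve")
}

#' @export
print.rarefaction_curve <- function(x, ...) {
  cat(sprintf("Rarefaction over %d scats: S_obs = %d, Chao2 = %.2f (Q1 = %d, Q2 = %d)\n",
              x$T, x$S_obs, x$chao2, x$Q1, x$Q2))
  cat(sprintf("  grid t = %d..%d; S(2T) = %.2f\n", min(x$grid$t),
              max(x$grid$t), x$grid$s_hat[nrow(x$grid)]))
  invisible(x)
}
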