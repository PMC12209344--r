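# Replicate-consensus retention and amplification-success rules.

test_that("compute_rra normalizes replicate counts", {
  expect_equal(compute_rra(c(A = 60, B = 40)), c(A = 0.6, B = 0.4))
  expect_equal(compute_rra(c(A = 100)), c(A = 1.0))
  expect_equal(compute_rra(c(A = 1, B = 1, C = 2)),
               c(A = 0.25, B = 0.25, C = 0.5))
  expect_equal(sum(compute_rra(c(A = 17, B = 5, C = 3))), 1, tolerance = 1e-12)
  expect_error(compute_rra(c(A = 0, B = 0)), "all-zero")
  expect_error(compute_rra(c(A = -1, B = 2)), "negative")
})

# Fixture: depths (2000, 1500, 800); replicate 3 is below the >1000 rule.
# A at RRA 0.50 in replicates 1-2 -> retained with reads from those two only;
# B at RRA 0.02 in replicate 1 only -> dropped (one qualifying replicate);
# E at RRA 0.7% in replicates 1-2 -> exploration only.
filter_fixture <- function() {
  counts_df(
    rep("S1", 9),
    c(1, 1, 1, 1, 2, 2, 2, 3, 3),
    c("A", "B", "C", "E", "A", "C", "E", "A", "C"),
    c(1000, 40, 946, 14, 750, 739, 11, 400, 400))
}

test_that("the consensus rule retains, drops, and fails as derived by hand", {
  res <- filter_scat(filter_fixture(), filter_config())
  expect_equal(res$status, "ok")
  expect_equal(res$valid_replicates, c(1L, 2L))
  expect_equal(sort(names(res$retained)), c("A", "C"))
  expect_equal(res$retained[["A"]], 1000L + 750L)  # replicate 3 excluded
  expect_equal(res$retained[["C"]], 946L + 739L)
  expect_false("B" %in% names(res$retained))
  expect_equal(res$exploration, "E")  # 0.70% and 0.73% in replicates 1-2

  # all replicates at 900 reads: amplification failed
  low <- counts_df(rep("S2", 3), 1:3, rep("A", 3), c(900, 900, 900))
  res2 <- filter_scat(low, filter_config())
  expect_equal(res2$status, "failed_amplification")
  expect_length(res2$retained, 0)
})

test_that("validity threshold is strict and boundary RRA is inclusive", {
  # exactly 1000 reads is NOT over 1000: invalid replicate
  cfg <- filter_config()
  df <- counts_df(rep("S", 6), rep(1:3, each = 2), rep(c("A", "B"), 3),
                  c(990, 10, 990, 10, 1000, 1000))
  res <- filter_scat(df, cfg)
  # replicates 1-2 have exactly 1000 total -> invalid; replicate 3 has 2000
  expect_equal(res$status, "failed_amplification")

  # RRA exactly at 1% qualifies ("at least")
  df2 <- counts_df(rep("S", 4), c(1, 1, 2, 2), c("A", "B", "A", "B"),
                   c(1980, 20, 1980, 20))
  res2 <- filter_scat(df2, cfg)
  expect_true("B" %in% names(res2$retained))
})

test_that("exploration taxa pass 0.5% but not 1% and never mix with retained", {
  df <- counts_df(rep("S", 6), rep(1:3, each = 2), rep(c("A", "B"), 3),
                  c(1985, 15, 1985, 15, 1985, 15))  # B at 0.75% everywhere
  res <- filter_scat(df, filter_config())
  expect_equal(res$exploration, "B")
  expect_false("B" %in% names(res$retained))
  expect_length(intersect(names(res$retained), res$exploration), 0)
})

# Independent oracle: enumerate the (taxon, replicate) qualification matrix
# with explicit loops.
oracle_filter <- function(df, cfg) {
  reps <- sort(unique(df$replicate))
  totals <- sapply(reps, function(r) sum(df$reads[df$replicate == r]))
  valid <- reps[totals > cfg$min_reads_per_replicate]
  if (length(valid) < cfg$min_replicates)
    return(list(status = "failed_amplification", retained = integer(0)))
  taxa <- sort(unique(df$taxon_id))
  retained <- stats::setNames(integer(0), character(0))
  for (tx in taxa) {
    n_qual <- 0; combined <- 0
    for (r in valid) {
      sub <- df[df$replicate == r, ]
      reads <- sum(sub$reads[sub$taxon_id == tx])
      if (reads / sum(sub$reads) >= cfg$min_rra) n_qual <- n_qual + 1
      combined <- combined + reads
    }
    if (n_qual >= cfg$min_replicates)
      retained[tx] <- combined
  }
  list(status = "ok", retained = retained)
}

random_scat <- function(seed) {
  set.seed(seed)
  taxa <- LETTERS[1:5]
  n <- sample(8:15, 1)
  df <- expand.grid(replicate = 1:3, taxon_id = taxa,
                    stringsAsFactors = FALSE)[sample(15, n), ]
  df$scat_id <- "S"
  df$reads <- rpois(n, lambda = sample(c(5, 50, 800), n, replace = TRUE))
  df[df$reads > 0, c("scat_id", "replicate", "taxon_id", "reads")]
}

test_that("filter_scat matches the brute-force oracle on random fixtures", {
  cfg <- filter_config(min_reads_per_replicate = 100)
  for (seed in 1:40) {
    df <- random_scat(seed)
    if (nrow(df) == 0) next
    got <- filter_scat(df, cfg)
    want <- oracle_filter(df, cfg)
    expect_equal(got$status, want$status, info = paste("seed", seed))
    if (want$status == "ok") {
      expect_equal(got$retained[sort(names(got$retained))],
                   want$retained[sort(names(want$retained))],
                   info = paste("seed", seed))
      # combined reads of retained taxa never exceed total valid reads
      tot_valid <- sum(df$reads[df$replicate %in% got$valid_replicates])
      expect_lte(sum(got$retained), tot_valid)
    }
  }
})

test_that("retention is monotone in min_rra and min_replicates", {
  for (seed in 1:15) {
    df <- random_scat(seed)
    if (nrow(df) == 0) next
    base <- filter_scat(df, filter_config(min_reads_per_replicate = 100,
                                          min_rra = 0.05,
                                          exploration_rra = 0.01))
    looser <- filter_scat(df, filter_config(min_reads_per_replicate = 100,
                                            min_rra = 0.01,
                                            exploration_rra = 0.01))
    if (base$status == "ok" && looser$status == "ok")
      expect_true(all(names(base$retained) %in% names(looser$retained)))
    strict <- filter_scat(df, filter_config(min_reads_per_replicate = 100,
                                            min_replicates = 3))
    if (strict$status == "ok" && base$status == "ok")
      expect_true(all(names(strict$retained) %in% names(looser$retained)))
  }
})

test_that("pooled RRA scope still requires detection in min_replicates", {
  # B is 5% of pooled reads but present in only one replicate
  df <- counts_df(rep("S", 3), c(1, 2, 2), c("A", "A", "B"),
                  c(2000, 1800, 200))
  pooled <- filter_scat(df, filter_config(rra_scope = "pooled"))
  expect_false("B" %in% names(pooled$retained))
  # present in both replicates at pooled 5% -> retained even though one
  # replicate is below 1% per-replicate RRA
  df2 <- counts_df(rep("S", 4), c(1, 1, 2, 2), c("A", "B", "A", "B"),
                   c(1990, 10, 1620, 190))
  pooled2 <- filter_scat(df2, filter_config(rra_scope = "pooled"))
  perrep2 <- filter_scat(df2, filter_config())
  expect_true("B" %in% names(pooled2$retained))
  expect_false("B" %in% names(perrep2$retained))
})

test_that("scats with fewer than three replicates follow the same rule", {
  df <- counts_df(rep("S", 4), c(1, 1, 2, 2), c("A", "B", "A", "B"),
                  c(1500, 500, 1400, 600))
  res <- filter_scat(df, filter_config())
  expect_equal(res$status, "ok")
  expect_setequal(names(res$retained), c("A", "B"))
  # a single valid replicate is below min_replicates = 2
  one <- counts_df(rep("S", 2), c(1, 1), c("A", "B"), c(1500, 500))
  expect_equal(filter_scat(one, filter_config())$status,
               "failed_amplification")
})
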