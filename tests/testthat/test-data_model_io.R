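# Tabular IO, validation, and round-trips.

write_tax_file <- function(df, path = tempfile(fileext = ".csv"), sep = ",") {
  utils::write.table(df, path, sep = sep, row.names = FALSE, quote = TRUE)
  path
}

synthetic_tax_df <- function(n_prey = 23, n_carn = 5) {
  rbind(
    data.frame(taxon_id = sprintf("prey%02d", seq_len(n_prey)),
               class_name = "Mammalia", order_name = "Rodentia",
               family_name = "Cricetidae", genus_name = "Genus",
               species_name = sprintf("Genus sp%02d", seq_len(n_prey)),
               candidate_defecator = FALSE, stringsAsFactors = FALSE),
    data.frame(taxon_id = sprintf("carn%02d", seq_len(n_carn)),
               class_name = "Mammalia", order_name = "Carnivora",
               family_name = "Canidae", genus_name = "Canis",
               species_name = sprintf("Canis sp%02d", seq_len(n_carn)),
               candidate_defecator = TRUE, stringsAsFactors = FALSE))
}

test_that("taxonomy reader validates and counts records", {
  path <- write_tax_file(synthetic_tax_df())
  tax <- read_taxonomy_table(path)
  expect_s3_class(tax, "taxonomy_table")
  expect_equal(nrow(tax), 28)
  expect_equal(sum(tax$candidate_defecator), 5)

  # a flagged Carnivora row is accepted
  df <- synthetic_tax_df()
  df$taxon_id[24] <- "Vulpes vulpes"
  expect_silent(tax2 <- read_taxonomy_table(write_tax_file(df)))
  expect_true(tax2$candidate_defecator[tax2$taxon_id == "Vulpes vulpes"])

  # duplicate taxon_id errors naming the duplicate
  df <- synthetic_tax_df()
  df$taxon_id[2] <- df$taxon_id[1]
  expect_error(read_taxonomy_table(write_tax_file(df)), "prey01")

  # carnivore flag on a non-Carnivora row errors
  df <- synthetic_tax_df()
  df$candidate_defecator[1] <- TRUE
  expect_error(read_taxonomy_table(write_tax_file(df)), "Carnivora")

  # empty class label errors
  df <- synthetic_tax_df()
  df$class_name[3] <- ""
  expect_error(read_taxonomy_table(write_tax_file(df)), "class_name")
})

test_that("taxonomy reader sniffs delimiters and honours column maps", {
  df <- synthetic_tax_df(3, 1)
  tsv <- write_tax_file(df, tempfile(fileext = ".tsv"), sep = "\t")
  expect_equal(nrow(read_taxonomy_table(tsv)), 4)

  # foreign headers via col_map
  renamed <- df
  names(renamed) <- c("Taxon", "Class", "Order", "Family", "Genus", "Species",
                      "IsCarnivore")
  tax <- read_taxonomy_table(write_tax_file(renamed),
                             col_map = c(taxon_id = "Taxon", class_name = "Class",
                                         order_name = "Order", family_name = "Family",
                                         genus_name = "Genus", species_name = "Species",
                                         candidate_defecator = "IsCarnivore"))
  expect_equal(tax$taxon_id, df$taxon_id)

  # mixed delimiters in the header are rejected
  mixed <- tempfile(fileext = ".csv")
  writeLines(c("taxon_id,class_name\torder_name", "x,y\tz"), mixed)
  expect_error(read_taxonomy_table(mixed), "mixed")
})

test_that("read-count reader validates keys, taxa and read values", {
  tax <- toy_taxonomy()
  df <- counts_df(rep("S1", 6), rep(1:3, each = 2),
                  rep(c("Vulpes vulpes", "Lepus americanus"), 3),
                  c(900, 100, 800, 200, 950, 50))
  path <- tempfile(fileext = ".csv")
  utils::write.csv(df, path, row.names = FALSE)
  tab <- read_read_count_table(path, taxonomy = tax)
  expect_s3_class(tab, "read_count_table")
  expect_equal(nrow(tab), 6)

  expect_error(read_count_table(transform(df, taxon_id = "Felis catus"), tax),
               "Felis catus")
  expect_error(read_count_table(transform(df, reads = c(-1, 100, 800, 200, 950, 50))),
               "negative")
  expect_error(read_count_table(transform(df, reads = reads + 0.5)),
               "non-integer")
  dup <- rbind(df, df[1, ])
  expect_error(read_count_table(dup), "duplicate")
})

test_that("zero-read rows are dropped with a logged count", {
  df <- counts_df(c("S1", "S1", "S1"), c(1, 1, 1),
                  c("A", "B", "C"), c(10, 0, 0))
  expect_message(tab <- read_count_table(df), "2 zero-read")
  expect_equal(nrow(tab), 1)
})

test_that("read-count table round-trips through CSV identically", {
  sim <- simulate_scats(noise_free_params(n = 3, seed = 7))
  path <- tempfile(fileext = ".csv")
  write_read_count_table(sim$counts, path)
  back <- read_read_count_table(path, taxonomy = sim$taxonomy)
  expect_equal(as.data.frame(back), as.data.frame(sim$counts))
})

test_that("config files parse, round-trip, and reject bad input", {
  path <- tempfile(fileext = ".cfg")
  writeLines(c("# thresholds", "min_rra = 0.02", "min_replicates: 3",
               "carnivores_as_prey = true", ""), path)
  cfg <- read_filter_config(path)
  expect_equal(cfg$min_rra, 0.02)
  expect_equal(cfg$min_replicates, 3L)
  expect_true(cfg$carnivores_as_prey)

  cfg2 <- filter_config(min_rra = 0.03, exploration_rra = 0.004, seed = 9L)
  p2 <- tempfile()
  write_filter_config(cfg2, p2)
  back <- read_filter_config(p2)
  expect_equal(back[names(back)], cfg2[names(cfg2)])

  writeLines("no_such_threshold = 1", path)
  expect_error(read_filter_config(path), "unknown config key")
  expect_error(filter_config(exploration_rra = 0.02, min_rra = 0.01),
               "exploration_rra")
  expect_error(filter_config(min_rra = 1.2), "proportion")
})

test_that("write_results emits a complete, re-readable bundle", {
  out <- tempfile("results_")

  # empty overlap/curve lists still produce a valid bundle
  expect_silent(write_results(list(), list(), list(), list(), out))
  empty <- read_results(out)
  expect_length(empty$overlaps, 0)
  expect_equal(nrow(empty$status), 0)

  comps <- list(comp_fixture("S1", c("Lepus americanus", "Microtus sp.",
                                     "Tamias sp.")),
                comp_fixture("S2", "Lepus americanus"))
  prof <- build_diet_profile(comps)
  ov <- overlap_analysis(comps, comps, metric = "wpoo",
                         config = filter_config(), n_iterations = 50,
                         n_boot = 50, seed = 4)
  cv <- rarefaction_curve(comps, n_boot = 20, seed = 4)
  write_results(comps, list(prof), list(ov), list(`Vulpes vulpes` = cv), out)

  # species table: one data row per taxon plus header
  tab_path <- file.path(out, "diet_Vulpes_vulpes.csv")
  expect_true(file.exists(tab_path))
  expect_length(readLines(tab_path), 3 + 1)

  back <- read_results(out)
  o <- back$overlaps[[1]]
  expect_equal(o$metric, "wpoo")
  # reals reproduce to >= 12 significant digits, integers bit-exactly
  expect_equal(o$o_observed, ov$o_observed, tolerance = 1e-12)
  expect_equal(unlist(o$null_ci), unname(ov$null_ci), tolerance = 1e-12)
  expect_identical(o$n_iterations, 50L)
  rr <- back$rarefaction[[1]]
  expect_identical(rr$S_obs, cv$S_obs)
  expect_equal(unlist(rr$grid$s_hat), cv$grid$s_hat, tolerance = 1e-12)
  expect_equal(back$status$status, c("assigned", "assigned"))
})
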