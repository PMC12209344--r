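# Incidence frequencies, interpolation, Chao2, and the full curve.

freq_fixture <- function() {
  # 3 scats: {A}, {A,B}, {A} -> T=3, Y_A=3, Y_B=1
  incidence_frequencies(list(comp_fixture("S1", "A"),
                             comp_fixture("S2", c("A", "B")),
                             comp_fixture("S3", "A")))
}

test_that("incidence frequencies count scats per taxon", {
  fr <- freq_fixture()
  expect_equal(fr$T, 3)
  expect_equal(fr$Y, c(A = 3L, B = 1L))
  expect_equal(fr$S_obs, 2)
  expect_equal(fr$Q1, 1); expect_equal(fr$Q2, 0)

  # all scats identical -> no uniques or duplicates
  same <- incidence_frequencies(lapply(1:4, function(i)
    comp_fixture(paste0("S", i), c("A", "B"))))
  expect_equal(same$Q1, 0); expect_equal(same$Q2, 0)

  # every taxon in exactly one scat -> Q1 = S_obs
  uniq <- incidence_frequencies(list(comp_fixture("S1", "A"),
                                     comp_fixture("S2", "B")))
  expect_equal(uniq$Q1, uniq$S_obs)
})

# Exhaustive subset oracle: mean richness over all C(T, t) scat subsets.
oracle_rarefy <- function(comps, t) {
  sets <- lapply(comps, function(c) unique(c$diet_items$taxon_id))
  idx <- utils::combn(length(sets), t, simplify = FALSE)
  mean(vapply(idx, function(i) length(unique(unlist(sets[i]))), numeric(1)))
}

test_that("interpolation matches the subset-enumeration oracle", {
  comps <- list(comp_fixture("S1", "A"), comp_fixture("S2", c("A", "B")),
                comp_fixture("S3", "A"))
  fr <- freq_fixture()
  expect_equal(rarefy_interpolate(fr, 2), 5 / 3, tolerance = 1e-12)
  expect_equal(rarefy_interpolate(fr, 2), oracle_rarefy(comps, 2),
               tolerance = 1e-12)
  expect_equal(rarefy_interpolate(fr, 1), 4 / 3, tolerance = 1e-12)  # sum(Y)/T
  expect_equal(rarefy_interpolate(fr, 3), fr$S_obs, tolerance = 1e-12)
  expect_error(rarefy_interpolate(fr, 0), "1..T")
  expect_error(rarefy_interpolate(fr, 4), "1..T")

  # random richer fixture, every t, against the exhaustive oracle
  set.seed(41)
  comps2 <- lapply(1:7, function(i)
    comp_fixture(paste0("R", i), sample(LETTERS[1:9], sample(1:4, 1))))
  fr2 <- incidence_frequencies(comps2)
  for (t in 1:7)
    expect_equal(rarefy_interpolate(fr2, t), oracle_rarefy(comps2, t),
                 tolerance = 1e-9)
})

test_that("interpolation agrees with Monte-Carlo subsampling within 3 MCse", {
  set.seed(55)
  comps <- lapply(1:12, function(i)
    comp_fixture(paste0("S", i), sample(LETTERS[1:10], sample(1:5, 1))))
  fr <- incidence_frequencies(comps)
  t <- ceiling(fr$T / 2)
  sets <- lapply(comps, function(c) unique(c$diet_items$taxon_id))
  draws <- replicate(10000, length(unique(unlist(
    sets[sample.int(length(sets), t)]))))
  mcse <- sd(draws) / sqrt(length(draws))
  expect_lt(abs(rarefy_interpolate(fr, t) - mean(draws)), 3 * mcse)
})

test_that("Chao2 follows both branches and never falls below S_obs", {
  # S_obs=4, T=5, Q1=2, Q2=1 -> Q0 = (4/5)*4/2 = 1.6, chao2 = 5.6
  comps <- list(comp_fixture("S1", c("A", "B")),
                comp_fixture("S2", c("A", "B")),
                comp_fixture("S3", c("A", "C")),
                comp_fixture("S4", "A"),
                comp_fixture("S5", c("A", "D")))
  fr <- incidence_frequencies(comps)
  expect_equal(fr$S_obs, 4); expect_equal(fr$Q1, 2); expect_equal(fr$Q2, 1)
  ch <- chao2(fr)
  expect_equal(ch$Q0_hat, 1.6, tolerance = 1e-12)
  expect_equal(ch$chao2, 5.6, tolerance = 1e-12)

  # Q1 = 0 -> chao2 = S_obs
  same <- incidence_frequencies(lapply(1:3, function(i)
    comp_fixture(paste0("S", i), c("A", "B"))))
  expect_equal(chao2(same)$chao2, same$S_obs)

  # Q1 = 1, Q2 = 0: bias-corrected branch gives Q0 = 0
  fr2 <- incidence_frequencies(list(comp_fixture("S1", c("A", "B")),
                                    comp_fixture("S2", c("A", "B")),
                                    comp_fixture("S3", c("A", "B", "C"))))
  expect_equal(chao2(fr2)$Q0_hat, 0)
  expect_equal(chao2(fr2)$chao2, fr2$S_obs)

  one <- incidence_frequencies(list(comp_fixture("S1", "A")))
  expect_error(chao2(one), "two sampling units")

  set.seed(61)
  for (i in 1:10) {
    comps <- lapply(1:6, function(j)
      comp_fixture(paste0("S", j), sample(LETTERS[1:8], sample(1:3, 1))))
    fr <- incidence_frequencies(comps)
    expect_gte(chao2(fr)$chao2, fr$S_obs)
  }
})

test_that("the curve interpolates, extrapolates, and is seeded", {
  set.seed(71)
  comps <- lapply(1:10, function(i)
    comp_fixture(paste0("S", i), sample(LETTERS[1:6], sample(2:4, 1))))
  cv <- rarefaction_curve(comps, n_boot = 50, seed = 9)
  expect_equal(nrow(cv$grid), 20)
  # S(T) == S_obs exactly; nondecreasing throughout
  expect_equal(cv$grid$s_hat[cv$grid$t == cv$T], cv$S_obs, tolerance = 1e-9)
  expect_true(all(diff(cv$grid$s_hat) >= -1e-9))
  expect_gte(cv$chao2, cv$S_obs)
  expect_true(all(cv$grid$ci_lo <= cv$grid$ci_hi))

  cv2 <- rarefaction_curve(comps, n_boot = 50, seed = 9)
  expect_identical(cv$grid, cv2$grid)
  expect_error(rarefaction_curve(comps, t_grid = integer(0)), "nonempty")
})

test_that("a saturated design plateaus and Q0 = 0 extrapolates flat", {
  # noise-free world with a 6-taxon pool and 40 scats: all taxa common
  params <- noise_free_params(n = 20, seed = 6)
  params$prey_pool <- params$prey_pool[1:6]
  params$prey_weights <- rep(1 / 6, 6)
  sim <- simulate_scats(params)
  comps <- assign_all(sim$counts, sim$taxonomy, permissive_config())
  assigned <- Filter(function(c) c$status == "assigned", comps)
  cv <- rarefaction_curve(assigned, n_boot = 30, seed = 3)
  s_T <- cv$grid$s_hat[cv$grid$t == cv$T]
  s_2T <- cv$grid$s_hat[nrow(cv$grid)]
  expect_lt(s_2T - s_T, 0.5)

  # Q0 = 0: flat extrapolation at S_obs
  flat <- rarefaction_curve(lapply(1:4, function(i)
    comp_fixture(paste0("S", i), c("A", "B"))), n_boot = 20, seed = 1)
  expect_true(all(flat$grid$s_hat[flat$grid$t >= flat$T] == flat$S_obs))
})
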