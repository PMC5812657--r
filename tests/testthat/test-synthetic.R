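test_that("noise-free simulated measurements reclassify perfectly and reproducibly", {
  s1 <- simulate_karyotype(12, noise_sd = 0, seed = 7)
  s2 <- simulate_karyotype(12, noise_sd = 0, seed = 7)
  expect_identical(s1, s2)
  got <- classify_morphology(centromeric_index(s1$measurements$p_len,
                                               s1$measurements$q_len))
  expect_identical(got,
                   s1$truth$morphology_true[s1$measurements$true_pair])
  s3 <- simulate_karyotype(12, noise_sd = 0, seed = 8)
  expect_false(identical(s1$measurements, s3$measurements))
  expect_error(simulate_karyotype(0), "config error")
  expect_error(simulate_karyotype(5, noise_sd = -1), "config error")
})

test_that("under noise, misclassification stays near class thresholds", {
  th <- unname(ci_thresholds()[c("metacentric", "submetacentric",
                                 "subtelocentric")])
  n_far <- 0L
  for (r in 1:200) {
    s <- simulate_karyotype(12, noise_sd = 0.05, seed = 10000 + r)
    meas_ci <- centromeric_index(s$measurements$p_len, s$measurements$q_len)
    got <- classify_morphology(meas_ci)
    truth <- s$truth$morphology_true[s$measurements$true_pair]
    ci_true <- s$truth$ci_true[s$measurements$true_pair]
    wrong <- got != truth
    if (any(wrong)) {
      dist <- vapply(ci_true[wrong], function(x) min(abs(x - th)), 1)
      n_far <- n_far + sum(dist > 0.06)   # ~4 sd of the induced CI noise
    }
  }
  expect_equal(n_far, 0L)
})

test_that("character simulation is seed-reproducible and history-consistent", {
  tr <- random_tree(16, seed = 3, polytomies = FALSE)
  a <- simulate_character(tr, 0.1, as.character(0:3), seed = 5)
  b <- simulate_character(tr, 0.1, as.character(0:3), seed = 5)
  expect_identical(a, b)
  ## tip states must be reachable from the root through the recorded changes
  expect_true(all(a$tip_states %in% as.character(0:3)))
  for (i in seq_len(nrow(a$changes)))
    expect_identical(a$node_states[[a$changes$child[i]]], a$changes$to[i])
  zero <- simulate_character(tr, 0, as.character(0:3), seed = 5)
  expect_true(all(zero$tip_states == zero$root_state))
  expect_equal(nrow(zero$changes), 0)
  expect_error(simulate_character(tr, 1.2), "input error")
  expect_error(simulate_character(tr, 0.1, alphabet = "0"), "input error")
})

test_that("parsimony length never exceeds the realized number of changes", {
  tr <- random_tree(16, seed = 9, polytomies = FALSE)
  ab <- as.character(0:3)
  for (r in 1:40) {
    sim <- simulate_character(tr, 0.15, ab, seed = 200 + r)
    if (length(unique(sim$tip_states)) < 2) next
    m <- character_matrix(names(sim$tip_states), "sim",
                          list(as.list(unname(sim$tip_states))),
                          alphabets = list(sim = ab))
    expect_lte(reconstruct(tr, m, "sim")$length, nrow(sim$changes))
  }
})

test_that("recovery experiment recovers the root perfectly at zero change", {
  tr <- random_tree(16, seed = 21, polytomies = FALSE)
  res <- recovery_experiment(tr, change_probs = c(0, 0.05, 0.15),
                             replicates = 40, seed = 11)
  expect_equal(res$recovery_freq[res$change_prob == 0], 1.0)
  expect_equal(res$mean_length[res$change_prob == 0], 0)
  expect_true(!is.unsorted(res$mean_length))      # monotone in change_prob
  expect_true(all(res$mean_length <= res$mean_changes))
  expect_error(recovery_experiment(tr, change_probs = c(-0.1)),
               "config error")
})
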