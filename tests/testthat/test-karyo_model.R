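test_that("centromeric index follows p/(p+q) and rejects bad measurements", {
  expect_equal(centromeric_index(1, 1), 0.5)
  expect_equal(centromeric_index(0, 2.3), 0)
  expect_equal(centromeric_index(0.41, 0.59), 0.41)
  expect_error(centromeric_index(-0.1, 1), "invalid measurement")
  expect_error(centromeric_index(2, 1), "orient arms")
  expect_error(centromeric_index(1, 0), "invalid measurement")
  o <- orient_arms(c(3, 1), c(2, 4))
  expect_equal(o$p, c(2, 1))
  expect_equal(o$q, c(3, 4))
})

test_that("morphology classification reproduces the printed CI assignments", {
  expect_equal(classify_morphology(0.41), "metacentric")
  expect_equal(classify_morphology(0.46), "metacentric")
  expect_equal(classify_morphology(0.34), "submetacentric")
  expect_equal(classify_morphology(0.35), "submetacentric")
  expect_equal(classify_morphology(0.25), "submetacentric")  # 'almost subtelocentric'
  expect_equal(classify_morphology(c(0.5, 0.37, 0.125, 0.1249, 0)),
               c("metacentric", "metacentric", "subtelocentric",
                 "telocentric", "telocentric"))
  expect_error(classify_morphology(0.6), "outside")
  expect_error(classify_morphology(-0.01), "outside")
})

test_that("classification is invariant under rescaling of arm lengths", {
  set.seed(7)
  for (i in 1:50) {
    q <- runif(1, 0.5, 10); p <- runif(1, 0, q); cc <- runif(1, 0.01, 100)
    expect_identical(classify_morphology(centromeric_index(p, q)),
                     classify_morphology(centromeric_index(cc * p, cc * q)))
  }
})

test_that("fundamental number counts arms and respects its bounds", {
  all_t <- karyotype("t_sp", lapply(1:10, function(i)
    chromosome_pair(i, morphology = "telocentric")))
  expect_equal(fundamental_number(all_t), 20)        # lower bound FN = 2n
  all_m <- karyotype("m_sp", lapply(1:12, function(i)
    chromosome_pair(i, morphology = "metacentric")))
  expect_equal(fundamental_number(all_m), 48)        # upper bound FN = 2*2n
  set.seed(11)
  for (i in 1:30) {
    n <- sample(3:14, 1)
    k <- karyotype("r", lapply(seq_len(n), function(j)
      chromosome_pair(j, morphology = sample(MORPHOLOGY_CLASSES, 1))))
    fn <- fundamental_number(k)
    expect_gte(fn, k$diploid_number_2n)
    expect_lte(fn, 2 * k$diploid_number_2n)
    n_t <- sum(vapply(k$pairs, function(p) p$morphology, "") == "telocentric")
    if (n_t == 0) expect_equal(fn, 2 * k$diploid_number_2n)
  }
  incomplete <- karyotype("i_sp", list(chromosome_pair(1)))
  expect_error(fundamental_number(incomplete), "incomplete karyotype")
})

test_that("relative lengths normalize to percent of the haploid complement", {
  equal12 <- karyotype("e", lapply(1:12, function(i)
    chromosome_pair(i, p_len = 1, q_len = 1)))
  expect_equal(relative_lengths(equal12), rep(100 / 12, 12))
  single <- karyotype("s", list(chromosome_pair(1, p_len = 2, q_len = 3)))
  expect_equal(relative_lengths(single), 100)
  ## spreadsheet-style recomputation on 11 known pairs
  p <- 1:11; q <- (1:11) + 0.5
  k <- karyotype("k", lapply(1:11, function(i)
    chromosome_pair(i, p_len = p[i], q_len = q[i])))
  expected <- 100 * (p + q) / 137.5    # sum(2i + 0.5, i = 1..11) = 137.5
  expect_equal(relative_lengths(k), expected)
  expect_equal(sum(relative_lengths(k)), 100, tolerance = 1e-9)
  ## a B chromosome is measured against the same A-complement denominator
  expect_equal(relative_length(list(p_len = 1, q_len = 1.75), k), 2)
})

test_that("validate_karyotype reports (not raises) invariant violations", {
  good <- measured_karyotype(6)
  expect_length(validate_karyotype(good), 0)
  bad2n <- good; bad2n$diploid_number_2n <- 99L
  expect_match(validate_karyotype(bad2n), "diploid_number_2n", all = FALSE)
  badrel <- good
  for (i in seq_along(badrel$pairs)) badrel$pairs[[i]]$rel_length <-
    badrel$pairs[[i]]$rel_length * 0.9
  expect_match(validate_karyotype(badrel), "rel_length", all = FALSE)
})

test_that("idiogram geometry splits pairs at the centromere", {
  k <- karyotype("i", list(
    chromosome_pair(1, ci = 0.5, rel_length = 10),
    chromosome_pair(2, ci = 0, rel_length = 90)))
  coords <- idiogram_coords(k)
  meta <- coords[coords$pair_index == 1 & coords$segment != "band", ]
  expect_equal(nrow(meta), 2)
  expect_equal(abs(meta$y1 - meta$y0), c(5, 5))
  telo <- coords[coords$pair_index == 2 & coords$segment != "band", ]
  expect_equal(nrow(telo), 1)              # telocentric: single q segment
  expect_equal(telo$segment, "q")
  ## heights over a full measured complement sum to 100
  mk <- measured_karyotype(12)
  for (i in seq_along(mk$pairs))
    mk$pairs[[i]]$ci <- centromeric_index(mk$pairs[[i]]$p_len,
                                          mk$pairs[[i]]$q_len)
  cc <- idiogram_coords(mk)
  cc <- cc[cc$segment != "band", ]
  expect_equal(sum(cc$y1 - cc$y0), 100, tolerance = 1e-9)
  nolen <- karyotype("n", list(chromosome_pair(1, ci = 0.3)))
  expect_error(idiogram_coords(nolen), "incomplete karyotype")
})
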