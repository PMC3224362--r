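test_that("trace generators are deterministic per seed and break-free", {
  expect_equal(make_helix(10), make_helix(10))
  expect_equal(make_loop(12, seed = 5), make_loop(12, seed = 5))
  expect_false(isTRUE(all.equal(make_loop(12, seed = 5)$xyz,
                                make_loop(12, seed = 6)$xyz)))
  expect_equal(make_helix(15, jitter = 0.2, seed = 3),
               make_helix(15, jitter = 0.2, seed = 3))
  for (ch in list(make_helix(20), make_strand(15), make_loop(18, seed = 1),
                  make_helix(20, curvature = 4)))
    expect_length(ch$breaks, 0)
})

test_that("strands are more extended than helices; curvature bends helices", {
  expect_gt(compute_descriptors(make_strand(4)$xyz)[["d2"]], 9)
  expect_gt(compute_descriptors(make_strand(4)$xyz)[["d2"]],
            compute_descriptors(make_helix(4)$xyz)[["d2"]])
  # a curved helix's windows sit closer to the curved-helix prototype 'a'
  # than a straight helix's do (descriptor-distance comparison)
  model <- default_alphabet_model()
  dist_to <- function(chain, letter) {
    d <- chain_descriptors(chain)
    mean(sqrt(colSums((t(d) - model$mean[letter, ])^2)))
  }
  expect_lt(dist_to(make_helix(12, curvature = 5), "a") -
              dist_to(make_helix(12, curvature = 5), "A"),
            dist_to(make_helix(12), "a") - dist_to(make_helix(12), "A"))
  # invalid geometry is rejected
  expect_error(make_helix(6, rise = 5), "distances")
})

test_that("synthetic complexes expose a tunable interface", {
  cx <- make_complex(make_helix(12), make_helix(12), separation = 9)
  acc_a <- accessibility_contexts(cx, "A")
  acc_b <- accessibility_contexts(cx, "B")
  expect_gte(sum(acc_a$compartment == "interface"), 3)
  expect_gte(sum(acc_b$compartment == "interface"), 3)
  # far-apart chains share no interface
  far <- make_complex(make_helix(12), make_helix(12), separation = 60)
  expect_equal(sum(accessibility_contexts(far, "A")$compartment ==
                     "interface"), 0)
  # monomer passthrough
  mono <- sadef:::chain_as_complex(make_helix(12))
  expect_equal(sum(accessibility_contexts(mono)$compartment == "interface"),
               0)
})

test_that("count sampling reproduces planted preferences in expectation", {
  prob <- matrix(rep(c(0.2, 0.5, 0.3), 3), 3, byrow = TRUE,
                 dimnames = list(c("D", "E", "F"),
                                 c("interface", "surface", "core")))
  tab <- sample_counts(list(prob = prob, n = 6000), seed = 11)
  expect_s3_class(tab, "CountTable")
  expect_equal(unname(rowSums(tab)), rep(6000, 3))
  expect_equal(sample_counts(list(prob = prob, n = 6000), seed = 11), tab)
  # empirical frequencies within 3 sigma of the plant
  for (l in rownames(prob)) for (cp in colnames(prob)) {
    p <- prob[l, cp]
    se <- sqrt(p * (1 - p) / 6000)
    expect_lt(abs(tab[l, cp] / 6000 - p), 4 * se)
  }
  # zero-probability compartment stays empty
  prob0 <- matrix(c(0, 0.5, 0.5), 1, dimnames = list("D", colnames(prob)))
  expect_equal(sample_counts(list(prob = prob0, n = 100), seed = 1)[1, 1], 0L)
})

test_that("sequence mutation honours per-compartment rates and substitutions", {
  sub <- matrix(0, 2, 2, dimnames = list(c("a", "A"), c("a", "A")))
  sub["a", "A"] <- 1; sub["A", "a"] <- 1
  lets <- rep("a", 20)
  cps <- rep("surface", 20)
  spec0 <- list(sub = sub, rate = c(surface = 0))
  expect_equal(mutate_sequence(lets, spec0, cps, seed = 1), lets)
  spec1 <- list(sub = sub, rate = c(surface = 1))
  expect_equal(mutate_sequence(lets, spec1, cps, seed = 1), rep("A", 20))
  # empirical substitution frequency converges to the spec (law of large numbers)
  sub2 <- matrix(c(0, 0.7, 0.3,
                   0, 1, 0,
                   0, 0, 1), 3, byrow = TRUE,
                 dimnames = list(c("a", "A", "V"), c("a", "A", "V")))
  long <- mutate_sequence(rep("a", 10000), list(sub = sub2,
                                                rate = c(interface = 1)),
                          rep("interface", 10000), seed = 2)
  phat <- mean(long == "A")
  expect_lt(abs(phat - 0.7), 3 * sqrt(0.7 * 0.3 / 10000))
  # NA letters and letters without a substitution row pass through
  expect_equal(mutate_sequence(c("Q", NA), list(sub = sub,
                                                rate = c(surface = 1)),
                               c("surface", "surface"), seed = 1),
               c("Q", NA))
})

test_that("toy models are valid and reproducible", {
  m <- toy_alphabet_model(3, seed = 4)
  expect_equal(rowSums(m$transition), setNames(rep(1, 3), m$letters),
               tolerance = 1e-12)
  expect_equal(sum(m$initial), 1, tolerance = 1e-12)
  expect_equal(toy_alphabet_model(3, seed = 4), m)
  expect_false(isTRUE(all.equal(toy_alphabet_model(3, seed = 5)$mean,
                                m$mean)))
  # usable by the decoder
  expect_length(viterbi_encode(matrix(runif(8), 2, 4), m), 2)
})

test_that("generators leave the caller's RNG stream untouched", {
  set.seed(123)
  before <- runif(1)
  set.seed(123)
  invisible(make_loop(8, seed = 99))
  invisible(sample_counts(list(prob = matrix(1 / 3, 1, 3,
                                             dimnames = list("D", NULL)),
                               n = 10), seed = 7))
  expect_equal(runif(1), before)
})
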