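make_chain_aa <- function(aa, seed = 1) {
  make_loop(nchar(aa), seed = seed, aa = aa)
}

test_that("chain pairing aligns identical, truncated and gapped sequences", {
  u <- make_chain_aa("ACDEFGHIKLMNPQ")
  b <- make_chain_aa("ACDEFGHIKLMNPQ", seed = 2)
  m <- pair_chains(u, b)
  expect_equal(m$pos_unbound, 1:14)
  expect_equal(m$pos_bound, 1:14)
  # bound missing two N-terminal residues
  b2 <- make_chain_aa("DEFGHIKLMNPQ", seed = 3)
  m2 <- pair_chains(u, b2)
  expect_equal(m2$pos_unbound, 3:14)
  expect_equal(m2$pos_bound, 1:12)
  expect_equal(attr(m2, "unaligned_unbound"), 1:2)
  # one internal three-residue gap: flanks pair, gap unpaired
  b3 <- make_chain_aa("ACDEFKLMNPQ", seed = 4)   # GHI removed
  m3 <- pair_chains(u, b3)
  expect_equal(m3$pos_unbound, setdiff(1:14, 6:8))
  expect_equal(nrow(m3), 11)
  # unrelated sequences are rejected
  expect_error(pair_chains(u, make_chain_aa("WWWWYYYYWWWWYY", seed = 5)),
               "identity")
})

test_that("transition counts follow the bound-state compartment", {
  u <- make_chain_aa("AAAAAAAAAA")
  b <- make_chain_aa("AAAAAAAAAA", seed = 2)
  map <- pair_chains(u, b)
  seq_u <- assign_letters(u)
  seq_b <- assign_letters(b)
  # hand-planted letter strings on residues 3..9 (coverage of a 10-mer)
  seq_u$residue_letters <- c(NA, NA, "B", "A", "A", "a", "a", "C", "A", NA)
  seq_b$residue_letters <- c(NA, NA, "B", "A", "A", "A", "A", "C", "A", NA)
  cp <- rep("interface", 10)
  C <- transition_counts(map, seq_u, seq_b, cp)
  expect_equal(C$interface["a", "A"], 2L)
  expect_equal(sum(diag(C$interface)), 5L)
  expect_equal(sum(C$interface), 7L)
  expect_equal(sum(C$surface) + sum(C$core), 0L)
  # proportion changed = off-diagonal mass / total
  expect_equal(1 - sum(diag(C$interface)) / sum(C$interface), 2 / 7,
               tolerance = 1e-12)
  # undefined compartments are skipped
  cp2 <- c(rep("interface", 5), rep("undefined", 5))
  C2 <- transition_counts(map, seq_u, seq_b, cp2)
  expect_equal(sum(C2$interface), 3L)
})

test_that("deformation proportions condition on deformed letters only", {
  C <- matrix(0L, 27, 27, dimnames = list(SA_LETTERS, SA_LETTERS))
  C["a", "A"] <- 3L; C["a", "V"] <- 1L; C["a", "a"] <- 50L
  C["L", "L"] <- 10L                      # undeformed only: row absent
  P <- deformation_proportions(C)
  expect_equal(rownames(P), "a")
  expect_equal(P["a", "A"], 0.75)
  expect_equal(P["a", "V"], 0.25)
  expect_true(is.na(P["a", "a"]))
  expect_equal(sum(P["a", ], na.rm = TRUE), 1)
  # single deformation gives probability one
  C1 <- matrix(0L, 2, 2, dimnames = list(c("a", "A"), c("a", "A")))
  C1["a", "A"] <- 1L
  expect_equal(deformation_proportions(C1)["a", "A"], 1)
})

test_that("delta_p differences matrices with zero-fill for one-sided rows", {
  P1 <- matrix(c(NA, 1, 0.5, NA), 2, 2,
               dimnames = list(c("a", "A"), c("a", "A")))
  expect_true(all(delta_p(P1, P1) == 0, na.rm = TRUE))
  P2 <- P1[1, , drop = FALSE]
  D <- delta_p(P1, P2)
  expect_equal(D["A", "a"], 1)   # missing surface row zero-filled
  expect_true("A" %in% attr(D, "one_sided"))
  # bounded in [-1, 1]
  expect_true(all(D >= -1 & D <= 1))
})

test_that("exposure differences carry the stated sign convention", {
  pos <- data.frame(pos_unbound = 1:4, pos_bound = 1:4,
                    letter_unbound = c("P", "P", "G", "G"),
                    letter_bound = c("H", "G", "G", "P"))
  acc_u <- c(30, 30, 10, 50)
  acc_b <- c(40, 25, 10, 20)
  res <- exposure_difference(pos, acc_u, acc_b)
  # unbound 30, bound 40: D = -10 (more exposed upon binding)
  expect_equal(res$positions$D, c(-10, 5, 0, 30))
  expect_equal(res$positions$category, c("s/s", "s/c", "c/c", "c/s"))
  agg <- res$aggregates
  expect_equal(agg$mean[agg$category == "s/s"], -10)
  expect_equal(agg$median[agg$category == "c/s"], 30)
  # positions lacking accessibility are skipped with a warning
  expect_warning(r2 <- exposure_difference(pos, c(NA, acc_u[-1]), acc_b))
  expect_equal(nrow(r2$positions), 3)
})

test_that("straight-letter shift counts [A,T,M] gains", {
  expect_equal(straight_letter_shift("AVTa", "AVTa"), 0)
  expect_equal(straight_letter_shift("aa", "AA"), 2)
  expect_equal(straight_letter_shift(c("A", "T", "M", "P"),
                                     c("A", "P", "P", "P")), -2)
})

test_that("Kabsch RMSD is zero under rigid motion and matches the collinear oracle", {
  set.seed(9)
  x <- matrix(rnorm(30), 10, 3)
  expect_equal(kabsch_rmsd(x, x), 0, tolerance = 1e-12)
  R <- random_rotation(2)
  y <- sweep(x %*% R, 2, c(4, -2, 7), "+")
  expect_equal(kabsch_rmsd(x, y), 0, tolerance = 1e-9)
  # symmetry and pre-rotation invariance
  z <- x + matrix(rnorm(30, sd = 0.3), 10, 3)
  expect_equal(kabsch_rmsd(x, z), kabsch_rmsd(z, x), tolerance = 1e-9)
  expect_equal(kabsch_rmsd(x %*% random_rotation(5), z), kabsch_rmsd(x, z),
               tolerance = 1e-9)
  # centered collinear set vs its doubling: closed form sqrt(2/3)
  a <- cbind(c(-1, 0, 1), 0, 0)
  expect_equal(kabsch_rmsd(a, 2 * a), sqrt(2 / 3), tolerance = 1e-9)
  expect_error(kabsch_rmsd(a[1:2, ], a[1:2, ]), "3 points")
  # cross-check against the bio3d implementation on a noisy pair
  skip_if_not_installed("bio3d")
  fit <- suppressWarnings(bio3d::fit.xyz(as.vector(t(x)), as.vector(t(z))))
  expect_equal(kabsch_rmsd(x, z),
               bio3d::rmsd(as.vector(t(x)), fit), tolerance = 1e-3)
})
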