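# hand-built count table: 2 strand letters, 2 loop letters
toy_table <- function() {
  tab <- rbind(L = c(5L, 10L, 5L), M = c(5L, 5L, 10L),
               D = c(2L, 6L, 2L), E = c(3L, 3L, 4L))
  colnames(tab) <- c("interface", "surface", "core")
  new_count_table(tab)
}

test_that("count_letters tallies letter/compartment pairs and drops undefined", {
  ch <- make_helix(10)
  s <- assign_letters(ch)
  acc <- data.frame(chain_id = "A", residue_number = 1:10,
                    insertion_code = "",
                    compartment = c(rep("interface", 3), rep("surface", 3),
                                    rep("core", 2), rep("undefined", 2)))
  tab <- count_letters(s, acc)
  # letters exist at positions 3..9; undefined at 9,10 removes position 9
  lettered <- which(!is.na(s$residue_letters))
  counted <- sum(tab)
  expect_equal(counted, sum(acc$compartment[lettered] != "undefined"))
  # hand tally: positions 3 interface, 4-6 surface, 7-8 core
  expect_equal(unname(colSums(tab)), c(1L, 3L, 2L))
  expect_equal(sum(tab["A", ]), counted)  # straight helix is all 'A'
  # no letter/compartment overlap is an error
  acc$compartment <- "undefined"
  expect_error(count_letters(s, acc), "no residue")
})

test_that("KLd follows the class-reference formula and chi-square flag", {
  # letter distributed exactly like its class: zero divergence
  tab <- new_count_table(rbind(L = c(10L, 20L, 30L), M = c(20L, 40L, 60L),
                               D = c(1L, 1L, 1L)) |>
                           `colnames<-`(c("interface", "surface", "core")))
  r <- kld(tab, "L")
  expect_equal(r$kld, 0, tolerance = 1e-12)
  expect_false(r$significant)
  # counts (10,20,70) against uniform class frequencies: direct evaluation
  tab2 <- new_count_table(rbind(L = c(10L, 20L, 70L),
                                M = c(1000L, 1000L, 1000L)) |>
                            `colnames<-`(c("interface", "surface", "core")))
  r2 <- kld(tab2, "L")
  p <- c(0.1, 0.2, 0.7)
  q <- colSums(rbind(c(10, 20, 70), c(1000, 1000, 1000)))
  q <- q / sum(q)
  expect_equal(r2$kld, sum(p * log(p / q)), tolerance = 1e-12)
  # against an exactly uniform reference the spec's worked numbers appear
  expect_equal(sum(p * log(p / rep(1 / 3, 3))), 0.2968, tolerance = 1e-4)
  expect_equal(r2$critical, qchisq(0.95, 2))
  expect_true(r2$quantity > 5.99 && r2$significant)
  # 0 * ln(0/q) is treated as zero, and an all-zero letter is an error
  tab3 <- new_count_table(rbind(L = c(5L, 5L, 1L), M = c(5L, 5L, 0L)) |>
                            `colnames<-`(c("interface", "surface", "core")))
  expect_silent(kld(tab3, "M"))
  expect_true(is.finite(kld(tab3, "M")$kld))
  tab4 <- new_count_table(rbind(L = c(5L, 5L, 1L), M = c(0L, 0L, 0L)) |>
                            `colnames<-`(c("interface", "surface", "core")))
  expect_error(kld(tab4, "M"), "zero")
})

test_that("Z-scores follow (obs - exp)/sqrt(exp) with the N_exp > 5 rule", {
  tab <- toy_table()
  # strand class: L + M; f_surface(L) = 10/15; exp = 10 * 10/15
  z <- zscore(tab, "L", "interface", "surface")
  n_exp <- 10 * (10 / 15)
  expect_equal(z$n_exp, n_exp)
  expect_equal(z$z, (5 - n_exp) / sqrt(n_exp))
  # symmetric case: obs equals exp gives z = 0
  tabe <- new_count_table(rbind(L = c(10L, 10L, 5L), M = c(10L, 10L, 5L)) |>
                            `colnames<-`(c("interface", "surface", "core")))
  expect_equal(zscore(tabe, "L", "interface", "surface")$z, 0)
  # worked numbers: N_obs = 30, class total cp1 = 100, f_cp2 = 0.2
  expect_equal((30 - 20) / sqrt(20), 2.236, tolerance = 1e-3)
  # meaningfulness requires N_exp > 5
  tabs <- new_count_table(rbind(L = c(2L, 4L, 20L), M = c(8L, 16L, 20L)) |>
                            `colnames<-`(c("interface", "surface", "core")))
  zs <- zscore(tabs, "L", "interface", "surface")
  expect_equal(zs$n_exp, 10 * 4 / 20)
  expect_false(zs$meaningful)
})

test_that("Z-score sign tracks relative over-representation on random tables", {
  for (s in 1:25) {
    set.seed(s)
    tab <- matrix(rpois(6, 40) + 1L, 2, 3,
                  dimnames = list(c("L", "M"),
                                  c("interface", "surface", "core")))
    tab <- new_count_table(tab)
    z <- zscore(tab, "L", "interface", "surface")$z
    f1 <- tab["L", "interface"] / sum(tab[, "interface"])
    f2 <- tab["L", "surface"] / sum(tab[, "surface"])
    if (abs(f1 - f2) > 1e-12)
      expect_equal(z > 0, f1 > f2, info = paste("seed", s))
  }
})

test_that("Bonferroni thresholds match normal quantiles", {
  expect_equal(bonferroni_threshold(m = 1), 1.960, tolerance = 1e-3)
  expect_equal(bonferroni_threshold(m = 12), qnorm(1 - 0.05 / 24))
  expect_equal(bonferroni_threshold(m = 12), 2.865, tolerance = 1e-3)
  expect_equal(bonferroni_threshold(m = 39), 3.221, tolerance = 1e-3)
  expect_equal(bonferroni_threshold(m = 5, sided = "one"),
               qnorm(1 - 0.05 / 5))
})

test_that("correspondence analysis recovers the residual-matrix eigensystem", {
  # independent table (outer product of margins): zero inertia
  r <- c(10, 20, 30); c <- c(2, 3, 5)
  tab <- outer(r, c)
  dimnames(tab) <- list(c("L", "M", "D"), c("interface", "surface", "core"))
  ca0 <- correspondence_analysis(tab)
  expect_equal(ca0$total_inertia, 0, tolerance = 1e-12)
  # letters x 3 table: at most 2 axes, fractions sum to 1
  ca <- correspondence_analysis(toy_table())
  expect_lte(ca$rank, 2)
  expect_equal(sum(ca$inertia_fraction), 1, tolerance = 1e-9)
  # 3 x 3 toy table: inertia equals eigenvalues of S'S (dense eigen oracle)
  tab3 <- matrix(c(20, 5, 5, 5, 20, 5, 5, 5, 20), 3, 3,
                 dimnames = list(c("D", "E", "F"),
                                 c("interface", "surface", "core")))
  ca3 <- correspondence_analysis(tab3)
  P <- tab3 / sum(tab3)
  S <- diag(1 / sqrt(rowSums(P))) %*% (P - outer(rowSums(P), colSums(P))) %*%
    diag(1 / sqrt(colSums(P)))
  ev <- sort(eigen(t(S) %*% S, symmetric = TRUE)$values, decreasing = TRUE)
  expect_equal(ca3$inertia, ev[ev > 1e-12], tolerance = 1e-9)
  # cross-check against the canonical-correlation implementation in MASS
  skip_if_not_installed("MASS")
  mca <- MASS::corresp(as.matrix(toy_table()), nf = 2)
  expect_equal(sort(ca$inertia), sort(mca$cor^2), tolerance = 1e-8)
})

test_that("PCA of descriptor tables gives exact small-case spectra", {
  # collinear points: one component carries everything
  x <- cbind(1:10, 2 * (1:10), -1 * (1:10), 0.5 * (1:10))
  p <- pca_descriptors(x, scale = FALSE)
  expect_equal(p$variance_fraction[1], 1, tolerance = 1e-12)
  # 2D closed form: eigenvalues of the 2x2 covariance by quadratic formula
  set.seed(4)
  y <- cbind(rnorm(40), rnorm(40))
  C <- stats::cov(y)
  tr <- sum(diag(C)); dt <- det(C)
  lam <- c(tr + sqrt(tr^2 - 4 * dt), tr - sqrt(tr^2 - 4 * dt)) / 2
  p2 <- prcomp(y)$sdev^2
  expect_equal(p2, lam, tolerance = 1e-10)
  expect_equal(sum(pca_descriptors(cbind(y, y), scale = FALSE)
                   $variance_fraction), 1, tolerance = 1e-9)
  # zero-variance column cannot be standardized
  expect_error(pca_descriptors(cbind(1:5, rep(2, 5), 1:5, 1:5)), "zero-variance")
})

test_that("preferential percentage matches the worked two-letter case", {
  # proportional table: nothing preferential
  tab <- new_count_table(rbind(L = c(10L, 20L, 30L), M = c(20L, 40L, 60L)) |>
                           `colnames<-`(c("interface", "surface", "core")))
  expect_equal(preferential_pct(tab, "strand", "surface"), 0)
  # two-letter class, counts X:(80,20), Y:(20,80): 30% in each compartment
  tab2 <- new_count_table(rbind(L = c(80L, 20L, 0L), M = c(20L, 80L, 0L)) |>
                            `colnames<-`(c("interface", "surface", "core")))
  tab2 <- tab2[, c("interface", "surface"), drop = FALSE] |>
    cbind(core = c(0L, 0L)) |> new_count_table()
  expect_equal(preferential_pct(tab2, "strand", "interface"), 30)
  expect_equal(preferential_pct(tab2, "strand", "surface"), 30)
  # bounded on random tables
  for (s in 1:50) {
    set.seed(s)
    tb <- new_count_table(matrix(rpois(6, 30) + 1L, 2, 3,
                                 dimnames = list(c("L", "M"),
                                                 c("interface", "surface",
                                                   "core"))))
    pct <- preferential_pct(tb, "strand", "core")
    expect_gte(pct, 0); expect_lte(pct, 100)
  }
})

test_that("amino-acid composition proportions sum to one per cell", {
  ch <- make_helix(12, aa = "ACDEFGHIKLMN")
  s <- assign_letters(ch)
  acc <- data.frame(chain_id = "A", residue_number = 1:12,
                    insertion_code = "",
                    compartment = rep(c("surface", "core"), 6))
  comp <- aa_composition(s, acc)
  sums <- tapply(comp$proportion, paste(comp$letter, comp$compartment), sum)
  expect_true(all(abs(sums - 1) < 1e-12))
  # single residue in a cell is an indicator vector
  one <- comp[comp$n > 0 & comp$compartment == "surface", ]
  expect_true(all(one$proportion <= 1))
})
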