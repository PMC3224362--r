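#' Count structural letters per compartment
#'
#' Tallies the letters x compartments occurrence matrix feeding all
#' distribution statistics.  A residue contributes one count when it both
#' carries a structural letter and is assigned to a non-undefined
#' compartment; undefined residues are excluded.
#'
#' @param sequences a [StructuralSequence][assign_letters] or list of them.
#' @param accessibility data frame(s) from [accessibility_contexts()]
#'   (matched to `sequences` by chain id and residue identity).
#' @param class_filter optional secondary-structure class (e.g. `"loop"`,
#'   `"helix"`, `"border"`) restricting the rows of the result.
#' @return a `CountTable`: integer matrix letters x
#'   `{interface, surface, core}` with the letters' classes in
#'   `attr(, "ss_class")`.
#' @export
count_letters <- function(sequences, accessibility, class_filter = NULL) {
  if (inherits(sequences, "StructuralSequence")) sequences <- list(sequences)
  if (is.data.frame(accessibility)) accessibility <- list(accessibility)
  acc <- do.call(rbind, accessibility)
  comps <- c("interface", "surface", "core")
  tab <- matrix(0L, length(SA_LETTERS), 3L,
                dimnames = list(SA_LETTERS, comps))
  n_matched <- 0L
  for (s in sequences) {
    keys <- paste(s$keys$chain_id, s$keys$residue_number,
                  s$keys$insertion_code, sep = "\r")
    akeys <- paste(acc$chain_id, acc$residue_number, acc$insertion_code,
                   sep = "\r")
    idx <- match(keys, akeys)
    for (i in seq_along(keys)) {
      let <- s$residue_letters[i]
      if (is.na(let) || is.na(idx[i])) next
      cp <- acc$compartment[idx[i]]
      if (!cp %in% comps) next
      tab[let, cp] <- tab[let, cp] + 1L
      n_matched <- n_matched + 1L
    }
  }
  if (n_matched == 0L)
    stop("no residue carries both a letter and a defined compartment")
  new_count_table(tab, class_filter)
}

#' @rdname count_letters
#' @param tab an integer matrix letters x compartments (rownames letters,
#'   colnames containing interface/surface/core).
#' @export
new_count_table <- function(tab, class_filter = NULL) {
  stopifnot(is.matrix(tab), !is.null(rownames(tab)))
  cls <- ss_class(rownames(tab), border_umbrella = TRUE)
  if (!is.null(class_filter)) {
    keep <- cls %in% class_filter
    tab <- tab[keep, , drop = FALSE]
    cls <- cls[keep]
  }
  structure(tab, ss_class = setNames(cls, rownames(tab)),
            class = c("CountTable", class(tab)))
}

# frequencies of a letter's class across compartments
class_profile <- function(tab, letter) {
  cls <- attr(tab, "ss_class")
  members <- rownames(tab)[cls == cls[[letter]]]
  cls_counts <- colSums(tab[members, , drop = FALSE])
  list(members = members, counts = cls_counts,
       freq = cls_counts / sum(cls_counts))
}

#' Kullback-Leibler divergence of a letter's compartment distribution
#'
#' Measures how far a letter's distribution over the interface, surface and
#' core compartments departs from the distribution of its own
#' secondary-structure class:
#' `KLd(sl) = sum_cp p(sl, cp) * ln(p(sl, cp) / p(ss, cp))`, with
#' `0 * ln(0/q) = 0`.  The quantity `2 * N_sl * KLd(sl)` is compared to the
#' 0.95 quantile of a chi-square distribution with 2 degrees of freedom
#' (5.99): larger values flag a significantly non-uniform distribution.
#'
#' @param tab a `CountTable` from [count_letters()].
#' @param letter one letter, or `NULL` for all rows of the table.
#' @param alpha significance level of the chi-square test.
#' @return data frame with columns `letter`, `n`, `kld` (nats), `quantity`,
#'   `critical`, `significant`.
#' @export
kld <- function(tab, letter = NULL, alpha = 0.05) {
  letters <- letter %||% rownames(tab)
  crit <- qchisq(1 - alpha, df = ncol(tab) - 1L)
  out <- lapply(letters, function(l) {
    n_sl <- sum(tab[l, ])
    if (n_sl == 0) stop("letter ", l, " has zero counts")
    prof <- class_profile(tab, l)
    p <- tab[l, ] / n_sl
    q <- prof$freq
    if (any(q == 0 & p > 0))
      stop("class frequency is zero where letter ", l, " has mass")
    terms <- ifelse(p > 0, p * log(p / q), 0)
    k <- sum(terms)
    data.frame(letter = l, n = n_sl, kld = k, quantity = 2 * n_sl * k,
               critical = crit, significant = 2 * n_sl * k > crit,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Z-score for the compartment preference of a letter
#'
#' Tests whether letter `sl` is over-represented in compartment `cp1`
#' relative to compartment `cp2`, against the background of its
#' secondary-structure class: the expected count is
#' `N_exp = (class total in cp1) * f_cp2(sl)` with
#' `f_cp2(sl) = N(sl, cp2) / (class total in cp2)`, and
#' `z = (N_obs - N_exp) / sqrt(N_exp)`.  The score is only considered
#' meaningful when `N_exp > 5`.  `z > T` (the Bonferroni threshold, see
#' [bonferroni_threshold()]) indicates a significant preference for `cp1`,
#' `z < -T` for `cp2`.
#'
#' @inheritParams kld
#' @param cp1,cp2 compartment names (columns of `tab`).
#' @param threshold significance threshold `T`; default the Bonferroni
#'   threshold for (letters in the class) x 3 two-sided comparisons.
#' @return data frame with `letter`, `cp1`, `cp2`, `n_obs`, `n_exp`, `z`,
#'   `meaningful`, `threshold`, `significant`.
#' @export
zscore <- function(tab, letter = NULL, cp1 = "interface", cp2 = "surface",
                   threshold = NULL) {
  letters <- letter %||% rownames(tab)
  out <- lapply(letters, function(l) {
    prof <- class_profile(tab, l)
    if (any(prof$counts[c(cp1, cp2)] == 0))
      stop("class total is zero in ", cp1, " or ", cp2)
    f_cp2 <- tab[l, cp2] / prof$counts[[cp2]]
    n_exp <- prof$counts[[cp1]] * f_cp2
    n_obs <- tab[l, cp1]
    z <- if (n_exp > 0) (n_obs - n_exp) / sqrt(n_exp) else NA_real_
    thr <- threshold %||%
      bonferroni_threshold(m = length(prof$members) * 3L, sided = "two")
    data.frame(letter = l, cp1 = cp1, cp2 = cp2, n_obs = n_obs,
               n_exp = n_exp, z = z, meaningful = is.finite(n_exp) & n_exp > 5,
               threshold = thr,
               significant = !is.na(z) && n_exp > 5 && abs(z) > thr,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Bonferroni-corrected normal significance threshold
#'
#' The standard-normal quantile at `1 - alpha/m` (one-sided) or
#' `1 - alpha/(2m)` (two-sided) for a family of `m` comparisons.
#'
#' @param alpha family-wise error rate.
#' @param m number of tests in the family; for letter-preference Z-scores
#'   the default family is (letters in the class) x 3 compartment pairs.
#' @param sided `"one"` or `"two"`.
#' @return the threshold `T`.
#' @examples
#' bonferroni_threshold(m = 1)   # 1.96
#' bonferroni_threshold(m = 12)  # 2.865
#' @export
bonferroni_threshold <- function(alpha = 0.05, m = 1L,
                                 sided = c("two", "one")) {
  sided <- match.arg(sided)
  stopifnot(m >= 1, alpha > 0, alpha < 1)
  p <- if (sided == "two") 1 - alpha / (2 * m) else 1 - alpha / m
  qnorm(p)
}

#' Correspondence analysis of a letters x compartments table
#'
#' Simple correspondence analysis: singular value decomposition of the
#' standardized-residual matrix of the contingency table.  For a table with
#' three compartments there are at most two nontrivial axes; the share of
#' total inertia carried by each axis measures how much of the
#' letters-by-compartments association it displays.
#'
#' @param tab a contingency matrix (e.g. a `CountTable`).
#' @return an `OrdinationResult` list: `row_coords`, `col_coords` (principal
#'   coordinates), `inertia` (per-axis), `inertia_fraction`, `total_inertia`,
#'   and `rank`.
#' @export
correspondence_analysis <- function(tab) {
  tab <- unclass(tab)[, , drop = FALSE]
  if (any(rowSums(tab) <= 0) || any(colSums(tab) <= 0))
    stop("all row and column margins must be positive")
  P <- tab / sum(tab)
  r <- rowSums(P)
  c <- colSums(P)
  S <- diag(1 / sqrt(r)) %*% (P - outer(r, c)) %*% diag(1 / sqrt(c))
  sv <- svd(S)
  keep <- sv$d > 1e-12
  rank <- sum(keep)
  if (rank == 0L) {
    return(structure(list(
      row_coords = matrix(0, nrow(tab), 0, dimnames = list(rownames(tab),
                                                           NULL)),
      col_coords = matrix(0, ncol(tab), 0, dimnames = list(colnames(tab),
                                                           NULL)),
      inertia = numeric(0), inertia_fraction = numeric(0),
      total_inertia = 0, rank = 0L, degenerate = TRUE),
      class = "OrdinationResult"))
  }
  d <- sv$d[keep]
  inertia <- d^2
  total <- sum(sv$d^2)
  frac <- if (total > 0) inertia / total else rep(0, rank)
  row_coords <- diag(1 / sqrt(r)) %*% sv$u[, keep, drop = FALSE] %*% diag(d, rank)
  col_coords <- diag(1 / sqrt(c)) %*% sv$v[, keep, drop = FALSE] %*% diag(d, rank)
  dimnames(row_coords) <- list(rownames(tab), paste0("Axis", seq_len(rank)))
  dimnames(col_coords) <- list(colnames(tab), paste0("Axis", seq_len(rank)))
  structure(list(row_coords = row_coords, col_coords = col_coords,
                 inertia = inertia, inertia_fraction = frac,
                 total_inertia = total, rank = rank,
                 degenerate = rank < min(dim(tab)) - 1L),
            class = "OrdinationResult")
}

#' Principal component analysis of the letter descriptor table
#'
#' PCA of the 27 x 4 descriptor matrix (d1, d2, d3, p4) of the structural
#' letters, by default on standardized columns (the descriptors mix
#' distances with a signed projection of different spreads); set
#' `scale = FALSE` for raw-covariance PCA.
#'
#' @param descriptors numeric matrix, letters x 4.
#' @param scale standardize columns before decomposition.
#' @return an `OrdinationResult` list with `row_coords` (scores), `loadings`,
#'   `variance_fraction` and `sdev`.
#' @export
pca_descriptors <- function(descriptors, scale = TRUE) {
  x <- as.matrix(descriptors)
  if (!all(is.finite(x))) stop("non-finite descriptor values")
  if (scale && any(apply(x, 2L, stats::sd) == 0))
    stop("zero-variance column cannot be standardized")
  p <- prcomp(x, center = TRUE, scale. = scale)
  frac <- p$sdev^2 / sum(p$sdev^2)
  structure(list(row_coords = p$x, loadings = p$rotation,
                 variance_fraction = frac, sdev = p$sdev),
            class = "OrdinationResult")
}

#' @export
print.OrdinationResult <- function(x, ...) {
  frac <- x$inertia_fraction %||% x$variance_fraction
  cat("OrdinationResult:", length(frac), "axes;",
      paste0(round(100 * frac, 1), "%", collapse = ", "), "\n")
  invisible(x)
}

#' Percentage of a secondary-structure class affected by preferential
#' distribution
#'
#' For the letters of one class in one compartment, the expected count of
#' each letter is its overall total shared out in proportion to the class's
#' presence in the compartment:
#' `Exp(sl, cp) = N_total(sl) * (class total in cp) / (class total)`.
#' The excess `max(Obs - Exp, 0)` summed over the class's letters, as a
#' fraction of the observed class count in the compartment, measures how
#' much of the class's occupancy is driven by letter-level preferences.
#'
#' @inheritParams kld
#' @param class a class label (`"helix"`, `"strand"`, `"loop"`, `"border"`).
#' @param compartment a compartment name, or `"all"` for the
#'   compartment-weighted overall percentage.
#' @return percentage in `[0, 100]`.
#' @export
preferential_pct <- function(tab, class, compartment) {
  cls <- attr(tab, "ss_class")
  members <- rownames(tab)[cls == class]
  if (!length(members)) stop("no letters of class ", class)
  sub <- unclass(tab)[members, , drop = FALSE]
  class_cp <- colSums(sub)
  class_tot <- sum(sub)
  if (class_tot == 0) stop("class ", class, " has zero counts")
  exp_tab <- outer(rowSums(sub), class_cp / class_tot)
  excess <- pmax(sub - exp_tab, 0)
  if (identical(compartment, "all")) {
    return(100 * sum(excess) / sum(sub))
  }
  obs_cp <- sum(sub[, compartment])
  if (obs_cp == 0) return(NA_real_)
  100 * sum(excess[, compartment]) / obs_cp
}

#' Amino-acid composition of letters per compartment
#'
#' Proportions of the 20 amino acids among residues carrying a given letter
#' in a given compartment.
#'
#' @inheritParams count_letters
#' @param letters which letters to report (default all observed).
#' @return data frame with `letter`, `compartment`, `aa`, `n`, `proportion`;
#'   proportions sum to 1 within each (letter, compartment) cell.
#' @export
aa_composition <- function(sequences, accessibility, letters = NULL) {
  if (inherits(sequences, "StructuralSequence")) sequences <- list(sequences)
  if (is.data.frame(accessibility)) accessibility <- list(accessibility)
  acc <- do.call(rbind, accessibility)
  akeys <- paste(acc$chain_id, acc$residue_number, acc$insertion_code,
                 sep = "\r")
  rows <- list()
  for (s in sequences) {
    keys <- paste(s$keys$chain_id, s$keys$residue_number,
                  s$keys$insertion_code, sep = "\r")
    idx <- match(keys, akeys)
    ok <- !is.na(s$residue_letters) & !is.na(idx)
    ok[ok] <- acc$compartment[idx[ok]] %in% c("interface", "surface", "core")
    if (!any(ok)) next
    rows[[length(rows) + 1L]] <- data.frame(
      letter = s$residue_letters[ok], aa = s$aa[ok],
      compartment = acc$compartment[idx[ok]], stringsAsFactors = FALSE)
  }
  if (!length(rows)) stop("no residues with both letter and compartment")
  d <- do.call(rbind, rows)
  if (!is.null(letters)) d <- d[d$letter %in% letters, , drop = FALSE]
  agg <- as.data.frame(table(letter = d$letter, compartment = d$compartment,
                             aa = d$aa), stringsAsFactors = FALSE)
  agg <- agg[agg$Freq > 0 | TRUE, ]
  cell_tot <- tapply(agg$Freq, paste(agg$letter, agg$compartment),
                     sum)
  tot <- cell_tot[paste(agg$letter, agg$compartment)]
  agg$proportion <- ifelse(tot > 0, agg$Freq / tot, NA_real_)
  names(agg)[names(agg) == "Freq"] <- "n"
  agg <- agg[tot > 0, c("letter", "compartment", "aa", "n", "proportion")]
  rownames(agg) <- NULL
  agg
}
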