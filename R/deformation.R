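#' Pair residues of unbound and bound conformations of a chain
#'
#' Global amino-acid sequence alignment (match +1, mismatch -1, linear gap
#' -2, via [Biostrings::pairwiseAlignment()]); aligned columns with identical
#' residues become pairs, mismatched columns are dropped with a warning
#' (letter changes at mutated positions could reflect the mutation rather
#' than deformation).
#'
#' @param unbound,bound [CaChain] objects of the same protein in its free
#'   and complexed state.
#' @param min_identity below this alignment identity (fraction of aligned
#'   columns) the pairing is rejected as a suspected wrong chain match.
#' @return a `PositionMap`: data frame with `pos_unbound`, `pos_bound`
#'   (indices into the chains' residue lists); attributes `unaligned_unbound`
#'   and `unaligned_bound` list the left-out positions.
#' @export
pair_chains <- function(unbound, bound, min_identity = 0.8) {
  stopifnot(inherits(unbound, "CaChain"), inherits(bound, "CaChain"))
  s1 <- paste(unbound$aa, collapse = "")
  s2 <- paste(bound$aa, collapse = "")
  alpha <- unique(c(unbound$aa, bound$aa, LETTERS))
  mat <- matrix(-1, length(alpha), length(alpha),
                dimnames = list(alpha, alpha))
  diag(mat) <- 1
  aln <- Biostrings::pairwiseAlignment(
    s1, s2, type = "global", substitutionMatrix = mat,
    gapOpening = 0, gapExtension = 2)
  a1 <- strsplit(as.character(Biostrings::alignedPattern(aln)), "")[[1L]]
  a2 <- strsplit(as.character(Biostrings::alignedSubject(aln)), "")[[1L]]
  i1 <- cumsum(a1 != "-")
  i2 <- cumsum(a2 != "-")
  both <- a1 != "-" & a2 != "-"
  ident <- both & a1 == a2
  if (sum(both) == 0 || sum(ident) / sum(both) < min_identity)
    stop("aligned identity ", round(100 * sum(ident) / max(1, sum(both))),
         "% below ", 100 * min_identity, "%: wrong chain pairing suspected")
  if (any(both & !ident))
    warning(sum(both & !ident), " mismatched aligned column(s) dropped")
  map <- data.frame(pos_unbound = i1[ident], pos_bound = i2[ident])
  attr(map, "unaligned_unbound") <- setdiff(seq_along(unbound$aa),
                                            map$pos_unbound)
  attr(map, "unaligned_bound") <- setdiff(seq_along(bound$aa),
                                          map$pos_bound)
  class(map) <- c("PositionMap", class(map))
  map
}

#' Structural-letter transition counts between unbound and bound states
#'
#' For every paired position where both states carry a structural letter,
#' the transition `(letter unbound -> letter bound)` is counted in the
#' compartment of the bound-state residue (the interface exists only in the
#' bound state; unbound positions inherit it through the position map).
#' Positions lacking a letter on either side, or whose bound compartment is
#' undefined, are skipped.
#'
#' @param map a `PositionMap` from [pair_chains()].
#' @param seq_unbound,seq_bound [StructuralSequence][assign_letters] objects.
#' @param compartments_bound data frame from [accessibility_contexts()] for
#'   the bound chain, or a character vector of compartment labels aligned
#'   with the bound chain's residues.
#' @return named list of 27 x 27 count matrices, one per compartment
#'   (`interface`, `surface`, `core`), rows the unbound letter, columns the
#'   bound letter.
#' @export
transition_counts <- function(map, seq_unbound, seq_bound,
                              compartments_bound) {
  comps <- c("interface", "surface", "core")
  if (is.data.frame(compartments_bound)) {
    bkeys <- paste(seq_bound$keys$chain_id, seq_bound$keys$residue_number,
                   seq_bound$keys$insertion_code, sep = "\r")
    akeys <- paste(compartments_bound$chain_id,
                   compartments_bound$residue_number,
                   compartments_bound$insertion_code, sep = "\r")
    cp_vec <- compartments_bound$compartment[match(bkeys, akeys)]
  } else {
    cp_vec <- compartments_bound
  }
  C <- setNames(lapply(comps, function(x)
    matrix(0L, 27L, 27L, dimnames = list(SA_LETTERS, SA_LETTERS))), comps)
  for (i in seq_len(nrow(map))) {
    l1 <- seq_unbound$residue_letters[map$pos_unbound[i]]
    l2 <- seq_bound$residue_letters[map$pos_bound[i]]
    cp <- cp_vec[map$pos_bound[i]]
    if (is.na(l1) || is.na(l2) || is.na(cp) || !cp %in% comps) next
    C[[cp]][l1, l2] <- C[[cp]][l1, l2] + 1L
  }
  C
}

#' Deformation proportions P(sl1, sl2)
#'
#' For each unbound letter `sl1` with at least one deformation, the
#' proportion of its deformations ending in each bound letter `sl2`:
#' `P(sl1, sl2) = C(sl1, sl2) / sum_{sl2' != sl1} C(sl1, sl2')` for
#' `sl2 != sl1`.  Conditioning on deformed letters removes differences in
#' deformation rate between letters; unchanged (diagonal) counts never
#' contribute, and rows without any deformation are absent rather than
#' zero-filled.
#'
#' @param C a square transition count matrix (e.g. one compartment of
#'   [transition_counts()]).
#' @return matrix with one row per deformed letter (subset of the rows of
#'   `C`), off-diagonal proportions summing to 1 per row; the diagonal
#'   entries are `NA`.
#' @export
deformation_proportions <- function(C) {
  stopifnot(is.matrix(C), nrow(C) == ncol(C), all(C >= 0))
  off <- C
  diag(off) <- 0L
  tot <- rowSums(off)
  keep <- tot > 0
  P <- sweep(off[keep, , drop = FALSE], 1L, tot[keep], "/")
  for (l in rownames(P)) P[l, l] <- NA_real_
  P
}

#' Interface-minus-surface deformation differences
#'
#' `deltaP(sl1, sl2) = P_interf(sl1, sl2) - P_surf(sl1, sl2)`.  Protein
#' flexibility should produce similar substitutions at interface and
#' surface, so strongly positive entries single out deformations induced by
#' the interaction.  Rows present in only one compartment use 0 for the
#' missing one and are listed in `attr(, "one_sided")`.
#'
#' @param P_interf,P_surf proportion matrices from
#'   [deformation_proportions()].
#' @return matrix over the union of the two row sets, entries in `[-1, 1]`.
#' @export
delta_p <- function(P_interf, P_surf) {
  rows <- union(rownames(P_interf), rownames(P_surf))
  cols <- colnames(P_interf) %||% colnames(P_surf)
  fill <- function(P) {
    out <- matrix(0, length(rows), length(cols),
                  dimnames = list(rows, cols))
    if (nrow(P)) out[rownames(P), ] <- ifelse(is.na(P), 0, P)
    out
  }
  D <- fill(P_interf) - fill(P_surf)
  attr(D, "one_sided") <- c(setdiff(rows, rownames(P_interf)),
                            setdiff(rows, rownames(P_surf)))
  D
}

#' Exposure differences of deformed loop positions
#'
#' For deformed positions (typically loop-letters in the bound interface
#' compartment), `D = a_chain(unbound) - a_chain(bound, disjoint)`: the
#' change in relative accessibility of the residue between the free protein
#' and the chain extracted alone from the complex.  A negative `D` means the
#' deformation increased exposure to the protein exterior (towards the
#' partner); positive means burial.  Each position is labelled by its
#' transition category from [LETTER_GROUPS]: `s/s`, `s/c`, `c/s`, `c/c`
#' (surface-letter or core-letter on the unbound/bound side), or `other`
#' when a letter belongs to neither group.
#'
#' @param positions data frame with columns `pos_unbound`, `pos_bound`,
#'   `letter_unbound`, `letter_bound` (e.g. deformed rows built from a
#'   [pair_chains()] map and the two structural sequences).
#' @param acc_unbound,acc_bound_disjoint numeric vectors of `a_chain`
#'   accessibilities indexed by chain position for the two states.
#' @return list with `positions` (the input plus `D` and `category`) and
#'   `aggregates` (mean, sd, median, n of `D` per category).
#' @export
exposure_difference <- function(positions, acc_unbound,
                                acc_bound_disjoint) {
  stopifnot(all(c("pos_unbound", "pos_bound", "letter_unbound",
                  "letter_bound") %in% names(positions)))
  grp <- function(l) ifelse(l %in% LETTER_GROUPS$surface, "s",
                            ifelse(l %in% LETTER_GROUPS$core, "c", "?"))
  a_u <- acc_unbound[positions$pos_unbound]
  a_b <- acc_bound_disjoint[positions$pos_bound]
  keep <- !is.na(a_u) & !is.na(a_b)
  if (any(!keep)) warning(sum(!keep), " position(s) missing accessibility; skipped")
  pos <- positions[keep, , drop = FALSE]
  pos$D <- a_u[keep] - a_b[keep]
  g1 <- grp(pos$letter_unbound)
  g2 <- grp(pos$letter_bound)
  pos$category <- ifelse(g1 == "?" | g2 == "?", "other",
                         paste(g1, g2, sep = "/"))
  cats <- sort(unique(pos$category))
  agg <- do.call(rbind, lapply(cats, function(cat) {
    d <- pos$D[pos$category == cat]
    data.frame(category = cat, n = length(d), mean = mean(d),
               sd = if (length(d) > 1L) stats::sd(d) else NA_real_,
               median = stats::median(d), stringsAsFactors = FALSE)
  }))
  list(positions = pos, aggregates = agg)
}

#' Occurrence shift of the straight regular letters [A, T, M]
#'
#' The correlated straightening-out of regular secondary structures upon
#' binding is summarized per subunit as
#' `count(A, T, M in bound) - count(A, T, M in unbound)`.
#'
#' @param seq_unbound,seq_bound [StructuralSequence][assign_letters] objects
#'   or plain character vectors of letters.
#' @return integer shift (positive = more straight letters when bound).
#' @export
straight_letter_shift <- function(seq_unbound, seq_bound) {
  lets <- function(s) {
    if (inherits(s, "StructuralSequence")) s <- s$residue_letters
    if (length(s) == 1L && nchar(s) > 1L) s <- strsplit(s, "")[[1L]]
    s
  }
  straight <- c("A", "T", "M")
  sum(lets(seq_bound) %in% straight, na.rm = TRUE) -
    sum(lets(seq_unbound) %in% straight, na.rm = TRUE)
}

#' Optimal-superposition RMSD (Kabsch)
#'
#' Least-squares superposition of two matched coordinate sets: both sets are
#' centered, the optimal rotation is obtained from the SVD of the covariance
#' matrix with the determinant sign corrected to enforce a proper rotation,
#' and the root-mean-square deviation of the superposed sets is returned.
#'
#' @param coords1,coords2 numeric matrices (n x 3) of matched points,
#'   `n >= 3`.
#' @return RMSD in the coordinate units (Angstrom).
#' @export
kabsch_rmsd <- function(coords1, coords2) {
  x <- as.matrix(coords1)
  y <- as.matrix(coords2)
  stopifnot(ncol(x) == 3L, ncol(y) == 3L)
  if (nrow(x) != nrow(y) || nrow(x) < 3L)
    stop("need two matched sets of at least 3 points")
  xc <- sweep(x, 2L, colMeans(x))
  yc <- sweep(y, 2L, colMeans(y))
  s <- svd(crossprod(xc, yc))
  d <- sign(det(s$v %*% t(s$u)))
  R <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  dev <- yc - xc %*% t(R)
  sqrt(mean(rowSums(dev^2)))
}
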