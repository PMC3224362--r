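# Synthetic-structure and synthetic-count generators.  These produce every
# input the pipeline needs: C-alpha traces with controlled secondary-structure
# shape, two-chain complexes with a genuine buried interface, letter-count
# tables with planted compartment preferences, and paired bound/unbound
# letter sequences with controlled substitution patterns.  All generators are
# deterministic given (parameters, seed).

#' Generate a (bent) alpha-helical C-alpha trace
#'
#' Residues are placed on a helical curve with canonical alpha-helix
#' parameters (radius 2.3 A, rise 1.5 A/residue, twist 100 degrees/residue
#' yield the classic window fingerprint d1 ~ 5.43, d2 ~ 5.05 A).  A positive
#' `curvature` bends the helix axis along a circular arc by that many
#' degrees per residue, turning a straight helix into a curved one.
#'
#' @param n number of residues (>= 4).
#' @param radius,rise,twist helix geometry (Angstrom, Angstrom/residue,
#'   degrees/residue).
#' @param curvature axis bend in degrees/residue (0 = straight).
#' @param jitter standard deviation of isotropic Gaussian coordinate noise
#'   (Angstrom; 0 = none).
#' @param seed RNG seed for the jitter.
#' @param chain_id chain identifier.
#' @param aa amino-acid 1-letter sequence (recycled; default all alanine).
#' @return a [CaChain].
#' @export
make_helix <- function(n, radius = 2.3, rise = 1.5, twist = 100,
                       curvature = 0, jitter = 0, seed = NULL,
                       chain_id = "A", aa = "A") {
  stopifnot(n >= 4L, curvature >= 0)
  i <- 0:(n - 1L)
  th <- i * twist * pi / 180
  if (curvature == 0) {
    xyz <- cbind(radius * cos(th), radius * sin(th), rise * i)
  } else {
    g <- curvature * pi / 180
    Ra <- rise / g                      # arc radius of the bent axis
    phi <- i * g
    xyz <- matrix(0, n, 3L)
    for (k in seq_len(n)) {
      # right-handed frame (u, v, t): reduces to the straight helix at g = 0
      axis_pt <- c(Ra * (1 - cos(phi[k])), 0, Ra * sin(phi[k]))
      t_vec <- c(sin(phi[k]), 0, cos(phi[k]))
      u <- c(cos(phi[k]), 0, -sin(phi[k]))
      v <- cross3(t_vec, u)
      xyz[k, ] <- axis_pt + radius * cos(th[k]) * u + radius * sin(th[k]) * v
    }
  }
  finish_trace(xyz, jitter, seed, chain_id, aa, "helix parameters")
}

#' Generate an extended beta-strand C-alpha trace
#'
#' A pleated zigzag along the strand axis: the axial step and pleat
#' amplitude combine to the canonical 3.8 A C-alpha step, and four-residue
#' windows reach d2 around 10 A (strands are the most extended local
#' conformations).  `curvature` bends the strand axis in-plane.
#'
#' @param n number of residues (>= 2).
#' @param pleat lateral pleat amplitude, Angstrom.
#' @param axial_step axial advance per residue, Angstrom.
#' @param curvature in-plane axis bend, degrees/residue.
#' @inheritParams make_helix
#' @return a [CaChain].
#' @export
make_strand <- function(n, pleat = 0.92, axial_step = NULL, curvature = 0,
                        jitter = 0, seed = NULL, chain_id = "A", aa = "A") {
  stopifnot(n >= 2L)
  if (is.null(axial_step)) {
    if (3.8^2 <= (2 * pleat)^2) stop("pleat too large for a 3.8 A step")
    axial_step <- sqrt(3.8^2 - (2 * pleat)^2)
  }
  i <- 0:(n - 1L)
  xyz <- cbind(axial_step * i, pleat * rep_len(c(1, -1), n), 0)
  if (curvature > 0) {
    g <- curvature * pi / 180
    ang <- i * g
    xyz <- cbind(cos(ang) * xyz[, 1L] - sin(ang) * xyz[, 3L], xyz[, 2L],
                 sin(ang) * xyz[, 1L] + cos(ang) * xyz[, 3L])
  }
  finish_trace(xyz, jitter, seed, chain_id, aa, "strand parameters")
}

#' Generate a random-coil (loop) C-alpha trace
#'
#' A self-avoiding random walk with fixed 3.8 A steps: successive step
#' directions are drawn from a cone around the previous direction, and a
#' trace is rejected and redrawn whenever two non-adjacent residues come
#' closer than 4.0 A.  Deterministic per seed.
#'
#' @param n number of residues.
#' @param seed RNG seed.
#' @param max_retries redraw attempts before giving up.
#' @inheritParams make_helix
#' @return a [CaChain].
#' @export
make_loop <- function(n, seed = 1L, max_retries = 200L, chain_id = "A",
                      aa = "G") {
  stopifnot(n >= 2L)
  xyz <- with_seed(seed, {
    result <- NULL
    for (try in seq_len(max_retries)) {
      cand <- matrix(0, n, 3L)
      dir <- c(1, 0, 0)
      ok <- TRUE
      for (k in 2:n) {
        # bend 40-100 degrees from the previous direction, random azimuth
        bend <- runif(1L, 40, 100) * pi / 180
        az <- runif(1L, 0, 2 * pi)
        ref <- if (abs(dir[1L]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
        e1 <- cross3(dir, ref); e1 <- e1 / vnorm(e1)
        e2 <- cross3(dir, e1)
        newdir <- cos(bend) * dir +
          sin(bend) * (cos(az) * e1 + sin(az) * e2)
        cand[k, ] <- cand[k - 1L, ] + 3.8 * newdir
        dir <- newdir
        if (k > 2L) {
          d2 <- rowSums(sweep(cand[1:(k - 2L), , drop = FALSE], 2L,
                              cand[k, ])^2)
          if (min(d2) < 16) { ok <- FALSE; break }
        }
      }
      if (ok) { result <- cand; break }
    }
    if (is.null(result))
      stop("self-avoiding loop generation failed after ", max_retries,
           " attempts")
    result
  })
  finish_trace(xyz, 0, NULL, chain_id, aa, "loop parameters")
}

# shared trailer for trace generators: jitter, validity check, CaChain
finish_trace <- function(xyz, jitter, seed, chain_id, aa, what) {
  n <- nrow(xyz)
  if (jitter > 0)
    xyz <- xyz + with_seed(seed, matrix(rnorm(3L * n, sd = jitter), n, 3L))
  steps <- sqrt(rowSums((xyz[-1L, , drop = FALSE] -
                           xyz[-n, , drop = FALSE])^2))
  if (any(steps < 2.5 | steps > 4.5))
    stop(what, " produce invalid consecutive C-alpha distances (",
         paste(round(range(steps), 2), collapse = "-"), " A)")
  aa <- rep_len(strsplit(paste(aa, collapse = ""), "")[[1L]], n)
  new_ca_chain(chain_id,
               keys = data.frame(chain_id = chain_id,
                                 residue_number = seq_len(n),
                                 insertion_code = "",
                                 stringsAsFactors = FALSE),
               aa = aa, xyz = xyz)
}

#' Assemble a synthetic two-chain complex
#'
#' Chain B is rigidly placed at `separation` Angstrom from chain A along the
#' y axis (after both chains are internally assembled from their segment
#' specs laid end to end).  The structure is represented with one C-alpha
#' pseudo-atom per residue for surface-area purposes.  Placements that
#' produce inter-chain contacts closer than 2 A are rejected.
#'
#' @param chain_a,chain_b a [CaChain] or list of `CaChain` segments (joined
#'   with 3.8 A spacing along x).
#' @param separation distance between the chains' placement axes, Angstrom.
#' @param seed seed for the (small) random orientation used when resolving
#'   clashes.
#' @return a [ComplexStructure][read_pdb] with chains `A` and `B` as the
#'   pair of interest.
#' @export
make_complex <- function(chain_a, chain_b, separation = 9, seed = NULL) {
  stopifnot(separation > 0)
  join <- function(x, id) {
    if (inherits(x, "CaChain")) segs <- list(x) else segs <- x
    xyz <- NULL
    aa <- character(0)
    for (s in segs) {
      sx <- s$xyz
      if (!is.null(xyz)) {
        shift <- max(xyz[, 1L]) + 3.8 - min(sx[, 1L])
        sx[, 1L] <- sx[, 1L] + shift
      }
      xyz <- rbind(xyz, sx)
      aa <- c(aa, s$aa)
    }
    new_ca_chain(id, data.frame(chain_id = id,
                                residue_number = seq_len(nrow(xyz)),
                                insertion_code = "",
                                stringsAsFactors = FALSE),
                 aa = aa, xyz = xyz)
  }
  a <- join(chain_a, "A")
  b <- join(chain_b, "B")
  b$xyz <- sweep(b$xyz, 2L, colMeans(b$xyz))
  b$xyz <- sweep(b$xyz, 2L, colMeans(a$xyz) + c(0, separation, 0), "+")
  mind <- sqrt(min(cross_dist2(a$xyz, b$xyz)))
  if (mind < 2) {
    # nudge along y until clash-free (deterministic), else error
    for (extra in seq(0.5, 5, by = 0.5)) {
      b2 <- b
      b2$xyz[, 2L] <- b2$xyz[, 2L] + extra
      if (sqrt(min(cross_dist2(a$xyz, b2$xyz))) >= 2) { b <- b2; break }
    }
    if (sqrt(min(cross_dist2(a$xyz, b$xyz))) < 2)
      stop("could not place chains without < 2 A clashes")
  }
  cplx_atoms <- function(ch) chain_as_complex(ch)$atoms
  structure(list(atoms = rbind(cplx_atoms(a), cplx_atoms(b)),
                 chains = list(A = a, B = b), pair = c("A", "B")),
            class = "ComplexStructure")
}

#' Sample a letter x compartment count table from a preference profile
#'
#' Each letter's total count is split over the interface, surface and core
#' compartments by an independent multinomial draw from its preference
#' probabilities.  Emulates observed letter-occurrence tables with known
#' (planted) compartment preferences.
#'
#' @param profile a `PreferenceProfile`: list with `prob` (matrix letters x
#'   3 compartments, rows summing to 1) and `n` (per-letter total counts,
#'   recycled).
#' @param seed RNG seed.
#' @return a `CountTable` (see [count_letters()]).
#' @export
sample_counts <- function(profile, seed = NULL) {
  p <- as.matrix(profile$prob)
  if (is.null(colnames(p))) colnames(p) <- c("interface", "surface", "core")
  if (is.null(rownames(p))) rownames(p) <- SA_LETTERS[seq_len(nrow(p))]
  stopifnot(all(abs(rowSums(p) - 1) < 1e-9))
  n <- rep_len(profile$n, nrow(p))
  tab <- with_seed(seed, t(vapply(seq_len(nrow(p)), function(i)
    as.integer(rmultinom(1L, n[i], p[i, ])), integer(3L))))
  dimnames(tab) <- dimnames(p)
  new_count_table(tab)
}

#' Mutate a structural-letter sequence with a substitution model
#'
#' Emulates bound-state letter sequences: at each position, with the
#' deformation rate of the position's compartment, the letter is replaced by
#' a draw from its substitution distribution (which may include the letter
#' itself).  Positions with rate 0 or letters without a substitution row are
#' left unchanged.
#'
#' @param letters character vector of unbound letters (`NA` allowed).
#' @param spec a `SubstitutionSpec`: list with `sub` (row-stochastic matrix,
#'   rows = source letters, columns = target letters) and `rate` (named
#'   vector of per-compartment deformation probabilities in `[0, 1]`).
#' @param compartments character vector of compartment labels aligned with
#'   `letters`.
#' @param seed RNG seed.
#' @return character vector of bound-state letters.
#' @export
mutate_sequence <- function(letters, spec, compartments, seed = NULL) {
  stopifnot(length(letters) == length(compartments))
  sub <- as.matrix(spec$sub)
  stopifnot(all(abs(rowSums(sub) - 1) < 1e-9), all(spec$rate >= 0),
            all(spec$rate <= 1))
  with_seed(seed, {
    out <- letters
    for (i in seq_along(letters)) {
      l <- letters[i]
      cp <- compartments[i]
      if (is.na(l) || !l %in% rownames(sub)) next
      r <- if (cp %in% names(spec$rate)) spec$rate[[cp]] else 0
      if (runif(1L) < r)
        out[i] <- sample(colnames(sub), 1L, prob = sub[l, ])
    }
    out
  })
}

#' Random small alphabet model for decoder testing
#'
#' Builds a valid `AlphabetModel`-shaped object with `k` states: random
#' well-separated Gaussian descriptor means, random row-stochastic
#' transition matrix and initial distribution.  Used to compare Viterbi
#' decoding against exhaustive path enumeration.
#'
#' @param k number of states (2..27).
#' @param seed RNG seed.
#' @return an `AlphabetModel` (its letters are the first `k` of the
#'   canonical alphabet; class labels are placeholders).
#' @export
toy_alphabet_model <- function(k = 3L, seed = 1L) {
  stopifnot(k >= 2L, k <= 27L)
  with_seed(seed, {
    lets <- SA_LETTERS[seq_len(k)]
    mu <- matrix(runif(4L * k, 0, 10), k, 4L,
                 dimnames = list(lets, c("d1", "d2", "d3", "p4")))
    # push means apart so states are identifiable
    mu <- mu + 3 * matrix(seq_len(k), k, 4L)
    cov <- matrix(runif(4L * k, 0.3, 1.5), k, 4L)
    trans <- matrix(runif(k * k, 0.05, 1), k, k)
    trans <- trans / rowSums(trans)
    init <- runif(k, 0.05, 1)
    init <- init / sum(init)
    dimnames(trans) <- list(lets, lets)
    structure(list(letters = lets,
                   ss_class = setNames(rep("loop", k), lets),
                   mean = mu, cov = cov, cov_type = "diagonal",
                   transition = trans, initial = setNames(init, lets)),
              class = "AlphabetModel")
  })
}
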