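#' Decompose a C-alpha chain into overlapping four-residue fragments
#'
#' Sliding windows of four consecutive residues are formed within each
#' unbroken segment of the chain; windows never span a chain break, and
#' segments shorter than four residues yield no windows.  An unbroken chain
#' of `n` residues yields `n - 3` windows.
#'
#' @param chain a [CaChain] object.
#' @return integer vector of window start positions (index into the chain's
#'   residue list); each window covers positions `start .. start + 3`.
#' @export
fragmentize <- function(chain) {
  stopifnot(inherits(chain, "CaChain"))
  n <- nrow(chain$xyz)
  if (n < 4L) return(integer(0))
  # break at position i means discontinuity between residues i and i+1
  seg_id <- cumsum(c(1L, as.integer(seq_len(n - 1L) %in% chain$breaks)))
  starts <- integer(0)
  for (s in split(seq_len(n), seg_id)) {
    if (length(s) >= 4L) starts <- c(starts, s[seq_len(length(s) - 3L)])
  }
  starts
}

#' Four-descriptor geometry of a fragment
#'
#' A four-residue fragment with C-alpha positions `C1..C4` is described by
#' three distances and one oriented projection:
#' `d1 = |C3 - C1|`, `d2 = |C4 - C1|`, `d3 = |C4 - C2|`, and `p4`, the signed
#' distance of `C4` from the plane through `C1, C2, C3`, the sign taken along
#' the normal `(C2 - C1) x (C3 - C2)`.  Under this convention windows of a
#' right-handed alpha-helix have `p4 > 0`, and mirror reflection flips only
#' the sign of `p4`.
#'
#' @param window a 4 x 3 numeric matrix of C-alpha coordinates (Angstrom).
#' @return named numeric vector `c(d1, d2, d3, p4)`, or a vector of `NA`s
#'   (attribute `valid = FALSE`) when the first three points are collinear
#'   (triangle area below `1e-6` A^2) and the plane is undefined.
#' @export
compute_descriptors <- function(window) {
  stopifnot(is.matrix(window), nrow(window) == 4L, ncol(window) == 3L,
            all(is.finite(window)))
  d1 <- vnorm(window[3L, ] - window[1L, ])
  d2 <- vnorm(window[4L, ] - window[1L, ])
  d3 <- vnorm(window[4L, ] - window[2L, ])
  v1 <- window[2L, ] - window[1L, ]
  v2 <- window[3L, ] - window[2L, ]
  nvec <- cross3(v1, v2)
  area <- vnorm(nvec) / 2
  if (area <= 1e-6) {
    out <- setNames(rep(NA_real_, 4L), c("d1", "d2", "d3", "p4"))
    attr(out, "valid") <- FALSE
    return(out)
  }
  p4 <- sum((window[4L, ] - window[1L, ]) * nvec / vnorm(nvec))
  out <- c(d1 = d1, d2 = d2, d3 = d3, p4 = p4)
  attr(out, "valid") <- TRUE
  out
}

# log Gaussian emission densities: n x k matrix for n descriptor rows
emission_logdens <- function(desc, model) {
  k <- length(model$letters)
  n <- nrow(desc)
  out <- matrix(NA_real_, n, k, dimnames = list(NULL, model$letters))
  for (j in seq_len(k)) {
    if (model$cov_type == "diagonal") {
      v <- model$cov[j, ]
      dev <- sweep(desc, 2L, model$mean[j, ])
      out[, j] <- -0.5 * (sum(log(2 * pi * v)) +
                            rowSums(sweep(dev^2, 2L, v, "/")))
    } else {
      S <- model$cov[[j]]
      ch <- chol(S)
      dev <- sweep(desc, 2L, model$mean[j, ])
      q <- rowSums((dev %*% chol2inv(ch)) * dev)
      out[, j] <- -0.5 * (4 * log(2 * pi) + 2 * sum(log(diag(ch))) + q)
    }
  }
  out
}

#' Viterbi decoding of descriptor sequences
#'
#' Finds the maximum-a-posteriori letter path for a sequence of descriptor
#' vectors under the model's Gaussian emissions and Markov transition/initial
#' probabilities, computed in log space.  Ties are broken toward the earlier
#' letter in the model's canonical order.  Rows with any non-finite
#' descriptor split the sequence into runs that are decoded independently;
#' those rows receive `NA`.
#'
#' @param descriptors numeric matrix with columns `d1, d2, d3, p4`, one row
#'   per fragment.
#' @param model an [AlphabetModel][load_alphabet_model].
#' @return character vector of letters, `NA` at invalid fragments.
#' @export
viterbi_encode <- function(descriptors, model) {
  validate_alphabet_model(model)
  desc <- as.matrix(descriptors)
  if (ncol(desc) != 4L) stop("descriptors must have 4 columns")
  n <- nrow(desc)
  out <- rep(NA_character_, n)
  valid <- apply(desc, 1L, function(r) all(is.finite(r)))
  if (!any(valid)) return(out)
  runs <- split(which(valid), cumsum(!valid)[valid])
  logA <- log(model$transition)
  logpi <- log(model$initial)
  for (idx in runs) {
    ld <- emission_logdens(desc[idx, , drop = FALSE], model)
    m <- length(idx)
    k <- length(model$letters)
    delta <- matrix(-Inf, m, k)
    back <- matrix(NA_integer_, m, k)
    delta[1L, ] <- logpi + ld[1L, ]
    if (m > 1L) for (t in 2:m) {
      for (j in seq_len(k)) {
        cand <- delta[t - 1L, ] + logA[, j]
        b <- which.max(cand)          # first max = earlier letter on ties
        back[t, j] <- b
        delta[t, j] <- cand[b] + ld[t, j]
      }
    }
    path <- integer(m)
    path[m] <- which.max(delta[m, ])
    if (m > 1L) for (t in (m - 1L):1L) path[t] <- back[t + 1L, path[t + 1L]]
    out[idx] <- model$letters[path]
  }
  out
}

#' Encode a chain into its structural sequence
#'
#' Fragments the chain, computes descriptors, Viterbi-decodes the letter
#' string, and maps letters back onto residues: within each unbroken segment
#' the residue at (1-based) segment position `r` (for `3 <= r <= n - 1`)
#' carries the letter of the fragment spanning positions `r - 2 .. r + 1`.
#' The first two and the last residue of every segment carry no letter.
#'
#' @inheritParams fragmentize
#' @param model an [AlphabetModel][load_alphabet_model]; default the shipped
#'   synthetic model.
#' @return an object of class `StructuralSequence`: list with `chain_id`,
#'   `keys` (residue identity data frame), `fragments` (data frame of window
#'   start, descriptors, letter), and `residue_letters` (character vector
#'   aligned with the chain's residues, `NA` where no letter applies).
#' @export
assign_letters <- function(chain, model = default_alphabet_model()) {
  stopifnot(inherits(chain, "CaChain"))
  starts <- fragmentize(chain)
  n <- nrow(chain$xyz)
  res_letters <- rep(NA_character_, n)
  frag <- data.frame(start = integer(0), d1 = numeric(0), d2 = numeric(0),
                     d3 = numeric(0), p4 = numeric(0),
                     letter = character(0))
  if (length(starts)) {
    desc <- t(vapply(starts, function(s) {
      d <- compute_descriptors(chain$xyz[s:(s + 3L), , drop = FALSE])
      as.numeric(d)
    }, numeric(4L)))
    colnames(desc) <- c("d1", "d2", "d3", "p4")
    letters <- viterbi_encode(desc, model)
    frag <- data.frame(start = starts, desc, letter = letters,
                       stringsAsFactors = FALSE)
    # fragment starting at s covers s..s+3; its letter is attributed to the
    # residue at position s+2 (the third residue of the window)
    res_letters[starts + 2L] <- letters
  }
  structure(list(chain_id = chain$chain_id, keys = chain$keys,
                 aa = chain$aa, fragments = frag,
                 residue_letters = res_letters),
            class = "StructuralSequence")
}

#' @export
print.StructuralSequence <- function(x, ...) {
  cat("StructuralSequence: chain", x$chain_id, "-",
      nrow(x$fragments), "fragments over", length(x$residue_letters),
      "residues\n")
  lets <- x$fragments$letter
  lets[is.na(lets)] <- "-"
  cat(paste(lets, collapse = ""), "\n")
  invisible(x)
}

#' Percent identity between two aligned structural sequences
#'
#' Computed as `100 * matches / comparable columns`, where comparable columns
#' are the aligned positions at which both strings carry a letter (gap
#' characters `-` and `.` are skipped).
#'
#' @param seq1,seq2 equal-length character strings (or character vectors of
#'   single letters), possibly containing gap characters.
#' @return percentage in `[0, 100]`; `NA` with a warning when there are no
#'   comparable columns.
#' @export
structural_identity <- function(seq1, seq2) {
  s1 <- if (length(seq1) == 1L) strsplit(seq1, "")[[1L]] else seq1
  s2 <- if (length(seq2) == 1L) strsplit(seq2, "")[[1L]] else seq2
  if (length(s1) != length(s2)) stop("sequences must have equal aligned length")
  gap <- c("-", ".")
  comparable <- !(s1 %in% gap) & !(s2 %in% gap) & !is.na(s1) & !is.na(s2)
  if (!any(comparable)) {
    warning("no comparable columns; identity undefined")
    return(NA_real_)
  }
  100 * sum(s1[comparable] == s2[comparable]) / sum(comparable)
}
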