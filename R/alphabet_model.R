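#' The 27 structural letters and their secondary-structure classes
#'
#' The alphabet names its letters `A`..`Z` plus lower-case `a`.  Four letters
#' describe alpha-helix conformations, five describe beta-strands, thirteen
#' describe loops, and five describe the transitional borders of helices and
#' strands.
#'
#' @format `SA_LETTERS` is a character vector of length 27 in canonical order.
#'   `SA_CLASSES` is a named character vector mapping each letter to one of
#'   `"helix"`, `"strand"`, `"loop"`, `"helix_border"`, `"strand_border"`.
#' @export
SA_LETTERS <- c(LETTERS, "a")

#' @rdname SA_LETTERS
#' @export
SA_CLASSES <- local({
  cls <- setNames(rep("loop", 27L), c(LETTERS, "a"))
  cls[c("a", "A", "V", "W")] <- "helix"
  cls[c("L", "M", "N", "T", "X")] <- "strand"
  cls[c("Z", "B", "C")] <- "helix_border"
  cls[c("J", "K")] <- "strand_border"
  cls
})

#' Letter groups defined by compartment preference
#'
#' Letters preferentially found on the protein surface, in the core, outside
#' interfaces, or at interfaces.  Letters `W` and `X` show no clear preference
#' and belong to no group.
#'
#' @format A named list with elements `surface`, `core`, `non_interface`,
#'   `interface`.
#' @export
LETTER_GROUPS <- list(
  surface       = c("a", "V", "L", "P", "H", "Y", "D", "U", "F", "B", "K"),
  core          = c("A", "T", "M", "N", "G", "R", "O", "I", "S", "E", "Q",
                    "Z", "C", "J"),
  non_interface = c("a", "N", "D"),
  interface     = "F"
)

#' Secondary-structure class of a structural letter
#'
#' @param letter character vector of letters from the 27-letter alphabet.
#' @param border_umbrella if `TRUE`, both border kinds are reported as the
#'   umbrella class `"border"`.
#' @return character vector of class labels.
#' @examples
#' ss_class("a")            # "helix"
#' ss_class("L")            # "strand"
#' ss_class("Z", border_umbrella = TRUE)  # "border"
#' @export
ss_class <- function(letter, border_umbrella = FALSE) {
  bad <- !letter %in% SA_LETTERS
  if (any(bad))
    stop("unknown structural letter(s): ", paste(letter[bad], collapse = ", "))
  cls <- unname(SA_CLASSES[letter])
  if (border_umbrella) cls[grepl("_border$", cls)] <- "border"
  cls
}

#' Load and validate a structural-alphabet model
#'
#' The model file is JSON with keys `letters`, `ss_class`, `emission`
#' (`mean`: 27 x 4, `cov`: 27 x 4 diagonal variances or a list of 4 x 4
#' matrices), `transition` (27 x 27 row-stochastic) and `initial` (27
#' probabilities).  Emissions are multivariate Gaussians on the descriptor
#' vector (d1, d2, d3, p4).
#'
#' @param path path to a JSON model file.
#' @return an object of class `AlphabetModel`: a list with elements
#'   `letters`, `ss_class`, `mean` (matrix letters x 4), `cov` (matrix of
#'   diagonal variances or list of full matrices), `cov_type`
#'   (`"diagonal"` or `"full"`), `transition`, `initial`.
#' @seealso [default_alphabet_model()] for the model shipped with the package.
#' @export
load_alphabet_model <- function(path) {
  if (!file.exists(path)) stop("model file not found: ", path)
  raw <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  letters <- as.character(raw$letters)
  mu <- as.matrix(raw$emission$mean)
  cov <- raw$emission$cov
  cov_type <- "diagonal"
  if (is.list(cov) && !is.data.frame(cov)) {
    cov_type <- "full"
    cov <- lapply(cov, function(m) matrix(as.numeric(unlist(m)), 4L, 4L))
  } else {
    cov <- as.matrix(cov)
  }
  model <- structure(list(
    letters    = letters,
    ss_class   = setNames(as.character(unlist(raw$ss_class[letters])), letters),
    mean       = structure(mu, dimnames = list(letters, c("d1", "d2", "d3", "p4"))),
    cov        = cov,
    cov_type   = cov_type,
    transition = structure(as.matrix(raw$transition),
                           dimnames = list(letters, letters)),
    initial    = setNames(as.numeric(raw$initial), letters)
  ), class = "AlphabetModel")
  validate_alphabet_model(model)
  model
}

#' @rdname load_alphabet_model
#' @param model an `AlphabetModel` object.
#' @export
validate_alphabet_model <- function(model) {
  stopifnot(inherits(model, "AlphabetModel"))
  n <- length(model$letters)
  if (anyDuplicated(model$letters)) stop("duplicate letters in model")
  if (n == 27L) {
    if (!setequal(model$letters, SA_LETTERS))
      stop("a 27-letter model must use the canonical alphabet [A-Z,a]")
    sizes <- table(factor(model$ss_class,
                          levels = c("helix", "strand", "loop",
                                     "helix_border", "strand_border")))
    if (!all(sizes == c(4L, 5L, 13L, 3L, 2L)))
      stop("class partition must be 4 helix / 5 strand / 13 loop / ",
           "3 helix-border / 2 strand-border letters")
  }
  if (!is.matrix(model$mean) || nrow(model$mean) != n || ncol(model$mean) != 4L)
    stop("emission means must be a ", n, " x 4 matrix")
  if (!all(is.finite(model$mean))) stop("non-finite emission means")
  if (model$cov_type == "diagonal") {
    if (!all(dim(model$cov) == c(n, 4L)) || any(model$cov <= 0))
      stop("diagonal covariances must be a ", n, " x 4 matrix of positive variances")
  } else {
    ok <- vapply(model$cov, function(m) {
      all(dim(m) == c(4L, 4L)) && all(eigen(m, symmetric = TRUE,
                                            only.values = TRUE)$values > 0)
    }, logical(1))
    if (length(model$cov) != n || !all(ok))
      stop("full covariances must be ", n, " positive-definite 4 x 4 matrices")
  }
  if (!all(dim(model$transition) == c(n, n)))
    stop("transition matrix must be ", n, " x ", n)
  if (any(model$transition < 0) ||
      any(abs(rowSums(model$transition) - 1) > 1e-6))
    stop("transition rows must be non-negative and sum to 1")
  if (length(model$initial) != n || any(model$initial < 0) ||
      abs(sum(model$initial) - 1) > 1e-6)
    stop("initial probabilities must be non-negative and sum to 1")
  invisible(model)
}

#' @rdname load_alphabet_model
#' @details
#' `default_alphabet_model()` loads the model shipped under
#' `inst/extdata/sa27_model_synthetic.json`.  Its descriptor prototype means
#' are a synthetic reconstruction built from idealized helix and strand
#' geometry plus loop prototypes spanning the descriptor space; the published
#' estimates of the alphabet's emission and transition parameters are not
#' redistributed with this package.  The synthetic model uses a shared
#' isotropic emission variance (0.5 A^2) and within-class-biased transitions,
#' so decoding behaves like regularized nearest-prototype assignment.
#' @export
default_alphabet_model <- function() {
  load_alphabet_model(system.file("extdata", "sa27_model_synthetic.json",
                                  package = "sadef", mustWork = TRUE))
}
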