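# internal helpers shared across modules

# Evaluate `expr` under a temporary RNG state seeded with `seed`; the caller's
# global RNG stream is untouched.  seed = NULL runs expr as-is.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

vnorm <- function(v) sqrt(sum(v * v))

cross3 <- function(a, b) {
  c(a[2L] * b[3L] - a[3L] * b[2L],
    a[3L] * b[1L] - a[1L] * b[3L],
    a[1L] * b[2L] - a[2L] * b[1L])
}

# pairwise squared distances between rows of two matrices (n x 3, m x 3)
cross_dist2 <- function(x, y) {
  outer(rowSums(x^2), rep(1, nrow(y))) +
    outer(rep(1, nrow(x)), rowSums(y^2)) - 2 * tcrossprod(x, y)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

write_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# three-to-one amino-acid code map (standard residues plus common variants
# mapped to their parent residue for geometry purposes)
AA3TO1 <- c(
  ALA = "A", ARG = "R", ASN = "N", ASP = "D", CYS = "C", GLN = "Q",
  GLU = "E", GLY = "G", HIS = "H", ILE = "I", LEU = "L", LYS = "K",
  MET = "M", PHE = "F", PRO = "P", SER = "S", THR = "T", TRP = "W",
  TYR = "Y", VAL = "V",
  MSE = "M", SEC = "C", PYL = "K", HYP = "P", SEP = "S", TPO = "T",
  PTR = "Y"
)

STANDARD_AA3 <- names(AA3TO1)[1:20]

aa_three_to_one <- function(resid) {
  out <- AA3TO1[toupper(resid)]
  out[is.na(out)] <- "X"
  unname(out)
}
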