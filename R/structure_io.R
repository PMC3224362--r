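#' Read a PDB coordinate file into a two-chain complex structure
#'
#' Parsing is delegated to [bio3d::read.pdb()]; this wrapper applies the
#' package's record policy and builds per-chain C-alpha traces:
#' * altloc duplicates keep the highest-occupancy record (ties: first in
#'   file order);
#' * `HETATM` residues are excluded from the C-alpha traces but can be kept
#'   for surface-area calculations via `keep_hetatm = TRUE`;
#' * multi-model files use the model selected by `model_index` (default the
#'   first);
#' * chains without any C-alpha atom are dropped with a warning;
#' * non-standard residues with a known parent amino acid (e.g. MSE) are
#'   mapped to the parent for composition purposes but keep their geometry.
#'
#' @param path path to a PDB-format text file.
#' @param pair optional character vector of two chain identifiers marking the
#'   interface of interest; defaults to the first two chains in the file.
#' @param model_index which model of a multi-model file to use.
#' @param keep_hetatm keep HETATM (non-water) atoms in the atom table.
#' @return an object of class `ComplexStructure`: list with `atoms` (data
#'   frame of kept atom records), `chains` (named list of [CaChain]) and
#'   `pair` (the two chain ids of interest, or fewer for monomers).
#' @export
read_pdb <- function(path, pair = NULL, model_index = 1L,
                     keep_hetatm = FALSE) {
  pdb <- bio3d::read.pdb(path, multi = FALSE, rm.alt = FALSE, verbose = FALSE)
  at <- pdb$atom
  if (model_index != 1L) {
    pdbm <- bio3d::read.pdb(path, multi = TRUE, rm.alt = FALSE, verbose = FALSE)
    nmod <- nrow(pdbm$xyz)
    if (model_index > nmod) stop("model_index ", model_index,
                                 " but file has ", nmod, " model(s)")
    xyz <- matrix(pdbm$xyz[model_index, ], ncol = 3L, byrow = TRUE)
    at$x <- xyz[, 1L]; at$y <- xyz[, 2L]; at$z <- xyz[, 3L]
  }
  if (!nrow(at) || !any(at$type == "ATOM")) stop("no ATOM records in ", path)
  if (!keep_hetatm) at <- at[at$type == "ATOM", , drop = FALSE]
  at <- at[!(at$resid %in% c("HOH", "WAT", "DOD")), , drop = FALSE]
  at$insert[is.na(at$insert)] <- ""
  at$alt[is.na(at$alt)] <- ""
  at$o[is.na(at$o)] <- 1
  # altloc policy: within (chain, resno, insert, atom name) keep the highest
  # occupancy record; ties resolved by file order
  key <- paste(at$chain, at$resno, at$insert, at$elety, sep = "\r")
  ord <- order(factor(key, levels = unique(key)), -at$o,
               seq_len(nrow(at)))
  at <- at[ord, , drop = FALSE]
  at <- at[!duplicated(paste(at$chain, at$resno, at$insert, at$elety,
                             sep = "\r")), , drop = FALSE]
  at <- at[order(match(paste(at$chain, at$resno, at$insert, sep = "\r"),
                       unique(paste(at$chain, at$resno, at$insert,
                                    sep = "\r")))), , drop = FALSE]
  if (any(!is.finite(c(at$x, at$y, at$z)))) stop("non-finite coordinates")
  atoms <- data.frame(
    chain_id = at$chain, residue_number = at$resno,
    insertion_code = at$insert, residue_name = at$resid,
    atom_name = at$elety,
    element = ifelse(is.na(at$elesy) | at$elesy == "",
                     substr(gsub("[0-9']", "", at$elety), 1L, 1L), at$elesy),
    x = at$x, y = at$y, z = at$z, occupancy = at$o,
    altloc = at$alt, record = at$type,
    stringsAsFactors = FALSE)
  chains <- list()
  for (ch in unique(atoms$chain_id)) {
    sub <- atoms[atoms$chain_id == ch & atoms$record == "ATOM", , drop = FALSE]
    ca <- sub[sub$atom_name == "CA", , drop = FALSE]
    if (!nrow(ca)) {
      warning("chain ", ch, " has no C-alpha atoms; dropped")
      next
    }
    chains[[ch]] <- new_ca_chain(
      chain_id = ch,
      keys = data.frame(chain_id = ca$chain_id,
                        residue_number = ca$residue_number,
                        insertion_code = ca$insertion_code,
                        stringsAsFactors = FALSE),
      aa = aa_three_to_one(ca$residue_name),
      xyz = as.matrix(ca[, c("x", "y", "z")]))
  }
  if (!length(chains)) stop("no usable protein chains in ", path)
  if (is.null(pair)) pair <- head(names(chains), 2L)
  if (length(pair) == 2L) {
    if (pair[1L] == pair[2L]) stop("pair chains must be distinct")
    missing <- setdiff(pair, names(chains))
    if (length(missing)) stop("pair chain(s) not in file: ",
                              paste(missing, collapse = ", "))
  }
  structure(list(atoms = atoms, chains = chains, pair = pair),
            class = "ComplexStructure")
}

# CaChain constructor: records breaks and validates step distances
new_ca_chain <- function(chain_id, keys, aa, xyz) {
  xyz <- as.matrix(xyz)
  stopifnot(nrow(xyz) >= 1L, ncol(xyz) == 3L, all(is.finite(xyz)))
  dimnames(xyz) <- NULL
  chain <- structure(list(chain_id = chain_id, keys = keys, aa = aa,
                          xyz = xyz, breaks = integer(0)),
                     class = "CaChain")
  chain$breaks <- detect_breaks(chain)
  chain
}

#' Detect discontinuities in a C-alpha trace
#'
#' A break is recorded between consecutive residues whose C-alpha distance
#' falls outside the peptide-bond-compatible window of 2.5 to 4.5 Angstrom.
#' Author-numbering jumps alone do not break the chain: the distance
#' criterion governs (a renumbered but geometrically continuous chain stays
#' whole).
#'
#' @param chain a [CaChain] (or list with an `xyz` matrix).
#' @return integer positions `i` meaning a break between residues `i` and
#'   `i + 1`.
#' @export
detect_breaks <- function(chain) {
  xyz <- chain$xyz
  n <- nrow(xyz)
  if (n < 2L) return(integer(0))
  d <- sqrt(rowSums((xyz[-1L, , drop = FALSE] - xyz[-n, , drop = FALSE])^2))
  which(d < 2.5 | d > 4.5)
}

#' @export
print.CaChain <- function(x, ...) {
  cat("CaChain", x$chain_id, "-", nrow(x$xyz), "residues,",
      length(x$breaks), "break(s)\n")
  invisible(x)
}

#' @export
print.ComplexStructure <- function(x, ...) {
  cat("ComplexStructure:", length(x$chains), "chain(s) [",
      paste(names(x$chains), collapse = ","), "], pair of interest:",
      paste(x$pair, collapse = "-"), "\n")
  invisible(x)
}

#' Write structural sequences as FASTA-like records
#'
#' One record per sequence, header `>id_chain`, body the fragment letter
#' string; segments separated by chain breaks are joined with `-` markers and
#' fragments without a letter (invalid geometry) are written as `-`.
#'
#' @param sequences a list of [StructuralSequence][assign_letters] objects
#'   (or a single one).
#' @param path output file path.
#' @param id record identifier prefix (recycled), e.g. a PDB id.
#' @return the path, invisibly.
#' @export
write_structural_fasta <- function(sequences, path, id = "struct") {
  if (inherits(sequences, "StructuralSequence")) sequences <- list(sequences)
  id <- rep_len(id, max(1L, length(sequences)))
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_along(sequences)) {
    s <- sequences[[i]]
    body <- structural_sequence_string(s)
    writeLines(c(paste0(">", id[i], "_", s$chain_id), body), con)
  }
  invisible(path)
}

# fragment letter string with '-' between discontinuous segments and at
# letterless fragments
structural_sequence_string <- function(s) {
  fr <- s$fragments
  if (!nrow(fr)) return("")
  lets <- fr$letter
  lets[is.na(lets)] <- "-"
  gap_after <- diff(fr$start) > 1L   # non-adjacent windows => segment gap
  out <- lets[1L]
  for (i in seq_along(gap_after)) {
    if (gap_after[i]) out <- paste0(out, "-")
    out <- paste0(out, lets[i + 1L])
  }
  out
}

#' Write a complex (or single chain) as PDB-format text
#'
#' Serializes the atom table of a [ComplexStructure][read_pdb] (or the
#' C-alpha pseudo-atoms of a [CaChain]) through [bio3d::write.pdb()].
#'
#' @param x a `ComplexStructure` or `CaChain`.
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_pdb_file <- function(x, path) {
  if (inherits(x, "CaChain")) x <- chain_as_complex(x)
  a <- x$atoms
  bio3d::write.pdb(
    file = path,
    xyz = as.numeric(t(as.matrix(a[, c("x", "y", "z")]))),
    type = a$record, resno = a$residue_number, resid = a$residue_name,
    insert = ifelse(a$insertion_code == "", "", a$insertion_code),
    chain = a$chain_id, elety = a$atom_name, o = a$occupancy,
    elesy = a$element)
  invisible(path)
}

# promote a bare CaChain to a one-chain ComplexStructure with CA pseudo-atoms
chain_as_complex <- function(chain) {
  aa3 <- names(AA3TO1)[match(chain$aa, AA3TO1)]
  aa3[is.na(aa3)] <- "GLY"
  atoms <- data.frame(
    chain_id = chain$keys$chain_id, residue_number = chain$keys$residue_number,
    insertion_code = chain$keys$insertion_code, residue_name = aa3,
    atom_name = "CA", element = "C",
    x = chain$xyz[, 1L], y = chain$xyz[, 2L], z = chain$xyz[, 3L],
    occupancy = 1, altloc = "", record = "ATOM",
    stringsAsFactors = FALSE)
  structure(list(atoms = atoms,
                 chains = setNames(list(chain), chain$chain_id),
                 pair = chain$chain_id),
            class = "ComplexStructure")
}
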