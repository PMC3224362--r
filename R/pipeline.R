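#' Pipeline configuration
#'
#' Collects every tunable threshold of the analysis in one object.  Defaults
#' are the study's conventions: water-probe radius 1.4 A, interface defined
#' by a loss of more than 1 percentage point of relative accessibility upon
#' association, burial below 5% exposure, equality tolerance 0.05 points,
#' alpha 0.05 with two-sided Bonferroni correction.
#'
#' @param model_path path to an alphabet model JSON (default: the shipped
#'   synthetic model).
#' @param probe probe radius, Angstrom.
#' @param interface_threshold accessibility-loss threshold, points.
#' @param burial_threshold exposure threshold separating core from surface,
#'   percent.
#' @param tol equality tolerance, points.
#' @param alpha significance level.
#' @param bonferroni_sided `"two"` or `"one"`.
#' @param n_points surface sampling points per atom.
#' @param seed base RNG seed for any stochastic stage.
#' @return a `PipelineConfig` list.
#' @export
pipeline_config <- function(model_path = NULL, probe = 1.4,
                            interface_threshold = 1.0,
                            burial_threshold = 5.0, tol = 0.05,
                            alpha = 0.05, bonferroni_sided = "two",
                            n_points = 960L, seed = 1L) {
  stopifnot(probe >= 0, interface_threshold > 0, burial_threshold > 0,
            tol > 0, alpha > 0, alpha < 1)
  structure(list(model_path = model_path, probe = probe,
                 interface_threshold = interface_threshold,
                 burial_threshold = burial_threshold, tol = tol,
                 alpha = alpha, bonferroni_sided = bonferroni_sided,
                 n_points = as.integer(n_points), seed = as.integer(seed)),
            class = "PipelineConfig")
}

#' @rdname pipeline_config
#' @param path YAML file with any subset of the configuration fields.
#' @export
read_pipeline_config <- function(path) {
  vals <- yaml::read_yaml(path)
  do.call(pipeline_config, vals)
}

#' Run the full analysis pipeline on a two-chain complex
#'
#' Orchestrates encode -> compartments -> counts -> statistics on a bound
#' complex and, when an unbound structure is supplied, the deformation
#' analysis (transition counts, deformation proportions, interface-minus-
#' surface differences, exposure differences, Kabsch RMSD).  All outputs are
#' returned and, when `out_dir` is given, also written as TSV tables plus a
#' YAML run manifest; re-running with the same configuration reproduces the
#' outputs exactly.
#'
#' @param bound a [ComplexStructure][read_pdb] (or path to a PDB file).
#' @param unbound optional [CaChain] (or PDB path, first chain of the pair
#'   taken) with the unbound conformation of `chain_id`.
#' @param chain_id chain to analyse; default the first of the bound pair.
#' @param config a [pipeline_config()].
#' @param out_dir optional output directory.
#' @return a list of result objects (structural sequences, accessibility
#'   table, count table, KLd / Z-score / ordination / preferential
#'   percentages, and a `deformation` sub-list when `unbound` is given).
#' @export
run_pipeline <- function(bound, unbound = NULL, chain_id = NULL,
                         config = pipeline_config(), out_dir = NULL) {
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("[", name, "] ", conditionMessage(e), call. = FALSE))
  }
  model <- stage("model", {
    if (is.null(config$model_path)) default_alphabet_model()
    else load_alphabet_model(config$model_path)
  })
  if (is.character(bound)) bound <- stage("read", read_pdb(bound))
  chain_id <- chain_id %||% bound$pair[1L]

  seqs <- stage("encode", lapply(bound$chains, assign_letters, model = model))
  acc <- stage("compartments", do.call(rbind, lapply(
    intersect(bound$pair, names(bound$chains)), function(ch)
      accessibility_contexts(bound, ch, probe = config$probe,
                             n_points = config$n_points,
                             interface_threshold = config$interface_threshold,
                             burial_threshold = config$burial_threshold,
                             tol = config$tol))))
  counts <- stage("counts", count_letters(seqs, acc))
  observed <- rownames(counts)[rowSums(counts) > 0]
  stats <- stage("stats", {
    usable <- observed[vapply(observed, function(l)
      all(class_profile(counts, l)$freq > 0), logical(1L))]
    list(kld = if (length(usable)) kld(counts, usable, config$alpha),
         zscore = if (length(usable))
           zscore(counts, usable, "interface", "surface"),
         ca = tryCatch(correspondence_analysis(
           counts[rowSums(counts) > 0, , drop = FALSE]),
           error = function(e) NULL),
         pca = pca_descriptors(model$mean),
         preferential = {
           cls <- unique(ss_class(observed, border_umbrella = TRUE))
           do.call(rbind, lapply(cls, function(cl) data.frame(
             class = cl,
             interface = preferential_pct(counts, cl, "interface"),
             surface = preferential_pct(counts, cl, "surface"),
             core = preferential_pct(counts, cl, "core"),
             all = preferential_pct(counts, cl, "all"))))
         })
  })
  out <- list(model = model, sequences = seqs, accessibility = acc,
              counts = counts, stats = stats, config = config)

  if (!is.null(unbound)) {
    out$deformation <- stage("deform", {
      if (is.character(unbound)) {
        ub <- read_pdb(unbound)
        unbound <- ub$chains[[ub$pair[1L]]]
      }
      bchain <- bound$chains[[chain_id]]
      map <- pair_chains(unbound, bchain)
      useq <- assign_letters(unbound, model)
      bseq <- seqs[[chain_id]]
      C <- transition_counts(map, useq, bseq,
                             acc[acc$chain_id == chain_id, , drop = FALSE])
      P_int <- deformation_proportions(C$interface)
      P_surf <- deformation_proportions(C$surface)
      ub_acc <- accessibility_contexts(chain_as_complex(unbound),
                                       probe = config$probe,
                                       n_points = config$n_points)
      bd_acc <- accessibility_contexts(chain_as_complex(bchain),
                                       probe = config$probe,
                                       n_points = config$n_points)
      idx <- !is.na(useq$residue_letters[map$pos_unbound]) &
        !is.na(bseq$residue_letters[map$pos_bound])
      defpos <- data.frame(
        pos_unbound = map$pos_unbound[idx], pos_bound = map$pos_bound[idx],
        letter_unbound = useq$residue_letters[map$pos_unbound[idx]],
        letter_bound = bseq$residue_letters[map$pos_bound[idx]])
      defpos <- defpos[defpos$letter_unbound != defpos$letter_bound, ,
                       drop = FALSE]
      expo <- if (nrow(defpos))
        exposure_difference(defpos, ub_acc$a_chain, bd_acc$a_chain)
      list(map = map, seq_unbound = useq, counts = C,
           P_interf = P_int, P_surf = P_surf,
           delta_p = delta_p(P_int, P_surf),
           exposure = expo,
           straight_shift = straight_letter_shift(useq, bseq),
           rmsd = kabsch_rmsd(unbound$xyz[map$pos_unbound, , drop = FALSE],
                              bchain$xyz[map$pos_bound, , drop = FALSE]))
    })
  }

  if (!is.null(out_dir)) stage("write", write_pipeline_outputs(out, out_dir))
  out
}

# serialize pipeline results as TSV tables + manifest
write_pipeline_outputs <- function(out, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  write_structural_fasta(unname(out$sequences),
                         file.path(out_dir, "structural_sequences.fasta"),
                         id = "chain")
  write_tsv(out$accessibility, file.path(out_dir, "compartments.tsv"))
  counts_df <- data.frame(letter = rownames(out$counts),
                          unclass(out$counts), check.names = FALSE)
  write_tsv(counts_df, file.path(out_dir, "letter_counts.tsv"))
  if (!is.null(out$stats$kld))
    write_tsv(out$stats$kld, file.path(out_dir, "kld.tsv"))
  if (!is.null(out$stats$zscore))
    write_tsv(out$stats$zscore, file.path(out_dir, "zscore.tsv"))
  if (!is.null(out$stats$preferential))
    write_tsv(out$stats$preferential,
              file.path(out_dir, "preferential_pct.tsv"))
  if (!is.null(out$deformation)) {
    long <- function(M) {
      df <- as.data.frame(as.table(M), stringsAsFactors = FALSE)
      names(df) <- c("sl1", "sl2", "value")
      df[!is.na(df$value) & df$value != 0, ]
    }
    for (cp in names(out$deformation$counts))
      write_tsv(long(out$deformation$counts[[cp]]),
                file.path(out_dir, paste0("transitions_", cp, ".tsv")))
    write_tsv(long(out$deformation$delta_p),
              file.path(out_dir, "delta_p.tsv"))
    if (!is.null(out$deformation$exposure))
      write_tsv(out$deformation$exposure$aggregates,
                file.path(out_dir, "exposure_aggregates.tsv"))
  }
  manifest <- out$config
  class(manifest) <- NULL
  manifest$package_version <- as.character(utils::packageVersion("sadef"))
  manifest$r_version <- R.version.string
  yaml::write_yaml(manifest, file.path(out_dir, "manifest.yaml"))
  invisible(out_dir)
}
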