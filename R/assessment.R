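# Ranking of predicted kinase models by activation-loop pLDDT and
# benchmarking against reference structures: sequence-correspondence
# superposition of the C-terminal domain followed by no-refit RMSD over the
# activation-loop backbone (N, CA, C, O).

#' Minimum and mean pLDDT over the activation loop
#'
#' Per-residue pLDDT is read from the CA atom's B-factor (model files write
#' the same value to every atom of a residue). Refuses chains not flagged
#' as models, since experimental B-factors are not confidences.
#'
#' @param chain A `kin_chain` with `is_model = TRUE`.
#' @param annotation A `kin_annotation` (activation-loop span).
#' @return Named numeric `c(min=, mean=)`.
#' @export
min_plddt_activation_loop <- function(chain, annotation) {
  stopifnot(inherits(chain, "kin_chain"))
  if (!isTRUE(chain$is_model)) {
    stop("chain '", chain$entry_id, "' is not flagged as a model: ",
         "B-factors of experimental structures are not pLDDT values")
  }
  ords <- activation_loop_ordinals(annotation)
  vals <- vapply(ords, function(o) {
    a <- get_atom(chain, o, "CA")
    if (is.null(a)) NA_real_ else a$b
  }, numeric(1))
  vals <- vals[!is.na(vals)]
  if (length(vals) == 0) stop("no activation-loop residues with CA atoms")
  c(min = min(vals), mean = mean(vals))
}

#' Score one model chain
#'
#' Convenience constructor of the per-model score record used by
#' [rank_models()].
#'
#' @param chain A model `kin_chain`.
#' @param annotation A `kin_annotation`.
#' @param rmsd_al Optional activation-loop RMSD versus a reference.
#' @param classification Optional `kin_conformation` for the model; when
#'   omitted it is computed from the chain.
#' @param model_id Identifier; defaults to the chain's entry id.
#' @return A one-row data.frame (`model_id`, `min_plddt_al`,
#'   `mean_plddt_al`, `rmsd_al`, `n_al_residues`, `active`).
#' @export
score_model <- function(chain, annotation, rmsd_al = NA_real_,
                        classification = NULL,
                        model_id = chain$entry_id) {
  pl <- min_plddt_activation_loop(chain, annotation)
  if (is.null(classification)) {
    classification <- classify(chain, annotation)
  }
  data.frame(
    model_id = model_id,
    min_plddt_al = pl[["min"]], mean_plddt_al = pl[["mean"]],
    rmsd_al = rmsd_al,
    n_al_residues = length(activation_loop_ordinals(annotation)),
    active = classification$active,
    stringsAsFactors = FALSE
  )
}

#' Rank model scores by activation-loop pLDDT
#'
#' Descending by the minimum pLDDT over the activation loop; ties broken by
#' mean pLDDT (descending) then by model id. With `require_active`, models
#' whose active verdict is not `"true"` are excluded before ranking (a
#' warning is emitted when nothing survives).
#'
#' @param scores data.frame as rows from [score_model()] (columns
#'   `model_id`, `min_plddt_al`, `mean_plddt_al`, optionally `active`).
#' @param require_active Exclude non-active models first.
#' @return The reordered (possibly filtered) data.frame.
#' @export
rank_models <- function(scores, require_active = FALSE) {
  stopifnot(is.data.frame(scores), nrow(scores) >= 1)
  if (require_active) {
    keep <- !is.na(scores$active) & scores$active == "true"
    scores <- scores[keep, , drop = FALSE]
    if (nrow(scores) == 0) {
      warning("no models with active == 'true'; returning empty ranking")
      return(scores)
    }
  }
  ord <- order(-scores$min_plddt_al, -scores$mean_plddt_al,
               scores$model_id)
  out <- scores[ord, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Residue correspondence between a model and a reference chain
#'
#' Aligns the two sequences globally (Needleman-Wunsch via
#' \pkg{Biostrings}) and derives (a) the C-terminal-domain pair set used
#' for superposition: aligned residues from the residue after the APE Glu
#' to the chain end, plus the catalytic-loop block from 10 residues before
#' the HRD His through the XHRD residue, restricted to pairs with CA atoms
#' on both sides, activation-loop residues always excluded; and (b) the
#' activation-loop pair set restricted to pairs where both partners have
#' complete N, CA, C, O backbone.
#'
#' @param model_chain,reference_chain `kin_chain` objects.
#' @param annotation_model,annotation_ref Their `kin_annotation`s.
#' @param min_identity Minimum sequence identity (matches over alignment
#'   columns) below which an error asks for an explicit map. Default 0.9.
#' @param ctd_ordinals_model Optional explicit model ordinals for the
#'   superposition set, overriding the default C-terminal-domain rule.
#' @return List with `ctd` and `loop` data.frames (`model_ord`, `ref_ord`)
#'   and `identity`.
#' @export
build_correspondence <- function(model_chain, reference_chain,
                                 annotation_model, annotation_ref,
                                 min_identity = 0.9,
                                 ctd_ordinals_model = NULL) {
  sm <- chain_sequence(model_chain)
  sr <- chain_sequence(reference_chain)
  aln <- Biostrings::pairwiseAlignment(sm, sr, type = "global")
  ap <- strsplit(as.character(Biostrings::alignedPattern(aln)), "")[[1]]
  as_ <- strsplit(as.character(Biostrings::alignedSubject(aln)), "")[[1]]
  idy <- sum(ap == as_ & ap != "-") / length(ap)
  if (idy < min_identity) {
    stop(sprintf(paste0(
      "model/reference sequence identity %.2f below %.2f: supply an ",
      "explicit correspondence (ctd_ordinals_model and matching ",
      "reference numbering)"), idy, min_identity))
  }
  # aligned-column -> ordinals
  mo <- cumsum(ap != "-") - 1L
  ro <- cumsum(as_ != "-") - 1L
  both <- ap != "-" & as_ != "-"
  pairs <- data.frame(model_ord = mo[both], ref_ord = ro[both])

  loop_m <- activation_loop_ordinals(annotation_model)
  ctd_m <- if (!is.null(ctd_ordinals_model)) {
    ctd_ordinals_model
  } else {
    nres <- nrow(model_chain$residues)
    c(
      seq.int(max(0L, annotation_model$hrd_h - 10L), annotation_model$xhrd),
      if (annotation_model$al_end + 1L <= nres - 1L)
        seq.int(annotation_model$al_end + 1L, nres - 1L) else integer(0)
    )
  }
  ctd_m <- setdiff(ctd_m, loop_m)

  has_ca <- function(chain, o) !is.null(get_atom(chain, o, "CA"))
  has_bb <- function(chain, o) {
    all(vapply(c("N", "CA", "C", "O"),
               function(nm) !is.null(get_atom(chain, o, nm)), logical(1)))
  }
  ctd <- pairs[pairs$model_ord %in% ctd_m, , drop = FALSE]
  keep <- vapply(seq_len(nrow(ctd)), function(i)
    has_ca(model_chain, ctd$model_ord[i]) &&
      has_ca(reference_chain, ctd$ref_ord[i]), logical(1))
  ctd <- ctd[keep, , drop = FALSE]

  loop <- pairs[pairs$model_ord %in% loop_m, , drop = FALSE]
  keep <- vapply(seq_len(nrow(loop)), function(i)
    has_bb(model_chain, loop$model_ord[i]) &&
      has_bb(reference_chain, loop$ref_ord[i]), logical(1))
  loop <- loop[keep, , drop = FALSE]
  rownames(ctd) <- rownames(loop) <- NULL
  list(ctd = ctd, loop = loop, identity = idy)
}

.bb_coords <- function(chain, ordinals, atoms = c("N", "CA", "C", "O")) {
  do.call(rbind, lapply(ordinals, function(o) {
    do.call(rbind, lapply(atoms, function(nm) {
      a <- get_atom(chain, o, nm)
      if (is.null(a)) stop("missing ", nm, " at ordinal ", o) else a$xyz
    }))
  }))
}

#' Activation-loop backbone RMSD after C-terminal-domain superposition
#'
#' Kabsch-fits the model's C-terminal-domain CA atoms onto the reference's,
#' applies the transform to the model, and measures the no-refit RMSD over
#' the activation-loop backbone atoms (N, CA, C, O). The loop itself never
#' participates in the fit.
#'
#' @param model_chain,reference_chain `kin_chain` objects.
#' @param map Correspondence from [build_correspondence()].
#' @return List: `rmsd_al`, `rmsd_ctd` (fitted CA RMSD), `n_al_residues`,
#'   `n_ctd_residues`.
#' @export
activation_loop_rmsd <- function(model_chain, reference_chain, map) {
  if (nrow(map$ctd) < 3) stop("need at least 3 C-terminal-domain CA pairs")
  if (nrow(map$loop) < 1) stop("need at least 1 complete loop residue pair")
  m_ctd <- .bb_coords(model_chain, map$ctd$model_ord, "CA")
  r_ctd <- .bb_coords(reference_chain, map$ctd$ref_ord, "CA")
  fit <- kabsch_superpose(m_ctd, r_ctd)
  m_loop <- .bb_coords(model_chain, map$loop$model_ord)
  r_loop <- .bb_coords(reference_chain, map$loop$ref_ord)
  m_loop_fitted <- apply_transform(m_loop, fit)
  list(
    rmsd_al = rmsd_no_fit(m_loop_fitted, r_loop),
    rmsd_ctd = fit$rmsd,
    n_al_residues = nrow(map$loop),
    n_ctd_residues = nrow(map$ctd)
  )
}

#' Summarise a benchmark of best-model loop RMSDs
#'
#' @param records data.frame with columns `kinase` and `rmsd_al` (one best
#'   model per kinase), or a named numeric vector.
#' @param thresholds RMSD thresholds (angstrom) to report fractions below.
#' @param bin_width Histogram bin width (angstrom).
#' @return List: `n`, per-threshold `counts` and `fractions`, and
#'   `histogram` (data.frame of bin edges and counts).
#' @export
benchmark_summary <- function(records, thresholds = c(1.0, 2.0),
                              bin_width = 0.5) {
  r <- if (is.data.frame(records)) records$rmsd_al else as.numeric(records)
  stopifnot(length(r) >= 1, all(is.finite(r)))
  counts <- vapply(thresholds, function(t) sum(r < t), numeric(1))
  breaks <- seq(0, max(r, max(thresholds)) + bin_width, by = bin_width)
  bin <- findInterval(r, breaks, rightmost.closed = FALSE)
  hcount <- tabulate(bin, nbins = length(breaks) - 1)
  list(
    n = length(r),
    counts = stats::setNames(counts, paste0("lt_", thresholds)),
    fractions = stats::setNames(counts / length(r),
                                paste0("lt_", thresholds)),
    histogram = data.frame(lower = breaks[-length(breaks)],
                           upper = breaks[-1], count = hcount)
  )
}
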