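# Anchor-residue annotation for one kinase chain.
#
# All offset arithmetic is done on 0-based sequence ordinals, never on
# author residue numbers, so insertion codes and numbering gaps cannot
# corrupt the derived positions. Derived positions:
#   dfg6 = dfg_d + 5        (sixth activation-loop residue, DFGxxX)
#   ape9 = ape_e - 8        (ninth residue from the loop end, XxxxxxAPE)
#   glu4 = chelix_glu + 4   (fourth residue after the C-helix Glu)
#   hpn7 = hpn_his + 6      (seventh residue from the HPN His, HPNxxxX)
#   xhrd = hrd_h - 1        (residue immediately preceding HRD)
#   xdfg = dfg_d - 1        (residue immediately preceding DFG)

.kin_families <- c("AGC", "CAMK", "CK1", "CMGC", "NEK", "OTHER", "STE",
                   "TKL", "TYR")

# anchors a user config may provide (author numbering); hrd/dfg/ape motifs
# are given by their first residue
.config_anchors <- c("beta3_lys", "chelix_glu", "hpn_his", "hrd_h", "dfg_d",
                     "ape_a", "al_end")

#' Read an annotation config (JSON or TSV)
#'
#' JSON: an object with `family`, `gene_label`, optional `chain`, and an
#' `anchors` object mapping anchor names (`beta3_lys`, `chelix_glu`,
#' `hpn_his`, `hrd_h`, `dfg_d`, `ape_a`, optionally `al_end` for kinases
#' without an APE motif) to author residue numbers (or `"123A"` strings with
#' insertion codes). TSV: columns `anchor`, `auth_seq_num`, optional
#' `icode`, plus rows with anchor `family` / `gene_label` carrying those
#' values in `auth_seq_num` read as text.
#'
#' @param path Config file path (`.json` or `.tsv`).
#' @return A list usable as `config` in [annotate_from_config()].
#' @export
read_annotation_config <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext == "json") {
    cfg <- jsonlite::fromJSON(path, simplifyVector = TRUE)
    if (is.list(cfg$anchors)) cfg$anchors <- unlist(cfg$anchors)
    return(cfg)
  }
  tb <- utils::read.delim(path, stringsAsFactors = FALSE,
                          colClasses = "character")
  meta <- tb$anchor %in% c("family", "gene_label")
  cfg <- list(anchors = stats::setNames(tb$auth_seq_num[!meta],
                                        tb$anchor[!meta]))
  if ("icode" %in% names(tb)) {
    ic <- tb$icode[!meta]
    has <- !is.na(ic) & ic != ""
    cfg$anchors[has] <- paste0(cfg$anchors[has], ic[has])
  }
  for (m in which(meta)) cfg[[tb$anchor[m]]] <- tb$auth_seq_num[m]
  cfg
}

# "123" or "123A" -> list(resno, insert)
.parse_reskey <- function(x) {
  x <- as.character(x)
  m <- regmatches(x, regexec("^(-?[0-9]+)([A-Za-z]?)$", x))[[1]]
  if (length(m) == 0) stop("malformed residue key '", x, "'")
  list(resno = as.integer(m[2]), insert = m[3])
}

.ordinal_of <- function(chain, reskey, anchor) {
  k <- .parse_reskey(reskey)
  i <- which(chain$residues$resno == k$resno &
               chain$residues$insert == k$insert)
  if (length(i) != 1) {
    stop("annotation error: anchor '", anchor, "' (residue ", reskey,
         ") not found in chain ", chain$chain_id)
  }
  chain$residues$ordinal[i]
}

#' Resolve a full kinase annotation from an explicit anchor config
#'
#' Derives every position the active-state criteria need from the given
#' anchor residues by pure ordinal offsets, and validates the anchor residue
#' types against expected motif sequences when provided (mismatches warn
#' rather than fail: e.g. AKT1 has YRD where most kinases have HRD).
#'
#' @param chain A `kin_chain`.
#' @param config List with `family`, `gene_label`, `anchors` (named author
#'   residue numbers, see [read_annotation_config()]), and optionally
#'   `expected` (named anchor motif strings, e.g. `c(dfg_d = "DFG")`) and
#'   `loop_span_inclusive` (logical, default `TRUE`: activation-loop span
#'   runs from the DFG Asp through the APE Glu inclusive).
#' @param apply_exceptions Apply the packaged family-exception registry
#'   (see [apply_family_exceptions()]). Default `TRUE`.
#' @return A `kin_annotation`: list of 0-based ordinals for every anchor and
#'   derived position, the activation-loop span (`al_start`, `al_end`),
#'   `family`, `gene_label` and the `skip_saltbridge` / `skip_actloopct`
#'   flags.
#' @export
annotate_from_config <- function(chain, config, apply_exceptions = TRUE) {
  stopifnot(inherits(chain, "kin_chain"))
  anch <- config$anchors
  need <- c("beta3_lys", "chelix_glu", "hpn_his", "hrd_h", "dfg_d")
  miss <- setdiff(need, names(anch))
  if (length(miss) && !identical(miss, "chelix_glu")) {
    stop("annotation error: missing anchor(s): ",
         paste(setdiff(miss, "chelix_glu"), collapse = ", "))
  }
  ords <- list()
  for (a in intersect(names(anch), .config_anchors)) {
    ords[[a]] <- .ordinal_of(chain, anch[[a]], a)
  }
  nres <- nrow(chain$residues)
  # Derived positions count residues of the protein sequence. A jump in
  # author numbering along the walk means residues are missing from the
  # coordinates (disorder): the derived position is then unresolvable and
  # the dependent criterion becomes unevaluable (NULL), not wrong.
  derive_ord <- function(base_ord, off, name) {
    if (is.null(base_ord) || length(base_ord) != 1) return(NULL)
    o <- base_ord + off
    if (o < 0 || o >= nres) {
      stop("annotation error: derived position '", name,
           "' falls outside the chain")
    }
    step <- sign(off)
    if (step != 0) {
      rn <- chain$residues$resno
      for (k in seq(base_ord, o - step, by = step)) {
        jump <- abs(rn[k + 1 + step] - rn[k + 1])  # +1: 0-based ordinals
        if (jump > 1) return(NULL)
      }
    }
    o
  }
  derive <- function(base, off, name) derive_ord(ords[[base]], off, name)
  ann <- list(
    family = if (!is.null(config$family)) config$family else "OTHER",
    gene_label = if (!is.null(config$gene_label)) config$gene_label else "",
    beta3_lys = ords$beta3_lys,
    chelix_glu = ords$chelix_glu,
    hpn_his = ords$hpn_his,
    hrd_h = ords$hrd_h,
    dfg_d = ords$dfg_d
  )
  if (!ann$family %in% .kin_families) {
    stop("unknown kinase family '", ann$family, "'")
  }
  ann$hrd_r <- derive("hrd_h", 1L, "hrd_r")
  ann$hrd_d <- derive("hrd_h", 2L, "hrd_d")
  ann$xhrd <- derive("hrd_h", -1L, "xhrd")
  ann$dfg_f <- derive("dfg_d", 1L, "dfg_f")
  ann$dfg_g <- derive("dfg_d", 2L, "dfg_g")
  ann$xdfg <- derive("dfg_d", -1L, "xdfg")
  ann$dfg6 <- derive("dfg_d", 5L, "dfg6")
  ann$glu4 <- derive("chelix_glu", 4L, "glu4")
  ann$hpn7 <- derive("hpn_his", 6L, "hpn7")
  if (!is.null(ords$ape_a)) {
    ann$ape_a <- ords$ape_a
    ann$ape_p <- derive("ape_a", 1L, "ape_p")
    ann$ape_e <- derive("ape_a", 2L, "ape_e")
    ann$ape9 <- derive_ord(ann$ape_e, -8L, "ape9")
  }
  ann$al_start <- ann$dfg_d
  ann$al_end <- if (!is.null(ann$ape_e)) {
    ann$ape_e
  } else if (!is.null(ords$al_end)) {
    ords$al_end
  } else {
    stop("annotation error: kinases without an APE motif need an explicit ",
         "'al_end' anchor for the activation-loop span")
  }
  if (isFALSE(config$loop_span_inclusive)) {
    ann$al_start <- ann$al_start + 1L
    ann$al_end <- ann$al_end - 1L
  }
  if (ann$al_end <= ann$al_start) {
    stop("annotation error: empty activation-loop span")
  }
  .validate_expected(chain, ann, config$expected)
  ann$skip_saltbridge <- FALSE
  ann$skip_actloopct <- FALSE
  ann <- structure(ann, class = "kin_annotation")
  if (apply_exceptions) ann <- apply_family_exceptions(ann)
  ann
}

.validate_expected <- function(chain, ann, expected) {
  if (is.null(expected)) return(invisible())
  aa_at <- function(o) chain$residues$aa1[match(o, chain$residues$ordinal)]
  for (nm in names(expected)) {
    o <- ann[[nm]]
    if (is.null(o)) next
    want <- strsplit(expected[[nm]], "")[[1]]
    got <- vapply(o + seq_along(want) - 1L, aa_at, character(1))
    if (!identical(got, want)) {
      warning("anchor '", nm, "': expected sequence ", expected[[nm]],
              " but found ", paste(got, collapse = ""),
              " (kept; motif variants such as YRD for HRD are known)")
    }
  }
  invisible()
}

#' @export
print.kin_annotation <- function(x, ...) {
  cat("<kin_annotation> ", x$gene_label, " (", x$family, ")\n", sep = "")
  show <- c("beta3_lys", "chelix_glu", "glu4", "hpn_his", "hpn7", "xhrd",
            "hrd_h", "xdfg", "dfg_d", "dfg6", "ape_e", "ape9")
  vals <- vapply(show, function(nm)
    if (is.null(x[[nm]])) "-" else as.character(x[[nm]]), character(1))
  cat("  ordinals: ", paste(show, vals, sep = "=", collapse = " "), "\n",
      sep = "")
  cat("  activation loop: [", x$al_start, ", ", x$al_end, "]",
      "; skip_saltbridge=", x$skip_saltbridge,
      " skip_actloopct=", x$skip_actloopct, "\n", sep = "")
  invisible(x)
}

#' Locate anchor motifs by degenerate pattern search
#'
#' Finds HRD-like, DFG-like and APE-like tripeptides by ordered regular
#' expression search with family-aware degeneracy, constrained so HRD
#' precedes DFG precedes APE and the DFG-to-APE separation (Asp ordinal to
#' Glu ordinal) lies within `spacing`. The remaining anchors (beta3 Lys,
#' C-helix Glu, HPN His) must come from `config`.
#'
#' @param chain A `kin_chain`.
#' @param family Kinase family string.
#' @param config As for [annotate_from_config()]; its `anchors` may omit
#'   `hrd_h`, `dfg_d`, `ape_a`, which this function fills in.
#' @param motif_patterns Named character regexes for `hrd`, `dfg`, `ape`.
#' @param spacing Allowed DFG-Asp to APE-Glu ordinal separation (inclusive).
#' @return A `kin_annotation`, as [annotate_from_config()].
#' @export
annotate_by_anchor_search <- function(chain, family, config,
                                      motif_patterns = c(
                                        hrd = "[HYLF][RK]D",
                                        dfg = "D[FLYWMV]G",
                                        ape = "[ASP]PE"),
                                      spacing = c(15L, 45L)) {
  seqstr <- chain_sequence(chain)
  find_all <- function(pat) {
    hits <- gregexpr(paste0("(?=", pat, ")"), seqstr, perl = TRUE)[[1]]
    if (hits[1] == -1) integer(0) else as.integer(hits) - 1L  # 0-based
  }
  hrd <- find_all(motif_patterns[["hrd"]])
  dfg <- find_all(motif_patterns[["dfg"]])
  ape <- find_all(motif_patterns[["ape"]])
  combos <- list()
  for (h in hrd) for (d in dfg) for (a in ape) {
    e <- a + 2L
    if (h + 3L <= d && d + 3L <= a &&
        (e - d) >= spacing[1] && (e - d) <= spacing[2]) {
      combos[[length(combos) + 1L]] <- c(h = h, d = d, a = a)
    }
  }
  if (length(combos) == 0) {
    stop("anchor search: no consistent HRD/DFG/APE placement found; ",
         "provide explicit anchors in the config")
  }
  if (length(combos) > 1) {
    stop("anchor search: ", length(combos), " consistent HRD/DFG/APE ",
         "placements (ambiguous); provide explicit anchors in the config")
  }
  hit <- combos[[1]]
  reskey_at <- function(o) {
    r <- chain$residues[match(o, chain$residues$ordinal), ]
    paste0(r$resno, r$insert)
  }
  config$family <- family
  config$anchors <- c(config$anchors,
                      hrd_h = reskey_at(hit[["h"]]),
                      dfg_d = reskey_at(hit[["d"]]),
                      ape_a = reskey_at(hit[["a"]]))
  annotate_from_config(chain, config)
}

#' Apply family/gene exception flags to an annotation
#'
#' The WNK kinases (which lack the beta3 Lys) and MAP3K12/13 (Asp in place
#' of the C-helix Glu) skip the salt-bridge criterion; HASPIN, TP53RK and
#' PKDCC lack an APE motif and skip the ActLoopCT criterion. The gene list
#' is a packaged registry table (`family_exceptions.tsv`) that users can
#' extend.
#'
#' @param annotation A `kin_annotation`.
#' @param registry Data frame with columns `gene_label`, `skip_saltbridge`,
#'   `skip_actloopct`; defaults to the packaged registry.
#' @return The annotation with exception flags set.
#' @export
apply_family_exceptions <- function(annotation,
                                    registry = read_exception_registry()) {
  stopifnot(inherits(annotation, "kin_annotation"))
  i <- match(annotation$gene_label, registry$gene_label)
  if (!is.na(i)) {
    annotation$skip_saltbridge <- isTRUE(as.logical(registry$skip_saltbridge[i]))
    annotation$skip_actloopct <- isTRUE(as.logical(registry$skip_actloopct[i]))
  } else {
    annotation$skip_saltbridge <- FALSE
    annotation$skip_actloopct <- FALSE
  }
  annotation
}

#' Read the packaged (or a user) gene-exception registry
#' @param path TSV path; default the registry shipped with the package.
#' @return Data frame.
#' @export
read_exception_registry <- function(path = system.file(
  "extdata", "family_exceptions.tsv", package = "kinactive")) {
  utils::read.delim(path, stringsAsFactors = FALSE)
}

#' Activation-loop residue ordinals of an annotation
#' @param annotation A `kin_annotation`.
#' @return Integer vector of 0-based ordinals, `al_start:al_end`.
#' @export
activation_loop_ordinals <- function(annotation) {
  seq.int(annotation$al_start, annotation$al_end)
}
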