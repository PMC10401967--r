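#' @keywords internal
"_PACKAGE"

# Minimal hierarchical structure container used throughout the package.
#
# A `kin_structure` is a list with:
#   entry_id      - character id (basename of file by default)
#   atoms         - data.frame, one row per atom: chain, resno, insert, resid
#                   (3-letter), aa1, elety (atom name), eleno, alt, x, y, z,
#                   o (occupancy), b (B-factor / pLDDT), het (logical)
#   source_format - "pdb" or "mmcif"
#   resolution    - numeric (angstrom) or NA
#   is_model      - TRUE when the B-factor column holds pLDDT values
#                   (AlphaFold-style model file), FALSE for experimental

#' Read a macromolecular structure (PDB or mmCIF)
#'
#' Parses a structure file into a minimal hierarchical atom table preserving
#' coordinates, residue identity, occupancy, alternate locations and the
#' B-factor column (interpreted as pLDDT for predicted-model files). Only the
#' first model of multi-model files is kept (with a warning). Parsing of the
#' standard record formats is delegated to \pkg{bio3d}.
#'
#' @param path Path to a `.pdb` or `.cif` file.
#' @param format One of `"auto"` (default; by file extension), `"pdb"`,
#'   `"mmcif"`.
#' @param is_model Logical; set `TRUE` for AlphaFold-style model files whose
#'   B-factor column holds per-residue pLDDT (0-100). pLDDT-dependent
#'   operations refuse structures read with `is_model = FALSE`.
#' @param entry_id Optional entry identifier; defaults to the file basename
#'   without extension.
#' @return A `kin_structure` object (see Details).
#' @export
read_structure <- function(path, format = c("auto", "pdb", "mmcif"),
                           is_model = FALSE, entry_id = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) {
    stop("cannot read structure file: '", path, "' does not exist")
  }
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- switch(ext,
      "cif" = "mmcif", "mmcif" = "mmcif",
      "pdb" = "pdb", "ent" = "pdb",
      stop("cannot infer format from extension '", ext,
           "'; pass format = 'pdb' or 'mmcif'")
    )
  }
  parsed <- tryCatch(
    if (format == "pdb") {
      bio3d::read.pdb(path, multi = FALSE, rm.alt = FALSE, rm.insert = FALSE,
                      verbose = FALSE)
    } else {
      suppressWarnings(bio3d::read.cif(path, multi = FALSE, rm.alt = FALSE,
                                       rm.insert = FALSE, verbose = FALSE))
    },
    error = function(e) {
      stop("failed to parse '", path, "' as ", format, ": ",
           conditionMessage(e))
    }
  )
  at <- parsed$atom
  if (is.null(at) || nrow(at) == 0) {
    stop("no atom records parsed from '", path, "'")
  }
  lines <- readLines(path, warn = FALSE)
  if (format == "pdb" && sum(grepl("^ENDMDL", lines)) > 1) {
    warning("multi-model file '", basename(path), "': only model 1 is read")
  }
  atoms <- data.frame(
    chain  = ifelse(is.na(at$chain), "", as.character(at$chain)),
    resno  = as.integer(at$resno),
    insert = ifelse(is.na(at$insert), "", as.character(at$insert)),
    resid  = as.character(at$resid),
    elety  = as.character(at$elety),
    eleno  = as.integer(at$eleno),
    alt    = ifelse(is.na(at$alt), "", as.character(at$alt)),
    x = as.numeric(at$x), y = as.numeric(at$y), z = as.numeric(at$z),
    o = ifelse(is.na(at$o), 1, as.numeric(at$o)),
    b = ifelse(is.na(at$b), 0, as.numeric(at$b)),
    het = as.character(at$type) == "HETATM",
    stringsAsFactors = FALSE
  )
  # mmCIF multi-model fallback: keep the first occurrence of each atom key
  key <- paste(atoms$chain, atoms$resno, atoms$insert, atoms$elety, atoms$alt,
               atoms$het)
  if (anyDuplicated(key)) {
    if (format == "mmcif") {
      warning("duplicate atom records in '", basename(path),
              "' (multi-model mmCIF?): keeping first occurrence only")
    }
    atoms <- atoms[!duplicated(key), , drop = FALSE]
  }
  atoms$aa1 <- suppressWarnings(bio3d::aa321(atoms$resid))
  atoms$aa1[is.na(atoms$aa1)] <- "X"
  bad <- !is.finite(atoms$x) | !is.finite(atoms$y) | !is.finite(atoms$z)
  if (any(bad)) {
    stop("non-finite coordinates at atom record(s) ",
         paste(utils::head(atoms$eleno[bad], 5), collapse = ", "))
  }
  structure(
    list(
      entry_id = if (is.null(entry_id))
        tools::file_path_sans_ext(basename(path)) else entry_id,
      atoms = atoms,
      source_format = format,
      resolution = .parse_resolution(lines, format),
      is_model = isTRUE(is_model)
    ),
    class = "kin_structure"
  )
}

# Resolution from REMARK 2 (PDB) or _refine.ls_d_res_high / _reflns (mmCIF).
.parse_resolution <- function(lines, format) {
  if (format == "pdb") {
    hit <- grep("^REMARK   2 RESOLUTION\\.", lines, value = TRUE)
    if (length(hit)) {
      m <- regmatches(hit[1], regexpr("[0-9]+\\.[0-9]+", hit[1]))
      if (length(m)) return(as.numeric(m))
    }
  } else {
    for (tag in c("_refine.ls_d_res_high", "_reflns.d_resolution_high")) {
      hit <- grep(paste0("^", tag, "\\s"), lines, value = TRUE)
      if (length(hit)) {
        v <- suppressWarnings(as.numeric(strsplit(trimws(hit[1]),
                                                  "\\s+")[[1]][2]))
        if (!is.na(v)) return(v)
      }
    }
  }
  NA_real_
}

#' @export
print.kin_structure <- function(x, ...) {
  ch <- unique(x$atoms$chain[!x$atoms$het])
  cat("<kin_structure> ", x$entry_id, " (", x$source_format, ")\n", sep = "")
  cat("  chains: ", paste(ch, collapse = ", "),
      "; atoms: ", nrow(x$atoms), "\n", sep = "")
  cat("  resolution: ", ifelse(is.na(x$resolution), "NA", x$resolution),
      " A; is_model: ", x$is_model, "\n", sep = "")
  invisible(x)
}

#' List chain identifiers of a structure
#' @param structure A `kin_structure`.
#' @param include_het Include chains containing only HETATM records.
#' @return Character vector of chain ids.
#' @export
chain_ids <- function(structure, include_het = FALSE) {
  stopifnot(inherits(structure, "kin_structure"))
  at <- structure$atoms
  if (!include_het) at <- at[!at$het, , drop = FALSE]
  unique(at$chain)
}

#' Extract one chain with deterministic alternate-location reduction
#'
#' Returns the polymer atoms of a chain with one atom per (residue, atom
#' name): when alternate locations exist the highest-occupancy one is kept,
#' ties broken by alphabetical alt-loc id. Residues are ordered by
#' (author residue number, insertion code) and assigned a 0-based ordinal
#' index used for all sequence-offset arithmetic.
#'
#' @param structure A `kin_structure`.
#' @param chain_id Chain identifier.
#' @return A `kin_chain` object: list with `atoms` (reduced atom table with a
#'   `res_ordinal` column), `residues` (one row per residue: `ordinal`,
#'   `resno`, `insert`, `aa3`, `aa1`), `chain_id`, `entry_id`, `is_model`,
#'   and `het_codes` (3-letter codes of HETATM groups on the chain, for
#'   ATP-presence reporting).
#' @export
select_chain <- function(structure, chain_id) {
  stopifnot(inherits(structure, "kin_structure"))
  at <- structure$atoms
  avail <- unique(at$chain[!at$het])
  if (!chain_id %in% avail) {
    stop("chain '", chain_id, "' not found; available chains: ",
         paste(avail, collapse = ", "))
  }
  het_codes <- unique(at$resid[at$het & at$chain == chain_id])
  at <- at[!at$het & at$chain == chain_id, , drop = FALSE]
  # alt-loc reduction: highest occupancy, ties to alphabetically first alt id
  akey <- paste(at$resno, at$insert, at$elety)
  ord <- order(akey, -at$o, at$alt)
  at <- at[ord, , drop = FALSE]
  at <- at[!duplicated(paste(at$resno, at$insert, at$elety)), , drop = FALSE]
  # residue ordering by (resno, insert); "" sorts before "A"
  rkey <- paste(at$resno, at$insert)
  runiq <- at[!duplicated(rkey), c("resno", "insert", "resid", "aa1")]
  runiq <- runiq[order(runiq$resno, runiq$insert), , drop = FALSE]
  residues <- data.frame(
    ordinal = seq_len(nrow(runiq)) - 1L,
    resno = runiq$resno, insert = runiq$insert,
    aa3 = runiq$resid, aa1 = runiq$aa1,
    stringsAsFactors = FALSE
  )
  idx <- match(paste(at$resno, at$insert),
               paste(residues$resno, residues$insert))
  at$res_ordinal <- residues$ordinal[idx]
  at <- at[order(at$res_ordinal, at$eleno), , drop = FALSE]
  rownames(at) <- NULL
  structure(
    list(atoms = at, residues = residues, chain_id = chain_id,
         entry_id = structure$entry_id, is_model = structure$is_model,
         het_codes = het_codes),
    class = "kin_chain"
  )
}

#' @export
print.kin_chain <- function(x, ...) {
  cat("<kin_chain> ", x$entry_id, " chain ", x$chain_id, ": ",
      nrow(x$residues), " residues, ", nrow(x$atoms), " atoms\n", sep = "")
  invisible(x)
}

#' One-letter sequence of a chain
#' @param chain A `kin_chain`.
#' @return Single character string.
#' @export
chain_sequence <- function(chain) {
  stopifnot(inherits(chain, "kin_chain"))
  paste(chain$residues$aa1, collapse = "")
}

#' Get a named atom of a residue
#'
#' Missing atoms are a value (`NULL`), not an error: classification criteria
#' must treat them as unevaluable rather than failed.
#'
#' @param chain A `kin_chain`.
#' @param ordinal 0-based residue ordinal within the chain.
#' @param name Atom name (PDB convention, e.g. `"CA"`, `"CZ"`, `"NZ"`).
#' @return Named list with `xyz` (numeric length-3), `b`, `o`, `name`; or
#'   `NULL` when the atom is absent.
#' @export
get_atom <- function(chain, ordinal, name) {
  stopifnot(inherits(chain, "kin_chain"))
  at <- chain$atoms
  i <- which(at$res_ordinal == ordinal & at$elety == name)
  if (length(i) == 0) return(NULL)
  i <- i[1]
  list(xyz = c(at$x[i], at$y[i], at$z[i]), b = at$b[i], o = at$o[i],
       name = name)
}

# All heavy side-chain atoms of a residue (backbone and OXT excluded),
# as a coordinate matrix with atom-name rownames; NULL when none.
.side_chain_atoms <- function(chain, ordinal) {
  at <- chain$atoms
  bb <- c("N", "CA", "C", "O", "OXT")
  i <- which(at$res_ordinal == ordinal & !(at$elety %in% bb) &
               !grepl("^H", at$elety))
  if (length(i) == 0) return(NULL)
  m <- as.matrix(at[i, c("x", "y", "z"), drop = FALSE])
  rownames(m) <- at$elety[i]
  m
}

#' Write a chain or structure to a PDB file
#'
#' Thin wrapper over [bio3d::write.pdb()]; intended for synthetic fixtures
#' and round-trip tests, not for archival deposition.
#'
#' @param x A `kin_structure` or `kin_chain`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_structure_pdb <- function(x, path) {
  at <- if (inherits(x, "kin_structure")) x$atoms else x$atoms
  if (inherits(x, "kin_chain")) at$het <- FALSE
  xyz <- as.numeric(t(as.matrix(at[, c("x", "y", "z")])))
  bio3d::write.pdb(
    pdb = NULL, file = path, xyz = xyz,
    type = ifelse(at$het, "HETATM", "ATOM"),
    resno = at$resno, resid = at$resid,
    eleno = seq_len(nrow(at)), elety = at$elety,
    chain = ifelse(at$chain == "", " ", at$chain),
    insert = ifelse(at$insert == "", "", at$insert),
    alt = ifelse(at$alt == "", "", at$alt),
    o = at$o, b = at$b
  )
  invisible(path)
}

#' Report ATP-like ligand codes associated with a chain
#'
#' Presence is by chain-associated HETATM 3-letter code only (ATP, ADP, ANP,
#' ACP by default); no geometric active-site qualification is attempted.
#'
#' @param chain A `kin_chain`.
#' @param codes Ligand codes counted as ATP-like.
#' @return Character vector of matching codes present (possibly empty).
#' @export
atp_ligand_codes <- function(chain, codes = c("ATP", "ADP", "ANP", "ACP")) {
  stopifnot(inherits(chain, "kin_chain"))
  intersect(codes, chain$het_codes)
}
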