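# Data-preparation rules for building ortholog sequence sets and active
# template sets: strict hit filtering, CD-HIT-style greedy redundancy
# reduction, per-kinase template selection and MSA-depth truncation. All
# operations work on tabular/sequence inputs; no network access.

#' Filter ortholog sequence hits by identity, coverage and gap fraction
#'
#' Keeps hits strictly above 50% identity, strictly above 90% query
#' coverage and strictly below 10% alignment gaps (all thresholds
#' overridable; the comparisons are strict in all three).
#'
#' @param hits data.frame with numeric columns `identity_fraction`,
#'   `coverage_fraction`, `gap_fraction` in `[0, 1]` (extra columns, e.g.
#'   BLAST outfmt-6 fields, are tolerated and preserved).
#' @param id_min,cov_min,gap_max Thresholds as fractions.
#' @return The kept subset of `hits`.
#' @export
filter_hits <- function(hits, id_min = 0.50, cov_min = 0.90,
                        gap_max = 0.10) {
  stopifnot(all(c("identity_fraction", "coverage_fraction",
                  "gap_fraction") %in% names(hits)))
  keep <- hits$identity_fraction > id_min &
    hits$coverage_fraction > cov_min &
    hits$gap_fraction < gap_max
  out <- hits[keep & !is.na(keep), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Read a hits table (TSV)
#'
#' Expects at least `query_id`, `subject_id`, `identity_fraction`,
#' `coverage_fraction`, `gap_fraction`; values given as percentages
#' (> 1.5) are converted to fractions.
#'
#' @param path TSV file path.
#' @return data.frame of hits.
#' @export
read_hits_tsv <- function(path) {
  tb <- utils::read.delim(path, stringsAsFactors = FALSE)
  for (col in c("identity_fraction", "coverage_fraction", "gap_fraction")) {
    if (col %in% names(tb) && any(tb[[col]] > 1.5, na.rm = TRUE)) {
      tb[[col]] <- tb[[col]] / 100
    }
  }
  tb
}

#' Pairwise global sequence identity
#'
#' Matches divided by alignment columns (gaps included) of a global
#' Needleman-Wunsch alignment with affine gap penalties (via
#' \pkg{Biostrings}).
#'
#' @param a,b Character sequences.
#' @return Identity fraction in `[0, 1]`.
#' @export
pairwise_identity <- function(a, b) {
  aln <- Biostrings::pairwiseAlignment(a, b, type = "global")
  ap <- strsplit(as.character(Biostrings::alignedPattern(aln)), "")[[1]]
  as_ <- strsplit(as.character(Biostrings::alignedSubject(aln)), "")[[1]]
  sum(ap == as_ & ap != "-") / length(ap)
}

#' Greedy identity-redundancy reduction (CD-HIT convention)
#'
#' Processes sequences longest-first (ties by input order); a sequence
#' founds a new cluster unless its identity to an existing representative
#' exceeds `threshold`, in which case it joins that representative's
#' cluster. Guarantees that no two representatives are more than
#' `threshold` identical.
#'
#' @param sequences Character vector (optionally named).
#' @param threshold Maximum allowed pairwise identity among
#'   representatives. Default 0.90.
#' @return Character vector of representatives in processing order,
#'   with a `clusters` attribute mapping each input index to its
#'   representative's input index.
#' @export
greedy_identity_cluster <- function(sequences, threshold = 0.90) {
  stopifnot(length(sequences) >= 1)
  ord <- order(-nchar(sequences), seq_along(sequences))
  reps <- integer(0)
  assign_to <- integer(length(sequences))
  for (i in ord) {
    placed <- FALSE
    for (r in reps) {
      if (pairwise_identity(sequences[i], sequences[r]) > threshold) {
        assign_to[i] <- r
        placed <- TRUE
        break
      }
    }
    if (!placed) {
      reps <- c(reps, i)
      assign_to[i] <- i
    }
  }
  out <- sequences[reps]
  attr(out, "clusters") <- assign_to
  out
}

#' Select active structural templates per kinase
#'
#' Per kinase, candidates flagged active are sorted by ordered
#' activation-loop residue count (descending), then resolution (ascending,
#' missing last), then PDB entry and chain id, and taken greedily while
#' enforcing distinct PDB entries, until `per_kinase` are chosen.
#' Candidates from `exclude_entry` (e.g. the prediction target's own PDB
#' entry) are removed first.
#'
#' @param candidates data.frame with columns `kinase_id`, `pdb_entry`,
#'   `chain`, `n_ordered_al`, `resolution` (NA allowed), `is_active`.
#' @param per_kinase Number of templates per kinase (default 2).
#' @param exclude_entry Optional PDB entry id(s) to drop (case
#'   insensitive).
#' @return data.frame of chosen candidates with a `rank` column (1 =
#'   first template), ordered by kinase then rank.
#' @export
select_active_templates <- function(candidates, per_kinase = 2,
                                    exclude_entry = NULL) {
  need <- c("kinase_id", "pdb_entry", "chain", "n_ordered_al",
            "resolution", "is_active")
  stopifnot(all(need %in% names(candidates)))
  cd <- candidates[candidates$is_active, , drop = FALSE]
  if (!is.null(exclude_entry)) {
    cd <- cd[!(tolower(cd$pdb_entry) %in% tolower(exclude_entry)), ,
             drop = FALSE]
  }
  out <- list()
  for (k in unique(cd$kinase_id)) {
    ck <- cd[cd$kinase_id == k, , drop = FALSE]
    res <- ifelse(is.na(ck$resolution), Inf, ck$resolution)
    ck <- ck[order(-ck$n_ordered_al, res, ck$pdb_entry, ck$chain), ,
             drop = FALSE]
    chosen <- ck[0, , drop = FALSE]
    for (i in seq_len(nrow(ck))) {
      if (nrow(chosen) >= per_kinase) break
      if (!ck$pdb_entry[i] %in% chosen$pdb_entry) {
        chosen <- rbind(chosen, ck[i, , drop = FALSE])
      }
    }
    if (nrow(chosen)) {
      chosen$rank <- seq_len(nrow(chosen))
      out[[k]] <- chosen
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Truncate a multiple sequence alignment to a fixed depth
#'
#' Returns the query (first row) plus the first `depth - 1` following
#' rows, preserving order; mirrors an MSA-depth limit such as
#' `uniref_max_hits = 30` or the very shallow 1-5-sequence regime used to
#' coerce template-driven modelling.
#'
#' @param msa Character vector of aligned sequences, query first
#'   (optionally named).
#' @param depth Number of rows to keep (>= 1).
#' @return Truncated character vector.
#' @export
truncate_msa <- function(msa, depth) {
  stopifnot(length(msa) >= 1)
  if (!is.numeric(depth) || depth < 1) {
    stop("MSA depth must be >= 1 (the query row is always kept)")
  }
  msa[seq_len(min(length(msa), as.integer(depth)))]
}

#' Read sequences from a FASTA file
#' @param path FASTA file.
#' @return Named character vector.
#' @export
read_fasta_sequences <- function(path) {
  ss <- Biostrings::readBStringSet(path)
  stats::setNames(as.character(ss), names(ss))
}

#' Write sequences to a FASTA file
#' @param sequences Named character vector.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta_sequences <- function(sequences, path) {
  nm <- names(sequences)
  if (is.null(nm)) nm <- paste0("seq", seq_along(sequences))
  Biostrings::writeXStringSet(
    Biostrings::BStringSet(stats::setNames(unname(sequences), nm)), path)
  invisible(path)
}
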