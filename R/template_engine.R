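# pMHC template library construction and similarity-ranked selection,
# TCR single-sequence template search, focused MSA database assembly.

#' Similarity scoring parameters
#'
#' Template ranking scores sequences with BLOSUM62. MHC sequences use an
#' ordinary affine global alignment (open -11 / extend -1, the matrix's
#' standard companions); peptide sequences use a large flat gap penalty
#' (-100) so that optimal equal-length alignments are ungapped and template
#' scoring reduces to a position-wise matrix sum.
#'
#' @param matrix_name substitution matrix identifier (only `"BLOSUM62"` is
#'   shipped).
#' @param gap_opening,gap_extension nonnegative gap costs (Biostrings sign
#'   convention: costs are subtracted).
#' @param mode `"global"` or `"ungapped-enforced"`; the latter is the
#'   peptide setting with the flat -100 penalty.
#' @return object of class `SimilarityParams`.
#' @export
similarity_params <- function(matrix_name = "BLOSUM62",
                              gap_opening = 10, gap_extension = 1,
                              mode = c("global", "ungapped-enforced")) {
  mode <- match.arg(mode)
  if (mode == "ungapped-enforced") { gap_opening <- 100; gap_extension <- 0 }
  if (gap_opening < 0 || gap_extension < 0)
    stop("gap costs must be nonnegative (they are subtracted)")
  structure(list(matrix_name = matrix_name, gap_opening = gap_opening,
                 gap_extension = gap_extension, mode = mode),
            class = "SimilarityParams")
}

#' Default peptide-scoring parameters (flat -100 gap penalty)
#' @return `SimilarityParams` enforcing ungapped equal-length alignments.
#' @export
peptide_similarity_params <- function() similarity_params(mode = "ungapped-enforced")

.as_seq <- function(x) {
  if (inherits(x, "ChainSequence")) x$sequence else as.character(x)
}

.check_alphabet <- function(seq, what = "sequence") {
  bad <- setdiff(strsplit(seq, "")[[1]],
                 rownames(.substitution_matrix("BLOSUM62")))
  if (length(bad))
    stop(what, " contains residue(s) with no substitution-matrix entry: ",
         paste(unique(bad), collapse = ""))
  invisible(seq)
}

.substitution_matrix <- function(name) {
  if (name != "BLOSUM62") stop("unknown substitution matrix: ", name)
  e <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = e)
  e$BLOSUM62
}

#' Optimal pairwise alignment score under BLOSUM62
#'
#' Global (Needleman-Wunsch) alignment score used to rank candidate
#' templates against a query. With the peptide parameter set
#' ([peptide_similarity_params()]) equal-length alignments are guaranteed
#' ungapped, so the score equals the position-wise sum of matrix entries.
#'
#' @param query,candidate amino-acid sequences (strings or
#'   `ChainSequence`).
#' @param params a `SimilarityParams`.
#' @return numeric alignment score.
#' @export
score_similarity <- function(query, candidate, params = similarity_params()) {
  q <- .as_seq(query); s <- .as_seq(candidate)
  if (!nzchar(q) || !nzchar(s)) stop("sequences must be nonempty")
  .check_alphabet(q, "query"); .check_alphabet(s, "candidate")
  as.numeric(Biostrings::pairwiseAlignment(
    Biostrings::AAString(q), Biostrings::AAString(s),
    substitutionMatrix = params$matrix_name,
    gapOpening = params$gap_opening, gapExtension = params$gap_extension,
    type = "global", scoreOnly = TRUE))
}

#' Global-alignment sequence identity
#'
#' Fraction of identical positions over the full global alignment length,
#' gap columns included in the denominator.
#'
#' @param a,b amino-acid sequences.
#' @param params a `SimilarityParams` (alignment is BLOSUM62 global,
#'   open -11/extend -1 by default).
#' @return identity fraction in `[0, 1]`.
#' @export
sequence_identity <- function(a, b, params = similarity_params()) {
  a <- .as_seq(a); b <- .as_seq(b)
  if (!nzchar(a) || !nzchar(b)) stop("sequences must be nonempty")
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(a), Biostrings::AAString(b),
    substitutionMatrix = params$matrix_name,
    gapOpening = params$gap_opening, gapExtension = params$gap_extension,
    type = "global")
  pa <- strsplit(as.character(Biostrings::alignedPattern(aln)), "")[[1]]
  pb <- strsplit(as.character(Biostrings::alignedSubject(aln)), "")[[1]]
  sum(pa == pb & pa != "-") / length(pa)
}

#' Trim a Class II peptide to its 11-mer template window
#'
#' Class II binding grooves are open-ended, so template peptides are reduced
#' to the 9-mer binding core plus one flanking residue at each terminus
#' where the flank exists; nothing is ever fabricated, so the result is at
#' most 11 residues (9 for a core flush with both termini).
#'
#' @param peptide peptide sequence, length >= 9.
#' @param core_start 1-based index of the first core residue.
#' @return trimmed peptide string (9-11 residues).
#' @export
trim_class2_peptide <- function(peptide, core_start) {
  peptide <- .as_seq(peptide)
  n <- nchar(peptide)
  core_start <- as.integer(core_start)
  if (n < 9L) stop("peptide shorter than the 9-mer core")
  if (core_start < 1L || core_start + 8L > n)
    stop("9-mer core window [", core_start, ", ", core_start + 8L,
         "] falls outside the ", n, "-mer peptide")
  from <- max(1L, core_start - 1L)
  to <- min(n, core_start + 9L)
  substr(peptide, from, to)
}

#' Construct a pMHC TemplateRecord
#'
#' @param source_id PDB-style identifier.
#' @param mhc_class `"I"` or `"II"`.
#' @param peptide_seq peptide sequence (Class II: already trimmed).
#' @param mhc_seq MHC sequence; for Class II the alpha then beta chain
#'   concatenated in that fixed order.
#' @param resolution Angstrom.
#' @param release_date `Date` or `NA`.
#' @param merged_structure single-chain `StructureModel` from
#'   [merge_pmhc_chains()], or `NULL`.
#' @return object of class `TemplateRecord`.
#' @export
template_record <- function(source_id, mhc_class, peptide_seq, mhc_seq,
                            resolution, release_date = NA,
                            merged_structure = NULL) {
  mhc_class <- match.arg(mhc_class, c("I", "II"))
  if (nchar(peptide_seq) < 8L && mhc_class == "I")
    stop("Class I template peptide shorter than 8 residues")
  if (mhc_class == "II" && nchar(peptide_seq) > 11L)
    stop("Class II template peptide longer than 11 residues; trim first")
  if (!is.na(release_date)) release_date <- as.Date(release_date)
  structure(list(source_id = source_id, mhc_class = mhc_class,
                 peptide_seq = peptide_seq, mhc_seq = mhc_seq,
                 resolution = as.numeric(resolution),
                 release_date = release_date,
                 merged_structure = merged_structure),
            class = "TemplateRecord")
}

#' Build the pMHC template library
#'
#' Applies the curation rules in order: drop entries above the resolution
#' cutoff; drop entries released after `cutoff_date` (when set); trim Class
#' II peptides to the 11-mer window around their annotated core; cap
#' identical (peptide, MHC) sequence pairs at two records, keeping the two
#' best resolutions (ties broken by `source_id`); merge peptide and MHC
#' into one index-shifted chain for featurization.
#'
#' @param entries list of annotated inputs, each a list with fields
#'   `structure` (`StructureModel`), `mhc_class`, `peptide_chain`,
#'   `mhc_chains` (one chain for Class I, alpha then beta for Class II),
#'   `resolution`, `release_date`, `source_id`, and for Class II
#'   `core_start` (1-based core position in the peptide chain; defaults to
#'   the centered window).
#' @param resolution_cutoff Angstrom; entries with resolution above this
#'   are dropped (default 3.5).
#' @param cutoff_date optional `Date`; entries released after it are
#'   dropped.
#' @param index_offset residue-index shift inserted at the MHC/peptide
#'   chain break (default 200).
#' @return object of class `TemplateLibrary` (fields `records`,
#'   `cutoff_date`, `resolution_cutoff`).
#' @export
build_pmhc_library <- function(entries, resolution_cutoff = 3.5,
                               cutoff_date = NA, index_offset = 200L) {
  if (!is.na(cutoff_date)) cutoff_date <- as.Date(cutoff_date)
  recs <- list()
  for (e in entries) {
    rec <- tryCatch(
      .curate_entry(e, resolution_cutoff, cutoff_date, index_offset),
      error = function(err) {
        warning("skipping template ", e$source_id, ": ",
                conditionMessage(err), call. = FALSE)
        NULL
      })
    if (!is.null(rec)) recs[[length(recs) + 1L]] <- rec
  }
  # redundancy cap: at most two records per identical (peptide, MHC) pair,
  # keeping best resolution, ties by source_id
  if (length(recs)) {
    key <- vapply(recs, function(r) paste(r$peptide_seq, r$mhc_seq), "")
    ord <- order(key,
                 vapply(recs, function(r) r$resolution, 0),
                 vapply(recs, function(r) r$source_id, ""))
    recs <- recs[ord]
    key <- key[ord]
    within <- stats::ave(seq_along(key), key, FUN = seq_along)
    recs <- recs[within <= 2L]
    recs <- recs[order(vapply(recs, function(r) r$source_id, ""))]
  }
  structure(list(records = recs, cutoff_date = cutoff_date,
                 resolution_cutoff = resolution_cutoff),
            class = "TemplateLibrary")
}

.curate_entry <- function(e, resolution_cutoff, cutoff_date, index_offset) {
  stopifnot(!is.null(e$structure), !is.null(e$mhc_class))
  if (is.na(e$resolution) || e$resolution > resolution_cutoff) return(NULL)
  if (!is.na(cutoff_date) && !is.null(e$release_date) &&
      !is.na(e$release_date) && as.Date(e$release_date) > cutoff_date)
    return(NULL)
  chains <- unique(e$structure$atoms$chain)
  need <- c(e$peptide_chain, e$mhc_chains)
  if (!all(need %in% chains))
    stop("annotated chain(s) absent: ",
         paste(setdiff(need, chains), collapse = ","))
  pep <- extract_sequence(e$structure, e$peptide_chain)$sequence
  struct <- e$structure
  if (e$mhc_class == "II" && nchar(pep) > 11L) {
    core_start <- if (!is.null(e$core_start)) e$core_start
                  else (nchar(pep) - 9L) %/% 2L + 1L
    trimmed <- trim_class2_peptide(pep, core_start)
    # drop peptide-chain atoms outside the retained window
    from <- max(1L, core_start - 1L)
    res <- residue_table(struct, chain = e$peptide_chain)
    keep_resno <- res$resno[from:(from + nchar(trimmed) - 1L)]
    drop <- struct$atoms$chain == e$peptide_chain &
      !(struct$atoms$resno %in% keep_resno)
    struct$atoms <- struct$atoms[!drop, , drop = FALSE]
    pep <- trimmed
  }
  mhc_seq <- paste(vapply(e$mhc_chains, function(ch)
    extract_sequence(struct, ch)$sequence, ""), collapse = "")
  merged <- merge_pmhc_chains(struct, peptide_chain = e$peptide_chain,
                              mhc_chains = e$mhc_chains,
                              index_offset = index_offset)
  template_record(e$source_id, e$mhc_class, pep, mhc_seq,
                  e$resolution, e$release_date, merged)
}

#' @export
print.TemplateLibrary <- function(x, ...) {
  cls <- vapply(x$records, function(r) r$mhc_class, "")
  cat(sprintf("TemplateLibrary: %d records (Class I: %d, Class II: %d)\n",
              length(x$records), sum(cls == "I"), sum(cls == "II")))
  invisible(x)
}

#' Merge peptide and MHC chains into one index-shifted template chain
#'
#' The folding engine consumes a pMHC template as a single chain; the chain
#' break between MHC and peptide is encoded as a residue-index shift (the
#' ColabFold convention, default offset 200). Residues are renumbered
#' sequentially MHC-first (order configurable), the peptide starting
#' `index_offset` positions after the last MHC residue; coordinates are
#' untouched.
#'
#' @param model `StructureModel` holding the annotated chains.
#' @param peptide_chain peptide chain ID.
#' @param mhc_chains MHC chain ID(s), alpha then beta for Class II.
#' @param index_offset numbering gap at the chain break; must be >= 32 so
#'   the break cannot be mistaken for a loop deletion.
#' @param chain_id output chain label.
#' @param mhc_first put MHC before peptide in the merged numbering
#'   (default) or the reverse.
#' @return single-chain `StructureModel`; attribute `segments` records the
#'   (role, original chain, from, to) blocks for the inverse split.
#' @export
merge_pmhc_chains <- function(model, peptide_chain, mhc_chains,
                              index_offset = 200L, chain_id = "A",
                              mhc_first = TRUE) {
  index_offset <- as.integer(index_offset)
  if (index_offset < 32L)
    stop("index_offset must be >= 32 (got ", index_offset, ")")
  order_chains <- if (mhc_first) c(mhc_chains, peptide_chain)
                  else c(peptide_chain, mhc_chains)
  pieces <- list(); segments <- NULL; next_no <- 0L
  for (ch in order_chains) {
    at <- model$atoms[model$atoms$chain == ch, , drop = FALSE]
    if (!nrow(at)) stop("chain not present: ", ch)
    res <- unique(at$resno)
    # index shift at every chain boundary (peptide|MHC and, for Class II,
    # MHC alpha|beta)
    if (next_no > 0L) next_no <- next_no + index_offset
    new_no <- next_no + match(at$resno, res)
    segments <- rbind(segments, data.frame(
      role = if (ch == peptide_chain) "peptide" else "mhc",
      chain = ch, from = next_no + 1L, to = next_no + length(res),
      stringsAsFactors = FALSE))
    next_no <- next_no + length(res)
    at$resno <- new_no
    at$chain <- chain_id
    pieces[[length(pieces) + 1L]] <- at
  }
  merged <- structure_model(do.call(rbind, pieces),
                            resolution = model$resolution,
                            release_date = model$release_date,
                            source_id = model$source_id)
  attr(merged, "segments") <- segments
  merged
}

#' Split a merged pMHC chain back into its original chains
#'
#' Inverse of [merge_pmhc_chains()], using the segment table it attached.
#'
#' @param merged output of [merge_pmhc_chains()].
#' @return `StructureModel` with the original chain IDs restored.
#' @export
split_pmhc_chains <- function(merged) {
  seg <- attr(merged, "segments")
  if (is.null(seg)) stop("no segment table: not a merged pMHC chain")
  at <- merged$atoms
  out <- lapply(seq_len(nrow(seg)), function(i) {
    blk <- at[at$resno >= seg$from[i] & at$resno <= seg$to[i], , drop = FALSE]
    blk$chain <- seg$chain[i]
    blk$resno <- blk$resno - seg$from[i] + 1L
    blk
  })
  structure_model(do.call(rbind, out), resolution = merged$resolution,
                  release_date = merged$release_date,
                  source_id = merged$source_id)
}

#' Select ranked pMHC templates for a query
#'
#' Candidates are restricted to the query's MHC class and to peptides of
#' exactly the query peptide length, then ranked by MHC similarity score
#' (descending), peptide similarity score (descending, flat -100 gap
#' penalty so equal-length scoring is ungapped), and `source_id`
#' (ascending) as the deterministic tie-break.
#'
#' @param query_peptide,query_mhc query sequences (Class II MHC: alpha then
#'   beta concatenated).
#' @param library a `TemplateLibrary`.
#' @param mhc_class `"I"` or `"II"`.
#' @param k maximum number of templates to return (default 4).
#' @return data.frame with columns `source_id`, `mhc_score`,
#'   `peptide_score`, `rank`; attribute `records` carries the matching
#'   `TemplateRecord`s in rank order. Zero rows (with a message) when no
#'   candidate matches the peptide length.
#' @export
select_pmhc_templates <- function(query_peptide, query_mhc, library,
                                  mhc_class = c("I", "II"), k = 4L) {
  mhc_class <- match.arg(mhc_class)
  stopifnot(k >= 1L)
  query_peptide <- .as_seq(query_peptide); query_mhc <- .as_seq(query_mhc)
  recs <- Filter(function(r) r$mhc_class == mhc_class &&
                   nchar(r$peptide_seq) == nchar(query_peptide),
                 library$records)
  if (!length(recs)) {
    message("no template with a length-", nchar(query_peptide),
            " peptide in Class ", mhc_class,
            "; prediction can proceed template-free")
    out <- data.frame(source_id = character(), mhc_score = numeric(),
                      peptide_score = numeric(), rank = integer())
    attr(out, "records") <- list()
    return(out)
  }
  mhc_sc <- vapply(recs, function(r)
    score_similarity(query_mhc, r$mhc_seq, similarity_params()), 0)
  pep_sc <- vapply(recs, function(r)
    score_similarity(query_peptide, r$peptide_seq,
                     peptide_similarity_params()), 0)
  ids <- vapply(recs, function(r) r$source_id, "")
  ord <- order(-mhc_sc, -pep_sc, ids)
  keep <- ord[seq_len(min(k, length(ord)))]
  out <- data.frame(source_id = ids[keep], mhc_score = mhc_sc[keep],
                    peptide_score = pep_sc[keep],
                    rank = seq_along(keep), stringsAsFactors = FALSE)
  attr(out, "records") <- recs[keep]
  out
}

#' Select TCR chain templates by single-sequence identity
#'
#' The query chain sequence itself (never an MSA-derived profile) is
#' globally aligned against every candidate, and candidates are ranked by
#' percent identity (matches over full alignment length, gaps counted in
#' the denominator). Ties break by `source_id` ascending.
#'
#' @param query_chain `ChainSequence` or string.
#' @param chain_db data.frame with columns `source_id`, `sequence` (one row
#'   per candidate chain).
#' @param k maximum number of hits.
#' @return data.frame with columns `source_id`, `identity`, `rank`.
#' @export
select_tcr_templates <- function(query_chain, chain_db, k = 4L) {
  q <- .as_seq(query_chain)
  if (!nzchar(q)) stop("empty query sequence")
  if (!nrow(chain_db)) stop("chain_db is empty")
  idy <- vapply(seq_len(nrow(chain_db)), function(i)
    sequence_identity(q, chain_db$sequence[i]), 0)
  ord <- order(-idy, chain_db$source_id)
  keep <- ord[seq_len(min(k, length(ord)))]
  data.frame(source_id = chain_db$source_id[keep], identity = idy[keep],
             rank = seq_along(keep), stringsAsFactors = FALSE)
}

#' Assemble focused MSA databases from tagged hit sets
#'
#' The folding engine's genetic search is pointed at small focused FASTA
#' databases instead of the full public ones: all hits obtained by seeding
#' searches with representative TCR and MHC sequences are merged per target
#' database, duplicate IDs removed (first occurrence kept).
#'
#' @param hit_sets named list: database name (e.g. `small_bfd_like`,
#'   `uniref90_like`, `uniprot_like`) mapping to a list of hit sets, each a
#'   named character vector of sequences (names are FASTA IDs) or an
#'   `AAStringSet`.
#' @return named list of `AAStringSet` focused databases.
#' @export
build_focused_dbs <- function(hit_sets) {
  out <- lapply(hit_sets, function(sets) {
    if (!is.list(sets)) sets <- list(sets)
    seqs <- character(); ids <- character()
    for (s in sets) {
      if (inherits(s, "AAStringSet")) s <- as.character(s)
      if (!length(s)) next
      if (is.null(names(s)) || any(!nzchar(names(s))))
        stop("hit set contains a record with no ID")
      if (any(!nzchar(s)))
        stop("hit set contains an empty sequence for ID ",
             names(s)[!nzchar(s)][1L])
      keep <- !(names(s) %in% ids)
      ids <- c(ids, names(s)[keep]); seqs <- c(seqs, s[keep])
    }
    Biostrings::AAStringSet(stats::setNames(seqs, ids))
  })
  out
}

#' Write focused databases as FASTA files
#' @param dbs output of [build_focused_dbs()].
#' @param dir output directory (created if needed).
#' @return named character vector of file paths.
#' @export
write_focused_dbs <- function(dbs, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- vapply(names(dbs), function(nm) {
    p <- file.path(dir, paste0(nm, ".fasta"))
    Biostrings::writeXStringSet(dbs[[nm]], p)
    p
  }, "")
  paths
}

#' Write a TemplateLibrary to disk
#'
#' One merged-template PDB per record plus a tab-separated index
#' (`source_id`, `mhc_class`, `peptide_seq`, `mhc_seq`, `resolution`,
#' `release_date`).
#'
#' @param library a `TemplateLibrary`.
#' @param dir output directory.
#' @return the index file path, invisibly.
#' @export
write_template_library <- function(library, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  idx <- do.call(rbind, lapply(library$records, function(r) {
    if (!is.null(r$merged_structure))
      write_structure(r$merged_structure,
                      file.path(dir, paste0(r$source_id, ".pdb")))
    data.frame(source_id = r$source_id, mhc_class = r$mhc_class,
               peptide_seq = r$peptide_seq, mhc_seq = r$mhc_seq,
               resolution = r$resolution,
               release_date = as.character(r$release_date),
               stringsAsFactors = FALSE)
  }))
  if (is.null(idx))
    idx <- data.frame(source_id = character(), mhc_class = character(),
                      peptide_seq = character(), mhc_seq = character(),
                      resolution = numeric(), release_date = character())
  path <- file.path(dir, "templates.tsv")
  utils::write.table(idx, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
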