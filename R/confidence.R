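# Model-quality scores computed from predictor outputs: pTM, ipTM,
# TCR-pMHC group ipTM, model confidence, CDR3 pLDDT; ranking and
# cutoff-based classification.

#' Construct a PredictionOutput
#'
#' One predictor result: coordinates, per-residue pLDDT, the N x N
#' predicted-aligned-error (PAE) matrix and the per-residue chain
#' assignment. Residue order follows the structure's atom order.
#'
#' @param structure a `StructureModel`.
#' @param plddt numeric vector in `[0, 100]`, one value per residue.
#' @param pae N x N nonnegative matrix, N = residue count; `pae[i, j]` is
#'   the expected position error (Angstrom) of residue j when the
#'   prediction is aligned on residue i.
#' @param chain_assignment per-residue chain label; defaults to the
#'   structure's chains.
#' @param model_name text identifier.
#' @return object of class `PredictionOutput`.
#' @export
prediction_output <- function(structure, plddt, pae, chain_assignment = NULL,
                              model_name = "model") {
  res <- residue_table(structure)
  n <- nrow(res)
  if (is.null(chain_assignment)) chain_assignment <- res$chain
  if (length(plddt) != n)
    stop("plddt length ", length(plddt), " != residue count ", n)
  if (any(plddt < 0 | plddt > 100)) stop("plddt values must lie in [0, 100]")
  pae <- as.matrix(pae)
  if (nrow(pae) != n || ncol(pae) != n)
    stop("pae must be ", n, " x ", n, ", got ", nrow(pae), " x ", ncol(pae))
  if (any(pae < 0)) stop("pae entries must be nonnegative")
  if (length(chain_assignment) != n)
    stop("chain_assignment length != residue count")
  structure(list(structure = structure, plddt = as.numeric(plddt),
                 pae = pae, chain_assignment = as.character(chain_assignment),
                 model_name = model_name),
            class = "PredictionOutput")
}

#' @export
print.PredictionOutput <- function(x, ...) {
  cat(sprintf("PredictionOutput '%s': %d residues, %d chain(s), mean pLDDT %.1f\n",
              x$model_name, length(x$plddt),
              length(unique(x$chain_assignment)), mean(x$plddt)))
  invisible(x)
}

# TM-score normalisation length constant; clamped below at 1.0.
# d0(N) = 1.24 (N - 15)^(1/3) - 1.8, which falls below 1 for N <= 26.
.tm_d0 <- function(n) {
  if (n > 26) 1.24 * (n - 15)^(1 / 3) - 1.8 else 1.0
}

#' Predicted TM-score from a PAE matrix
#'
#' The pTM estimator: for each alignment residue i, average
#' `1 / (1 + (pae[i, j] / d0)^2)` over the scored residues j, and take the
#' maximum over i. `d0` is the TM-score normalisation
#' `1.24 (N - 15)^(1/3) - 1.8` (clamped below at 1), with N the number of
#' residues participating in scored pairs. An optional pair mask restricts
#' which (i, j) contribute, which is how the interface variants are built.
#'
#' @param pae square PAE matrix.
#' @param pair_mask optional logical matrix of the same shape; only `TRUE`
#'   pairs are scored.
#' @return score in `[0, 1]`.
#' @export
compute_ptm <- function(pae, pair_mask = NULL) {
  pae <- as.matrix(pae)
  if (nrow(pae) != ncol(pae))
    stop("pae must be square, got ", nrow(pae), " x ", ncol(pae))
  n_total <- nrow(pae)
  if (is.null(pair_mask)) {
    pair_mask <- matrix(TRUE, n_total, n_total)
  } else {
    pair_mask <- as.matrix(pair_mask)
    if (!identical(dim(pair_mask), dim(pae)))
      stop("pair_mask dimensions differ from pae")
  }
  participates <- rowSums(pair_mask) > 0 | colSums(pair_mask) > 0
  n_scored <- sum(participates)
  if (n_scored < 2L) stop("fewer than 2 residues participate in scored pairs")
  d0 <- .tm_d0(n_scored)
  term <- 1 / (1 + (pae / d0)^2)
  term[!pair_mask] <- 0
  counts <- rowSums(pair_mask)
  vals <- rowSums(term)[counts > 0] / counts[counts > 0]
  max(vals)
}

#' Interface pTM (ipTM) across all chain pairs
#'
#' pTM restricted to residue pairs whose chain assignments differ; with the
#' full four-chain complex this spans every interface (peptide-MHC, TCR
#' alpha-beta, TCR-pMHC).
#'
#' @param pred a `PredictionOutput` with at least two chains.
#' @return score in `[0, 1]`.
#' @export
compute_iptm <- function(pred) {
  stopifnot(inherits(pred, "PredictionOutput"))
  ch <- pred$chain_assignment
  if (length(unique(ch)) < 2L)
    stop("ipTM needs at least two chains; got ", unique(ch))
  compute_ptm(pred$pae, outer(ch, ch, `!=`))
}

#' Group ipTM (e.g. TCR vs pMHC)
#'
#' pTM restricted to residue pairs whose group labels differ. Relabelling
#' the complex so that the TCR and the pMHC are each one super-chain and
#' computing ipTM yields exactly this score, which isolates the TCR-pMHC
#' docking interface from the intra-partner interfaces that the default
#' ipTM mixes in.
#'
#' @param pred a `PredictionOutput`.
#' @param groups per-residue group labels (at least two groups, each
#'   nonempty), e.g. `"TCR"` / `"pMHC"`.
#' @return score in `[0, 1]`.
#' @export
compute_group_iptm <- function(pred, groups) {
  stopifnot(inherits(pred, "PredictionOutput"))
  groups <- as.character(groups)
  if (length(groups) != length(pred$plddt))
    stop("groups must label every residue")
  if (any(table(groups) == 0L) || length(unique(groups)) < 2L)
    stop("need at least two nonempty groups")
  compute_ptm(pred$pae, outer(groups, groups, `!=`))
}

#' Model confidence: 0.2 pTM + 0.8 ipTM
#'
#' The ranking score: a fixed linear combination weighting the interface
#' term four times the global term.
#'
#' @param ptm,iptm scores in `[0, 1]`.
#' @return score in `[0, 1]`.
#' @export
model_confidence <- function(ptm, iptm) {
  if (any(ptm < 0 | ptm > 1) || any(iptm < 0 | iptm > 1))
    stop("ptm and iptm must lie in [0, 1]")
  0.2 * ptm + 0.8 * iptm
}

#' Mean pLDDT over CDR3 loop residues
#'
#' @param pred a `PredictionOutput`.
#' @param loop_ranges named list; each element `list(chain =, from =, to =)`
#'   giving an inclusive author-numbering residue range on one chain.
#' @return named numeric vector of per-loop mean pLDDT.
#' @export
cdr3_plddt <- function(pred, loop_ranges) {
  stopifnot(inherits(pred, "PredictionOutput"))
  res <- residue_table(pred$structure)
  vapply(loop_ranges, function(lr) {
    sel <- res$chain == lr$chain & res$resno >= lr$from & res$resno <= lr$to
    if (!any(sel))
      stop("empty loop range ", lr$chain, ":", lr$from, "-", lr$to)
    mean(pred$plddt[sel])
  }, 0)
}

#' Summarise all confidence scores for one prediction
#'
#' @param pred a `PredictionOutput`.
#' @param groups optional per-residue TCR/pMHC group labels for the group
#'   ipTM (skipped when `NULL`, e.g. unbound-TCR runs).
#' @param loop_ranges optional CDR3 loop ranges for [cdr3_plddt()].
#' @return object of class `ConfidenceSummary`: `model_name`, `mean_plddt`,
#'   `ptm`, `iptm`, `tcr_pmhc_iptm`, `model_confidence`, `cdr3_plddt`.
#' @export
confidence_summary <- function(pred, groups = NULL, loop_ranges = NULL) {
  ptm <- compute_ptm(pred$pae)
  multi <- length(unique(pred$chain_assignment)) > 1L
  iptm <- if (multi) compute_iptm(pred) else NA_real_
  gi <- if (!is.null(groups)) compute_group_iptm(pred, groups) else NA_real_
  conf <- if (multi) model_confidence(ptm, iptm) else ptm
  loops <- if (!is.null(loop_ranges)) cdr3_plddt(pred, loop_ranges)
           else stats::setNames(numeric(), character())
  structure(list(model_name = pred$model_name, mean_plddt = mean(pred$plddt),
                 ptm = ptm, iptm = iptm, tcr_pmhc_iptm = gi,
                 model_confidence = conf, cdr3_plddt = loops),
            class = "ConfidenceSummary")
}

#' @export
print.ConfidenceSummary <- function(x, ...) {
  cat(sprintf("ConfidenceSummary '%s': confidence %.3f (pTM %.3f, ipTM %s, TCR-pMHC ipTM %s)\n",
              x$model_name, x$model_confidence, x$ptm,
              ifelse(is.na(x$iptm), "-", sprintf("%.3f", x$iptm)),
              ifelse(is.na(x$tcr_pmhc_iptm), "-",
                     sprintf("%.3f", x$tcr_pmhc_iptm))))
  invisible(x)
}

#' Rank models by model confidence
#'
#' Descending by `model_confidence`, ties broken by `model_name` ascending;
#' rank 1 is the top model.
#'
#' @param summaries list of `ConfidenceSummary`.
#' @return the list reordered, each element gaining a `rank` field.
#' @export
rank_models <- function(summaries) {
  if (!length(summaries)) stop("no summaries to rank")
  conf <- vapply(summaries, function(s) s$model_confidence, 0)
  nm <- vapply(summaries, function(s) s$model_name, "")
  ord <- order(-conf, nm)
  out <- summaries[ord]
  for (i in seq_along(out)) out[[i]]$rank <- i
  out
}

#' Confidence cutoffs for model classification
#'
#' Defaults are the published operating points: models with confidence
#' >= 0.85 are likely accurate and <= 0.49 likely inaccurate (both bounds
#' inclusive).
#'
#' @param accurate_min lower bound of the likely-accurate band.
#' @param inaccurate_max upper bound of the likely-inaccurate band.
#' @return object of class `ConfidenceCutoffs`.
#' @export
confidence_cutoffs <- function(accurate_min = 0.85, inaccurate_max = 0.49) {
  if (!(inaccurate_max >= 0 && inaccurate_max < accurate_min &&
        accurate_min <= 1))
    stop("require 0 <= inaccurate_max < accurate_min <= 1")
  structure(list(accurate_min = accurate_min, inaccurate_max = inaccurate_max),
            class = "ConfidenceCutoffs")
}

#' Classify a model-confidence score
#'
#' @param score model confidence in `[0, 1]` (vectorised).
#' @param cutoffs a `ConfidenceCutoffs`.
#' @return character vector in `likely_accurate`, `indeterminate`,
#'   `likely_inaccurate`.
#' @export
classify_confidence <- function(score, cutoffs = confidence_cutoffs()) {
  if (any(score < 0 | score > 1)) stop("score must lie in [0, 1]")
  ifelse(score >= cutoffs$accurate_min, "likely_accurate",
         ifelse(score <= cutoffs$inaccurate_max, "likely_inaccurate",
                "indeterminate"))
}

#' Read a PredictionOutput from a PDB file plus a JSON sidecar
#'
#' Reference ingestion dialect: the JSON holds `pae` (N x N array),
#' `plddt` (length N), optionally `chains` (length N) and `model_name`.
#'
#' @param structure_path PDB/mmCIF file.
#' @param json_path JSON sidecar path.
#' @return a `PredictionOutput`.
#' @export
read_prediction_json <- function(structure_path, json_path) {
  model <- read_structure(structure_path)
  j <- jsonlite::fromJSON(json_path)
  if (is.null(j$pae) || is.null(j$plddt))
    stop("JSON sidecar must contain 'pae' and 'plddt'")
  prediction_output(model, plddt = as.numeric(j$plddt),
                    pae = as.matrix(j$pae),
                    chain_assignment = if (!is.null(j$chains)) j$chains,
                    model_name = if (!is.null(j$model_name)) j$model_name
                                 else sub("\\.[^.]+$", "",
                                          basename(structure_path)))
}

#' Write a TSV confidence report
#'
#' @param summaries list of `ConfidenceSummary` (ranked or not).
#' @param path output TSV path.
#' @param cutoffs `ConfidenceCutoffs` used for the `class` column.
#' @return the report data.frame, invisibly.
#' @export
write_confidence_report <- function(summaries, path,
                                    cutoffs = confidence_cutoffs()) {
  loops <- sort(unique(unlist(lapply(summaries,
                                     function(s) names(s$cdr3_plddt)))))
  df <- do.call(rbind, lapply(summaries, function(s) {
    row <- data.frame(model_name = s$model_name,
                      mean_plddt = s$mean_plddt, ptm = s$ptm, iptm = s$iptm,
                      tcr_pmhc_iptm = s$tcr_pmhc_iptm,
                      model_confidence = s$model_confidence,
                      class = classify_confidence(s$model_confidence, cutoffs),
                      stringsAsFactors = FALSE)
    for (l in loops)
      row[[paste0(l, "_plddt")]] <-
        if (l %in% names(s$cdr3_plddt)) s$cdr3_plddt[[l]] else NA_real_
    row
  }))
  utils::write.table(format(df, digits = 6, trim = TRUE), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(df)
}
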