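# Docking accuracy metrics (Fnat, I-RMSD, L-RMSD, DockQ, CAPRI class),
# peptide-MHC interface assessment, CDR loop RMSD, benchmark redundancy
# filtering and confidence-vs-accuracy discrimination statistics.

#' Load the CAPRI threshold configuration
#'
#' Thresholds are shipped as a versioned JSON config rather than hard-coded
#' so that alternative tables can be swapped in.
#'
#' @param path config file; defaults to the packaged table.
#' @return list with elements `protein_protein`, `peptide`,
#'   `contact_cutoff`, `interface_cutoff`, `version`.
#' @export
capri_config <- function(path = system.file("extdata",
                                            "capri_thresholds.json",
                                            package = "tcrpmhc")) {
  jsonlite::fromJSON(path)
}

# squared-distance cross matrix
.cross_dist2 <- function(a, b) {
  outer(rowSums(a^2), rowSums(b^2), `+`) - 2 * tcrossprod(a, b)
}

#' Residue contacts across a binding interface
#'
#' All cross-partner residue pairs with any heavy-atom pair within the
#' cutoff (hydrogens, if present, are ignored).
#'
#' @param model a `StructureModel` holding both partners.
#' @param receptor_chains,ligand_chains chain IDs of the two partners.
#' @param cutoff heavy-atom distance cutoff in Angstrom (default 5, the
#'   DockQ Fnat convention).
#' @return data.frame with columns `rec_chain`, `rec_resno`, `lig_chain`,
#'   `lig_resno`, one row per contacting residue pair.
#' @export
interface_contacts <- function(model, receptor_chains, ligand_chains,
                               cutoff = 5) {
  at <- model$atoms[!grepl("^H", model$atoms$elety), , drop = FALSE]
  rec <- at[at$chain %in% receptor_chains, , drop = FALSE]
  lig <- at[at$chain %in% ligand_chains, , drop = FALSE]
  if (!nrow(rec) || !nrow(lig)) stop("a partner has no atoms")
  d2 <- .cross_dist2(as.matrix(rec[, c("x", "y", "z")]),
                     as.matrix(lig[, c("x", "y", "z")]))
  hit <- which(d2 <= cutoff^2, arr.ind = TRUE)
  if (!nrow(hit))
    return(data.frame(rec_chain = character(), rec_resno = integer(),
                      lig_chain = character(), lig_resno = integer()))
  pairs <- unique(data.frame(
    rec_chain = rec$chain[hit[, 1]], rec_resno = rec$resno[hit[, 1]],
    lig_chain = lig$chain[hit[, 2]], lig_resno = lig$resno[hit[, 2]],
    stringsAsFactors = FALSE))
  rownames(pairs) <- NULL
  pairs
}

.contact_keys <- function(contacts) {
  paste(contacts$rec_chain, contacts$rec_resno,
        contacts$lig_chain, contacts$lig_resno)
}

#' Fraction of native contacts reproduced by a model (Fnat)
#'
#' @param native,model `StructureModel`s sharing chain IDs and residue
#'   numbering.
#' @param receptor_chains,ligand_chains partner chain IDs.
#' @param cutoff contact cutoff in Angstrom (default 5).
#' @return fraction in `[0, 1]`.
#' @export
compute_fnat <- function(native, model, receptor_chains, ligand_chains,
                         cutoff = 5) {
  nat <- interface_contacts(native, receptor_chains, ligand_chains, cutoff)
  if (!nrow(nat))
    stop("native structure has no interface contacts; Fnat undefined")
  mod <- interface_contacts(model, receptor_chains, ligand_chains, cutoff)
  mean(.contact_keys(nat) %in% .contact_keys(mod))
}

# native interface residues: any heavy atom within cutoff of the partner
.interface_residues <- function(native, receptor_chains, ligand_chains,
                                cutoff) {
  contacts <- interface_contacts(native, receptor_chains, ligand_chains,
                                 cutoff)
  if (!nrow(contacts)) stop("no interface residues within ", cutoff, " A")
  unique(rbind(
    stats::setNames(contacts[, c("rec_chain", "rec_resno")],
                    c("chain", "resno")),
    stats::setNames(contacts[, c("lig_chain", "lig_resno")],
                    c("chain", "resno"))))
}

#' Interface backbone RMSD (I-RMSD)
#'
#' Backbone (N, CA, C, O) RMSD over the native interface residues (any
#' heavy atom within `interface_cutoff` of the partner, default 10 A per
#' the DockQ convention), after optimal superposition on those same atoms.
#'
#' @inheritParams compute_fnat
#' @param interface_cutoff interface-residue selection cutoff in Angstrom.
#' @return RMSD in Angstrom.
#' @export
compute_irmsd <- function(native, model, receptor_chains, ligand_chains,
                          interface_cutoff = 10) {
  ires <- .interface_residues(native, receptor_chains, ligand_chains,
                              interface_cutoff)
  key <- paste(ires$chain, ires$resno)
  sel <- function(m) {
    at <- m$atoms
    at[paste(at$chain, at$resno) %in% key &
         at$elety %in% backbone_atoms(), , drop = FALSE]
  }
  a <- structure_model(sel(native)); b <- structure_model(sel(model))
  pair <- .match_atoms(a, b)
  if (pair$n < 3L) stop("fewer than 3 matched interface backbone atoms")
  superpose(pair$a, pair$b)$rmsd
}

#' Ligand backbone RMSD (L-RMSD)
#'
#' Superpose model on native using the receptor backbone, then report the
#' backbone RMSD of the ligand without further fitting.
#'
#' @inheritParams compute_fnat
#' @return RMSD in Angstrom.
#' @export
compute_lrmsd <- function(native, model, receptor_chains, ligand_chains) {
  for (ch in c(receptor_chains, ligand_chains))
    if (!ch %in% model$atoms$chain || !ch %in% native$atoms$chain)
      stop("chain missing from partition: ", ch)
  rec <- .match_atoms(native, model, chain = receptor_chains,
                      elety = backbone_atoms())
  if (rec$n < 3L) stop("fewer than 3 matched receptor backbone atoms")
  sp <- superpose(rec$a, rec$b)
  lig <- .match_atoms(native, model, chain = ligand_chains,
                      elety = backbone_atoms())
  if (!lig$n) stop("no matched ligand backbone atoms")
  rmsd_nofit(lig$a, apply_superposition(sp, lig$b))
}

#' DockQ score
#'
#' Mean of Fnat and the scaled RMSD terms `1 / (1 + (irmsd / 1.5)^2)` and
#' `1 / (1 + (lrmsd / 8.5)^2)`.
#'
#' @param fnat fraction in `[0, 1]`.
#' @param irmsd,lrmsd Angstrom, nonnegative.
#' @return score in `[0, 1]` (vectorised).
#' @export
dockq_score <- function(fnat, irmsd, lrmsd) {
  if (any(fnat < 0 | fnat > 1) || any(irmsd < 0) || any(lrmsd < 0))
    stop("metrics out of range")
  (fnat + 1 / (1 + (irmsd / 1.5)^2) + 1 / (1 + (lrmsd / 8.5)^2)) / 3
}

#' CAPRI accuracy class from the three docking metrics
#'
#' Tiers are tested from High down; each requires `fnat >= fnat_min` and
#' (`lrmsd <= lrmsd_max` or `irmsd <= irmsd_max`). Models satisfying no
#' tier are Incorrect.
#'
#' @param fnat,irmsd,lrmsd docking metrics.
#' @param thresholds a tier table (named list High/Medium/Acceptable) from
#'   [capri_config()]; defaults to the protein-protein table.
#' @return one of `"High"`, `"Medium"`, `"Acceptable"`, `"Incorrect"`.
#' @export
capri_class <- function(fnat, irmsd, lrmsd,
                        thresholds = capri_config()$protein_protein) {
  stopifnot(is.finite(fnat), is.finite(irmsd), is.finite(lrmsd))
  for (cls in c("High", "Medium", "Acceptable")) {
    th <- thresholds[[cls]]
    if (fnat >= th$fnat_min &&
        (lrmsd <= th$lrmsd_max || irmsd <= th$irmsd_max))
      return(cls)
  }
  "Incorrect"
}

#' Full docking assessment of a model against its native structure
#'
#' Receptor = pMHC, ligand = TCR in the complex-level convention.
#'
#' @inheritParams compute_fnat
#' @param config threshold configuration from [capri_config()].
#' @param thresholds which tier table to classify with
#'   (`"protein_protein"` or `"peptide"`).
#' @return object of class `DockingAssessment`: `fnat`, `irmsd`, `lrmsd`,
#'   `dockq`, `capri_class`.
#' @export
assess_docking <- function(native, model, receptor_chains, ligand_chains,
                           config = capri_config(),
                           thresholds = "protein_protein") {
  fnat <- compute_fnat(native, model, receptor_chains, ligand_chains,
                       cutoff = config$contact_cutoff)
  irmsd <- compute_irmsd(native, model, receptor_chains, ligand_chains,
                         interface_cutoff = config$interface_cutoff)
  lrmsd <- compute_lrmsd(native, model, receptor_chains, ligand_chains)
  structure(list(fnat = fnat, irmsd = irmsd, lrmsd = lrmsd,
                 dockq = dockq_score(fnat, irmsd, lrmsd),
                 capri_class = capri_class(fnat, irmsd, lrmsd,
                                           config[[thresholds]])),
            class = "DockingAssessment")
}

#' @export
print.DockingAssessment <- function(x, ...) {
  cat(sprintf("DockingAssessment: %s (Fnat %.3f, I-RMSD %.2f A, L-RMSD %.2f A, DockQ %.3f)\n",
              x$capri_class, x$fnat, x$irmsd, x$lrmsd, x$dockq))
  invisible(x)
}

#' Peptide-MHC interface assessment
#'
#' Receptor = MHC, ligand = peptide; classified with the stricter CAPRI
#' peptide-docking tiers to flag models whose peptide is partially or
#' fully displaced from the groove (peptide class Incorrect).
#'
#' @param native,model `StructureModel`s of the pMHC (complex chains may
#'   be present; only the named ones are used).
#' @param mhc_chains,peptide_chain chain IDs.
#' @param config threshold configuration.
#' @return `DockingAssessment` classified on the peptide tier table.
#' @export
assess_peptide_dock <- function(native, model, mhc_chains, peptide_chain,
                                config = capri_config()) {
  assess_docking(native, model, receptor_chains = mhc_chains,
                 ligand_chains = peptide_chain, config = config,
                 thresholds = "peptide")
}

#' CDR loop backbone RMSD after framework superposition
#'
#' The model is superposed onto the native once, on the pooled framework
#' backbone atoms of both TCR chains, and each CDR loop's backbone RMSD is
#' then measured without re-fitting.
#'
#' @param native_tcr,model_tcr `StructureModel`s numbered in the same
#'   scheme.
#' @param loops list of loop definitions, each
#'   `list(loop_name =, chain =, from =, to =)` (inclusive residue range).
#' @param framework list of framework masks, each
#'   `list(chain =, resno = <vector>)`; these positions must be disjoint
#'   from every loop range.
#' @return named numeric vector of per-loop RMSD (Angstrom); loops whose
#'   residues are missing in either structure come back `NA` with a
#'   warning.
#' @export
cdr_loop_rmsd <- function(native_tcr, model_tcr, loops, framework) {
  fw_key <- unlist(lapply(framework, function(f) paste(f$chain, f$resno)))
  for (lp in loops) {
    lp_key <- paste(lp$chain, lp$from:lp$to)
    if (any(lp_key %in% fw_key))
      stop("loop ", lp$loop_name, " overlaps the framework mask")
  }
  sel <- function(m, keys) {
    at <- m$atoms
    structure_model(at[paste(at$chain, at$resno) %in% keys &
                         at$elety %in% backbone_atoms(), , drop = FALSE])
  }
  fw <- .match_atoms(sel(native_tcr, fw_key), sel(model_tcr, fw_key))
  if (fw$n < 3L) stop("fewer than 3 matched framework backbone atoms")
  sp <- superpose(fw$a, fw$b)
  out <- vapply(loops, function(lp) {
    keys <- paste(lp$chain, lp$from:lp$to)
    pair <- tryCatch(.match_atoms(sel(native_tcr, keys), sel(model_tcr, keys)),
                     error = function(e) list(n = 0L))
    if (!pair$n) {
      warning("loop ", lp$loop_name, " has no matched atoms; RMSD undefined",
              call. = FALSE)
      return(NA_real_)
    }
    rmsd_nofit(pair$a, apply_superposition(sp, pair$b))
  }, 0)
  names(out) <- vapply(loops, function(lp) lp$loop_name, "")
  out
}

#' Benchmark redundancy thresholds
#'
#' @param chain_identity_max single-chain (V alpha or V beta) identity at
#'   or above which two cases are redundant (default 0.95).
#' @param domain_identity_max concatenated V-domain identity threshold
#'   (default 0.92).
#' @return object of class `RedundancyThresholds`.
#' @export
redundancy_thresholds <- function(chain_identity_max = 0.95,
                                  domain_identity_max = 0.92) {
  stopifnot(chain_identity_max > 0, chain_identity_max <= 1,
            domain_identity_max > 0, domain_identity_max <= 1)
  structure(list(chain_identity_max = chain_identity_max,
                 domain_identity_max = domain_identity_max),
            class = "RedundancyThresholds")
}

#' Construct a benchmark candidate case
#'
#' @param source_id PDB-style code.
#' @param mhc_class `"I"` or `"II"`.
#' @param release_date `Date` or string.
#' @param resolution Angstrom.
#' @param alpha_seq,beta_seq TCR V-domain sequences.
#' @param has_modified_peptide does the peptide carry modified amino acids
#'   (citrullination, lipopeptide, ...)? Such cases are excluded.
#' @return object of class `BenchmarkCase`.
#' @export
benchmark_case <- function(source_id, mhc_class, release_date, resolution,
                           alpha_seq, beta_seq, has_modified_peptide = FALSE) {
  structure(list(source_id = source_id,
                 mhc_class = match.arg(mhc_class, c("I", "II")),
                 release_date = as.Date(release_date),
                 resolution = as.numeric(resolution),
                 alpha_seq = alpha_seq, beta_seq = beta_seq,
                 has_modified_peptide = isTRUE(has_modified_peptide)),
            class = "BenchmarkCase")
}

#' Are two benchmark cases redundant?
#'
#' Redundant iff they share the MHC class and any of: V alpha identity >=
#' the chain threshold, V beta identity >= the chain threshold, or
#' concatenated (alpha then beta) V-domain identity >= the domain
#' threshold.
#'
#' @param case_a,case_b `BenchmarkCase` objects.
#' @param t a `RedundancyThresholds`.
#' @return logical.
#' @export
is_redundant <- function(case_a, case_b, t = redundancy_thresholds()) {
  for (cs in list(case_a, case_b))
    if (is.null(cs$alpha_seq) || is.null(cs$beta_seq) ||
        !nzchar(cs$alpha_seq) || !nzchar(cs$beta_seq))
      stop("case ", cs$source_id, " is missing a V-domain sequence")
  if (case_a$mhc_class != case_b$mhc_class) return(FALSE)
  sequence_identity(case_a$alpha_seq, case_b$alpha_seq) >=
    t$chain_identity_max ||
    sequence_identity(case_a$beta_seq, case_b$beta_seq) >=
      t$chain_identity_max ||
    sequence_identity(paste0(case_a$alpha_seq, case_a$beta_seq),
                      paste0(case_b$alpha_seq, case_b$beta_seq)) >=
      t$domain_identity_max
}

#' Assemble a nonredundant benchmark set
#'
#' Keeps candidates released strictly after `date_cutoff`, at resolution
#' `<= resolution_cutoff`, without modified peptides, not redundant with
#' any reference case (structures from on or before the cutoff), and
#' greedily nonredundant among themselves in `source_id` order.
#'
#' @param candidates list of `BenchmarkCase`.
#' @param reference list of `BenchmarkCase` already-known structures.
#' @param date_cutoff `Date` or string.
#' @param resolution_cutoff Angstrom (default 3.25).
#' @param t a `RedundancyThresholds`.
#' @return list of accepted `BenchmarkCase`, in `source_id` order.
#' @export
assemble_benchmark <- function(candidates, reference = list(),
                               date_cutoff, resolution_cutoff = 3.25,
                               t = redundancy_thresholds()) {
  date_cutoff <- as.Date(date_cutoff)
  ids <- vapply(candidates, function(cs) cs$source_id, "")
  candidates <- candidates[order(ids)]
  accepted <- list()
  for (cs in candidates) {
    if (cs$release_date <= date_cutoff) next
    if (cs$resolution > resolution_cutoff) next
    if (cs$has_modified_peptide) next
    clash <- any(vapply(c(reference, accepted),
                        function(other) is_redundant(cs, other, t), TRUE))
    if (!clash) accepted[[length(accepted) + 1L]] <- cs
  }
  accepted
}

#' Confidence-vs-accuracy discrimination statistics
#'
#' Rank-based ROC AUC (probability that a positive outranks a negative,
#' ties counted one half) for discriminating Medium-or-High models from
#' Incorrect ones -- Acceptable models are excluded from the AUC -- plus
#' the Pearson correlation of confidence against DockQ when DockQ values
#' are supplied.
#'
#' @param scores per-model confidence scores.
#' @param labels per-model CAPRI classes (`High`, `Medium`, `Acceptable`,
#'   `Incorrect`).
#' @param dockq optional per-model DockQ scores for the correlation.
#' @return list with `roc_auc`, `pearson_r`, `n_positive`, `n_negative`.
#' @export
evaluate_discrimination <- function(scores, labels, dockq = NULL) {
  stopifnot(length(scores) == length(labels))
  if (length(scores) < 2L) stop("need at least 2 models")
  pos <- labels %in% c("Medium", "High")
  neg <- labels == "Incorrect"
  if (!any(pos) || !any(neg))
    stop("AUC undefined: need both positive (Medium/High) and negative ",
         "(Incorrect) models")
  s <- scores[pos | neg]
  p <- pos[pos | neg]
  r <- rank(s)
  auc <- (sum(r[p]) - sum(p) * (sum(p) + 1) / 2) / (sum(p) * sum(!p))
  pearson <- if (!is.null(dockq)) {
    stopifnot(length(dockq) == length(scores))
    stats::cor(scores, dockq, method = "pearson")
  } else NA_real_
  list(roc_auc = auc, pearson_r = pearson,
       n_positive = sum(p), n_negative = sum(!p))
}
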