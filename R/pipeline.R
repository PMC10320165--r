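# End-to-end orchestration: query preprocessing (V-domain extraction,
# gene-based assembly, Class II truncation), feature assembly, predictor
# invocation through a pluggable interface, model postprocessing.

# anchor motif closing the V domain / CDR3: F/W - G - any - G
.j_anchor_regex <- "[FW]G.G"
# residues of the J segment retained after the anchor F/W
.j_tail_len <- 10L

# locate the CDR3 within a V-domain sequence by its conserved anchors:
# start = the last Cys preceding the J anchor motif; end = the F/W opening
# the motif. Returns c(start, end) or NULL.
.locate_cdr3 <- function(seq) {
  m <- regexpr(.j_anchor_regex, seq)
  if (m < 0L) return(NULL)
  prefix <- substr(seq, 1L, m - 1L)
  cys <- gregexpr("C", prefix)[[1]]
  if (cys[1] < 0L) return(NULL)
  c(start = max(cys), end = as.integer(m))
}

#' Extract the variable domain from a full-length TCR chain sequence
#'
#' Uses an external immunoglobulin numbering tool when supplied through
#' `numberer`; otherwise falls back to an internal anchor-motif scan
#' (conserved Cys ... CDR3 ... F/W-G-X-G) that truncates the chain shortly
#' after the J segment, removing any constant-region tail.
#'
#' @param seq full-chain or V-domain sequence (string or
#'   `ChainSequence`).
#' @param numberer optional function `seq -> list(v_domain =, map =)`
#'   implementing the numbering-tool contract.
#' @return list with `v_domain` (string), `map` (integer positions of the
#'   V domain in the input) and `cdr3` (c(start, end) within the V
#'   domain).
#' @export
extract_variable_domain <- function(seq, numberer = NULL) {
  s <- .as_seq(seq)
  if (!is.null(numberer)) return(numberer(s))
  anchors <- .locate_cdr3(s)
  if (is.null(anchors))
    stop("no variable domain recognized: missing Cys ... ",
         "F/W-G-X-G anchor pair")
  end <- min(nchar(s), anchors["end"] + .j_tail_len)
  v <- substr(s, 1L, end)
  list(v_domain = v, map = seq_len(end),
       cdr3 = c(start = unname(anchors["start"]),
                end = unname(anchors["end"])))
}

#' Load a gene reference table
#'
#' A user-supplied TSV with columns `species`, `gene_name`, `region`
#' (`V`, `J` or `MHC`) and `sequence`; (species, gene_name) must be
#' unique.
#'
#' @param path TSV file.
#' @return data.frame of class `GeneTable`.
#' @export
read_gene_table <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  gene_table(df)
}

#' Validate a gene table data.frame
#' @param df data.frame with columns `species`, `gene_name`, `region`,
#'   `sequence`.
#' @return the validated data.frame, classed `GeneTable`.
#' @export
gene_table <- function(df) {
  need <- c("species", "gene_name", "region", "sequence")
  if (!all(need %in% names(df)))
    stop("gene table needs columns: ", paste(need, collapse = ", "))
  if (anyDuplicated(paste(df$species, df$gene_name)))
    stop("duplicate (species, gene_name) in gene table")
  if (!all(df$region %in% c("V", "J", "MHC")))
    stop("region must be V, J or MHC")
  class(df) <- c("GeneTable", "data.frame")
  df
}

.lookup_gene <- function(table, gene_name, region,
                         species = NULL) {
  sel <- table$gene_name == gene_name & table$region == region
  if (!is.null(species)) sel <- sel & table$species == species
  hit <- table$sequence[sel]
  if (!length(hit))
    stop("gene not found in table: ", gene_name, " (region ", region, ")")
  hit[1L]
}

#' Assemble a V-domain sequence from germline genes plus a CDR3
#'
#' The V gene contributes everything before its germline CDR3 start (the
#' conserved Cys), the user CDR3 is inserted in full, and the J gene
#' contributes everything after its CDR3 end (the F/W opening the
#' F/W-G-X-G motif). This lets TCRs catalogued as gene names plus CDR3
#' (VDJdb-style records) be modeled without hand-building sequences.
#'
#' @param table a `GeneTable`.
#' @param v_gene,j_gene gene names present in the table.
#' @param cdr3 CDR3 sequence; by default required to start with C and end
#'   with F or W.
#' @param species optional species filter.
#' @param strict_cdr3 enforce the C.../F|W anchor check (default TRUE).
#' @return assembled V-domain sequence (string).
#' @export
assemble_from_genes <- function(table, v_gene, j_gene, cdr3,
                                species = NULL, strict_cdr3 = TRUE) {
  vseq <- .lookup_gene(table, v_gene, "V", species)
  jseq <- .lookup_gene(table, j_gene, "J", species)
  if (strict_cdr3 &&
      (substr(cdr3, 1, 1) != "C" ||
       !substr(cdr3, nchar(cdr3), nchar(cdr3)) %in% c("F", "W")))
    stop("CDR3 must start with C and end with F or W: ", cdr3)
  vcys <- gregexpr("C", vseq)[[1]]
  if (vcys[1] < 0L)
    stop("cannot locate the germline CDR3 start (conserved Cys) in V gene ",
         v_gene)
  jm <- regexpr(.j_anchor_regex, jseq)
  if (jm < 0L)
    stop("cannot locate the CDR3 end (F/W-G-X-G) in J gene ", j_gene)
  paste0(substr(vseq, 1L, max(vcys) - 1L), cdr3,
         substr(jseq, jm + 1L, nchar(jseq)))
}

#' Construct a TCR complex query
#'
#' @param alpha_seq,beta_seq TCR V-domain sequences.
#' @param peptide peptide sequence (length >= 8 for Class I).
#' @param mhc_seqs character vector of MHC sequences: one (Class I heavy
#'   chain) or two (Class II alpha then beta).
#' @param mhc_class `"I"` or `"II"`.
#' @param run_mode `"complex"` or `"tcr_only"`.
#' @return object of class `TCRComplexQuery`; carries the CDR3 ranges
#'   located in each chain as attribute fields `cdr3_alpha`, `cdr3_beta`.
#' @export
tcr_complex_query <- function(alpha_seq, beta_seq, peptide = NULL,
                              mhc_seqs = NULL, mhc_class = c("I", "II"),
                              run_mode = c("complex", "tcr_only")) {
  run_mode <- match.arg(run_mode)
  mhc_class <- match.arg(mhc_class)
  if (run_mode == "complex") {
    missing <- c(if (is.null(peptide)) "peptide",
                 if (is.null(mhc_seqs)) "mhc_seqs")
    if (length(missing))
      stop("complex mode requires field(s): ", paste(missing, collapse = ", "))
    if (mhc_class == "II" && length(mhc_seqs) != 2L)
      stop("Class II queries carry exactly two MHC sequences (alpha, beta)")
    if (mhc_class == "I" && length(mhc_seqs) != 1L)
      stop("Class I queries carry exactly one MHC sequence")
    if (mhc_class == "I" && nchar(peptide) < 8L)
      stop("Class I peptide must be at least 8 residues")
  }
  structure(list(alpha_seq = alpha_seq, beta_seq = beta_seq,
                 peptide = peptide, mhc_seqs = mhc_seqs,
                 mhc_class = mhc_class, run_mode = run_mode,
                 cdr3_alpha = .locate_cdr3(alpha_seq),
                 cdr3_beta = .locate_cdr3(beta_seq)),
            class = "TCRComplexQuery")
}

#' Preprocess raw user input into a TCRComplexQuery
#'
#' Sequence mode: TCR chains are reduced to their variable domains.
#' Gene mode (fields `va`/`ja`/`cdr3a`, `vb`/`jb`/`cdr3b`, and MHC gene
#' names): chains are assembled from the gene table first. Class II
#' peptides longer than 11 residues are truncated to the 11-mer window
#' around a 9-mer core supplied either by `core_predictor` (a pluggable
#' `peptide -> core_start` contract standing in for an external core
#' predictor) or an explicit `core_start`. Class I peptides pass through
#' untouched.
#'
#' @param raw named list of user inputs: either `alpha_seq`/`beta_seq` or
#'   `va`,`ja`,`cdr3a`,`vb`,`jb`,`cdr3b`; plus `peptide`, `mhc_seqs` (or
#'   `mhc_genes`), `mhc_class`, optional `run_mode`, optional `core_start`.
#' @param table optional `GeneTable` (required for gene mode).
#' @param core_predictor optional function `peptide -> core_start`.
#' @param numberer optional numbering-tool contract for
#'   [extract_variable_domain()].
#' @return a `TCRComplexQuery`.
#' @export
preprocess_query <- function(raw, table = NULL, core_predictor = NULL,
                             numberer = NULL) {
  run_mode <- if (!is.null(raw$run_mode)) raw$run_mode else "complex"
  mhc_class <- if (!is.null(raw$mhc_class)) raw$mhc_class else "I"
  get_chain <- function(seq_field, v, j, c3) {
    if (!is.null(raw[[seq_field]]))
      return(extract_variable_domain(raw[[seq_field]], numberer)$v_domain)
    if (is.null(raw[[v]]))
      stop("missing field(s): ", seq_field, " (or ", v, "/", j, "/", c3, ")")
    if (is.null(table)) stop("gene mode requires a gene table")
    assemble_from_genes(table, raw[[v]], raw[[j]], raw[[c3]])
  }
  alpha <- get_chain("alpha_seq", "va", "ja", "cdr3a")
  beta <- get_chain("beta_seq", "vb", "jb", "cdr3b")
  peptide <- raw$peptide
  mhc_seqs <- raw$mhc_seqs
  if (is.null(mhc_seqs) && !is.null(raw$mhc_genes)) {
    if (is.null(table)) stop("gene mode requires a gene table")
    mhc_seqs <- vapply(raw$mhc_genes, function(g)
      .lookup_gene(table, g, "MHC"), "")
  }
  if (run_mode == "complex" && mhc_class == "II" &&
      !is.null(peptide) && nchar(peptide) > 11L) {
    core_start <- if (!is.null(raw$core_start)) raw$core_start
                  else if (!is.null(core_predictor)) core_predictor(peptide)
                  else stop("Class II peptide longer than 11 residues needs ",
                            "a core_start or a core_predictor")
    peptide <- trim_class2_peptide(peptide, core_start)
  }
  tcr_complex_query(alpha, beta, peptide, mhc_seqs, mhc_class, run_mode)
}

#' Default chain naming map
#'
#' Output chain letters by role: MHC heavy/alpha chain A, MHC beta chain
#' B, peptide C, TCR alpha D, TCR beta E. Configurable; passed to
#' [postprocess_models()].
#' @return named character vector role -> chain letter.
#' @export
default_chain_map <- function() {
  c(mhc_heavy = "A", mhc_alpha = "A", mhc_beta = "B",
    peptide = "C", tcr_alpha = "D", tcr_beta = "E")
}

# chain roles present for a query, in modeled order
.query_roles <- function(query) {
  if (query$run_mode == "tcr_only") return(c("tcr_alpha", "tcr_beta"))
  mhc_roles <- if (query$mhc_class == "I") "mhc_heavy"
               else c("mhc_alpha", "mhc_beta")
  c(mhc_roles, "peptide", "tcr_alpha", "tcr_beta")
}

.query_chain_seqs <- function(query) {
  roles <- .query_roles(query)
  seqs <- character(length(roles))
  for (i in seq_along(roles)) {
    seqs[i] <- switch(roles[i],
                      tcr_alpha = query$alpha_seq,
                      tcr_beta = query$beta_seq,
                      peptide = query$peptide,
                      mhc_heavy = query$mhc_seqs[1L],
                      mhc_alpha = query$mhc_seqs[1L],
                      mhc_beta = query$mhc_seqs[2L])
  }
  stats::setNames(seqs, roles)
}

#' Assemble the feature bundle for a query
#'
#' Collects the ranked pMHC templates, the per-chain TCR templates (single
#' -sequence search) and the focused MSA databases into one serializable
#' bundle handed to the predictor.
#'
#' @param query a `TCRComplexQuery`.
#' @param library optional `TemplateLibrary` for pMHC templates.
#' @param dbs optional focused databases ([build_focused_dbs()]).
#' @param tcr_chain_db optional data.frame (`source_id`, `sequence`) of
#'   PDB TCR chain sequences for the template search.
#' @param k_templates templates to select per search (default 4).
#' @return list of class `FeatureBundle`.
#' @export
build_features <- function(query, library = NULL, dbs = NULL,
                           tcr_chain_db = NULL, k_templates = 4L) {
  pmhc <- NULL
  if (query$run_mode == "complex" && !is.null(library)) {
    mhc_query <- paste(query$mhc_seqs, collapse = "")
    pmhc <- select_pmhc_templates(query$peptide, mhc_query, library,
                                  query$mhc_class, k = k_templates)
  }
  tcr <- NULL
  if (!is.null(tcr_chain_db)) {
    tcr <- list(alpha = select_tcr_templates(query$alpha_seq, tcr_chain_db,
                                             k_templates),
                beta = select_tcr_templates(query$beta_seq, tcr_chain_db,
                                            k_templates))
  }
  structure(list(query = query, pmhc_templates = pmhc,
                 tcr_templates = tcr, msa_dbs = dbs,
                 k_templates = k_templates),
            class = "FeatureBundle")
}

#' Deterministic mock predictor
#'
#' Stands in for the folding engine behind the predictor interface: it
#' builds an idealized complex from the query sequences, perturbs it per
#' model with seeded noise, and fabricates pLDDT and block-structured PAE
#' so that downstream scoring, ranking and postprocessing are exercised
#' end to end. Fully deterministic given the seed.
#'
#' @param coordinate_noise per-model coordinate noise scale in Angstrom
#'   (model m gets sd `coordinate_noise * m`).
#' @param base_pae baseline intra-chain PAE level in Angstrom.
#' @param inter_pae_step additional inter-chain PAE added per model index,
#'   so that successive models rank strictly lower.
#' @return a predictor function `(features, n_models, seed) -> list of
#'   PredictionOutput` with attribute `predictor_name`.
#' @export
mock_predictor <- function(coordinate_noise = 0.05, base_pae = 2,
                           inter_pae_step = 1.5) {
  fn <- function(features, n_models, seed) {
    query <- features$query
    seqs <- .query_chain_seqs(query)
    chain_map <- default_chain_map()
    lapply(seq_len(n_models), function(m) {
      set.seed((seed * 131L + m) %% .Machine$integer.max)
      model <- .ideal_complex_structure(seqs, chain_map)
      xyz <- as.matrix(model$atoms[, c("x", "y", "z")])
      xyz <- xyz + matrix(stats::rnorm(length(xyz),
                                       sd = coordinate_noise * m),
                          nrow(xyz), 3)
      model$atoms[, c("x", "y", "z")] <- xyz
      res <- residue_table(model)
      n <- nrow(res)
      plddt <- pmin(100, pmax(0, 92 - 4 * (m - 1) +
                                   stats::rnorm(n, sd = 1)))
      same <- outer(res$chain, res$chain, `==`)
      pae <- matrix(base_pae + inter_pae_step * (m - 1), n, n)
      pae[same] <- base_pae / 2
      diag(pae) <- 0
      prediction_output(model, plddt, pae, res$chain,
                        model_name = sprintf("model_%d", m))
    })
  }
  attr(fn, "predictor_name") <- "mock"
  fn
}

#' Run a modeling job
#'
#' Builds features, invokes the predictor for `n_models` predictions,
#' scores each one (pTM, ipTM, TCR-pMHC group ipTM, model confidence,
#' CDR3 pLDDT), ranks by model confidence, and postprocesses (chain
#' naming, renumbering hook, alignment of every model to the top-ranked
#' one by the pMHC chains). The manifest records what is needed to rerun.
#'
#' @param query a `TCRComplexQuery`.
#' @param predictor a predictor function (see [mock_predictor()]).
#' @param n_models number of models to generate (default 5).
#' @param seed integer seed forwarded to the predictor.
#' @param library,dbs,tcr_chain_db,k_templates forwarded to
#'   [build_features()].
#' @param chain_map role -> chain letter map for postprocessing.
#' @return object of class `JobResult`: `models` (list of
#'   `list(prediction, summary)` in rank order), `manifest`.
#' @export
run_job <- function(query, predictor, n_models = 5L, seed = 1L,
                    library = NULL, dbs = NULL, tcr_chain_db = NULL,
                    k_templates = 4L, chain_map = default_chain_map()) {
  features <- build_features(query, library, dbs, tcr_chain_db, k_templates)
  preds <- predictor(features, n_models, seed)
  if (length(preds) != n_models)
    stop("predictor returned ", length(preds), " models, expected ", n_models)
  # predictors emit chains labeled by the default map; scoring uses those
  # labels, renaming to the user's map happens in postprocessing
  def_map <- default_chain_map()
  loop_ranges <- .cdr3_loop_ranges(query, def_map)
  summaries <- lapply(preds, function(p) {
    g <- if (query$run_mode == "complex") {
      role_of <- names(def_map)[match(p$chain_assignment, def_map)]
      ifelse(role_of %in% c("tcr_alpha", "tcr_beta"), "TCR", "pMHC")
    } else NULL
    confidence_summary(p, groups = g, loop_ranges = loop_ranges)
  })
  ranked <- rank_models(summaries)
  order_idx <- match(vapply(ranked, function(s) s$model_name, ""),
                     vapply(preds, function(p) p$model_name, ""))
  models <- lapply(seq_along(ranked), function(i)
    list(prediction = preds[[order_idx[i]]], summary = ranked[[i]]))
  manifest <- list(
    predictor = if (!is.null(attr(predictor, "predictor_name")))
      attr(predictor, "predictor_name") else "custom",
    seed = seed, n_models = n_models, k_templates = k_templates,
    run_mode = query$run_mode, mhc_class = query$mhc_class,
    chain_map = as.list(chain_map),
    pmhc_templates = if (!is.null(features$pmhc_templates))
      features$pmhc_templates$source_id else character(),
    tcr_templates = if (!is.null(features$tcr_templates))
      lapply(features$tcr_templates, function(x) x$source_id) else list(),
    query_sequences = as.list(.query_chain_seqs(query)))
  result <- structure(list(models = models, manifest = manifest,
                           query = query),
                      class = "JobResult")
  postprocess_models(result, chain_map = chain_map)
}

# CDR3 loop ranges in output-chain numbering (models are numbered 1..n per
# chain by the mock/idealized builder)
.cdr3_loop_ranges <- function(query, chain_map) {
  out <- list()
  if (!is.null(query$cdr3_alpha))
    out$cdr3_alpha <- list(chain = chain_map[["tcr_alpha"]],
                           from = query$cdr3_alpha[["start"]],
                           to = query$cdr3_alpha[["end"]])
  if (!is.null(query$cdr3_beta))
    out$cdr3_beta <- list(chain = chain_map[["tcr_beta"]],
                          from = query$cdr3_beta[["start"]],
                          to = query$cdr3_beta[["end"]])
  if (!length(out)) NULL else out
}

#' Postprocess the models of a job
#'
#' Renames chains per the configured map, applies the renumbering contract
#' when supplied (failures degrade to a warning; coordinates are still
#' aligned), and rigid-transforms models 2..n so their pMHC backbone
#' superposes onto the top-ranked model's (whole-TCR backbone for unbound
#' runs). Alignment is rigid, so no internal geometry changes.
#'
#' @param result a `JobResult`.
#' @param chain_map role -> chain letter map.
#' @param numberer optional per-chain renumbering contract:
#'   `function(model) -> model`.
#' @return the postprocessed `JobResult`.
#' @export
postprocess_models <- function(result, chain_map = default_chain_map(),
                               numberer = NULL) {
  stopifnot(inherits(result, "JobResult"), length(result$models) >= 1L)
  # rename chains from the predictor-contract letters to the configured map
  roles <- .query_roles(result$query)
  old <- unname(default_chain_map()[roles])
  new <- unname(chain_map[roles])
  if (any(is.na(new)))
    stop("chain_map lacks role(s): ", paste(roles[is.na(new)], collapse = ","))
  if (!identical(old, new)) {
    for (i in seq_along(result$models)) {
      p <- result$models[[i]]$prediction
      # two-phase rename so overlapping letter sets cannot collide
      tmp <- paste0("\1", seq_along(old))
      ch <- p$structure$atoms$chain; ca <- p$chain_assignment
      for (k in seq_along(old)) {
        ch[ch == old[k]] <- tmp[k]; ca[ca == old[k]] <- tmp[k]
      }
      for (k in seq_along(old)) {
        ch[ch == tmp[k]] <- new[k]; ca[ca == tmp[k]] <- new[k]
      }
      p$structure$atoms$chain <- ch
      p$chain_assignment <- ca
      result$models[[i]]$prediction <- p
    }
  }
  if (!is.null(numberer)) {
    for (i in seq_along(result$models)) {
      renumbered <- tryCatch(
        numberer(result$models[[i]]$prediction$structure),
        error = function(e) {
          warning("renumbering failed for ",
                  result$models[[i]]$prediction$model_name, ": ",
                  conditionMessage(e), call. = FALSE)
          NULL
        })
      if (!is.null(renumbered))
        result$models[[i]]$prediction$structure <- renumbered
    }
  }
  ref_chains <- if (result$query$run_mode == "complex") {
    roles <- setdiff(.query_roles(result$query), c("tcr_alpha", "tcr_beta"))
    unname(chain_map[roles])
  } else unname(chain_map[c("tcr_alpha", "tcr_beta")])
  ref <- result$models[[1L]]$prediction$structure
  if (length(result$models) > 1L) {
    for (i in seq_along(result$models)[-1L]) {
      mod <- result$models[[i]]$prediction$structure
      pair <- .match_atoms(ref, mod, chain = ref_chains,
                           elety = backbone_atoms())
      if (pair$n >= 3L) {
        sp <- superpose(pair$a, pair$b)
        result$models[[i]]$prediction$structure <-
          apply_superposition(sp, mod)
      }
    }
  }
  result
}

#' @export
print.JobResult <- function(x, ...) {
  cat(sprintf("JobResult: %d model(s), predictor '%s'\n",
              length(x$models), x$manifest$predictor))
  for (m in x$models)
    cat(sprintf("  rank %d  %s  confidence %.3f\n", m$summary$rank,
                m$summary$model_name, m$summary$model_confidence))
  invisible(x)
}

#' Write a JobResult to a directory
#'
#' Emits `model_<rank>.pdb` per model, `confidence.tsv` and
#' `manifest.json`. Output is a pure function of the job (no timestamps),
#' so reruns with the same seed are byte-identical.
#'
#' @param result a `JobResult`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_job_result <- function(result, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (i in seq_along(result$models))
    write_structure(result$models[[i]]$prediction$structure,
                    file.path(dir, sprintf("model_%d.pdb", i)))
  write_confidence_report(lapply(result$models, `[[`, "summary"),
                          file.path(dir, "confidence.tsv"))
  jsonlite::write_json(result$manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(dir)
}
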