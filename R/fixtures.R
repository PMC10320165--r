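# Synthetic fixture generators: idealized toy complexes with analytically
# known assessment metrics, synthetic PAE/pLDDT bundles, toy gene tables
# and template libraries. Pure functions of their seed.

.aa1to3 <- function() {
  stats::setNames(names(.aa3to1)[1:20], unname(.aa3to1)[1:20])
}

.random_peptide <- function(n) {
  paste(sample(unname(.aa3to1)[1:20], n, replace = TRUE), collapse = "")
}

# backbone atoms for one residue centered on a CA position; ori is a unit
# vector along the chain, perp a unit vector normal to it
.residue_atoms <- function(chain, resno, resid, ca, ori, perp) {
  data.frame(chain = chain, resno = resno, resid = resid,
             elety = backbone_atoms(),
             x = c(ca[1] - 1.2 * ori[1], ca[1], ca[1] + 1.2 * ori[1],
                   ca[1] + 1.2 * ori[1] + 1.1 * perp[1]),
             y = c(ca[2] - 1.2 * ori[2], ca[2], ca[2] + 1.2 * ori[2],
                   ca[2] + 1.2 * ori[2] + 1.1 * perp[2]),
             z = c(ca[3] - 1.2 * ori[3], ca[3], ca[3] + 1.2 * ori[3],
                   ca[3] + 1.2 * ori[3] + 1.1 * perp[3]),
             stringsAsFactors = FALSE)
}

# idealized alpha-helix backbone: 1.5 A rise and 100 degree twist per
# residue, 2.3 A radius, axis along +x from origin
.helix_chain <- function(sequence, chain, origin, resno_start = 1L) {
  aa <- strsplit(sequence, "")[[1]]
  a3 <- .aa1to3()
  out <- lapply(seq_along(aa), function(i) {
    th <- (i - 1) * 100 * pi / 180
    ca <- origin + c(1.5 * (i - 1), 2.3 * cos(th), 2.3 * sin(th))
    nxt <- origin + c(1.5 * i, 2.3 * cos(th + 100 * pi / 180),
                      2.3 * sin(th + 100 * pi / 180))
    ori <- (nxt - ca) / sqrt(sum((nxt - ca)^2))
    perp <- c(0, cos(th), sin(th))
    .residue_atoms(chain, resno_start + i - 1L,
                   a3[[aa[i]]], ca, ori, perp)
  })
  do.call(rbind, out)
}

# idealized extended strand: 3.3 A per residue along +x with a small
# alternating pucker
.strand_chain <- function(sequence, chain, origin, resno_start = 1L) {
  aa <- strsplit(sequence, "")[[1]]
  a3 <- .aa1to3()
  out <- lapply(seq_along(aa), function(i) {
    ca <- origin + c(3.3 * (i - 1), 0, 0.4 * (-1)^i)
    .residue_atoms(chain, resno_start + i - 1L, a3[[aa[i]]],
                   ca, c(1, 0, 0), c(0, 1, 0))
  })
  do.call(rbind, out)
}

# idealized TCR-pMHC complex: MHC groove proxy (two helices flanking the
# peptide strand) with the two TCR domains docked above the peptide.
# seqs: named role -> sequence vector; chain_map: role -> chain letter.
.ideal_complex_structure <- function(seqs, chain_map = default_chain_map()) {
  pieces <- list()
  add <- function(df) pieces[[length(pieces) + 1L]] <<- df
  if ("mhc_heavy" %in% names(seqs)) {
    s <- seqs[["mhc_heavy"]]; ch <- chain_map[["mhc_heavy"]]
    half <- nchar(s) %/% 2L
    add(.helix_chain(substr(s, 1, half), ch, c(0, -6, 0)))
    add(.helix_chain(substr(s, half + 1L, nchar(s)), ch, c(0, 6, 0),
                     resno_start = half + 1L))
  }
  if ("mhc_alpha" %in% names(seqs)) {
    add(.helix_chain(seqs[["mhc_alpha"]], chain_map[["mhc_alpha"]],
                     c(0, -6, 0)))
    add(.helix_chain(seqs[["mhc_beta"]], chain_map[["mhc_beta"]],
                     c(0, 6, 0)))
  }
  if ("peptide" %in% names(seqs))
    add(.strand_chain(seqs[["peptide"]], chain_map[["peptide"]], c(2, 0, 1)))
  if ("tcr_alpha" %in% names(seqs)) {
    s <- seqs[["tcr_alpha"]]; ch <- chain_map[["tcr_alpha"]]
    half <- nchar(s) %/% 2L
    add(.strand_chain(substr(s, 1, half), ch, c(0, -2, 4.6)))
    add(.strand_chain(substr(s, half + 1L, nchar(s)), ch, c(0, -2, 9),
                      resno_start = half + 1L))
  }
  if ("tcr_beta" %in% names(seqs)) {
    s <- seqs[["tcr_beta"]]; ch <- chain_map[["tcr_beta"]]
    half <- nchar(s) %/% 2L
    add(.strand_chain(substr(s, 1, half), ch, c(4, 2, 4.6)))
    add(.strand_chain(substr(s, half + 1L, nchar(s)), ch, c(4, 2, 9),
                      resno_start = half + 1L))
  }
  structure_model(do.call(rbind, pieces))
}

#' Fixture specification
#'
#' @param seed integer; every generator is a pure function of it.
#' @param n_peptide,n_mhc,n_tcr residues per peptide / MHC / TCR chain.
#' @param perturbation list describing how the model copy differs from the
#'   native: `list(type = "none")`, `"rigid"`, `list(type = "ligand_shift",
#'   shift = d)`, `list(type = "loop_shift", loop = "cdr3_beta", shift =
#'   d)`, or `list(type = "noise", sigma = s)`.
#' @param pae_profile for PAE fixtures: `list(type = "uniform", value = v)`
#'   or `list(type = "block", intra = a, inter = b)`.
#' @return list of class `FixtureSpec`.
#' @export
fixture_spec <- function(seed = 1L, n_peptide = 9L, n_mhc = 40L,
                         n_tcr = 16L, perturbation = list(type = "none"),
                         pae_profile = list(type = "uniform", value = 0)) {
  stopifnot(is.numeric(seed))
  if (!is.null(perturbation$shift) && perturbation$shift < 0)
    stop("shift must be nonnegative")
  if (!is.null(perturbation$sigma) && perturbation$sigma < 0)
    stop("sigma must be nonnegative")
  structure(list(seed = as.integer(seed), n_peptide = as.integer(n_peptide),
                 n_mhc = as.integer(n_mhc), n_tcr = as.integer(n_tcr),
                 perturbation = perturbation, pae_profile = pae_profile),
            class = "FixtureSpec")
}

.random_rotation <- function() {
  # QR of a Gaussian matrix, sign-fixed to a proper rotation
  q <- qr.Q(qr(matrix(stats::rnorm(9), 3)))
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}

#' Generate a native/model toy complex pair with known expected metrics
#'
#' Builds an idealized four-chain TCR-pMHC complex (MHC helix pair as a
#' groove proxy, peptide strand, two TCR domains) and a perturbed copy.
#' Where the perturbation has a closed-form consequence the expected
#' metric is annotated: `none` and `rigid` give Fnat 1 and all RMSD 0; a
#' uniform `ligand_shift` of d gives L-RMSD exactly d (and Fnat 0 once the
#' interface is broken, d > 12); a `loop_shift` of d gives that loop's CDR
#' RMSD exactly d and 0 for the others. Unannotated metrics are `NA`.
#'
#' @param spec a `FixtureSpec`.
#' @return list: `native`, `model` (`StructureModel`s),
#'   `receptor_chains` (pMHC), `ligand_chains` (TCR), `peptide_chain`,
#'   `mhc_chains`, `loops`, `framework` (CDR-style loop and framework
#'   definitions on the TCR chains), `expected` (named list `fnat`,
#'   `irmsd`, `lrmsd`, `loop_rmsd`).
#' @export
make_toy_complex <- function(spec = fixture_spec()) {
  set.seed(spec$seed)
  seqs <- c(mhc_heavy = .random_peptide(spec$n_mhc),
            peptide = .random_peptide(spec$n_peptide),
            tcr_alpha = .random_peptide(spec$n_tcr),
            tcr_beta = .random_peptide(spec$n_tcr))
  native <- .ideal_complex_structure(seqs)
  model <- native
  pert <- spec$perturbation
  half <- spec$n_tcr %/% 2L
  # second strand of each TCR domain plays the CDR loop role; the first
  # strand is the framework
  loops <- list(list(loop_name = "cdr3_alpha", chain = "D",
                     from = half + 1L, to = spec$n_tcr),
                list(loop_name = "cdr3_beta", chain = "E",
                     from = half + 1L, to = spec$n_tcr))
  framework <- list(list(chain = "D", resno = 1:half),
                    list(chain = "E", resno = 1:half))
  expected <- list(fnat = NA_real_, irmsd = NA_real_, lrmsd = NA_real_,
                   loop_rmsd = c(cdr3_alpha = NA_real_,
                                 cdr3_beta = NA_real_))
  shift_atoms <- function(m, sel, delta) {
    m$atoms[sel, c("x", "y", "z")] <-
      sweep(m$atoms[sel, c("x", "y", "z")], 2, delta, `+`)
    m
  }
  if (pert$type == "none") {
    expected$fnat <- 1; expected$irmsd <- 0; expected$lrmsd <- 0
    expected$loop_rmsd[] <- 0
  } else if (pert$type == "rigid") {
    R <- .random_rotation()
    tr <- stats::rnorm(3, sd = 20)
    xyz <- as.matrix(model$atoms[, c("x", "y", "z")])
    model$atoms[, c("x", "y", "z")] <-
      xyz %*% t(R) + matrix(tr, nrow(xyz), 3, byrow = TRUE)
    expected$fnat <- 1; expected$irmsd <- 0; expected$lrmsd <- 0
    expected$loop_rmsd[] <- 0
  } else if (pert$type == "ligand_shift") {
    d <- pert$shift
    model <- shift_atoms(model, model$atoms$chain %in% c("D", "E"),
                         c(0, 0, d))
    expected$lrmsd <- d
    if (d == 0) { expected$fnat <- 1; expected$irmsd <- 0 }
    if (d > 12) expected$fnat <- 0
  } else if (pert$type == "loop_shift") {
    lp <- loops[[match(pert$loop, vapply(loops, `[[`, "", "loop_name"))]]
    sel <- model$atoms$chain == lp$chain &
      model$atoms$resno >= lp$from & model$atoms$resno <= lp$to
    model <- shift_atoms(model, sel, c(pert$shift, 0, 0))
    expected$loop_rmsd[] <- 0
    expected$loop_rmsd[[pert$loop]] <- pert$shift
  } else if (pert$type == "noise") {
    xyz <- as.matrix(model$atoms[, c("x", "y", "z")])
    model$atoms[, c("x", "y", "z")] <-
      xyz + matrix(stats::rnorm(length(xyz), sd = pert$sigma), nrow(xyz), 3)
  } else stop("unknown perturbation type: ", pert$type)
  list(native = native, model = model,
       receptor_chains = c("A", "C"), ligand_chains = c("D", "E"),
       peptide_chain = "C", mhc_chains = "A",
       loops = loops, framework = framework, expected = expected)
}

#' Generate a synthetic PredictionOutput with a controlled PAE profile
#'
#' @param spec a `FixtureSpec`; `pae_profile` selects a uniform PAE level
#'   or an intra/inter block structure over the chain partition.
#' @param plddt_level constant pLDDT level, or `NULL` for seeded values in
#'   `[60, 100]`.
#' @return a `PredictionOutput` over the idealized complex, plus attribute
#'   `groups` holding the TCR/pMHC residue grouping.
#' @export
make_synthetic_pae <- function(spec = fixture_spec(), plddt_level = 90) {
  set.seed(spec$seed)
  seqs <- c(mhc_heavy = .random_peptide(spec$n_mhc),
            peptide = .random_peptide(spec$n_peptide),
            tcr_alpha = .random_peptide(spec$n_tcr),
            tcr_beta = .random_peptide(spec$n_tcr))
  model <- .ideal_complex_structure(seqs)
  res <- residue_table(model)
  n <- nrow(res)
  prof <- spec$pae_profile
  if (prof$type == "uniform") {
    pae <- matrix(prof$value, n, n)
  } else if (prof$type == "block") {
    same <- outer(res$chain, res$chain, `==`)
    pae <- matrix(prof$inter, n, n)
    pae[same] <- prof$intra
  } else if (prof$type == "random") {
    pae <- matrix(stats::runif(n * n, 0, 30), n, n)
  } else stop("unknown pae_profile type: ", prof$type)
  plddt <- if (is.null(plddt_level)) stats::runif(n, 60, 100)
           else rep(plddt_level, n)
  out <- prediction_output(model, plddt, pae, res$chain,
                           model_name = sprintf("synthetic_%d", spec$seed))
  attr(out, "groups") <- ifelse(res$chain %in% c("D", "E"), "TCR", "pMHC")
  out
}

#' Generate a toy germline gene table
#'
#' Small internally consistent table exercising the V/J junction logic:
#' V genes end in a conserved-Cys anchor region, J genes carry the
#' F/W-G-X-G motif, and MHC genes are plain sequences.
#'
#' @param seed integer seed.
#' @return a `GeneTable`.
#' @export
make_toy_gene_table <- function(seed = 1L) {
  set.seed(seed)
  rand <- function(n) paste(sample(setdiff(unname(.aa3to1)[1:20],
                                           c("C", "F", "W")),
                                   n, replace = TRUE), collapse = "")
  rows <- list(
    c("human", "TRAV-T1", "V", paste0(rand(50), "YFC")),
    c("human", "TRAV-T2", "V", paste0(rand(48), "YLC")),
    c("human", "TRAJ-T1", "J", paste0(rand(4), "FGQGTRLTVVP")),
    c("human", "TRAJ-T2", "J", paste0(rand(3), "WGPGTRLLVVH")),
    c("human", "TRBV-T1", "V", paste0(rand(52), "YIC")),
    c("human", "TRBJ-T1", "J", paste0(rand(5), "FGPGTRLTVTA")),
    c("human", "MHC-T1", "MHC", rand(40)),
    c("human", "MHC-T2", "MHC", rand(40)))
  df <- as.data.frame(do.call(rbind, rows), stringsAsFactors = FALSE)
  names(df) <- c("species", "gene_name", "region", "sequence")
  gene_table(df)
}

#' Generate a toy pMHC template library
#'
#' Builds annotated toy structures (peptide strand + MHC helix chains) and
#' curates them through [build_pmhc_library()], exercising the resolution
#' filter and the identical-sequence redundancy cap.
#'
#' @param seed integer seed.
#' @param n_templates distinct pMHC entries per class.
#' @param classes MHC classes to include (subset of `c("I", "II")`).
#' @param duplicates extra copies of the first Class I entry (identical
#'   pMHC sequence, differing source_id/resolution) appended before
#'   curation, to exercise the at-most-two cap.
#' @param resolution_cutoff forwarded to [build_pmhc_library()].
#' @return a `TemplateLibrary`.
#' @export
make_toy_library <- function(seed = 1L, n_templates = 4L, classes = "I",
                             duplicates = 0L, resolution_cutoff = 3.5) {
  set.seed(seed)
  entries <- list(); serial <- 0L
  add_entry <- function(cls, pep, mhc_seqs, resol, src) {
    chains <- list(.strand_chain(pep, "C", c(0, 0, 2)))
    mhc_ch <- c("A", "B")[seq_along(mhc_seqs)]
    for (i in seq_along(mhc_seqs))
      chains[[length(chains) + 1L]] <-
        .helix_chain(mhc_seqs[i], mhc_ch[i], c(0, c(-6, 6)[i], 0))
    entries[[length(entries) + 1L]] <<- list(
      structure = structure_model(do.call(rbind, chains)),
      mhc_class = cls, peptide_chain = "C", mhc_chains = mhc_ch,
      resolution = resol, release_date = as.Date("2017-01-01") + serial,
      source_id = src,
      core_start = if (cls == "II" && nchar(pep) > 11L) 3L else NULL)
    serial <<- serial + 1L
  }
  for (cls in classes) {
    for (i in seq_len(n_templates)) {
      pep <- .random_peptide(if (cls == "I") 9L else 15L)
      mhc <- if (cls == "I") .random_peptide(30L)
             else c(.random_peptide(15L), .random_peptide(15L))
      add_entry(cls, pep, mhc, round(stats::runif(1, 1.8, 3.4), 2),
                sprintf("T%s%02d", cls, i))
    }
  }
  if (duplicates > 0L) {
    first <- entries[[1L]]
    for (d in seq_len(duplicates)) {
      dup <- first
      dup$source_id <- sprintf("TDUP%02d", d)
      dup$resolution <- round(first$resolution + 0.02 * d, 2)
      entries[[length(entries) + 1L]] <- dup
    }
  }
  build_pmhc_library(entries, resolution_cutoff = resolution_cutoff)
}
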