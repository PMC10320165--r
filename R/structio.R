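# Atomic data model, structure I/O and rigid-body superposition.

#' The 20 standard residues plus common substitutions
#'
#' Three-letter to one-letter residue code map. Selenomethionine (MSE) maps
#' to M; anything absent from this table is treated as nonstandard and maps
#' to X in extracted sequences.
#' @keywords internal
.aa3to1 <- c(
  ALA = "A", ARG = "R", ASN = "N", ASP = "D", CYS = "C",
  GLN = "Q", GLU = "E", GLY = "G", HIS = "H", ILE = "I",
  LEU = "L", LYS = "K", MET = "M", PHE = "F", PRO = "P",
  SER = "S", THR = "T", TRP = "W", TYR = "Y", VAL = "V",
  MSE = "M"
)

.water_resids <- c("HOH", "WAT", "DOD", "H2O")

#' Construct a StructureModel
#'
#' A `StructureModel` is the universal currency for templates, predictions
#' and experimental (native) structures: an ordered atom table plus optional
#' experimental metadata.
#'
#' @param atoms data.frame with columns `chain` (character), `resno`
#'   (integer, author numbering), `resid` (3-letter residue code), `elety`
#'   (PDB atom name), `x`, `y`, `z` (Angstrom).
#' @param resolution crystallographic resolution in Angstrom, or `NA`.
#' @param release_date a `Date` (or string coercible to one), or `NA`.
#' @param source_id free-text identifier, typically a PDB code.
#' @return An object of class `StructureModel`.
#' @export
structure_model <- function(atoms, resolution = NA_real_, release_date = NA,
                            source_id = NA_character_) {
  required <- c("chain", "resno", "resid", "elety", "x", "y", "z")
  missing <- setdiff(required, names(atoms))
  if (length(missing))
    stop("atoms is missing column(s): ", paste(missing, collapse = ", "))
  atoms <- as.data.frame(atoms)[, required]
  atoms$chain <- as.character(atoms$chain)
  atoms$resno <- as.integer(atoms$resno)
  atoms$resid <- as.character(atoms$resid)
  atoms$elety <- as.character(atoms$elety)
  if (nrow(atoms) && !all(is.finite(c(atoms$x, atoms$y, atoms$z))))
    stop("atom coordinates must be finite")
  key <- paste(atoms$chain, atoms$resno, atoms$elety)
  if (anyDuplicated(key))
    stop("duplicate (chain, resno, elety) atom records: ",
         key[duplicated(key)][1L])
  if (!is.na(release_date)) release_date <- as.Date(release_date)
  rownames(atoms) <- NULL
  structure(list(atoms = atoms,
                 resolution = as.numeric(resolution),
                 release_date = release_date,
                 source_id = source_id),
            class = "StructureModel")
}

#' @export
print.StructureModel <- function(x, ...) {
  res <- residue_table(x)
  cat(sprintf("StructureModel: %d atoms, %d residues, %d chain(s) [%s]\n",
              nrow(x$atoms), nrow(res), length(unique(x$atoms$chain)),
              paste(unique(x$atoms$chain), collapse = ",")))
  if (!is.na(x$resolution))
    cat(sprintf("  resolution: %.2f A\n", x$resolution))
  if (!is.na(x$source_id)) cat("  source:", x$source_id, "\n")
  invisible(x)
}

#' One row per residue of a StructureModel, in atom order
#'
#' @param model a `StructureModel`.
#' @param chain optional chain filter.
#' @return data.frame with columns `chain`, `resno`, `resid`.
#' @export
residue_table <- function(model, chain = NULL) {
  at <- model$atoms
  if (!is.null(chain)) at <- at[at$chain %in% chain, , drop = FALSE]
  keep <- !duplicated(paste(at$chain, at$resno))
  out <- at[keep, c("chain", "resno", "resid"), drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Coordinate matrix of selected atoms
#'
#' @param model a `StructureModel`.
#' @param chain optional chain filter.
#' @param elety optional atom-name filter (e.g. `backbone_atoms()`).
#' @return numeric matrix n x 3.
#' @export
atom_xyz <- function(model, chain = NULL, elety = NULL) {
  at <- model$atoms
  if (!is.null(chain)) at <- at[at$chain %in% chain, , drop = FALSE]
  if (!is.null(elety)) at <- at[at$elety %in% elety, , drop = FALSE]
  as.matrix(at[, c("x", "y", "z")])
}

#' Backbone atom names used for backbone RMSD
#'
#' The N, CA, C, O set, following the DockQ convention.
#' @return character vector.
#' @export
backbone_atoms <- function() c("N", "CA", "C", "O")

#' Read a structure from PDB or mmCIF
#'
#' ATOM records are loaded with author chain identifiers and residue numbers
#' preserved. Water molecules are skipped; non-water HETATM residues (e.g.
#' selenomethionine) are kept so that modified residues remain addressable.
#' When alternate locations are present only the highest-occupancy conformer
#' of each atom is retained.
#'
#' @param path file path.
#' @param format `"pdb"`, `"mmcif"`, or `"auto"` (by extension).
#' @param resolution,release_date,source_id optional metadata to attach;
#'   `source_id` defaults to the file base name.
#' @return a `StructureModel`.
#' @export
read_structure <- function(path, format = c("auto", "pdb", "mmcif"),
                           resolution = NA_real_, release_date = NA,
                           source_id = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("no such file: ", path)
  if (format == "auto") {
    format <- if (grepl("\\.cif$", path, ignore.case = TRUE)) "mmcif" else "pdb"
  }
  pdb <- tryCatch(
    if (format == "mmcif") bio3d::read.cif(path, verbose = FALSE, rm.alt = FALSE)
    else bio3d::read.pdb(path, verbose = FALSE, rm.alt = FALSE),
    error = function(e) stop("cannot parse ", path, " as ", format, ": ",
                             conditionMessage(e), call. = FALSE))
  at <- pdb$atom
  at <- at[!(at$resid %in% .water_resids), , drop = FALSE]
  if (!nrow(at)) stop("no ATOM records in ", path)
  # alternate locations: keep highest occupancy, ties broken by file order
  if (any(!is.na(at$alt))) {
    occ <- ifelse(is.na(at$o), 1, at$o)
    ord <- order(paste(at$chain, at$resno, at$elety), -occ)
    at <- at[ord, , drop = FALSE]
    at <- at[!duplicated(paste(at$chain, at$resno, at$elety)), , drop = FALSE]
    at <- at[order(as.integer(rownames(at))), , drop = FALSE]
  }
  structure_model(
    data.frame(chain = at$chain, resno = at$resno, resid = at$resid,
               elety = at$elety, x = at$x, y = at$y, z = at$z,
               stringsAsFactors = FALSE),
    resolution = resolution, release_date = release_date,
    source_id = if (is.null(source_id))
      sub("\\.[^.]+$", "", basename(path)) else source_id)
}

#' Write a StructureModel as PDB text
#'
#' Chain identifiers and author residue numbers are written exactly as
#' stored; coordinates are rounded to 3 decimals (format precision).
#'
#' @param model a nonempty `StructureModel`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_structure <- function(model, path) {
  stopifnot(inherits(model, "StructureModel"))
  at <- model$atoms
  if (!nrow(at)) stop("refusing to write an empty StructureModel")
  if (any(nchar(at$chain) != 1L))
    stop("PDB format requires single-character chain IDs; offending chain: ",
         at$chain[nchar(at$chain) != 1L][1L])
  bio3d::write.pdb(pdb = NULL, file = path,
                   xyz = as.numeric(t(as.matrix(at[, c("x", "y", "z")]))),
                   type = rep("ATOM", nrow(at)),
                   resno = at$resno, resid = at$resid,
                   eleno = seq_len(nrow(at)), elety = at$elety,
                   chain = at$chain)
  invisible(path)
}

#' Extract a one-letter sequence from one chain
#'
#' One letter per residue in residue-number order as stored; nonstandard
#' residues (anything outside the 20 standard codes, selenomethionine
#' excepted) become `X`.
#'
#' @param model a `StructureModel`.
#' @param chain_id chain to extract.
#' @param chain_role role tag recorded on the result (see [chain_sequence()]).
#' @return a `ChainSequence`.
#' @export
extract_sequence <- function(model, chain_id, chain_role = NA_character_) {
  res <- residue_table(model, chain = chain_id)
  if (!nrow(res)) stop("chain not present in structure: ", chain_id)
  one <- .aa3to1[res$resid]
  one[is.na(one)] <- "X"
  chain_sequence(paste(one, collapse = ""), label = chain_id,
                 chain_role = chain_role)
}

#' Construct a ChainSequence
#'
#' @param sequence uppercase amino-acid string over the 20-letter alphabet;
#'   `X` is accepted (flagged nonstandard).
#' @param label free-text label (often the chain ID).
#' @param chain_role one of `tcr_alpha`, `tcr_beta`, `peptide`, `mhc_heavy`,
#'   `mhc_alpha`, `mhc_beta`, or `NA`.
#' @return object of class `ChainSequence`.
#' @export
chain_sequence <- function(sequence, label = NA_character_,
                           chain_role = NA_character_) {
  if (!is.character(sequence) || length(sequence) != 1L || !nzchar(sequence))
    stop("sequence must be a single nonempty string")
  sequence <- toupper(sequence)
  bad <- setdiff(strsplit(sequence, "")[[1]], c(unname(.aa3to1), "X"))
  if (length(bad))
    stop("sequence contains non-amino-acid character(s): ",
         paste(unique(bad), collapse = ""))
  if (!is.na(chain_role))
    chain_role <- match.arg(chain_role, c("tcr_alpha", "tcr_beta", "peptide",
                                          "mhc_heavy", "mhc_alpha", "mhc_beta"))
  structure(list(sequence = sequence, label = label, chain_role = chain_role),
            class = "ChainSequence")
}

#' @export
print.ChainSequence <- function(x, ...) {
  cat(sprintf("ChainSequence [%s%s] %d aa: %s\n",
              if (is.na(x$label)) "?" else x$label,
              if (is.na(x$chain_role)) "" else paste0("/", x$chain_role),
              nchar(x$sequence), x$sequence))
  invisible(x)
}

#' Least-squares rigid-body superposition (Kabsch)
#'
#' Computes the proper rotation and translation minimising the RMSD between
#' paired points, by singular value decomposition of the cross-covariance
#' with reflection correction. The mobile set is mapped onto the reference:
#' `x %*% t(rotation) + translation`.
#'
#' @param reference n x 3 matrix of reference coordinates.
#' @param mobile n x 3 matrix of mobile coordinates, paired row-wise.
#' @return object of class `Superposition` with fields `rotation` (3 x 3,
#'   det +1), `translation` (length 3) and `rmsd` (Angstrom, after
#'   transform).
#' @export
superpose <- function(reference, mobile) {
  reference <- as.matrix(reference); mobile <- as.matrix(mobile)
  if (!identical(dim(reference), dim(mobile)))
    stop("reference and mobile must have the same dimensions")
  if (nrow(reference) < 3L)
    stop("need at least 3 point pairs for a unique rotation")
  cr <- colMeans(reference); cm <- colMeans(mobile)
  A <- sweep(reference, 2, cr); B <- sweep(mobile, 2, cm)
  if (qr(A)$rank < 2L || qr(B)$rank < 2L)
    stop("degenerate (collinear) point set: rotation is not unique")
  H <- crossprod(B, A)            # 3x3 covariance, mobile -> reference
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  tr <- as.numeric(cr - R %*% cm)
  fitted <- mobile %*% t(R) + matrix(tr, nrow(mobile), 3, byrow = TRUE)
  rmsd <- sqrt(mean(rowSums((fitted - reference)^2)))
  structure(list(rotation = R, translation = tr, rmsd = rmsd),
            class = "Superposition")
}

#' @export
print.Superposition <- function(x, ...) {
  cat(sprintf("Superposition: rmsd %.4f A\n", x$rmsd))
  invisible(x)
}

#' Apply a Superposition to coordinates or a StructureModel
#'
#' @param sp a `Superposition`.
#' @param x an n x 3 coordinate matrix or a `StructureModel`.
#' @return object of the same type, transformed.
#' @export
apply_superposition <- function(sp, x) {
  stopifnot(inherits(sp, "Superposition"))
  if (inherits(x, "StructureModel")) {
    xyz <- as.matrix(x$atoms[, c("x", "y", "z")])
    xyz <- xyz %*% t(sp$rotation) + matrix(sp$translation, nrow(xyz), 3,
                                           byrow = TRUE)
    x$atoms[, c("x", "y", "z")] <- xyz
    return(x)
  }
  as.matrix(x) %*% t(sp$rotation) +
    matrix(sp$translation, nrow(as.matrix(x)), 3, byrow = TRUE)
}

#' Plain RMSD between paired coordinate sets (no fitting)
#' @param a,b n x 3 matrices, paired row-wise.
#' @return RMSD in Angstrom.
#' @export
rmsd_nofit <- function(a, b) {
  a <- as.matrix(a); b <- as.matrix(b)
  stopifnot(identical(dim(a), dim(b)), nrow(a) > 0L)
  sqrt(mean(rowSums((a - b)^2)))
}

# match two models' atom tables on (chain, resno, elety); returns paired
# coordinate matrices in the first model's order
.match_atoms <- function(a, b, chain = NULL, elety = NULL) {
  ta <- a$atoms; tb <- b$atoms
  if (!is.null(chain)) {
    ta <- ta[ta$chain %in% chain, , drop = FALSE]
    tb <- tb[tb$chain %in% chain, , drop = FALSE]
  }
  if (!is.null(elety)) {
    ta <- ta[ta$elety %in% elety, , drop = FALSE]
    tb <- tb[tb$elety %in% elety, , drop = FALSE]
  }
  ka <- paste(ta$chain, ta$resno, ta$elety)
  kb <- paste(tb$chain, tb$resno, tb$elety)
  idx <- match(ka, kb)
  keep <- !is.na(idx)
  list(a = as.matrix(ta[keep, c("x", "y", "z")]),
       b = as.matrix(tb[idx[keep], c("x", "y", "z")]),
       n = sum(keep))
}
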