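# Docking metrics, CAPRI classification, peptide-MHC assessment, CDR loop
# RMSD, benchmark redundancy filtering, discrimination statistics.

test_that("interface contacts match the brute-force distance scan", {
  toy <- make_toy_complex(fixture_spec(seed = 61, n_mhc = 16, n_tcr = 8))
  m <- toy$native
  got <- interface_contacts(m, toy$receptor_chains, toy$ligand_chains, 5)
  dm <- oracle_min_residue_dist(m, toy$receptor_chains, toy$ligand_chains)
  want <- which(dm <= 5, arr.ind = TRUE)
  expect_equal(nrow(got), nrow(want))
  got_keys <- sort(paste(got$rec_chain, got$rec_resno, got$lig_chain,
                         got$lig_resno))
  want_keys <- sort(paste(rownames(dm)[want[, 1]],
                          colnames(dm)[want[, 2]]))
  expect_equal(got_keys, want_keys)
  # two residues 3 A apart -> one pair; far partners -> none
  two <- structure_model(data.frame(
    chain = c("A", "A", "B", "B"), resno = c(1, 1, 1, 1),
    resid = "GLY", elety = c("CA", "C", "CA", "C"),
    x = c(0, 1.5, 3, 4.5), y = 0, z = c(0, 0, 0, 0)))
  expect_equal(nrow(interface_contacts(two, "A", "B", 5)), 1L)
  far <- two
  far$atoms$x[far$atoms$chain == "B"] <- far$atoms$x[far$atoms$chain == "B"] + 100
  expect_equal(nrow(interface_contacts(far, "A", "B", 5)), 0L)
})

test_that("Fnat is 1 for the native, 0 for an expelled ligand, fractional between", {
  toy <- make_toy_complex(fixture_spec(seed = 62))
  expect_equal(compute_fnat(toy$native, toy$native, toy$receptor_chains,
                            toy$ligand_chains), 1.0)
  gone <- make_toy_complex(fixture_spec(
    seed = 62, perturbation = list(type = "ligand_shift", shift = 100)))
  expect_equal(compute_fnat(gone$native, gone$model, gone$receptor_chains,
                            gone$ligand_chains), 0.0)
  # a native with no contacts is an undefined metric
  apart <- toy$native
  apart$atoms$z[apart$atoms$chain %in% c("D", "E")] <-
    apart$atoms$z[apart$atoms$chain %in% c("D", "E")] + 500
  expect_error(compute_fnat(apart, apart, toy$receptor_chains,
                            toy$ligand_chains), "undefined|no interface")
})

test_that("I-RMSD is zero under rigid motion and matches the oracle under noise", {
  rigid <- make_toy_complex(fixture_spec(seed = 63,
                                         perturbation = list(type = "rigid")))
  expect_equal(compute_irmsd(rigid$native, rigid$model, rigid$receptor_chains,
                             rigid$ligand_chains), 0, tolerance = 1e-9)
  noisy <- make_toy_complex(fixture_spec(
    seed = 64, perturbation = list(type = "noise", sigma = 0.4)))
  got <- compute_irmsd(noisy$native, noisy$model, noisy$receptor_chains,
                       noisy$ligand_chains)
  # oracle: same interface-residue definition, Horn-quaternion optimal fit
  dm <- oracle_min_residue_dist(noisy$native, noisy$receptor_chains,
                                noisy$ligand_chains)
  hits <- which(dm <= 10, arr.ind = TRUE)
  keys <- unique(c(rownames(dm)[hits[, 1]], colnames(dm)[hits[, 2]]))
  bb <- function(m) {
    at <- m$atoms
    at <- at[paste(at$chain, at$resno) %in% keys &
               at$elety %in% c("N", "CA", "C", "O"), ]
    as.matrix(at[order(at$chain, at$resno, at$elety), c("x", "y", "z")])
  }
  expect_equal(got, oracle_fit_rmsd(bb(noisy$native), bb(noisy$model)),
               tolerance = 1e-6)
})

test_that("L-RMSD equals the shift for a uniformly translated ligand", {
  for (d in c(0, 2, 7.5)) {
    toy <- make_toy_complex(fixture_spec(
      seed = 65, perturbation = list(type = "ligand_shift", shift = d)))
    expect_equal(compute_lrmsd(toy$native, toy$model, toy$receptor_chains,
                               toy$ligand_chains), d, tolerance = 1e-9)
  }
  # whole-complex rigid transform scores 0
  rigid <- make_toy_complex(fixture_spec(seed = 66,
                                         perturbation = list(type = "rigid")))
  expect_equal(compute_lrmsd(rigid$native, rigid$model, rigid$receptor_chains,
                             rigid$ligand_chains), 0, tolerance = 1e-9)
  expect_error(compute_lrmsd(rigid$native, rigid$model, "Z", "D"),
               "missing")
})

test_that("DockQ follows the published formula and is monotone", {
  expect_equal(dockq_score(1, 0, 0), 1.0)
  expect_equal(dockq_score(0.5, 1.5, 8.5), 0.5)
  expect_lt(dockq_score(0, 1e6, 1e6), 1e-3)
  expect_error(dockq_score(-0.1, 1, 1), "range")
  # monotone in each argument on a grid
  f <- seq(0, 1, length.out = 10)
  expect_true(all(diff(dockq_score(f, 2, 4)) >= 0))
  r <- seq(0, 20, length.out = 10)
  expect_true(all(diff(dockq_score(0.5, r, 4)) <= 0))
  expect_true(all(diff(dockq_score(0.5, 2, r)) <= 0))
})

test_that("CAPRI classes change exactly at the configured thresholds", {
  expect_equal(capri_class(1, 0, 0), "High")
  expect_equal(capri_class(0.05, 12, 30), "Incorrect")
  th <- capri_config()$protein_protein
  # Medium/Acceptable boundary on irmsd with lrmsd out of range
  eps <- 1e-9
  expect_equal(capri_class(0.4, th$Medium$irmsd_max, 20), "Medium")
  expect_equal(capri_class(0.4, th$Medium$irmsd_max + eps, 20), "Acceptable")
  # fnat gate
  expect_equal(capri_class(th$Medium$fnat_min, 1.5, 20), "Medium")
  expect_equal(capri_class(th$Medium$fnat_min - eps, 1.5, 20), "Acceptable")
  # high fnat alone is not enough when both RMSDs are out of range
  expect_equal(capri_class(0.9, 11, 30,
                           thresholds = capri_config()$protein_protein),
               "Incorrect")
})

test_that("peptide docking assessment flags displaced peptides", {
  toy <- make_toy_complex(fixture_spec(seed = 67))
  a <- assess_peptide_dock(toy$native, toy$native, toy$mhc_chains,
                           toy$peptide_chain)
  expect_equal(a$capri_class, "High")
  # peptide pushed 50 A out of the groove
  displaced <- toy$native
  sel <- displaced$atoms$chain == "C"
  displaced$atoms$y[sel] <- displaced$atoms$y[sel] + 50
  b <- assess_peptide_dock(toy$native, displaced, toy$mhc_chains,
                           toy$peptide_chain)
  expect_equal(b$capri_class, "Incorrect")
  expect_equal(b$fnat, 0)
  # a one-register shift along the groove: metrics classified by the table
  shifted <- toy$native
  shifted$atoms$x[sel] <- shifted$atoms$x[sel] + 3.3
  cfg <- capri_config()
  s <- assess_peptide_dock(toy$native, shifted, toy$mhc_chains,
                           toy$peptide_chain)
  hand <- function(fnat, irmsd, lrmsd) {
    for (cls in c("High", "Medium", "Acceptable")) {
      t <- cfg$peptide[[cls]]
      if (fnat >= t$fnat_min && (lrmsd <= t$lrmsd_max || irmsd <= t$irmsd_max))
        return(cls)
    }
    "Incorrect"
  }
  expect_equal(s$capri_class, hand(s$fnat, s$irmsd, s$lrmsd))
  expect_equal(s$dockq, dockq_score(s$fnat, s$irmsd, s$lrmsd))
})

test_that("CDR loop RMSD isolates the displaced loop after framework fitting", {
  toy <- make_toy_complex(fixture_spec(
    seed = 68, perturbation = list(type = "loop_shift", loop = "cdr3_beta",
                                   shift = 2)))
  out <- cdr_loop_rmsd(toy$native, toy$model, toy$loops, toy$framework)
  expect_equal(out[["cdr3_beta"]], 2.0, tolerance = 1e-9)
  expect_equal(out[["cdr3_alpha"]], 0.0, tolerance = 1e-9)
  # rigid transform of the whole model: all loops zero
  rigid <- make_toy_complex(fixture_spec(seed = 69,
                                         perturbation = list(type = "rigid")))
  out2 <- cdr_loop_rmsd(rigid$native, rigid$model, rigid$loops,
                        rigid$framework)
  expect_true(all(abs(out2) < 1e-9))
  # a loop absent from the model is NA with a warning
  chopped <- toy$model
  lp <- toy$loops[[1]]
  chopped$atoms <- chopped$atoms[!(chopped$atoms$chain == lp$chain &
                                     chopped$atoms$resno >= lp$from), ]
  expect_warning(out3 <- cdr_loop_rmsd(toy$native, chopped, toy$loops,
                                       toy$framework), "undefined")
  expect_true(is.na(out3[["cdr3_alpha"]]))
  # overlapping loop/framework definitions are rejected
  bad_fw <- list(list(chain = lp$chain, resno = lp$from:lp$to))
  expect_error(cdr_loop_rmsd(toy$native, toy$model, toy$loops, bad_fw),
               "overlap")
})

test_that("sequence identity counts matches over the global alignment length", {
  expect_equal(sequence_identity("ACDEFGHIKL", "ACDEFGHIKL"), 1.0)
  set.seed(71)
  aas <- c("A", "R", "N", "D", "E", "Q", "G", "H", "I", "L", "K", "M",
           "F", "P", "S", "T", "W", "Y", "V")
  base <- paste(sample(aas, 100, TRUE), collapse = "")
  mut <- base
  for (p in sample(100, 5)) {
    substr(mut, p, p) <- if (substr(mut, p, p) == "A") "V" else "A"
  }
  expect_equal(sequence_identity(base, mut), 0.95)
  # short toys against an exhaustive hand alignment: one terminal gap
  expect_equal(sequence_identity("ACDEF", "ACDEFG"), 5 / 6)
})

test_that("redundancy uses OR semantics over chain and domain identity, gated by class", {
  va <- paste(rep("ACDEFGHIKL", 10), collapse = "")
  vb <- paste(rep("MNPQRSTVWY", 10), collapse = "")
  mutate <- function(s, k) {
    for (p in seq_len(k)) {
      cur <- substr(s, p * 3, p * 3)
      substr(s, p * 3, p * 3) <- if (cur == "A") "G" else "A"
    }
    s
  }
  a <- benchmark_case("7AAA", "I", "2019-01-01", 2.5, va, vb)
  expect_true(is_redundant(a, a))
  # same sequences, different class: not redundant
  b <- benchmark_case("7BBB", "II", "2019-01-01", 2.5, va, vb)
  expect_false(is_redundant(a, b))
  # Valpha 0.96 / Vbeta ~0.5: redundant via the chain rule
  c1 <- benchmark_case("7CCC", "I", "2019-01-01", 2.5, mutate(va, 4),
                       paste(rep("GASGASGASG", 10), collapse = ""))
  expect_gte(sequence_identity(a$alpha_seq, c1$alpha_seq), 0.95)
  expect_lt(sequence_identity(a$beta_seq, c1$beta_seq), 0.9)
  expect_true(is_redundant(a, c1))
  # both chains at ~0.93: caught only by the 0.92 domain rule
  d1 <- benchmark_case("7DDD", "I", "2019-01-01", 2.5, mutate(va, 7),
                       mutate(vb, 7))
  expect_lt(sequence_identity(a$alpha_seq, d1$alpha_seq), 0.95)
  expect_true(is_redundant(a, d1))
  far <- benchmark_case("7EEE", "I", "2019-01-01", 2.5, mutate(va, 30),
                        mutate(vb, 30))
  expect_false(is_redundant(a, far))
  expect_error(is_redundant(a, benchmark_case("7FFF", "I", "2019-01-01",
                                              2.5, "", vb)), "missing")
})

test_that("benchmark assembly keeps exactly the planted nonredundant set", {
  va1 <- paste(rep("ACDEFGHIKL", 10), collapse = "")
  vb1 <- paste(rep("MNPQRSTVWY", 10), collapse = "")
  va2 <- paste(rep("LKIHGFEDCA", 10), collapse = "")
  vb2 <- paste(rep("YWVTSRQPNM", 10), collapse = "")
  va3 <- paste(rep("GASTRANDLY", 10), collapse = "")
  vb3 <- paste(rep("HISPELMATE", 10), collapse = "")
  near <- function(s) { substr(s, 3, 3) <- "G"; s }
  cand <- list(
    benchmark_case("7AAA", "I", "2019-06-01", 2.0, va1, vb1),
    benchmark_case("7AAB", "I", "2019-07-01", 1.9, near(va1), vb1),  # redundant with 7AAA
    benchmark_case("7BBB", "I", "2019-06-01", 3.30, va2, vb2),       # resolution fail
    benchmark_case("7CCC", "I", "2017-01-01", 2.0, va2, vb2),        # pre-cutoff
    benchmark_case("7DDD", "I", "2019-08-01", 2.2, va2, vb2,
                   has_modified_peptide = TRUE),                     # modified peptide
    benchmark_case("7EEE", "II", "2019-06-01", 2.0, va1, vb1),       # other class: kept
    benchmark_case("7FFF", "I", "2019-09-01", 2.4, va3, vb3))        # kept
  kept <- assemble_benchmark(cand, reference = list(),
                             date_cutoff = "2018-04-30")
  expect_equal(vapply(kept, function(x) x$source_id, ""),
               c("7AAA", "7EEE", "7FFF"))
  # a reference case knocks out its match
  ref <- list(benchmark_case("6REF", "I", "2016-01-01", 2.0, va1, vb1))
  kept2 <- assemble_benchmark(cand, reference = ref,
                              date_cutoff = "2018-04-30")
  expect_equal(vapply(kept2, function(x) x$source_id, ""),
               c("7EEE", "7FFF"))
  expect_length(assemble_benchmark(list(), date_cutoff = "2018-04-30"), 0L)
  # mutual redundancy keeps the lexicographically first candidate
  pair <- list(benchmark_case("7ZZB", "I", "2019-01-02", 2.0, va1, vb1),
               benchmark_case("7ZZA", "I", "2019-01-03", 2.1, near(va1), vb1))
  kept3 <- assemble_benchmark(pair, date_cutoff = "2018-04-30")
  expect_equal(vapply(kept3, function(x) x$source_id, ""), "7ZZA")
  # no redundant pair survives in the output (exhaustive scan)
  for (i in seq_along(kept)) for (j in seq_len(i - 1L))
    expect_false(is_redundant(kept[[i]], kept[[j]]))
})

test_that("discrimination statistics reproduce the pair-counting oracle", {
  # perfectly separated scores
  expect_equal(evaluate_discrimination(
    c(0.9, 0.8, 0.2, 0.1), c("High", "Medium", "Incorrect", "Incorrect"))$roc_auc,
    1.0)
  # all scores equal: ties count one half
  expect_equal(evaluate_discrimination(
    rep(0.5, 4), c("High", "Medium", "Incorrect", "Incorrect"))$roc_auc, 0.5)
  # 6-model toy vs exhaustive concordant-pair counting; Acceptable excluded
  scores <- c(0.9, 0.55, 0.52, 0.6, 0.3, 0.52)
  labels <- c("High", "Medium", "Incorrect", "Acceptable", "Incorrect",
              "Medium")
  got <- evaluate_discrimination(scores, labels,
                                 dockq = c(0.8, 0.5, 0.1, 0.3, 0.05, 0.45))
  pos <- which(labels %in% c("Medium", "High"))
  neg <- which(labels == "Incorrect")
  cmp <- 0
  for (p in pos) for (n in neg)
    cmp <- cmp + (scores[p] > scores[n]) + 0.5 * (scores[p] == scores[n])
  expect_equal(got$roc_auc, cmp / (length(pos) * length(neg)))
  expect_equal(got$pearson_r,
               cor(scores, c(0.8, 0.5, 0.1, 0.3, 0.05, 0.45)))
  expect_error(evaluate_discrimination(c(0.5, 0.6), c("High", "Medium")),
               "undefined")
})
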