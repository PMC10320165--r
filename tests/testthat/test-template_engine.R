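# Similarity scoring, Class II trimming, library curation, ranked template
# selection, chain merging, focused database assembly.

b62 <- local({
  e <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = e)
  e$BLOSUM62
})

ungapped_sum <- function(a, b) {
  pa <- strsplit(a, "")[[1]]; pb <- strsplit(b, "")[[1]]
  sum(vapply(seq_along(pa), function(i) b62[pa[i], pb[i]], 0))
}

random_pep <- function(n) paste(sample(rownames(b62)[1:20], n, TRUE),
                                collapse = "")

test_that("alignment scores reproduce direct BLOSUM62 lookups", {
  expect_equal(score_similarity("AAAA", "AAAA"), 4 * b62["A", "A"],
               ignore_attr = TRUE)
  expect_equal(score_similarity("A", "A"), b62["A", "A"],
               ignore_attr = TRUE)
  expect_error(score_similarity("AB2", "AAA"), "non-amino-acid|matrix")
})

test_that("the flat -100 gap penalty makes equal-length peptide scoring ungapped", {
  set.seed(101)
  for (i in 1:1000) {
    n <- sample(8:11, 1)
    a <- random_pep(n); b <- random_pep(n)
    expect_equal(score_similarity(a, b, peptide_similarity_params()),
                 ungapped_sum(a, b))
  }
})

test_that("Class II trimming keeps the 9-mer core plus available flanks", {
  # 15-mer with an internal core: core + one flank each side = 11-mer
  expect_equal(trim_class2_peptide("TEVVRHCPHHERCSD", 3), "EVVRHCPHHER")
  expect_equal(nchar(trim_class2_peptide("TEVVRHCPHHERCSD", 3)), 11L)
  # 9-mer flush with both termini: unchanged
  expect_equal(trim_class2_peptide("SPRWYFYYL", 1), "SPRWYFYYL")
  # 10-mer with the core at the N terminus: only the C-terminal flank exists
  p10 <- "ACDEFGHIKL"
  expect_equal(trim_class2_peptide(p10, 1), p10)
  expect_equal(nchar(trim_class2_peptide(p10, 1)), 10L)
  expect_error(trim_class2_peptide("SPRWYFYYL", 2), "outside")
  expect_error(trim_class2_peptide("SPRWYF", 1), "shorter")
})

test_that("library curation applies resolution, date, trimming and the 2-copy cap", {
  expect_length(build_pmhc_library(list())$records, 0L)
  lib <- make_toy_library(seed = 5, n_templates = 3, duplicates = 4)
  # the duplicated pMHC sequence is retained at most twice
  key <- vapply(lib$records, function(r) paste(r$peptide_seq, r$mhc_seq), "")
  expect_true(all(table(key) <= 2L))
  expect_length(lib$records, 4L)  # 2 of the duplicated + 2 distinct
  # the two kept duplicates are the best-resolution copies
  dup_res <- vapply(lib$records[key == key[duplicated(key)][1]],
                    function(r) r$resolution, 0)
  expect_equal(length(dup_res), 2L)
  # resolution cutoff is inclusive (<=)
  mk <- function(res, id) list(
    structure = make_toy_complex(fixture_spec(seed = 8))$native,
    mhc_class = "I", peptide_chain = "C", mhc_chains = "A",
    resolution = res, release_date = as.Date("2017-05-01"), source_id = id)
  lib2 <- build_pmhc_library(list(mk(3.4, "R1"), mk(3.5, "R2"),
                                  mk(3.6, "R3")), resolution_cutoff = 3.5)
  expect_equal(sort(vapply(lib2$records, function(r) r$source_id, "")),
               c("R1", "R2"))
  # date cutoff drops later releases
  e <- mk(3.0, "D1"); e$release_date <- as.Date("2020-01-01")
  lib3 <- build_pmhc_library(list(e), cutoff_date = "2018-04-30")
  expect_length(lib3$records, 0L)
  # Class II peptides come out trimmed to <= 11 residues
  libII <- make_toy_library(seed = 6, n_templates = 2, classes = "II")
  expect_true(all(vapply(libII$records,
                         function(r) nchar(r$peptide_seq), 0L) <= 11L))
})

test_that("an entry with missing annotated chains is skipped with a warning", {
  e <- list(structure = make_toy_complex(fixture_spec(seed = 9))$native,
            mhc_class = "I", peptide_chain = "Z", mhc_chains = "A",
            resolution = 2.0, release_date = as.Date("2017-01-01"),
            source_id = "BAD")
  expect_warning(lib <- build_pmhc_library(list(e)), "skipping")
  expect_length(lib$records, 0L)
})

test_that("pMHC template selection filters by peptide length and ranks deterministically", {
  lib <- make_toy_library(seed = 21, n_templates = 4)
  # all library peptides are 9-mers; a 10-mer query finds nothing
  expect_message(
    hits <- select_pmhc_templates(random_pep(10), random_pep(30), lib, "I"),
    "template-free")
  expect_equal(nrow(hits), 0L)
  # query identical to a library entry ranks that entry first
  rec <- lib$records[[3]]
  hits <- select_pmhc_templates(rec$peptide_seq, rec$mhc_seq, lib, "I", k = 4)
  expect_equal(hits$source_id[1], rec$source_id)
  expect_true(all(vapply(attr(hits, "records"),
                         function(r) nchar(r$peptide_seq), 0L) ==
                    nchar(rec$peptide_seq)))
  # identical MHC, peptides differing by one substitution: peptide score decides
  base <- lib$records[[1]]
  pep2 <- base$peptide_seq
  substr(pep2, 5, 5) <- if (substr(pep2, 5, 5) == "A") "W" else "A"
  lib2 <- lib
  lib2$records <- list(base,
                       template_record("ZZZZ", "I", pep2, base$mhc_seq, 2.5))
  hits2 <- select_pmhc_templates(base$peptide_seq, base$mhc_seq, lib2, "I")
  expect_equal(hits2$source_id[1], base$source_id)
  expect_gt(hits2$peptide_score[1], hits2$peptide_score[2])
  expect_equal(hits2$mhc_score[1], hits2$mhc_score[2])
})

test_that("template ranking is invariant to library insertion order", {
  lib <- make_toy_library(seed = 22, n_templates = 5)
  q <- lib$records[[2]]
  base <- select_pmhc_templates(q$peptide_seq, q$mhc_seq, lib, "I", k = 5)
  set.seed(1)
  for (i in 1:5) {
    perm <- lib
    perm$records <- lib$records[sample(length(lib$records))]
    expect_identical(
      select_pmhc_templates(q$peptide_seq, q$mhc_seq, perm, "I", k = 5),
      base, ignore_attr = TRUE)
  }
})

test_that("TCR template search ranks by single-sequence identity", {
  set.seed(31)
  q <- random_pep(100)
  # candidate differing at 11 of 100 positions: identity 0.89
  cand <- q
  pos <- sample(100, 11)
  for (p in pos) {
    cur <- substr(cand, p, p)
    substr(cand, p, p) <- if (cur == "A") "W" else "A"
  }
  db <- data.frame(source_id = c("5W1V", "6VQO", "9XYZ"),
                   sequence = c(cand, q, random_pep(90)),
                   stringsAsFactors = FALSE)
  hits <- select_tcr_templates(q, db, k = 10)
  expect_equal(hits$source_id[1], "6VQO")   # verbatim match first
  expect_equal(hits$identity[1], 1.0)
  expect_equal(hits$identity[hits$source_id == "5W1V"], 0.89)
  expect_equal(nrow(hits), 3L)              # k larger than the db
  expect_error(select_tcr_templates("", db), "empty")
})

test_that("merging pMHC chains shifts the peptide index and splits back exactly", {
  toy <- make_toy_complex(fixture_spec(seed = 41, n_mhc = 20))
  m <- toy$native
  merged <- merge_pmhc_chains(m, peptide_chain = "C", mhc_chains = "A",
                              index_offset = 200)
  expect_equal(unique(merged$atoms$chain), "A")
  pep_res <- residue_table(m, "C")
  mhc_res <- residue_table(m, "A")
  merged_pep <- (nrow(mhc_res) + 200 + 1):(nrow(mhc_res) + 200 + nrow(pep_res))
  expect_equal(sort(unique(merged$atoms$resno)),
               c(seq_len(nrow(mhc_res)), merged_pep))
  # round trip restores both chains' coordinates exactly
  back <- split_pmhc_chains(merged)
  for (ch in c("A", "C"))
    expect_equal(atom_xyz(back, ch), atom_xyz(m, ch), ignore_attr = TRUE)
  expect_error(merge_pmhc_chains(m, "C", "A", index_offset = 0), ">= 32")
})

test_that("focused databases union hit sets and drop duplicate IDs", {
  s1 <- setNames(replicate(10, random_pep(20)), paste0("id", 1:10))
  s2 <- setNames(replicate(8, random_pep(20)),
                 paste0("id", 8:15))           # shares id8, id9, id10
  dbs <- build_focused_dbs(list(uniref90_like = list(s1, s2)))
  expect_equal(length(dbs$uniref90_like), 15L)
  expect_false(anyDuplicated(names(dbs$uniref90_like)) > 0)
  # first occurrence wins
  expect_equal(as.character(dbs$uniref90_like[["id8"]]), unname(s1["id8"]))
  # empty input produces a valid empty database
  empty <- build_focused_dbs(list(small_bfd_like = list(character())))
  expect_equal(length(empty$small_bfd_like), 0L)
  p <- write_focused_dbs(empty, tempfile())
  expect_true(file.exists(p))
  # single hit set is the identity
  one <- build_focused_dbs(list(uniprot_like = list(s1)))
  expect_equal(unname(as.character(one$uniprot_like)), unname(s1))
})

test_that("template libraries round-trip through their on-disk layout", {
  lib <- make_toy_library(seed = 51, n_templates = 2)
  dir <- tempfile()
  write_template_library(lib, dir)
  idx <- read.table(file.path(dir, "templates.tsv"), header = TRUE,
                    sep = "\t", stringsAsFactors = FALSE)
  expect_equal(nrow(idx), length(lib$records))
  for (r in lib$records) {
    m <- read_structure(file.path(dir, paste0(r$source_id, ".pdb")))
    expect_equal(nrow(m$atoms), nrow(r$merged_structure$atoms))
  }
})
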