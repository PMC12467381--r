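make_set <- function(n, prefix = "T", offset = 0L, term_pool = NULL) {
  term_pool <- term_pool %||% ae_term_vocabulary()
  rows <- do.call(rbind, lapply(seq_len(n), function(i) {
    idx <- offset + i
    withr::with_seed(idx, {
      terms <- sample(term_pool, sample(2:5, 1))
      organs <- sample(c("Heart", "Lung", "Kidney", "Skin"), sample(1:2, 1))
    })
    data.frame(target_id = sprintf("%s%03d", prefix, idx),
               accession = sprintf("%s%03d", prefix, idx),
               organ_group = rep(organs, length.out = length(terms)),
               ae_term = terms, stringsAsFactors = FALSE)
  }))
  annotation_set(rows)
}

test_that("merging annotation sets unions records by accession", {
  a <- annotation_set(data.frame(
    target_id = "t1", accession = "P1", organ_group = "Heart",
    ae_term = c("nausea", "Headache"), stringsAsFactors = FALSE))
  b <- annotation_set(data.frame(
    target_id = "t1b", accession = "P1",
    organ_group = c("Heart", "Lung"),
    ae_term = c("headache", "cough"), stringsAsFactors = FALSE))
  m <- merge_annotation_sets(a, b)
  expect_length(m, 1L)
  r <- m$records[["P1"]]
  # case-insensitive union of terms
  expect_setequal(tolower(r$ae_terms), c("nausea", "headache", "cough"))
  expect_setequal(names(r$organ_terms), c("Heart", "Lung"))
  expect_setequal(tolower(r$organ_terms$Heart), c("nausea", "headache"))
  # merging with an empty-ish set is the identity
  empty <- structure(list(records = list()), class = "annotation_set")
  expect_identical(merge_annotation_sets(a, empty)$records, a$records)
})

test_that("merge is idempotent and commutative up to record order", {
  a <- make_set(6)
  self <- merge_annotation_sets(a, a)
  expect_identical(self$records, a$records)
  b <- make_set(4, offset = 3L) # overlaps a on 3 accessions
  ab <- merge_annotation_sets(a, b)
  ba <- merge_annotation_sets(b, a)
  expect_setequal(names(ab$records), names(ba$records))
  for (acc in names(ab$records)) {
    expect_setequal(tolower(ab$records[[acc]]$ae_terms),
                    tolower(ba$records[[acc]]$ae_terms))
  }
})

test_that("disjoint sets of 24 and 94 targets merge to 118 unique accessions", {
  a <- make_set(24, prefix = "SMIT")
  b <- make_set(94, prefix = "BASS")
  m <- merge_annotation_sets(a, b)
  expect_identical(length(m), 118L)
  expect_identical(anyDuplicated(names(m$records)), 0L)
})

test_that("conflicting sequences under one accession are rejected", {
  a <- annotation_set(data.frame(target_id = "t", accession = "P1",
                                 organ_group = "Heart", ae_term = "nausea",
                                 sequence_ref = "seqA"))
  b <- annotation_set(data.frame(target_id = "t", accession = "P1",
                                 organ_group = "Heart", ae_term = "rash",
                                 sequence_ref = "seqB"))
  expect_error(merge_annotation_sets(a, b), "conflicting sequences")
})

test_that("organ ranking orders by term count with alphabetical tie-break", {
  rec <- list(ae_terms = letters[1:6],
              organ_terms = list(Kidney = c("a"), Lung = c("b", "c", "d"),
                                 Heart = c("e", "f")))
  expect_identical(rank_organ_sources(rec), "Lung/Heart/Kidney")
  # invariant to the input ordering of organ_terms
  rec2 <- rec; rec2$organ_terms <- rev(rec$organ_terms)
  expect_identical(rank_organ_sources(rec2), "Lung/Heart/Kidney")
  # single organ stands alone
  expect_identical(rank_organ_sources(list(organ_terms = list(Skin = "a"))), "Skin")
  # tie: alphabetical
  expect_identical(rank_organ_sources(list(organ_terms = list(
    Lung = c("a", "b"), Heart = c("c", "d")))), "Heart/Lung")
})

test_that("levenshtein agrees with the DP oracle and satisfies metric axioms", {
  expect_identical(levenshtein("abc", "abc"), 0L)
  expect_identical(levenshtein("", "abc"), 3L)
  expect_identical(levenshtein("kitten", "sitting"), 3L)
  withr::local_seed(5)
  for (i in 1:50) {
    a <- random_word(sample(0:8, 1)); b <- random_word(sample(0:8, 1))
    c <- random_word(sample(0:8, 1))
    expect_identical(levenshtein(a, b), as.integer(dp_levenshtein(a, b)))
    expect_identical(levenshtein(a, b), levenshtein(b, a))
    expect_identical(levenshtein(a, a), 0L)
    expect_lte(levenshtein(a, c), levenshtein(a, b) + levenshtein(b, c))
  }
})

test_that("profile clustering cuts to exactly k with zero-distance targets co-clustered", {
  set <- make_set(12)
  # duplicate one profile under a fresh accession
  dup <- set$records[[1]]
  dup$accession <- "DUP001"; dup$target_id <- "DUP001"
  set$records[["DUP001"]] <- dup
  cl <- cluster_targets_by_ae(set, k = 5L)
  expect_identical(length(unique(cl)), 5L)
  expect_identical(unname(cl[set$records[[1]]$accession]), unname(cl["DUP001"]))
  # k = n gives singletons
  cln <- cluster_targets_by_ae(set, k = length(set))
  expect_identical(length(unique(cln)), length(set))
  expect_error(cluster_targets_by_ae(set, k = length(set) + 1L), "exceeds")
})

test_that("small-instance clustering matches a brute-force agglomerative oracle", {
  profiles <- c(A = "aaaa", B = "aaab", C = "bbbb", D = "bbbc", E = "zzzzzzzz")
  rows <- do.call(rbind, lapply(names(profiles), function(nm) {
    data.frame(target_id = nm, accession = nm, organ_group = "Heart",
               ae_term = profiles[[nm]], stringsAsFactors = FALSE)
  }))
  set <- annotation_set(rows)
  co_membership <- function(lab) outer(lab, lab, `==`)
  for (linkage in c("average", "single", "complete")) {
    cl <- cluster_targets_by_ae(set, k = 3L, linkage = linkage)
    oracle <- brute_agglom(utils::adist(profiles), 3L, linkage)
    # same partition up to label renaming
    expect_identical(unname(co_membership(unname(cl[names(profiles)]))),
                     unname(co_membership(oracle)), label = linkage)
  }
})

test_that("dendrograms export as Newick readable by standard tree tools", {
  set <- make_set(8)
  cl <- cluster_targets_by_ae(set, k = 3L)
  f <- withr::local_tempfile(fileext = ".nwk")
  write_cluster_newick(cl, f)
  tr <- ape::read.tree(f)
  expect_setequal(tr$tip.label, names(set$records))
})

test_that("annotation tables round-trip through CSV and JSON", {
  set <- make_set(5)
  for (ext in c(".csv", ".json")) {
    f <- withr::local_tempfile(fileext = ext)
    write_annotation_table(set, f)
    back <- read_annotation_table(f)
    expect_setequal(names(back$records), names(set$records))
    for (acc in names(set$records)) {
      expect_setequal(tolower(back$records[[acc]]$ae_terms),
                      tolower(set$records[[acc]]$ae_terms))
    }
  }
})

test_that("curation patches add and remove terms declaratively", {
  set <- annotation_set(data.frame(
    target_id = "t1", accession = "P1", organ_group = c("Lung", "Heart"),
    ae_term = c("cough", "palpitations"), stringsAsFactors = FALSE))
  patched <- apply_annotation_patch(set, list(
    list(action = "add", accession = "P1", organ_group = "Skin",
         ae_term = "rash"),
    list(action = "remove", accession = "P1", organ_group = "Lung",
         ae_term = "cough")
  ))
  r <- patched$records[["P1"]]
  expect_true("rash" %in% r$organ_terms$Skin)
  expect_false("cough" %in% unlist(r$organ_terms))
  expect_warning(apply_annotation_patch(set, list(
    list(action = "add", accession = "NOPE", organ_group = "Skin",
         ae_term = "rash"))), "unknown accession")
})
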