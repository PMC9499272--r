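test_that("multi-label FASTA headers parse into records and label sets", {
  f <- withr::local_tempfile(fileext = ".fa")
  writeLines(c(">p1|ABP,ACP", "GLFDIIKKIAESF"), f)
  recs <- read_multilabel_fasta(f)
  expect_equal(nrow(recs), 1L)
  expect_equal(recs$id, "p1")
  expect_setequal(recs$labels[[1]], c("ABP", "ACP"))
  expect_equal(recs$sequence, "GLFDIIKKIAESF")
})

test_that("unknown label codes are kept but flagged", {
  f <- withr::local_tempfile(fileext = ".fa")
  writeLines(c(">p2|XYZ", "AAAAA"), f)
  expect_warning(recs <- read_multilabel_fasta(f, label_vocab(MFTP_CLASSES)),
                 "XYZ")
  expect_equal(nrow(recs), 1L)
  expect_equal(recs$labels[[1]], "XYZ")
})

test_that("malformed FASTA fails with a line number; empty file warns", {
  f <- withr::local_tempfile(fileext = ".fa")
  writeLines(c("ACDEF", ">p1|ABP", "AAAAA"), f)
  expect_error(read_multilabel_fasta(f), "line 1")
  writeLines(c(">p1|ABP", ">p2|ACP", "AAAAA"), f)
  expect_error(read_multilabel_fasta(f), "line 1.*no sequence")
  writeLines(character(), f)
  expect_warning(recs <- read_multilabel_fasta(f), "empty")
  expect_equal(nrow(recs), 0L)
})

test_that("write/read round-trips random record sets", {
  recs <- random_records(20, seed = 11)
  f <- withr::local_tempfile(fileext = ".fa")
  write_multilabel_fasta(recs, f)
  back <- read_multilabel_fasta(f)
  expect_equal(back$id, recs$id)
  expect_equal(back$sequence, recs$sequence)
  expect_equal(back$labels, recs$labels)
})

test_that("merging sources unions labels of identical sequences", {
  m <- merge_peptide_sources(list(ABP = c("AAAAA", "CCCCC"), ACP = "CCCCC"))
  expect_equal(nrow(m), 2L)
  expect_equal(m$sequence, c("AAAAA", "CCCCC"))  # lexicographic
  expect_equal(m$labels[[1]], "ABP")
  expect_setequal(m$labels[[2]], c("ABP", "ACP"))
})

test_that("disjoint sources keep every sequence; duplicates within a source collapse", {
  m <- merge_peptide_sources(list(ABP = c("AAAAA", "AAAAA", "CCCCC"),
                                  ACP = "DDDDD"))
  expect_equal(nrow(m), 3L)
})

test_that("merge matches a brute-force dictionary and ignores source order", {
  withr::with_seed(5, {
    pool <- vapply(1:30, function(i) {
      paste(sample(AA_ALPHABET, 8, replace = TRUE), collapse = "")
    }, "")
    src <- list(ABP = sample(pool, 20, replace = TRUE),
                ACP = sample(pool, 15, replace = TRUE),
                AFP = sample(pool, 10, replace = TRUE))
  })
  m <- merge_peptide_sources(src)
  # brute force: dictionary of sequence -> label set
  dict <- list()
  for (code in names(src)) {
    for (s in src[[code]]) dict[[s]] <- union(dict[[s]], code)
  }
  expect_equal(nrow(m), length(dict))
  for (i in seq_len(nrow(m))) {
    expect_setequal(m$labels[[i]], dict[[m$sequence[i]]])
  }
  m2 <- merge_peptide_sources(src[c(3, 1, 2)])
  expect_equal(m2$sequence, m$sequence)
  expect_equal(m2$labels, m$labels)
})

test_that("the three curation criteria drop short, long, non-standard and rare-class records", {
  recs <- peptide_set(
    paste0("p", 1:5),
    c("ACDE",                                   # length 4 < 5
      strrep("A", 51),                          # length 51 > 50
      "ACDEB",                                  # non-standard 'B'
      "GLFDIIKKIAESF", "KWKLFKKIGAVLKVL"),      # valid
    list("ABP", "ABP", "ABP", c("ABP", "ACP"), "ABP"))
  cur <- curate_peptides(recs, min_class_count = 1)
  expect_equal(nrow(cur$records), 2L)
  expect_setequal(cur$records$id, c("p4", "p5"))
  expect_setequal(unclass(cur$vocab), c("ABP", "ACP"))
})

test_that("classes below the membership threshold are pruned from vocabulary and labels", {
  recs <- peptide_set(
    sprintf("p%02d", 1:41),
    replicate(41, paste(rep("ACDEF", 2), collapse = "")),
    c(rep(list(c("ABP", "ACP")), 39), list("ABP"), list("ABP")))
  cur <- curate_peptides(recs, min_class_count = 40)
  expect_false("ACP" %in% unclass(cur$vocab))
  expect_true(all(vapply(cur$records$labels,
                         function(l) !"ACP" %in% l, TRUE)))
  expect_equal(nrow(cur$records), 41L)  # records keep their ABP label
})

test_that("curation is the identity on clean data and is idempotent", {
  recs <- random_records(50, seed = 3)
  cur1 <- curate_peptides(recs, min_class_count = 1)
  expect_equal(nrow(cur1$records), 50L)
  cur2 <- curate_peptides(cur1$records, min_class_count = 1)
  expect_equal(cur2$records$sequence, cur1$records$sequence)
  expect_equal(cur2$records$labels, cur1$records$labels)
  expect_equal(unclass(cur2$vocab), unclass(cur1$vocab))
})

test_that("curating an all-invalid set raises an empty-dataset error", {
  recs <- peptide_set("p1", "ACDE", list("ABP"))
  expect_error(curate_peptides(recs), "empty dataset")
})

test_that("token encoding maps letters to alphabetical indices with zero padding", {
  v <- label_vocab(c("ABP", "ACP"))
  enc <- encode_peptides(peptide_set("p", "AAAAA", list("ABP")), v, L = 50)
  expect_equal(enc$tokens[1, ], c(rep(1L, 5), rep(0L, 45)))
  enc2 <- encode_peptides(peptide_set("p", "ACDE", list("ABP")), v, L = 50)
  expect_equal(enc2$tokens[1, 1:5], c(1L, 2L, 3L, 4L, 0L))
  expect_equal(unname(enc2$labels[1, ]), c(1L, 0L))
})

test_that("encoding rejects overlong sequences and non-standard residues", {
  v <- label_vocab(c("ABP", "ACP"))
  expect_error(encode_peptides(peptide_set("p", strrep("A", 9), list("ABP")),
                               v, L = 8), "longer than L")
  expect_error(encode_peptides(peptide_set("p", "ACDEX", list("ABP")),
                               v, L = 8), "'X'")
})

test_that("decode inverts encode on curated sequences", {
  recs <- random_records(25, seed = 9)
  v <- label_vocab(c("ABP", "ACP", "AFP"))
  enc <- encode_peptides(recs, v, L = 30)
  expect_equal(decode_tokens(enc$tokens), recs$sequence)
})

test_that("train/test split has exact sizes and is a reproducible partition", {
  recs <- random_records(10, seed = 2)
  sp <- split_train_test(recs, ratio = 0.8, seed = 7)
  expect_equal(nrow(sp$train), 8L)
  expect_equal(nrow(sp$test), 2L)
  sp2 <- split_train_test(recs, ratio = 0.8, seed = 7)
  expect_equal(sp2$train$id, sp$train$id)
  for (run in 1:100) {
    r <- random_records(sample(5:40, 1), seed = run)
    s <- split_train_test(r, ratio = 0.7, seed = run)
    expect_equal(sort(c(s$train$id, s$test$id)), sort(r$id))
    expect_length(intersect(s$train$id, s$test$id), 0L)
  }
  expect_error(split_train_test(recs[1, ]), "at least 2")
})

test_that("TSV export and vocabulary JSON round-trip", {
  recs <- random_records(5, seed = 1)
  f <- withr::local_tempfile(fileext = ".tsv")
  write_peptide_tsv(recs, f)
  tab <- read.delim(f)
  expect_equal(tab$sequence, recs$sequence)
  vj <- withr::local_tempfile(fileext = ".json")
  v <- label_vocab(c("ABP", "ACP", "AFP"))
  write_vocab_json(v, vj)
  expect_equal(unclass(read_vocab_json(vj)), unclass(v))
})
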