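test_that("preprocessing lowercases, drops non-alphabetic tokens and chunks greedily", {
  expect_equal(preprocess_report("No acute disease.", 22), "no acute disease")
  expect_equal(preprocess_report("Lungs clear. Heart size normal.", 2),
               c("lungs clear", "heart size", "normal"))
  expect_equal(preprocess_report("Opacity in left lobe, 3 cm.", 22),
               "opacity in left lobe cm")
  # two short sentences pack into one chunk when they fit together
  expect_equal(preprocess_report("Lungs clear. Heart size normal.", 22),
               "lungs clear heart size normal")
  expect_error(preprocess_report("123 !?", 22), "no tokens survive")
  expect_error(preprocess_report("   ", 22), "no tokens survive")
})

test_that("preprocessing is idempotent and conserves the token stream", {
  set.seed(31)
  words <- c("lungs", "clear", "heart", "opacity", "cm", "x", "effusion")
  for (rep in 1:20) {
    n <- sample(3:30, 1)
    toks <- sample(words, n, replace = TRUE)
    raw <- paste(toks, collapse = " ")
    # sprinkle punctuation and digits
    raw <- gsub("opacity", "Opacity, 3", raw)
    mw <- sample(2:25, 1)
    chunks <- preprocess_report(raw, mw)
    again <- unlist(lapply(chunks, preprocess_report, max_words = mw))
    expect_identical(chunks, again)
    stream <- unlist(strsplit(chunks, " "))
    expect_identical(stream, unlist(strsplit(tolower(gsub("[^a-zA-Z]+", " ", raw)), " +"))[
      nzchar(unlist(strsplit(tolower(gsub("[^a-zA-Z]+", " ", raw)), " +")))])
    expect_true(all(lengths(strsplit(chunks, " ")) <= mw))
  }
})

test_that("vocabulary has sentinels, deterministic frequency-ranked ids", {
  v <- build_vocabulary("no acute disease")
  expect_equal(vocab_size(v), 5L)
  expect_equal(vocab_size(build_vocabulary(c("a b", "b c"))), 5L)
  expect_error(build_vocabulary(character(0)), "empty corpus")

  v2 <- build_vocabulary(c("b a", "b c", "c b"))
  expect_identical(v2$tokens[1:2], c("startseq", "endseq"))
  # b (freq 3) before c (freq 2) before a (freq 1)
  expect_identical(v2$tokens[3:5], c("b", "c", "a"))
  expect_identical(build_vocabulary(c("b a", "b c", "c b")), v2)
  expect_error(build_vocabulary("report with startseq inside"), "reserved")
})

test_that("encode/decode round-trips with exact padding layout", {
  v <- build_vocabulary("no acute disease")
  ids <- encode_report("no acute disease", v, 6L)
  expect_length(ids, 6L)
  expect_equal(ids[1], v$start_id)
  expect_equal(ids[5], v$end_id)
  expect_equal(ids[6], v$pad_id)
  expect_equal(sum(ids != v$pad_id), 3L + 2L)
  expect_equal(decode_report(ids, v), "no acute disease")

  empty <- encode_report("", v, 4L)
  expect_equal(empty, c(1L, 2L, 0L, 0L))
  expect_error(encode_report("no xyz", v, 6L), "xyz")
  expect_error(encode_report("no acute disease", v, 4L), "fit")
})

test_that("round-trip and padding conservation hold on generated corpora", {
  set.seed(7)
  words <- letters[1:12]
  reports <- replicate(25, paste(sample(words, sample(1:15, 1), TRUE),
                                 collapse = " "))
  v <- build_vocabulary(reports)
  for (r in reports) {
    ids <- encode_report(r, v, 20L)
    expect_equal(decode_report(ids, v), r)
    expect_equal(sum(ids != 0L), length(strsplit(r, " ")[[1]]) + 2L)
  }
})

test_that("corpus splits are sized, disjoint, seeded and varied across repeats", {
  plans <- split_corpus(10L, fraction = 0.8, seed = 3L)
  expect_length(plans[[1]]$train, 8L)
  expect_length(plans[[1]]$test, 2L)
  expect_length(intersect(plans[[1]]$train, plans[[1]]$test), 0L)
  expect_setequal(c(plans[[1]]$train, plans[[1]]$test), 1:10)

  expect_identical(split_corpus(50L, 0.8, seed = 9L, repeats = 4L),
                   split_corpus(50L, 0.8, seed = 9L, repeats = 4L))

  plans10 <- split_corpus(10L, 0.8, seed = 5L, repeats = 10L)
  tests <- sapply(plans10, function(p) paste(p$test, collapse = ","))
  expect_gt(length(unique(tests)), 1L)
  expect_error(split_corpus(10L, fraction = 1.2), "fraction")
})

test_that("manifests round-trip through JSON-lines and CSV", {
  df <- data.frame(image = c("a.png", "b.png"),
                   findings = c("Lungs are clear.", "There is an opacity."),
                   stringsAsFactors = FALSE)
  jl <- tempfile(fileext = ".jsonl")
  write_manifest(df, jl)
  expect_equal(read_manifest(jl), df)

  cs <- tempfile(fileext = ".csv")
  write.csv(df, cs, row.names = FALSE)
  expect_equal(read_manifest(cs), df)
})

test_that("vocabulary JSON serialisation round-trips", {
  v <- build_vocabulary(c("lungs are clear", "heart is enlarged"))
  f <- tempfile(fileext = ".json")
  write_vocab(v, f, l_max = 24L)
  v2 <- read_vocab(f)
  expect_identical(v2$tokens, v$tokens)
  expect_identical(v2$pad_id, v$pad_id)
})

test_that("prepare_corpus yields one record per chunk with valid encodings", {
  df <- data.frame(
    image = c("x.png", "y.png"),
    findings = c("Lungs are clear.",
                 paste(rep("opacity in the left lung.", 6), collapse = " ")),
    stringsAsFactors = FALSE)
  corp <- prepare_corpus(df, l_max = 12L, max_words = 10L, base_dir = "d")
  expect_s3_class(corp, "cxr_corpus")
  expect_gt(nrow(corp$records), 2L)  # long findings were chunked
  expect_true(all(corp$ids[, 1] == 1L))
  expect_true(all(rowSums(corp$ids == 2L) == 1L))
  expect_equal(ncol(corp$ids), 12L)
  # every record decodes back to its text
  for (i in seq_len(nrow(corp$records)))
    expect_equal(decode_report(corp$ids[i, ], corp$vocab),
                 corp$records$text[i])
})
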