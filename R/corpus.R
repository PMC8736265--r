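#' Preprocess raw findings text into short report chunks
#'
#' Radiology findings are free text of arbitrary length. The sequence model
#' works on short reports, so long findings are lowercased, stripped of
#' every non-alphabetic token, and greedily packed into chunks of at most
#' `max_words` words. Chunk boundaries fall at sentence boundaries
#' (`.`, `?`, `!`) whenever the next sentence still fits; a single sentence
#' longer than `max_words` is split at exactly `max_words` words. The
#' concatenation of all chunk tokens always equals the filtered token stream
#' of the input, so no word is lost or duplicated.
#'
#' Only ASCII letters survive the filter: digits, punctuation and non-ASCII
#' characters are treated as token separators, so "3 cm." contributes the
#' single token "cm".
#'
#' @param raw_text Character scalar, the raw findings text.
#' @param max_words Maximum number of words per chunk (start/end sentinels
#'   are added later and do not count).
#' @return Character vector of one or more preprocessed report strings.
#' @examples
#' preprocess_report("No acute disease.")
#' preprocess_report("Lungs clear. Heart size normal.", max_words = 2)
#' @export
preprocess_report <- function(raw_text, max_words = 22L) {
  stopifnot(is.character(raw_text), length(raw_text) == 1L)
  max_words <- as.integer(max_words)
  if (is.na(max_words) || max_words < 1L)
    stop("`max_words` must be a positive integer")
  if (!nzchar(gsub("[[:space:]]+", "", raw_text)))
    stop("no tokens survive filtering: input is empty")

  sentences <- strsplit(raw_text, "[.?!]+")[[1]]
  tokenise <- function(s) {
    s <- gsub("[^a-z]+", " ", tolower(s), perl = TRUE)
    toks <- strsplit(trimws(s), "[[:space:]]+")[[1]]
    toks[nzchar(toks)]
  }
  sent_tokens <- lapply(sentences, tokenise)
  sent_tokens <- sent_tokens[vapply(sent_tokens, length, 1L) > 0L]
  if (length(sent_tokens) == 0L)
    stop("no tokens survive filtering")

  chunks <- list()
  current <- character(0)
  flush <- function() {
    if (length(current) > 0L) chunks[[length(chunks) + 1L]] <<- current
    current <<- character(0)
  }
  for (toks in sent_tokens) {
    if (length(current) + length(toks) <= max_words) {
      current <- c(current, toks)
    } else {
      flush()
      while (length(toks) > max_words) {
        chunks[[length(chunks) + 1L]] <- toks[seq_len(max_words)]
        toks <- toks[-seq_len(max_words)]
      }
      current <- toks
    }
  }
  flush()
  vapply(chunks, paste, "", collapse = " ")
}

#' Build a token vocabulary from preprocessed reports
#'
#' Tokens are assigned integer ids 1..V. The sentinels `"startseq"` (id 1)
#' and `"endseq"` (id 2) are always present; corpus words follow, ordered by
#' descending corpus frequency with lexicographic tie-break, so the mapping
#' is deterministic across runs. Id 0 is reserved for padding and is never a
#' word.
#'
#' @param reports Character vector of preprocessed report strings
#'   (see [preprocess_report()]).
#' @return An object of class `cxr_vocab`: a list with `tokens` (character
#'   vector indexed by id), `start_id`, `end_id`, `pad_id`.
#' @export
build_vocabulary <- function(reports) {
  if (length(reports) == 0L) stop("empty corpus: no reports to build a vocabulary from")
  words <- unlist(strsplit(reports, "[[:space:]]+"))
  words <- words[nzchar(words)]
  if (length(words) == 0L) stop("empty corpus: reports contain no tokens")
  if (any(words %in% c("startseq", "endseq")))
    stop("corpus contains a reserved sentinel token ('startseq'/'endseq')")
  if (any(grepl("[^a-z]", words)))
    stop("reports are not preprocessed: non-lowercase-alphabetic token found")
  freq <- table(words)
  ord <- order(-as.integer(freq), names(freq), method = "radix")
  vocab <- structure(
    list(tokens = c("startseq", "endseq", names(freq)[ord]),
         start_id = 1L, end_id = 2L, pad_id = 0L),
    class = "cxr_vocab")
  vocab
}

#' @export
print.cxr_vocab <- function(x, ...) {
  cat("<cxr_vocab> ", length(x$tokens), " tokens (incl. startseq/endseq), pad_id = ",
      x$pad_id, "\n", sep = "")
  invisible(x)
}

#' Number of tokens in a vocabulary
#' @param vocab A `cxr_vocab`.
#' @return Integer V (words + the two sentinels).
#' @export
vocab_size <- function(vocab) length(vocab$tokens)

#' Map tokens to integer ids
#' @param tokens Character vector of tokens.
#' @param vocab A `cxr_vocab`.
#' @return Integer ids; `NA` for out-of-vocabulary tokens.
#' @export
token_ids <- function(tokens, vocab) match(tokens, vocab$tokens)

#' Encode a preprocessed report as a fixed-length id sequence
#'
#' Produces `[id(startseq), word ids..., id(endseq), 0, 0, ...]` of length
#' exactly `l_max`, right-padded with the pad id 0.
#'
#' @param report A preprocessed report string (possibly empty).
#' @param vocab A `cxr_vocab` containing every token of `report`.
#' @param l_max Total sequence length including the two sentinels.
#' @return Integer vector of length `l_max`.
#' @export
encode_report <- function(report, vocab, l_max) {
  stopifnot(is.character(report), length(report) == 1L)
  toks <- strsplit(report, "[[:space:]]+")[[1]]
  toks <- toks[nzchar(toks)]
  ids <- token_ids(toks, vocab)
  if (anyNA(ids))
    stop("out-of-vocabulary token: '", toks[which(is.na(ids))[1]], "'")
  if (length(ids) + 2L > l_max)
    stop("report has ", length(ids), " words; does not fit in l_max = ", l_max)
  c(vocab$start_id, ids, vocab$end_id,
    rep(vocab$pad_id, l_max - length(ids) - 2L))
}

#' Decode an id sequence back to a report string
#'
#' Inverse of [encode_report()]: strips the start/end sentinels and padding
#' and joins the word tokens with single spaces.
#'
#' @param ids Integer id sequence.
#' @param vocab A `cxr_vocab`.
#' @return Character scalar.
#' @export
decode_report <- function(ids, vocab) {
  ids <- ids[ids != vocab$pad_id]
  ids <- ids[!(ids %in% c(vocab$start_id, vocab$end_id))]
  paste(vocab$tokens[ids], collapse = " ")
}

#' Random train/test splits of a corpus
#'
#' Draws `repeats` independent random splits, each assigning
#' `round(fraction * n)` records to training and the rest to testing.
#' Identical seeds reproduce identical plans.
#'
#' @param n Number of records, or anything with a `length()`/`nrow()`.
#' @param fraction Train proportion in (0, 1). Default 0.8.
#' @param seed Integer RNG seed.
#' @param repeats Number of independent splits. Default 1.
#' @return A list of `repeats` plans, each a list with sorted integer index
#'   vectors `train` and `test` and the `seed`/`fraction` used.
#' @export
split_corpus <- function(n, fraction = 0.8, seed = 1L, repeats = 1L) {
  if (!is.numeric(n)) n <- if (is.data.frame(n)) nrow(n) else length(n)
  n <- as.integer(n)
  stopifnot(n >= 2L, repeats >= 1L)
  if (!(fraction > 0 && fraction < 1))
    stop("`fraction` must lie strictly between 0 and 1")
  n_train <- as.integer(round(fraction * n))
  n_train <- max(1L, min(n - 1L, n_train))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(as.integer(seed))
  lapply(seq_len(repeats), function(r) {
    perm <- sample.int(n)
    list(train = sort(perm[seq_len(n_train)]),
         test = sort(perm[-seq_len(n_train)]),
         seed = as.integer(seed), fraction = fraction)
  })
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}

.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
  invisible(NULL)
}

#' Read an image/findings manifest
#'
#' Accepts JSON-lines (one `{"image": ..., "findings": ...}` object per
#' line) or a two-column CSV with an `image,findings` header.
#'
#' @param path Manifest file path.
#' @return A data.frame with character columns `image` and `findings`.
#' @export
read_manifest <- function(path) {
  if (!file.exists(path)) stop("manifest not found: ", path)
  if (grepl("\\.csv$", path, ignore.case = TRUE)) {
    df <- utils::read.csv(path, stringsAsFactors = FALSE)
    if (!all(c("image", "findings") %in% names(df)))
      stop("CSV manifest must have 'image' and 'findings' columns")
    return(df[, c("image", "findings")])
  }
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  recs <- lapply(lines, jsonlite::fromJSON)
  data.frame(image = vapply(recs, `[[`, "", "image"),
             findings = vapply(recs, `[[`, "", "findings"),
             stringsAsFactors = FALSE)
}

#' Write a manifest as JSON-lines
#' @param df Data.frame with `image` and `findings` columns.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(df, path) {
  lines <- vapply(seq_len(nrow(df)), function(i) {
    jsonlite::toJSON(list(image = df$image[i], findings = df$findings[i]),
                     auto_unbox = TRUE)
  }, "")
  writeLines(lines, path)
  invisible(path)
}

#' Serialise a vocabulary to JSON
#' @param vocab A `cxr_vocab`.
#' @param path Output path.
#' @param l_max Optional maximum sequence length to store as metadata.
#' @return `path`, invisibly.
#' @export
write_vocab <- function(vocab, path, l_max = NULL) {
  ids <- as.list(seq_along(vocab$tokens))
  names(ids) <- vocab$tokens
  obj <- list(tokens = ids,
              meta = list(pad_id = vocab$pad_id, start_id = vocab$start_id,
                          end_id = vocab$end_id, l_max = l_max))
  writeLines(jsonlite::toJSON(obj, auto_unbox = TRUE, null = "null"), path)
  invisible(path)
}

#' Read a vocabulary written by [write_vocab()]
#' @param path JSON path.
#' @return A `cxr_vocab`.
#' @export
read_vocab <- function(path) {
  obj <- jsonlite::fromJSON(path)
  ids <- unlist(obj$tokens)
  tokens <- names(sort(ids))
  structure(list(tokens = tokens,
                 start_id = as.integer(obj$meta$start_id),
                 end_id = as.integer(obj$meta$end_id),
                 pad_id = as.integer(obj$meta$pad_id)),
            class = "cxr_vocab")
}

#' Prepare a corpus: preprocess, tokenize, encode and index reports
#'
#' Runs [preprocess_report()] on every manifest row (a long findings text
#' may yield several chunks, i.e. several training records per image),
#' builds the vocabulary over all chunks, and encodes every chunk to a
#' fixed-length id sequence.
#'
#' @param manifest Data.frame from [read_manifest()], or a path to one.
#' @param l_max Total encoded length including sentinels. Default 24
#'   (22 words plus startseq/endseq).
#' @param max_words Maximum words per chunk. Default 22.
#' @param base_dir Directory image paths are relative to. Default the
#'   manifest's directory, or "." for a data.frame input.
#' @return An object of class `cxr_corpus`: list with `records` (data.frame
#'   of `image`, `text`), `ids` (matrix, one row per record), `vocab`,
#'   `l_max`.
#' @export
prepare_corpus <- function(manifest, l_max = 24L, max_words = 22L, base_dir = NULL) {
  if (is.character(manifest)) {
    if (is.null(base_dir)) base_dir <- dirname(manifest)
    manifest <- read_manifest(manifest)
  }
  if (is.null(base_dir)) base_dir <- "."
  stopifnot(nrow(manifest) >= 1L)
  chunks <- lapply(seq_len(nrow(manifest)), function(i)
    preprocess_report(manifest$findings[i], max_words = max_words))
  records <- data.frame(
    image = rep(file.path(base_dir, manifest$image),
                vapply(chunks, length, 1L)),
    text = unlist(chunks),
    stringsAsFactors = FALSE)
  vocab <- build_vocabulary(records$text)
  ids <- t(vapply(records$text, encode_report, integer(l_max),
                  vocab = vocab, l_max = l_max))
  dimnames(ids) <- NULL
  structure(list(records = records, ids = ids, vocab = vocab,
                 l_max = as.integer(l_max)),
            class = "cxr_corpus")
}

#' @export
print.cxr_corpus <- function(x, ...) {
  cat("<cxr_corpus> ", nrow(x$records), " records, vocabulary of ",
      vocab_size(x$vocab), " tokens, l_max = ", x$l_max, "\n", sep = "")
  invisible(x)
}
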