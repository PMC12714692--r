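# Text preprocessing: normalization, tokenization, stemming, and the
# document-term matrix.

## ---- Porter stemmer ---------------------------------------------------
# Suffix-stripping stemmer implemented from the classic algorithm
# definition: five ordered rule steps driven by the stem "measure" m (the
# number of vowel-consonant sequences). Words of length <= 2 are returned
# unchanged. Operates on lower-case ASCII words.

.p_is_cons <- function(ch, i) {
  c0 <- ch[i]
  if (c0 %in% c("a", "e", "i", "o", "u")) return(FALSE)
  if (c0 == "y") {
    if (i == 1L) return(TRUE)
    return(!.p_is_cons(ch, i - 1L))
  }
  TRUE
}

# measure of ch[1..j]: number of VC sequences
.p_measure <- function(ch, j) {
  n <- 0L
  i <- 1L
  while (i <= j && .p_is_cons(ch, i)) i <- i + 1L
  repeat {
    if (i > j) return(n)
    while (i <= j && !.p_is_cons(ch, i)) i <- i + 1L
    if (i > j) return(n)
    n <- n + 1L
    while (i <= j && .p_is_cons(ch, i)) i <- i + 1L
  }
}

.p_vowel_in <- function(ch, j) {
  for (i in seq_len(j)) if (!.p_is_cons(ch, i)) return(TRUE)
  FALSE
}

.p_doublec <- function(ch, j) {
  j >= 2L && ch[j] == ch[j - 1L] && .p_is_cons(ch, j)
}

# consonant-vowel-consonant ending at j, final consonant not w, x, or y
.p_cvc <- function(ch, j) {
  if (j < 3L) return(FALSE)
  .p_is_cons(ch, j) && !.p_is_cons(ch, j - 1L) && .p_is_cons(ch, j - 2L) &&
    !(ch[j] %in% c("w", "x", "y"))
}

.p_ends <- function(w, suf) {
  nw <- nchar(w)
  ns <- nchar(suf)
  nw >= ns && substring(w, nw - ns + 1L, nw) == suf
}

.p_chars <- function(w) strsplit(w, "", fixed = TRUE)[[1]]

.p_m_of <- function(w) {
  ch <- .p_chars(w)
  .p_measure(ch, length(ch))
}

# suffix tables for steps 2-4, longest suffix first; first match wins and
# its m-condition decides whether anything is replaced.
.p_step2_rules <- list(
  c("ational", "ate"), c("ization", "ize"), c("iveness", "ive"),
  c("fulness", "ful"), c("ousness", "ous"), c("tional", "tion"),
  c("biliti", "ble"), c("entli", "ent"), c("ousli", "ous"),
  c("ation", "ate"), c("alism", "al"), c("aliti", "al"),
  c("iviti", "ive"), c("enci", "ence"), c("anci", "ance"),
  c("izer", "ize"), c("abli", "able"), c("alli", "al"),
  c("ator", "ate"), c("eli", "e")
)

.p_step3_rules <- list(
  c("icate", "ic"), c("ative", ""), c("alize", "al"), c("iciti", "ic"),
  c("ical", "ic"), c("ful", ""), c("ness", "")
)

.p_step4_sufs <- c("ement", "ance", "ence", "able", "ible", "ment", "ion",
                   "ant", "ent", "ism", "ate", "iti", "ous", "ive", "ize",
                   "al", "er", "ic", "ou")

.porter_one <- function(w) {
  if (nchar(w) <= 2L) return(w)

  # step 1a
  if (.p_ends(w, "sses")) {
    w <- substring(w, 1L, nchar(w) - 2L)
  } else if (.p_ends(w, "ies")) {
    w <- paste0(substring(w, 1L, nchar(w) - 3L), "i")
  } else if (!.p_ends(w, "ss") && .p_ends(w, "s")) {
    w <- substring(w, 1L, nchar(w) - 1L)
  }

  # step 1b
  flag1b <- FALSE
  if (.p_ends(w, "eed")) {
    stem <- substring(w, 1L, nchar(w) - 3L)
    if (.p_m_of(stem) > 0L) w <- substring(w, 1L, nchar(w) - 1L)
  } else if (.p_ends(w, "ed")) {
    stem <- substring(w, 1L, nchar(w) - 2L)
    if (.p_vowel_in(.p_chars(stem), nchar(stem))) {
      w <- stem
      flag1b <- TRUE
    }
  } else if (.p_ends(w, "ing")) {
    stem <- substring(w, 1L, nchar(w) - 3L)
    if (.p_vowel_in(.p_chars(stem), nchar(stem))) {
      w <- stem
      flag1b <- TRUE
    }
  }
  if (flag1b) {
    if (.p_ends(w, "at") || .p_ends(w, "bl") || .p_ends(w, "iz")) {
      w <- paste0(w, "e")
    } else {
      ch <- .p_chars(w)
      j <- length(ch)
      if (.p_doublec(ch, j) && !(ch[j] %in% c("l", "s", "z"))) {
        w <- substring(w, 1L, j - 1L)
      } else if (.p_measure(ch, j) == 1L && .p_cvc(ch, j)) {
        w <- paste0(w, "e")
      }
    }
  }

  # step 1c
  if (.p_ends(w, "y")) {
    stem <- substring(w, 1L, nchar(w) - 1L)
    if (nchar(stem) > 0L && .p_vowel_in(.p_chars(stem), nchar(stem))) {
      w <- paste0(stem, "i")
    }
  }

  # step 2
  for (rule in .p_step2_rules) {
    if (.p_ends(w, rule[[1]])) {
      stem <- substring(w, 1L, nchar(w) - nchar(rule[[1]]))
      if (.p_m_of(stem) > 0L) w <- paste0(stem, rule[[2]])
      break
    }
  }

  # step 3
  for (rule in .p_step3_rules) {
    if (.p_ends(w, rule[[1]])) {
      stem <- substring(w, 1L, nchar(w) - nchar(rule[[1]]))
      if (.p_m_of(stem) > 0L) w <- paste0(stem, rule[[2]])
      break
    }
  }

  # step 4
  for (suf in .p_step4_sufs) {
    if (.p_ends(w, suf)) {
      stem <- substring(w, 1L, nchar(w) - nchar(suf))
      if (suf == "ion") {
        last <- substring(stem, nchar(stem), nchar(stem))
        if (!(last %in% c("s", "t"))) break
      }
      if (.p_m_of(stem) > 1L) w <- stem
      break
    }
  }

  # step 5a
  if (.p_ends(w, "e")) {
    stem <- substring(w, 1L, nchar(w) - 1L)
    m <- .p_m_of(stem)
    ch <- .p_chars(stem)
    if (m > 1L || (m == 1L && !.p_cvc(ch, length(ch)))) w <- stem
  }

  # step 5b
  ch <- .p_chars(w)
  j <- length(ch)
  if (j >= 2L && .p_measure(ch, j) > 1L && .p_doublec(ch, j) && ch[j] == "l") {
    w <- substring(w, 1L, j - 1L)
  }

  w
}

#' Porter-stem a vector of words
#'
#' Applies the classic five-step suffix-stripping algorithm to each
#' lower-case word. Words of length two or less are returned unchanged.
#'
#' @param words Character vector of lower-case words.
#' @return Character vector of stems, same length as `words`.
#' @export
porter_stem <- function(words) {
  vapply(words, .porter_one, character(1), USE.NAMES = FALSE)
}

## ---- preprocessing pipeline -------------------------------------------

#' Preprocess raw document text into tokens
#'
#' Applies, in order: Unicode compatibility normalization (NFKC); removal of
#' characters outside the Latin ASCII repertoire; lowercasing; replacement
#' of punctuation and digits by spaces; whitespace collapse; whitespace
#' tokenization; stopword removal; Porter stemming; and removal of tokens
#' shorter than two characters.
#'
#' @param raw A single character string (may be empty).
#' @param stopwords Character vector of lower-case stopwords (removed before
#'   stemming).
#' @return Character vector of tokens (possibly empty), each matching
#'   `^[a-z]{2,}$`.
#' @export
preprocess_text <- function(raw, stopwords = character(0)) {
  stopifnot(length(raw) == 1L)
  if (is.na(raw) || !nzchar(raw)) return(character(0))
  x <- stringi::stri_trans_nfkc(raw)
  # drop non-ASCII residues (Greek letters etc.), then non-letters -> space
  x <- gsub("[^\x20-\x7E]", " ", x, perl = TRUE)
  x <- tolower(x)
  x <- gsub("[^a-z]", " ", x)
  x <- trimws(gsub("[ ]+", " ", x))
  if (!nzchar(x)) return(character(0))
  tokens <- strsplit(x, " ", fixed = TRUE)[[1]]
  tokens <- tokens[!(tokens %in% stopwords)]
  if (length(tokens) == 0L) return(character(0))
  tokens <- porter_stem(tokens)
  tokens[nchar(tokens) >= 2L]
}

#' Merge document records to one document per gene set
#'
#' Concatenates the texts belonging to one `set_id` into a single document
#' (joined by a single space, in input order). Abstracts take precedence:
#' when a set has both abstracts and descriptions, only the abstracts are
#' kept; descriptions are used only for sets with no abstract.
#'
#' @param records Data frame with columns `doc_id`, `set_id`, `source`
#'   (`"abstract"` or `"description"`), `text`.
#' @return Data frame with one row per `set_id` (in first-appearance order)
#'   and columns `doc_id` (= set id), `set_id`, `source`, `text`.
#' @export
merge_documents <- function(records) {
  stopifnot(all(c("doc_id", "set_id", "source", "text") %in% names(records)))
  set_ids <- unique(records$set_id)
  out <- lapply(set_ids, function(sid) {
    rec <- records[records$set_id == sid, , drop = FALSE]
    has_abs <- any(rec$source == "abstract")
    if (has_abs) rec <- rec[rec$source == "abstract", , drop = FALSE]
    data.frame(
      doc_id = sid,
      set_id = sid,
      source = if (has_abs) "abstract" else "description",
      text = paste(rec$text, collapse = " "),
      stringsAsFactors = FALSE
    )
  })
  do.call(rbind, out)
}

#' Build a document-term count matrix
#'
#' @param docs Named list of token vectors (names are document ids), e.g.
#'   from [preprocess_text()] applied per document.
#' @return A sparse `dgCMatrix` (documents x tokens) of counts, with row
#'   names the document ids and column names the vocabulary sorted in C
#'   (byte) lexicographic order.
#' @export
build_dtm <- function(docs) {
  stopifnot(is.list(docs), length(docs) >= 1L, !is.null(names(docs)))
  vocab <- sort(unique(unlist(docs, use.names = FALSE)), method = "radix")
  doc_ids <- names(docs)
  ii <- integer(0)
  jj <- integer(0)
  xx <- integer(0)
  for (d in seq_along(docs)) {
    toks <- docs[[d]]
    if (length(toks) == 0L) next
    tab <- table(factor(toks, levels = vocab))
    nz <- which(tab > 0L)
    ii <- c(ii, rep.int(d, length(nz)))
    jj <- c(jj, nz)
    xx <- c(xx, as.integer(tab[nz]))
  }
  Matrix::sparseMatrix(
    i = ii, j = jj, x = xx,
    dims = c(length(docs), length(vocab)),
    dimnames = list(doc_ids, vocab)
  )
}

#' Iteratively prune rare tokens and emptied documents
#'
#' Drops token columns whose corpus-wide frequency (sum over documents) is
#' below `min_freq`, then drops document rows left with no tokens, and
#' repeats until both invariants hold simultaneously (a fixpoint).
#'
#' @param dtm Sparse document-term matrix from [build_dtm()].
#' @param min_freq Minimum corpus frequency for a token to be retained
#'   (default 5; tokens with frequency < `min_freq` are removed).
#' @return The pruned document-term matrix.
#' @export
prune_rare_tokens <- function(dtm, min_freq = 5L) {
  stopifnot(min_freq >= 1L)
  repeat {
    cs <- Matrix::colSums(dtm)
    keep_tok <- cs >= min_freq
    dtm <- dtm[, keep_tok, drop = FALSE]
    rs <- Matrix::rowSums(dtm)
    keep_doc <- rs > 0
    dtm <- dtm[keep_doc, , drop = FALSE]
    if (nrow(dtm) == 0L) stop("corpus emptied by pruning")
    if (all(keep_tok) && all(keep_doc)) return(dtm)
  }
}

#' Export a document-term matrix as MatrixMarket triplets
#'
#' Writes `<prefix>.mtx` (sparse triplet counts) plus sidecar
#' `<prefix>.vocab.txt` (one token per line) and `<prefix>.docs.txt` (one
#' document id per line).
#'
#' @param dtm Sparse document-term matrix.
#' @param prefix Output path prefix.
#' @return Character vector of the three file paths, invisibly.
#' @export
write_dtm <- function(dtm, prefix) {
  mtx <- paste0(prefix, ".mtx")
  Matrix::writeMM(methods::as(dtm, "CsparseMatrix"), mtx)
  vocab <- paste0(prefix, ".vocab.txt")
  writeLines(colnames(dtm), vocab)
  docs <- paste0(prefix, ".docs.txt")
  writeLines(rownames(dtm), docs)
  invisible(c(mtx, vocab, docs))
}
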