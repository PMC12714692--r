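#' Read a gene-set collection from a GMT file
#'
#' Parses the tab-separated GMT dialect used by MSigDB-style collections:
#' one gene set per line, fields `set_id`, `description`, then one gene
#' symbol per remaining field. Gene symbols are treated as case-sensitive
#' opaque strings; duplicates within a line are collapsed keeping the first
#' occurrence.
#'
#' @param path Path to a GMT file.
#' @return A named list of character vectors (one per set, names are set
#'   ids), with a `"description"` attribute holding the per-set description
#'   strings (named by set id).
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) stop("GMT file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  sets <- vector("list", length(lines))
  ids <- character(length(lines))
  descs <- character(length(lines))
  for (i in seq_along(lines)) {
    fields <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1]]
    if (length(fields) < 3L) {
      stop("malformed GMT line ", i, ": expected >= 3 tab-separated fields, got ",
           length(fields))
    }
    genes <- fields[-(1:2)]
    genes <- genes[nzchar(genes)]
    if (length(genes) == 0L) {
      stop("malformed GMT line ", i, ": no gene symbols")
    }
    ids[[i]] <- fields[[1]]
    descs[[i]] <- fields[[2]]
    sets[[i]] <- genes[!duplicated(genes)]
  }
  dup <- ids[duplicated(ids)]
  if (length(dup) > 0L) {
    stop("duplicate set ids in GMT file: ", paste(unique(dup), collapse = ", "))
  }
  names(sets) <- ids
  names(descs) <- ids
  attr(sets, "description") <- descs
  sets
}

#' Write a gene-set collection to a GMT file
#'
#' Inverse of [read_gmt()]: one line per set, `set_id`, description, genes.
#'
#' @param sets Named list of character gene vectors; an optional
#'   `"description"` attribute (named character) supplies the second field
#'   (defaults to the set id).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(sets, path) {
  stopifnot(is.list(sets), !is.null(names(sets)))
  descs <- attr(sets, "description")
  lines <- vapply(names(sets), function(id) {
    desc <- if (!is.null(descs) && id %in% names(descs)) descs[[id]] else id
    paste(c(id, desc, sets[[id]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read a stopword list
#'
#' One token per line; `#` starts a comment (full-line or trailing); blank
#' lines are ignored. Tokens are lowercased.
#'
#' @param path Path to the stopword file.
#' @return Character vector of lower-case stopwords.
#' @export
read_stopwords <- function(path) {
  if (!file.exists(path)) stop("stopword file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  unique(tolower(lines[nzchar(lines)]))
}

#' Read a document table
#'
#' Reads the per-gene-set document records either from a TSV file with
#' columns `doc_id`, `set_id`, `source`, `text`, or from line-delimited JSON
#' (one object with those keys per line, detected by a `.json`/`.jsonl`
#' extension or a leading `{`).
#'
#' @param path Path to the document table.
#' @return A data frame with columns `doc_id`, `set_id`, `source`, `text`.
#' @export
read_documents <- function(path) {
  if (!file.exists(path)) stop("document file not found: ", path)
  first <- readLines(path, n = 1L, warn = FALSE)
  is_json <- grepl("\\.jsonl?$", path, ignore.case = TRUE) ||
    grepl("^\\s*\\{", first)
  if (is_json) {
    lines <- readLines(path, warn = FALSE)
    lines <- lines[nzchar(trimws(lines))]
    recs <- lapply(lines, jsonlite::fromJSON)
    docs <- data.frame(
      doc_id = vapply(recs, function(r) as.character(r$doc_id), character(1)),
      set_id = vapply(recs, function(r) as.character(r$set_id), character(1)),
      source = vapply(recs, function(r) as.character(r$source), character(1)),
      text = vapply(recs, function(r) {
        if (is.null(r$text)) "" else as.character(r$text)
      }, character(1)),
      stringsAsFactors = FALSE
    )
  } else {
    docs <- utils::read.delim(path, header = TRUE, sep = "\t", quote = "",
                              comment.char = "", stringsAsFactors = FALSE,
                              colClasses = "character")
  }
  required <- c("doc_id", "set_id", "source", "text")
  missing <- setdiff(required, names(docs))
  if (length(missing) > 0L) {
    stop("document table lacks required column(s): ",
         paste(missing, collapse = ", "))
  }
  bad <- setdiff(unique(docs$source), c("abstract", "description"))
  if (length(bad) > 0L) {
    stop("unknown document source value(s): ", paste(bad, collapse = ", "))
  }
  docs[, required]
}

#' Write a document table as TSV
#'
#' @param docs Data frame with columns `doc_id`, `set_id`, `source`, `text`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_documents <- function(docs, path) {
  utils::write.table(docs[, c("doc_id", "set_id", "source", "text")], path,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
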