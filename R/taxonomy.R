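# Hierarchical category codes and taxonomies.
#
# Codes are dotted strings of 1-4 positive integers ("16.3.1.1"). Some source
# tables print a trailing dot ("16.3.1.1."); the canonical internal form strips
# it, and writers can restore it on request.

#' Normalize a category code
#'
#' Strips surrounding whitespace and a single trailing dot, then validates the
#' canonical form: 1 to 4 dot-separated positive integers.
#'
#' @param code Character vector of raw codes.
#' @param context Optional label (e.g. a file name) used in error messages.
#' @return Character vector of canonical codes.
#' @examples
#' normalize_code("16.3.1.1.")  # "16.3.1.1"
#' @export
normalize_code <- function(code, context = NULL) {
  code <- sub("\\.$", "", trimws(as.character(code)))
  bad <- !grepl("^[0-9]+(\\.[0-9]+){0,3}$", code)
  if (any(bad)) {
    where <- if (is.null(context)) "" else paste0(" in ", context)
    stop("malformed category code", where, ": ",
         paste(utils::head(code[bad], 5), collapse = ", "),
         call. = FALSE)
  }
  code
}

#' Level of a category code
#'
#' The level is the number of dot-separated segments (1 = first-level,
#' 4 = fourth-level).
#'
#' @param code Character vector of canonical codes.
#' @return Integer vector of levels in 1..4.
#' @export
code_level <- function(code) {
  lengths(strsplit(code, ".", fixed = TRUE))
}

#' Prefix of a category code
#'
#' @param code Character vector of canonical codes.
#' @param n_segments Number of leading segments to keep (default 1, the
#'   first-level category).
#' @return Character vector of truncated codes.
#' @export
code_prefix <- function(code, n_segments = 1L) {
  vapply(strsplit(code, ".", fixed = TRUE), function(s) {
    paste(utils::head(s, n_segments), collapse = ".")
  }, character(1))
}

# Deterministic ordering of codes by numeric segment (1.2 < 1.10 < 2).
code_order <- function(code) {
  segs <- strsplit(code, ".", fixed = TRUE)
  mat <- t(vapply(segs, function(s) {
    out <- rep(-1L, 4L)
    out[seq_along(s)] <- as.integer(s)
    out
  }, integer(4)))
  order(mat[, 1], mat[, 2], mat[, 3], mat[, 4])
}

#' Construct a taxonomy
#'
#' A taxonomy maps category codes to human-readable names. Codes must be
#' unique, and every fourth-level code must have its first-level prefix
#' declared as a category of its own.
#'
#' @param codes Character vector of codes (trailing-dot dialect accepted).
#' @param names Character vector of category names, same length.
#' @return A `cpc_taxonomy` object: a data frame with columns `code`, `name`,
#'   `level`, ordered by code.
#' @examples
#' tax <- taxonomy(c("1", "1.1.1.1"), c("outpatient", "hospital choice"))
#' taxonomy_levels(tax)
#' @export
taxonomy <- function(codes, names) {
  stopifnot(length(codes) == length(names))
  codes <- normalize_code(codes)
  if (anyDuplicated(codes)) {
    stop("duplicate category codes: ",
         paste(unique(codes[duplicated(codes)]), collapse = ", "),
         call. = FALSE)
  }
  level <- code_level(codes)
  lvl1 <- codes[level == 1L]
  need <- unique(code_prefix(codes[level == 4L], 1L))
  missing1 <- setdiff(need, lvl1)
  if (length(missing1)) {
    stop("fourth-level codes without a declared first-level category: ",
         paste(missing1, collapse = ", "), call. = FALSE)
  }
  out <- data.frame(code = codes, name = as.character(names), level = level,
                    stringsAsFactors = FALSE)
  out <- out[code_order(out$code), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("cpc_taxonomy", "data.frame")
  out
}

#' Look up category names by code
#'
#' Lookup is total over declared codes; an undeclared code is an error.
#'
#' @param tax A `cpc_taxonomy`.
#' @param codes Character vector of canonical codes.
#' @return Character vector of names.
#' @export
taxonomy_name <- function(tax, codes) {
  idx <- match(codes, tax$code)
  if (anyNA(idx)) {
    stop("unknown category code: ",
         paste(unique(codes[is.na(idx)]), collapse = ", "), call. = FALSE)
  }
  tax$name[idx]
}

#' Count categories per level
#'
#' @param tax A `cpc_taxonomy`.
#' @return Named integer vector, counts for levels "1".."4" (zero-filled).
#' @export
taxonomy_levels <- function(tax) {
  out <- integer(4)
  names(out) <- as.character(1:4)
  tab <- table(factor(tax$level, levels = 1:4))
  out[names(tab)] <- as.integer(tab)
  out
}

#' @export
print.cpc_taxonomy <- function(x, ...) {
  lv <- taxonomy_levels(x)
  cat("<cpc_taxonomy> ", nrow(x), " categories (",
      paste(sprintf("level %s: %d", names(lv)[lv > 0], lv[lv > 0]),
            collapse = ", "), ")\n", sep = "")
  print.data.frame(utils::head(as.data.frame(x), 10))
  if (nrow(x) > 10) cat("... ", nrow(x) - 10, " more rows\n", sep = "")
  invisible(x)
}

#' Read a taxonomy file
#'
#' TSV rows are `code<TAB>name` (UTF-8, no header unless `header = TRUE`);
#' JSONL rows are objects with keys `code` and `name`. Trailing-dot codes are
#' normalized on read.
#'
#' @param path File path.
#' @param format `"tsv"` or `"jsonl"`.
#' @param header For TSV, whether the first row is a header.
#' @return A `cpc_taxonomy`.
#' @export
read_taxonomy <- function(path, format = c("tsv", "jsonl"), header = FALSE) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  if (format == "tsv") {
    if (file.size(path) == 0) return(taxonomy(character(), character()))
    df <- utils::read.delim(path, header = header, sep = "\t", quote = "",
                            colClasses = "character", fileEncoding = "UTF-8")
    if (ncol(df) < 2) stop("taxonomy TSV needs (code, name) columns: ", path,
                           call. = FALSE)
    codes <- df[[1]]
    nms <- df[[2]]
  } else {
    lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
    lines <- lines[nzchar(lines)]
    if (!length(lines)) return(taxonomy(character(), character()))
    recs <- lapply(lines, jsonlite::fromJSON)
    codes <- vapply(recs, function(r) as.character(r$code), character(1))
    nms <- vapply(recs, function(r) as.character(r$name), character(1))
  }
  codes <- normalize_code(codes, context = path)
  taxonomy(codes, nms)
}

#' Write a taxonomy file
#'
#' @param tax A `cpc_taxonomy`.
#' @param path Output path.
#' @param format `"tsv"` or `"jsonl"`.
#' @param trailing_dot Emit codes in the trailing-dot dialect ("16.3.1.1.").
#' @param header For TSV, write a `code<TAB>name` header row.
#' @return `path`, invisibly.
#' @export
write_taxonomy <- function(tax, path, format = c("tsv", "jsonl"),
                           trailing_dot = FALSE, header = FALSE) {
  format <- match.arg(format)
  codes <- if (trailing_dot) paste0(tax$code, ".") else tax$code
  if (format == "tsv") {
    lines <- paste(codes, tax$name, sep = "\t")
    if (header) lines <- c("code\tname", lines)
    writeLines(lines, path, useBytes = TRUE)
  } else {
    lines <- vapply(seq_len(nrow(tax)), function(i) {
      jsonlite::toJSON(list(code = codes[i], name = tax$name[i]),
                       auto_unbox = TRUE)
    }, character(1))
    writeLines(lines, path, useBytes = TRUE)
  }
  invisible(path)
}
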