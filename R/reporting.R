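# Frequency tables, long-tail diagnostics, and extraction filters.
#
# Shares are computed against the number of classified queries (queries whose
# ranking is empty stay in the denominator by default, mirroring surveys that
# report shares of the full target set). Printed percentages round half-up to
# one decimal.

#' Round half-up (decimal)
#'
#' Commercial rounding used for printed percentages: `round_half_up(23.75, 1)`
#' is 23.8 where `round()` would banker-round.
#'
#' @param x Numeric vector.
#' @param digits Decimal digits.
#' @return Rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 1) {
  f <- 10^digits
  floor(x * f + 0.5 + 1e-9) / f
}

new_freq_table <- function(df, total_classified) {
  attr(df, "total_classified") <- total_classified
  class(df) <- c("cpc_freq_table", "data.frame")
  df
}

#' Category frequency table of top-1 assignments
#'
#' Counts, per category, the queries whose top-1 prediction is that
#' category; ranks descending by count (ties by ascending code). Queries
#' with empty rankings contribute no counts but are (by default) kept in the
#' share denominator.
#'
#' @param predictions A `cpc_predictions`.
#' @param taxonomy A `cpc_taxonomy` for the name column.
#' @param top_n Keep only the first `top_n` rows (default: all).
#' @param count_empty_in_total Keep zero-ranking queries in
#'   `total_classified` (default `TRUE`).
#' @return A `cpc_freq_table`: data frame `(rank, code, name, count, share)`
#'   with attribute `total_classified`.
#' @export
frequency_table <- function(predictions, taxonomy, top_n = Inf,
                            count_empty_in_total = TRUE) {
  top1 <- top1_assignments(predictions)
  assigned <- top1[!is.na(top1)]
  total <- if (count_empty_in_total) length(top1) else length(assigned)
  if (!length(assigned)) {
    return(new_freq_table(data.frame(rank = integer(), code = character(),
                                     name = character(), count = integer(),
                                     share = numeric(),
                                     stringsAsFactors = FALSE), total))
  }
  tab <- table(assigned)
  codes <- names(tab)
  counts <- as.integer(tab)
  ord <- order(-counts, code_order_key(codes))
  codes <- codes[ord]
  counts <- counts[ord]
  keep <- seq_len(min(length(codes), top_n))
  df <- data.frame(rank = keep, code = codes[keep],
                   name = taxonomy_name(taxonomy, codes[keep]),
                   count = counts[keep], share = counts[keep] / total,
                   stringsAsFactors = FALSE)
  new_freq_table(df, total)
}

#' Build a frequency table from printed counts
#'
#' For re-deriving shares and long-tail diagnostics from an already
#' published table of per-category counts.
#'
#' @param code,name,count Parallel vectors; `count` must be non-increasing.
#' @param total_classified Denominator for shares (>= sum of counts).
#' @return A `cpc_freq_table`.
#' @export
frequency_table_from_counts <- function(code, name, count, total_classified) {
  count <- as.integer(count)
  if (is.unsorted(rev(count))) {
    stop("counts must be non-increasing by rank", call. = FALSE)
  }
  if (sum(count) > total_classified) {
    stop("counts exceed total_classified", call. = FALSE)
  }
  df <- data.frame(rank = seq_along(code), code = normalize_code(code),
                   name = as.character(name), count = count,
                   share = count / total_classified, stringsAsFactors = FALSE)
  new_freq_table(df, total_classified)
}

#' @export
print.cpc_freq_table <- function(x, ...) {
  cat("<cpc_freq_table> ", nrow(x), " categories, total classified = ",
      attr(x, "total_classified"), "\n", sep = "")
  show <- as.data.frame(x)
  show$share_pct <- sprintf("%.1f", round_half_up(100 * show$share, 1))
  show$share <- NULL
  print.data.frame(utils::head(show, 15), row.names = FALSE)
  if (nrow(x) > 15) cat("... ", nrow(x) - 15, " more rows\n", sep = "")
  invisible(x)
}

#' Write a frequency table as TSV
#'
#' Columns `rank, code, name, count, share_pct` (share in percent, one
#' decimal, half-up).
#'
#' @param table A `cpc_freq_table`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_frequency_table <- function(table, path) {
  lines <- paste(table$rank, table$code, table$name, table$count,
                 sprintf("%.1f", round_half_up(100 * table$share, 1)),
                 sep = "\t")
  writeLines(c("rank\tcode\tname\tcount\tshare_pct", lines), path,
             useBytes = TRUE)
  invisible(path)
}

#' Rank-to-rank relative change of a frequency table
#'
#' Element i is `(count_i - count_{i+1}) / count_i`: the relative drop from
#' rank i to rank i+1. Large early drops followed by small ones diagnose a
#' long-tailed distribution.
#'
#' @param table A `cpc_freq_table` with at least 2 rows.
#' @return Numeric vector of length `nrow(table) - 1`, values in \[0, 1).
#' @export
rank_change_curve <- function(table) {
  if (nrow(table) < 2) stop("need at least 2 ranked rows", call. = FALSE)
  cnt <- table$count
  (cnt[-length(cnt)] - cnt[-1]) / cnt[-length(cnt)]
}

#' Cumulative share of the top-n categories
#'
#' @param table A `cpc_freq_table`.
#' @param n Number of top rows to accumulate; capped at the row count.
#' @return Sum of the top-n counts divided by `total_classified`.
#' @export
cumulative_share <- function(table, n) {
  if (n < 1) stop("n must be >= 1", call. = FALSE)
  n <- min(n, nrow(table))
  sum(table$count[seq_len(n)]) / attr(table, "total_classified")
}

#' Overlap of the top-n categories of two frequency tables
#'
#' @param a,b `cpc_freq_table` objects.
#' @param n Depth of the comparison.
#' @return Integer: size of the intersection of the two top-n code sets.
#' @export
top_overlap <- function(a, b, n) {
  if (n < 1) stop("n must be >= 1", call. = FALSE)
  length(intersect(utils::head(a$code, n), utils::head(b$code, n)))
}

#' Filter queries by the category prefix of their top-1 assignment
#'
#' Selects queries whose top-1 code equals `prefix` or starts with
#' `prefix` + "." (segment boundary: prefix "11" matches "11.1.2.3", not
#' "1.1.2.3"). Used e.g. to pull the "symptoms, side effects, and sequelae"
#' branch for adverse-event signal review.
#'
#' @param predictions A `cpc_predictions`.
#' @param queries The classified `cpc_corpus` (same query ids).
#' @param prefix A valid level 1-3 code prefix.
#' @return List with `corpus` (the matching subset, original order),
#'   `count`, and `share` (relative to total classified queries).
#' @export
filter_by_category_prefix <- function(predictions, queries, prefix) {
  prefix <- normalize_code(prefix)
  if (code_level(prefix) > 3) {
    stop("prefix must be a level 1-3 code", call. = FALSE)
  }
  top1 <- top1_assignments(predictions)
  hit <- !is.na(top1) &
    (top1 == prefix | startsWith(top1, paste0(prefix, ".")))
  ids <- names(top1)[hit]
  sel <- queries$doc_id %in% ids
  list(corpus = corpus_subset(queries, sel),
       count = sum(hit),
       share = sum(hit) / length(top1))
}

#' Keyword search over raw query texts
#'
#' Plain substring match on the raw (pre-tokenization) text, preserving
#' corpus order; case-insensitive by default. Used to surface emergent
#' topics ("COVID") that the taxonomy does not yet cover.
#'
#' @param queries A `cpc_corpus`.
#' @param term Nonempty search string.
#' @param case_sensitive Match case exactly (default `FALSE`).
#' @return A `cpc_corpus` restricted to the matching documents.
#' @export
keyword_search <- function(queries, term, case_sensitive = FALSE) {
  if (!nzchar(term)) stop("search term must be nonempty", call. = FALSE)
  hay <- if (case_sensitive) queries$text else tolower(queries$text)
  needle <- if (case_sensitive) term else tolower(term)
  corpus_subset(queries, grepl(needle, hay, fixed = TRUE))
}

#' Bar chart of the top-n category frequencies
#'
#' Base-graphics rank-abundance plot of a frequency table (the long-tail
#' picture). Optionally overlays a second table for side-by-side
#' distribution comparison.
#'
#' @param table A `cpc_freq_table`.
#' @param n Number of top categories to draw.
#' @param compare Optional second `cpc_freq_table` aligned by the first
#'   table's codes.
#' @param ... Passed to [graphics::barplot()].
#' @return Invisibly, the matrix of plotted shares.
#' @export
plot_frequency_table <- function(table, n = 30, compare = NULL, ...) {
  n <- min(n, nrow(table))
  codes <- table$code[seq_len(n)]
  h <- table$share[seq_len(n)]
  if (is.null(compare)) {
    m <- matrix(h, nrow = 1, dimnames = list("share", codes))
  } else {
    h2 <- compare$share[match(codes, compare$code)]
    h2[is.na(h2)] <- 0
    m <- rbind(a = h, b = h2)
    colnames(m) <- codes
  }
  graphics::barplot(m, beside = !is.null(compare), las = 2,
                    cex.names = 0.6, ylab = "share", ...)
  invisible(m)
}
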