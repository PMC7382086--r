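#' Construct a competing-risks sample
#'
#' Bundles subject-level records \code{(time, status, group)} for a
#' competing-risks study with one event of interest and one competing event.
#' Status codes follow the usual convention: 0 = censored, 1 = event of
#' interest, 2 = competing event.  Codes above 2 are accepted (additional
#' competing causes) but the two-sample tests address the two-cause setting.
#'
#' @param time numeric vector of non-negative observed times
#'   (\code{min(T, C)} per subject).
#' @param status integer vector of cause codes (0 censored, 1 event of
#'   interest, 2 competing event).
#' @param group optional vector of group labels; when supplied it must have
#'   exactly two distinct levels for the two-sample procedures.  A factor is
#'   created with levels in sort order unless \code{ref} names the reference
#'   (first) level.
#' @param ref optional reference group label; the test effect size is
#'   (non-reference minus reference).
#'
#' @return A data frame of class \code{"cr_sample"} with columns
#'   \code{time}, \code{status} and, when given, \code{group}.
#' @examples
#' cr_sample(c(1, 2, 3, 4), c(1, 2, 1, 0))
#' @export
cr_sample <- function(time, status, group = NULL, ref = NULL) {
  time <- as.numeric(time)
  status <- as.integer(status)
  if (length(time) == 0L) stop("empty sample: at least one record required")
  if (length(status) != length(time))
    stop("'time' and 'status' lengths differ")
  bad <- which(!is.finite(time) | time < 0)
  if (length(bad))
    stop("non-finite or negative 'time' at row(s): ",
         paste(utils::head(bad, 5L), collapse = ", "))
  bad <- which(is.na(status) | status < 0L)
  if (length(bad))
    stop("invalid 'status' code at row(s): ",
         paste(utils::head(bad, 5L), collapse = ", "))
  out <- data.frame(time = time, status = status)
  if (!is.null(group)) {
    if (length(group) != length(time))
      stop("'group' length differs from 'time'")
    if (anyNA(group)) stop("missing group labels")
    lev <- sort(unique(as.character(group)))
    if (!is.null(ref)) {
      ref <- as.character(ref)
      if (!ref %in% lev) stop("ref group '", ref, "' not present in data")
      lev <- c(ref, setdiff(lev, ref))
    }
    out$group <- factor(as.character(group), levels = lev)
    if (nlevels(out$group) != 2L)
      stop("two-sample procedures need exactly 2 groups, found ",
           nlevels(out$group))
    if (any(table(out$group) == 0L)) stop("each group must be non-empty")
  }
  class(out) <- c("cr_sample", "data.frame")
  out
}

#' Read a competing-risks sample from delimited text
#'
#' Expects a header row with columns \code{time} (numeric), \code{status}
#' (integer 0/1/2) and optionally \code{group}; other columns are ignored.
#' Malformed rows are reported with their line numbers.
#'
#' @param path path to a CSV (or other delimited) file.
#' @param time_col,status_col,group_col column names; set
#'   \code{group_col = NULL} for a one-group sample.
#' @param sep field separator, default comma.
#' @param ref optional reference group label, passed to [cr_sample()].
#' @return A \code{"cr_sample"} data frame.
#' @export
read_cr_sample <- function(path, time_col = "time", status_col = "status",
                           group_col = "group", sep = ",", ref = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, comment.char = "")
  need <- c(time_col, status_col)
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("missing required column(s): ", paste(miss, collapse = ", "))
  tm <- suppressWarnings(as.numeric(df[[time_col]]))
  st <- suppressWarnings(as.integer(df[[status_col]]))
  # +1 for the header row so the message matches the file's line numbers
  bad <- which(is.na(tm) | tm < 0 | is.na(st) | st < 0L)
  if (length(bad))
    stop("malformed row(s) at file line(s): ",
         paste(utils::head(bad + 1L, 10L), collapse = ", "))
  grp <- NULL
  if (!is.null(group_col) && group_col %in% names(df)) grp <- df[[group_col]]
  cr_sample(tm, st, group = grp, ref = ref)
}

#' Write a competing-risks sample to CSV
#'
#' @param x a \code{"cr_sample"}.
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
write_cr_sample <- function(x, path) {
  stopifnot(inherits(x, "cr_sample"))
  df <- as.data.frame(x)
  # full double precision so a round trip reproduces analyses bit-exactly
  df$time <- sprintf("%.17g", df$time)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Split a two-group sample into its per-group components
#' @param x a two-group \code{"cr_sample"}.
#' @return A named list of two one-group \code{"cr_sample"} objects, in
#'   level order (reference first).
#' @export
split_groups <- function(x) {
  stopifnot(inherits(x, "cr_sample"))
  if (is.null(x$group)) stop("sample has no 'group' column")
  lev <- levels(x$group)
  out <- lapply(lev, function(g) {
    i <- x$group == g
    cr_sample(x$time[i], x$status[i])
  })
  names(out) <- lev
  out
}

#' Bind two one-group samples into a labelled two-group sample
#' @param a,b one-group \code{"cr_sample"} objects.
#' @param labels length-2 character vector of group labels (reference first).
#' @return A two-group \code{"cr_sample"}.
#' @export
bind_groups <- function(a, b, labels = c("1", "2")) {
  cr_sample(c(a$time, b$time), c(a$status, b$status),
            group = rep(labels, c(nrow(a), nrow(b))), ref = labels[1L])
}

#' @export
print.cr_sample <- function(x, ...) {
  cat("Competing-risks sample: ", nrow(x), " subjects\n", sep = "")
  tab <- table(factor(x$status, levels = 0:max(2L, x$status)))
  cat("  status counts:",
      paste(sprintf("%s=%d", names(tab), tab), collapse = ", "), "\n")
  if (!is.null(x$group)) {
    gt <- table(x$group)
    cat("  groups:",
        paste(sprintf("%s (n=%d)", names(gt), gt), collapse = ", "), "\n")
  }
  invisible(x)
}
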