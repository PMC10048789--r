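#' Normalize a ratio vector to proportions
#'
#' Converts a vector of nonnegative ratio values (e.g. raw cause counts
#' `2:6:7:7`) to proportions summing to one. Order is preserved and the
#' result is scale-invariant: `normalize_weights(k * x)` equals
#' `normalize_weights(x)` for any `k > 0`.
#'
#' @param ratios Numeric vector, all entries `>= 0`, at least one `> 0`.
#' @return Numeric vector of the same length summing to 1.
#' @examples
#' round(normalize_weights(c(2, 6, 7, 7)), 2)   # 0.09 0.27 0.32 0.32
#' round(normalize_weights(c(21, 77, 44)), 2)   # 0.15 0.54 0.31
#' @export
normalize_weights <- function(ratios) {
  if (!is.numeric(ratios) || length(ratios) == 0 || anyNA(ratios))
    stop("`ratios` must be a non-empty numeric vector without NA",
         call. = FALSE)
  if (any(ratios < 0))
    stop("invalid ratios: negative entries are not allowed", call. = FALSE)
  total <- sum(ratios)
  if (total <= 0)
    stop("invalid ratios: at least one entry must be positive",
         call. = FALSE)
  ratios / total
}

#' Construct and validate a weight table
#'
#' A weight table holds one proportion vector per weight group of the cause
#' taxonomy. Each vector must match the group's element count and sum to 1
#' within `1e-3` (published vectors are rounded to at most four decimals, so
#' their sums can be off by a few 1e-4).
#'
#' @param ... Named numeric vectors, one per group `a`..`h`; alternatively a
#'   single named list.
#' @param taxonomy A `cause_taxonomy` giving the expected group sizes.
#' @return An object of class `weight_table` (a named list of proportion
#'   vectors named by element code).
#' @seealso [default_weights()], [estimate_weights()]
#' @export
weight_table <- function(..., taxonomy = default_taxonomy()) {
  dots <- list(...)
  if (length(dots) == 1 && is.list(dots[[1]]) && is.null(names(dots)[1]))
    dots <- dots[[1]]
  validate_taxonomy(taxonomy)
  if (!setequal(names(dots), names(taxonomy)))
    stop("weight table must contain exactly the groups ",
         paste(names(taxonomy), collapse = ", "), call. = FALSE)
  out <- list()
  for (id in names(taxonomy)) {
    w <- as.numeric(dots[[id]])
    ne <- length(taxonomy[[id]]$elements)
    if (length(w) != ne)
      stop(sprintf("group '%s' expects %d weights, got %d", id, ne,
                   length(w)), call. = FALSE)
    if (anyNA(w) || any(w < 0) || any(w > 1))
      stop(sprintf("group '%s': weights must lie in [0, 1]", id),
           call. = FALSE)
    if (abs(sum(w) - 1) > 1e-3)
      stop(sprintf("group '%s': weights sum to %.6f, not 1 within 1e-3",
                   id, sum(w)), call. = FALSE)
    out[[id]] <- stats::setNames(w, taxonomy[[id]]$elements)
  }
  structure(out, class = "weight_table")
}

#' Default layer weights estimated from coal and gas outburst accidents
#'
#' The default weight vectors come from a cause analysis of 84 coal and gas
#' outburst accidents. Groups `a` and `b` are published as raw cause-count
#' ratios (`2:6:7:7` and `21:77:44`) and are normalised exactly here rather
#' than taken at their 2-decimal rounding; the remaining groups are
#' published as decimals and are used verbatim.
#'
#' @param taxonomy A `cause_taxonomy`.
#' @return A `weight_table`.
#' @examples
#' default_weights()$h   # 0.5 0.1 0.2 0.2
#' @export
default_weights <- function(taxonomy = default_taxonomy()) {
  weight_table(
    a = normalize_weights(c(2, 6, 7, 7)),
    b = normalize_weights(c(21, 77, 44)),
    c = c(0.08, 0.08, 0.21, 0.17, 0.12, 0.17, 0.17),
    d = c(0.2, 0.5, 0.3),
    e = c(0.7896, 0.0861, 0.0615, 0.0232, 0.0137, 0.0178, 0.0082),
    f = c(0.6066, 0.2049, 0.1885),
    g = c(0.4085, 0.2022, 0.2336, 0.1557),
    h = c(0.5, 0.1, 0.2, 0.2),
    taxonomy = taxonomy
  )
}

#' Estimate layer weights from accident-cause records
#'
#' For every weight group, the estimated weight of an element is its summed
#' occurrence count divided by the group's total count — the maximum
#' likelihood estimate under multinomial sampling of causes within a group.
#'
#' @param records A data frame of cause records with columns `accident_id`,
#'   `group_id`, `element_code`, `count` (see [read_cause_records()]).
#' @param taxonomy A `cause_taxonomy`.
#' @return A `weight_table`.
#' @export
estimate_weights <- function(records, taxonomy = default_taxonomy()) {
  validate_taxonomy(taxonomy)
  records <- validate_cause_records(records, taxonomy)
  w <- list()
  for (id in names(taxonomy)) {
    codes <- taxonomy[[id]]$elements
    sub <- records[records$group_id == id, , drop = FALSE]
    tot <- vapply(codes, function(cc)
      sum(sub$count[sub$element_code == cc]), numeric(1))
    if (sum(tot) <= 0)
      stop(sprintf("cannot estimate weights: group '%s' has zero total count",
                   id), call. = FALSE)
    w[[id]] <- normalize_weights(tot)
  }
  weight_table(w, taxonomy = taxonomy)
}

#' Validate a cause-record data frame against a taxonomy
#'
#' @param records Data frame with columns `accident_id`, `group_id`,
#'   `element_code`, `count`.
#' @param taxonomy A `cause_taxonomy`.
#' @return The records, with `count` coerced to integer, invisibly valid.
#' @export
validate_cause_records <- function(records, taxonomy = default_taxonomy()) {
  need <- c("accident_id", "group_id", "element_code", "count")
  if (!is.data.frame(records) || !all(need %in% names(records)))
    stop("cause records must be a data frame with columns ",
         paste(need, collapse = ", "), call. = FALSE)
  if (nrow(records) == 0) return(records)
  if (anyNA(records$count) || any(records$count < 0) ||
      any(records$count != round(records$count)))
    stop("`count` must be a nonnegative integer", call. = FALSE)
  bad_grp <- setdiff(unique(records$group_id), names(taxonomy))
  if (length(bad_grp))
    stop("unknown group_id: ", paste(bad_grp, collapse = ", "),
         call. = FALSE)
  for (id in unique(records$group_id)) {
    codes <- taxonomy[[id]]$elements
    bad <- setdiff(unique(records$element_code[records$group_id == id]),
                   codes)
    if (length(bad))
      stop(sprintf("element codes not in group '%s': %s", id,
                   paste(bad, collapse = ", ")), call. = FALSE)
  }
  records$count <- as.integer(records$count)
  records
}

#' @export
print.weight_table <- function(x, ...) {
  cat("Layer weight table\n")
  for (id in names(x))
    cat(sprintf("  %s: %s\n", id,
                paste(formatC(x[[id]], format = "f", digits = 4),
                      collapse = " ")))
  invisible(x)
}

#' Write / read a weight table as JSON
#'
#' The JSON representation is a named object of named proportion vectors
#' and round-trips losslessly at full double precision.
#'
#' @param weights A `weight_table`.
#' @param path File path.
#' @return `write_weight_table()` returns `path` invisibly;
#'   `read_weight_table()` returns a `weight_table`.
#' @export
write_weight_table <- function(weights, path) {
  stopifnot(inherits(weights, "weight_table"))
  jsonlite::write_json(lapply(weights, as.list), path, digits = NA,
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' @rdname write_weight_table
#' @param taxonomy A `cause_taxonomy` used to validate what was read.
#' @export
read_weight_table <- function(path, taxonomy = default_taxonomy()) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  weight_table(lapply(raw, unlist), taxonomy = taxonomy)
}

#' Write / read accident-cause records as CSV
#'
#' UTF-8 CSV with header `accident_id,group_id,element_code,count`.
#'
#' @param records Cause-record data frame.
#' @param path File path.
#' @export
write_cause_records <- function(records, path) {
  need <- c("accident_id", "group_id", "element_code", "count")
  stopifnot(is.data.frame(records), all(need %in% names(records)))
  utils::write.csv(records[, need, drop = FALSE], path, row.names = FALSE,
                   quote = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname write_cause_records
#' @param taxonomy A `cause_taxonomy` to validate against.
#' @export
read_cause_records <- function(path, taxonomy = default_taxonomy()) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        fileEncoding = "UTF-8",
                        colClasses = c(accident_id = "character",
                                       group_id = "character",
                                       element_code = "character",
                                       count = "integer"))
  validate_cause_records(df, taxonomy)
}
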