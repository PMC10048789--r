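#' Generate synthetic accident-cause records
#'
#' Emulates a cause tally over the 24Model taxonomy, such as the 84-accident
#' coal and gas outburst analysis that parameterises the default weights.
#' For every accident and weight group, the number of recorded cause
#' occurrences is drawn as `Poisson(mean_causes_per_group)` and allocated to
#' the group's elements by a multinomial draw with the supplied true
#' proportions. Identical inputs and seed reproduce identical records.
#'
#' Only elements with a positive count appear in the output; a group can
#' therefore be absent from a very small dataset, in which case
#' [estimate_weights()] refuses to estimate it.
#'
#' @param taxonomy A `cause_taxonomy`.
#' @param true_weights A `weight_table` of true element proportions.
#' @param n_accidents Number of accidents (0 gives an empty record set).
#' @param mean_causes_per_group Expected cause occurrences recorded per
#'   accident and group (default 3, a typical density for multi-cause
#'   accident investigations).
#' @param seed Integer RNG seed (mandatory; no silent nondeterminism).
#' @return A cause-record data frame with columns `accident_id`,
#'   `group_id`, `element_code`, `count`.
#' @examples
#' rec <- generate_accident_records(n_accidents = 5, seed = 1)
#' head(rec)
#' @export
generate_accident_records <- function(taxonomy = default_taxonomy(),
                                      true_weights = default_weights(taxonomy),
                                      n_accidents = 84,
                                      mean_causes_per_group = 3,
                                      seed) {
  validate_taxonomy(taxonomy)
  stopifnot(inherits(true_weights, "weight_table"))
  if (missing(seed) || !is.numeric(seed) || length(seed) != 1)
    stop("`seed` is required and must be a single integer", call. = FALSE)
  if (!is.numeric(n_accidents) || length(n_accidents) != 1 ||
      n_accidents != round(n_accidents) || n_accidents < 0)
    stop("`n_accidents` must be a single nonnegative integer",
         call. = FALSE)
  if (mean_causes_per_group <= 0)
    stop("`mean_causes_per_group` must be positive", call. = FALSE)

  empty <- data.frame(accident_id = character(), group_id = character(),
                      element_code = character(), count = integer(),
                      stringsAsFactors = FALSE)
  if (n_accidents == 0) return(empty)

  out <- local_rng(seed, {
    # Poisson occurrence totals per (accident, group), each occurrence
    # allocated independently by the true proportions -- equivalent to a
    # multinomial split of the Poisson total, but vectorised per group.
    per_group <- lapply(names(taxonomy), function(id) {
      codes <- taxonomy[[id]]$elements
      m <- stats::rpois(n_accidents, mean_causes_per_group)
      total <- sum(m)
      if (total == 0) return(NULL)
      acc <- rep(seq_len(n_accidents), m)
      el <- sample(codes, total, replace = TRUE,
                   prob = true_weights[[id]])
      tab <- table(accident = acc, element = factor(el, levels = codes))
      idx <- which(tab > 0, arr.ind = TRUE)
      data.frame(
        accident_id = sprintf("ACC%04d",
                              as.integer(rownames(tab))[idx[, 1]]),
        group_id = id,
        element_code = codes[idx[, 2]],
        count = as.integer(tab[idx]),
        stringsAsFactors = FALSE)
    })
    per_group <- per_group[!vapply(per_group, is.null, logical(1))]
    if (length(per_group) == 0) empty else do.call(rbind, per_group)
  })
  out <- out[order(out$accident_id, out$group_id, out$element_code), ,
             drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Evaluate an expression under a local, restored RNG state
#'
#' Sets the RNG to Mersenne-Twister with the given seed for the duration of
#' `expr` and restores the caller's RNG state afterwards, so that synthetic
#' data generation never perturbs user-level randomness.
#'
#' @param seed Integer seed.
#' @param expr Expression to evaluate.
#' @keywords internal
local_rng <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed), kind = "Mersenne-Twister")
  expr
}
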