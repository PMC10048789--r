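#' The 24Model cause taxonomy
#'
#' The accident-cause taxonomy groups causes into eight weight groups, one
#' per weighted sum appearing in the simulation equations:
#'
#' * `a` — safety-culture element categories feeding the SC stock (4 elements);
#' * `b` — organisational-structure sub-elements feeding SM2 (3);
#' * `c` — safety-procedure sub-elements feeding SM3 (7);
#' * `d` — the three safety-management sub-systems weighted inside the SM
#'   layer uptake (policy SM1, structure SM2, procedures SM3);
#' * `e` — safety-knowledge sub-elements feeding SA1 (7);
#' * `f` — safety-awareness sub-elements feeding SA2 (3);
#' * `g` — safety-psychology sub-elements feeding SA4 (4);
#' * `h` — the four safety-ability components weighted inside the SA layer
#'   uptake (knowledge SA1, awareness SA2, habits SA3, psychology SA4).
#'
#' Element codes for groups whose member names are not fully documented in
#' the source accident analyses (`c`, `e`, `g` and parts of `b`) carry
#' generic labels; the codes themselves are the stable identifiers.
#'
#' @param a_category_map Named character vector mapping the four `a`-group
#'   element codes (`SC1`..`SC4`) to culture category labels. The assignment
#'   of indices to categories is not uniquely determined by the published
#'   weights, so it is configurable; the default places the concept category
#'   on `SC1` (the smallest weight) and the measures category on `SC4`.
#' @return An object of class `cause_taxonomy`: a named list of groups, each
#'   with `group_id`, `layer` (a human-readable layer name), `elements`
#'   (ordered element codes) and `labels` (display names).
#' @examples
#' tax <- default_taxonomy()
#' vapply(tax, function(g) length(g$elements), integer(1))
#' @export
default_taxonomy <- function(a_category_map = c(
                               SC1 = "safety concept elements",
                               SC2 = "safety discipline elements",
                               SC3 = "safety responsibility elements",
                               SC4 = "safety measures elements")) {
  stopifnot(is.character(a_category_map))
  a_codes <- paste0("SC", 1:4)
  if (!setequal(names(a_category_map), a_codes))
    stop("`a_category_map` must be named by the codes SC1..SC4", call. = FALSE)
  grp <- function(id, layer, elements, labels = elements) {
    list(group_id = id, layer = layer, elements = elements,
         labels = stats::setNames(labels, elements))
  }
  structure(list(
    a = grp("a", "safety culture element categories", a_codes,
            unname(a_category_map[a_codes])),
    b = grp("b", "safety management organisational structure (SM2)",
            paste0("SM2", 1:3),
            c("mechanism setup", "responsibility assignment",
              "personnel allocation")),
    c = grp("c", "safety management procedures (SM3)",
            paste0("SM3", 1:7),
            paste("procedure element", 1:7)),
    d = grp("d", "safety management sub-systems",
            c("SM1", "SM2", "SM3"),
            c("safety policy", "safety management organisational structure",
              "safety management procedures")),
    e = grp("e", "safety knowledge (SA1)", paste0("SA1", 1:7),
            paste("knowledge element", 1:7)),
    f = grp("f", "safety awareness (SA2)", paste0("SA2", 1:3),
            c("safety regulation awareness", "safety risk awareness",
              "safety responsibility awareness")),
    g = grp("g", "safety psychology (SA4)", paste0("SA4", 1:4),
            paste("psychology element", 1:4)),
    h = grp("h", "safety ability components",
            paste0("SA", 1:4),
            c("safety knowledge", "safety awareness", "safety habits",
              "safety psychology"))
  ), class = "cause_taxonomy")
}

#' Expected element counts per weight group
#' @keywords internal
.group_sizes <- c(a = 4L, b = 3L, c = 7L, d = 3L, e = 7L, f = 3L,
                  g = 4L, h = 4L)

#' Validate a cause taxonomy
#'
#' Checks the fixed group sizes (a:4, b:3, c:7, d:3, e:7, f:3, g:4, h:4)
#' and uniqueness of element codes within each group.
#'
#' @param taxonomy A `cause_taxonomy`.
#' @return The taxonomy, invisibly, if valid; otherwise an error.
#' @export
validate_taxonomy <- function(taxonomy) {
  if (!inherits(taxonomy, "cause_taxonomy"))
    stop("not a `cause_taxonomy` object", call. = FALSE)
  if (!identical(names(taxonomy), names(.group_sizes)))
    stop("taxonomy must contain exactly the groups ",
         paste(names(.group_sizes), collapse = ", "), call. = FALSE)
  for (id in names(taxonomy)) {
    g <- taxonomy[[id]]
    if (length(g$elements) != .group_sizes[[id]])
      stop(sprintf("group '%s' must have %d elements, found %d",
                   id, .group_sizes[[id]], length(g$elements)), call. = FALSE)
    if (anyDuplicated(g$elements))
      stop(sprintf("duplicate element codes in group '%s'", id),
           call. = FALSE)
  }
  invisible(taxonomy)
}

#' @export
print.cause_taxonomy <- function(x, ...) {
  cat("24Model cause taxonomy:", length(x), "weight groups\n")
  for (g in x)
    cat(sprintf("  %s (%s): %s\n", g$group_id, g$layer,
                paste(g$elements, collapse = ", ")))
  invisible(x)
}

#' Write / read a cause taxonomy as JSON
#'
#' Serialises the group structure (id, layer name, element codes and
#' display labels); round-trips losslessly.
#'
#' @param taxonomy A `cause_taxonomy`.
#' @param path File path.
#' @export
write_taxonomy_json <- function(taxonomy, path) {
  validate_taxonomy(taxonomy)
  obj <- lapply(taxonomy, function(g)
    list(group_id = g$group_id, layer = g$layer,
         elements = as.list(g$elements), labels = as.list(g$labels)))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' @rdname write_taxonomy_json
#' @export
read_taxonomy_json <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  tax <- lapply(raw, function(g)
    list(group_id = g$group_id, layer = g$layer,
         elements = unlist(g$elements),
         labels = unlist(g$labels)))
  validate_taxonomy(structure(tax, class = "cause_taxonomy"))
  structure(tax, class = "cause_taxonomy")
}
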