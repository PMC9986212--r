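#' Item registry: the 120-item space and its subscale definitions
#'
#' The registry holds one record per inventory item (integer IDs 1--120) with a
#' short label where one is published, the syndrome-subscale assignment, and a
#' 0/1 membership flag per screening subscale. Item IDs follow the printed
#' CBCL 6-18 problem-item numbering for items 1--113 (56 denoting 56a), with
#' IDs 114--120 standing for items 56b--56h. The packaged registry transcribes
#' the published subscale memberships: the three syndrome subscales of interest
#' (Withdrawn/Depressed, Thought Problems, Social Problems), their combinations
#' (ASD profile, WTP), the two previously published specific ASD subscales
#' (Ooi, So), and the two newly constructed subscales (data-driven,
#' clinician-expert).
#'
#' @name registry
NULL

.SYNDROME_LEVELS <- c(
  "WithdrawnDepressed", "ThoughtProblems", "SocialProblems",
  "AttentionProblems", "AnxiousDepressed", "AggressiveBehavior",
  "RuleBreaking", "SomaticComplaints", "OtherProblems", "none"
)

#' Create a subscale definition
#'
#' @param name Subscale name (a single string).
#' @param item_ids Integer vector of item IDs in 1..120.
#' @return An object of class `subscale_definition`: a list with elements
#'   `name` and `item_ids` (sorted, unique).
#' @export
subscale_definition <- function(name, item_ids) {
  stopifnot(is.character(name), length(name) == 1L)
  item_ids <- as.integer(item_ids)
  if (anyNA(item_ids) || any(item_ids < 1L | item_ids > 120L)) {
    stop("item_ids must be integers in 1..120", call. = FALSE)
  }
  structure(list(name = name, item_ids = sort(unique(item_ids))),
            class = "subscale_definition")
}

#' @export
#' @method print subscale_definition
print.subscale_definition <- function(x, ...) {
  cat(sprintf("<subscale '%s': %d items>\n", x$name, length(x$item_ids)))
  invisible(x)
}

#' @export
length.subscale_definition <- function(x) length(x$item_ids)

#' Path to the packaged item registry
#'
#' @return File path of the CSV registry shipped with the package.
#' @export
default_registry_path <- function() {
  system.file("extdata", "cbcl_asd_registry.csv", package = "cbclscreen",
              mustWork = TRUE)
}

#' Load an item registry
#'
#' Reads a registry CSV (header row; columns `item_id`, `label`, `syndrome`,
#' plus one 0/1 column per subscale) and validates it: item IDs must be unique
#' integers in 1..120, syndromes must be known level names, and membership
#' flags must be 0/1.
#'
#' @param path Registry file; defaults to the packaged registry.
#' @return An object of class `item_registry`: a list with `items` (data.frame
#'   of `item_id`, `label`, `syndrome`) and `subscales` (named list of
#'   [subscale_definition()] objects, one per flag column).
#' @export
load_registry <- function(path = default_registry_path()) {
  if (!file.exists(path)) stop("registry file not found: ", path, call. = FALSE)
  reg <- tryCatch(
    utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE),
    error = function(e) stop("failed to parse registry file '", path, "': ",
                             conditionMessage(e), call. = FALSE)
  )
  required <- c("item_id", "label", "syndrome")
  missing_cols <- setdiff(required, names(reg))
  if (length(missing_cols)) {
    stop("registry is missing column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  reg$item_id <- suppressWarnings(as.integer(reg$item_id))
  if (anyNA(reg$item_id) || any(reg$item_id < 1L | reg$item_id > 120L)) {
    stop("registry item_id values must be integers in 1..120", call. = FALSE)
  }
  if (anyDuplicated(reg$item_id)) {
    dups <- unique(reg$item_id[duplicated(reg$item_id)])
    stop("duplicate item_id in registry: ", paste(dups, collapse = ", "),
         call. = FALSE)
  }
  reg$label[is.na(reg$label)] <- ""
  bad_syn <- setdiff(unique(reg$syndrome), .SYNDROME_LEVELS)
  if (length(bad_syn)) {
    stop("unknown syndrome value(s): ", paste(bad_syn, collapse = ", "),
         call. = FALSE)
  }
  flag_cols <- setdiff(names(reg), required)
  subscales <- list()
  for (col in flag_cols) {
    v <- reg[[col]]
    if (!all(v %in% c(0L, 1L))) {
      stop("subscale column '", col, "' must contain only 0/1", call. = FALSE)
    }
    subscales[[col]] <- subscale_definition(col, reg$item_id[v == 1L])
  }
  out <- structure(
    list(items = reg[, required], subscales = subscales),
    class = "item_registry"
  )
  validate_registry_unions(out)
  out
}

# The ASD profile and WTP subscales are defined as unions of syndrome
# subscales; check this whenever all constituents are present.
validate_registry_unions <- function(registry) {
  s <- registry$subscales
  has <- function(nm) nm %in% names(s)
  if (has("ASDProfile") && all(vapply(c("WithdrawnDepressed", "ThoughtProblems",
                                        "SocialProblems"), has, logical(1)))) {
    u <- sort(unique(c(s$WithdrawnDepressed$item_ids, s$ThoughtProblems$item_ids,
                       s$SocialProblems$item_ids)))
    if (!identical(u, s$ASDProfile$item_ids)) {
      stop("ASDProfile must equal the union of Withdrawn/Depressed, Thought ",
           "Problems and Social Problems", call. = FALSE)
    }
  }
  if (has("WTP") && has("WithdrawnDepressed") && has("ThoughtProblems")) {
    u <- sort(unique(c(s$WithdrawnDepressed$item_ids, s$ThoughtProblems$item_ids)))
    if (!identical(u, s$WTP$item_ids)) {
      stop("WTP must equal the union of Withdrawn/Depressed and Thought Problems",
           call. = FALSE)
    }
  }
  invisible(registry)
}

#' @export
#' @method print item_registry
print.item_registry <- function(x, ...) {
  cat(sprintf("<item registry: %d items, %d subscales>\n",
              nrow(x$items), length(x$subscales)))
  for (s in x$subscales) cat(sprintf("  %-20s %3d items\n", s$name, length(s)))
  invisible(x)
}

#' Number of items shared by two subscales
#'
#' @param a,b [subscale_definition()] objects over the same item space.
#' @return Non-negative integer count of common items.
#' @export
item_overlap <- function(a, b) {
  stopifnot(inherits(a, "subscale_definition"), inherits(b, "subscale_definition"))
  length(intersect(a$item_ids, b$item_ids))
}

#' Syndrome composition of a subscale
#'
#' Counts a subscale's items per syndrome subscale, in the sense of the
#' published composition sentences ("five were from the Withdrawn/Depressed,
#' ..."). Items assigned to no syndrome are counted under `none`.
#'
#' @param subscale A [subscale_definition()].
#' @param registry An [load_registry()] result supplying syndrome assignments.
#' @return Named integer vector over all syndrome levels; sums to the subscale
#'   size.
#' @export
composition_by_syndrome <- function(subscale, registry) {
  stopifnot(inherits(subscale, "subscale_definition"),
            inherits(registry, "item_registry"))
  syn <- registry$items$syndrome[match(subscale$item_ids, registry$items$item_id)]
  if (anyNA(syn)) {
    stop("subscale references item IDs absent from the registry", call. = FALSE)
  }
  tab <- table(factor(syn, levels = .SYNDROME_LEVELS))
  out <- as.integer(tab)
  names(out) <- .SYNDROME_LEVELS
  out
}
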