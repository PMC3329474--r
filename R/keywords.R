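#' Contamination-category keyword table
#'
#' Returns the default keyword table used to assign a contamination category
#' to a notification from its free-text hazard description. Each category is
#' mapped to a set of lower-case key components; a hazard is assigned to a
#' category when its text contains one of that category's keywords as a
#' case-insensitive substring.
#'
#' The default table covers the five dominant contaminant classes of EU
#' food/feed notifications: heavy metals, mycotoxins, bacteria, chemicals and
#' a residual "other" class of named low-frequency contaminants. Categories
#' are ordered; when a hazard text matches keywords from several categories
#' the first matching category in this order wins (see
#' [categorize_hazard()]).
#'
#' @param table Optional named list `category -> character vector of keywords`
#'   to validate and use instead of the default.
#' @return A named list of class `keyword_table`: one character vector of
#'   unique, non-empty, lower-case keywords per category, in priority order.
#' @examples
#' rasff_keywords()
#' @export
rasff_keywords <- function(table = NULL) {
  if (is.null(table)) {
    table <- list(
      metal     = c("arsenic", "lead", "mercury", "cadmium"),
      mycotoxin = c("aflatoxin", "fumonisin", "ochratoxin"),
      bacteria  = c("salmonella", "bacillus cereus", "listeria monocytogenes"),
      chemical  = c("benzoic acid", "colour sudan 1", "methomyl",
                    "nitrofuran", "sulphites"),
      other     = c("chloramphenicol", "dioxins", "methamidophos")
    )
  }
  if (!is.list(table) || is.null(names(table)) || any(!nzchar(names(table)))) {
    stop("keyword table must be a named list of character vectors", call. = FALSE)
  }
  table <- lapply(table, function(k) {
    k <- tolower(trimws(as.character(k)))
    if (length(k) == 0L || any(!nzchar(k))) {
      stop("each category needs at least one non-empty keyword", call. = FALSE)
    }
    if (anyDuplicated(k)) {
      stop("keywords must be unique within a category", call. = FALSE)
    }
    k
  })
  structure(table, class = "keyword_table")
}

#' Hazard categories recognized by the package
#'
#' The derived `category` field of a notification takes one of the keyword
#' table's categories or `"uncategorized"`.
#'
#' @param table A keyword table (default [rasff_keywords()]).
#' @return Character vector of category labels, priority order first,
#'   `"uncategorized"` last.
#' @export
hazard_categories <- function(table = rasff_keywords()) {
  c(names(table), "uncategorized")
}

#' Assign contamination categories to hazard texts
#'
#' Case-insensitive substring matching of hazard free text against a keyword
#' table. Text matching no keyword is `"uncategorized"`. Text matching
#' keywords from more than one category is assigned to the first matching
#' category in table order, and a warning summarizes how many records were
#' ambiguous; all matched categories are retained in the `"matches"`
#' attribute for diagnostics.
#'
#' The function is total and deterministic: any character input (including
#' `""` and `NA`) yields exactly one category per element.
#'
#' @param text Character vector of hazard descriptions.
#' @param table Keyword table, see [rasff_keywords()].
#' @param quiet Suppress the multi-match warning.
#' @return Character vector of categories, same length as `text`, with a
#'   `"matches"` attribute: a list of all matching categories per element.
#' @examples
#' categorize_hazard("Aflatoxin B1 in pistachio kernels")  # mycotoxin
#' categorize_hazard("incorrect labelling of allergens")   # uncategorized
#' @export
categorize_hazard <- function(text, table = rasff_keywords(), quiet = FALSE) {
  table <- rasff_keywords(unclass(table))
  text <- as.character(text)
  low <- tolower(text)
  low[is.na(low)] <- ""
  cats <- names(table)
  # category x text logical match matrix
  hit <- vapply(cats, function(cat) {
    m <- rep(FALSE, length(low))
    for (kw in table[[cat]]) m <- m | grepl(kw, low, fixed = TRUE)
    m
  }, logical(length(low)))
  hit <- matrix(hit, nrow = length(low), dimnames = list(NULL, cats))
  nmatch <- rowSums(hit)
  out <- rep("uncategorized", length(low))
  any_hit <- nmatch > 0L
  if (any(any_hit)) {
    first <- apply(hit[any_hit, , drop = FALSE], 1L, function(r) cats[which(r)[1L]])
    out[any_hit] <- first
  }
  if (!quiet && any(nmatch > 1L)) {
    warning(sum(nmatch > 1L), " hazard text(s) matched keywords from more ",
            "than one category; first category in table order was used",
            call. = FALSE)
  }
  matches <- lapply(seq_along(low), function(i) cats[hit[i, ]])
  attr(out, "matches") <- matches
  out
}
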