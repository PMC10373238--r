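#' Analytical eco-scale greenness score
#'
#' The analytical eco-scale starts from an ideal score of 100 and subtracts
#' penalty points for every deviation from green-analytical-chemistry
#' principles: reagent amounts and hazards, energy consumption, occupational
#' exposure, and waste. Scores above 75 denote an excellent green analysis,
#' 50-75 acceptable, below 50 inadequate.
#'
#' @param penalties Non-negative integer penalty points: a named numeric
#'   vector, or a data frame with columns `item` and `points`.
#' @return An object of class `eco_scale` with elements `items` (tibble),
#'   `score` and `category`; [tidy()] returns the itemized penalties,
#'   [glance()] the score and category.
#' @export
#' @examples
#' eco_scale(c(ethanol = 8, acetonitrile = 6, waste = 5, energy = 2))
eco_scale <- function(penalties) {
  if (is.data.frame(penalties)) {
    items <- tibble(item = as.character(penalties$item),
                    points = penalties$points)
  } else {
    items <- tibble(
      item = names(penalties) %||% paste0("item_", seq_along(penalties)),
      points = as.numeric(penalties)
    )
  }
  if (any(is.na(items$points)) || any(items$points < 0) ||
      any(items$points != round(items$points))) {
    abort("Penalty points must be non-negative integers.",
          class = "specmix_invalid_penalty")
  }
  score <- 100 - sum(items$points)
  structure(
    list(items = items, score = score, category = eco_scale_category(score)),
    class = "eco_scale"
  )
}

#' @rdname eco_scale
#' @param score A numeric eco-scale score.
#' @export
eco_scale_category <- function(score) {
  dplyr::case_when(
    score > 75 ~ "excellent",
    score >= 50 ~ "acceptable",
    TRUE ~ "inadequate"
  )
}

#' @export
print.eco_scale <- function(x, ...) {
  cat(sprintf("<eco_scale> score %d (%s); %d penalty item(s), %d points total\n",
              x$score, x$category, nrow(x$items), sum(x$items$points)))
  invisible(x)
}

#' @export
tidy.eco_scale <- function(x, ...) x$items

#' @export
glance.eco_scale <- function(x, ...) {
  tibble(score = x$score, category = x$category,
         total_penalty = sum(x$items$points))
}
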