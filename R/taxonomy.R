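#' The six consolidated leaf behavior categories
#'
#' Leaves are ordered canonically: two affiliative, two neutral, two avoidant.
#' This order fixes the class order used throughout the package (factor levels,
#' probability matrix columns, argmax tie-breaking).
#'
#' @return Character vector of length 6.
#' @export
#' @examples
#' behavior_leaves()
behavior_leaves <- function() {
  c("affiliative_active", "affiliative_subtle",
    "neutral_horse", "neutral_human",
    "avoidant_horse", "avoidant_human")
}

#' The three parent valence categories
#'
#' @return Character vector: affiliative, neutral, avoidant.
#' @export
behavior_parents <- function() {
  c("affiliative", "neutral", "avoidant")
}

#' Map a leaf category to its parent valence category
#'
#' Total over the six leaves: `affiliative_*` maps to affiliative, and so on.
#'
#' @param leaf Character vector of leaf category names.
#' @return Character vector of parent names, same length as `leaf`.
#' @export
#' @examples
#' leaf_parent(c("affiliative_subtle", "avoidant_human"))
leaf_parent <- function(leaf) {
  leaf <- as.character(leaf)
  bad <- !leaf %in% behavior_leaves()
  if (any(bad)) {
    stop("unknown leaf categor", if (sum(bad) > 1) "ies: " else "y: ",
         paste(unique(leaf[bad]), collapse = ", "))
  }
  sub("_(active|subtle|horse|human)$", "", leaf)
}

#' Default 13-behavior ethogram with consolidation mapping
#'
#' The shipped ethogram of 13 operationally defined behaviors, each carrying an
#' acting species, a parent valence category and the leaf category it
#' consolidates to. "Move Away" is the only actor-dependent code: it
#' consolidates to `avoidant_horse` or `avoidant_human` depending on which
#' subject moves away, so its `leaf` entry is `NA` and is resolved by
#' [consolidate()].
#'
#' @return A data.frame with columns `behavior`, `actor` (horse/human/either),
#'   `parent`, `leaf` and `definition`.
#' @export
default_ethogram <- function() {
  data.frame(
    behavior = c("Approach", "Touch", "Mutual Grooming", "Follow",
                 "Stand Together", "Explore Near",
                 "Graze", "Self-Groom", "Stand Still", "Wait",
                 "Move Away", "Ear Pin", "Back Away"),
    actor = c("either", "either", "either", "either",
              "either", "horse",
              "horse", "horse", "horse", "human",
              "either", "horse", "human"),
    parent = c(rep("affiliative", 6), rep("neutral", 4), rep("avoidant", 3)),
    leaf = c(rep("affiliative_active", 4), rep("affiliative_subtle", 2),
             rep("neutral_horse", 3), "neutral_human",
             NA, "avoidant_horse", "avoidant_human"),
    definition = c(
      "Deliberate movement toward partner, reducing distance",
      "Physical contact initiated by either species (nuzzle, stroke)",
      "Reciprocal grooming between horse and human",
      "Sustained movement maintaining proximity with partner",
      "Relaxed co-presence without active engagement",
      "Environmental investigation while maintaining proximity",
      "Horse feeding behavior without human-directed attention",
      "Horse self-maintenance (scratching, shaking, rolling)",
      "Horse stationary, aware of but not engaging human",
      "Human stationary, observing without initiating interaction",
      "Deliberate increase in distance from partner",
      "Ears flattened against head indicating stress/aggression",
      "Backward movement maintaining visual contact"),
    stringsAsFactors = FALSE
  )
}

# normalize a behavior code for matching: lower-case, collapse whitespace
.normalize_code <- function(x) {
  tolower(gsub("\\s+", " ", trimws(as.character(x))))
}

#' Consolidate ethogram behavior codes into leaf categories
#'
#' Matching is case-insensitive after whitespace normalization. Actor-dependent
#' codes (those whose `leaf` is `NA` in the ethogram, by default only
#' "Move Away") require `actor` to be `"horse"` or `"human"` and consolidate to
#' the corresponding avoidant leaf.
#'
#' @param behavior Character vector of behavior code names.
#' @param actor Character vector (recycled): `"horse"`, `"human"` or
#'   `"either"`.
#' @param ethogram An ethogram data.frame as returned by [default_ethogram()].
#' @return Character vector of leaf category names.
#' @export
#' @examples
#' consolidate("Graze", "horse")       # neutral_horse
#' consolidate("Move Away", "human")   # avoidant_human
consolidate <- function(behavior, actor = "either", ethogram = default_ethogram()) {
  n <- max(length(behavior), length(actor))
  behavior <- rep_len(as.character(behavior), n)
  actor <- rep_len(as.character(actor), n)
  idx <- match(.normalize_code(behavior), .normalize_code(ethogram$behavior))
  if (anyNA(idx)) {
    stop("unknown behavior code(s): ",
         paste(unique(behavior[is.na(idx)]), collapse = ", "))
  }
  leaf <- ethogram$leaf[idx]
  dep <- is.na(leaf)
  if (any(dep)) {
    bad <- dep & !actor %in% c("horse", "human")
    if (any(bad)) {
      stop("actor-dependent code(s) require actor 'horse' or 'human': ",
           paste(unique(behavior[bad]), collapse = ", "))
    }
    leaf[dep] <- paste0(ethogram$parent[idx[dep]], "_", actor[dep])
  }
  leaf
}
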