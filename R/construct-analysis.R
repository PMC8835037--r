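#' Map a 1..7 rating to a canonical activation in [-1, 1]
#'
#' The canonical frame is right-pole-positive: rating 7 ("very" like the
#' right pole) maps to +1, rating 1 ("very" like the left pole) to -1, the
#' midpoint 4 to 0. The map is `a = (r - 4) / 3`, the unique affine map with
#' those anchors, so the image of the scale is
#' {-1, -2/3, -1/3, 0, 1/3, 2/3, 1}.
#'
#' @param r integer rating(s) in 1..7 (vectorised).
#' @return numeric activation(s) in [-1, 1].
#' @export
#' @examples
#' rating_to_activation(c(1, 4, 7))  # -1 0 1
rating_to_activation <- function(r) {
  if (anyNA(r) || any(r < 1 | r > 7 | r != round(r)))
    stop("ratings must be integers in 1..7", call. = FALSE)
  (r - 4) / 3
}

#' Classify a construct as congruent, discrepant or dilemmatic
#'
#' A construct is *dilemmatic* when the Ideal-Self sits at the midpoint: the
#' person prefers neither pole, so no change direction is even defined (this
#' includes the fully undefined case with the Self-Now also at the
#' midpoint). It is *congruent* when Self-Now and Ideal-Self are on the same
#' pole (both strictly left or both strictly right of the midpoint): the
#' person is content. It is *discrepant* when they are on opposite poles, or
#' when the Self-Now is at the midpoint while the Ideal is not: change is
#' desired. The three statuses partition all 49 rating pairs.
#'
#' @param self_rating,ideal_rating integer ratings in 1..7 (vectorised,
#'   recycled).
#' @return A data frame of class `construct_status` with columns `status`
#'   (`"congruent"`, `"discrepant"` or `"dilemmatic"`), `self_activation`,
#'   `ideal_activation` and `desired_direction` (sign of ideal minus self in
#'   the canonical frame; 0 when no change is desired or definable).
#' @export
#' @examples
#' classify_construct(1, 7)  # discrepant, desired_direction +1
#' classify_construct(2, 1)  # congruent
#' classify_construct(3, 4)  # dilemmatic
classify_construct <- function(self_rating, ideal_rating) {
  k <- max(length(self_rating), length(ideal_rating))
  self_rating <- rep_len(self_rating, k)
  ideal_rating <- rep_len(ideal_rating, k)
  a <- rating_to_activation(self_rating)
  i <- rating_to_activation(ideal_rating)
  ss <- sign(a); si <- sign(i)
  status <- ifelse(si == 0, "dilemmatic",
            ifelse(ss == si, "congruent", "discrepant"))
  structure(
    data.frame(status = status,
               self_activation = a,
               ideal_activation = i,
               desired_direction = sign(i - a),
               stringsAsFactors = FALSE),
    class = c("construct_status", "data.frame")
  )
}

#' Classify every construct of a repertory grid
#'
#' @param grid a [repgrid()].
#' @return A `construct_status` data frame, one row per construct, with the
#'   pole labels prepended.
#' @export
classify_grid <- function(grid) {
  stopifnot(inherits(grid, "repgrid"))
  s <- grid$ratings[, role_index(grid, "self_now")]
  i <- grid$ratings[, role_index(grid, "ideal_self")]
  st <- classify_construct(s, i)
  cbind(grid$constructs[c("left_pole", "right_pole")], st)
}

#' Label a construct node by the pole the person currently occupies
#'
#' Nodes in the map digraph are named after the pole with which the person
#' defines themselves. A self rating below the midpoint selects the left
#' pole, above it the right pole. At the midpoint the label falls back to
#' the pole *opposite* the ideal pole (the person has not yet moved off the
#' undesired side); if the ideal is also at the midpoint the label combines
#' both poles.
#'
#' @param construct one-row data frame (or list) with `left_pole` and
#'   `right_pole`.
#' @param self_rating,ideal_rating integer ratings in 1..7.
#' @return character label.
#' @export
#' @examples
#' cns <- data.frame(left_pole = "overweight", right_pole = "correct weight")
#' self_pole_label(cns, 1, 7)  # "overweight"
self_pole_label <- function(construct, self_rating, ideal_rating) {
  stopifnot(length(self_rating) == 1L, length(ideal_rating) == 1L)
  rating_to_activation(c(self_rating, ideal_rating))  # range check
  if (self_rating < 4) return(construct$left_pole)
  if (self_rating > 4) return(construct$right_pole)
  if (ideal_rating < 4) return(construct$right_pole)
  if (ideal_rating > 4) return(construct$left_pole)
  paste(construct$left_pole, "vs", construct$right_pole)
}
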