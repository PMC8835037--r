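#' The packaged worked-example case
#'
#' A complete 12-construct x 11-element healthy-habits case for a person
#' who sees himself as very overweight, slightly uncontrolled in eating,
#' content with enjoying food, rather sedentary and wishing to be very
#' active, and unsure whether he is healthy — together with the implication
#' structure in which his desired changes (healthy eating, eating control,
#' willpower, health) are inversely tied to the "enjoys eating" pole he is
#' content with.
#'
#' Only a handful of its cells are anchored by the narrative the case
#' illustrates (construct 1's ratings 1, 4, 2, 5, 3 and ideal 7; construct
#' 2's self 3 / ideal 7; the three implications of construct 1, of
#' intensities very/very/quite). All remaining cells are fixed synthetic
#' completions, chosen once to realise the narrative (a stable system whose
#' desired changes are blocked), and flagged via
#' `meta$synthetic_completion`. The same case ships as a JSON file under
#' `inst/extdata/worked_example_synthetic.json`.
#'
#' @return A list with components `grid` (a [repgrid()]) and `imp` (an
#'   [impgrid()]).
#' @export
#' @examples
#' we <- worked_example()
#' we$grid
#' sum(we$imp$scores[1, ] != 0)  # the first construct implies 3 others
worked_example <- function() {
  constructs <- data.frame(
    left_pole = c("overweight", "uncontrolled eating", "enjoys eating",
                  "active", "healthy", "confident",
                  "weak willpower", "eats unhealthily", "sad",
                  "lazy", "stressed", "solitary"),
    right_pole = c("correct weight", "control of eating",
                   "indifferent to eating", "sedentary", "unhealthy",
                   "insecure", "strong willpower", "healthy eating",
                   "cheerful", "disciplined", "calm", "sociable"),
    predefined = rep(c(TRUE, FALSE), each = 6L),
    stringsAsFactors = FALSE
  )
  elements <- data.frame(
    label = c("Self-Now", "Self-in-a-year", "father", "mother",
              "partner / significant other", "overweight person",
              "not-overweight person", "person with healthy habits",
              "person without healthy habits", "persona non grata",
              "Ideal-Self"),
    role = c("self_now", "self_year", rep("other", 8L), "ideal_self"),
    stringsAsFactors = FALSE
  )
  ratings <- matrix(c(
    # self yr fa mo pa ow nw hh nh png ideal
      1, 4, 2, 5, 3, 1, 6, 6, 2, 3, 7,   # overweight | correct weight
      3, 4, 3, 5, 4, 2, 5, 6, 2, 2, 7,   # uncontrolled | control of eating
      2, 2, 2, 3, 2, 1, 4, 5, 2, 6, 2,   # enjoys | indifferent to eating
      6, 5, 5, 3, 4, 6, 2, 2, 6, 5, 1,   # active | sedentary
      4, 4, 3, 4, 4, 5, 3, 2, 5, 6, 1,   # healthy | unhealthy
      5, 4, 3, 3, 4, 5, 3, 3, 5, 6, 2,   # confident | insecure
      2, 3, 4, 5, 3, 2, 5, 6, 2, 3, 6,   # weak | strong willpower
      2, 3, 3, 5, 3, 1, 5, 6, 2, 2, 7,   # eats unhealthily | healthy eating
      5, 5, 4, 5, 5, 3, 5, 5, 4, 2, 6,   # sad | cheerful
      3, 3, 4, 5, 4, 3, 5, 6, 2, 3, 6,   # lazy | disciplined
      3, 3, 2, 4, 3, 3, 5, 5, 3, 2, 6,   # stressed | calm
      5, 5, 4, 5, 6, 4, 5, 5, 4, 2, 6    # solitary | sociable
  ), nrow = 12L, byrow = TRUE)
  grid <- repgrid(constructs, elements, ratings)

  # stored scores: right-pole-positive frame of the target; the hypothesized
  # change of each source runs from its current pole to the opposite pole
  s <- matrix(0L, 12L, 12L)
  s[1, c(4, 5, 6)] <- c(-3L, -3L, -2L)   # -> very active, very healthy, quite confident
  s[2, c(3, 5, 8)] <- c(2L, -2L, 2L)     # control -> less enjoyment, healthier, healthy eating
  s[3, c(2, 5, 7, 8)] <- c(3L, -2L, 2L, 3L)  # indifference -> control, health, willpower
  s[4, c(1, 5, 6)] <- c(2L, -2L, -1L)    # active -> correct weight, healthy, confident
  s[5, c(1, 3, 9)] <- c(2L, 2L, 1L)      # healthy -> correct weight, less enjoyment
  s[6, c(9, 12)] <- c(2L, 2L)            # confident -> cheerful, sociable
  s[7, c(2, 3, 10)] <- c(3L, 2L, 2L)     # willpower -> control, less enjoyment, discipline
  s[8, c(1, 3, 5)] <- c(2L, 3L, -3L)     # healthy eating -> weight, less enjoyment, very healthy
  s[9, 6] <- 2L                          # sadness -> insecurity
  s[10, c(2, 4)] <- c(2L, -2L)           # discipline -> control, activity
  s[11, c(5, 9)] <- c(-1L, 2L)           # calm -> healthier, cheerful
  s[12, 9] <- -2L                        # solitude -> sadness
  imp <- impgrid(constructs, s)
  list(grid = grid, imp = imp,
       meta = list(synthetic_completion = TRUE,
                   anchored_cells = "construct 1 ratings/implications; construct 2 self and ideal"))
}

#' Configuration for the random case generator
#'
#' Defaults mirror the healthy-habits study conditions: 12 constructs, 11
#' elements, roughly a quarter of the implication matrix populated, a
#' quarter of constructs congruent and none dilemmatic (the worked case's
#' census).
#'
#' @param n_constructs,n_elements grid dimensions (`n_elements >= 2`, to
#'   fit the Self-Now and Ideal-Self).
#' @param implication_density probability that an off-diagonal implication
#'   cell is nonzero.
#' @param congruent_fraction,dilemmatic_fraction target shares of construct
#'   statuses; the discrepant share is the remainder. Counts are allocated
#'   by round-half-up: `floor(fraction * n_constructs + 0.5)`.
#' @param seed integer seed; the only entropy source of [random_case()].
#' @return A list of class `generator_config`.
#' @export
generator_config <- function(n_constructs = 12L, n_elements = 11L,
                             implication_density = 0.25,
                             congruent_fraction = 0.25,
                             dilemmatic_fraction = 0,
                             seed = 1L) {
  stopifnot(n_constructs >= 1, n_elements >= 2,
            implication_density >= 0, implication_density <= 1,
            congruent_fraction >= 0, congruent_fraction <= 1,
            dilemmatic_fraction >= 0, dilemmatic_fraction <= 1)
  n_c <- floor(congruent_fraction * n_constructs + 0.5)
  n_d <- floor(dilemmatic_fraction * n_constructs + 0.5)
  if (n_c + n_d > n_constructs)
    stop("congruent and dilemmatic fractions are infeasible for this many constructs",
         call. = FALSE)
  structure(list(n_constructs = as.integer(n_constructs),
                 n_elements = as.integer(n_elements),
                 implication_density = implication_density,
                 congruent_fraction = congruent_fraction,
                 dilemmatic_fraction = dilemmatic_fraction,
                 n_congruent = n_c, n_dilemmatic = n_d,
                 seed = as.integer(seed)),
            class = "generator_config")
}

#' Generate a seeded random case
#'
#' Ratings are drawn uniformly on 1..7, then the Self-Now and Ideal-Self
#' cells are adjusted so the construct-status census matches the configured
#' fractions exactly (under the round-half-up allocation documented in
#' [generator_config()]): dilemmatic constructs get ideal = 4 with an
#' off-midpoint self; congruent constructs get self and ideal on the same
#' (randomly chosen) side; discrepant constructs get them on opposite
#' sides. Every off-diagonal implication cell is nonzero with probability
#' `implication_density`, with value uniform on {-3,-2,-1,1,2,3}. The same
#' configuration (including seed) always yields the identical case, and
#' every generated case passes [validate_case()] with no violations.
#'
#' The caller's RNG state is saved and restored.
#'
#' @param config a [generator_config()].
#' @return A list with components `grid` and `imp`.
#' @export
random_case <- function(config = generator_config()) {
  stopifnot(inherits(config, "generator_config"))
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old_seed <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old_seed, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()))
  }
  set.seed(config$seed)
  n <- config$n_constructs; m <- config$n_elements
  roles <- c("self_now", "ideal_self",
             if (m >= 3L) "self_year", rep("other", max(0L, m - 3L)))
  roles <- roles[seq_len(m)]
  labels <- ifelse(roles == "self_now", "Self-Now",
            ifelse(roles == "ideal_self", "Ideal-Self",
            ifelse(roles == "self_year", "Self-in-a-year",
                   paste("element", seq_len(m)))))
  constructs <- data.frame(
    left_pole = sprintf("construct %d left", seq_len(n)),
    right_pole = sprintf("construct %d right", seq_len(n)),
    predefined = FALSE, stringsAsFactors = FALSE
  )
  ratings <- matrix(sample(1:7, n * m, replace = TRUE), n, m)
  i_self <- which(roles == "self_now"); i_ideal <- which(roles == "ideal_self")
  status <- rep("discrepant", n)
  pick <- sample.int(n, config$n_congruent + config$n_dilemmatic)
  status[pick[seq_len(config$n_congruent)]] <- "congruent"
  if (config$n_dilemmatic > 0)
    status[pick[config$n_congruent + seq_len(config$n_dilemmatic)]] <- "dilemmatic"
  left_side <- function(k) sample(1:3, k, replace = TRUE)
  right_side <- function(k) sample(5:7, k, replace = TRUE)
  for (i in seq_len(n)) {
    side <- sample(c(-1L, 1L), 1L)
    draw <- function(s) if (s < 0) left_side(1L) else right_side(1L)
    if (status[i] == "dilemmatic") {
      ratings[i, i_self] <- draw(side)
      ratings[i, i_ideal] <- 4L
    } else if (status[i] == "congruent") {
      ratings[i, i_self] <- draw(side)
      ratings[i, i_ideal] <- draw(side)
    } else {
      ratings[i, i_self] <- draw(side)
      ratings[i, i_ideal] <- draw(-side)
    }
  }
  grid <- repgrid(constructs,
                  data.frame(label = labels, role = roles,
                             stringsAsFactors = FALSE),
                  ratings)
  s <- matrix(0L, n, n)
  if (n > 1L) {
    off <- which(row(s) != col(s))
    nz <- off[stats::runif(length(off)) < config$implication_density]
    s[nz] <- sample(c(-3:-1, 1:3), length(nz), replace = TRUE)
  }
  list(grid = grid, imp = impgrid(constructs, s))
}

#' @importFrom stats runif
NULL
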